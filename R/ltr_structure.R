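# Structural validation of candidate full-length LTR retrotransposons:
# Smith-Waterman boundary refinement, TG..CA termini, target-site
# duplications, primer binding sites, polypurine tracts, and superfamily
# classification from protein domain order.

# Fetch one scaffold sequence from a genome_records object (or accept a bare
# character string when only one sequence is in play).
get_scaffold <- function(genome, scaffold_id) {
  if (is.character(genome) && length(genome) == 1L && !grepl("^>", genome))
    return(toupper(genome))
  rec <- genome[[scaffold_id]]
  if (is.null(rec)) pm_domain_error(sprintf("scaffold '%s' not in genome", scaffold_id))
  rec$seq
}

as_candidate <- function(cand) {
  if (is.data.frame(cand)) {
    if (nrow(cand) != 1L) pm_domain_error("expected a single candidate row")
    cand <- as.list(cand)
  }
  cand
}

#' Refine LTR boundaries by local (Smith-Waterman) alignment
#'
#' Extracts a window around each LTR of a candidate element, locally aligns
#' the 5' region against the 3' region with affine gap penalties, and moves
#' the four LTR boundaries to the ends of the maximal-scoring local
#' alignment. The element interval is updated to run from the refined 5' LTR
#' start to the refined 3' LTR end.
#'
#' @param genome A `genome_records` object (or a single sequence string).
#' @param cand One candidate (single-row data.frame or list) with 1-based
#'   closed fields `scaffold_id, start, end, name, ltr5_start, ltr5_end,
#'   ltr3_start, ltr3_end`.
#' @param window Bases of context on each side of each LTR (default 50).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring (defaults
#'   +2/-2, open 5, extend 1).
#' @return The candidate with refined coordinates.
#' @export
refine_boundaries <- function(genome, cand, window = 50L, match = 2,
                              mismatch = -2, gap_open = 5, gap_extend = 1) {
  cand <- as_candidate(cand)
  seq <- get_scaffold(genome, cand$scaffold_id)
  lo5 <- cand$ltr5_start - window; hi5 <- cand$ltr5_end + window
  lo3 <- cand$ltr3_start - window; hi3 <- cand$ltr3_end + window
  if (lo5 < 1L || hi3 > nchar(seq))
    pm_domain_error("refinement window exceeds scaffold boundaries")
  hi5 <- min(hi5, cand$ltr3_start - 1L)  # keep the two regions disjoint
  lo3 <- max(lo3, cand$ltr5_end + 1L)
  r5 <- substr1(seq, lo5, hi5)
  r3 <- substr1(seq, lo3, hi3)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(r5), Biostrings::DNAString(r3), type = "local",
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_extend)
  p <- aln@pattern@range
  s <- aln@subject@range
  cand$ltr5_start <- lo5 + IRanges::start(p) - 1L
  cand$ltr5_end <- lo5 + IRanges::end(p) - 1L
  cand$ltr3_start <- lo3 + IRanges::start(s) - 1L
  cand$ltr3_end <- lo3 + IRanges::end(s) - 1L
  cand$start <- cand$ltr5_start
  cand$end <- cand$ltr3_end
  cand
}

#' Check the TG..CA terminal dinucleotides of an element
#'
#' @inheritParams refine_boundaries
#' @return TRUE iff the element starts with `TG` and ends with `CA`.
#' @export
check_termini <- function(genome, cand) {
  cand <- as_candidate(cand)
  seq <- get_scaffold(genome, cand$scaffold_id)
  substr1(seq, cand$start, cand$start + 1L) == "TG" &&
    substr1(seq, cand$end - 1L, cand$end) == "CA"
}

#' Find a target-site duplication flanking an element
#'
#' Searches for the longest exact direct repeat of length 4-6 ending at the
#' element's 5' edge and beginning at its 3' edge, allowing each edge to
#' jitter by at most `max_offset` bases. Ties are broken toward greater
#' length, then smaller total offset.
#'
#' @inheritParams refine_boundaries
#' @param max_offset Edge jitter in bp (default 2).
#' @param min_len,max_len TSD length range (defaults 4 and 6).
#' @return A list `(seq, len, offset5, offset3)` or `NULL` when absent.
#' @export
find_tsd <- function(genome, cand, max_offset = 2L, min_len = 4L, max_len = 6L) {
  cand <- as_candidate(cand)
  seq <- get_scaffold(genome, cand$scaffold_id)
  need <- max_len + max_offset
  if (cand$start - 1L < need || nchar(seq) - cand$end < need)
    pm_domain_error("insufficient flanking sequence for TSD search")
  best <- NULL
  for (len in seq(max_len, min_len)) {
    for (o5 in 0:max_offset) {
      left <- substr1(seq, cand$start - len - o5, cand$start - 1L - o5)
      for (o3 in 0:max_offset) {
        right <- substr1(seq, cand$end + 1L + o3, cand$end + len + o3)
        if (left == right) {
          score <- c(len, -(o5 + o3))
          if (is.null(best) || score[1L] > best$len ||
              (score[1L] == best$len && o5 + o3 < best$offset5 + best$offset3)) {
            best <- list(seq = left, len = len, offset5 = o5, offset3 = o3)
          }
        }
      }
    }
    if (!is.null(best)) break  # lengths scanned longest-first
  }
  best
}

#' Locate a primer binding site downstream of the 5' LTR
#'
#' Scans windows of length 15-18 starting within `search_window` bases after
#' the 5' LTR end; a window is a PBS hit when its reverse complement matches
#' the 3' end of a tRNA in the library at identity >= `min_identity`
#' (inclusive). The best hit (highest identity, then longer, then closer to
#' the LTR) is returned.
#'
#' @inheritParams refine_boundaries
#' @param trna_library Named character vector of tRNA 3'-end sequences
#'   (default: the bundled synthetic library, [default_trna_library()]).
#' @param search_window Bases after the 5' LTR end to consider (default 20).
#' @param min_identity Inclusive identity threshold (default 0.8).
#' @param min_len,max_len PBS length range (defaults 15 and 18).
#' @return A list `(start, end, len, trna, identity)` or `NULL`.
#' @export
find_pbs <- function(genome, cand, trna_library = default_trna_library(),
                     search_window = 20L, min_identity = 0.8,
                     min_len = 15L, max_len = 18L) {
  cand <- as_candidate(cand)
  if (length(trna_library) == 0L) pm_domain_error("empty tRNA library")
  seq <- get_scaffold(genome, cand$scaffold_id)
  best <- NULL
  for (off in 0:(search_window - 1L)) {
    s <- cand$ltr5_end + 1L + off
    for (len in seq(max_len, min_len)) {
      e <- s + len - 1L
      if (e > nchar(seq) || e >= cand$ltr3_start) next
      win <- substr1(seq, s, e)
      rc <- revcomp(win)
      for (tn in names(trna_library)) {
        tail3 <- trna_library[[tn]]
        L <- min(len, nchar(tail3))
        a <- chars(substr(rc, 1L, L))
        b <- chars(substr(tail3, nchar(tail3) - L + 1L, nchar(tail3)))
        ident <- sum(a == b) / L
        if (ident >= min_identity) {
          if (is.null(best) || ident > best$identity ||
              (ident == best$identity && len > best$len)) {
            best <- list(start = s, end = e, len = len, trna = tn,
                         identity = ident)
          }
        }
      }
    }
  }
  best
}

#' Locate a polypurine tract upstream of the 3' LTR
#'
#' Scans windows of length 20-25 ending within `search_window` bases before
#' the 3' LTR start; a window qualifies when its purine (A/G) fraction is at
#' least `min_purine`. Ties are broken toward higher purine fraction, then
#' longer windows, then windows closer to the LTR.
#'
#' @inheritParams refine_boundaries
#' @param search_window Bases upstream of the 3' LTR considered (default 20).
#' @param min_purine Inclusive purine-fraction threshold (default 0.9).
#' @param min_len,max_len PPT length range (defaults 20 and 25).
#' @return A list `(start, end, len, purine_fraction)` or `NULL`.
#' @export
find_ppt <- function(genome, cand, search_window = 20L, min_purine = 0.9,
                     min_len = 20L, max_len = 25L) {
  cand <- as_candidate(cand)
  seq <- get_scaffold(genome, cand$scaffold_id)
  best <- NULL
  for (back in 0:(search_window - 1L)) {
    e <- cand$ltr3_start - 1L - back
    for (len in seq(max_len, min_len)) {
      s <- e - len + 1L
      if (s < 1L || s <= cand$ltr5_end) next
      v <- chars(substr1(seq, s, e))
      frac <- mean(is_purine(v))
      if (frac >= min_purine) {
        better <- is.null(best) || frac > best$purine_fraction ||
          (frac == best$purine_fraction &&
             (len > best$len || (len == best$len && e > best$end)))
        if (better)
          best <- list(start = s, end = e, len = len, purine_fraction = frac)
      }
    }
  }
  best
}

#' Validate a candidate element against the four structural criteria
#'
#' Runs the TG..CA terminus check, the TSD search, the PBS search, and the
#' PPT search. Under the default rule the element passes when all four
#' criteria are satisfied; `rule = "any3"` requires at least three.
#'
#' @inheritParams find_pbs
#' @param config A [run_config()] carrying the search tunables.
#' @param rule `"all"` (default) or `"any3"`.
#' @return A list of class `structural_evidence`: `termini_ok`, `tsd`,
#'   `pbs`, `ppt` (sub-results or NULL), the four logical flags in `flags`,
#'   and `overall_pass`.
#' @export
validate_element <- function(genome, cand, trna_library = default_trna_library(),
                             config = run_config(), rule = config$validate_rule) {
  cand <- as_candidate(cand)
  termini <- check_termini(genome, cand)
  tsd <- find_tsd(genome, cand, max_offset = config$tsd_max_offset,
                  min_len = config$tsd_min_len, max_len = config$tsd_max_len)
  pbs <- find_pbs(genome, cand, trna_library,
                  search_window = config$pbs_window,
                  min_identity = config$pbs_min_identity,
                  min_len = config$pbs_min_len, max_len = config$pbs_max_len)
  ppt <- find_ppt(genome, cand, search_window = config$ppt_window,
                  min_purine = config$ppt_min_purine,
                  min_len = config$ppt_min_len, max_len = config$ppt_max_len)
  flags <- c(termini = termini, tsd = !is.null(tsd), pbs = !is.null(pbs),
             ppt = !is.null(ppt))
  pass <- if (identical(rule, "any3")) sum(flags) >= 3L else all(flags)
  structure(list(termini_ok = termini, tsd = tsd, pbs = pbs, ppt = ppt,
                 flags = flags, overall_pass = pass),
            class = "structural_evidence")
}

#' Classify an element's superfamily from protein-domain order
#'
#' In the pol polyprotein the integrase (INT) precedes the reverse
#' transcriptase (RT) in Ty1-Copia elements and follows it in Ty3-Gypsy
#' elements; Gypsy elements additionally carrying a chromodomain (CHROMO)
#' form the chromovirus lineage. Domain order is judged by interval
#' midpoints.
#'
#' @param hits Data.frame of domain hits for one element with columns
#'   `domain` (among GAG, PR, INT, RT, RH, CHROMO), `start`, `end`.
#' @return One of `"Copia"`, `"Gypsy"`, `"Chromovirus-Gypsy"`,
#'   `"Unclassified"`. Conflicting duplicate INT/RT hits yield
#'   `"Unclassified"` with a warning.
#' @export
classify_superfamily <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0L) return("Unclassified")
  mid <- (hits$start + hits$end) / 2
  int_mid <- mid[hits$domain == "INT"]
  rt_mid <- mid[hits$domain == "RT"]
  if (length(int_mid) > 1L || length(rt_mid) > 1L) {
    warning("conflicting duplicate INT/RT domain hits; element unclassified")
    return("Unclassified")
  }
  if (length(int_mid) == 0L || length(rt_mid) == 0L) return("Unclassified")
  if (int_mid < rt_mid) return("Copia")
  if (any(hits$domain == "CHROMO")) return("Chromovirus-Gypsy")
  "Gypsy"
}

#' Bundled synthetic tRNA 3'-end library
#'
#' A small set of synthetic tRNA 3'-end sequences (each ending in the
#' universal CCA terminus) bundled for primer-binding-site detection and for
#' the genome simulator. These are constructed stand-ins, not database
#' sequences; supply your own library for real annotation work.
#'
#' @return Named character vector of 3'-end sequences.
#' @export
default_trna_library <- function() {
  path <- system.file("extdata", "trna_3prime_synthetic.fa",
                      package = "micrantha")
  if (!nzchar(path)) pm_domain_error("bundled tRNA library not found")
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}
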