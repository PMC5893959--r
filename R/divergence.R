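# Nucleotide divergence estimation: Kimura two-parameter distances between
# sister LTRs, Nei-Gojobori (1986) synonymous substitution rates between
# orthologous coding sequences, molecular-clock calibration, and
# insertion-age dating.

#' Kimura two-parameter distance from transition/transversion proportions
#'
#' `K = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)` where `P` and `Q` are the
#' proportions of aligned gap-free sites showing a transition and a
#' transversion respectively.
#'
#' @param P Transition proportion.
#' @param Q Transversion proportion.
#' @return The K2P distance.
#' @examples
#' kimura_distance(0.10, 0.05)  # ~0.1702
#' @export
kimura_distance <- function(P, Q) {
  if (P < 0 || Q < 0 || P + Q > 1) pm_domain_error("need 0 <= P+Q <= 1")
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (a <= 0 || b <= 0)
    pm_saturation_error(sprintf("K2P saturated (1-2P-Q = %g, 1-2Q = %g)", a, b))
  -0.5 * log(a) - 0.25 * log(b)
}

# Global affine-gap alignment of two sequences; returns the two aligned
# strings. Scoring defaults match the boundary-refinement scoring.
align_global <- function(x, y, match = 2, mismatch = -2,
                         gap_open = 5, gap_extend = 1) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(x), Biostrings::DNAString(y), type = "global",
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_extend)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Divergence between two aligned (or alignable) sequences
#'
#' Columns containing a gap or a non-ACGT symbol are eliminated; transitions
#' and transversions are counted over the remaining sites and converted to a
#' K2P distance.
#'
#' @param seq1,seq2 Nucleotide sequences (character strings). If
#'   `aligned = FALSE` they are first globally aligned with affine gap
#'   penalties.
#' @param aligned Set `TRUE` when the inputs are already aligned
#'   (equal length, possibly containing `-`).
#' @param match,mismatch,gap_open,gap_extend Alignment scoring.
#' @return A `divergence_record` list: `sites` (gap-free site count),
#'   `transitions`, `transversions`, `P`, `Q`, `K`.
#' @examples
#' pair_divergence("ACGT", "ACGT")$K  # 0
#' @export
pair_divergence <- function(seq1, seq2, aligned = FALSE, match = 2,
                            mismatch = -2, gap_open = 5, gap_extend = 1) {
  if (!aligned) {
    al <- align_global(seq1, seq2, match, mismatch, gap_open, gap_extend)
    seq1 <- al$a; seq2 <- al$b
  }
  a <- chars(toupper(seq1)); b <- chars(toupper(seq2))
  if (length(a) != length(b)) pm_domain_error("aligned sequences differ in length")
  keep <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n == 0L) pm_domain_error("no usable gap-free sites")
  ts <- sum(is_transition_pair(a, b))
  tv <- sum(a != b) - ts
  P <- ts / n; Q <- tv / n
  structure(list(sites = n, transitions = ts, transversions = tv,
                 P = P, Q = Q, K = kimura_distance(P, Q)),
            class = "divergence_record")
}

#' Inter-LTR divergence of a full-length element
#'
#' Aligns the 5' and 3' LTR of an element globally, eliminates indel columns,
#' and returns the K2P divergence record. Both LTRs must be at least 50 bp.
#'
#' @param ltr5_seq,ltr3_seq The two LTR sequences.
#' @param ... Passed to [pair_divergence()] (alignment scoring).
#' @return A `divergence_record` (see [pair_divergence()]).
#' @export
ltr_divergence <- function(ltr5_seq, ltr3_seq, ...) {
  if (nchar(ltr5_seq) < 50L || nchar(ltr3_seq) < 50L)
    pm_domain_error("LTR sequences must be at least 50 bp")
  pair_divergence(ltr5_seq, ltr3_seq, aligned = FALSE, ...)
}

## ---- Nei-Gojobori (1986) synonymous substitution rates ----

codon_alphabet <- c("T", "C", "A", "G")

# Environment caching the genetic-code derived tables.
.ng86_cache <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_cache$sites)) return(as.list(.ng86_cache))
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  stops <- codons[gc == "*"]
  # Per-codon synonymous site count: at each position, the fraction of the
  # three possible single-nucleotide changes that are synonymous; changes to
  # stop codons are excluded from both numerator and denominator (mutations
  # creating stops are disregarded, the standard NG86 treatment).
  syn_sites <- numeric(length(codons)); names(syn_sites) <- codons
  syn_at_pos <- matrix(0, length(codons), 3, dimnames = list(codons, NULL))
  for (cd in codons) {
    if (cd %in% stops) { syn_sites[cd] <- NA; next }
    v <- chars(cd)
    for (pos in 1:3) {
      alts <- vapply(setdiff(codon_alphabet, v[pos]), function(nt) {
        w <- v; w[pos] <- nt; paste(w, collapse = "")
      }, "")
      alts <- alts[!alts %in% stops]
      if (length(alts) == 0L) next
      frac <- sum(gc[alts] == gc[cd]) / 3
      syn_sites[cd] <- syn_sites[cd] + frac
      syn_at_pos[cd, pos] <- sum(gc[alts] == gc[cd]) / 3
    }
  }
  # Pairwise synonymous/nonsynonymous difference counts with pathway
  # averaging; pathways through stop codons are excluded.
  path_counts <- function(c1, c2) {
    diffpos <- which(chars(c1) != chars(c2))
    nd <- length(diffpos)
    if (nd == 0L) return(c(sd = 0, nd = 0))
    perms <- if (nd == 1L) list(diffpos) else
      if (nd == 2L) list(diffpos, rev(diffpos)) else
        lapply(asplit(perms3(), 1), function(ix) diffpos[ix])
    acc <- c(sd = 0, nd = 0); nvalid <- 0
    for (ord in perms) {
      cur <- chars(c1); sd <- 0; ndn <- 0; valid <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- chars(c2)[pos]
        from <- paste(cur, collapse = ""); to <- paste(nxt, collapse = "")
        if (to %in% stops || from %in% stops) { valid <- FALSE; break }
        if (gc[from] == gc[to]) sd <- sd + 1 else ndn <- ndn + 1
        cur <- nxt
      }
      if (valid) { acc <- acc + c(sd = sd, nd = ndn); nvalid <- nvalid + 1 }
    }
    if (nvalid == 0L) return(c(sd = NA_real_, nd = NA_real_))
    acc / nvalid
  }
  .ng86_cache$sites <- syn_sites
  .ng86_cache$syn_at_pos <- syn_at_pos
  .ng86_cache$stops <- stops
  .ng86_cache$path_counts <- path_counts
  as.list(.ng86_cache)
}

perms3 <- function() {
  m <- expand.grid(1:3, 1:3, 1:3)
  m <- as.matrix(m[apply(m, 1, function(r) length(unique(r)) == 3L), ])
  unname(m)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' NG86 synonymous substitution rate for one codon-aligned CDS pair
#'
#' Counts synonymous sites and differences by the method of Nei and Gojobori
#' (1986) with pathway averaging, then applies the Jukes-Cantor correction
#' `Ks = -3/4 * log(1 - 4/3 * ps)`.
#'
#' @param cds1,cds2 Codon-aligned coding sequences (equal length, multiple of
#'   3, no internal stop codons).
#' @return List: `S` (synonymous sites, averaged over the two sequences),
#'   `N`, `Sd`, `Nd`, `ps`, `pn`, `Ks`, `Ka`, and `saturated` (logical; when
#'   TRUE `Ks` is NA).
#' @export
ng86_ks <- function(cds1, cds2) {
  if (nchar(cds1) != nchar(cds2))
    pm_domain_error("CDS pair must be codon-aligned to equal length")
  if (nchar(cds1) %% 3L != 0L)
    pm_domain_error("CDS length must be a multiple of 3")
  tabs <- ng86_tables()
  co1 <- split_codons(toupper(cds1)); co2 <- split_codons(toupper(cds2))
  internal <- seq_len(length(co1) - 1L)
  if (any(co1[internal] %in% tabs$stops) || any(co2[internal] %in% tabs$stops))
    pm_domain_error("internal stop codon in CDS pair")
  # drop terminal stop codons and codons with ambiguity
  keep <- !(co1 %in% tabs$stops) & !(co2 %in% tabs$stops) &
    grepl("^[ACGT]{3}$", co1) & grepl("^[ACGT]{3}$", co2)
  co1 <- co1[keep]; co2 <- co2[keep]
  if (length(co1) == 0L) pm_domain_error("no usable codons")
  S <- (sum(tabs$sites[co1]) + sum(tabs$sites[co2])) / 2
  N <- 3 * length(co1) - S
  sd <- 0; nd <- 0
  for (i in seq_along(co1)) {
    if (co1[i] == co2[i]) next
    pc <- tabs$path_counts(co1[i], co2[i])
    if (any(is.na(pc))) next
    sd <- sd + pc["sd"]; nd <- nd + pc["nd"]
  }
  ps <- sd / S; pn <- nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- unname(jc(ps)); ka <- unname(jc(pn))
  list(S = S, N = N, Sd = unname(sd), Nd = unname(nd), ps = unname(ps),
       pn = unname(pn), Ks = unname(ks), Ka = unname(ka),
       saturated = is.na(ks))
}

#' Per-pair Ks over a set of codon-aligned ortholog pairs
#'
#' @param cds_pairs A list of two-element character vectors (or a list with
#'   elements `cds1`, `cds2`), each a codon-aligned CDS pair.
#' @return List: `per_pair` data.frame (pair, S, Sd, ps, Ks, saturated,
#'   error), `ks_mean` (unweighted mean over non-saturated pairs),
#'   `ks_mean_weighted` (weighted by synonymous sites), `n_used`,
#'   `aligned_bp` (total aligned length over usable pairs).
#' @export
pairwise_ks <- function(cds_pairs) {
  if (length(cds_pairs) == 0L) pm_domain_error("no CDS pairs supplied")
  rows <- lapply(seq_along(cds_pairs), function(i) {
    p <- cds_pairs[[i]]
    c1 <- if (is.list(p)) p$cds1 else p[[1L]]
    c2 <- if (is.list(p)) p$cds2 else p[[2L]]
    res <- tryCatch(ng86_ks(c1, c2), error = function(e)
      list(S = NA, N = NA, Sd = NA, Nd = NA, ps = NA, pn = NA, Ks = NA,
           Ka = NA, saturated = NA, error = conditionMessage(e)))
    data.frame(pair = i, S = res$S, Sd = res$Sd, ps = res$ps, Ks = res$Ks,
               saturated = isTRUE(res$saturated),
               error = if (is.null(res$error)) NA_character_ else res$error,
               aligned_bp = nchar(c1))
  })
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$Ks) & !tab$saturated
  list(per_pair = tab,
       ks_mean = mean(tab$Ks[ok]),
       ks_mean_weighted = sum(tab$Ks[ok] * tab$S[ok]) / sum(tab$S[ok]),
       n_used = sum(ok),
       aligned_bp = sum(tab$aligned_bp[ok]))
}

#' Calibrate substitution rates from a mean Ks and a divergence time
#'
#' The default convention mirrors the worked arithmetic this package targets:
#' the gene rate is `r_g = ks_mean / t_div_years` and the LTR rate is
#' `factor * r_g` (LTR retrotransposons mutate about twice as fast as silent
#' sites in genes). The alternative `convention = "per_lineage"` uses
#' `r_g = ks_mean / (2 * t_div_years)`; combined with the matching age
#' formula both conventions give identical element ages (see the methods
#' vignette).
#'
#' @param ks_mean Mean synonymous substitutions per synonymous site.
#' @param t_div_years Divergence time in years (default 24.22 My).
#' @param factor LTR-to-gene rate multiplier (default 2).
#' @param convention `"total"` (the default: rate over the full divergence path) or `"per_lineage"`.
#' @return List of class `rate_calibration`: `ks_mean`, `t_div_years`,
#'   `gene_rate`, `ltr_rate`, `convention`.
#' @examples
#' calibrate_rate(0.064, 24.22e6)$gene_rate  # ~2.64e-9
#' @export
calibrate_rate <- function(ks_mean, t_div_years = 24.22e6, factor = 2,
                           convention = c("total", "per_lineage")) {
  convention <- match.arg(convention)
  if (ks_mean < 0) pm_domain_error("ks_mean must be >= 0")
  stopifnot_scalar_number(t_div_years, "t_div_years", positive = TRUE)
  denom <- if (convention == "total") t_div_years else 2 * t_div_years
  r_g <- ks_mean / denom
  structure(list(ks_mean = ks_mean, t_div_years = t_div_years,
                 gene_rate = r_g, ltr_rate = factor * r_g,
                 convention = convention),
            class = "rate_calibration")
}

#' Insertion age of an element from its inter-LTR distance
#'
#' Under the default convention the age is `K / r_ltr`; under
#' `convention = "per_lineage"` it is `K / (2 * r_ltr)`. Use the same
#' convention as in [calibrate_rate()]; the resulting ages coincide.
#'
#' @param K Inter-LTR K2P distance (>= 0).
#' @param r_ltr LTR substitution rate per site per year (> 0).
#' @param convention `"total"` (the default: rate over the full divergence path) or `"per_lineage"`.
#' @return Age in years.
#' @examples
#' insertion_age(0.124, 5.28e-9) / 1e6  # ~23.48 My
#' @export
insertion_age <- function(K, r_ltr, convention = c("total", "per_lineage")) {
  convention <- match.arg(convention)
  if (any(K < 0)) pm_domain_error("K must be >= 0")
  stopifnot_scalar_number(r_ltr, "r_ltr", positive = TRUE)
  if (convention == "total") K / r_ltr else K / (2 * r_ltr)
}

#' Count and percentage table of element annotations
#'
#' @param annotations Data.frame with columns `element_id`, `superfamily`,
#'   `family`.
#' @return List with `by_family` (superfamily, family, count, percent at 2
#'   decimals) and `by_superfamily` data.frames, and `total`.
#' @export
family_summary <- function(annotations) {
  if (is.null(annotations) || nrow(annotations) == 0L)
    pm_domain_error("no annotations supplied")
  total <- nrow(annotations)
  fam <- stats::aggregate(list(count = annotations$element_id),
                          by = list(superfamily = annotations$superfamily,
                                    family = annotations$family),
                          FUN = length)
  fam <- fam[order(fam$superfamily, fam$family), , drop = FALSE]
  fam$percent <- round(100 * fam$count / total, 2)
  sup <- stats::aggregate(list(count = annotations$element_id),
                          by = list(superfamily = annotations$superfamily),
                          FUN = length)
  sup$percent <- round(100 * sup$count / total, 2)
  rownames(fam) <- rownames(sup) <- NULL
  list(by_family = fam, by_superfamily = sup, total = total)
}

#' Genome proportion represented by read clusters
#'
#' Per-cluster percentages and the clustered total, as used both for
#' graph-clustering repeat abundance and for effective-abundance summaries of
#' mapped read classes.
#'
#' @param per_cluster_reads Vector of reads per cluster (or per class).
#' @param total_reads Total number of reads; must be at least the sum of
#'   cluster reads.
#' @return List: `per_cluster` data.frame (`reads`, `percent`),
#'   `clustered_percent` (full precision) and `clustered_percent_printed`
#'   (1 decimal).
#' @examples
#' genome_proportion(c(600, 401838 + 401000), 1484780)
#' @export
genome_proportion <- function(per_cluster_reads, total_reads) {
  stopifnot_scalar_number(total_reads, "total_reads", positive = TRUE)
  if (any(per_cluster_reads < 0)) pm_domain_error("negative cluster read count")
  s <- sum(per_cluster_reads)
  if (s > total_reads) pm_domain_error("cluster reads exceed total reads")
  p <- 100 * s / total_reads
  list(per_cluster = data.frame(reads = per_cluster_reads,
                                percent = 100 * per_cluster_reads / total_reads),
       clustered_percent = p,
       clustered_percent_printed = round(p, 1))
}
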