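#' Read a FASTA file of genome records with a soft-mask track
#'
#' Sequences are uppercased on read; runs of lowercase letters in the input
#' (the common soft-masking convention for repeats) are recorded per record as
#' a mask track of 1-based closed intervals.
#'
#' @param path Path to a FASTA file.
#' @return An object of class `genome_records`: a list with one element per
#'   record, each a list with `id`, `seq` (uppercase character string) and
#'   `mask` (data.frame with `start`, `end`, 1-based closed).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "ACGTacgtACGT"), fa)
#' g <- read_fasta(fa)
#' g[[1]]$mask   # the lowercase run
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) pm_format_error(sprintf("file not found: %s", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) pm_format_error(
                    sprintf("malformed FASTA '%s': %s", path, conditionMessage(e))))
  if (length(set) == 0L)
    pm_format_error(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) pm_format_error("FASTA record with empty id")
  recs <- vector("list", length(set))
  for (i in seq_along(set)) {
    raw <- as.character(set[[i]])
    v <- chars(raw)
    bad <- !grepl("^[ACGTUNRYSWKMBDHVacgtunryswkmbdhv]*$", raw)
    if (bad) {
      # locate the offending line for the diagnostic
      lines <- readLines(path, warn = FALSE)
      ln <- which(!startsWith(lines, ">") &
                    grepl("[^ACGTUNRYSWKMBDHVacgtunryswkmbdhv]", lines))[1L]
      pm_format_error(sprintf(
        "illegal nucleotide character in record '%s' (line %s of %s)",
        ids[i], ifelse(is.na(ln), "?", ln), path))
    }
    low <- v %in% letters
    mask <- if (any(low)) {
      r <- IRanges::IRanges(low)
      data.frame(start = IRanges::start(r), end = IRanges::end(r))
    } else {
      data.frame(start = integer(0), end = integer(0))
    }
    recs[[i]] <- list(id = ids[i], seq = toupper(raw), mask = mask)
  }
  names(recs) <- ids
  structure(recs, class = "genome_records")
}

#' Write genome records to FASTA
#'
#' Mask tracks are re-expressed as lowercase runs so that a write/read
#' round-trip reproduces the in-memory value exactly.
#'
#' @param records A `genome_records` object (or plain named character vector).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.character(records))
    records <- lapply(seq_along(records), function(i)
      list(id = names(records)[i], seq = records[[i]],
           mask = data.frame(start = integer(0), end = integer(0))))
  for (rec in records) {
    s <- rec$seq
    if (!is.null(rec$mask) && nrow(rec$mask) > 0L) {
      v <- chars(s)
      for (j in seq_len(nrow(rec$mask))) {
        idx <- rec$mask$start[j]:rec$mask$end[j]
        v[idx] <- tolower(v[idx])
      }
      s <- paste(v, collapse = "")
    }
    writeLines(paste0(">", rec$id), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read gene models from a GFF3-like exon table
#'
#' Expects tab-separated rows with the nine standard GFF3 columns; rows whose
#' feature type is `exon` are grouped into gene models using the `gene_id=`,
#' `Parent=` or `ID=` attribute (first one present). Coordinates on disk are
#' 1-based closed and are kept 1-based closed internally.
#'
#' @param path Path to the tab-separated file. Comment lines (`#`) ignored.
#' @return A named list of class `gene_models`; each element has `gene_id`,
#'   `scaffold_id`, `strand` and `exons` (data.frame `start`,`end`, sorted,
#'   non-overlapping).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) pm_format_error(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 9L)
    pm_format_error(sprintf("expected 9 GFF3 columns, found %d in %s", ncol(tab), path))
  names(tab)[1:9] <- c("seqid", "source", "type", "start", "end",
                       "score", "strand", "phase", "attributes")
  tab <- tab[tab$type == "exon", , drop = FALSE]
  if (nrow(tab) == 0L) pm_format_error(sprintf("no exon rows in %s", path))
  if (!is.numeric(tab$start) || !is.numeric(tab$end))
    pm_format_error("non-numeric exon coordinates")
  if (any(tab$end < tab$start))
    pm_format_error(sprintf("exon with end < start at row %d",
                            which(tab$end < tab$start)[1L]))
  if (!all(tab$strand %in% c("+", "-")))
    pm_format_error(sprintf("unknown strand symbol '%s'",
                            setdiff(unique(tab$strand), c("+", "-"))[1L]))
  gene <- extract_attr(tab$attributes)
  models <- lapply(split(seq_len(nrow(tab)), gene), function(idx) {
    sub <- tab[idx, , drop = FALSE]
    if (length(unique(sub$seqid)) != 1L)
      pm_format_error(sprintf("gene '%s' spans multiple scaffolds", gene[idx[1L]]))
    ord <- order(sub$start)
    ex <- data.frame(start = as.integer(sub$start[ord]),
                     end = as.integer(sub$end[ord]))
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)]))
      pm_format_error(sprintf("overlapping exons in gene '%s'", gene[idx[1L]]))
    list(gene_id = gene[idx[1L]], scaffold_id = sub$seqid[1L],
         strand = sub$strand[1L], exons = ex)
  })
  structure(models, class = "gene_models")
}

extract_attr <- function(attrs) {
  g <- sub('.*gene_id[=\\s]+"?([^";]+)"?.*', "\\1", attrs)
  miss <- g == attrs
  g[miss] <- sub(".*Parent=([^;]+).*", "\\1", attrs[miss])
  miss <- g == attrs
  g[miss] <- sub(".*ID=([^;]+).*", "\\1", attrs[miss])
  if (any(g == attrs)) pm_format_error("exon row without gene_id/Parent/ID attribute")
  g
}

#' Read a typed, header-checked TSV table
#'
#' @param path Path to a tab-separated file with a header row.
#' @param schema Named character vector mapping required column names to types
#'   (`"character"`, `"numeric"`, `"integer"`). Extra columns are kept as-is.
#' @return A data.frame with typed columns; row order preserved.
#' @examples
#' tf <- tempfile(); writeLines(c("gene_id\tn", "g1\t3"), tf)
#' read_table(tf, c(gene_id = "character", n = "integer"))
#' @export
read_table <- function(path, schema) {
  if (!file.exists(path)) pm_format_error(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing <- setdiff(names(schema), names(tab))
  if (length(missing))
    pm_schema_error(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  for (col in names(schema)) {
    type <- schema[[col]]
    if (type %in% c("numeric", "integer")) {
      v <- suppressWarnings(as.numeric(tab[[col]]))
      bad <- which(is.na(v) & !is.na(tab[[col]]) & tab[[col]] != "NA")
      if (length(bad))
        pm_schema_error(sprintf("non-numeric value '%s' in column '%s' (row %d)",
                                tab[[col]][bad[1L]], col, bad[1L]))
      tab[[col]] <- if (type == "integer") as.integer(round(v)) else v
    } else {
      tab[[col]] <- as.character(tab[[col]])
    }
  }
  tab
}

#' Write a data.frame as a TSV file (deterministic layout)
#'
#' @param tab A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read LTR element candidates from a BED-like table
#'
#' On-disk columns (no header, tab-separated, BED convention 0-based
#' half-open): scaffold, element start, element end, name, ltr5 start,
#' ltr5 end, ltr3 start, ltr3 end. Internally coordinates become 1-based
#' closed.
#'
#' @param path Path to the candidate table.
#' @return Data.frame of class `ltr_candidates` with 1-based closed columns
#'   `scaffold_id, start, end, name, ltr5_start, ltr5_end, ltr3_start,
#'   ltr3_end`.
#' @export
read_ltr_candidates <- function(path) {
  if (!file.exists(path)) pm_format_error(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 8L)
    pm_format_error("candidate BED needs 8 columns (element + both LTR intervals)")
  names(tab)[1:8] <- c("scaffold_id", "start", "end", "name",
                       "ltr5_start", "ltr5_end", "ltr3_start", "ltr3_end")
  for (col in c("start", "ltr5_start", "ltr3_start"))
    tab[[col]] <- as.integer(tab[[col]]) + 1L  # 0-based half-open -> 1-based closed
  for (col in c("end", "ltr5_end", "ltr3_end"))
    tab[[col]] <- as.integer(tab[[col]])
  validate_candidates(tab)
  class(tab) <- c("ltr_candidates", "data.frame")
  tab
}

#' Write LTR candidates back to the BED-like format
#'
#' @param cands Data.frame as returned by [read_ltr_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ltr_candidates <- function(cands, path) {
  out <- data.frame(
    scaffold = cands$scaffold_id,
    start = cands$start - 1L, end = cands$end, name = cands$name,
    ltr5_start = cands$ltr5_start - 1L, ltr5_end = cands$ltr5_end,
    ltr3_start = cands$ltr3_start - 1L, ltr3_end = cands$ltr3_end)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}

validate_candidates <- function(tab, min_ltr = 100L) {
  ok <- tab$ltr5_start >= tab$start & tab$ltr3_end <= tab$end &
    tab$ltr5_end < tab$ltr3_start
  if (any(!ok))
    pm_format_error(sprintf("candidate '%s' violates LTR interval invariants",
                            tab$name[which(!ok)[1L]]))
  len5 <- tab$ltr5_end - tab$ltr5_start + 1L
  len3 <- tab$ltr3_end - tab$ltr3_start + 1L
  if (any(len5 < min_ltr | len3 < min_ltr))
    pm_format_error(sprintf("candidate '%s' has an LTR shorter than %d bp",
                            tab$name[which(len5 < min_ltr | len3 < min_ltr)[1L]],
                            min_ltr))
  invisible(tab)
}

#' Default run configuration
#'
#' Collects every tunable used across the pipeline stages with defaults equal
#' to the values stated in the study design where stated (strict intron
#' support > 60 reads; FPKM filter 1000; sqrt(MSR) > 2.00 and p < 1e-3;
#' ortholog hit filter E <= 1e-4 and coverage >= 0.5; TSD length 4-6 with
#' jitter <= 2; PBS length 15-18, identity >= 0.8; PPT length 20-25, purine
#' fraction >= 0.9; divergence time 24.22 My; LTR rate = 2 x gene rate).
#'
#' @param ... Name-value overrides of the defaults.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    pg_per_mbp = 978,            # Mbp per pg of DNA
    intron_min_reads = 60,       # strict '>' threshold
    min_ltr_len = 100L,
    sw_match = 2, sw_mismatch = -2, sw_gap_open = 5, sw_gap_extend = 1,
    refine_window = 50L,
    tsd_max_offset = 2L, tsd_min_len = 4L, tsd_max_len = 6L,
    pbs_min_len = 15L, pbs_max_len = 18L, pbs_window = 20L, pbs_min_identity = 0.8,
    ppt_min_len = 20L, ppt_max_len = 25L, ppt_window = 20L, ppt_min_purine = 0.9,
    validate_rule = "all",       # or "any3"
    t_div_years = 24.22e6,
    ltr_rate_factor = 2,
    age_convention = "total",    # r_g = Ks/T, age = K/r_LTR (see vignette)
    fpkm_threshold = 1000,
    msr_cut = 2.00, p_cut = 1e-3,
    vst_method = "quadratic",    # or "none"
    max_e = 1e-4, min_cov = 0.5,
    merge_window = 1000L,
    min_anchors = 3L, max_skip = 2L,
    anchor_thresholds = c(1L, 10L, 50L, 100L),
    seed = 0L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    pm_usage_error(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  num <- vapply(cfg, function(x) is.numeric(x) && all(is.finite(x)), TRUE)
  chr <- vapply(cfg, is.character, TRUE)
  if (!all(num | chr)) pm_domain_error("all config thresholds must be finite")
  if (cfg$seed < 0) pm_domain_error("seed must be a non-negative integer")
  structure(cfg, class = c("run_config", "list"))
}

#' Read a plain-text key = value configuration file
#'
#' Grammar: one `key = value` pair per line; blank lines and lines starting
#' with `#` are ignored; values are parsed as numbers when possible,
#' otherwise kept as strings. Unknown keys are rejected.
#'
#' @param path Path to the config file.
#' @return A `run_config` with the file's overrides applied.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) pm_format_error(sprintf("file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad))
    pm_format_error(sprintf("config line not of form 'key = value': '%s'",
                            lines[which(bad)[1L]]))
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  parsed <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(parsed) <- keys
  do.call(run_config, parsed)
}
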