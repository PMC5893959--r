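# Ortholog-anchor microsynteny: hit filtering, unambiguous anchoring,
# greedy collinear block construction, inversion and translocation
# reporting, and anchoring summaries.

#' Filter ortholog hits on E-value and query coverage
#'
#' Keeps hits with `e_value <= max_e` and `query_coverage >= min_cov`
#' (both boundaries inclusive).
#'
#' @param hits Data.frame with columns `gene_id`, `scaffold_id`,
#'   `scaffold_pos`, `target_chrom`, `target_pos`, `e_value`,
#'   `query_coverage`.
#' @param max_e Maximum E-value (default 1e-4).
#' @param min_cov Minimum query coverage (default 0.5).
#' @return The filtered hit table.
#' @export
filter_hits <- function(hits, max_e = 1e-4, min_cov = 0.5) {
  needed <- c("gene_id", "e_value", "query_coverage")
  missing <- setdiff(needed, names(hits))
  if (length(missing))
    pm_schema_error(sprintf("hit table missing column(s): %s",
                            paste(missing, collapse = ", ")))
  hits[hits$e_value <= max_e & hits$query_coverage >= min_cov, , drop = FALSE]
}

#' Reduce filtered hits to unambiguous gene anchors
#'
#' Hits of one gene lying within `merge_window` bp of each other on the same
#' target chromosome count as a single location. A gene becomes an anchor
#' only when exactly one merged location remains; the anchor takes the
#' position of the location's best (lowest E-value) hit. Multi-location
#' genes are excluded and reported.
#'
#' @param hits A pre-filtered hit table (see [filter_hits()]).
#' @param merge_window Merge radius in bp (default 1000).
#' @return List: `anchors` (data.frame gene_id, scaffold_id, scaffold_pos,
#'   target_chrom, target_pos, e_value) and `ambiguous` (excluded gene ids
#'   with their location counts).
#' @export
unambiguous_anchors <- function(hits, merge_window = 1000L) {
  if (nrow(hits) == 0L)
    return(list(anchors = hits[0, , drop = FALSE],
                ambiguous = data.frame(gene_id = character(0),
                                       n_locations = integer(0))))
  res <- lapply(split(hits, hits$gene_id), function(h) {
    # cluster hits into locations: same chromosome, gaps <= merge_window
    h <- h[order(h$target_chrom, h$target_pos), , drop = FALSE]
    newloc <- c(TRUE, h$target_chrom[-1L] != h$target_chrom[-nrow(h)] |
                  diff(h$target_pos) > merge_window)
    loc <- cumsum(newloc)
    if (max(loc) == 1L) {
      best <- h[which.min(h$e_value), , drop = FALSE]
      list(anchor = best, n = 1L)
    } else {
      list(anchor = NULL, n = max(loc))
    }
  })
  anchors <- do.call(rbind, lapply(res, `[[`, "anchor"))
  ns <- vapply(res, `[[`, 1L, "n")
  ambiguous <- data.frame(gene_id = names(ns)[ns > 1L],
                          n_locations = unname(ns[ns > 1L]))
  if (is.null(anchors)) anchors <- hits[0, , drop = FALSE]
  rownames(anchors) <- NULL
  list(anchors = anchors, ambiguous = ambiguous)
}

#' Build collinear synteny blocks for one scaffold
#'
#' Greedy monotone chaining: walking the scaffold's anchors in scaffold
#' order, a block grows while successive anchors share its target chromosome
#' and keep a monotone target-position trend (either direction, fixed at the
#' block's second member). Up to `max_skip` consecutive intervening anchors
#' belonging elsewhere may be skipped; a same-chromosome anchor breaking
#' monotonicity also counts against the skip budget, so isolated order noise
#' is tolerated but a sustained reversal starts a new block. Runs shorter
#' than `min_anchors` are reported separately as singletons.
#'
#' @param anchors Anchor table of a single scaffold (see
#'   [unambiguous_anchors()]).
#' @param min_anchors Minimum anchors per reported block (default 3).
#' @param max_skip Skip budget (default 2).
#' @return List: `blocks` (list of data.frames of member anchors, each with
#'   attributes `target_chrom` and `orientation`), `block_table` (summary
#'   data.frame), `singletons` (anchors in sub-threshold runs).
#' @export
build_blocks <- function(anchors, min_anchors = 3L, max_skip = 2L) {
  if (nrow(anchors) == 0L)
    return(list(blocks = list(), block_table = empty_block_table(),
                singletons = anchors))
  if (length(unique(anchors$scaffold_id)) != 1L)
    pm_domain_error("build_blocks expects anchors of a single scaffold")
  anchors <- anchors[order(anchors$scaffold_pos), , drop = FALSE]
  n <- nrow(anchors)
  assigned <- rep(FALSE, n)
  runs <- list()
  while (!all(assigned)) {
    seed <- which(!assigned)[1L]
    members <- seed
    chrom <- anchors$target_chrom[seed]
    dir <- 0L
    last_t <- anchors$target_pos[seed]
    skipped <- 0L
    i <- seed + 1L
    while (i <= n && skipped <= max_skip) {
      if (!assigned[i]) {
        ok_chrom <- anchors$target_chrom[i] == chrom
        step <- sign(anchors$target_pos[i] - last_t)
        ok_dir <- dir == 0L || step == 0L || step == dir
        if (ok_chrom && ok_dir) {
          members <- c(members, i)
          if (dir == 0L && step != 0L) dir <- step
          last_t <- anchors$target_pos[i]
          skipped <- 0L
          i <- i + 1L
          next
        }
      }
      skipped <- skipped + 1L
      i <- i + 1L
    }
    assigned[members] <- TRUE
    runs[[length(runs) + 1L]] <- members
  }
  is_block <- vapply(runs, length, 1L) >= min_anchors
  blocks <- lapply(runs[is_block], function(idx) {
    b <- anchors[idx, , drop = FALSE]
    rownames(b) <- NULL
    attr(b, "target_chrom") <- b$target_chrom[1L]
    attr(b, "orientation") <- detect_inversions(b)
    b
  })
  singles <- anchors[unlist(runs[!is_block]), , drop = FALSE]
  list(blocks = blocks, block_table = block_table(blocks),
       singletons = singles)
}

empty_block_table <- function() {
  data.frame(scaffold_id = character(0), target_chrom = character(0),
             scaffold_start = numeric(0), scaffold_end = numeric(0),
             target_start = numeric(0), target_end = numeric(0),
             orientation = character(0), gene_count = integer(0))
}

block_table <- function(blocks) {
  if (length(blocks) == 0L) return(empty_block_table())
  do.call(rbind, lapply(blocks, function(b) {
    data.frame(scaffold_id = b$scaffold_id[1L],
               target_chrom = attr(b, "target_chrom"),
               scaffold_start = min(b$scaffold_pos),
               scaffold_end = max(b$scaffold_pos),
               target_start = min(b$target_pos),
               target_end = max(b$target_pos),
               orientation = attr(b, "orientation"),
               gene_count = nrow(b))
  }))
}

#' Orientation of a synteny block
#'
#' The sign of the Kendall rank correlation between the members' scaffold
#' order and target positions: positive is `forward`, negative `inverted`.
#' Ties are broken by target position, then gene id.
#'
#' @param block Data.frame of member anchors (at least 2 rows).
#' @return `"forward"` or `"inverted"`.
#' @export
detect_inversions <- function(block) {
  if (nrow(block) < 2L) pm_domain_error("block needs at least 2 members")
  ord <- order(block$scaffold_pos, block$target_pos, block$gene_id)
  b <- block[ord, , drop = FALSE]
  tau <- suppressWarnings(
    stats::cor(seq_len(nrow(b)), b$target_pos, method = "kendall"))
  if (is.na(tau)) tau <- 1  # all target positions tied
  if (tau >= 0) "forward" else "inverted"
}

#' Scaffolds whose blocks span more than one target chromosome
#'
#' @param block_tab A block summary table (rbind of [build_blocks()]
#'   `block_table`s over scaffolds).
#' @return Data.frame, one row per translocation-like scaffold:
#'   `scaffold_id`, `n_chroms`, `chroms` (comma-separated), `gene_counts`
#'   (comma-separated per-block counts).
#' @export
split_scaffolds <- function(block_tab) {
  if (nrow(block_tab) == 0L)
    return(data.frame(scaffold_id = character(0), n_chroms = integer(0),
                      chroms = character(0), gene_counts = character(0)))
  out <- lapply(split(block_tab, block_tab$scaffold_id), function(b) {
    chroms <- unique(b$target_chrom)
    if (length(chroms) < 2L) return(NULL)
    data.frame(scaffold_id = b$scaffold_id[1L],
               n_chroms = length(chroms),
               chroms = paste(sort(chroms), collapse = ","),
               gene_counts = paste(b$gene_count, collapse = ","))
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    return(data.frame(scaffold_id = character(0), n_chroms = integer(0),
                      chroms = character(0), gene_counts = character(0)))
  rownames(res) <- NULL
  res
}

#' Anchoring summary over scaffolds
#'
#' Counts scaffolds holding at least 1, 10, 50, 100 (configurable) anchors,
#' and reports the total length and assembly fraction of scaffolds with at
#' least one anchor.
#'
#' @param anchors Anchor table over all scaffolds.
#' @param scaffold_lengths Named vector of scaffold lengths (bp).
#' @param thresholds Anchor-count ladder (default `c(1, 10, 50, 100)`).
#' @return List: `counts` (data.frame threshold, n_scaffolds), `anchored_bp`,
#'   `total_bp`, `anchored_percent` (1 decimal in `anchored_percent_printed`).
#' @export
anchoring_summary <- function(anchors, scaffold_lengths,
                              thresholds = c(1L, 10L, 50L, 100L)) {
  per_scaf <- table(anchors$scaffold_id)
  counts <- data.frame(
    threshold = thresholds,
    n_scaffolds = vapply(thresholds, function(t) sum(per_scaf >= t), 1L))
  anchored <- names(per_scaf)[per_scaf >= 1L]
  anchored_bp <- sum(scaffold_lengths[anchored], na.rm = TRUE)
  total_bp <- sum(scaffold_lengths)
  p <- 100 * anchored_bp / total_bp
  list(counts = counts, anchored_bp = anchored_bp, total_bp = total_bp,
       anchored_percent = p, anchored_percent_printed = round(p, 1))
}

#' Run the full synteny stage on a raw hit table
#'
#' Filter, anchor, chain blocks per scaffold, and report inversions and
#' multi-chromosome scaffolds.
#'
#' @param hits Raw hit table (see [filter_hits()]).
#' @param config A [run_config()].
#' @return List: `anchors`, `ambiguous`, `block_table`, `split_scaffolds`,
#'   `blocks` (per-scaffold lists).
#' @export
run_synteny <- function(hits, config = run_config()) {
  kept <- filter_hits(hits, config$max_e, config$min_cov)
  ua <- unambiguous_anchors(kept, config$merge_window)
  per_scaf <- split(ua$anchors, ua$anchors$scaffold_id)
  built <- lapply(per_scaf, build_blocks,
                  min_anchors = config$min_anchors, max_skip = config$max_skip)
  tab <- do.call(rbind, lapply(built, `[[`, "block_table"))
  if (is.null(tab)) tab <- empty_block_table()
  rownames(tab) <- NULL
  list(anchors = ua$anchors, ambiguous = ua$ambiguous, block_table = tab,
       split_scaffolds = split_scaffolds(tab),
       blocks = lapply(built, `[[`, "blocks"))
}
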