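# Flow-cytometry genome-size conversion and assembly/annotation summary
# arithmetic.

#' Convert a 2C flow-cytometry DNA amount to a 1C genome size in Mbp
#'
#' Uses the standard conversion that 1 pg of DNA corresponds to 978 Mbp, so
#' the haploid (1C) genome size is `(pg_2c / 2) * 978`.
#'
#' @param pg_2c DNA amount of a 2C nucleus in picograms.
#' @param pg_per_mbp Conversion constant, Mbp per pg (default 978).
#' @return List with `mbp` (full precision) and `mbp_printed` (2 decimals).
#' @examples
#' pg_to_mbp(0.83)$mbp_printed  # 405.87
#' @export
pg_to_mbp <- function(pg_2c, pg_per_mbp = 978) {
  stopifnot_scalar_number(pg_2c, "pg_2c", positive = TRUE)
  stopifnot_scalar_number(pg_per_mbp, "pg_per_mbp", positive = TRUE)
  mbp <- (pg_2c / 2) * pg_per_mbp
  list(mbp = mbp, mbp_printed = round(mbp, 2))
}

#' Assembly summary statistics from genome records
#'
#' N50 is the length of the scaffold at which the cumulative length of
#' scaffolds sorted in descending order first reaches at least half the total
#' assembly size (a cumulative sum hitting exactly total/2 defines N50).
#'
#' @param records A `genome_records` object from [read_fasta()], or a named
#'   character vector of sequences.
#' @return List of class `assembly_stats`: `n_scaffolds`, `total_bp`,
#'   `longest_bp`, `n50_bp`, `gapped_n_bp` (N characters only), `atcg_bp`,
#'   `other_bp` (non-N ambiguity codes).
#' @export
assembly_stats <- function(records) {
  seqs <- if (is.character(records)) records else
    vapply(records, function(r) r$seq, "")
  if (length(seqs) == 0L) pm_domain_error("no scaffolds supplied")
  lens <- nchar(seqs)
  counts <- vapply(seqs, function(s) {
    v <- chars(s)
    c(acgt = sum(v %in% c("A", "C", "G", "T")), n = sum(v == "N"))
  }, c(acgt = 0, n = 0))
  total <- sum(lens)
  atcg <- sum(counts["acgt", ])
  ns <- sum(counts["n", ])
  structure(list(
    n_scaffolds = length(seqs),
    total_bp = total,
    longest_bp = max(lens),
    n50_bp = n50(lens),
    gapped_n_bp = ns,
    atcg_bp = atcg,
    other_bp = total - atcg - ns
  ), class = "assembly_stats")
}

#' N50 of a vector of scaffold lengths
#'
#' @param lengths Positive scaffold lengths.
#' @return The N50 length.
#' @examples
#' n50(c(100, 200, 300, 400))  # 300
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) pm_domain_error("no lengths supplied")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Fraction of an estimated genome size covered by an assembly
#'
#' @param assembly_bp Assembly size in bp.
#' @param genome_size_bp Estimated genome size in bp.
#' @param digits Decimals for the printed value (default 2).
#' @return List with `percent` (full precision) and `percent_printed`.
#' @examples
#' coverage_fraction(326533584, 405.87e6)$percent_printed  # 80.45
#' @export
coverage_fraction <- function(assembly_bp, genome_size_bp, digits = 2) {
  stopifnot_scalar_number(assembly_bp, "assembly_bp", positive = TRUE)
  stopifnot_scalar_number(genome_size_bp, "genome_size_bp", positive = TRUE)
  p <- 100 * assembly_bp / genome_size_bp
  list(percent = p, percent_printed = round(p, digits))
}

#' Signed percent change between two values
#'
#' @param before,after The two values; `before` must be > 0.
#' @param digits Decimals for the printed value (default 1).
#' @return List with `percent` and `percent_printed`.
#' @examples
#' percent_change(67706454, 27311787)$percent_printed  # -59.7
#' @export
percent_change <- function(before, after, digits = 1) {
  stopifnot_scalar_number(before, "before", positive = TRUE)
  stopifnot_scalar_number(after, "after")
  p <- 100 * (after - before) / before
  list(percent = p, percent_printed = round(p, digits))
}

#' Distribution of scaffold lengths over half-open size bins
#'
#' @param lengths Scaffold lengths.
#' @param bin_edges Strictly increasing edges; bin i is `[edge_i, edge_{i+1})`.
#' @return Data.frame with `lo`, `hi`, `count`, `percent` (1 decimal).
#' @export
size_bin_distribution <- function(lengths,
                                  bin_edges = c(0, 1e4, 5e4, 2e5, 1e6, Inf)) {
  if (length(lengths) == 0L) pm_domain_error("no lengths supplied")
  if (any(diff(bin_edges) <= 0)) pm_domain_error("bin edges must be strictly increasing")
  idx <- findInterval(lengths, bin_edges, left.open = FALSE)
  nb <- length(bin_edges) - 1L
  counts <- tabulate(idx, nbins = nb)
  data.frame(lo = bin_edges[-length(bin_edges)], hi = bin_edges[-1L],
             count = counts,
             percent = round(100 * counts / length(lengths), 1))
}

#' Summarise BUSCO category counts as completeness percentages
#'
#' @param complete_single,complete_duplicated,fragmented,missing Category
#'   counts; they must sum to `total_queried`.
#' @param total_queried Number of BUSCO groups queried.
#' @return List with full-precision and printed percentages for complete
#'   (single + duplicated), fragmented, missing, and complete-or-fragmented.
#' @examples
#' busco_summary(1337, 33, 2, 68, 1440)$complete_printed  # 95.1
#' @export
busco_summary <- function(complete_single, complete_duplicated, fragmented,
                          missing, total_queried) {
  if (total_queried <= 0) pm_domain_error("total_queried must be > 0")
  cats <- c(complete_single, complete_duplicated, fragmented, missing)
  if (any(cats < 0)) pm_domain_error("negative category count")
  if (sum(cats) != total_queried)
    pm_domain_error(sprintf("categories sum to %d, not total_queried = %d",
                            sum(cats), total_queried))
  pc <- function(x) 100 * x / total_queried
  complete <- pc(complete_single + complete_duplicated)
  frag <- pc(fragmented)
  list(complete = complete, complete_printed = round(complete, 1),
       fragmented = frag, fragmented_printed = round(frag, 1),
       missing = pc(missing),
       complete_or_fragmented = complete + frag,
       complete_or_fragmented_printed = round(complete + frag, 2))
}

#' Gene structure statistics from gene models
#'
#' Introns are the gaps between consecutive exons of a gene.
#'
#' @param models A `gene_models` object from [read_gene_models()].
#' @return List: `n_genes`, `n_exons`, `mean_exon_len`, `exons_per_gene`
#'   (2 decimals in `exons_per_gene_printed`), `n_introns`, `mean_intron_len`,
#'   `n_multi_exon`, `n_single_exon`.
#' @export
gene_structure_stats <- function(models) {
  if (length(models) == 0L) pm_domain_error("no gene models supplied")
  exon_lens <- unlist(lapply(models, function(m) m$exons$end - m$exons$start + 1L))
  intron_lens <- unlist(lapply(models, function(m) {
    if (nrow(m$exons) < 2L) return(integer(0))
    m$exons$start[-1L] - m$exons$end[-nrow(m$exons)] - 1L
  }))
  n_genes <- length(models)
  n_exons <- length(exon_lens)
  nex <- vapply(models, function(m) nrow(m$exons), 1L)
  list(n_genes = n_genes, n_exons = n_exons,
       mean_exon_len = mean(exon_lens),
       exons_per_gene = n_exons / n_genes,
       exons_per_gene_printed = round(n_exons / n_genes, 2),
       n_introns = length(intron_lens),
       mean_intron_len = if (length(intron_lens)) mean(intron_lens) else NA_real_,
       n_multi_exon = sum(nex > 1L), n_single_exon = sum(nex == 1L))
}

#' Keep only reliably identified intron junctions
#'
#' A junction is reliable when its supporting RNA-seq read count is strictly
#' greater than the threshold (default 60).
#'
#' @param junctions Data.frame with at least a `supporting_reads` column.
#' @param min_reads Strict threshold (default 60).
#' @return The subset of reliable junctions.
#' @export
filter_reliable_introns <- function(junctions, min_reads = 60) {
  if (!"supporting_reads" %in% names(junctions))
    pm_schema_error("junction table needs a 'supporting_reads' column")
  junctions[junctions$supporting_reads > min_reads, , drop = FALSE]
}

#' Percentage of the unambiguous genome sequence that is repeat-masked
#'
#' @param masked_bp Masked base pairs.
#' @param atcg_bp Unambiguous (A/C/G/T) base pairs of the assembly.
#' @return List with `percent` and `percent_printed` (2 decimals).
#' @examples
#' masked_fraction(138597969, 298987576)$percent_printed  # 46.36
#' @export
masked_fraction <- function(masked_bp, atcg_bp) {
  stopifnot_scalar_number(atcg_bp, "atcg_bp", positive = TRUE)
  stopifnot_scalar_number(masked_bp, "masked_bp")
  if (masked_bp < 0) pm_domain_error("masked_bp must be >= 0")
  if (masked_bp > atcg_bp) pm_domain_error("masked_bp exceeds atcg_bp")
  p <- 100 * masked_bp / atcg_bp
  list(percent = p, percent_printed = round(p, 2))
}

#' Total masked bases from mask tracks of genome records
#'
#' @param records A `genome_records` object.
#' @return Total masked bp across records.
#' @export
masked_bp <- function(records) {
  sum(vapply(records, function(r)
    sum(r$mask$end - r$mask$start + 1L), 0))
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics\n")
  cat(sprintf("  scaffolds : %d\n", x$n_scaffolds))
  cat(sprintf("  total bp  : %s\n", format(x$total_bp, big.mark = ",")))
  cat(sprintf("  longest   : %s\n", format(x$longest_bp, big.mark = ",")))
  cat(sprintf("  N50       : %s\n", format(x$n50_bp, big.mark = ",")))
  cat(sprintf("  gapped Ns : %s\n", format(x$gapped_n_bp, big.mark = ",")))
  cat(sprintf("  ATCG bp   : %s\n", format(x$atcg_bp, big.mark = ",")))
  invisible(x)
}
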