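# The differential-expression procedure: FPKM, a high-expression filter,
# mode-aligned linear rescaling of log2 counts, variance stabilisation,
# gene-wise one-way ANOVA with sqrt(MSR) and p-value cut-offs, volcano
# output, and ortholog expression-divergence classification.

#' Construct an expression set
#'
#' @param counts Gene-by-sample matrix of non-negative integer read counts
#'   (rownames = gene ids, colnames = sample ids).
#' @param exon_length Named vector of per-gene exon length sums (bp), > 0.
#' @param stages Named character vector or factor mapping each sample to its
#'   developmental stage; every stage must have at least 2 samples.
#' @param mapped_reads Named vector of per-sample total mapped reads;
#'   defaults to the column sums of `counts`.
#' @return A list of class `expression_set`.
#' @export
expression_set <- function(counts, exon_length, stages,
                           mapped_reads = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) pm_domain_error("negative counts")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    pm_domain_error("counts must carry gene and sample names")
  exon_length <- exon_length[rownames(counts)]
  if (any(is.na(exon_length)) || any(exon_length <= 0))
    pm_domain_error("every gene needs an exon length > 0")
  mapped_reads <- mapped_reads[colnames(counts)]
  if (any(is.na(mapped_reads)) || any(mapped_reads <= 0))
    pm_domain_error("every sample needs a mapped-read total > 0")
  stages <- stages[colnames(counts)]
  if (any(is.na(stages))) pm_domain_error("every sample needs a stage label")
  tab <- table(as.character(stages))
  if (any(tab < 2L))
    pm_domain_error(sprintf("stage '%s' has fewer than 2 replicates",
                            names(tab)[tab < 2L][1L]))
  structure(list(counts = counts, exon_length = exon_length,
                 mapped_reads = mapped_reads,
                 stages = factor(as.character(stages))),
            class = "expression_set")
}

#' FPKM matrix of an expression set
#'
#' `FPKM[g, s] = 1e9 * counts[g, s] / (exon_length[g] * mapped_reads[s])`.
#'
#' @param es An [expression_set()].
#' @return Gene-by-sample FPKM matrix.
#' @examples
#' # 100 reads on a 1 kb gene in a library of 1e6 mapped reads -> FPKM 100
#' @export
fpkm <- function(es) {
  denom <- outer(as.numeric(es$exon_length), as.numeric(es$mapped_reads))
  out <- 1e9 * es$counts / denom
  dimnames(out) <- dimnames(es$counts)
  out
}

#' Retain highly expressed genes
#'
#' A gene is removed only when its FPKM is below the threshold in every
#' sample; a gene reaching the threshold exactly in at least one sample is
#' retained.
#'
#' @param fpkm_matrix Gene-by-sample FPKM matrix.
#' @param threshold FPKM threshold (default 1000).
#' @return Character vector of retained gene ids.
#' @export
filter_highly_expressed <- function(fpkm_matrix, threshold = 1000) {
  keep <- apply(fpkm_matrix, 1L, max) >= threshold
  rownames(fpkm_matrix)[keep]
}

# Density-based mode of a numeric vector (Gaussian kernel, Silverman
# bandwidth). Degenerate input returns its single value.
density_mode <- function(x) {
  if (length(unique(x)) == 1L) return(x[1L])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Mode-align samples in log2 space
#'
#' Estimates each sample's distribution mode by Gaussian kernel density and
#' shifts every sample additively in log2 space (a linear rescaling of the
#' counts) so that all modes coincide with the reference mode, the median of
#' the per-sample modes.
#'
#' @param log2_matrix Gene-by-sample matrix of log2-scale values (at least 2
#'   samples; at least 30 genes for stable density estimation).
#' @return List: `matrix` (shifted), `offsets` (per-sample additive shifts),
#'   `modes` (pre-shift modes), `reference`.
#' @export
mode_align <- function(log2_matrix) {
  log2_matrix <- as.matrix(log2_matrix)
  if (ncol(log2_matrix) < 2L) pm_domain_error("need at least 2 samples")
  if (nrow(log2_matrix) < 30L)
    pm_domain_error("need at least 30 genes for mode estimation")
  degenerate <- apply(log2_matrix, 2L, function(x) length(unique(x)) == 1L)
  if (any(degenerate))
    warning(sprintf("sample(s) %s have constant values; mode set to that value",
                    paste(colnames(log2_matrix)[degenerate], collapse = ", ")))
  modes <- apply(log2_matrix, 2L, density_mode)
  reference <- stats::median(modes)
  offsets <- reference - modes
  shifted <- sweep(log2_matrix, 2L, offsets, `+`)
  list(matrix = shifted, offsets = offsets, modes = modes,
       reference = reference)
}

#' Variance stabilisation by a quadratic mean-variance trend
#'
#' Fits `v(mu) = a + b * mu^2` to the per-gene (mean, variance) pairs by a
#' quantile-robust fit and applies the matching closed-form generalised-log
#' transform `h(x) = asinh(x * sqrt(b / a)) / sqrt(b)`; as `b -> 0` the
#' transform degenerates to the affine map `x / sqrt(a)`. With
#' `method = "none"` the input is returned unchanged.
#'
#' @param mat Gene-by-sample matrix (mode-aligned log2 values, or any matrix
#'   whose rows share a mean-variance trend).
#' @param method `"quadratic"` (default) or `"none"`.
#' @return List: `matrix` (transformed), `a`, `b`, `method`.
#' @export
variance_stabilize <- function(mat, method = c("quadratic", "none")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (method == "none")
    return(list(matrix = mat, a = NA_real_, b = NA_real_, method = method))
  if (nrow(mat) < 10L) pm_domain_error("need at least 10 genes to calibrate")
  mu <- rowMeans(mat)
  v <- apply(mat, 1L, stats::var)
  # robust quantile fit: the sampling noise of per-gene variances scales
  # with the variance itself, so an unweighted regression is dominated by
  # high-mean genes; medians over the low/high mean quartiles are stable
  mu2 <- mu^2
  qlow <- mu2 <= stats::quantile(mu2, 0.25)
  qhigh <- mu2 >= stats::quantile(mu2, 0.75)
  a <- max(stats::median(v[qlow]), 1e-8)
  b <- 0
  for (it in 1:4) {  # alternate the two medians to separate floor and slope
    b <- max(stats::median((v[qhigh] - a) / mu2[qhigh]), 0)
    a <- max(stats::median(v[qlow] - b * mu2[qlow]), 1e-8)
  }
  if (!is.finite(b) || b <= 1e-10) {
    out <- mat / sqrt(a)
    return(list(matrix = out, a = a, b = 0, method = method))
  }
  out <- asinh(mat * sqrt(b / a)) / sqrt(b)
  list(matrix = out, a = a, b = b, method = method)
}

#' Gene-wise one-way ANOVA with the MSR effect statistic
#'
#' For every gene (row), performs a one-way analysis of variance across
#' stages. MSR -- the mean squared anomaly -- is the between-stage
#' (treatment) mean square, `SSB / (k - 1)`; the volcano effect axis is
#' `sqrt(MSR)`. p-values come from the F distribution on `(k - 1, n - k)`
#' degrees of freedom. A gene whose values are all equal gets `MSR = 0`,
#' `F = 0`, `p = 1`.
#'
#' @param mat Gene-by-sample matrix of rescaled values.
#' @param stages Factor (or character) of stage labels, one per column; at
#'   least 2 stages, each with at least 2 samples.
#' @return Data.frame: `gene`, `msr`, `sqrt_msr`, `f`, `p`.
#' @export
anova_msr <- function(mat, stages) {
  mat <- as.matrix(mat)
  stages <- factor(as.character(stages))
  if (length(stages) != ncol(mat))
    pm_domain_error("one stage label per sample required")
  tab <- table(stages)
  if (length(tab) < 2L) pm_domain_error("need at least 2 stages")
  if (any(tab < 2L))
    pm_domain_error(sprintf("stage '%s' has a single sample",
                            names(tab)[tab < 2L][1L]))
  n <- ncol(mat); k <- nlevels(stages)
  grand <- rowMeans(mat)
  group_sums <- t(rowsum(t(mat), stages))       # genes x stages
  nk <- as.vector(tab[colnames(group_sums)])
  group_means <- sweep(group_sums, 2L, nk, `/`)
  ssb <- rowSums(sweep((group_means - grand)^2, 2L, nk, `*`))
  sst <- rowSums((mat - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  p <- ifelse(is.infinite(f), 0,
              stats::pf(f, k - 1, n - k, lower.tail = FALSE))
  p[msb == 0] <- 1
  data.frame(gene = rownames(mat), msr = msb, sqrt_msr = sqrt(msb),
             f = f, p = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG when `sqrt_msr > msr_cut` and `p < p_cut`, both strict.
#'
#' @param results Data.frame from [anova_msr()].
#' @param msr_cut Threshold on `sqrt_msr` (default 2.00).
#' @param p_cut Threshold on the ANOVA p-value (default 1e-3).
#' @return `results` with a logical `deg` column appended, plus an
#'   information-only Benjamini-Hochberg `p_bh` column (no correction enters
#'   the DEG call).
#' @export
call_degs <- function(results, msr_cut = 2.00, p_cut = 1e-3) {
  results$p_bh <- stats::p.adjust(results$p, method = "BH")
  results$deg <- results$sqrt_msr > msr_cut & results$p < p_cut
  results
}

#' Volcano table of DE results
#'
#' @param results Data.frame from [call_degs()] (or [anova_msr()], in which
#'   case flags are computed with the default cut-offs).
#' @param msr_cut,p_cut Cut-offs used when flags are absent.
#' @return Data.frame ordered by gene id: `gene`, `sqrt_msr`,
#'   `neg_log10_p`, `deg`.
#' @export
volcano_table <- function(results, msr_cut = 2.00, p_cut = 1e-3) {
  if (!"deg" %in% names(results))
    results <- call_degs(results, msr_cut, p_cut)
  out <- data.frame(gene = results$gene, sqrt_msr = results$sqrt_msr,
                    neg_log10_p = -log10(results$p), deg = results$deg,
                    stringsAsFactors = FALSE)
  out[order(out$gene), , drop = FALSE]
}

#' Volcano plot of DE results
#'
#' @param results Data.frame from [call_degs()].
#' @return A ggplot object (requires ggplot2).
#' @export
plot_volcano <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    pm_usage_error("ggplot2 is required for plotting")
  tab <- volcano_table(results)
  sqrt_msr <- neg_log10_p <- deg <- NULL  # NSE bindings
  ggplot2::ggplot(tab, ggplot2::aes(x = sqrt_msr, y = neg_log10_p,
                                    colour = deg)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = expression(sqrt(MSR)), y = expression(-log[10](p)),
                  colour = "DEG") +
    ggplot2::theme_bw()
}

#' Run the full differential-expression procedure on counts
#'
#' log2(count + 1), mode alignment, variance stabilisation (optional), then
#' gene-wise one-way ANOVA and DEG calling. When an [expression_set()] is
#' supplied the FPKM high-expression filter is applied first.
#'
#' @param es An [expression_set()], or a plain counts matrix when
#'   `stages` is given.
#' @param stages Stage labels (taken from `es` when absent).
#' @param fpkm_threshold FPKM filter threshold; `0` disables the filter
#'   (used for plain matrices without length/depth information).
#' @param vst `"quadratic"` (default) or `"none"`.
#' @param anova_on `"stabilized"` (default) or `"aligned"` -- whether the
#'   ANOVA runs on the variance-stabilised or only mode-aligned values.
#' @param msr_cut,p_cut DEG thresholds.
#' @return List: `results` (with `deg` flags), `volcano`, `n_deg`,
#'   `offsets`, `vst` (fit parameters), `retained` gene ids.
#' @export
run_de <- function(es, stages = NULL, fpkm_threshold = 1000,
                   vst = "quadratic", anova_on = c("stabilized", "aligned"),
                   msr_cut = 2.00, p_cut = 1e-3) {
  anova_on <- match.arg(anova_on)
  if (inherits(es, "expression_set")) {
    counts <- es$counts
    stages <- es$stages
    retained <- if (fpkm_threshold > 0)
      filter_highly_expressed(fpkm(es), fpkm_threshold) else rownames(counts)
  } else {
    counts <- as.matrix(es)
    if (is.null(stages)) pm_domain_error("stage labels required")
    retained <- rownames(counts)
  }
  if (length(retained) == 0L)
    pm_domain_error("no genes pass the expression filter")
  lg <- log2(counts[retained, , drop = FALSE] + 1)
  al <- mode_align(lg)
  vs <- variance_stabilize(al$matrix, method = vst)
  input <- if (anova_on == "stabilized") vs$matrix else al$matrix
  res <- call_degs(anova_msr(input, stages), msr_cut, p_cut)
  list(results = res, volcano = volcano_table(res), n_deg = sum(res$deg),
       offsets = al$offsets, vst = vs[c("a", "b", "method")],
       retained = retained)
}

#' Classify expression divergence of ortholog pairs
#'
#' A species' profile is *silent* when its FPKM is below `silent_max` in
#' every stage and *high* when it reaches `high_min` in at least one stage.
#' A pair is divergent when one profile is silent and the other high;
#' conserved when all stage-wise log2 ratios (with a +1 pseudocount) lie
#' within `conserved_band`; otherwise `other`.
#'
#' @param profile1,profile2 Named numeric vectors of stage-wise FPKM for the
#'   two species; stage sets must match.
#' @param silent_max,high_min,conserved_band Classification tunables
#'   (defaults 1, 100, 1).
#' @return One of `"conserved"`, `"divergent_silent_in_1"`,
#'   `"divergent_silent_in_2"`, `"other"`.
#' @export
expression_divergence <- function(profile1, profile2, silent_max = 1,
                                  high_min = 100, conserved_band = 1) {
  if (!is.null(names(profile1)) && !is.null(names(profile2))) {
    if (!setequal(names(profile1), names(profile2)))
      pm_domain_error("stage sets differ between the two profiles")
    profile2 <- profile2[names(profile1)]
  } else if (length(profile1) != length(profile2)) {
    pm_domain_error("stage sets differ between the two profiles")
  }
  silent1 <- all(profile1 < silent_max)
  silent2 <- all(profile2 < silent_max)
  high1 <- any(profile1 >= high_min)
  high2 <- any(profile2 >= high_min)
  if (silent1 && high2) return("divergent_silent_in_1")
  if (silent2 && high1) return("divergent_silent_in_2")
  ratio <- log2((profile1 + 1) / (profile2 + 1))
  if (all(abs(ratio) <= conserved_band)) return("conserved")
  "other"
}
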