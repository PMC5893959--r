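toy_es <- function(counts, lengths = NULL, stages = NULL) {
  if (is.null(lengths))
    lengths <- setNames(rep(1000, nrow(counts)), rownames(counts))
  if (is.null(stages))
    stages <- setNames(rep(c("A", "B"), each = ncol(counts) / 2),
                       colnames(counts))
  expression_set(counts, lengths, stages)
}

test_that("FPKM follows its defining formula and conserves counts", {
  counts <- matrix(c(100, 0), 1, 2,
                   dimnames = list("g1", c("A_r1", "A_r2")))
  es <- expression_set(counts, c(g1 = 1000),
                       stages = c(A_r1 = "A", A_r2 = "A"),
                       mapped_reads = c(A_r1 = 1e6, A_r2 = 1e6))
  f <- fpkm(es)
  expect_equal(f["g1", "A_r1"], 100)   # 1e9 * 100 / (1000 * 1e6)
  expect_equal(f["g1", "A_r2"], 0)

  # random fixture vs an explicit double loop
  set.seed(8)
  counts <- matrix(rpois(50 * 6, 40), 50, 6,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("s%d", 1:6)))
  lens <- setNames(as.numeric(sample(200:5000, 50)), rownames(counts))
  mr <- setNames(as.numeric(sample(1e5:1e6, 6)), colnames(counts))
  es2 <- expression_set(counts, lens,
                        stages = setNames(rep(c("A", "B", "C"), each = 2),
                                          colnames(counts)),
                        mapped_reads = mr)
  f2 <- fpkm(es2)
  brute <- f2 * 0
  for (g in rownames(counts)) for (s in colnames(counts))
    brute[g, s] <- 1e9 * counts[g, s] / (lens[g] * mr[s])
  expect_equal(f2, brute)
  # conservation: sum_g FPKM * EL * MR / 1e9 gives back each column sum
  recon <- colSums(f2 * lens) * mr / 1e9
  expect_equal(unname(recon), unname(colSums(counts)))
})

test_that("expression-set invariants are enforced", {
  counts <- matrix(1, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(expression_set(counts, c(g1 = 0, g2 = 10),
                              c(s1 = "A", s2 = "A")),
               class = "pm_domain_error")
  expect_error(expression_set(counts, c(g1 = 10, g2 = 10),
                              c(s1 = "A", s2 = "B")),
               "replicates", class = "pm_domain_error")
})

test_that("the high-expression filter removes only genes below threshold everywhere", {
  f <- rbind(hi = c(1200, 10), edge = c(1000, 10), lo = c(999, 999))
  colnames(f) <- c("s1", "s2")
  kept <- filter_highly_expressed(f)
  expect_true("hi" %in% kept)
  expect_true("edge" %in% kept)   # exactly 1000 is retained
  expect_false("lo" %in% kept)
})

test_that("mode alignment equalises distribution modes and is idempotent", {
  set.seed(4)
  x <- matrix(rnorm(500 * 2, mean = 8), 500, 2,
              dimnames = list(NULL, c("s1", "s2")))
  x[, 2] <- x[, 1]
  al <- mode_align(x)
  expect_equal(unname(al$offsets), c(0, 0))

  # a constant log2 shift is removed exactly
  y <- cbind(s1 = x[, 1], s2 = x[, 1] + 1.0)
  al2 <- mode_align(y)
  expect_equal(unname(al2$offsets[1] - al2$offsets[2]), 1.0, tolerance = 1e-9)
  modes_after <- apply(al2$matrix, 2, function(v) {
    d <- density(v, bw = "nrd0"); d$x[which.max(d$y)]
  })
  expect_equal(unname(diff(modes_after)), 0, tolerance = 1e-9)

  # idempotence
  al3 <- mode_align(al2$matrix)
  expect_equal(unname(al3$offsets), c(0, 0), tolerance = 1e-9)
  expect_equal(al3$matrix, al2$matrix, tolerance = 1e-9)

  expect_error(mode_align(x[1:10, ]), class = "pm_domain_error")
  expect_error(mode_align(x[, 1, drop = FALSE]), class = "pm_domain_error")
  expect_warning(mode_align(cbind(s1 = rep(1, 50), s2 = rnorm(50))),
                 "constant")
})

test_that("variance stabilisation flattens a quadratic mean-variance trend", {
  set.seed(6)
  # already homoscedastic input: transform must not create a trend
  hom <- matrix(rnorm(2000 * 6, mean = rep(runif(2000, 5, 12), 6), sd = 0.5),
                2000, 6)
  vs <- variance_stabilize(hom)
  rho <- cor(rowMeans(vs$matrix), apply(vs$matrix, 1, var),
             method = "spearman")
  expect_lt(abs(rho), 0.1)

  # multiplicative noise: variance proportional to mean^2
  mu <- 10^runif(2000, 0.5, 3)
  raw <- matrix(mu * (1 + 0.3 * rnorm(2000 * 6)), 2000, 6)
  vs2 <- variance_stabilize(raw)
  m <- rowMeans(vs2$matrix); v <- apply(vs2$matrix, 1, var)
  keep <- m > 0 & v > 0
  slope <- coef(lm(log(v[keep]) ~ log(m[keep])))[2]
  # on the raw scale the slope of log-var on log-mean is ~2; stabilised ~0
  raw_slope <- coef(lm(log(apply(raw, 1, var)) ~ log(rowMeans(raw))))[2]
  expect_gt(raw_slope, 1.5)
  expect_lt(abs(slope), 0.4)

  # a near-constant matrix is changed only up to an affine map
  const <- matrix(5, 50, 4) + matrix(rnorm(200, 0, 1e-3), 50, 4)
  vsc <- variance_stabilize(const)
  expect_gt(cor(as.vector(const), as.vector(vsc$matrix)), 1 - 1e-6)
  expect_identical(variance_stabilize(const, method = "none")$matrix, const)
  expect_error(variance_stabilize(const[1:5, ]), class = "pm_domain_error")
})

test_that("gene-wise ANOVA matches hand computation and stats::aov", {
  # equal group means: MSR 0, F 0, p 1
  m0 <- matrix(c(1, 3, 1, 3), 1, 4,
               dimnames = list("g", c("a1", "a2", "b1", "b2")))
  r0 <- anova_msr(m0, c("A", "A", "B", "B"))
  expect_equal(r0$msr, 0)
  expect_equal(r0$f, 0)
  expect_equal(r0$p, 1)

  # hand-computed: A = {1,2}, B = {4,5} -> SSB 9, MSR 9, sqrt 3, F 18
  m1 <- matrix(c(1, 2, 4, 5), 1, 4,
               dimnames = list("g", c("a1", "a2", "b1", "b2")))
  r1 <- anova_msr(m1, c("A", "A", "B", "B"))
  expect_equal(r1$msr, 9)
  expect_equal(r1$sqrt_msr, 3)
  expect_equal(r1$f, 18)
  expect_equal(r1$p, pf(18, 1, 2, lower.tail = FALSE))

  # all-equal gene
  m2 <- matrix(7, 1, 4, dimnames = list("g", colnames(m1)))
  r2 <- anova_msr(m2, c("A", "A", "B", "B"))
  expect_equal(c(r2$msr, r2$f), c(0, 0))
  expect_equal(r2$p, 1)

  # agreement with stats::aov over random matrices and unbalanced groups
  set.seed(12)
  stages <- c("A", "A", "B", "B", "B", "C", "C")
  mat <- matrix(rnorm(20 * 7), 20, 7,
                dimnames = list(sprintf("g%02d", 1:20), NULL))
  res <- anova_msr(mat, stages)
  for (i in seq_len(20)) {
    fit <- summary(aov(mat[i, ] ~ factor(stages)))[[1]]
    expect_equal(res$msr[i], fit$`Mean Sq`[1], tolerance = 1e-10)
    expect_equal(res$f[i], fit$`F value`[1], tolerance = 1e-10)
    expect_equal(res$p[i], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }

  expect_error(anova_msr(mat, c("A", rep("B", 6))), class = "pm_domain_error")
  expect_error(anova_msr(mat, rep("A", 7)), class = "pm_domain_error")
})

test_that("null p-values are uniform", {
  set.seed(19)
  mat <- matrix(rnorm(5000 * 12), 5000, 12,
                dimnames = list(sprintf("g%04d", 1:5000), NULL))
  res <- anova_msr(mat, rep(LETTERS[1:4], each = 3))
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("DEG calling applies strict thresholds and is monotone in them", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    msr = c(6.25, 4, 9, 1),
                    sqrt_msr = c(2.5, 2.0, 3.0, 1.0),
                    f = c(30, 25, 40, 2),
                    p = c(1e-4, 1e-6, 2e-3, 0.5))
  out <- call_degs(res)
  expect_identical(out$deg, c(TRUE, FALSE, FALSE, FALSE))
  # b fails on the strict sqrt_msr boundary; c fails the p cut

  # monotonicity: tightening either cut never adds DEGs
  set.seed(2)
  rnd <- data.frame(gene = sprintf("g%03d", 1:200),
                    sqrt_msr = runif(200, 0, 5), p = runif(200))
  base <- call_degs(rnd, msr_cut = 2, p_cut = 1e-2)$deg
  tighter_m <- call_degs(rnd, msr_cut = 3, p_cut = 1e-2)$deg
  tighter_p <- call_degs(rnd, msr_cut = 2, p_cut = 1e-3)$deg
  expect_true(all(tighter_m <= base))
  expect_true(all(tighter_p <= base))
  # invariance to gene order
  perm <- sample(200)
  expect_identical(call_degs(rnd[perm, ], 2, 1e-2)$deg, base[perm])
})

test_that("volcano tables mirror the DEG flags with correct -log10 p", {
  res <- call_degs(data.frame(gene = c("z", "a", "m"),
                              msr = c(9, 0.25, 16), sqrt_msr = c(3, 0.5, 4),
                              f = c(20, 1, 30), p = c(1e-5, 1, 1e-7)))
  v <- volcano_table(res)
  expect_equal(v$gene, c("a", "m", "z"))  # deterministic ordering
  expect_equal(v$neg_log10_p[v$gene == "z"], 5, tolerance = 1e-6)
  expect_equal(v$neg_log10_p[v$gene == "a"], 0)
  expect_identical(v$deg[match(res$gene, v$gene)], res$deg)
})

test_that("the full DE pipeline detects planted trajectories and controls the null", {
  sim <- simulate_counts(1500, de_fraction = 0.1, log2_effect = 2,
                         nb_dispersion = 0.1, seed = 41)
  de <- run_de(sim$counts, stages = sim$metadata$stage, fpkm_threshold = 0)
  called <- de$results$deg[match(sim$truth$gene, de$results$gene)]
  sens <- sum(called & sim$truth$deg) / sum(sim$truth$deg)
  fdp <- sum(called & !sim$truth$deg) / max(1, sum(called))
  expect_gte(sens, 0.8)
  expect_lte(fdp, 0.1)

  # FPKM filter gates which genes are tested at all
  es <- expression_set(sim$counts, sim$lengths,
                       setNames(sim$metadata$stage, sim$metadata$sample))
  de_filt <- run_de(es, fpkm_threshold = 1000)
  expect_true(all(de_filt$results$gene %in%
                    filter_highly_expressed(fpkm(es), 1000)))
})

test_that("ortholog expression-divergence classification follows its rules", {
  stages <- c(A = 0, B = 0, C = 0, D = 0)
  high <- c(A = 2, B = 500, C = 30, D = 8)
  expect_equal(expression_divergence(stages, high), "divergent_silent_in_1")
  expect_equal(expression_divergence(high, stages), "divergent_silent_in_2")
  expect_equal(expression_divergence(high, high), "conserved")
  mid1 <- c(A = 10, B = 20, C = 40, D = 10)
  mid2 <- c(A = 10, B = 300, C = 4, D = 10)
  expect_equal(expression_divergence(mid1, mid2), "other")
  expect_error(expression_divergence(c(A = 1), c(B = 1)),
               class = "pm_domain_error")

  # planted 100-pair set: classification equals the construction
  set.seed(33)
  truth <- sample(c("conserved", "divergent_silent_in_1",
                    "divergent_silent_in_2", "other"), 100, replace = TRUE)
  got <- vapply(truth, function(tt) {
    base <- runif(4, 150, 400); names(base) <- LETTERS[1:4]
    pr <- switch(tt,
      conserved = list(base, base * 2^runif(4, -0.5, 0.5)),
      divergent_silent_in_1 = list(setNames(runif(4, 0, 0.9), LETTERS[1:4]), base),
      divergent_silent_in_2 = list(base, setNames(runif(4, 0, 0.9), LETTERS[1:4])),
      other = list(base, base * c(16, 1, 1, 1 / 16)))
    expression_divergence(pr[[1]], pr[[2]])
  }, "")
  expect_identical(unname(got), truth)
})
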