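test_that("the K2P distance formula behaves across its domain", {
  expect_equal(kimura_distance(0, 0), 0)
  expect_equal(kimura_distance(0.10, 0.05), 0.1701812, tolerance = 1e-6)
  # Q = 0 reduces to the transition-only form
  for (P in c(0.05, 0.2, 0.4))
    expect_equal(kimura_distance(P, 0), -0.5 * log(1 - 2 * P))
  # monotone non-decreasing in both arguments
  grid <- seq(0, 0.2, by = 0.02)
  K_P <- vapply(grid, function(p) kimura_distance(p, 0.05), 1)
  K_Q <- vapply(grid, function(q) kimura_distance(0.05, q), 1)
  expect_true(all(diff(K_P) > 0))
  expect_true(all(diff(K_Q) > 0))
  # saturation raised exactly when a log argument hits zero
  expect_error(kimura_distance(0.45, 0.1), class = "pm_saturation_error")
  expect_error(kimura_distance(0.0, 0.5), class = "pm_saturation_error")
  expect_silent(kimura_distance(0.4499, 0.1))
  expect_error(kimura_distance(0.8, 0.4), class = "pm_domain_error")
})

test_that("divergence counting agrees exactly with brute-force site classification", {
  # identical sequences
  d0 <- pair_divergence("ACGTACGT", "ACGTACGT", aligned = TRUE)
  expect_equal(d0$K, 0)
  expect_equal(d0$P + d0$Q, 0)
  # gap and ambiguity columns are eliminated
  dg <- pair_divergence("AC-GTN", "ACAGTA", aligned = TRUE)
  expect_equal(dg$sites, 4)
  # randomized aligned pairs vs the independent brute-force counter
  set.seed(11)
  alpha <- c("A", "C", "G", "T", "-", "N")
  for (i in 1:50) {
    n <- sample(8:20, 1)
    a <- paste(sample(alpha, n, TRUE, prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")
    b <- paste(sample(alpha, n, TRUE, prob = c(rep(0.23, 4), 0.04, 0.04)), collapse = "")
    bp <- brute_pq(a, b)
    if (bp$n == 0) next
    d <- tryCatch(pair_divergence(a, b, aligned = TRUE),
                  pm_saturation_error = function(e) NULL)
    if (is.null(d)) {
      expect_error(kimura_distance(bp$P, bp$Q), class = "pm_saturation_error")
      next
    }
    expect_identical(d$sites, bp$n)
    expect_equal(d$P, bp$P)
    expect_equal(d$Q, bp$Q)
    expect_equal(d$K, kimura_distance(bp$P, bp$Q))
  }
  expect_error(pair_divergence("----", "ACGT", aligned = TRUE),
               class = "pm_domain_error")
})

test_that("alignment-based LTR divergence agrees with an independent K80 estimator", {
  skip_if_not_installed("ape")
  set.seed(5)
  anc <- random_dna(1500)
  der <- mutate_k2p(anc, 0.06, seed = 9)
  d <- ltr_divergence(anc, der)
  m <- rbind(strsplit(tolower(anc), "")[[1]], strsplit(tolower(der), "")[[1]])
  ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "K80"))
  expect_equal(d$K, ref, tolerance = 1e-8)
  expect_error(ltr_divergence("ACGT", "ACGT"), class = "pm_domain_error")
})

test_that("K2P mutation simulator is seeded, exact at K = 0, and unbiased", {
  s <- random_dna(500)
  expect_identical(mutate_k2p(s, 0, seed = 1), s)
  expect_identical(mutate_k2p(s, 0.1, seed = 4), mutate_k2p(s, 0.1, seed = 4))
  expect_false(identical(mutate_k2p(s, 0.1, seed = 4), mutate_k2p(s, 0.1, seed = 5)))
  expect_error(mutate_k2p(s, -0.1), class = "pm_domain_error")
  expect_error(mutate_k2p("ACGU", 0.1), class = "pm_domain_error")

  # estimator on the simulator's own output: K = 0.08 on 10 kb
  set.seed(2)
  base <- random_dna(10000)
  khat <- vapply(1:20, function(i)
    pair_divergence(base, mutate_k2p(base, 0.08, seed = 100 + i),
                    aligned = TRUE)$K, 1)
  expect_lt(abs(mean(khat) - 0.08), 2 * stats::sd(khat) / sqrt(length(khat)) + 1e-4)

  # consistency: the spread shrinks as the sequence grows
  base1 <- random_dna(1000)
  k1 <- vapply(1:15, function(i)
    pair_divergence(base1, mutate_k2p(base1, 0.08, seed = 200 + i),
                    aligned = TRUE)$K, 1)
  expect_lt(stats::sd(khat), stats::sd(k1))
})

test_that("NG86 synonymous-rate counting matches a hand count on codon toys", {
  # GGT|GGT|GGT vs GGC|GGT|GGT: glycine four-fold third position.
  # Hand count: each GGT codon has 1 synonymous site (third position; the
  # other two positions admit no synonymous change), so S = 3, N = 6.
  # The single difference is synonymous: Sd = 1, ps = 1/3,
  # Ks = -3/4 log(1 - 4/9).
  r <- ng86_ks("GGTGGTGGT", "GGCGGTGGT")
  expect_equal(r$S, 3)
  expect_equal(r$N, 6)
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$Ks, -0.75 * log(1 - 4 / 9))
  expect_equal(r$Ka, 0)

  # identical pair
  expect_equal(ng86_ks("ATGAAA", "ATGAAA")$Ks, 0)

  # a nonsynonymous difference: AAA (Lys) vs AGA (Arg) at position 2
  r2 <- ng86_ks("AAA", "AGA")
  expect_equal(r2$Sd, 0)
  expect_equal(r2$Nd, 1)

  # errors: length not a multiple of 3; internal stop; unequal lengths
  expect_error(ng86_ks("ACGT", "ACGT"), class = "pm_domain_error")
  expect_error(ng86_ks("TAAAAA", "TAAAAA"), class = "pm_domain_error")
  expect_error(ng86_ks("ACG", "ACGACG"), class = "pm_domain_error")
})

test_that("mean Ks over simulated ortholog pairs recovers the planted value", {
  sim <- simulate_codon_pairs(50, ks_true = 0.064, len_codons = 350, seed = 21)
  pk <- pairwise_ks(sim$pairs)
  expect_equal(pk$n_used, 50)
  expect_lt(abs(pk$ks_mean - 0.064) / 0.064, 0.10)
  expect_equal(pk$aligned_bp, 50 * 350 * 3)
  # identical pairs give exactly zero
  sim0 <- simulate_codon_pairs(5, ks_true = 0, len_codons = 100, seed = 1)
  expect_equal(pairwise_ks(sim0$pairs)$ks_mean, 0)
})

test_that("rate calibration reproduces the published substitution rates", {
  cal <- calibrate_rate(0.064, 24.22e6)
  expect_equal(cal$gene_rate, 2.64e-9, tolerance = 0.002)
  expect_equal(cal$ltr_rate, 5.28e-9, tolerance = 0.002)
  expect_equal(calibrate_rate(0, 1e6)$gene_rate, 0)
  expect_error(calibrate_rate(0.064, 0), class = "pm_domain_error")
  # per-lineage convention halves the rate but (with the matching age
  # formula) leaves ages unchanged
  cal2 <- calibrate_rate(0.064, 24.22e6, convention = "per_lineage")
  expect_equal(cal2$ltr_rate, cal$ltr_rate / 2)
  expect_equal(insertion_age(0.1, cal$ltr_rate, "total"),
               insertion_age(0.1, cal2$ltr_rate, "per_lineage"))
})

test_that("insertion ages are linear in K and inverse in rate", {
  expect_equal(insertion_age(0, 5.28e-9), 0)
  expect_equal(insertion_age(0.124, 5.28e-9), 0.124 / 5.28e-9)
  expect_equal(insertion_age(0.2, 2 * 5.28e-9), insertion_age(0.2, 5.28e-9) / 2)
  ks <- c(0.01, 0.05, 0.1)
  ages <- insertion_age(ks, 5.28e-9)
  expect_equal(ages / ks, rep(1 / 5.28e-9, 3))
  expect_error(insertion_age(-0.1, 5.28e-9), class = "pm_domain_error")
  expect_error(insertion_age(0.1, 0), class = "pm_domain_error")
})

test_that("family summaries reproduce the published percentage table", {
  # counts from the published annotation of 505 full-length elements
  ann <- data.frame(
    element_id = seq_len(505),
    superfamily = c(rep("Copia", 220), rep("Gypsy", 256), rep("Unclassified", 29)),
    family = c(rep("AleI/Retrofit", 14), rep("AleII", 26), rep("Angela", 20),
               rep("Bianca", 114), rep("Ivana", 23), rep("Maximus/SIRE", 10),
               rep("TAR/Tork", 11), rep("Unknown", 2),
               rep("Athila", 3), rep("Chromovirus", 42), rep("Ogre/TAT", 186),
               rep("Unknown", 25), rep("none", 29)))
  fs <- family_summary(ann)
  sup <- fs$by_superfamily
  expect_equal(sup$percent[sup$superfamily == "Copia"], 43.56)
  expect_equal(round(sup$percent[sup$superfamily == "Copia"], 1), 43.6)
  expect_equal(sup$percent[sup$superfamily == "Gypsy"], 50.69)
  fam <- fs$by_family
  expect_equal(fam$percent[fam$family == "Bianca"], 22.57)
  expect_equal(fam$percent[fam$family == "Ogre/TAT"], 36.83)
  expect_equal(sum(sup$count), 505)
  expect_equal(sum(fs$by_family$count), 505)
  # percentages sum to 100 up to rounding
  expect_lt(abs(sum(sup$percent) - 100), 0.05)
  one <- family_summary(data.frame(element_id = 1, superfamily = "Copia",
                                   family = "Bianca"))
  expect_equal(one$by_superfamily$percent, 100)
  expect_error(family_summary(NULL), class = "pm_domain_error")
})

test_that("genome proportion arithmetic reproduces the clustering summary", {
  gp <- genome_proportion(c(1001838), 1484780)
  expect_equal(gp$clustered_percent_printed, 67.5)
  expect_equal(genome_proportion(numeric(0), 100)$clustered_percent, 0)
  set.seed(9)
  reads <- sample.int(1000, 50)
  gp2 <- genome_proportion(reads, 1e5)
  expect_equal(gp2$per_cluster$percent, 100 * reads / 1e5)
  expect_equal(gp2$clustered_percent, 100 * sum(reads) / 1e5)
  expect_error(genome_proportion(c(60, 50), 100), class = "pm_domain_error")
})
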