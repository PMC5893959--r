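# Seeded synthetic-data generators with ground-truth tables. Each generator
# is a pure function of (parameters, seed): regeneration with the same seed
# is identical.

#' Mutate a sequence under the Kimura two-parameter model
#'
#' Applies, independently per site, the exact K2P substitution probabilities
#' at total expected distance `K` with transition/transversion rate ratio
#' `kappa`: with `b = K / (kappa + 2)` and `a = kappa * b`, the transition
#' probability is `1/4 - 1/2 exp(-2(a+b)) + 1/4 exp(-4b)` and each of the
#' two transversions has probability `1/4 - 1/4 exp(-4b)`.
#'
#' @param seq A nucleotide string over ACGT.
#' @param K Expected substitutions per site (>= 0).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed Integer seed.
#' @return The diverged sequence (same length).
#' @export
mutate_k2p <- function(seq, K, kappa = 2.0, seed = 0L) {
  if (K < 0) pm_domain_error("K must be >= 0")
  if (kappa <= 0) pm_domain_error("kappa must be > 0")
  probs <- k2p_site_probs(K, kappa)
  set.seed(seed)
  v <- chars(toupper(seq))
  if (!all(v %in% c("A", "C", "G", "T")))
    pm_domain_error("sequence must be over {A,C,G,T}")
  fate <- sample(c("same", "ts", "tv1", "tv2"), length(v), replace = TRUE,
                 prob = c(probs$same, probs$ts, probs$tv_each, probs$tv_each))
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv1_map <- c(A = "C", G = "C", C = "A", T = "A")
  tv2_map <- c(A = "T", G = "T", C = "G", T = "G")
  v[fate == "ts"] <- ts_map[v[fate == "ts"]]
  v[fate == "tv1"] <- tv1_map[v[fate == "tv1"]]
  v[fate == "tv2"] <- tv2_map[v[fate == "tv2"]]
  paste(v, collapse = "")
}

k2p_site_probs <- function(K, kappa) {
  b <- K / (kappa + 2)
  a <- kappa * b
  p_ts <- 0.25 - 0.5 * exp(-2 * (a + b)) + 0.25 * exp(-4 * b)
  p_tv_each <- 0.25 - 0.25 * exp(-4 * b)
  p_same <- 1 - p_ts - 2 * p_tv_each
  if (any(c(p_ts, p_tv_each, p_same) < 0) || any(c(p_ts, p_tv_each, p_same) > 1))
    pm_domain_error("K2P site probabilities outside [0,1]")
  list(same = p_same, ts = p_ts, tv_each = p_tv_each)
}

#' Simulate a genome with planted full-length LTR retrotransposons
#'
#' Each element sits on its own scaffold inside random flanking sequence and
#' carries every structural hallmark: TG..CA termini, an exact target-site
#' duplication of length 4-6, a primer binding site complementary to a
#' bundled tRNA 3' end directly after the 5' LTR, a polypurine tract
#' directly before the 3' LTR, and a 3' LTR diverged from the 5' LTR by a
#' planted K2P distance (the terminal dinucleotides are exempt from
#' mutation so termini stay intact). Decoy elements each violate exactly one
#' criterion; their construction guarantees the violated feature cannot
#' reappear by chance (disjoint flank alphabets for missing TSDs,
#' pyrimidine-only PBS regions, pyrimidine-interleaved PPT regions).
#'
#' @param n_elements Number of intact elements.
#' @param ltr_len LTR length in bp (default 300).
#' @param internal_len Internal region length in bp (default 1000).
#' @param K Planted inter-LTR distances, recycled over intact elements
#'   (default 0.02).
#' @param tsd_len TSD lengths, recycled (values in 4..6; default 5).
#' @param decoys Named integer vector giving how many decoys of each type to
#'   plant, among `no_termini`, `no_tsd`, `no_pbs`, `no_ppt` (default none).
#' @param flank Flanking sequence per side (default 200).
#' @param seed Integer seed.
#' @param trna_library tRNA 3'-end library for PBS planting.
#' @return List: `genome` (a `genome_records`), `candidates`
#'   (`ltr_candidates` data.frame, 1-based closed), `truth` (data.frame with
#'   planted K, TSD, tRNA, decoy type and per-criterion expectations).
#' @export
simulate_genome_with_ltrs <- function(n_elements, ltr_len = 300L,
                                      internal_len = 1000L, K = 0.02,
                                      tsd_len = 5L, decoys = c(),
                                      flank = 200L, seed = 0L,
                                      trna_library = default_trna_library()) {
  if (n_elements < 0) pm_domain_error("n_elements must be >= 0")
  if (ltr_len < 100L) pm_domain_error("ltr_len must be >= 100")
  if (internal_len < 100L) pm_domain_error("internal_len must be >= 100")
  if (any(tsd_len < 4L | tsd_len > 6L)) pm_domain_error("tsd_len must be 4..6")
  if (flank < 10L) pm_domain_error("flank must be >= 10")
  decoy_types <- rep(names(decoys), times = as.integer(decoys))
  stopifnot(all(decoy_types %in% c("no_termini", "no_tsd", "no_pbs", "no_ppt")))
  total <- n_elements + length(decoy_types)
  types <- c(rep("none", n_elements), decoy_types)
  Ks <- rep_len(K, total)
  tsds <- rep_len(as.integer(tsd_len), total)
  set.seed(seed)
  recs <- vector("list", total)
  cand_rows <- vector("list", total)
  truth_rows <- vector("list", total)
  for (i in seq_len(total)) {
    type <- types[i]
    tl <- tsds[i]
    trna_id <- sample(names(trna_library), 1L)
    tail3 <- trna_library[[trna_id]]
    pbs <- revcomp(tail3)                       # full tail, 15-19 nt
    if (nchar(pbs) > 18L) pbs <- substr(pbs, 1L, 18L)
    # boundary well-posedness: the TSD (which abuts the 5' LTR on the left
    # and the 3' LTR on the right) is drawn from pyrimidines while the PPT
    # (left of the 3' LTR) and the spacer (right of the 5' LTR) are purines,
    # so local alignment cannot extend across the planted LTR boundaries
    tsd <- paste(sample(c("C", "T"), tl, replace = TRUE), collapse = "")
    ltr5 <- paste0("TG", random_dna(ltr_len - 4L), "CA")
    core <- substr(ltr5, 3L, ltr_len - 2L)
    ltr3 <- paste0("TG", mutate_k2p(core, Ks[i], seed = derive_seed(seed, i)),
                   "CA")
    ppt <- paste(sample(c("A", "G"), 22L, replace = TRUE), collapse = "")
    sp1 <- paste(sample(c("A", "G"), 6L, replace = TRUE), collapse = "")
    mid_len <- internal_len - nchar(pbs) - nchar(ppt) - nchar(sp1)
    middle <- random_dna(mid_len)
    internal <- paste0(sp1, pbs, middle, ppt)
    left <- random_dna(flank)
    right <- random_dna(flank)
    # apply decoy corruption
    if (type == "no_tsd") {
      guard <- tl + 2L
      tsd_left <- paste(sample(c("A", "G"), tl, replace = TRUE), collapse = "")
      tsd_right <- paste(sample(c("C", "T"), tl, replace = TRUE), collapse = "")
      left <- paste0(substr(left, 1L, flank - 2L),
                     paste(sample(c("A", "G"), 2L, replace = TRUE), collapse = ""))
      right <- paste0(paste(sample(c("C", "T"), 2L, replace = TRUE), collapse = ""),
                      substr(right, 3L, flank))
      element <- paste0(ltr5, internal, ltr3)
      seq <- paste0(left, tsd_left, element, tsd_right, right)
      el_start <- flank + tl + 1L
    } else {
      if (type == "no_pbs") {
        # pyrimidine fill across the whole PBS search window: identity to a
        # purine-containing tRNA tail cannot reach the threshold
        bad <- paste(sample(c("C", "T"), 40L, replace = TRUE), collapse = "")
        internal <- paste0(bad, substr(internal, 41L, nchar(internal) - 22L),
                           ppt)
      }
      if (type == "no_ppt") {
        # every 4th base a pyrimidine: no 20-25 nt window near the 3' LTR
        # can reach 90% purines
        patt <- paste(rep_len(c("A", "G", "A", "C"), 46L), collapse = "")
        internal <- paste0(substr(internal, 1L, nchar(internal) - 46L), patt)
      }
      element <- paste0(ltr5, internal, ltr3)
      if (type == "no_termini")
        element <- paste0("AC", substr(element, 3L, nchar(element)))
      seq <- paste0(left, tsd, element, tsd, right)
      el_start <- flank + tl + 1L
    }
    il <- nchar(internal)
    el_end <- el_start + ltr_len + il + ltr_len - 1L
    scaf <- sprintf("scaffold_%03d", i)
    name <- sprintf("elem_%03d", i)
    recs[[i]] <- list(id = scaf, seq = seq,
                      mask = data.frame(start = integer(0), end = integer(0)))
    cand_rows[[i]] <- data.frame(
      scaffold_id = scaf, start = el_start, end = el_end, name = name,
      ltr5_start = el_start, ltr5_end = el_start + ltr_len - 1L,
      ltr3_start = el_end - ltr_len + 1L, ltr3_end = el_end,
      stringsAsFactors = FALSE)
    truth_rows[[i]] <- data.frame(
      name = name, scaffold_id = scaf, decoy = type, K_planted = Ks[i],
      tsd_seq = if (type == "no_tsd") NA_character_ else tsd,
      trna = if (type == "no_pbs") NA_character_ else trna_id,
      exp_termini = type != "no_termini", exp_tsd = type != "no_tsd",
      exp_pbs = type != "no_pbs", exp_ppt = type != "no_ppt",
      exp_pass = type == "none", stringsAsFactors = FALSE)
  }
  names(recs) <- vapply(recs, `[[`, "", "id")
  cands <- do.call(rbind, cand_rows)
  class(cands) <- c("ltr_candidates", "data.frame")
  list(genome = structure(recs, class = "genome_records"),
       candidates = cands, truth = do.call(rbind, truth_rows))
}

#' Simulate a negative-binomial count matrix with planted DEGs
#'
#' Gene base means are log-normal (meanlog = log(1000), sdlog = 1),
#' reflecting the highly expressed gene population that survives the FPKM
#' filter. Counts are negative binomial with variance
#' `mu + dispersion * mu^2`. Planted DEGs follow a monotone log2 ramp across
#' stages (offset `0, e, 2e, ...` with per-step effect `log2_effect` and
#' random direction), emulating developmental trajectories. Per-sample
#' library-size multipliers are log-normal (sdlog 0.15) unless supplied.
#'
#' @param n_genes Number of genes.
#' @param stages Number of stages (default 4).
#' @param reps Replicates per stage (default 3; at least 2).
#' @param de_fraction Fraction of genes planted as DEGs.
#' @param log2_effect Per-stage-step log2 effect for DEGs (default 2).
#' @param nb_dispersion NB dispersion (default 0.1; 0 gives Poisson).
#' @param lib_sizes Optional per-sample multipliers.
#' @param seed Integer seed.
#' @return List: `counts` (gene x sample), `lengths` (per-gene exon bp),
#'   `metadata` (sample, stage), `truth` (gene, deg, direction, base_mean).
#' @export
simulate_counts <- function(n_genes, stages = 4L, reps = 3L,
                            de_fraction = 0.1, log2_effect = 2,
                            nb_dispersion = 0.1, lib_sizes = NULL,
                            seed = 0L) {
  if (reps < 2L) pm_domain_error("reps must be >= 2 (ANOVA needs replication)")
  if (stages < 2L) pm_domain_error("need at least 2 stages")
  if (de_fraction < 0 || de_fraction > 1)
    pm_domain_error("de_fraction must be in [0,1]")
  set.seed(seed)
  n_samples <- stages * reps
  stage_lab <- rep(LETTERS[seq_len(stages)], each = reps)
  samples <- sprintf("%s_r%d", stage_lab, rep(seq_len(reps), times = stages))
  genes <- sprintf("g%05d", seq_len(n_genes))
  base <- stats::rlnorm(n_genes, meanlog = log(1000), sdlog = 1)
  n_de <- round(de_fraction * n_genes)
  de_idx <- if (n_de > 0) sample.int(n_genes, n_de) else integer(0)
  direction <- integer(n_genes)
  direction[de_idx] <- sample(c(-1L, 1L), n_de, replace = TRUE)
  if (is.null(lib_sizes)) lib_sizes <- stats::rlnorm(n_samples, 0, 0.15)
  ramp <- (seq_len(stages) - 1L)  # per-stage step multiplier
  log2mu <- outer(log2(base), rep(0, n_samples), `+`)
  for (j in seq_len(n_samples)) {
    st <- match(stage_lab[j], LETTERS)
    log2mu[, j] <- log2(base) + direction * log2_effect * ramp[st]
  }
  mu <- sweep(2^log2mu, 2L, lib_sizes, `*`)
  counts <- matrix(0L, n_genes, n_samples, dimnames = list(genes, samples))
  for (j in seq_len(n_samples)) {
    counts[, j] <- if (nb_dispersion > 0)
      stats::rnbinom(n_genes, mu = mu[, j], size = 1 / nb_dispersion)
    else stats::rpois(n_genes, mu[, j])
  }
  lengths <- round(10^stats::runif(n_genes, log10(200), log10(10000)))
  names(lengths) <- genes
  list(counts = counts,
       lengths = lengths,
       metadata = data.frame(sample = samples, stage = stage_lab,
                             stringsAsFactors = FALSE),
       truth = data.frame(gene = genes, deg = direction != 0L,
                          direction = direction, base_mean = base,
                          stringsAsFactors = FALSE))
}

#' Simulate codon-aligned ortholog pairs with a planted synonymous divergence
#'
#' One partner is drawn uniformly over non-stop codons; the other receives
#' substitutions only at four-fold degenerate third positions, with the
#' per-site difference probability calibrated so that the NG86 proportion of
#' synonymous differences over all synonymous sites matches the
#' Jukes-Cantor forward value for `ks_true`. No internal stops can arise
#' (four-fold third-position changes are always synonymous).
#'
#' @param n_pairs Number of pairs.
#' @param ks_true Target synonymous divergence (default 0.064).
#' @param len_codons Codons per CDS (default 350).
#' @param seed Integer seed.
#' @return List: `pairs` (list of `list(cds1, cds2)`), `truth` (pair,
#'   ks_true, n_syn_sites, n_mutated).
#' @export
simulate_codon_pairs <- function(n_pairs, ks_true = 0.064, len_codons = 350L,
                                 seed = 0L) {
  if (ks_true < 0) pm_domain_error("ks_true must be >= 0")
  ps_target <- 0.75 * (1 - exp(-4 * ks_true / 3))
  if (ps_target >= 0.75) pm_domain_error("ks_true beyond Jukes-Cantor saturation")
  tabs <- ng86_tables()
  nonstop <- setdiff(names(tabs$sites), tabs$stops)
  fourfold <- nonstop[tabs$syn_at_pos[nonstop, 3L] == 1]
  set.seed(seed)
  pairs <- vector("list", n_pairs)
  truth <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    co <- sample(nonstop, len_codons, replace = TRUE)
    S1 <- sum(tabs$sites[co])
    ff <- which(co %in% fourfold)
    if (length(ff) == 0L) pm_domain_error("no four-fold sites drawn; increase length")
    q <- ps_target * S1 / length(ff)
    if (q >= 0.75)
      pm_domain_error("ks_true beyond saturation for this codon composition")
    co2 <- co
    mutate <- ff[stats::runif(length(ff)) < q]
    for (j in mutate) {
      third <- substr(co2[j], 3L, 3L)
      nt <- sample(setdiff(c("A", "C", "G", "T"), third), 1L)
      co2[j] <- paste0(substr(co2[j], 1L, 2L), nt)
    }
    pairs[[i]] <- list(cds1 = paste(co, collapse = ""),
                       cds2 = paste(co2, collapse = ""))
    truth[[i]] <- data.frame(pair = i, ks_true = ks_true, n_syn_sites = S1,
                             n_mutated = length(mutate))
  }
  list(pairs = pairs, truth = do.call(rbind, truth))
}

#' Simulate an ortholog hit table with planted rearrangements
#'
#' Each scaffold carries a collinear ladder of gene anchors against one of 7
#' target pseudomolecules. Planted inversions reverse the target order of a
#' central sub-run; translocated scaffolds switch chromosome at their
#' midpoint. Noise rows failing the E-value or coverage filter are added for
#' every scaffold, and `dropout` removes true anchors at random.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param genes_per_scaffold Anchors per scaffold (default 30).
#' @param n_inversions Scaffolds given one internal inversion.
#' @param n_translocations Scaffolds split across two chromosomes.
#' @param dropout Per-anchor removal probability (default 0).
#' @param n_ambiguous Genes given a second passing hit on another chromosome
#'   (they must be excluded by anchoring; default 0).
#' @param seed Integer seed.
#' @return List: `hits` (data.frame ready for [filter_hits()]),
#'   `scaffold_lengths`, `truth` (per-scaffold data.frame: home chromosome,
#'   inversion flag and run, translocation flag and second chromosome),
#'   `ambiguous_genes`.
#' @export
simulate_anchor_table <- function(n_scaffolds, genes_per_scaffold = 30L,
                                  n_inversions = 0L, n_translocations = 0L,
                                  dropout = 0, n_ambiguous = 0L, seed = 0L) {
  g <- genes_per_scaffold
  if (n_inversions + n_translocations > n_scaffolds)
    pm_domain_error("more rearranged scaffolds than scaffolds")
  if (n_inversions > 0L && g < 9L)
    pm_domain_error("inversion needs at least 9 genes per scaffold")
  set.seed(seed)
  chroms <- sprintf("Fvb%d", 1:7)
  scafs <- sprintf("S%03d", seq_len(n_scaffolds))
  kind <- rep("plain", n_scaffolds)
  if (n_inversions > 0L) kind[seq_len(n_inversions)] <- "inversion"
  if (n_translocations > 0L)
    kind[n_inversions + seq_len(n_translocations)] <- "translocation"
  kind <- sample(kind)  # shuffle which scaffolds are rearranged
  rows <- list(); truth <- list()
  for (s in seq_len(n_scaffolds)) {
    home <- sample(chroms, 1L)
    spos <- seq_len(g) * 10000
    tstart <- round(stats::runif(1, 1e5, 2e7))
    tpos <- tstart + seq_len(g) * 12000
    chrom <- rep(home, g)
    inv_lo <- NA_integer_; inv_hi <- NA_integer_
    chrom2 <- NA_character_; split_at <- NA_integer_
    if (kind[s] == "inversion") {
      run <- max(3L, g %/% 4L)
      inv_lo <- 4L
      inv_hi <- inv_lo + run - 1L
      if (inv_hi > g - 3L) inv_hi <- g - 3L
      tpos[inv_lo:inv_hi] <- rev(tpos[inv_lo:inv_hi])
    } else if (kind[s] == "translocation") {
      split_at <- g %/% 2L
      chrom2 <- sample(setdiff(chroms, home), 1L)
      t2 <- round(stats::runif(1, 1e5, 2e7))
      idx <- (split_at + 1L):g
      chrom[idx] <- chrom2
      tpos[idx] <- t2 + seq_along(idx) * 12000
    }
    keep <- stats::runif(g) >= dropout
    genes <- sprintf("%s_g%03d", scafs[s], seq_len(g))
    tab <- data.frame(gene_id = genes[keep], scaffold_id = scafs[s],
                      scaffold_pos = spos[keep], target_chrom = chrom[keep],
                      target_pos = tpos[keep],
                      e_value = 10^-stats::runif(sum(keep), 5, 30),
                      query_coverage = stats::runif(sum(keep), 0.5, 1),
                      stringsAsFactors = FALSE)
    noise_gene <- sample(genes, 2L)
    noise <- data.frame(gene_id = noise_gene, scaffold_id = scafs[s],
                        scaffold_pos = spos[match(noise_gene, genes)],
                        target_chrom = sample(chroms, 2L, replace = TRUE),
                        target_pos = round(stats::runif(2, 1e5, 2e7)),
                        e_value = c(1e-3, 1e-10),
                        query_coverage = c(0.8, 0.3),
                        stringsAsFactors = FALSE)
    rows[[s]] <- rbind(tab, noise)
    truth[[s]] <- data.frame(scaffold_id = scafs[s], home_chrom = home,
                             inversion = kind[s] == "inversion",
                             inv_lo = inv_lo, inv_hi = inv_hi,
                             translocation = kind[s] == "translocation",
                             chrom2 = chrom2, split_at = split_at,
                             stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  ambiguous_genes <- character(0)
  if (n_ambiguous > 0L) {
    pool <- hits$gene_id[hits$e_value <= 1e-4 & hits$query_coverage >= 0.5]
    ambiguous_genes <- sample(unique(pool), n_ambiguous)
    extra <- hits[match(ambiguous_genes, hits$gene_id), , drop = FALSE]
    extra$target_chrom <- vapply(extra$target_chrom, function(ch)
      sample(setdiff(chroms, ch), 1L), "")
    extra$target_pos <- round(stats::runif(n_ambiguous, 1e5, 2e7))
    hits <- rbind(hits, extra)
  }
  lens <- stats::setNames(rep((g + 1L) * 10000, n_scaffolds), scafs)
  rownames(hits) <- rownames(truth) <- NULL
  list(hits = hits, scaffold_lengths = lens, truth = truth,
       ambiguous_genes = ambiguous_genes)
}
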