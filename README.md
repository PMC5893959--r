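# micrantha

Comparative genomics toolkit for a non-berry-forming relative of the
woodland strawberry: the quantitative stages of a *Potentilla micrantha* /
*Fragaria vesca* genome and transcriptome comparison, implemented as
reusable, tested R functions that run end to end on seeded synthetic data —
no downloads required.

The two genera split only ~24 My ago yet differ strongly in genome size,
almost entirely through LTR retrotransposon activity. The package covers the
four analysis stages such a study rests on:

* **Genome & annotation metrics** — flow-cytometry genome-size conversion
  (1 pg = 978 Mbp, so 1C Mbp = pg<sub>2C</sub>/2 × 978), N50 and assembly
  statistics, scaffold size bins, BUSCO completeness and gene-structure
  summaries, repeat-masked fractions, and the strict ">60 supporting reads"
  intron-reliability filter.
* **Full-length LTR retrotransposons** — structural validation
  (TG..CA termini, 4–6 nt target-site duplication, 15–18 nt primer binding
  site complementary to a tRNA 3' end, 20–25 nt polypurine tract),
  Smith–Waterman boundary refinement, Copia/Gypsy/chromovirus classification
  from pol domain order, inter-LTR Kimura two-parameter divergence
  K = −½ ln(1−2P−Q) − ¼ ln(1−2Q), Nei–Gojobori (1986) synonymous rates with
  Jukes–Cantor correction, molecular-clock calibration
  (r<sub>g</sub> = K<sub>s</sub>/T, r<sub>LTR</sub> = 2 r<sub>g</sub>), and
  insertion ages K / r<sub>LTR</sub>.
* **Differential expression across developmental stages** —
  FPKM = 10⁹·ER/(EL×MR), an FPKM ≥ 1000 high-expression filter, mode-aligned
  rescaling of log2 counts, a generalised-log variance stabilisation, and
  gene-wise one-way ANOVA calling DEGs at √MSR > 2.00 and p < 10⁻³ (MSR =
  between-stage mean square), plus volcano tables and ortholog
  expression-divergence classification.
* **Microsynteny** — ortholog-hit filtering (E ≤ 10⁻⁴, coverage ≥ 50%),
  unambiguous anchoring, greedy monotone block chaining, inversion calls by
  Kendall rank correlation, translocation-like multi-chromosome scaffolds,
  and anchoring summaries at the ≥1/≥10/≥50/≥100 ladder.

A fifth module provides seeded simulators with ground-truth tables (genomes
with planted elements, negative-binomial counts with planted DEGs,
codon-aligned ortholog pairs with planted K<sub>s</sub>, anchor tables with
planted rearrangements) so every pipeline stage is scored against known
truth. See the methods vignette (`vignettes/methods.Rmd`) for the full model
descriptions, parameter defaults, and design rationale.

## Worked example

```r
library(micrantha)

pg_to_mbp(0.83)$mbp_printed          # 1C genome size from 0.83 pg/2C
#> [1] 405.87

cal <- calibrate_rate(0.064, 24.22e6)  # Ks and divergence time -> rates
#> gene rate 2.64e-09 /site/yr, LTR rate 5.28e-09 /site/yr

# simulate a genome with three planted elements and date them
sim <- simulate_genome_with_ltrs(3, K = c(0.01, 0.05, 0.10), seed = 42)
for (i in 1:3) {
  cd <- sim$candidates[i, ]
  s  <- sim$genome[[cd$scaffold_id]]$seq
  d  <- ltr_divergence(substr(s, cd$ltr5_start, cd$ltr5_end),
                       substr(s, cd$ltr3_start, cd$ltr3_end))
  ev <- validate_element(sim$genome, cd)
  cat(sprintf("%s planted K=%.2f  estimated K=%.4f  age=%.2f My  pass=%s\n",
              cd$name, sim$truth$K_planted[i], d$K,
              insertion_age(d$K, cal$ltr_rate) / 1e6, ev$overall_pass))
}
#> elem_001 planted K=0.01  estimated K=0.0135  age=2.56 My  pass=TRUE
#> elem_002 planted K=0.05  estimated K=0.0555  age=10.51 My  pass=TRUE
#> elem_003 planted K=0.10  estimated K=0.1112  age=21.04 My  pass=TRUE

# differential expression on simulated counts (200 planted DEGs)
simc <- simulate_counts(2000, de_fraction = 0.1, log2_effect = 2,
                        nb_dispersion = 0.1, seed = 1)
de <- run_de(simc$counts, stages = simc$metadata$stage, fpkm_threshold = 0)
de$n_deg
#> [1] 199
```

The estimated inter-LTR distances track the planted divergences, the ages
follow from the calibrated rate (an element with K = 0.10 inserted ~21 My
ago under this clock), every intact element passes all four structural
criteria, and the ANOVA procedure recovers 199 of the 200 planted
differential genes with no false positives at these settings.

A command-line entry point wrapping the same functions ships in
`inst/scripts/micrantha-cli` (subcommands `genome-size`, `assembly-stats`,
`ltr-validate`, `ltr-date`, `de-run`, `synteny`, `simulate`); identical
inputs and seed give byte-identical outputs.

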