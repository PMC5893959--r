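---
title: "Methods: assembly metrics, LTR dating, expression dynamics, and microsynteny"
author: "micrantha authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assembly metrics, LTR dating, expression dynamics, and microsynteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micrantha)
```

# Scope and scientific setting

*Potentilla micrantha* is a close, non-berry-forming relative of the woodland
strawberry *Fragaria vesca*; the two genera diverged roughly 24 million years
ago, yet differ markedly in genome size, almost entirely through
retrotransposon activity. This package implements the quantitative procedures
such a comparison rests on, as reusable, tested functions over four stages:

1. **Genome and annotation metrics** — flow-cytometry genome-size
   conversion, assembly statistics (N50, gap content, size bins), BUSCO and
   gene-structure summary arithmetic, repeat-masking fractions, and the
   strict read-support filter for reliable intron junctions.
2. **Full-length LTR retrotransposons** — structural validation of
   candidate elements, superfamily classification from protein-domain order,
   inter-LTR divergence, and insertion-age dating calibrated from
   orthologous synonymous substitution rates.
3. **Differential expression across flower/fruit developmental stages** —
   FPKM, a high-expression filter, mode-aligned rescaling, variance
   stabilisation, and gene-wise one-way ANOVA with joint effect/p-value
   cut-offs.
4. **Microsynteny** — ortholog-hit filtering, unambiguous anchoring,
   collinear block chaining, and inversion/translocation reporting.

Every stage is exercised end to end on seeded synthetic data with ground
truth, so the whole analysis is testable without any external downloads.

# Conventions

Genomic intervals are 1-based and closed inside the package — the
Bioconductor (IRanges) convention — and are converted only at I/O
boundaries: GFF3-like tables are 1-based closed on disk and pass through
unchanged, BED-like element tables are 0-based half-open on disk. Functions
that mirror printed summary values return the full-precision number together
with a `_printed` companion rounded the way such reports are conventionally
printed (Mbp to 2 decimals, percentages to 1–2 decimals).

# Genome-size and summary arithmetic

Flow cytometry yields a 2C DNA amount in picograms; with the standard
conversion of 978 Mbp per pg, the haploid genome size is
`(pg_2c / 2) * 978`. N50 is the scaffold length at which the cumulative
length of scaffolds sorted descending first reaches half the assembly; when
the cumulative sum hits exactly half, that scaffold defines N50. "Gapped
Ns" count only `N` characters; other IUPAC ambiguity codes are tallied
separately. The intron-support filter keeps junctions with *strictly more
than* 60 supporting reads; the threshold is configurable in `run_config()`.

```{r}
pg_to_mbp(0.83)$mbp_printed
busco_summary(1337, 33, 2, 68, 1440)$complete_printed
```

# LTR retrotransposon validation

A candidate full-length element (discovered upstream by any LTR finder and
supplied as a BED-like table) is validated against four structural criteria:

* **(a) termini** — the element begins with `TG` and ends with `CA`;
* **(b) TSD** — an exact direct repeat of 4–6 nt flanks the element, with
  up to 2 bp of edge jitter; the longest match wins, ties resolved toward
  smaller offset;
* **(c) PBS** — a 15–18 nt window starting within 20 bp of the 5' LTR end
  whose reverse complement matches the 3' end of a tRNA at identity ≥ 0.8
  (inclusive);
* **(d) PPT** — a 20–25 nt window ending within 20 bp of the 3' LTR with
  purine fraction ≥ 0.9; ties go to higher fraction, then longer windows,
  then proximity to the LTR.

By default an element passes only when all four criteria hold; an
"any 3 of 4" rule is selectable. Candidate boundaries can first be refined
by a Smith–Waterman local alignment of the two LTR neighbourhoods
(match +2, mismatch −2, gap open 5, gap extend 1 — common defaults, all
configurable); each boundary moves to the corresponding end of the
maximal-scoring local alignment. The bundled tRNA 3'-end library is
synthetic (constructed stand-ins ending in the universal CCA); real
annotation work should supply a curated library.

Superfamily classification uses the pol domain order: integrase before
reverse transcriptase is Ty1-Copia, the reverse is Ty3-Gypsy, and a Gypsy
element with a chromodomain is a chromovirus. Elements missing either
ordering domain, or with conflicting duplicates, stay unclassified.

# Divergence, calibration, and dating

The two LTRs of an element are aligned globally with affine gaps; every
column containing a gap or ambiguity symbol is eliminated (the "indels
removed" treatment), and the remaining sites are split into transition and
transversion proportions $P$ and $Q$, giving the Kimura two-parameter
distance

$$K = -\tfrac12\ln(1 - 2P - Q) - \tfrac14\ln(1 - 2Q).$$

Saturation ($1-2P-Q \le 0$ or $1-2Q \le 0$) raises a typed error rather
than returning NaN.

Synonymous divergence between orthologous coding sequences uses the
Nei–Gojobori (1986) counts — synonymous sites from per-position degeneracy
(mutations to stop codons disregarded), synonymous differences with pathway
averaging over substitution orders — followed by the Jukes–Cantor
correction $K_s = -\tfrac34\ln(1 - \tfrac43 p_s)$. The original analysis
names no specific $K_s$ estimator; NG86 + JC is the transparent classical
choice and the interface accepts any per-pair estimator.

**Rate conventions.** The calibration exposes two self-consistent
conventions. The default mirrors the worked arithmetic this package
reproduces: $r_g = K_s / T_{div}$ and age $= K / r_{LTR}$ with
$r_{LTR} = 2 r_g$. The textbook per-lineage convention
($r_g = K_s / 2T_{div}$, age $= K / 2r_{LTR}$) is also available; the two
factor-of-two choices cancel, so element ages are identical — only the
intermediate printed rates differ (the default yields the familiar
$2.64\times10^{-9}$ and $5.28\times10^{-9}$ per year for
$K_s = 0.064$ and $T_{div} = 24.22$ My).

```{r}
cal <- calibrate_rate(0.064, 24.22e6)
c(cal$gene_rate, cal$ltr_rate)
insertion_age(0.124, cal$ltr_rate) / 1e6   # My
```

Note that dividing the maximal observed distance 0.124 by the calibrated
rate gives 23.46–23.48 My, slightly below the commonly quoted 23.54 My for
these inputs; the discrepancy is at rounding level (unrounded intermediate
inputs) and the package reports the recomputed value.

# The differential-expression procedure

Counts are converted to FPKM as $10^9 \cdot ER / (EL \times MR)$ with $ER$
the exon reads of a gene, $EL$ its summed exon length and $MR$ the sample's
mapped-read total. Genes whose FPKM stays below 1000 in *every* sample are
removed (a gene reaching 1000 exactly in one sample is retained — the
removal rule is strictly "below threshold everywhere"). Whether such a high
bar should gate differential testing is debatable; the threshold is a
configurable parameter with this value as default.

The retained counts are processed as:

1. **log2 with a +1 pseudocount** (the handling of zeros is otherwise
   unspecified);
2. **mode alignment** — each sample's distribution mode is estimated by a
   Gaussian kernel density (Silverman's bandwidth) and the sample is
   shifted additively in log2 space so all modes coincide with the median
   of the modes. One mode constraint determines exactly one parameter per
   sample, which is what "linear rescaling aligning the modes" admits; the
   operation is idempotent.
3. **variance stabilisation** — a quadratic mean–variance trend
   $v(\mu) = a + b\mu^2$ is fitted by alternating medians over the low- and
   high-mean quartiles (per-gene variance estimates have noise proportional
   to the variance itself, so unweighted least squares would be dominated
   by high-mean genes), and the closed-form generalised-log transform
   $h(x) = \operatorname{asinh}(x\sqrt{b/a})/\sqrt{b}$ is applied; as
   $b \to 0$ this degenerates to the affine map $x/\sqrt{a}$. `"none"` is
   selectable, and the ANOVA can alternatively be run on the merely
   mode-aligned values (the ordering of rescaling and stabilisation in the
   original description is ambiguous; the default uses the fully
   transformed values).
4. **gene-wise one-way ANOVA** over stages. "MSR" (mean squared anomaly)
   is interpreted as the between-stage (treatment) mean square
   $SSB/(k-1)$ — the quantity that supports a volcano effect axis; its
   square root is the effect statistic. A gene is called differentially
   expressed when $\sqrt{MSR} > 2.00$ *and* $p < 10^{-3}$, both strict. No
   multiple-testing correction enters the call (the original cut-off is on
   raw p-values); a Benjamini–Hochberg column is emitted for information.

Ortholog expression-divergence classification labels a species profile
*silent* when FPKM < 1 in all stages and *high* when FPKM ≥ 100 in at least
one; a pair is divergent when one side is silent and the other high,
conserved when all stage-wise log2 ratios sit within ±1, and `other`
otherwise. All three thresholds are arguments.

# Microsynteny

Ortholog hits are filtered at E-value ≤ 10⁻⁴ and query coverage ≥ 50%
(both inclusive, per "maximum" and "at least"). A gene anchors a scaffold
position to a target pseudomolecule only when exactly one hit location
survives filtering — hits within 1 kb on the same chromosome count as one
location, anchored at the best E-value; "unambiguous" means a single merged
location, not merely a best hit. Anchor positions are gene midpoints.

Blocks are built by greedy monotone chaining per scaffold: walking anchors
in scaffold order, a block grows while anchors share its target chromosome
and keep a monotone target trend (direction fixed at the second member),
tolerating up to `max_skip = 2` consecutive non-matching anchors; runs
shorter than `min_anchors = 3` are reported as singletons. The underlying
published block criteria are not restated in the source literature, so
these two defaults are explicit, configurable, and written into output
headers. One deterministic consequence worth knowing: at an inversion
junction the peak (or trough) anchor continues the upstream trend and is
therefore assigned to the preceding block, so a planted inverted run of
$n$ anchors is reported as an inverted block of $n-1$ with the junction
anchor absorbed upstream. Orientation is the sign of the Kendall rank
correlation between scaffold order and target positions. Scaffolds whose
blocks span more than one chromosome are reported as translocation-like,
with per-block gene counts. Macro-synteny (map-based scaffold ordering) is
deliberately out of scope.

# Synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameters and a seed, and each
returns a truth table sufficient to score the downstream operation without
re-derivation.

* `mutate_k2p()` applies the exact K2P site-substitution probabilities at
  distance $K$ with transition/transversion rate ratio $\kappa = 2$, so
  estimator-bias checks are clean rather than approximated.
* `simulate_genome_with_ltrs()` plants complete elements (TG..CA termini,
  exact TSD, PBS complementary to a bundled tRNA tail, PPT, LTR pair
  diverged by a planted $K$) in i.i.d. uniform-composition background
  sequence. Three deliberate artificialities keep the truth table exact:
  the two terminal bases of each LTR are exempt from mutation (so termini
  survive divergence), TSDs are drawn from pyrimidines while the PPT and
  the post-LTR spacer are purines (so local alignment cannot creep across
  a planted boundary and boundary-recovery is well-posed), and decoys
  violate exactly one criterion through disjoint-alphabet constructions
  that cannot re-satisfy it by chance. Real repeat landscapes — nested
  insertions, truncated elements, GC structure — are not emulated, so
  passing validation tests demonstrates correctness of the decision rules,
  not robustness to degraded elements.
* `simulate_counts()` draws negative-binomial counts
  (variance $\mu + \phi\mu^2$) around log-normal base means
  (meanlog $= \log 1000$, sdlog 1 — a highly expressed population,
  matching the genes that survive the FPKM filter), log-normal library-size
  factors (sdlog 0.15), and plants differential genes as monotone log2
  ramps across stages (offset $0, e, 2e, \dots$ with random direction),
  emulating developmental trajectories over four flower/fruit stages. Real
  count data additionally shows outliers, batch structure, and correlated
  genes.
* `simulate_codon_pairs()` places substitutions only at four-fold
  degenerate third positions, with the per-site difference probability
  calibrated against the pair's own synonymous-site total so that the
  expected NG86 $p_s$ equals the Jukes–Cantor forward value for the target
  $K_s$; no internal stops can arise.
* `simulate_anchor_table()` lays collinear anchor ladders over a virtual
  7-pseudomolecule target, reverses a central sub-run for inversions,
  switches chromosome at the midpoint for translocations, adds rows that
  fail the E-value/coverage filter, and removes anchors at random for
  dropout studies.

# Numerical choices and degenerate inputs

Typed error conditions separate format errors (malformed inputs), domain
errors (contract violations such as empty inputs or non-positive rates),
saturation errors (K2P/JC logs of non-positive arguments), and usage errors
(CLI). An all-equal expression gene gets $MSR = 0$, $F = 0$, $p = 1$; a
within-stage variance of zero with a non-zero effect yields $p = 0$.
Degenerate (constant) samples in mode alignment use their single value as
the mode, with a warning. Tie-breaks are fixed and documented: TSD (length,
then offset), PPT (fraction, length, proximity), Kendall ties broken by
target position then gene id.

# Problem sizes and reproducibility

The bundled tests and the acceptance script size their simulations for
tight, stable statistics at interactive runtimes: 200 elements with 2 kb
LTRs for divergence-recovery regression, 20 × 50 pairs × 350 codons for
$K_s$ recovery, 10⁴ genes for the null false-positive rate and 2 × 10³ for
sensitivity, and 24 scaffolds × 30 anchors with 20% dropout for
rearrangement recovery. `scripts/acceptance.R --seed N --out file` re-runs
everything from scratch and writes the resulting quantities as JSON; all
randomness flows from the single seed.

# Known limitations

Candidate element discovery, read mapping, orthology clustering, repeat
clustering, and phylogenetics are out of scope by design — their outputs
are consumed as tables. Heterozygosity estimation is not recomputable from
the shipped inputs. The DE procedure tests a global stage effect per gene
(one-way ANOVA), not specific stage contrasts; the published pairwise-
contrast counts are therefore not a target of this implementation.
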