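---
title: "Statistical methods for multi-strain ALE multi-omics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for multi-strain ALE multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aleomics)
```

# The experimental design this package models

Adaptive laboratory evolution (ALE) propagates bacterial cultures under
sustained selection for growth rate. The design this package analyses is a
multi-strain campaign: several *E. coli* strains of different genetic
backgrounds, each evolved in replicate lineages, with clones isolated at a
handful of *flasks* — the unit of evolutionary time, flask 0 being the
preculture — and assayed by RNA-seq (biological duplicates), $^{13}$C
fluxomics, physiology, and whole-genome sequencing. Two views of the data
recur throughout:

* the **flask view**: one profile per (strain, flask), and
* the **jump view**: differences between consecutive assayed flasks of a
  strain. With 22 assayed flasks over 6 strains there are $22 - 6 = 16$
  jumps. A jump carries a growth-rate gain, omics changes, and the set of
  mutations gained at its destination flask.

The pipeline (`run_pipeline()`) chains five screens over these views:
phenotype convergence/divergence, iModulon activity projection with
differential-activity testing, growth-correlation screens, trade-off
detection, and mutation-correlate screening.

# Convergence and divergence of phenotypes

For each phenotype (a flux or physiological quantity), the per-strain means
at the wild-type (WT) and endpoint (EP) stages are reduced to vectors of
all pairwise absolute differences — with 6 strains, 15 distances per stage.
A one-sided Mann-Whitney U test then asks whether EP distances are smaller
(convergence: strains moved closer together) or larger (divergence) than WT
distances. We count $U = \#\{d^{EP} < d^{WT}\}$ (ties one half) and use the
Gaussian approximation

$$ p = \Phi\!\left(\frac{U + \tfrac12 - n_1 n_2/2}{\sigma}\right),
\qquad \sigma^2 = \frac{n_1 n_2}{12}\Big((n+1) - \frac{\sum_t (t^3-t)}{n(n-1)}\Big), $$

with the half-unit continuity correction on by default; tabulated exact
p-values do not exist for the small U values this design produces. With
$U = 19$ at $n_1 = n_2 = 15$ the lower tail gives $p = 5.7\times10^{-5}$:

```{r mwu}
signif(mwu_normal_p(19, 15, 15, "less", continuity = TRUE), 2)
```

Benjamini-Hochberg control at FDR 5% is applied within each direction
across the panel, and each phenotype is labelled by whichever direction
passes.

**A calibration caveat that users should know.** The 15 distances per stage
are functions of only 6 strain means and are therefore positively
dependent, while the U test assumes independent samples. Under a neutral
null (both stages equally dispersed) the raw test is anticonservative: we
measure roughly 15% rejection at a nominal $\alpha = 0.05$, and the null
p-values are visibly non-uniform. This is intrinsic to the pairwise-distance
transform, not to the implementation; labels at FDR 5% should be read as a
ranking device, strongly enriched for true convergence/divergence (planted
labels are recovered at well over 90% in the validation suite) rather than
as a strictly calibrated error rate. The dedicated calibration test in the
acceptance suite documents the measured behaviour.

# iModulon activities and differential activation

Transcriptome composition is described by a fixed basis of *iModulons* —
independently modulated gene sets obtained by ICA of a reference
compendium — through the factorization $X = M A$, with $M$ the genes
$\times$ iModulons weight matrix and $A$ the iModulons $\times$ samples
activities. New samples are projected by least squares,
$A = (M^\top M)^{-1} M^\top X$, on the intersection of gene identifiers
(`project_activities()` refuses to run below a 50% gene match or when the
restricted basis loses rank). Explained variance is reported as
$1 - \|X_c - (MA)_c\|_F^2 / \|X_c\|_F^2$ with per-gene centering of both
terms: centering makes the fraction measure shape agreement and renders it
invariant to constant per-gene offsets, which lie partly outside the basis
column space and otherwise dominate the residual; the uncentered variant
remains available.

Differential iModulon activity (DIMA) between two conditions uses an
empirical replicate null: absolute activity differences between biological
replicates of the same flask, pooled across iModulons, fitted by a
log-normal (absolute rather than signed differences, since a log-normal is
undefined for negatives). A change $\Delta$ is significant when its
BH-adjusted upper-tail probability under this null passes $\alpha = 0.05$
**and** $|\Delta| > 5$ activity units — the absolute minimum-change rule is
the primary gate, and an optional fold-change gate is off by default. The
screen runs per jump and per strain WT-vs-EP, with counts aggregated by
functional category.

Two related screens reuse the activity matrix: WT-discriminating iModulons
(one-way ANOVA F across strains on WT samples, BH at a deliberately strict
FDR 0.005) and growth-correlated iModulons (per-strain Pearson correlation
of flask-level activity with growth rate; selected when the median |R|
across strains exceeds 0.75 with median p below 0.05; the sign is the sign
of the median R).

# Trade-off detection

To avoid testing all iModulon pairs, PCA of the jump-specific activity
changes (columns mean-centered, no variance scaling) shortlists candidates:
iModulons with |loading| > 0.10 on any component explaining at least 5% of
the variance. Known single-jump outliers (the motility-burst pattern a
single strain's first jump can produce) can be excluded cell-wise before
the PCA. Candidate pairs are then tested on flask-level activities with an
ANCOVA sharing one slope across strains with strain-specific intercepts,
$y \sim x + \text{strain}$; a trade-off requires a negative Pearson
correlation, a BH-passing slope, and ANCOVA $R^2 > 0.95$. The 0.95
threshold follows the reported result (a 0.90 variant appears in the
method's description; `r2_min` is configurable and the choice is recorded
in the output). The slope-by-strain interaction F-test is reported
alongside as a homogeneity diagnostic, and pairs are canonically ordered so
results are independent of input order.

# Mutation correlates

Mutation events are reduced to a binary jumps $\times$ loci matrix: a locus
is *gained* in the jump ending at the first assayed flask at or after its
first observation in that strain; loci first observed at or before a
strain's first assayed flask are wild-type alleles and never gained; loci
appearing in fewer than two jumps are untestable and dropped. Each feature
is tested against each jump-specific flux change and activity change by
point-biserial correlation with a two-sided t p-value — the
smallest-assumption test for binary-versus-continuous data at 16 jumps — or
by a seeded permutation test (enumerated exactly when the number of
placements is small). BH runs separately within flux targets and within
iModulon targets, mirroring their separate reporting. Because mutations
co-occur in jumps, significant associations include genuine hitchhiking
correlations; the screen reports association, not causation.

# The synthetic-data generator as a validation instrument

`simulate_ale_dataset()` builds a full campaign with *planted, recorded
truths* so every screen can be validated end to end. The default
conditions mirror the assay structure above: 6 strains with 4/4/4/4/3/3
assayed flasks (22 flasks, 16 jumps), 2 biological replicates, growth rates
rising monotonically from strain-specific WT values (0.55-0.85 1/h) to
plateaus in 0.98-1.11 1/h. Its layers:

* **Activities.** 25 iModulons; baselines shared across strains so WT
  states differ only through planted signals. Six growth-correlated
  iModulons (three positive, three negative) follow the within-strain
  growth gain at 18 activity units per 1/h; three trade-off pairs obey
  $B = -cA$ ($c = 1, 0.8, 1.2$) around per-strain random walks (step s.d.
  14); five strain-specific WT offsets of $\pm 20$; flask noise s.d. 0.5.
  Replicate pairs differ by $\pm d/2$ with $|d| \sim$ LogNormal(0, 0.5) —
  exactly the form the DIMA null assumes, which makes its type-I error
  checkable (measured $\approx 0.05$ at $\alpha = 0.05$).
* **Scale.** The activity scale is anchored to the DIMA rule: a
  "biologically meaningful" planted shift is 10 units against the absolute
  threshold of 5, giving essentially full power under the replicate null.
* **Expression.** $X = MA$ plus Gaussian noise (s.d. 0.3), plus a per-gene
  baseline (N(7, 6)) emulating the large between-gene differences in mean
  log-TPM that dominate replicate concordance in real compendia, then a
  recorded global shift to non-negativity. Basis weights are sparse
  Gaussians with s.d. 0.5, matching the small per-gene weights of
  ICA-derived bases.
* **Phenotypes.** A 62-phenotype panel: 10 convergent (8 of them
  convergent *through* growth coupling — their stage means are affine in
  the stage growth rate, so WT means disperse with WT growth rates while
  EP means cluster with the narrow fitness plateau), 2 divergent, 50
  neutral.
* **Mutations and fluxes.** 12 causal loci — 4 shifting a reaction flux,
  8 shifting an iModulon activity, each by $\pm 10$ from the gaining flask
  onward, each planted in two strains — on iModulons carrying no other
  planted signal, plus Poisson background events.

The signal geometry was chosen once so that each planted signal clears its
own screen's threshold while cross-structure couplings stay below others'
thresholds: for example, the growth-correlation slope puts the
within-strain signal near three noise standard deviations, high enough for
per-strain $|R| \gg 0.75$ yet keeping the activity-versus-activity coupling
between opposite-sign growth-correlated iModulons far below the trade-off
$R^2 = 0.95$ gate — so the only near-perfect negative couplings are the
planted pairs, exactly as the screens assume.

What the generator deliberately does **not** emulate: realistic regulatory
network topology, count-level sequencing noise, population allele-frequency
dynamics, or isotopomer measurement structure. Passing the recovery suite
therefore shows that the statistical machinery recovers the signal classes
it targets at realistic sizes and noise levels — not that real data meet
the generator's assumptions.

# Numerical choices and degenerate inputs

* Replicate QC removes a failing pair entirely in groups of two; in larger
  groups it iteratively drops the replicate with the lowest mean pairwise
  $R^2$ until all pairs pass, preserving data while honouring the 0.9
  cutoff. Constant expression vectors are an error (correlation
  undefined).
* Monotone trajectory smoothing is isotonic regression (pool adjacent
  violators) at the nodes followed by a shape-preserving monotone cubic
  interpolant (PCHIP), which cannot overshoot between nodes; only the
  monotonicity constraint is prescribed by the method, the algorithm is a
  package choice.
* Fragments-per-million in the gene filter uses the mapped fragments
  present in the table as denominator, making the filter self-contained;
  the length and FPM rules are both required, per sample.
* Flux records recompute $v_{net} = v_f - v_b$, $v_{exch} = \min(v_f,
  v_b)$ and the quarter-CI-width precision on read, warning and replacing
  values that violate the identities beyond $10^{-6}$.
* All tables are comma-separated UTF-8 with full-precision numeric
  serialization, so write-read round-trips are bit-exact and regeneration
  under a fixed seed is byte-identical.
* Every stochastic stage draws a sub-seed derived from the master seed, so
  adding or reordering stages never perturbs other stages' draws.

Validation problem sizes were chosen to exercise each property at the scale
of the design itself (16 jumps, 22 flasks, duplicate replicates): recovery
suites use 20 generator seeds, DIMA calibration 100 seeds, and the
projection and distance identities are exact. The exact-enumeration oracle
for the U statistic is feasible only for small samples ($n_1 = n_2 \le 8$)
and is used as a testing oracle, not an analysis path.

# Known limitations

* The convergence test's raw null is anticonservative (see above); its FDR
  is controlled against the test's own null, not the data-generating null.
* The normal approximation to the U distribution is accurate to 0.02
  absolute for $n_1 = n_2 \ge 3$; at $n_1 = n_2 = 2$ (which the distance
  transform cannot produce) no approximation meets that bound.
* The mutation-correlate screen inherits the confounding of co-selected
  mutations: loci gained in the same jump share correlates.
* ANCOVA $R^2$ is reported from the common-slope model; when the
  interaction F-test rejects homogeneity, the single-slope summary should
  be interpreted with care.
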