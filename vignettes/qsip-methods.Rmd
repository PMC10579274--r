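---
title: "Models and methods behind thermoqsip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thermoqsip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoqsip)
```

## The problem

Quantitative stable isotope probing (qSIP) asks which members of a microbial
community assimilate a particular substrate. A sediment or soil sample is
incubated with a $^{13}$C-labeled compound, DNA is separated on an
isopycnic density gradient and fractionated, and every fraction is profiled by
16S rRNA gene amplicon sequencing plus broad-coverage qPCR. Taxa that built the
heavy isotope into new DNA sit slightly deeper in the gradient; the size of
that shift, corrected for GC content, is converted into the **atom fraction
excess** (AFE) of $^{13}$C in the taxon's DNA. thermoqsip implements this
estimator together with the statistics that typically surround it in a
community study: absolute-abundance conversion, alpha/beta diversity and group
tests, a resource-partitioning contingency test, phylogenetic-signal
statistics for substrate assimilation, a Spearman co-occurrence network, and a
genome-informed classification of primary utilizers versus cross-feeders.

Because fraction-level field data are rarely released, the package is built
around a forward simulator (`simulate_experiment()`) that generates a complete
experiment with known per-taxon truth. Every estimator in the package is
validated by parameter recovery against that truth.

## The density model and the AFE estimator

The physical core is a pair of linear calibrations (in
`gradient_calibration()`):

* unlabeled buoyant density: $W_{light} = 0.083506\,GC + 1.646057$ g/mL,
* mean nucleotide molecular weight: $M_{light} = 0.496\,GC + 307.691$ g/mol,
* maximal molecular-weight gain under complete $^{13}$C substitution:
  $\Delta M_{max} = 9.974564 - 0.4987282\,GC$ g/mol,

plus the natural $^{13}$C abundance $a = 0.01111233$. A taxon with GC
content $g$ and atom fraction excess $A$ equilibrates at

$$W_{lab} = W_{light}(g)\,\frac{M_{light}(g) + \frac{A}{1-a}\Delta M_{max}(g)}{M_{light}(g)}.$$

`taxon_mean_density()` evaluates this forward model and `compute_afe()` is its
exact algebraic inverse: GC is estimated from the unlabeled density
(`estimate_gc()`), the labeled/unlabeled density ratio gives the labeled
molecular weight, and the excess mass is scaled by $\Delta M_{max}$ and
$1-a$. The round trip is exact to floating-point precision, which the test
suite asserts at 1e-10 over a grid of GC and AFE values. The calibration
constants are overridable only as a unit, so a run can never mix constants
from two calibrations.

Per tube, a taxon's density is summarized by its weighted average density
(WAD): fraction densities weighted by the taxon's copy numbers (relative
abundance times the fraction's qPCR total). The treatment comparison is
labeled tubes (`13C-acetate` or `13C-aspartate`) against the pooled unlabeled
tubes. Natural-abundance acetate tubes and the no-substrate control are
combined into one unlabeled pool to maximize the number of taxa with a
usable light density — the main reason unlabeled replicates exist in this
design. The unincubated (initial) samples are excluded from the pool by
default because time-zero chemistry differs from incubated controls; the
`include_initial` flag reverses this.

Decisions where the field convention is not fixed:

* a taxon contributes a WAD for a tube only if it has nonzero copies there;
  tubes without the taxon are dropped from that treatment's mean,
* an AFE is reported only when at least 2 labeled and 2 unlabeled tubes are
  informative (`min_tubes`); anything less is `"unscored"` rather than a
  one-tube artifact,
* negative AFE values are reported as computed, not truncated at zero, so the
  null distribution stays symmetric and coverage can be audited,
* **emergent taxa** — zero copies in every unlabeled and initial tube but
  present after labeling — are flagged (`detect_emergent_taxa()`) and carry
  no AFE, since no light density exists for them.

## Bootstrap uncertainty and its small-sample behavior

Uncertainty comes from resampling tubes with replacement, independently
within the labeled and unlabeled groups, recomputing the AFE per iterate
(1000 by default), and reporting the median and the 90% percentile interval.
This mirrors the convention of reference qSIP pipelines and is deterministic
given a seed.

An honest caveat, quantified by the package's own null simulations: with the
replicate counts of the emulated design (3–4 labeled tubes against 4+1
unlabeled), a tube-level percentile bootstrap is anti-conservative. Under a
true AFE of zero the nominal 90% interval excludes zero for roughly 15–25% of
taxa rather than 10%; the same code reaches the nominal rate when tube counts
grow (about 10.5% at 10 vs 10 tubes). Two effects combine: the classical
downward bias of bootstrap variance at n of 3–5, and qPCR noise that is shared
by all taxa of a fraction, which correlates exclusion events within an
experiment. Consumers who need calibrated per-taxon decisions at these
replicate counts should treat "CI excludes zero" as a liberal screen, or use
the `positive = "ci"` option only with that caveat in mind.

## The simulator

`simulate_experiment()` emulates the experimental design it is meant to test:
treatments `13C-acetate` (n = 3), `13C-aspartate` (n = 4), `nat-acetate`
(n = 4), `control` (n = 1), `initial` (n = 4); 13–15 fractions per tube (drawn
per tube, so downstream code must handle ragged tables); a density grid of
1.60–1.78 g/mL. Per tube, each taxon's DNA mass is spread over equal-width
density bins by Normal CDF differences around its treatment-dependent mean
density (sd 0.008 g/mL), truncated to the grid and renormalized, which keeps
the per-tube mass balance exact. Observation noise is multinomial read
sampling per fraction (50,000 reads by default) and multiplicative lognormal
qPCR noise (CV 0.1, mean 1). GC contents are uniform on 0.35–0.65, tube-level
abundances lognormal(meanlog 14, sdlog 2) — a heavy-tailed community in which
roughly the top half of taxa exceed the 0.1% relative-abundance level at
which recovery is assessed. A configurable number of taxa are *emergent*:
absent from all unlabeled and initial tubes, present and labeled after
amendment. Where the emulated design fixes a value (replicates, fraction
counts) the default is that value; where it does not (noise levels, abundance
distribution), defaults were chosen once as ecologically plausible and are
not tuned.

What the simulator does **not** model: PCR and primer bias, chimeras,
contaminant removal, gradient-media chemistry, per-fraction DNA recovery
efficiency (treated as complete and uniform), compositional coupling beyond
the multinomial, or multi-isotope labeling. Passing recovery tests therefore
demonstrates correctness of the estimator under the stated noise model, not
robustness to every artifact of real amplicon data.

With reads per fraction at 50,000 and qPCR CV 0.1, the median absolute AFE
error for taxa above 0.1% relative abundance is about 0.004–0.006 (tolerance
0.02), and emergent-taxon recall is 1.0.

## Diversity, partitioning and group tests

* `chao1()` uses the bias-corrected form $S_{obs} + F_1(F_1-1)/(2(F_2+1))$;
  `shannon()` is in nats; `pielou()` normalizes by observed richness and is 1
  for a single-taxon community.
* `bray_curtis()`, `pcoa()` and `anosim_test()` wrap the standard vegan/stats
  machinery; PCoA reports negative eigenvalues unchanged and computes variance
  explained over positive eigenvalues only.
* `partition_test()` builds the 2×2 table (both / A-only / B-only / neither)
  from Venn counts of labeled taxa. The default is Pearson's test of
  independence without continuity correction; a goodness-of-fit variant
  against the independence expectation (df 3) is exposed because both names
  are used for this analysis in the literature. On the counts 492/58/34/26
  the statistic is ≈147, p ≈ 8e-34.
* `log2_change()` applies the +1 offset to all values, not only zeros, so the
  map is continuous at zero.

## Phylogenetic signal

`morans_i()` implements Moran's I with row-standardized weights and a trait
permutation test (999 permutations, one-sided "greater" by default, p =
(1 + #{perm ≥ obs})/(1 + n\_perm)). For trees the default weights are inverse
patristic distances (`moran_weights()`); zero distances between distinct tips
are an error rather than silently patched. The permutation null mean is the
analytic $-1/(n-1)$, which the tests verify by exact enumeration at n = 5.

`abouheif_cmean()` is Moran's I on the Abouheif proximity matrix: the
reciprocal of the product of direct-descendant counts over the internal nodes
on the path between two tips, the most recent common ancestor counted once.
On the tree `((A,B),C)` this gives proximities A–B = 1/2 and A–C = B–C = 1/4.
Because only node degrees enter, the statistic is invariant to branch-length
rescaling.

`phylo_correlogram()` bins patristic distances into equal-count classes
(falling back to splits between unique distances on small symmetric trees,
where quantile breaks collapse) and computes a binary-weight Moran's I with a
seeded permutation p per class. Equal-count binning was chosen over
equal-width because patristic distances on real trees are strongly skewed;
the class count is a parameter, not a constant. Under Brownian-motion traits
the I profile decreases with distance-class midpoint in ≥ 18/20 seeded
replicates on a 64-tip balanced tree.

## Co-occurrence network

`co_occurrence_network()` chains a strict prevalence filter (present in more
than 10% of samples), pairwise Spearman correlations with two-sided p from
the t approximation, edge retention at rho > 0.7 and p < 0.01, Louvain module
detection at resolution 1, and topology metrics: average degree 2E/N, average
path length over connected pairs of the largest connected component, and mean
local clustering over nodes of degree ≥ 2. Only positive correlations form
edges by default (`use_abs` admits both signs); p-values are raw by default
with an optional Benjamini–Hochberg mode, matching the common practice of
reporting uncorrected thresholds for these networks. Recovery tests plant
latent-factor correlation blocks (15 samples, noise sd 0.3) and stochastic
block models; edge precision/recall and adjusted Rand index against the
planted truth exceed 0.9 and 0.8 respectively.

## Utilizer classification

`classify_utilizers()` merges AFE results with genome features. For
aspartate, a primary utilizer needs a positive median AFE, at least one
aspartate transporter (any of the ABC substrate-binding proteins
GltI/AatJ, Peb1A/GlnH, AapJ/BztA, ABC.PA.S or the symporters GltP, GltT,
GltTK, GltPh, YbeC) **and** the pathway to move aspartate carbon into
nucleotides, operationalized as aspartate carbamoyltransferase (ATCase) —
the shortest route into pyrimidine biosynthesis. For acetate the transporter
requirement is waived (acetic acid crosses membranes passively) and the
pathway is ACK-PTA or ACS. Positive AFE without the genomic machinery is a
cross-feeder; nonpositive AFE a non-utilizer; emergent taxa and taxa without
a matched genome get their own classes. "Positive" means median > 0 strictly
by default; a CI-based mode is available but is subject to the bootstrap
caveat above.

Representative genomes are selected per taxon by 16S identity (> 95%),
then source-spring proximity (Gongxiaoshe, then Jinze, then Rehai, then
other), then the MAG quality score completeness − 5 × contamination, then
identity, with genome-id tie-breaks. The quality score is the common MAG
convention; the combining rule is a package decision since only the
criteria order is standard. When one genome matches several AFE values,
`resolve_duplicate_afe()` keeps the maximum. Genome sizes follow
$(Size_{obs} - Size_{obs}\cdot contamination)/completeness$.

## Pipeline and reproducibility

`run_qsip_pipeline()` executes simulate → AFE (both substrates) → diversity →
partition → classify → phylogenetic signal → network, with stage toggles,
writes each stage's table plus a JSON report, and derives every stage seed
deterministically from one master seed (`seed * 1000 + stage offset`), so an
identical configuration produces a byte-identical report. ANOSIM is run on
treatments with at least two tubes, since the statistic is undefined for
singleton groups.

Problem sizes used in the package's own validation experiments — 200 taxa,
50,000 reads per fraction and 5 seeds for recovery; 3 seeds with 1000
bootstrap iterates for CI calibration; 20 Brownian replicates with 999
permutations for signal power — were chosen as the smallest designs at which
the Monte-Carlo error of each check is comfortably below its tolerance.

## Known limitations

* Bootstrap CIs are anti-conservative at 3–5 tubes per group (see above).
* The AFE estimator assumes the density grid covers every taxon's
  distribution; mass truncated at the gradient edge would bias WADs inward.
* GC estimation inherits any error in the unlabeled density, so taxa seen in
  few light tubes have noisier GC and AFE.
* The correlogram's distance classes and the network's thresholds are
  conventions, not inferences; conclusions should be checked for robustness
  to them.
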