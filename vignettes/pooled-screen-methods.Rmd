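---
title: "Methods: pooled shRNA screen deconvolution and downstream analyses"
author: "poolscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled shRNA screen deconvolution and downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

# The measurement model

In a pooled shRNA fitness screen, cells carrying thousands of hairpin
constructs are grown together under a control and a stress condition. After
treatment, the genome-integrated hairpin sequences are PCR-amplified from
each arm, labeled (Cy3 for control, Cy5 for stress), and competitively
hybridized to arrays whose probes match the hairpin sequences — one array
per library sub-pool. The per-probe statistic is the log2 "R/G" ratio of
net stress over net control intensity: a hairpin whose host cells died
under stress is depleted (negative R/G, "synthetic sick/lethal" gene), one
whose knockdown protected its host is enriched (positive R/G, "synthetic
survival/protective" gene).

`simulate_screen()` generates this readout from a known truth. Per hairpin
$h$ of gene $g$ and replicate:

- an initial count $N_{0h} \sim \mathrm{Poisson}(\texttt{representation})$
  seeds both arms (default 1000 cells per hairpin, the usual representation
  target for genome-wide libraries);
- the stress-arm endpoint abundance is
  $N_{0h}\, s\, 2^{\delta_g e_h + \varepsilon}$, where $s$ is the baseline
  stress survival of a neutral gene (default 0.5, a treatment that roughly
  halves cell number), $\delta_g$ is the gene's signed log2 fitness effect,
  $e_h \in [0,1]$ the hairpin's knockdown efficacy, and
  $\varepsilon \sim N(0, \texttt{noise\_sd}^2)$ replicate noise in log2
  units (default 0.25);
- both channels share a lognormal per-probe amplification factor (both
  arms pass through the same PCR, so it cancels in the ratio) and receive
  additive lognormal background, which is also reported as the background
  estimate.

The treatment window is collapsed into the single factor
$2^{\delta_g e_h}$ because only endpoint abundances are observable;
pre-selection infection dynamics are likewise not modeled beyond the
Poisson seeding. Efficacy defaults to $U(0.5, 1)$ so that multi-hairpin
concordance — the basis of the hit rule below — is a non-trivial property
of simulated data. Noise is placed on the stress arm so that the
per-replicate log2 R/G noise standard deviation equals `noise_sd` exactly;
with hairpin-level effect spread $\sigma_b$ the expected replicate-pair
Pearson correlation is then $\sigma_b^2 / (\sigma_b^2 +
\texttt{noise\_sd}^2)$, which the QC tests exploit as a closed-form oracle.

# Preprocessing

`filter_background()` discards a probe row when a channel's foreground is
less than `fold` (default 2) times that channel's background, strictly:
a foreground exactly at twice background survives. Filtering is per
replicate, so a hairpin missing on one array keeps its other replicates.
Whether the original protocol tested one or both channels is not
documented for this assay class; both-channel testing is the default and a
`rule` argument exposes the alternatives.

`compute_log_ratios()` takes net intensity (foreground minus background)
before the ratio; an entry whose net intensity is non-positive becomes
missing and is counted in QC rather than raising an error. Background
subtraction is switchable (`use_net`) since raw-foreground ratios are also
defensible when background is small.

`quantile_normalize()` equalizes the replicate columns within each
sub-pool's probe set (each sub-pool was a separate physical array; a flag
normalizes globally instead). The algorithm is the classical one — replace
each column's $k$-th order statistic by the mean of all columns' $k$-th
order statistics — with one extension: missing entries keep their
missingness and are excluded from rank computation, with each column's
ranks mapped onto the mean quantile function by linear interpolation.
Integer rank positions index the reference directly, so on complete data
all columns end with bit-identical value multisets and the operation is
idempotent. A column with fewer than two observed values in a group cannot
be ranked meaningfully and passes through with a warning.

`median_center()` then subtracts each pool group's median. Competitive
hybridization compares equal amounts of labeled product, so the global
survival factor common to every hairpin (about $\log_2 0.5 = -1$ at 50%
survival) carries no gene-level information; centering puts the unchanged
bulk of the library at R/G = 0, which is the scale the fixed thresholds
below assume. Applied after quantile normalization the shift is common to
all columns of a group, preserving the equal-multiset invariant. The step
is on by default in the pipeline and switchable.

`replicate_qc()` reports pairwise replicate Pearson correlations (over
jointly observed entries; undefined below three shared entries), the
fraction of missing entries, the empirical R/G range, and a histogram.

# Multiple-hairpin hit calling

A hairpin scores an *event* when $|R/G| > 0.7$ in at least 2 of the 3
biological replicates **and** the coefficient of variation of its
replicate values — sample (n−1) standard deviation over the absolute
mean — is below 0.5. Both inequalities are strict, mirroring how such
thresholds are printed. The CV denominator is the absolute mean because a
plain "stdev/ave" is sign-ambiguous on log ratios; a zero mean leaves the
CV undefined and calls no event. The event direction is the sign of the
replicate mean.

A gene is a *hit* when at least two distinct hairpins agree: protective
with ≥ 2 enriched hairpins, lethal with ≥ 2 depleted. Requiring
same-direction pairs is a design choice — mixed-direction support is
biologically incoherent for a knockdown phenotype — and a gene qualifying
in both directions through disjoint hairpin subsets is flagged ambiguous
and classed none (`allow_mixed_direction` disables this). Thresholds are
evaluated on normalized values. `cross_condition_overlap()` intersects hit
sets between two stress conditions separately per class, one Venn per
direction.

There is deliberately no p-value machinery here: the rule is a
deterministic filter, and its false-positive behaviour is characterized
instead by the null-calibration analysis (below).

# Second-best-hairpin ranking

For ranking, each hairpin's score is its mean log2 R/G across replicates —
the simplest faithful log-fold-change statistic, since the weighting used
by interactive screen-analysis tools is not published. A gene's score is
its **second** most extreme hairpin score in the tested direction
(second-largest for enrichment, second-smallest for depletion; genes with
fewer than two scored hairpins are omitted). The second order statistic is
robust to a single off-target hairpin: one spurious extreme cannot carry a
gene.

`permutation_nes()` normalizes gene scores against a permutation null:
for each hairpin-count stratum $m$, $B$ pseudo-genes are drawn (each $m$
scores sampled without replacement from the global score pool) and their
second-best statistics give the stratum's null mean and standard
deviation. The NES is the resulting z-score; stratification is necessary
because the second order statistic's null distribution depends on $m$. The
reciprocal 1/NES is reported where defined, genes are ranked by NES
(descending for enrichment, ascending for depletion) with lexicographic
tie-break, and a degenerate stratum (null sd 0) yields an undefined NES
ranked last rather than an error. Because the null draws are indices into
the score pool under a fixed seed, the whole ranking is invariant to a
common additive shift of all scores. The exact normalization used by the
original interactive tools is not printed anywhere we could verify, so
this stratified z-normalization is this package's documented stand-in.

# Expression signatures

`zero_transform()` subtracts each gene's mean over designated scramble
control samples, so values read as log2 changes relative to controls;
the operation is idempotent for a fixed control set. `fold_filter()` keeps
genes reaching a 1.7-fold change ($|\log_2| \ge \log_2 1.7 \approx 0.766$)
in at least 6 arrays. The threshold is interpreted on the linear fold scale
(a "1.7-fold change"), not as 1.7 log2 units — the two readings circulate
for such filters, so `scale = "log2"` selects the other; the boundary is
inclusive, matching common occurrence-filter semantics, with a `strict`
mode.

`create_signature()` builds a two-class projector in the
CreateSignature/binary-regression style: genes are ranked by the absolute
signal-to-noise ratio between classes (difference of class means over the
sum of class standard deviations, sds floored at $10^{-6}$), the top
`n_sig` (default 100) retained; the selected, row-centered training
submatrix is decomposed by SVD; and class is regressed on the top
`k_factors` (default 2) factor scores by ridge-penalized probit maximum
likelihood. The published tool's exact defaults are not printed, so
`n_sig` and `k_factors` are this package's documented defaults, exposed in
the configuration. The small ridge (default 0.01, intercept unpenalized)
keeps coefficients finite under the perfect separation that 6–9 training
samples routinely produce; SVD factor signs are anchored (largest loading
positive) for cross-platform determinism. `project_signature()` centers
test profiles with the training statistics and maps them through the basis
and probit link to a probability of resembling the knockdown class; genes
outside the signature provably cannot influence the output.
`signature_regression()` is ordinary least squares of one signature's
per-sample probabilities on another's, with the slope t-test p-value —
probabilities are regressed directly, not logit-transformed.

The expression generator plants two knockdown gene programs (default 50
differentially expressed genes each, sharing a configurable fraction,
default 60%, with concordant directions) over a common per-gene baseline.
Cohort samples carry *independent* uniform activities of the two programs,
so any correlation between the two projected signatures on the cohort
arises only through the shared genes — making the cross-signature
regression a genuine test of program overlap rather than of a built-in
correlation.

# Metabolite statistics

All metabolite values are first normalized by each sample's total protein
content. `hypoxia_change()` reports, per cell line and metabolite, the
fold change of hypoxia over normoxia replicate means (or the equivalent
percent change, $(\mathrm{fold}-1)\times 100$), with the SEM propagated by
the delta method for a ratio of independent means — appropriate at the
n = 3 replicates typical of such panels. `substrate_product_ratio()`
computes the α-ketoglutarate/succinate ratio (a proxy for the activity of
2-oxoglutarate–dependent dioxygenases) per sample and then averages, so
error bars reflect replicate scatter; a ratio-of-means mode is available.
Samples with a zero denominator are excluded and counted. The metabolite
generator makes raw signal proportional to each sample's protein content,
so planted effects are recoverable only after normalization — the
structure the statistics assume.

# What the synthetic data does and does not show

The generators reproduce the statistical structure the pipeline assumes:
library pool structure, Poisson representation, multiplicative fitness
effects with variable per-hairpin efficacy, shared-PCR amplification bias,
additive background, replicate noise, overlapping expression programs, and
protein-scaled metabolite signal. They do **not** model hairpin sequence
effects, hybridization cross-talk, dye bias, intensity saturation, spatial
array artifacts, batch effects, or the heavy-tailed noise and correlated
probes of real arrays. Passing tests therefore demonstrate that the
implementation is correct and well calibrated under its stated model, not
that the thresholds are optimal for any particular real dataset.

Default study conditions used by the test-suite analyses: 500 genes × 4
hairpins in six sub-pools with 20 protective and 20 lethal genes
(δ = ±1.2, efficacy U(0.6, 1), noise sd 0.25, triplicates, 50% stress
survival) for recovery; 2000 neutral genes for null calibration; 1000
permutations per stratum for the NES; 1000-gene expression matrices with
50 DE genes (effect 1 log2, noise sd 0.5, 6+6 training samples) and
130-sample cohorts, 100 seeded repeats, for the signature analyses. These
sizes were chosen as the smallest at which the planted effects, noise
levels and Monte-Carlo error bands are comfortably resolved.

# Worked example

```{r example, eval = FALSE}
res <- run_screen_pipeline(
  list(seed = 1L,
       screen = list(n_genes = 500L, n_protective = 20L, n_lethal = 20L,
                     effect_size = 1.2, conditions = "hypoxia")),
  outdir = "screen_out")
h <- res$per_condition$hypoxia
table(h$hits$class)
head(h$ranking[order(h$ranking$rank), ])
```

# Known limitations

- The NES normalization is a documented stand-in for an unpublished
  interactive-tool internal; absolute NES values should not be compared
  across implementations, only ranks.
- Quantile normalization with heavy missingness interpolates the reference
  distribution; with very sparse columns the equal-multiset guarantee
  holds only for equal observation counts.
- The probit signature model is linear in two factor scores; strongly
  nonlinear class structure would need more factors (`k_factors`) or a
  different classifier.
- Delta-method SEMs for fold changes are first-order approximations and
  degrade when the normoxic mean is near zero.
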