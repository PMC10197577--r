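---
title: "Models and methods in rdhtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rdhtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`rdhtools` implements the statistical machinery for relating genome-wide
RNA:DNA hybrid (RDH) accumulation to gene expression, gene orientation
relative to DNA replication, and mutagenesis in bacteria with circular
chromosomes. This vignette documents the models, their assumptions, the
parameters that matter, and the design decisions taken where the design
was genuinely open. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The genome model and orientation

A `genome_model` is a circle of `length_bp` bases replicated
bidirectionally from `origin_pos` to `terminus_pos`. The two replichores
partition the circle; on the replichore where the fork travels in the
increasing-coordinate direction a plus-strand gene is transcribed
codirectionally with replication, and flipping either the strand or the
replichore makes it head-on. Features are assigned to a replichore by
their midpoint, so a feature is never split (a deliberate simplification:
genes straddling the terminus are rare and their orientation is ambiguous
anyway). Coordinates are 0-based half-open internally; GFF3 I/O converts
to and from the 1-based inclusive convention.

## Enrichment estimation

For one genotype, bin $b$ and sample $j$:

$$y_{bj} \sim \mathrm{NB}\!\left(\mu_{bj},\ \phi\right),\qquad
\mu_{bj} = s_j\,\lambda_b\,2^{\alpha_b\,[j\ \text{is pulldown}]},\qquad
\mathrm{Var} = \mu + \mu^2/\phi$$

with priors $\alpha_b \sim N(0, 1)$ (log2 enrichment), $\log\lambda_b
\sim N(\hat\ell, 5^2)$ centered on the observed mean input count, and
$\phi \sim \mathrm{Gamma}(2, 0.1)$ shared within the genotype. The
posterior is sampled with JAGS (two chains; 500 retained draws by
default, matching the quantile-interval display convention of
enrichment-track figures); each bin reports the posterior mean and the
equal-tailed 90% interval. Whether that interval should instead be an
HPD interval is not determined by the displays the model imitates;
equal-tailed was chosen for its invariance to monotone transformation
of the summary.

Two properties drive the remaining choices:

* **All-zero bins** carry no likelihood information, so the $N(0,1)$
  prior shrinks them to zero enrichment rather than producing NaN.
* **Size factors.** Sequencing yields only relative enrichment, so some
  normalization assumption is unavoidable. Raw library totals are biased
  whenever a non-negligible fraction of the genome is truly enriched:
  the pulldown totals inflate and the planted signal is partially
  absorbed. `fit_enrichment` therefore removes replicate depth
  differences within each sample type by median-of-ratios against the
  type's geometric-mean reference bin, then aligns the pulldown scale to
  the input scale at the *mode* of the per-bin log ratio of the two
  reference tracks. Enriched bins shift that ratio's mean and median but
  not its mode as long as unenriched bins are the largest coherent
  population — the operative assumption, which also fixes the zero point
  of $\alpha$. Library totals remain as a fallback when almost no bin is
  covered in every sample.

Tracks are post-processed with `robust_z`
($z = (x - \mathrm{median})/(1.4826\,\mathrm{MAD})$; the constant makes
the MAD estimate a normal standard deviation), `rolling_median`
(centered windows, shrinking at linear-track edges, wrapping on circular
tracks, even windows averaging the two central order statistics), and
`genotype_contrast`, which differences posterior draws paired by draw
index so that contrast intervals inherit the within-fit Monte-Carlo
structure (independent pairing is available by flag).

`qpcr_ddcq` models replicate-level
$\Delta\Delta C_q = (C_q^{\text{pull}} - C_q^{\text{input}})_{\text{locus}} -
(C_q^{\text{pull}} - C_q^{\text{input}})_{\text{spike}}$ with a normal
likelihood, a flat location prior and a half-normal scale prior scaled to
ten times the observed spread; 95% HPD intervals come from sorting the
posterior draws and taking the shortest window.

## Feature statistics

A feature's enrichment score is the **median** robust z of sense-strand
bins over its span (or its first 100 bp from the 5$'$ end; shorter
features use their whole span). Medians over bins make scores robust to
single-bin spikes; masked multicopy loci (consensus rRNA) are excluded,
and a feature with no covered bins is missing, never zero.

Orientation comparisons report the difference of group medians (head-on
minus codirectional) with a seeded percentile-bootstrap 95% CI (1000
resamples by default; the CI construction is a package choice — nothing
in the imitated displays pins it down) and a two-sided Wilcoxon rank-sum
p-value; batches are corrected by Benjamini–Hochberg FDR with the star
bands `*` [0.01, 0.05), `**` [0.001, 0.01), `***` < 0.001. Expression
quintile filters are computed on the filtered class itself, so "top 20%"
always means the top quintile of the features actually being compared.
Group-size gates: the rank-sum comparison requires at least 3 features
per group; the paired genotype comparison requires more than 3 pairs, so
the three consensus rRNA loci are reported as point estimates without
CIs or tests.

The per-genotype regression of CDS score on orientation, expression z,
and their interaction uses a conjugate Normal–Inverse-Gamma model
($\beta \sim N(0, 100\,\sigma^2 I)$, $\sigma^2 \sim
\mathrm{InvGamma}(0.01, 0.01)$), so posterior draws are exact — no
sampler, no convergence question.

## MA-line statistics

Substitutions split into transitions (purine–purine, pyrimidine–
pyrimidine) and transversions; length changes are insertions or
deletions. Classification is reverse-complement invariant, which the
suite checks over all 12 substitution pairs.

Structural variants within 100 bp of a line's engineered allele are
construction artifacts: any SV overlapping the closed window
$[\text{start} - 100, \text{end} + 100]$ is removed (any-base-overlap
semantics; the filter is idempotent and monotone in the margin). Lines
carrying an SV in a blocklisted gene (e.g. a mismatch-repair gene) are
excluded from rate estimation entirely — numerator and denominator —
because their mutational process is no longer the one under study.

Rates use the exact Garwood CI,
$[\chi^2_{\alpha/2}(2k),\ \chi^2_{1-\alpha/2}(2k+2)]/2T$, which is
conservative (coverage slightly above nominal) and handles $k = 0$ with
a zero lower bound. Two rates are compared by the exact conditional
test: given $n = k_1 + k_2$, $k_1$ is binomial with probability
$T_1/(T_1+T_2)$ under equal rates; the suite checks this against direct
enumeration of the conditional pmf for all counts up to 10 and against
`stats::poisson.test`. Positional densities use `stats::density` with
`adjust = 0.2` of the Silverman reference bandwidth, on the linear
coordinate (no circular wrapping — a plotting convention; densities very
near the origin of coordinates are mildly underestimated).

## The mutation-rate regression

For mutation class $m$ (transitions, transversions, indels — insertions
and deletions pooled) and CDS–genotype row $i$:

$$y_{im} \sim \mathrm{Poisson}\!\left(E_i\, e^{\eta_{im}}\right),\qquad
\eta_{im} = \beta_{0m} + \text{genotype} + \beta_{1m}\,\text{RDH}z +
\beta_{2m}\,\text{expr}z + \beta_{3m}\,\text{head-on} + \text{interactions}$$

with exposure $E_i$ = CDS length (bp) × the genotype's total
generations — this makes coefficients log rates per bp per generation and
gives exposure-doubling invariance a testable form. Covariates are
re-standardized by robust z over the assembled design; standardized
coefficients get $N(0,1)$ priors. Classes share the design but not
coefficients (separate fits are exactly the no-pooling joint model).

Sampling uses the JAGS `glm` block sampler, which is roughly 20× faster
per effective draw here than generic slice sampling but autocorrelated,
so chains are run long and thinned (default thin 20; 1000 retained
draws). The intercept is centered on the pooled log rate by folding it
into the offset, with a diffuse $N(\text{pooled}, 10^2)$ prior — a pure
reparameterization that keeps the sampler in a well-scaled region (the
raw intercept sits near $-22$ on the log scale). Convergence is gated at
split-chain $\widehat{R} < 1.01$ for every reported coefficient; an
unconverged fit is an error naming the worst term, not a warning.

**Bayes factors.** For each coefficient, three hypotheses are scored
against the region of practical equivalence (ROPE) half-width $\delta$:
$H_+ : \beta > \delta$, $H_- : \beta < -\delta$, and
$H_0 : |\beta| \le \delta$. The Bayes factor for a region hypothesis is
the posterior odds divided by the prior odds, with prior masses computed
analytically from the normal prior; $K$ reports the favored directional
hypothesis and $K_0$ the near-zero hypothesis, with the standard bands
($K \ge 150$ very strong, $[20, 150)$ strong, $[3, 20)$ positive). A
region-based (encompassing-odds) definition was chosen over
Savage–Dickey because $H_0$ is an interval, not a point. The default
$\delta = 0.05$ prior-sd units is an explicit, logged parameter — "near
zero" has no canonical width, and a precisely estimated coefficient
close to zero can legitimately score high on both $K$ and $K_0$. When
the posterior is supplied analytically, odds are computed in log space
so saturated tail masses still yield finite $K$.

**LOO-CV.** Model comparison uses importance-sampling leave-one-out
with per-observation weights $1/p(y_i \mid \theta_s)$ truncated at
$\sqrt{S}$ times their mean, pooling all fitted classes; observations
whose weights required truncation are counted and reported. This is a
self-contained implementation of the standard truncated-IS estimator;
differences are reported with standard errors from the pointwise elpd
differences.

**Fitted curves** evaluate $e^{\eta}$ per unit exposure over a covariate
grid with all other covariates at their design means (genotype dummies
at their frequencies; orientation either averaged or stratified); grid
points outside the observed covariate range are flagged and warned
about, not silently extrapolated.

## Replication profiling

Coverage becomes $\log_2(\text{count} \cdot 10^6 / \text{library size})$
per sample (pseudocount 0.5 by default, recorded in the output and
removable for exactness checks), then the replicate mean, then a loess
smooth with `span = 0.03` and local-linear degree — local linear
reproduces exactly linear profiles, which anchors the smoother's unit
tests. Slopes are estimated by least squares in windows (default 5 kb)
that never cross a replichore boundary, expressed per base of *fork
travel* (sign-flipped on the leftward replichore) so "more negative"
means "slower fork" genome-wide, robust z-scored per replichore, and
contiguous runs below $-z_{\text{threshold}}$ (default 4) become stall
intervals. The threshold-based caller is an operationalization of what
is otherwise a visual judgement; the default of 4 keeps the false-call
rate under normal tails near zero at genome scale.

One artifact is worth knowing about: a persistent stall depresses all
coverage downstream of itself on its replichore, which creates a step at
the terminus where the two replichores meet. Smoothing across that step
can produce a mirror stall call in the first windows of the opposite
replichore. The planted-signal tests therefore assert recovery of the
interval overlapping the plant; stall-free profiles have no step and no
such artifact.

## The synthetic-data generator

The generator's defaults describe the study conditions the package is
exercised under; they are fixed choices, not tuning knobs.

* **Genome**: 400 kb circle (a 4 Mb *Bacillus*-like chromosome scaled
  ×0.1 to keep desk-scale runs fast), origin at 0, terminus at 200 kb,
  360 CDSs of log-normal length (mean 800 bp), 35% with 100 bp UTRs,
  plus 20 ncRNAs, 3 masked consensus rRNAs and 20 tRNAs, packed without
  overlap with a 75% codirectional bias typical of bacterial genomes.
  Bins are 100 bp so first-100-bp windows hold at least one bin.
* **Expression**: log-normal, $\log$-mean 2, $\log$-sd 1; robust
  z-scores of log abundance.
* **Hybrid truth** per genotype:
  baseline + slope·expression-z + 5$'$-UTR boost + first-100-bp boost on
  the transcript's sense strand, zero elsewhere. The strand convention
  is a stand-in — which DNA strand a pulldown reports relative to
  transcript sense is an open experimental question — so it is isolated
  in one place. Defaults encode the qualitative genotype contrast the
  analyses must resolve: a wild-type-like block (slope 0.20), an
  RNase-HII-deletion-like block biased to UTRs and early CDS (slope
  0.25, UTR5 boost 0.9, first-100 boost 0.8), and an
  RNase-HIII-deletion-like block dominated by expression dependence
  (slope 0.70).
* **Counts**: NB with mean 60 per input bin, dispersion 20
  (variance = μ + μ²/20), 3 replicates per sample type, log-normal size
  factors (sd 0.1).
* **Mutations**: per-CDS Poisson with exposure length × generations;
  72 lines × 3688 generations ≈ 265,500 generations per genotype; class
  intercepts around 1.6 × 10⁻¹⁰ (transitions), 6 × 10⁻¹¹
  (transversions), 4 × 10⁻¹¹ (indels) per bp per generation — together
  a genome-wide substitution+indel rate of order 10⁻³ per generation on
  the full-size chromosome; genotype multipliers (transversions ×2 and
  transitions ×1.5 in the HIII-deletion-like genotype, transitions ×1.6
  in the HII-deletion-like genotype) and covariate effects (RDH → indel
  0.3, expression → transitions +0.1 / transversions −0.2 /
  indels −0.2) mirror the sign structure the regression is meant to
  detect. SVs accrue at 6.4 × 10⁻⁵ per generation.
* **Coverage**: expected log2 coverage declines linearly by 1 log2 unit
  from origin to terminus per replichore (typical marker-frequency decay
  in exponential growth), Poisson noise, 3 replicates; one default
  stall (severity 1.5 log2 units over 5 kb) near the terminus.

Every generator is a pure function of its configuration: each pipeline
stage derives its own seed substream from the master seed, so stages are
decoupled and whole runs are bit-reproducible (the acceptance script
checks manifest checksums across two runs).

What the generator does *not* emulate: sequence-context mutation
signatures, raw reads and alignment artifacts, operon structure,
copy-number variation of the rRNA loci, and any coupling between
replication stalls and local mutagenesis. Passing tests therefore
demonstrate that the estimators recover the statistical structure they
assume — not that real libraries satisfy those assumptions.

## Problem sizes and numerical choices

The test suite and acceptance script run the enrichment model at
hundreds of bins, the regression at 100–750 CDS rows, CI coverage at
2000 replicates, and the full pipeline on a 30 kb genome — sizes chosen
so the whole suite completes comfortably on one CPU while leaving every
statistical assertion at its stated tolerance. Tolerances follow the
source of noise: exact arithmetic is asserted to 10⁻¹² (robust z,
rolling medians, enumeration oracles), MCMC recoveries at ±0.3 log2
units with interval-calibration bands of 85–95%, and frequency
properties (coverage, null rejection rates) with binomial slack at
their simulation sizes. Ties in the rolling median resolve through the
order-statistic midpoint; degenerate inputs (constant tracks, zero MAD,
all-zero bins, zero exposures) raise explicit errors or documented
fallbacks rather than propagating NaN.

## The pipeline

`run_pipeline` chains synthetic data → enrichment → feature statistics →
MA statistics → regression → replication profiling under one
configuration, writing FASTA/GFF3/TSV/bedGraph/BED outputs and a
`manifest.json` with an MD5 checksum per file and the resolved
configuration. The package's interface is R functions plus this
orchestrator; there is no shell entry point — scripted use goes through
`Rscript` and the exported API, as in `scripts/acceptance.R`.

## Known limitations

* The enrichment model assumes a shared dispersion per genotype and
  independent bins; real fragment counts are autocorrelated along the
  genome, so intervals at fine scales are likely anti-conservative.
* Absolute cross-genotype comparison of sequencing tracks is out of
  scope by design (the normalization fixes each genotype's own zero
  point); the qPCR ΔΔCq route is the cross-genotype instrument.
* The mode-alignment normalization requires unenriched bins to dominate;
  a genome that is mostly enriched would defeat it.
* The stall caller reports the smoothing-induced terminus echo of a
  severe stall (see above) and does not attempt to deconvolve fork
  collision geometry.
* LOO uses truncated importance sampling without Pareto-smoothed tail
  fitting; the per-observation truncation flags are the honesty check.
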