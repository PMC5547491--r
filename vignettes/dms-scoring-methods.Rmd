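---
title: "Scoring deep mutational scans: models, assumptions, and design choices"
author: "dmscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring deep mutational scans: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmscore)
```

This vignette is the package's account of its statistical model: what is
estimated, under which assumptions, which knobs matter, and where genuinely
open design choices were resolved.

## From reads to counts

Variant calling is **alignment-free**: each quality-filtered read is compared
position-by-position to the wild-type sequence, which requires reads to share
the wild-type's length and start point. This is what makes counting millions
of reads cheap, and it is also the reason insertions and deletions are out of
scope — a read of the wrong length is rejected and tallied, not aligned.
Overlapping paired-end reads are merged base-by-base before filtering: the
higher-quality base wins and the merged quality is the maximum of the pair.
The max rule is a choice, not a claim about any particular sequencer's error
model; sum- or recalibration-based merging would be defensible too. Ties
between disagreeing bases become `N` deliberately, so that ambiguity flows
into the existing no-`N` filter rather than producing a silent base call.
The default quality floor is Phred 20 at every position; it is configurable
because some assays warrant stricter thresholds (e.g. 23 for short,
deeply-mutagenized regions where a single miscalled base creates a spurious
variant).

Barcoded libraries bypass calling: barcode reads are looked up in a
many-to-one barcode→variant map, and unmapped barcodes are excluded but
logged. The handling of unmapped barcodes is not dictated by the model;
excluding them biases nothing as long as mapping failures are unrelated to
variant identity, which is the natural assumption when the map was built
from the same library.

Counting always satisfies a conservation law — every input read is either
counted or attributed to a rejection tally — and the tests enforce it.

## The enrichment score

For a selection sampled at timepoints $t \in T$ (with $t_0$ the input), the
wild-type-normalized log ratio of variant $v$ is

$$M_{v,t} = \ln\frac{c_{v,t} + \tfrac12}{c_{wt,t} + \tfrac12},$$

and the score $\hat\beta_v$ is the slope of the weighted least-squares
regression of $M_{v,t}$ on $x_t = t/\max T$. Normalizing the time axis makes
scores comparable between selections whose timepoints differ in units or
magnitude (rounds 0–5 versus hours 0–72). Normalizing by the wild-type count
at *each timepoint* absorbs library-size terms and any non-linearity shared
across variants (e.g. the wild-type's own frequency drift); what remains
non-linear after normalization shows up as residual variance and hence as a
large standard error — which is exactly how unreliable fits should surface.
The intercept is estimated but is not part of the score: it reflects input
composition, not selection.

The regression weight of a timepoint is the inverse of the Poisson variance
of its log ratio,

$$V_{v,t} = \frac{1}{c_{v,t} + \tfrac12} + \frac{1}{c_{wt,t} + \tfrac12},$$

so shallowly sequenced timepoints are downweighted instead of forcing a
choice between adding noise, dropping the timepoint, or re-sequencing. The
$\tfrac12$ pseudocount keeps every quantity finite at zero counts; a
zero-count timepoint still carries (low) weight $\approx \tfrac12$.

The slope standard error multiplies the nominal weighted-least-squares slope
variance by the weighted residual mean square $s^2 = \sum_t w_t e_t^2/(n-2)$.
The rationale for this choice: with an exact fit it gives SE $= 0$ (the
wild-type against itself being the canonical case), and with well-calibrated
Poisson weights $s^2 \approx 1$ so it reduces to the nominal variance. Raw
p-values come from a two-sided z-test of $\hat\beta_v/\mathrm{SE}$ under the
null that the variant behaves like wild-type; multiple-testing correction is
left to the analyst, with Benjamini–Hochberg provided (`adjust_pvalues()`).
More elaborate FDR estimators that require estimating the null proportion are
deliberately not bundled.

Two-timepoint designs have no residual degrees of freedom, so the score is
the two-point slope $L_v$ and its standard error is the closed-form Poisson
expression over all four counts. Scoring eligibility requires presence in
the input ($c_{v,0} > 0$): a log-ratio trajectory anchored at an unobserved
input is not interpretable, so such variants are reported unscored rather
than silently dropped.

When a library has no wild-type sequence, the same formulas run with the
**filtered library size** (the per-timepoint sum of counts over variants
present at every timepoint) in place of the wild-type count, including the
pseudocount — the original formulation gives no separate variance formula
for this mode, and using identical formulas keeps the two modes directly
comparable. Whether the pseudocount "should" be added to a denominator that
is already in the thousands is immaterial in practice.

## Combining replicates

Replicate scores $\hat\beta_i$ with standard errors $\hat\sigma_i$ are
combined per variant by a one-random-effect meta-analysis model estimated by
restricted maximum likelihood. The between-replicate variance
$\hat\sigma_s^2$ starts at the sample variance of the replicate scores
(the overline mean is read as the unweighted mean; the alternative weighted
reading changes only the starting point of an iteration that converges to
the same fixed point) and is updated with the multiplicative Fisher-scoring
fixed-point rule, with the combined score recomputed each iteration as the
precision-weighted average with weights $(\hat\sigma_s^2 +
\hat\sigma_i^2)^{-1}$. The stationary points of this update are exactly the
REML score-equation solutions, which the tests verify against a brute-force
one-dimensional grid maximizer of the restricted likelihood and against an
independent REML fitter.

A fixed 50 iterations are run for all variants in parallel — cheaper than
per-variant convergence checks — and the final change $\varepsilon_s$ is
recorded; variants with $|\varepsilon_s| > 10^{-6}$ are flagged rather than
re-iterated. The $10^{-6}$ flag threshold is conservative: a variant a hair
above it is typically within $10^{-5}$ of its fixed point, far below any
scientifically meaningful difference. Iterates that undershoot below zero
are clamped at zero and flagged; a replicate with zero standard error while
$\hat\sigma_s^2 = 0$ would carry infinite weight, in which case that
replicate's (exact) score is reported directly.

The combined standard error is $\sqrt{1/\sum_i(\hat\sigma_s^2 +
\hat\sigma_i^2)^{-1}}$ — the standard random-effects expression consistent
with the weighted average; the source formulation names the property (it
captures selection-specific error *and* replicate spread) without displaying
the formula. It is bounded below by the fixed-effect standard error
$\sqrt{1/\sum_i \hat\sigma_i^{-2}}$, with equality exactly when
$\hat\sigma_s^2 = 0$; the fixed-effect model is implemented as a comparison
baseline only, because it dramatically understates uncertainty whenever
replicates disagree. Each variant is combined independently: no shrinkage or
information-sharing across variants is applied, so a variant's score never
depends on other variants' behaviour.

## Filtering and hypothesis testing

Per-variant standard errors support principled filtering: retain the
fraction of variants with the smallest combined SE (count-based criteria —
input count, total count — are provided as the comparison baselines they
are). Ties break by variant label so results are reproducible. Between-
condition comparisons use $z = (\hat\beta_A - \hat\beta_B)/
\sqrt{SE_A^2 + SE_B^2}$; no cross-condition normalization is applied, and the
output carries an explicit caveat that the test presumes roughly similar
score distributions across conditions — score distributions shift with
selection pressure, and normalizing across pressures is an open problem this
package does not claim to solve.

## The simulator

The simulator generates the full causal chain of a selection with known
truth, which is what makes end-to-end validation possible. Reference
conditions (the defaults):

| parameter | default | meaning |
|---|---|---|
| `n_variants` | 10,000 | library size incl. wild-type |
| `effect_sd` | 0.1 | SD of the true-effect distribution |
| `wt_percentile` | 0.75 | wild-type's rank in that distribution |
| `wt_effect` | 0.5 / 1 | binding probability / growth rate of wild-type |
| `effect_bounds` | (0.05, 0.99) / (0.05, 5) | rejection-sampling bounds |
| `population_size` | 10⁷ | population restored after each round |
| `wt_input_frequency` | 1% | wild-type share of the input population |
| `input_count_mean`, `input_log_sd` | 990, 0.4 | log-normal input counts |
| `rounds`, `replicates` | 5, 5 | design size |
| `reads_per_variant` | 200 | mean sequencing depth (2×10⁶ reads/timepoint) |
| `doublings_per_round` | 2 | wild-type doublings per growth round |

True effects are drawn from a normal distribution whose mean is placed so
the wild-type sits at the 75th percentile (deleterious variants outnumber
beneficial ones, as in empirical scans); out-of-bounds draws are redrawn
rather than clipped, to avoid artificial point masses at the bounds. The
log-normal input count scale parameter (`input_log_sd = 0.4`) is read as the
standard deviation of the underlying normal — a count-scale SD of 0.4 reads
would be meaningless — and the location is set so the log-normal mean equals
990; since counts are rescaled to fill the population exactly, only the
shape parameter matters.

A binding round draws survivors $k_v \sim \mathrm{Binomial}(c'_v, p_v)$. A
growth round of duration $\Delta t = \delta \ln 2/\mu_{wt}$ draws the
post-growth count from the negative binomial with $r = c'_v$ and
$p = e^{-\mu_v \Delta t}$, *taken literally as the drawn count* (support
from 0, mean $c'_v(e^{\mu_v \Delta t} - 1)$). The alternative reading —
pure-birth growth, i.e. the founders plus that draw, mean
$c'_v e^{\mu_v \Delta t}$ — was implemented and compared during development:
the literal draw gives the better end-to-end score recovery for growth
selections (the acceptance script computes it, $r^2 \ge 0.992$ against
predicted scores at reference conditions), and it is also what a standard
negative-binomial sampler produces when called with exactly the stated
parameters. Its per-round
wild-type expectation is $e^{\delta\ln 2} - 1 = 3$, not $2^\delta = 4$; the
discrepancy is absorbed by the wild-type normalization except for a mild,
monotone curvature in the score–effect relationship, which is also why the
growth recovery $r^2$ sits slightly below the binding one. After each round
the population is restored to exactly $10^7$ by multinomial resampling, and
sequencing is a multinomial draw of $2\times10^6$ reads per timepoint.

Expected ("predicted") scores under the regression model are
$\beta'_v = (\max T)\,\ln(p_v/p_{wt})$ for binding. For growth the natural-
log slope on the normalized time axis is $m\,\delta\,\ln 2\,(\mu_v -
\mu_{wt})/\mu_{wt}$; the same quantity per wild-type doubling in log2 units,
$m\,\delta\,(\mu_v - \mu_{wt})$, is emitted alongside
(`predicted_per_doubling`) since both conventions appear in the literature
and they differ only by a constant factor — correlation-based validation is
identical under either.

Two noise processes mimic common artifacts. *Replicate-effect noise*
resamples the true effect of 10% of non-wild-type variants in exactly one
replicate each (2% of the library per replicate), modelling cloning errors
and replicate-specific biology; the induced between-replicate disagreement
should — and does — surface as a large combined standard error whose
magnitude tracks the size of the effect change. *Jackpot noise* multiplies
or divides one randomly chosen (replicate, timepoint) population count by 50
for 5% + 5% of variants before the sequencing draw, modelling PCR
jackpotting; it is applied to the sequencing weights only, so it perturbs
one observation rather than the selection trajectory.

All randomness flows from one master seed, which spawns one independent
stream per replicate, so replicates are exchangeable and a configuration
reproduces byte-identical datasets.

### What the simulator does and does not establish

The simulator reproduces the sampling structure of a real scan (selection
noise, bottleneck resampling, finite sequencing depth, two artifact types)
but idealizes everything else: effects are constant through time (constant
selection pressure), amplification is uniform across variants, sequencing
errors and index hopping do not exist (counts are simulated directly, not
reads), and binding/growth effects map to scores through the stated model
itself. Passing validation therefore demonstrates that the estimator
recovers the generative model's truth at realistic noise levels — it cannot
certify accuracy on real data where the generative assumptions (constant
pressure, shared non-linearity, Poisson counts) may fail; those failures are
designed to surface as large standard errors rather than remain invisible.

## Numerical and testing choices

Validation problem sizes: end-to-end recovery and noise studies run at the
full reference conditions above (10,000 variants × 5 rounds × 5 replicates ×
2 assays); solver-equivalence suites use 1,000 random regression instances
and hundreds of random replicate sets with $n \le 5$; the fixed-point/REML
comparison runs the fixed point to convergence (the 50-iteration production
default is an engineering truncation, flagged via $\varepsilon_s$, not a
different estimator). Unit tests use a scaled-down configuration (301
variants, 3×10⁵ population, 100 reads/variant, 3 rounds × 3 replicates)
where only qualitative behaviour is asserted.

Degenerate inputs are handled explicitly rather than by numerical accident:
zero read totals are an error naming the offending timepoint; an empty
present-everywhere set makes the filtered library size 0 with a warning;
variants with fewer than two usable replicates are reported `NA`; zero
standard errors propagate as exact statements (p-value 0 or 1, flagged
degenerate). Scores and standard errors are computed in closed form from the
weighted normal equations — no iterative fitting is involved per variant —
and the test suite pins them to R's generic solvers at $10^{-10}$ relative
tolerance.
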