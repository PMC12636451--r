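---
title: "Models and methods behind flymetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flymetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flymetab)
```

flymetab implements the four quantitative layers that fly
neurodegeneration-and-aging studies combine — lifespan decomposition,
single-neuron ATP/ADP trace analysis, tissue-level flux assays and a
transcriptome summary layer — together with generators that produce
data with exactly the statistical structure each layer assumes. This
vignette explains the models, the parameters that matter, the numerical
choices, and what the synthetic data do and do not establish about
real recordings.

## 1. Gompertz mortality decomposition

Mortality is modelled as $h(t) = \alpha e^{\beta t}$: $\alpha$ (per
day) is the hazard at the time origin — adult eclosion, when cohorts
are collected — and $\beta$ (per day) the exponential rate at which
risk grows with age. Separating the two matters because median or
maximum lifespan conflates them: an insult can shorten life by raising
the floor ($\alpha$) or by accelerating aging itself ($\beta$), and
only the decomposition distinguishes these.

**Census coarsening.** Deaths are observed only at vial transfers
(default cadence 3.5 days, i.e. twice weekly, at most 15 flies per
vial). `impute_event_times()` expands each death to a representative
time of its census interval. The default is the interval midpoint: at
this cadence the midpoint leaves at most 1.75 days of systematic error
on any single fly and essentially none on average, whereas the right
endpoint biases all times late by half an interval. The right-endpoint
rule is available for sensitivity analysis; both are exercised in the
tests.

**Likelihood.** With death indicator $d_i$ and right-censored times
$t_i$, the log-likelihood is
$\sum_{d_i=1} (\ln\alpha + \beta t_i) - \sum_i H(t_i)$ with cumulative
hazard $H(t) = (\alpha/\beta)(e^{\beta t} - 1)$. The code writes
$H(t) = \alpha t \, g(\beta t)$ with $g(x) = (e^x-1)/x$ and evaluates
$g$, $g'$, $g''$ by series below $|x| = 10^{-4}$, so the exponential
submodel $\beta \to 0$ is reached continuously (the suite checks
agreement with the exponential log-likelihood to $10^{-6}$ at
$\beta = 10^{-8}$). Optimization is quasi-Newton (L-BFGS-B) on
$(\ln\alpha, \ln\beta)$ with the analytic gradient and a Nelder–Mead
fallback, initialized from the OLS fit to the log empirical hazard.
Standard errors come from inverting the *analytic* observed
information at the optimum; a fit is flagged unconverged when the
optimizer fails and the scaled gradient is not at numerical noise, or
when the information matrix is not usable.

**Hazard diagnostic.** Because $\ln h(t)$ is linear in $t$ under the
model, `empirical_hazard()` smooths Nelson–Aalen increments with an
Epanechnikov kernel (left-boundary reflection at $t = 0$; automatic
global bandwidth $1.06\,\mathrm{sd}\,n^{-1/5}$, user-overridable) and
`loghazard_linearity()` regresses $\ln h$ on $t$ after trimming 10% of
the grid at each end and any nonpositive hazard values — kernel
estimates at the boundary are biased and would otherwise dominate the
fit. A cohort of a few hundred flies typically yields $R^2 \ge 0.9$
when the data are genuinely Gompertz; the suite reproduces this at
$n = 300$, $\alpha = 0.002$, $\beta = 0.08$ over 50 seeded replicates.

**Comparisons.** Genotype pairs are compared by Wald z-tests on one
parameter at a time, with Holm adjustment applied separately within
the $\alpha$ family and the $\beta$ family (all pairwise comparisons).
The diagnostic slope and the MLE $\hat\beta$ agree within 20% on large
cohorts, which the suite asserts as a consistency property.

## 2. ATP/ADP trace correction and integrated change

The PercevalHR excitation ratio (488/405 nm) tracks the ATP:ADP ratio
but is confounded by photobleaching and by cytosolic pH. The
processing chain is:

1. **Background subtraction**: a cell-free ROI's intensities are
   subtracted per channel; timepoints whose denominator falls to or
   below background are masked rather than producing wild ratios.
2. **Baseline normalization**: $A e^{-kt}$ ($k \ge 0$) is fitted to
   the premix ratio (log-linear fit refined by `nls`; constant
   fallback is flagged), the whole trace is divided by the
   extrapolated fit, and the premix mean is pinned at exactly 1. A
   single exponential absorbs both bleach and baseline level; separate
   per-channel bleach models are not identifiable from ROI-level
   ratios, so the correction is applied on the ratio.
3. **pH correction**: the terminal NH₄Cl pulse perturbs pH alone, so
   within that window the sensor deviation is a linear function of the
   pHrodo deviation (both measured from the mean of the 30 s before
   onset, window configurable). The fitted slope corrects the whole
   trace: corrected = normalized − slope × pHrodo deviation.
   Calibration is per-ROI by default with a pooled fallback when a
   ROI's NH₄Cl response is degenerate (e.g. zero pHrodo variance) —
   pooling trades ROI-specific accuracy for robustness.
4. **Counterfactual baseline**: a Gaussian local-level + trend
   state-space model (`StructTS`, variances by ML on the pre-treatment
   window) is projected over the treatment window with a pointwise 95%
   band forced nondecreasing in width; a deterministic OLS linear
   trend with its prediction band is the fallback and an explicit
   option. Any model producing an extrapolated mean and band satisfies
   the downstream contract; the state-space choice keeps the package
   free of heavier Bayesian structural-time-series machinery while
   behaving identically where it matters (level + drift + widening
   uncertainty).
5. **Integrated change**: trapezoidal AUC of (trace − baseline) from
   treatment to washout, divided by the window length — an average
   deflection per unit time, comparable across recordings of different
   lengths. Group comparisons use Mann–Whitney tests and
   order-statistic 95% CIs for medians, appropriate for the skewed,
   outlier-prone per-ROI values.

The generator composes artifacts as
(1 + deflection + coupling × pHrodo deviation + noise) × bleach
envelope. Placing the pH artifact inside the envelope (on the
normalized scale) is the composition under which an exact linear
calibration exists even when the NH₄Cl pulse arrives late in a
strongly bleached recording; with artifacts outside the envelope no
single slope could be exact, contradicting the linearity the
correction protocol relies on. The pHrodo channel idles at 1 AU and
the pulse rises with a ~15 s time constant and decays with ~90 s, so
deviations vary within the window and the calibration regression is
well posed.

What the synthetic traces do **not** model: photon shot noise,
segmentation error, focal drift, or saturating sensor kinetics.
Passing tests therefore demonstrate correctness of the arithmetic and
the statistical machinery under Gaussian noise, not robustness to
imaging pathologies.

## 3. Flux metrics by random-intercept mixed models

Seahorse-style plates repeat measurements within wells across
injection phases, with whole plates run in batches. All metrics are
estimated through `response ~ fixed + (1|well) + (1|batch)` fitted by
REML (ML available), with single-level random factors dropped with a
warning and zero-boundary variance components flagged. Estimated
marginal means are equally weighted fixed-effect cell predictions, so
in balanced designs they equal raw cell means, and metrics are EMM
differences on the phase codings used in the field:

* glycolytic reserve = EMM(post rotenone+antimycin ECAR) −
  EMM(baseline ECAR), basal = all pre-injection cycles, maximal = all
  post-rotenone/antimycin, pre-2DG cycles;
* maximal ECAR modelled within the rotenone+antimycin phase with
  genotype as the only fixed effect;
* post-2DG decline = genotype-specific slope on centred time;
* ATP-linked respiration = EMM(baseline) − EMM(post-oligomycin) OCR;
  respiratory reserve = EMM(post-FCCP) − EMM(baseline); peak capacity
  = EMM(post-FCCP) − EMM(post rotenone+antimycin).

**Inference reference.** Contrasts are tested against a Satterthwaite
t reference (via lmerTest), not a plain normal. This was a genuinely
open choice: the normal reference is simpler, but desk-scale plates
carry few well-level degrees of freedom and the normal is
anticonservative there — with a handful of wells per genotype the
effective reference is a t with single-digit df, for which
$P(|t| > 1.96)$ is well above 5%. The Satterthwaite t reference
passes the suite's 1,000-replicate null calibration check on a
deliberately small design; the statistic and the df used are reported,
and the code falls back to z only when the df computation itself
fails. Negative variance estimates are truncated
at zero with a boundary flag, standard for REML.

The simulation sizes used by the suite were chosen to give each
check adequate resolution: the variance-recovery benchmark uses 24
wells across 8 batches (a 2-batch design leaves one degree of freedom
for the batch component, whose REML estimate is then uninformative —
no estimator recovers it reliably), while the type-I calibration uses
a deliberately small 4-wells-per-genotype, 2-batch design where
batch and well effects cancel in the reserve contrast.

## 4. Transcriptome summaries

TPM follows the standard two-step normalization: RPK = count/(length
in kb), TPM = RPK/ΣRPK × 10⁶ per sample, so each sample sums to one
million and depth scaling cancels exactly. PCA/k-means QC removes
genes with zero expression in all samples, z-scores each remaining
gene (constant genes are dropped as zero-variance), projects samples
by PCA and labels them by k-means with a fixed seed and 50 restarts.

The dual-control DEG intersection takes two per-contrast tables
(log2FC, p, BH-adjusted p), keeps genes with padj < 0.05 in both
(strict inequality: a gene at exactly 0.05 is non-significant), and
retains only directionally concordant genes in the high-confidence
set. Over-representation uses the 2×2 table over a configurable
universe (default: the genes present in the DEG tables), two-sided
Fisher p, and the *sample* (cross-product) odds ratio ad/bc — the
estimate reference worked counts reproduce — with a Haldane 0.5
correction applied, and flagged, only when a cell is zero. Scores are
OR × −log₁₀(padj) after BH adjustment across the collection of sets;
ranking is by descending score with ties broken by smaller padj, then
larger overlap.

DE testing itself is out of scope: `de_stub()` (Welch t on
log2(TPM+1) with BH) exists solely so synthetic end-to-end runs are
possible and is labelled as such; it is not a negative-binomial DE
method and should not be used on real counts. Ortholog maps are
ingested as from/to/confidence tables with a user-chosen confidence
cutoff, since no universal threshold exists.

## 5. Synthetic-data generators

Each generator emits exactly the structure its consumer assumes, with
one private RNG stream seeded explicitly (the caller's RNG state is
restored; two runs with one seed are bit-identical):

* **Lifespans** are drawn by inverse-CDF from
  $S(t) = \exp(-(\alpha/\beta)(e^{\beta t}-1))$, assigned round-robin
  to vials of ≤ 15, and binned to the census grid, recording the
  interval right endpoint as the census day. Cohorts default to 100
  flies per genotype — a realistic fly-room cohort and enough for
  stable (α, β) estimates; cohort sizes are rarely reported per
  genotype in publications, so this is the package's own default.
* **Traces** use the composition described in section 2, with default
  event times mirroring a typical protocol (2 min baseline, 6 min
  treatment, 2 min washout, 2 min NH₄Cl).
* **Flux plates** add well, batch and residual Gaussian intercepts to
  genotype×phase means; `default_flux_means()` encodes a
  control-vs-insult contrast (reduced glycolytic reserve via elevated
  basal ECAR, reduced maximal OCR) in typical instrument units.
* **Counts** are negative-binomial with log-normal baseline means, a
  configurable DEG fraction with N(0, lfc_sd) effects (optionally
  bounded away from zero for recovery benchmarks), and ground-truth
  direction labels for concordance tests.

## 6. Numerical choices and degenerate inputs

* Gompertz: series evaluation of $g$, $g'$, $g''$ below
  $|x| = 10^{-4}$; optimizer box $\ln$-scale bounds at ±30; all-equal
  death times are rejected; non-convergence is reported, not hidden.
* Hazard: at least 10 deaths required; bandwidth must be positive;
  hazard clipped at 0.
* Traces: ratios with nonpositive denominators are masked with a
  warning and fully masked traces are errors; premix fits need ≥ 5
  points, counterfactuals ≥ 10 pre-treatment points; zero pHrodo
  variance in the calibration window is an error (per-ROI scope falls
  back to pooled calibration in the pipeline wrapper).
* LMMs: singular fits are tolerated (boundary flag) because zero
  variance components are legitimate; the Satterthwaite step falls
  back to z if it fails.
* Multiple testing is delegated to `stats::p.adjust`; the suite pins
  both Holm and BH against brute-force implementations of their
  step-down/step-up definitions on 1,000 random vectors.

## 7. Orchestration

`run_pipeline()` executes the stages in dependency order from a single
config (YAML or list) with one root seed, writes per-stage CSV/TSV
outputs, and emits a JSON manifest with the package version, config
checksum, seeds, per-file md5s, timings and accumulated warnings.
Missing upstream inputs produce an error naming the stage. The
pipeline adds no computation of its own, and every stage can be run
standalone through its module functions — those functions, together
with `make_fixtures()` for the toy datasets, are the package's
command surface; no shell wrapper is shipped because the intended
users drive analyses from R.

## Known limitations

* The interval-censored likelihood is approximated by representative
  event times; at much coarser census cadences than 3.5 days a full
  interval-censored likelihood would be preferable.
* The counterfactual band assumes Gaussian innovations; heavy-tailed
  recording artifacts will under-cover.
* EMM weighting is balanced-population; severely unbalanced plates
  with interaction structure will make EMMs differ from raw means.
* The enrichment layer assumes a fixed, correctly specified universe;
  results shift with the universe choice, which is therefore exposed
  as an argument rather than fixed internally.
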