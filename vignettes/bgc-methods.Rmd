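---
title: "Between-network global connectivity and symptom severity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Between-network global connectivity and symptom severity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcnet)
```

## The scientific question and the statistic

Resting-state functional connectivity (FC) between two cortical parcels is
the Pearson correlation of their BOLD time series. Classical "global brain
connectivity" summaries (the mean FC of a region to all others) are biased
by network size: regions in large networks accumulate strong within-network
edges by construction. Between-network global connectivity (BGC) removes
that bias by averaging only out-of-network edges. For region $i$ in network
$C$,

$$\mathrm{BGC}_i \;=\; \frac{\sum_{j \notin C} W_{ij}}{N_{total} - N_C},$$

where $W_{ij}$ is the FC estimate between regions $i$ and $j$, $N_{total}$
the total region count and $N_C$ the size of $i$'s network. Network-level
BGC is the unweighted mean of $\mathrm{BGC}_i$ over the network's regions.
The package's scientific target is the association between network-level
BGC — especially of the fronto-parietal control network (FPN) — and
depression-symptom severity measured with the 20-item CES-D, in an
undiagnosed population sample.

Two algebraic facts anchor the implementation and are asserted to `1e-12`
in the tests: network BGC equals the $N_D$-weighted mean of the pairwise
between-network mean FCs, and connection-exclusion BGC with an empty
exclusion set is identical to the plain network BGC. FC weights enter the
averages as raw Pearson $r$, not Fisher-transformed values: the statistic
is defined directly on the FC estimates, and typical network means sit
near zero where the transform is immaterial anyway.

## Preprocessing

Each subject's parcellated series passes through a fixed, logged order:
framewise displacement (FD) → low-pass of the FD trace → scrub mask →
nuisance regression on retained frames.

* **FD** is the L2 norm of the six frame-to-frame motion-parameter
  differences ("Euclidean distance", as opposed to the more common L1
  variant), with rotations converted to arc length on a 50 mm sphere — the
  field's conventional radius, the method description being silent on it.
  `fd[1] = 0` since the first frame has no predecessor.
* **FD low-pass** (default 0.3 Hz) suppresses respiration-band fluctuation
  before thresholding. It is realized as an order-2 Butterworth applied
  forward and backward (zero phase), since only the cutoff is part of the
  method definition. We apply it with odd-reflection end padding so a
  constant trace passes through exactly; filtered values are clamped at 0
  because FD is a magnitude and a zero-phase filter can undershoot next to
  a spike. A cutoff at or above Nyquist is a hard error, never a silent
  pass-through.
* **Scrubbing** censors every frame whose filtered FD exceeds 0.3 mm,
  plus one frame prior and two following, windows clipped at the series
  boundaries.
* **Nuisance regression** uses an intercept plus 17 regressors: the six
  rigid-body estimates and their first differences (the "12 motion
  parameters" — the standard reading of that phrase), ventricle and
  white-matter signals with their first differences, and the global
  signal. The global signal's derivative is excluded: the derivative
  clause in the method description attaches to the tissue signals.
  First differences are backward differences with first element 0,
  computed *before* censoring so gaps cannot corrupt them; the
  least-squares fit then uses retained frames only (censor-then-regress —
  the order is not dictated by the method description, so it is fixed here
  and logged). Rank deficiency is an error naming the collinear columns.

Subjects are never excluded for motion beyond frame censoring, but a
configurable floor on retained frames (default 200) drops subjects whose
FC estimate would be degenerate; drops are warnings and appear in the
scrub summary.

## Symptom scoring and normalization

CES-D items are scored 0–3 with the standard four reverse-worded items
(4, 8, 12, 16) scored $3 - \text{response}$; the total ranges 0–60. Three
factor sub-scores (somatic, negative affect, anhedonia) follow the
three-factor literature; since the exact item map is not part of the
method description, the default map — somatic {1,2,5,7,11,13,20}, negative
affect {3,6,9,10,14,15,17,18,19}, anhedonia = the reverse items — is a
documented, configurable decision. The laterality quotient is
$100 \times \sum \text{scores} / 22$ over 11 handedness items.

Totals are gated through a one-sample Kolmogorov–Smirnov test
(standardize, then test against N(0,1) without Lilliefors correction —
the common default, flagged here as anti-conservative) and normalized with
a Box–Cox power transform: $\lambda$ chosen by profile maximum likelihood
on the grid $[-5, 5]$ in steps of 0.01, with a $+1$ shift because the
CES-D minimum is 0. The transform is monotone, so Spearman analyses are
unaffected by it.

## Inference

* Pearson and Spearman correlations use the t approximation
  $t = r\sqrt{(n-2)/(1-r^2)}$ with two-tailed p; Spearman is Pearson on
  average ranks (the t approximation, not exact permutation, matches the
  printed rho→p pairs at n = 96).
* Partial correlations rank-transform all variables, residualize on the
  covariates plus intercept, and correlate the residuals with $n - 2 - k$
  df; a `method = "pearson"` switch skips the rank step.
* Comparison of two correlations uses the independent-samples Fisher-z
  formula even when the correlations share subjects. This reproduces the
  reported comparison exactly; a dependent-correlations test would need
  the unreported correlation between the two measures. The choice is
  documented in the function help.
* BH-FDR families are never pooled: the network-level table is one family,
  the region-level table another. The a-priori network's uncorrected p is
  a reporting convention handled in the report, not in the math.
* Residualization for the age/gender control encodes gender as a single
  binary indicator and always includes an intercept.

## The synthetic cohort

No subject-level data are distributable, so the generator produces
cohorts carrying exactly the statistical structure the analysis assumes:

* **BOLD**: frames drawn i.i.d. (optional AR(1)) from a zero-mean
  multivariate normal whose correlation matrix has within-network blocks
  $w_k$ (default 0.3), baseline between-network entries $b$ (default
  0.05), and the effect network's cross-network entries set to the
  subject's realized coupling
  $b_j = b + \beta s_j + \varepsilon_j$, where $s_j$ is the subject's
  standardized latent severity. I.i.d. frames keep the oracle tests exact,
  and correlations are autocorrelation-robust in expectation. If the
  target matrix is not positive definite it is repaired by clipping
  eigenvalues at $10^{-6}$ and rescaling to unit diagonal — the smallest
  intervention preserving block structure — and the repair errors if any
  entry moves by more than 0.05.
* **Global signal**: a shared component scaled by `global_amp` (default
  0.4) is added to every region; the recorded nuisance signals are noisy
  mixtures of it (ventricle, white matter) and the region mean (global),
  so global-signal regression is genuinely exercised. With mixing enabled,
  raw FC does not match the block targets until regression removes the
  shared component; covariance-fidelity tests therefore run with
  `global_amp = 0`.
* **Motion**: smooth sinusoidal drift far below threshold plus isolated
  1 mm single-frame translation spikes at rate `motion_spike_rate`
  (default 0.02/frame); the spike amplitude keeps filtered FD above the
  0.3 mm threshold, and the designed spike frames are returned so
  scrubbing can be tested against ground truth.
* **CES-D items**: a graded-response model (logistic category curves with
  per-item loadings and shared thresholds −0.3, 1.0, 2.0) whose expected
  total is strictly increasing in severity; thresholds were set so a
  standard-normal severity population gives totals with mean ≈ 17–19 and
  SD ≈ 9–11, the range typical of undiagnosed young adults. Reverse items
  are stored inverted so scoring has something real to undo.
* **Demographics**: balanced binary gender and age uniform on 18–35,
  matching the shape needed by the residualization control.

### Calibrating the planted effect

The only effect-size anchor available is the observed network-level
association of roughly $r = -0.25$ at the study scale, so the generator
treats that as the default planted *population* effect — a modeling
choice, not a constraint. Because the measured correlation is attenuated
by FC estimation noise, CES-D measurement error and coupling noise,
`effect_beta` cannot be written down analytically. It was calibrated
once, before the acceptance tests were written, by a parameter-recovery
sweep at the scaled geometry (n = 2000 subjects): betas
{−0.003, −0.0042, −0.006} gave measured r {−0.144, −0.212, −0.307};
linear interpolation to −0.25 gave $\beta = -0.0049$, verified at
r = −0.250 and −0.263 on two fresh seeds and frozen as the default with
`coupling_noise_sd = 0.01`. Attenuation differs slightly at the
full-scale geometry (more frames and regions average away more estimation
noise), which is one reason recovered values scatter around the target.

Because the planted effect perturbs the effect network's couplings to
*all* other networks, companion networks' BGC also correlates with
severity (their out-of-network averages include edges to the effect
network) — the same entanglement the connection-exclusion and
between-network-FC controls exist to probe, which makes the synthetic
cohort a fair rehearsal of those controls.

## Problem sizes and determinism

Routine tests use the scaled geometry — 4 networks × 15 regions,
600 frames, cohorts of 10–96 subjects — chosen to preserve every code
path while keeping a full suite run to a few minutes. The
parameter-recovery check uses 500 subjects; the null calibration check
pools 200 seeded 40-subject cohorts (the per-network uncorrected
false-positive rate does not depend on cohort size). Every generator
output is a pure function of the config seed, per-subject seeds being
drawn deterministically from it, and two pipeline runs under the same
config produce byte-identical report tables.

## What passing tests do and do not show

The generator emulates second-order structure (block correlations, a
shared global component, motion spikes, ordinal item responses), not real
BOLD physiology: no hemodynamic response, no spatially structured noise,
no physiological spectra, no site or scanner effects, and i.i.d. frames
by default. Passing recovery tests therefore demonstrates that the
pipeline measures what it claims on data satisfying its assumptions — not
that those assumptions hold in any particular empirical dataset. The KS +
Box–Cox stage is likewise only lightly exercised: synthetic totals are
mildly skewed, and at many seeds pass the normality gate even before
transformation.

## Known limitations

* The KS gate without Lilliefors correction is anti-conservative;
  printed-era compatibility was preferred over strictness, and the choice
  is flagged in the docs.
* The independent-samples Fisher-z comparison ignores the dependence
  between BGC and within-network FC computed on the same subjects.
* The exact three-factor item map and the per-network parcel counts of
  the full partition are configurable defaults, not ground truth.
* Connection-exclusion and between-network controls are defined for a
  trio of networks (effect network plus two companions); other exclusion
  patterns are available through `bgc_excluding()` directly.
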