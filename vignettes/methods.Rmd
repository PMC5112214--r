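---
title: "Estimating cochlear gain reduction from temporal masking curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cochlear gain reduction from temporal masking curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moctmc)
```

## The model

The active cochlear amplifier boosts the response to low-level sounds and
compresses the response growth at intermediate levels. `moctmc` represents
the input--output (IO) function of a cochlear place by a piecewise-linear
"tip" response in dB: unit slope below a lower break point $BP_1$, slope $c$
(the compression exponent, $0 < c \le 1$) between $BP_1$ and an upper break
point $BP_2$, and unit slope again above $BP_2$. The level-dependent gain is

$$G(L) = \max\{\min\{(c - 1)(L - BP_1) + G_{\max},\, G_{\max}\},\, 0\},$$

so the three parameters are mutually constrained by
$G_{\max} = (1 - c)(BP_2 - BP_1)$. The package stores $(G_{\max}, c, BP_1)$
and derives $BP_2$; the center of the compressive range
$BP_{ctr} = (BP_1 + BP_2)/2$ is exposed for reporting because it is the
quantity that shifts the compressive section of a temporal masking curve
(TMC) along the gap axis independently of its slope. An off-frequency masker
(well below the probe frequency) drives the place through its passive "tail"
response, modelled as the input level minus a constant attenuation $P$
(allowed to be negative).

Forward-masking thresholds follow from three assumptions: the signal is
detected when its response equals $k$ times the residual masker effect
($k$ in linear intensity units); the masker effect decays at $\mu$ dB/ms
over the masker--signal gap $t$; and the signal (level $L_s$) and
on-frequency masker pass through the tip function while the off-frequency
masker passes through the tail. The required masker *output* in dB is then
$f_a(L_s) - 10\log_{10} k + \mu t$, mapped back through the inverse tip
(on-frequency) or tail (off-frequency) function. Two geometric consequences
anchor the method: the off-frequency TMC is a straight line of slope $\mu$,
and the on-frequency TMC has local slope $\mu$, $\mu/c$, $\mu$ in the three
regimes. A contralateral elicitor of the medial olivocochlear (MOC) reflex
is modelled as reducing $G_{\max}$ by $\Delta G$ with the break points held
fixed, which forces the with-elicitor compression exponent to
$\tilde c = 1 - (G_{\max} - \Delta G)/(BP_2 - BP_1)$, clamped at 1 because
the effective gain cannot fall below zero. $\Delta G$ itself is
sign-unconstrained. The competing explanation — direct excitatory masking of
the signal by the elicitor — is implemented by `apply_excitatory_masking()`,
which scales $k$; it shifts both TMCs down equally and leaves the inferred
IO function unchanged, which is exactly what distinguishes it from a gain
reduction.

## Units and conventions

Levels are dB SPL throughout; gaps are ms between the $-3$-dB points of
masker and signal. The masker-effect decay is implemented as division of
intensity by $10^{\mu t / 10}$, so thresholds in dB rise at exactly $\mu$
dB/ms, matching the convention in which $\mu$ is reported in dB/ms and
equals the off-frequency TMC slope. $k$ enters thresholds as
$-10\log_{10} k$ dB. The constructor rejects $c < 10^{-3}$ to keep the
inverse tip function well conditioned. The signal level is treated as fixed
across the with- and without-elicitor conditions, as in the experimental
protocol the package models.

## Fitting

`fit_tmc_baseline()` minimizes the summed squared deviation between all
observed and predicted without-elicitor thresholds (on- and off-frequency
together) over $(G_{\max}, c, BP_{ctr}, k, \mu, P)$, using bounded
Levenberg--Marquardt least squares from a fixed 27-point multistart lattice
(3 levels each of $G_{\max}$, $c$, $BP_{ctr}$, central $k$, $\mu$, $P$).
Bounds are generous supersets of values reported for normal-hearing adults:
$G_{\max} \in [0, 60]$ dB, $c \in [10^{-3}, 1]$,
$BP_{ctr} \in [10, 90]$ dB SPL, $k \in [0.05, 20]$,
$\mu \in [0.01, 3]$ dB/ms, $P \in [-20, 60]$ dB. Function and parameter
tolerances are $10^{-10}$ with at most 2000 evaluations per start; ties are
broken by lattice order, so refitting identical data gives identical
results. Without off-frequency rows $P$ is not identifiable and is fixed at
a configurable value (default 20 dB) and flagged.

`fit_tmc_elicitor()` then varies only $\Delta G \in [-30, 60]$ dB on the
with-elicitor rows, with all other parameters carried over. The
one-dimensional SSE profile is localized on a 0.25-dB grid and polished by
Brent's method. Because the gain floors at zero, the SSE is exactly flat for
$\Delta G \ge G_{\max}$; the boundary value is reported there (the smallest
equivalent gain reduction), which is also how published tables behave where
the printed $\Delta G$ equals $G_{\max}$.

### Identifiability and its resolution

A structural property of the model deserves emphasis: the signal and the
on-frequency masker receive the *same* gain, so $G_{\max}$ cancels out of
the on-frequency predictions except through the location of the break
points. If the sampled masker-output range never crosses the lower knee of
the tip function, $(G_{\max}, BP_1)$ trade off exactly (along
$dG_{\max} = -(1 - c)\,dBP_1$) with bit-identical predictions; if it never
crosses $BP_2$, $(G_{\max}, P)$ trade off. Real TMC designs often miss the
lower knee — short maskers are inefficient and push thresholds up — so the
baseline fit can terminate anywhere on an exactly flat SSE valley.

The with-elicitor condition breaks these ties: the off-frequency threshold
drop pins the gain reduction at the signal place, and the with-elicitor
compressive slope $\mu/\tilde c$ pins the remaining freedom. The package
therefore keeps every SSE-tied multistart solution as a candidate and, in
`fit_tmc_elicitor()`, runs a multistart weighted joint fit (baseline
residuals weighted 300:1) over the baseline parameters and $\Delta G$.
Solutions that would degrade the without-elicitor SSE beyond a small
tolerance are discarded, so the sequential logic — the baseline fit is
determined by the baseline data — is preserved; the with-elicitor data only
resolve directions the baseline data genuinely do not determine. Reported
parameter tables use these resolved values. In simulation this step reduces
the median absolute error of the recovered $G_{\max}$ by roughly half
relative to reporting the raw baseline solution.

## The synthetic-data generator

`population_spec()` draws subjects with uniform marginals bracketing the
spread reported for normal-hearing adults at 2 kHz: $G_{\max}$ 13--36 dB,
$c$ 0.05--0.65, $BP_{ctr}$ 37--53 dB SPL, $k$ 0.69--3.0, $\mu$ 0.12--0.97
dB/ms, $P$ 11--35 dB, $\Delta G$ $-1$ to 22 dB, and quiet thresholds of
18--28 dB SPL with the signal presented 10 dB above them. Joint draws whose
lower break point falls below the signal level are rejected: presenting the
signal at a low sensation level so that it receives the full gain is the
TMC method's own design premise, and without it the elicitor effect is
provably not identifiable from the design (the flat direction described
above extends through the with-elicitor condition). A side effect of this
constraint is a negative correlation between sampled $G_{\max}$ and $c$ —
the same tendency reported in fitted cohorts. A drawn $\Delta G$ above
$G_{\max}$ is retained but has no physical effect beyond flooring the gain
at zero, so recovery is always assessed against the effective gain
reduction $\min(\Delta G, G_{\max})$.

Thresholds are produced by simulating the three-interval 3-AFC adaptive
procedure: a two-up one-down masker track (10, 5, 2.5-dB steps keyed to the
first, second and remaining ten of 12 reversals; estimate = mean of the
last ten reversal levels), six estimates per condition, and selection of
the subset of three or more estimates with minimum standard error (ties
toward the larger subset, then lexicographic order; subsets are arbitrary,
not contiguous). The observer answers according to a logistic psychometric
function of level in dB with chance 1/3 and midpoint at the true threshold;
the slope parameter doubles as the observer-noise setting (0 gives an
idealized deterministic observer with no guessing, and the generated table
then equals the model predictions exactly). Tracks start 20 dB above the
true threshold so the early 10-dB steps are exercised. The two-up one-down
rule converges on the 70.7 %-correct level, which for this psychometric
sits $0.244 \times \mathrm{slope}$ dB from the midpoint — about 0.5 dB at
the default slope of 2 dB; this offset is common to all conditions and is
absorbed by $k$ in the fit.

What the generator does not emulate: middle-ear-muscle contamination,
attention or session-order effects, across-gap threshold correlations, and
any mechanistic cochlear dynamics. Passing recovery tests therefore shows
that the estimation chain inverts the model it assumes under realistic
tracking noise — not that the model is correct for real ears.

## Group statistics

`enumerate_bootstrap()` enumerates all $\binom{2N-1}{N}$ multisets of size
$N$ drawn from the $N$ subject values (1,352,078 at $N = 12$, enumerated in
compiled code) and weights each by its multinomial coefficient — the exact
iid bootstrap. Only this weighting makes the distribution of resample means
have exactly the sample mean as its mean and the population standard
deviation over $\sqrt N$ as its standard deviation, which is what the
closed-form Gaussian description `fit_gaussian()` reports.
`fit_nakagami()` fits the positively skewed Nakagami density by weighted
maximum likelihood on the strictly positive resample means (the excluded
probability mass is reported); since $x^2$ is Gamma-distributed, the ML
equations reduce to the Gamma shape equation, solved by bracketed root
finding — no iterative optimizer. Regression slopes take their confidence
intervals from the same exhaustive resample distribution over $(x, y)$
pairs, excluding degenerate resamples with fewer than two distinct $x$
values. Percentiles use linear interpolation between order statistics;
weighted quantiles of bootstrap distributions use the inverse weighted
step-function ECDF.

One caveat found while validating against the published per-subject table:
the printed median for the $G_{\max}$ column equals the mean of the 5th and
6th order statistics rather than the conventional 6th/7th midpoint, unlike
every other column of the same row. The package computes the conventional
median; the table's other columns reproduce to the printed precision.

## CEOAE analysis

The click-evoked otoacoustic emission chain follows the measurement order:
second-order Butterworth band-pass (250--6000 Hz) applied forward and
backward for zero phase; windowing to 6--16 ms after the click with 2-ms
quarter-sine/cosine edges; then the amplitude as the square root of the
band-integrated co-spectrum (real part of the cross-spectrum) of the two
replicates, floored at zero. The root makes the quantity a linear pressure
amplitude so that the suppression index
$\Delta\mathrm{CEOAE}_n = 100\,(A_{without} - A_{with})/A_{without}$ is a
proportion of amplitude; the integration band is taken equal to the filter
band since no separate band is specified by the protocol. Using the
co-spectrum rather than a single replicate's power means uncorrelated noise
averages out of the amplitude estimate. Recordings are valid when the
replicate correlation ("reproducibility") exceeds 0.7. The synthetic
generator builds the emission as decaying tone bursts with latencies inside
the analysis window (longer latencies at lower frequencies), per-trial
microphone noise of 1 mPa scaled by $1/\sqrt{2000}$ through averaging —
calibrated so that reproducibility averages near 0.95 — and optional
artifact trials exceeding the 5-mPa rejection threshold.

## Problem sizes used in the test suite

The packaged tests run the recovery study at 100 simulated subjects with
observer noise 2 dB (about three minutes), noiseless recovery on a handful
of fixed-seed draws, 100 seeded CEOAE pairs, and full bootstrap enumeration
at $N = 12$. These sizes were chosen to make the Monte-Carlo standard error
of each checked mean comfortably smaller than the tolerance it is checked
against.

## Known limitations

Single-tone stimuli and symmetric single-parameter roex filters only in the
excitation module; no asymmetric roex variants or suppression between
components. Subjects are fit independently — no hierarchical pooling. The
reduced (on-frequency-only) elicitor design identifies $\Delta G$ only when
the baseline design samples all three response regimes; otherwise only the
full design does. Bootstrap enumeration is bounded at $N \le 14$
(memory grows as $\binom{2N-1}{N}$); a seeded Monte-Carlo fallback covers
larger cohorts.
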