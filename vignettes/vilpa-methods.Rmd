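---
title: "Methods: from wrist-accelerometer epochs to a mortality dose-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from wrist-accelerometer epochs to a mortality dose-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Vigorous intermittent lifestyle physical activity (VILPA) consists of brief
(up to 1-2 min) bursts of vigorous-intensity movement embedded in daily
living — a fast walk up a hill, a sprint for a bus — rather than structured
exercise. Wrist-worn accelerometers classified into 10-second epochs can
resolve these micro-patterns, and the epidemiological question is whether
more daily VILPA is associated with lower all-cause, cardiovascular (CVD)
and cancer mortality, and at what dose.

`vilpa` implements the full analytic pathway for that question as reusable,
tested components:

1. **Bout engine** — intensity classification, vigorous-bout detection,
   length standardization, wear-validity screening, daily exposure
   construction, percentile capping.
2. **Survival models** — restricted-cubic-spline dose-response in Cox
   proportional hazards (all-cause) and Fine-Gray subdistribution hazards
   (cause-specific, accounting for competing deaths), with landmark and
   prevalent-disease exclusions and the standard diagnostics.
3. **Dose-response outputs** — HR curves with pointwise 95% bands, the
   minimal dose (ED50), HRs at the median and maximum exposure, and
   E-values for unmeasured confounding.
4. **Synthetic cohort generator** — a seeded simulator of epoch series,
   covariates and competing-risks outcomes, so every stage can be validated
   end-to-end without access-controlled cohort data.

## Exposure construction

### Intensity and bouts

Each 10-s epoch arrives with an activity class (`sedentary`, `standing`,
`walking`, `running`, `sleep`, `nonwear`) from an upstream classifier —
training such a classifier is out of scope here — plus a mean acceleration
in milli-gravity (mg). Ambulatory epochs are graded **light** below 100 mg,
**moderate** from 100 mg, and **vigorous** from 400 mg; standing is light
and sedentary stays sedentary regardless of acceleration.

A **raw bout** is a maximal run of consecutive vigorous epochs within a
participant-day. Runs of up to 6 epochs (<= 1 min) and up to 12 epochs
(<= 2 min) are VILPA bouts under the two bout-length definitions (the 2-min
definition cumulatively includes the 1-min bouts); runs of more than 12
consecutive vigorous windows are long VPA sessions, excluded from VILPA but
carried as adjustment covariates (duration and frequency of bouts longer
than the chosen standard).

### Length standardization

Raw bouts vary in length, which both inflates collinearity between bout
frequency and daily duration and muddies interpretation. Frequencies are
therefore **length-standardized**: bout durations are accumulated in
temporal order, one analytic bout is scored whenever the running sum
reaches or exceeds the standard length (60 or 120 s) — the excess beyond
the threshold is discarded at each reset — and the terminal remainder is
scored fractionally. Five raw bouts of 20, 30, 20, 40 and 10 s at a 60-s
standard give 1.83 analytic bouts: the first three complete one bout
(70 s, 10 s discarded), the last two leave 50/60 = 0.83. Discarding the
excess is forced by that arithmetic; retaining it would give 2.0. The
rolling sum is scoped within each participant-day (bouts never cross
midnight; a run spanning midnight is split at the boundary) because the
exposure is built per day and then averaged.

Whether a day with no completed bout should still contribute its fractional
remainder is not decidable from the scoring rule alone; we retain
fractions, consistent with the worked example above.

### Wear validity and aggregation

A monitoring day is valid when wear time is strictly greater than 16 h; a
participant is analysable with at least three valid days including at least
one weekend day (Saturday/Sunday of the local timestamp; timestamps are
treated as local civil time). Daily durations and standardized frequencies
are computed per valid day and averaged over valid days. Exposures are then
winsorized at the 97.5th percentile (linear-interpolation definition) to
blunt the influence of the sparse upper tail. The capping step records its
thresholds: re-applying a recorded threshold changes nothing, whereas
re-estimating the percentile on already-capped data slides it marginally
below the cap (an interpolated percentile sits between order statistics),
so caps are estimated once, on the uncapped analysis sample.

## Survival modelling

### Exclusions and ordering

To limit reverse causation, participants whose **death** (any cause) occurs
within the first 2 years of follow-up are excluded; participants *censored*
early are retained, since censoring is not an event — the landmark rule is
read literally as applying to events. Cause-specific analyses additionally
drop participants with the corresponding prevalent disease at baseline.
The pipeline fixes the ordering as: exclusions, then capping, then knot
placement on the capped analysis sample — knots should describe the
exposure distribution actually entering the model.

### Spline dose-response

The exposure enters through a restricted cubic spline with three knots at
the 10th, 50th and 90th percentiles of the capped analysis-sample exposure.
With three knots the basis has two columns: the exposure itself and one
restricted cubic term

$$
C(x) \;=\; \frac{(x-k_1)_+^3 \;-\; (x-k_2)_+^3\,\tfrac{k_3-k_1}{k_3-k_2}
\;+\; (x-k_3)_+^3\,\tfrac{k_2-k_1}{k_3-k_2}}{(k_3-k_1)^2},
$$

cubic between the knots, linear beyond the boundary knots, with continuous
second derivative, and exactly zero below $k_1$ — so zero exposure is the
natural referent. The basis is scaled by the squared knot span to keep the
two coefficients on comparable scales. Tests verify the construction
against the equivalent `splines::ns()` model space (identical maximized
partial likelihood and fitted curve).

All-cause mortality uses Cox proportional hazards with Efron tie handling
(`survival::coxph()` performs the partial-likelihood maximization behind
the package's fitting surface). Cause-specific mortality uses the
Fine-Gray subdistribution hazards model, implemented via the
`survival::finegray()` weighted-data expansion followed by a weighted Cox
fit: competing-event participants stay in the risk sets with time-varying
weights from the Kaplan-Meier estimate of the overall censoring
distribution of the analysis sample (weights truncated below at $10^{-8}$).
When the data contain no competing events the subdistribution and
cause-specific hazards coincide and the fit falls back to Cox with a
logged note. An independent implementation (`cmprsk::crr`) serves as a
cross-check in the test suite, never as the implementation.

Departure from linearity is tested by a Wald chi-square on the nonlinear
spline coefficient (equal to the squared z-score in this 1-df case);
proportional hazards by the scaled-Schoenfeld-residual test.

### Dose-response outputs

The curve evaluates $\log \mathrm{HR}(x) = [B(x)-B(0)]'\hat\beta$ on a grid
from 0 to the capped maximum, with pointwise delta-method standard errors
$\sqrt{d'\hat V d}$ and 95% Wald limits on the log scale. The **minimal
dose (ED50)** is the smallest exposure achieving half the optimal risk
reduction, where "optimal" is read as the minimum HR over the observed
(capped) exposure range — appropriate for near-linear curves without an
inflection point; the crossing is refined by linear interpolation of the
log HR between grid neighbours, and ED50 is stable under grid refinement
beyond about $10^{-3}$ of the exposure range. Its CI is the pointwise
curve CI at that exposure, not a CI for the ED50 location. For a fitted
log-linear curve $\mathrm{HR}(x)=e^{\beta x}$ with maximum exposure $X$
the definition has the closed form
$\mathrm{ED}_{50} = \ln\!\big(1-\tfrac12(1-e^{\beta X})\big)/\beta$,
used as an oracle in the tests.

**E-values** quantify robustness to unmeasured confounding: for a
protective hazard ratio the risk ratio is $RR^\* = 1/\mathrm{HR}$ (the
hazard ratio is treated as a rate ratio, a rare-outcome setting) and
$E = RR^\* + \sqrt{RR^\*(RR^\*-1)}$, applied to the point estimate and to
the CI limit closer to the null; a CI crossing the null yields 1.

## The synthetic cohort generator

The generator is first-class, tested code that defines the study
conditions under which the pipeline is validated. It emulates a 7-day
wrist-accelerometer protocol in older, nonexercising adults.

**Epoch series.** Each day of 8,640 ten-second epochs is laid out as
contiguous nonwear blocks at the day edges (mirroring don/doff behaviour
and exercising the 16-h rule; by default ~5% of days fail it), a sleep
block of about 7.4 h, and an awake period evolving as a semi-Markov chain
over sedentary/standing/walking with exponential dwell times (means 25, 5
and 4 min). Acceleration is drawn state-conditionally. The awake mixing
weights and the walking moderate-intensity share are set so light activity
averages about 100 min/day and moderate about 26 min/day.

**Vigorous runs** are planted on top: per-day counts are Poisson with a
participant-level rate (a zero-VILPA point mass of 0.112 plus gamma
heterogeneity with shape 2 around a population mean of 12 runs/day), run
lengths follow a distribution with 92.3% of mass at up to 6 epochs, 97.7%
at up to 12, and a small long-VPA tail. These choices reproduce the
summary statistics typical of such cohorts — a median daily VILPA duration
near 4 min/day among the exposed, a median of about 3 length-standardized
bouts/day, and roughly 11% of participants with no VILPA. Runs never touch
sleep or nonwear, never cross midnight, and are separated by at least one
non-vigorous epoch; planted epochs draw acceleration in [400, 900) mg and
non-planted walking below 400 mg, so on generator output the bout engine
recovers the planted runs *exactly* — the basis of the oracle-equivalence
tests. The generator also logs its planted runs, from which ground-truth
exposures are recomputed independently of the epoch series.

**Survival.** Cause-specific event times are exponential,
$h_c(t\mid x,z) = \lambda_c \exp(\beta_c x + \gamma'z)$, for CVD, cancer
and other death, with administrative censoring at 6.9 years. Default
baseline hazards (1.5, 3.2 and 0.5 per 1,000 person-years) match the
mortality rates of the emulated cohort; default exposure effects are
protective log hazard ratios per min/day of true VILPA. Covariates are a
reduced schema (age, sex, 3-level smoking, one continuous confounder,
prevalence flags); the model-fitting interface is schema-agnostic so a
richer covariate set fits the same surface.

**Reproducibility.** One root seed; per-participant substreams are derived
by a deterministic counter, so cohorts are bit-identical across runs and
participants are reproducible individually.

### What the simulator does not emulate

State-conditional acceleration draws are independent across epochs (no
autocorrelation, no raw 100-Hz signal, no calibration error); activity
labels are noise-free, whereas a real classifier mislabels epochs;
exposure is constant over follow-up; hazards are constant in time. Passing
the validation suite therefore demonstrates that the *pipeline computes
what it claims* under its stated assumptions — not that those assumptions
hold in any real cohort, nor that real effect estimates would be unbiased
under classifier error.

## Validation design and problem sizes

The suite validates each stage against an independent oracle: a
brute-force accumulator for length standardization, sort-based percentiles
for capping, risk-set enumeration for the Cox partial likelihood,
`splines::ns` for the basis model space, `cmprsk::crr` for Fine-Gray, a
direct subdistribution-model simulator for Fine-Gray effect recovery, and
closed forms for ED50 and E-values. Calibration checks use seeded
replicates: exact bout-engine/ground-truth equivalence on a 200-participant,
7-day cohort; spline-Cox effect recovery and 95% CI coverage on
5,000-participant cohorts with a planted log-linear protective effect
(log HR -0.3 per min/day, baseline hazard 0.033/yr giving roughly 500
events over 6.9 years) across 200 replicates; and the size of the Wald
nonlinearity test across 500 replicates of 2,000 participants. These sizes
give Monte-Carlo error comfortably inside the asserted binomial bounds
while keeping the default run lightweight.

## Known limitations

- Three knots only; the spec of the spline is fixed by percentile, not
  selected by fit.
- The Fine-Gray censoring distribution is estimated overall, not
  stratified by cause or covariates.
- Complete-case analysis only; no multiple imputation, frailty,
  time-varying covariates or interval censoring.
- ED50 values from fitted curves are data-dependent; on synthetic cohorts
  they validate against the closed form, but no desk-scale computation can
  reproduce cohort-specific published values without the underlying data.
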