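---
title: "Models and methods in wmcda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in wmcda}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

wmcda analyzes visual working-memory (WM) experiments that combine
confidence-rating recognition with lateralized EEG. Its scientific core
is twofold: a hierarchical Bayesian dual-process signal-detection
(DPSD) model that decomposes recognition into recollection and
familiarity, and a contralateral-delay-activity (CDA) pipeline that
asks whether a stimulus-type difference in the EEG marker of WM storage
scales with memory load (a storage effect) or is additive across set
sizes (a stimulus-driven effect). Because raw recordings are bulky and
rarely shippable, every analysis stage is paired with a synthetic-data
generator that reproduces the statistical structure the stage assumes,
so the whole pipeline is testable end to end from code alone.

## The dual-process signal-detection model

A recognition probe is answered on a 6-point confidence scale
(1 = surely-new ... 6 = surely-old). The DPSD model treats each old
probe as recognized through one of two independent routes:

* **Recollection**: with probability $R$, an all-or-none retrieval of
  contextual detail that produces a surely-old (bin 6) response. We
  adopt the classic identification of recollected trials with the
  highest-confidence old bin; recollection never occurs for new probes.
* **Familiarity**: otherwise, a continuous strength signal
  $x \sim \mathcal{N}(F, 1)$ is compared against five ordered criteria
  $c_1 < \dots < c_5$; new probes draw $x \sim \mathcal{N}(0, 1)$.

The cumulative response probabilities are the standard closed forms

$$\mathrm{HR}_i = R + (1 - R)\,\Phi(F - c_i), \qquad
  \mathrm{FAR}_i = \Phi(-c_i),$$

implemented in `dpsd_predict()`; `dpsd_loglik()` evaluates the
multinomial likelihood of a 2 x 6 response table with bin
probabilities given by successive differences of these curves. The
recollection parameter produces the characteristic left-end elevation
of the ROC above the curvilinear familiarity component, which is what
lets confidence ROCs separate the two processes.

## Hierarchical estimation

`fit_dpsd()` estimates population-level $R$ and $F$ per condition with
participant random effects, sampling by MCMC through JAGS:

* **Links.** $R$ on the probit scale, $F$ on the identity scale, and
  the criteria as a first criterion plus log-increments. Each
  participant-condition parameter is the sum of a condition fixed
  effect and a participant random effect, so every draw respects
  $R \in [0,1]$ and $c_1 < \dots < c_5$.
* **Criteria.** Shared across conditions within a participant. The
  conditions are blocked but use the same response scale, so a common
  criterion set is the parsimonious default; the likelihood imposes no
  obstacle to relaxing this in the model string.
* **Priors.** Normal(0, 1.5) on all fixed effects and half-Normal(1)
  on random-effect SDs (`dpsd_priors()`, overridable). These are
  weakly informative on the probit/identity scales: they keep the
  sampler in a plausible region without competing with 100+ trials per
  participant.
* **Parameterization.** Random effects are non-centered
  (participant-level z-scores scaled by the population SD). This
  matters in the small-variance regime, where a centered
  parameterization produces the usual funnel and visibly poor mixing of
  the SD hyperparameters.
* **Budgets.** The `"full"` preset mirrors a production budget of
  12,000 draws after 12,000 warm-up iterations per chain. The `"test"`
  preset (4 chains x 3,000 draws after 2,000 warm-up plus 1,000
  adaptation) runs in about three minutes on one core at the default
  design size (31 participants x 3 conditions x 120 trials) and is the
  size used throughout the test suite; at that budget all
  population-level split-chain R-hat values sit at 1.00-1.01 with
  effective sample sizes in the hundreds to thousands.
* **Diagnostics and summaries.** `summarize_posterior()` reports the
  posterior mean, the shortest 95% highest-density interval, the
  split-chain Gelman-Rubin R-hat (authored in-package;
  `coda::effectiveSize()` supplies ESS). A fit with any population
  R-hat above `rhat_limit` (default 1.1) is flagged and warned about
  but still returned. Population summaries default to transforming the
  fixed-effect chains; `population = "participant_mean"` instead
  averages participant-level draws within each iteration, the
  construction that treats the recruited sample as the population of
  interest. Under small between-participant variation the two agree
  closely.

## What the recognition generator emulates

`gen_recognition_trials()` is the exact generative inverse of the
likelihood: participant parameters are drawn around the population
means on the transformed scales, then trials are simulated from the
recollection/familiarity mixture. Defaults encode a six-item,
three-condition recognition study: population recollection
(0.35, 0.35, 0.36) and familiarity (0.93, 0.91, 1.10) for
repeated-color, repeated-object and trial-unique-object conditions,
31 participants, 120 trials per condition, equal old/new probe rates.
The criteria means (-0.4, 0.2, 0.8, 1.4, 2.0) place the old/new
boundary ($c_3 = 0.8$) where the implied false-alarm rate of the
repeated conditions is approximately 0.21, matching the behavioral
scale of such designs; the remaining criteria are spread roughly
evenly so that all six bins receive usable mass. Between-participant
SDs (0.2 probit for recollection, 0.2 for familiarity, 0.15 for the
criterion shift, 0.1 for log-increments) are fixture choices of a
typical individual-differences scale — no published values exist for
them — and parameter-recovery protocols use smaller values (0.05) so
that recovery error reflects estimation rather than sampling of
participants.

## Behavioral summaries

* `bin_confidence()` maps the continuous semicircular response scale
  onto the six bins. The two 90-degree response arcs (OLD right, NEW
  left) are separated by 90-degree gaps; angles in a gap are rejected
  responses. Within each arc confidence increases toward the bottom of
  the scale, and a boundary angle belongs to the lower-numbered bin (a
  deterministic tie-break for a measure-zero event).
* `compute_rates()` forms hit and false-alarm rates from integer
  counts and Cowan's single-probe capacity estimate
  $K = N(\mathrm{HR} - \mathrm{FAR})$. An "old" response is any bin in
  the OLD half of the scale (4-6). $K$ is deliberately not truncated
  at zero: below-chance participants keep negative estimates so that
  group means are unbiased.
* `build_roc()` cumulates counts from the strictest criterion down,
  giving the five-point confidence ROC with guaranteed monotone
  coordinates.
* `rm_anova()` wraps `stats::aov()` with participant error strata for
  one- and two-way within-subject designs and reports partial
  eta-squared from the stratum sums of squares, with integer degrees of
  freedom (no sphericity correction). Exactly-null effects are reported
  as $F = 0$, $p = 1$ rather than the 0/0 ratio. `pairwise_tests()`
  runs paired t tests with Bonferroni correction capped at 1 and
  Cohen's $d$ as mean difference over the SD of difference scores
  (equivalently $d = t/\sqrt{n}$).

## The fixed-capacity change-detection observer

`gen_change_detection()` simulates single-probe change detection from
an observer holding $K$ items: the probed item is in memory with
probability $\min(K/N, 1)$, remembered probes are answered correctly,
and everything else is a guess (plus a small lapse rate). Under this
observer Cowan's $K$ recovers $\min(K, N)(1 - \text{lapse})$ in
expectation, which is what makes it a useful ground truth for the
behavioral arm of the lateralized experiment. Defaults (capacities 2.6
and 3.1 items for the two stimulus types, 2% lapse, 200 trials per
cell, set sizes 1/3/5, 25 participants) emulate the scale of such
studies.

## The lateralized ERP simulator

`gen_erp_epochs()` produces 500-Hz epochs spanning -200 to 2000 ms
around memory-array onset (half-open sample grid), with the eight
posterior CDA electrodes (P3/4, P7/8, PO3/4, PO7/8), VEOG/HEOG, and
optional gaze channels. Channels contralateral to the cued hemifield
receive a sustained negativity of

$$a \cdot \min(N, K_\text{plateau}) + \delta \quad \mu V,$$

rising linearly over the 100 ms before 400 ms and sustained to the end
of the epoch, so every measurement window sees the full amplitude.
Equal plateaus with a stimulus offset $\delta$ produce a purely
additive stimulus-type effect; distinct plateaus produce a set-size by
type interaction — the two competing patterns the additivity test must
distinguish. Defaults: slope -0.6 uV/item, plateau 3 items, object
offset -0.5 uV, which places amplitudes in the -0.6 to -2.3 uV range
typical of CDA grand averages.

Noise is Gaussian with optional spectral shaping (power
$\propto 1/f$, exponent configurable), scaled to 10 uV RMS — a typical
single-trial EEG scale. Shaping is applied per epoch via FFT, so the
lowest represented frequency is one cycle per epoch; the very slow
drifts a hardware high-pass would remove are absent by construction.

Artifacts are injected per trial at configurable rates, each with
amplitude at least 1.5x its detection threshold, and ground-truth
labels are stored with the trial metadata: blink (400-ms biphasic
VEOG deflection, 150 uV peak), saccade (sustained 60 uV HEOG step,
with a 1-degree gaze step when gaze is simulated), drift (150 uV
linear ramp), muscle (200-ms windowed 60-Hz burst, 150 uV
peak-to-peak), step (120 uV DC shift) and flatline (a constant
channel).

What the simulator does **not** emulate: realistic scalp topography or
volume conduction (channels are independent up to the lateralized
signal), spatially correlated noise, overlapping ERP components,
ocular-artifact propagation into the EEG channels, or amplitude
nonstationarity across a session. Passing tests therefore certify the
*rules* of the pipeline — thresholds, windows, bookkeeping, statistics
— not robustness to every pathology of real recordings.

## Artifact rejection and the CDA

The detectors implement the rule set verbatim, with sliding windows on
sample indices (half-open, trailing partial windows skipped) and
step-like activity measured as the difference between the mean of the
first and second half of each window (for an odd window length the
middle sample belongs to neither half):

| detector | channels | rule |
|---|---|---|
| `detect_eog()` | VEOG/HEOG | abs > 50 uV; half-window step > 30 uV (100-ms window, 10-ms step) |
| `detect_gaze()` | gaze x/y | step > 0.5 deg (100-ms window, 10-ms step) |
| `detect_drift()` | EEG | fitted linear change > 75 uV with R^2 >= 0.3 |
| `detect_p2p()` | EEG | peak-to-peak > 75 uV (200-ms window, 100-ms step) |
| `detect_abs_and_steps()` | EEG | abs > 100 uV; step > 60 uV (150-ms window, 10-ms step); flatline |

The drift rule reads "slope" as the total fitted voltage change across
the epoch (the trend-rejection convention of the standard ERP
toolboxes), not uV/s. The flatline criterion — unspecified in most
rule sets — defaults to zero variance over the whole epoch and is
configurable. Every detector is held to exact agreement with a
brute-force window-scanning oracle in the test suite.

`reject_and_exclude()` rejects a trial when any detector flags it and
excludes participants whose rejection rate exceeds 30% (strictly
greater). Rejection applies to the EEG analyses only; behavioral trial
tables are never filtered by EEG artifacts, so the pipeline naturally
keeps two masks.

`compute_cda()` subtracts the -200..0 ms per-channel baseline
(standard ERP practice; configurable, including off), forms
contralateral-minus-ipsilateral differences per electrode pair,
averages the four pairs, and takes window means over encoding
(400-1000 ms), delay (1400-2000 ms) and the combined 400-2000 ms
window, aggregated to participant means and grand averages with SEM.

## The additivity test and its calibration

`test_additivity()` runs the two-way within-subject ANOVA
(stimulus type x set size) on per-participant window amplitudes and
issues a verdict at a configurable $\alpha = .05$: **interactive** when
the interaction is significant (the capacity-expansion signature),
**additive** when the type main effect is significant but the
interaction is not (the stimulus-driven signature), and
**indeterminate** otherwise.

Calibration is checked at two levels. `sim_cda_cell_means()` draws
per-participant cell means directly from the same amplitude function
(participant intercept SD 0.8 uV, residual SD 0.5 uV — scales chosen
to match what the epoch simulator induces at a few dozen trials per
cell), which makes hundreds of simulated experiments cheap: over 500
null (additive) simulations the interaction's type-I error must sit in
[0.03, 0.07] at $\alpha = .05$, and over 500 capacity-expansion
simulations (plateaus 3 vs 5 items) its power must exceed 0.8. The
full epoch-level pipeline is additionally checked for verdict
correctness and null calibration at small sizes; simulating hundreds
of full EEG datasets would cost hundreds of megabytes each for no
additional inferential content, since the ANOVA consumes only the cell
means.

## Numerical and reproducibility choices

* Every stochastic operation takes an explicit seed; generators run
  under `withr::with_seed()` so the caller's RNG stream is untouched,
  and identical spec + seed reproduce output bit for bit. MCMC chains
  receive per-chain RNG seeds derived from the user seed, making
  draws reproducible for a fixed JAGS version and chain count.
* Degenerate likelihood evaluations (observed mass in a
  zero-probability bin) return `-Inf` rather than throwing.
* HDIs are shortest-interval by direct scan of the sorted draws.
* Window placement is always on sample indices with the half-open
  `[start, end)` convention at 500 Hz, so the 400-2000 ms combined
  window contains exactly 800 samples and equals the time-weighted
  mean of its parts.

## Known limitations

* Posterior precision for the population familiarity means is
  data-limited: at 120 trials per condition and 31 participants the
  95% HDIs have half-widths near 0.09, so two conditions whose true
  familiarity differs by less than roughly twice that will often show
  overlapping intervals even when the posterior means order correctly
  and the paired difference excludes zero. Interval non-overlap is a
  conservative criterion for a credible difference; testing the
  difference directly is sharper.
* The model fixes recollection for new probes at zero (no false
  recollection) and uses equal-variance familiarity; unequal-variance
  variants and model comparison are out of scope.
* The ERP simulator's independence assumptions (above) mean rejection
  sensitivity/specificity estimates transfer to real data only to the
  extent that real artifacts exceed the same thresholds.
* `rm_anova()` intentionally applies no sphericity correction, to
  match integer-df reporting conventions; with three-level factors and
  clear violations the p-values will be liberal.

## Problem sizes used by the test suite

The suite fits one recovery run at the full design size (31 x 3 x 120
trials, reduced sampler preset, about 3 minutes), checks the
closed-form ROC against twenty one-million-trial simulations, holds
every detector to a brute-force oracle on 100 random epochs plus a
labeled-injection screen at 300 trials, and calibrates the additivity
test over 2 x 500 summary-level simulated experiments. Epoch-level
tests use 2-8 participants at 6-25 trials per cell, which keeps the
largest simulated tensor around 100 MB and the whole suite under ten
minutes on one core.
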