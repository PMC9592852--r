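---
title: "Simulating and analyzing threat-conditioned reaching vigor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing threat-conditioned reaching vigor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachvigor)
```

## The paradigm

`reachvigor` implements the analysis pipeline of a Pavlovian
threat-conditioning paradigm for reaching movements, together with a
synthetic-data generator that stands in for the raw recordings. The task
has up to four phases. In the reaching phases (an optional baseline and
two tests, one with shock electrodes attached and one without),
participants click a start point at screen coordinates (0, -416) px
(Cartesian, origin at screen centre, y up) and reach with the mouse
toward a circle that flashes for 100 ms at one of three vertical
positions - low (0, -96), middle (0, 64) or high (0, 224) px - giving
movement distances of 320, 480 and 640 px. Each reaching phase crosses
2 stimulus colours (CS types) with the 3 positions, 20 trials per cell
(120 trials), in uniformly random order. In the conditioning phase, the
stimuli are shown for 6 s each, 9 trials per cell (54 trials); one
colour (CS+) co-terminates with an electric shock on 7 of its 9
presentations per position (77.8% reinforcement) while the other (CS-)
is never shocked. The first six conditioning trials are three CS- and
three reinforced CS+ presentations, one per position each, in random
order; afterwards no more than two consecutive stimuli of the same type
may occur. Cursor position is sampled at 100 Hz; skin conductance is
recorded at 1250 Hz during conditioning.

The scientific question is whether conditioning invigorates subsequent
reaching: higher peak velocity and acceleration toward the CS+ than the
CS-, and whether that kinematic change correlates, across participants,
with the strength of the sympathetic conditioned response (the CS+
minus CS- difference in skin-conductance response, SCR) acquired during
learning.

## The synthetic generator

### Reaches

Each simulated reach follows a straight minimum-jerk path: displacement
fraction $s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5$, $\tau = t/T$. This
kernel was chosen because its profile peaks have closed forms - peak
speed $1.875\,D/T$ and peak acceleration $\approx 5.7735\,D/T^2$ for
distance $D$ and duration $T$ - which gives the kinematic scorer exact
oracles. Movement latency from stimulus onset is a truncated normal
(default mean 330 ms, SD 50 ms, so that offset-referenced reaction
times land near the 225-240 ms typically observed). Base movement times
default to 0.50/0.55/0.60 s for the low/middle/high targets; they are
free parameters of the generator, not estimates, and the package makes
no attempt to match published absolute velocity magnitudes (the
original logger's units are not fully reconstructible); only orderings
and standardized effects are meaningful. Because distance grows faster
than duration, peak speed and acceleration increase with target
eccentricity, reproducing the canonical position ordering.

The conditioned invigoration is modelled as movement-time scaling: CS+
movement times shrink by the vigor gain (default 3%), so peak speed
scales by $1/(1-g)$ while endpoint accuracy is untouched - matching the
empirical pattern of faster, more accelerated, equally accurate CS+
reaches. Trial-to-trial duration jitter is lognormal (CV 0.10);
per-sample path noise (0.02 cm) and endpoint scatter (0.3 cm) are
Gaussian. With probability `anomaly_rate` a trial is made erratic
(three alternating lateral excursions) to exercise the anomaly screen.

### Skin conductance

The electrodermal signal is tonic level (5 uS) + random-walk drift
(0.005 uS/sqrt(s)) + event-related phasic responses + white noise
(0.005 uS). Each CS triggers a response of Bateman (biexponential)
shape, $k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}$ (rise 0.75 s,
decay 2 s), normalized to unit peak, starting 1.5 s after CS onset -
inside the 0.5-4.5 s validity window, so noiseless responses are always
scoreable. Amplitudes are truncated normals with CS-type means of 0.60
(CS+) and 0.26 (CS-) uS, the group means reported for this paradigm,
and trial SD 0.15 uS.

### Cohorts

`run_experiment()` adds participant-level random effects: a lognormal
movement-time multiplier (CV 0.15), a lognormal overall electrodermal
responsiveness (CV 0.5, chosen so simulated group SDs match the
published 0.2-0.5 uS range), and a latent "threat reactivity" z-score
that shifts both the CS+ vigor gain (SD 0.02) and the CS+ SCR amplitude
(0.10 uS per z unit). The latent factor plants a cross-participant
coupling between sympathetic and kinematic conditioned responses, which
the correlation analysis should recover in sign.

What the generator does *not* emulate: online movement corrections,
submovements, biomechanical constraints, SCR habituation (only an
optional linear decay flag), non-stationary electrode artifacts, and
the acquisition hardware's 10 Hz anti-aliasing filter (the synthetic
signal is raw, which is why the pipeline's default scoring config turns
the optional 10 Hz low-pass on). Passing tests therefore demonstrate
correctness of the scoring and inference machinery under a plausible
generative model - not that the pipeline is robust to every artifact of
real recordings.

## Kinematic scoring

Velocities are central differences of the raw pixel samples per axis
(one-sided at the ends), converted to cm/s via the screen's pixel pitch
(43-inch diagonal at 1920 x 1080 gives 0.0496 cm/px; the 64 px stimulus
is 3.17 cm). Speed is the Euclidean norm of the two axis velocities;
acceleration is the signed central difference of speed, so deceleration
appears as negative values. No smoothing is applied by default - at
100 Hz the data are coarse and smoothing would bias the closed-form
oracles - but an odd moving-average window is available.

Movement onset is the first sample at or above 2% of peak speed;
reaction time runs from stimulus offset (the stimulus lasts 100 ms) to
that onset, as is conventional for this task; `rt_reference = "onset"`
switches the reference. Movement offset is the first sample at or after
the speed peak that falls back to the threshold (the final sample if
speed never does), searched only after the peak so the onset crossing
can never be reused. Accuracy is the distance in cm from the cursor at
offset to the target centre. Peak acceleration and deceleration are the
extrema of the signed speed derivative between onset and offset.

The anomaly screen replaces visual trial inspection with a declared
rule: each axis's velocity is split into runs of constant sign, runs
with net displacement under 0.5 cm are ignored, and a trial is flagged
when either axis shows more than 2 direction reversals. The defaults
are a seed-stable surrogate for human judgement, not a claim about any
particular dataset's exclusions. Flagged trials are excluded from
condition means; a cell left empty yields `NA` with a warning, never a
silent zero, and exclusion counts are carried into the results bundle.

## SCR scoring

Preprocessing decimates to 200 Hz: a zero-phase 4th-order Butterworth
low-pass at 80% of the target Nyquist, then linear interpolation onto
the 200 Hz grid. Zero-phase filtering uses odd-reflection edge padding
so constant signals pass through unchanged. The optional 10 Hz low-pass
(for signals not filtered at acquisition) uses the same machinery.

Trough-to-peak scoring works on discrete extrema of the preprocessed
signal. Sub-prominence wiggles (adjacent-extremum amplitude below half
the 0.02 uS validity floor) are merged away; only locally smallest
counter-movements may be merged, which consolidates a gradual rise
carried by many small ripples instead of destroying it. Each remaining
trough is paired with the highest subsequent maximum inside the 5 s
rise window (so a residual ripple cannot truncate a rise); amplitude is
peak minus trough minimum. A deflection's start is bracketed between
the raw minimum and the foot of the rise (the last pre-peak sample
within a small tolerance of the minimum) - slow drift can park the raw
minimum well before the response begins - and the onset-window rule
(0.5-4.5 s after CS onset, inclusive) is satisfied if either endpoint
falls inside. The three validity rules apply in order - window, rise
time (max 5 s), amplitude (strictly greater than 0.02 uS) - and the
first failure zero-scores the trial with a machine-readable reason.
Among several qualifying deflections the largest amplitude wins, ties
going to the earliest trough. Zero-scored trials enter condition means
as zeros, not missing values.

## Statistics

The inferential layer mirrors standard within-subject practice for this
literature:

* `rm_anova()` - balanced fully crossed within-subject ANOVA computed
  from orthonormal contrast scores; for every effect the error term is
  the effect-by-participant interaction. Greenhouse-Geisser epsilon
  comes from the contrast-score covariance (eigen/trace form, clamped
  to $[1/df, 1]$) and the epsilon-corrected degrees of freedom and
  p-value are adopted whenever Mauchly's test rejects at 0.05 (the
  correction trigger is a package choice; both corrected and
  uncorrected rows are always reported). A degenerate zero contrast
  covariance is treated as trivially spherical (epsilon 1).
* `partial_eta_squared()` and `eta_squared_ci()` - the exact identity
  $\eta_p^2 = F\,df_1/(F\,df_1+df_2)$ and its 90% interval by
  noncentral-F pivot ($\eta_p^2 = \lambda/(\lambda+df_1+df_2+1)$),
  lower bound truncated at zero.
* `paired_t()` - difference-score t-test with paired Cohen's
  $d = t/\sqrt{n}$ and a 95% noncentral-t interval (inversion tolerance
  1e-8).
* `helmert_contrasts()` - level 1 vs the mean of levels 2-3 and level 2
  vs level 3, tested against the pooled factor-by-participant error
  with $df = 2(n-1)$ (66 at n = 34); raw weights are used since any
  rescaling cancels in t. A per-contrast error option exists.
* `within_subject_ci()` - Cousineau normalization (subtract participant
  mean, add grand mean) with Morey's $\sqrt{M/(M-1)}$ inflation.
* `robust_pearson()` - least-squares line, single-pass removal of
  points with residuals beyond 3 residual SDs, correlation on the
  remainder with removed indices reported. The screen is single-pass,
  not iterated.
* `differential_scores()` - per-participant CS+ minus CS- differences,
  averaging positions and test phases before differencing.

No multiple-testing correction is applied anywhere; every test uses a
0.05 threshold, mirroring the analysis convention this pipeline
reproduces. That choice is deliberate and should be kept in mind when
many measures are inspected.

Design choices that were genuinely open: the 7-of-9 reinforcement is
balanced within each CS+ x position cell (the SCR analysis is by
position, and per-cell balancing also yields the 77.8% overall rate);
the constrained conditioning order is drawn sequentially (uniform
choice among CS types that do not create a run of three, restart on
dead ends, 10,000-attempt cap) because whole-sequence rejection has a
vanishing acceptance rate at 54 trials - the sequential draw is not
exactly uniform over all valid sequences, which is acceptable because
no analysis depends on the order distribution beyond the stated
constraints; and a paired test with exactly zero difference variance is
an error rather than t = 0, since the statistic is undefined there.

## Numerical choices and problem sizes

Discretization at 100 Hz bounds the peak-speed error of the
minimum-jerk oracle by about 1% for 0.4-0.6 s movements (the tests
allow 2%). Reaction-time recovery is asserted against the continuous
2%-of-peak crossing time, within one 10 ms sample. SCR amplitude
recovery on noiseless traces is within 1% across 0.03-2 uS and
latencies 0.6-4.4 s. Replicate (power-style) studies simulate skin
conductance at 200 Hz rather than 1250 Hz - scoring happens on the
200 Hz downsampled signal either way, and single-cohort tests retain
the 1250 Hz default - and use 100 seeded replicates of 34-participant
cohorts; these sizes are the package's declared simulation scale.
Randomness is controlled by one master seed per run; each stage
(design, motion, SCR, per participant) draws from its own derived
stream, so perturbing one stage's parameters never changes another
stage's data.

## Known limitations

* The generator's movement-time and amplitude defaults are plausible,
  not fitted; absolute simulated magnitudes should not be compared to
  any particular dataset.
* The trough-to-peak scorer is a transparent extremum rule; published
  scoring software may differ in edge cases (overlapping responses,
  extreme drift), though all validity rules are enforced identically.
* `rm_anova()` requires complete balanced designs and rejects missing
  cells rather than imputing; participants with empty cells must be
  handled upstream.
* The pipeline analyzes one experiment layout at a time; cross-
  experiment pooling is provided only for the differential correlation
  analysis.

## A complete run

```{r, eval = FALSE}
cfg <- run_config(seed = 1, experiment = 2, n_participants = 34,
                  scr = scr_params(sample_rate = 200),
                  out_dir = "results/exp2")
bundle <- run_experiment(cfg)
bundle$anova$scr              # stimulus-type and position effects on SCR
bundle$paired$test_peak_velocity_cs  # CS+ vs CS- peak velocity at test
bundle$correlations$peak_velocity    # SCR differential vs vigor differential
```

External data in the documented long formats can be re-analyzed with
`run_on_external()`, which skips simulation and runs scoring plus the
statistical suite, capturing inferential-stage failures (e.g. a single
participant) without discarding the per-trial scores.
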