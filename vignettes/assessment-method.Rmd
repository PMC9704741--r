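---
title: "Trajectory-based motor assessment for a bilateral VR catching task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory-based motor assessment for a bilateral VR catching task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vrmotor` implements an evidence-based motor-assessment workflow for a
bilateral virtual-reality ball-catching task used in upper-limb stroke
rehabilitation. This vignette is the package's account of the method:
the models it assumes, the tunable parameters and their defaults, the
design decisions taken where the method description left choices open,
and what the synthetic cohort does and does not establish.

## The task and its data

A virtual ball flies along a parabola from one side of the patient to
the other; the patient must touch it with the near hand (which launches
it) and catch it with the opposite hand, back and forth. Difficulty is
set by the effective gravity (1/9, 2/9 or 3/9 of 9.81 m/s²), the
horizontal flight range (30–50%, 30–75% or 30–100% of the patient's arm
length) and the number of catches. A depth sensor records both hands at
about 30 Hz. A session recording is therefore a time series of two hand
positions, the ball position and a ball-state channel
(`idle/flying/caught/missed`), plus task settings and identity
(`vr_session`; CSV frames + JSON sidecar on disk).

Clinical context comes from three upper-extremity scales per subject and
timepoint: FMA (0–22), TEMPA (0–27) and WMFT (0–5); higher is better.

## Motor indicators

`segment_attempts()` finds one attempt per flying episode. The apex —
the ball's highest point, after which the landing point is predictable —
splits each attempt into a *before* and *after* phase. The attempt's
analysis window runs from the ball's spawn to the **next attempt's
launch**, not to the catch moment: a severely slowed hand often reaches
the catching zone only after the ball has landed, and cutting the window
at the landing would make reaction-type indicators systematically
missing for exactly the patients they are meant to measure.

Of the 25 indicators (`extract_indicators()`), the horizontal (HMI) and
vertical (VMI) families evaluate the affected hand against a per-axis
band (`axis_band_m`, default 0.12 m) around the landing point; the
full-body family (FBMI) uses 3-D geometry and whole-session statistics:

* *first/last range-entry time, re-entry count* — per-attempt band
  crossings, averaged over the affected hand's attempts;
* *aiming time* — first band presence at or after the apex, minus the
  apex time (lower = faster reaction);
* *stabilization-to-catch* — catch time minus the start of the first
  interval, inside the band, with smoothed speed below
  `stabilization_speed_mps` (0.05 m/s) for at least
  `stabilization_dwell_s` (0.1 s). "Stability" is defined only verbally
  in the field; these numeric defaults are package choices;
* *speed statistics* — `v_max`, mean speed, and V-variation (the
  **population** standard deviation, divisor N) of instantaneous speeds
  `ΔD_i/Δt_i`, pooled over all attempts' before-apex
  (`[spawn, apex)`) and after-apex (`[apex, catch]`) windows;
* *path length, movement ratio, extension extents* — whole-session
  affected-hand polyline length, the normal/affected length ratio, and
  per-axis maximum displacement from the rest pose (the hand's first
  recorded position).

Positions are smoothed with a centred moving average
(`smoothing_window_frames`, default 5, shrinking symmetrically at the
edges) before differencing: raw 30 Hz finite differences amplify tremor
noise far beyond what a speed indicator intends to measure. Path length
uses the same smoothing; extension extents use raw positions (a maximum
is much less noise-sensitive).

Open points resolved as package decisions: catch time is
axis-independent, so `hmi_3` and `vmi_3` coincide; the inter-arm timing
indicator `fbmi_1` is the mean catch-minus-launch interval of successful
affected-hand attempts (the launch *is* the other hand's touch);
HMI/VMI are computed for the affected hand only; per-session aggregation
is the arithmetic mean over valid attempts (sums for `fbmi_2`).
Undefined values stay missing — never 0, which is a meaningful count or
time. All of these are pinned by an independently coded brute-force
oracle in the test suite.

## The synthetic cohort

No public recordings of this task exist, so the package simulates them.
The simulator is first-class, tested code, and its defaults *are* the
study conditions used by the tests and the acceptance script.

**Ball.** Closed-form ballistic flight through both endpoints under
`g_eff = gravity_fraction × 9.81` m/s², apex 0.35 × arm length above the
launch height (high enough to be clearly visible, low enough to stay
within reach). Physics agrees with the kinematic closed form to 1e-9 in
the tests.

**Arm.** The catching hand rests until `t_apex + reaction delay`, then
moves straight toward the landing point at 80% of its speed cap, dwells,
and returns to rest cued by the next ball spawn (a fixed 0.15 s cue
latency); per-frame Gaussian tremor is added throughout. The catch
succeeds iff the hand is within 0.12 m of the landing point when the
ball lands. Severity `theta ∈ [0,1]` maps affinely to the controller:
reaction delay `0.15 + 0.8 θ` s, speed cap `2.5 − 1.8 θ` m/s, tremor SD
`0.0005 + 0.003 θ` m, reach fraction `1 − 0.7 θ` of arm length, plus a
downward aiming droop of `0.05 θ` m. No kinematic parameters of real
patients are published for this task; these maps were chosen once to
span plausible healthy-to-severe behaviour, and they make the key
indicators monotone in `theta` (aiming time up; pre-apex speed and
vertical extension down), which the test suite checks statistically.
The spawn-cued return to rest is what gives the *before-apex* speed
indicators their signal: pre-apex affected-hand movement is mostly the
recentring movement after the previous catch, and its speed scales with
the subject's capacity.

**Scales.** `score = round(clip(max × (1 − θ) + noise))` with noise SDs
(1.5, 2.0, 0.4) for (FMA, TEMPA, WMFT) — roughly the test–retest
variability one expects on these ranges.

**Cohort.** 20 subjects recruited in balanced quotas across three
severity strata, with severities drawn around the stratum means
(0.10, 0.50, 0.90; SD 0.04), and two timepoints with
`theta_post = theta_pre × Beta(8, 2)` (mean retention 0.8, i.e. a
modest stochastic improvement). Three separated strata mirror the
pooled pre+post scale triples falling into three impairment levels;
the retention model produces signed-rank-detectable gains without
assuming any particular published effect size.

What the simulator does **not** emulate: multi-joint arm dynamics,
trunk compensation, fatigue or learning within a session, sensor
dropout, and any real patient's kinematic idiosyncrasies. Passing tests
therefore show that the *pipeline* recovers planted structure from
realistic-looking data — not that the indicators are clinically valid.
One consequence of the fixed difficulty is that moderately and severely
impaired simulated subjects rarely catch, so success-conditioned
indicators (catch time, stabilization) are informatively missing for
them; the assessment models see that missingness through imputation
flags, as a real deployment would.

## Clustering scale triples

`kmeans_scales()` is a direct Lloyd implementation: best of 10 seeded
restarts by within-cluster sum of squares, iterated to assignment
stability (max 300), with an emptied cluster re-seeded at the point
farthest from its centroid (which strictly decreases the objective).
Scales are clustered **unscaled** by default, matching the direct
mapping of the three scores to (x, y, z); a `normalize` flag exists
because the ranges (0–22/0–27/0–5) make this consequential, but it
defaults off. K is selected by the mean silhouette coefficient
(`select_k()`, candidates 2–6; singleton clusters contribute 0; ties go
to the smaller K). Clusters are ordered by ascending centroid score sum
so that **level 1 = most impaired**; the ordering is what makes the
label usable as an ordinal variable in correlations and as the MAPE
denominator.

## Statistics

Pre/post gains use the Wilcoxon **signed-rank** test: the design is
paired (same patients before and after training), so the paired test is
the default even though rank-sum naming is common in this literature;
the unpaired rank-sum test remains available via `method`. The exact
null distribution is computed for n ≤ 25 by dynamic programming over
doubled midranks, which stays exact under tied |differences| — the
normal case for integer scale scores, and something `wilcox.test`
cannot do exactly; zero differences are dropped, p-values are
two-sided, and the implementation is checked against full 2^n
enumeration. Indicator–scale and indicator–level associations use
Spearman's rho (Pearson on midranks) with a two-sided t-approximation
p-value, pairwise-complete over missing indicators, at least 4 pairs
per cell. No multiple-testing correction is applied; reports carry raw
p-values with 0.05/0.01 stars only.

## Assessment models

Three families predict the cluster-derived level from the indicators:
an MLP (single hidden layer, logistic units, softmax output; BFGS with
`maxit = 2000`, decay `1e-4`), an RBF network (K-means centres, Gaussian
units with width defaulting to the median pairwise training distance,
ridge least-squares output weights, argmax prediction), and an RBF-kernel
SVM (cost 1, gamma 1/d, one-vs-one). Published hyperparameters for this
task are not available; these defaults are deliberately ordinary and all
overridable through `model_spec()`.

Evaluation is stratified 5-fold cross-validation over sessions, pooling
a subject's pre and post sessions as independent points. That pooling
can leak subject identity across folds, so a `grouped` mode that keeps
each subject's sessions on one side of every split is provided and
recommended when subject-level generalisation is the question.
Imputation (training-fold medians plus missingness flags) and
standardization use training-fold statistics only. MAPE is computed on
1-based levels so its denominator is never zero; bands follow the
standard scale with <10 "accurate" and ≥50 "inaccurate" as the anchor
points.

## Numerical and reproducibility notes

Session files are written with fixed column order and 17-significant-
digit floats, so writes are byte-stable and read–write round trips are
exact; the gravity fraction is stored as integer ninths to survive JSON.
All randomness flows from explicit integer seeds (`withr::with_seed`),
including K-means restarts, fold assignment and network initialisation;
`run_pipeline()` writes a manifest with the config hash and per-file MD5
checksums, and a repeated run with the same seed reproduces it
byte-identically. Degenerate inputs are handled conservatively:
all-identical triples yield duplicate centroids rather than errors, a
hand that never enters the range yields missing entry times and a zero
count, and an all-zero difference vector yields p = 1 with a warning.

The test suite runs at deliberately small problem sizes — sessions of
2–20 attempts, cohorts of 40 sessions, 100 clustering replicates, 20
cohort replicates for the classification benchmark — chosen so the full
statistical checks (power, recovery rates, oracle equivalence) complete
in a few minutes while keeping Monte-Carlo margins comfortable.

## Limitations

The indicator set is specific to this catching task; nothing here
claims transfer to other tasks. The cluster labels are a *relabelling
of the scales*, so the classifiers learn an indicator→scale mapping,
not a ground-truth diagnosis. Real cohort sizes near n = 40 leave wide
confidence intervals on accuracy-type metrics, and the simulator's
clean strata make the classification task easier than a clinical
population would be; treat the benchmark numbers as an upper bound on
what this pipeline could achieve on real data.
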