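---
title: "Quantifying odor-guided walking: models, parameters and design choices"
author: "flywalkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying odor-guided walking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its own science: the models
it implements, the parameters that matter, the choices made where the
method leaves room, and what its synthetic-data tests do and do not
establish about recorded data.

## The assay and its analysis chain

A single starved fly walks in a dark circular arena (6.4 cm diameter)
whose central disc (1.2 cm radius) can be filled with an odorant at a
constant concentration. A trial is 3 min without odor ("before")
followed by 3 min with odor ("during"), filmed at 30 frames/s. The
analysis chain is:

1. **Tracking** — the mean frame is subtracted from each frame; the fly
   is the only bright object left; its position is the
   intensity-weighted centroid of the largest connected component above
   an Otsu threshold.
2. **Smoothing and kinematics** — coordinates are smoothed with a
   10-frame sliding window; speed is the displacement between
   consecutive smoothed frames times the frame rate; angular speed is
   the wrapped heading difference times the frame rate, discarded when
   the fly moves slower than 2 mm/s (heading is unreliable at near-zero
   displacement).
3. **Segmentation** — runs and stops by a two-threshold Schmidt
   trigger (0.5 mm/s down, 1 mm/s up); smooth and sharp turns from the
   5-frame angular-displacement sum (0.3 rad and 1.3 rad).
4. **Epochs and transits** — before is [0, 180) s; during starts at
   185 s if the fly is inside the odor zone at odor-on (odor takes
   about 5 s to reach the arena), otherwise at the fly's first
   subsequent entry; flies that never enter are excluded with a
   recorded reason. Zone entries and exits define transits.
5. **Features** — 17 motor parameters per fly
   (`motorParameterNames()`), mixing normalized changes
   ((during − before)/before), during/before ratios, and during-only
   turn fractions.
6. **Statistics** — per-parameter two-sided Wilcoxon rank-sum tests at
   the Bonferroni level 0.05/17 ≈ 0.003; a 136-pair Pearson correlation
   screen; PCA of the standardized feature matrix; canonical variate
   analysis (eigenvectors of $W^{-1}B$) with a label-shuffle
   permutation test.

## The synthetic walker

`simulateFly` is a semi-Markov run/stop walker. Its defaults are the
study conditions the analysis assumes:

| parameter | default | unit | rationale |
|---|---|---|---|
| median run duration | 4.81 | s | no-odor baseline of walking flies |
| median stop duration | 0.67 | s | no-odor baseline |
| median run speed | 0.57 | cm/s | no-odor baseline |
| episode duration law | log-normal, $\sigma_{\log} = 0.8$ | — | medians plus heavy right tails (runs frequently exceed 10 s); a two-parameter law reproduces both |
| per-run speed law | log-normal, $\sigma_{\log} = 0.3$ | — | between-run speed variability without within-run jitter |
| heading diffusion | 0.2 | rad²/s | see below |
| sharp-turn rate | 0.25 | events/s | a handful of abrupt reorientations per run, as seen in walking flies |
| sharp-turn angle | 1.6 | rad | clearly above the 1.3 rad detector threshold, below a U-turn |
| wall attraction | 0.7 | — | probability of aligning with the wall tangent on contact; produces the edge dwelling of undisturbed flies |
| boundary turn bias | 0 (null), 0.05 (attractant) | per frame | inward-directed sharp turns within 2 mm of the odor boundary |

`acvWalkerConfig()` switches the during-inside block to the
attractant-response values (run 1.0 s, stop 0.3 s, speed 0.18 cm/s),
raises speed outside, weakens edge dwelling and adds the inward
boundary-turn bias.

**Heading diffusion = 0.2 rad²/s.** The turn detector sums angular
displacement over 5 frames, so diffusion contributes noise with sd
$\sqrt{5 \cdot 0.2/30} \approx 0.18$ rad to the statistic. The
generator must keep its two turning modes separable — a single-frame
1.6 rad jump has to stand clear of the 1.3 rad threshold
($0.3/0.18 \approx 1.6$ sd of headroom) while diffusion alone stays
clear of it and still produces smooth-turn frames above 0.3 rad. A
diffusion of 1 rad²/s would blur the two modes into one another and no
threshold detector could recover the events the generator itself
planted.

**Boundary turn bias = 0.05/frame.** The bias is a per-frame
probability while the fly is within 2 mm of the odor boundary. Larger
values (0.3/frame ≈ 9 turns/s) trap the fly inside the zone for the
entire odor period, which contradicts the observed behavior that flies
enter and leave the zone several times per period and would leave every
outside-during parameter undefined.

**Context switching.** Crossing the odor-zone boundary (or odor onset)
switches the active parameter block instantly and resamples the ongoing
episode from the new context — the simplest model consistent with acute
speed changes at the boundary. A side effect worth knowing: resampling
restarts the episode clock, so realized run durations exceed the
configured median by roughly 10–15% in conditions with frequent
boundary crossings. The during/before *ratios* are robust to this when
one parameter family is varied at a time; varying run duration and
speed jointly couples the bias to the crossing rate.

**Wall interaction.** On contact the heading either aligns with the
nearer tangent direction (probability `wallAttraction`) or is reflected
about the tangent. Wall contacts therefore produce genuine abrupt
heading changes that the sharp-turn detector correctly reports but that
are not part of the Poisson turn process; analyses of the *planted*
turn events exclude a 1.5 mm rim ring.

## Numerical and design choices

* **Even smoothing windows.** The default 10-frame moving average uses
  a centred kernel with half weights on its two outermost points, so
  linear motion is exactly invariant in the interior; edge frames use
  shrunken symmetric windows.
* **Turn statistic sign.** "Sum of angular velocity over 5 frames" is
  ambiguous about sign; the package uses |Σ signed displacement| so
  left/right symmetry holds and jitter cancels, with `signedSum =
  FALSE` switching to Σ|·|.
* **Schmidt-trigger start and dead bands.** The initial state is
  backfilled from the first decisive frame; a record entirely inside
  the dead band is an error (state undeterminable). Thresholds are
  strict inequalities as printed. Known bias, accepted: stops of 1–3
  frames can go undetected; tests score episode agreement ignoring
  sub-100 ms stops.
* **Attraction index uses raw times.** The during epoch is shorter
  than before (entry-conditioned start), so one might normalize per
  second; measured on null cohorts, the raw-time index is centred
  (median ≈ −0.01 over 60 flies) because the shorter window and the
  conditioning-on-entry bias cancel, while the per-second version is
  biased +0.2. The raw formula is kept.
* **Transit dwells are right-censored at epoch ends.** Spells still
  open at an epoch end enter the median clipped to the epoch end in
  *both* epochs; dropping them instead censors the shorter during epoch
  more heavily and biases its median down by ~0.1.
* **Transit debounce.** Inside/outside spells shorter than 2 frames are
  treated as boundary chatter; the boundary radius used for transits
  (`odorBoundaryRadius`) is configured independently of the nominal
  zone radius (1.2 cm nominal; 1.9 cm is the conservative estimate
  appropriate for undiluted attractant).
* **Jump rule units.** The published figure of "3 mm/s" as a tracking
  error threshold cannot be taken literally, since normal runs reach
  5.7 mm/s. The default reads it as 3 mm per frame, i.e. 30 mm/s at 30
  frames/s (`jumpLimit = 30`); `jumpPerFrame = TRUE` applies the other
  reading. Flagged frames are repaired by linear interpolation between
  unflagged neighbours.
* **Thresholding.** Otsu by default on each background-subtracted
  frame, with a fixed-value override; a contrast floor
  (`minContrast = 0.05`) prevents thresholding pure sensor noise into a
  phantom fly, and a frame without the fly is "missing", fatal only
  above 20% of frames.
* **CVA numerics.** $W^{-1}B$ is diagonalized through the symmetric
  generalized eigenproblem via the Cholesky factor of $W$, so
  eigenvalues are real by construction. If $W$ is singular (fewer
  within-group degrees of freedom than parameters) a minimal ridge is
  added with a warning, and the same ridge is reused across permutation
  shuffles. The permutation p is the fraction of shuffles with median
  distance *strictly greater* than observed, as defined; the
  (k+1)/(n+1) convention is reported alongside.
* **Missing features.** Parameters with a zero before-denominator or
  no qualifying events are NA with a recorded reason, never imputed;
  rank-sum tests use pairwise-complete data, PCA and CVA complete
  cases.
* **Turn-fraction parameters** (smooth turns in/out, sharp turns at
  boundary) are computed on the during period only; whether they should
  be before-normalized is left open by the method's description, and
  during-only matches their use as group-comparison variables against a
  solvent control.
* **Correlation screen criterion.** The significance rule behind a
  "significantly correlated pairs" count is not fixed by the method;
  the default is unadjusted p < 0.05 per pair, switchable to
  Bonferroni.
* **PCA standardization** defaults to z-scoring because the 17
  parameters mix ratios and normalized changes on different scales.
* **Smoothing synthetic tracks.** The 10-frame window exists to tame
  video noise. Simulated trajectories are exact, so analyses of
  simulator output set `smoothingWindow = 1`; smoothing exact tracks
  would blur single-frame turn events across ten frames and shorten
  detected stops.

## What the tests establish — and what they do not

The test suite validates every stage against constructions with known
answers: closed-form cases (lines, circles, uniform discs), brute-force
oracles (an explicit state machine for the Schmidt trigger on all
3-level speed sequences up to length 12; a naive generalized
eigendecomposition for CVA; exhaustive rank-assignment enumeration for
the rank-sum test), ground-truth recovery on simulated cohorts
(fold-changes of 0.5/1/2 in run duration, stop duration and speed
recovered within 15% from cohorts of 30 flies at 3 seeds; null cohorts
centred via 99% bootstrap CIs over 180 flies), statistical calibration
(permutation rejection rate within 0.03–0.07 over 400 null datasets of
1000 shuffles; ~5% of 136 correlation pairs significant under
independence), and a render-and-retrack round trip (RMS error below
0.5 px, under 1% flagged frames).

Problem sizes were chosen so the full suite runs in a few minutes:
1-minute phases for determinism and recovery spot-checks, full 3+3 min
trials wherever epoch structure matters, 30-fly cohorts for parameter
recovery, 180 × 180 px videos for tracking.

Passing these tests shows the *implementation* is faithful and the
*statistics* are calibrated. It does not show that the generator is a
complete model of fly behavior: the walker has no body orientation
(centroid only, so no distinction between translation and sideways
drift), no plume structure (odor is a binary zone), no wind, no
multi-fly interaction, no floor/ceiling transitions, and its episode
durations are log-normal by assumption — recorded data may have
different tail behavior, short-latency motor corrections, and tracking
artifacts (reflections, occlusion at arena fixtures) that the renderer
does not emulate.

## Known limitations

* With fewer complete flies than parameters plus groups, CVA rests on
  the automatic ridge; results are then regularization-dependent and
  the permutation p is the quantity to trust, not the axis itself.
* Per-fly transit medians rest on a handful of transits per epoch; at
  30 flies per cohort their normalized changes fluctuate by about
  ±0.1 under the null. Comparisons between odors should rely on the
  rank-sum panel across flies, not on single-fly values.
* The sharp-turn detector reports any 5-frame angular displacement
  above 1.3 rad, including wall reflections; `sharp_turns_at_boundary`
  is therefore meaningful near the odor boundary ring but rim-adjacent
  events should be excluded when estimating turn *rates*.
* The tracker assumes exactly one fly and a static background; it does
  not maintain identity across occlusions.
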