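---
title: "Methods: Shannon entropy of shoal-centroid trajectories and the warning-system model"
author: "shoalSE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Shannon entropy of shoal-centroid trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement

A fixed overhead camera films a tank of shoaling fish (European seabass is
the reference species) as 640 x 480 pixel frames at 24 fps. Each frame is
thresholded and segmented into connected components ("elements"); the
group's position is summarized by one point per frame, the cluster
centroid, giving a time series $(x_i, y_i)$ with $0 \le x_i < 640$,
$0 \le y_i < 480$. A recording contains three arbitrary 3.5-minute clips of
undisturbed (basal, shoaling) behavior and one 3.5-minute clip starting at a
deliberate disturbance — a hit on the tank that elicits a schooling burst.
At 24 fps a clip is 5,040 frames.

The behavioral statistic is the plug-in (histogram) Shannon entropy of the
centroid positions,
$$H(X) = -\sum_{x_i \in \Theta} p(x_i)\,\log_2 p(x_i), \qquad
p\log p = 0 \text{ when } p = 0,$$
computed per axis over unit-pixel bins (640 for x, 480 for y) and combined
as the arithmetic mean of $H_x$ and $H_y$. A centroid that barely moves
concentrates its histogram (SE near 0); one that jumps uniformly over the
frame attains $\log_2 640 \approx 9.32$ bits in x. SE is therefore a
predictability measure for the group's movement, not a description of the
behavior itself.

Two conventions are configurable and always recorded in the result: the
log base (2 by default, so entropies are in bits) and the x/y combiner
(mean by default; sum available). Bins are half-open $[e_j, e_{j+1})$ with
the last bin closed. Z-scored trajectories are supported (binned over the
observed range with the same bin counts; the transform is monotone affine,
so entropy changes only through bin-edge effects), but the default pipeline
analyzes raw pixel trajectories — on real data the two gave equivalent
results, and raw pixels need no extra convention.

## Trajectory extraction

`segment_frame()` applies a global Otsu threshold (fixed threshold
configurable), a 3 x 3 morphological opening, connected-component
labelling, and an area filter (default: components under 5 px discarded).
These three knobs are the whole segmentation contract; they are deliberate
defaults rather than a reconstruction of any particular laboratory's
recipe.

Two centroid estimators are provided:

* **Naive**: the unweighted mean of element centers per frame. Unbiased
  when every fish is detected, but a single spurious detection in frame
  $f$ moves the estimate by (distance)/(elements + 1).
* **K-means smoothed**: $k$ is the element count of the first frame;
  cluster centers are seeded from that frame's element centers; every
  subsequent frame runs a *single* warm-started Lloyd update and reports
  the mean of the $k$ centers. Three small policies make this a robust
  tracker rather than a textbook k-means:
  1. *single update per frame* — a transient blob drags a center only part
     of the way, so it snaps back when the blob vanishes; iterating to
     convergence lets the blob capture the center outright;
  2. *validation gate* (default 50 px) — detections farther than the gate
     from every current center are ignored as noise (fish displace a few
     pixels per frame); if gating would discard a whole frame it is
     suspended for that frame;
  3. *re-anchoring* — a center whose cluster ends a frame empty has lost
     its track and is reset onto the mean of the occupied centers.

  The phrase "k-means with the first frame's centers as input" admits
  several readings (one run per clip; per-frame independent runs; per-frame
  warm starts). The warm-start reading is adopted because it is the one
  that actually yields the documented noise reduction over the naive
  estimator; this is an interpretation, and it is flagged as such here.

Frames with zero elements carry the last valid centroid forward (leading
gaps copy the first valid value backward): the entropy binning requires a
gap-free series of full clip length. Sub-pixel centers are kept as reals;
rounding happens only inside the histogram.

A round-trip property ties the chain together: simulate, render each fish
as a filled disk, segment, smooth — the recovered trajectory matches the
simulator's true centroid to well under a pixel RMSE in clean scenes.

## The synthetic shoal

No movement model ships with any published trajectory data here, so the
package defines one explicitly, with two requirements: it must be fully
seeded (bit-identical reruns), and it must reproduce the *qualitative* laws
the analysis rests on — entropy rising and saturating with group size,
one-fish systems with very low SE and very high replicate dispersion, and a
schooling burst after the disturbance. It makes no claim to match real
seabass kinematics; only the SE-versus-group-size ordering is asserted and
tested.

Each fish carries a unit heading updated from: its previous heading (weight
0.8), the group's mean heading (alignment 0.5), attraction to the group
centroid (0.05 per pixel of offset), and Gaussian jitter (sd 0.6). Speed
during movement is 4 px/frame, scaled by a per-fish lognormal boldness
multiplier (sd 0.5 on the log scale). Walls reflect. Two further
ingredients matter:

* **Intermittent locomotion.** The group alternates between moving bouts
  (mean length 5 s) and hovering (3% of swim speed). The long-run moving
  fraction is $0.6\,(1 - e^{-n/8})$: larger shoals are bolder and explore
  more of the arena. Without this term a persistent random walk covers the
  whole tank within a 3.5-min clip at *every* group size and the
  SE-versus-n curve is flat or decreasing — the saturating rise the data
  show cannot emerge.
* **One-fish freezing.** A lone shoaling fish barely moves (the
  selfish-herd account: alone, exposed, it minimizes motion). Displacement
  is scaled by `freeze_factor` (default 0.1) when `n_fish == 1`. Combined
  with boldness variation this produces both the very low one-fish SE and
  its very large between-day CV.

The disturbance multiplies speed by 3 and centroid attraction by 2 for its
duration (10 s default) and startles the group into its moving state —
except that multipliers of exactly 1 are an exact no-op, a convenient
identity for testing. The event segment is re-integrated from the stored
state with the same seeded noise, so pre-event frames are untouched
bit-for-bit.

All behavioral parameters live in `sim_config()` with these defaults; they
were fixed once, when the generator was calibrated to the qualitative laws
above, and the acceptance checks run against them unchanged.

Simulated studies in this package use 840-second recordings — the shortest
recording that holds three disjoint basal clips, the event and a full
response clip — rather than the one-hour field protocol; clips themselves
are always the full 5,040 frames. Rendering-based checks use short frame
ranges (a rendered full clip is about 1.5 GB of pixels; nothing about the
estimators depends on clip length).

## Aggregation conventions

* Sample (n-1) standard deviations everywhere (replicate counts are 3).
* A tank-day is complete with exactly 3 basal + 1 event clip; incomplete
  days are an error naming the missing clips, never silently dropped.
* CV = 100 * sd / mean. Two pooling bases for the CV-by-fish-count table:
  `all_measurements` (every clip SE pooled) and `daily_averages`
  (per-tank-day basal means). The two disagree by construction — pooling
  all clips includes within-day scatter. `pooled_cv()` reconstructs the
  all-measurements CV exactly from per-day (mean, sd, 3) triples, which is
  what allows the published daily table to be re-analyzed without per-clip
  raw values. The published "average of three replicates" CV row could not
  be reproduced from the daily table under any standard definition tried
  (e.g. 2.31 printed vs 3.58 recomputed for 50 fish), so that basis is
  exposed as configuration and the discrepancy is documented rather than
  guessed away.
* Basal and event states never share a pooling group.

## Power-law fitting

SE versus fish count follows $se = a\,n^b + c$ (for $b<0$: rises from
$a + c$ at $n=1$ to the asymptote $c$). Fitting is Levenberg–Marquardt
nonlinear least squares with:

* anchor start $c_0 = \max(se)$, $a_0 = \min(se) - c_0$, $b_0 = -0.5$, plus
  4 jittered restarts (best SSE kept) — with only small fish counts the
  likelihood is nearly flat in $(a, b)$ and single starts are fragile;
* $b$ bounded to $[-5, 5]$ against overflow at $n = 50$;
* 95% bounds from the coefficient covariance with $t_{n-3}$ quantiles — the
  degrees-of-freedom convention of mainstream curve-fitting toolboxes, so
  RMSE and intervals are comparable with published panels;
* the goodness panel (SSE, $R^2$, adjusted $R^2$, RMSE with $n-3$ dof);
* constant input returns a flagged degenerate fit ($a=0$, $c=$ mean,
  $R^2=0$) instead of erroring;
* at least 3 distinct fish counts are required — fewer cannot identify
  three parameters, and `run_pipeline()` skips fitting in that case.

Whether fits should use every clip SE or daily means as points is a free
choice; both are supported and the choice is recorded in the fit's `mode`
field. Interval calibration is tested by simulation: with noise sd 0.4 and
3 replicates at $n \in \{1, 13, 25, 50\}$, each coefficient's 95% interval
covers the truth in at least 90% of 100 seeded fits.

## The warning-system model

A healthy system at a fixed fish count is summarized by three reference
sub-models, each a mean ± sd across reference days: basal SE, event SE, and
their ratio (basal/event — the direction is a convention and is recorded).
For a newly observed day the error signal per channel is observed minus
reference mean; a channel alarms when $|e| > k\,\sigma$ with $k = 2$ by
default, two-sided. "Larger than the normal variation" is not quantified
anywhere authoritative, so the $k\sigma$ band is the simplest faithful
rule; $k$ is configurable. References are conditional on fish count, and a
one-fish reference carries a structured warning (one-fish replicate CVs
reach ~60%, an order of magnitude above 13-50 fish groups, so one-fish
sensors should be avoided). Monitoring operates on daily summaries — the
unit at which those dispersions were characterized — rather than on
individual clips; a per-clip mode is deliberately not offered.

Calibration: under Gaussian channel noise the two-sided 2-sigma rule has a
nominal false-alarm probability of 4.55% per channel per day. The test
measures this with a 1,000-day reference (so the band itself is tight; a
short reference inflates the rate above the nominal value) and a
10,000-day monitored stream (Monte-Carlo error ~0.2%), asserting the ≤5%
bound; the acceptance script additionally reports the rate over a 100-day
stream, the scale at which such a monitor would actually run. A sustained
deviation of 3 reference sds alarms on every affected day. Integration of
error signals into higher-order farm knowledge is deliberately out of
scope: `monitor_stream()` exposes a logging callback as the contract
boundary.

## Known limitations

* The simulator is a calibration target for the *analysis*, not a model of
  seabass: spatial statistics (speed distributions, wall affinity, polarity
  dynamics) are not fitted to data, and passing tests say nothing about
  real kinematics beyond the SE ordering.
* 2D only — the camera geometry already collapses a 3D scene, and so does
  the simulation.
* No identity tracking, interaction, or leadership analysis; the cluster
  centroid is the only spatial summary.
* Absolute SE values depend on the binning/base/combiner conventions;
  comparisons across settings are refused by construction (every result
  records its settings) but the defaults here need not match any
  particular published implementation's internals.
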