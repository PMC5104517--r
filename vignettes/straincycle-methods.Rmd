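---
title: "Models and methods behind straincycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind straincycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

straincycle quantifies cell-cycle progression in quiescent epithelial
monolayers under equi-biaxial mechanical strain, from Fucci two-colour
time-lapse imaging: mKO2-Cdt1 (red) marks G0/G1, mAG-Geminin (green) marks
S/G2 from S entry until its degradation at mitosis. Because the kind of
live-imaging data it targets is rarely redistributable, the package carries
a fully ground-truthed synthetic pipeline: an agent-based monolayer
simulator plus an image renderer, so every analysis stage (segmentation,
tracking, trace classification, event counting, strain estimation,
statistics) can be exercised and validated end to end with no external
data. This vignette documents the models, the defaults, and the design
choices a maintainer would want to know.

## The monolayer simulator

Cells sit on a jittered hexagonal packing at 1000 cells/mm^2 in a 656 x 656
um field (about 0.43 mm^2, one movie frame at a 20x-objective scale of 0.65
um/px). Each cell carries a cycle phase (G0, G1, S, G2), per-phase clocks,
fluorophore levels, and a scalar transcriptional-activity proxy `A_i` for
beta-catenin signalling.

**Two-threshold activity model.** Each cell draws a baseline `A0_i` from a
log-normal distribution (meanlog 0, sdlog 0.25). Treatments act
multiplicatively:

    A_i(t) = A0_i * (1 + beta_s * s(t - onset) + beta_w * [wnt or D4476])

with `beta_s = 0.9`, `beta_w = 2.5`, and `s()` a logistic onset centred 6 h
after stretch (width 1 h), reproducing S entry 6-8 h after strain. iCRT3
forces `A_i = 0`. Two thresholds gate progression: `theta1 = 1.8` for
G1-to-S and `theta2 = 3.0` for G2-to-M. The placement is deliberate: under
control conditions essentially no baseline draw falls in `[theta1,
theta2)`; the strain increment (factor 1.9) lands most induced entrants in
that interval, so they enter S and then hold in G2 (S/G2 accumulation
without division); the Wnt/D4476 increment (factor 3.5 alone, 4.4 with
strain) pushes entrants past `theta2`, licensing mitosis.

**Transitions.** G0 cells exit at hazard `h0 = 0.01/h` (basal) plus
`h_strain = 0.02/h` while stretched — the mechanosensitive arm, active
immediately. Spontaneous (basal-trigger) exits redraw `A0` from the upper
tail above `theta2`, so they complete the cycle; induced exits keep their
baseline draw. G1 lasts an Erlang(2) time with mean 1 h, after which a cell
enters S only if it exited quiescence in this cycle *and* `A_i >= theta1`;
otherwise it returns to G0. This commitment rule encodes the pathway
epistasis of the underlying biology: beta-catenin activity alone cannot
drive S entry without prior quiescence exit, which is why post-mitotic
daughters (placed in G1 with red restored) always re-quiesce rather than
cascade into uncontrolled proliferation under Wnt. S lasts a fixed
`tau_s = 4` h; G2 exits to mitosis at the *graded* hazard
`k_m * A_i/theta2` (with `k_m = 1/6` per h) once `A_i >= theta2`. Grading
matters: multiplying the standing S/G2 pool's hazard is what produces the
early, transient mitotic burst seen under Wnt alone, which then decays back
to the control rate as the pool drains.

**Calibration by steady-state relations.** The two control baselines are
analytic consequences of two parameters rather than tuned curves: with
basal S-entry flux `lambda = 0.01` per cell per hour and total S/G2 dwell
`tau_SG2 = tau_s + 1/k_m ~ 10 h`, the stationary Geminin-positive fraction
is `lambda * tau_SG2 ~ 10%`, and the division rate is `lambda * (cells per
0.1 mm^2) ~ 1` per hour per 0.1 mm^2 at the default density. The split of
the 10 h between S (4 h) and graded G2 (~6 h mean) is chosen so the
standing G2 pool is large enough for the Wnt burst to be detectable above
counting noise.

**Quiescence versus steady turnover.** A monolayer in which more than 95%
of cells are in G0 cannot simultaneously be 10% Geminin-positive — the two
baselines refer to different moments of the protocol. The initializer
simulates a contact-inhibited maturation (G0-exit hazard multiplied by
`1/(1 + (density/600)^2)`, about 0.2 at matured density) for 48 h, ending
with ~97% of cells quiescent; this is the state in which strain is applied
in the physical protocol. `simulate_timelapse()` then inserts a 12 h
untreated equilibration segment — the mounting, medium-refresh and
treatment-preparation interval between maturation and imaging — during
which the basal hazard returns to `h0` and the S/G2 pool relaxes towards
its ~10% steady state, so that control movies open near baseline and stay
stationary (the fitted slope of the control S/G2 fraction is below
0.002/h). Treatments and stretch always start at movie time zero.

**Other simulator choices.** Mitosis is instantaneous: the parent is
replaced by two daughters at +/- half a nuclear radius along a random axis,
with green dropped to zero and red restored — the single-frame
green-to-red-plus-split signature used for counting. Nuclei have an
exclusion volume: any pair closer than 2.5 radii (10 um) relaxes apart at
up to 0.75 radius per frame. Without this, daughter nuclei placed 4 um
apart would stay optically unresolvable forever (positions are otherwise
static apart from a 0.3 um/frame Brownian jitter that exercises the
tracker), making track-split detection structurally impossible; with it,
sibling nuclei are resolvable from their first imaged frame, emulating
cytokinesis. There is no cell death, extrusion or directed migration, so
the cell count grows by the division rate (~1%/h in control); real
monolayers balance this by extrusion, which is out of scope here.

## Image formation and quantification

Rendering draws each nucleus as an isotropic Gaussian spot (sd = half the
4 um nuclear radius) in three channels — constant-amplitude nuclear stain,
red and green scaled by the fluorophore levels — over a constant background
of 100 counts, then applies Poisson shot noise, Gaussian read noise (sd
10), and 16-bit clipping. Red recovers towards its plateau with a 1 h time
constant in G0/G1 and decays with a 1 h half-life after S entry (so red and
green overlap only briefly); green accumulates linearly (0.3/h, capped at
2) from S entry, indicating time since entering S, and collapses at
mitosis.

Segmentation is the canonical nuclear recipe: Gaussian smoothing (sd 2 px,
implemented as a separable truncated kernel), rolling-ball background
subtraction (grayscale opening, radius 15 px), global Otsu threshold, hole
filling, and a distance-transform watershed (tolerance 2 px) to split
touching nuclei, discarding objects under 20 px^2. Per-nucleus measures are
the intensity-unweighted centroid (0-based pixel coordinates, y down),
area, and per-channel means; the whole-image cytoplasmic intensity (mean
over the complement of the 2 px-dilated nuclear mask) doubles as the
background estimate subtracted before thresholding. Border-touching nuclei
are kept, since event counts are per unit area. A nucleus is
Geminin-positive when its background-subtracted green mean exceeds a fixed
threshold (default 150 counts, about 0.3 h into S at the default gain) that
is held constant between compared conditions.

## Tracking and event counting

Frame-to-frame linking is an optimal (maximum-cardinality, minimum total
squared displacement) bipartite matching over candidate pairs within a
physical gate, computed in micrometres. The default gate of 1.5 um is a few
times the expected frame displacement — large enough that random-walk tails
essentially never break a link, small enough that a dividing parent can
never link to a daughter (which appears ~5 um away). Gap closing bridges a
disappearance to an appearance `g+1` frames later (default `max_gap = 1`)
within a widened gate. A track that terminates with at least two new tracks
appearing within 6 um in the next frame is annotated as a parent; the two
nearest candidates become daughters, ties broken by summed distance then
track id.

Fucci traces are classified with hysteresis on the balance ratio
`green/(green+red)` of background-subtracted nuclear means: GREEN above
0.6, back to RED below 0.4. The hysteresis band absorbs the red/green
handover noise; its cost is a classification lag of one to two hours after
true S entry, which shifts dwell times but not counts. A mitosis is counted
only when both cues agree — fluorescence collapse (or a green track end)
*and* an annotated lineage split; single-cue tracks are logged as warnings
rather than events. Cumulative tallies follow the single-cell-tracking
readout: *accumulated* counts tracks with an observed red-to-green
transition, *divided* the subset that went red-to-green-to-red with a
split, so divided never exceeds accumulated. Rates are reported per hour
both per movie frame (0.43 mm^2) and normalized per 0.1 mm^2.

## Strain estimation

Two estimators mirror the device calibration. From matched fiducial beads,
the least-squares isotropic scale about the common centroid has the closed
form `s = sum(p.q)/sum(|p|^2)` on centred coordinates, and percent strain
is `100(s-1)`; the post-fit residual RMS is reported as an
anisotropy/noise diagnostic rather than fitted. From unmatched nuclear
centroids, the DNN-7 metric — each cell's mean distance to its 7 nearest
neighbours — increases proportionally under dilation, and percent strain is
the percent increase of its population mean between snapshots. Edge cells
are included (the closed-form hexagonal worked example `(6+sqrt(3))/7 * d`
applies to interior cells only); `k = 7` is the validated default but is
exposed as a parameter.

## Statistics

Condition summaries are mean +/- SEM over independent simulated experiments
(one seed = one replicate, the analogue of one imaging run). Families of
unpaired t-tests use the Welch form by default (the pooled-variance test is
a flag) and are corrected with the Holm-Sidak step-down: sort raw p
ascending, `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforce a running
maximum, unsort; underpowered comparisons are flagged and excluded from
`m`. Distribution-valued metrics use the two-sample Kolmogorov-Smirnov
statistic with its asymptotic p-value; no exact small-sample enumeration is
attempted, and the statistic `D` itself is what the tests check against a
brute-force ECDF-gap oracle.

## What the synthetic data does and does not show

The generator reproduces the study conditions: quiescent baseline with
steady ~10% S/G2 turnover and ~1 division/h/0.1 mm^2; strain-induced S/G2
accumulation from 6-8 h without extra divisions; the early transient
mitotic burst under Wnt or D4476 alone; sustained strain+Wnt (or
strain+D4476) mitotic entry; and complete suppression by iCRT3. It does
not emulate uneven illumination, photobleaching, segmentation-hostile
nuclear shapes, cell death or extrusion, 3D motion, or strain-field
inhomogeneity, so green pipeline tests certify the algorithmic chain on
idealized imaging physics, not robustness to every real-microscope
artefact. Magnitudes shown only graphically in the source experiments
(e.g. the exact strain-induced accumulation at 24 h) are matched in shape,
not to a printed value.

## Numerical and scale choices

Simulation steps are 15 min (one frame); hazards are applied as
`1 - exp(-h dt)`; Erlang G1 times are drawn at G1 entry; the S timer is
exact. All runs are bit-reproducible given a seed: the RNG state travels
inside the monolayer state, so interleaving other computations cannot
perturb a run. Full-scale validation (0.43 mm^2, 97 frames, three seeds)
renders and segments ~150,000 nuclei in a few minutes on one core; the
test suite therefore runs its property checks on smaller fields and keeps
three full-scale control replicates, which the worked analyses share.
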