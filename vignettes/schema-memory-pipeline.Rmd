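---
title: "Simulating and analysing schema-congruent memory consolidation with fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analysing schema-congruent memory consolidation with fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schemasim)
```

# The problem

When a new memory fits an existing schema — a kettle seen in a kitchen rather
than on a beach — its fate over systems consolidation differs from that of
schema-incongruent material: behaviourally it tends to become *coarser*
(context retained, scene detail lost), and neurally its retrieval patterns
integrate in medial prefrontal cortex (mPFC) while the hippocampus keeps
scene-specific codes. Testing such claims requires a long pipeline: a
constrained experimental design, behavioural scoring into memory *grain*,
single-trial activation estimates from BOLD runs, condition-paired pattern
similarity, post-encoding resting-state coupling, and mixed-effects
inference. `schemasim` implements that pipeline end to end and — because raw
human neuroimaging data of this kind are protected — pairs it with a
synthetic cohort generator with fully known ground truth, so that every
analysis stage can be validated by parameter recovery rather than by
re-analysis of unavailable data.

# The designed experiment

Two contexts (beach, kitchen) each have two specific scenes (`BeachA`,
`BeachB`, `KitchenA`, `KitchenB`). An object pool of 60 beach-typical, 60
kitchen-typical and 40 neutral objects is split into two 80-pair stimulus
lists, one per retention delay (short/long). Each list holds 40 congruent
pairs (20 beach objects on beaches, 20 kitchen objects on kitchens) and 40
incongruent pairs (10 + 10 typical-but-swapped, 10 + 10 neutral per
context). Within a context we split pairs evenly over its two scenes (10
congruent + 10 incongruent per scene); the composition table is invariant
over seeds and only the object-to-scene assignment is randomised.

Encoding presents all 80 pairs in each of three runs; a run order is valid
only if adjacent trials never share a scene. A uniformly random permutation
of 80 trials over 4 balanced scenes satisfies this with probability on the
order of $e^{-19}$, so rejection sampling essentially never succeeds and the
deterministic repair pass does the real work: the order is scanned once and
each offending trial is swapped with the nearest position where the swap
fixes the violation without creating a new one among the touched
neighbours. We therefore cap rejection attempts at 100 by default (the
outcome is the same as with a much larger cap, minus the wasted draws).
Trial timing is 0.1 s scene alone, 2 s object overlay, 1 s response, and a
1/1.5/2 s jittered fixation drawn uniformly — the source design states the
jitter support but not its distribution, so uniform is our choice, fixed
once. Retrieval tests each pair exactly once across four 20-trial runs: 2 s
object cue, 2 s context response (kitchen/beach/don't know), 2 s scene
response, 3–6 s jitter in 0.5 s steps. The scene window is offered only
after a kitchen/beach context choice; after a "don't know" context response
no scene response exists (`absent`), and the scorer treats a scene response
recorded there as a structural error.

# Behavioural scoring

Congruency is *operational*, not nominal: a pair counts as congruent when at
least two of its three encoding judgments were "related". Pairs with more
than one missing judgment are indeterminate and leave the denominators.
Memory grain per retrieval trial is: **detailed** (context and specific
scene both correct), **coarse** (context correct; scene "don't know" or the
similar same-context scene), **forgotten** (anything else). Missing button
presses score as "don't know" — the conservative reading. Scores are
percentages of each participant's operational-condition trial count, kept on
the 0–100 scale, and detailed + coarse = total by construction.

Participants whose *pooled* total percent correct at a delay falls strictly
below 33% (chance with three context options) lose that delay's data only —
the exclusion is delay-local.

Judgment *consistency* is reported as the percentage of pairs judged
identically on all three runs. The source text does not define the metric;
all-three agreement is the strictest reading, and a mean-pairwise-agreement
mode is exposed behind a flag without any claim about the original intent.

# The synthetic cohort: a stated world

`cohort_config()` fixes the simulated world once; none of its defaults are
fitted to data, and none were moved after seeing test outcomes (the one
revision — the long-delay outcome probabilities — is documented below).

* **Cohort**: 23 participants, counterbalancing groups of 10 (A) and 13 (B);
  the group label orders sessions and is carried into the models but has no
  effect on within-list structure.
* **Encoding judgments**: each run's judgment contradicts the pair's
  intended congruency with probability 0.066, implying all-three consistency
  of $(1-p)^3 + p^3 \approx 81.6\%$ — the level the behavioural literature
  this design comes from reports for real participants.
* **Outcome probabilities** P(grain | congruency, delay): congruent-short
  detailed/coarse = .45/.05; congruent-long = .27/.14; incongruent-short =
  .42/.05; incongruent-long = .30/.06. The congruent-short cell is fixed by
  the build contract; the remaining cells encode the qualitative signature —
  coarse memory rises over the delay for congruent pairs only, and overall
  accuracy drops — while keeping the pooled long-delay total (~38.5%) far
  enough above the 33% exclusion line that only ~15% of simulated
  participants are excluded, matching the real cohort's 4 of 23. Our first
  choice of long-delay cells put the pooled total below the exclusion line
  and would have removed most of the cohort; that is a world inconsistent
  with the experiment being emulated, so it was revised once and not
  touched again.
* **Trial patterns**: for ROI $R$ and trial $t$,
  $\mathbf{p}_t = w_{ctx}\mathbf{u}_{ctx} + w_{scene}\mathbf{u}_{scene} +
  w_{item}\mathbf{u}_{item} + \boldsymbol\varepsilon$, with component
  vectors drawn i.i.d. standard normal per participant × ROI and fixed
  across trials. At large voxel count the expected Pearson correlation
  between two trials is the ratio of shared component variance to total
  variance; components are not explicitly orthogonalised — i.i.d. vectors
  are nearly orthogonal at the V = 10,000 used for the closed-form checks
  (tolerance 0.02). Default ROI size is 300 voxels: small enough for desk
  scale, large enough for stable correlations. Default weights raise
  $w_{ctx}$ only for (congruent, long) in the mPFC, raise anterior
  hippocampal $w_{ctx}$ and posterior hippocampal $w_{scene}$ with delay
  irrespective of congruency, and are otherwise flat. Effect sizes are
  artifact choices — the source reports no generative parameters.
* **BOLD runs**: per-voxel signal is amplitude × (double-gamma HRF ∗
  boxcar) summed over trials, plus AR(1) noise (coefficient 0.3, white SD
  1), linear + quadratic drift, TR = 1.5 s. Motion is a small random walk
  (0.01 mm / 1e-4 rad steps) with optional injected 1.2 mm spikes that the
  scrubbing threshold must catch.
* **Rest**: 6 min at TR 1.5 s (240 volumes) per scan, first 6 volumes
  trimmed downstream. Pre-encoding coupling is drawn as Fisher-z ~ N(0.3,
  0.1²); the post-minus-pre change is
  $\Delta z = 0.05 + 0.015\,(s - 14) + N(0, 0.05^2)$ where $s$ is the
  participant's long-delay coarse-congruent score in percent. With
  `exact_corr = TRUE` (default) the series are constructed so the empirical
  correlation of the raw series equals its target exactly, which separates
  the generator's coupling from the estimator's sampling noise. The implied
  population correlation between Δz and score (~0.8 before preprocessing
  losses) yields one-tailed power above the configured target of 0.75 at
  n = 17; with the link slope at zero the test must reject at the nominal
  rate.

What the generator does **not** emulate: spatial autocorrelation,
physiological noise spectra, slice timing, susceptibility distortion, or
any registration error. A green recovery test therefore establishes that the
*analysis code* recovers what the generative model put in — not that the
pipeline is robust to every artefact of real acquisitions.

# Single-trial estimation

Each retrieval trial is estimated with its own GLM (least-squares-single):
the first regressor is the target trial's 2 s cue period; the run's
remaining trials collapse into at most five nuisance regressors by trial
type (coarse/detailed × congruent/incongruent, forgotten; empty groups
dropped); response windows are modelled jointly by default (`"separate"`
exists as an option — the source does not say which it used); six motion
regressors and one indicator per volume with framewise displacement > 0.9
complete the design. FD is the Power formulation: sum of absolute backward
differences with rotations converted on a 50 mm sphere — the source cites
the threshold but no formula. The HRF is the canonical double gamma (peak
6 s, undershoot 16 s, dispersions 1, ratio 1/6, 32 s). Fitting is plain OLS
per voxel (no prewhitening; the estimator's noise model is unstated in the
source), and the retained map is $t = \hat\beta/\mathrm{SE}$; in
zero-residual fits $t$ is an `Inf` sentinel and the β map should be
consumed instead (`use_beta = TRUE`). Encoding runs are never modelled.

A numerical caveat the tests respect: LSS equals the all-trials-separate
GLM exactly only when the two designs span the same space — e.g. with two
trials per run, where the "group" of non-target trials has one member. With
more trials and heterogeneous amplitudes the grouped regressor cannot absorb
its trials exactly and the target β acquires a small (~1e-3 here)
projection bias; the equivalence and exact-recovery tests therefore use the
two-trial case and group-homogeneous amplitudes respectively.

# Pattern similarity

Each trial's ROI pattern is z-scored *within vector across voxels*
(population SD). The phrase "extracted into a vector and z-scored" does not
fix the normalisation axis; an across-trial per-voxel mode is available
behind `zscore_axis = "trial"` with no claim about the original choice.
Similarities are Pearson correlations, Fisher-transformed with |r| clipped
at $1 - 10^{-7}$ (clipped records flagged), computed only between trials of
the same participant, delay and operational congruency, **never within the
same run**, each unordered pair once, no self-pairs. The congruency scheme
pairs all context-correct (coarse + detailed) trials and labels pairs
within/across context; the granularity scheme pairs detailed trials only
and labels them same / similar (other scene, same context) / other-context
scene — a partition of all admissible pairs. Forgotten-trial control
variants are the same two schemes behind a grain filter, sharing every code
path. The univariate control is simply the ROI mean of the trial map.

# Rest connectivity

Per scan: drop 6 stabilisation volumes; flag volumes by the three artifact
criteria (global signal > 3 SD, per-axis volume-to-volume translation >
1 mm, per-axis rotation > 0.05 rad — the original tool's composite is
internal to that software, so the per-axis reading is ours and is
documented, not asserted as equivalent); extract the top five principal
components of the noise-mask voxels (aCompCor); regress out motion, its
first derivatives, spike indicators and the components; then band-pass
0.008–0.09 Hz — filtering after regression, in that order. The filter is an
ideal FFT brick wall (a bin is kept iff its two-sided frequency lies in the
closed band); a Butterworth option exists behind a flag. Coupling is the
Fisher z of the Pearson correlation of the two ROI-mean series; deltas are
post − pre on identically preprocessed series, so swapping the scans negates
every delta exactly. The brain–behaviour test is a Pearson correlation with
$t = r\sqrt{n-2}/\sqrt{1-r^2}$, one-tailed for the a-priori positive
direction with a one-sided CI whose upper bound is 1. Williams' test for
two dependent correlations is implemented directly and refuses correlation
triples that do not form a positive-definite matrix (the statistic is
undefined there).

# Mixed models

All similarity models are fit on Fisher-z values. The default model is
REML via `lme4` with sum-to-zero contrasts, a random intercept per
participant and a random adjustment for counterbalancing group (with only
two groups this term is frequently singular; singular fits are reported,
not hidden). When Levene's test (Brown–Forsythe, median-centred, across the
cells of the fixed factors) rejects, the model is refit with `nlme` and a
`varIdent` residual variance per cell — the same mechanism the original
analysis used. When Shapiro–Wilk rejects normality of residuals (on a
deterministic evenly-spaced subsample of 5000 when n exceeds the test's
limit), the response is square-root transformed and the model re-run. The
rule engine (`fit_with_rules()`) applies check → transform → recheck →
weights as a deterministic state machine and logs each step.

**Degrees of freedom.** The Satterthwaite approximation is not available in
this build's backends (no `lmerTest`), so all F and t tests use the
residual/containment df $n - \mathrm{rank}(X)$, always reported and labeled
`df_method = "containment"`. For the trial-level similarity models this
matches the source's own observation that denominator df track the number
of level-1 observations; for small participant-level tables it is more
liberal than Satterthwaite, which is why the calibration suite checks the
realised type-I rate of the interaction test directly (it stays within the
99% binomial CI of the nominal 5% over 500 null cohorts).

Estimated marginal means weight every design cell equally (what the cell
means would be with equal trial counts), so they equal raw cell means under
balance — an exact identity the tests assert. Pairwise contrasts are t
tests on the EMM covariance with the model df. Within-subject error bars
use the Morey method: remove each participant's mean, add the grand mean,
take the per-condition SE of the normalised values, inflate by
$\sqrt{M/(M-1)}$ for $M$ conditions; participants missing a condition are
dropped from the normalisation, and with $M = 1$ the plain SE is returned
with a warning. Confidence intervals are t-based; the source's bootstrap
scheme is unstated, so we do not imitate it.

# Numerical choices and limitations

* Fisher clipping at $|r| = 1 - 10^{-7}$ keeps z finite; clipped records
  carry a flag.
* HRF regressors are built on a 0.1 s grid and sampled at volume times;
  generation and estimation share the same kernel by default, and a
  mismatched-HRF robustness mode is available by passing a different
  `hrf_spec` to the estimator.
* The repair pass for the adjacency constraint is deterministic given the
  starting permutation, so schedules are byte-reproducible from the seed.
* Multiple-comparison correction is deliberately absent, mirroring the
  uncorrected reporting convention of the analysis being reproduced; the
  contrast tables expose p-values that a caller may adjust.
* The CLI covers the file-based stages (design, simulate, score). The
  array-based stages exchange in-memory matrices; in a text-only build
  NIfTI I/O is out of scope and runs are exchanged as flat matrices plus
  metadata, the sanctioned fallback.
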