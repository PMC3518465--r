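---
title: "Analysing saccadic choice data: minimal SRT, congruency onsets, and a feedforward model bench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing saccadic choice data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacchoice)
```

## The task and the questions

In a saccadic choice experiment two scenes are flashed simultaneously left
and right of fixation and the observer saccades as fast as possible to the
side showing the target category. Because the first saccade can leave within
100–200 ms of image onset, the distribution of saccadic reaction times
(SRTs) is a window on the earliest sweep of visual processing. The analyses
this package implements answer three questions:

1. **When does category-selective information first drive the eyes?**
   The *minimal SRT* is the earliest 10-ms latency bin in which correct
   saccades reliably outnumber errors.
2. **When does scene context start to modulate object detection?** The
   *congruency onset* compares trials where an object sits in its typical
   context (animal/natural, vehicle/man-made) against trials where both
   scenes violate that pairing.
3. **Would simple feedforward image statistics predict this behaviour?**
   Four classic feature models (GIST, Weibull contrast statistics, a
   saliency map, HMAX C1) are scored with a repeated linear-SVM protocol
   on scene and object categorization of a synthetic image set.

No public trial-level recordings exist for this paradigm, so the package is
organised around a synthetic-data generator whose parameters *are* the
planted ground truth: every estimator is validated by parameter recovery.

## The two-process race generator

`generate_srt_data()` reduces the race between a fast, task-blind saccade
process and a slower selective process to a latency-then-accuracy mixture.
Each trial draws one latency $L$ from a shifted ex-Gaussian,

$$L = \mathrm{shift} + \mathcal N(\mu_s, \sigma^2) + \mathrm{Exp}(\tau),$$

truncated by redrawing into the 80–800 ms validity window, and then picks
the saccade side:

$$\Pr(\text{correct} \mid L) =
  \begin{cases} p_{\mathrm{ns}} & L < t_{\mathrm{sel}} \\
                p_{\mathrm{sel}} \pm \delta\,[L \ge t_{\mathrm{ctx}}] &
                L \ge t_{\mathrm{sel}} \end{cases}$$

with $p_{\mathrm{ns}} = 0.5$ for an unbiased early process (below 0.5 it is
pulled toward the distractor, as vehicle-task data show when the distractor
is an animal), $t_{\mathrm{sel}}$ the planted selective onset,
$p_{\mathrm{sel}}$ the asymptotic selective accuracy, and $\pm\delta$ the
context modulation applied from $t_{\mathrm{ctx}}$ on congruent (+) and
incongruent (−) pairs. A full race of two competing accumulators would also
produce latency–accuracy coupling *within* a process; the mixture is the
simplest mechanism that reproduces every distributional feature the
estimators consume (binned correct/error counts, subject medians, planted
onsets), and it keeps the planted truth readable off the spec. That is a
modelling choice of this package, not a claim about the generating process
in real observers.

Subjects are exchangeable but not identical: each synthetic subject jitters
$\mu$ by $\mathcal N(0, 10^2)$ ms (the `subject_mu_sd` field, configurable),
enough to make subject-level bootstrap and permutation resampling
non-degenerate. The trial list is a deterministic, bit-reproducible
function of the `scenario_spec`, including its seed.

### Calibration of the packaged scenarios

`packaged_scenarios()` encodes five conditions whose planted summaries are
the descriptive statistics a 12-subject session (4 runs of 48 trials each)
produced: animal (accuracy 80.9%, mean of subject median SRTs 181 ms,
minimal SRT 120 ms), vehicle (63.2%, 207 ms, 180 ms, with an early bias
$p_{\mathrm{ns}} = 0.40$ toward the animal distractor), natural and
man-made scenes (72.2%/217 ms and 73.8%/212 ms, both with minimal SRT
160 ms), and an animal-task congruency condition (87.5% vs 75.5% for
congruent vs incongruent pairs, context onset 160 ms).

For each condition the shape parameters $\sigma, \tau$ were fixed once at
values giving realistic right-skewed SRT distributions with adequate counts
in the bins around the planted onset; $\mu$ and $p_{\mathrm{sel}}$ were
then solved numerically so that (a) the truncated-mixture accuracy
$\Pr(L < t_{\mathrm{sel}})\,p_{\mathrm{ns}} +
\Pr(L \ge t_{\mathrm{sel}})\,p_{\mathrm{sel}}$, averaged over the subject
jitter, equals the planted accuracy, and (b) the median of the correct-trial
latency distribution equals the planted median. The congruency condition
has no separate planted median, so it was calibrated to 182 ms, the average
of the congruent and incongruent medians (178/186 ms) the condition
summarises; its $\delta$ then follows from the planted accuracy split:
$2\delta\Pr(L \ge t_{\mathrm{ctx}}) = 0.12$.

### The blocked pair design of the congruency scenario

Randomly pairing target and distractor contexts makes half of all pairs
"mixed" (one image congruent, one not), which the congruency analysis must
discard. The packaged congruency scenario instead blocks pairs — every
trial is fully congruent or fully incongruent, 50/50 — so the two analysed
conditions are maximally and equally powered at the session's trial budget.
`context_assignment = "random"` restores random pairing (a quarter
congruent, a quarter incongruent, half mixed), and is what the tests use to
exercise the mixed-pair exclusion path.

## The estimators

**Validity filter.** Trials without a saccade or with SRT outside 80–800 ms
are discarded, with per-condition exclusion percentages reported. The
window is taken as inclusive: the convention is documented here rather than
claimed as established practice, since "below 80" and "over 800" leave the
boundary values themselves ambiguous.

**Binned distributions.** Correct and error counts are pooled over subjects
into contiguous half-open bins $[80, 90), [90, 100), \ldots$ of 10 ms. The
single latency equal to 800 ms joins the last bin so the inclusive filter
loses nothing.

**Minimal SRT.** Each bin's correct/error pair is tested against an equal
split with a Pearson goodness-of-fit statistic,
$X^2 = (n_c - n_e)^2/(n_c + n_e)$ on 1 df, no continuity correction. A bin
qualifies when $p < .05$, correct responses outnumber errors, and the bin
holds at least 5 responses; the minimal SRT is the lower edge of the first
qualifying bin whose four successors also qualify. Three of those choices
deserve a note. The direction requirement is implied by the question (an
onset of *correct* dominance); without it, early bins of a distractor-biased
condition would fire in the wrong direction. The per-bin minimum of 5
responses guards the sparse tails, where a 3–0 split is nominally
"significant"; the threshold is exposed as `min_total`. Whether a continuity
correction belongs in the original procedure is not decidable from its
description; none is applied, and the choice is config-visible in
`chi2_correct_vs_error()`.

**Group summaries.** Accuracy is the pooled proportion correct; the latency
summary is the unweighted mean over subjects of each subject's median
correct-trial SRT (midpoint interpolation for even counts). Confidence
intervals are percentile bootstrap over *subjects* (2000 resamples, 2.5/97.5
percentiles) — the subject, not the trial, is the exchangeable unit.

**Permutation tests.** Condition contrasts resample per-subject summaries:
the pooled 24 values are reshuffled into two fake groups of 12, 2000 times,
and the two-sided p-value counts null differences at least as extreme as
the observed one with the $+1/(n+1)$ correction, so the smallest reportable
p is $1/2001 \approx 5\times10^{-4}$ — reported as a floor, never as zero.
A 2000-draw Monte-Carlo cannot substantiate a smaller p; the normal
approximation to the null (mean/sd of the permuted differences) is also
computed for reference, count-based p primary. Trial-level pooling is
deliberately not the default: per-subject summaries respect the repeated
measurement structure.

**Congruency onset.** Each condition's binned distribution is collapsed to
hits minus false alarms per bin. How the original per-bin test was applied
to *differenced* counts (which can be negative) is not recoverable from its
description; the reconstruction here rescales both conditions to equal
totals, clips negatives to zero, and applies the same 2-cell Pearson /
consecutive-bin rule as the minimal SRT, requiring the congruent difference
to exceed the incongruent one. This is flagged prominently as a
reconstruction; `method = "raw2x2"` implements the other defensible
reading (a per-bin 2×2 test of raw hit/false-alarm counts by condition).

A power caveat follows directly from the arithmetic: with
$\delta \approx 0.08$, selective accuracy $\approx 0.82$, and 1152 trials
per condition, the expected per-bin statistic is roughly $0.08\, n_b$ for a
bin holding $n_b$ trials per condition, so a single session rarely yields
five consecutive qualifying bins. On regenerated sessions the detected
onset is nonetheless sharply modal at the planted 160 ms (and detections at
other bins are rare), so the stable readout — used by the recovery tests
and the reproduction script — is the modal onset over seeded replicates,
not any single dataset's detection.

## Numerical choices and degenerate inputs

* Ex-Gaussian tail probabilities are evaluated on the log scale; the naive
  closed form overflows a few hundred ms into the tail.
* `qexgauss()` inverts the CDF by root bracketing to $10^{-8}$ ms.
* Empty bins have undefined $X^2$ and never qualify; an empty distribution
  is an error for every downstream estimator, not a silent zero.
* A subject with no correct trials has no median and is dropped from the
  latency mean with a warning.
* Ties in the cost line search go to the smallest cost; ties in model
  ranking break by model name, so reports are deterministic.
* Onsets are reported as the lower edge of the first qualifying bin, which
  is how 120/160/180 ms values on a 10-ms grid should be read.

## The synthetic image set

`generate_scene_images()` builds grayscale textures by spectral shaping:
white noise is filtered in the frequency domain with a $1/f^{1.2}$ radial
falloff and an orientation gain $1 + k\cos 4\theta$, cardinal-dominated
($k > 0$) for man-made backgrounds, oblique-rich ($k < 0$) for natural
ones. Object categories composite a region — a smooth closed
Fourier-contour blob for animals, a rectilinear two-block assembly for
vehicles, 9–13% of image width in radius at a random central position —
into a background drawn half from each context, with the binary mask
recorded. `separation` scales both the background spectral gap and the
object blend weight; at 0 every category is the same texture process and
all classifiers sit at chance. The whole set is then equalized to common
mean luminance and RMS contrast by iterated affine rescaling with clipping
to $[0,1]$, to within $10^{-7}$ per image.

What this set emulates is the *statistical* structure the feature models
consume: orientation-spectrum differences between scene categories, weaker
and more local object signals, luminance/contrast equalization, and the
half-natural/half-man-made embedding of objects. What it does not emulate
is photographic content — occlusion, clutter, perspective, semantic
diversity of real animals and vehicles. Passing the model bench here shows
the protocol and extractors behave, and that the generator's built-in
scene-over-object separability ordering is detected; it does not reproduce
absolute accuracies on any photographic dataset, which would require the
original images.

## The model bench

Feature extractors use conventional configurations, all config-exposed:
GIST as 4 scales × 8 orientations of frequency-domain Gabor energy averaged
on a 4×4 grid (512 values); Weibull scale $\beta$ and shape $\gamma$ fitted
by maximum likelihood to gradient magnitudes; saliency as normalized
center-surround differences of intensity and orientation channels on a
dyadic pyramid, downsampled to 8×8; HMAX as Gabor S1 (four filter sizes,
four orientations), C1 max-pooling over space and adjacent scales, and a
seed-fixed dictionary of random C1 patch prototypes read out by max dot
product — the standard surrogate when no trained prototype set exists.
The evaluation protocol defaults to the published constants: balanced
180/12 train/test splits, cost line search over $10^{-3}\ldots10^3$ by
8-fold cross-validation on the training set, linear SVM, 100 random
repeats; features are standardized by training-set mean/sd (the protocol's
accuracy is then invariant to feature-wise affine rescaling). Chance is
judged against the binomial null aggregated over the held-out sets.

## Problem sizes

The recovery analyses regenerate the 12 × 192-trial design: 50 replicates
per condition for minimal-SRT recovery, 200 for the congruency onset, 20
seeds for the summary statistics, 1000 null datasets for the
false-detection rate, and 1000 × 2000-resample bootstrap runs at $n = 200$
for CI coverage — each a few minutes on one core. The bundled model-bench
script runs 48 images per category at 96×96 px with a 64/16 split and 25
repeats; the full 216-per-category, 400×400, 100-repeat configuration is a
matter of the same calls with larger arguments.

## Known limitations

* The latency-then-accuracy mixture cannot express within-process
  speed–accuracy trade-offs; planted medians and onsets are the only
  distributional truths it guarantees.
* The congruency-onset contingency structure is a reconstruction (see
  above); alternative readings shift single-session detections, though the
  modal recovered onset is stable across both implemented readings.
* Bootstrap CIs resample 12 subjects; percentile intervals at that group
  size are approximate, which is why coverage is verified by simulation
  rather than assumed.
* The image generator's categories are texture processes, not objects in
  scenes; model accuracies transfer qualitatively (ordering, scene–object
  gap), not numerically.
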