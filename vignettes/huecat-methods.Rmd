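---
title: "Detecting emergent color categories: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting emergent color categories: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the measurement idea

Color is the textbook case of categorical perception: differences within a
category look smaller than equal-sized differences across a category
boundary. `huecat` implements a match-to-sample style probe for asking
whether a *learned visual representation* carries such category structure,
without ever asking the system to name a color.

The probe works as follows. A frozen feature extractor maps a raster image
to a fixed-length vector. A fresh linear readout (a "probe head") is
trained to classify colored-word stimuli whose hues come from K narrow
training bands on the HSV hue circle (full saturation and brightness, so
the spectrum is the edge path of the RGB cube; hues are stored as
fractions in [0, 1)). The trained head is then evaluated on the *whole*
spectrum, discretized into 100 bins, and each bin's most frequent
predicted class (the column mode) yields a one-dimensional *mode row*.
Transitions between classes in the mode row are candidate category
borders. The decisive manipulation is to repeat this while *sliding* the
training bands around the circle: if the representation is continuous,
borders travel with the bands; if it is categorical, borders stay put.
Summing transitions over all runs gives a *transition count* signal whose
peaks are the category borders; the reciprocal-weighted circular mean of
each inter-border interval is the category's prototype color.

Three further components complete the toolkit:

* a *shift analysis* quantifying border invariance: for every pair of mode
  rows, the circular lag maximizing the correlation of their unit-circle
  coordinates, folded into one class period, with Fisher comparison and
  histogram-overlap statistics between a row stack and simulated
  categorical/continuous comparators;
* an *evolutionary search* over 7-border partitions whose fitness is
  learning speed — how accurate a readout becomes after only 3 epochs when
  its training bands are placed just inside each candidate category;
* a *psychophysics module* with the same transition/peak analysis at
  35-bin resolution for match-to-sample observer tables, a simulated
  observer, and a bootstrap test of cross-observer alignment.

Everything runs end-to-end from seeds on synthetic components; no
downloads or external weights are involved.

## Synthetic study conditions

The package ships two *responder models* that stand in for a trained
network, and a small trainable backbone:

* `categorical_responder(borders, eps)` labels a hue by the class whose
  band center shares the hue's planted category. A category holding no
  band center is generalized as a whole to the class nearest its
  midpoint — a deliberately *categorical* fallback; a per-hue
  nearest-center fallback would re-introduce continuous behavior and break
  the defining invariance. When several classes share a category, the
  nearest center wins, so doubly-occupied categories split at the midpoint
  between their centers (these internal transitions shift with the bands
  and average out in the transition count).
* `continuous_responder(eps)` labels each hue by the circularly nearest
  band center; its borders shift with the bands by construction.
* `make_scratch_category_backbone(planted)` trains a small dense network
  end-to-end to classify word stimuli into the planted categories and
  returns its frozen penultimate layer as a feature extractor. The
  architecture is two tanh hidden layers (32, then one unit per category)
  over 16 x 16 block-averaged, ImageNet-normalized pixels, trained with
  minibatch SGD (momentum 0.9, learning rate 0.1, batch 64, 250 epochs,
  best-epoch checkpoint, validation criterion 0.95 with up to two restarts
  on derived seeds). Two design points matter. *Depth*: the RGB cube
  corners are kinks of the input manifold; with a single hidden layer a
  kink inside a broad category (e.g. pure blue at h = 2/3) survives into
  the features and shows up as a systematic spurious border near h = 0.70.
  *Penultimate width*: a penultimate as wide as the class count yields a
  compactly categorical code; wider penultimates retain continuous hue
  information that probes exploit to re-split broad categories. Individual
  training runs still occasionally retain an extra internal boundary — the
  same kind of "about 7–8 discontinuities" fuzziness a full-scale network
  shows.

The reference planted partition, `default_planted_borders()`, is
`(0.045, 0.125, 0.21, 0.40, 0.52, 0.63, 0.84)`: seven unevenly spaced
borders with narrow warm categories and a broad green region, mirroring
the qualitative layout of human hue categories. Category spans were kept
at or above 0.08 for a statistical-power reason worth knowing about: two
*adjacent* categories can only pin the border between them when both
contain a band center, and consecutive centers are 1/K apart, so a pair of
adjacent categories whose combined span falls below the band spacing is
essentially undetectable by K <= 7 probes.

Stimulus generators follow the published designs: 224 x 224 rasters; a
single word ("color", nominal size 40, roughly 100 x 25 pixels) in one of
five packaged bitmap fonts at a uniform random position on mid-grey
(128, 128, 128); multi-word scenes with three target words, two random
distractor words drawn on top, and a random-hue background at 50%
brightness (value 0.5 before 8-bit round-half-up, so the brightest
background channel is 128); and outline shapes stroked at 4 pixels whose
interior is defined by the enclosure rule — a pixel is filled iff drawn
lines exist strictly to its left, right, above and below. Glyphs are
rendered without anti-aliasing so that every glyph pixel carries exactly
the quantized target color; this makes pixel-level contracts testable.
The 14 outline families (ellipses, polygons, stars, Fourier blobs,
multi-lobe forms) are parametric stand-ins for hand-drawn object outlines
with clear outer borders and large enclosed interiors; they reproduce the
enclosure-fill geometry but none of the stroke-level irregularity of
human drawings.

What passing tests on these responders do and do not show: they validate
the *analysis machinery* (border detection, shift statistics, evolution,
bootstrap) against planted ground truth, and they validate the full
training loop on a reduced-scale backbone. They do not certify behavior
on a full-scale pretrained network, which plugs in through the
`feature_extractor()` contract.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `total_width` | 0.2 | combined width of the K training bands (fraction of the hue circle) |
| `n_bins`, `samples_per_bin` | 100, 60 | evaluation grid: 6000 classifications per row |
| `n_train_per_class`, `n_val_per_class`, `epochs` | 500, 50, 5 | probe-head training; the best-validation epoch is kept |
| `class_counts`, `n_shifts` | 4:9, 150 | invariant experiment: 900 sessions, shift i spans the full circle as (i-1)/150 |
| smoothing `sigma` | 1.5 bins | circular Gaussian, mass-preserving (display/summary only; peaks use raw counts) |
| peak `min_separation`, `prominence_frac` | 5 bins, 0.10 | circular local maxima filtering |
| prototype weights | 1/(raw+1) | reciprocal transition count; +1 avoids division by zero |
| evolution | pop 100 = 10 elites + 90 offspring; tiers 55/30/15% over ranked quartiles, bottom quartile excluded; merge threshold 0.05; mutation rate 0.025, SD 0.025; 40 generations, mutation off after 30; 3 fitness epochs; 12 replicates | the published scheme |
| category bands | gap 5%, width 10% of span | two bands just inside each border pair |
| object bands | 2 per category, width span/5, centered on the half-centers | 14 disjoint bands |
| psychophysics | 35 targets x 35 shifts, 7 choices | 1225 trials per observer |

## Numerical choices

**Bin and edge conventions.** Bin `b` of `N` covers `[b/N, (b+1)/N)`;
evaluation hues are bin centers; transition edge `e` sits at hue `e/N`,
and edge 0 closes the circle. Band membership uses half-open circular
intervals so shared edges are unambiguous. Mode ties break to the lowest
class index; nearest-center ties likewise.

**Shift folding.** The optimal circular shift is the global argmax of the
summed x/y cross-correlation over all lags, folded into
`(-P/2, P/2]` with `P = round(n_bins/K)`. The fold uses the *true*
(fractional) class period `n_bins/K` before rounding: the row structure
repeats every `n_bins/K` bins, so folding an argmax several sub-periods
from the origin by the integer `P` instead would alias it (at
`n_bins = 100, K = 7`, the alignment residue of lag 94 is -6, while
94 mod 14 would report -4). True-period folding keeps a rotation by 3
bins at +3, reports a 10-bin rotation as its residue -4, and gives the
borderless comparator its expected near-uniform shift distribution.
Ties break to the smallest absolute shift, negative first. The
borderless comparator can be simulated at any label-noise level; note
that near half-period offsets its correlation landscape is a shallow
plateau, so the measured distribution is cleanest when the comparison is
driven by the row geometry rather than by noise.

**Fisher comparison.** Positive-shift count tables (r x 2 or r x 3) are
tested exactly up to a table total of 200 and by Monte-Carlo (1e5 draws,
standard error reported) above it. The overlap between two shift
histograms is the histogram intersection, `100 * sum(min(p_i, q_i))` on
normalized frequencies — reported prominently because "overlap" admits
several definitions and downstream numbers depend on this one.

**Recombination merging.** Borders from the two parents are merged
closest-first into their circular mean when less than 0.05 apart, with a
disjoint matching; a border that could participate in more than one
candidate pair has its working threshold halved, so crowded regions merge
conservatively. From the pooled borders, 7 are drawn uniformly without
replacement; exact duplicates are jittered by 1e-4 before the draw.
Initialization is i.i.d. uniform with redraws below a 0.02 pairwise gap.
Fitness evaluations receive seeds derived from (run seed, generation,
member), and elites carry their fitness forward, which makes the best
recorded fitness non-decreasing by construction.

**Analytic fitness oracle.** For desk-scale testing the learning-speed
fitness has a closed form: assign each planted category to the candidate
class holding the largest share of its band mass and average the assigned
shares. It equals 1 exactly at the planted truth, is flat within the 5%
band gap (moving a border less than the gap does not move any band across
a planted border), and decreases beyond it; crowding several classes into
one category is penalized because one class per category at most can be
assigned. The trained-head fitness is the faithful path; the two rank
random border sets concordantly on a categorical backbone.

**Degenerate inputs.** Border sets with a category span below 0.02 are
rejected (`bands_from_borders`) or scored 0 with a `degenerate` flag
(fitness paths). Flat transition signals yield an empty border estimate
rather than an error. Empty outlines yield an empty enclosure mask.

**Observer simulator.** Each observer owns a jittered copy of the planted
borders. A trial's choice is any option whose category matches the
target's: the first such option, deterministically — the chosen class is
then constant within a category, so ties leak no sub-category structure
into the transition counts (a nearest-hue tie rule would plant
choice-set-midpoint transitions shared by *all* observers and
mis-calibrate the bootstrap null). With no category match the closest hue
is chosen; lapses pick uniformly. The bootstrap statistic is the mean
pairwise Pearson correlation of per-bin transition counts; the null
shifts each observer's counts circularly by an independent uniform
offset, which preserves each profile's shape and autocorrelation while
destroying alignment.

## Problem sizes

Module tests run at reduced sizes (tens of training samples, 5-10
evaluation samples per bin, populations of 40) chosen so the full suite
completes in about two minutes while exercising every code path at the
published geometry. The end-to-end checks use the desk preset — 50
shifts, class counts 5-7, 100 training / 20 validation samples per class,
10 evaluation samples per bin, and 3 evolutionary replicates at
population 100 for 40 generations — the package's reference configuration
for single-CPU runs; `scale_preset("paper")` restores the published
counts. The desk preset changes counts only, never formulas or
thresholds.

## Known limitations

* The backbone is a small dense network on downsampled rasters, not a
  deep convolutional model; it demonstrates the pipeline's recovery
  behavior, not full-scale emergence. External pretrained extractors can
  be wrapped with `feature_extractor()`.
* The packaged bitmap fonts are stylized 5 x 7 designs; pixel-exact
  reproduction of any particular TrueType rendering is out of scope.
* At 35-bin psychophysics resolution with 7 choices, category pairs much
  narrower than the choice spacing are at the edge of detectability, for
  the same power reason as in the probing experiment.
* Perceptually uniform color spaces (CIELAB and relatives) are
  intentionally not used: the analysis lives in the HSV/RGB geometry of
  the representation under study.
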