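# huecat

Tools for detecting **emergent color categories** in a learned visual
representation. The package is aimed at researchers in computational
neuroscience and vision science who want to ask whether a
representation — a frozen network layer, an analytic responder, a human
observer's match-to-sample choices — treats the hue circle continuously
or carves it into categories, without ever asking the system to *name* a
color.

## The method

Hues live on the circle as fractions h ∈ [0, 1), rendered at full HSV
saturation and brightness (the edge path of the RGB cube). A frozen
feature extractor φ maps a 224×224 raster to a D-vector; a linear probe
head (softmax readout) is trained to classify colored-word stimuli whose
hues are drawn from K narrow training bands with centers at
s + k/K (k = 0…K−1) and combined width 0.2. The head is then evaluated
over the whole spectrum (100 bins × 60 samples) and summarized by the
per-bin modal class — the *mode row*. Repeating this for K = 4…9 and 150
band shifts s gives 900 mode rows; edges where a mode row changes class
are summed into the **transition count** T(e). Category borders are the
circular peaks of T; each category's prototype is the circular mean of
its member-bin hues weighted by 1/(T+1).

Border invariance is quantified by the pairwise **optimal circular
shift**: rows are mapped to unit-circle coordinates
(cos 2πh, sin 2πh), cross-correlated at all lags, and the best lag is
folded into (−P/2, P/2] with P = round(100/K). A categorical
representation keeps |shift| ≤ 2 for most pairs; a borderless one spreads
shifts across the period. The two count tables are compared with Fisher's
exact test and a histogram-intersection overlap.

Two further experiments probe the same structure from different angles:
an **evolutionary search** over 7-border partitions whose fitness is
learning speed (validation accuracy of a 3-epoch readout trained on bands
placed just inside each candidate category; elitism 10/100, tiered parent
selection 55/30/15% over ranked quartiles, closest-first border merging
below 0.05, 2.5% mutation with SD 0.025, 40 generations), and a
**psychophysics module** applying the identical transition/peak analysis
to 35×35 match-to-sample observer tables, with a bootstrap null built by
circularly shifting each observer's transition counts.

All stimuli (colored words, multi-word distractor scenes,
enclosure-filled outline shapes), responder models and a small
scratch-trained backbone are generated in code, so every analysis is
reproducible end-to-end from a seed.

## A worked example

Recover planted category borders from a noisy categorical responder
(the desk-scale stand-in for a trained network):

```r
library(huecat)

planted <- default_planted_borders()  # 0.045 0.125 0.21 0.40 0.52 0.63 0.84
model   <- categorical_responder(planted, label_noise = 0.05)
rows    <- simulate_row_stack(model, class_counts = 5:7, n_shifts = 50,
                              grid = eval_grid(100, 60), seed = 11)

tc      <- accumulate_transition_counts(rows)
borders <- detect_peaks(tc)
protos  <- compute_prototypes(borders, tc)
tc; borders; round(protos, 3)
```

```
<transition_count> 100 bins, 150 rows, total transitions 900
<border_estimate> 7 borders: 0.040, 0.120, 0.210, 0.400, 0.520, 0.630, 0.840
  left right prototype    r    g     b
1 0.04  0.12     0.085 1.00 0.51 0.000
2 0.12  0.21     0.170 0.98 1.00 0.000
3 0.21  0.40     0.310 0.14 1.00 0.000
4 0.40  0.52     0.465 0.00 1.00 0.790
5 0.52  0.63     0.580 0.00 0.52 1.000
6 0.63  0.84     0.740 0.44 0.00 1.000
7 0.84  0.04     0.945 1.00 0.00 0.332
```

All seven planted borders are recovered to within half a bin (peaks sit
on the 1/100 edge grid), and the prototypes are the orange, yellow,
green, cyan, blue, purple and red-pink representatives of their
categories. The shift signature confirms the borders barely move as the
training bands slide:

```r
shift_distribution(Filter(function(r) r$K == 7, rows))
```

```
<shift_histogram> period 14, 1225 pairs, 99.8% with |shift| <= 2
```

The same pipeline runs end-to-end on a trained representation: train a
small backbone on the planted categories with
`make_scratch_category_backbone(planted, seed = 42)`, pass it to
`run_invariant_experiment()`, and the detected peaks land within 0.01 of
the planted borders. Higher-level drivers live behind
`run_pipeline(run_config("invariant" | "evolution" | "within_category" |
"objects" | "psychophysics", seed, scale = "desk"))`.

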