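# pigeonpix

Analysis pipeline for two-alternative forced-choice discrimination of
pixelated patterns by pigeons.

In the underlying paradigm, pigeons learn to discriminate two reinforced
training patterns shown on 5×7 LED matrices — a Z-shaped pattern (Z\*) and a
Viking-cross / H-shaped pattern (H\*), each of 13 lit pixels — and are then
probed with unreinforced "generalization" test pairs of degraded patterns.
Every pixel location is classified against the training pair as **z** (lit
in Z\* only), **h** (lit in H\* only), **zh** (lit in both) or **n** (lit in
neither); for the canonical pair the counts are 10 z, 10 h, 3 zh and 12 n.
The package implements the analyses this design supports:

- **Discriminability indices.** The base index of a test pair is
  `z_Z + h_H`: the number of lit z pixels in its Z-like member plus the
  number of lit h pixels in its H-like member (range 0–20). Variants
  subtract the cross-class "inhibitory" counts (`h_Z + z_H`), or add the
  ambiguous `zh` and neutral `n` lit counts; a *select index* (range 0–14)
  restricts the count to 8 z and 6 h salient cluster locations.
- **Translation-tolerant registration.** Translocated test patterns are
  re-registered against their training reference by maximizing matched-lit
  overlap over shifts up to ±2 rows/columns, converting matrix-centred to
  pattern-centred pixel counts before classification.
- **Classification-image maps.** Per-location point-biserial correlations
  between a pixel's lit indicator (1/0 across tests) and the percent choice
  scores, with zero-variance masking, 8-neighbour cluster extraction at a
  salience threshold (r ≥ 0.30, p < 0.01 at n = 84), pooled-cluster
  correlations and two-pixel configural-feature comparisons.
- **Cohort analyses.** Replication (repeat tests vs session gap),
  relativity (same pattern, changing partner, preference flips), exact
  binomial tail tests, across-team concordance of mean choice preferences
  and inter-individual score correlations.
- **A generative simulator.** Choices are simulated per trial from a
  logistic rule on summed per-pixel evidence weights,
  `P(correct) = 1 / (1 + exp(-βE))`, with planted salient locations, two
  reward-mirrored 3-bird teams, team-level and per-bird weight
  idiosyncrasies, and a master seed making every run byte-reproducible. This
  lets every stage of the pipeline be exercised and validated without any
  behavioural data.

## Worked example

```r
library(pigeonpix)

pair <- training_pair("A")
case <- test_case(pair$grid_Z, pair$grid_H, test_id = 1)
index_breakdown(case, pair)
#> Index breakdown (test 1): base=20  -inhib=20  +zh=26  +n=20
#>   z_Z=10 h_H=10 z_H=0 h_Z=0 zh=6 n=0 richness=26
```

Presented as its own test pair, the training pair attains the index maximum
of 20 (all 10 z and all 10 h pixels lit in their own members, no cross-class
intrusions) and the maximum pair richness of 26 lit pixels.

```r
sim <- simulate_experiment(sim_config(seed = 5))
sim
#> Simulated experiment: 84 tests x 6 pigeons x 20 trials (seed 5)
#> mean percent correct: 75.9

scores <- test_scores(sim$choices)
cc <- index_choice_correlation(sim$cases, scores, "base")
sprintf("r = %.2f, p = %.2g, n = %d", cc$r, cc$p, cc$n)
#> "r = 0.56, p = 3.8e-08, n = 84"

team_concordance(sim$choices)
#> Teams concordant on 81 of 84 tests (exact binomial p = 5.11e-21)

mapZ <- pixelwise_correlation(sim$cases, scores, side = "Z")
salient_clusters(mapZ, r_threshold = 0.30)
#> 2 cluster(s) at r >= 0.30 (8-neighbour connectivity)
#>   [1] ii5
#>   [2] vi4 vi5

top_salient_locations(mapZ, 8)
#> [1] "vi5"  "vi4"  "ii5"  "ii2"  "v2"   "iii4" "ii1"  "vi2"
```

The simulated cohort behaves like the analyses assume: the base index
correlates strongly with the per-test mean choice scores, the two
oppositely rewarded teams agree on almost every test, and the top-ranked
map locations are dominated by the planted salient z pixels (7 of these 8
are planted; `ii5` is the one interloper). `analysis_report()` runs all
stages at once and writes TSV/JSON artifacts to a directory.

## Documentation

The methods vignette (`vignettes/pixel-pattern-analysis.Rmd`) describes the
model and its assumptions, the reconstruction of the training-pattern
fixtures, the registration and clustering conventions, the generative
choice model and its calibration, and known limitations.
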