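---
title: "Methods: analysing pixel-pattern discrimination by pigeons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing pixel-pattern discrimination by pigeons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigeonpix)
```

## The paradigm and the data model

This package analyses a two-alternative forced-choice paradigm in which
pigeons first learn to discriminate two reinforced training patterns shown
on 5×7 red-LED matrices — a Z-shaped figure (Z\*) and a Viking-cross /
H-shaped figure (H\*), each of 13 lit pixels — and are then probed with
non-reinforced pairs of degraded test patterns. On every test trial the
bird chooses one member of the pair; the percentage of choices of the
member judged similar to the bird's rewarded training pattern is its
percent-correct score for that test. Three pigeons are rewarded on Z\*
(team `Z+H-`) and three on H\* (team `H+Z-`), so the two teams' scores
measure the same discrimination from opposite reward assignments.

Everything rests on four data structures: the `pixel_grid` (a 7×5 logical
matrix; rows are labelled i–vii top to bottom and columns 1–5, so `"iv3"`
names the matrix centre), the `training_pair`, the `test_case` (one test
session's pattern pair plus session/repeat bookkeeping) and the
choice-record table (one row per pigeon per test). Percent scores stay on
the 0–100 scale throughout; proportions appear only inside the choice
simulator.

## Pixel classes and the canonical fixtures

Classifying the 35 locations against a training pair yields the labels
**z** (lit in Z\* only), **h** (lit in H\* only), **zh** (lit in both) and
**n** (lit in neither). For the canonical pair A the counts are 10/10/3/12;
the 20 z and h locations are the differential pixels that carry all the
discriminative information, and the outer rows i and vii contain 10 of the
12 neutral locations.

The shipped pair-A grids were reconstructed from the published textual
description of the stimulus set, which constrains them essentially
uniquely: 13 lit pixels per pattern within the 5×5 core; the class counts
above; the Z diagonal running between the vertex pixels ii5 and vi1; h
pixels at iii1 and v5 and on the central meridian at iii3 and v3; and a
salience topology in which 8 z locations form four two-pixel clusters
(top-left, top-right, lower-left, lower-right) while 6 h locations form two
three-pixel clusters inside potential four-pixel left and right arms. The
test suite verifies all of these properties jointly, including the derived
fact that rotating Z\* clockwise by 90° produces a pattern whose h-pixel
count exceeds its z-pixel count — the rotated Z reads as H-like.

Variant B (each pattern with 4 pixels left unlit) is anchored in the text
only by the two Z\* vertex pixels ii5 and vi1 that this pair was designed
to de-emphasize; the remaining removals are the package's own
reconstruction and should be treated as synthetic. Variant C shifts Z\* one
row south and H\* one row north; published descriptions of this pair
disagree about which pattern moved in which direction, and the package
follows the training-procedure account (Z south, H north). No quantitative
result in the package depends on the B or C fixtures.

## Discriminability indices

For a test pair, `index_breakdown()` counts lit pixels per class and
member. The base index is `z_Z + h_H` — lit z pixels in the Z-like member
plus lit h pixels in the H-like member, range 0–20. Three conventions
matter:

- `zh_lit` and `n_lit` are summed over *both* members (giving the 0–6 and
  0–8 ranges seen in practice: 3 zh locations × 2 members = 6). The
  per-member alternative was rejected because it cannot reach the stated
  zh ceiling.
- Rows i and vii participate in n counts everywhere; they are rare but not
  excluded from index arithmetic.
- The "inhibitory" variant subtracts the cross-class counts `h_Z + z_H`;
  the `plus_zh`/`plus_n` variants add the ambiguous/neutral lit counts.

The select index applies the same `z_Z + h_H` count restricted to the 8 z
and 6 h salient cluster locations (`salient_sets()`), range 0–14, and
validates that the supplied sets are genuinely z- and h-class locations.

## Translation-tolerant registration

Translocated test patterns are re-registered to pattern-centred coordinates
before classification: `register_to_reference()` searches all integer
shifts within ±2 rows and ±2 columns and keeps the shift maximizing the
number of lit pixels coinciding with the training reference's lit pixels.
Ties break by smaller `|d_row| + |d_col|`, then by a fixed scan order
(north before south, west before east), making the result deterministic.
Each member is registered against its own class's reference (Z-like against
Z\*, H-like against H\*). The overlap objective is the package's
interpretation of an adjustment that is defined in the source material only
by worked examples; maximizing matched-lit overlap reproduces the intent of
all illustrated cases. The ±2 bound reflects the behavioural finding that
one- and two-row displacements were compensated by the birds while a
four-row displacement was not: a shift requirement beyond the bound is
simply not applied. Translation semantics are curtailing — pixels shifted
past the frame edge are dropped, with no wrap-around — matching the
pixel-curtailed stimuli used for east–west displacements.

## Choice scores and correlation machinery

The per-test score entering all correlations defaults to the unweighted
mean of the per-pigeon percentages (`test_scores(..., method = "mean")`);
a pooled-trials percentage is available as an option, since either
aggregation is defensible and the source material does not say which was
used. Correlations are plain Pearson product-moment coefficients; with a
0/1 lit indicator this is exactly the point-biserial case, so no separate
formula is implemented. Two-sided p-values use the t transform
`t = r√(n−2)/√(1−r²)`; at n = 84 this maps r = 0.30 to p < 0.01 and
r ≈ 0.21 to p ≈ 0.05, the thresholds used for salience calls.

`pixelwise_correlation()` builds the classification-image map: for each of
the 35 locations, the correlation between its lit indicator across tests
(on one pair side) and the score vector. Locations that are never or always
lit have an undefined coefficient and are masked — they are *not* assigned
r = 0, and they never enter clusters. `salient_clusters()` extracts
connected components of supra-threshold locations under 8-neighbour
connectivity (horizontal, vertical and diagonal contact); the published
cluster descriptions include diagonal contact, and the weaker salience of
diagonal neighbours discussed there concerns salience, not grouping, so
8-connectivity is the faithful choice. `top_salient_locations()` ranks map
coefficients and by default restricts ranking to the core rows ii–vi: the
outer rows are lit in only a handful of tests, and coefficients estimated
from one or two presentations are sampling noise; the published salience
figures likewise omit those rows.

The two-pixel feature analysis treats any two neighbouring (Chebyshev
distance 1) same-class salient pixels as a candidate configural feature,
correlating the both-lit indicator with the scores, and compares the mean
against an equal number of clearly non-neighbouring (Chebyshev distance
≥ 2) same-class control pairs sampled with a documented seed. Similar
means in the two groups argue against a distinct feature-extraction
strategy over and above single-pixel evidence.

## Cohort analyses

Replication rows pair each repeated test with its previous presentation of
the identical pair (difference = later − earlier score; gap = session
difference). The relativity analysis tracks every pattern — identified
content-addressedly by its serialized grid, so "the same pattern" means
bit-exact equality — across tests with changing partners, expressing each
occurrence as a Z-likeness (the score if the pattern was the Z-like member,
100 − score otherwise) and flagging flips across the 50% line.

`binomial_test()` computes exact binomial tail probabilities (tail
summation via the distribution function, no normal approximation; verified
in the tests against full enumeration of the fair-coin outcome distribution
for all n ≤ 20). Concordance between teams is directional — both teams
agreeing with the same Z/H assignment above chance — so the one-sided upper
tail is the default. A test is concordant when both team means fall
strictly on the same side of 50%; an exact 50 expresses no preference and
conservatively breaks concordance, a tie rule the source material leaves
open.

## The generative choice model

The simulator is the package's own construction: the analysed paradigm
posits no generative model, so the package supplies the minimal one
consistent with the evidence-count reasoning behind the discriminability
index. Each simulated pigeon carries a 7×5 evidence-weight map — positive
on its rewarded class's pixels, negative on the punished class's, zero on
zh and n pixels — and on each test accrues evidence
`E = Σ w(lit, correct member) − Σ w(lit, other member)`, choosing the
designated-correct member with probability `plogis(β·E)` independently on
each of its 20 trials.

Defaults encode the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| `n_tests` | 84 | number of test sessions in the emulated design |
| `richness_range` | 4–26 | lit pixels per pair in the test materials |
| `n_repeat_pairs`, `n_triple_pairs` | 17, 2 | 19 repeat events (17 pairs twice, 2 of them thrice) |
| `repeat_gap_range` | 8–49 sessions | observed replication gaps |
| `n_pigeons`, `trials_per_test` | 6 (3+3), 20 | cohort and session structure |
| `lit_rates` | own 0.51, cross 0.22, zh 0.61, inner n 0.19, outer n 0.02 | per-location lit frequencies matching the published presentation-frequency profile |
| `weight_salient`, `weight_base` | 3, 0.25 | planted salience on the 8 z + 6 h cluster locations; ordinary class pixels keep a weak weight, reflecting the finding that a minority of locations dominated choices |
| `β` | 0.1 | calibrated so the default cohort averages ≈ 75–80% correct |
| `jitter_sd`, `team_jitter_sd` | 0.2, 1.0 | per-bird idiosyncrasy and a team-shared weight component |

The team-level jitter deserves a note: with exactly mirrored team weights
and only independent per-bird jitter, within-team and between-team
inter-individual correlations coincide by symmetry. Real cohorts show
markedly higher within-team than between-team agreement, so a team-shared
idiosyncratic component is structurally necessary; its default is the
largest value at which the planted-salience recovery property below still
holds.

Suites are sampled by drawing each member's lit pixels independently at the
class rates and rejecting pairs outside the richness range; repeats reuse
earlier pairs at scheduled gaps with strictly increasing session indices.
All randomness flows from one master seed: identical configurations give
byte-identical suites and choice tables.

What the generator deliberately does **not** emulate: trial-by-trial
learning dynamics (overshadowing, blocking, drift across phases),
translocated or rotated test patterns (those are exercised through
constructed cases), partner-dependent relativity in the generative rule,
within-session sequencing effects, and reaction times. Passing recovery
tests on synthetic cohorts therefore shows that the estimators recover the
structure this model plants — not that real birds obey the model.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles: naive
double-loop recomputation for the pixel-wise maps, a hand-evaluated
product-moment value, permutation calibration of analytic p-values,
convolution enumeration for the binomial tail, and brute-force shift
search for registration. Stochastic properties use fixed seeds and
pre-registered bands: across ten seeded default cohorts (84 tests × 6
pigeons × 20 trials), the top-8 Z-side map locations recover at least 6 of
the 8 planted z locations on a majority of seeds; the base-index/score
correlation falls in 0.5–0.95 on a majority of seeds; and with β = 0 the
share of map locations reaching p < 0.01 stays inside a 99.9% binomial
band around the nominal 1%. These sizes keep the full suite under half a
minute while leaving the stochastic checks well-powered.

## Known limitations

- The pair-A fixture is a reconstruction from a textual description, not a
  facsimile of the original stimulus artwork; variant B beyond its two
  anchored pixels is explicitly synthetic.
- The registration objective (matched-lit overlap) is an interpretation of
  an adjustment defined only by example; alternative objectives (e.g.
  index-maximizing shifts) could differ on pathological patterns.
- Headline correlation magnitudes from real cohorts depend on the exact
  deposited choice data and test materials and are not reproduced by the
  synthetic generator; the package validates machinery and structural
  constants, not empirical effect sizes.
- The importer for deposited spreadsheet data is limited to the documented
  choices-CSV layout; adapting other layouts is the caller's job.
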