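---
title: "Methods: simulating and analyzing layout-perception studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing layout-perception studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(layoutstudy)
```

## The study being modeled

The pipeline implements a perceptual study design for spatial-connectivity
data: viewers are shown a segmented 3D chain with a single highlighted
contact and asked to identify, from a 2D encoding, which pair of segments
touches. Three encodings are compared — a full adjacency matrix, its upper
half, and a circular chord diagram. The design constants live in
`study_config()`: an 8-segment chain; contacts must span a sequence
separation of at least 3, which yields a family of exactly 15 contacts;
five answer options per question; and every question duplicated once, so
each participant sees 30 presentations. The 3D rendering parameters
(3° rocking, 136 frames over 3 s) are carried in the config for provenance
only — nothing downstream uses them.

Each question's options always include the *inverted answer* where one
exists: the contact obtained by reading the chain backwards
(`i -> n + 1 - i`). Contacts with `a + b = n + 1` (3–6, 2–7 and 1–8 on
eight segments) are their own inversion and contribute no such option.
The inverted answer is the instrument that separates "misread the 3D
model's direction" from "misread the 2D layout". Distractors are drawn
without replacement from the same 15-contact family (minus the correct and
inverted answers) rather than from all 28 possible pairs: every option is
then a stimulus that could occur in the study, which keeps distractors
visually plausible. Surveys are randomized per participant — question
order, option order within each presentation, and the distractor draw are
all independent — and no spacing constraint is placed on where a duplicate
lands relative to its first showing.

## The behavioral model

`participant_profile()` parameterizes a respondent:

| parameter | meaning | unit / range | default |
|---|---|---|---|
| `p_correct` | probability of reading the model correctly | [0, 1] | 0.9 |
| `p_invert_given_error` | probability a misread is a direction inversion | [0, 1] | 0.6 |
| `separation_bias` (γ) | error skew toward contacts closer in sequence | ≥ 0 | 0.8 |
| `proximity_bias` (β) | error skew toward near-miss contacts | ≥ 0 | 0.6 |
| `rt_plateau` | asymptotic response time | s > 0 | 6 |
| `rt_amplitude` | initial excess over the plateau | s ≥ 0 | 10 |
| `rt_decay` (λ) | per-presentation decay rate | ≥ 0 | 0.3 |
| `rt_noise_sd` (σ) | log-scale response-time noise | ≥ 0 | 0.45 |
| `memory` (ρ) | probability of repeating one's earlier answer on a duplicate | [0, 1] | 0.7 |

A choice is drawn as: repeat the earlier answer with probability ρ on a
duplicate; otherwise the correct option with probability `p_correct`;
otherwise an inverted reading with probability `p_invert_given_error`;
otherwise a distractor with weight
`exp(-β · MinDistance(d, correct) − γ · (sep(d) − sep(correct)))`.
Two modeling points deserve emphasis:

* **Inversion on self-symmetric questions yields the correct answer.** An
  inversion is a property of how the viewer reads the 3D model, not of the
  layout; when the contact is its own inversion, the misreading is
  harmless. This matters quantitatively: with 12 invertible and 3 symmetric
  questions the expected share of inversions among errors is
  `12p / (15 − 3p)`, which ranges up to 1 — whereas a model in which the
  inversion branch simply falls through on symmetric questions caps the
  share at 12/15 = 0.8 and could not generate the high inversion shares the
  circular layout produces. `invert_rate_for_share()` inverts the relation
  (`p = 5·share / (4 + share)` for this design) so cohorts can be generated
  with a target share.
* **Answer memory is explicit.** Consistency differences between layouts
  cannot be expressed through accuracy alone (two layouts with equal
  accuracy can differ in how repeatable their misreadings are), so ρ models
  the recall of one's earlier answer directly.

Response times follow a decay-to-plateau curve
`rt(k) = (plateau + amplitude · e^{−λ(k−1)}) · ε` with multiplicative
lognormal noise ε. The noise is mean-one (`exp(σZ − σ²/2)`), so expected
times sit exactly on the deterministic curve for any σ; times are positive
and right-skewed, which is why the analysis plots them on a log scale. The
decay-to-plateau form itself is a modeling choice validated only
qualitatively — no quantitative response-time model is claimed.

A `random_clicker_profile()` chooses uniformly among the presented options
with ρ = 0. It is implemented as an explicit uniform choice model rather
than a parameter setting of the mixture, because with the symmetric-question
inversion rule above no mixture setting is exactly uniform over all five
options on every question. Its expected consistency is exactly 1/5, the
randomness threshold used for participant exclusion.

### Preset cohorts

`preset_cohorts("mturk")` (50 participants per layout, 4,500 responses) and
`preset_cohorts("expert")` (10 per layout, 900 responses) fix per-layout
profiles chosen once, at design time, by analytic calibration: inversion
rates from `invert_rate_for_share(0.845 / 0.566 / 0.605)` for the
crowdsourced preset; accuracies 0.92/0.82/0.80; memory values solved from
`consistency = ρ + (1 − ρ)·P(agree | independent redraws)` so that the
half-matrix and matrix cohorts sit about 10 and 8 percentage points of
consistency below the circular cohort; and response-time parameters chosen
so cohort mean times differ by about 5.6 s (half-matrix) and 6.4 s (matrix)
from the circular cohort, with the circular cohort reaching its plateau
fastest. The expert preset uses uniformly high memory (no consistency
differences), accuracy ordered circular ≈ half-matrix > matrix, and the
matrix cohort fastest. These presets emulate the *structure* of real
cohorts — they make no claim to reproduce any human dataset's values.

### What the simulator does not emulate

Participants are exchangeable within a cohort (no per-participant random
effects beyond the sampling noise), error rates are homogeneous across
questions given the symmetry split, there is no fatigue or attention drift,
qualification-test attrition is not modeled, and duplicate-answer memory is
all-or-none recall rather than graded familiarity. Passing parameter-recovery
tests on these cohorts therefore shows that the analysis battery measures
what the generator encodes — not that real viewers behave this way.

## Scores and filters

*Inter-segment distance* is `|a − b|` of the chosen contact minus `|a − b|`
of the correct one: 0 for correct answers and inversions, negative when the
chosen segments are too close in sequence. *MinDistance* is the total
index displacement `|a_c − a_t| + |b_c − b_t|` minimized over the direct
and inverted readings of the chosen contact; the inverted reading re-sorts
the pair ascending, so contacts stay canonical and the fixed first-with-first
pairing of endpoints is optimal (the test suite checks this against a
brute-force minimizer over all endpoint pairings, for all 15 × 15 contact
pairs). The error taxonomy (`correct` / `inversion` / `inverted_missing` /
`other`) partitions every response; class fractions are reported over
incorrect answers only, the inter-segment distance distribution over
incorrect answers only, and the MinDistance distribution over all answers.

Filtering happens in a fixed order: responses slower than 5000 s are
removed first; consistency is then computed per participant and anyone at
or below 20% (an inclusive bound) is excluded entirely; accuracy and all
downstream scores use only retained responses of retained participants.

Learning curves average the two response times of each duplicated question
into one pair value per participant. Because presentation order of a
duplicate relative to its partner is not assumed recorded, the pair is
placed at the rank of its *earlier* presentation index — the closest
monotone analogue of "questions 1 through 15" — and the k-th curve point is
the cohort mean of the k-th ranked pair value.

## Inference

`analyze_study()` runs, on the filtered data: one-way ANOVA with Tukey HSD
post hoc for consistency, raw response times and pair-averaged learning
times; pairwise Pearson chi-squared tests of independence (no continuity
correction — the designed group sizes keep expected counts large, and the
uncorrected statistic is reported as-is when they are not) for accuracy and
for the inversion share of errors; and tie-corrected Kruskal–Wallis with
Dunn post hoc z tests for the two score distributions. The Dunn test is
implemented in the package (no installed dependency provides it) and is
pinned to `kruskal.test` through the identity z² = H for two groups, which
holds with the tie-corrected variance
`N(N+1)/12 − Σ(t³−t)/(12(N−1))`. Multiple-testing adjustment defaults to
Benjamini–Hochberg and can be switched to Holm or Bonferroni; Tukey
p-values are already family-adjusted and are not re-adjusted. Significance
is flagged at α = 0.05, and every adjusted p-value is at least its raw one.

Degenerate inputs are defined rather than left to error: identical values
everywhere give statistic 0 and p = 1 for ANOVA and Kruskal–Wallis; a 2×2
table with a zero margin reports an NA (not-applicable) test; a cohort with
zero errors reports an empty breakdown with n = 0.

### A caveat on response-level tests

The accuracy and score tests treat responses as independent observations,
but duplicated questions answered from memory (ρ > 0) are correlated within
participant. Under a null simulation with ρ = 0.6 the response-level
chi-squared test's rejection rate roughly quadruples relative to its
nominal 5% level — a pseudo-replication property of analyzing 30 correlated
responses per participant, not of any particular implementation. The
type-I calibration in the test suite therefore uses memory-free null
cohorts, which satisfy the tests' independence assumptions; analysts of
real data should read the response-level p-values with this caveat in mind
(participant-level aggregation is the conservative alternative).

## Numerical and design choices

* Segments are 1-based and contacts stored ascending everywhere; the
  inversion map `i -> n + 1 − i` generalizes the 8-segment design to any
  chain length.
* The circular layout places segment 1 at twelve o'clock, numbering
  clockwise, with the chord joining arc midpoints; the half-matrix is a
  45°-rotated triangle on an alternately shaded base row; matrix diagonal
  shading starts light gray at segment 1. Orientation and anchoring are
  conventions chosen for determinism; only the category-level fills
  (light/dark gray, green) are contracted.
* SVG serialization is hand-rendered from the geometry primitives with
  fixed 4-decimal coordinate formatting and no timestamps, so identical
  geometry yields byte-identical files.
* Simulation is reproducible from a single integer seed; analysis of a
  given table is fully deterministic.
* Problem sizes used in the shipped tests: full presets (4,500 and 900
  responses) for structural checks; 50 × 30 single-layout cohorts for
  parameter recovery (3 Monte-Carlo-SE tolerance); 10,000 random clickers
  for the consistency baseline; 60 null replicates of 3 × 12-participant
  cohorts for type-I calibration (bound α + 3 SE). These sizes give
  Monte-Carlo error well inside every tolerance asserted.

## Known limitations

The simulator's behavioral assumptions are listed above; in addition, the
pipeline does not model qualification screening, does not weight contacts
(one unweighted contact per model), does not encode contact strength in the
layouts, and makes no attempt to reproduce the numerical results of any
human cohort — those require the original response data. Heat-map color
scales, arc-thickness encodings, edge bundling and interactive linking are
out of scope.
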