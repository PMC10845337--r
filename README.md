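# layoutstudy

Design, simulation and analysis of multiple-choice perceptual studies that
compare 2D visual layouts for 3D spatial-connectivity data.

## The problem

Pairwise spatial contacts on a segmented chain — the kind of data produced by
chromosome-conformation-capture (3C) experiments — are conventionally drawn
in one of three ways: a full **adjacency matrix** (cell *(i, j)* marks a
contact between segments *i* and *j*, symmetric about the diagonal), a
**half-matrix** (the upper triangle only, removing the redundant half), or a
**circular layout** (segments as arcs on a circle, contacts as explicit
chords). Which encoding do viewers actually decode most accurately and most
intuitively?

`layoutstudy` packages the full experimental pipeline for answering that
question with a crowdsourced or expert multiple-choice survey:

* **Stimuli** — enumerate the admissible contact family on an *n*-segment
  chain (default: 8 segments, minimum sequence separation 3, giving 15
  contacts), attach to each question its *inverted answer* (the contact read
  in the opposite segment direction, `i -> n + 1 - i`; three contacts are
  self-symmetric and have none), fill the remaining slots with random
  distractors, and build per-participant randomized surveys in which every
  question is duplicated for consistency scoring (15 unique questions,
  30 presentations).
* **Layouts** — deterministic vector geometry for all three encodings of any
  contact, written as byte-stable SVG.
* **Respondents** — a synthetic cohort simulator with layout-dependent
  accuracy, inversion propensity, a bias of erroneous choices toward
  contacts closer in sequence than the truth, decay-to-plateau response
  times, and partial memory of earlier answers on duplicated questions.
* **Metrics and inference** — the complete analysis battery described below.

## The scores and tests

For a chosen contact (*A*, *B*)<sub>chosen</sub> and correct contact
(*A*, *B*)<sub>correct</sub>, both stored ascending:

* **Inter-segment distance** = |A − B|<sub>chosen</sub> − |A − B|<sub>correct</sub>.
  Zero for correct answers *and* for inversion errors; negative when the
  chosen segments are too close in sequence.
* **MinDistance** = min of |A<sub>c</sub> − A<sub>t</sub>| + |B<sub>c</sub> − B<sub>t</sub>|
  over the direct reading and the inverted reading
  (A<sub>c</sub> → n + 1 − A<sub>c</sub>, re-sorted) of the chosen contact.
  Zero exactly when the answer is correct or a pure inversion.
* **Error taxonomy** — every answer is `correct`, `inversion` (the inverted
  answer was chosen), `inverted_missing` (an error on a self-symmetric
  question, where inversion is excluded by symmetry), or `other`.
* **Consistency** — the fraction of duplicated questions a participant
  answers identically; 1/5 (20%) is the analytic baseline for a uniform
  random clicker with five options, and participants at or below that
  threshold are excluded.
* **Filters** — responses slower than 5000 s are removed as outliers before
  any analysis.
* **Inference** — one-way ANOVA with Tukey HSD post hoc (consistency,
  response times, pair-averaged learning-curve times), pairwise Pearson
  chi-squared tests of independence without continuity correction (accuracy,
  inversion share of errors), and tie-corrected Kruskal–Wallis with Dunn
  post hoc (inter-segment distance over errors, MinDistance over all
  answers), with Benjamini–Hochberg adjustment (configurable: `bh`, `holm`,
  `bonferroni`) at α = 0.05.

## Worked example

```r
library(layoutstudy)

tab <- simulate_study("expert", study_config(), seed = 1)  # 900 responses
fit <- analyze_study(tab)
fit
```

```
Layout perception study analysis
  900 responses retained (0 removed as outliers, 0 participants excluded)
  per-layout means:
    circular     n=10  consistency 0.987  accuracy 0.907  rt 6.42s
    half_matrix  n=10  consistency 0.987  accuracy 0.947  rt 10.41s
    matrix       n=10  consistency 0.967  accuracy 0.857  rt 6.26s
  significant pairwise contrasts (alpha=0.05): consistency 0/3, accuracy 1/3, rt 2/3
```

Each row is one simulated 10-expert cohort: its mean consistency on
duplicated questions, its response-level accuracy, and its mean response
time. The last line counts Tukey/chi-squared pairwise contrasts that remain
significant after adjustment. The error taxonomy among incorrect answers:

```r
fit$breakdown$class_fractions
#>       layout inversion inverted_missing     other n_errors n_answers
#>     circular 0.8571429                0 0.1428571       28       300
#>  half_matrix 0.3125000                0 0.6875000       16       300
#>       matrix 0.6046512                0 0.3953488       43       300
```

At this small cohort size the circular layout's errors are dominated by pure
3D-model inversions (not layout misreadings), while the matrix layouts show
more genuine decoding errors — the qualitative signature the simulator's
per-layout profiles encode. `summary(fit)` prints every test table,
`plot(fit)` draws the four overview panels, and `write_report(fit, dir)`
exports CSV tables, an SVG figure and a text summary. A command-line wrapper
for `simulate` / `analyze` / `render` / `report` lives at
`inst/cli/layoutstudy.R`.

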