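---
title: "Selective prediction for crop-photo classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective prediction for crop-photo classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropvision)
```

## The problem

Surveys such as LUCAS collect geo-tagged close-up photos of crops across
the European Union. A convolutional classifier trained on such photos
emits, for every image, a softmax vector over the twelve major crop
classes (B11 common wheat through B55 temporary grassland). Used
operationally — say, as evidence checking for agricultural subsidy
schemes — raw classifier output is not good enough: cereals are
notoriously confusable with one another and with grassland, and photos
taken under unfavorable conditions (blurry, too close, too early, and so
on) degrade badly. The practical remedy is *selective prediction*:
score each prediction's uncertainty, and abstain on the least certain
ones so that accuracy on the retained set rises.

This package implements that post-processing pipeline end to end — the
uncertainty scores, the automated threshold search, the quadrant
filtering rules, the evaluation metrics, the crop-calendar machinery
that defines which photos show a *mature* crop, and the cohort
construction — together with a synthetic-data generator that stands in
for the photo corpus and the CNN, so every step is testable at desk
scale.

## Uncertainty scores

For a softmax vector $p = (p_1, \dots, p_k)$ the package computes:

* **MP**, the maximum probability $p_{i^*}$ of the winning class
  $i^* = \arg\max_i p_i$ (ties to the lowest index, for
  reproducibility);
* **self-information** $h(p) = -\log_2 p$ and **Shannon entropy**
  $H = -\sum_i p_i \log_2 p_i$ (bits, with $0 \log 0 = 0$);
* the **expected information divergence** between the winning class and
  the rest,
  $$E[D] = \log p_{i^*} - \frac{1}{1 - p_{i^*}}
           \sum_{i \ne i^*} p_i \log p_i;$$
* the **equivalent reference probability**
  $$p^* = \frac{e^{E[D]}}{e^{E[D]} + k - 1} \in [0, 1].$$

ERP re-expresses the unbounded divergence as a probability-like score:
a uniform vector maps to $1/k$, a one-hot vector to $1$ (the analytic
limit; $E[D]$ returns an infinity sentinel there), and in between it
rewards vectors whose winning class stands far above a flat remainder.
It is this two-dimensional (MP, ERP) view that the filter exploits: the
two scores separate correct from incorrect predictions better than MP
alone.

Numerical choices worth noting: entropy and self-information are
reported in bits as is conventional, but $E[D]$ uses the natural log so
that the exponential in the ERP mapping inverts it — ERP itself is
base-invariant as long as the two steps agree. Probability entries
below $10^{-15}$ contribute zero to the divergence sum; ERP is
evaluated in the overflow-safe form $1/(1 + (k-1)e^{-E[D]})$; input
vectors must sum to one within $10^{-9}$.

## Threshold search and quadrant filtering

The threshold finder walks the grid $\{0, s, 2s, \dots, 1\}$ (default
step $s = 0.01$) and returns the largest threshold that discards at
most a settable fraction (default 1%) of the *correctly* classified
records — the most conservative filter the analyst can afford. The two
axes are searched independently and combined into four quadrants of the
(MP, ERP) plane; a value equal to its threshold counts as above, which
keeps the four quadrants an exhaustive partition. Four keep-rules are
provided: QM1 (MP above), QM2 (ERP above), QM3 (both), QM4 (either),
nesting as $QM3 \subseteq QM1, QM2 \subseteq QM4$. Quadrant numbering
(Q1 both above, Q2 ERP only, Q3 both below, Q4 MP only) is a labelling
convention, documented in the filter report.

Two caveats are inherent to the procedure and deliberately preserved.
First, the search *peeks* at the correctness labels of the records it
tunes on; thresholds are descriptive of that set, not an unbiased
estimate for new data. Second, with a 1% budget per axis, QM3 can
remove up to ~2% of correct records (union bound), which the tests
check.

```{r filtering-demo}
records <- scoreRecords(genRecords(seed = 42))
thr <- findThresholds(records, loss_frac = 0.01)
thr
before <- evaluate(confusion(records))
after <- evaluate(confusion(applyQuadrantMethod(records, thr, "QM3")$kept))
c(macro_f1_before = before$macro_f1, macro_f1_after = after$macro_f1)
```

## Evaluation

Confusion matrices are laid out true-by-predicted in the canonical LC1
order. Per class the package reports producer accuracy (PA, recall),
user accuracy (UA, precision) and their harmonic mean F1; overall
accuracy is the trace over the total; macro-F1 is the *unweighted* mean
of per-class F1, the right summary under heavy class imbalance. Classes
absent from both truth and prediction of the evaluated set are excluded
from the macro mean; a class present with $PA + UA = 0$ contributes an
F1 of zero. This zero-fill-if-present rule is one of two defensible
conventions for filtered subsets; it is deterministic and keeps a
filter that annihilates a weak class from silently inflating the mean.
PA/UA are stored as fractions and displayed ×100 with one decimal;
printed accuracy tables round half-up to two decimals (so 12/59
displays as 0.20).

Class grouping (e.g. the five cereals into one CEREAL class) sums rows
and columns, conserving the record total; grouping mutually confusable
classes can only move their confusions onto the diagonal, so overall
accuracy never drops. The condition report tallies true/false counts
and OA per unfavorable-condition tag and summarises the top-1
probability per condition against reference sets. The
resolution-accuracy diagnostic bins records by exact native
(width, height), regresses per-bin proportion correct on pixel count by
OLS, and reports $R^2$ — near zero when accuracy is independent of
native resolution.

## Crop calendars and maturity windows

Time is measured in half-months: index $2m - 1$ is days 1–15 of month
$m$, index $2m$ the rest, giving a circular 1..24 scale. Raw calendar
entries (country, crop, variety, stage, window, provenance) are
harmonized to one harvest window per (country, crop): where a country
cultivates both members of a variety pair, the winter (resp. early
ware) entry is kept and the row flagged; distinct windows for the same
(country, crop, variety) are treated as contradictory and refused;
non-official provenance (expert knowledge, model output) is carried
through as a `gap_filled` flag rather than being second-guessed.

The mature pre-harvest window is derived from the harvest window by
removing the last half-month and extending the start backwards — two
months (4 half-months) for cereals, rapeseed, sunflower and soya, three
months (6 half-months) for maize, potatoes, sugar beet and rice — with
all arithmetic modulo 24 so windows wrap across the year end.
Temporary grassland has no such rule; rather than guess silently, the
module requires an explicit override window for it (default: open all
year, flagged as overridden). Rice carries no LC1 code among the
twelve classes but stays in the rule table for completeness.

## Cohort construction

From the maturity-filtered clean photos the package draws the study
cohorts: a training sample of 400 per class, stratified across
countries proportionally to availability with largest-remainder
rounding (deterministic, and never more than one photo away from exact
proportionality); a balanced inference set of 85 per class drawn from
the leftover pool with per-class country proportions matching the
training sample; and an imbalanced inference set of all leftovers
capped at 1000 per class, retaining the balanced members first when a
class is capped. Training is disjoint from both inference sets and the
balanced set is contained in the imbalanced one — invariants checked on
every build.

One allocation subtlety: when a class's leftover pool is barely larger
than the balanced draw (the least-represented class leaves exactly 85
leftovers under the default tallies), a strict largest-remainder match
to the training geography can demand one more photo than some country
holds, because both sides carry ±1 rounding. The balanced draw
therefore caps each country at its availability and re-apportions the
excess over the remaining countries — as close to the training
geography as the pool permits. Class-level shortfalls still fail
loudly; only the within-class geography bends.

The unfavorable-condition sample draws at most one rejected photo per
(year, class, condition) cell — five survey years × twelve classes ×
six conditions — skipping empty cells rather than back-filling, and
reports them.

## The synthetic generator

The generator produces every input the pipeline needs, with the
statistical features the analysis relies on — and its defaults are
fixed study conditions, not tuning knobs:

* **Records.** Class counts default to the published per-class clean
  totals (15,876 in all), so imbalance is realistic. Each record is
  correct with its class's accuracy; defaults encode the study's error
  structure (cereals 0.35–0.72, grassland 0.65, maize 0.955, rapeseed
  0.93). Errors land on a destination drawn from a confusion kernel
  whose cereal block sends 60% of a cereal's errors to the other
  cereals and 25% to grassland. Softmax vectors are Dirichlet draws
  peaked on the target class — concentration 12 for correct, 2.5 for
  incorrect, base 0.4 elsewhere — rejection-resampled (bounded at
  1,000 rounds) so the argmax equals the target. The two
  concentrations are what produce the bimodal MP marginals (correct
  predictions peak high, errors low) that make quadrant filtering
  work; they were chosen once to reproduce that qualitative shape.
* **Photos.** Per-(country, class) counts default to the published
  tally; dates fall inside the cell's maturity window with probability
  0.9 by default (1.0 where a test needs every photo mature);
  resolutions come from a mix dominated by 1600×1200 (66%) and
  2048×1536 (22%) with a long tail of other device resolutions.
* **Calendars.** Harvest windows of 2–6 half-months around
  crop-typical harvest periods, with optional injected variety
  conflicts to exercise harmonization.
* **Images.** Tiny (16×16) matrices whose classes differ in mean
  intensity and stripe frequency — enough for a linear classifier to
  separate configured classes and to sit at chance when classes share
  parameters.

What the generator does *not* emulate: photo content (no pixels
resembling crops at corpus scale), intra-class phenological variation,
label noise in the truth, and any dependence of classifier accuracy on
resolution or condition tags (these are attached independently). Tests
passing on synthetic data therefore validate the *pipeline logic* —
scores, thresholds, cohort arithmetic, metric algebra — not the
recognisability of real crops.

## The search harness

The two-round random hyperparameter search is implemented
classifier-agnostically: a trainer is any function
`(config, train) -> predictor`. Round one samples `n_round1`
configurations (learning rate log-uniform in $[10^{-4}, 10^{-2}]$,
batch size in {256, 512, 1024}, momentum in {0, 0.9}, optimizer among
plain gradient descent, momentum, and adaptive moments — bounds chosen
to contain the winning configurations reported for this kind of
search), ranks them by test overall accuracy (ties by validation
accuracy, then trial id), and re-runs the top five with augmentations:
random horizontal flip (probability 0.5) and a uniform brightness shift
clipped back to [0, 1]. The harness passes only training data to the
trainer — a contract the tests audit with a recording stub. The
shipped `softmaxTrainer()` is a deliberately small multinomial-logistic
model on centred raw pixels; it exists so the protocol runs end to end
in seconds, not to approximate a CNN.

Desk-scale defaults used throughout the tests and the acceptance
script: 8 round-1 trials, top 3 finalists, 3 classes × 20 training /
15 evaluation images. These sizes make the full protocol deterministic
and fast while still exercising ranking, augmentation and count
conservation.

## Known limitations

* ERP thresholds inherit the label-peeking of the search procedure;
  they describe the tuning set.
* The macro-F1 convention for filtered subsets (zero-fill classes
  present in the subset, drop classes absent from it entirely) is a
  choice; alternatives exist and would shift filtered macro-F1 slightly.
* Calendar harmonization resolves only the two variety pairs named by
  the rules (winter/spring, early/late ware); any other multi-variety
  cell is an error by design.
* The printed imbalanced-set size in the source material (8,642)
  differs by one from the arithmetic the cohort rules imply (8,643);
  the package reports what it computes.
* The generator's correctness flags are independent of resolution and
  condition tags, so the corresponding diagnostics on synthetic data
  measure a true null.
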