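---
title: "Methods: random-forest biomarker discovery for follicular-fluid proteomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: random-forest biomarker discovery for follicular-fluid proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ffproteo)
```

## The problem

Follicular fluid (FF) bathes the developing oocyte; its proteome mixes
local secretion with plasma transudate and responds to systemic conditions
such as polycystic ovary syndrome (PCOS).  Label-free SWATH-MS
quantification of FF yields a matrix of normalized protein intensities
with a deeply nested design: each patient contributes 2--3 fluids, and
each fluid is measured in 3 technical repeats.  The statistical task is a
two-group contrast (PCOS vs oocyte donors) over a few hundred proteins
with at most a few dozen patients per group, where naive row-wise testing
would both pseudoreplicate (repeats of one fluid are not independent) and
drown weak effects in multiplicity.

`ffproteo` implements the machinery for this setting:

1. a **class-weighted, capacity-limited random forest** scored by Gini
   impurity, used not as a maximal-accuracy classifier but as a
   multivariate effect detector;
2. **grouped recursive feature elimination with cross-validation (RFECV)**
   accumulated into per-protein *persistence scores* over repeated cycles,
   with outlier-based biomarker selection;
3. **bootstrap difference-in-medians log2 fold changes** computed on
   fluid-level medians (the pseudoreplication guard);
4. a **winsorised robust correlation matrix** over the selected proteins;
5. a **synthetic cohort generator** so that all of the above is testable
   without access to patient data.

## The forest and its capacity limits

Trees split on weighted Gini impurity
\(I(Q) = \sum_{c \in \{\text{control}, \text{pcos}\}} p_c (1 - p_c)\),
where \(p_c\) is the weighted relative frequency of class \(c\) in the
node.  The defaults are deliberately small-capacity: 50 trees, depth at
most 3, and at least 30 samples per leaf; rows are weighted inversely to
class size so the 112-vs-110-fluid imbalance cannot bias the trees, and no
hyperparameter optimisation is performed.  Three conventions the
literature leaves open are fixed as follows:

* **Weighted occupancy.** Sample weights enter both the impurity and the
  leaf-occupancy count; per tree, the (bootstrapped) weights are rescaled
  to sum to the number of training rows, which keeps the "30 samples per
  leaf" threshold on its familiar raw-count scale.
* **Randomness.** Each tree sees a bootstrap resample of rows and
  \(\lceil\sqrt{p}\,\rceil\) candidate features per split -- the
  conventional random-forest choices.
* **Determinism.** Equal-gain splits resolve to the lowest feature index,
  then the lowest threshold; every random draw flows from one master seed
  through a counter-based derivation, so any cycle, fold or tree is
  reproducible in isolation.

Feature importance is the mean decrease in impurity (MDI): the weighted
impurity decrease of every split, credited to its feature, normalised by
the root weight and averaged over trees.  Stored node tables allow the
importances (and the depth/occupancy constraints) to be re-derived by
brute force, which the test suite does.

## Grouped RFECV and persistence scores

Cross-validation is grouped by patient: patients, not rows, are dealt into
20 folds (shuffled within clinical group, round-robin, sizes within one
patient of each other), so no patient's fluids ever straddle a train/test
boundary.  One RFECV cycle walks a single elimination path: at each round
every training fold fits a forest on the active proteins, held-out
balanced accuracy (the mean of per-class recalls) is recorded, and the
protein(s) with the lowest fold-averaged MDI are dropped -- one per round
by default, or a fraction (`step = 0.1` eliminates the bottom 10% per
round, the documented speed knob for wide matrices).  The walk continues
to a single feature; the optimal feature count is the argmax of the CV
accuracy curve with ties resolved toward fewer features.

The per-cycle **persistence score** is under-specified in the methodology
this package reimplements, so its exact form is a design decision here: a
protein's cycle score is *the number of elimination rounds it survives,
counted from the first round* (a protein eliminated in round one scores 0;
a protein retained to the end scores all rounds).  We also considered
scoring only survival beyond the optimal feature count (zero for anything
eliminated earlier).  That variant reproduces a heavier-tailed score
distribution, but on wide matrices it assigns a nonzero score to only
about as many proteins as the optimal count, which makes ranked-recovery
statements ("the top 30 scores") degenerate.  Counting from round one
ranks every protein while still compressing the background: with
fractional elimination most noise proteins fall in the first few rounds,
while persistent proteins survive tens of rounds, cycle after cycle.
Scores are summed over `n_cycles` independent cycles (fold assignment
re-drawn each cycle by default), and proteins whose total exceeds
`median + 1.5 * IQR` of the score distribution are selected.  The final
classifier -- a forest restricted to the selected proteins -- is assessed
by grouped-CV balanced accuracy.

## Effect sizes without pseudoreplication

Technical repeats of one fluid are collapsed to the median of their log2
intensities, making fluids the unit of inference.  The effect size per
protein is the difference of group medians on the log2 scale (so it is a
log2 fold change directly); its 95% interval is a percentile bootstrap:
both groups are resampled independently with replacement (10,000 times by
default) and the 2.5/97.5 percentiles of the resampled statistic are
taken.  The percentile method is the minimal construction consistent with
"bootstrap CI"; no bias correction (BCa) is applied, and no multiplicity
adjustment is made to the significance flags -- both are deliberate,
documented choices of the emulated analysis.  Log base 2 is chosen so the
estimate is reported in the same unit as the reference effect table; any
other base differs only by a constant factor.

Resampling treats fluids as exchangeable within group, ignoring the
patient clustering of 2--3 fluids; this follows the emulated analysis'
stated independence construction and will be slightly anti-conservative
when between-patient variance dominates.

## Winsorised correlation

The robust correlation between selected proteins clips each column's most
extreme `floor(gamma * n)` observations per tail to the nearest retained
order statistic, then computes the plain product-moment correlation.
`gamma = 0.2` is the default, the standard choice in the robust statistics
literature; `gamma = 0` reproduces Pearson correlation exactly.  Pairs
degenerate after winsorisation (zero variance) are reported `NA` rather
than a fabricated 0, and the diagonal is fixed at 1.

## The synthetic cohort: a stated world

The generator emulates the reference study's geometry: 34 PCOS + 40
control patients, 2--3 fluids per patient drawn uniformly (giving about
213 fluids), 3 repeats per fluid, 484 proteins.  Natural-log intensity is
a sum of independent pieces,

\[
\ln X_{ijkg} = \mu_g + a_{ig} + b_{ijg} + e_{ijkg}
  + \mathbb{1}[\text{pcos}] \cdot \ln(2)\,\beta_g ,
\]

a three-level random-intercept decomposition (patient / fluid / repeat)
with the group effect specified in log2 units (`beta`), the minimal
structure under which fluid-median aggregation and patient-grouped CV are
both meaningful.  Default parameter choices, fixed once:

* `effects`: the 20 reference log2 fold changes (`table2_default_effects()`),
  one large negative (-0.61), two small negatives (-0.07), seventeen
  positives 0.18--0.41, assigned to evenly spaced protein indices.
* `patient_sd = fluid_sd = 0.15` (natural-log scale): together with the
  design these reproduce the reference analysis' reported CI half-widths
  of roughly 0.1--0.15 log2 units for a difference of group medians.
* `repeat_sd = 0.25` with a per-protein lognormal spread
  (`repeat_sd_spread = 0.3`): the implied technical CV distribution puts
  roughly a fifth of proteins below 20% CV, matching the reference
  instrument-performance figure (98 of 484 proteins with CV < 20%).
* Correlated block: the positive-effect proteins share a latent factor
  with loading \(\sqrt{\rho}\) at every variance level (`block_rho = 0.5`,
  a moderate value typical of co-regulated plasma-derived proteins), so
  pairwise block correlations equal \(\rho\); the most downregulated
  protein loads with \(-\sqrt{\rho}\), reproducing the lone
  anti-correlated biomarker pattern.
* `baseline_log_mean_range = (3, 12)`: baselines span about four orders of
  magnitude of raw intensity, typical of SWATH protein abundances.

**What the generator does not emulate.**  No missing intensities (the
emulated analysis does not describe missingness handling); no per-protein
heterogeneity of *biological* variance (every protein shares the
patient/fluid sds, so a protein's detectability is determined by its
injected fold change alone); no multivariate structure beyond the single
block factor.  Consequently a green recovery test establishes that the
pipeline finds effects whose marginal separability supports finding them
-- it cannot certify behaviour on real data where a protein with a small
median shift may still be highly discriminative (low variance,
multivariate interactions), as the reference study's own score table
suggests.

## Known limitations, and one honest red

The acceptance suite encodes a scaled-down recovery target: with the 20
reference effects injected and 5 RFECV cycles, at least 15 of 20 injected
proteins should rank in the top 30 persistence scores and the outlier
selection should return 10--30 proteins with the MYL6-like protein as its
only negative-effect member.  In this generator's stated world that target
is not attainable at 5 cycles, and we left the criterion red rather than
tune the world toward it.  The evidence, reproducible from the test
fixtures: a univariate oracle (per-protein t statistics on fluid medians)
recovers 15--19 of 20, so the information is present in the data; averaged
single-forest MDI recovers 14--15 of 20, and scikit-learn's reference
implementation with identical hyperparameters recovers the same; but
recursive elimination itself -- ours and scikit-learn's RFE equally --
degrades the ranking to about 11 of 20, because elimination order among
correlated, weakly separable features is noisy and two of the injected
effects (-0.07) are statistically negligible by construction.  Running the
full 30 cycles of the reference analysis (about half an hour, outside the
test budget) lifts recovery only to 12 of 20 with ~53 proteins selected,
so the target is out of reach in this stated world at any cycle count: the
generator ties each protein's discriminability to its marginal fold change
alone, whereas in the reference study's real data proteins with small
reported fold changes still achieved maximal persistence scores.  The
non-acceptance suite pins every component
along this chain (forest, MDI against a brute-force oracle, grouped folds,
elimination determinism), so the red criterion localises the gap in the
scaled-down design, not the implementation.

Other limitations: the bootstrap ignores patient-level clustering of
fluids (see above); the outlier selection rule `median + 1.5 IQR` is
scale-dependent and can select nothing when the score distribution is
near-uniform (narrow matrices eliminated one feature per round), which is
why narrow-fixture tests lower the multiplier; and balanced accuracy is
averaged over CV folds whose test sets, at 20 folds and 74 patients, each
hold only 3--4 patients, so per-fold accuracies are coarse.
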