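---
title: "Proteo-metabolomic signature discovery for plasma EVs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteo-metabolomic signature discovery for plasma EVs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plasma extracellular vesicles (EVs) carry protein and metabolite cargo that
may reflect the presence and stage of melanoma. A typical discovery study
quantifies a few hundred EV proteins by label-free mass spectrometry
(duplicate injections per subject) and a targeted panel of ~90 metabolites
(mostly glycerophospholipids and sphingolipids), across a modest cohort:
here, 24 primary melanoma, 12 metastatic melanoma and 13 healthy-control
subjects. The analytical task is to find small feature panels
("signatures") whose unsupervised structure separates the clinical groups,
and to quantify honestly whether that separation beats guessing.

`evsig` implements this analysis end to end: preprocessing, differential
abundance, consensus feature selection, clustering-as-classifier
evaluation against an exact binomial null, and proteo-metabolomic
integration — plus a seeded synthetic-cohort generator with known ground
truth, because pipelines of this kind should be validated on data where
the right answer is known.

```{r, eval = FALSE}
library(evsig)
report <- run_discovery(default_config(seed = 1))
print(report)
```

## Synthetic cohorts

`generate_cohort()` draws, per feature, a subject-level log-normal
baseline: log2 intensities are Normal(25, 3) for proteins (the scale of
label-free quantification values) and Normal(0, 2) for log2 metabolite
concentrations in uM; per-feature log2 standard deviations follow
Gamma(shape = 4, rate = 5) (mean 0.8). Designated marker features
(PRG4, APOC4, HPR, VWF, SERPIND1, TNC, PLG; phosphatidylcholines and a
lysophosphatidylcholine on the metabolite side) receive fixed baselines
(27 / 1.5) and dispersion 0.8, reflecting that credible biomarkers are
reliably quantified, and their group effects are applied multiplicatively
(`2^log2fc`) at the subject level. Technical replicates are multiplicative
log-normal jitter with a 15% coefficient of variation. Ages are drawn per
group from the cohort's published demographics (melanoma groups older),
and one marker (PRG4 by default) is coupled to age by signed rank
blending until the realised Spearman correlation is within +/- 0.05 of the
target 0.34.

Missingness has two parts: a small missing-completely-at-random rate
(2%) and a logistic missing-not-at-random (MNAR) term whose probability
increases as log-intensity falls. The MNAR midpoint sits at the median
protein log2 intensity — so roughly half of the proteins exceed the 40%
missingness threshold and are filtered, emulating the published reduction
from ~210 usable proteins to ~107 — and at the 2% quantile for
metabolites, where two designated low-abundance panel members emulate the
published 88-to-86 reduction. Immunoglobulin decoys are named with IGHG/
IGKC/IGLC-style symbols and given high baselines (abundant plasma
proteins), so they survive the missingness filter and genuinely exercise
the removal step.

None of these distributions is estimated from the study — its raw data are
not deposited. They are explicit stand-ins chosen to match the field's
conventions for label-free intensities and targeted concentrations. What
the generator does *not* emulate: correlation structure among real plasma
proteins (features are independent given group), batch or acquisition-order
effects, limit-of-quantification censoring in the targeted assay, and
biological covariance between proteins and metabolites. Passing tests on
these cohorts therefore validate the pipeline's mechanics and calibration,
not its behaviour under real-world feature correlation.

## Preprocessing

The stage order is fixed: identification filtering (reverse hits,
potential contaminants, identified-by-site-only, applied when reading
MaxQuant proteinGroups tables), then the missingness filter (features
missing *strictly* more than 40% of values are removed; a feature at
exactly 40% is retained), then immunoglobulin removal by case-insensitive
gene-symbol prefix (IGH, IGK, IGL, IGJ, JCHAIN by default — configurable,
since no canonical list exists), then imputation, then normalisation.

Imputation is the iterative random-forest scheme: initialise missing
entries at feature means, visit features in order of increasing
missingness, regress each on all others and re-predict its missing
entries, and stop when the sum of squared changes of the imputed values
increases (keeping the previous iteration, the missForest convention) or
after 10 sweeps. Forest predictions are averages of observed values, so
imputed entries always lie inside the observed range of their feature.
Defaults are 100 trees and mean initialisation; the imputation is run
separately per omic.

Normalisation is log2 transformation followed by per-observation median
centring: every observation's median becomes exactly 0, removing global
per-sample scale differences. This is one concrete choice among several
defensible ones (quantile or VSN normalisation would be alternatives); it
is recorded in every run log.

A consequence worth stating plainly: under intensity-dependent dropout,
observed values of a down-shifted group are biased upwards (the low values
are preferentially missing), and imputation pulls filled-in entries toward
the pooled feature mean. Both effects *attenuate* fold-change estimates
after the full chain. This is a property of MNAR data and single-imputation
pipelines generally, not a defect of the estimator: on complete data the
moderated-t confidence intervals cover the true spiked effect at their
nominal rate, and the package's tests check exactly that separation.

## Differential abundance

The workhorse is the empirical-Bayes moderated t-statistic. For feature
$g$ with pooled two-sample variance $s_g^2$ on $d_g$ residual degrees of
freedom, the log variances are moment-matched to a scaled inverse-chi-
squared prior: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$,
the prior degrees of freedom $d_0$ solve
$\psi'(d_0/2) = \mathrm{mean}\{(e_g-\bar e)^2 \tfrac{G}{G-1} - \psi'(d_g/2)\}$
(Newton iteration on the trigamma inverse, at most 50 steps, tolerance
1e-8; $d_0 = \infty$ when the right-hand side is non-positive), and the
prior variance is $s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$.
The posterior variance
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ yields
$t_g = (\bar x_{1g} - \bar x_{2g}) / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$
on $d_0 + d_g$ degrees of freedom. Setting `prior_df = 0` recovers the
ordinary pooled t exactly (a tested oracle equivalence), and the test
suite verifies agreement with the reference empirical-Bayes implementation
to machine precision.

Significance is declared at unadjusted p < 0.05 — the convention of the
analysis being reproduced, which applies no multiple-testing correction;
a Benjamini-Hochberg option exists (`adjust = "BH"`) but is off by
default. Classical tests (Mann-Whitney with exact enumeration for small
tie-free samples, Spearman correlation with the t approximation, ROC-AUC
as the pairwise win fraction, one-way ANOVA from group summaries, Pearson
chi-squared without continuity correction) round out the module.

## Feature selection and consensus

Three selectors run per contrast:

* **Serial kNN**: features are ranked by moderated-t p-value; a
  k-nearest-neighbour classifier (Euclidean distance on the top-N
  features) is scored over a grid of odd k and prefix sizes N under
  cross-validation. The default is leave-one-subject-out, so technical
  replicates of one subject never straddle the train/test split; a
  leave-one-observation-out mode reproduces the convention that treats
  each duplicate as an independent quantification. Grid ties break toward
  smaller N, then smaller k; distance ties break toward the lowest
  training-observation index, making the whole grid deterministic.
  Only odd k are accepted, so binary votes cannot tie.
* **LASSO logistic regression** over a decreasing lambda path with
  10-fold cross-validated deviance; the `"min"` rule is the default (no
  rule is documented for the original analysis; `"1se"` is available).
  Features are standardised internally, so selection is scale-invariant.
* **Random-forest importance**: mean impurity decrease, keeping the top
  `ceiling(0.10 * G)` features.

The consensus is the intersection, ordered by mean rank across the three
sources. When it is empty, a *lenient* set — the union of pairwise
intersections — is reported, mirroring the fallback the original analysis
applied; when that is empty too, the grid-search panel falls back to the
top differentially abundant features. Panels are capped (default 8, hard
limit 12) because the downstream grid search is exhaustive.

## Evaluating signatures: clustering as a classifier

A signature is evaluated by hierarchical clustering (Euclidean distance,
complete linkage by default — the default of the heat-mapping tools this
analysis style relies on) of the feature-restricted matrix, cut at k = 2,
with clusters mapped to the two classes by whichever of the two
assignments maximises accuracy (the original mapping rule is unstated;
maximising is the deterministic, conservative-against-relabelling choice).
Reported alongside the accuracy are its exact 95% Clopper-Pearson
interval, the No-Information Rate (majority-class proportion), the exact
one-sided binomial p-value for accuracy above the NIR, sensitivity
(positive = disease class) and specificity.

**Evaluation levels.** The printed arithmetic of the original results
identifies the conventions: an interval of 57.45% (46.82-67.60%) is the
Clopper-Pearson interval for 54 of 94 predictions (replicate level), while
p = 0.031 against a NIR of 72.34% is the exact tail of 40 of 47 at 34/47
(subject level). The pipeline therefore evaluates proteomic signatures at
replicate level and metabolomic/combined signatures at subject level
(duplicate metabolite measurements are averaged to one representative
value per subject before analysis), both overridable. For *inference* —
the moderated t and its calibration — the package defaults to subject
level, because technical replicates are not independent units: using them
as such roughly doubles the apparent sample size and inflates type-I
error. The replicate-level option remains available for compatibility.

**Honesty of the binomial test.** The Acc > NIR binomial test is exact for
a pre-specified signature. For a grid-search *winner* it is optimistic:
the maximum accuracy over many subsets of data-selected candidates is
biased upward, and no correction for that selection is applied — again
matching the procedure being reproduced. The package's null-calibration
tests quantify this on zero-effect cohorts at subject level; at replicate
level the combination of selection bias and pseudo-replication can make
null winners appear strongly significant, which is precisely why the
inferential default is subject level.

## Multi-omic integration

Integration is deliberate concatenation, not latent-factor modelling:
proteomic replicates are averaged to subject level and the feature columns
of the two omics are joined (feature kinds preserved). Feature relatedness
is summarised by a Spearman similarity matrix — features clustered on the
distance 1 - rho (anticorrelated features are far apart; using 1 - |rho|
is a documented alternative) and cut into k partitions (default 6).
Constant features, whose correlation is undefined, are assigned zero
similarity with a warning rather than an error.

## Numerical and degenerate-input choices

* Trigamma inverse by Newton iteration, capped at 50 steps, tolerance
  1e-8; closed-form limits for very large/small arguments.
* Zero-variance features are excluded from prior estimation; a feature
  with zero fold change and zero variance gets t = 0, p = 1.
* Mann-Whitney p-values are exact (no ties, n1*n2 <= 400) or
  normal-approximated with tie and continuity corrections.
* `filter_missing` uses strict inequality at the 40% boundary.
* Grid-search ties break toward smaller subsets, then lexicographic
  feature order, so winners are invariant to candidate input order.
* Empty cluster classes, subjects present in only one omic, non-positive
  values before log transformation, and features with no observed values
  are all rejected with messages naming the offending item.
* All forests run single-threaded with fixed seeds; a single run seed
  derives every stage seed, so end-to-end runs are byte-reproducible
  (reports contain no timestamps).

## Problem sizes used by the test suite

The simulation-based tests run study-shaped cohorts (49 subjects x 2
replicates; 257 proteins, 88 metabolites): 20 null cohorts for
calibration (complete data, subject level — isolating the statistic from
imputation effects) and 50 spiked cohorts for marker recovery (full
missingness and imputation). Inside these loops the imputation forests
use 25 trees and the selection forests 300 — sizes chosen so the full
suite runs in a few minutes on one CPU; forest sizes beyond this change
the results negligibly on matrices of this scale. Package defaults stay
at 100 (imputation) and 500 (selection).

## Known limitations

* Synthetic features are conditionally independent; real EV proteomes are
  strongly co-regulated, which affects imputation quality and the
  similarity partitioning in ways these cohorts cannot reveal.
* The binomial evaluation of grid-search winners inherits the original
  procedure's selection optimism (see above).
* MNAR dropout plus single imputation attenuates fold changes; downstream
  effect sizes should be read as conservative.
* No batch correction, no peptide-level processing, no
  limit-of-quantification handling for the targeted assay, no moderated
  F for three-group contrasts.
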