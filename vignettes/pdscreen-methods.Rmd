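---
title: "Methods: picture-description screening for MCI subtypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: picture-description screening for MCI subtypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdscreen)
```

## The analysis problem

Mild cognitive impairment (MCI) is heterogeneous: amnestic MCI (aMCI)
involves memory-domain deficits, non-amnestic MCI (naMCI) deficits in
other domains. A picture-description task — a participant describes the
Cookie Theft scene while their speech is recorded — yields two families
of quantitative features: acoustic measures computed from the audio
(F0 statistics, jitter, shimmer, intensity, tremor, timing) and
language measures computed from a POS-tagged transcript (content-unit
counts, lexical-category counts, response length). `pdscreen`
implements the full screening analysis over such a feature panel:

1. **Transcript scoring** — content-unit, lexical and length features
   from pre-tagged transcripts and an editable content-unit lexicon.
2. **Preparation** — quantile normalization of every feature;
   split-aware low-rank imputation of the six vocal-tremor features;
   all within-modality pairwise contrasts.
3. **Screening** — per-feature and per-contrast logistic association
   tests adjusted for age and gender, with Benjamini–Yekutieli (BY)
   false discovery rates, plus per-feature ridge classifiers evaluated
   by repeated cross-validated AUROC and specificity-constrained
   threshold metrics.
4. **Risk scores** — elastic-net logistic models per cohort pair with
   unpenalized age and gender, and an alternative penalized multinomial
   model whose pairwise liability differences act as risk scores.

Because no participant-level data are distributed, the package ships a
synthetic cohort generator whose defaults encode the study design the
pipeline targets (62 HC, 18 aMCI, 15 naMCI); every stage is exercised
and tested end-to-end against it.

## Models and statistics

**Association screen.** For each feature or contrast $x$ the model is
$\text{logit}\,P(y=1) = \beta_0 + \beta_a\,\text{age} +
\beta_g\,\text{gender} + \beta x$, with cases coded 1 and controls 0
and gender coded female = 0, male = 1. The reported p-value is the Wald
test of $\beta$ (the convention of standard GLM summaries; a likelihood
ratio test would be a defensible alternative but is not what `glm`
summaries print). The effect direction is $\operatorname{sign}(\beta)$:
negative means controls sit higher after adjustment. Complete or
quasi-complete separation is detected from a diverging coefficient
($|\beta| > 15$, a huge standard error, or non-convergence) and
flagged; the p-value is then reported `NA` rather than a misleading
number.

**BY FDR.** With $m$ ascending p-values, the adjusted value at rank $i$
is $p_i\, m\, c(m)/i$, $c(m)=\sum_{k=1}^m 1/k$, monotonized downward
from the largest rank and capped at 1. The BY correction is valid under
arbitrary dependence, which matters here because all features are
computed from the same responses. The family is exactly the vector
passed in: the 91 features and the 2,027 contrasts are adjusted as
separate families, matching the separate reporting of the two screens.
The implementation is checked against `stats::p.adjust(method = "BY")`
to $10^{-12}$ in the test suite.

**Contrasts.** Quantile normalization puts every feature on the same
normal scale, so the difference $A - B$ of two normalized features is
in standard-deviation units: a participant with words at $+1$ SD and
sentences at $+2$ SD has a words−sentences contrast of $-1$ (short
sentences); the reverse participant has $+1$. Contrasts are built for
all same-modality pairs — $\binom{47}{2}=1081$ language plus
$\binom{44}{2}=946$ acoustic, 2,027 total, never mixed pairs — oriented
with A earlier in registry order (directions are reported relative to
that orientation). Contrast values use only observed data: a contrast
is missing whenever either feature is missing, and such rows drop out
of the screen. Imputed values are never used in contrasts or in
single-feature screens; imputation exists solely for the multivariate
risk-score fits, which need complete design matrices.

**AUROC.** Mann–Whitney concordance: the probability a random case
outscores a random control, ties counted one half. Computed from ranks
and verified against brute-force pair enumeration.

**Threshold rule.** Candidate thresholds are midpoints between adjacent
sorted unique scores plus $\pm\infty$; among candidates with
specificity $\ge 0.85$ the F1-maximizing one is chosen, ties broken
toward higher specificity and then higher threshold. The floor reflects
the screening use-case (tolerable false-positive rate); under it,
sensitivity, precision and F1 can legitimately be low. The $+\infty$
candidate (everyone negative, specificity 1, F1 0) makes the
constraint always satisfiable. The rule is invariant under strictly
monotone transforms of the scores.

**Risk scores.** Elastic-net logistic regression over all 91 features
plus age and gender, with zero penalty factors on age and gender so
they are never removed. Mixing $\alpha$ and scale $\lambda$ are chosen
jointly by 5-fold cross-validated predictive deviance: $\alpha$ over
$\{0, 0.1, \dots, 1\}$, $\lambda$ over the usual auto-scaled
log-spaced 100-point path. We use the deviance-minimizing $\lambda$
(`lambda_choice = "min"`); the 1-SE rule is available as a flag.
Because features are already quantile normalized, no internal
standardization is applied — re-standardizing would also rescale the
unpenalized covariates. After fixing the penalties, the model is refit
on all data for the reported weights, and out-of-sample link-scale
predictions from 10 further replications of 5-fold cross-validation
are averaged per participant; these averages — estimates of each
participant's log-odds of being a case — are the risk scores, and
their AUROC is the headline performance number. Fold splits are
stratified by class (with 15–18 cases, unstratified folds can lose a
class entirely) and recorded, so the out-of-sample discipline is
auditable: no participant is ever scored by a model trained on a fold
containing them. The three two-class tasks use independent seeded
splits.

**Per-split imputation.** Tremor features can be missing (tremor
estimation fails on some recordings); the completion is a
soft-thresholded SVD scheme: fill missing entries with column means,
then iterate truncated SVD (rank at most 5, threshold $\lambda = 0$ by
default, tolerance $10^{-4}$, at most 200 iterations per rank) and
refill. Ranks are escalated 1, 2, …, 5 with warm starts: jumping
straight to the full rank can lock the initial column-mean fill into
excess components, while the escalated scheme recovers planted
low-rank matrices to well under 0.1 RMSE (tested). Inside every
cross-validation split, the training and test subsets are completed
*independently* — the completion for the test rows never sees training
rows — so imputation cannot leak label-side information across the
split. A column entirely missing within a split falls back to 0, the
center of the normalized scale, with a message.

**Multinomial alternative.** One penalized multinomial model over
HC/aMCI/naMCI (age and gender unpenalized), penalties by 5-fold CV
deviance, liabilities averaged over 10 further CV rounds. Class
liabilities are identified only up to a common shift, so pairwise
differences — which estimate the pairwise log-odds — are the risk
scores; additivity (aMCI−HC) + (HC−naMCI) = (aMCI−naMCI) holds exactly
by construction.

## The synthetic generator

The generator draws, per participant, a latent standard-normal value
per feature, adds the configured group shift (in SD units), and applies
missingness only to the six tremor features. Defaults encode the
target study design and are fixed:

* **Cohort sizes** 62/18/15 (HC/aMCI/naMCI); ages truncated-normal
  within 64–85 years with per-cohort means/SDs (70.3/4.5, 70.2/7.4,
  71.5/5.8) and female fractions (35/62, 6/18, 6/15).
* **Effect map.** aMCI carries negative shifts of 0.6–1.1 SD on the 19
  verbosity-linked count features the screen targets and $+0.8$ SD on
  the standard deviation of F0; naMCI carries no effects. Directions
  follow the consistent finding that counts are lower and pitch
  variability higher in aMCI; magnitudes are back-solved from the
  per-feature discriminations such a design should produce
  (single-feature cross-validated AUROCs of roughly 0.65–0.85, via
  $\mathrm{AUROC}=\Phi(d/\sqrt2)$).
* **Correlation.** Count-type language features load 0.6 on a shared
  latent "verbosity" factor — longer responses raise every count —
  which is exactly the correlation structure that motivates contrast
  analysis. The within-group covariance of real features is otherwise
  unknown; this single-factor default is an explicit artifact choice,
  and other structure can be injected by editing the config.
* **Missingness** 10% MCAR on the tremor features. The real
  missingness mechanism (tremor estimation failure) is plausibly
  value-dependent; MCAR is a simplification.
* **Scale.** Features are exposed on the latent Gaussian scale by
  default; an optional monotone count link (rounded exponential) is
  available, and quantile normalization makes the choice immaterial
  downstream — which is precisely why the pipeline can be validated
  without knowing each feature's native scale.

What passing tests on this generator do **not** show: performance on
real speech (no discourse structure, no tagger errors, no
instrument-specific acoustics), robustness to informative missingness,
or calibration of risk scores as probabilities.

The toy transcript generator emits minimal template sentences around
content-unit mentions drawn at configured Poisson rates, tracking true
counts at emission time; it exercises the scorer's matching logic, not
realistic language.

## Transcript-scoring conventions

* Matching is case-insensitive, longest-match-first over multi-token
  surface forms, left-to-right and non-overlapping, so "cookie jar" is
  one mention of the jar unit rather than cookie + jar. Verified
  against an independent brute-force window scanner on randomized
  token streams.
* The shipped Cookie Theft lexicon (`inst/extdata/`) is a package
  default enumerating the scene's standard objects, actors and actions
  with side-of-picture labels; study-specific unit lists can be
  swapped in as JSON. Every scoring function is parameterized over the
  lexicon.
* Tag-based lexical categories use Penn-Treebank tags (nouns `NN*`,
  prepositions `IN`, modals `MD`, …); indefinite articles, function
  words, pro-sentences ("yes", "okay", …) and fillers use editable
  closed-class word lists. Unknown tags are skipped for tag-based
  categories, with a message.
* "Complete sentence" (at least one finite-verb tag and one nominal
  tag) and "phrase" (maximal chunk from a lightweight NP/VP/PP rule)
  have no standard definitions in this context; both defaults are
  explicit heuristics, and both are pluggable. The same goes for the
  vowel-group syllable counter (hand-checked at ≥90% exact agreement
  on a fixture list) and the syllables-per-word minimum.

## Numerical and design choices

* Quantile normalization maps rank $r$ of $n$ non-missing values to
  $\Phi^{-1}(r/(n+1))$; ties get mean ranks, making the transform
  permutation-invariant and constant columns all-zero. The normal
  target (rather than an arbitrary reference distribution) is what
  makes contrasts readable in SD units.
* FDR families: features and contrasts separately (matching their
  separate result tables); a joint family would be a different, also
  defensible, choice and can be had by passing the union.
* Penalty grids: `glmnet`'s auto-scaled 100-point lambda path; alpha
  grid of 11 points. Exposed in `pipeline_config()`.
* Seeds: one global seed expands into per-stage seeds through a fixed
  Lehmer-style hash (`derive_seed()`), so a single integer reproduces
  the whole pipeline bitwise while stages stay decoupled.
* Problem sizes in the test suite and acceptance script (e.g., 200
  null cohorts for screen calibration, 50 seeds for planted-signal
  recovery, 20 seeds for the subtype-asymmetry check, 10-seed
  summaries in the acceptance script) were chosen as the package's
  own balance between Monte-Carlo resolution and a test run that
  stays pleasant to execute.

## Known limitations

* Acoustic features are never computed from audio here; they enter as
  externally supplied or synthetic columns. Likewise POS tagging is an
  input, not a stage.
* The screen's Wald p-values are asymptotic; with 18 cases they are
  slightly conservative in the far tail (visible in the null
  calibration, which lands near 0.042–0.05 at $\alpha=0.05$).
* With very small case groups the classifier reduces folds (minimum
  3) and warns; below that it refuses.
* The multinomial path requires at least 3 members per class and is
  reported as a secondary analysis; with 15 naMCI cases its
  naMCI-related AUROCs are noisy.
* Risk scores are relative log-odds, not calibrated probabilities.
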