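---
title: "Methods: models, parameters and design choices in dialymet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in dialymet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dialymet` implements a complete plasma-metabolomics analysis chain for
paired dialysis studies. This vignette is the package's account of the
science inside it: the statistical model of the synthetic cohorts, the
preprocessing conventions, the multivariate and univariate procedures,
and the places where the design was genuinely open together with the
choice made and why.

## The study design

Five study groups — healthy controls, patients sampled immediately before
and after one low-flux hemodialysis session (pre-HD/post-HD), and patients
sampled before and after one high-flux session (pre-HFD/post-HFD) — plus a
series of pooled QC injections. Each patient contributes exactly one
pre/post pair linked by `patient_id`; all group comparisons against
control are between independent subjects. Six contrasts are analysed:
post-vs-pre within each therapy (paired) and each of the four patient
groups vs control (unpaired).

## The synthetic cohort model

`generate_cohort()` draws intensities from a log-normal multiplicative
model. For metabolite $j$ in study sample $i$ of subject $s(i)$ and group
$g(i)$:

$$\log x_{ij} = \log \beta_j + \delta_{g(i)j} + u_{s(i)j} + \varepsilon_{ij}$$

* $\beta_j$ — metabolite baseline, $\log\beta_j \sim N(\log 100, 1)$;
* $\delta_{gj}$ — fixed group effect determined by the metabolite's
  change-pattern region (below);
* $u_{sj} \sim N(0, \sigma_b^2)$ — subject effect, drawn once per subject
  per metabolite and **shared by a patient's pre and post samples**, so
  the paired *t* test is the correct pre/post analysis and unpaired
  analysis of paired data loses power, exactly as in a real crossover of
  this kind;
* $\varepsilon_{ij} \sim N(0, \sigma_a^2)$ — analytical noise.

QC samples carry only analytical noise around the pooled mean of all
study samples, which is what a pooled-plasma injection measures. Two
internal-standard columns (one per ion mode) are spiked at a near-constant
intensity (log-SD 0.02). A log-normal model keeps intensities positive and
makes planted effects act multiplicatively, so group fold changes equal
$\exp(\Delta\delta)$ exactly in expectation.

### Regions and planted truth

Each metabolite belongs to one of the four change-pattern regions of the
five-group heat map:

| region | pattern | group effects used |
|---|---|---|
| A | low pre-dialysis, **rises** after dialysis | control ×0.35, pre ×0.25, post ×0.90 |
| B | high in controls, low in patients | patients ×0.5 |
| C | accumulated pre-dialysis, cleared by dialysis | pre × `toxin_fc_pre_vs_control` (4.0); post × `clearance_fc_post_vs_pre` (0.45) on top |
| D | stable | none |

Only the region-C magnitudes are externally meaningful (a typical uremic
toxin accumulates about four-fold and is roughly halved by one session);
the A/B/D multipliers are free parameters of the generator, chosen once
as qualitatively plausible effect sizes, and are documented here as such.

Uremic solutes are placed in region C. The HFD-only subset (default 11,
given the names of typical small uremic retention solutes such as
guanidine and hippuric acid) receives **no** clearance under HD and the
extra factor `hfd_only_extra_clearance` (0.5) under HFD — these are the
solutes the clearance comparison must find. A configurable number of
metabolites receive inflated analytical noise (log-SD 0.5, QC RSD ≈ 53%)
so the RSD filter has real work; they are drawn from non-solute, unnamed
columns so a random collision cannot silently empty the planted clearance
panel or remove a ratio-pair anchor.

Missingness emulates detection-limit censoring: entries are removed with
probability `missing_rate_low_group` (0.25) only in the group(s) where a
metabolite's expected level is lowest. Flat metabolites have no lowest
group and receive no missingness — this is deliberate, since the 80% rule
is a per-group detection rule and censoring a flat metabolite uniformly
would simply delete it from the study.

### Default geometry

47 controls; 85 HD and 42 HFD patients, each pre and post (301 study
samples); 38 QC injections; 160 metabolites + 2 internal standards;
region fractions A/B/C/D = 0.10/0.15/0.40/0.35; 55 solutes, 11 HFD-only;
$\sigma_a = 0.15$ (QC RSD ≈ 15%, comfortably under the 30% filter),
$\sigma_b = 0.30$; 16 inflated-noise metabolites, so the default run
retains about 144 reliable metabolites. All randomness flows from the
single `seed` through one local RNG stream; the global RNG state of the
session is never touched.

### What the generator does **not** emulate

Injection-order drift and batch effects; correlated metabolite blocks
(pathway co-regulation); heavy-tailed or adduct/isotope artefacts;
clinical covariates. Tests passing on these cohorts therefore validate
the *statistical machinery* under the declared model — they do not
certify performance on real CE-MS data, where drift correction and
correlated features can matter.

## Preprocessing conventions

* **80% rule** — keep a metabolite iff its non-missing fraction is
  ≥ 0.80 (inclusive) in *at least one* non-QC study group. The per-group
  variant preserves compounds that are detectable only in patients (or
  only in controls), which the region structure requires.
* **IS normalization** — divide each intensity by the same-sample
  internal standard of the matching ion mode; exactly one IS per mode is
  required, must be positive and complete, and the IS columns leave the
  analysis set afterwards.
* **QC RSD filter** — RSD% = 100·SD/mean over non-missing QC entries,
  sample SD (n−1) throughout the package; keep strictly below 30%. A QC
  mean of zero drops the metabolite. At least 3 QC injections are
  required to make an SD meaningful.
* **Half-minimum imputation** — remaining missing entries become half the
  minimum observed value of that metabolite: the conventional
  detection-limit stand-in, applied only after the 80% rule so no
  metabolite is mostly imputed. Probabilistic imputation is out of scope.
* **UV scaling** — column-wise centring and division by the sample SD;
  the stored means/SDs make the transform invertible. Zero-SD columns are
  an error rather than silently kept.

The chain order is fixed: 80% rule → IS normalization → RSD filter →
imputation → scaling. Univariate statistics run on the *unimputed,
unscaled* normalized table (tests handle missingness by exclusion; fold
changes must be ratios of real intensities), while PCA and the SVM need
the complete scaled matrix.

## PCA: NIPALS, R²X and Q²

Components are extracted by NIPALS with Gram–Schmidt re-orthogonalization
of each score iterate against earlier components (finite convergence
would otherwise leak small correlations between scores). Convergence is
declared when the relative squared change of the score vector falls below
`tol = 1e-16` (default cap 5000 iterations); the sign is fixed so the
largest-magnitude loading is positive. R²X(k) is the cumulative explained
fraction of the total sum of squares.

Q² uses row-wise 7-fold cross-validation with deterministic interleaved
fold membership: the model is refit without each fold, held-out rows are
projected onto the fold loadings (regression on loadings, which for
orthonormal loadings is the simple projection), and
Q²(k) = 1 − PRESS(k)/SS. This mirrors the spirit of the commercial
SIMCA default, but that algorithm is proprietary; numerical equivalence
with values produced by that software is therefore *not* asserted
anywhere in the package.

## SVM-RFE stability selection

The classifier is a soft-margin linear SVM (libsvm via `e1071`), cost
fixed at 1.0 with no inner tuning — the procedure being emulated reports
none. Recursive feature elimination ranks features by squared weight
$w_j^2$ in the linear decision function (the standard operationalization
of "contribution to the hyper-plane") and removes
`max(1, floor(0.05 · current size))` features per iteration until none
remain, recording the cross-validated accuracy of every visited subset.

Three design points were genuinely open:

* **Where the ranking SVM is fit.** Ranking uses the squared weights of
  the models fit on each *training fold* of the repetition's partition,
  summed over folds — never a model that has seen the held-out fold.
  Besides avoiding leakage, this is what makes stability selection
  informative: ranking on the full data gives an elimination path that is
  identical in every repetition, so selection frequencies degenerate (the
  late survivors appear in every best subset by construction).
  Per-training-fold scaling is applied for the same reason.
* **The best subset on accuracy ties.** Ties along the path are broken
  towards the *largest* (earliest-visited) subset. On a completely
  separable contrast every subset size down to a handful of features
  achieves 100% accuracy, so a parsimony tie-break would select almost
  nothing — whereas the procedure this package reproduces reports *all
  144 features selected at 100.00% ± 0.00%* for the separable high-flux
  contrast. Only the largest-subset tie-break is consistent with that
  behaviour (and with frequencies of 1.0 for every feature in the fully
  separable limit).
* **How frequencies are counted.** Per repetition (100 trials), not per
  fold (300): a feature is counted once per repetition when it is in that
  repetition's best subset, making frequencies multiples of 1/100 and
  directly comparable with the 0.8 threshold.

Accuracy is summarized as the mean ± sample SD over the 100 repetition
accuracies, in percent. Note one honest caveat: the reported accuracy is
that of the *best* subset along the path, an optimistically biased
quantity on weak-signal data (on pure noise it sits near 70–80%, not
50%). On a fixed null dataset a few chance-correlated features can also
remain frequent across repetitions under any resampling scheme — the
tests assert that this residue stays small rather than exactly empty.

## Univariate statistics

* **Mann–Whitney U** (patient vs control): U from midrank sums; exact
  two-sided p via the null distribution of U when $n_a + n_b \le 12$ with
  no ties, otherwise the normal approximation with tie correction and
  continuity correction — the behaviour of mainstream statistics
  software. All observations tied ⇒ p = 1.
* **Paired t** (post vs pre): pairs aligned by patient id, incomplete
  pairs dropped and counted, at least 3 complete pairs required.
  Degenerate inputs follow an explicit convention: all differences zero ⇒
  flat, p = 1; constant nonzero difference ⇒ error (a flagged artefact,
  not a p-value).
* **BH-FDR** per contrast across all metabolites (the family is one
  contrast). Significance requires **both** raw p < 0.05 and q < 0.05.
* **Fold change** = ratio of group arithmetic means on IS-normalized,
  unscaled intensities — the convention under which printed group means
  reproduce printed fold changes; *not* the mean of per-pair ratios.
  Direction of a pre/post change is read from FC(post/pre) relative to 1,
  so direction and magnitude come from the same scale.
* **Ratios** (Glu/Gln, Trp/Kyn): element-wise per sample on normalized
  intensities, missing where either member is missing or the denominator
  is nonpositive; group comparison reuses the Mann–Whitney + BH path.

### Region classification

The four regions are formalized from the six contrasts using the global
significance rule only (no new thresholds):

* **C** — pre-vs-control significant with FC > 1 in both therapies AND
  post-vs-pre a significant decrease in both therapies;
* **A** — post-vs-pre a significant increase in both therapies AND
  pre-vs-control FC ≤ 1 in both;
* **B** — all four patient-vs-control contrasts significant with FC < 1;
* **D** — otherwise.

Requiring the conditions in *both* therapies makes false region calls on
stable metabolites vanishingly rare (two to four independent null tests
must fire jointly). A consequence worth knowing: an HFD-only cleared
solute is planted as region C but is *not* cleared by HD, so the
classifier files it (correctly, by the rule) under D; default-noise
recovery is therefore ≈ 93% with the 11-solute panel present and 100%
without it.

### Clearance comparison

`decreased_X` = uremic solutes significantly decreased (FC post/pre < 1)
under therapy X; `hfd_only` is the plain set difference
`decreased_HFD \ decreased_HD` — no additional effect-size criterion is
imposed, because the question "cleared by HFD rather than HD" is a
question about statistical evidence of clearance, and any magnitude
cutoff would introduce a tunable knob the analysis does not need. Both p
and q columns are emitted in every table so either convention for volcano
significance can be applied downstream.

## Reproducibility and problem sizes

Every stochastic function takes a seed and restores the caller's RNG
state; the pipeline derives per-stage child seeds deterministically from
one master seed, so identical config + seed gives identical artifacts
byte for byte. The test suite validates the machinery at deliberately
scaled sizes chosen to keep the full suite fast while preserving each
property being tested: the cohort-structure, region and clearance checks
run at the full 301-sample geometry; preprocessing and pipeline checks
use ~30-metabolite cohorts; stability-selection properties use 100 × 3-fold
selection on 144 features for the separable and recovery checks and
10–15 repetitions for reproducibility/null properties; the BH and
Mann–Whitney oracles enumerate thousands of small random cases.

## Known limitations

* No drift/batch correction; the generator produces none.
* The accuracy reported by stability selection is best-subset-biased (see
  above); it reproduces the convention of the emulated procedure and
  should not be read as an unbiased error estimate.
* Q² is one member of a family of cross-validated PCA criteria; absolute
  values are method-dependent.
* The positive/negative ion-mode merge is taken as given (one column per
  metabolite); duplicate detections across modes are the caller's
  responsibility, though `ion_mode` is carried so either convention can
  be expressed.
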