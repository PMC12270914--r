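---
title: "Methods behind icclock: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind icclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it implements:
the composite intrinsic-capacity (IC) score, the methylation clock trained on
it, and the downstream association machinery — together with every design
choice that was genuinely open, and what the synthetic-data tests do and do
not establish.

## 1. The IC score

Five clinical domains enter the score: cognition (MMSE, 0–30), locomotion
(SPPB, 0–12), psychological well-being (PHQ-9, 0–27, higher is *worse*),
sensory (WHO simple eye chart 0–3 and whisper test 0–2), and vitality
(handgrip strength, no fixed bounds). The scoring pipeline is:

1. **Complete cases only.** A participant missing any domain is dropped;
   the count removed is reported. No imputation is attempted — domain
   instruments are too heterogeneous for a defensible default.
2. **Rescale to [0,1], higher is better.** `(raw − min)/(max − min)` with
   instrument bounds; PHQ-9 is reversed. Grip strength has no instrument
   bounds, so the cohort-observed minimum and maximum define them. We do
   *not* sex-stratify the grip rescaling: the scoring rule is one rescaling
   per domain for everyone, and sex differences in vitality then appear in
   the score (as they should — they are a finding, not a nuisance).
3. **Sensory averaging.** The vision and hearing unit scores are averaged
   into one sensory domain before the z-step, so five domains enter the
   composite.
4. **Z-transform.** Per-domain `(x − mean)/sd` with the sample (n−1) sd;
   a zero-variance domain is an error naming the domain, not a silent NaN.
5. **Average and min–max normalize.** The overall IC is the row mean of
   the five z-scores, min–max normalized over the cohort so it spans
   exactly [0,1]. *Empirical* extremes of the domain average are used (the
   alternative — theoretical extremes of the instruments — is not well
   defined after z-transformation). All transform parameters (bounds,
   centers, scales, min–max frame) are frozen on the scoring cohort and
   stored so the identical transform can be reapplied to new individuals.

Two properties are worth stating precisely. The score is invariant to any
strictly increasing *affine* change of units in one domain's raw scores
(the z-transform absorbs it) — tested with a kg→lb change of grip units.
Monotonicity holds in *rank* form: raising one participant's
higher-is-better raw score never lowers their IC rank. The raw-value form
is not a theorem — the participant's change also moves the domain mean, sd
and potentially the min–max frame — so the rank form is what the tests
assert.

## 2. Age-trend statistics

Because the score–age relationships are nonlinear, correlations are
Spearman, with p-values from the t approximation
`t = ρ√((n−2)/(1−ρ²))` on n−2 df. Sex contrasts use the two-sided Wilcoxon
rank-sum test: exact enumeration of the rank-sum null over all assignments
when both groups have ≤ 10 members (ties included; the p-value is the null
probability of a rank sum at least as far from its mean as observed),
otherwise the tie-corrected normal approximation with continuity
correction.

The "age of decline" per domain comes from a continuous two-phase
regression. The parameterization is the hinge form

  `score ~ b0 + b1·age + b2·max(0, age − c)`

which is continuous at the breakpoint by construction; `slope1 = b1`,
`slope2 = b1 + b2`. The breakpoint is found by exhaustive grid search
(default step 1 year) rather than smooth optimization: the RSS profile in
`c` is piecewise smooth with many local minima, grid search is trivially
reproducible, and the natural independent oracle (a 0.1-year grid) checks
it. Candidates exclude the outer 5% of the age distribution (boundary
hinges are nearly collinear with the intercept/slope); equal-RSS ties go to
the smallest candidate. Note the first phase is estimated, not constrained
flat — the generator plants a flat first phase, the fitter does not assume
one.

## 3. The IC clock

**Bin filter.** Before training, IC scores are split into 20 bins of width
0.05 (`[k·0.05, (k+1)·0.05)`, the last bin closed at 1.0) and samples in
bins with fewer than 10 members are dropped. In an aging cohort this
removes the sparsely observed low-IC tail, which would otherwise dominate
the MAE loss with a handful of high-leverage samples.

**Cross-validated elastic net.** For each mixing parameter
α ∈ {0.1, …, 1.0}, a tenfold cross-validated elastic net is fit with mean
absolute error as the CV metric (glmnet's parameterization:
`(1/2n)·RSS + λ[α‖β‖₁ + (1−α)/2·‖β‖₂²]`, predictors standardized
internally, coefficients reported on the original beta scale). λ is chosen
at the CV-MAE minimum — *not* the one-standard-error rule, because the MAE
criterion is the only one named for this step. Folds are a seeded random
partition stratified by IC decile, which stabilizes fold difficulty at
modest n. Out-of-fold predictions at the selected λ cover each retained
sample exactly once and are stored.

**Model selection.** The α candidates are ranked three ways — descending
correlation between observed IC and out-of-fold predictions, ascending CV
MAE, ascending number of selected CpGs — and the winner minimizes the rank
sum. Rank-sum ties break toward the *larger* α (the sparser regime), since
parsimony is the stated third criterion. The winner is refit on all
retained samples at its selected λ.

**Prediction and acceleration.** A clock is just
`intercept + Σ weight·beta`, so the same path applies any published linear
clock from a `cpg,weight` coefficient file. Model CpGs missing from an
input matrix are an error by default; with `impute = "mean"` the training
mean beta (stored in the model/sidecar) is substituted up to a configurable
fraction — the pragmatic cross-platform policy. Age acceleration is the OLS
residual of the clock score on age (plus sex for the mortality models);
quintile extremes take `floor(n/5)` members per tail by rank with
first-occurrence tie-breaking, so the grouping is deterministic even under
ties.

**A numerical note on glmnet.** The L1 part of the objective is honored
exactly at any outcome scale, but glmnet internally standardizes the
outcome and the ridge part of the penalty picks up a factor of 1/sd(y)
relative to the documented objective. The objective-level oracle test
therefore standardizes the outcome (unit population variance), where both
conventions coincide; at the IC score's natural scale (sd ≈ 0.15–0.25) the
practical effect is a mild reparameterization of λ at α < 1.

## 4. Cell-type deconvolution

Houseman-style reference-based deconvolution is a constrained projection:
per sample, minimize ‖x − Rp‖² subject to p ≥ 0 and Σp = 1, where R is the
cell-type reference restricted to shared CpGs. We constrain Σp = 1 (not
≤ 1): outputs are reported as proportions of a whole, which also makes any
re-normalization question moot. The quadratic program is solved *exactly*
by enumerating nonzero-support subsets of the (≤ 12) cell types: each
subset gives one equality-constrained linear KKT solve, and the feasible
candidate with minimal RSS is the global optimum (the optimum's own support
appears among the candidates, and every candidate is a feasible point of
the full problem). KKT inverses are precomputed per subset, so per-sample
cost is a handful of small matrix–vector products. The shipped 6-type
reference is *synthetic* (marker-per-CpG construction); real published
blood references are user-supplied CSVs.

## 5. Transcriptome association and enrichment

Differential expression is per-gene OLS of (already normalized,
log-scale) expression on age-adjusted DNAm IC plus covariates, with t
statistics on residual df, two-sided p-values, and Benjamini–Hochberg
step-up q-values (`q(i) = min_{j≥i} m·p(j)/j`, capped at 1); the
significant set is q < 0.05.

The CpG–gene linkage statistic is the mean over clock CpGs of the maximum
over significant genes of |Spearman ρ| — "each clock CpG's best-correlated
signature gene". The phrase it operationalizes is ambiguous between
aggregations; mean-of-max is the implemented reading, chosen because it
directly measures whether *every* clock CpG connects to the expression
signature rather than a few CpGs connecting strongly. The null permutes the
expression matrix's sample labels, preserving both internal correlation
structures while severing the cross-linkage, with the +1 convention
`p = (1 + #{null ≥ obs})/(1 + B)` so p is never zero.

Over-representation is the one-sided hypergeometric tail with BH across
sets. Preranked GSEA ranks genes by −log10(p) descending and uses weight
exponent 1: members increment the running sum by their score (normalized by
the in-set score total), non-members decrement by a constant; the
enrichment score is the running-sum maximum (one-signed, positive extreme
only, matching a query signature that has no meaningful "depleted" end).
Significance comes from *gene-label* permutations — the preranked setting
has no sample labels to permute — again with the +1 convention.

## 6. Mortality

Cox proportional-hazards fits use the survival package (Efron tie
handling, the ecosystem default) behind this module's contracts; the focal
predictor is standardized so the hazard ratio is per one s.d. of age
acceleration, and models adjust for age and sex. Kaplan–Meier curves and
the two-group log-rank test compare the extreme DNAm IC quintiles.

The "lives X years longer" contrast is implemented as a restricted-mean
survival difference: the difference in areas under the two KM step
functions on [0, τ], computed by exact rectangle sums. This is an
interpretation — "based on the survival curves" admits several estimators —
but RMST is the standard curve-based life-expectancy-style contrast, and τ
must not exceed either curve's last observed time (no extrapolation).
Cause-specific analyses treat deaths from other causes as censored.

## 7. Health and lifestyle

The overall-health score is PC1 of the column-standardized health matrix.
Variables with > 20% missingness are dropped before samples are restricted
to complete cases (the cap keeps one badly collected variable from deleting
half the cohort). PC1's sign is arbitrary, so it is anchored: the score is
flipped if needed to correlate positively with a named anchor variable
(e.g. gait speed), making "higher = healthier" reproducible across runs.
Individual health variables are tested by logistic regression of
high-vs-low DNAm IC membership (IRLS via `glm`), with complete separation
detected and reported as non-estimable rather than returned as a huge
coefficient. Lifestyle/diet features go through a Spearman + BH screen;
constant features are excluded from the multiplicity count with a warning.

## 8. The synthetic world

The generator's defaults describe one fixed cohort model, chosen once:

- **Design**: 1,000 participants, ages uniform on 20–102, sex
  Bernoulli(0.5); ~0.7% missingness per domain (≈ 4% of participants
  incomplete across six instruments, matching a well-run cohort).
- **Domain trajectories**: flat at a young-adult baseline until a
  domain-specific breakpoint (78, 62, 60, 55, 55, 55 years), then linear
  decline; additive male offsets (better psychological score, +10 kg grip,
  slightly worse sensory scores); Gaussian noise at instrument-realistic
  sds; clipping to instrument bounds. Flat-then-linear matches the
  two-phase model the fit stage assumes, making recovery tests well-posed.
- **Methylome**: causal CpGs have mean beta `plogis(b0 + b1(IC − mean))`
  with b1 ~ N(0, 4) — the logistic link keeps betas in (0,1) without
  clipping dominating; cell-type CpGs are convex mixtures of the reference
  with age-trending softmax proportions (granulocytes rise, naive
  lymphocyte compartments shrink); the rest are flat noise. Measurement
  noise sd 0.03 everywhere, then clipping as a safety net.
- **Expression**: planted genes are linear in the supplied predictor with
  slopes ~ N(0, sd); the rest pure noise around gene baselines.
- **Survival**: exponential event times with rate
  `0.02·exp(log(1.38)·predictor)` per year, independent exponential
  censoring (0.015/year) and an administrative horizon of 25 years —
  i.e. the planted mortality effect equals the hazard ratio scale the
  downstream Cox stage is expected to recover.

One master seed drives everything; each stage draws from a deterministic
sub-stream of it, so regenerating one stage never perturbs another, and
identical configs are byte-identical.

**What a green test does not establish.** The generator does not emulate:
batch or plate effects; array probe artifacts (cross-reactivity, SNPs,
detection failures) — preprocessing is out of scope by design; the observed
inter-domain correlation matrix of any real cohort (domain couplings here
arise only through shared age structure); non-flat pre-breakpoint slopes;
non-proportional or non-exponential hazards; or informative censoring.
Passing recovery tests therefore demonstrates that the estimators are
correct *for the model class they assume*, not that the assumptions hold in
any particular cohort.

## 9. Tolerances and degenerate inputs

Exact algebraic identities (hand OLS, product-limit steps, simplex sums)
are tested at 1e-8–1e-12; solver-mediated agreements (Cox vs a 1-D
partial-likelihood maximizer, PCA vs power iteration, the penalized
objective vs a direct minimizer) at 1e-6–1e-7; stochastic calibrations at
the band stated by the acceptance criteria (e.g. 5% ± 2% null rejection).
Degenerate inputs fail loudly with typed conditions: constant vectors in
correlations, zero-variance domains, rank-deficient references, empty bin
retention, τ beyond a curve's support, complete separation in logistic
fits. Permutation p-values are bounded below by 1/(1+B) and never zero.
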