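---
title: "Methods: ancestry-stratified TWAS for survival outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ancestry-stratified TWAS for survival outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Predictive models of tumor gene expression built from germline genotypes
(TWAS expression models) are trained almost exclusively in cohorts of
European ancestry. When such models are carried into cohorts of African
ancestry, differences in allele frequencies and linkage disequilibrium
(LD) degrade both the models' accuracy and the validity of downstream
association tests. `stratwas` implements a fully stratified pipeline —
every stage fitted separately per ancestry stratum — from genotype and
expression quality control through cause-specific survival association,
together with a synthetic-cohort generator so that each stage's
statistical guarantees can be tested end-to-end without access to
restricted patient data.

# Pipeline stages and their models

## Genotype QC and expression normalization

Variants are filtered on dosage-based minor allele frequency (default
minimum 0.01) and on a Hardy–Weinberg exact test applied to rounded hard
calls (default threshold 1e-8). The exact test enumerates all
heterozygote counts compatible with the observed allele counts and uses
the mid-p correction, matching common PLINK practice. Two genotype
panels are intersected on (chrom, pos, ref, alt) keys, with swapped
ref/alt resolved by reflecting dosages (d → 2 − d).

Expression counts are upper-quartile scaled to the cohort's mean upper
quartile, transformed by log2(x + 1), and cleaned of `k` dimensions of
unwanted variation estimated by singular decomposition of the centered
control-gene (housekeeping) submatrix and regressed out of every gene.
log2(x + 1) is used as the variance-stabilizing step because the
downstream linear models need only approximate homoskedasticity; a
count-model-specific transform would add a dependency on distributional
assumptions the pipeline never uses. Outlying samples are flagged by
robust Mahalanobis distance on the top two principal-component scores
against a chi-squared(2) quantile; the level (default 0.01) is a
documented choice, since "significant outlier" has no canonical
definition in this setting.

## Covariate residualization and eQTL mapping

Expression is residualized on covariates (age, body-mass index,
menopausal status and genotype principal components are the intended
use) by OLS with an intercept; constant and collinear covariates are
dropped deterministically (later-listed columns lose). The eQTL scan
fits, for every gene–variant pair, E_g = X_s β_s + X_C β_C + ε and
reports the Wald test of β_s = 0. Computationally both expression and
dosages are residualized on the covariate design and the per-pair
statistics formed from cross-products; by the Frisch–Waugh theorem this
reproduces the joint fit exactly, and the degrees of freedom count all
fitted coefficients. A variant is *cis* to a gene when it lies within
500 kb of either gene end, *trans* otherwise — a pure function of
coordinates. Samples labeled with the Normal-like molecular subtype are
excluded before fitting (low tumor content).

Multiplicity is controlled hierarchically (Benjamini–Bogomolov): a
gene-level p-value is formed by Simes combination over each gene's
variants, genes are selected by BH at the target level, and within the
selected genes variant p-values are BH-adjusted and scaled by
(total genes / selected genes). An eGene is a selected family; an eSNP
is any variant with adjusted p below the level inside an eGene. Simes is
the natural within-family combination for a by-gene hierarchy; cis and
trans variants share one family per gene by default. A global-null
simulation in the test suite checks that the frequency of any false
eGene stays at the nominal level.

Cis effects of interest can be re-examined under local-ancestry
adjustment: expression, SNP dosage and local-ancestry dosage are each
residualized on the covariates, standardized, and jointly regressed
(g̃ ~ s̃ + l̃), reporting both unadjusted and adjusted SNP effects.

Functional enrichment of eSNPs near annotation intervals counts
observed overlaps within a window (default 1 kb), estimates the expected
count by resampling equal-sized variant sets from the tested background
(default 10,000 draws), and compares the two counts by Fisher's exact
test.

## Cis-heritability (stratified GREML)

Cis-heritability per gene is estimated by REML on variance components
with MAF/LD stratification: cis variants are standardized, assigned a
per-variant LD score (sum of squared correlations with cis neighbors),
binned by MAF × LD-score quantiles (default 2 × 2 at the package's desk
scale; the stratification counteracts bias when causal variants differ
from the panel in frequency or LD), and one GRM A = ZZ′/m is built per
non-empty bin. All GRMs plus a residual component are fitted jointly by
average-information (AI) REML with: an active-set treatment of
components pinned at the zero bound, step halving whenever the AI step
would decrease the restricted likelihood, and an EM-REML fallback step
(guaranteed ascent) when no damped AI step is acceptable. Convergence is
declared below 1e-6 change in restricted log-likelihood (cap 100
iterations); non-convergence is flagged, never silent. For a single GRM
the same updates run in the GRM eigenbasis where the covariance is
diagonal, making each iteration O(n); the two code paths are verified
equal in the tests. Trans variants never enter heritability estimation.

The h² > 0 test is a likelihood-ratio test against the intercept-only
model referred to the boundary mixture 0.5·χ²(0) + 0.5·χ²(1) (a single
aggregate test even with several components, giving one nominal p per
gene); genes pass the downstream filter at p < 0.10.

## Expression models and scheme selection

The feature set per gene is all cis variants plus trans variants with
hierarchically adjusted p below 0.01, LD-pruned by the greedy sliding
window rule (window 50 variants, step 5, r² threshold 0.5; within a
window the later-positioned member of the worst pair is removed). Two
estimation schemes are registered by default: elastic net (mixing 0.5,
penalty tuned by five-fold CV) and BLUP (single-GRM REML for the
variance components, weights via the ridge identity with penalty
λ* = m·σ²_e/σ²_g). A third, Bayesian-sparse-style scheme was considered
and left out: with the desk-scale panels used here its CV behavior is
indistinguishable from the elastic net at several times the cost.

The final model per (gene, stratum) is the scheme with the best
five-fold cross-validated R² (squared Pearson correlation between
strictly out-of-fold predictions and observations, with a shared, seeded
fold assignment across schemes); ties prefer the elastic net (sparser,
cheaper to impute). Genes qualify for survival association when
CV R² > 0.01 and the heritability filter passed. Weights are defined on
covariate-residualized expression — consumers must not re-add covariate
effects.

## GReX imputation and sampling-variability-aware validation

Imputation into a target panel matches model variants by
(chrom, pos, ref, alt), reflecting dosages for swapped alleles and
logging per-gene match rates; GReX = matched dosages × matched weights.
External-validation R² (EV R²) is the squared Spearman correlation
between imputed and observed expression — deliberately rank-based (and
therefore distinct from the Pearson-based training CV R²) so that
monotone distortions between platforms cannot masquerade as model
failure.

Because validation subgroups can be very small, every EV R² is
accompanied by a permutation analysis: observed expression is permuted
(default 10,000 times; within subgroup, where exchangeability holds),
the null EV R² recorded, and the empirical p computed with the add-one
estimator (never exactly zero). q-values across genes use Storey's
estimator with λ fixed at 0.5. A 90% confidence interval is built by
inverting the permutation acceptance region with a translation pivot on
the Fisher-z scale of the signed Spearman correlation: the null
z-values are centered at their mean and their α/2 and 1 − α/2 quantiles
translate the observed z; the interval is mapped back and squared (an
interval spanning zero has lower bound 0). The z scale matters: the
permutation null carries the sampling spread at ρ = 0 only, and
Fisher's transform is what makes that spread approximately valid at any
ρ. A pivot applied directly on the R² scale inherits the null's
(χ²₁-like, much narrower) spread and under-covers severely; the
coverage simulation in the acceptance suite (target 0.90, simulated
ρ² = 0.25 at n = 100) is the warrant for the construction, and the
duality "interval excludes 0 ⇔ small empirical p" holds to quantile
resolution because the permutation null of the signed correlation is
symmetric.

## Survival association

Association with survival uses the cause-specific proportional hazards
model λ_k(t) = λ_0k(t)·exp(GReX_g β_g + Z_C β_C): deaths from the
primary cause are events, competing-cause deaths and administrative
censoring are both censoring. The partial likelihood is maximized by
Newton–Raphson with Efron tie handling; the baseline hazard is never
estimated. Strata are analyzed by fully separate fits, not by a shared
baseline. Covariates intended here are age, estrogen-receptor status,
stage and study-phase analogues.

Wald z-statistics across the gene panel are corrected for bias and
inflation with an empirical-null fit: a three-component normal mixture
sampled by Gibbs on robustly standardized statistics, with conjugate
priors (Dirichlet weights strongly favoring the central component;
normal means; inverse-gamma variances) and the flanking components'
means constrained at least 2.5 current null-SDs away from the current
null location, so genuine signals are absorbed by the flanks. The
reported bias and inflation are posterior averages of the median and
MAD of the null-assigned statistics — robust summaries chosen because a
mixture inevitably reassigns a sliver of extreme nulls to the flanks,
which biases moment-based summaries but leaves median/MAD essentially
untouched. Corrected statistics (z − bias)/inflation feed BH adjustment
at FDR 0.10. Chain health is monitored by split R-hat on the bias chain
(default 5000 iterations, 2000 burn-in, seeded). Panels below 20 genes
skip the correction with a note rather than fit an unstable mixture.

The companion SNP-level survival GWAS runs the same cause-specific model
per variant; conditional analyses refit a gene's model with the most
significant local survival SNP appended to the covariates, flagging
near-collinearity (|r| > 0.99) between SNP and GReX. Hazard-ratio
intervals are plain Wald intervals.

Collider bias in case-only designs is inspected with the weighted burden
statistic Z̃ = WZ / (W Σ_ss W′)^{1/2} against external GWAS summary
statistics, with W the trained expression weights (the finite-sample
stand-in for Σ_es Σ_ss⁻¹, the convention of summary-based TWAS tools)
and Σ_ss the LD correlation matrix from a reference panel,
ridge-stabilized (default epsilon 1e-4) only when numerically singular,
with the applied epsilon reported.

## Power analysis

Both power modules are simulation-based with exponential event times and
independent censoring whose rate is tuned by bisection to the target
event fraction. The SNP-level module simulates genotype ~ Binomial(2,
risk-allele frequency 0.1), event rate 0.10, n = 3828 and significance
1.70e-8 by default, recording the 90th percentile of event times as a
landmark; the GReX-level module resamples a supplied empirical GReX
distribution with replacement and tests at 0.0096 (an FDR-adjusted 0.10
equivalent). Power is the fraction of replicates below the threshold,
with its binomial Monte Carlo standard error.

# The synthetic-cohort generator

The generator produces the minimal data structure on which every claim
above can be tested: two ancestry strata whose allele frequencies are
differentiated and whose genomes carry local LD.

* **Allele frequencies.** Ancestral frequencies are uniform on
  `maf_range` (default 0.05–0.5); population-specific frequencies follow
  a Balding–Nichols model with differentiation `fst` (default 0.15,
  typical of West African/European contrasts).
* **LD.** Haplotypes are drawn by thresholding a latent standard-normal
  AR(1) series (autocorrelation `ld_decay`, default 0.7) at the
  population frequency. This latent-copula scheme keeps the
  Balding–Nichols marginals exact — a literal copy-the-previous-allele
  scheme would distort them — while giving the geometrically decaying
  first-order LD the cross-ancestry findings hinge on; `ld_decay = 0`
  is exact independence. The chain resets between gene blocks, so genes
  tiled 1.2 Mb apart on the single synthetic chromosome are unlinked and
  cis/trans labels are unambiguous.
* **Admixture.** Stratum 1 is admixed: each sample's admixture
  proportion is Beta(`admixture_alpha`, 2) (default mean 0.8 from the
  first ancestral population), haplotype block origins are drawn per
  gene block, and the latent origin dosage is exposed directly as local
  ancestry — no inference step, by design.
* **Expression.** E_g = X_g w_g + X_C β_C + ε with weights on
  `n_causal_cis` variants (default 3) scaled so the realized genetic
  variance fraction equals the configured cis-h² (defaults cycle through
  0–0.3, bracketing the few-percent panel average reported for tumor
  expression); covariates (age-like, binary receptor status, two
  PC surrogates) carry a fixed variance fraction (default 0.1). With
  `shared_architecture` (default) one weight vector is drawn and scaled
  on stratum 1 and shared, so the second stratum's realized h² drifts
  with frequency differentiation — exactly the regime in which
  cross-stratum imputation degrades.
* **Survival.** Exponential cause-specific hazards: the primary cause
  loads `survival_beta` on standardized true GReX (plus a small age
  effect), the competing cause and censoring are independent
  exponentials, and the three rate constants are tuned by fixed-point
  iteration so the expected fractions match the configured
  event/competing/censor split (defaults 0.09/0.085/0.825, the split of
  a cohort with ~9% primary-cause mortality). Exponential rather than
  uniform censoring keeps the closed-form cause-probability of the
  all-exponential competing-risks model that makes the tuning exact.
* **Summary statistics.** Z ~ N(√n·Rβ, R) with R the realized
  (ridge-stabilized) LD correlation of a reference panel, so effects
  propagate through LD as in a real GWAS.

Everything is a deterministic function of the config seed (sub-stages
use fixed offsets), and re-runs are byte-identical.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: realistic recombination maps and
long-range LD, genotype-imputation error, count-level measurement noise
of expression platforms, population structure beyond two
strata/ancestries, non-proportional hazards, and informative censoring.
Trans effects have no mechanistic model for cross-ancestry asymmetry;
the generator simply parameterizes them per stratum.

# Numerical choices and degenerate inputs

* Missing dosages are mean-imputed per variant at read time (complete
  matrices are required downstream); the imputed fraction is recorded.
* REML components are floored at 1e-8 of var(y); negative LRT statistics
  are clipped to 0; h² is clamped to [0, 1]; the h² standard error comes
  from the inverse AI matrix by the delta method.
* The empirical permutation p uses the add-one estimator; a degenerate
  permutation null yields a flagged point interval.
* Zero-variance inputs (constant covariates, monomorphic variants,
  constant expression) are dropped or flagged rather than propagated.
* Ridge stabilization (LD matrices): applied only when the smallest
  eigenvalue falls below 1e-8, with the applied epsilon reported.
* Ties: LD pruning removes the later-positioned variant; scheme
  selection prefers the elastic net; average ranks handle ties in
  Spearman correlations.

# Problem sizes used by the test and acceptance suites

The suites exercise the pipeline at sizes chosen to make Monte Carlo
error small relative to the property being checked while keeping a
desk-scale footprint: calibration suites use 100–2000 replicates of
cohorts with 100–300 samples; parameter recovery uses n = 1000 (REML,
50 replicates), n = 3000 (Cox, 200 replicates) and 2000 statistics
(empirical null); the coverage simulation uses 1000 replicates at
n = 100 with 200 permutations; the end-to-end survival analysis uses
cohorts of 1900 with 800-sample training subsets, mirroring the
relative sizes of a training-within-cohort design. `scripts/acceptance.R`
re-runs the same computations from scratch at comparable sizes and
writes the resulting quantities as JSON.

# Known limitations

* The hierarchical FDR procedure treats each gene's variant family as
  exchangeable; strong within-family LD makes Simes conservative.
* The empirical-null mixture assumes most genes are null; panels where a
  large fraction of genes carry true survival signal would bias the
  null component.
* BLUP weights inherit single-GRM REML's assumption of a homogeneous
  per-variant effect variance; the elastic net usually wins model
  selection when architectures are sparse.
* The CI inversion is an approximation warranted by simulation, not an
  exact pivot; coverage slightly below nominal (a few points) is
  expected for Spearman correlations at moderate ρ.
* Cause-specific hazards answer etiological questions; they are not
  cumulative-incidence (Fine–Gray) estimates and should not be read as
  absolute-risk statements.
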