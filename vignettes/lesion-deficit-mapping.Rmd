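---
title: "Mapping domain-specific cognition with and without g: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping domain-specific cognition with and without g: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Lesion-deficit mapping associates focal brain damage with behavioral
deficits, voxel by voxel or connection by connection. Performance on
essentially every cognitive test, however, draws on domain-general
cognition (g) as well as on the targeted domain. When a domain score
still contains g variance, its lesion-deficit map inherits the anatomy
of g, and maps of nominally distinct abilities end up looking alike.

`gLDM` implements the full analysis needed to quantify that effect:

1. model a 23-test neuropsychological battery twice — once with a
   **bifactor** model (every test loads on g plus one domain factor;
   all factors orthogonal), once with a **correlated-factors** model
   (domain factors only, freely inter-correlated, so g variance stays
   embedded in each factor);
2. derive factor scores per patient from each model;
3. map every domain score onto the brain with three modalities —
   voxelwise lesion-behavior mapping (LBM), structural lesion network
   mapping (sLNM, streamline disconnection), functional lesion network
   mapping (fLNM, normative connectivity seed maps);
4. compare the spatial inter-correlations of the domain maps between
   the two cognitive models with a sign-flip permutation test of a
   dependent-samples t statistic.

Real patient registries of this kind are not redistributable, so the
package ships a synthetic-cohort generator with exported ground truth;
every statistical property of the pipeline is validated against that
ground truth.

# Cognitive models

## Structure

The default battery has 23 tests in five domains (crystallized
knowledge, verbal learning/memory, processing speed, visuospatial
ability, language); `defaultTestBattery()` prints the assignment. Two
residual covariances are freed by default (copy/recall trials of the
same figure; the two trail-making parts) because these pairs share
method variance beyond their factors.

The bifactor specification adds a g factor loading on all 23 tests and
constrains all factor covariances to zero. The correlated-factors
specification removes g and frees the domain-factor correlations.
Factor variances are fixed to 1 and all loadings are free — this
identifies the model without marker variables and makes omega
coefficients direct functions of the loadings.

## Estimation

`fitCfa()` maximizes the multivariate-normal likelihood with a
quasi-Newton (BFGS) optimizer on transformed parameters:

* uniquenesses enter as log-variances, so Heywood cases surface as
  boundary solutions (with a warning) rather than negative variances;
* free factor correlations enter as `tanh` of unconstrained reals;
* means are saturated (one free mean per test).

Missing data are handled by full-information maximum likelihood
(FIML): the likelihood is accumulated casewise over each patient's
observed test subset. Internally patients are grouped by missing-data
pattern and per-pattern sufficient statistics are evaluated in
compiled code with analytic gradients, so a 473-patient fit with ~21%
missingness takes seconds. With complete data FIML reduces exactly to
ordinary ML (`estimator = "ml_complete"` forces listwise deletion).

The saturated model needed for the likelihood-ratio chi-square is
estimated by EM on the same pattern statistics; the independence
baseline has closed-form per-column MLEs. Fit indices (CFI, TLI,
RMSEA, SRMR) use the standard ML formulas; robust (scaled) variants
require weight estimates outside this package's scope and are
deliberately not implemented, so printed indices from robust-ML
analyses elsewhere are not directly comparable.

The optimizer runs three starts by default (one moment-based, two
jittered); a likelihood-ascent guard never accepts a solution worse
than its own start, and the convergence flag is stored honestly in the
fitted object. Heavy simulation studies in the test suite use single
starts — the recovery statistics are indistinguishable in practice.

Factor scores are regression (maximum a posteriori) scores computed
from each patient's observed subset with model-implied covariances;
patients missing up to a third of the battery still receive finite
scores. The extractor choice matters little for mapping because maps
use correlations, which are invariant to affine rescaling of scores.

Omega hierarchical for factor f is `(sum of f's loadings)^2 /
(model-implied variance of the corresponding scale score)`, computed
for the general factor over all tests and for each group factor over
its indicators.

# Lesion-deficit mapping

## Mass-univariate engine

For each feature (voxel lesion indicator, parcel-pair percent
disconnection, or connectivity T value), `voxelwisePartialCorr()`
computes the partial Pearson correlation with the score, controlling
log lesion volume (natural log of lesion volume in mm³) by default.
Partialling is done by exact least-squares residualization (QR), so
the result matches a residualize-then-correlate oracle to machine
precision. Signs are kept: damage that lowers scores gives negative r.
The t statistic is `r * sqrt((n - 2 - c) / (1 - r^2))` with c
covariates.

Feature inclusion: binary features must be lesioned in at least
`minLesion = 4` and at most `n - 4` patients; continuous features must
be non-constant (and, for disconnection edges, nonzero in at least
`minLesion` patients). The field has no published standard for this
filter, so it is configuration, not doctrine.

## Family-wise error correction

`permutationFwe()` implements continuous FWE correction: scores are
permuted across patients (lesion-covariate pairs stay intact), the
statistics are recomputed, and the v-th largest |t| of each
permutation forms the null distribution. With `v = 1` this is the
classical max-statistic correction controlling the probability of even
one false-positive feature. The threshold is the ceiling-index
(1 - alpha) order statistic of the null set *including the observed
statistic* — both choices are conservative and guarantee validity of
the procedure, which the test suite verifies empirically (the
realized familywise error rate over 200 null cohorts sits below the
nominal 0.05). Permuting only the score vector is the simplest scheme
consistent with a mass-univariate partial-correlation analysis;
maps feed the spatial comparison *unthresholded*, so the correction
affects inference about single features, not the headline comparison.

## PLSR

`plsrMap()` provides the multivariate counterpart: scores are
residualized on the covariates, the PLS component count is chosen by
repeated cross-validation (5 folds x 5 repeats by default, predictive
correlation criterion), and the final model is fitted to all data. The
PLS decomposition itself is delegated to `mixOmics::pls`; the package
owns the residualization, CV, and the variance-explained convention
(correlation between full-model predictions and observed scores).
Degenerate folds with constant responses are refolded with a warning.

# Lesion network mapping

**sLNM.** `disconnectionMatrix()` marks a streamline disconnected as
soon as one of its voxels lies in the lesion (any-voxel intersection),
and reports per parcel pair the percentage of its streamlines
disconnected — a P x P symmetric matrix with zero diagonal. Growing a
lesion can never decrease any entry. Edges are vectorized over the
upper triangle so each pair is tested once.

**fLNM.** `flnmMap()` seeds the normative resting-state data with the
lesion: per normative subject, the first principal component time
course of the within-lesion voxels (sign-aligned with the mean seed
series, which resolves PCA's sign ambiguity) is correlated with every
voxel and Fisher-z transformed; a one-sample t across subjects yields
the patient's map. A single-voxel lesion degenerates exactly to plain
seed-based connectivity. Voxels inside the seeding lesion are excluded
(`NA`) because seed-target overlap is uninformative; the group
analysis handles these voxels with per-voxel complete cases, which the
mapping engine implements by grouping features with identical
missing-patient patterns. The PC1-based seed time course is the
default; a mean-time-course variant would differ only in how the seed
signal is summarized and is intentionally not a separate code path —
PC1 equals the (sign-aligned) dominant axis, and for compact synthetic
lesions the two are nearly collinear.

# Comparing the two models' maps

`compareModelMaps()` computes all pairwise spatial correlations
(Pearson, over the identical unthresholded feature set) among the K
domain maps per model, Fisher-transforms them, and forms paired
differences `d = z_correlated - z_bifactor` matched by domain pair.
The observed statistic is the dependent-samples t of `d`; its null is
built by independently sign-flipping each pair (`signFlipPairedTest()`),
the canonical exact permutation analogue of a paired t test. The
default alternative is one-sided — bifactor maps *less*
inter-correlated — matching the directional scientific hypothesis;
`two.sided` is available. Crystallized knowledge is not mapped by
default (largely robust to focal damage and historically poorly
localizing), so K = 4 domains and 6 pairs enter the comparison; with
fewer than 3 pairs the function warns that p is unreliable. The
comparison runs separately per modality.

Note a deliberate statistical subtlety: the 6 pairs share maps, so
they are not independent. Sign-flipping is exact under sign-symmetry
of `d`; under map-level exchangeability it is the standard
approximation used in the field, and the test suite checks both that
p values are exactly valid under sign-symmetric differences and
approximately uniform under exchangeable map sets.

# The synthetic world

The generator produces, from a config and a master seed:

* an ellipsoidal brain mask on an isotropic 3 mm grid (default
  20 x 24 x 20 voxels), tiled into contiguous parcels (Voronoi cells
  of random in-mask seeds; cells of a convex mask are connected),
  grouped into spatially coherent networks (k-means on centroids);
* a streamline tractogram: jittered voxel paths between random voxels
  of each connected parcel pair;
* normative resting-state series: per voxel,
  `sqrt(w) * networkSignal + sqrt(1 - w) * noise`, so within-network
  voxel pairs correlate ~`w` (default 0.4) and across-network pairs
  ~0;
* lesions: unions of 1-3 jittered spheres (radii uniform on 1.2-3.5
  voxels) clipped to the mask — the simplest generator of contiguous,
  variably sized lesions;
* behavior: latent factor scores drawn standard normal, decremented by
  `effect x fractionLesioned` of each factor's planted anatomy
  (a minimal monotone dose-response), then observed tests =
  loadings x factors + noise, with entries deleted completely at
  random (MCAR) at 20.8% by default. MCAR matches the FIML assumption;
  nothing in the pipeline estimates the missingness mechanism.

Ground-truth defaults are a standardized bifactor: every test loads
0.6 on g and 0.45 on its domain, uniquenesses completing unit
variance. True per-test loading magnitudes of real batteries are not
public tabled quantities; these values give communalities (~0.56) and
inter-domain correlations (~0.6 under the correlated-factors view)
typical of neuropsychological batteries, and they are free
configuration, not empirical claims. Planted anatomy gives g two
parcels and each mapped domain one disjoint parcel (spheres of ~2.2
voxel radius around parcel centroids); crystallized knowledge gets no
anatomy, encoding its robustness to focal damage. The effect size 3
(score SD per fully lesioned region) makes a typical partial overlap
shift scores by ~0.5-1 SD — a strong but clinically plausible deficit
signal.

What the generator does *not* emulate: vascular lesion anatomy and
etiology structure, registration error, spatial autocorrelation of
real BOLD data, demographic norming, non-MCAR missingness (real
missingness is plausibly related to deficit severity), and measurement
non-normality. Passing tests therefore demonstrate the statistical
machinery is correct and calibrated under the stated generative
assumptions — not that real-data results are reproduced.

# Numerical choices and conventions

* Voxel indices are 0-based in all external files (NIfTI affine
  carries world coordinates; the tractogram JSONL stores 0-based
  (i, j, k) triples); in-memory R objects use 1-based linear indices.
* Optimizer: BFGS, relative tolerance 1e-10 on the discrepancy
  (about 1e-6 absolute on the log-likelihood at study scale), up to
  1000 iterations, 3 starts.
* EM for the saturated model stops when -2 loglik changes by < 1e-7
  relative; a tiny ridge is added if an EM covariance iterate loses
  definiteness.
* Permutation thresholds use the ceiling-index order statistic and
  include the observed statistic (both conservative).
* Ties and sign conventions: each fitted factor's loading sum is
  flipped nonnegative; fLNM PC1 is sign-aligned to the mean seed
  series.
* Every generator and analysis derives a child seed from the master
  seed plus a stage tag, so stages are independently reproducible and
  a full `runAll()` is bit-identical under a fixed seed.
* A score left without variance after partialling (e.g. the score *is*
  the covariate) yields partial r defined as 0 rather than numerical
  noise.

A subtlety worth knowing when designing null checks: even with *no*
lesion-deficit anatomy for g, correlated-factors domain scores still
share g's behavioral variance, and that shared score component
correlates the *estimation noise* of their maps — inflating inter-map
correlations at any sample size. The package's neutrality check
therefore uses a world with no g at all (zero g loadings and no g
anatomy); there the two models' map sets are equally inter-correlated,
as they should be. Conversely, this phenomenon means that merely
removing g's anatomy does not make the correlated-factors approach
innocuous: shared behavioral variance alone biases map similarity,
which is precisely the argument for bifactor scoring. For fLNM the
analogue of "disjoint domain anatomy" is placement of the domain
regions in distinct functional networks; the comparison study pins one
parcel per domain to a distinct network and gives g two further
parcels.

# Problem sizes used by the test suite

Simulation-based checks run at sizes chosen to make their statistical
assertions decisive while keeping the suite practical on one CPU:
familywise-error calibration uses 200 null cohorts of 150 patients on
a 12 x 14 x 12 grid (~760 analyzable voxels) with 500 permutations;
parameter recovery uses 20 cohorts at the full study scale (n = 473,
20.8% MCAR); the directional model-comparison replication uses 50
cohorts of 200 patients with 2000 comparison permutations; comparison
null calibration uses 200 exchangeable map-set replicates (the
comparison statistic depends on the maps only, so cohort regeneration
adds nothing to that check).

# Pipeline and formats

`runAll(config, outdir)` executes simulate → fit-factors → map-lbm →
map-slnm → map-flnm → compare, writing NIfTI volumes (lesion stack,
parcellation, per-map r/t/significance), TSV tables (behavior, truth
and estimated factor scores, per-feature map statistics, pairwise
comparison values), JSON reports (fitted models with indices and
omega, per-modality comparisons, permutation sidecars) and a
provenance manifest (config hash, seed, version, file inventory).
`runStage()` reruns any stage idempotently and fails with an explicit
dependency error if upstream artifacts are missing; mapping stages
accept externally supplied lesion stacks and score tables, and an
individual-test mode maps raw test columns instead of factor scores.
Normative functional data are regenerated deterministically from the
config seed rather than persisted, trading a few seconds of compute
for gigabytes of storage. A thin CLI wrapper lives at
`inst/scripts/ldm.R`.

# Known limitations

* Robust (scaled) fit indices and non-normal/ordinal indicators are
  out of scope; standard ML indices are reported.
* The model-modification workflow is deliberately manual: candidate
  specifications are fitted and compared with `chisqDiffTest()`; there
  is no automatic specification search.
* Spatial-autocorrelation-preserving null maps (spin tests) are not
  implemented; the sign-flip comparison addresses pairing, not
  spatial autocorrelation.
* The synthetic tractogram and functional data are statistical
  stand-ins, not anatomical atlases; parcel counts and matrix
  dimensions follow configuration.
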