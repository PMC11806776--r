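---
title: "Methods: landmark shape analysis with replicated digitization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark shape analysis with replicated digitization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

prosomorph implements the classical landmark-based geometric-morphometrics
workflow for 2-D configurations digitized in replicate: superimposition,
measurement-error decomposition, ordination, discrimination, and allometric
regression. This vignette is the package's account of the underlying models,
the choices that were genuinely open, and what the synthetic data generator
does and does not emulate.

## Data model

A dataset is a tibble with one row per digitized configuration: coordinate
columns `x1..xk, y1..yk` plus free-form metadata. The reference design — the
one the built-in generator reproduces — is a two-population
("H1"/"H2") by two-sex study of spider prosomata with k = 17 landmarks
(1–8 on the pars cephalica, 9–17 on the pars thoracica), 129 specimens
(28 + 27 + 42 + 32 per population-by-sex group), each photographed twice and
each photo digitized twice: 516 configurations in all. Coordinates are read
and written in the tpsDig dialect of the TPS format; classifiers travel in a
CSV keyed by a per-configuration `id`.

Coordinates are x-right, y-up with arbitrary origin. No image-row inversion
is applied: superimposition removes the convention, but wireframe plots
inherit it.

## Superimposition

`gpa()` performs generalized Procrustes analysis. Every configuration is
centered and scaled to unit centroid size
(CS = sqrt of the summed squared landmark distances from the centroid);
each is rotated to the current consensus by the closed-form 2-D solution
(no reflections, rotation determinant +1); the consensus is the re-normalized
mean of the aligned configurations, iterated until its RMS change falls
below `tol` (default 1e-10, `max_iter` 100 with a flagged partial result on
non-convergence). Original centroid sizes are recorded before scaling;
log CS uses the natural log (the base only rescales regression slopes).

Two conventions are worth stating:

* **Frame standardization.** After convergence everything is rotated so the
  consensus lies along its principal axes, with a deterministic 180°
  convention. The first configuration seeds the iteration but leaves no trace
  in the result, which makes GPA output invariant to input order and to
  arbitrary similarity transforms of the input — both properties are tested.
  Estimated directions (PC loadings, discriminant axes, allometric slopes)
  are therefore expressed in the consensus frame, not the raw digitizing
  frame.
* **Fit type.** Configurations stay at unit centroid size during iteration
  (the partial-fit convention); `align_pair()` additionally optimizes scale
  and returns the full Procrustes distance. For the small shape distances
  this workflow targets the two agree to third order; tests assert the
  full-fit identity through `procrustes_distance()`.

`shape_variables()` projects aligned configurations orthogonally onto the
tangent plane at the consensus, removing residual components along the four
similarity directions (two translations, scaling, infinitesimal rotation).
The resulting coordinates span at most 2k − 4 dimensions (30 for k = 17) —
the rank deficiency every downstream covariance inversion must respect.

With replicated digitization, GPA runs on **all** replicates and
between-group analyses run on per-specimen averages
(`average_replicates()`). The averaging rule is a documented choice: the
source study does not state how its four replicates per specimen entered the
between-group stages, and averaging after a joint GPA is the standard
workflow for replicated designs.

## Measurement error

`procrustes_anova()` is the Goodall-style nested ANOVA of tangent
coordinates — individuals / images within individuals / digitizations within
images — with sums of squares pooled over coordinates (the isotropy
assumption) and design df multiplied by the shape dimension 2k − 4. Each
level is tested against the level nested inside it. Variance components per
coordinate come from the balanced-design expected mean squares; the
digitization component equals `MS_dig` directly, which is what the
recovery tests check (within 20% at 50 specimens × 2 × 2, where the
estimator's relative standard error is about 2.6%).

Because isotropy is an assumption, `pillai_check()` re-tests the replicate
factor non-isotropically: a one-way MANOVA (Pillai's trace) on leading PCs
retaining 95% of the variance, capped at the residual df minus one so the
error covariance stays nonsingular. With one retained dimension it reduces
exactly to the univariate ANOVA F.

## Ordination and group tests

`shape_pca()` eigendecomposes the sample variance–covariance matrix
(divisor n − 1; covariance, not correlation, since shape coordinates share
a scale) with a deterministic sign convention. `manova_on_pcs()` computes
Wilks' λ as the determinant ratio of within to total cross-products on the
leading PCs — by default enough PCs for 90% of the variance, configurable up
to the full nonzero-rank space — with Rao's F approximation (exact for two
groups). The source study reports MANOVA df implying the full 30-dimensional
response yet a 13-PC retention rule; both are supported via `retain`/`m`, and
the package takes no position on which was run.

`dfa()` reduces shape variables to their nonzero-variance PCs (capped at
n − 3) before inverting the pooled within-group covariance W; the axis is
W⁻¹(m₂ − m₁), D² the corresponding quadratic form, T² = n₁n₂/n · D² with its
exact F. The Procrustes distance between group means is the tangent-space
Euclidean distance. Permutation tests reshuffle group labels wholesale at
specimen level — specimens, not replicates, are the exchangeable units — with
the add-one estimator p = (#{stat ≥ observed} + 1)/(n_perm + 1), so p is
never 0 and never below 1/(n_perm + 1). Classification is nearest-Mahalanobis
with ties broken toward the first sorted label, reported both by
resubstitution and by leave-one-out jackknife (each held-out specimen is
classified with means and a W recomputed without it, via a rank-one SSCP
downdate).

`cva()` whitens by the pooled within-group covariance (Cholesky) and solves
the symmetric eigenproblem of the between-group covariance, scaling axes to
unit within-group variance; with two groups CV1 spans the DFA axis exactly.
Pairwise group statistics reuse the two-group machinery per pair.

p-values are two-sided and uncorrected for multiple testing — the workflow
this package reproduces applies none — which users combining many pairwise
tests should keep in mind.

## Allometry

`regress_shape_on_size()` regresses every tangent coordinate on log CS.
With `pooled_within = TRUE` both sides are first centered within groups, so
the slope is the common static allometry and group mean differences cannot
leak into it. The headline statistic is the percent of total shape variation
predicted, 100·SS_pred/SS_total pooled over coordinates; its permutation
test reshuffles sizes against shapes (within groups when pooled, matching
the model's conditioning). The fitted slope lies in the tangent subspace by
construction. `mancova_trajectories()` fits scores ~ group × log CS on PCs
retained to 90% (configurable), reads the common-slopes test off the
interaction term, then refits without the interaction to test the group
effect at fixed size.

## Visualization

`exaggerate()` magnifies a mean-shape difference linearly in tangent space
(the standard "5×/10× magnification" display); `wireframe_segments()` turns
it into plot-ready segments using a link list. The default 17-landmark link
list and the default mean shape are illustrative fixtures — a prosoma-like
convex outline with a cephalica/thoracica chord — not measurements.
`tps_warp()` solves the standard 2-D thin-plate spline interpolation with
kernel U(r) = r² log r², reporting the bending energy of the non-affine part
(zero iff the map is affine) and evaluating the warp on a regular grid;
`tps_transform()` evaluates it anywhere, so grid refinement never moves a
previously evaluated point. Numeric outputs (segments, grid coordinates) are
the tested surface; ggplot2 display is a thin layer above them.

## The synthetic generator

Since the emulated study deposited no raw data, `synthetic_spec()` +
`generate_dataset()` define the study conditions. Per specimen the generator
draws a true log CS (group-specific normal) and an individual tangent
deviation; adds fixed population, sex and interaction effects (half the
effect vector to each factor level, so the vector's norm equals the
Procrustes distance between level means) and an optional allometric
component proportional to the specimen's log CS deviation from its group
mean; then layers photo- and digitization-level isotropic Gaussian jitter,
applies a random rotation and translation, and scales the configuration so
its centroid size is exp(log CS) exactly. Noise is injected in the shape
frame before the nuisance transform, matching the exchangeable-landmark
error model Procrustes ANOVA assumes. One master seed derives a deterministic
substream per tier (specimen / image / digitization / nuisance), so toggling
the nuisance tier reproduces the identical shape variables — a tested
invariant.

Default magnitudes are calibrated once to the statistics the emulated study
prints, since no raw data exist to fit: population effect 0.017 (its reported
between-population Procrustes distance), sex effect 0.07 (between its two
per-population sex distances), individual noise SD 0.01 per coordinate
(placing the population effect inside the individual scatter, reproducing the
reported population overlap), image and digitization SDs 0.002 (digitizing
error "negligible" next to individual variation), log CS means 0.74/0.82 with
SD 0.08 (second population larger, size ANOVA F of the reported order), and a
common allometric vector of 0.08 per unit log CS (about 1% of shape variance
predicted by size). These are illustrative study conditions, fixed in the
defaults and not tuned thereafter.

What the generator does **not** emulate: non-Gaussian or landmark-specific
digitizing error, correlated individual variation (real covariance structure
concentrates variance in few PCs; isotropic noise spreads it evenly, so
simulated eigenvalue spectra are flatter than real ones), outliers,
semilandmarks, or any image-level artifact. Passing tests therefore certify
the statistical machinery under the stated error model, not the biology of
any real population.

## Numerical choices and limitations

* GPA: tol 1e-10 RMS on the consensus, max 100 iterations; typical data
  converge in < 10.
* Rank handling: eigenvalues below max·1e-10 are treated as zero everywhere a
  covariance is inverted; response dimensions are additionally capped by
  residual df (with a warning) in MANOVA/MANCOVA/Pillai.
* Permutation p-values use the add-one estimator with a 1e-12 tie tolerance.
* Tie-breaks in classification go to the first sorted group label.
* Degenerate inputs (coincident landmarks, collinear TPS sources, constant
  log CS, groups below minimum size, unbalanced replicate designs) raise
  errors rather than warnings.
* Problem sizes in the test suite are chosen for desk-scale runs: null
  calibrations use 500 simulated datasets of 24 specimens with 499
  permutations; recovery checks use up to 400 configurations. The package
  itself has no size limits beyond memory.
* Only 2-D landmarks, nested (not crossed) replicate designs, linear
  discriminants and a single size covariate are supported.
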