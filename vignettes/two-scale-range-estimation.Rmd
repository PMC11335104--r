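---
title: "Two-scale range estimation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-scale range estimation: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occuRange)
```

# The problem

Where a rare species *could* live and where it *does* live are different
questions, answered at different spatial scales with different data. A
correlative ecological niche model (ENM) relates presence-only records to
macro-scale environmental rasters and delimits the *potential* distribution;
a site-occupancy model relates repeated detection/non-detection surveys to
habitat covariates, correcting for imperfect detection, and describes
habitat use at the micro scale. `occuRange` implements both components and
a fusion rule — keep the fine-resolution cells that are macro-suitable
*and* above an occupancy threshold — yielding a *realized* distribution map
with area accounting, plus the IUCN extent-of-occurrence (EOO) and
area-of-occupancy (AOO) comparators.

# The maximum-entropy niche model

## Model

Given presence cells $x_1 \dots x_m$ and a background sample $B$ drawn from
the accessible area $M$, the model is the Gibbs distribution
$q_\lambda(x) \propto e^{\lambda' f(x)}$ over $B$ that minimizes

$$-\frac1m \sum_{i=1}^m \lambda' f(x_i)
  + \log \sum_{x \in B} e^{\lambda' f(x)}
  + \sum_j \beta_j |\lambda_j|.$$

Features $f$ are the covariates rescaled to $[0,1]$ by their background
min/max (linear class `l`), their squares (quadratic class `q`), or both
(`lq`); hinge, product and threshold features are deliberately out of
scope, which keeps the objective smooth apart from the L1 term. The penalty
scale $\beta_j$ is the regularization multiplier times the published
default for linear/quadratic features, interpolated in the presence count
$m$ through the points $(10, 1.0)$, $(30, 0.2)$, $(100, 0.05)$ and clamped
outside. Note the penalty does not include a per-feature standard-deviation
factor; the contract is the interpolation table itself, and the practical
consequence (fit invariance under duplication of the presence list) holds
exactly once $m \ge 100$.

## Optimizer

The objective is convex; `fitMaxent()` uses an active-set Newton method:
coordinates enter the active set when their subgradient condition
$|g_j| \le \beta_j$ is violated, Newton steps with backtracking are taken
within the active set (truncated at sign crossings, which also removes
coordinates that return to zero), and the fit is declared converged when
the optimality residual's sup-norm drops below $10^{-6}$. Failure to reach
that residual is an error, not a silent result. The unit tests pin the
optimizer against an exhaustive $0.01$-step grid search of the same loss on
a 20-cell background.

## Output scales

*Raw* output is $q_\lambda$ itself (summing to 1 over the background; used
for AICc, with $K$ = the number of nonzero weights). *Cloglog* output is
$1 - \exp(-e^{H} q_\lambda(x))$ with $H$ the entropy of the fitted raw
distribution — a monotone rescaling onto $[0,1]$ used for thresholding and
consensus. AICc on raw output and consensus on cloglog output follow the
conventions of the candidate-evaluation literature for this model family.

## Candidate grid and selection

`runCandidateGrid()` crosses regularization multipliers (default grid 0.1
to 5, where 1 is the conventional default), feature classes (`l`, `q`,
`lq`) and variable sets, all sharing one 20% random test partition of the
occurrences. Candidates are evaluated by omission rate at the 5%
training-presence threshold, bootstrap partial ROC (500 iterations, 50%
resampling — common practice for this statistic; the AUC ratio is the
partial area of the model ROC over the sensitivity $\ge 0.95$ region
divided by the chance diagonal over the same proportion-of-area interval),
and AICc. Selection retains candidates with omission $< 5\%$, mean AUC
ratio $> 1$ and pROC $p < 0.05$, then applies a $\Delta\mathrm{AICc} \le 2$
window within the survivors; both cuts are arguments. The consensus map is
the cellwise median of the selected cloglog grids, binarized at the mean of
the per-model 10th-percentile training-presence thresholds
(linear-interpolation percentile; ties binarize to presence).

# Data preparation

Occurrences are thinned greedily in input order so all pairwise great-circle
distances (haversine, mean Earth radius 6371.0088 km) are at least 1 km;
greedy in-order retention is deterministic and idempotent, which we value
over the marginally larger sets a randomized thinner can keep. The
accessible area $M$ is the convex hull of 50-km buffers around each record
(buffers built in a per-record azimuthal-equidistant projection, so the
radius is metric), clipped against the supplied region polygon. Rasters are
resampled bilinearly (nearest-neighbour for categorical layers) onto the
1-km modelling grid: geographic WGS84, cell-center registration, row 1
northernmost. The Spearman filter computes all pairwise correlations over
cells inside $M$ and keeps layers greedily in input order under
$|\rho| < 0.8$ — the drop rule (earlier-listed layer wins) is our
determinism choice; the criterion itself is the standard one.

# The occupancy model

## Likelihood

For site $i$ with detections $y_{ij} \in \{0, 1\}$ over conducted occasions,

$$L_i = \psi_i \prod_j p_{ij}^{y_{ij}} (1-p_{ij})^{1-y_{ij}}
      + (1-\psi_i)\, \mathbf 1\{\text{no detection at } i\},$$

with $\operatorname{logit}\psi_i = x_i'\beta$ and
$\operatorname{logit} p_{ij} = w_{ij}'\alpha$. Unconducted surveys
(missing cells) contribute nothing, and their covariate values are never
touched. All covariates are standardized (mean 0, sd 1) with the
transformation recorded, so predictions accept natural units. The
implementation is checked against brute-force enumeration of the latent
state vector on every random dataset with at most 10 sites.

## Estimation and selection

`fitOccupancy()` maximizes the likelihood by BFGS with an analytic
gradient, from a zero start plus four seeded $N(0, 0.5)$-jittered restarts
(these likelihoods are multimodal in small samples). Unbounded estimates
(|coefficient| > 15, i.e. complete separation) and failed convergence yield
*flagged* fits that model tables exclude. AICc uses $n$ = number of sites —
the common convention; with 30 sites and $K = 3$ the correction over AIC is
$24/26 \approx 0.923$. Model selection is detection-first: the best
detection structure under constant occupancy is fixed, then occupancy
candidates are compared; candidates are limited to one or two covariates by
a validator, and the candidate lists are plain R lists, not hard-coded.

## Goodness of fit

The parametric bootstrap uses the MacKenzie–Bailey chi-squared on
detection-history frequencies: sites are grouped into cohorts by their
missingness pattern, expected history counts are accumulated over sites
within a cohort, observed histories contribute $(O-E)^2/E$, and the pooled
expectation of unobserved histories is added. The choice of this statistic
is ours — the requirement was only "a chi-squared test" — because it is the
standard history-frequency discrepancy for this model class. Bootstrap
refits start from the fitted coefficients (single start, standard parboot
practice); refit failures are dropped with a warning up to 10%, beyond
which the test errors out. $p = (1 + \#\{T_s \ge T_{obs}\})/(n_{sim}+1)$.

# Integration and areas

The best occupancy model is projected onto a fine covariate grid
(inverse-logit of the standardized linear predictor), masked to fine cells
whose containing coarse cell is suitable (center-point containment — the
unambiguous rule at resolution boundaries), and binarized at the third
quartile of the masked values (linear-interpolation quantile; a constant
grid degenerates with a warning). When the best model has a single habitat
covariate, `psiThresholdCovariate()` reports the covariate value implied by
the threshold — the habitat-interpretation cross-check of the quantile.
Areas use the spherical-degree approximation
$(\Delta\lambda \cdot 111.320\cos\phi)(\Delta\phi \cdot 110.574)$ km² per
cell, which the tests hold to within 1% of an equal-area projection oracle
at low latitude. EOO is the convex-hull area in a Lambert azimuthal
equal-area plane centred on the point centroid; AOO counts occupied 2-km
cells on a grid anchored at the projection of the whole-degree-rounded
centroid — a fixed anchor (not the IUCN-permitted minimizing shift),
chosen for determinism and so AOO cannot shrink when records are added.

# The synthetic world

The generator states one fixed world; its defaults are not tuned to tests.
Covariate layers are Gaussian random fields (white noise convolved with a
Gaussian kernel; correlation length in cells), standardized to mean 0, sd
1. Layers 1 and 2 are mixed — after empirically orthogonalizing the second
field — to a Pearson correlation of exactly 0.92, emulating a ground-level
versus atmospheric temperature pair; the two variable sets split this pair.
Occurrences are drawn with probability proportional to a known Gibbs
surface times $e^{\text{bias} \times \text{smooth field}}$, standing in
for accessibility bias without road data. Detection histories follow the
stated design: 30 sites × 5 occasions with 5 surveys unconducted
(missingness uniform at random — the real mechanism is unstated, so this
is a stand-in, not an inference — re-drawn so every site keeps one
conducted survey), $\psi$ declining in vegetation height, detection
increasing with cover-object counts. What a green test establishes is
therefore internal consistency and statistical calibration on data whose
generating process matches the model family; it does not establish
transferability to real rasters, spatially structured detection
heterogeneity, or non-random survey loss.

# Numerical and scale choices

* Maxent convergence: optimality residual $< 10^{-6}$; AICc undefined
  (flagged, excluded) when $n \le K + 1$.
* Quantiles everywhere use linear interpolation between order statistics
  (R type 7).
* The pipeline demo and acceptance script run a ~100×100-cell coarse grid
  at 0.01° with a refinement factor of 8 (0.00125°) rather than the
  0.00025° of a production run, and a reduced regularization grid — purely
  a compute-budget scale-down; every function accepts production
  resolutions.
* Background: all valid cells inside $M$ up to a 10,000-cell cap, then a
  seeded uniform sample.
* No GeoTIFF/GEOS stack is assumed: rasters are matrices with an affine
  transform, written as ESRI ASCII grids; polygons are GeoJSON.

# Known limitations

Buffers and hulls are vertex-discretized (72 points per circle); polygon
clipping requires the convex hull as the clip ring (always true here). The
spherical-degree area constants are an approximation, documented and
tested at the 1% level at low latitude. Partial ROC thresholds are the
unique background values capped at 1500 quantile points. The maxent
feature family is limited to `l`, `q`, `lq` by design.
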