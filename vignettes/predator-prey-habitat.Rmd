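---
title: "Predator, prey and habitat structure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predator, prey and habitat structure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oncatools)
```

`oncatools` links four strands of evidence about the conservation status of
a tropical-forest system organized around an apex predator (the jaguar,
*Panthera onca*): habitat suitability modelled from presence-only sightings,
field-measured predator density from camera-trap capture–recapture, prey
abundance from line transects, and canopy-structure proxies from remote
sensing. Each strand is a module with a small surface; a synthetic-landscape
generator with known ground truth makes the whole chain testable without
access to the original field data, which are not publicly released. This
vignette explains the models, the tunable parameters, the numerical choices,
and what the synthetic experiments do and do not demonstrate.

## The suitability model

Habitat suitability is a maximum-entropy (Gibbs) distribution over landscape
cells. Let $f_j(x)$ be features of cell $x$: each continuous layer rescaled
to $[0,1]$ contributes a linear and a quadratic feature, and each categorical
layer one 0/1 indicator per observed class (`build_features()`). The model is

$$\mathrm{raw}(x) = \frac{\exp\big(\sum_j \lambda_j f_j(x)\big)}
{\sum_{x' \in \mathcal{B}} \exp\big(\sum_j \lambda_j f_j(x')\big)},$$

over the background $\mathcal{B}$, fitted by maximizing the per-presence
log-likelihood penalized by $\sum_j \beta_j |\lambda_j|$. At the optimum the
KKT conditions bound every feature discrepancy,
$|E_\mathrm{raw}[f_j] - \bar f_j^{\mathrm{pres}}| \le \beta_j$ — the
defining moment-matching property of the regularized fit, asserted in the
test suite. The default regularization is
$\beta_j = m^{-1/2} s_j \times \texttt{reg\_multiplier}$ with $s_j$ the
presence-sample standard deviation and $m$ the presence count; only linear
and quadratic feature classes are supported (no hinge/product/threshold
features, by design).

Numerically, the fit is a proximal-Newton ascent (compiled in C++ with
Armadillo): each outer iteration expands the smooth part to second order
(gradient $\bar f^{\mathrm{pres}} - E_\mathrm{raw}[f]$, Hessian
$-\mathrm{Cov}_\mathrm{raw}[f]$), solves the L1-penalized quadratic
subproblem by coordinate descent with soft-thresholding, and backtracks on
the true objective. Convergence is declared when the largest weight update
falls below `tol` (default $10^{-5}$) within `max_iter` (default 5000)
iterations; both defaults are the standard settings for this class of model
and are recorded in the fit object. Flat directions (zero curvature) move
only if the gradient exceeds the penalty, under the same line search.

Reported suitability is the logistic output
$e^H \mathrm{raw}(x) / (1 + e^H \mathrm{raw}(x))$ with $H$ the entropy of
the fitted raw distribution — the transform with implicit prevalence 0.5. It
is strictly monotone in $\mathrm{raw}$, so rankings, AUC and the null-model
test are unaffected by the choice.

Observation bias is handled by *training-background restriction*: presence
records collected opportunistically concentrate where observers go, so with
`bias = TRUE` the training background is drawn from the sampling mask (cells
with observer effort) while projection covers the full valid region. The
background is every mask cell when there are at most 20,000, otherwise a
seeded uniform subsample of 10,000. A bootstrap option (default 10
replicates resampling training presences with replacement) averages the
projected suitability across replicate fits. Presences are split 75/25 into
training and test by a seeded uniform partition.

### Evaluation and the null model

AUC is the rank-based (Mann–Whitney) probability that a random test
presence outscores a random background cell, ties counted ½; the tests
assert exact equality with exhaustive pair counting. Because presence–
background AUC alone can mislead, significance comes from a null model: 99
replicates draw the same number of presences uniformly at random from the
study mask, are fitted and evaluated identically, and the observed AUC is
compared with the 95th-ranked null AUC; exceeding it gives $p < 0.05$, and
the reported rank-based p-value uses the +1 permutation convention. The
acceptance suite verifies the calibration empirically: with truly random
presences the rejection rate over 200 outer replicates must lie in
[0.02, 0.09] (a binomial band around the nominal 0.05).

Jackknife importance refits the model with each environmental variable's
features alone and with all but them, reporting training gain (penalized
log-likelihood above the uniform baseline, per presence) and AUC for each
refit. On synthetic truth driven by rainfall, rainfall must rank first —
a recovery test, not a claim about any particular landscape.

## Camera-trap density

Detections of photo-identified individuals are collapsed into an
individuals × occasions binary matrix, grouping survey nights into
consecutive occasions of configurable length (the original ~90-night
surveys map naturally onto 10 occasions; the last occasion may be short).

Two closed-population estimators are implemented from their published
closed forms:

* **M0** (null model): all individuals share one detection probability
  $p$. The estimate maximizes the joint likelihood over real-relaxed $N$
  with the profile $\hat p = n_\cdot/(t\hat N)$; the SE comes from the
  observed information (finite differences). With very few recaptures the
  likelihood is effectively unbounded in $N$, so the search interval
  expands adaptively; a boundary flag marks the all-captured case
  ($\hat N = M_{t+1}$, $\hat p = 1$).
* **Mh jackknife** (Burnham–Overton): under individual heterogeneity the
  estimators $N_{Jk} = \sum_i a_{ik} f_i$ for orders $k = 1..5$ are linear
  in the capture frequencies $f_i$, with
  $\widehat{\mathrm{var}}(N_{Jk}) = \sum_i a_{ik}^2 f_i - N_{Jk}$. The
  reported order is chosen by the standard sequential test on successive
  differences at $\alpha = 0.05$ (first non-significant increment; the
  highest order if all increments are significant).

The simulation tests quantify the textbook behaviour: with logit-normal
heterogeneity (sd 0.75) M0 is negatively biased and the jackknife lands
closer to truth; with homogeneous detection M0 recovers the true
population within 5% on average.

The effective survey area is the station minimum convex polygon dilated by
a buffer: half the MMDM (the classical choice) or the full MMDM (less prone
to overestimating density). MMDM averages, over individuals photographed at
two or more distinct stations, the maximum pairwise distance among their
stations; single-station individuals are excluded, and if no individual
qualifies the MMDM is undefined and density cannot proceed. Station-based
(rather than occasion-based) qualification is used. For a convex polygon
the dilated area is exact in closed form, $A + Pb + \pi b^2$; the tests
check it against fine-grid rasterization. Density is $100\hat N / A$
animals per 100 km², with the interval $100(\hat N \pm \mathrm{SE})/A$, and
table output is rounded half-away-from-zero to one decimal. Distances are
planar Euclidean on projected-km coordinates throughout.

## Transect indices and survey effort

The kilometric index (KI) is the encounter rate per km walked — contacts
for solitary species, individuals (group sizes summed) for gregarious ones
— and the biomass index multiplies KI by mean adult mass, summing over
species for a community value. No detection function is fitted: these are
relative indices. Adult masses ship as an editable traits table
(`inst/extdata/species_traits.csv`).

Effort sufficiency asks how much transect length is needed before
abundance stabilizes: truncate every survey to its first $d$ km, recompute
KI, and correlate with the full-effort KI across surveys. For homogeneous
Poisson encounters the correlation is exactly $\sqrt{d/L}$ — independent of
the encounter rate. Rarity matters only through between-site rate
variation: if per-km rates vary across sites with mean $m$ and variance
$v$, the correlation generalizes to

$$\rho(d) = \sqrt{\frac{d\,(m + vL)}{L\,(m + vd)}},$$

which reduces to $\sqrt{d/L}$ at $v = 0$ and rises faster for common
species (between-site signal dominates Poisson noise sooner). The
acceptance suite verifies both regimes against simulation and recovers the
expected ordering: at a 0.9 correlation threshold a common species (0.5
contacts/km) stabilizes near 40 km while a rare one (0.05/km) needs 80–90
km, the qualitative pattern seen in field accumulation analyses (tens of km
for detectable birds, beyond 80 km for ungulates).

## Habitat structure

Canopy roughness is the focal 3×3 sample (n−1) standard deviation of a
DEM, borders masked (no partial windows); it is invariant to elevation
offsets and checked cell-by-cell against direct per-window computation.
Waveform extent — the elevation span between a large-footprint LiDAR
return's signal beginning and end — is extracted by thresholding at the
noise mean plus $k$ standard deviations (default $k = 3$), both estimated
from the waveform tails; it is invariant to uniform intensity scaling. The
synthetic waveform generator (two Gaussian returns for canopy top and
ground plus an understorey plateau) defines its true extent analytically at
the same $k$-sigma convention, so extraction can be tested to within two
sampling steps. Site summaries aggregate rasters over a site polygon: max
canopy height, mean roughness/AGB/footprint, modal geology class, mean
waveform extent over footprints inside the polygon; missing layers yield
missing fields rather than errors.

## Associations

Cross-site relations are product–moment correlations with two-sided
uncorrected p-values from the t reference distribution (a rank-based option
exists); no multiple-testing correction is applied by default, matching the
uncorrected-p reporting convention of field studies in this design (a Holm
adjustment can be applied externally). The multivariate association between
modelled suitability and structure variables is a regression random forest
scored by the correlation between out-of-bag predictions and the observed
response — an internally cross-validated analogue of a multivariate r, and
the only construction of "a random forest ... correlated (r = …)" that
yields an r; resubstitution correlations would be optimistically biased.
The conservation-priority overlay flags cells with footprint below 15 and
roughness above 12, the thresholds associated with maintained prey
abundance and high prey biomass.

## The synthetic landscape: what it emulates, and what it does not

`generate_layers()` builds spatially autocorrelated fields (Gaussian-kernel
smoothed white noise — any smooth field suffices for recovery testing, and
this is the simplest), thresholds some into categorical layers (4
vegetation, 3 biogeographic, 5 geology classes), and derives the human
footprint from distance to randomly placed access lines. Fine-scale DEM
texture shrinks where the footprint is high, encoding the degradation
mechanism (smoother canopy surface in disturbed forest) that links
roughness to pressure. The sampling mask covers a corridor (default 6 km)
around the access lines; its scale is a free parameter, as nothing in the
study design pins it down.

`truth_model()` defines suitability as a logistic function of standardized
rainfall (linear + quadratic), altitude and footprint, with weights on the
per-SD scale (defaults 2.0, −0.8, 1.0, −0.4) — strong enough that recovery
is meaningful (the tests require Spearman > 0.8 between projected and true
suitability for n = 302 presences on a 64×64 grid) without being separable.
Camera-trap truth uses g0 = 0.3–0.35, σ = 2 km and heterogeneity sd 0.75 —
plausible for a large felid on a 2–3-km station grid, and the minimal
mechanism that makes Mh the right estimator. Activity centres are uniform
on the station polygon buffered by 2σ, keeping edge effects realistic for
MMDM; explicit centres can be supplied for controlled experiments. Prey
counts are Poisson with log-rates declining in the footprint; all seven
default species decline (birds fastest), group sizes are 1 + Poisson for
gregarious species, and per-site effort is 97 ± 2.1 km over 30 sites.

What passing tests show: the estimators recover known truth under their
own assumptions, the null test is calibrated, geometry and index
arithmetic are exact, and the qualitative field signatures (negative
prey–footprint correlations, higher predator density in better habitat,
roughness declining with pressure) re-emerge end to end. What they do not
show: performance under real-world violations — non-Poisson clumping of
prey, transient individuals violating closure, spatially structured
detection failure, misregistered rasters — and none of the published
correlation magnitudes are reproduced, because the underlying field data
are unreleased; those magnitudes are covered only by sign and calibration
surrogates.

## Problem sizes and reproducibility

The test and acceptance runs use 64×64 landscapes (0.5-km cells), 302
presences, 99-replicate null models with 100–200 outer replications,
500-replicate estimator recoveries and 100-replicate end-to-end sign
checks — sizes chosen so the full chain demonstrates its statistical
properties while remaining quick to rerun on a single CPU. Every stochastic
step takes an explicit seed; pipeline stages derive independent substreams
from one master seed by hashing the stage name (`stage_seed()`), so a stage
can be rerun in isolation and full runs are bit-reproducible (the run
manifest records an MD5 checksum per artifact).

## Known limitations

* Presence sampling is proportional to suitability by construction; real
  sighting processes have additional structure (roads, settlements,
  detectability) only partially captured by the sampling-mask bias.
* No spatially explicit capture–recapture: MMDM buffering is a geometric
  convention, and the half-MMDM design is known to overestimate density —
  the end-to-end density check is therefore a calibration property (median
  within 25% of truth), not exactness.
* Significance of cross-site correlations ignores spatial autocorrelation
  between sites.
* No hinge features, no extrapolation diagnostics, and no open-population
  dynamics (closure is assumed).
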