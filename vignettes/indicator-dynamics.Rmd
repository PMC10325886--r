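---
title: "Dynamics-based characterization and classification of biodiversity indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics-based characterization and classification of biodiversity indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biodiversity is multifaceted: richness, total abundance, diversity and
evenness indices, taxonomic diversity, and biogeographic composition each
summarize a different dimension of a community. Correlation between two
indicators computed on the same surveys is a weak guide to whether they track
the same dimension, because correlations are condition dependent and
non-stationary. `biodivedm` instead compares indicators by their
*environmental responsiveness*: when the environment changes the rules of
community dynamics, indicators reflecting the affected dimension change their
own dynamics at the same time. Two indicators whose dynamics break in the
same places are treated as reflecting the same dimension, whether or not
their values correlate.

The package was built around monthly visual-census data for a coastal marine
fish community exposed to intermittent anthropogenic warm-water discharge
(on the order of +2 °C at the survey site), but every stage works on any
community abundance time series with species metadata.

## The ten indicators

For each survey with counts $n_i$ over present species ($n_i > 0$,
$N = \sum n_i$, $p_i = n_i / N$, $S$ = number of present species):

| indicator | definition |
|---|---|
| $S$ | species richness |
| $N$ | total abundance |
| $p_{\max}$ | $\max_i p_i$ (dominance) |
| $D$ | $1 - \sum_i p_i^2$ (Simpson diversity) |
| $H'$ | $-\sum_i p_i \ln p_i$ (Shannon diversity) |
| $E_D$ | $D\,S/(S-1)$ (Simpson evenness) |
| $E_{H'}$ | $H' / \ln S$ (Shannon evenness) |
| $E_{var}$ | $1 - \frac{2}{\pi}\arctan\!\big(\frac{1}{S}\sum_i (\ln n_i - \overline{\ln n})^2\big)$ (Smith–Wilson evenness) |
| $\delta$ | $\sum_{i<j} w_{ij} n_i n_j \,/\, \binom{N}{2}$ (taxonomic diversity) |
| cCOD | $\sum_i p_i z_i$, community mean of standardized COD latitude |

Natural logarithms are used throughout, and $E_{var}$'s inner variance uses
the $1/S$ normalization. The taxonomic weight $w_{ij}$ is the finest shared
rank: 1 within a genus, 2 within a family, 3 within an order, 4 otherwise;
the species reader enforces that taxonomy is nested, so finer sharing
implies coarser sharing. The denominator of $\delta$ equals the number of
individual pairs $N(N-1)/2$, so $\delta$ is the abundance-weighted mean
taxonomic path length between individuals of different species (it is 0 when
one species holds all individuals, and undefined for a single individual).

Each species' centre of distribution (COD, in °N) is z-scored with the mean
and **population** (1/n) variance of the pool of all species observed
anywhere in the dataset, once per dataset — not survey by survey — so cCOD
is comparable across surveys. Whether the original field protocol used the
population or sample variance is not something the indicator table itself
fixes; the population convention is this package's documented choice, made
for consistency with the sRMSE baseline below.

Undefined values ($E_D$, $E_{H'}$ at $S = 1$; $\delta$ at $N = 1$; all
indicators for an empty survey) propagate as `NA`, never as 0. The windowed
analyses refuse series containing `NA` with an explicit message, because a
silent zero would masquerade as signal.

## Measuring changes in dynamics

The engine is nonlinear mutual prediction. From an indicator series of $n$
surveys, all $n - w + 1$ sliding windows of length $w$ (default 48; 41
windows for the 88-survey design) are extracted. For each training window a
simplex-projection model is built in delay-embedded space: the forecast for
a point is the exponentially distance-weighted average of the one-step
futures of its $E+1$ nearest library neighbours, with weights
$\exp(-d_k/d_{\min})$. The embedding dimension $E$ is chosen per training
window by minimizing leave-one-out self-prediction error over $E = 1,
\dots, 10$ (capped so that at least $E+2$ usable neighbours always remain;
ties go to the smaller $E$).

Forecast skill of model $i$ on window $j$ is standardized as
$\mathrm{sRMSE}_{ij} = \mathrm{RMSE}_{ij} / \mathrm{sd}_j$, where
$\mathrm{sd}_j$ is the population standard deviation of window $j$'s
observed targets. Predicting the test-window mean then scores exactly 1, so
$\mathrm{sRMSE}_{ij} \ge 1$ marks deterministic prediction failure; the
package uses strict $< 1$ as success everywhere. The $n_w \times n_w$ matrix
of these values is the indicator's *mutual prediction matrix*: a block
structure with poor cross-block prediction localizes a change in the
dynamical rule at the block boundary.

Numerical conventions worth stating:

* $\tau = 1$ and prediction horizon $T_p = 1$ (monthly surveys, one-step
  forecasts).
* Because stride-1 windows overlap, a library point that coincides with the
  test target in absolute time, or whose future falls inside the target's
  own coordinate span, is excluded from the neighbour search. On the
  diagonal this is exactly leave-one-out self-prediction; off the diagonal
  it removes shared self-pairs and nothing else. No additional Theiler
  margin is applied (windows are short); the exclusion is structural, not
  configurable per entry.
* If the nearest neighbour distance is 0, all zero-distance neighbours share
  the weight equally.
* A constant test window has $\mathrm{sd}_j = 0$; its column is reported
  undefined rather than infinite.

`window_size_scan()` reports, per candidate $w$, the mean self-prediction
sRMSE (skill grows with $w$) and the cross- vs within-half block contrast (a
change-point sensitivity proxy that shrinks as windows straddle the
boundary). It reports the trade-off table only; the default $w = 48$ is part
of the study design, not an optimized quantity.

## Determinism and nonlinearity

Determinism per indicator is the fraction of windows with self-prediction
$\mathrm{sRMSE}_{ii} < 1$. Nonlinearity uses the regularized S-map: for each
embedded point, a local linear map to its future is fit on all other points
with state-space weights $\exp(-\theta d/\bar d)$ and an elastic-net penalty
(mixing 0.5, path chosen by leave-one-out over a 12-value data-adaptive
grid; `glmnet` does the fitting, with a closed-form single-predictor solver
for $E = 1$). $\theta = 0$ is a global linear model; forecast error that
*decreases* for $\theta > 0$ indicates state-dependent dynamics.

The per-window $\hat\theta$ is selected from the grid
$\{0, 0.1, 0.3, 0.5, 0.75, 1, 1.5, 2, 3, 4, 6, 8\}$ by leave-one-out error
with a **one-standard-error rule**: the smallest $\theta$ whose MSE lies
within one standard error of the minimum. The raw argmin is available
(`rule = "min"`) but is biased away from 0 under a linear null, because the
error curve in $\theta$ is then nearly flat and the argmin inherits pure
selection noise; the 1-SE rule restores calibration (on AR(1) surrogates the
median $\hat\theta$ is 0 and the test below rejects at close to nominal
rate) while chaotic series still show $\hat\theta > 0$ decisively, since
their error curves fall steeply in $\theta$.

The linearity null "$\theta = 0$ in all windows" is tested per indicator by
a one-sided many-to-one comparison of the mean window $\hat\theta$ against
0, adjusted across indicators by a max-T bound under an independence working
correlation (equal degrees of freedom make this a Šidák-type adjustment);
the true dependence between windows of one series is unknown, so a sign-flip
permutation fallback (`method = "signflip"`) is provided. Degenerate inputs
are decided exactly: all $\hat\theta = 0$ gives $p = 1$; identical positive
$\hat\theta$ in all windows gives $p = 0$.

## Classifying indicators

Similarity of environmental responsiveness between two indicators is the
Euclidean distance between their flattened mutual prediction matrices
(entries are already dimensionless, so no re-standardization). Ward
clustering (`ward.D2`; labels sorted lexicographically first, making the
tree order-invariant and deterministic) builds the dendrogram, and SIMPROF
permutation tests gate the descent: at each node with at least three
indicators, the ordered profile of pairwise distances is compared with the
mean ordered profile under independent permutation of each matrix entry
across indicators ($\pi$ = sum of absolute deviations; a second,
independent permutation set supplies the null distribution of $\pi$; the
add-one estimator keeps $p > 0$). Descent continues only through nodes with
$p \le \alpha$ (default $\alpha = 0.01$, 999 permutations); the leaves of
the stopped traversal are the significant clusters. Nodes with fewer than
three members are untestable and treated as homogeneous.

The SIMPROF variant here follows the distance-profile convention of its
original description — observed profile against the permutation-mean
profile, variables permuted independently within columns. The permutation
stream is seeded and consumed in a deterministic traversal order, so a given
input and seed always yield the same classification, regardless of the
order in which matrices are supplied.

## The synthetic community

`community_sim()` generates the validation data: 95 species, 88 monthly
surveys, multispecies Ricker dynamics with sparse random interactions,
Gaussian thermal performance curves whose optima are tied to each species'
COD latitude (low-latitude species prefer warm water), seasonal temperature
forcing with period 12 and amplitude 4 °C around 16 °C, observation by
Poisson sampling of latent abundances (visual-census counts), and seasonal
immigration pulses for warm-affinity species that guarantee turnover (at
least 10% of species miss at least one survey). The regime shift raises the
forcing mean by 2 °C after survey 44 — a warming analogue that changes the
dynamical rule rather than any single state. The Ricker form was chosen over
Lotka–Volterra for its integer-friendly boom–bust dynamics; the regime
change deliberately alters only the forcing mean, the minimal warming
analogue, though both the forcing and the interaction structure are
configurable.

What the simulator does *not* emulate: real observation effort varying
between dives, species-level detection differences, within-month visit
timing, and the actual Maizuru/Uchiura community parameters. Passing tests
on synthetic data therefore demonstrate that the machinery detects planted
regime shifts and respects its null calibrations — not that any particular
a given real community will show any particular grouping.

`piecewise_map()` (a logistic map whose parameter changes mid-series) and
`archetype_matrices()` (uniform / block / noisy mutual-prediction
archetypes) provide sharper ground truth for single stages: the piecewise
map yields the expected cross-regime prediction failure at
$r: 3.6 \to 3.9$, and the three archetypes are recovered as exactly three
significant SIMPROF groups.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data at
the study design sizes where that is what is being checked (88 surveys, 48
or 24-point windows, 41 windows) and at reduced sizes (10 windows per
replicate for the type-I-error simulation of the nonlinearity test, 199
permutations for the SIMPROF calibration sweep) where a property is being
sampled over many replicates; these reduced designs are stated in the tests
themselves.

## Known limitations

* Surveys are indexed by rank, not calendar time; unequal survey spacing is
  accepted silently.
* The S-map stage is the slow path ($\mathcal{O}$(windows × grid × targets)
  elastic-net fits); `do_theta = FALSE` skips it when only determinism and
  classification are needed.
* The Dunnett-type adjustment assumes independence across indicators as a
  working correlation; with strongly coupled indicators it is conservative.
* No convergent cross-mapping, multivariate embedding, rarefaction, or
  Hill-number generalization — those are outside this package's scope.
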