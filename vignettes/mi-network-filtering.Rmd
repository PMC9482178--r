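---
title: "Filtering contaminant taxa with mutual-information networks"
author: "MIFilter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering contaminant taxa with mutual-information networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MIFilter)
```

## The model

Microbial communities are interaction networks: member taxa co-occur,
compete and respond to the same environmental states, so their abundance
profiles across samples share information. Contaminants — reagent
bacteria, index hopping, residual sequencing error — enter the table
through processes unrelated to the community and are therefore
(approximately) independent of everything else. MIFilter operationalizes
this: a taxon that shares no information with any other taxon is treated
as noise.

Dependence is measured by mutual information rather than correlation
because community relationships are rarely linear: presence/absence
complementarity, dominance switches and saturating responses all register
in MI but can null out a Pearson coefficient. Profiles are discretized
per taxon and the plug-in estimates

$$H(X) = -\sum_x p(x)\log p(x), \qquad
I(X;Y) = H(X) + H(Y) - H(X,Y)$$

are computed from the empirical bin frequencies (in nats). We use the
entropy-sum identity throughout; it guarantees symmetry and, after
clamping floating-point negatives in $(-10^{-12}, 0)$ to zero,
nonnegativity. Each pair is then normalized by its joint entropy,

$$\widetilde{I}_{jj'} = \frac{I(X_j; X_{j'})}{H(X_j, X_{j'})},$$

which maps every entry into $[0,1]$, fixes the diagonal at 1, and cancels
the logarithm base — the three conditions of a network adjacency. A pair
of two constant taxa has joint entropy zero; such pairs are defined to
share nothing (entry 0), so degenerate columns never propagate NaNs.

### Discretization

The binning is the one genuinely free estimation choice. The default is
equal-width bins with Sturges' rule, $\lceil \log_2 n \rceil + 1$ bins
for $n$ samples — the standard histogram default, and a deliberately
crude one: plug-in MI on few bins is biased upward for sparse profiles,
but the normalization by joint entropy keeps that bias small in the
adjacency scale, and all downstream decisions are made relative to the
same estimator. Equal-frequency binning and fixed bin counts are
available through `discretizationScheme()`; equal-frequency bins resist
skew but collapse on the long runs of zeros typical of contaminants.
Constant profiles collapse to a single bin rather than failing. We do
not implement kernel, k-NN or bias-corrected estimators: the method's
decisions depend on the ordering of adjusted-MI values far more than on
their absolute level, and a single documented estimator keeps runs
reproducible.

## Threshold selection and filtering

The weighted adjacency is hard-thresholded with an inclusive cutoff:
taxa are connected iff $\widetilde{I}_{jj'} \ge \tau$. Following
standard practice for co-expression and co-occurrence networks, $\tau$
is chosen by the scale-free criterion: over a grid (0.05–0.95 in steps
of 0.05 by default) we fit $\log P(k)$ on $\log k$ by ordinary least
squares over the distinct observed degrees and pick the $\tau$ with the
highest $R^2$, breaking exact ties toward higher mean connectivity
$\bar k$ so the network retains as much information as possible.
Choices embedded here, made once and documented:

* the fit is in log–log coordinates (a power law is linear nowhere
  else), over raw distinct degrees without logarithmic binning — with a
  few dozen taxa there are too few distinct degrees to bin;
* degree-zero nodes cannot enter a log fit and are excluded from it, but
  they do count toward $\bar k$, which is why $\bar k$ can fall below 1;
* a threshold with fewer than two distinct positive degrees has an
  undefined fit and is excluded from selection (`n_points` in the scan
  table flags two-point fits, which are exact by construction);
* $R^2$ is the coefficient of determination of that regression;
* degrees never count the diagonal.

Taxa isolated at the selected $\tau$ are the putative contaminants; the
default pipeline (`miFilter()`) removes exactly these.

## Information loss and the removal tests

To decide how aggressively one may filter, taxa are ranked by weighted
degree $d_j = \sum_{j' \ne j} \widetilde{I}_{jj'}$ (diagonal excluded so
the unit self-information does not compress the ranking) and removed in
batches below successive quantiles $q = 0.01, 0.06, \ldots, 0.96$. The
loss of a retained principal submatrix $\widetilde{I}'$ is

$$\Lambda = 1 -
\frac{\|\widetilde{I}'\|_F^2}{\|\widetilde{I}\|_F^2},$$

zero when nothing is removed, one when everything is, non-decreasing as
the retained set shrinks, and dependent only on the retained set, not on
removal order. Pairwise MI does not change when other columns are
dropped, so the submatrix is exact — nothing is recomputed. Quantiles
use the type-7 convention and removal is strict (`d < quantile`); with
tied degrees a batch can be empty, which downstream tests flag as a
degenerate step. Ties in the one-at-a-time ordering break
lexicographically by taxon ID, so runs are deterministic.

### The permutation step test

For adjacent quantiles $(q_k, q_{k+1})$ we test whether the extra loss
$\Delta = \Lambda_{k+1} - \Lambda_k$ exceeds what chance would produce.
The null model permutes each taxon's profile across samples
independently — every marginal is preserved, every inter-taxon
association destroyed — and reruns the *entire* computation on the
permuted table: adjusted MI, weighted degrees, degree-ordered quantile
removal. The one-sided p-value uses add-one smoothing,
$p = (1 + \#\{\Delta^* \ge \Delta\})/(M+1)$, so reportable values span
exactly $[1/(M+1), 1]$ (with $M = 500$: a floor below 0.002 and a
ceiling of 1).

This null was chosen after two simpler candidates failed calibration.
Resampling only the *identity* of the removed taxa (keeping the observed
matrix) produces a null increment distribution that is nearly degenerate
— the diagonal contribution is fixed by the batch size — and ignores
that the observed batch was *selected* by degree ordering; empirically
it rejects far above nominal level on exchangeable tables. Shuffling
edge weights fails for the same reason in aggravated form, since edges
sharing a taxon are not exchangeable. Recomputing the network on
profile-permuted tables handles both: under i.i.d. taxa the permuted
tables are distributed exactly like the data, so p-values are uniform by
construction, and the package's type-I test (exchangeable tables,
$n = 200$, $m = 40$, 200 replicates, $M = B = 200$) holds the rejection
rate at $\alpha = 0.05$ within binomial noise. On structured tables the
permuted networks lose the community block, so a step that cuts into
connected taxa produces a loss increment no permutation matches — the
p-value pattern along the grid is a flat band of 1.000 over the noise
steps and a collapse to the floor at the community boundary. One
permutation set is shared by all steps of a scan, which is both cheaper
and statistically standard.

### The bootstrap step test

The companion bootstrap statistic studentizes $\Delta$ by the Frobenius
norms of the covariance matrices of the retained count sub-tables, and
resamples columns with replacement from the pooled retained sets,
splitting each resample into analogues of the two sets and centering at
the observed difference. Covariances are computed on raw counts by
default (a relative-abundance option exists), the norm is the squared
Frobenius norm matching the loss, and resamples containing constant
columns are kept — their MI rows are zero by the degenerate-pair rule.
Because the pool is the retained sets themselves, this construction
tests their exchangeability: it is conservative (it essentially never
rejects on exchangeable data, and its p-values on structured data are
driven by the size and composition of the retained sets), and it lacks
the permutation test's sensitivity at the community boundary. For that
reason `scanSteps()` reports both columns but bases its recommendation
on the permutation test. The recommended removal level is the largest
quantile reached before the first significant step; if every step is
degenerate (uniform degrees) the highest grid value is recommended with
a warning.

## The mock-community generator

All tests run against `simulateCommunity()`, which emulates the
structure of a sequenced mock community: a handful of high-abundance,
mutually dependent true taxa and many sparse, independent contaminants.
Mock communities are built from *prescribed mixtures* — each sample is
assembled from known strains at designed proportions spanning orders of
magnitude, including absences — and that design is what the generator
reproduces. Each sample realizes one of `nStates` (default 8) mixture
states per guild; a taxon's prescribed proportion across states runs
over a shuffled linear dilution grid including zero, so abundance
*levels* (not just presence) are co-determined by the state. The
parameter `rho` (default 0.99) is the fraction of log-abundance variance
the design explains: the prescribed profile is blended toward flat by
$1-\rho$ and replicate lognormal noise of scale
$\sigma\sqrt{1-\rho}$ (σ = 1) is added, so at `rho = 0` true taxa are
i.i.d. and — with `gap = 0`, `sparsity = 1` — statistically
exchangeable with contaminants, the null configuration used in the
calibration tests. True taxa are split into two independent guilds
(4 + 3 by default), reflecting community sub-structure; this also gives
the thresholded network two clique sizes, so the degree distribution has
support for the scale-free fit in the regime where contaminants are
already isolated. Contaminants are present in each sample with
probability `sparsity` (0.3) and otherwise draw independent lognormal
weights; the abundance `gap` of log(1000) gives the true taxa ≈ 99.8% of
reads (`expectedTrueShare()` provides the closed form). Counts are
multinomial at depth $10^4$ per sample, so the table is compositional
and integer like real data. All draws flow from one seed in a fixed
stream order; identical spec + seed is byte-identical.

What the generator does *not* emulate: taxon-specific amplification
bias (a constant multiplicative bias is invisible to discretized MI),
phylogenetic correlation among contaminants from a shared reagent
source, batch structure, and read-level error. Passing tests on this
fixture therefore demonstrate that the machinery recovers a designed
community against independent sparse noise — not that any particular
real study is filtered correctly.

## Numerical choices and degenerate inputs

* MI values in $(-10^{-12}, 0)$ are clamped to zero; more negative
  values abort (they would indicate an inconsistent contingency count).
* Adjusted values are clipped into $[0,1]$ against floating-point
  overshoot; analytically $I \le H(X,Y)$.
* Thresholding is inclusive ($\ge \tau$), exactly as the signum rule.
* An empty network (everything isolated) removes all taxa with a
  warning; an all-undefined threshold scan is an error suggesting a
  denser grid or different binning.
* Count validation requires integral, nonnegative entries and unique
  IDs; file readers report the offending line or cell.
* Resampling functions restore the caller's RNG state when given a
  seed.

## Problem sizes in the test suite

The suite checks estimator exactness against a brute-force
contingency-table oracle on 200 random tables (≤ 50 samples, ≤ 5 bins),
type-I error on 200 exchangeable tables (200 × 40, 200 resamples per
test), and end-to-end recovery on 50 seeded mock communities
(240 × 46); power and recommendation-recovery checks use 8–12 seeds at
reduced resample counts. These sizes keep the full suite in the
minutes range on a single core while leaving each check enough
replication to be meaningful.

## Limitations

Isolated-node filtering cannot separate contaminants that are mutually
correlated (a shared reagent source produces exactly that), and with
many taxa, chance edges among contaminants grow more likely — community
detection or centrality-based selection on the unweighted graph would
be the natural extensions. The scale-free criterion is a heuristic: on
small tables the degree distribution has few support points and $R^2$
is a coarse guide, which is why the scan table, not just the selected
$\tau$, is exported. The bootstrap step test is reported for
completeness but is conservative by construction. Finally, plug-in MI
on histogram bins is biased for very sparse taxa; the bias is shared by
all pairs and partially cancels in the normalization, but adjusted-MI
values near the contaminant noise floor (≈ 0.05–0.10 at 240 samples)
should not be over-interpreted.
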