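---
title: "Generalized Poincaré plots: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generalized Poincaré plots: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpoincare)
```

This vignette records how the package defines the generalized Poincaré
analysis, the conventions it fixes where several were possible, and the
design of its synthetic validation generator — including a structural
limitation of the asymmetry measure that anyone interpreting its output
should know about.

## The point sets and the r(j,k) matrix

A tachogram is the ordered sequence of RR intervals $RR_1, \dots, RR_N$ (in
seconds; the package converts milliseconds on read). For an order $(j, k)$
the generalized Poincaré plot pairs the summed duration of $j$ intervals
preceding an anchor with the summed duration of the $k$ intervals following
it. We fix the anchor between two intervals: the point with anchor index $i$
is

$$x_i = \sum_{u=i}^{i+j-1} RR_u, \qquad y_i = \sum_{v=i+j}^{i+j+k-1} RR_v,
\qquad i = 1, \dots, N - j - k .$$

The anchor range is chosen so that exactly $N - j - k$ points exist; this is
the count the method's sample-size bookkeeping uses throughout (the
symmetric alternative admits one more anchor; see *Numerical conventions*).
Both window sums come from a single cumulative-sum pass, so a full grid costs
$O(m\,n\,N)$ with small constants.

`gpp_matrix()` tabulates the Pearson correlation $r(j,k)$ of these point
sets for $j = 1..m$, $k = 1..n$. The orientation convention is fixed
package-wide: the first index (matrix row) is $j$, the number of *preceding*
intervals, plotted on the abscissa; the second is $k$, the *following*
count, on the ordinate. Cells whose order leaves fewer than 3 points, or a
coordinate with zero variance, are *masked as undefined* rather than
raising an error — one degenerate cell must not kill a $100 \times 100$
run. `sd1_sd2()` reports the dispersion of a point set across and along the
identity line, the standard deviations of $(x-y)/\sqrt2$ and
$(x+y)/\sqrt2$; at order $(1,1)$ these are the conventional HRV SD1/SD2 and
satisfy $SD1^2 = \tfrac12\,\mathrm{var}(\Delta RR)$.

## The asymmetry index and its surrogate correction

For a square $m \times n$ matrix the normalized asymmetry index is

$$NAI = \frac{1}{m n}\,\frac{1}{\bar r}\sum_{j=1}^{m}\sum_{k=j+1}^{n}
\bigl(r(k,j) - r(j,k)\bigr), \qquad
\bar r = \frac{1}{m n}\sum_{j,k}\lvert r(j,k)\rvert .$$

$NAI < 0$ means the region above the identity diagonal ($k > j$: fewer
preceding, more following intervals) carries more correlation than the
region below. The $\bar r$ normalization makes indices comparable across
matrices of different overall correlation strength; as a consequence NAI is
exactly scale-invariant and antisymmetric under matrix transposition (both
are tested properties). Following the definition literally, diagonal cells
enter $\bar r$ but not the difference sum, and a non-square matrix is
rejected rather than cropped, because the paired $r(k,j)$ terms only exist
when $m = n$.

To separate structure from artefacts of the interval histogram, the package
computes the same index on the element-wise average of matrices from
`n_reshuffles = 10` random permutations of the series ($NAI_{sh}$, one
index per subject from the averaged matrix, not the average of per-shuffle
indices), and the corrected index $NAIC = NAI - NAI_{sh}$. One caveat is
intrinsic to the definition: reshuffling a structured series leaves
$\bar r_{sh}$ near zero, and dividing by it makes $NAI_{sh}$ a
noise-amplified quantity. For white-noise cohorts its distribution is
centered on zero (a tested property), but individual values fluctuate far
more than the physiological $NAI$ does.

Undefined cells contribute zero to both sums while the denominator stays
$m\,n$; with no undefined cells this reduces to the plain definition.

## Local maxima and their clustering

A cell of $r(j,k)$ is a local maximum when it is defined and strictly
greater than all of its defined 8-neighbors; border cells compare against
the neighbors that exist, and plateaus yield no maximum. This is the
simplest definition consistent with discrete contour maps; it is verified
against an exhaustive brute-force scan. All strict maxima are pooled — no
prominence or minimum-$r$ filter is applied by default, since any threshold
would change which maxima the cohort statistics describe.

Pooled maxima are treated as points $(j, k, r)$ and partitioned with
k-means on the *raw* coordinates (10 restarts, best within-cluster sum of
squares, seed-controlled). No feature scaling is applied by default: $j$ and
$k$ live on the grid scale and $r$ in $[-1, 1]$, and rescaling would change
the cluster geometry the summaries describe; a `standardize` flag exists
for users who want isotropic coordinates. The number of clusters is chosen
by maximizing the mean silhouette width over $k = 2..8$ — a transparent,
reproducible stand-in for proprietary two-step procedures — with a fixed
$k$ (e.g. 4) available to mirror a prescribed cluster count. Cluster ×
group tables report $N$, mean $r$ and its standard error, and groups are
compared with the two-sided Mann–Whitney U test using the tie-corrected
normal approximation for $Z$.

## The synthetic validation generator

`generate_validation_series()` produces tachograms whose $r(j,k)$ matrix
peaks at a chosen order $(j^*, k^*)$, inside the physiological range
0.75–1.2 s; `generate_white_noise_series()` (i.i.d. truncated normal — an
AF-like null) and `generate_correlated_series()` (range-mapped AR(1) — a
healthy-like slow modulation) provide cohort fixtures. Defaults: 1200
intervals (about a 20-minute recording at ~1 s per beat), center
$(lo+hi)/2 = 0.975$ s, spread $(hi-lo)/6 = 0.075$ s so that the range is
filled without piling onto the bounds.

### Why the obvious feedback construction fails

The natural reading of "make the next $k$ intervals track the previous
$j$" — choose each new interval so that the trailing-$k$ sum equals
$(k^*/j^*)$ times the preceding-$j^*$ sum — is a linear recurrence with a
unit root ($z = 1$ solves $z^{j+k} - (1 + k/j) z^{j} + k/j$): the series
drifts, saturates at the range bounds, and its correlation surface peaks at
$(1,1)$ or on the diagonal, never at the planted order. Softened gains,
anti-correlating ("compensating") variants and block-tiled constructions
fail the same way. The generator therefore plants the structure directly.

### Transpose symmetry, and what any generator can and cannot plant

There is a structural fact worth stating precisely. In
$\sum_i x_i y_i$, the product $RR_s \cdot RR_{s+L}$ of two intervals at lag
$L$ appears once for every anchor whose preceding window contains $s$ and
whose following window contains $s+L$; counting anchors gives the weight
$\min(j, k, L, j+k-L)$ — *symmetric in $j \leftrightarrow k$*. Window
variances likewise depend on the window length alone. Hence for any single
sequence, stationary or not, the sample surface satisfies
$r(j,k) \approx r(k,j)$, with a discrepancy carried entirely by terms within
$j + k$ positions of the two ends of the recording — an edge effect of
relative order $(j+k)/N$.

Two consequences shape the design and the honest interpretation of
validation results:

1. A generator can plant the *unordered* pair $\{(j^*,k^*), (k^*,j^*)\}$ as
   the twin peak of the surface, but the ordered cell can beat its
   transpose only through $O((j+k)/N)$ nonstationarity. Exact-side argmax
   recovery is therefore statistical, not guaranteed per run.
2. $NAI$ itself aggregates exactly these transpose differences, so for
   series of ~1200 intervals its magnitude is bounded at the few-$10^{-3}$
   to $10^{-2}$ level regardless of how strong the planted correlation is.
   Larger printed values from single synthetic runs should be read as
   single-realization fluctuations at this scale.

### The adopted construction

The generator builds the series as
$RR_t = \mu + \sigma\,\tilde x_t$, $\tilde x$ standardized from
$x_t = a_t\, z_t + \varepsilon_t$, clipped to $[lo, hi]$ (the range limit
overrides the structure), where:

- $z$ is a moving-average process $z_t = \sum_q h_q \zeta_{t-q}$ of i.i.d.
  Gaussian innovations. The finite impulse response $h$ is designed at run
  time (`template_kernel()`, cached per order): BFGS with an analytic
  gradient maximizes the margin of $r(j^*,k^*)$ over all other cells of the
  closed-form stationary surface on the analysis grid, subject to the peak
  staying above 0.25. This places the twin peak exactly at the planted
  order with a margin that finite samples preserve.
- $a_t$ ramps linearly from 0 to 1 across the recording — the coupling
  switches on gradually, so the series starts as the uncorrelated noise
  floor $\varepsilon_t$ (relative amplitude `noise`, default 0.05). This
  onset is the sole source of direction: it biases the ordered cell over
  its transpose and tilts $NAI$ negative for $j^* < k^*$.
- Configurations with $j^* > k^*$ are generated as the time reversal of the
  transposed configuration; reversal exchanges preceding and following
  windows, so this is the construction's exact duality, and it flips the
  $NAI$ tilt positive.

What the generator does *not* emulate: respiratory sinus arrhythmia, $1/f$
spectra, ectopy, or any physiological feedback — only the correlation
geometry the validation needs. Passing validation tests therefore shows
that the *analysis* recovers planted correlation structure and signs its
asymmetry correctly; it says nothing about physiological realism of the
series themselves.

## Numerical conventions and degenerate inputs

- **Anchor count.** $N - j - k$ points per order. Under this convention
  reversing a series transposes the matrix only up to one boundary anchor,
  so reversal tests use near-equality; the symmetric $N-j-k+1$ convention
  would make it exact but break the stated point count.
- **Pearson guard.** Zero-variance coordinates give an undefined (masked)
  cell; fewer than 3 points likewise. `gpp_cor()` on a standalone point set
  with fewer than 3 points is an error, since there is nothing to mask.
- **SD1/SD2** use the population (divisor $n$) standard deviation by
  default, with `sample = TRUE` available; the conventions differ only by
  $\sqrt{n/(n-1)}$ and the choice cancels in $r(j,k)$.
- **Maxima ties** (plateaus) yield no maximum, so a constant matrix has
  none.
- **Seeds.** Every stochastic step (reshuffles, generators, k-means
  restarts) takes a seed; master seeds spawn child seeds via
  `sample.int(2^31 - 1)`, recorded in the results. The template-kernel
  optimizer uses a fixed internal seed so the template depends only on the
  planted order, not on the caller's RNG stream.
- **Null band for i.i.d. series.** Overlapping window sums are
  autocorrelated, so the null standard deviation of $r(j,k)$ is
  $\sqrt{c_{jk}/n_{pts}}$ with
  $c_{jk} = \sum_h (1-|h|/j)^+ (1-|h|/k)^+$, about 2.6× the naive
  $1/\sqrt{n_{pts}}$ at $j = k = 10$. Tests use this corrected band.

## Problem sizes used by the test suite

The suite validates oracle equivalence on series up to $N = 200$ with grids
up to $20 \times 20$ (tolerance $10^{-12}$), maxima detection against brute
force on $30 \times 30$ matrices, the validation study on 20-seed batches of
1200-interval series with $30 \times 30$ grids, the surrogate null on 50
white-noise series with $10 \times 10$ grids, and cluster-count recovery on
20 seeded four-cluster geometries. These sizes were chosen so the whole
suite exercises every claim at full fidelity while remaining quick to run;
the $100 \times 100$ default grid is exercised through the same code paths.

## Known limitations

- Ordered-side argmax recovery and the $NAI$ sign law hold statistically
  across seeds (the onset tilt is an $O((j+k)/N)$ effect competing with
  same-order sampling noise), and median $NAI$ magnitudes for 1200-interval
  series sit at the few-$10^{-3}$ level — see the transpose-symmetry
  discussion above.
- $NAI_{sh}$ is ill-conditioned for strongly structured series (division by
  a near-zero $\bar r_{sh}$); interpret per-subject $NAIC$ accordingly.
- The analysis assumes an edited tachogram; ectopic-beat handling and
  R-peak detection are out of scope.
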