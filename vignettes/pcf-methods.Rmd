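---
title: "Piecewise constant fitting for copy number data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise constant fitting for copy number data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcfseg)
```

## The segmentation model

Copy number measurements on one chromosome arm are modelled as
$y_j = z_j + \varepsilon_j$, where $z$ is piecewise constant — its value
changes only at breakpoints between true copy number segments — and
$\varepsilon_j$ is measurement noise. The fit minimizes

$$L(S \mid y, \gamma) \;=\; \sum_{I \in S} \sum_{j \in I} (y_j - \bar y_I)^2
\;+\; \gamma\,|S|,$$

over all segmentations $S$; within a segment the optimal fitted value is the
segment average, so the whole estimate is determined by the breakpoints.
Expanding the squares shows the equivalent criterion
$L'(S) = -\sum_{I}\left(\sum_{j\in I} y_j\right)^2 / n_I + \gamma |S|$,
which differs from $L$ by the constant $\sum_j y_j^2$; the implementation
minimizes $L'$ and reports both values.

Assumptions worth keeping in mind: noise is independent across probes with
constant variance within a sample (robust rescaling absorbs differences
*between* samples, not local trends such as GC waves), and the truth is
genuinely piecewise constant. The criterion is least-squares, so single
extreme observations are attractive to fit as one-probe segments; this is
why Winsorization and/or the minimum segment length matter in practice.

## The dynamic program

Let $e_k$ be the optimal $L'$ value for the first $k$ probes. There must be
a last segment starting at some $j \le k$, whose cost term is
$d_{jk} = -\left(\sum_{r=j}^{k} y_r\right)^2/(k-j+1)$, giving the recursion
$e_k = \min_j \left(d_{jk} + e_{j-1} + \gamma\right)$, $e_0 = 0$. The
implementation evaluates each step with whole-vector operations on running
cumulative sums, so the $O(p^2)$ program is fast in interpreted R. The
recorded argmins $t_k$ are backtracked from $k = p$ to recover the segment
starts, and segment means are recomputed from the data (they are exact
averages, asserted to $10^{-10}$ in the tests).

Numerical and tie-breaking choices:

* Ties in the minimization go to the smallest start index $j$, i.e. the
  longest final segment — deterministic first-minimum behaviour.
* A minimum segment length `kmin` is enforced by giving infinite cost to
  candidate segments of fewer than `kmin` probes; prefixes that admit no
  legal split carry $e = \infty$ and the constraint propagates exactly.
  With `kmin = 1` the program is unconstrained. An input shorter than
  `kmin` yields a single segment with a warning.
* Accumulated sums are kept in double precision without compensated
  summation; at arm lengths up to $\sim 10^5$ probes the rounding error is
  many orders of magnitude below the comparison tolerances.

The multi-sample variant keeps one running-sum row per sample and sums the
candidate costs across samples, with penalty $n\gamma$ per segment; its
structure (and argmin sequence at $n = 1$) is identical to the
single-sample program.

Correctness is anchored by an independent oracle: `brute_force_pcf()`
enumerates every segmentation (up to $p = 16$) and the test suite requires
cost agreement to $10^{-9}$ on hundreds of random instances for every
fitting route, plus equality of the vectorized recursion with a naive
double-loop reference.

## Choosing the penalty

$\gamma$ trades sensitivity against specificity and is deliberately left to
the user; information criteria (AIC/BIC, cross-validation) are known to
undersmooth breakpoint problems and are not offered. Guidance comes from
two tools:

* `false_call_rate()` applies the fit to simulated pure-noise sequences.
  With variance-normalized data, penalties around 12 / 10 / 8 produce on
  the order of 0.5 / 2 / 10 falsely called aberrations per 10,000 probes
  (each fitted segment beyond the first on a null sequence counted as one
  false aberration), so 8–12 is a practical lower bound; the package
  default of `gamma = 40` is deliberately conservative because real data
  contain local trends that inflate false calls beyond the iid-noise rate.
* `gamma_diagnostics()` and `pcf_profile_over_gamma()` trace segment counts
  and residual variance over a penalty grid; segment counts are
  non-increasing in $\gamma$.

Because the criterion is scale dependent, `pcf()`/`multipcf()` divide each
sample by a robust residual SD before fitting (and rescale the means after),
equivalent to a per-sample penalty $\gamma\hat\sigma_i^2$. The estimator is
the MAD scale of lag-1 differences divided by $\sqrt 2$, combined across
arms by the median: differencing removes the piecewise-constant signal
except at the (few) true breakpoints, whereas a raw MAD would be inflated by
genuine segments. The low-level `pcf_exact()` leaves normalization off so
the algorithm itself stays scale-transparent.

```{r gamma-profile}
set.seed(1)
y <- rep(c(0, 1, 0), each = 40) + rnorm(120, sd = 0.3)
pcf_profile_over_gamma(y, c(2, 10, 40, 160))
```

## Outlier handling

Copy number data contain a high fraction of single-probe outliers of both
technical and biological origin. Winsorization replaces each observation by
$\hat m_j + \Psi(y_j - \hat m_j \mid \tau s)$, where $\hat m$ is a
running-median trend (half-width `k_trend = 25` probes by default), $s$ is
the MAD scale ($1.4826\cdot$MAD) of the residuals, and $\Psi$ clips at
$\pm\tau s$. Defaults: $\tau = 2.5$, the midpoint of the conventional
1.5–3 range. Design details the formulas do not fix:

* Edge policy: windows shrink at the arm ends (no padding, no invented
  data); even-sized windows use the midpoint-average median.
* A degenerate residual scale $s = 0$ (noiseless fixtures) is floored at
  $10^{-12}$ with a warning, so every deviation from the trend is clipped
  to the trend.
* The optional iterative mode (`iterate = TRUE`) re-estimates the trend
  from a PCF fit to the Winsorized values (default one pass,
  `gamma = 40`, `kmin = 5`) and re-clips the raw residuals against it.
  This protects probes adjacent to true breakpoints, where a running
  median blurs the trend. The iteration count and trend penalty are
  exposed because no canonical values exist.

The contaminated normal $(1-\alpha)N(0,\sigma^2) + \alpha N(0, d^2\sigma^2)$
with $\alpha = 0.05$, $d = 3$ is the reference model for outlier-prone
noise. Its diagnostic signature, computed exactly by
`tail_fractions_analytic()`: about 1.67% of draws fall beyond 3
MAD-estimated SD units and 0.42% beyond 5, versus 0.27% and $\approx 0$
for a pure Gaussian — the MAD barely moves under 5% contamination, so the
excess tail mass is fully visible. The acceptance suite also verifies the
qualitative effect that motivates the procedure: on contaminated profiles
with planted aberrations, Winsorization brings the false-spike rate of the
fit back to within a factor two of the clean-data rate, at least threefold
below the unwinsorized rate.

A minimum segment length (`kmin`, default 5 at the table level) is the
complementary guard: used *with* Winsorization it suppresses residual
spikes; used alone it is markedly less effective.

## Multi-sample and allele-specific fitting

`multipcf()` imposes one breakpoint set on all samples, which pools
evidence for concordant low-amplitude events (germline CNVs, related tumor
clones) at the cost of forcing shared boundaries. Per-sample residual-SD
normalization is on by default so a single noisy sample cannot dictate the
breakpoints; optional weights `w` (e.g. tumor cell fraction adjustments)
multiply the normalized tracks. Missing probes are imputed per sample
(nearest observed neighbour mean) rather than dropped, preserving the
common grid.

`aspcf()` preprocesses SNP-array pairs in three steps — mirror BAF around
0.5; drop probes with mirrored BAF below `theta_baf` (default 0.1; use 0 if
germline homozygotes were already set to NA from a matched normal); pair
each logR probe with the nearest retained BAF probe (ties to the left) and
average logR within a pair — and then runs the two-track joint fit, which is
exactly the multi-sample program on the stacked tracks (penalty $2\gamma$
per segment). Per-track normalization is applied because BAF and logR have
different scales; without it the noisier track dominates the summed
criterion. The joint criterion is what detects events invisible in logR
alone, e.g. copy-neutral LOH: total copy number (logR) is flat while
allelic balance (BAF) shifts. Segment boundaries are mapped back to
genomic coordinates via the pairing: a segment starts at the first logR
probe paired into its first BAF probe (`n.probes` counts retained BAF
probes). The default penalty follows the single-sample default (40) and is
an exposed flag. Filtering happens after mirroring, so the threshold cuts
only the homozygote side. Note one consequence of mirroring: for a balanced
segment the *mirrored* BAF mean sits slightly below 0.5 (noise above 0.5 is
folded down, by $\approx \mathrm{sd}\cdot\sqrt{2/\pi}$).

## The fast heuristic

`pcf_fast()` restricts breakpoints to candidates found by high-pass
difference filters: at position $i$ the filter contrasts the next $k$
observations with the previous $k$, with the outer third of each window at
half weight to soften edge artifacts; widths 3 and 12 are always applied,
plus a width matching `kmin` so aberrations of the shortest accepted length
stay detectable. Candidates are local maxima of the absolute score
(plateaus keep their leftmost point) above a per-filter quantile threshold.
The per-filter share is fixed at $0.7\times$ the requested union fraction,
calibrated once on Gaussian noise so the default bank covers
$\approx 15\%$ of positions at `target_fraction = 0.15`; a planted 5-SD
step exceeds the noise quantile with overwhelming margin, so recall of
clear breakpoints is effectively 1 (asserted over 100 seeded replicates).
The dynamic program then runs on per-interval aggregated sums and counts in
$O(q^2)$, and is *exact within the candidate set* — with all positions as
candidates it reproduces `pcf_exact()` bit-for-bit, and its cost can never
beat the exact optimum (both asserted).

Arms longer than 15,000 probes are processed in overlapping subsequences
(length 5,000, overlap 1,000): filters nominate candidates in each new
subsequence, the already-accepted breakpoints are carried forward as
candidates, and the restricted fit is re-run on the growing prefix.
Segment means are exact full-data averages by construction. On 20-segment
profiles of 20,000 probes with jump heights 0.5–2 SD, the validation suite
requires the fast fit to retain the exact fit's variance reduction to a
relative gap below $10^{-4}$.

## Aberration calling

`call_aberrations()` thresholds fitted values: gain if above `theta_plus`,
loss if below `-theta_minus`, strict inequalities (a value exactly at a
threshold is normal). Defaults 0.1; lower values (0.05) suit
high-sensitivity frequency scans. Calls depend on the fitted values only
through the thresholds, so rescaling values and thresholds together changes
nothing. `aberration_frequencies()` reduces a call matrix to per-probe
gain/loss/normal fractions, which sum to one per probe.

## What the simulators emulate — and what they do not

`simulate_null()`, `simulate_profile()` and `simulate_snp_tracks()` generate
all test inputs in code: iid (optionally contaminated) Gaussian noise around
exactly piecewise-constant levels, with every generator taking an explicit
seed and recording its ground truth. SNP tracks attenuate event levels by an
aberrant-cell fraction (default 0.7, at which loss / gain / copy-neutral-LOH
mirrored-BAF levels of about 0.23 / 0.37 / 0.15 survive the default 0.1
homozygote filter), place a configurable fraction of germline homozygous
probes (default 0.33) near BAF 0 and 1, and clip BAF noise (SD 0.03) to
$[0,1]$.

Real arrays violate these idealizations in known ways: GC-content waves and
other local trends (the main reason the default penalty is 40 rather than
the iid lower bound), spatially correlated noise, probe-density variation
along the genome, heterogeneous attenuation, and segmental artifacts near
centromeres and telomeres. Passing tests therefore demonstrate that the
algorithms optimize their criteria correctly and behave as designed under
the stated noise models — not that any particular $\gamma$ or threshold is
optimal for a given platform.

Validation problem sizes were chosen to exercise every code path at desk
scale: oracle comparisons at $p \le 12$ (where exhaustive enumeration is
feasible), null-rate studies on 20 sequences of 10,000 probes, fast-vs-exact
comparisons on 20,000-probe arms (crossing the subsequence threshold), and
tail fractions from $10^6$ draws.

## Conventions and limitations

* Coordinates are 1-based and inclusive; a segment's `start.pos`/`end.pos`
  are the positions of its first/last probe. Probes at positions $\le$ the
  centromere coordinate belong to the p arm (a convention, exposed via
  user-supplied centromere tables; `whole_chrom = TRUE` needs none). A
  small built-in hg19 centromere table supports zero-setup use.
* The `NA` token in input files is case-sensitive `"NA"` (extensible via
  `na_tokens`).
* Imputation uses the mean of the nearest observed value on each side
  (one-sided at arm edges) — simple, deterministic, and adequate because
  segmentation only needs locally plausible values.
* The exact fit is $O(p^2)$ per arm; use the fast variant (default above
  15,000 probes in `pcf()`) for high-density platforms. The fast variant
  exists for single-sample fitting; `multipcf()` is exact-only.
* Allele-specific output is a segmentation, not allele-specific copy number
  calls (no ploidy or aberrant-fraction estimation).
* No automatic penalty selection, recurrence statistics, or GC correction.
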