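---
title: "Multiple change-point models for root developmental zonation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple change-point models for root developmental zonation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootzones)
```

## The statistical problem

Along a growing root apex, epidermal cells are short in the division zone
(DZ), lengthen roughly linearly through the elongation zone (EZ), and are
long and highly dispersed in the mature zone (MZ). Given one root's ordered
cell lengths $x_1,\dots,x_T$ at axial positions $p_t$ (µm from the root cap
junction, cells from several files merged and sorted by position), we want
the number of zones, the limits between them, and honest uncertainty about
both.

The model is a heteroscedastic piecewise Gaussian linear model: change
points $\tau_1<\dots<\tau_{J-1}$ (convention $\tau_0=1$, $\tau_J=T+1$) with,
inside zone $j$,
$$X_t \sim \mathcal N(\alpha_j + \beta_j\,p_t,\ \sigma_j^2),\qquad
  \tau_{j-1}\le t<\tau_j .$$
The zone-specific variances are the point of the exercise: dispersion grows
by an order of magnitude from meristem to mature tissue, so a common
variance (as in segmented/broken-line regression) both misfits and distorts
the limits. The fitted piecewise function is deliberately *not* constrained
to be continuous: approximate continuity is measured afterwards, limit by
limit, and is informative in its own right.

A change point $\tau_j$ is the index of the first cell of the shootward
zone, and the reported limit position (µm) is that cell's position. This
convention is why the most probable limit can sit at an endpoint of its own
uncertainty interval.

## Inference

**Per-segment fits.** Each candidate segment $[u,v]$ is scored by its
Gaussian log-likelihood with maximum-likelihood plug-in parameters: OLS
intercept and slope, $\hat\sigma^2=\mathrm{RSS}/n$. (The unbiased
variant $\mathrm{RSS}/(n-2)$ changes little and is not used; the ML form
keeps the segment score and the dynamic-programming cost identical.) All
$O(T^2)$ segment costs come from running sums of $p,p^2,x,x^2,px$, centered
globally first for numerical stability.

**Optimal and top-N segmentations.** Dynamic programming maximizes the
summed segment scores over all segmentations into $J$ contiguous segments
of at least `min_len` cells ($O(JT^2)$). A generalized (N-best) recursion
keeps, per state, the N best partial scores with their full change-point
vectors, yielding the top-N segmentations in strictly decreasing
likelihood order. Exact ties break toward the lexicographically smallest
change-point vector, so every result is deterministic.

**Posterior diagnostics.** With a uniform prior over feasible
segmentations, forward–backward recursions in log-sum-exp arithmetic give:
the evidence (log-summed likelihood over all segmentations); the posterior
probability of any segmentation; per-cell zone-occupancy profiles (sum
over segmentations); max-type segmentation probability profiles (the
max-analogue, useful to see exactly where an alternative segmentation
disagrees with the optimum); and the posterior distribution of each change
point. Everything is checked in the test suite against exhaustive
enumeration on small series.

**Change-point uncertainty intervals** are contiguous highest-mass
intervals around the most probable change point: grow greedily toward the
side offering more mass (ties rootward) until the target coverage (default
0.95) is reached. This is a documented reconstruction — the coverage level
and contiguity rule of the original smoothing-algorithm intervals are not
published — and it guarantees that the interval contains the optimal change
point, matching the published tables where the limit can sit at an interval
endpoint.

## Selecting the number of zones

$\ell(J)$, the optimal log-likelihood, is nondecreasing in $J$; the slope
heuristic penalizes it by a data-driven constant. With model dimension
$D(J)$ ($4J-1$ for the linear family: $\alpha,\beta,\sigma^2$ per zone plus
the change points; $2J$ for the change-in-variance family), the criterion is
$$C(J)=\ell(J)-2\hat s\,D(J),\qquad
  w_J=\frac{e^{C(J)}}{\sum_{J'}e^{C(J')}},$$
and $J^\*=\arg\max_J C(J)$ (smallest $J$ on ties).

The penalty constant $\hat s$ is estimated from the upper half of the $J$
range (at least three points, otherwise all $J\ge2$), where additional
zones can only overfit. We use the **largest per-parameter increment**
$\max_k \Delta\ell/\Delta D$ over that range rather than an OLS slope of
$\ell$ on $D$: the first spurious split captures the most spurious
likelihood, and an averaged slope under-penalizes exactly that split. In
simulation this choice removed most over-segmentation of single-regime and
two-regime series while leaving all structured scenarios untouched.
`J_max` defaults to 5 for both families so the fitting range is $J=3..5$;
pushing the variance family down to `J_max = 4` makes its fitting range
collapse onto $J\ge2$, which includes genuinely structural gains and makes
the selector miss real third regimes — hence the common default.

The model weights $w_J$ are a pragmatic device of this reconstruction: they
rank neighbouring $J$ and feed the "well-supported" screening below; they
are not asserted against any published per-root weight.

## Residual analysis: the change-in-variance model

Subtracting the retained piecewise linear function gives a residual series
(zero mean within each zone by construction). A Gaussian
change-in-the-variance model — constant mean $\alpha$ fixed at the global
residual mean, constant variance between change points — is fitted with the
*same* cost/DP/posterior/selection machinery, only the segment score
changes. A limit of the linear model is *co-localized* when its uncertainty
interval overlaps (closed intervals, touching counts) the interval of the
nearest variance-model change point. Co-localization separates limits
driven by a slope change from limits driven mostly by a dispersion change —
the latter are exactly the ones that tend to disagree with the first
root-hair position.

$\alpha$ is estimated (global mean) rather than fixed at zero: on genuine
residual series it is numerically indistinguishable from zero, and the
estimated form keeps the model usable on raw series.

## From segmentation to labeled zones

`label_zones()` reads segments positionally: one segment is MZ; with two,
the first is EZ if its slope is significantly positive (two-sided t-test,
$n-2$ df, level 0.05 — the "n.s." convention of the reference tables) *and*
at least 20 µm/mm (published EZ slopes run 9.8–201.8 µm/mm, DZ slopes
−22.1 to 27.9, so the threshold only disambiguates the 2-segment case),
otherwise DZ; three are DZ, EZ, MZ, with an "EZ-missing" diagnosis when the
middle slope is not significantly positive; four are read as a split
meristem (proliferation + transition) when both rootward segments hold
small cells, and the transition zone is collapsed into DZ for cohort
summaries.

`select_final_segmentation()` then applies the published selection
strategy, made deterministic:

1. the slope heuristic picks $J^\*$ and the optimal segmentation is labeled;
2. if zones appear merged, the well-supported segmentations at $J^\*+1$
   (posterior within a factor 10 of the best — a threshold chosen so that
   published examples retaining 2nd- and 3rd-ranked segmentations are
   admitted) are screened for a consistent labeling;
3. if the retained function jumps by more than twice the smaller adjacent
   residual sd at any limit (the published narratives reject a jump of
   ≈4 sd and accept ≈1 sd), well-supported alternatives at the same $J$
   are screened and the best-posterior candidate passing the rule is
   retained;
4. if nothing passes, the optimum is kept and the warning recorded.

Provenance (optimal / alternative rank k / J+1 model, with posteriors) is
part of the output. The first-root-hair position is **never** used to choose
a segmentation; `hair_match()` only compares afterwards (match = hair
rootward of the EZ–MZ limit or inside its uncertainty interval).

Approximate continuity at a limit uses the standard OLS conditional-mean
interval from each adjacent segment at the limit position,
$\hat y_0 \pm t_{n-2,(1+\gamma)/2}\, s\sqrt{1/n+(x_0-\bar x)^2/S_{xx}}$
with $s^2=\mathrm{RSS}/(n-2)$ and $\gamma=0.95$ by default; overlap of the
rootward and shootward intervals is the continuity verdict.

## The synthetic generator

`generate_profile()` emulates how profiles arise: each cell *file* tiles
the axis from 0 — the mean length is the zone's line evaluated at the
current rootward edge, the drawn length is normal with the zone's sd,
truncated at 0.5 µm, the recorded position is the cell center, and the edge
advances by the drawn length. Files (default 3, the protocol's usual count)
are generated independently and merged by position; ground-truth limits,
per-zone parameters and a synthetic first-hair position (EZ–MZ limit +
100 µm) are returned. The `spec_vigorous()` preset mirrors a typical long
lateral root (flat DZ of ~6 µm cells over 855 µm, sd 1.3; EZ to 1494 µm,
slope 59.5 µm/mm, sd 5.5; MZ to 2990 µm, slope 49.6 µm/mm, sd 18.2);
`spec_arrested()` mirrors short arrested roots (one MZ-like zone, mild
positive slope, sd 13).

What the generator does *not* emulate — and hence what passing tests do not
certify about real data: inter-file correlation of cell lengths (files are
independent), measurement error and missed cross-walls, uneven axial
sampling density, and non-stationary growth within a zone. The mean is
evaluated at the cell's rootward edge rather than its center for
construction simplicity; at published slopes the within-cell mean shift is
far below the residual sd. Truncation bias at 0.5 µm is negligible at the
signal-to-noise ratios of the presets.

One structural consequence worth knowing: when the generating zone lines
are value-continuous at a limit, the boundary cells genuinely fit both
adjacent zones, so the optimal-segmentation posterior stays split over a
few neighbouring segmentations *however small the noise*. Posterior
concentration toward 1 as noise vanishes is only expected — and only
tested — for discontinuous constructions.

## Numerical choices

* **Minimum segment length**: 4 cells (3 are needed for a positive residual
  variance; the 4th adds stability). Configurable everywhere.
* **Variance floor**: $10^{-6}$ µm² inside segment costs, so collinear
  stretches keep finite likelihoods; such fits are flagged degenerate.
* **Precision near the floor**: running-sum RSS carries cancellation noise
  that the floor amplifies by $10^6$; segments whose RSS falls near the
  floored regime are recomputed with exact two-pass arithmetic, keeping all
  posterior quantities within $10^{-9}$ of exhaustive enumeration.
* **Tie-breaking**: lexicographically smallest change-point vector, both in
  the optimal reconstruction (front-to-back, ties resolved rootward within
  $10^{-9}$ relative) and in the N-best ordering.
* **Degenerate inputs**: profiles shorter than `2 * min_len` refuse to
  segment; equal positions within a segment make the slope undefined
  (error in `fit_segment()`, mean-only fallback inside DP costs); empty or
  column-deficient CSVs fail loudly with counts of dropped rows.
* **PCA determinism**: correlation-matrix PCA with each axis oriented so
  its largest-magnitude loading is positive; supplementary variables are
  correlated with scores post hoc and never influence axes.

## Problem sizes in the test suite

Exhaustive-enumeration checks run on 200 randomized series with $T\le12$,
$J\le3$; recovery checks use 50 seeded replicates of the vigorous preset
(~600 cells each) and 50 two-block variance series of length 80; the
generator's spread calibration uses 200 replicates. Limit-recovery
tolerance is three mean cell lengths of the zones adjacent to each limit —
three cells of local slack, the natural resolution of a cell-indexed
change point.

## Known limitations

* The published expert choices among alternative segmentations encode
  judgment; the automated strategy reproduces their logic but cannot
  reproduce every manual decision. All automated choices carry provenance,
  and the file-level interface accepts forced J or rank overrides.
* The slope-heuristic weights and the uncertainty-interval rule are
  documented reconstructions (see above); printed per-root posterior
  weights are therefore not comparison targets.
* The cohort PCA of published roots cannot be reproduced from the packaged
  tables because mature-zone diameters are not printed; `cmd_cohort()`
  skips PCA and says so when diameters are absent.
* Very short mature zones with few, highly dispersed cells make the EZ–MZ
  limit intrinsically uncertain; the package reports that uncertainty
  rather than hiding it, and rate-based tests accept occasional large
  misses there.
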