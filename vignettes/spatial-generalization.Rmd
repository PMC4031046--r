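---
title: "Quantifying spatial generalization in operant shot-selection learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatial generalization in operant shot-selection learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hooplearn)
```

## The scientific question

When a basketball player makes or misses a shot, how does that outcome
reshape where the *next* shot comes from? If learning were spatially
local, a make from the left corner would mostly boost further left-corner
attempts. If learning generalized by abstract shot class, a make from any
3pt location would boost 3pt attempts everywhere. `hooplearn` provides the
estimation and testing machinery to distinguish these hypotheses from
sequences of located field-goal attempts, together with a generative model
in which the true answer is known exactly.

## The estimator

All statistics are **within game** and **within player**: a player's shots
`1..N` in one game contribute the pairs `(1,2), ..., (N-1, N)`; a player is
a (`player_id`, `season`) unit and is never pooled across seasons. For a
partition of the half court into regions, the estimator computes the prior
`P_j` over all of the player's included attempts (first shots of games
included — the prior describes where the player shoots from, not only
where he follows up), the outcome-conditioned next-shot distributions
`P(j | S_i)` and `P(j | F_i)` from the pairs, and the learning index

$$L_{ij} = \frac{P(j \mid S_i) - P(j \mid F_i)}{P_j}.$$

Two limiting cases anchor the interpretation: an outcome-blind policy has
equal conditionals and hence $L = 0$; a player who always repeats a made
shot's region and never a missed one has $L_{ii} > 0$ and
$L_{ij} \le 0$. Cohort matrices are equal-weight means over players, with
the entrywise standard error of the mean (sample SD over players,
$n-1$ denominator) attached.

A row $i$ of the matrix is only meaningful if the player has both a made
and a missed antecedent from region $i$; a player-season with any
ill-defined row at the analysis resolution is excluded from that analysis
entirely, and the region-level selection additionally requires at least
`min_per_region = 10` attempts from each region. The coarse 3×3 matrix
(3pt / long-2pt / short-2pt) is **re-estimated on regrouped events**, not
averaged from the 16×16 matrix: the index is nonlinear in the underlying
probabilities, so the two disagree in general.

## Court geometry and the default region map

Coordinates are continuous feet with the origin at the baseline's midpoint
and the basket at `(0, 5.25)`. The 2pt/3pt boundary follows the corner
line (`|x| = 22`) below the corner break (`y = 14.198`) and the arc
(radius 23.75) above it, so distances between 22 and 23.75 ft contain both
2pt and 3pt locations depending on angle — the lever used to dissociate
shot class from distance. All constants are parameters of `court_spec()`,
so other leagues' lines can be modeled.

The published 16-region partition exists only as a figure, so the default
map is a parameterized reconstruction validated by its structural
invariants: a central zone around the basket (`d <= 8` ft), a short-range
ring (8–16 ft) in five angular sectors, a long-2pt band (beyond 16 ft,
inside the line) in the same sectors, and five 3pt sectors; labels
interleave so that regions 1, 4, 7, 11, 14 are the 3pt group and 2, 5, 8,
12, 15 the long-2pt group. Every analysis accepts any user-supplied
region map; boundary points resolve deterministically (lowest label
wins). Each region also carries a polar *placement rectangle* proven (by
test) to lie entirely inside the region: the generator samples uniformly
from these rectangles, so generated labels and `assign_region()` agree
exactly. The two corner rectangles were placed so that the 2pt and 3pt
cells straddling the line sit at nearly equal mean distance (22.65 vs
23.2 ft), mirroring the real court where the straddling bins are almost
equidistant from the basket.

## The generative model and its oracle

In `one_step` mode a player's base policy is `P(region r) ∝ w_r`; after a
shot from region `i` with outcome `o`, the next shot's weights are
`w_j * exp(±η K_ij)` (`+` after a make), after which the policy resets.
The default base weights are the observed NBA shares of attempts per
region of the default partition; the default make probability declines
linearly with distance, `q(d) = 0.62 − 0.01 d` (clamped), equal for 2pt
and 3pt attempts at the same distance — difficulty is continuous while
the planted kernel is categorical. Returns follow an explicit possession
model: a made shot returns its point value; a missed shot yields a
2-point putback with probability `putback_prob = 0.15`.

One-step memory keeps the model exactly solvable: (region, outcome) is a
Markov chain whose transition matrix combines the softmax conditionals
with each region's expected make probability (the integral of `q` over
the region's distance band — exact, because distance is conditionally
independent of the next shot given region and outcome).
`oracle_statistics()` computes the stationary distribution (power
iteration to 1e-14), the *finite-game prior* that the pipeline actually
estimates (the average of the within-game marginals of shots
`1..shots_per_game`, the first drawn from the base policy), the exact
conditionals and learning matrices, and exact binned statistics via
closed-form overlap integrals. The multiplicative-exponential update was
chosen so the conditionals have closed softmax form; at small `η` the
index is approximately `2η(K_ij − Σ_k P_k K_ik)`, making `η` and `K`
identifiable from `L`.

The planted scenario (`planted_scenario()`) encodes, by construction, the
qualitative pattern seen in professional cohorts: 3pt outcomes transfer
mostly to 3pt attempts and suppress short-range attempts; long-2pt
outcomes transfer to long-2pt at the expense of short-range, with a small
positive spillover to 3pt; short-range outcomes barely matter.

`melioration` mode replaces the kernel with a running 2pt/3pt allocation:
exponentially smoothed per-class return estimates (rate 0.02) drive the
3pt propensity (step 0.01 per unit return difference), while each class's
make probability diminishes with its running allocation frequency
(pressure 0.9 on 3pt, 0.3 on 2pt — chosen for an interior equilibrium
near realistic allocation). Its fixed point is the matching law: equal
return per attempt. Because the transient from the uninformed initial
allocation (0.5) is not part of the equilibrium being characterized, the
generator discards a 50-game burn-in by default.

## Statistical tests

The permutation null redraws, independently per player, each consequent
shot's region from that player's estimated prior, keeping antecedents,
outcomes and the pairing skeleton fixed — destroying outcome dependence
while preserving marginals. The p-value is the fraction of `n_rep`
surrogates whose statistic **strictly exceeds** the observed one (ties
count as non-exceeding); `p = 0` is reportable as `p < 1/n_rep`. For
speed, surrogate pair counts are drawn directly from the multinomial
distribution these independent draws imply — exactly equivalent in
distribution, and verified against an event-level surrogate oracle in the
test suite. The sign test on the diagonal uses the exact binomial upper
tail, summed term by term.

The near-line test compares the two cells straddling the 3pt line
(`[22, 24)` ft, 2pt vs 3pt). For the learning statistic, surrogate
conditional probabilities are redrawn from each bin's pooled
(outcome-free) prior; for the shooting percentage, outcomes are redrawn
from the player's percentage pooled across the two bins (the
no-difference null).

## Clustering

Ward linkage is implemented directly (naive $O(n^3)$ agglomeration) with
the square-root height form
$d(A,B) = \sqrt{2 n_A n_B / (n_A + n_B)}\,\lVert c_A - c_B \rVert$, which
reduces to the Euclidean distance for singletons and therefore extends
the reported dissimilarity matrices; the squared form is available behind
`form = "squared"` and changes only the heights, never the merge order.
Distance ties break deterministically toward the lexicographically
smallest pair of cluster ids. Rows are clustered with all 16 coordinates
(including the self-coordinate; `drop_self = TRUE` removes it). The
implementation is checked against an exhaustive from-scratch
recomputation and against `stats::hclust(method = "ward.D2")` to 1e-10.

## Study designs used by the tests

Problem sizes were chosen so each check isolates its property at
comfortable signal-to-noise:

- *Null cohort*: 100 memoryless players × 1,000 shots; p-value
  calibration uses 200 reduced runs (4-region map, 8 players × 300 shots,
  200 surrogates each) and a Kolmogorov–Smirnov uniformity check.
- *Oracle recovery*: 200 players × 2,000 shots from the 3-block kernel at
  `η = 0.3`, then ×4 the games to confirm the worst-case deviation
  shrinks roughly by half (the max-over-entries statistic is noisy, so
  the ratio is only bounded into `[0.3, 0.8]`).
- *Cluster recovery on finite data* uses 3 players × 20,000 shots. The
  entry noise of a per-player matrix scales like
  $\sqrt{(1/n_{iS} + 1/n_{iF})/P_j}$; real cohorts reach adequate row
  signal-to-noise through ~170 players at ~1,000 shots each, and a
  3-player cohort needs correspondingly more shots per player for the
  between-group row separation to dominate. This is a deliberately
  data-rich design that isolates the clustering property rather than
  emulating a season.
- *Near-line dissociation*: 100 planted-scenario cohorts (100 players ×
  1,200 shots); significance of the learning contrast at `p < 0.01` and
  non-significance of the percentage contrast at `p > 0.05`, each in at
  least 90% of runs.
- *Matching*: 30 melioration players × 3,000 shots after burn-in.

Where a check bounds **every** entry of a family of $m$ estimates against
the oracle, the test uses a simultaneous band: the per-entry threshold
$\Phi^{-1}(1 - \alpha/(2m))$ with $\alpha = 2(1-\Phi(3))$, so the
familywise false-alarm rate equals that of a single 3-SEM comparison.
With $m = 256$ entries a plain 3-SEM bound on each would fail a correct
implementation roughly half the time (about 0.7 expected exceedances per
family).

## Numerical and degenerate-input choices

Band integrals of `q(d)` use adaptive quadrature at `rel.tol = 1e-11`;
the stationary distribution iterates to 1e-14; Ward heights are exact
floating-point comparisons (ties are genuine equalities, broken by id).
Empty tables, single-shot games (no pairs), regions never visited
(dropped from the player's region set), players with an undefined prior,
and `k` outside `1..n` in tree cuts all raise informative errors or are
excluded per the selection rules rather than silently imputed. An empty
bin set makes the bin selection criterion vacuous (all players included).
`return_points` distinguishes *absent* (`NA`, unknown possession context)
from zero.

## What passing tests do and do not show

The generator emulates within-game sequences with outcome-dependent
policy updates, region-structured transfer, distance-dependent
difficulty and a possession model for returns. It does **not** emulate
defensive adaptation, teammate/coach influence, shot-clock or score
context, heterogeneous player skill, or free throws. Passing the suite
therefore shows that the estimation pipeline is correct and well
calibrated — unbiased against an exact oracle, with valid nulls — not
that real cohorts must exhibit the planted pattern. Applying the
pipeline to real data additionally requires the user to supply shot
tables in the canonical CSV schema and, for return analyses, possession
context via `compute_returns()`.
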