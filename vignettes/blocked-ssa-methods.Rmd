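---
title: "Blocked partial sums for the exact stochastic simulation algorithm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blocked partial sums for the exact stochastic simulation algorithm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model class

`blockssa` simulates spatially homogeneous mass-action reaction networks as
continuous-time Markov jump processes — the regime where molecular counts
are too small for rate equations and the chemical master equation must be
sampled by Monte Carlo. A model is a list of $N$ species with non-negative
integer counts $[s_i]$ and $M$ reaction channels of three elementary
types, each with a rate constant $k_l$:

| type | form | propensity $a_l$ |
|------|-------------------|------------------|
| 1 | $s_i \rightarrow \dots$ | $k_l\,[s_i]$ |
| 2 | $s_i + s_j \rightarrow \dots$ ($i \neq j$) | $k_l\,[s_i][s_j]$ |
| 3 | $s_i + s_i \rightarrow \dots$ | $k_l\,[s_i]([s_i]-1)/2$ |

Each channel has at most two reactant and two product molecules, so a
firing changes at most four species counts, each by a delta in
$\{-2,-1,+1,+2\}$. The stoichiometry is stored as a flat packed table: one
entry per changed species, a 29-bit species-index field plus a 3-bit
signed delta field (supporting up to $2^{29}-1$ species), with a reserved
null entry for unused slots. A species with net delta 0 (a catalyst such
as $A + B \rightarrow A + C$) is not representable in this format and is
rejected by `validate_network()`; catalytic kinetics must be modelled
through an explicit intermediate.

The exact simulation loop is the classical one: compute the total
propensity $a_R = \sum_l a_l$, pick the next channel $f$ as the smallest
index whose propensity prefix sum reaches $z_1 a_R$, advance the clock by
$\Delta t = \ln(1/z_2)/a_R$, apply the stoichiometry, and repeat until the
final time — $z_1, z_2$ uniform on $(0,1]$ (the endpoints are excluded:
$z_2 = 0$ would be a log singularity and $z_1 = 0$ a zero selection
target). The algorithm is exact: no leaping or rate approximation is made
anywhere in this package.

## The blocked-partial-sum engine

The cost of an exact SSA step is dominated by data movement: the search
for $f$ touches the propensity array, and the update after a firing
touches every propensity that depends on a changed species. The blocked
engine restructures both steps around a fixed partition of the reaction
list into $p$ contiguous blocks of $b$ propensities ($b$ a multiple of
the 128-element chunk size, chunks a multiple of the 32-wide lane — the
granularities of the lock-step execution groups the data layout is
designed for; in this serial implementation they are array-segmentation
parameters with the same defaults).

**Selection** maintains the *cumulative* block sums
$C_i = \sum_{l \le i} B_l$ (so $a_R = C_p$) and proceeds in three levels:

1. *block*: the first $i$ with $C_i \ge z_1 a_R$ — the ballot/first-set
   primitive, realized as "first index satisfying a predicate over an
   array segment";
2. *chunk*: a scan over 128-wide chunks of the selected block, each chunk
   summed by a lane-strided reduction (lane $j$ accumulates elements
   $j, j+32, j+64, \dots$, lane partials combined in lane order);
3. *lane*: a prefix scan in 32-wide batches inside the selected chunk.

Ties at exact prefix-sum boundaries resolve to the lower index (the
predicate is $\ge$), matching the linear Direct Method scan index for
index; this equivalence is asserted exactly, not approximately, over
$10^5$ randomized cases including zero runs and boundary-exact targets.

**Update** uses a reaction–reaction dependency graph: for each channel,
the list of channels whose reactants intersect its changed species
(including itself whenever it consumes a species it changes). Entries are
denormalized — type, global index, rate constant, reactant indices are
copied into the graph, trading memory for locality — and sorted by owning
block, with an integer offset array marking each block's slice (blocks
are contiguous index ranges, so block order coincides with index order).
After a firing, each dependent's propensity is recomputed from the
current counts, the changes are accumulated per block, a prefix sum over
the per-block deltas is formed, and the cumulative sums are updated as
$C_i \mathrel{+}= \sum_{j \le i} \delta_j$. Whether one lane or a full
lane group is scheduled per block is chosen by comparing the mean number
of dependents per block against `dense_update_threshold` (default 32);
both schedules accumulate per-block deltas in the same ascending
dependent order, so their results are bitwise identical — the threshold
changes work accounting, never numbers.

**The block-count trade-off.** More blocks make selection cheaper (the
chunk scan covers $b \approx M/p$ elements) and the update dearer (the
delta prefix runs over $p$ blocks). `block_sweep()` measures both as
element touches per firing; the default geometry picks the smallest
$b$ that is a multiple of 128 with $p \le 25$, the flat region of the
trade-off for this serial engine, and both `p` and `b` are overridable
everywhere (CLI flags `--blocks`, `--block-size`).

**Floating-point drift.** Incremental cumulative sums accumulate rounding
error, so they are recomputed from scratch every `refresh_interval`
firings (default $10^4$). With integer-valued counts and rate constants
every increment is exactly representable and the drift is literally zero;
with irrational rate constants the measured drift after $10^4$ updates
stays below $10^{-12}$ relative, comfortably inside the $10^{-8}$
tolerance the tests assert. A selection overshoot caused by drift (a
target marginally beyond the last positive prefix) falls back to the last
positive-propensity index rather than failing.

## Reference engines and the RNG contract

Two serial references are built in: the Direct Method (full propensity
recompute, linear cumulative scan — the oracle) and the Optimized Direct
Method (dependency-graph incremental updates, incremental $a_R$, linear
scan). All three engines consume exactly two uniforms per step, $z_1$
then $z_2$, from a counter-based per-trajectory PCG32 stream, so under a
shared `(seed, stream)` they are *trajectory-identical*: the same
reaction sequence exactly, and waiting times equal to within the $\sim
10^{-15}$ relative difference of their differently-accumulated $a_R$.
This turns cross-engine validation into exact equality testing instead of
distributional comparison. Every stepping primitive also exists as a
documented pure-R function (`hierarchical_select()`, `ssa_step()`,
`direct_method_step()`, `odm_step()`, ...), and the R and compiled paths
are checked against each other event by event.

**Pre-simulation reordering.** `presimulate_and_order()` runs a short ODM
realization (default $10^4$ firings, one realization, fixed seed — the
budget is a package default; it only needs to rank channels stably) and
counts, per reaction, how often its propensity is recomputed and, per
species, how often its count is updated. Sorting both arrays by
descending access count (stable for ties) packs the hot channels and
species together; the classical ordering by time-averaged propensity is
available as `order_by = "propensity"`. Reordering is a pure relabeling:
the permuted network generates the same physical trajectories, which the
tests verify by mapping the selection variate through the permuted
cumulative intervals.

## Recording and ensemble statistics

Event times are irregular, so trajectories are recorded on a uniform grid
(default spacing 0.01 time units) by interpolating between the event
states bracketing each grid time; when $a_R$ reaches zero the terminal
state is held to the final time. The loop runs while $t < t_f$, so the
event that crosses $t_f$ supplies the right bracket for the last grid
points.

Linear interpolation of a piecewise-constant jump process is a *biased*
estimator of the state mean: by the inspection paradox the grid value
sits about $\mathbb{E}[w]\,\overline{\Delta x} \approx 0.5$ molecules
below $\mathbb{E}[X(t)]$ on a pure death process (the fraction $w$
through the bracketing interval is uniform in the limit). The bias is
*shared* by any two engines recorded the same way, so engine-vs-engine
residuals are unaffected — which is exactly why the accuracy protocol
works — but it matters when comparing against closed-form means. Both
semantics are therefore provided: `interpolation = "linear"` (default,
the method's protocol) and `"hold"` (piecewise-constant, the unbiased
estimator); the analytic-limit test of the decay model uses `"hold"`,
and a dedicated test pins the $\approx -0.5$-molecule offset of the
linear mode so the artifact stays documented rather than surprising.

`run_ensemble()` runs $l$ independent realizations — trajectory $i$ on
stream `stream_offset + i - 1`, a counter-based scheme that makes results
independent of batching and execution order (batched and sequential runs
are bitwise identical; means over disjoint stream ranges pool exactly).
It reports grid means, Monte-Carlo standard errors, and the average
updates per realization $m$; `time_per_update()` derives the throughput
metric $T_{up} = T_t/(l\,m)$, which is reported but never asserted
against reference values (it is hardware-dependent).

`percentage_residuals()` compares two summaries as
$100\,|\bar x_A - \bar x_B| / \bar x_B$ per species and grid point,
excluding (and counting) points where the reference mean is below a
0.5-molecule floor — a percentage of a near-zero mean is noise, not
signal. The residual is asymmetric in its denominator by construction;
the reference engine's mean is always the denominator here.

## The benchmark families

`cyclic_chain(N)`: $s_i \rightarrow s_{i+1 \bmod N}$, $M = N$, all
$k = 1$, one molecule per species. Total count is conserved and every
reaction has exactly 2 dependents — the weakly coupled extreme.

`colloidal_aggregation(N)`: aggregates $A_1..A_N$ with
$A_i + A_j \rightarrow A_{i+j}$ for $i \le j$, $i+j \le N$, and the
reverse fragmentations. Reaction counts come from pair enumeration (the
tests pin them against an independent oracle); the largest dependent list
has $3N-7$ entries, achieved by the small-aggregate channels — the
strongly coupled extreme. Structure tests run at $N = 20$; the engine is
exercised at the $N = 252$ scale.

`random_network(N, M, dependency_range)`: random consistent networks.
Three constructions share one surface. A `c(2, 2)` request returns a
randomly labelled chain. A general band such as the default `c(8, 16)`
uses a *two-hub* design: reactions are partitioned into groups of about
6 sharing a hub reactant, and every reaction is
$H_t + s \rightarrow H_{\sigma(t)} + u$ with $\sigma$ a fixed-point-free
group permutation and $s, u$ drawn from balanced low-degree multisets.
Each firing then changes two hub species (consumer lists of group size)
plus two low-degree ordinary species, which pins every per-reaction
dependent count inside the band (measured: 12–15 at the default
geometry); the generator verifies the band with `connectivity_stats()`
and redraws on failure, raising a generation error after bounded
retries. `dependency_range = NULL` gives an unconstrained
molecule-conserving network with a configurable type mix whose product
multiset is a shuffle of its consumption multiset. All three guarantee
closed species flow — every species consumed somewhere is produced
somewhere — so no species is driven extinct by construction, and every
generated network passes `validate_network()`. Generation is a pure
function of its seed (regenerated model files are byte-identical).

## The accuracy protocol

`accuracy_benchmark()` is the package's standard engine-vs-engine
validation, reproduced end to end by `scripts/acceptance.R`: generate a
random consistent network (256 reactions × 256 species, dependent counts
8–16, all $k = 1$), run 2000 independent realizations per engine with the
blocked engine and with the reference ODM on *disjoint* stream ranges, so
the two ensembles are statistically independent and their disagreement
includes full Monte-Carlo noise; interpolate to the 0.01 grid, average,
and take the maximum percentage residual over all 256 species and all
grid points. The acceptance bound is 4%.

Two protocol parameters deserve their rationale:

* *Initial counts are 50 molecules per species.* The maximum residual
  between two independent exact ensembles has a Monte-Carlo noise floor
  of $100\sqrt{2\,\mathrm{var}/l}/\mathrm{mean}$ per cell — with
  near-Poisson counts this is $\approx 316\%/\sqrt{l\cdot\text{mean}}$
  per standard deviation, maximized over thousands of cells. At one
  molecule per species no feasible ensemble size puts the *maximum* under
  4% (measured: ~39% at $l = 200$, i.e. ~12% at $l = 2000$); at 50
  molecules the floor sits near 1.5–2% at $l = 2000$, so the bound tests
  engine agreement rather than noise.
* *The horizon is $t_f = 0.05$*, which at this density gives $m \approx
  3\times 10^4$ updates per realization — inside the $10^4$–$5\times
  10^4$ updates-per-run band the performance protocol targets — and
  keeps species means well above the residual floor. Longer horizons
  (e.g. $t_f = 0.5$, $m \approx 2.4\times10^5$) let slow species drain
  to means of 2–6 molecules where percentage residuals measure only
  noise.

Desk-scale sizes were chosen to keep the full protocol under about a
minute of CPU: 256×256 with $2\times 2000$ realizations rather than the
1024×1024 with $10^4$ realizations a production validation would use.
What passing shows: the blocked selection/update machinery introduces no
bias relative to a plainly-implemented ODM under identical recording.
What it does not show: agreement with real biochemical kinetics — the
generator's networks are mass-action, dilute, spatially homogeneous, and
type-limited by construction, with none of the stiffness, conservation
structure, or rate heterogeneity of curated pathway models.

## Numerical and design choices, in brief

* Propensities and sums are 64-bit doubles throughout; counts are
  integer-valued doubles (exact below $2^{53}$).
* Selection boundary convention: $\ge$, ties to the lower index, at all
  three levels and in both reference scans.
* The bit-packed stoichiometric table is the storage format; operations
  use an unpacked view, so correctness never depends on bit twiddling.
* Internal indices are 0-based in the engine, 1-based at the R surface;
  model files name species by label, mapped to dense indices on read.
* Degenerate inputs: $t_f = 0$ records the initial state only; $a_R = 0$
  terminates with the state held; an empty propensity vector is an
  invalid state; a firing that would drive a count negative is an
  internal-consistency error (it can only follow from a selection bug, so
  it fails loudly instead of clamping).
* `run_ensemble()` accumulates in stream order, making batch size
  invisible to the result.

## Limitations

Only the three elementary mass-action types are supported — no reversible
sugar, no time-varying rates, no general rate laws, and no catalysts in a
single reaction. The dependency graph is stored in full per source
reaction; very large, tightly coupled systems would want the bipartite
species–reaction factorization, which is out of scope here. The engine is
serial: lane and chunk widths reproduce the blocked algorithm's access
pattern and contracts, not parallel wall-clock behaviour, so all
performance claims in this package are stated as counted element touches,
never as hardware speed-ups.
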