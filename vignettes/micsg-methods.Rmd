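---
title: "Computing MIC precisely: grids, budgets, and the annealed genetic search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing MIC precisely: grids, budgets, and the annealed genetic search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(micsg)
```

## The statistic

The maximal information coefficient (MIC) of a paired sample
$(x_i, y_i)_{i=1}^n$ is

$$\mathrm{MIC} = \max_{G} \frac{I_G(x, y)}{\log_2 \min(n_x, n_y)},
\qquad n_x n_y < B(n),\; B(n) = n^{0.6},$$

where the maximum runs over all grids $G$ that partition the plane into
$n_x$ columns and $n_y$ rows, $I_G$ is the empirical mutual information of
the induced contingency table (in bits), and the denominator is the largest
value $I_G$ can attain on an $n_x \times n_y$ grid, so the score lies in
$[0, 1]$. MIC is attractive for expression-profile screening because it is
distribution-free and sensitive to a broad class of functional and
non-functional association shapes.

Everything in this package operates on *ranks*: both axes are first replaced
by their order statistics (a consecutive integer series per axis, ties broken
by original index so the result is a true permutation). Cut lines then live
*between* adjacent ranks — a cut at position $k$ separates rank $k$ from
$k+1$, and bins are the half-open rank intervals between consecutive cuts.
Two consequences are worth spelling out:

* MIC as computed here is invariant under any strictly increasing transform
  of either axis (the ranks do not change);
* a grid search is a purely combinatorial problem over subsets of the
  $n - 1$ candidate cut positions per axis.

Constant axes are rejected with an error: ranking them would manufacture an
arbitrary permutation and a spurious score.

### The budget $B(n)$

Without the constraint $n_x n_y < B(n)$ the finest grid trivially maximizes
normalized information (every cell holds at most one point), so the budget is
what makes MIC a statistic rather than an artifact. $B(n)$ is real-valued;
since the shape counts are integers, we use the equivalent integer budget
$\lfloor n^{0.6} \rfloor$ with $n_x n_y \le \lfloor n^{0.6}\rfloor$, plus a
floor of 4 so the minimal informative $2\times 2$ grid is always admissible —
for $n \le 10$, $n^{0.6} < 4$ would otherwise forbid *every* grid and leave
MIC undefined exactly in the short-profile regime where expression data live.

The exponent 0.6 is a calibration: independent data should receive scores
approaching zero as $n$ grows, while exponents near 1 admit grids so fine
that independent data keep receiving inflated scores. `null_mic_curve()`
reproduces this calibration on independent uniform clouds; the package's
validation suite operationalizes "does not decrease comparably" for the
contrast exponent 0.95 as (i) the relative decline of the null median from
$n = 25$ to $n = 100$ being less than two-thirds of the decline at 0.6, and
(ii) the null median at $n = 100$ staying above 0.5 — i.e. bounded away from
zero in the plain sense.

## Three engines

### Exhaustive enumeration (`exhaustive_mic`)

The gold standard encodes each axis partition as an integer mask in
$1 \ldots 2^{n-1}-1$ (bit $k$, least significant first, inserts a cut between
ranks $k$ and $k+1$), loops x-masks outer and y-masks inner in ascending
order, skips any pair whose implied shape violates the budget *before*
scoring it, and keeps the first maximum encountered. The implementation
generates the admissible masks by cut-set size and sorts them by mask value —
the same result set and tie-break order as the literal $1 \ldots 2^{n-1}-1$
loop, exponentially cheaper. The engine still refuses $n$ above `n_cap`
(default 18, overridable): without budget pruning a 23-point profile already
costs hours, and the cap keeps the oracle honest about being a desk-scale
tool.

### The equipartition-y baseline (`equiy_mic`)

The known failure mode of the original MIC heuristic is to fix an
equipartition of the $n$ points with horizontal lines and optimize only the
vertical cuts. `equiy_mic` models exactly that restriction — and optimizes
the x-cuts *exhaustively*, which can only make the baseline stronger than the
heuristic it models, so any gap we demonstrate against the full optimum is
conservative. Since its grids are a subset of the full search space,
`equiy_mic <= exhaustive_mic` always; `cluster_split_fixture()` ships an
eight-point sample on which the inequality is strict by a wide margin,
because the optimal horizontal cut sits far off-center where no
equipartition can place it.

### The annealed genetic search (`sg_mic`)

The production engine is a genetic algorithm over grid chromosomes,
hybridized with simulated annealing. A chromosome is one grid: its genes are
the vertical cut positions (x-genes) and horizontal cut positions (y-genes).
Gene counts are fixed within a run, so one GA run explores one shape
$(n_x, n_y)$; `sg_mic` runs every feasible shape under the budget and
returns the maximum. This per-shape design is deliberate: the crossover and
mutation operators preserve gene counts, so a single mixed-shape population
could never reach every grid, while per-shape runs make the whole admissible
space reachable.

One generation applies, in order:

1. **Proportional selection** — roulette sampling with replacement,
   probability proportional to fitness (the MIC of the chromosome's grid;
   non-negative by construction). A uniform fallback handles the all-zero
   corner.
2. **Same-axis one-point crossover** — an x-gene list is only ever exchanged
   with another x-gene list, a y-gene list with a y-gene list, so shapes are
   preserved. The cut point is uniform on $0 \ldots k$ for a $k$-gene axis:
   including both ends means a lone-gene axis can still swap wholesale,
   which is what lets $2 \times k$ shapes recombine a good x-cut found in one
   chromosome with a good y-cut found in another. Duplicates created by the
   exchange are repaired by resampling from free positions. The crossover
   probability is self-adaptive (below), evaluated at the fitter parent of
   the pair.
3. **Self-adaptive mutation** — each chromosome moves one randomly chosen
   gene per axis: interior lines to a uniform position strictly between
   their neighbors, the first and last lines within their boundary gaps, and
   a lone line anywhere on its axis (it is both "first" and "last"; without
   this extension single-cut axes could never explore).
4. **Metropolis-filtered replacement** — each offspring is compared with the
   selected parent it derived from: improvements are always kept, and a
   deterioration $\Delta < 0$ survives with probability
   $\exp(\Delta / T)$ under the current temperature, allowing early escape
   from local optima. The temperature cools geometrically,
   $T_{g+1} = 0.95\, T_g$ from $T_0 = 0.1$ (fitness lives in $[0,1]$, so
   $T_0$ of a tenth of the scale makes moderate deteriorations survivable
   for the first dozens of generations).
5. **Elitism** — the best chromosome ever seen replaces the current worst,
   so the champion fitness trace is non-decreasing by construction.

A shape's run stops once the champion has been unchanged for
`stall_limit = 30` consecutive generations, or at `max_generations = 2000`.

#### The adaptive rates and the mutation trigger

The self-adaptive rate for both operators is the standard form

$$p(f) = \begin{cases} p_1 & f < f_{ave} \text{ or } f_{max} = f_{ave},\\
p_1 - (p_1 - p_2)\,\dfrac{f - f_{ave}}{f_{max} - f_{ave}} & f \ge f_{ave},
\end{cases}$$

with $p_1 > p_2$ (defaults $pm_1 = 0.1$, $pm_2 = 0.01$ for mutation,
$pc_1 = 0.9$, $pc_2 = 0.6$ for crossover — conventional GA values, all
exposed in `ga_config()`). Fit individuals get the *small* rate.

The mutation *trigger* deserves its own paragraph, because two readings are
possible and they produce very different searches. The rule implemented
here: each chromosome draws $u \sim U(0,1)$ and mutates iff $u \ge pm$ —
i.e. $pm$ acts as a *protection* probability. Under this rule nearly the
whole population is perturbed every generation (fitter individuals slightly
more, since their $pm$ is smaller), and the global champion is protected by
elitism alone. The alternative convention — mutate iff $u < pm$ — would make
mutation an event of probability at most $pm_1 = 0.1$, and the search would
explore a 2×2 shape's $\,(n-1)^2$ grid essentially by rare random probes.
We adopt the first reading for two reasons: it is the rule as printed in the
algorithm's source description, and it is the one under which the engine
actually delivers its defining property — agreement with the exhaustive
oracle in (nearly) every seeded run, exact attainment of 1.0 on noiseless
monotone data, and strict noise discrimination. The exported primitive
`maybe_mutate()` keeps the plain "mutate with probability $p$" contract;
the engine passes it the complement of the adaptive rate.

#### Determinism and parallel batches

All stochastic draws — in both the pure-R reference engine and the compiled
engine — come from R's RNG stream, so a fixed `seed` in `ga_config()` makes
`sg_mic` bit-reproducible (the caller's RNG state is saved and restored).
In batch mode (`pairwise_mic`) each pair receives a seed derived
deterministically from the global seed and the two row identifiers, so the
output is byte-identical for any worker count.

The compiled engine (Rcpp) and the pure-R reference engine
(`engine = "reference"` in `ga_config()`) implement the identical loop; the
reference engine is built from the exported operator functions and exists so
the compiled inner loop can be cross-checked at small $n$. Their RNG draw
*order* differs, so for a given seed they agree in distribution and in the
properties that matter (bounds, determinism, oracle agreement), not bitwise.

#### Population sizing

The default population is 20 chromosomes, which suffices below roughly 30
points; `population_size_for()` implements the published schedule for larger
random clouds (100 up to 50 points, 1000 up to 100, 10000 up to 200, and
beyond that upwards of 100000 with a runtime warning). Expression profiles
rarely exceed 50 time points, where 100 individuals are enough; the schedule
is advisory and not applied implicitly, because the default of 20 is part of
the engine's stated operating conditions.

## The synthetic test-bed

Real expression compendia are large, external and noisy in uncontrolled
ways, so the package validates itself on a synthetic generator instead.
`generate_relationship()` draws from 14 registered families: trigonometric
(sine, tangent), power ($y = x^2$), exponential ($y = 10^x$), inverse
proportion ($y = 1/x$), a composite ($y = x \sin x$), a polygonal zigzag
line, and seven non-functional figures — taijitu, a two-armed galaxy spiral,
a heart curve, circle, ellipse, cross, and two intersecting lines. The last
four complete the set of fourteen and are standard non-functional test
shapes; they, and the parametrizations of the named figures, are
reconstructions chosen once, not transcriptions of the original drawings.

Noise grades 1–3 add centered Gaussian noise with standard deviation 5%,
15% and 30% of the coordinate range — to $y$ for function families, to both
axes for figure families (whose shapes have no privileged axis). The grades
are strictly increasing by construction, which is the precondition for the
noise-discrimination property the validation suite checks: the median SG MIC
should fall strictly as the grade rises, family by family.

What passing these tests does *not* show about real data: the generator
produces i.i.d. points with homoscedastic Gaussian noise and tie-free
continuous values. Real expression profiles are short autocorrelated time
series with heteroscedastic, occasionally heavy-tailed noise, batch
structure, and ties from quantization. The rank transform removes marginal
distribution effects, but tie-breaking by index means heavily tied profiles
get an arbitrary (if deterministic) within-tie order, and nothing here
validates behavior under missingness — the batch reader simply drops
incomplete rows.

## Validation protocol and problem sizes

The test suite exercises the scientific claims at these scales, chosen so
the whole protocol runs comfortably on a laptop core:

* oracle agreement: 50 seeded uniform clouds at $n = 8$, SG (defaults)
  vs exhaustive, equality within $10^{-12}$ required in at least 95% of
  runs;
* dominance: 100 clouds at $n = 8$, `equiy <= exhaustive` and
  `sg <= exhaustive` on every single sample;
* the cluster-split fixture: strict equipartition gap, SG recovering the
  exhaustive optimum;
* exact perfection: strictly monotone noiseless samples at
  $n \in \{10, 20, 50\}$ must score exactly 1.0 (even $n$ makes the
  balanced $2 \times 2$ information exactly 1 bit in floating point);
* noise discrimination: median SG MIC over 10 seeds at $n = 200$, strictly
  decreasing across the four noise grades in at least 12 of 14 families;
* null calibration: 100 clouds per size at $n \in \{25, 50, 100\}$,
  exponents 0.6 vs 0.95 as described above;
* enumeration self-check: the bitmask engine against an independently
  coded recursive enumerator, exact agreement on 100 samples at
  $n \le 8$;
* distributional unit checks: Metropolis acceptance at
  $(\Delta, T) = (-0.05, 0.05)$ against $e^{-1}$, the exact rank-sum
  p-value $2/20$ for complete 3-vs-3 separation, and MIC invariance under
  strictly increasing transforms.

`scripts/acceptance.R` recomputes the headline quantities of this protocol
from scratch at an arbitrary seed and writes them as JSON.

## Numerical choices and degenerate inputs

* Logs are base 2 throughout; mutual information is reported in bits.
* $0 \log 0 = 0$ in the MI sum; empty cells contribute nothing.
* The normalized score is clamped to $[0, 1]$ only against floating error,
  never by more than $10^{-9}$; a larger excess raises an error rather than
  hiding a bug.
* Maximization ties are broken by the first grid encountered in the fixed
  loop order (exhaustive, baseline) or by the first shape in lexicographic
  order (SG), for bit-reproducibility.
* A gene with no room to move stays put; mutation never changes gene
  counts; crossover repairs duplicates rather than shrinking an axis.
* `wilcox.test` supplies the rank-sum p-value: exact enumeration when the
  pooled length is at most 20 with no ties, the tie-corrected normal
  approximation with continuity correction otherwise. A rank-sum test
  compares the two profiles' distributions, which is an unusual surrogate
  for independence; it is provided as specified, and
  `mic_permutation_pvalue()` offers a direct permutation test on the MIC
  statistic as a clearly-labelled extension (off by default in batch
  output).

## Known limitations

* The exhaustive oracle is exponential and capped at 18 points by default;
  above that, SG's answer has no same-sample certificate, only the
  statistical evidence of the oracle-agreement protocol at small $n$.
* SG is a stochastic search: a single run with an unlucky seed can stall
  below the optimum (the protocol's 95% bar is a property of the ensemble,
  not of each run). Raising `max_generations` or the population size never
  lowers the result.
* At the published population schedule, samples beyond a few hundred points
  are expensive; that is intrinsic to the method's search space, not to
  this implementation.
* The budget floor of 4 means that for $n \le 10$ all engines effectively
  compare $2 \times 2$ grids only.
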