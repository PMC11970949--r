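---
title: "Finding multiple optima of integer programs by objective perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding multiple optima of integer programs by objective perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morseopt)
```

## The problem

Integer linear programs (ILPs) routinely have several distinct optimal
solutions, and in applications such as gene-target selection the *set* of
optima carries more information than any single one: two equally small gene
panels may differ greatly in druggability, prior evidence, or off-target
risk. Deterministic solvers, however, return one optimum — usually the same
one on every call — and solution-pool mechanisms tend to return near-copies
that differ only in constraint-only bookkeeping variables.

`morseopt` implements the MORSE approach: solve many independent, randomly
*perturbed* copies of the instance, where the perturbation is small enough
that **every optimum of a perturbed copy is an optimum of the original**,
but large enough to break ties differently on every draw. Each run is
embarrassingly parallel and returns one verified optimum; aggregating runs
yields a growing set of distinct optima together with diversity metrics.

## The perturbation and the radius ε

Let the objective be $\sum_i c_i x_i$. For each binary/integer objective
variable we draw an independent multiplier

$$v_i \sim U(1-\varepsilon,\; 1+\varepsilon)$$

and solve the instance with coefficients $c_i v_i$ (continuous variables
are never perturbed). Constraints, bounds, and sense are untouched, so
feasibility is unchanged; only tie-breaking among optima is affected.

The radius is chosen per instance. With

$$S = \sum_i |c_i| \cdot \max(|lb(x_i)|, |ub(x_i)|)$$

over the binary/integer objective variables (continuous variables
contribute 0), the package sets

$$\varepsilon = \frac{1}{2S}.$$

The rationale: when all perturbable coefficients are integers and the
variables are integral, any two solutions with different objective values
differ by at least 1, while the perturbation moves any feasible solution's
value by at most $\varepsilon S = 1/2$. A perturbed-optimal solution that
was not originally optimal would need a swing of more than 1 — impossible.
So optima are *preserved*: the perturbed argmin is always an original
argmin. The rule is scale-covariant: multiplying all coefficients by $k>0$
divides $\varepsilon$ by $k$ (`choose_epsilon` reproduces 0.025, 0.005 and
0.125 on the worked three-variable example and its two rescalings).

```{r}
fx <- toy_fixtures()
choose_epsilon(fx$eps_example)
choose_epsilon(fx$eps_example_div5)$epsilon
```

**Fractional coefficients.** The tie gap of 1 assumes integral
coefficients. `integer_scaling_factor` computes the least $L$ with $L c$
integral (exact continued-fraction rationals, denominator capped at
`max_denominator = 1e6`). Because the perturbation is *multiplicative*,
rescaling the objective by $L$ changes neither the feasible set nor which
perturbed solutions win, so the package reports $L$ in the
`epsilon_report` and keeps $\varepsilon = 1/(2S)$ on the coefficients as
given — this is the radius that the worked scaling examples pin down. The
report notes, when $L > 1$, that the conservative radius under which the
tie-gap argument applies verbatim to the integralized objective is
$\varepsilon / L$; users who need the formal guarantee for fractional
coefficients can pass that value to `run_batch(..., epsilon = )`.
Verification (below) covers the gap in practice.

**Fallbacks.** If an integral objective variable has an infinite bound,
$S$ is unavailable; the package then solves the instance once and
substitutes the reference optimum's $|x_i|$ for the bound weight, with a
0.999 safety factor to keep the strict inequality the argument needs
($\varepsilon = 0.999/(2S')$). If $S = 0$ (all counted terms vanish) the
radius defaults to 0.01, a practical value for selection problems whose
optima contain well under 100 selected items. Radii below $10^{-12}$
trigger a warning, since solver tolerances would swallow the perturbation.

## Solving and verification

No LP/MIP backend ships with this package's dependency stack, so the
package carries its own solver: a dense two-phase tableau simplex with
general variable bounds (shift/mirror/split transforms, Bland-rule
fallback against cycling) and a depth-first branch-and-bound with
most-fractional branching. It proves optimality by exhausting the search
tree and is sized for the tens-of-variables instances this package
targets. The solver's seed randomizes branching tie-breaks and child
order: on instances with tied optima, different seeds surface different
optima, which is exactly the role the random-generator seed plays in the
homogeneous-weights baseline (`mode = "uniform"`). The adapter surface —
a `backend` argument recorded in every run record — leaves room for
plugging in external solvers.

Every run evaluates its solution under the *original* objective and
verifies it: feasibility within $10^{-6}$ (relative, row-scaled) and
agreement of the original-objective value with the reference optimum
within $10^{-6}$ relative. For pure-integer instances with integral
coefficients this is an audit of a guarantee; with continuous variables it
is mandatory, because infinitesimally close objective values make
preservation impossible to guarantee. Failed verifications are recorded
(`verified_optimal = FALSE`) and can optionally be resampled with a fresh
derived seed.

The test suite cross-validates the solver three ways: against `boot`'s
textbook simplex on the nonnegative-LP configurations where that routine
is sound, against exhaustive lattice enumeration on random ILPs, and
against the HiGHS solver behind `scipy.optimize.milp` in one batched
call to the `python` interpreter present in the environment.

## The all-optima oracle

`enumerate_all_optima` provides ground truth. The `exhaustive` strategy
scans every lattice point of the bound box (capped at `limit` points) and
keeps the full argmin/argmax set. The `cuts` strategy repeatedly solves
and excludes the found key with a *no-good cut*: for binary variables the
classical row $\sum_{j: v_j=0} x_j + \sum_{j: v_j=1}(1-x_j) \ge 1$; for
bounded general integers, auxiliary "deviate up"/"deviate down" binaries
force $x_j \ge v_j+1$ or $x_j \le v_j-1$, and the cut requires at least
one deviation. Enumeration stops when the augmented instance becomes
infeasible or its optimum degrades. The two strategies are verified to
agree across a mixed corpus; keys are always formed over
objective-function variables only, so solutions differing only in
constraint-only variables are the same optimum.

## Diversity metrics

* `hamming` counts differing coordinates (magnitude ignored).
* `avg_pairwise_hamming_curve` reports, for each prefix of an ordered
  solution list, the mean pairwise distance normalized by the *total
  binary solution size*. That phrase is interpreted here as the number of
  binary/integer objective variables, and it is exposed as the
  `normalizer` parameter precisely because the interpretation is a
  convention.
* `entropy_multiset` is the Shannon entropy $-\sum_x p_x \log_2 p_x$ of
  the empirical solution frequencies, computed over the list *with*
  repetitions and never normalized by the number of distinct solutions
  (0.918, 1.585 and 1.459 bits on the three reference examples).
* `avg_variable_entropy` averages per-variable value entropies across the
  sampled list; constant variables contribute 0.

Solutions are ordered three ways before curve computation: `seed_based`
(the reproducible default), `random_shuffle`, and `greedy_diversity`
(random first pick, then repeatedly the candidate maximizing average
distance to the selection; ties resolved by earliest seed order;
duplicate keys participate as separate entries).

## Equal-probability sampling — exactly where it holds

For unit-coefficient selection (0/1 minimization) problems, all optima
select exactly $d$ items, and a perturbed run returns the feasible
$d$-set with the smallest sum of perturbed coefficients. When the family
of optimal $d$-sets is *exchangeable* — some permutation of elements maps
any optimum to any other while mapping the family onto itself, as for
instances whose optima are independent one-per-pool choices from disjoint
pools — symmetry of the i.i.d. multipliers makes every optimum equally
likely. The package's uniformity suite (`uniformity_chisq`,
$\chi^2$ goodness of fit, expected counts kept $\ge 5$) confirms this on
such designs with 2–6 oracle-verified optima.

The property **fails for asymmetrically overlapping optima**, and the
package documents this deliberately rather than asserting uniformity in
general. With covering sets $\{e_1,e_2\}, \{e_3,e_4\}, \{e_1,e_4\}$ the
three minimum hitting sets $\{e_1,e_3\}, \{e_1,e_4\}, \{e_2,e_4\}$ are
sampled with exact probabilities $3/8, 1/4, 3/8$: the middle optimum wins
only when $p_4 < p_3$ *and* $p_1 < p_2$, two independent coin flips. A
permutation of multipliers mapping one optimum onto another does not keep
the *competing* sets feasible, so the symmetry argument breaks. The test
suite checks the observed frequencies against these exact values — and
checks that a uniformity test decisively rejects. Practically: the method
still finds every optimum with positive probability, but sampling can be
biased toward optima that overlap fewer alternatives.

## Synthetic gene-target instances

`generate_selection_instance` draws random covering families (each
element included in a set with probability `density`; empty sets
redrawn). `generate_cellmatrix_instance` emulates the single-cell
gene-target setting: per patient, binary gene-by-cell expression matrices
are drawn i.i.d. at `expression_probability`; a cell is killed iff it
expresses a selected gene; per-patient constraints require killing at
least `ceiling(lb * n_tumor)` tumor cells and at most
`floor(ub * n_healthy)` healthy cells, linearized with one binary kill
indicator per cell (constraint-only, so they never affect solution
identity). Defaults in tests use a handful of patients with tens of
cells and expression probability around 0.3 — large enough to produce
multiple overlapping optima, small enough for the exhaustive oracle.

What these generators deliberately do not emulate: correlated gene
expression across cells, dropout noise, patient heterogeneity in
expression probability, and the cohort-level second optimization layer
(re-using targets across patients) of the real application — the model
here is single-layer per-cohort. Passing tests therefore show the
*optimization* behaviour is right, not that biological expression
structure is captured.

## Numerical choices and test problem sizes

* Canonical solution keys: integral variables rounded to the nearest
  integer, continuous objective variables to 6 decimals.
* LP pivot tolerance $10^{-9}$; feasibility threshold
  $10^{-7}$ (row-scaled); branch-and-bound integrality tolerance
  $10^{-6}$; node limit $10^5$.
* Rational approximation for $L$: continued fractions, denominators up
  to $10^6$, least common multiples kept in exact double range.
* Degenerate inputs: empty objectives are rejected by screening;
  `epsilon = 0` is the identity draw; infeasible covering rows yield an
  infeasible census rather than an error.
* The statistical suites run at: 200 random integer ILPs × 20 runs
  (optimum preservation; zero violations required), 20 replicates of
  $200m$ runs on selection designs with $m = 2..6$ optima (uniformity,
  $\alpha = 0.001$, at most 1 rejection), ~25-instance oracle
  cross-validation corpora, and 20 paired 30-run comparisons against the
  uniform-weights baseline. These sizes are the package's chosen test
  conditions; all corpora are generated in code from fixed seeds.

## Limitations

* The solver is exact but dense and single-threaded; it is not intended
  for large MIPLIB-scale instances. Supplying an external backend is the
  intended route there.
* Optimum preservation is guaranteed only for integral variables with
  integral (or integralizable) coefficients; with continuous objective
  variables the package verifies instead of guaranteeing.
* Equal-probability sampling holds exactly only under exchangeable
  optimal-set structure (see above); expect bias when optima overlap
  asymmetrically.
* The number of runs needed to collect all $m$ optima grows like
  $m \log m$ under uniform sampling (coupon collecting, confirmed in the
  test suite) and can be worse under biased sampling.
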