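---
title: "Quadratic descriptors: models, selection, and feature-space inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadratic descriptors: models, selection, and feature-space inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The modelling problem

Quantitative structure–activity/property models (QSAR/QSPR) predict a
chemical property $a(C)$ of a compound $C$ from a vector of graph-theoretic
*linear descriptors* $x(1), \dots, x(K_1)$ — frequency-type counts of local
structural features. Linear models over such descriptors are attractive
because they can be *inverted*: a linear prediction function embeds directly
into a mixed-integer linear program (MILP) that searches for descriptor
vectors attaining a target property range, the first step of inverse QSAR.

Purely linear models, however, underfit many properties. This package
implements a middle road: augment the linear descriptors with *quadratic*
interaction terms while keeping the model linear in its coefficients, so
that prediction stays a hyperplane and inversion stays a MILP.

After min–max normalization of each descriptor (and of the property) into
$[0, 1]$, the quadratic universe over $K_1$ linear descriptors is

$$D^{(2)} = \{\, x(i)\,x(j) : 1 \le i \le j \le K_1 \,\} \cup
           \{\, x(i)\,(1 - x(j)) : 1 \le i, j \le K_1 \,\},$$

of size $(3K_1^2 + K_1)/2$, giving $K_1 + (3K_1^2 + K_1)/2$ candidate
descriptors in total. Squares ($i = j$) are included in both families.
`descriptor_universe(K1)` enumerates the universe in a canonical order
(linear, then products by $(i,j)$, then complement-products by $(i,j)$).

Two consequences of this construction matter throughout:

* **Boundedness.** On normalized inputs every quadratic descriptor lies in
  $[0, 1]$; the package deliberately does *not* re-normalize quadratic
  columns (they are already on the common scale, and re-normalizing would
  break the algebra the MILP inversion relies on).
* **Exact collinearity.** $x(i) = x(i)x(j) + x(i)(1-x(j))$ holds
  identically, so the universe is rank-deficient *by design*. Model fits
  must tolerate this (see "Numerical choices"), and "recovering a planted
  support" can only ever mean recovery up to this equivalence (see
  "What the synthetic generator shows").

## Descriptor selection

With $O(K_1^2)$ candidates, fitting everything invites overfitting and
makes inversion hopeless; the package implements a three-stage reduction.

**Randomized lasso reduction** (`llr_reduce()`). While the candidate set is
larger than a target size $\tilde K$ (default 5000), it is partitioned into
random blocks of at most $d_{\max} = 200$ descriptors; each block is fitted
by lasso on a random subsample of at most $c_{\max} = 200$ compounds, and
only the support (nonzero weights, with $|w| \le 10^{-6}$ snapped to zero)
survives. If the final pass undershoots $\tilde K$, the set is padded back
from the previous iterate by a K-best univariate filter — we rank candidate
keys by the absolute Pearson correlation of their evaluated column with the
property on the full table, a standard, cheap and deterministic choice for
a filter the procedure's description names but does not define. If a full
pass removes nothing while the set is still too large (which happens when
the penalty is too small to shrink), the same K-best filter truncates
directly, with a warning.

**Backward stepwise elimination** (`bs_reduce()`). The workhorse score is
$g_p(S)$: the median test-fold coefficient of determination $R^2$ of an
ordinary least-squares fit over descriptor set $S$, across $p$ independent
rounds of 5-fold cross-validation. Starting from the full set, the
procedure repeatedly deletes the single descriptor whose removal maximizes
$g_p$, and finally returns the best-scoring set seen anywhere along the
path (never worse than the starting set, by construction). All $g_p$
evaluations share one seeded family of fold assignments, so subset scores
are comparable; ties break on the first candidate in canonical order,
making the whole procedure deterministic given the seed.

**Penalty-tuned selection** (`select_des_set()`). A grid $A$ of 17 lasso
penalties ($0, 10^{-6}, \dots, 100$) is scanned; each support is scored by
$g_{p_1}$ and the best penalty $\lambda_{best}$ is refined over 16 nearby
values. The refinement set $B(\lambda)$ is described only as "close to"
each grid value; we use 16 geometrically spaced values in
$[\lambda_{best}/4,\, 4\lambda_{best}]$ (linearly spaced in $[0, 10^{-6}]$
when $\lambda_{best} = 0$) — a symmetric local refinement on the log scale
the grid itself lives on. Each refined support is capped at
$s_{\max} = \lfloor 150 + 10^4 / (|C| + 200) \rfloor$ keys by largest
$|w|$, reduced by backward stepwise elimination with $p_2$ rounds, and
scored with $p_3$ rounds; the best candidate wins. Defaults
$p_1 = p_2 = p_3 = 5$.

`run_train()` chains the stages: normalize, expand, reduce to 5000 when the
universe is larger (it is not for $K_1 \le 57$), select, fit the final
multi-linear model, and score it with the reporting protocol — the median
of the 50 test $R^2$ values from 10 rounds of 5-fold cross-validation
(`final_evaluation()`).

## Inverting the model: the product gadget

A trained hyperplane $\eta(x) = b + \sum_d w(d)\, v_d(x)$ is inverted by a
MILP over the normalized descriptor box $[0,1]^{K_1}$: find $x^*$ with
$y_* \le \eta(x^*) \le \bar y^*$, subject to optional per-descriptor
bounds, integrality of count-valued raw descriptors, and linear side
constraints. Linear terms are trivial; each quadratic term $z = x y$ needs
linearization, done by a $p$-bit binary-expansion gadget:

* binaries $\chi_0, \dots, \chi_p$ bracket the quantized first factor:
  $\sum_j 2^j \chi_j - 1 \le (2^{p+1}-1)\,x \le \sum_j 2^j \chi_j$;
* continuous $z_j \in [0,1]$ pick up the second factor bit-wise:
  $z_j \le \chi_j$ and $y - (1-\chi_j) \le z_j \le y + (1-\chi_j)$;
* the output is $z = \sum_j 2^j z_j / (2^{p+1}-1)$.

For every feasible assignment, $xy \le z \le xy + 1/(2^{p+1}-1)$: the
gadget *over*-approximates by at most one quantization step, $1/127
\approx 0.8\%$ at the default $p = 6$. (The construction uses $p+1$
binaries, $j \in [0, p]$.) The package treats this bound as an absolute
deviation on the unit interval, where absolute and relative coincide.
`gadget_feasible_z()` verifies the bracket without a solver by enumerating
bit patterns against the emitted constraint rows; the test suite and the
acceptance script scan dense grids and random samples with it.

Two asymmetries are worth recording. The construction quantizes one factor
and leaves the other continuous; the package quantizes the *first* index of
a quadratic key (for complement keys, the continuous factor is the affine
$1 - x(j)$). The error bound is identical either way. And because the
gadget only errs upward, a feasible MILP solution satisfies the target
range in its internal $\eta$, while the exact re-evaluation
$\eta(x^*)$ can undershoot $y_*$ by at most
$\sum_q \max(w_q, 0)/127$ and overshoot $\bar y^*$ by at most
$\sum_q \max(-w_q, 0)/127$ — `solve_inverse()` reports both slacks.

Solving goes through a subprocess contract: the model is serialized and
handed to a branch-and-bound solver (the bundled backend uses the HiGHS
solver via `scipy.optimize.milp`), and variable assignments are parsed
back. `write_lp()` exports the same model in CPLEX-LP format for use with
any other solver. The default solver time limit is 300 s.

## Neighbor solutions

Around a solved inverse instance $x^\dagger$, `neighbor_search()` explores
a two-dimensional grid defined by two auxiliary prediction functions
$\theta_1, \theta_2$ (typically models of *other* properties over the same
descriptor space). The solution maps to the grid origin; cell
$g = (g_1, g_2) \in \{-3..3\}^2 \setminus \{0\}$ adds the constraints
$\theta_k(x) - \theta_k(x^\dagger) \in
[(g_k - \tfrac12)\,\delta R_k,\ (g_k + \tfrac12)\,\delta R_k]$, where
$R_k$ is the observed range of $\theta_k$ on the training table and
$\delta$ (0.1 or 0.05) is the grid step. The 48 cells are checked in
non-decreasing Euclidean distance (ties lexicographic), each with the
solver time limit, and every cell ends in exactly one of four states:
solution, infeasible, ignored, or timeout.

The *ignore* rule skips a cell when a strictly closer infeasible cell lies
on the same ray from the origin ($g = c\,g'$, integer $c \ge 2$). A
literal "ignore everything farther than any infeasible neighbor" rule
would let one near infeasibility wipe out nearly the whole grid, which
contradicts observed accounting patterns where a single infeasible cell
coexists with many solved ones; the ray rule preserves the monotonicity
intuition (feasible regions are star-shaped along the constraint
direction) without that collapse. By default all 48 cells are solved in
one batched solver call and the ignore rule is applied afterwards in
distance order — ignored cells never contribute infeasibility, so the
statuses equal those of sequential checking; only wall-clock is traded.

## What the synthetic generator emulates — and what it does not

`planted_model()` / `gen_table()` produce count-valued descriptor tables
(integer counts, uniform on $[0, 20]$ by default, mirroring the
frequency-type descriptors of real feature extractions) with a response
that is an intercept plus a sparse linear combination of *normalized*
descriptor values over a planted support of linear and quadratic keys,
plus homoscedastic Gaussian noise. Defaults used across the tests: five
planted terms with weights of magnitude 0.6–1.2, intercept 0.2, noise sd
0.01, $n = 300$ compounds, $K_1 = 30$ — a regime where the signal is
clearly identifiable yet the candidate universe (1395 descriptors) is much
larger than the sample.

What passing tests on such data do show: the selection machinery finds a
descriptor set that represents the planted signal essentially exactly, the
final model generalizes (median CV test $R^2 \ge 0.95$), and inversion
round-trips. What they do not show: behaviour under the skewed, heavily
dependent descriptor distributions of real chemical datasets, under
heteroscedastic or structured noise, or at the descriptor dimensionalities
($K_1$ in the hundreds) where the randomized lasso reduction stage carries
the load. Conclusions about real chemical data require real tables.

Because of the exact identity $x_i = x_i x_j + x_i(1-x_j)$, "support
recovery" is defined as *span* recovery (`support_spanned()`): every
planted descriptor column must lie in the span of the selected columns
plus intercept (relative projection residual below $10^{-6}$). Literal
key-identity recovery is not a well-posed target in this universe.

The toy-molecule layer (`toy_molecule()`, `eligibility_filter()`)
implements the dataset-eligibility rules — connected heavy-atom graph, at
least four carbons, at most four non-hydrogen neighbors per atom — on a
minimal multigraph representation; distinct neighbors are counted once
regardless of bond order. SMILES/SDF ingestion is delegated to
ChemmineR/ChemmineOB when available.

## Numerical choices

* **Lasso.** `fit_lasso()` uses the common $1/(2n)$ objective scaling
  (glmnet's convention). Fits warm-start along a descending geometric
  penalty path ending exactly at the requested $\lambda$; a single-column
  problem uses the closed-form soft-threshold solution, and $\lambda = 0$
  falls back to (minimum-norm) least squares. The $10^{-6}$ zero-snap is
  applied to fitted weights regardless of scaling.
* **Least squares under collinearity.** `fit_mlr()` and the
  cross-validation kernel solve the normal equations by Cholesky and fall
  back to the pseudoinverse (minimum-norm solution) when the Gram matrix
  is singular — routine here, given the universe's built-in collinearity.
  The kernel is compiled (RcppArmadillo) because backward stepwise
  elimination evaluates $g_p$ $O(|D|^2)$ times; $g_p$ values are also
  memoised per (subset, seed).
* **$R^2$ on a test fold** uses the test-fold mean in the denominator;
  folds with zero test variance are skipped. Scores can be negative and
  never exceed 1.
* **Fold assignment** is a uniformly random near-equal partition per
  round, seeded deterministically from (base seed, round index); no
  stratification.
* **Degenerate (constant) descriptor columns** normalize to 0, are
  excluded from quadratic expansion, and are pinned to 0 in the inversion
  box. Test-table values outside the training range are *not* clipped —
  clipping would silently distort test $R^2$.
* **Ties** (penalty scan, stepwise removal, final candidate) break on the
  first occurrence in canonical order, keeping every stage deterministic
  given its seed.
* **Problem sizes in the checks.** The bundled verification runs use
  $n \le 300$, $K_1 \le 30$, dense gadget grids up to $201 \times 201$,
  20-model inversion batches and 48-cell neighbor grids — sizes chosen so
  the whole battery reruns comfortably on a laptop while still exercising
  every code path at the documented defaults.

## Known limitations

* The inversion operates purely in descriptor space: it returns a
  descriptor vector, not a molecule, and nothing guarantees a molecule
  realizing that vector exists. Graph reconstruction (topological
  specifications, seed graphs) is out of scope.
* The randomized lasso reduction at a very small fixed penalty can stall
  (lasso keeps almost everything); the K-best fallback then decides, and
  the run warns. Choosing the block penalty adaptively is future work.
* Backward stepwise elimination is quadratic in the capped support size;
  $s_{\max}$ keeps it tractable but a support at the cap is the dominant
  cost of `select_des_set()`.
* The neighbor-cell construction relies on the two auxiliary hyperplanes
  being meaningfully different directions; nearly parallel
  $\theta_1, \theta_2$ make cells thin and mostly infeasible.
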