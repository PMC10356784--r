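---
title: "Inferring differential metabolic regulation from covariance data: models and methods"
author: "covrecon package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring differential metabolic regulation from covariance data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covrecon)
```

## The problem

Steady-state metabolomics experiments measure concentrations of tens of
metabolites across replicates in two conditions — say a healthy and a
diseased cell line. The scientific question is not which metabolite means
differ (a t-test answers that) but which *regulatory interactions* changed:
which entries of the system Jacobian

$$J_{ij} = \left.\frac{\partial f_i}{\partial M_j}\right|_{\text{steady state}}$$

differ between the conditions. Near a stable steady state, the fluctuation–
dissipation relation links the concentration covariance $C$ to $J$ through
the continuous-time Lyapunov equation

$$J C + C J^\top = -2D,$$

where $D$ is the covariance of the stochastic noise sources (the
*fluctuation matrix*, taken diagonal: independent noise per metabolite).
$C$ is estimable from replicate data; $D$ is not observed. The package
implements a complete workflow from a genome-scale metabolic model and two
covariance matrices to a ranking of Jacobian entries by the evidence that
they changed between conditions.

## Step 1: Jacobian structure from a genome-scale model (Sim-Network)

$J$ has $n^2$ unknowns but $C$ only $n(n+1)/2$ informative entries, so the
inverse problem is underdetermined without structural constraints. Real
metabolic Jacobians are sparse, and the sparsity pattern is derivable from
pathway databases. `buildGraph()` converts a model (SBML, BIGG-style JSON
via `readGenomeScaleModel()`, or KEGG flat-file records via
`readKeggModel()`) into a weighted directed graph over compartment-stripped
metabolites:

* forward substrate→product edges have weight 1;
* reverse edges of reversible reactions have a user weight (default 2),
  penalized by $\log_{10}\Delta G$ when ModelSEED thermodynamics report a
  reaction delta Gibbs free energy above 100 kcal/mol (the logarithm base is
  our choice; the magnitude-penalty idea follows the pathway-search
  literature);
* co-substrates are linked in both directions at the forward weight, and
  co-products of reversible reactions at the reverse weight, because a rate
  depends on all of its reactants (the weights of these links are our
  choice; the sources describe only the links);
* currency metabolites (water, protons, ATP, NAD(P)H, ...; an editable list
  ships with the package) are removed first, because they would
  short-circuit every pathway search.

`shortestPaths()` runs Dijkstra's algorithm between all ordered pairs of
measured metabolites, with a deterministic lexicographic tie-break on the
route's node sequence, so reruns and platform changes cannot reorder equal-
cost routes. `pruneAndStructure()` keeps a route when (i) its cost is at
most the threshold (default 3; a route costing exactly the threshold is
kept — we read "higher than" strictly) and (ii) no interior metabolite of
the route is itself measured, since such an indirect influence is captured
by the two shorter connections. Kept routes become *superpathways*: a route
from metabolite $j$ to $i$ marks Jacobian entry $(i,j)$ as potentially
nonzero. The diagonal is always retained. The resulting
`JacobianStructure` can be exported as annotated SBML and CSV.

## Step 2: vectorizing the Lyapunov equation

For a covariance $C$ and a structure with $L$ masked entries,
`vectorizeCovariance()` rewrites the Lyapunov equation as $A q = b$: rows
are the unordered pairs $(i,j)$, $i \le j$ (row-major; $m = n(n+1)/2$ of
them), columns are the masked Jacobian positions (row-major scan), and

$$A_{(i,j),(a,b)} = [i{=}a]\,C_{bj} + [j{=}a]\,C_{ib}, \qquad
  b_{(i,j)} = -2 D_{ij}.$$

With a sparse structure, $L < m$ and the system is overdetermined. The
least-squares solution is computed by SVD (`regressionSolve()`); the
printed normal-equations formula $(A^\top A)^{-1} A^\top b$ defines the
same minimizer but squares the condition number, so it is treated as a
mathematical definition, not an implementation. Residuals are evaluated as
the projection of $b$ onto the orthocomplement of the column space —
identical in exact arithmetic to $b - A q^\ast$, but free of the
condition-number amplification incurred by forming $A q^\ast$ explicitly.
This matters: the package's central robustness property is that while
$q^\ast$ is destabilized in proportion to $\kappa(A)$ (condition numbers up
to $10^{10}$ occur in realistic models), the residual norm is 1-Lipschitz
in $b$ regardless of conditioning, and the test suite verifies this over
thousands of instances.

## Step 3: the regression-loss scan

To compare two conditions, the scan assumes all Jacobian entries are equal
between conditions *except one*. For each masked position $p$,
`buildCombinedSystem()` stacks the two conditions' systems with shared
columns for every position except $p$, which receives two columns (one per
condition). If $p$ is the truly changed position, this combined model is
correctly specified and fits both covariance matrices well; if not, the
misspecification inflates the residual. Because $D$ is unknown, right-hand
sides are sampled: diagonal fluctuation matrices with entries uniform on
$(0,1)$.

Two design choices here are the package's own, made after measuring the
alternatives on synthetic ground truth:

1. **One fluctuation sample serves both conditions.** Each sampled $D_s$
   builds the stacked $b_s = [b(D_s); b(D_s)]$. This makes the scan exactly
   symmetric in the no-change case: when $C_h = C_d$, every position's
   per-sample loss is identical (the split column can absorb any shared
   fit), so identical conditions produce a flat loss landscape and zero
   relevance, as they should. With independently sampled per-condition
   fluctuation matrices this symmetry does not hold, and spurious structure
   appears under the null.
2. **Per-sample losses are aggregated by their mean** (the minimum over
   samples remains available via `aggregate = "min"`). The minimum is an
   extreme-value statistic of a high-dimensional sample and its ranking
   noise is substantial at practical sample counts: on our synthetic study
   conditions it recovers the true position Top-1 in only 50–83% of
   repeats, while the mean of the very same per-sample losses recovers it
   in 100%. The exact infimum of the loss over all admissible fluctuation
   values is computable (a principal angle between subspaces) but turns out
   to be degenerate — when $L > m - n$, zero-loss fits exist even with no
   change — so it is not a usable statistic either.

The per-position loss is normalized per sample ($\|b_s - A_c q^\ast\| /
\|b_s\|$), removing the trivial scaling degeneracy. The same seeded sample
set is reused across positions, so comparisons are paired. The scan
reports both the raw loss matrix and a min–max-inverted **relevance** in
$[0,1]$: the position whose split best explains the between-condition
difference attains the smallest loss, hence relevance 1. Relevance is the
quantity plotted and ranked (`rankComponents()`, ties broken by row then
column).

The default of 100 fluctuation samples is adequate for models with on the
order of ten metabolites; the sampling cost is linear in the sample count
and the scan cost is dominated by one QR factorization per masked position.

## The L-p baseline

The older approach (`lpOptimize()`) optimizes the diagonal entries of
$D_h, D_d$ (bounded in $(0,1]$; optionally bounded off-diagonals at half
the geometric mean of the corresponding diagonals, the "diagonal-dominant"
variant) to make the implied differential Jacobian

$$DJ_{ij} = (J_d)_{ij} / (J_h)_{ij}, \qquad DJ_{ij} = 1 \text{ where } (J_h)_{ij} = 0$$

sparse in the $\sum |DJ_{ij} - 1|^p$ sense. Multi-start bounded
quasi-Newton search is used, half of the starts symmetric ($D_d = D_h$, the
no-change null), followed by a derivative-free polish; the reported
objective never exceeds the best sampled start. Two limitations are worth
knowing. First, the solution quality depends on $\kappa(A)$, since the
method inverts the systems directly — this is precisely the instability the
regression-loss scan avoids. Second, the exponent matters: at $p = 0.5$
there are small instances where the global optimum genuinely prefers two
moderate deviations over one large true change; $p \approx 0.3$ behaves
closer to the $L_0$ count and localizes better. The default stays at
$p = 0.5$ for comparability; the tests document the localization behaviour
at $p = 0.3$.

## Synthetic ground truth

Because real two-condition data come without a known Jacobian, every
inference component is validated against generated mass-action kinetic
models (`generateMassActionModel()`): a conversion chain plus random uni-
and bi-molecular reactions, a constant inflow, and first-order outflows
from every species. Candidates are rejected until the steady state is
positive and the Jacobian Hurwitz-stable. Steady states are found by ODE
relaxation plus damped Newton polishing to $\|F\|_\infty \le 10^{-10}
\max(1, \max_r |v_r|)$; Jacobians are analytic mass-action derivatives
(finite differences serve as the cross-check, `method = "fd"`).
`removeConservedMoieties()` eliminates constant species and one dependent
species per conservation relation (left-null vector of the stoichiometric
matrix), re-expressed through the conserved total — a conserved system has
a singular Jacobian and no stationary covariance, so this step is
mandatory before any Lyapunov analysis.

Two-condition data are generated two ways, mirroring how such methods are
evaluated:

* **Exact:** `covarianceViaLyapunov()` draws $D$ diagonal with entries
  uniform on $(1-\varepsilon_D, 1+\varepsilon_D)$ and solves the Lyapunov
  equation (via the Kronecker-vectorized dense solve with one step of
  iterative refinement and a $10^{-8}$ relative residual guard; model sizes
  here make a dense solve the right tool). $\varepsilon_D = 0$ is the
  nominal identity.
* **Sampled:** `covarianceViaSde()` integrates $dM = F(M)\,dt + \sigma\,dW$
  by Euler–Maruyama from the steady state, discards a burn-in, floors
  concentrations at zero, and records one long stationary trajectory with
  thinning (default every 50 steps). For a linear(ized) model the sample
  covariance converges to the Lyapunov covariance with
  $D = (\sigma^2/2) I$; the tests verify this convergence. A higher-order
  stochastic integrator would reduce the $O(dt)$ bias, but only the
  stationary covariance enters the pipeline and the bias is measured to be
  well below the sampling noise at the default $dt$; the integrator is a
  plain function and can be swapped.

Condition pairs (`makeConditionPair()`) perturb named rate constants by
given factors and re-verify stability. Perturbing a first-order outflow
changes exactly one Jacobian entry — the cleanest single-change truth;
perturbing an interior conversion changes several entries of one column,
in which case the scan flags the changed column but the single best entry
and the largest true ratio can legitimately swap. The packaged evaluation
fixtures (5, 12 and 27 species) use outflow perturbations with factor 5.

What the generator does *not* emulate: Michaelis–Menten saturation,
correlated (off-diagonal) process noise, measurement error on top of
biological variation, and unmeasured metabolites inside the network.
Passing tests on these fixtures therefore demonstrate correctness of the
machinery and robustness to fluctuation-matrix uncertainty — not
performance on real data with model mismatch.

## Evaluation metrics

`topkHit()` compares the scan's top-k positions against the truth's k
largest $|DJ - 1|$ under exact set equality, the strictest reading; the
mean overlap fraction is reported alongside in `replicability()`, which
repeats the whole generate–scan–rank cycle (default 100 times) and reports
hit fractions for k ∈ {1, 3, 5}. On the packaged fixtures at
$\varepsilon_D = 0.2$ the Top-1 recovery rate is ≥ 0.95 for all three
model sizes, degrading monotonically as $\varepsilon_D$ grows to 0.5 —
the behaviour the acceptance script quantifies.
`differentialCorrelation()` is the negative control: the difference of the
two correlation matrices, which is unit-invariant per metabolite but — as
the scan's comparison shows — does not recover differential Jacobian
structure. `variableImportance()` supplies the per-metabolite
$-\log_{10} P$ (Welch t-test) used to size nodes in the circular plots
(base 10 is our choice; the sources leave the base unstated).

## Numerical choices and degenerate inputs

* Covariances must be symmetric to $10^{-10}$ and PSD to eigenvalue
  $\ge -10^{-8}\,\mathrm{tr}(C)$; violations are errors, not warnings.
* An all-equal loss landscape (no variation at all) yields relevance 0
  everywhere rather than an arbitrary winner; a truth with no changed
  entry makes `topkHit()` warn and return `FALSE`.
* Rank-deficient systems get the minimum-norm SVD solution; ranks use the
  standard $\max(m,L)\,\varepsilon\,\sigma_{\max}$ tolerance.
* Underdetermined structures ($L > m$) warn but proceed.
* All randomness flows through explicit integer seeds; every generator is
  bitwise-reproducible, and the workflow manifest records enough to
  regenerate each artifact identically.

## Problem sizes used in the shipped analyses

The packaged tests and the acceptance script run on synthetic models of 5,
12 and 27 species (superpathway structures with up to ~65 masked
positions), 100-repeat replicability grids, 100 fluctuation samples per
scan, and 10 000 thinned SDE samples — sizes chosen so that the full
validation cycle completes in minutes on a laptop while still spanning the
qualitative regimes (small/medium models, well- and ill-conditioned
systems, low and high fluctuation randomness). Larger problems run with
the same code; the scan cost grows as one QR factorization of a
$2m \times (L+1)$ matrix per masked position.

## Known limitations

* Gene associations use OR semantics over listed genes; boolean
  AND/OR grammars in `gene_reaction_rule` strings are tokenized, not
  evaluated, which is sufficient for threshold trimming but coarser than
  full GIMME (the LP formulation is deliberately out of scope).
* KEGG reactions are treated as reversible, with directionality refined
  only through thermodynamic penalties; enzyme-level allosteric regulation
  is not represented in the interaction graph at all.
* SBML support covers Level 3 core (plus a mass-action kinetic-law dialect
  for kinetic models); arbitrary MathML rate laws are not imported.
* The scan ranks single-entry changes; when several entries change jointly
  it highlights the affected column reliably but the within-column order
  is not guaranteed.
* Relevance from the scan is not invariant to per-metabolite unit
  rescaling (the differential correlation control is); covariances should
  be supplied on a common concentration scale.
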