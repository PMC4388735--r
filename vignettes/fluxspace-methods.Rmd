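---
title: "Methods: exact enumeration of FBA optimal solution spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact enumeration of FBA optimal solution spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxspace)
```

## The model

A stoichiometric model is a matrix `N` (rows: balanced species; boundary
species are dropped from balancing), flux bounds, an objective vector
`c`, and optional gene–protein–reaction (GPR) rules. FBA is the linear
program `max c'J` subject to `NJ = 0` and the bounds. Its optimal set

`P* = { J : NJ = 0, bounds, c'J = Z* }`

is a polyhedron. Everything this package does is a statement about `P*`,
and every statement is combinatorial: *how many* vertices, *which*
subnetworks vary, *whether* a flux is support-minimal. Such statements
are brittle under floating point — a vertex count changes when a
residual of `1e-9` is read as nonzero — so the entire stack (simplex,
FVA, double description, rank tests) runs over exact rationals.

### Exact rationals

Rationals are reduced numerator/denominator pairs held in doubles.
Every product is checked against the exact-integer limit `2^53`;
exceeding it raises an error rather than silently rounding. For the
desk-scale networks the package targets (tens of reactions, stoichiometric
coefficients of magnitude ≤ 2) intermediate values stay orders of
magnitude below the guard. Decimal input (e.g. a bound of `12.77`) is
converted exactly via its shortest round-tripping decimal form,
`1277/100`.

### Exact LP and MILP

The LP core is a two-phase primal simplex with Bland's rule (which
guarantees termination) over the rationals. Bounded variables are
reduced to standard form by shifting (finite lower bound), reflection
(finite upper bound only), or splitting (free variables); redundant
steady-state rows are detected in phase 1 and dropped. Optimality and
feasibility verdicts are exact: a returned flux satisfies `NJ = 0` with
zero residual. Pathway-length minimization is a branch-and-bound search
over binary activity indicators on top of this LP; bounds are rational
throughout, and the incumbent is seeded by rounding the relaxation
witness (activity = nonzero flux), which is always feasible.

## Characterizing the optimum

### Minkowski sum

Every optimal flux decomposes into a convex combination of vertices, a
conical combination of extreme rays, and a linear combination of
linealities. Rays and linealities of `P*` are futile in the sense that
they carry no objective (`c'r = 0`); linealities exist only while
reversible reactions are intact and are reversible cycles or reversible
boundary-to-boundary routes.

### Vertex enumeration and the lineality quotient

Vertices, rays and linealities are computed by exact double description
(DD): equalities are eliminated by restriction to their rational
nullspace, the polytope is homogenized (`x` to `(x, λ)`), and the
constraints are inserted incrementally with the standard combinatorial
adjacency test. A polyhedron with a nonzero lineality space has no
vertices in the strict sense, so enumeration works in the quotient: the
package adds one equality per lineality direction and reports canonical
representatives. Among all representatives of a vertex class
(`v + span(linealities)`), the *support-minimal* one is chosen (ties
broken deterministically by support and values). This convention makes
each non-split vertex an instance of a minimal pathway — the form in
which vertices of non-split models are usually drawn and compared with
EFMs — and it is safe: lineality directions are zero on every reaction
with a finite bound, so changing representative never violates bounds.

Rays are classified by their net stoichiometric action: `split-pair`
(the forward/backward two-cycle of one split reversible reaction),
`cycle` (zero net action on all species), or `input-output`.

### Flux modules

Reactions whose exact FVA interval at the optimum has nonzero width form
the variable part; the rest is the fixed network with a unique exact
flux. The variable reactions are partitioned into connected components
of the species–reaction graph (joined through species touched by at
least two variable reactions), and each component is *verified* as a
module: for every species it touches, its net production by the
component's reactions must be constant over all of `P*` (two exact LPs
per species). Failing components are merged with the components sharing
the offending species and verification repeats to a fixed point. The
verified property — constant interface `d` — is what downstream steps
rely on, so correctness does not depend on the discovery heuristic.
For the graph-component heuristic, components never share species, and
a species touched by only one component has its balance pinned by the
fixed network, so in practice verification succeeds on the first pass;
the merge loop is a safety net.

Each essential module (`d ≠ 0`) becomes a standalone submodel: its
reactions and species, plus an input pseudo-reaction supplying the
net-consumed species and an output pseudo-reaction removing the
net-produced ones, both pinned to unit flux, with a dummy species
forcing both to run. Module vertices are enumerated on these submodels;
whole-network vertices are the product over modules (reconstructed
lazily by mixed-radix indexing, so the product is never materialized
unless asked for). A module is reported as a *subnetwork with
alternatives* when it has at least two vertices after its own lineality
quotient; a module whose variability is purely a lineality (the
reversible triangle of the demonstration network) is still a verified
module but contributes factor 1 to the vertex product. This is the
convention under which the demonstration network has 3 modules but 2
subnetworks before splitting, and 3 of each after.

### EFMs and the rank test

Elementary flux modes are enumerated as extreme rays of the split flux
cone `{N r = 0, r ≥ 0}` (bounds and objective play no role). For models
with reversible reactions the split is internal and rays are mapped back
to net fluxes: two-cycle modes vanish and are dropped; a fully
reversible mode appears in both directions and is reported once, with
the direction chosen so the leading nonzero coordinate is positive. The
count of a fully reversible cycle is therefore one, not two. An
already-split input model keeps its two-cycle modes, one per pair.

Optimal-yield filtering scales each mode to saturate the restricting
non-zero constraint and keeps those attaining the optimum; modes with
zero objective flux are non-operational. With several restricting
constraints the criterion is only necessary, and the function warns.

Support-minimality is certified by the rank test: restrict `N` to the
support columns and compute the exact rank by rational elimination;
nullity one means the flux is an EFM instance. The conventional
singular-value route is provided as a floating-point cross-check
(`rank_test_svd`, tolerance `1e-9`), but the authoritative verdict is
the exact one. Vertices are matched to EFMs by exact proportionality on
identical support.

With a single restricting constraint, every split-model vertex passes
the rank test. Demanding constraints break this: adding a forced
side-draw (a demand reaction pinned to a fixed flux) superimposes a
second route on every vertex, and vertices stop being elementary. The
demonstration network is mass-rigid downstream of its first branch
point, so the packaged demand variant draws from that branch point —
any later draw (including an ATP-maintenance demand) is stoichiometrically
infeasible in this particular network. The qualitative effect (all
vertices fail the rank test) is what the construction demonstrates.

## Secondary objectives

`P_L` counts active reactions (exact zero test; a documented threshold,
default `1e-9`, applies only to externally supplied floating-point
fluxes). `P_J` sums absolute fluxes. `P_C` weights them with per-reaction
protein costs from GPR rules: AND-connected subunits sum their lengths,
OR-connected isozymes take the minimum, maximum, or average, and the
result is divided by the mean length over the model's annotated proteins
so that `c_j < 1` marks a cheaper-than-average enzyme; unannotated
reactions cost 1, and the `equal` rule (all costs 1) reduces `P_C` to
`P_J`.

On split models `P_J`/`P_C` minimization is a plain LP (all fluxes
nonnegative), and a minimum is always attained at a vertex. `P_L`
minimization is the MILP described above with exact big-M values: the
FVA maximum where finite. Futile-cycle directions make some FVA maxima
infinite even on split models, so those reactions are capped from the
enumerated vertex hull (twice the largest vertex flux plus the model's
flux scale), leaving headroom for circulation. For split models this is
provably exact — adding nonnegative ray flux can only enlarge a
support — so the capped minimum equals the true minimum. For non-split
models a support-cancelling circulation larger than the cap would be
missed; this is a known limitation, and the package recommends the
split representation for secondary optimization (where the question is
also better posed: the shortest pathway is then always a vertex).

Tie-breaking: when several solutions attain the secondary minimum, the
reported count of optimal vertices says so explicitly; the witness is
the solver's deterministic choice, never a silent pick.

## The synthetic generator

`generate_random_model()` emulates the small branched networks on which
the package's combinatorial claims can be verified against brute force:
a substrate-to-product backbone chain through all internal species
(guaranteeing a nonzero steady-state route), plus random internal
reactions with integer coefficients in `{-2..2}` and a configurable
reversible fraction (default 0.3). Extra reactions are drawn
mass-conserving (equal total stoichiometry on both sides), so a bounded
input implies a bounded optimum; draws are resampled until every
reaction is reachable from the input. The same seed always yields the
same model. What it does *not* emulate: cofactor coupling, compartments,
biomass-style lumped reactions, or genome-scale sparsity — so passing
property tests on these fixtures certifies the polyhedral machinery,
not the biological realism of any particular reconstruction.

## Numerical and design choices

- Exact comparisons everywhere; no epsilons in variability, vertex
  identity, module verification, or rank verdicts.
- Deterministic ordering: vertices, rays and EFMs are sorted by support
  pattern and values; reruns are byte-identical.
- DD adjacency uses the combinatorial zero-set test with exact
  tight-sets recomputed per new ray; duplicates are removed by exact
  primitive canonical form (signs preserved for cone rays).
- Degenerate inputs: models with a unique optimum yield zero modules and
  a single (fixed) vertex; infeasible or unbounded FBA is reported as a
  status with a certificate ray, never an error code.
- Problem sizes: the shipped analyses run the 18/23-reaction fixture;
  property suites use seeded random fixtures with ≤ 8 reactions before
  splitting, where a support-subset brute-force oracle is feasible
  (100 seeds for vertex-enumeration equivalence, 50 for the
  single-constraint rank-test theorem). Larger networks are supported by
  the same code paths but enumeration cost grows with module size, not
  network size — the intended regime is "few, small modules".

## Known limitations

- EFM enumeration is guarded at ~30 reactions after splitting; use
  module submodels beyond that. Genome-scale EFM enumeration is out of
  scope.
- The vertex *product* is only counted and lazily indexed; materializing
  it (e.g. for `decompose_in_space`) is guarded at 10^4 vertices.
- Rational arithmetic overflows (beyond 2^53 in a reduced intermediate)
  raise an error; models with pathological coefficient growth would need
  arbitrary-precision arithmetic.
- The non-split `P_L` cap caveat described above.
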