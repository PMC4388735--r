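# fluxspace

Exact characterization of the optimal solution space of flux balance
analysis (FBA).

## The problem

FBA predicts a metabolic flux distribution by maximizing an objective
(typically biomass or product flux) over the steady-state flux polyhedron

```
maximize  Z = c' J
subject to  N J = 0,   J_min <= J <= J_max
```

With realistic constraint sets the optimum is almost never unique: the set
of optimal flux vectors is itself a polyhedron, often with astronomically
many corner points. `fluxspace` is for modellers who want that space
*explained*, not sampled: every optimal flux decomposes as a Minkowski sum

```
J_opt = sum_k alpha_k phi_k + sum_k beta_k rho_k + sum_k gamma_k psi_k
        (convex: vertices)    (conical: rays)     (linear: linealities)
```

and the package computes each part exactly:

- **Vertices, extreme rays, linealities** by exact double description —
  no floating-point tolerances anywhere; all arithmetic is rational.
- **Flux modules**: the variable part of the optimum splits into small
  subnetworks with fixed net input–output stoichiometry
  (`N_A J_A = d`); whole-network vertex counts are the *product* of tiny
  per-module counts, which is why optima with millions of vertices are
  tractable.
- **Reversible-reaction splitting**, which removes linealities and makes
  the vertex set the complete, unique set of non-decomposable optimal
  pathways.
- **Elementary flux modes** (EFMs) of small networks, the optimal-yield
  subset, the nullity-one rank test, and the vertex↔EFM correspondence
  (a bijection after splitting under a single restricting constraint).
- **Secondary objectives** that collapse the optimum: pathway length
  `P_L` (an exact branch-and-bound MILP), flux sum `P_J`, and protein
  cost `P_C` with costs derived from gene–protein–reaction rules
  (AND = sum of protein lengths, OR = min/max/average, scaled by the mean
  annotated protein length).

Models are read from SBML Level 3 (fbc) or a human-diffable tabular
dialect; all solver and enumeration verdicts are exact, so counts are
combinatorial facts rather than tolerance artifacts.

## Worked example

The built-in 18-species / 18-reaction demonstration network converts a
substrate X to a product Y through two branched segments, a reversible
triangle, and an ATP/ADP couple, with one capacity constraint `J_1 <= 2`
and objective `max J_18`:

```r
library(fluxspace)

toy <- build_toy_model()
solve_fba(toy)
#> FBA solution: status optimal, objective 1 (1)

optimal_space(toy)
#> optimal solution space
#>   objective: 1 (1)
#>   vertices: 4 (product over modules; sum 5)
#>   rays: 0, linealities: 1
#>   modules: 3 (2 subnetworks with alternatives: counts 2 x 2 x 1)

sp <- split_reversible(toy)
os <- optimal_space(sp$model)
os
#> optimal solution space
#>   objective: 1 (1)
#>   vertices: 12 (product over modules; sum 7)
#>   rays: 7, linealities: 0
#>   modules: 3 (3 subnetworks with alternatives: counts 2 x 3 x 2)

minimize_pathway_length(sp$model, 1, space = os)
#> secondary optimization P_L: minimum 11 (attained by 1 enumerated vertex/vertices)
```

Reading: without splitting the optimum has 4 vertices plus one lineality
(the reversible triangle); after splitting, all 12 non-decomposable
optimal pathways appear as vertices (2 x 3 x 2 alternatives over three
subnetworks) and 7 rays (5 forward/backward two-cycles plus the triangle
in both directions). The shortest optimal pathway uses 11 reactions and
is one of the 12 vertices; without splitting, no vertex attains 11 — the
shortest pathway is a convex combination of two vertices. Adding a second
constraint `J_15 <= 1/2` raises the minimum to 12.

EFM analysis on the same fixture:

```r
efms <- enumerate_efms(toy)
length(efms)                                        # 13
oy <- optimal_yield_filter(efms, toy, 1)
length(oy)                                          # 12
vs <- enumerate_vertices(sp$model, z_star = 1)
match_vertices_to_efms(vs$vertices, optimal_yield_filter(
  enumerate_efms(sp$model), sp$model, 1))$bijection  # TRUE
```

A command-line wrapper ships in `inst/cli/fluxspace`
(`fluxspace enumerate|efm|secondary|toy|random`).

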