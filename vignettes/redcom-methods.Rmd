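---
title: "Reduced community metabolic models from elementary flux vectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced community metabolic models from elementary flux vectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redcom)
```

## The modeling problem

Stoichiometric models of microbial communities under *balanced growth* assume
that every member grows at the community growth rate $\mu_c$ (equal to the
dilution rate in a chemostat).  Writing $F_i$ for the fractional abundance of
species $i$ (gDW of species $i$ per gDW of community biomass,
$\sum_i F_i = 1$), the community model couples each member's fluxes to its
abundance:

* steady state $N^c r^c = 0$ for all internal metabolites, including the
  shared exchange compartment where former single-species external
  metabolites are balanced;
* balanced growth $r_{BM_i \to BM_c} = F_i\,\mu_c$ (needed for $n-1$ species;
  the $n$-th is implied by the biomass balance);
* abundance-scaled bounds $F_i\,\alpha_{ij} \le r^c_{ij} \le F_i\,\beta_{ij}$
  and $A_i r^c_i \le F_i\,b_i$, which force all fluxes of an absent species
  ($F_i = 0$) to zero — this is why every flux must carry finite bounds.

The products $F_i \mu_c$ make the model **bilinear**.  Fixing $\mu_c$
linearizes it; `linearize_fix_mu()` implements exactly that, and
`find_mu_max()` locates the maximum feasible rate by the iterative scheme of
starting at 0.005 h$^{-1}$, doubling while feasible, and then bisecting the
last feasible/infeasible bracket down to $10^{-5}$ h$^{-1}$.  We deliberately
do not ship a general nonlinear solve of the bilinear model: on larger
communities such solvers are initialization-dependent (plateaus in the
objective), whereas a sweep of linearized models over $\mu_c$ is
deterministic and answers the same questions.  Quantities "over all growth
rates" are therefore obtained by sweeping a grid on $[0, \mu_{c,\max}]$ and
taking range unions.

## Elementary flux vectors

With inhomogeneous constraints (maintenance demands, uptake caps, a pinned
growth rate) the feasible flux set is a polyhedron, not a cone, and the right
pathway concept is the *elementary flux vector* (EFV).  The polyhedron is
generated by convex combinations of its **bounded** EFVs plus conic
combinations of its **unbounded** EFVs:

$$P = \Big\{ r : r = \sum_k \gamma_k p^k + \sum_i \alpha_i x^i,\quad
\gamma_k \ge 0,\ \textstyle\sum_k \gamma_k = 1,\ \alpha_i \ge 0 \Big\}.$$

`enumerate_efvs()` computes both classes by the double description method on
the homogenized cone: a coordinate $\xi \ge 0$ is appended, every
inhomogeneous constraint $a^\top r \le b$ becomes $a^\top r - b\,\xi \le 0$,
reversible reactions are split into forward/backward parts, and inequality
rows receive slack coordinates, producing a pointed cone
$\{z \ge 0 : Mz = 0\}$ whose extreme rays are enumerated incrementally with
the combinatorial adjacency test.  Rays with $\xi > 0$ are rescaled to
$\xi = 1$ (bounded EFVs, feasible points); rays with $\xi = 0$ are the
recession directions (unbounded EFVs, reported max-norm scaled).
Elementarity is support minimality in this split, homogenized coordinate
system; futile forward+backward two-cycles are removed.

`brute_force_vertices()` is an independent oracle for small instances: it
enumerates vertices and extreme rays per sign-orthant of the reversible
reactions by exhaustive active-set combinations, solved in exact integer
arithmetic (rows are scaled to integers, determinants by fraction-free
Bareiss elimination, solutions by Cramer's rule, null vectors by signed
maximal minors, all with an overflow guard).  The test suite checks the two
routes against each other on hundreds of random polyhedra, which is the
strongest correctness evidence in the package: the two enumerations share no
code beyond the polyhedron container.

Numerical choices: the zero threshold after per-ray max-norm scaling is
$10^{-9}$; EFV sets are deduplicated at $10^{-6}$ relative tolerance before
counting (counts are tolerance-sensitive, and the exact oracle arbitrates
disputes at desk scale).  Enumeration refuses polyhedra above 400 reactions
unless forced, because double description memory grows combinatorially.

## The reduction

For a community growth rate of interest, $\mu_i = \mu_{c,fix}$ is pinned in
every single-species model and all bounded EFVs are computed (growth-coupled
conversions always involve bounded substrate uptake, so unbounded EFVs are
not needed downstream).  Each EFV is projected onto its $q$ exchange
reactions plus the growth rate.  Projections are expressed as *non-negative
turnovers* — uptake and export as separate non-negative columns — because the
dominance test below compares "total turnover", and signed fluxes would make
larger uptake look smaller.  Identical projections are collapsed (lowest
source index kept, deterministically).

A projected conversion $e^k$ is then **discarded** when a convex combination
of the other candidates consumes and secretes no more of anything while
delivering the same growth rate:

$$E^{*}w \le e^k,\qquad \mathbf{1}^\top w = 1,\qquad w \ge 0,$$

a feasibility LP (`filter_minimal_conversions()`).  The convexity row is
essential: it guarantees the combination meets the same fixed growth rate and
inhomogeneous constraints.  The filter removes exactly the altruistic
phenotypes — a species burning substrate into byproducts far beyond what its
own growth requires — that inflate the solution spaces of full community
models.  For a given substrate/product pattern only biomass-yield-optimal
conversions survive, but at least one conversion survives per alternative
product, retaining metabolic flexibility.  Because convex dominations
substitute transitively, testing each row once against all other candidates
is order independent; the property suite verifies this under row shuffles,
and a stored certificate $w$ accompanies every discard.

The survivors become reactions of the reduced species model,
$N^{red} = N^{EX} E$, all irreversible, each producing the species biomass at
rate $\mu_{c,fix}$ per unit conversion flux.  The reduced community model
then needs only two compartments (exchange and medium): non-accumulating
exchange metabolites are balanced, medium exchanges are added for substrates
and accumulating products, and biomass plumbing
($BM_i \to BM_c \to$ export at $\mu_c$) is retained so abundances remain
readable via $F_i = \sum_{j \in \text{species } i} \lambda_j$.  No
abundance-scaled bounds are re-imposed: a solution $\lambda$ unpacks to
$r_i = \sum_j \lambda_j e_j$, a convex-conic mixture of single-species EFVs
that satisfies the scaled constraints at $F_i = \sum_j \lambda_j$ by
construction.  `unpack_solution()` performs the reconstruction and checks
this consistency property explicitly; the test suite exercises it on
hundreds of random solutions.

The $\mu_c = 0$ case loses the biomass-balance normalization (all growth
fluxes are zero), so the model carries explicit abundance variables with
$\sum_{j} \lambda_j = F_i$ and $\sum_i F_i = 1$ throughout; for
$\mu_c > 0$ these rows are implied and change nothing.  This is one
consistent reading of the degenerate case, not the only possible one, and is
flagged as such.

## Model conventions

Models carry a designated biomass reaction that *drains* exactly one internal
biomass metabolite with unit coefficient; its rate is the specific growth
rate.  (Biomass synthesis from precursors is an ordinary metabolic reaction
producing that metabolite.)  In community assembly the drain is retargeted to
produce $BM_c$, which makes it the biomass-integration reaction — the
integration flux and the single-species drain always carry equal flux, so no
separate pseudo-reaction is needed.  Exchange metabolites are matched across
species by exact (case-sensitive) id string equality.  Coefficients are kept
as small rationals so the exact oracle applies; declared-infinite bounds are
replaced by a configurable big-M (default 1000 mmol/gDW/h) with a warning,
since finiteness underpins the $F_i = 0 \Rightarrow r_i = 0$ argument.

## What the toy fixtures emulate — and what they do not

The fixture community is a producer (S $\to$ P + biomass, yield 0.1 gDW/mmol,
uptake cap 10 mmol/gDW/h) feeding a consumer (P $\to$ biomass, same
parameters): an obligate cross-feeding chain like the syntrophies of
anaerobic digestion, small enough that every number is checkable by hand.
The unique composition is $F = (0.5, 0.5)$ when the byproduct must be
consumed, $F_A \in [0.5, 1]$ when it may accumulate, and
$\mu_{c,\max} = $ yield $\times$ uptake bound $= 1.0$ h$^{-1}$.  The wasteful
variant adds a growth-independent S $\to$ P route whose projected conversion
is dominated and must be filtered; the maintenance variant adds an ATP drain
to exercise inhomogeneous constraints.  Default toys are maintenance-free by
design so the derivations stay closed-form.

Passing tests on these fixtures demonstrate the machinery — enumeration,
filtering, assembly, containment of reduced in full ranges, abundance
recovery — under exactly known conditions.  They do not demonstrate
genome-scale behavior: real community models have hundreds of reactions per
species, EFV counts in the tens of thousands, maintenance coefficients
spanning an order of magnitude, and multi-substrate media.  The scenario
layer (`load_scenario()`) encodes the nine-species anaerobic-digestion case
study — species subsets, ethanol/lactate/glucose media, accumulation rules,
maintenance coefficients and uptake caps per organism — but the curated SBML
files themselves are distributed with the original model collection and must
be supplied in `model_dir` by the user; the package refuses those scenarios
with an explicit file listing otherwise.

## Problem sizes and determinism

The shipped property suite runs at desk scale by construction: random
polyhedra are capped at 6 reactions (at most 8 after splitting) so the exact
oracle's active-set enumeration stays in the thousands of combinations, and
decomposition/unpacking properties use 50–100 seeded random solutions.  All
randomness flows through explicit seeds; two runs of any command with the
same inputs produce byte-identical outputs (the LP solver is a deterministic
Bland-rule simplex, written for this package because no LP backend is
available in the target environment, and cross-checked against an
independent solver on the programs both can express).

## Known limitations

* Double description is implemented for correctness, not for genome-scale
  EFM performance (no bit-pattern trees, no parallelism); the practical
  ceiling is a few hundred reactions.
* The exact oracle requires small rational coefficients; it aborts rather
  than degrade silently on dense irrational data.
* The bilinear community model is represented but never solved directly;
  all analyses go through the $\mu_c$-fixed linearization.
* SBML support covers the Level 3 + fbc subset the curated models need
  (species, boundary flags, stoichiometry, flux-bound parameters, one
  objective); groups, layout and gene-protein-reaction rules are out of
  scope.
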