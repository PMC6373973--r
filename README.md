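# redcom

Constraint-based modeling of multi-species microbial communities under
balanced growth, with the **RedCom** reduction: community models whose
reactions are the *minimal net conversions* of the member species, computed
from elementary flux vectors (EFVs) of the single-species networks.

## Who this is for

Modelers of microbial consortia — syntrophic chains in anaerobic digestion,
cross-feeding gut or soil communities, defined co-cultures — who want to
predict feasible community compositions, exchange fluxes and product yields
from single-species stoichiometric models, without the two standard
obstacles: the bilinearity of balanced-growth community models, and solution
spaces cluttered with unrealistic "altruistic" flux distributions in which
one species wastes substrate to feed another.

## The model

Under balanced growth every member grows at the community rate μc, and the
fractional abundances F_i (Σ F_i = 1) couple to the fluxes through

* steady state `N^c r^c = 0` (former external metabolites are balanced in a
  shared exchange compartment),
* `r_BMi→BMc = F_i · μc` for n−1 species (the n-th is implied), and
* abundance-scaled bounds `F_i·α ≤ r^c ≤ F_i·β`, `A_i r ≤ F_i b_i`.

Fixing μc linearizes the model (`linearize_fix_mu()`); the maximum rate is
found by doubling from 0.005 h⁻¹ and bisecting to 1e−5 h⁻¹
(`find_mu_max()`).  The RedCom reduction goes further: at the fixed μc all
bounded EFVs of each species are enumerated (`enumerate_efvs()`, double
description on the homogenized cone, with an exact-arithmetic brute-force
oracle for validation), projected onto exchange reactions plus growth, and a
projected conversion `e^k` is discarded whenever the feasibility LP

```
E* w ≤ e^k,   1ᵀ w = 1,   w ≥ 0
```

has a solution — i.e. a convex mixture of the other conversions achieves the
same growth rate with no greater turnover of any external metabolite.  The
survivors form `N^red = N^EX · E`, the reactions of a small, fully linear
two-compartment community model whose "community EFVs", FVA ranges and
yield optima are cheap to compute, and whose solutions unpack back to full
single-species flux distributions (`unpack_solution()`).

## Worked example

The canonical toy: producer A converts substrate S to byproduct P
(0.1 gDW/mmol yield, uptake cap 10 mmol/gDW/h) and consumer B grows on P.
P must not accumulate, so every P molecule A exports must be eaten by B:

```r
library(redcom)
ts <- make_toy_syntrophy()
res <- redcom_pipeline(ts$models, ts$medium, mu_c = 0.1)
res$rcm
#> Reduced community model: 2 species, 2 net conversions, mu_c = 0.1
res$ranges
#>       quantity min max
#> 1         F::A 0.5 0.5
#> 2         F::B 0.5 0.5
#> 3 EX::S[e]::up 0.5 0.5

cm <- assemble_full_community(ts$models, ts$medium)
find_mu_max(cm)
#> [1] 1
```

The composition is pinned at F = (0.5, 0.5): with equal biomass yields, the
P balance forces equal conversion fluxes.  The community substrate demand at
μc = 0.1 is 0.5 mmol/gDW_c/h, and the maximum community growth rate is
yield × uptake bound = 1.0 h⁻¹.  With a wasteful producer variant (an extra
S → P route without growth), the dominance filter removes the wasteful
conversion before it can distort the community model:

```r
cmd_reduce("toy_wasteful", out = tempdir())
#> kept conversions: A 2->1, B 1->1; community EFVs: 1
```

A shell entry point with the same commands ships as
`inst/scripts/redcom` (`redcom mumax|reduce|analyze --scenario ... `).

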