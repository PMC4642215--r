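# fockconj

Quantum representations of concept-conjunction membership data.

## The problem

When participants rate how well an exemplar belongs to two concepts and to
their conjunction — *is a skateboard a Machine? a Vehicle? a Machine And
Vehicle?* — the three membership weights μ(A), μ(B), μ(AB) routinely defy
classical probability: μ(AB) exceeds μ(A) or μ(B) (**overextension**), or
μ(A)+μ(B)−μ(AB) > 1 (the **Kolmogorovian factor violation**). Quantum
cognitive models accommodate such data by representing concepts as unit
states in a complex Hilbert space and membership as projector
measurements. `fockconj` is for researchers in mathematical
psychology/quantum cognition who want to go from a CSV of membership
triplets to concrete, verifiable representations.

## What it computes

* **Classicality** — a triplet is classical conjunction data iff
  μ(AB) ≤ μ(A), μ(AB) ≤ μ(B) and μ(A)+μ(B)−μ(AB) ≤ 1
  (`check_classical()`).
* **First sector (emergent conjunction, ℂ³)** — orthonormal states
  |A⟩, |B⟩ and a projector M with ⟨A|M|A⟩ = μ(A), ⟨B|M|B⟩ = μ(B) and
  μ(AB) = ½(μ(A)+μ(B)) + ℜ⟨A|M|B⟩. Such a model exists iff μ(AB) lies in
  [ave − dev, ave + dev], ave = ½(μ(A)+μ(B)),
  dev = min(√(μ(A)μ(B)), √((1−μ(A))(1−μ(B)))); the package gives the
  interval (`feasibility_interval()`) and a deterministic closed-form
  construction (`construct_first_sector()`, `fit_first_sector()`).
* **Second sector (logical conjunction, ℂ²⊗ℂ²)** — a state |C⟩ and factor
  projector M with ⟨C|M⊗1|C⟩ = μ(A), ⟨C|1⊗M|C⟩ = μ(B),
  ⟨C|M⊗M|C⟩ = μ(AB); exists iff the triplet is classical
  (`construct_tensor_rep()`).
* **Unification** — whole datasets re-expressed with a *single* conceptual
  state and exemplar-dependent operators via unitary changes of basis:
  `unify_first_sector()` (canonical |A⟩ = e₁, |B⟩ = e₂),
  `unify_zero_type()` (shared |1⟩⊗|1⟩), `unify_second_type()`
  (product-state models for independent triplets), `embed_in_C3()`.
* **Fock membership formula** — μ(AB) = n²(½(μ(A)+μ(B)) + I) +
  (1−n²)·μ(A)μ(B) with |I| ≤ √(μ(A)μ(B)); evaluation and deterministic
  fitting (`fock_membership()`, `fit_fock()`).
* **Compatibility** — commutator expectations c_X = ⟨·|[M₁,M₂]|·⟩ between
  exemplar pairs in a unified model; nonzero values predict order effects
  (`compatibility_matrix()`).
* **Synthetic data** — seeded generators for classical, overextended-but-
  representable, first-sector-infeasible and independent regimes
  (`simulate_triplets()`).

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods and
ggplot2 displays (`plot_membership()`, `plot_feasibility()`,
`autoplot()` on compatibility matrices).

## Worked example

```r
library(fockconj)

d <- read_membership_csv(system.file("extdata", "machine_vehicle.csv",
                                     package = "fockconj"))
check_classical(d)[, c("exemplar", "mu_a", "mu_b", "mu_ab", "is_classical", "category")]
#>   exemplar    mu_a  mu_b mu_ab is_classical category
#> 1 sailboat    0.56  0.8   0.42 TRUE         classical
#> 2 skateboard  0.28  0.84  0.34 FALSE        single_overextension
```

The skateboard triplet is singly overextended (0.34 > 0.28), so it has no
classical — hence no tensor-product — model, but both exemplars fit in ℂ³:

```r
fit <- fit_first_sector(d)
glance(fit)
#>   n_exemplars n_representable max_residual
#> 1           2               2     1.15e-16
```

`max_residual` is the worst deviation from the six defining conditions:
both representations are exact to machine precision. Unifying them puts
both projectors in one basis, where their commutator shows the pair is
incompatible — a predicted order effect in sequential judgements:

```r
cm <- compatibility_matrix(unify_first_sector(fit))
cm[cm$exemplar_1 != cm$exemplar_2,
   c("exemplar_1", "exemplar_2", "mag_a", "mag_b", "mag_ab", "compatible")]
#>   exemplar_1 exemplar_2 mag_a  mag_b mag_ab compatible
#> 1 sailboat   skateboard 0.104 0.0880 0.0369 FALSE
```

By contrast the *Building/Dwelling* pair (cave, synagogue) is classical,
and its unified tensor model is exactly compatible:

```r
bd <- read_membership_csv(system.file("extdata", "building_dwelling.csv",
                                      package = "fockconj"))
cm2 <- compatibility_matrix(unify_zero_type(bd))
max(cm2$mag_a, cm2$mag_b, cm2$mag_ab)
#> [1] 0
```

A triplet that neither sector handles alone can still satisfy the
two-sector Fock formula; for (1, 0.49, 0.78) the fit puts all weight on
the emergent sector with interference 0.035:

```r
fit_fock(membership_triplets("heated waterbed", 1, 0.49, 0.78))[,
  c("exemplar", "fock_n", "interference", "mu_ab_fit")]
#>   exemplar        fock_n interference mu_ab_fit
#> 1 heated waterbed      1       0.0350      0.78
```

A thin command-line wrapper over the same functions lives at
`inst/cli/fockconj.R` (subcommands `classify`, `represent-first`,
`represent-second`, `unify-first`, `unify-second`, `fock-fit`, `compat`,
`simulate`, `report`).

## Acceptance script

`scripts/acceptance.R` recomputes the headline quantities from scratch by
running the installed package on the bundled exemplar data — the
first-sector round trip of the skateboard conjunction weight, the tensor
expectation values for sailboat, cave and synagogue, and the maximum
commutator magnitude of the unified cave/synagogue tensor model — and
writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/concept-conjunctions.Rmd` documents the models, the
deterministic solver conventions (amplitude splits, closed-form phases,
basis completion), tolerances, the synthetic-data regimes, and known
limitations.
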