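---
title: "Quantum models of concept conjunction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantum models of concept conjunction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fockconj)
```

## The phenomenon and the data model

When people judge whether an exemplar (say, *skateboard*) is a member of a
concept pair (*Machine*, *Vehicle*) and of their conjunction (*Machine And
Vehicle*), the three empirical membership weights
$\mu(A), \mu(B), \mu(AB) \in [0,1]$ frequently violate classical
probability: the conjunction weight exceeds one constituent weight (*single
overextension*), both (*double overextension*), or the triple fails the
bound $\mu(A)+\mu(B)-\mu(AB) \le 1$ (*Kolmogorovian factor violation*). A
triplet admits a classical (Kolmogorovian) probability model exactly when

$$\mu(AB) \le \mu(A), \qquad \mu(AB) \le \mu(B), \qquad
\mu(A)+\mu(B)-\mu(AB) \le 1 .$$

`check_classical()` evaluates these three inequalities with a tolerance
$\varepsilon = 10^{-9}$ (the slack must fall below $-\varepsilon$ to count
as a violation) and stores the raw slacks next to the boolean flags, so a
caller can re-threshold without recomputation. Weights of exactly 0 or 1
are legal; out-of-range weights are an error, never clamped. Every triplet
receives exactly one category; a triplet that is overextended *and*
violates the Kolmogorovian bound is categorised by its overextension, and
`kolmogorov_only` is reserved for triplets whose only failure is the third
inequality.

## First sector: the conjunction as an emergent entity

The emergent-conjunction model places unit states
$|A\rangle, |B\rangle \in \mathbb{C}^3$ with
$\langle A|B\rangle = 0$ and an orthogonal projector $M$ such that
$\langle A|M|A\rangle = \mu(A)$, $\langle B|M|B\rangle = \mu(B)$, and

$$\mu(AB) = \tfrac12\bigl(\mu(A)+\mu(B)\bigr) +
\Re\langle A|M|B\rangle .$$

A triplet is representable if and only if $\mu(AB)$ lies in the interval
$[\mathrm{ave}-\mathrm{dev},\ \mathrm{ave}+\mathrm{dev}]$ with
$\mathrm{ave} = \tfrac12(\mu(A)+\mu(B))$ and
$\mathrm{dev} = \min\!\bigl(\sqrt{\mu(A)\mu(B)},
\sqrt{(1-\mu(A))(1-\mu(B))}\bigr)$. Three complex dimensions suffice;
higher dimension adds no modelling power and $\mathbb{C}^2$ forces
$\mu(A)+\mu(B)=1$, so the package fixes the dimension at three.

### The deterministic constructive solver

The representability proof leaves a two-parameter amplitude split
($\lambda, \kappa$) and three relative phases free, so representations form
a continuum. For reproducibility `construct_first_sector()` commits to one
canonical member:

* **Amplitude split** $\lambda = \kappa = \tfrac12$. In the rank-1 branch
  (used when $\mu(A)+\mu(B) \le 1$, inclusively at equality) the states are
  $|A\rangle = (\sqrt{\mu_A}e^{i\gamma_1},
  \sqrt{(1-\mu_A)/2}\,e^{i\gamma_2}, \sqrt{(1-\mu_A)/2}\,e^{i\gamma_3})$
  with $|B\rangle$ real, $M$ projecting on the first coordinate; the rank-2
  branch (when $\mu(A)+\mu(B) > 1$) splits the *inside* amplitudes and
  projects on the first two coordinates.
* **Phases in closed form.** Writing $I = \mu(AB)-\mathrm{ave}$ for the
  required interference, $p = \sqrt{\mu_A\mu_B}$ and
  $t = \sqrt{(1-\mu_A)(1-\mu_B)}$: in the rank-1 branch
  $\cos\gamma_1 = I/p$ with $\sin\gamma_1 \ge 0$, and orthogonality is
  solved symmetrically by $\gamma_{2,3} = \pi + \gamma_1 \pm \delta$,
  $\delta = \arccos(p/t)$ (well defined because $p \le t$ there). The
  rank-2 branch mirrors this with $\cos\gamma_3 = -I/t$ and
  $\delta = \arccos(t/p)$. One can check by substitution that
  $\langle A|B\rangle = 0$ and $\Re\langle A|M|B\rangle = I$ hold exactly.
* **Degenerate weights.** All-zero and all-one triplets short-circuit to
  the rank-0 and rank-3 projectors with canonical orthonormal states.
  Weights of exactly 0/1 elsewhere collapse $p$ or $t$ to zero; the solver
  then uses reduced phase assignments (e.g. $\gamma_{1,2} = \pm\pi/2$) for
  which orthogonality is automatic and the interference is necessarily 0,
  consistent with the interval degenerating to a point.
* The printed form of the convex-combination function in the source
  analysis omits square roots on its coefficients; the solver works
  directly with amplitudes, for which the algebra is unambiguous.

`verify_first_sector()` returns all six condition residuals; the solver
keeps them below $10^{-10}$ across the whole feasible region (tested on
random triplets in both branches and on every 0/1 edge case).

### One conceptual state for a whole dataset

A dataset-level representation keeps a *single* pair of concept states and
moves all exemplar dependence into measurement operators.
`unify_first_sector()` completes each exemplar's solved pair to the basis
$\{|A_i\rangle, |B_i\rangle, |C_i\rangle\}$, builds the unitary $U_i$
mapping it onto the canonical basis, and conjugates the projector:
$M_i = U_i \hat M_i U_i^{-1}$. Since conjugation preserves all inner
products, every membership expectation survives the change of basis
exactly.

One numerical subtlety: for complex vectors the bare component-wise cross
product $|A_i\rangle \times |B_i\rangle$ is *not* orthogonal to its factors
under the Hermitian inner product. The package uses the complex conjugate
of the cross product, normalised, which is (because
$\langle A|\overline{A \times B}\rangle = \overline{A\cdot(A\times B)} =
0$). Constructed basis vectors get their global phase fixed by making the
first nonzero component real non-negative, so completions are reproducible
bit-for-bit.

## Second sector: the conjunction as a logical entity

The logical model represents the pair by one unit state $|C\rangle$ on the
tensor product, with a single-factor projector $M$ measured as
$M\otimes 1$, $1 \otimes M$ and $M \otimes M$. A triplet admits such a
representation on $\mathbb{C}^2 \otimes \mathbb{C}^2$ *iff it is
classical*; the constructive state is real with coefficients
$c_{11} = \sqrt{\mu_{AB}}$, $c_{12} = \sqrt{\mu_A-\mu_{AB}}$,
$c_{21} = \sqrt{\mu_B-\mu_{AB}}$, $c_{22} = \sqrt{1-\mu_A-\mu_B+\mu_{AB}}$
(all construction phases zero), and $M$ projects on the first canonical
factor vector. These four squared coefficients are precisely the 4-atom
probability mass function underlying the classical model, which is the
content of the equivalence.

Tensor objects are handled through the flat isomorphism
$|i\rangle\otimes|j\rangle \mapsto e_{n(i-1)+j}$ — exactly the ordering of
`base::kronecker` — so operators on the product space are plain Kronecker
products.

### Zero-, first- and second-type models

* **Zero-type** (`unify_zero_type()`): each exemplar's state is rotated
  onto the shared $|1\rangle\otimes|1\rangle$ by completing
  $\{|C_i\rangle\}$ to an orthonormal basis of $\mathbb{C}^4$ and
  conjugating the three operators by the basis-change unitary. This is the
  most general shared-state tensor model; the conjugated marginals may be
  entangled operators.
* **First-type**: the package does not construct these directly (no
  necessary-and-sufficient condition is available); instead each unified
  exemplar is *flagged* `first_type` when its conjugated marginals happen
  to factor as $X\otimes 1$ and $1\otimes Y$ (checked block-wise at
  $10^{-10}$).
* **Second-type** (`unify_second_type()`): the shared state is the product
  $|1\rangle\otimes|1\rangle$ and each exemplar carries *single-factor*
  projectors. On a product state the conjunction expectation necessarily
  factorises, $\langle M^A \otimes M^B\rangle = \mu(A)\mu(B)$, so this
  model exists exactly for independent triplets
  ($\mu_{AB} = \mu_A\mu_B$ within tolerance); the package enforces that as
  the precondition rather than reporting an unresolved "unknown", since the
  factorisation argument closes the question for the constructions used
  here. The factor unitaries are chosen to map each solved factor state to
  $|1\rangle$ and the projectors are conjugated accordingly (the direction
  of conjugation is fixed by the contract that expectations on
  $|1\rangle$ reproduce the data).

`embed_in_C3()` zero-pads states and operators into
$\mathbb{C}^3\otimes\mathbb{C}^3$ (coefficient map $c^*_{ij} = c_{ij}$ for
$i,j \le 2$, else 0), which changes no expectation, norm, Hermiticity or
idempotence and makes tensor models dimensionally comparable with the
first-sector analysis.

## The two-sector Fock formula

The full model superposes both modes with weight $n \in [0,1]$ on the
emergent sector:

$$\mu(AB) = n^2\Bigl(\tfrac{\mu(A)+\mu(B)}{2} + I\Bigr) +
(1-n^2)\,\mu(A)\mu(B),$$

where the interference $I = \Re\langle A|M|B\rangle$ obeys
$|I| \le \sqrt{\mu(A)\mu(B)}$. The square-root form of the bound is the one
consistent with the rank-1 amplitude algebra of the first-sector analysis
(the source text's displayed bound lost its radicals in typesetting, a loss
also visible elsewhere in the same display). Likewise the membership
operator is the direct sum $M \oplus (M \otimes M)$: the two additive terms
of the formula are the two sector expectations, and a test asserts that
decomposition against actually constructed sector representations.

`fit_fock()` returns one deterministic representative of the solution
continuum: $n = 1$ with $I = \mu(AB) - \mathrm{ave}$ whenever that is in
bound, otherwise the largest feasible $n$ on a fixed 0.01 grid. Two
consequences worth knowing: (a) the grid is part of the contract, and a few
classical triplets whose only solutions sit between grid points are
reported infeasible; (b) with `n =` fixed, one sector weight is shared
across all exemplars of a concept pair — the per-exemplar fit is the
default because desk-scale worked examples are fitted case by case.

## Compatibility of exemplar measurements

Once a dataset shares one basis, two exemplars' membership operators can be
compared via the commutator $[M_1, M_2]$. The package reports the
expectation values
$c_A = \langle A|[M_1,M_2]|A\rangle$,
$c_B = \langle B|[M_1,M_2]|B\rangle$ and
$c_{AB} = \tfrac12(\langle A|+\langle B|)[M_1,M_2](|A\rangle+|B\rangle)$
(the $\tfrac12$ compensating the unnormalised superposed conjunction
state) in the first sector, and the analogous primed values on the shared
tensor state in the second sector. Hermitian operators give purely
imaginary values; a pair is compatible when the magnitude falls below
$10^{-10}$. Raw complex values ride along in the report so callers can
rescale.

Two caveats are deliberate. First, first-sector *numeric* c-values depend
on the solver's phase conventions, because representations are non-unique;
only their zero/nonzero structure is convention-independent, and only that
structure is asserted in tests. Second, for the all-real second-sector
construction the commutator is a real antisymmetric form evaluated on a
real state, so every c-value vanishes identically — the tensor model
predicts compatible (classical, order-effect-free) measurements, and the
package's tests assert this across randomised classical datasets.

## The synthetic generator: what it emulates and what not

`simulate_triplets()` draws from four disjoint, verifiable regimes:
`classical` marginalises a uniform draw from the 4-atom probability
simplex (sorted-uniform spacings), so classicality holds by construction;
`overextended_representable` rejection-samples conjunction weights inside
the first-sector interval but above a constituent weight;
`first_sector_infeasible` samples outside the interval;
`independent` sets $\mu_{AB} = \mu_A\mu_B$. Rejection caps at $10^4$
attempts, and the seed is part of the public contract (identical seed,
identical dataset).

The generator emulates the *regions* of the triplet cube, not human data:
real membership judgements cluster (weights near 0.5–0.9, overextensions
of a few hundredths), carry sampling noise from finite participant counts,
and correlate across exemplars of one concept pair. None of that is
modelled, and regime frequencies are not fitted to any empirical corpus. A
green property test therefore establishes that the constructions and
theorems hold over each entire region — not that the package has been
validated against experimental distributions.

## Numerical choices

| Quantity | Value | Why |
|---|---|---|
| Inequality/classicality tolerance | $10^{-9}$ | well above double-precision noise, far below data resolution (weights are printed to 2 decimals) |
| Feasibility boundary | inclusive, $\pm 10^{-9}$ | boundary triplets are representable (interval is closed) |
| Unit-norm invariant | $10^{-12}$ | construction-level float error |
| Projector/unitary invariants, expectation preservation | $10^{-10}$ | a few conjugations of well-conditioned 3x3/4x4 matrices |
| Compatibility threshold | $10^{-10}$ | same order as the preservation guarantee |
| Fock fit grid | 0.01 in $n$ | deterministic, desk-scale; finer grids change no worked example |
| Basis completion | canonical-seeded modified Gram–Schmidt, largest-residual pivot, lowest-index tie-break, phase-fixed | deterministic and stable for the dimensions used (2, 3, 4, 9) |

## Known limitations

* No combined two-sector state construction (the Fock fit treats the
  sectors through their expectation values only).
* First-type tensor representations are recognised, not constructed.
* The first-sector solver returns one canonical representation; it does not
  explore the $(\lambda, \kappa, \gamma)$ continuum, so quantities that are
  not convention-invariant (individual commutator values) should not be
  compared across implementations.
* Dimensions are fixed at the minimal sufficient ones
  ($\mathbb{C}^3$, $\mathbb{C}^2\otimes\mathbb{C}^2$ with a trivial
  $\mathbb{C}^3\otimes\mathbb{C}^3$ embedding).
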