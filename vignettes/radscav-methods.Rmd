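---
title: "Methods: radical-scavenging kinetics in radscav"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radical-scavenging kinetics in radscav}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscav)
```

`radscav` turns per-channel thermochemistry of antioxidant/radical
reactions into overall scavenging rate constants, branching ratios and a
reference-relative capacity. This vignette is the package's account of the
underlying model, its tunable parameters, the numerical choices, and what
the synthetic test data do and do not establish.

## The mechanism network model

A scavenger is represented as a `mechanism_network`: its acid–base forms,
the solvent (dielectric, viscosity, temperature, pressure, optional fixed
diffusion rate constant), and a table of candidate pathways. Four
mechanism families are covered:

* **HAT** — hydrogen atom abstraction from a phenolic O–H;
* **RAF** — addition of the radical to a ring atom;
* **SPLET** — proton loss followed by electron transfer from the anion;
* **SET-PT** — electron transfer forming a radical cation, then proton
  loss.

The two-step mechanisms are encoded as *composite* pathways: two rows
sharing a `composite_id`, each carrying its own ΔrG. All energies are
kJ mol⁻¹ at the interface and converted to J mol⁻¹ internally exactly
once; rate constants are always M⁻¹ s⁻¹. Symmetry-equivalent sites that
share one transition state are a single row with reaction-path degeneracy
σ ≥ 1, never duplicated rows; aggregation multiplies by σ, so splitting a
σ = 3 row into three σ = 1 rows provably leaves every aggregate unchanged
(this is a tested invariant).

Where two composite mechanisms intertwine through the same elementary
step — a real situation for phenolate anions, whose SET-PT first step is
the parent's SPLET second step — both rows carry one shared `reaction`
identifier and rate tables count that reaction once.

Physical constants are fixed at their CODATA-2018 values
(`physical_constants()`); the Eyring prefactor k_B·T/h at 298.15 K is
6.2124×10¹² s⁻¹.

## Speciation

For pKa values pKa₁ < … < pKa_n at pH p, the molar fraction of the form
with j protons removed is

f_j ∝ 10^(j·p − Σ_{i≤j} pKa_i), normalized to Σ f_j = 1.

Exponents are accumulated in log₁₀ space and shifted by their maximum
before exponentiation, so arbitrarily long pKa lists cannot overflow.
Only macrostates (number of protons removed) are resolved; which hydroxyl
deprotonates first is not modelled. `dominant_forms()` selects the forms
that enter the aqueous pipeline, with a default threshold of 5% — chosen
as a round midpoint between populations that published speciation
analyses of this kind retain (20%) and drop (2.5%) — and always keeps the
most populated form, so the selection is never empty.

## The exergonicity gate

A single-step pathway is retained iff ΔrG < 0; a composite iff both steps
are exergonic. The inequality is strict with no tolerance band: published
screening practice treats even +2.6 kJ mol⁻¹ as excluding a channel, so
the boundary is sharp and ΔrG = 0 is rejected. Channels whose reactant is
itself a downstream radical (e.g. the phenoxyl radical formed by a prior
electron transfer) pass through the same gate but stay tagged
`secondary`, so aggregation can include them (`all_pathways`) or not
(`primary_only`).

## Rate constants

**Dispatch.** Each retained pathway gets its rate by provenance, recorded
in the `method` column of the rate table: `REFERENCE` (a bundled
literature value, used verbatim), `DIFFUSION` (barrierless),
`TST_ECKART` / `TST_PLAIN` (activated), `MARCUS` (electron transfer).
Keeping the provenance explicit means comparisons against published
tables never silently mix conventions.

**TST.** k = σ κ (k_B T/h) exp(−ΔG‡/RT) at the 1 M standard state. ΔG‡
inputs are taken as already referred to 1 M — published tables pair ΔG‡
with 1 M rate constants — so no Δn concentration correction is applied. A
negative ΔG‡ triggers a warning but is computed (recrossing is not
modelled).

**Eckart (ZCT-0) tunneling.** κ is the thermal average of the closed-form
transmission probability of the asymmetric Eckart barrier parameterized
by the forward barrier V_f, reverse barrier V_r and imaginary frequency
ν‡:

κ = e^{V_f/RT} ∫ P(E) e^{−E/RT} dE/RT,

integrated from max(0, V_f − V_r). Numerics: the hyperbolic-cosine ratio
in P(E) is evaluated in log space (it overflows for thick barriers
around 10²-10³ kJ mol⁻¹ · cm); the integrand is a sharp unimodal peak, so
its mode is bracketed on a 401-point grid, refined by golden-section
search, and the adaptive quadrature (`stats::integrate`, relative
tolerance 10⁻⁶) is applied piecewise between the integration limit, the
mode, the barrier top and V_f + 20·RT, with the analytic bound
P(E_max)·e^{(V_f−E_max)/RT} added for the truncated tail (≤ e⁻²⁰
relative). The result is ≥ 1 within the quadrature tolerance, decreases
with temperature and increases with ν‡; the unit tests pin it to an
independent fine-grid trapezoidal oracle to 4 significant digits. If the
estimated quadrature error exceeds 10⁻⁴ of the value, the function stops
with the barrier parameters in the message rather than returning a
doubtful number. When ν‡ (or V_r) is unknown, κ = 1 and the row is
flagged `TST_PLAIN`.

**Marcus electron transfer.** ΔG‡ = (λ/4)(1 + ΔG/λ)². The reorganization
energy λ is an input, derived as λ = ΔE_vertical − ΔG when a vertical
energy is supplied; published tables generally print neither λ nor the
vertical energies, so no attempt is made to invert printed activation
energies back to λ. The thermal rate (k_B T/h)·e^{−ΔG‡/RT} is combined
with the diffusion limit k_D by the Collins–Kimball form
k_app = k_D·k_act/(k_D + k_act), which guarantees
k_app ≤ min(k_act, k_D); the cruder `min` clipping is available behind a
flag for sensitivity checks. The quadratic barrier makes k_app maximal at
ΔG = −λ and strictly decreasing beyond — the inverted region, relevant
for highly exergonic transfers from multiply deprotonated anions.

**Diffusion.** Barrierless channels get the solvent's diffusion rate
constant. The water preset fixes it at 1.91×10⁹ M⁻¹ s⁻¹, the value
conventionally assigned to barrierless scavenging steps in aqueous
solution; otherwise it is estimated from the Smoluchowski encounter rate
k_D = 4π(a_A + a_B)(D_A + D_B)N_A with Stokes–Einstein diffusivities
D = k_B T/(6πηa) and default encounter radii of 2.0 Å. Default
viscosities are handbook values at 298.15 K: water 8.91×10⁻⁴ Pa s,
benzene 6.04×10⁻⁴ Pa s.

## Scan classification and spin crossing

A relaxed-scan profile (energy vs approach distance, relative to the
reactants) is `BARRIERLESS` when every forward step rises by at most
`noise_tol` and the global maximum does not exceed the first point by
more than `noise_tol`; otherwise `ACTIVATED` with barrier
max(E) − E[1]. The default `noise_tol` of 0.5 kJ mol⁻¹ is a
chemical-accuracy noise floor for scan grids — published criteria say
only "continuous decrease", so this tolerance rule is a reconstruction,
and it is configurable. Classification is invariant to energy offsets and
to the traversal direction of the coordinate.

For two-state reactivity, `find_spin_crossing()` interpolates both
spin-state profiles onto the union grid of their overlapping range
(which makes the operation exactly symmetric in its arguments) and
refines each sign change of the energy difference by linear
interpolation. With several crossings, the one at the largest approach
distance is returned — the first met along the approach, where spin
inversion can first occur — and all crossings are attached as an
attribute. Degenerate inputs: profiles shorter than 3 points,
non-monotone coordinates and non-overlapping ranges are errors; exactly
tangent (zero-difference) grid points count as crossings.

## Aggregation

k_overall = Σ_f w_f Σ_i σ_i k_i over the radical-consuming mechanisms
(HAT, RAF, SET, ET; proton-transfer steps react with hydroxide and do not
consume the radical). In non-polar solvent there is a single neutral form
and w_f = 1: this unweighted, degeneracy-weighted sum reproduces the
published benzene totals of the bundled fixtures to within the rounding
of their 3-significant-digit inputs, and is the validated aggregation
rule. In water the convention is w_f = the form's molar fraction; both
`all_pathways` and `primary_only` totals are always computed, because the
published water totals in the bundled study are not exactly recoverable
from its printed per-pathway constants under any single obvious rule —
the fixtures therefore pin the printed water totals in a
`k_overall_ref` field, used for the reference-relative capacities.

Branching ratios are per unique site: Γ_i = 100·w_i·k_i/k_overall, so
three equivalent sites at Γ = 22% each carry 66% of the flux and
Σ σ_i Γ_i = 100. r^T = k_overall/k_overall(reference). One rounding
artefact worth knowing: the bundled study's printed benzene r^T values
(2.60, 1.80) are not the ratios of its own printed rate constants
(3.26×10⁸/1.31×10⁸ = 2.49; 2.29×10⁸/1.31×10⁸ = 1.75); `radscav` reports
the ratio as defined.

## Reference values vs recomputation

Published kinetics tables print ΔG‡ and k but not the tunneling
parameters behind them: e.g. a printed ΔG‡ of 34.0 kJ mol⁻¹ alongside
k = 3.65×10⁷ implies κ ≈ 5.3, which cannot be recomputed without the
unprinted ν‡. The fixtures therefore carry printed k values as
`REFERENCE` rows, taking precedence over recomputation by default
(`use_reference = TRUE`); plain-Eyring recomputation is available by
switching the flag, and is flagged `TST_PLAIN` so the two conventions
cannot be confused.

## The synthetic generator

`generate_network()` emulates the *structure* of a polyphenol study —
RAF at every ring position, HAT at alternating hydroxylated positions,
one SET-PT and one SPLET composite — with ΔrG drawn per mechanism from
normal distributions: HAT mean −100 sd 30, RAF mean −30 sd 15, and the
SET first step mean +300 sd 100 in non-polar solvent versus +50 sd 80 in
water, reflecting the qualitative pattern that electron loss is
prohibitive without dielectric stabilization (with these defaults,
essentially no non-polar SET-PT survives the gate — a tested Monte-Carlo
property). Activation energies of exergonic activated channels come from
a truncated normal (mean 40, sd 20) on (0, 80] kJ mol⁻¹; 20% of channels
are barrierless; half of the activated ones carry Eckart parameters with
ν‡ ~ U(800, 2000) cm⁻¹ and a thermodynamically consistent reverse
barrier V_r = ΔG‡ − ΔrG; ET steps carry vertical energies built from
λ ~ U(20, 120) kJ mol⁻¹. These defaults are loose caricatures of
realistic ranges, chosen once and documented as such — they are not fits.

`generate_scan()` produces Morse-like barrierless descents, activated
profiles with an interior Gaussian barrier (the product well is placed
5 barrier-widths past the peak so the engineered barrier height is
accurate to ~0.1%), and crossing pairs whose energy difference is a
smooth function with exactly one root at a recorded ground-truth
coordinate. Each generator call seeds the single base-R RNG once; the
seed is recorded in the output metadata, and byte-identical files from
equal seeds is a tested property.

What the synthetic data do **not** emulate: correlated errors between
ΔrG and ΔG‡ (real channels obey Bell–Evans–Polanyi-like trends),
conformer and tautomer multiplicity, temperature-dependent pKa, and any
realistic electronic-structure noise. Passing the synthetic tests
therefore establishes the *bookkeeping* — screening logic, dispatch,
aggregation algebra, seed reproducibility — not the chemical accuracy of
any input.

## Problem sizes and runtimes

The test suite and the acceptance script are sized to run comfortably on
one CPU: 100 seeded crossing pairs for the spin-crossing recovery check,
50 six-site networks for end-to-end parameter recovery (per-pathway
rates re-derived from Γ·k_overall match the rate table to 10⁻⁶
relative), 300 three-site networks for the Monte-Carlo gate property,
and a 2×10⁵-point trapezoidal oracle for the Eckart integral. The full
suite runs in well under a minute.

## Known limitations

* No variational TST, small-curvature tunneling, or partition-function
  evaluation from frequencies; the Eckart barrier is fitted to free
  energies, a standard but approximate convention.
* No electronic-coupling prefactor or nonadiabatic correction in the
  Marcus rates; λ must be supplied or derivable from a vertical energy.
* Spin-crossing location is geometric (profile intersection); crossing
  probabilities (Landau–Zener) and true minimum-energy crossing-point
  optimization are out of scope.
* Aqueous aggregation weights are taken from the supplied molar
  fractions; microspecies-resolved speciation and time-dependent product
  distributions are not modelled.
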