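---
title: "Methods: implicit-solvent energetics, alchemical decoupling and helix-12 classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: implicit-solvent energetics, alchemical decoupling and helix-12 classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixbind)
```

helixbind analyses molecular-simulation output for nuclear-receptor
pharmacology questions: does a ligand's ensemble behave like an agonist's
or an antagonist's, and how strong is its binding relative to the natural
hormone? This vignette documents the models, the tunable parameters, the
synthetic-data generators, and the numerical and design choices, in that
order.

## Structures, trajectories and bookkeeping

Structures are parsed from fixed-column PDB; multi-MODEL files are read as
trajectories (one frame per MODEL). Author residue numbering is preserved
verbatim so that selections such as helix 12 (residues 532–552) or the
binding-site triad Glu353/Arg394/His524 mean the same thing on crystal
structures and on the package's synthetic mimics. Alternate locations
other than blank/'A' are dropped; insertion codes are rejected loudly
(receptor ligand-binding domains do not need them, and silently renumbering
would corrupt every downstream selection). Hydrogens are accepted, but
selections default to heavy atoms, and `"backbone"` expands to
{N, CA, C, O} — O included, stated explicitly because "backbone" is
ambiguous in the field.

Homodimer simulations sample two monomers per frame.
`concatenate_monomers()` implements the standard bookkeeping: the
atom-matched chain-A and chain-B trajectories of every run are concatenated
into one monomeric trajectory, doubling the usable simulated time (eight
50-ns dimer runs → 400 ns aggregate → 800 ns of monomer sampling). Time
metadata is optional; operations warn rather than fail without it, since
the frame-level analyses do not need it.

## MM-GB/SA energetics

The scorer implements the single-trajectory scheme: receptor and ligand
coordinates are extracted from the complex frame, so intramolecular bonded
terms cancel exactly and only intermolecular molecular-mechanics terms are
computed:

$$\Delta G \approx E^{inter}_{coul} + E^{inter}_{LJ}
  + G_{solv}(\mathrm{complex}) - G_{solv}(\mathrm{receptor}) - G_{solv}(\mathrm{ligand}),
  \qquad G_{solv} = G_{GB} + \gamma\,\mathrm{SASA} + b.$$

* **Coulomb / Lennard-Jones**: plain pair sums with Lorentz–Berthelot
  combination and *no distance cutoff* — these are end-state rescoring
  energies, not simulation forces, and a cutoff would bias the
  intermolecular terms the estimator depends on.
* **Generalized Born**: Still's interpolation formula over
  Hawkins–Cramer–Truhlar pairwise-descreening effective radii. No GB
  "flavor" is canonical for a small self-contained implementation;
  HCT + Still is the standard fully analytic pairwise scheme, it reduces
  exactly to the Born ion for a single charge, and its descreening
  integral has a closed form that we verify against shell quadrature in
  the tests.
* **SASA**: Shrake–Rupley with a deterministic Fibonacci sphere lattice
  (default 960 points/atom), using the intrinsic GB radii as atomic radii.
  A deterministic point set makes every energy bit-reproducible.

Defaults (`solvent_model()`): k_e = 332.0636 kcal·Å/(mol·e²), ε_in = 1,
ε_out = 78.5, probe 1.4 Å, γ = 0.0072 kcal/(mol·Å²), b = 0. All are
exposed; none is sacred. Known limitations: no salt (no Debye screening
term in GB), no Poisson–Boltzmann cross-check, no entropy term. Absolute
ΔG values from different GB parameterizations are not comparable across
codes — which is why ligand rankings are reported as differences against a
reference ligand (`relative_binding()`), with the sign convention that a
positive ΔΔG means weaker binding; errors combine in quadrature.

## Alchemical decoupling and thermodynamic integration

Decoupling switches the ligand–environment interactions off in two stages,
charges first (vdW intact), then van der Waals:

* The charge stage scales the intermolecular Coulomb term linearly in λ —
  no soft-core is needed because the vdW core still prevents particle
  overlap.
* The vdW stage uses a Beutler-style soft-core,
  $u(\lambda) = 4\varepsilon\lambda\left[A^{-2} - A^{-1}\right]$ with
  $A = \alpha(1-\lambda)^2 + (r/\sigma)^6$, α = 0.5, power 2, which keeps
  ∂H/∂λ finite as the particle vanishes; at λ = 1 it reduces *exactly* to
  plain LJ, so the fully coupled endpoint is the unperturbed Hamiltonian
  to machine precision (a tested identity).

**Node placement.** "5 steps then 12 steps" is read as 5 and 12 uniform
λ-*intervals*, i.e. 6 and 13 equally spaced nodes including both
endpoints. Trapezoidal integration requires endpoint evaluations, so the
interval reading is the only one under which the stated integrator is
well-defined; it is nevertheless a declared interpretation (the phrase
could mean 5 nodes), recorded here prominently.

⟨∂H/∂λ⟩ at each node is estimated by single-particle-move Metropolis
sampling at fixed λ (the package's stand-in for an MD engine, which is out
of scope). The proposal half-width is auto-tuned toward 30–50% acceptance
during burn-in, then frozen so production sampling satisfies detailed
balance. Stage integrals use the trapezoidal rule; node standard errors
propagate through the trapezoid weights in quadrature under a node-wise
independence assumption (correlated-sample corrections are out of scope and
the assumption is stated for that reason). Replicates (default four) pool
by sample mean and SD/√n. Double decoupling closes the cycle:
ΔG_bind = ΔG_decouple(solvent leg) − ΔG_decouple(complex leg). Whether an
upstream analysis used a solvent leg or reported complex-leg-only values is
not always known, so both modes are exposed (`run_ti()` modes `"double"`
and `"complex_only"`) and neither is asserted as canonical.

Validation relies on closed forms: the harmonic alchemical change
H(λ) = ½[(1−λ)k₁+λk₂]x² has ΔF = ½k_BT ln(k₂/k₁) exactly, and
`harmonic_alchemy()` maps it onto the staged schedule (k₁ → √(k₁k₂) → k₂)
so the *production* 6 + 13 node protocol itself is what gets validated;
a Widom-insertion estimate cross-checks the soft-core vdW decoupling of an
LJ particle in a small periodic fluid. Temperature defaults to 310 K
(physiological); k_B in kcal/(mol·K).

## Conformational classification

`rmsd_series()` superposes every frame on a reference by the Kabsch
algorithm (SVD with determinant correction, so reflections are excluded)
and reports RMSD. Fit and measure selections both default to the monomer
backbone: the alternative — measuring H12 only — is offered as an option
because published density curves do not always state their atom set, and
the two choices change curve shapes but not orderings on the package's
generators.

`density_estimate()` uses a Gaussian kernel with Silverman's rule
bandwidth, floored at 0.01 Å so that degenerate samples (e.g. frozen
fixtures) still produce a proper density; the grid spans the data ± 3
bandwidths and the trapezoid integral of the density is checked to 1 ± 1e-3.

`classify_tendency()` compares the query's RMSD-to-antagonist-reference
values with agonist and antagonist controls. Staying *away* from the open
reference (higher RMSD) is agonist-like. The verdict compares sample
medians with a small tie margin (default 0.1 Å): agonist-like when the
query median is at or above the agonist control's minus the margin,
antagonist-like when at or below the antagonist control's plus the margin,
intermediate otherwise, with the nearer control winning if both fire. The
margin exists because a query drawn from the same ensemble as a control
lands above or below that control's sample median by coin flip; a strict
inequality would turn on-distribution queries into "intermediate" half the
time. Verdicts are never reported alone — the medians, ranks and
exhaustive-pairing ordering probabilities P(A<B)+P(B<A)+P(ties)=1 always
accompany them, because the underlying scientific call is comparative, not
thresholded.

`h12_state()` superposes each frame on the *non*-H12 backbone of each
reference and compares unrefitted H12 RMSDs; a 0.5 Å margin separates
closed/open from intermediate so boundary frames do not flip-flop.
`pose_contacts()` quantifies "interaction distance" as minimum heavy-atom
distance ≤ 4.0 Å (configurable) — wide enough to cover hydrogen bonds and
close polar contacts; losing exactly His524 is labelled as such because it
is the classic antagonist binding signature.

## What the synthetic generators emulate — and what they do not

`make_mimic_receptor()` builds a two-helix mimic (31-residue core,
21-residue H12 carrying the 532–552 author numbering) whose H12 can be
rigidly displaced into an "open" position; `gen_two_basin_trajectory()`
draws frames open with a planted probability, adds isotropic Gaussian
jitter (default 0.3 Å), and returns the per-frame labels in a sidecar
table (never embedded in the PDB). This exercises exactly the quantities
the classifier consumes: a bimodal RMSD distribution whose open-basin
weight is known. It does *not* emulate real protein dynamics — no
correlated/elastic-network motion, no partial displacements, no rotamers —
so passing recovery tests demonstrates that the estimator chain is correct
and well-calibrated on its own assumptions, not that any particular real
ligand is an agonist. The displacement default (6, 6, 0) Å gives an H12
shift of ~8.5 Å, of the order of a genuine closed→open transition and far
above the jitter, which is what makes planted labels recoverable; the
jitter σ = 0.3 Å is a typical per-atom backbone fluctuation scale.

`gen_toy_complex()` builds receptor clusters and ligands with printed
charges/LJ parameters at chosen separations (ion-pair and non-interacting
fixtures have closed-form energies); `gen_lambda_series()` attaches the
analytic integral of its constant/linear/quadratic models so the
integrator's bias (e.g. 1.02 vs 1 for 3λ² on 6 nodes) is checked against
hand arithmetic.

## Numerical choices and degenerate inputs

* Coincident atoms in an unmasked pair, all-collinear superposition input,
  and <3 superposition points raise structured geometry errors rather than
  returning NaN.
* Born radii are clamped below by a tiny inverse-radius floor (1e-6 Å⁻¹)
  against pathological over-descreening.
* Zero-variance density input falls back to the bandwidth floor with a
  warning; fewer than 10 values is an error.
* Metropolis acceptance of zero across burn-in raises a diagnostics error
  suggesting a step-size change; a zero proposal width is treated as a
  deliberate frozen-system evaluation (mean = point value, SE = 0).
* All stochastic stages take explicit seeds and are bit-reproducible;
  derived child seeds stay below 2³¹.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
desk-scale inputs chosen to finish quickly while leaving no estimator
unexercised: ≤25-atom random systems for oracle equivalence, a 14-particle
periodic fluid for the Widom cross-check, 500-frame ensembles × 20 seeds
for classifier recovery, 800 production sweeps × 4 replicates for the
harmonic TI, and 120 sweeps per node for the identical-leg null. These
sizes are the package's own validation choices; users analysing real
trajectories simply pass longer inputs through the same functions.

## Known limitations

No explicit-solvent energies, no PB solver, no salt screening in GB, no
normal-mode entropy, no BAR/MBAR estimators, no automated helix detection,
no mmCIF or binary trajectory formats, and no parameter derivation — force
fields are consumed as tables. The pipeline analyses simulation output; it
does not generate dynamics beyond the validation toys.
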