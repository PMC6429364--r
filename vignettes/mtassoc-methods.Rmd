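---
title: "Methods: models, parameters and design choices in mtassoc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mtassoc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mtassoc)
```

mtassoc analyses the association of a compact, positively patched binder
domain (the dynein microtubule-binding domain, MTBD) with a charged
filament carrying intrinsically disordered acidic tails (tubulin E-hooks).
This vignette documents the models behind each stage, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and do
not establish about real trajectories.

## Structure model and model building

A structure is a tibble of atoms (coordinates in Å, element, residue
identity, partial charge in e, intrinsic radius in Å, a segment tag and a
group label). Groups partition atoms into `binder`, `filament` and
`tail_A`..`tail_D`; segments carry finer annotation (helices H1–H6, the
loops LH1/LF, the flap insertion, tails).

**Extended-tail builder.** The disordered tails are unresolved in crystal
structures, so they are built from sequence as all-trans pseudo-chains:
one CA bead per residue at 3.8 Å spacing plus a single side-chain
pseudo-atom (`SC`, 2.5 Å off-axis) for every titratable residue to carry
its formal charge. Only coarse electrostatics and contact statistics of
the tails are analysed downstream, so no attempt is made at realistic
backbone geometry or side-chain rotamers — the builder is deterministic
and dependency-free, which is what the tests need.

**Ionization.** Charges are assigned by a fixed-pKa rule table
(Asp 3.65, Glu 4.25, His 6.0, Lys 10.53, Arg 12.48): at pH 7 this gives
Asp/Glu −1, Lys/Arg +1, His 0 — the standard picture for this system, in
which all titratable residues except histidine are fully ionized at
neutral pH. The formal charge sits on the residue's charge-bearing
side-chain atom (CG/CD/NZ/CZ/ND1 in all-atom structures, the SC bead in
built tails). Termini are left neutral by default because the tails are
internal fragments of tubulin; `charge_termini = TRUE` adds +1/−1 per
chain. No continuum pKa calculation is performed.

**Offset protocol.** `offset_binder()` translates only the binder group
along a unit axis perpendicular to the filament long axis (z by
construction in synthetic systems; the filament runs along x). The
conventional sweep is 0, 5, 15, 25, 35, 45, 55 Å. Distances are
transform-invariant, so offsetting commutes with any whole-system rigid
transform when the axis is co-transformed (tested).

**Clash removal.** How clashes were removed after docking a homologous
binder is generally unreported in modelling protocols; mtassoc uses a
deterministic, auditable stand-in: translate the binder group along +axis
in 0.5 Å steps until no binder–filament heavy-atom pair is below the
cutoff (default 2 Å), reporting the initial clash pairs and the total
displacement. Side-chain repacking is out of scope.

## The synthetic ensemble generator

`generate_system()` builds a toy bound pose that preserves the *relations*
the analysis depends on, not microtubule lattice geometry:

* a rigid filament block of four 64-bead monomer lattices (5 Å spacing)
  along x, with the two dimers meeting beta-to-beta at the center so the
  beta-tail anchors B and D flank the binder footprint (A and C anchor at
  the outer ends);
* four extended tails anchored at the monomer C-terminal positions on the
  top face, using the alpha- and beta-tubulin E-hook sequences by default
  (net charges −8 and −11 by the letter-count rule);
* a ~150-bead binder sphere (lattice beads inside a ball, ~33 Å³ per
  residue) whose bottom sits 4 Å above the filament top — the
  Lennard-Jones minimum of the generic bead type — with helix-like segment
  bands (LH1 at the interface, H4 at the top) assigned by height;
* 16 positive and 16 − net_charge negative charge sites on the outer bead
  shell. With `charge_layout = "interface_clustered"` 13 of 16 positive
  sites sit within 10 Å of the interface plane (fraction 0.81 ≥ 0.7);
  with `"scattered"` they are spread via a Fibonacci direction set and
  rebalanced so the interface slab holds strictly less than half. The
  negative sites stay off the binding face in both layouts — the binding
  face is positively biased in both motor types; the layouts differ in
  where the *positive* charge goes. The filament body carries a few −1
  sites on its top face (the strong negative charge of the system lives
  in the tails, as it does in reality).

`generate_ensemble()` emulates the statistical structure of a restrained
implicit-solvent trajectory rather than its physics:

* filament beads get iid Gaussian jitter of σ = 0.1 Å (harmonic
  restraints);
* binder beads get isotropic jitter with per-axis σ =
  (fluctuation_base + fluctuation_distance_gain · d)/√3, so the planted 3D
  RMSF is exactly `fluctuation_base + gain · d` — the defaults are 1.0 Å
  at contact and 0.02 Å of RMSF per Å of offset, making slope recovery a
  well-posed test (linear RMSF-vs-distance trends are what the fit stage
  is designed for);
* each tail is resampled per frame as a directed random walk from its
  anchor (persistence + Gaussian noise + attraction toward the nearest
  positive binder patch with strength exp(−d / contact_decay_length),
  decay length 15 Å), and charged side chains orient toward the nearest
  positive patch when close — a sampling-bias rendering of
  electrostatically guided soft binding, not a force field. Excluded
  volume is approximate: beads reflect off the filament top, stay at
  least 3.8 Å (CA) / 3.2 Å (SC) from binder beads and 2.4 Å from other
  tail atoms (bonded side chains exempt). The walks are regenerated
  independently each frame; frame-to-frame autocorrelation is not an
  analysis surface anywhere in the package.
* at offsets at or beyond `zero_contact_distance` (default 50 Å, between
  the 45 Å and 55 Å extinction distances seen for the two motor types)
  tail atoms are reflected below the frame's jittered binder minimum z
  minus 4.5 Å, guaranteeing exactly zero contacts at the 4 Å criterion.

Determinism: each replicate run seeds R's RNG with `seed + 1000·run`, so
identical spec + seed gives bitwise-identical ensembles.

What passing tests on this generator show: the analysis chain recovers
planted statistical structure (contact decay, fluctuation gradients,
cluster populations, energy contrasts) from trajectory-shaped data. What
they do not show: anything about force-field accuracy, kinetics, solvent
structure, or the absolute energies of real complexes.

## Contacts

A contact is a heavy-atom pair (one atom from each group) within the
cutoff (default 4.0 Å), counted per atom pair per frame. Hydrogens are
excluded on both sides — the synthetic beads have none and the relevant
crystal structures lack them. Counting uses a spatial cell list above
40 000 candidate pairs with arithmetic identical to the all-pairs
definition (tested for exact equality on random fixtures). Time series are
restricted to a trailing analysis window (default the last half of each
run, the usual equilibrated-tail convention) and averaged across replicate
runs frame-by-frame. Segment percentages are 100·count/total, rounded
half-up to two decimals to match the convention of printed contact tables;
residues are ranked by total contacts with ties broken by ascending
residue number.

## Superposition, RMSF and trend fits

Pairwise superposition is the Kabsch algorithm (SVD of the weighted
cross-covariance; reflections excluded by sign correction; collinear point
sets rejected). RMSF uses the ensemble-average structure as reference,
refined once (mean → fit → re-mean), and only CA atoms of the binder by
default; a configurable `exclude_resno` drops restrained stalk-tip
residues if desired — the default keeps all CA because the synthetic
binder has no restrained tips. With replicates the per-residue RMSF is
averaged across runs first and the scalar mean RMSF is the arithmetic mean
over residues. Trend fits (`fit_linear()`) are ordinary least squares via
`lm()` with the Pearson r reported; `tidy()`/`glance()` follow broom
conventions.

## Daura clustering and cross-state matrices

`daura_cluster()` implements the greedy neighbor-count algorithm: the
frame with the most neighbors within the RMSD cutoff (superposed, CA
selection) seeds a cluster with those neighbors, all are removed, and the
procedure repeats. Ties on neighbor count break to the lowest frame index
— the tie rule is documented because cluster identity depends on it.
Populations are percentages of all frames and are never renormalised by
`top_k()`. Cutoffs: 2 Å suits a compact domain, 1.5 Å a short disordered
tail (fewer residues need a tighter cutoff to resolve multiple clusters).
Tail RMSD superposes on the tail itself; fitting on the restrained
filament instead is possible by passing a different selection, but the
tail-fit default answers the question actually asked (internal
conformation, not position). The pairwise RMSD matrix is O(N²); ensembles
beyond a few thousand frames should be subsampled (the pipeline thins to
~150 frames before clustering).

Cross-state matrices compare free-state and bound-state cluster
representatives; per-column minima flag, for each bound cluster, the most
similar free cluster. Because the bolding convention of printed tables is
ambiguous between columns and rows, both minima sets are computed.

## MM/GB energetics

Energies follow E = E_elec + E_VDW with
E_elec = Coulomb + GB polarization:

* Coulomb: k q_i q_j / (ε_in r), k = 332.0636 kcal·Å/(mol·e²), no cutoff,
  ε_in = 1 (the standard MM/GB convention; the continuum solver below uses
  2 for its solute region — the two conventions intentionally differ);
* Born radii: Hawkins–Cramer–Truhlar pairwise descreening with neighbor
  radii scaled by 0.72 (the conventional 0.7–0.85 band) and the stated
  12 Å descreening cutoff; the closed-form pair term is verified against
  numeric integration of the 1/r⁴ descreening integral;
* GB: Still's pair function f = sqrt(r² + R_i R_j exp(−r²/4R_iR_j)) with
  Debye screening exp(−κ f), κ from I = 0.15 M at 300 K; the isolated-ion
  limit reproduces the Born formula to 1e-9;
* Lennard-Jones 12-6 with Lorentz–Berthelot combination; synthetic
  pseudo-atoms use one generic type (ε = 0.1 kcal/mol, r_min = 4.0 Å)
  unless a per-type table is supplied.

This GB flavour is a documented stand-in: the exact GB variant behind
published numbers is rarely recoverable, so absolute energies are not
comparable to any specific MD package — the analysis surfaces are the
decomposition identities (E = E_elec + E_VDW exactly;
ΔE = E_complex − E_A − E_B exactly) and qualitative contrasts.

`binding_energy()` evaluates complex and parts at fixed coordinates
(rigid-body protocol). The complex energy is assembled part-wise
(E_A + E_B + cross-Coulomb + cross-LJ + ΔGB): identical to the all-pairs
total in exact arithmetic, but the binding difference is then computed
without subtracting two nearly equal large numbers — with coarse
pseudo-atoms, intra-part Lennard-Jones terms can reach 1e9 kcal/mol and a
naive difference of totals would be pure floating-point noise.
`ensemble_binding_energy()` averages over frames with at least one
tail–binder contact (evenly subsampled to `max_snapshots`, default 60, to
bound cost), reports the population SD, and with `strip_tails = TRUE`
deletes all tail atoms from complex and parts alike at fixed coordinates.
On default synthetic systems the tail-stripped ΔE is near zero while the
full ΔE is clearly negative: the favorable cross-group interactions are
tail-mediated by construction.

## Linearized Poisson-Boltzmann electrostatics

`solve_lpbe()` discretises ∇·(ε∇φ) − ε_out κ² φ = −4π ρ on a cubic grid
with the 7-point stencil, face dielectrics as arithmetic means of node
values, trilinear charge spreading to the 8 nearest nodes, and Debye
screening only in the solvent region. The solute region is the union of
probe-inflated atom spheres (probe 1.4 Å) — a deliberate simplification of
a full molecular-surface construction, acceptable because correctness is
checked against analytic oracles, not against any particular continuum
package's output. Defaults mirror common practice for this system: 2
grids/Å, 70% box fill ("perfil"), ε 2/80, I = 0.15 M. Boundary potentials
are Debye-screened monopole sums; the interior is solved by red-black SOR
with ω = 2/(1 + sin(π/n)), converging when the largest update falls below
`tol` (default 1e-5 kT/e) and erroring with the residual if `max_iter` is
exhausted. Potentials are in kT/e at 300 K.

Verified properties: a unit charge in uniform ε = 80 salt water matches
the Debye–Hückel closed form within 0.2% at 10–15 Å (3% asserted);
solutions superpose in the charges; halving the spacing moves the far
field by under 2% on a Born-ion fixture; a mirror charge pair gives an
antisymmetric field.

`trace_field_lines()` integrates unit-speed streamlines of E = −∇φ
(centered differences, trilinear interpolation) by fixed-step RK4 in both
directions from each seed, terminating at the grid margin, below a field
floor, or inside a sink radius around a supplied charge center. Lines are
radial around an isolated ion to well under 5° and straight in uniform
fields. `surface_potential()` averages trilinear samples on each atom's
sphere (Fibonacci directions); `interface_charge_asymmetry()` reports the
fraction of positive charge within a slab (default 10 Å) of the interface
plane — ≥ 0.7 for the interface-clustered layout, < 0.5 for scattered, by
the generator contract.

## Pipeline and problem sizes

`run_pipeline()` chains build → offset sweep → ensembles → contacts →
RMSF → fits → clustering → energies → (optional) LPBE from one
`run_config()`, writes TSV/OpenDX/CSV outputs plus a manifest with seed
and per-stage wall time, and is bit-identical on reruns with the same
configuration. Default problem sizes are chosen to make the statistics
stable at interactive cost: 3 replicate runs of 500 frames per offset for
the headline sweep (the acceptance script and test use exactly this),
20–100 frames for unit tests, ~150-frame thinning before clustering,
up to 60 snapshots for ensemble energies, and a coarse 0.5 grids/Å lattice
for the full-system LPBE overview (analytic-oracle tests use 2 grids/Å on
small boxes). The full acceptance computation runs in roughly 6–8 minutes
on one CPU.

## Known limitations

* The generator is a statistical mimic: no thermodynamics, kinetics,
  solvent structure or lattice geometry; energies of synthetic systems
  are internally consistent but not comparable to any experiment.
* The extended-tail builder makes no claim of conformational realism;
  only contact/electrostatic summaries of the tails are meaningful.
* GB here is one member of the GB family (HCT radii, Still pairing);
  absolute solvation energies differ from other flavours.
* The LPBE dielectric boundary is a probe-inflated van der Waals surface,
  not a molecular (solvent-excluded) surface; potentials very close to
  the surface differ from molecular-surface solvers, while the far field
  agrees with the analytic limits.
* Printed reference contact percentages for one system are internally
  inconsistent at the last decimal (two entries differ by 0.01 from exact
  arithmetic on their own printed counts); the package reports the exact
  arithmetic.
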