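# mtassoc

Analysis of how a dynein microtubule-binding domain (MTBD) associates with
a microtubule decorated with disordered, acidic C-terminal tubulin tails
(E-hooks).

## The scientific problem

Dynein motors attach to microtubules through a small helical domain, the
MTBD. The microtubule surface is strongly negative, and each tubulin
carries an intrinsically disordered Glu/Asp-rich C-terminal tail (the
E-hook, net charge around −10 e) that is invisible to crystallography but
dominates the long-range electrostatics of the encounter. Understanding
association therefore requires tracking, as a function of the
MTBD-microtubule separation *d*:

* the number of heavy-atom contacts between E-hooks and the MTBD
  (a contact is a pair within 4 Å),
* the conformational fluctuations of the MTBD,
  RMSF_i = sqrt(mean_t ||r_i(t) − r̄_i||²), and the ensemble mean
  RMSF = (1/N) Σ_i RMSF_i,
* the conformational states of the tails, found by Daura (GROMOS-style)
  clustering at an RMSD cutoff and compared between bound and free states
  through the cross-state RMSD matrix of cluster representatives,
* the rigid-body binding energy
  ΔE_binding = E_complex − E_MTBD − E_MT, with each term an MM/GB energy
  E = E_elec + E_VDW (Coulomb + generalized-Born polarization +
  Lennard-Jones), averaged over contact-bearing snapshots, and
* the continuum electrostatic potential around the complex from a
  finite-difference linearized Poisson-Boltzmann (LPBE) solver, with
  electrostatic field lines traced from the potential.

mtassoc implements this entire analysis chain as composable, tibble-first
R functions, plus a synthetic ensemble generator that emulates the
statistical structure of restrained implicit-solvent trajectories (a rigid
two-dimer filament, four anchored tails, a ~150-residue binder with
configurable surface-charge placement, and planted distance-dependent
contact frequency and fluctuation amplitude), so every stage can be tested
end-to-end without any trajectory data.

## Worked example

```r
library(mtassoc)

spec <- synthetic_spec(n_frames = 100, n_runs = 2, seed = 42)
system <- generate_system(spec)          # filament + tails + binder, bound pose

# sweep the binder away from the filament and analyse each ensemble
res <- lapply(c(0, 15, 35, 55), function(d) {
  e  <- generate_ensemble(offset_binder(system, d), spec, offset_d = d)
  ct <- contact_table(e, tail_group = "tail_b", cutoff = 4)
  tibble::tibble(offset = d,
                 mean_contacts = mean(ct$per_frame$n_contacts),
                 mean_rmsf = mean_rmsf(rmsf(analysis_window(e))))
}) |> dplyr::bind_rows()
res
#> # A tibble: 4 × 3
#>   offset mean_contacts mean_rmsf
#>    <dbl>         <dbl>     <dbl>
#> 1      0         34.7      0.987
#> 2     15         10.9      1.28
#> 3     35          0.07     1.68
#> 4     55          0        2.07

glance(fit_linear(res$offset, res$mean_rmsf))
#> # A tibble: 1 × 5
#>    slope intercept     r r.squared     n
#>    <dbl>     <dbl> <dbl>     <dbl> <int>
#> 1 0.0197     0.987 1.000     1.000     4
```

Contacts fall with distance (34.7 pairs per frame at contact, a stray
0.07 at 35 Å) and are exactly zero at/beyond the planted threshold
(50 Å by default), while the mean RMSF grows linearly — the fitted slope
0.0197 Å/Å recovers the generator's planted fluctuation gain of 0.02 Å of
RMSF per Å of offset. The same pipeline runs in one call from a config:
`run_pipeline(run_config(...))` writes contact tables, RMSF profiles and
fits, bound/free cluster cross-matrices, binding energies with and without
tails, and an OpenDX potential grid with field lines; `render_report()`
formats the bundle as Markdown tables.

Bundled reference tables (`reference_table()`) carry reported per-segment
contact counts, per-residue contact totals, bound/free cluster RMSD
matrices and MM/GB binding-energy components for the cytoplasmic and
axonemal MTBD systems, as worked-example inputs for
`aggregate_by_segment()`, `top_contact_residues()`,
`cross_state_matrix()` and `binding_delta()`:

```r
ref <- reference_table("binding_components")
binding_delta(ref$e_complex, ref$e_mtbd, ref$e_mt)
#> [1] -40.84  20.76 -28.75  25.05
```

## Package layout

| file | contents |
|---|---|
| `R/structure.R`, `R/pdb-io.R` | atom-table structures, PDB/PQR I/O, tail builder, rigid transforms, offsets, clash removal, ionization |
| `R/synthetic.R` | synthetic system and replicate-ensemble generator |
| `R/contacts.R` | contact counting (cell list == all-pairs), series, segment/residue aggregation |
| `R/conformation.R` | Kabsch superposition, RMSD, RMSF, linear trend fits |
| `R/clustering.R` | Daura clustering, top-k, cross-state RMSD matrices |
| `R/energetics.R` | Coulomb, HCT Born radii, GB, LJ, rigid-body binding energies |
| `R/pbe.R`, `R/fieldlines.R` | LPBE solver, surface potential, OpenDX export, field-line tracing |
| `R/pipeline.R`, `R/report.R` | end-to-end orchestration and Markdown report |

The methods vignette (`vignettes/mtassoc-methods.Rmd`) documents the
models, parameter choices and limitations.
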