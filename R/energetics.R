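# Molecular-mechanics/generalized-Born energies and the rigid-body
# binding-energy decomposition
#   dE_binding = E_complex - E_partA - E_partB,   E = E_elec + E_VDW
# with E_elec = Coulomb + GB polarization (Still's pairwise function over
# HCT pairwise-descreening effective Born radii, Debye-screened) and E_VDW
# a 12-6 Lennard-Jones sum with Lorentz-Berthelot combination.

#' Force-field parameters for MM/GB energies
#'
#' @param eps_in solute dielectric used for Coulomb and the GB self-term
#'   (standard MM/GB convention: 1).
#' @param eps_out solvent dielectric.
#' @param ionic_strength mol/L, converted to a Debye screening factor in the
#'   GB pair function.
#' @param born_cutoff Angstrom; pairs beyond this are excluded from Born
#'   radius descreening.
#' @param hct_scale HCT descreening scaling factor applied to neighbor
#'   radii (0.72, in the conventional 0.7-0.85 band; 1 gives unscaled
#'   spheres).
#' @param lj_eps,lj_rmin generic Lennard-Jones well depth (kcal/mol) and
#'   minimum-energy distance (Angstrom) used for atoms without explicit
#'   parameters (coarse pseudo-atoms).
#' @param temperature Kelvin.
#' @return A list of class `ff_params`.
#' @export
ff_params <- function(eps_in = 1, eps_out = 80, ionic_strength = 0.15,
                      born_cutoff = 12.0, hct_scale = 0.72, lj_eps = 0.1,
                      lj_rmin = 4.0, temperature = 300) {
  stopifnot(eps_in > 0, eps_out > 0, born_cutoff > 0, lj_eps >= 0,
            lj_rmin > 0, hct_scale > 0, hct_scale <= 1)
  structure(list(eps_in = eps_in, eps_out = eps_out,
                 ionic_strength = ionic_strength,
                 kappa = debye_kappa(ionic_strength, eps_out, temperature),
                 born_cutoff = born_cutoff, hct_scale = hct_scale,
                 lj_eps = lj_eps, lj_rmin = lj_rmin,
                 temperature = temperature),
            class = "ff_params")
}

dist_matrix <- function(xyz) {
  d2 <- pair_dist2(xyz, xyz)
  diag(d2) <- 0
  sqrt(d2)
}

#' Coulomb energy of a structure
#'
#' `sum_{i<j} k q_i q_j / (eps_in r_ij)` with
#' `k = 332.0636 kcal A / (mol e^2)`; no distance cutoff.
#'
#' @param s an `mt_structure` with charges assigned.
#' @param params [ff_params()].
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(s, params = ff_params()) {
  q <- s$charge
  nz <- which(q != 0)
  if (length(nz) < 2) return(0)
  xyz <- coords(s)[nz, , drop = FALSE]
  r <- dist_matrix(xyz)
  if (any(r[upper.tri(r)] < 1e-6)) abort("overlapping charged atoms")
  qq <- outer(q[nz], q[nz])
  sum((qq / r)[upper.tri(r)]) * K_COULOMB / params$eps_in
}

#' Effective Born radii by HCT pairwise descreening
#'
#' `1/R_i = 1/rho_i - sum_j H(r_ij, rho_j)` where H is the analytic
#' integral of `1/r^4` over the descreening sphere of neighbor j
#' (Hawkins-Cramer-Truhlar, unit scaling factors). Pairs beyond
#' `born_cutoff` are excluded; `R_i` never falls below the intrinsic
#' radius of an isolated atom.
#'
#' @param s an `mt_structure` with positive intrinsic radii.
#' @param params [ff_params()].
#' @return Numeric vector of per-atom effective radii, Angstrom.
#' @export
born_radii <- function(s, params = ff_params()) {
  rho <- s$radius
  n <- nrow(s)
  if (n == 0) return(numeric(0))
  stopifnot(all(rho > 0))
  r <- dist_matrix(coords(s))
  inv <- 1 / rho
  for (i in seq_len(n)) {
    js <- which(r[i, ] > 0 & r[i, ] <= params$born_cutoff)
    if (length(js) > 0) {
      inv[i] <- inv[i] - sum(hct_term(r[i, js], rho[i],
                                      params$hct_scale * rho[js]))
    }
  }
  pmax(1 / pmax(inv, 1e-6), rho)
}

# HCT descreening integral of one neighbor sphere (radius rho_j at distance
# rij) as seen by atom i with intrinsic radius rho_i
hct_term <- function(rij, rho_i, rho_j) {
  U <- rij + rho_j
  L <- pmax(rho_i, abs(rij - rho_j))
  engulfed <- rho_i >= U              # neighbor buried inside atom i
  term <- 0.5 * (1 / L - 1 / U + (rij / 4) * (1 / U^2 - 1 / L^2) +
                   (1 / (2 * rij)) * log(L / U) +
                   (rho_j^2 / (4 * rij)) * (1 / L^2 - 1 / U^2))
  term[engulfed] <- 0
  term
}

#' Generalized Born polarization energy
#'
#' Still's pairwise function with Debye screening:
#' `E_GB = -(k/2) sum_{i,j} (1/eps_in - exp(-kappa f_ij)/eps_out)
#'  q_i q_j / f_ij`, `f_ij = sqrt(r_ij^2 + R_i R_j exp(-r_ij^2/(4 R_i R_j)))`
#' including the i = j self terms (f_ii = R_i).
#'
#' @param s an `mt_structure` with charges assigned.
#' @param params [ff_params()].
#' @param radii optional precomputed effective Born radii.
#' @return Energy in kcal/mol.
#' @export
gb_energy <- function(s, params = ff_params(), radii = NULL) {
  q <- s$charge
  if (all(q == 0)) return(0)
  if (is.null(radii)) radii <- born_radii(s, params)
  nz <- which(q != 0)
  xyz <- coords(s)[nz, , drop = FALSE]
  qn <- q[nz]; Rn <- radii[nz]
  r2 <- pair_dist2(xyz, xyz)
  RR <- outer(Rn, Rn)
  f <- sqrt(r2 + RR * exp(-r2 / (4 * RR)))
  pref <- 1 / params$eps_in - exp(-params$kappa * f) / params$eps_out
  -(K_COULOMB / 2) * sum(pref * outer(qn, qn) / f)
}

#' Lennard-Jones (12-6) energy
#'
#' `sum eps_ij [ (rmin_ij/r)^12 - 2 (rmin_ij/r)^6 ]` with Lorentz-Berthelot
#' combination. When `group_a`/`group_b` are given only cross-group pairs
#' are summed; otherwise all pairs.
#'
#' @param s an `mt_structure`.
#' @param params [ff_params()] providing the generic type parameters.
#' @param group_a,group_b optional group labels restricting to cross pairs.
#' @param lj_table optional tibble with `elety`, `eps`, `rmin` overriding the
#'   generic parameters per atom type.
#' @return Energy in kcal/mol.
#' @export
lj_energy <- function(s, params = ff_params(), group_a = NULL,
                      group_b = NULL, lj_table = NULL) {
  n <- nrow(s)
  if (n < 2) return(0)
  eps_i <- rep(params$lj_eps, n)
  rmin_i <- rep(params$lj_rmin, n)
  if (!is.null(lj_table)) {
    m <- match(s$elety, lj_table$elety)
    eps_i[!is.na(m)] <- lj_table$eps[m[!is.na(m)]]
    rmin_i[!is.na(m)] <- lj_table$rmin[m[!is.na(m)]]
  }
  xyz <- coords(s)
  if (is.null(group_a)) {
    r <- dist_matrix(xyz)
    ut <- upper.tri(r)
    if (any(r[ut] < 1e-6)) abort("overlapping atoms in LJ energy")
    epsm <- sqrt(outer(eps_i, eps_i))
    rminm <- outer(rmin_i, rmin_i, "+") / 2
    sr6 <- (rminm / r)^6
    return(sum((epsm * (sr6^2 - 2 * sr6))[ut]))
  }
  ia <- group_idx(s, group_a); ib <- group_idx(s, group_b)
  r <- sqrt(pair_dist2(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE]))
  if (any(r < 1e-6)) abort("overlapping atoms in LJ energy")
  epsm <- sqrt(outer(eps_i[ia], eps_i[ib]))
  rminm <- outer(rmin_i[ia], rmin_i[ib], "+") / 2
  sr6 <- (rminm / r)^6
  sum(epsm * (sr6^2 - 2 * sr6))
}

#' Total MM/GB energy components of a structure
#'
#' @param s an `mt_structure` with charges and radii.
#' @param params [ff_params()].
#' @return Tibble with one row: `e_elec` (Coulomb + GB), `e_vdw`, `e_mm_gb`
#'   (their exact sum).
#' @export
mmgb_energy <- function(s, params = ff_params()) {
  e_el <- coulomb_energy(s, params) + gb_energy(s, params)
  e_vdw <- lj_energy(s, params)
  tibble(e_elec = e_el, e_vdw = e_vdw, e_mm_gb = e_el + e_vdw)
}

#' Binding-energy arithmetic
#'
#' `dE_binding = E_complex - E_partA - E_partB`, applied to component
#' energies exactly as printed or computed.
#'
#' @param e_complex,e_part_a,e_part_b component energies, kcal/mol.
#' @return dE_binding in kcal/mol.
#' @export
binding_delta <- function(e_complex, e_part_a, e_part_b) {
  e_complex - e_part_a - e_part_b
}

#' Rigid-body binding energy of a two-part complex
#'
#' Computes the MM/GB energy of the complex and of each part alone at fixed
#' (unrelaxed) coordinates, so the difference reflects interaction and
#' desolvation only.
#'
#' @param s an `mt_structure`.
#' @param group_a,group_b group labels partitioning the atoms of interest
#'   (may be vectors of labels); they must not overlap.
#' @param params [ff_params()].
#' @return Tibble with `e_complex`, `e_part_a`, `e_part_b` and `de_binding`
#'   (their exact Eq.-style difference), kcal/mol.
#' @export
binding_energy <- function(s, group_a = "binder",
                           group_b = c("filament", "tail_a", "tail_b",
                                       "tail_c", "tail_d"),
                           params = ff_params()) {
  ia <- group_idx(s, group_a); ib <- group_idx(s, group_b)
  if (length(intersect(ia, ib)) > 0) abort("groups overlap")
  if (length(ia) == 0 || length(ib) == 0) abort("empty group")
  sub <- s[sort(c(ia, ib)), ]
  class(sub) <- class(s)
  sa <- s[ia, ]; class(sa) <- class(s)
  sb <- s[ib, ]; class(sb) <- class(s)
  e_a <- mmgb_energy(sa, params)$e_mm_gb
  e_b <- mmgb_energy(sb, params)$e_mm_gb
  # assemble the complex energy part-wise: identical in exact arithmetic to
  # the all-pairs total, but the binding difference is then free of the
  # catastrophic cancellation that large intra-part terms would cause
  cross_coul <- coulomb_cross(s, ia, ib, params)
  cross_lj <- lj_energy(s, params, group_a, group_b)
  d_gb <- gb_energy(sub, params) - gb_energy(sa, params) -
    gb_energy(sb, params)
  e_cx <- e_a + e_b + cross_coul + cross_lj + d_gb
  tibble(e_complex = e_cx, e_part_a = e_a, e_part_b = e_b,
         de_binding = binding_delta(e_cx, e_a, e_b))
}

coulomb_cross <- function(s, ia, ib, params) {
  qa <- s$charge[ia]; qb <- s$charge[ib]
  nza <- which(qa != 0); nzb <- which(qb != 0)
  if (length(nza) == 0 || length(nzb) == 0) return(0)
  xyz <- coords(s)
  r <- sqrt(pair_dist2(xyz[ia[nza], , drop = FALSE],
                       xyz[ib[nzb], , drop = FALSE]))
  if (any(r < 1e-6)) abort("overlapping charged atoms")
  K_COULOMB / params$eps_in * sum(outer(qa[nza], qb[nzb]) / r)
}

#' Ensemble-averaged binding energy over contact-bearing snapshots
#'
#' Selects the frames of the contact table with at least one contact,
#' optionally strips all tail atoms (from complex and parts alike, at fixed
#' coordinates), and reports the mean and population SD of the rigid-body
#' binding energy over those snapshots.
#'
#' @param e an `mt_ensemble`.
#' @param ct an `mt_contact_table` computed on the same ensemble (same
#'   window).
#' @param params [ff_params()].
#' @param strip_tails drop all `tail_*` atoms before the energy evaluation.
#' @param max_snapshots cap on evaluated snapshots (evenly subsampled) to
#'   bound cost; `Inf` evaluates all selected frames.
#' @return Tibble of class `mt_energy`: one row with mean `e_complex`,
#'   `e_part_a`, `e_part_b`, `de_binding`, `sd` (population SD of
#'   `de_binding`) and `n_snapshots`.
#' @export
ensemble_binding_energy <- function(e, ct, params = ff_params(),
                                    strip_tails = FALSE,
                                    max_snapshots = 60) {
  stopifnot(inherits(ct, "mt_contact_table"))
  sel <- ct$per_frame$frame[ct$per_frame$n_contacts >= 1]
  if (length(sel) == 0) {
    abort(sprintf("no contact-bearing snapshot among %d frames",
                  nrow(ct$per_frame)))
  }
  ew <- analysis_window(e, ct$window %||% 0.5)
  use <- sel
  if (is.finite(max_snapshots) && length(use) > max_snapshots) {
    use <- sel[unique(round(seq(1, length(sel), length.out = max_snapshots)))]
  }
  rows <- vector("list", length(use))
  for (k in seq_along(use)) {
    fr <- ensemble_frame(ew, use[k])
    if (strip_tails) {
      keep <- !grepl("^tail_", fr$group)
      fr <- fr[keep, ]
      class(fr) <- c("mt_structure", class(tibble()))
    }
    rows[[k]] <- binding_energy(
      fr, group_a = "binder",
      group_b = intersect(c("filament", "tail_a", "tail_b", "tail_c",
                            "tail_d"), unique(fr$group)),
      params = params)
  }
  all_rows <- bind_rows(rows)
  out <- tibble(
    e_complex = mean(all_rows$e_complex),
    e_part_a = mean(all_rows$e_part_a),
    e_part_b = mean(all_rows$e_part_b),
    de_binding = mean(all_rows$de_binding),
    sd = sqrt(mean((all_rows$de_binding - mean(all_rows$de_binding))^2)),
    n_snapshots = length(use))
  attr(out, "per_snapshot") <- all_rows
  class(out) <- c("mt_energy", class(out))
  out
}
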