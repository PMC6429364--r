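# Synthetic binder-filament-tail systems and replicate conformational
# ensembles. These stand in for implicit-solvent MD trajectories: the
# filament is restrained, the binder fluctuates with a planted
# distance-dependent amplitude, and the disordered tails are resampled each
# frame as biased directed walks whose attraction to the binder's positive
# patches decays with the binder-filament offset.

#' Ensemble container
#'
#' Ordered frames of coordinates over a fixed atom roster with per-frame
#' replicate-run labels. Coordinates are held as a dense
#' `frames x atoms x 3` array; use [as_tibble()] methods on derived results
#' for tidy analysis output.
#'
#' @param topology an `mt_structure` describing the atoms.
#' @param xyz numeric array `n_frames x n_atoms x 3`.
#' @param run integer run label per frame.
#' @return An object of class `mt_ensemble`.
#' @export
mt_ensemble <- function(topology, xyz, run = rep(1L, dim(xyz)[1])) {
  stopifnot(inherits(topology, "mt_structure"))
  if (length(dim(xyz)) != 3 || dim(xyz)[2] != nrow(topology) || dim(xyz)[3] != 3) {
    abort("xyz must be an n_frames x n_atoms x 3 array matching the topology")
  }
  if (!all(is.finite(xyz))) abort("ensemble coordinates must be finite")
  if (length(run) != dim(xyz)[1]) abort("one run label per frame required")
  structure(list(topology = topology, xyz = xyz, run = as.integer(run)),
            class = "mt_ensemble")
}

#' @export
print.mt_ensemble <- function(x, ...) {
  cat(sprintf("<mt_ensemble> %d frames (%d run(s)) x %d atoms\n",
              n_frames(x), length(unique(x$run)), nrow(x$topology)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param e an `mt_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(e) dim(e$xyz)[1]

#' Extract one frame as a structure
#' @param e an `mt_ensemble`.
#' @param i frame index.
#' @return An `mt_structure` with that frame's coordinates.
#' @export
ensemble_frame <- function(e, i) {
  stopifnot(i >= 1, i <= n_frames(e))
  set_coords(e$topology, e$xyz[i, , ])
}

#' Subset an ensemble by frame index
#' @param e an `mt_ensemble`.
#' @param idx frame indices to keep.
#' @return An `mt_ensemble` with the selected frames.
#' @export
ensemble_subset <- function(e, idx) {
  mt_ensemble(e$topology, e$xyz[idx, , , drop = FALSE], run = e$run[idx])
}

#' Trailing analysis window of an ensemble
#'
#' Restricts each run to its trailing fraction of frames, mirroring the
#' usual practice of analysing only the equilibrated tail of a trajectory.
#'
#' @param e an `mt_ensemble`.
#' @param window fraction in (0, 1] of each run's frames to keep, from the end.
#' @return An `mt_ensemble`.
#' @export
analysis_window <- function(e, window = 0.5) {
  stopifnot(window > 0, window <= 1)
  keep <- unlist(lapply(unique(e$run), function(r) {
    idx <- which(e$run == r)
    idx[idx > idx[length(idx)] - floor(length(idx) * window)]
  }))
  ensemble_subset(e, sort(keep))
}

# ---------------------------------------------------------------------------

#' Specification of a synthetic binder-filament-tail system
#'
#' Defines the study conditions emulated by the generator: a rigid
#' two-dimer filament block with four anchored disordered tails (defaults
#' are the alpha- and beta-tubulin E-hook sequences), a compact ~150-residue
#' binder with configurable surface-charge placement, and replicate
#' ensembles whose contact frequency and fluctuation amplitude depend on the
#' binder-filament offset.
#'
#' @param binder_n_residues beads in the binder (one per residue).
#' @param charge_layout `"interface_clustered"` (processive-motor-like: most
#'   positive charge at the binding face) or `"scattered"` (beating-motor-like:
#'   positive charge spread over the whole surface).
#' @param binder_net_charge net charge of the binder in e.
#' @param tail_sequences named character vector `A`..`D`; defaults assign the
#'   alpha-tubulin tail to chains A/C and the beta-tubulin tail to B/D.
#' @param n_frames frames per replicate run.
#' @param n_runs replicate runs.
#' @param seed RNG seed; identical spec + seed gives bitwise-identical output.
#' @param contact_decay_length Angstrom; decay length of the tail-binder
#'   attraction bias with offset.
#' @param fluctuation_base Angstrom; planted binder RMSF at offset 0.
#' @param fluctuation_distance_gain Angstrom of RMSF per Angstrom of offset.
#' @param zero_contact_distance Angstrom; offsets at or beyond this are
#'   guaranteed contact-free.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(binder_n_residues = 150L,
                           charge_layout = c("interface_clustered", "scattered"),
                           binder_net_charge = 0L,
                           tail_sequences = c(A = ehook_sequences[["alpha"]],
                                              B = ehook_sequences[["beta"]],
                                              C = ehook_sequences[["alpha"]],
                                              D = ehook_sequences[["beta"]]),
                           n_frames = 500L,
                           n_runs = 3L,
                           seed = 42L,
                           contact_decay_length = 15,
                           fluctuation_base = 1.0,
                           fluctuation_distance_gain = 0.02,
                           zero_contact_distance = 50) {
  charge_layout <- match.arg(charge_layout)
  stopifnot(binder_n_residues > 0, n_frames > 0, n_runs >= 1,
            contact_decay_length > 0, fluctuation_base > 0,
            fluctuation_distance_gain >= 0, zero_contact_distance > 0)
  if (!all(c("A", "B", "C", "D") %in% names(tail_sequences))) {
    abort("tail_sequences must name tails A, B, C and D")
  }
  structure(list(binder_n_residues = as.integer(binder_n_residues),
                 charge_layout = charge_layout,
                 binder_net_charge = as.integer(binder_net_charge),
                 tail_sequences = tail_sequences,
                 n_frames = as.integer(n_frames), n_runs = as.integer(n_runs),
                 seed = as.integer(seed),
                 contact_decay_length = contact_decay_length,
                 fluctuation_base = fluctuation_base,
                 fluctuation_distance_gain = fluctuation_distance_gain,
                 zero_contact_distance = zero_contact_distance),
            class = "synthetic_spec")
}

# deterministic, roughly uniform directions on the unit sphere
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Filament geometry constants: two alpha-beta pseudo-dimers along x.
.fil_spacing <- 5       # bead lattice spacing, Angstrom
.fil_nx <- 4            # beads per monomer along each axis
.fil_top <- 15          # z of the filament top bead layer
.bound_gap <- 4         # binder bottom above the top layer (at the LJ minimum)

#' Generate a synthetic binder-filament-tail system
#'
#' Builds the bound pose: a rigid filament block of two pseudo-dimers (four
#' monomer bead blocks along x, chains A-D), four extended tails anchored at
#' the monomer C-terminal positions on the top surface (B and D proximal to
#' the binder), and a compact spherical binder bead blob placed on top.
#' Binder charges are placed per the layout contract: with
#' `interface_clustered` at least 70% of the positive charge lies within
#' 10 Angstrom of the interface plane; with `scattered` it is spread evenly
#' over the surface (under 50% in the slab on this geometry). Construction
#' is fully deterministic for a given spec.
#'
#' @param spec a [synthetic_spec()].
#' @return An `mt_structure` with groups `binder`, `filament`,
#'   `tail_A`..`tail_D` and ionization assigned.
#' @export
generate_system <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  sp <- .fil_spacing
  # --- filament: 4 monomer blocks along x. The two dimers meet beta-to-beta
  # at the center (order A,B | D,C) so the beta-tail anchors B and D flank the
  # binder footprint; this emulates the proximity relations of the bound
  # pose, not microtubule lattice geometry.
  monomers <- list()
  chains <- c("A", "B", "D", "C")
  for (m in 0:3) {
    gx <- (seq_len(.fil_nx) - 1) * sp + m * .fil_nx * sp
    gy <- (seq_len(.fil_nx) - 1) * sp
    gz <- (seq_len(.fil_nx) - 1) * sp
    grid <- expand.grid(x = gx, y = gy, z = gz)
    monomers[[m + 1]] <- tibble(
      elety = "CA", element = "C", x = grid$x, y = grid$y, z = grid$z,
      chain = chains[m + 1], resno = seq_len(nrow(grid)),
      resname = "GLY", segment = "BODY", group = "filament")
  }
  filament <- bind_rows(monomers)

  # a few fixed -1 charges per monomer on the top layer (the filament body
  # itself is acidic, though far less than the tails)
  body_charges <- integer(0)
  for (m in 0:3) {
    top <- which(filament$z == max(filament$z) &
                   filament$chain == chains[m + 1])
    body_charges <- c(body_charges, top[seq(1, length(top), length.out = 4)])
  }

  # --- binder: lattice beads inside a sphere, ~1 bead per residue
  nb <- spec$binder_n_residues
  r_blob <- (nb * 33 * 3 / (4 * pi))^(1 / 3)   # ~33 A^3 per residue
  g <- seq(-ceiling(r_blob), ceiling(r_blob), by = 3.2)
  cand <- as.matrix(expand.grid(x = g, y = g, z = g))
  d <- sqrt(rowSums(cand^2))
  cand <- cand[order(d), , drop = FALSE][seq_len(nb), , drop = FALSE]
  # center of the filament top face, binder bottom at .bound_gap above it
  cx <- mean(range(filament$x)); cy <- mean(range(filament$y))
  zmin_blob <- min(cand[, 3])
  binder <- tibble(
    elety = "CA", element = "C",
    x = cand[, 1] + cx, y = cand[, 2] + cy,
    z = cand[, 3] - zmin_blob + .fil_top + .bound_gap,
    chain = "M", resno = seq_len(nb), resname = "GLY",
    segment = "BODY", group = "binder")
  # helix-like segment bands by height: interface-proximal loops/helices at
  # the bottom, stalk-side helices on top (coarse mimic of the domain map)
  bands <- c("LH1", "H1", "H5", "H2", "H6", "H3", "H4")
  qz <- stats::quantile(binder$z, probs = seq(0, 1, length.out = 8))
  binder$segment <- as.character(
    cut(binder$z, breaks = unique(qz), labels = bands[seq_len(length(unique(qz)) - 1)],
        include.lowest = TRUE))

  # --- binder charges
  n_pos <- 16L
  n_neg <- n_pos - spec$binder_net_charge
  if (n_neg < 0) {
    abort("binder_net_charge too large for the fixed positive-site count")
  }
  center <- c(cx, cy, mean(binder$z))
  rel <- sweep(as.matrix(binder[, c("x", "y", "z")]), 2, center)
  rad <- sqrt(rowSums(rel^2))
  surface <- which(rad > stats::quantile(rad, 0.45))   # outer shell beads
  z_iface <- min(binder$z)                             # interface plane
  pos_sites <- switch(
    spec$charge_layout,
    interface_clustered = {
      # 13 sites in the interface slab, 3 elsewhere (fraction 13/16 >= 0.7)
      slab <- surface[binder$z[surface] - z_iface <= 10]
      away <- setdiff(surface, slab)
      c(slab[order(binder$z[slab])][seq_len(13)],
        away[order(-binder$z[away])][seq_len(3)])
    },
    scattered = {
      # map evenly spread directions to nearest distinct surface beads,
      # then rebalance borderline sites so the interface slab holds
      # strictly less than half of the positive charge
      dirs <- fibonacci_sphere(n_pos)
      taken <- integer(0)
      for (k in seq_len(n_pos)) {
        cand_i <- surface[order(-(rel[surface, ] %*% dirs[k, ]))]
        cand_i <- setdiff(cand_i, taken)
        taken <- c(taken, cand_i[1])
      }
      in_slab <- binder$z[taken] - z_iface <= 10
      while (mean(in_slab) >= 0.5) {
        move <- which(in_slab)[which.max(binder$z[taken[in_slab]])]
        pool <- setdiff(surface[binder$z[surface] - z_iface > 10], taken)
        taken[move] <- pool[which.max(binder$z[pool])]
        in_slab <- binder$z[taken] - z_iface <= 10
      }
      taken
    })
  # negative sites stay off the binding face in both layouts (the interface
  # is positively biased; only the positive-charge placement differs)
  neg_pool <- setdiff(surface[binder$z[surface] > stats::median(binder$z)],
                      pos_sites)
  dirs_n <- fibonacci_sphere(n_neg + 3)[seq_len(n_neg), , drop = FALSE] %*%
    matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)  # rotate to decorrelate
  neg_sites <- integer(0)
  for (k in seq_len(n_neg)) {
    cand_i <- neg_pool[order(-(rel[neg_pool, ] %*% dirs_n[k, ]))]
    cand_i <- setdiff(cand_i, neg_sites)
    neg_sites <- c(neg_sites, cand_i[1])
  }
  binder$resname[pos_sites] <- "LYS"
  binder$resname[neg_sites] <- "GLU"

  # --- tails anchored at monomer C-terminal positions on the top surface;
  # beta anchors (B, D) are nudged toward the binder footprint, alpha
  # anchors (A, C) toward the outer filament ends
  tails <- list()
  for (m in 0:3) {
    lab <- chains[m + 1]
    mono_cx <- m * .fil_nx * sp + (.fil_nx - 1) * sp / 2
    nudge <- if (lab %in% c("B", "D")) sign(cx - mono_cx) * sp else
      -sign(cx - mono_cx) * sp
    anchor <- c(mono_cx + nudge, cy, .fil_top + 1.5)
    # grow base tails up and away from the binder so the reference pose is
    # clash-free; ensemble frames resample them anyway
    away <- sign(anchor[1] - cx)
    if (away == 0) away <- 1
    # single-letter tail chains (PDB field width): E-H map to tails A-D
    tail_chain <- c(A = "E", B = "F", C = "G", D = "H")
    tails[[lab]] <- build_extended_tail(
      spec$tail_sequences[[lab]], anchor = anchor,
      direction = c(0.7 * away, 0, 1),
      chain = tail_chain[[lab]], segment = paste0("TAIL_", lab),
      group = paste0("tail_", tolower(lab)))
  }

  s <- mt_structure(bind_rows(filament, binder, bind_rows(tails)))
  # keep the reference pose clash-free: tail atoms out of the binder core
  bxyz <- as.matrix(binder[, c("x", "y", "z")])
  for (g in paste0("tail_", tolower(chains))) {
    rows <- group_idx(s, g)
    ca <- rows[s$elety[rows] == "CA"]; sc <- rows[s$elety[rows] == "SC"]
    xyz_t <- push_out(coords(s)[ca, , drop = FALSE], bxyz, 3.8)
    s$x[ca] <- xyz_t[, 1]; s$y[ca] <- xyz_t[, 2]; s$z[ca] <- xyz_t[, 3]
    if (length(sc) > 0) {
      xyz_s <- push_out(coords(s)[sc, , drop = FALSE], bxyz, 3.2)
      s$x[sc] <- xyz_s[, 1]; s$y[sc] <- xyz_s[, 2]; s$z[sc] <- xyz_s[, 3]
    }
  }
  s <- assign_ionization(s)
  fil_rows <- group_idx(s, "filament")
  s$charge[fil_rows[body_charges]] <- -1
  s$eleno <- seq_len(nrow(s))
  s
}

# ---------------------------------------------------------------------------

#' Generate a replicate conformational ensemble for an offset system
#'
#' Emulates the statistical structure of a restrained implicit-solvent
#' trajectory: filament atoms get Gaussian jitter of sigma 0.1 Angstrom
#' (harmonic restraints), binder atoms get isotropic jitter whose 3D RMSF
#' equals `fluctuation_base + fluctuation_distance_gain * offset_d`, and
#' each tail is resampled per frame as a directed random walk from its
#' anchor, biased toward the binder's positive patches with strength
#' `exp(-offset_d / contact_decay_length)`. At offsets at or beyond
#' `zero_contact_distance` tail beads are kept more than 4.5 Angstrom below
#' the binder, guaranteeing zero contacts at the 4 Angstrom criterion.
#'
#' @param base system built by [generate_system()] and offset by
#'   [offset_binder()].
#' @param spec the [synthetic_spec()] used to build `base`.
#' @param offset_d the binder-filament offset of `base`, Angstrom.
#' @return An `mt_ensemble` with `spec$n_runs * spec$n_frames` frames.
#' @export
generate_ensemble <- function(base, spec, offset_d = 0) {
  stopifnot(inherits(base, "mt_structure"), inherits(spec, "synthetic_spec"),
            offset_d >= 0)
  xyz0 <- coords(base)
  n_at <- nrow(base)
  ib <- group_idx(base, "binder")
  ifil <- group_idx(base, "filament")
  sigma_b <- (spec$fluctuation_base +
                spec$fluctuation_distance_gain * offset_d) / sqrt(3)
  bias <- exp(-offset_d / spec$contact_decay_length)
  clamp <- offset_d >= spec$zero_contact_distance
  # static attraction targets: binder positive beads (offset pose)
  pos_idx <- ib[base$charge[ib] > 0]
  targets <- xyz0[pos_idx, , drop = FALSE]
  binder_xyz <- xyz0[ib, , drop = FALSE]
  z_surface <- max(xyz0[ifil, 3])

  tail_groups <- grep("^tail_", unique(base$group), value = TRUE)
  all_tail_rows <- unlist(lapply(tail_groups, function(g) group_idx(base, g)))
  # side-chain/parent-CA pairs within the concatenated tail-atom block are
  # bonded and exempt from the excluded-volume minimum
  bonded_pairs <- {
    key <- paste(base$chain[all_tail_rows], base$resno[all_tail_rows])
    is_sc <- base$elety[all_tail_rows] == "SC"
    sc_pos <- which(is_sc)
    ca_pos <- which(!is_sc)[match(key[is_sc], key[!is_sc])]
    cbind(sc_pos, ca_pos)
  }
  tail_info <- lapply(tail_groups, function(g) {
    rows <- group_idx(base, g)
    ca <- rows[base$elety[rows] == "CA"]
    sc <- rows[base$elety[rows] == "SC"]
    # map each SC to its CA by residue number
    sc_of <- match(base$resno[sc], base$resno[ca])
    list(rows = rows, ca = ca, sc = sc, sc_of = sc_of,
         anchor = xyz0[ca[1], ], n = length(ca))
  })

  total <- spec$n_runs * spec$n_frames
  xyz <- array(0, dim = c(total, n_at, 3))
  run <- integer(total)
  fi <- 0L
  for (r in seq_len(spec$n_runs)) {
    set.seed(spec$seed + 1000L * r)
    for (f in seq_len(spec$n_frames)) {
      fi <- fi + 1L
      run[fi] <- r
      frame <- xyz0
      frame[ifil, ] <- frame[ifil, ] +
        matrix(rnorm(length(ifil) * 3, sd = 0.1), ncol = 3)
      frame[ib, ] <- frame[ib, ] +
        matrix(rnorm(length(ib) * 3, sd = sigma_b), ncol = 3)
      z_binder_min <- min(frame[ib, 3])
      binder_frame <- frame[ib, , drop = FALSE]
      for (tl in tail_info) {
        beads <- tail_walk(tl$anchor, tl$n, targets, bias, z_surface,
                           binder_xyz)
        beads <- push_out(beads, binder_frame, 3.8)
        if (clamp) {
          cap <- z_binder_min - 4.5
          over <- beads[, 3] > cap
          beads[over, 3] <- 2 * cap - beads[over, 3]   # reflect below cap
        }
        frame[tl$ca, ] <- beads
        if (length(tl$sc) > 0) {
          # charged side chains orient toward the nearest positive binder
          # patch when near it (electrostatic steering), else randomly
          sc_dir <- matrix(rnorm(length(tl$sc) * 3), ncol = 3)
          parent <- beads[tl$sc_of, , drop = FALSE]
          for (m in seq_len(nrow(parent))) {
            dvp <- sweep(targets, 2, parent[m, ], "-")
            dp <- sqrt(rowSums(dvp^2))
            jm <- which.min(dp)
            w <- 4 * exp(-dp[jm] / 8)
            sc_dir[m, ] <- sc_dir[m, ] + w * dvp[jm, ] / (dp[jm] + 1e-9)
          }
          sc_dir <- sc_dir / sqrt(rowSums(sc_dir^2))
          scpos <- parent + 2.0 * sc_dir
          scpos <- push_out(scpos, binder_frame, 3.2)
          if (clamp) {
            cap <- z_binder_min - 4.5
            over <- scpos[, 3] > cap
            scpos[over, 3] <- 2 * cap - scpos[over, 3]
          }
          frame[tl$sc, ] <- scpos
        }
      }
      # global excluded volume over all tail atoms (side chains included):
      # no tail-atom pair closer than 2.4 A (bonded side chains exempt), no
      # tail atom within 3.2 A of a binder bead or below the filament top
      tp <- frame[all_tail_rows, , drop = FALSE]
      low <- tp[, 3] < z_surface + 0.5
      tp[low, 3] <- 2 * (z_surface + 0.5) - tp[low, 3]
      tp <- resolve_tail_clashes(tp, binder_frame, bonded_pairs)
      frame[all_tail_rows, ] <- tp
      xyz[fi, , ] <- frame
    }
  }
  mt_ensemble(base, xyz, run = run)
}

# resolve remaining excluded-volume violations among tail atoms and against
# the (jittered) binder: detect offending atoms from the full distance
# matrices and push only those, re-checking until clean
resolve_tail_clashes <- function(tp, binder_xyz, bonded_pairs,
                                 min_tail = 2.4, min_binder = 3.2,
                                 max_rounds = 12) {
  n <- nrow(tp)
  for (round in seq_len(max_rounds)) {
    d2t <- pair_dist2(tp, tp)
    d2t[cbind(seq_len(n), seq_len(n))] <- Inf
    if (nrow(bonded_pairs) > 0) {
      d2t[bonded_pairs] <- Inf
      d2t[bonded_pairs[, c(2, 1), drop = FALSE]] <- Inf
    }
    d2b <- pair_dist2(tp, binder_xyz)
    off <- union(which(apply(d2t, 1, min) < min_tail^2),
                 which(apply(d2b, 1, min) < min_binder^2))
    if (length(off) == 0) break
    for (i in off) {
      excl <- c(i, bonded_pairs[bonded_pairs[, 1] == i, 2],
                bonded_pairs[bonded_pairs[, 2] == i, 1])
      tp[i, ] <- push_out(tp[i, , drop = FALSE],
                          tp[-excl, , drop = FALSE], min_tail, max_iter = 6)
      # binder exclusion last: it is the hard constraint (cross-group terms
      # enter the binding energy; tail-tail terms are intra-part)
      tp[i, ] <- push_out(tp[i, , drop = FALSE], binder_xyz, min_binder)
    }
  }
  # final guarantee against the binder even if tail-tail contention remains
  d2b <- pair_dist2(tp, binder_xyz)
  for (i in which(apply(d2b, 1, min) < min_binder^2)) {
    tp[i, ] <- push_out(tp[i, , drop = FALSE], binder_xyz, min_binder)
  }
  # bonded side chains projected onto the same binder-surface point as
  # their parent bead would coincide: separate them tangentially (keeps
  # the binder clearance of the shared projection ray)
  for (b in seq_len(nrow(bonded_pairs))) {
    i <- bonded_pairs[b, 1]; j <- bonded_pairs[b, 2]
    v <- tp[i, ] - tp[j, ]
    d <- sqrt(sum(v^2))
    if (d < 1.6) {
      jb <- which.min(rowSums(sweep(binder_xyz, 2, tp[i, ], "-")^2))
      ray <- tp[i, ] - binder_xyz[jb, ]
      ray <- ray / max(sqrt(sum(ray^2)), 1e-9)
      tan1 <- c(-ray[2], ray[1], 0)
      if (sqrt(sum(tan1^2)) < 1e-6) tan1 <- c(1, 0, 0)
      tan1 <- tan1 / sqrt(sum(tan1^2))
      tp[i, ] <- tp[i, ] + (1.6 - d) * tan1
    }
  }
  tp
}

# move points radially out of the nearest reference bead until none is
# closer than min_sep (iterated: a single radial push can land a point near
# a different bead)
push_out <- function(pts, ref_xyz, min_sep, max_iter = 30) {
  for (i in seq_len(nrow(pts))) {
    for (it in seq_len(max_iter)) {
      d2 <- rowSums(sweep(ref_xyz, 2, pts[i, ], "-")^2)
      j <- which.min(d2)
      if (d2[j] >= min_sep^2) break
      d <- sqrt(d2[j])
      pts[i, ] <- if (d < 1e-6) pts[i, ] + c(0, 0, min_sep) else
        ref_xyz[j, ] + (pts[i, ] - ref_xyz[j, ]) / d * (min_sep * 1.02)
    }
  }
  pts
}

# one biased directed walk: n beads from anchor, step 3.8, persistence plus
# Gaussian noise plus attraction toward the nearest positive binder patch;
# beads are kept off the filament surface and out of the binder core
tail_walk <- function(anchor, n, targets, bias, z_surface, binder_xyz,
                      min_sep = 3.8) {
  beads <- matrix(0, n, 3)
  beads[1, ] <- anchor
  dirn <- c(0, 0, 1)
  for (k in 2:n) {
    pos <- beads[k - 1, ]
    dv <- sweep(targets, 2, pos, "-")
    d2 <- rowSums(dv^2)
    j <- which.min(d2)
    u <- dv[j, ] / sqrt(d2[j] + 1e-9)
    step <- 0.6 * dirn + 0.9 * rnorm(3) + 1.4 * bias * u
    nrm <- sqrt(sum(step^2))
    if (nrm < 1e-9) step <- c(0, 0, 1) else step <- step / nrm
    pos <- pos + 3.8 * step
    # soft excluded volume: reflect off the filament surface, stay out of
    # the binder core and avoid earlier beads of the same tail
    if (pos[3] < z_surface + 1) pos[3] <- 2 * (z_surface + 1) - pos[3]
    pos <- push_out(matrix(pos, 1, 3), binder_xyz, min_sep)[1, ]
    if (k > 2) {
      pos <- push_out(matrix(pos, 1, 3),
                      beads[seq_len(k - 2), , drop = FALSE], 3.0,
                      max_iter = 5)[1, ]
    }
    beads[k, ] <- pos
    dirn <- step
  }
  beads
}

#' Serialise a synthetic spec to YAML
#' @param spec a [synthetic_spec()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spec <- function(spec, path) {
  v <- unclass(spec)
  v$tail_sequences <- as.list(v$tail_sequences)   # keep names in YAML map
  yaml::write_yaml(v, path)
  invisible(path)
}

#' Read a synthetic spec from YAML
#' @param path YAML file written by [write_spec()].
#' @return A [synthetic_spec()].
#' @export
read_spec <- function(path) {
  v <- yaml::read_yaml(path)
  v$tail_sequences <- unlist(v$tail_sequences)
  do.call(synthetic_spec, v)
}
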