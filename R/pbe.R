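# Finite-difference linearized Poisson-Boltzmann electrostatics on a cubic
# grid: two-dielectric solute/solvent model with Debye ionic screening,
# solved by red-black successive over-relaxation. Potentials are in kT/e.
#
# Discretization (integrate div(eps grad u) - eps_out kappa^2 u = -C rho
# over a grid cell, u = e phi / kT):
#   sum_faces eps_f (u_nb - u_0) h - eps_out kappa0^2 u_0 h^3 = -C q_0 / 1
# with C = e^2/(eps0 kT) expressed in Angstrom; charges are spread to the 8
# nearest nodes by trilinear weighting.

#' Parameters for the linearized Poisson-Boltzmann solver
#'
#' @param scale grid points per Angstrom (spacing = 1/scale).
#' @param perfil percentage of the grid's linear dimension occupied by the
#'   solute's longest dimension.
#' @param eps_in,eps_out solute and solvent relative dielectrics.
#' @param ionic_strength mol/L of 1:1 salt (screening only in solvent).
#' @param probe_radius Angstrom added to atom radii when carving the
#'   solute dielectric region (probe-inflated van der Waals surface).
#' @param temperature Kelvin (sets the kT/e unit).
#' @param max_iter,tol SOR iteration cap and max-update convergence
#'   tolerance in kT/e.
#' @return A list of class `pbe_params`.
#' @export
pbe_params <- function(scale = 2, perfil = 70, eps_in = 2, eps_out = 80,
                       ionic_strength = 0.15, probe_radius = 1.4,
                       temperature = 300, max_iter = 2000, tol = 1e-5) {
  stopifnot(scale > 0, perfil > 0, perfil <= 100, eps_in > 0, eps_out > 0,
            ionic_strength >= 0, probe_radius >= 0, max_iter > 0, tol > 0)
  structure(list(scale = scale, perfil = perfil, eps_in = eps_in,
                 eps_out = eps_out, ionic_strength = ionic_strength,
                 probe_radius = probe_radius, temperature = temperature,
                 max_iter = max_iter, tol = tol),
            class = "pbe_params")
}

#' Solve the linearized Poisson-Boltzmann equation for a structure
#'
#' 7-point finite-difference discretization of
#' `div(eps grad phi) - eps_out kappa^2 phi = -4 pi rho` on a cubic grid
#' sized by `perfil`; the solute interior (probe-inflated atom spheres) gets
#' `eps_in` and no salt, the exterior `eps_out` with Debye screening from
#' the ionic strength. Boundary potentials are a screened-Coulomb sum over
#' all charges; the interior is iterated by red-black SOR until the largest
#' update falls below `tol`.
#'
#' @param s an `mt_structure` with charges and radii assigned.
#' @param params [pbe_params()].
#' @param charges optional per-atom charge vector overriding `s$charge`
#'   (same dielectric geometry; used e.g. for superposition checks).
#' @return Object of class `mt_grid`: list with `origin`, `spacing`, `dims`,
#'   `phi` (3D array, kT/e), `eps` (node dielectric), `kappa2`, `iterations`
#'   and `residual`.
#' @export
solve_lpbe <- function(s, params = pbe_params(), charges = NULL) {
  xyz <- coords(s)
  q <- charges %||% s$charge
  stopifnot(length(q) == nrow(s))
  h <- 1 / params$scale
  ext <- apply(xyz, 2, range)
  span <- max(ext[2, ] - ext[1, ], 1)
  L <- span / (params$perfil / 100)            # grid box edge, Angstrom
  n <- 2 * ceiling(L / (2 * h)) + 1            # odd node count
  center <- colMeans(ext)
  origin <- center - (n - 1) / 2 * h
  ax <- origin[1] + (seq_len(n) - 1) * h
  ay <- origin[2] + (seq_len(n) - 1) * h
  az <- origin[3] + (seq_len(n) - 1) * h

  # node dielectric: eps_in inside any probe-inflated atom sphere
  eps <- array(params$eps_out, dim = c(n, n, n))
  inflate <- s$radius + params$probe_radius
  for (i in seq_len(nrow(s))) {
    r <- inflate[i]
    ix <- which(abs(ax - xyz[i, 1]) <= r)
    iy <- which(abs(ay - xyz[i, 2]) <= r)
    iz <- which(abs(az - xyz[i, 3]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax[ix] - xyz[i, 1])^2
    dy2 <- (ay[iy] - xyz[i, 2])^2
    dz2 <- (az[iz] - xyz[i, 3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r^2
    block <- eps[ix, iy, iz]
    block[inside] <- params$eps_in
    eps[ix, iy, iz] <- block
  }
  kappa <- debye_kappa(params$ionic_strength, params$eps_out,
                       params$temperature)
  kappa2 <- array(0, dim = c(n, n, n))
  kappa2[eps == params$eps_out] <- kappa^2 * params$eps_out

  # trilinear charge spreading; source constant C = e^2/(eps0 kT) in A
  Cconst <- 4 * pi * bjerrum_vacuum(params$temperature)
  src <- array(0, dim = c(n, n, n))
  for (i in which(q != 0)) {
    g <- (xyz[i, ] - origin) / h + 1
    i0 <- pmin(pmax(floor(g), 1), n - 1)
    f <- g - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) *
        (if (dy) f[2] else 1 - f[2]) *
        (if (dz) f[3] else 1 - f[3])
      src[i0[1] + dx, i0[2] + dy, i0[3] + dz] <-
        src[i0[1] + dx, i0[2] + dy, i0[3] + dz] + Cconst * q[i] * w
    }
  }

  # boundary: Debye-screened monopole sum (in kT/e)
  u <- array(0, dim = c(n, n, n))
  lb <- bjerrum_vacuum(params$temperature)
  bset <- boundary_nodes(n)
  bxyz <- cbind(ax[bset[, 1]], ay[bset[, 2]], az[bset[, 3]])
  nzq <- which(q != 0)
  if (length(nzq) > 0) {
    vals <- numeric(nrow(bxyz))
    for (i in nzq) {
      d <- sqrt(rowSums(sweep(bxyz, 2, xyz[i, ])^2))
      d <- pmax(d, 1e-3)
      vals <- vals + lb * q[i] * exp(-kappa * d) / (params$eps_out * d)
    }
    u[bset] <- vals
  }

  sol <- sor_solve(u, eps, kappa2, src, h, params$max_iter, params$tol)
  structure(list(origin = origin, spacing = h, dims = c(n, n, n),
                 phi = sol$u, eps = eps, kappa2 = kappa2,
                 iterations = sol$iterations, residual = sol$residual,
                 params = params),
            class = "mt_grid")
}

boundary_nodes <- function(n) {
  idx <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  on_b <- idx$i %in% c(1, n) | idx$j %in% c(1, n) | idx$k %in% c(1, n)
  as.matrix(idx[on_b, ])
}

# red-black SOR, vectorized over checkerboard masks
sor_solve <- function(u, eps, kappa2, src, h, max_iter, tol) {
  n <- dim(u)[1]
  ii <- 2:(n - 1)
  # face dielectrics (arithmetic mean of node values) for interior nodes
  exm <- (eps[ii, ii, ii] + eps[ii - 1, ii, ii]) / 2
  exp_ <- (eps[ii, ii, ii] + eps[ii + 1, ii, ii]) / 2
  eym <- (eps[ii, ii, ii] + eps[ii, ii - 1, ii]) / 2
  eyp <- (eps[ii, ii, ii] + eps[ii, ii + 1, ii]) / 2
  ezm <- (eps[ii, ii, ii] + eps[ii, ii, ii - 1]) / 2
  ezp <- (eps[ii, ii, ii] + eps[ii, ii, ii + 1]) / 2
  diagc <- exm + exp_ + eym + eyp + ezm + ezp + kappa2[ii, ii, ii] * h^2
  b <- src[ii, ii, ii] / h
  m <- n - 2
  par <- outer(outer(ii, ii, "+"), ii, "+") %% 2
  red <- par == 0
  omega <- 2 / (1 + sin(pi / n))
  delta <- Inf
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    delta <- 0
    for (color in list(red, !red)) {
      nb <- exm * u[ii - 1, ii, ii] + exp_ * u[ii + 1, ii, ii] +
        eym * u[ii, ii - 1, ii] + eyp * u[ii, ii + 1, ii] +
        ezm * u[ii, ii, ii - 1] + ezp * u[ii, ii, ii + 1]
      unew <- (nb + b) / diagc
      cur <- u[ii, ii, ii]
      upd <- cur + omega * (unew - cur)
      cur[color] <- upd[color]
      delta <- max(delta, max(abs(upd - u[ii, ii, ii])[color]))
      u[ii, ii, ii] <- cur
    }
    if (delta < tol) break
  }
  if (delta >= tol) {
    abort(sprintf("LPBE solver did not converge: max update %.3g after %d iterations",
                  delta, it))
  }
  list(u = u, iterations = it, residual = delta)
}

#' Trilinear interpolation of a grid field at arbitrary points
#'
#' @param g an `mt_grid` (or any list with `origin`, `spacing`, `dims` and a
#'   3D array in `field`).
#' @param pts m x 3 matrix of coordinates.
#' @param field which array to interpolate (default `"phi"`).
#' @return Numeric vector of interpolated values; errors if a point lies
#'   outside the grid.
#' @export
interp_grid <- function(g, pts, field = "phi") {
  A <- g[[field]]
  n <- g$dims
  pts <- matrix(pts, ncol = 3)
  gcoord <- sweep(pts, 2, g$origin) / g$spacing + 1
  if (any(gcoord < 1 - 1e-9) || any(sweep(gcoord, 2, n) > 1e-9)) {
    abort("point outside grid")
  }
  out <- numeric(nrow(pts))
  for (p in seq_len(nrow(pts))) {
    gp <- pmin(pmax(gcoord[p, ], 1), n - 1e-9)
    i0 <- pmin(floor(gp), n - 1)
    f <- gp - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) *
        (if (dy) f[2] else 1 - f[2]) *
        (if (dz) f[3] else 1 - f[3])
      acc <- acc + w * A[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    out[p] <- acc
  }
  out
}

#' Mean surface potential per atom
#'
#' Samples the potential by trilinear interpolation at evenly spread points
#' on each atom's sphere and reports the per-atom mean in kT/e.
#'
#' @param g an `mt_grid` covering the structure.
#' @param s the `mt_structure`.
#' @param n_samples sphere sample points per atom.
#' @return Tibble with atom identity columns and `surface_potential`.
#' @export
surface_potential <- function(g, s, n_samples = 26) {
  dirs <- fibonacci_sphere(n_samples)
  xyz <- coords(s)
  vals <- numeric(nrow(s))
  for (i in seq_len(nrow(s))) {
    pts <- sweep(dirs * s$radius[i], 2, xyz[i, ], "+")
    vals[i] <- mean(interp_grid(g, pts))
  }
  tibble(eleno = s$eleno, elety = s$elety, chain = s$chain,
         resno = s$resno, resname = s$resname, segment = s$segment,
         group = s$group, surface_potential = vals)
}

#' Fraction of positive charge near the binding interface
#'
#' Sums the positive charges lying within `slab` Angstrom of the interface
#' plane and divides by all positive charge: a direct measure of whether
#' positive patches cluster at the binding face or scatter over the surface.
#'
#' @param s an `mt_structure` with ionization assigned.
#' @param point a point on the interface plane.
#' @param normal plane normal.
#' @param slab slab half-thickness in Angstrom (default 10).
#' @param group optional group restriction (e.g. `"binder"`).
#' @return Fraction in `[0, 1]`.
#' @export
interface_charge_asymmetry <- function(s, point, normal, slab = 10,
                                       group = NULL) {
  if (!is.null(group)) {
    s <- s[group_idx(s, group), ]
  }
  pos <- s$charge > 0
  if (!any(pos)) abort("structure has no positive charges")
  nrm <- normal / sqrt(sum(normal^2))
  d <- abs(as.matrix(sweep(coords(s), 2, point)) %*% nrm)
  sum(s$charge[pos & d[, 1] <= slab]) / sum(s$charge[pos])
}

#' Write a potential grid in OpenDX scalar-field format
#'
#' @param g an `mt_grid`.
#' @param path output `.dx` file.
#' @return `path`, invisibly.
#' @export
write_dx <- function(g, path) {
  n <- g$dims
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", n[1], n[2], n[3]),
    sprintf("origin %.6e %.6e %.6e", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6e 0.0 0.0", g$spacing),
    sprintf("delta 0.0 %.6e 0.0", g$spacing),
    sprintf("delta 0.0 0.0 %.6e", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", n[1], n[2], n[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(n))), con)
  # DX node order: z varies fastest, then y, then x
  vals <- as.vector(aperm(g$phi, c(3, 2, 1)))
  writeLines(apply(matrix(c(sprintf("%.6e", vals),
                            rep("", (3 - length(vals) %% 3) %% 3)),
                          ncol = 3, byrow = TRUE),
                   1, paste, collapse = " "), con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}
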