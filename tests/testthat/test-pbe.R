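born_ion <- function(charge = 1, radius = 2) {
  s <- pair_structure(1, charge = charge)
  s$radius <- radius
  s
}

test_that("zero charge gives an identically zero potential", {
  s <- line_structure(4, charge = 0)
  g <- solve_lpbe(s, pbe_params(scale = 1, perfil = 40, max_iter = 500))
  expect_equal(max(abs(g$phi)), 0)
  expect_equal(g$spacing, 1)
})

test_that("uniform-dielectric potential matches Debye-Hueckel at 10-15 A", {
  p <- pbe_params(scale = 2, perfil = 3, eps_in = 80, eps_out = 80,
                  ionic_strength = 0.15, max_iter = 5000, tol = 1e-6)
  g <- solve_lpbe(born_ion(), p)
  kap <- debye_kappa(0.15, 80)
  lb <- mtassoc:::bjerrum_vacuum(300)
  rs <- seq(10, 15, by = 0.5)
  phi <- interp_grid(g, cbind(rs, 0, 0))
  dh <- lb * exp(-kap * rs) / (80 * rs)
  expect_lt(max(abs(phi / dh - 1)), 0.03)
})

test_that("the solved field is antisymmetric for a mirror charge pair", {
  s <- mt_structure(tibble::tibble(
    elety = "CA", x = c(-4, 4), y = 0, z = 0, chain = "A", resno = 1:2,
    resname = "GLY", charge = c(1, -1), radius = 2))
  p <- pbe_params(scale = 1.5, perfil = 30, max_iter = 4000, tol = 1e-6)
  g <- solve_lpbe(s, p)
  pts <- rbind(c(6, 1, 2), c(2, -3, 1), c(8, 0, 0))
  mirror <- pts; mirror[, 1] <- -mirror[, 1]
  expect_equal(interp_grid(g, pts), -interp_grid(g, mirror),
               tolerance = 1e-3)
})

test_that("the linearized solution superposes charge sets", {
  s <- mt_structure(tibble::tibble(
    elety = "CA", x = c(-3, 3), y = 0, z = 0, chain = "A", resno = 1:2,
    resname = "GLY", charge = c(1, -1), radius = 1.8))
  p <- pbe_params(scale = 1.5, perfil = 30, eps_in = 2, max_iter = 4000,
                  tol = 1e-7)
  g_both <- solve_lpbe(s, p)
  g_a <- solve_lpbe(s, p, charges = c(1, 0))
  g_b <- solve_lpbe(s, p, charges = c(0, -1))
  expect_equal(g_both$phi, g_a$phi + g_b$phi, tolerance = 1e-4)
})

test_that("halving the spacing changes the far field by under 2 percent", {
  s <- born_ion(radius = 2)
  p1 <- pbe_params(scale = 1, perfil = 5, eps_in = 2, max_iter = 4000,
                   tol = 1e-6)
  p2 <- pbe_params(scale = 2, perfil = 5, eps_in = 2, max_iter = 6000,
                   tol = 1e-6)
  g1 <- solve_lpbe(s, p1)
  g2 <- solve_lpbe(s, p2)
  pts <- rbind(c(8, 0, 0), c(0, 9, 0), c(6, 6, 0))
  expect_lt(max(abs(interp_grid(g1, pts) / interp_grid(g2, pts) - 1)), 0.02)
})

test_that("surface potentials interpolate the grid faithfully", {
  s <- line_structure(3, spacing = 5)
  n <- 31
  gU <- list(origin = c(-10, -10, -10), spacing = 1, dims = c(n, n, n),
             phi = array(4.2, c(n, n, n)))
  class(gU) <- "mt_grid"
  sp <- surface_potential(gU, s)
  expect_equal(sp$surface_potential, rep(4.2, 3), tolerance = 1e-12)

  # trilinear interpolation is exact on a linear field
  lin <- array(0, c(n, n, n))
  for (i in 1:n) for (j in 1:n) lin[i, j, ] <- 0.5 * i - 0.2 * j +
      0.1 * (1:n)
  gL <- list(origin = c(-10, -10, -10), spacing = 1, dims = c(n, n, n),
             phi = lin)
  class(gL) <- "mt_grid"
  set.seed(33)
  pts <- matrix(runif(30, -8, 8), 10, 3)
  gcoord <- sweep(pts, 2, gL$origin) + 1
  oracle <- 0.5 * gcoord[, 1] - 0.2 * gcoord[, 2] + 0.1 * gcoord[, 3]
  expect_equal(interp_grid(gL, pts), oracle, tolerance = 1e-9)

  expect_error(interp_grid(gU, matrix(c(100, 0, 0), 1, 3)), "outside")
  out_atom <- line_structure(1); out_atom$x <- 500
  expect_error(surface_potential(gU, out_atom), "outside")
})

test_that("field lines are straight in uniform fields and radial for an ion", {
  n <- 25
  phi <- array(0, c(n, n, n))
  for (i in 1:n) phi[i, , ] <- -(i - 1)          # E = +x
  g <- list(origin = c(0, 0, 0), spacing = 1, dims = c(n, n, n), phi = phi)
  class(g) <- "mt_grid"
  fl <- trace_field_lines(g, rbind(c(12, 12, 12)), step = 0.5)
  expect_lt(max(abs(fl$y - 12)), 1e-6)
  expect_lt(max(abs(fl$z - 12)), 1e-6)
  expect_equal(fl$termination[1], "boundary")

  # two parallel lines in a uniform field never converge (non-crossing)
  fl2 <- trace_field_lines(g, rbind(c(10, 10, 10), c(10, 14, 10)),
                           step = 0.5)
  a <- fl2[fl2$line == 1, c("y", "z")]
  b <- fl2[fl2$line == 2, c("y", "z")]
  expect_gt(min(abs(b$y[1] - a$y[1])), 3.9)

  p <- pbe_params(scale = 2, perfil = 10, eps_in = 80, eps_out = 80,
                  ionic_strength = 0.15, max_iter = 4000, tol = 1e-6)
  gr <- solve_lpbe(born_ion(), p)
  seeds <- rbind(c(4, 0, 0), c(0, 4, 2), c(-3, -3, 0))
  flr <- trace_field_lines(gr, seeds, step = 0.5,
                           charges = rbind(c(0, 0, 0)))
  for (ln in unique(flr$line)) {
    pts <- as.matrix(flr[flr$line == ln, c("x", "y", "z")])
    if (nrow(pts) < 3) next
    dirs <- diff(pts)
    rads <- pts[-nrow(pts), , drop = FALSE]
    cosang <- abs(rowSums(dirs * rads)) /
      (sqrt(rowSums(dirs^2)) * sqrt(rowSums(rads^2)))
    expect_lt(max(acos(pmin(cosang, 1))) * 180 / pi, 5)
  }
  expect_error(trace_field_lines(gr, rbind(c(1e4, 0, 0))), "outside")
})

test_that("dipole field lines run from the positive to the negative charge", {
  s <- mt_structure(tibble::tibble(
    elety = "CA", x = c(-5, 5), y = 0, z = 0, chain = "A", resno = 1:2,
    resname = "GLY", charge = c(1, -1), radius = 1.8))
  p <- pbe_params(scale = 1.5, perfil = 25, eps_in = 80, eps_out = 80,
                  max_iter = 4000, tol = 1e-6)
  g <- solve_lpbe(s, p)
  fl <- trace_field_lines(g, rbind(c(-2.5, 0.5, 0)), step = 0.4,
                          charges = coords(s), sink_radius = 1.5)
  expect_equal(fl$termination[1], "charge_sink")
  endpt <- as.numeric(fl[nrow(fl), c("x", "y", "z")])
  expect_lt(sqrt(sum((endpt - c(5, 0, 0))^2)), 2.5)
})

test_that("interface charge asymmetry counts positive charge in the slab", {
  s <- line_structure(4, charge = c(1, 1, 1, -1))
  expect_equal(interface_charge_asymmetry(s, c(0, 0, 0), c(0, 0, 1),
                                          slab = 10), 1)
  s2 <- s; s2$z <- c(20, 30, 40, 0)
  expect_equal(interface_charge_asymmetry(s2, c(0, 0, 0), c(0, 0, 1),
                                          slab = 10), 0)
  expect_error(interface_charge_asymmetry(line_structure(3, charge = -1),
                                          c(0, 0, 0), c(0, 0, 1)),
               "positive")

  sys_c <- generate_system(fast_spec())
  ibz <- min(sys_c$z[group_idx(sys_c, "binder")])
  frac_c <- interface_charge_asymmetry(sys_c, c(0, 0, ibz), c(0, 0, 1),
                                       slab = 10, group = "binder")
  expect_gte(frac_c, 0.7)
  sys_s <- generate_system(fast_spec(charge_layout = "scattered"))
  frac_s <- interface_charge_asymmetry(sys_s, c(0, 0, ibz), c(0, 0, 1),
                                       slab = 10, group = "binder")
  expect_lt(frac_s, 0.5)
})

test_that("grids export to OpenDX text format", {
  s <- born_ion()
  g <- solve_lpbe(s, pbe_params(scale = 1, perfil = 30, max_iter = 2000))
  f <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, f)
  lines <- readLines(f)
  expect_match(lines[1], "gridpositions counts")
  n_items <- prod(g$dims)
  expect_match(lines[7], sprintf("items %d", n_items))
})
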