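test_that("Coulomb energy matches the definition and the pairwise oracle", {
  p <- ff_params(ionic_strength = 0)
  s <- pair_structure(2, spacing = 1, charge = 1)
  expect_equal(coulomb_energy(s, p), 332.0636, tolerance = 1e-9)

  # net-zero pair at great separation -> ~0
  sfar <- pair_structure(2, spacing = 1e6, charge = c(1, -1))
  expect_lt(abs(coulomb_energy(sfar, p)), 1e-3)

  set.seed(14)
  s20 <- mt_structure(tibble::tibble(
    elety = "CA", x = runif(20, 0, 20), y = runif(20, 0, 20),
    z = runif(20, 0, 20), chain = "A", resno = 1:20, resname = "GLY",
    charge = sample(c(-1, 0, 1), 20, replace = TRUE)))
  oracle <- 0
  xyz <- coords(s20); q <- s20$charge
  for (i in 1:19) for (j in (i + 1):20) {
    oracle <- oracle + 332.0636 * q[i] * q[j] /
      sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  expect_equal(coulomb_energy(s20, p), oracle, tolerance = 1e-9)

  sbad <- pair_structure(2, spacing = 1e-9, charge = 1)
  expect_error(coulomb_energy(sbad, p), "overlap")
})

test_that("HCT Born radii match the analytic descreening integral", {
  p <- ff_params()
  iso <- pair_structure(1)
  iso$radius <- 1.8
  expect_equal(born_radii(iso, p), 1.8)

  # two-atom system vs independent numeric evaluation of the descreening
  # integral over the (scaled) neighbor sphere
  two <- pair_structure(2, spacing = 4)
  two$radius <- c(1.5, 1.2)
  got <- born_radii(two, p)
  num_int <- function(d, rho_i, rho_j) {
    lo <- max(rho_i, d - rho_j); hi <- d + rho_j
    f <- function(r) ((1 - (r^2 + d^2 - rho_j^2) / (2 * r * d)) / 2) / r^2
    stats::integrate(f, lo, hi, rel.tol = 1e-10)$value
  }
  expect_equal(got[1], 1 / (1 / 1.5 - num_int(4, 1.5, p$hct_scale * 1.2)),
               tolerance = 1e-9)
  expect_equal(got[2], 1 / (1 / 1.2 - num_int(4, 1.2, p$hct_scale * 1.5)),
               tolerance = 1e-9)

  # burial among neighbors increases the effective radius
  center <- pair_structure(1); center$radius <- 1.5
  shell_pts <- 5 * mtassoc:::fibonacci_sphere(12)
  shell <- mt_structure(tibble::tibble(
    elety = "CA", x = c(0, shell_pts[, 1]), y = c(0, shell_pts[, 2]),
    z = c(0, shell_pts[, 3]), chain = "A", resno = 1:13, resname = "GLY"))
  shell$radius <- 1.5
  r_buried <- born_radii(shell, p)[1]
  expect_gt(r_buried, 1.5)
  # descreening beyond the 12 A cutoff is excluded
  far <- pair_structure(2, spacing = 13)
  far$radius <- 1.5
  expect_equal(born_radii(far, p), c(1.5, 1.5))
})

test_that("GB energy reproduces the Born closed form and the pair formula", {
  for (case in list(c(q = 1, R = 2, eps = 80), c(q = -2, R = 3.1, eps = 40),
                    c(q = 0.5, R = 1.2, eps = 78.5))) {
    s <- pair_structure(1, charge = case[["q"]])
    s$radius <- case[["R"]]
    p <- ff_params(eps_in = 1, eps_out = case[["eps"]], ionic_strength = 0)
    born <- -(332.0636 / 2) * (1 - 1 / case[["eps"]]) * case[["q"]]^2 /
      case[["R"]]
    expect_equal(gb_energy(s, p), born, tolerance = 1e-9)
  }
  # example magnitude: unit charge, 2 A radius
  s1 <- pair_structure(1, charge = 1); s1$radius <- 2
  expect_equal(gb_energy(s1, ff_params(ionic_strength = 0)), -81.98,
               tolerance = 1e-3)

  expect_equal(gb_energy(pair_structure(5, charge = 0)), 0)

  # two-charge system vs direct evaluation of Still's function
  p <- ff_params(ionic_strength = 0.15)
  two <- pair_structure(2, spacing = 5, charge = c(1, -1))
  two$radius <- c(2, 1.6)
  R <- born_radii(two, p)
  terms <- 0
  for (i in 1:2) for (j in 1:2) {
    rij <- if (i == j) 0 else 5
    f <- sqrt(rij^2 + R[i] * R[j] * exp(-rij^2 / (4 * R[i] * R[j])))
    terms <- terms + (1 / p$eps_in - exp(-p$kappa * f) / p$eps_out) *
      two$charge[i] * two$charge[j] / f
  }
  expect_equal(gb_energy(two, p), -(332.0636 / 2) * terms, tolerance = 1e-9)
})

test_that("Lennard-Jones energy matches the 12-6 form and the oracle", {
  p <- ff_params()
  pair <- pair_structure(2, spacing = 4)   # at r_min
  expect_equal(lj_energy(pair, p), -0.1, tolerance = 1e-12)
  farpair <- pair_structure(2, spacing = 1e4)
  expect_lt(abs(lj_energy(farpair, p)), 1e-12)

  set.seed(77)
  n <- 15
  s <- mt_structure(tibble::tibble(
    elety = "CA", x = runif(n, 0, 12), y = runif(n, 0, 12),
    z = runif(n, 0, 12), chain = "A", resno = seq_len(n), resname = "GLY"))
  xyz <- coords(s)
  oracle <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    sr6 <- (4 / r)^6
    oracle <- oracle + 0.1 * (sr6^2 - 2 * sr6)
  }
  expect_equal(lj_energy(s, p), oracle, tolerance = 1e-9)

  # Eq-style additivity of the reported components
  s$charge <- rep(c(1, -1, 0), length.out = n)
  en <- mmgb_energy(s, p)
  expect_identical(en$e_mm_gb, en$e_elec + en$e_vdw)
})

test_that("binding arithmetic reproduces the reference decomposition", {
  ref <- reference_table("binding_components")
  de <- binding_delta(ref$e_complex, ref$e_mtbd, ref$e_mt)
  expect_equal(round(de, 2), c(-40.84, 20.76, -28.75, 25.05))
})

test_that("rigid-body binding energy is transform-invariant with clean limits", {
  spec <- fast_spec()
  s <- generate_system(spec)
  be <- binding_energy(s)
  expect_equal(be$de_binding,
               binding_delta(be$e_complex, be$e_part_a, be$e_part_b))

  set.seed(55)
  st <- apply_transform(s, random_rotation(), rnorm(3, sd = 50))
  bet <- binding_energy(st)
  expect_equal(bet$de_binding, be$de_binding, tolerance = 1e-6)

  # far-separated parts with strong screening: dE -> 0
  sfar <- offset_binder(s, 250)
  pfar <- ff_params(ionic_strength = 500)
  expect_lt(abs(binding_energy(sfar, params = pfar)$de_binding), 1e-6)

  expect_error(binding_energy(s, group_a = "binder", group_b = "binder"),
               "overlap")
})

test_that("ensemble binding energies select contact-bearing snapshots", {
  spec <- fast_spec()
  base <- generate_system(spec)
  e <- generate_ensemble(base, spec, 0)
  ct <- contact_table(e, "tail_b")

  en <- ensemble_binding_energy(e, ct, max_snapshots = 8)
  oracle_sel <- ct$per_frame$frame[ct$per_frame$n_contacts >= 1]
  expect_lte(en$n_snapshots, 8)
  expect_gte(length(oracle_sel), en$n_snapshots)

  # identical frames -> SD exactly 0
  one <- ensemble_frame(e, which(ct$per_frame$n_contacts >= 1)[1])
  xyzrep <- array(rep(coords(one), each = 4), c(4, nrow(one), 3))
  erep <- mt_ensemble(one, xyzrep)
  ctrep <- contact_table(erep, "tail_b", window = 1)
  enrep <- ensemble_binding_energy(erep, ctrep, max_snapshots = Inf)
  expect_equal(enrep$sd, 0)
  expect_equal(enrep$n_snapshots, sum(ctrep$per_frame$n_contacts >= 1))

  # an ensemble with no contacts errors with a count report
  e55 <- generate_ensemble(offset_binder(base, 55), spec, 55)
  ct55 <- contact_table(e55, "tail_b")
  expect_error(ensemble_binding_energy(e55, ct55), "no contact-bearing")
})

test_that("tail-mediated interactions make binding more favorable", {
  spec <- synthetic_spec(n_frames = 80, n_runs = 2, seed = 11)
  base <- generate_system(spec)
  e <- generate_ensemble(base, spec, 0)
  ct <- contact_table(e, "tail_b")
  ew <- ensemble_binding_energy(e, ct, strip_tails = FALSE, max_snapshots = 30)
  en <- ensemble_binding_energy(e, ct, strip_tails = TRUE, max_snapshots = 30)
  expect_lt(ew$de_binding, en$de_binding)
})
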