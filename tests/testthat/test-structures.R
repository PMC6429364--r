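test_that("PDB round-trip preserves atoms, order and coordinates", {
  # 1-atom minimal file
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1      11.104  13.207   2.100  1.00  0.00",
    "END"), f1)
  s1 <- read_structure(f1)
  expect_equal(nrow(s1), 1)
  expect_equal(unname(coords(s1)[1, ]), c(11.104, 13.207, 2.100))

  # synthetic 2-chain, 10-residue file generated programmatically
  s <- mt_structure(tibble::tibble(
    elety = "CA", x = rnorm(10, sd = 20), y = rnorm(10, sd = 20),
    z = rnorm(10, sd = 20),
    chain = rep(c("A", "B"), each = 5), resno = rep(1:5, 2),
    resname = rep(c("ALA", "GLY", "LYS", "GLU", "SER"), 2)))
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f2)
  s2 <- read_structure(f2)
  expect_equal(nrow(s2), 10)
  expect_equal(length(unique(s2$chain)), 2)
  expect_equal(n_residues(s2), 10)
  expect_equal(s2$resname, s$resname)
  expect_equal(s2$chain, s$chain)
  expect_equal(coords(s2), coords(s), tolerance = 2e-3)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3 + 1e-9)
})

test_that("malformed and empty PDB files fail with a line diagnosis", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  GLY A   1      11.104  13.207   x.xxx",
               "END"), f)
  expect_error(read_structure(f), "line 1")
  f2 <- withr::local_tempfile(fileext = ".pdb")
  file.create(f2)
  expect_error(read_structure(f2), "empty")
})

test_that("extended tail builder produces one residue per letter at 3.8 A", {
  tail_a <- build_extended_tail(ehook_sequences[["alpha"]])
  expect_equal(n_residues(tail_a), 17)
  ca <- coords(tail_a)[tail_a$elety == "CA", ]
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(steps - 3.8) < 0.01))

  expect_equal(nrow(build_extended_tail("")), 0)
  expect_error(build_extended_tail("AXB"), "unknown")

  # ionizable-residue count oracle: brute-force letter count
  seq_b <- ehook_sequences[["beta"]]
  n_acid <- sum(strsplit(seq_b, "")[[1]] %in% c("D", "E"))
  tail_b <- build_extended_tail(seq_b)
  expect_equal(n_residues(tail_b), 19)
  expect_equal(sum(tail_b$resname %in% c("ASP", "GLU") &
                     tail_b$elety == "SC"), n_acid)
})

test_that("rigid transforms map coordinates exactly and validate inputs", {
  s <- line_structure(8)
  expect_equal(coords(apply_transform(s, diag(3), c(0, 0, 0))), coords(s))

  t1 <- c(3, -2, 7)
  st <- apply_transform(s, diag(3), t1)
  expect_equal(colMeans(coords(st)) - colMeans(coords(s)), t1,
               ignore_attr = TRUE)

  set.seed(3)
  R1 <- random_rotation(); R2 <- random_rotation()
  t2 <- rnorm(3)
  a <- apply_transform(apply_transform(s, R1, t1), R2, t2)
  b <- apply_transform(s, R2 %*% R1, as.numeric(R2 %*% t1) + t2)
  expect_lt(max(abs(coords(a) - coords(b))), 1e-9)

  expect_error(apply_transform(s, diag(3) * 2), "rotation")
  expect_error(apply_transform(s, diag(c(1, 1, -1))), "rotation")
})

test_that("offset_binder displaces only the binder along the axis", {
  s <- generate_system(fast_spec())
  expect_equal(coords(offset_binder(s, 0)), coords(s))

  d <- 35
  so <- offset_binder(s, d)
  ib <- group_idx(s, "binder")
  delta <- colMeans(coords(so)[ib, ]) - colMeans(coords(s)[ib, ])
  expect_equal(delta, c(0, 0, 35), ignore_attr = TRUE)
  others <- setdiff(seq_len(nrow(s)), ib)
  expect_equal(coords(so)[others, ], coords(s)[others, ])

  back <- offset_binder(so, -d)
  expect_lt(max(abs(coords(back) - coords(s))), 1e-9)

  s_no <- line_structure(5)
  expect_error(offset_binder(s_no, 5), "binder")
})

test_that("offset commutes with whole-system rigid transforms", {
  s <- generate_system(fast_spec())
  set.seed(5)
  R <- random_rotation(); tr <- rnorm(3, sd = 10)
  p0 <- offset_protocol()
  p_rot <- offset_protocol(axis = as.numeric(R %*% p0$axis))
  a <- apply_transform(offset_binder(s, 25, p0), R, tr)
  b <- offset_binder(apply_transform(s, R, tr), 25, p_rot)
  expect_lt(max(abs(coords(a) - coords(b))), 1e-9)
})

test_that("clash removal translates the binder until the cutoff is met", {
  s <- generate_system(fast_spec())
  clean <- remove_clashes(s, cutoff = 2.0)
  expect_equal(clash_report(clean)$displacement, 0)
  expect_equal(coords(clean), coords(s))

  # construct a clash: drop the binder into the filament
  s_bad <- offset_binder(s, -3)
  fixed <- remove_clashes(s_bad, cutoff = 2.0)
  rep_ <- clash_report(fixed)
  expect_gt(nrow(rep_$pairs), 0)
  expect_gt(rep_$displacement, 0)
  ib <- intersect(group_idx(fixed, "binder"), which(fixed$is_heavy))
  if_ <- intersect(group_idx(fixed, "filament"), which(fixed$is_heavy))
  d2 <- outer(rowSums(coords(fixed)[ib, ]^2), rowSums(coords(fixed)[if_, ]^2),
              "+") - 2 * coords(fixed)[ib, ] %*% t(coords(fixed)[if_, ])
  expect_gte(sqrt(min(d2)), 2.0)

  # filament and tail atoms never move
  others <- setdiff(seq_len(nrow(s_bad)), group_idx(s_bad, "binder"))
  expect_equal(coords(fixed)[others, ], coords(s_bad)[others, ])

  # displacement monotone nondecreasing in cutoff
  disp <- vapply(c(2, 3, 4), function(co) {
    clash_report(remove_clashes(s_bad, cutoff = co))$displacement
  }, numeric(1))
  expect_true(all(diff(disp) >= 0))
})

test_that("fixed-pKa ionization reproduces the letter-count oracle", {
  polyg <- build_extended_tail("GGGGGG")
  expect_equal(net_charge(assign_ionization(polyg)), 0)

  for (sq in c(ehook_sequences[["beta"]], ehook_sequences[["alpha"]],
               "KRDEHKG", "DDDDKKRR")) {
    letters1 <- strsplit(sq, "")[[1]]
    oracle <- sum(letters1 %in% c("K", "R")) - sum(letters1 %in% c("D", "E"))
    s <- assign_ionization(build_extended_tail(sq))
    expect_equal(net_charge(s), oracle)
  }
  # beta tail: 11 acidic residues
  sb <- assign_ionization(build_extended_tail(ehook_sequences[["beta"]]))
  expect_equal(net_charge(sb), -11)

  # termini flag adds +1/-1 per chain (net zero)
  st <- assign_ionization(build_extended_tail("GAG"), charge_termini = TRUE)
  expect_equal(net_charge(st), 0)
  expect_equal(st$charge[1], 1)

  # His neutral at pH 7, charged at pH 5
  sh <- assign_ionization(build_extended_tail("H"))
  expect_equal(net_charge(sh), 0)
  sh5 <- assign_ionization(build_extended_tail("H"),
                           rules = ionization_rules(pH = 5))
  expect_equal(net_charge(sh5), 1)
})

test_that("PQR files are parsed with charges and radii", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM 1 CA GLY A 1 0.000 0.000 0.000 -0.500 1.900",
    "ATOM 2 NZ LYS A 2 3.800 0.000 0.000 1.000 1.625"), f)
  s <- read_pqr(f)
  expect_equal(s$charge, c(-0.5, 1))
  expect_equal(s$radius, c(1.9, 1.625))
  expect_equal(s$chain, c("A", "A"))
  # chain-free dialect
  f2 <- withr::local_tempfile(fileext = ".pqr")
  writeLines("ATOM 1 CA GLY 1 0.0 0.0 0.0 -1.0 2.0", f2)
  s2 <- read_pqr(f2)
  expect_equal(s2$charge, -1)
})
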