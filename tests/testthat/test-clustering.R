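test_that("degenerate ensembles cluster as expected", {
  s <- line_structure(8)
  xyz <- array(rep(coords(s), each = 12), c(12, 8, 3))
  e <- mt_ensemble(s, xyz)
  cl <- daura_cluster(e, selection = 1:8, cutoff = 2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$population, 100)
  expect_equal(sort(cl$members[[1]]), 1:12)

  # cutoff below every pairwise RMSD -> singletons
  eb <- blob_ensemble(sizes = rep(1, 8), spread = 0)
  clb <- daura_cluster(eb, selection = 1:10, cutoff = 1e-4)
  expect_equal(nrow(clb), 8)
  expect_true(all(clb$population == 100 / 8))

  expect_error(daura_cluster(matrix(numeric(0), 0, 0), cutoff = 1), "empty")
})

test_that("planted blob populations are recovered and match the brute oracle", {
  e <- blob_ensemble(sizes = c(30, 15, 5), spread = 0.05)
  cl <- daura_cluster(e, selection = 1:10, cutoff = 1.5)
  expect_equal(nrow(cl), 3)
  expect_equal(cl$population, c(60, 30, 10))
  expect_equal(sum(lengths(cl$members)), 50)

  M <- pairwise_rmsd(e, selection = 1:10)
  oracle <- daura_brute(M, 1.5)
  ocl <- sort(vapply(oracle, function(x) length(x$members), integer(1)),
              decreasing = TRUE)
  expect_equal(lengths(cl$members), ocl)
})

test_that("clustering equals the brute-force oracle on random ensembles", {
  set.seed(17)
  for (rep in 1:10) {
    nfr <- sample(10:40, 1)
    nblob <- sample(2:4, 1)
    sizes <- as.vector(stats::rmultinom(1, nfr - nblob, rep(1, nblob))) + 1
    e <- blob_ensemble(sizes = sizes, spread = runif(1, 0.02, 0.4),
                       seed = rep * 13)
    cutoff <- runif(1, 0.5, 3)
    M <- pairwise_rmsd(e, selection = 1:10)
    got <- daura_cluster(M, cutoff = cutoff)
    oracle <- daura_brute(M, cutoff)
    # same partition: same number of clusters, same member sets
    expect_equal(nrow(got), length(oracle))
    got_sets <- lapply(got$members, sort)
    oracle_sets <- lapply(oracle, function(x) sort(x$members))
    expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                    vapply(oracle_sets, paste, character(1), collapse = ","))
    expect_equal(sum(lengths(got$members)), nfr)
    expect_equal(sum(got$population), 100, tolerance = 1e-9)
  }
})

test_that("clustering is invariant to frame permutation up to tie-breaks", {
  e <- blob_ensemble(sizes = c(12, 6), spread = 0.05, seed = 19)
  cl <- daura_cluster(e, selection = 1:10, cutoff = 1.5)
  set.seed(23)
  perm <- sample(n_frames(e))
  ep <- ensemble_subset(e, perm)
  clp <- daura_cluster(ep, selection = 1:10, cutoff = 1.5)
  expect_equal(clp$population, cl$population)
  # member sets map back through the permutation
  back <- lapply(clp$members, function(m) sort(perm[m]))
  expect_setequal(vapply(back, paste, character(1), collapse = ","),
                  vapply(lapply(cl$members, sort), paste, character(1),
                         collapse = ","))
})

test_that("top_k truncates without renormalising and warns when short", {
  e <- blob_ensemble(sizes = c(20, 10, 5), spread = 0.05)
  cl <- daura_cluster(e, selection = 1:10, cutoff = 1.5)
  t1 <- top_k(cl, 2)
  expect_equal(nrow(t1), 2)
  expect_equal(t1$population, cl$population[1:2])
  expect_warning(t5 <- top_k(cl, 5), "3 cluster")
  expect_equal(nrow(t5), 3)
  single <- daura_cluster(
    mt_ensemble(line_structure(8),
                array(rep(coords(line_structure(8)), each = 3), c(3, 8, 3))),
    selection = 1:8, cutoff = 2)
  expect_equal(top_k(single, 1), single)
})

test_that("cross-state matrices flag the printed minima", {
  Ma <- reference_crossstate_block("cyto_0")
  csa <- cross_state_matrix(Ma)
  expect_equal(csa$col_minima$value, c(2.68, 2.28, 2.31, 3.06, 4.1))
  expect_equal(csa$global_min, 2.28)
  # exhaustive-scan oracle on the same matrix
  expect_equal(csa$global_min, min(as.vector(Ma)))
  expect_equal(csa$col_minima$value, apply(Ma, 2, min), ignore_attr = TRUE)

  Md <- reference_crossstate_block("axo_25")
  csd <- cross_state_matrix(Md)
  expect_equal(csd$global_min, 2.15)
  expect_equal(unique(csd$col_minima$row), 4)

  # random matrices vs exhaustive scan
  set.seed(29)
  for (rep in 1:20) {
    M <- matrix(runif(25, 1, 9), 5, 5)
    cs <- cross_state_matrix(M)
    expect_equal(cs$global_min, min(M))
    expect_equal(cs$col_minima$value, apply(M, 2, min), ignore_attr = TRUE)
    expect_equal(cs$row_minima$value, apply(M, 1, min), ignore_attr = TRUE)
  }
})

test_that("cross-state matrices from cluster sets have zero diagonal", {
  e <- blob_ensemble(sizes = c(10, 6, 4), spread = 0.05, seed = 3)
  cl <- daura_cluster(e, selection = 1:10, cutoff = 1.5)
  cs <- cross_state_matrix(cl, cl)
  expect_equal(diag(cs$rmsd), rep(0, nrow(cs$rmsd)), tolerance = 1e-9)
  long <- tidy(cs)
  expect_equal(sum(long$is_col_min), ncol(cs$rmsd))
})
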