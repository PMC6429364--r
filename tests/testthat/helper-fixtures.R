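# Shared fixtures, built in code.

# minimal structure: n CA beads on a shallow zig-zag (non-collinear, so
# superposition is well posed) with optional charges
line_structure <- function(n = 10, spacing = 3.8, charge = 0, group = "") {
  mt_structure(tibble::tibble(
    elety = "CA", x = (seq_len(n) - 1) * spacing,
    y = rep_len(c(0, 1.5), n), z = 0,
    chain = "A", resno = seq_len(n), resname = "GLY",
    charge = rep_len(charge, n), group = group))
}

# exactly-spaced straight pair/chain along x (for closed-form energy checks)
pair_structure <- function(n = 2, spacing = 1, charge = 0) {
  mt_structure(tibble::tibble(
    elety = "CA", x = (seq_len(n) - 1) * spacing, y = 0, z = 0,
    chain = "A", resno = seq_len(n), resname = "GLY",
    charge = rep_len(charge, n)))
}

# ensemble of iid Gaussian-jittered copies of a base structure
gaussian_ensemble <- function(s, n_frames, sigma, runs = 1, seed = 1) {
  set.seed(seed)
  n_at <- nrow(s)
  xyz <- array(0, c(n_frames * runs, n_at, 3))
  for (f in seq_len(n_frames * runs)) {
    xyz[f, , ] <- coords(s) + matrix(rnorm(n_at * 3, sd = sigma), n_at, 3)
  }
  mt_ensemble(s, xyz, run = rep(seq_len(runs), each = n_frames))
}

# ensemble of conformationally distinct "blobs": each blob has its own
# random reference conformation, frames are tight copies of it
blob_ensemble <- function(sizes = c(30, 15, 5), n_atoms = 10, spread = 0.05,
                          seed = 7) {
  set.seed(seed)
  s <- line_structure(n_atoms)
  refs <- lapply(seq_along(sizes), function(b) matrix(rnorm(n_atoms * 3, sd = 6),
                                                      n_atoms, 3))
  xyz <- array(0, c(sum(sizes), n_atoms, 3))
  idx <- 0
  for (b in seq_along(sizes)) {
    for (k in seq_len(sizes[b])) {
      idx <- idx + 1
      xyz[idx, , ] <- refs[[b]] + matrix(rnorm(n_atoms * 3, sd = spread),
                                         n_atoms, 3)
    }
  }
  mt_ensemble(s, xyz)
}

# independent brute-force Daura re-implementation (oracle)
daura_brute <- function(M, cutoff) {
  n <- nrow(M)
  alive <- rep(TRUE, n)
  out <- list()
  while (any(alive)) {
    best <- 0; best_i <- NA
    for (i in seq_len(n)) {
      if (!alive[i]) next
      cnt <- sum(M[i, alive] <= cutoff)  # includes self
      if (cnt > best) { best <- cnt; best_i <- i }
    }
    members <- which(alive & M[best_i, ] <= cutoff)
    out[[length(out) + 1]] <- list(rep = best_i, members = members)
    alive[members] <- FALSE
  }
  out
}

random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    if (sum(q^2) > 1e-6) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# small synthetic spec for fast unit tests
fast_spec <- function(...) {
  synthetic_spec(n_frames = 30, n_runs = 2, seed = 11, ...)
}
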