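# Daura (GROMOS-style) RMSD clustering: greedy neighbor-count clustering on
# the pairwise superposed-RMSD matrix, top-k truncation, and bound/free
# cross-state RMSD matrices with per-column and per-row minima flagged.

#' Pairwise superposed RMSD matrix of an ensemble
#'
#' @param e an `mt_ensemble`.
#' @param selection atom row indices used for the RMSD (default: CA atoms).
#' @param superpose superpose each pair before the RMSD (default TRUE).
#' @return Symmetric n_frames x n_frames matrix, Angstrom.
#' @export
pairwise_rmsd <- function(e, selection = NULL, superpose = TRUE) {
  s <- e$topology
  if (is.null(selection)) selection <- which(s$elety == "CA")
  n <- n_frames(e)
  if (n > 5000) {
    warn("pairwise RMSD on > 5000 frames; consider subsampling")
  }
  M <- matrix(0, n, n)
  frames <- lapply(seq_len(n), function(i) e$xyz[i, selection, ])
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      M[i, j] <- M[j, i] <- rmsd(frames[[i]], frames[[j]],
                                 superpose = superpose)
    }
  }
  M
}

#' Daura clustering of an ensemble
#'
#' Greedy neighbor-count clustering: the unassigned frame with the most
#' unassigned neighbors within `cutoff` (superposed RMSD) becomes the
#' representative of a new cluster containing itself and those neighbors;
#' assigned frames are removed and the procedure repeats. Ties on neighbor
#' count are broken by lowest frame index. Cluster populations are
#' percentages of all frames and sum to 100 over all clusters.
#'
#' @param e an `mt_ensemble` (non-empty), or a precomputed pairwise RMSD
#'   matrix.
#' @param selection atom indices for the RMSD (see [pairwise_rmsd()]).
#' @param cutoff neighbor RMSD cutoff in Angstrom (> 0); 2 is conventional
#'   for a compact domain, 1.5 for a short disordered tail.
#' @param superpose superpose frames pairwise before the RMSD.
#' @return Object of class `mt_clusters`: tibble with `cluster`,
#'   `population` (percent), `representative` (frame id) and a list-column
#'   `members`; the ensemble and settings ride along as attributes.
#' @export
daura_cluster <- function(e, selection = NULL, cutoff = 2.0,
                          superpose = TRUE) {
  stopifnot(cutoff > 0)
  if (is.matrix(e)) {
    M <- e
    n <- nrow(M)
    ens <- NULL
  } else {
    if (n_frames(e) == 0) abort("empty ensemble")
    M <- pairwise_rmsd(e, selection, superpose)
    n <- nrow(M)
    ens <- e
  }
  if (n == 0) abort("empty ensemble")
  neigh <- M <= cutoff
  diag(neigh) <- TRUE
  alive <- rep(TRUE, n)
  clusters <- list()
  while (any(alive)) {
    counts <- colSums(neigh[alive, , drop = FALSE]) * alive
    rep_id <- which.max(counts)          # ties: lowest index (which.max)
    members <- which(neigh[, rep_id] & alive)
    clusters[[length(clusters) + 1]] <- list(rep = rep_id, members = members)
    alive[members] <- FALSE
  }
  out <- tibble(
    cluster = seq_along(clusters),
    population = vapply(clusters, function(cl) 100 * length(cl$members) / n,
                        numeric(1)),
    representative = vapply(clusters, function(cl) cl$rep, integer(1)),
    members = lapply(clusters, function(cl) cl$members)
  ) |>
    arrange(desc(.data$population), .data$representative) |>
    mutate(cluster = row_number())
  attr(out, "ensemble") <- ens
  attr(out, "selection") <- selection
  attr(out, "cutoff") <- cutoff
  class(out) <- c("mt_clusters", class(out))
  out
}

#' Keep the k most populated clusters
#'
#' Populations keep their global percentages (no renormalisation). If fewer
#' than `k` clusters exist, all are returned with a warning.
#'
#' @param cs an `mt_clusters` result.
#' @param k number of clusters to keep (>= 1).
#' @return An `mt_clusters` tibble with at most `k` rows.
#' @export
top_k <- function(cs, k = 5) {
  stopifnot(k >= 1)
  if (k > nrow(cs)) {
    warn(sprintf("only %d cluster(s) available; returning all", nrow(cs)))
    return(cs)
  }
  out <- cs[seq_len(k), ]
  for (a in c("ensemble", "selection", "cutoff")) {
    attr(out, a) <- attr(cs, a)
  }
  class(out) <- class(cs)
  out
}

#' Representative coordinates of each cluster
#' @param cs an `mt_clusters` computed from an ensemble.
#' @return List of n x 3 matrices (selection atoms of each representative).
#' @export
cluster_representatives <- function(cs) {
  e <- attr(cs, "ensemble")
  if (is.null(e)) abort("clusters were built from a bare RMSD matrix")
  sel <- attr(cs, "selection")
  if (is.null(sel)) sel <- which(e$topology$elety == "CA")
  lapply(cs$representative, function(fi) e$xyz[fi, sel, ])
}

#' Cross-state RMSD matrix between free and bound cluster representatives
#'
#' `rmsd[i, j]` is the superposed RMSD between free-state representative i
#' and bound-state representative j. Column minima identify, for each bound
#' cluster, the most similar free-state cluster; row minima are reported as
#' well since the bolding convention of printed tables is ambiguous.
#'
#' @param free,bound `mt_clusters` over identical atom selections, or a bare
#'   numeric matrix for `free` (printed-table input; `bound` then ignored).
#' @return Object of class `mt_crossstate`: list with `rmsd` matrix,
#'   `row_pop`/`col_pop` (populations if known), `col_minima` and
#'   `row_minima` tibbles and `global_min`.
#' @export
cross_state_matrix <- function(free, bound = NULL) {
  if (is.matrix(free) && is.numeric(free)) {
    M <- free
    row_pop <- col_pop <- NULL
  } else {
    stopifnot(inherits(free, "mt_clusters"), inherits(bound, "mt_clusters"))
    sel_f <- attr(free, "selection"); sel_b <- attr(bound, "selection")
    if (!identical(length(sel_f %||% integer()), length(sel_b %||% integer()))) {
      abort("free and bound cluster sets use different atom selections")
    }
    rf <- cluster_representatives(free)
    rb <- cluster_representatives(bound)
    if (ncol(rf[[1]]) != 3 || nrow(rf[[1]]) != nrow(rb[[1]])) {
      abort("free and bound cluster sets use different atom selections")
    }
    M <- matrix(0, length(rf), length(rb))
    for (i in seq_along(rf)) {
      for (j in seq_along(rb)) M[i, j] <- rmsd(rf[[i]], rb[[j]])
    }
    row_pop <- free$population
    col_pop <- bound$population
  }
  col_minima <- tibble(
    col = seq_len(ncol(M)),
    row = unname(apply(M, 2, which.min)),
    value = unname(apply(M, 2, min)))
  row_minima <- tibble(
    row = seq_len(nrow(M)),
    col = unname(apply(M, 1, which.min)),
    value = unname(apply(M, 1, min)))
  structure(list(rmsd = M, row_pop = row_pop, col_pop = col_pop,
                 col_minima = col_minima, row_minima = row_minima,
                 global_min = min(M)),
            class = "mt_crossstate")
}

#' @export
print.mt_crossstate <- function(x, ...) {
  cat(sprintf("<mt_crossstate> %d free x %d bound clusters, global min %.3g A\n",
              nrow(x$rmsd), ncol(x$rmsd), x$global_min))
  print(round(x$rmsd, 2))
  invisible(x)
}
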