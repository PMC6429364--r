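# Heavy-atom contact counting between a tail group and a binder group:
# per-frame pair counts (cell-list accelerated, bit-identical to the
# all-pairs definition), per-run series with replicate means, per-residue
# totals and per-segment percentages.

#' Count heavy-atom contacts between two atom sets in one frame
#'
#' A contact is a pair (a in A, b in B) of heavy atoms with distance at most
#' `cutoff`. Counting uses spatial binning for large sets but is exactly
#' equal to the brute-force all-pairs definition.
#'
#' @param xyz n x 3 coordinate matrix for the whole frame.
#' @param idx_a,idx_b disjoint row-index vectors of the two atom sets
#'   (already restricted to heavy atoms by the callers).
#' @param cutoff contact distance in Angstrom (> 0).
#' @return Integer pair count (0 for empty groups).
#' @export
count_contacts <- function(xyz, idx_a, idx_b, cutoff = 4.0) {
  stopifnot(cutoff > 0)
  if (length(idx_a) == 0 || length(idx_b) == 0) return(0L)
  if (length(intersect(idx_a, idx_b)) > 0) abort("atom sets must be disjoint")
  contact_count_impl(xyz[idx_a, , drop = FALSE],
                     xyz[idx_b, , drop = FALSE], cutoff)
}

contact_count_impl <- function(A, B, cutoff) {
  if (nrow(A) * nrow(B) <= 40000) {
    return(sum(pair_dist2(A, B) <= cutoff^2))
  }
  # cell list on B with cell edge = cutoff; identical squared-distance
  # arithmetic to the brute-force path
  origin <- pmin(apply(A, 2, min), apply(B, 2, min))
  cell_of <- function(M) {
    ic <- floor(sweep(M, 2, origin) / cutoff)
    ic[, 1] * 73856093 + ic[, 2] * 19349663 + ic[, 3] * 83492791
  }
  icB <- floor(sweep(B, 2, origin) / cutoff)
  keyB <- icB[, 1] * 73856093 + icB[, 2] * 19349663 + icB[, 3] * 83492791
  bins <- split(seq_len(nrow(B)), keyB)
  icA <- floor(sweep(A, 2, origin) / cutoff)
  total <- 0L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(A))) {
    keys <- (icA[i, 1] + offs[, 1]) * 73856093 +
      (icA[i, 2] + offs[, 2]) * 19349663 +
      (icA[i, 3] + offs[, 3]) * 83492791
    cand <- unlist(bins[as.character(keys)], use.names = FALSE)
    if (length(cand) == 0) next
    d2 <- rowSums(sweep(B[cand, , drop = FALSE], 2, A[i, ])^2)
    total <- total + sum(d2 <= cutoff^2)
  }
  as.integer(total)
}

# per-pair logical matrix for residue-level accumulation (brute force; used
# on the modest group sizes of residue bookkeeping)
contact_pair_matrix <- function(xyz, idx_a, idx_b, cutoff) {
  pair_dist2(xyz[idx_a, , drop = FALSE], xyz[idx_b, , drop = FALSE]) <= cutoff^2
}

heavy_idx <- function(s, group) {
  intersect(group_idx(s, group), which(s$is_heavy))
}

#' Per-run contact time series with replicate mean
#'
#' Counts tail-binder heavy-atom contacts in every frame of the trailing
#' analysis window of each run and averages across runs at each frame index.
#'
#' @param e an `mt_ensemble` whose runs share the topology and length.
#' @param tail_group,binder_group group labels on the topology.
#' @param cutoff contact distance, Angstrom.
#' @param window trailing fraction of each run analysed (default last half).
#' @return A tibble of class `mt_contact_series` with columns `frame`
#'   (index within the window), `run`, `n_contacts`; the across-run mean
#'   series is in `attr(, "mean_series")` and via [contact_mean()].
#' @export
contact_series <- function(e, tail_group = "tail_b", binder_group = "binder",
                           cutoff = 4.0, window = 0.5) {
  runs <- unique(e$run)
  lens <- vapply(runs, function(r) sum(e$run == r), integer(1))
  if (length(unique(lens)) != 1) abort("replicate runs have unequal lengths")
  ew <- analysis_window(e, window)
  ia <- heavy_idx(ew$topology, tail_group)
  ib <- heavy_idx(ew$topology, binder_group)
  out <- vector("list", length(runs))
  for (k in seq_along(runs)) {
    idx <- which(ew$run == runs[k])
    counts <- vapply(idx, function(fi) {
      count_contacts(ew$xyz[fi, , ], ia, ib, cutoff)
    }, integer(1))
    out[[k]] <- tibble(frame = seq_along(idx), run = runs[k],
                       n_contacts = counts)
  }
  res <- bind_rows(out)
  mean_series <- res |>
    group_by(.data$frame) |>
    summarise(mean_contacts = mean(.data$n_contacts), .groups = "drop")
  attr(res, "mean_series") <- mean_series
  attr(res, "cutoff") <- cutoff
  class(res) <- c("mt_contact_series", class(res))
  res
}

#' Across-run mean contact series
#' @param cs result of [contact_series()].
#' @return Tibble with `frame` and `mean_contacts`.
#' @export
contact_mean <- function(cs) attr(cs, "mean_series")

#' Full contact bookkeeping for an ensemble
#'
#' Accumulates, over the analysis window of all runs, the per-frame pair
#' count, the per-binder-residue total and the per-segment total with
#' percentages.
#'
#' @inheritParams contact_series
#' @return A list of class `mt_contact_table` with tibbles `per_frame`,
#'   `per_residue`, `per_segment` and the settings used.
#' @export
contact_table <- function(e, tail_group = "tail_b", binder_group = "binder",
                          cutoff = 4.0, window = 0.5) {
  ew <- analysis_window(e, window)
  s <- ew$topology
  ia <- heavy_idx(s, tail_group)
  ib <- heavy_idx(s, binder_group)
  res_key <- paste(s$chain[ib], s$resno[ib])
  per_frame <- integer(n_frames(ew))
  res_tot <- setNames(numeric(length(unique(res_key))), unique(res_key))
  for (fi in seq_len(n_frames(ew))) {
    pm <- contact_pair_matrix(ew$xyz[fi, , ], ia, ib, cutoff)
    per_frame[fi] <- sum(pm)
    if (per_frame[fi] > 0) {
      by_res <- tapply(colSums(pm), res_key, sum)
      res_tot[names(by_res)] <- res_tot[names(by_res)] + by_res
    }
  }
  first_of_res <- ib[!duplicated(res_key)]
  per_residue <- tibble(
    chain = s$chain[first_of_res], resno = s$resno[first_of_res],
    resname = s$resname[first_of_res], segment = s$segment[first_of_res],
    n_contacts = as.numeric(res_tot[paste(s$chain[first_of_res],
                                          s$resno[first_of_res])])) |>
    arrange(desc(.data$n_contacts), .data$resno)
  per_segment <- aggregate_by_segment(
    per_residue |> group_by(.data$segment) |>
      summarise(n_contacts = sum(.data$n_contacts), .groups = "drop"))
  structure(list(per_frame = tibble(frame = seq_len(n_frames(ew)),
                                    run = ew$run, n_contacts = per_frame),
                 per_residue = per_residue, per_segment = per_segment,
                 cutoff = cutoff, window = window,
                 groups = c(tail = tail_group, binder = binder_group)),
            class = "mt_contact_table")
}

#' Aggregate contact counts by segment with percentages
#'
#' `percentage = 100 * count / total`, rounded half-up to two decimals in
#' the `percentage_2dp` column (the raw percentage is kept alongside).
#' Accepts either an `mt_contact_table` or a tibble with `segment` and
#' `n_contacts` columns (so printed count tables can be re-aggregated).
#'
#' @param x contact table or tibble of per-segment counts.
#' @return Tibble with `segment`, `n_contacts`, `percentage`,
#'   `percentage_2dp`, ordered by count descending.
#' @export
aggregate_by_segment <- function(x) {
  tab <- if (inherits(x, "mt_contact_table")) {
    x$per_residue |> group_by(.data$segment) |>
      summarise(n_contacts = sum(.data$n_contacts), .groups = "drop")
  } else {
    as_tibble(x)
  }
  if (!all(c("segment", "n_contacts") %in% names(tab))) {
    abort("need columns 'segment' and 'n_contacts'")
  }
  total <- sum(tab$n_contacts)
  tab |>
    mutate(percentage = if (total > 0) 100 * .data$n_contacts / total else 0,
           percentage_2dp = round_half_up(.data$percentage, 2)) |>
    arrange(desc(.data$n_contacts))
}

#' Top contacting residues
#'
#' Residues ranked by total contact count, descending; ties broken by
#' residue number ascending.
#'
#' @param x an `mt_contact_table`, or a tibble with `resno` and `n_contacts`
#'   (e.g. a printed residue-contact table).
#' @param k number of residues to return (default all nonzero).
#' @return Tibble of the top `k` residues with nonzero contacts.
#' @export
top_contact_residues <- function(x, k = Inf) {
  tab <- if (inherits(x, "mt_contact_table")) x$per_residue else as_tibble(x)
  if (!all(c("resno", "n_contacts") %in% names(tab))) {
    abort("need columns 'resno' and 'n_contacts'")
  }
  tab |>
    filter(.data$n_contacts > 0) |>
    arrange(desc(.data$n_contacts), .data$resno) |>
    head(n = if (is.finite(k)) k else nrow(tab))
}
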