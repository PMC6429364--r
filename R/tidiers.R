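# broom-style tidiers for fitted/derived objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a linear trend fit
#' @param x an `mt_linfit` from [fit_linear()].
#' @param ... unused.
#' @return One row per model term with estimate, std.error, statistic,
#'   p.value.
#' @method tidy mt_linfit
#' @export
tidy.mt_linfit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' One-row summary of a linear trend fit
#' @param x an `mt_linfit`.
#' @param ... unused.
#' @return Tibble with slope, intercept, r, r.squared, n.
#' @method glance mt_linfit
#' @export
glance.mt_linfit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept, r = x$r,
         r.squared = x$r^2, n = nrow(x$data))
}

#' Tidy a cluster set
#' @param x an `mt_clusters` from [daura_cluster()].
#' @param ... unused.
#' @return Tibble with cluster, population, representative, n_members.
#' @method tidy mt_clusters
#' @export
tidy.mt_clusters <- function(x, ...) {
  tibble(cluster = x$cluster, population = x$population,
         representative = x$representative,
         n_members = lengths(x$members))
}

#' One-row summary of a cluster set
#' @param x an `mt_clusters`.
#' @param ... unused.
#' @return Tibble with n_clusters, n_frames, top_population, cutoff.
#' @method glance mt_clusters
#' @export
glance.mt_clusters <- function(x, ...) {
  tibble(n_clusters = nrow(x),
         n_frames = sum(lengths(x$members)),
         top_population = max(x$population),
         cutoff = attr(x, "cutoff"))
}

#' Tidy a cross-state RMSD matrix
#' @param x an `mt_crossstate` from [cross_state_matrix()].
#' @param ... unused.
#' @return Long tibble with free, bound, rmsd, is_col_min, is_row_min.
#' @method tidy mt_crossstate
#' @export
tidy.mt_crossstate <- function(x, ...) {
  M <- x$rmsd
  long <- tibble(
    free = rep(seq_len(nrow(M)), ncol(M)),
    bound = rep(seq_len(ncol(M)), each = nrow(M)),
    rmsd = as.vector(M))
  long |>
    mutate(is_col_min = paste(.data$free, .data$bound) %in%
             paste(x$col_minima$row, x$col_minima$col),
           is_row_min = paste(.data$free, .data$bound) %in%
             paste(x$row_minima$row, x$row_minima$col))
}

#' Tidy an ensemble binding-energy result
#' @param x an `mt_energy` from [ensemble_binding_energy()].
#' @param ... unused.
#' @return Per-snapshot component tibble.
#' @method tidy mt_energy
#' @export
tidy.mt_energy <- function(x, ...) {
  attr(x, "per_snapshot")
}
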