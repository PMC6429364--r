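# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_tile
#'   geom_col geom_smooth labs scale_fill_gradient2 theme_minimal facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Plot a contact time series with its replicate mean
#' @param object an `mt_contact_series`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mt_contact_series <- function(object, ...) {
  ms <- contact_mean(object)
  ggplot(object, aes(x = .data$frame, y = .data$n_contacts,
                     group = .data$run)) +
    geom_line(alpha = 0.35) +
    geom_line(data = ms, aes(y = .data$mean_contacts, group = 1),
              linewidth = 0.9, colour = "firebrick") +
    labs(x = "frame (analysis window)", y = "tail-binder contacts",
         title = "Heavy-atom contacts per frame (replicates and mean)") +
    theme_minimal()
}

#' Plot a per-residue RMSF profile
#' @param object an `mt_rmsf`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mt_rmsf <- function(object, ...) {
  ggplot(object, aes(x = .data$resno, y = .data$rmsf)) +
    geom_line() +
    labs(x = "residue", y = "RMSF (Å)",
         title = sprintf("Per-residue RMSF (mean %.2f Å)",
                         mean_rmsf(object))) +
    theme_minimal()
}

#' Plot cluster populations
#' @param object an `mt_clusters`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mt_clusters <- function(object, ...) {
  ggplot(tidy(object), aes(x = factor(.data$cluster), y = .data$population)) +
    geom_col() +
    labs(x = "cluster", y = "population (%)",
         title = "Cluster populations (Daura clustering)") +
    theme_minimal()
}

#' Heatmap of a cross-state RMSD matrix with minima flagged
#' @param object an `mt_crossstate`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mt_crossstate <- function(object, ...) {
  long <- tidy(object)
  ggplot(long, aes(x = factor(.data$bound), y = factor(.data$free),
                   fill = .data$rmsd)) +
    geom_tile() +
    geom_point(data = long[long$is_col_min, ], size = 2) +
    scale_fill_gradient2(midpoint = mean(long$rmsd)) +
    labs(x = "bound-state cluster", y = "free-state cluster",
         fill = "RMSD (Å)",
         title = "Free vs bound representatives (dots: column minima)") +
    theme_minimal()
}

#' Plot a mid-plane slice of a potential grid
#' @param object an `mt_grid`.
#' @param axis slicing axis (1, 2 or 3).
#' @param index slice index (default: middle).
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mt_grid <- function(object, axis = 3, index = NULL, ...) {
  n <- object$dims
  if (is.null(index)) index <- (n[axis] + 1) / 2
  sl <- switch(axis,
               object$phi[index, , ],
               object$phi[, index, ],
               object$phi[, , index])
  df <- tibble(a = rep(seq_len(nrow(sl)), ncol(sl)),
               b = rep(seq_len(ncol(sl)), each = nrow(sl)),
               phi = as.vector(sl))
  ggplot(df, aes(x = .data$a, y = .data$b, fill = .data$phi)) +
    geom_tile() +
    scale_fill_gradient2() +
    labs(fill = "phi (kT/e)", title = "Electrostatic potential slice") +
    theme_minimal()
}

#' Scatter plot with fitted trend line for an RMSF fit
#' @param object an `mt_linfit`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.mt_linfit <- function(object, ...) {
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "firebrick") +
    labs(title = sprintf("slope %.3g, r = %.3f", object$slope, object$r)) +
    theme_minimal()
}
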