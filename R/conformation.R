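# Superposition and fluctuation analysis: Kabsch least-squares fitting,
# RMSD, per-residue RMSF about the ensemble mean, and linear trend fits of
# mean RMSF against offset distance or contact counts.

#' Kabsch superposition
#'
#' Finds the proper rotation and translation minimising the (weighted) RMSD
#' of `P` onto `Q`. Reflections are excluded.
#'
#' @param P,Q n x 3 coordinate matrices, n >= 3, not all collinear.
#' @param weights optional non-negative per-point weights.
#' @return List with `rotation` (3x3, det +1), `translation` (length 3) such
#'   that `P %*% t(rotation) + translation` best fits `Q`, and `rmsd`.
#' @export
kabsch_superpose <- function(P, Q, weights = NULL) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) abort("point counts differ")
  if (nrow(P) < 3) abort("need at least 3 points")
  w <- if (is.null(weights)) rep(1, nrow(P)) else weights
  stopifnot(length(w) == nrow(P), all(w >= 0), sum(w) > 0)
  w <- w / sum(w)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- t(Pc * w) %*% Qc
  sv <- svd(H)
  if (sv$d[2] < 1e-10) abort("points are collinear; superposition is degenerate")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- Pc %*% t(R)
  rmsd_val <- sqrt(sum(w * rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp), rmsd = rmsd_val)
}

#' Root-mean-square deviation between two conformations
#'
#' @param P,Q n x 3 coordinate matrices.
#' @param superpose optimally superpose `P` onto `Q` first (default TRUE).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(P, Q, superpose = TRUE) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q)) abort("point counts differ")
  if (superpose) {
    return(kabsch_superpose(P, Q)$rmsd)
  }
  sqrt(mean(rowSums((P - Q)^2)))
}

#' Per-residue RMSF profile of an ensemble
#'
#' Each frame is superposed onto the ensemble-average structure (one
#' refinement iteration: mean, fit, re-mean), then
#' `RMSF_i = sqrt(mean_t ||r_i(t) - rbar_i||^2)`. With replicate runs the
#' per-residue RMSF is computed per run and averaged across runs; the
#' ensemble mean RMSF is the arithmetic mean of the per-residue values.
#'
#' @param e an `mt_ensemble` with at least 2 frames.
#' @param selection row indices of the atoms to analyse (default: CA atoms
#'   of the binder group).
#' @param superpose superpose frames onto the running mean first; disable
#'   only for diagnostics on pre-aligned ensembles.
#' @param exclude_resno residue numbers (of the selection's structure) to
#'   drop from the selection, e.g. restrained stalk tips.
#' @return Tibble of class `mt_rmsf` with `chain`, `resno`, `resname`,
#'   `segment`, `rmsf`; the scalar ensemble average is in
#'   `attr(, "mean_rmsf")` and via [mean_rmsf()].
#' @export
rmsf <- function(e, selection = NULL, superpose = TRUE,
                 exclude_resno = NULL) {
  if (n_frames(e) < 2) abort("RMSF needs at least 2 frames")
  s <- e$topology
  if (is.null(selection)) {
    selection <- intersect(group_idx(s, "binder"), which(s$elety == "CA"))
  }
  if (!is.null(exclude_resno)) {
    selection <- selection[!s$resno[selection] %in% exclude_resno]
  }
  if (length(selection) < 3) abort("selection must keep at least 3 atoms")
  runs <- unique(e$run)
  prof <- matrix(0, length(selection), length(runs))
  for (k in seq_along(runs)) {
    idx <- which(e$run == runs[k])
    X <- e$xyz[idx, selection, , drop = FALSE]
    if (superpose) X <- superpose_onto_mean(X)
    mu <- apply(X, c(2, 3), mean)
    dev2 <- sweep(X, c(2, 3), mu)^2
    prof[, k] <- sqrt(apply(dev2, 2, sum) / length(idx))
  }
  per_res <- rowMeans(prof)
  out <- tibble(chain = s$chain[selection], resno = s$resno[selection],
                resname = s$resname[selection],
                segment = s$segment[selection], rmsf = per_res)
  attr(out, "mean_rmsf") <- mean(per_res)
  class(out) <- c("mt_rmsf", class(out))
  out
}

# fit every frame onto the frame-average, once refined
superpose_onto_mean <- function(X) {
  mu <- apply(X, c(2, 3), mean)
  for (pass in 1:2) {
    for (fi in seq_len(dim(X)[1])) {
      fit <- kabsch_superpose(X[fi, , ], mu)
      X[fi, , ] <- sweep(X[fi, , ] %*% t(fit$rotation), 2,
                         fit$translation, "+")
    }
    mu <- apply(X, c(2, 3), mean)
  }
  X
}

#' Ensemble-average RMSF
#'
#' Arithmetic mean of the per-residue RMSF values of an [rmsf()] profile.
#'
#' @param profile an `mt_rmsf` tibble.
#' @return Mean RMSF in Angstrom.
#' @export
mean_rmsf <- function(profile) {
  attr(profile, "mean_rmsf") %||% mean(profile$rmsf)
}

#' Ordinary least-squares line fit
#'
#' Fits `y = intercept + slope * x` by OLS (via [lm()]) and reports the
#' Pearson correlation.
#'
#' @param x,y numeric vectors, length >= 3; `x` must vary.
#' @return Object of class `mt_linfit`: list with `slope`, `intercept`, `r`,
#'   the underlying `lm` fit and the data; supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("need at least 3 points")
  if (stats::var(x) == 0) abort("x has zero variance")
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  r <- if (stats::var(y) == 0) 0 else stats::cor(x, y)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = r, fit = fit, data = tibble(x = x, y = y)),
            class = "mt_linfit")
}

#' @export
print.mt_linfit <- function(x, ...) {
  cat(sprintf("<mt_linfit> slope %.4g, intercept %.4g, r = %.3f\n",
              x$slope, x$intercept, x$r))
  invisible(x)
}
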