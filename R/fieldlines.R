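# Electrostatic field-line tracing: E = -grad(phi) by centered differences
# on the potential grid, streamlines integrated with fixed-step 4th-order
# Runge-Kutta in both directions from each seed.

grid_gradient <- function(g) {
  phi <- g$phi
  n <- g$dims
  h <- g$spacing
  gx <- array(0, n); gy <- array(0, n); gz <- array(0, n)
  gx[2:(n[1] - 1), , ] <- (phi[3:n[1], , ] - phi[1:(n[1] - 2), , ]) / (2 * h)
  gy[, 2:(n[2] - 1), ] <- (phi[, 3:n[2], ] - phi[, 1:(n[2] - 2), ]) / (2 * h)
  gz[, , 2:(n[3] - 1)] <- (phi[, , 3:n[3]] - phi[, , 1:(n[3] - 2)]) / (2 * h)
  # one-sided at the faces
  gx[1, , ] <- (phi[2, , ] - phi[1, , ]) / h
  gx[n[1], , ] <- (phi[n[1], , ] - phi[n[1] - 1, , ]) / h
  gy[, 1, ] <- (phi[, 2, ] - phi[, 1, ]) / h
  gy[, n[2], ] <- (phi[, n[2], ] - phi[, n[2] - 1, ]) / h
  gz[, , 1] <- (phi[, , 2] - phi[, , 1]) / h
  gz[, , n[3]] <- (phi[, , n[3]] - phi[, , n[3] - 1]) / h
  list(ex = -gx, ey = -gy, ez = -gz)
}

field_at <- function(g, grad, p) {
  c(interp_safe(g, grad$ex, p), interp_safe(g, grad$ey, p),
    interp_safe(g, grad$ez, p))
}

interp_safe <- function(g, A, p) {
  tmp <- list(origin = g$origin, spacing = g$spacing, dims = g$dims,
              field = A)
  interp_grid(tmp, matrix(p, 1, 3), field = "field")
}

inside_grid <- function(g, p, margin = 1) {
  lo <- g$origin + margin * g$spacing
  hi <- g$origin + (g$dims - 1 - margin) * g$spacing
  all(p >= lo) && all(p <= hi)
}

#' Trace electrostatic field lines through a potential grid
#'
#' Unit-speed streamlines of `E = -grad(phi)` are integrated by fixed-step
#' RK4 in both directions from each seed. A line terminates at the grid
#' boundary, where the field magnitude falls below `e_min`, inside the sink
#' radius of a provided charge center, or at `max_steps`.
#'
#' @param g an `mt_grid`.
#' @param seeds m x 3 matrix of seed points (must lie inside the grid).
#' @param step step length in Angstrom.
#' @param charges optional k x 3 matrix of charge centers acting as sinks.
#' @param sink_radius termination radius around charge centers, Angstrom.
#' @param e_min low-field termination threshold, kT/e per Angstrom.
#' @param max_steps per-direction step cap.
#' @return Tibble of class `mt_fieldlines` with columns `line`, `seed`,
#'   `point` (order along the line), `x`, `y`, `z`, and per-line
#'   `termination` (`"boundary"`, `"low_field"`, `"charge_sink"` or
#'   `"max_steps"`, for the forward direction).
#' @export
trace_field_lines <- function(g, seeds, step = 0.5, charges = NULL,
                              sink_radius = 1.5, e_min = 1e-4,
                              max_steps = 2000) {
  seeds <- matrix(seeds, ncol = 3)
  grad <- grid_gradient(g)
  for (k in seq_len(nrow(seeds))) {
    if (!inside_grid(g, seeds[k, ])) abort("seed outside grid")
  }
  out <- vector("list", nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    fwd <- trace_one(g, grad, seeds[k, ], +1, step, charges, sink_radius,
                     e_min, max_steps)
    bwd <- trace_one(g, grad, seeds[k, ], -1, step, charges, sink_radius,
                     e_min, max_steps)
    pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
                 fwd$points[-1, , drop = FALSE])
    out[[k]] <- tibble(line = k, seed = k, point = seq_len(nrow(pts)),
                       x = pts[, 1], y = pts[, 2], z = pts[, 3],
                       termination = fwd$termination)
  }
  res <- bind_rows(out)
  class(res) <- c("mt_fieldlines", class(res))
  res
}

trace_one <- function(g, grad, p0, direction, step, charges, sink_radius,
                      e_min, max_steps) {
  pts <- matrix(p0, 1, 3)
  p <- p0
  termination <- "max_steps"
  unit_field <- function(p) {
    E <- direction * field_at(g, grad, p)
    nrm <- sqrt(sum(E^2))
    list(v = if (nrm > 0) E / nrm else c(0, 0, 0), mag = nrm)
  }
  for (i in seq_len(max_steps)) {
    f0 <- unit_field(p)
    if (f0$mag < e_min) { termination <- "low_field"; break }
    k1 <- f0$v
    p2 <- p + step / 2 * k1
    if (!inside_grid(g, p2)) { termination <- "boundary"; break }
    k2 <- unit_field(p2)$v
    p3 <- p + step / 2 * k2
    if (!inside_grid(g, p3)) { termination <- "boundary"; break }
    k3 <- unit_field(p3)$v
    p4 <- p + step * k3
    if (!inside_grid(g, p4)) { termination <- "boundary"; break }
    k4 <- unit_field(p4)$v
    pn <- p + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!inside_grid(g, pn)) { termination <- "boundary"; break }
    pts <- rbind(pts, pn)
    p <- pn
    if (!is.null(charges)) {
      d <- sqrt(rowSums(sweep(matrix(charges, ncol = 3), 2, p)^2))
      if (any(d <= sink_radius)) { termination <- "charge_sink"; break }
    }
  }
  list(points = pts, termination = termination)
}

#' Write field lines as a CSV polyline file
#' @param fl an `mt_fieldlines` tibble.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_field_lines <- function(fl, path) {
  readr::write_csv(fl, path)
  invisible(path)
}
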