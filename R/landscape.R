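#' Two-dimensional protein-ligand binding landscape
#'
#' Constructs the default benchmark potential: a flat "solvent" plateau, a
#' hard protein exclusion slab pierced by a narrow binding channel, a deep
#' bound well at the channel end, a pre-bound well near the channel mouth and
#' two shallow mis-bound (non-native) wells on the protein surface. All
#' energies are in units of \eqn{k_BT} (\eqn{k_BT \equiv 1}), lengths are
#' dimensionless. The five designated metastable regions are
#' \code{bound}, \code{prebound}, \code{misbound1}, \code{misbound2} and
#' \code{dissociated}.
#'
#' The well depths are chosen so that the bound state is much deeper than
#' every other well, placing the system in a sampling-hardness regime where
#' the mean bound-state exit time (order \eqn{10^6} Monte Carlo steps at the
#' default step size) far exceeds the length of typical short unbiased
#' trajectories. Overrides are merged over the defaults; an override that
#' makes the bound well no deeper than a surface well is rejected.
#'
#' @param overrides named list of parameters to override. Recognized names:
#'   \code{wells} (4-column matrix: center x, center y, depth, width),
#'   \code{plateau}, \code{box} (xlo, xhi, ylo, yhi), \code{slab_xhi},
#'   \code{channel} (channel end x, half-width), \code{wall_k},
#'   \code{wall_skin}, \code{dissociation_threshold}, \code{flatten_alpha}.
#' @return an object of class \code{potential_surface}.
#' @export
build_default_landscape <- function(overrides = NULL) {
  wells <- rbind(
    bound     = c(-1.70,  0.0, 11.5, 0.35),
    prebound  = c(-0.40,  0.0,  4.0, 0.30),
    misbound1 = c( 0.45,  2.0,  3.5, 0.45),
    misbound2 = c( 0.45, -2.0,  3.0, 0.45)
  )
  colnames(wells) <- c("cx", "cy", "depth", "sigma")
  surf <- list(
    wells = wells,
    plateau = 0.0,
    box = c(-3, 6, -4, 4),
    slab_xhi = 0.0,
    channel = c(-2.2, 0.55),   # channel end x, half width
    wall_k = 8.0,
    wall_skin = 0.2,
    mouth = c(0, 0),
    dissociation_threshold = 3.0,
    flatten_alpha = 1.0,
    lambda = 0.0
  )
  if (!is.null(overrides)) {
    if (!is.list(overrides)) stop("'overrides' must be a named list")
    for (nm in names(overrides)) {
      if (!nm %in% names(surf))
        stop(sprintf("unknown landscape parameter '%s'", nm))
      surf[[nm]] <- overrides[[nm]]
    }
    if (!is.matrix(surf$wells) || ncol(surf$wells) != 4)
      stop("'wells' must be a 4-column matrix (cx, cy, depth, sigma)")
    if (is.null(rownames(surf$wells)))
      rownames(surf$wells) <- paste0("well", seq_len(nrow(surf$wells)))
  }
  d <- surf$wells[, 3]
  if (any(d[-1] >= d[1]))
    stop("invalid landscape: the bound well (first row of 'wells') must be ",
         "strictly deeper than every other well; got depths ",
         paste(signif(d, 3), collapse = ", "))
  if (any(d < 0)) stop("well depths must be non-negative")
  class(surf) <- "potential_surface"
  surf
}

#' Flatten the attractive part of a landscape
#'
#' Returns a copy of the surface whose well depths are scaled by
#' \eqn{(1 - \lambda\alpha)} with flattening strength \eqn{\alpha} taken from
#' the surface (\code{flatten_alpha}). Walls and plateau are untouched: only
#' attractive interactions are boosted, so the excluded volume is never
#' flattened and the bias energy \eqn{b(x) = U^\lambda(x) - U^0(x) \ge 0}
#' everywhere.
#'
#' @param surface a \code{potential_surface}.
#' @param lambda flattening factor in \eqn{[0, 1]}; 0 returns the unbiased
#'   surface, 1 with \eqn{\alpha = 1} removes the wells entirely.
#' @return a \code{potential_surface} with scaled well depths.
#' @export
bias_surface <- function(surface, lambda) {
  stopifnot(inherits(surface, "potential_surface"))
  stopifnot_scalar(lambda, "lambda")
  if (lambda < 0 || lambda > 1)
    stop("'lambda' must lie in [0, 1]")
  out <- surface
  out$lambda <- lambda
  out
}

# effective lambda * alpha entering the C++ energy kernel
lambda_alpha <- function(surface) surface$lambda * surface$flatten_alpha

#' Evaluate the potential energy
#'
#' @param surface a \code{potential_surface}.
#' @param points 2-column matrix (or length-2 vector) of coordinates.
#' @return numeric vector of energies in \eqn{k_BT}; \code{Inf} in the
#'   excluded region.
#' @export
potential_energy <- function(surface, points) {
  stopifnot(inherits(surface, "potential_surface"))
  points <- as_points(points)
  .toy_energy_cpp(unclass(surface), points, lambda_alpha(surface))
}

#' Per-frame bias energies for a schedule of flattened ensembles
#'
#' Entry \eqn{(t, k)} is the unit-less bias energy
#' \eqn{b^k(x_t) = (U^k(x_t) - U^0(x_t))/k_BT} of frame \eqn{t} evaluated in
#' ensemble \eqn{k}. Column 1 (the unbiased ensemble) is identically zero.
#'
#' @param traj an \code{mc_trajectory} (or a 2-column coordinate matrix).
#' @param schedule a \code{bias_schedule}.
#' @param surface the \code{potential_surface} the trajectory was sampled on.
#' @return numeric matrix with one row per frame, one column per ensemble.
#' @export
compute_bias_matrix <- function(traj, schedule, surface) {
  stopifnot(inherits(schedule, "bias_schedule"),
            inherits(surface, "potential_surface"))
  pts <- if (inherits(traj, "mc_trajectory")) traj$positions else as_points(traj)
  u0 <- .toy_energy_cpp(unclass(surface), pts, 0.0)
  K <- schedule$n_ensembles
  b <- matrix(0.0, nrow(pts), K)
  for (k in seq_len(K)) {
    la <- schedule$scaling[k] * surface$flatten_alpha
    if (la != 0)
      b[, k] <- .toy_energy_cpp(unclass(surface), pts, la) - u0
  }
  b
}

#' Ladder of flattened bias ensembles
#'
#' Ensemble 1 is always the unbiased ensemble (\eqn{\lambda = 0}); scaling
#' factors must be non-decreasing, interpolating between the unbiased and the
#' fully boosted potential.
#'
#' @param scaling numeric vector of per-ensemble flattening factors
#'   \eqn{\lambda^k \in [0,1]}, first element 0.
#' @return an object of class \code{bias_schedule}.
#' @export
bias_schedule <- function(scaling = seq(0, 1, length.out = 5)) {
  if (scaling[1] != 0)
    stop("ensemble 1 must be unbiased: scaling[1] must be 0")
  if (any(diff(scaling) < 0))
    stop("scaling factors must be non-decreasing in the ensemble index")
  if (any(scaling < 0 | scaling > 1))
    stop("scaling factors must lie in [0, 1]")
  structure(list(n_ensembles = length(scaling), scaling = scaling,
                 temperature = 1.0),
            class = "bias_schedule")
}

as_points <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 2, byrow = TRUE)
  if (ncol(x) != 2) stop("points must have two columns (x, y)")
  storage.mode(x) <- "double"
  x
}

#' Assign coordinates to the five designated metastable regions
#'
#' @param surface a \code{potential_surface}.
#' @param points 2-column coordinate matrix.
#' @return factor with levels \code{bound}, \code{prebound},
#'   \code{misbound1}, \code{misbound2}, \code{dissociated}, \code{transit}.
#' @export
region_of <- function(surface, points) {
  stopifnot(inherits(surface, "potential_surface"))
  points <- as_points(points)
  w <- surface$wells
  lv <- c(rownames(w), "dissociated", "transit")
  out <- rep("transit", nrow(points))
  # nearest well within 2 sigma
  d2w <- sapply(seq_len(nrow(w)), function(i)
    sqrt((points[, 1] - w[i, 1])^2 + (points[, 2] - w[i, 2])^2) / w[i, 4])
  d2w <- matrix(d2w, nrow = nrow(points))
  nearest <- apply(d2w, 1, which.min)
  inwell <- d2w[cbind(seq_len(nrow(points)), nearest)] <= 2
  out[inwell] <- rownames(w)[nearest[inwell]]
  dm <- sqrt((points[, 1] - surface$mouth[1])^2 +
             (points[, 2] - surface$mouth[2])^2)
  out[dm > surface$dissociation_threshold] <- "dissociated"
  factor(out, levels = lv)
}

#' @export
print.potential_surface <- function(x, ...) {
  cat("2D binding landscape (kBT units)\n")
  cat(sprintf("  box: x in [%g, %g], y in [%g, %g]; plateau %g\n",
              x$box[1], x$box[2], x$box[3], x$box[4], x$plateau))
  cat(sprintf("  channel: x in [%g, %g], |y| <= %g\n",
              x$channel[1], x$slab_xhi, x$channel[2]))
  cat(sprintf("  lambda = %g (alpha = %g)\n", x$lambda, x$flatten_alpha))
  cat("  wells (cx, cy, depth, sigma):\n")
  print(round(x$wells, 3))
  invisible(x)
}

#' @export
print.bias_schedule <- function(x, ...) {
  cat(sprintf("bias schedule: %d ensembles, lambda = %s\n",
              x$n_ensembles, paste(signif(x$scaling, 3), collapse = ", ")))
  invisible(x)
}
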