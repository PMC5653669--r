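#' Grid discretizer with explicit dissociated states
#'
#' Axis-aligned binning of the 2D domain into Markov states, with frames
#' beyond the dissociation threshold (distance from the channel mouth)
#' mapped into a designated set of dissociated shell states occupying the
#' highest state indices, regardless of their grid cell. This mirrors the
#' practice of defining dissociated microstates explicitly by intermolecular
#' distance because the dissociated region has low metastability.
#'
#' @param surface a \code{potential_surface} (provides box, mouth and
#'   dissociation threshold).
#' @param dx,dy grid spacing.
#' @param n_shells number of dissociated distance shells (>= 1).
#' @param shell_width radial width of each shell beyond the threshold; the
#'   last shell is unbounded.
#' @return an object of class \code{discretizer} with fields
#'   \code{x_edges}, \code{y_edges}, \code{n_states},
#'   \code{dissociated_states} (1-based indices), \code{threshold}.
#' @export
grid_discretizer <- function(surface, dx = 0.5, dy = 0.5, n_shells = 2L,
                             shell_width = 1.5) {
  stopifnot(inherits(surface, "potential_surface"))
  b <- surface$box
  x_edges <- seq(b[1], b[2] + dx * 0.999, by = dx)
  y_edges <- seq(b[3], b[4] + dy * 0.999, by = dy)
  n_grid <- (length(x_edges) - 1L) * (length(y_edges) - 1L)
  n_states <- n_grid + n_shells
  structure(list(x_edges = x_edges, y_edges = y_edges,
                 n_grid = n_grid, n_states = n_states,
                 n_shells = as.integer(n_shells), shell_width = shell_width,
                 threshold = surface$dissociation_threshold,
                 mouth = surface$mouth,
                 dissociated_states = n_grid + seq_len(n_shells)),
            class = "discretizer")
}

#' Map a trajectory onto Markov state indices
#'
#' Every accessible frame receives exactly one state index in
#' \code{1..n_states}; frames farther than the dissociation threshold from
#' the channel mouth are assigned to the dissociated shells.
#'
#' @param traj an \code{mc_trajectory} or 2-column coordinate matrix.
#' @param disc a \code{discretizer}.
#' @param ensemble 0-based ensemble index of the data (defaults to the
#'   trajectory's label).
#' @param role \code{"tram"} for time-correlated data that may contribute
#'   transition counts, \code{"mbar"} for equilibrium data that never does.
#' @param bias optional per-frame bias matrix (frames x ensembles) attached
#'   to the discrete trajectory.
#' @return a \code{discrete_trajectory} with 1-based \code{states}.
#' @export
discretize <- function(traj, disc, ensemble = NULL, role = c("tram", "mbar"),
                       bias = NULL) {
  stopifnot(inherits(disc, "discretizer"))
  role <- match.arg(role)
  pts <- if (inherits(traj, "mc_trajectory")) traj$positions else as_points(traj)
  if (is.null(ensemble))
    ensemble <- if (inherits(traj, "mc_trajectory")) traj$ensemble_labels[1] else 0L
  ix <- findInterval(pts[, 1], disc$x_edges, rightmost.closed = TRUE)
  iy <- findInterval(pts[, 2], disc$y_edges, rightmost.closed = TRUE)
  nx <- length(disc$x_edges) - 1L
  ny <- length(disc$y_edges) - 1L
  bad <- which(ix < 1L | ix > nx | iy < 1L | iy > ny)
  if (length(bad) > 0)
    stop(sprintf("frame %d lies outside the discretizer domain", bad[1]))
  s <- (iy - 1L) * nx + ix
  dm <- sqrt((pts[, 1] - disc$mouth[1])^2 + (pts[, 2] - disc$mouth[2])^2)
  far <- dm > disc$threshold
  if (any(far)) {
    shell <- pmin(ceiling((dm[far] - disc$threshold) / disc$shell_width),
                  disc$n_shells)
    shell <- pmax(shell, 1L)
    s[far] <- disc$n_grid + shell
  }
  if (!is.null(bias)) {
    bias <- as.matrix(bias)
    if (nrow(bias) != length(s))
      stop("bias matrix must have one row per frame")
  }
  structure(list(states = as.integer(s), ensemble = as.integer(ensemble),
                 role = role, stride = 1L, bias = bias),
            class = "discrete_trajectory")
}

#' Turn trajectories into an equilibrium (MBAR) data set
#'
#' Removes the initial equilibration phase and subsamples the remainder, the
#' standard treatment of rapidly exchanging replica data before analyzing it
#' under a global-equilibrium assumption.
#'
#' @param trajs list of \code{discrete_trajectory} objects.
#' @param discard number of initial frames to drop.
#' @param stride keep every \code{stride}-th remaining frame.
#' @return list of \code{discrete_trajectory} objects with role
#'   \code{"mbar"} and updated stride bookkeeping.
#' @export
prepare_equilibrium_set <- function(trajs, discard = 0L, stride = 1L) {
  if (inherits(trajs, "discrete_trajectory")) trajs <- list(trajs)
  lapply(trajs, function(tr) {
    stopifnot(inherits(tr, "discrete_trajectory"))
    n <- length(tr$states)
    if (discard + stride >= n)
      stop(sprintf(
        "discard (%d) + stride (%d) must be smaller than trajectory length (%d)",
        discard, stride, n))
    keep <- seq.int(discard + 1L, n, by = stride)
    tr$states <- tr$states[keep]
    if (!is.null(tr$bias)) tr$bias <- tr$bias[keep, , drop = FALSE]
    tr$role <- "mbar"
    tr$stride <- as.integer(stride * tr$stride)
    tr$source_frames <- keep
    tr
  })
}

#' Per-ensemble transition-count tensor
#'
#' Counts lag-\code{lag} transitions from TRAM-set trajectories only;
#' MBAR-set (equilibrium) trajectories never contribute counts. In
#' \code{"sliding"} mode every pair \eqn{(t, t+\mathrm{lag})} is counted; in
#' \code{"sample"} mode the trajectory is first strided by the lag so counted
#' pairs do not overlap. Trajectories shorter than \code{lag + 1} contribute
#' zero counts (with a warning).
#'
#' @param trajs list of \code{discrete_trajectory} objects.
#' @param lag lag time in frames (>= 1).
#' @param n_states total state count.
#' @param n_ensembles number of ensembles K.
#' @param mode \code{"sliding"} or \code{"sample"}.
#' @return a \code{count_model} with fields \code{counts}
#'   (\code{n x n x K} array), \code{lag}, \code{state_sample_counts}
#'   (\code{n x K}, TRAM-set), \code{mbar_sample_counts} (length K),
#'   \code{trajs} (the input), \code{active} (initially all states).
#' @export
count_transitions <- function(trajs, lag, n_states, n_ensembles,
                              mode = c("sliding", "sample")) {
  mode <- match.arg(mode)
  if (inherits(trajs, "discrete_trajectory")) trajs <- list(trajs)
  if (lag < 1) stop("'lag' must be >= 1")
  n <- as.integer(n_states)
  K <- as.integer(n_ensembles)
  counts <- array(0.0, dim = c(n, n, K))
  ssc <- matrix(0.0, n, K)
  msc <- numeric(K)
  short_warned <- FALSE
  for (tr in trajs) {
    stopifnot(inherits(tr, "discrete_trajectory"))
    if (any(tr$states > n))
      stop("state index exceeds n_states")
    k <- tr$ensemble + 1L
    if (k > K) stop("ensemble index exceeds n_ensembles")
    if (tr$role == "mbar") {
      msc[k] <- msc[k] + length(tr$states)
      next
    }
    tb <- tabulate(tr$states, nbins = n)
    ssc[, k] <- ssc[, k] + tb
    s <- tr$states
    len <- length(s)
    if (len < lag + 1L) {
      if (!short_warned) {
        warning("trajectory shorter than lag + 1 contributes no counts")
        short_warned <- TRUE
      }
      next
    }
    if (mode == "sample") {
      s <- s[seq.int(1L, len, by = lag)]
      from <- s[-length(s)]
      to <- s[-1L]
    } else {
      from <- s[seq_len(len - lag)]
      to <- s[seq.int(lag + 1L, len)]
    }
    tab <- tabulate(from + n * (to - 1L), nbins = n * n)
    counts[, , k] <- counts[, , k] + matrix(tab, n, n)
  }
  structure(list(counts = counts, lag = as.integer(lag), n_states = n,
                 n_ensembles = K, state_sample_counts = ssc,
                 mbar_sample_counts = msc, mode = mode, trajs = trajs,
                 active = seq_len(n)),
            class = "count_model")
}

#' Restrict a count model to its largest connected component
#'
#' Two states are linked if any ensemble holds counts between them in either
#' direction, or — under the equilibrium rule — if both carry equilibrium
#' samples in a common ensemble. By default only MBAR-set samples count as
#' equilibrium evidence (\code{eq_roles = "mbar"}); with
#' \code{eq_roles = "mbar+tram"}, TRAM-set samples in a shared ensemble link
#' states too (the stronger local-equilibrium reading). Estimation is
#' restricted to the largest linked component; removed states are reported in
#' the \code{removed} field.
#'
#' @param cm a \code{count_model}.
#' @param eq_roles which sample roles establish equilibrium connectivity.
#' @return a \code{count_model} restricted to the active set, with fields
#'   \code{active} (original 1-based indices of retained states),
#'   \code{removed}, and all tensors/bookkeeping re-indexed.
#' @export
apply_connectivity <- function(cm, eq_roles = c("mbar", "mbar+tram")) {
  stopifnot(inherits(cm, "count_model"))
  eq_roles <- match.arg(eq_roles)
  n <- cm$n_states
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  csum <- apply(cm$counts, c(1, 2), sum)
  link <- which(csum + t(csum) > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(link))) union_(link[r, 1], link[r, 2])
  # equilibrium-sample linking: all states sampled in a common ensemble merge
  eq_states <- vector("list", cm$n_ensembles)
  for (tr in cm$trajs) {
    use <- tr$role == "mbar" || (eq_roles == "mbar+tram" && tr$role == "tram")
    if (!use) next
    k <- tr$ensemble + 1L
    eq_states[[k]] <- union(eq_states[[k]], unique(tr$states))
  }
  for (k in seq_len(cm$n_ensembles)) {
    st <- eq_states[[k]]
    if (length(st) > 1)
      for (i in st[-1]) union_(st[1], i)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # weight components by total samples + counts
  wt <- rowSums(cm$state_sample_counts) + rowSums(csum) + colSums(csum)
  visited <- wt > 0
  if (!any(visited)) stop("empty active set: no state carries data")
  comp_wt <- tapply(wt[visited], roots[visited], sum)
  best <- as.integer(names(comp_wt)[which.max(comp_wt)])
  active <- which(roots == best & visited)
  removed <- setdiff(which(visited), active)
  idx_map <- integer(n)
  idx_map[active] <- seq_along(active)
  out <- cm
  out$counts <- cm$counts[active, active, , drop = FALSE]
  out$state_sample_counts <- cm$state_sample_counts[active, , drop = FALSE]
  out$n_states <- length(active)
  out$active <- active
  out$removed <- removed
  out$trajs <- lapply(cm$trajs, function(tr) {
    keep <- tr$states %in% active
    tr$states <- idx_map[tr$states[keep]]
    if (!is.null(tr$bias)) tr$bias <- tr$bias[keep, , drop = FALSE]
    tr
  })
  # recompute sample bookkeeping on the restricted state set
  ssc <- matrix(0.0, out$n_states, cm$n_ensembles)
  msc <- numeric(cm$n_ensembles)
  for (tr in out$trajs) {
    k <- tr$ensemble + 1L
    if (tr$role == "mbar") msc[k] <- msc[k] + length(tr$states)
    else ssc[, k] <- ssc[, k] + tabulate(tr$states, nbins = out$n_states)
  }
  out$state_sample_counts <- ssc
  out$mbar_sample_counts <- msc
  out
}

#' @export
print.count_model <- function(x, ...) {
  cat(sprintf(
    "count model: %d states, %d ensembles, lag %d (%s), %g transitions\n",
    x$n_states, x$n_ensembles, x$lag, x$mode, sum(x$counts)))
  if (!is.null(x$removed) && length(x$removed))
    cat(sprintf("  %d states removed by connectivity\n", length(x$removed)))
  invisible(x)
}
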