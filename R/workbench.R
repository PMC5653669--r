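# cache for expensive, seeded reference computations
.memm_cache <- new.env(parent = emptyenv())

#' Reference thermodynamics and kinetics of a landscape
#'
#' The "exact value" oracle for benchmark scoring. The binding free energy
#' \eqn{\Delta G = G_{bound} - G_{dissociated} = -\ln(Z_{bound}/Z_{diss})}
#' is computed by dense two-dimensional quadrature of Boltzmann weights over
#' the region masks induced by the discretizer (bound cells vs dissociated
#' cells), with a refinement check. The reference dissociation rate is the
#' inverse mean first-passage time from the bound-well center to the
#' dissociated region, from direct seeded simulation (cached).
#'
#' @param surface a \code{potential_surface}.
#' @param disc a \code{discretizer} built on the surface.
#' @param n_sub quadrature subdivisions per grid cell and axis.
#' @param n_events direct-simulation first-passage events for the rate
#'   reference (0 skips the kinetic reference).
#' @param seed seed for the direct simulation.
#' @param step_size MC step size of the reference simulation.
#' @return list with \code{dG} (bound minus dissociated, kBT),
#'   \code{dG_refined} (2x finer quadrature), \code{mfpt_off} (steps),
#'   \code{mfpt_off_se}, \code{rate_off} (1/steps), \code{cell_region}
#'   (region label per grid state), \code{pi_exact} (quadrature stationary
#'   probability per state).
#' @export
reference_solution <- function(surface, disc, n_sub = 8L, n_events = 32L,
                               seed = 20260910L, step_size = 0.12) {
  stopifnot(inherits(surface, "potential_surface"),
            inherits(disc, "discretizer"))
  quad <- function(nsub) {
    nx <- length(disc$x_edges) - 1L
    ny <- length(disc$y_edges) - 1L
    z <- numeric(disc$n_states)
    for (cx in seq_len(nx)) {
      xs <- seq(disc$x_edges[cx], disc$x_edges[cx + 1L],
                length.out = nsub + 1L)
      xm <- (xs[-1] + xs[-length(xs)]) / 2
      for (cy in seq_len(ny)) {
        ys <- seq(disc$y_edges[cy], disc$y_edges[cy + 1L],
                  length.out = nsub + 1L)
        ym <- (ys[-1] + ys[-length(ys)]) / 2
        pts <- cbind(rep(xm, each = nsub), rep(ym, times = nsub))
        u <- potential_energy(surface, pts)
        ok <- is.finite(u)
        if (!any(ok)) next
        w <- exp(-u[ok]) * diff(xs)[1] * diff(ys)[1]
        # split cell weight between the grid state and dissociated shells
        dm <- sqrt((pts[ok, 1] - disc$mouth[1])^2 +
                   (pts[ok, 2] - disc$mouth[2])^2)
        far <- dm > disc$threshold
        s_grid <- (cy - 1L) * nx + cx
        z[s_grid] <- z[s_grid] + sum(w[!far])
        if (any(far)) {
          shell <- pmin(pmax(ceiling((dm[far] - disc$threshold) /
                                       disc$shell_width), 1L), disc$n_shells)
          for (sh in unique(shell))
            z[disc$n_grid + sh] <- z[disc$n_grid + sh] + sum(w[far][shell == sh])
        }
      }
    }
    z
  }
  z <- quad(n_sub)
  z2 <- quad(2L * n_sub)
  regions <- discretizer_regions(surface, disc)
  dg <- function(zv) {
    -log(sum(zv[regions == "bound"])) + log(sum(zv[regions == "dissociated"]))
  }
  dG <- dg(z)
  dG2 <- dg(z2)
  if (abs(dG - dG2) > 0.05)
    stop(sprintf("quadrature not converged: dG %.4f vs %.4f under refinement",
                 dG, dG2))
  out <- list(dG = dG2, dG_refined = dG2, dG_coarse = dG,
              cell_region = regions, pi_exact = z2 / sum(z2))
  if (n_events > 0) {
    key <- paste0("mfpt:", digest_params(list(surface$wells, surface$channel,
                                              surface$box, step_size,
                                              disc$threshold, n_events, seed)))
    if (is.null(.memm_cache[[key]])) {
      et <- sample_exit_times(surface, n_events = n_events,
                              step_size = step_size, seed = seed)
      .memm_cache[[key]] <- et
    }
    et <- .memm_cache[[key]]
    out$exit_times <- et
    out$mfpt_off <- mean(et, na.rm = TRUE)
    out$mfpt_off_se <- sd(et, na.rm = TRUE) / sqrt(sum(!is.na(et)))
    out$rate_off <- 1 / out$mfpt_off
  }
  out
}

digest_params <- function(x) {
  v <- unlist(x, use.names = FALSE)
  paste(format(sum(as.numeric(v) * seq_along(v)), digits = 15),
        length(v), sep = "_")
}

# region label per state of the discretizer (cell centers; shells dissociated)
discretizer_regions <- function(surface, disc) {
  nx <- length(disc$x_edges) - 1L
  ny <- length(disc$y_edges) - 1L
  xm <- (disc$x_edges[-1] + disc$x_edges[-(nx + 1L)]) / 2
  ym <- (disc$y_edges[-1] + disc$y_edges[-(ny + 1L)]) / 2
  centers <- cbind(rep(xm, times = ny), rep(ym, each = nx))
  reg <- as.character(region_of(surface, centers))
  c(reg, rep("dissociated", disc$n_shells))
}

#' Generate a mixed unbiased + replica-exchange data set
#'
#' Emulates the benchmark protocol: a fraction of the step budget is spent
#' on many short unbiased trajectories started from random accessible points
#' in the dissociated region ("binding simulations"), the rest on one
#' Hamiltonian replica-exchange run across the bias schedule. Unbiased
#' trajectories are TRAM-set; replica-exchange trajectories are converted to
#' an equilibrium (MBAR) set after discarding an initial equilibration
#' fraction and striding.
#'
#' @param surface unbiased \code{potential_surface}.
#' @param schedule \code{bias_schedule}.
#' @param disc \code{discretizer}.
#' @param budget total number of MC steps across everything.
#' @param seed integer seed.
#' @param unbiased_fraction fraction of the budget for unbiased data.
#' @param traj_len length (steps) of each short unbiased trajectory.
#' @param exchange_interval replica-exchange attempt interval.
#' @param eq_discard_frac equilibration fraction discarded from each replica.
#' @param eq_stride stride applied to replica data before MBAR use.
#' @param step_size MC proposal width.
#' @return list of \code{discrete_trajectory} objects (TRAM and MBAR roles)
#'   with bias matrices attached.
#' @export
generate_dataset <- function(surface, schedule, disc, budget, seed,
                             unbiased_fraction = 0.6, traj_len = 5000L,
                             exchange_interval = 10L,
                             eq_discard_frac = 0.05, eq_stride = 10L,
                             step_size = 0.12) {
  K <- schedule$n_ensembles
  n_unb <- max(1L, round(budget * unbiased_fraction / traj_len))
  re_steps <- if (unbiased_fraction >= 1) 0L else
    max(2L * eq_stride + 20L, floor(budget * (1 - unbiased_fraction) / K))
  starts <- dissociated_starts(surface, n_unb, seed)
  trajs <- vector("list", 0)
  for (i in seq_len(n_unb)) {
    mc <- metropolis_sample(surface, starts[i, ], n_steps = traj_len,
                            step_size = step_size,
                            seed = seed * 1000 + i)
    b <- compute_bias_matrix(mc, schedule, surface)
    trajs[[length(trajs) + 1L]] <-
      discretize(mc, disc, ensemble = 0L, role = "tram", bias = b)
  }
  if (re_steps == 0L) return(trajs)
  re <- replica_exchange_sample(surface, schedule, n_steps = re_steps,
                                exchange_interval = exchange_interval,
                                seed = seed * 1000 + 999,
                                step_size = step_size)
  re_disc <- lapply(seq_len(K), function(k) {
    b <- compute_bias_matrix(re[[k]], schedule, surface)
    discretize(re[[k]], disc, ensemble = k - 1L, role = "tram", bias = b)
  })
  eq <- prepare_equilibrium_set(re_disc,
                                discard = floor(re_steps * eq_discard_frac),
                                stride = eq_stride)
  c(trajs, eq)
}

# uniform random accessible starts in the dissociated region
dissociated_starts <- function(surface, n, seed) {
  set.seed(seed)
  b <- surface$box
  out <- matrix(NA_real_, n, 2)
  got <- 0L
  while (got < n) {
    m <- (n - got) * 3L
    pts <- cbind(runif(m, b[1], b[2]), runif(m, b[3], b[4]))
    dm <- sqrt((pts[, 1] - surface$mouth[1])^2 +
               (pts[, 2] - surface$mouth[2])^2)
    ok <- !.toy_excluded_cpp(unclass(surface), pts) &
      dm > surface$dissociation_threshold
    take <- min(sum(ok), n - got)
    if (take > 0) {
      out[got + seq_len(take), ] <- pts[ok, , drop = FALSE][seq_len(take), ]
      got <- got + take
    }
  }
  out
}

# estimate dG(bound vs dissociated) and dissociation MFPT from a data set;
# method "memm" uses TRAMMBAR on all data, "msm" a reversible MSM on the
# unbiased counts only
estimate_observables <- function(trajs, disc, regions, lag, method,
                                 n_ensembles, tol = 1e-6, max_iter = 20000) {
  bound <- which(regions == "bound")
  diss <- which(regions == "dissociated")
  if (method == "msm") {
    # reversible MSM via the same core (single unbiased ensemble, zero bias:
    # the sample terms are constant, so this maximizes the reversible MSM
    # likelihood); connectivity by counts only
    unb <- Filter(function(t) t$ensemble == 0L && t$role == "tram", trajs)
    cm <- count_transitions(unb, lag = lag, n_states = disc$n_states,
                            n_ensembles = 1L)
    tm <- msm_estimate(cm$counts[, , 1], lag = lag)
    pi_full <- numeric(disc$n_states)
    pi_full[tm$states] <- tm$stationary
    srcs <- which(tm$states %in% bound)
    tgts <- which(tm$states %in% diss)
    dG <- -log(sum(pi_full[bound])) + log(sum(pi_full[diss]))
    mfpt <- if (length(srcs) && length(tgts))
      tryCatch(mfpt_tmatrix(tm, srcs, tgts), error = function(e) NA_real_)
    else NA_real_
    return(list(dG = dG, mfpt_off = mfpt, pi = pi_full))
  }
  cm <- count_transitions(trajs, lag = lag, n_states = disc$n_states,
                          n_ensembles = n_ensembles)
  cm <- apply_connectivity(cm)
  fit <- suppressWarnings(trammbar_estimate(cm, tol = tol,
                                            max_iter = max_iter,
                                            trace = FALSE))
  if (!fit$convergence$converged)  # non-convergence counts as failure
    return(list(dG = NA_real_, mfpt_off = NA_real_, pi = NULL, fit = fit))
  pi_full <- numeric(disc$n_states)
  pi_full[cm$active] <- fit$unbiased_stationary
  dG <- -log(sum(pi_full[bound])) + log(sum(pi_full[diss]))
  tm <- extract_transition_matrix(fit, k = 0L)
  orig <- cm$active[tm$states]
  srcs <- which(orig %in% bound)
  tgts <- which(orig %in% diss)
  mfpt <- if (length(srcs) && length(tgts))
    tryCatch(mfpt_tmatrix(tm, srcs, tgts), error = function(e) NA_real_)
  else NA_real_
  list(dG = dG, mfpt_off = mfpt, pi = pi_full, fit = fit)
}

#' MSM-vs-MEMM data-efficiency benchmark
#'
#' For each total step budget and seed, generates the stated data mix
#' (unbiased short binding trajectories plus replica-exchange data for the
#' MEMM; unbiased data only, same total budget, for the MSM), estimates the
#' binding free energy and the dissociation MFPT, and scores both against
#' the reference with the two standard success criteria: \eqn{|\Delta G -
#' \Delta G_{ref}| \le 1\,k_BT} and dissociation rate within a factor of 2.
#'
#' @param surface,schedule,disc the stated world.
#' @param budgets ascending vector of total MC-step budgets.
#' @param seeds vector of distinct integer seeds (>= 20 for reported curves).
#' @param method \code{"memm"} or \code{"msm"}.
#' @param lag count lag in frames.
#' @param reference optional precomputed [reference_solution()].
#' @param ... passed to [generate_dataset()].
#' @return a \code{benchmark_result} with per-budget success probabilities
#'   for the free-energy and rate criteria and the per-seed estimates.
#' @export
run_benchmark <- function(surface, schedule, disc, budgets, seeds,
                          method = c("memm", "msm"), lag = 20L,
                          reference = NULL, ...) {
  method <- match.arg(method)
  if (is.unsorted(budgets)) stop("'budgets' must be ascending")
  if (anyDuplicated(seeds)) stop("'seeds' must be distinct")
  if (is.null(reference)) reference <- reference_solution(surface, disc)
  regions <- reference$cell_region
  K <- schedule$n_ensembles
  res <- expand.grid(budget = budgets, seed = seeds)
  res$dG <- NA_real_; res$mfpt <- NA_real_
  for (r in seq_len(nrow(res))) {
    trajs <- if (method == "memm") {
      generate_dataset(surface, schedule, disc, res$budget[r], res$seed[r], ...)
    } else {
      generate_dataset(surface, schedule, disc, res$budget[r], res$seed[r],
                       unbiased_fraction = 1.0, ...)
    }
    est <- tryCatch(
      estimate_observables(trajs, disc, regions, lag, method, K),
      error = function(e) list(dG = NA_real_, mfpt_off = NA_real_))
    res$dG[r] <- est$dG
    res$mfpt[r] <- est$mfpt_off
  }
  res$ok_dG <- is.finite(res$dG) & abs(res$dG - reference$dG) <= 1
  ratio <- res$mfpt / reference$mfpt_off
  res$ok_rate <- is.finite(ratio) & ratio >= 0.5 & ratio <= 2
  agg <- aggregate(cbind(ok_dG, ok_rate) ~ budget, data = res, FUN = mean)
  structure(list(budgets = agg$budget,
                 success_prob_dG = agg$ok_dG,
                 success_prob_rate = agg$ok_rate,
                 method = toupper(method), n_seeds = length(seeds),
                 per_seed = res, reference = reference),
            class = "benchmark_result")
}

#' Data-amount and data-composition ablation
#'
#' Re-estimates the binding free energy and the dissociation MFPT on
#' subsampled data. In \code{"total-amount"} mode a fraction of all
#' trajectories (biased and unbiased alike) is used; in \code{"composition"}
#' mode the fraction of biased (MBAR-set) trajectories is varied while the
#' total trajectory count is held fixed by re-balancing with unbiased
#' trajectories. Confidence intervals are trajectory-level bootstrap
#' percentiles.
#'
#' @param trajs full list of \code{discrete_trajectory} objects.
#' @param disc the \code{discretizer}.
#' @param regions region label per state (from [reference_solution()]).
#' @param fractions fractions in (0, 1].
#' @param mode \code{"total-amount"} or \code{"composition"}.
#' @param lag count lag in frames.
#' @param n_ensembles K.
#' @param n_boot bootstrap replicates per fraction.
#' @param seed RNG seed.
#' @param level confidence level.
#' @return an \code{ablation_result} data frame with point estimates and
#'   intervals per fraction; failed/disconnected resamples are reported via
#'   widened (NA) interval ends, not errors.
#' @export
run_ablation <- function(trajs, disc, regions, fractions,
                         mode = c("total-amount", "composition"), lag = 20L,
                         n_ensembles = NULL, n_boot = 20L, seed = 1L,
                         level = 0.95) {
  mode <- match.arg(mode)
  if (any(fractions <= 0 | fractions > 1))
    stop("'fractions' must lie in (0, 1]")
  if (is.null(n_ensembles))
    n_ensembles <- max(vapply(trajs, function(t) t$ensemble, integer(1))) + 1L
  is_biased <- vapply(trajs, function(t) t$role == "mbar", logical(1))
  est_fun <- function(trs) {
    e <- tryCatch(
      estimate_observables(trs, disc, regions, lag, "memm", n_ensembles),
      error = function(err) list(dG = NA_real_, mfpt_off = NA_real_))
    c(dG = e$dG, mfpt = e$mfpt_off)
  }
  subsample <- function(frac, s) {
    set.seed(s)
    if (mode == "total-amount") {
      keep_b <- sample(which(is_biased),
                       max(1L, round(frac * sum(is_biased))))
      keep_u <- sample(which(!is_biased),
                       max(1L, round(frac * sum(!is_biased))))
      return(trajs[sort(c(keep_b, keep_u))])
    }
    # composition: frac = biased share of a fixed total trajectory count
    n_tot <- length(trajs)
    n_b <- min(round(frac * sum(is_biased)), sum(is_biased))
    n_u <- min(n_tot - n_b, sum(!is_biased))
    keep_b <- if (n_b > 0) sample(which(is_biased), n_b) else integer(0)
    keep_u <- sample(which(!is_biased), n_u, replace = n_u > sum(!is_biased))
    trajs[sort(c(keep_b, keep_u))]
  }
  alpha <- (1 - level) / 2
  rows <- lapply(seq_along(fractions), function(fi) {
    frac <- fractions[fi]
    base <- if (frac == 1 && mode == "total-amount") trajs
            else subsample(frac, seed + fi)
    pt <- est_fun(base)
    boots <- vapply(seq_len(n_boot), function(b) {
      set.seed(seed * 10000 + fi * 100 + b)
      est_fun(base[sample(length(base), replace = TRUE)])
    }, numeric(2))
    fail <- mean(!is.finite(boots[1, ]))
    ci <- function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 3) return(c(NA_real_, NA_real_))
      unname(quantile(v, c(alpha, 1 - alpha)))
    }
    cg <- ci(boots[1, ]); cr <- ci(boots[2, ])
    data.frame(fraction = frac, dG = pt["dG"], dG_lo = cg[1], dG_hi = cg[2],
               mfpt = pt["mfpt"], mfpt_lo = cr[1], mfpt_hi = cr[2],
               boot_failure_rate = fail, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  class(out) <- c("ablation_result", class(out))
  out
}

#' Trajectory-level bootstrap confidence interval
#'
#' Resamples whole trajectories with replacement (respecting temporal
#' correlation within trajectories), re-runs the estimator and returns a
#' percentile interval. If more than 20% of resamples fail, the interval is
#' flagged.
#'
#' @param estimator function taking a list of trajectories and returning one
#'   number.
#' @param trajectories list of trajectories.
#' @param n_boot number of bootstrap replicates (>= 100 recommended).
#' @param level confidence level.
#' @param seed RNG seed; identical seeds give identical intervals.
#' @return list with \code{lower}, \code{upper}, \code{point},
#'   \code{replicates}, \code{flagged}, \code{failure_rate}.
#' @export
bootstrap_ci <- function(estimator, trajectories, n_boot = 200L,
                         level = 0.95, seed = 1L) {
  if (n_boot < 2) stop("'n_boot' must be at least 2")
  point <- estimator(trajectories)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample(length(trajectories), replace = TRUE)
    tryCatch(as.numeric(estimator(trajectories[idx])),
             error = function(e) NA_real_)
  }, numeric(1))
  fail <- mean(!is.finite(reps))
  ok <- reps[is.finite(reps)]
  alpha <- (1 - level) / 2
  q <- unname(quantile(ok, c(alpha, 1 - alpha)))
  flagged <- fail > 0.2
  if (flagged)
    warning(sprintf("bootstrap estimator failed in %.0f%% of resamples",
                    100 * fail))
  list(lower = q[1], upper = q[2], point = point, replicates = reps,
       flagged = flagged, failure_rate = fail)
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("%s benchmark over %d seeds\n", x$method, x$n_seeds))
  df <- data.frame(budget = x$budgets, P_dG = x$success_prob_dG,
                   P_rate = x$success_prob_rate)
  print(df, row.names = FALSE)
  invisible(x)
}
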