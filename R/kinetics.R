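#' Implied relaxation timescales across lag times
#'
#' For each lag \eqn{\tau} a reversible MSM is estimated from the TRAM-set
#' trajectories and the leading non-unit eigenvalues \eqn{\lambda_i(\tau)}
#' are converted to timescales \eqn{t_i = -\tau/\ln\lambda_i}. Constancy of
#' \eqn{t_i(\tau)} across \eqn{\tau} indicates Markovianity at that
#' discretization. Complex leading eigenvalues are flagged and their moduli
#' used.
#'
#' @param trajs list of \code{discrete_trajectory} objects (or a
#'   \code{count_model}, whose trajectories are used).
#' @param lags integer vector of lag times in frames.
#' @param n_states total state count.
#' @param m number of timescales to report.
#' @param dt physical time per frame.
#' @return a \code{timescales_result} with matrix \code{timescales}
#'   (lags x m, physical units) and \code{lags}.
#' @export
implied_timescales <- function(trajs, lags, n_states, m = 3, dt = 1) {
  if (inherits(trajs, "count_model")) trajs <- trajs$trajs
  if (inherits(trajs, "discrete_trajectory")) trajs <- list(trajs)
  lags <- sort(unique(as.integer(lags)))
  ts <- matrix(NA_real_, length(lags), m)
  complex_flag <- logical(length(lags))
  for (li in seq_along(lags)) {
    cm <- count_transitions(trajs, lag = lags[li], n_states = n_states,
                            n_ensembles = max(vapply(trajs, function(t)
                              t$ensemble, integer(1))) + 1L)
    C <- apply(cm$counts, c(1, 2), sum)
    tm <- msm_estimate(C, lag = lags[li] * dt)
    ev <- tmatrix_eigenvalues(tm, m + 1L)
    if (any(abs(Im(ev)) > 1e-10)) {
      complex_flag[li] <- TRUE
      warning("complex eigenvalues at lag ", lags[li], "; moduli used")
    }
    lam <- Mod(ev)[-1]
    lam <- lam[lam < 1 & lam > 0]
    k <- min(m, length(lam))
    if (k > 0)
      ts[li, seq_len(k)] <- -(lags[li] * dt) / log(lam[seq_len(k)])
  }
  structure(list(lags = lags * dt, timescales = ts,
                 complex_flagged = complex_flag),
            class = "timescales_result")
}

# top eigenvalues of a reversible transition matrix via the symmetrized form
tmatrix_eigenvalues <- function(tm, k = 5L, vectors = FALSE) {
  T <- tm$matrix
  pi0 <- tm$stationary
  if (all(abs(pi0 * T - t(pi0 * T)) < 1e-8 * max(pi0 %o% rep(1, length(pi0))))) {
    s <- sqrt(pi0)
    A <- (s %o% (1 / s)) * T
    A <- (A + t(A)) / 2
    e <- eigen(A, symmetric = TRUE)
    k <- min(k, nrow(T))
    if (vectors) {
      # right eigenvectors of T: psi = D^{-1/2} v
      return(list(values = e$values[seq_len(k)],
                  vectors = e$vectors[, seq_len(k), drop = FALSE] / s))
    }
    return(as.complex(e$values[seq_len(k)]))
  }
  e <- eigen(T)
  ord <- order(Mod(e$values), decreasing = TRUE)
  k <- min(k, nrow(T))
  if (vectors)
    return(list(values = e$values[ord][seq_len(k)],
                vectors = e$vectors[, ord[seq_len(k)], drop = FALSE]))
  e$values[ord][seq_len(k)]
}

#' Chapman-Kolmogorov self-consistency test
#'
#' Compares set-to-set transition probabilities predicted by propagating the
#' lag-\eqn{\tau} model, \eqn{(T(\tau))^m}, against models re-estimated at
#' lag \eqn{m\tau}, with trajectory-bootstrap error bands on the
#' re-estimates.
#'
#' @param trajs list of \code{discrete_trajectory} objects.
#' @param lag base lag in frames.
#' @param multiples integer multiples m to test (1 is allowed and trivial).
#' @param macro_sets named list of state-index sets.
#' @param n_states total state count.
#' @param n_boot bootstrap replicates for the error bands.
#' @param seed RNG seed for the bootstrap.
#' @return data frame with columns set_from, set_to, multiple, predicted,
#'   estimated, lower, upper.
#' @export
ck_test <- function(trajs, lag, multiples = c(1, 2, 4), macro_sets,
                    n_states, n_boot = 30, seed = 1L) {
  if (inherits(trajs, "discrete_trajectory")) trajs <- list(trajs)
  if (is.null(names(macro_sets)))
    names(macro_sets) <- paste0("set", seq_along(macro_sets))
  est_T <- function(trs, l) {
    cm <- count_transitions(trs, lag = l, n_states = n_states,
                            n_ensembles = 1L)
    msm_estimate(apply(cm$counts, c(1, 2), sum), lag = l)
  }
  setprob <- function(tm, P, A, B) {
    idx <- tm$states
    a <- which(idx %in% A)
    b <- which(idx %in% B)
    if (!length(a) || !length(b)) return(NA_real_)
    w <- tm$stationary[a]
    sum((w / sum(w)) * rowSums(P[a, b, drop = FALSE]))
  }
  base <- est_T(trajs, lag)
  rows <- list()
  set.seed(seed)
  for (m in multiples) {
    Pp <- matpow(base$matrix, m)
    est <- tryCatch(est_T(trajs, lag * m), error = function(e) NULL)
    boots <- replicate(n_boot, {
      idx <- sample(length(trajs), replace = TRUE)
      tme <- tryCatch(est_T(trajs[idx], lag * m), error = function(e) NULL)
      tme
    }, simplify = FALSE)
    for (a in names(macro_sets)) for (b in names(macro_sets)) {
      pred <- setprob(base, Pp, macro_sets[[a]], macro_sets[[b]])
      em <- if (is.null(est)) NA_real_ else
        setprob(est, est$matrix, macro_sets[[a]], macro_sets[[b]])
      bv <- vapply(boots, function(tme) {
        if (is.null(tme)) return(NA_real_)
        setprob(tme, tme$matrix, macro_sets[[a]], macro_sets[[b]])
      }, numeric(1))
      bv <- bv[!is.na(bv)]
      rows[[length(rows) + 1L]] <- data.frame(
        set_from = a, set_to = b, multiple = m, predicted = pred,
        estimated = em,
        lower = if (length(bv)) unname(quantile(bv, 0.025)) else NA_real_,
        upper = if (length(bv)) unname(quantile(bv, 0.975)) else NA_real_,
        insufficient = is.null(est))
    }
  }
  do.call(rbind, rows)
}

matpow <- function(M, m) {
  P <- diag(nrow(M))
  B <- M
  while (m > 0) {
    if (m %% 2 == 1) P <- P %*% B
    B <- B %*% B
    m <- m %/% 2
  }
  P
}

# real matrix logarithm via eigendecomposition, projected onto the
# generator cone (off-diagonals clipped at 0, diagonal = -rowsums)
generator_from_logm <- function(T, lag) {
  e <- eigen(T)
  lam <- e$values
  lam[Re(lam) <= 0 & abs(Im(lam)) < 1e-12] <- 1e-12
  L <- e$vectors %*% diag(log(lam), nrow(T)) %*% solve(e$vectors)
  L <- Re(L) / lag
  Q <- L
  Q[Q < 0] <- 0
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  list(Q = Q, raw = L)
}

rate_matrix_obj <- function(Q, lag, method) {
  structure(list(generator = Q, lag = lag, estimation_method = method),
            class = "rate_matrix")
}

#' Maximum-likelihood rate matrix from transition counts
#'
#' Estimates the continuous-time generator Q maximizing
#' \eqn{\sum_{ij} c_{ij} \log [e^{Q\tau}]_{ij}} over matrices with
#' non-negative off-diagonals and zero row sums (the discrete-observation
#' maximum-likelihood approach for Markov jump processes). Off-diagonal
#' rates are optimized in log space (quasi-Newton), initialized from the
#' projected real matrix logarithm of the count MLE transition matrix; pairs
#' with no counts in either direction are pinned at rate 0. Gradients are
#' numerical, so the method is intended for small models (tens of states,
#' e.g. after [metastable_coarse_grain()]), not for the full microstate
#' space.
#'
#' @param counts square count matrix (restricted to the unbiased ensemble),
#'   or a \code{count_model} whose ensemble-0 counts are used.
#' @param lag lag time \eqn{\tau} in physical units (> 0).
#' @return a \code{rate_matrix}; attribute \code{loglik_gap} reports the
#'   log-likelihood difference to the unconstrained count MLE.
#' @export
estimate_rate_matrix_ml <- function(counts, lag) {
  if (inherits(counts, "count_model")) counts <- counts$counts[, , 1]
  C <- as.matrix(counts)
  if (lag <= 0) stop("'lag' must be positive")
  n <- nrow(C)
  Tmle <- C / pmax(rowSums(C), .Machine$double.eps)
  init <- generator_from_logm(Tmle, lag)$Q
  free <- which(row(C) != col(C) & (C + t(C)) > 0)
  if (!length(free)) return(rate_matrix_obj(matrix(0, n, n), lag, "ML"))
  q0 <- pmax(init[free], 1e-8)
  nll <- function(lq) {
    Q <- matrix(0, n, n)
    Q[free] <- exp(lq)
    diag(Q) <- -rowSums(Q)
    P <- as.matrix(Matrix::expm(Q * lag))
    P[P < 1e-300] <- 1e-300
    -sum(C[C > 0] * log(P[C > 0]))
  }
  opt <- optim(log(q0), nll, method = "L-BFGS-B",
               lower = log(1e-12), upper = log(1e6),
               control = list(maxit = 500, factr = 1e5))
  Q <- matrix(0, n, n)
  Q[free] <- exp(opt$par)
  diag(Q) <- -rowSums(Q)
  out <- rate_matrix_obj(Q, lag, "ML")
  # likelihood gap to the unconstrained count MLE (embeddability check)
  llT <- sum(C[C > 0] * log(Tmle[C > 0]))
  attr(out, "loglik_gap") <- llT - (-opt$value)
  out
}

#' Least-squares rate matrix from spectral data
#'
#' Fits a generator Q whose spectral data match those of the transition
#' matrix: eigenvalues \eqn{\log(\lambda_i)/\tau} and the eigenvectors of T
#' (the spectral least-squares approach for non-embeddable transition
#' matrices). The objective is
#' \eqn{\sum_i \|Q r_i - \mu_i r_i\|^2 + \|l_i^T Q - \mu_i l_i^T\|^2}
#' with unit weights over all eigenpairs (right vectors \eqn{r_i}, left
#' vectors \eqn{l_i}, \eqn{\mu_i = \log(\lambda_i)/\tau}), minimized over the
#' generator cone (off-diagonals >= 0, zero row sums) by box-constrained
#' quasi-Newton from the projected matrix-logarithm start. For an exactly
#' embeddable T this objective is zero at the matrix logarithm, so the
#' methods agree there.
#'
#' @param T a \code{transition_matrix} (or plain row-stochastic matrix).
#' @param lag lag time in physical units (taken from the object if missing).
#' @return a \code{rate_matrix}.
#' @export
estimate_rate_matrix_lsq <- function(T, lag = NULL) {
  if (inherits(T, "transition_matrix")) {
    if (is.null(lag)) lag <- T$lag
    T <- T$matrix
  }
  if (is.null(lag) || lag <= 0) stop("'lag' must be positive")
  n <- nrow(T)
  er <- eigen(T)
  el <- eigen(t(T))
  keep_r <- which(abs(Im(er$values)) < 1e-8 & Re(er$values) > 0)
  keep_l <- which(abs(Im(el$values)) < 1e-8 & Re(el$values) > 0)
  if (length(keep_r) < n)
    warning("complex or non-positive eigenvalues; only real positive ",
            "eigenpairs enter the spectral objective")
  mu_r <- log(Re(er$values[keep_r])) / lag
  mu_l <- log(Re(el$values[keep_l])) / lag
  R <- Re(er$vectors[, keep_r, drop = FALSE])
  R <- sweep(R, 2, sqrt(colSums(R^2)), "/")
  L <- Re(el$vectors[, keep_l, drop = FALSE])
  L <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  init <- generator_from_logm(T, lag)$Q
  free <- which(row(T) != col(T))
  obj <- function(q) {
    Q <- matrix(0, n, n)
    Q[free] <- q
    diag(Q) <- -rowSums(Q)
    s <- 0
    for (i in seq_along(keep_r))
      s <- s + sum((Q %*% R[, i] - mu_r[i] * R[, i])^2)
    for (i in seq_along(keep_l))
      s <- s + sum((as.vector(crossprod(L[, i], Q)) - mu_l[i] * L[, i])^2)
    s
  }
  opt <- optim(pmax(init[free], 0), obj, method = "L-BFGS-B", lower = 0,
               control = list(maxit = 1000, factr = 1e4))
  Q <- matrix(0, n, n)
  Q[free] <- opt$par
  diag(Q) <- -rowSums(Q)
  rate_matrix_obj(Q, lag, "LSQ")
}

#' Mean first-passage time from a rate matrix
#'
#' Solves \eqn{Q_{rest} m = -1} on the complement of the target set (with
#' \eqn{m = 0} on the target) and returns the stationary-weighted average of
#' \eqn{m} over the source set (equilibrium-start convention).
#'
#' @param Q a \code{rate_matrix} or generator matrix.
#' @param pi stationary distribution used for source weighting.
#' @param source_set,target_set disjoint, non-empty state index sets.
#' @return mean first-passage time in the inverse units of Q.
#' @export
mfpt_rate <- function(Q, pi, source_set, target_set) {
  if (inherits(Q, "rate_matrix")) Q <- Q$generator
  check_sets(nrow(Q), source_set, target_set)
  rest <- setdiff(seq_len(nrow(Q)), target_set)
  m <- rep(0, nrow(Q))
  sol <- tryCatch(
    solve(Q[rest, rest, drop = FALSE], rep(-1, length(rest))),
    error = function(e) stop("target set unreachable: singular restricted ",
                             "system (", conditionMessage(e), ")"))
  m[rest] <- sol
  w <- pi[source_set]
  sum(w / sum(w) * m[source_set])
}

#' Mean first-passage time from a discrete-time transition matrix
#'
#' Discrete-time counterpart of [mfpt_rate()]: solves
#' \eqn{(I - T_{rest}) m = \tau \cdot 1}, so times are multiples of the lag.
#'
#' @param T a \code{transition_matrix} (or plain matrix; then \code{lag} and
#'   \code{pi} are required).
#' @param source_set,target_set disjoint, non-empty state index sets.
#' @param lag,pi overrides for plain-matrix input.
#' @return mean first-passage time in physical units.
#' @export
mfpt_tmatrix <- function(T, source_set, target_set, lag = NULL, pi = NULL) {
  if (inherits(T, "transition_matrix")) {
    if (is.null(lag)) lag <- T$lag
    if (is.null(pi)) pi <- T$stationary
    T <- T$matrix
  }
  if (is.null(lag) || is.null(pi))
    stop("'lag' and 'pi' are required with a plain matrix")
  check_sets(nrow(T), source_set, target_set)
  rest <- setdiff(seq_len(nrow(T)), target_set)
  A <- diag(length(rest)) - T[rest, rest, drop = FALSE]
  m <- rep(0, nrow(T))
  sol <- tryCatch(solve(A, rep(lag, length(rest))),
                  error = function(e) stop("target set unreachable: ",
                                           conditionMessage(e)))
  m[rest] <- sol
  w <- pi[source_set]
  sum(w / sum(w) * m[source_set])
}

check_sets <- function(n, source_set, target_set) {
  if (!length(source_set) || !length(target_set))
    stop("source and target sets must be non-empty")
  if (length(intersect(source_set, target_set)))
    stop("source and target sets must be disjoint")
  if (any(c(source_set, target_set) > n | c(source_set, target_set) < 1))
    stop("state indices out of range")
  invisible(TRUE)
}

#' Bimolecular association rate constant
#'
#' Converts an association mean first-passage time at the simulation-box
#' concentration into a second-order rate constant:
#' \eqn{k_{on} = 1 / (\mathrm{MFPT_{on}} \cdot C_{box})} with
#' \eqn{C_{box} = 1/(N_A V)}.
#'
#' @param mfpt_on association MFPT (> 0), in time units.
#' @param box_volume box volume in nm^3.
#' @return rate constant in M^-1 per time unit.
#' @export
bimolecular_on_rate <- function(mfpt_on, box_volume) {
  stopifnot_scalar(mfpt_on, "mfpt_on")
  if (mfpt_on <= 0) stop("'mfpt_on' must be positive")
  1 / (mfpt_on * box_concentration(box_volume))
}

#' Spectral metastable coarse-graining (PCCA-style)
#'
#' Groups states into \code{n_macro} metastable sets from the top
#' eigenvectors of a reversible transition matrix, using the inner-simplex
#' vertex construction: memberships are the linear transform of the
#' eigenvector rows mapping the most extreme rows to the unit vertices,
#' clipped to \eqn{[0,1]} and row-normalized. Crisp assignments take the
#' argmax.
#'
#' @param T a \code{transition_matrix}.
#' @param n_macro number of macrostates (at most the number of leading real
#'   eigenvalues).
#' @return list with \code{memberships} (states x n_macro, rows sum to 1),
#'   \code{assignment} (crisp macrostate index per state) and
#'   \code{spectral_gap}.
#' @export
metastable_coarse_grain <- function(T, n_macro) {
  stopifnot(inherits(T, "transition_matrix"))
  n <- nrow(T$matrix)
  if (n_macro > n) stop("n_macro exceeds the number of states")
  if (n_macro == n) {
    return(list(memberships = diag(n), assignment = seq_len(n),
                spectral_gap = NA_real_))
  }
  ev <- tmatrix_eigenvalues(T, k = min(n, n_macro + 1L), vectors = TRUE)
  lam <- Re(ev$values)
  gap <- if (length(lam) > n_macro) lam[n_macro] - lam[n_macro + 1] else NA_real_
  if (!is.na(gap) && gap < 0.05)
    warning("weak spectral gap after ", n_macro, " processes")
  X <- ev$vectors[, seq_len(n_macro), drop = FALSE]
  X[, 1] <- 1
  # inner simplex vertex search
  idx <- integer(n_macro)
  d <- rowSums(X^2)
  idx[1] <- which.max(d)
  ortho <- X
  for (j in seq_len(n_macro - 1L)) {
    v <- ortho[idx[j], ]
    v <- v / sqrt(sum(v^2))
    ortho <- ortho - (ortho %*% v) %*% t(v)  # project out chosen vertex
    dd <- rowSums(ortho^2)
    idx[j + 1L] <- which.max(dd)
  }
  A <- solve(X[idx, , drop = FALSE])
  chi <- X %*% A
  chi[chi < 0] <- 0
  chi <- chi / rowSums(chi)
  list(memberships = chi, assignment = apply(chi, 1, which.max),
       spectral_gap = gap, vertices = idx)
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("rate matrix (%s): %d states, lag %g\n",
              x$estimation_method, nrow(x$generator), x$lag))
  invisible(x)
}
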