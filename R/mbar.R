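#' Multistate Bennett acceptance ratio (MBAR) estimator
#'
#' Self-consistent solution of the MBAR equations for the ensemble free
#' energies \eqn{f^k} and unbiased point weights \eqn{\mu(x)} from
#' equilibrium samples of K ensembles:
#' \deqn{e^{-f^k} = \sum_x \frac{e^{-b^k(x)}}{\sum_l M^l e^{f^l - b^l(x)}}}
#' with \eqn{M^l} the sample count of ensemble \eqn{l}. Every sample must
#' carry its unit-less bias energy in all K ensembles. Free energies are
#' gauge-fixed to \eqn{f^0 = 0} and weights normalized to sum to one. All
#' reductions use log-sum-exp, so bias energies up to several hundred
#' \eqn{k_BT} are safe.
#'
#' @param bias_matrices a single numeric matrix (samples x ensembles) stacked
#'   over ensembles, or a list of per-ensemble matrices.
#' @param sample_counts per-ensemble sample counts \eqn{M^k}; required (and
#'   checked) when \code{bias_matrices} is a single stacked matrix, derived
#'   otherwise.
#' @param tol convergence threshold on the sup-norm change of \eqn{f^k}.
#' @param max_iter iteration cap; non-convergence is flagged, not raised.
#' @return list with \code{f} (length K, \code{f[1] == 0}), \code{log_weights}
#'   and \code{weights} (normalized \eqn{\mu(x)} per sample, stacked in input
#'   order), \code{iterations}, \code{converged}, \code{overlap}
#'   (K x K effective overlap matrix), and \code{ess} (per-ensemble effective
#'   sample sizes).
#' @export
mbar_estimate <- function(bias_matrices, sample_counts = NULL,
                          tol = 1e-10, max_iter = 100000) {
  if (is.list(bias_matrices)) {
    sample_counts <- vapply(bias_matrices, nrow, integer(1))
    b <- do.call(rbind, bias_matrices)
  } else {
    b <- as.matrix(bias_matrices)
    if (is.null(sample_counts))
      stop("'sample_counts' is required with a stacked bias matrix")
  }
  K <- ncol(b)
  if (length(sample_counts) != K)
    stop("length(sample_counts) must equal the number of ensembles")
  if (sum(sample_counts) != nrow(b))
    stop("sample_counts must sum to the number of bias rows")
  N <- nrow(b)
  logM <- ifelse(sample_counts > 0, log(sample_counts), -Inf)

  f <- numeric(K)
  converged <- FALSE
  iter <- 0L
  # log denominator per sample: lse_l (log M^l + f^l - b^l(x))
  for (iter in seq_len(max_iter)) {
    a <- sweep(-b, 2, logM + f, "+")       # N x K
    m <- apply(a, 1, max)
    logden <- m + log(rowSums(exp(a - m)))
    # f_new^k = -lse_x(-b^k(x) - logden(x))
    v <- -b - logden                        # N x K
    mv <- apply(v, 2, max)
    fnew <- -(mv + log(colSums(exp(sweep(v, 2, mv, "-")))))
    fnew <- fnew - fnew[1]
    d <- max(abs(fnew - f))
    f <- fnew
    if (d < tol) { converged <- TRUE; break }
  }
  a <- sweep(-b, 2, logM + f, "+")
  m <- apply(a, 1, max)
  logden <- m + log(rowSums(exp(a - m)))
  logw <- -logden
  logw <- logw - logsumexp(logw)
  w <- exp(logw)

  # overlap and effective sample size diagnostics
  # W_k(x) propto mu(x) e^{-b^k(x)}: normalized weight of sample x in ensemble k
  lw_k <- sweep(-b, 1, logw, "+")          # N x K (log mu - b^k)
  lZ <- apply(lw_k, 2, logsumexp)
  Wk <- exp(sweep(lw_k, 2, lZ, "-"))
  ess <- 1 / colSums(Wk^2)
  overlap <- crossprod(Wk)
  # ensembles must form one overlap-connected component, else the relative
  # free energies are effectively undetermined; normalized overlap ~ 1 for
  # identical ensembles, ~ 0 for disjoint support
  norm_ov <- overlap / sqrt(diag(overlap) %o% diag(overlap))
  conn <- largest_component(norm_ov > 0.01)
  if (any(ess < 2 & sample_counts > 0) || length(conn) < K)
    warning("poor ensemble overlap: free-energy differences ill-determined; ",
            "inspect the returned overlap matrix")
  if (!converged)
    warning(sprintf("MBAR did not converge within %d iterations", max_iter))
  list(f = f, log_weights = logw, weights = w, iterations = iter,
       converged = converged, overlap = overlap, ess = ess)
}
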