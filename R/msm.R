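#' Transition matrix container
#'
#' @param mat row-stochastic square matrix.
#' @param lag lag time in physical time units.
#' @param stationary optional stationary distribution; computed from the
#'   leading left eigenvector if omitted.
#' @return a \code{transition_matrix}.
#' @export
transition_matrix <- function(mat, lag = 1, stationary = NULL) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("transition matrix must be square")
  rs <- rowSums(mat)
  if (any(abs(rs - 1) > 1e-8) || any(mat < -1e-12))
    stop("rows must sum to 1 with non-negative entries")
  mat <- mat / rs
  if (is.null(stationary)) stationary <- stationary_distribution(mat)
  if (abs(sum(stationary) - 1) > 1e-8)
    stop("stationary distribution must sum to 1")
  structure(list(matrix = mat, lag = lag, stationary = stationary),
            class = "transition_matrix")
}

# leading left eigenvector, normalized
stationary_distribution <- function(T) {
  e <- eigen(t(T))
  i <- which.max(Re(e$values))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# largest connected component of a symmetric adjacency (logical) matrix
largest_component <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- which(adj[v, ] & comp == 0L)
      stack <- c(stack, nb)
    }
  }
  sizes <- tabulate(comp)
  which(comp == which.max(sizes))
}

#' Reversible maximum-likelihood Markov state model
#'
#' Estimates the reversible transition matrix maximizing
#' \eqn{\sum_{ij} c_{ij} \log p_{ij}} under detailed balance, by the standard
#' self-consistent update on the symmetric flux variables
#' \eqn{x_{ij} = \pi_i p_{ij}}. Estimation is restricted to the largest
#' component connected by \eqn{c_{ij} + c_{ji} > 0}.
#'
#' @param counts square count matrix (may be non-integer).
#' @param lag lag time in physical units attached to the result.
#' @param reversible if \code{FALSE}, the row-normalized count matrix is
#'   returned instead.
#' @param tol,max_iter fixed-point convergence controls.
#' @return a \code{transition_matrix} with a \code{states} field giving the
#'   retained (connected) state indices.
#' @export
msm_estimate <- function(counts, lag = 1, reversible = TRUE, tol = 1e-12,
                         max_iter = 100000) {
  counts <- as.matrix(counts)
  keep <- largest_component((counts + t(counts)) > 0)
  C <- counts[keep, keep, drop = FALSE]
  n <- nrow(C)
  if (n == 0) stop("no connected states with counts")
  if (!reversible) {
    Tm <- C / rowSums(C)
    tm <- transition_matrix(Tm, lag = lag)
    tm$states <- keep
    return(tm)
  }
  res <- .rev_mle_cpp(C, tol, as.integer(max_iter))
  tm <- transition_matrix(res$T, lag = lag, stationary = res$pi)
  tm$states <- keep
  tm
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition matrix: %d states, lag %g\n",
              nrow(x$matrix), x$lag))
  invisible(x)
}
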