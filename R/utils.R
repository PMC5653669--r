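#' @useDynLib memmtools, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim quantile rnorm runif sd var setNames
#' @importFrom utils write.table read.table head tail
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  x
}

# Avogadro constant (1/mol)
.N_AVOGADRO <- 6.02214076e23

# standard concentration of one molecule in a box of volume `v_nm3` (mol/L)
box_concentration <- function(v_nm3) {
  stopifnot_scalar(v_nm3, "v_nm3")
  if (v_nm3 <= 0) stop("box volume must be positive")
  1 / (.N_AVOGADRO * v_nm3 * 1e-24)
}
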