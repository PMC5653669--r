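#' Write a trajectory set to a portable container
#'
#' One group per trajectory (positions or states, ensemble label, bias
#' matrix, role, seed and sampling parameters), serialized with base R's
#' portable binary format (RDS, version 3). [export_trajectories_csv()]
#' provides the flat delimited-text alternative.
#'
#' @param trajs list of \code{mc_trajectory} or \code{discrete_trajectory}.
#' @param path output file.
#' @param metadata optional named list stored alongside.
#' @export
write_trajectory_set <- function(trajs, path, metadata = list()) {
  obj <- list(format = "memmtools-trajectory-set", version = 1L,
              created = format(Sys.time(), tz = "UTC"),
              metadata = metadata, trajectories = trajs)
  saveRDS(obj, path, version = 3)
  invisible(path)
}

#' Read a trajectory set container
#' @param path file written by [write_trajectory_set()].
#' @return list of trajectories with a \code{metadata} attribute.
#' @export
read_trajectory_set <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "memmtools-trajectory-set"))
    stop("not a memmtools trajectory container")
  out <- obj$trajectories
  attr(out, "metadata") <- obj$metadata
  out
}

#' Export trajectories as flat delimited text
#'
#' Continuous trajectories become (traj, frame, x, y, ensemble) rows;
#' discrete ones (traj, frame, state, ensemble, role) plus bias columns.
#'
#' @param trajs list of trajectories.
#' @param path output TSV file.
#' @export
export_trajectories_csv <- function(trajs, path) {
  rows <- lapply(seq_along(trajs), function(i) {
    tr <- trajs[[i]]
    if (inherits(tr, "mc_trajectory")) {
      data.frame(traj = i, frame = seq_len(nrow(tr$positions)) - 1L,
                 x = tr$positions[, 1], y = tr$positions[, 2],
                 ensemble = tr$ensemble_labels[1])
    } else {
      d <- data.frame(traj = i, frame = seq_along(tr$states) - 1L,
                      state = tr$states, ensemble = tr$ensemble,
                      role = tr$role)
      if (!is.null(tr$bias)) {
        b <- as.data.frame(tr$bias)
        names(b) <- paste0("bias", seq_len(ncol(b)) - 1L)
        d <- cbind(d, b)
      }
      d
    }
  })
  same <- length(unique(vapply(rows, ncol, integer(1)))) == 1L
  if (!same) stop("cannot mix continuous and discrete trajectories")
  write.table(do.call(rbind, rows), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Export a count tensor as a sparse coordinate list
#'
#' Delimited text with columns (ensemble, from, to, count), 1-based.
#' @param cm a \code{count_model}.
#' @param path output TSV file.
#' @export
export_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_model"))
  rows <- list()
  for (k in seq_len(cm$n_ensembles)) {
    nz <- which(cm$counts[, , k] > 0, arr.ind = TRUE)
    if (nrow(nz))
      rows[[k]] <- data.frame(ensemble = k - 1L, from = nz[, 1],
                              to = nz[, 2], count = cm$counts[, , k][nz])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ensemble = integer(0), from = integer(0), to = integer(0),
               count = numeric(0))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sparse count tensor written by [export_counts()]
#' @param path TSV file.
#' @param n_states,n_ensembles tensor dimensions (inferred if omitted).
#' @param lag lag to attach.
#' @return a \code{count_model} without trajectories (counts only).
#' @export
read_counts <- function(path, n_states = NULL, n_ensembles = NULL, lag = 1L) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (is.null(n_states)) n_states <- max(df$from, df$to, 0L)
  if (is.null(n_ensembles)) n_ensembles <- max(df$ensemble, 0L) + 1L
  counts <- array(0.0, dim = c(n_states, n_states, n_ensembles))
  for (r in seq_len(nrow(df)))
    counts[df$from[r], df$to[r], df$ensemble[r] + 1L] <-
      counts[df$from[r], df$to[r], df$ensemble[r] + 1L] + df$count[r]
  structure(list(counts = counts, lag = as.integer(lag),
                 n_states = as.integer(n_states),
                 n_ensembles = as.integer(n_ensembles),
                 state_sample_counts = matrix(0, n_states, n_ensembles),
                 mbar_sample_counts = numeric(n_ensembles),
                 mode = "sliding", trajs = list(),
                 active = seq_len(n_states)),
            class = "count_model")
}

#' Export a flux network as a weighted edge list
#' @param fn a \code{flux_network}.
#' @param path output TSV file.
#' @export
export_flux <- function(fn, path) {
  stopifnot(inherits(fn, "flux_network"))
  nz <- which(fn$net_flux > 0, arr.ind = TRUE)
  df <- data.frame(from = nz[, 1], to = nz[, 2], net_flux = fn$net_flux[nz],
                   gross_flux = fn$gross_flux[nz])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' JSON record of the configuration, seeds, package version and input file
#' digests, sufficient to reproduce deterministic stages bit-for-bit.
#'
#' @param path output JSON file.
#' @param config named list echoed verbatim.
#' @param seeds seeds used.
#' @param inputs character vector of input file paths to digest (size +
#'   first/last bytes based fingerprint; no external digest dependency).
#' @export
write_manifest <- function(path, config = list(), seeds = integer(0),
                           inputs = character(0)) {
  digests <- lapply(inputs, function(f) {
    if (!file.exists(f)) return(list(file = f, exists = FALSE))
    sz <- file.info(f)$size
    con <- file(f, "rb")
    on.exit(close(con))
    headb <- readBin(con, "raw", n = min(sz, 4096))
    list(file = f, exists = TRUE, size = sz,
         fingerprint = paste0(sz, "-", sum(as.integer(headb)) %% 1e9))
  })
  obj <- list(tool = "memmtools",
              version = as.character(utils::packageVersion("memmtools")),
              r_version = R.version.string,
              created = format(Sys.time(), tz = "UTC"),
              seeds = seeds, config = config, inputs = digests)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
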