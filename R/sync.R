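#' Level-of-Synchronicity (LoS) matrix
#'
#' `LoS_ij` is the time-averaged Gaussian kernel of the pairwise voltage
#' difference, `mean_t exp(-(V_i - V_j)^2 / (2 sigma^2))`, evaluated over an
#' analysis window (by default the final second of the run, after
#' transients). 1 means identical trajectories; a constant offset of `sigma`
#' gives `exp(-1/2) ~ 0.61`.
#'
#' @param result a [integrate_network()] result, or a plain nodes-x-samples
#'   voltage matrix.
#' @param window length (s) of the trailing analysis window (ignored for a
#'   plain matrix, which is used whole).
#' @param sigma kernel scale, mV.
#' @return symmetric `los_matrix` with unit diagonal and entries in `[0, 1]`;
#'   attributes `sigma` and `window`.
#' @export
los_matrix <- function(result, window = 1, sigma = 0.1) {
  V <- window_voltages(result, window)
  n <- nrow(V)
  L <- matrix(1, n, n, dimnames = list(rownames(V), rownames(V)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      d2 <- (V[i, ] - V[j, ])^2
      L[i, j] <- L[j, i] <- mean(exp(-d2 / (2 * sigma^2)))
    }
  }
  structure(L, class = c("los_matrix", "matrix"), sigma = sigma,
            window = window)
}

window_voltages <- function(result, window) {
  if (is.matrix(result)) return(result)
  stopifnot(inherits(result, "simulation_result"))
  tmax <- max(result$times)
  if (window > tmax) stop("analysis window exceeds the simulated span")
  keep <- result$times >= tmax - window
  if (!any(keep)) stop("empty analysis window")
  result$V[, keep, drop = FALSE]
}

#' Idealized LoS matrix of a partition
#'
#' Block matrix with ones inside each cell (full within-fiber synchrony) and
#' zeros across cells.
#'
#' @param part a [node_partition()].
#' @export
ideal_los <- function(part) {
  nodes <- names(part$membership)
  same <- outer(part$membership, part$membership, "==") * 1
  dimnames(same) <- list(nodes, nodes)
  structure(same, class = c("los_matrix", "matrix"))
}

#' Synchronization difference score against the ideal LoS
#'
#' Binarizes the observed LoS (entries at least `1 - eps` become 1, the rest
#' 0), subtracts it from the ideal block matrix, sums the off-diagonal
#' entries and divides by `2 (n^2 - n)`. Zero means perfect agreement with
#' the fiber partition; negative values flag additional cross-fiber
#' synchrony; positive values flag missing within-fiber synchrony.
#'
#' @param observed an observed [los_matrix()].
#' @param ideal the [ideal_los()] matrix (same node order).
#' @param eps binarization tolerance (1 - eps cut).
#' @export
sync_difference <- function(observed, ideal, eps = 0.005) {
  if (!all(dim(observed) == dim(ideal))) stop("matrix shapes differ")
  obs <- (unclass(observed) >= 1 - eps) * 1
  idl <- unclass(ideal)
  if (!is.null(rownames(obs)) && !is.null(rownames(idl))) {
    idl <- idl[rownames(obs), colnames(obs)]
  }
  diffm <- idl - obs
  diag(diffm) <- 0
  n <- nrow(obs)
  sum(diffm) / (2 * (n^2 - n))
}

#' Phase Locking Value (PLV) matrix
#'
#' `PLV_ij` is the magnitude of the time-averaged unit phasor of the
#' instantaneous phase difference between two signals, in `[0, 1]`: 1 for a
#' constant phase difference, near 0 for unrelated phases. Instantaneous
#' phases come from the analytic signal (Hilbert transform) of each
#' mean-removed trace over the analysis window.
#'
#' @inheritParams los_matrix
#' @export
plv_matrix <- function(result, window = 1) {
  V <- window_voltages(result, window)
  n <- nrow(V)
  phases <- matrix(0, n, ncol(V))
  for (i in seq_len(n)) {
    x <- V[i, ] - mean(V[i, ])
    phases[i, ] <- Arg(analytic_signal(x))
  }
  P <- matrix(1, n, n, dimnames = list(rownames(V), rownames(V)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      P[i, j] <- P[j, i] <- Mod(mean(exp(1i * (phases[i, ] - phases[j, ]))))
    }
  }
  P
}

# analytic signal x + i H[x] via the one-sided FFT spectrum
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Calibrate the LoS kernel scale
#'
#' Walks a decreasing grid of `sigma` values starting at 10 mV and returns
#' the first (largest) value for which the mean LoS over all cross-fiber
#' pairs falls below `threshold`, so that distinct fibers are resolved while
#' within-fiber agreement is retained. With no cross-fiber pairs (a single
#' fiber) the grid maximum is returned with a warning.
#'
#' @param result a [integrate_network()] result or a list of them (use the
#'   network with the most fibers; with a list, the cross-fiber mean is
#'   pooled over all runs).
#' @param part the fiber partition of that network.
#' @param threshold cross-fiber mean LoS cut (default 0.001).
#' @param grid decreasing sigma grid, mV.
#' @param window analysis window, s.
#' @export
calibrate_sigma <- function(result, part, threshold = 0.001,
                            grid = c(10, 5, 2, 1, 0.5, 0.2, 0.1, 0.05,
                                     0.02, 0.01),
                            window = 1) {
  grid <- sort(grid, decreasing = TRUE)
  results <- if (inherits(result, "simulation_result") || is.matrix(result)) {
    list(result)
  } else {
    result
  }
  nodes <- names(part$membership)
  cross <- outer(part$membership[nodes], part$membership[nodes], "!=")
  if (!any(cross)) {
    warning("single-fiber partition: no cross-fiber pairs, returning grid maximum")
    return(grid[1L])
  }
  for (sg in grid) {
    m <- mean(vapply(results, function(r) {
      L <- los_matrix(r, window = window, sigma = sg)
      mean(unclass(L)[nodes, nodes][cross])
    }, 0))
    if (m < threshold) return(sg)
  }
  grid[length(grid)]
}
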