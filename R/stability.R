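#' Jacobian of a model at the threshold equilibrium
#'
#' At the equilibrium `V = V_threshold` every sigmoid evaluates to 0.5 (and
#' its derivative to `gamma / 4`), and the Chem II synaptic variables sit at
#' `s_eq`. Gap junction: `J = -alpha_leak I - alpha_gap L` with `L` the
#' in-Laplacian — independent of the stimulus. Chem I carries the
#' sigmoid-derivative off-diagonals; Chem II is the `2n x 2n` block matrix
#' over `(V, s)` whose only stimulus dependence is the `dV/ds` block
#' `-alpha_chem A[j,i] (V_i - V_s,j)`. All blocks are validated against
#' finite differences of [neuron_rhs()] in the test suite.
#'
#' @inheritParams threshold_voltage
#' @param V_threshold equilibrium voltages; computed from `I_drive` when
#'   omitted.
#' @param I_drive constant drive used when computing the equilibrium.
#' @export
jacobian_matrix <- function(model, net, params, V_threshold = NULL,
                            I_drive = 0) {
  model <- check_model(model)
  nodes <- network_nodes(net)
  n <- length(nodes)
  adj <- net$adj
  al <- params$alpha_leak
  if (model == "gap") {
    adj <- zero_diag(adj)
    L <- diag(colSums(adj), n) - t(adj)
    J <- -al * diag(n) - params$alpha_gap * L
    dimnames(J) <- list(nodes, nodes)
    return(J)
  }
  if (is.null(V_threshold)) {
    V_threshold <- threshold_voltage(net, params, model, I_drive)
  }
  V <- expand_per_node(V_threshold, nodes)
  Vs <- expand_Vs(params, nodes)
  ac <- params$alpha_chem
  gm <- params$gamma
  if (model == "chem1") {
    # dVdot_i/dV_i: leak + sum_j A[j,i] * 0.5 (phi at equilibrium)
    J <- matrix(0, n, n, dimnames = list(nodes, nodes))
    diag(J) <- -al - 0.5 * ac * colSums(adj)
    # dVdot_i/dV_j through phi(V_j): -ac A[j,i] phi'(V_j) (V_i - Vs_j)
    phip <- gm / 4
    for (i in seq_len(n)) {
      J[i, ] <- J[i, ] - ac * adj[, i] * phip * (V[i] - Vs)
    }
    return(J)
  }
  seq_v <- seq_len(n)
  s_eq <- params$s_eq
  J <- matrix(0, 2 * n, 2 * n,
              dimnames = list(c(nodes, paste0("s.", nodes)),
                              c(nodes, paste0("s.", nodes))))
  # dV/dV: diagonal only (V_j enters V-dot_i only through s_j)
  diag(J)[seq_v] <- -al - ac * s_eq * colSums(adj)
  # dV/ds: -ac A[j,i] (V_i - Vs_j)
  for (i in seq_v) {
    J[i, n + seq_v] <- -ac * adj[, i] * (V[i] - Vs)
  }
  # ds/dV: diagonal, a_r phi'(V_i)(1 - s_eq)
  J[cbind(n + seq_v, seq_v)] <- params$a_r * (gm / 4) * (1 - s_eq)
  # ds/ds: diagonal, -a_r * 0.5 - a_d
  J[cbind(n + seq_v, n + seq_v)] <- -params$a_r * 0.5 - params$a_d
  J
}

#' Instability threshold sweep over external-drive strength
#'
#' For every grid value of the constant drive applied to the target fiber(s),
#' recomputes the threshold equilibrium, builds the Jacobian and records the
#' leading eigenvalue real part; the smallest |drive| with a positive leading
#' real part (per sign of the drive) is refined by bisection. The gap model's
#' Jacobian is drive-independent, so a stable gap network reports no
#' crossing.
#'
#' @inheritParams jacobian_matrix
#' @param targets nodes receiving the drive (should form whole fibers).
#' @param I_range length-2 range of drives to scan (pA); a negative lower
#'   bound scans both signs.
#' @param step grid spacing (pA).
#' @param eig_tol positivity tolerance on the leading real part.
#' @param refine_tol bisection tolerance on the crossing (pA).
#' @return object of class `stability_report`: `grid` (data frame of drive
#'   vs leading real part), `threshold_pos`, `threshold_neg` (NA when no
#'   crossing), and `unstable_nodes` (neurons carrying the first unstable
#'   mode).
#' @export
sweep_instability <- function(model, net, params, targets,
                              I_range = c(0, 500), step = 1,
                              eig_tol = 1e-9, refine_tol = 0.01) {
  model <- check_model(model)
  stopifnot(length(I_range) == 2L, I_range[2] > I_range[1])
  leading <- function(I) {
    Iv <- setNames(rep(0, n_nodes(net)), network_nodes(net))
    Iv[targets] <- I
    J <- jacobian_matrix(model, net, params, I_drive = Iv)
    ev <- eigen(J, only.values = TRUE)$values
    max(Re(ev))
  }
  grid <- seq(I_range[1], I_range[2], by = step)
  lead <- vapply(grid, leading, 0)
  find_crossing <- function(gr, le) {
    # gr ordered by increasing |drive|, starting stable
    pos <- which(le > eig_tol)
    if (length(pos) == 0L) return(NA_real_)
    first <- pos[1L]
    if (first == 1L) return(gr[1L]) # unstable from the start
    lo <- gr[first - 1L]; hi <- gr[first]
    while (abs(hi - lo) > refine_tol) {
      mid <- (lo + hi) / 2
      if (leading(mid) > eig_tol) hi <- mid else lo <- mid
    }
    hi
  }
  up <- grid >= 0
  thr_pos <- find_crossing(grid[up], lead[up])
  thr_neg <- if (any(!up)) {
    dn <- order(-grid[!up]) # increasing |drive|
    find_crossing(grid[!up][dn], lead[!up][dn])
  } else NA_real_
  unstable_nodes <- character(0)
  thr <- c(thr_pos, thr_neg)
  thr <- thr[!is.na(thr)]
  if (length(thr) > 0) {
    at <- thr[which.min(abs(thr))]
    Iv <- setNames(rep(0, n_nodes(net)), network_nodes(net))
    Iv[targets] <- at + sign(at + .Machine$double.eps) * refine_tol
    J <- jacobian_matrix(model, net, params, I_drive = Iv)
    eg <- eigen(J)
    lead_i <- which.max(Re(eg$values))
    vec <- abs(Re(eg$vectors[, lead_i]))
    nn <- rownames(J)[vec > 0.5 * max(vec)]
    unstable_nodes <- unique(sub("^s\\.", "", nn))
  }
  structure(list(
    grid = data.frame(I_drive = grid, leading_re = lead),
    threshold_pos = thr_pos, threshold_neg = thr_neg,
    unstable_nodes = unstable_nodes, model = model, targets = targets
  ), class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "none found" else sprintf("%.2f pA", v)
  cat(sprintf(
    "<stability_report: %s model, targets %s>\n  first positive leading eigenvalue at +%s / -%s\n",
    x$model, paste(x$targets, collapse = ","),
    fmt(x$threshold_pos), fmt(abs(x$threshold_neg))
  ))
  invisible(x)
}
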