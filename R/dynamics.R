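#' Model parameters for the admissible neuron ODEs
#'
#' Units: voltages in mV, time in s, currents in pA; the membrane capacitance
#' C = 1 pF is absorbed into `alpha_ext = 1/C` so that a 1 pA current drives
#' the voltage at 1 mV/s (the package's working convention, matching the
#' stimulus and threshold scales used throughout). `gamma` is the sigmoid
#' steepness in 1/mV (default 0.125, i.e. 125 V^-1); [gamma_from_range()]
#' gives the value implied by a 0.1-to-0.9 sigmoid rise over 36 mV.
#' `s_eq = a_r / (a_r + 2 a_d)` is the synaptic-variable equilibrium with the
#' sigmoid at 0.5.
#'
#' @param alpha_leak leak rate, 1/s.
#' @param alpha_gap,alpha_chem coupling rates, 1/s.
#' @param alpha_ext external-drive gain, 1/pF.
#' @param V_rest resting potential, mV.
#' @param gamma sigmoid steepness, 1/mV.
#' @param a_r,a_d synaptic rise and decay rates, 1/s.
#' @param V_s synaptic reversal potential(s), mV: 0 excitatory, -70
#'   inhibitory; scalar or named per-presynaptic-neuron vector.
#' @export
model_params <- function(alpha_leak = 10, alpha_gap = 100, alpha_chem = 100,
                         alpha_ext = 1, V_rest = -37, gamma = 0.125,
                         a_r = 1, a_d = 5, V_s = 0) {
  stopifnot(alpha_leak > 0, alpha_gap > 0, alpha_chem > 0, alpha_ext > 0,
            gamma > 0, a_r > 0, a_d > 0)
  structure(list(
    alpha_leak = alpha_leak, alpha_gap = alpha_gap, alpha_chem = alpha_chem,
    alpha_ext = alpha_ext, V_rest = V_rest, gamma = gamma,
    a_r = a_r, a_d = a_d, s_eq = a_r / (a_r + 2 * a_d), V_s = V_s
  ), class = "model_params")
}

#' @rdname model_params
#' @param rise_range voltage range (mV) over which the sigmoid rises from
#'   0.1 to 0.9.
#' @export
gamma_from_range <- function(rise_range = 36) {
  2 * log(0.9 / 0.1) / rise_range
}

check_model <- function(model) {
  match.arg(model, c("gap", "chem1", "chem2"))
}

# per-presynaptic-neuron reversal potentials as a full named vector
expand_Vs <- function(params, nodes) {
  vs <- params$V_s
  if (length(vs) == 1L && is.null(names(vs))) {
    return(setNames(rep(vs, length(nodes)), nodes))
  }
  out <- setNames(rep(0, length(nodes)), nodes)
  out[names(vs)] <- vs
  out
}

expand_per_node <- function(x, nodes, default = 0) {
  out <- setNames(rep(default, length(nodes)), nodes)
  if (length(x) == 1L && is.null(names(x))) {
    out[] <- x
  } else if (!is.null(names(x))) {
    bad <- setdiff(names(x), nodes)
    if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
    out[names(x)] <- x
  } else if (length(x) == length(nodes)) {
    out[] <- x
  } else {
    stop("per-node value has wrong length")
  }
  out
}

#' Threshold (equilibrium) voltages
#'
#' Solves the linear steady state of the chosen model with the sigmoid fixed
#' at 0.5 and the synaptic variable at `s_eq` (Chem II) — the stable-point
#' solution used both as the sigmoid midpoint `V_threshold` and as the
#' equilibrium around which stability is analyzed. The constant drive
#' `I_drive` enters the right-hand side; oscillatory and noise terms average
#' to zero and are excluded.
#'
#' @param net a [neuron_network()].
#' @param params a [model_params()].
#' @param model `"gap"`, `"chem1"` or `"chem2"`.
#' @param I_drive constant drive, pA: scalar or named per-node vector.
#' @return named vector of per-neuron threshold voltages (mV).
#' @export
threshold_voltage <- function(net, params, model, I_drive = 0) {
  model <- check_model(model)
  nodes <- network_nodes(net)
  n <- length(nodes)
  adj <- net$adj
  if (model == "gap") adj <- zero_diag(adj)
  Iv <- expand_per_node(I_drive, nodes)
  Vs <- expand_Vs(params, nodes)
  al <- params$alpha_leak
  M <- diag(n)
  b <- rep(params$V_rest, n)
  if (model == "gap") {
    indeg <- colSums(adj)
    M <- M + diag(params$alpha_gap * indeg / al, n)
    M <- M - params$alpha_gap * t(adj) / al
  } else {
    cc <- if (model == "chem1") 0.5 else params$s_eq
    indeg <- colSums(adj)
    M <- M + diag(cc * params$alpha_chem * indeg / al, n)
    b <- b + cc * params$alpha_chem * as.vector(t(adj) %*% Vs) / al
  }
  b <- b + params$alpha_ext * Iv / al
  rc <- rcond(M)
  if (!is.finite(rc) || rc < 1e-12) {
    stop(sprintf("steady-state system is singular (rcond = %.3e)", rc))
  }
  setNames(solve(M, b), nodes)
}

zero_diag <- function(adj) {
  diag(adj) <- 0
  adj
}

sigmoid_phi <- function(V, V_thr, gamma) {
  1 / (1 + exp(-gamma * (V - V_thr)))
}

#' Right-hand side of the admissible ODEs (reference implementation)
#'
#' Gap junction: `dV_i = f(V_i) - a_gap * sum_j A[j,i] (V_i - V_j) + I_i`;
#' Chem type I couples through `Phi(V_j) (V_i - V_s,j)`; Chem type II through
#' `s_j (V_i - V_s,j)` with `ds_i = a_r Phi(V_i)(1 - s_i) - a_d s_i`;
#' `f(V) = -a_leak (V - V_rest)`. Coupling always sums over in-edges with
#' multiplicity. The compiled integrator reproduces this function; it is
#' exposed for residual and finite-difference checks.
#'
#' @inheritParams threshold_voltage
#' @param state numeric state vector: voltages (gap, chem1) or voltages then
#'   synaptic variables (chem2).
#' @param t time (s); unused unless `I_ext` is a function of time.
#' @param I_ext per-node external current (pA) at time `t`: scalar, named
#'   vector, or function of `t`.
#' @param V_threshold per-neuron sigmoid midpoints; defaults to the
#'   zero-drive threshold solution.
#' @export
neuron_rhs <- function(model, state, t, net, params, I_ext = 0,
                       V_threshold = NULL) {
  model <- check_model(model)
  nodes <- network_nodes(net)
  n <- length(nodes)
  adj <- net$adj
  if (model == "gap") {
    adj <- zero_diag(adj)
    if (!isTRUE(all.equal(adj, t(adj)))) {
      stop("gap model requires an undirected (symmetric) network")
    }
  }
  if (is.function(I_ext)) I_ext <- I_ext(t)
  Iv <- expand_per_node(I_ext, nodes)
  V <- state[seq_len(n)]
  f <- -params$alpha_leak * (V - params$V_rest)
  drive <- params$alpha_ext * Iv
  if (model == "gap") {
    coup <- params$alpha_gap * (colSums(adj) * V - as.vector(t(adj) %*% V))
    return(f - coup + drive)
  }
  Vs <- expand_Vs(params, nodes)
  if (is.null(V_threshold)) {
    V_threshold <- threshold_voltage(net, params, model)
  }
  Vt <- expand_per_node(V_threshold, nodes)
  if (model == "chem1") {
    phi <- sigmoid_phi(V, Vt, params$gamma)
    # sum_j A[j,i] phi(V_j) (V_i - Vs_j)
    coup <- params$alpha_chem *
      (as.vector(t(adj) %*% phi) * V - as.vector(t(adj) %*% (phi * Vs)))
    return(f - coup + drive)
  }
  s <- state[n + seq_len(n)]
  coup <- params$alpha_chem *
    (as.vector(t(adj) %*% s) * V - as.vector(t(adj) %*% (s * Vs)))
  dV <- f - coup + drive
  phi <- sigmoid_phi(V, Vt, params$gamma)
  ds <- params$a_r * phi * (1 - s) - params$a_d * s
  c(dV, ds)
}

#' External stimulus specification
#'
#' A stimulus is a set of per-node channels
#' `I(t) = I_drive + I_osc sin(2 pi f t) + I_noise(t)`, where `I_noise` is a
#' Gaussian random walk (unit-variance increments) min-max rescaled into
#' `[-noise_scale, noise_scale]` over the run. When a partition is supplied
#' and `share_within_fiber` is set, nodes of the same fiber share one noise
#' path, preserving the input symmetry; a warning flags stimuli that cover a
#' fiber only partially (symmetry-breaking).
#'
#' @param targets character vector of stimulated nodes.
#' @param I_drive constant current, pA.
#' @param I_osc oscillation amplitude, pA.
#' @param freq oscillation frequency, Hz.
#' @param noise_scale random-walk bound, pA.
#' @param part optional [node_partition()] used for sharing/diagnostics.
#' @param share_within_fiber share one noise path per targeted fiber.
#' @export
build_stimulus <- function(targets, I_drive = 0, I_osc = 0, freq = 0,
                           noise_scale = 0, part = NULL,
                           share_within_fiber = TRUE) {
  targets <- as.character(targets)
  group <- targets
  if (!is.null(part)) {
    memb <- part$membership
    covered <- split(targets, memb[targets])
    for (cell in names(covered)) {
      if (length(covered[[cell]]) < length(part$cells[[cell]]) &&
          share_within_fiber) {
        warning(sprintf(
          "stimulus covers fiber %s only partially; fiber symmetry is broken",
          cell
        ))
      }
    }
    if (share_within_fiber) group <- unname(memb[targets])
  }
  channels <- data.frame(
    node = targets, I_drive = I_drive, I_osc = I_osc, freq = freq,
    noise_scale = noise_scale, noise_group = group,
    stringsAsFactors = FALSE
  )
  structure(list(channels = channels), class = "stimulus")
}

#' @rdname build_stimulus
#' @param ... `stimulus` objects to combine (e.g. interneuron and
#'   motor-neuron channels at different frequencies).
#' @export
combine_stimuli <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, inherits, NA, "stimulus")))
  structure(list(channels = do.call(rbind, lapply(parts, `[[`, "channels"))),
            class = "stimulus")
}

# Materialize a stimulus on a time grid: per-node constant drive, sinusoid
# channels (evaluated at RK stage times inside the integrator), and the
# per-node noise matrix (one seeded Gaussian random walk per noise group,
# min-max rescaled, advancing once per step). `trace` is the stimulus as
# sampled on the grid, for the result record.
stimulus_realization <- function(stim, nodes, times, seed = NULL) {
  n <- length(nodes)
  nt <- length(times)
  empty <- list(
    Id = setNames(rep(0, n), nodes), ch_node = integer(0),
    ch_amp = numeric(0), ch_freq = numeric(0),
    noise = matrix(0, n, 0), trace = matrix(0, n, nt,
                                            dimnames = list(nodes, NULL))
  )
  if (is.null(stim)) return(empty)
  ch <- stim$channels
  bad <- setdiff(ch$node, nodes)
  if (length(bad)) stop("stimulus targets unknown node(s): ",
                        paste(bad, collapse = ", "))
  out <- empty
  for (r in seq_len(nrow(ch))) {
    out$Id[ch$node[r]] <- out$Id[ch$node[r]] + ch$I_drive[r]
  }
  osc <- ch$I_osc != 0
  out$ch_node <- match(ch$node[osc], nodes) - 1L
  out$ch_amp <- ch$I_osc[osc]
  out$ch_freq <- ch$freq[osc]
  if (any(ch$noise_scale > 0)) {
    if (!is.null(seed)) set.seed(seed)
    noise <- matrix(0, n, nt, dimnames = list(nodes, NULL))
    for (g in sort(unique(ch$noise_group[ch$noise_scale > 0]))) {
      inc <- rnorm(nt)
      walk <- cumsum(inc)
      rng <- range(walk)
      sc <- max(ch$noise_scale[ch$noise_group == g])
      walk <- if (diff(rng) > 0) {
        (walk - rng[1]) / diff(rng) * 2 * sc - sc
      } else {
        rep(0, nt)
      }
      for (nd in unique(ch$node[ch$noise_group == g & ch$noise_scale > 0])) {
        noise[nd, ] <- noise[nd, ] + walk
      }
    }
    out$noise <- noise
  }
  trace <- matrix(out$Id, n, nt, dimnames = list(nodes, NULL))
  for (k in seq_along(out$ch_node)) {
    i <- out$ch_node[k] + 1L
    trace[i, ] <- trace[i, ] + out$ch_amp[k] * sin(2 * pi * out$ch_freq[k] * times)
  }
  if (ncol(out$noise) > 0) trace <- trace + out$noise
  out$trace <- trace
  attr(out$trace, "max_amplitude_nominal") <-
    max(abs(ch$I_drive) + abs(ch$I_osc) + abs(ch$noise_scale))
  out
}

#' Integrate a network model
#'
#' Fixed-step 4th-order Runge-Kutta with time step `dt`; the stimulus
#' (including its seeded random-walk noise path, updated per step so the
#' noise advances on the sqrt(dt) diffusion scale) is held piecewise constant
#' over each step. Deterministic runs are bit-reproducible; stochastic runs
#' are bit-reproducible for a fixed seed.
#'
#' @inheritParams threshold_voltage
#' @param stim a [build_stimulus()] specification, or `NULL`.
#' @param init list with `V` (scalar or per-node, mV) and, for chem2, `s`
#'   (defaults to `s_eq`).
#' @param T total simulated time, s.
#' @param dt time step, s (default 1e-4, i.e. 0.1 ms).
#' @param seed integer seed for the stimulus noise.
#' @return object of class `simulation_result`: `times`, voltage matrix `V`
#'   (nodes x samples), synaptic matrix `S` (chem2), the per-node stimulus
#'   trace of targeted nodes, `model`, `dt`, `seed`.
#' @export
integrate_network <- function(model, net, params, stim = NULL, init,
                              T = 5, dt = 1e-4, seed = NULL) {
  model <- check_model(model)
  stopifnot(dt > 0, T >= dt)
  nodes <- network_nodes(net)
  n <- length(nodes)
  nsteps <- as.integer(round(T / dt))
  times <- seq(0, by = dt, length.out = nsteps + 1L)
  sr <- stimulus_realization(stim, nodes, times, seed)
  Vt <- if (model == "gap") rep(0, n) else {
    threshold_voltage(net, params, model, I_drive = sr$Id)
  }
  V0 <- expand_per_node(init$V, nodes)
  s0 <- if (model == "chem2") {
    expand_per_node(if (is.null(init$s)) params$s_eq else init$s, nodes)
  } else numeric(0)
  adj <- if (model == "gap") zero_diag(net$adj) else net$adj
  if (model == "gap" && !isTRUE(all.equal(adj, t(adj)))) {
    stop("gap model requires an undirected (symmetric) network")
  }
  Vs <- expand_Vs(params, nodes)
  code <- match(model, c("gap", "chem1", "chem2"))
  noise <- if (ncol(sr$noise) > 0) {
    sr$noise[, seq_len(nsteps), drop = FALSE]
  } else {
    matrix(0, n, 0)
  }
  res <- rk4_core(
    adj, code,
    c(params$alpha_leak, params$alpha_gap, params$alpha_chem,
      params$alpha_ext, params$V_rest, params$gamma, params$a_r, params$a_d),
    Vs, Vt, unname(sr$Id), sr$ch_node, sr$ch_amp, sr$ch_freq, noise,
    V0, s0, dt, nsteps
  )
  if (res$status != 0L) {
    stop(sprintf("simulation diverged (non-finite state) at step %d (t = %.4f s)",
                 res$bad_step, res$bad_step * dt))
  }
  V <- res$V
  dimnames(V) <- list(nodes, NULL)
  S <- NULL
  if (model == "chem2") {
    S <- res$S
    dimnames(S) <- list(nodes, NULL)
  }
  tgt <- if (is.null(stim)) character(0) else unique(stim$channels$node)
  stim_trace <- sr$trace[tgt, , drop = FALSE]
  attr(stim_trace, "max_amplitude_nominal") <-
    attr(sr$trace, "max_amplitude_nominal")
  structure(list(
    times = times, V = V, S = S,
    stimulus = stim_trace,
    V_threshold = if (model == "gap") NULL else Vt,
    model = model, dt = dt, seed = seed
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: %s model, %d neurons, %.3f s @ dt = %g>\n",
              x$model, nrow(x$V), max(x$times), x$dt))
  invisible(x)
}
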