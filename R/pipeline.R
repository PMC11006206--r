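#' Simulation test 1: free-running synchronization
#'
#' Runs the chosen chemical model with no external stimulus from initial
#' voltages normally distributed around a mean (the resting state in the
#' study setup), over a grid of initial-condition standard deviations, and
#' compares the final-window LoS blocks against the fiber partition. Gap
#' networks are documented to synchronize globally in this setting and are
#' reported as a single block.
#'
#' @param cfg list with fields: `net`, `partition`, `model`, optional
#'   `params` ([model_params()]), `ic_mean` (mV, default -35), `ic_sds`
#'   (grid of voltage IC standard deviations, default `c(0, 0.05, 0.1)`),
#'   `s_sd` (chem2 synaptic IC sd, default 0), `T` (s, default 5), `dt`
#'   (default 1e-4), `sigma` (LoS scale, default 0.1), `seed`.
#' @return report list: per-sd LoS matrices, within-fiber verdicts, and
#'   cross-fiber merges observed (reported, not failed).
#' @export
run_test1 <- function(cfg) {
  cfg <- default_cfg(cfg, ic_mean = -35, ic_sds = c(0, 0.05, 0.1), s_sd = 0,
                     T = 5, dt = 1e-4, sigma = 0.1, seed = 1L)
  part <- cfg$partition
  runs <- list()
  for (sd_v in cfg$ic_sds) {
    set.seed(cfg$seed + round(1000 * sd_v))
    n <- n_nodes(cfg$net)
    V0 <- rnorm(n, cfg$ic_mean, sd_v)
    s0 <- if (cfg$model == "chem2") {
      pmax(0, pmin(1, rnorm(n, cfg$params$s_eq, cfg$s_sd)))
    } else NULL
    res <- integrate_network(cfg$model, cfg$net, cfg$params, stim = NULL,
                             init = list(V = V0, s = s0),
                             T = cfg$T, dt = cfg$dt, seed = cfg$seed)
    L <- los_matrix(res, window = min(1, cfg$T / 2), sigma = cfg$sigma)
    runs[[length(runs) + 1L]] <- list(
      ic_sd = sd_v,
      los = L,
      within_fiber_ok = within_fiber_synchrony(L, part),
      cross_fiber_merges = cross_fiber_merges(L, part)
    )
  }
  list(config = cfg, runs = runs)
}

#' Simulation test 2: driven synchronization below the instability threshold
#'
#' Sweeps the instability threshold for the drive targets, then drives the
#' network with a constant input at 90% of that threshold plus a sinusoidal
#' stimulus at 5% of it (interneurons at `f_inter` Hz; gap networks get an
#' additional motor-fiber channel at `f_motor` Hz, needed to break their
#' global synchrony). Reports the binarized LoS, the sync-difference score
#' against the ideal fiber LoS, and the stability report.
#'
#' @param cfg list with `net`, `partition`, `model`, `drive_targets`
#'   (interneuron pair fiber), optional `motor_targets` (gap networks),
#'   `params`, `I_range`, `step`, `fallback_drive` (pA, used when no
#'   instability is found in range, e.g. the gap model), `f_inter` (2 Hz),
#'   `f_motor` (1 Hz), `T`, `dt`, `sigma`, `seed`.
#' @export
run_test2 <- function(cfg) {
  cfg <- default_cfg(cfg, I_range = c(0, 500), step = 5, fallback_drive = 200,
                     f_inter = 2, f_motor = 1, T = 5, dt = 1e-4, sigma = 0.1,
                     seed = 1L, ic_mean = -35)
  part <- cfg$partition
  rep_stab <- sweep_instability(cfg$model, cfg$net, cfg$params,
                                cfg$drive_targets, I_range = cfg$I_range,
                                step = cfg$step)
  thr <- rep_stab$threshold_pos
  base_I <- if (is.na(thr)) cfg$fallback_drive else 0.9 * thr
  osc_I <- if (is.na(thr)) 0.05 * cfg$fallback_drive else 0.05 * thr
  stim <- build_stimulus(cfg$drive_targets, I_drive = base_I, I_osc = osc_I,
                         freq = cfg$f_inter, part = part)
  if (!is.null(cfg$motor_targets)) {
    stim <- combine_stimuli(stim, build_stimulus(
      cfg$motor_targets, I_drive = base_I, I_osc = osc_I,
      freq = cfg$f_motor, part = part
    ))
  }
  res <- integrate_network(cfg$model, cfg$net, cfg$params, stim = stim,
                           init = list(V = cfg$ic_mean),
                           T = cfg$T, dt = cfg$dt, seed = cfg$seed)
  L <- los_matrix(res, window = min(1, cfg$T / 2), sigma = cfg$sigma)
  score <- sync_difference(L, ideal_los(part))
  list(config = cfg, stability = rep_stab, drive = base_I, los = L,
       score = score,
       within_fiber_ok = within_fiber_synchrony(L, part))
}

#' Simulation test 3: robustness to weight perturbation
#'
#' For every perturbation level on the std grid, draws `n_reps` seeded
#' weight-perturbed copies of the network, simulates each under the stated
#' drive (constant 0.1 pA + 0.5 pA oscillation at 2 Hz interneuron / 1 Hz
#' motor + random-walk noise in ±0.01 pA — nominal max amplitude 0.61 pA,
#' asserted), averages the LoS matrices, masks them with the binarized
#' unperturbed LoS and reports the within-block difference curve, plus
#' within/cross-fiber PLV summaries.
#'
#' @param cfg list with `net`, `partition`, `model`, `drive_targets`,
#'   optional `motor_targets`, `params`, `stds` (default `seq(0, 0.1,
#'   0.01)`), `n_reps` (default 10), `T`, `dt`, `sigma`, `seed`, `plv`
#'   (compute PLV summaries, default TRUE).
#' @export
run_test3 <- function(cfg) {
  cfg <- default_cfg(cfg, stds = seq(0, 0.1, by = 0.01), n_reps = 10L,
                     T = 5, dt = 1e-4, sigma = 0.1, seed = 1L, plv = TRUE,
                     ic_mean = -35, f_inter = 2, f_motor = 1)
  part <- cfg$partition
  stim <- build_stimulus(cfg$drive_targets, I_drive = 0.1, I_osc = 0.5,
                         freq = cfg$f_inter, noise_scale = 0.01, part = part)
  if (!is.null(cfg$motor_targets)) {
    stim <- combine_stimuli(stim, build_stimulus(
      cfg$motor_targets, I_drive = 0.1, I_osc = 0.5, freq = cfg$f_motor,
      noise_scale = 0.01, part = part
    ))
  }
  nominal_max <- max(abs(stim$channels$I_drive) + abs(stim$channels$I_osc) +
                       abs(stim$channels$noise_scale))
  stopifnot(isTRUE(all.equal(nominal_max, 0.61)))
  simulate_one <- function(net, seed) {
    integrate_network(cfg$model, net, cfg$params, stim = stim,
                      init = list(V = cfg$ic_mean),
                      T = cfg$T, dt = cfg$dt, seed = seed)
  }
  res0 <- simulate_one(cfg$net, cfg$seed)
  L0 <- los_matrix(res0, window = min(1, cfg$T / 2), sigma = cfg$sigma)
  mask <- (unclass(L0) >= 0.995) * 1
  rows <- list()
  plv_rows <- list()
  for (std in cfg$stds) {
    acc <- 0
    plv_acc <- NULL
    for (r in seq_len(cfg$n_reps)) {
      seed_r <- cfg$seed + 7919L * r + round(1e4 * std)
      net_p <- perturb_weights(cfg$net, std, seed = seed_r)
      res <- simulate_one(net_p, seed_r)
      L <- los_matrix(res, window = min(1, cfg$T / 2), sigma = cfg$sigma)
      acc <- acc + unclass(L) / cfg$n_reps
      if (cfg$plv) {
        P <- plv_matrix(res, window = min(1, cfg$T / 2))
        plv_acc <- if (is.null(plv_acc)) P / cfg$n_reps else
          plv_acc + P / cfg$n_reps
      }
    }
    # masked comparison on the expected (diagonal-block) synchronizations
    diffm <- (mask - acc) * mask
    diag(diffm) <- 0
    n <- nrow(mask)
    rows[[length(rows) + 1L]] <- data.frame(
      std = std, block_difference = sum(diffm) / (2 * (n^2 - n))
    )
    if (cfg$plv) {
      same <- outer(part$membership, part$membership, "==")
      diag(same) <- NA
      plv_rows[[length(plv_rows) + 1L]] <- data.frame(
        std = std,
        plv_within = mean(plv_acc[same & !is.na(same)]),
        plv_cross = mean(plv_acc[!same & !is.na(same)])
      )
    }
  }
  list(config = cfg, curve = do.call(rbind, rows),
       plv = if (cfg$plv) do.call(rbind, plv_rows) else NULL,
       baseline_los = L0)
}

default_cfg <- function(cfg, ...) {
  defaults <- list(...)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  if (is.null(cfg$params)) cfg$params <- model_params()
  stopifnot(inherits(cfg$net, "neuron_network"),
            inherits(cfg$partition, "node_partition"))
  cfg$model <- check_model(cfg$model)
  cfg
}

# TRUE iff every within-fiber pair is (near-)fully synchronous
within_fiber_synchrony <- function(L, part, eps = 0.005) {
  nodes <- rownames(L)
  same <- outer(part$membership[nodes], part$membership[nodes], "==")
  diag(same) <- FALSE
  all(unclass(L)[same] >= 1 - eps)
}

# pairs of distinct cells whose blocks are mutually synchronous
cross_fiber_merges <- function(L, part, eps = 0.005) {
  nodes <- rownames(L)
  memb <- part$membership[nodes]
  cells <- names(part$cells)
  merges <- character(0)
  for (a in seq_along(cells)) {
    for (b in seq_len(a - 1L)) {
      blk <- unclass(L)[memb == cells[a], memb == cells[b], drop = FALSE]
      if (all(blk >= 1 - eps)) {
        merges <- c(merges, paste(cells[b], cells[a], sep = "+"))
      }
    }
  }
  merges
}
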