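## Precompute everything a trial loop needs that does not change within a
## run: kernel operator matrices, the velocity kick, lattice index grids.
build_engine <- function(config) {
  n <- config$geometry$size
  list(
    n = n,
    c0 = (n + 1) / 2,
    ker_tl = make_kernel(config$tl$c_exc, config$tl$s_exc,
                         config$tl$c_inh, config$tl$s_inh,
                         config$tl$g_inh, n),
    ker_d = make_kernel(config$disp$c_exc, config$disp$s_exc,
                        config$disp$c_inh, config$disp$s_inh,
                        config$disp$g_inh, n),
    ker_v = make_kernel(config$vel$c_exc, config$vel$s_exc,
                        config$vel$c_inh, config$vel$s_inh,
                        config$vel$g_inh, n),
    qker_d = kernel_matrix(config$disp$q_s, n),
    qker_v = kernel_matrix(config$vel$q_s, n),
    kick = gaussian_blob(c((n + 1) / 2, (n + 1) / 2),
                         config$vel$kick_sigma, n)
  )
}

#' Simulate one closed-loop reach trial
#'
#' Runs the full loop on one display: the visual front end parses the
#' image into items, saliency levels and the movement-onset scaling
#' factor; then, at every step, the saliency competition nodes, the
#' target location field, the hand-target displacement field and the
#' two-layer velocity field are updated concurrently, the velocity blob
#' is read out, and the end effector moves. Selection and movement are
#' coupled throughout, so unresolved competition leaks into the early
#' movement and curves the trajectory. All state is created afresh per
#' trial (hard inter-trial reset).
#'
#' @param display a \code{crt_display} (or H x W x 3 pixel array).
#' @param config a \code{crt_config}.
#' @param seed integer seed for this trial's noise streams; with
#'   \code{config$noise_sd = 0} the trial is fully deterministic.
#' @param record_fields optional integer vector of steps at which to
#'   snapshot all field lattices (returned under \code{$fields}, for
#'   diagnostics).
#' @return Object of class \code{crt_trace}: positions (steps x 2),
#'   speeds, per-step gate and readout peak, selected item, success flag,
#'   winner node of the saliency competition, condition code, seed.
#' @examples
#' cfg <- crt_config(noise_sd = 0)
#' tr <- run_trial(crt_display("ddT"), cfg)
#' tr$success
#' @export
run_trial <- function(display, config = crt_config(), seed = NULL,
                      record_fields = NULL) {
  snapshots <- if (!is.null(record_fields)) list() else NULL
  eng <- build_engine(config)
  vis <- parse_display(display, config)
  n <- eng$n
  dt <- config$dt
  noise_sd <- config$noise_sd

  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  maps <- location_maps(vis$items, config$motor$loc_width, n,
                        size_exp = config$motor$loc_size_exp)
  centroids <- cbind(vis$items$centroid_row, vis$items$centroid_col)
  gate_delay <- round(config$motor$onset_steps_per_unit * vis$s_prox)

  # inter-trial reset: everything starts at its resting level
  u <- rep(config$competition$h, 3)
  TL <- matrix(config$tl$h, n, n)
  D <- matrix(config$disp$h, n, n)
  v <- list(v1 = matrix(config$vel$h, n, n),
            v2 = matrix(config$vel$h, n, n))
  hand <- config$motor$start
  Hm <- hand_map(hand, config$motor$hand_width, n)

  max_steps <- config$max_steps
  positions <- matrix(NA_real_, max_steps + 1, 2)
  speeds <- numeric(max_steps)
  gates <- numeric(max_steps)
  peaks <- numeric(max_steps)
  positions[1, ] <- hand

  cw <- config$wta
  streak <- 0L; leader <- NA_integer_; winner <- NA_integer_
  winner_step <- NA_integer_
  converged <- FALSE
  steps_done <- 0L

  for (t in seq_len(max_steps)) {
    nz <- function(k) if (noise_sd > 0) stats::rnorm(k, 0, noise_sd) else
      numeric(k)
    # saliency competition (noise at the nodes)
    u <- step_competition(u, vis$levels, config$competition, dt, nz(3))
    fu <- field_sigmoid(u, config$competition$beta, config$competition$u0)
    if (is.na(winner)) {
      ord <- order(fu, decreasing = TRUE)
      ok <- fu[ord[1]] > cw$f_win && (fu[ord[1]] - fu[ord[2]]) > cw$lead
      if (ok && identical(ord[1], leader)) streak <- streak + 1L
      else if (ok) { leader <- ord[1]; streak <- 1L }
      else { leader <- NA_integer_; streak <- 0L }
      if (streak >= cw$hold) { winner <- leader; winner_step <- t }
    }
    # target location field (noise-free per the noise injection sites)
    TL <- step_target_field(TL, target_field_input(fu, maps,
                                                   config$tl$input_gain),
                            config$tl, eng$ker_tl, dt, 0)
    fT <- field_sigmoid(TL, config$tl$beta)
    # hand-target displacement field (noisy)
    Din <- displacement_input(hand, fT, config$motor$hand_width,
                              config$disp$input_gain)
    D <- step_displacement_field(D, Din, Hm, config$disp, eng$ker_d,
                                 eng$qker_d, dt,
                                 matrix(nz(n * n), n, n))
    # gated velocity drive and two-layer velocity field (noisy)
    gate <- onset_gate(vis$s_prox, t, config$motor$onset_steps_per_unit)
    Iv1 <- config$vel$input_gain *
      velocity_input(D, eng$kick, config$vel$kick_amp,
                     config$vel$kick_sigma, gate)
    v <- step_velocity_fields(v, Iv1, Hm, config$vel, eng$ker_v,
                              eng$qker_v, dt,
                              matrix(nz(n * n), n, n),
                              matrix(nz(n * n), n, n))
    # readout and closed-loop hand update
    mv <- readout_and_move(v$v2, hand, config$vel, config$motor$gain, dt,
                           config$motor$readout_sat)
    hand <- mv$position
    Hm <- hand_map(hand, config$motor$hand_width, n)
    positions[t + 1, ] <- hand
    speeds[t] <- mv$speed
    gates[t] <- gate
    peaks[t] <- mv$peak
    steps_done <- t
    if (!is.null(record_fields) && t %in% record_fields)
      snapshots[[as.character(t)]] <-
        list(u = u, TL = TL, D = D, v1 = v$v1, v2 = v$v2, hand = hand)
    d2 <- sqrt(rowSums((centroids - matrix(hand, 3, 2, byrow = TRUE))^2))
    if (min(d2) <= config$arrive_tol) { converged <- TRUE; break }
  }

  keep <- seq_len(steps_done)
  positions <- positions[c(1L, keep + 1L), , drop = FALSE]
  d2 <- sqrt(rowSums((centroids - matrix(hand, 3, 2, byrow = TRUE))^2))
  selected <- which.min(d2)
  structure(list(
    code = vis$code,
    seed = seed,
    positions = positions,
    speeds = speeds[keep],
    gate = gates[keep],
    peak_vel = peaks[keep],
    selected_item = selected,
    target_item = vis$target_position,
    success = converged && selected == vis$target_position,
    converged = converged,
    steps = steps_done,
    winner_node = winner,
    winner_step = winner_step,
    s_prox = vis$s_prox,
    gate_delay = gate_delay,
    start = config$motor$start,
    target_centroid = centroids[vis$target_position, ],
    fields = snapshots
  ), class = "crt_trace")
}

#' @export
print.crt_trace <- function(x, ...) {
  cat(sprintf("crt_trace '%s': %d steps, %s (item %d, target %d)\n",
              x$code, x$steps,
              if (x$success) "hit target" else
                if (x$converged) "hit wrong item" else "did not converge",
              x$selected_item, x$target_item))
  invisible(x)
}

#' Run the full factorial reaching experiment
#'
#' Simulates \code{n_sets} randomised sets of the 24 display conditions
#' (the reference layout: 25 sets, 600 trials) with per-trial seeds
#' derived from the master seed, then aggregates initiation latency and
#' maximum deviation per condition. Non-convergent trials are kept in the
#' trace list, flagged, counted, and excluded from condition means.
#'
#' @param config a \code{crt_config}; \code{config$n_sets} and
#'   \code{config$seed} define the layout.
#' @param progress print per-set progress.
#' @return Object of class \code{crt_experiment}: \code{traces} (list of
#'   \code{crt_trace}), \code{manifest}, \code{summary} (condition
#'   summary data frame from \code{\link{summarize_traces}}),
#'   \code{measures} (per-trial IL/MD data frame), \code{config}.
#' @export
run_experiment <- function(config = crt_config(), progress = FALSE) {
  batch <- crt_batch(config$n_sets, config$seed, config$geometry,
                     config$palette)
  traces <- vector("list", nrow(batch$manifest))
  for (i in seq_len(nrow(batch$manifest))) {
    traces[[i]] <- run_trial(batch$displays[[i]], config,
                             batch$manifest$seed[i])
    if (progress && batch$manifest$trial[i] == 24L)
      message(sprintf("set %d/%d done", batch$manifest$set[i],
                      config$n_sets))
  }
  measures <- trial_measures(traces)
  structure(list(
    traces = traces,
    manifest = batch$manifest,
    measures = measures,
    summary = summarize_traces(traces, measures),
    n_failed = sum(!vapply(traces, `[[`, TRUE, "converged")),
    config = config
  ), class = "crt_experiment")
}

#' @export
print.crt_experiment <- function(x, ...) {
  cat(sprintf("crt_experiment: %d trials (%d sets), %d non-convergent\n",
              length(x$traces), x$config$n_sets, x$n_failed))
  cat(sprintf("  success rate %.1f%%, mean IL %.1f steps, mean MD %.2f px\n",
              100 * mean(vapply(x$traces, `[[`, TRUE, "success")),
              mean(x$measures$il, na.rm = TRUE),
              mean(x$measures$md, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.crt_experiment <- function(object, ...) {
  object$summary
}
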