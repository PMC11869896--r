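#' Simulation configuration for the choice-reaching model
#'
#' Collects every tunable quantity of the simulator in one serialisable
#' object: display geometry and palette, the per-item saliency level table,
#' the proximity-based movement-onset scaling factors, the dynamic neural
#' field parameters of each stage, motor readout constants, noise, and the
#' experiment layout. A full run is reproducible from the config plus a
#' master seed alone.
#'
#' Defaults follow the tuned model: saliency levels small target 5.0 >
#' large target 4.8 > small distractor 4.6 > large distractor 4.4;
#' movement-onset scaling factors 0.125 (dd), 0.1 (Dd/dD), 0.075 (DD);
#' competition node parameters tau 20, h -1, beta 1, A 1, B 7, C 0.7,
#' D -4; field rows for the target-location, hand-target displacement and
#' two-layer velocity fields; noise s.d. 0.005 injected at the competition
#' nodes, the displacement field and the velocity field; velocity movement
#' threshold 0.5.
#'
#' @param ... named overrides. Top-level scalar entries (e.g.
#'   \code{n_sets}, \code{seed}, \code{noise_sd}) are replaced; list
#'   entries (e.g. \code{motor = list(gain = 0.04)}) are merged into the
#'   corresponding default sub-list, so only the named fields change.
#' @return An object of class \code{crt_config} (a nested named list).
#' @examples
#' cfg <- crt_config(n_sets = 1, seed = 7)
#' cfg$factors
#' crt_config(factors = c(dd = 0.35, Dd = 0.2, DD = 0))$factors
#' @export
crt_config <- function(...) {
  cfg <- list(
    geometry = list(
      size = 30L,
      item_row = 10,
      item_cols = c(7.5, 15.5, 23.5),
      r_small = 2,
      r_large = 3,
      margin = 6
    ),
    palette = list(
      background = c(0, 0, 0),
      target = c(1, 0, 0),
      distractor = c(0, 1, 0)
    ),
    levels = c(t = 5.0, T = 4.8, d = 4.6, D = 4.4),
    factors = c(dd = 0.125, Dd = 0.1, DD = 0.075),
    competition = list(tau = 20, h = -1, beta = 1, u0 = 0,
                       A = 1, B = 7, C = 0.7, D = -4),
    tl = list(tau = 20, h = -1, beta = 4,
              c_exc = 3, s_exc = 7.5, c_inh = 1, s_inh = 15, g_inh = 0,
              input_gain = 5),
    disp = list(tau = 30, h = -5, beta = 4,
                c_exc = 3, s_exc = 5.5, c_inh = 0, s_inh = 0, g_inh = -0.01,
                q_c = 0.005, q_s = 1,
                input_gain = 2),
    vel = list(tau = 30, h = -0.2, beta = 4,
               c_exc = 3, s_exc = 5.5, c_inh = 1, s_inh = 10, g_inh = -0.005,
               q_c = 0.005, q_s = 1,
               kick_amp = 2, kick_sigma = 3,
               move_threshold = 0.5,
               input_gain = 1, relay_gain = 8),
    motor = list(gain = 0.01, dt = 1,
                 loc_width = 1.5, loc_size_exp = 0.14, hand_width = 1.5,
                 onset_steps_per_unit = 640,
                 readout_sat = 3,
                 start = c(22, 15.5)),
    wta = list(f_win = 0.9, lead = 0.5, hold = 5),
    vision = list(binarize_tol = 0.1, size_tol = 2, area_split = 21),
    noise_sd = 0.005,
    dt = 1,
    max_steps = 500L,
    arrive_tol = 1.5,
    n_sets = 25L,
    seed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(!nzchar(names(dots))))
      stop("all overrides must be named")
    if (anyDuplicated(names(dots)))
      stop("duplicated config entries: ",
           paste(unique(names(dots)[duplicated(names(dots))]),
                 collapse = ", "))
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
      stop("unknown config entries: ", paste(bad, collapse = ", "))
    for (nm in names(dots)) {
      if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
        unknown <- setdiff(names(dots[[nm]]), names(cfg[[nm]]))
        if (length(unknown))
          stop("unknown fields in '", nm, "': ",
               paste(unknown, collapse = ", "))
        cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
      } else {
        cfg[[nm]] <- dots[[nm]]
      }
    }
  }
  validate_config(cfg)
  structure(cfg, class = "crt_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$geometry$size >= 10,
    length(cfg$geometry$item_cols) == 3,
    cfg$geometry$r_large > cfg$geometry$r_small,
    all(c("t", "T", "d", "D") %in% names(cfg$levels)),
    all(c("dd", "Dd", "DD") %in% names(cfg$factors)),
    all(cfg$factors >= 0),
    cfg$noise_sd >= 0,
    cfg$n_sets >= 1,
    cfg$max_steps >= 1,
    cfg$motor$gain > 0
  )
  # the WTA regime needs global inhibition
  if (cfg$competition$D >= 0)
    warning("competition global coefficient D is non-negative; ",
            "winner-takes-all behaviour is not guaranteed")
  invisible(cfg)
}

#' @export
print.crt_config <- function(x, ...) {
  cat("Choice-reaching simulation config\n")
  cat(sprintf("  lattice %dx%d, items row %g at cols {%s}, radii %g/%g px\n",
              x$geometry$size, x$geometry$size, x$geometry$item_row,
              paste(x$geometry$item_cols, collapse = ", "),
              x$geometry$r_small, x$geometry$r_large))
  cat(sprintf("  saliency levels: t=%.1f T=%.1f d=%.1f D=%.1f\n",
              x$levels[["t"]], x$levels[["T"]], x$levels[["d"]],
              x$levels[["D"]]))
  cat(sprintf("  onset factors:   dd=%g Dd=%g DD=%g (%g steps per unit)\n",
              x$factors[["dd"]], x$factors[["Dd"]], x$factors[["DD"]],
              x$motor$onset_steps_per_unit))
  cat(sprintf("  noise sd %g, max %d steps, %d set(s), seed %d\n",
              x$noise_sd, x$max_steps, x$n_sets, x$seed))
  invisible(x)
}
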