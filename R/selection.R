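#' One Euler step of the saliency competition nodes
#'
#' The three nodes (one per display item) obey
#' \deqn{\tau \dot u_i = -A u_i + B f(u_i) + C I_i + D \sum_j f(u_j) + h}
#' with the logistic output \code{\link{field_sigmoid}}. The global term
#' sums over all nodes including the node itself; self-excitation is
#' carried separately by B. With the default parameters (tau 20, h -1,
#' beta 1, A 1, B 7, C 0.7, D -4) the symmetric state is unstable and the
#' network implements winner-takes-all over the inputs.
#'
#' @param u activation vector (3 nodes).
#' @param inputs input vector (the saliency levels).
#' @param params competition parameter list (see \code{crt_config()}).
#' @param dt Euler time step (default 1).
#' @param noise pre-drawn additive noise vector (or 0).
#' @return Updated activation vector.
#' @export
step_competition <- function(u, inputs, params, dt = 1, noise = 0) {
  f <- field_sigmoid(u, params$beta, params$u0)
  un <- u + (dt / params$tau) *
    (-params$A * u + params$B * f + params$C * inputs +
       params$D * sum(f) + params$h) + noise
  if (!all(is.finite(un)))
    stop("competition node activation diverged (non-finite values)")
  un
}

#' Run the winner-takes-all saliency competition to selection
#'
#' Integrates the three competition nodes from rest until one node's
#' output satisfies the win criterion (output above \code{f_win} and
#' leading the runner-up by at least \code{lead}, held for \code{hold}
#' consecutive steps). With noise off and untied inputs the winner is
#' always \code{which.max(inputs)}; exact ties are reported as ties,
#' never broken silently.
#'
#' @param inputs length-3 saliency levels.
#' @param params competition parameters.
#' @param max_steps step budget before declaring non-convergence.
#' @param criterion list(f_win, lead, hold).
#' @param dt Euler time step.
#' @param noise_sd noise standard deviation (0 = deterministic).
#' @return List: \code{winner} (index, or NA on tie), \code{tie},
#'   \code{steps}, \code{course} (steps x 3 matrix of outputs f(u)).
#' @export
run_wta <- function(inputs, params = crt_config()$competition,
                    max_steps = 2000, criterion = crt_config()$wta,
                    dt = 1, noise_sd = 0) {
  stopifnot(length(inputs) == 3)
  u <- rep(params$h, 3)
  streak <- 0L
  leader <- NA_integer_
  nsteps <- ceiling(max_steps / dt)
  course <- matrix(NA_real_, nsteps, 3)
  for (t in seq_len(nsteps)) {
    noise <- if (noise_sd > 0) stats::rnorm(3, 0, noise_sd) else 0
    u <- step_competition(u, inputs, params, dt, noise)
    f <- field_sigmoid(u, params$beta, params$u0)
    course[t, ] <- f
    ord <- order(f, decreasing = TRUE)
    ok <- f[ord[1]] > criterion$f_win &&
      (f[ord[1]] - f[ord[2]]) > criterion$lead
    if (ok && identical(ord[1], leader)) streak <- streak + 1L
    else if (ok) { leader <- ord[1]; streak <- 1L }
    else { leader <- NA_integer_; streak <- 0L }
    if (streak >= criterion$hold)
      return(list(winner = leader, tie = FALSE, steps = t,
                  course = course[seq_len(t), , drop = FALSE]))
  }
  # no winner: distinguish a symmetric stand-off (tie) from slow dynamics
  f <- course[nsteps, ]
  tie <- (max(f) - sort(f, decreasing = TRUE)[2]) < 1e-9
  if (tie)
    return(list(winner = NA_integer_, tie = TRUE, steps = nsteps,
                course = course))
  stop("no convergence: competition produced no winner within max_steps")
}

#' Spatial location maps for the display items
#'
#' One unit-peak Gaussian per item, centred at its centroid; these maps,
#' weighted by the competition node outputs and summed, form the input to
#' the target location field. By default the Gaussian width scales with
#' the item's radius (width applies to an item of \code{ref_radius}), so
#' a large item casts a spatially larger blob -- the carrier of
#' field-level proximity grouping between neighbouring items.
#'
#' @param items item data frame (needs centroid_row/centroid_col; with
#'   \code{scale_with_size} also area).
#' @param width Gaussian width (px) for an item of radius
#'   \code{ref_radius}.
#' @param size lattice side.
#' @param scale_with_size scale each width by the item's equivalent
#'   radius sqrt(area/pi) relative to \code{ref_radius}.
#' @param ref_radius reference radius (px) at which the width equals
#'   \code{width}.
#' @param size_exp exponent of the radius scaling (1 = proportional,
#'   0 = no scaling); sub-linear values temper the spatial advantage of
#'   large items.
#' @return List of three matrices (left, middle, right item).
#' @export
location_maps <- function(items, width = crt_config()$motor$loc_width,
                          size = crt_config()$geometry$size,
                          scale_with_size = TRUE, ref_radius = 2,
                          size_exp = crt_config()$motor$loc_size_exp) {
  w <- rep(width, nrow(items))
  if (scale_with_size && "area" %in% names(items))
    w <- width * (sqrt(items$area / pi) / ref_radius)^size_exp
  lapply(seq_len(nrow(items)), function(k)
    gaussian_blob(c(items$centroid_row[k], items$centroid_col[k]),
                  w[k], size))
}

#' Input map to the target location field
#'
#' Weighted sum of the three spatial location maps, weights being the
#' current competition node outputs f(u). Early in a trial all items are
#' represented; after the competition resolves only the winner's blob
#' carries appreciable weight.
#'
#' @param node_outputs f(u) per node (length 3).
#' @param maps list of location maps from \code{\link{location_maps}}.
#' @param gain overall input scaling into the field.
#' @return Matrix input map.
#' @export
target_field_input <- function(node_outputs, maps, gain = 1) {
  stopifnot(length(node_outputs) == length(maps))
  out <- matrix(0, nrow(maps[[1]]), ncol(maps[[1]]))
  for (k in seq_along(maps)) out <- out + node_outputs[k] * maps[[k]]
  gain * out
}

#' One Euler step of the target location field
#'
#' Amari field with local excitation (c 3, sigma 7.5), surround
#' inhibition (c 1, sigma 15) and no global term; resting level -1,
#' output gain beta 4.
#'
#' @param u field matrix.
#' @param input input map (same size).
#' @param fp field parameter list (\code{crt_config()$tl}).
#' @param ker precomputed kernel set (see \code{make_kernel}).
#' @param dt time step.
#' @param noise additive noise matrix or 0.
#' @return Updated field matrix.
#' @export
step_target_field <- function(u, input, fp = crt_config()$tl,
                              ker = NULL, dt = 1, noise = 0) {
  if (is.null(ker))
    ker <- make_kernel(fp$c_exc, fp$s_exc, fp$c_inh, fp$s_inh, fp$g_inh,
                       nrow(u))
  f <- field_sigmoid(u, fp$beta)
  field_step(u, input, field_interaction(f, ker), fp$h, fp$tau, dt, noise)
}
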