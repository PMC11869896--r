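#' Hand map: a unit-peak Gaussian at the current hand position
#'
#' @param position continuous (row, col) of the end effector.
#' @param width Gaussian width (px).
#' @param size lattice side.
#' @return size x size matrix, maximum at \code{position}.
#' @export
hand_map <- function(position, width = crt_config()$motor$hand_width,
                     size = crt_config()$geometry$size) {
  stopifnot(all(position >= 1), all(position <= size))
  gaussian_blob(position, width, size)
}

#' Hand-target displacement drive
#'
#' Cross-correlates the (continuous) hand Gaussian with the thresholded
#' target-field output. The result lives on a displacement lattice whose
#' centre represents zero hand-to-target displacement: a target blob
#' offset (dr, dc) from the hand produces a peak offset (dr, dc) from the
#' map centre. Computed separably as A \%*\% fT \%*\% t(B) with
#' per-dimension Gaussian operators, which implicitly zero-pads off-lattice
#' displacements.
#'
#' @param hand_pos continuous hand (row, col).
#' @param target_output matrix f(T_loc), the target field output.
#' @param width hand Gaussian width.
#' @param gain input scaling into the displacement field.
#' @return Displacement-space input matrix (same size as the field).
#' @export
displacement_input <- function(hand_pos, target_output,
                               width = crt_config()$motor$hand_width,
                               gain = 1) {
  n <- nrow(target_output)
  c0 <- (n + 1) / 2
  idx <- seq_len(n)
  # A[i, r] = exp(-((r - hand_r) - (i - c0))^2 / (2 w^2)); likewise B.
  A <- exp(-outer(idx - c0 + hand_pos[1], idx, function(a, r)
    (r - a)^2) / (2 * width^2))
  B <- exp(-outer(idx - c0 + hand_pos[2], idx, function(a, cc)
    (cc - a)^2) / (2 * width^2))
  gain * (A %*% target_output %*% t(B))
}

#' One Euler step of the hand-target displacement field
#'
#' The hand-target difference map: tau 30, h -5, beta 4; self
#' kernel c_exc 3, sigma 5.5 with weak global inhibition g_inh -0.01; a
#' tiny proprioceptive kernel (c 0.005, sigma 1) feeds the hand lattice in.
#'
#' @param u field matrix.
#' @param input displacement drive from \code{\link{displacement_input}}.
#' @param hand_lattice current hand map (proprioceptive feedback), or NULL.
#' @param fp parameter list (\code{crt_config()$disp}).
#' @param ker,qker precomputed kernels (built from fp when NULL).
#' @param dt time step.
#' @param noise additive noise matrix or 0.
#' @return Updated field matrix.
#' @export
step_displacement_field <- function(u, input, hand_lattice = NULL,
                                    fp = crt_config()$disp, ker = NULL,
                                    qker = NULL, dt = 1, noise = 0) {
  n <- nrow(u)
  if (is.null(ker))
    ker <- make_kernel(fp$c_exc, fp$s_exc, fp$c_inh, fp$s_inh, fp$g_inh, n)
  f <- field_sigmoid(u, fp$beta)
  inter <- field_interaction(f, ker)
  drive <- input
  if (!is.null(hand_lattice)) {
    if (is.null(qker)) qker <- kernel_matrix(fp$q_s, n)
    drive <- drive + conv_gauss(hand_lattice, qker, fp$q_c)
  }
  field_step(u, drive, inter, fp$h, fp$tau, dt, noise)
}

#' Movement-onset gate from the proximity scaling factor
#'
#' The proximity information of the distractor pair delays movement onset:
#' the velocity drive is gated off for the first
#' \code{round(steps_per_unit * s_prox)} steps of the trial and fully open
#' afterwards. A zero factor opens the gate from the first step; the gate
#' is monotone non-decreasing in time and always opens eventually.
#'
#' @param s_prox proximity scaling factor (>= 0).
#' @param t trial step (1-based).
#' @param steps_per_unit onset delay per unit scaling factor (steps).
#' @return Gate multiplier, 0 or 1.
#' @export
onset_gate <- function(s_prox, t,
                       steps_per_unit =
                         crt_config()$motor$onset_steps_per_unit) {
  stopifnot(s_prox >= 0)
  as.numeric(t > round(steps_per_unit * s_prox))
}

#' Input to the first velocity layer
#'
#' Displacement-field activation plus a centre-anchored Gaussian kick that
#' seeds activation, all modulated by the onset gate:
#' I = gate * (D + Amp * exp(-|x - centre|^2 / (2 sigma^2))).
#'
#' @param disp_lattice displacement field activation matrix.
#' @param kick precomputed kick matrix (unit peak at the map centre); if
#'   NULL it is built from \code{amp}/\code{sigma}.
#' @param amp kick amplitude.
#' @param sigma kick width (px).
#' @param gate onset gate multiplier in [0, 1].
#' @return Input matrix for the Vel1 layer.
#' @export
velocity_input <- function(disp_lattice, kick = NULL,
                           amp = crt_config()$vel$kick_amp,
                           sigma = crt_config()$vel$kick_sigma,
                           gate = 1) {
  n <- nrow(disp_lattice)
  if (is.null(kick))
    kick <- gaussian_blob(c((n + 1) / 2, (n + 1) / 2), sigma, n)
  gate * (disp_lattice + amp * kick)
}

#' One Euler step of the two-layer velocity field
#'
#' Layer Vel1 receives the gated displacement drive plus local excitation
#' of its own output and surround/global inhibition; layer Vel2 is the
#' stabilising layer, driven by local excitation of Vel1's output with
#' surround inhibition also taken from Vel1. Kernels: c_exc 3 sigma 5.5,
#' c_inh 1 sigma 10, g_inh -0.005; tau 30, h -0.2, beta 4.
#'
#' @param v list(v1, v2) of field matrices.
#' @param input_v1 input to Vel1 from \code{\link{velocity_input}}.
#' @param hand_lattice hand map for the weak proprioceptive kernel, or NULL.
#' @param fp parameter list (\code{crt_config()$vel}).
#' @param ker,qker precomputed kernels (built from fp when NULL).
#' @param dt time step.
#' @param noise1,noise2 additive noise matrices (or 0) per layer.
#' @return Updated list(v1, v2).
#' @export
step_velocity_fields <- function(v, input_v1, hand_lattice = NULL,
                                 fp = crt_config()$vel, ker = NULL,
                                 qker = NULL, dt = 1,
                                 noise1 = 0, noise2 = 0) {
  n <- nrow(v$v1)
  if (is.null(ker))
    ker <- make_kernel(fp$c_exc, fp$s_exc, fp$c_inh, fp$s_inh, fp$g_inh, n)
  f1 <- field_sigmoid(v$v1, fp$beta)
  f2 <- field_sigmoid(v$v2, fp$beta)
  drive1 <- input_v1
  if (!is.null(hand_lattice)) {
    if (is.null(qker)) qker <- kernel_matrix(fp$q_s, n)
    drive1 <- drive1 + conv_gauss(hand_lattice, qker, fp$q_c)
  }
  inh1 <- conv_gauss(f1, ker$Kinh, ker$c_inh) - ker$g_inh * sum(f1)
  exc1 <- conv_gauss(f1, ker$Kexc, ker$c_exc)
  v1 <- field_step(v$v1, drive1, exc1 - inh1, fp$h, fp$tau, dt, noise1)
  # Vel2: the whole excitation/inhibition projection is relayed from Vel1,
  # scaled by the inter-layer coupling strength; at rest the projection is
  # net inhibitory, keeping the readout layer below the movement threshold.
  rg <- if (is.null(fp$relay_gain)) 1 else fp$relay_gain
  v2 <- field_step(v$v2, 0, rg * (exc1 - inh1), fp$h, fp$tau, dt, noise2)
  list(v1 = v1, v2 = v2)
}

#' Velocity readout: move the hand from the stabilised velocity blob
#'
#' If the peak output of the readout layer is at or below the movement
#' threshold the hand stays put (the threshold keeps random noise from
#' moving the hand). Otherwise the supra-threshold output mass is taken,
#' its activation-weighted centroid located, and the centroid's offset
#' from the map centre -- the commanded velocity vector -- scaled by
#' \code{gain * dt} and added to the hand position. The commanded speed is
#' additionally scaled by the saturating blob mass
#' \code{min(mass / readout_sat, 1)}, so a barely supra-threshold blob
#' moves the hand slowly and a fully formed blob at offset k moves it by
#' \code{gain * dt * k} exactly. The position is clamped to the workspace.
#'
#' @param v2 readout layer activation matrix.
#' @param hand_pos current hand (row, col).
#' @param fp velocity parameter list (for beta and move_threshold).
#' @param gain velocity gain (px/step per px of blob offset).
#' @param dt time step.
#' @param readout_sat blob mass at which the readout saturates.
#' @param readout_floor output level subtracted before taking the
#'   activation centroid; activation below it carries no vote. Defaults
#'   to the layer's resting output (background-corrected centroid), so
#'   sub-selection blobs still deflect the commanded direction while the
#'   0.5 peak threshold alone decides whether the hand moves at all.
#' @return List: \code{position} (new hand), \code{speed} (px moved),
#'   \code{moved} (logical), \code{peak} (readout peak output).
#' @export
readout_and_move <- function(v2, hand_pos, fp = crt_config()$vel,
                             gain = crt_config()$motor$gain, dt = 1,
                             readout_sat = crt_config()$motor$readout_sat,
                             readout_floor = NULL) {
  n <- nrow(v2)
  c0 <- (n + 1) / 2
  f <- field_sigmoid(v2, fp$beta)
  peak <- max(f)
  if (peak <= fp$move_threshold)
    return(list(position = hand_pos, speed = 0, moved = FALSE, peak = peak))
  if (is.null(readout_floor))
    readout_floor <- field_sigmoid(fp$h, fp$beta)
  w <- pmax(f - readout_floor, 0)
  mass <- sum(w)
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  centroid <- c(sum(w * rows), sum(w * cols)) / mass
  step_vec <- gain * dt * (centroid - c0) * min(mass / readout_sat, 1)
  newpos <- pmin(pmax(hand_pos + step_vec, 1), n)
  list(position = newpos, speed = sqrt(sum((newpos - hand_pos)^2)),
       moved = TRUE, peak = peak)
}
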