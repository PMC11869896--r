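#' Logistic output function of a dynamic neural field
#'
#' The rate-to-output nonlinearity shared by the saliency competition nodes
#' and all two-dimensional fields. It is the increasing logistic
#' \deqn{f(u) = 1 / (1 + e^{-\beta (u - u_0)})}
#' so that higher activation always means stronger output; \code{f(u0) = 0.5}.
#'
#' @param u activation (scalar, vector or matrix).
#' @param beta sigmoid gain (steepness), dimensionless.
#' @param u0 sigmoid midpoint; defaults to 0.
#' @return Output in (0, 1), same shape as \code{u}.
#' @examples
#' field_sigmoid(0)           # 0.5
#' field_sigmoid(2, beta = 1) # ~0.8808
#' @export
field_sigmoid <- function(u, beta = 1, u0 = 0) {
  1 / (1 + exp(-beta * (u - u0)))
}

#' Unit-peak isotropic Gaussian on a lattice
#'
#' @param centre numeric length-2 (row, col), continuous coordinates allowed.
#' @param width Gaussian width sigma in pixels.
#' @param size lattice side length.
#' @return \code{size x size} matrix with maximum 1 attained at the centre.
#' @export
gaussian_blob <- function(centre, width, size) {
  stopifnot(length(centre) == 2, width > 0)
  gr <- exp(-((seq_len(size) - centre[1])^2) / (2 * width^2))
  gc <- exp(-((seq_len(size) - centre[2])^2) / (2 * width^2))
  outer(gr, gc)
}

## One-dimensional convolution operator matrix for an isotropic Gaussian
## kernel slice exp(-d^2/(2 sigma^2)) / (sigma sqrt(2 pi)).  Lattice borders
## are zero-padded (indices outside the lattice contribute nothing), which
## the Toeplitz form encodes implicitly.
kernel_matrix <- function(sigma, size) {
  if (sigma <= 0) return(matrix(0, size, size))
  idx <- seq_len(size)
  d <- outer(idx, idx, "-")
  exp(-d^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
}

## Separable 2-D convolution: kernel w(x) = c * N(sigma) (x) N(sigma),
## total kernel mass c.  K is the per-dimension operator from
## kernel_matrix(); the full convolution is c * K %*% X %*% K because the
## kernel factorises over rows and columns.
conv_gauss <- function(X, K, c) {
  if (c == 0) return(matrix(0, nrow(X), ncol(X)))
  c * (K %*% X %*% K)
}

## Lateral interaction of a field: local excitation minus surround
## inhibition plus a global (space-free) inhibition term g_inh * sum(f).
## `ker` is a list with precomputed operators Kexc/Kinh and strengths.
field_interaction <- function(f, ker) {
  out <- conv_gauss(f, ker$Kexc, ker$c_exc)
  if (ker$c_inh != 0) out <- out - conv_gauss(f, ker$Kinh, ker$c_inh)
  if (ker$g_inh != 0) out <- out + ker$g_inh * sum(f)
  out
}

## One explicit Euler step of a 2-D field obeying
##   tau * du/dt = -u + input + interaction(f(u)) + h  (+ noise)
## `noise` is a pre-drawn matrix (or 0) added directly to the update,
## so that all randomness flows through the caller's RNG stream.
field_step <- function(u, input, inter, h, tau, dt, noise = 0) {
  un <- u + (dt / tau) * (-u + input + inter + h) + noise
  if (!all(is.finite(un))) stop("field activation diverged (non-finite values)")
  un
}

## Build the precomputed per-field kernel set from config entries.
make_kernel <- function(c_exc, s_exc, c_inh, s_inh, g_inh, size) {
  list(
    c_exc = c_exc, c_inh = c_inh, g_inh = g_inh,
    Kexc = kernel_matrix(s_exc, size),
    Kinh = kernel_matrix(s_inh, size)
  )
}
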