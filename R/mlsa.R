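#' Mel-cepstrum to MLSA filter coefficients
#'
#' Converts mel-cepstral coefficients `c(0..M)` to the coefficients `b(0..M)`
#' of the MLSA digital filter basis via the standard backward recursion
#' `b(M) = c(M)`, `b(m) = c(m) - alpha * b(m+1)`. The transform is linear and
#' invertible ([filter_coeffs_to_mel()]); at `alpha = 0` it is the identity.
#'
#' @param cep a [mel_cepstrogram], or a numeric matrix/vector of coefficients.
#' @param alpha warp coefficient; taken from `cep` when it is a
#'   [mel_cepstrogram].
#' @return Matrix (or vector) of filter coefficients, same shape as input.
#' @export
mel_to_filter_coeffs <- function(cep, alpha = NULL) {
  if (inherits(cep, "mel_cepstrogram")) {
    if (is.null(alpha)) alpha <- cep$alpha
    cmat <- cep$frames
  } else cmat <- cep
  if (is.null(alpha)) stop("alpha required for plain matrix input")
  vec <- is.null(dim(cmat))
  if (vec) cmat <- matrix(cmat, nrow = 1)
  M1 <- ncol(cmat)
  b <- cmat
  if (M1 > 1) for (m in (M1 - 1):1) b[, m] <- cmat[, m] - alpha * b[, m + 1]
  if (vec) drop(b) else b
}

#' Inverse of [mel_to_filter_coeffs()]
#' @param b filter-coefficient matrix or vector.
#' @param alpha warp coefficient.
#' @return Mel-cepstral coefficients, same shape as input.
#' @export
filter_coeffs_to_mel <- function(b, alpha) {
  vec <- is.null(dim(b))
  if (vec) b <- matrix(b, nrow = 1)
  M1 <- ncol(b)
  cmat <- b
  if (M1 > 1) for (m in (M1 - 1):1) cmat[, m] <- b[, m] + alpha * b[, m + 1]
  if (vec) drop(cmat) else cmat
}

# Order-L Pade coefficients A_l of exp(w) ~ P(w)/P(-w),
# A_l = (2L-l)! L! / ((2L)! l! (L-l)!)
pade_coefficients <- function(order = 5) {
  l <- seq_len(order)
  exp(lfactorial(2 * order - l) + lfactorial(order) -
        lfactorial(2 * order) - lfactorial(l) - lfactorial(order - l))
}

# Fresh MLSA filter state for M+1 coefficients and Pade order L.
mlsa_state <- function(n_coef, pade_order = 5) {
  numeric(2 * pade_order + pade_order * n_coef)
}

# One hop of MLSA filtering (forward or inverse) with per-sample linear
# coefficient interpolation. `state` is modified by reference (C++ side);
# callers own the state vector.
mlsa_frame <- function(x, b_from, b_to, alpha, pade, state, inverse = FALSE) {
  mlsa_step_cpp(x, b_from, b_to, alpha, pade, inverse, state)
}

# Shared driver for forward synthesis and inverse filtering: chop the signal
# into hops paired with cepstral frames, interpolate coefficients from the
# previous frame's values (causal), run the C++ filter per hop.
mlsa_run <- function(x, cep, inverse, pade_order = 5) {
  stopifnot(inherits(cep, "mel_cepstrogram"))
  hop <- cep$hop
  Tn <- nrow(cep$frames)
  n <- length(x)
  if (n > Tn * hop || n <= (Tn - 1) * hop)
    stop("signal length ", n, " does not match ", Tn, " frames of hop ", hop)
  B <- mel_to_filter_coeffs(cep)
  pade <- pade_coefficients(pade_order)
  state <- mlsa_state(ncol(B), pade_order)
  y <- numeric(n)
  b_prev <- B[1, ]
  for (t in seq_len(Tn)) {
    i0 <- (t - 1) * hop + 1
    i1 <- min(t * hop, n)
    if (i0 > i1) break
    y[i0:i1] <- mlsa_frame(x[i0:i1], b_prev, B[t, ], cep$alpha, pade,
                           state, inverse = inverse)
    b_prev <- B[t, ]
  }
  y
}

#' MLSA synthesis filtering
#'
#' Drives the Mel Log Spectrum Approximation filter with an excitation
#' signal. The filter realizes `exp(sum_m c_alpha(m) ztilde^-m)` per frame
#' through two cascaded order-5 Pade approximations of the exponential
#' (gain + first coefficient + remaining coefficients); filter coefficients
#' are linearly interpolated per sample from the previous frame's values to
#' the current frame's, which keeps the filter causal in the frame stream.
#'
#' @param excitation an [excitation] object, [waveform], or numeric vector of
#'   source samples; its length must lie in `((T-1)*hop, T*hop]` for the
#'   cepstrogram's T frames.
#' @param cep a [mel_cepstrogram].
#' @param pade_order order of the Pade approximation of `exp` (default 5).
#' @return A [waveform] of the same length as the excitation.
#' @export
mlsa_synthesize <- function(excitation, cep, pade_order = 5) {
  x <- excitation_samples(excitation)
  waveform(mlsa_run(x, cep, inverse = FALSE, pade_order = pade_order),
           rate = cep$rate)
}

#' MLSA inverse filtering
#'
#' Applies the exact rational inverse of the synthesis filter (same Pade
#' structure with negated coefficients, stages in reverse order), recovering
#' the excitation/residual from a waveform given its mel-cepstra. Feeding the
#' residual back through [mlsa_synthesize()] with the same cepstra
#' reconstructs the input.
#'
#' @param wave a [waveform] (or numeric vector).
#' @param cep a [mel_cepstrogram] describing the wave.
#' @param pade_order order of the Pade approximation (default 5).
#' @return A [waveform] holding the residual.
#' @export
mlsa_inverse_filter <- function(wave, cep, pade_order = 5) {
  wave <- as_waveform(wave, rate = cep$rate)
  waveform(mlsa_run(wave$samples, cep, inverse = TRUE,
                    pade_order = pade_order), rate = cep$rate)
}

# Analytic warped log-amplitude spectrum exp(sum c_m cos(m wt(omega))) of a
# single cepstral frame on an FFT grid; used for spectral verification.
mlsa_model_spectrum <- function(c_frame, alpha, nfft = 4096) {
  omega <- 2 * pi * (0:(nfft / 2)) / nfft
  wo <- warp_omega(omega, alpha)
  m <- seq_along(c_frame) - 1
  exp(drop(outer(wo, m, function(w, mm) cos(mm * w)) %*% c_frame))
}
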