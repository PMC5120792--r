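#' Mel-cepstrogram objects
#'
#' A mel-cepstrogram is a T x M matrix of mel-cepstral coefficients
#' `c_alpha(m)`, m = 0..M-1, one row per analysis frame. Coefficient 0
#' carries the log gain; the warp coefficient `alpha` bends the frequency
#' axis towards a mel-like scale (0.455 approximates mel at 22,050 Hz).
#'
#' @param frames numeric T x M matrix of coefficients.
#' @param alpha frequency-warp coefficient in \[0, 1).
#' @param rate audio sampling rate in Hz.
#' @param hop frame hop in samples.
#' @param window analysis window length in samples.
#' @return An object of class `mel_cepstrogram`.
#' @export
mel_cepstrogram <- function(frames, alpha = 0.455, rate = 22050,
                            hop = 220, window = 512) {
  frames <- as.matrix(frames)
  if (!all(is.finite(frames))) stop("mel-cepstral coefficients must be finite")
  if (ncol(frames) < 1L) stop("need at least one coefficient")
  if (alpha < 0 || alpha >= 1) stop("alpha must be in [0, 1)")
  structure(list(frames = frames, alpha = alpha, rate = rate, hop = hop,
                 window = window, frame_rate = rate / hop),
            class = "mel_cepstrogram")
}

#' @export
print.mel_cepstrogram <- function(x, ...) {
  cat(sprintf("<mel_cepstrogram: %d frames x %d coefs, alpha=%g, hop=%d @ %g Hz>\n",
              nrow(x$frames), ncol(x$frames), x$alpha, x$hop, x$rate))
  invisible(x)
}

# Blackman window (periodic form not needed; symmetric, as in spectral analysis)
blackman_window <- function(n) {
  k <- seq_len(n) - 1
  0.42 - 0.5 * cos(2 * pi * k / (n - 1)) + 0.08 * cos(4 * pi * k / (n - 1))
}

# Warped frequency axis: omega_tilde(omega) for first-order all-pass warp
warp_omega <- function(omega, alpha) {
  omega + 2 * atan2(alpha * sin(omega), 1 - alpha * cos(omega))
}

# Design matrix Phi[k, m+1] = cos(m * omega_tilde_k) on the half FFT grid,
# with trapezoid weights (endpoints half weight), for the spectral-matching
# criterion and for evaluating model log spectra.
warped_basis <- function(nfft, alpha, n_coef) {
  omega <- 2 * pi * (0:(nfft / 2)) / nfft
  wo <- warp_omega(omega, alpha)
  Phi <- outer(wo, 0:(n_coef - 1), function(w, m) cos(m * w))
  w <- rep(1, length(omega))
  w[c(1, length(omega))] <- 0.5
  list(Phi = Phi, weights = w)
}

# One frame of mel-cepstral analysis: minimize the spectral-matching
# criterion E(c) = mean_k[ exp(R_k) - R_k - 1 ],  R_k = log I_k - 2 Phi c,
# by Newton iteration (the Hessian is positive definite everywhere).
mcep_frame <- function(log_periodogram, basis, max_iter = 30, tol = 1e-6) {
  Phi <- basis$Phi
  w <- basis$weights
  W <- sum(w)
  crit <- function(R) sum(w * (exp(R) - R - 1)) / W
  # initial estimate: weighted least squares of log I / 2 on the warped basis
  A <- Phi * sqrt(w)
  c_hat <- qr.solve(crossprod(A), crossprod(A, (log_periodogram / 2) * sqrt(w)))
  c_hat <- drop(c_hat)
  R <- log_periodogram - 2 * drop(Phi %*% c_hat)
  e <- crit(R)
  for (it in seq_len(max_iter)) {
    u <- w * exp(R)
    g <- -2 * drop(crossprod(Phi, w * (exp(R) - 1))) / W
    H <- 4 * crossprod(Phi * sqrt(u)) / W
    step <- tryCatch(drop(solve(H, g)), error = function(e2) g)
    lam <- 1
    repeat {
      c_new <- c_hat - lam * step
      R_new <- log_periodogram - 2 * drop(Phi %*% c_new)
      e_new <- crit(R_new)
      if (is.finite(e_new) && e_new <= e) break
      lam <- lam / 2
      if (lam < 1e-8) { c_new <- c_hat; R_new <- R; e_new <- e; break }
    }
    dec <- e - e_new
    c_hat <- c_new; R <- R_new; e <- e_new
    if (dec < tol) break
  }
  c_hat
}

#' Mel-cepstral analysis of a waveform
#'
#' Slides a Blackman window over the signal and, for each frame, finds the
#' mel-cepstral coefficients minimizing the log-spectral matching criterion
#' `mean(exp(R) - R - 1)` with `R` the difference between the frame's log
#' periodogram and the model log spectrum on the warped frequency axis.
#' The minimization is a damped Newton iteration; the criterion's Hessian is
#' positive definite so convergence is fast (typically < 10 iterations).
#'
#' @param wave a [waveform] (or numeric vector at `rate`).
#' @param n_coef number of coefficients (default 25: m = 0..24).
#' @param alpha frequency-warp coefficient (default 0.455 for 22,050 Hz).
#' @param window analysis window length in samples (default 512, ~23 ms).
#' @param hop frame hop in samples (default 220, ~10 ms at 22,050 Hz).
#' @param max_iter,tol Newton iteration cap and absolute criterion-decrease
#'   convergence threshold.
#' @return A [mel_cepstrogram] with `floor((n - window)/hop) + 1` frames.
#' @examples
#' w <- waveform(sin(2 * pi * 150 * seq_len(4410) / 22050))
#' cep <- analyze_mel_cepstrum(w)
#' nrow(cep$frames)
#' @export
analyze_mel_cepstrum <- function(wave, n_coef = 25, alpha = 0.455,
                                 window = 512, hop = 220,
                                 max_iter = 30, tol = 1e-6) {
  wave <- as_waveform(wave)
  x <- wave$samples
  n <- length(x)
  if (n < window) stop("signal shorter than one analysis window (",
                       n, " < ", window, ")")
  if (n_coef < 1) stop("n_coef must be >= 1")
  n_frames <- floor((n - window) / hop) + 1
  nfft <- 2^ceiling(log2(window))
  win <- blackman_window(window)
  basis <- warped_basis(nfft, alpha, n_coef)
  half <- 1:(nfft / 2 + 1)

  # frame the signal into a window x T matrix, window and FFT all frames at once
  idx <- outer(seq_len(window), (seq_len(n_frames) - 1) * hop, `+`)
  frames <- matrix(x[idx], nrow = window) * win
  if (nfft > window)
    frames <- rbind(frames, matrix(0, nfft - window, n_frames))
  spec <- mvfft(frames)
  pgram <- abs(spec[half, , drop = FALSE])^2
  floor_val <- pmax(max(pgram) * 1e-10, 1e-20)
  pgram <- pmax(pgram, floor_val)

  out <- matrix(0, n_frames, n_coef)
  for (t in seq_len(n_frames))
    out[t, ] <- mcep_frame(log(pgram[, t]), basis, max_iter, tol)
  mel_cepstrogram(out, alpha = alpha, rate = wave$rate,
                  hop = hop, window = window)
}

#' Serialize a mel-cepstrogram to tab-separated text
#'
#' One frame per row; `#`-prefixed header lines record the analysis
#' settings so the file is self-describing.
#'
#' @param cep a [mel_cepstrogram].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_melcep <- function(cep, path) {
  hdr <- c(sprintf("# emasynth mel-cepstrogram v1"),
           sprintf("# alpha\t%.17g", cep$alpha),
           sprintf("# rate\t%g", cep$rate),
           sprintf("# hop\t%d", as.integer(cep$hop)),
           sprintf("# window\t%d", as.integer(cep$window)))
  body <- apply(cep$frames, 1, function(r) paste(sprintf("%.17g", r),
                                                 collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a mel-cepstrogram written by [write_melcep()]
#' @param path input path.
#' @return A [mel_cepstrogram].
#' @export
read_melcep <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, "\t"), hdr, value = TRUE)
    if (length(ln) != 1) stop("missing header field '", key, "' in ", path)
    as.numeric(strsplit(ln, "\t")[[1]][2])
  }
  body <- lines[!grepl("^#", lines)]
  frames <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  mel_cepstrogram(frames, alpha = getv("alpha"), rate = getv("rate"),
                  hop = getv("hop"), window = getv("window"))
}
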