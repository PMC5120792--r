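#' Fundamental-frequency contours
#'
#' Per-frame fundamental frequency estimates; `f0 = 0` marks unvoiced
#' frames, and the `voiced` flag is `f0 > 0` by construction.
#'
#' @param f0 numeric per-frame f0 (Hz), 0 where unvoiced.
#' @param frame_rate contour frame rate (Hz).
#' @return An object of class `f0_contour`.
#' @export
f0_contour <- function(f0, frame_rate = 100) {
  f0 <- as.numeric(f0)
  if (any(!is.finite(f0)) || any(f0 < 0)) stop("f0 must be finite and >= 0")
  structure(list(f0 = f0, voiced = f0 > 0, frame_rate = frame_rate),
            class = "f0_contour")
}

#' Pitch extraction by frame-wise autocorrelation
#'
#' Estimates one f0 value per analysis frame from the normalized
#' autocorrelation of a window centred on the frame. A frame is voiced when
#' the autocorrelation peak inside the candidate period range exceeds
#' `voicing_threshold` and the frame has non-negligible energy; the peak lag
#' is refined by parabolic interpolation. The frame grid matches
#' [analyze_mel_cepstrum()]'s (same hop, aligned to its analysis window), so
#' contours pair with mel-cepstrograms by index.
#'
#' @param wave a [waveform].
#' @param f0_range two-element vector, candidate f0 range in Hz
#'   (default 50-400).
#' @param hop frame hop in samples (default 220).
#' @param window correlation window length in samples (default 1024; must
#'   exceed two periods of the lowest candidate f0 for a reliable peak).
#' @param align_window the spectral-analysis window the frame grid aligns to
#'   (default 512).
#' @param voicing_threshold normalized autocorrelation peak required to call
#'   a frame voiced (default 0.3).
#' @return An [f0_contour] with `floor((n - align_window)/hop) + 1` frames.
#' @export
extract_pitch <- function(wave, f0_range = c(50, 400), hop = 220,
                          window = 1024, align_window = 512,
                          voicing_threshold = 0.3) {
  wave <- as_waveform(wave)
  x <- wave$samples
  n <- length(x)
  if (n == 0) stop("empty signal")
  rate <- wave$rate
  if (f0_range[1] <= 0 || f0_range[2] >= rate / 2 ||
      f0_range[1] >= f0_range[2])
    stop("f0_range must lie within (0, rate/2)")
  n_frames <- max(1, floor((n - align_window) / hop) + 1)
  lag_min <- max(2, floor(rate / f0_range[2]))
  lag_max <- ceiling(rate / f0_range[1])
  if (lag_max >= window)
    stop("window too short for lowest candidate f0")
  nfft <- 2^ceiling(log2(2 * window))
  f0 <- numeric(n_frames)
  for (t in seq_len(n_frames)) {
    center <- (t - 1) * hop + align_window / 2
    i0 <- max(1, round(center - window / 2))
    seg <- x[i0:min(n, i0 + window - 1)]
    seg <- seg - mean(seg)
    if (sqrt(mean(seg^2)) < 1e-8) next  # silence: unvoiced
    r <- Re(fft(Mod(fft(c(seg, numeric(nfft - length(seg)))))^2,
                inverse = TRUE))
    if (r[1] <= 0) next
    r <- r / r[1]
    lags <- lag_min:min(lag_max, length(seg) - 1)
    peak <- which.max(r[lags + 1])
    lag <- lags[peak]
    if (r[lag + 1] < voicing_threshold) next
    # parabolic refinement around the peak
    if (lag > lag_min && lag < lag_max) {
      y1 <- r[lag]; y2 <- r[lag + 1]; y3 <- r[lag + 2]
      denom <- y1 - 2 * y2 + y3
      delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
      lag <- lag + max(-0.5, min(0.5, delta))
    }
    cand <- rate / lag
    if (cand >= f0_range[1] && cand <= f0_range[2]) f0[t] <- cand
  }
  f0_contour(f0, frame_rate = rate / hop)
}
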