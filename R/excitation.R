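#' Excitation objects
#'
#' The source signal of the source-filter model: a pulse train following a
#' pitch contour plus white noise in unvoiced spans (`pitch_driven`), or a
#' single glottal period tiled end to end, giving a constant artificial
#' pitch for silent-speech use (`fixed_template`).
#'
#' @param samples numeric sample vector at audio rate.
#' @param rate sampling rate (Hz).
#' @param mode `"pitch_driven"` or `"fixed_template"`.
#' @param template the single-period residual used (fixed_template only).
#' @return An object of class `excitation`.
#' @export
excitation <- function(samples, rate, mode = c("pitch_driven", "fixed_template"),
                       template = NULL) {
  mode <- match.arg(mode)
  if (!all(is.finite(samples))) stop("excitation samples must be finite")
  structure(list(samples = as.numeric(samples), rate = rate, mode = mode,
                 template = template), class = "excitation")
}

#' @export
print.excitation <- function(x, ...) {
  cat(sprintf("<excitation (%s): %d samples @ %g Hz>\n",
              x$mode, length(x$samples), x$rate))
  invisible(x)
}

excitation_samples <- function(x) {
  if (inherits(x, "excitation")) x$samples
  else if (inherits(x, "waveform")) x$samples
  else as.numeric(x)
}

#' Build a pitch-driven excitation signal
#'
#' Voiced frames produce a pulse train whose instantaneous period follows
#' the fundamental frequency via phase accumulation (a pulse fires each time
#' the accumulated phase crosses an integer); unvoiced frames produce white
#' Gaussian noise. Pulses have amplitude `sqrt(rate/f0)` so the voiced spans
#' have unit average power, matching the unit-variance noise.
#'
#' @param f0 an [f0_contour] (or numeric per-frame f0 vector, 0 = unvoiced).
#' @param rate audio sampling rate (Hz).
#' @param length output length in samples.
#' @param hop samples per contour frame (default 220).
#' @param seed optional integer seed for the noise segments.
#' @return An [excitation] of mode `pitch_driven`.
#' @export
build_pitch_excitation <- function(f0, rate = 22050, length, hop = 220,
                                   seed = NULL) {
  f0v <- if (inherits(f0, "f0_contour")) f0$f0 else as.numeric(f0)
  if (any(f0v >= rate / 2)) stop("f0 at or above Nyquist")
  if (any(f0v < 0)) stop("negative f0")
  n_frames <- base::length(f0v)
  if (n_frames * hop < length - hop)
    stop("f0 contour does not cover requested length")
  if (!is.null(seed)) set.seed(seed)
  frame_of <- pmin(((seq_len(length) - 1) %/% hop) + 1, n_frames)
  f0s <- f0v[frame_of]
  phase <- cumsum(f0s / rate)
  fired <- floor(phase) > floor(c(0, phase[-length]))
  x <- numeric(length)
  voiced <- f0s > 0
  x[fired & voiced] <- sqrt(rate / f0s[fired & voiced])
  n_unv <- sum(!voiced)
  if (n_unv > 0) x[!voiced] <- rnorm(n_unv)
  excitation(x, rate, "pitch_driven")
}

#' Build a fixed-template excitation signal
#'
#' Tiles a single-period glottal residual end to end (final copy truncated),
#' producing a constantly voiced source with pitch `rate / length(template)`.
#' This is the excitation used in silent-speech mode, where no glottal
#' activity is available.
#'
#' @param template numeric vector holding one glottal period.
#' @param rate audio sampling rate (Hz).
#' @param length output length in samples.
#' @return An [excitation] of mode `fixed_template`.
#' @export
build_template_excitation <- function(template, rate = 22050, length) {
  template <- as.numeric(template)
  if (base::length(template) == 0) stop("empty excitation template")
  reps <- ceiling(length / base::length(template))
  x <- rep(template, reps)[seq_len(length)]
  excitation(x, rate, "fixed_template", template = template)
}

#' Synthetic single-period glottal template
#'
#' One period of a Rosenberg-style glottal flow derivative whose spectrum
#' is then flattened to unit magnitude (phase kept). A residual obtained by
#' inverse filtering a vowel is approximately spectrally flat — the vocal
#' tract envelope has been removed — so the synthetic stand-in is whitened
#' the same way; otherwise the template's own spectral tilt would color
#' every synthesized sound. Unit RMS by construction. Synthetic, not
#' derived from any recording.
#'
#' @param rate sampling rate (Hz).
#' @param f0 desired constant pitch (Hz); the period is `round(rate/f0)`.
#' @param open_quotient fraction of the period the glottis is open.
#' @return Numeric vector of one period.
#' @export
glottal_template <- function(rate = 22050, f0 = 105, open_quotient = 0.6) {
  n <- round(rate / f0)
  t <- seq_len(n) / n
  open <- t <= open_quotient
  g <- numeric(n)
  tp <- t[open] / open_quotient
  g[open] <- sin(pi * tp)^2 * (1 - tp * 0.5)
  d <- c(diff(g), -g[n])  # flow derivative: sharp closure excitation
  # whiten: unit magnitude at every harmonic, glottal phase retained
  tf <- fft(d)
  mag <- Mod(tf)
  tf <- ifelse(mag > 1e-12, tf / mag, 1)
  Re(fft(tf, inverse = TRUE)) / n * sqrt(n)
}
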