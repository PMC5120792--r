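#' Waveform objects
#'
#' A waveform is a mono audio signal: a numeric vector of samples plus a
#' sampling rate in Hz. All vocoder functions consume and produce waveforms.
#'
#' @param samples numeric vector of finite sample amplitudes.
#' @param rate sampling rate in Hz (default 22050, the rate the reference
#'   corpus was recorded at).
#' @return An object of class `waveform` with fields `samples` and `rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 220 * seq_len(2205) / 22050))
#' length(w$samples)
#' @export
waveform <- function(samples, rate = 22050) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("waveform samples must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar")
  structure(list(samples = samples, rate = rate), class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$rate, length(x$samples) / x$rate))
  invisible(x)
}

#' @export
length.waveform <- function(x) length(x$samples)

as_waveform <- function(x, rate = 22050) {
  if (inherits(x, "waveform")) x else waveform(x, rate)
}
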