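# Shared fixtures, all generated in code.

# harmonic vowel-like signal: formant-shaped amplitudes at multiples of f0
harmonic_vowel <- function(f0 = 130, dur = 1, rate = 22050,
                           formants = c(700, 1200), widths = c(400, 500),
                           gains = c(1, 0.6)) {
  n <- round(dur * rate)
  t <- seq_len(n) / rate
  h <- floor(rate / 2 / f0)
  freq <- (1:h) * f0
  amps <- 0.05 + Reduce(`+`, lapply(seq_along(formants), function(i)
    gains[i] * exp(-0.5 * ((freq - formants[i]) / widths[i])^2)))
  x <- rowSums(vapply(1:h, function(k) amps[k] * sin(2 * pi * freq[k] * t),
                      numeric(n)))
  waveform(x / max(abs(x)) * 0.5, rate)
}

# band-limited sawtooth at f0 (additive synthesis, no aliasing)
sawtooth_wave <- function(f0 = 120, dur = 1, rate = 22050) {
  n <- round(dur * rate)
  t <- seq_len(n) / rate
  h <- floor(rate / 2 / f0)
  x <- rowSums(vapply(1:h, function(k) sin(2 * pi * k * f0 * t) / k,
                      numeric(n)))
  waveform(x / max(abs(x)) * 0.5, rate)
}

# constant-coefficient cepstrogram helper
const_cep <- function(c_frame, n_frames, alpha = 0.455, hop = 220) {
  mel_cepstrogram(matrix(rep(c_frame, each = n_frames), n_frames,
                         length(c_frame)), alpha = alpha, hop = hop)
}

# small EMA recording with given coords (T x 27) and optional pose
make_ema <- function(coords, rate = 400, pose = NULL) {
  ema_recording(coords, rate, ema_sensor_order(), reference_pose = pose)
}

# tiny trained-ready linear "network": layers implementing an affine map
linear_dnn <- function(A, b, in_norm = NULL, out_norm = NULL, slope = 0.01) {
  emasynth:::new_dnn_model(list(list(W = A, b = b)), slope, in_norm, out_norm)
}
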