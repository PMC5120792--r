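# Mel-cepstral analysis, MLSA synthesis/inverse filtering, pitch and
# excitation construction.

test_that("analysis framing, defaults and input validation", {
  w <- harmonic_vowel(dur = 1)
  cep <- analyze_mel_cepstrum(w)
  expect_equal(nrow(cep$frames), floor((22050 - 512) / 220) + 1) # 98
  expect_equal(ncol(cep$frames), 25)
  expect_equal(cep$alpha, 0.455)
  expect_error(analyze_mel_cepstrum(waveform(numeric(100))), "shorter")
  expect_error(waveform(c(1, NA)), "finite")
})

test_that("scaling audio by k shifts only the gain coefficient by ln k", {
  w <- harmonic_vowel(dur = 0.25)
  k <- 3.7
  c1 <- analyze_mel_cepstrum(w)$frames
  c2 <- analyze_mel_cepstrum(waveform(k * w$samples))$frames
  expect_lt(max(abs(c2[, 1] - c1[, 1] - log(k))), 1e-3)
  expect_lt(max(abs(c2[, -1] - c1[, -1])), 1e-3)
})

test_that("alpha = 0 analysis matches an independent unwarped-criterion oracle", {
  w <- harmonic_vowel(dur = 0.1)
  got <- analyze_mel_cepstrum(w, n_coef = 12, alpha = 0, tol = 1e-14)$frames
  # oracle: minimize the unwarped log-spectral matching criterion with BFGS
  x <- w$samples
  win <- 0.42 - 0.5 * cos(2 * pi * (0:511) / 511) +
    0.08 * cos(4 * pi * (0:511) / 511)
  n_frames <- floor((length(x) - 512) / 220) + 1
  omega <- 2 * pi * (0:256) / 512
  Phi <- outer(omega, 0:11, function(w_, m) cos(m * w_))
  wt <- c(0.5, rep(1, 255), 0.5)
  for (t in seq_len(n_frames)) {
    frame <- x[(t - 1) * 220 + 1:512] * win
    I <- abs(fft(frame)[1:257])^2
    I <- pmax(I, max(I) * 1e-10)
    logI <- log(I)
    crit <- function(cc) {
      R <- logI - 2 * drop(Phi %*% cc)
      sum(wt * (exp(R) - R - 1)) / sum(wt)
    }
    grad <- function(cc) {
      R <- logI - 2 * drop(Phi %*% cc)
      -2 * drop(crossprod(Phi, wt * (exp(R) - 1))) / sum(wt)
    }
    oracle <- optim(numeric(12), crit, grad, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-16))$par
    expect_lt(max(abs(got[t, ] - oracle)), 1e-6)
  }
})

test_that("mel-to-filter coefficient recursion: identity at alpha 0, pure gain, exact inverse", {
  cc <- c(0.5, rnorm(24, sd = 0.2))
  expect_equal(mel_to_filter_coeffs(cc, alpha = 0), cc)
  g <- mel_to_filter_coeffs(c(1.3, numeric(24)), alpha = 0.455)
  expect_equal(g[1], 1.3) # pure gain exp(1.3): b0 carries it, others zero
  expect_true(all(g[-1] == 0))
  b <- mel_to_filter_coeffs(cc, alpha = 0.455)
  expect_lt(max(abs(filter_coeffs_to_mel(b, 0.455) - cc)), 1e-10)
})

test_that("MLSA pure-gain filter doubles the excitation exactly", {
  set.seed(4)
  cep <- const_cep(c(log(2), numeric(24)), 10)
  x <- rnorm(2200)
  y <- mlsa_synthesize(x, cep)$samples
  expect_lt(max(abs(y - 2 * x)) / 2, 1e-6)
})

test_that("MLSA impulse response matches the analytic warped spectrum within 0.1 dB", {
  set.seed(2)
  cfr <- c(0.3, rnorm(24, sd = 0.15))
  stopifnot(max(abs(cfr)) <= 1)
  cep <- const_cep(cfr, 20)
  h <- mlsa_synthesize(c(1, numeric(20 * 220 - 1)), cep)$samples
  nfft <- 4096
  H <- abs(fft(h[1:nfft])[1:(nfft / 2 + 1)])
  Hm <- emasynth:::mlsa_model_spectrum(cfr, 0.455, nfft)
  sel <- seq_len(round(8000 / 22050 * nfft)) # 0-8 kHz
  expect_lt(max(abs(20 * log10(H[sel]) - 20 * log10(Hm[sel]))), 0.1)
})

test_that("analysis-synthesis round trip on a harmonic vowel stays under 1 dB MCD", {
  w <- harmonic_vowel(f0 = 130, dur = 1)
  cep <- analyze_mel_cepstrum(w)
  f0c <- extract_pitch(w)
  exc <- build_pitch_excitation(f0c, 22050, nrow(cep$frames) * 220, seed = 7)
  cep2 <- analyze_mel_cepstrum(mlsa_synthesize(exc, cep))
  k <- nrow(cep2$frames)
  expect_lt(mel_cepstral_distortion(cep$frames[1:k, ], cep2$frames[1:k, ]), 1)
})

test_that("inverse filtering undoes synthesis and vice versa", {
  set.seed(5)
  cfr <- c(0.2, rnorm(24, sd = 0.15))
  cep <- const_cep(cfr, 12)
  # zero in, zero out
  expect_equal(mlsa_inverse_filter(numeric(12 * 220), cep)$samples,
               numeric(12 * 220))
  # inverse o forward = identity on the excitation
  e <- rnorm(12 * 220)
  y <- mlsa_synthesize(e, cep)$samples
  r <- mlsa_inverse_filter(y, cep)$samples
  expect_lt(sqrt(mean((r - e)^2) / mean(e^2)), 1e-3)
  # forward o inverse = identity on a waveform
  w <- harmonic_vowel(dur = 0.2)
  cepw <- analyze_mel_cepstrum(w)
  n <- nrow(cepw$frames) * 220
  res <- mlsa_inverse_filter(w$samples[1:n], cepw)
  back <- mlsa_synthesize(res, cepw)$samples
  expect_lt(sqrt(mean((back - w$samples[1:n])^2) / mean(w$samples[1:n]^2)),
            1e-3)
})

test_that("the residual of a vowel is quasi-periodic at its f0", {
  w <- harmonic_vowel(f0 = 110, dur = 0.5)
  cep <- analyze_mel_cepstrum(w)
  n <- nrow(cep$frames) * 220
  r <- mlsa_inverse_filter(w$samples[1:n], cep)$samples
  seg <- r[2001:6000] # skip filter warm-up
  ac <- acf(seg, lag.max = 300, plot = FALSE, demean = TRUE)$acf[-1]
  period <- 22050 / 110
  expect_lt(abs(which.max(ac[100:300]) + 99 - period), 2)
})

test_that("pitch extraction: periodic, aperiodic and silent inputs", {
  saw <- sawtooth_wave(f0 = 120, dur = 1)
  p <- extract_pitch(saw)
  expect_true(all(p$voiced))
  expect_gte(median(p$f0), 119)
  expect_lte(median(p$f0), 121)

  set.seed(8)
  noise <- waveform(rnorm(22050) * 0.3)
  pn <- extract_pitch(noise)
  expect_gte(mean(!pn$voiced), 0.9)

  ps <- extract_pitch(waveform(numeric(22050)))
  expect_true(all(!ps$voiced))
  expect_true(all(ps$f0 == 0))
  expect_error(extract_pitch(waveform(numeric(0))), "empty")
})

test_that("pitch-driven excitation: pulse counts, noise spans, determinism", {
  f0 <- f0_contour(rep(100, 101))
  e <- build_pitch_excitation(f0, 22050, 22050, seed = 1)
  expect_equal(length(e$samples), 22050)
  n_pulses <- sum(e$samples > 0.5 * sqrt(22050 / 100))
  expect_lte(abs(n_pulses - 100), 1)

  unv <- build_pitch_excitation(f0_contour(numeric(101)), 22050, 22050,
                                seed = 2)
  expect_equal(sum(unv$samples > 5), 0) # no pulses, just unit noise
  unv2 <- build_pitch_excitation(f0_contour(numeric(101)), 22050, 22050,
                                 seed = 2)
  expect_identical(unv$samples, unv2$samples)
  expect_error(build_pitch_excitation(f0_contour(rep(12000, 101)),
                                      22050, 22050), "Nyquist")
})

test_that("template excitation tiles exactly and synthesizes at the template pitch", {
  tmpl <- glottal_template() # 210 samples at 22050 Hz
  expect_equal(length(tmpl), 210)
  e <- build_template_excitation(tmpl, 22050, 2100)
  expect_equal(length(e$samples), 2100)
  expect_identical(e$samples, rep(tmpl, 10))
  expect_true(all(e$samples[1:(2100 - 210)] ==
                    e$samples[211:2100])) # periodicity
  expect_error(build_template_excitation(numeric(0), 22050, 100), "empty")

  # synthesizing a vowel envelope with it yields pitch = rate / 210
  w <- harmonic_vowel(dur = 0.6)
  cep <- analyze_mel_cepstrum(w)
  exc <- build_template_excitation(tmpl, 22050, nrow(cep$frames) * 220)
  y <- mlsa_synthesize(exc, cep)
  p <- extract_pitch(y)
  expect_lt(abs(median(p$f0[p$f0 > 0]) - 22050 / 210), 1)
})

test_that("waveform and mel-cepstrogram round-trip through their text/WAV formats", {
  w <- harmonic_vowel(dur = 0.05)
  tf <- tempfile(fileext = ".wav")
  write_wav(w, tf, format = "float32")
  w2 <- read_wav(tf, expect_rate = 22050)
  expect_equal(w2$samples, w$samples, tolerance = 1e-6)
  write_wav(w, tf, format = "pcm16")
  w3 <- read_wav(tf)
  expect_lt(max(abs(w3$samples - w$samples)), 1 / 32768)

  cep <- analyze_mel_cepstrum(harmonic_vowel(dur = 0.1))
  tc <- tempfile(fileext = ".tsv")
  write_melcep(cep, tc)
  cep2 <- read_melcep(tc)
  expect_equal(cep2$frames, cep$frames)
  expect_equal(cep2$alpha, cep$alpha)
  expect_equal(cep2$hop, cep$hop)
})
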