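# Synthetic articulatory-acoustic corpus generator. Emulates the structure
# of a reference EMA corpus — paired articulatory/acoustic items (isolated
# pseudo-vowels, VCV-like sequences, longer pseudo-sentences) with silence
# margins and pseudo-phone segmentations — plus affine+delayed+noisy
# "new speaker" renditions, so that every processing stage has inputs with
# known ground truth. Pseudo-phones are defined by fixed articulatory
# targets, not recordings; the articulatory-to-acoustic relation is a fixed
# smooth random map.

#' Specification of a synthetic corpus
#'
#' Defaults describe the standard study conditions: 50 items averaging
#' about two seconds (silence margins included), a 17-phone inventory
#' (10 pseudo-vowels, 7 pseudo-consonants), 14 articulatory dimensions at
#' 400 Hz raw / 100 Hz processed, millimetre-scale targets with small
#' coloured articulator noise, and mel-cepstral observation noise at 40%
#' of the per-coefficient signal spread.
#'
#' @param n_items number of items.
#' @param d articulatory dimension (default 14, the midsagittal set).
#' @param n_vowels,n_consonants pseudo-phone inventory sizes.
#' @param vowel_frac,vcv_frac fraction of isolated-vowel and VCV items
#'   (the remainder are pseudo-sentences).
#' @param vowel_dur,seg_dur,sent_phones,silence_dur duration ranges (s) for
#'   isolated vowels and other phones, sentence phone-count range, and
#'   per-end silence margins.
#' @param target_sd spread of the phone articulatory targets (mm).
#' @param artic_noise_sd coloured articulator noise (mm).
#' @param transition_s raised-cosine transition time between targets (s).
#' @param noise_mel_rel mel-cepstral observation noise, relative to each
#'   coefficient's signal sd.
#' @param new_A,new_b,new_delay,new_sigma new-speaker affine map, frame
#'   delay, and articulatory noise sd (mm); `NULL` draws A and b from the
#'   seed (A = I + 0.15 R).
#' @param seed integer seed; every random quantity derives from it.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_items = 50, d = 14, n_vowels = 10, n_consonants = 7,
                       vowel_frac = 0.15, vcv_frac = 0.25,
                       vowel_dur = c(0.3, 0.5), seg_dur = c(0.08, 0.2),
                       sent_phones = c(11, 17), silence_dur = c(0.15, 0.35),
                       target_sd = 5, artic_noise_sd = 0.2,
                       transition_s = 0.05, noise_mel_rel = 0.4,
                       new_A = NULL, new_b = NULL, new_delay = 5,
                       new_sigma = 0.3, seed = 1) {
  if (any(c(vowel_dur, seg_dur, silence_dur) <= 0)) stop("durations must be > 0")
  if (new_sigma < 0 || noise_mel_rel < 0) stop("noise levels must be >= 0")
  structure(as.list(environment()), class = "synth_spec")
}

#' Deterministic smooth articulatory-to-acoustic ground-truth map
#'
#' A fixed shallow random network of 50 tanh basis functions from the
#' stacked articulatory context (5 x d dims) to 25 mel-cepstral
#' coefficients. Smooth and Lipschitz-bounded by construction; fully
#' reproducible from the seed. Output coefficients decay with quefrency
#' like real spectral envelopes so that synthesized audio is well behaved.
#'
#' @param seed integer seed.
#' @param d articulatory dimension (input is `5*d` after stacking).
#' @param n_basis number of tanh units (default 50).
#' @param n_out output dimension (default 25 mel-cepstral coefficients).
#' @return A `ground_truth_map`.
#' @export
make_ground_truth_map <- function(seed = 1, d = 14, n_basis = 50,
                                  n_out = 25) {
  set.seed(seed + 101)
  d_in <- 5 * d
  W1 <- matrix(rnorm(d_in * n_basis, sd = 0.3 / sqrt(d_in)), d_in, n_basis)
  b1 <- rnorm(n_basis, sd = 0.5)
  W2 <- matrix(rnorm(n_basis * n_out, sd = 1 / sqrt(n_basis)), n_basis, n_out)
  decay <- 1 / (1 + 0.25 * (seq_len(n_out) - 1))
  offset <- c(-0.8, rep(0, n_out - 1))
  structure(list(W1 = W1, b1 = b1, W2 = W2, decay = decay, offset = offset),
            class = "ground_truth_map")
}

#' @rdname make_ground_truth_map
#' @param map a `ground_truth_map`.
#' @param stacked T x (5*d) matrix of stacked articulatory frames (mm).
#' @return T x 25 matrix of mel-cepstral coefficients.
#' @export
apply_ground_truth_map <- function(map, stacked) {
  H <- tanh(sweep(as.matrix(stacked) %*% map$W1, 2, map$b1, "+"))
  sweep(sweep(H %*% map$W2, 2, map$decay, "*"), 2, map$offset, "+")
}

# raised-cosine smoothing kernel covering `width` frames
raised_cosine_kernel <- function(width) {
  k <- 0.5 - 0.5 * cos(2 * pi * seq_len(width) / (width + 1))
  k / sum(k)
}

# piecewise-constant target track smoothed by a raised-cosine kernel
smooth_targets <- function(track, width) {
  ker <- raised_cosine_kernel(width)
  half <- length(ker) %/% 2
  pad <- rbind(track[rep(1, half), , drop = FALSE], track,
               track[rep(nrow(track), length(ker) - half - 1), , drop = FALSE])
  apply(pad, 2, function(col) stats::filter(col, ker, sides = 1)) |>
    (\(m) m[(length(ker)):(length(ker) + nrow(track) - 1), , drop = FALSE])()
}

# low-passed Gaussian noise (coloured articulator jitter)
coloured_noise <- function(n, d, noise_sd) {
  if (noise_sd <= 0) return(matrix(0, n, d))
  bf <- signal::butter(2, 0.05)
  raw <- matrix(rnorm(n * d), n, d)
  sm <- apply(raw, 2, function(col) as.numeric(signal::filter(bf, col)))
  sm <- sweep(sm, 2, apply(sm, 2, stats::sd), "/")
  sm * noise_sd
}

#' Generate the synthetic reference corpus
#'
#' Each item is a pseudo-phone sequence with silence margins: articulatory
#' trajectories are raised-cosine interpolations between per-phone target
#' postures plus coloured noise at 400 Hz, down-sampled to 100 Hz;
#' mel-cepstra are the ground-truth map of the stacked 100 Hz trajectory
#' plus observation noise; audio (optional) is MLSA synthesis with a
#' 120 Hz pulse excitation. Segmentations tile each item exactly.
#'
#' @param spec a [synth_spec()].
#' @param with_audio also synthesize per-item audio (slower; off by
#'   default, the mapping stages don't need it).
#' @return A `synth_corpus`: list of items (each with `artic400`,
#'   `artic100`, `seg`, `melcep`, `audio`, `transcript`, `type`), plus the
#'   phone inventory, targets, ground-truth map and spec.
#' @export
generate_reference_corpus <- function(spec = synth_spec(),
                                      with_audio = FALSE) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  vowels <- sprintf("v%02d", seq_len(spec$n_vowels))
  consonants <- sprintf("c%02d", seq_len(spec$n_consonants))
  inventory <- c(vowels, consonants)
  targets <- matrix(rnorm(length(inventory) * spec$d, sd = spec$target_sd),
                    length(inventory), spec$d,
                    dimnames = list(inventory, NULL))
  rest <- rnorm(spec$d, sd = spec$target_sd / 2)  # silence posture
  gmap <- make_ground_truth_map(spec$seed, d = spec$d)

  n_v <- round(spec$vowel_frac * spec$n_items)
  n_c <- round(spec$vcv_frac * spec$n_items)
  types <- c(rep("vowel", n_v), rep("vcv", n_c),
             rep("sentence", spec$n_items - n_v - n_c))

  mel_sd_ref <- NULL  # per-dim signal sd, measured on clean cepstra
  items <- vector("list", spec$n_items)
  clean_store <- vector("list", spec$n_items)
  for (it in seq_len(spec$n_items)) {
    type <- types[it]
    phones <- switch(type,
      vowel = sample(vowels, 1),
      vcv = {v <- sample(vowels, 1); c(v, sample(consonants, 1), v)},
      sentence = sample(inventory, sample(spec$sent_phones[1]:spec$sent_phones[2], 1),
                        replace = TRUE))
    durs <- switch(type,
      vowel = runif(1, spec$vowel_dur[1], spec$vowel_dur[2]),
      runif(length(phones), spec$seg_dur[1], spec$seg_dur[2]))
    sil <- runif(2, spec$silence_dur[1], spec$silence_dur[2])
    labels <- c("SILENCE", phones, "SILENCE")
    all_durs <- c(sil[1], durs, sil[2])
    # quantize to the 400 Hz grid so segmentations tile exactly
    nf <- pmax(1, round(all_durs * 400))
    ends400 <- cumsum(nf)
    T400 <- ends400[length(ends400)]
    seg <- segmentation(c(0, ends400[-length(ends400)]) / 400,
                        ends400 / 400, labels)
    track <- matrix(0, T400, spec$d)
    pos <- 1
    for (sgi in seq_along(labels)) {
      tgt <- if (labels[sgi] == "SILENCE") rest else targets[labels[sgi], ]
      track[pos:(pos + nf[sgi] - 1), ] <- matrix(tgt, nf[sgi], spec$d,
                                                 byrow = TRUE)
      pos <- pos + nf[sgi]
    }
    width <- max(3, round(spec$transition_s * 400))
    traj400 <- smooth_targets(track, width) +
      coloured_noise(T400, spec$d, spec$artic_noise_sd)
    traj100 <- anti_alias_decimate(traj400, 4)
    clean <- apply_ground_truth_map(gmap, stack_context(traj100, 4))
    clean_store[[it]] <- clean
    items[[it]] <- list(
      artic400 = artic_features(traj400, "custom", rate = 400),
      artic100 = artic_features(traj100,
                                if (spec$d == 14) "midsag14" else "custom",
                                rate = 100),
      seg = seg, melcep = NULL, audio = NULL,
      transcript = phones, type = type)
  }

  mel_sd_ref <- apply(do.call(rbind, clean_store), 2, sd)
  noise_sd <- spec$noise_mel_rel * mel_sd_ref
  for (it in seq_len(spec$n_items)) {
    clean <- clean_store[[it]]
    noisy <- clean + matrix(rnorm(length(clean)), nrow(clean)) %*%
      diag(noise_sd)
    items[[it]]$melcep <- mel_cepstrogram(noisy, alpha = 0.455,
                                          rate = 22050, hop = 220,
                                          window = 512)
    if (with_audio) {
      Tn <- nrow(noisy)
      exc <- build_pitch_excitation(rep(120, Tn), rate = 22050,
                                    length = Tn * 220, hop = 220,
                                    seed = spec$seed + it)
      items[[it]]$audio <- mlsa_synthesize(exc, items[[it]]$melcep)
    }
  }
  structure(list(items = items, inventory = inventory, targets = targets,
                 rest = rest, map = gmap, noise_mel_sd = noise_sd,
                 mel_signal_sd = mel_sd_ref, spec = spec),
            class = "synth_corpus")
}

#' @export
print.synth_corpus <- function(x, ...) {
  total <- sum(vapply(x$items, function(i) nrow(i$artic100$frames), 0))
  cat(sprintf("<synth_corpus: %d items, %d phones, %d frames @ 100 Hz>\n",
              length(x$items), length(x$inventory), total))
  invisible(x)
}

#' Training pairs from a synthetic corpus
#'
#' Stacks each item's 100 Hz articulatory frames with 4 past frames, pairs
#' them with the item's mel-cepstra, and removes silence frames — the form
#' [train_layerwise()] consumes.
#'
#' @param corpus a `synth_corpus`.
#' @return List of items with `x` (T x 5d) and `y` (T x 25).
#' @export
corpus_training_pairs <- function(corpus) {
  lapply(corpus$items, function(item) {
    X <- stack_context(item$artic100, 4)
    Y <- item$melcep$frames
    sp <- remove_silence(item$artic100, item$seg)
    keep <- attr(sp, "index_map")
    list(x = X[keep, , drop = FALSE], y = Y[keep, , drop = FALSE])
  })
}

#' Simulate a new speaker's rendition of the reference corpus
#'
#' Applies `x_new(t) = A x_ref(t - delay) + b + noise` to every item's
#' 100 Hz trajectory (edges held at the first/last reference frame), the
#' silence segmentation carried over. Emulates a calibration recording:
#' same utterances in a different articulatory space with system latency.
#'
#' @param corpus a `synth_corpus`.
#' @param A,b affine map (defaults: the spec's, or seed-drawn
#'   `I + 0.15 R` / `N(0, 2 mm)`).
#' @param delay integer frame delay (default from the spec).
#' @param sigma articulatory noise sd in mm (default from the spec).
#' @param seed seed for noise (default spec seed + 1).
#' @return List with per-item `artic100` features, the `seg`s, and the true
#'   `A`, `b`, `delay`, `sigma` used.
#' @export
generate_new_speaker <- function(corpus, A = NULL, b = NULL, delay = NULL,
                                 sigma = NULL, seed = NULL) {
  spec <- corpus$spec
  d <- spec$d
  if (is.null(seed)) seed <- spec$seed + 1
  set.seed(seed)
  if (is.null(A)) A <- spec$new_A
  if (is.null(A)) A <- diag(d) + matrix(rnorm(d * d, sd = 0.15), d, d)
  if (is.null(b)) b <- spec$new_b
  if (is.null(b)) b <- rnorm(d, sd = 2)
  if (is.null(delay)) delay <- spec$new_delay
  if (is.null(sigma)) sigma <- spec$new_sigma
  items <- lapply(corpus$items, function(item) {
    X <- item$artic100$frames
    Tn <- nrow(X)
    src <- pmin(pmax(seq_len(Tn) - delay, 1), Tn)  # x_new(t) = f(x_ref(t - delay))
    Xn <- X[src, , drop = FALSE] %*% t(A)
    Xn <- sweep(Xn, 2, b, "+")
    if (sigma > 0) Xn <- Xn + matrix(rnorm(Tn * ncol(Xn), sd = sigma),
                                     Tn, ncol(Xn))
    list(artic100 = artic_features(Xn, item$artic100$parameterization, 100),
         seg = item$seg)
  })
  list(items = items, A = A, b = b, delay = delay, sigma = sigma)
}

#' Steady-state frame indices of labelled phones
#'
#' Returns, for each non-silence interval (optionally restricted to given
#' labels), the 100 Hz frames in its central portion — the steady state
#' used for template building and classification.
#'
#' @param seg a [segmentation].
#' @param rate frame rate (Hz).
#' @param labels optional label subset.
#' @param trim fraction trimmed from each end of the interval
#'   (default 0.25).
#' @return List of lists with `label` and `frames` (indices).
#' @export
phone_frame_indices <- function(seg, rate = 100, labels = NULL, trim = 0.25) {
  rows <- which(seg$label != "SILENCE" &
                  (is.null(labels) | seg$label %in% labels))
  lapply(rows, function(r) {
    span <- seg$end[r] - seg$start[r]
    lo <- seg$start[r] + trim * span
    hi <- seg$end[r] - trim * span
    centers <- ((1:ceiling(seg$end[nrow(seg)] * rate)) - 0.5) / rate
    list(label = seg$label[r], frames = which(centers >= lo & centers < hi))
  })
}
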