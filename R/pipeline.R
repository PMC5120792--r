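# End-to-end synthesis: articulatory frames -> (optional linear
# calibration) -> context stacking -> DNN -> MLSA filtering of the
# excitation. The streaming core processes exactly one articulatory frame
# into one hop of audio with O(1) state (a 5-frame context buffer, the
# MLSA filter state, and the excitation phase); offline synthesis drives
# the same core in a loop, so batch and streaming output are identical by
# construction and the causality of the whole cascade is structural.

#' Initialize a streaming synthesis state
#'
#' @param model a trained `dnn_model`.
#' @param template single-period excitation template (silent-speech mode
#'   uses a fixed template; see [glottal_template()]).
#' @param calibration optional `linear_calibration` applied to each
#'   incoming frame before the network.
#' @param rate audio sampling rate (Hz).
#' @param hop audio samples per articulatory frame (default 220).
#' @param alpha mel-cepstral warp of the model's output coefficients.
#' @param n_past context frames appended to the current one (default 4).
#' @param pade_order MLSA Pade order.
#' @return A `stream_state` to pass through [stream_step()].
#' @export
stream_state <- function(model, template, calibration = NULL, rate = 22050,
                         hop = 220, alpha = 0.455, n_past = 4,
                         pade_order = 5) {
  n_coef <- length(model$layers[[length(model$layers)]]$b)
  structure(list(model = model, cal = calibration,
                 template = as.numeric(template), rate = rate, hop = hop,
                 alpha = alpha, n_past = n_past,
                 pade = pade_coefficients(pade_order),
                 filt = mlsa_state(n_coef, pade_order),
                 buffer = NULL, b_prev = NULL, phase = 0L,
                 frames_seen = 0L, step_ops = NA_real_),
            class = "stream_state")
}

# multiply-accumulate count of one step (constant in t: the O(1) claim)
stream_step_cost <- function(state) {
  d <- if (is.null(state$cal)) 0 else length(state$cal$bias) * ncol(state$cal$matrix)
  sizes <- c(nrow(state$model$layers[[1]]$W),
             vapply(state$model$layers, function(l) ncol(l$W), 0L))
  net <- sum(sizes[-length(sizes)] * sizes[-1])
  n_coef <- sizes[length(sizes)]
  mlsa <- state$hop * length(state$pade) * 2 * (n_coef + 2)
  d + net + mlsa
}

#' Advance the streaming synthesizer by one articulatory frame
#'
#' Applies the calibration (if any), pushes the frame into the causal
#' context buffer (cold start replicates the first frame), runs the network
#' forward, and MLSA-filters the next `hop` samples of the tiled template
#' excitation, interpolating filter coefficients from the previous frame's.
#' Output depends only on frames received so far.
#'
#' @param state a [stream_state()].
#' @param frame numeric articulatory frame (calibration input dimension, or
#'   model input dimension when no calibration is set).
#' @return List with `state` (updated) and `samples` (`hop` audio samples).
#' @export
stream_step <- function(state, frame) {
  exc <- state$template[((state$phase + 0:(state$hop - 1)) %%
                           length(state$template)) + 1]
  out <- stream_step_exc(state, frame, exc)
  out$state$phase <- (state$phase + state$hop) %% length(state$template)
  out
}

# shared per-frame core: one articulatory frame + one pre-built excitation
# chunk -> hop samples. Excitation source is the only thing stream_step and
# synthesize_offline differ in.
stream_step_exc <- function(state, frame, exc_chunk) {
  x <- as.numeric(frame)
  if (!is.null(state$cal)) {
    if (length(x) != ncol(state$cal$matrix))
      stop("frame dimension ", length(x), " != calibration input ",
           ncol(state$cal$matrix))
    x <- drop(apply_calibration(state$cal, x))
  }
  d <- length(x)
  if (is.null(state$buffer))
    state$buffer <- matrix(x, nrow = state$n_past + 1, ncol = d,
                           byrow = TRUE)  # replication padding at cold start
  else
    state$buffer <- rbind(matrix(x, 1), state$buffer[seq_len(state$n_past), ,
                                                     drop = FALSE])
  stacked <- matrix(t(state$buffer), nrow = 1)  # current frame first
  cep <- dnn_predict(state$model, stacked)
  b <- mel_to_filter_coeffs(drop(cep), alpha = state$alpha)
  if (is.null(state$b_prev)) state$b_prev <- b
  y <- mlsa_frame(exc_chunk, state$b_prev, b, state$alpha, state$pade,
                  state$filt)
  state$b_prev <- b
  state$frames_seen <- state$frames_seen + 1L
  state$step_ops <- stream_step_cost(state)
  list(state = state, samples = y)
}

#' Offline articulatory-to-audio synthesis
#'
#' Synthesizes a whole utterance from articulatory features: the excitation
#' is built for the full duration (`T * hop` samples), then the streaming
#' core is driven frame by frame, so the output is sample-identical to
#' feeding the frames through [stream_step()].
#'
#' @param features [artic_features] (or matrix) in the model's input space
#'   (reference articulatory space; stacking is internal).
#' @param model a trained `dnn_model`.
#' @param excitation the excitation source: an [f0_contour] (pitch-driven),
#'   a numeric single-period template, or a ready-made [excitation] of
#'   length `T * hop`.
#' @param calibration optional `linear_calibration` applied per frame.
#' @param rate,hop,alpha,pade_order as in [stream_state()].
#' @param seed seed for pitch-driven noise segments.
#' @return A [waveform] of `T * hop` samples.
#' @export
synthesize_offline <- function(features, model, excitation,
                               calibration = NULL, rate = 22050, hop = 220,
                               alpha = 0.455, pade_order = 5, seed = NULL) {
  X <- feature_frames(features)
  Tn <- nrow(X)
  n <- Tn * hop
  if (inherits(excitation, "f0_contour")) {
    exc <- build_pitch_excitation(excitation, rate, n, hop, seed = seed)$samples
    template <- numeric(1)
  } else if (inherits(excitation, "excitation")) {
    if (length(excitation$samples) != n)
      stop("excitation length ", length(excitation$samples),
           " != T * hop = ", n)
    exc <- excitation$samples
    template <- numeric(1)
  } else {
    template <- as.numeric(excitation)
    exc <- build_template_excitation(template, rate, n)$samples
  }
  st <- stream_state(model, if (length(template) > 1) template else exc,
                     calibration, rate, hop, alpha, pade_order = pade_order)
  y <- numeric(n)
  for (t in seq_len(Tn)) {
    idx <- ((t - 1) * hop + 1):(t * hop)
    step <- stream_step_exc(st, X[t, ], exc[idx])
    st <- step$state
    y[idx] <- step$samples
  }
  waveform(y, rate)
}

#' Run a batch closed-loop synthesis session
#'
#' Streams each item's (new-speaker) articulatory frames through
#' calibration, network and MLSA with the template excitation — the
#' silent-speech closed-loop cascade — and writes one WAV per item.
#' I/O failures are recorded per item and the session continues.
#'
#' @param items list of items, each with an `artic100` [artic_features]
#'   element (as produced by [generate_new_speaker()]) or a plain feature
#'   matrix.
#' @param calibration a `linear_calibration` (or `NULL` for the reference
#'   speaker).
#' @param model a trained `dnn_model`.
#' @param template single-period excitation template.
#' @param out_dir output directory for the WAV files.
#' @param rate,hop,alpha as in [stream_state()].
#' @return Data frame manifest: item, frames, samples, path, status.
#' @export
run_closed_loop_session <- function(items, calibration, model, template,
                                    out_dir = tempdir(), rate = 22050,
                                    hop = 220, alpha = 0.455) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  empty <- data.frame(item = integer(), frames = integer(),
                      samples = integer(), path = character(),
                      status = character(), stringsAsFactors = FALSE)
  if (length(items) == 0) return(empty)
  rows <- lapply(seq_along(items), function(i) {
    feats <- items[[i]]
    if (is.list(feats) && !inherits(feats, "artic_features") &&
        !is.null(feats$artic100)) feats <- feats$artic100
    path <- file.path(out_dir, sprintf("item_%03d.wav", i))
    res <- tryCatch({
      w <- synthesize_offline(feats, model, template,
                              calibration = calibration, rate = rate,
                              hop = hop, alpha = alpha)
      write_wav(w, path)
      data.frame(item = i, frames = nrow(feature_frames(feats)),
                 samples = length(w$samples), path = path,
                 status = "ok", stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(item = i, frames = NA_integer_, samples = NA_integer_,
                 path = path, status = paste("error:", conditionMessage(e)),
                 stringsAsFactors = FALSE))
    res
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
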