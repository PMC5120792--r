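# Articulatory parameterizations: 27 raw coordinates (9 sensors x 3D),
# 14 midsagittal coordinates (7 sensors x 2D), or 10/7 PCA scores.

#' Articulatory feature objects
#'
#' @param frames T x d numeric matrix of per-frame articulatory parameters.
#' @param parameterization one of `"raw27"`, `"midsag14"`, `"pca10"`,
#'   `"pca7"`, or `"custom"`.
#' @param rate frame rate in Hz (nominal 100).
#' @return An object of class `artic_features`.
#' @export
artic_features <- function(frames, parameterization = "custom", rate = 100) {
  frames <- as.matrix(frames)
  if (!all(is.finite(frames))) stop("non-finite articulatory features")
  expected <- c(raw27 = 27L, midsag14 = 14L, pca10 = 10L, pca7 = 7L)
  if (parameterization %in% names(expected) &&
      ncol(frames) != expected[[parameterization]])
    stop(parameterization, " requires ", expected[[parameterization]],
         " dimensions, got ", ncol(frames))
  structure(list(frames = frames, parameterization = parameterization,
                 rate = rate), class = "artic_features")
}

#' @export
print.artic_features <- function(x, ...) {
  cat(sprintf("<artic_features (%s): %d frames x %d @ %g Hz>\n",
              x$parameterization, nrow(x$frames), ncol(x$frames), x$rate))
  invisible(x)
}

feature_frames <- function(x) {
  if (inherits(x, "artic_features")) x$frames else as.matrix(x)
}

#' Full 27-parameter articulatory features from an EMA recording
#'
#' All nine sensors, three coordinates each, in canonical sensor order.
#' @param rec a head-corrected [ema_recording] with the nine canonical
#'   sensors.
#' @return [artic_features] with parameterization `raw27`.
#' @export
ema_to_raw27 <- function(rec) {
  stopifnot(inherits(rec, "ema_recording"))
  missing <- setdiff(ema_sensor_order(), rec$sensors)
  if (length(missing)) stop("missing sensors: ", paste(missing, collapse = ", "))
  ord <- match(ema_sensor_order(), rec$sensors)
  cols <- as.vector(vapply(ord, function(s) (s - 1L) * 3L + 1:3, integer(3)))
  artic_features(rec$coords[, cols, drop = FALSE], "raw27", rate = rec$rate)
}

#' Midsagittal projection (14 parameters)
#'
#' Drops the lip-corner sensors and projects the remaining seven sensors
#' onto the midsagittal plane. After head correction the midsagittal plane
#' is the x-y plane of the reference-coil frame, so the projection keeps
#' the caudo-rostral X and ventro-dorsal Y coordinates and discards the
#' lateral Z. Column order: tongue_tip, tongue_dorsum, tongue_back,
#' upper_lip, lower_lip, jaw, velum, each contributing (x, y).
#'
#' @param rec a head-corrected [ema_recording].
#' @return [artic_features] with parameterization `midsag14`.
#' @export
project_midsagittal <- function(rec) {
  stopifnot(inherits(rec, "ema_recording"))
  keep <- midsagittal_sensor_order()
  missing <- setdiff(keep, rec$sensors)
  if (length(missing)) stop("missing sensors: ", paste(missing, collapse = ", "))
  idx <- match(keep, rec$sensors)
  cols <- as.vector(vapply(idx, function(s) (s - 1L) * 3L + 1:2, integer(2)))
  out <- rec$coords[, cols, drop = FALSE]
  colnames(out) <- paste(rep(keep, each = 2), c("x", "y"), sep = "_")
  artic_features(out, "midsag14", rate = rec$rate)
}

#' @rdname project_midsagittal
#' @export
midsagittal_sensor_order <- function() {
  setdiff(ema_sensor_order(), c("lip_corner_l", "lip_corner_r"))
}

#' Fit / apply a PCA reduction of the 27-parameter features
#'
#' The 27-dimensional data are z-scored per dimension, then the top-k
#' principal axes are extracted. `apply_pca` projects new data with the
#' stored scaling; `reconstruct_pca` maps scores back to the 27-dimensional
#' space (lossy for k < 27).
#'
#' @param features [artic_features] (raw27) or T x 27 matrix.
#' @param k number of components to keep (10 or 7 in the standard setups).
#' @return `fit_pca`: a `pca_model` (means, sds, rotation, explained
#'   variance ratios); `apply_pca`: [artic_features] of scores;
#'   `reconstruct_pca`: a T x 27 matrix.
#' @export
fit_pca <- function(features, k) {
  X <- feature_frames(features)
  d <- ncol(X)
  if (k > d) stop("k = ", k, " exceeds dimension ", d)
  if (nrow(X) <= d) stop("need more frames than dimensions to fit PCA")
  sds <- apply(X, 2, sd)
  if (any(sds <= 0)) stop("zero-variance dimension(s): ",
                          paste(which(sds <= 0), collapse = ", "))
  pc <- prcomp(X, center = TRUE, scale. = TRUE)
  structure(list(mean = pc$center, sd = pc$scale,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 k = k,
                 explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "pca_model")
}

#' @rdname fit_pca
#' @param model a `pca_model` from `fit_pca`.
#' @export
apply_pca <- function(model, features) {
  X <- feature_frames(features)
  rate <- if (inherits(features, "artic_features")) features$rate else 100
  Z <- sweep(sweep(X, 2, model$mean), 2, model$sd, "/")
  scores <- Z %*% model$rotation
  tag <- if (model$k %in% c(10, 7)) paste0("pca", model$k) else "custom"
  artic_features(scores, tag, rate = rate)
}

#' @rdname fit_pca
#' @param scores matrix (or [artic_features]) of PCA scores.
#' @export
reconstruct_pca <- function(model, scores) {
  S <- feature_frames(scores)
  Z <- S %*% t(model$rotation)
  sweep(sweep(Z, 2, model$sd, "*"), 2, model$mean, "+")
}

#' Phone segmentations
#'
#' An ordered, non-overlapping list of labelled intervals in seconds; the
#' label `SILENCE` marks non-speech stretches.
#'
#' @param start,end numeric vectors of interval bounds (s).
#' @param label character vector of phone labels (or `"SILENCE"`).
#' @return A `segmentation` (data frame with columns start, end, label).
#' @export
segmentation <- function(start, end, label) {
  d <- data.frame(start = as.numeric(start), end = as.numeric(end),
                  label = as.character(label), stringsAsFactors = FALSE)
  if (any(d$start >= d$end)) stop("intervals must satisfy start < end")
  if (is.unsorted(d$start)) stop("intervals must be sorted by start")
  if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)] - 1e-9))
    stop("intervals must not overlap")
  class(d) <- c("segmentation", "data.frame")
  d
}

#' @rdname segmentation
#' @param seg a `segmentation`.
#' @param path file path (`start<TAB>end<TAB>label`, seconds).
#' @export
write_segmentation <- function(seg, path) {
  writeLines(sprintf("%.10g\t%.10g\t%s", seg$start, seg$end, seg$label), path)
  invisible(path)
}

#' @rdname segmentation
#' @export
read_segmentation <- function(path) {
  parts <- strsplit(readLines(path), "\t")
  segmentation(vapply(parts, function(p) as.numeric(p[1]), 0),
               vapply(parts, function(p) as.numeric(p[2]), 0),
               vapply(parts, function(p) p[3], ""))
}

#' Remove silence frames
#'
#' Drops frames whose centre time falls inside a `SILENCE` interval of the
#' segmentation. The indices of the kept frames (into the original feature
#' matrix) are attached as attribute `"index_map"`.
#'
#' @param features [artic_features] or a frame matrix.
#' @param seg a [segmentation] covering the features' time span.
#' @param rate frame rate in Hz; taken from `features` when available.
#' @return Features of the same class with silence frames removed.
#' @export
remove_silence <- function(features, seg, rate = NULL) {
  X <- feature_frames(features)
  if (is.null(rate))
    rate <- if (inherits(features, "artic_features")) features$rate else 100
  centers <- (seq_len(nrow(X)) - 0.5) / rate
  sil <- seg[seg$label == "SILENCE", , drop = FALSE]
  in_sil <- rep(FALSE, length(centers))
  for (i in seq_len(nrow(sil)))
    in_sil <- in_sil | (centers >= sil$start[i] & centers < sil$end[i])
  keep <- which(!in_sil)
  if (length(keep) == 0) warning("all frames fall in silence")
  out <- if (inherits(features, "artic_features"))
    artic_features(X[keep, , drop = FALSE], features$parameterization, rate)
  else X[keep, , drop = FALSE]
  attr(out, "index_map") <- keep
  out
}

#' Z-score normalizers
#'
#' Per-dimension mean/sd computed on training frames only; applying the
#' fitted normalizer to new data carries no information from that data
#' (no leakage).
#'
#' @param features training [artic_features] or matrix (T >= 2 frames).
#' @return `fit_normalizer`: a `normalizer`; apply/invert: matrix or
#'   [artic_features] matching the input class.
#' @export
fit_normalizer <- function(features) {
  X <- feature_frames(features)
  if (nrow(X) < 2) stop("need at least 2 frames to fit a normalizer")
  mu <- colMeans(X)
  sds <- apply(X, 2, sd)
  bad <- which(sds <= 0)
  if (length(bad)) stop("zero-variance dimension(s): ",
                        paste(bad, collapse = ", "))
  structure(list(mean = mu, sd = sds), class = "normalizer")
}

#' @rdname fit_normalizer
#' @param norm a `normalizer`.
#' @param x features or matrix to transform.
#' @export
apply_normalizer <- function(norm, x) {
  X <- feature_frames(x)
  Z <- sweep(sweep(X, 2, norm$mean), 2, norm$sd, "/")
  if (inherits(x, "artic_features"))
    artic_features(Z, x$parameterization, x$rate) else Z
}

#' @rdname fit_normalizer
#' @export
invert_normalizer <- function(norm, x) {
  Z <- feature_frames(x)
  X <- sweep(sweep(Z, 2, norm$sd, "*"), 2, norm$mean, "+")
  if (inherits(x, "artic_features"))
    artic_features(X, x$parameterization, x$rate) else X
}

#' Causal context stacking
#'
#' Concatenates each frame with its `n_past` predecessors (default 4: a
#' 50 ms context at 100 Hz), producing `(n_past+1)*d` columns ordered
#' current frame first, then t-1, ..., t-n_past. Rows near the start reuse
#' the first frame (replication padding), so the output has exactly T rows
#' and row t never depends on frames after t.
#'
#' @param features [artic_features] or T x d matrix.
#' @param n_past number of past frames to append (default 4).
#' @return T x ((n_past+1)*d) matrix.
#' @export
stack_context <- function(features, n_past = 4) {
  X <- feature_frames(features)
  Tn <- nrow(X)
  blocks <- lapply(0:n_past, function(k) {
    idx <- pmax(seq_len(Tn) - k, 1)
    X[idx, , drop = FALSE]
  })
  do.call(cbind, blocks)
}
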