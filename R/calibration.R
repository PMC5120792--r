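# Cross-speaker calibration: a frame-wise affine map from a new speaker's
# articulatory space to the reference speaker's, preceded by a global
# integer-frame delay estimated by grid search on the linear-fit MSE.

# align two sequences for candidate delay (new lags ref by `delay` frames:
# new[t] corresponds to ref[t - delay]); returns row indices into each.
align_delay <- function(n_new, n_ref, delay) {
  if (delay >= 0) {
    len <- min(n_new - delay, n_ref)
    if (len < 1) return(NULL)
    list(new = delay + seq_len(len), ref = seq_len(len))
  } else {
    len <- min(n_new, n_ref + delay)
    if (len < 1) return(NULL)
    list(new = seq_len(len), ref = -delay + seq_len(len))
  }
}

ols_fit <- function(X, Y) {
  Xd <- cbind(1, X)
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) {
    dep <- setdiff(seq_len(ncol(Xd)), qr_x$pivot[seq_len(qr_x$rank)]) - 1L
    stop("rank-deficient design; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  B <- qr.coef(qr_x, Y)
  fitted <- Xd %*% B
  list(bias = B[1, ], matrix = t(B[-1, , drop = FALSE]),
       mse = mean((Y - fitted)^2))
}

#' Estimate the global delay between a new speaker and the reference
#'
#' For each candidate delay the sequences are shifted and trimmed, frames
#' flagged silent are discarded, an ordinary-least-squares linear map from
#' the new speaker's frames to the reference frames is fitted, and its MSE
#' recorded. The delay with the smallest MSE wins; ties go to the smallest
#' absolute delay.
#'
#' @param new,ref feature matrices (or [artic_features]) of the new speaker
#'   and the reference, same utterances, one frame per row.
#' @param grid integer candidate delays in frames (default -30..30, i.e.
#'   +-300 ms at 100 Hz).
#' @param silence_new,silence_ref optional logical vectors flagging silence
#'   frames of each sequence; aligned frame pairs touching silence are
#'   dropped before fitting.
#' @return List with `delay` (best), `mse` (at best), and `curve`
#'   (data frame of delay vs MSE over the grid).
#' @export
estimate_delay <- function(new, ref, grid = -30:30,
                           silence_new = NULL, silence_ref = NULL) {
  Xn <- feature_frames(new); Xr <- feature_frames(ref)
  if (max(abs(grid)) >= min(nrow(Xn), nrow(Xr)))
    stop("delay grid exceeds sequence length")
  mses <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    al <- align_delay(nrow(Xn), nrow(Xr), grid[i])
    if (is.null(al)) next
    keep <- rep(TRUE, length(al$new))
    if (!is.null(silence_new)) keep <- keep & !silence_new[al$new]
    if (!is.null(silence_ref)) keep <- keep & !silence_ref[al$ref]
    Xa <- Xn[al$new[keep], , drop = FALSE]
    Ya <- Xr[al$ref[keep], , drop = FALSE]
    if (nrow(Xa) < 10 * ncol(Xa)) next
    mses[i] <- tryCatch(ols_fit(Xa, Ya)$mse, error = function(e) NA_real_)
  }
  if (all(is.na(mses))) stop("no candidate delay admitted a fit")
  best <- min(mses, na.rm = TRUE)
  cand <- which(abs(mses - best) <= 0)  # exact argmin set
  cand <- cand[order(abs(grid[cand]))][1]
  list(delay = grid[cand], mse = mses[cand],
       curve = data.frame(delay = grid, mse = mses))
}

#' Fit the frame-wise linear calibration
#'
#' Ordinary least squares with intercept, frame by frame with no temporal
#' context: `ref_t ~ matrix %*% new_{t} + bias` after correcting the given
#' delay by shifting and trimming.
#'
#' @param new,ref feature matrices (or [artic_features]); `new` may have a
#'   different dimension than `ref` (e.g. 18 three-dimensional coordinates
#'   mapped onto 14 midsagittal parameters).
#' @param delay integer frame delay from [estimate_delay()] (default 0).
#' @param silence_new,silence_ref optional silence flags as in
#'   [estimate_delay()].
#' @return A `linear_calibration`: `matrix` (d_ref x d_new), `bias`,
#'   `delay`, `fit_mse`.
#' @export
fit_linear <- function(new, ref, delay = 0,
                       silence_new = NULL, silence_ref = NULL) {
  Xn <- feature_frames(new); Xr <- feature_frames(ref)
  al <- align_delay(nrow(Xn), nrow(Xr), delay)
  if (is.null(al)) stop("delay leaves no overlapping frames")
  keep <- rep(TRUE, length(al$new))
  if (!is.null(silence_new)) keep <- keep & !silence_new[al$new]
  if (!is.null(silence_ref)) keep <- keep & !silence_ref[al$ref]
  X <- Xn[al$new[keep], , drop = FALSE]
  Y <- Xr[al$ref[keep], , drop = FALSE]
  if (nrow(X) <= ncol(X) + 1) stop("too few frames for the linear fit")
  fit <- ols_fit(X, Y)
  structure(list(matrix = fit$matrix, bias = fit$bias, delay = delay,
                 fit_mse = fit$mse), class = "linear_calibration")
}

#' @export
print.linear_calibration <- function(x, ...) {
  cat(sprintf("<linear_calibration: %d -> %d dims, delay %d frames, fit MSE %.4g>\n",
              ncol(x$matrix), nrow(x$matrix), x$delay, x$fit_mse))
  invisible(x)
}

#' Apply a linear calibration
#'
#' Maps frames of the new speaker into the reference articulatory space:
#' `y_t = matrix %*% x_t + bias`, frame by frame, causally (no context).
#'
#' @param cal a `linear_calibration`.
#' @param frames T x d_new matrix (or [artic_features], or a single frame
#'   vector).
#' @return T x d_ref matrix of mapped frames.
#' @export
apply_calibration <- function(cal, frames) {
  X <- feature_frames(if (is.null(dim(frames)) &&
                          !inherits(frames, "artic_features"))
                        matrix(frames, nrow = 1) else frames)
  if (ncol(X) != ncol(cal$matrix))
    stop("frame dimension ", ncol(X), " != calibration input dimension ",
         ncol(cal$matrix))
  sweep(X %*% t(cal$matrix), 2, cal$bias, "+")
}

#' Per-sensor calibration error report
#'
#' Euclidean distance in the midsagittal plane between predicted and
#' reference sensor positions, per sensor and pooled, over speech frames.
#'
#' @param predicted,ref T x 14 midsagittal feature matrices in canonical
#'   sensor order (see [midsagittal_sensor_order()]).
#' @return A `sensor_error_report`: data frame of per-sensor mean/sd
#'   distance (mm) plus a pooled `"All"` row.
#' @export
sensor_error_report <- function(predicted, ref) {
  P <- feature_frames(predicted); R <- feature_frames(ref)
  if (!all(dim(P) == dim(R))) stop("shape mismatch")
  if (ncol(P) %% 2 != 0) stop("expected paired (x, y) columns")
  sensors <- midsagittal_sensor_order()
  ns <- ncol(P) / 2
  labs <- if (ns == length(sensors)) sensors else paste0("sensor", seq_len(ns))
  dists <- vapply(seq_len(ns), function(s) {
    dx <- P[, 2 * s - 1] - R[, 2 * s - 1]
    dy <- P[, 2 * s] - R[, 2 * s]
    sqrt(dx^2 + dy^2)
  }, numeric(nrow(P)))
  rep <- data.frame(sensor = c(labs, "All"),
                    mean_mm = c(colMeans(dists), mean(dists)),
                    sd_mm = c(apply(dists, 2, sd), sd(as.vector(dists))))
  class(rep) <- c("sensor_error_report", "data.frame")
  rep
}

#' Serialize / load a calibration as text
#' @param cal a `linear_calibration`.
#' @param path file path.
#' @return `path` invisibly, or the restored `linear_calibration`.
#' @export
write_calibration <- function(cal, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(v) paste(sprintf("%.17g", v), collapse = "\t")
  writeLines(c("# emasynth calibration v1",
               sprintf("dims\t%d\t%d", nrow(cal$matrix), ncol(cal$matrix)),
               sprintf("delay\t%d", cal$delay),
               sprintf("fit_mse\t%.17g", cal$fit_mse),
               sprintf("bias\t%s", num(cal$bias)),
               sprintf("matrix\t%s", num(cal$matrix))), con)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  kv <- strsplit(lines, "\t")
  keys <- vapply(kv, `[[`, "", 1)
  val <- function(k) as.numeric(kv[[match(k, keys)]][-1])
  d <- as.integer(val("dims"))
  structure(list(matrix = matrix(val("matrix"), d[1], d[2]),
                 bias = val("bias"), delay = as.integer(val("delay")),
                 fit_mse = val("fit_mse")), class = "linear_calibration")
}
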