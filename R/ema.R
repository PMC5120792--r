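# EMA recordings: positional trajectories of coils glued to the articulators
# (tongue tip/dorsum/back, lips, lip corners, jaw, velum), with the 6-DOF
# pose stream of a reference coil used to cancel head movements.

#' Canonical EMA sensor order
#'
#' All matrices in the package use this fixed sensor order; the midsagittal
#' parameterization keeps the first five plus jaw and velum (lip corners
#' dropped).
#' @return Character vector of the nine sensor names.
#' @export
ema_sensor_order <- function() {
  c("tongue_tip", "tongue_dorsum", "tongue_back", "upper_lip", "lower_lip",
    "lip_corner_l", "lip_corner_r", "jaw", "velum")
}

#' EMA recording objects
#'
#' @param coords T x (3*n_sensors) matrix of x,y,z positions in mm, sensor
#'   blocks in `sensors` order.
#' @param rate sampling rate in Hz (400 raw, 100 after down-sampling).
#' @param sensors character vector of sensor names.
#' @param reference_pose T x 6 matrix: reference-coil translation (mm) and
#'   rotation (radians, intrinsic x-y-z Euler angles) per frame. `NULL`
#'   means the recording is already head-corrected (identity pose).
#' @param time optional per-frame times in seconds (default `(0:(T-1))/rate`).
#' @return An object of class `ema_recording`.
#' @export
ema_recording <- function(coords, rate, sensors = ema_sensor_order(),
                          reference_pose = NULL, time = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L * length(sensors))
    stop("coords must have 3 columns per sensor")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (!is.null(reference_pose)) {
    reference_pose <- as.matrix(reference_pose)
    if (nrow(reference_pose) != nrow(coords) || ncol(reference_pose) != 6L)
      stop("reference_pose must be T x 6")
  }
  if (is.null(time)) time <- (seq_len(nrow(coords)) - 1) / rate
  colnames(coords) <- paste(rep(sensors, each = 3), c("x", "y", "z"),
                            sep = "_")
  structure(list(time = time, coords = coords, sensors = sensors,
                 reference_pose = reference_pose, rate = rate),
            class = "ema_recording")
}

#' @export
print.ema_recording <- function(x, ...) {
  cat(sprintf("<ema_recording: %d frames @ %g Hz, %d sensors%s>\n",
              nrow(x$coords), x$rate, length(x$sensors),
              if (is.null(x$reference_pose)) ", head-corrected" else ""))
  invisible(x)
}

# Rotation matrix for intrinsic x-y-z Euler angles
euler_rotation <- function(rx, ry, rz) {
  Rx <- matrix(c(1, 0, 0, 0, cos(rx), sin(rx), 0, -sin(rx), cos(rx)), 3, 3)
  Ry <- matrix(c(cos(ry), 0, -sin(ry), 0, 1, 0, sin(ry), 0, cos(ry)), 3, 3)
  Rz <- matrix(c(cos(rz), sin(rz), 0, -sin(rz), cos(rz), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Head-movement correction
#'
#' Re-expresses every sensor in the rigid frame of the reference coil:
#' per frame, the reference translation is subtracted and the inverse
#' reference rotation applied. Head motion common to all sensors cancels;
#' the returned recording carries an identity pose (`reference_pose = NULL`).
#'
#' @param rec an [ema_recording] with a `reference_pose`.
#' @return A head-corrected [ema_recording].
#' @export
head_correct <- function(rec) {
  stopifnot(inherits(rec, "ema_recording"))
  if (is.null(rec$reference_pose))
    return(rec) # already corrected
  pose <- rec$reference_pose
  if (any(!is.finite(pose))) stop("missing/non-finite reference pose frames")
  Tn <- nrow(rec$coords)
  ns <- length(rec$sensors)
  out <- rec$coords
  # per-frame rotation entries, vectorized over frames
  for (t in seq_len(Tn)) {
    R <- euler_rotation(pose[t, 4], pose[t, 5], pose[t, 6])
    for (s in seq_len(ns)) {
      j <- (s - 1) * 3 + 1:3
      out[t, j] <- crossprod(R, rec$coords[t, j] - pose[t, 1:3])
    }
  }
  ema_recording(out, rec$rate, rec$sensors, reference_pose = NULL,
                time = rec$time)
}

#' Down-sample an EMA recording
#'
#' Anti-alias low-pass filtering followed by decimation. The low-pass is a
#' 4th-order Butterworth at the new Nyquist frequency run forward and
#' backward (zero phase, 8th-order magnitude response), so constant
#' trajectories pass through unchanged and no group delay is introduced.
#' Output frame count is `ceiling(T/factor)` (frames 1, 1+factor, ...).
#'
#' @param rec an [ema_recording].
#' @param factor integer decimation factor (default 4: 400 Hz to 100 Hz).
#' @return The down-sampled [ema_recording].
#' @export
downsample_frames <- function(rec, factor = 4) {
  stopifnot(inherits(rec, "ema_recording"))
  if (factor != round(factor) || factor < 1) stop("factor must be a positive integer")
  if (rec$rate %% factor != 0) stop("rate not divisible by factor")
  if (factor == 1) return(rec)
  keep <- seq(1, nrow(rec$coords), by = factor)
  coords <- anti_alias_decimate(rec$coords, factor)
  pose <- rec$reference_pose
  if (!is.null(pose)) pose <- anti_alias_decimate(pose, factor)
  ema_recording(coords, rec$rate / factor, rec$sensors,
                reference_pose = pose, time = rec$time[keep])
}

# zero-phase 4th-order Butterworth low-pass at the new Nyquist, then keep
# every `factor`-th frame (rows 1, 1+factor, ...)
anti_alias_decimate <- function(X, factor) {
  X <- as.matrix(X)
  Tn <- nrow(X)
  keep <- seq(1, Tn, by = factor)
  if (Tn <= 24) return(X[keep, , drop = FALSE]) # too short to filter stably
  bf <- signal::butter(4, 1 / factor)
  # filter about the column mean: avoids start-up transients on signals
  # with a DC offset (constant trajectories pass through exactly)
  mu <- colMeans(X)
  low <- apply(sweep(X, 2, mu), 2, function(col) signal::filtfilt(bf, col))
  sweep(low, 2, mu, "+")[keep, , drop = FALSE]
}

#' Write / read EMA trajectories as tab-separated text
#'
#' One frame per row: time in seconds, x/y/z per sensor in canonical order,
#' then the 6 reference-pose values (zeros when head-corrected). `#` header
#' lines carry the rate and sensor names.
#'
#' @param rec an [ema_recording].
#' @param path file path.
#' @return `path` invisibly, or an [ema_recording].
#' @export
write_ema <- function(rec, path) {
  pose <- rec$reference_pose
  corrected <- is.null(pose)
  if (corrected) pose <- matrix(0, nrow(rec$coords), 6)
  hdr <- c("# emasynth ema v1",
           sprintf("# rate\t%g", rec$rate),
           sprintf("# sensors\t%s", paste(rec$sensors, collapse = "\t")),
           sprintf("# head_corrected\t%d", as.integer(corrected)))
  m <- cbind(rec$time, rec$coords, pose)
  body <- apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ema
#' @export
read_ema <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_line <- function(key) {
    ln <- grep(paste0("^# ", key, "\t"), hdr, value = TRUE)
    if (length(ln) != 1) stop("missing header '", key, "' in ", path)
    strsplit(ln, "\t")[[1]][-1]
  }
  rate <- as.numeric(get_line("rate"))
  sensors <- get_line("sensors")
  corrected <- as.integer(get_line("head_corrected")) == 1L
  body <- lines[!grepl("^#", lines)]
  m <- do.call(rbind, lapply(strsplit(body, "\t"), as.numeric))
  nc <- 3 * length(sensors)
  ema_recording(m[, 1 + seq_len(nc), drop = FALSE], rate, sensors,
                reference_pose = if (corrected) NULL else
                  m[, 1 + nc + 1:6, drop = FALSE],
                time = m[, 1])
}
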