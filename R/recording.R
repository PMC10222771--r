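#' Construct a multimodal recording
#'
#' Container for one recording session: ambient channels, inertial channels,
#' an ordered frame/mask sequence, per-sample labels per modality timeline,
#' and the sampling rate of each modality. Any modality may be absent (empty
#' track); downstream stages zero-pad its features.
#'
#' @param ambient numeric matrix, samples x channels (sensor units), or NULL.
#' @param ambient_fs ambient sampling rate in Hz.
#' @param inertial numeric matrix, samples x channels (m/s^2, rad/s), or NULL.
#' @param inertial_fs inertial sampling rate in Hz.
#' @param quaternions optional samples x 4 orientation quaternion matrix.
#' @param frames list of grayscale images or binary masks (matrices in
#'   \code{[0,1]}, rows = y, cols = x), possibly empty.
#' @param frame_fs frame rate in Hz.
#' @param labels named list with integer class-id vectors \code{ambient},
#'   \code{inertial}, \code{frames}, each aligned with its sample track.
#' @param session_id character identifier.
#' @return An object of class \code{multimodal_recording}.
#' @export
multimodal_recording <- function(ambient = NULL, ambient_fs = 10,
                                 inertial = NULL, inertial_fs = 25,
                                 quaternions = NULL,
                                 frames = list(), frame_fs = 10,
                                 labels = list(), session_id = "session") {
  assert_that(ambient_fs > 0 && inertial_fs > 0 && frame_fs > 0,
              "all sampling rates must be > 0")
  ambient  <- if (is.null(ambient)) matrix(numeric(0), 0, 0) else as.matrix(ambient)
  inertial <- if (is.null(inertial)) matrix(numeric(0), 0, 0) else as.matrix(inertial)
  if (!is.null(quaternions)) {
    quaternions <- as.matrix(quaternions)
    assert_that(ncol(quaternions) == 4, "quaternions must have 4 columns")
  }
  for (m in c("ambient", "inertial", "frames")) {
    n <- switch(m, ambient = nrow(ambient), inertial = nrow(inertial),
                frames = length(frames))
    if (!is.null(labels[[m]]))
      assert_that(length(labels[[m]]) == n,
                  sprintf("label track '%s' must match its sample track (%d)", m, n))
  }
  if (length(frames) > 1) {
    dims <- vapply(frames, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      mf_format_error("frame dimensions must be constant within a session")
  }
  structure(list(ambient = ambient, ambient_fs = ambient_fs,
                 inertial = inertial, inertial_fs = inertial_fs,
                 quaternions = quaternions,
                 frames = frames, frame_fs = frame_fs,
                 labels = labels, session_id = session_id),
            class = "multimodal_recording")
}

#' @export
print.multimodal_recording <- function(x, ...) {
  cat(sprintf("<multimodal_recording '%s'>\n", x$session_id))
  cat(sprintf("  ambient : %d samples x %d channels @ %g Hz\n",
              nrow(x$ambient), ncol(x$ambient), x$ambient_fs))
  cat(sprintf("  inertial: %d samples x %d channels @ %g Hz%s\n",
              nrow(x$inertial), ncol(x$inertial), x$inertial_fs,
              if (is.null(x$quaternions)) "" else " (+quaternions)"))
  cat(sprintf("  frames  : %d @ %g Hz\n", length(x$frames), x$frame_fs))
  invisible(x)
}

#' Filter / preprocessing configuration
#'
#' @param butterworth_order Butterworth low-pass order (default 3).
#' @param butterworth_cutoff cutoff frequency in Hz (default 5, the upper end
#'   of the ADL band; ambient switch signals are low-frequency).
#' @param wavelet_name mother wavelet for inertial shrinkage (only "db4").
#' @param wavelet_levels decomposition depth (default 3).
#' @param wavelet_threshold_rule "universal-soft" or "universal-hard".
#' @param background_quantile per-pixel quantile for the background model
#'   (0.5 = median).
#' @param mask_threshold foreground threshold in 8-bit intensity units
#'   (default 25; applied as \code{mask_threshold/255} on \code{[0,1]} images).
#' @param morph_radius radius in pixels of the opening/closing element.
#' @return A \code{filter_config} list.
#' @export
filter_config <- function(butterworth_order = 3, butterworth_cutoff = 5,
                          wavelet_name = "db4", wavelet_levels = 3,
                          wavelet_threshold_rule = c("universal-soft", "universal-hard"),
                          background_quantile = 0.5, mask_threshold = 25,
                          morph_radius = 2) {
  wavelet_threshold_rule <- match.arg(wavelet_threshold_rule)
  assert_that(butterworth_order >= 1, "butterworth_order must be >= 1")
  assert_that(butterworth_cutoff > 0, "butterworth_cutoff must be > 0")
  assert_that(wavelet_levels >= 1, "wavelet_levels must be >= 1")
  assert_that(background_quantile > 0 && background_quantile < 1,
              "background_quantile must be in (0,1)")
  structure(list(butterworth_order = butterworth_order,
                 butterworth_cutoff = butterworth_cutoff,
                 wavelet_name = wavelet_name,
                 wavelet_levels = wavelet_levels,
                 wavelet_threshold_rule = wavelet_threshold_rule,
                 background_quantile = background_quantile,
                 mask_threshold = mask_threshold,
                 morph_radius = morph_radius),
            class = "filter_config")
}

# Read a timestamped CSV stream: column 1 `timestamp` (s), remaining columns
# channels. Rows are sorted by time, exact-duplicate timestamps deduplicated
# (first kept), and resampled to `fs` by linear interpolation only when the
# observed spacing is irregular.
read_stream_csv <- function(path, fs) {
  if (!file.exists(path)) mf_input_error(sprintf("cannot read file '%s'", path))
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) mf_input_error(
                   sprintf("cannot parse CSV '%s': %s", path, conditionMessage(e))))
  if (ncol(df) < 2 || names(df)[1] != "timestamp")
    mf_format_error(sprintf("'%s' must have a 'timestamp' column plus >=1 data column", path))
  ord <- order(df$timestamp)
  df <- df[ord, , drop = FALSE]
  dup <- duplicated(df$timestamp)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    message(sprintf("read_stream_csv: dropped %d duplicated timestamp row(s) in '%s'",
                    n_dup, basename(path)))
    df <- df[!dup, , drop = FALSE]
  }
  ts <- df$timestamp
  if (any(diff(ts) <= 0))
    mf_format_error(sprintf("non-monotone timestamps in '%s' after sort/dedup", path))
  x <- as.matrix(df[, -1, drop = FALSE])
  # regular grid check against the declared rate
  if (length(ts) > 2) {
    d <- diff(ts)
    if (max(d) - min(d) > 0.01 / fs) {
      grid <- seq(ts[1], ts[length(ts)], by = 1 / fs)
      x <- apply(x, 2, function(col) stats::approx(ts, col, xout = grid)$y)
      ts <- grid
    }
  }
  list(data = x, timestamps = ts, n_duplicates = n_dup)
}

#' Load a multimodal recording from disk
#'
#' Reads the on-disk session layout: ambient and inertial CSV streams (first
#' column \code{timestamp} in seconds, remaining columns channels, header row
#' required), a directory of zero-padded numbered PNG frames (lexicographic =
#' temporal order), and a labels CSV with columns \code{timestamp,label}.
#' Irregular timelines are resampled to the declared rates by linear
#' interpolation; a missing modality yields an empty track.
#'
#' @param ambient_path,inertial_path CSV file paths (or NULL for absent).
#' @param frames_path directory of PNG frames (or NULL/absent directory).
#' @param labels_path labels CSV path (or NULL; labels then empty).
#' @param rates named list/vector with \code{ambient}, \code{inertial},
#'   \code{frames} sampling rates in Hz.
#' @param session_id session identifier (default: basename of ambient path).
#' @return A [multimodal_recording].
#' @export
load_recording <- function(ambient_path = NULL, inertial_path = NULL,
                           frames_path = NULL, labels_path = NULL,
                           rates = list(ambient = 10, inertial = 25, frames = 10),
                           session_id = NULL) {
  amb <- ine <- NULL
  amb_ts <- ine_ts <- NULL
  quat <- NULL
  if (!is.null(ambient_path)) {
    s <- read_stream_csv(ambient_path, rates$ambient)
    amb <- s$data; amb_ts <- s$timestamps
  }
  if (!is.null(inertial_path)) {
    s <- read_stream_csv(inertial_path, rates$inertial)
    ine <- s$data; ine_ts <- s$timestamps
    qcols <- grepl("^quat_", colnames(ine))
    if (sum(qcols) == 4) {
      quat <- ine[, qcols, drop = FALSE]
      ine <- ine[, !qcols, drop = FALSE]
    }
  }
  frames <- list()
  if (!is.null(frames_path) && dir.exists(frames_path)) {
    ff <- sort(list.files(frames_path, pattern = "\\.png$", full.names = TRUE))
    frames <- lapply(ff, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3) img <- img[, , 1]
      img
    })
  }
  labels <- list()
  if (!is.null(labels_path) && file.exists(labels_path)) {
    lab <- utils::read.csv(labels_path)
    lab_at <- function(ts) {
      if (is.null(ts)) return(NULL)
      idx <- findInterval(ts, lab$timestamp)
      as.integer(lab$label[pmax(idx, 1L)])
    }
    labels$ambient  <- lab_at(amb_ts)
    labels$inertial <- lab_at(ine_ts)
    if (length(frames) > 0)
      labels$frames <- lab_at((seq_along(frames) - 1) / rates$frames)
  }
  if (is.null(session_id))
    session_id <- if (!is.null(ambient_path)) {
      sub("\\.[^.]*$", "", basename(ambient_path))
    } else "session"
  multimodal_recording(ambient = amb, ambient_fs = rates$ambient,
                       inertial = ine, inertial_fs = rates$inertial,
                       quaternions = quat,
                       frames = frames, frame_fs = rates$frames,
                       labels = labels, session_id = session_id)
}
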