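#' Segment a signal into fixed-length windows
#'
#' Cuts a multichannel signal into windows of \code{window_s} seconds
#' (default 4 s). The step between window starts is
#' \code{window * (1 - overlap)} samples; a trailing partial window is
#' discarded. Each window is labelled by majority vote over its per-sample
#' labels; ties go to the smaller class id.
#'
#' @param x numeric vector or samples x channels matrix.
#' @param fs sampling rate in Hz.
#' @param labels optional integer per-sample class ids (same length as rows).
#' @param window_s window duration in seconds (default 4).
#' @param overlap fractional overlap in \code{[0, 1)} (default 0).
#' @return List of \code{signal_window} objects, each with \code{data}
#'   (window_samples x channels), \code{start_time} (s), \code{duration} (s)
#'   and \code{label} (majority class id or NA). A signal shorter than one
#'   window yields an empty list.
#' @export
segment_windows <- function(x, fs, labels = NULL, window_s = 4, overlap = 0) {
  assert_that(overlap >= 0 && overlap < 1, "overlap must be in [0, 1)")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(xm)
  w <- round(fs * window_s)
  assert_that(w >= 2, "fs * window_s must be >= 2 samples")
  if (!is.null(labels))
    assert_that(length(labels) == n, "labels must have one entry per sample")
  if (n < w) {
    message(sprintf("segment_windows: signal (%d samples) shorter than one window (%d); empty result", n, w))
    return(list())
  }
  step <- max(1L, round(w * (1 - overlap)))
  starts <- seq(1L, n - w + 1L, by = step)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    lab <- NA_integer_
    if (!is.null(labels)) lab <- majority_label(labels[s:(s + w - 1L)])
    structure(list(data = xm[s:(s + w - 1L), , drop = FALSE],
                   start_time = (s - 1L) / fs,
                   duration = window_s,
                   label = lab,
                   window_index = i),
              class = "signal_window")
  })
}

# majority vote; ties broken toward the smaller class id
majority_label <- function(labels) {
  labels <- labels[!is.na(labels)]
  if (length(labels) == 0) return(NA_integer_)
  tab <- table(labels)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

#' Background subtraction over a frame sequence
#'
#' Builds a static background as the per-pixel quantile (default median)
#' across all frames, thresholds the absolute difference of each frame from
#' it, and cleans the resulting binary mask by morphological opening followed
#' by closing with a disc of radius \code{morph_radius}.
#'
#' @param frames list of grayscale matrices in \code{[0,1]}, constant size,
#'   at least 3 frames.
#' @param cfg a [filter_config]; uses \code{background_quantile},
#'   \code{mask_threshold} (8-bit units) and \code{morph_radius}.
#' @return List of binary (0/1) mask matrices, same dimensions as the frames.
#' @export
subtract_background <- function(frames, cfg = filter_config()) {
  assert_that(length(frames) >= 3, "background subtraction needs >= 3 frames")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    mf_format_error("inconsistent frame sizes")
  # the background model uses at most 64 evenly spaced frames; per-pixel
  # quantiles stabilize well before that and the cost is linear in frames
  sel <- if (length(frames) > 64)
    frames[round(seq(1, length(frames), length.out = 64))] else frames
  arr <- array(unlist(sel), dim = c(dims[1, 1], dims[2, 1], length(sel)))
  bg <- apply(arr, c(1, 2), stats::quantile,
              probs = cfg$background_quantile, names = FALSE, type = 7)
  thr <- cfg$mask_threshold / 255
  brush <- EBImage::makeBrush(2 * cfg$morph_radius + 1, shape = "disc")
  lapply(frames, function(f) {
    m <- (abs(f - bg) > thr) * 1
    m <- EBImage::closing(EBImage::opening(m, brush), brush)
    matrix(as.numeric(m > 0.5), nrow = nrow(f))
  })
}
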