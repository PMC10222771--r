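#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-\code{order} Butterworth low-pass forward and backward
#' (zero phase), after odd-reflection edge padding so that DC level and edge
#' samples are preserved. The effective magnitude response is the squared
#' single-pass response, so the gain at the cutoff is \eqn{|H(f_c)|^2 = 1/2}.
#'
#' @param x numeric vector or samples x channels matrix.
#' @param fs sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz; must be below \code{fs/2}.
#' @param order filter order (default 3).
#' @return Filtered signal, same shape as \code{x}.
#' @export
butterworth_lowpass <- function(x, fs, cutoff, order = 3) {
  assert_that(cutoff > 0 && cutoff < fs / 2,
              sprintf("cutoff (%g Hz) must be in (0, fs/2 = %g Hz)", cutoff, fs / 2))
  assert_that(order >= 1, "order must be >= 1")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(xm)
  assert_that(n > 3 * (order + 1),
              sprintf("signal too short (%d samples) for order-%d zero-phase filtering", n, order))
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd-reflection padding tames filtfilt's zero-state startup transient;
  # ten cutoff periods lets it decay below 1e-6 even at low normalized cutoffs
  pad <- min(n - 1, max(10 * round(fs / cutoff), 9 * (order + 1)))
  out <- apply(xm, 2, function(col) {
    ext <- c(2 * col[1] - col[(pad + 1):2],
             col,
             2 * col[n] - col[(n - 1):(n - pad)])
    y <- signal::filtfilt(bf, ext)
    y[(pad + 1):(pad + n)]
  })
  out <- matrix(out, nrow = n)
  dimnames(out) <- dimnames(xm)
  if (vec) drop(out) else out
}

## ---- Daubechies-4 discrete wavelet transform (periodized) -----------------
## Written here because the denoising primitive (decompose, universal
## threshold on details, reconstruct) is part of the pipeline's preprocessing
## contract; coefficients are the standard 8-tap db4 pair.

db4_lowpass <- c(
   0.230377813308855230, 0.714846570552541500,
   0.630880767929590400, -0.027983769416983850,
  -0.187034811718881140, 0.030841381835986965,
   0.032883011666982945, -0.010597401784997278)

db4_highpass <- {
  h <- db4_lowpass
  L <- length(h)
  rev(h) * (-1)^(seq_len(L) - 1)
}

# one periodized analysis step: x (even length) -> list(approx, detail)
dwt_step <- function(x, h, g) {
  n <- length(x)
  L <- length(h)
  idx <- outer(seq(1, n, by = 2), 0:(L - 1), "+")  # x[k], x[k+1], ...
  idx <- ((idx - 1) %% n) + 1
  xm <- matrix(x[idx], nrow = n / 2)
  list(approx = as.numeric(xm %*% h), detail = as.numeric(xm %*% g))
}

# inverse of dwt_step (orthonormal periodized filter bank)
idwt_step <- function(approx, detail, h, g) {
  n2 <- length(approx)
  n <- 2 * n2
  L <- length(h)
  x <- numeric(n)
  pos <- outer(seq(1, n, by = 2), 0:(L - 1), "+")
  pos <- ((pos - 1) %% n) + 1
  for (k in seq_len(n2)) {
    p <- pos[k, ]
    x[p] <- x[p] + approx[k] * h + detail[k] * g
  }
  x
}

# multi-level periodized db4 DWT; x length must be divisible by 2^levels
dwt_db4 <- function(x, levels) {
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    s <- dwt_step(a, db4_lowpass, db4_highpass)
    details[[l]] <- s$detail
    a <- s$approx
  }
  list(approx = a, details = details)
}

idwt_db4 <- function(decomp) {
  a <- decomp$approx
  for (l in rev(seq_along(decomp$details)))
    a <- idwt_step(a, decomp$details[[l]], db4_lowpass, db4_highpass)
  a
}

# pad x at the end by even (mirror) reflection to a multiple of 2^levels
pad_to_multiple <- function(x, m) {
  n <- length(x)
  r <- (m - n %% m) %% m
  if (r == 0) return(list(x = x, n = n))
  refl <- x[n:max(1, n - r + 1)]
  refl <- rep_len(refl, r)
  list(x = c(x, refl), n = n)
}

# VisuShrink-style universal threshold denoising of one channel
wavelet_denoise_channel <- function(x, levels, rule) {
  p <- pad_to_multiple(x, 2^levels)
  dec <- dwt_db4(p$x, levels)
  d1 <- dec$details[[1]]
  sigma <- stats::median(abs(d1)) / 0.6745
  thr <- sigma * sqrt(2 * log(length(p$x)))
  dec$details <- lapply(dec$details, function(d) {
    if (rule == "universal-soft") sign(d) * pmax(abs(d) - thr, 0)
    else d * (abs(d) > thr)
  })
  idwt_db4(dec)[seq_len(p$n)]
}

#' Wavelet shrinkage denoising of inertial channels with quaternion renormalization
#'
#' Each inertial channel is decomposed with a periodized db4 wavelet transform,
#' the detail coefficients are thresholded with the universal (VisuShrink)
#' threshold \eqn{\sigma\sqrt{2\log n}} (\eqn{\sigma} estimated from the
#' finest-level details via the median absolute deviation), and the channel is
#' reconstructed. Orientation quaternion rows, when present, are renormalized
#' to unit norm.
#'
#' @param inertial samples x channels numeric matrix.
#' @param quaternions optional samples x 4 matrix.
#' @param cfg a [filter_config].
#' @return List with elements \code{inertial} (denoised matrix, same shape)
#'   and \code{quaternions} (unit-norm rows, or NULL).
#' @export
wavelet_quaternion_filter <- function(inertial, quaternions = NULL,
                                      cfg = filter_config()) {
  inertial <- as.matrix(inertial)
  assert_that(nrow(inertial) > 0, "inertial signal must be non-empty")
  assert_that(nrow(inertial) >= 2^cfg$wavelet_levels,
              sprintf("wavelet_levels = %d infeasible for %d samples",
                      cfg$wavelet_levels, nrow(inertial)))
  out <- apply(inertial, 2, wavelet_denoise_channel,
               levels = cfg$wavelet_levels, rule = cfg$wavelet_threshold_rule)
  out <- matrix(out, nrow = nrow(inertial), dimnames = dimnames(inertial))
  q <- NULL
  if (!is.null(quaternions)) {
    quaternions <- as.matrix(quaternions)
    nrm <- sqrt(rowSums(quaternions^2))
    bad <- which(nrm < 1e-8)
    if (length(bad) > 0)
      mf_stop(sprintf("degenerate orientation: quaternion row %d has norm < 1e-8", bad[1]),
              "momofuse_degenerate_orientation_error")
    q <- quaternions / nrm
  }
  list(inertial = out, quaternions = q)
}
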