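#' Pearson correlation between two window variables
#'
#' Direct evaluation of
#' \eqn{PC = \sum (g_x-\bar g)(h_x-\bar h) / \sqrt{\sum (g_x-\bar g)^2 \sum (h_x-\bar h)^2}}.
#' When either input is constant the correlation is undefined; 0 is returned
#' with a \code{degenerate} attribute set.
#'
#' @param g,h numeric vectors of equal length >= 2.
#' @return Scalar in \code{[-1, 1]} (attribute \code{degenerate = TRUE} when
#'   either input is constant).
#' @export
pearson_correlation <- function(g, h) {
  assert_that(length(g) == length(h), "g and h must have equal length")
  assert_that(length(g) >= 2, "need at least 2 samples")
  gd <- g - mean(g); hd <- h - mean(h)
  den <- sqrt(sum(gd^2) * sum(hd^2))
  if (den == 0) return(structure(0, degenerate = TRUE))
  sum(gd * hd) / den
}

#' Windowed Pearson-correlation activity gate for ambient channels
#'
#' Computes the pairwise Pearson correlation over all unordered channel pairs
#' of a window, averages the absolute values, and flags an "action performed"
#' when that average exceeds the threshold (default 0.04). The feature vector
#' is the upper-triangle correlations followed by the mean absolute
#' correlation and the flag.
#'
#' For a single-channel window the gate falls back to the lag-1
#' autocorrelation of the channel (logged).
#'
#' @param window a \code{signal_window} (from [segment_windows()]) or a
#'   samples x channels matrix.
#' @param threshold gate threshold on the mean absolute correlation.
#' @return List of class \code{pearson_gate}: \code{pc_matrix} (channels x
#'   channels), \code{mean_abs_pc}, \code{action_flag}, \code{threshold},
#'   \code{features} (named numeric vector).
#' @export
ambient_gate <- function(window, threshold = 0.04) {
  x <- if (inherits(window, "signal_window")) window$data else as.matrix(window)
  k <- ncol(x)
  if (k < 2) {
    message("ambient_gate: single channel; using lag-1 autocorrelation fallback")
    n <- nrow(x)
    pc <- as.numeric(pearson_correlation(x[1:(n - 1), 1], x[2:n, 1]))
    feats <- c(pc_lag1 = pc, mean_abs_pc = abs(pc),
               action_flag = as.numeric(abs(pc) > threshold))
    return(structure(list(pc_matrix = matrix(pc, 1, 1),
                          mean_abs_pc = abs(pc),
                          action_flag = abs(pc) > threshold,
                          threshold = threshold, features = feats),
                     class = "pearson_gate"))
  }
  pcm <- diag(1, k)
  vals <- c(); nms <- c()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    pc <- as.numeric(pearson_correlation(x[, i], x[, j]))
    pcm[i, j] <- pcm[j, i] <- pc
    vals <- c(vals, pc)
    nms <- c(nms, sprintf("pc_ch%d_ch%d", i - 1, j - 1))
  }
  mean_abs <- mean(abs(vals))
  flag <- mean_abs > threshold
  feats <- c(setNames(vals, nms), mean_abs_pc = mean_abs,
             action_flag = as.numeric(flag))
  structure(list(pc_matrix = pcm, mean_abs_pc = mean_abs,
                 action_flag = flag, threshold = threshold, features = feats),
            class = "pearson_gate")
}

#' Linear prediction coefficients by Levinson-Durbin recursion
#'
#' Solves the order-\code{p} autocorrelation normal equations for the
#' forward-prediction model \eqn{x_t \approx \sum_{k=1}^p a_k x_{t-k}}; the
#' resulting prediction-error filter is minimum-phase.
#'
#' @param x numeric signal, length > \code{2p}, not identically zero.
#' @param p prediction order.
#' @return Numeric vector \code{a} of length \code{p}.
#' @export
lpc_coefficients <- function(x, p) {
  n <- length(x)
  assert_that(p >= 1, "order p must be >= 1")
  assert_that(n > 2 * p, sprintf("signal length (%d) must exceed 2p (%d)", n, 2 * p))
  if (all(x == 0) || stats::sd(x) == 0)
    mf_param_error("zero-energy signal: LPC undefined")
  r <- vapply(0:p, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n, numeric(1))
  a <- numeric(p)          # a[k] in the positive prediction convention
  e <- r[1]
  for (m in 1:p) {
    acc <- r[m + 1]
    if (m > 1) acc <- acc - sum(a[1:(m - 1)] * r[m:2])
    k_m <- acc / e
    a_new <- a
    a_new[m] <- k_m
    if (m > 1) a_new[1:(m - 1)] <- a[1:(m - 1)] - k_m * a[(m - 1):1]
    a <- a_new
    e <- e * (1 - k_m^2)
    if (e <= 0) break      # perfectly predictable; remaining orders stay as-is
  }
  a
}

#' Linear prediction cepstral coefficients
#'
#' Cepstral recursion on LPC coefficients \code{a} (order \code{p}),
#' producing \code{d >= p} coefficients:
#' \deqn{c_x = a_x + \sum_{t=1}^{x-1} (t/x)\, c_t\, a_{x-t}, \quad 1 \le x \le p}
#' \deqn{c_x = \sum_{t=1}^{x-1} (t/x)\, c_t\, a_{x-t}, \quad x > p}
#' with \code{a}-indices outside \code{1..p} contributing zero.
#'
#' @param a LPC coefficient vector (length \code{p}).
#' @param p LPC order; must equal \code{length(a)}.
#' @param d number of cepstral coefficients, \code{d >= p}.
#' @return Numeric vector \code{c} of length \code{d}.
#' @export
lpcc <- function(a, p = length(a), d = p) {
  assert_that(length(a) == p, "length(a) must equal p")
  assert_that(d >= p, "d must be >= p")
  cc <- numeric(d)
  for (x in seq_len(d)) {
    s <- 0
    t_hi <- x - 1
    if (t_hi >= 1) {
      t <- seq_len(t_hi)
      ai <- x - t                       # a-index of each term
      ok <- ai >= 1 & ai <= p
      if (any(ok)) s <- sum((t[ok] / x) * cc[t[ok]] * a[ai[ok]])
    }
    cc[x] <- if (x <= p) a[x] + s else s
  }
  cc
}

#' Per-window LPCC features over inertial channels
#'
#' Applies [lpc_coefficients()] then [lpcc()] to each channel of a window and
#' concatenates the cepstra.
#'
#' @param window \code{signal_window} or samples x channels matrix.
#' @param p LPC order (default 10).
#' @param d cepstral count (default 12).
#' @return Named numeric vector of length \code{channels * d}; channels with
#'   zero energy yield zero blocks.
#' @export
lpcc_window_features <- function(window, p = 10, d = 12) {
  x <- if (inherits(window, "signal_window")) window$data else as.matrix(window)
  out <- lapply(seq_len(ncol(x)), function(j) {
    cj <- tryCatch(lpcc(lpc_coefficients(x[, j], p), p, d),
                   momofuse_parameter_error = function(e) numeric(d))
    setNames(cj, sprintf("lpcc_ch%d_c%d", j - 1, seq_len(d)))
  })
  unlist(out)
}

#' Spider-web sampling grid
#'
#' @param rings strictly increasing positive radii.
#' @param spokes integer number of angular spokes (>= 4).
#' @param anchors character vector of skeleton point names to anchor webs at
#'   (default: all 12).
#' @return A \code{spider_web_config} list.
#' @export
spider_web_config <- function(rings = c(8, 16, 32), spokes = 16,
                              anchors = skeleton_point_names()) {
  assert_that(all(rings > 0) && all(diff(rings) > 0),
              "rings must be strictly increasing positive radii")
  assert_that(spokes >= 4, "spokes must be >= 4")
  structure(list(rings = rings, spokes = as.integer(spokes), anchors = anchors),
            class = "spider_web_config")
}

#' Spider-web intersection points around a centre
#'
#' Point (ring \code{x}, spoke \code{z}) lies at
#' \code{centre + (x cos(2 pi z / Z), x sin(2 pi z / Z))} for
#' \code{z = 0..Z-1}; with the image convention the y axis points downward.
#'
#' @param center length-2 (x, y) coordinate.
#' @param cfg a [spider_web_config()].
#' @return (rings * spokes) x 2 matrix of (x, y) coordinates, ring-major.
#' @export
spider_web_points <- function(center, cfg = spider_web_config()) {
  z <- 0:(cfg$spokes - 1)
  ang <- 2 * pi * z / cfg$spokes
  do.call(rbind, lapply(cfg$rings, function(r)
    cbind(center[1] + r * cos(ang), center[2] + r * sin(ang))))
}

#' Spider local image feature (SLIF) descriptor
#'
#' For each anchor skeleton point, samples binary mask occupancy at every
#' web intersection (off-image samples read 0) and appends the anchor's mean
#' occupancy fraction. Anchors whose skeleton point is missing contribute a
#' zero block.
#'
#' @param mask binary matrix (rows = y, cols = x).
#' @param skeleton a [skeleton_frame] for the same frame.
#' @param cfg a [spider_web_config()].
#' @return Named numeric vector of length
#'   \code{anchors * (rings * spokes + 1)}.
#' @export
slif_descriptor <- function(mask, skeleton, cfg = spider_web_config()) {
  mask <- as.matrix(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- lapply(cfg$anchors, function(an) {
    p <- skeleton$points[an, ]
    nring <- length(cfg$rings)
    nms <- c(sprintf("slif_%s_r%d_z%d", an,
                     rep(seq_len(nring), each = cfg$spokes),
                     rep(0:(cfg$spokes - 1), nring)),
             sprintf("slif_%s_frac", an))
    if (anyNA(p)) return(setNames(numeric(nring * cfg$spokes + 1), nms))
    pts <- spider_web_points(p, cfg)
    xi <- round(pts[, 1]); yi <- round(pts[, 2])
    inside <- xi >= 1 & xi <= nc & yi >= 1 & yi <= nr
    occ <- numeric(nrow(pts))
    occ[inside] <- mask[cbind(yi[inside], xi[inside])]
    setNames(c(occ, mean(occ)), nms)
  })
  unlist(out)
}
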