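#' Construct a skeleton frame
#'
#' @param points 12 x 2 matrix of (x, y) pixel coordinates in the canonical
#'   order of [skeleton_point_names()]; missing points as NA rows.
#' @param confidence 12 values in \code{[0,1]}.
#' @param frame_index integer frame index.
#' @return Object of class \code{skeleton_frame}.
#' @export
skeleton_frame <- function(points, confidence = rep(1, 12), frame_index = 1L) {
  points <- as.matrix(points)
  assert_that(nrow(points) == 12 && ncol(points) == 2,
              "points must be a 12 x 2 matrix")
  assert_that(all(confidence >= 0 & confidence <= 1, na.rm = TRUE),
              "confidence must lie in [0,1]")
  rownames(points) <- skeleton_point_names()
  structure(list(points = points,
                 confidence = setNames(as.numeric(confidence), skeleton_point_names()),
                 frame_index = as.integer(frame_index)),
            class = "skeleton_frame")
}

#' Extract a 12-point skeleton from a binary silhouette
#'
#' Deterministic geometric procedure on the largest connected foreground
#' component: the torso is the thickness-weighted centre of mass (centroid
#' weighted by the squared distance transform, dominated by the fattest body
#' region); the head is the first local maximum of the
#' row-wise distance-transform profile from the top (the head's medial
#' centre); shoulders are the left/right silhouette extrema in a row band one
#' fifth of body height below the top of the head, refined to the local
#' medial axis;
#' wrists are the points farthest from the torso centre in the left/right
#' mid-body band; ankles are the lowest foreground points on each side below
#' the hip line; elbows and knees are the midpoints shoulder-wrist and
#' hip-ankle. Per-point confidence is the distance-transform value at the
#' point relative to the component maximum, clamped to \code{[0,1]}.
#'
#' "Left"/"right" follow image-x order (single fixed camera convention).
#'
#' @param mask binary matrix (rows = y, cols = x), values 0/1.
#' @param min_area minimum foreground component area in pixels (default 200).
#' @param frame_index frame index stored in the result.
#' @return A [skeleton_frame].
#' @export
extract_skeleton <- function(mask, min_area = 200, frame_index = 1L) {
  mask <- (as.matrix(mask) > 0.5) * 1
  if (sum(mask) == 0)
    mf_stop("extraction failed: empty mask", "momofuse_extraction_error")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  if (max(sizes) < min_area)
    mf_stop(sprintf("extraction failed: largest component %d px < %d px",
                    max(sizes), min_area), "momofuse_extraction_error")
  top <- which(sizes == max(sizes))
  if (length(top) > 1)
    mf_stop("extraction failed: multiple equal-size foreground components",
            "momofuse_ambiguity_error")
  comp <- (lab == top) * 1
  dt <- as.matrix(EBImage::distmap(comp))
  dmax <- max(dt)

  fg <- which(comp == 1, arr.ind = TRUE)   # (row = y, col = x)
  ys <- fg[, 1]; xs <- fg[, 2]
  y0 <- min(ys); y1 <- max(ys)
  H <- y1 - y0 + 1

  # torso: thickness-weighted centre of mass (distance transform squared);
  # dominated by the fat torso region, robust to mask erosion/dilation
  wdt <- dt^2
  torso <- c(sum(col(dt) * wdt), sum(row(dt) * wdt)) / sum(wdt)

  # head: first local maximum, from the top, of the row-wise profile of the
  # distance transform (restricted to the upper two thirds)
  rows_upper <- y0:(y0 + floor(2 * H / 3))
  rowmax <- vapply(rows_upper, function(r) max(dt[r, ]), numeric(1))
  head_pt <- NULL
  for (i in seq(2, length(rowmax) - 1)) {
    if (rowmax[i] >= 2 &&
        rowmax[i] >= rowmax[i - 1] && rowmax[i] > rowmax[i + 1]) {
      r <- rows_upper[i]
      head_pt <- c(which.max(dt[r, ]), r)
      break
    }
  }
  if (is.null(head_pt)) {                  # monotone profile: fall back
    r <- rows_upper[which.max(rowmax)]
    head_pt <- c(which.max(dt[r, ]), r)
  }

  # hip line: bottom of the thick torso region
  thick <- which(dt >= 0.5 * dmax, arr.ind = TRUE)
  hip_y <- max(thick[, 1])
  hip_row <- thick[thick[, 1] == hip_y, , drop = FALSE]
  hip_half <- max(1, (max(hip_row[, 2]) - min(hip_row[, 2])) / 2)
  hip_l <- c(torso[1] - hip_half, hip_y)
  hip_r <- c(torso[1] + hip_half, hip_y)

  # shoulders: silhouette extrema in the band head_y + H/5, refined inward to
  # the local medial axis (max distance transform)
  band_y <- round(y0 + H / 5)
  band_rows <- max(y0, band_y - 2):min(y1, band_y + 2)
  in_band <- fg[ys %in% band_rows, , drop = FALSE]
  refine <- function(x, y, dir) {
    win_x <- x + dir * (0:6)
    win_x <- win_x[win_x >= 1 & win_x <= ncol(comp)]
    cand <- expand.grid(y = band_rows, x = win_x)
    v <- dt[cbind(cand$y, cand$x)]
    best <- which.max(v)
    c(cand$x[best], cand$y[best])
  }
  if (nrow(in_band) > 0) {
    xl <- min(in_band[, 2]); yl <- in_band[which.min(in_band[, 2]), 1]
    xr <- max(in_band[, 2]); yr <- in_band[which.max(in_band[, 2]), 1]
    sho_l <- refine(xl, yl, +1)
    sho_r <- refine(xr, yr, -1)
  } else {
    sho_l <- sho_r <- c(NA_real_, NA_real_)
  }

  # wrists: farthest foreground point from the torso centre on each side,
  # within the mid-body band (below the shoulders, above the hip line)
  y_top <- min(c(sho_l[2], sho_r[2]), na.rm = TRUE) + 3
  band <- ys > y_top & ys <= hip_y
  side_extreme <- function(sel) {
    if (!any(sel)) return(c(NA_real_, NA_real_))
    px <- xs[sel]; py <- ys[sel]
    d2 <- (px - torso[1])^2 + (py - torso[2])^2
    i <- which.max(d2)
    c(px[i], py[i])
  }
  wri_l <- side_extreme(band & xs < torso[1])
  wri_r <- side_extreme(band & xs >= torso[1])

  # ankles: lowest point per side below the hip line (tie: outermost)
  lowest <- function(sel, outer_dir) {
    if (!any(sel)) return(c(NA_real_, NA_real_))
    px <- xs[sel]; py <- ys[sel]
    ymax <- max(py)
    cand_x <- px[py == ymax]
    x <- if (outer_dir < 0) min(cand_x) else max(cand_x)
    c(x, ymax)
  }
  ank_l <- lowest(ys > hip_y & xs < torso[1], -1)
  ank_r <- lowest(ys > hip_y & xs >= torso[1], +1)

  midpoint <- function(a, b) (a + b) / 2
  elb_l <- midpoint(sho_l, wri_l)
  elb_r <- midpoint(sho_r, wri_r)
  kne_l <- midpoint(hip_l, ank_l)
  kne_r <- midpoint(hip_r, ank_r)

  pts <- rbind(head_pt, sho_l, sho_r, elb_l, elb_r, wri_l, wri_r,
               torso, kne_l, kne_r, ank_l, ank_r)
  conf <- apply(pts, 1, function(p) {
    if (anyNA(p)) return(0)
    x <- min(max(round(p[1]), 1), ncol(comp))
    y <- min(max(round(p[2]), 1), nrow(comp))
    min(max(dt[y, x] / dmax, 0), 1)
  })
  skeleton_frame(pts, conf, frame_index)
}

#' Scaled Euclidean distance between a detected point and its ground truth
#'
#' Computes \eqn{D = \sqrt{\sum_{n=1}^{M} (X_n S_n - Y_n S_n)^2}} over the
#' \code{M} coordinate components; with unit scales this is the plain
#' Euclidean pixel distance. The per-component scale \code{S} supports
#' resolution normalization (e.g. evaluating 320x240 detections on the
#' 640x480 scale with \code{S = 2}).
#'
#' @param X,Y numeric coordinate vectors of equal length.
#' @param S positive scale vector (recycled; default 1).
#' @return Non-negative distance.
#' @export
point_distance <- function(X, Y, S = 1) {
  assert_that(length(X) == length(Y), "X and Y must have the same dimension")
  S <- rep_len(S, length(X))
  assert_that(all(S > 0), "scales must be positive")
  sqrt(sum((X * S - Y * S)^2))
}

# internal: frames x 12 matrix of detection distances (NA detection -> Inf)
skeleton_distances <- function(detected, truth, S = 1) {
  assert_that(length(detected) == length(truth) && length(detected) > 0,
              "detected and truth sequences must align frame-by-frame",
              error = function(m) mf_stop(m, "momofuse_evaluation_error"))
  t(vapply(seq_along(detected), function(i) {
    det <- detected[[i]]$points
    tru <- as.matrix(truth[[i]])
    vapply(1:12, function(j) {
      if (anyNA(det[j, ]) || anyNA(tru[j, ])) return(Inf)
      point_distance(det[j, ], tru[j, ], S)
    }, numeric(1))
  }, numeric(12)))
}

#' Per-point skeleton recognition accuracy
#'
#' A point is recognized in a frame when its distance from ground truth is at
#' most \code{threshold} (default 15 pixels, the 640x480 operating point).
#' Missing detections count as failures.
#'
#' @param detected list of [skeleton_frame] objects.
#' @param truth list of 12 x 2 ground-truth coordinate matrices, aligned by
#'   frame index.
#' @param threshold recognition threshold in pixels (default 15).
#' @param S per-coordinate scale passed to [point_distance()].
#' @return List with \code{per_point} (named accuracy vector over the 12
#'   points), \code{mean} (their unweighted average) and \code{mean_distance}
#'   (mean finite distance over all points and frames).
#' @export
recognition_accuracy <- function(detected, truth, threshold = 15, S = 1) {
  D <- skeleton_distances(detected, truth, S)
  per_point <- colMeans(D <= threshold)
  names(per_point) <- skeleton_point_names()
  list(per_point = per_point,
       mean = mean(per_point),
       mean_distance = mean(D[is.finite(D)]))
}

#' Skeleton point confidence table
#'
#' One row per skeleton point: mean detection confidence, mean distance from
#' ground truth, and recognition accuracy at the threshold; a final row of
#' unweighted column means (reported at 2 decimals, like the per-dataset
#' keypoint summary tables this mirrors).
#'
#' @inheritParams recognition_accuracy
#' @return data.frame with columns \code{point}, \code{confidence},
#'   \code{distance}, \code{accuracy}; last row \code{"mean"} holds column
#'   means rounded to 2 decimals.
#' @export
confidence_table <- function(detected, truth, threshold = 15, S = 1) {
  D <- skeleton_distances(detected, truth, S)
  conf <- rowMeans(vapply(detected, function(f) f$confidence, numeric(12)))
  dist <- apply(D, 2, function(col) mean(col[is.finite(col)]))
  acc <- colMeans(D <= threshold)
  tab <- data.frame(point = skeleton_point_names(),
                    confidence = conf, distance = dist, accuracy = acc,
                    row.names = NULL)
  rbind(tab, data.frame(point = "mean",
                        confidence = round(mean(conf), 2),
                        distance = round(mean(dist, na.rm = TRUE), 2),
                        accuracy = round(mean(acc), 2)))
}
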