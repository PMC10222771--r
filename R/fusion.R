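#' Align per-window features from the three modalities and fuse
#'
#' Ambient and motion feature tables are joined on the window index; vision
#' features, computed per frame, are assigned to the motion window containing
#' their timestamp and mean-pooled within it. A modality absent for a window
#' contributes a zero-filled span (flagged). The result is one fused vector
#' per retained window, with the (ambient, motion, vision) spans recorded.
#'
#' @param ambient_feats windows x dims matrix (rownames/order = window index),
#'   or NULL for an absent modality.
#' @param motion_feats windows x dims matrix, or NULL.
#' @param vision_feats frames x dims matrix, or NULL.
#' @param vision_times frame timestamps in seconds (length = rows of
#'   \code{vision_feats}).
#' @param window_starts window start times in seconds (one per window).
#' @param window_s window duration in seconds (default 4).
#' @param labels per-window class ids.
#' @return Object of class \code{fused_features}: \code{x} (windows x dims
#'   matrix), \code{spans} (list of index ranges per modality),
#'   \code{labels}, \code{missing} (windows x 3 logical).
#' @export
align_and_fuse <- function(ambient_feats = NULL, motion_feats = NULL,
                           vision_feats = NULL, vision_times = NULL,
                           window_starts, window_s = 4, labels = NULL) {
  nw <- length(window_starts)
  if (nw == 0) mf_stop("zero overlapping windows across modalities",
                       "momofuse_fusion_error")
  fix <- function(tab, d_fallback = 1) {
    if (is.null(tab)) matrix(0, nw, 0) else {
      tab <- as.matrix(tab)
      assert_that(nrow(tab) == nw, "per-window table must have one row per window")
      tab
    }
  }
  amb <- fix(ambient_feats)
  mot <- fix(motion_feats)
  missing <- matrix(FALSE, nw, 3,
                    dimnames = list(NULL, c("ambient", "motion", "vision")))
  missing[, 1] <- is.null(ambient_feats)
  missing[, 2] <- is.null(motion_feats)
  if (!is.null(vision_feats)) {
    vision_feats <- as.matrix(vision_feats)
    assert_that(length(vision_times) == nrow(vision_feats),
                "vision_times must align with vision_feats rows")
    dv <- ncol(vision_feats)
    vis <- matrix(0, nw, dv, dimnames = list(NULL, colnames(vision_feats)))
    idx <- findInterval(vision_times, c(window_starts, max(window_starts) + window_s))
    idx[vision_times >= max(window_starts) + window_s] <- NA
    idx[idx < 1] <- NA
    for (w in seq_len(nw)) {
      sel <- which(idx == w)
      if (length(sel) > 0) vis[w, ] <- colMeans(vision_feats[sel, , drop = FALSE])
      else missing[w, 3] <- TRUE
    }
  } else {
    vis <- matrix(0, nw, 0)
    missing[, 3] <- TRUE
  }
  x <- cbind(amb, mot, vis)
  d <- c(ncol(amb), ncol(mot), ncol(vis))
  ends <- cumsum(d)
  spans <- list(ambient = if (d[1]) 1:ends[1] else integer(0),
                motion  = if (d[2]) (ends[1] + 1):ends[2] else integer(0),
                vision  = if (d[3]) (ends[2] + 1):ends[3] else integer(0))
  structure(list(x = x, spans = spans,
                 labels = labels, window_starts = window_starts,
                 missing = missing),
            class = "fused_features")
}

#' Score a candidate feature mask
#'
#' Fitness used by the cross-entropy optimizer. \code{fisher}: ratio of
#' summed between-class to summed within-class scatter over the included
#' dimensions (fast, deterministic; note it is maximized by the single most
#' discriminative dimension, so it suits comparative scoring more than subset
#' recovery). \code{cv_loss}: negative 3-fold stratified error of a
#' nearest-centroid classifier on the included dimensions, averaged over
#' \code{cv_repeats} fold splits (repeated CV keeps single-split luck from
#' rewarding uninformative dimensions), minus a parsimony penalty
#' (\code{size_penalty * included/total}) that pushes equally predictive
#' masks toward smaller ones.
#'
#' @param mask logical/0-1 inclusion vector over feature dimensions.
#' @param features samples x dims matrix.
#' @param labels class ids (>= 2 classes present).
#' @param scorer "fisher" or "cv_loss".
#' @param seed integer seed fixing the cross-validation fold assignment.
#' @param size_penalty parsimony weight for \code{cv_loss} (default 0.45,
#'   sized so that one neutral dimension costs more than the fold-split
#'   luck it can buy on mid-size problems).
#' @param cv_repeats repeated-CV fold splits averaged by \code{cv_loss}
#'   (default 3).
#' @return Scalar score (higher is better).
#' @export
mask_score <- function(mask, features, labels, scorer = c("fisher", "cv_loss"),
                       seed = 1, size_penalty = 0.45, cv_repeats = 3) {
  scorer <- match.arg(scorer)
  mask <- as.logical(mask)
  if (!any(mask)) mf_stop("empty feature mask", "momofuse_scoring_error")
  if (length(unique(labels)) < 2)
    mf_stop("scoring needs >= 2 classes", "momofuse_scoring_error")
  sc <- dim_scatter(features, labels)
  if (scorer == "fisher") {
    sum(sc$sb[mask]) / max(sum(sc$sw[mask]), .Machine$double.eps)
  } else {
    err <- mean(vapply(seq_len(cv_repeats), function(r)
      nearest_centroid_cv_error(features[, mask, drop = FALSE], labels,
                                k = 3, seed = seed + 7919 * (r - 1)),
      numeric(1)))
    -err - size_penalty * sum(mask) / length(mask)
  }
}

# per-dimension between/within-class scatter
dim_scatter <- function(x, labels) {
  labels <- as.factor(labels)
  mu <- colMeans(x)
  sb <- numeric(ncol(x)); sw <- numeric(ncol(x))
  for (cl in levels(labels)) {
    xc <- x[labels == cl, , drop = FALSE]
    mc <- colMeans(xc)
    sb <- sb + nrow(xc) * (mc - mu)^2
    sw <- sw + colSums((xc - matrix(mc, nrow(xc), ncol(xc), byrow = TRUE))^2)
  }
  list(sb = sb, sw = sw)
}

# deterministic stratified fold ids
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  rng <- local({ set.seed(seed); sample.int(1e9, 1) })
  set.seed(rng)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

nearest_centroid_cv_error <- function(x, labels, k = 3, seed = 1) {
  labels <- as.integer(as.factor(labels))
  folds <- stratified_folds(labels, k, seed)
  wrong <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    cls <- sort(unique(labels[tr]))
    cent <- do.call(rbind, lapply(cls, function(cl)
      colMeans(x[tr & labels == cl, , drop = FALSE])))
    xt <- x[te, , drop = FALSE]
    d2 <- outer(rowSums(xt^2), rep(1, length(cls))) -
      2 * xt %*% t(cent) + outer(rep(1, nrow(xt)), rowSums(cent^2))
    pred <- cls[max.col(-d2, ties.method = "first")]
    wrong <- wrong + sum(pred != labels[te])
  }
  wrong / length(labels)
}

#' Cross-entropy-method feature subset selection
#'
#' Maintains a per-dimension Bernoulli inclusion probability vector
#' (initialized at \code{init_prob}). Each iteration samples
#' \code{population} masks, scores them with [mask_score()], takes the best
#' \code{elite_fraction}, re-estimates the inclusion probabilities from the
#' elite masks and blends with the previous vector by \code{smoothing}.
#' Probabilities are clipped to \code{[0.01, 0.99]} to prevent premature
#' absorption. The best mask ever sampled is then polished by deterministic
#' backward elimination (greedily dropping any included dimension whose
#' removal improves the score) -- sampling noise in the early iterations can
#' absorb a few uninformative dimensions alongside the informative ones, and
#' the polish removes exactly those. Fully reproducible from the seed. Three
#' consecutive iterations with all-identical scores trigger an early stop
#' with a warning.
#'
#' @param features samples x dims matrix.
#' @param labels class ids.
#' @param population samples per iteration (default 50, >= 10).
#' @param elite_fraction fraction kept as elites (default 0.2).
#' @param iterations CEM iterations (default 30).
#' @param smoothing blend weight on the new estimate (default 0.7).
#' @param init_prob initial inclusion probability (default 0.5).
#' @param scorer,size_penalty,cv_repeats passed to [mask_score()].
#' @param seed RNG seed.
#' @return Object of class \code{feature_mask}: \code{include} (0/1 vector),
#'   \code{score}, \code{prob} (final probabilities), \code{history}
#'   (best-ever score per iteration), \code{config}.
#' @export
cem_optimize <- function(features, labels, population = 50,
                         elite_fraction = 0.2, iterations = 30,
                         smoothing = 0.7, init_prob = 0.5,
                         scorer = "fisher", size_penalty = 0.45,
                         cv_repeats = 3, seed = 1) {
  features <- as.matrix(features)
  D <- ncol(features)
  assert_that(length(unique(labels)) >= 2, "need >= 2 classes")
  assert_that(population >= 10, "population must be >= 10")
  n_elite <- max(2L, floor(population * elite_fraction))
  cfg <- list(population = population, elite_fraction = elite_fraction,
              iterations = iterations, smoothing = smoothing,
              init_prob = init_prob, scorer = scorer,
              size_penalty = size_penalty, cv_repeats = cv_repeats, seed = seed)
  if (D == 1) {
    sc <- mask_score(1, features, labels, scorer, seed, size_penalty, cv_repeats)
    return(structure(list(include = 1L, score = sc, prob = 1,
                          history = sc, config = cfg),
                     class = "feature_mask"))
  }
  set.seed(seed)
  prob <- rep(init_prob, D)
  best_mask <- NULL; best_score <- -Inf
  history <- numeric(0)
  flat_runs <- 0L
  for (it in seq_len(iterations)) {
    masks <- matrix(stats::runif(population * D) < rep(prob, each = population),
                    nrow = population)
    empty <- rowSums(masks) == 0
    if (any(empty)) masks[empty, which.max(prob)] <- TRUE
    scores <- apply(masks, 1, mask_score, features = features, labels = labels,
                    scorer = scorer, seed = seed, size_penalty = size_penalty,
                    cv_repeats = cv_repeats)
    elite <- order(scores, decreasing = TRUE)[seq_len(n_elite)]
    if (scores[elite[1]] > best_score) {
      best_score <- scores[elite[1]]
      best_mask <- masks[elite[1], ]
    }
    history <- c(history, best_score)
    prob_new <- colMeans(masks[elite, , drop = FALSE])
    prob <- smoothing * prob_new + (1 - smoothing) * prob
    prob <- pmin(pmax(prob, 0.01), 0.99)
    if (max(scores) - min(scores) == 0) {
      flat_runs <- flat_runs + 1L
      if (flat_runs >= 3L) {
        warning("cem_optimize: degenerate scores for 3 iterations; early stop")
        break
      }
    } else flat_runs <- 0L
  }
  # backward-elimination polish of the best sampled mask
  repeat {
    incl <- which(best_mask)
    if (length(incl) <= 1) break
    trial <- vapply(incl, function(j) {
      m <- best_mask; m[j] <- FALSE
      mask_score(m, features, labels, scorer, seed, size_penalty, cv_repeats)
    }, numeric(1))
    if (max(trial) <= best_score) break
    drop <- incl[which.max(trial)]
    best_mask[drop] <- FALSE
    best_score <- max(trial)
  }
  structure(list(include = as.integer(best_mask), score = best_score,
                 prob = prob, history = history, config = cfg),
            class = "feature_mask")
}

#' Apply a feature mask to a fused feature table
#'
#' Retains the included columns in order and remaps the per-modality span
#' metadata onto the reduced vector.
#'
#' @param features a \code{fused_features} object or plain matrix.
#' @param mask a \code{feature_mask} or 0/1 vector.
#' @return Same type as \code{features}, reduced to the included columns.
#' @export
apply_mask <- function(features, mask) {
  include <- if (inherits(mask, "feature_mask")) mask$include else mask
  if (inherits(features, "fused_features")) {
    assert_that(length(include) == ncol(features$x),
                "mask length must match feature dimension")
    keep <- which(include == 1)
    new_pos <- match(seq_along(include), keep)  # old index -> new column
    spans <- lapply(features$spans, function(s) {
      v <- new_pos[s]; v[!is.na(v)]
    })
    out <- features
    out$x <- features$x[, keep, drop = FALSE]
    out$spans <- spans
    out
  } else {
    features <- as.matrix(features)
    assert_that(length(include) == ncol(features),
                "mask length must match feature dimension")
    features[, include == 1, drop = FALSE]
  }
}

#' Persist / restore a feature mask as JSON
#'
#' @param mask a \code{feature_mask}.
#' @param path output JSON path.
#' @return \code{save_mask}: the path, invisibly. \code{load_mask}: the
#'   restored \code{feature_mask}.
#' @export
save_mask <- function(mask, path) {
  jsonlite::write_json(list(include = mask$include, score = mask$score,
                            config = mask$config),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_mask
#' @export
load_mask <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(include = as.integer(obj$include), score = obj$score,
                 prob = NULL, history = NULL, config = obj$config),
            class = "feature_mask")
}
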