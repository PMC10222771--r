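#' Pipeline configuration
#'
#' Collects the per-stage settings of the full pipeline run:
#' generation, filtering, windowing, feature extraction, cross-entropy
#' selection, and RvNN training/evaluation.
#'
#' @param generator a [generator_config()].
#' @param filter a [filter_config()].
#' @param window_s window duration in seconds (default 4).
#' @param lpc_p,lpc_d LPC order and cepstral count (defaults 10, 12).
#' @param web a [spider_web_config()].
#' @param gate_threshold Pearson gate threshold (default 0.04).
#' @param cem named list of [cem_optimize()] arguments.
#' @param train a [train_config()].
#' @param k cross-validation folds (default 10).
#' @param distance_threshold skeleton recognition threshold in pixels;
#'   default scales the 15 px / 480-row operating point to the generator
#'   frame height.
#' @return \code{pipeline_config} list.
#' @export
pipeline_config <- function(generator = generator_config(),
                            filter = filter_config(),
                            window_s = 4, lpc_p = 10, lpc_d = 12,
                            web = spider_web_config(),
                            gate_threshold = 0.04,
                            cem = list(population = 50, elite_fraction = 0.2,
                                       iterations = 30, smoothing = 0.7,
                                       init_prob = 0.5, scorer = "cv_loss"),
                            train = train_config(n = 32, epochs = 150),
                            k = 10,
                            distance_threshold = NULL) {
  if (is.null(distance_threshold))
    distance_threshold <- 15 * generator$frame_size[2] / 480
  list(generator = generator, filter = filter, window_s = window_s,
       lpc_p = lpc_p, lpc_d = lpc_d, web = web,
       gate_threshold = gate_threshold, cem = cem, train = train, k = k,
       distance_threshold = distance_threshold)
}

#' Preprocess a recording: filter every modality and build silhouette masks
#'
#' Ambient channels through the zero-phase Butterworth low-pass, inertial
#' channels through wavelet shrinkage (quaternions renormalized), frames
#' through background subtraction.
#'
#' @param recording a [multimodal_recording].
#' @param cfg a [filter_config()].
#' @return The recording with filtered tracks and an added \code{masks}
#'   element (list of binary silhouette masks; empty if no frames).
#' @export
preprocess_recording <- function(recording, cfg = filter_config()) {
  out <- recording
  if (nrow(out$ambient) > 0)
    out$ambient <- butterworth_lowpass(out$ambient, out$ambient_fs,
                                       min(cfg$butterworth_cutoff,
                                           0.45 * out$ambient_fs),
                                       cfg$butterworth_order)
  if (nrow(out$inertial) > 0) {
    fl <- wavelet_quaternion_filter(out$inertial, out$quaternions, cfg)
    out$inertial <- fl$inertial
    out$quaternions <- fl$quaternions
  }
  out$masks <- if (length(out$frames) >= 3)
    subtract_background(out$frames, cfg) else list()
  out
}

# per-window feature tables + skeletons for one preprocessed recording
extract_all_features <- function(rec, cfg) {
  win_a <- segment_windows(rec$ambient, rec$ambient_fs, rec$labels$ambient,
                           cfg$window_s)
  win_m <- segment_windows(rec$inertial, rec$inertial_fs, rec$labels$inertial,
                           cfg$window_s)
  nw <- min(length(win_a), length(win_m))
  if (nw == 0) mf_stop("recording shorter than one window", "momofuse_fusion_error")
  amb_feats <- t(vapply(win_a[seq_len(nw)], function(w)
    ambient_gate(w, cfg$gate_threshold)$features,
    ambient_gate(win_a[[1]], cfg$gate_threshold)$features))
  mot_feats <- t(vapply(win_m[seq_len(nw)], function(w)
    lpcc_window_features(w, cfg$lpc_p, cfg$lpc_d),
    lpcc_window_features(win_m[[1]], cfg$lpc_p, cfg$lpc_d)))
  skels <- NULL; vis_feats <- NULL; vis_times <- NULL
  if (length(rec$masks) > 0) {
    skels <- lapply(seq_along(rec$masks), function(i)
      tryCatch(extract_skeleton(rec$masks[[i]], frame_index = i),
               momofuse_error = function(e) NULL))
    keep <- !vapply(skels, is.null, logical(1))
    if (any(keep)) {
      idx <- which(keep)
      vis_feats <- t(vapply(idx, function(i)
        slif_descriptor(rec$masks[[i]], skels[[i]], cfg$web),
        slif_descriptor(rec$masks[[idx[1]]], skels[[idx[1]]], cfg$web)))
      vis_times <- (idx - 1) / rec$frame_fs
    }
  }
  labels <- vapply(win_m[seq_len(nw)], `[[`, integer(1), "label")
  starts <- vapply(win_m[seq_len(nw)], `[[`, numeric(1), "start_time")
  fused <- align_and_fuse(amb_feats, mot_feats, vis_feats, vis_times,
                          window_starts = starts, window_s = cfg$window_s,
                          labels = labels)
  list(fused = fused, skeletons = skels,
       windows = list(ambient = win_a, motion = win_m))
}

#' Run the full synthetic pipeline
#'
#' Generates a seeded session, preprocesses each modality, extracts and
#' fuses the three feature families, selects a feature subset by the
#' cross-entropy method, trains and evaluates the RvNN with stratified
#' k-fold cross-validation, and evaluates skeleton extraction against the
#' generator's ground-truth joints.
#'
#' @param cfg a [pipeline_config()].
#' @param out optional output directory; when given, writes
#'   \code{report.json}, \code{report.md} and \code{confusion.csv}.
#' @return Report list: per-stage \code{timings} (s), \code{n_windows},
#'   \code{n_features} (fused and selected), \code{confusion},
#'   \code{mean_class_accuracy}, \code{fold_accuracy}, \code{skeleton}
#'   (confidence table and mean joint distance), \code{mask}, \code{seed}.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out = NULL) {
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  session <- generate_session(cfg$generator)
  timings["simulate"] <- tic() - t0

  t0 <- tic()
  rec <- preprocess_recording(session$recording, cfg$filter)
  timings["preprocess"] <- tic() - t0

  t0 <- tic()
  fx <- extract_all_features(rec, cfg)
  fused <- fx$fused
  timings["features"] <- tic() - t0

  # skeleton evaluation against generator ground truth
  skel_report <- NULL
  if (!is.null(fx$skeletons)) {
    keep <- which(!vapply(fx$skeletons, is.null, logical(1)))
    if (length(keep) > 0) {
      det <- fx$skeletons[keep]
      tru <- session$truth[keep]
      skel_report <- list(
        table = confidence_table(det, tru, cfg$distance_threshold),
        accuracy = recognition_accuracy(det, tru, cfg$distance_threshold),
        threshold = cfg$distance_threshold,
        n_frames = length(keep))
    }
  }

  t0 <- tic()
  cem_args <- c(list(features = fused$x, labels = fused$labels,
                     seed = cfg$generator$seed), cfg$cem)
  mask <- do.call(cem_optimize, cem_args)
  reduced <- apply_mask(fused, mask)
  timings["select"] <- tic() - t0

  t0 <- tic()
  eval_res <- kfold_evaluate(reduced, k = cfg$k, cfg = cfg$train,
                             seed = cfg$generator$seed)
  timings["train_evaluate"] <- tic() - t0

  report <- list(
    seed = cfg$generator$seed,
    n_windows = nrow(fused$x),
    n_features = c(fused = ncol(fused$x), selected = sum(mask$include)),
    timings = as.list(timings),
    fold_accuracy = eval_res$fold_accuracy,
    mean_class_accuracy = eval_res$mean_class_accuracy,
    confusion = eval_res$confusion,
    skeleton = skel_report,
    mask = mask)
  if (!is.null(out)) write_report(report, out)
  report
}

write_report <- function(report, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  js <- list(seed = report$seed,
             n_windows = report$n_windows,
             n_features = as.list(report$n_features),
             timings = report$timings,
             fold_accuracy = report$fold_accuracy,
             mean_class_accuracy = report$mean_class_accuracy,
             confusion = list(classes = report$confusion$classes,
                              matrix = unname(as.data.frame(report$confusion$matrix))),
             skeleton = if (!is.null(report$skeleton)) list(
               mean_distance = report$skeleton$accuracy$mean_distance,
               mean_accuracy = report$skeleton$accuracy$mean,
               threshold = report$skeleton$threshold) else NULL)
  jsonlite::write_json(js, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$confusion$matrix,
                   file.path(out, "confusion.csv"))
  md <- c(
    "# Pipeline report",
    "",
    sprintf("- seed: %d", report$seed),
    sprintf("- windows: %d", report$n_windows),
    sprintf("- fused features: %d, selected: %d",
            report$n_features["fused"], report$n_features["selected"]),
    sprintf("- mean class accuracy: %.4f", report$mean_class_accuracy),
    sprintf("- per-fold accuracy: %s",
            paste(sprintf("%.2f", report$fold_accuracy), collapse = " ")),
    if (!is.null(report$skeleton))
      sprintf("- skeleton: mean joint distance %.2f px (threshold %.1f), mean recognition accuracy %.2f",
              report$skeleton$accuracy$mean_distance,
              report$skeleton$threshold,
              report$skeleton$accuracy$mean),
    "",
    "## Stage timings (s)",
    sprintf("- %s: %.2f", names(report$timings), unlist(report$timings)))
  writeLines(md, file.path(out, "report.md"))
  invisible(out)
}
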