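test_that("load_recording reads timestamped CSV streams and tolerates absent modalities", {
  td <- withr::local_tempdir()
  amb <- data.frame(timestamp = (0:99) / 10,
                    a = sin(0:99), b = cos(0:99), c = (0:99) %% 2)
  write.csv(amb, file.path(td, "ambient.csv"), row.names = FALSE)
  rec <- load_recording(ambient_path = file.path(td, "ambient.csv"),
                        rates = list(ambient = 10, inertial = 25, frames = 10))
  expect_s3_class(rec, "multimodal_recording")
  expect_equal(dim(rec$ambient), c(100, 3))
  expect_equal(unname(rec$ambient[, 1]), amb$a)
  expect_length(rec$frames, 0)

  # duplicated timestamp rows are deduplicated (first kept)
  amb_dup <- rbind(amb, amb[c(5, 50), ])
  write.csv(amb_dup, file.path(td, "dup.csv"), row.names = FALSE)
  expect_message(
    rec2 <- load_recording(ambient_path = file.path(td, "dup.csv"),
                           rates = list(ambient = 10, inertial = 25, frames = 10)),
    "2 duplicated")
  expect_equal(nrow(rec2$ambient), 100)

  expect_error(load_recording(ambient_path = file.path(td, "nope.csv"),
                              rates = list(ambient = 10, inertial = 25, frames = 10)),
               class = "momofuse_input_error")
})

test_that("Butterworth low-pass is zero-phase, DC-preserving, and half-power at cutoff", {
  # DC passthrough
  y <- butterworth_lowpass(rep(2, 200), fs = 25, cutoff = 5, order = 3)
  expect_lt(max(abs(y - 2)), 1e-6)
  expect_equal(butterworth_lowpass(numeric(200) , 25, 5, 3), numeric(200))

  # forward-backward amplitude at the cutoff = |H|^2 = 1/2
  fs <- 100; fc <- 5
  t <- seq(0, 20, by = 1 / fs)
  y <- butterworth_lowpass(sin(2 * pi * fc * t), fs, fc, 3)
  mid <- seq(round(length(t) * 0.3), round(length(t) * 0.7))
  expect_equal(max(abs(y[mid])), 0.5, tolerance = 0.05 / 0.5)

  # zero-phase: cross-correlation peak of a below-cutoff tone at lag 0
  s <- sin(2 * pi * 1 * t)
  yf <- butterworth_lowpass(s, fs, fc, 3)
  cc <- stats::ccf(yf, s, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # shape preserved for matrices
  m <- cbind(sin(2 * pi * t), cos(2 * pi * t))
  expect_equal(dim(butterworth_lowpass(m, fs, fc, 3)), dim(m))

  expect_error(butterworth_lowpass(s, fs, cutoff = 60, order = 3),
               class = "momofuse_parameter_error")
  expect_error(butterworth_lowpass(s[1:5], fs, 5, 3),
               class = "momofuse_parameter_error")
})

test_that("wavelet shrinkage preserves clean signals, denoises noisy ones, renormalizes quaternions", {
  t <- seq(0, 10, by = 1 / 25)
  clean <- sin(2 * pi * 0.5 * t)
  out <- wavelet_quaternion_filter(matrix(clean), cfg = filter_config())
  expect_equal(dim(out$inertial), c(length(t), 1))
  rel <- sqrt(mean((out$inertial[, 1] - clean)^2)) / sqrt(mean(clean^2))
  expect_lt(rel, 1e-3)

  set.seed(5)
  noisy <- clean + rnorm(length(t), 0, 0.5)
  den <- wavelet_quaternion_filter(matrix(noisy))$inertial[, 1]
  expect_lt(sqrt(mean((den - clean)^2)), sqrt(mean((noisy - clean)^2)))

  # near-idempotent on already-smooth signals
  twice <- wavelet_quaternion_filter(matrix(den))$inertial[, 1]
  expect_lt(sqrt(mean((twice - den)^2)), 0.05)

  q <- matrix(c(2, 0, 0, 0), 1, 4)
  res <- wavelet_quaternion_filter(matrix(clean), rbind(q[rep(1, length(t)), ]))
  expect_equal(res$quaternions[1, ], c(1, 0, 0, 0))

  qbad <- matrix(0, length(t), 4)
  expect_error(wavelet_quaternion_filter(matrix(clean), qbad),
               class = "momofuse_degenerate_orientation_error")
})

test_that("periodized db4 transform is an orthonormal perfect-reconstruction filter bank", {
  set.seed(1)
  x <- rnorm(256)
  dec <- momofuse:::dwt_db4(x, 3)
  expect_lt(max(abs(momofuse:::idwt_db4(dec) - x)), 1e-10)
  # Parseval: energy preserved across the decomposition
  e <- sum(dec$approx^2) + sum(unlist(dec$details)^2)
  expect_equal(e, sum(x^2), tolerance = 1e-10)
})

test_that("background subtraction recovers moving foreground and rejects degenerate input", {
  bg <- matrix(0.3, 60, 80)
  frames <- lapply(1:6, function(i) {
    f <- bg
    f[10:29, (i * 8):(i * 8 + 14)] <- 0.9   # 20 x 15 moving rectangle
    f
  })
  masks <- subtract_background(frames, filter_config(morph_radius = 1))
  areas <- vapply(masks, sum, numeric(1))
  expect_true(all(abs(areas - 300) / 300 <= 0.10))

  same <- lapply(1:5, function(i) bg)
  expect_true(all(vapply(subtract_background(same), sum, numeric(1)) == 0))

  expect_error(subtract_background(frames[1:2]), class = "momofuse_parameter_error")
  bad <- c(frames[1:3], list(matrix(0.3, 30, 80)))
  expect_error(subtract_background(bad), class = "momofuse_format_error")
})

test_that("windowing yields exact window counts, majority labels, and conserves samples", {
  x <- matrix(rnorm(1000 * 2), 1000, 2)
  w <- segment_windows(x, fs = 25, window_s = 4)
  expect_length(w, 10)
  expect_true(all(vapply(w, function(v) nrow(v$data), numeric(1)) == 100))
  expect_equal(w[[2]]$start_time, 4)

  w2 <- segment_windows(x, fs = 25, window_s = 4, overlap = 0.5)
  expect_length(w2, 19)   # floor((1000 - 100) / 50) + 1

  expect_message(w3 <- segment_windows(matrix(rnorm(99)), fs = 25, window_s = 4),
                 "shorter")
  expect_length(w3, 0)

  # majority label; tie broken toward the smaller class id
  lab <- c(rep(2L, 40), rep(7L, 60))
  w4 <- segment_windows(matrix(rnorm(100)), 25, labels = lab)
  expect_equal(w4[[1]]$label, 7L)
  lab_tie <- c(rep(9L, 50), rep(4L, 50))
  expect_equal(segment_windows(matrix(rnorm(100)), 25, labels = lab_tie)[[1]]$label, 4L)

  # sample conservation: n_windows * step + window <= n + step
  for (ov in c(0, 0.25, 0.5)) {
    ww <- segment_windows(x, 25, window_s = 4, overlap = ov)
    step <- max(1, round(100 * (1 - ov)))
    expect_lte(length(ww) * step + 100, 1000 + step)
  }
})
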