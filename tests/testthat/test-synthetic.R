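test_that("generation is byte-identical under a fixed seed", {
  cfg <- generator_config(n_classes = 3, segment_s = 8, frame_fs = 1, seed = 7)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1$recording$ambient, s2$recording$ambient)
  expect_identical(s1$recording$inertial, s2$recording$inertial)
  expect_identical(s1$recording$frames, s2$recording$frames)
  expect_identical(s1$truth, s2$truth)

  s3 <- generate_session(generator_config(n_classes = 3, segment_s = 8,
                                          frame_fs = 1, seed = 8))
  expect_false(identical(s1$recording$ambient, s3$recording$ambient))
})

test_that("rendered mask area matches the analytic geometry budget", {
  fx <- fixture_pose()
  g <- fx$geom
  # analytic sum: torso ellipse + head disc + thick limb segments (with end
  # caps), ignoring attachment overlaps -- rendered area must be within 15%
  seg_len <- function(a, b) sqrt(sum((a - b)^2))
  j <- fx$pose$joints; hips <- fx$pose$hips
  torso <- j["torso", ]
  lens <- c(seg_len(j["left_shoulder", ], j["left_elbow", ]),
            seg_len(j["left_elbow", ], j["left_wrist", ]),
            seg_len(j["right_shoulder", ], j["right_elbow", ]),
            seg_len(j["right_elbow", ], j["right_wrist", ]),
            seg_len(hips[1, ], j["left_knee", ]),
            seg_len(j["left_knee", ], j["left_ankle", ]),
            seg_len(hips[2, ], j["right_knee", ]),
            seg_len(j["right_knee", ], j["right_ankle", ]),
            seg_len(torso + c(0, -g$torso_b + 2), j["head", ]),
            seg_len(torso + c(0, -g$torso_b + 3), j["left_shoulder", ]),
            seg_len(torso + c(0, -g$torso_b + 3), j["right_shoulder", ]),
            seg_len(torso + c(0, g$torso_b - 3), hips[1, ]),
            seg_len(torso + c(0, g$torso_b - 3), hips[2, ]))
  analytic <- pi * g$torso_a * g$torso_b + pi * g$head_r^2 +
    sum(lens * g$thickness)
  expect_equal(sum(fx$mask), analytic, tolerance = 0.15)

  # identical pose renders identical masks
  fx2 <- fixture_pose()
  expect_identical(fx$mask, fx2$mask)
})

test_that("empty-scene frames yield zero foreground after subtraction", {
  set.seed(1)
  bg <- matrix(runif(60 * 80, 0.2, 0.5), 60, 80)
  frames <- lapply(1:5, function(i) bg)
  masks <- subtract_background(frames, filter_config())
  expect_true(all(vapply(masks, sum, numeric(1)) == 0))
})

test_that("the Pearson gate fires less on idle than on active segments", {
  cfg <- generator_config(n_classes = 4, segment_s = 48, frame_fs = 1, seed = 13)
  ses <- generate_session(cfg)
  rec <- ses$recording
  wins <- segment_windows(rec$ambient, rec$ambient_fs, rec$labels$ambient)
  flags <- vapply(wins, function(w) ambient_gate(w)$action_flag, logical(1))
  labs <- vapply(wins, `[[`, integer(1), "label")
  idle_rate <- mean(flags[labs == 1])      # class 1 has zero coupling
  active_rate <- mean(flags[labs > 1])
  expect_lt(idle_rate, active_rate)

  # flag rate is monotone in the configured coupling strength
  rates <- vapply(sort(unique(labs)), function(cl) mean(flags[labs == cl]),
                  numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("sessions round-trip through the on-disk layout", {
  cfg <- generator_config(n_classes = 2, segment_s = 8, frame_fs = 1,
                          frame_size = c(160, 120), seed = 3)
  ses <- generate_session(cfg)
  td <- withr::local_tempdir()
  write_session(ses, td)
  expect_true(file.exists(file.path(td, "manifest.json")))
  rec <- load_recording(file.path(td, "ambient.csv"),
                        file.path(td, "inertial.csv"),
                        file.path(td, "frames"),
                        file.path(td, "labels.csv"),
                        rates = list(ambient = cfg$ambient_fs,
                                     inertial = cfg$inertial_fs,
                                     frames = cfg$frame_fs))
  expect_equal(rec$ambient, ses$recording$ambient, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(rec$inertial, ses$recording$inertial, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(rec$quaternions, ses$recording$quaternions, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_length(rec$frames, length(ses$recording$frames))
  # PNG stores 8-bit intensities; allow quantization error up to 1/510
  expect_lt(max(abs(rec$frames[[1]] - ses$recording$frames[[1]])), 1 / 254)
  expect_equal(rec$labels$ambient, ses$recording$labels$ambient)
})

test_that("rendered silhouettes close the loop through skeleton extraction", {
  cfg <- generator_config(n_classes = 5, segment_s = 8, frame_fs = 1, seed = 21)
  ses <- generate_session(cfg)
  sk <- lapply(seq_along(ses$masks), function(i)
    extract_skeleton(ses$masks[[i]], frame_index = i))
  # mean joint distance within 15 px at the 640x480-equivalent scale
  ra <- recognition_accuracy(sk, ses$truth, threshold = 15,
                             S = 480 / cfg$frame_size[2])
  expect_lte(ra$mean_distance, 15)
  expect_gte(ra$mean, 0.9)
})
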