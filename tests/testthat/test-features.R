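test_that("Pearson correlation matches direct formula evaluation and its invariances", {
  expect_equal(as.numeric(pearson_correlation(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_equal(as.numeric(pearson_correlation(c(1, 2, 3), c(3, 2, 1))), -1)
  expect_equal(as.numeric(pearson_correlation(c(1, 2, 3), c(1, 2, 4))),
               pearson_direct(c(1, 2, 3), c(1, 2, 4)), tolerance = 1e-12)

  # constant input: defined as 0, flagged degenerate
  r <- pearson_correlation(rep(2, 5), 1:5)
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
  expect_error(pearson_correlation(1:4, 1:5), class = "momofuse_parameter_error")

  # symmetry and shift/scale invariance with sign flip
  set.seed(3)
  for (i in 1:20) {
    g <- rnorm(30); h <- rnorm(30)
    expect_equal(as.numeric(pearson_correlation(g, h)),
                 as.numeric(pearson_correlation(h, g)), tolerance = 1e-12)
    a <- runif(1, -3, 3); b <- runif(1, -5, 5)
    if (abs(a) > 1e-3)
      expect_equal(as.numeric(pearson_correlation(a * g + b, h)),
                   sign(a) * as.numeric(pearson_correlation(g, h)),
                   tolerance = 1e-10)
  }
})

test_that("ambient gate thresholds mean absolute pairwise correlation", {
  w <- cbind(sin(1:100), sin(1:100))
  g <- ambient_gate(w)
  expect_equal(g$mean_abs_pc, 1)
  expect_true(g$action_flag)
  expect_equal(g$threshold, 0.04)

  gconst <- ambient_gate(cbind(rep(1, 50), rep(2, 50)))
  expect_equal(gconst$mean_abs_pc, 0)
  expect_false(gconst$action_flag)

  # feature vector layout: upper-triangle pairs + mean + flag
  w3 <- matrix(rnorm(300), 100, 3)
  g3 <- ambient_gate(w3)
  expect_length(g3$features, 3 + 2)
  expect_equal(names(g3$features)[1:3], c("pc_ch0_ch1", "pc_ch0_ch2", "pc_ch1_ch2"))
  expect_true(abs(g3$pc_matrix[1, 2]) <= 1 + 1e-12)
  expect_equal(g3$action_flag, g3$mean_abs_pc > 0.04)

  expect_message(g1 <- ambient_gate(matrix(rnorm(50), 50, 1)), "single channel")
  expect_length(g1$features, 3)
})

test_that("gate flag rate under independent noise matches the Monte-Carlo null", {
  # for two independent N(0,1) channels of length 100, PC ~ approx N(0, 1/99);
  # expected flag rate = P(|PC| > 0.04)
  expected <- 2 * (1 - pnorm(0.04 / sqrt(1 / 99)))
  set.seed(11)
  flags <- vapply(1:1000, function(i)
    ambient_gate(matrix(rnorm(200), 100, 2))$action_flag, logical(1))
  expect_equal(mean(flags), expected, tolerance = 0.1 / expected)
})

test_that("LPC recovers known autoregressive structure", {
  set.seed(2)
  n <- 5000
  x <- as.numeric(stats::filter(rnorm(n), 0.8, "recursive"))
  expect_equal(lpc_coefficients(x, 1)[1], 0.8, tolerance = 0.05 / 0.8)

  wn <- rnorm(2000)
  expect_true(all(abs(lpc_coefficients(wn, 2)) < 0.1))

  expect_error(lpc_coefficients(rnorm(20), 10), class = "momofuse_parameter_error")
  expect_error(lpc_coefficients(rep(0, 100), 4), class = "momofuse_parameter_error")

  # minimum-phase: zeros of A(z) = 1 - sum a_k z^-k inside the unit circle,
  # i.e. the roots of the ascending polynomial 1 - a_1 x - ... lie outside
  set.seed(4)
  y <- as.numeric(stats::filter(rnorm(3000), c(0.5, -0.3), "recursive"))
  a <- lpc_coefficients(y, 4)
  roots <- polyroot(c(1, -a))
  expect_true(all(Mod(roots) > 1 - 1e-8))
})

test_that("cepstral recursion matches closed forms and the brute-force oracle", {
  expect_equal(lpcc(rep(0, 4), 4, 8), rep(0, 8))
  expect_equal(lpcc(0.5, 1, 2), c(0.5, 0.125))

  set.seed(7)
  for (i in 1:200) {
    p <- sample(2:6, 1)
    d <- p + sample(0:6, 1)
    a <- random_stable_lpc(p)
    expect_equal(lpcc(a, p, d), lpcc_bruteforce(a, p, d), tolerance = 1e-12)
  }
  expect_error(lpcc(c(0.1, 0.2), 2, 1), class = "momofuse_parameter_error")
})

test_that("per-window LPCC features concatenate channels", {
  w <- cbind(sin(2 * pi * (1:200) / 25), cos(2 * pi * (1:200) / 10))
  f <- lpcc_window_features(w, p = 6, d = 8)
  expect_length(f, 16)
  expect_equal(names(f)[1], "lpcc_ch0_c1")
  # zero-energy channel contributes a zero block instead of failing
  f0 <- lpcc_window_features(cbind(w[, 1], 0), p = 6, d = 8)
  expect_equal(unname(f0[9:16]), rep(0, 8))
})

test_that("spider web points follow the polar grid", {
  cfg <- spider_web_config(rings = 2, spokes = 4)
  pts <- spider_web_points(c(10, 20), cfg)
  expect_equal(pts[1, ], c(12, 20))         # z = 0: offset (r, 0)
  expect_equal(pts[2, ], c(10, 22))         # z = Z/4: quarter turn, y down
  cfg8 <- spider_web_config(rings = 1, spokes = 8)
  pts8 <- spider_web_points(c(0, 0), cfg8)
  ang <- 2 * pi * (0:7) / 8
  expect_equal(pts8, cbind(cos(ang), sin(ang)), tolerance = 1e-12)
  expect_error(spider_web_config(rings = c(3, 2)), class = "momofuse_parameter_error")
})

test_that("SLIF descriptor samples occupancy and is translation-equivariant", {
  cfg <- spider_web_config(rings = c(4, 8), spokes = 8,
                           anchors = c("head", "torso"))
  pts <- matrix(60, 12, 2, dimnames = list(skeleton_point_names(), NULL))
  sk <- skeleton_frame(pts)

  all_fg <- matrix(1, 120, 120)
  d1 <- slif_descriptor(all_fg, sk, cfg)
  expect_length(d1, 2 * (2 * 8 + 1))
  expect_true(all(d1 == 1))
  expect_true(all(slif_descriptor(matrix(0, 120, 120), sk, cfg) == 0))

  # disk of radius r centred on the anchor: inner ring inside, outer outside
  r <- 10
  gx <- matrix(1:120, 120, 120, byrow = TRUE); gy <- t(gx)
  disk <- ((gx - 60)^2 + (gy - 60)^2 <= r^2) * 1
  cfg_d <- spider_web_config(rings = c(r / 2, 2 * r), spokes = 8,
                             anchors = "torso")
  dd <- slif_descriptor(disk, sk, cfg_d)
  expect_true(all(dd[1:8] == 1))
  expect_true(all(dd[9:16] == 0))
  expect_equal(unname(dd[17]), 0.5)

  # translating mask and skeleton together leaves the descriptor unchanged
  shift <- c(7, -5)
  disk2 <- ((gx - 60 - shift[1])^2 + (gy - 60 - shift[2])^2 <= r^2) * 1
  sk2 <- skeleton_frame(sweep(pts, 2, -shift))
  expect_equal(slif_descriptor(disk2, sk2, cfg_d), dd)

  # missing anchor: zero block
  pts_na <- pts; pts_na["torso", ] <- NA
  dna <- slif_descriptor(disk, skeleton_frame(pts_na), cfg_d)
  expect_true(all(dna == 0))
})
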