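# Independent brute-force oracles used across tests.

# literal double-loop transcription of the cepstral recursion, kept naive on
# purpose so it stays independent of the vectorized implementation
lpcc_bruteforce <- function(a, p, d) {
  cc <- numeric(d)
  for (x in 1:d) {
    s <- 0
    if (x >= 2) {
      for (t in 1:(x - 1)) {
        ai <- x - t
        if (ai >= 1 && ai <= p) s <- s + (t / x) * cc[t] * a[ai]
      }
    }
    cc[x] <- if (x <= p) a[x] + s else s
  }
  cc
}

# direct textbook Pearson correlation
pearson_direct <- function(g, h) {
  num <- sum((g - mean(g)) * (h - mean(h)))
  num / sqrt(sum((g - mean(g))^2) * sum((h - mean(h))^2))
}

# a stable random LPC coefficient vector (via reflection coefficients)
random_stable_lpc <- function(p) {
  k <- stats::runif(p, -0.6, 0.6)
  a <- numeric(0)
  for (m in 1:p) {
    a_new <- c(a, k[m])
    if (m > 1) a_new[1:(m - 1)] <- a[1:(m - 1)] - k[m] * a[(m - 1):1]
    a <- a_new
  }
  a
}

# fixed small pose + rendering used by skeleton/feature tests
fixture_pose <- function(t = 0.3, class_id = 3, center = c(160, 120)) {
  geom <- momofuse:::stick_geometry(1)
  pose <- momofuse:::stick_pose(t, center, class_id, 9, geom)
  rend <- render_stick_figure(pose$joints, c(320, 240), geom, hips = pose$hips)
  list(pose = pose, mask = rend$mask, geom = geom)
}

# planted-feature problem: dim j carries a one-vs-rest mean shift for class j
planted_problem <- function(seed, n_classes = 8, n_per = 20, dims = 40,
                            informative = 8, delta = 3) {
  set.seed(seed)
  y <- rep(seq_len(n_classes), each = n_per)
  X <- matrix(stats::rnorm(n_classes * n_per * dims), n_classes * n_per, dims)
  for (j in seq_len(informative)) {
    cl <- (j - 1) %% n_classes + 1
    X[y == cl, j] <- X[y == cl, j] + delta
  }
  list(X = X, y = y, informative = seq_len(informative))
}
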