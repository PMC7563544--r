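test_that("max_xcorr identity, delay recovery and conventions", {
  set.seed(1)
  x <- rnorm(600)
  r <- max_xcorr(x, x, rate = 100)
  expect_equal(r$coefficient, 1, tolerance = 1e-9)
  expect_equal(r$lag, 0)
  # y delayed by 10 samples: x leads y, positive lag
  y <- c(rep(0, 10), x)[1:600]
  r <- max_xcorr(x, y, rate = 100, max_lag = 1)
  expect_equal(r$lag, 10 / 100)
  # antisymmetry of the lag
  r2 <- max_xcorr(y, x, rate = 100, max_lag = 1)
  expect_equal(r2$lag, -r$lag)
  expect_equal(r2$coefficient, r$coefficient, tolerance = 1e-9)
  expect_error(max_xcorr(rep(1, 100), rnorm(100), 100), "zero-variance")
})

test_that("independent white noise yields small coefficients", {
  set.seed(2)
  hits <- vapply(1:40, function(i) {
    r <- max_xcorr(rnorm(10000), rnorm(10000), rate = 256, max_lag = 1)
    r$coefficient < 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("adjacency from a common noiseless source is complete", {
  set.seed(3)
  n <- 240 * 30
  src <- abs(sin(2 * pi * (1:n) / 240) + 0.2)
  speeds <- outer(src, c(1, 0.5, 0.25, 2))
  colnames(speeds) <- paste0("s", 1:4)
  starts <- seq(1, by = 400, length.out = 8)
  fwd <- cbind(starts, starts + 199)
  seg <- make_segmentation(fwd, fwd + 200)
  adj <- build_adjacency(speeds, 240, seg, "forward")
  off <- adj$weights[upper.tri(adj$weights)]
  expect_equal(off, rep(1, 6), tolerance = 1e-6)
  expect_true(isSymmetric(adj$weights))
  expect_equal(diag(adj$weights), rep(0, 4), ignore_attr = TRUE)
  expect_equal(adj$lags, -t(adj$lags), ignore_attr = TRUE)
  expect_error(build_adjacency(speeds, 240, seg[1:3, ], "forward"),
               "insufficient")
})

test_that("clustering coefficients on canonical graphs", {
  # complete unit-weight triangle
  W <- matrix(1, 3, 3); diag(W) <- 0
  cc <- clustering_coefficients(W)
  expect_equal(cc$clustering, rep(1, 3))
  # star graph: center has no triangles
  W <- matrix(0, 5, 5)
  W[1, 2:5] <- W[2:5, 1] <- 0.8
  cc <- clustering_coefficients(W)
  expect_equal(cc$clustering[1], 0)
  expect_equal(cc$degree[1], 4)
  # empty graph
  cc <- clustering_coefficients(matrix(0, 4, 4))
  expect_equal(cc$clustering, rep(0, 4))
})

test_that("clustering equals exhaustive triangle enumeration", {
  set.seed(4)
  for (rep in 1:30) {
    S <- sample(4:8, 1)
    W <- matrix(runif(S * S), S, S)
    W <- (W + t(W)) / 2
    W[W < 0.3] <- 0  # some missing edges
    diag(W) <- 0
    cc <- clustering_coefficients(W)
    ref <- clustering_brute(W)
    expect_equal(cc$clustering, ref$clustering, tolerance = 1e-12)
    expect_equal(cc$triangle_intensity, ref$triangle_intensity,
                 tolerance = 1e-12)
  }
})

test_that("clustering is non-decreasing under uniform weight increase", {
  set.seed(6)
  W <- matrix(runif(36), 6, 6); W <- (W + t(W)) / 2; diag(W) <- 0
  W[W < 0.4] <- 0
  base <- clustering_coefficients(W)$clustering
  W2 <- W
  W2[W > 0] <- W[W > 0] + 0.2
  up <- clustering_coefficients(W2)$clustering
  expect_true(all(up >= base - 1e-12))
})

test_that("heart-body connectivity rejects unresampled kinematics", {
  ecg <- ecg_recording((0:999) / 256, rnorm(1000), 256, filtered = TRUE)
  speeds <- matrix(abs(rnorm(1000 * 2)), ncol = 2,
                   dimnames = list(NULL, c("a", "b")))
  seg <- make_segmentation(cbind(c(1, 200), c(150, 350)),
                           cbind(c(151, 360), c(300, 500)), rate = 240)
  expect_error(
    heart_body_connectivity(ecg, speeds, 240, seg, "forward"),
    "rate mismatch")
})
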