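test_that("config invariants are enforced", {
  expect_error(rosetta_config(min_clusters = 3, max_clusters = 2), "exceed")
  expect_error(rosetta_config(min_clusters = 1), "silhouette")
  expect_silent(rosetta_config(min_clusters = 1, use_cluster_id = TRUE))
  expect_error(rosetta_config(min_components_per_cluster = c(2, 2),
                              max_components_per_cluster = c(1, 1)), "min <= max")
  expect_error(rosetta_config(tolerance = 0), "tolerance")
  expect_error(rosetta_config(outer_percent = 100), "outer_percent")
})

test_that("principal_angle recovers known orientations", {
  # points exactly on the line through the origin along (1,1): 45 degrees
  t <- seq(-1, 1, length.out = 101)
  expect_equal(as.numeric(principal_angle(cbind(t, t), outer_percent = 0)),
               45, tolerance = 1e-9)
  # anisotropic Gaussian at 30 degrees clockwise from vertical (SD 400 / 100)
  set.seed(8)
  n <- 1e4
  base <- cbind(rnorm(n, sd = 100), rnorm(n, sd = 400))
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  ang <- principal_angle(base %*% t(R), outer_percent = 0)
  expect_lt(ang_dist(as.numeric(ang), 30), 1)
  expect_true(attr(ang, "direction_defined"))
})

test_that("outer-point trimming makes the angle robust to far outliers", {
  set.seed(9)
  n <- 5000
  base <- cbind(rnorm(n, sd = 1), rnorm(n, sd = 6))  # vertical, sd ratio 6
  clean <- as.numeric(principal_angle(base, outer_percent = 2))
  # add 1% of points far out along the minor (horizontal) axis
  spiked <- rbind(base, cbind(rnorm(n / 100, sd = 1) + 20 * 6, rnorm(n / 100)))
  trimmed <- as.numeric(principal_angle(spiked, outer_percent = 2))
  untrimmed <- as.numeric(principal_angle(spiked, outer_percent = 0))
  expect_lt(ang_dist(trimmed, clean), 0.5)
  expect_gt(ang_dist(untrimmed, clean), ang_dist(trimmed, clean))
})

test_that("near-isotropic clusters are flagged direction-undefined", {
  # points on a circle have exactly equal covariance eigenvalues; a random
  # isotropic sample would not trigger the flag (its empirical eigenvalue
  # ratio is ~1.1 at n = 2000, above the 1.01 cutoff)
  th <- seq(0, 2 * pi, length.out = 1001)[-1001]
  iso <- cbind(cos(th), sin(th))
  expect_warning(ang <- principal_angle(iso), "isotropic")
  expect_false(attr(ang, "direction_defined"))
})

test_that("alignment diagonalizes the covariance and is invertible", {
  set.seed(11)
  base <- cbind(rnorm(3000, sd = 50), rnorm(3000, sd = 200))
  th <- 290 * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  pts <- sweep(base %*% t(R), 2, c(1000, -500), `+`)

  al <- rotate_to_axis(pts, "vertical", outer_percent = 2)
  cv <- cov(al$points)
  expect_lt(abs(cv[1, 2]) / sqrt(cv[1, 1] * cv[2, 2]), 0.05)
  expect_gt(cv[2, 2], cv[1, 1])        # principal axis vertical
  # aligning an already-aligned cluster is the identity rotation
  again <- rotate_to_axis(al$points, "vertical", outer_percent = 2)
  expect_lt(ang_dist(again$transform$rotation_deg, 0), 0.5)
  # horizontal alignment is the vertical one rotated a quarter turn
  ah <- rotate_to_axis(pts, "horizontal", outer_percent = 2)
  expect_lt(ang_dist(ah$transform$rotation_deg,
                     al$transform$rotation_deg - 90), 1e-6)
  expect_gt(cov(ah$points)[1, 1], cov(ah$points)[2, 2])
  # exact round trip
  expect_lt(max(abs(apply_inverse(al$points, al$transform) - pts)), 1e-9)
  # the recorded centroid is the image of the origin
  expect_equal(as.numeric(apply_inverse(matrix(0, 1, 2), al$transform)),
               colMeans(pts), tolerance = 1e-9)
})

test_that("independent transforms preserve inter-cluster geometry", {
  set.seed(12)
  c1 <- matrix(rnorm(2000, sd = c(1, 5)), ncol = 2, byrow = TRUE)
  c2 <- sweep(matrix(rnorm(2000, sd = c(2, 8)), ncol = 2, byrow = TRUE),
              2, c(100, 40), `+`)
  a1 <- rotate_to_axis(c1); a2 <- rotate_to_axis(c2)
  r1 <- apply_inverse(a1$points, a1$transform)
  r2 <- apply_inverse(a2$points, a2$transform)
  expect_equal(colMeans(r2) - colMeans(r1), colMeans(c2) - colMeans(c1),
               tolerance = 1e-9)
})

test_that("outlier removal cuts exactly the per-dimension z-score tails", {
  set.seed(13)
  pts <- matrix(rnorm(300), ncol = 2)
  pts[1, ] <- c(6 * sd(pts[-1, 1]), 0)    # one clear X outlier
  kept <- remove_outliers(pts, 5, 5)
  expect_equal(attr(kept, "removed"), 1L)
  expect_equal(nrow(kept), 149L)
  # infinite thresholds are the identity
  kept2 <- remove_outliers(pts, Inf, Inf)
  expect_equal(nrow(kept2), 150L)
  # Gaussian tail oracle: expected removed fraction at 3.5 SD in both
  # dimensions is about 2 * 2 * (1 - pnorm(3.5)) = 9.3e-4
  big <- matrix(rnorm(2e5), ncol = 2)
  frac <- attr(remove_outliers(big, 3.5, 3.5), "removed") / 1e5
  expect_gt(frac, 9.3e-4 / 1.5)
  expect_lt(frac, 9.3e-4 * 1.5)
  expect_error(remove_outliers(pts, 1e-9, 1e-9), "every point")
})

test_that("silhouette selection finds well-separated blobs", {
  set.seed(14)
  blob1 <- matrix(rnorm(2000), ncol = 2)
  blob2 <- sweep(matrix(rnorm(2000), ncol = 2), 2, c(50, 0), `+`)
  ev <- labeled_events(rbind(blob1, blob2))
  foc <- find_optimal_clusters(ev, rosetta_config(max_clusters = 4), seed = 1)
  expect_equal(foc$k, 2)
  expect_gt(foc$silhouette, 0.95)
})

test_that("use_cluster_id passes labels through unchanged", {
  set.seed(15)
  v <- rbind(matrix(rnorm(200), ncol = 2),
             matrix(rnorm(200, mean = 20), ncol = 2))
  ev <- labeled_events(v, labels = rep(c(0L, 1L), each = 100))
  foc <- find_optimal_clusters(ev, rosetta_config(use_cluster_id = TRUE))
  expect_identical(foc$labels, ev$labels)
  expect_true(is.finite(foc$silhouette))
  expect_equal(foc$k, 2L)
})

test_that("low silhouette triggers the suboptimal-clustering warning", {
  set.seed(16)
  ev <- labeled_events(matrix(rnorm(2000), ncol = 2),
                       labels = rep(c(0L, 1L), 500))
  expect_warning(find_optimal_clusters(ev, rosetta_config(use_cluster_id = TRUE)),
                 "suboptimal")
})
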