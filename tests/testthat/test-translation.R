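make_model <- function(cx, cy, n = 1000L) {
  # assemble a cluster_model by hand for aggregate arithmetic tests
  structure(list(
    n_events = n, m_x = nrow(cx), m_y = nrow(cy),
    x_model = list(axis = "X", components = cx, loglik = -10, bic = 1),
    y_model = list(axis = "Y", components = cy, loglik = -20, bic = 2),
    loglik = -30, full_bic = 3, converged = TRUE, iterations = 1L,
    joint = TRUE), class = "cluster_model")
}

test_that("single-component report equals the component parameters", {
  cx <- data.frame(weight = 1, mu = 5, sigma = 2, shape = 2 * pi * 0.07)
  cy <- data.frame(weight = 1, mu = -3, sigma = 4, shape = 0.25)
  tr <- cluster_transform(c(100, 200), 0)
  rep_ <- model_to_report(make_model(cx, cy), tr, silhouette = 0.5)
  expect_equal(rep_$x_mean, 105)   # identity rotation: centroid + mu
  expect_equal(rep_$y_mean, 197)
  expect_equal(rep_$x_sd, 2)
  expect_equal(rep_$y_sd, 4)
  expect_equal(rep_$x_skew, 0.07)  # shape reported in generator units
  expect_equal(rep_$y_kurtosis, 0.25)
})

test_that("mixture aggregation follows the mixture-moment identity", {
  cx <- data.frame(weight = c(0.5, 0.5), mu = c(-1, 1),
                   sigma = c(1, 1), shape = c(0, 0))
  cy <- data.frame(weight = c(0.3, 0.7), mu = c(0, 10),
                   sigma = c(2, 3), shape = c(0, 0))
  rep_ <- model_to_report(make_model(cx, cy), cluster_transform(c(0, 0), 0))
  expect_equal(rep_$x_sd, sqrt(2), tolerance = 1e-9)
  # independent recomputation of the identity for the y dimension
  my <- 0.3 * 0 + 0.7 * 10
  vy <- 0.3 * (4 + 0) + 0.7 * (9 + 100) - my^2
  expect_equal(rep_$y_sd, sqrt(vy), tolerance = 1e-9)
  expect_equal(rep_$y_mean, my)
  # dominant-weight component's shape is the reported one
  cy2 <- data.frame(weight = c(0.3, 0.7), mu = c(0, 0),
                    sigma = c(1, 1), shape = c(-0.5, 0.9))
  rep2 <- model_to_report(make_model(cx, cy2), cluster_transform(c(0, 0), 0))
  expect_equal(rep2$y_kurtosis, 0.9)
})

test_that("report means are re-expressed through the inverse transform", {
  cx <- data.frame(weight = 1, mu = 10, sigma = 1, shape = 0)
  cy <- data.frame(weight = 1, mu = 0, sigma = 2, shape = 0)
  tr <- cluster_transform(c(1000, 1000), 90)  # aligned X' points along -Y
  rep_ <- model_to_report(make_model(cx, cy), tr)
  expect_equal(rep_$x_mean, 1000, tolerance = 1e-9)
  expect_equal(rep_$y_mean, 990, tolerance = 1e-9)
  expect_equal(rep_$rotation_deg, 90)
})

test_that("report to generator args is the inverse mapping", {
  rep_ <- data.frame(cluster_id = 1L, events = 500L, rotation_deg = 325,
                     x_mean = 1e5, x_sd = 200, x_skew = 0.1, x_bic = 1,
                     y_mean = 2e5, y_sd = 400, y_kurtosis = 0.4, y_bic = 2,
                     full_bic = 3, silhouette = 0.8)
  class(rep_) <- c("rosetta_report", "data.frame")
  a <- report_to_generator_args(rep_)[[1]]
  expect_equal(a$num_points, 500L)
  expect_equal(a$center, c(1e5, 2e5))
  expect_equal(a$direction_deg, 325)
  expect_equal(a$proj_sigma, 200)
  expect_equal(a$proj_alpha, 0.1)   # same generator units, no re-division
  expect_equal(a$lateral_sigma, 400)
  expect_equal(a$lateral_beta, 0.4)
  rep_bad <- rep_; rep_bad$x_sd <- 0
  expect_error(report_to_generator_args(rep_bad), "positive")
})

test_that("report files round-trip exactly and fail loudly when truncated", {
  rep_ <- data.frame(cluster_id = 1:2, events = c(5000L, 1000L),
                     rotation_deg = c(325.61, 352.08),
                     x_mean = c(100007.123456789, 102996.5),
                     x_sd = c(196, 100), x_skew = c(0.096, -0.049),
                     x_bic = c(65824.71, 11860.2),
                     y_mean = c(100009, 100204), y_sd = c(398, 260),
                     y_kurtosis = c(0.449, -0.286),
                     y_bic = c(74513.8, 13482.6),
                     full_bic = c(140338.5, 25342.8),
                     silhouette = c(0.823, 0.823))
  class(rep_) <- c("rosetta_report", "data.frame")
  tmp <- file.path(tempdir(), "report.yaml")
  write_report(rep_, tmp, seed = 9L, config = rosetta_config())
  back <- read_report(tmp)
  for (cn in names(rep_))
    expect_equal(back[[cn]], rep_[[cn]], tolerance = 0, label = cn)
  expect_true(file.exists(file.path(tempdir(), "report.csv")))
  csv <- read.csv(file.path(tempdir(), "report.csv"))
  expect_identical(names(csv),
                   c("cluster_id", "events", "rotation_deg", "x_mean", "x_sd",
                     "x_skew", "x_bic", "y_mean", "y_sd", "y_kurtosis",
                     "y_bic", "full_bic", "silhouette"))
  expect_match(attr(back, "meta")$config_hash, "^[0-9a-f]+$")
  # a report missing a mandatory field names it in the error
  doc <- yaml::read_yaml(tmp)
  doc$clusters[[1]]$y_sd <- NULL
  writeLines(yaml::as.yaml(doc), tmp)
  expect_error(read_report(tmp), "y_sd")
})

test_that("end-to-end analyze -> args -> regenerate is self-consistent", {
  # single elongated cluster, moderate size for speed
  a <- generator_args(3000, c(5e4, 5e4), 300, 150, 0.08, 420, 0.3, seed = 31)
  ev <- sample_cluster(a)
  an <- rosetta_analyze(labeled_events(ev$values, rep(0L, 3000)),
                        fast_cfg(use_cluster_id = TRUE, min_clusters = 1),
                        seed = 1)
  r <- an$report
  expect_lt(ang_dist(r$rotation_deg, 300), 2)
  expect_lt(abs(r$y_sd - 420) / 420, 0.05)
  # round trip: regenerate from the report and re-analyze
  a2 <- report_to_generator_args(r, seed = 77)[[1]]
  ev2 <- sample_cluster(a2)
  an2 <- rosetta_analyze(labeled_events(ev2$values, rep(0L, nrow(ev2$values))),
                         fast_cfg(use_cluster_id = TRUE, min_clusters = 1),
                         seed = 2)
  r2 <- an2$report
  expect_lt(ang_dist(r2$rotation_deg, r$rotation_deg), 3)
  expect_lt(abs(r2$x_mean - r$x_mean), 60)
  expect_lt(abs(r2$y_mean - r$y_mean), 60)
  expect_lt(abs(r2$y_sd - r$y_sd) / r$y_sd, 0.06)
  expect_lt(abs(r2$y_kurtosis - r$y_kurtosis), 0.3)
})
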