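#' Analysis configuration
#'
#' The adjustable options controlling clustering, model fitting, rotation
#' adjustment and outlier removal.
#'
#' @param min_clusters,max_clusters search range for the number of clusters
#'   (k-means + silhouette selection); `min_clusters >= 2` unless
#'   `use_cluster_id` is `TRUE`.
#' @param min_components_per_cluster,max_components_per_cluster integer
#'   pairs `(x, y)`: per-dimension mixture component ranges swept by BIC.
#' @param use_cluster_id if `TRUE`, the labels carried by the events are
#'   used as-is and the built-in clustering is bypassed.
#' @param max_iterations maximum EM iterations per fit.
#' @param tolerance convergence tolerance on scaled parameter changes
#'   between EM iterations (location and scale changes are measured relative
#'   to the component scale; shape changes absolutely).
#' @param angle_method `"vertical"` aligns the principal axis with the
#'   vertical, `"horizontal"` with the horizontal.
#' @param outer_percent percent of outermost points (Euclidean distance from
#'   the centroid) excluded temporarily when computing the rotation angle.
#' @param threshold_x,threshold_y outlier-removal cutoffs per dimension, in
#'   standard-deviation (z-score) units; removal is permanent.
#' @return An object of class `rosetta_config`.
#' @export
rosetta_config <- function(min_clusters = 2L, max_clusters = 5L,
                           min_components_per_cluster = c(1L, 1L),
                           max_components_per_cluster = c(2L, 2L),
                           use_cluster_id = FALSE,
                           max_iterations = 100L, tolerance = 1e-3,
                           angle_method = c("vertical", "horizontal"),
                           outer_percent = 2, threshold_x = 3, threshold_y = 3) {
  angle_method <- match.arg(angle_method)
  cfg <- list(min_clusters = as.integer(min_clusters),
              max_clusters = as.integer(max_clusters),
              min_components_per_cluster = as.integer(min_components_per_cluster),
              max_components_per_cluster = as.integer(max_components_per_cluster),
              use_cluster_id = isTRUE(use_cluster_id),
              max_iterations = as.integer(max_iterations),
              tolerance = tolerance, angle_method = angle_method,
              outer_percent = outer_percent,
              threshold_x = threshold_x, threshold_y = threshold_y)
  if (cfg$min_clusters > cfg$max_clusters)
    stop_arg("min_clusters must not exceed max_clusters")
  if (!cfg$use_cluster_id && cfg$min_clusters < 2L)
    stop_arg("min_clusters must be >= 2 when use_cluster_id is FALSE ",
             "(silhouette is undefined for a single cluster)")
  if (length(cfg$min_components_per_cluster) != 2L ||
      length(cfg$max_components_per_cluster) != 2L)
    stop_arg("component ranges must be integer pairs (x, y)")
  if (any(cfg$min_components_per_cluster < 1L) ||
      any(cfg$min_components_per_cluster > cfg$max_components_per_cluster))
    stop_arg("component ranges must satisfy 1 <= min <= max in each dimension")
  if (cfg$tolerance <= 0) stop_arg("tolerance must be positive")
  if (cfg$outer_percent < 0 || cfg$outer_percent >= 100)
    stop_arg("outer_percent must be in [0, 100)")
  if (cfg$threshold_x <= 0 || cfg$threshold_y <= 0)
    stop_arg("outlier thresholds must be positive")
  structure(cfg, class = "rosetta_config")
}

#' @export
print.rosetta_config <- function(x, ...) {
  cat("<rosetta_config>\n")
  for (nm in names(x)) cat(sprintf("  %-28s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  invisible(x)
}

# mean silhouette width; exact up to max_exact points, seeded subsample above
mean_silhouette <- function(values, labels, max_exact = 20000L, seed = NULL) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  n <- nrow(values)
  if (n > max_exact) {
    idx <- with_seed(seed, sample.int(n, max_exact))
    values <- values[idx, , drop = FALSE]; labels <- labels[idx]
    if (length(unique(labels)) < 2L) return(NA_real_)
  }
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(values))
  mean(sil[, "sil_width"])
}

#' Optimal clustering by silhouette selection
#'
#' Runs k-means (k-means++-style multiple restarts via `nstart`) for each
#' candidate number of clusters and keeps the one with the largest mean
#' silhouette width; ties are broken toward fewer clusters. When
#' `cfg$use_cluster_id` is `TRUE` the labels carried by `events` are passed
#' through unchanged and only scored. A mean silhouette below 0.25 triggers
#' a warning that the clustering may be suboptimal.
#'
#' @param events a [labeled_events()].
#' @param cfg a [rosetta_config()].
#' @param seed optional integer seed (k-means restarts and the silhouette
#'   subsample are seeded from it).
#' @return A list with `labels` (integer, 0-based), `k` and `silhouette`.
#' @export
find_optimal_clusters <- function(events, cfg = rosetta_config(), seed = NULL) {
  if (!inherits(events, "labeled_events")) stop_arg("'events' must be labeled_events")
  v <- events$values
  if (cfg$use_cluster_id) {
    if (all(events$labels < 0L)) stop_arg("use_cluster_id is TRUE but events carry no labels")
    labels <- events$labels
    sil <- mean_silhouette(v, labels, seed = seed)
  } else {
    if (nrow(v) < 2L * cfg$min_clusters)
      stop_arg("need at least 2*min_clusters events")
    ks <- seq(cfg$min_clusters, min(cfg$max_clusters, nrow(v) - 1L))
    d <- if (nrow(v) <= 20000L) stats::dist(v) else NULL
    best <- NULL
    for (k in ks) {
      km <- with_seed(seed, kmeans(v, centers = k, nstart = 10L, iter.max = 50L))
      s <- if (is.null(d)) mean_silhouette(v, km$cluster, seed = seed)
           else mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
      if (is.null(best) || s > best$silhouette + 1e-12)
        best <- list(labels = km$cluster - 1L, k = k, silhouette = s)
    }
    labels <- best$labels; sil <- best$silhouette
  }
  if (is.finite(sil) && sil < 0.25)
    warning("mean silhouette ", signif(sil, 3),
            " < 0.25: clustering results may be suboptimal", call. = FALSE)
  list(labels = as.integer(labels),
       k = length(unique(labels[labels >= 0L])), silhouette = sil)
}

#' Principal-axis angle of a point cloud
#'
#' Angle of the maximum-variance eigenvector of the covariance matrix,
#' reported in degrees clockwise from vertical. The eigenvector sign is
#' fixed by requiring a non-negative vertical component, so the angle lies
#' in `[0, 90] U (270, 360)`. Before the covariance is computed, the
#' `outer_percent` of points farthest (Euclidean) from the centroid are
#' excluded — for this computation only — to keep extreme events from
#' tilting the axis.
#'
#' @param points numeric `N x 2` matrix (a.u.).
#' @param outer_percent percent of outermost points to trim, `[0, 100)`.
#' @return Angle in degrees with attribute `direction_defined`; `FALSE`
#'   (with a warning) when the trimmed covariance is near isotropic
#'   (eigenvalue ratio < 1.01) and the axis is therefore undefined.
#' @export
principal_angle <- function(points, outer_percent = 2) {
  points <- as.matrix(points)
  ctr <- colMeans(points)
  P <- sweep(points, 2L, ctr)
  if (outer_percent > 0) {
    d2 <- rowSums(P^2)
    keep <- d2 <= quantile(d2, 1 - outer_percent / 100, names = FALSE)
    if (sum(keep) >= 3L) P <- P[keep, , drop = FALSE]
  }
  if (nrow(P) < 3L) stop_arg("need at least 3 points after trimming")
  ev <- eigen(cov(P), symmetric = TRUE)
  defined <- ev$values[1L] >= 1.01 * ev$values[2L]
  if (!defined)
    warning("cluster is near isotropic: principal direction undefined", call. = FALSE)
  v <- ev$vectors[, 1L]
  if (v[2L] < 0 || (v[2L] == 0 && v[1L] < 0)) v <- -v
  ang <- (atan2(v[1L], v[2L]) * 180 / pi) %% 360
  structure(ang, direction_defined = defined)
}

#' Recorded spatial transform of one cluster
#'
#' Records the centroid and the rotation (degrees clockwise from vertical)
#' that [rotate_to_axis()] applied to reach the analysis orientation, so
#' that [apply_inverse()] can place synthetic replicates back into the
#' original sample geometry. `principal_deg` keeps the cluster's principal
#' axis angle regardless of the alignment method.
#'
#' @param centroid 2-vector, a.u.
#' @param rotation_deg applied rotation, degrees clockwise from vertical.
#' @param principal_deg principal-axis angle, degrees clockwise from
#'   vertical.
#' @return An object of class `cluster_transform`.
#' @export
cluster_transform <- function(centroid, rotation_deg,
                              principal_deg = rotation_deg) {
  structure(list(centroid = as.numeric(centroid),
                 rotation_deg = rotation_deg,
                 principal_deg = principal_deg %% 360),
            class = "cluster_transform")
}

#' Align a cluster with its principal axis
#'
#' Centres the points on their centroid and rotates them so that the
#' principal (maximum-variance) axis is vertical (`angle_method =
#' "vertical"`) or horizontal (`"horizontal"`). The applied centroid and
#' rotation are recorded in the returned transform; the transformation is
#' exactly invertible by [apply_inverse()].
#'
#' @param points numeric `N x 2` matrix (a.u.).
#' @param angle_method `"vertical"` or `"horizontal"`.
#' @param outer_percent trimming percentage passed to [principal_angle()].
#' @return A list with `points` (aligned matrix) and `transform`
#'   (a [cluster_transform()]).
#' @export
rotate_to_axis <- function(points, angle_method = c("vertical", "horizontal"),
                           outer_percent = 2) {
  angle_method <- match.arg(angle_method)
  points <- as.matrix(points)
  theta <- principal_angle(points, outer_percent)
  rot <- if (angle_method == "vertical") as.numeric(theta) else as.numeric(theta) - 90
  ctr <- colMeans(points)
  aligned <- sweep(points, 2L, ctr) %*% rotation_matrix(rot)  # A(rot)^T row-wise
  tr <- cluster_transform(ctr, rot, principal_deg = as.numeric(theta))
  attr(tr, "direction_defined") <- attr(theta, "direction_defined")
  list(points = aligned, transform = tr)
}

#' Undo a cluster alignment
#'
#' Rotates by the recorded angle and translates by the recorded centroid:
#' the exact inverse of [rotate_to_axis()], used to place synthetic
#' replicate clusters back into the original sample geometry.
#'
#' @param points numeric `N x 2` matrix in the aligned frame.
#' @param transform a [cluster_transform()].
#' @return Matrix of repositioned points.
#' @export
apply_inverse <- function(points, transform) {
  if (!inherits(transform, "cluster_transform"))
    stop_arg("'transform' must be a cluster_transform")
  points <- as.matrix(points)
  sweep(points %*% t(rotation_matrix(transform$rotation_deg)),
        2L, transform$centroid, `+`)
}

#' Remove per-dimension z-score outliers
#'
#' Permanently removes every point whose absolute z-score (computed from the
#' mean and standard deviation of the input, per dimension) exceeds the
#' dimension's threshold.
#'
#' @param points numeric `N x 2` matrix.
#' @param threshold_x,threshold_y positive cutoffs in SD units.
#' @return The retained points, with attributes `removed` (count) and
#'   `bounds` (the per-dimension retention window, used downstream by the
#'   truncation-aware model fit).
#' @export
remove_outliers <- function(points, threshold_x = 3, threshold_y = 3) {
  if (threshold_x <= 0 || threshold_y <= 0) stop_arg("thresholds must be positive")
  points <- as.matrix(points)
  mx <- mean(points[, 1L]); sx <- sd(points[, 1L])
  my <- mean(points[, 2L]); sy <- sd(points[, 2L])
  keep <- abs(points[, 1L] - mx) / sx <= threshold_x &
          abs(points[, 2L] - my) / sy <= threshold_y
  if (!any(keep))
    stop_arg("outlier removal discarded every point; thresholds are degenerate")
  structure(points[keep, , drop = FALSE], removed = sum(!keep),
            bounds = list(x = c(mx - threshold_x * sx, mx + threshold_x * sx),
                          y = c(my - threshold_y * sy, my + threshold_y * sy)))
}
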