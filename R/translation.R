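#' @keywords internal
.report_columns <- c("cluster_id", "events", "rotation_deg",
                     "x_mean", "x_sd", "x_skew", "x_bic",
                     "y_mean", "y_sd", "y_kurtosis", "y_bic",
                     "full_bic", "silhouette")

# mixture aggregate of one dimension model: overall location mean and SD
# via the mixture-moment identity on the component (w, mu, sigma) tables.
.dim_aggregate <- function(comps) {
  m <- sum(comps$weight * comps$mu)
  v <- sum(comps$weight * (comps$sigma^2 + comps$mu^2)) - m^2
  dom <- which.max(comps$weight)
  list(mean = m, sd = sqrt(v), shape = comps$shape[dom])
}

#' Summarize a fitted model as a report row
#'
#' Aggregates each dimension's mixture to an overall mean and SD via the
#' standard mixture-moment identity (variance `sum w_i (sigma_i^2 + mu_i^2)
#' - mean^2`); the reported shape is the dominant-weight component's. The
#' dimension means are re-expressed in the original (pre-rotation)
#' coordinates through the recorded inverse transform; the rotation column
#' is the cluster's principal-axis angle clockwise from vertical. The
#' X-dimension shape is reported in generator skew units (the fitted
#' distribution shape divided by 2*pi, see [alpha_from_generator_skew()]);
#' the Y-dimension shape is the kurtosis-family `beta`.
#'
#' @param model a [em_fit()] / [select_model()] result.
#' @param transform the cluster's [cluster_transform()].
#' @param silhouette silhouette score carried from clustering (may be `NA`).
#' @param cluster_id integer identifier for the report row.
#' @param events event count recorded on the row; defaults to the number of
#'   fitted points, but the analysis pipeline records the cluster's full
#'   size before outlier removal so that regeneration restores it.
#' @return A one-row `rosetta_report` data frame with columns
#'   `cluster_id, events, rotation_deg, x_mean, x_sd, x_skew, x_bic,
#'   y_mean, y_sd, y_kurtosis, y_bic, full_bic, silhouette`.
#' @export
model_to_report <- function(model, transform, silhouette = NA_real_,
                            cluster_id = 1L, events = model$n_events) {
  if (!inherits(model, "cluster_model")) stop_arg("'model' must be a cluster_model")
  if (!inherits(transform, "cluster_transform"))
    stop_arg("'transform' must be a cluster_transform")
  ax <- .dim_aggregate(model$x_model$components)
  ay <- .dim_aggregate(model$y_model$components)
  orig <- as.numeric(rotation_matrix(transform$rotation_deg) %*%
                       c(ax$mean, ay$mean) + transform$centroid)
  out <- data.frame(
    cluster_id = as.integer(cluster_id), events = as.integer(events),
    rotation_deg = transform$principal_deg,
    x_mean = orig[1L], x_sd = ax$sd,
    x_skew = generator_skew_from_alpha(ax$shape), x_bic = model$x_model$bic,
    y_mean = orig[2L], y_sd = ay$sd,
    y_kurtosis = ay$shape, y_bic = model$y_model$bic,
    full_bic = model$full_bic, silhouette = silhouette)
  class(out) <- c("rosetta_report", "data.frame")
  out
}

# analyze one cluster's points: align, clean, fit, report
.analyze_cluster <- function(points, cfg, silhouette = NA_real_,
                             cluster_id = 1L) {
  al <- rotate_to_axis(points, cfg$angle_method, cfg$outer_percent)
  kept <- remove_outliers(al$points, cfg$threshold_x, cfg$threshold_y)
  model <- select_model(kept[, 1L], kept[, 2L], cfg,
                        bounds = attr(kept, "bounds"))
  list(model = model, transform = al$transform,
       report = model_to_report(model, al$transform, silhouette, cluster_id,
                                events = nrow(points)))
}

#' Run the full analysis routine on an event table
#'
#' The end-to-end deciphering pipeline: optimal clustering (or label
#' pass-through), principal-axis alignment, permanent z-score outlier
#' removal, histogram-initialized constrained EM fitting with BIC component
#' selection, and aggregation into one report row per cluster. Clusters are
#' numbered 1..k by decreasing size.
#'
#' @param events a [labeled_events()].
#' @param cfg a [rosetta_config()].
#' @param seed optional integer seed (clustering restarts).
#' @return An object of class `rosetta_analysis`: list with `report`
#'   (a `rosetta_report` data frame), `models`, `transforms`, and
#'   `clustering` (`k`, `silhouette`, 0-based `labels`).
#' @examples
#' \donttest{
#' ev <- two_cluster_fixture(seed = 1)
#' an <- rosetta_analyze(ev, rosetta_config(), seed = 1)
#' an$report
#' }
#' @export
rosetta_analyze <- function(events, cfg = rosetta_config(), seed = NULL) {
  if (!inherits(events, "labeled_events")) stop_arg("'events' must be labeled_events")
  foc <- find_optimal_clusters(events, cfg, seed = seed)
  ids <- sort(unique(foc$labels[foc$labels >= 0L]))
  sizes <- vapply(ids, function(i) sum(foc$labels == i), integer(1L))
  ids <- ids[order(-sizes, ids)]
  models <- list(); transforms <- list(); rows <- list()
  for (j in seq_along(ids)) {
    pts <- events$values[foc$labels == ids[j], , drop = FALSE]
    res <- .analyze_cluster(pts, cfg, silhouette = foc$silhouette, cluster_id = j)
    models[[j]] <- res$model; transforms[[j]] <- res$transform
    rows[[j]] <- res$report
  }
  report <- do.call(rbind, rows)
  class(report) <- c("rosetta_report", "data.frame")
  structure(list(report = report, models = models, transforms = transforms,
                 clustering = foc),
            class = "rosetta_analysis")
}

#' @export
print.rosetta_analysis <- function(x, ...) {
  cat(sprintf("<rosetta_analysis: %d cluster(s), silhouette %s>\n",
              nrow(x$report),
              if (is.na(x$clustering$silhouette)) "NA"
              else sprintf("%.3f", x$clustering$silhouette)))
  print(as.data.frame(x$report), row.names = FALSE, digits = 6)
  invisible(x)
}

#' Translate a report into generator arguments
#'
#' The statistic-to-argument mapping: events become `num_points`, the
#' reported dimension means the cluster `center` (the report already
#' expresses the fitted support-line location in original coordinates), the
#' rotation the generator `direction_deg`, the X-dimension SD and skew the
#' projection-axis scale and shape, and the Y-dimension SD and kurtosis the
#' principal-axis scale and tail shape. Report skew and generator skew
#' share the same units, so the value passes through unchanged (the
#' division by pi and 2 was applied once, when the fitted shape entered the
#' report).
#'
#' @param report a `rosetta_report` (any number of rows).
#' @param seed optional seed stored on each returned argument set.
#' @return A list of [generator_args()], one per report row.
#' @export
report_to_generator_args <- function(report, seed = NULL) {
  if (!inherits(report, "data.frame")) stop_arg("'report' must be a rosetta_report")
  if (any(report$x_sd <= 0) || any(report$y_sd <= 0))
    stop_arg("report SDs must be strictly positive")
  sub <- derive_seeds(seed, nrow(report))
  lapply(seq_len(nrow(report)), function(i) {
    r <- report[i, ]
    generator_args(num_points = r$events,
                   center = c(r$x_mean, r$y_mean),
                   direction_deg = r$rotation_deg,
                   proj_sigma = r$x_sd, proj_alpha = r$x_skew,
                   lateral_sigma = r$y_sd, lateral_beta = r$y_kurtosis,
                   seed = sub[[i]])
  })
}

#' Write / read a report file
#'
#' `write_report()` stores the report as a structured key-value text file
#' (YAML) carrying provenance metadata (package version, seed, config), and
#' a flat CSV mirror with one row per cluster in the fixed column order
#' `cluster_id, events, rotation_deg, x_mean, x_sd, x_skew, x_bic, y_mean,
#' y_sd, y_kurtosis, y_bic, full_bic, silhouette`. `read_report()` restores
#' the report exactly; a missing mandatory field raises an error naming it.
#'
#' @param report a `rosetta_report`.
#' @param path destination of the structured-text file.
#' @param csv_path destination of the CSV mirror; default replaces the
#'   extension of `path` with `.csv` (set `NA` to skip).
#' @param seed,config optional provenance recorded in the file header.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the `rosetta_report`.
#' @export
write_report <- function(report, path, csv_path = NULL,
                         seed = NULL, config = NULL) {
  if (!inherits(report, "data.frame")) stop_arg("'report' must be a rosetta_report")
  if (is.null(csv_path)) csv_path <- sub("\\.[A-Za-z]+$", ".csv", path)
  meta <- list(generator = "flowrosetta",
               version = as.character(packageVersion("flowrosetta")),
               created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(seed)) meta$seed <- as.integer(seed)
  if (!is.null(config)) {
    meta$config <- unclass(config)
    ser <- paste(names(meta$config), vapply(meta$config, function(v)
      paste(format(v, digits = 15), collapse = ","), character(1L)),
      sep = "=", collapse = ";")
    meta$config_hash <- sprintf("%08x",
      sum(utf8ToInt(ser) * (seq_len(nchar(ser)) %% 31L + 1L)) %% 4294967296)
  }
  clusters <- lapply(seq_len(nrow(report)), function(i)
    as.list(report[i, .report_columns]))
  writeLines(yaml::as.yaml(list(meta = meta, clusters = clusters),
                           precision = 17L), path)
  if (!is.na(csv_path))
    write.csv(as.data.frame(report)[, .report_columns], csv_path,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_arg("no such report file: ", path)
  doc <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_arg("malformed report file: ",
                                               conditionMessage(e)))
  if (is.null(doc$clusters)) stop_arg("report file is missing field 'clusters'")
  rows <- lapply(doc$clusters, function(cl) {
    for (f in .report_columns)
      if (is.null(cl[[f]])) stop_arg("report cluster entry is missing field '", f, "'")
    as.data.frame(cl[.report_columns])
  })
  out <- do.call(rbind, rows)
  out$cluster_id <- as.integer(out$cluster_id)
  out$events <- as.integer(out$events)
  class(out) <- c("rosetta_report", "data.frame")
  attr(out, "meta") <- doc$meta
  out
}
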