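#' Field-by-field comparison of two reports
#'
#' Per-cluster absolute and percent differences of every numeric report
#' field, with `b` compared relative to `a` (percent difference
#' `100 * (b - a) / a`; `NA` when the reference is zero).
#'
#' @param a,b `rosetta_report` data frames with the same number of
#'   clusters.
#' @return A data frame with one row per cluster and field: `cluster_id`,
#'   `field`, `a`, `b`, `abs_diff`, `pct_diff`.
#' @export
compare_reports <- function(a, b) {
  if (!inherits(a, "data.frame") || !inherits(b, "data.frame"))
    stop_arg("'a' and 'b' must be rosetta_report data frames")
  if (nrow(a) != nrow(b)) stop_arg("reports have different cluster counts")
  fields <- setdiff(.report_columns, "cluster_id")
  out <- list()
  for (i in seq_len(nrow(a))) {
    va <- unlist(a[i, fields]); vb <- unlist(b[i, fields])
    out[[i]] <- data.frame(
      cluster_id = a$cluster_id[i], field = fields,
      a = as.numeric(va), b = as.numeric(vb),
      abs_diff = abs(as.numeric(vb) - as.numeric(va)),
      pct_diff = ifelse(va == 0, NA_real_,
                        100 * (as.numeric(vb) - as.numeric(va)) / as.numeric(va)),
      row.names = NULL)
  }
  do.call(rbind, out)
}

#' Distributional comparison of two event tables
#'
#' For each channel: the two-sample Kolmogorov-Smirnov statistic and the
#' overlap coefficient of 64-bin shared-range histograms (the sum of
#' per-bin minimum proportions), both in `[0, 1]`. Identical samples give
#' KS 0 and overlap 1.
#'
#' @param real,synth [labeled_events()] (non-empty).
#' @param bins number of shared-range histogram bins.
#' @return A data frame with one row per channel: `channel`, `ks_stat`,
#'   `overlap`.
#' @export
distribution_compare <- function(real, synth, bins = 64L) {
  for (e in list(real, synth))
    if (!inherits(e, "labeled_events") || nrow(e$values) == 0L)
      stop_arg("inputs must be non-empty labeled_events")
  out <- lapply(1:2, function(j) {
    a <- real$values[, j]; b <- synth$values[, j]
    ks <- suppressWarnings(ks.test(a, b)$statistic)
    rng <- range(c(a, b))
    br <- seq(rng[1L], rng[2L], length.out = bins + 1L)
    pa <- tabulate(pmin(pmax(findInterval(a, br, rightmost.closed = TRUE), 1L),
                        bins), nbins = bins) / length(a)
    pb <- tabulate(pmin(pmax(findInterval(b, br, rightmost.closed = TRUE), 1L),
                        bins), nbins = bins) / length(b)
    data.frame(channel = real$channel_names[j],
               ks_stat = as.numeric(ks), overlap = sum(pmin(pa, pb)))
  })
  do.call(rbind, out)
}

#' Generational-variance experiment
#'
#' Generates `n_seeds` replicate datasets from the same generator argument
#' sets with distinct derived RNG seeds, runs the full analysis routine on
#' each, and summarizes every recovered report parameter as a mean and SD
#' across seeds — the spread attributable purely to random number
#' generation.
#'
#' @param specs list of [generator_args()] (or a single one).
#' @param n_seeds number of replicates (>= 2).
#' @param cfg a [rosetta_config()].
#' @param seed master seed from which the replicate seeds are derived.
#' @return An object of class `generational_variance`: list with `mean`
#'   and `sd` report-shaped data frames, the individual `reports`, and
#'   `failures` (character vector of failed replicates, normally empty).
#' @export
generational_variance <- function(specs, n_seeds = 13L,
                                  cfg = rosetta_config(), seed = NULL) {
  if (n_seeds < 2L) stop_arg("'n_seeds' must be >= 2")
  if (inherits(specs, "generator_args")) specs <- list(specs)
  seeds <- derive_seeds(if (is.null(seed)) 1L else seed, 2L * n_seeds)
  reports <- list(); failures <- character()
  for (i in seq_len(n_seeds)) {
    res <- tryCatch({
      ev <- sample_dataset(specs, seed = seeds[[i]])
      rosetta_analyze(ev, cfg, seed = seeds[[n_seeds + i]])$report
    }, error = function(e) e)
    if (inherits(res, "error"))
      failures <- c(failures, sprintf("seed %d: %s", i, conditionMessage(res)))
    else reports[[length(reports) + 1L]] <- res
  }
  if (length(reports) == 0L)
    stop_arg("every replicate analysis failed:\n  ",
             paste(failures, collapse = "\n  "))
  fields <- setdiff(.report_columns, "cluster_id")
  ids <- reports[[1L]]$cluster_id
  agg <- function(f) {
    rows <- lapply(ids, function(cid) {
      vals <- vapply(fields, function(fd) {
        xs <- vapply(reports, function(r) r[[fd]][r$cluster_id == cid][1L],
                     numeric(1L))
        f(xs)
      }, numeric(1L))
      cbind(data.frame(cluster_id = cid), as.data.frame(as.list(vals)))
    })
    do.call(rbind, rows)
  }
  structure(list(mean = agg(mean), sd = agg(sd),
                 reports = reports, failures = failures,
                 n_seeds = n_seeds),
            class = "generational_variance")
}

#' @export
print.generational_variance <- function(x, ...) {
  cat(sprintf("<generational_variance: %d replicates, %d failure(s)>\nmeans:\n",
              x$n_seeds, length(x$failures)))
  print(x$mean, row.names = FALSE, digits = 6)
  cat("sds:\n")
  print(x$sd, row.names = FALSE, digits = 4)
  invisible(x)
}
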