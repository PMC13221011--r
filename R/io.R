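# ---------------------------------------------------------------------
# Event table, configuration and gate file input/output.
# CSV is the canonical interchange format; FCS support is a minimal
# list-mode float implementation of the FCS 3.0/3.1 standard (no
# compensation or transforms are ever applied).
# ---------------------------------------------------------------------

#' Read an event table
#'
#' Reads CSV (columns: two channels plus an optional integer `cluster_id`)
#' or FCS 3.0/3.1 (list mode, float or double data) event files. Channel
#' names are matched case-insensitively; for FCS both the $PnN and $PnS
#' keywords are consulted. Values are returned raw, in channel arbitrary
#' units — no compensation or transformation is applied.
#'
#' @param path input file; format inferred from the `.csv` / `.fcs`
#'   extension.
#' @param channels optional two channel names; default: the first two
#'   non-label columns/parameters.
#' @return A [labeled_events()].
#' @export
read_events <- function(path, channels = NULL) {
  if (!file.exists(path)) stop_arg("no such file: ", path)
  if (grepl("\\.fcs$", path, ignore.case = TRUE))
    .read_events_fcs(path, channels)
  else .read_events_csv(path, channels)
}

.pick_channels <- function(available, channels, labels_col = "cluster_id") {
  usable <- setdiff(available, labels_col)
  if (is.null(channels)) {
    if (length(usable) < 2L) stop_arg("need at least two channel columns")
    return(usable[1:2])
  }
  if (length(channels) != 2L) stop_arg("'channels' must name two channels")
  idx <- match(tolower(channels), tolower(available))
  if (anyNA(idx))
    stop_arg("channel(s) not found: ",
             paste(channels[is.na(idx)], collapse = ", "),
             "; available: ", paste(usable, collapse = ", "))
  available[idx]
}

.read_events_csv <- function(path, channels) {
  df <- read.csv(path, check.names = FALSE)
  sel <- .pick_channels(names(df), channels)
  labels <- if ("cluster_id" %in% names(df)) as.integer(df[["cluster_id"]]) else NULL
  labeled_events(as.matrix(df[, sel]), labels, channel_names = sel)
}

#' Write an event table
#'
#' CSV files get a header of the two channel names plus `cluster_id`; FCS
#' files are written as FCS 3.1, list mode, 32-bit float, little endian,
#' with the labels stored as a third integer-valued parameter
#' (`cluster_id`). Both round-trip through [read_events()] (exactly for
#' CSV, to float32 precision for FCS).
#'
#' @param events a [labeled_events()].
#' @param path output file.
#' @param format `"csv"` or `"fcs"`; default inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, format = NULL) {
  if (!inherits(events, "labeled_events")) stop_arg("'events' must be labeled_events")
  if (is.null(format))
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  format <- match.arg(format, c("csv", "fcs"))
  if (format == "csv") {
    # full-precision serialization so CSV round trips are exact
    df <- data.frame(a = sprintf("%.17g", events$values[, 1L]),
                     b = sprintf("%.17g", events$values[, 2L]),
                     cluster_id = events$labels)
    names(df)[1:2] <- events$channel_names
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    .write_fcs(events, path)
  }
  invisible(path)
}

## ------------------------- minimal FCS 3.1 ---------------------------

.fcs_text_segment <- function(kw) {
  d <- "/"
  paste0(d, paste(vapply(names(kw), function(k)
    paste0(k, d, kw[[k]]), character(1L)), collapse = d), d)
}

.write_fcs <- function(events, path) {
  n <- nrow(events$values)
  dat <- cbind(events$values, as.numeric(events$labels))
  npar <- ncol(dat)
  names_ <- c(events$channel_names, "cluster_id")
  databytes <- n * npar * 4L
  kw <- list("$FCSversion" = "3.1", "$MODE" = "L", "$DATATYPE" = "F",
             "$BYTEORD" = "1,2,3,4", "$PAR" = npar, "$TOT" = n,
             "$NEXTDATA" = 0)
  for (j in seq_len(npar)) {
    kw[[sprintf("$P%dN", j)]] <- names_[j]
    kw[[sprintf("$P%dB", j)]] <- 32
    kw[[sprintf("$P%dE", j)]] <- "0,0"
    kw[[sprintf("$P%dR", j)]] <- format(ceiling(max(abs(dat[, j]), 1)) * 2,
                                        scientific = FALSE)
  }
  # two-pass: compute offsets with placeholder, then rewrite
  header_len <- 58L
  make_text <- function(bd, ed) {
    kw$"$BEGINDATA" <- bd; kw$"$ENDDATA" <- ed
    kw$"$BEGINANALYSIS" <- 0; kw$"$ENDANALYSIS" <- 0
    .fcs_text_segment(kw)
  }
  txt <- make_text(0, 0)
  # iterate once more so the offset digits are stable
  for (i in 1:3) {
    ts <- header_len
    te <- ts + nchar(txt, type = "bytes") - 1L
    bd <- te + 1L
    ed <- bd + databytes - 1L
    new_txt <- make_text(bd, ed)
    if (nchar(new_txt, type = "bytes") == nchar(txt, type = "bytes")) {
      txt <- new_txt; break
    }
    txt <- new_txt
  }
  ts <- header_len
  te <- ts + nchar(txt, type = "bytes") - 1L
  bd <- te + 1L; ed <- bd + databytes - 1L
  hdr <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", ts, te,
                 if (bd <= 99999999) bd else 0,
                 if (ed <= 99999999) ed else 0, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  writeBin(charToRaw(txt), con)
  writeBin(as.vector(t(dat)), con, size = 4L, endian = "little")
  invisible(path)
}

.parse_fcs_text <- function(raw_txt) {
  txt <- rawToChar(raw_txt)
  d <- substr(txt, 1L, 1L)
  parts <- strsplit(substring(txt, 2L), d, fixed = TRUE)[[1L]]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- parts[seq(1L, length(parts), by = 2L)]
  vals <- parts[seq(2L, length(parts), by = 2L)]
  setNames(as.list(trimws(vals)), toupper(trimws(keys)))
}

.read_events_fcs <- function(path, channels) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 58L))
  if (!grepl("^FCS3\\.[01]", hdr)) stop_arg("malformed FCS header (not FCS 3.0/3.1)")
  off <- suppressWarnings(as.integer(c(
    substr(hdr, 11L, 18L), substr(hdr, 19L, 26L),
    substr(hdr, 27L, 34L), substr(hdr, 35L, 42L))))
  if (anyNA(off)) stop_arg("malformed FCS header offsets")
  seek(con, off[1L])
  kw <- .parse_fcs_text(readBin(con, "raw", off[2L] - off[1L] + 1L))
  need <- function(k) {
    v <- kw[[toupper(k)]]
    if (is.null(v)) stop_arg("FCS file missing keyword ", k)
    v
  }
  npar <- as.integer(need("$PAR")); ntot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  if (!dtype %in% c("F", "D"))
    stop_arg("unsupported FCS $DATATYPE '", dtype, "' (only F/D)")
  endian <- if (startsWith(need("$BYTEORD"), "1")) "little" else "big"
  bd <- as.integer(kw[["$BEGINDATA"]]); ed <- as.integer(kw[["$ENDDATA"]])
  if (is.null(bd) || is.na(bd) || bd == 0L) { bd <- off[3L]; ed <- off[4L] }
  size <- if (dtype == "F") 4L else 8L
  seek(con, bd)
  dat <- readBin(con, "numeric", n = npar * ntot, size = size, endian = endian)
  m <- matrix(dat, ncol = npar, byrow = TRUE)
  pnames <- vapply(seq_len(npar), function(j) {
    nm <- kw[[sprintf("$P%dN", j)]]
    if (is.null(nm) || nm == "") nm <- kw[[sprintf("$P%dS", j)]]
    if (is.null(nm) || nm == "") nm <- sprintf("P%d", j)
    nm
  }, character(1L))
  sel <- .pick_channels(pnames, channels)
  labels <- if ("cluster_id" %in% pnames)
    as.integer(round(m[, match("cluster_id", pnames)])) else NULL
  labeled_events(m[, match(sel, pnames), drop = FALSE], labels,
                 channel_names = sel)
}

## ------------------------- config and gate files ---------------------

#' Read / write a run configuration file
#'
#' Configurations are stored as structured text (YAML) with the field
#' names of [rosetta_config()] verbatim; `parse(serialize(config))`
#' round-trips exactly.
#'
#' @param cfg a [rosetta_config()].
#' @param path file path.
#' @return `read_config()` returns a [rosetta_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  if (!inherits(cfg, "rosetta_config")) stop_arg("'cfg' must be a rosetta_config")
  writeLines(yaml::as.yaml(unclass(cfg), precision = 17L), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_arg("no such config file: ", path)
  lst <- yaml::read_yaml(path)
  known <- names(formals(rosetta_config))
  extra <- setdiff(names(lst), known)
  if (length(extra) > 0L)
    stop_arg("unknown configuration field(s): ", paste(extra, collapse = ", "))
  do.call(rosetta_config, lst)
}

#' Read / write a polygon gate file
#'
#' Gates are stored as structured text (YAML): a `name` and an ordered
#' `vertices` list of `[x, y]` pairs in channel coordinates.
#'
#' @param g a [gate()].
#' @param path file path.
#' @return `read_gate()` returns a [gate()]; `write_gate()` returns `path`
#'   invisibly.
#' @export
write_gate <- function(g, path) {
  if (!inherits(g, "gate")) stop_arg("'g' must be a gate")
  writeLines(yaml::as.yaml(list(
    name = g$name,
    vertices = lapply(seq_len(nrow(g$vertices)),
                      function(i) as.numeric(g$vertices[i, ]))),
    precision = 17L), path)
  invisible(path)
}

#' @rdname write_gate
#' @export
read_gate <- function(path) {
  if (!file.exists(path)) stop_arg("no such gate file: ", path)
  lst <- yaml::read_yaml(path)
  if (is.null(lst$vertices)) stop_arg("gate file is missing field 'vertices'")
  gate(do.call(rbind, lst$vertices),
       name = if (is.null(lst$name)) "gate" else lst$name)
}
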