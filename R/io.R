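# Text I/O: delimited time-series matrices in, JSON emergence reports out.

#' Read a multivariate time series from a delimited text file
#'
#' Accepts tab- or comma-delimited text with a header row.  An optional
#' `trial` column splits the rows into trials (lagged pairs never cross
#' trials); rows within a trial are taken in file order.
#'
#' @param path file path (.tsv/.txt = tab, .csv = comma; otherwise the
#'   delimiter is sniffed from the header line).
#' @param system_cols names of the system columns.
#' @param feature_cols names of the feature columns (optional).
#' @param kind "discrete" (integer codes) or "continuous"; columns are
#'   validated against it.
#' @return list with `system` (a [sample_matrix]) and `feature` (a
#'   [sample_matrix] or NULL).
#' @export
read_timeseries <- function(path, system_cols, feature_cols = NULL,
                            kind = c("discrete", "continuous")) {
  kind <- match.arg(kind)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  header <- readLines(path, n = 1)
  if (!grepl(sep, header, fixed = TRUE))
    sep <- if (sep == "\t") "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      colClasses = "numeric", comment.char = ""),
    error = function(e) {
      # re-parse to localise the offending line for the error message
      lines <- strsplit(readLines(path), sep, fixed = TRUE)
      ncol1 <- length(lines[[1]])
      bad <- which(vapply(lines, length, integer(1)) != ncol1)[1]
      if (!is.na(bad))
        stop(sprintf("ragged row in %s: line %d has %d fields, expected %d",
                     path, bad, length(lines[[bad]]), ncol1), call. = FALSE)
      nums <- suppressWarnings(lapply(lines[-1], as.numeric))
      for (i in seq_along(nums)) {
        j <- which(is.na(nums[[i]]))[1]
        if (!is.na(j))
          stop(sprintf("non-numeric value in %s: line %d, column '%s'",
                       path, i + 1, lines[[1]][j]), call. = FALSE)
      }
      stop(sprintf("could not parse %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  need <- c(system_cols, feature_cols)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("missing named column(s) in %s: %s", path,
                 paste(missing_cols, collapse = ", ")))
  if (kind == "discrete") {
    for (nm in need) {
      v <- df[[nm]]
      if (any(v != round(v)) || any(v < 0))
        stop(sprintf("column '%s' is not non-negative integer codes; %s", nm,
                     "use kind = \"continuous\" or discretise"))
    }
  }
  trial <- if ("trial" %in% names(df)) df$trial else rep(1, nrow(df))
  ids <- unique(trial)
  lens <- table(trial)
  if (length(unique(lens)) != 1)
    stop("all trials must have the same number of rows")
  Tn <- as.integer(lens[1])
  to_array <- function(cols) {
    a <- array(0, dim = c(length(ids), Tn, length(cols)))
    for (i in seq_along(ids))
      a[i, , ] <- as.matrix(df[trial == ids[i], cols, drop = FALSE])
    sample_matrix(a, kind = kind, vars = cols)
  }
  list(system = to_array(system_cols),
       feature = if (length(feature_cols)) to_array(feature_cols))
}

#' Write a sample matrix to a delimited text file
#'
#' Inverse of [read_timeseries()]: writes a header row, one row per
#' (trial, time) sample, with a `trial` column when there is more than one
#' trial.
#'
#' @param x a [sample_matrix].
#' @param path output path (.csv = comma, otherwise tab).
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "sample_matrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- pooled_rows(x)
  df <- as.data.frame(m)
  if (n_trials(x) > 1)
    df <- cbind(trial = rep(seq_len(n_trials(x)), each = n_time(x)), df)
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

report_schema_version <- "1"

#' Serialise an emergence report to JSON
#'
#' Writes all report fields (criteria, components, surrogate summary,
#' verdicts and provenance) plus a schema version; [read_report()] is its
#' inverse.
#'
#' @param report an `emergence_report` from [emergence()].
#' @param path output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "emergence_report"))
  payload <- unclass(report)
  payload$schema_version <- report_schema_version
  # keep names through JSON: named vectors serialise as objects
  payload$components <- as.list(payload$components)
  if (!is.null(payload$surrogate))
    for (f in c("mean", "sd", "p_value"))
      payload$surrogate[[f]] <- as.list(payload$surrogate[[f]])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an emergence report written by [write_report()]
#'
#' @param path JSON path.
#' @return an `emergence_report`.
#' @export
read_report <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(as.character(payload$schema_version), report_schema_version))
    stop(sprintf("report schema version mismatch: file has '%s', reader expects '%s'",
                 payload$schema_version, report_schema_version))
  payload$schema_version <- NULL
  payload$components <- unlist(payload$components)
  if (!is.null(payload$surrogate)) {
    for (f in c("mean", "sd", "p_value"))
      payload$surrogate[[f]] <- unlist(payload$surrogate[[f]])
    payload$surrogate$gamma_q95 <- as.numeric(payload$surrogate$gamma_q95)
  }
  structure(payload, class = "emergence_report")
}
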