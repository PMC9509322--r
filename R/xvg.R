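# GROMACS XVG pull-file dialect: '#' comment lines, '@' grace directives,
# blank lines allowed, whitespace-separated numeric columns. Single data set
# per file (pullf.xvg / pullx.xvg), first column time in ps, second column
# force in kJ/mol/nm or distance in nm.

#' Read a GROMACS-style XVG pull file
#'
#' Parses the two-column plain-text format written by the GROMACS pull code
#' (`pullf.xvg` / `pullx.xvg`): lines starting with `#` or `@` are metadata
#' and ignored, blank lines are skipped, data rows are whitespace-separated
#' numbers with time (ps) first and force (kJ/mol/nm) or distance (nm)
#' second.
#'
#' @param path file to read.
#' @param kind `"force"` or `"distance"`: selects the return type.
#' @param ... metadata passed on to [force_trace()] (velocity, spring_k,
#'   temperature, replica_id); ignored for distance traces.
#' @return A [force_trace()] or [distance_trace()].
#' @examples
#' f <- tempfile(fileext = ".xvg")
#' writeLines(c("# pull force", "@ title \"f\"", "0.0 0.0", "0.1 5.0"), f)
#' read_xvg(f, "force")
#' @export
read_xvg <- function(path, kind = c("force", "distance"), ...) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_meta <- grepl("^\\s*[#@]", lines) | !nzchar(trimws(lines))
  data_idx <- which(!is_meta)
  if (length(data_idx) < 2L)
    stop("degenerate input: fewer than 2 data rows in ", path)
  t <- numeric(length(data_idx))
  y <- numeric(length(data_idx))
  for (i in seq_along(data_idx)) {
    fields <- strsplit(trimws(lines[data_idx[i]]), "\\s+")[[1]]
    if (length(fields) < 2L)
      stop("parse error at line ", data_idx[i], " of ", path,
           ": expected at least 2 columns")
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (anyNA(vals))
      stop("parse error at line ", data_idx[i], " of ", path,
           ": non-numeric field in '", lines[data_idx[i]], "'")
    t[i] <- vals[1]
    y[i] <- vals[2]
  }
  if (any(diff(t) <= 0))
    stop("validation error: times not strictly increasing in ", path)
  if (kind == "force") force_trace(t, y, ...) else distance_trace(t, y)
}

#' Write a trace in the XVG dialect
#'
#' Inverse of [read_xvg()]: writes comment metadata lines followed by two
#' whitespace-separated numeric columns at full double precision, so that
#' read/write round-trips are exact to within formatting (17 significant
#' digits).
#'
#' @param trace a [force_trace()] or [distance_trace()].
#' @param path output file.
#' @param comments character vector written as leading '#' lines.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(trace, path, comments = character()) {
  if (inherits(trace, "force_trace")) {
    y <- trace$forces
    header <- c("# pull force (kJ/mol/nm) vs time (ps)",
                "@ xaxis label \"Time (ps)\"",
                "@ yaxis label \"Force (kJ/mol/nm)\"")
  } else if (inherits(trace, "distance_trace")) {
    y <- trace$distances
    header <- c("# COM-COM distance (nm) vs time (ps)",
                "@ xaxis label \"Time (ps)\"",
                "@ yaxis label \"Distance (nm)\"")
  } else stop("trace must be a force_trace or distance_trace")
  rows <- paste(formatC(trace$times, format = "g", digits = 17),
                formatC(y, format = "g", digits = 17))
  writeLines(c(paste0("# ", comments), header, rows), path)
  invisible(path)
}

#' Write records as a CSV table with a fixed schema
#'
#' Deterministic column order (the order of `columns`, default the data frame
#' order), a header row, and floats rendered with a configurable number of
#' significant digits. Tables written this way are re-readable losslessly at
#' the chosen precision with [read_table_csv()].
#'
#' @param records a data frame (may have zero rows: a header-only file is
#'   written).
#' @param path output file.
#' @param columns optional character vector fixing the column order; must
#'   name existing, non-duplicated columns.
#' @param digits significant digits for numeric columns (default 6).
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(records, path, columns = NULL, digits = 6) {
  records <- as.data.frame(records)
  if (anyDuplicated(names(records)))
    stop("schema error: duplicate column names: ",
         paste(names(records)[duplicated(names(records))], collapse = ", "))
  if (!is.null(columns)) {
    if (!all(columns %in% names(records)))
      stop("schema error: unknown columns: ",
           paste(setdiff(columns, names(records)), collapse = ", "))
    if (anyDuplicated(columns))
      stop("schema error: duplicate column names in schema")
    records <- records[, columns, drop = FALSE]
  }
  out <- records
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]]))
      out[[j]] <- formatC(out[[j]], format = "g", digits = digits)
  }
  tryCatch(
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("I/O error writing ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
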