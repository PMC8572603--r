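#' Read a time-series table (CSV or OpenSim-style .sto/.mot)
#'
#' Reads a tabular time series whose first column is `time`. Two dialects
#' are supported: comma-separated with a header row, and OpenSim-style
#' storage/motion text (free header lines terminated by `endheader`,
#' then a tab-delimited table). The dialect is inferred from the file
#' extension (`.sto`/`.mot` vs anything else) unless given explicitly.
#'
#' @param path File to read.
#' @param dialect `"auto"` (default), `"csv"` or `"sto"`.
#' @return Data frame with a `time` first column; for the sto dialect the
#'   raw header lines are kept in `attr(, "header")`.
#' @export
read_timeseries <- function(path, dialect = c("auto", "csv", "sto")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(sto|mot)$", path, ignore.case = TRUE))
      "sto" else "csv"
  }
  if (dialect == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    header <- NULL
  } else {
    lines <- readLines(path)
    end <- which(trimws(lines) == "endheader")
    if (!length(end)) {
      stop("not an OpenSim-style storage file (no `endheader` line): ",
           path, "\n  hint: use dialect = \"csv\" for comma-separated ",
           "tables with a single header row", call. = FALSE)
    }
    header <- lines[seq_len(end[1] - 1)]
    body <- lines[-seq_len(end[1])]
    body <- body[nzchar(trimws(body))]
    df <- utils::read.delim(text = paste(body, collapse = "\n"),
                            check.names = FALSE)
  }
  if (!ncol(df) || tolower(names(df)[1]) != "time") {
    stop("first column must be `time`; got: ",
         paste(utils::head(names(df), 3), collapse = ", "), call. = FALSE)
  }
  names(df)[1] <- "time"
  if (any(!is.finite(df$time)) || any(diff(df$time) <= 0)) {
    stop("`time` column must be finite and strictly increasing",
         call. = FALSE)
  }
  if (!is.null(header)) attr(df, "header") <- header
  df
}

#' Write a time-series table (CSV or OpenSim-style .sto/.mot)
#'
#' Inverse of [read_timeseries()]. Values are written with 15 significant
#' digits so a write/read round trip reproduces them to within 1e-12
#' relative error.
#'
#' @param x Data frame whose first column is `time`.
#' @param path Output file.
#' @param dialect `"auto"` (by extension), `"csv"` or `"sto"`.
#' @param header Character vector of header lines for the sto dialect
#'   (before the automatic `nRows`/`nColumns` lines); defaults to the file
#'   name.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path, dialect = c("auto", "csv", "sto"),
                             header = NULL) {
  dialect <- match.arg(dialect)
  x <- as.data.frame(x)
  if (!ncol(x) || tolower(names(x)[1]) != "time") {
    stop("first column must be `time`", call. = FALSE)
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(sto|mot)$", path, ignore.case = TRUE))
      "sto" else "csv"
  }
  fmt <- function(v) {
    if (is.numeric(v)) sprintf("%.15g", v) else as.character(v)
  }
  cells <- vapply(x, fmt, character(nrow(x)))
  if (!is.matrix(cells)) cells <- matrix(cells, nrow = nrow(x))
  if (dialect == "csv") {
    writeLines(c(paste(names(x), collapse = ","),
                 apply(cells, 1, paste, collapse = ",")), path)
  } else {
    if (is.null(header)) header <- basename(path)
    writeLines(c(header,
                 sprintf("nRows=%d", nrow(x)),
                 sprintf("nColumns=%d", ncol(x)),
                 "endheader",
                 paste(names(x), collapse = "\t"),
                 apply(cells, 1, paste, collapse = "\t")), path)
  }
  invisible(path)
}

#' Write a torque result to disk
#'
#' Writes the tidy per-muscle state table (`muscle_states.csv`: `time,
#' muscle, l_mt, l_m, v_n, phi, f_l, f_v, f_PE, F_M, r, tau`) and the
#' resultant torque series (`resultant.csv`: `time, tau_sum`) produced by
#' [simulate_elbow_torque()] into a directory.
#'
#' @param result A `torque_result`.
#' @param dir Output directory (created if absent).
#' @param dialect Dialect for the resultant series file; the per-muscle
#'   long table is always CSV.
#' @return The directory, invisibly.
#' @export
write_torque_result <- function(result, dir, dialect = "csv") {
  stopifnot(inherits(result, "torque_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$samples, file.path(dir, "muscle_states.csv"),
                   row.names = FALSE)
  ext <- if (dialect == "sto") "sto" else "csv"
  write_timeseries(result$resultant,
                   file.path(dir, paste0("resultant.", ext)),
                   dialect = dialect)
  invisible(dir)
}
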