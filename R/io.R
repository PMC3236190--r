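#' Read an ISI series from a plain-text file
#'
#' Accepts one decimal interval per line, or two comma-separated columns
#' with the provenance label (`pattern`/`noise`) in the second column.
#' Blank lines and lines starting with `#` are skipped. Non-numeric,
#' non-positive or non-finite intervals are rejected with the offending
#' line number.
#'
#' @param path Path to the file.
#' @return An [isi_series()].
#' @export
read_isi <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty series file: ", path)
  has_label <- grepl(",", lines, fixed = TRUE)
  vals <- numeric(length(lines))
  labs <- rep(NA_character_, length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    v <- suppressWarnings(as.numeric(trimws(parts[1])))
    if (is.na(v) || !is.finite(v)) {
      stop("line ", lineno[i], ": not a finite number: '", lines[i], "'")
    }
    if (v <= 0) {
      stop("line ", lineno[i], ": interval must be strictly positive: '",
           lines[i], "'")
    }
    vals[i] <- v
    if (length(parts) > 1L) labs[i] <- trimws(parts[2])
  }
  labels <- NULL
  if (any(has_label)) {
    if (!all(has_label)) {
      stop("mixed labelled and unlabelled lines (first unlabelled at line ",
           lineno[which(!has_label)[1]], ")")
    }
    if (!all(labs %in% c("pattern", "noise"))) {
      bad <- which(!labs %in% c("pattern", "noise"))[1]
      stop("line ", lineno[bad], ": label must be 'pattern' or 'noise'")
    }
    labels <- labs
  }
  isi_series(vals, labels = labels)
}

#' Write an ISI series to a plain-text file
#'
#' Inverse of [read_isi()]: one interval per line at full (17 significant
#' digit) precision, with a second comma-separated label column when the
#' series carries labels.
#'
#' @param series An [isi_series()] or numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isi <- function(series, path) {
  if (is.numeric(series)) series <- isi_series(series)
  stopifnot(inherits(series, "isi_series"))
  vals <- formatC(series$intervals, format = "g", digits = 17)
  lines <- if (is.null(series$labels)) vals else
    paste(vals, series$labels, sep = ",")
  writeLines(lines, path)
  invisible(path)
}

#' Write a correlation curve as TSV
#'
#' Columns `log10_eps`, `log10_C`, `m`.
#'
#' @param curve A `correlation_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a correlation curve written by [write_curve()]
#'
#' @param path Path to the TSV file.
#' @return A `correlation_curve` (grid metadata reconstructed from the
#'   samples).
#' @export
read_curve <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  structure(list(log_eps = df$log10_eps, log_C = df$log10_C,
                 m = df$m[1], n_points = NA_integer_, n_ref = NA_integer_,
                 log_eps_step = stats::median(diff(df$log10_eps)),
                 norm = "max"),
            class = "correlation_curve")
}
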