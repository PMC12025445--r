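#' Paired method-comparison dataset
#'
#' Container for specimen-wise paired measurements: `x` from the comparative
#' (reference) method and `y` from the candidate method under validation,
#' both on the same unit scale. This is the substrate of all comparison
#' statistics in the package.
#'
#' @param x numeric vector of comparative-method values (finite, > 0).
#' @param y numeric vector of candidate-method values, same length as `x`.
#' @param unit `"ifcc"` or `"ngsp"`.
#' @param ids optional character vector of specimen labels.
#' @return an object of class `paired_dataset`: a list with elements `x`,
#'   `y`, `unit`, `ids` and `n`.
#' @examples
#' d <- paired_dataset(c(35, 47, 64), c(34, 46, 63), unit = "ifcc")
#' d$n
#' @export
paired_dataset <- function(x, y, unit = c("ifcc", "ngsp"), ids = NULL) {
  x <- check_numeric(x, "x")
  y <- check_numeric(y, "y")
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (any(x <= 0) || any(y <= 0)) {
    stop("all measurement values must be > 0", call. = FALSE)
  }
  unit <- unit_system(unit)
  if (!is.null(ids)) {
    ids <- as.character(ids)
    if (length(ids) != length(x)) {
      stop("`ids` must match the number of pairs", call. = FALSE)
    }
  }
  structure(
    list(x = x, y = y, unit = unit, ids = ids, n = length(x)),
    class = "paired_dataset"
  )
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat("Paired method-comparison dataset:", x$n, "specimens, unit",
      unit_label(x$unit), "\n")
  cat("  comparative: median", format(median(x$x)), " range [",
      format(min(x$x)), ", ", format(max(x$x)), "]\n", sep = "")
  cat("  candidate:   median", format(median(x$y)), " range [",
      format(min(x$y)), ", ", format(max(x$y)), "]\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.paired_dataset <- function(x, ...) {
  data.frame(
    id = if (is.null(x$ids)) as.character(seq_len(x$n)) else x$ids,
    x = x$x, y = x$y, stringsAsFactors = FALSE
  )
}

#' Differences candidate - comparative
#'
#' @param data a [paired_dataset()].
#' @return numeric vector `y - x` (candidate minus comparative).
#' @export
paired_differences <- function(data) {
  stopifnot(inherits(data, "paired_dataset"))
  data$y - data$x
}

#' Read a paired measurement table from delimited text
#'
#' Reads a comma- or tab-delimited file (auto-detected from the header line)
#' with one row per specimen. Rows whose `x` or `y` entry is missing or
#' non-numeric are dropped with a warning reporting the count. Decimal
#' commas are rejected with an error naming the offending line.
#'
#' @param path path to the delimited text file (header required).
#' @param x_col,y_col column names holding the comparative and candidate
#'   values. Defaults `"x"` and `"y"`.
#' @param unit `"ifcc"` or `"ngsp"`.
#' @param id_col optional column name holding specimen labels.
#' @return a [paired_dataset()].
#' @export
read_paired_table <- function(path, x_col = "x", y_col = "y",
                              unit = c("ifcc", "ngsp"), id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("file has no data rows: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  # decimal commas are ambiguous with the comma separator; refuse them
  bad <- grep("[0-9],[0-9]", if (sep == "\t") lines[-1] else character(0))
  if (length(bad) > 0) {
    stop("decimal commas are not supported (line ", bad[1] + 1, " of ", path,
         ")", call. = FALSE)
  }
  tab <- read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE)
  for (col in c(x_col, y_col)) {
    if (!col %in% names(tab)) {
      stop("column '", col, "' not found in ", path, call. = FALSE)
    }
  }
  xs <- suppressWarnings(as.numeric(tab[[x_col]]))
  ys <- suppressWarnings(as.numeric(tab[[y_col]]))
  usable <- is.finite(xs) & is.finite(ys) & xs > 0 & ys > 0
  n_drop <- sum(!usable)
  if (n_drop > 0) {
    warning(n_drop, " row(s) dropped: missing or non-numeric entries",
            call. = FALSE)
  }
  if (sum(usable) < 3) {
    stop("fewer than 3 usable rows in ", path, call. = FALSE)
  }
  ids <- if (!is.null(id_col) && id_col %in% names(tab)) {
    as.character(tab[[id_col]][usable])
  } else {
    NULL
  }
  paired_dataset(xs[usable], ys[usable], unit = unit, ids = ids)
}

#' Write a paired dataset as CSV
#'
#' @param data a [paired_dataset()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_paired_table <- function(data, path) {
  stopifnot(inherits(data, "paired_dataset"))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Clinical decision limits
#'
#' Validates an ordered set of medical decision limits against the plausible
#' assay range for the unit scale (NGSP 3-20 %, IFCC 10-200 mmol/mol).
#' The conventional HbA1c limits are 39 and 47 mmol/mol (5.7 and 6.4 %) for
#' increased diabetes risk and diagnosis, with 53 and 64 mmol/mol
#' (7.0 and 8.0 %) as common treatment targets.
#'
#' @param limits strictly increasing numeric vector of decision values.
#' @param unit `"ifcc"` or `"ngsp"`.
#' @return an object of class `decision_limits`.
#' @export
decision_limits <- function(limits, unit = c("ifcc", "ngsp")) {
  limits <- check_numeric(limits, "limits")
  unit <- unit_system(unit)
  if (is.unsorted(limits, strictly = TRUE)) {
    stop("decision limits must be strictly increasing", call. = FALSE)
  }
  rng <- if (unit == "ifcc") c(10, 200) else c(3, 20)
  if (any(limits < rng[1]) || any(limits > rng[2])) {
    stop("decision limits outside the plausible assay range [",
         rng[1], ", ", rng[2], "] ", unit_label(unit), call. = FALSE)
  }
  structure(list(limits = limits, unit = unit), class = "decision_limits")
}

#' Allowable total error (ATE) limits
#'
#' Symmetric bound on the candidate-minus-comparative difference deemed
#' clinically acceptable; for HbA1c the conventional value is +/-5 mmol/mol
#' (+/-0.46 %), the minimum difference that would lead to a change in
#' therapy.
#'
#' @param half_width positive half-width of the symmetric ATE band, in
#'   dataset units.
#' @param unit `"ifcc"` or `"ngsp"`.
#' @return an object of class `ate_limits`.
#' @export
ate_limits <- function(half_width, unit = c("ifcc", "ngsp")) {
  half_width <- check_numeric(half_width, "half_width")
  if (length(half_width) != 1 || half_width <= 0) {
    stop("`half_width` must be a single positive value", call. = FALSE)
  }
  structure(list(half_width = half_width, unit = unit_system(unit)),
            class = "ate_limits")
}

#' Default ATE limits for a unit system
#'
#' @param unit `"ifcc"` or `"ngsp"`.
#' @return an [ate_limits()] object: 5 mmol/mol or 0.46 %.
#' @export
default_ate <- function(unit = c("ifcc", "ngsp")) {
  unit <- unit_system(unit)
  ate_limits(if (unit == "ifcc") 5 else 0.46, unit = unit)
}
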