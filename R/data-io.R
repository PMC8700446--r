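#' Packaged engineering lifetime datasets
#'
#' Two classical engineering datasets shipped as plain-text fixtures:
#' `"yarn"` (25 values) gives cycles to failure of 100 cm yarn specimens
#' tested at a fixed strain level; `"equipment"` (30 values) gives times
#' between failures of repairable mechanical equipment items.
#'
#' @param name `"yarn"` or `"equipment"`.
#' @return numeric vector of positive lifetimes, with attributes `name` and
#'   `source`.
#' @examples
#' length(eigo_data("yarn"))   # 25
#' @export
eigo_data <- function(name = c("yarn", "equipment")) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: yarn, equipment", call. = FALSE)
  })
  path <- system.file("extdata", paste0(name, ".csv"), package = "eigompertz",
                      mustWork = TRUE)
  values <- read_lifetimes(path)
  attr(values, "name") <- name
  attr(values, "source") <- switch(name,
    yarn = "cycles to failure of 25 yarn specimens (100 cm) at fixed strain",
    equipment = "time between failures of 30 repairable mechanical equipment items")
  values
}

#' Read a one-column file of positive lifetimes
#'
#' Accepts plain text or single-column CSV: one number per line, blank lines
#' and `#` comment lines skipped.  Non-numeric or non-positive entries are an
#' error naming the offending line.
#'
#' @param path file to read.
#' @return numeric vector of positive values.
#' @export
read_lifetimes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  vals <- suppressWarnings(as.numeric(lines[keep]))
  if (anyNA(vals)) {
    bad <- idx[which(is.na(vals))[1L]]
    stop("non-numeric entry at line ", bad, " of ", path, ": '", lines[bad], "'")
  }
  if (any(vals <= 0)) {
    bad <- idx[which(vals <= 0)[1L]]
    stop("non-positive lifetime at line ", bad, " of ", path, ": '", lines[bad], "'")
  }
  if (!length(vals)) stop("no data in ", path)
  vals
}

#' Write lifetimes as a one-column text file
#'
#' Full-precision companion to [read_lifetimes()]: values round-trip
#' bit-exactly.
#'
#' @param values numeric vector of positive lifetimes.
#' @param path destination file.
#' @export
write_lifetimes <- function(values, path) {
  stop_if_not_positive(values, "values")
  writeLines(sprintf("%.17g", values), path)
  invisible(path)
}
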