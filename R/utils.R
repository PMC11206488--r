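#' Read a simple key/value configuration file
#'
#' Parses plain-text files of `key = value` lines. `#` starts a comment,
#' blank lines are ignored, and comma-separated values become numeric
#' vectors when every element parses as a number; everything else is kept
#' as a character scalar.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_kv_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (line in lines) {
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) {
      stop("malformed config line (no '='): ", line, call. = FALSE)
    }
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(parts))
    out[[key]] <- if (!anyNA(nums)) nums else val
  }
  out
}

# stop() with a consistent message for invalid nutrient input
check_nonneg_finite <- function(x, field) {
  if (!is.numeric(x)) {
    stop("field '", field, "' must be numeric", call. = FALSE)
  }
  bad <- !is.finite(x) | x < 0
  if (any(bad)) {
    stop(
      "field '", field, "' must be non-negative and finite (offending value at position ",
      which(bad)[1], ")",
      call. = FALSE
    )
  }
  invisible(x)
}

# count of thresholds strictly exceeded, vectorised over x
points_from_thresholds <- function(x, thresholds) {
  as.integer(rowSums(outer(x, thresholds, FUN = ">")))
}
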