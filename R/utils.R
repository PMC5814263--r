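# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Format numbers for the TSV dialect so that read-back is bit-exact.
#' @noRd
fmt_field <- function(x) {
  out <- character(length(x))
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else formatC(v, digits = 17, format = "g")
    }, character(1))
  } else if (is.logical(x)) {
    out <- ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE"))
  } else {
    x <- as.character(x)
    out <- ifelse(is.na(x), "", x)
  }
  out
}

#' Parse numeric fields, flagging genuinely malformed (non-empty, non-numeric)
#' values with the originating line number.
#' @noRd
parse_num <- function(x, lines, what) {
  x[!nzchar(x)] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("line %d: malformed %s value '%s'",
                 lines[bad[1]], what, x[bad[1]]), call. = FALSE)
  }
  out
}

#' @noRd
parse_lgl <- function(x, lines, what) {
  x <- toupper(trimws(x))
  x[!nzchar(x)] <- NA_character_
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop(sprintf("line %d: malformed %s value '%s'",
                 lines[bad[1]], what, x[bad[1]]), call. = FALSE)
  }
  out
}

# Display rounding used by reports: stored values keep full precision,
# display strings follow the presentation conventions (R^2 to 4 decimals,
# percentages to the nearest whole number).
#' @noRd
display_r2 <- function(x) formatC(round(x, 4), format = "f", digits = 4)

#' @noRd
display_pct <- function(x) formatC(round(x), format = "d")
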