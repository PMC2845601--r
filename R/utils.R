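#' Round half away from zero
#'
#' Standard commercial rounding used for all rendered report values: ties go
#' away from zero rather than to even as in [base::round()]. `1/X kb`
#' densities are rounded to integer kb and percentages to one decimal with
#' this rule.
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal places to keep.
#' @return numeric vector of the same length.
#' @examples
#' roundHalfUp(0.5)    # 1, where round(0.5) gives 0
#' roundHalfUp(6.65, 1)
#' @export
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render a reciprocal mutation density
#'
#' Formats kb-per-mutation values in the conventional `"1/X kb"` style with
#' X rounded half away from zero to integer kb. Undefined densities (no
#' mutations observed) render as `"-"`.
#'
#' @param kbPerMutation numeric vector of kb-per-mutation values (`NA` for
#'   undefined).
#' @return character vector.
#' @examples
#' formatDensity(c(558.8, NA))
#' @export
formatDensity <- function(kbPerMutation) {
  out <- ifelse(is.na(kbPerMutation), "-",
                sprintf("1/%d kb", as.integer(roundHalfUp(kbPerMutation))))
  out
}

## "3,885" -> 3885; "-" -> 0 (zero cells are printed as dashes in screen
## tables); anything else non-numeric is a parse error reported by callers.
.parseCount <- function(x) {
  x <- trimws(as.character(x))
  x[x == "-"] <- "0"
  x <- gsub(",", "", x, fixed = TRUE)
  suppressWarnings(as.numeric(x))
}

.isSingleString <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

.stopf <- function(fmt, ..., class = "tillkit_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

## collapse repeated whitespace and trim; used for vocabulary matching
.squish <- function(x) gsub("[[:space:]]+", " ", trimws(x))

DNA_BASES4 <- c("A", "C", "G", "T")

.complementBase <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[x])
}
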