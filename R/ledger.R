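#' Population ledger: per-dose generation accounting
#'
#' A population ledger records, per mutagen dose, how many seeds were
#' treated, how many M1 plants were transplanted, and how many M2 and M3
#' seed families were obtained. Attrition is monotone:
#' `m3_families <= m2_families <= m1_transplanted <= seeds_treated`.
#'
#' `populationLedger()` builds and checks the ledger; `readLedger()` loads
#' one from a delimited file with the same column names (thousands
#' separators accepted); `redSetterLedger()` returns the packaged ledger of
#' the Red Setter tomato collection.
#'
#' @param dose dose labels.
#' @param seeds_treated,m1_transplanted,m2_families,m3_families
#'   non-negative integer counts per dose.
#' @return data.frame with the five columns above.
#' @seealso [ledgerSummary()]
#' @examples
#' redSetterLedger()
#' @export
populationLedger <- function(dose, seeds_treated, m1_transplanted,
                             m2_families, m3_families) {
  led <- data.frame(dose = as.character(dose),
                    seeds_treated = as.integer(seeds_treated),
                    m1_transplanted = as.integer(m1_transplanted),
                    m2_families = as.integer(m2_families),
                    m3_families = as.integer(m3_families),
                    stringsAsFactors = FALSE)
  counts <- as.matrix(led[-1])
  if (any(counts < 0))
    .stopf("ledger counts must be non-negative")
  bad <- led$m3_families > led$m2_families |
    led$m2_families > led$m1_transplanted |
    led$m1_transplanted > led$seeds_treated
  if (any(bad))
    .stopf("attrition must be monotone (m3 <= m2 <= m1 <= seeds) in dose %s",
           paste(sQuote(led$dose[bad]), collapse = ", "))
  led
}

#' @rdname populationLedger
#' @param path delimited file with header
#'   `dose seeds_treated m1_transplanted m2_families m3_families`.
#' @param sep field delimiter.
#' @export
readLedger <- function(path, sep = "\t") {
  if (!file.exists(path))
    .stopf("ledger file not found: %s", path, class = "tillkit_input_error")
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", stringsAsFactors = FALSE)
  need <- c("dose", "seeds_treated", "m1_transplanted", "m2_families",
            "m3_families")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    .stopf("ledger missing column(s): %s",
           paste(sQuote(miss), collapse = ", "),
           class = "tillkit_format_error")
  populationLedger(raw$dose, .parseCount(raw$seeds_treated),
                   .parseCount(raw$m1_transplanted),
                   .parseCount(raw$m2_families),
                   .parseCount(raw$m3_families))
}

#' @rdname populationLedger
#' @export
redSetterLedger <- function() {
  readLedger(system.file("extdata", "red_setter_ledger.tsv",
                         package = "tillkit", mustWork = TRUE))
}

#' Summarize a population ledger
#'
#' Adds, per dose and in a grand-total row, the number of M2 families that
#' failed to yield M3 seed (`m2_families - m3_families`) and the failure
#' rate as a percentage rounded to one decimal.
#'
#' @param ledger data.frame as returned by [populationLedger()].
#' @return data.frame: the ledger columns plus `m3_failures` and
#'   `m3_failure_rate_pct`, with a final `"Total"` row.
#' @examples
#' ledgerSummary(redSetterLedger())
#' @export
ledgerSummary <- function(ledger) {
  ledger <- populationLedger(ledger$dose, ledger$seeds_treated,
                             ledger$m1_transplanted, ledger$m2_families,
                             ledger$m3_families)
  tot <- data.frame(dose = "Total",
                    seeds_treated = sum(ledger$seeds_treated),
                    m1_transplanted = sum(ledger$m1_transplanted),
                    m2_families = sum(ledger$m2_families),
                    m3_families = sum(ledger$m3_families),
                    stringsAsFactors = FALSE)
  out <- rbind(ledger, tot)
  out$m3_failures <- out$m2_families - out$m3_families
  out$m3_failure_rate_pct <- ifelse(
    out$m2_families > 0,
    roundHalfUp(100 * out$m3_failures / out$m2_families, 1L),
    0)
  out
}
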