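#' Read a screen summary table
#'
#' Reads a delimited screen table with one row per amplicon per dose and
#' header columns `gene`, `amplicon_kb`, `families_screened`, `mutations`,
#' `dose`, and returns one [CohortScreen-class] per dose in order of first
#' appearance. Numbers may carry thousands separators (`"3,885"`); a dash
#' in the `mutations` column means zero (the convention used in printed
#' screen tables). Any density-like columns are ignored: densities are
#' outputs, not inputs.
#'
#' @param path file path.
#' @param sep field delimiter, tab by default.
#' @return list of [CohortScreen-class], named by dose label.
#' @seealso [writeScreenTable()], [redSetterScreen()]
#' @examples
#' screens <- redSetterScreen()
#' screenTable(screens[["0.7% EMS"]])
#' @export
readScreenTable <- function(path, sep = "\t") {
  if (!file.exists(path))
    .stopf("screen table not found: %s", path, class = "tillkit_input_error")
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("gene", "amplicon_kb", "families_screened", "mutations", "dose")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    .stopf("screen table missing column(s): %s",
           paste(sQuote(miss), collapse = ", "),
           class = "tillkit_format_error")
  numeric_cols <- c("amplicon_kb", "families_screened", "mutations")
  for (col in numeric_cols) {
    vals <- .parseCount(raw[[col]])
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (length(bad))
      .stopf("non-numeric value '%s' in column '%s', row %d",
             raw[[col]][bad[1]], col, bad[1], class = "tillkit_parse_error")
    raw[[col]] <- vals
  }
  doses <- unique(raw$dose)
  out <- lapply(doses, function(d) {
    sub <- raw[raw$dose == d, , drop = FALSE]
    cohortScreen(d, data.frame(
      gene = sub$gene,
      amplicon_kb = sub$amplicon_kb,
      families_screened = as.integer(sub$families_screened),
      mutations = as.integer(sub$mutations),
      stringsAsFactors = FALSE))
  })
  names(out) <- doses
  out
}

#' Write a screen summary table
#'
#' Inverse of [readScreenTable()]: serializes cohorts to the long delimited
#' layout. Zero-mutation cells are written as `"-"` (the printed-table
#' convention); thousands separators are never emitted.
#'
#' @param cohorts list of [CohortScreen-class] (or a single one).
#' @param path output file path.
#' @param sep field delimiter.
#' @return invisibly, `path`.
#' @export
writeScreenTable <- function(cohorts, path, sep = "\t") {
  if (is(cohorts, "CohortScreen")) cohorts <- list(cohorts)
  rows <- do.call(rbind, lapply(cohorts, function(co) {
    tab <- screenTable(co)
    data.frame(gene = tab$gene,
               amplicon_kb = tab$amplicon_kb,
               families_screened = tab$families_screened,
               mutations = ifelse(tab$mutations == 0L, "-",
                                  as.character(tab$mutations)),
               dose = doseLabel(co), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' The Red Setter tomato validation screen
#'
#' Packaged transcription of the published seven-gene TILLING validation
#' screen of the Red Setter EMS populations: per amplicon and dose, the
#' amplicon size, number of M3 families screened and mutations identified
#' (41 at 0.7% EMS, 25 at 1% EMS over 9.447 kb of amplicons).
#'
#' @return list of two [CohortScreen-class] objects (`"0.7% EMS"`,
#'   `"1% EMS"`).
#' @seealso [densityReport()], [redSetterLedger()]
#' @examples
#' densityReport(redSetterScreen())
#' @export
redSetterScreen <- function() {
  readScreenTable(system.file("extdata", "red_setter_screen.tsv",
                              package = "tillkit", mustWork = TRUE))
}
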