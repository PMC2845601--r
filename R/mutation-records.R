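REGION_LEVELS <- c("coding", "noncoding", "unknown")
EFFECT_LEVELS <- c("silent", "missense", "nonsense", "stop-loss")

#' Build a table of mutation records
#'
#' Canonical tabular representation of individual induced substitutions:
#' one row per mutation with the amplicon (gene) name, the M3 family it was
#' found in, its 1-based position on the amplicon forward strand, reference
#' and alternate base, the genomic region and, for coding positions, the
#' predicted coding effect.
#'
#' @param gene,family_id character vectors (recycled to a common length).
#' @param position 1-based integer positions within the amplicon.
#' @param ref,alt single bases in `A, C, G, T`; `ref != alt` rowwise.
#' @param region one of `"coding"`, `"noncoding"`, `"unknown"`.
#' @param effect one of `"silent"`, `"missense"`, `"nonsense"`,
#'   `"stop-loss"`, or `NA` when not applicable/known.
#' @param amplicon optional [AmpliconTarget-class] used to bounds-check
#'   positions.
#' @return data.frame with columns `gene`, `family_id`, `position`, `ref`,
#'   `alt`, `region`, `effect`.
#' @examples
#' mutationRecords("Exp1", "F012", 42, "C", "T")
#' @export
mutationRecords <- function(gene, family_id = NA_character_, position,
                            ref, alt, region = "unknown", effect = NA,
                            amplicon = NULL) {
  df <- data.frame(gene = as.character(gene),
                   family_id = as.character(family_id),
                   position = as.integer(position),
                   ref = toupper(as.character(ref)),
                   alt = toupper(as.character(alt)),
                   region = as.character(region),
                   effect = as.character(effect),
                   stringsAsFactors = FALSE)
  validateMutationRecords(df, amplicon = amplicon)
}

#' @rdname mutationRecords
#' @export
emptyMutationRecords <- function() {
  data.frame(gene = character(), family_id = character(),
             position = integer(), ref = character(), alt = character(),
             region = character(), effect = character(),
             stringsAsFactors = FALSE)
}

#' @rdname mutationRecords
#' @param records a data.frame of mutation records to check.
#' @export
validateMutationRecords <- function(records, amplicon = NULL) {
  need <- names(emptyMutationRecords())
  miss <- setdiff(need, names(records))
  if (length(miss))
    .stopf("mutation records lack column(s) %s",
           paste(sQuote(miss), collapse = ", "),
           class = "tillkit_format_error")
  records <- records[need]
  if (nrow(records) == 0L) return(records)
  badBase <- !(records$ref %in% DNA_BASES4) | !(records$alt %in% DNA_BASES4)
  if (any(badBase))
    .stopf("invalid base in record(s) %s (bases must be A/C/G/T)",
           paste(which(badBase), collapse = ", "))
  same <- records$ref == records$alt
  if (any(same))
    .stopf("ref equals alt in record(s) %s", paste(which(same), collapse = ", "))
  if (any(is.na(records$position)) || any(records$position < 1L))
    .stopf("positions must be 1-based positive integers")
  if (!all(records$region %in% REGION_LEVELS))
    .stopf("region must be one of %s",
           paste(sQuote(REGION_LEVELS), collapse = ", "))
  if (!all(is.na(records$effect) | records$effect %in% EFFECT_LEVELS))
    .stopf("effect must be NA or one of %s",
           paste(sQuote(EFFECT_LEVELS), collapse = ", "))
  if (!is.null(amplicon)) {
    lim <- as.integer(round(ampliconKb(amplicon) * 1000))
    out <- records$position > lim
    if (any(out))
      .stopf("position beyond amplicon '%s' (%d bp) in record(s) %s",
             geneName(amplicon), lim, paste(which(out), collapse = ", "),
             class = "tillkit_bounds_error")
  }
  records
}
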