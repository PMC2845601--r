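#' @rdname AmpliconTarget-class
setMethod("geneName", "AmpliconTarget", function(x) x@geneName)

#' @rdname AmpliconTarget-class
setMethod("ampliconKb", "AmpliconTarget", function(x) x@lengthKb)

#' @rdname AmpliconTarget-class
setMethod("refSequence", "AmpliconTarget", function(x) x@sequence)

#' @rdname AmpliconTarget-class
setMethod("cdsSegments", "AmpliconTarget", function(x) x@cdsSegments)

#' @rdname AmpliconTarget-class
setMethod("frameOffset", "AmpliconTarget", function(x) x@frameOffset)

#' @rdname CohortScreen-class
setMethod("doseLabel", "CohortScreen", function(x) x@doseLabel)

#' @rdname CohortScreen-class
setMethod("screenTable", "CohortScreen", function(x) x@screenTable)

#' @rdname CohortScreen-class
setMethod("mutations", "CohortScreen", function(x) x@mutationRecords)

#' @rdname CohortScreen-class
setMethod("amplicons", "CohortScreen", function(x) x@amplicons)

setMethod("show", "AmpliconTarget", function(object) {
  cat(sprintf("AmpliconTarget '%s': %.3f kb", object@geneName,
              object@lengthKb))
  if (!is.null(object@sequence)) cat(", with sequence")
  if (!is.null(object@cdsSegments))
    cat(sprintf(", %d CDS segment(s), frame offset %d",
                length(object@cdsSegments), object@frameOffset))
  cat("\n")
})

setMethod("show", "CohortScreen", function(object) {
  tab <- object@screenTable
  cat(sprintf("CohortScreen '%s': %d amplicon(s), %s screened kb, %d mutation(s)\n",
              object@doseLabel, nrow(tab),
              format(sum(tab$amplicon_kb * tab$families_screened)),
              sum(tab$mutations)))
  if (nrow(object@mutationRecords))
    cat(sprintf("  with %d individual mutation record(s)\n",
                nrow(object@mutationRecords)))
})

setMethod("show", "SimulationParams", function(object) {
  cat(sprintf(paste0(
    "SimulationParams: rate %.5f /kb (1/%s kb), %d families, %d amplicon(s)\n",
    "  segregation (%s), detection %.2f, %d plants/family, %d-fold pools, seed %d\n"),
    object@ratePerKb,
    format(roundHalfUp(1 / object@ratePerKb)),
    object@families, length(object@amplicons),
    paste(object@segregationProbs, collapse = ":"),
    object@detectionProb, object@plantsPooled, object@poolSize, object@seed))
})
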