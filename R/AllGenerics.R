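#' @rdname AmpliconTarget-class
#' @param x,object an object.
#' @export
setGeneric("geneName", function(x) standardGeneric("geneName"))

#' @rdname AmpliconTarget-class
#' @export
setGeneric("ampliconKb", function(x) standardGeneric("ampliconKb"))

#' @rdname AmpliconTarget-class
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))

#' @rdname AmpliconTarget-class
#' @export
setGeneric("cdsSegments", function(x) standardGeneric("cdsSegments"))

#' @rdname AmpliconTarget-class
#' @export
setGeneric("frameOffset", function(x) standardGeneric("frameOffset"))

#' @rdname CohortScreen-class
#' @export
setGeneric("doseLabel", function(x) standardGeneric("doseLabel"))

#' @rdname CohortScreen-class
#' @export
setGeneric("screenTable", function(x) standardGeneric("screenTable"))

#' @rdname CohortScreen-class
#' @export
setGeneric("mutations", function(x) standardGeneric("mutations"))

#' @rdname CohortScreen-class
#' @export
setGeneric("amplicons", function(x) standardGeneric("amplicons"))
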