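#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet GENETIC_CODE
#' @importClassesFrom Biostrings DNAString
#' @importFrom IRanges IRanges start end width
#' @importClassesFrom IRanges IRanges
NULL

setClassUnion("DNAString_OR_NULL", c("DNAString", "NULL"))
setClassUnion("IRanges_OR_NULL", c("IRanges", "NULL"))

#' AmpliconTarget: a tilled gene fragment
#'
#' Represents one PCR amplicon screened for induced mutations: its gene
#' label, its length in kilobases, and optionally its reference sequence
#' with coding (CDS) segments. Positions are 1-based inclusive on the
#' forward strand of the amplicon; genes on the genomic reverse strand must
#' be supplied as reverse-complemented amplicons so that coordinate handling
#' stays single-stranded.
#'
#' The concatenated CDS need not be a multiple of 3 (amplicons truncate
#' genes); `frameOffset` gives the number of bases of the first CDS segment
#' that complete a codon started upstream of the amplicon (0, 1 or 2),
#' which fixes the codon phase of every coding base.
#'
#' @slot geneName single character label.
#' @slot lengthKb amplicon length in kb, positive.
#' @slot sequence a [Biostrings::DNAString] or `NULL`.
#' @slot cdsSegments an [IRanges::IRanges] of 1-based inclusive CDS
#'   intervals on the amplicon, or `NULL` when the coding structure is
#'   unknown.
#' @slot frameOffset integer 0-2, reading-frame offset of the first CDS
#'   segment.
#'
#' @seealso [ampliconTarget()], [annotateMutations()]
#' @aliases AmpliconTarget
#' @exportClass AmpliconTarget
setClass("AmpliconTarget",
  representation(
    geneName = "character",
    lengthKb = "numeric",
    sequence = "DNAString_OR_NULL",
    cdsSegments = "IRanges_OR_NULL",
    frameOffset = "integer"
  ),
  prototype(sequence = NULL, cdsSegments = NULL, frameOffset = 0L)
)

setValidity("AmpliconTarget", function(object) {
  msg <- character()
  if (!.isSingleString(object@geneName) || !nzchar(object@geneName))
    msg <- c(msg, "'geneName' must be a single non-empty string")
  if (length(object@lengthKb) != 1L || is.na(object@lengthKb) ||
      object@lengthKb <= 0)
    msg <- c(msg, "'lengthKb' must be a single positive number")
  if (!(object@frameOffset %in% 0:2))
    msg <- c(msg, "'frameOffset' must be 0, 1 or 2")
  if (!is.null(object@sequence)) {
    seqKb <- length(object@sequence) / 1000
    if (length(object@lengthKb) == 1L && !is.na(object@lengthKb) &&
        abs(seqKb - object@lengthKb) > 0.0005)
      msg <- c(msg, sprintf(
        "sequence length (%.3f kb) disagrees with 'lengthKb' (%.3f kb)",
        seqKb, object@lengthKb))
  }
  if (!is.null(object@cdsSegments) && length(object@cdsSegments) > 0L) {
    s <- start(object@cdsSegments); e <- end(object@cdsSegments)
    if (any(s > e))
      msg <- c(msg, "CDS segments must have start <= end")
    if (is.unsorted(s, strictly = TRUE) ||
        any(s[-1] <= e[-length(e)]))
      msg <- c(msg, "CDS segments must be ascending and non-overlapping")
    if (any(s < 1L))
      msg <- c(msg, "CDS segments must start at position >= 1")
    if (!is.null(object@sequence) && any(e > length(object@sequence)))
      msg <- c(msg, "CDS segment extends beyond the amplicon sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AmpliconTarget
#'
#' @param geneName gene label.
#' @param lengthKb amplicon length in kb; may be omitted when `sequence` is
#'   given (derived as `length(sequence)/1000`).
#' @param sequence amplicon nucleotide sequence (character or
#'   [Biostrings::DNAString]), forward strand; uppercased.
#' @param cdsSegments CDS intervals as an [IRanges::IRanges], or a
#'   two-column matrix / data.frame of 1-based inclusive (start, end).
#' @param frameOffset reading-frame offset of the first CDS segment (0-2).
#' @return an [AmpliconTarget-class] object.
#' @examples
#' ampliconTarget("Exp1", lengthKb = 1.025)
#' ampliconTarget("toy", sequence = "ATGAAATGA",
#'                cdsSegments = cbind(1, 9))
#' @export
ampliconTarget <- function(geneName, lengthKb = NULL, sequence = NULL,
                           cdsSegments = NULL, frameOffset = 0L) {
  if (!is.null(sequence) && !is(sequence, "DNAString"))
    sequence <- DNAString(toupper(as.character(sequence)))
  if (is.null(lengthKb)) {
    if (is.null(sequence))
      .stopf("either 'lengthKb' or 'sequence' must be supplied")
    lengthKb <- length(sequence) / 1000
  }
  if (!is.null(cdsSegments) && !is(cdsSegments, "IRanges")) {
    cdsSegments <- as.matrix(cdsSegments)
    if (any(cdsSegments[, 1] > cdsSegments[, 2]))
      .stopf("CDS interval with start > end", class = "tillkit_bounds_error")
    cdsSegments <- IRanges(start = as.integer(cdsSegments[, 1]),
                           end = as.integer(cdsSegments[, 2]))
  }
  new("AmpliconTarget", geneName = geneName, lengthKb = as.numeric(lengthKb),
      sequence = sequence, cdsSegments = cdsSegments,
      frameOffset = as.integer(frameOffset))
}

#' CohortScreen: one EMS dose's mutation screen
#'
#' Holds, for one mutagen dose, the per-amplicon screening effort (families
#' screened) and outcome (mutations found), optionally together with the
#' individual mutation records and the amplicon annotations.
#'
#' @slot doseLabel free-text dose key, e.g. `"0.7% EMS"`. Dose labels are
#'   not parsed; the dose-to-rate mapping belongs to the simulator.
#' @slot screenTable data.frame with columns `gene`, `amplicon_kb`,
#'   `families_screened`, `mutations` (a count), one row per amplicon.
#' @slot mutationRecords data.frame of individual substitution records
#'   (columns as in [mutationRecords()]); zero rows when only counts are
#'   known. When present, per-gene record tallies must equal the
#'   `mutations` counts.
#' @slot amplicons named list of [AmpliconTarget-class] annotations
#'   (possibly empty).
#'
#' @seealso [cohortScreen()], [readScreenTable()], [populationDensity()]
#' @aliases CohortScreen
#' @exportClass CohortScreen
setClass("CohortScreen",
  representation(
    doseLabel = "character",
    screenTable = "data.frame",
    mutationRecords = "data.frame",
    amplicons = "list"
  )
)

setValidity("CohortScreen", function(object) {
  msg <- character()
  tab <- object@screenTable
  need <- c("gene", "amplicon_kb", "families_screened", "mutations")
  if (!all(need %in% names(tab)))
    return(sprintf("screenTable must have columns %s",
                   paste(sQuote(need), collapse = ", ")))
  if (!.isSingleString(object@doseLabel))
    msg <- c(msg, "'doseLabel' must be a single string")
  if (anyDuplicated(tab$gene))
    msg <- c(msg, "one row per amplicon: duplicated gene in screenTable")
  if (any(tab$amplicon_kb <= 0))
    msg <- c(msg, "'amplicon_kb' must be positive")
  if (any(tab$families_screened < 0) || any(tab$mutations < 0))
    msg <- c(msg, "family and mutation counts must be non-negative")
  if (any(tab$families_screened != floor(tab$families_screened)) ||
      any(tab$mutations != floor(tab$mutations)))
    msg <- c(msg, "family and mutation counts must be integers")
  rec <- object@mutationRecords
  if (nrow(rec) > 0L) {
    tallies <- table(factor(rec$gene, levels = tab$gene))
    if (any(as.integer(tallies) != tab$mutations))
      msg <- c(msg, "mutation record tallies disagree with 'mutations' counts")
  }
  if (length(object@amplicons) &&
      !all(vapply(object@amplicons, is, logical(1), "AmpliconTarget")))
    msg <- c(msg, "'amplicons' must be AmpliconTarget objects")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortScreen
#'
#' @param doseLabel dose key, e.g. `"1% EMS"`.
#' @param screenTable data.frame with columns `gene`, `amplicon_kb`,
#'   `families_screened`, `mutations`.
#' @param mutationRecords optional data.frame of individual records (see
#'   [mutationRecords()]); per-gene tallies must equal the counts.
#' @param amplicons optional named list of [AmpliconTarget-class].
#' @return a [CohortScreen-class] object.
#' @examples
#' cohortScreen("0.7% EMS", data.frame(
#'   gene = "Rab11a", amplicon_kb = 0.407,
#'   families_screened = 1373, mutations = 1))
#' @export
cohortScreen <- function(doseLabel, screenTable,
                         mutationRecords = emptyMutationRecords(),
                         amplicons = list()) {
  screenTable <- as.data.frame(screenTable)
  rownames(screenTable) <- NULL
  new("CohortScreen", doseLabel = doseLabel, screenTable = screenTable,
      mutationRecords = as.data.frame(mutationRecords),
      amplicons = amplicons)
}

#' SimulationParams: forward-simulation settings for a pooled screen
#'
#' Parameters of the forward EMS-screen simulator. The generative model:
#' each M3 family carries, per amplicon, a Poisson number of induced
#' variants with mean `ratePerKb * lengthKb`; a variant segregates into the
#' sampled M3 family unless its M2 parent was homozygous wild type
#' (probability `segregationProbs[1]`, 1/4 under 1:2:1 Mendelian
#' segregation), and a segregating variant is detected in the screen with
#' probability `detectionProb`.
#'
#' @slot ratePerKb true induced-mutation rate per kb per family genome
#'   (the reciprocal of the kb-per-mutation density).
#' @slot amplicons list of [AmpliconTarget-class] screened.
#' @slot families number of M3 families screened per amplicon.
#' @slot spectrumProbs named probabilities over the six substitution
#'   classes (names `substitutionClasses()`), summing to 1.
#' @slot segregationProbs probabilities of the M2 parent being (hom. wild
#'   type, heterozygous, hom. mutant); default `c(1, 2, 1)/4`.
#' @slot plantsPooled M3 plants pooled per family DNA sample (default 4).
#' @slot poolSize families per screening pool (default 8). Carried as
#'   screen metadata; detection is governed by `detectionProb` alone.
#' @slot detectionProb probability a segregating variant is detected.
#' @slot seed RNG seed.
#'
#' @seealso [simulationParams()], [simulateScreen()], [recoveryExperiment()]
#' @aliases SimulationParams
#' @exportClass SimulationParams
setClass("SimulationParams",
  representation(
    ratePerKb = "numeric",
    amplicons = "list",
    families = "integer",
    spectrumProbs = "numeric",
    segregationProbs = "numeric",
    plantsPooled = "integer",
    poolSize = "integer",
    detectionProb = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (length(object@ratePerKb) != 1L || object@ratePerKb < 0)
    msg <- c(msg, "'ratePerKb' must be a single non-negative number")
  if (!length(object@amplicons) ||
      !all(vapply(object@amplicons, is, logical(1), "AmpliconTarget")))
    msg <- c(msg, "'amplicons' must be a non-empty list of AmpliconTarget")
  if (object@families < 1L)
    msg <- c(msg, "'families' must be a positive integer")
  sp <- object@spectrumProbs
  if (length(sp) != 6L || !identical(names(sp), substitutionClasses()))
    msg <- c(msg, "'spectrumProbs' must be named by substitutionClasses()")
  else if (abs(sum(sp) - 1) > 1e-9 || any(sp < 0) || any(sp > 1))
    msg <- c(msg, "'spectrumProbs' must be probabilities summing to 1")
  sg <- object@segregationProbs
  if (length(sg) != 3L || abs(sum(sg) - 1) > 1e-9 || any(sg < 0))
    msg <- c(msg, "'segregationProbs' must be 3 probabilities summing to 1")
  if (object@plantsPooled < 1L || object@poolSize < 1L)
    msg <- c(msg, "'plantsPooled' and 'poolSize' must be positive")
  if (object@detectionProb < 0 || object@detectionProb > 1)
    msg <- c(msg, "'detectionProb' must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct SimulationParams
#'
#' @param ratePerKb true mutation rate per kb per family genome; for a
#'   density of 1 mutation / 322 kb use `1/322`.
#' @param amplicons list of [AmpliconTarget-class] (or a single one).
#' @param families M3 families screened per amplicon.
#' @param spectrumProbs named probabilities over [substitutionClasses()];
#'   the default is the empirical 0.7% EMS tomato spectrum
#'   (9, 1, 3, 2, 0, 0 of 15).
#' @param segregationProbs M2-parent genotype probabilities (hom. wild
#'   type, het, hom. mutant); 1:2:1 by default.
#' @param plantsPooled M3 plants pooled per family sample.
#' @param poolSize families per screening pool.
#' @param detectionProb detection probability for a segregating variant.
#' @param seed RNG seed.
#' @return a [SimulationParams-class] object.
#' @examples
#' p <- simulationParams(1/322, ampliconTarget("A", 1.0), families = 1000)
#' @export
simulationParams <- function(ratePerKb, amplicons, families,
                             spectrumProbs = defaultSpectrumProbs(),
                             segregationProbs = c(1, 2, 1) / 4,
                             plantsPooled = 4L, poolSize = 8L,
                             detectionProb = 1.0, seed = 1L) {
  if (is(amplicons, "AmpliconTarget")) amplicons <- list(amplicons)
  names(amplicons) <- vapply(amplicons, geneName, character(1))
  new("SimulationParams", ratePerKb = as.numeric(ratePerKb),
      amplicons = amplicons, families = as.integer(families),
      spectrumProbs = spectrumProbs,
      segregationProbs = as.numeric(segregationProbs),
      plantsPooled = as.integer(plantsPooled),
      poolSize = as.integer(poolSize),
      detectionProb = as.numeric(detectionProb), seed = as.integer(seed))
}
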