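#' Coding effect of a single-base codon change
#'
#' Compares two codons differing at exactly one position under the
#' standard nuclear genetic code: `silent` if they encode the same amino
#' acid, `nonsense` if the change creates a stop codon, `stop-loss` if it
#' destroys one, `missense` otherwise.
#'
#' @param refCodon,altCodon 3-base strings (vectorized, recycled);
#'   must differ at exactly one position.
#' @return character vector of effect labels.
#' @examples
#' codonEffect("GAA", "GAG")  # silent (both Glu)
#' codonEffect("TGG", "TGA")  # nonsense (Trp -> stop)
#' @export
codonEffect <- function(refCodon, altCodon) {
  refCodon <- toupper(as.character(refCodon))
  altCodon <- toupper(as.character(altCodon))
  n <- max(length(refCodon), length(altCodon))
  refCodon <- rep_len(refCodon, n); altCodon <- rep_len(altCodon, n)
  ok <- grepl("^[ACGT]{3}$", refCodon) & grepl("^[ACGT]{3}$", altCodon)
  if (!all(ok))
    .stopf("codons must be 3-base A/C/G/T strings",
           class = "tillkit_domain_error")
  diffs <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, refCodon, altCodon)
  if (any(diffs != 1L))
    .stopf("codons must differ at exactly one position",
           class = "tillkit_domain_error")
  refAA <- unname(GENETIC_CODE[refCodon])
  altAA <- unname(GENETIC_CODE[altCodon])
  ifelse(refAA == altAA, "silent",
         ifelse(altAA == "*", "nonsense",
                ifelse(refAA == "*", "stop-loss", "missense")))
}

## Amplicon positions of CDS bases, in translation order. frameOffset
## bases at the start complete a codon begun upstream of the amplicon.
.cdsPositions <- function(amplicon) {
  segs <- cdsSegments(amplicon)
  if (is.null(segs) || length(segs) == 0L) return(integer(0))
  unlist(mapply(seq.int, start(segs), end(segs), SIMPLIFY = FALSE),
         use.names = FALSE)
}

#' Annotate mutations with region and coding effect
#'
#' Fills the `region` and `effect` columns of mutation records from
#' CDS-annotated amplicon references. A position outside every CDS
#' segment is `noncoding` (no effect); inside, the containing codon is
#' assembled on the spliced CDS — codons may span segment junctions — and
#' classified with [codonEffect()]. Amplicons without CDS annotation give
#' `region = "unknown"`. Codons truncated by the amplicon boundary (the
#' few CDS bases whose codon is not fully contained) keep
#' `region = "coding"` with `effect = NA`.
#'
#' Annotation is idempotent and checks that the record's `ref` base equals
#' the amplicon reference at its position.
#'
#' @param records mutation-record data.frame (see [mutationRecords()]).
#' @param amplicons a single [AmpliconTarget-class] or named list of them;
#'   every amplicon referenced by `records$gene` must carry a sequence.
#' @return the records with `region` and `effect` filled.
#' @examples
#' amp <- ampliconTarget("toy", sequence = "AAATGGACGAATAA",
#'                       cdsSegments = cbind(3, 14))
#' annotateMutations(mutationRecords("toy", "F1", 9, "C", "T"), amp)
#' @export
annotateMutations <- function(records, amplicons) {
  records <- validateMutationRecords(records)
  if (is(amplicons, "AmpliconTarget"))
    amplicons <- stats::setNames(list(amplicons), geneName(amplicons))
  if (!nrow(records)) return(records)
  for (g in unique(records$gene)) {
    amp <- amplicons[[g]]
    if (is.null(amp))
      .stopf("no amplicon annotation for gene '%s'", g,
             class = "tillkit_input_error")
    if (is.null(refSequence(amp)))
      .stopf("amplicon '%s' has no reference sequence", g,
             class = "tillkit_input_error")
    seqChars <- strsplit(as.character(refSequence(amp)), "")[[1]]
    idxRows <- which(records$gene == g)
    pos <- records$position[idxRows]
    if (any(pos > length(seqChars)))
      .stopf("position beyond amplicon '%s' (%d bp)", g, length(seqChars),
             class = "tillkit_bounds_error")
    mism <- seqChars[pos] != records$ref[idxRows]
    if (any(mism)) {
      i <- idxRows[mism][1]
      .stopf("reference mismatch in '%s' at position %d: record has %s, sequence has %s",
             g, records$position[i], records$ref[i],
             seqChars[records$position[i]],
             class = "tillkit_consistency_error")
    }
    cdsPos <- .cdsPositions(amp)
    f <- frameOffset(amp)
    for (i in idxRows) {
      p <- records$position[i]
      if (length(cdsPos) == 0L) {
        records$region[i] <- "unknown"; records$effect[i] <- NA_character_
        next
      }
      k <- match(p, cdsPos)
      if (is.na(k)) {
        records$region[i] <- "noncoding"; records$effect[i] <- NA_character_
        next
      }
      records$region[i] <- "coding"
      phase <- (k - 1L - f) %% 3L
      startK <- k - phase
      if (startK < 1L || startK + 2L > length(cdsPos)) {
        records$effect[i] <- NA_character_  # codon truncated by amplicon edge
        next
      }
      codonIdx <- cdsPos[startK:(startK + 2L)]
      refCodon <- paste(seqChars[codonIdx], collapse = "")
      altChars <- seqChars
      altChars[p] <- records$alt[i]
      altCodon <- paste(altChars[codonIdx], collapse = "")
      records$effect[i] <- codonEffect(refCodon, altCodon)
    }
  }
  records
}

#' Summarize coding effects
#'
#' Counts and percentages of coding effects among annotated records. The
#' percentage base is coding records only — noncoding and unannotated
#' records are counted separately and excluded, matching how exonic
#' silent/missense splits are quoted for TILLING screens.
#'
#' @param records annotated mutation records.
#' @return list: `effects` (data.frame of count and pct per effect label),
#'   `coding_total`, `noncoding`, `unknown_region`, `unclassified_coding`
#'   (coding records whose codon was truncated). Percentages are `NA` when
#'   no coding record is classifiable.
#' @examples
#' effectSummary(mutationRecords("g", "f", 1:8, "G", "A",
#'   region = "coding",
#'   effect = rep(c("silent", "missense"), c(3, 5))))
#' @export
effectSummary <- function(records) {
  records <- validateMutationRecords(records)
  coding <- records[records$region == "coding", , drop = FALSE]
  classified <- coding[!is.na(coding$effect), , drop = FALSE]
  counts <- vapply(EFFECT_LEVELS, function(e) sum(classified$effect == e),
                   integer(1))
  total <- sum(counts)
  pct <- if (total > 0) roundHalfUp(100 * counts / total, 1L) else
    rep(NA_real_, length(counts))
  list(effects = data.frame(effect = EFFECT_LEVELS, count = unname(counts),
                            pct = unname(pct), stringsAsFactors = FALSE),
       coding_total = nrow(coding),
       noncoding = sum(records$region == "noncoding"),
       unknown_region = sum(records$region == "unknown"),
       unclassified_coding = nrow(coding) - nrow(classified))
}
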