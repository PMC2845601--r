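#' Read amplicon sequences with CDS annotations
#'
#' Loads amplicon reference sequences from a FASTA file and, optionally,
#' their CDS segments from a tab-delimited interval file with columns
#' `name`, `start`, `end` and an optional `frame` column (reading-frame
#' offset of the record's first segment). Intervals are 1-based inclusive
#' on the amplicon forward strand, as the file's header comment should
#' declare. Records without interval lines get no CDS annotation, so
#' region calls on them are `"unknown"`.
#'
#' @param seqPath FASTA file of amplicon sequences.
#' @param intervalPath optional interval TSV; `NULL` for sequences only.
#' @return named list of [AmpliconTarget-class].
#' @seealso [annotateMutations()]
#' @export
readAmpliconAnnotations <- function(seqPath, intervalPath = NULL) {
  seqs <- readDNAStringSet(seqPath)
  if (anyDuplicated(names(seqs)))
    .stopf("duplicate record name(s) in %s: %s", seqPath,
           paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "),
           class = "tillkit_duplicate_error")
  seqs <- DNAStringSet(toupper(seqs))
  ivl <- NULL
  if (!is.null(intervalPath)) {
    ivl <- utils::read.table(intervalPath, sep = "\t", header = TRUE,
                             comment.char = "#", stringsAsFactors = FALSE)
    need <- c("name", "start", "end")
    miss <- setdiff(need, names(ivl))
    if (length(miss))
      .stopf("interval file missing column(s): %s",
             paste(sQuote(miss), collapse = ", "),
             class = "tillkit_format_error")
    if (is.null(ivl$frame)) ivl$frame <- 0L
  }
  out <- lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    segs <- NULL; frame <- 0L
    if (!is.null(ivl)) {
      rows <- ivl[ivl$name == nm, , drop = FALSE]
      if (nrow(rows)) {
        if (any(rows$start > rows$end))
          .stopf("interval with start > end for record '%s'", nm,
                 class = "tillkit_bounds_error")
        if (any(rows$end > length(s)) || any(rows$start < 1))
          .stopf("interval beyond sequence end for record '%s' (%d bp)",
                 nm, length(s), class = "tillkit_bounds_error")
        rows <- rows[order(rows$start), , drop = FALSE]
        segs <- IRanges(start = as.integer(rows$start),
                        end = as.integer(rows$end))
        frame <- as.integer(rows$frame[1])
      }
    }
    ampliconTarget(nm, sequence = s, cdsSegments = segs, frameOffset = frame)
  })
  names(out) <- names(seqs)
  out
}
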