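#' The six canonical substitution classes
#'
#' Single-base substitutions are reported strand-symmetrically as base-pair
#' changes: `G>A` on either strand is the `GC/AT` change, and so on. The
#' six classes partition all 12 ordered single-base substitutions.
#'
#' `substitutionClasses()` returns the class labels in conventional
#' reporting order; `substitutionKind()` maps classes to
#' transition/transversion. Chemically, `GC/AT` and `AT/GC` are the two
#' transitions (purine-to-purine on one strand). EMS spectra are often
#' summarized counting only `GC/AT` as "the transition" because EMS
#' alkylates guanine; `definition = "gc-at-only"` reproduces that
#' convention in summaries while leaving the six-class table itself
#' unchanged.
#'
#' @param definition `"chemical"` (GC/AT and AT/GC are transitions) or
#'   `"gc-at-only"` (only GC/AT counted as a transition, the convention
#'   used when quoting EMS transition percentages).
#' @return `substitutionClasses()`: character vector of 6 labels.
#'   `substitutionKind()`: named character vector mapping each class to
#'   `"transition"` or `"transversion"`.
#' @examples
#' substitutionClasses()
#' substitutionKind()
#' substitutionKind("gc-at-only")
#' @export
substitutionClasses <- function() {
  c("GC/AT", "GC/TA", "AT/TA", "AT/GC", "AT/CG", "GC/CG")
}

#' @rdname substitutionClasses
#' @export
substitutionKind <- function(definition = c("chemical", "gc-at-only")) {
  definition <- match.arg(definition)
  transitions <- switch(definition,
    chemical = c("GC/AT", "AT/GC"),
    `gc-at-only` = "GC/AT")
  cls <- substitutionClasses()
  structure(ifelse(cls %in% transitions, "transition", "transversion"),
            names = cls)
}

#' Classify a substitution into its canonical base-pair-change class
#'
#' Maps an ordered single-base substitution to its strand-symmetric class:
#' a change and its reverse complement are the same class (`G>A` and `C>T`
#' are both `GC/AT`). Vectorized and total over the 12 valid ordered
#' pairs.
#'
#' @param ref,alt reference and alternate bases (`A`, `C`, `G`, `T`;
#'   `ref != alt`), recycled to a common length.
#' @return factor with levels [substitutionClasses()].
#' @examples
#' canonicalClass("C", "T")  # GC/AT
#' canonicalClass("A", "C")  # AT/CG
#' @export
canonicalClass <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (!all(ref %in% DNA_BASES4) || !all(alt %in% DNA_BASES4))
    .stopf("bases must be A, C, G or T", class = "tillkit_domain_error")
  if (any(ref == alt))
    .stopf("ref and alt must differ", class = "tillkit_domain_error")
  ## normalize to the strand whose ref is a purine, then name the pairs
  flip <- ref %in% c("C", "T")
  ref[flip] <- .complementBase(ref[flip])
  alt[flip] <- .complementBase(alt[flip])
  pairName <- c(A = "AT", C = "CG", G = "GC", T = "TA")
  factor(paste0(pairName[ref], "/", pairName[alt]),
         levels = substitutionClasses())
}

#' Substitution-spectrum table across cohorts
#'
#' Tabulates counts and percentages of the six substitution classes for
#' one or more cohorts of mutation records, optionally appending fixed
#' published comparison columns (percent only), in the layout of standard
#' EMS-spectrum tables.
#'
#' @param cohorts a named list of mutation-record data.frames (see
#'   [mutationRecords()]) or [CohortScreen-class] objects (their record
#'   slots are used); a single object is accepted.
#' @param referenceColumns optional named list/data.frame of fixed
#'   percentage columns in class order, e.g.
#'   `spectrumReferenceColumns()[c("barley", "rice")]`.
#' @param definition transition definition for the `kind` column, see
#'   [substitutionKind()].
#' @return data.frame with columns `class`, `kind`, then per cohort
#'   `count_<name>` and `pct_<name>` (1 decimal, `NA` for empty cohorts),
#'   then one percent column per reference. Attribute `"transition_pct"`
#'   holds the per-cohort transition percentage under `definition`.
#' @examples
#' recs <- mutationRecords("g", "f", 1:3, c("G", "C", "A"), c("A", "T", "T"))
#' spectrumTable(list(demo = recs))
#' @export
spectrumTable <- function(cohorts, referenceColumns = NULL,
                          definition = c("chemical", "gc-at-only")) {
  definition <- match.arg(definition)
  if (is(cohorts, "CohortScreen") || is.data.frame(cohorts))
    cohorts <- list(cohort = cohorts)
  recs <- lapply(cohorts, function(co) {
    if (is(co, "CohortScreen")) mutations(co) else validateMutationRecords(co)
  })
  if (is.null(names(recs)) || any(!nzchar(names(recs))))
    .stopf("cohorts must be named")
  kind <- substitutionKind(definition)
  out <- data.frame(class = substitutionClasses(),
                    kind = unname(kind), stringsAsFactors = FALSE)
  transPct <- numeric(0)
  for (nm in names(recs)) {
    r <- recs[[nm]]
    counts <- if (nrow(r))
      as.integer(table(canonicalClass(r$ref, r$alt)))
    else integer(6)
    total <- sum(counts)
    pct <- if (total > 0) roundHalfUp(100 * counts / total, 1L) else
      rep(NA_real_, 6L)
    out[[paste0("count_", nm)]] <- counts
    out[[paste0("pct_", nm)]] <- pct
    transPct[nm] <- if (total > 0)
      roundHalfUp(100 * sum(counts[kind == "transition"]) / total, 1L)
    else NA_real_
  }
  if (!is.null(referenceColumns)) {
    for (nm in names(referenceColumns)) {
      col <- referenceColumns[[nm]]
      if (length(col) != 6L)
        .stopf("reference column '%s' must have 6 values in class order", nm)
      out[[paste0("pct_", nm)]] <- as.numeric(col)
    }
  }
  attr(out, "transition_pct") <- transPct
  attr(out, "transition_definition") <- definition
  out
}

#' Published comparison spectra
#'
#' Packaged percentage columns from published reverse TILLING screens of
#' other species (barley, rice), in [substitutionClasses()] order, for use
#' as `referenceColumns` in [spectrumTable()].
#'
#' @return named list of numeric vectors of length 6.
#' @examples
#' spectrumReferenceColumns()$barley
#' @export
spectrumReferenceColumns <- function() {
  j <- jsonlite::read_json(system.file("extdata", "spectrum_references.json",
                                       package = "tillkit", mustWork = TRUE),
                           simplifyVector = TRUE)
  stopifnot(identical(j$classes, substitutionClasses()))
  as.list(as.data.frame(j$columns))
}
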