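#' Phenotype controlled vocabulary
#'
#' The controlled vocabulary used to score visual M2 phenotypes in the
#' Red Setter tomato mutant collection: 17 classes subdivided into 51
#' subclasses (including subclasses with zero recorded plants — the
#' vocabulary is fixed, the counts are data). Ships as packaged JSON and
#' loads as a data.frame of one row per subclass with the published
#' per-subclass plant counts.
#'
#' @return data.frame with columns `class`, `subclass`, `plants`.
#' @examples
#' vocab <- phenotypeVocabulary()
#' length(unique(vocab$class))  # 17
#' nrow(vocab)                  # 51
#' @export
phenotypeVocabulary <- function() {
  j <- jsonlite::read_json(system.file("extdata", "phenotype_vocabulary.json",
                                       package = "tillkit", mustWork = TRUE))
  rows <- do.call(rbind, lapply(j$classes, function(cl) {
    do.call(rbind, lapply(cl$subclasses, function(sc) {
      data.frame(class = cl$class, subclass = sc$subclass,
                 plants = as.integer(sc$plants), stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

.normTerm <- function(x) tolower(.squish(x))

.nearestTerm <- function(x, candidates) {
  d <- utils::adist(.normTerm(x), .normTerm(candidates))
  candidates[which.min(d)]
}

#' Validate phenotype observations against the vocabulary
#'
#' Checks that each observation's class and subclass are vocabulary terms
#' (matching is case-insensitive and whitespace-normalized) and returns
#' the observations with terms canonicalized to the vocabulary spelling.
#' Unknown terms raise a validation error naming the nearest valid term.
#'
#' @param observations data.frame with columns `plant_code`, `family_id`,
#'   `class`, `subclass` and optionally `stage`, `photo`.
#' @param vocab vocabulary data.frame, [phenotypeVocabulary()] by default.
#' @return the observations with canonical `class`/`subclass` spellings.
#' @examples
#' validateObservations(data.frame(
#'   plant_code = "P1", family_id = "F1",
#'   class = "fruit  COLOUR", subclass = "yellow fruit"))
#' @export
validateObservations <- function(observations, vocab = phenotypeVocabulary()) {
  need <- c("plant_code", "family_id", "class", "subclass")
  miss <- setdiff(need, names(observations))
  if (length(miss))
    .stopf("observations lack column(s): %s",
           paste(sQuote(miss), collapse = ", "),
           class = "tillkit_format_error")
  if (is.null(observations$stage)) observations$stage <- NA_character_
  if (is.null(observations$photo)) observations$photo <- NA_character_
  if (!nrow(observations)) return(observations)
  classes <- unique(vocab$class)
  clIdx <- match(.normTerm(observations$class), .normTerm(classes))
  if (anyNA(clIdx)) {
    bad <- observations$class[which(is.na(clIdx))[1]]
    .stopf("unknown phenotype class '%s'; nearest valid class: '%s'",
           bad, .nearestTerm(bad, classes), class = "tillkit_validation_error")
  }
  observations$class <- classes[clIdx]
  key <- paste(.normTerm(observations$class), .normTerm(observations$subclass),
               sep = "\r")
  vkey <- paste(.normTerm(vocab$class), .normTerm(vocab$subclass), sep = "\r")
  scIdx <- match(key, vkey)
  if (anyNA(scIdx)) {
    i <- which(is.na(scIdx))[1]
    inClass <- vocab$subclass[vocab$class == observations$class[i]]
    .stopf("unknown subclass '%s' in class '%s'; valid subclasses: %s (nearest: '%s')",
           observations$subclass[i], observations$class[i],
           paste(sQuote(inClass), collapse = ", "),
           .nearestTerm(observations$subclass[i], inClass),
           class = "tillkit_validation_error")
  }
  observations$subclass <- vocab$subclass[scIdx]
  rownames(observations) <- NULL
  observations
}

#' @rdname validateObservations
#' @param path CSV file with header
#'   `plant_code,family_id,class,subclass,stage,photo`.
#' @export
readObservations <- function(path, vocab = phenotypeVocabulary()) {
  if (!file.exists(path))
    .stopf("observations file not found: %s", path,
           class = "tillkit_input_error")
  validateObservations(utils::read.csv(path, stringsAsFactors = FALSE),
                       vocab = vocab)
}

#' Summarize a phenotype catalog
#'
#' Per-class and per-subclass distinct-plant counts, the fraction of
#' plants showing at least one scored trait, and — among those mutant
#' plants — the fraction observed in more than one major phenotype class.
#' A plant observed in several classes contributes to each class count but
#' once to the mutant-plant fraction.
#'
#' @param observations validated observations (see
#'   [validateObservations()]).
#' @param plants_total total number of scored plants (the denominator for
#'   the mutant fraction).
#' @return list: `by_subclass`, `by_class` (distinct-plant counts),
#'   `plants_with_trait`, `pct_with_trait`, `pct_multi_class` (percent of
#'   mutant plants in >1 class; `NA` when there are no mutant plants).
#' @examples
#' obs <- validateObservations(data.frame(
#'   plant_code = c("P1", "P1", "P2"), family_id = "F1",
#'   class = c("Seed", "Sterility", "Seed"),
#'   subclass = c("No germination", "Total sterility", "No germination")))
#' summarizeCatalog(obs, plants_total = 4)
#' @export
summarizeCatalog <- function(observations, plants_total) {
  if (plants_total <= 0)
    .stopf("'plants_total' must be positive", class = "tillkit_domain_error")
  vocab <- phenotypeVocabulary()
  if (nrow(observations) == 0L) {
    full <- vocab[c("class", "subclass")]
    full$plants <- 0L
    byClass <- data.frame(class = unique(vocab$class), plants = 0L,
                          stringsAsFactors = FALSE)
    return(list(by_subclass = full, by_class = byClass,
                plants_with_trait = 0L, pct_with_trait = 0,
                pct_multi_class = NA_real_))
  }
  bySub <- stats::aggregate(
    plant_code ~ class + subclass, data = observations,
    FUN = function(x) length(unique(x)), drop = FALSE)
  names(bySub)[3] <- "plants"
  full <- merge(vocab[c("class", "subclass")], bySub,
                by = c("class", "subclass"), all.x = TRUE, sort = FALSE)
  full$plants[is.na(full$plants)] <- 0L
  ## restore vocabulary order lost by merge
  full <- full[match(paste(vocab$class, vocab$subclass),
                     paste(full$class, full$subclass)), ]
  rownames(full) <- NULL
  byClass <- do.call(rbind, lapply(unique(vocab$class), function(cl) {
    sub <- observations[observations$class == cl, , drop = FALSE]
    data.frame(class = cl, plants = length(unique(sub$plant_code)),
               stringsAsFactors = FALSE)
  }))
  mutantPlants <- unique(observations$plant_code)
  nMut <- length(mutantPlants)
  multi <- if (nMut) {
    perPlant <- tapply(observations$class, observations$plant_code,
                       function(x) length(unique(x)))
    sum(perPlant > 1)
  } else 0L
  list(by_subclass = full, by_class = byClass,
       plants_with_trait = nMut,
       pct_with_trait = roundHalfUp(100 * nMut / plants_total, 1L),
       pct_multi_class = if (nMut) roundHalfUp(100 * multi / nMut, 1L)
                         else NA_real_)
}

#' Query a phenotype catalog
#'
#' Conjunctive filtering of observations by plant code, family, class
#' and/or subclass, preserving input order. Term matching is
#' case-insensitive and whitespace-normalized like validation; an empty
#' result is returned as an empty data.frame, not an error.
#'
#' @param observations validated observations.
#' @param plant,family,class,subclass filter values (`NULL` = no filter).
#' @param ... guards against misspelled filter names (any unused argument
#'   is an error).
#' @return the matching observations.
#' @examples
#' obs <- validateObservations(data.frame(
#'   plant_code = c("P1", "P2"), family_id = c("F001", "F002"),
#'   class = "Sterility",
#'   subclass = c("Partial sterility", "Total sterility")))
#' queryCatalog(obs, class = "Sterility", family = "F001")
#' @export
queryCatalog <- function(observations, plant = NULL, family = NULL,
                         class = NULL, subclass = NULL, ...) {
  extra <- list(...)
  if (length(extra))
    .stopf("unknown query field(s): %s",
           paste(sQuote(names(extra)), collapse = ", "),
           class = "tillkit_query_error")
  keep <- rep(TRUE, nrow(observations))
  if (!is.null(plant))
    keep <- keep & observations$plant_code %in% plant
  if (!is.null(family))
    keep <- keep & observations$family_id %in% family
  if (!is.null(class))
    keep <- keep & .normTerm(observations$class) %in% .normTerm(class)
  if (!is.null(subclass))
    keep <- keep & .normTerm(observations$subclass) %in% .normTerm(subclass)
  out <- observations[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
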