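#' Write mutation records as a minimal sites-only VCF
#'
#' Serializes mutation records to a minimal VCF 4.2 file with the amplicon
#' (gene) name in the CHROM column, the 1-based amplicon position in POS,
#' and the region, coding effect and source family carried as the INFO
#' tags `REGION`, `EFFECT` and `FAMILY`. Coordinates are amplicon-local:
#' no genome assembly is implied.
#'
#' @param records data.frame of mutation records (see [mutationRecords()]).
#' @param path output file path.
#' @param source value of the `##source` header line.
#' @return invisibly, `path`.
#' @seealso [readMutations()]
#' @examples
#' f <- tempfile(fileext = ".vcf")
#' writeMutations(mutationRecords("Exp1", "F012", 42, "C", "T"), f)
#' readLines(f)
#' @export
writeMutations <- function(records, path, source = "tillkit") {
  records <- validateMutationRecords(records)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=%s", source),
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Amplicon region: coding, noncoding or unknown\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Coding effect: silent, missense, nonsense or stop-loss\">",
    "##INFO=<ID=FAMILY,Number=1,Type=String,Description=\"M3 family the mutation was identified in\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(records)) {
    info <- vapply(seq_len(nrow(records)), function(i) {
      tags <- c(REGION = records$region[i],
                EFFECT = records$effect[i],
                FAMILY = records$family_id[i])
      tags <- tags[!is.na(tags) & tags != "NA"]
      if (!length(tags)) "." else
        paste(sprintf("%s=%s", names(tags), gsub("[ ;=]", "_", tags)),
              collapse = ";")
    }, character(1))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                       records$gene, records$position, records$ref,
                       records$alt, info), con)
  }
  invisible(path)
}

#' Read mutation records from a minimal sites-only VCF
#'
#' Inverse of [writeMutations()]. INFO tags other than `REGION`, `EFFECT`
#' and `FAMILY` are ignored; missing tags become `"unknown"` region /
#' `NA` effect and family.
#'
#' @param path VCF file path.
#' @return data.frame of mutation records.
#' @export
readMutations <- function(path) {
  if (!file.exists(path))
    .stopf("mutation file not found: %s", path, class = "tillkit_input_error")
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) return(emptyMutationRecords())
  fields <- strsplit(body, "\t", fixed = TRUE)
  getTag <- function(info, tag) {
    m <- regmatches(info, regexec(sprintf("(?:^|;)%s=([^;]*)", tag), info))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  info <- vapply(fields, `[`, character(1), 8L)
  region <- getTag(info, "REGION")
  region[is.na(region)] <- "unknown"
  mutationRecords(
    gene = vapply(fields, `[`, character(1), 1L),
    family_id = getTag(info, "FAMILY"),
    position = as.integer(vapply(fields, `[`, character(1), 2L)),
    ref = vapply(fields, `[`, character(1), 4L),
    alt = vapply(fields, `[`, character(1), 5L),
    region = region,
    effect = getTag(info, "EFFECT"))
}
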