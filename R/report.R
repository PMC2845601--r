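.md5Of <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(x, tmp)
  unname(tools::md5sum(tmp))
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
}

#' Run the full screen-analysis pipeline
#'
#' Single entry point tying the analysis stages together: reads a screen
#' table (and optionally a population ledger, mutation records, amplicon
#' annotations and phenotype observations), computes the density report,
#' substitution spectrum, coding-effect summary, ledger summary and — when
#' a `simulate` block is given — an estimator parameter-recovery report,
#' and writes each as a delimited table plus one machine-readable JSON
#' twin carrying metadata (tool version, config hash, seed, timestamp).
#'
#' Outputs are deterministic for a fixed config and seed; the timestamp is
#' the only field that varies between identical runs.
#'
#' @param config a named list, or path to a YAML file with the same
#'   structure. Recognized fields: `screen` (path, required), `ledger`,
#'   `mutations` (minimal VCF), `amplicons` (FASTA), `cds` (interval TSV),
#'   `observations` (CSV), `plants_total`, `correction` (default 0.75),
#'   `transition_definition` (`"chemical"` or `"gc-at-only"`), `seed`
#'   (default 1), `out_dir` (required), and `simulate`: a block with
#'   `kb_per_mutation`, `families`, `replicates` and optionally
#'   `detection_prob` (amplicon sizes are taken from the screen table's
#'   first cohort).
#' @param quiet suppress progress messages (sent to standard error).
#' @return invisibly, a named list of written artifact paths.
#' @examples
#' cfg <- list(
#'   screen = system.file("extdata", "red_setter_screen.tsv",
#'                        package = "tillkit"),
#'   ledger = system.file("extdata", "red_setter_ledger.tsv",
#'                        package = "tillkit"),
#'   out_dir = tempfile("report"))
#' paths <- runReport(cfg, quiet = TRUE)
#' @export
runReport <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      .stopf("config file not found: %s", config,
             class = "tillkit_input_error")
    config <- yaml::read_yaml(config)
  }
  say <- function(...) if (!quiet) message(...)
  if (is.null(config$screen) || is.null(config$out_dir))
    .stopf("config must name 'screen' and 'out_dir'",
           class = "tillkit_input_error")
  for (f in c("screen", "ledger", "mutations", "amplicons", "cds",
              "observations")) {
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      .stopf("input file for '%s' not found: %s", f, config[[f]],
             class = "tillkit_input_error")
  }
  correction <- if (is.null(config$correction)) 0.75 else config$correction
  transDef <- if (is.null(config$transition_definition)) "chemical" else
    config$transition_definition
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  paths <- list()
  report <- list(metadata = list(
    tool = "tillkit",
    version = as.character(utils::packageVersion("tillkit")),
    config_hash = .md5Of(jsonlite::toJSON(
      # hash the analytic settings only, not where the run writes
      config[sort(setdiff(names(config), "out_dir"))], auto_unbox = TRUE)),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))

  say("Reading screen table: ", config$screen)
  cohorts <- readScreenTable(config$screen)
  dens <- densityReport(cohorts, correction = correction)
  if (any(is.na(dens$totals$kb_per_mutation_corrected)))
    warning("population density undefined for a cohort with no mutations; ",
            "report written with '-' markers")
  utils::write.table(dens$rows, out("density.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(dens$totals, out("density_totals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths$density <- out("density.tsv")
  report$density <- list(rows = dens$rows, totals = dens$totals,
                         total_amplicon_kb = dens$total_amplicon_kb,
                         total_mutations = dens$total_mutations,
                         correction = correction,
                         ci_extension = lapply(cohorts, function(co)
                           as.list(populationDensityCI(co, correction))))

  if (!is.null(config$ledger)) {
    say("Summarizing ledger: ", config$ledger)
    led <- ledgerSummary(readLedger(config$ledger))
    utils::write.table(led, out("ledger.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$ledger <- out("ledger.tsv")
    report$ledger <- led
  }

  recs <- NULL
  if (!is.null(config$mutations)) {
    say("Reading mutation records: ", config$mutations)
    recs <- readMutations(config$mutations)
  } else if (any(vapply(cohorts, function(co) nrow(mutations(co)) > 0,
                        logical(1)))) {
    recs <- do.call(rbind, lapply(cohorts, mutations))
  }
  if (!is.null(recs) && nrow(recs)) {
    if (!is.null(config$amplicons)) {
      say("Annotating coding effects")
      amps <- readAmpliconAnnotations(config$amplicons, config$cds)
      recs <- annotateMutations(recs, amps)
      report$effects <- effectSummary(recs)
      writeMutations(recs, out("mutations_annotated.vcf"))
      paths$mutations <- out("mutations_annotated.vcf")
    }
    spec <- spectrumTable(list(all = recs),
                          referenceColumns = spectrumReferenceColumns(),
                          definition = transDef)
    utils::write.table(spec, out("spectrum.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$spectrum <- out("spectrum.tsv")
    report$spectrum <- list(table = spec,
                            transition_pct = attr(spec, "transition_pct"),
                            transition_definition = transDef)
  }

  if (!is.null(config$observations)) {
    say("Summarizing phenotype catalog")
    obs <- readObservations(config$observations)
    total <- if (is.null(config$plants_total))
      length(unique(obs$plant_code)) else config$plants_total
    report$phenotypes <- summarizeCatalog(obs, plants_total = total)
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    say("Running parameter-recovery simulation")
    tab <- screenTable(cohorts[[1]])
    amps <- lapply(seq_len(nrow(tab)), function(i)
      ampliconTarget(tab$gene[i], lengthKb = tab$amplicon_kb[i]))
    params <- simulationParams(
      ratePerKb = 1 / sim$kb_per_mutation,
      amplicons = amps,
      families = sim$families,
      detectionProb = if (is.null(sim$detection_prob)) 1.0 else
        sim$detection_prob,
      seed = seed)
    rec <- recoveryExperiment(params, replicates = sim$replicates)
    report$recovery <- list(
      replicates = rec$replicates, excluded = rec$excluded,
      true_kb_per_mutation = rec$true_kb_per_mutation,
      estimators = rec$estimators,
      detection_prob_assumed = params@detectionProb)
  }

  .writeJSON(report, out("report.json"))
  paths$report <- out("report.json")
  say("Report written to ", config$out_dir)
  invisible(paths)
}
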