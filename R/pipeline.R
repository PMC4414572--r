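#' Right-pad sequences to a common aligned length
#'
#' COI-5P barcodes are anchored at the 5' primer end, so shorter (truncated)
#' reads can be compared with full-length ones by right-padding with gap
#' characters; the padded tail is then excluded by pairwise deletion in all
#' distance calculations.
#'
#' @param seqs Named character vector.
#' @return Named character vector, all elements the same width.
#' @export
pad_sequences <- function(seqs) {
  w <- max(nchar(seqs))
  vapply(seqs, function(s)
    paste0(s, strrep("-", w - nchar(s))), "", USE.NAMES = TRUE)
}

.read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(mode = "files", specimen_table = NULL, dialect = "tsv",
                   checklist = NULL, synonyms = NULL,
                   min_length = 500L, max_ambiguity_fraction = 0.01,
                   threshold = 0.022, refine = TRUE, inflation = 2,
                   country = "", seed = 1L, outdir = NULL,
                   simulate = list())
  cfg <- utils::modifyList(defaults, config)
  if (cfg$mode == "files") {
    for (p in c("specimen_table", "checklist"))
      if (is.null(cfg[[p]]) || !file.exists(cfg[[p]]))
        stop("config error: input path '", p, "' missing or does not exist")
    if (!is.null(cfg$synonyms) && !file.exists(cfg$synonyms))
      stop("config error: synonyms path does not exist: ", cfg$synonyms)
  }
  cfg
}

.stage_log <- function(...) message("[barcodelib] ", ...)

#' Run the full library-construction pipeline
#'
#' Chains the stages: read (or simulate) a specimen table, checklist and
#' synonym table; QC every record; cluster all sequenced records into
#' BIN-style OTUs; reconcile names; assemble the library with exclusion
#' accounting; audit concordance, unnamed bins and intraspecific divergence;
#' and emit the summary tables. Per-stage record counts are logged to
#' stderr. With an `outdir`, all interchange files plus a single
#' `audit.json` aggregating every count are written.
#'
#' @param config A YAML file path or a list. Recognized keys: `mode`
#'   ("files" or "simulate"), `specimen_table`, `dialect`, `checklist`,
#'   `synonyms`, `min_length`, `max_ambiguity_fraction`, `threshold`,
#'   `refine`, `inflation`, `country`, `seed`, `outdir`, and `simulate` (a
#'   list of [simulation_config()] arguments used when mode = "simulate").
#' @return Invisibly, a list: `audit` (all counts), `build`, `partition`,
#'   `concordance`, `species_status`, `divergence`, `tables`; plus `truth`
#'   and `ledger` when simulating.
#' @export
run_pipeline <- function(config) {
  cfg <- .read_run_config(config)
  sim <- NULL
  if (cfg$mode == "simulate") {
    sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$simulate)
    sim <- do.call(simulation_config, sim_args)
    bundle <- simulate_dataset(sim)
    ds <- bundle$dataset
    checklist <- bundle$checklist
    synonyms <- bundle$synonyms
    .stage_log("simulated ", nrow(ds), " records, ",
               nrow(checklist), " checklist species")
  } else {
    ds <- read_specimen_table(cfg$specimen_table, dialect = cfg$dialect)
    checklist <- read_checklist(cfg$checklist)
    synonyms <- if (!is.null(cfg$synonyms)) read_synonyms(cfg$synonyms)
    .stage_log("read ", nrow(ds), " records, ",
               nrow(checklist), " checklist species")
  }
  qc <- qc_config(min_length = cfg$min_length,
                  max_ambiguity_fraction = cfg$max_ambiguity_fraction)
  qc_res <- compliance_check(ds, qc)
  .stage_log("QC: ", sum(qc_res$pass), " pass, ", sum(!qc_res$pass), " fail")

  seqs <- stats::setNames(ds$sequence, ds$process_id)
  seqs <- seqs[nzchar(seqs)]
  partition <- assign_bins(pad_sequences(seqs), threshold = cfg$threshold,
                           refine = isTRUE(cfg$refine),
                           inflation = cfg$inflation)
  .stage_log("clustering: ", length(seqs), " sequences -> ",
             length(unique(partition$assignment)), " bins")

  build <- build_library(ds, checklist, synonyms, qc, bins = partition)
  ann <- build$annotated
  res_counts <- annotate_dataset(ds, checklist, synonyms)$counts
  .stage_log("library: ", nrow(build$records), " records included, ",
             nrow(build$excluded), " excluded")

  conc <- bin_concordance(partition, ann)
  lib_conc <- bin_concordance(partition, build$records)
  sp_status <- species_status(lib_conc, build$records, partition)
  unnamed <- unnamed_bins(conc, ann, partition, cfg$country)

  lib_seqs <- pad_sequences(
    stats::setNames(build$records$sequence, build$records$process_id))
  by_species <- split(lib_seqs, build$records$accepted_name)
  divergence <- intraspecific_stats(by_species, metric = "k2p")
  divergent <- flag_high_divergence(divergence, 0.02)
  .stage_log("divergence: ", length(divergent),
             " species over 2% mean intraspecific divergence")

  tables <- list(
    suborder_summary = suborder_summary(build, ann, checklist,
                                        bins = partition,
                                        divergent_species = divergent),
    family_coverage = build$checklist_coverage,
    concordance_histogram = concordance_histogram(lib_conc, build$records,
                                                  bins = partition),
    primer_success = primer_success_matrix(ds)
  )
  excl_reasons <- table(unlist(build$excluded$reasons))
  audit <- list(
    n_records = nrow(ds),
    n_qc_pass = sum(qc_res$pass),
    n_library = nrow(build$records),
    n_excluded = nrow(build$excluded),
    exclusion_reasons = as.list(excl_reasons),
    name_resolution = as.list(res_counts),
    n_bins = length(unique(partition$assignment)),
    bins_by_status = as.list(table(conc$status)),
    n_library_bins = length(unique(
      partition$assignment[build$records$process_id])),
    species_by_status = as.list(table(sp_status$status)),
    n_library_species = nrow(sp_status),
    n_unnamed_bins = length(unnamed),
    n_high_divergence_species = length(divergent),
    high_divergence_species = divergent,
    threshold = cfg$threshold,
    refined = isTRUE(cfg$refine),
    country_filter = cfg$country
  )
  if (!is.null(sim)) {
    truth_cl <- bundle$truth$cluster[match(names(partition$assignment),
                                           bundle$truth$process_id)]
    audit$rand_index_vs_truth <-
      rand_index(partition$assignment, truth_cl)
    audit$realized_divergence <- bundle$realized
  }
  out <- list(audit = audit, build = build, partition = partition,
              concordance = conc, species_status = sp_status,
              divergence = divergence, tables = tables,
              dataset = ann, checklist = checklist, synonyms = synonyms)
  if (!is.null(sim)) {
    out$truth <- bundle$truth
    out$ledger <- bundle$ledger
  }
  if (!is.null(cfg$outdir)) .write_pipeline_outputs(out, cfg)
  invisible(out)
}

.write_pipeline_outputs <- function(out, cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$outdir, f)
  write_specimen_table(out$dataset, p("annotated_dataset.tsv"))
  write_specimen_table(out$build$records, p("library.tsv"))
  utils::write.table(
    data.frame(process_id = names(out$partition$assignment),
               bin_id = unname(out$partition$assignment)),
    p("bin_partition.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  excl <- out$build$excluded
  excl_flat <- data.frame(
    process_id = excl$process_id,
    reasons = vapply(excl$reasons, paste, "", collapse = ";"))
  utils::write.table(excl_flat, p("exclusions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(out$checklist, p("checklist.csv"), row.names = FALSE)
  if (!is.null(out$synonyms) && nrow(out$synonyms))
    utils::write.csv(out$synonyms, p("synonyms.csv"), row.names = FALSE)
  utils::write.csv(out$tables$suborder_summary, p("suborder_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(out$tables$family_coverage, p("family_coverage.csv"),
                   row.names = FALSE)
  utils::write.csv(out$tables$concordance_histogram$triples,
                   p("concordance_triples.csv"), row.names = FALSE)
  utils::write.csv(out$tables$primer_success, p("primer_success.csv"),
                   row.names = FALSE)
  utils::write.csv(out$divergence, p("divergence_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(out$audit, p("audit.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(out$ledger))
    jsonlite::write_json(out$ledger, p("truth_ledger.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(cfg$outdir)
}
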