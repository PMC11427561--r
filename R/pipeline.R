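#' Pipeline configuration
#'
#' Bundles the stage toggles, module configurations, input paths and
#' output directory of the full post-processing pipeline. The stage order
#' is fixed: read -> q-value/contaminant filtering -> exclusion of
#' matching-enhancer runs -> normalization -> protein summarization ->
#' metrics. Matching-enhancer exclusion always precedes normalization;
#' a configuration that enables normalization while disabling the
#' exclusion stage is rejected at validation time.
#'
#' @param report_path Path to a report table (ignored when `simulate` is
#'   given).
#' @param annotation_path Path to the sample annotation.
#' @param dialect Report dialect for [read_report()].
#' @param simulate Optional [simulation_config()]; when given, the
#'   pipeline generates its input instead of reading files.
#' @param out_dir Output directory for intermediate tables and the
#'   manifest.
#' @param filters A [filter_config()].
#' @param species A [species_map()] or `NULL` to skip species assignment.
#' @param stages Named logical vector toggling `filter_q`,
#'   `filter_contaminants`, `drop_me`, `normalize`, `summarize`,
#'   `entrapment`.
#' @param seed Seed recorded in the manifest (and used for simulation).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(report_path = NULL, annotation_path = NULL,
                            dialect = "generic", simulate = NULL,
                            out_dir = tempfile("pipeline_"),
                            filters = filter_config(),
                            species = NULL,
                            stages = c(filter_q = TRUE,
                                       filter_contaminants = TRUE,
                                       drop_me = TRUE, normalize = TRUE,
                                       summarize = TRUE,
                                       entrapment = TRUE),
                            seed = 1L) {
  defaults <- c(filter_q = TRUE, filter_contaminants = TRUE,
                drop_me = TRUE, normalize = TRUE, summarize = TRUE,
                entrapment = TRUE)
  unknown <- setdiff(names(stages), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(stages)] <- stages
  cfg <- structure(
    list(report_path = report_path, annotation_path = annotation_path,
         dialect = dialect, simulate = simulate, out_dir = out_dir,
         filters = filters, species = species, stages = defaults,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$stages[["normalize"]] && !cfg$stages[["drop_me"]]) {
    stop(paste("invalid pipeline configuration: normalization requires",
               "prior exclusion of matching-enhancer runs (enable the",
               "drop_me stage)"), call. = FALSE)
  }
  if (is.null(cfg$simulate) && is.null(cfg$report_path)) {
    stop("either a report path or a simulation config is required",
         call. = FALSE)
  }
  invisible(cfg)
}

#' Run the full post-processing pipeline
#'
#' Executes the enabled stages in their fixed order, writes every
#' intermediate table to the output directory, and returns a manifest
#' recording the package version, seed, per-stage record/run counts and
#' the MD5 checksum of every written file. The manifest is also written
#' as `manifest.json`.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("diametrics")),
    seed = cfg$seed,
    stages = list(),
    outputs = list()
  )
  note <- function(stage, table) {
    manifest$stages[[stage]] <<- list(
      records = nrow(table), runs = length(unique(table$run_id)))
  }

  if (!is.null(cfg$simulate)) {
    sim <- simulate_two_proteome(cfg$simulate)
    report <- sim$report
    ann <- sim$annotation
    write_simulation(sim, file.path(cfg$out_dir, "simulated"))
  } else {
    report <- read_report(cfg$report_path, cfg$dialect)
    ann <- read_sample_annotation(cfg$annotation_path)
  }
  note("read", report)

  if (!is.null(cfg$species)) report <- assign_species(report, cfg$species)

  if (cfg$stages[["filter_q"]]) {
    report <- apply_qvalue_filters(report, cfg$filters)
    note("filter_q", report)
  }
  if (cfg$stages[["filter_contaminants"]]) {
    report <- filter_contaminants(report, cfg$filters$contaminant_ids)
    note("filter_contaminants", report)
  }

  if (cfg$stages[["entrapment"]] &&
      all(report$species != "unknown") && nrow(report) > 0) {
    analyte_runs <- ann$run_id[ann$role == "analyte"]
    ftr <- ftr_table(report, runs = intersect(unique(report$run_id),
                                              analyte_runs))
    readr::write_tsv(ftr, file.path(cfg$out_dir, "ftr_per_replicate.tsv"),
                     progress = FALSE)
    manifest$stages[["entrapment"]] <- list(
      pooled_ftr = attr(ftr, "pooled"),
      n_undefined = attr(ftr, "n_undefined"))
  }

  if (cfg$stages[["drop_me"]]) {
    report <- drop_me_runs(report, ann)
    note("drop_me", report)
  }

  normalized <- cfg$stages[["normalize"]] && nrow(report) > 0
  if (normalized) {
    report <- normalize_traces(report)
    readr::write_tsv(attr(report, "shifts"),
                     file.path(cfg$out_dir, "normalization_shifts.tsv"),
                     progress = FALSE)
    note("normalize", report)
  }
  write_report(report, file.path(cfg$out_dir, "report_processed.tsv"))

  if (cfg$stages[["summarize"]] && nrow(report) > 0) {
    mat <- summarize_proteins(report)
    write_protein_matrix(mat, file.path(
      cfg$out_dir,
      if (normalized) "protein_matrix.tsv"
      else "protein_matrix_unnormalized.tsv"))
    manifest$stages[["summarize"]] <- list(
      proteins = nrow(mat), samples = ncol(mat),
      normalized = normalized)
  }

  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  sums <- tools::md5sum(files)
  manifest$outputs <- as.list(setNames(unname(sums),
                                       basename(names(sums))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
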