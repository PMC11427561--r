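# Shared toy-report builders for the test suite.

toy_report <- function(run_id, protein_group, precursor_id, intensity,
                       q_run = 0.001, q_global = 0.001,
                       pgq_run = 0.001, pgq_global = 0.001,
                       species = "unknown", provenance = "first_pass") {
  as_report_table(tibble::tibble(
    run_id = run_id, protein_group = protein_group,
    precursor_id = precursor_id, intensity = intensity,
    q_run = q_run, q_global = q_global,
    pgq_run = pgq_run, pgq_global = pgq_global,
    species = species, provenance = provenance
  ))
}

prefix_species_map <- function(...) {
  species_map(prefixes = c("^HUMAN" = "human", "^ECOLI" = "entrapment"),
              ...)
}

# Report with known per-run loading factors: every protein observed as one
# ion in every run, intensity = base * loading.
loading_report <- function(loadings, n_proteins = 50, base_log2 = 10,
                           seed = 1) {
  set.seed(seed)
  base <- 2^(base_log2 + rnorm(n_proteins))
  runs <- names(loadings)
  tab <- do.call(rbind, lapply(runs, function(r) {
    data.frame(run_id = r,
               protein_group = sprintf("HUMAN_P%03d", seq_len(n_proteins)),
               precursor_id = sprintf("HUMAN_P%03d_pep1/2",
                                      seq_len(n_proteins)),
               intensity = base * loadings[[r]],
               q_run = 0.001, q_global = 0.001,
               pgq_run = 0.001, pgq_global = 0.001,
               species = "human", provenance = "first_pass")
  }))
  as_report_table(tab)
}

# Counts helper for FTR examples.
counts_row <- function(h, e, mode, replicate_id = "R1") {
  tibble::tibble(replicate_id = replicate_id, ids_human = h,
                 ids_entrapment = e, ids_total = h + e, mode = mode)
}
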