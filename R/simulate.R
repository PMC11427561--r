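#' Configuration of the two-proteome spike-in simulator
#'
#' Describes a synthetic two-proteome (human background + entrapment
#' spike) experiment at the report-table level: proteome sizes, peptide
#' multiplicity, the log-normal abundance model, the analyte and
#' matching-enhancer run layout, loading jitter, the intensity-dependent
#' detection model, the matching (transfer) model and the q-value models
#' for genuine and falsely transferred identifications. The simulator
#' models the report table, not the instrument: chromatography, ion
#' mobility and spectra are out of scope.
#'
#' Intensities are built as protein abundance x peptide factor x species
#' weight ((1 - rho) for human, rho for entrapment) x input amount x
#' per-run loading factor x log-normal noise. First-pass detection is
#' Bernoulli with logistic probability in the log2 intensity, so
#' low-intensity features are preferentially missing. In co-analyses,
#' analyte features missed in the first pass but present in the internal
#' library (first-pass detections of the co-analyzed runs, in particular
#' the high-input matching-enhancer runs) are recovered with
#' `true_transfer_prob`; each matching event is independently a false
#' transfer with probability `false_transfer_prob`, in which case the
#' extracted identity is an entrapment library feature that is not
#' genuinely present in the run. `false_transfer_prob` is therefore the
#' expected fraction of matched identifications that are false.
#'
#' @param n_human_proteins,n_entrapment_proteins Proteome sizes.
#' @param peptides_per_protein_mean Mean of the (shifted geometric)
#'   peptides-per-protein distribution (default 8).
#' @param abundance_log2_mean,abundance_log2_sd Protein abundance model in
#'   log2 (defaults 14 and 2.5, arbitrary units).
#' @param peptide_factor_sd_log2 Log2 sd of the per-peptide response
#'   factor (default 1).
#' @param analyte Data frame of analyte conditions with columns
#'   `condition`, `spike_fraction`, `amount_ng`, `n_replicates`.
#' @param me Data frame of matching-enhancer conditions with columns
#'   `condition`, `spike_fraction`, `amount_ng`, `n_runs` (may have zero
#'   rows for an individual/MBR-only design).
#' @param loading_factor_sd_log2 Log2 sd of the per-run loading factor
#'   (default `log2(1.3)`, about +/-30%).
#' @param detection_midpoint,detection_slope Logistic detection model on
#'   the log2 intensity (defaults 14 and 1.5: 1-ng-scale runs identify
#'   roughly half of what 10-ng runs do).
#' @param true_transfer_prob Probability that a library feature missed in
#'   the first pass is recovered by matching (default 0.6).
#' @param false_transfer_prob Probability that a matching event extracts a
#'   false (entrapment) identity (default 0.002).
#' @param noise_sd_log2 Log2 sd of the multiplicative measurement noise
#'   (default 0.24; implies a median CV of about 0.17).
#' @param qtrue_shape2 Genuine identifications draw q-values from
#'   Beta(1, `qtrue_shape2`) (default 200, mass near 0).
#' @param qfalse_max False transfers draw q-values from
#'   Uniform(0, `qfalse_max`) (default 0.05), so a fraction of false
#'   transfers survives default filtering.
#' @param shared_peptide_fraction Fraction of human peptides flagged as
#'   also present in the entrapment proteome (default 0; the workflow
#'   excludes shared peptides anyway, the flag exists for testing species
#'   assignment).
#' @param seed Mandatory integer seed; identical seeds give identical
#'   tables.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_human_proteins = 800L,
                              n_entrapment_proteins = 300L,
                              peptides_per_protein_mean = 8,
                              abundance_log2_mean = 14,
                              abundance_log2_sd = 2.5,
                              peptide_factor_sd_log2 = 1,
                              analyte = NULL,
                              me = NULL,
                              loading_factor_sd_log2 = log2(1.3),
                              detection_midpoint = 14,
                              detection_slope = 1.5,
                              true_transfer_prob = 0.6,
                              false_transfer_prob = 0.002,
                              noise_sd_log2 = 0.24,
                              qtrue_shape2 = 200,
                              qfalse_max = 0.05,
                              shared_peptide_fraction = 0,
                              seed) {
  if (missing(seed) || is.null(seed)) {
    stop("a seed is mandatory for the simulator", call. = FALSE)
  }
  if (is.null(analyte)) {
    # default layout: seven non-spiked 1-ng analyte replicates
    analyte <- data.frame(condition = "human_1ng", spike_fraction = 0,
                          amount_ng = 1, n_replicates = 7L)
  }
  if (is.null(me)) {
    # triplicate 10x matching enhancers spiked at 10% w/w
    me <- data.frame(condition = "me_10ng_rho10", spike_fraction = 0.10,
                     amount_ng = 10, n_runs = 3L)
  }
  analyte <- tibble::as_tibble(analyte)
  me <- tibble::as_tibble(me)
  for (p in c(true_transfer_prob, false_transfer_prob,
              shared_peptide_fraction)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]",
                             call. = FALSE)
  }
  rho <- c(analyte$spike_fraction, me$spike_fraction)
  if (any(rho < 0 | rho >= 1)) {
    stop("spike fractions must lie in [0, 1)", call. = FALSE)
  }
  if (any(rho > 0) && n_entrapment_proteins == 0) {
    stop("spike fraction > 0 requires entrapment proteins", call. = FALSE)
  }
  structure(
    list(n_human_proteins = as.integer(n_human_proteins),
         n_entrapment_proteins = as.integer(n_entrapment_proteins),
         peptides_per_protein_mean = peptides_per_protein_mean,
         abundance_log2_mean = abundance_log2_mean,
         abundance_log2_sd = abundance_log2_sd,
         peptide_factor_sd_log2 = peptide_factor_sd_log2,
         analyte = analyte, me = me,
         loading_factor_sd_log2 = loading_factor_sd_log2,
         detection_midpoint = detection_midpoint,
         detection_slope = detection_slope,
         true_transfer_prob = true_transfer_prob,
         false_transfer_prob = false_transfer_prob,
         noise_sd_log2 = noise_sd_log2,
         qtrue_shape2 = qtrue_shape2,
         qfalse_max = qfalse_max,
         shared_peptide_fraction = shared_peptide_fraction,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

with_preserved_rng <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

draw_q <- function(n, genuine, cfg) {
  if (genuine) {
    qbeta(runif(n), 1, cfg$qtrue_shape2)
  } else {
    runif(n, 0, cfg$qfalse_max)
  }
}

#' Simulate a two-proteome spike-in report table with ground truth
#'
#' Generates the long-format precursor report of a synthetic entrapment
#' experiment (see [simulation_config()]), together with the sample
#' annotation and a ground-truth object recording true abundances,
#' per-run loading factors and the per-record provenance label
#' (`first_pass`, `true_transfer` or `false_transfer`).
#'
#' @param cfg A [simulation_config()].
#' @return A list with elements `report` (report table), `annotation`
#'   (sample annotation) and `truth` (class `ground_truth`).
#' @export
simulate_two_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_preserved_rng(cfg$seed, {
    features <- simulate_feature_catalog(cfg)
    runs <- simulate_run_layout(cfg)
    sim <- simulate_runs(cfg, features, runs)
    truth <- structure(
      list(features = features, runs = runs,
           record_labels = sim$labels,
           shared_peptides = attr(features, "shared_peptides"),
           injected_rates = list(
             true_transfer_prob = cfg$true_transfer_prob,
             false_transfer_prob = cfg$false_transfer_prob)),
      class = "ground_truth"
    )
    list(report = sim$report, annotation = sim$annotation, truth = truth)
  })
}

simulate_feature_catalog <- function(cfg) {
  n_prot <- cfg$n_human_proteins + cfg$n_entrapment_proteins
  protein <- c(sprintf("HUMAN_P%04d", seq_len(cfg$n_human_proteins)),
               sprintf("ECOLI_P%04d", seq_len(cfg$n_entrapment_proteins)))
  species <- rep(c("human", "entrapment"),
                 c(cfg$n_human_proteins, cfg$n_entrapment_proteins))
  abundance <- rnorm(n_prot, cfg$abundance_log2_mean, cfg$abundance_log2_sd)
  n_pep <- 1L + rgeom(n_prot, 1 / cfg$peptides_per_protein_mean)
  idx <- rep(seq_len(n_prot), n_pep)
  pep_no <- sequence(n_pep)
  feats <- tibble::tibble(
    precursor_id = paste0(protein[idx], "_pep", pep_no, "/2"),
    protein_group = protein[idx],
    species = species[idx],
    base_log2 = abundance[idx] +
      rnorm(length(idx), 0, cfg$peptide_factor_sd_log2)
  )
  shared <- character()
  if (cfg$shared_peptide_fraction > 0) {
    human_feats <- which(feats$species == "human")
    n_shared <- round(cfg$shared_peptide_fraction * length(human_feats))
    picked <- sample(human_feats, n_shared)
    shared <- split_precursor_id(feats$precursor_id[picked])$sequence
  }
  attr(feats, "shared_peptides") <- shared
  feats
}

simulate_run_layout <- function(cfg) {
  mk <- function(df, role, n_col) {
    if (nrow(df) == 0) return(NULL)
    idx <- rep(seq_len(nrow(df)), df[[n_col]])
    rep_no <- sequence(df[[n_col]])
    tibble::tibble(
      run_id = paste0(df$condition[idx],
                      if (role == "me") "_ME" else "_R", rep_no),
      role = role,
      condition = df$condition[idx],
      replicate = as.integer(rep_no),
      spike_fraction = df$spike_fraction[idx],
      amount_ng = df$amount_ng[idx]
    )
  }
  runs <- dplyr::bind_rows(mk(cfg$analyte, "analyte", "n_replicates"),
                           mk(cfg$me, "me", "n_runs"))
  runs$loading_log2 <- rnorm(nrow(runs), 0, cfg$loading_factor_sd_log2)
  runs
}

simulate_runs <- function(cfg, features, runs) {
  n_feat <- nrow(features)
  per_run <- vector("list", nrow(runs))
  detected <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    run <- runs[i, ]
    weight <- ifelse(features$species == "human",
                     1 - run$spike_fraction, run$spike_fraction)
    present <- weight > 0
    log2i <- features$base_log2 + log2(ifelse(present, weight, NA)) +
      log2(run$amount_ng) + run$loading_log2 +
      rnorm(n_feat, 0, cfg$noise_sd_log2)
    p_det <- plogis((log2i - cfg$detection_midpoint) / cfg$detection_slope)
    det <- present & runif(n_feat) < p_det
    per_run[[i]] <- list(log2i = log2i, present = present, det = det)
    detected[[i]] <- det
  }
  # internal library: union of first-pass detections across co-analyzed runs
  library_mask <- Reduce(`|`, detected)

  records <- vector("list", nrow(runs))
  labels <- vector("list", nrow(runs))
  for (i in seq_len(nrow(runs))) {
    run <- runs[i, ]
    st <- per_run[[i]]
    first_idx <- which(st$det)
    matched_idx <- integer(0)
    false_idx <- integer(0)
    if (cfg$true_transfer_prob > 0) {
      candidates <- which(st$present & !st$det & library_mask)
      attempted <- candidates[runif(length(candidates)) <
                                cfg$true_transfer_prob]
      if (length(attempted) > 0 && cfg$false_transfer_prob > 0) {
        is_false <- runif(length(attempted)) < cfg$false_transfer_prob
        n_false <- sum(is_false)
        if (n_false > 0) {
          pool <- which(library_mask & features$species == "entrapment" &
                          !st$present)
          pool <- setdiff(pool, c(first_idx, false_idx))
          # mis-assigned events do not recover their intended target; if
          # the entrapment pool is exhausted the excess events yield nothing
          n_false <- min(n_false, length(pool))
          false_idx <- if (n_false > 0) sample(pool, n_false) else integer(0)
          attempted <- attempted[!is_false]
        }
      }
      matched_idx <- attempted
    }
    n_first <- length(first_idx)
    n_true <- length(matched_idx)
    n_false <- length(false_idx)
    all_idx <- c(first_idx, matched_idx, false_idx)
    genuine <- rep(c(TRUE, TRUE, FALSE), c(n_first, n_true, n_false))
    # false transfers surface as low-intensity extractions
    false_log2 <- rnorm(n_false, cfg$detection_midpoint, 0.5)
    intensity_log2 <- c(st$log2i[first_idx], st$log2i[matched_idx],
                        false_log2)
    n_rec <- length(all_idx)
    rec <- tibble::tibble(
      run_id = rep(run$run_id, n_rec),
      protein_group = features$protein_group[all_idx],
      precursor_id = features$precursor_id[all_idx],
      intensity = 2^intensity_log2,
      q_run = ifelse(genuine, draw_q(n_rec, TRUE, cfg),
                     draw_q(n_rec, FALSE, cfg)),
      q_global = ifelse(genuine, draw_q(n_rec, TRUE, cfg),
                        draw_q(n_rec, FALSE, cfg)),
      pgq_run = ifelse(genuine, draw_q(n_rec, TRUE, cfg),
                       draw_q(n_rec, FALSE, cfg)),
      pgq_global = ifelse(genuine, draw_q(n_rec, TRUE, cfg),
                          draw_q(n_rec, FALSE, cfg)),
      species = features$species[all_idx],
      provenance = rep(c("first_pass", "matched", "matched"),
                       c(n_first, n_true, n_false))
    )
    records[[i]] <- rec
    labels[[i]] <- tibble::tibble(
      run_id = rec$run_id,
      precursor_id = rec$precursor_id,
      label = rep(c("first_pass", "true_transfer", "false_transfer"),
                  c(n_first, n_true, n_false))
    )
  }
  report <- as_report_table(dplyr::bind_rows(records))
  annotation <- as_sample_annotation(
    runs[, c("run_id", "role", "condition", "replicate")])
  list(report = report, annotation = annotation,
       labels = dplyr::bind_rows(labels))
}

#' Realized transfer counts and rates from ground truth
#'
#' Tallies the per-run record labels of a simulation: first-pass, true-
#' and false-transfer counts, the matched total, and the realized
#' false-transfer fraction among matched records (`NA` where nothing was
#' matched).
#'
#' @param truth A `ground_truth` object from [simulate_two_proteome()].
#' @return A tibble with one row per run, plus a `"pooled_false_rate"`
#'   attribute.
#' @export
truth_rates <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  lab <- truth$record_labels
  out <- dplyr::summarise(
    dplyr::group_by(lab, run_id = .data$run_id),
    n_first_pass = sum(.data$label == "first_pass"),
    n_true_transfer = sum(.data$label == "true_transfer"),
    n_false_transfer = sum(.data$label == "false_transfer"),
    .groups = "drop"
  )
  out <- out[match(unique(lab$run_id), out$run_id), ]
  out$n_matched <- out$n_true_transfer + out$n_false_transfer
  out$false_rate <- ifelse(out$n_matched > 0,
                           out$n_false_transfer / out$n_matched, NA_real_)
  attr(out, "pooled_false_rate") <-
    if (sum(out$n_matched) > 0) {
      sum(out$n_false_transfer) / sum(out$n_matched)
    } else {
      NA_real_
    }
  out
}

#' Write a simulation to tab-separated files
#'
#' Writes `report.tsv`, `annotation.tsv` and `truth_records.tsv` (one
#' provenance label per record) into a directory, in the same formats the
#' readers consume.
#'
#' @param sim A [simulate_two_proteome()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_report(sim$report, file.path(dir, "report.tsv"))
  write_sample_annotation(sim$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(sim$truth$record_labels,
                   file.path(dir, "truth_records.tsv"), progress = FALSE)
  invisible(dir)
}
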