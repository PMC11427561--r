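#' Between-sample ion-trace normalization
#'
#' Applies a single additive shift per sample in log2 space, chosen so
#' that the median log-ratio of shared ions between each sample and an
#' anchor sample (the sample with the most observed ions; ties broken by
#' run order) is zero. Within-sample ion ratios are unchanged (shift-only
#' contract), and a second application yields shifts of zero. The shifts
#' are returned in the `"shifts"` attribute as a tibble
#' (`run_id`, `shift_log2`).
#'
#' Matching-enhancer runs must be excluded ([drop_me_runs()]) before
#' normalization: a high-input run would otherwise become the anchor, and
#' its one-sidedly censored overlap with each analyte biases the
#' recovered loadings.
#'
#' Being a global median-ratio scaler, the normalization assumes that the
#' typical shared ion is unchanged between samples; systematic
#' composition differences (e.g. different spike fractions of the
#' background proteome) are absorbed into the shifts.
#'
#' @param table A report table with positive intensities.
#' @return The report table with normalized intensities (linear scale),
#'   plus a `"shifts"` attribute.
#' @export
normalize_traces <- function(table) {
  table <- as_report_table(table)
  if (nrow(table) == 0) {
    attr(table, "shifts") <- tibble::tibble(run_id = character(),
                                            shift_log2 = numeric())
    return(table)
  }
  if (any(table$intensity <= 0)) {
    stop("normalization requires strictly positive intensities",
         call. = FALSE)
  }
  runs <- unique(table$run_id)
  log2i <- log2(table$intensity)
  by_run <- split(seq_len(nrow(table)), factor(table$run_id, levels = runs))
  n_obs <- lengths(by_run)
  anchor <- runs[which.max(n_obs)]
  anchor_ions <- setNames(log2i[by_run[[anchor]]],
                          table$precursor_id[by_run[[anchor]]])
  shifts <- vapply(runs, function(r) {
    if (r == anchor) return(0)
    idx <- by_run[[r]]
    hit <- match(table$precursor_id[idx], names(anchor_ions))
    shared <- !is.na(hit)
    if (!any(shared)) {
      stop("sample '", r, "' shares no ions with the anchor sample '",
           anchor, "'", call. = FALSE)
    }
    median(anchor_ions[hit[shared]] - log2i[idx][shared])
  }, numeric(1))
  table$intensity <- table$intensity *
    2^unname(shifts[match(table$run_id, runs)])
  attr(table, "shifts") <- tibble::tibble(run_id = runs,
                                          shift_log2 = unname(shifts))
  attr(table, "anchor") <- anchor
  table
}

#' Trace-aligned protein summarization
#'
#' Summarizes the ion traces of one protein into a per-sample protein
#' trace: each ion trace is shifted by the median offset between it and
#' the protein's consensus trace (the per-sample median over ions), and
#' the protein value per sample is the median across aligned ions
#' observed in that sample.
#'
#' @param ion_matrix Numeric matrix of log2 ion intensities, ions in rows,
#'   samples in columns, `NA` for unobserved cells.
#' @return Named numeric vector of per-sample log2 protein intensities.
#' @export
summarize_protein <- function(ion_matrix) {
  if (is.null(dim(ion_matrix))) {
    ion_matrix <- matrix(ion_matrix, nrow = 1,
                         dimnames = list(NULL, names(ion_matrix)))
  }
  if (nrow(ion_matrix) == 0) {
    stop("protein summarization requires at least one ion", call. = FALSE)
  }
  if (nrow(ion_matrix) == 1) return(ion_matrix[1, ])
  consensus <- apply(ion_matrix, 2, median, na.rm = TRUE)
  offsets <- apply(ion_matrix, 1, function(trace) {
    shared <- !is.na(trace) & !is.na(consensus)
    if (!any(shared)) return(0)
    median(consensus[shared] - trace[shared])
  })
  aligned <- ion_matrix + offsets
  out <- apply(aligned, 2, median, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Summarize a report table into a protein matrix by trace alignment
#'
#' Builds the per-protein ion-trace matrices from a (normalized) report
#' table and applies [summarize_protein()] to each, returning a proteins
#' x runs log2 matrix.
#'
#' @param table A report table.
#' @return A numeric log2 matrix with proteins in rows, runs in columns.
#' @export
summarize_proteins <- function(table) {
  table <- as_report_table(table)
  if (nrow(table) == 0) stop("empty report table", call. = FALSE)
  runs <- unique(table$run_id)
  proteins <- sort(unique(table$protein_group))
  run_idx <- match(table$run_id, runs)
  log2i <- log2(table$intensity)
  out <- matrix(NA_real_, nrow = length(proteins), ncol = length(runs),
                dimnames = list(proteins, runs))
  by_protein <- split(seq_len(nrow(table)),
                      factor(table$protein_group, levels = proteins))
  for (p in seq_along(proteins)) {
    idx <- by_protein[[p]]
    ions <- unique(table$precursor_id[idx])
    ion_matrix <- matrix(NA_real_, nrow = length(ions), ncol = length(runs),
                         dimnames = list(ions, runs))
    ion_matrix[cbind(match(table$precursor_id[idx], ions), run_idx[idx])] <-
      log2i[idx]
    out[p, ] <- summarize_protein(ion_matrix)
  }
  out
}

#' Per-protein coefficient of variation
#'
#' CV on the linear scale: sample standard deviation (n - 1) divided by
#' the mean of the linear intensities across replicate columns. Proteins
#' with fewer than `min_obs` observations get `NA`.
#'
#' @param matrix A log2 protein matrix (columns are replicates of one
#'   condition).
#' @param min_obs Minimum observations per protein (default 2).
#' @return Named numeric vector of CVs.
#' @export
protein_cv <- function(matrix, min_obs = 2L) {
  linear <- 2^matrix
  vapply(seq_len(nrow(matrix)), function(i) {
    v <- linear[i, ]
    v <- v[!is.na(v)]
    if (length(v) < min_obs) return(NA_real_)
    sd(v) / mean(v)
  }, numeric(1)) |> setNames(rownames(matrix))
}

#' Spike-in design
#'
#' Describes a two-proteome spike-in design: for each condition the
#' entrapment weight fraction rho (e.g. 0.05 for 5% w/w E. coli) and the
#' total peptide input amount in ng.
#'
#' @param conditions Character vector of condition names.
#' @param spike_fraction Numeric vector of entrapment weight fractions in
#'   \[0, 1).
#' @param input_amount Positive input amounts (ng).
#' @return A tibble of class `spike_design`.
#' @export
spike_design <- function(conditions, spike_fraction, input_amount) {
  stopifnot(length(conditions) == length(spike_fraction),
            length(conditions) == length(input_amount))
  if (any(spike_fraction < 0 | spike_fraction >= 1)) {
    stop("spike fractions must lie in [0, 1)", call. = FALSE)
  }
  if (any(input_amount <= 0)) {
    stop("input amounts must be positive", call. = FALSE)
  }
  out <- tibble::tibble(condition = as.character(conditions),
                        spike_fraction = spike_fraction,
                        input_amount = input_amount)
  class(out) <- c("spike_design", class(out))
  out
}

#' Expected log2 ratio between two spike conditions
#'
#' For the entrapment species the expected log2 ratio of condition `b`
#' over condition `a` is `log2(rho_b / rho_a) + log2(amount_b /
#' amount_a)`; for the human background it is
#' `log2((1 - rho_b) / (1 - rho_a)) + log2(amount_b / amount_a)`.
#'
#' @param design A [spike_design()].
#' @param cond_a,cond_b Condition names (ratio is b over a).
#' @param species `"human"` or `"entrapment"`.
#' @return Expected log2 ratio.
#' @export
expected_log2_ratio <- function(design, cond_a, cond_b,
                                species = c("human", "entrapment")) {
  species <- match.arg(species)
  stopifnot(inherits(design, "spike_design"))
  ia <- match(cond_a, design$condition)
  ib <- match(cond_b, design$condition)
  if (is.na(ia) || is.na(ib)) {
    stop("condition(s) not in the spike design", call. = FALSE)
  }
  amount <- log2(design$input_amount[ib] / design$input_amount[ia])
  if (species == "entrapment") {
    if (design$spike_fraction[ia] == 0) {
      stop("expected entrapment ratio undefined: spike fraction 0 in '",
           cond_a, "'", call. = FALSE)
    }
    log2(design$spike_fraction[ib] / design$spike_fraction[ia]) + amount
  } else {
    log2((1 - design$spike_fraction[ib]) /
           (1 - design$spike_fraction[ia])) + amount
  }
}

#' Per-protein deviation from the expected spike ratio
#'
#' For each protein with at least one observation per condition, computes
#' the observed log2 ratio of condition summaries (median over replicate
#' columns by default) between `cond_b` and `cond_a`, and the deviation
#' from the species-specific expected ratio of the design. Proteins
#' missing a condition are excluded; their number is reported in the
#' `"n_excluded"` attribute.
#'
#' @param matrix A log2 protein matrix.
#' @param conditions Character vector assigning each column to a condition.
#' @param design A [spike_design()].
#' @param species Named character vector protein -> species, or a single
#'   species label for all proteins.
#' @param cond_a,cond_b Conditions to compare (ratio is b over a).
#' @param center `"median"` (default) or `"mean"` condition summary.
#' @return A tibble with `protein`, `species`, `observed_log2_ratio`,
#'   `expected_log2_ratio`, `deviation`.
#' @export
ratio_deviation <- function(matrix, conditions, design, species,
                            cond_a, cond_b,
                            center = c("median", "mean")) {
  center <- match.arg(center)
  stopifnot(length(conditions) == ncol(matrix))
  conditions <- as.character(conditions)
  if (length(species) == 1) {
    species <- setNames(rep(species, nrow(matrix)), rownames(matrix))
  }
  fun <- if (center == "median") {
    function(v) median(v, na.rm = TRUE)
  } else {
    function(v) mean(v, na.rm = TRUE)
  }
  summ_a <- apply(matrix[, conditions == cond_a, drop = FALSE], 1, fun)
  summ_b <- apply(matrix[, conditions == cond_b, drop = FALSE], 1, fun)
  observed <- unname(summ_b - summ_a)
  keep <- !is.na(observed)
  sp <- unname(species[rownames(matrix)])
  expected <- vapply(sp, function(s) {
    if (is.na(s) || !s %in% c("human", "entrapment")) return(NA_real_)
    expected_log2_ratio(design, cond_a, cond_b, s)
  }, numeric(1), USE.NAMES = FALSE)
  out <- tibble::tibble(
    protein = rownames(matrix)[keep],
    species = sp[keep],
    observed_log2_ratio = observed[keep],
    expected_log2_ratio = expected[keep],
    deviation = observed[keep] - expected[keep]
  )
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Data completeness in abundance bins
#'
#' Ranks proteins by their median log2 intensity (descending; ties broken
#' by protein identifier order), partitions them into `n_bins` near-equal
#' bins (any remainder going to the top bins), and reports the fraction
#' of non-missing cells per bin.
#'
#' @param matrix A log2 protein matrix.
#' @param n_bins Number of abundance bins (default 6).
#' @return A tibble with `bin`, `n_proteins`, `completeness`.
#' @export
completeness_bins <- function(matrix, n_bins = 6L) {
  n_bins <- as.integer(n_bins)
  if (nrow(matrix) < n_bins) {
    stop("fewer proteins (", nrow(matrix), ") than bins (", n_bins, ")",
         call. = FALSE)
  }
  med <- apply(matrix, 1, median, na.rm = TRUE)
  ids <- if (is.null(rownames(matrix))) seq_len(nrow(matrix))
         else rownames(matrix)
  ord <- order(-med, ids)
  sizes <- rep(nrow(matrix) %/% n_bins, n_bins)
  rem <- nrow(matrix) %% n_bins
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1
  bin <- rep(seq_len(n_bins), times = sizes)
  completeness <- vapply(seq_len(n_bins), function(b) {
    rows <- ord[bin == b]
    mean(!is.na(matrix[rows, , drop = FALSE]))
  }, numeric(1))
  tibble::tibble(bin = seq_len(n_bins), n_proteins = sizes,
                 completeness = completeness)
}

#' Pairwise sample correlation
#'
#' Pearson correlation between samples on pairwise-complete log2 values.
#' Pairs sharing fewer than `min_pairwise` proteins are `NA`; the
#' diagonal is 1.
#'
#' @param matrix A log2 protein matrix (samples in columns).
#' @param min_pairwise Minimum shared observations per pair (default 10).
#' @return A symmetric correlation matrix.
#' @export
sample_correlation <- function(matrix, min_pairwise = 10L) {
  if (ncol(matrix) < 2) stop("need at least two samples", call. = FALSE)
  r <- suppressWarnings(cor(matrix, use = "pairwise.complete.obs"))
  obs <- !is.na(matrix)
  n_pair <- crossprod(obs)
  r[n_pair < min_pairwise] <- NA_real_
  diag(r) <- 1
  r
}

#' PCA of samples on fully observed proteins
#'
#' Restricts the matrix to proteins with full data completeness,
#' mean-centers each protein row, and computes principal-component scores
#' for the samples together with explained-variance fractions.
#'
#' @param matrix A log2 protein matrix.
#' @param n_components Number of components to return (default 2).
#' @return A list with `scores` (samples x components) and
#'   `explained_variance` (fractions).
#' @export
pca_scores <- function(matrix, n_components = 2L) {
  complete <- matrix[rowSums(is.na(matrix)) == 0, , drop = FALSE]
  if (nrow(complete) < 2) {
    stop("PCA requires at least two fully observed proteins", call. = FALSE)
  }
  centered <- complete - rowMeans(complete)
  fit <- prcomp(t(centered), center = FALSE)
  k <- min(n_components, ncol(fit$x))
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       explained_variance = ev[seq_len(k)])
}

#' Dynamic range of median protein intensities
#'
#' Orders of magnitude (log10) spanned by the per-protein median linear
#' intensities.
#'
#' @param matrix A log2 protein matrix.
#' @return `log10(max median / min median)`.
#' @export
dynamic_range <- function(matrix) {
  if (nrow(matrix) < 1) stop("empty matrix", call. = FALSE)
  med <- apply(matrix, 1, median, na.rm = TRUE)
  med <- med[is.finite(med)]
  if (length(med) == 0) stop("no observed proteins", call. = FALSE)
  (max(med) - min(med)) * log10(2)
}
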