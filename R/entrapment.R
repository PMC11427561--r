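#' Per-replicate entrapment identification counts
#'
#' Counts identified units (distinct precursors or distinct protein
#' groups) per run, split by species, after excluding `"shared"` records.
#' `mode = "indiv"` counts only first-pass identifications (individual
#' analysis without matching); `mode = "mbr"` counts all identifications
#' including matched ones.
#'
#' @param table A report table with species labels assigned.
#' @param mode `"mbr"` or `"indiv"`.
#' @param level `"precursor"` (default) or `"protein"`.
#' @param runs Optional run subset (default: all runs in the table).
#' @return A tibble with columns `replicate_id`, `ids_human`,
#'   `ids_entrapment`, `ids_total`, `mode`.
#' @export
entrapment_counts <- function(table, mode = c("mbr", "indiv"),
                              level = c("precursor", "protein"),
                              runs = NULL) {
  mode <- match.arg(mode)
  level <- match.arg(level)
  table <- as_report_table(table)
  if (any(table$species == "unknown")) {
    stop("species labels must be assigned before counting (assign_species)",
         call. = FALSE)
  }
  if (is.null(runs)) runs <- unique(table$run_id)
  table <- table[table$run_id %in% runs & table$species != "shared", ]
  if (mode == "indiv") table <- table[table$provenance == "first_pass", ]
  unit <- if (level == "precursor") table$precursor_id else table$protein_group
  key <- !duplicated(data.frame(table$run_id, unit))
  table <- table[key, ]
  counts <- dplyr::summarise(
    dplyr::group_by(table, replicate_id = .data$run_id),
    ids_human = sum(.data$species == "human"),
    ids_entrapment = sum(.data$species == "entrapment"),
    .groups = "drop"
  )
  # runs with no surviving records still get a zero row
  missing_runs <- setdiff(runs, counts$replicate_id)
  if (length(missing_runs) > 0) {
    counts <- dplyr::bind_rows(counts, tibble::tibble(
      replicate_id = missing_runs, ids_human = 0L, ids_entrapment = 0L))
  }
  counts <- counts[match(runs, counts$replicate_id), ]
  counts$ids_total <- counts$ids_human + counts$ids_entrapment
  counts$mode <- mode
  counts
}

#' False-positive rate of a replicate
#'
#' The fraction of entrapment-species identifications among all
#' identifications of a non-spiked replicate:
#' `FPR = ids_entrapment / ids_total`.
#'
#' @param counts A one-row entrapment count (see [entrapment_counts()]) or
#'   a list with `ids_entrapment` and `ids_total`.
#' @return FPR in \[0, 1\].
#' @export
false_positive_rate <- function(counts) {
  if (counts$ids_total <= 0) {
    stop("FPR undefined: replicate has zero identifications", call. = FALSE)
  }
  counts$ids_entrapment / counts$ids_total
}

#' False-transfer rate of a replicate
#'
#' The fraction of entrapment identifications among the identifications
#' gained by matching, computed on count differences between the matched
#' (`mbr`) and individual (`indiv`) analysis of the same replicate:
#' `FTR = (e_mbr - e_indiv) / (t_mbr - t_indiv)`.
#'
#' Degenerate counts follow the reporting convention: when matching
#' reduced the human count while adding entrapment identifications the
#' rate is set to 100% (1.0); when no identifications were gained and that
#' convention does not apply the rate is undefined (`NA`). Ratios above 1
#' arising from mixed gains/losses are clipped to 1 with a warning.
#'
#' @param mbr,indiv One-row entrapment counts for the same replicate with
#'   modes `"mbr"` and `"indiv"` respectively.
#' @return FTR in \[0, 1\], or `NA` when undefined.
#' @export
false_transfer_rate <- function(mbr, indiv) {
  if (!is.null(mbr$replicate_id) && !is.null(indiv$replicate_id) &&
      !identical(as.character(mbr$replicate_id),
                 as.character(indiv$replicate_id))) {
    stop("FTR requires matched and individual counts of the same replicate",
         call. = FALSE)
  }
  delta_e <- mbr$ids_entrapment - indiv$ids_entrapment
  delta_t <- mbr$ids_total - indiv$ids_total
  delta_h <- mbr$ids_human - indiv$ids_human
  if (delta_h < 0 && delta_e > 0) return(1.0)
  if (delta_t > 0) {
    ftr <- delta_e / delta_t
    if (ftr > 1 || ftr < 0) {
      warning("FTR of ", signif(ftr, 4), " clipped to [0, 1]", call. = FALSE)
      ftr <- min(max(ftr, 0), 1)
    }
    return(ftr)
  }
  NA_real_
}

#' Per-replicate and pooled FTR table
#'
#' Joins matched and individual entrapment counts by replicate and
#' computes the per-replicate FTR plus a pooled estimate
#' (summed entrapment gains over summed total gains). Undefined
#' replicates are reported as `NA` and excluded from the mean; their
#' number is returned in the `n_undefined` attribute. The
#' `ftr_variant = "sets"` diagnostic computes gains as distinct precursor
#' identifiers present in the matched but not the individual analysis,
#' instead of count differences.
#'
#' @param table A species-assigned report table.
#' @param runs Runs (replicates) to evaluate, default all.
#' @param level Count level, `"precursor"` or `"protein"`.
#' @param ftr_variant `"counts"` (canonical) or `"sets"`.
#' @return A tibble with per-replicate `ftr`, plus attributes `pooled`
#'   (pooled FTR), `mean`, `sd` and `n_undefined`.
#' @export
ftr_table <- function(table, runs = NULL, level = "precursor",
                      ftr_variant = c("counts", "sets")) {
  ftr_variant <- match.arg(ftr_variant)
  table <- as_report_table(table)
  if (is.null(runs)) runs <- unique(table$run_id)
  if (ftr_variant == "counts") {
    mbr <- entrapment_counts(table, "mbr", level, runs)
    indiv <- entrapment_counts(table, "indiv", level, runs)
    ftr <- vapply(seq_along(runs), function(i) {
      suppressWarnings(false_transfer_rate(mbr[i, ], indiv[i, ]))
    }, numeric(1))
    delta_e <- mbr$ids_entrapment - indiv$ids_entrapment
    delta_t <- mbr$ids_total - indiv$ids_total
  } else {
    keep <- table$run_id %in% runs & table$species != "shared"
    tab <- table[keep, ]
    per_run <- lapply(runs, function(r) {
      rt <- tab[tab$run_id == r, ]
      gained <- setdiff(rt$precursor_id[rt$provenance != "first_pass"],
                        rt$precursor_id[rt$provenance == "first_pass"])
      g <- rt[match(gained, rt$precursor_id), ]
      c(e = sum(g$species == "entrapment"), t = length(gained))
    })
    delta_e <- vapply(per_run, `[[`, numeric(1), "e")
    delta_t <- vapply(per_run, `[[`, numeric(1), "t")
    ftr <- ifelse(delta_t > 0, delta_e / delta_t, NA_real_)
  }
  out <- tibble::tibble(replicate_id = runs, delta_entrapment = delta_e,
                        delta_total = delta_t, ftr = ftr)
  pooled <- if (sum(delta_t) > 0) sum(delta_e) / sum(delta_t) else NA_real_
  attr(out, "pooled") <- pooled
  attr(out, "mean") <- mean(ftr, na.rm = TRUE)
  attr(out, "sd") <- sd(ftr, na.rm = TRUE)
  attr(out, "n_undefined") <- sum(is.na(ftr))
  out
}

#' Protein-level false-positive rate
#'
#' The fraction of distinct entrapment protein groups among all distinct
#' protein groups identified in each replicate (shared groups excluded;
#' each group counted once regardless of its peptide count).
#'
#' @param table A species-assigned report table.
#' @param runs Optional run subset.
#' @return A tibble with columns `replicate_id` and `fpr_protein`.
#' @export
protein_level_fpr <- function(table, runs = NULL) {
  counts <- entrapment_counts(table, mode = "mbr", level = "protein",
                              runs = runs)
  if (any(counts$ids_total == 0)) {
    stop("FPR undefined: replicate with zero protein groups", call. = FALSE)
  }
  tibble::tibble(replicate_id = counts$replicate_id,
                 fpr_protein = counts$ids_entrapment / counts$ids_total)
}

#' ROC curve of a q-value column against species truth
#'
#' Sweeps every observed q-value (plus 0 and 1) as an acceptance
#' threshold (keep record if q <= t). Human records are the positive
#' class, entrapment records the negative class: `tpr` is the retained
#' human fraction and `fpr` the retained entrapment fraction at each
#' threshold. The AUROC is obtained by trapezoidal integration and is
#' invariant under strictly monotone transforms of the q-value.
#'
#' @param table A species-assigned report table (shared records are
#'   ignored).
#' @param qvalue_column One of `"q_run"`, `"q_global"`, `"pgq_run"`,
#'   `"pgq_global"`.
#' @return A list of class `roc_curve` with `thresholds`, `tpr`, `fpr`,
#'   `auroc` and `qvalue_column`.
#' @export
roc_over_qvalues <- function(table,
                             qvalue_column = c("q_run", "q_global",
                                               "pgq_run", "pgq_global")) {
  qvalue_column <- match.arg(qvalue_column)
  table <- as_report_table(table)
  table <- table[table$species %in% c("human", "entrapment"), ]
  q <- table[[qvalue_column]]
  ok <- !is.na(q)
  q <- q[ok]
  positive <- table$species[ok] == "human"
  if (!any(positive) || all(positive)) {
    stop("ROC requires both human and entrapment records", call. = FALSE)
  }
  thresholds <- sort(unique(c(0, 1, q)))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  # cumulative counts at each threshold via sorted q-values
  tpr <- vapply(thresholds, function(t) sum(positive & q <= t) / n_pos,
                numeric(1))
  fpr <- vapply(thresholds, function(t) sum(!positive & q <= t) / n_neg,
                numeric(1))
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(
    list(thresholds = thresholds, tpr = tpr, fpr = fpr,
         auroc = auroc, qvalue_column = qvalue_column),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC over", x$qvalue_column, "-", length(x$thresholds),
      "thresholds, AUROC =", format(x$auroc, digits = 4), "\n")
  invisible(x)
}

#' Szymkiewicz-Simpson overlap coefficient
#'
#' `|a intersect b| / min(|a|, |b|)` on deduplicated identifier sets.
#'
#' @param a,b Character vectors (identification sets).
#' @return Overlap coefficient in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 || length(b) == 0) {
    stop("overlap coefficient undefined for an empty set", call. = FALSE)
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Jaccard similarity coefficient
#'
#' `|a intersect b| / |a union b|` on deduplicated identifier sets.
#'
#' @param a,b Character vectors (identification sets).
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) {
    stop("Jaccard index undefined for two empty sets", call. = FALSE)
  }
  length(intersect(a, b)) / length(u)
}
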