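#' Filtering configuration
#'
#' Collects every filtering threshold applied before metric computation,
#' with the defaults of the workflow: run-wise and global precursor
#' q-values at 0.01, global protein-group q-value at 0.01, the run-wise
#' protein-group q-value filter off by default (a moderate cutoff such as
#' 0.05 can be enabled for additional stringency), at least 500 proteins
#' per cell, at least 3 replicates per group, and exclusion of proteins
#' missing in more than 70% of cells.
#'
#' @param q_run_max Run-wise precursor q-value cutoff (default 0.01).
#' @param q_global_max Global precursor q-value cutoff (default 0.01).
#' @param pgq_global_max Global protein-group q-value cutoff (default 0.01).
#' @param pgq_run_max Optional run-wise protein-group q-value cutoff
#'   (default `NULL`, i.e. not applied; 0.05 is a recommended moderate
#'   value).
#' @param min_proteins_per_cell Minimum identified proteins per cell
#'   (default 500).
#' @param min_replicates_per_group Minimum non-missing replicates per group
#'   (default 3).
#' @param max_missing_fraction Maximum tolerated fraction of cells in which
#'   a protein may be missing (default 0.70, i.e. keep proteins seen in at
#'   least 30% of cells).
#' @param contaminant_ids Character vector of contaminant protein
#'   identifiers.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(q_run_max = 0.01, q_global_max = 0.01,
                          pgq_global_max = 0.01, pgq_run_max = NULL,
                          min_proteins_per_cell = 500L,
                          min_replicates_per_group = 3L,
                          max_missing_fraction = 0.70,
                          contaminant_ids = character()) {
  for (v in c(q_run_max, q_global_max, pgq_global_max, pgq_run_max,
              max_missing_fraction)) {
    if (!is.null(v) && (v < 0 || v > 1)) {
      stop("filter thresholds must lie in [0, 1]", call. = FALSE)
    }
  }
  if (min_proteins_per_cell < 1 || min_replicates_per_group < 1) {
    stop("count thresholds must be >= 1", call. = FALSE)
  }
  structure(
    list(q_run_max = q_run_max, q_global_max = q_global_max,
         pgq_global_max = pgq_global_max, pgq_run_max = pgq_run_max,
         min_proteins_per_cell = as.integer(min_proteins_per_cell),
         min_replicates_per_group = as.integer(min_replicates_per_group),
         max_missing_fraction = max_missing_fraction,
         contaminant_ids = as.character(contaminant_ids)),
    class = "filter_config"
  )
}

#' Apply precursor- and protein-level q-value filters
#'
#' Retains records satisfying the conjunction `q_run <= q_run_max` and
#' `q_global <= q_global_max` and `pgq_global <= pgq_global_max` and, when
#' `pgq_run_max` is set, `pgq_run <= pgq_run_max`. A record with an `NA`
#' protein-group q-value passes the corresponding protein-level filter
#' (the value was not reported), but `NA` precursor q-values fail.
#'
#' @param table A report table.
#' @param cfg A [filter_config()].
#' @return The filtered report table (possibly empty).
#' @export
apply_qvalue_filters <- function(table, cfg = filter_config()) {
  table <- as_report_table(table)
  stopifnot(inherits(cfg, "filter_config"))
  keep <- !is.na(table$q_run) & table$q_run <= cfg$q_run_max &
    !is.na(table$q_global) & table$q_global <= cfg$q_global_max &
    (is.na(table$pgq_global) | table$pgq_global <= cfg$pgq_global_max)
  if (!is.null(cfg$pgq_run_max)) {
    keep <- keep & (is.na(table$pgq_run) | table$pgq_run <= cfg$pgq_run_max)
  }
  table[keep, ]
}

#' Exclude matching-enhancer (and blank) runs from a report table
#'
#' Removes all records whose run is not annotated as an analyte run. This
#' must happen before normalization, so that the high-input
#' matching-enhancer runs cannot influence the normalization anchor.
#' Run order is preserved.
#'
#' @param table A report table.
#' @param ann A sample annotation (see [read_sample_annotation()]).
#' @return The report table restricted to analyte runs.
#' @export
drop_me_runs <- function(table, ann) {
  table <- as_report_table(table)
  ann <- as_sample_annotation(ann)
  runs <- unique(table$run_id)
  unannotated <- setdiff(runs, ann$run_id)
  if (length(unannotated) > 0) {
    stop("run(s) missing from sample annotation: ",
         paste(head(unannotated, 5), collapse = ", "),
         if (length(unannotated) > 5) " ..." else "", call. = FALSE)
  }
  analyte_runs <- ann$run_id[ann$role == "analyte"]
  out <- table[table$run_id %in% analyte_runs, ]
  if (nrow(out) == 0 && nrow(table) > 0) {
    warning("no analyte runs remain after excluding matching-enhancer runs",
            call. = FALSE)
  }
  out
}

#' Remove contaminant proteins
#'
#' Removes rows (protein matrix) or records (report table) whose
#' semicolon-separated protein group contains any listed contaminant
#' identifier (exact match within the split group).
#'
#' @param x A report table or a protein matrix.
#' @param contaminant_ids Character vector of contaminant identifiers.
#' @return The same kind of object with contaminant entries removed.
#' @export
filter_contaminants <- function(x, contaminant_ids) {
  contaminant_ids <- as.character(contaminant_ids)
  if (length(contaminant_ids) == 0) return(x)
  is_contam <- function(groups) {
    vapply(strsplit(groups, ";", fixed = TRUE), function(members) {
      any(trimws(members) %in% contaminant_ids)
    }, logical(1))
  }
  if (is.matrix(x)) {
    x[!is_contam(rownames(x)), , drop = FALSE]
  } else {
    x <- as_report_table(x)
    x[!is_contam(x$protein_group), ]
  }
}

#' Keep only cells with a minimum number of identified proteins
#'
#' Drops columns (cells) of a protein matrix with fewer than `min_n`
#' non-missing protein values. "Identified" means a non-missing intensity
#' after q-value filtering.
#'
#' @param matrix A protein matrix (columns are cells).
#' @param min_n Minimum number of proteins per cell (default 500).
#' @return The matrix restricted to qualifying cells.
#' @export
filter_cells_min_proteins <- function(matrix, min_n = 500L) {
  counts <- colSums(!is.na(matrix))
  matrix[, counts >= min_n, drop = FALSE]
}

#' Keep proteins observed in enough replicates per group
#'
#' Retains proteins (rows) with at least `min_k` non-missing values in
#' every group (`mode = "all-groups"`) or in at least one group
#' (`mode = "any-group"`, the default, so that each group remains
#' testable on its own).
#'
#' @param matrix A protein matrix.
#' @param groups Character/factor vector assigning each column to a group.
#' @param min_k Minimum replicates per group (default 3).
#' @param mode `"any-group"` or `"all-groups"`.
#' @return The matrix restricted to qualifying proteins.
#' @export
filter_min_group_replicates <- function(matrix, groups, min_k = 3L,
                                        mode = c("any-group", "all-groups")) {
  mode <- match.arg(mode)
  if (length(groups) != ncol(matrix)) {
    stop("'groups' must assign every column to a group", call. = FALSE)
  }
  groups <- as.character(groups)
  sizes <- table(groups)
  if (any(sizes < min_k)) {
    stop("group(s) with fewer than min_k columns: ",
         paste(names(sizes)[sizes < min_k], collapse = ", "), call. = FALSE)
  }
  counts <- vapply(unique(groups), function(g) {
    rowSums(!is.na(matrix[, groups == g, drop = FALSE]))
  }, numeric(nrow(matrix)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(matrix))
  keep <- if (mode == "all-groups") {
    rowSums(counts >= min_k) == ncol(counts)
  } else {
    rowSums(counts >= min_k) >= 1
  }
  matrix[keep, , drop = FALSE]
}

#' Drop proteins missing in too many cells
#'
#' Removes proteins observed in fewer than `1 - max_missing_fraction` of
#' cells (default: proteins present in under 30% of cells are excluded),
#' the pre-filter used before PCA and hierarchical clustering of
#' single-cell matrices.
#'
#' @param matrix A protein matrix (columns are cells).
#' @param max_missing_fraction Maximum tolerated missing fraction per
#'   protein (default 0.70).
#' @return The matrix restricted to qualifying proteins.
#' @export
filter_max_missing <- function(matrix, max_missing_fraction = 0.70) {
  frac_missing <- rowMeans(is.na(matrix))
  matrix[frac_missing <= max_missing_fraction, , drop = FALSE]
}
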