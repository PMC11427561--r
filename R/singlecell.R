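#' Two-group differential expression on a protein matrix
#'
#' Per-protein two-sided Student's t-test (pooled variance by default,
#' Welch via `welch = TRUE`) of log2 values between two groups, with the
#' log2 fold change computed as the treated-minus-control difference of
#' group means. Proteins with fewer than two observations in either group
#' are skipped; their number is returned in the `"n_skipped"` attribute.
#' Records are flagged significant at the configurable thresholds
#' (defaults p < 0.05 and |log2 FC| > 0.95). An optional
#' Benjamini-Hochberg adjusted p-value column is provided (flags use raw
#' p-values unless `use_adjusted = TRUE`).
#'
#' @param matrix A log2 protein matrix.
#' @param groups Character/factor vector assigning each column to one of
#'   two groups.
#' @param control Name of the control group (default: first level).
#' @param welch Use Welch's unequal-variance t-test instead of the pooled
#'   test (default `FALSE`).
#' @param p_max Significance threshold on the p-value (default 0.05).
#' @param fc_min Significance threshold on |log2 fold change|
#'   (default 0.95).
#' @param adjust Add a BH-adjusted p-value column (default `TRUE`).
#' @param use_adjusted Flag significance on the adjusted p-value
#'   (default `FALSE`).
#' @return A tibble with `protein`, `log2_fc`, `p_value`, `p_adjusted`,
#'   `n_treated`, `n_control`, `significant`.
#' @export
differential_expression <- function(matrix, groups, control = NULL,
                                    welch = FALSE, p_max = 0.05,
                                    fc_min = 0.95, adjust = TRUE,
                                    use_adjusted = FALSE) {
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(matrix))
  lev <- unique(groups)
  if (length(lev) != 2) {
    stop("differential expression requires exactly two groups", call. = FALSE)
  }
  if (is.null(control)) control <- lev[1]
  if (!control %in% lev) stop("unknown control group", call. = FALSE)
  treated <- setdiff(lev, control)
  idx_t <- which(groups == treated)
  idx_c <- which(groups == control)
  res <- lapply(seq_len(nrow(matrix)), function(i) {
    xt <- matrix[i, idx_t]; xt <- xt[!is.na(xt)]
    xc <- matrix[i, idx_c]; xc <- xc[!is.na(xc)]
    if (length(xt) < 2 || length(xc) < 2) {
      return(c(fc = NA_real_, p = NA_real_,
               nt = length(xt), nc = length(xc)))
    }
    p <- if (sd(c(xt, xc)) == 0) {
      1.0  # identical values in both groups: no evidence of difference
    } else {
      t.test(xt, xc, var.equal = !welch)$p.value
    }
    c(fc = mean(xt) - mean(xc), p = p, nt = length(xt), nc = length(xc))
  })
  res <- do.call(rbind, res)
  out <- tibble::tibble(
    protein = rownames(matrix),
    log2_fc = res[, "fc"],
    p_value = res[, "p"],
    n_treated = as.integer(res[, "nt"]),
    n_control = as.integer(res[, "nc"])
  )
  skipped <- is.na(out$p_value)
  out$p_adjusted <- if (adjust) p.adjust(out$p_value, "BH") else NA_real_
  p_for_flag <- if (use_adjusted) out$p_adjusted else out$p_value
  out$significant <- !is.na(p_for_flag) & p_for_flag < p_max &
    abs(out$log2_fc) > fc_min
  attr(out, "n_skipped") <- sum(skipped)
  attr(out, "treated") <- treated
  attr(out, "control") <- control
  out[!skipped | TRUE, ]
}

#' k-nearest-neighbor imputation of missing protein values
#'
#' Replaces each missing cell by the mean value, at that sample, of the
#' `k` nearest proteins (Euclidean distance over shared observed samples,
#' scaled to the number of shared samples) that are observed at that
#' sample. Observed cells are never altered. Rows with no overlap with
#' any other row are left missing with a warning.
#'
#' @param matrix A log2 protein matrix.
#' @param k Number of neighbors (default 5).
#' @return The imputed matrix.
#' @export
impute_knn <- function(matrix, k = 5L) {
  out <- matrix
  missing_idx <- which(is.na(matrix), arr.ind = TRUE)
  if (nrow(missing_idx) == 0) return(out)
  obs <- !is.na(matrix)
  orphan <- FALSE
  for (row in unique(missing_idx[, 1])) {
    shared <- obs & rep(obs[row, ], each = nrow(matrix))
    n_shared <- rowSums(shared)
    n_shared[row] <- 0L
    d <- vapply(seq_len(nrow(matrix)), function(j) {
      if (n_shared[j] == 0) return(Inf)
      cols <- shared[j, ]
      sqrt(mean((matrix[row, cols] - matrix[j, cols])^2))
    }, numeric(1))
    cols_missing <- missing_idx[missing_idx[, 1] == row, 2]
    for (col in cols_missing) {
      candidates <- which(is.finite(d) & obs[, col])
      if (length(candidates) == 0) { orphan <- TRUE; next }
      nearest <- candidates[order(d[candidates])][seq_len(min(k,
                                                  length(candidates)))]
      out[row, col] <- mean(matrix[nearest, col])
    }
  }
  if (orphan) {
    warning("some missing cells had no imputable neighbor and were left NA",
            call. = FALSE)
  }
  out
}

#' Minimum-value imputation
#'
#' Replaces every missing cell by the lowest intensity value observed
#' anywhere in the matrix.
#'
#' @param matrix A log2 protein matrix.
#' @return The imputed matrix.
#' @export
impute_min <- function(matrix) {
  observed <- matrix[!is.na(matrix)]
  if (length(observed) == 0) {
    stop("cannot impute an all-missing matrix", call. = FALSE)
  }
  matrix[is.na(matrix)] <- min(observed)
  matrix
}

#' Median-centered Z-score per protein row
#'
#' Per row: `(x - row median) / row sd`, where the standard deviation is
#' the usual n - 1 deviation about the mean. Rows with zero variance (or
#' fewer than two observations) become all-`NA` with a warning.
#'
#' @param matrix A log2 protein matrix.
#' @return The row-wise Z-scored matrix.
#' @export
zscore_rows <- function(matrix) {
  out <- matrix
  degenerate <- FALSE
  for (i in seq_len(nrow(matrix))) {
    v <- matrix[i, ]
    n <- sum(!is.na(v))
    s <- if (n >= 2) sd(v, na.rm = TRUE) else NA_real_
    if (is.na(s) || s == 0) {
      out[i, ] <- NA_real_
      degenerate <- TRUE
    } else {
      out[i, ] <- (v - median(v, na.rm = TRUE)) / s
    }
  }
  if (degenerate) {
    warning("zero-variance or under-observed row(s) set to NA",
            call. = FALSE)
  }
  out
}

#' Protein co-variation matrix across single cells
#'
#' Restricts the matrix to proteins observed in at least `min_cells`
#' cells, computes the pairwise Pearson correlation over the cells shared
#' by each protein pair (observed values only; imputation must not be
#' applied beforehand), and masks pairs sharing fewer than `min_pairwise`
#' cells as `NA`.
#'
#' @param matrix A log2 protein matrix with cells in columns.
#' @param min_cells Minimum cells a protein must be observed in
#'   (default 20).
#' @param min_pairwise Minimum shared cells per protein pair (default 20).
#' @return A list of class `covariation_result` with `correlation`,
#'   `pairwise_n` and `proteins`.
#' @export
covariation_matrix <- function(matrix, min_cells = 20L, min_pairwise = 20L) {
  n_obs <- rowSums(!is.na(matrix))
  keep <- n_obs >= min_cells
  if (sum(keep) < 2) {
    stop("fewer than two proteins observed in >= ", min_cells, " cells",
         call. = FALSE)
  }
  sub <- matrix[keep, , drop = FALSE]
  r <- suppressWarnings(cor(t(sub), use = "pairwise.complete.obs"))
  obs <- !is.na(sub)
  n_pair <- tcrossprod(obs)
  r[n_pair < min_pairwise] <- NA_real_
  diag(r) <- 1
  structure(
    list(correlation = r, pairwise_n = n_pair, proteins = rownames(sub)),
    class = "covariation_result"
  )
}

#' @export
print.covariation_result <- function(x, ...) {
  cat("Co-variation over", length(x$proteins), "proteins;",
      sum(is.na(x$correlation[upper.tri(x$correlation)])),
      "pairs below the pairwise-n threshold\n")
  invisible(x)
}

#' Cluster proteins by their correlation profiles
#'
#' Hierarchical agglomerative clustering of proteins using the Euclidean
#' distance between rows of the co-variation matrix, cut at `n_clusters`.
#' Undefined correlation cells are replaced by 0 (the neutral
#' correlation) for the distance computation only; the stored matrix is
#' untouched. Returns the cluster membership and the dendrogram leaf
#' ordering for heatmap display.
#'
#' @param result A [covariation_matrix()] result.
#' @param n_clusters Number of clusters to cut (default 2).
#' @param linkage Linkage method: `"average"` (default), `"single"`,
#'   `"complete"` or `"ward"` (Ward.D2).
#' @return A list with `clusters` (named integer vector), `order` (leaf
#'   order) and `tree` (the hclust object).
#' @export
cluster_correlation <- function(result, n_clusters = 2L,
                                linkage = c("average", "single",
                                            "complete", "ward")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(result, "covariation_result"))
  r <- result$correlation
  if (n_clusters > nrow(r)) {
    stop("more clusters requested than proteins", call. = FALSE)
  }
  r[is.na(r)] <- 0
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- hclust(dist(r, method = "euclidean"), method = method)
  clusters <- cutree(tree, k = n_clusters)
  list(clusters = clusters, order = tree$order, tree = tree)
}
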