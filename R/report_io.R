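#' Canonical precursor report columns
#'
#' A report table is a tibble in long format with one row per identified
#' precursor per run. Intensities are stored on the linear scale; q-values
#' are probabilities in \[0, 1\]. `species` is one of `"human"`,
#' `"entrapment"`, `"shared"`, `"unknown"`; `provenance` is one of
#' `"first_pass"`, `"matched"`, `"unknown"`.
#'
#' @name report_table
#' @keywords internal
NULL

REPORT_COLUMNS <- c(
  "run_id", "protein_group", "precursor_id", "intensity",
  "q_run", "q_global", "pgq_run", "pgq_global",
  "species", "provenance"
)

SPECIES_LEVELS <- c("human", "entrapment", "shared", "unknown")
PROVENANCE_LEVELS <- c("first_pass", "matched", "unknown")

# DIA-NN report spellings for the canonical columns (spec'd dialect).
DIANN_COLUMNS <- c(
  run_id = "Run",
  protein_group = "Protein.Group",
  modified_sequence = "Modified.Sequence",
  precursor_charge = "Precursor.Charge",
  intensity = "Precursor.Quantity",
  q_run = "Q.Value",
  q_global = "Lib.Q.Value",
  pgq_run = "PG.Q.Value",
  pgq_global = "Lib.PG.Q.Value"
)

#' Construct / validate a precursor report table
#'
#' Coerces a data frame with the canonical columns (see [report_table])
#' into a validated report table. Missing optional columns (`species`,
#' `provenance`, the protein-group q-values) are filled with
#' `"unknown"` / `NA`.
#'
#' @param x A data frame with at least `run_id`, `protein_group`,
#'   `precursor_id`, `intensity`, `q_run`, `q_global`.
#' @return A tibble of class `report_table`.
#' @export
as_report_table <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("run_id", "protein_group", "precursor_id", "intensity",
                "q_run", "q_global")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("report table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"pgq_run" %in% names(x)) x$pgq_run <- NA_real_
  if (!"pgq_global" %in% names(x)) x$pgq_global <- NA_real_
  if (!"species" %in% names(x)) x$species <- "unknown"
  if (!"provenance" %in% names(x)) x$provenance <- "unknown"
  x <- x[REPORT_COLUMNS]
  x$run_id <- as.character(x$run_id)
  x$protein_group <- as.character(x$protein_group)
  x$precursor_id <- as.character(x$precursor_id)
  for (col in c("intensity", "q_run", "q_global", "pgq_run", "pgq_global")) {
    if (!is.numeric(x[[col]])) {
      stop("report column '", col, "' must be numeric", call. = FALSE)
    }
  }
  validate_report_values(x)
  dup <- duplicated(x[c("run_id", "precursor_id")])
  if (any(dup)) {
    keys <- unique(paste0(x$run_id[dup], " / ", x$precursor_id[dup]))
    stop("duplicate (run, precursor) pairs in report: ",
         paste(head(keys, 5), collapse = "; "),
         if (length(keys) > 5) " ..." else "", call. = FALSE)
  }
  class(x) <- c("report_table", class(x))
  x
}

validate_report_values <- function(x) {
  if (any(x$intensity < 0, na.rm = TRUE)) {
    stop("negative intensities in report table", call. = FALSE)
  }
  for (col in c("q_run", "q_global", "pgq_run", "pgq_global")) {
    v <- x[[col]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("q-values in column '", col, "' outside [0, 1]", call. = FALSE)
    }
  }
  bad_sp <- setdiff(unique(x$species), SPECIES_LEVELS)
  if (length(bad_sp) > 0) {
    stop("unknown species label(s): ", paste(bad_sp, collapse = ", "),
         call. = FALSE)
  }
  bad_pv <- setdiff(unique(x$provenance), PROVENANCE_LEVELS)
  if (length(bad_pv) > 0) {
    stop("unknown provenance label(s): ", paste(bad_pv, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Read a long-format precursor report table
#'
#' Reads a tab-separated precursor report. The `"diann"` dialect expects
#' DIA-NN column names (`Run`, `Protein.Group`, `Modified.Sequence`,
#' `Precursor.Charge`, `Precursor.Quantity`, `Q.Value`, `Lib.Q.Value`,
#' `PG.Q.Value`, `Lib.PG.Q.Value`); the precursor identifier is formed as
#' `Modified.Sequence/Precursor.Charge`. The `"generic"` dialect expects the
#' canonical column names directly (see [report_table]). Other spellings can
#' be mapped with `column_map`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect `"diann"` or `"generic"`.
#' @param column_map Optional named character vector mapping canonical names
#'   to the file's header spellings, overriding the dialect defaults.
#' @return A validated report table; duplicated (run, precursor) rows are an
#'   error.
#' @export
read_report <- function(path, dialect = c("generic", "diann"),
                        column_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such report file: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = c("", "NA"))
  if (dialect == "diann") {
    map <- DIANN_COLUMNS
    if (!is.null(column_map)) map[names(column_map)] <- column_map
    required <- map[c("run_id", "protein_group", "modified_sequence",
                      "precursor_charge", "intensity", "q_run", "q_global")]
    missing_cols <- setdiff(unname(required), names(raw))
    if (length(missing_cols) > 0) {
      stop("report file lacks required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    out <- tibble::tibble(
      run_id = raw[[map[["run_id"]]]],
      protein_group = raw[[map[["protein_group"]]]],
      precursor_id = paste0(raw[[map[["modified_sequence"]]]], "/",
                            raw[[map[["precursor_charge"]]]]),
      intensity = parse_report_numeric(raw[[map[["intensity"]]]],
                                       map[["intensity"]]),
      q_run = parse_report_numeric(raw[[map[["q_run"]]]], map[["q_run"]]),
      q_global = parse_report_numeric(raw[[map[["q_global"]]]],
                                      map[["q_global"]])
    )
    if (nrow(raw) == 0) out <- out[0, ]
    out$pgq_run <- optional_numeric(raw, map[["pgq_run"]])
    out$pgq_global <- optional_numeric(raw, map[["pgq_global"]])
    out$species <- optional_character(raw, "Species", "unknown")
    out$provenance <- optional_character(raw, "Provenance", "unknown")
  } else {
    missing_cols <- setdiff(c("run_id", "protein_group", "precursor_id",
                              "intensity", "q_run", "q_global"), names(raw))
    if (length(missing_cols) > 0) {
      stop("report file lacks required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    out <- tibble::tibble(
      run_id = raw$run_id,
      protein_group = raw$protein_group,
      precursor_id = raw$precursor_id,
      intensity = parse_report_numeric(raw$intensity, "intensity"),
      q_run = parse_report_numeric(raw$q_run, "q_run"),
      q_global = parse_report_numeric(raw$q_global, "q_global"),
      pgq_run = optional_numeric(raw, "pgq_run"),
      pgq_global = optional_numeric(raw, "pgq_global"),
      species = optional_character(raw, "species", "unknown"),
      provenance = optional_character(raw, "provenance", "unknown")
    )
  }
  as_report_table(out)
}

parse_report_numeric <- function(x, column) {
  if (length(x) == 0) return(numeric(0))
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop("unparsable numeric in column '", column, "' at data line(s) ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "", call. = FALSE)
  }
  out
}

optional_numeric <- function(raw, column) {
  if (!is.null(column) && !is.na(column) && column %in% names(raw)) {
    parse_report_numeric(raw[[column]], column)
  } else {
    rep(NA_real_, nrow(raw))
  }
}

optional_character <- function(raw, column, default) {
  if (column %in% names(raw)) {
    out <- raw[[column]]
    out[is.na(out)] <- default
    out
  } else {
    rep(default, nrow(raw))
  }
}

#' Write a precursor report table
#'
#' Writes tab-separated text; missing values are serialized as empty
#' fields. `read_report(write_report(x), dialect = "generic")` round-trips
#' field-for-field.
#'
#' @param table A report table.
#' @param path Output path.
#' @param dialect Output column spelling, as in [read_report()].
#' @return `path`, invisibly.
#' @export
write_report <- function(table, path, dialect = c("generic", "diann")) {
  dialect <- match.arg(dialect)
  table <- as_report_table(table)
  if (dialect == "diann") {
    seq_charge <- split_precursor_id(table$precursor_id)
    out <- tibble::tibble(
      Run = table$run_id,
      Protein.Group = table$protein_group,
      Modified.Sequence = seq_charge$sequence,
      Precursor.Charge = seq_charge$charge,
      Precursor.Quantity = table$intensity,
      Q.Value = table$q_run,
      Lib.Q.Value = table$q_global,
      PG.Q.Value = table$pgq_run,
      Lib.PG.Q.Value = table$pgq_global,
      Species = table$species,
      Provenance = table$provenance
    )
  } else {
    out <- table
    class(out) <- class(tibble::tibble())
  }
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(path)
}

split_precursor_id <- function(ids) {
  pos <- regexpr("/[0-9]+$", ids)
  sequence <- ifelse(pos > 0, substr(ids, 1, pos - 1), ids)
  charge <- ifelse(pos > 0, substring(ids, pos + 1), NA_character_)
  list(sequence = sequence, charge = charge)
}

#' Read / write sample annotations
#'
#' Sample annotations assign each run a role (`"analyte"`, `"me"` for
#' matching-enhancer runs, or `"blank"`), a condition label and a replicate
#' number. Stored as tab-separated text with columns `run_id`, `role`,
#' `condition`, `replicate`.
#'
#' @param path File path.
#' @return A tibble with one row per run.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("no such annotation file: ", path,
                               call. = FALSE)
  ann <- readr::read_tsv(path, col_types = "cccd", progress = FALSE)
  as_sample_annotation(ann)
}

#' @rdname read_sample_annotation
#' @param ann An annotation data frame.
#' @export
write_sample_annotation <- function(ann, path) {
  ann <- as_sample_annotation(ann)
  readr::write_tsv(ann, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname read_sample_annotation
#' @export
as_sample_annotation <- function(ann) {
  ann <- tibble::as_tibble(ann)
  missing_cols <- setdiff(c("run_id", "role", "condition", "replicate"),
                          names(ann))
  if (length(missing_cols) > 0) {
    stop("sample annotation lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ann$run_id <- as.character(ann$run_id)
  ann$role <- as.character(ann$role)
  bad <- setdiff(unique(ann$role), c("analyte", "me", "blank"))
  if (length(bad) > 0) {
    stop("unknown role(s) in sample annotation: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(ann$run_id)) {
    stop("duplicate run_id in sample annotation", call. = FALSE)
  }
  ann$replicate <- as.integer(ann$replicate)
  if (any(!is.na(ann$replicate) & ann$replicate < 1)) {
    stop("replicate numbers must be >= 1", call. = FALSE)
  }
  ann
}

#' Pivot a report table to a protein-by-run log2 matrix
#'
#' Aggregates precursor intensities per (protein group, run) and returns a
#' log2-scale matrix with proteins in rows and runs in columns. Absent
#' (protein, run) combinations are `NA`. With `aggregation = "median"` the
#' median of the log2 ion intensities is taken; with `"sum"` linear
#' intensities are summed before the log2 transform. For trace-aligned
#' protein summarization use [summarize_proteins()] instead.
#'
#' @param table A report table (already filtered/normalized upstream).
#' @param aggregation `"median"` or `"sum"`.
#' @return A numeric matrix (log2) with `dimnames` (protein group, run).
#' @export
pivot_protein_matrix <- function(table, aggregation = c("median", "sum")) {
  aggregation <- match.arg(aggregation)
  table <- as_report_table(table)
  if (nrow(table) == 0 || length(unique(table$run_id)) == 0) {
    stop("cannot pivot a report with zero runs", call. = FALSE)
  }
  runs <- unique(table$run_id)
  proteins <- sort(unique(table$protein_group))
  agg <- dplyr::group_by(table, .data$protein_group, .data$run_id)
  agg <- dplyr::summarise(
    agg,
    value = if (aggregation == "median") {
      median(log2(.data$intensity))
    } else {
      log2(sum(.data$intensity))
    },
    .groups = "drop"
  )
  mat <- matrix(NA_real_, nrow = length(proteins), ncol = length(runs),
                dimnames = list(proteins, runs))
  mat[cbind(match(agg$protein_group, proteins),
            match(agg$run_id, runs))] <- agg$value
  mat
}

#' Read / write a protein matrix
#'
#' Tab-separated protein matrices have the protein group in the first
#' column (`protein_group`) and one column per run; values are log2
#' intensities, missing values are empty fields.
#'
#' @param path File path.
#' @return A numeric matrix with proteins in rows.
#' @export
read_protein_matrix <- function(path) {
  if (!file.exists(path)) stop("no such matrix file: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(
    protein_group = "c", .default = "d"), progress = FALSE, na = c("", "NA"))
  mat <- as.matrix(df[-1])
  rownames(mat) <- df$protein_group
  mat
}

#' @rdname read_protein_matrix
#' @param matrix A numeric matrix with protein rownames.
#' @export
write_protein_matrix <- function(matrix, path) {
  df <- tibble::as_tibble(matrix, rownames = "protein_group")
  readr::write_tsv(df, path, na = "", progress = FALSE)
  invisible(path)
}
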