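#' Species maps
#'
#' A species map assigns each protein identifier to a species label
#' (`"human"` for the background proteome, `"entrapment"` for the spiked
#' foreign proteome). It can be given explicitly (`mapping`), by identifier
#' prefix patterns (`prefixes`, regular expressions matched against each
#' member of a protein group), or derived from FASTA headers with
#' [species_map_from_fasta_headers()]. Peptides listed in `shared_peptides`
#' occur in both proteomes and force the `"shared"` label, which excludes
#' the record from all species-specific metrics downstream.
#'
#' @param mapping Named character vector: protein identifier -> species.
#' @param prefixes Named character vector: regex pattern -> species label,
#'   e.g. `c("^HUMAN" = "human", "^ECOLI" = "entrapment")`.
#' @param shared_peptides Character vector of peptide sequences present in
#'   both proteomes.
#' @param default Optional species label for unmapped identifiers; if
#'   `NULL` (default) unmapped identifiers are an error in
#'   [assign_species()].
#' @return An object of class `species_map`.
#' @export
species_map <- function(mapping = character(), prefixes = character(),
                        shared_peptides = character(), default = NULL) {
  if (!is.null(default) && !default %in% SPECIES_LEVELS) {
    stop("default species must be one of: ",
         paste(SPECIES_LEVELS, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(c(unname(mapping), unname(prefixes))),
                 SPECIES_LEVELS)
  if (length(bad) > 0) {
    stop("unknown species label(s) in map: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(mapping = mapping, prefixes = prefixes,
         shared_peptides = unique(shared_peptides), default = default),
    class = "species_map"
  )
}

#' Build a species map from FASTA-style headers or accession suffixes
#'
#' Uses the UniProt-style organism suffix of accessions
#' (`sp|P12345|NAME_HUMAN`) to label proteins. Identifiers whose suffix
#' matches `human_tag` become `"human"`, those matching `entrapment_tag`
#' become `"entrapment"`.
#'
#' @param ids Character vector of protein identifiers or FASTA headers.
#' @param human_tag,entrapment_tag Regular expressions for the organism
#'   suffix (defaults `_HUMAN$` and `_ECOLI$`).
#' @inheritParams species_map
#' @return A `species_map` with an explicit mapping for `ids`.
#' @export
species_map_from_fasta_headers <- function(ids, human_tag = "_HUMAN$",
                                           entrapment_tag = "_ECOLI$",
                                           shared_peptides = character(),
                                           default = NULL) {
  ids <- sub("^>", "", ids)
  accession <- vapply(strsplit(ids, "[| ]"), function(parts) {
    parts[length(parts) >= 3][if (length(parts) >= 3) 3 else 1]
  }, character(1))
  accession[is.na(accession)] <- ids[is.na(accession)]
  label <- rep(NA_character_, length(ids))
  label[grepl(human_tag, accession)] <- "human"
  label[grepl(entrapment_tag, accession)] <- "entrapment"
  keep <- !is.na(label)
  species_map(mapping = setNames(label[keep], accession[keep]),
              shared_peptides = shared_peptides, default = default)
}

species_of_protein <- function(ids, map) {
  out <- rep(NA_character_, length(ids))
  if (length(map$mapping) > 0) {
    hit <- match(ids, names(map$mapping))
    out[!is.na(hit)] <- unname(map$mapping[hit[!is.na(hit)]])
  }
  if (length(map$prefixes) > 0) {
    for (pat in names(map$prefixes)) {
      out[is.na(out) & grepl(pat, ids)] <- map$prefixes[[pat]]
    }
  }
  if (!is.null(map$default)) out[is.na(out)] <- map$default
  out
}

#' Assign species labels to a report table
#'
#' Labels every record `"human"` or `"entrapment"` from the species map.
#' Records whose protein group mixes species, and records whose peptide
#' sequence is in the map's shared-peptide set, are labelled `"shared"`;
#' shared records are excluded from all species-specific metrics
#' downstream. The operation is idempotent and never relabels a shared
#' record back to a single species.
#'
#' @param table A report table.
#' @param map A [species_map()].
#' @return The report table with its `species` column filled in.
#' @export
assign_species <- function(table, map) {
  table <- as_report_table(table)
  stopifnot(inherits(map, "species_map"))
  if (nrow(table) == 0) return(table)

  groups <- unique(table$protein_group)
  group_species <- vapply(strsplit(groups, ";", fixed = TRUE),
                          function(members) {
    members <- trimws(members)
    sp <- species_of_protein(members, map)
    if (anyNA(sp)) return(NA_character_)
    sp <- unique(sp)
    if (length(sp) == 1) sp else "shared"
  }, character(1))
  if (anyNA(group_species)) {
    offenders <- groups[is.na(group_species)]
    stop("unmapped protein identifier(s) and no default species: ",
         paste(head(offenders, 5), collapse = "; "),
         if (length(offenders) > 5) " ..." else "", call. = FALSE)
  }
  new_species <- unname(group_species[match(table$protein_group, groups)])
  if (length(map$shared_peptides) > 0) {
    peptide <- split_precursor_id(table$precursor_id)$sequence
    new_species[peptide %in% map$shared_peptides] <- "shared"
  }
  # never downgrade a previously shared label
  new_species[table$species == "shared"] <- "shared"
  table$species <- new_species
  table
}
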