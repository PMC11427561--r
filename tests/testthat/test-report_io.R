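test_that("report round-trips through write_report/read_report", {
  tab <- toy_report(
    run_id = rep(c("A", "B"), c(3, 2)),
    protein_group = c("HUMAN_P1", "HUMAN_P1", "HUMAN_P2", "HUMAN_P1",
                      "ECOLI_P9"),
    precursor_id = c("pepA/2", "pepB/2", "pepC/3", "pepA/2", "pepZ/2"),
    intensity = c(8, 4, 16, 9, 2),
    q_run = c(0.001, 0.002, 0.01, 0.02, 0),
    species = c("human", "human", "human", "human", "entrapment")
  )
  tab$pgq_run[2] <- NA_real_  # missing values serialize as empty fields
  path <- withr::local_tempfile(fileext = ".tsv")
  write_report(tab, path)
  back <- read_report(path, "generic")
  expect_equal(as.data.frame(back), as.data.frame(tab))

  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_report(tab, path2, dialect = "diann")
  back2 <- read_report(path2, "diann")
  expect_equal(back2$intensity, tab$intensity)
  expect_equal(back2$precursor_id, tab$precursor_id)
  expect_equal(back2$q_run, tab$q_run)
  expect_equal(back2$species, tab$species)
})

test_that("header-only files give an empty table and bad input errors name the problem", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("run_id", "protein_group", "precursor_id", "intensity",
                     "q_run", "q_global"), collapse = "\t"), path)
  empty <- read_report(path, "generic")
  expect_s3_class(empty, "report_table")
  expect_equal(nrow(empty), 0)

  writeLines(c("run_id\tprotein_group\tintensity", "A\tP1\t5"), path)
  expect_error(read_report(path, "generic"), "precursor_id")

  writeLines(c(paste(c("run_id", "protein_group", "precursor_id",
                       "intensity", "q_run", "q_global"), collapse = "\t"),
               "A\tP1\tpep/2\toops\t0.001\t0.001"), path)
  expect_error(read_report(path, "generic"), "unparsable.*intensity")
})

test_that("duplicated (run, precursor) rows are rejected with the offending key", {
  path <- withr::local_tempfile(fileext = ".tsv")
  header <- paste(c("run_id", "protein_group", "precursor_id", "intensity",
                    "q_run", "q_global"), collapse = "\t")
  writeLines(c(header,
               "A\tP1\tpepA/2\t5\t0.001\t0.001",
               "A\tP1\tpepA/2\t6\t0.002\t0.001"), path)
  expect_error(read_report(path, "generic"), "A / pepA/2", fixed = TRUE)
})

test_that("report validation enforces value invariants", {
  expect_error(toy_report("A", "P1", "pep/2", -1), "negative")
  expect_error(toy_report("A", "P1", "pep/2", 1, q_run = 1.2), "\\[0, 1\\]")
  expect_error(toy_report("A", "P1", "pep/2", 1, species = "mouse"),
               "species")
})

test_that("species are assigned from prefixes, with mixed groups and shared peptides going to 'shared'", {
  map <- prefix_species_map(shared_peptides = "pepS")
  tab <- toy_report(
    run_id = "A",
    protein_group = c("ECOLI_P9", "HUMAN_P1;HUMAN_P2",
                      "HUMAN_P1;ECOLI_P9", "HUMAN_P3"),
    precursor_id = c("pepA/2", "pepB/2", "pepC/2", "pepS/2"),
    intensity = 1
  )
  out <- assign_species(tab, map)
  expect_equal(out$species,
               c("entrapment", "human", "shared", "shared"))
  # idempotent, and shared is never relabelled back
  again <- assign_species(out, prefix_species_map())
  expect_equal(again$species, out$species)
})

test_that("unmapped identifiers error unless a default is configured", {
  tab <- toy_report("A", c("HUMAN_P1", "YEAST_P1"), c("a/2", "b/2"), 1)
  expect_error(assign_species(tab, prefix_species_map()), "YEAST_P1")
  out <- assign_species(tab, prefix_species_map(default = "unknown"))
  expect_equal(out$species, c("human", "unknown"))
})

test_that("pivot_protein_matrix aggregates ions per protein and run", {
  tab <- toy_report("R1", "HUMAN_P1", "pepA/2", 8, species = "human")
  expect_equal(pivot_protein_matrix(tab)["HUMAN_P1", "R1"], 3)

  tab2 <- toy_report("R1", c("HUMAN_P1", "HUMAN_P1"),
                     c("pepA/2", "pepB/2"), c(4, 16), species = "human")
  expect_equal(pivot_protein_matrix(tab2, "median")["HUMAN_P1", "R1"], 3)
  expect_equal(pivot_protein_matrix(tab2, "sum")["HUMAN_P1", "R1"],
               log2(20))

  tab3 <- toy_report(c("R1", "R2", "R2"),
                     c("HUMAN_P1", "HUMAN_P1", "HUMAN_P2"),
                     c("pepA/2", "pepA/2", "pepB/2"), c(8, 8, 2),
                     species = "human")
  mat <- pivot_protein_matrix(tab3)
  expect_true(is.na(mat["HUMAN_P2", "R1"]))
  # non-missing cells never exceed distinct (protein, run) pairs
  expect_lte(sum(!is.na(mat)), 3)
  expect_error(pivot_protein_matrix(tab3[0, ]), "zero runs")
})

test_that("protein matrices and annotations round-trip as TSV", {
  mat <- matrix(c(1.5, NA, 3, 4.25), nrow = 2,
                dimnames = list(c("P1", "P2"), c("R1", "R2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_protein_matrix(mat, path)
  expect_equal(read_protein_matrix(path), mat)

  ann <- tibble::tibble(run_id = c("R1", "R2"), role = c("analyte", "me"),
                        condition = "c1", replicate = c(1L, 1L))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_sample_annotation(ann, path2)
  expect_equal(as.data.frame(read_sample_annotation(path2)),
               as.data.frame(ann))
  expect_error(as_sample_annotation(dplyr::mutate(ann, role = "sample")),
               "role")
})

test_that("FASTA-header species maps classify by organism suffix", {
  map <- species_map_from_fasta_headers(
    c(">sp|P1|ALBU_HUMAN text", "sp|P2|LACB_ECOLI", "tr|P3|XXX_YEAST"))
  expect_equal(unname(map$mapping[c("ALBU_HUMAN", "LACB_ECOLI")]),
               c("human", "entrapment"))
  expect_false("XXX_YEAST" %in% names(map$mapping))
})
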