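test_that("false_positive_rate is the entrapment fraction of identifications", {
  expect_equal(false_positive_rate(counts_row(1000, 0, "mbr")), 0)
  expect_equal(false_positive_rate(counts_row(998, 2, "mbr")), 0.002)
  expect_error(false_positive_rate(counts_row(0, 0, "mbr")), "undefined")
})

test_that("false_transfer_rate implements the count-difference formula and its conventions", {
  # 10 entrapment among 200 gained identifications
  expect_equal(false_transfer_rate(counts_row(1190, 10, "mbr"),
                                   counts_row(1000, 0, "indiv")), 0.05)
  # human count decreased while entrapment increased: rate set to 100%
  expect_equal(false_transfer_rate(counts_row(995, 5, "mbr"),
                                   counts_row(1000, 0, "indiv")), 1.0)
  # nothing gained: undefined
  expect_true(is.na(false_transfer_rate(counts_row(1000, 0, "mbr"),
                                        counts_row(1000, 0, "indiv"))))
  # entrapment losses alongside human gains would go negative: clipped
  expect_warning(
    ftr <- false_transfer_rate(counts_row(1200, 5, "mbr"),
                               counts_row(1000, 10, "indiv")),
    "clipped")
  expect_equal(ftr, 0)
  expect_error(false_transfer_rate(counts_row(1, 0, "mbr", "R1"),
                                   counts_row(1, 0, "indiv", "R2")),
               "same replicate")
})

test_that("entrapment_counts splits identifications by species and provenance", {
  tab <- toy_report(
    run_id = rep("R1", 5),
    protein_group = c("HUMAN_P1", "HUMAN_P2", "ECOLI_P1", "HUMAN_P3",
                      "HUMAN_P4;ECOLI_P2"),
    precursor_id = sprintf("p%d/2", 1:5), intensity = 1,
    species = c("human", "human", "entrapment", "human", "shared"),
    provenance = c("first_pass", "first_pass", "matched", "matched",
                   "matched"))
  mbr <- entrapment_counts(tab, "mbr")
  indiv <- entrapment_counts(tab, "indiv")
  expect_equal(mbr$ids_total, 4)      # shared record excluded
  expect_equal(mbr$ids_entrapment, 1)
  expect_equal(indiv$ids_total, 2)
  expect_equal(indiv$ids_entrapment, 0)
  expect_equal(false_transfer_rate(mbr, indiv), 0.5)
  expect_error(entrapment_counts(toy_report("R1", "P1", "a/2", 1), "mbr"),
               "assign_species")
})

test_that("protein-level FPR counts distinct groups once", {
  tab <- toy_report(
    run_id = "R1",
    protein_group = c(rep("HUMAN_P1", 3), "ECOLI_P1", "ECOLI_P1",
                      rep("HUMAN_P2", 2)),
    precursor_id = sprintf("p%d/2", 1:7), intensity = 1,
    species = c(rep("human", 3), "entrapment", "entrapment",
                rep("human", 2)))
  out <- protein_level_fpr(tab)
  expect_equal(out$fpr_protein, 1 / 3)  # 1 entrapment group of 3 groups
})

test_that("ftr_table pools replicates and tallies undefined ones", {
  tab <- toy_report(
    run_id = c(rep("R1", 4), rep("R2", 2)),
    protein_group = c("HUMAN_P1", "HUMAN_P2", "ECOLI_P1", "HUMAN_P3",
                      "HUMAN_P1", "HUMAN_P2"),
    precursor_id = c(sprintf("p%d/2", 1:4), "p1/2", "p2/2"),
    intensity = 1,
    species = c("human", "human", "entrapment", "human", "human", "human"),
    provenance = c("first_pass", "first_pass", "matched", "matched",
                   "first_pass", "first_pass"))
  out <- ftr_table(tab)
  expect_equal(out$ftr, c(0.5, NA))
  expect_equal(attr(out, "pooled"), 0.5)
  expect_equal(attr(out, "n_undefined"), 1)
  # the set-difference diagnostic agrees here (matching only added ids)
  sets <- ftr_table(tab, ftr_variant = "sets")
  expect_equal(sets$ftr, out$ftr)
})

test_that("ROC over q-values matches brute-force pair ordering and handles the toy cases", {
  tab <- toy_report("R1", "P", sprintf("p%d/2", 1:4), 1,
                    q_run = c(0.01, 0.02, 0.015, 0.05),
                    species = c("human", "human", "entrapment",
                                "entrapment"))
  roc <- roc_over_qvalues(tab, "q_run")
  # oracle: fraction of (human, entrapment) pairs ordered correctly,
  # ties counting one half
  q <- tab$q_run; human <- tab$species == "human"
  pairs <- expand.grid(h = which(human), e = which(!human))
  auc_oracle <- mean(ifelse(q[pairs$h] < q[pairs$e], 1,
                            ifelse(q[pairs$h] == q[pairs$e], 0.5, 0)))
  expect_equal(auc_oracle, 0.75)
  expect_equal(roc$auroc, auc_oracle)
  expect_equal(roc$tpr[1], 0)
  expect_equal(roc$tpr[length(roc$tpr)], 1)
  expect_true(all(diff(roc$tpr) >= 0) && all(diff(roc$fpr) >= 0))

  perfect <- toy_report("R1", "P", sprintf("p%d/2", 1:4), 1,
                        q_run = c(0.001, 0.001, 0.9, 0.9),
                        species = c("human", "human", "entrapment",
                                    "entrapment"))
  expect_equal(roc_over_qvalues(perfect, "q_run")$auroc, 1.0)
  onecls <- toy_report("R1", "P", "p1/2", 1, species = "human")
  expect_error(roc_over_qvalues(onecls, "q_run"), "both")
})

test_that("AUROC is invariant under strictly monotone q-value transforms", {
  set.seed(11)
  n <- 400
  tab <- toy_report("R1", "P", sprintf("p%d/2", 1:n), 1,
                    q_run = c(rbeta(n / 2, 1, 50), runif(n / 2, 0, 0.3)),
                    species = rep(c("human", "entrapment"), each = n / 2))
  a1 <- roc_over_qvalues(tab, "q_run")$auroc
  tab$q_run <- tab$q_run^3          # strictly increasing on [0, 1]
  a2 <- roc_over_qvalues(tab, "q_run")$auroc
  tab$q_run <- 1 - (1 - tab$q_run)^2
  a3 <- roc_over_qvalues(tab, "q_run")$auroc
  expect_equal(a1, a2)
  expect_equal(a1, a3)
})

test_that("AUROC of uniformly shuffled labels is ~0.5", {
  set.seed(19)
  n <- 10000
  tab <- toy_report("R1", "P", sprintf("p%d/2", 1:n), 1,
                    q_run = runif(n),
                    species = sample(c("human", "entrapment"), n,
                                     replace = TRUE))
  expect_equal(roc_over_qvalues(tab, "q_run")$auroc, 0.5,
               tolerance = 0.02 / 0.5)
})

test_that("overlap and Jaccard match explicit set arithmetic", {
  expect_equal(overlap_coefficient(letters[1:3], letters[1:3]), 1)
  expect_equal(overlap_coefficient(c("a", "b", "c"), c("b", "c", "d")),
               2 / 3)
  expect_equal(overlap_coefficient(c("a", "b"), c("x", "y")), 0)
  expect_equal(jaccard_index(letters[1:3], letters[1:3]), 1)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  # subset: jaccard = |b|/|a|, overlap = 1
  expect_equal(jaccard_index(letters[1:4], letters[1:2]), 0.5)
  expect_equal(overlap_coefficient(letters[1:4], letters[1:2]), 1)
  expect_error(overlap_coefficient(character(), character()), "empty")
  expect_error(jaccard_index(character(), character()), "empty")
})

test_that("overlap >= jaccard with equality iff one set contains the other", {
  set.seed(5)
  for (i in 1:200) {
    a <- sample(letters, sample(1:15, 1))
    b <- sample(letters, sample(1:15, 1))
    ov <- overlap_coefficient(a, b)
    jc <- jaccard_index(a, b)
    expect_gte(ov, jc)
    # equality holds exactly when the sets coincide or are disjoint
    expect_equal(ov == jc, setequal(a, b) || ov == 0)
  }
})
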