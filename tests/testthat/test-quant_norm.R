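test_that("normalize_traces recovers pure loading differences", {
  # one sample: identity with zero shift
  one <- loading_report(c(A = 1))
  out1 <- normalize_traces(one)
  expect_equal(attr(out1, "shifts")$shift_log2, 0)
  expect_equal(out1$intensity, one$intensity)

  # sample B = A with every intensity doubled
  two <- loading_report(c(A = 1, B = 2))
  out2 <- normalize_traces(two)
  sh <- attr(out2, "shifts")
  expect_equal(abs(diff(sh$shift_log2)), 1)
  ratio <- log2(out2$intensity[out2$run_id == "B"]) -
    log2(out2$intensity[out2$run_id == "A"])
  expect_equal(median(ratio), 0)

  # loading factors {0.25, 1, 4} recovered up to a common offset
  tab <- loading_report(c(A = 0.25, B = 1, C = 4))
  shifts <- attr(normalize_traces(tab), "shifts")
  rec <- -shifts$shift_log2
  rec <- rec - mean(rec)
  expect_equal(rec, c(-2, 0, 2) - 0, tolerance = 0.05)
})

test_that("normalization is idempotent and shift-only", {
  sim <- simulate_two_proteome(simulation_config(seed = 2))
  tab <- drop_me_runs(sim$report, sim$annotation)
  once <- normalize_traces(tab)
  twice <- normalize_traces(once)
  expect_lt(max(abs(attr(twice, "shifts")$shift_log2)), 1e-9)

  # within-sample ion ratios unchanged (to one ulp of the common scaling)
  r <- once$run_id == once$run_id[1]
  before <- tab$intensity[r][-1] / tab$intensity[r][1]
  after <- once$intensity[r][-1] / once$intensity[r][1]
  expect_true(all(abs(after - before) <= 4e-16 * abs(before)))
})

test_that("a sample sharing no ions with the anchor is reported by name", {
  tab <- toy_report(c("A", "A", "A", "B"),
                    "HUMAN_P1", c("a/2", "b/2", "c/2", "z/2"), 2,
                    species = "human")
  expect_error(normalize_traces(tab), "'B'")
  expect_error(normalize_traces(dplyr::mutate(tab, intensity = 0)),
               "positive")
})

test_that("summarize_protein aligns and medians ion traces", {
  # single ion: protein trace equals the ion trace
  one <- matrix(c(1, 2, 3), nrow = 1,
                dimnames = list("i1", c("s1", "s2", "s3")))
  expect_equal(summarize_protein(one), one[1, ])

  # two complete ions offset by 2 log2: per-sample differences preserved
  ions <- rbind(i1 = c(10, 11, 12), i2 = c(12, 13, 14))
  colnames(ions) <- c("s1", "s2", "s3")
  out <- summarize_protein(ions)
  expect_equal(diff(out), diff(ions["i1", ]))

  # an outlying sample in one of three ions is damped by the median
  ions3 <- rbind(i1 = c(10, 10, 10), i2 = c(10, 10, 10),
                 i3 = c(10, 15, 10))
  colnames(ions3) <- c("s1", "s2", "s3")
  out3 <- summarize_protein(ions3)
  expect_equal(unname(out3["s2"] - out3["s1"]), 0)

  expect_error(summarize_protein(matrix(numeric(0), nrow = 0)), "ion")
})

test_that("summarize_proteins agrees with summarize_protein per protein", {
  tab <- toy_report(
    run_id = rep(c("R1", "R2"), each = 3),
    protein_group = rep(c("HUMAN_P1", "HUMAN_P1", "HUMAN_P2"), 2),
    precursor_id = rep(c("a/2", "b/2", "c/2"), 2),
    intensity = c(4, 16, 8, 8, 32, 16), species = "human")
  mat <- summarize_proteins(tab)
  expect_equal(dim(mat), c(2, 2))
  ion <- rbind(c(2, 3), c(4, 5))
  colnames(ion) <- c("R1", "R2")
  expect_equal(unname(mat["HUMAN_P1", ]), unname(summarize_protein(ion)))
  expect_equal(unname(mat["HUMAN_P2", ]), c(3, 4))
})

test_that("protein CVs are linear-scale sd/mean with a minimum-observation rule", {
  mat <- rbind(P1 = log2(c(1, 2, 3)), P2 = log2(c(5, 5, 5)),
               P3 = c(3, NA, NA))
  cv <- protein_cv(mat)
  expect_equal(unname(cv["P1"]), 0.5)      # sd{1,2,3}=1, mean=2
  expect_equal(unname(cv["P2"]), 0)
  expect_true(is.na(cv["P3"]))             # single observation
})

test_that("median CV tracks the log-normal noise level", {
  sigma_log2 <- 0.24
  sigma_ln <- sigma_log2 * log(2)
  expected_cv <- sqrt(exp(sigma_ln^2) - 1)
  set.seed(8)
  base <- rnorm(400, 12, 2)
  mat <- sapply(1:7, function(i) base + rnorm(400, 0, sigma_log2))
  cv <- protein_cv(mat)
  expect_equal(median(cv), expected_cv, tolerance = 0.10)
})

test_that("expected spike ratios follow the mixing design", {
  d <- spike_design(c("rho05", "rho20", "rho10_10ng"),
                    c(0.05, 0.20, 0.10), c(1, 1, 10))
  expect_equal(expected_log2_ratio(d, "rho05", "rho20", "entrapment"), 2)
  expect_equal(expected_log2_ratio(d, "rho05", "rho20", "human"),
               log2(0.80 / 0.95))
  expect_equal(expected_log2_ratio(d, "rho05", "rho05", "human"), 0)
  expect_equal(expected_log2_ratio(d, "rho05", "rho10_10ng", "entrapment"),
               1 + log2(10))
  d0 <- spike_design(c("pure", "sp"), c(0, 0.1), c(1, 1))
  expect_error(expected_log2_ratio(d0, "pure", "sp", "entrapment"),
               "spike fraction 0")
})

test_that("ratio deviations are zero on perfect data and report exclusions", {
  d <- spike_design(c("a", "b"), c(0.05, 0.20), c(1, 1))
  conditions <- c("a", "a", "b", "b")
  human <- 10 + log2(0.95) + c(0, 0, rep(log2(0.80 / 0.95), 2))
  ecoli <- 8 + log2(0.05) + c(0, 0, rep(2, 2))
  mat <- rbind(HUMAN_P1 = human, ECOLI_P1 = ecoli,
               HUMAN_P2 = c(5, 5, NA, NA))
  sp <- c(HUMAN_P1 = "human", ECOLI_P1 = "entrapment", HUMAN_P2 = "human")
  out <- ratio_deviation(mat, conditions, d, sp, "a", "b")
  expect_equal(out$deviation, c(0, 0))
  expect_equal(attr(out, "n_excluded"), 1)
})

test_that("completeness bins partition by abundance rank", {
  # 6 proteins x 2 samples, 3 missing cells in the two least abundant rows
  mat <- matrix(rep(seq(12, 7), each = 2), nrow = 6, byrow = TRUE,
                dimnames = list(paste0("P", 1:6), c("R1", "R2")))
  mat[5, 1] <- NA
  mat[6, ] <- NA
  out <- completeness_bins(mat, 6)
  expect_equal(out$completeness, c(1, 1, 1, 1, 0.5, 0))
  expect_equal(completeness_bins(mat, 1)$completeness, mean(!is.na(mat)))
  full <- matrix(1, 7, 2)
  expect_equal(completeness_bins(full, 6)$completeness, rep(1, 6))
  expect_equal(completeness_bins(full, 6)$n_proteins, c(2, 1, 1, 1, 1, 1))
  expect_error(completeness_bins(mat[1:3, ], 6), "fewer proteins")
})

test_that("sample correlations use pairwise-complete values with a minimum n", {
  set.seed(3)
  x <- rnorm(20)
  mat <- cbind(s1 = x, s2 = x, s3 = -x + mean(x) * 2)
  r <- sample_correlation(mat, min_pairwise = 10)
  expect_equal(r["s1", "s2"], 1)
  expect_equal(r["s1", "s3"], -1)
  # hand-computed Pearson on a 5-protein pair
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 6)
  hand <- sum((a - 3) * (b - mean(b))) /
    sqrt(sum((a - 3)^2) * sum((b - mean(b))^2))
  r2 <- sample_correlation(cbind(a, b), min_pairwise = 5)
  expect_equal(r2["a", "b"], hand)
  # a pair sharing too few proteins is undefined
  short <- cbind(s1 = c(x[1:9], rep(NA, 11)), s2 = x)
  expect_true(is.na(sample_correlation(short, 10)["s1", "s2"]))
})

test_that("PCA separates planted groups on complete proteins", {
  base <- matrix(rnorm(40, 10), nrow = 10)
  mat <- cbind(base, base)  # two identical blocks -> identical scores
  colnames(mat) <- paste0("s", 1:8)
  p <- pca_scores(mat)
  expect_equal(p$scores[1:4, ], p$scores[5:8, ], ignore_attr = TRUE)
  expect_lte(sum(p$explained_variance), 1)

  sep <- rbind(marker = c(0, 0, 0, 5, 5, 5),
               flat1 = rep(1, 6), flat2 = rep(2, 6),
               noise = c(1, 1.1, 0.9, 1, 1.1, 0.9))
  colnames(sep) <- paste0("s", 1:6)
  sc <- pca_scores(sep)$scores[, 1]
  expect_true(max(sc[1:3]) < min(sc[4:6]) || min(sc[1:3]) > max(sc[4:6]))
  expect_error(pca_scores(matrix(c(1, NA), 1, 2)), "two fully observed")
})

test_that("dynamic range counts orders of magnitude of median intensities", {
  mat <- rbind(log2(c(1, 1)), log2(c(50, 50)), log2(c(1000, 1000)))
  expect_equal(dynamic_range(mat), 3)
  expect_equal(dynamic_range(rbind(c(3, 3), c(3, 3))), 0)
})
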