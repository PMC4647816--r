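# two perfectly separated groups: disjoint fixed loci (freq 1 vs 0)
separated_cohort <- function(n_per = 20, L = 40) {
  gA <- cbind(matrix(2L, n_per, L / 2), matrix(0L, n_per, L / 2))
  gB <- cbind(matrix(0L, n_per, L / 2), matrix(2L, n_per, L / 2))
  toy_cohort(list(A = gA, B = gB), groups = c(A = "A", B = "B"))
}

test_that("locus ranking is by descending F_ST with coordinate tie-breaks", {
  st <- data.frame(locus_id = c("L1", "L2", "L3", "L4"),
                   chrom = c("chr2", "chr1", "chr1", "chr3"),
                   pos = c(5, 9, 2, 1),
                   fst = c(0.3, 0.5, 0.5, NA), stringsAsFactors = FALSE)
  expect_equal(rank_loci(st, 2), c("L3", "L2"))  # tie broken by (chrom, pos)
  expect_equal(rank_loci(st, 0), character(0))
  expect_error(rank_loci(st, 4), "exceeds")      # NA-F_ST locus is excluded

  # nestedness: top-n is a prefix of top-m
  expect_equal(rank_loci(st, 2), rank_loci(st, 3)[1:2])
})

test_that("perfectly separated groups give accuracy 1 and error 0", {
  toy <- separated_cohort()
  st <- locus_stats(toy$matrix, toy$panel, comparison_groups = c("A", "B"))
  rk <- rank_loci(st, 40)
  cv <- ancestry_cv(toy$matrix, toy$panel, c("A", "B"), rk,
                    subset_sizes = c(40, 10), replicates = 3, seed = 5)
  expect_equal(cv$accuracy, c(1, 1))
  expect_equal(cv$call_rate, c(1, 1))
  expect_lt(max(cv$error), 1e-6)
})

test_that("call threshold 1 excludes no-calls from the accuracy denominator", {
  set.seed(41)
  # noisy overlap: same frequencies in both groups except a few loci
  f <- runif(30, 0.3, 0.7)
  gA <- matrix(rbinom(15 * 30, 2, rep(f, each = 15)), 15, 30)
  gB <- matrix(rbinom(15 * 30, 2, rep(f, each = 15)), 15, 30)
  gB[, 1:3] <- 2L
  toy <- toy_cohort(list(A = gA, B = gB), groups = c(A = "A", B = "B"))
  st <- locus_stats(toy$matrix, toy$panel, comparison_groups = c("A", "B"))
  rk <- rank_loci(st, 30)
  cv <- ancestry_cv(toy$matrix, toy$panel, c("A", "B"), rk,
                    subset_sizes = 30, replicates = 5, seed = 5,
                    call_threshold = 1.0)
  expect_lt(cv$call_rate, 1)
  reps <- attr(cv, "replicates")
  expect_true(all(is.na(reps$accuracy) | (reps$accuracy >= 0 & reps$accuracy <= 1)))
})

test_that("cross-validation reports are bit-reproducible from the seed", {
  toy <- separated_cohort(n_per = 10, L = 20)
  st <- locus_stats(toy$matrix, toy$panel, comparison_groups = c("A", "B"))
  rk <- rank_loci(st, 20)
  cv1 <- ancestry_cv(toy$matrix, toy$panel, c("A", "B"), rk,
                     subset_sizes = c(20, 10), replicates = 4, seed = 99)
  cv2 <- ancestry_cv(toy$matrix, toy$panel, c("A", "B"), rk,
                     subset_sizes = c(20, 10), replicates = 4, seed = 99)
  expect_identical(cv1, cv2)
})

test_that("random-assignment accuracy floor is ~1/K on balanced exchangeable groups", {
  set.seed(43)
  # three groups drawn from identical frequencies: no signal, so with a
  # permissive call threshold the classifier cannot beat chance by much
  f <- runif(60, 0.2, 0.8)
  gs <- lapply(1:3, function(i) matrix(rbinom(20 * 60, 2, rep(f, each = 20)), 20, 60))
  names(gs) <- c("A", "B", "C")
  toy <- toy_cohort(gs, groups = c(A = "A", B = "B", C = "C"))
  st <- locus_stats(toy$matrix, toy$panel, comparison_groups = c("A", "B", "C"))
  rk <- rank_loci(st, 60)
  cv <- ancestry_cv(toy$matrix, toy$panel, c("A", "B", "C"), rk,
                    subset_sizes = 60, replicates = 10, seed = 5,
                    call_threshold = 0)
  expect_gt(cv$accuracy, 1 / 3 - 0.25)
  expect_lt(cv$accuracy, 1 / 3 + 0.25)
})

test_that("admixture prediction error is 0 (cor 1) for the full set and grows as subsets shrink", {
  sim <- preset_fixture()
  st <- locus_stats(sim$matrix, sim$panel)
  full_rank <- rank_loci(st, sum(!is.na(st$fst)))
  # restrict to the rankable loci so the largest subset IS the full set
  m <- subset_matrix(sim$matrix, loci = full_rank)
  res <- admixture_prediction_error(m, sim$panel,
                                    c("African", "European"), "ASW_SIM",
                                    full_rank,
                                    subset_sizes = c(length(full_rank), 50, 10))
  expect_equal(res$rmsd[1], 0, tolerance = 1e-6)   # subset = full set
  expect_equal(res$cor[1], 1, tolerance = 1e-6)
  expect_gt(res$rmsd[3], res$rmsd[2])              # 10 loci worse than 50
})

test_that("uninformative subsets push q toward uniform", {
  sim <- preset_fixture()
  st <- locus_stats(sim$matrix, sim$panel)
  # least informative defined loci: F_ST ascending
  ok <- st[!is.na(st$fst), ]
  dull <- ok$locus_id[order(ok$fst)][1:30]
  res <- admixture_prediction_error(sim$matrix, sim$panel,
                                    c("African", "European"), "ASW_SIM",
                                    dull, subset_sizes = 30)
  q_full <- attr(res, "q_full")
  # RMSD approaches the distance from the full-set q to the uniform vector
  rmsd_uniform <- mean(sqrt(rowMeans((q_full - 0.5)^2)))
  expect_lt(abs(res$rmsd - rmsd_uniform), 0.15)
})
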