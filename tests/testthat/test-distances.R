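test_that("allele-sharing distance is the L1 dosage difference", {
  toy <- toy_cohort(list(P = rbind(c(0, 2, 1), c(1, 0, 1))))
  d <- allele_sharing_distance(toy$matrix)
  expect_equal(d[1, 2], 3)
  expect_equal(diag(d), c(P_01 = 0, P_02 = 0))

  dn <- allele_sharing_distance(toy$matrix, normalize = TRUE)
  expect_equal(dn[1, 2], 3 / 6)
})

test_that("distance to the ancestor equals total insertion load", {
  toy <- toy_cohort(list(P = rbind(c(0, 2, 1), c(2, 2, 2))))
  m <- add_ancestor(toy$matrix)
  d <- allele_sharing_distance(m)
  expect_equal(unname(d["ANCESTOR", 1:2]), c(3, 6))
  # monotone in insertion load by construction of the L1 distance
  expect_gt(d["ANCESTOR", 2], d["ANCESTOR", 1])
})

test_that("raw allele-sharing distance is a metric on random matrices", {
  set.seed(11)
  for (rep in 1:5) {
    x <- matrix(sample(0:2, 8 * 20, replace = TRUE), 8, 20,
                dimnames = list(paste0("s", 1:8), NULL))
    d <- allele_sharing_distance(polyte_matrix(x))
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("normalized distance is invariant to duplicating every locus", {
  set.seed(12)
  x <- matrix(sample(0:2, 6 * 15, replace = TRUE), 6, 15,
              dimnames = list(paste0("s", 1:6), NULL))
  m1 <- polyte_matrix(x)
  m2 <- polyte_matrix(cbind(x, x))
  expect_equal(allele_sharing_distance(m1, normalize = TRUE),
               allele_sharing_distance(m2, normalize = TRUE))
})

test_that("population-averaged distances follow the between/within contract", {
  toy <- toy_cohort(list(P1 = matrix(c(0, 1), 1, 2),
                         P2 = matrix(c(2, 2), 1, 2)))
  d <- allele_sharing_distance(toy$matrix)
  pa <- population_average_distances(d, toy$panel)
  expect_equal(unname(pa$between), rbind(c(0, 3), c(3, 0)))
  expect_true(all(is.na(pa$within)))  # single-member populations

  # a population duplicated under two labels has zero between-distance iff
  # all its members are identical
  x <- rbind(a = c(1L, 1L), b = c(1L, 1L), c = c(1L, 1L), d = c(1L, 1L))
  panel <- data.frame(sample = c("a", "b", "c", "d"),
                      population = c("P", "P", "Q", "Q"),
                      group = "G", stringsAsFactors = FALSE)
  d2 <- allele_sharing_distance(polyte_matrix(x))
  pa2 <- population_average_distances(d2, panel)
  expect_equal(pa2$between["P", "Q"], 0)
  expect_equal(unname(pa2$within), c(0, 0))
  x2 <- x; x2["c", ] <- c(0L, 2L)
  pa3 <- population_average_distances(allele_sharing_distance(polyte_matrix(x2)),
                                      panel)
  expect_gt(pa3$between["P", "Q"], 0)
})

test_that("diversity distributions and rank-sum tests behave at the extremes", {
  # identical distance multisets -> p = 1
  x <- rbind(a = c(0L, 1L), b = c(1L, 0L), c = c(0L, 1L), d = c(1L, 0L))
  panel <- data.frame(sample = letters[1:4], population = c("P", "P", "Q", "Q"),
                      group = c("G1", "G1", "G2", "G2"), stringsAsFactors = FALSE)
  d <- allele_sharing_distance(polyte_matrix(x))
  dv <- diversity_distributions(d, panel)
  expect_equal(dv$p_values["G1", "G2"], 1)

  # extreme separation -> small p for moderate sizes
  set.seed(4)
  hi <- matrix(sample(0:2, 12 * 60, replace = TRUE, prob = c(1, 2, 1)), 12, 60)
  lo <- matrix(rbinom(12 * 60, 2, 0.01), 12, 60)
  x2 <- rbind(hi, lo)
  rownames(x2) <- paste0("s", 1:24)
  panel2 <- data.frame(sample = rownames(x2),
                       population = rep(c("H", "L"), each = 12),
                       group = rep(c("H", "L"), each = 12),
                       stringsAsFactors = FALSE)
  dv2 <- diversity_distributions(allele_sharing_distance(polyte_matrix(x2)),
                                 panel2)
  expect_true(all(dv2$distances$H > max(dv2$distances$L)))
  expect_lt(dv2$p_values["H", "L"], 1e-10)
})

test_that("serial-founder preset yields the designed diversity ordering", {
  sim <- preset_fixture()
  d <- allele_sharing_distance(sim$matrix)
  dv <- diversity_distributions(d, sim$panel)
  med <- dv$medians[c("African", "American", "European", "Asian")]
  expect_true(all(diff(med) < 0))  # African > admixed American > European > Asian

  # oracle: direct averaging over the generator's known genotypes
  afr <- sim$panel$sample[sim$panel$group == "African"]
  block <- d[afr, afr]
  expect_equal(unname(dv$medians["African"]),
               median(block[upper.tri(block)]))
})

test_that("distance matrices serialise as square TSV and PHYLIP", {
  d <- rbind(c(0, 2.5, 3), c(2.5, 0, 1), c(3, 1, 0))
  dimnames(d) <- list(c("P1", "P2", "P3"), c("P1", "P2", "P3"))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, f1)
  back <- as.matrix(read.table(f1, header = TRUE, sep = "\t", row.names = 1))
  expect_equal(back, d, ignore_attr = TRUE)

  f2 <- withr::local_tempfile(fileext = ".phy")
  write_distance_matrix(d, f2, format = "phylip")
  lines <- readLines(f2)
  expect_equal(as.integer(trimws(lines[1])), 3)
  expect_length(lines, 4)
  expect_match(lines[2], "^P1")
})

test_that("family masking restricts loci without separate code paths", {
  sim <- preset_fixture()
  alu <- family_subset(sim$matrix, "ALU")
  expect_true(all(loci_info(alu)$family == "ALU"))
  expect_equal(ncol(alu), sum(loci_info(sim$matrix)$family == "ALU"))
  expect_error(family_subset(sim$matrix, "MIR"))
})
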