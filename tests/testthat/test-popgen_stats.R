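test_that("allele frequencies are TEi/2n per stratum and conserve counts", {
  toy <- toy_cohort(list(P1 = matrix(c(0, 1, 2, 0), 4, 1),
                         P2 = matrix(c(2, 2), 2, 1)),
                    groups = c(P1 = "G1", P2 = "G2"))
  fr <- allele_frequencies(toy$matrix, toy$panel, level = "population")
  p1 <- fr[fr$stratum == "P1", ]
  expect_equal(p1$te_count, 3)
  expect_equal(p1$n_alleles, 8)
  expect_equal(p1$freq, 0.375)

  overall <- allele_frequencies(toy$matrix, level = "overall")
  expect_equal(sum(fr$te_count), overall$te_count)  # conservation over strata

  zero <- toy_cohort(list(P1 = matrix(0, 3, 2)))
  fz <- allele_frequencies(zero$matrix, zero$panel, level = "population")
  expect_true(all(fz$freq == 0))
})

test_that("unfolded SFS uses half-open bins with a closed final bin", {
  fr <- data.frame(locus_id = paste0("L", 1:4), stratum = "all",
                   te_count = 0, n_alleles = 2,
                   freq = c(0.01, 0.02, 0.5, 1.0))
  sfs <- unfolded_sfs(fr, bins = c(0, 0.05, 1.0))
  expect_equal(sfs$count, c(2, 2))
  expect_equal(sum(sfs$count), 4)
  expect_error(unfolded_sfs(fr, bins = c(0, 1, 0.5)), "increasing")

  all_zero <- within(fr, freq <- 0)
  sfs0 <- unfolded_sfs(all_zero, bins = c(0, 0.05, 1.0))
  expect_equal(sfs0$count, c(4, 0))
})

test_that("sharing summary applies the strict >threshold rule", {
  fm <- rbind(L1 = c(A = 0.1, B = 0.0, C = 0.0),
              L2 = c(A = 0.06, B = 0.06, C = 0.0),
              L3 = c(A = 0.05, B = 0.0, C = 0.0))  # boundary: not counted
  s <- sharing_summary(fm, threshold = 0.05)
  pg <- s$per_group
  expect_equal(pg$above_threshold[pg$group == "A"], 2)
  expect_equal(pg$exclusive[pg$group == "A"], 1)
  expect_equal(pg$exclusive[pg$group == "B"], 0)
  expect_equal(s$combinations$count[s$combinations$combination == "A+B"], 1)
  # combination counts account for every locus above threshold somewhere
  expect_equal(sum(s$combinations$count), 2)
  expect_true(all(pg$exclusive <= pg$above_threshold))
})

test_that("delta is the max pairwise |frequency difference|", {
  expect_equal(delta_stat(c(0.6, 0.2)), 0.4)
  expect_equal(delta_stat(c(0.3, 0.3, 0.3)), 0)
  expect_equal(delta_stat(c(0.1, 0.5, 0.35)), 0.4)
  expect_error(delta_stat(0.5), ">= 2 groups")
  # symmetric under permutation, invariant to duplicating a group
  set.seed(1)
  for (i in 1:20) {
    f <- runif(4)
    expect_equal(delta_stat(f), delta_stat(sample(f)))
    expect_equal(delta_stat(f), delta_stat(c(f, f[2])))
  }
  # matrix form agrees with scalar form
  fm <- matrix(runif(30), 10, 3)
  expect_equal(delta_stat(fm), apply(fm, 1, delta_stat))
})

test_that("Weir-Cockerham F_ST matches the literal component oracle", {
  # frozen hand case: pop1 [2,2,1,1,0], pop2 [0,0,0,1,0]
  toy <- toy_cohort(list(P1 = matrix(c(2, 2, 1, 1, 0), 5, 1),
                         P2 = matrix(c(0, 0, 0, 1, 0), 5, 1)),
                    groups = c(P1 = "G1", P2 = "G2"))
  fst <- weir_cockerham_fst(toy$matrix, toy$panel, strata = c("G1", "G2"))
  expect_equal(fst$fst, 0.353448275862069, tolerance = 1e-12)

  # complete fixation
  fix <- toy_cohort(list(P1 = matrix(2, 3, 1), P2 = matrix(0, 3, 1)),
                    groups = c(P1 = "G1", P2 = "G2"))
  expect_equal(weir_cockerham_fst(fix$matrix, fix$panel,
                                  strata = c("G1", "G2"))$fst, 1)

  # identical genotype vectors in both strata: no among-population excess
  same <- toy_cohort(list(P1 = matrix(c(0, 1, 2), 3, 1),
                          P2 = matrix(c(0, 1, 2), 3, 1)),
                     groups = c(P1 = "G1", P2 = "G2"))
  expect_lte(weir_cockerham_fst(same$matrix, same$panel,
                                strata = c("G1", "G2"))$fst, 0)

  # monomorphic everywhere: undefined flag, not NaN propagation
  mono <- toy_cohort(list(P1 = matrix(0, 3, 1), P2 = matrix(0, 3, 1)),
                     groups = c(P1 = "G1", P2 = "G2"))
  f <- weir_cockerham_fst(mono$matrix, mono$panel, strata = c("G1", "G2"))
  expect_false(f$defined)
  expect_true(is.na(f$fst))
})

test_that("F_ST ranks group-exclusive common loci above uniform loci", {
  set.seed(3)
  n <- 40
  excl <- c(rbinom(n, 2, 0.4), rbinom(n, 2, 0.001))   # high freq in G1 only
  unif <- c(rbinom(n, 2, 0.2), rbinom(n, 2, 0.2))     # same freq everywhere
  toy <- toy_cohort(list(P1 = cbind(excl[1:n], unif[1:n]),
                         P2 = cbind(excl[(n + 1):(2 * n)], unif[(n + 1):(2 * n)])),
                    groups = c(P1 = "G1", P2 = "G2"))
  fst <- weir_cockerham_fst(toy$matrix, toy$panel, strata = c("G1", "G2"))
  expect_gt(fst$fst[1], fst$fst[2])
})

test_that("AIM threshold counts use strict exceedance", {
  tab <- data.frame(delta = c(0.31, 0.45, 0.55))
  expect_equal(unname(aim_threshold_counts(tab, c(0.3, 0.4, 0.5))), c(3, 2, 1))
  expect_equal(unname(aim_threshold_counts(tab, 0.55)), 0)  # strict
  expect_equal(unname(aim_threshold_counts(tab[0, , drop = FALSE],
                                           c(0.3, 0.4, 0.5))), c(0, 0, 0))
})

test_that("locus_stats assembles frequencies, F_ST and delta coherently", {
  sim <- preset_fixture()
  st <- locus_stats(sim$matrix, sim$panel)
  expect_equal(nrow(st), ncol(sim$matrix))
  expect_true(all(st$delta >= 0 & st$delta <= 1, na.rm = TRUE))
  expect_true(all(st$fst <= 1, na.rm = TRUE))
  # delta recomputable from the frequency columns
  fm <- as.matrix(st[, c("freq_African", "freq_Asian", "freq_European")])
  expect_equal(st$delta, unname(apply(fm, 1, max) - apply(fm, 1, min)))
})
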