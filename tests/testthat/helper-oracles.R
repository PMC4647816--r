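# Independent oracles used to validate the package implementations.
# Each is a deliberately plain, scalar, per-case translation of the
# textbook definition, kept free of the package's vectorised code paths.

# Weir & Cockerham (1984) theta-hat for one locus, from a list of per-
# population dosage vectors; literal scalar evaluation of the a, b, c
# variance components with observed heterozygote proportions.
wc_fst_literal <- function(pops) {
  r <- length(pops)
  n <- vapply(pops, length, numeric(1))
  p <- vapply(pops, function(g) sum(g) / (2 * length(g)), numeric(1))
  h <- vapply(pops, function(g) mean(g == 1), numeric(1))
  n_bar <- sum(n) / r
  nc <- (r * n_bar - sum(n^2) / (r * n_bar)) / (r - 1)
  p_bar <- sum(n * p) / (r * n_bar)
  s2 <- sum(n * (p - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- sum(n * h) / (r * n_bar)
  a <- (n_bar / nc) *
    (s2 - (1 / (n_bar - 1)) * (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# build a polyte_matrix from a list of per-population dosage matrices
# (individuals x loci), with a matching panel
toy_cohort <- function(pop_dosages, groups = names(pop_dosages)) {
  if (is.null(groups)) groups <- names(pop_dosages)
  mats <- list(); samples <- character(0); pop <- character(0)
  for (p in names(pop_dosages)) {
    g <- as.matrix(pop_dosages[[p]])
    rownames(g) <- sprintf("%s_%02d", p, seq_len(nrow(g)))
    mats[[p]] <- g
    samples <- c(samples, rownames(g)); pop <- c(pop, rep(p, nrow(g)))
  }
  x <- do.call(rbind, mats)
  colnames(x) <- paste0("chr1:", seq_len(ncol(x)), ":ALU")
  loci <- data.frame(chrom = "chr1", pos = seq_len(ncol(x)), family = "ALU",
                     locus_id = colnames(x), stringsAsFactors = FALSE)
  grp <- if (is.null(names(groups))) stats::setNames(groups, names(pop_dosages)) else groups
  list(matrix = polyte_matrix(x, loci),
       panel = data.frame(sample = samples, population = pop,
                          group = unname(grp[pop]), stringsAsFactors = FALSE))
}

# exhaustive maximum-likelihood q over the K-simplex at a fixed grid step,
# for the binomial admixture likelihood with fixed cluster frequencies
grid_q_oracle <- function(g, F_mat, step = 0.001) {
  K <- nrow(F_mat)
  stopifnot(K == 2)  # exhaustive enumeration is kept to the 2-simplex
  qs <- seq(0, 1, by = step)
  best <- c(NA, NA); best_ll <- -Inf
  for (q1 in qs) {
    p <- q1 * F_mat[1, ] + (1 - q1) * F_mat[2, ]
    ll <- sum(g * log(p) + (2 - g) * log(1 - p))
    if (ll > best_ll) {
      best_ll <- ll
      best <- c(q1, 1 - q1)
    }
  }
  list(q = best, loglik = best_ll)
}

# orthogonal Procrustes superposition (translation + rotation/reflection,
# no scaling): returns the aligned X and the max coordinate discrepancy
procrustes_align <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  s <- svd(crossprod(Xc, Yc))
  R <- s$u %*% t(s$v)
  list(aligned = Xc %*% R, target = Yc,
       max_err = max(abs(Xc %*% R - Yc)))
}

# random binary tree with strictly positive branch lengths and its additive
# path-length matrix (the NJ consistency oracle)
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.1, 2))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

# memoised serial-founder preset dataset shared across test files
preset_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_polyte(serial_founder_preset(seed = 7))
    }
    cache
  }
})
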