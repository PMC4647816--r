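#' Pairwise allele-sharing distances
#'
#' The allele-sharing distance between two diploid individuals is the total
#' number of polyTE presence/absence alleles that differ between them across
#' all loci: the L1 distance on dosage vectors. The normalised variant divides
#' by the maximum attainable value, 2 x (number of loci), giving `[0, 1]`.
#'
#' @param m A [polyte_matrix()] (>= 2 samples, >= 1 locus).
#' @param normalize Divide by `2 * n_loci`?
#' @return Symmetric numeric matrix with zero diagonal, sample IDs as
#'   dimnames.
#' @export
allele_sharing_distance <- function(m, normalize = FALSE) {
  if (ncol(m) == 0) stop("dosage matrix has zero loci")
  if (nrow(m) < 2) stop("need >= 2 samples")
  d <- as.matrix(stats::dist(unclass(m), method = "manhattan"))
  if (normalize) d <- d / (2 * ncol(m))
  d
}

#' Add the hypothetical insertion-free ancestor
#'
#' The ancestral state of every polyTE locus is absence of the insertion, so
#' a hypothetical ancestral genome is the all-zero dosage vector. Appends it
#' as a pseudo-sample labelled `"ANCESTOR"`.
#'
#' @param m A [polyte_matrix()].
#' @param label Pseudo-sample label.
#' @return A [polyte_matrix()] with one extra row.
#' @export
add_ancestor <- function(m, label = "ANCESTOR") {
  x <- rbind(unclass(m), matrix(0L, 1, ncol(m), dimnames = list(label, NULL)))
  polyte_matrix(x, loci_info(m))
}

#' Population-averaged distance matrix
#'
#' Entry (P, Q) is the mean individual-level distance over pairs i in P,
#' j in Q; the diagonal is 0 (within-population pairs do not enter the
#' between-population averages), as NJ and MDS input conventions require.
#' Within-population mean pairwise distance is reported separately as
#' diversity.
#'
#' @param d Individual-level distance matrix.
#' @param panel Sample panel.
#' @param by Average over `"population"` or `"group"` labels.
#' @return List: `between` (populations x populations matrix, zero diagonal)
#'   and `within` (named vector of within-population mean pairwise distances;
#'   `NA` for strata with < 2 members).
#' @export
population_average_distances <- function(d, panel, by = c("population", "group")) {
  by <- match.arg(by)
  lab <- panel[[by]][match(rownames(d), panel$sample)]
  if (anyNA(lab)) stop("samples missing from panel")
  pops <- unique(lab)
  k <- length(pops)
  between <- matrix(0, k, k, dimnames = list(pops, pops))
  within <- stats::setNames(rep(NA_real_, k), pops)
  idx <- split(seq_len(nrow(d)), factor(lab, levels = pops))
  for (a in seq_len(k)) {
    ia <- idx[[a]]
    if (length(ia) >= 2) {
      block <- d[ia, ia, drop = FALSE]
      within[a] <- mean(block[upper.tri(block)])
    }
    for (b in seq_len(k)) {
      if (b <= a) next
      between[a, b] <- between[b, a] <- mean(d[ia, idx[[b]], drop = FALSE])
    }
  }
  list(between = between, within = within)
}

#' Within-group diversity distributions and pairwise rank-sum tests
#'
#' For each group, the multiset of within-group pairwise allele-sharing
#' distances — the package's diversity measure — and, for every group pair,
#' the two-sided Wilcoxon rank-sum p-value comparing those multisets
#' (normal approximation with continuity correction for large samples).
#'
#' @param d Individual-level distance matrix.
#' @param panel Sample panel.
#' @param by Group samples by `"group"` (default) or `"population"`.
#' @return List: `distances` (named list of numeric vectors), `medians`
#'   (named vector) and `p_values` (symmetric matrix of Wilcoxon p-values).
#' @export
diversity_distributions <- function(d, panel, by = c("group", "population")) {
  by <- match.arg(by)
  lab <- panel[[by]][match(rownames(d), panel$sample)]
  if (anyNA(lab)) stop("samples missing from panel")
  groups <- unique(lab)
  dists <- lapply(stats::setNames(groups, groups), function(g) {
    i <- which(lab == g)
    if (length(i) < 2) stop("group ", g, " has < 2 members")
    block <- d[i, i, drop = FALSE]
    block[upper.tri(block)]
  })
  k <- length(groups)
  p <- matrix(NA_real_, k, k, dimnames = list(groups, groups))
  for (a in seq_len(k - 1)) {
    for (b in (a + 1):k) {
      pv <- stats::wilcox.test(dists[[a]], dists[[b]], exact = FALSE,
                               correct = TRUE)$p.value
      # all-tied samples have zero rank variance; no evidence of a shift
      if (is.nan(pv)) pv <- 1
      p[a, b] <- p[b, a] <- pv
    }
  }
  list(distances = dists, medians = vapply(dists, stats::median, numeric(1)),
       p_values = p)
}

#' Mask a dosage matrix to one TE family
#'
#' Per-family analyses (diversity, distances, trees restricted to Alu, L1 or
#' SVA) reuse the whole-matrix code paths on a column mask.
#'
#' @param m A [polyte_matrix()].
#' @param family One of `"ALU"`, `"L1"`, `"SVA"`.
#' @export
family_subset <- function(m, family) {
  family <- match.arg(family, TE_FAMILIES)
  keep <- which(loci_info(m)$family == family)
  if (length(keep) == 0) stop("no loci of family ", family)
  subset_matrix(m, loci = keep)
}

#' Write a distance matrix as square TSV or PHYLIP
#' @param d Symmetric distance matrix with labels.
#' @param path Output path.
#' @param format `"tsv"` (labelled square TSV) or `"phylip"` (square).
#' @export
write_distance_matrix <- function(d, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = TRUE, col.names = NA)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", nrow(d)), con)
    for (i in seq_len(nrow(d))) {
      writeLines(paste(formatC(rownames(d)[i], width = -10),
                       paste(sprintf("%.6f", d[i, ]), collapse = " ")), con)
    }
  }
  invisible(path)
}
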