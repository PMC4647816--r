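#' Per-locus insertion allele frequencies
#'
#' The insertion allele frequency of a polyTE locus in a stratum is TEi/2n:
#' the number of present insertion alleles (TEi, the sum of dosages) over the
#' total number of allele copies (2n for n diploid individuals).
#'
#' @param m A [polyte_matrix()].
#' @param panel Sample panel (`sample`, `population`, `group`); may be `NULL`
#'   for `level = "overall"`.
#' @param level Stratification: `"population"`, `"group"` or `"overall"`.
#' @return Data frame with one row per (locus, stratum): `locus_id`,
#'   `stratum`, `te_count`, `n_alleles`, `freq`.
#' @export
allele_frequencies <- function(m, panel = NULL,
                               level = c("group", "population", "overall")) {
  level <- match.arg(level)
  if (level == "overall") {
    strata <- rep("overall", nrow(m))
  } else {
    panel <- align_panel(m, panel)
    strata <- if (level == "group") panel$group else panel$population
  }
  counts <- rowsum(unclass(m), strata)            # strata x loci TEi
  n <- 2L * as.integer(table(strata)[rownames(counts)])
  if (any(n == 0L)) stop("empty stratum")
  out <- data.frame(
    locus_id = rep(colnames(m), each = nrow(counts)),
    stratum = rep(rownames(counts), times = ncol(m)),
    te_count = as.vector(counts),
    n_alleles = rep(n, times = ncol(m)),
    stringsAsFactors = FALSE
  )
  out$freq <- out$te_count / out$n_alleles
  out
}

# wide loci x strata frequency matrix from allele_frequencies() output
freq_matrix <- function(freqs) {
  strata <- unique(freqs$stratum)
  loci <- unique(freqs$locus_id)
  fm <- matrix(NA_real_, length(loci), length(strata),
               dimnames = list(loci, strata))
  fm[cbind(match(freqs$locus_id, loci), match(freqs$stratum, strata))] <- freqs$freq
  fm
}

#' Unfolded allele frequency spectrum
#'
#' Histogram of per-locus insertion allele frequencies per stratum. The
#' insertion is always the derived allele (the ancestral state of a polyTE
#' locus is absence), so the spectrum needs no folding. Bins are half-open
#' `[lo, hi)`; the final bin is closed so frequency 1 is counted.
#'
#' @param freqs Output of [allele_frequencies()].
#' @param bins Increasing numeric vector of bin edges spanning `[0, 1]`.
#' @return Data frame: `stratum`, `bin_lo`, `bin_hi`, `count`.
#' @export
unfolded_sfs <- function(freqs, bins = seq(0, 1, by = 0.05)) {
  if (is.unsorted(bins, strictly = TRUE)) stop("bin edges must be increasing")
  nb <- length(bins) - 1L
  out <- lapply(split(freqs$freq, freqs$stratum), function(f) {
    idx <- findInterval(f, bins, rightmost.closed = TRUE)
    if (any(idx < 1L | idx > nb)) stop("frequency outside bin range")
    tabulate(idx, nbins = nb)
  })
  data.frame(
    stratum = rep(names(out), each = nb),
    bin_lo = rep(bins[-length(bins)], times = length(out)),
    bin_hi = rep(bins[-1], times = length(out)),
    count = unlist(out, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Sharing and exclusivity of common loci among groups
#'
#' A locus counts for a group iff its frequency there strictly exceeds
#' `threshold`; it is exclusive to a group iff it counts for exactly one.
#' Combination counts are reported over every observed group combination.
#'
#' @param fm Loci x groups frequency matrix (see [allele_frequencies()]),
#'   or its long form.
#' @param threshold Strict frequency cutoff (default 0.05, the >5\% rule).
#' @return List with `per_group` (data frame: group, above_threshold,
#'   exclusive), `combinations` (data frame: combination, count) and
#'   `threshold`.
#' @export
sharing_summary <- function(fm, threshold = 0.05) {
  if (is.data.frame(fm)) fm <- freq_matrix(fm)
  above <- fm > threshold
  n_groups <- rowSums(above)
  per_group <- data.frame(
    group = colnames(fm),
    above_threshold = colSums(above),
    exclusive = colSums(above & n_groups == 1L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  in_any <- n_groups > 0L
  combo <- apply(above[in_any, , drop = FALSE], 1, function(z) {
    paste(colnames(fm)[z], collapse = "+")
  })
  combos <- as.data.frame(table(combination = combo), stringsAsFactors = FALSE)
  names(combos)[2] <- "count"
  list(per_group = per_group, combinations = combos, threshold = threshold)
}

#' Delta ancestry-informativeness statistic
#'
#' The classical AIM statistic: the absolute allele-frequency difference
#' between two populations. For more than two groups the maximum pairwise
#' absolute difference is returned, which reduces to the two-group definition
#' and equals `max(f) - min(f)`.
#'
#' @param freqs Numeric vector of per-group frequencies for one locus (length
#'   >= 2), or a loci x groups matrix for many loci at once.
#' @return Scalar (or per-locus vector) in `[0, 1]`.
#' @export
delta_stat <- function(freqs) {
  if (is.matrix(freqs)) {
    if (ncol(freqs) < 2) stop("delta requires >= 2 groups")
    return(apply(freqs, 1, max) - apply(freqs, 1, min))
  }
  if (length(freqs) < 2) stop("delta requires >= 2 groups")
  max(freqs) - min(freqs)
}

#' Per-locus Weir-Cockerham F_ST
#'
#' The Weir & Cockerham (1984) theta-hat estimator from the variance
#' components a (among populations), b (among individuals within populations)
#' and c (within individuals), with heterozygosity taken from observed
#' heterozygote counts rather than Hardy-Weinberg expectation. Negative
#' estimates are retained. Loci monomorphic across all strata have
#' a + b + c = 0 and are returned as `NA` with `defined = FALSE`.
#'
#' @param m A [polyte_matrix()].
#' @param panel Sample panel.
#' @param strata Which panel groups (or populations) form the comparison;
#'   samples outside are dropped. Default: the three non-admixed continental
#'   groups African, Asian, European.
#' @param level `"group"` or `"population"` stratification.
#' @return Data frame: `locus_id`, `fst`, `a`, `b`, `c`, `defined`.
#' @export
weir_cockerham_fst <- function(m, panel,
                               strata = c("African", "Asian", "European"),
                               level = c("group", "population")) {
  level <- match.arg(level)
  panel <- align_panel(m, panel)
  lab <- if (level == "group") panel$group else panel$population
  keep <- lab %in% strata
  if (length(unique(lab[keep])) < 2) stop("need >= 2 strata with samples")
  x <- unclass(m)[keep, , drop = FALSE]
  lab <- lab[keep]
  if (any(table(lab) < 2)) stop("each stratum needs >= 2 samples")

  n_i <- as.vector(table(lab))                 # diploid sample sizes
  pops <- names(table(lab))
  r <- length(pops)
  te <- rowsum(x, lab)                         # r x L insertion allele counts
  p <- te / (2 * n_i)                          # r x L allele frequencies
  het <- rowsum((x == 1L) + 0L, lab) / n_i     # r x L observed het proportions

  n_bar <- mean(n_i)
  n_c <- (r * n_bar - sum(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- colSums(n_i * p) / (r * n_bar)
  s2 <- colSums(n_i * (p - rep(p_bar, each = r))^2) / ((r - 1) * n_bar)
  h_bar <- colSums(n_i * het) / (r * n_bar)

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2

  denom <- a + b + cc
  defined <- abs(denom) > .Machine$double.eps * 100
  fst <- ifelse(defined, a / denom, NA_real_)
  data.frame(locus_id = colnames(m), fst = fst, a = a, b = b, c = cc,
             defined = defined, row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the per-locus statistics table
#'
#' One row per locus: TE family, insertion allele frequency in every group,
#' three-way continental F_ST and delta (African/Asian/European by default;
#' admixed groups are excluded from the differentiation statistics, not from
#' the frequency columns).
#'
#' @param m A [polyte_matrix()].
#' @param panel Sample panel.
#' @param comparison_groups Groups entering F_ST and delta.
#' @return Data frame: `locus_id`, `chrom`, `pos`, `family`,
#'   `freq_<group>`..., `fst`, `delta`.
#' @export
locus_stats <- function(m, panel,
                        comparison_groups = c("African", "Asian", "European")) {
  freqs <- allele_frequencies(m, panel, level = "group")
  fm <- freq_matrix(freqs)
  comparison_groups <- intersect(comparison_groups, colnames(fm))
  if (length(comparison_groups) < 2) stop("need >= 2 comparison groups present")
  fst <- weir_cockerham_fst(m, panel, strata = comparison_groups)
  info <- loci_info(m)
  out <- data.frame(locus_id = info$locus_id, chrom = info$chrom,
                    pos = info$pos, family = info$family,
                    stringsAsFactors = FALSE)
  for (g in colnames(fm)) out[[paste0("freq_", g)]] <- fm[info$locus_id, g]
  out$fst <- fst$fst[match(out$locus_id, fst$locus_id)]
  out$delta <- delta_stat(fm[info$locus_id, comparison_groups, drop = FALSE])
  out
}

#' Count ancestry-informative loci above delta thresholds
#'
#' Number of loci whose delta strictly exceeds each proposed AIM cutoff
#' (classically 0.3, 0.4 and 0.5).
#'
#' @param table Output of [locus_stats()] (or any data frame with a `delta`
#'   column).
#' @param thresholds Numeric cutoffs.
#' @return Named integer vector of counts.
#' @export
aim_threshold_counts <- function(table, thresholds = c(0.3, 0.4, 0.5)) {
  d <- table$delta
  vapply(stats::setNames(thresholds, thresholds),
         function(t) sum(d > t, na.rm = TRUE), integer(1))
}
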