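#' Rank loci by F_ST into nested ancestry-informative marker subsets
#'
#' Orders loci by descending F_ST, ties broken deterministically by
#' (chromosome, position); loci with undefined F_ST are excluded. Because the
#' ranking is a fixed total order, the top-n subset is nested inside every
#' top-m subset with m > n.
#'
#' @param stats Output of [locus_stats()] (needs `locus_id`, `fst`, `chrom`,
#'   `pos`).
#' @param n_top Subset size.
#' @return Character vector of locus IDs, descending F_ST.
#' @export
rank_loci <- function(stats, n_top) {
  ok <- stats[!is.na(stats$fst), , drop = FALSE]
  if (n_top > nrow(ok)) {
    stop("n_top (", n_top, ") exceeds loci with defined F_ST (", nrow(ok), ")")
  }
  ord <- order(-ok$fst, ok$chrom, ok$pos)
  ok$locus_id[ord][seq_len(n_top)]
}

# per-individual RMSD between two q matrices (rows aligned)
q_rmsd <- function(q1, q2) sqrt(rowMeans((q1 - q2)^2))

#' Marker-subset ancestry prediction by cross-validation
#'
#' For each marker subset size: repeat an 80/20 split stratified within each
#' group; learn cluster frequencies from the 80\% training individuals;
#' estimate each 20\% test individual's ancestry fractions q over the subset
#' loci; call the individual to the argmax group iff max q >= the call
#' threshold. Accuracy is correct calls over calls made (no-calls are
#' excluded from numerator and denominator; the call rate is reported so the
#' information is not lost). Error is the mean over test individuals of the
#' RMSD between the subset-based q and the q computed from the complete
#' locus set with the same training split. Metrics are averaged over
#' replicates; the whole report is reproducible from `seed` (per-replicate
#' streams are derived deterministically from the master seed by replicate
#' index).
#'
#' @param m A [polyte_matrix()].
#' @param panel Sample panel.
#' @param groups The non-admixed strata under comparison (panel `level`
#'   labels); K = number of groups.
#' @param ranking Locus IDs in informativeness order (see [rank_loci()]);
#'   subsets are its prefixes.
#' @param subset_sizes Integer vector of subset sizes (default the
#'   500, 490, ..., 10 sweep intersected with the ranking length).
#' @param replicates Number of 80/20 replicates (default 100).
#' @param call_threshold Minimum max-q to make an ancestry call (default 0.9).
#' @param split Training fraction (default 0.8), stratified within group.
#' @param seed Master seed.
#' @param level Grouping level, `"group"` or `"population"`.
#' @param tol,max_iter EM controls.
#' @return Data frame with one row per subset size: `size`, `accuracy`,
#'   `error`, `call_rate`, `replicates`, `seed`. Per-replicate values are in
#'   `attr(, "replicates")`.
#' @export
ancestry_cv <- function(m, panel, groups, ranking,
                        subset_sizes = seq(500, 10, by = -10),
                        replicates = 100, call_threshold = 0.9, split = 0.8,
                        seed = 1, level = c("group", "population"),
                        tol = 1e-6, max_iter = 500) {
  level <- match.arg(level)
  subset_sizes <- subset_sizes[subset_sizes <= length(ranking)]
  if (length(subset_sizes) == 0) stop("no subset size fits the ranking")
  pan <- align_panel(m, panel)
  lab <- stats::setNames(pan[[level]], pan$sample)
  members <- lapply(stats::setNames(groups, groups),
                    function(g) names(lab)[lab == g])
  n_train <- vapply(members, function(s) floor(split * length(s)), numeric(1))
  if (any(n_train < 1) || any(vapply(members, length, numeric(1)) - n_train < 1)) {
    stop("a group is too small for a stratified ", split, " split")
  }

  rep_seeds <- seed + seq_len(replicates)          # derived per-replicate streams
  per_rep <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    train <- unlist(lapply(groups, function(g) {
      sample(members[[g]], n_train[[g]])
    }), use.names = FALSE)
    test <- setdiff(unlist(members, use.names = FALSE), train)
    truth <- lab[test]

    # one training fit per replicate: subsets are column masks of it, and
    # the complete-locus-set q (the "actual" inference) shares its F
    F_train <- train_F(m, lab, groups, train)
    F_all <- F_train
    class(F_all) <- c("ancestral_freqs", "matrix")
    q_full <- estimate_q(unclass(m)[test, , drop = FALSE], F_all,
                         tol = tol, max_iter = max_iter)$q

    res <- lapply(subset_sizes, function(sz) {
      sub <- ranking[seq_len(sz)]
      Fs <- F_train[, sub, drop = FALSE]
      class(Fs) <- c("ancestral_freqs", "matrix")
      q_sub <- estimate_q(unclass(m)[test, sub, drop = FALSE], Fs,
                          tol = tol, max_iter = max_iter)$q
      called <- apply(q_sub, 1, max) >= call_threshold
      pred <- groups[apply(q_sub, 1, which.max)]
      acc <- if (any(called)) mean(pred[called] == truth[called]) else NA_real_
      data.frame(size = sz, accuracy = acc,
                 error = mean(q_rmsd(q_sub, q_full)),
                 call_rate = mean(called))
    })
    per_rep[[r]] <- do.call(rbind, res)
    per_rep[[r]]$replicate <- r
  }
  all_rep <- do.call(rbind, per_rep)
  agg <- do.call(rbind, lapply(split(all_rep, all_rep$size), function(x) {
    data.frame(size = x$size[1],
               accuracy = mean(x$accuracy, na.rm = TRUE),
               error = mean(x$error),
               call_rate = mean(x$call_rate))
  }))
  agg <- agg[order(-agg$size), , drop = FALSE]
  rownames(agg) <- NULL
  agg$replicates <- replicates
  agg$seed <- seed
  attr(agg, "replicates") <- all_rep
  agg
}

# full-set training fit shared by the 80% split: F over all loci, aligned
# to `groups` row order
train_F <- function(m, lab, groups, samples) {
  F_mat <- estimate_ancestral_frequencies(subset_matrix(m, samples = samples),
                                          lab[samples])
  unclass(F_mat)[groups, , drop = FALSE]
}

#' Admixture prediction error for marker subsets
#'
#' Trains the supervised model on complete reference groups (no split: the
#' paper's admixed-target design has disjoint reference and target sets by
#' construction), estimates target ancestry fractions from the full locus set
#' and from each ranked subset, and reports the RMSD between subset-based and
#' full-set-based fractions over the named ancestry components, averaged over
#' target individuals, plus the Pearson correlation of component fractions
#' between the two runs.
#'
#' @param m A [polyte_matrix()].
#' @param panel Sample panel.
#' @param reference_groups The K ancestral clusters (panel groups).
#' @param target_group Panel population or group naming the admixed targets.
#' @param ranking Locus IDs in informativeness order.
#' @param subset_sizes Sizes to evaluate.
#' @param level Level at which `target_group` is resolved
#'   (`"population"` or `"group"`).
#' @param tol,max_iter EM controls.
#' @return Data frame: `size`, `rmsd`, `cor` (`cor` is the correlation of the
#'   first component's fractions across targets between subset and full run;
#'   with K = 2 the second component is its mirror image).
#' @export
admixture_prediction_error <- function(m, panel, reference_groups, target_group,
                                       ranking,
                                       subset_sizes = seq(500, 10, by = -10),
                                       level = c("population", "group"),
                                       tol = 1e-6, max_iter = 500) {
  level <- match.arg(level)
  pan <- align_panel(m, panel)
  targets <- pan$sample[pan[[level]] == target_group]
  if (length(targets) == 0) stop("target group is empty: ", target_group)
  subset_sizes <- subset_sizes[subset_sizes <= length(ranking)]

  fit_full <- supervised_admixture(m, panel, reference_groups, targets,
                                   tol = tol, max_iter = max_iter)
  q_full <- fit_full$q
  out <- lapply(subset_sizes, function(sz) {
    sub <- ranking[seq_len(sz)]
    q_sub <- supervised_admixture(m, panel, reference_groups, targets,
                                  marker_subset = sub, tol = tol,
                                  max_iter = max_iter)$q
    data.frame(size = sz,
               rmsd = mean(q_rmsd(q_sub, q_full)),
               cor = stats::cor(q_sub[, 1], q_full[, 1]))
  })
  res <- do.call(rbind, out)
  attr(res, "q_full") <- q_full
  res
}
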