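#' Ancestral cluster allele frequencies from labelled references
#'
#' Supervised admixture phase 1: each ancestral cluster's insertion allele
#' frequency at each locus is the observed TEi/2n among its labelled
#' reference individuals, clamped into `[epsilon, 1 - epsilon]` so the
#' binomial log-likelihood stays finite at monomorphic loci.
#'
#' @param m A [polyte_matrix()] restricted to reference samples.
#' @param labels Named character vector: sample -> cluster; every matrix
#'   sample must be labelled with exactly one cluster.
#' @param epsilon Frequency clamp (default 1e-4).
#' @return K x L matrix of class `ancestral_freqs` (clusters x loci).
#' @export
estimate_ancestral_frequencies <- function(m, labels, epsilon = 1e-4) {
  lab <- labels[rownames(m)]
  if (anyNA(lab)) stop("unlabelled reference sample(s)")
  n_k <- table(lab)
  if (any(n_k == 0)) stop("empty cluster")
  te <- rowsum(unclass(m), as.character(lab))
  f <- te / (2 * as.vector(n_k[rownames(te)]))
  f <- pmin(pmax(f, epsilon), 1 - epsilon)
  structure(f, class = c("ancestral_freqs", "matrix"))
}

#' Ancestry fractions by maximum likelihood (EM)
#'
#' Estimates each individual's ancestry fraction vector q over K fixed
#' ancestral clusters under the unlinked binomial admixture model
#' g_l ~ Binomial(2, p_l) with p_l = sum_k q_k f_kl, by EM on the simplex
#' from uniform initialisation (deterministic; no randomness involved).
#' The log-likelihood is non-decreasing across iterations, which is asserted.
#'
#' @param g Dosage vector for one individual, or an N x L matrix for many
#'   (rows are individuals); loci must match the columns of `F_mat`.
#' @param F_mat K x L `ancestral_freqs` matrix.
#' @param tol Convergence threshold on the log-likelihood improvement
#'   (default 1e-7).
#' @param max_iter Iteration cap (default 2000).
#' @return List: `q` (N x K matrix on the simplex), `loglik` (per
#'   individual), `iterations`, `converged`, `identifiable` (`FALSE` when the
#'   cluster frequencies are identical at every locus, leaving the likelihood
#'   flat in q).
#' @export
estimate_q <- function(g, F_mat, tol = 1e-7, max_iter = 2000) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)
  g <- unclass(g)
  storage.mode(g) <- "double"
  F_mat <- unclass(F_mat)
  K <- nrow(F_mat); L <- ncol(F_mat); N <- nrow(g)
  if (ncol(g) != L) stop("locus sets of g and F differ")
  if (any(F_mat <= 0 | F_mat >= 1)) {
    stop("cluster frequencies must be clamped inside (0, 1)")
  }
  identifiable <- K == 1 ||
    max(apply(F_mat, 2, max) - apply(F_mat, 2, min)) > 1e-12
  if (!identifiable) warning("identical cluster frequencies at every locus; q is unidentifiable")

  Q <- matrix(1 / K, N, K)
  tF <- t(F_mat)                       # L x K
  tG <- t(1 - F_mat)
  ll_of <- function(P) rowSums(g * log(P) + (2 - g) * log(1 - P))
  P <- Q %*% F_mat
  ll <- ll_of(P)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    # E-step responsibilities folded into the simplex update:
    # q_k <- (1/2L) sum_l [ g_l q_k f_kl / p_l + (2-g_l) q_k (1-f_kl)/(1-p_l) ]
    A <- (g / P) %*% tF          # N x K
    B <- ((2 - g) / (1 - P)) %*% tG
    Q <- Q * (A + B) / (2 * L)
    Q <- Q / rowSums(Q)
    P <- Q %*% F_mat
    ll_new <- ll_of(P)
    if (any(!is.finite(ll_new))) stop("non-finite log-likelihood in EM")
    if (any(ll_new < ll - 1e-8 * (abs(ll) + 1))) {
      stop("EM log-likelihood decreased; numerical failure")
    }
    if (max(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  rn <- rownames(g)
  dimnames(Q) <- list(rn, rownames(F_mat))
  list(q = Q, loglik = stats::setNames(ll, rn), iterations = iter,
       converged = converged, identifiable = identifiable)
}

#' Supervised admixture estimation
#'
#' Two-phase supervised admixture: ancestral cluster frequencies are learned
#' from labelled reference individuals by closed form
#' ([estimate_ancestral_frequencies()]), then each target individual's
#' ancestry fractions are estimated by EM with those frequencies fixed
#' ([estimate_q()]). Reference and target sample sets must be disjoint.
#'
#' @param m A [polyte_matrix()] holding references and targets.
#' @param panel Sample panel.
#' @param reference_groups Panel groups (or populations, see `level`) whose
#'   members serve as the K labelled ancestral clusters.
#' @param target_samples Sample IDs to estimate q for.
#' @param marker_subset Optional locus IDs restricting the analysis.
#' @param level Reference labelling from `"group"` or `"population"`.
#' @param epsilon,tol,max_iter Passed to the two phases.
#' @return List as from [estimate_q()], plus `F` (the fitted cluster
#'   frequencies) and `clusters`.
#' @export
supervised_admixture <- function(m, panel, reference_groups, target_samples,
                                 marker_subset = NULL,
                                 level = c("group", "population"),
                                 epsilon = 1e-4, tol = 1e-7, max_iter = 2000) {
  level <- match.arg(level)
  if (!is.null(marker_subset)) {
    if (length(marker_subset) == 0) stop("marker subset is empty")
    m <- subset_matrix(m, loci = marker_subset)
  }
  pan <- align_panel(m, panel)
  lab <- stats::setNames(pan[[level]], pan$sample)
  refs <- names(lab)[lab %in% reference_groups]
  if (length(intersect(refs, target_samples)) > 0) {
    stop("reference and target sample sets overlap")
  }
  F_mat <- estimate_ancestral_frequencies(
    subset_matrix(m, samples = refs), lab[refs], epsilon = epsilon)
  F_mat <- unclass(F_mat)[reference_groups, , drop = FALSE]
  class(F_mat) <- c("ancestral_freqs", "matrix")
  fit <- estimate_q(unclass(m)[target_samples, , drop = FALSE], F_mat,
                    tol = tol, max_iter = max_iter)
  fit$F <- F_mat
  fit$clusters <- reference_groups
  fit
}

#' Write ancestry fractions in ADMIXTURE Q-file layout
#'
#' Whitespace-delimited K columns, one row per target individual, no header.
#'
#' @param q N x K ancestry fraction matrix.
#' @param path Output path.
#' @export
write_q_matrix <- function(q, path) {
  utils::write.table(format(q, digits = 6, scientific = FALSE), path,
                     sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
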