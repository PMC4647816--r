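#' Simulation configuration for polyTE-like cohorts
#'
#' Describes a synthetic polyTE dataset: the low-frequency-skewed insertion
#' allele spectrum, continental-group-exclusive loci, per-group drift away
#' from the ancestral frequency (serial-founder bottlenecks), population
#' substructure within groups, and admixed cohorts with Dirichlet-distributed
#' ancestry fractions generating binomial genotypes.
#'
#' The base frequency law is a mixture: with probability `freq_law$w_low` the
#' ancestral frequency is Beta(`shape1`, `shape2`) concentrated near zero
#' (the rare-insertion class), otherwise Uniform(`common_min`, `common_max`)
#' (the common class). Group frequencies drift from the ancestral frequency
#' under the Balding-Nichols Beta model: non-founder groups first share one
#' out-of-Africa bottleneck (`ooa_drift`), then each group drifts by its own
#' residual `drift` (larger drift = stronger bottleneck = lower diversity);
#' populations within a group drift again by `pop_drift`.
#'
#' @param n_loci Number of polyTE loci.
#' @param family_mix Named proportions over ALU, L1, SVA (must sum to 1).
#' @param groups Data frame with columns `name`, `n_populations`,
#'   `n_individuals_each`, `drift` — the non-admixed ancestral groups.
#' @param freq_law List: `w_low`, `shape1`, `shape2`, `common_min`,
#'   `common_max`, and optionally `w_low_exclusive` (the rare-class weight
#'   applied to group-private loci; defaults to `w_low`).
#' @param exclusive_fraction Named vector (by group) of the fraction of loci
#'   structurally private to that group; must sum to < 1.
#' @param pop_drift Within-group population-level drift.
#' @param founder_group The group that keeps drawing from the ancestral
#'   frequency pool (default: the first group). All other groups descend
#'   from a single shared bottlenecked pool, so they cluster together and
#'   the deepest divergence in the data is founder vs rest — the
#'   serial-founder topology.
#' @param ooa_drift Drift of the shared out-of-Africa pool that all
#'   non-founder groups descend from.
#' @param admixed_cohorts List of lists, each with `name` (population code),
#'   `n` and `alpha` (named Dirichlet concentration over source groups).
#'   Admixed cohorts are assigned to continental group `"American"`.
#' @param seed Master seed; recorded in the output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_loci = 2000,
                              family_mix = c(ALU = 0.79, L1 = 0.16, SVA = 0.05),
                              groups = data.frame(
                                name = c("African", "European", "Asian"),
                                n_populations = c(2, 2, 2),
                                n_individuals_each = c(50, 50, 50),
                                drift = c(0.005, 0.015, 0.08)),
                              freq_law = list(w_low = 0.98, shape1 = 0.3,
                                              shape2 = 40, common_min = 0.05,
                                              common_max = 0.45,
                                              w_low_exclusive = 0.92),
                              exclusive_fraction = c(African = 0.15,
                                                     European = 0.05,
                                                     Asian = 0.05),
                              pop_drift = 0.01,
                              founder_group = NULL,
                              ooa_drift = 0.05,
                              admixed_cohorts = list(),
                              seed = 42) {
  if (is.null(founder_group)) founder_group <- groups$name[1]
  stopifnot(abs(sum(family_mix) - 1) < 1e-8,
            all(names(family_mix) %in% TE_FAMILIES),
            n_loci > 0, all(groups$n_populations > 0),
            all(groups$n_individuals_each > 0))
  if (sum(exclusive_fraction) >= 1) {
    stop("exclusive fractions must sum to < 1")
  }
  if (!all(names(exclusive_fraction) %in% groups$name)) {
    stop("exclusive_fraction names must be simulated groups")
  }
  for (ac in admixed_cohorts) {
    if (!all(names(ac$alpha) %in% groups$name)) {
      stop("admixed cohort ", ac$name, " draws on unknown source groups")
    }
  }
  structure(list(n_loci = n_loci, family_mix = family_mix, groups = groups,
                 freq_law = freq_law, exclusive_fraction = exclusive_fraction,
                 pop_drift = pop_drift, founder_group = founder_group,
                 ooa_drift = ooa_drift, admixed_cohorts = admixed_cohorts,
                 seed = seed),
            class = "simulation_config")
}

#' Serial-founder preset configuration
#'
#' The packaged study conditions: an African-like group at highest diversity
#' (weakest drift), bottlenecked European-like and Asian-like groups, three
#' ancestral groups of 2 populations x 50 individuals over 2,000 loci, a
#' two-way admixed African/European cohort (ASW-like, Dirichlet alpha 12:3,
#' i.e. 80/20 mean ancestry) and a three-way admixed Latino-like cohort
#' (alpha African 3 : European 8 : Asian 5, the Asian pole standing in for
#' Native American ancestry).
#'
#' @param seed Master seed.
#' @param n_loci Number of loci (default 2000).
#' @return A [simulation_config()].
#' @export
serial_founder_preset <- function(seed = 42, n_loci = 2000) {
  simulation_config(
    n_loci = n_loci,
    admixed_cohorts = list(
      list(name = "ASW_SIM", n = 30, alpha = c(African = 12, European = 3)),
      list(name = "LAT_SIM", n = 30,
           alpha = c(African = 3, European = 8, Asian = 5))
    ),
    seed = seed
  )
}

# Balding-Nichols drift: child frequency ~ Beta(f(1-F)/F, (1-f)(1-F)/F);
# F -> 0 returns f unchanged, fixed alleles stay fixed
bn_drift <- function(f, F_drift) {
  if (F_drift <= 0) return(f)
  lam <- (1 - F_drift) / F_drift
  out <- f
  seg <- f > 0 & f < 1
  out[seg] <- stats::rbeta(sum(seg), f[seg] * lam, (1 - f[seg]) * lam)
  out
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  sw <- x / rowSums(x)
  colnames(sw) <- names(alpha)
  sw
}

#' Simulate a polyTE cohort with full ground truth
#'
#' Draws ancestral insertion frequencies from the skewed law, assigns
#' exclusive loci to single groups (zero frequency elsewhere), drifts
#' frequencies per group and per population, and generates genotypes:
#' non-admixed individuals as Binomial(2, f_pop,l), admixed individuals as
#' Binomial(2, sum_k q_k f_k,l) with q ~ Dirichlet(alpha). Output is
#' bit-reproducible from `config$seed`. Optionally writes a
#' mobile-element-insertion VCF, a panel TSV, ground-truth tables and a JSON
#' echo of the configuration.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory for VCF/panel/truth files.
#' @return List: `matrix` (a [polyte_matrix()]), `panel`, `group_map`,
#'   `truth` (list: `ancestral_freq`, `group_freqs`, `pop_freqs`,
#'   `exclusive_group`, `q_true`), `config`, and `paths` when `dir` is given.
#' @export
simulate_polyte <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$n_loci
  fam <- sample(names(config$family_mix), L, replace = TRUE,
                prob = config$family_mix)
  chrom <- sample(paste0("chr", 1:22), L, replace = TRUE)
  pos <- integer(L)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- sort(sample.int(2e8, length(i)))
  }
  loci <- data.frame(chrom = chrom, pos = pos, family = fam,
                     locus_id = paste(chrom, pos, fam, sep = ":"),
                     stringsAsFactors = FALSE)

  ex <- config$exclusive_fraction
  excl_group <- sample(c(names(ex), NA), L, replace = TRUE,
                       prob = c(ex, 1 - sum(ex)))

  # group-private loci reflect polymorphism arisen (or retained) after the
  # group split, so they carry more common-class mass than the shared pool
  fl <- config$freq_law
  w_ex <- if (is.null(fl$w_low_exclusive)) fl$w_low else fl$w_low_exclusive
  w <- ifelse(is.na(excl_group), fl$w_low, w_ex)
  is_low <- stats::runif(L) < w
  f_anc <- ifelse(is_low,
                  stats::rbeta(L, fl$shape1, fl$shape2),
                  stats::runif(L, fl$common_min, fl$common_max))

  gnames <- config$groups$name
  # serial-founder structure: non-founder groups descend from one shared
  # out-of-Africa bottleneck pool, so they cluster together and the deepest
  # divergence is founder vs rest
  f_ooa <- bn_drift(f_anc, config$ooa_drift)
  group_freqs <- matrix(0, L, length(gnames), dimnames = list(loci$locus_id, gnames))
  for (gi in seq_along(gnames)) {
    g <- gnames[gi]
    pool <- if (g == config$founder_group) f_anc else f_ooa
    active <- is.na(excl_group) | excl_group == g
    fg <- numeric(L)
    fg[active] <- bn_drift(pool[active], config$groups$drift[gi])
    group_freqs[, gi] <- fg
  }

  pops <- character(0); pop_group <- character(0)
  pop_freqs <- NULL
  for (gi in seq_along(gnames)) {
    for (pi in seq_len(config$groups$n_populations[gi])) {
      pcode <- sprintf("%s%d", toupper(substr(gnames[gi], 1, 3)), pi)
      pops <- c(pops, pcode); pop_group <- c(pop_group, gnames[gi])
      pf <- bn_drift(group_freqs[, gi], config$pop_drift)
      pf[group_freqs[, gi] == 0] <- 0      # exclusivity survives drift
      pop_freqs <- cbind(pop_freqs, pf)
    }
  }
  colnames(pop_freqs) <- pops
  rownames(pop_freqs) <- loci$locus_id

  samples <- character(0); sample_pop <- character(0)
  dosage <- NULL
  for (pi in seq_along(pops)) {
    gi <- match(pop_group[pi], gnames)
    n <- config$groups$n_individuals_each[gi]
    ids <- sprintf("%s_%03d", pops[pi], seq_len(n))
    g <- matrix(stats::rbinom(n * L, 2, rep(pop_freqs[, pi], each = n)), n, L)
    dosage <- rbind(dosage, g)
    samples <- c(samples, ids); sample_pop <- c(sample_pop, rep(pops[pi], n))
  }

  q_true <- NULL
  for (ac in config$admixed_cohorts) {
    q <- rdirichlet(ac$n, ac$alpha)
    p <- q %*% t(group_freqs[, names(ac$alpha), drop = FALSE])   # n x L
    g <- matrix(stats::rbinom(ac$n * L, 2, t(p)), ac$n, L, byrow = TRUE)
    ids <- sprintf("%s_%03d", ac$name, seq_len(ac$n))
    dosage <- rbind(dosage, g)
    samples <- c(samples, ids); sample_pop <- c(sample_pop, rep(ac$name, ac$n))
    qq <- matrix(0, ac$n, length(gnames), dimnames = list(ids, gnames))
    qq[, names(ac$alpha)] <- q
    q_true <- rbind(q_true, qq)
    pops <- c(pops, ac$name); pop_group <- c(pop_group, "American")
  }

  rownames(dosage) <- samples
  m <- polyte_matrix(dosage, loci)
  group_map <- stats::setNames(pop_group, pops)
  panel <- data.frame(sample = samples, population = sample_pop,
                      group = unname(group_map[sample_pop]),
                      stringsAsFactors = FALSE)
  truth <- list(ancestral_freq = stats::setNames(f_anc, loci$locus_id),
                group_freqs = group_freqs, pop_freqs = pop_freqs,
                exclusive_group = stats::setNames(excl_group, loci$locus_id),
                q_true = q_true)
  out <- list(matrix = m, panel = panel, group_map = group_map,
              truth = truth, config = config)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(vcf = file.path(dir, "polyte_sim.vcf"),
                  panel = file.path(dir, "panel.tsv"),
                  pop_freqs = file.path(dir, "true_pop_freqs.tsv"),
                  q_true = file.path(dir, "true_q.tsv"),
                  config = file.path(dir, "config.json"))
    write_mei_vcf(m, paths$vcf)
    write_panel(panel, paths$panel)
    utils::write.table(data.frame(locus_id = rownames(pop_freqs),
                                  round(pop_freqs, 6)),
                       paths$pop_freqs, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(q_true)) {
      utils::write.table(data.frame(sample = rownames(q_true),
                                    round(q_true, 6)),
                         paths$q_true, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    cfg <- unclass(config)
    cfg$groups <- as.list(config$groups)
    jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)
    out$paths <- paths
  }
  out
}

#' Write a dosage matrix as a mobile-element-insertion VCF
#'
#' Emits VCF 4.2 with the 1000 Genomes MEI dialect (symbolic ALT alleles
#' `<INS:ME:ALU>`, `<INS:ME:LINE1>`, `<INS:ME:SVA>`), closing the round trip
#' with [read_mei_vcf()]. Dosage 1 is written as the phased heterozygote
#' `0|1`.
#'
#' @param m A [polyte_matrix()].
#' @param path Output path.
#' @export
write_mei_vcf <- function(m, path) {
  info <- loci_info(m)
  alt_of <- c(ALU = "<INS:ME:ALU>", L1 = "<INS:ME:LINE1>", SVA = "<INS:ME:SVA>")
  gt_of <- c("0|0", "0|1", "1|1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=polyTE_simulate",
    "##ALT=<ID=INS:ME:ALU,Description=\"Insertion of ALU element\">",
    "##ALT=<ID=INS:ME:LINE1,Description=\"Insertion of LINE1 element\">",
    "##ALT=<ID=INS:ME:SVA,Description=\"Insertion of SVA element\">",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=MEINFO,Number=4,Type=String,Description=\"Mobile element info\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(m)), collapse = "\t")
  ), con)
  gt <- matrix(gt_of[unclass(m) + 1L], nrow(m), ncol(m))
  for (j in seq_len(ncol(m))) {
    writeLines(paste(c(info$chrom[j], info$pos[j], info$locus_id[j], "A",
                       alt_of[[info$family[j]]], ".", "PASS",
                       paste0("SVTYPE=", info$family[j]), "GT", gt[, j]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write a sample panel TSV
#' @param panel Data frame with `sample`, `population`, `group`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  out <- data.frame(sample = panel$sample, pop = panel$population,
                    super_pop = panel$group)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
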