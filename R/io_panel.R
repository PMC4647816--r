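#' Construct a polyTE dosage matrix
#'
#' The universal substrate of the package: an integer matrix of insertion
#' allele dosages in \{0, 1, 2\} with samples as rows and loci as columns,
#' carrying a locus annotation table (chromosome, position, TE family).
#'
#' @param dosage Integer matrix, samples x loci, entries in \{0, 1, 2\}.
#'   Row names are sample IDs; column names are locus IDs.
#' @param loci Data frame with columns `chrom`, `pos`, `family`, `locus_id`,
#'   one row per matrix column, in column order. `family` must be one of
#'   `"ALU"`, `"L1"`, `"SVA"`. If `NULL`, a minimal table is built from the
#'   matrix column names.
#' @return A `polyte_matrix`: the dosage matrix with the locus table attached
#'   as the `"loci"` attribute.
#' @export
polyte_matrix <- function(dosage, loci = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) {
    stop("dosage matrix must have sample IDs as row names")
  }
  if (anyNA(dosage)) stop("dosage matrix contains missing entries")
  if (any(dosage < 0L | dosage > 2L)) stop("dosages must lie in {0, 1, 2}")
  if (is.null(loci)) {
    ids <- colnames(dosage)
    if (is.null(ids)) ids <- paste0("L", seq_len(ncol(dosage)))
    loci <- data.frame(chrom = NA_character_, pos = NA_integer_,
                       family = NA_character_, locus_id = ids,
                       stringsAsFactors = FALSE)
  }
  stopifnot(nrow(loci) == ncol(dosage))
  if (anyDuplicated(loci$locus_id)) stop("locus IDs must be unique")
  if (!all(is.na(loci$family) | loci$family %in% TE_FAMILIES)) {
    stop("TE family must be one of ", paste(TE_FAMILIES, collapse = ", "))
  }
  colnames(dosage) <- loci$locus_id
  structure(dosage, loci = loci, class = c("polyte_matrix", class(dosage)))
}

#' The three active human TE families
#' @export
TE_FAMILIES <- c("ALU", "L1", "SVA")

#' Locus annotation of a dosage matrix
#' @param m A `polyte_matrix`.
#' @return Data frame with columns `chrom`, `pos`, `family`, `locus_id`.
#' @export
loci_info <- function(m) attr(m, "loci")

#' Subset a dosage matrix by loci and/or samples
#'
#' Keeps the locus annotation in step with the matrix columns; plain `[`
#' indexing would drop it.
#'
#' @param m A `polyte_matrix`.
#' @param samples Sample IDs or indices (default all).
#' @param loci Locus IDs or column indices (default all).
#' @export
subset_matrix <- function(m, samples = NULL, loci = NULL) {
  info <- loci_info(m)
  if (is.null(samples)) samples <- rownames(m)
  if (is.null(loci)) {
    j <- seq_len(ncol(m))
  } else if (is.character(loci)) {
    j <- match(loci, info$locus_id)
    if (anyNA(j)) stop("unknown locus IDs: ", paste(loci[is.na(j)], collapse = ", "))
  } else {
    j <- loci
  }
  polyte_matrix(unclass(m)[samples, j, drop = FALSE], info[j, , drop = FALSE])
}

# Map a VCF ALT / INFO description to a TE family label, or NA.
# The 1000 Genomes MEI dialect writes symbolic ALT alleles <INS:ME:ALU>,
# <INS:ME:LINE1>, <INS:ME:SVA>; other dialects put the subtype in INFO
# (e.g. MEINFO=AluYa5,...). Both are scanned.
classify_te_family <- function(alt, info = "") {
  x <- toupper(paste(alt, info, sep = ";"))
  if (grepl("ALU", x)) return("ALU")
  if (grepl("LINE1|\\bL1\\b|:L1\\b|ME:L1|SVTYPE=L1", x) || grepl("INS:ME:L1", x)) return("L1")
  if (grepl("SVA", x)) return("SVA")
  NA_character_
}

#' Read mobile-element-insertion genotypes from a VCF
#'
#' Loads diploid presence/absence genotypes at polymorphic TE insertion loci
#' and converts them to insertion-allele dosages (count of ALT alleles per
#' genotype; any ALT allele counts as insertion presence). Phasing is ignored.
#' Records whose TE family cannot be recognised from the ALT symbolic allele
#' or INFO field are skipped with a reported count.
#'
#' @param vcf_path Path to a VCF 4.x file (plain or bgzipped).
#' @param family_filter Character vector of TE families to retain
#'   (default all of `ALU`, `L1`, `SVA`).
#' @param missing One of `"error"` (default: a missing genotype is a hard
#'   error naming the offending record) or `"zero"` (treat missing as
#'   ancestral absence, dosage 0).
#' @return A [polyte_matrix()] with locus order as in the file.
#' @export
read_mei_vcf <- function(vcf_path, family_filter = TE_FAMILIES,
                         missing = c("error", "zero")) {
  missing <- match.arg(missing)
  if (!file.exists(vcf_path)) stop("VCF not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info <- vcf@fix[, "INFO"]
  info[is.na(info)] <- ""
  fam <- mapply(classify_te_family, fix[, "ALT"], info, USE.NAMES = FALSE)
  n_unclassified <- sum(is.na(fam))
  if (n_unclassified > 0) {
    message("read_mei_vcf: skipped ", n_unclassified,
            " record(s) with unrecognised variant class")
  }
  keep <- !is.na(fam) & fam %in% family_filter
  if (!any(keep)) stop("no records match family filter ",
                       paste(family_filter, collapse = ","))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  fam <- fam[keep]

  # dosage = number of non-reference alleles in the GT string ("0|1" -> 1);
  # multi-allelic records collapse to presence of any insertion allele
  dos <- gt_to_dosage(gt, missing = missing)
  loci <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    family = fam,
    locus_id = paste(fix[, "CHROM"], fix[, "POS"], fam, sep = ":"),
    stringsAsFactors = FALSE
  )
  polyte_matrix(t(dos), loci)
}

# loci x samples GT character matrix -> integer dosage matrix
gt_to_dosage <- function(gt, missing = "error") {
  alleles <- gsub("[|/]", "", gt)
  miss <- is.na(gt) | grepl("\\.", alleles)
  if (any(miss)) {
    if (missing == "error") {
      idx <- which(miss, arr.ind = TRUE)[1, ]
      stop("missing genotype at record ", rownames(gt)[idx[1]],
           ", sample ", colnames(gt)[idx[2]])
    }
    alleles[miss] <- "00"
  }
  dos <- nchar(alleles) - nchar(gsub("[1-9]", "", alleles))
  dos <- matrix(as.integer(dos), nrow = nrow(gt), dimnames = dimnames(gt))
  if (any(dos > 2L)) stop("genotype ploidy exceeds 2")
  dos
}

#' Default population to continental-group map
#'
#' The 26 human populations of the 1000 Genomes Phase3 panel organised into
#' five continental groups: African, Asian (East Asian populations), European,
#' Indian (South Asian populations) and American (admixed populations of the
#' Americas, including the African-American ASW/ACB).
#'
#' @return Named character vector, population code -> group name.
#' @export
default_group_map <- function() {
  c(ESN = "African", GWD = "African", LWK = "African", MSL = "African",
    YRI = "African",
    CDX = "Asian", CHB = "Asian", CHS = "Asian", JPT = "Asian", KHV = "Asian",
    CEU = "European", FIN = "European", GBR = "European", IBS = "European",
    TSI = "European",
    BEB = "Indian", GIH = "Indian", ITU = "Indian", PJL = "Indian",
    STU = "Indian",
    ACB = "American", ASW = "American", CLM = "American", MXL = "American",
    PEL = "American", PUR = "American")
}

#' Read a sample panel
#'
#' Maps each sample to a population and a continental group. The panel file is
#' a TSV with columns `sample` and `pop` (a `super_pop` column, if present, is
#' ignored in favour of `group_map`).
#'
#' @param panel_path Path to the panel TSV.
#' @param group_map Named character vector population -> group;
#'   defaults to [default_group_map()].
#' @return Data frame with columns `sample`, `population`, `group`.
#' @export
read_panel <- function(panel_path, group_map = default_group_map()) {
  tab <- utils::read.table(panel_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(tab))
  s_col <- which(nm %in% c("sample", "sample_id", "id"))[1]
  p_col <- which(nm %in% c("pop", "population"))[1]
  if (is.na(s_col) || is.na(p_col)) {
    stop("panel must have 'sample' and 'pop' columns")
  }
  pops <- tab[[p_col]]
  unknown <- setdiff(unique(pops), names(group_map))
  if (length(unknown) > 0) {
    stop("population(s) absent from group map: ", paste(unknown, collapse = ", "))
  }
  panel <- data.frame(sample = tab[[s_col]], population = pops,
                      group = unname(group_map[pops]), stringsAsFactors = FALSE)
  if (anyDuplicated(panel$sample)) stop("duplicate sample IDs in panel")
  panel
}

# Check every matrix sample has exactly one panel entry; return panel rows
# aligned to the matrix sample order.
align_panel <- function(m, panel) {
  i <- match(rownames(m), panel$sample)
  if (anyNA(i)) {
    stop("samples missing from panel: ",
         paste(rownames(m)[is.na(i)][1:min(5, sum(is.na(i)))], collapse = ", "))
  }
  panel[i, , drop = FALSE]
}

#' Write a per-locus statistics table
#'
#' Serialises a locus statistics table (family, per-group frequencies, F_ST,
#' delta) as a TSV with numeric columns at 6 decimal digits; the round trip
#' through [read_locus_stats()] is lossless at that precision.
#'
#' @param table Data frame as produced by [locus_stats()].
#' @param path Output path.
#' @export
write_locus_stats <- function(table, path) {
  out <- table
  num <- vapply(out, is.numeric, logical(1)) & names(out) != "pos"
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), "NA", sprintf("%.6f", x))
  })
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-locus statistics table written by [write_locus_stats()]
#' @param path Path to the TSV.
#' @export
read_locus_stats <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}
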