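# Signed LD matrices, greedy clumping, and multicollinearity screening.

#' Construct a signed LD matrix
#'
#' Stores pairwise signed Pearson correlations (r, not r-squared) between
#' effect-allele dosages: the GLS covariance needs the signs, while clumping
#' squares them. Symmetry, a unit diagonal and entries in \[-1, 1\] are
#' enforced.
#'
#' @param r Square numeric matrix of signed correlations.
#' @param variant_ids Variant ids, in matrix order.
#' @param panel_label Label of the reference panel (ancestry is a label only).
#' @param panel_n Reference-panel sample size, if known.
#' @param ea Optional per-variant effect (counted) allele of the panel
#'   dosages, used by [harmonize()] to align signs.
#' @return An `ld_matrix` object (a matrix with attributes).
#' @export
ld_matrix <- function(r, variant_ids, panel_label = "unknown", panel_n = NA_integer_,
                      ea = NULL) {
  r <- as.matrix(r)
  m <- length(variant_ids)
  if (nrow(r) != m || ncol(r) != m) {
    cismr_error("LD matrix dimensions do not match variant count", "cismr_config_error")
  }
  if (max(abs(r - t(r))) > 1e-8) cismr_error("LD matrix not symmetric", "cismr_config_error")
  r <- (r + t(r)) / 2
  if (any(abs(r) > 1 + 1e-8)) cismr_error("LD entries must lie in [-1, 1]", "cismr_config_error")
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  dimnames(r) <- list(variant_ids, variant_ids)
  structure(r, panel_label = panel_label, panel_n = panel_n, ea = ea,
            class = c("ld_matrix", "matrix", "array"))
}

ld_variant_ids <- function(ld) rownames(ld)

unclass_ld <- function(ld) {
  attributes(ld)[c("panel_label", "panel_n", "ea", "class")] <- NULL
  ld
}

#' Subset an LD matrix to a set of variants
#'
#' @param ld An `ld_matrix`.
#' @param ids Variant ids to keep (must all be present).
#' @return An `ld_matrix` on the requested variants, in the requested order.
#' @export
subset_ld <- function(ld, ids) {
  stopifnot(inherits(ld, "ld_matrix"))
  missing <- setdiff(ids, rownames(ld))
  if (length(missing)) {
    cismr_error(paste0("variant(s) absent from LD matrix: ",
                       paste(missing, collapse = ", ")), "cismr_config_error")
  }
  idx <- match(ids, rownames(ld))
  ea <- attr(ld, "ea")
  ld_matrix(unclass_ld(ld)[idx, idx, drop = FALSE], ids,
            panel_label = attr(ld, "panel_label"), panel_n = attr(ld, "panel_n"),
            ea = if (!is.null(ea)) ea[idx])
}

#' Compute a signed LD matrix from reference-panel dosages
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns;
#'   entries in \[0, 2\] counting copies of the effect allele.
#' @param variant_ids Variant ids (default: column names).
#' @param panel_label Panel label.
#' @param ea Optional effect-allele vector recorded on the result.
#' @return An `ld_matrix` with `panel_n = nrow(dosages)`.
#' @export
ld_from_genotypes <- function(dosages, variant_ids = colnames(dosages),
                              panel_label = "genotype-panel", ea = NULL) {
  dosages <- as.matrix(dosages)
  if (nrow(dosages) < 2L) cismr_error("need >= 2 panel samples", "cismr_config_error")
  if (is.null(variant_ids)) cismr_error("variant ids required", "cismr_config_error")
  v <- apply(dosages, 2L, stats::var)
  if (any(v == 0)) {
    cismr_error(paste0("monomorphic variant(s) in panel: ",
                       paste(variant_ids[v == 0], collapse = ", ")),
                "cismr_monomorphic")
  }
  r <- stats::cor(dosages)
  ld_matrix(r, variant_ids, panel_label = panel_label, panel_n = nrow(dosages),
            ea = ea)
}

#' Read a precomputed LD matrix from a square TSV
#'
#' Expects a header row of variant ids and a leading id column.
#'
#' @param path Path to the TSV.
#' @param panel_label,panel_n Panel metadata.
#' @return An `ld_matrix`.
#' @export
read_ld_tsv <- function(path, panel_label = basename(path), panel_n = NA_integer_) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  r <- as.matrix(df[, -1, drop = FALSE])
  if (!identical(colnames(r), ids)) {
    cismr_error("LD TSV row and column ids disagree", "cismr_config_error")
  }
  ld_matrix(r, ids, panel_label = panel_label, panel_n = panel_n)
}

#' Read a genotype dosage matrix from TSV
#'
#' Plain matrix format: header of variant ids, one row per sample.
#'
#' @param path Path to the TSV.
#' @return Numeric dosage matrix with variant ids as column names.
#' @export
read_panel_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  as.matrix(df)
}

#' Read dosages from a VCF reference panel
#'
#' Converts GT fields to alternate-allele dosages; the counted (effect)
#' allele is the ALT allele, recorded so [harmonize()] can align signs.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF.
#' @return List with `dosages` (samples x variants) and `ea` (ALT alleles).
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    cismr_error("reading VCF panels requires the vcfR package", "cismr_config_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(g) {
    ifelse(is.na(g), NA_real_,
           vapply(strsplit(g, "[/|]"), function(a) sum(a == "1"), numeric(1)))
  }
  dos <- apply(gt, c(1, 2), count_alt)
  ids <- vcfR::getID(v)
  ids[is.na(ids)] <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))[is.na(ids)]
  dos <- t(dos)
  colnames(dos) <- ids
  list(dosages = dos, ea = vcfR::getALT(v))
}

#' Greedy LD clumping
#'
#' Repeatedly takes the smallest-p unassigned variant as a sentinel and
#' assigns to it every unassigned variant with `r^2 >= r2_threshold`, until
#' all variants are assigned. Ties on p are broken by position, then by id,
#' so output is deterministic.
#'
#' @param stats A `summary_stats` object supplying the p-values for ranking.
#' @param ld An `ld_matrix` covering all variants in `stats`.
#' @param r2_threshold r-squared at or above which variants join a sentinel's
#'   block, in (0, 1].
#' @return A `clump_result`: list with `retained_ids` (sentinels in p order),
#'   `block_assignment` (named character vector variant -> sentinel) and
#'   `r2_threshold`.
#' @export
clump <- function(stats, ld, r2_threshold) {
  stopifnot(inherits(stats, "summary_stats"))
  if (r2_threshold <= 0 || r2_threshold > 1) {
    cismr_error("r2_threshold must be in (0, 1]", "cismr_config_error")
  }
  ids <- stats$SNP
  ldm <- subset_ld(ld, ids)  # errors listing missing ids
  r2 <- unclass_ld(ldm)^2
  ord <- order(stats$P, stats$POS, stats$SNP)
  assigned <- rep(NA_character_, length(ids))
  names(assigned) <- ids
  retained <- character()
  for (i in ord) {
    if (!is.na(assigned[i])) next
    sentinel <- ids[i]
    members <- which(is.na(assigned) & r2[i, ] >= r2_threshold)
    assigned[members] <- sentinel
    assigned[i] <- sentinel
    retained <- c(retained, sentinel)
  }
  structure(list(retained_ids = retained, block_assignment = assigned,
                 r2_threshold = r2_threshold),
            class = "clump_result")
}

#' Screen a harmonised input for multicollinearity
#'
#' When the LD matrix's condition number exceeds `condition_limit` (or a
#' Cholesky factorisation fails), iteratively removes the single variant
#' whose removal most improves the condition number, preferring
#' lower-MAF variants among near-ties (low-MAF variants are where panel LD is
#' least stable). Removal stops once the matrix is acceptable and is capped
#' at half the variants.
#'
#' @param input A `harmonized_input`.
#' @param condition_limit Maximum acceptable condition number (default 1e8).
#' @param maf Optional per-variant minor allele frequencies; defaults to the
#'   frequencies stored on the input.
#' @param tie_tol Relative closeness within which candidate removals count as
#'   tied (default 0.05).
#' @return List with `input` (possibly reduced), and `diagnostics`
#'   (`condition_before`, `condition_after`, `removed`).
#' @export
collinearity_screen <- function(input, condition_limit = 1e8, maf = NULL,
                                tie_tol = 0.05) {
  stopifnot(inherits(input, "harmonized_input"))
  if (is.null(maf)) maf <- pmin(input$eaf, 1 - input$eaf)
  cur <- input
  cond0 <- condition_number(unclass_ld(cur$ld))
  cond <- cond0
  removed <- character()
  max_remove <- floor(length(input$variant_ids) / 2)
  while (cond > condition_limit) {
    if (length(removed) >= max_remove || length(cur$variant_ids) <= 1L) {
      cismr_error(sprintf(
        "collinearity_screen: condition number %.3g still above %g after removing %d variants",
        cond, condition_limit, length(removed)), "cismr_multicollinearity")
    }
    r <- unclass_ld(cur$ld)
    J <- nrow(r)
    conds <- vapply(seq_len(J), function(j) condition_number(r[-j, -j, drop = FALSE]),
                    numeric(1))
    best <- min(conds)
    cand <- which(conds <= best * (1 + tie_tol) | (is.infinite(best) & is.infinite(conds)))
    mafs <- maf[match(cur$variant_ids, input$variant_ids)][cand]
    pick <- if (all(is.na(mafs))) cand[1] else cand[which.min(replace(mafs, is.na(mafs), Inf))]
    removed <- c(removed, cur$variant_ids[pick])
    cur <- subset_input(cur, cur$variant_ids[-pick])
    cond <- condition_number(unclass_ld(cur$ld))
  }
  list(input = cur,
       diagnostics = list(condition_before = cond0, condition_after = cond,
                          removed = removed))
}
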