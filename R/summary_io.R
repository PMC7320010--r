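# Reading, validating and harmonising GWAS summary statistics.

#' Canonical summary-statistic column names
#'
#' The canonical dialect used throughout the package: `SNP`, `CHR`, `POS`,
#' `EA` (effect allele), `OA` (other allele), `EAF`, `BETA`, `SE`, `P`, `N`.
#' A dialect passed to [read_summary_stats()] is a named character vector
#' mapping these canonical names to the column names found in a file.
#'
#' @return Named character vector (identity mapping).
#' @export
canonical_dialect <- function() {
  nm <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  stats::setNames(nm, nm)
}

#' Construct a summary-statistic set
#'
#' Validates a data frame of per-variant GWAS associations and tags it with
#' trait metadata. Rows violating the per-variant invariants (`se > 0`,
#' `effect_allele != other_allele`, `eaf` in \[0, 1\] when present, `p` in
#' (0, 1\], `position >= 1`) are dropped with a message; duplicated variant
#' ids are dropped beyond the first occurrence. Missing p-values are
#' recomputed from `beta`/`se` under the standard normal (they are only used
#' for ranking in clumping). Records are sorted by (chromosome, position).
#'
#' @param df Data frame with canonical columns (see [canonical_dialect()];
#'   `EAF`, `P`, `N` optional).
#' @param trait_label Character label for the trait.
#' @param trait_scale One of `"linear"`, `"log_odds"`, `"log_scale"`.
#' @param genome_build Genome build tag (e.g. `"GRCh37"`).
#' @return A `summary_stats` object: a data frame with columns
#'   `SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N` and attributes
#'   `trait_label`, `trait_scale`, `genome_build`, `n_dropped`.
#' @export
summary_stats <- function(df, trait_label = "trait",
                          trait_scale = c("linear", "log_odds", "log_scale"),
                          genome_build = "GRCh37") {
  trait_scale <- match.arg(trait_scale)
  req <- c("SNP", "CHR", "POS", "EA", "OA", "BETA", "SE")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    cismr_error(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
                "cismr_config_error")
  }
  for (opt in c("EAF", "P", "N")) if (!opt %in% names(df)) df[[opt]] <- NA_real_
  df <- df[c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")]
  df$SNP <- as.character(df$SNP)
  df$CHR <- as.character(df$CHR)
  df$POS <- as.integer(df$POS)
  df$EA <- toupper(as.character(df$EA))
  df$OA <- toupper(as.character(df$OA))
  for (num in c("EAF", "BETA", "SE", "P", "N")) df[[num]] <- as.numeric(df[[num]])

  n0 <- nrow(df)
  valid_allele <- function(a) grepl("^[ACGT]+$", a)
  keep <- !is.na(df$SNP) & !is.na(df$POS) & df$POS >= 1L &
    valid_allele(df$EA) & valid_allele(df$OA) & df$EA != df$OA &
    !is.na(df$BETA) & !is.na(df$SE) & df$SE > 0 &
    (is.na(df$EAF) | (df$EAF >= 0 & df$EAF <= 1)) &
    (is.na(df$P) | (df$P >= 0 & df$P <= 1))
  df <- df[keep, , drop = FALSE]
  dup <- duplicated(df$SNP)
  df <- df[!dup, , drop = FALSE]
  n_dropped <- n0 - nrow(df)
  if (n_dropped > 0) {
    message(sprintf("summary_stats: dropped %d invalid or duplicated row(s) for '%s'",
                    n_dropped, trait_label))
  }
  if (nrow(df) == 0L) cismr_error("no valid summary-statistic rows", "cismr_empty_input")
  df$P[is.na(df$P)] <- z_pvalue(df$BETA[is.na(df$P)], df$SE[is.na(df$P)])
  # underflowed p-values (printed as 0) are common for strong associations;
  # p is only used for ranking, so clamp rather than drop
  df$P[df$P == 0] <- .Machine$double.xmin
  df <- df[order(df$CHR, df$POS, df$SNP), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            trait_label = trait_label, trait_scale = trait_scale,
            genome_build = genome_build, n_dropped = n_dropped,
            class = c("summary_stats", "data.frame"))
}

#' Read GWAS summary statistics from delimited text
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Named character vector mapping canonical column names
#'   (see [canonical_dialect()]) to the file's column names; defaults to the
#'   canonical names themselves.
#' @param sep Field separator (default tab).
#' @inheritParams summary_stats
#' @return A `summary_stats` object.
#' @export
read_summary_stats <- function(path, dialect = canonical_dialect(), sep = "\t",
                               trait_label = basename(path),
                               trait_scale = c("linear", "log_odds", "log_scale"),
                               genome_build = "GRCh37") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  full <- canonical_dialect()
  full[names(dialect)] <- dialect
  req <- c("SNP", "CHR", "POS", "EA", "OA", "BETA", "SE")
  miss <- req[!full[req] %in% names(raw)]
  if (length(miss)) {
    cismr_error(paste0("column(s) not found in ", path, ": ",
                       paste(full[miss], collapse = ", ")), "cismr_config_error")
  }
  cols <- lapply(names(full), function(canon) {
    if (full[[canon]] %in% names(raw)) raw[[full[[canon]]]] else NA
  })
  df <- do.call(data.frame, c(stats::setNames(cols, names(full)),
                              list(stringsAsFactors = FALSE)))
  summary_stats(df, trait_label = trait_label, trait_scale = trait_scale,
                genome_build = genome_build)
}

#' Define a gene region
#'
#' Coordinates are 1-based and inclusive on both ends; the effective
#' interval is `[start - flank, end + flank]`, clipped at 1.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome label.
#' @param start,end 1-based inclusive interval.
#' @param flank Flank in base pairs added on each side (default 2500,
#'   the conventional cis window for biomarker-weighted analyses).
#' @return A `region` object.
#' @export
region <- function(gene_id, chromosome, start, end, flank = 2500) {
  if (start > end) cismr_error("region start > end", "cismr_config_error")
  if (flank < 0) cismr_error("flank must be >= 0", "cismr_config_error")
  structure(list(gene_id = as.character(gene_id),
                 chromosome = as.character(chromosome),
                 start = as.integer(start), end = as.integer(end),
                 flank = as.integer(flank)),
            class = "region")
}

#' Read gene regions from a BED file
#'
#' BED intervals are 0-based, half-open; they are converted to the 1-based
#' closed convention used internally (`start + 1`, `end`).
#'
#' @param path Path to a 4+-column BED file (chrom, start, end, name).
#' @param flank Flank in base pairs applied to every region.
#' @return List of `region` objects named by gene id.
#' @export
read_regions_bed <- function(path, flank = 2500) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) cismr_error("BED file needs >= 4 columns", "cismr_config_error")
  out <- lapply(seq_len(nrow(bed)), function(i) {
    region(gene_id = bed[i, 4], chromosome = bed[i, 1],
           start = as.integer(bed[i, 2]) + 1L, end = as.integer(bed[i, 3]),
           flank = flank)
  })
  stats::setNames(out, vapply(out, `[[`, "", "gene_id"))
}

#' Extract variants in a region, filtering on minor allele frequency
#'
#' Retains variants with position inside `[start - flank, end + flank]`
#' (both ends inclusive) and `min(eaf, 1 - eaf) > maf_min`. Variants lacking
#' an allele frequency are dropped (with a warning) when `maf_min > 0`,
#' since the filter cannot be verified for them, and kept when
#' `maf_min = 0`.
#'
#' @param stats A `summary_stats` object.
#' @param reg A `region` object.
#' @param maf_min Minor-allele-frequency lower bound (default 0.01).
#' @return Filtered `summary_stats` (order preserved).
#' @export
extract_region <- function(stats, reg, maf_min = 0.01) {
  stopifnot(inherits(stats, "summary_stats"), inherits(reg, "region"))
  lo <- max(1L, reg$start - reg$flank)
  hi <- reg$end + reg$flank
  keep <- stats$CHR == reg$chromosome & stats$POS >= lo & stats$POS <= hi
  out <- stats[keep, , drop = FALSE]
  if (maf_min > 0) {
    no_eaf <- is.na(out$EAF)
    if (any(no_eaf)) {
      warning(sprintf("extract_region: dropped %d variant(s) lacking EAF under maf_min = %g",
                      sum(no_eaf), maf_min))
    }
    maf <- pmin(out$EAF, 1 - out$EAF)
    out <- out[!no_eaf & maf > maf_min, , drop = FALSE]
  }
  rownames(out) <- NULL
  attributes(out)[c("trait_label", "trait_scale", "genome_build")] <-
    attributes(stats)[c("trait_label", "trait_scale", "genome_build")]
  class(out) <- class(stats)
  out
}

#' Construct a harmonised estimator input directly
#'
#' Low-level constructor used by [harmonize()] and by the simulation engine
#' (whose outputs are aligned by construction). All vectors must share the
#' ordering of `variant_ids`, and the LD matrix must be allele-aligned to
#' `beta_exposure`'s effect alleles.
#'
#' @param variant_ids Character vector of variant ids.
#' @param beta_exposure,se_exposure Exposure association estimates / SEs.
#' @param beta_outcome,se_outcome Outcome association estimates / SEs.
#' @param ld `ld_matrix` on the same variants (any order; subset internally).
#' @param exposure_type One of `"protein"`, `"biomarker"`, `"expression"`.
#' @param outcome_scale Scale of the outcome betas (`"log_odds"` for
#'   case-control outcomes, `"linear"` otherwise).
#' @param eaf Optional effect-allele frequencies (used by MAF-aware steps).
#' @param provenance Optional data frame logging harmonisation actions.
#' @return A `harmonized_input` object.
#' @export
harmonized_input <- function(variant_ids, beta_exposure, se_exposure,
                             beta_outcome, se_outcome, ld,
                             exposure_type = c("protein", "biomarker", "expression"),
                             outcome_scale = "linear",
                             eaf = NULL, provenance = NULL) {
  exposure_type <- match.arg(exposure_type)
  J <- length(variant_ids)
  stopifnot(length(beta_exposure) == J, length(se_exposure) == J,
            length(beta_outcome) == J, length(se_outcome) == J)
  if (any(se_exposure <= 0) || any(se_outcome <= 0)) {
    cismr_error("all standard errors must be > 0", "cismr_config_error")
  }
  ld <- subset_ld(ld, variant_ids)
  structure(list(variant_ids = as.character(variant_ids),
                 beta_exposure = as.numeric(beta_exposure),
                 se_exposure = as.numeric(se_exposure),
                 beta_outcome = as.numeric(beta_outcome),
                 se_outcome = as.numeric(se_outcome),
                 ld = ld,
                 exposure_type = exposure_type,
                 outcome_scale = outcome_scale,
                 eaf = if (is.null(eaf)) rep(NA_real_, J) else as.numeric(eaf),
                 provenance = provenance %||%
                   data.frame(variant_id = character(), action = character(),
                              note = character())),
            class = "harmonized_input")
}

#' @export
print.harmonized_input <- function(x, ...) {
  cat(sprintf("harmonized_input: %d variants, exposure_type = %s, outcome_scale = %s\n",
              length(x$variant_ids), x$exposure_type, x$outcome_scale))
  invisible(x)
}

#' Subset a harmonised input to a set of variants
#'
#' @param input A `harmonized_input`.
#' @param ids Variant ids (or integer indices) to keep, in input order.
#' @return A `harmonized_input` on the retained variants.
#' @export
subset_input <- function(input, ids) {
  idx <- if (is.character(ids)) match(ids, input$variant_ids) else ids
  if (anyNA(idx)) cismr_error("unknown variant id(s) in subset_input", "cismr_config_error")
  idx <- sort(idx)
  harmonized_input(input$variant_ids[idx],
                   input$beta_exposure[idx], input$se_exposure[idx],
                   input$beta_outcome[idx], input$se_outcome[idx],
                   subset_ld(input$ld, input$variant_ids[idx]),
                   exposure_type = input$exposure_type,
                   outcome_scale = input$outcome_scale,
                   eaf = input$eaf[idx], provenance = input$provenance)
}

#' Harmonise exposure and outcome summary statistics with an LD matrix
#'
#' Intersects the variant sets, re-expresses the outcome associations on the
#' exposure's effect allele (flipping beta signs and allele frequencies where
#' the outcome is coded on the other allele, including across a strand flip),
#' aligns the LD matrix's allele orientation where the panel records effect
#' alleles, and drops strand-ambiguous (A/T, C/G) variants whose allele
#' frequency is too close to 0.5 to resolve the strand. Every action is
#' recorded in the provenance log.
#'
#' Variant identity is matched on id first, then on chromosome:position with
#' a matching allele set; ambiguous position matches are dropped.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param ld `ld_matrix` covering (at least) the shared variants.
#' @param palindrome_eaf_band Drop palindromic variants whose minor allele
#'   frequency is at or above this value (default 0.42); palindromic
#'   variants with missing frequency are always dropped.
#' @param exposure_type Exposure position in the causal chain (`"protein"`,
#'   `"biomarker"` or `"expression"`); recorded for estimand interpretation.
#' @return A `harmonized_input`.
#' @export
harmonize <- function(exposure, outcome, ld, palindrome_eaf_band = 0.42,
                      exposure_type = c("protein", "biomarker", "expression")) {
  exposure_type <- match.arg(exposure_type)
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))

  prov <- list()
  note <- function(id, action, msg = "") {
    prov[[length(prov) + 1L]] <<- data.frame(variant_id = id, action = action,
                                             note = msg)
  }

  # -- match outcome rows to exposure rows: id first, chr:pos + allele set next
  om <- match(exposure$SNP, outcome$SNP)
  unmatched <- which(is.na(om))
  if (length(unmatched)) {
    okey <- paste(outcome$CHR, outcome$POS, sep = ":")
    ekey <- paste(exposure$CHR, exposure$POS, sep = ":")
    for (i in unmatched) {
      hits <- which(okey == ekey[i])
      hits <- hits[vapply(hits, function(h) {
        setequal(c(outcome$EA[h], outcome$OA[h]), c(exposure$EA[i], exposure$OA[i])) ||
          setequal(c(allele_complement(outcome$EA[h]), allele_complement(outcome$OA[h])),
                   c(exposure$EA[i], exposure$OA[i]))
      }, logical(1))]
      if (length(hits) == 1L) {
        om[i] <- hits
        note(exposure$SNP[i], "position_match", outcome$SNP[hits])
      } else if (length(hits) > 1L) {
        note(exposure$SNP[i], "dropped", "ambiguous position match")
      }
    }
  }
  keep <- !is.na(om)
  if (!any(keep)) cismr_error("no overlapping variants after matching", "cismr_empty_input")

  ids <- exposure$SNP[keep]
  ex <- exposure[keep, , drop = FALSE]
  ou <- outcome[om[keep], , drop = FALSE]

  # -- allele alignment of the outcome onto the exposure effect allele
  bx <- ex$BETA; sx <- ex$SE
  by <- ou$BETA; sy <- ou$SE
  eaf <- ex$EAF
  drop <- logical(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    ea1 <- ex$EA[i]; oa1 <- ex$OA[i]
    ea2 <- ou$EA[i]; oa2 <- ou$OA[i]
    if (ea2 == ea1 && oa2 == oa1) {
      # aligned
    } else if (ea2 == oa1 && oa2 == ea1) {
      by[i] <- -by[i]
      note(ids[i], "flip_outcome", "outcome coded on other allele")
    } else if (allele_complement(ea2) == ea1 && allele_complement(oa2) == oa1) {
      note(ids[i], "strand_flip", "outcome on opposite strand")
    } else if (allele_complement(ea2) == oa1 && allele_complement(oa2) == ea1) {
      by[i] <- -by[i]
      note(ids[i], "strand_flip_and_flip", "opposite strand, other allele")
    } else {
      drop[i] <- TRUE
      note(ids[i], "dropped", sprintf("irreconcilable alleles %s/%s vs %s/%s",
                                      ea1, oa1, ea2, oa2))
      next
    }
    if (is_palindromic(ea1, oa1)) {
      f <- if (!is.na(eaf[i])) eaf[i] else ou$EAF[i]
      if (is.na(f) || min(f, 1 - f) >= palindrome_eaf_band) {
        drop[i] <- TRUE
        note(ids[i], "dropped", "palindromic with uninformative allele frequency")
      }
    }
  }

  # -- LD availability and allele orientation of the panel
  ld_ids <- ld_variant_ids(ld)
  absent <- !(ids %in% ld_ids)
  for (i in which(absent & !drop)) note(ids[i], "dropped", "absent from LD matrix")
  drop <- drop | absent

  ids2 <- ids[!drop]
  if (!length(ids2)) cismr_error("no variants survived harmonisation", "cismr_empty_input")
  ldm <- subset_ld(ld, ids2)
  panel_ea <- attr(ldm, "ea")
  if (!is.null(panel_ea)) {
    ex2 <- ex[!drop, , drop = FALSE]
    sgn <- rep(1, length(ids2))
    for (i in seq_along(ids2)) {
      pa <- panel_ea[[i]]
      if (is.na(pa) || pa == ex2$EA[i] || allele_complement(pa) == ex2$EA[i]) next
      if (pa == ex2$OA[i] || allele_complement(pa) == ex2$OA[i]) {
        sgn[i] <- -1
        note(ids2[i], "ld_sign_flip", "panel dosage counts the other allele")
      }
    }
    if (any(sgn < 0)) {
      r <- unclass_ld(ldm) * outer(sgn, sgn)
      diag(r) <- 1
      ldm <- ld_matrix(r, ids2, panel_label = attr(ldm, "panel_label"),
                       panel_n = attr(ldm, "panel_n"),
                       ea = ifelse(sgn < 0, ex[!drop, , drop = FALSE]$EA, panel_ea))
    }
  }

  prov_df <- if (length(prov)) do.call(rbind, prov) else
    data.frame(variant_id = character(), action = character(), note = character())

  harmonized_input(ids2,
                   bx[!drop], sx[!drop], by[!drop], sy[!drop], ldm,
                   exposure_type = exposure_type,
                   outcome_scale = attr(outcome, "trait_scale") %||% "linear",
                   eaf = eaf[!drop], provenance = prov_df)
}

#' Read a variant consequence annotation table
#'
#' @param path TSV with columns `variant_id`, `consequence`, and optionally
#'   `is_enhancer`.
#' @param vocabulary Severity-ordered consequence vocabulary (most severe
#'   first); defaults to [consequence_severity()].
#' @return An `annotation_table` data frame with a `severity_rank` column.
#' @export
read_annotations <- function(path, vocabulary = consequence_severity()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  annotation_table(df, vocabulary)
}

#' @rdname read_annotations
#' @param df Data frame with columns `variant_id` and `consequence`.
#' @export
annotation_table <- function(df, vocabulary = consequence_severity()) {
  if (!all(c("variant_id", "consequence") %in% names(df))) {
    cismr_error("annotation table needs variant_id and consequence columns",
                "cismr_config_error")
  }
  bad <- setdiff(unique(df$consequence), vocabulary)
  if (length(bad)) {
    cismr_error(paste0("consequence term(s) outside vocabulary: ",
                       paste(bad, collapse = ", ")), "cismr_config_error")
  }
  if (!"is_enhancer" %in% names(df)) df$is_enhancer <- FALSE
  df$severity_rank <- match(df$consequence, vocabulary)
  structure(df, vocabulary = vocabulary,
            class = c("annotation_table", "data.frame"))
}

#' Severity-ordered consequence vocabulary
#'
#' The standard variant-effect ontology ranking (most severe first), read
#' from the package's data file; override by passing any character vector of
#' terms in decreasing severity.
#'
#' @return Character vector of consequence terms.
#' @export
consequence_severity <- function() {
  path <- system.file("extdata", "consequence_severity.tsv", package = "cismr")
  utils::read.delim(path, stringsAsFactors = FALSE)$consequence
}
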