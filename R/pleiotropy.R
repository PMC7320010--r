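# Sequential non-target-gene pruning: an empirical screen for LD-based
# horizontal pleiotropy. A cis variant may associate, through LD, with the
# expression (or product) of a neighbouring gene; pruning such variants at
# increasingly liberal p-value thresholds and watching the estimate reveals
# associations that depend on potentially pleiotropic variants.

#' Read a non-target association table
#'
#' @param path TSV with columns `variant_id`, `gene_id`, `p` and optionally
#'   `tissue`, `gene_chr`, `gene_start`, `gene_end`.
#' @return A validated data frame.
#' @export
read_nontarget_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  nontarget_table(df)
}

#' @rdname read_nontarget_table
#' @param df Data frame with at least `variant_id`, `gene_id`, `p`.
#' @export
nontarget_table <- function(df) {
  need <- c("variant_id", "gene_id", "p")
  if (!all(need %in% names(df))) {
    cismr_error("non-target table needs variant_id, gene_id, p columns",
                "cismr_config_error")
  }
  if (any(is.na(df$p) | df$p <= 0 | df$p > 1)) {
    cismr_error("non-target p-values must lie in (0, 1]", "cismr_config_error")
  }
  if (!"tissue" %in% names(df)) df[["tissue"]] <- rep(NA_character_, nrow(df))
  structure(df, class = c("nontarget_table", "data.frame"))
}

#' Sequentially prune variants associated with non-target genes
#'
#' For each p-value threshold `t` (default `1e-8 ... 1e-3`), removes every
#' variant whose smallest association p-value with any non-target gene
#' (within `neighbour_flank` of the target locus, when gene coordinates are
#' supplied) is below `t`, then re-clumps, re-screens and re-estimates on
#' the survivors. Pruning precedes re-clumping, so sentinels are re-chosen
#' among the surviving variants. Retained sets are monotone: a more liberal
#' removal threshold retains a subset of a stricter one's set (asserted on
#' every run). A threshold that prunes everything yields a flagged point.
#'
#' @param input A `harmonized_input`.
#' @param table A `nontarget_table` (per-tissue screening: filter the table
#'   first).
#' @param thresholds Ascending removal p-value thresholds.
#' @param neighbour_flank Neighbour window in bp around the target region
#'   (default 1e6); applied only when the table carries gene coordinates
#'   and `target_region` is given.
#' @param target_region Optional `region` locating the target gene.
#' @param clump_r2 Optional r-squared for re-clumping survivors (NULL skips).
#' @param estimator,effects_mode Estimator used per threshold.
#' @return A `prune_result`: data frame `points` (one row per threshold) and
#'   list `retained` of surviving variant ids per threshold.
#' @export
prune_nontarget <- function(input, table,
                            thresholds = 10^seq(-8, -3),
                            neighbour_flank = 1e6, target_region = NULL,
                            clump_r2 = NULL,
                            estimator = "gls_ivw", effects_mode = "fixed") {
  stopifnot(inherits(input, "harmonized_input"))
  table <- nontarget_table(table)
  if (is.unsorted(thresholds, strictly = TRUE)) {
    cismr_error("thresholds must be strictly ascending", "cismr_config_error")
  }
  if (!is.null(target_region) &&
      all(c("gene_chr", "gene_start", "gene_end") %in% names(table))) {
    lo <- target_region$start - neighbour_flank
    hi <- target_region$end + neighbour_flank
    keep <- table$gene_chr == target_region$chromosome &
      table$gene_end >= lo & table$gene_start <= hi
    table <- table[keep, , drop = FALSE]
  }
  if (!is.null(target_region)) {
    table <- table[table$gene_id != target_region$gene_id, , drop = FALSE]
  }

  # a variant is pruned on its minimum non-target p across genes/tissues
  min_p <- tapply(table$p, table$variant_id, min)
  min_p_of <- function(id) {
    v <- min_p[id]
    ifelse(is.na(v), 1, v)
  }
  vp <- min_p_of(input$variant_ids)

  retained <- list()
  pts <- vector("list", length(thresholds))
  for (k in seq_along(thresholds)) {
    t <- thresholds[k]
    keep_ids <- input$variant_ids[vp >= t]
    retained[[k]] <- keep_ids
    pts[[k]] <- if (length(keep_ids) == 0L) {
      data.frame(threshold = t, n_variants = 0L, estimate = NA_real_,
                 se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p = NA_real_, flag = "all variants pruned",
                 stringsAsFactors = FALSE)
    } else {
      tryCatch({
        sub <- subset_input(input, keep_ids)
        if (!is.null(clump_r2)) {
          cl <- clump(ranking_stats(sub), sub$ld, clump_r2)
          sub <- subset_input(sub, cl$retained_ids)
        }
        scr <- collinearity_screen(sub)
        fit <- estimator_fun(estimator)(scr$input, effects_mode)
        data.frame(threshold = t, n_variants = length(scr$input$variant_ids),
                   estimate = fit$estimate, se = fit$se,
                   ci_low = fit$ci_low, ci_high = fit$ci_high, p = fit$p,
                   flag = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(threshold = t, n_variants = length(keep_ids),
                   estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, p = NA_real_,
                   flag = conditionMessage(e), stringsAsFactors = FALSE)
      })
    }
  }
  # monotone-retention invariant: more liberal removal keeps a subset
  for (k in seq_along(thresholds)[-1]) {
    stopifnot(all(retained[[k]] %in% retained[[k - 1]]))
  }
  structure(list(points = do.call(rbind, pts), retained = retained,
                 thresholds = thresholds),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat("prune_result across non-target p thresholds:\n")
  print(x$points, row.names = FALSE)
  invisible(x)
}
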