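# Instrument-selection strategies: clumping-threshold and region-size grid
# searches, random-subset stability experiments, and stratification of
# subset estimates by functional consequence.

estimator_fun <- function(name) {
  switch(name,
         gls_ivw = gls_ivw,
         gls_egger = gls_egger,
         cismr_error(paste0("unknown estimator: ", name), "cismr_config_error"))
}

# Internal: p-values for ranking derived from the exposure betas (the
# clumping design decision: stored p is trusted when present, recomputed
# from beta/se otherwise).
ranking_stats <- function(input, stats_for_ranking = NULL) {
  if (!is.null(stats_for_ranking)) {
    return(stats_for_ranking[match(input$variant_ids, stats_for_ranking$SNP), ,
                             drop = FALSE])
  }
  df <- data.frame(SNP = input$variant_ids, CHR = "0",
                   POS = seq_along(input$variant_ids),
                   EA = "A", OA = "G", EAF = input$eaf,
                   BETA = input$beta_exposure, SE = input$se_exposure,
                   P = z_pvalue(input$beta_exposure, input$se_exposure),
                   N = NA_real_)
  suppressMessages(summary_stats(df, trait_label = "ranking", trait_scale = "linear"))
}

one_grid_point <- function(input, value, clump_stats, r2_threshold,
                           estimator, effects_mode, condition_limit) {
  res <- tryCatch({
    keep_stats <- clump_stats[clump_stats$SNP %in% input$variant_ids, , drop = FALSE]
    cl <- clump(keep_stats, input$ld, r2_threshold)
    sub <- subset_input(input, cl$retained_ids)
    scr <- collinearity_screen(sub, condition_limit = condition_limit)
    fit <- estimator_fun(estimator)(scr$input, effects_mode)
    list(fit = fit, n = length(scr$input$variant_ids),
         removed = scr$diagnostics$removed, flag = NA_character_)
  }, error = function(e) {
    list(fit = NULL, n = NA_integer_, removed = character(),
         flag = conditionMessage(e))
  })
  data.frame(axis_value = value,
             n_variants = res$n,
             estimate = if (is.null(res$fit)) NA_real_ else res$fit$estimate,
             se = if (is.null(res$fit)) NA_real_ else res$fit$se,
             ci_low = if (is.null(res$fit)) NA_real_ else res$fit$ci_low,
             ci_high = if (is.null(res$fit)) NA_real_ else res$fit$ci_high,
             p = if (is.null(res$fit)) NA_real_ else res$fit$p,
             intercept = if (is.null(res$fit)) NA_real_ else res$fit$intercept,
             n_screened_out = length(res$removed),
             flag = res$flag,
             stringsAsFactors = FALSE)
}

#' Grid search over LD-clumping thresholds
#'
#' For each r-squared threshold: clump, screen for multicollinearity, and
#' estimate. Per-point failures (e.g. irreducible multicollinearity at
#' liberal thresholds) are recorded as flagged points, not raised — a
#' flagged point is itself informative about where the model breaks down.
#'
#' @param input A `harmonized_input` on the full candidate variant set.
#' @param thresholds Increasing r-squared thresholds, each in (0, 1];
#'   default `seq(0.1, 0.9, by = 0.1)`.
#' @param stats_for_ranking Optional `summary_stats` supplying clumping
#'   p-values; by default they are recomputed from the exposure betas.
#' @param estimator `"gls_ivw"` or `"gls_egger"`.
#' @param effects_mode Passed to the estimator.
#' @param condition_limit Passed to [collinearity_screen()].
#' @return A `grid_result`: list with `axis = "r2_threshold"`, `points`
#'   (one row per threshold) and `chosen_index` (NA until
#'   [select_threshold()] is applied).
#' @export
grid_search_r2 <- function(input, thresholds = seq(0.1, 0.9, by = 0.1),
                           stats_for_ranking = NULL,
                           estimator = "gls_ivw", effects_mode = "fixed",
                           condition_limit = 1e8) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    cismr_error("thresholds must be strictly increasing", "cismr_config_error")
  }
  if (any(thresholds <= 0 | thresholds > 1)) {
    cismr_error("thresholds must lie in (0, 1]", "cismr_config_error")
  }
  clump_stats <- ranking_stats(input, stats_for_ranking)
  pts <- do.call(rbind, lapply(thresholds, function(t) {
    one_grid_point(input, t, clump_stats, t, estimator, effects_mode,
                   condition_limit)
  }))
  structure(list(axis = "r2_threshold", points = pts, chosen_index = NA_integer_,
                 estimator = estimator, effects_mode = effects_mode),
            class = "grid_result")
}

#' Choose an LD threshold from a grid by point-estimate stability
#'
#' Operationalises the rule of comparing the point estimate at threshold
#' `l` with that at `l - 1`: the chosen threshold is the largest `l` whose
#' estimate moved by at most `stability_tol` standard errors (of the `l - 1`
#' point) from the previous threshold's estimate, with no collinearity flag
#' at `l`. If no point qualifies, the smallest-threshold point is returned
#' with a warning.
#'
#' @param grid A `grid_result` from [grid_search_r2()].
#' @param stability_tol Stability tolerance in units of se(l-1) (default 0.5).
#' @return The `grid_result` with `chosen_index` set and a `selection_note`.
#' @export
select_threshold <- function(grid, stability_tol = 0.5) {
  pts <- grid$points
  ok <- !is.na(pts$estimate)
  if (sum(ok) < 2L) cismr_error("need >= 2 non-failed grid points", "cismr_config_error")
  chosen <- NA_integer_
  for (l in rev(seq_len(nrow(pts))[-1])) {
    prev <- l - 1L
    if (is.na(pts$estimate[l]) || is.na(pts$estimate[prev])) next
    if (abs(pts$estimate[l] - pts$estimate[prev]) <= stability_tol * pts$se[prev]) {
      chosen <- l
      break
    }
  }
  if (is.na(chosen)) {
    warning("select_threshold: no stable point; returning the smallest threshold")
    chosen <- which(ok)[1]
    grid$selection_note <- "no threshold met the stability rule; smallest used"
  } else {
    grid$selection_note <- sprintf(
      "largest threshold with |estimate(l) - estimate(l-1)| <= %g * se(l-1) and no flag",
      stability_tol)
  }
  grid$chosen_index <- chosen
  grid
}

#' Grid search over region flank sizes
#'
#' Re-extracts, harmonises, clumps and estimates at each flank, so the
#' analyst can compare a tight cis window with a broad one (e.g. +-2.5 kB
#' versus +-1 MB) and watch the estimate and Egger intercept as neighbours
#' enter.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param ld `ld_matrix` covering the widest flank.
#' @param gene A `region` (its own `flank` is ignored).
#' @param flanks Increasing flank sizes in base pairs; default
#'   `c(2500, 1e6)`, the two conventional regimes.
#' @param maf_min Minor-allele-frequency filter for extraction.
#' @param r2_threshold Clumping threshold applied within each flank.
#' @param estimator,effects_mode,condition_limit As in [grid_search_r2()].
#' @inheritParams harmonize
#' @return A `grid_result` with `axis = "region_flank"`.
#' @export
grid_search_region <- function(exposure, outcome, ld, gene,
                               flanks = c(2500, 1e6), maf_min = 0.01,
                               r2_threshold = 0.6,
                               estimator = "gls_ivw", effects_mode = "fixed",
                               exposure_type = "protein",
                               condition_limit = 1e8) {
  if (is.unsorted(flanks, strictly = TRUE)) {
    cismr_error("flanks must be strictly increasing", "cismr_config_error")
  }
  pts <- do.call(rbind, lapply(flanks, function(f) {
    reg <- region(gene$gene_id, gene$chromosome, gene$start, gene$end, flank = f)
    tryCatch({
      ex <- extract_region(exposure, reg, maf_min = maf_min)
      if (nrow(ex) == 0L) cismr_error("no variants in region", "cismr_empty_input")
      inp <- harmonize(ex, outcome, ld, exposure_type = exposure_type)
      one_grid_point(inp, f, ranking_stats(inp, ex), r2_threshold,
                     estimator, effects_mode, condition_limit)
    }, error = function(e) {
      data.frame(axis_value = f, n_variants = NA_integer_, estimate = NA_real_,
                 se = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p = NA_real_, intercept = NA_real_, n_screened_out = 0L,
                 flag = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }))
  structure(list(axis = "region_flank", points = pts, chosen_index = NA_integer_,
                 estimator = estimator, effects_mode = effects_mode),
            class = "grid_result")
}

#' Random-subset instrument-selection experiment
#'
#' Mimics ad hoc instrument selection by repeatedly sampling a small number
#' of variants at random from the candidate pool (after MAF and pairwise-LD
#' filtering) and estimating with the LD-aware GLS each time. The spread of
#' the resulting estimates measures how sensitive a locus's conclusion is to
#' which handful of variants an analyst happens to pick.
#'
#' @param input A `harmonized_input` (the candidate pool).
#' @param maf_min Candidate MAF filter (default 0.01).
#' @param r2_max Candidates are pre-clumped so no retained pair has
#'   `r^2 >= r2_max` (default 0.8).
#' @param subset_size Variants drawn per iteration (default 4).
#' @param n_iterations Number of random draws (default 500).
#' @param seed Master seed; per-iteration seeds are derived by counter so
#'   individual iterations can be reproduced independently.
#' @param estimator,effects_mode Passed through to the estimator.
#' @param expected_sign Optional declared direction (+1 or -1) for the
#'   (target, outcome) pair; never inferred from the data.
#' @return A `subset_experiment`: estimates data frame (one row per
#'   iteration), the subsets drawn, pool ids, summary quartiles, and the
#'   fraction of estimates in the declared expected direction.
#' @export
random_subset_experiment <- function(input, maf_min = 0.01, r2_max = 0.8,
                                     subset_size = 4, n_iterations = 500,
                                     seed = 1, estimator = "gls_ivw",
                                     effects_mode = "fixed",
                                     expected_sign = NULL) {
  maf <- pmin(input$eaf, 1 - input$eaf)
  keep <- is.na(maf) | maf > maf_min
  pool_input <- subset_input(input, input$variant_ids[keep])
  cl <- clump(ranking_stats(pool_input), pool_input$ld, r2_max)
  pool <- cl$retained_ids
  if (length(pool) < subset_size) {
    cismr_error(sprintf("candidate pool (%d) smaller than subset_size (%d)",
                        length(pool), subset_size), "cismr_config_error")
  }
  rows <- vector("list", n_iterations)
  subsets <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    set.seed(derive_seed(seed, 1L, i))
    ids <- sort(sample(pool, subset_size))
    subsets[[i]] <- ids
    fit <- tryCatch(estimator_fun(estimator)(subset_input(input, ids), effects_mode),
                    error = function(e) NULL)
    rows[[i]] <- data.frame(
      iteration = i,
      estimate = if (is.null(fit)) NA_real_ else fit$estimate,
      se = if (is.null(fit)) NA_real_ else fit$se,
      p = if (is.null(fit)) NA_real_ else fit$p,
      failed = is.null(fit))
  }
  est <- do.call(rbind, rows)
  q <- stats::quantile(est$estimate, c(0.25, 0.5, 0.75), na.rm = TRUE)
  prop_dir <- if (is.null(expected_sign)) NA_real_ else
    mean(sign(est$estimate) == sign(expected_sign), na.rm = TRUE)
  structure(list(estimates = est, subsets = subsets, pool_ids = pool,
                 n_iterations = n_iterations, subset_size = subset_size,
                 seed = seed,
                 quartiles = stats::setNames(q, c("q1", "median", "q3")),
                 expected_sign = expected_sign,
                 prop_expected_direction = prop_dir),
            class = "subset_experiment")
}

#' @export
print.subset_experiment <- function(x, ...) {
  cat(sprintf("subset_experiment: %d iterations of %d/%d variants\n",
              x$n_iterations, x$subset_size, length(x$pool_ids)))
  cat(sprintf("  estimate quartiles: Q1 %.4f, median %.4f, Q3 %.4f\n",
              x$quartiles[1], x$quartiles[2], x$quartiles[3]))
  if (!is.na(x$prop_expected_direction)) {
    cat(sprintf("  in expected direction: %.1f%%\n", 100 * x$prop_expected_direction))
  }
  invisible(x)
}

#' Stratify subset-experiment estimates by worst functional consequence
#'
#' Labels each iteration by the most severe consequence category present in
#' its subset (fixed severity order), drops categories occurring fewer than
#' `min_category_count` times, and summarises estimates per category.
#'
#' @param experiment A `subset_experiment`.
#' @param annotations An `annotation_table` covering every pool variant.
#' @param min_category_count Minimum iterations per category (default 5).
#' @return Data frame: one row per retained category with counts and
#'   estimate quartiles.
#' @export
stratify_by_annotation <- function(experiment, annotations, min_category_count = 5) {
  stopifnot(inherits(experiment, "subset_experiment"))
  pool <- experiment$pool_ids
  missing <- setdiff(unlist(experiment$subsets), annotations$variant_id)
  if (length(missing)) {
    cismr_error(paste0("unannotated variant(s): ", paste(unique(missing), collapse = ", ")),
                "cismr_config_error")
  }
  rank_of <- stats::setNames(annotations$severity_rank, annotations$variant_id)
  cons_of <- stats::setNames(annotations$consequence, annotations$variant_id)
  labels <- vapply(experiment$subsets, function(ids) {
    r <- rank_of[ids]
    cons_of[ids][which.min(r)]
  }, character(1))
  est <- experiment$estimates$estimate
  tab <- table(labels)
  keep_cats <- names(tab)[tab >= min_category_count]
  out <- do.call(rbind, lapply(keep_cats, function(cat) {
    e <- est[labels == cat]
    q <- stats::quantile(e, c(0.25, 0.5, 0.75), na.rm = TRUE)
    data.frame(category = cat, n_iterations = sum(labels == cat),
               q1 = q[[1]], median = q[[2]], q3 = q[[3]],
               stringsAsFactors = FALSE)
  }))
  rank_cat <- match(out$category, attr(annotations, "vocabulary"))
  out[order(rank_cat), , drop = FALSE]
}

#' Write a grid or subset experiment as tidy TSV
#'
#' @param x A `grid_result` or `subset_experiment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_experiment_tsv <- function(x, path) {
  df <- if (inherits(x, "grid_result")) x$points else x$estimates
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
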