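# Config-driven orchestration: single-target analysis and multi-outcome
# phenome-wide scans, with tabular reports and a run log.

#' Read an analysis configuration
#'
#' A single declarative YAML file; see [run_target()] for recognised keys.
#' Defaults are filled in and logged so reports are self-describing.
#'
#' @param path Path to a YAML config.
#' @param overrides Named list overriding config keys (CLI flags map here).
#' @return A named list.
#' @export
read_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(cfg, overrides)
}

config_defaults <- function(cfg) {
  def <- list(flank = 2500, maf_min = 0.01, r2_grid = seq(0.1, 0.9, by = 0.1),
              effects_mode = "fixed", estimators = c("gls_ivw", "gls_egger"),
              exposure_type = "protein", exposure_scale = "linear",
              outcome_scale = "log_odds", stability_tol = 0.5,
              outlier_criterion = "q_pvalue", seed = 1,
              condition_limit = 1e8, adjust_denominator = NULL)
  utils::modifyList(def, cfg)
}

load_stats <- function(x, label, scale) {
  if (inherits(x, "summary_stats")) return(x)
  read_summary_stats(x, trait_label = label, trait_scale = scale)
}

load_ld <- function(x) {
  if (inherits(x, "ld_matrix")) return(x)
  if (grepl("\\.vcf(\\.gz)?$", x)) {
    panel <- read_panel_vcf(x)
    return(ld_from_genotypes(panel$dosages, panel_label = basename(x),
                             ea = panel$ea))
  }
  if (grepl("panel", basename(x))) {
    return(ld_from_genotypes(read_panel_matrix(x), panel_label = basename(x)))
  }
  read_ld_tsv(x)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    cismr_error(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                class(e)[1])
  })
}

#' Run a full single-target drug-target MR analysis
#'
#' Executes extract -> harmonise -> (optional non-target pruning) ->
#' clumping grid search -> threshold selection -> estimation (IVW and Egger,
#' fixed and the configured effects mode) -> heterogeneity and outlier
#' diagnostics -> (optional annotation stratification), writing a TSV + JSON
#' report and a run log. Hard errors carry their stage name; per-point
#' failures inside grids become flagged rows.
#'
#' Config keys: `gene_id`, `chromosome`, `start`, `end`, `flank`,
#' `exposure` (path or object), `exposure_type`, `exposure_scale`,
#' `outcome`, `outcome_scale`, `ld` (path to square TSV / `*panel*.tsv`
#' dosage matrix / VCF, or an `ld_matrix`), `maf_min`, `r2_grid`,
#' `effects_mode`, `estimators`, `pleiotropy_table`, `annotations`,
#' `stability_tol`, `outlier_criterion`, `seed`, `out_dir`.
#'
#' @param config Named list (see [read_config()]).
#' @return A `target_report`: list with `results` (data frame), `grid`,
#'   `heterogeneity`, `outliers`, `prune`, `config`, plus file paths when
#'   `out_dir` is set.
#' @export
run_target <- function(config) {
  cfg <- config_defaults(config)
  set.seed(cfg$seed)

  reg <- with_stage("region", region(cfg$gene_id, cfg$chromosome, cfg$start,
                                     cfg$end, flank = cfg$flank))
  exposure <- with_stage("read_exposure",
                         load_stats(cfg$exposure, "exposure", cfg$exposure_scale))
  outcome <- with_stage("read_outcome",
                        load_stats(cfg$outcome, "outcome", cfg$outcome_scale))
  ld <- with_stage("read_ld", load_ld(cfg$ld))

  ex_reg <- with_stage("extract", {
    out <- extract_region(exposure, reg, maf_min = cfg$maf_min)
    if (nrow(out) == 0L) cismr_error("no variants in region", "cismr_empty_input")
    out
  })
  input <- with_stage("harmonize",
                      harmonize(ex_reg, outcome, ld,
                                exposure_type = cfg$exposure_type))

  prune <- NULL
  if (!is.null(cfg$pleiotropy_table)) {
    tab <- if (is.character(cfg$pleiotropy_table)) {
      read_nontarget_table(cfg$pleiotropy_table)
    } else nontarget_table(cfg$pleiotropy_table)
    prune <- with_stage("prune",
                        prune_nontarget(input, tab, target_region = reg))
  }

  grid <- with_stage("grid", {
    g <- grid_search_r2(input, thresholds = cfg$r2_grid,
                        stats_for_ranking = ex_reg,
                        estimator = "gls_ivw", effects_mode = cfg$effects_mode,
                        condition_limit = cfg$condition_limit)
    select_threshold(g, stability_tol = cfg$stability_tol)
  })
  chosen_r2 <- grid$points$axis_value[grid$chosen_index]

  analysed <- with_stage("estimate", {
    cl <- clump(ex_reg[ex_reg$SNP %in% input$variant_ids, , drop = FALSE],
                input$ld, chosen_r2)
    scr <- collinearity_screen(subset_input(input, cl$retained_ids),
                               condition_limit = cfg$condition_limit)
    scr$input
  })

  rows <- list(); hets <- list()
  for (est in cfg$estimators) {
    for (mode in unique(c("fixed", cfg$effects_mode))) {
      fit <- tryCatch(estimator_fun(est)(analysed, mode), error = function(e) NULL)
      if (is.null(fit)) {
        rows[[paste(est, mode)]] <- data.frame(
          method = est, estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
          ci_high = NA_real_, p = NA_real_, odds_ratio = NA_real_,
          or_ci_low = NA_real_, or_ci_high = NA_real_, intercept = NA_real_,
          intercept_se = NA_real_, intercept_p = NA_real_,
          n_variants = length(analysed$variant_ids), effects_mode = mode,
          outcome_scale = cfg$outcome_scale, scale_note = "",
          stringsAsFactors = FALSE)
        next
      }
      rows[[paste(est, mode)]] <- as.data.frame(fit)
      if (mode == "fixed") {
        hets[[est]] <- tryCatch(heterogeneity(analysed, fit),
                                error = function(e) NULL)
      }
    }
  }
  results <- do.call(rbind, rows)
  results <- cbind(data.frame(target = cfg$gene_id, r2_threshold = chosen_r2),
                   results)
  rownames(results) <- NULL
  if (!is.null(cfg$adjust_denominator)) {
    results$p_adjusted <- pmin(1, results$p * cfg$adjust_denominator)
  }

  outliers <- tryCatch(
    remove_outliers(analysed, criterion = cfg$outlier_criterion),
    error = function(e) NULL)

  strat <- NULL
  if (!is.null(cfg$annotations)) {
    ann <- if (is.character(cfg$annotations)) read_annotations(cfg$annotations)
           else cfg$annotations
    strat <- tryCatch({
      exp_res <- random_subset_experiment(analysed, seed = cfg$seed,
                                          n_iterations = cfg$subset_iterations %||% 100,
                                          subset_size = min(4, length(analysed$variant_ids)))
      stratify_by_annotation(exp_res, ann)
    }, error = function(e) NULL)
  }

  report <- structure(list(results = results, grid = grid,
                           heterogeneity = hets, outliers = outliers,
                           prune = prune, stratification = strat,
                           n_input_variants = length(input$variant_ids),
                           provenance = input$provenance, config = cfg),
                      class = "target_report")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    tsv <- file.path(cfg$out_dir, paste0(cfg$gene_id, "_results.tsv"))
    utils::write.table(results, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    js <- file.path(cfg$out_dir, paste0(cfg$gene_id, "_report.json"))
    jsonlite::write_json(list(
      results = results, grid = grid$points,
      chosen_r2 = chosen_r2, selection_note = grid$selection_note,
      prune = if (!is.null(prune)) prune$points,
      outlier_log = if (!is.null(outliers)) outliers$log,
      config = cfg[setdiff(names(cfg), c("exposure", "outcome", "ld"))],
      package_version = as.character(utils::packageVersion("cismr"))),
      js, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    log <- file.path(cfg$out_dir, paste0(cfg$gene_id, "_run.log"))
    writeLines(c(
      sprintf("cismr %s", utils::packageVersion("cismr")),
      sprintf("seed: %s", cfg$seed),
      sprintf("chosen r2 threshold: %s (%s)", chosen_r2, grid$selection_note),
      sprintf("variants harmonised: %d, analysed: %d",
              length(input$variant_ids), length(analysed$variant_ids))), log)
    report$files <- list(tsv = tsv, json = js, log = log)
  }
  report
}

#' @export
print.target_report <- function(x, ...) {
  cat(sprintf("target_report for %s (%d variants analysed)\n",
              x$config$gene_id, x$results$n_variants[1]))
  print(x$results[, c("method", "effects_mode", "estimate", "se", "p")],
        row.names = FALSE)
  invisible(x)
}

#' Phenome-wide drug-target scan over multiple outcomes
#'
#' Harmonises one fixed instrument set (a gene region of the exposure
#' statistics) against each outcome in turn, applies the threshold-selection
#' and outlier-removal rules, estimates, and appends one row per outcome and
#' method. Estimates are positioned in the exposure-increasing direction
#' (the exposure-increasing allele is the effect allele by harmonisation).
#' An outcome failing harmonisation yields a flagged row; the scan
#' continues.
#'
#' @param config As for [run_target()] (without `outcome`); `maf_min`
#'   defaults here to 0.05 and `flank` to 2000, the scan regime.
#' @param outcomes Named list of outcome summary-statistic paths or
#'   `summary_stats` objects.
#' @return A `scan_result` data frame: one row per outcome x method.
#' @export
run_scan <- function(config, outcomes) {
  if (!length(outcomes)) cismr_error("need >= 1 outcome", "cismr_config_error")
  cfg <- config_defaults(utils::modifyList(list(maf_min = 0.05, flank = 2000),
                                           config))
  if (is.null(names(outcomes))) names(outcomes) <- paste0("outcome", seq_along(outcomes))
  rows <- list()
  for (nm in names(outcomes)) {
    res <- tryCatch({
      rep <- run_target(utils::modifyList(cfg, list(outcome = outcomes[[nm]],
                                                    out_dir = NULL)))
      cbind(data.frame(outcome = nm), rep$results, flag = NA_character_)
    }, error = function(e) {
      data.frame(outcome = nm, target = cfg$gene_id, r2_threshold = NA_real_,
                 method = cfg$estimators, estimate = NA_real_, se = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                 odds_ratio = NA_real_, or_ci_low = NA_real_,
                 or_ci_high = NA_real_, intercept = NA_real_,
                 intercept_se = NA_real_, intercept_p = NA_real_,
                 n_variants = NA_integer_, effects_mode = cfg$effects_mode,
                 outcome_scale = cfg$outcome_scale, scale_note = "",
                 flag = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[nm]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out, file.path(cfg$out_dir, "scan_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(out, class = c("scan_result", "data.frame"))
}
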