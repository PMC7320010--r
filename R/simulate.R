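# Simulation engine for the gene -> expression -> protein -> biomarker ->
# disease causal model. Produces LD-structured genotypes in three disjoint
# samples (exposure, outcome, LD panel: the two-sample design plus an
# external reference panel) and per-variant marginal summary statistics,
# with the implied estimands carried as ground truth.

#' Generative truth for a simulated locus
#'
#' Encodes the causal diagram: variants G affect expression E (per-variant
#' `delta_GE`), expression affects the protein P (`delta_EP`), the protein
#' affects a downstream biomarker X (`mu`) and disease D directly (`phi_P`),
#' the biomarker affects disease (`theta`), and variants may affect disease
#' directly (`phi_G`, horizontal pleiotropy). A shared standard-normal
#' confounder U loads on P, X and D. The implied estimands are derived and
#' read-only: the drug-target effect `omega = phi_P + mu * theta`, its
#' biomarker-weighted counterpart `omega_bw = omega / mu`, and its
#' expression-weighted counterpart `omega_ew = delta_EP * omega`. The total
#' variant-to-protein effect is `delta = delta_EP * delta_GE`.
#'
#' @param m Number of variants.
#' @param delta_GE Per-variant effect on expression (recycled to length m).
#' @param delta_EP Expression-to-protein effect (scalar).
#' @param mu Protein-to-biomarker effect.
#' @param theta Biomarker-to-disease effect.
#' @param phi_P Direct protein-to-disease effect.
#' @param phi_G Direct variant-to-disease effect (scalar or length-m vector).
#' @param conf Confounder loadings on (protein, biomarker, disease);
#'   default 0.3 each.
#' @param maf Minor allele frequencies in (0, 0.5]; default an even spread
#'   over 0.15-0.45.
#' @param ld_rho AR(1) parameter of the latent LD (|rho| < 1), or an
#'   explicit target correlation matrix.
#' @param sd_E,sd_P,sd_X,sd_D Residual standard deviations (default 1).
#' @return A `sim_truth` object with derived fields `delta`, `omega`,
#'   `omega_bw`, `omega_ew`.
#' @export
sim_truth <- function(m, delta_GE = 0.2, delta_EP = 1, mu = 0, theta = 0,
                      phi_P = 0, phi_G = 0,
                      conf = c(p = 0.3, x = 0.3, d = 0.3),
                      maf = NULL, ld_rho = 0,
                      sd_E = 1, sd_P = 1, sd_X = 1, sd_D = 1) {
  maf <- maf %||% seq(0.15, 0.45, length.out = m)
  if (any(maf <= 0 | maf > 0.5)) cismr_error("maf must lie in (0, 0.5]", "cismr_config_error")
  if (is.matrix(ld_rho)) {
    if (nrow(ld_rho) != m) cismr_error("LD target matrix must be m x m", "cismr_config_error")
  } else if (abs(ld_rho) >= 1) {
    cismr_error("|ld_rho| must be < 1", "cismr_config_error")
  }
  delta_GE <- rep_len(delta_GE, m)
  phi_G <- rep_len(phi_G, m)
  conf <- rep_len(conf, 3)
  omega <- phi_P + mu * theta
  structure(list(m = as.integer(m), delta_GE = delta_GE, delta_EP = delta_EP,
                 mu = mu, theta = theta, phi_P = phi_P, phi_G = phi_G,
                 conf = stats::setNames(conf, c("p", "x", "d")),
                 maf = rep_len(maf, m), ld_rho = ld_rho,
                 sd_E = sd_E, sd_P = sd_P, sd_X = sd_X, sd_D = sd_D,
                 delta = delta_EP * delta_GE,
                 omega = omega,
                 omega_bw = if (mu == 0) NA_real_ else omega / mu,
                 omega_ew = delta_EP * omega),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: m = %d, omega = %.4g (omega_bw = %.4g, omega_ew = %.4g)\n",
              x$m, x$omega, x$omega_bw, x$omega_ew))
  invisible(x)
}

ld_target_matrix <- function(ld_rho, m) {
  if (is.matrix(ld_rho)) ld_rho else ld_rho^abs(outer(seq_len(m), seq_len(m), "-"))
}

#' Simulate LD-structured genotype dosages
#'
#' Draws a latent multivariate Gaussian per haplotype with the target
#' correlation, thresholds each coordinate at the allele-frequency quantile,
#' and sums two haplotypes into dosages in \{0, 1, 2\}. Realised dosage LD
#' approximates the target (attenuated by dichotomisation, as for any
#' threshold model).
#'
#' @param n Number of samples (>= 2).
#' @param maf Allele frequencies (length determines variant count).
#' @param ld AR(1) parameter or explicit latent correlation matrix.
#' @param variant_ids Column names for the result.
#' @param seed Optional seed (set once at entry; NULL leaves the RNG state).
#' @return Integer dosage matrix, samples x variants.
#' @export
simulate_genotypes <- function(n, maf, ld = 0, variant_ids = NULL, seed = NULL) {
  if (n < 2) cismr_error("need n >= 2", "cismr_config_error")
  if (!is.null(seed)) set.seed(seed)
  m <- length(maf)
  sigma <- ld_target_matrix(ld, m)
  cl <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(cl)) cismr_error("target LD matrix is not positive definite", "cismr_config_error")
  thr <- matrix(stats::qnorm(maf), n, m, byrow = TRUE)
  hap <- function() (matrix(stats::rnorm(n * m), n, m) %*% cl) < thr
  g <- hap() + hap()
  storage.mode(g) <- "integer"
  colnames(g) <- variant_ids %||% sprintf("rs%04d", seq_len(m))
  g
}

# Vectorised per-variant simple linear regression (slope on each dosage
# column, with intercept).
marginal_linear <- function(G, y) {
  n <- nrow(G)
  gc <- scale(G, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  sxy <- drop(crossprod(gc, yc))
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta * sxy
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  list(beta = beta, se = se)
}

marginal_logistic <- function(G, y) {
  m <- ncol(G)
  beta <- se <- numeric(m)
  for (j in seq_len(m)) {
    X <- cbind(1, G[, j])
    fit <- stats::glm.fit(X, y, family = stats::binomial())
    beta[j] <- fit$coefficients[2]
    V <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
    se[j] <- sqrt(V[2, 2])
  }
  list(beta = beta, se = se)
}

make_sumstats <- function(assoc, G, ids, pos, trait_label, trait_scale, n) {
  df <- data.frame(SNP = ids, CHR = "1", POS = pos, EA = "A", OA = "G",
                   EAF = colMeans(G) / 2, BETA = assoc$beta, SE = assoc$se,
                   P = z_pvalue(assoc$beta, assoc$se), N = n)
  suppressMessages(summary_stats(df, trait_label = trait_label,
                                 trait_scale = trait_scale,
                                 genome_build = "simulated"))
}

#' Simulate a two-sample MR study with an external LD panel
#'
#' Generates genotypes in three disjoint samples, builds the phenotypes of
#' the causal model (`E = G delta_GE + e`; `P = delta_EP E + a U + e`;
#' `X = mu P + b U + e`; linear `D = G phi_G + phi_P P + theta X + c U + e`,
#' or a Bernoulli draw on the logistic liability for case-control outcomes),
#' runs per-variant marginal regressions of the designated exposure in the
#' exposure sample and of disease in the outcome sample, and packages the
#' marginal summary statistics together with a panel-derived LD matrix.
#' All three exposure weightings (protein, biomarker, expression) are
#' computed on the same draws and kept in `$exposures`.
#'
#' @param truth A `sim_truth`.
#' @param n_exposure,n_outcome,n_panel Sample sizes of the three samples.
#' @param exposure_type Which exposure weighting `$exposure` points at.
#' @param outcome_model `"linear"` or `"logistic"` (logistic draws cases at
#'   a ~30% baseline rate on the liability scale).
#' @param seed Optional master seed.
#' @param keep_panel Keep the raw panel dosages on the result.
#' @return A `sim_study`: list with `exposure`, `exposures` (all three
#'   `summary_stats`), `outcome`, `ld`, `truth`, `seed` and metadata.
#' @export
simulate_study <- function(truth, n_exposure = 20000, n_outcome = 20000,
                           n_panel = 2000,
                           exposure_type = c("protein", "biomarker", "expression"),
                           outcome_model = c("linear", "logistic"),
                           seed = NULL, keep_panel = FALSE) {
  exposure_type <- match.arg(exposure_type)
  outcome_model <- match.arg(outcome_model)
  stopifnot(inherits(truth, "sim_truth"))
  if (!is.null(seed)) set.seed(seed)
  m <- truth$m
  ids <- sprintf("rs%04d", seq_len(m))
  pos <- 1000000L + 500L * (seq_len(m) - 1L)

  draw_phenotypes <- function(G) {
    n <- nrow(G)
    U <- stats::rnorm(n)
    E <- drop(G %*% truth$delta_GE) + stats::rnorm(n, sd = truth$sd_E)
    P <- truth$delta_EP * E + truth$conf["p"] * U + stats::rnorm(n, sd = truth$sd_P)
    X <- truth$mu * P + truth$conf["x"] * U + stats::rnorm(n, sd = truth$sd_X)
    lin <- drop(G %*% truth$phi_G) + truth$phi_P * P + truth$theta * X +
      truth$conf["d"] * U
    list(E = E, P = P, X = X, lin = lin)
  }

  G_x <- simulate_genotypes(n_exposure, truth$maf, truth$ld_rho, ids)
  ph_x <- draw_phenotypes(G_x)
  G_y <- simulate_genotypes(n_outcome, truth$maf, truth$ld_rho, ids)
  ph_y <- draw_phenotypes(G_y)
  G_p <- simulate_genotypes(n_panel, truth$maf, truth$ld_rho, ids)

  exposures <- list(
    protein = make_sumstats(marginal_linear(G_x, ph_x$P), G_x, ids, pos,
                            "protein level", "linear", n_exposure),
    biomarker = make_sumstats(marginal_linear(G_x, ph_x$X), G_x, ids, pos,
                              "biomarker level", "linear", n_exposure),
    expression = make_sumstats(marginal_linear(G_x, ph_x$E), G_x, ids, pos,
                               "mRNA expression", "linear", n_exposure))

  if (outcome_model == "linear") {
    D <- ph_y$lin + stats::rnorm(n_outcome, sd = truth$sd_D)
    outcome <- make_sumstats(marginal_linear(G_y, D), G_y, ids, pos,
                             "disease liability", "linear", n_outcome)
  } else {
    pr <- stats::plogis(stats::qlogis(0.3) + ph_y$lin - mean(ph_y$lin))
    D <- stats::rbinom(n_outcome, 1L, pr)
    if (length(unique(D)) < 2L) {
      cismr_error("logistic outcome degenerate: no case/control variation",
                  "cismr_config_error")
    }
    outcome <- make_sumstats(marginal_logistic(G_y, D), G_y, ids, pos,
                             "disease", "log_odds", n_outcome)
  }

  ld <- ld_from_genotypes(G_p, ids, panel_label = "simulated-panel",
                          ea = rep("A", m))
  structure(list(exposure = exposures[[exposure_type]], exposures = exposures,
                 outcome = outcome, ld = ld,
                 panel = if (keep_panel) G_p else NULL,
                 truth = truth, seed = seed, exposure_type = exposure_type,
                 outcome_model = outcome_model),
            class = "sim_study")
}

#' Assemble a harmonised input directly from a simulated study
#'
#' The simulator emits allele-aligned statistics, so this skips the full
#' harmonisation bookkeeping (exercised separately through the I/O path)
#' and is the fast route used inside replicate loops.
#'
#' @param study A `sim_study`.
#' @param exposure_type Exposure weighting to use (default: the study's).
#' @return A `harmonized_input`.
#' @export
as_harmonized <- function(study, exposure_type = study$exposure_type) {
  ex <- study$exposures[[exposure_type]]
  ou <- study$outcome
  harmonized_input(ex$SNP, ex$BETA, ex$SE, ou$BETA, ou$SE, study$ld,
                   exposure_type = exposure_type,
                   outcome_scale = attr(ou, "trait_scale"),
                   eaf = ex$EAF)
}

#' Preset simulation scenarios
#'
#' Named presets of the generative model, each embodying one regime of the
#' causal framework:
#' \describe{
#'   \item{null}{`omega = 0` with instruments acting on the biomarker
#'     (`mu = 2`): the false-positive-calibration regime.}
#'   \item{protein_causal}{`omega = 0.3` via both a direct protein effect
#'     and the biomarker path; protein-weighted exposure; the estimand
#'     recovery regime (m = 30, AR(1) 0.6, n = 20k/20k/2k).}
#'   \item{biomarker_proxy}{Same truth, biomarker-weighted (`omega / mu`).}
#'   \item{expression_proxy}{Same truth, expression-weighted
#'     (`delta_EP * omega`).}
#'   \item{directional_pleiotropy}{Constant direct variant effect
#'     `phi_G = 0.05` drawn independently of instrument strength (INSIDE
#'     holds), independent variants: Egger's intercept should recover it.}
#'   \item{post_translational_pleiotropy}{`theta = 0`, `phi_P != 0`: the
#'     protein acts on disease not via the measured biomarker, yet the
#'     biomarker-weighted test of `omega = 0` remains valid and powered.}
#'   \item{neighbour_gene_pleiotropy}{Appends a neighbour gene's causal
#'     variant in LD with the locus (no effect on the target protein, a
#'     direct disease effect) and emits the matching non-target association
#'     table for [prune_nontarget()].}
#' }
#'
#' @param name Preset name.
#' @param overrides Named list of `sim_truth` / `simulate_study` arguments
#'   to override.
#' @param seed Master seed.
#' @return A `sim_study` (with `$nontarget_table` for the neighbour preset).
#' @export
scenario <- function(name = c("null", "protein_causal", "biomarker_proxy",
                              "expression_proxy", "directional_pleiotropy",
                              "post_translational_pleiotropy",
                              "neighbour_gene_pleiotropy"),
                     overrides = list(), seed = 1) {
  name <- tryCatch(match.arg(name), error = function(e) {
    cismr_error(paste0("unknown scenario '", name[1], "'; presets: ",
                       paste(eval(formals(scenario)$name), collapse = ", ")),
                "cismr_config_error")
  })
  base <- switch(name,
    null = list(truth = list(m = 20, delta_GE = seq(0.1, 0.3, length.out = 20),
                             delta_EP = 1, mu = 2, theta = 0, phi_P = 0,
                             ld_rho = 0.3),
                study = list(n_exposure = 5000, n_outcome = 5000, n_panel = 2000,
                             exposure_type = "biomarker")),
    protein_causal = list(truth = list(m = 30,
                                       delta_GE = seq(0.15, 0.4, length.out = 30),
                                       delta_EP = 0.8, mu = 2, theta = 0.1,
                                       phi_P = 0.1, ld_rho = 0.6, sd_D = 3),
                          study = list(n_exposure = 20000, n_outcome = 20000,
                                       n_panel = 2000, exposure_type = "protein")),
    directional_pleiotropy = list(truth = list(m = 20,
                                               delta_GE = seq(0.1, 0.7, length.out = 20),
                                               delta_EP = 1, mu = 1, theta = 0.2,
                                               phi_P = 0.1, phi_G = 0.05,
                                               ld_rho = 0),
                                  study = list(n_exposure = 200000, n_outcome = 20000,
                                               n_panel = 2000,
                                               exposure_type = "protein")),
    post_translational_pleiotropy = list(truth = list(m = 20,
                                                      delta_GE = seq(0.15, 0.4, length.out = 20),
                                                      delta_EP = 1, mu = 2,
                                                      theta = 0, phi_P = 0.3,
                                                      ld_rho = 0.3),
                                         study = list(n_exposure = 5000,
                                                      n_outcome = 5000,
                                                      n_panel = 2000,
                                                      exposure_type = "biomarker")),
    neighbour_gene_pleiotropy = list(truth = list(m = 12,
                                                  delta_GE = c(seq(0.15, 0.4, length.out = 11), 0),
                                                  delta_EP = 1, mu = 2, theta = 0.1,
                                                  phi_P = 0.1,
                                                  phi_G = c(rep(0, 11), 0.4),
                                                  ld_rho = 0.6),
                                     study = list(n_exposure = 20000,
                                                  n_outcome = 20000,
                                                  n_panel = 2000,
                                                  exposure_type = "protein")),
    # biomarker_proxy / expression_proxy share the protein_causal truth
    list(truth = list(m = 30, delta_GE = seq(0.15, 0.4, length.out = 30),
                      delta_EP = 0.8, mu = 2, theta = 0.1, phi_P = 0.1,
                      ld_rho = 0.6, sd_D = 3),
         study = list(n_exposure = 20000, n_outcome = 20000, n_panel = 2000,
                      exposure_type = sub("_proxy", "", name))))

  for (k in names(overrides)) {
    if (k %in% names(base$truth) || k %in% names(formals(sim_truth))) {
      base$truth[[k]] <- overrides[[k]]
    } else {
      base$study[[k]] <- overrides[[k]]
    }
  }
  truth <- do.call(sim_truth, base$truth)
  study <- do.call(simulate_study,
                   c(list(truth = truth, seed = seed), base$study))
  study$scenario <- name

  if (name == "neighbour_gene_pleiotropy") {
    # neighbour-gene expression driven by the last (causal) variant; the
    # non-target table records each locus variant's marginal association
    set.seed(derive_seed(seed, 7L))
    G2 <- simulate_genotypes(base$study$n_exposure, truth$maf, truth$ld_rho)
    E2 <- G2[, truth$m] * 1.0 + stats::rnorm(nrow(G2))
    a2 <- marginal_linear(G2, E2)
    study$nontarget_table <- nontarget_table(data.frame(
      variant_id = sprintf("rs%04d", seq_len(truth$m)),
      gene_id = "NEIGHBOUR1",
      p = pmax(z_pvalue(a2$beta, a2$se), .Machine$double.xmin),
      tissue = "blood"))
  }
  study
}

#' Write a simulated study in the formats the I/O module reads
#'
#' Emits `exposure.tsv`, `outcome.tsv`, `ld.tsv` (square signed-r TSV),
#' `panel.tsv` (dosage matrix, if kept), `region.bed`, and
#' `nontarget.tsv` when present — so integration tests exercise the real
#' file-reading path end to end.
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return Named list of the paths written, invisibly.
#' @export
write_study_files <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[sub("\\.tsv$|\\.bed$", "", name)]] <<- p
    p
  }
  wr(as.data.frame(study$exposure), "exposure.tsv")
  wr(as.data.frame(study$outcome), "outcome.tsv")
  ldm <- unclass_ld(study$ld)
  ld_df <- data.frame(SNP = rownames(ldm), ldm, check.names = FALSE)
  wr(ld_df, "ld.tsv")
  if (!is.null(study$panel)) wr(as.data.frame(study$panel), "panel.tsv")
  pos <- study$exposure$POS
  bed <- data.frame(chrom = "1", start = min(pos) - 1L, end = max(pos),
                    name = "SIMGENE")
  p <- file.path(dir, "region.bed")
  utils::write.table(bed, p, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  paths$region <- p
  if (!is.null(study$nontarget_table)) {
    wr(as.data.frame(study$nontarget_table), "nontarget.tsv")
  }
  invisible(paths)
}
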