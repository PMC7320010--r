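# MR estimators: ratio, GLS-IVW and GLS-Egger for correlated variants,
# heterogeneity / influence diagnostics, and iterative outlier removal.
#
# Throughout, the GLS weight matrix is built from the outcome standard
# errors and the signed LD matrix: Omega[j,k] = se_y[j] * se_y[k] * r[j,k].
# Exposure-side uncertainty is ignored in the weighting; under the
# two-sample design the resulting weak-instrument bias is towards the null.

mr_result <- function(method, estimate, se, n_variants, effects_mode,
                      outcome_scale = "linear", scale_note = "",
                      intercept = NA_real_, intercept_se = NA_real_,
                      intercept_p = NA_real_, rss = NA_real_, df = NA_integer_) {
  ci_low <- estimate - stats::qnorm(0.975) * se
  ci_high <- estimate + stats::qnorm(0.975) * se
  out <- list(method = method, estimate = estimate, se = se,
              ci_low = ci_low, ci_high = ci_high,
              p = z_pvalue(estimate, se),
              n_variants = as.integer(n_variants),
              effects_mode = effects_mode,
              outcome_scale = outcome_scale, scale_note = scale_note,
              intercept = intercept, intercept_se = intercept_se,
              intercept_p = intercept_p, rss = rss, df = as.integer(df))
  if (identical(outcome_scale, "log_odds")) {
    out$odds_ratio <- exp(estimate)
    out$or_ci_low <- exp(ci_low)
    out$or_ci_high <- exp(ci_high)
  }
  structure(out, class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s (%s effects), %d variant(s)\n", x$method, x$effects_mode,
              x$n_variants))
  cat(sprintf("  estimate %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$estimate, x$se, x$ci_low, x$ci_high, x$p))
  if (!is.null(x$odds_ratio)) {
    cat(sprintf("  OR %.3f [%.3f, %.3f]\n", x$odds_ratio, x$or_ci_low, x$or_ci_high))
  }
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
             odds_ratio = x$odds_ratio %||% NA_real_,
             or_ci_low = x$or_ci_low %||% NA_real_,
             or_ci_high = x$or_ci_high %||% NA_real_,
             intercept = x$intercept, intercept_se = x$intercept_se,
             intercept_p = x$intercept_p,
             n_variants = x$n_variants, effects_mode = x$effects_mode,
             outcome_scale = x$outcome_scale, scale_note = x$scale_note,
             stringsAsFactors = FALSE)
}

#' Single-variant ratio (Wald) estimate
#'
#' The causal effect as the quotient of the genetic effect on the outcome by
#' the genetic effect on the exposure, with a first-order delta-method
#' standard error `se_y / |beta_x|` and normal-theory interval.
#'
#' @param beta_x,se_x Exposure association and its standard error.
#' @param beta_y,se_y Outcome association and its standard error.
#' @param outcome_scale `"log_odds"` adds an odds-ratio presentation.
#' @param scale_note Free-text exposure units annotation.
#' @return An `mr_result`.
#' @export
ratio_estimate <- function(beta_x, se_x, beta_y, se_y,
                           outcome_scale = "linear", scale_note = "") {
  if (beta_x == 0) cismr_error("ratio undefined: beta_x = 0", "cismr_undefined_ratio")
  mr_result("ratio", beta_y / beta_x, se_y / abs(beta_x), 1L, "fixed",
            outcome_scale = outcome_scale, scale_note = scale_note, df = 0L)
}

# Whitened design/response for the GLS fit: returns Wx (J x p), Wy, and the
# Cholesky factor used. Egger orientation (beta_exposure >= 0) is applied
# jointly to both beta vectors and to the LD signs before weighting.
gls_prepare <- function(input, egger = FALSE) {
  bx <- input$beta_exposure
  by <- input$beta_outcome
  sy <- input$se_outcome
  r <- unclass_ld(input$ld)
  if (egger) {
    s <- ifelse(bx >= 0, 1, -1)  # ties at zero oriented positive
    bx <- s * bx
    by <- s * by
    r <- r * outer(s, s)
  }
  omega <- outer(sy, sy) * r
  L <- chol_or_fail(omega)  # upper triangular, omega = t(L) %*% L
  X <- if (egger) cbind(intercept = 1, slope = bx) else cbind(slope = bx)
  Wx <- backsolve(L, X, transpose = TRUE)
  Wy <- backsolve(L, by, transpose = TRUE)
  list(Wx = Wx, Wy = Wy, bx = bx, by = by)
}

gls_fit <- function(input, egger, effects_mode, method_name) {
  J <- length(input$variant_ids)
  npar <- if (egger) 2L else 1L
  if (J < npar + (if (egger) 1L else 0L)) {
    cismr_error(sprintf("%s needs at least %d variants", method_name,
                        if (egger) 3L else 1L), "cismr_insufficient_instruments")
  }
  if (egger && J < 3L) {
    cismr_error("gls_egger needs at least 3 variants", "cismr_insufficient_instruments")
  }
  w <- gls_prepare(input, egger = egger)
  if (egger && stats::var(w$bx) == 0) {
    cismr_error("constant exposure betas: Egger slope unidentifiable",
                "cismr_unidentifiable")
  }
  xtx <- crossprod(w$Wx)
  xtx_inv <- tryCatch(chol2inv(chol(xtx)), error = function(e) NULL)
  if (is.null(xtx_inv)) {
    cismr_error("GLS normal equations singular; run collinearity_screen()",
                "cismr_multicollinearity")
  }
  coef <- drop(xtx_inv %*% crossprod(w$Wx, w$Wy))
  resid <- drop(w$Wy - w$Wx %*% coef)
  rss <- sum(resid^2)
  df <- J - npar
  mult <- if (effects_mode == "random" && df > 0) max(1, sqrt(rss / df)) else 1
  ses <- sqrt(diag(xtx_inv)) * mult
  slope_i <- npar  # slope is the last column
  mr_result(method_name, coef[slope_i], ses[slope_i], J, effects_mode,
            outcome_scale = input$outcome_scale,
            scale_note = paste0("per unit ", input$exposure_type, " exposure"),
            intercept = if (egger) coef[1] else NA_real_,
            intercept_se = if (egger) ses[1] else NA_real_,
            intercept_p = if (egger) z_pvalue(coef[1], ses[1]) else NA_real_,
            rss = rss, df = df)
}

#' GLS inverse-variance-weighted estimate with correlated variants
#'
#' Regresses the outcome associations on the exposure associations through
#' the origin, weighting by `Omega^{-1}` where
#' `Omega[j,k] = se_y[j] * se_y[k] * r[j,k]` and `r` is the signed LD:
#' `estimate = (bx' Omega^-1 bx)^-1 bx' Omega^-1 by`. With identity LD this
#' is the classic IVW estimate; with one variant it is the ratio estimate.
#'
#' @param input A `harmonized_input`.
#' @param effects_mode `"fixed"` uses the model-based standard error;
#'   `"random"` multiplies it by `max(1, sqrt(RSS_gls / (J - 1)))` so
#'   dispersion beyond the model inflates the interval but can never shrink
#'   it.
#' @return An `mr_result`.
#' @export
gls_ivw <- function(input, effects_mode = c("fixed", "random")) {
  effects_mode <- match.arg(effects_mode)
  gls_fit(input, egger = FALSE, effects_mode = effects_mode, method_name = "gls_ivw")
}

#' GLS-Egger estimate with correlated variants
#'
#' As [gls_ivw()] but with a free intercept: variants are first oriented so
#' every exposure association is non-negative (flipping the paired outcome
#' association and the LD signs), then a two-parameter GLS fit of the outcome
#' associations on `[1, bx]` is made. The intercept estimates average
#' directional horizontal pleiotropy (valid under the INSIDE assumption);
#' the slope is the pleiotropy-corrected causal effect.
#'
#' @inheritParams gls_ivw
#' @return An `mr_result` with `intercept`, `intercept_se`, `intercept_p`.
#' @export
gls_egger <- function(input, effects_mode = c("fixed", "random")) {
  effects_mode <- match.arg(effects_mode)
  gls_fit(input, egger = TRUE, effects_mode = effects_mode, method_name = "gls_egger")
}

#' Heterogeneity and influence diagnostics for a GLS fit
#'
#' Residuals are whitened by the symmetric inverse square root of the GLS
#' weight matrix; Q is the sum of squared whitened residuals (reducing to
#' Cochran's Q under identity LD), with per-variant components that sum to
#' Q exactly. Leverage is the hat-matrix diagonal in the whitened space, and
#' `estimate_change_on_removal[j]` is the leave-one-out change in the
#' causal estimate.
#'
#' @param input The `harmonized_input` the fit was computed on.
#' @param fit An `mr_result` from [gls_ivw()] or [gls_egger()].
#' @return A `heterogeneity_report`: list with `Q`, `df`, `p`,
#'   `per_variant_q`, `leverage`, `cooks`, `estimate_change_on_removal`.
#' @export
heterogeneity <- function(input, fit) {
  stopifnot(inherits(fit, "mr_result"))
  egger <- identical(fit$method, "gls_egger")
  npar <- if (egger) 2L else 1L
  J <- length(input$variant_ids)

  bx <- input$beta_exposure
  by <- input$beta_outcome
  sy <- input$se_outcome
  r <- unclass_ld(input$ld)
  if (egger) {
    s <- ifelse(bx >= 0, 1, -1)
    bx <- s * bx; by <- s * by; r <- r * outer(s, s)
  }
  omega <- outer(sy, sy) * r
  W <- inv_sqrtm(omega)
  X <- if (egger) cbind(1, bx) else cbind(bx)
  fitted <- if (egger) fit$intercept + fit$estimate * bx else fit$estimate * bx
  wresid <- drop(W %*% (by - fitted))
  per_q <- wresid^2
  Q <- sum(per_q)
  df <- J - npar
  Wx <- W %*% X
  H <- Wx %*% chol2inv(chol(crossprod(Wx))) %*% t(Wx)
  lev <- diag(H)
  sigma2 <- if (df > 0) Q / df else NA_real_
  cooks <- if (df > 0) per_q * lev / (npar * sigma2 * (1 - lev)^2) else rep(NA_real_, J)

  loo <- rep(NA_real_, J)
  min_j <- if (egger) 3L else 1L
  if (J > min_j) {
    for (j in seq_len(J)) {
      sub <- subset_input(input, input$variant_ids[-j])
      est_j <- tryCatch({
        f <- if (egger) gls_egger(sub, fit$effects_mode) else gls_ivw(sub, fit$effects_mode)
        f$estimate
      }, error = function(e) NA_real_)
      loo[j] <- est_j - fit$estimate
    }
  }
  structure(list(Q = Q, df = df,
                 p = if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE) else NA_real_,
                 per_variant_q = stats::setNames(per_q, input$variant_ids),
                 leverage = stats::setNames(lev, input$variant_ids),
                 cooks = stats::setNames(cooks, input$variant_ids),
                 estimate_change_on_removal = stats::setNames(loo, input$variant_ids),
                 method = fit$method),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat(sprintf("heterogeneity (%s): Q = %.3f on %d df, p = %.3g\n",
              x$method, x$Q, x$df, x$p))
  invisible(x)
}

#' Iterative outlier removal
#'
#' Refits the chosen estimator, removes the single worst variant exceeding
#' the criterion, and repeats until no variant exceeds it, `max_removed` is
#' reached, or removal would leave too few variants (1 for IVW, 3 for Egger;
#' then it stops with a warning rather than an error). Default thresholds:
#' per-variant Q component p below `0.05 / J` (Bonferroni within locus),
#' Cook's distance above `4 / J`, leverage above `2 p / J`.
#'
#' @param input A `harmonized_input`.
#' @param criterion One of `"q_pvalue"`, `"cooks"`, `"leverage"`.
#' @param limit Criterion threshold; `NULL` uses the defaults above.
#' @param max_removed Cap on removals (default unlimited).
#' @param estimator `"gls_ivw"` or `"gls_egger"`.
#' @param effects_mode Passed to the estimator.
#' @return List with `input` (reduced) and `log` (data frame of removals with
#'   the triggering statistic).
#' @export
remove_outliers <- function(input, criterion = c("q_pvalue", "cooks", "leverage"),
                            limit = NULL, max_removed = Inf,
                            estimator = c("gls_ivw", "gls_egger"),
                            effects_mode = "fixed") {
  criterion <- match.arg(criterion)
  estimator <- match.arg(estimator)
  fit_fun <- if (estimator == "gls_egger") gls_egger else gls_ivw
  npar <- if (estimator == "gls_egger") 2L else 1L
  min_keep <- if (estimator == "gls_egger") 3L else 1L
  cur <- input
  log <- data.frame(variant_id = character(), criterion = character(),
                    statistic = numeric(), threshold = numeric())
  while (nrow(log) < max_removed) {
    J <- length(cur$variant_ids)
    fit <- fit_fun(cur, effects_mode)
    het <- heterogeneity(cur, fit)
    thr <- limit %||% switch(criterion,
                             q_pvalue = 0.05 / J,
                             cooks = 4 / J,
                             leverage = 2 * npar / J)
    stat <- switch(criterion,
                   q_pvalue = stats::pchisq(het$per_variant_q, 1, lower.tail = FALSE),
                   cooks = het$cooks,
                   leverage = het$leverage)
    exceeds <- if (criterion == "q_pvalue") stat < thr else stat > thr
    exceeds[is.na(exceeds)] <- FALSE
    if (!any(exceeds)) break
    worst <- if (criterion == "q_pvalue") which.min(stat) else which.max(stat)
    if (J - 1L < min_keep) {
      warning(sprintf("remove_outliers: stopping, removal would leave < %d variants",
                      min_keep))
      break
    }
    log <- rbind(log, data.frame(variant_id = cur$variant_ids[worst],
                                 criterion = criterion,
                                 statistic = stat[[worst]], threshold = thr))
    cur <- subset_input(cur, cur$variant_ids[-worst])
  }
  list(input = cur, log = log)
}
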