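# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

cismr_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cismr_error", "error", "condition")))
}

# Deterministic sub-seed derivation: one master seed, per-stream counters.
# Kept well inside 32-bit integer range.
derive_seed <- function(master, stream, i = 0L) {
  as.integer((as.numeric(master) * 1009 + stream * 9973 + i) %% 2147483587)
}

# Two-sided normal p-value from an estimate and its standard error.
z_pvalue <- function(est, se) 2 * stats::pnorm(-abs(est / se))

# Complement of A/C/G/T alleles (vectorised over multi-base strings).
allele_complement <- function(x) {
  chartr("ACGT", "TGCA", x)
}

is_palindromic <- function(ea, oa) allele_complement(ea) == oa

# Condition number of a symmetric matrix via its eigenvalues; Inf when the
# smallest eigenvalue is not strictly positive.
condition_number <- function(m) {
  if (nrow(m) == 1L) return(1)
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return(Inf)
  max(ev) / min(ev)
}

# Symmetric inverse square root, used to whiten GLS residuals.
inv_sqrtm <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) <= 0) {
    cismr_error("matrix is not positive definite; run collinearity_screen()",
                "cismr_multicollinearity")
  }
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

# Cholesky with an actionable failure mode: the GLS weight matrix losing
# positive definiteness is a multicollinearity symptom, not a numerics bug.
chol_or_fail <- function(omega) {
  out <- tryCatch(chol(omega), error = function(e) NULL)
  if (is.null(out)) {
    cismr_error(
      "LD-weighted covariance is not positive definite (multicollinearity); run collinearity_screen()",
      "cismr_multicollinearity")
  }
  out
}
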