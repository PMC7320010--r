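# Fixtures are built in code at test time; nothing is stored on disk.

# Quick summary_stats builder with sensible defaults.
fix_stats <- function(m, snp = sprintf("rs%02d", seq_len(m)), chr = "1",
                      pos = 100L + 10L * seq_len(m), ea = "A", oa = "G",
                      eaf = rep(0.3, m), beta = rep(0.1, m), se = rep(0.02, m),
                      p = NULL, n = 10000, trait_scale = "linear",
                      trait_label = "fixture", genome_build = "GRCh37") {
  df <- data.frame(SNP = snp, CHR = chr, POS = pos, EA = ea, OA = oa,
                   EAF = eaf, BETA = beta, SE = se,
                   P = if (is.null(p)) NA_real_ else p, N = n)
  suppressMessages(summary_stats(df, trait_label = trait_label,
                                 trait_scale = trait_scale,
                                 genome_build = genome_build))
}

# Identity-LD harmonised input from raw beta vectors.
fix_input <- function(bx, by, sy, sx = rep(0.01, length(bx)),
                      r = diag(length(bx)), eaf = rep(0.3, length(bx)),
                      exposure_type = "protein", outcome_scale = "linear") {
  ids <- sprintf("rs%02d", seq_along(bx))
  harmonized_input(ids, bx, sx, by, sy,
                   ld_matrix(r, ids, panel_label = "fixture"),
                   exposure_type = exposure_type, outcome_scale = outcome_scale,
                   eaf = eaf)
}

# AR(1) signed correlation matrix.
ar1 <- function(m, rho) rho^abs(outer(seq_len(m), seq_len(m), "-"))

# Classic (independent-variant) IVW closed form: the identity-LD oracle.
ivw_closed_form <- function(bx, by, sy) {
  w <- 1 / sy^2
  sum(bx * by * w) / sum(bx^2 * w)
}

# Classic Cochran's Q for a fitted slope.
cochran_q <- function(bx, by, sy, est) sum((by - est * bx)^2 / sy^2)

write_tsv <- function(df, path, col.names = TRUE) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = col.names)
  path
}
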