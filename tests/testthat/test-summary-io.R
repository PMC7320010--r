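# Reading, validation and harmonisation of summary statistics.

test_that("well-formed TSV parses identically under canonical and renamed dialects", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3"), CHR = "1",
                   POS = c(100L, 200L, 300L), EA = c("A", "C", "T"),
                   OA = c("G", "T", "C"), EAF = c(0.1, 0.4, 0.25),
                   BETA = c(0.05, -0.02, 0.11), SE = c(0.01, 0.02, 0.03),
                   P = c(1e-6, 0.3, 1e-4), N = 5000L)
  f1 <- write_tsv(df, tempfile(fileext = ".tsv"))
  st <- read_summary_stats(f1)
  expect_s3_class(st, "summary_stats")
  expect_equal(nrow(st), 3L)
  expect_equal(st$SNP, c("rs1", "rs2", "rs3"))

  # GWAS-catalog-style column names, same content
  df2 <- df
  names(df2) <- c("variant_id", "chromosome", "base_pair_location",
                  "effect_allele", "other_allele", "effect_allele_frequency",
                  "beta", "standard_error", "p_value", "n")
  f2 <- write_tsv(df2, tempfile(fileext = ".tsv"))
  dialect <- c(SNP = "variant_id", CHR = "chromosome", POS = "base_pair_location",
               EA = "effect_allele", OA = "other_allele",
               EAF = "effect_allele_frequency", BETA = "beta",
               SE = "standard_error", P = "p_value", N = "n")
  st2 <- read_summary_stats(f2, dialect = dialect, trait_label = attr(st, "trait_label"))
  expect_equal(as.data.frame(st), as.data.frame(st2))
})

test_that("invalid rows are dropped with a message and missing columns error", {
  df <- data.frame(SNP = c("rs1", "rs2", "rs3", "rs4", "rs1"), CHR = "1",
                   POS = c(100L, 200L, 300L, 400L, 500L),
                   EA = c("A", "C", "X", "A", "A"), OA = c("G", "C", "G", "G", "G"),
                   EAF = c(0.1, 0.2, 0.3, 1.4, 0.2),
                   BETA = 0.1, SE = c(0.01, 0, 0.01, 0.01, 0.01),
                   P = 0.5, N = 1000L)
  # rs2: se = 0; rs3: bad allele; rs4: eaf > 1; duplicate rs1 -> 4 dropped
  expect_message(st <- summary_stats(df), "dropped 4")
  expect_equal(st$SNP, "rs1")
  expect_equal(attr(st, "n_dropped"), 4L)

  expect_error(summary_stats(df[, -1]), class = "cismr_config_error")
  f <- write_tsv(df, tempfile(fileext = ".tsv"))
  expect_error(read_summary_stats(f, dialect = c(SNP = "absent_col")),
               class = "cismr_config_error")
})

test_that("missing p-values are recomputed and underflowed ones clamped", {
  st <- fix_stats(2, beta = c(1, 0.1), se = c(0.01, 0.05))
  expect_equal(st$P[st$SNP == "rs02"], 2 * pnorm(-2))
  expect_gt(st$P[st$SNP == "rs01"], 0)
})

test_that("extract_region respects closed boundaries, MAF symmetry, and flank nesting", {
  st <- fix_stats(4, pos = c(99L, 100L, 200L, 201L))
  reg <- region("G1", "1", 100, 200, flank = 0)
  expect_equal(extract_region(st, reg, maf_min = 0)$POS, c(100L, 200L))

  st2 <- fix_stats(2, pos = c(150L, 160L), eaf = c(0.995, 0.4))
  expect_equal(extract_region(st2, reg, maf_min = 0.01)$SNP, "rs02")

  # brute-force interval scan oracle on 50 scattered variants
  set.seed(7)
  pos <- sort(sample.int(20000L, 50))
  st3 <- fix_stats(50, pos = pos, eaf = runif(50, 0.02, 0.5))
  reg3 <- region("G3", "1", 8000, 9000, flank = 2500)
  got <- extract_region(st3, reg3, maf_min = 0)$POS
  expect_equal(got, pos[vapply(pos, function(p) p >= 8000 - 2500 & p <= 9000 + 2500,
                               logical(1))])

  # nesting: smaller flank set contained in larger
  for (f1 in c(0, 500, 1500)) {
    a <- extract_region(st3, region("G3", "1", 8000, 9000, flank = f1), maf_min = 0)$SNP
    b <- extract_region(st3, region("G3", "1", 8000, 9000, flank = f1 + 1000), maf_min = 0)$SNP
    expect_true(all(a %in% b))
  }
})

test_that("variants lacking EAF drop under a positive MAF filter but not at zero", {
  st <- fix_stats(2, pos = c(150L, 160L), eaf = c(NA, 0.3))
  reg <- region("G1", "1", 100, 200, flank = 0)
  expect_warning(out <- extract_region(st, reg, maf_min = 0.01), "lacking EAF")
  expect_equal(out$SNP, "rs02")
  expect_equal(nrow(extract_region(st, reg, maf_min = 0)), 2L)
})

test_that("BED regions convert from 0-based half-open to 1-based closed", {
  f <- write_tsv(data.frame(c("1"), 99L, 200L, "G1"), tempfile(fileext = ".bed"),
                 col.names = FALSE)
  regs <- read_regions_bed(f, flank = 10)
  expect_equal(regs$G1$start, 100L)
  expect_equal(regs$G1$end, 200L)
})

test_that("harmonize aligns alleles, flips signs, and drops ambiguous palindromes", {
  ex <- fix_stats(4, ea = c("A", "A", "A", "A"), oa = c("G", "G", "G", "T"),
                  beta = c(0.1, 0.2, 0.3, 0.4), eaf = c(0.2, 0.2, 0.2, 0.5))
  ou_df <- as.data.frame(ex)
  ou_df$BETA <- c(0.05, -0.08, 0.02, 0.01)
  # rs02 coded on the other allele in the outcome
  ou_df$EA[2] <- "G"; ou_df$OA[2] <- "A"; ou_df$BETA[2] <- -ou_df$BETA[2]
  ou <- suppressMessages(summary_stats(ou_df, trait_label = "out"))
  ld <- ld_matrix(diag(4), ex$SNP)

  inp <- harmonize(ex, ou, ld)
  # rs04 is palindromic (A/T) at eaf 0.5 -> dropped; rs02 flipped back
  expect_equal(inp$variant_ids, c("rs01", "rs02", "rs03"))
  expect_equal(inp$beta_outcome, c(0.05, -0.08, 0.02))
  expect_true(any(inp$provenance$action == "flip_outcome"))

  # identical orientation everywhere: no flips, no drops
  inp0 <- harmonize(ex[1:3, ], ou[c(1, 3), ], ld)
  expect_equal(inp0$variant_ids, c("rs01", "rs03"))
  expect_equal(inp0$beta_outcome, c(0.05, 0.02))
})

test_that("harmonisation round-trips a randomly re-oriented outcome set", {
  set.seed(11)
  m <- 12
  ex <- fix_stats(m, ea = rep("A", m), oa = rep("G", m),
                  beta = rnorm(m, 0.2, 0.05), eaf = runif(m, 0.05, 0.45))
  ou_df <- as.data.frame(ex)
  ou_df$BETA <- rnorm(m, 0.05, 0.02)
  ld <- ld_matrix(ar1(m, 0.4), ex$SNP)
  ou <- suppressMessages(summary_stats(ou_df, trait_label = "out"))
  ref <- harmonize(ex, ou, ld)

  # apply known flips/strand swaps to the outcome and re-harmonise
  flip <- seq_len(m) %% 2 == 0
  strand <- seq_len(m) %% 3 == 0
  ou2 <- ou_df
  ou2$EA[flip] <- "G"; ou2$OA[flip] <- "A"; ou2$BETA[flip] <- -ou2$BETA[flip]
  ou2$EAF[flip] <- 1 - ou2$EAF[flip]
  comp <- c(A = "T", G = "C", C = "G", T = "A")
  ou2$EA[strand] <- comp[ou2$EA[strand]]
  ou2$OA[strand] <- comp[ou2$OA[strand]]
  ou2 <- suppressMessages(summary_stats(ou2, trait_label = "out"))
  got <- harmonize(ex, ou2, ld)
  expect_equal(got$variant_ids, ref$variant_ids)
  expect_equal(got$beta_outcome, ref$beta_outcome)
  expect_equal(unclass(got$ld), unclass(ref$ld))
})

test_that("flipping every outcome effect allele leaves MR estimates invariant", {
  set.seed(3)
  m <- 8
  ex <- fix_stats(m, beta = rnorm(m, 0.2, 0.05), eaf = runif(m, 0.05, 0.4))
  ou_df <- as.data.frame(ex)
  ou_df$BETA <- 0.3 * ou_df$BETA + rnorm(m, 0, 0.01)
  ld <- ld_matrix(ar1(m, 0.5), ex$SNP)
  ou <- suppressMessages(summary_stats(ou_df, trait_label = "out"))
  fit1 <- gls_ivw(harmonize(ex, ou, ld))

  ou2 <- ou_df
  tmp <- ou2$EA; ou2$EA <- ou2$OA; ou2$OA <- tmp
  ou2$BETA <- -ou2$BETA; ou2$EAF <- 1 - ou2$EAF
  ou2 <- suppressMessages(summary_stats(ou2, trait_label = "out"))
  inp2 <- harmonize(ex, ou2, ld)
  expect_equal(inp2$beta_outcome, -ou2$BETA[match(inp2$variant_ids, ou2$SNP)])
  fit2 <- gls_ivw(inp2)
  expect_equal(fit2$estimate, fit1$estimate)
  expect_equal(fit2$se, fit1$se)
})

test_that("harmonize matches on position when ids differ and errors on no overlap", {
  ex <- fix_stats(3)
  ou_df <- as.data.frame(ex)
  ou_df$SNP <- c("1:110", "1:120", "1:130")
  ou <- suppressMessages(summary_stats(ou_df, trait_label = "out"))
  ld <- ld_matrix(diag(3), ex$SNP)
  inp <- harmonize(ex, ou, ld)
  expect_equal(length(inp$variant_ids), 3L)
  expect_true(all(inp$provenance$action == "position_match"))

  ou_far <- suppressMessages(summary_stats(transform(ou_df, POS = POS + 5000L),
                                           trait_label = "out"))
  expect_error(harmonize(ex, ou_far, ld), class = "cismr_empty_input")
})

test_that("irreconcilable allele pairs are dropped with a reason", {
  ex <- fix_stats(2, ea = c("A", "A"), oa = c("C", "G"))
  ou_df <- as.data.frame(ex)
  ou_df$EA <- c("A", "A"); ou_df$OA <- c("G", "G")  # rs01 A/G vs exposure A/C
  ou <- suppressMessages(summary_stats(ou_df, trait_label = "out"))
  ld <- ld_matrix(diag(2), ex$SNP)
  inp <- harmonize(ex, ou, ld)
  expect_equal(inp$variant_ids, "rs02")
  expect_match(inp$provenance$note[inp$provenance$action == "dropped"],
               "irreconcilable")
})
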