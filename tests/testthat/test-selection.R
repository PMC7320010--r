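# Instrument-selection grids, random-subset experiment, stratification.

make_sim_input <- function(seed = 1, m = 15, rho = 0.5, n = 4000) {
  tr <- sim_truth(m = m, delta_GE = seq(0.15, 0.4, length.out = m), mu = 2,
                  theta = 0.1, phi_P = 0.1, ld_rho = rho)
  st <- simulate_study(tr, n_exposure = n, n_outcome = n, n_panel = 1500,
                       seed = seed)
  list(study = st, input = as_harmonized(st))
}

test_that("LD-free grids are flat and a single-point grid equals clump + estimate", {
  set.seed(2)
  m <- 6
  bx <- runif(m, 0.1, 0.4)
  sy <- rep(0.02, m)
  by <- 0.3 * bx + rnorm(m, 0, sy)
  r <- ar1(m, 0.1)  # all r^2 < 0.05, below every threshold
  inp <- fix_input(bx, by, sy, r = r)
  g <- grid_search_r2(inp, thresholds = c(0.1, 0.3, 0.5, 0.9))
  expect_true(all(!is.na(g$points$estimate)))
  expect_equal(length(unique(round(g$points$estimate, 12))), 1L)
  expect_true(all(diff(g$points$n_variants) >= 0))

  g1 <- grid_search_r2(inp, thresholds = 0.1)
  cl <- clump(cismr:::ranking_stats(inp), inp$ld, 0.1)
  direct <- gls_ivw(subset_input(inp, cl$retained_ids))
  expect_equal(g1$points$estimate, direct$estimate, tolerance = 1e-12)
})

test_that("on AR(1) loci the se tightens as the threshold liberalises", {
  sim <- make_sim_input(seed = 3, rho = 0.75)
  g <- grid_search_r2(sim$input, thresholds = seq(0.1, 0.9, by = 0.2))
  ok <- which(is.na(g$points$flag))
  expect_gte(length(ok), 2)
  ses <- g$points$se[ok]
  expect_lte(ses[length(ses)], ses[1] + 1e-12)
  expect_true(all(diff(g$points$n_variants[ok]) >= 0))
})

test_that("threshold selection follows the l vs l-1 stability rule", {
  mk_grid <- function(est, se = rep(0.05, length(est)), flag = NA_character_) {
    structure(list(axis = "r2_threshold",
                   points = data.frame(axis_value = seq(0.1, by = 0.1,
                                                        length.out = length(est)),
                                       n_variants = seq_along(est),
                                       estimate = est, se = se,
                                       ci_low = est - 2 * se, ci_high = est + 2 * se,
                                       p = 0.01, intercept = NA_real_,
                                       n_screened_out = 0L,
                                       flag = rep_len(flag, length(est))),
                   chosen_index = NA_integer_),
              class = "grid_result")
  }
  # all identical: the largest threshold wins
  g <- select_threshold(mk_grid(rep(0.3, 5)))
  expect_equal(g$chosen_index, 5L)

  # planted instability from 0.8 on: selects 0.7
  est <- c(0.30, 0.30, 0.30, 0.30, 0.30, 0.31, 0.30, 1.30, 0.10)
  g2 <- select_threshold(mk_grid(est))
  expect_equal(g2$points$axis_value[g2$chosen_index], 0.7)

  # a flagged (failed) last point can never be chosen
  est3 <- c(0.3, 0.3, 0.3, NA)
  g3 <- mk_grid(est3)
  g3$points$flag[4] <- "multicollinearity"
  g3 <- select_threshold(g3)
  expect_lt(g3$chosen_index, 4L)

  # nothing stable: smallest threshold with a warning
  expect_warning(g4 <- select_threshold(mk_grid(c(0, 10, -10, 20))), "smallest")
  expect_equal(g4$chosen_index, 1L)
})

test_that("threshold selection is invariant to affine exposure rescaling", {
  sim <- make_sim_input(seed = 5)
  inp <- sim$input
  g1 <- select_threshold(grid_search_r2(inp, thresholds = seq(0.2, 0.8, by = 0.2)))
  k <- 3.7
  inp2 <- harmonized_input(inp$variant_ids, k * inp$beta_exposure,
                           k * inp$se_exposure, inp$beta_outcome,
                           inp$se_outcome, inp$ld,
                           exposure_type = inp$exposure_type,
                           outcome_scale = inp$outcome_scale, eaf = inp$eaf)
  g2 <- select_threshold(grid_search_r2(inp2, thresholds = seq(0.2, 0.8, by = 0.2)))
  expect_equal(g2$chosen_index, g1$chosen_index)
})

test_that("region grids collapse to the same estimate when flanks tie, and to the ratio at one variant", {
  sim <- make_sim_input(seed = 7, m = 10)
  st <- sim$study
  gene <- region("SIMGENE", "1", 1000000L, 1000000L + 9L * 500L, flank = 0)
  # both flanks wide enough to catch every simulated variant
  g <- grid_search_region(st$exposure, st$outcome, st$ld, gene,
                          flanks = c(10000, 20000), maf_min = 0,
                          r2_threshold = 0.9)
  expect_equal(g$points$estimate[1], g$points$estimate[2], tolerance = 1e-12)
  expect_equal(g$points$n_variants[1], g$points$n_variants[2])

  # flank 0 on a single-variant gene reduces to the ratio estimate
  gene1 <- region("SIMGENE", "1", 1000000L, 1000000L, flank = 0)
  g1 <- grid_search_region(st$exposure, st$outcome, st$ld, gene1,
                           flanks = c(0, 200), maf_min = 0)
  ex1 <- st$exposure[st$exposure$POS == 1000000L, ]
  ou1 <- st$outcome[st$outcome$POS == 1000000L, ]
  rat <- ratio_estimate(ex1$BETA, ex1$SE, ou1$BETA, ou1$SE)
  expect_equal(g1$points$estimate[1], rat$estimate, tolerance = 1e-12)
  expect_equal(g1$points$se[1], rat$se, tolerance = 1e-12)
})

test_that("a pleiotropic neighbour entering at wide flanks shifts the estimate and the Egger intercept", {
  st <- scenario("neighbour_gene_pleiotropy", seed = 11,
                 overrides = list(n_exposure = 8000, n_outcome = 8000))
  # relocate the neighbour's causal variant 500 kB away
  far_id <- sprintf("rs%04d", st$truth$m)
  for (nm in c("exposure", "outcome")) {
    st[[nm]]$POS[st[[nm]]$SNP == far_id] <- 1500000L
  }
  gene <- region("SIMGENE", "1", 1000000L, 1000000L + 500L * (st$truth$m - 2L),
                 flank = 0)
  g <- grid_search_region(st$exposure, st$outcome, st$ld, gene,
                          flanks = c(5000, 600000), maf_min = 0,
                          r2_threshold = 0.99, estimator = "gls_egger")
  narrow <- g$points[1, ]; wide <- g$points[2, ]
  expect_equal(wide$n_variants, narrow$n_variants + 1L)
  expect_gt(abs(wide$intercept), abs(narrow$intercept))
  expect_gt(abs(wide$estimate - narrow$estimate), 1e-3)
})

test_that("random-subset experiment is deterministic and degenerates correctly", {
  sim <- make_sim_input(seed = 9, m = 8, rho = 0.3)
  inp <- sim$input
  e1 <- random_subset_experiment(inp, subset_size = 4, n_iterations = 20, seed = 5,
                                 r2_max = 0.95)
  e2 <- random_subset_experiment(inp, subset_size = 4, n_iterations = 20, seed = 5,
                                 r2_max = 0.95)
  expect_identical(e1$estimates$estimate, e2$estimates$estimate)

  # subset_size = pool size: every iteration identical, zero spread
  pool_n <- length(e1$pool_ids)
  e3 <- random_subset_experiment(inp, subset_size = pool_n, n_iterations = 10,
                                 seed = 5, r2_max = 0.95)
  expect_equal(unname(diff(e3$quartiles[c(1, 3)])), 0)

  expect_error(random_subset_experiment(inp, subset_size = pool_n + 1,
                                        n_iterations = 5, seed = 1, r2_max = 0.95),
               class = "cismr_config_error")
})

test_that("subset quartiles approach the exact enumeration over all subsets", {
  sim <- make_sim_input(seed = 13, m = 7, rho = 0.3)
  inp <- sim$input
  ex <- random_subset_experiment(inp, subset_size = 4, n_iterations = 600,
                                 seed = 3, r2_max = 0.999, maf_min = 0)
  pool <- ex$pool_ids
  combos <- utils::combn(pool, 4)
  all_est <- apply(combos, 2, function(ids) {
    gls_ivw(subset_input(inp, sort(ids)))$estimate
  })
  pop_q <- quantile(all_est, c(0.25, 0.5, 0.75))
  spread <- diff(range(all_est))
  expect_lt(abs(ex$quartiles[["median"]] - pop_q[[2]]), 0.15 * spread)
  expect_lt(abs(ex$quartiles[["q1"]] - pop_q[[1]]), 0.15 * spread)
  expect_lt(abs(ex$quartiles[["q3"]] - pop_q[[3]]), 0.15 * spread)
})

test_that("homogeneous loci give direction-consistent subset estimates", {
  sim <- make_sim_input(seed = 15, m = 12, rho = 0.4, n = 6000)
  ex <- random_subset_experiment(sim$input, subset_size = 4, n_iterations = 200,
                                 seed = 2, expected_sign = +1)
  expect_gte(ex$prop_expected_direction, 0.95)
})

test_that("stratification labels by worst consequence and drops rare categories", {
  sim <- make_sim_input(seed = 17, m = 8, rho = 0.2)
  inp <- sim$input
  ex <- random_subset_experiment(inp, subset_size = 3, n_iterations = 40, seed = 4,
                                 r2_max = 0.999)
  vocab <- consequence_severity()
  ann_all <- annotation_table(data.frame(variant_id = inp$variant_ids,
                                         consequence = "intron_variant"))
  s1 <- stratify_by_annotation(ex, ann_all)
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$category, "intron_variant")
  expect_equal(s1$n_iterations, 40L)
  expect_equal(unname(s1$median), unname(ex$quartiles[["median"]]))

  # one missense variant: iterations containing it are labelled missense;
  # categories with < min_category_count iterations vanish
  cons <- rep("intron_variant", length(inp$variant_ids))
  cons[1] <- "missense_variant"
  ann <- annotation_table(data.frame(variant_id = inp$variant_ids,
                                     consequence = cons))
  s2 <- stratify_by_annotation(ex, ann, min_category_count = 5)
  n_with <- sum(vapply(ex$subsets, function(ids) inp$variant_ids[1] %in% ids,
                       logical(1)))
  if (n_with >= 5) {
    expect_setequal(s2$category, c("missense_variant", "intron_variant"))
  }
  s3 <- stratify_by_annotation(ex, ann, min_category_count = n_with + 1)
  expect_false("missense_variant" %in% s3$category)

  ann_miss <- annotation_table(data.frame(variant_id = inp$variant_ids[-1],
                                          consequence = cons[-1]))
  expect_error(stratify_by_annotation(ex, ann_miss), class = "cismr_config_error")
})

test_that("coding and non-coding tags of the same signal stratify to similar medians", {
  # planted null difference: annotations assigned independently of effects
  sim <- make_sim_input(seed = 19, m = 10, rho = 0.5, n = 6000)
  inp <- sim$input
  ex <- random_subset_experiment(inp, subset_size = 4, n_iterations = 150,
                                 seed = 6, r2_max = 0.999)
  cons <- rep("intron_variant", length(inp$variant_ids))
  cons[c(2, 5, 8)] <- "missense_variant"
  ann <- annotation_table(data.frame(variant_id = inp$variant_ids,
                                     consequence = cons))
  s <- stratify_by_annotation(ex, ann, min_category_count = 5)
  if (nrow(s) == 2L) {
    iqr_within <- max(s$q3 - s$q1)
    expect_lt(abs(diff(s$median)), iqr_within + 1e-12)
  }
})
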