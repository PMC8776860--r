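test_that("exclusion filters remove the declared rows and are idempotent", {
  tb <- data.frame(
    patient_id = paste0("p", 1:10),
    os_months = c(10, -1, NA, 20, 5, 8, 30, 12, 7, 14),
    os_event = c(TRUE, TRUE, TRUE, NA, FALSE, TRUE, FALSE, TRUE, TRUE, FALSE),
    stage_group = c("early", "early", "late", "late", "excluded", "early",
                    "late", "early", "late", "early"))
  got <- quiet(filter_tcga_cohort(tb))
  expect_equal(nrow(got), 6L)   # drops OS<0, missing OS, missing status, stage
  expect_setequal(got$patient_id,
                  c("p1", "p6", "p7", "p8", "p9", "p10"))
  expect_equal(quiet(filter_tcga_cohort(got)), got)
  # no violations: unchanged
  clean <- tb[c(1, 6, 7), ]
  expect_equal(quiet(filter_tcga_cohort(clean))$patient_id, clean$patient_id)
  all_bad <- tb[2:3, ]
  expect_error(quiet(filter_tcga_cohort(all_bad)), "no patients remain")
})

test_that("median split follows the ties-to-low convention", {
  expect_equal(as.character(quiet(median_split(c(1, 2, 3, 4)))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(quiet(median_split(c(1, 2, 2, 3)))),
               c("low", "low", "low", "high"))
  expect_equal(as.character(quiet(median_split(c(1, 2, 3)))),
               c("low", "low", "high"))
  expect_error(quiet(median_split(rep(3, 4))), "constant")
})

test_that("Kaplan-Meier matches the empirical survivor function without censoring", {
  km <- kaplan_meier(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km_surv_at(km, 2), 0.5)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  set.seed(77)
  t <- rexp(300, 0.1)
  km2 <- kaplan_meier(t, rep(1, 300))
  grid <- quantile(t, c(0.1, 0.4, 0.8))
  expect_equal(km_surv_at(km2, grid),
               vapply(grid, function(g) mean(t > g), numeric(1)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_warning(kaplan_meier(c(1, 2), c(0, 0)), "no events")
})

test_that("log-rank is null on identical groups and powered on separated ones", {
  t <- c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5)
  e <- rep(1, 10)
  g <- rep(c("a", "b"), each = 5)
  res <- log_rank(t, e, g)
  expect_equal(res$chisq, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1, tolerance = 1e-10)
  expect_error(log_rank(t, e, rep("a", 10)), ">= 2 groups")
  # HR 3 separation, n = 200/arm: decisive at the fixed seed
  set.seed(15)
  t2 <- c(rexp(200, 0.01), rexp(200, 0.03))
  res2 <- log_rank(t2, rep(1, 400), rep(c("a", "b"), each = 200))
  expect_lt(res2$p_value, 1e-3)
})

test_that("per-IQR Cox HR is scale-invariant and recovers programmed effects", {
  cfg <- surv_sim_config(n = 800, betas = c(sox10_z = log(2)),
                         baseline_hazard = 0.01, censor_rate = 0.003,
                         seed = 20)
  tb <- simulate_survival_cohort(cfg)
  fit <- cox_per_iqr(tb$os_months, tb$os_event, tb$sox10_z)
  h <- fit$hr_per_iqr$x
  expect_true(h["lo"] <= h["hr"] && h["hr"] <= h["hi"])
  # affine rescaling of the covariate leaves the per-IQR HR unchanged
  fit2 <- cox_per_iqr(tb$os_months, tb$os_event, 100 * tb$sox10_z + 7)
  expect_equal(unname(fit2$hr_per_iqr$x["hr"]), unname(h["hr"]),
               tolerance = 1e-8)
  expect_error(cox_per_iqr(tb$os_months, tb$os_event, rep(1, nrow(tb))),
               "constant")
  expect_error(cox_per_iqr(tb$os_months, rep(0, nrow(tb)), tb$sox10_z),
               "zero events")
})

test_that("stratified interaction models recover a programmed interaction", {
  cfg <- surv_sim_config(
    n = 1000, betas = c(sox10_z = 0.3, immune_score = -0.4),
    interaction = c("immune_score:sox10_z" = 0.8),
    baseline_hazard = 0.01, censor_rate = 0.002, seed = 33)
  tb <- simulate_survival_cohort(cfg)
  fits <- stratified_cox_interaction(tb, "immune_score", "sox10_z")
  inter_term <- grep(":", names(fits$full$coefficients), value = TRUE)
  beta_hat <- fits$full$coefficients[[inter_term]]["beta"]
  expect_lt(abs(beta_hat - 0.8), 0.2)
  expect_equal(fits$full$df - fits$reduced$df, 1L)
  expect_true(all(c("hr", "lo", "hi") %in% names(fits$marker_hr_adjusted)))
})

test_that("LR test bookkeeping: zero statistic on equal models, df = added terms", {
  cfg <- surv_sim_config(n = 300, betas = c(sox10_z = 0.3,
                                            immune_score = -0.3),
                         censor_rate = 0.002, seed = 40)
  tb <- simulate_survival_cohort(cfg)
  fits <- stratified_cox_interaction(tb, "immune_score", "sox10_z")
  same <- lr_test(fits$reduced, fits$reduced)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  lr <- lr_test(fits$full, fits$reduced)
  expect_equal(lr$df, 1L)
  expect_gte(lr$statistic, 0)
  expect_error(lr_test(fits$reduced, fits$full), "not nested")
})

test_that("c-index: perfect ordering gives 1, random scores sit near 0.5", {
  t <- sort(rexp(100, 0.05), decreasing = TRUE)
  risk <- seq_len(100)   # highest risk has shortest time
  expect_equal(harrell_c(t, rep(1, 100), risk), 1)
  set.seed(50)
  t2 <- rexp(500, 0.05)
  expect_gt(harrell_c(t2, rep(1, 500), rnorm(500)), 0.45)
  expect_lt(harrell_c(t2, rep(1, 500), rnorm(500)), 0.55)
})

test_that("bootstrap optimism correction shrinks an overfit model's c-index", {
  set.seed(60)
  n <- 60
  tb <- data.frame(os_months = rexp(n, 0.05), os_event = 1)
  for (j in 1:10) tb[[paste0("noise", j)]] <- rnorm(n)
  res <- quiet(c_index_optimism(tb, paste0("noise", 1:10), B = 60, seed = 61))
  expect_gt(res$optimism, 0)
  expect_lt(res$corrected, res$apparent)
  # deterministic given seed
  res2 <- quiet(c_index_optimism(tb, paste0("noise", 1:10), B = 60,
                                 seed = 61))
  expect_equal(res, res2)
  expect_error(c_index_optimism(tb, "noise1", B = 10), "B must be >= 50")
})

test_that("subgroup expression tests apply the exact Bonferroni rule", {
  set.seed(70)
  n <- 200
  tb <- data.frame(sox10_z = rnorm(n), cd8a_expr = rlnorm(n))
  tb$expr_IFNG <- rep(1, n)          # identical response everywhere
  grp_shift <- tb$sox10_z > median(tb$sox10_z) &
    tb$cd8a_expr > median(tb$cd8a_expr)
  tb$expr_GZMB <- rnorm(n) + ifelse(grp_shift, 50, 0)
  res <- quiet(subgroup_expression_tests(tb, "sox10_z", "cd8a_expr",
                                         c("expr_IFNG", "expr_GZMB")))
  expect_equal(nrow(res), 12L)       # 6 pairwise comparisons x 2 genes
  ifng <- res[res$response == "expr_IFNG", ]
  expect_true(all(ifng$p_bonferroni == 1))
  # the shifted subgroup's three comparisons are decisive
  gz <- res[res$response == "expr_GZMB" &
            (res$group1 == "hi_hi" | res$group2 == "hi_hi"), ]
  expect_equal(nrow(gz), 3L)
  expect_true(all(gz$p_bonferroni < 0.01))
  # adjusted p = min(1, 6 * raw) exactly
  ok <- !res$flagged
  expect_equal(res$p_bonferroni[ok], pmin(1, 6 * res$p_raw[ok]))
})

test_that("subgroup comparisons with tiny subgroups are flagged, not computed", {
  tb <- data.frame(sox10_z = c(-2, -1, 1, 2, 3, 4),
                   cd8a_expr = c(1, 2, 3, 4, 5, 6),
                   expr_IFNG = rnorm(6))
  res <- quiet(subgroup_expression_tests(tb, "sox10_z", "cd8a_expr",
                                         "expr_IFNG"))
  expect_true(any(res$flagged))
  expect_true(all(is.na(res$p_bonferroni[res$flagged])))
})

test_that("linear interaction model recovers exact and noisy coefficients", {
  set.seed(80)
  n <- 400
  tb <- data.frame(sox10_z = rnorm(n), cd8a_expr = 2^rnorm(n, 3))
  # exact: y = 1 + 0.5 * sox10, no CD8 terms
  tb$expr_A <- 2^(1 + 0.5 * tb$sox10_z)
  res <- quiet(linear_interaction(tb, "expr_A"))
  expect_equal(res$estimate, c(1, 0.5, 0, 0), tolerance = 1e-9)
  # interaction truth 0.5 with noise
  l2 <- log2(tb$cd8a_expr)
  tb$expr_B <- 2^(0.2 + 0.3 * tb$sox10_z + 0.1 * l2 +
                  0.5 * tb$sox10_z * l2 + rnorm(n, 0, 0.1))
  res2 <- quiet(linear_interaction(tb, "expr_B"))
  expect_lt(abs(res2$estimate[4] - 0.5), 0.05)
  # non-positive expression rows are excluded with a logged count
  tb$expr_B[1:5] <- 0
  expect_message(linear_interaction(tb, "expr_B"), "excluded")
})
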