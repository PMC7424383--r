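test_that("median split sends ties to the low group", {
  s1 <- median_split(setNames(c(1, 2, 3, 4), paste0("P", 1:4)))
  expect_equal(s1$split_value, 2.5)
  expect_equal(as.character(s1$group), c("low", "low", "high", "high"))
  s2 <- median_split(setNames(c(1, 2, 2, 3), paste0("P", 1:4)))
  expect_equal(s2$split_value, 2)
  expect_equal(sum(s2$group == "high"), 1)
  expect_equal(sum(s2$group == "low"), 3)
  expect_error(median_split(setNames(rep(1, 5), paste0("P", 1:5))),
               "degenerate")
  expect_error(median_split(setNames(1:3, paste0("P", 1:3))), ">= 4")
})

test_that("log-rank is zero on mirrored groups and label-symmetric", {
  # two groups that are exact copies of each other
  clin <- clinical_table(data.frame(
    sample_id = paste0("P", 1:8),
    time_days = rep(c(30, 60, 90, 120), 2),
    event = rep(c(1, 0, 1, 1), 2)))
  split <- split_from_groups(paste0("P", 1:8), rep(c("low", "high"), each = 4))
  lr <- logrank_test(split, clin)
  expect_equal(lr$chi_square, 0, tolerance = 1e-10)
  expect_equal(lr$p, 1, tolerance = 1e-10)
  expect_equal(sum(lr$observed), sum(lr$expected), tolerance = 1e-9)

  # swapping group labels leaves the statistic unchanged
  set.seed(12)
  clin2 <- random_clinical(30)
  g <- sample(c("low", "high"), 30, replace = TRUE, prob = c(0.5, 0.5))
  lr_a <- logrank_test(split_from_groups(clin2$sample_id, g), clin2)
  g_swap <- ifelse(g == "low", "high", "low")
  lr_b <- logrank_test(split_from_groups(clin2$sample_id, g_swap), clin2)
  expect_equal(lr_a$chi_square, lr_b$chi_square, tolerance = 1e-9)
})

test_that("log-rank matches the hand-built risk-table oracle", {
  # 6 patients, all events: A at (1,2,3), B at (4,5,6)
  clin <- clinical_table(data.frame(
    sample_id = paste0("P", 1:6), time_days = 1:6, event = 1))
  grp <- rep(c("low", "high"), each = 3)
  lr <- logrank_test(split_from_groups(clin$sample_id, grp), clin)
  orc <- logrank_oracle(clin$time_days, clin$event, grp)
  expect_equal(lr$chi_square, orc$chi_square, tolerance = 1e-9)
  expect_equal(lr$p, orc$p, tolerance = 1e-9)

  # random censored cohorts, with ties
  set.seed(8)
  for (i in 1:20) {
    n <- sample(10:25, 1)
    clin_i <- clinical_table(data.frame(
      sample_id = paste0("P", 1:n),
      time_days = sample(1:12, n, replace = TRUE),
      event = rbinom(n, 1, 0.7)))
    g_i <- c("low", "high", sample(c("low", "high"), n - 2, replace = TRUE))
    if (sum(clin_i$event) == 0) next
    lr_i <- suppressWarnings(
      logrank_test(split_from_groups(clin_i$sample_id, g_i), clin_i))
    orc_i <- logrank_oracle(clin_i$time_days, clin_i$event, g_i)
    expect_equal(lr_i$chi_square, orc_i$chi_square, tolerance = 1e-8)
  }
})

test_that("KM curve equals the closed form and the product-limit oracle", {
  # no events -> survival stays at 1
  clin0 <- clinical_table(data.frame(
    sample_id = paste0("P", 1:6), time_days = 1:6, event = 0))
  km0 <- km_curve(split_from_groups(clin0$sample_id,
                                    rep(c("low", "high"), 3)), clin0)
  expect_true(all(km0$surv == 1))

  # n=2 in a group, events at t=1,2 -> S = 0.5 then 0
  clin2 <- clinical_table(data.frame(
    sample_id = paste0("P", 1:6),
    time_days = c(1, 2, 5, 6, 7, 8), event = c(1, 1, 1, 0, 1, 0)))
  grp <- c("low", "low", "high", "high", "high", "high")
  km2 <- km_curve(split_from_groups(clin2$sample_id, grp), clin2)
  lowc <- km2[km2$group == "low", ]
  expect_equal(lowc$surv[lowc$time == 1], 0.5)
  expect_equal(lowc$surv[lowc$time == 2], 0)

  # oracle equivalence on random small cohorts
  set.seed(15)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    clin_i <- clinical_table(data.frame(
      sample_id = paste0("P", 1:n),
      time_days = sample(1:10, n, replace = TRUE),
      event = rbinom(n, 1, 0.6)))
    grp_i <- rep(c("low", "high"), length.out = n)
    km_i <- km_curve(split_from_groups(clin_i$sample_id, grp_i), clin_i)
    for (g in c("low", "high")) {
      idx <- grp_i == g
      orc <- km_oracle(clin_i$time_days[idx], clin_i$event[idx])
      got <- km_i[km_i$group == g & km_i$n_event > 0, ]
      expect_equal(got$surv[match(orc$time, got$time)], orc$surv,
                   tolerance = 1e-12)
    }
    # non-increasing within group
    expect_true(all(tapply(km_i$surv, km_i$group,
                           function(s) all(diff(s) <= 1e-12))))
  }
})

test_that("Cox fit recovers a known coefficient and flags degeneracy", {
  set.seed(44)
  betas <- replicate(5, {
    n <- 500
    X <- matrix(scale(rnorm(n)), n, 1,
                dimnames = list(paste0("P", 1:n), "x"))
    clin <- simulate_survival(X, 0.8)
    fit_cox(X, clin)$betas
  })
  expect_true(all(betas > 0.65 & betas < 0.95))

  # null feature -> small coefficient
  set.seed(45)
  n <- 500
  X <- matrix(scale(rnorm(n)), n, 1, dimnames = list(paste0("P", 1:n), "x"))
  clin <- simulate_survival(matrix(0, n, 1,
                                   dimnames = list(rownames(X), "z")), 0)
  expect_lt(abs(fit_cox(X, clin)$betas), 0.2)

  # two identical copies of a feature -> collinearity error
  X2 <- cbind(x1 = X[, 1], x2 = X[, 1])
  rownames(X2) <- rownames(X)
  expect_error(fit_cox(X2, clin), "collinear")

  # too few events
  clin_few <- clinical_table(data.frame(
    sample_id = rownames(X), time_days = rexp(n, 1 / 100) + 1,
    event = c(rep(1, 5), rep(0, n - 5))))
  expect_error(fit_cox(X, clin_few), ">= 10")
})

test_that("risk score is the plain linear predictor", {
  X <- matrix(c(1, 2, 3), 1, 3,
              dimnames = list("P1", c("L", "M", "G")))
  expect_equal(unname(risk_score(c(L = 0.5, M = -0.2, G = 0.1), X)), 0.4)
  # all-zero standardized features score 0
  X0 <- matrix(0, 1, 3, dimnames = list("P1", c("L", "M", "G")))
  expect_equal(unname(risk_score(c(L = 0.5, M = -0.2, G = 0.1), X0)), 0)
})

test_that("triplet risk analysis separates survival on a planted cohort", {
  co <- simulate_cohort(seed = 6)
  tr <- co$truth$designated_triplet
  rm1 <- triplet_risk_analysis(tr, log_cpm(co$lncrna), log_cpm(co$mirna),
                               log_cpm(co$mrna), co$clinical)
  expect_s3_class(rm1, "RiskModel")
  expect_length(rm1$betas, 3)
  expect_lt(rm1$logrank$p, 0.05)
  # recovered signs of the strong positive coefficients (miRNA's -0.5 is
  # within one sampling sd of zero at n = 100, so its sign is not asserted
  # for a single seed)
  expect_gt(rm1$betas[1], 0)
  expect_gt(rm1$betas[3], 0)
  # risk scores reproduce Eq-style arithmetic against the stored betas
  samples <- names(rm1$risk_scores)
  expect_equal(length(samples), rm1$n)
  # high-risk group dies faster: worse KM at median follow-up
  km <- rm1$km
  expect_gt(mean(km$surv[km$group == "low"]),
            mean(km$surv[km$group == "high"]))

  # missing member is an informative error
  bad <- tr; bad$mrna_id <- "NOPE"
  expect_error(triplet_risk_analysis(bad, log_cpm(co$lncrna),
                                     log_cpm(co$mirna), log_cpm(co$mrna),
                                     co$clinical), "absent")
})

test_that("single-gene survival screening runs the median-split log-rank", {
  co <- simulate_cohort(seed = 26)
  g <- co$truth$designated_triplet$mrna_id
  gs <- gene_survival(g, log_cpm(co$mrna), co$clinical)
  expect_s3_class(gs$logrank, "LogRankResult")
  expect_true(all(c("low", "high") %in% gs$km$group))
  expect_error(gene_survival("NOPE", log_cpm(co$mrna), co$clinical),
               "not in matrix")
})
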