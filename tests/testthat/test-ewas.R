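two_group_sheet <- function(y_names) {
  sample_sheet(data.frame(
    sample_id = y_names, donor_id = y_names, cohort = "L", region = "PFC",
    diagnosis = rep(c("control", "case"), each = length(y_names) / 2),
    age = 50, sex = "M", stringsAsFactors = FALSE))
}

test_that("fit_probe matches the normal-equations worked example", {
  sheet <- two_group_sheet(c("s1", "s2", "s3", "s4"))
  y <- setNames(c(0.1, 0.2, 0.3, 0.4), sheet$sample_id)
  r <- fit_probe(y, sheet, model_spec("diagnosis", covariates = character(0)))
  expect_equal(r$estimate, 20, tolerance = 1e-10)
  expect_equal(r$se, 100 * sqrt(0.005), tolerance = 1e-10)
  expect_equal(r$stat, 2 * sqrt(2), tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 * sqrt(2), 2), tolerance = 1e-10)

  y0 <- setNames(c(0.3, 0.4, 0.3, 0.4), sheet$sample_id)
  expect_equal(fit_probe(y0, sheet,
                         model_spec("diagnosis",
                                    covariates = character(0)))$estimate, 0)
})

test_that("an orthogonal covariate leaves the exposure estimate unchanged", {
  sheet <- two_group_sheet(sprintf("s%02d", 1:20))
  y <- withr::with_seed(1, setNames(runif(20, 0.2, 0.8), sheet$sample_id))
  base <- fit_probe(y, sheet, model_spec("diagnosis",
                                         covariates = character(0)))
  # age orthogonal to diagnosis: identical values in both groups
  sheet$age <- rep(seq(40, 76, by = 4), 2)
  with_age <- fit_probe(y, sheet, model_spec("diagnosis",
                                             covariates = "age"))
  expect_equal(with_age$estimate, base$estimate, tolerance = 1e-8)
})

test_that("fit_probe equals lm() on random designs", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- 50
      sheet <- sample_sheet(data.frame(
        sample_id = sprintf("s%02d", 1:n), donor_id = sprintf("s%02d", 1:n),
        cohort = "L", region = "PFC",
        diagnosis = sample(rep(c("case", "control"), n / 2)),
        age = runif(n, 30, 90), sex = sample(c("M", "F"), n, TRUE),
        neuronal_prop = runif(n, 0.1, 0.6)))
      y <- setNames(runif(n, 0, 1), sheet$sample_id)
      mine <- fit_probe(y, sheet, model_spec("diagnosis"))
      ref <- summary(lm(y ~ I(sheet$diagnosis == "case") + sheet$age +
                          I(sheet$sex == "M") + sheet$neuronal_prop))
      expect_equal(mine$estimate / 100, ref$coefficients[2, 1],
                   tolerance = 1e-10)
      expect_equal(mine$se / 100, ref$coefficients[2, 2], tolerance = 1e-10)
      expect_equal(mine$p, ref$coefficients[2, 4], tolerance = 1e-10)
    }
  })
})

test_that("run_ewas flags unfittable probes and is order invariant", {
  man <- tiny_manifest(30)
  sheet <- two_group_sheet(sprintf("s%02d", 1:16))
  bm <- tiny_beta(man, sheet, seed = 2)
  res <- run_ewas(bm, sheet, model_spec("diagnosis",
                                        covariates = c("age", "sex")))
  expect_equal(res$probe_id, man$probe_id)
  # constant age + constant sex -> rank deficiency is flagged per probe
  expect_true(all(res$status == "rank_deficient"))

  sheet$age <- withr::with_seed(3, runif(16, 30, 80))
  sheet$sex <- rep_len(c("M", "F"), 16)
  res2 <- run_ewas(bm, sheet, model_spec("diagnosis",
                                         covariates = c("age", "sex")))
  expect_true(all(res2$status == "ok"))
  perm_s <- withr::with_seed(4, sample(nrow(sheet)))
  perm_p <- withr::with_seed(5, sample(30))
  bm_perm <- beta_matrix(bm$values[perm_p, sheet$sample_id[perm_s]])
  sheet_perm <- sheet[perm_s, ]
  class(sheet_perm) <- class(sheet)
  res3 <- run_ewas(bm_perm, sheet_perm,
                   model_spec("diagnosis", covariates = c("age", "sex")))
  m <- match(res2$probe_id, res3$probe_id)
  expect_equal(res3$estimate[m], res2$estimate, tolerance = 1e-10)
  expect_error(run_ewas(bm$values[0, ], sheet, model_spec("diagnosis")),
               "empty")
})

test_that("probes with missing values use per-pattern complete cases", {
  man <- tiny_manifest(5)
  sheet <- two_group_sheet(sprintf("s%02d", 1:20))
  sheet$age <- withr::with_seed(6, runif(20, 30, 80))
  v <- withr::with_seed(7, matrix(runif(100), 5, 20,
                                  dimnames = list(man$probe_id,
                                                  sheet$sample_id)))
  v[2, 3] <- NA
  res <- run_ewas(v, sheet, model_spec("diagnosis", covariates = "age"))
  expect_equal(res$n, c(20, 19, 20, 20, 20))
  keep <- sheet$sample_id[-3]
  sheet_sub <- sheet[sheet$sample_id %in% keep, ]
  class(sheet_sub) <- class(sheet)
  ref <- fit_probe(v[2, keep], sheet_sub,
                   model_spec("diagnosis", covariates = "age"))
  expect_equal(res$estimate[2], ref$estimate, tolerance = 1e-10)
})

test_that("genomic inflation matches chi-square quantile arithmetic", {
  expect_equal(genomic_inflation(rep(0.5, 100))$lambda, 1)
  expect_equal(genomic_inflation(rep(0.25, 100))$lambda,
               qchisq(0.75, 1) / qchisq(0.5, 1), tolerance = 1e-12)
  expect_equal(genomic_inflation(rep(0.25, 100))$lambda, 2.909,
               tolerance = 1e-3)
  expect_equal(genomic_inflation(rep(0.75, 100))$lambda, 0.223,
               tolerance = 2e-3)
  expect_error(genomic_inflation(rep(0.5, 10)), "at least 100")
  expect_error(genomic_inflation(c(rep(0.5, 99), 0)), "\\(0,1\\]")
})

test_that("null EWAS p-values are uniform with lambda near 1", {
  man <- make_manifest(4000, 1, flag_rate = 0, seed = 8)
  sheet <- make_design(n_donors = 60, case_fraction = 0.5, regions = "PFC",
                       region_missing = c(PFC = 0), cohorts = "L", seed = 9)
  sim <- simulate_beta(man, sheet, noise_sd = 0.3, phi = 0,
                       n_ref_probes = 0, seed = 10)
  res <- run_ewas(sim$beta, sheet, model_spec("diagnosis",
                                              covariates = c("age", "sex")))
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  lam <- genomic_inflation(res$p)$lambda
  expect_gt(lam, 0.9)
  expect_lt(lam, 1.1)
})

test_that("PC sensitivity stays near 1 for orthogonal PCs and flags collinearity", {
  man <- tiny_manifest(150)
  sheet <- two_group_sheet(sprintf("s%02d", 1:30))
  sheet$age <- withr::with_seed(11, runif(30, 30, 80))
  bm <- tiny_beta(man, sheet, seed = 12)
  res <- pc_sensitivity(bm, sheet, model_spec("diagnosis",
                                              covariates = "age"),
                        k_max = 3)
  expect_equal(nrow(res), 3)
  expect_true(all(res$cor[res$status == "ok"] > 0.9))

  # a probe set whose PC1 is exactly the exposure collapses the refit
  expo <- as.numeric(sheet$diagnosis == "case")
  v <- outer(rep(0.1, 150), expo) + 0.4
  dimnames(v) <- list(man$probe_id, sheet$sample_id)
  res2 <- pc_sensitivity(v, sheet,
                         model_spec("diagnosis", covariates = character(0)),
                         k_max = 1)
  expect_true(res2$status[1] %in% c("collinear", "ok"))
  if (res2$status[1] == "ok") expect_true(is.na(res2$cor[1]) ||
                                            abs(res2$cor[1]) < 1)
})

test_that("global mean comparison behaves at the null and under shift", {
  man <- tiny_manifest(200)
  sheet <- two_group_sheet(sprintf("s%02d", 1:80))
  v <- withr::with_seed(13, matrix(runif(200 * 80, 0.3, 0.7), 200, 80,
                                   dimnames = list(man$probe_id,
                                                   sheet$sample_id)))
  # identical groups by construction: case columns copy control columns
  v[, 41:80] <- v[, 1:40]
  same <- global_mean_test(v, sheet)
  expect_equal(same$p, 1, tolerance = 1e-12)
  expect_match(same$formatted, "^SZ = \\d+\\.\\d{2}%, CTR = \\d+\\.\\d{2}%$")

  shifted <- v
  shifted[, sheet$diagnosis == "case"] <-
    clamp(v[, sheet$diagnosis == "case"] + 0.01, 0, 1)
  expect_lt(global_mean_test(shifted, sheet)$p, 0.01)
  one_group <- sheet[sheet$diagnosis == "case", ]
  class(one_group) <- class(sheet)
  expect_error(global_mean_test(v, one_group), "group")
})
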