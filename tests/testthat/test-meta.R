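test_that("Welch summary test matches high-precision arithmetic", {
  r <- welch_from_summary(1, 1, 10, 2, 1, 10)
  expect_equal(r$t, -1 / sqrt(0.2), tolerance = 1e-12)
  expect_equal(r$t, -2.236, tolerance = 1e-3)
  expect_equal(r$df, 18, tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-sqrt(5), 18), tolerance = 1e-12)
  expect_equal(round(r$p, 3), 0.038)

  same <- welch_from_summary(5, 2, 10, 5, 2, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  degen_eq <- welch_from_summary(3, 0, 5, 3, 0, 5)
  expect_equal(degen_eq$p, 1)
  expect_true(degen_eq$degenerate)
  degen_ne <- welch_from_summary(3, 0, 5, 4, 0, 5)
  expect_equal(degen_ne$p, 0)

  # cross-check against t.test on raw data reconstructed to the summaries
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  ref <- t.test(x, y)
  mine <- welch_from_summary(mean(x), sd(x), 4, mean(y), sd(y), 4)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-10)
})

test_that("fixed-effects pooling follows the inverse-variance closed form", {
  single <- meta_fixed(0.3, 0.1)
  expect_equal(single$estimate, 0.3)
  expect_equal(single$se, 0.1)

  eq <- meta_fixed(c(0.5, 0.2), c(0.1, 0.1))
  expect_equal(eq$estimate, 0.35)
  expect_equal(eq$se, 0.1 / sqrt(2), tolerance = 1e-12)

  r <- meta_fixed(c(0.5, 0.2), c(0.1, 0.2))
  expect_equal(r$estimate, (100 * 0.5 + 25 * 0.2) / 125, tolerance = 1e-14)
  expect_equal(r$estimate, 0.44, tolerance = 1e-12)
  expect_equal(r$se, sqrt(1 / 125), tolerance = 1e-14)
  expect_equal(r$z, 4.92, tolerance = 1e-2)
  expect_error(meta_fixed(c(1, 2), c(0.1, 0)), "> 0")
})

test_that("fixed-effects pooling agrees with metafor and obeys invariances", {
  skip_if_not_installed("metafor")
  withr::with_seed(21, {
    for (rep in 1:5) {
      k <- sample(2:5, 1)
      th <- rnorm(k); se <- runif(k, 0.05, 0.5)
      mine <- meta_fixed(th, se)
      ref <- metafor::rma(yi = th, sei = se, method = "FE")
      expect_equal(mine$estimate, as.numeric(ref$beta), tolerance = 1e-10)
      expect_equal(mine$se, ref$se, tolerance = 1e-10)
      expect_equal(mine$p, ref$pval, tolerance = 1e-10)
      # cohort order invariance and scale equivariance
      o <- sample(k)
      expect_equal(meta_fixed(th[o], se[o])$estimate, mine$estimate,
                   tolerance = 1e-14)
      sc <- meta_fixed(3 * th, 3 * se)
      expect_equal(sc$estimate, 3 * mine$estimate, tolerance = 1e-12)
      expect_equal(sc$z, mine$z, tolerance = 1e-12)
      # combined se below the smallest cohort se, decreasing as cohorts add
      expect_lte(mine$se, min(se))
      if (k > 2)
        expect_lt(mine$se, meta_fixed(th[-1], se[-1])$se)
    }
  })
})

test_that("group-summary meta reduces to the expected special cases", {
  one <- meta_from_groups(data.frame(mean1 = 0.6, sd1 = 0.1, n1 = 10,
                                     mean0 = 0.5, sd0 = 0.2, n0 = 12))
  expect_equal(one$estimate, 0.1, tolerance = 1e-12)
  expect_equal(one$se, sqrt(0.01 / 10 + 0.04 / 12), tolerance = 1e-12)

  two_same <- meta_from_groups(data.frame(
    mean1 = c(0.6, 0.6), sd1 = 0.1, n1 = 10,
    mean0 = c(0.5, 0.5), sd0 = 0.2, n0 = 12))
  expect_equal(two_same$estimate, one$estimate, tolerance = 1e-12)
  expect_equal(two_same$se, one$se / sqrt(2), tolerance = 1e-12)

  # definitional equivalence with meta_fixed on the same (MD, se) pairs
  s <- data.frame(mean1 = c(0.7, 0.55), sd1 = c(0.15, 0.12),
                  n1 = c(20, 18), mean0 = c(0.5, 0.52),
                  sd0 = c(0.2, 0.1), n0 = c(23, 15))
  md <- s$mean1 - s$mean0
  se <- sqrt(s$sd1^2 / s$n1 + s$sd0^2 / s$n0)
  expect_equal(meta_from_groups(s)$estimate, meta_fixed(md, se)$estimate,
               tolerance = 1e-12)
  expect_equal(meta_from_groups(s)$p, meta_fixed(md, se)$p,
               tolerance = 1e-12)
  expect_warning(meta_from_groups(data.frame(
    mean1 = c(1, 1), sd1 = 1, n1 = c(10, 1), mean0 = 0, sd0 = 1,
    n0 = 10)), "n < 2")
})

test_that("adjusted betas preserve the group contrast net of covariates", {
  sheet <- tiny_sheet(10, 10)
  # ages balanced across groups so the raw and adjusted contrasts agree
  sheet$age <- rep(withr::with_seed(22, runif(10, 30, 80)), 2)
  y <- withr::with_seed(23, 0.4 + 0.002 * sheet$age +
                          0.05 * (sheet$diagnosis == "case") +
                          rnorm(20, 0, 0.01))
  names(y) <- sheet$sample_id
  adj <- adjust_betas(y, sheet, covariates = "age")
  d <- mean(adj[sheet$diagnosis == "case"]) -
    mean(adj[sheet$diagnosis == "control"])
  expect_lt(abs(d - 0.05), 0.02)
})

test_that("meta_ewas pools per-probe tables over the common probes", {
  t1 <- data.frame(probe_id = c("p1", "p2", "p3"), estimate = c(1, 2, 3),
                   se = c(0.5, 0.5, 0.5), stat = 0, p = 0.5, n = 40,
                   df = 36, status = "ok")
  t2 <- data.frame(probe_id = c("p2", "p3"), estimate = c(2, 1),
                   se = c(0.5, 1), stat = 0, p = 0.5, n = 30, df = 26,
                   status = "ok")
  res <- meta_ewas(list(a = t1, b = t2))
  expect_equal(res$probe_id, c("p2", "p3"))
  expect_equal(res$estimate[1], 2)
  expect_equal(res$se[1], 0.5 / sqrt(2), tolerance = 1e-12)
  m <- meta_fixed(c(3, 1), c(0.5, 1))
  expect_equal(res$estimate[2], m$estimate, tolerance = 1e-12)
})

test_that("the cross-region model collapses to OLS without variance components", {
  sheet <- make_design(n_donors = 30, case_fraction = 0.5,
                       regions = c("PFC", "STR"),
                       region_missing = c(PFC = 0, STR = 0),
                       hc_cohorts = NULL, cohorts = "L", seed = 31)
  withr::with_seed(32, {
    long <- data.frame(beta = runif(nrow(sheet), 0.3, 0.7), sheet,
                       stringsAsFactors = FALSE)
  })
  fit <- fit_cross_region(long, "diagnosis")
  ref <- summary(lm(beta ~ I(diagnosis == "case") + I(sex == "M") + age,
                    data = long))$coefficients
  # independent samples: variance components ~ 0, estimate matches pooled OLS
  expect_equal(fit$estimate / 100, ref[2, 1], tolerance = 1e-5)
  vc <- attr(fit, "varcomp")
  expect_true(all(vc >= -1e-12))
})

test_that("donor correlation widens the cross-region standard error", {
  sheet <- make_design(n_donors = 10, case_fraction = 0.5,
                       regions = c("PFC", "STR"),
                       region_missing = c(PFC = 0, STR = 0),
                       hc_cohorts = NULL, cohorts = "L", seed = 33)
  withr::with_seed(34, {
    donor_effect <- rnorm(10, 0, 0.08)
    names(donor_effect) <- unique(sheet$donor_id)
    long <- data.frame(
      beta = 0.5 + donor_effect[sheet$donor_id] +
        rnorm(nrow(sheet), 0, 0.03),
      sheet, stringsAsFactors = FALSE)
  })
  fit <- fit_cross_region(long, "diagnosis")
  ols_se <- summary(lm(beta ~ I(diagnosis == "case") + I(sex == "M") + age,
                       data = long))$coefficients[2, 2]
  expect_gt(fit$se / 100, ols_se)
})

test_that("the cross-region model recovers a homogeneous effect", {
  errs <- vapply(1:5, function(s) {
    sheet <- make_design(n_donors = 40, case_fraction = 0.5,
                         regions = c("PFC", "STR", "HC"),
                         region_missing = c(PFC = 0, STR = 0, HC = 0),
                         hc_cohorts = NULL, seed = 40 + s)
    withr::with_seed(50 + s, {
      donor_effect <- stats::setNames(rnorm(40, 0, 0.008),
                                      unique(sheet$donor_id))
      region_effect <- stats::setNames(rnorm(3, 0, 0.01),
                                       c("PFC", "STR", "HC"))
      long <- data.frame(
        beta = 0.45 + 0.03 * (sheet$diagnosis == "case") +
          donor_effect[sheet$donor_id] + region_effect[sheet$region] +
          rnorm(nrow(sheet), 0, 0.012),
        sheet, stringsAsFactors = FALSE)
    })
    fit_cross_region(long, "diagnosis")$estimate / 100 - 0.03
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.01)
})
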