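test_that("sample detection filter applies the strict > 1% rule", {
  man <- tiny_manifest(200)
  sheet <- tiny_sheet(3, 3)
  bm <- tiny_beta(man, sheet)
  res <- filter_samples_by_detection(bm)
  expect_equal(res$retained, sheet$sample_id)  # all detection p = 0

  # sample with exactly 2% failing probes is removed; exactly 1% is kept
  dp <- bm$detection_p
  dp[1:4, "s01"] <- 0.5   # 2% of 200
  dp[1:2, "s02"] <- 0.5   # 1% of 200: not "more than 1%"
  bm2 <- beta_matrix(bm$values, detection_p = dp, beadcount = bm$beadcount)
  res2 <- filter_samples_by_detection(bm2)
  expect_false("s01" %in% res2$retained)
  expect_true("s02" %in% res2$retained)
  expect_equal(res2$report$n_before - res2$report$n_after, 1)

  expect_error(filter_samples_by_detection(beta_matrix(bm$values)),
               "detection")
})

test_that("sample filter matches a brute-force count on random failures", {
  man <- tiny_manifest(120)
  sheet <- tiny_sheet(5, 5)
  bm <- tiny_beta(man, sheet)
  dp <- withr::with_seed(8, matrix(sample(c(0, 0.5), 1200, TRUE,
                                          prob = c(0.985, 0.015)),
                                   120, 10, dimnames = dimnames(bm$values)))
  bm <- beta_matrix(bm$values, detection_p = dp)
  res <- filter_samples_by_detection(bm, 0.01, 0.01)
  brute <- colnames(dp)[sapply(colnames(dp), function(s)
    mean(dp[, s] > 0.01) > 0.01)]
  expect_setequal(setdiff(colnames(dp), res$retained), brute)
})

test_that("probe filter implements the inclusive disjunction", {
  man <- tiny_manifest(100)
  sheet <- tiny_sheet(50, 50)
  bm <- tiny_beta(man, sheet)
  res <- filter_probes(bm)
  expect_equal(res$retained, man$probe_id)  # clean layers

  dp <- bm$detection_p
  dp["p01", 1] <- 0.5                        # exactly 1% of 100 samples
  bc <- bm$beadcount
  bc["p02", 1:5] <- 2                        # exactly 5% below 3
  bc["p03", 1:4] <- 2                        # 4%: retained
  bm2 <- beta_matrix(bm$values, detection_p = dp, beadcount = bc)
  res2 <- filter_probes(bm2)
  expect_false("p01" %in% res2$retained)     # "at least 1%" is inclusive
  expect_false("p02" %in% res2$retained)
  expect_true("p03" %in% res2$retained)

  # random layers equal brute-force evaluation
  dp <- withr::with_seed(9, matrix(sample(c(0, 0.1), 10000, TRUE,
                                          prob = c(0.99, 0.01)),
                                   100, 100, dimnames = dimnames(dp)))
  bc <- withr::with_seed(10, matrix(sample(c(10, 2), 10000, TRUE,
                                           prob = c(0.95, 0.05)),
                                    100, 100, dimnames = dimnames(dp)))
  bm3 <- beta_matrix(bm$values, detection_p = dp, beadcount = bc)
  res3 <- filter_probes(bm3)
  brute <- rownames(dp)[sapply(rownames(dp), function(p)
    mean(dp[p, ] > 0.05) >= 0.01 || mean(bc[p, ] < 3) >= 0.05)]
  expect_setequal(setdiff(rownames(dp), res3$retained), brute)
})

test_that("flagged-probe exclusion removes exactly the flagged classes", {
  flags <- rep("", 100)
  flags[1:65] <- "control_snp"
  flags[70:74] <- "sex_chromosome;cross_hybridizing"
  man <- tiny_manifest(100, flags = flags)
  expect_equal(exclude_flagged_probes(tiny_manifest(10)),
               tiny_manifest(10)$probe_id)  # no flags: identity
  kept <- exclude_flagged_probes(man, "control_snp")
  expect_equal(sum(!man$probe_id %in% kept), 65)
  # union of classes equals brute-force set union
  kept2 <- exclude_flagged_probes(man, c("control_snp", "sex_chromosome"))
  brute <- man$probe_id[!(grepl("control_snp", man$flags) |
                            grepl("sex_chromosome", man$flags))]
  expect_setequal(kept2, brute)
  expect_error(exclude_flagged_probes(man, "nope"), "unknown flag")
})

test_that("type-stratified quantile normalization matches the hand example", {
  man <- probe_manifest(c("p1", "p2", "p3"), "chr1", c(1, 2, 3) * 100, "II")
  v <- cbind(A = c(0.1, 0.2, 0.3), B = c(0.2, 0.4, 0.6))
  rownames(v) <- man$probe_id
  out <- quantile_normalize_by_type(beta_matrix(v), man)
  expect_equal(unname(out$values),
               cbind(c(0.15, 0.30, 0.45), c(0.15, 0.30, 0.45)))
})

test_that("normalization is a fixed point on identical distributions and preserves ranks", {
  man <- tiny_manifest(60)
  man$probe_type <- rep(c("I", "II"), 30)
  sheet <- tiny_sheet(3, 3)
  base <- withr::with_seed(3, runif(60, 0.05, 0.95))
  # same values within each type stratum, shuffled per sample
  v <- withr::with_seed(7, {
    m <- matrix(0, 60, 6)
    for (ty in c("I", "II")) {
      idx <- which(man$probe_type == ty)
      m[idx, ] <- replicate(6, sample(base[idx]))
    }
    m
  })
  dimnames(v) <- list(man$probe_id, sheet$sample_id)
  out <- quantile_normalize_by_type(beta_matrix(v), man)
  for (ty in c("I", "II")) {
    idx <- man$probe_type == ty
    # shared distribution within type is unchanged
    expect_equal(apply(out$values[idx, ], 2, sort),
                 apply(v[idx, ], 2, sort))
  }
  # random input: within-sample within-type ranks preserved, sorted columns equal
  v2 <- withr::with_seed(4, matrix(runif(360), 60, 60,
                                   dimnames = list(man$probe_id,
                                                   sprintf("t%02d", 1:60))))
  out2 <- quantile_normalize_by_type(beta_matrix(v2), man)
  for (ty in c("I", "II")) {
    idx <- man$probe_type == ty
    expect_equal(apply(out2$values[idx, ], 2, rank),
                 apply(v2[idx, ], 2, rank))
    sorted <- apply(out2$values[idx, ], 2, sort)
    expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  }
  expect_true(all(out2$values >= 0 & out2$values <= 1))
})

test_that("sex check flags swapped labels and survives degenerate input", {
  flags <- rep("", 40); flags[1:10] <- "sex_chromosome"
  man <- tiny_manifest(40, flags = flags)
  sheet <- tiny_sheet(4, 4)
  v <- matrix(0.5, 40, 8, dimnames = list(man$probe_id, sheet$sample_id))
  males <- sheet$sample_id[sheet$sex == "M"]
  v[1:10, males] <- 0.3
  v[1:10, setdiff(sheet$sample_id, males)] <- 0.7
  expect_length(check_sex(beta_matrix(v), man, sheet), 0)

  swapped <- sheet
  swapped$sex[1] <- ifelse(sheet$sex[1] == "M", "F", "M")
  expect_equal(check_sex(beta_matrix(v), man, swapped), sheet$sample_id[1])

  vc <- matrix(0.5, 40, 8, dimnames = dimnames(v))
  expect_warning(out <- check_sex(beta_matrix(vc), man, sheet), "constant")
  expect_length(out, 0)
  man0 <- tiny_manifest(5)
  expect_warning(out0 <- check_sex(beta_matrix(v[1:5, ]), man0, sheet),
                 "no sex-chromosome")
  expect_length(out0, 0)
})

test_that("QC filters are idempotent and reports reconcile", {
  man <- tiny_manifest(100)
  sheet <- tiny_sheet(5, 5)
  bm <- tiny_beta(man, sheet)
  dp <- bm$detection_p
  dp[1:3, 1] <- withr::with_seed(2, runif(3, 0.1, 1))
  dp[4, ] <- 0.2
  bm <- beta_matrix(bm$values, detection_p = dp, beadcount = bm$beadcount)
  r1 <- filter_probes(bm)
  bm_f <- crossmeth:::subset_beta(bm, probes = r1$retained)
  r2 <- filter_probes(bm_f)
  expect_equal(r2$retained, r1$retained)
  expect_equal(r1$report$n_after, length(r1$retained))
  expect_equal(r1$report$n_before,
               length(r1$retained) + length(r1$report$removed))
})

test_that("the full QC chain runs in the documented order", {
  flags <- rep("", 80); flags[5] <- "cross_hybridizing"
  man <- make_manifest(80, 1, flag_rate = 0, seed = 1)
  man$flags <- flags
  sheet <- tiny_sheet(4, 4)
  sim <- simulate_beta(man, sheet, noise_sd = 0.2, n_ref_probes = 0,
                       seed = 2)
  res <- suppressWarnings(run_qc(sim$beta, man, sheet))
  expect_false(man$probe_id[5] %in% rownames(res$beta$values))
  expect_equal(res$reports$samples$n_before, 8)
  expect_lte(nrow(res$beta$values), 80)
})
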