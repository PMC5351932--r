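test_that("the exact HWE test matches full enumeration", {
  expect_equal(hwe_exact(10, 0, 0), 1)           # monomorphic
  expect_equal(hwe_exact(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact(25, 50, 25), 1)         # observed h is modal
  withr::with_seed(81, {
    for (rep in 1:40) {
      n <- sample(1:200, 1)
      nAA <- sample(0:n, 1)
      nAa <- sample(0:(n - nAA), 1)
      naa <- n - nAA - nAa
      expect_equal(hwe_exact(nAA, nAa, naa), hwe_enum_oracle(nAA, nAa, naa),
                   tolerance = 1e-12)
    }
  })
})

test_that("genotype QC applies the quoted thresholds in order", {
  sheet <- tiny_sheet(30, 30)
  withr::with_seed(82, {
    d <- matrix(rbinom(5 * 60, 2, 0.3), 5, 60,
                dimnames = list(sprintf("rs%d", 1:5), sheet$sample_id))
    storage.mode(d) <- "double"
    d["rs2", ] <- rbinom(60, 2, 0.04)           # MAF ~ 0.04: removed
    d["rs3", 1:30] <- 1; d["rs3", 31:60] <- 1   # all hets: HWE fails
    d["rs4", 1:2] <- NA                          # 3.3% missing: removed
    d["rs5", ] <- rbinom(60, 2, 0.5)
    d["rs5", 1] <- NA                            # 1.7% missing: removed
  })
  map <- data.frame(snp_id = rownames(d), chrom = "chr1",
                    pos = 1:5 * 1000, effect_allele = "A",
                    other_allele = "G")
  # wide sample tolerance: the tiny 5-SNP panel makes one missing
  # cell 20% of a sample, which is the sample filter's job otherwise
  res <- qc_genotypes(genotype_set(d, map), sample_miss = 0.5)
  expect_true("rs2" %in% res$report$snps_maf)
  expect_true("rs3" %in% res$report$snps_hwe)
  expect_true(all(c("rs4", "rs5") %in% res$report$snps_missing))
  expect_true("rs1" %in% rownames(res$genotypes$dosage))

  # removal sets equal brute-force re-evaluation on random masks
  withr::with_seed(83, {
    d2 <- matrix(rbinom(40 * 60, 2, runif(40, 0.02, 0.5)), 40, 60,
                 dimnames = list(sprintf("s%02d", 1:40), sheet$sample_id))
    storage.mode(d2) <- "double"
    d2[sample(length(d2), 60)] <- NA
  })
  map2 <- data.frame(snp_id = rownames(d2), chrom = "chr1",
                     pos = seq_len(40) * 1000, effect_allele = "A",
                     other_allele = "G")
  res2 <- qc_genotypes(genotype_set(d2, map2))
  # brute force replicates the order: sample filter first, then SNP rules
  keep_samples <- colnames(d2)[colMeans(is.na(d2)) <= 0.05]
  brute_keep <- rownames(d2)[sapply(rownames(d2), function(s) {
    r <- d2[s, keep_samples]
    miss_ok <- mean(is.na(r)) <= 0.01
    g <- r[!is.na(r)]
    hwe_ok <- hwe_enum_oracle(sum(g == 2), sum(g == 1), sum(g == 0)) >= 1e-3
    af <- mean(g) / 2
    maf_ok <- min(af, 1 - af) >= 0.05
    miss_ok && hwe_ok && maf_ok
  })]
  expect_setequal(rownames(res2$genotypes$dosage), brute_keep)
})

test_that("LD pruning drops duplicates and its postcondition holds", {
  sheet <- tiny_sheet(25, 25)
  withr::with_seed(84, {
    base <- rbinom(50, 2, 0.4)
    d <- rbind(rs1 = base, rs2 = base,                 # duplicates 100bp apart
               rs3 = rbinom(50, 2, 0.4))
    storage.mode(d) <- "double"
    colnames(d) <- sheet$sample_id
  })
  map <- data.frame(snp_id = c("rs1", "rs2", "rs3"), chrom = "chr1",
                    pos = c(1000, 1100, 1200), effect_allele = "A",
                    other_allele = "G")
  kept <- ld_prune(genotype_set(d, map))
  expect_true("rs1" %in% kept)
  expect_false("rs2" %in% kept)                        # later twin dropped

  # random LD blocks: exhaustive pair check of the postcondition
  withr::with_seed(85, {
    n_snp <- 60
    blocks <- sort(sample(1:10, n_snp, TRUE))
    d2 <- t(sapply(seq_len(n_snp), function(i) {
      core <- rbinom(50, 2, 0.4)
      if (i > 1 && blocks[i] == blocks[i - 1] && runif(1) < 0.7) {
        core <- d2_prev
      }
      d2_prev <<- core
      pmin(pmax(core + rbinom(50, 1, 0.1) - rbinom(50, 1, 0.1), 0), 2)
    }))
    rownames(d2) <- sprintf("v%02d", seq_len(n_snp))
    colnames(d2) <- sheet$sample_id
    storage.mode(d2) <- "double"
  })
  map2 <- data.frame(snp_id = rownames(d2), chrom = "chr1",
                     pos = cumsum(sample(100:600, n_snp, TRUE)),
                     effect_allele = "A", other_allele = "G")
  gs2 <- genotype_set(d2, map2)
  kept2 <- ld_prune(gs2, window = 1500, r2_cut = 0.2)
  km <- map2[map2$snp_id %in% kept2, ]
  for (i in seq_len(nrow(km))) {
    for (j in seq_len(i - 1)) {
      if (abs(km$pos[i] - km$pos[j]) <= 1500) {
        r <- cor(d2[km$snp_id[i], ], d2[km$snp_id[j], ])
        expect_lte(r^2, 0.2 + 1e-12)
      }
    }
  }
})

test_that("PRS scoring follows PLINK conventions including allele flips", {
  d <- matrix(c(2, 1, 0, 1), 2, 2,
              dimnames = list(c("rs1", "rs2"), c("s1", "s2")))
  map <- data.frame(snp_id = c("rs1", "rs2"), chrom = "chr1",
                    pos = c(1, 2), effect_allele = c("A", "C"),
                    other_allele = c("G", "T"))
  gs <- genotype_set(d, map)
  sc <- score_file(c("rs1", "rs2"), c("A", "C"), c(0.5, -0.2))
  res <- compute_prs(gs, sc)
  expect_equal(unname(res$scores["s1"]), 2 * 0.5 + 1 * (-0.2))
  expect_equal(unname(res$scores["s1"]), 0.8)
  expect_equal(unname(compute_prs(gs, sc, mode = "mean")$scores["s1"]), 0.4)

  # all-zero dosages on effect alleles score 0
  gs0 <- genotype_set(matrix(0, 2, 2, dimnames = dimnames(d)), map)
  expect_equal(unname(compute_prs(gs0, sc)$scores), c(0, 0))

  # flipping the scored allele changes a sample's score by w * (2 - 2d)
  sc_flip <- score_file(c("rs1", "rs2"), c("G", "C"), c(0.5, -0.2))
  res_flip <- compute_prs(gs, sc_flip)
  expect_equal(res_flip$scores - res$scores,
               0.5 * (2 - 2 * d["rs1", ]))

  # invariant to SNP order and to splitting the score file into chunks
  sc_rev <- score_file(c("rs2", "rs1"), c("C", "A"), c(-0.2, 0.5))
  expect_equal(compute_prs(gs, sc_rev)$scores, res$scores)
  part1 <- compute_prs(gs, score_file("rs1", "A", 0.5))$scores
  part2 <- compute_prs(gs, score_file("rs2", "C", -0.2))$scores
  expect_equal(part1 + part2, res$scores)

  # unmatched SNPs are skipped and counted
  sc_extra <- score_file(c("rs1", "rs2", "rs9"), c("A", "C", "A"),
                         c(0.5, -0.2, 1))
  expect_equal(compute_prs(gs, sc_extra)$n_skipped, 1)
})

test_that("the PRS group test separates a 0.8 SD shift at study-like n", {
  hits <- vapply(1:10, function(s) {
    withr::with_seed(90 + s, {
      g1 <- rnorm(34, 0.8, 1)
      g0 <- rnorm(40, 0, 1)
    })
    scores <- c(g1, g0)
    names(scores) <- sprintf("s%02d", seq_along(scores))
    prs_group_test(scores, rep(c("case", "control"), c(34, 40)))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  same <- prs_group_test(setNames(c(1, 2, 1, 2), letters[1:4]),
                         c("case", "case", "control", "control"))
  expect_equal(same$p, 1)
})

test_that("the mQTL scan finds spiked effects with matching sign and skips monomorphs", {
  man <- make_manifest(200, 1, flag_rate = 0, seed = 91)
  sheet <- make_design(n_donors = 70, case_fraction = 0.5, regions = "PFC",
                       region_missing = c(PFC = 0), cohorts = "L",
                       seed = 92)
  eff <- effect_spec(mqtl = data.frame(snp_id = "rsQ",
                                       probe_id = man$probe_id[10],
                                       delta_beta = 0.05, baseline = 0.3))
  g <- simulate_genotypes(sheet, 10, maf_range = c(0.3, 0.3),
                          effects = eff, manifest = man, seed = 93)
  # add a monomorphic SNP
  g$genotypes$dosage["snp00001", ] <- 0
  sim <- simulate_beta(man, sheet, eff, genotypes = g$genotypes,
                       noise_sd = 0.1, phi = 0, n_ref_probes = 0,
                       seed = 94)
  res <- mqtl_scan(sim$beta, g$genotypes, sheet,
                   covariates = c("age", "sex"), relaxed = 1e-10)
  hit <- res$pairs[res$pairs$snp_id == "rsQ" &
                     res$pairs$probe_id == man$probe_id[10], ]
  expect_equal(nrow(hit), 1)
  expect_gt(hit$estimate, 0)     # sign matches the simulated direction
  expect_true("snp00001" %in% res$skipped$snp_id)

  # null probes produce no pairs at either threshold
  null_res <- mqtl_scan(sim$beta$values[20:60, ], g$genotypes, sheet,
                        covariates = c("age", "sex"), relaxed = 1e-10)
  expect_equal(nrow(null_res$pairs), 0)
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  in_region <- rep(c(TRUE, FALSE), each = 4)
  is_dmp <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  res <- enrichment_fisher(in_region, is_dmp)
  expect_equal(res$p, 34 / 70, tolerance = 1e-12)
  expect_equal(res$p, fisher_enum_oracle(3, 1, 1, 3), tolerance = 1e-12)

  # zero DMPs anywhere: p = 1
  res0 <- enrichment_fisher(in_region, rep(FALSE, 8))
  expect_equal(res0$p, 1)
  expect_true(is.na(res0$odds_ratio))

  # agreement with full enumeration over random tables with totals <= 50
  withr::with_seed(95, {
    for (rep in 1:25) {
      n <- sample(4:50, 1)
      a_flag <- sample(c(TRUE, FALSE), n, TRUE)
      b_flag <- sample(c(TRUE, FALSE), n, TRUE)
      mine <- enrichment_fisher(a_flag, b_flag)$p
      tab <- table(factor(a_flag, c(TRUE, FALSE)),
                   factor(b_flag, c(TRUE, FALSE)))
      expect_equal(mine, fisher_enum_oracle(tab[1, 1], tab[1, 2],
                                            tab[2, 1], tab[2, 2]),
                   tolerance = 1e-9)
    }
  })
})

test_that("probe-region overlap is 1-based inclusive", {
  man <- probe_manifest(c("a", "b", "c"), "chr1", c(100, 200, 300))
  regions <- data.frame(chrom = "chr1", start = 100, end = 200)
  expect_equal(probe_in_regions(man, regions), c(TRUE, TRUE, FALSE))
})
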