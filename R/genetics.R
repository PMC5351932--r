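#' Exact Hardy-Weinberg equilibrium test
#'
#' Levene-Haldane exact test: conditional on the allele counts, the
#' probability of each compatible heterozygote count `h` is
#' `P(h) = n! / (nAA! nAa! naa!) * 2^h * nA! na! / (2n)!`; the p-value sums
#' `P(h)` over all `h` whose probability does not exceed the observed
#' one. Monomorphic sites return 1 by convention.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (>= 0, total >= 1).
#' @return Exact p-value.
#' @export
hwe_exact <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stopf("total genotype count must be >= 1")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  minor <- min(nA, na)
  if (minor == 0) return(1)
  hs <- seq(minor %% 2, minor, by = 2)   # h shares the parity of the margin
  log_prob <- lgamma(n + 1) - lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) -
    lgamma((na - hs) / 2 + 1) + hs * log(2) +
    lgamma(nA + 1) + lgamma(na + 1) - lgamma(2 * n + 1)
  probs <- exp(log_prob - max(log_prob))
  probs <- probs / sum(probs)
  obs <- probs[match(n_Aa, hs)]
  if (is.na(obs)) stopf("observed heterozygote count incompatible with margins")
  min(sum(probs[probs <= obs * (1 + 1e-9)]), 1)
}

# Round dosages to hard genotype calls; dosages further than `tol` from an
# integer become missing.
hard_calls <- function(dosage, tol = 0.1) {
  g <- round(dosage)
  g[!is.na(dosage) & abs(dosage - g) > tol] <- NA_real_
  g
}

#' Genotype quality control
#'
#' Filters in the standard order: samples with more than `sample_miss`
#' missing dosages, then SNPs with more than `snp_miss` missingness,
#' Hardy-Weinberg exact p below `hwe_cut` (counted on hard calls at
#' threshold 0.1), or minor allele frequency below `maf_cut`.
#'
#' @param genos a [genotype_set()].
#' @param sample_miss,snp_miss,hwe_cut,maf_cut thresholds.
#' @return list(genotypes = filtered set, report = list of removed ids by
#'   reason).
#' @export
qc_genotypes <- function(genos, sample_miss = 0.05, snp_miss = 0.01,
                         hwe_cut = 1e-3, maf_cut = 0.05) {
  d <- genos$dosage
  smiss <- colMeans(is.na(d))
  bad_samples <- colnames(d)[smiss > sample_miss]
  d <- d[, setdiff(colnames(d), bad_samples), drop = FALSE]
  pmiss <- rowMeans(is.na(d))
  bad_miss <- rownames(d)[pmiss > snp_miss]
  g <- hard_calls(d)
  hwe_p <- apply(g, 1, function(r) {
    r <- r[!is.na(r)]
    if (!length(r)) return(1)
    hwe_exact(sum(r == 2), sum(r == 1), sum(r == 0))
  })
  bad_hwe <- rownames(d)[hwe_p < hwe_cut]
  af <- rowMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  bad_maf <- rownames(d)[!is.finite(maf) | maf < maf_cut]
  drop <- unique(c(bad_miss, bad_hwe, bad_maf))
  keep <- setdiff(rownames(d), drop)
  if (!length(keep)) stopf("all SNPs removed by genotype QC")
  out <- genotype_set(d[keep, , drop = FALSE],
                      genos$map[match(keep, genos$map$snp_id), ])
  list(genotypes = out,
       report = list(samples_missing = bad_samples, snps_missing = bad_miss,
                     snps_hwe = bad_hwe, snps_maf = bad_maf))
}

#' Greedy LD pruning
#'
#' Scans SNPs in position order per chromosome; a SNP is dropped when its
#' squared Pearson dosage correlation with any already retained SNP within
#' `window` bp exceeds `r2_cut` (the later SNP of an offending pair is
#' dropped). The postcondition — no retained pair within the window with
#' r-squared above the cut — is verified before returning.
#'
#' @param genos a [genotype_set()].
#' @param window pair window in bp (default 1500).
#' @param r2_cut squared-correlation cut-off (default 0.20).
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(genos, window = 1500, r2_cut = 0.20) {
  map <- genos$map
  d <- genos$dosage
  retained <- character(0)
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    kept_idx <- integer(0)
    for (i in seq_len(nrow(sub))) {
      ok <- TRUE
      for (kk in rev(kept_idx)) {
        if (sub$pos[i] - sub$pos[kk] > window) break
        r <- suppressWarnings(cor(d[sub$snp_id[i], ], d[sub$snp_id[kk], ],
                                  use = "pairwise.complete.obs"))
        if (is.finite(r) && r^2 > r2_cut) { ok <- FALSE; break }
      }
      if (ok) kept_idx <- c(kept_idx, i)
    }
    # postcondition check over all retained pairs in window
    kp <- sub[kept_idx, , drop = FALSE]
    if (nrow(kp) > 1) {
      for (i in 2:nrow(kp)) {
        for (k in (i - 1):1) {
          if (kp$pos[i] - kp$pos[k] > window) break
          r <- suppressWarnings(cor(d[kp$snp_id[i], ], d[kp$snp_id[k], ],
                                    use = "pairwise.complete.obs"))
          if (is.finite(r) && r^2 > r2_cut)
            stopf("LD pruning postcondition violated at %s / %s",
                  kp$snp_id[i], kp$snp_id[k])
        }
      }
    }
    retained <- c(retained, kp$snp_id)
  }
  retained
}

#' Polygenic risk scores
#'
#' Weighted sum of effect-allele dosages over the SNPs shared between the
#' genotype set and the score file. When the score file's effect allele is
#' the map's other allele the dosage is flipped (`2 - d`); SNPs matching
#' neither allele are skipped and counted. Missing dosages are omitted
#' from a sample's sum (`mode = "sum"`) or the score is divided by the
#' number of non-missing scored SNPs (`mode = "mean"`).
#'
#' @param genos a [genotype_set()].
#' @param score a [score_file()].
#' @param mode "sum" (default) or "mean".
#' @return list(scores = named per-sample scores, n_used = per-sample
#'   non-missing SNP counts, n_skipped = unmatched score SNPs, flagged =
#'   samples with zero scored SNPs, mode).
#' @export
compute_prs <- function(genos, score, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  m <- match(score$snp_id, genos$map$snp_id)
  present <- !is.na(m)
  n_skipped <- sum(!present)
  sc <- score[present, , drop = FALSE]
  mp <- genos$map[m[present], , drop = FALSE]
  use <- sc$effect_allele == mp$effect_allele |
    sc$effect_allele == mp$other_allele
  n_skipped <- n_skipped + sum(!use)
  sc <- sc[use, , drop = FALSE]
  mp <- mp[use, , drop = FALSE]
  if (!nrow(sc))
    return(list(scores = setNames(rep(NA_real_, ncol(genos$dosage)),
                                  colnames(genos$dosage)),
                n_used = 0, n_skipped = n_skipped,
                flagged = colnames(genos$dosage), mode = mode))
  d <- genos$dosage[mp$snp_id, , drop = FALSE]
  flip <- sc$effect_allele == mp$other_allele
  d[flip, ] <- 2 - d[flip, , drop = FALSE]
  contrib <- d * sc$weight
  scores <- colSums(contrib, na.rm = TRUE)
  n_used <- colSums(!is.na(d))
  flagged <- names(n_used)[n_used == 0]
  scores[n_used == 0] <- NA_real_
  if (mode == "mean") scores <- scores / pmax(n_used, 1)
  list(scores = scores, n_used = n_used, n_skipped = n_skipped,
       flagged = flagged, mode = mode)
}

#' Case-control comparison of polygenic scores
#'
#' Two-sided two-sample t-test of scores between diagnosis groups.
#'
#' @param scores named per-sample scores.
#' @param diagnosis "case"/"control" per sample.
#' @return list(mean_case, mean_control, p, degenerate).
#' @export
prs_group_test <- function(scores, diagnosis) {
  ok <- is.finite(scores)
  scores <- scores[ok]; diagnosis <- diagnosis[ok]
  g1 <- scores[diagnosis == "case"]
  g0 <- scores[diagnosis == "control"]
  if (length(g1) < 2 || length(g0) < 2)
    stopf("need at least 2 samples per group")
  if (sd(g1) == 0 && sd(g0) == 0) {
    return(list(mean_case = mean(g1), mean_control = mean(g0),
                p = if (isTRUE(all.equal(mean(g1), mean(g0)))) 1 else 0,
                degenerate = TRUE))
  }
  list(mean_case = mean(g1), mean_control = mean(g0),
       p = t.test(g1, g0)$p.value, degenerate = FALSE)
}

#' Methylation QTL scan
#'
#' Per (SNP, probe) pair, an additive linear regression of methylation on
#' dosage with the configured covariates; all probes for a SNP are fitted
#' in one batched solve. Pairs with p below `threshold` are the
#' genome-wide set; those below `relaxed` form a separately flagged
#' relaxed pass. In-sample monomorphic SNPs are skipped with a reason.
#'
#' @param bm a [beta_matrix()].
#' @param genos a [genotype_set()] with sample columns matching the sheet.
#' @param sheet a [sample_sheet()].
#' @param covariates covariate names as in [model_spec()] (the EWAS
#'   default set).
#' @param pairs optional data.frame(snp_id, probe_id) restricting the
#'   scan; NULL scans all SNP-probe combinations.
#' @param threshold genome-wide significance threshold.
#' @param relaxed relaxed threshold.
#' @return list(pairs = data.frame(snp_id, probe_id, estimate (%), se,
#'   stat, p, significant, relaxed), skipped = data.frame(snp_id, reason)).
#' @export
mqtl_scan <- function(bm, genos, sheet,
                      covariates = c("age", "sex", "neuronal_prop"),
                      pairs = NULL, threshold = 3.69e-13,
                      relaxed = 1e-10) {
  values <- if (inherits(bm, "beta_matrix")) bm$values else bm
  samples <- intersect(colnames(values), colnames(genos$dosage))
  samples <- intersect(samples, sheet$sample_id)
  if (length(samples) < 10) stopf("fewer than 10 aligned samples")
  sheet <- sheet[match(samples, sheet$sample_id), , drop = FALSE]
  spec <- model_spec("diagnosis", covariates)
  X0 <- build_design(sheet, spec)
  X0 <- X0[, setdiff(colnames(X0), "exposure"), drop = FALSE]
  cc <- rowSums(!is.finite(X0)) == 0
  samples <- samples[cc]
  X0 <- X0[cc, , drop = FALSE]
  snps <- if (is.null(pairs)) rownames(genos$dosage) else unique(pairs$snp_id)
  hits <- list()
  skipped <- list()
  for (s in snps) {
    dos <- genos$dosage[s, samples]
    use <- is.finite(dos)
    if (sum(use) < ncol(X0) + 3 || sd(dos[use]) == 0) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(snp_id = s, reason = "monomorphic_in_sample",
                   stringsAsFactors = FALSE)
      next
    }
    probe_set <- if (is.null(pairs)) rownames(values) else
      pairs$probe_id[pairs$snp_id == s]
    X <- cbind(X0[use, , drop = FALSE], exposure = dos[use])
    Y <- t(values[probe_set, samples[use], drop = FALSE])
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(snp_id = s, reason = "rank_deficient",
                   stringsAsFactors = FALSE)
      next
    }
    coefs <- qr.coef(qr_x, Y)
    res <- Y - X %*% coefs
    df <- nrow(X) - ncol(X)
    sigma2 <- colSums(res^2) / df
    jj <- match("exposure", colnames(X))
    se <- sqrt(sigma2 * chol2inv(qr.R(qr_x))[jj, jj])
    est <- coefs[jj, ]
    stat <- ifelse(se > 0, est / se, 0)
    p <- pmax(2 * pt(-abs(stat), df), .Machine$double.xmin)
    sel <- p < relaxed
    if (any(sel)) {
      hits[[length(hits) + 1L]] <- data.frame(
        snp_id = s, probe_id = probe_set[sel], estimate = est[sel] * 100,
        se = se[sel] * 100, stat = stat[sel], p = p[sel],
        significant = p[sel] < threshold, relaxed = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  empty_pairs <- data.frame(snp_id = character(0), probe_id = character(0),
                            estimate = numeric(0), se = numeric(0),
                            stat = numeric(0), p = numeric(0),
                            significant = logical(0), relaxed = logical(0),
                            stringsAsFactors = FALSE)
  list(pairs = if (length(hits)) do.call(rbind, hits) else empty_pairs,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(snp_id = character(0), reason = character(0)))
}

#' Fisher's exact enrichment of DMPs in GWAS regions
#'
#' Tests whether probes below the DMP p-value cut are over-represented
#' among probes lying inside GWAS-nominated genomic regions, using the
#' exact two-sided Fisher test (summing hypergeometric probabilities no
#' larger than the observed table's). The verdict compares the p-value to
#' a Bonferroni-corrected cut.
#'
#' @param in_region logical per probe: inside any GWAS region.
#' @param is_dmp logical per probe: association p below the DMP cut.
#' @param bonferroni_cut verdict threshold (default 1.25e-2).
#' @return list(table, odds_ratio, p, significant).
#' @export
enrichment_fisher <- function(in_region, is_dmp,
                              bonferroni_cut = 1.25e-2) {
  stopifnot(length(in_region) == length(is_dmp))
  tab <- table(factor(in_region, c(TRUE, FALSE)),
               factor(is_dmp, c(TRUE, FALSE)))
  if (any(tab < 0)) stopf("negative counts")
  ft <- fisher.test(tab)
  or <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    NA_real_
  } else unname(ft$estimate)
  list(table = tab, odds_ratio = or, p = ft$p.value,
       significant = ft$p.value < bonferroni_cut)
}

#' Probe membership in GWAS regions
#'
#' 1-based inclusive interval overlap of probe positions with a set of
#' genomic regions.
#'
#' @param manifest a [probe_manifest()].
#' @param regions data.frame(chrom, start, end), 1-based inclusive.
#' @return Logical vector per manifest probe.
#' @export
probe_in_regions <- function(manifest, regions) {
  out <- rep(FALSE, nrow(manifest))
  for (k in seq_len(nrow(regions))) {
    out <- out | (manifest$chrom == regions$chrom[k] &
                    manifest$pos >= regions$start[k] &
                    manifest$pos <= regions$end[k])
  }
  out
}
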