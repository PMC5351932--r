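#' Specification of spiked-in effects for the simulator
#'
#' Describes the ground-truth signal injected into a simulated study:
#' differentially methylated positions (DMPs) and regions (DMRs) targeting
#' either diagnosis or polygenic risk score (PRS), methylation QTLs, and the
#' PRS construct itself (causal SNPs, weights, and the case-control score
#' shift in SD units). Effect sizes are on the beta (proportion) scale; they
#' are converted to logit shifts at each probe's baseline so that the
#' noise-free case-control difference equals `delta_beta`.
#'
#' @param dmp data.frame(probe_id, delta_beta, target) with target in
#'   `{"diagnosis","prs"}`; `delta_beta` in `[-1,1]` (per SD of PRS when
#'   target = "prs").
#' @param dmr data.frame(chrom, start, end, delta_beta, target).
#' @param mqtl data.frame(snp_id, probe_id, delta_beta) — per-allele effect.
#' @param prs list(snp_ids, weights, shift_sd): causal SNPs, their weights,
#'   and the case-control shift of the true score in SD units.
#' @return An `effect_spec` list.
#' @export
effect_spec <- function(dmp = NULL, dmr = NULL, mqtl = NULL, prs = NULL) {
  chk <- function(df, cols, what) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stopf("%s effects need column(s): %s", what, paste(miss, collapse = ", "))
    df
  }
  dmp <- chk(dmp, c("probe_id", "delta_beta", "target"), "dmp")
  dmr <- chk(dmr, c("chrom", "start", "end", "delta_beta", "target"), "dmr")
  mqtl <- chk(mqtl, c("snp_id", "probe_id", "delta_beta"), "mqtl")
  for (df in list(dmp, dmr)) {
    if (!is.null(df) && !all(df$target %in% c("diagnosis", "prs")))
      stopf("effect target must be 'diagnosis' or 'prs'")
  }
  if (!is.null(prs)) {
    stopifnot(is.list(prs), length(prs$snp_ids) == length(prs$weights),
              is.numeric(prs$shift_sd), length(prs$shift_sd) == 1L)
  }
  structure(list(dmp = dmp, dmr = dmr, mqtl = mqtl, prs = prs),
            class = "effect_spec")
}

#' Simulate a probe manifest
#'
#' Probes are laid down per chromosome with geometric inter-probe gaps
#' (mean `mean_gap` bp), mimicking the clustered spacing of array probes.
#' About `flag_rate` of probes are randomly assigned one exclusion class.
#'
#' @param n_probes total probes (>= 1).
#' @param n_chroms chromosomes ("chr1".."chrN"); probes split evenly.
#' @param mean_gap mean inter-probe gap in bp.
#' @param flag_rate fraction of probes carrying an exclusion flag.
#' @param type1_fraction fraction of Infinium type-I probes.
#' @param seed RNG seed.
#' @return A [probe_manifest()].
#' @export
make_manifest <- function(n_probes, n_chroms = 1, mean_gap = 300,
                          flag_rate = 0.02, type1_fraction = 0.3, seed = 1) {
  if (!is_count(n_probes) || n_probes < 1) stopf("n_probes must be >= 1")
  if (!is_count(n_chroms) || n_chroms < 1) stopf("need at least 1 chromosome")
  with_seed(seed, {
    per <- diff(floor(seq(0, n_probes, length.out = n_chroms + 1)))
    rows <- lapply(seq_len(n_chroms), function(ci) {
      np <- per[ci]
      if (np == 0) return(NULL)
      gaps <- rgeom(np, 1 / mean_gap) + 1L
      data.frame(chrom = sprintf("chr%d", ci),
                 pos = 10000L + cumsum(gaps), stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    df$probe_id <- sprintf("cg%07d", seq_len(nrow(df)))
    df$probe_type <- ifelse(runif(nrow(df)) < type1_fraction, "I", "II")
    flags <- rep("", nrow(df))
    flagged <- runif(nrow(df)) < flag_rate
    flags[flagged] <- sample(known_flag_classes(), sum(flagged),
                             replace = TRUE)
    probe_manifest(df$probe_id, df$chrom, df$pos, df$probe_type, flags)
  })
}

#' Simulate the study design (sample sheet)
#'
#' Donors are split across cohorts and diagnosis groups; each donor
#' contributes one sample per available brain region, with region-specific
#' missingness. Hippocampus can be restricted to a subset of cohorts,
#' mirroring designs where one brain bank lacks that tissue. Ages are drawn
#' from a truncated normal (default N(60, 15^2), >= `age_min`).
#'
#' @param n_donors number of donors.
#' @param case_fraction fraction of donors with diagnosis "case" (0,1).
#' @param cohorts cohort labels; donors assigned by `cohort_weights`.
#' @param regions brain-region labels.
#' @param cohort_weights donor allocation across cohorts (sums to 1).
#' @param region_missing named per-region probability that a donor lacks
#'   that region's sample.
#' @param hc_cohorts cohorts in which "HC" is available (NULL = all).
#' @param age_mean,age_sd,age_min truncated-normal age model (years).
#' @param male_fraction probability a donor is male.
#' @param seed RNG seed.
#' @return A [sample_sheet()].
#' @export
make_design <- function(n_donors = 88, case_fraction = 41 / 88,
                        cohorts = c("LNDBB", "DBCBB"),
                        regions = c("PFC", "STR", "HC", "CER"),
                        cohort_weights = NULL,
                        region_missing = c(PFC = 0.14, STR = 0.07,
                                           HC = 0.49, CER = 0.12),
                        hc_cohorts = "LNDBB",
                        age_mean = 60, age_sd = 15, age_min = 18,
                        male_fraction = 0.75, seed = 1) {
  if (case_fraction < 0 || case_fraction >= 1)
    stopf("case_fraction must lie in [0,1)")
  if (!length(regions)) stopf("regions must be non-empty")
  if (is.null(cohort_weights))
    cohort_weights <- rep(1 / length(cohorts), length(cohorts))
  with_seed(seed, {
    donor_id <- sprintf("D%03d", seq_len(n_donors))
    n_case <- round(case_fraction * n_donors)
    diagnosis <- sample(rep(c("case", "control"),
                            c(n_case, n_donors - n_case)))
    cohort <- sample(cohorts, n_donors, replace = TRUE,
                     prob = cohort_weights)
    age <- numeric(n_donors)
    for (i in seq_len(n_donors)) {
      repeat {
        a <- rnorm(1, age_mean, age_sd)
        if (a >= age_min) break
      }
      age[i] <- round(a, 1)
    }
    sex <- ifelse(runif(n_donors) < male_fraction, "M", "F")
    rows <- list()
    for (i in seq_len(n_donors)) {
      for (r in regions) {
        if (identical(r, "HC") && !is.null(hc_cohorts) &&
            !(cohort[i] %in% hc_cohorts)) next
        miss_p <- if (r %in% names(region_missing)) region_missing[[r]] else 0
        if (runif(1) < miss_p) next
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = paste(donor_id[i], r, sep = "_"),
          donor_id = donor_id[i], cohort = cohort[i], region = r,
          diagnosis = diagnosis[i], age = age[i], sex = sex[i],
          stringsAsFactors = FALSE)
      }
    }
    sample_sheet(do.call(rbind, rows))
  })
}

# Convert a beta-scale delta at baseline p0 into an additive logit shift;
# errors when the shifted expectation leaves [0.02, 0.98].
delta_to_logit <- function(p0, delta, probe_id, max_mult = 1) {
  target <- p0 + delta * max_mult
  bad <- target < 0.02 | target > 0.98
  if (any(bad))
    stopf("expected beta outside [0.02, 0.98] after effect at probe %s",
          probe_id[which(bad)[1]])
  qlogis(p0 + delta) - qlogis(p0)
}

# Exact draw of a zero-mean, unit-variance Gaussian process with kernel
# exp(-d / phi) along one chromosome: the 1-D exponential kernel is Markov,
# so the process is a gap-dependent AR(1) recursion (O(n) per sample).
ou_noise <- function(pos, n_samples, phi) {
  n <- length(pos)
  z <- matrix(rnorm(n * n_samples), n, n_samples)
  if (n > 1 && phi > 0) {
    r <- exp(-diff(pos) / phi)
    s <- sqrt(1 - r^2)
    for (i in 2:n) z[i, ] <- r[i - 1] * z[i - 1, ] + s[i - 1] * z[i, ]
  }
  z
}

#' Simulate beta values with spatial correlation and spiked effects
#'
#' Betas are generated as `inverse-logit(baseline + covariate terms +
#' effects + spatially correlated noise)`. Noise is a stationary Gaussian
#' process on the logit scale with exponential kernel `exp(-d/phi)` per
#' chromosome, scaled by `noise_sd`. Covariates (age, sex, neuronal
#' proportion, cohort batch) act through per-probe loadings drawn from
#' zero-mean normals with the given SDs, so each probe carries its own
#' covariate signature. A subset of probes is reserved as cell-type
#' reference probes whose values are a noisy neuron/glia mixture driven by
#' each sample's latent neuronal proportion; the matching reference
#' profiles are returned for use with [estimate_neuronal_proportion()].
#'
#' @param manifest a [probe_manifest()].
#' @param sheet a [sample_sheet()].
#' @param effects an [effect_spec()].
#' @param genotypes optional [genotype_set()] (samples as columns) carrying
#'   the dosages referenced by mQTL effects.
#' @param prs optional named per-sample true polygenic score (standardized
#'   internally) driving PRS-targeted effects.
#' @param phi spatial correlation range in bp.
#' @param noise_sd logit-scale noise SD.
#' @param baseline_range baseline beta drawn uniformly from this interval.
#' @param age_slope_sd,sex_shift_sd,neuronal_sd,cohort_sd SDs of the
#'   per-probe covariate loadings (logit scale; age per year).
#' @param type2_attenuation multiplier on spiked effects at type-II probes.
#' @param sex_chrom_shift logit shift added for female samples at probes
#'   flagged `sex_chromosome`, emulating X-inactivation-driven intermediate
#'   methylation (gives the predicted-sex check a real signal).
#' @param n_ref_probes number of cell-type reference probes.
#' @param ref_noise_sd beta-scale noise SD at reference probes.
#' @param detection_fail_rate,beadcount_low_rate per-cell failure rates for
#'   the generated detection-p and beadcount layers.
#' @param neuronal_mean named per-region mean latent neuronal proportion.
#' @param seed RNG seed.
#' @return list(beta = [beta_matrix()], truth = ground-truth list with the
#'   realized effects, latent neuronal proportions, reference profiles and
#'   parameters).
#' @export
simulate_beta <- function(manifest, sheet, effects = effect_spec(),
                          genotypes = NULL, prs = NULL,
                          phi = 200, noise_sd = 0.3,
                          baseline_range = c(0.1, 0.9),
                          age_slope_sd = 0.003, sex_shift_sd = 0.03,
                          neuronal_sd = 0.3, cohort_sd = 0.05,
                          type2_attenuation = 1, sex_chrom_shift = 1,
                          n_ref_probes = 50, ref_noise_sd = 0.02,
                          detection_fail_rate = 0.002,
                          beadcount_low_rate = 0.002,
                          neuronal_mean = c(PFC = 0.35, STR = 0.30,
                                            HC = 0.40, CER = 0.20),
                          seed = 1) {
  n_p <- nrow(manifest)
  n_s <- nrow(sheet)
  spiked <- unique(c(effects$dmp$probe_id, effects$mqtl$probe_id))
  missing_probes <- setdiff(spiked, manifest$probe_id)
  if (length(missing_probes))
    stopf("effect targets absent from manifest: %s",
          paste(missing_probes, collapse = ", "))
  with_seed(seed, {
    baseline_beta <- runif(n_p, baseline_range[1], baseline_range[2])
    names(baseline_beta) <- manifest$probe_id
    # effect rows may pin the baseline of their target probes, so recovery
    # experiments run at a defined signal-to-noise operating point
    pin_baseline <- function(df, ids) {
      if (!is.null(df) && !is.null(df$baseline)) {
        ok <- is.finite(df$baseline)
        baseline_beta[ids[ok]] <<- df$baseline[ok]
      }
    }
    pin_baseline(effects$dmp, effects$dmp$probe_id)
    pin_baseline(effects$mqtl, effects$mqtl$probe_id)
    if (!is.null(effects$dmr) && !is.null(effects$dmr$baseline)) {
      for (k in seq_len(nrow(effects$dmr))) {
        e <- effects$dmr[k, ]
        if (!is.finite(e$baseline)) next
        in_r <- manifest$chrom == e$chrom & manifest$pos >= e$start &
          manifest$pos <= e$end
        baseline_beta[in_r] <- e$baseline
      }
    }
    is_case <- as.numeric(sheet$diagnosis == "case")
    is_male <- as.numeric(sheet$sex == "M")
    nm <- ifelse(sheet$region %in% names(neuronal_mean),
                 neuronal_mean[sheet$region], 0.30)
    neuronal <- clamp(rnorm(n_s, nm, 0.05), 0.02, 0.98)
    names(neuronal) <- sheet$sample_id
    z_prs <- NULL
    if (!is.null(prs)) {
      p <- prs[sheet$sample_id]
      z_prs <- if (sd(p, na.rm = TRUE) > 0) as.numeric(scale(p)) else p * 0
      z_prs[is.na(z_prs)] <- 0
    }

    # per-probe covariate loadings (logit scale)
    age_coef <- rnorm(n_p, 0, age_slope_sd)
    sex_coef <- rnorm(n_p, 0, sex_shift_sd)
    neur_coef <- rnorm(n_p, 0, neuronal_sd)
    cohorts <- sort(unique(sheet$cohort))
    cohort_coef <- matrix(rnorm(n_p * length(cohorts), 0, cohort_sd),
                          n_p, length(cohorts),
                          dimnames = list(NULL, cohorts))
    if (length(cohorts)) cohort_coef[, 1] <- 0  # first cohort is reference

    mu <- matrix(qlogis(baseline_beta), n_p, n_s,
                 dimnames = list(manifest$probe_id, sheet$sample_id))
    mu <- mu + outer(age_coef, sheet$age - mean(sheet$age)) +
      outer(sex_coef, is_male) +
      outer(neur_coef, neuronal - mean(neuronal)) +
      cohort_coef[, match(sheet$cohort, cohorts), drop = FALSE]

    sexflag <- manifest_has_flag(manifest, "sex_chromosome")
    if (any(sexflag) && sex_chrom_shift != 0) {
      mu[sexflag, ] <- mu[sexflag, ] +
        sex_chrom_shift * rep(1 - is_male, each = sum(sexflag))
    }
    atten <- ifelse(manifest$probe_type == "II", type2_attenuation, 1)
    names(atten) <- manifest$probe_id
    realized <- list(dmp = effects$dmp, dmr = NULL, mqtl = effects$mqtl)

    apply_effect <- function(mu, probe, delta, target) {
      i <- match(probe, manifest$probe_id)
      d <- delta * atten[i]
      if (identical(target, "diagnosis")) {
        dl <- delta_to_logit(baseline_beta[i], d, probe)
        mu[i, ] <- mu[i, ] + dl * is_case
      } else {
        if (is.null(z_prs)) stopf("PRS-targeted effect but no prs supplied")
        dl <- delta_to_logit(baseline_beta[i], d, probe,
                             max_mult = 2)  # ~2 SD range
        mu[i, ] <- mu[i, ] + dl * z_prs
      }
      mu
    }

    if (!is.null(effects$dmp)) {
      for (k in seq_len(nrow(effects$dmp))) {
        e <- effects$dmp[k, ]
        mu <- apply_effect(mu, e$probe_id, e$delta_beta, e$target)
      }
    }
    if (!is.null(effects$dmr)) {
      dmr_probes <- list()
      for (k in seq_len(nrow(effects$dmr))) {
        e <- effects$dmr[k, ]
        in_r <- manifest$chrom == e$chrom & manifest$pos >= e$start &
          manifest$pos <= e$end
        ids <- manifest$probe_id[in_r]
        if (!length(ids))
          stopf("DMR effect %s:%d-%d covers no probes", e$chrom, e$start,
                e$end)
        for (pid in ids) mu <- apply_effect(mu, pid, e$delta_beta, e$target)
        dmr_probes[[k]] <- ids
      }
      realized$dmr <- cbind(effects$dmr,
                            probe_ids = vapply(dmr_probes, paste,
                                               character(1), collapse = ";"))
    }
    if (!is.null(effects$mqtl)) {
      if (is.null(genotypes))
        stopf("mQTL effects require genotypes")
      for (k in seq_len(nrow(effects$mqtl))) {
        e <- effects$mqtl[k, ]
        if (!e$snp_id %in% rownames(genotypes$dosage))
          stopf("mQTL SNP %s absent from genotypes", e$snp_id)
        i <- match(e$probe_id, manifest$probe_id)
        dl <- delta_to_logit(baseline_beta[i], e$delta_beta * atten[i],
                             e$probe_id, max_mult = 2)
        dos <- genotypes$dosage[e$snp_id, sheet$sample_id]
        dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
        mu[i, ] <- mu[i, ] + dl * dos
      }
    }

    # spatially correlated noise per chromosome (manifest is coordinate
    # sorted, so rows within a chromosome are contiguous and ordered)
    if (noise_sd > 0) {
      for (ch in unique(manifest$chrom)) {
        idx <- which(manifest$chrom == ch)
        mu[idx, ] <- mu[idx, ] +
          noise_sd * ou_noise(manifest$pos[idx], n_s, phi)
      }
    }
    values <- inv_logit(mu)

    # cell-type reference probes: overwrite with neuron/glia mixtures
    ref <- NULL
    if (n_ref_probes > 0) {
      cand <- setdiff(manifest$probe_id, spiked)
      ref_ids <- sample(cand, min(n_ref_probes, length(cand)))
      mu_n <- runif(length(ref_ids), 0.15, 0.85)
      gap <- sample(c(-1, 1), length(ref_ids), TRUE) *
        runif(length(ref_ids), 0.25, 0.5)
      mu_g <- clamp(mu_n + gap, 0.05, 0.95)
      ref <- data.frame(probe_id = ref_ids, neuron = mu_n, glia = mu_g,
                        stringsAsFactors = FALSE)
      i <- match(ref_ids, manifest$probe_id)
      mix <- outer(mu_n, neuronal) + outer(mu_g, 1 - neuronal)
      values[i, ] <- clamp(mix + matrix(rnorm(length(mix), 0, ref_noise_sd),
                                        nrow(mix)), 0, 1)
    }

    detection_p <- matrix(runif(n_p * n_s) * 1e-4, n_p, n_s,
                          dimnames = dimnames(values))
    fail <- runif(n_p * n_s) < detection_fail_rate
    detection_p[fail] <- runif(sum(fail), 0.06, 1)
    beadcount <- matrix(3 + rpois(n_p * n_s, 11), n_p, n_s,
                        dimnames = dimnames(values))
    low <- runif(n_p * n_s) < beadcount_low_rate
    beadcount[low] <- sample(0:2, sum(low), TRUE)

    truth <- list(effects = realized, baseline_beta = baseline_beta,
                  neuronal_prop = neuronal, ages = setNames(sheet$age,
                                                            sheet$sample_id),
                  reference_profiles = ref,
                  params = list(phi = phi, noise_sd = noise_sd,
                                type2_attenuation = type2_attenuation),
                  seed = seed)
    list(beta = beta_matrix(values, detection_p = detection_p,
                            beadcount = beadcount),
         truth = truth)
  })
}

#' Simulate genotypes with mQTL and polygenic structure
#'
#' Genotypes are drawn at the donor level under Hardy-Weinberg proportions
#' with per-SNP minor-allele frequencies uniform on `maf_range`, then
#' replicated across each donor's samples. SNPs named in the effect spec's
#' mQTL list are placed adjacent to their target probe. When a PRS
#' construct is present, case allele frequencies at the causal SNPs are
#' shifted (proportionally to weight and allele variance) so that the true
#' score differs between cases and controls by `shift_sd` standard
#' deviations in expectation.
#'
#' @param sheet a [sample_sheet()].
#' @param n_snps total SNP count (>= number of causal/mQTL SNPs).
#' @param maf_range bounds for minor allele frequency, within (0, 0.5].
#' @param effects an [effect_spec()].
#' @param manifest optional manifest used to place mQTL SNPs.
#' @param missing_rate per-cell probability of a missing dosage.
#' @param seed RNG seed.
#' @return list(genotypes = [genotype_set()] with sample columns,
#'   true_prs = named per-sample true score, maf = per-SNP frequency).
#' @export
simulate_genotypes <- function(sheet, n_snps = 200,
                               maf_range = c(0.05, 0.5),
                               effects = effect_spec(), manifest = NULL,
                               missing_rate = 0, seed = 1) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stopf("maf_range must lie within (0, 0.5]")
  named <- unique(c(effects$mqtl$snp_id, effects$prs$snp_ids))
  if (n_snps < length(named))
    stopf("n_snps smaller than the number of causal SNPs")
  donors <- unique(sheet[, c("donor_id", "diagnosis")])
  n_d <- nrow(donors)
  with_seed(seed, {
    snp_id <- c(named, sprintf("snp%05d", seq_len(n_snps - length(named))))
    maf <- runif(n_snps, maf_range[1], maf_range[2])
    names(maf) <- snp_id
    freq <- matrix(maf, n_snps, n_d, dimnames = list(snp_id,
                                                     donors$donor_id))
    if (!is.null(effects$prs) && length(effects$prs$snp_ids)) {
      w <- effects$prs$weights
      ids <- effects$prs$snp_ids
      p <- maf[ids]
      v <- sum(w^2 * 2 * p * (1 - p))
      if (v > 0) {
        dp <- effects$prs$shift_sd * w * p * (1 - p) / sqrt(v)
        case_cols <- donors$diagnosis == "case"
        freq[ids, case_cols] <- clamp(p + dp, 0.01, 0.99)
      }
    }
    dosage_d <- matrix(rbinom(n_snps * n_d, 2, freq), n_snps, n_d,
                       dimnames = dimnames(freq))
    if (missing_rate > 0) {
      dosage_d[runif(length(dosage_d)) < missing_rate] <- NA_real_
    }
    storage.mode(dosage_d) <- "double"
    # positions: mQTL SNPs sit next to their target probe
    chrom <- rep("chr1", n_snps)
    pos <- 5000L + 5000L * seq_len(n_snps)
    names(chrom) <- names(pos) <- snp_id
    if (!is.null(effects$mqtl) && !is.null(manifest)) {
      i <- match(effects$mqtl$probe_id, manifest$probe_id)
      chrom[effects$mqtl$snp_id] <- manifest$chrom[i]
      pos[effects$mqtl$snp_id] <- manifest$pos[i] + 1L
    }
    map <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                      effect_allele = "A", other_allele = "G",
                      stringsAsFactors = FALSE)
    dosage <- dosage_d[, sheet$donor_id, drop = FALSE]
    colnames(dosage) <- sheet$sample_id
    true_prs <- setNames(rep(0, nrow(sheet)), sheet$sample_id)
    if (!is.null(effects$prs) && length(effects$prs$snp_ids)) {
      sc <- colSums(dosage[effects$prs$snp_ids, , drop = FALSE] *
                      effects$prs$weights, na.rm = TRUE)
      true_prs <- sc
    }
    list(genotypes = genotype_set(dosage, map), true_prs = true_prs,
         maf = maf)
  })
}

#' Simulate a complete study bundle
#'
#' Orchestrates [make_manifest()], [make_design()], [simulate_genotypes()]
#' and [simulate_beta()] into a full input bundle with a ground-truth
#' ledger, optionally writing every component to `dir` as plain-text files
#' (`beta.tsv`, `detection_p.tsv`, `beadcount.tsv`, `manifest.tsv`,
#' `samples.csv`, `dosages.tsv`, `score.txt`, `reference_profiles.tsv`,
#' `ground_truth.json`).
#'
#' @param n_probes,n_chroms,mean_gap manifest parameters.
#' @param n_donors,case_fraction design parameters.
#' @param n_snps genotype count.
#' @param effects an [effect_spec()].
#' @param dir optional output directory.
#' @param seed RNG seed; component seeds are derived from it.
#' @param ... further arguments passed to [simulate_beta()].
#' @return list(manifest, sheet, beta, genotypes, score, truth).
#' @export
simulate_study <- function(n_probes = 2000, n_chroms = 2, mean_gap = 300,
                           n_donors = 88, case_fraction = 41 / 88,
                           n_snps = 200, effects = effect_spec(),
                           dir = NULL, seed = 1, ...) {
  manifest <- make_manifest(n_probes, n_chroms, mean_gap,
                            seed = child_seed(seed, 1))
  sheet <- make_design(n_donors = n_donors, case_fraction = case_fraction,
                       seed = child_seed(seed, 2))
  g <- simulate_genotypes(sheet, n_snps = n_snps, effects = effects,
                          manifest = manifest, seed = child_seed(seed, 3))
  sim <- simulate_beta(manifest, sheet, effects = effects,
                       genotypes = g$genotypes, prs = g$true_prs,
                       seed = child_seed(seed, 4), ...)
  score <- if (!is.null(effects$prs) && length(effects$prs$snp_ids)) {
    score_file(effects$prs$snp_ids, "A", effects$prs$weights)
  } else NULL
  truth <- sim$truth
  truth$true_prs <- g$true_prs
  truth$maf <- g$maf
  truth$root_seed <- seed
  out <- list(manifest = manifest, sheet = sheet, beta = sim$beta,
              genotypes = g$genotypes, score = score, truth = truth)
  if (!is.null(dir)) write_bundle(out, dir)
  out
}

#' @rdname simulate_study
#' @param bundle result of `simulate_study()`.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_beta_matrix(bundle$beta, fp("beta.tsv"),
                    detection_p_path = fp("detection_p.tsv"),
                    beadcount_path = fp("beadcount.tsv"))
  write_manifest(bundle$manifest, fp("manifest.tsv"))
  write_sample_sheet(bundle$sheet, fp("samples.csv"))
  if (!is.null(bundle$genotypes))
    write_dosages(bundle$genotypes, fp("dosages.tsv"))
  if (!is.null(bundle$score)) write_score_file(bundle$score, fp("score.txt"))
  if (!is.null(bundle$truth$reference_profiles))
    data.table::fwrite(bundle$truth$reference_profiles,
                       fp("reference_profiles.tsv"), sep = "\t")
  truth <- bundle$truth
  truth$reference_profiles <- NULL
  jsonlite::write_json(truth, fp("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(dir)
}
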