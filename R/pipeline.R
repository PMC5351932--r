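#' Default spiked-effect configuration for a simulated study
#'
#' Builds an [effect_spec()] against a concrete manifest: a handful of
#' diagnosis DMPs, one 5-probe diagnosis DMR, one PRS-associated DMP, two
#' cis mQTLs and a 30-SNP polygenic construct with a 0.8 SD case-control
#' shift. Spiked probes are pinned to baseline 0.2 so the injected 5%
#' differences sit at a defined signal-to-noise operating point.
#'
#' @param manifest a [probe_manifest()].
#' @param seed RNG seed for target selection.
#' @return An [effect_spec()].
#' @export
default_study_effects <- function(manifest, seed = 1) {
  with_seed(seed, {
    clean <- manifest[manifest$flags == "", , drop = FALSE]
    dmp_ids <- sample(clean$probe_id, 4)
    # a run of 5 consecutive probes with gaps <= 300 bp for the DMR
    dmr <- NULL
    for (ch in unique(clean$chrom)) {
      sub <- clean[clean$chrom == ch, ]
      gaps <- diff(sub$pos)
      ok <- which(vapply(seq_len(max(0, nrow(sub) - 4)), function(i)
        all(gaps[i:(i + 3)] <= 300), logical(1)))
      ok <- setdiff(ok, which(sub$probe_id %in% dmp_ids))
      if (length(ok)) {
        i <- sample(ok, 1)
        dmr <- data.frame(chrom = ch, start = sub$pos[i],
                          end = sub$pos[i + 4], delta_beta = 0.05,
                          target = "diagnosis", baseline = 0.2)
        break
      }
    }
    mqtl_ids <- sample(setdiff(clean$probe_id, dmp_ids), 2)
    effect_spec(
      dmp = data.frame(
        probe_id = dmp_ids,
        delta_beta = c(0.05, 0.05, -0.05, 0.02),
        target = c("diagnosis", "diagnosis", "diagnosis", "prs"),
        baseline = 0.2),
      dmr = dmr,
      mqtl = data.frame(snp_id = c("rsQTL1", "rsQTL2"),
                        probe_id = mqtl_ids, delta_beta = c(0.12, -0.12),
                        baseline = 0.3),
      prs = list(snp_ids = sprintf("rsPRS%02d", 1:30),
                 weights = runif(30, 0.02, 0.2), shift_sd = 0.8))
  })
}

#' Run the complete analysis pipeline on a simulated study
#'
#' Simulates a two-cohort, four-region study bundle and drives every stage
#' end to end: QC and normalization, neuronal-proportion and PRS
#' covariates, per-cohort EWAS and fixed-effects meta-analysis per region,
#' a cross-region mixed model on the top meta-analysis probes, DMR
#' detection, the permutation FWER threshold, the PRS case-control test
#' and PRS EWAS, the mQTL scan on LD-pruned SNPs, and GWAS-region
#' enrichment. Every output is written to `out_dir` as deterministic
#' plain-text files; a run log records the seed, configuration hash and
#' package version.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master RNG seed; all stage seeds derive from it.
#' @param config a [pipeline_config()]; `config$n_perm` controls the FWER
#'   stage.
#' @param n_probes,n_chroms,n_donors,n_snps simulated study size.
#' @param effects an [effect_spec()] or NULL for
#'   [default_study_effects()].
#' @param cross_region_top number of top meta-analysis probes refitted
#'   with the cross-region mixed model.
#' @return Invisible list with the main in-memory results (sheet, per
#'   region assoc/meta tables, dmrs, fwer, prs, mqtl, enrichment, paths).
#' @export
run_study_pipeline <- function(out_dir, seed = 1,
                               config = pipeline_config(n_perm = 200),
                               n_probes = 20000, n_chroms = 4,
                               n_donors = 57, n_snps = 100,
                               effects = NULL, cross_region_top = 50) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fp <- function(...) file.path(out_dir, ...)

  manifest <- make_manifest(n_probes, n_chroms, mean_gap = 300,
                            seed = child_seed(seed, 1))
  if (is.null(effects))
    effects <- default_study_effects(manifest, seed = child_seed(seed, 2))
  sheet <- make_design(n_donors = n_donors, seed = child_seed(seed, 3))
  g <- simulate_genotypes(sheet, n_snps = n_snps, effects = effects,
                          manifest = manifest, seed = child_seed(seed, 4))
  sim <- simulate_beta(manifest, sheet, effects = effects,
                       genotypes = g$genotypes, prs = g$true_prs,
                       seed = child_seed(seed, 5))
  bundle <- list(manifest = manifest, sheet = sheet, beta = sim$beta,
                 genotypes = g$genotypes,
                 score = score_file(effects$prs$snp_ids, "A",
                                    effects$prs$weights),
                 truth = c(sim$truth, list(true_prs = g$true_prs)))
  write_bundle(bundle, fp("input"))

  # --- QC + normalization -------------------------------------------------
  qc <- suppressWarnings(run_qc(sim$beta, manifest, sheet, config))
  write_beta_matrix(qc$beta, fp("beta_normalized.tsv"))
  jsonlite::write_json(
    list(samples = qc$reports$samples[c("n_before", "n_after")],
         probes = qc$reports$probes[c("n_before", "n_after")],
         flagged = qc$reports$flags[c("n_before", "n_after")],
         sex_mismatches = qc$sex_mismatches),
    fp("qc_report.json"), auto_unbox = TRUE, digits = NA)

  # --- covariates ---------------------------------------------------------
  sheet2 <- qc$sheet
  np <- estimate_neuronal_proportion(qc$beta,
                                     sim$truth$reference_profiles)
  sheet2$neuronal_prop <- unname(np[sheet2$sample_id])

  gqc <- qc_genotypes(g$genotypes, config$sample_missing,
                      config$snp_missing, config$hwe_p, config$maf_min)
  pruned <- ld_prune(gqc$genotypes, config$ld_window, config$ld_r2)
  gs_pruned <- genotype_set(
    gqc$genotypes$dosage[pruned, , drop = FALSE],
    gqc$genotypes$map[match(pruned, gqc$genotypes$map$snp_id), ])
  prs <- compute_prs(gqc$genotypes, bundle$score)
  sheet2$prs <- unname(prs$scores[sheet2$sample_id])
  donor_first <- !duplicated(sheet2$donor_id)
  prs_test <- prs_group_test(sheet2$prs[donor_first],
                             sheet2$diagnosis[donor_first])
  jsonlite::write_json(
    list(mean_case = prs_test$mean_case,
         mean_control = prs_test$mean_control, p = prs_test$p,
         n_snps_scored = nrow(bundle$score) - prs$n_skipped,
         n_pruned = length(pruned)),
    fp("prs_summary.json"), auto_unbox = TRUE, digits = NA)

  # --- per-region EWAS, meta-analysis, DMRs, diagnostics ------------------
  regions <- sort(unique(sheet2$region))
  assoc_meta <- list()
  summaries <- list()
  for (rg in regions) {
    tabs <- list()
    for (co in sort(unique(sheet2$cohort[sheet2$region == rg]))) {
      n_stratum <- sum(sheet2$region == rg & sheet2$cohort == co)
      if (n_stratum < 10) next       # stratum too small to model
      spec <- model_spec("diagnosis", region = rg, cohort = co)
      tab <- run_ewas(qc$beta, sheet2, spec)
      tabs[[co]] <- tab
      write_assoc_table(tab, fp(sprintf("ewas_%s_%s.tsv", rg, co)))
    }
    if (!length(tabs)) next
    meta <- if (length(tabs) > 1) meta_ewas(tabs) else tabs[[1]]
    assoc_meta[[rg]] <- meta
    write_assoc_table(meta, fp(sprintf("meta_%s.tsv", rg)))
    dmrs <- call_dmrs(meta, qc$manifest, config)
    write_regions(dmrs, fp(sprintf("dmrs_%s.tsv", rg)))
    # global means on filtered, unnormalized betas: full quantile
    # normalization equalizes per-sample distributions by construction
    gm <- global_mean_test(qc$beta_raw, sheet2[sheet2$region == rg, ])
    ok_p <- meta$p[meta$status == "ok"]
    summaries[[rg]] <- list(
      lambda = genomic_inflation(ok_p)$lambda,
      global_mean = gm[c("mean_case", "mean_control", "p")],
      n_dmr_sidak05 = sum(dmrs$p_sidak < 0.05),
      n_dmp_fwer = sum(ok_p < reference_fwer_threshold()))
  }
  jsonlite::write_json(summaries, fp("region_summaries.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- cross-region mixed model on the top meta probes --------------------
  meta_all <- assoc_meta[[which.max(vapply(assoc_meta, nrow, 0L))]]
  top <- meta_all$probe_id[order(meta_all$p)][seq_len(
    min(cross_region_top, nrow(meta_all)))]
  cr <- run_cross_region(subset_beta(qc$beta, probes = top), sheet2,
                         exposure = "diagnosis")
  write_assoc_table(cr, fp("cross_region_top.tsv"))

  # --- PRS EWAS (meta across cohorts, largest region) ---------------------
  rg_prs <- regions[which.max(vapply(regions, function(r)
    sum(sheet2$region == r), 0L))]
  prs_tabs <- list()
  for (co in sort(unique(sheet2$cohort[sheet2$region == rg_prs]))) {
    if (sum(sheet2$region == rg_prs & sheet2$cohort == co) < 10) next
    spec <- model_spec("prs", region = rg_prs, cohort = co)
    prs_tabs[[co]] <- run_ewas(qc$beta, sheet2, spec)
  }
  prs_meta <- if (length(prs_tabs) > 1) meta_ewas(prs_tabs) else
    prs_tabs[[1]]
  write_assoc_table(prs_meta, fp(sprintf("ewas_prs_%s.tsv", rg_prs)))

  # --- permutation FWER threshold (largest cohort-region stratum) ---------
  strata <- table(paste(sheet2$region, sheet2$cohort))
  big <- strsplit(names(which.max(strata)), " ")[[1]]
  fw_spec <- model_spec("diagnosis", region = big[1], cohort = big[2])
  fw <- fwer_threshold(qc$beta, sheet2, fw_spec, n_perm = config$n_perm,
                       alpha = config$fwer_alpha,
                       seed = child_seed(seed, 6))
  jsonlite::write_json(fw[c("threshold", "n_perm", "alpha", "n_failed")],
                       fp("fwer.json"), auto_unbox = TRUE, digits = NA)

  # --- mQTL scan: LD-pruned SNPs x probes of the largest region -----------
  mq_sheet <- sheet2[sheet2$region == big[1], , drop = FALSE]
  mq <- mqtl_scan(qc$beta, gs_pruned, mq_sheet,
                  threshold = config$mqtl_p,
                  relaxed = config$mqtl_p_relaxed)
  data.table::fwrite(mq$pairs, fp("mqtl_pairs.tsv"), sep = "\t")

  # --- GWAS-region enrichment ---------------------------------------------
  gwas_regions <- with_seed(child_seed(seed, 7), {
    anchors <- sample(nrow(qc$manifest), 30)
    data.frame(chrom = qc$manifest$chrom[anchors],
               start = pmax(1, qc$manifest$pos[anchors] - 5000),
               end = qc$manifest$pos[anchors] + 5000)
  })
  meta_big <- assoc_meta[[big[1]]]
  mi <- match(meta_big$probe_id, qc$manifest$probe_id)
  enr <- enrichment_fisher(
    probe_in_regions(qc$manifest[mi, ], gwas_regions),
    meta_big$p < config$dmp_p & meta_big$status == "ok",
    config$enrich_bonferroni)
  jsonlite::write_json(list(odds_ratio = enr$odds_ratio, p = enr$p,
                            significant = enr$significant),
                       fp("enrichment.json"), auto_unbox = TRUE,
                       digits = NA)

  # --- run log ------------------------------------------------------------
  write_config(config, fp("config.json"))
  jsonlite::write_json(
    list(seed = seed,
         config_md5 = unname(tools::md5sum(fp("config.json"))),
         package_version = as.character(utils::packageVersion("crossmeth")),
         n_probes = n_probes, n_samples = nrow(sheet)),
    fp("run_log.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(sheet = sheet2, manifest = qc$manifest, beta = qc$beta,
                 assoc_meta = assoc_meta, summaries = summaries,
                 cross_region = cr, prs_meta = prs_meta, fwer = fw,
                 prs_test = prs_test, mqtl = mq, enrichment = enr,
                 effects = effects, truth = bundle$truth,
                 out_dir = out_dir))
}
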