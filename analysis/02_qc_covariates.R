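#!/usr/bin/env Rscript
# Quality control, normalization and covariate derivation for the bundle
# written by 01_simulate.R: sample and probe detection/beadcount filters,
# flagged-probe exclusion, within-type quantile normalization, the
# predicted-vs-reported sex check, neuronal-proportion estimation from the
# reference profiles, genotype QC, LD pruning and polygenic scoring.
# Writes results/study/qc/.

suppressMessages(library(crossmeth))

inp <- "results/study/input"
out <- "results/study/qc"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config()

manifest <- read_manifest(file.path(inp, "manifest.tsv"))
sheet <- read_sample_sheet(file.path(inp, "samples.csv"))
beta <- read_beta_matrix(file.path(inp, "beta.tsv"), manifest,
                         detection_p_path = file.path(inp, "detection_p.tsv"),
                         beadcount_path = file.path(inp, "beadcount.tsv"))

qc <- suppressWarnings(run_qc(beta, manifest, sheet, cfg))
cat(sprintf("samples: %d -> %d; probes: %d -> %d (then %d after flags)\n",
            qc$reports$samples$n_before, qc$reports$samples$n_after,
            qc$reports$probes$n_before, qc$reports$probes$n_after,
            qc$reports$flags$n_after))
if (length(qc$sex_mismatches))
  cat("sex mismatches:", paste(qc$sex_mismatches, collapse = ", "), "\n")

refs <- read_reference_profiles(file.path(inp, "reference_profiles.tsv"))
np <- estimate_neuronal_proportion(qc$beta, refs)
sheet2 <- qc$sheet
sheet2$neuronal_prop <- unname(np[sheet2$sample_id])
cat(sprintf("neuronal proportion: median %.2f (IQR %.2f-%.2f)\n",
            median(np), quantile(np, 0.25), quantile(np, 0.75)))

genos <- read_dosages(file.path(inp, "dosages.tsv"))
score <- read_score_file(file.path(inp, "score.txt"))
gqc <- qc_genotypes(genos, cfg$sample_missing, cfg$snp_missing,
                    cfg$hwe_p, cfg$maf_min)
pruned <- ld_prune(gqc$genotypes, cfg$ld_window, cfg$ld_r2)
cat(sprintf("genotype QC kept %d/%d SNPs; %d after LD pruning\n",
            nrow(gqc$genotypes$dosage), nrow(genos$dosage),
            length(pruned)))
prs <- compute_prs(gqc$genotypes, score)
sheet2$prs <- unname(prs$scores[sheet2$sample_id])
dd <- !duplicated(sheet2$donor_id)
pt <- prs_group_test(sheet2$prs[dd], sheet2$diagnosis[dd])
cat(sprintf("PRS case mean %.2f vs control %.2f, p = %.3g\n",
            pt$mean_case, pt$mean_control, pt$p))

write_beta_matrix(qc$beta, file.path(out, "beta_normalized.tsv"))
write_sample_sheet(sheet2, file.path(out, "samples_covariates.csv"))
write_manifest(qc$manifest, file.path(out, "manifest_qc.tsv"))
writeLines(pruned, file.path(out, "snps_pruned.txt"))
write_dosages(gqc$genotypes, file.path(out, "dosages_qc.tsv"))
cat("QC outputs written to", out, "\n")
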