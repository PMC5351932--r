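#!/usr/bin/env Rscript
# Differentially methylated regions per brain region (autocorrelation
# estimation, neighbour smoothing, run finding, Stouffer-Liptak region
# scoring, Sidak correction) and the permutation family-wise-error
# threshold for the largest cohort-region stratum. Reads
# results/study/{qc,ewas}/, writes results/study/dmr/.

suppressMessages(library(crossmeth))

qcd <- "results/study/qc"
ewd <- "results/study/ewas"
out <- "results/study/dmr"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config(n_perm = 1000)

manifest <- read_manifest(file.path(qcd, "manifest_qc.tsv"))
sheet <- read_sample_sheet(file.path(qcd, "samples_covariates.csv"))
beta <- read_beta_matrix(file.path(qcd, "beta_normalized.tsv"), manifest)

for (f in list.files(ewd, pattern = "^meta_", full.names = TRUE)) {
  rg <- sub("^meta_(.*)\\.tsv$", "\\1", basename(f))
  assoc <- read_assoc_table(f)
  dmrs <- call_dmrs(assoc, manifest, cfg)
  write_regions(dmrs, file.path(out, sprintf("dmrs_%s.tsv", rg)))
  sig <- dmrs[dmrs$p_sidak < 0.05, , drop = FALSE]
  cat(sprintf("%s: %d candidate regions, %d with Sidak p < 0.05", rg,
              nrow(dmrs), nrow(sig)))
  if (nrow(sig))
    cat(sprintf(" (avg %.1f probes, %.0f bp)",
                mean(sig$n_probes), mean(sig$end - sig$start)))
  cat("\n")
}

# permutation FWER threshold, largest cohort-region stratum
strata <- table(paste(sheet$region, sheet$cohort))
big <- strsplit(names(which.max(strata)), " ")[[1]]
cat(sprintf("FWER permutations (%d) on %s / %s (n = %d)...\n",
            cfg$n_perm, big[1], big[2], max(strata)))
fw <- fwer_threshold(beta, sheet,
                     model_spec("diagnosis", region = big[1],
                                cohort = big[2]),
                     n_perm = cfg$n_perm, alpha = cfg$fwer_alpha, seed = 1)
jsonlite::write_json(fw[c("threshold", "n_perm", "alpha", "n_failed")],
                     file.path(out, "fwer.json"), auto_unbox = TRUE,
                     digits = NA)
data.table::fwrite(data.frame(min_p = fw$minima),
                   file.path(out, "fwer_minima.tsv"), sep = "\t")
cat(sprintf("5%% family-wise error threshold: %.3e\n", fw$threshold))
cat(sprintf("(450K-scale reference constant: %.2e)\n",
            reference_fwer_threshold()))
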