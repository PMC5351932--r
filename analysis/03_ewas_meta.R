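#!/usr/bin/env Rscript
# Probe-wise EWAS of diagnosis per brain region and cohort, fixed-effects
# inverse-variance meta-analysis across cohorts, inflation diagnostics,
# the global-mean comparison, the PRS EWAS, and the cross-region mixed
# model on the top meta-analysis probes. Reads results/study/qc/, writes
# results/study/ewas/.

suppressMessages(library(crossmeth))

qcd <- "results/study/qc"
inp <- "results/study/input"
out <- "results/study/ewas"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest(file.path(qcd, "manifest_qc.tsv"))
sheet <- read_sample_sheet(file.path(qcd, "samples_covariates.csv"))
beta <- read_beta_matrix(file.path(qcd, "beta_normalized.tsv"), manifest)
beta_raw <- read_beta_matrix(file.path(inp, "beta.tsv"),
                             read_manifest(file.path(inp, "manifest.tsv")))

meta_tabs <- list()
for (rg in sort(unique(sheet$region))) {
  tabs <- list()
  for (co in sort(unique(sheet$cohort[sheet$region == rg]))) {
    if (sum(sheet$region == rg & sheet$cohort == co) < 10) next
    tab <- run_ewas(beta, sheet, model_spec("diagnosis", region = rg,
                                            cohort = co))
    tabs[[co]] <- tab
    write_assoc_table(tab, file.path(out, sprintf("ewas_%s_%s.tsv", rg, co)))
  }
  if (!length(tabs)) next
  meta <- if (length(tabs) > 1) meta_ewas(tabs) else tabs[[1]]
  meta_tabs[[rg]] <- meta
  write_assoc_table(meta, file.path(out, sprintf("meta_%s.tsv", rg)))
  lam <- genomic_inflation(meta$p[meta$status == "ok"])$lambda
  gm <- global_mean_test(beta_raw, sheet[sheet$region == rg, ])
  cat(sprintf(
    "%s: %d probes, lambda = %.2f, global mean %s (p = %.2g), min p = %.2e\n",
    rg, nrow(meta), lam, gm$formatted, gm$p, min(meta$p, na.rm = TRUE)))
}

# PRS EWAS in the largest region, meta-analysed across cohorts
rg_big <- names(which.max(table(sheet$region)))
prs_tabs <- list()
for (co in sort(unique(sheet$cohort[sheet$region == rg_big]))) {
  if (sum(sheet$region == rg_big & sheet$cohort == co) < 10) next
  prs_tabs[[co]] <- run_ewas(beta, sheet, model_spec("prs", region = rg_big,
                                                     cohort = co))
}
prs_meta <- if (length(prs_tabs) > 1) meta_ewas(prs_tabs) else prs_tabs[[1]]
write_assoc_table(prs_meta, file.path(out, sprintf("ewas_prs_%s.tsv",
                                                   rg_big)))
cat(sprintf("PRS EWAS (%s): min p = %.2e at %s\n", rg_big,
            min(prs_meta$p, na.rm = TRUE),
            prs_meta$probe_id[which.min(prs_meta$p)]))

# cross-region mixed model on the 50 top meta probes (CER excluded)
ref_meta <- meta_tabs[[which.max(vapply(meta_tabs, nrow, 0L))]]
top <- ref_meta$probe_id[order(ref_meta$p)][1:50]
cr <- run_cross_region(crossmeth:::subset_beta(beta, probes = top), sheet)
write_assoc_table(cr, file.path(out, "cross_region_top.tsv"))
cat(sprintf("cross-region model: %d/%d probes converged, min p = %.2e\n",
            sum(cr$status == "ok"), nrow(cr), min(cr$p, na.rm = TRUE)))
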