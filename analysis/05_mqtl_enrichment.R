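#!/usr/bin/env Rscript
# Methylation-QTL scan of LD-pruned SNPs against all QC'd probes in the
# largest brain region, and Fisher's-exact enrichment of nominal DMPs
# within GWAS-nominated genomic regions. Reads results/study/{qc,ewas}/,
# writes results/study/genetics/.

suppressMessages(library(crossmeth))

qcd <- "results/study/qc"
ewd <- "results/study/ewas"
out <- "results/study/genetics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config()

manifest <- read_manifest(file.path(qcd, "manifest_qc.tsv"))
sheet <- read_sample_sheet(file.path(qcd, "samples_covariates.csv"))
beta <- read_beta_matrix(file.path(qcd, "beta_normalized.tsv"), manifest)
genos <- read_dosages(file.path(qcd, "dosages_qc.tsv"))
pruned <- readLines(file.path(qcd, "snps_pruned.txt"))
gs <- genotype_set(genos$dosage[pruned, , drop = FALSE],
                   genos$map[match(pruned, genos$map$snp_id), ])

rg <- names(which.max(table(sheet$region)))
mq <- mqtl_scan(beta, gs, sheet[sheet$region == rg, ],
                threshold = cfg$mqtl_p, relaxed = cfg$mqtl_p_relaxed)
data.table::fwrite(mq$pairs, file.path(out, "mqtl_pairs.tsv"), sep = "\t")
cat(sprintf(
  "mQTL scan (%s, %d SNPs x %d probes): %d pairs at p < %.2e, %d at p < %.2e\n",
  rg, nrow(gs$dosage), nrow(beta$values), sum(mq$pairs$significant),
  cfg$mqtl_p, nrow(mq$pairs), cfg$mqtl_p_relaxed))

# GWAS-region enrichment of nominal DMPs (p < 1e-3) in the same region's
# meta-analysis; regions are 10-kb windows anchored at a reproducible
# sample of array probes, standing in for published GWAS loci
meta <- read_assoc_table(file.path(ewd, sprintf("meta_%s.tsv", rg)))
gwas_regions <- withr::with_seed(7, {
  anchors <- sample(nrow(manifest), 30)
  data.frame(chrom = manifest$chrom[anchors],
             start = pmax(1, manifest$pos[anchors] - 5000),
             end = manifest$pos[anchors] + 5000)
})
mi <- match(meta$probe_id, manifest$probe_id)
enr <- enrichment_fisher(probe_in_regions(manifest[mi, ], gwas_regions),
                         meta$p < cfg$dmp_p & meta$status == "ok",
                         cfg$enrich_bonferroni)
jsonlite::write_json(list(odds_ratio = enr$odds_ratio, p = enr$p,
                          significant = enr$significant),
                     file.path(out, "enrichment.json"), auto_unbox = TRUE,
                     digits = NA)
cat(sprintf("GWAS-region enrichment: OR = %.2f, p = %.2g (%ssignificant at %.3g)\n",
            ifelse(is.na(enr$odds_ratio), NA, enr$odds_ratio), enr$p,
            ifelse(enr$significant, "", "not "), cfg$enrich_bonferroni))
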