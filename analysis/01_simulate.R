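#!/usr/bin/env Rscript
# Generates the simulated study bundle: a two-cohort, four-brain-region
# post-mortem design (57 donors, ~160 samples) profiled at 20,000 probes,
# with spiked diagnosis DMPs, a 5-probe DMR, a PRS-associated probe, two
# cis-mQTLs and a 30-SNP polygenic construct shifted 0.8 SD in cases.
# Writes results/study/input/ (beta.tsv, layers, manifest, samples,
# dosages, score file, reference profiles, ground_truth.json).

suppressMessages(library(crossmeth))

seed <- 1
out <- "results/study"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

manifest <- make_manifest(20000, 4, mean_gap = 300,
                          seed = crossmeth:::child_seed(seed, 1))
effects <- default_study_effects(manifest,
                                 seed = crossmeth:::child_seed(seed, 2))
sheet <- make_design(n_donors = 57, seed = crossmeth:::child_seed(seed, 3))
g <- simulate_genotypes(sheet, n_snps = 100, effects = effects,
                        manifest = manifest,
                        seed = crossmeth:::child_seed(seed, 4))
sim <- simulate_beta(manifest, sheet, effects = effects,
                     genotypes = g$genotypes, prs = g$true_prs,
                     seed = crossmeth:::child_seed(seed, 5))
bundle <- list(manifest = manifest, sheet = sheet, beta = sim$beta,
               genotypes = g$genotypes,
               score = score_file(effects$prs$snp_ids, "A",
                                  effects$prs$weights),
               truth = c(sim$truth, list(true_prs = g$true_prs)))
write_bundle(bundle, file.path(out, "input"))

cat(sprintf("simulated %d probes x %d samples (%d donors, %d regions)\n",
            nrow(manifest), nrow(sheet), length(unique(sheet$donor_id)),
            length(unique(sheet$region))))
cat(sprintf("spiked: %d DMPs, %d DMR(s), %d mQTL pair(s), PRS over %d SNPs\n",
            nrow(effects$dmp), nrow(effects$dmr), nrow(effects$mqtl),
            length(effects$prs$snp_ids)))
cat(sprintf("bundle written to %s/input\n", out))
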