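#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' Defaults follow standard practice for Illumina 450K-style array studies:
#' samples are dropped when more than 1% of probes have a detection p-value
#' above 0.01; probes are dropped when detection p exceeds 0.05 in at least
#' 1% of samples or the beadcount falls below 3 in at least 5% of samples.
#' Region calling seeds on adjusted p < 1e-3, bridges gaps up to 300 bp and
#' requires at least 2 probes. Genotype QC uses >5% sample missingness, >1%
#' SNP missingness, Hardy-Weinberg exact p < 1e-3 and MAF < 5%; LD pruning
#' removes pairs within 1500 bp with r-squared > 0.20. The mQTL scan reports
#' pairs below 3.69e-13 (genome-wide) and 1e-10 (relaxed); GWAS-region
#' enrichment is judged against a Bonferroni-corrected 1.25e-2.
#'
#' @param ... named overrides of any default listed above.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sample_detection_p   = 0.01,
    sample_fail_fraction = 0.01,
    probe_detection_p    = 0.05,
    probe_fail_fraction  = 0.01,
    beadcount_min        = 3,
    beadcount_fraction   = 0.05,
    exclude_flags        = c("control_snp", "sex_chromosome",
                             "cross_hybridizing", "snp_proximal"),
    dmr_seed_p           = 1e-3,
    dmr_max_gap          = 300,
    dmr_min_probes       = 2,
    fwer_alpha           = 0.05,
    n_perm               = 5000,
    hwe_p                = 1e-3,
    maf_min              = 0.05,
    snp_missing          = 0.01,
    sample_missing       = 0.05,
    ld_window            = 1500,
    ld_r2                = 0.20,
    mqtl_p               = 3.69e-13,
    mqtl_p_relaxed       = 1e-10,
    dmp_p                = 1e-3,
    enrich_bonferroni    = 1.25e-2,
    na_token             = "NA",
    seed                 = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stopf("unknown configuration field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  in01 <- c("sample_detection_p", "sample_fail_fraction", "probe_detection_p",
            "probe_fail_fraction", "beadcount_fraction", "dmr_seed_p",
            "fwer_alpha", "hwe_p", "maf_min", "snp_missing", "sample_missing",
            "ld_r2", "mqtl_p", "mqtl_p_relaxed", "dmp_p", "enrich_bonferroni")
  for (f in in01) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stopf("config field '%s' must be a single value in [0,1]", f)
  }
  for (f in c("beadcount_min", "dmr_max_gap", "dmr_min_probes", "n_perm",
              "ld_window")) {
    if (!is_count(cfg[[f]]) || cfg[[f]] < 1)
      stopf("config field '%s' must be a positive integer", f)
  }
  bad <- setdiff(cfg$exclude_flags, known_flag_classes())
  if (length(bad))
    stopf("unknown probe flag class(es): %s", paste(bad, collapse = ", "))
  invisible(cfg)
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path file path.
#' @return `read_config` returns a validated `pipeline_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
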