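qc_report <- function(axis, removed, reasons, n_before) {
  structure(list(axis = axis, removed = removed, reasons = reasons,
                 n_before = n_before, n_after = n_before - length(removed)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %d -> %d (removed %d)\n", x$axis,
              x$n_before, x$n_after, length(x$removed)))
  invisible(x)
}

#' Sample filter on detection p-values
#'
#' A sample is removed when strictly more than `max_failed_fraction` of its
#' probes have a detection p-value above `p_cut` ("more than 1% of probes
#' with detection p > 0.01"). Missing detection p-values count as passes.
#'
#' @param bm a [beta_matrix()] with a detection-p layer.
#' @param p_cut detection p-value cut-off per probe.
#' @param max_failed_fraction maximum tolerated failing-probe fraction.
#' @return list(retained = sample ids, report = qc_report).
#' @export
filter_samples_by_detection <- function(bm, p_cut = 0.01,
                                        max_failed_fraction = 0.01) {
  if (is.null(bm$detection_p)) stopf("beta matrix has no detection-p layer")
  frac <- colMeans(bm$detection_p > p_cut, na.rm = TRUE)
  drop <- names(frac)[frac > max_failed_fraction]
  list(retained = setdiff(colnames(bm$values), drop),
       report = qc_report("samples", drop,
                          setNames(rep("detection_p", length(drop)), drop),
                          ncol(bm$values)))
}

#' Probe filter on detection p-values and beadcounts
#'
#' A probe is removed when detection p exceeds `det_cut` in at least
#' `det_fraction` of samples, or the beadcount falls below `bead_cut` in at
#' least `bead_fraction` of samples (both boundaries inclusive, "at least").
#' A missing beadcount layer skips the beadcount clause.
#'
#' @param bm a [beta_matrix()] with QC layers.
#' @param det_cut,det_fraction detection clause thresholds.
#' @param bead_cut,bead_fraction beadcount clause thresholds.
#' @return list(retained = probe ids, report = qc_report).
#' @export
filter_probes <- function(bm, det_cut = 0.05, det_fraction = 0.01,
                          bead_cut = 3, bead_fraction = 0.05) {
  if (is.null(bm$detection_p)) stopf("beta matrix has no detection-p layer")
  det_frac <- rowMeans(bm$detection_p > det_cut, na.rm = TRUE)
  fail_det <- det_frac >= det_fraction
  fail_bead <- rep(FALSE, nrow(bm$values))
  if (!is.null(bm$beadcount)) {
    bead_frac <- rowMeans(bm$beadcount < bead_cut, na.rm = TRUE)
    fail_bead <- bead_frac >= bead_fraction
  }
  drop <- rownames(bm$values)[fail_det | fail_bead]
  reasons <- ifelse(fail_det[fail_det | fail_bead] &
                      fail_bead[fail_det | fail_bead], "detection+beadcount",
                    ifelse(fail_det[fail_det | fail_bead], "detection",
                           "beadcount"))
  list(retained = setdiff(rownames(bm$values), drop),
       report = qc_report("probes", drop, setNames(reasons, drop),
                          nrow(bm$values)))
}

#' Exclude flagged probes
#'
#' Removes probes carrying any of the configured exclusion classes
#' (genotyping control probes, sex-chromosome probes, cross-hybridizing
#' probes, SNP-proximal probes).
#'
#' @param manifest a [probe_manifest()].
#' @param classes flag classes to exclude.
#' @return Character vector of retained probe ids.
#' @export
exclude_flagged_probes <- function(manifest,
                                   classes = known_flag_classes()) {
  manifest$probe_id[!manifest_has_flag(manifest, classes)]
}

#' Between-sample quantile normalization stratified by probe type
#'
#' Within each Infinium probe type, every sample's values are replaced by
#' the rank-matched mean-of-sorted reference distribution, so all samples
#' share one distribution per type while within-sample, within-type rank
#' order is preserved. This is a beta-level stand-in for intensity-based
#' type-stratified normalization: it enforces the same contract
#' (type-stratified distribution alignment) on the data the pipeline
#' ingests.
#'
#' @param bm a [beta_matrix()].
#' @param manifest a [probe_manifest()] covering the probes of `bm`.
#' @return A normalized [beta_matrix()] (layers carried through unchanged).
#' @export
quantile_normalize_by_type <- function(bm, manifest) {
  if (ncol(bm$values) < 2) stopf("normalization needs at least 2 samples")
  values <- bm$values
  types <- manifest$probe_type[match(rownames(values), manifest$probe_id)]
  if (anyNA(types)) stopf("probes missing from manifest")
  for (ty in unique(types)) {
    idx <- which(types == ty)
    if (length(idx) < 2) {
      warnf("probe type %s has < 2 probes; left unnormalized", ty)
      next
    }
    values[idx, ] <- limma::normalizeQuantiles(values[idx, , drop = FALSE],
                                               ties = TRUE)
  }
  beta_matrix(clamp(values, 0, 1), detection_p = bm$detection_p,
              beadcount = bm$beadcount)
}

#' Predicted-versus-reported sex check
#'
#' Splits samples into two clusters on mean sex-chromosome methylation
#' (1-D threshold at the midpoint of the two cluster means, centers
#' initialized at the extremes) and reports samples whose reported sex
#' disagrees with the majority mapping of cluster to sex. Mismatches are
#' reported, never removed.
#'
#' @param bm a [beta_matrix()].
#' @param manifest a [probe_manifest()] with sex-chromosome flags.
#' @param sheet a [sample_sheet()].
#' @return Character vector of mismatched sample ids (possibly empty).
#' @export
check_sex <- function(bm, manifest, sheet) {
  sex_probes <- manifest$probe_id[manifest_has_flag(manifest,
                                                    "sex_chromosome")]
  sex_probes <- intersect(sex_probes, rownames(bm$values))
  if (!length(sex_probes)) {
    warnf("no sex-chromosome probes present; sex check skipped")
    return(character(0))
  }
  m <- colMeans(bm$values[sex_probes, , drop = FALSE], na.rm = TRUE)
  if (max(m) - min(m) < 1e-12) {
    warnf("sex-chromosome methylation is constant; single cluster")
    return(character(0))
  }
  # 1-D 2-means with deterministic extreme initialization
  centers <- c(min(m), max(m))
  for (it in 1:100) {
    assign_hi <- m > mean(centers)
    new_centers <- c(mean(m[!assign_hi]), mean(m[assign_hi]))
    if (anyNA(new_centers) || isTRUE(all.equal(new_centers, centers))) break
    centers <- new_centers
  }
  cluster <- ifelse(m > mean(centers), "hi", "lo")
  reported <- setNames(sheet$sex, sheet$sample_id)[names(m)]
  mismatch_for <- function(map) names(m)[map[cluster] != reported]
  m1 <- mismatch_for(c(hi = "M", lo = "F"))
  m2 <- mismatch_for(c(hi = "F", lo = "M"))
  if (length(m1) <= length(m2)) m1 else m2
}

#' Run the full QC and normalization chain
#'
#' Order: sample detection filter, probe detection/beadcount filter,
#' flagged-probe exclusion, then within-type quantile normalization.
#'
#' @param bm a [beta_matrix()] with QC layers.
#' @param manifest a [probe_manifest()].
#' @param sheet a [sample_sheet()].
#' @param config a [pipeline_config()].
#' @return list(beta, beta_raw (filtered, unnormalized), manifest, sheet,
#'   reports, sex_mismatches).
#' @export
run_qc <- function(bm, manifest, sheet, config = pipeline_config()) {
  s <- filter_samples_by_detection(bm, config$sample_detection_p,
                                   config$sample_fail_fraction)
  bm <- subset_beta(bm, samples = s$retained)
  p <- filter_probes(bm, config$probe_detection_p, config$probe_fail_fraction,
                     config$beadcount_min, config$beadcount_fraction)
  bm <- subset_beta(bm, probes = p$retained)
  manifest2 <- manifest[manifest$probe_id %in% p$retained, , drop = FALSE]
  keep <- exclude_flagged_probes(manifest2, config$exclude_flags)
  n_before_flags <- nrow(manifest2)
  flag_report <- qc_report("probes",
                           setdiff(manifest2$probe_id, keep),
                           setNames(rep("flagged",
                                        n_before_flags - length(keep)),
                                    setdiff(manifest2$probe_id, keep)),
                           n_before_flags)
  sex_mismatches <- check_sex(bm, manifest, sheet)
  bm <- subset_beta(bm, probes = keep)
  manifest2 <- manifest2[manifest2$probe_id %in% keep, , drop = FALSE]
  bm_raw <- bm
  bm <- quantile_normalize_by_type(bm, manifest2)
  sheet2 <- sheet[sheet$sample_id %in% colnames(bm$values), , drop = FALSE]
  class(sheet2) <- class(sheet)
  list(beta = bm, beta_raw = bm_raw, manifest = manifest2, sheet = sheet2,
       reports = list(samples = s$report, probes = p$report,
                      flags = flag_report),
       sex_mismatches = sex_mismatches)
}
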