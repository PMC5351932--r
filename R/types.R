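known_flag_classes <- function() {
  c("sex_chromosome", "cross_hybridizing", "snp_proximal", "control_snp")
}

#' Probe manifest
#'
#' Genomic coordinates and exclusion flags for each array probe. Coordinates
#' are 1-based positions. Flags mark probes scheduled for exclusion during
#' QC: probes on sex chromosomes, cross-hybridizing probes, probes with a
#' nearby SNP, and dedicated genotyping control probes.
#'
#' @param probe_id character, unique.
#' @param chrom character chromosome names.
#' @param pos integer, 1-based positions.
#' @param probe_type "I" or "II" (Infinium design type).
#' @param flags character; per probe, flag classes joined by ";" ("" = none).
#' @return A `probe_manifest` data.frame sorted by (chrom, pos).
#' @export
probe_manifest <- function(probe_id, chrom, pos, probe_type = "II",
                           flags = "") {
  n <- length(probe_id)
  df <- data.frame(probe_id = as.character(probe_id),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   probe_type = rep_len(as.character(probe_type), n),
                   flags = rep_len(as.character(flags), n),
                   stringsAsFactors = FALSE)
  validate_manifest(df)
  df <- df[order(df$chrom, df$pos, df$probe_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("probe_manifest", "data.frame")
  df
}

validate_manifest <- function(df) {
  if (anyDuplicated(df$probe_id))
    stopf("duplicate probe id(s): %s",
          paste(unique(df$probe_id[duplicated(df$probe_id)]), collapse = ", "))
  if (any(!is.finite(df$pos) | df$pos < 1))
    stopf("probe positions must be integers >= 1")
  if (!all(df$probe_type %in% c("I", "II")))
    stopf("probe_type must be 'I' or 'II'")
  key <- paste(df$chrom, df$pos, df$probe_id)
  if (anyDuplicated(key))
    stopf("duplicate (chrom, pos, probe_id) row(s)")
  fl <- unlist(strsplit(df$flags[nzchar(df$flags)], ";", fixed = TRUE))
  bad <- setdiff(unique(fl), known_flag_classes())
  if (length(bad))
    stopf("unknown flag class(es): %s", paste(bad, collapse = ", "))
  invisible(df)
}

manifest_has_flag <- function(manifest, classes) {
  bad <- setdiff(classes, known_flag_classes())
  if (length(bad))
    stopf("unknown flag class(es): %s", paste(bad, collapse = ", "))
  vapply(strsplit(manifest$flags, ";", fixed = TRUE),
         function(f) any(f %in% classes), logical(1))
}

#' Beta-value matrix with optional QC layers
#'
#' Methylation proportions (beta values) for probes (rows) by samples
#' (columns), each in `[0,1]`, optionally carrying same-shape detection
#' p-value and beadcount layers used by the QC filters.
#'
#' @param values numeric matrix in `[0,1]` with probe rownames and sample
#'   colnames.
#' @param detection_p optional numeric matrix in `[0,1]`, same dimnames.
#' @param beadcount optional non-negative integer matrix, same dimnames.
#' @return A `beta_matrix` object.
#' @export
beta_matrix <- function(values, detection_p = NULL, beadcount = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("beta values need probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate probe id(s) in beta matrix")
  if (anyDuplicated(colnames(values)))
    stopf("duplicate sample id(s) in beta matrix")
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("beta value outside [0,1] at (%s, %s)",
          rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]])
  }
  check_layer <- function(layer, name) {
    if (is.null(layer)) return(NULL)
    if (!is.matrix(layer)) layer <- as.matrix(layer)
    if (!identical(dim(layer), dim(values)) ||
        !identical(dimnames(layer), dimnames(values)))
      stopf("%s layer must share shape and dimnames with beta values", name)
    layer
  }
  dp <- check_layer(detection_p, "detection_p")
  if (!is.null(dp) && any(!is.na(dp) & (dp < 0 | dp > 1)))
    stopf("detection p-values must lie in [0,1]")
  bc <- check_layer(beadcount, "beadcount")
  if (!is.null(bc)) {
    if (any(!is.na(bc) & bc < 0)) stopf("beadcounts must be non-negative")
    storage.mode(bc) <- "double"
  }
  structure(list(values = values, detection_p = dp, beadcount = bc),
            class = "beta_matrix")
}

#' @export
dim.beta_matrix <- function(x) dim(x$values)

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d probes x %d samples; layers: %s\n",
              nrow(x$values), ncol(x$values),
              paste(c("values",
                      if (!is.null(x$detection_p)) "detection_p",
                      if (!is.null(x$beadcount)) "beadcount"),
                    collapse = ", ")))
  invisible(x)
}

# Subset a beta_matrix (and its layers) by probe and/or sample ids.
subset_beta <- function(bm, probes = NULL, samples = NULL) {
  pi <- probes %||% rownames(bm$values)
  si <- samples %||% colnames(bm$values)
  beta_matrix(bm$values[pi, si, drop = FALSE],
              detection_p = if (!is.null(bm$detection_p))
                bm$detection_p[pi, si, drop = FALSE],
              beadcount = if (!is.null(bm$beadcount))
                bm$beadcount[pi, si, drop = FALSE])
}

#' Sample sheet
#'
#' One record per array sample: donor, cohort (brain bank), brain region,
#' diagnosis, age at death, sex, and optional derived covariates (neuronal
#' proportion, polygenic risk score). A donor contributes at most one sample
#' per region within a cohort.
#'
#' @param df data.frame with columns `sample_id`, `donor_id`, `cohort`,
#'   `region`, `diagnosis` ("case"/"control"), `age`, `sex` ("M"/"F") and
#'   optionally `neuronal_prop`, `prs`; extra columns are preserved.
#' @return A validated `sample_sheet` data.frame.
#' @export
sample_sheet <- function(df) {
  required <- c("sample_id", "donor_id", "cohort", "region", "diagnosis",
                "age", "sex")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stopf("sample sheet is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in c("sample_id", "donor_id", "cohort", "region", "diagnosis",
                "sex"))
    df[[col]] <- as.character(df[[col]])
  df$age <- as.numeric(df$age)
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in sample sheet")
  if (!all(df$diagnosis %in% c("case", "control")))
    stopf("diagnosis must be 'case' or 'control'")
  if (!all(df$sex %in% c("M", "F"))) stopf("sex must be 'M' or 'F'")
  if (any(!is.finite(df$age) | df$age < 0))
    stopf("age must be finite and >= 0")
  key <- paste(df$donor_id, df$region, df$cohort)
  if (anyDuplicated(key))
    stopf("duplicate (donor_id, region) within cohort: %s",
          paste(unique(key[duplicated(key)]), collapse = "; "))
  if (is.null(df$neuronal_prop)) df$neuronal_prop <- NA_real_
  if (is.null(df$prs)) df$prs <- NA_real_
  np <- df$neuronal_prop
  if (any(!is.na(np) & (np < 0 | np > 1)))
    stopf("neuronal_prop must lie in [0,1] where present")
  rownames(df) <- NULL
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Genotype dosage set
#'
#' SNP-by-sample additive dosages in `[0,2]` (NA = missing) together with a
#' SNP map giving position and the allele the dosage counts.
#'
#' @param dosage numeric matrix, SNPs x samples, entries in `[0,2]` or NA;
#'   rownames are SNP ids.
#' @param map data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele` matching the dosage rows.
#' @return A `genotype_set` object.
#' @export
genotype_set <- function(dosage, map) {
  if (!is.matrix(dosage)) dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    stopf("dosage matrix needs SNP rownames and sample colnames")
  if (anyDuplicated(rownames(dosage))) stopf("duplicate snp_id in dosages")
  bad <- which(!is.na(dosage) & (dosage < 0 | dosage > 2), arr.ind = TRUE)
  if (nrow(bad))
    stopf("dosage outside [0,2] at (%s, %s)",
          rownames(dosage)[bad[1, 1]], colnames(dosage)[bad[1, 2]])
  req <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(req %in% names(map)))
    stopf("SNP map is missing column(s): %s",
          paste(setdiff(req, names(map)), collapse = ", "))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  map$snp_id <- as.character(map$snp_id)
  map$effect_allele <- toupper(as.character(map$effect_allele))
  map$other_allele <- toupper(as.character(map$other_allele))
  map$pos <- as.integer(map$pos)
  if (anyDuplicated(map$snp_id)) stopf("duplicate snp_id in map")
  if (!setequal(map$snp_id, rownames(dosage)))
    stopf("SNP map and dosage rows must list the same SNPs")
  map <- map[match(rownames(dosage), map$snp_id), , drop = FALSE]
  rownames(map) <- NULL
  structure(list(dosage = dosage, map = map), class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("<genotype_set> %d SNPs x %d samples\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Polygenic score weight file
#'
#' @param snp_id character, unique.
#' @param effect_allele character (upper-cased).
#' @param weight finite numeric per-allele weights.
#' @return A `score_file` data.frame.
#' @export
score_file <- function(snp_id, effect_allele, weight) {
  df <- data.frame(snp_id = as.character(snp_id),
                   effect_allele = toupper(as.character(effect_allele)),
                   weight = as.numeric(weight), stringsAsFactors = FALSE)
  if (anyDuplicated(df$snp_id)) stopf("duplicate snp_id in score file")
  if (any(!is.finite(df$weight))) stopf("score weights must be finite")
  class(df) <- c("score_file", "data.frame")
  df
}
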