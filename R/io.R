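read_tsv_matrix <- function(path, na_token = "NA") {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = na_token, data.table = FALSE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

write_tsv_matrix <- function(m, path, id_col, na_token = "NA") {
  # %.17g guarantees bitwise round-trips of doubles through text
  txt <- matrix(sprintf("%.17g", m), nrow(m))
  txt[is.na(m)] <- NA_character_
  df <- data.frame(id = rownames(m), txt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m))
  data.table::fwrite(df, path, sep = "\t", na = na_token, quote = FALSE)
  invisible(path)
}

#' Read a beta-value matrix
#'
#' Reads a tab-separated probes-by-samples table (header row of sample ids,
#' first column of probe ids), validates every value against `[0,1]`, and
#' aligns rows to the manifest's probe order. Probes present in the file but
#' absent from the manifest are an error.
#'
#' @param path TSV file of beta values.
#' @param manifest a [probe_manifest()].
#' @param detection_p_path,beadcount_path optional same-shape TSV layers.
#' @param na_token string representing missing cells (default "NA").
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path, manifest, detection_p_path = NULL,
                             beadcount_path = NULL, na_token = "NA") {
  m <- read_tsv_matrix(path, na_token)
  if (anyDuplicated(rownames(m)))
    stopf("duplicate probe id(s) in %s", path)
  unknown <- setdiff(rownames(m), manifest$probe_id)
  if (length(unknown))
    stopf("probe(s) absent from manifest: %s",
          paste(utils::head(unknown, 5L), collapse = ", "))
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad))
    stopf("beta value outside [0,1] at (%s, %s) in %s",
          rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]], path)
  ord <- manifest$probe_id[manifest$probe_id %in% rownames(m)]
  m <- m[ord, , drop = FALSE]
  load_layer <- function(p) {
    if (is.null(p)) return(NULL)
    l <- read_tsv_matrix(p, na_token)
    l[ord, colnames(m), drop = FALSE]
  }
  beta_matrix(m, detection_p = load_layer(detection_p_path),
              beadcount = load_layer(beadcount_path))
}

#' Write a beta-value matrix (and layers) to TSV
#'
#' @param bm a [beta_matrix()].
#' @param path output TSV for the beta values.
#' @param detection_p_path,beadcount_path optional output paths for layers.
#' @inheritParams read_beta_matrix
#' @export
write_beta_matrix <- function(bm, path, detection_p_path = NULL,
                              beadcount_path = NULL, na_token = "NA") {
  write_tsv_matrix(bm$values, path, "probe_id", na_token)
  if (!is.null(detection_p_path) && !is.null(bm$detection_p))
    write_tsv_matrix(bm$detection_p, detection_p_path, "probe_id", na_token)
  if (!is.null(beadcount_path) && !is.null(bm$beadcount))
    write_tsv_matrix(bm$beadcount, beadcount_path, "probe_id", na_token)
  invisible(path)
}

#' Read / write a probe manifest (BED-like TSV)
#'
#' Columns: chrom, pos (1-based), probe_id, probe_type, flags
#' (";"-separated, empty for none).
#'
#' @param path TSV file.
#' @export
read_manifest <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = NULL, colClasses = list(
                            character = c("chrom", "probe_id", "probe_type",
                                          "flags")))
  df$flags[is.na(df$flags)] <- ""
  probe_manifest(df$probe_id, df$chrom, df$pos, df$probe_type, df$flags)
}

#' @rdname read_manifest
#' @param manifest a [probe_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  out <- manifest[, c("chrom", "pos", "probe_id", "probe_type", "flags")]
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read / write a sample sheet (CSV)
#'
#' @param path CSV file with the required sample-sheet columns; unknown
#'   columns are preserved.
#' @export
read_sample_sheet <- function(path) {
  df <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          na.strings = c("NA", ""))
  sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet a [sample_sheet()].
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(as.data.frame(sheet), path, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read / write a genotype dosage table (PLINK traw-like TSV)
#'
#' Map columns (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`)
#' followed by one numeric dosage column per sample. Missing cells carry the
#' NA token, never 0.
#'
#' @param path TSV file.
#' @param na_token missing-cell token (default "NA").
#' @export
read_dosages <- function(path, na_token = "NA") {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          na.strings = na_token, data.table = FALSE)
  mapcols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(mapcols %in% names(df)))
    stopf("dosage file is missing map column(s): %s",
          paste(setdiff(mapcols, names(df)), collapse = ", "))
  d <- as.matrix(df[, setdiff(names(df), mapcols), drop = FALSE])
  storage.mode(d) <- "double"
  rownames(d) <- as.character(df$snp_id)
  genotype_set(d, df[, mapcols])
}

#' @rdname read_dosages
#' @param genos a [genotype_set()].
#' @export
write_dosages <- function(genos, path, na_token = "NA") {
  out <- cbind(genos$map, as.data.frame(genos$dosage, check.names = FALSE))
  data.table::fwrite(out, path, sep = "\t", na = na_token, quote = FALSE)
  invisible(path)
}

#' Read a polygenic score weight file
#'
#' Whitespace-delimited, PLINK `--score`-compatible column order:
#' SNP id, effect allele, weight. A header line is detected and skipped when
#' the third field of the first line is not numeric.
#'
#' @param path score file.
#' @export
read_score_file <- function(path) {
  first <- strsplit(trimws(readLines(path, n = 1L)), "\\s+")[[1]]
  has_header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3])))
  df <- utils::read.table(path, header = has_header,
                          stringsAsFactors = FALSE)[, 1:3]
  names(df) <- c("snp_id", "effect_allele", "weight")
  score_file(df$snp_id, df$effect_allele, df$weight)
}

#' @rdname read_score_file
#' @param score a [score_file()].
#' @export
write_score_file <- function(score, path) {
  utils::write.table(as.data.frame(score), path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write an association table (TSV)
#'
#' Per-probe effect (% methylation difference), standard error, statistic,
#' p-value, sample size, degrees of freedom and status code.
#'
#' @param path TSV file.
#' @export
read_assoc_table <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          na.strings = "NA")
  validate_assoc(df)
}

#' @rdname read_assoc_table
#' @param assoc an association table.
#' @export
write_assoc_table <- function(assoc, path) {
  data.table::fwrite(as.data.frame(assoc), path, sep = "\t", na = "NA",
                     quote = FALSE)
  invisible(path)
}

validate_assoc <- function(df) {
  req <- c("probe_id", "estimate", "se", "stat", "p", "n")
  if (!all(req %in% names(df)))
    stopf("association table is missing column(s): %s",
          paste(setdiff(req, names(df)), collapse = ", "))
  if (is.null(df$df)) df$df <- NA_real_
  if (is.null(df$status)) df$status <- "ok"
  ok <- df$status == "ok"
  if (any(ok & (!is.finite(df$p) | df$p <= 0 | df$p > 1)))
    stopf("fitted rows must have p in (0,1]")
  if (any(ok & df$se < 0)) stopf("standard errors must be >= 0")
  df
}

#' Write detected regions as BED-compatible TSV
#'
#' Columns chrom, start, end (1-based inclusive of first and last probe
#' position) plus `n_probes`, `p_combined`, `p_sidak` and the member probe
#' ids (";"-separated).
#'
#' @param regions region table from [call_dmrs()].
#' @param path output file.
#' @export
write_regions <- function(regions, path) {
  data.table::fwrite(as.data.frame(regions), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_regions
#' @export
read_regions <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}
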