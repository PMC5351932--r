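# Small in-code fixtures shared across the suite.

tiny_manifest <- function(n = 6, chrom = "chr1", gap = 100, flags = "") {
  probe_manifest(sprintf("p%02d", seq_len(n)), chrom,
                 seq(1000, by = gap, length.out = n), "II", flags)
}

tiny_sheet <- function(n_case = 3, n_ctrl = 3, region = "PFC",
                       cohort = "LNDBB") {
  n <- n_case + n_ctrl
  sample_sheet(data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    donor_id = sprintf("d%02d", seq_len(n)),
    cohort = cohort, region = region,
    diagnosis = rep(c("case", "control"), c(n_case, n_ctrl)),
    age = seq(40, 80, length.out = n),
    sex = rep_len(c("M", "F"), n), stringsAsFactors = FALSE))
}

tiny_beta <- function(manifest, sheet, values = NULL, seed = 1) {
  n_p <- nrow(manifest)
  n_s <- nrow(sheet)
  if (is.null(values)) {
    values <- withr::with_seed(seed,
                               matrix(runif(n_p * n_s, 0.1, 0.9), n_p, n_s))
  }
  dimnames(values) <- list(manifest$probe_id, sheet$sample_id)
  beta_matrix(values,
              detection_p = matrix(0, n_p, n_s, dimnames = dimnames(values)),
              beadcount = matrix(10L, n_p, n_s,
                                 dimnames = dimnames(values)))
}

# Independent brute-force oracle for the exact two-sided Fisher p:
# enumerate every table with the observed margins and sum hypergeometric
# probabilities no larger than the observed table's.
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(ks, c1, n - c1, r1)
  obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Independent brute-force oracle for the Levene-Haldane exact HWE p:
# enumerate all heterozygote counts compatible with the allele margins.
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  minor <- min(nA, na)
  if (minor == 0) return(1)
  hs <- seq(minor %% 2, minor, by = 2)
  pr <- vapply(hs, function(h) {
    exp(lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
          lfactorial((na - h) / 2) + h * log(2) +
          lfactorial(nA) + lfactorial(na) - lfactorial(2 * n))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  min(sum(pr[pr <= obs * (1 + 1e-9)]), 1)
}
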