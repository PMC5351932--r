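# One-sided z transform used throughout the region stack; p = 1 is clamped
# just inside the open interval before the quantile.
p_to_z <- function(p) {
  qnorm(1 - clamp(p, 1e-300, 1 - 1e-16))
}

#' Estimate the distance-binned autocorrelation of association z-scores
#'
#' For each half-open distance bin, the Pearson correlation of
#' `z = qnorm(1 - p)` over all same-chromosome probe pairs whose distance
#' falls in the bin. Bins with fewer than `min_pairs` pairs, and negative
#' estimates, are truncated to 0 — the combination step never deflates
#' variance.
#'
#' @param p per-probe p-values in (0,1).
#' @param chrom,pos per-probe chromosome and 1-based position (coordinate
#'   sorted within chromosome).
#' @param breaks bin edges in bp (default `(0,50], ..., (250,300]`).
#' @param min_pairs minimum pairs per usable bin (default 50).
#' @return An `acf_estimate`: data.frame(lo, hi, cor, n_pairs).
#' @export
estimate_acf <- function(p, chrom, pos, breaks = seq(0, 300, by = 50),
                         min_pairs = 50) {
  if (any(!is.finite(p) | p <= 0 | p >= 1))
    stopf("p-values must lie strictly within (0,1) for ACF estimation")
  z <- p_to_z(p)
  max_d <- max(breaks)
  nb <- length(breaks) - 1L
  zi <- vector("list", nb)
  zj <- vector("list", nb)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cpos <- pos[idx]
    o <- order(cpos)
    idx <- idx[o]; cpos <- cpos[o]
    n <- length(idx)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      jmax <- i
      while (jmax < n && cpos[jmax + 1] - cpos[i] <= max_d) jmax <- jmax + 1
      if (jmax == i) next
      js <- (i + 1):jmax
      d <- cpos[js] - cpos[i]
      b <- findInterval(d, breaks, left.open = TRUE)
      b[d <= breaks[1]] <- 0L
      keep <- b >= 1 & b <= nb
      for (bb in unique(b[keep])) {
        sel <- js[keep & b == bb]
        zi[[bb]] <- c(zi[[bb]], rep(z[idx[i]], length(sel)))
        zj[[bb]] <- c(zj[[bb]], z[idx[sel]])
      }
    }
  }
  cors <- numeric(nb)
  n_pairs <- integer(nb)
  for (bb in seq_len(nb)) {
    n_pairs[bb] <- length(zi[[bb]])
    if (n_pairs[bb] < min_pairs) {
      warnf("ACF bin (%d,%d] has %d pairs (< %d); set to 0",
            breaks[bb], breaks[bb + 1], n_pairs[bb], min_pairs)
      cors[bb] <- 0
    } else {
      x <- c(zi[[bb]], zj[[bb]])
      y <- c(zj[[bb]], zi[[bb]])  # symmetrized
      cc <- suppressWarnings(cor(x, y))
      cors[bb] <- if (is.finite(cc)) max(cc, 0) else 0
    }
  }
  structure(data.frame(lo = breaks[-length(breaks)], hi = breaks[-1],
                       cor = cors, n_pairs = n_pairs),
            class = c("acf_estimate", "data.frame"))
}

# Correlation at a set of pairwise distances under the step-function ACF:
# the bin's estimate within a bin, 0 beyond the last bin, 1 at distance 0.
acf_at <- function(acf, d) {
  out <- numeric(length(d))
  out[d <= 0] <- 1
  b <- findInterval(d, c(acf$lo[1], acf$hi), left.open = TRUE)
  inside <- d > 0 & b >= 1 & b <= nrow(acf)
  out[inside] <- acf$cor[b[inside]]
  out
}

# Correlation matrix for member probes at given positions.
sigma_from_acf <- function(pos, acf) {
  n <- length(pos)
  S <- diag(1, n)
  if (n > 1) {
    d <- abs(outer(pos, pos, "-"))
    S[] <- acf_at(acf, as.vector(d))
    diag(S) <- 1
  }
  S
}

#' Stouffer-Liptak combination of correlated p-values
#'
#' Combines p-values with `z_i = qnorm(1 - p_i)`,
#' `C = sum(z) / sqrt(sum(Sigma))`, returning `1 - pnorm(C)`. With the
#' identity matrix this is the classic Stouffer combination; a perfectly
#' correlated set of equal p-values is returned unchanged.
#'
#' @param p p-values in (0,1].
#' @param sigma correlation matrix (symmetric, unit diagonal, entries in
#'   `[0,1]`); defaults to the identity.
#' @return Combined p-value.
#' @export
stouffer_liptak <- function(p, sigma = NULL) {
  k <- length(p)
  if (k == 1) return(p)
  if (is.null(sigma)) sigma <- diag(1, k)
  if (!isTRUE(all.equal(sigma, t(sigma))) ||
      any(abs(diag(sigma) - 1) > 1e-12) ||
      any(sigma < -1e-12 | sigma > 1 + 1e-12))
    stopf("sigma must be symmetric with unit diagonal and entries in [0,1]")
  total <- sum(sigma)
  if (total <= 0) stopf("total covariance must be positive")
  C <- sum(p_to_z(p)) / sqrt(total)
  min(max(1 - pnorm(C), .Machine$double.xmin), 1)
}

#' Autocorrelation-aware p-value smoothing
#'
#' Replaces each probe's p-value by the Stouffer-Liptak combination of all
#' probes within `window` bp on the same chromosome, with the correlation
#' matrix taken from the ACF at pairwise distances. Isolated probes are
#' unchanged.
#'
#' @param p per-probe p-values.
#' @param chrom,pos per-probe coordinates.
#' @param acf an [estimate_acf()] result.
#' @param window half-width in bp (default 300).
#' @return Adjusted p-values in the input order.
#' @export
smooth_adjust <- function(p, chrom, pos, acf, window = 300) {
  out <- p
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    o <- order(pos[idx])
    idx <- idx[o]
    cpos <- pos[idx]
    n <- length(idx)
    lo <- 1L
    hi <- 1L
    for (i in seq_len(n)) {
      while (cpos[i] - cpos[lo] > window) lo <- lo + 1L
      if (hi < i) hi <- i
      while (hi < n && cpos[hi + 1] - cpos[i] <= window) hi <- hi + 1L
      nb <- lo:hi
      if (length(nb) == 1) next
      S <- sigma_from_acf(cpos[nb], acf)
      out[idx[i]] <- stouffer_liptak(p[idx[nb]], S)
    }
  }
  out
}

#' Find candidate regions of spatially clustered small p-values
#'
#' Maximal runs of probes with adjusted p below `seed_p` in which
#' consecutive members are at most `max_gap` bp apart; runs shorter than
#' `min_probes` are discarded. Intervals are reported 1-based inclusive of
#' the first and last probe position.
#'
#' @param p adjusted per-probe p-values.
#' @param chrom,pos per-probe coordinates (sorted by position within
#'   chromosome; unsorted input is an error).
#' @param probe_id per-probe ids.
#' @param seed_p seed threshold (default 1e-3).
#' @param max_gap maximum member spacing in bp (default 300).
#' @param min_probes minimum probes per region (default 2).
#' @return data.frame(chrom, start, end, n_probes, probe_ids) — possibly
#'   empty.
#' @export
find_regions <- function(p, chrom, pos, probe_id = NULL, seed_p = 1e-3,
                         max_gap = 300, min_probes = 2) {
  if (is.null(probe_id)) probe_id <- as.character(seq_along(p))
  out <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cpos <- pos[idx]
    if (is.unsorted(cpos)) stopf("positions must be sorted within chromosome")
    below <- p[idx] < seed_p
    run_start <- NULL
    members <- integer(0)
    flush <- function(members) {
      if (length(members) >= min_probes) {
        out[[length(out) + 1L]] <<- data.frame(
          chrom = ch, start = cpos[members[1]],
          end = cpos[members[length(members)]],
          n_probes = length(members),
          probe_ids = paste(probe_id[idx[members]], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    for (i in seq_along(idx)) {
      if (below[i]) {
        if (length(members) &&
            cpos[i] - cpos[members[length(members)]] > max_gap) {
          flush(members)
          members <- integer(0)
        }
        members <- c(members, i)
      } else if (length(members)) {
        # a non-seed probe does not break a run unless the gap rule does
        next
      }
    }
    flush(members)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_probes = integer(0),
                      probe_ids = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Combined p-value of one region
#'
#' Stouffer-Liptak over the raw member p-values with the correlation matrix
#' from the ACF at member pairwise distances (0 beyond the last bin).
#'
#' @param p raw member p-values (region order).
#' @param pos member positions.
#' @param acf an [estimate_acf()] result.
#' @return Combined p-value.
#' @export
score_region <- function(p, pos, acf) {
  stouffer_liptak(p, sigma_from_acf(pos, acf))
}

#' Sidak correction of a region's combined p-value
#'
#' `p_sidak = 1 - (1 - p)^(n_a / n_r)` with `n_a` the total probes tested
#' in the EWAS and `n_r` the probes in the region, evaluated in log space
#' for small p.
#'
#' @param p_combined combined p in `[0,1]`.
#' @param n_a total probes tested (>= n_r).
#' @param n_r probes in the region (>= 1).
#' @return Corrected p-value.
#' @export
sidak_correct <- function(p_combined, n_a, n_r) {
  if (any(p_combined < 0 | p_combined > 1)) stopf("p must lie in [0,1]")
  if (any(n_r < 1) || any(n_a < n_r)) stopf("need n_a >= n_r >= 1")
  -expm1((n_a / n_r) * log1p(-p_combined))
}

#' Detect differentially methylated regions from an association table
#'
#' The full region pipeline: estimate the distance-binned autocorrelation
#' of the EWAS z-scores, optionally smooth each probe's p against its
#' neighbours, find candidate runs below the seed threshold, score each
#' region by correlation-aware Stouffer-Liptak combination of the raw
#' member p-values, and apply the Sidak correction for `n_a / n_r` tests.
#'
#' @param assoc association table from [run_ewas()] / [meta_ewas()].
#' @param manifest a [probe_manifest()] covering the fitted probes.
#' @param config a [pipeline_config()] (seed p, gap, min probes).
#' @param smooth seed on smoothed p-values (default TRUE); when FALSE,
#'   seeding uses the raw p-values.
#' @param acf optionally precomputed [estimate_acf()] result.
#' @return data.frame(chrom, start, end, n_probes, probe_ids, p_combined,
#'   p_sidak, n_a) sorted by p_sidak.
#' @export
call_dmrs <- function(assoc, manifest, config = pipeline_config(),
                      smooth = TRUE, acf = NULL) {
  ok <- assoc$status == "ok" & is.finite(assoc$p)
  assoc <- assoc[ok, , drop = FALSE]
  i <- match(assoc$probe_id, manifest$probe_id)
  if (anyNA(i)) stopf("association probes missing from manifest")
  chrom <- manifest$chrom[i]
  pos <- manifest$pos[i]
  o <- order(chrom, pos)
  assoc <- assoc[o, , drop = FALSE]
  chrom <- chrom[o]; pos <- pos[o]
  p_raw <- clamp(assoc$p, 1e-300, 1 - 1e-16)
  if (is.null(acf)) {
    acf <- suppressWarnings(estimate_acf(p_raw, chrom, pos))
  }
  p_seed <- if (smooth) smooth_adjust(p_raw, chrom, pos, acf) else p_raw
  regions <- find_regions(p_seed, chrom, pos, assoc$probe_id,
                          seed_p = config$dmr_seed_p,
                          max_gap = config$dmr_max_gap,
                          min_probes = config$dmr_min_probes)
  n_a <- nrow(assoc)
  if (!nrow(regions)) {
    regions$p_combined <- numeric(0)
    regions$p_sidak <- numeric(0)
    regions$n_a <- integer(0)
    return(regions)
  }
  pc <- numeric(nrow(regions))
  for (r in seq_len(nrow(regions))) {
    ids <- strsplit(regions$probe_ids[r], ";", fixed = TRUE)[[1]]
    m <- match(ids, assoc$probe_id)
    pc[r] <- score_region(p_raw[m], pos[m], acf)
  }
  regions$p_combined <- pc
  regions$p_sidak <- sidak_correct(pc, n_a, regions$n_probes)
  regions$n_a <- n_a
  regions[order(regions$p_sidak, regions$chrom, regions$start), ,
          drop = FALSE]
}
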