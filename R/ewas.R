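#' EWAS model specification
#'
#' Defines the probe-wise regression model: the exposure (diagnosis or
#' polygenic risk score), the covariate list, and optional restriction to
#' one brain region and/or cohort. By default the neuronal-proportion
#' covariate is dropped for cerebellum models, where bulk NeuN-based
#' deconvolution is not meaningful.
#'
#' @param exposure "diagnosis" or "prs".
#' @param covariates subset of `{"age","sex","neuronal_prop"}`.
#' @param region optional region restriction.
#' @param cohort optional cohort restriction.
#' @param drop_neuronal_regions regions for which `neuronal_prop` is
#'   removed from the covariates (default "CER").
#' @return A `model_spec` list.
#' @export
model_spec <- function(exposure = c("diagnosis", "prs"),
                       covariates = c("age", "sex", "neuronal_prop"),
                       region = NULL, cohort = NULL,
                       drop_neuronal_regions = "CER") {
  exposure <- match.arg(exposure)
  allowed <- c("age", "sex", "neuronal_prop")
  bad <- setdiff(covariates, allowed)
  if (length(bad)) stopf("unknown covariate(s): %s", paste(bad, collapse = ", "))
  if (exposure %in% covariates)
    stopf("exposure must not be duplicated among covariates")
  if (!is.null(region) && region %in% drop_neuronal_regions)
    covariates <- setdiff(covariates, "neuronal_prop")
  structure(list(exposure = exposure, covariates = covariates,
                 region = region, cohort = cohort),
            class = "model_spec")
}

# Restrict a sample sheet to the spec's region/cohort.
spec_samples <- function(sheet, spec) {
  keep <- rep(TRUE, nrow(sheet))
  if (!is.null(spec$region)) keep <- keep & sheet$region == spec$region
  if (!is.null(spec$cohort)) keep <- keep & sheet$cohort == spec$cohort
  sheet[keep, , drop = FALSE]
}

# Design matrix for a model spec; diagnosis coded control = 0 / case = 1
# (positive estimates = hypermethylation in cases), sex coded F = 0 / M = 1.
build_design <- function(sheet, spec, pcs = NULL) {
  n <- nrow(sheet)
  X <- matrix(1, n, 1, dimnames = list(sheet$sample_id, "(Intercept)"))
  expo <- switch(spec$exposure,
                 diagnosis = as.numeric(sheet$diagnosis == "case"),
                 prs = as.numeric(sheet$prs))
  X <- cbind(X, exposure = expo)
  for (cv in spec$covariates) {
    col <- switch(cv,
                  age = as.numeric(sheet$age),
                  sex = as.numeric(sheet$sex == "M"),
                  neuronal_prop = as.numeric(sheet$neuronal_prop))
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  if (!is.null(pcs)) {
    pcs <- as.matrix(pcs)
    X <- cbind(X, pcs[sheet$sample_id, , drop = FALSE])
  }
  X
}

# OLS of one response on a design, t-test on the "exposure" column.
# Returns a flagged (not failed) row on rank deficiency / insufficient n.
ols_exposure <- function(y, X) {
  ok <- is.finite(y) & rowSums(!is.finite(X)) == 0
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y)
  k <- ncol(X)
  out <- list(estimate = NA_real_, se = NA_real_, stat = NA_real_,
              p = NA_real_, n = n, df = NA_real_, status = "ok")
  if (n < k + 2) { out$status <- "insufficient_n"; return(out) }
  qr_x <- qr(X)
  if (qr_x$rank < k) { out$status <- "rank_deficient"; return(out) }
  coefs <- qr.coef(qr_x, y)
  res <- y - X %*% coefs
  df <- n - k
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qr_x))
  j <- match("exposure", colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  est <- coefs[j]
  stat <- if (se > 0) est / se else 0
  p <- 2 * pt(-abs(stat), df)
  list(estimate = unname(est), se = unname(se), stat = unname(stat),
       p = max(unname(p), .Machine$double.xmin), n = n, df = df,
       status = "ok")
}

#' Fit a single probe's association model
#'
#' Ordinary least squares of one probe's beta values on the design implied
#' by a [model_spec()], with a two-sided t-test on the exposure
#' coefficient. Estimates are reported as % methylation difference
#' (coefficient x 100). Samples with any missing covariate are dropped
#' (complete-case); rank-deficient designs yield a flagged row, not an
#' error.
#'
#' @param y numeric beta values, named by sample id.
#' @param sheet a [sample_sheet()] (restricted to the modelled samples).
#' @param spec a [model_spec()].
#' @return One-row data.frame (estimate, se, stat, p, n, df, status).
#' @export
fit_probe <- function(y, sheet, spec) {
  sheet <- spec_samples(sheet, spec)
  X <- build_design(sheet, spec)
  r <- ols_exposure(y[sheet$sample_id], X)
  data.frame(estimate = r$estimate * 100, se = r$se * 100, stat = r$stat,
             p = r$p, n = r$n, df = r$df, status = r$status,
             stringsAsFactors = FALSE)
}

#' Probe-wise EWAS
#'
#' Runs the [model_spec()] regression for every probe. Probes sharing a
#' missingness pattern are fitted in one batched matrix solve, so the scan
#' is a handful of linear-algebra calls rather than a per-probe loop.
#' Unfittable probes carry a reason code in `status` instead of being
#' dropped.
#'
#' @param bm a [beta_matrix()] (or plain probes-x-samples matrix).
#' @param sheet a [sample_sheet()].
#' @param spec a [model_spec()].
#' @param min_samples minimum complete-case sample count (default 10).
#' @return Association table: data.frame(probe_id, estimate (%), se, stat,
#'   p, n, df, status) in the input probe order.
#' @export
run_ewas <- function(bm, sheet, spec, min_samples = 10) {
  values <- if (inherits(bm, "beta_matrix")) bm$values else bm
  if (!nrow(values)) stopf("empty probe set")
  sheet <- spec_samples(sheet, spec)
  X_all <- build_design(sheet, spec)
  cc <- rowSums(!is.finite(X_all)) == 0
  if (sum(cc) < min_samples)
    stopf("fewer than %d samples after complete-case restriction",
          min_samples)
  sheet <- sheet[cc, , drop = FALSE]
  X <- X_all[cc, , drop = FALSE]
  Y <- values[, sheet$sample_id, drop = FALSE]
  k <- ncol(X)
  j <- match("exposure", colnames(X))
  n_probes <- nrow(Y)
  out <- data.frame(probe_id = rownames(Y), estimate = NA_real_,
                    se = NA_real_, stat = NA_real_, p = NA_real_,
                    n = NA_integer_, df = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  # group probes by NA pattern for batched solves
  na_pat <- !is.finite(Y)
  pat_key <- if (any(na_pat)) {
    apply(na_pat, 1, function(r) paste(which(r), collapse = ","))
  } else rep("", n_probes)
  for (key in unique(pat_key)) {
    rows <- which(pat_key == key)
    use <- if (nzchar(key)) {
      setdiff(seq_len(ncol(Y)), as.integer(strsplit(key, ",")[[1]]))
    } else seq_len(ncol(Y))
    n <- length(use)
    if (n < max(k + 2, min_samples)) {
      out$status[rows] <- "insufficient_n"
      out$n[rows] <- n
      next
    }
    Xs <- X[use, , drop = FALSE]
    qr_x <- qr(Xs)
    if (qr_x$rank < k) {
      out$status[rows] <- "rank_deficient"
      out$n[rows] <- n
      next
    }
    Ys <- t(Y[rows, use, drop = FALSE])
    coefs <- qr.coef(qr_x, Ys)                     # k x m
    res <- Ys - Xs %*% coefs
    df <- n - k
    sigma2 <- colSums(res^2) / df
    xtx_inv_jj <- chol2inv(qr.R(qr_x))[j, j]
    se <- sqrt(sigma2 * xtx_inv_jj)
    est <- coefs[j, ]
    stat <- ifelse(se > 0, est / se, 0)
    p <- pmax(2 * pt(-abs(stat), df), .Machine$double.xmin)
    out$estimate[rows] <- est * 100
    out$se[rows] <- se * 100
    out$stat[rows] <- stat
    out$p[rows] <- p
    out$n[rows] <- n
    out$df[rows] <- df
  }
  out
}

#' Genomic inflation factor (lambda)
#'
#' Ratio of the observed median association chi-squared statistic to its
#' null expectation: `lambda = qchisq(1 - median(p), 1) / qchisq(0.5, 1)`.
#' Also returns observed-vs-expected `-log10 p` pairs for QQ plotting.
#'
#' @param p numeric p-values in `(0, 1]` (at least 100).
#' @return list(lambda, qq = data.frame(expected, observed)).
#' @export
genomic_inflation <- function(p) {
  if (length(p) < 100) stopf("need at least 100 p-values")
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stopf("p-values must lie in (0,1]")
  lambda <- qchisq(1 - median(p), df = 1) / qchisq(0.5, df = 1)
  obs <- sort(-log10(p))
  exp_q <- -log10(rev(stats::ppoints(length(p))))
  list(lambda = lambda,
       qq = data.frame(expected = sort(exp_q), observed = obs))
}

#' Principal-component sensitivity analysis
#'
#' Refits the EWAS with the top-`k` methylation PCs appended to the
#' covariates, for `k = 1..k_max`, and reports the Pearson correlation of
#' the per-probe exposure estimates with the PC-free base model.
#'
#' @param bm a [beta_matrix()].
#' @param sheet a [sample_sheet()].
#' @param spec a [model_spec()].
#' @param k_max maximum number of PCs (default 10).
#' @return data.frame(k, cor, status) with one row per k.
#' @export
pc_sensitivity <- function(bm, sheet, spec, k_max = 10) {
  values <- if (inherits(bm, "beta_matrix")) bm$values else bm
  sheet <- spec_samples(sheet, spec)
  base <- run_ewas(values, sheet, spec)
  pcs <- compute_pcs(values[, sheet$sample_id, drop = FALSE], k_max)$scores
  out <- data.frame(k = seq_len(k_max), cor = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  for (k in seq_len(k_max)) {
    fit_k <- run_ewas_with_pcs(values, sheet, spec,
                               pcs[, seq_len(k), drop = FALSE])
    ok <- base$status == "ok" & fit_k$status == "ok"
    if (sum(ok) < 3 || sd(fit_k$estimate[ok]) == 0 ||
        sd(base$estimate[ok]) == 0) {
      out$status[k] <- "collinear"
    } else {
      out$cor[k] <- cor(base$estimate[ok], fit_k$estimate[ok])
    }
  }
  out
}

# run_ewas with extra PC columns in the design.
run_ewas_with_pcs <- function(values, sheet, spec, pcs) {
  X <- build_design(sheet, spec, pcs = pcs)
  qr_x <- qr(X)
  out <- data.frame(probe_id = rownames(values), estimate = NA_real_,
                    se = NA_real_, stat = NA_real_, p = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  if (qr_x$rank < ncol(X)) {
    out$status <- "rank_deficient"
    return(out)
  }
  Y <- t(values[, sheet$sample_id, drop = FALSE])
  coefs <- qr.coef(qr_x, Y)
  res <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  j <- match("exposure", colnames(X))
  se <- sqrt(sigma2 * chol2inv(qr.R(qr_x))[j, j])
  out$estimate <- coefs[j, ] * 100
  out$se <- se * 100
  out$stat <- ifelse(se > 0, coefs[j, ] / se, 0)
  out$p <- pmax(2 * pt(-abs(out$stat), df), .Machine$double.xmin)
  out
}

#' Global mean methylation comparison
#'
#' Averages beta values across all probes per sample and compares cases to
#' controls with a two-sided two-sample t-test. Means are reported in
#' percent.
#'
#' @param bm a [beta_matrix()].
#' @param sheet a [sample_sheet()].
#' @return list(mean_case, mean_control (%), p, formatted — e.g.
#'   `"SZ = 48.43%, CTR = 48.57%"`).
#' @export
global_mean_test <- function(bm, sheet) {
  values <- if (inherits(bm, "beta_matrix")) bm$values else bm
  sheet <- sheet[sheet$sample_id %in% colnames(values), , drop = FALSE]
  m <- colMeans(values[, sheet$sample_id, drop = FALSE], na.rm = TRUE)
  grp <- split(m, sheet$diagnosis)
  if (length(grp) < 2 || any(lengths(grp) < 2))
    stopf("need at least 2 samples per diagnosis group")
  p <- t.test(grp$case, grp$control)$p.value
  mc <- mean(grp$case) * 100
  m0 <- mean(grp$control) * 100
  list(mean_case = mc, mean_control = m0, p = p,
       formatted = sprintf("SZ = %.2f%%, CTR = %.2f%%", mc, m0))
}
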