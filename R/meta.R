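#' Welch two-sample test from group summaries
#'
#' Computes the Welch t statistic and Welch-Satterthwaite degrees of
#' freedom directly from per-group mean, SD and n — the form needed to
#' reanalyse published summary tables.
#'
#' @param mean1,sd1,n1 summaries of group 1.
#' @param mean0,sd0,n0 summaries of group 0.
#' @return list(difference, t, df, p, degenerate).
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean0, sd0, n0) {
  stopifnot(sd1 >= 0, sd0 >= 0, n1 >= 2, n0 >= 2)
  diff <- mean1 - mean0
  v1 <- sd1^2 / n1
  v0 <- sd0^2 / n0
  if (v1 + v0 == 0) {
    if (isTRUE(all.equal(mean1, mean0)))
      return(list(difference = 0, t = 0, df = NA_real_, p = 1,
                  degenerate = TRUE))
    return(list(difference = diff, t = Inf, df = NA_real_, p = 0,
                degenerate = TRUE))
  }
  se <- sqrt(v1 + v0)
  t <- diff / se
  df <- (v1 + v0)^2 / (v1^2 / (n1 - 1) + v0^2 / (n0 - 1))
  list(difference = diff, t = t, df = df, p = 2 * pt(-abs(t), df),
       degenerate = FALSE)
}

#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools per-cohort estimates with weights `w_i = 1/se_i^2`:
#' combined estimate `sum(w th)/sum(w)`, combined `se = 1/sqrt(sum(w))`,
#' Wald z with a two-sided normal p, plus Cochran's Q as a heterogeneity
#' diagnostic. A single-cohort input is returned unchanged.
#'
#' @param estimates per-cohort effect estimates.
#' @param ses per-cohort standard errors (> 0).
#' @return list(estimate, se, z, p, q, components).
#' @export
meta_fixed <- function(estimates, ses) {
  if (!length(estimates)) stopf("need at least one cohort")
  if (length(estimates) != length(ses)) stopf("estimate/se length mismatch")
  if (any(!is.finite(ses) | ses <= 0)) stopf("all ses must be finite and > 0")
  w <- 1 / ses^2
  est <- sum(w * estimates) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- est / se
  q <- sum(w * (estimates - est)^2)
  list(estimate = est, se = se, z = z, p = 2 * pnorm(-abs(z)), q = q,
       components = data.frame(estimate = estimates, se = ses, weight = w))
}

#' Fixed-effects meta-analysis from covariate-adjusted group summaries
#'
#' For each cohort the mean difference between groups of covariate-adjusted
#' values is formed with `se = sqrt(sd1^2/n1 + sd0^2/n0)`, then pooled with
#' [meta_fixed()]. Cohorts with fewer than 2 samples in either group are
#' dropped with a warning.
#'
#' @param summaries data.frame with one row per cohort: `mean1`, `sd1`,
#'   `n1`, `mean0`, `sd0`, `n0`.
#' @return As [meta_fixed()].
#' @export
meta_from_groups <- function(summaries) {
  keep <- summaries$n1 >= 2 & summaries$n0 >= 2
  if (!all(keep)) warnf("dropping %d cohort(s) with group n < 2", sum(!keep))
  s <- summaries[keep, , drop = FALSE]
  if (!nrow(s)) stopf("no usable cohorts")
  md <- s$mean1 - s$mean0
  se <- sqrt(s$sd1^2 / s$n1 + s$sd0^2 / s$n0)
  meta_fixed(md, se)
}

#' Covariate-adjusted beta values
#'
#' Fits the full model (diagnosis plus covariates) and subtracts each
#' sample's fitted covariate contribution, centred so the overall mean is
#' preserved. The group summaries of the adjusted values carry the
#' covariate-adjusted group contrast and feed [meta_from_groups()].
#'
#' @param y numeric response (named by sample id).
#' @param sheet a [sample_sheet()] for those samples.
#' @param covariates covariate names as in [model_spec()].
#' @return Named numeric adjusted values.
#' @export
adjust_betas <- function(y, sheet, covariates = c("age", "sex",
                                                  "neuronal_prop")) {
  spec <- model_spec("diagnosis", covariates)
  X <- build_design(sheet, spec)
  y <- y[sheet$sample_id]
  b <- stats::lm.fit(X, y)$coefficients
  cov_cols <- setdiff(colnames(X), c("(Intercept)", "exposure"))
  if (!length(cov_cols)) return(setNames(y, sheet$sample_id))
  cov_part <- drop(X[, cov_cols, drop = FALSE] %*% b[cov_cols])
  setNames(y - cov_part + mean(cov_part), sheet$sample_id)
}

#' Meta-analyse per-cohort association tables
#'
#' Joins per-cohort EWAS tables on the probes fitted in every cohort and
#' pools estimate/se rows probe-by-probe with [meta_fixed()].
#'
#' @param tables named list of association tables (from [run_ewas()]).
#' @return Combined association table over the common probes.
#' @export
meta_ewas <- function(tables) {
  stopifnot(length(tables) >= 1)
  usable <- lapply(tables, function(t) t[t$status == "ok", , drop = FALSE])
  common <- Reduce(intersect, lapply(usable, `[[`, "probe_id"))
  if (!length(common)) stopf("no probes fitted in every cohort")
  est <- sapply(usable, function(t) t$estimate[match(common, t$probe_id)])
  se <- sapply(usable, function(t) t$se[match(common, t$probe_id)])
  est <- matrix(est, nrow = length(common))
  se <- matrix(se, nrow = length(common))
  w <- 1 / se^2
  sw <- rowSums(w)
  cest <- rowSums(w * est) / sw
  cse <- 1 / sqrt(sw)
  z <- cest / cse
  n_tot <- rowSums(sapply(usable, function(t) t$n[match(common, t$probe_id)]))
  data.frame(probe_id = common, estimate = cest, se = cse, stat = z,
             p = pmax(2 * pnorm(-abs(z)), .Machine$double.xmin),
             n = n_tot, df = NA_real_, status = "ok",
             stringsAsFactors = FALSE)
}

#' Cross-region mixed model for one probe
#'
#' Linear mixed model over the long table of all samples (cerebellum
#' excluded by default upstream): fixed effects for the exposure, sex, age,
#' neuronal proportion and cohort (brain bank); random intercepts for donor
#' and for brain region. Variance components by REML; the exposure is
#' tested with a Wald z. Non-convergence is flagged, not thrown.
#'
#' @param long data.frame with columns `beta`, exposure column (`diagnosis`
#'   or `prs`), `sex`, `age`, `neuronal_prop`, `cohort`, `donor_id`,
#'   `region`.
#' @param exposure "diagnosis" or "prs".
#' @return One-row data.frame(estimate (%), se, stat, p, n, df, status)
#'   plus variance components as attribute `varcomp`.
#' @export
fit_cross_region <- function(long, exposure = c("diagnosis", "prs")) {
  exposure <- match.arg(exposure)
  if (length(unique(long$region)) < 2) stopf("need at least 2 regions")
  long$expo <- if (exposure == "diagnosis") {
    as.numeric(long$diagnosis == "case")
  } else as.numeric(long$prs)
  long$sexm <- as.numeric(long$sex == "M")
  use_np <- "neuronal_prop" %in% names(long) &&
    all(is.finite(long$neuronal_prop))
  use_cohort <- length(unique(long$cohort)) > 1
  fml <- paste("beta ~ expo + sexm + age",
               if (use_np) "+ neuronal_prop" else "",
               if (use_cohort) "+ cohort" else "",
               "+ (1 | donor_id) + (1 | region)")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(stats::as.formula(fml), data = long, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular =
                                               "ignore")))),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(data.frame(estimate = NA_real_, se = NA_real_,
                                stat = NA_real_, p = NA_real_,
                                n = nrow(long), df = NA_real_,
                                status = "non_convergence",
                                stringsAsFactors = FALSE),
                     varcomp = c(donor = NA_real_, region = NA_real_)))
  }
  sm <- summary(fit)$coefficients
  est <- sm["expo", "Estimate"]
  se <- sm["expo", "Std. Error"]
  z <- est / se
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- setNames(vc$vcov[match(c("donor_id", "region"), vc$grp)],
                      c("donor", "region"))
  structure(data.frame(estimate = est * 100, se = se * 100, stat = z,
                       p = pmax(2 * pnorm(-abs(z)), .Machine$double.xmin),
                       n = nrow(long), df = NA_real_, status = "ok",
                       stringsAsFactors = FALSE),
            varcomp = varcomp)
}

#' Cross-region mixed-model EWAS
#'
#' Applies [fit_cross_region()] to every probe of a beta matrix, after
#' excluding the configured regions (cerebellum by default, whose global
#' methylation patterns are distinct from the other regions).
#'
#' @param bm a [beta_matrix()].
#' @param sheet a [sample_sheet()] with `neuronal_prop` (and `prs` when
#'   that is the exposure) populated.
#' @param exposure "diagnosis" or "prs".
#' @param exclude_regions regions dropped from the long table.
#' @return Association table with one row per probe.
#' @export
run_cross_region <- function(bm, sheet, exposure = "diagnosis",
                             exclude_regions = "CER") {
  values <- if (inherits(bm, "beta_matrix")) bm$values else bm
  sheet <- sheet[!(sheet$region %in% exclude_regions), , drop = FALSE]
  rows <- lapply(rownames(values), function(pid) {
    long <- data.frame(beta = values[pid, sheet$sample_id],
                       sheet, stringsAsFactors = FALSE)
    cbind(probe_id = pid, fit_cross_region(long, exposure))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
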