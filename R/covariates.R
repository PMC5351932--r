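#' Read cell-type reference profiles
#'
#' TSV with columns `probe_id`, `neuron`, `glia` — the mean reference beta
#' per probe for the two cell classes.
#'
#' @param path TSV file.
#' @return data.frame of reference profiles.
#' @export
read_reference_profiles <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  req <- c("probe_id", "neuron", "glia")
  if (!all(req %in% names(df)))
    stopf("reference profiles need columns: %s", paste(req, collapse = ", "))
  assert_prob(df$neuron, "neuron reference")
  assert_prob(df$glia, "glia reference")
  df
}

#' Estimate the neuronal proportion of bulk brain samples
#'
#' Closed-form two-class constrained projection: the least-squares mixing
#' weight of each sample's reference-probe betas onto the line between the
#' glial and neuronal mean profiles,
#' `p = <x - mu_g, mu_n - mu_g> / ||mu_n - mu_g||^2`, clamped to `[0,1]`.
#'
#' @param betas numeric matrix (reference probes x samples) or a
#'   [beta_matrix()]; rows are matched to `refs$probe_id`.
#' @param refs reference profiles (columns `probe_id`, `neuron`, `glia`).
#' @return Named numeric vector of per-sample proportions in `[0,1]`.
#' @export
estimate_neuronal_proportion <- function(betas, refs) {
  if (inherits(betas, "beta_matrix")) betas <- betas$values
  if (is.null(dim(betas))) betas <- matrix(betas, ncol = 1)
  common <- intersect(refs$probe_id, rownames(betas) %||% refs$probe_id)
  if (is.null(rownames(betas))) {
    if (nrow(betas) != nrow(refs))
      stopf("unnamed beta rows must match the reference probe count")
    x <- betas
    mu_n <- refs$neuron
    mu_g <- refs$glia
  } else {
    if (length(common) < 2)
      stopf("need at least 2 reference probes present in the data")
    x <- betas[common, , drop = FALSE]
    i <- match(common, refs$probe_id)
    mu_n <- refs$neuron[i]
    mu_g <- refs$glia[i]
  }
  d <- mu_n - mu_g
  denom <- sum(d^2)
  if (denom <= 0)
    stopf("neuron and glia reference profiles are identical (unidentifiable)")
  p <- colSums((x - mu_g) * d) / denom
  clamp(p, 0, 1)
}

#' Epigenetic-clock model
#'
#' Container for a published DNA-methylation-age predictor: an intercept,
#' per-probe coefficients and the adult-age anchor of the age transform.
#' Coefficients are always supplied by the user (e.g. via
#' [read_clock_model()]), never bundled.
#'
#' @param intercept numeric.
#' @param coef named numeric vector of per-probe coefficients.
#' @param adult_age anchor of the age transform in years (default 20).
#' @param impute_means optional named per-probe training means used for
#'   missing clock probes.
#' @return A `clock_model` list.
#' @export
clock_model <- function(intercept, coef, adult_age = 20,
                        impute_means = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coef), !is.null(names(coef)))
  structure(list(intercept = intercept, coef = coef, adult_age = adult_age,
                 impute_means = impute_means), class = "clock_model")
}

#' @rdname clock_model
#' @param path TSV of (probe_id, value) rows; the intercept and adult age
#'   come from an adjacent JSON header file `<path>.json` with fields
#'   `intercept` and `adult_age`.
#' @export
read_clock_model <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  clock_model(hdr$intercept, setNames(df[[2]], df[[1]]),
              adult_age = hdr$adult_age %||% 20)
}

# Forward age transform of the clock: maps years to the linear-predictor
# scale (log-linear below the adult anchor, linear above).
clock_transform_age <- function(age, adult_age = 20) {
  ifelse(age <= adult_age,
         log(age + 1) - log(adult_age + 1),
         (age - adult_age) / (adult_age + 1))
}

#' DNA methylation age
#'
#' Evaluates the clock's linear predictor `L = intercept + sum(coef * beta)`
#' and inverts its age transform: `(1 + A) * exp(L) - 1` for `L <= 0`, else
#' `(1 + A) * L + A`, with `A` the adult-age anchor.
#'
#' @param betas numeric matrix (probes x samples), a [beta_matrix()], or a
#'   named vector for a single sample.
#' @param clock a [clock_model()].
#' @return Named numeric vector of predicted ages in years.
#' @export
dnam_age <- function(betas, clock) {
  if (inherits(betas, "beta_matrix")) betas <- betas$values
  if (is.null(dim(betas))) betas <- matrix(betas, ncol = 1,
                                           dimnames = list(names(betas),
                                                           "sample"))
  need <- names(clock$coef)
  missing_probes <- setdiff(need, rownames(betas))
  if (length(missing_probes)) {
    if (is.null(clock$impute_means) ||
        !all(missing_probes %in% names(clock$impute_means)))
      stopf("clock probes missing without imputation means: %s",
            paste(utils::head(missing_probes, 5L), collapse = ", "))
    fill <- matrix(clock$impute_means[missing_probes],
                   length(missing_probes), ncol(betas),
                   dimnames = list(missing_probes, colnames(betas)))
    betas <- rbind(betas, fill)
  }
  L <- clock$intercept + colSums(betas[need, , drop = FALSE] * clock$coef)
  A <- clock$adult_age
  ifelse(L <= 0, (1 + A) * exp(L) - 1, (1 + A) * L + A)
}

#' Epigenetic age acceleration test
#'
#' Reports the Spearman correlation of methylation-predicted age with
#' chronological age, per-sample acceleration, and a two-sided two-sample
#' t-test of acceleration between cases and controls. Acceleration is the
#' residual of predicted age regressed on chronological age by default
#' (`method = "residual"`); `method = "difference"` uses the raw
#' predicted-minus-chronological difference.
#'
#' @param dnam numeric predicted ages.
#' @param chron numeric chronological ages.
#' @param diagnosis character "case"/"control" per sample.
#' @param method "residual" (default) or "difference".
#' @return list(rho, rho_p, acceleration, group_diff, p, degenerate).
#' @export
age_acceleration_test <- function(dnam, chron, diagnosis,
                                  method = c("residual", "difference")) {
  method <- match.arg(method)
  stopifnot(length(dnam) == length(chron),
            length(dnam) == length(diagnosis))
  if (min(table(factor(diagnosis, c("case", "control")))) < 3)
    stopf("need at least 3 samples per diagnosis group")
  degenerate <- sd(chron) == 0 || sd(dnam) == 0
  if (degenerate) {
    rho <- NA_real_; rho_p <- NA_real_
    warnf("constant ages; Spearman correlation undefined")
  } else {
    ct <- suppressWarnings(cor.test(dnam, chron, method = "spearman"))
    rho <- unname(ct$estimate); rho_p <- ct$p.value
  }
  acc <- if (method == "residual" && !degenerate) {
    unname(residuals(lm(dnam ~ chron)))
  } else dnam - chron
  a_case <- acc[diagnosis == "case"]
  a_ctrl <- acc[diagnosis == "control"]
  tol <- 1e-8 * (1 + sd(chron))
  if (sd(a_case) < tol && sd(a_ctrl) < tol &&
      abs(mean(a_case) - mean(a_ctrl)) < tol) {
    return(list(rho = rho, rho_p = rho_p, acceleration = acc,
                group_diff = 0, p = 1, degenerate = degenerate))
  }
  if (sd(a_case) == 0 && sd(a_ctrl) == 0) {
    p <- if (isTRUE(all.equal(mean(a_case), mean(a_ctrl)))) 1 else 0
  } else {
    p <- t.test(a_case, a_ctrl)$p.value
  }
  list(rho = rho, rho_p = rho_p, acceleration = acc,
       group_diff = mean(a_case) - mean(a_ctrl), p = p,
       degenerate = degenerate)
}

#' Principal-component scores of the methylation matrix
#'
#' Scores of the top-`k` components of the sample-by-probe matrix, centered
#' per probe, with a deterministic sign convention (the largest-magnitude
#' probe loading of each component is positive).
#'
#' @param bm a [beta_matrix()] or numeric probes-x-samples matrix.
#' @param k number of components, `0 < k < min(probes, samples)`.
#' @return list(scores = samples x k matrix, var_explained = length-k
#'   fractions of total variance).
#' @export
compute_pcs <- function(bm, k) {
  values <- if (inherits(bm, "beta_matrix")) bm$values else bm
  if (!is_count(k) || k <= 0) stopf("k must be a positive integer")
  if (k >= min(dim(values))) stopf("k must be < min(probes, samples)")
  x <- t(values)                      # samples x probes
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  rownames(scores) <- colnames(values)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       var_explained = (sv$d[seq_len(k)]^2) / sum(sv$d^2))
}
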