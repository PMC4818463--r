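#' Prepare the covariate table for model fitting
#'
#' Takes the per-polygon covariate records, log-transforms the response
#' (already present as `log_mfpt`), removes response outliers (|z| of the
#' log response above `outlier_z`), and z-scores every numeric predictor
#' over the retained records so coefficient magnitudes are comparable.
#' `site` stays categorical with a configurable reference level.
#'
#' @param table covariate table from [build_covariate_table()].
#' @param outlier_z response outlier threshold in SD units (default 3).
#' @param ref_site reference site level (default: alphabetical first).
#' @return data frame ready for [fit_candidates()]; attributes `removed`
#'   (dropped row count) and `scaling` (per-predictor centre/scale).
#' @export
prepare_inputs <- function(table, outlier_z = 3, ref_site = NULL) {
  stopifnot(nrow(table) >= 1)
  if (!is.null(table$mfpt_rmax_h)) table$log_mfpt <- log(table$mfpt_rmax_h)
  y <- table$log_mfpt
  z <- (y - mean(y)) / sd(y)
  keep <- abs(z) <= outlier_z
  if (any(!keep))
    message(sprintf("removed %d response outlier(s) with |z| > %g",
                    sum(!keep), outlier_z))
  dat <- table[keep, , drop = FALSE]
  num <- setdiff(predictor_names(), "site")
  scaling <- list()
  for (v in num) {
    s <- sd(dat[[v]])
    if (!is.finite(s) || s == 0)
      stop("predictor has zero variance: ", v)
    m <- mean(dat[[v]])
    scaling[[v]] <- c(center = m, scale = s)
    dat[[v]] <- (dat[[v]] - m) / s
  }
  lv <- sort(unique(dat$site))
  if (is.null(ref_site)) ref_site <- lv[1]
  dat$site <- factor(dat$site, levels = c(ref_site, setdiff(lv, ref_site)))
  dat$bird_id <- factor(dat$bird_id)
  rownames(dat) <- NULL
  attr(dat, "removed") <- sum(!keep)
  attr(dat, "scaling") <- scaling
  dat
}

#' The 36-model candidate set
#'
#' Enumerates the standard candidate set: eleven single/paired models
#' (current-condition terms, site, temperature + elevation), four
#' reactive-movement (RM) combinations of current conditions with and
#' without site + temperature + elevation, four prescient-movement (PM)
#' combinations for each lag (16 and 32 days) with and without site, and
#' the null model.  Every model carries a random intercept per bird.
#'
#' @return list of `model_spec`s: `model_id`, `terms` (fixed-effect
#'   predictor names), `tag` in \{single, RM, PM16, PM32, null\}.
#' @export
candidate_set <- function() {
  rm_combos <- list(c("ndvi_t", "mndwi_t", "precip_t"),
                    c("ndvi_t", "mndwi_t"),
                    c("ndvi_t", "precip_t"),
                    c("mndwi_t", "precip_t"))
  pm16 <- list(c("d_ndvi_16", "d_mndwi_16", "d_precip_16"),
               c("d_ndvi_16", "d_mndwi_16"),
               c("d_ndvi_16", "d_precip_16"),
               c("d_mndwi_16", "d_precip_16"))
  pm32 <- lapply(pm16, function(x) sub("_16$", "_32", x))
  specs <- c(
    lapply(c("ndvi_t", "d_ndvi_16", "d_ndvi_32", "mndwi_t", "d_mndwi_16",
             "d_mndwi_32", "precip_t", "d_precip_16", "d_precip_32"),
           function(v) list(terms = v, tag = "single")),          # 1-9
    list(list(terms = "site", tag = "single"),                    # 10
         list(terms = c("temp", "elev"), tag = "single")),        # 11
    lapply(rm_combos, function(v) list(terms = v, tag = "RM")),   # 12-15
    lapply(rm_combos, function(v)
      list(terms = c(v, "site", "temp", "elev"), tag = "RM")),    # 16-19
    lapply(pm16, function(v) list(terms = v, tag = "PM16")),      # 20-23
    lapply(pm16, function(v)
      list(terms = c(v, "site"), tag = "PM16")),                  # 24-27
    lapply(pm32, function(v) list(terms = v, tag = "PM32")),      # 28-31
    lapply(pm32, function(v)
      list(terms = c(v, "site"), tag = "PM32")),                  # 32-35
    list(list(terms = character(), tag = "null")))                # 36
  for (i in seq_along(specs)) {
    specs[[i]]$model_id <- i
    class(specs[[i]]) <- "model_spec"
  }
  specs
}

#' @export
print.model_spec <- function(x, ...) {
  rhs <- if (length(x$terms)) paste(x$terms, collapse = " + ") else "1"
  cat(sprintf("model %d [%s]: log_mfpt ~ %s + (1|bird_id)\n",
              x$model_id, x$tag, rhs))
  invisible(x)
}

#' Fit one candidate linear mixed model
#'
#' Gaussian linear mixed model with a random intercept per bird, fitted by
#' maximum likelihood (not REML) so AICc comparisons across fixed-effect
#' structures are valid.  A singular fit (bird variance estimated at zero)
#' is returned with `boundary = TRUE`, not an error.
#'
#' @param spec a `model_spec`.
#' @param data prepared table from [prepare_inputs()].
#' @return an `fpt_fit`: list with the lme4 fit, coefficient table (estimate,
#'   SE, Wald 95% CI), variance components, ML log-likelihood, `k` (fixed
#'   effects incl. intercept + 2 variance components), `aicc`, and R2.
#' @export
fit_mixed_model <- function(spec, data) {
  rhs <- if (length(spec$terms)) paste(spec$terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste("log_mfpt ~", rhs, "+ (1 | bird_id)"))
  fit <- lme4::lmer(form, data = data, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- lme4::VarCorr(fit)
  sigma2_id <- as.numeric(vc$bird_id[1])
  sigma2_e <- stats::sigma(fit)^2
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  ci <- cbind(beta - qnorm(0.975) * se, beta + qnorm(0.975) * se)
  ll <- as.numeric(stats::logLik(fit))
  n <- stats::nobs(fit)
  k <- length(beta) + 2L
  r2 <- r2_glmm(fit)
  structure(list(model_id = spec$model_id, terms = spec$terms,
                 tag = spec$tag, fit = fit,
                 coef = data.frame(term = names(beta), beta = unname(beta),
                                   se = unname(se), lower = ci[, 1],
                                   upper = ci[, 2], row.names = NULL),
                 sigma2_id = sigma2_id, sigma2_e = sigma2_e,
                 loglik = ll, n = n, k = k,
                 aicc = aicc(ll, k, n),
                 r2_marginal = unname(r2[1]), r2_conditional = unname(r2[2]),
                 boundary = lme4::isSingular(fit)),
            class = "fpt_fit")
}

#' @export
print.fpt_fit <- function(x, ...) {
  cat(sprintf("<fpt_fit model %d [%s]: n = %d, k = %d, AICc = %.2f, R2m = %.3f, R2c = %.3f%s>\n",
              x$model_id, x$tag, x$n, x$k, x$aicc, x$r2_marginal,
              x$r2_conditional, if (x$boundary) ", singular" else ""))
  print(x$coef, digits = 3)
  invisible(x)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n - k - 1)`; `k` counts fixed effects
#' (including the intercept) plus both variance components.
#'
#' @param loglik ML log-likelihood.
#' @param k parameter count.
#' @param n number of observations; must exceed `k + 1`.
#' @return scalar AICc.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the full candidate set
#'
#' @param data prepared table from [prepare_inputs()].
#' @param specs candidate list (default [candidate_set()]).
#' @return named list of `fpt_fit` objects.
#' @export
fit_candidates <- function(data, specs = candidate_set()) {
  fits <- lapply(specs, fit_mixed_model, data = data)
  names(fits) <- vapply(specs, function(s) as.character(s$model_id),
                        character(1))
  fits
}

#' Rank fitted candidates by AICc
#'
#' Sorts ascending by AICc (ties broken by smaller `k`, then model id),
#' computes Delta AICc against the best model, Akaike weights over the whole
#' candidate set, and cumulative weights in rank order.
#'
#' @param fits list of `fpt_fit` objects fitted to identical data rows.
#' @return a `selection_table` data frame.
#' @export
rank_models <- function(fits) {
  n_obs <- vapply(fits, `[[`, numeric(1), "n")
  if (length(unique(n_obs)) != 1)
    stop("fits were made on differing numbers of observations")
  tab <- data.frame(
    model_id = vapply(fits, `[[`, numeric(1), "model_id"),
    tag = vapply(fits, `[[`, character(1), "tag"),
    formula = vapply(fits, function(f)
      if (length(f$terms)) paste(f$terms, collapse = " + ") else "1",
      character(1)),
    k = vapply(fits, `[[`, numeric(1), "k"),
    aicc = vapply(fits, `[[`, numeric(1), "aicc"),
    r2_marginal = vapply(fits, `[[`, numeric(1), "r2_marginal"),
    r2_conditional = vapply(fits, `[[`, numeric(1), "r2_conditional"))
  ord <- order(tab$aicc, tab$k, tab$model_id)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  w <- exp(-tab$delta_aicc / 2)
  tab$weight <- w / sum(w)
  tab$cum_weight <- cumsum(tab$weight)
  rownames(tab) <- NULL
  class(tab) <- c("selection_table", "data.frame")
  tab
}

#' @export
print.selection_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$aicc <- round(df$aicc, 2)
  df$delta_aicc <- round(df$delta_aicc, 2)
  df$weight <- round(df$weight, 3)
  df$cum_weight <- round(df$cum_weight, 3)
  print(head(df, 10), row.names = FALSE)
  if (nrow(df) > 10) cat(sprintf("... and %d more models\n", nrow(df) - 10))
  invisible(x)
}

#' Marginal and conditional R-squared for a mixed model
#'
#' Variance-partition R2 for a Gaussian random-intercept model: with
#' `sf2` the variance of the fixed-effect linear predictor, marginal
#' R2 = sf2 / (sf2 + sigma2_id + sigma2_e) and conditional
#' R2 = (sf2 + sigma2_id) / (sf2 + sigma2_id + sigma2_e).
#'
#' @param fit an `lmerMod` (or an `fpt_fit`, whose lme4 fit is used).
#' @return numeric `c(marginal, conditional)`.
#' @export
r2_glmm <- function(fit) {
  if (inherits(fit, "fpt_fit")) fit <- fit$fit
  eta <- as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit))
  sf2 <- if (length(eta) > 1) var(eta) else 0
  vc <- lme4::VarCorr(fit)
  s_id <- as.numeric(vc$bird_id[1])
  s_e <- stats::sigma(fit)^2
  tot <- sf2 + s_id + s_e
  if (tot <= 0) stop("all variance components are zero")
  c(marginal = sf2 / tot, conditional = (sf2 + s_id) / tot)
}

#' Collinearity diagnostics for a fixed-effect design
#'
#' Condition number (kappa) of the standardized design (ratio of extreme
#' singular values of the centred, unit-variance predictor columns) and
#' variance inflation factors: `VIF_j = 1 / (1 - R2_j)` from regressing
#' column j on the remaining columns; multi-column (factor) terms get the
#' generalized VIF with `GVIF^(1/(2 df))` also reported.
#'
#' @param data prepared data.
#' @param terms predictor names (e.g. a `model_spec$terms`).
#' @return list with `kappa`, `vif` (per term), and `collinear` flag.
#' @export
collinearity_diagnostics <- function(data, terms) {
  stopifnot(length(terms) >= 1)
  X <- stats::model.matrix(stats::as.formula(paste("~", paste(terms, collapse = "+"))),
                           data = data)[, -1, drop = FALSE]
  if (ncol(X) < 2) {
    return(list(kappa = 1, vif = setNames(1, terms), collinear = FALSE))
  }
  Xs <- scale(X)
  sv <- svd(Xs, nu = 0, nv = 0)$d
  collinear <- min(sv) < max(sv) * 1e-10
  kappa <- if (collinear) Inf else max(sv) / min(sv)
  # term assignment: columns of X per predictor term
  assign <- attr(stats::model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = "+"))),
    data = data), "assign")[-1]
  R <- stats::cor(X)
  vif <- numeric(length(terms))
  names(vif) <- terms
  if (collinear) {
    vif[] <- Inf
  } else {
    detR <- det(R)
    for (j in seq_along(terms)) {
      cols <- which(assign == j)
      oth <- setdiff(seq_len(ncol(X)), cols)
      if (!length(oth)) { vif[j] <- 1; next }
      # generalized VIF (reduces to 1/(1-R2) for single columns)
      vif[j] <- det(R[cols, cols, drop = FALSE]) *
        det(R[oth, oth, drop = FALSE]) / detR
    }
  }
  list(kappa = kappa, vif = vif, collinear = collinear)
}

#' Empirical semivariogram of model residuals
#'
#' Distance-binned semivariance `gamma(h) = sum (r_i - r_j)^2 / (2 N(h))`
#' over all point pairs, with equal-width bins up to the maximum pairwise
#' distance; used to check residual spatial autocorrelation.
#'
#' @param residuals numeric residuals.
#' @param x,y planar coordinates of the sampling units (e.g. polygon
#'   centroids).
#' @param n_bins number of distance bins (default 12).
#' @return a `semivariogram` data frame with `dist` (bin midpoint),
#'   `gamma`, and `n_pairs`.
#' @export
residual_semivariogram <- function(residuals, x, y, n_bins = 12) {
  n <- length(residuals)
  if (n < 2) stop("need at least 2 points")
  d <- as.vector(stats::dist(cbind(x, y)))
  g <- as.vector(stats::dist(residuals))^2 / 2
  breaks <- seq(0, max(d) * (1 + 1e-9), length.out = n_bins + 1)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    dist = (breaks[-1] + breaks[-length(breaks)]) / 2,
    gamma = vapply(seq_len(n_bins),
                   function(b) if (any(bin == b)) mean(g[bin == b]) else NA_real_,
                   numeric(1)),
    n_pairs = vapply(seq_len(n_bins), function(b) sum(bin == b), numeric(1)))
  class(out) <- c("semivariogram", "data.frame")
  out
}
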