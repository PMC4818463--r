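test_that("prepare_inputs log-transforms, screens outliers, and z-scores", {
  # controlled table: response spread is known, so z-scores are exact
  n <- 40
  set.seed(3)
  tab <- data.frame(polygon_id = 1:n,
                    bird_id = rep(c("BAR01", "STR01", "MAN01"),
                                  length.out = n))
  tab$track_label <- tab$bird_id
  tab$site <- substr(tab$bird_id, 1, 3)
  for (v in setdiff(predictor_names(), "site")) tab[[v]] <- rnorm(n)
  base <- rep(c(4.8, 5.2), length.out = n)        # sd-controlled response
  tab$mfpt_rmax_h <- exp(base)
  dat <- prepare_inputs(tab)
  expect_equal(dat$log_mfpt, base)                # natural-log contract
  for (v in setdiff(predictor_names(), "site")) {
    expect_lt(abs(mean(dat[[v]])), 1e-12)
    expect_equal(sd(dat[[v]]), 1, tolerance = 1e-12)
  }
  expect_s3_class(dat$site, "factor")
  expect_equal(levels(dat$site)[1], "BAR")
  expect_equal(levels(prepare_inputs(tab, ref_site = "STR")$site)[1], "STR")

  # a planted outlier above |z| = 3 is removed; at |z| = 2.9 it is kept
  plant <- function(z) {
    t2 <- tab
    # choose y so that its z-score in the modified sample is exactly z
    f <- function(y) {
      yy <- c(base[-n], y)
      (y - mean(yy)) / sd(yy) - z
    }
    y_star <- uniroot(f, c(5, 100))$root
    t2$mfpt_rmax_h[n] <- exp(y_star)
    t2
  }
  expect_message(d2 <- prepare_inputs(plant(5)), "1 response outlier")
  expect_equal(nrow(d2), n - 1)
  expect_equal(nrow(suppressMessages(prepare_inputs(plant(2.9)))), n)

  # zero-variance predictor is a named error
  tab_flat <- tab
  tab_flat$elev <- 100
  expect_error(prepare_inputs(tab_flat), "elev")
})

test_that("candidate set enumerates the full 36-model design", {
  cs <- candidate_set()
  expect_length(cs, 36)
  expect_equal(vapply(cs, `[[`, numeric(1), "model_id"), 1:36)
  # anchors of the enumeration
  expect_equal(cs[[34]]$terms, c("d_ndvi_32", "d_precip_32", "site"))
  expect_equal(cs[[32]]$terms, c("d_ndvi_32", "d_mndwi_32", "d_precip_32",
                                 "site"))
  expect_equal(cs[[36]]$terms, character())
  expect_equal(cs[[10]]$terms, "site")
  expect_equal(cs[[11]]$terms, c("temp", "elev"))
  expect_equal(cs[[19]]$terms, c("mndwi_t", "precip_t", "site", "temp",
                                 "elev"))
  expect_equal(cs[[20]]$terms, c("d_ndvi_16", "d_mndwi_16", "d_precip_16"))
  # tag structure: 11 singles, 8 RM, 8 PM16, 8 PM32, 1 null
  tags <- vapply(cs, `[[`, character(1), "tag")
  expect_equal(unname(table(tags)[c("single", "RM", "PM16", "PM32", "null")]),
               c(11L, 8L, 8L, 8L, 1L), ignore_attr = TRUE)
  # every 16-day spec has a 32-day twin four ids later
  for (i in 20:27)
    expect_equal(gsub("_16", "_32", paste(cs[[i]]$terms, collapse = "+")),
                 paste(cs[[i + 8]]$terms, collapse = "+"))
})

test_that("AICc matches its closed form and limits", {
  expect_equal(aicc(-100, 5, 50), 211.364, tolerance = 5e-4)
  expect_equal(aicc(-100, 5, 1e9), -2 * -100 + 10, tolerance = 1e-6)
  expect_error(aicc(-100, 5, 6), "n must exceed")
  expect_true(is.finite(aicc(-10, 3, 5)))
})

test_that("mixed model reduces to OLS without between-bird variability", {
  # construct data with exactly zero bird-level variation: residuals are
  # centred within birds after projecting out the fixed effects
  sim <- simulate_covariate_data(n_polygons = 200, sigma_id = 0, seed = 11)
  dat <- prepare_inputs(sim$table)
  ols0 <- lm(log_mfpt ~ d_ndvi_32 + d_precip_32, dat)
  e <- resid(ols0)
  dat$log_mfpt <- fitted(ols0) + e - ave(e, dat$bird_id)
  spec <- candidate_set()[[30]]  # d_ndvi_32 + d_precip_32
  fit <- fit_mixed_model(spec, dat)
  ols <- lm(log_mfpt ~ d_ndvi_32 + d_precip_32, dat)
  expect_true(fit$boundary)  # sigma_id estimated at the boundary
  expect_equal(fit$coef$beta, unname(coef(ols)), tolerance = 1e-6)
})

test_that("variance components match closed-form ANOVA on balanced data", {
  # balanced one-way layout: m birds, r records each, no covariates
  set.seed(12)
  m <- 10; r <- 8
  sig_id <- 0.5; sig_e <- 0.7
  b <- rnorm(m, 0, sig_id)
  tab <- data.frame(bird_id = factor(rep(seq_len(m), each = r)))
  tab$log_mfpt <- 3 + b[as.integer(tab$bird_id)] + rnorm(m * r, 0, sig_e)
  fit <- lme4::lmer(log_mfpt ~ 1 + (1 | bird_id), data = tab, REML = FALSE)
  s2_id <- as.numeric(lme4::VarCorr(fit)$bird_id[1])
  s2_e <- sigma(fit)^2
  # ML closed forms for the balanced one-way random-effects model
  ybar_i <- tapply(tab$log_mfpt, tab$bird_id, mean)
  ybar <- mean(tab$log_mfpt)
  sse <- sum((tab$log_mfpt - ybar_i[tab$bird_id])^2)
  ssa <- r * sum((ybar_i - ybar)^2)
  s2_e_ref <- sse / (m * (r - 1))
  s2_id_ref <- max((ssa / m - s2_e_ref) / r, 0)
  expect_equal(s2_e, s2_e_ref, tolerance = 1e-4)
  expect_equal(s2_id, s2_id_ref, tolerance = 1e-4)
})

test_that("coefficients and intervals recover simulated truth", {
  hits <- 0; est <- NULL
  spec <- candidate_set()[[34]]
  for (seed in 1:50) {
    sim <- simulate_covariate_data(n_polygons = 300, n_birds = 15,
                                   seed = seed)
    dat <- suppressMessages(prepare_inputs(sim$table))
    fit <- fit_mixed_model(spec, dat)
    co <- fit$coef
    i <- co$term == "d_precip_32"
    truth <- sim$truth$beta[["d_precip_32"]] *
      attr(dat, "scaling")$d_precip_32[["scale"]]
    if (co$lower[i] <= truth && truth <= co$upper[i]) hits <- hits + 1
    est <- c(est, co$beta[i] - truth)
  }
  expect_lt(abs(mean(est)), 0.02)
  expect_gte(hits / 50, 0.90)
  expect_lte(hits / 50, 0.99)
})

test_that("model ranking orders by AICc with normalized weights", {
  sim <- simulate_covariate_data(n_polygons = 150, seed = 2)
  dat <- prepare_inputs(sim$table)
  fits <- fit_candidates(dat)
  sel <- rank_models(fits)
  expect_equal(nrow(sel), 36)
  expect_equal(sel$delta_aicc[1], 0)
  expect_false(is.unsorted(sel$aicc))
  expect_equal(sum(sel$weight), 1, tolerance = 1e-12)
  expect_false(is.unsorted(sel$cum_weight))
  expect_equal(sel$weight[1], max(sel$weight))
  # mismatched data rows are rejected
  f2 <- fits
  f2[["1"]] <- fit_mixed_model(candidate_set()[[1]], dat[-1, ])
  expect_error(rank_models(f2), "differing")
  # identical-AICc ties break towards smaller k
  fa <- fits[["36"]]; fb <- fits[["36"]]
  fa$aicc <- fb$aicc <- 100
  fa$k <- 3; fb$k <- 5; fb$model_id <- 99
  expect_equal(rank_models(list(fa, fb))$k, c(3, 5))
})

test_that("R2 decomposition follows the variance-partition formulas", {
  # closed-form check through a constructed fit: sf2 = 1, id = 1, e = 2
  sim <- simulate_covariate_data(n_polygons = 400, seed = 9)
  dat <- prepare_inputs(sim$table)
  fit <- fit_mixed_model(candidate_set()[[30]], dat)
  eta <- as.vector(model.matrix(fit$fit) %*% lme4::fixef(fit$fit))
  sf2 <- var(eta)
  r2 <- r2_glmm(fit)
  expect_equal(unname(r2[1]), sf2 / (sf2 + fit$sigma2_id + fit$sigma2_e),
               tolerance = 1e-10)
  expect_equal(unname(r2[2]),
               (sf2 + fit$sigma2_id) / (sf2 + fit$sigma2_id + fit$sigma2_e),
               tolerance = 1e-10)
  expect_lte(r2[1], r2[2])
  expect_lte(r2[2], 1)
  # null model: marginal R2 is zero
  null_fit <- fit_mixed_model(candidate_set()[[36]], dat)
  expect_equal(unname(null_fit$r2_marginal), 0, tolerance = 1e-10)
  # without bird variance, marginal equals conditional
  sim0 <- simulate_covariate_data(n_polygons = 200, sigma_id = 0, seed = 13)
  d0 <- prepare_inputs(sim0$table)
  ols0 <- lm(log_mfpt ~ d_ndvi_32 + d_precip_32, d0)
  e0 <- resid(ols0)
  d0$log_mfpt <- fitted(ols0) + e0 - ave(e0, d0$bird_id)
  f0 <- fit_mixed_model(candidate_set()[[30]], d0)
  expect_equal(f0$r2_marginal, f0$r2_conditional, tolerance = 1e-6)
})

test_that("collinearity diagnostics give exact values on constructed designs", {
  # columns orthonormal after centring: kappa = 1, VIF = 1
  set.seed(14)
  n <- 64
  X <- qr.Q(qr(scale(matrix(rnorm(n * 3), n, 3), scale = FALSE)))
  dat <- data.frame(a = X[, 1], b = X[, 2], c = X[, 3])
  d <- collinearity_diagnostics(dat, c("a", "b", "c"))
  expect_equal(d$kappa, 1, tolerance = 1e-8)
  expect_equal(unname(d$vif), rep(1, 3), tolerance = 1e-8)
  # two predictors with correlation 0.9: VIF = 1 / (1 - 0.81) = 5.263
  set.seed(15)
  a <- rnorm(5000)
  b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(5000)
  r <- cor(a, b)
  dat2 <- data.frame(a = a, b = b)
  d2 <- collinearity_diagnostics(dat2, c("a", "b"))
  expect_equal(unname(d2$vif["a"]), 1 / (1 - r^2), tolerance = 1e-6)
  expect_lt(abs(d2$vif[["a"]] - 5.263), 0.3)
  # duplicated column flags exact collinearity
  dat3 <- data.frame(a = a, b = a)
  d3 <- collinearity_diagnostics(dat3, c("a", "b"))
  expect_true(d3$collinear)
  expect_equal(d3$kappa, Inf)
})

test_that("generalized VIF agrees with the car package", {
  skip_if_not_installed("car")
  sim <- simulate_covariate_data(n_polygons = 200, seed = 21)
  dat <- prepare_inputs(sim$table)
  terms <- c("d_ndvi_32", "d_precip_32", "site")
  ours <- collinearity_diagnostics(dat, terms)
  ref <- car::vif(lm(log_mfpt ~ d_ndvi_32 + d_precip_32 + site, dat))
  expect_equal(unname(ours$vif), unname(ref[, "GVIF"]), tolerance = 1e-6)
})

test_that("semivariogram is flat for iid residuals and zero for constants", {
  set.seed(20)
  n <- 500
  x <- runif(n, 0, 1e4); y <- runif(n, 0, 1e4)
  r <- rnorm(n, 0, 2)
  sv <- residual_semivariogram(r, x, y, n_bins = 8)
  expect_equal(sum(sv$n_pairs), n * (n - 1) / 2)
  busy <- sv$n_pairs > 200
  expect_true(all(abs(sv$gamma[busy] - 4) / 4 < 0.2))
  sv0 <- residual_semivariogram(rep(1, 30), runif(30), runif(30))
  expect_true(all(sv0$gamma[sv0$n_pairs > 0] == 0))
  expect_error(residual_semivariogram(1, 1, 1), "at least 2")
})

test_that("likelihood never decreases when a predictor is added", {
  for (seed in 1:5) {
    sim <- simulate_covariate_data(n_polygons = 120, seed = seed)
    dat <- suppressMessages(prepare_inputs(sim$table))
    f_small <- fit_mixed_model(candidate_set()[[30]], dat)
    f_big <- fit_mixed_model(candidate_set()[[28]], dat)  # + d_mndwi_32
    expect_gte(f_big$loglik, f_small$loglik - 1e-6)
  }
})

test_that("selection is invariant to affine predictor rescaling", {
  sim <- simulate_covariate_data(n_polygons = 150, seed = 30)
  tab2 <- sim$table
  tab2$d_ndvi_32 <- 100 * tab2$d_ndvi_32 - 7
  f1 <- fit_candidates(prepare_inputs(sim$table))
  f2 <- fit_candidates(prepare_inputs(tab2))
  w1 <- rank_models(f1)$weight
  w2 <- rank_models(f2)$weight
  expect_equal(w1, w2, tolerance = 1e-9)
})
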