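test_that("implausible measurement values are removed value-wise", {
  meas <- data.frame(id = c(1, 1, 2, 2, 3, 3),
                     factor = c("sbp", "sbp", "hdl", "hdl", "tc", "smoking"),
                     age = 50,
                     value = c(251, 250, 0.25, 0.3, 1.75, 1))
  out <- clean_measurements(meas)
  expect_equal(attr(out, "n_removed"), 2L)
  ## boundary values are retained, strict exceedances removed
  expect_true(250 %in% out$value[out$factor == "sbp"])
  expect_false(251 %in% out$value[out$factor == "sbp"])
  expect_false(0.25 %in% out$value[out$factor == "hdl"])
  expect_true(1.75 %in% out$value[out$factor == "tc"])
  ## other measurements of the same person survive
  expect_true(all(c(1, 2, 3) %in% out$id))

  empty <- clean_measurements(meas[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "n_removed"), 0L)

  bad <- data.frame(id = 1, factor = "ldl", age = 50, value = 3)
  expect_error(clean_measurements(bad), "unknown risk factor")
  expect_error(cleaning_rules(sbp = c(250, 60)), "lower bound")
})

test_that("the multivariate mixed fit recovers the generator's trajectory
           parameters", {
  co <- stage1_cohort()
  cfg <- co$config
  rs <- build_risk_set(co, 50, "male")
  std <- standardization_constants(co)
  fit <- fit_multivariate_mixed(rs, standardization = std)
  expect_true(fit$converged)

  ## translate fitted (standardized-scale) variances back to natural units
  sds <- c(std$male$sd, smoking = 1)
  Sig_nat <- fit$Sigma_u * outer(sds, sds)
  resid_nat <- fit$resid_var * sds^2

  ## continuous factors: compare against the configured truth
  for (f in c("sbp", "tc", "hdl")) {
    expect_lt(abs(Sig_nat[f, f] / cfg$Sigma_u[f, f] - 1), 0.15)
    expect_lt(abs(resid_nat[[f]] / cfg$resid_sd[[f]]^2 - 1), 0.15)
  }
  ## smoking: the latent probability is clipped to [0,1] before the
  ## Bernoulli draw, so the oracle variance components come from the
  ## stored person effects
  tr <- co$truth[match(rs$data$id, co$truth$id), ]
  p_lat <- pmin(pmax(cfg$factor_means[["smoking"]] +
                       cfg$factor_trends[["smoking"]] * (50 - 60) +
                       tr$u_smoking, 0), 1)
  expect_lt(abs(Sig_nat["smoking", "smoking"] / var(p_lat) - 1), 0.15)
  expect_lt(abs(resid_nat[["smoking"]] / mean(p_lat * (1 - p_lat)) - 1),
            0.15)
  ## cross-factor correlations within 0.15 absolute of the truth
  corr_hat <- cov2cor(fit$Sigma_u)
  corr_true <- cov2cor(cfg$Sigma_u)
  expect_lt(max(abs(corr_hat - corr_true)), 0.15)
})

test_that("a balanced single-factor fit matches the ANOVA decomposition", {
  set.seed(42)
  n <- 60
  u <- rnorm(n, sd = 2)
  ages <- c(49, 50)
  meas <- data.frame(id = rep(1:n, each = 2),
                     factor = "smoking",
                     age = rep(ages, n),
                     value = rep(u, each = 2) + 0.3 * rep(ages - 50, n) +
                       rnorm(2 * n, sd = 1))
  rs <- structure(list(landmark_age = 50, sex = "male", horizon = 10,
                       lookback = 10,
                       data = data.frame(id = 1:n, time = 10, event = 0L,
                                         statin_time = NA_real_,
                                         diabetes = 0L, htn = 0L),
                       measurements = meas),
                  class = "landmark_risk_set")
  fit <- fit_multivariate_mixed(rs)
  ## balanced design with the age effect removed: REML equals the moment
  ## estimators sigma_e^2 = MSW, sigma_u^2 = (MSB - MSW) / m
  av <- summary(stats::aov(value ~ factor(age) + Error(factor(id)),
                           data = meas))
  msb <- av[["Error: factor(id)"]][[1]]["Residuals", "Mean Sq"]
  msw <- av[["Error: Within"]][[1]]["Residuals", "Mean Sq"]
  expect_equal(fit$resid_var[["smoking"]], msw, tolerance = 1e-4)
  expect_equal(fit$Sigma_u["smoking", "smoking"], (msb - msw) / 2,
               tolerance = 1e-4)
})

test_that("BLUPs obey the textbook single-factor shrinkage formula", {
  std <- list(male = list(mean = c(sbp = 0, tc = 0, hdl = 0),
                          sd = c(sbp = 1, tc = 1, hdl = 1)))
  std$female <- std$male
  su2 <- 0.8; se2 <- 0.4; trend <- 0.3
  fit <- mixed_fit(fixed = cbind(rep(trend, 4), rep(0, 4)),
                   Sigma_u = diag(rep(su2, 4)),
                   resid_var = rep(se2, 4),
                   standardization = std, landmark_age = 50)
  y <- 1.7
  meas <- data.frame(id = 1, factor = "sbp", age = 50, value = y)
  pred <- predict_blups(fit, meas, rules = wide_rules())
  expect_equal(pred[1, "sbp"], trend + su2 / (su2 + se2) * (y - trend),
               tolerance = 1e-12)
  ## other factors stay at the trend: the covariance is diagonal
  expect_equal(unname(pred[1, "tc"]), trend, tolerance = 1e-12)

  ## no measurements at all: population fixed-trend prediction
  pred0 <- predict_blups(fit, meas[0, ], ids = 7, rules = wide_rules())
  expect_equal(unname(pred0[1, 1:3]), rep(trend, 3), tolerance = 1e-12)
})

test_that("cross-factor information moves predictions along the covariance",
          {
  std <- list(male = list(mean = c(sbp = 0, tc = 0, hdl = 0),
                          sd = c(sbp = 1, tc = 1, hdl = 1)))
  std$female <- std$male
  Sig <- diag(4)
  Sig[1, 2] <- Sig[2, 1] <- 0.6   # sbp-tc positive
  Sig[1, 3] <- Sig[3, 1] <- -0.5  # sbp-hdl negative
  fit <- mixed_fit(fixed = cbind(rep(0, 4), rep(0, 4)), Sigma_u = Sig,
                   resid_var = rep(0.5, 4), standardization = std,
                   landmark_age = 50)
  meas <- data.frame(id = 1, factor = "sbp", age = 50, value = 2)
  pred <- predict_blups(fit, meas, rules = wide_rules())
  expect_gt(pred[1, "tc"], 0)
  expect_lt(pred[1, "hdl"], 0)
})

test_that("BLUPs equal the joint-MVN conditioning oracle", {
  std <- list(male = list(mean = c(sbp = 130, tc = 5, hdl = 1.4),
                          sd = c(sbp = 15, tc = 1, hdl = 0.35)))
  std$female <- std$male
  Sig <- matrix(0.3, 4, 4) + diag(0.7, 4)
  fit <- mixed_fit(fixed = cbind(c(0.2, -0.1, 0, 0.4), rep(0.05, 4)),
                   Sigma_u = Sig, resid_var = c(0.5, 0.4, 0.6, 0.2),
                   standardization = std, landmark_age = 60)
  set.seed(7)
  meas <- data.frame(
    id = sample(1:5, 12, replace = TRUE),
    factor = sample(RISK_FACTORS, 12, replace = TRUE),
    age = runif(12, 52, 60),
    value = NA)
  ## raw-scale values that standardize to modest numbers
  m <- std$male
  raw <- function(f, z) if (f == "smoking") z else m$mean[[f]] + z * m$sd[[f]]
  z <- rnorm(12, 0, 0.8)
  meas$value <- mapply(raw, meas$factor, pmin(pmax(z, -2), 2))
  pred <- predict_blups(fit, meas, ids = 1:5)

  meas_std <- meas
  for (f in c("sbp", "tc", "hdl")) {
    sel <- meas_std$factor == f
    meas_std$value[sel] <- (meas_std$value[sel] - m$mean[[f]]) / m$sd[[f]]
  }
  oracle <- gls_blup_oracle(fit, meas_std, 1:5)
  oracle[, "smoking"] <- pmin(pmax(oracle[, "smoking"], 0), 1)
  expect_equal(unname(pred), unname(oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("additional measurements never inflate the conditional variance",
          {
  std <- list(male = list(mean = c(sbp = 0, tc = 0, hdl = 0),
                          sd = c(sbp = 1, tc = 1, hdl = 1)))
  std$female <- std$male
  Sig <- matrix(0.2, 4, 4) + diag(0.8, 4)
  fit <- mixed_fit(fixed = cbind(rep(0, 4), rep(0, 4)), Sigma_u = Sig,
                   resid_var = rep(0.5, 4), standardization = std,
                   landmark_age = 50)
  meas1 <- data.frame(id = 1, factor = "sbp", age = 49, value = 1)
  meas2 <- rbind(meas1,
                 data.frame(id = 1, factor = "tc", age = 48, value = 0.5))
  v1 <- predict_blups(fit, meas1, se = TRUE, rules = wide_rules())$cond_var[["1"]]
  v2 <- predict_blups(fit, meas2, se = TRUE, rules = wide_rules())$cond_var[["1"]]
  expect_true(all(diag(v2) <= diag(v1) + 1e-12))
})

test_that("shrinkage vanishes in the zero-noise limit", {
  std <- list(male = list(mean = c(sbp = 0, tc = 0, hdl = 0),
                          sd = c(sbp = 1, tc = 1, hdl = 1)))
  std$female <- std$male
  fit_noisy <- mixed_fit(fixed = cbind(rep(0.1, 4), rep(0, 4)),
                         Sigma_u = diag(4), resid_var = rep(0.5, 4),
                         standardization = std, landmark_age = 50)
  fit_exact <- mixed_fit(fixed = cbind(rep(0.1, 4), rep(0, 4)),
                         Sigma_u = diag(4), resid_var = rep(1e-10, 4),
                         standardization = std, landmark_age = 50)
  meas <- data.frame(id = c(1, 1, 2), factor = c("sbp", "tc", "hdl"),
                     age = 50, value = c(1.9, -0.7, 0.4))
  exact <- predict_blups(fit_exact, meas, ids = 1:2, rules = wide_rules())
  expect_equal(exact[1, "sbp"], 1.9, tolerance = 1e-6)
  expect_equal(exact[1, "tc"], -0.7, tolerance = 1e-6)
  expect_equal(exact[2, "hdl"], 0.4, tolerance = 1e-6)
  ## with residual noise, the prediction shrinks strictly towards the trend
  noisy <- predict_blups(fit_noisy, meas, ids = 1:2, rules = wide_rules())
  expect_lt(noisy[1, "sbp"], 1.9)
  expect_gt(noisy[1, "sbp"], 0.1)
})

test_that("shrinkage keeps every BLUP between trend and observed mean", {
  std <- list(male = list(mean = c(sbp = 0, tc = 0, hdl = 0),
                          sd = c(sbp = 1, tc = 1, hdl = 1)))
  std$female <- std$male
  fit <- mixed_fit(fixed = cbind(c(0.3, -0.2, 0, 0.5), rep(0, 4)),
                   Sigma_u = diag(c(0.9, 0.5, 0.7, 0.04)),
                   resid_var = c(0.6, 0.3, 0.8, 0.2),
                   standardization = std, landmark_age = 50)
  set.seed(9)
  for (rep in 1:20) {
    f <- sample(RISK_FACTORS, 1)
    k <- sample(1:4, 1)
    y <- rnorm(k, 0, 1)
    meas <- data.frame(id = 1, factor = f, age = 50, value = y)
    pred <- predict_blups(fit, meas, rules = wide_rules())
    trend <- fit$fixed[f, "intercept"]
    lo <- min(trend, mean(y)); hi <- max(trend, mean(y))
    val <- pred[1, f]
    if (f == "smoking") { lo <- max(lo, 0) - 1e-12; hi <- min(hi, 1) + 1e-12 }
    expect_gte(val, lo - 1e-10)
    expect_lte(val, hi + 1e-10)
  }
})
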