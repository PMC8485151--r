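## Risk-factor bookkeeping shared across modules.  Order is load-bearing:
## covariance matrices, coefficient vectors and BLUP output all use it.
RISK_FACTORS <- c("sbp", "tc", "hdl", "smoking")

#' Configuration of the synthetic cohort generator
#'
#' Bundles every parameter of the data-generating process emulated by
#' [generate_cohort()]: correlated person-level trajectories of systolic
#' blood pressure (SBP, mm Hg), total cholesterol (TC, mmol/L), HDL
#' cholesterol (mmol/L) and current smoking (probability scale); Weibull
#' event times with a multiplicative hazard reduction after statin
#' initiation; age- and cholesterol-dependent statin initiation on a yearly
#' grid; diabetes and antihypertensive-treatment onset; and administrative
#' censoring.
#'
#' The defaults describe a primary-care population aged 40-85 followed for
#' up to 13.7 years in which roughly one person in seven initiates statins,
#' statins reduce the cardiovascular hazard by 25% (`statin_hr = 0.75`), and
#' true 10-year risks span roughly 1%-40% across the age range.
#'
#' @param n_persons Number of persons to simulate.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @param entry_age_range Range of study entry ages in years (uniform).
#' @param entry_spike Probability of entering exactly at the lower end of
#'   `entry_age_range`, emulating people who reach the eligibility age
#'   during the study window (the rest enter uniformly over the range).
#' @param prop_male Proportion of men.
#' @param min_followup,max_followup Administrative follow-up is uniform on
#'   this range (years), emulating staggered entry over a fixed study
#'   window, and further capped at age 95.
#' @param visit_rate Expected number of measurements per person-year of the
#'   measurement window, which runs from 10 years before entry to exit.
#' @param factor_means,factor_trends Named per-factor population value at
#'   age 60 and linear slope per year of age.
#' @param Sigma_u 4x4 between-person random-intercept covariance
#'   (sbp, tc, hdl, smoking); must be symmetric positive semi-definite.
#' @param resid_sd Named per-factor residual (measurement-error) SD; the
#'   smoking entry is ignored because smoking observations are Bernoulli
#'   draws of the latent probability.
#' @param scale_sd Named SDs used to put SBP/TC/HDL on a standardized scale
#'   inside the event-hazard linear predictor.
#' @param weibull_shape Shape \eqn{\nu > 0} of the Weibull event hazard.
#' @param log_baseline_rate Named per-sex log baseline rate \eqn{\alpha}
#'   at age 60 (hazard \eqn{\lambda = e^{\alpha}}).
#' @param log_rate_age_slope Slope of the log baseline rate per year of
#'   entry age; carries the age gradient of cardiovascular risk, since age
#'   is not one of the six hazard covariates.
#' @param beta_true Named log-hazard coefficients for the six covariates
#'   (standardized SBP/TC/HDL, smoking probability, diabetes flag,
#'   hypertension-treatment flag).
#' @param statin_hr Multiplicative hazard factor after statin initiation;
#'   must lie in (0, 1].  `1` switches the treatment effect off.
#' @param statin_init Named per-year initiation log-odds: intercept, slope
#'   per year of current age (centred at 60) and slope per SD of latent
#'   total cholesterol.  An `-Inf` intercept disables initiation.
#' @param diabetes_rate,htn_rate Per-year onset probabilities, simulated on
#'   a yearly grid from 10 years before entry.
#'
#' @return An object of class `generator_config` (a validated list).
#' @seealso [generate_cohort()], [paired_counterfactual_times()]
#' @export
generator_config <- function(n_persons = 10000L,
                             seed = 1L,
                             entry_age_range = c(40, 85),
                             entry_spike = 0.2,
                             prop_male = 0.45,
                             min_followup = 1,
                             max_followup = 13.7,
                             visit_rate = 0.8,
                             factor_means = c(sbp = 135, tc = 5.5,
                                              hdl = 1.45, smoking = 0.35),
                             factor_trends = c(sbp = 0.4, tc = 0.01,
                                               hdl = -0.002, smoking = -0.004),
                             Sigma_u = default_sigma_u(),
                             resid_sd = c(sbp = 10, tc = 0.5,
                                          hdl = 0.15, smoking = 0),
                             scale_sd = c(sbp = 18, tc = 1.1, hdl = 0.4),
                             weibull_shape = 1.15,
                             log_baseline_rate = c(male = -4.9, female = -5.35),
                             log_rate_age_slope = 0.065,
                             beta_true = c(sbp = 0.25, tc = 0.20, hdl = -0.20,
                                           smoking = 0.55, diabetes = 0.60,
                                           htn = 0.30),
                             statin_hr = 0.75,
                             statin_init = c(intercept = -3.9, age = 0.05,
                                             tc = 0.5),
                             diabetes_rate = 0.0025,
                             htn_rate = 0.017) {
  cfg <- list(n_persons = as.integer(n_persons), seed = as.integer(seed),
              entry_age_range = as.numeric(entry_age_range),
              entry_spike = entry_spike,
              prop_male = prop_male,
              min_followup = min_followup, max_followup = max_followup,
              visit_rate = visit_rate,
              factor_means = factor_means[RISK_FACTORS],
              factor_trends = factor_trends[RISK_FACTORS],
              Sigma_u = Sigma_u,
              resid_sd = resid_sd[RISK_FACTORS],
              scale_sd = scale_sd[RISK_FACTORS[1:3]],
              weibull_shape = weibull_shape,
              log_baseline_rate = log_baseline_rate,
              log_rate_age_slope = log_rate_age_slope,
              beta_true = beta_true,
              statin_hr = statin_hr,
              statin_init = statin_init,
              diabetes_rate = diabetes_rate, htn_rate = htn_rate)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

#' @keywords internal
default_sigma_u <- function() {
  sds <- c(sbp = 12, tc = 0.9, hdl = 0.33, smoking = 0.25)
  corr <- diag(4)
  dimnames(corr) <- list(RISK_FACTORS, RISK_FACTORS)
  corr["sbp", "tc"] <- corr["tc", "sbp"] <- 0.10
  corr["sbp", "hdl"] <- corr["hdl", "sbp"] <- -0.05
  corr["sbp", "smoking"] <- corr["smoking", "sbp"] <- 0.05
  corr["tc", "hdl"] <- corr["hdl", "tc"] <- -0.20
  corr["tc", "smoking"] <- corr["smoking", "tc"] <- 0.05
  corr["hdl", "smoking"] <- corr["smoking", "hdl"] <- -0.10
  diag(sds) %*% corr %*% diag(sds)
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_persons >= 0, length(cfg$entry_age_range) == 2,
            cfg$entry_age_range[1] <= cfg$entry_age_range[2],
            cfg$prop_male >= 0, cfg$prop_male <= 1,
            cfg$entry_spike >= 0, cfg$entry_spike <= 1,
            cfg$min_followup > 0, cfg$max_followup >= cfg$min_followup,
            cfg$visit_rate >= 0)
  if (!is.matrix(cfg$Sigma_u) || any(dim(cfg$Sigma_u) != 4) ||
      max(abs(cfg$Sigma_u - t(cfg$Sigma_u))) > 1e-8 ||
      min(eigen(cfg$Sigma_u, symmetric = TRUE, only.values = TRUE)$values) <
        -1e-8 * max(abs(cfg$Sigma_u)))
    stop("'Sigma_u' must be a symmetric positive semi-definite 4x4 matrix",
         call. = FALSE)
  dimnames(cfg$Sigma_u) <- list(RISK_FACTORS, RISK_FACTORS)
  if (!(cfg$weibull_shape > 0))
    stop("'weibull_shape' must be positive", call. = FALSE)
  if (!(cfg$statin_hr > 0 && cfg$statin_hr <= 1))
    stop("'statin_hr' must lie in (0, 1]", call. = FALSE)
  if (cfg$factor_means["smoking"] < 0 || cfg$factor_means["smoking"] > 1)
    stop("smoking probability must lie in [0, 1]", call. = FALSE)
  if (anyNA(cfg$factor_means) || anyNA(cfg$beta_true[1:6]))
    stop("factor_means and beta_true must be fully named ",
         "(sbp, tc, hdl, smoking[, diabetes, htn])", call. = FALSE)
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic cohort generator configuration\n")
  cat(sprintf("  persons: %d (%.0f%% male), entry ages %g-%g, follow-up %g-%g y\n",
              x$n_persons, 100 * x$prop_male, x$entry_age_range[1],
              x$entry_age_range[2], x$min_followup, x$max_followup))
  cat(sprintf("  Weibull shape %.3g, statin hazard ratio %.3g\n",
              x$weibull_shape, x$statin_hr))
  invisible(x)
}
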