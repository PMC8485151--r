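RISK_FACTORS <- c("sbp", "tc", "hdl", "smoking")

## Cohorts are expensive to simulate, so each named fixture is built once
## per test run and reused across files.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

## Large cohort under the default study conditions (used for recovery of
## the statin effect, coefficient attenuation, crude-rate ordering).
big_cohort <- function() {
  fixture("big", generate_cohort(generator_config(n_persons = 20000,
                                                  seed = 101)))
}

## Moderate cohort for parameter-recovery and coupling checks.
mid_cohort <- function() {
  fixture("mid", generate_cohort(generator_config(n_persons = 2000,
                                                  seed = 11)))
}

## Trajectory-recovery cohort: everyone male, entering at 50 with fixed
## follow-up, event hazard independent of the random effects and no
## statin initiation, so the landmark-50 risk set is an unselected sample
## from the measurement model itself.
stage1_cohort <- function() {
  fixture("stage1",
          generate_cohort(generator_config(
            n_persons = 2000, seed = 21, entry_age_range = c(50, 50),
            prop_male = 1, min_followup = 10.5, max_followup = 10.5,
            beta_true = c(sbp = 0, tc = 0, hdl = 0, smoking = 0,
                          diabetes = 0, htn = 0),
            statin_init = c(intercept = -Inf, age = 0, tc = 0))))
}

## A degenerate configuration with no covariate variation: the event rate
## is exactly `rate` for everyone (used for closed-form checks).
flat_config <- function(rate = 0.1, shape = 1, hr = 0.75, seed = 31,
                        n = 100) {
  generator_config(
    n_persons = n, seed = seed, entry_age_range = c(60, 60),
    entry_spike = 0,
    Sigma_u = matrix(0, 4, 4), resid_sd = c(sbp = 0, tc = 0, hdl = 0,
                                            smoking = 0),
    weibull_shape = shape,
    log_baseline_rate = c(male = log(rate), female = log(rate)),
    log_rate_age_slope = 0,
    beta_true = c(sbp = 0, tc = 0, hdl = 0, smoking = 0, diabetes = 0,
                  htn = 0),
    statin_hr = hr,
    statin_init = c(intercept = -Inf, age = 0, tc = 0),
    diabetes_rate = 0, htn_rate = 0)
}

## Plausibility bounds wide enough to pass standardized-scale test values
## straight through to the BLUP machinery.
wide_rules <- function() {
  cleaning_rules(sbp = c(-1e9, 1e9), tc = c(-1e9, 1e9), hdl = c(-1e9, 1e9))
}

## Hand-built four-person cohort exercising the landmark eligibility rules.
toy_cohort <- function() {
  persons <- data.frame(
    id = 1:4,
    sex = "male",
    entry_age = c(45, 45, 41, 44),
    exit_age = c(52, 55, 58, 53),
    event_flag = c(1L, 0L, 0L, 1L))
  statin <- data.frame(id = 2L, initiation_age = 49)
  as_cohort(persons, statin = statin)
}

## O(n^2) concordance oracle: usable pairs are those where the shorter
## time is an event; tied predictions count 1/2.
brute_force_c <- function(p, time, event) {
  conc <- usable <- 0
  n <- length(p)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ti <- time[i]; tj <- time[j]
      if (ti == tj) next
      short <- if (ti < tj) i else j
      long <- if (ti < tj) j else i
      if (event[short] != 1) next
      usable <- usable + 1
      if (p[short] > p[long]) conc <- conc + 1
      else if (p[short] == p[long]) conc <- conc + 0.5
    }
  }
  conc / usable
}

## Classical (uncensored) continuous NRI by direct counting.
counting_continuous_nri <- function(p_old, p_new, d) {
  up <- p_new > p_old
  dn <- p_new < p_old
  ev <- (sum(up & d == 1) - sum(dn & d == 1)) / sum(d == 1)
  ne <- (sum(dn & d == 0) - sum(up & d == 0)) / sum(d == 0)
  c(event = ev, nonevent = ne, overall = ev + ne)
}

## Joint multivariate-normal conditioning oracle for BLUPs: stacks all
## persons' observations into one covariance matrix and conditions once.
gls_blup_oracle <- function(fit, meas_std, ids) {
  k <- 4
  Sig <- fit$Sigma_u
  nid <- length(ids)
  nobs <- nrow(meas_std)
  Zu <- matrix(0, nobs, k * nid)
  fidx <- match(meas_std$factor, RISK_FACTORS)
  pidx <- match(meas_std$id, ids)
  Zu[cbind(seq_len(nobs), (pidx - 1) * k + fidx)] <- 1
  Su <- kronecker(diag(nid), Sig)
  V <- Zu %*% Su %*% t(Zu) + diag(fit$resid_var[fidx], nobs)
  age_c <- meas_std$age - fit$landmark_age
  m <- fit$fixed[fidx, "intercept"] + fit$fixed[fidx, "slope"] * age_c
  u <- drop(Su %*% t(Zu) %*% solve(V, meas_std$value - m))
  pred <- matrix(rep(fit$fixed[, "intercept"], nid), nid, k, byrow = TRUE) +
    matrix(u, nid, k, byrow = TRUE)
  dimnames(pred) <- list(ids, RISK_FACTORS)
  pred
}
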