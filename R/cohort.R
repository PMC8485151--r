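#' Generate a synthetic longitudinal cohort
#'
#' Simulates person-level electronic-health-record-like data with the
#' statistical structure assumed by the landmark models: correlated repeat
#' risk-factor measurements around latent person trajectories, Weibull
#' cardiovascular event times whose hazard is multiplied by
#' `config$statin_hr` from the moment of statin initiation, initiation
#' simulated year-by-year from a logistic model in current age and latent
#' cholesterol (only while event-free), yearly diabetes and
#' hypertension-treatment onset from 10 years before entry, and
#' administrative censoring.
#'
#' Event times are drawn by inverse transform on the closed-form piecewise
#' cumulative hazard
#' \deqn{H(t) = \lambda e^{x\beta}\,[t^\nu] \quad (t < t_s), \qquad
#'       H(t) = \lambda e^{x\beta}\,[t_s^\nu + \mathrm{hr}\,(t^\nu - t_s^\nu)]
#'       \quad (t \ge t_s),}
#' with the clock starting at study entry and covariates frozen at their
#' entry-age latent values.  The same exponential variate drives a latent
#' *untreated* event time, stored in the truth table so that the
#' counterfactual time transformation can be checked against exactly
#' coupled potential outcomes.
#'
#' @param config A [generator_config()].
#' @param truth Keep the ground-truth sidecar table (latent random
#'   intercepts, entry covariates, linear predictor, true naive 10-year
#'   risk, coupled untreated event time)?
#'
#' @return An object of class `cohort`: a list of data frames
#'   `persons` (id, sex, entry_age, exit_age, event_flag, event_age),
#'   `measurements` (id, factor, age, value), `statin` (id,
#'   initiation_age), `conditions` (id, condition, onset_age), optionally
#'   `truth`, plus the `config`.  All ages are in years.
#' @export
generate_cohort <- function(config, truth = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_persons
  if (n == 0L) return(empty_cohort(config))

  sex <- ifelse(stats::runif(n) < config$prop_male, "male", "female")
  entry <- draw_entry_ages(config, n)
  fu_admin <- pmin(stats::runif(n, config$min_followup, config$max_followup),
                   pmax(95 - entry, config$min_followup))

  ## latent person effects and entry covariates
  u <- matrix(stats::rnorm(n * 4), n, 4) %*% chol_psd(config$Sigma_u)
  colnames(u) <- RISK_FACTORS
  lat_entry <- latent_values(config, entry, u)
  z <- sweep(lat_entry[, 1:3, drop = FALSE], 2,
             config$factor_means[1:3], "-")
  z <- sweep(z, 2, config$scale_sd, "/")
  colnames(z) <- paste0("z_", RISK_FACTORS[1:3])
  smoking_p <- lat_entry[, "smoking"]

  ## condition onsets on a yearly grid from entry - 10
  diab_onset <- onset_ages(n, entry, config$diabetes_rate)
  htn_onset <- onset_ages(n, entry, config$htn_rate)
  diab_entry <- as.integer(diab_onset <= entry)
  htn_entry <- as.integer(htn_onset <= entry)

  beta <- config$beta_true
  lp <- drop(z %*% beta[1:3]) + beta["smoking"] * smoking_p +
    beta["diabetes"] * diab_entry + beta["htn"] * htn_entry
  log_r <- config$log_baseline_rate[sex] + config$log_rate_age_slope *
    (entry - 60) + lp
  r <- exp(unname(log_r))

  sim <- simulate_event_times(r, fu_admin, entry, z[, "z_tc"], config)

  event <- !is.na(sim$t_event)
  exit_t <- ifelse(event, sim$t_event, fu_admin)
  exit_t <- pmax(exit_t, 1 / 365.25)
  ## initiation at/after the event or censoring time is not observed
  ts <- sim$t_s
  ts[!is.na(ts) & ts >= exit_t] <- NA_real_

  persons <- data.frame(id = seq_len(n), sex = sex, entry_age = entry,
                        exit_age = entry + exit_t,
                        event_flag = as.integer(event),
                        event_age = ifelse(event, entry + exit_t, NA_real_))
  statin <- data.frame(id = which(!is.na(ts)),
                       initiation_age = entry[!is.na(ts)] + ts[!is.na(ts)])
  diab_ids <- which(diab_onset <= persons$exit_age)
  htn_ids <- which(htn_onset <= persons$exit_age)
  conditions <- rbind(
    data.frame(id = diab_ids,
               condition = rep("diabetes", length(diab_ids)),
               onset_age = diab_onset[diab_ids]),
    data.frame(id = htn_ids,
               condition = rep("htn_treatment", length(htn_ids)),
               onset_age = htn_onset[htn_ids]))
  conditions <- conditions[order(conditions$id), ]
  rownames(conditions) <- NULL

  measurements <- simulate_measurements(config, persons, u)

  out <- list(persons = persons, measurements = measurements,
              statin = statin, conditions = conditions, config = config)
  if (truth) {
    nu <- config$weibull_shape
    out$truth <- data.frame(
      id = seq_len(n), sex = sex, entry_age = entry,
      u_sbp = u[, 1], u_tc = u[, 2], u_hdl = u[, 3], u_smoking = u[, 4],
      z_sbp = z[, 1], z_tc = z[, 2], z_hdl = z[, 3], smoking = smoking_p,
      diabetes = diab_entry, htn = htn_entry,
      lp = lp, rate = r, exp_draw = sim$E,
      true_risk10 = 1 - exp(-r * 10^nu),
      untreated_time = (sim$E / r)^(1 / nu))
  }
  class(out) <- "cohort"
  out
}

## Entry ages: a point mass at the lower bound (people reaching the
## eligibility age during the study window) plus a uniform body.
draw_entry_ages <- function(config, n) {
  lo <- config$entry_age_range[1]
  hi <- config$entry_age_range[2]
  at_lo <- stats::runif(n) < config$entry_spike
  ifelse(at_lo, lo, stats::runif(n, lo, hi))
}

## Lower-triangular factor that tolerates semi-definite Sigma.
chol_psd <- function(S) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(S, symmetric = TRUE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(S)) %*% t(e$vectors))
}

latent_values <- function(config, age, u) {
  m <- outer(rep(1, length(age)), config$factor_means) +
    outer(age - 60, config$factor_trends) + u
  m[, "smoking"] <- pmin(pmax(m[, "smoking"], 0), 1)
  m
}

onset_ages <- function(n, entry, rate) {
  if (rate <= 0) return(rep(Inf, n))
  entry - 10 + stats::rgeom(n, rate) + stats::runif(n)
}

## Year-by-year inverse-transform simulation of the piecewise Weibull
## event process with statin initiation drawn at year starts while
## event-free.  Returns times since entry.
simulate_event_times <- function(r, fu, entry, z_tc, config) {
  n <- length(r)
  nu <- config$weibull_shape
  hr <- config$statin_hr
  si <- config$statin_init
  E <- stats::rexp(n)
  t_event <- rep(NA_real_, n)
  t_s <- rep(NA_real_, n)
  cum <- numeric(n)
  for (k in seq_len(ceiling(max(fu))) - 1L) {
    act <- which(is.na(t_event) & fu > k)
    if (!length(act)) break
    cand <- act[is.na(t_s[act])]
    if (length(cand) && is.finite(si[["intercept"]])) {
      p_init <- stats::plogis(si[["intercept"]] +
                                si[["age"]] * (entry[cand] + k - 60) +
                                si[["tc"]] * z_tc[cand])
      hit <- cand[stats::runif(length(cand)) < p_init]
      t_s[hit] <- k + stats::runif(length(hit))
    }
    a <- k
    b <- pmin(k + 1, fu[act])
    s <- t_s[act]
    cut <- pmin(pmax(ifelse(is.na(s), Inf, s), a), b)
    ra <- r[act]
    ## untreated piece (a, cut], then treated piece (cut, b]
    dH1 <- ra * (cut^nu - a^nu)
    ev1 <- cum[act] + dH1 >= E[act]
    t1 <- ((E[act] - cum[act]) / ra + a^nu)^(1 / nu)
    cum2 <- cum[act] + dH1
    dH2 <- ra * hr * (b^nu - cut^nu)
    ev2 <- !ev1 & cum2 + dH2 >= E[act]
    t2 <- (cut^nu + (E[act] - cum2) / (ra * hr))^(1 / nu)
    t_event[act[ev1]] <- t1[ev1]
    t_event[act[ev2]] <- t2[ev2]
    cum[act] <- cum2 + dH2
  }
  ## initiation never realized before the event is dropped from the record
  drop <- !is.na(t_s) & !is.na(t_event) & t_s >= t_event
  t_s[drop] <- NA_real_
  list(t_event = t_event, t_s = t_s, E = E)
}

simulate_measurements <- function(config, persons, u) {
  n <- nrow(persons)
  win_lo <- persons$entry_age - 10
  win_hi <- persons$exit_age
  k <- stats::rpois(n, config$visit_rate * (win_hi - win_lo))
  id <- rep(persons$id, k)
  age <- stats::runif(sum(k), rep(win_lo, k), rep(win_hi, k))
  fac <- sample(RISK_FACTORS, sum(k), replace = TRUE)
  idx <- match(id, persons$id)
  mu <- config$factor_means[fac] + config$factor_trends[fac] * (age - 60) +
    u[cbind(idx, match(fac, RISK_FACTORS))]
  value <- mu + stats::rnorm(sum(k)) * config$resid_sd[fac]
  smk <- fac == "smoking"
  value[smk] <- stats::rbinom(sum(smk), 1, pmin(pmax(mu[smk], 0), 1))
  out <- data.frame(id = id, factor = fac, age = age, value = unname(value))
  out <- out[order(out$id, out$factor, out$age), ]
  rownames(out) <- NULL
  out
}

empty_cohort <- function(config) {
  out <- list(
    persons = data.frame(id = integer(), sex = character(),
                         entry_age = numeric(), exit_age = numeric(),
                         event_flag = integer(), event_age = numeric()),
    measurements = data.frame(id = integer(), factor = character(),
                              age = numeric(), value = numeric()),
    statin = data.frame(id = integer(), initiation_age = numeric()),
    conditions = data.frame(id = integer(), condition = character(),
                            onset_age = numeric()),
    truth = data.frame(),
    config = config)
  class(out) <- "cohort"
  out
}

#' Assemble a cohort object from its component tables
#'
#' Constructor used to build small hand-written cohorts (e.g. in tests or
#' when ingesting external delimited files).  Checks the structural
#' invariants: entry before exit, `event_age == exit_age` for events,
#' measurement ages within `[entry_age - 10, exit_age]`, and onset or
#' initiation ages no earlier than 10 years before entry.
#'
#' @param persons Data frame with columns id, sex ("male"/"female"),
#'   entry_age, exit_age, event_flag (0/1) and optionally event_age.
#' @param measurements,statin,conditions Optional component tables in the
#'   layout produced by [generate_cohort()].
#' @param truth Optional ground-truth sidecar table.
#' @param config Optional [generator_config()] to attach.
#' @return A `cohort` object.
#' @export
as_cohort <- function(persons, measurements = NULL, statin = NULL,
                      conditions = NULL, truth = NULL, config = NULL) {
  stopifnot(all(c("id", "sex", "entry_age", "exit_age", "event_flag") %in%
                  names(persons)))
  if (is.null(persons$event_age))
    persons$event_age <- ifelse(persons$event_flag == 1, persons$exit_age,
                                NA_real_)
  if (any(persons$entry_age >= persons$exit_age))
    stop("entry_age must be strictly before exit_age", call. = FALSE)
  ev <- persons$event_flag == 1
  if (any(abs(persons$event_age[ev] - persons$exit_age[ev]) > 1e-8))
    stop("event_age must equal exit_age for events", call. = FALSE)
  blank <- empty_cohort(config)
  if (is.null(measurements)) measurements <- blank$measurements
  if (is.null(statin)) statin <- blank$statin
  if (is.null(conditions)) conditions <- blank$conditions
  if (nrow(measurements)) {
    i <- match(measurements$id, persons$id)
    if (anyNA(i)) stop("measurement ids not in persons", call. = FALSE)
    if (any(measurements$age < persons$entry_age[i] - 10 - 1e-8) ||
        any(measurements$age > persons$exit_age[i] + 1e-8))
      stop("measurement ages must lie in [entry_age - 10, exit_age]",
           call. = FALSE)
    if (!all(measurements$factor %in% RISK_FACTORS))
      stop("unknown risk factor in measurements", call. = FALSE)
  }
  if (nrow(statin)) {
    i <- match(statin$id, persons$id)
    if (any(statin$initiation_age < persons$entry_age[i] - 10 - 1e-8))
      stop("initiation_age before entry_age - 10", call. = FALSE)
  }
  out <- list(persons = persons, measurements = measurements,
              statin = statin, conditions = conditions,
              truth = truth, config = config)
  class(out) <- "cohort"
  out
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d persons, %d events, %d statin initiators\n",
              nrow(x$persons), sum(x$persons$event_flag), nrow(x$statin)))
  cat(sprintf("  %d measurements, %d condition onsets%s\n",
              nrow(x$measurements), nrow(x$conditions),
              if (!is.null(x$truth) && nrow(x$truth)) ", truth attached" else ""))
  invisible(x)
}

#' Exactly coupled treated and untreated event times
#'
#' Draws covariates as in [generate_cohort()] and inverts one shared
#' uniform variate per draw under both the treated (piecewise, hazard
#' multiplied by `statin_hr` from `t_s`) and the untreated cumulative
#' hazard, yielding paired potential outcomes.  Serves as the oracle for
#' the counterfactual survival-time transformation: transforming the
#' treated time with [counterfactual_times()] at the true shape must
#' recover the untreated time exactly.
#'
#' @param config A [generator_config()]; `statin_hr` is used as the
#'   treatment effect.
#' @param n Number of draws.
#' @param t_s Statin initiation times (recycled); default uniform on
#'   (0, `max_followup`).
#' @param u Optional uniform survival variates (the event time solves
#'   \eqn{S(t) = u}); default `runif(n)`.
#' @return Data frame with columns `treated_time`, `untreated_time`,
#'   `t_s`, `rate` (the per-draw \eqn{\lambda e^{x\beta}}).
#' @export
paired_counterfactual_times <- function(config, n, t_s = NULL, u = NULL) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  nu <- config$weibull_shape
  hr <- config$statin_hr
  sex <- ifelse(stats::runif(n) < config$prop_male, "male", "female")
  entry <- draw_entry_ages(config, n)
  uu <- matrix(stats::rnorm(n * 4), n, 4) %*% chol_psd(config$Sigma_u)
  colnames(uu) <- RISK_FACTORS
  lat <- latent_values(config, entry, uu)
  z <- sweep(lat[, 1:3, drop = FALSE], 2, config$factor_means[1:3], "-")
  z <- sweep(z, 2, config$scale_sd, "/")
  beta <- config$beta_true
  lp <- drop(z %*% beta[1:3]) + beta["smoking"] * lat[, "smoking"]
  r <- exp(unname(config$log_baseline_rate[sex] +
                    config$log_rate_age_slope * (entry - 60) + lp))
  if (is.null(t_s)) t_s <- stats::runif(n, 0, config$max_followup)
  t_s <- rep_len(t_s, n)
  if (is.null(u)) u <- stats::runif(n)
  E <- -log(rep_len(u, n))
  untreated <- (E / r)^(1 / nu)
  Hs <- r * t_s^nu
  treated <- ifelse(E <= Hs,
                    (E / r)^(1 / nu),
                    (t_s^nu + (E / r - t_s^nu) / hr)^(1 / nu))
  data.frame(treated_time = treated, untreated_time = untreated,
             t_s = t_s, rate = r)
}

#' Entry-anchored evaluation data with true covariates
#'
#' Reshapes a generated cohort (with its truth sidecar) into the
#' risk-set layout used by [split_at_statin()] and [fit_weibull_ph()],
#' with the clock starting at study entry: follow-up time, event flag,
#' statin initiation time (years since entry) and the exact generative
#' covariates, including sex and centred entry age.  Fitting the Weibull
#' model on this table with a free time-dependent statin term recovers the
#' generator's treatment effect; it is the standard harness for
#' parameter-recovery checks.
#'
#' @param cohort A `cohort` generated with `truth = TRUE`.
#' @return Data frame with columns id, time, event, statin_time, male,
#'   age_c and the six hazard covariates.
#' @export
entry_eval_data <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(cohort$truth) || !nrow(cohort$truth))
    stop("cohort was generated without the truth sidecar", call. = FALSE)
  p <- cohort$persons
  tr <- cohort$truth[match(p$id, cohort$truth$id), ]
  st <- cohort$statin$initiation_age[match(p$id, cohort$statin$id)]
  data.frame(id = p$id,
             time = pmax(p$exit_age - p$entry_age, 1 / 365.25),
             event = p$event_flag,
             statin_time = st - p$entry_age,
             male = as.integer(p$sex == "male"),
             age_c = p$entry_age - 60,
             z_sbp = tr$z_sbp, z_tc = tr$z_tc, z_hdl = tr$z_hdl,
             smoking = tr$smoking, diabetes = tr$diabetes, htn = tr$htn)
}

#' Write / read a cohort as delimited text
#'
#' The four component tables (and the truth sidecar, if present) are
#' written as CSV files with the documented column names and units (ages
#' in years, SBP in mm Hg, cholesterol in mmol/L, smoking 0/1); the
#' generator configuration is written as YAML.
#'
#' @param cohort A `cohort`.
#' @param dir Directory to write to (created if needed).
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` returns
#'   the reassembled `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tab in c("persons", "measurements", "statin", "conditions"))
    utils::write.csv(cohort[[tab]], file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE)
  if (!is.null(cohort$truth) && nrow(cohort$truth))
    utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  if (!is.null(cohort$config)) {
    cfg <- unclass(cohort$config)
    cfg$Sigma_u <- as.vector(cfg$Sigma_u)
    ## named vectors must become maps, or yaml drops the names
    cfg <- lapply(cfg, function(x)
      if (!is.null(names(x))) as.list(x) else x)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(f) {
    path <- file.path(dir, f)
    if (file.exists(path)) utils::read.csv(path) else NULL
  }
  config <- NULL
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    cfg$Sigma_u <- matrix(unlist(cfg$Sigma_u), 4, 4)
    nm <- intersect(names(cfg), names(formals(generator_config)))
    cfg <- lapply(cfg[nm], function(x) if (is.list(x)) unlist(x) else x)
    config <- do.call(generator_config, cfg)
  }
  as_cohort(rd("persons.csv"), rd("measurements.csv"), rd("statin.csv"),
            rd("conditions.csv"), truth = rd("truth.csv"), config = config)
}
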