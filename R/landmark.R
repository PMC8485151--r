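#' Build an age- and sex-specific landmark risk set
#'
#' Selects the persons eligible for the landmark model at a given age:
#' under observation at the landmark age (`entry_age <= landmark_age <
#' exit_age`), with no cardiovascular event and no statin prescription
#' strictly before the landmark age.  "Before" is strict: an event or
#' prescription exactly at the landmark age counts as occurring after it,
#' so follow-up lives on the half-open interval
#' `(landmark_age, landmark_age + horizon]`.
#'
#' Follow-up time is years since the landmark age, administratively capped
#' at the horizon (events beyond the horizon become censorings at the
#' horizon).  A minimum positive follow-up of 1/365.25 years is enforced so
#' that the Weibull log-likelihood is defined for same-day events.
#' Diabetes and hypertension-treatment flags carry the most recent status
#' at the landmark age forward.  Measurement histories within
#' `lookback` years before the landmark age are attached for stage 1.
#'
#' @param cohort A `cohort`.
#' @param landmark_age Landmark age in years (40-85).
#' @param sex `"male"` or `"female"`.
#' @param horizon Prediction horizon in years (default 10).
#' @param lookback Measurement lookback window in years (default 10).
#' @return An object of class `landmark_risk_set`: a list with
#'   `landmark_age`, `sex`, `horizon` and data frame `data` (columns id,
#'   time, event, statin_time, diabetes, htn) plus the attached
#'   `measurements`.  Empty risk sets are returned with zero rows.
#' @export
build_risk_set <- function(cohort, landmark_age, sex,
                           horizon = 10, lookback = 10) {
  stopifnot(inherits(cohort, "cohort"),
            landmark_age >= 40, landmark_age <= 85,
            sex %in% c("male", "female"), horizon > 0)
  p <- cohort$persons
  L <- landmark_age
  init <- cohort$statin$initiation_age[match(p$id, cohort$statin$id)]
  keep <- p$sex == sex & p$entry_age <= L & p$exit_age > L &
    (is.na(init) | init >= L)
  p <- p[keep, , drop = FALSE]
  init <- init[keep]

  time_raw <- p$exit_age - L
  time <- pmax(pmin(time_raw, horizon), 1 / 365.25)
  event <- as.integer(p$event_flag == 1 & time_raw <= horizon)

  statin_time <- pmax(init - L, 1 / 365.25)
  statin_time[!is.na(statin_time) & statin_time > time] <- NA_real_

  cond <- cohort$conditions
  flag_at <- function(which_cond) {
    on <- cond$id[cond$condition == which_cond & cond$onset_age <= L]
    as.integer(p$id %in% on)
  }
  data <- data.frame(id = p$id, time = time, event = event,
                     statin_time = statin_time,
                     diabetes = flag_at("diabetes"),
                     htn = flag_at("htn_treatment"))
  rownames(data) <- NULL
  meas <- cohort$measurements
  meas <- meas[meas$id %in% p$id & meas$age >= L - lookback & meas$age <= L, ,
               drop = FALSE]
  rownames(meas) <- NULL
  structure(list(landmark_age = L, sex = sex, horizon = horizon,
                 lookback = lookback, data = data, measurements = meas),
            class = "landmark_risk_set")
}

#' @export
print.landmark_risk_set <- function(x, ...) {
  cat(sprintf("Landmark risk set: age %g, %s, horizon %g y\n",
              x$landmark_age, x$sex, x$horizon))
  cat(sprintf("  %d persons, %d events, %d statin initiators, %d measurements\n",
              nrow(x$data), sum(x$data$event),
              sum(!is.na(x$data$statin_time)), nrow(x$measurements)))
  invisible(x)
}

#' Build the full grid of landmark risk sets
#'
#' @param cohort A `cohort`.
#' @param landmark_ages Integer vector of landmark ages (default 40-85,
#'   which together with both sexes gives the 92 age- and sex-specific
#'   risk sets of the modelling framework).
#' @param sexes Character vector of sexes.
#' @inheritParams build_risk_set
#' @return Named list of `landmark_risk_set` objects (`"<sex>_<age>"`).
#' @export
build_risk_sets <- function(cohort, landmark_ages = 40:85,
                            sexes = c("male", "female"),
                            horizon = 10, lookback = 10) {
  grid <- expand.grid(sex = sexes, age = landmark_ages,
                      stringsAsFactors = FALSE)
  out <- Map(function(s, a) build_risk_set(cohort, a, s, horizon, lookback),
             grid$sex, grid$age)
  names(out) <- paste0(grid$sex, "_", grid$age)
  out
}

#' Crude incidence and statin-initiation rates by landmark age
#'
#' For each landmark age and sex, computes the 10-year (horizon) crude
#' cardiovascular incidence rate and the statin-initiation rate, each per
#' 1,000 person-years with exact Poisson 95% confidence intervals.  For
#' initiation, the initiating prescription is the event and follow-up is
#' censored at the cardiovascular event or exit; person-time for incidence
#' is the capped landmark follow-up, so summed person-years equal the sum
#' of `min(time, horizon)` over risk-set rows.
#'
#' @inheritParams build_risk_sets
#' @param by_statin Also stratify the incidence rate by whether the person
#'   initiated statins within the horizon?
#' @return Data frame with one row per landmark age, sex and measure
#'   (`"cvd"`, `"statin_initiation"`, and with `by_statin` also
#'   `"cvd_initiators"` / `"cvd_noninitiators"`): events, person_years,
#'   rate (per 1,000 person-years), conf.low, conf.high, n and an
#'   `empty` flag for cells with no eligible persons.
#' @export
crude_rates <- function(cohort, landmark_ages = 40:85,
                        sexes = c("male", "female"), horizon = 10,
                        by_statin = FALSE) {
  rows <- list()
  for (sex in sexes) {
    for (L in landmark_ages) {
      rs <- build_risk_set(cohort, L, sex, horizon)$data
      add <- function(measure, events, py, n) {
        rows[[length(rows) + 1L]] <<- data.frame(
          landmark_age = L, sex = sex, measure = measure, n = n,
          events = events, person_years = py,
          rate = if (py > 0) 1000 * events / py else NA_real_,
          conf.low = if (py > 0) 1000 * stats::qchisq(0.025, 2 * events) /
            (2 * py) else NA_real_,
          conf.high = if (py > 0) 1000 * stats::qchisq(0.975, 2 * (events + 1)) /
            (2 * py) else NA_real_,
          empty = n == 0L)
      }
      add("cvd", sum(rs$event), sum(rs$time), nrow(rs))
      has_init <- !is.na(rs$statin_time)
      init_time <- ifelse(has_init, rs$statin_time, rs$time)
      add("statin_initiation", sum(has_init), sum(init_time), nrow(rs))
      if (by_statin) {
        add("cvd_initiators", sum(rs$event[has_init]), sum(rs$time[has_init]),
            sum(has_init))
        add("cvd_noninitiators", sum(rs$event[!has_init]),
            sum(rs$time[!has_init]), sum(!has_init))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
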