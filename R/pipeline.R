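## Covariate order of the stage-2 linear predictor.
STAGE2_COVARS <- c("sbp", "tc", "hdl", "smoking", "diabetes", "htn")

#' Subset a cohort to a set of persons
#'
#' @param cohort A `cohort`.
#' @param ids Person ids to keep.
#' @return A `cohort` containing only those persons.
#' @export
subset_cohort <- function(cohort, ids) {
  stopifnot(inherits(cohort, "cohort"))
  out <- cohort
  for (tab in c("persons", "measurements", "statin", "conditions", "truth")) {
    if (!is.null(out[[tab]]) && nrow(out[[tab]])) {
      out[[tab]] <- out[[tab]][out[[tab]]$id %in% ids, , drop = FALSE]
      rownames(out[[tab]]) <- NULL
    }
  }
  out
}

#' Run the full landmark modelling pipeline
#'
#' Simulates (or takes) a cohort; splits persons 2:1 into derivation and
#' validation portions; freezes sex-specific standardization constants on
#' the derivation portion; and then, for every landmark age and sex,
#' fits stage 1 (multivariate mixed model and BLUPs), the constrained
#' statin-naive Weibull model on follow-up split at initiation, and the
#' standard model ignoring initiation.  Validation persons receive
#' statin-naive and standard 10-year risk predictions from their own
#' BLUPs, and their follow-up times are transformed to counterfactual
#' statin-naive times with the derivation shape of the same landmark age
#' and sex.  The default landmark grid (ages 40-85, both sexes) yields 92
#' models per model kind.
#'
#' A model cell that cannot be fitted (e.g. an empty risk set or no
#' events) is recorded as a flagged placeholder carrying the error
#' message, never dropped silently.  The run is deterministic given the
#' configuration seed.
#'
#' @param config A [generator_config()]; ignored when `cohort` is given
#'   except for its seed.
#' @param cohort Optional pre-built `cohort` (e.g. from [read_cohort()]).
#' @param landmark_ages,sexes Landmark grid.
#' @param horizon Prediction horizon in years.
#' @param hr Constrained statin hazard ratio.
#' @param lookback Stage-1 measurement lookback in years.
#' @param derivation_frac Fraction of persons allocated to derivation.
#' @param compute_metrics Also compute validation performance metrics
#'   (per-sex stacked Brier/C for both models; NRI/IDI at `metric_ages`)
#'   and impact measures (NNS/NNT per landmark, standardized
#'   threshold-exceedance proportions)?
#' @param metric_ages Landmark ages for the reclassification measures.
#' @param bootstrap_reps Bootstrap replicates for metric uncertainty.
#' @param std_pop Standard population for the weighted proportions.
#' @param out_dir Optional directory; predictions, hazard-ratio tables
#'   and a run manifest are written as delimited text.
#' @param verbose Print progress?
#' @return List with `fits_naive`, `fits_standard`, `stage1` (named by
#'   `"<sex>_<age>"`), `predictions` (validation data frame with columns
#'   id, landmark_age, sex, p_naive, p_standard, time, event, statin_time,
#'   time_cf), `metrics`, `impact`, `manifest`.
#' @export
run_pipeline <- function(config = generator_config(), cohort = NULL,
                         landmark_ages = 40:85,
                         sexes = c("male", "female"), horizon = 10,
                         hr = 0.75, lookback = 10, derivation_frac = 2 / 3,
                         compute_metrics = FALSE,
                         metric_ages = c(40, 50, 60, 70),
                         bootstrap_reps = 200,
                         std_pop = standard_population(),
                         out_dir = NULL, verbose = FALSE) {
  if (is.null(cohort)) cohort <- generate_cohort(config)
  seed <- if (!is.null(cohort$config)) cohort$config$seed else config$seed
  set.seed(seed + 7919L)
  ids <- cohort$persons$id
  deriv_ids <- sort(sample(ids, size = round(derivation_frac * length(ids))))
  deriv <- subset_cohort(cohort, deriv_ids)
  valid <- subset_cohort(cohort, setdiff(ids, deriv_ids))
  std <- standardization_constants(deriv)

  fits_naive <- fits_standard <- stage1 <- list()
  pred_rows <- list()
  failed_fit <- function(msg, kind, L, sex)
    structure(list(converged = FALSE, error = conditionMessage(msg),
                   statin = kind, landmark_age = L, sex = sex),
              class = "failed_fit")
  for (sex in sexes) {
    for (L in landmark_ages) {
      key <- paste0(sex, "_", L)
      if (verbose) message("landmark ", key)
      rs_d <- build_risk_set(deriv, L, sex, horizon, lookback)
      s1 <- tryCatch(fit_multivariate_mixed(rs_d, standardization = std),
                     error = function(e) failed_fit(e, "stage1", L, sex))
      stage1[[key]] <- s1
      fit_n <- fit_s <- NULL
      if (!inherits(s1, "failed_fit")) {
        bl_d <- predict_blups(s1, rs_d$measurements, ids = rs_d$data$id)
        df_d <- cbind(rs_d$data, as.data.frame(bl_d)[STAGE2_COVARS[1:4]])
        df_d$diabetes <- rs_d$data$diabetes
        df_d$htn <- rs_d$data$htn
        fit_n <- tryCatch(
          fit_weibull_ph(split_at_statin(df_d, hr), covars = STAGE2_COVARS,
                         statin = "constrained", hr = hr,
                         landmark_age = L, sex = sex),
          error = function(e) failed_fit(e, "constrained", L, sex))
        unsplit <- data.frame(start = 0, stop = df_d$time,
                              event = df_d$event)
        unsplit[STAGE2_COVARS] <- df_d[STAGE2_COVARS]
        fit_s <- tryCatch(
          fit_weibull_ph(unsplit, covars = STAGE2_COVARS,
                         statin = "ignored", landmark_age = L, sex = sex),
          error = function(e) failed_fit(e, "standard", L, sex))
      } else {
        fit_n <- failed_fit(simpleError("stage 1 failed"), "constrained",
                            L, sex)
        fit_s <- failed_fit(simpleError("stage 1 failed"), "standard",
                            L, sex)
      }
      fits_naive[[key]] <- fit_n
      fits_standard[[key]] <- fit_s

      ok <- inherits(fit_n, "weibull_fit") && inherits(fit_s, "weibull_fit")
      if (ok) {
        rs_v <- build_risk_set(valid, L, sex, horizon, lookback)
        if (nrow(rs_v$data)) {
          bl_v <- predict_blups(s1, rs_v$measurements, ids = rs_v$data$id)
          df_v <- cbind(rs_v$data, as.data.frame(bl_v)[STAGE2_COVARS[1:4]])
          df_v$diabetes <- rs_v$data$diabetes
          df_v$htn <- rs_v$data$htn
          cf <- counterfactual_times(df_v$time, df_v$event,
                                     df_v$statin_time,
                                     shape = fit_n$shape, hr = hr)
          pred_rows[[key]] <- data.frame(
            id = df_v$id, landmark_age = L, sex = sex,
            p_naive = predict_risk(fit_n, df_v, horizon),
            p_standard = predict_risk(fit_s, df_v, horizon),
            time = df_v$time, event = df_v$event,
            statin_time = df_v$statin_time, time_cf = cf$time)
        }
      }
    }
  }
  predictions <- if (length(pred_rows)) do.call(rbind, pred_rows)
  else data.frame()
  rownames(predictions) <- NULL

  metrics <- impact <- NULL
  if (compute_metrics && nrow(predictions)) {
    metrics <- pipeline_metrics(predictions, horizon, metric_ages,
                                bootstrap_reps, seed)
    impact <- pipeline_impact(predictions, horizon, std_pop)
  }

  manifest <- list(seed = seed, n_persons = nrow(cohort$persons),
                   n_derivation = length(deriv_ids),
                   n_validation = nrow(valid$persons),
                   landmark_ages = landmark_ages, sexes = sexes,
                   horizon = horizon, hr = hr,
                   n_fits_naive = length(fits_naive),
                   n_fits_standard = length(fits_standard),
                   n_converged_naive = sum(vapply(
                     fits_naive, function(f)
                       inherits(f, "weibull_fit") && f$converged,
                     logical(1))),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  out <- list(fits_naive = fits_naive, fits_standard = fits_standard,
              stage1 = stage1, predictions = predictions,
              metrics = metrics, impact = impact, manifest = manifest)
  class(out) <- "landmark_pipeline"
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

pipeline_metrics <- function(pred, horizon, metric_ages, bootstrap_reps,
                             seed) {
  clamp <- function(p) pmin(pmax(p, 1e-10), 1 - 1e-10)
  stacked <- lapply(c(male = "male", female = "female"), function(s) {
    ps <- pred[pred$sex == s, ]
    if (!nrow(ps)) return(NULL)
    list(standard = stack_and_summarize(
      data.frame(id = ps$id, p = clamp(ps$p_standard), time = ps$time,
                 event = ps$event),
      horizon, bootstrap_reps, seed + 11L),
      naive = stack_and_summarize(
        data.frame(id = ps$id, p = clamp(ps$p_naive), time = ps$time_cf,
                   event = ps$event),
        horizon, bootstrap_reps, seed + 12L))
  })
  reclass <- list()
  for (s in unique(pred$sex)) {
    for (L in intersect(metric_ages, unique(pred$landmark_age))) {
      ps <- pred[pred$sex == s & pred$landmark_age == L, ]
      if (nrow(ps) < 10) next
      key <- paste0(s, "_", L)
      reclass[[key]] <- list(
        categorical = categorical_nri(ps$p_standard, ps$p_naive,
                                      ps$time_cf, ps$event, horizon),
        continuous = continuous_nri(ps$p_standard, ps$p_naive, ps$time_cf,
                                    ps$event, horizon,
                                    bootstrap_reps = bootstrap_reps,
                                    seed = seed + 13L),
        idi = idi(ps$p_standard, ps$p_naive, ps$time_cf, ps$event, horizon))
    }
  }
  list(stacked = stacked, reclassification = reclass)
}

pipeline_impact <- function(pred, horizon, std_pop) {
  rows <- list()
  for (s in unique(pred$sex)) {
    for (L in sort(unique(pred$landmark_age))) {
      ps <- pred[pred$sex == s & pred$landmark_age == L, ]
      if (!nrow(ps)) next
      for (model in c("standard", "naive")) {
        p <- if (model == "standard") ps$p_standard else ps$p_naive
        tm <- if (model == "standard") ps$time else ps$time_cf
        nn <- nns_nnt(p, tm, ps$event, horizon = horizon)
        rows[[length(rows) + 1L]] <- data.frame(
          sex = s, landmark_age = L, model = model, nns = nn$nns,
          nnt = nn$nnt, n = nn$n, n_high = nn$n_high)
      }
    }
  }
  props <- lapply(c(standard = "p_standard", naive = "p_naive"),
                  function(col) {
                    threshold_proportions(
                      data.frame(landmark_age = pred$landmark_age,
                                 sex = pred$sex, p = pred[[col]]),
                      std_pop = std_pop)
                  })
  list(nns_nnt = do.call(rbind, rows), threshold_proportions = props)
}

write_pipeline <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(run$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  hrs <- hazard_ratio_table(run)
  utils::write.csv(hrs, file.path(out_dir, "hazard_ratios.csv"),
                   row.names = FALSE)
  if (!is.null(run$impact))
    utils::write.csv(run$impact$nns_nnt, file.path(out_dir, "nns_nnt.csv"),
                     row.names = FALSE)
  yaml::write_yaml(run$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' Per-SD hazard-ratio table across landmark models
#'
#' Extracts `exp(beta)` for the continuous risk factors (already per
#' standard deviation, since stage 2 uses standardized BLUPs) from every
#' converged landmark fit, for both model kinds.
#'
#' @param run A [run_pipeline()] result.
#' @return Data frame with columns sex, landmark_age, model, factor,
#'   hazard_ratio, conf.low, conf.high.
#' @export
hazard_ratio_table <- function(run) {
  rows <- list()
  for (model in c("naive", "standard")) {
    fits <- if (model == "naive") run$fits_naive else run$fits_standard
    for (f in fits) {
      if (!inherits(f, "weibull_fit")) next
      se <- sqrt(diag(f$vcov))
      for (v in intersect(c("sbp", "tc", "hdl"), names(f$beta))) {
        rows[[length(rows) + 1L]] <- data.frame(
          sex = f$sex, landmark_age = f$landmark_age, model = model,
          factor = v, hazard_ratio = exp(f$beta[[v]]),
          conf.low = exp(f$beta[[v]] - 1.96 * se[[v]]),
          conf.high = exp(f$beta[[v]] + 1.96 * se[[v]]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.landmark_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("Landmark pipeline run: %d persons (%d derivation / %d validation)\n",
              m$n_persons, m$n_derivation, m$n_validation))
  cat(sprintf("  %d statin-naive and %d standard landmark fits (%d naive converged)\n",
              m$n_fits_naive, m$n_fits_standard, m$n_converged_naive))
  cat(sprintf("  %d validation predictions\n",
              nrow(x$predictions)))
  invisible(x)
}
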