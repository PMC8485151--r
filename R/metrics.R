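## Product-limit probability of an event by `horizon`.
km_event_prob <- function(time, event, horizon) {
  if (!length(time)) return(NA_real_)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(sf, times = horizon, extend = TRUE)$surv
  1 - s
}

restrict_horizon <- function(time, event, horizon) {
  keep <- (event == 1 & time <= horizon) | time >= horizon
  d <- as.integer(event == 1 & time <= horizon)
  list(keep = keep, d10 = d)
}

#' Calibration of predicted 10-year risks
#'
#' Groups persons into tenths of predicted risk and compares the group
#' mean predicted risk with the nonparametric (product-limit) observed
#' risk at the horizon.  The calibration slope is the coefficient of the
#' prognostic index on the log cumulative-hazard scale,
#' \eqn{\log(-\log(1-p))}, in a refitted one-covariate Weibull model:
#' perfectly calibrated predictions give slope 1, and predictions whose
#' log-hazard spread is doubled give slope 0.5.
#'
#' @param p Predicted risks in (0, 1).
#' @param time,event Follow-up times and event indicators (observed, or
#'   counterfactual statin-naive times when evaluating the statin-naive
#'   model).
#' @param horizon Horizon in years.
#' @param n_groups Number of risk groups (default 10).
#' @return List with `table` (group, n, events, mean_predicted, observed,
#'   plus a `no_events` flag per group), `slope`, `slope_se`, and
#'   `flagged` (`TRUE` when the slope is undefined, e.g. constant
#'   predictions).
#' @export
calibration <- function(p, time, event, horizon = 10, n_groups = 10) {
  stopifnot(all(p > 0 & p < 1), all(time > 0))
  brk <- unique(stats::quantile(p, probs = seq(0, 1, length.out =
                                                 n_groups + 1)))
  grp <- if (length(brk) > 1)
    cut(p, breaks = brk, include.lowest = TRUE, labels = FALSE)
  else rep(1L, length(p))
  tab <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sel <- grp == g
    data.frame(group = g, n = sum(sel), events = sum(event[sel]),
               mean_predicted = mean(p[sel]),
               observed = if (any(event[sel] == 1))
                 km_event_prob(time[sel], event[sel], horizon) else 0,
               no_events = !any(event[sel] == 1))
  }))
  if (stats::sd(p) == 0 || length(unique(p)) < 2) {
    warning("constant predictions: calibration slope undefined")
    return(list(table = tab, slope = NA_real_, slope_se = NA_real_,
                flagged = TRUE))
  }
  pi <- log(-log(1 - p))
  ep <- data.frame(start = 0, stop = time, event = event, pi = pi)
  fit <- fit_weibull_ph(ep, covars = "pi", statin = "ignored")
  list(table = tab, slope = unname(fit$beta["pi"]),
       slope_se = unname(sqrt(diag(fit$vcov))["pi"]),
       flagged = !fit$converged)
}

#' Restricted Brier score at the horizon
#'
#' Mean squared difference between the within-horizon event indicator and
#' the predicted risk, computed only over persons with known 10-year
#' status: at least `horizon` years of follow-up, or an event within the
#' horizon.  Persons censored early are excluded rather than reweighted.
#'
#' @inheritParams calibration
#' @return The score (in \[0, 1\]), with attribute `"n"` (restricted
#'   subset size).
#' @export
brier_10yr <- function(p, time, event, horizon = 10) {
  r <- restrict_horizon(time, event, horizon)
  if (!any(r$keep))
    stop("no persons with known status at the horizon", call. = FALSE)
  out <- mean((r$d10[r$keep] - p[r$keep])^2)
  attr(out, "n") <- sum(r$keep)
  out
}

#' Harrell's C index with bootstrap uncertainty
#'
#' Concordance over usable pairs (the member with the shorter follow-up
#' time had the event); tied predictions count 1/2.  The standard error
#' and percentile confidence interval come from resampling persons; when
#' `cluster` is supplied (e.g. person ids in a stacked data set with one
#' row per landmark age), all rows of a resampled person move together.
#'
#' @inheritParams calibration
#' @param bootstrap_reps Number of bootstrap resamples (0 skips the
#'   bootstrap).
#' @param seed Seed for the bootstrap (required when `bootstrap_reps >
#'   0`).
#' @param cluster Optional person identifiers for clustered resampling.
#' @return List with `c_index`, `se`, `conf.low`, `conf.high`, `n`.
#' @export
harrell_c <- function(p, time, event, bootstrap_reps = 200, seed = NULL,
                      cluster = NULL) {
  cidx <- function(p, time, event) {
    fit <- survival::concordance(survival::Surv(time, event) ~ p,
                                 reverse = TRUE)
    if (is.na(fit$concordance))
      stop("no usable pairs for the C index", call. = FALSE)
    unname(fit$concordance)
  }
  est <- cidx(p, time, event)
  se <- cl <- ch <- NA_real_
  if (bootstrap_reps > 0) {
    if (is.null(seed)) stop("a bootstrap seed is required", call. = FALSE)
    set.seed(seed)
    if (is.null(cluster)) cluster <- seq_along(p)
    ids <- unique(cluster)
    rows_by <- split(seq_along(p), factor(cluster, levels = ids))
    reps <- vapply(seq_len(bootstrap_reps), function(b) {
      take <- unlist(rows_by[sample.int(length(ids), replace = TRUE)],
                     use.names = FALSE)
      tryCatch(cidx(p[take], time[take], event[take]),
               error = function(e) NA_real_)
    }, numeric(1))
    reps <- reps[is.finite(reps)]
    se <- stats::sd(reps)
    qs <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
    cl <- qs[1]; ch <- qs[2]
  }
  list(c_index = est, se = se, conf.low = cl, conf.high = ch,
       n = length(p))
}

#' Royston's D statistic and explained variation
#'
#' The prognostic index (log cumulative-hazard scale,
#' \eqn{\log(-\log(1-p))}, or `pi` directly) is replaced by standard
#' normal order statistics (rankits, ties averaged) scaled by
#' \eqn{\sqrt{8/\pi}}; D is the fitted coefficient of that score in a
#' one-covariate Weibull model, interpretable as the log hazard ratio
#' between the prognostic halves of the population.  Explained variation
#' is \eqn{R^2_D = (D^2/\sigma^2) / (D^2/\sigma^2 + \pi^2/6)} with
#' \eqn{\sigma^2 = 8/\pi}.
#'
#' @inheritParams calibration
#' @param pi Optional prognostic index overriding `p`.
#' @return List with `D`, `se`, `r_squared_d`, `n`.
#' @export
royston_d <- function(p = NULL, time, event, horizon = 10, pi = NULL) {
  if (is.null(pi)) {
    stopifnot(!is.null(p), all(p > 0 & p < 1))
    pi <- log(-log(1 - p))
  }
  if (length(unique(pi)) < 2)
    stop("need at least 2 distinct predictions for the D statistic",
         call. = FALSE)
  n <- length(pi)
  rk <- rank(pi, ties.method = "average")
  z <- stats::qnorm((rk - 3 / 8) / (n + 1 / 4)) / sqrt(8 / base::pi)
  ep <- data.frame(start = 0, stop = time, event = event, z = z)
  fit <- fit_weibull_ph(ep, covars = "z", statin = "ignored")
  D <- unname(fit$beta["z"])
  s2 <- 8 / base::pi
  list(D = D, se = unname(sqrt(diag(fit$vcov))["z"]),
       r_squared_d = (D^2 / s2) / (D^2 / s2 + base::pi^2 / 6), n = n)
}

nri_component_ci <- function(up, down, n) {
  est <- (up - down) / n
  se <- sqrt((up / n + down / n - est^2) / n)
  c(estimate = est, se = se, conf.low = est - 1.96 * se,
    conf.high = est + 1.96 * se)
}

#' Categorical net reclassification improvement at a risk threshold
#'
#' Compares the old (standard) and new (statin-naive) classifications at
#' the treatment threshold (default 10%), using only persons whose
#' horizon status is known (event within the horizon, or event-free at
#' the horizon; when the new model is the statin-naive one, the
#' counterfactual times define that status).  The event component is
#' (up-moves − down-moves)/n among events, the nonevent component
#' (down − up)/n among nonevents, and the overall NRI their sum.
#' Confidence intervals use the asymptotic normal formula.
#'
#' @param p_old,p_new Predicted risks from the old and new model.
#' @inheritParams calibration
#' @param threshold Risk threshold; the high-risk category is
#'   `p >= threshold` (closed at the threshold).
#' @return Data frame with rows `event`, `nonevent`, `overall`:
#'   estimate, se, conf.low, conf.high, n, flagged.
#' @export
categorical_nri <- function(p_old, p_new, time, event, horizon = 10,
                            threshold = 0.10) {
  r <- restrict_horizon(time, event, horizon)
  keep <- r$keep
  d <- r$d10[keep] == 1
  up <- (p_old[keep] < threshold & p_new[keep] >= threshold)
  down <- (p_old[keep] >= threshold & p_new[keep] < threshold)
  categorical_nri_from_counts(
    events = c(up = sum(up & d), down = sum(down & d), n = sum(d)),
    nonevents = c(up = sum(up & !d), down = sum(down & !d), n = sum(!d)))
}

#' @rdname categorical_nri
#' @param events,nonevents Either named vectors `c(up, down, n)` of
#'   reclassification counts, or 2x2 count matrices with rows = old
#'   category (low, high) and columns = new category (low, high), as
#'   printed in reclassification tables.
#' @export
categorical_nri_from_counts <- function(events, nonevents) {
  as_counts <- function(m) {
    if (is.matrix(m)) c(up = m[1, 2], down = m[2, 1], n = sum(m))
    else m[c("up", "down", "n")]
  }
  e <- as_counts(events); ne <- as_counts(nonevents)
  flag_e <- e[["n"]] == 0; flag_ne <- ne[["n"]] == 0
  ev <- if (flag_e) rep(NA_real_, 4) else
    nri_component_ci(e[["up"]], e[["down"]], e[["n"]])
  nv <- if (flag_ne) rep(NA_real_, 4) else
    nri_component_ci(ne[["down"]], ne[["up"]], ne[["n"]])
  ov_est <- ev[1] + nv[1]
  ov_se <- sqrt(ev[2]^2 + nv[2]^2)
  out <- data.frame(
    component = c("event", "nonevent", "overall"),
    estimate = c(ev[1], nv[1], ov_est),
    se = c(ev[2], nv[2], ov_se),
    conf.low = c(ev[3], nv[3], ov_est - 1.96 * ov_se),
    conf.high = c(ev[4], nv[4], ov_est + 1.96 * ov_se),
    n = c(e[["n"]], ne[["n"]], e[["n"]] + ne[["n"]]),
    flagged = c(flag_e, flag_ne, flag_e || flag_ne))
  rownames(out) <- out$component
  out
}

#' Continuous (prospective-form) net reclassification improvement
#'
#' Category-free NRI for survival data: persons are partitioned into
#' up-movers (`p_new > p_old`) and down-movers, event probabilities at
#' the horizon within each mover group are estimated by the product-limit
#' method, and the components are assembled from the implied
#' P(up | event) and P(up | nonevent), so censored persons contribute and
#' no restriction to complete follow-up is needed.  With no censoring the
#' estimate reduces to the classical counting form.  Confidence intervals
#' are by person bootstrap.
#'
#' @inheritParams categorical_nri
#' @param bootstrap_reps,seed Bootstrap settings for the confidence
#'   intervals (`bootstrap_reps = 0` skips them).
#' @return Data frame with rows `event`, `nonevent`, `overall` and a
#'   `flagged` column (set when there are no movers).
#' @export
continuous_nri <- function(p_old, p_new, time, event, horizon = 10,
                           bootstrap_reps = 200, seed = NULL) {
  point <- function(idx) {
    up <- p_new[idx] > p_old[idx]
    dn <- p_new[idx] < p_old[idx]
    n_up <- sum(up); n_dn <- sum(dn)
    if (n_up + n_dn == 0) return(c(0, 0, 0))
    q_up <- if (n_up) km_event_prob(time[idx][up], event[idx][up], horizon)
    else 0
    q_dn <- if (n_dn) km_event_prob(time[idx][dn], event[idx][dn], horizon)
    else 0
    ev_mass <- n_up * q_up + n_dn * q_dn
    ne_mass <- n_up * (1 - q_up) + n_dn * (1 - q_dn)
    p_up_ev <- if (ev_mass > 0) n_up * q_up / ev_mass else 0.5
    p_up_ne <- if (ne_mass > 0) n_up * (1 - q_up) / ne_mass else 0.5
    e_comp <- p_up_ev - (1 - p_up_ev)
    ne_comp <- (1 - p_up_ne) - p_up_ne
    c(e_comp, ne_comp, e_comp + ne_comp)
  }
  est <- point(seq_along(p_old))
  flag <- all(p_new == p_old)
  ci <- matrix(NA_real_, 3, 2)
  se <- rep(NA_real_, 3)
  if (bootstrap_reps > 0) {
    if (is.null(seed)) stop("a bootstrap seed is required", call. = FALSE)
    set.seed(seed)
    reps <- t(vapply(seq_len(bootstrap_reps), function(b)
      point(sample.int(length(p_old), replace = TRUE)), numeric(3)))
    se <- apply(reps, 2, stats::sd)
    ci <- t(apply(reps, 2, stats::quantile, probs = c(0.025, 0.975),
                  names = FALSE))
  }
  out <- data.frame(component = c("event", "nonevent", "overall"),
                    estimate = est, se = se,
                    conf.low = ci[, 1], conf.high = ci[, 2],
                    flagged = flag)
  rownames(out) <- out$component
  out
}

#' Integrated discrimination improvement
#'
#' Difference in discrimination slopes between the new and old model:
#' (mean new − old predicted risk among events) − (mean new − old among
#' nonevents), over persons with known status at the horizon (as for the
#' categorical NRI).  The standard error is the usual two-sample formula
#' on the per-person prediction differences.
#'
#' @inheritParams categorical_nri
#' @return List with `idi`, `se`, `conf.low`, `conf.high`, `n_events`,
#'   `n_nonevents`, `flagged`.
#' @export
idi <- function(p_old, p_new, time, event, horizon = 10) {
  r <- restrict_horizon(time, event, horizon)
  keep <- r$keep
  d <- r$d10[keep] == 1
  dp <- p_new[keep] - p_old[keep]
  flag <- !any(d) || all(d)
  if (flag)
    return(list(idi = NA_real_, se = NA_real_, conf.low = NA_real_,
                conf.high = NA_real_, n_events = sum(d),
                n_nonevents = sum(!d), flagged = TRUE))
  est <- mean(dp[d]) - mean(dp[!d])
  se <- sqrt(stats::var(dp[d]) / sum(d) + stats::var(dp[!d]) / sum(!d))
  list(idi = est, se = se, conf.low = est - 1.96 * se,
       conf.high = est + 1.96 * se, n_events = sum(d),
       n_nonevents = sum(!d), flagged = FALSE)
}

#' Stack landmark evaluation sets and summarize overall performance
#'
#' Concatenates per-landmark evaluation data (a person may appear at
#' several landmark ages) and computes the overall restricted Brier score
#' and Harrell's C on the stacked rows.  Bootstrap uncertainty resamples
#' persons, keeping all landmark rows of a person together.
#'
#' @param eval_sets A list of data frames, each with columns id, p, time,
#'   event (and optionally landmark_age), or a single pre-stacked data
#'   frame.
#' @inheritParams harrell_c
#' @param horizon Horizon in years.
#' @return List with `brier`, `brier_n`, `c_index` (as from
#'   [harrell_c()]), and `n_rows`.
#' @export
stack_and_summarize <- function(eval_sets, horizon = 10,
                                bootstrap_reps = 200, seed = NULL) {
  stacked <- if (is.data.frame(eval_sets)) eval_sets
  else do.call(rbind, eval_sets)
  stopifnot(all(c("id", "p", "time", "event") %in% names(stacked)))
  br <- brier_10yr(stacked$p, stacked$time, stacked$event, horizon)
  cc <- harrell_c(stacked$p, stacked$time, stacked$event,
                  bootstrap_reps = bootstrap_reps, seed = seed,
                  cluster = stacked$id)
  list(brier = as.numeric(br), brier_n = attr(br, "n"), c_index = cc,
       n_rows = nrow(stacked))
}
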