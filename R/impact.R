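#' Number needed to screen / treat to prevent one event
#'
#' Under the allocation rule "treat everyone with predicted risk at or
#' above the threshold" and a treatment relative risk reduction
#' `treatment_rr`, the expected number of events prevented is
#' `treatment_rr x (observed event risk at the horizon among the
#' high-risk group, product-limit estimate) x n_high`.  NNS is the total
#' number screened per event prevented and NNT the number treated per
#' event prevented, so NNT <= NNS always.
#'
#' @param p Predicted risks.
#' @param time,event Observed (or counterfactual) follow-up and event
#'   indicators.
#' @param threshold High-risk threshold; the high-risk set is
#'   `p >= threshold`.
#' @param treatment_rr Relative risk reduction from treatment (default
#'   0.25, the trial value).
#' @param horizon Horizon in years.
#' @return List with `nns`, `nnt`, `n`, `n_high`, `observed_risk_high`,
#'   `events_prevented`.  Both numbers are `Inf` when nobody exceeds the
#'   threshold, the observed high-risk risk is zero, or
#'   `treatment_rr = 0`.
#' @export
nns_nnt <- function(p, time, event, threshold = 0.10, treatment_rr = 0.25,
                    horizon = 10) {
  stopifnot(length(p) > 0)
  high <- p >= threshold
  n_high <- sum(high)
  risk_high <- if (n_high) km_event_prob(time[high], event[high], horizon)
  else 0
  prevented <- treatment_rr * risk_high * n_high
  list(nns = if (prevented > 0) length(p) / prevented else Inf,
       nnt = if (prevented > 0) n_high / prevented else Inf,
       n = length(p), n_high = n_high, observed_risk_high = risk_high,
       events_prevented = prevented)
}

#' Bundled synthetic standard population
#'
#' Reads an external age- and sex-specific standard population (CSV with
#' columns sex, age, weight).  The bundled default is a synthetic uniform
#' population over ages 40-85 — a stand-in for a real national standard
#' population table, which is not shipped with the package.
#'
#' @param path CSV path; `NULL` for the bundled synthetic uniform table.
#' @return Data frame with columns sex, age, weight.
#' @export
standard_population <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "standard_population_synthetic.csv",
                        package = "statinnaive", mustWork = TRUE)
  pop <- utils::read.csv(path)
  stopifnot(all(c("sex", "age", "weight") %in% names(pop)),
            all(pop$weight >= 0))
  pop
}

#' Population-weighted proportions exceeding treatment thresholds
#'
#' For each sex and threshold, computes the proportion of persons at each
#' landmark age whose predicted risk is at or above the threshold, then
#' combines ages as a weighted mean with external standard-population
#' weights: \eqn{\sum_a w_a \hat{\pi}_a / \sum_a w_a}.
#'
#' @param predictions Data frame with columns landmark_age, sex, p.
#' @param thresholds Numeric thresholds (default 5% to 30%).
#' @param std_pop Standard population from [standard_population()]; must
#'   cover every landmark age present.
#' @return Data frame with columns sex, threshold, proportion
#'   (nonincreasing in the threshold within sex).
#' @export
threshold_proportions <- function(predictions,
                                  thresholds = seq(0.05, 0.30, by = 0.05),
                                  std_pop = standard_population()) {
  stopifnot(all(c("landmark_age", "sex", "p") %in% names(predictions)))
  out <- list()
  for (s in unique(predictions$sex)) {
    ps <- predictions[predictions$sex == s, ]
    ages <- sort(unique(ps$landmark_age))
    w <- std_pop$weight[std_pop$sex == s][match(ages,
                                                std_pop$age[std_pop$sex == s])]
    if (anyNA(w))
      stop("standard population is missing ages: ",
           paste(ages[is.na(w)], collapse = ", "), " for sex ", s,
           call. = FALSE)
    for (th in thresholds) {
      prop_a <- vapply(ages, function(a)
        mean(ps$p[ps$landmark_age == a] >= th), numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        sex = s, threshold = th,
        proportion = sum(w * prop_a) / sum(w))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
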