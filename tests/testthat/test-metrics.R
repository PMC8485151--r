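## Simple uncensored/censored evaluation data from a one-covariate
## Weibull model, with the true 10-year risk attached.
sim_eval <- function(n, nu = 1.2, alpha = -3.2, beta = 0.8, cens = 15,
                     seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  rate <- exp(alpha + beta * x)
  t_ev <- (rexp(n) / rate)^(1 / nu)
  c_t <- runif(n, 0.5, cens)
  data.frame(x = x,
             time = pmin(t_ev, c_t),
             event = as.integer(t_ev <= c_t),
             p = 1 - exp(-rate * 10^nu))
}

test_that("the restricted Brier score matches hand arithmetic", {
  ## perfect binary predictions (approached within the open interval)
  eps <- 1e-8
  expect_equal(as.numeric(brier_10yr(c(1 - eps, eps), time = c(4, 12),
                                     event = c(1, 0))), 0,
               tolerance = 1e-7)
  expect_equal(as.numeric(brier_10yr(rep(0.5, 4), time = c(1, 2, 11, 12),
                                     event = c(1, 1, 0, 0))), 0.25)
  b <- brier_10yr(c(0.8, 0.1, 0.4, 0.3), time = c(3, 11, 7, 10),
                  event = c(1, 0, 1, 0))
  expect_equal(as.numeric(b), 0.125)
  ## persons censored before the horizon are excluded
  b2 <- brier_10yr(c(0.8, 0.1, 0.4, 0.3, 0.9), time = c(3, 11, 7, 10, 5),
                   event = c(1, 0, 1, 0, 0))
  expect_equal(as.numeric(b2), 0.125)
  expect_equal(attr(b2, "n"), 4L)
  expect_error(brier_10yr(0.5, time = 3, event = 0), "no persons")
})

test_that("Harrell's C equals brute-force pair counting", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 25
    time <- sample(1:40, n)  # distinct times
    event <- rbinom(n, 1, 0.6)
    p <- round(runif(n), 1)  # ties in predictions
    cc <- harrell_c(p, time, event, bootstrap_reps = 0)
    expect_equal(cc$c_index, brute_force_c(p, time, event),
                 tolerance = 1e-12)
  }
  ## all predictions equal: pure ties
  expect_equal(harrell_c(rep(0.3, 10), time = 1:10,
                         event = rep(1, 10), bootstrap_reps = 0)$c_index,
               0.5)
  ## predictions that reverse the event-time order on fully observed data
  time <- c(5, 2, 9, 1, 7)
  expect_equal(harrell_c(max(time) - time, time, rep(1, 5),
                         bootstrap_reps = 0)$c_index, 1)
  ## bootstrap is deterministic given the seed
  ev <- sim_eval(150, seed = 3)
  c1 <- harrell_c(ev$p, ev$time, ev$event, bootstrap_reps = 50, seed = 5)
  c2 <- harrell_c(ev$p, ev$time, ev$event, bootstrap_reps = 50, seed = 5)
  expect_identical(c1, c2)
  expect_true(c1$conf.low < c1$c_index & c1$c_index < c1$conf.high)
})

test_that("Royston's D agrees with an independent AFT-based computation", {
  ev <- sim_eval(800, seed = 11)
  d <- royston_d(ev$p, ev$time, ev$event)
  ## independent route: the same rankit score fitted with survreg; the
  ## Weibull PH coefficient is -gamma/scale of the AFT parameterization
  n <- nrow(ev)
  pi <- log(-log(1 - ev$p))
  z <- qnorm((rank(pi, ties.method = "average") - 3 / 8) / (n + 1 / 4)) /
    sqrt(8 / base::pi)
  sr <- survival::survreg(survival::Surv(time, event) ~ z, data
                          = cbind(ev, z = z), dist = "weibull")
  d_ref <- -coef(sr)[["z"]] / sr$scale
  expect_equal(d$D, d_ref, tolerance = 1e-4)
  expect_gt(d$D, 0)
  ## R-squared follows the closed form, and D = 0 gives 0
  s2 <- 8 / base::pi
  expect_equal(d$r_squared_d, (d$D^2 / s2) / (d$D^2 / s2 + base::pi^2 / 6),
               tolerance = 1e-12)
  ## permuting predictions against outcomes gives D compatible with 0
  set.seed(2)
  dperm <- royston_d(sample(ev$p), ev$time, ev$event)
  expect_lt(abs(dperm$D), 3 * dperm$se)
  expect_error(royston_d(rep(0.2, 5), time = 1:5, event = rep(1, 5)),
               "distinct")
})

test_that("categorical NRI counts reclassification at the threshold", {
  ## identical classifications
  out0 <- categorical_nri(c(0.05, 0.2), c(0.06, 0.3), time = c(12, 3),
                          event = c(0, 1))
  expect_equal(out0$estimate, c(0, 0, 0))
  ## count and matrix interfaces agree
  m_ev <- matrix(c(764, 0, 55, 480), 2, 2)
  m_ne <- matrix(c(1368, 0, 59, 390), 2, 2)
  a <- categorical_nri_from_counts(m_ev, m_ne)
  b <- categorical_nri_from_counts(c(up = 55, down = 0, n = 1299),
                                   c(up = 59, down = 0, n = 1817))
  expect_equal(a$estimate, b$estimate, tolerance = 1e-12)
  ## the restricted subset drops persons censored before the horizon
  out1 <- categorical_nri(c(0.05, 0.05, 0.05), c(0.15, 0.15, 0.15),
                          time = c(3, 12, 6), event = c(1, 0, 0))
  expect_equal(out1["event", "n"], 1)
  expect_equal(out1["nonevent", "n"], 1)
  expect_equal(out1["overall", "estimate"], 1 - 1)
})

test_that("continuous NRI reduces to direct counting without censoring", {
  set.seed(6)
  n <- 300
  p_old <- runif(n, 0.01, 0.6)
  p_new <- pmin(pmax(p_old + rnorm(n, 0, 0.05), 0.005), 0.95)
  d <- rbinom(n, 1, p_old)
  time <- ifelse(d == 1, runif(n, 0.1, 9.9), 10.5)  # no early censoring
  out <- continuous_nri(p_old, p_new, time, d, bootstrap_reps = 0)
  oracle <- counting_continuous_nri(p_old, p_new, d)
  expect_equal(out$estimate, unname(oracle), tolerance = 1e-10)

  ## all-up degenerate case: event +1, nonevent -1, overall 0
  up <- continuous_nri(p_old, p_old + 0.01, time, d, bootstrap_reps = 0)
  expect_equal(up$estimate, c(1, -1, 0))
  ## no movers: zero with flag
  none <- continuous_nri(p_old, p_old, time, d, bootstrap_reps = 0)
  expect_equal(none$estimate, c(0, 0, 0))
  expect_true(all(none$flagged))
})

test_that("a genuinely informative covariate raises the continuous NRI", {
  set.seed(8)
  n <- 1500
  x1 <- rnorm(n); x2 <- rnorm(n)
  lp <- -2.5 + 0.6 * x1 + 0.8 * x2
  d <- rbinom(n, 1, plogis(lp))
  time <- ifelse(d == 1, runif(n, 0.5, 9.5), 10.5)
  p_old <- plogis(-2.5 + 0.6 * x1)
  p_new <- plogis(lp)
  out <- continuous_nri(p_old, p_new, time, d, bootstrap_reps = 0)
  expect_gt(out["overall", "estimate"], 0)
})

test_that("IDI matches hand arithmetic and is antisymmetric", {
  p_old <- c(0.2, 0.2, 0.2, 0.2)
  p_new <- c(0.3, 0.3, 0.1, 0.1)
  time <- c(2, 5, 11, 12); event <- c(1, 1, 0, 0)
  out <- idi(p_old, p_new, time, event)
  expect_equal(out$idi, 0.2, tolerance = 1e-12)
  rev <- idi(p_new, p_old, time, event)
  expect_equal(rev$idi, -0.2, tolerance = 1e-12)
  same <- idi(p_old, p_old, time, event)
  expect_equal(same$idi, 0)
})

test_that("true risks self-calibrate and log-hazard doubling halves the
           slope", {
  ev <- sim_eval(4000, seed = 13)
  cal <- calibration(ev$p, ev$time, ev$event)
  expect_false(cal$flagged)
  expect_lt(abs(cal$slope - 1), 2 * cal$slope_se)
  ## groups sit near the diagonal
  good <- cal$table$n >= 50 & !cal$table$no_events
  expect_lt(max(abs(cal$table$mean_predicted[good] -
                      cal$table$observed[good])), 0.08)
  ## doubling the prognostic index on the log cumulative-hazard scale
  ## (a lower-risk setting keeps the doubled risks inside (0, 1))
  ev2 <- sim_eval(4000, alpha = -4.5, beta = 0.6, seed = 14)
  p2 <- 1 - exp(-exp(2 * log(-log(1 - ev2$p))))
  cal2 <- calibration(p2, ev2$time, ev2$event)
  expect_lt(abs(cal2$slope - 0.5), 2 * cal2$slope_se)
  ## constant predictions: flagged, slope undefined
  expect_warning(cal0 <- calibration(rep(0.2, 100), time = rexp(100) + 0.1,
                                     event = rbinom(100, 1, 0.5)),
                 "constant")
  expect_true(cal0$flagged)
  expect_true(is.na(cal0$slope))
})

test_that("stacked metrics agree with direct computation and pair counting",
          {
  ev <- sim_eval(120, seed = 17)
  ev$id <- seq_len(nrow(ev))
  one <- stack_and_summarize(list(ev[c("id", "p", "time", "event")]),
                             bootstrap_reps = 0)
  expect_equal(one$brier, as.numeric(brier_10yr(ev$p, ev$time, ev$event)))
  expect_equal(one$c_index$c_index,
               harrell_c(ev$p, ev$time, ev$event,
                         bootstrap_reps = 0)$c_index)
  ## duplicating the whole set leaves pair proportions unchanged
  twice <- stack_and_summarize(list(ev[c("id", "p", "time", "event")],
                                    ev[c("id", "p", "time", "event")]),
                               bootstrap_reps = 0)
  expect_equal(twice$c_index$c_index, one$c_index$c_index,
               tolerance = 1e-12)
  ## cross-age pairs are usable: brute force on a small concatenation
  a <- sim_eval(14, seed = 18); a$id <- 1:14
  b <- sim_eval(14, seed = 19); b$id <- 8:21
  stk <- rbind(a[c("id", "p", "time", "event")],
               b[c("id", "p", "time", "event")])
  res <- stack_and_summarize(stk, bootstrap_reps = 0)
  expect_equal(res$c_index$c_index,
               brute_force_c(stk$p, stk$time, stk$event), tolerance = 1e-12)
})
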