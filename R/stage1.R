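#' Plausibility bounds for risk-factor measurements
#'
#' Biologically implausible values are removed before any modelling:
#' SBP outside 60-250 mm Hg, total cholesterol outside 1.75-20 mmol/L,
#' HDL cholesterol outside 0.3-3.1 mmol/L.  Bounds are closed (a value
#' exactly at the bound is retained).  Smoking is a 0/1 indicator and has
#' no plausibility bounds.
#'
#' @param sbp,tc,hdl Length-2 numeric `c(lower, upper)` bounds.
#' @return A named list of bounds of class `cleaning_rules`.
#' @export
cleaning_rules <- function(sbp = c(60, 250), tc = c(1.75, 20),
                           hdl = c(0.3, 3.1)) {
  rules <- list(sbp = sbp, tc = tc, hdl = hdl)
  for (nm in names(rules)) {
    if (!nm %in% RISK_FACTORS)
      stop("unknown risk factor in cleaning rules: ", nm, call. = FALSE)
    if (!(rules[[nm]][1] < rules[[nm]][2]))
      stop("lower bound must be below upper bound for ", nm, call. = FALSE)
  }
  structure(rules, class = "cleaning_rules")
}

#' Remove biologically implausible measurement values
#'
#' Sets out-of-range values to missing, value-wise (a person's other
#' measurements are untouched), and drops the resulting missing rows.
#'
#' @param measurements Data frame with columns id, factor, age, value.
#' @param rules A [cleaning_rules()].
#' @return The cleaned measurements, with attribute `"n_removed"` giving
#'   the number of values set to missing.
#' @export
clean_measurements <- function(measurements, rules = cleaning_rules()) {
  stopifnot(is.data.frame(measurements))
  if (!nrow(measurements)) {
    attr(measurements, "n_removed") <- 0L
    return(measurements)
  }
  if (!all(measurements$factor %in% RISK_FACTORS))
    stop("unknown risk factor in measurements: ",
         paste(setdiff(unique(measurements$factor), RISK_FACTORS),
               collapse = ", "), call. = FALSE)
  bad <- rep(FALSE, nrow(measurements))
  for (nm in names(rules)) {
    sel <- measurements$factor == nm
    bad[sel] <- !is.na(measurements$value[sel]) &
      (measurements$value[sel] < rules[[nm]][1] |
         measurements$value[sel] > rules[[nm]][2])
  }
  bad <- bad | is.na(measurements$value)
  out <- measurements[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(bad)
  out
}

#' Sex-specific standardization constants
#'
#' Mean and standard deviation of the first post-entry measurement of SBP,
#' total cholesterol and HDL cholesterol per sex, computed after cleaning.
#' Computed once on the derivation portion of a cohort and frozen into
#' every stage-1 fit so validation uses identical scaling.
#'
#' @param cohort A `cohort`.
#' @param rules A [cleaning_rules()].
#' @return Named list (`male`, `female`), each with named vectors `mean`
#'   and `sd` over sbp, tc, hdl.
#' @export
standardization_constants <- function(cohort, rules = cleaning_rules()) {
  stopifnot(inherits(cohort, "cohort"))
  meas <- clean_measurements(cohort$measurements, rules)
  p <- cohort$persons
  i <- match(meas$id, p$id)
  meas <- meas[meas$age >= p$entry_age[i] & meas$factor %in% names(rules), ,
               drop = FALSE]
  meas <- meas[order(meas$id, meas$factor, meas$age), ]
  first <- meas[!duplicated(meas[c("id", "factor")]), ]
  first$sex <- p$sex[match(first$id, p$id)]
  out <- lapply(c(male = "male", female = "female"), function(s) {
    m <- sapply(names(rules), function(f) {
      v <- first$value[first$sex == s & first$factor == f]
      c(mean = mean(v), sd = stats::sd(v))
    })
    if (anyNA(m["sd", ]) || any(m["sd", ] <= 0, na.rm = TRUE))
      m["sd", !is.finite(m["sd", ]) | m["sd", ] <= 0] <- 1
    if (anyNA(m["mean", ])) m["mean", is.na(m["mean", ])] <- 0
    list(mean = m["mean", ], sd = m["sd", ])
  })
  out
}

standardize_measurements <- function(measurements, constants, sex) {
  cst <- constants[[sex]]
  for (f in names(cst$mean)) {
    sel <- measurements$factor == f
    measurements$value[sel] <- (measurements$value[sel] - cst$mean[[f]]) /
      cst$sd[[f]]
  }
  measurements
}

#' Construct a stage-1 mixed-model fit from components
#'
#' Low-level constructor for the object returned by
#' [fit_multivariate_mixed()]; useful for building fits with known
#' parameters (e.g. to verify BLUP formulas against closed forms).
#'
#' @param fixed 4x2 matrix of per-factor fixed intercepts and linear age
#'   slopes (rows sbp, tc, hdl, smoking; intercepts at the landmark age,
#'   slopes per year of `age - landmark_age`), on the standardized scale
#'   for sbp/tc/hdl and the probability scale for smoking.
#' @param Sigma_u 4x4 random-intercept covariance (same scales).
#' @param resid_var Named per-factor residual variances.
#' @param standardization As returned by [standardization_constants()].
#' @param sex,landmark_age,lookback Metadata carried into prediction.
#' @param converged,flags,logLik,iterations Diagnostics.
#' @return An object of class `mixed_fit`.
#' @export
mixed_fit <- function(fixed, Sigma_u, resid_var, standardization,
                      sex = "male", landmark_age = NA_real_, lookback = 10,
                      converged = TRUE, flags = character(),
                      logLik = NA_real_, iterations = NA_integer_) {
  fixed <- as.matrix(fixed)
  dimnames(fixed) <- list(RISK_FACTORS, c("intercept", "slope"))
  Sigma_u <- as.matrix(Sigma_u)
  dimnames(Sigma_u) <- list(RISK_FACTORS, RISK_FACTORS)
  resid_var <- stats::setNames(as.numeric(resid_var), RISK_FACTORS)
  stopifnot(all(resid_var > 0),
            max(abs(Sigma_u - t(Sigma_u))) < 1e-6,
            min(eigen(Sigma_u, symmetric = TRUE,
                      only.values = TRUE)$values) > -1e-8)
  structure(list(fixed = fixed, Sigma_u = Sigma_u, resid_var = resid_var,
                 standardization = standardization, sex = sex,
                 landmark_age = landmark_age, lookback = lookback,
                 converged = converged, flags = flags, logLik = logLik,
                 iterations = iterations),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("Stage-1 multivariate mixed fit (landmark age %s, %s)%s\n",
              format(x$landmark_age), x$sex,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  print(cbind(x$fixed, resid_var = x$resid_var, u_var = diag(x$Sigma_u)))
  invisible(x)
}

#' Fit the landmark-specific multivariate linear mixed model
#'
#' Stage 1 of the landmark framework: the four risk factors (standardized
#' SBP/TC/HDL, smoking on its 0/1 values) measured in the lookback window
#' before the landmark age are modelled jointly with per-factor fixed
#' intercepts and linear trends in `age - landmark_age`, correlated
#' person-level random intercepts (unstructured 4x4 covariance) and
#' factor-specific residual variances.  Smoking is treated as a linear
#' outcome so that its shrunken prediction is a continuous propensity.
#'
#' The marginal likelihood is maximized with [nlme::lme()] (`pdSymm`
#' random structure, `varIdent` residuals, REML).  If the joint fit fails,
#' the model falls back to independent univariate random-intercept fits
#' (diagonal covariance) and flags the fit; a factor with no observations
#' in the window gets a diffuse variance and the population trend, also
#' flagged.  Non-convergence is reported via `converged`/`flags`, never
#' silently.
#'
#' @param risk_set A [build_risk_set()] result.
#' @param standardization Output of [standardization_constants()]; when
#'   `NULL`, constants are computed from the risk set's own measurement
#'   window (suitable only for derivation data).
#' @param rules A [cleaning_rules()].
#' @param min_factor_obs Minimum observations (and persons) for a factor
#'   to enter the joint fit.
#' @return A [mixed_fit()].
#' @export
fit_multivariate_mixed <- function(risk_set, standardization = NULL,
                                   rules = cleaning_rules(),
                                   min_factor_obs = 5L) {
  stopifnot(inherits(risk_set, "landmark_risk_set"))
  meas <- clean_measurements(risk_set$measurements, rules)
  flags <- character()
  if (is.null(standardization)) {
    standardization <- local_standardization(meas, risk_set$sex)
    flags <- c(flags, "standardization computed from risk-set measurements")
  }
  meas <- standardize_measurements(meas, standardization, risk_set$sex)
  dat <- data.frame(id = meas$id, fac = meas$factor,
                    age_c = meas$age - risk_set$landmark_age,
                    value = meas$value)

  n_obs <- table(factor(dat$fac, levels = RISK_FACTORS))
  n_per <- sapply(RISK_FACTORS, function(f)
    length(unique(dat$id[dat$fac == f])))
  usable <- RISK_FACTORS[n_obs >= min_factor_obs & n_per >= 2]
  if (length(unique(dat$id[dat$fac %in% usable])) < 2 || !length(usable))
    stop("need at least 2 persons with measurements to fit stage 1",
         call. = FALSE)

  fixed <- matrix(0, 4, 2, dimnames = list(RISK_FACTORS,
                                           c("intercept", "slope")))
  fixed["smoking", "intercept"] <- mean(dat$value[dat$fac == "smoking"])
  if (!is.finite(fixed["smoking", "intercept"]))
    fixed["smoking", "intercept"] <- 0.25
  Sigma <- diag(c(1, 1, 1, 0.25^2))
  dimnames(Sigma) <- list(RISK_FACTORS, RISK_FACTORS)
  resid_var <- c(sbp = 1, tc = 1, hdl = 1, smoking = 0.25^2)
  if (length(setdiff(RISK_FACTORS, usable)))
    flags <- c(flags, paste("no usable observations; diffuse default for:",
                            paste(setdiff(RISK_FACTORS, usable),
                                  collapse = ", ")))

  sub <- dat[dat$fac %in% usable, , drop = FALSE]
  sub$fac <- factor(sub$fac, levels = usable)
  fit <- joint_lme(sub)
  converged <- !is.null(fit)
  logLik_val <- NA_real_
  iterations <- NA_integer_
  if (converged) {
    est <- extract_lme(fit, usable)
    logLik_val <- as.numeric(stats::logLik(fit))
    iterations <- tryCatch(fit$numIter, error = function(e) NA_integer_)
    if (is.null(iterations)) iterations <- NA_integer_
  } else {
    flags <- c(flags, "joint multivariate fit failed; univariate fallback")
    est <- univariate_fallback(sub, usable)
    converged <- est$converged
  }
  fixed[usable, ] <- est$fixed
  Sigma[usable, usable] <- nearest_psd(est$Sigma_u)
  resid_var[usable] <- pmax(est$resid_var, 1e-10)

  mixed_fit(fixed, Sigma, resid_var, standardization,
            sex = risk_set$sex, landmark_age = risk_set$landmark_age,
            lookback = risk_set$lookback, converged = converged,
            flags = flags, logLik = logLik_val, iterations = iterations)
}

local_standardization <- function(meas, sex) {
  cst <- sapply(RISK_FACTORS[1:3], function(f) {
    v <- meas$value[meas$factor == f]
    s <- stats::sd(v)
    c(mean = if (length(v)) mean(v) else 0,
      sd = if (length(v) > 1 && is.finite(s) && s > 0) s else 1)
  })
  one <- list(mean = cst["mean", ], sd = cst["sd", ])
  list(male = one, female = one)
}

joint_lme <- function(sub) {
  ctrl <- nlme::lmeControl(maxIter = 500, msMaxIter = 500, niterEM = 50,
                           msMaxEval = 2000, tolerance = 1e-8,
                           returnObject = FALSE)
  tryCatch(
    if (nlevels(sub$fac) > 1)
      nlme::lme(value ~ 0 + fac + fac:age_c,
                random = list(id = nlme::pdSymm(~ 0 + fac)),
                weights = nlme::varIdent(form = ~ 1 | fac),
                data = sub, method = "REML", control = ctrl)
    else
      nlme::lme(value ~ age_c, random = ~ 1 | id, data = sub,
                method = "REML", control = ctrl),
    error = function(e) NULL)
}

extract_lme <- function(fit, usable) {
  k <- length(usable)
  fe <- nlme::fixef(fit)
  if (k > 1) {
    ic <- fe[paste0("fac", usable)]
    sl <- fe[paste0("fac", usable, ":age_c")]
    Sg <- as.matrix(nlme::getVarCov(fit))
    ord <- match(paste0("fac", usable), rownames(Sg))
    Sg <- Sg[ord, ord, drop = FALSE]
    vs <- fit$modelStruct$varStruct
    w <- stats::coef(vs, unconstrained = FALSE, allCoef = TRUE)
    rv <- (fit$sigma * w[usable])^2
  } else {
    ic <- fe[["(Intercept)"]]
    sl <- fe[["age_c"]]
    Sg <- matrix(as.numeric(nlme::getVarCov(fit)), 1, 1)
    rv <- fit$sigma^2
  }
  list(fixed = cbind(intercept = unname(ic), slope = unname(sl)),
       Sigma_u = unname(Sg), resid_var = unname(rv))
}

univariate_fallback <- function(sub, usable) {
  k <- length(usable)
  fixed <- matrix(0, k, 2)
  Sg <- matrix(0, k, k)
  rv <- numeric(k)
  ok <- TRUE
  for (j in seq_len(k)) {
    dj <- sub[sub$fac == usable[j], ]
    fj <- tryCatch(
      nlme::lme(value ~ age_c, random = ~ 1 | id, data = dj,
                method = "REML",
                control = nlme::lmeControl(returnObject = TRUE)),
      error = function(e) NULL)
    if (!is.null(fj)) {
      fe <- nlme::fixef(fj)
      fixed[j, ] <- c(fe[["(Intercept)"]], fe[["age_c"]])
      Sg[j, j] <- as.numeric(nlme::getVarCov(fj))
      rv[j] <- fj$sigma^2
    } else {
      ok <- FALSE
      lm_j <- stats::lm(value ~ age_c, data = dj)
      fixed[j, ] <- stats::coef(lm_j)
      v <- stats::var(dj$value)
      Sg[j, j] <- v / 2
      rv[j] <- v / 2
    }
  }
  list(fixed = fixed, Sigma_u = Sg, resid_var = pmax(rv, 1e-10),
       converged = ok)
}

nearest_psd <- function(S) {
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) >= 0) return(S)
  e$vectors %*% diag(pmax(e$values, 1e-12), nrow(S)) %*% t(e$vectors)
}

#' Best linear unbiased predictions of risk-factor values at the landmark
#'
#' Returns the shrunken "error-free" value of each of the four risk
#' factors at the landmark age for each requested person: the conditional
#' expectation of the person's random intercepts given whatever subset of
#' measurements they have (generalized-least-squares formula with the
#' fitted covariance), added to the fixed trend evaluated at the landmark
#' age.  Defined for any missingness pattern; a person with no
#' measurements receives the population fixed-trend value.  With
#' correlated random intercepts, observing one factor shifts the
#' predictions of the others in the direction implied by the covariance.
#'
#' @param fit A [mixed_fit()].
#' @param measurements Raw measurements (id, factor, age, value); cleaned
#'   and standardized internally with the fit's frozen constants.
#' @param ids Person ids to predict for (default: all ids appearing in
#'   `measurements`).  Include ids without measurements to obtain their
#'   population predictions.
#' @param rules A [cleaning_rules()].
#' @param se Also return per-person conditional covariance matrices of the
#'   random effects?
#' @return A numeric matrix (rows = persons, columns sbp, tc, hdl,
#'   smoking; SBP/TC/HDL on the standardized scale, smoking on the
#'   probability scale, clipped to \[0, 1\] with the number of clipped
#'   values in attribute `"n_clipped"`).  With `se = TRUE`, a list
#'   `list(pred, cond_var)`.
#' @export
predict_blups <- function(fit, measurements, ids = NULL,
                          rules = cleaning_rules(), se = FALSE) {
  stopifnot(inherits(fit, "mixed_fit"))
  meas <- clean_measurements(measurements, rules)
  if (nrow(meas) && !is.na(fit$landmark_age)) {
    keep <- meas$age >= fit$landmark_age - fit$lookback &
      meas$age <= fit$landmark_age
    meas <- meas[keep, , drop = FALSE]
  }
  meas <- standardize_measurements(meas, fit$standardization, fit$sex)
  if (is.null(ids)) ids <- unique(meas$id)
  Sig <- fit$Sigma_u
  pred <- matrix(rep(fit$fixed[, "intercept"], each = length(ids)),
                 length(ids), 4, dimnames = list(ids, RISK_FACTORS))
  cond_var <- if (se) rep(list(Sig), length(ids)) else NULL
  if (se) names(cond_var) <- ids
  L0 <- if (is.na(fit$landmark_age)) 0 else fit$landmark_age
  by_id <- split(seq_len(nrow(meas)), factor(meas$id, levels = ids))
  for (i in seq_along(ids)) {
    rows <- by_id[[i]]
    if (!length(rows)) next
    fidx <- match(meas$factor[rows], RISK_FACTORS)
    age_c <- meas$age[rows] - L0
    m_fix <- fit$fixed[fidx, "intercept"] + fit$fixed[fidx, "slope"] * age_c
    y <- meas$value[rows]
    Z <- matrix(0, length(rows), 4)
    Z[cbind(seq_along(rows), fidx)] <- 1
    V <- Z %*% Sig %*% t(Z) + diag(fit$resid_var[fidx],
                                   nrow = length(rows))
    SZt <- Sig %*% t(Z)
    u_hat <- drop(SZt %*% solve(V, y - m_fix))
    pred[i, ] <- fit$fixed[, "intercept"] + u_hat
    if (se) cond_var[[i]] <- Sig - SZt %*% solve(V, t(SZt))
  }
  clip <- pred[, "smoking"] < 0 | pred[, "smoking"] > 1
  pred[, "smoking"] <- pmin(pmax(pred[, "smoking"], 0), 1)
  attr(pred, "n_clipped") <- sum(clip)
  if (se) list(pred = pred, cond_var = cond_var) else pred
}
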