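#' L2-penalized Cox proportional hazards fit
#'
#' Maximizes the Breslow partial likelihood penalized by
#' `c/2 * ||beta||^2` (no L1 term, no intercept): the penalty constant `c`
#' multiplies the squared coefficient norm added to the negative partial
#' log-likelihood. Fitting is delegated to `survival::coxph()` with a
#' `ridge()` penalty term at `theta = c`.
#'
#' @param data data frame holding the columns below.
#' @param time_col,event_col names of the follow-up time (months, > 0) and
#'   0/1 event indicator columns.
#' @param covariates character vector of covariate column names; none may
#'   be constant.
#' @param l2_c L2 penalty constant (default 0.3).
#' @param ties tie handling, `"breslow"` (default) or `"efron"`.
#' @return object of class `cox_l2_fit`: named `coefficients`, per-subject
#'   `linear_predictor` (`X %*% beta`, no centring), training
#'   `cindex_train`, the Breslow baseline cumulative hazard table
#'   `baseline`, and the underlying `coxph` fit.
#' @export
fit_cox <- function(data, time_col = "time_months", event_col = "event",
                    covariates, l2_c = 0.3, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  assert_that(all(c(time_col, event_col, covariates) %in% names(data)),
              "missing columns in data")
  time <- data[[time_col]]
  event <- data[[event_col]]
  assert_that(all(time > 0), "times must be positive")
  assert_that(all(event %in% c(0, 1)), "event must be 0/1")
  if (sum(event) < 1) {
    stop("no events in the data; cannot fit a Cox model", call. = FALSE)
  }
  X <- as.matrix(data[, covariates, drop = FALSE])
  csd <- apply(X, 2, sd)
  if (any(csd == 0)) {
    stop("constant covariate(s): ",
         paste(covariates[csd == 0], collapse = ", "), call. = FALSE)
  }
  assert_that(is.numeric(l2_c) && l2_c >= 0, "l2_c must be non-negative")

  # short internal covariate names: coxph's penalty-term bookkeeping
  # mismatches its own term labels when the deparsed ridge() term gets long
  Xs <- X
  short <- sprintf("v%d", seq_along(covariates))
  colnames(Xs) <- short
  df <- data.frame(.time = time, .event = event, Xs)
  # the ridge() special must appear unqualified for coxph's penalty
  # detection; resolve it from the survival namespace via the formula env
  env <- new.env(parent = asNamespace("survival"))
  rhs <- paste0("ridge(", paste(short, collapse = ", "),
                ", theta = ", l2_c, ", scale = FALSE)")
  fml <- stats::as.formula(paste0("Surv(.time, .event) ~ ", rhs), env = env)
  fit <- survival::coxph(fml, data = df, ties = ties,
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 100))
  if (!is.null(fit$fail)) {
    stop("Cox fit did not converge: ", fit$fail, call. = FALSE)
  }
  beta <- stats::setNames(as.numeric(stats::coef(fit)), covariates)
  lp <- as.numeric(X %*% beta)
  res <- list(
    coefficients = beta,
    l2_c = l2_c,
    ties = ties,
    covariates = covariates,
    linear_predictor = lp,
    cindex_train = concordance_index(lp, time, event),
    baseline = breslow_baseline(lp, time, event),
    coxph = fit
  )
  class(res) <- "cox_l2_fit"
  res
}

#' @export
print.cox_l2_fit <- function(x, ...) {
  cat("L2-penalized Cox fit (c =", x$l2_c, ", ties =", x$ties, ")\n")
  print(round(x$coefficients, 4))
  cat("training C-index:", round(x$cindex_train, 4), "\n")
  invisible(x)
}

# Breslow estimate of the baseline cumulative hazard at the uncentred
# linear predictor: H0(t) = sum_{event times s <= t} d(s) / sum_{R(s)} exp(lp)
breslow_baseline <- function(lp, time, event) {
  et <- sort(unique(time[event == 1]))
  h <- vapply(et, function(s) {
    sum(time == s & event == 1) / sum(exp(lp[time >= s]))
  }, numeric(1))
  data.frame(time = et, cumhaz = cumsum(h))
}

#' Predicted survival probability from a `cox_l2_fit`
#'
#' `S(t | x) = exp(-H0(t) * exp(x' beta))` with the Breslow baseline.
#'
#' @param fit a [fit_cox()] result.
#' @param lp linear predictor value(s) `x' beta`.
#' @param horizon time(s) in months.
#' @return matrix of survival probabilities, `length(lp)` rows x
#'   `length(horizon)` columns.
#' @export
cox_survival_at <- function(fit, lp, horizon) {
  H0 <- vapply(horizon, function(t) {
    rows <- fit$baseline$time <= t
    if (!any(rows)) 0 else max(fit$baseline$cumhaz[rows])
  }, numeric(1))
  outer(exp(lp), H0, function(r, h) exp(-h * r))
}

#' Concordance index (C-index)
#'
#' Fraction of comparable pairs whose predicted risk ordering agrees with
#' the observed survival ordering. A pair `(i, j)` is comparable iff
#' `time_i < time_j` and subject `i` had the event; concordant iff
#' `risk_i > risk_j`, with risk ties counting one half. Pairs with equal
#' follow-up time are not comparable.
#'
#' @param risk numeric risk scores (higher = shorter expected survival).
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @return C-index in `[0, 1]`; `NA` with attribute `undefined = TRUE` if
#'   no pair is comparable.
#' @export
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  assert_that(length(time) == n && length(event) == n, "length mismatch")
  dt <- outer(time, time, "<")                   # time_i < time_j
  comparable <- dt & matrix(event == 1, n, n)    # and i had the event
  if (!any(comparable)) {
    return(structure(NA_real_, undefined = TRUE))
  }
  dr <- outer(risk, risk, "-")
  score <- (dr > 0) + 0.5 * (dr == 0)
  sum(score[comparable]) / sum(comparable)
}

#' Log-rank test
#'
#' Standard log-rank chi-square over two or more groups (delegated to
#' `survival::survdiff`). The degenerate case where every subject has the
#' event at one shared time has zero variance and zero observed-minus-
#' expected in every group; it is reported as statistic 0, p = 1.
#'
#' @param groups group membership vector (>= 2 non-empty groups).
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(groups, time, event) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  assert_that(nlevels(groups) >= 2, "need at least two non-empty groups")
  df <- nlevels(groups) - 1
  sd_fit <- tryCatch(
    survival::survdiff(survival::Surv(time, event) ~ groups),
    error = function(e) NULL
  )
  stat <- if (is.null(sd_fit)) NA_real_ else sd_fit$chisq
  if (!is.finite(stat)) {
    # zero-variance corner (e.g. every subject dies at one shared time):
    # fall back on the observed-minus-expected tally computed directly
    oe <- vapply(levels(groups), function(g) {
      sum(vapply(unique(time[event == 1]), function(s) {
        at_risk <- time >= s
        d <- sum(time == s & event == 1)
        sum(time == s & event == 1 & groups == g) -
          d * sum(at_risk & groups == g) / sum(at_risk)
      }, numeric(1)))
    }, numeric(1))
    if (all(abs(oe) < 1e-10)) {
      stat <- 0
    } else {
      stop("log-rank statistic undefined for these data", call. = FALSE)
    }
  }
  list(statistic = as.numeric(stat), df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE))
}

#' Kaplan-Meier stratification at the log-rank-optimal percentile
#'
#' Dichotomizes the risk score at every candidate percentile threshold,
#' computes the two-group log-rank test, and returns the threshold with the
#' smallest p-value on the supplied (training) data. The chosen threshold
#' is an absolute risk value: freeze it and apply it unchanged to the test
#' cohort with [stratify_risk()]. When risk is unrelated to survival this
#' minimum-p selection is exploratory (an optimized p-value); interpret the
#' training p accordingly.
#'
#' @param risk numeric risk scores.
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @param percentiles candidate percentile grid (default 20 to 80 by 5).
#' @param min_group minimum subjects per group for a candidate (default 2).
#' @return list with `percentile`, `threshold`, `groups` (factor
#'   `low`/`high`), `logrank_p`, and the full `candidates` table.
#' @export
km_stratify <- function(risk, time, event, percentiles = seq(20, 80, 5),
                        min_group = 2) {
  cand <- lapply(percentiles, function(p) {
    thr <- as.numeric(quantile(risk, p / 100))
    grp <- stratify_risk(risk, thr)
    if (min(table(grp)) < min_group || nlevels(droplevels(grp)) < 2) {
      return(data.frame(percentile = p, threshold = thr, p_value = NA_real_))
    }
    lr <- logrank_test(grp, time, event)
    data.frame(percentile = p, threshold = thr, p_value = lr$p_value)
  })
  cand <- do.call(rbind, cand)
  if (all(is.na(cand$p_value))) {
    stop("no candidate percentile yields two usable groups", call. = FALSE)
  }
  best <- which.min(cand$p_value)  # ties resolve to the lowest percentile
  thr <- cand$threshold[best]
  list(
    percentile = cand$percentile[best],
    threshold = thr,
    groups = stratify_risk(risk, thr),
    logrank_p = cand$p_value[best],
    candidates = cand
  )
}

#' Apply a frozen risk threshold
#'
#' @param risk numeric risk scores.
#' @param threshold absolute threshold from [km_stratify()].
#' @return factor with levels `low` (`risk <= threshold`) and `high`.
#' @export
stratify_risk <- function(risk, threshold) {
  factor(ifelse(risk > threshold, "high", "low"), levels = c("low", "high"))
}

#' Build a nomogram from a Cox fit
#'
#' Maps each covariate linearly to a 0-100 point scale: the covariate whose
#' coefficient-times-range product is largest spans the full scale, and
#' each covariate's reference (0-point) end is the end of its range with
#' the lowest hazard, so points always accumulate towards higher risk.
#' Total points convert back to the linear predictor and then to predicted
#' survival probabilities at the configured horizons through the Breslow
#' baseline.
#'
#' @param fit a [fit_cox()] result.
#' @param covariate_ranges named list of `c(min, max)` per covariate
#'   (finite, non-degenerate).
#' @param horizons survival-probability horizons in months
#'   (default `c(36, 60)`).
#' @return object of class `nomogram_spec`.
#' @export
build_nomogram <- function(fit, covariate_ranges, horizons = c(36, 60)) {
  assert_that(inherits(fit, "cox_l2_fit"), "fit must come from fit_cox()")
  covs <- fit$covariates
  assert_that(all(covs %in% names(covariate_ranges)),
              "covariate_ranges must cover every model covariate")
  ranges <- covariate_ranges[covs]
  assert_that(all(vapply(ranges, function(r) {
    length(r) == 2 && all(is.finite(r)) && diff(r) > 0
  }, logical(1))), "each range must be finite c(min, max) with min < max")
  beta <- fit$coefficients
  span <- vapply(covs, function(v) abs(beta[[v]] * diff(ranges[[v]])),
                 numeric(1))
  M <- max(span)
  if (M <= 0) stop("all point scales are zero; nomogram undefined", call. = FALSE)
  scales <- lapply(covs, function(v) {
    r <- ranges[[v]]
    ref <- if (beta[[v]] >= 0) r[1] else r[2]  # lowest-hazard end scores 0
    list(ref = ref, points_per_unit = 100 * abs(beta[[v]]) / M, range = r)
  })
  names(scales) <- covs
  lp_ref <- sum(vapply(covs, function(v) beta[[v]] * scales[[v]]$ref,
                       numeric(1)))
  spec <- list(
    covariates = covs,
    coefficients = beta,
    scales = scales,
    max_scale = M,
    lp_ref = lp_ref,
    horizons = horizons,
    baseline = fit$baseline
  )
  class(spec) <- "nomogram_spec"
  spec
}

#' Evaluate a nomogram for new patients
#'
#' @param spec a [build_nomogram()] spec.
#' @param newdata data frame with the nomogram covariates.
#' @return data frame with per-covariate points, `total_points`,
#'   `linear_predictor`, and `surv_prob_<horizon>m` columns.
#' @export
predict_nomogram <- function(spec, newdata) {
  assert_that(inherits(spec, "nomogram_spec"), "spec must be a nomogram_spec")
  assert_that(all(spec$covariates %in% names(newdata)),
              "newdata must contain every nomogram covariate")
  pts <- vapply(spec$covariates, function(v) {
    sc <- spec$scales[[v]]
    abs(newdata[[v]] - sc$ref) * sc$points_per_unit
  }, numeric(nrow(newdata)))
  pts <- matrix(pts, nrow = nrow(newdata),
                dimnames = list(NULL, paste0("points_", spec$covariates)))
  total <- rowSums(pts)
  lp <- spec$lp_ref + total / 100 * spec$max_scale
  H0 <- vapply(spec$horizons, function(t) {
    rows <- spec$baseline$time <= t
    if (!any(rows)) 0 else max(spec$baseline$cumhaz[rows])
  }, numeric(1))
  sp <- outer(exp(lp), H0, function(r, h) exp(-h * r))
  colnames(sp) <- sprintf("surv_prob_%gm", spec$horizons)
  cbind(as.data.frame(pts), total_points = total, linear_predictor = lp,
        as.data.frame(sp))
}
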