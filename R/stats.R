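#' Odds ratio from a 2x2 table
#'
#' Cross-product odds ratio `ad/bc` with a Woolf (log-scale Wald) 95%
#' confidence interval. When any cell is zero, the Haldane-Anscombe
#' correction adds 0.5 to every cell before estimation.
#'
#' @param a,b,c,d Non-negative counts: `a`/`b` exposed with/without the
#'   outcome, `c`/`d` unexposed with/without. Alternatively pass a 2x2
#'   matrix as `a`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `or`, `ci_lower`, `ci_upper`, `log_or`, `se_log_or`,
#'   and `corrected` (whether the 0.5 correction was applied).
#' @examples
#' odds_ratio(20, 10, 10, 20)
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("2x2 cells must be non-negative counts", call. = FALSE)
  }
  if (sum(cells) == 0) stop("empty 2x2 table", call. = FALSE)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  log_or <- log(cells[1]) - log(cells[2]) - log(cells[3]) + log(cells[4])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(log_or),
       ci_lower = exp(log_or - z * se),
       ci_upper = exp(log_or + z * se),
       log_or = log_or, se_log_or = se, corrected = corrected)
}

#' Multivariable logistic regression with odds-ratio output
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()], up to 100 iterations) returning per-term estimates,
#' standard errors, and odds ratios with Wald 95% confidence intervals.
#' Complete separation (diverging coefficients or boundary fitted
#' probabilities) and rank-deficient designs raise errors naming the
#' offending covariate.
#'
#' @param formula Model formula; the response must be binary (logical or
#'   0/1).
#' @param data Data frame of patient covariates.
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @return A tibble with `term`, `estimate`, `std_error`, `or`, `or_lower`,
#'   `or_upper`, `p_value`.
#' @export
fit_logistic <- function(formula, data, conf_level = 0.95) {
  data <- as.data.frame(data)
  if (nrow(data) < 10) {
    stop("logistic fit needs at least 10 observations", call. = FALSE)
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  if (length(unique(y)) < 2) {
    stop("outcome is constant; logistic model is undefined", call. = FALSE)
  }
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; aliased covariate(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  se <- sqrt(diag(vcov(fit)))
  diverged <- abs(cf) > 15 & names(cf) != "(Intercept)"
  if (any(diverged)) {
    stop("separation detected for covariate(s): ",
         paste(names(cf)[diverged], collapse = ", "), call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(cf),
    estimate = unname(cf),
    std_error = unname(se),
    or = exp(unname(cf)),
    or_lower = exp(unname(cf) - z * unname(se)),
    or_upper = exp(unname(cf) + z * unname(se)),
    p_value = 2 * stats::pnorm(-abs(unname(cf) / unname(se)))
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' Survival step function for one group of right-censored times, computed
#' with [survival::survfit()]: at each event time `t_i`,
#' `S(t) = prod(1 - d_i / n_i)` over event times up to `t`; censored times
#' reduce the risk set only.
#'
#' @param time Follow-up times (months), non-negative.
#' @param event Logical or 0/1 event indicator (TRUE = event, FALSE =
#'   censored).
#' @return A `km_fit` tibble with `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (one row per distinct observed time).
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                          conf.type = "none")
  out <- tibble::tibble(
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, surv = sf$surv
  )
  class(out) <- c("km_fit", class(out))
  out
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' @param km A [km_estimate()] result.
#' @param t Times at which to evaluate `S(t)` (right-continuous step
#'   function; `S(t) = 1` before the first observed time).
#' @return Numeric vector of survival probabilities.
#' @export
km_surv <- function(km, t) {
  stopifnot(inherits(km, "km_fit"))
  vapply(t, function(ti) {
    i <- which(km$time <= ti)
    if (length(i) == 0) 1 else km$surv[max(i)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic via [survival::survdiff()]: at each event
#' time the observed minus hypergeometric-expected events in group one are
#' accumulated; the squared standardized sum is chi-square with one degree
#' of freedom. The statistic is invariant to swapping group labels.
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level grouping vector (e.g. carrier status).
#' @return A list with `chisq`, `df`, `p_value`, `observed`, `expected`
#'   (per-group event counts).
#' @export
log_rank <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2) stop("log-rank test requires exactly two groups",
                            call. = FALSE)
  if (sum(as.integer(event)) == 0) {
    stop("no events observed; log-rank statistic undefined", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ g)
  list(chisq = unname(sd$chisq), df = 1,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}
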