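#' Kaplan-Meier product-limit estimate
#'
#' Product-limit estimator of the survival function; at tied times, deaths
#' are processed before censorings (the standard convention).
#'
#' @param os_time positive times.
#' @param os_event event indicators in \{0, 1\}.
#' @return data.frame of class `km_curve` with `time` (sorted distinct
#'   observed times), `n_risk`, `n_event`, `n_censor`, `surv`.
#' @export
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$surv  # 2/3, 1/3, 0
km_estimate <- function(os_time, os_event) {
  if (length(os_time) == 0L) stop("empty survival input", call. = FALSE)
  if (!is.numeric(os_time) || any(!is.finite(os_time)) || any(os_time <= 0))
    stop("'os_time' must be positive and finite", call. = FALSE)
  if (length(os_event) != length(os_time) || !all(os_event %in% c(0, 1)))
    stop("'os_event' must be 0/1 and aligned with 'os_time'", call. = FALSE)
  fit <- survival::survfit(survival::Surv(os_time, os_event) ~ 1)
  res <- data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                    n_censor = fit$n.censor, surv = fit$surv)
  class(res) <- c("km_curve", "data.frame")
  res
}

#' Log-rank test across groups
#'
#' Observed-minus-expected chi-square statistic over the pooled event times,
#' with `groups - 1` degrees of freedom.
#'
#' @param groups group labels, >= 2 non-empty groups.
#' @param os_time,os_event survival outcome aligned with `groups`; at least
#'   one event overall.
#' @return list with `chi_square`, `df`, `p`.
#' @export
logrank_test <- function(groups, os_time, os_event) {
  .check_survival(os_time, os_event)
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (length(groups) != length(os_time))
    stop("'groups' must align with the survival data", call. = FALSE)
  if (nlevels(groups) < 2L)
    stop("log-rank test needs >= 2 groups", call. = FALSE)
  fit <- survival::survdiff(survival::Surv(os_time, os_event) ~ groups)
  df <- nlevels(groups) - 1L
  list(chi_square = fit$chisq, df = df,
       p = pchisq(fit$chisq, df = df, lower.tail = FALSE))
}

#' Restricted mean survival time from a Kaplan-Meier curve
#'
#' Area under the KM curve up to `tau` (default: the largest observed time).
#' Used to compare survival between score groups when the median is not
#' reached.
#'
#' @param km a `km_curve` from [km_estimate()].
#' @param tau upper integration limit.
#' @return a single number (same time units as the input).
#' @export
km_restricted_mean <- function(km, tau = max(km$time)) {
  if (!inherits(km, "km_curve")) stop("'km' must be a km_curve", call. = FALSE)
  times <- c(0, km$time[km$time <= tau], tau)
  surv <- c(1, km$surv[km$time <= tau])
  sum(diff(times) * surv)
}
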