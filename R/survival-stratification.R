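#' Combine morphology and immunostaining clusters into risk tiers
#'
#' Low risk when both clusters are in their low-risk arm (MC1 and IC1),
#' high risk when both are in the high-risk arm (MC2 and IC2), medium
#' risk for the two discordant combinations.
#'
#' @param mc character/factor vector of MC1/MC2 labels.
#' @param ic character/factor vector of IC1/IC2 labels.
#' @return factor of low/medium/high, ordered.
#' @examples
#' assignTier(c("MC1", "MC2", "MC2"), c("IC1", "IC1", "IC2"))
#' @export
assignTier <- function(mc, ic) {
  mc <- as.character(mc); ic <- as.character(ic)
  if (!all(mc %in% c("MC1", "MC2")) || !all(ic %in% c("IC1", "IC2")))
    stop("labels must be MC1/MC2 and IC1/IC2")
  tier <- ifelse(mc == "MC1" & ic == "IC1", "low",
          ifelse(mc == "MC2" & ic == "IC2", "high", "medium"))
  factor(tier, levels = c("low", "medium", "high"), ordered = TRUE)
}

#' Kaplan-Meier curve with Greenwood confidence bands
#'
#' Product-limit estimator per group with log-log transformed 95\%
#' confidence intervals.
#'
#' @param time positive follow-up times (years).
#' @param event 1 = event observed, 0 = censored.
#' @param group optional grouping vector (a single curve when NULL).
#' @return data.frame: group, time, n_risk, n_event, surv, lower, upper —
#'   right-continuous step values at the observed times.
#' @export
kmCurve <- function(time, event, group = NULL) {
  if (any(time <= 0)) stop("times must be positive")
  if (is.null(group)) group <- rep("all", length(time))
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           conf.type = "log-log")
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(group)[1], length(s$time))
         else sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, surv = s$surv,
             lower = s$lower, upper = s$upper)
}

#' Recurrence-free survival at a landmark time
#'
#' Reads the Kaplan-Meier curve of every group at \code{t_years} with its
#' log-log confidence interval.  Beyond the last observed time of a group
#' the last value is carried forward with a warning.
#'
#' @param time,event,group as in \code{\link{kmCurve}}.
#' @param t_years landmark time in years.
#' @return data.frame: group, rfs, lower, upper (proportions in [0, 1]).
#' @export
rfsAt <- function(time, event, group = NULL, t_years) {
  if (is.null(group)) group <- rep("all", length(time))
  if (t_years > max(time))
    warning("t beyond last observed time; carrying the last value forward")
  fit <- survival::survfit(survival::Surv(time, event) ~ group,
                           conf.type = "log-log")
  s <- summary(fit, times = t_years, extend = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(group)[1], length(s$time))
         else sub("^group=", "", as.character(s$strata))
  data.frame(group = grp, rfs = s$surv, lower = s$lower, upper = s$upper)
}

#' Log-rank test across groups
#'
#' @param time,event,group as in \code{\link{kmCurve}}; at least two
#'   groups and one event.
#' @return list: \code{chisq}, \code{df} (groups - 1), \code{p}.
#' @export
logrankTest <- function(time, event, group) {
  if (length(unique(group)) < 2)
    stop("at least two groups required")
  if (sum(event) < 1) stop("at least one event required")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1
  list(chisq = unname(fit$chisq), df = df,
       p = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards ratio between groups
#'
#' Partial-likelihood fit with Efron tie handling (default) and Wald
#' confidence intervals \eqn{\exp(\beta \pm 1.96\,SE)}.  Monotone
#' likelihood (complete separation of events) is flagged and no estimate
#' is returned for the affected contrast.
#'
#' @param time,event as in \code{\link{kmCurve}}.
#' @param group factor or character; the first level is the reference.
#' @param ties tie-handling method, \code{efron} or \code{breslow}.
#' @return data.frame with one row per non-reference level: contrast,
#'   HR, lower, upper, p, flagged (TRUE when not estimable).
#' @export
coxHR <- function(time, event, group, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  # strip orderedness so coxph uses treatment contrasts vs the first level
  group <- if (is.factor(group))
    factor(as.character(group), levels = levels(droplevels(group)))
  else factor(group)
  if (nlevels(group) < 2) stop("at least two groups required")
  if (sum(event) < 5) stop("at least five events required")
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ group, ties = ties),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  flagged <- !is.finite(beta) | !is.finite(se) | abs(beta) > 15
  out <- data.frame(
    contrast = paste(sub("^group", "", names(beta)), "vs",
                     levels(group)[1]),
    HR = exp(beta), lower = exp(beta - 1.96 * se),
    upper = exp(beta + 1.96 * se),
    p = 2 * pnorm(-abs(beta / se)), flagged = flagged,
    row.names = NULL)
  out[flagged, c("HR", "lower", "upper", "p")] <- NA_real_
  out
}
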