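# Survival machinery: Kaplan-Meier, log-rank, Aalen-Johansen cumulative
# incidence under competing risks, and cause-specific Cox regression. The
# estimators are delegated to the survival package; this module fixes the
# event-state conventions (relapse with death as competing event), the ties
# method, and the reporting shapes used throughout the pipeline.

#' Recognized outcome event states
#'
#' `relapse` and `death` (death without prior relapse, the competing event)
#' are the two causes; `censored` is administrative loss to follow-up.
#'
#' @return Character vector of event-state names, censoring first.
#' @export
event_states <- function() c("censored", "relapse", "death")

#' Validate and normalize an outcomes table
#'
#' @param data Data frame with columns `subject_id`, `time` (months,
#'   strictly positive, finite) and `event` (one of [event_states()]),
#'   plus any covariate columns.
#' @return The same data frame with `event` coerced to a factor with
#'   censoring as the first level.
#' @export
as_outcomes <- function(data) {
  need <- c("subject_id", "time", "event")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("outcomes table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(data$time)) || any(data$time <= 0)) {
    stop("outcome times must be finite and strictly positive", call. = FALSE)
  }
  ev <- as.character(data$event)
  bad <- !(ev %in% event_states())
  if (any(bad)) {
    stop("unknown event state(s): ", paste(unique(ev[bad]), collapse = ", "),
         call. = FALSE)
  }
  data$event <- factor(ev, levels = event_states())
  data
}

step_curve <- function(time, n_risk, n_event, estimate, std_err, type) {
  structure(
    data.frame(time = time, n_risk = n_risk, n_event = n_event,
               estimate = estimate, std_err = std_err),
    type = type, class = c("step_curve", "data.frame"))
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator with Greenwood pointwise standard errors.
#' At tied times events are handled before censorings, the standard
#' risk-set convention.
#'
#' @param data Outcomes table (see [as_outcomes()]).
#' @param event_def Which event states count as the event; by default both
#'   causes, giving event-free survival (use `"death"` alone for overall
#'   survival in death-only data).
#' @return A `step_curve` data frame: `time`, `n_risk`, `n_event`,
#'   `estimate` (survival probability), `std_err` (Greenwood SE of the
#'   survival probability).
#' @export
km_estimate <- function(data, event_def = c("relapse", "death")) {
  data <- as_outcomes(data)
  if (!nrow(data)) stop("empty outcomes table", call. = FALSE)
  status <- as.integer(data$event %in% event_def)
  sf <- survival::survfit(survival::Surv(data$time, status) ~ 1,
                          conf.type = "none")
  sm <- summary(sf, times = sf$time, extend = TRUE)
  step_curve(sm$time, sm$n.risk, sm$n.event, sm$surv, sm$std.err,
             type = "kaplan-meier")
}

#' Log-rank test for differences between survival curves
#'
#' Standard (unweighted) k-sample log-rank; the statistic is referred to a
#' chi-square distribution with k-1 degrees of freedom.
#'
#' @param data Outcomes table.
#' @param group Name of the grouping column in `data` (2 or more levels,
#'   each with at least one subject).
#' @param event_def Event states counting as the event.
#' @return List: `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(data, group, event_def = c("relapse", "death")) {
  data <- as_outcomes(data)
  g <- factor(data[[group]])
  if (nlevels(droplevels(g)) < 2L) {
    stop("log-rank test needs at least 2 groups", call. = FALSE)
  }
  status <- as.integer(data$event %in% event_def)
  sd <- survival::survdiff(survival::Surv(data$time, status) ~ g)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Cause-specific cumulative incidence function (CIF) treating the other
#' cause as a competing event. With no competing events the CIF equals
#' 1 - KM of the cause; at every event time the cause-specific CIFs and the
#' all-cause event-free probability sum to one.
#'
#' @param data Outcomes table.
#' @param cause The event state whose incidence is estimated
#'   (`"relapse"` by default, with `"death"` competing).
#' @return A `step_curve` data frame: `time`, `n_risk`, `n_event` (events
#'   of the cause), `estimate` (CIF), `std_err`.
#' @export
cif_estimate <- function(data, cause = "relapse") {
  data <- as_outcomes(data)
  if (!nrow(data)) stop("empty outcomes table", call. = FALSE)
  if (!cause %in% setdiff(event_states(), "censored")) {
    stop("unknown cause: ", cause, call. = FALSE)
  }
  sf <- survival::survfit(survival::Surv(data$time, data$event) ~ 1)
  sm <- summary(sf, times = sf$time, extend = TRUE)
  col <- match(cause, sm$states)
  nev <- sm$n.event
  if (is.matrix(nev)) nev <- nev[, col] else nev <- nev
  step_curve(sm$time, sm$n.risk[, 1L], nev,
             sm$pstate[, col], sm$std.err[, col],
             type = paste0("aalen-johansen:", cause))
}

#' Cause-specific Cox proportional-hazards regression
#'
#' Fits the cause-specific hazard of `cause` by treating competing events
#' as censored at their event time (the cause-specific convention), via
#' partial-likelihood maximization with Efron handling of ties by default.
#' Categorical covariates must be factors; their first level is the
#' reference. Wald 95% confidence intervals use the 1.96 normal quantile
#' and all p-values are two-sided.
#'
#' @param data Outcomes table including the covariate columns.
#' @param cause Event state modeled (`"relapse"` or `"death"`).
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return A `cox_fit` object: data frame `terms` (`term`, `coef`, `se`,
#'   `hr`, `ci_lower`, `ci_upper`, `p_value`) plus `loglik`, `ties`, `n`,
#'   `n_event`.
#' @export
cox_cause_specific <- function(data, cause = "relapse", covariates,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  data <- as_outcomes(data)
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("covariate column(s) absent: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(data[covariates])) {
    stop("covariates must be present for all subjects", call. = FALSE)
  }
  mdf <- data[c("time", covariates)]
  mdf$.status <- as.integer(data$event == cause)
  fml <- stats::reformulate(covariates,
                            response = quote(survival::Surv(time, .status)))
  fit <- survival::coxph(
    fml, data = mdf, ties = ties,
    control = survival::coxph.control(eps = 1e-10, iter.max = 100))
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    stop("Cox fit did not converge (singular or non-identifiable terms: ",
         paste(names(beta)[is.na(beta)], collapse = ", "), ")", call. = FALSE)
  }
  if (any(abs(beta) > 15)) {
    stop("monotone partial likelihood (complete separation) for: ",
         paste(names(beta)[abs(beta) > 15], collapse = ", "),
         "; penalized fitting is out of scope", call. = FALSE)
  }
  se <- sqrt(diag(fit$var))
  terms <- data.frame(
    term = names(beta), coef = unname(beta), se = se,
    hr = exp(unname(beta)),
    ci_lower = exp(unname(beta) - 1.96 * se),
    ci_upper = exp(unname(beta) + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(unname(beta) / se)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(terms = terms, loglik = unname(fit$loglik[2L]), ties = ties,
         n = fit$n, n_event = fit$nevent, cause = cause),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cause-specific Cox fit (cause: ", x$cause, ", ties: ", x$ties,
      ", n = ", x$n, ", events = ", x$n_event, ")\n", sep = "")
  print(cbind(x$terms[1L],
              round(x$terms[c("coef", "se", "hr", "ci_lower", "ci_upper")], 4),
              p_value = signif(x$terms$p_value, 3)))
  invisible(x)
}
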