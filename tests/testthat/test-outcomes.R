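mk_outcomes <- function(time, event, ...) {
  as_outcomes(data.frame(subject_id = paste0("s", seq_along(time)),
                         time = time, event = event, ...,
                         stringsAsFactors = FALSE))
}

test_that("outcome validation enforces time positivity and the event vocabulary", {
  expect_error(mk_outcomes(c(1, 0), c("relapse", "censored")), "positive")
  expect_error(mk_outcomes(1, "dead"), "unknown event state")
  oc <- mk_outcomes(c(2, 1), c("relapse", "death"))
  expect_identical(levels(oc$event), c("censored", "relapse", "death"))
})

test_that("Kaplan-Meier matches hand product-limit computation", {
  # all censored -> flat at 1
  flat <- km_estimate(mk_outcomes(c(1, 2, 3), rep("censored", 3)))
  expect_true(all(flat$estimate == 1))
  # event at 1, censor at 2, event at 3: S(1) = 2/3, then the last subject
  # at risk fails at 3 so S(3) = 0
  km <- km_estimate(mk_outcomes(c(1, 2, 3), c("relapse", "censored", "death")))
  expect_equal(km$estimate[km$time == 1], 2 / 3)
  expect_equal(km$estimate[km$time == 3], 0)
  # single subject: survival jumps from 1 to 0 at the event time
  one <- km_estimate(mk_outcomes(5, "relapse"))
  expect_equal(one$estimate, 0)
  empty <- data.frame(subject_id = character(0), time = numeric(0),
                      event = character(0))
  expect_error(km_estimate(empty), "empty")
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(31)
  time <- stats::rexp(40) + 0.01
  oc <- mk_outcomes(time, sample(c("relapse", "death"), 40, TRUE))
  km <- km_estimate(oc)
  emp <- vapply(km$time, function(t) mean(time > t), 0)
  expect_equal(km$estimate, emp, tolerance = 1e-12)
  # and matches the independent product-limit oracle under censoring
  status <- c(rep(1, 25), rep(0, 15))
  oc2 <- mk_outcomes(time, ifelse(status == 1, "relapse", "censored"))
  km2 <- km_estimate(oc2)
  orc <- oracle_km(time, status)
  expect_equal(km2$estimate[match(orc$time, km2$time)], orc$surv)
})

test_that("log-rank agrees with observed-minus-expected oracle and handles degenerate groups", {
  set.seed(7)
  n <- 30
  time <- stats::rexp(n, 0.2) + 0.01
  event <- sample(c("relapse", "censored"), n, TRUE, prob = c(0.7, 0.3))
  grp <- rep(c("a", "b"), each = n / 2)
  oc <- mk_outcomes(time, event, g = grp)
  got <- logrank_test(oc, "g")
  expect_equal(got$statistic,
               oracle_logrank(time, as.integer(event == "relapse"), grp),
               tolerance = 1e-10)
  expect_equal(got$df, 1L)
  # relabeling the groups leaves the statistic unchanged
  oc$g <- ifelse(grp == "a", "z", "y")
  expect_equal(logrank_test(oc, "g")$statistic, got$statistic)
  # identical event patterns in both groups -> statistic 0, p = 1
  oc0 <- mk_outcomes(rep(c(1, 2, 3), 2), rep(c("relapse", "censored", "relapse"), 2),
                     g = rep(c("a", "b"), 3))
  z <- logrank_test(oc0, "g")
  expect_equal(z$statistic, 0, tolerance = 1e-12)
  expect_equal(z$p_value, 1)
  expect_error(logrank_test(mk_outcomes(1:3 + 0, rep("relapse", 3),
                                        g = rep("a", 3)), "g"),
               "at least 2 groups")
})

test_that("Aalen-Johansen CIF matches hand computation and known equivalences", {
  # toy mix of 6 subjects, both causes and censoring
  time <- c(1, 2, 2.5, 3, 4, 5)
  event <- c("relapse", "death", "censored", "relapse", "death", "censored")
  oc <- mk_outcomes(time, event)
  got <- cif_estimate(oc, "relapse")
  orc <- oracle_cif(time, event, "relapse")
  expect_equal(got$estimate[match(orc$time, got$time)], orc$cif,
               tolerance = 1e-12)
  # no competing events -> CIF == 1 - KM of the cause
  oc2 <- mk_outcomes(c(1, 2, 3, 4), c("relapse", "censored", "relapse", "relapse"))
  cif2 <- cif_estimate(oc2, "relapse")
  km2 <- km_estimate(oc2, event_def = "relapse")
  expect_equal(cif2$estimate, 1 - km2$estimate[match(cif2$time, km2$time)],
               tolerance = 1e-12)
  # all deaths precede any relapse -> relapse CIF identically 0
  oc3 <- mk_outcomes(c(1, 1.5, 9, 10), c("death", "death", "relapse", "relapse"))
  cif3 <- cif_estimate(oc3, "relapse")
  expect_equal(cif3$estimate[cif3$time < 9], rep(0, sum(cif3$time < 9)))
})

test_that("CIF conservation: cause CIFs plus event-free probability sum to 1", {
  set.seed(12)
  n <- 80
  oc <- mk_outcomes(stats::rexp(n, 0.1) + 0.01,
                    sample(c("relapse", "death", "censored"), n, TRUE))
  cr <- cif_estimate(oc, "relapse")
  cd <- cif_estimate(oc, "death")
  km <- km_estimate(oc, event_def = c("relapse", "death"))
  expect_equal(cr$time, cd$time)
  s_at <- km$estimate[match(cr$time, km$time)]
  expect_lt(max(abs(cr$estimate + cd$estimate + s_at - 1)), 1e-12)
  # independent implementation cross-check (cmprsk)
  ci <- cmprsk::cuminc(oc$time, as.character(oc$event), cencode = "censored")
  ts <- cr$time[cr$n_event > 0]
  est <- cmprsk::timepoints(ci, ts)$est
  expect_equal(unname(est["1 relapse", ]),
               cr$estimate[match(ts, cr$time)], tolerance = 1e-8)
})

test_that("cause-specific Cox matches brute-force partial-likelihood maximization", {
  time <- c(1, 2, 3, 4, 5, 6)
  status <- c(1, 0, 1, 1, 0, 1)
  x <- c(1, 1, 0, 1, 0, 0)
  oc <- mk_outcomes(time, ifelse(status == 1, "relapse", "censored"), x = x)
  fit <- cox_cause_specific(oc, "relapse", "x")
  grid <- seq(-3, 3, by = 1e-3)
  ll <- vapply(grid, oracle_cox_loglik, 0, time = time, status = status, x = x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 2e-3, b0 + 2e-3, by = 1e-5)
  llf <- vapply(fine, oracle_cox_loglik, 0, time = time, status = status, x = x)
  expect_equal(fit$terms$coef, fine[which.max(llf)], tolerance = 1e-4)
  expect_equal(fit$terms$hr, exp(fit$terms$coef))
  expect_equal(fit$terms$ci_lower,
               exp(fit$terms$coef - 1.96 * fit$terms$se))
  expect_true(fit$terms$ci_lower < fit$terms$hr &
                fit$terms$hr < fit$terms$ci_upper)
})

test_that("Cox under the null shrinks toward HR 1 and competing events are censored", {
  set.seed(5)
  n <- 2000
  x <- stats::rbinom(n, 1, 0.5)
  t_r <- stats::rexp(n, 0.02)           # hazard free of x
  t_d <- stats::rexp(n, 0.015)
  time <- pmin(t_r, t_d, 60)
  event <- ifelse(time == 60, "censored", ifelse(t_r <= t_d, "relapse", "death"))
  oc <- mk_outcomes(time + 1e-9, event, x = factor(x))
  fit <- cox_cause_specific(oc, "relapse", "x")
  expect_lt(abs(fit$terms$coef), 0.15)
  # the cause-specific fit treats death as censoring: identical to an
  # explicit recode
  oc2 <- oc; oc2$event[oc2$event == "death"] <- "censored"
  fit2 <- cox_cause_specific(oc2, "relapse", "x")
  expect_equal(fit$terms$coef, fit2$terms$coef, tolerance = 1e-12)
})

test_that("separation and missing covariates raise errors", {
  oc <- mk_outcomes(c(1, 2, 3, 4), c("relapse", "relapse", "censored", "censored"),
                    x = c(1, 1, 0, 0))
  suppressWarnings(   # coxph itself warns of the infinite coefficient
    expect_error(cox_cause_specific(oc, "relapse", "x"), "separation"))
  expect_error(cox_cause_specific(oc, "relapse", "nope"), "absent")
  oc$y <- c(1, NA, 0, 0)
  expect_error(cox_cause_specific(oc, "relapse", "y"), "all subjects")
})
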