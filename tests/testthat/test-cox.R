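test_that("partial-likelihood maximum matches a fine grid search", {
  # 40-subject two-state data with a binary time-fixed covariate
  set.seed(14)
  n <- 40
  x <- rep(0:1, each = n / 2)
  tev <- rexp(n, 0.2 * exp(0.8 * x))
  cen <- runif(n, 2, 12)
  rows <- data.frame(subject_id = seq_len(n), start = 0,
                     stop = pmin(tev, cen), x = x,
                     event = as.integer(tev <= cen))
  fit <- fit_cox(rows)
  expect_equal(unname(fit$coefficients), grid_max_cox(rows),
               tolerance = 1e-3)
})

test_that("fit agrees with the reference implementation to 1e-6", {
  skip_if_not_installed("survival")
  set.seed(3)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  tev <- rexp(n, 0.15 * exp(0.7 * x))
  cen <- runif(n, 1, 15)
  rows <- data.frame(start = 0, stop = pmin(tev, cen), x = x,
                     event = as.integer(tev <= cen))
  fit <- fit_cox(rows)
  ref <- survival::coxph(survival::Surv(stop, event) ~ x, data = rows,
                         ties = "breslow")
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se), sqrt(unname(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(unname(fit$loglik["final"]), ref$loglik[2],
               tolerance = 1e-8)
  # Efron flag matches too, on start-stop data with time-varying covariate
  coh <- simulate_cohort(illness_death_config(n = 300, loghr = 1, seed = 6))
  cp <- to_counting_process(coh$histories, "Ill", "Dead")
  for (tie in c("breslow", "efron")) {
    fit2 <- fit_cox(cp, ties = tie)
    ref2 <- survival::coxph(survival::Surv(start, stop, event) ~ Ill,
                            data = cp, ties = tie)
    expect_equal(unname(fit2$coefficients), unname(coef(ref2)),
                 tolerance = 1e-6)
  }
})

test_that("degenerate inputs raise categorized errors", {
  rows <- data.frame(start = 0, stop = c(1, 2), x = c(0, 0),
                     event = c(1L, 0L))
  expect_error(fit_cox(rows), "constant covariate",
               class = "stagecif_estimation_error")
  rows2 <- data.frame(start = 0, stop = c(1, 2), x = c(0, 1),
                      event = c(0L, 0L))
  expect_error(fit_cox(rows2), "no events",
               class = "stagecif_estimation_error")
  # perfect separation: events only while x = 1 and x = 1 only for them
  rows3 <- data.frame(start = 0, stop = c(1, 2, 3, 4),
                      x = c(1, 1, 0, 0), event = c(1L, 1L, 0L, 0L))
  expect_error(fit_cox(rows3), class = "stagecif_estimation_error")
})

test_that("Wald summary reproduces the printed staging-cohort row", {
  w <- wald_stats(1.6233, 0.7147)
  expect_equal(round(w$z, 3), 2.271)
  expect_equal(round(w$hazard_ratio, 3), 5.070)
  expect_equal(round(2 * pnorm(-abs(2.2713)), 4), 0.0231)
  w0 <- wald_stats(0, 0.5)
  expect_equal(w0$z, 0)
  expect_equal(w0$p, 1)
  expect_equal(w0$hazard_ratio, 1)
})

test_that("Breslow increments follow the hand-evaluated formula", {
  # single event among 4 at risk, all x = 0: increment 1/4
  rows <- data.frame(start = 0, stop = c(1, 2, 3, 4),
                     event = c(1L, 0L, 0L, 0L))
  fit0 <- fit_cox(rows)  # null model
  inc <- breslow_increments(fit0)
  expect_equal(inc$increment[1], 0.25)
  expect_equal(cif_at(cif_cox(fit0), 1), 1 - exp(-0.25), tolerance = 1e-12)

  # risk set of 3 with x = (0, 0, 1), beta-hat = log 2, path x* = 1:
  # dA = 1 * exp(log 2) / (1 + 1 + 2) = 0.5
  fake <- structure(list(
    coefficients = c(x = log(2)), se = c(x = 1), var = matrix(1),
    loglik = c(null = 0, final = 0), iter = 0L, n = 3L, nevent = 1L,
    ties = "breslow", covariates = "x",
    baseline = data.frame(time = 5, nevent = 1,
                          denom = exp(0) + exp(0) + exp(log(2)))),
    class = "cox_tvc_fit")
  inc2 <- breslow_increments(fake, constant_path(1))
  expect_equal(inc2$increment, 0.5)

  # beta-hat = 0 reduces to the Nelson-Aalen increment d(s)/Y(s)
  coh <- simulate_cohort(illness_death_config(n = 150, loghr = 0, seed = 2))
  cp <- to_counting_process(coh$histories, "Ill", "Dead")
  fitn <- fit_cox(cp[, c("start", "stop", "event")])
  na_inc <- breslow_increments(fitn)
  expect_true(all(na_inc$increment > 0))
  expect_equal(na_inc$increment,
               fitn$baseline$nevent / fitn$baseline$denom)
})

test_that("cif_cox accumulates only increments after the origin age", {
  rows <- data.frame(start = 0, stop = c(4, 6, 8, 10),
                     event = c(1L, 1L, 0L, 0L))
  fit <- fit_cox(rows)
  curve <- cif_cox(fit, origin_age = 5)
  expect_equal(curve$time, 6)
  expect_equal(cif_at(curve, 5.5), 0)
  # no events after origin: CIF identically zero
  curve2 <- cif_cox(fit, origin_age = 7)
  expect_equal(nrow(curve2), 0L)
  expect_equal(cif_at(curve2, 30), 0)
})

test_that("cif_cox with beta = 0 equals 1 - exp(-Nelson-Aalen)", {
  h <- two_state_histories(n = 120, seed = 31)
  cp <- to_counting_process(h, NULL, "Z")
  fit <- fit_cox(cp)
  curve <- cif_cox(fit)
  haz <- nelson_aalen_transitions(to_transition_long(h))
  ch <- cumulative_hazard(haz, "W", "Z")
  expect_equal(curve$time, ch$time)
  expect_equal(curve$cif, 1 - exp(-ch$cumhaz), tolerance = 1e-12)
})

test_that("estimate is a local maximum of the partial likelihood", {
  for (seed in 1:3) {
    coh <- simulate_cohort(illness_death_config(n = 150, loghr = 1,
                                                seed = seed))
    cp <- to_counting_process(coh$histories, "Ill", "Dead")
    fit <- fit_cox(cp)
    b <- unname(fit$coefficients)
    llhat <- naive_cox_loglik(cp, b)
    expect_gte(llhat, naive_cox_loglik(cp, 0))
    for (eps in c(-0.05, -0.01, 0.01, 0.05))
      expect_gt(llhat, naive_cox_loglik(cp, b + eps))
  }
})

test_that("Breslow weights conserve total event mass at beta = 0", {
  coh <- simulate_cohort(illness_death_config(n = 200, loghr = 0, seed = 4))
  cp <- to_counting_process(coh$histories, "Ill", "Dead")
  fit0 <- fit_cox(cp[, c("start", "stop", "event")])
  inc <- breslow_increments(fit0)
  expect_equal(sum(inc$increment * fit0$baseline$denom),
               sum(cp$event), tolerance = 1e-12)
})

test_that("covariate paths are right-continuous step functions", {
  p <- covariate_path(c(0, 18), c(0, 1))
  expect_equal(drop(path_at_test(p, c(0, 17.999, 18, 25))), c(0, 0, 1, 1))
  expect_error(covariate_path(c(5, 5), c(0, 1)),
               class = "stagecif_usage_error")
  expect_error(breslow_increments(
    structure(list(coefficients = c(x = 1), covariates = "x",
                   baseline = data.frame(time = 1, nevent = 1, denom = 2)),
              class = "cox_tvc_fit"),
    covariate_path(10, 1)), class = "stagecif_usage_error")
})
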