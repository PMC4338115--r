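test_that("Nelson-Aalen increments match the hand-counted fixture", {
  rec <- to_transition_long(fixture_histories())
  haz <- nelson_aalen_transitions(rec)
  inc <- haz$increments
  expect_equal(inc$dhaz, c(1 / 3, 1 / 2, 1))
  expect_equal(inc$n_risk, c(3, 2, 1))
  expect_equal(inc$from, c("W", "W", "MM"))
  expect_equal(inc$to, c("BD", "MM", "BD"))
  # single W -> BD transition with 4 in W gives increment 1/4
  st <- stage_structure(c("W", "BD"))
  h <- event_histories(data.frame(subject_id = 1:4,
                                  BD = c(2, NA, NA, NA),
                                  censor_age = c(2, 5, 5, 5)), st)
  haz2 <- nelson_aalen_transitions(to_transition_long(h))
  expect_equal(haz2$increments$dhaz, 0.25)
  # no transitions at all: empty increments
  h0 <- event_histories(data.frame(subject_id = 1:3, censor_age = 5), st)
  haz0 <- nelson_aalen_transitions(to_transition_long(h0))
  expect_equal(nrow(haz0$increments), 0L)
})

test_that("disallowed transitions are rejected", {
  st <- stage_structure(c("W", "MM", "BD"),
                        transitions = data.frame(from = c("W", "MM"),
                                                 to = c("MM", "BD")))
  rec <- data.frame(subject_id = 1, from_state = "W", to_state = "BD",
                    time = 2, entry_age = 0)
  expect_error(nelson_aalen_transitions(rec, st),
               class = "stagecif_validation_error")
})

test_that("Aalen-Johansen matrix matches the hand product on the fixture", {
  haz <- nelson_aalen_transitions(to_transition_long(fixture_histories()))
  P <- aalen_johansen(haz, 0, 3)
  # (I + dL(1))(I + dL(2))(I + dL(3)) over (W, MM, BD) by hand:
  # P_W,BD = 1/3 + 2/3*1/2*1 = 2/3; P_W,W = 2/3 * 1/2 = 1/3
  expect_equal(P["W", "BD"], 2 / 3, tolerance = 1e-12)
  expect_equal(P["W", "W"], 1 / 3, tolerance = 1e-12)
  expect_equal(P["W", "MM"], 0, tolerance = 1e-12)
  expect_equal(unname(state_occupation(haz, 3, "W")),
               c(1 / 3, 0, 2 / 3), tolerance = 1e-12)
  # s = t gives the identity
  expect_equal(aalen_johansen(haz, 2, 2)[1:3, 1:3], diag(3),
               ignore_attr = TRUE)
  expect_error(aalen_johansen(haz, 3, 2), class = "stagecif_usage_error")
})

test_that("product integral matches an explicit brute-force product", {
  for (seed in c(2, 7)) {
    coh <- simulate_cohort(default_sim_config(n = 25, seed = seed))
    rec <- to_transition_long(coh$histories)
    haz <- nelson_aalen_transitions(rec)
    st <- default_stage_structure()
    for (s in c(0, 15)) {
      t <- 22
      P <- aalen_johansen(haz, s, t)
      B <- brute_aj(rec, st, s, t)
      expect_equal(unclass(P)[st$states, st$states], B, tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("rows are stochastic and Chapman-Kolmogorov holds", {
  coh <- simulate_cohort(default_sim_config(n = 200, seed = 12))
  haz <- nelson_aalen_transitions(to_transition_long(coh$histories))
  st <- default_stage_structure()
  for (tt in c(10, 18, 25)) {
    P <- aalen_johansen(haz, 0, tt)
    expect_true(all(P >= -1e-15 & P <= 1 + 1e-15))
    expect_equal(unname(rowSums(P)), rep(1, 5), tolerance = 1e-12)
    # absorbing row is a unit vector
    expect_equal(unname(P["Bipolar", ]), c(0, 0, 0, 0, 1))
  }
  P_su <- aalen_johansen(haz, 5, 25)
  P_st <- aalen_johansen(haz, 5, 15)
  P_tu <- aalen_johansen(haz, 15, 25)
  expect_equal(unclass(P_su), unclass(P_st %*% P_tu), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("two-state reduction reproduces 1 - Kaplan-Meier exactly", {
  skip_if_not_installed("survival")
  h <- two_state_histories(n = 300, seed = 17)
  haz <- nelson_aalen_transitions(to_transition_long(h))
  curve <- cif_absorbing(haz, "W", "Z", 0)
  time <- ifelse(is.na(h$Z), h$censor_age, h$Z)
  status <- as.integer(!is.na(h$Z))
  km <- survival::survfit(survival::Surv(time, status) ~ 1)
  kms <- summary(km, times = curve$time)$surv
  expect_equal(curve$cif, 1 - kms, tolerance = 1e-12)
})

test_that("absorbing-state CIF is monotone and guards its target", {
  coh <- simulate_cohort(default_sim_config(n = 150, seed = 3))
  haz <- nelson_aalen_transitions(to_transition_long(coh$histories))
  curve <- cif_absorbing(haz, "MajorMood", "Bipolar", s = 18)
  expect_true(all(diff(curve$cif) >= -1e-15))
  expect_equal(cif_at(curve, 18), 0)
  expect_error(cif_absorbing(haz, "Well", "MajorMood"),
               class = "stagecif_usage_error")
})

test_that("delta-method cloglog band equals the Greenwood KM band", {
  h <- two_state_histories(n = 200, seed = 23)
  haz <- nelson_aalen_transitions(to_transition_long(h))
  curve <- cif_absorbing(haz, "W", "Z", 0)
  band <- cif_confidence_band(curve, haz, 0.95)
  time <- ifelse(is.na(h$Z), h$censor_age, h$Z)
  km <- naive_km(time, as.integer(!is.na(h$Z)))
  keep <- !is.na(band$se)
  expect_equal(band$se[keep], sqrt(km$var)[keep], tolerance = 1e-10)
  expect_equal(band$lower[keep], km$cif_lower[keep], tolerance = 1e-10)
  expect_equal(band$upper[keep], km$cif_upper[keep], tolerance = 1e-10)
  expect_true(all(band$lower[keep] <= band$cif[keep] + 1e-12))
  expect_true(all(band$cif[keep] <= band$upper[keep] + 1e-12))
})

test_that("no band is emitted where the CIF is degenerate", {
  st <- stage_structure(c("W", "Z"))
  h <- event_histories(data.frame(subject_id = 1:3, Z = c(1, 2, 3),
                                  censor_age = c(1, 2, 3)), st)
  haz <- nelson_aalen_transitions(to_transition_long(h))
  curve <- cif_absorbing(haz, "W", "Z", 0)
  band <- cif_confidence_band(curve, haz)
  expect_true(is.na(band$se[curve$cif == 1][1]))
  expect_true(all(!is.na(band$se[curve$cif > 0 & curve$cif < 1])))
})

test_that("occupation curves stack to one and start at the initial state", {
  coh <- simulate_cohort(default_sim_config(n = 100, seed = 19))
  haz <- nelson_aalen_transitions(to_transition_long(coh$histories))
  occ <- state_occupation_curves(haz)
  st <- default_stage_structure()
  expect_equal(unname(rowSums(occ[st$states])), rep(1, nrow(occ)),
               tolerance = 1e-12)
  expect_equal(unname(state_occupation(haz, 0, "Well")),
               c(1, 0, 0, 0, 0))
  # stacked ordinates are the cumulated probabilities in severity order
  cum <- t(apply(as.matrix(occ[st$states]), 1, cumsum))
  expect_true(all(diff(t(cum)) >= -1e-12))
})

test_that("bootstrap band roughly agrees with the delta-method band", {
  h <- two_state_histories(n = 150, seed = 41)
  rec <- to_transition_long(h)
  haz <- nelson_aalen_transitions(rec)
  curve <- cif_absorbing(haz, "W", "Z", 0)
  band <- cif_confidence_band(curve, haz)
  boot <- cif_bootstrap_band(rec, "W", "Z", B = 60, seed = 5)
  mid <- which.min(abs(curve$cif - stats::median(curve$cif)))
  expect_lt(abs(boot$lower[mid] - band$lower[mid]), 0.08)
  expect_lt(abs(boot$upper[mid] - band$upper[mid]), 0.08)
})
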