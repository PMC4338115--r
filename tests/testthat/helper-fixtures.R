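# Shared fixtures and independent oracles.  Oracles deliberately use naive
# direct computations (explicit risk-set loops, explicit matrix products)
# so they share no code path with the package implementation.

# 3-subject hand fixture over states W < MM < BD:
#   subject 1: W -> BD at age 1   (3 subjects in W at age 1)
#   subject 2: censored in W at 4 (2 in W at age 2)
#   subject 3: W -> MM at 2, MM -> BD at 3 (1 in MM at age 3)
fixture_structure <- function() stage_structure(c("W", "MM", "BD"))

fixture_histories <- function() {
  event_histories(
    data.frame(subject_id = c("a", "b", "c"),
               MM = c(NA, NA, 2), BD = c(1, NA, 3),
               censor_age = c(1, 4, 3)),
    fixture_structure())
}

# two-state survival data as an event-history set (W -> Z)
two_state_histories <- function(n = 500, rate = 0.1, cens_min = 1,
                                cens_max = 25, seed = 9) {
  set.seed(seed)
  tev <- rexp(n, rate)
  cen <- runif(n, cens_min, cens_max)
  obs <- tev <= cen
  event_histories(
    data.frame(subject_id = seq_len(n),
               Z = ifelse(obs, tev, NA),
               censor_age = ifelse(obs, tev, cen)),
    stage_structure(c("W", "Z")))
}

# Naive Breslow partial log-likelihood for a single covariate on
# (start, stop] rows: explicit loop over event times and risk sets.
naive_cox_loglik <- function(rows, beta) {
  evt_times <- sort(unique(rows$stop[rows$event == 1]))
  x <- rows[[setdiff(names(rows),
                     c("subject_id", "start", "stop", "event"))]]
  ll <- 0
  for (s in evt_times) {
    at_risk <- rows$start < s & rows$stop >= s
    events <- rows$event == 1 & rows$stop == s
    ll <- ll + beta * sum(x[events]) -
      sum(events) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Coarse-to-fine grid maximization of the naive partial likelihood,
# final resolution 1e-4.
grid_max_cox <- function(rows, lo = -5, hi = 5) {
  coarse <- seq(lo, hi, by = 0.01)
  ll <- vapply(coarse, function(b) naive_cox_loglik(rows, b), 0)
  b0 <- coarse[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-4)
  llf <- vapply(fine, function(b) naive_cox_loglik(rows, b), 0)
  fine[which.max(llf)]
}

# Independent brute-force Aalen-Johansen product over transition times:
# reconstructs sojourn intervals and risk sets from scratch with plain
# loops, then multiplies the (I + dL) factors explicitly.
brute_aj <- function(records, structure, s, t) {
  states <- structure$states
  S <- length(states)
  ids <- unique(records$subject_id)
  intervals <- list()
  for (id in ids) {
    rr <- records[records$subject_id == id, , drop = FALSE]
    rr <- rr[order(rr$time, is.na(rr$to_state)), , drop = FALSE]
    enter <- if ("entry_age" %in% names(rr)) rr$entry_age[1] else 0
    for (k in seq_len(nrow(rr))) {
      intervals[[length(intervals) + 1L]] <-
        list(state = rr$from_state[k], enter = enter, exit = rr$time[k])
      enter <- rr$time[k]
    }
  }
  ev <- records[!is.na(records$to_state), , drop = FALSE]
  times <- sort(unique(ev$time))
  times <- times[times > s & times <= t]
  P <- diag(S)
  for (u in times) {
    dL <- matrix(0, S, S)
    for (h in seq_len(S)) for (j in seq_len(S)) {
      if (h == j) next
      d <- sum(ev$from_state == states[h] & ev$to_state == states[j] &
                 ev$time == u)
      if (d == 0) next
      Y <- 0
      for (iv in intervals)
        if (iv$state == states[h] && iv$enter < u && u <= iv$exit)
          Y <- Y + 1
      dL[h, j] <- d / Y
    }
    diag(dL) <- -rowSums(dL)
    P <- P %*% (diag(S) + dL)
  }
  dimnames(P) <- list(states, states)
  P
}

path_at_test <- function(path, s) stagecif:::path_at(path, s)

# Kaplan-Meier with Greenwood variance and cloglog CI, direct formulas.
naive_km <- function(time, status, conf_level = 0.95) {
  tt <- sort(unique(time[status == 1]))
  d <- vapply(tt, function(s) sum(time == s & status == 1), 0)
  Y <- vapply(tt, function(s) sum(time >= s), 0)
  S <- cumprod(1 - d / Y)
  gw <- ifelse(Y > d, d / (Y * (Y - d)), NA)
  varS <- S^2 * cumsum(gw)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se_cll <- sqrt(varS) / (S * abs(log(S)))
  list(time = tt, surv = S, var = varS,
       cif_lower = 1 - S^exp(-z * se_cll),
       cif_upper = 1 - S^exp(z * se_cll))
}
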