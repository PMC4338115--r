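# Nonparametric Markov multi-state estimation: Nelson-Aalen transition
# hazards, Aalen-Johansen transition probabilities (product integral),
# state occupation, absorbing-state CIFs, and delta-method / cloglog
# confidence bands.

#' Nelson-Aalen transition hazards
#'
#' For every allowed transition `(h, j)` the cumulative hazard is estimated
#' as `sum over s <= t of d_hj(s) / Y_h(s)`, where `d_hj(s)` counts observed
#' `h -> j` transitions at age `s` and `Y_h(s)` counts subjects occupying
#' state `h` just before `s` and still under observation at `s`.  Sojourn
#' intervals are half-open `(enter, exit]`: a subject leaving (or censored
#' in) state `h` at `s` is still in `Y_h(s)`.
#'
#' @param records [to_transition_long()] output (columns `subject_id`,
#'   `from_state`, `to_state` with `NA` for censoring, `time`, optional
#'   `entry_age`).
#' @param structure A [stage_structure()]; defaults to the one attached to
#'   `records`.
#' @return Object of class `transition_hazards`: list with `increments`
#'   (data.frame `from`, `to`, `time`, `n_event`, `n_risk`, `dhaz`, sorted
#'   by time) and `structure`.
#' @export
nelson_aalen_transitions <- function(records,
                                     structure = attr(records, "structure")) {
  if (is.null(structure)) stop_usage("a stage structure is required")
  records <- as.data.frame(records)
  if (!"entry_age" %in% names(records)) records$entry_age <- 0
  obs <- !is.na(records$to_state)
  if (any(obs)) {
    ok <- mapply(has_transition, records$from_state[obs],
                 records$to_state[obs], MoreArgs = list(structure = structure))
    if (!all(ok)) {
      i <- which(obs)[!ok][1]
      stop_validation(sprintf("transition %s -> %s not in structure",
                              records$from_state[i], records$to_state[i]))
    }
  }

  # sojourn intervals (enter, exit] per record, in time order per subject;
  # a transition and a censoring record at the same instant keep the
  # transition first so the post-transition sojourn has zero length
  o <- order(records$subject_id, records$time, is.na(records$to_state))
  r <- records[o, , drop = FALSE]
  first <- !duplicated(r$subject_id)
  enter <- ifelse(first, r$entry_age, c(NA, r$time[-nrow(r)]))
  intervals <- data.frame(state = r$from_state, enter = enter, exit = r$time)

  ev <- r[!is.na(r$to_state), , drop = FALSE]
  if (nrow(ev) == 0L) {
    inc <- data.frame(from = character(), to = character(), time = numeric(),
                      n_event = integer(), n_risk = numeric(),
                      dhaz = numeric())
    return(structure(list(increments = inc, structure = structure),
                     class = "transition_hazards"))
  }
  # group identical (from, to, time) triplets without a string round-trip of
  # the numeric time (keys use 17 significant digits, enough to be unique)
  key <- paste(ev$from_state, ev$to_state, sprintf("%.17g", ev$time),
               sep = "\r")
  uk <- !duplicated(key)
  grp <- match(key, key[uk])
  inc <- data.frame(from = ev$from_state[uk], to = ev$to_state[uk],
                    time = ev$time[uk],
                    n_event = as.integer(tabulate(grp, nbins = sum(uk))),
                    stringsAsFactors = FALSE)
  inc$n_risk <- NA_real_
  for (h in unique(inc$from)) {
    iv <- intervals[intervals$state == h, , drop = FALSE]
    sel <- inc$from == h
    u <- inc$time[sel]
    ones <- rep(1, nrow(iv))
    inc$n_risk[sel] <- sum_at_or_after(iv$exit, ones, u) -
      sum_at_or_after(iv$enter, ones, u)
  }
  if (any(inc$n_risk < inc$n_event))
    stop_validation("risk set smaller than event count (zero-length sojourn?)")
  inc$dhaz <- inc$n_event / inc$n_risk
  inc <- inc[order(inc$time, match(inc$from, structure$states),
                   match(inc$to, structure$states)), , drop = FALSE]
  rownames(inc) <- NULL
  structure(list(increments = inc, structure = structure),
            class = "transition_hazards")
}

#' @export
print.transition_hazards <- function(x, ...) {
  cat(sprintf("Nelson-Aalen transition hazards: %d increments over %d transitions\n",
              nrow(x$increments),
              length(unique(paste(x$increments$from, x$increments$to)))))
  tot <- stats::aggregate(dhaz ~ from + to, data = x$increments, FUN = sum)
  if (nrow(tot)) print(tot)
  invisible(x)
}

#' Cumulative transition hazard step function
#' @param hazards A [nelson_aalen_transitions()] result.
#' @param from,to State labels of the transition.
#' @return data.frame `time`, `cumhaz`.
#' @export
cumulative_hazard <- function(hazards, from, to) {
  inc <- hazards$increments
  inc <- inc[inc$from == from & inc$to == to, , drop = FALSE]
  data.frame(time = inc$time, cumhaz = cumsum(inc$dhaz))
}

# Greenwood-type covariance of the vectorized increment matrix at one time:
# transitions out of each state h are multinomial counts out of Y_h, so
# cov(dL_hj, dL_hl) = d_hj (1{j=l} Y_h - d_hl) / Y_h^3 for j, l != h, rows
# independent, and the diagonal entry dL_hh = -sum_j dL_hj by linearity.
increment_cov <- function(from_i, to_i, n_event, n_risk, S) {
  W <- matrix(0, S * S, S * S)
  for (h in unique(from_i)) {
    sel <- from_i == h
    dvec <- n_event[sel]
    Y <- n_risk[sel][1]
    C <- (diag(dvec, nrow = length(dvec)) * Y - outer(dvec, dvec)) / Y^3
    B <- matrix(0, S, length(dvec))
    B[cbind(to_i[sel], seq_along(dvec))] <- 1
    B[h, ] <- B[h, ] - 1
    full <- B %*% C %*% t(B)
    idx <- h + (seq_len(S) - 1L) * S
    W[idx, idx] <- W[idx, idx] + full
  }
  W
}

# Walk the product integral over transition times in (s, tmax], optionally
# propagating the covariance of vec(P) and recording a tracked entry.
aj_walk <- function(hazards, s, tmax = Inf, cov = FALSE, track = NULL,
                    track_row = NULL) {
  st <- hazards$structure
  states <- st$states
  S <- length(states)
  inc <- hazards$increments
  inc <- inc[inc$time > s & inc$time <= tmax, , drop = FALSE]
  from_i <- match(inc$from, states)
  to_i <- match(inc$to, states)
  dhaz <- inc$dhaz
  n_event <- inc$n_event
  n_risk <- inc$n_risk
  times <- sort(unique(inc$time))
  groups <- split(seq_along(from_i),
                  factor(match(inc$time, times), levels = seq_along(times)))
  P <- diag(S)
  V <- if (cov) matrix(0, S * S, S * S) else NULL
  tr_val <- tr_var <- numeric(length(times))
  ti <- if (!is.null(track)) {
    c(match(track[1], states), match(track[2], states))
  } else NULL
  row_i <- if (!is.null(track_row)) match(track_row, states) else NULL
  row_mat <- if (!is.null(row_i))
    matrix(NA_real_, length(times), S, dimnames = list(NULL, states))
  else NULL
  IS <- diag(S)
  for (k in seq_along(times)) {
    g <- groups[[k]]
    M <- matrix(0, S, S)
    M[cbind(from_i[g], to_i[g])] <- dhaz[g]
    diag(M) <- -rowSums(M)
    A <- IS + M
    if (cov) {
      W <- increment_cov(from_i[g], to_i[g], n_event[g], n_risk[g], S)
      TT <- kronecker(t(A), IS)
      G <- kronecker(IS, P)
      V <- TT %*% V %*% t(TT) + G %*% W %*% t(G)
    }
    P <- P %*% A
    if (!is.null(ti)) {
      tr_val[k] <- P[ti[1], ti[2]]
      if (cov) tr_var[k] <- V[ti[1] + (ti[2] - 1L) * S,
                              ti[1] + (ti[2] - 1L) * S]
    }
    if (!is.null(row_i)) row_mat[k, ] <- P[row_i, ]
  }
  dimnames(P) <- list(states, states)
  list(P = P, V = V, times = times, track_value = tr_val,
       track_var = if (cov) tr_var else NULL, track_rows = row_mat)
}

#' Aalen-Johansen transition probability matrix
#'
#' The product integral `P(s, t) = prod over u in (s, t] of (I + dL(u))`,
#' where `dL(u)` has off-diagonal entries `d_hj(u) / Y_h(u)` and diagonal
#' entries `1 - sum_j d_hj(u) / Y_h(u)`.  Simultaneous transitions in
#' different `(h, j)` pairs at the same age are composed within a single
#' factor.  The result is row-stochastic with rows of absorbing states equal
#' to unit vectors, and `P(s, s) = I`.
#'
#' @param hazards A [nelson_aalen_transitions()] result.
#' @param s,t Origin and evaluation ages, `s <= t`.
#' @return Matrix with entries `P_hj(s, t)`, dimnames the state labels,
#'   attributes `s` and `t`.
#' @export
aalen_johansen <- function(hazards, s, t) {
  if (s > t) stop_usage("aalen_johansen requires s <= t")
  w <- aj_walk(hazards, s, t)
  out <- w$P
  attr(out, "s") <- s
  attr(out, "t") <- t
  out
}

#' State occupation probabilities at an age
#'
#' The `initial_state` row of the Aalen-Johansen matrix `P(0, t)` (with
#' everyone starting in `initial_state` at age 0, these are the marginal
#' state occupation probabilities).
#'
#' @param hazards A [nelson_aalen_transitions()] result.
#' @param t Age in years.
#' @param initial_state State label (default: least severe state).
#' @return Named probability vector over states, summing to 1.
#' @export
state_occupation <- function(hazards, t,
                             initial_state = hazards$structure$states[1]) {
  if (!initial_state %in% hazards$structure$states)
    stop_usage("unknown initial_state")
  P <- aalen_johansen(hazards, 0, t)
  P[initial_state, ]
}

#' State occupation curves over all transition times
#'
#' @param hazards A [nelson_aalen_transitions()] result.
#' @param initial_state State label (default: least severe state).
#' @return data.frame: `time` plus one probability column per state.
#'   Cumulating columns in severity order gives the ordinates of a stacked
#'   occupation plot.
#' @export
state_occupation_curves <- function(hazards,
                                    initial_state =
                                      hazards$structure$states[1]) {
  if (!initial_state %in% hazards$structure$states)
    stop_usage("unknown initial_state")
  w <- aj_walk(hazards, -Inf, Inf, track_row = initial_state)
  data.frame(time = w$times, w$track_rows, check.names = FALSE)
}

#' Stacked state occupation plot
#'
#' Cumulates the occupation probabilities in severity order, so the height
#' of each shaded band at an age is the estimated probability of occupying
#' that state then.
#'
#' @param hazards A [nelson_aalen_transitions()] result.
#' @param initial_state State everyone occupies at age 0.
#' @param col Fill colours, one per state.
#' @param xlab,ylab Axis labels.
#' @return Invisibly, the [state_occupation_curves()] data.frame.
#' @export
plot_state_occupation <- function(hazards,
                                  initial_state =
                                    hazards$structure$states[1],
                                  col = grDevices::hcl.colors(
                                    length(hazards$structure$states),
                                    "Zissou 1"),
                                  xlab = "Age (years)",
                                  ylab = "Probability") {
  st <- hazards$structure
  occ <- state_occupation_curves(hazards, initial_state)
  tt <- c(0, occ$time)
  cum <- t(apply(rbind(as.numeric(st$states == initial_state),
                       as.matrix(occ[st$states])), 1, cumsum))
  graphics::plot(range(tt), c(0, 1), type = "n", xlab = xlab, ylab = ylab)
  lower <- rep(0, length(tt))
  for (k in seq_along(st$states)) {
    upper <- cum[, k]
    sx <- rep(tt, each = 2)[-1]
    su <- rep(upper, each = 2)[-2 * length(tt)]
    sl <- rep(lower, each = 2)[-2 * length(tt)]
    graphics::polygon(c(sx, rev(sx)), c(su, rev(sl)), col = col[k],
                      border = NA)
    lower <- upper
  }
  graphics::legend("bottomleft", legend = st$states, fill = col, bg = "white")
  invisible(occ)
}

#' Cumulative incidence of an absorbing state
#'
#' The curve `t -> P_hz(s, t)` from the Aalen-Johansen estimator, for
#' `h = from_state` and `z = absorbing_state`.  Because `z` is absorbing the
#' curve is non-decreasing and is a conditional cumulative incidence given
#' occupation of `from_state` at age `s` (under the Markov assumption the
#' history before `s` is irrelevant).
#'
#' @param hazards A [nelson_aalen_transitions()] result.
#' @param from_state Conditioning state at age `s`.
#' @param absorbing_state Target state; must be absorbing.
#' @param s Conditioning age (default 0).
#' @return A [cif_curve()] recorded at every transition time after `s`, with
#'   attributes `from_state` and `absorbing_state`.
#' @export
cif_absorbing <- function(hazards, from_state, absorbing_state, s = 0) {
  st <- hazards$structure
  if (!absorbing_state %in% st$absorbing)
    stop_usage(sprintf("'%s' is not absorbing; CIF monotonicity not guaranteed",
                       absorbing_state))
  if (identical(from_state, absorbing_state))
    stop_usage("from_state must differ from absorbing_state")
  if (!from_state %in% st$states) stop_usage("unknown from_state")
  w <- aj_walk(hazards, s, Inf, track = c(from_state, absorbing_state))
  curve <- cif_curve(w$times, w$track_value, origin_age = s)
  attr(curve, "from_state") <- from_state
  attr(curve, "absorbing_state") <- absorbing_state
  curve
}

#' Delta-method / complementary log-log confidence band for a CIF
#'
#' Pointwise variances of the Aalen-Johansen estimate are obtained by
#' recursive covariance propagation through the product integral with
#' Greenwood-type multinomial increment covariances (in the two-state case
#' this reduces exactly to the Greenwood formula for the Kaplan-Meier
#' estimator).  Pointwise intervals are formed on the complementary log-log
#' scale `g(p) = log(-log(1 - p))` and back-transformed, so they respect
#' `[0, 1]`; no band is emitted where the estimate is 0 or 1 (the transform
#' is undefined there).
#'
#' @param curve A [cif_absorbing()] result.
#' @param hazards The [nelson_aalen_transitions()] object the curve came
#'   from.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return The curve with columns `se`, `lower`, `upper` added (`NA` where
#'   the estimate is degenerate).
#' @export
cif_confidence_band <- function(curve, hazards, level = 0.95) {
  if (level <= 0 || level >= 1) stop_usage("level must be in (0, 1)")
  from_state <- attr(curve, "from_state")
  absorbing_state <- attr(curve, "absorbing_state")
  if (is.null(from_state) || is.null(absorbing_state))
    stop_usage("curve must come from cif_absorbing()")
  s <- attr(curve, "origin_age")
  if (nrow(curve) == 0L) return(curve)
  w <- aj_walk(hazards, s, max(curve$time), cov = TRUE,
               track = c(from_state, absorbing_state))
  se <- sqrt(pmax(w$track_var[match(curve$time, w$times)], 0))
  p <- curve$cif
  z <- stats::qnorm(1 - (1 - level) / 2)
  ok <- p > 0 & p < 1 & se > 0
  g <- se_g <- lower <- upper <- rep(NA_real_, length(p))
  g[ok] <- log(-log(1 - p[ok]))
  se_g[ok] <- se[ok] / ((1 - p[ok]) * abs(log(1 - p[ok])))
  lower[ok] <- 1 - exp(-exp(g[ok] - z * se_g[ok]))
  upper[ok] <- 1 - exp(-exp(g[ok] + z * se_g[ok]))
  se[!ok] <- NA_real_
  out <- cif_curve(curve$time, p, se = se, lower = lower, upper = upper,
                   origin_age = s, conf_level = level)
  attr(out, "from_state") <- from_state
  attr(out, "absorbing_state") <- absorbing_state
  out
}

#' Bootstrap cross-check band for an absorbing-state CIF
#'
#' Nonparametric bootstrap over subjects: resample event histories with
#' replacement, re-estimate the Aalen-Johansen CIF, and take pointwise
#' percentile intervals on the original curve's time grid.  Intended as a
#' cross-check of the delta-method band, not a replacement.
#'
#' @param records [to_transition_long()] output.
#' @param from_state,absorbing_state,s As in [cif_absorbing()].
#' @param B Number of bootstrap replicates.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return A [cif_curve()] with percentile `lower` / `upper`.
#' @export
cif_bootstrap_band <- function(records, from_state, absorbing_state, s = 0,
                               B = 200L, level = 0.95, seed = 1L) {
  st <- attr(records, "structure")
  base_h <- nelson_aalen_transitions(records, st)
  base <- cif_absorbing(base_h, from_state, absorbing_state, s)
  ids <- unique(records$subject_id)
  set.seed(seed)
  samp <- matrix(NA_real_, B, nrow(base))
  for (b in seq_len(B)) {
    take <- sample(ids, length(ids), replace = TRUE)
    pieces <- lapply(seq_along(take), function(k) {
      rr <- records[records$subject_id == take[k], , drop = FALSE]
      rr$subject_id <- paste0("b", k)
      rr
    })
    rec_b <- do.call(rbind, pieces)
    attr(rec_b, "structure") <- st
    hb <- nelson_aalen_transitions(rec_b, st)
    cb <- tryCatch(cif_absorbing(hb, from_state, absorbing_state, s),
                   stagecif_error = function(e) NULL)
    if (!is.null(cb)) samp[b, ] <- cif_at(cb, base$time)
  }
  alpha <- (1 - level) / 2
  qs <- apply(samp, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  out <- cif_curve(base$time, base$cif, lower = qs[1, ], upper = qs[2, ],
                   origin_age = s, conf_level = level)
  attr(out, "from_state") <- from_state
  attr(out, "absorbing_state") <- absorbing_state
  out
}
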