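# Cox proportional hazards with internal time-varying covariates on
# counting-process (start, stop] data: Newton-Raphson partial likelihood,
# Breslow (default) or Efron ties, Breslow baseline cumulative hazard, and
# CIF for a specified covariate path.

# sum of w[v >= tau] for each element of tau, O((n + K) log n)
sum_at_or_after <- function(v, w, tau) {
  o <- order(v)
  cs <- c(0, cumsum(w[o]))
  n_less <- findInterval(tau, v[o], left.open = TRUE)
  cs[length(cs)] - cs[n_less + 1L]
}

# Partial-likelihood value, score, information and risk-set denominators.
# Risk set at s: rows with start < s <= stop (half-open intervals, events at
# stop).  Breslow path is fully vectorized; Efron loops over event times.
cox_pl_quantities <- function(X, start, stop, event, beta, ties) {
  p <- ncol(X)
  eta <- if (p) drop(X %*% beta) else numeric(length(start))
  w <- exp(eta)
  evt <- event == 1
  tau <- sort(unique(stop[evt]))
  K <- length(tau)
  grp <- match(stop[evt], tau)
  d <- drop(rowsum(rep(1, sum(evt)), grp))
  sumx_evt <- if (p) rowsum(X[evt, , drop = FALSE] * 1, grp) else NULL

  S0 <- sum_at_or_after(stop, w, tau) - sum_at_or_after(start, w, tau)
  if (any(S0 <= 0))
    stop_estimation("empty risk set at an event time (inconsistent intervals)")
  S1 <- matrix(0, K, p)
  if (p) for (j in seq_len(p))
    S1[, j] <- sum_at_or_after(stop, w * X[, j], tau) -
      sum_at_or_after(start, w * X[, j], tau)

  if (ties == "breslow" || K == 0L) {
    loglik <- sum(eta[evt]) - sum(d * log(S0))
    if (!p)
      return(list(loglik = loglik, score = numeric(0),
                  info = matrix(0, 0, 0), tau = tau, d = d, S0 = S0))
    m <- S1 / S0
    score <- colSums(sumx_evt) - colSums(d * m)
    info <- matrix(0, p, p)
    for (j in seq_len(p)) for (l in j:p) {
      S2jl <- sum_at_or_after(stop, w * X[, j] * X[, l], tau) -
        sum_at_or_after(start, w * X[, j] * X[, l], tau)
      info[j, l] <- info[l, j] <- sum(d * (S2jl / S0 - m[, j] * m[, l]))
    }
    return(list(loglik = loglik, score = score, info = info,
                tau = tau, d = d, S0 = S0))
  }

  # Efron approximation for tied events
  loglik <- sum(eta[evt])
  score <- numeric(p)
  info <- matrix(0, p, p)
  for (k in seq_len(K)) {
    at_risk <- start < tau[k] & stop >= tau[k]
    tied <- evt & stop == tau[k]
    wD <- w[tied]
    S0k <- sum(w[at_risk]); S0D <- sum(wD)
    S1k <- if (p) colSums(w[at_risk] * X[at_risk, , drop = FALSE]) else 0
    S1D <- if (p) colSums(wD * X[tied, , drop = FALSE]) else 0
    dk <- d[k]
    for (l in seq_len(dk) - 1L) {
      den <- S0k - l / dk * S0D
      loglik <- loglik - log(den)
      mvec <- (S1k - l / dk * S1D) / den
      score <- score - mvec
      for (j1 in seq_len(p)) for (j2 in j1:p) {
        S2 <- sum(w[at_risk] * X[at_risk, j1] * X[at_risk, j2]) -
          l / dk * sum(wD * X[tied, j1] * X[tied, j2])
        v <- S2 / den - mvec[j1] * mvec[j2]
        info[j1, j2] <- info[j1, j2] + v
        if (j2 > j1) info[j2, j1] <- info[j2, j1] + v
      }
    }
    score <- score + (if (p) colSums(X[tied, , drop = FALSE]) else 0)
  }
  list(loglik = loglik, score = score, info = info, tau = tau, d = d, S0 = S0)
}

#' Fit a Cox model on counting-process data
#'
#' Maximum partial-likelihood estimation by Newton-Raphson with
#' step-halving, starting at `beta = 0`, for a hazard
#' `alpha0(t) exp(beta' x(t))` with piecewise-constant (internal)
#' time-varying covariates represented as `(start, stop]` risk intervals.
#' Breslow tie handling is the default so the baseline cumulative hazard
#' and CIF machinery are internally consistent; the Efron approximation is
#' available for the regression step.
#'
#' @param rows data.frame with columns `start`, `stop`, `event` (0/1, event
#'   at `stop`), optionally `subject_id`, and one column per covariate
#'   (every remaining column).  A model with zero covariate columns is the
#'   null model: no regression step, Nelson-Aalen baseline.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param tol_loglik,tol_score,max_iter Convergence controls: absolute
#'   partial-log-likelihood change, score norm, iteration cap.
#' @return Object of class `cox_tvc_fit` with elements `coefficients`,
#'   `se`, `var`, `loglik` (null and maximized), `iter`, `n`, `nevent`,
#'   `baseline` (distinct event times with event counts `nevent` and
#'   Breslow denominators `denom` evaluated at the estimate).
#' @export
fit_cox <- function(rows, ties = c("breslow", "efron"),
                    tol_loglik = 1e-9, tol_score = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  rows <- as.data.frame(rows)
  req <- c("start", "stop", "event")
  if (!all(req %in% names(rows)))
    stop_usage("counting-process data needs columns start, stop, event")
  covnames <- setdiff(names(rows), c("subject_id", "start", "stop", "event"))
  start <- as.numeric(rows$start); stop_ <- as.numeric(rows$stop)
  event <- as.integer(rows$event)
  if (any(start >= stop_))
    stop_validation("risk intervals must satisfy start < stop")
  if (!any(event == 1)) stop_estimation("no events")
  X <- if (length(covnames))
    as.matrix(as.data.frame(lapply(rows[covnames], as.numeric)))
  else matrix(0, nrow(rows), 0)
  p <- ncol(X)
  if (p) {
    flat <- apply(X, 2, function(col) diff(range(col)) == 0)
    if (any(flat))
      stop_estimation(sprintf("constant covariate: %s",
                              paste(covnames[flat], collapse = ", ")))
  }

  beta <- rep(0, p)
  q <- cox_pl_quantities(X, start, stop_, event, beta, ties)
  loglik0 <- q$loglik
  ll <- loglik0
  converged <- p == 0L
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(q$info, q$score),
                     error = function(e) stop_estimation(
                       "singular information matrix in Cox fit"))
    halve <- 0L
    repeat {
      qn <- cox_pl_quantities(X, start, stop_, event, beta + step, ties)
      if (is.finite(qn$loglik) && qn$loglik >= ll - 1e-12) break
      halve <- halve + 1L
      if (halve > 20L)
        stop_estimation(paste("Cox partial likelihood diverged",
                              "(monotone likelihood / separation?)"))
      step <- step / 2
    }
    beta <- beta + step
    if (any(abs(beta) > 20))
      stop_estimation(paste("Cox partial likelihood diverged:",
                            "monotone likelihood (perfect separation",
                            "in risk sets?)"))
    converged <- abs(qn$loglik - ll) < tol_loglik &&
      sqrt(sum(qn$score^2)) < tol_score
    ll <- qn$loglik
    q <- qn
  }
  if (!converged)
    stop_estimation(paste("Cox partial likelihood did not converge in",
                          max_iter, "iterations",
                          "(monotone likelihood / separation?)"))
  vcov <- if (p) solve(q$info) else matrix(0, 0, 0)
  if (p && any(diag(vcov) <= 0))
    stop_estimation("observed information not positive definite at estimate")

  # baseline machinery is always the Breslow form (Eq-consistent with the
  # CIF construction), evaluated at the final estimate
  qb <- if (ties == "breslow") q else
    cox_pl_quantities(X, start, stop_, event, beta, "breslow")
  baseline <- data.frame(time = qb$tau, nevent = qb$d, denom = qb$S0)

  names(beta) <- covnames
  structure(list(
    coefficients = beta,
    se = if (p) stats::setNames(sqrt(diag(vcov)), covnames) else numeric(0),
    var = vcov,
    loglik = c(null = loglik0, final = ll),
    score_norm = sqrt(sum(q$score^2)),
    iter = iter, n = nrow(rows), nevent = sum(event == 1),
    ties = ties, baseline = baseline, covariates = covnames,
    call = match.call()
  ), class = "cox_tvc_fit")
}

#' Wald statistics from an estimate and its standard error
#'
#' `Z = estimate / se`, two-sided p-value from the standard normal, hazard
#' ratio `exp(estimate)`.
#'
#' @param estimate Log hazard-ratio estimate(s).
#' @param se Standard error(s), same length.
#' @return data.frame with columns `estimate`, `se`, `z`, `p`,
#'   `hazard_ratio`.
#' @export
wald_stats <- function(estimate, se) {
  z <- ifelse(estimate == 0, 0, estimate / se)
  data.frame(estimate = estimate, se = se, z = z,
             p = 2 * stats::pnorm(-abs(z)),
             hazard_ratio = exp(estimate))
}

#' Wald summary table of a Cox fit
#' @param fit A [fit_cox()] result.
#' @return data.frame, one row per covariate: estimate, se, z, p,
#'   hazard_ratio.
#' @export
wald_summary <- function(fit) {
  out <- wald_stats(unname(fit$coefficients), unname(fit$se))
  rownames(out) <- fit$covariates
  out
}

#' @export
print.cox_tvc_fit <- function(x, ...) {
  cat(sprintf("Cox time-varying-covariate fit (%s ties): n = %d rows, %d events\n",
              x$ties, x$n, x$nevent))
  if (length(x$coefficients)) {
    print(round(wald_summary(x), 4))
  } else cat("null model (no covariates); Nelson-Aalen baseline\n")
  cat(sprintf("partial log-likelihood %.4f (null %.4f), %d iterations\n",
              x$loglik["final"], x$loglik["null"], x$iter))
  invisible(x)
}

#' Piecewise-constant covariate path
#'
#' Describes the covariate vector `x*(s)` of a (possibly hypothetical)
#' subject as a right-continuous step function: on `[times[k], times[k+1])`
#' the path takes the k-th row of `values`.
#'
#' @param times Sorted breakpoints (years); the path is defined from
#'   `times[1]` onward.
#' @param values Matrix with one row per breakpoint (a vector is taken as a
#'   single covariate).
#' @return Object of class `covariate_path`.
#' @export
covariate_path <- function(times, values) {
  values <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (length(times) != nrow(values))
    stop_usage("one row of values per breakpoint required")
  if (is.unsorted(times, strictly = TRUE))
    stop_usage("path breakpoints must be strictly increasing")
  structure(list(times = as.numeric(times), values = values),
            class = "covariate_path")
}

#' Constant covariate path
#' @param value Covariate value(s) held from age `from` onward.
#' @param from Age at which the path starts (default 0).
#' @return A [covariate_path()].
#' @export
constant_path <- function(value = 1, from = 0) {
  covariate_path(from, matrix(value, nrow = 1))
}

path_at <- function(path, s) {
  idx <- findInterval(s, path$times)
  if (any(idx == 0))
    stop_usage("covariate path not defined at all requested times")
  path$values[idx, , drop = FALSE]
}

#' Breslow baseline-hazard increments along a covariate path
#'
#' At each distinct event time `s` the increment is
#' `dA(s) = d(s) exp(beta' x*(s)) / sum_i Y_i(s) exp(beta' x_i(s))`,
#' where `d(s)` is the event count and the denominator is the risk-set sum
#' stored in the fit.  With `beta = 0` this reduces to the Nelson-Aalen
#' increment `d(s) / Y(s)`.
#'
#' @param fit A [fit_cox()] result.
#' @param path A [covariate_path()] defined at all event times (defaults to
#'   the baseline path `x* = 0`).
#' @return data.frame with columns `time`, `increment`.
#' @export
breslow_increments <- function(fit, path = NULL) {
  tau <- fit$baseline$time
  p <- length(fit$coefficients)
  relrisk <- if (p) {
    xs <- if (is.null(path)) matrix(0, length(tau), p) else path_at(path, tau)
    if (ncol(xs) != p)
      stop_usage("covariate path dimension does not match the fit")
    drop(exp(xs %*% fit$coefficients))
  } else rep(1, length(tau))
  data.frame(time = tau,
             increment = fit$baseline$nevent * relrisk / fit$baseline$denom)
}

#' Cumulative incidence from a Cox fit along a covariate path
#'
#' `CIF(t) = 1 - exp(-sum of dA(s) over origin_age < s <= t)` with the
#' Breslow increments of [breslow_increments()].  Increments at or before
#' `origin_age` are excluded, so the curve is the conditional cumulative
#' incidence given event-free survival to `origin_age` with covariate path
#' `x*`; the increments come from the model fit to the full data.
#'
#' @param fit A [fit_cox()] result.
#' @param path A [covariate_path()] (defaults to baseline `x* = 0`).
#' @param origin_age Conditioning age `s >= 0` (default 0: unconditional).
#' @return A [cif_curve()].
#' @export
cif_cox <- function(fit, path = NULL, origin_age = 0) {
  if (origin_age < 0) stop_usage("origin_age must be >= 0")
  inc <- breslow_increments(fit, path)
  inc <- inc[inc$time > origin_age, , drop = FALSE]
  cif_curve(inc$time, 1 - exp(-cumsum(inc$increment)),
            origin_age = origin_age)
}
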