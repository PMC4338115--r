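# Head-to-head comparison of the two frameworks: conditional cumulative
# incidence of the absorbing diagnosis given occupation of an earlier stage
# at a conditioning age, estimated (i) from a Cox fit with the stage as an
# internal time-varying covariate and (ii) from the Aalen-Johansen matrix.

#' Conditional CIF from both frameworks on the same data
#'
#' The Cox curve fixes the covariate path at 1 from the conditioning age and
#' accumulates Breslow increments strictly after it (the fit uses the entire
#' dataset); it jumps at every outcome event.  The multi-state curve is the
#' `(condition_state, absorbing_state)` entry of the Aalen-Johansen matrix
#' `P(condition_age, t)`; it jumps only at outcome events out of the
#' conditioning state's pathway.  Under the Markov assumption the multi-state
#' curve depends only on the state occupied at the conditioning age, not on
#' when it was entered.
#'
#' When `condition_state` is the initial state the Cox model has no
#' covariate and its curve is the Breslow (Nelson-Aalen) cumulative
#' incidence of the null model.
#'
#' @param histories An [event_histories()] set.
#' @param condition_state Non-absorbing state assumed occupied at
#'   `condition_age`.
#' @param condition_age Conditioning age in years.
#' @param absorbing_state Absorbing target state.
#' @param ties Tie handling passed to [fit_cox()].
#' @return Object of class `cif_comparison`: list with `cox_curve`,
#'   `msm_curve`, `sup_distance` (exact sup-norm over the union of jump
#'   times), `n`, and `conditioning`.
#' @export
conditional_cif_pair <- function(histories, condition_state, condition_age,
                                 absorbing_state, ties = "breslow") {
  st <- history_structure(histories)
  if (condition_state %in% st$absorbing)
    stop_usage("condition_state must be non-absorbing")
  if (!absorbing_state %in% st$absorbing)
    stop_usage(sprintf("'%s' is not absorbing", absorbing_state))

  records <- to_transition_long(histories)
  hazards <- nelson_aalen_transitions(records, st)

  # subjects must occupy the conditioning state just after condition_age
  occ <- state_at(histories, condition_age)
  at_risk <- !is.na(occ) & occ == condition_state &
    histories$censor_age > condition_age
  if (!any(at_risk))
    stop_estimation(sprintf("no subjects at risk in state '%s' at age %g",
                            condition_state, condition_age))

  if (condition_state == st$states[1]) {
    cp <- to_counting_process(histories, NULL, absorbing_state)
    fit <- fit_cox(cp, ties = ties)
    cox_curve <- cif_cox(fit, origin_age = condition_age)
  } else {
    cp <- to_counting_process(histories, condition_state, absorbing_state)
    fit <- fit_cox(cp, ties = ties)
    cox_curve <- cif_cox(fit, constant_path(1), origin_age = condition_age)
  }
  msm_curve <- cif_absorbing(hazards, condition_state, absorbing_state,
                             s = condition_age)
  structure(list(
    cox_curve = cox_curve,
    msm_curve = msm_curve,
    cox_fit = fit,
    sup_distance = sup_distance(cox_curve, msm_curve),
    n = nrow(histories),
    conditioning = list(state = condition_state, age = condition_age,
                        absorbing = absorbing_state)
  ), class = "cif_comparison")
}

#' @export
print.cif_comparison <- function(x, ...) {
  cat(sprintf(
    "Conditional CIF comparison (n = %d): %s occupied at age %g -> %s\n",
    x$n, x$conditioning$state, x$conditioning$age, x$conditioning$absorbing))
  cat(sprintf("  Cox curve: %d jumps, final %.4f\n",
              n_jumps(x$cox_curve),
              if (nrow(x$cox_curve)) max(x$cox_curve$cif) else 0))
  cat(sprintf("  MSM curve: %d jumps, final %.4f\n",
              n_jumps(x$msm_curve),
              if (nrow(x$msm_curve)) max(x$msm_curve$cif) else 0))
  cat(sprintf("  sup distance: %.5f\n", x$sup_distance))
  invisible(x)
}

#' Sample-size convergence experiment for the two conditional CIFs
#'
#' For each cohort size, simulate replicate cohorts from `base_config`,
#' build both conditional CIF curves, and aggregate the sup-norm distance
#' between them.  With exponential sojourn times the two estimators target
#' the same quantity, so the mean distance should shrink as the sample size
#' grows.
#'
#' @param base_config A [sim_config()] whose `n` is overridden by the grid.
#' @param n_grid Increasing vector of cohort sizes.
#' @param replicates Replicates per size (>= 1).
#' @param seed Master seed for replicate sub-seeds.
#' @param condition_state,condition_age,absorbing_state Conditioning as in
#'   [conditional_cif_pair()].
#' @return data.frame with one row per size: `n`, `mean_sup`, `sd_sup`,
#'   `n_ok` (replicates where both curves were estimable).
#' @export
convergence_experiment <- function(base_config, n_grid, replicates = 50L,
                                   seed = 1L,
                                   condition_state = "MajorMood",
                                   condition_age = 18,
                                   absorbing_state = "Bipolar") {
  if (is.unsorted(n_grid, strictly = TRUE))
    stop_usage("n_grid must be strictly increasing")
  if (replicates < 1) stop_usage("replicates must be >= 1")
  set.seed(seed)
  rep_seeds <- matrix(sample.int(2147483647L, length(n_grid) * replicates),
                      nrow = length(n_grid))
  out <- data.frame(n = n_grid, mean_sup = NA_real_, sd_sup = NA_real_,
                    n_ok = 0L)
  for (g in seq_along(n_grid)) {
    dists <- rep(NA_real_, replicates)
    for (r in seq_len(replicates)) {
      cfg <- base_config
      cfg$n <- as.integer(n_grid[g])
      cfg$seed <- rep_seeds[g, r]
      cohort <- simulate_cohort(cfg)
      dists[r] <- tryCatch(
        conditional_cif_pair(cohort$histories, condition_state,
                             condition_age, absorbing_state)$sup_distance,
        stagecif_error = function(e) NA_real_)
    }
    out$mean_sup[g] <- mean(dists, na.rm = TRUE)
    out$sd_sup[g] <- stats::sd(dists, na.rm = TRUE)
    out$n_ok[g] <- sum(!is.na(dists))
  }
  out
}
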