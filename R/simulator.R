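# Seeded Markov multi-state cohort simulator: competing exponential sojourn
# draws over a staging DAG, optional proportional-hazards covariate effects
# triggered by earlier stage entry, and right censoring.

#' Censoring schemes for the cohort simulator
#'
#' @param age Administrative censoring age (years).
#' @param min,max Range of a uniform administrative censoring age.
#' @param rate Rate (per year) of exponential random censoring from entry.
#' @return A censoring specification list.
#' @export
censoring_administrative <- function(age) {
  list(type = "administrative", age = as.numeric(age))
}

#' @rdname censoring_administrative
#' @export
censoring_uniform <- function(min, max) {
  if (max < min) stop_usage("censoring_uniform needs min <= max")
  list(type = "uniform", min = as.numeric(min), max = as.numeric(max))
}

#' @rdname censoring_administrative
#' @export
censoring_exponential <- function(rate) {
  if (rate <= 0) stop_usage("censoring rate must be > 0")
  list(type = "exponential", rate = as.numeric(rate))
}

#' @rdname censoring_administrative
#' @export
censoring_none <- function() list(type = "none")

#' Simulation configuration for a Markov staging cohort
#'
#' Sojourn times are exponential: from the current state, competing
#' exponential waiting times are drawn for every allowed outgoing
#' transition and the minimum wins.  A covariate effect multiplies the
#' baseline intensity of a transition by `exp(loghr)` once the subject has
#' entered the `trigger` state, giving proportional-hazards structure on
#' that transition.
#'
#' @param n Cohort size (>= 1).
#' @param rates data.frame with columns `from`, `to`, `rate` (baseline
#'   intensities per year, >= 0); every pair must be an allowed transition
#'   of `structure`.
#' @param structure A [stage_structure()].
#' @param effects Optional data.frame with columns `trigger`, `from`, `to`,
#'   `loghr`.
#' @param censoring One of the `censoring_*()` specifications.
#' @param entry_age Scalar fixed entry age, or length-2 vector for a
#'   uniform entry-age range.
#' @param seed Master integer seed; per-subject streams are split from it
#'   so growing `n` does not reshuffle earlier subjects.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n, rates, structure = default_stage_structure(),
                       effects = NULL,
                       censoring = censoring_uniform(15, 30),
                       entry_age = 0, seed = 1L) {
  if (n < 1) stop_usage("n must be >= 1")
  rates <- as.data.frame(rates, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "rate") %in% names(rates)))
    stop_usage("rates needs columns from, to, rate")
  rates$rate <- as.numeric(rates$rate)
  if (any(rates$rate < 0)) stop_usage("rates must be >= 0")
  ok <- mapply(has_transition, rates$from, rates$to,
               MoreArgs = list(structure = structure))
  if (!all(ok))
    stop_validation(sprintf("rate given for disallowed transition %s -> %s",
                            rates$from[!ok][1], rates$to[!ok][1]))
  if (!is.null(effects)) {
    effects <- as.data.frame(effects, stringsAsFactors = FALSE)
    if (!all(c("trigger", "from", "to", "loghr") %in% names(effects)))
      stop_usage("effects needs columns trigger, from, to, loghr")
    if (!all(effects$trigger %in% structure$states))
      stop_usage("effect trigger must be a known state")
  }
  if (length(entry_age) == 2L && entry_age[2] < entry_age[1])
    stop_usage("entry_age range must be increasing")
  structure(list(n = as.integer(n), rates = rates, structure = structure,
                 effects = effects, censoring = censoring,
                 entry_age = entry_age, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default staging-cohort configuration
#'
#' Five stages with the forward-complete DAG, administrative censoring
#' uniform on ages 15-30, and baseline intensities chosen so the simulated
#' spread of diagnoses qualitatively resembles a high-risk offspring cohort
#' (roughly a fifth never diagnosed, about half developing a non-mood
#' disorder, a sizeable minority progressing to major mood, and roughly ten
#' percent reaching bipolar disorder by end of follow-up).
#'
#' @param n Cohort size.
#' @param seed Master seed.
#' @param effects Optional covariate-effect data.frame (see
#'   [sim_config()]).
#' @return A [sim_config()].
#' @export
default_sim_config <- function(n = 500L, seed = 1L, effects = NULL) {
  rates <- data.frame(
    from = c("Well", "Well", "Well", "Well",
             "NonMood", "NonMood", "NonMood",
             "MinorMood", "MinorMood", "MajorMood"),
    to = c("NonMood", "MinorMood", "MajorMood", "Bipolar",
           "MinorMood", "MajorMood", "Bipolar",
           "MajorMood", "Bipolar", "Bipolar"),
    rate = c(0.045, 0.010, 0.010, 0.002,
             0.060, 0.025, 0.004,
             0.080, 0.008, 0.025),
    stringsAsFactors = FALSE)
  sim_config(n = n, rates = rates, effects = effects,
             censoring = censoring_uniform(15, 30), seed = seed)
}

#' Illness-death configuration
#'
#' Three states (Well, Ill, Dead) with the terminal intensity multiplied by
#' `exp(loghr)` once the intermediate state is entered -- the standard
#' proportional-hazards illness-death setup used for recovery and coverage
#' experiments.
#'
#' @param n Cohort size.
#' @param loghr Log hazard ratio of the terminal transition after illness
#'   (0 = time-homogeneous Markov chain, required by [analytic_cif()]).
#' @param seed Master seed.
#' @param rate_wi,rate_wd Baseline Well-to-Ill and Well-to-Dead intensities;
#'   the Ill-to-Dead baseline equals `rate_wd` so `loghr` is the log hazard
#'   ratio of the single terminal-event covariate.
#' @param censor_age Administrative censoring age.
#' @return A [sim_config()].
#' @export
illness_death_config <- function(n = 200L, loghr = 0, seed = 1L,
                                 rate_wi = 0.10, rate_wd = 0.04,
                                 censor_age = 30) {
  st <- stage_structure(c("Well", "Ill", "Dead"))
  rates <- data.frame(from = c("Well", "Well", "Ill"),
                      to = c("Ill", "Dead", "Dead"),
                      rate = c(rate_wi, rate_wd, rate_wd))
  effects <- if (loghr != 0)
    data.frame(trigger = "Ill", from = "Ill", to = "Dead", loghr = loghr)
  else NULL
  sim_config(n = n, rates = rates, structure = st, effects = effects,
             censoring = censoring_administrative(censor_age), seed = seed)
}

draw_censor <- function(censoring, entry) {
  switch(censoring$type,
         administrative = censoring$age,
         uniform = stats::runif(1, censoring$min, censoring$max),
         exponential = entry + stats::rexp(1, censoring$rate),
         none = Inf,
         stop_usage(sprintf("unknown censoring type '%s'", censoring$type)))
}

simulate_subject <- function(config) {
  st <- config$structure
  entry <- if (length(config$entry_age) == 2L)
    stats::runif(1, config$entry_age[1], config$entry_age[2])
  else config$entry_age
  censor <- draw_censor(config$censoring, entry)
  state <- st$states[1]
  t <- entry
  visited <- state
  ages <- stats::setNames(rep(NA_real_, length(st$states)), st$states)
  repeat {
    outs <- config$rates[config$rates$from == state, , drop = FALSE]
    lam <- outs$rate
    if (!is.null(config$effects) && nrow(outs)) {
      for (k in seq_len(nrow(outs))) {
        e <- config$effects
        hit <- e$from == outs$from[k] & e$to == outs$to[k] &
          e$trigger %in% visited
        if (any(hit)) lam[k] <- lam[k] * exp(sum(e$loghr[hit]))
      }
    }
    pos <- lam > 0
    if (!any(pos)) {
      if (is.infinite(censor))
        stop_validation(sprintf(
          "non-terminating subject: state '%s' has no positive outgoing rate and no censoring",
          state))
      break
    }
    waits <- stats::rexp(sum(pos), lam[pos])
    j <- which.min(waits)
    t_next <- t + waits[j]
    if (t_next > censor) break
    state <- outs$to[pos][j]
    t <- t_next
    ages[state] <- t
    visited <- c(visited, state)
    if (is_absorbing(st, state)) break
  }
  censor_age <- if (is.finite(censor)) max(censor, entry) else t
  c(list(entry_age = entry, censor_age = censor_age), as.list(ages))
}

#' Simulate a Markov staging cohort
#'
#' Deterministic given the configuration's seed: per-subject random streams
#' are derived from the master seed, so the first `k` subjects of a larger
#' cohort coincide with a smaller cohort simulated from the same seed.
#'
#' @param config A [sim_config()].
#' @return Object of class `simulated_cohort`: list with `histories` (an
#'   [event_histories()] set), `config`, and the per-subject `seeds`.
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop_usage("config must be a sim_config")
  set.seed(config$seed)
  sub_seeds <- sample.int(2147483647L, config$n)
  rows <- vector("list", config$n)
  for (i in seq_len(config$n)) {
    set.seed(sub_seeds[i])
    rows[[i]] <- simulate_subject(config)
  }
  fields <- names(rows[[1]])
  df <- as.data.frame(lapply(fields, function(f)
    vapply(rows, function(r) as.numeric(r[[f]]), 0)),
    col.names = fields)
  df$subject_id <- sprintf("s%05d", seq_len(config$n))
  histories <- event_histories(df, config$structure)
  structure(list(histories = histories, config = config, seeds = sub_seeds),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  st <- x$config$structure
  cat(sprintf("Simulated cohort: n = %d, seed = %d\n",
              x$config$n, x$config$seed))
  stage_cols <- setdiff(st$states, st$states[1])
  counts <- vapply(stage_cols, function(s) sum(!is.na(x$histories[[s]])), 0L)
  cat("Subjects ever diagnosed per stage:\n")
  print(counts)
  invisible(x)
}

generator_matrix <- function(config) {
  st <- config$structure
  S <- length(st$states)
  Q <- matrix(0, S, S, dimnames = list(st$states, st$states))
  Q[cbind(match(config$rates$from, st$states),
          match(config$rates$to, st$states))] <- config$rates$rate
  diag(Q) <- -rowSums(Q)
  Q
}

#' Exact transition probability of a time-homogeneous configuration
#'
#' `P(s, t) = expm(Q (t - s))` with `Q` the intensity matrix built from the
#' configuration's rates.  Only valid without covariate effects (those make
#' the chain time-inhomogeneous given the past).
#'
#' @param config A [sim_config()] with `effects = NULL`.
#' @param from_state,to_state State labels.
#' @param s Conditioning age.
#' @param t Vector of evaluation ages, `>= s`.
#' @return Numeric vector `P_(from,to)(s, t)`.
#' @export
analytic_transition_probability <- function(config, from_state, to_state,
                                            s, t) {
  if (!is.null(config$effects))
    stop_usage("analytic solution requires a configuration without covariate effects")
  if (any(t < s)) stop_usage("t must be >= s")
  Q <- generator_matrix(config)
  vapply(t, function(tt) {
    P <- as.matrix(Matrix::expm(Matrix::Matrix(Q * (tt - s))))
    P[from_state, to_state]
  }, 0)
}

#' Analytic cumulative incidence curve of an absorbing state
#'
#' Closed-form ground truth for simulation studies: the `(from, absorbing)`
#' entry of the matrix exponential of the intensity matrix.
#'
#' @param config A [sim_config()] with `effects = NULL`.
#' @param from_state Conditioning state at age `s`.
#' @param absorbing_state Absorbing target state.
#' @param s Conditioning age (default 0).
#' @param times Evaluation ages (default: 201-point grid from `s` to the
#'   latest possible censoring age, or `s + 50` without censoring bound).
#' @return A [cif_curve()] evaluated on `times`.
#' @export
analytic_cif <- function(config, from_state, absorbing_state, s = 0,
                         times = NULL) {
  st <- config$structure
  if (!absorbing_state %in% st$absorbing)
    stop_usage(sprintf("'%s' is not absorbing", absorbing_state))
  if (is.null(times)) {
    horizon <- switch(config$censoring$type,
                      administrative = config$censoring$age,
                      uniform = config$censoring$max,
                      s + 50)
    times <- seq(s, horizon, length.out = 201L)
  }
  vals <- analytic_transition_probability(config, from_state,
                                          absorbing_state, s, times)
  cif_curve(times, vals, origin_age = s)
}
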