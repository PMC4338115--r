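#' Build a validated set of staged event histories
#'
#' One row per subject on the age time scale.  Stage columns hold the age at
#' first diagnosis of that stage (NA = never observed).  A subject's state at
#' age `t` is the most severe diagnosis recorded at or before `t`.
#'
#' @param data data.frame with columns `subject_id`, `censor_age`, one column
#'   per non-initial state of `structure` (missing columns are treated as
#'   all-NA), and optionally `entry_age` (delayed entry, default 0),
#'   `family_id`, and logical `prevalent` (TRUE permits stage ages before
#'   `entry_age`).
#' @param structure A [stage_structure()].
#' @return data.frame of class `event_history_set` with normalized columns
#'   and the structure attached as attribute `"structure"`.
#' @export
event_histories <- function(data, structure = default_stage_structure()) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "censor_age") %in% names(data)))
    stop_parse("event history table needs columns 'subject_id' and 'censor_age'")
  stage_cols <- setdiff(structure$states, structure$states[1])
  for (s in stage_cols)
    if (!s %in% names(data)) data[[s]] <- rep(NA_real_, nrow(data))
  if (!"entry_age" %in% names(data)) data$entry_age <- rep(0, nrow(data))
  data$entry_age[is.na(data$entry_age)] <- 0
  if (!"family_id" %in% names(data))
    data$family_id <- rep(NA_character_, nrow(data))
  if (!"prevalent" %in% names(data)) data$prevalent <- rep(FALSE, nrow(data))
  data$prevalent[is.na(data$prevalent)] <- FALSE
  for (s in c(stage_cols, "entry_age", "censor_age"))
    data[[s]] <- as.numeric(data[[s]])

  if (anyDuplicated(data$subject_id))
    stop_validation("duplicated subject_id in event history table")
  if (any(is.na(data$censor_age)))
    stop_validation("censor_age is required for every subject")
  if (any(data$entry_age < 0))
    stop_validation("entry_age must be >= 0")

  # vectorized invariant checks over the n x K stage-age matrix
  # (stage_cols is already in severity order)
  M <- as.matrix(data[stage_cols])
  if (nrow(data)) {
    prev <- rep(-Inf, nrow(data))
    for (k in seq_along(stage_cols)) {
      col <- M[, k]
      bad <- !is.na(col) & col < prev
      if (any(bad))
        stop_validation(sprintf(
          "subject %s: stage '%s' dated before a less severe stage",
          data$subject_id[which(bad)[1]], stage_cols[k]))
      prev <- ifelse(is.na(col), prev, pmax(prev, col))
    }
    late <- which(rowSums(M > data$censor_age, na.rm = TRUE) > 0)
    if (length(late))
      stop_validation(sprintf("subject %s: stage age after censor_age",
                              data$subject_id[late[1]]))
    early <- which(rowSums(M < data$entry_age, na.rm = TRUE) > 0 &
                     !data$prevalent)
    if (length(early))
      stop_validation(sprintf(
        "subject %s: stage age before entry_age but not flagged prevalent",
        data$subject_id[early[1]]))
  }

  out <- data[, c("subject_id", "family_id", "entry_age",
                  stage_cols, "censor_age", "prevalent")]
  attr(out, "structure") <- structure
  class(out) <- c("event_history_set", "data.frame")
  out
}

#' Read staged event histories from a wide CSV file
#'
#' Expected dialect: comma-separated, header row, ages in decimal years,
#' empty field = stage never observed.
#'
#' @param path Path to a CSV file with one row per subject.
#' @param structure A [stage_structure()].
#' @return An [event_histories()] set (possibly with zero rows).
#' @export
load_event_histories <- function(path, structure = default_stage_structure()) {
  if (!file.exists(path)) stop_parse(sprintf("cannot read '%s'", path))
  data <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop_parse(sprintf("malformed CSV '%s': %s",
                                           path, conditionMessage(e))))
  if (nrow(data) == 0L) {
    empty <- data.frame(subject_id = character(), censor_age = numeric())
    return(event_histories(empty, structure))
  }
  event_histories(data, structure)
}

#' Write event histories to a wide CSV file
#' @param histories An [event_histories()] set.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_event_histories <- function(histories, path) {
  utils::write.csv(as.data.frame(histories), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @export
`[.event_history_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "structure") <- attr(x, "structure")
    class(out) <- class(x)
  }
  out
}

history_structure <- function(histories) {
  st <- attr(histories, "structure")
  if (is.null(st)) stop_validation("event history set lost its stage structure")
  st
}

#' State occupied by each subject at a given age
#'
#' The state at age `t` is the most severe stage diagnosed at or before `t`
#' (the initial state if none).  Subjects censored before `t` get `NA`.
#'
#' @param histories An [event_histories()] set.
#' @param t Age in years.
#' @return Character vector of state labels, `NA` where follow-up ended
#'   before `t` without reaching an absorbing state.
#' @export
state_at <- function(histories, t) {
  st <- history_structure(histories)
  stage_cols <- setdiff(st$states, st$states[1])
  ages <- as.matrix(histories[, stage_cols, drop = FALSE])
  out <- character(nrow(histories))
  for (i in seq_len(nrow(histories))) {
    reached <- which(!is.na(ages[i, ]) & ages[i, ] <= t)
    state <- if (length(reached)) stage_cols[max(reached)] else st$states[1]
    if (histories$censor_age[i] < t && !is_absorbing(st, state))
      state <- NA_character_
    out[i] <- state
  }
  out
}

# Realized path of one subject: the states actually entered, in order, with
# entry ages.  Stages tied at the same age collapse to the most severe of the
# tie (no zero-length sojourns).
realized_path <- function(ages, stage_cols) {
  obs <- which(!is.na(ages))
  if (!length(obs)) return(data.frame(state = character(), age = numeric()))
  o <- obs[order(ages[obs], seq_along(ages)[obs])]
  # within a tie, keep only the most severe stage (largest severity index)
  keep <- vapply(seq_along(o),
                 function(k) o[k] == max(o[ages[o] == ages[o[k]]]),
                 TRUE)
  o <- o[keep]
  data.frame(state = stage_cols[o], age = as.numeric(ages[o]),
             stringsAsFactors = FALSE)
}

#' Convert event histories to transition-long format
#'
#' Each subject contributes one record per realized stage transition, plus a
#' censoring record (empty `to_state`) in the last occupied state when that
#' state is not absorbing.  Two stages dated at the identical age are
#' recorded as one direct transition to the more severe stage.
#'
#' @param histories An [event_histories()] set.
#' @return data.frame of class `transition_records` with columns
#'   `subject_id`, `from_state`, `to_state` (`NA` = censored), `time`,
#'   `entry_age`; structure attached as attribute.
#' @export
to_transition_long <- function(histories) {
  st <- history_structure(histories)
  stage_cols <- setdiff(st$states, st$states[1])
  M <- as.matrix(as.data.frame(histories)[stage_cols])
  sid <- fs <- ts <- character(0)
  tm <- en <- numeric(0)
  acc <- vector("list", nrow(histories))
  for (i in seq_len(nrow(histories))) {
    ages <- M[i, ]
    entry <- histories$entry_age[i]
    path <- realized_path(ages, stage_cols)
    # state occupied at entry (prevalent stages)
    pre <- path$age <= entry
    cur <- if (any(pre)) path$state[max(which(pre))] else st$states[1]
    path <- path[!pre, , drop = FALSE]
    from <- c(cur, path$state)
    n <- nrow(path)
    last <- from[n + 1L]
    censored <- !is_absorbing(st, last)
    m <- n + censored
    acc[[i]] <- list(
      subject_id = rep(histories$subject_id[i], m),
      from_state = from[seq_len(m)],
      to_state = c(path$state, if (censored) NA_character_),
      time = c(path$age, if (censored) histories$censor_age[i]),
      entry_age = rep(entry, m))
  }
  out <- data.frame(
    subject_id = unlist(lapply(acc, `[[`, "subject_id")),
    from_state = unlist(lapply(acc, `[[`, "from_state")),
    to_state = unlist(lapply(acc, `[[`, "to_state")),
    time = unlist(lapply(acc, `[[`, "time")),
    entry_age = unlist(lapply(acc, `[[`, "entry_age")),
    stringsAsFactors = FALSE)
  if (nrow(histories) == 0L)
    out <- data.frame(subject_id = character(), from_state = character(),
                      to_state = character(), time = numeric(),
                      entry_age = numeric(), stringsAsFactors = FALSE)
  bad <- !is.na(out$to_state) &
    !mapply(has_transition, out$from_state, out$to_state,
            MoreArgs = list(structure = st))
  if (any(bad))
    stop_validation(sprintf("subject %s: transition %s -> %s not in structure",
                            out$subject_id[bad][1], out$from_state[bad][1],
                            out$to_state[bad][1]))
  rownames(out) <- NULL
  attr(out, "structure") <- st
  class(out) <- c("transition_records", "data.frame")
  out
}

#' Convert event histories to counting-process (start-stop) format
#'
#' Builds risk intervals for a Cox model of the age at first diagnosis of
#' `outcome_stage`, with a single 0/1 internal time-varying covariate that
#' switches on when `covariate_stage` is first diagnosed.  Intervals are
#' half-open `(start, stop]`; events occur at `stop`.  Subjects are censored
#' at `censor_age` or at entry into any stage more severe than
#' `outcome_stage` (which removes them from risk of a first
#' `outcome_stage` diagnosis).
#'
#' @param histories An [event_histories()] set.
#' @param covariate_stage State label whose first diagnosis defines the
#'   covariate (0 before, 1 after), or `NULL` for a null model with no
#'   covariate column.
#' @param outcome_stage State label of the outcome; must be strictly more
#'   severe than `covariate_stage`.
#' @return data.frame of class `counting_process` with columns `subject_id`,
#'   `start`, `stop`, one covariate column named after `covariate_stage`,
#'   and `event`.
#' @export
to_counting_process <- function(histories, covariate_stage, outcome_stage) {
  st <- history_structure(histories)
  sev_o <- severity(st, outcome_stage)
  if (is.na(sev_o)) stop_usage("unknown outcome stage")
  if (!is.null(covariate_stage)) {
    sev_c <- severity(st, covariate_stage)
    if (is.na(sev_c)) stop_usage("unknown covariate stage")
    if (sev_o <= sev_c)
      stop_usage("outcome stage must be strictly more severe than covariate stage")
  }
  stage_cols <- setdiff(st$states, st$states[1])
  rows <- vector("list", nrow(histories))
  for (i in seq_len(nrow(histories))) {
    entry <- histories$entry_age[i]
    out_age <- histories[[outcome_stage]][i]
    more_severe <- st$states[seq_along(st$states) > sev_o]
    ms_ages <- unlist(histories[i, intersect(more_severe, stage_cols)])
    ms_age <- if (length(ms_ages) && any(!is.na(ms_ages)))
      min(ms_ages, na.rm = TRUE) else Inf
    end <- min(out_age, histories$censor_age[i], ms_age, na.rm = TRUE)
    event <- as.integer(!is.na(out_age) && out_age <= end)
    if (end <= entry) next
    if (is.null(covariate_stage)) {
      rows[[i]] <- data.frame(subject_id = histories$subject_id[i],
                              start = entry, stop = end, event = event)
      next
    }
    cov_age <- histories[[covariate_stage]][i]
    if (!is.na(cov_age) && cov_age > entry && cov_age < end) {
      r <- data.frame(subject_id = histories$subject_id[i],
                      start = c(entry, cov_age), stop = c(cov_age, end),
                      x = c(0, 1), event = c(0L, event))
    } else {
      x <- as.numeric(!is.na(cov_age) && cov_age <= entry)
      r <- data.frame(subject_id = histories$subject_id[i],
                      start = entry, stop = end, x = x, event = event)
    }
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(subject_id = character(), start = numeric(),
                      stop = numeric(), x = numeric(), event = integer())
    if (is.null(covariate_stage)) out$x <- NULL
  }
  if (!is.null(covariate_stage))
    names(out)[names(out) == "x"] <- covariate_stage
  rownames(out) <- NULL
  class(out) <- c("counting_process", "data.frame")
  out
}

#' Select one subject per family
#'
#' Cohorts recruiting several offspring per family are not independent
#' between rows; estimators here ignore `family_id`, so a common device is
#' to retain a single randomly chosen subject per family.
#'
#' @param histories An [event_histories()] set.
#' @param seed Integer seed for the random selection.
#' @return The subset of `histories` with one row per family (subjects with
#'   missing `family_id` are all kept).
#' @export
select_one_per_family <- function(histories, seed = 1L) {
  fam <- histories$family_id
  keep <- is.na(fam)
  set.seed(seed)
  for (f in unique(fam[!is.na(fam)])) {
    idx <- which(!is.na(fam) & fam == f)
    keep[if (length(idx) == 1L) idx else sample(idx, 1L)] <- TRUE
  }
  out <- histories[keep, , drop = FALSE]
  attr(out, "structure") <- attr(histories, "structure")
  class(out) <- class(histories)
  out
}
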