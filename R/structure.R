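#' Define a forward-progressive stage structure
#'
#' A stage structure is a directed acyclic graph over clinical stages ordered
#' by severity.  Transitions must always move toward a more severe stage
#' (backward transitions are not allowed); skipping of intermediate stages is
#' permitted whenever the corresponding pair is listed in `transitions`.
#' States with no outgoing transitions are absorbing.
#'
#' @param states Character vector of state labels ordered from least to most
#'   severe.  The first element is the initial state every subject occupies
#'   at the start of follow-up.
#' @param transitions Two-column data.frame (`from`, `to`) of allowed
#'   transitions, or `NULL` for the forward-complete default (every pair
#'   `(h, j)` with `severity(j) > severity(h)`).
#' @return An object of class `stage_structure` with elements `states`,
#'   `transitions` (data.frame with columns `from`, `to`) and `absorbing`.
#' @examples
#' stage_structure(c("Well", "Ill", "Dead"))
#' @export
stage_structure <- function(states, transitions = NULL) {
  states <- as.character(states)
  if (length(states) < 2L || anyDuplicated(states))
    stop_validation("'states' must be >= 2 distinct labels ordered by severity")
  if (is.null(transitions)) {
    idx <- which(upper.tri(diag(length(states))), arr.ind = TRUE)
    transitions <- data.frame(from = states[idx[, "row"]],
                              to = states[idx[, "col"]],
                              stringsAsFactors = FALSE)
  }
  transitions <- as.data.frame(transitions, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(transitions)))
    stop_validation("'transitions' needs columns 'from' and 'to'")
  transitions <- transitions[, c("from", "to")]
  bad <- !(transitions$from %in% states) | !(transitions$to %in% states)
  if (any(bad))
    stop_validation(sprintf("transition uses unknown state: %s -> %s",
                            transitions$from[bad][1], transitions$to[bad][1]))
  sev_from <- match(transitions$from, states)
  sev_to <- match(transitions$to, states)
  if (any(sev_to <= sev_from)) {
    i <- which(sev_to <= sev_from)[1]
    stop_validation(sprintf(
      "backward (or self) transition not allowed: %s -> %s",
      transitions$from[i], transitions$to[i]))
  }
  transitions <- transitions[order(sev_from, sev_to), , drop = FALSE]
  rownames(transitions) <- NULL
  absorbing <- setdiff(states, unique(transitions$from))
  structure(
    list(states = states, transitions = transitions, absorbing = absorbing),
    class = "stage_structure"
  )
}

#' Default 5-stage structure for progression to bipolar disorder
#'
#' Well, non-mood disorder, minor mood disorder, major mood disorder and
#' bipolar disorder, with all forward transitions allowed (stage skipping)
#' and bipolar disorder the unique absorbing state.
#'
#' @return A [stage_structure()] object.
#' @export
default_stage_structure <- function() {
  stage_structure(c("Well", "NonMood", "MinorMood", "MajorMood", "Bipolar"))
}

severity <- function(structure, state) match(state, structure$states)

is_absorbing <- function(structure, state) state %in% structure$absorbing

has_transition <- function(structure, from, to) {
  any(structure$transitions$from == from & structure$transitions$to == to)
}

#' @export
print.stage_structure <- function(x, ...) {
  cat("Stage structure (", length(x$states), " states, severity order):\n  ",
      paste(x$states, collapse = " < "), "\n", sep = "")
  cat("Absorbing:", paste(x$absorbing, collapse = ", "), "\n")
  cat(nrow(x$transitions), "allowed transitions (forward, skipping permitted)\n")
  invisible(x)
}
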