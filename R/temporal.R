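#' Mean dwell time of a state
#'
#' Average length (in windows) of the maximal runs of consecutive windows
#' spent in \code{state}. A subject who never enters the state gets 0 by
#' default; \code{absentAsNA = TRUE} switches to missing-value semantics.
#'
#' @param labels integer state sequence (values 1..k).
#' @param state state label to measure.
#' @param absentAsNA return NA instead of 0 when the state never occurs.
#' @return mean run length in window units.
#' @examples
#' meanDwellTime(c(1, 1, 1, 2, 2), 1)  # 3
#' @export
meanDwellTime <- function(labels, state, absentAsNA = FALSE) {
  stopifnot(length(labels) >= 1L)
  if (length(state) != 1L || is.na(state) || state < 1 || state != round(state))
    stop("unknown state label ", state)
  r <- rle(labels)
  runs <- r$lengths[r$values == state]
  if (!length(runs)) return(if (absentAsNA) NA_real_ else 0)
  mean(runs)
}

#' Fraction of time in a state
#'
#' @param labels integer state sequence.
#' @param state state label.
#' @return proportion of windows spent in \code{state}, in [0, 1].
#' @export
fractionTime <- function(labels, state) {
  stopifnot(length(labels) >= 1L)
  mean(labels == state)
}

#' Number of state transitions
#'
#' @param labels integer state sequence.
#' @return count of indices t with labels[t] != labels[t-1].
#' @export
nTransitions <- function(labels) {
  stopifnot(length(labels) >= 1L)
  sum(diff(labels) != 0)
}

#' Temporal profiles for a fitted state model
#'
#' One row per subject: per-state mean dwell time and fraction of time, and
#' the number of transitions.
#'
#' @param model a [StateModel-class] (or a named list of label sequences
#'   plus \code{k}).
#' @param k number of states; taken from the model when omitted.
#' @param absentAsNA see [meanDwellTime()].
#' @return data.frame with columns \code{subject_id}, \code{dwell_s1..sk},
#'   \code{frac_s1..sk}, \code{n_transitions}.
#' @export
temporalProfiles <- function(model, k = NULL, absentAsNA = FALSE) {
  if (is(model, "StateModel")) {
    labels <- model@labels
    k <- model@k
  } else {
    labels <- model
    stopifnot(!is.null(k))
  }
  rows <- lapply(names(labels), function(id) {
    l <- labels[[id]]
    dw <- vapply(seq_len(k), function(s)
      meanDwellTime(l, s, absentAsNA = absentAsNA), numeric(1))
    fr <- vapply(seq_len(k), function(s) fractionTime(l, s), numeric(1))
    out <- data.frame(subject_id = id)
    out[paste0("dwell_s", seq_len(k))] <- as.list(dw)
    out[paste0("frac_s", seq_len(k))] <- as.list(fr)
    out$n_transitions <- nTransitions(l)
    out
  })
  do.call(rbind, rows)
}
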