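#' Study design bookkeeping for subjects and AM/PM sessions
#'
#' A sample design records which subjects were sampled at which sessions. A
#' session is a (day, period) pair, where the period is `"AM"` or `"PM"`, and
#' sessions are ordered chronologically (by day, with AM before PM within a
#' day). The availability mask `present` records which subject-session
#' combinations were actually collected, and `n_sessions` counts the present
#' sessions per subject.
#'
#' @param subjects Character vector of subject labels, in display order.
#' @param n_days Number of consecutive study days.
#' @param missing Optional data.frame with columns `subject`, `day`,
#'   `session` listing subject-sessions that were not collected.
#'
#' @return An object of class `sample_design`: a list with elements
#'   `subjects`, `sessions` (data.frame with `sample`, `day`, `period`),
#'   `present` (logical subjects x sessions matrix) and `n_sessions`.
#' @examples
#' d <- sample_design(paste0("S", 1:4), n_days = 3)
#' d$n_sessions
#' @export
sample_design <- function(subjects, n_days = 3, missing = NULL) {
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) .cb_stop("duplicate subject labels")
  sessions <- expand.grid(period = c("AM", "PM"), day = seq_len(n_days),
                          stringsAsFactors = FALSE)
  sessions <- sessions[order(sessions$day, sessions$period), , drop = FALSE]
  sessions <- data.frame(
    sample = paste0("D", sessions$day, "_", sessions$period),
    day = sessions$day, period = sessions$period,
    stringsAsFactors = FALSE, row.names = NULL)
  present <- matrix(TRUE, nrow = length(subjects), ncol = nrow(sessions),
                    dimnames = list(subjects, sessions$sample))
  if (!is.null(missing) && nrow(missing)) {
    for (i in seq_len(nrow(missing))) {
      sid <- paste0("D", missing$day[i], "_", missing$session[i])
      if (!missing$subject[i] %in% subjects || !sid %in% sessions$sample)
        .cb_stop("missing_samples entry not in design")
      present[missing$subject[i], sid] <- FALSE
    }
  }
  structure(list(subjects = subjects, sessions = sessions,
                 present = present, n_sessions = rowSums(present)),
            class = "sample_design")
}

#' @export
print.sample_design <- function(x, ...) {
  cat("sample_design:", length(x$subjects), "subjects x",
      nrow(x$sessions), "sessions;",
      sum(!x$present), "missing subject-session(s)\n")
  invisible(x)
}

#' Build a sample design from a cell annotation table
#'
#' Enumerates the (day, session) pairs observed in the annotation in
#' chronological order and marks a subject-session as present when at least
#' one cell carries that combination.
#'
#' @param annotation Data.frame with columns `subject`, `day`, `session`
#'   (cells with subject `"unassigned"` are ignored).
#' @return A [sample_design()] object.
#' @export
design_from_annotation <- function(annotation) {
  ann <- annotation[annotation$subject != "unassigned" &
                    !is.na(annotation$subject), , drop = FALSE]
  if (!nrow(ann)) .cb_stop("no subject-assigned cells in annotation")
  subjects <- sort(unique(ann$subject))
  d <- sample_design(subjects, n_days = max(ann$day))
  seen <- unique(ann[, c("subject", "day", "session")])
  seen_id <- paste0("D", seen$day, "_", seen$session)
  d$present[] <- FALSE
  d$present[cbind(match(seen$subject, subjects),
                  match(seen_id, d$sessions$sample))] <- TRUE
  d$n_sessions <- rowSums(d$present)
  d
}
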