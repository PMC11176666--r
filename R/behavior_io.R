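#' @keywords internal
"_PACKAGE"

## Controlled vocabularies for the event-log and physiology schemas.
BEHAVIOR_LEVELS    <- c("AGG", "SUB", "GRO", "PRO")
OBSERVATION_LEVELS <- c("OBS1", "OBS3A", "OBS3B")
TRIPHASE_ANALYTES  <- c("HC", "OT", "AVP", "WEIGHT")
WEEKLY_ANALYTES    <- c("IGG", "IGA")
TRIPHASE_TIMEPOINTS <- c("S1", "S2", "S3")
WEEKLY_TIMEPOINTS   <- c("W0", "W1", "W2", "W3", "W4")

EVENT_LOG_HEADER <- c("group_id", "observation_id", "day",
                      "initiator", "receiver", "behavior", "count")
PHYSIO_HEADER <- c("group_id", "subject_id", "analyte", "timepoint", "value")

#' Validate a behavioral event log
#'
#' Checks a data frame of directed, counted behavior records against the
#' event-log schema: column set, observation and behavior vocabularies,
#' integer day in 1..6, non-negative integer counts, and
#' initiator != receiver. When `roster` is supplied, every initiator and
#' receiver must belong to its group's roster.
#'
#' @param events Data frame with columns
#'   `group_id, observation_id, day, initiator, receiver, behavior, count`.
#' @param roster Optional named list mapping group id to a character vector
#'   of subject ids.
#' @return The validated events, invisibly, with columns coerced to their
#'   canonical types.
#' @export
validate_event_log <- function(events, roster = NULL) {
  missing_cols <- setdiff(EVENT_LOG_HEADER, names(events))
  if (length(missing_cols) > 0) {
    stop("event log schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  events <- events[EVENT_LOG_HEADER]
  events$group_id <- as.character(events$group_id)
  events$observation_id <- as.character(events$observation_id)
  events$initiator <- as.character(events$initiator)
  events$receiver <- as.character(events$receiver)
  events$behavior <- as.character(events$behavior)

  bad <- which(!events$observation_id %in% OBSERVATION_LEVELS)
  if (length(bad) > 0) {
    stop("event log validation error: unknown observation_id '",
         events$observation_id[bad[1]], "' at row ", bad[1], call. = FALSE)
  }
  bad <- which(!events$behavior %in% BEHAVIOR_LEVELS)
  if (length(bad) > 0) {
    stop("event log validation error: unknown behavior code '",
         events$behavior[bad[1]], "' at row ", bad[1], call. = FALSE)
  }
  day <- suppressWarnings(as.integer(events$day))
  bad <- which(is.na(day) | day < 1L | day > 6L | day != as.numeric(events$day))
  if (length(bad) > 0) {
    stop("event log validation error: day must be an integer in 1..6 (row ",
         bad[1], ")", call. = FALSE)
  }
  events$day <- day
  count <- suppressWarnings(as.numeric(events$count))
  bad <- which(is.na(count) | count < 0 | count != floor(count))
  if (length(bad) > 0) {
    stop("event log validation error: count must be a non-negative integer ",
         "(row ", bad[1], ")", call. = FALSE)
  }
  events$count <- as.integer(count)
  bad <- which(events$initiator == events$receiver)
  if (length(bad) > 0) {
    stop("event log validation error: initiator equals receiver ('",
         events$initiator[bad[1]], "') at row ", bad[1], call. = FALSE)
  }
  if (!is.null(roster)) {
    for (g in unique(events$group_id)) {
      rows <- events$group_id == g
      if (is.null(roster[[g]])) {
        stop("event log validation error: group '", g,
             "' absent from roster", call. = FALSE)
      }
      strangers <- setdiff(
        unique(c(events$initiator[rows], events$receiver[rows])), roster[[g]])
      if (length(strangers) > 0) {
        stop("event log validation error: subject(s) ",
             paste(strangers, collapse = ", "),
             " not on the roster of group '", g, "'", call. = FALSE)
      }
    }
  }
  rownames(events) <- NULL
  invisible(events)
}

#' Read a behavioral event log from CSV
#'
#' The file must be UTF-8 CSV with the exact header
#' `group_id,observation_id,day,initiator,receiver,behavior,count`.
#' Each row is one directed, counted record: `initiator` performed
#' `behavior` toward `receiver` `count` times on `day` (1..6) of the given
#' observation period. Duplicate (day, initiator, receiver, behavior) rows
#' are legal and are summed at aggregation time.
#'
#' @inheritParams validate_event_log
#' @param path Path to the CSV file.
#' @return A data frame of validated events, row order preserved.
#' @seealso [aggregate_interactions()], [write_event_log()]
#' @export
read_event_log <- function(path, roster = NULL) {
  if (!file.exists(path)) stop("event log file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  extra <- setdiff(names(raw), EVENT_LOG_HEADER)
  if (length(extra) > 0) {
    stop("event log schema error: unexpected column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  ev <- validate_event_log(raw, roster = roster)
  ev
}

#' Write a behavioral event log to CSV
#'
#' @param events Validated event data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  events <- validate_event_log(events)
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Roster of a group inferred from an event log
#'
#' Subjects appearing as initiator or receiver in the group's rows, in
#' first-appearance order.
#'
#' @param events Event data frame.
#' @param group_id Group identifier; defaults to the single group present.
#' @return Character vector of subject ids.
#' @export
event_roster <- function(events, group_id = NULL) {
  if (is.null(group_id)) {
    group_id <- unique(events$group_id)
    if (length(group_id) != 1) {
      stop("events span multiple groups; give group_id explicitly",
           call. = FALSE)
    }
  }
  rows <- events$group_id == group_id
  unique(c(rbind(events$initiator[rows], events$receiver[rows])))
}

#' Aggregate an event log into a directed interaction matrix
#'
#' Sums counts over the six observation days into a square matrix
#' `M[i, j]` = frequency of `behavior` initiated by subject i toward
#' subject j during `observation_id`. Dyads with no matching events get 0;
#' the diagonal is structurally zero.
#'
#' @param events Event data frame from a single group.
#' @param behavior One of `"AGG"`, `"SUB"`, `"GRO"`, `"PRO"`.
#' @param observation_id One of `"OBS1"`, `"OBS3A"`, `"OBS3B"`.
#' @param roster Optional subject ordering; defaults to first-appearance
#'   order in the full log so matrices from different observations align.
#' @return An `interaction_matrix`: an integer matrix with `behavior`,
#'   `observation_id` and `group_id` attributes.
#' @export
aggregate_interactions <- function(events, behavior, observation_id,
                                   roster = NULL) {
  behavior <- match.arg(behavior, BEHAVIOR_LEVELS)
  observation_id <- match.arg(observation_id, OBSERVATION_LEVELS)
  events <- validate_event_log(events)
  groups <- unique(events$group_id)
  if (length(groups) != 1) {
    stop("aggregate_interactions expects events from a single group, got: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  if (is.null(roster)) roster <- event_roster(events, groups)
  n <- length(roster)
  M <- matrix(0L, n, n, dimnames = list(roster, roster))
  sel <- events$behavior == behavior & events$observation_id == observation_id
  if (any(sel)) {
    sub <- events[sel, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      M[sub$initiator[k], sub$receiver[k]] <-
        M[sub$initiator[k], sub$receiver[k]] + sub$count[k]
    }
  }
  structure(M, class = c("interaction_matrix", class(M)),
            behavior = behavior, observation_id = observation_id,
            group_id = groups)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("<interaction_matrix> %s / %s / group %s (%d subjects, total %d)\n",
              attr(x, "behavior"), attr(x, "observation_id"),
              attr(x, "group_id"), nrow(x), sum(x)))
  print(unclass(x))
  invisible(x)
}

#' Validate a longitudinal physiology panel
#'
#' Long-format measurements, one row per subject x analyte x timepoint.
#' Hair cortisol (HC), plasma oxytocin (OT) and vasopressin (AVP), and body
#' weight follow the three-sample schedule S1..S3 (end of baseline, end of
#' isolation, end of recovery); fecal IgG and IgA follow the five weekly
#' samples W0..W4 taken during isolation. Every subject must carry the
#' complete schedule for each analyte it has, and values must be
#' non-negative.
#'
#' @param panel Data frame with columns
#'   `group_id, subject_id, analyte, timepoint, value`.
#' @return The validated panel, invisibly.
#' @export
validate_physio_panel <- function(panel) {
  missing_cols <- setdiff(PHYSIO_HEADER, names(panel))
  if (length(missing_cols) > 0) {
    stop("physiology schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  panel <- panel[PHYSIO_HEADER]
  panel$group_id <- as.character(panel$group_id)
  panel$subject_id <- as.character(panel$subject_id)
  panel$analyte <- as.character(panel$analyte)
  panel$timepoint <- as.character(panel$timepoint)
  panel$value <- as.numeric(panel$value)

  all_analytes <- c(TRIPHASE_ANALYTES, WEEKLY_ANALYTES)
  bad <- which(!panel$analyte %in% all_analytes)
  if (length(bad) > 0) {
    stop("physiology validation error: unknown analyte '",
         panel$analyte[bad[1]], "' at row ", bad[1], call. = FALSE)
  }
  tri <- panel$analyte %in% TRIPHASE_ANALYTES
  bad <- which(tri & !panel$timepoint %in% TRIPHASE_TIMEPOINTS)
  if (length(bad) > 0) {
    stop("physiology validation error: analyte ", panel$analyte[bad[1]],
         " requires timepoints S1..S3, got '", panel$timepoint[bad[1]],
         "' at row ", bad[1], call. = FALSE)
  }
  bad <- which(!tri & !panel$timepoint %in% WEEKLY_TIMEPOINTS)
  if (length(bad) > 0) {
    stop("physiology validation error: analyte ", panel$analyte[bad[1]],
         " requires timepoints W0..W4, got '", panel$timepoint[bad[1]],
         "' at row ", bad[1], call. = FALSE)
  }
  if (anyNA(panel$value) || any(panel$value < 0)) {
    stop("physiology validation error: values must be non-negative numbers",
         call. = FALSE)
  }
  expected <- ifelse(panel$analyte %in% TRIPHASE_ANALYTES, 3L, 5L)
  key <- paste(panel$subject_id, panel$analyte)
  cnt <- table(key)
  need <- tapply(expected, key, unique)
  short <- names(cnt)[as.integer(cnt) != unlist(need)[names(cnt)]]
  if (length(short) > 0) {
    stop("physiology validation error: incomplete or duplicated schedule for ",
         short[1], call. = FALSE)
  }
  rownames(panel) <- NULL
  invisible(panel)
}

#' Read a physiology panel from CSV
#'
#' Header must be exactly `group_id,subject_id,analyte,timepoint,value`.
#'
#' @param path Path to the CSV file.
#' @return A validated long-format data frame.
#' @export
read_physio_panel <- function(path) {
  if (!file.exists(path)) stop("physiology file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  extra <- setdiff(names(raw), PHYSIO_HEADER)
  if (length(extra) > 0) {
    stop("physiology schema error: unexpected column(s) ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  validate_physio_panel(raw)
}

#' Write a physiology panel to CSV
#'
#' @param panel Validated panel data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_physio_panel <- function(panel, path) {
  panel <- validate_physio_panel(panel)
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
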