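# Session container and bundle I/O.
#
# A VR stress session carries four multi-rate traces on one clock (seconds
# from session start): controller motion (~90 Hz), discrete input events,
# an optional GSR trace (~5 Hz, microsiemens), and the stressor schedule.

SESSION_CONDITIONS <- c("baseline", "red_light", "time_pressure", "high_stress")
EVENT_KINDS <- c("prompt", "action", "success", "failure")
STRESSOR_KINDS <- c("red_light", "alarm", "time_pressure")
CLASS_LEVELS <- c("Negative", "Neutral", "Positive")

#' Construct and validate a VR stress session
#'
#' Bundles the multi-rate traces of one session into a validated `vr_session`
#' object. All traces share one clock: seconds from session start.
#'
#' @param id Session identifier (scalar character).
#' @param condition One of `"baseline"`, `"red_light"`, `"time_pressure"`,
#'   `"high_stress"`. A baseline session must have an empty stressor table.
#' @param motion Tibble with columns `t, x, y, z` — controller positions in
#'   tracker units, `t` strictly increasing.
#' @param events Tibble with columns `t, kind, task_id`; `kind` is one of
#'   `"prompt"`, `"action"`, `"success"`, `"failure"`, sorted by `t`.
#' @param gsr Optional tibble with columns `t, conductance_uS`
#'   (nonnegative, `t` strictly increasing), or `NULL` for behavior-only
#'   sessions.
#' @param stressors Tibble with columns `t_onset, kind, duration`; `kind` is
#'   one of `"red_light"`, `"alarm"`, `"time_pressure"`, `duration > 0`.
#' @param class_label Optional stress class, one of `"Negative"`,
#'   `"Neutral"`, `"Positive"`.
#' @return A `vr_session` object (a named list of tibbles plus metadata).
#' @seealso [read_session()], [write_session()], [derive_trials()]
#' @export
vr_session <- function(id, condition, motion, events, gsr = NULL,
                       stressors = NULL, class_label = NULL) {
  if (is.null(stressors)) {
    stressors <- tibble::tibble(t_onset = double(), kind = character(),
                                duration = double())
  }
  s <- structure(
    list(
      id = as.character(id),
      condition = condition,
      class_label = class_label,
      motion = tibble::as_tibble(motion),
      events = tibble::as_tibble(events),
      gsr = if (!is.null(gsr)) tibble::as_tibble(gsr),
      stressors = tibble::as_tibble(stressors)
    ),
    class = "vr_session"
  )
  validate_session(s)
}

#' @export
print.vr_session <- function(x, ...) {
  cat("<vr_session> ", x$id, "  condition: ", x$condition,
      if (!is.null(x$class_label)) paste0("  class: ", x$class_label), "\n",
      sep = "")
  cat("  motion:    ", nrow(x$motion), " samples\n", sep = "")
  cat("  events:    ", nrow(x$events), " events\n", sep = "")
  cat("  gsr:       ",
      if (is.null(x$gsr)) "absent (behavior-only)"
      else paste0(nrow(x$gsr), " samples"), "\n", sep = "")
  cat("  stressors: ", nrow(x$stressors), "\n", sep = "")
  invisible(x)
}

#' Session end time (last observed sample or event)
#' @param session A `vr_session`.
#' @return Scalar time in seconds.
#' @export
session_end <- function(session) {
  max(0, session$motion$t, session$events$t,
      if (!is.null(session$gsr)) session$gsr$t,
      session$stressors$t_onset + session$stressors$duration)
}

check_sorted <- function(t, what, strict = TRUE) {
  if (length(t) == 0) return(invisible(TRUE))
  if (any(t < 0)) {
    stop(what, ": negative timestamp at row ", which(t < 0)[1], call. = FALSE)
  }
  bad <- if (strict) which(diff(t) <= 0) else which(diff(t) < 0)
  if (length(bad) > 0) {
    stop(what, ": timestamps out of order at row ", bad[1] + 1, call. = FALSE)
  }
  invisible(TRUE)
}

#' Validate a session against its invariants
#'
#' Checks monotone timestamps, closed kind sets, nonnegative conductance,
#' the baseline-has-no-stressors rule and stressor onsets within the session
#' span. Called by [vr_session()] and [read_session()]; exported so mutated
#' or hand-built objects can be re-checked.
#'
#' @param session A candidate `vr_session`.
#' @return The session, invisibly coerced to class `vr_session`, or an error
#'   naming the violated invariant and offending row.
#' @export
validate_session <- function(session) {
  stopifnot(is.list(session))
  if (!is.character(session$id) || length(session$id) != 1) {
    stop("session id must be a scalar character", call. = FALSE)
  }
  if (!(session$condition %in% SESSION_CONDITIONS)) {
    stop("unknown condition '", session$condition, "' (expected one of ",
         paste(SESSION_CONDITIONS, collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(session$class_label) &&
      !(session$class_label %in% CLASS_LEVELS)) {
    stop("unknown class label '", session$class_label, "'", call. = FALSE)
  }
  m <- session$motion
  if (!all(c("t", "x", "y", "z") %in% names(m))) {
    stop("motion: missing required columns (need t, x, y, z)", call. = FALSE)
  }
  check_sorted(m$t, "motion", strict = TRUE)
  e <- session$events
  if (!all(c("t", "kind", "task_id") %in% names(e))) {
    stop("events: missing required columns (need t, kind, task_id)", call. = FALSE)
  }
  check_sorted(e$t, "events", strict = FALSE)
  bad_kind <- which(!(e$kind %in% EVENT_KINDS))
  if (length(bad_kind) > 0) {
    stop("events: unknown kind '", e$kind[bad_kind[1]], "' at row ",
         bad_kind[1], call. = FALSE)
  }
  if (!is.null(session$gsr)) {
    g <- session$gsr
    if (!all(c("t", "conductance_uS") %in% names(g))) {
      stop("gsr: missing required columns (need t, conductance_uS)", call. = FALSE)
    }
    check_sorted(g$t, "gsr", strict = TRUE)
    neg <- which(g$conductance_uS < 0)
    if (length(neg) > 0) {
      stop("gsr: negative conductance at row ", neg[1], call. = FALSE)
    }
  }
  st <- session$stressors
  if (!all(c("t_onset", "kind", "duration") %in% names(st))) {
    stop("stressors: missing required columns (need t_onset, kind, duration)",
         call. = FALSE)
  }
  bad_sk <- which(!(st$kind %in% STRESSOR_KINDS))
  if (length(bad_sk) > 0) {
    stop("stressors: unknown kind '", st$kind[bad_sk[1]], "' at row ",
         bad_sk[1], call. = FALSE)
  }
  if (any(st$duration <= 0)) {
    stop("stressors: duration must be > 0 at row ",
         which(st$duration <= 0)[1], call. = FALSE)
  }
  if (session$condition == "baseline" && nrow(st) > 0) {
    stop("baseline session must have an empty stressor schedule", call. = FALSE)
  }
  span <- max(0, m$t, e$t, if (!is.null(session$gsr)) session$gsr$t)
  if (nrow(st) > 0 && any(st$t_onset < 0 | st$t_onset > span)) {
    stop("stressors: onset outside session span at row ",
         which(st$t_onset < 0 | st$t_onset > span)[1], call. = FALSE)
  }
  class(session) <- "vr_session"
  invisible(session)
}

#' Read a session bundle from disk
#'
#' A session bundle is a directory holding `manifest.json`
#' (`id`, `condition`, optional `class_label`) and four comma-separated UTF-8
#' tables with header rows: `motion.csv` (`t,x,y,z`), `events.csv`
#' (`t,kind,task_id`), `stressors.csv` (`t_onset,kind,duration`) and an
#' optional `gsr.csv` (`t,conductance_uS`). A missing `gsr.csv` yields a
#' behavior-only session.
#'
#' @param path Directory containing the bundle.
#' @return A validated [vr_session()].
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("no session bundle at '", path, "'", call. = FALSE)
  manifest_path <- file.path(path, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("bundle is missing manifest.json", call. = FALSE)
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  read_tbl <- function(file, col_types) {
    fp <- file.path(path, file)
    if (!file.exists(fp)) stop("bundle is missing ", file, call. = FALSE)
    readr::read_csv(fp, col_types = col_types, progress = FALSE)
  }
  gsr <- NULL
  if (file.exists(file.path(path, "gsr.csv"))) {
    gsr <- read_tbl("gsr.csv", readr::cols(t = "d", conductance_uS = "d"))
  }
  vr_session(
    id = man$id,
    condition = man$condition,
    class_label = man$class_label,
    motion = read_tbl("motion.csv", readr::cols(t = "d", x = "d", y = "d", z = "d")),
    events = read_tbl("events.csv", readr::cols(t = "d", kind = "c", task_id = "c")),
    gsr = gsr,
    stressors = read_tbl("stressors.csv",
                         readr::cols(t_onset = "d", kind = "c", duration = "d"))
  )
}

#' Write a session bundle to disk
#'
#' Inverse of [read_session()]: `read_session(write_session(s, path))`
#' reproduces `s` field for field.
#'
#' @param session A validated `vr_session`.
#' @param path Destination directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create bundle directory '", path, "'",
                              call. = FALSE)
  man <- list(id = session$id, condition = session$condition)
  if (!is.null(session$class_label)) man$class_label <- session$class_label
  jsonlite::write_json(man, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(session$motion, file.path(path, "motion.csv"), progress = FALSE)
  readr::write_csv(session$events, file.path(path, "events.csv"), progress = FALSE)
  readr::write_csv(session$stressors, file.path(path, "stressors.csv"), progress = FALSE)
  if (!is.null(session$gsr)) {
    readr::write_csv(session$gsr, file.path(path, "gsr.csv"), progress = FALSE)
  }
  invisible(path)
}

#' Derive per-trial records from an event log
#'
#' Segments the event log into trials, one per `prompt` event. A trial's
#' window is half-open: from its prompt up to the next prompt (any task) or
#' the session end. Within the window, `t_first_action` is the first
#' `action` event for the prompted task, `failure_count` counts `failure`
#' events, and the outcome is `success` if a `success` event occurred,
#' `failure` if only failures occurred, and `timeout` otherwise.
#'
#' @param events Event tibble (`t, kind, task_id`) sorted by `t`.
#' @param t_end Session end time; defaults to the last event time.
#' @return A tibble with one row per prompt: `task_id, t_prompt,
#'   t_first_action` (`NA` when no action occurred), `t_end, failure_count,
#'   outcome`.
#' @export
derive_trials <- function(events, t_end = NULL) {
  events <- tibble::as_tibble(events)
  check_sorted(events$t, "events", strict = FALSE)
  if (is.null(t_end)) t_end <- if (nrow(events)) max(events$t) else 0
  prompts <- dplyr::filter(events, .data$kind == "prompt")
  others <- dplyr::filter(events, .data$kind != "prompt")
  if (nrow(others) > 0) {
    # every non-prompt event must follow a prompt for the same task
    orphan <- vapply(seq_len(nrow(others)), function(i) {
      !any(prompts$task_id == others$task_id[i] & prompts$t <= others$t[i])
    }, logical(1))
    if (any(orphan)) {
      stop("orphan ", others$kind[which(orphan)[1]],
           " event with no preceding prompt for task_id '",
           others$task_id[which(orphan)[1]], "'", call. = FALSE)
    }
  }
  if (nrow(prompts) == 0) {
    return(tibble::tibble(task_id = character(), t_prompt = double(),
                          t_first_action = double(), t_end = double(),
                          failure_count = integer(), outcome = character()))
  }
  window_end <- c(prompts$t[-1], max(t_end, prompts$t[nrow(prompts)]))
  purrr::map_dfr(seq_len(nrow(prompts)), function(i) {
    w0 <- prompts$t[i]
    w1 <- window_end[i]
    in_win <- others$t >= w0 & others$t < w1 & others$task_id == prompts$task_id[i]
    ev <- others[in_win, ]
    actions <- ev$t[ev$kind == "action"]
    n_fail <- sum(ev$kind == "failure")
    outcome <- if (any(ev$kind == "success")) "success"
               else if (n_fail > 0) "failure" else "timeout"
    tibble::tibble(
      task_id = prompts$task_id[i],
      t_prompt = w0,
      t_first_action = if (length(actions)) min(actions) else NA_real_,
      t_end = w1,
      failure_count = n_fail,
      outcome = outcome
    )
  })
}
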