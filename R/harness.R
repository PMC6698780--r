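# Trial/block session skeleton: present a stimulus, store its onset, wait
# for a response, store the reaction time, wait out the inter-trial
# interval; finally write everything as TSV. All timestamps come from the
# injected clock, never from the wall clock, so scripted sessions recover
# latencies exactly.

#' Specify one trial
#'
#' @param stimulus The stimulus screen (an element, raw image, or `NULL`).
#' @param valid_keys Non-empty character vector of accepted response keys.
#' @param iti Inter-trial interval in seconds (>= 0): the pause enforced
#'   after this trial's response. By convention the last trial of a block has
#'   `iti = 0`.
#' @param timeout Optional response timeout in seconds; `NULL` (default)
#'   waits indefinitely.
#' @param background Background color of the composed screen.
#' @return A trial specification (class `"sc_trial_spec"`).
#' @export
trial_spec <- function(stimulus, valid_keys, iti = 0, timeout = NULL,
                       background = "#FFFFFF") {
  if (!is.character(valid_keys) || length(valid_keys) == 0L)
    abort_invalid("valid_keys must be a non-empty character vector")
  check_scalar_number(iti, "iti", min = 0)
  if (!is.null(timeout)) check_scalar_number(timeout, "timeout", strict_min = 0)
  structure(list(stimulus = stimulus, valid_keys = valid_keys, iti = iti,
                 timeout = timeout, background = parse_color(background)),
            class = "sc_trial_spec")
}

#' Run a block of trials
#'
#' For each trial: composes and presents the stimulus, stores the onset
#' (seconds since `session_start` on the listener's clock), waits for one of
#' the trial's valid keys, stores the reaction time (response timestamp minus
#' onset), then waits out the trial's inter-trial interval. A response
#' timeout yields `NA` response and `NA` rt. If the subject aborts (quit
#' event), the abort propagates with the completed records attached to the
#' condition as field `records`.
#'
#' @param trials List of [trial_spec()]s. The last trial's `iti` should be 0;
#'   a nonzero value is tolerated with a warning.
#' @param listener An [event_listener()].
#' @param context A display context from [display_init()] (its resolution
#'   sizes the composed screens).
#' @param block Block index recorded in the results (default 1).
#' @param session_start Clock time of session start; defaults to the clock's
#'   current time.
#' @return A data frame with one row per trial: `block`, `trial`, `onset`,
#'   `response` (key, or `NA` on timeout), `rt` (seconds, or `NA` on
#'   timeout).
#' @export
run_block <- function(trials, listener, context = display_context(),
                      block = 1L, session_start = NULL) {
  if (!is.list(trials) || length(trials) == 0L ||
      !all(vapply(trials, inherits, TRUE, "sc_trial_spec")))
    abort_invalid("trials must be a non-empty list of trial_spec objects")
  if (!inherits(listener, "sc_event_listener"))
    abort_invalid("listener must be an event listener")
  n <- length(trials)
  if (trials[[n]]$iti != 0)
    warning("last trial's inter-trial interval is not zero", call. = FALSE)
  clock <- listener$clock
  if (is.null(session_start)) session_start <- clock$now()
  done <- new.env(parent = emptyenv())
  done$records <- data.frame(block = integer(0), trial = integer(0),
                             onset = numeric(0), response = character(0),
                             rt = numeric(0), stringsAsFactors = FALSE)
  tryCatch(
    for (i in seq_len(n)) {
      tr <- trials[[i]]
      buf <- pixel_buffer(context$resolution[1], context$resolution[2],
                          tr$background)
      compose(tr$stimulus, buf)
      display_show(buf)
      onset_abs <- clock$now()
      resp <- wait_for_keys(listener, tr$valid_keys, tr$timeout)
      row <- if (is_timeout(resp))
        data.frame(block = as.integer(block), trial = i,
                   onset = onset_abs - session_start,
                   response = NA_character_, rt = NA_real_,
                   stringsAsFactors = FALSE)
      else
        data.frame(block = as.integer(block), trial = i,
                   onset = onset_abs - session_start,
                   response = as.character(resp),
                   rt = attr(resp, "time") - onset_abs,
                   stringsAsFactors = FALSE)
      done$records <- rbind(done$records, row)
      wait_for_seconds(listener, tr$iti)
    },
    sc_user_abort = function(cond) {
      # flush what completed before propagating the abort
      cond$records <- done$records
      stop(cond)
    })
  done$records
}

#' Write trial records as TSV
#'
#' Writes a tab-separated file with header
#' `subject  block  trial  onset  response  rt`; onsets and reaction times as
#' decimal seconds with 6 places, missing responses/rts as `NA`, one row per
#' record in input order.
#'
#' @param records Data frame from [run_block()] (or several, row-bound).
#' @param subject Subject identifier written into every row.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, subject, path) {
  if (!is.data.frame(records))
    abort_invalid("records must be a data frame")
  needed <- c("block", "trial", "onset", "response", "rt")
  if (!all(needed %in% names(records)))
    abort_invalid(sprintf("records must have columns %s",
                          paste(needed, collapse = ", ")))
  fmt6 <- function(x) ifelse(is.na(x), "NA", formatC(x, format = "f", digits = 6))
  out <- data.frame(
    subject = as.character(subject),
    block = records$block,
    trial = records$trial,
    onset = fmt6(records$onset),
    response = ifelse(is.na(records$response), "NA", records$response),
    rt = fmt6(records$rt),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort_io(sprintf("cannot write results to %s", path))
  invisible(path)
}

#' Read back a TSV results file
#'
#' Inverse of [write_results()]: parses the TSV into a data frame with
#' numeric onsets/rts (`NA` where written as `NA`).
#'
#' @param path Path to a results TSV.
#' @return A data frame.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("no such results file: %s", path))
  utils::read.table(path, header = TRUE, sep = "\t",
                    colClasses = c(subject = "character",
                                   response = "character"),
                    na.strings = "NA", stringsAsFactors = FALSE)
}
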