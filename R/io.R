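#' Render and parse feedback identifiers
#'
#' Every feedback period has a stable identifier of the form
#' `"S<subject>_Sess<NN>_FB<NNN>"` (session zero-padded to 2 digits,
#' feedback index to 3). `feedback_id()` renders; `parse_feedback_id()`
#' inverts it, so the two are a round-trip identity.
#'
#' @param subject_id character subject label (e.g. `"02"`).
#' @param session session number 1-5.
#' @param feedback_index feedback index within the session (>= 1).
#' @return `feedback_id()`: character vector of ids. `parse_feedback_id()`:
#'   data.frame with columns `subject_id`, `session`, `feedback_index`.
#' @export
feedback_id <- function(subject_id, session, feedback_index) {
  stopifnot(all(session %in% 1:5), all(feedback_index >= 1))
  sprintf("S%s_Sess%02d_FB%03d", subject_id, as.integer(session),
          as.integer(feedback_index))
}

#' @rdname feedback_id
#' @param id character vector of rendered identifiers.
#' @export
parse_feedback_id <- function(id) {
  m <- regmatches(id, regexec("^S(.+)_Sess([0-9]{2})_FB([0-9]{3})$", id))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    stop("malformed feedback id: ", id[bad][1], call. = FALSE)
  }
  data.frame(subject_id = vapply(m, `[`, "", 2L),
             session = as.integer(vapply(m, `[`, "", 3L)),
             feedback_index = as.integer(vapply(m, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Write / read a continuous recording as CSV
#'
#' The on-disk dialect is one CSV per session: a `Time` column in seconds
#' at 5 ms steps, one column per scalp channel in montage order, an `EOG`
#' column, and a binary `FeedBackEvent` column with a 1 at each feedback
#' onset sample. `read_recording()` validates the header, time axis and
#' marker track and rejects malformed files rather than repairing them;
#' channels are matched by header name, not position.
#'
#' @param rec an `errp_recording`.
#' @param path file path.
#' @return `read_recording()` returns an `errp_recording`; round-tripping
#'   reproduces samples to better than 1e-6 uV and markers exactly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "errp_recording"))
  n <- ncol(rec$samples)
  dt <- data.table::as.data.table(t(rec$samples))
  data.table::setnames(dt, rec$channel_names)
  dt[, Time := (seq_len(n) - 1) / rec$sampling_rate]
  dt[, FeedBackEvent := rec$feedback_marker]
  data.table::setcolorder(dt, c("Time", rec$channel_names, "FeedBackEvent"))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  dt <- data.table::fread(path)
  expected <- c("Time", montage_channels(), "EOG", "FeedBackEvent")
  if (anyDuplicated(names(dt))) {
    stop("duplicated header field: ",
         names(dt)[duplicated(names(dt))][1], call. = FALSE)
  }
  missing <- setdiff(expected, names(dt))
  if (length(missing)) {
    stop("missing header field: ", missing[1], call. = FALSE)
  }
  tt <- dt$Time
  dt_step <- 1 / FS_HZ
  if (length(tt) > 1) {
    dev <- abs(diff(tt) - dt_step)
    if (any(dev > dt_step)) {
      stop("non-uniform Time column at row ",
           which(dev > dt_step)[1] + 1L,
           ": expected ", dt_step, " s steps", call. = FALSE)
    }
    if (any(diff(tt) <= 0)) {
      stop("non-monotone Time column at row ",
           which(diff(tt) <= 0)[1] + 1L, call. = FALSE)
    }
  }
  fb <- dt$FeedBackEvent
  if (!all(fb %in% c(0, 1))) {
    stop("FeedBackEvent outside {0,1} at row ",
         which(!fb %in% c(0, 1))[1], call. = FALSE)
  }
  ch <- c(montage_channels(), "EOG")
  samples <- t(as.matrix(dt[, ch, with = FALSE]))
  dimnames(samples) <- NULL
  new_recording(samples, ch, as.integer(fb))
}

#' Write a session plan as a TSV metadata table
#'
#' One row per trial carrying all trial metadata fields, keyed by the
#' rendered feedback id.
#'
#' @param plan a session plan (or row-bound plans) from
#'   [make_session_plan()].
#' @param path file path.
#' @export
write_plan <- function(plan, path) {
  out <- cbind(
    IdFeedBack = feedback_id(plan$subject_id, plan$session,
                             plan$feedback_index),
    plan)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  as.data.frame(dt[, !"IdFeedBack"])
}

#' Read trial labels / write prediction files
#'
#' Labels and predictions share a two-column CSV dialect,
#' `IdFeedBack,Prediction`. In a label file `Prediction` is the binary
#' class (1 = Error, 0 = NoError); in a prediction file it is the
#' posterior probability of the Error class, so that downstream ROC
#' analysis remains possible. Prediction rows are written sorted by id.
#'
#' @param path file path.
#' @return `read_labels()`: a named integer vector (1 = Error) keyed by
#'   feedback id.
#' @export
read_labels <- function(path) {
  dt <- data.table::fread(path)
  if (!all(c("IdFeedBack", "Prediction") %in% names(dt))) {
    stop("label file must have columns IdFeedBack,Prediction",
         call. = FALSE)
  }
  if (anyDuplicated(dt$IdFeedBack)) {
    stop("duplicate feedback id: ",
         dt$IdFeedBack[duplicated(dt$IdFeedBack)][1], call. = FALSE)
  }
  if (!all(dt$Prediction %in% c(0, 1))) {
    stop("labels must be 0/1; offending id: ",
         dt$IdFeedBack[!dt$Prediction %in% c(0, 1)][1], call. = FALSE)
  }
  stats::setNames(as.integer(dt$Prediction), dt$IdFeedBack)
}

#' @rdname read_labels
#' @param records data.frame with columns `id` and `posterior_error` (and
#'   optionally `label`), one row per feedback.
#' @export
write_predictions <- function(records, path) {
  stopifnot(all(c("id", "posterior_error") %in% names(records)))
  if (anyDuplicated(records$id)) {
    stop("duplicate feedback id: ",
         records$id[duplicated(records$id)][1], call. = FALSE)
  }
  bad <- records$posterior_error < 0 | records$posterior_error > 1
  if (any(bad)) {
    stop("posterior outside [0,1] for id: ", records$id[bad][1],
         call. = FALSE)
  }
  ord <- order(records$id)
  out <- data.frame(IdFeedBack = records$id[ord],
                    Prediction = records$posterior_error[ord])
  data.table::fwrite(out, path)
  invisible(path)
}

#' @rdname read_labels
#' @export
read_predictions <- function(path) {
  dt <- data.table::fread(path)
  if (!all(c("IdFeedBack", "Prediction") %in% names(dt))) {
    stop("prediction file must have columns IdFeedBack,Prediction",
         call. = FALSE)
  }
  if (anyDuplicated(dt$IdFeedBack)) {
    stop("duplicate feedback id: ",
         dt$IdFeedBack[duplicated(dt$IdFeedBack)][1], call. = FALSE)
  }
  stats::setNames(as.numeric(dt$Prediction), dt$IdFeedBack)
}
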