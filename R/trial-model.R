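#' @title Core data model for motion trials and labels
#' @name codseg-model
#' @description
#' All frame indices handled by this package are **0-based** and refer to the
#' ordinary motion frames of a recording (calibration poses excluded). This
#' matches the frame numbering of MVNX exports and keeps indices stable across
#' readers; R's 1-based vectors are an internal detail.
NULL

CONTACT_CHANNELS <- c("left_heel", "left_toe", "right_heel", "right_toe")
TEST_TYPES <- c("VCUT", "VCUT_BK")

#' Construct a motion trial
#'
#' A `motion_trial` holds the per-frame trunk velocity components in the
#' horizontal plane plus four binary foot-contact channels (heel and toe point
#' per foot, 1 = ground contact) sampled at a common frame rate.
#'
#' @param trial_id Character scalar identifying the trial.
#' @param frame_rate Sampling rate in Hz (positive).
#' @param trunk_vx,trunk_vy Numeric vectors, trunk velocity components (m/s)
#'   along the global horizontal axes, one value per frame.
#' @param contacts Named list of four 0/1 integer vectors
#'   (`left_heel`, `left_toe`, `right_heel`, `right_toe`), same length as the
#'   velocity series.
#' @param test_type `"VCUT"` (plain agility sprint) or `"VCUT_BK"` (with ball
#'   dribbling).
#' @param meta Named list of free-form metadata (gender, team category,
#'   repetition, ...).
#' @return An object of class `motion_trial` with fields `trial_id`,
#'   `test_type`, `frame_rate`, `n_frames`, `trunk_vx`, `trunk_vy`,
#'   `contacts`, `meta`.
#' @export
motion_trial <- function(trial_id, frame_rate, trunk_vx, trunk_vy, contacts,
                         test_type = "VCUT", meta = list()) {
  stopifnot(is.character(trial_id), length(trial_id) == 1L)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L || frame_rate <= 0)
    stop("frame_rate must be a positive scalar (Hz)")
  test_type <- match.arg(test_type, TEST_TYPES)
  trunk_vx <- as.numeric(trunk_vx)
  trunk_vy <- as.numeric(trunk_vy)
  n <- length(trunk_vx)
  if (n < 2L) stop("a trial needs at least 2 frames")
  if (length(trunk_vy) != n)
    stop("trunk_vx and trunk_vy differ in length")
  if (!is.list(contacts) || !all(CONTACT_CHANNELS %in% names(contacts)))
    stop("contacts must be a named list with channels: ",
         paste(CONTACT_CHANNELS, collapse = ", "))
  contacts <- contacts[CONTACT_CHANNELS]
  for (ch in CONTACT_CHANNELS) {
    v <- contacts[[ch]]
    if (length(v) != n)
      stop("contact channel '", ch, "' has length ", length(v),
           ", expected ", n)
    if (anyNA(v) || !all(v %in% c(0, 1)))
      stop("contact channel '", ch, "' contains values outside {0, 1}")
    contacts[[ch]] <- as.integer(v)
  }
  structure(
    list(trial_id = trial_id, test_type = test_type,
         frame_rate = as.numeric(frame_rate), n_frames = n,
         trunk_vx = trunk_vx, trunk_vy = trunk_vy,
         contacts = contacts, meta = meta),
    class = "motion_trial")
}

#' @export
print.motion_trial <- function(x, ...) {
  cat(sprintf("<motion_trial> %s (%s): %d frames @ %g Hz (%.2f s)\n",
              x$trial_id, x$test_type, x$n_frames, x$frame_rate,
              x$n_frames / x$frame_rate))
  invisible(x)
}

#' Construct manual COD labels
#'
#' Gold-standard initial/final frames of each change of direction, as
#' produced by manual video annotation. Frames are 0-based motion-frame
#' indices.
#'
#' @param trial_id Character scalar, the trial these labels belong to.
#' @param events Data frame with integer columns `cod_index`, `if_frame`,
#'   `ff_frame`; one row per COD.
#' @return An object of class `manual_labels`.
#' @export
manual_labels <- function(trial_id, events) {
  stopifnot(is.character(trial_id), length(trial_id) == 1L)
  req <- c("cod_index", "if_frame", "ff_frame")
  if (!is.data.frame(events) || !all(req %in% names(events)))
    stop("events must be a data frame with columns: ",
         paste(req, collapse = ", "))
  events <- events[req]
  for (col in req) events[[col]] <- as.integer(events[[col]])
  if (anyDuplicated(events$cod_index))
    stop("duplicate cod_index in manual labels")
  bad <- which(events$if_frame >= events$ff_frame)
  if (length(bad))
    stop("if_frame must precede ff_frame (violated for cod_index ",
         paste(events$cod_index[bad], collapse = ", "), ")")
  if (any(events$if_frame < 0L))
    stop("negative frame index in manual labels")
  events <- events[order(events$if_frame), , drop = FALSE]
  rownames(events) <- NULL
  structure(list(trial_id = trial_id, events = events),
            class = "manual_labels")
}

#' @export
print.manual_labels <- function(x, ...) {
  cat(sprintf("<manual_labels> %s: %d CODs\n", x$trial_id, nrow(x$events)))
  print(x$events)
  invisible(x)
}

#' Construct a segmentation result
#'
#' The output of [detect_cods()]: one row per detected COD event, ordered by
#' the frame of the qualifying velocity minimum.
#'
#' @param trial_id Character scalar.
#' @param params The [detection_params()] used.
#' @param events Data frame with columns `cod_index`, `minimum_frame`,
#'   `if_frame`, `ff_frame` (`NA` = undetected), `pfc_side`, `ffc_side`
#'   (`"left"`/`"right"`/`NA`), `status` (one of `"COMPLETE"`, `"IF_MISSING"`,
#'   `"FF_MISSING"`, `"BOTH_MISSING"`).
#' @param frame_rate Hz of the underlying trial (kept for time conversion).
#' @param test_type Test condition of the underlying trial.
#' @return An object of class `segmentation_result`.
#' @export
segmentation_result <- function(trial_id, params, events,
                                frame_rate = NA_real_, test_type = "VCUT") {
  req <- c("cod_index", "minimum_frame", "if_frame", "ff_frame",
           "pfc_side", "ffc_side", "status")
  if (!is.data.frame(events) || !all(req %in% names(events)))
    stop("events must be a data frame with columns: ",
         paste(req, collapse = ", "))
  events <- events[req]
  if (nrow(events)) {
    if (is.unsorted(events$minimum_frame, strictly = TRUE))
      stop("events must be strictly ordered by minimum_frame")
  }
  structure(
    list(trial_id = trial_id, params_used = params, events = events,
         frame_rate = as.numeric(frame_rate), test_type = test_type),
    class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %s: %d events (prominence %g, region -%d/+%d)\n",
              x$trial_id, nrow(x$events), x$params_used$prominence,
              x$params_used$region_before, x$params_used$region_after))
  print(x$events)
  invisible(x)
}
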