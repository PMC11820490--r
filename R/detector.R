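#' Detection parameters
#'
#' Configuration of the COD detector. The search-region bounds are defined in
#' frames at `reference_rate` and rescaled proportionally when a trial is
#' sampled at a different rate, so the temporal window stays physically
#' constant.
#'
#' @param prominence Minimum prominence (m/s) of a filtered-speed trough to
#'   qualify as a COD candidate. Default 1.5, the tuned optimum.
#' @param region_before,region_after Search-region extent in frames at the
#'   reference rate, before and after the velocity minimum. Defaults 40 and
#'   25, the tuned optimum (-40..+25).
#' @param cutoff Low-pass cut-off frequency in Hz (default 1.5).
#' @param filter_order Butterworth order of a single pass (default 4,
#'   applied two-way).
#' @param reference_rate Frame rate (Hz) at which the region bounds are
#'   expressed (default 60).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(prominence = 1.5, region_before = 40,
                             region_after = 25, cutoff = 1.5,
                             filter_order = 4, reference_rate = 60) {
  if (prominence <= 0) stop("prominence must be positive")
  if (region_before <= 0 || region_after <= 0)
    stop("region bounds must be positive")
  structure(list(prominence = prominence,
                 region_before = as.integer(region_before),
                 region_after = as.integer(region_after),
                 cutoff = cutoff, filter_order = as.integer(filter_order),
                 reference_rate = reference_rate),
            class = "detection_params")
}

#' Search region around a velocity minimum
#'
#' Inclusive frame interval scanned for foot-contact transitions, clipped to
#' the trial. Bounds are scaled from the reference rate to the trial's frame
#' rate.
#'
#' @param minimum_frame 0-based frame of the velocity minimum.
#' @param params [detection_params()].
#' @param frame_rate Trial frame rate in Hz.
#' @param n_frames Number of frames in the trial.
#' @return Integer vector `c(lo, hi)`, 0-based inclusive.
#' @export
build_search_region <- function(minimum_frame, params, frame_rate, n_frames) {
  s <- frame_rate / params$reference_rate
  lo <- max(0L, as.integer(minimum_frame - round(params$region_before * s)))
  hi <- min(n_frames - 1L,
            as.integer(minimum_frame + round(params$region_after * s)))
  c(lo, hi)
}

# 0-based frames at which channel `ch` steps 0 -> 1 (value 1 with a unit
# backward difference)
.rising_frames <- function(ch) which(diff(ch) == 1L)

# 0-based frames at which channel `ch` steps 1 -> 0 (first flight frame)
.falling_frames <- function(ch) which(diff(ch) == -1L)

#' Initial-frame detection (heel strike of the penultimate foot contact)
#'
#' Scans the heel channel of the non-cutting (PFC) foot inside
#' `[region lo, minimum_frame]` for rising edges (contact value 1 whose
#' backward difference is 1) and returns the latest one — the heel strike
#' nearest the braking trough.
#'
#' @param contacts The four binary contact channels of a trial.
#' @param region Integer `c(lo, hi)` from [build_search_region()].
#' @param minimum_frame 0-based frame of the velocity minimum.
#' @param pfc_side `"left"` or `"right"`.
#' @return 0-based frame, or `NA_integer_` when no qualifying edge exists.
#' @export
detect_if <- function(contacts, region, minimum_frame, pfc_side) {
  heel <- contacts[[paste0(pfc_side, "_heel")]]
  edges <- .rising_frames(heel)
  edges <- edges[edges >= region[1] & edges <= minimum_frame]
  if (!length(edges)) NA_integer_ else max(edges)
}

#' Final-frame detection (toe off of the final foot contact)
#'
#' Scans the toe channel of the cutting (FFC) foot inside
#' `[minimum_frame, region hi]` for falling edges (contact value 0 with a
#' unit-magnitude backward difference) and returns the earliest one — the
#' first toe off after the trough.
#'
#' @inheritParams detect_if
#' @param ffc_side `"left"` or `"right"`.
#' @return 0-based frame, or `NA_integer_` when no qualifying edge exists.
#' @export
detect_ff <- function(contacts, region, minimum_frame, ffc_side) {
  toe <- contacts[[paste0(ffc_side, "_toe")]]
  edges <- .falling_frames(toe)
  edges <- edges[edges >= minimum_frame & edges <= region[2]]
  if (!length(edges)) NA_integer_ else min(edges)
}

#' Resolve which foot executes the cut
#'
#' The cutting foot (FFC side) is taken as the foot whose toe falling edge is
#' earliest at or after the velocity minimum within the search region; the
#' penultimate contact (PFC) is the contralateral foot. Ties go to the left
#' foot for determinism.
#'
#' @inheritParams detect_if
#' @return List with `pfc` and `ffc`, each `"left"`, `"right"` or `NA`.
#' @export
assign_foot_sides <- function(contacts, region, minimum_frame) {
  first_off <- function(side) {
    e <- .falling_frames(contacts[[paste0(side, "_toe")]])
    e <- e[e >= minimum_frame & e <= region[2]]
    if (length(e)) min(e) else NA_integer_
  }
  l <- first_off("left"); r <- first_off("right")
  if (is.na(l) && is.na(r)) return(list(pfc = NA_character_, ffc = NA_character_))
  ffc <- if (is.na(r) || (!is.na(l) && l <= r)) "left" else "right"
  list(pfc = if (ffc == "left") "right" else "left", ffc = ffc)
}

#' Detect change-of-direction events in a trial
#'
#' Full detection pipeline: trunk horizontal speed, zero-phase low-pass
#' filter, prominence-qualified local minima, then per minimum a search
#' region, cutting-foot resolution, and IF/FF edge detection. Deterministic:
#' the same trial and parameters always yield the same result.
#'
#' @param trial A [motion_trial()].
#' @param params [detection_params()]; defaults are the tuned optimum.
#' @param cut_sides Optional character vector overriding the inferred cutting
#'   foot per event (`"left"`/`"right"`, recycled), for users who know the
#'   cut schedule.
#' @return A [segmentation_result()] whose `events` rows are ordered by
#'   `minimum_frame` with `cod_index` 1..k and a `status` flag per event.
#' @export
detect_cods <- function(trial, params = detection_params(), cut_sides = NULL) {
  stopifnot(inherits(trial, "motion_trial"))
  v <- compute_horizontal_velocity(trial)
  f <- lowpass_filter(v, trial$frame_rate, cutoff = params$cutoff,
                      order = params$filter_order)
  mins <- find_velocity_minima(f, prominence = params$prominence)
  k <- nrow(mins)
  if (!is.null(cut_sides) && k) cut_sides <- rep(cut_sides, length.out = k)
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    m <- mins$frame[i]
    region <- build_search_region(m, params, trial$frame_rate, trial$n_frames)
    if (!is.null(cut_sides)) {
      ffc <- match.arg(cut_sides[i], c("left", "right"))
      sides <- list(pfc = if (ffc == "left") "right" else "left", ffc = ffc)
    } else {
      sides <- assign_foot_sides(trial$contacts, region, m)
    }
    if_f <- if (is.na(sides$pfc)) NA_integer_ else
      detect_if(trial$contacts, region, m, sides$pfc)
    ff_f <- if (is.na(sides$ffc)) NA_integer_ else
      detect_ff(trial$contacts, region, m, sides$ffc)
    status <- if (is.na(if_f) && is.na(ff_f)) "BOTH_MISSING"
      else if (is.na(if_f)) "IF_MISSING"
      else if (is.na(ff_f)) "FF_MISSING"
      else "COMPLETE"
    rows[[i]] <- data.frame(
      cod_index = i, minimum_frame = m, if_frame = if_f, ff_frame = ff_f,
      pfc_side = sides$pfc, ffc_side = sides$ffc, status = status,
      stringsAsFactors = FALSE)
  }
  events <- if (k) do.call(rbind, rows) else
    data.frame(cod_index = integer(0), minimum_frame = integer(0),
               if_frame = integer(0), ff_frame = integer(0),
               pfc_side = character(0), ffc_side = character(0),
               status = character(0), stringsAsFactors = FALSE)
  segmentation_result(trial$trial_id, params, events,
                      frame_rate = trial$frame_rate,
                      test_type = trial$test_type)
}
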