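#' Read a trial from an MVNX motion-capture export
#'
#' Parses the XML dialect exported by full-body inertial motion-capture
#' suites: per-frame segment velocities plus binary foot-contact channels.
#' Only ordinary motion frames (`type="normal"`) are read; calibration poses
#' (npose/tpose/identity) are excluded, and frame indices are 0-based over
#' the motion frames. The trunk segment defaults to the pelvis — the best
#' proxy of whole-body horizontal momentum — but any segment label can be
#' supplied (e.g. `"T8"` for a thoracic segment).
#'
#' @param path Path to the MVNX file.
#' @param trunk_segment Label of the segment whose velocity is used
#'   (default `"Pelvis"`).
#' @param contact_channels Named character vector mapping the four model
#'   channels to contact-point labels in the file.
#' @param trial_id Trial identifier; defaults to the subject label in the
#'   file, else the file name.
#' @return A [motion_trial()]. Velocity components are the file's global x
#'   and y axes (the horizontal plane); no re-orientation is attempted.
#' @export
parse_mvnx <- function(path, trunk_segment = "Pelvis",
                       contact_channels = c(left_heel = "LeftHeel",
                                            left_toe = "LeftToe",
                                            right_heel = "RightHeel",
                                            right_toe = "RightToe"),
                       trial_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- xml2::read_xml(path)          # malformed XML fails here
  xml2::xml_ns_strip(doc)
  subject <- xml2::xml_find_first(doc, ".//subject")
  if (inherits(subject, "xml_missing")) stop("no <subject> element in ", path)
  frame_rate <- as.numeric(xml2::xml_attr(subject, "frameRate"))
  if (!is.finite(frame_rate) || frame_rate <= 0)
    stop("missing or invalid frameRate attribute")

  seg_nodes <- xml2::xml_find_all(doc, ".//segments/segment")
  seg_labels <- xml2::xml_attr(seg_nodes, "label")
  seg_pos <- match(trunk_segment, seg_labels)
  if (is.na(seg_pos))
    stop("segment '", trunk_segment, "' not found; file has: ",
         paste(seg_labels, collapse = ", "))

  cdef <- xml2::xml_find_all(doc, ".//footContactDefinition/contactDefinition")
  if (length(cdef)) {
    cd_labels <- xml2::xml_attr(cdef, "label")
    cd_index <- as.integer(xml2::xml_attr(cdef, "index"))
    col_of <- function(lbl) {
      i <- match(lbl, cd_labels)
      if (is.na(i)) stop("contact channel '", lbl, "' not found; file has: ",
                         paste(cd_labels, collapse = ", "))
      cd_index[i] + 1L
    }
    cols <- vapply(contact_channels, col_of, integer(1))
  } else {
    cols <- c(left_heel = 1L, left_toe = 2L, right_heel = 3L, right_toe = 4L)
  }

  frames <- xml2::xml_find_all(doc, ".//frames/frame[@type='normal']")
  n <- length(frames)
  if (!n) stop("no motion frames (type='normal') in ", path)
  if (n / frame_rate < 1)
    stop("degenerate trial: shorter than 1 s of motion frames")

  vel_txt <- xml2::xml_text(xml2::xml_find_first(frames, "velocity"))
  vel <- lapply(strsplit(trimws(vel_txt), "\\s+"), as.numeric)
  nv <- lengths(vel)
  if (any(nv < 3 * seg_pos))
    stop("velocity vector too short for segment '", trunk_segment, "'")
  vx <- vapply(vel, `[`, numeric(1), 3L * (seg_pos - 1L) + 1L)
  vy <- vapply(vel, `[`, numeric(1), 3L * (seg_pos - 1L) + 2L)

  fc_txt <- xml2::xml_text(xml2::xml_find_first(frames, "footContacts"))
  if (anyNA(fc_txt)) stop("missing <footContacts> in one or more motion frames")
  fc <- lapply(strsplit(trimws(fc_txt), "\\s+"), as.integer)
  fmat <- do.call(rbind, fc)
  if (any(cols > ncol(fmat)))
    stop("footContacts rows have ", ncol(fmat), " values; need column ",
         max(cols))
  contacts <- lapply(cols, function(j) fmat[, j])
  names(contacts) <- names(contact_channels)

  if (is.null(trial_id)) {
    trial_id <- xml2::xml_attr(subject, "label")
    if (is.na(trial_id) || !nzchar(trial_id))
      trial_id <- tools::file_path_sans_ext(basename(path))
  }
  tt <- xml2::xml_attr(subject, "testType")
  test_type <- if (!is.na(tt) && tt %in% TEST_TYPES) tt else "VCUT"
  motion_trial(trial_id, frame_rate, vx, vy, contacts, test_type = test_type)
}

#' Write a trial as a minimal MVNX file
#'
#' Emits the MVNX dialect read back by [parse_mvnx()]: segment definitions,
#' contact-point definitions, `calib_frames` calibration-pose frames followed
#' by the motion frames with per-segment velocities (the vertical component
#' is written as zero) and four binary foot contacts per frame.
#'
#' @param trial A [motion_trial()].
#' @param path Output path.
#' @param calib_frames Number of leading calibration frames (default 3).
#' @return `path`, invisibly.
#' @export
write_mvnx <- function(trial, path, calib_frames = 3L) {
  stopifnot(inherits(trial, "motion_trial"))
  segs <- c("Pelvis", "RightFoot")
  seg_xml <- paste(sprintf('      <segment id="%d" label="%s"/>',
                           seq_along(segs), segs), collapse = "\n")
  cdef <- c("LeftHeel", "LeftToe", "RightHeel", "RightToe")
  cdef_xml <- paste(sprintf('      <contactDefinition index="%d" label="%s"/>',
                            seq_along(cdef) - 1L, cdef), collapse = "\n")
  calib_types <- rep(c("identity", "tpose", "npose"),
                     length.out = max(0L, calib_frames))
  calib_xml <- sprintf(
    '      <frame time="0" index="-1" type="%s"><velocity>%s</velocity></frame>',
    calib_types, paste(rep("0", 3 * length(segs)), collapse = " "))
  t_ms <- round((seq_len(trial$n_frames) - 1L) * 1000 / trial$frame_rate)
  vel <- sprintf("%.17g %.17g 0 0 0 0", trial$trunk_vx, trial$trunk_vy)
  fc <- paste(trial$contacts$left_heel, trial$contacts$left_toe,
              trial$contacts$right_heel, trial$contacts$right_toe)
  frame_xml <- sprintf(
    '      <frame time="%d" index="%d" type="normal"><velocity>%s</velocity><footContacts>%s</footContacts></frame>',
    t_ms, seq_len(trial$n_frames) - 1L, vel, fc)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mvnx version="4">',
    sprintf('  <subject label="%s" frameRate="%g" testType="%s" segmentCount="%d">',
            trial$trial_id, trial$frame_rate, trial$test_type, length(segs)),
    "    <segments>", seg_xml, "    </segments>",
    "    <footContactDefinition>", cdef_xml, "    </footContactDefinition>",
    sprintf('    <frames segmentCount="%d" count="%d">',
            length(segs), trial$n_frames + length(calib_types)),
    calib_xml, frame_xml,
    "    </frames>", "  </subject>", "</mvnx>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a trial from the tabular fallback format
#'
#' Delimited text with one row per frame and header columns `trunk_vx`,
#' `trunk_vy`, `left_heel`, `left_toe`, `right_heel`, `right_toe` — the
#' portable route for motion data exported from other capture systems.
#'
#' @param path Path to the CSV file.
#' @param frame_rate Sampling rate in Hz (tabular files carry no rate).
#' @param trial_id Defaults to the file name without extension.
#' @param test_type `"VCUT"` or `"VCUT_BK"`.
#' @return A [motion_trial()].
#' @export
parse_tabular_trial <- function(path, frame_rate, trial_id = NULL,
                                test_type = "VCUT") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("trunk_vx", "trunk_vy", CONTACT_CHANNELS)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  for (ch in CONTACT_CHANNELS) {
    bad <- which(!(df[[ch]] %in% c(0, 1)))
    if (length(bad))
      stop("contact value outside {0,1} in column '", ch, "' at row ", bad[1])
  }
  if (is.null(trial_id)) trial_id <- tools::file_path_sans_ext(basename(path))
  motion_trial(trial_id, frame_rate, df$trunk_vx, df$trunk_vy,
               as.list(df[CONTACT_CHANNELS]), test_type = test_type)
}

#' Write a trial in the tabular fallback format
#' @param trial A [motion_trial()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tabular_trial <- function(trial, path) {
  stopifnot(inherits(trial, "motion_trial"))
  # full-precision velocities so a read-back reproduces the series exactly
  df <- data.frame(trunk_vx = sprintf("%.17g", trial$trunk_vx),
                   trunk_vy = sprintf("%.17g", trial$trunk_vy),
                   trial$contacts)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read manual COD labels
#'
#' CSV with columns `cod_index`, `if_frame`, `ff_frame` (0-based motion-frame
#' indices in the capture numbering — any video-to-capture offset must be
#' resolved upstream).
#'
#' @param path Path to the labels CSV.
#' @param trial_id Defaults to the file name without extension (a trailing
#'   `.labels` suffix is stripped).
#' @return A [manual_labels()].
#' @export
read_manual_labels <- function(path, trial_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("cod_index", "if_frame", "ff_frame")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (is.null(trial_id)) {
    trial_id <- tools::file_path_sans_ext(basename(path))
    trial_id <- sub("\\.labels$", "", trial_id)
  }
  manual_labels(trial_id, df)
}

#' Write manual COD labels
#' @param labels A [manual_labels()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manual_labels <- function(labels, path) {
  stopifnot(inherits(labels, "manual_labels"))
  utils::write.csv(labels$events, path, row.names = FALSE)
  invisible(path)
}

#' Write a segmentation result (and optional evaluation report) as JSON
#'
#' One record per detected event (cod_index, minimum frame, IF, FF, foot
#' sides, status) plus the parameters used; the metric block is included when
#' a report is given. [read_results()] reproduces the structures exactly.
#'
#' @param result A [segmentation_result()].
#' @param path Output path (`.json`).
#' @param report Optional [evaluate_agreement()] report.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, report = NULL) {
  stopifnot(inherits(result, "segmentation_result"))
  obj <- list(trial_id = result$trial_id,
              test_type = result$test_type,
              frame_rate = result$frame_rate,
              params_used = unclass(result$params_used),
              events = result$events)
  if (!is.null(report)) obj$report <- unclass(report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a segmentation result written by [write_results()]
#' @param path Path to the JSON file.
#' @return List with `result` ([segmentation_result()]) and `report`
#'   (an `evaluation_report` or `NULL`).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- obj$events
  if (is.null(ev) || !NROW(ev)) {
    ev <- data.frame(cod_index = integer(0), minimum_frame = integer(0),
                     if_frame = integer(0), ff_frame = integer(0),
                     pfc_side = character(0), ffc_side = character(0),
                     status = character(0), stringsAsFactors = FALSE)
  } else {
    for (col in c("cod_index", "minimum_frame", "if_frame", "ff_frame"))
      ev[[col]] <- as.integer(ev[[col]])
    for (col in c("pfc_side", "ffc_side", "status"))
      ev[[col]] <- as.character(ev[[col]])
  }
  params <- do.call(detection_params, obj$params_used)
  result <- segmentation_result(obj$trial_id, params, ev,
                                frame_rate = obj$frame_rate %||% NA_real_,
                                test_type = obj$test_type %||% "VCUT")
  report <- if (!is.null(obj$report))
    structure(obj$report, class = "evaluation_report") else NULL
  list(result = result, report = report)
}

#' Write detected events as a CSV table
#' @param result A [segmentation_result()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events_csv <- function(result, path) {
  stopifnot(inherits(result, "segmentation_result"))
  utils::write.csv(result$events, path, row.names = FALSE)
  invisible(path)
}
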