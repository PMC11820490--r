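#' Specification of a synthetic V-cut trial
#'
#' Parameterizes the generator of V-cut-like trials: a trunk-speed profile
#' cruising at `cruise_speed` with `n_cods` smooth braking troughs (raised-
#' cosine dips to `trough_speed`), alternating-foot stance trains, and
#' ground-truth heel-strike/toe-off edges placed at known offsets around each
#' trough. Defaults emulate the standard test: a ~25 m sprint of five 5 m
#' segments with four cuts, alternating cutting leg starting on the right.
#'
#' @param n_cods Number of changes of direction (default 4).
#' @param frame_rate Hz (default 60).
#' @param cruise_speed Cruise trunk speed, m/s (default 4).
#' @param trough_speed Speed at the braking trough, m/s (default 0.8).
#' @param segment_duration Seconds per 5 m course segment (default 1.2).
#' @param step_rate Steps per second, both feet pooled (default 3.5).
#' @param duty_factor Stance fraction of a foot's stride cycle (default 0.35).
#' @param if_offset Frames between the PFC heel strike and the trough
#'   (default 18, inside the -40 search bound).
#' @param ff_offset Frames between the trough and the FFC toe off
#'   (default 10, inside the +25 search bound).
#' @param velocity_noise_sd Additive Gaussian noise on the speed trace, m/s
#'   (default 0.1).
#' @param jitter_sd Standard deviation (frames) of integer jitter applied to
#'   each ground-truth edge (default 0 = clean).
#' @param seed RNG seed; identical seeds give bit-identical trials.
#' @param trial_id,test_type,meta Passed through to the generated trial.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cods = 4, frame_rate = 60, cruise_speed = 4,
                           trough_speed = 0.8, segment_duration = 1.2,
                           step_rate = 3.5, duty_factor = 0.35,
                           if_offset = 18, ff_offset = 10,
                           velocity_noise_sd = 0.1, jitter_sd = 0,
                           seed = 1, trial_id = "SYN001",
                           test_type = "VCUT", meta = list()) {
  if (trough_speed >= cruise_speed)
    stop("trough_speed must be below cruise_speed")
  if (duty_factor <= 0 || duty_factor >= 1)
    stop("duty_factor must lie in (0, 1)")
  if (if_offset <= 0 || ff_offset <= 0) stop("offsets must be positive")
  structure(list(
    n_cods = as.integer(n_cods), frame_rate = frame_rate,
    cruise_speed = cruise_speed, trough_speed = trough_speed,
    segment_duration = segment_duration, step_rate = step_rate,
    duty_factor = duty_factor, if_offset = as.integer(if_offset),
    ff_offset = as.integer(ff_offset),
    velocity_noise_sd = velocity_noise_sd, jitter_sd = jitter_sd,
    seed = seed, trial_id = trial_id, test_type = test_type, meta = meta),
    class = "synthetic_spec")
}

#' Generate one synthetic V-cut trial with ground truth
#'
#' Builds the trunk-speed profile, decomposes it into horizontal velocity
#' components along a path with 45-degree internal cut angles, lays down
#' alternating-foot stance trains with the PFC heel strike `if_offset` frames
#' before each trough and the FFC toe off `ff_offset` frames after, applies
#' optional integer jitter to the edges, and records the realized edges as
#' ground truth (so perfect detection means zero frame error).
#'
#' @param spec A [synthetic_spec()].
#' @return An object of class `synthetic_trial`: list with `trial`
#'   ([motion_trial()]), `truth` ([manual_labels()]) and `cut_schedule`
#'   (cutting side per COD, alternating from `"right"`).
#' @export
generate_trial <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  .build_trial(spec)
}

# Internal builder; the fixture generator reaches the knobs the public API
# does not expose (per-COD offsets, trough displacement, extra stances).
.build_trial <- function(spec, if_offsets = NULL, ff_offsets = NULL,
                         trough_shift = NULL, extra_stances = NULL,
                         exclusion_pad = NULL) {
  fs <- spec$frame_rate
  ncod <- spec$n_cods
  lead <- 1.0; tail <- 1.0
  segf <- spec$segment_duration * fs
  tk <- round(lead * fs + (1:ncod) * segf)             # contact anchors
  n <- round((lead + (ncod + 1) * spec$segment_duration + tail) * fs)
  if_offsets <- rep(if_offsets %||% spec$if_offset, length.out = ncod)
  ff_offsets <- rep(ff_offsets %||% spec$ff_offset, length.out = ncod)
  trough_shift <- rep(trough_shift %||% 0L, length.out = ncod)
  exclusion_pad <- rep(exclusion_pad %||% 0L, length.out = ncod)
  if (any(if_offsets + ff_offsets >= segf))
    stop("IF/FF offsets exceed the inter-COD spacing")

  jit <- function() if (spec$jitter_sd > 0)
    as.integer(round(stats::rnorm(ncod, 0, spec$jitter_sd))) else
    integer(ncod)
  if_frames <- tk - if_offsets + jit()
  ff_frames <- tk + ff_offsets + jit()
  if (any(if_frames < 1L) || any(ff_frames > n - 2L) ||
      any(if_frames >= ff_frames))
    stop("realized edges fall outside the trial")

  # speed profile: ramp up over the lead-in, cruise, raised-cosine dips at
  # the (possibly displaced) trough centers, ramp down over the tail
  t0 <- 0:(n - 1)
  speed <- rep(spec$cruise_speed, n)
  nl <- round(lead * fs); nt <- round(tail * fs)
  speed[1:nl] <- spec$cruise_speed * 0.5 * (1 - cos(pi * (0:(nl - 1)) / nl))
  speed[(n - nt + 1):n] <-
    spec$cruise_speed * 0.5 * (1 + cos(pi * (0:(nt - 1)) / nt))
  w <- round(0.33 * segf)
  depth <- spec$cruise_speed - spec$trough_speed
  dk <- tk + trough_shift
  for (k in seq_len(ncod)) {
    idx <- which(abs(t0 - dk[k]) <= w)
    speed[idx] <- speed[idx] -
      depth * 0.5 * (1 + cos(pi * (t0[idx] - dk[k]) / w))
  }
  if (spec$velocity_noise_sd > 0)
    speed <- pmax(0, speed + stats::rnorm(n, 0, spec$velocity_noise_sd))

  # heading alternates +/- 67.5 deg (135 deg direction change = 45 deg
  # internal angle), blended linearly across each dip
  theta <- rep(67.5, n)
  for (k in seq_len(ncod)) {
    prev <- 67.5 * (-1)^(k - 1)
    target <- 67.5 * (-1)^k
    lo <- dk[k] - w; hi <- dk[k] + w
    seg <- t0 >= lo & t0 <= hi
    theta[seg] <- prev + (t0[seg] - lo) / (hi - lo) * (target - prev)
    theta[t0 > hi] <- target
  }
  th <- theta * pi / 180
  vx <- speed * cos(th); vy <- speed * sin(th)

  # contact channels: anchor stances realize the ground-truth edges; fill
  # stances provide the background gait but stay out of each COD's protected
  # window so the anchors remain the latest-before / earliest-after edges
  cut_schedule <- rep(c("right", "left"), length.out = ncod)
  other <- function(s) ifelse(s == "left", "right", "left")
  L <- max(4L, as.integer(round(spec$duty_factor * 2 * fs / spec$step_rate)))
  p <- max(L + 2L, as.integer(round(fs / spec$step_rate)))
  stances <- list()
  for (k in seq_len(ncod)) {
    stances[[length(stances) + 1L]] <-
      list(side = other(cut_schedule[k]), start = if_frames[k])       # PFC
    stances[[length(stances) + 1L]] <-
      list(side = cut_schedule[k], start = ff_frames[k] - L)          # FFC
  }
  if (!is.null(extra_stances))
    for (st in extra_stances) stances[[length(stances) + 1L]] <- st
  zlo <- if_frames - 2L
  zhi <- ff_frames + 2L + exclusion_pad
  feet <- c("left", "right")
  i <- 0L
  repeat {
    s <- i * p
    if (s + L >= n) break
    clear <- all(s + L < zlo | s - 1L > zhi)
    if (clear)
      stances[[length(stances) + 1L]] <-
        list(side = feet[(i %% 2L) + 1L], start = s)
    i <- i + 1L
  }
  chan <- list(left = integer(n), right = integer(n))
  for (st in stances) {
    a <- max(0L, st$start); b <- min(n - 1L, st$start + L - 1L)
    if (a <= b) chan[[st$side]][(a + 1L):(b + 1L)] <- 1L
  }
  contacts <- list(left_heel = chan$left, left_toe = chan$left,
                   right_heel = chan$right, right_toe = chan$right)

  trial <- motion_trial(spec$trial_id, fs, vx, vy, contacts,
                        test_type = spec$test_type, meta = spec$meta)
  truth <- manual_labels(spec$trial_id,
                         data.frame(cod_index = seq_len(ncod),
                                    if_frame = if_frames,
                                    ff_frame = ff_frames))
  structure(list(trial = trial, truth = truth, cut_schedule = cut_schedule),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("<synthetic_trial>\n")
  print(x$trial)
  print(x$truth)
  cat("cutting sides:", paste(x$cut_schedule, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a labeled synthetic dataset
#'
#' Draws `n_trials` trials with per-trial variation of cruise/trough speed
#' and edge offsets, assigning stratification metadata (gender x team
#' category x test type) round-robin over the twelve combinations, so a
#' stratified split always sees balanced strata. Reproducible by seed.
#'
#' @param n_trials Number of trials (>= 1).
#' @param spec Template [synthetic_spec()]; noise/jitter settings and rates
#'   are inherited, speeds and offsets are perturbed per trial.
#' @param seed Master seed for all per-trial randomness.
#' @return A [labeled_dataset()].
#' @export
generate_dataset <- function(n_trials, spec = synthetic_spec(), seed = 1) {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  combos <- expand.grid(gender = c("M", "F"),
                        category = c("U13", "U17", "U18"),
                        test_type = c("VCUT", "VCUT_BK"),
                        stringsAsFactors = FALSE)
  items <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cb <- combos[((i - 1L) %% nrow(combos)) + 1L, ]
    cruise <- stats::runif(1, 3.6, 4.4) * if (cb$test_type == "VCUT_BK") 0.92 else 1
    sp <- spec
    sp$cruise_speed <- cruise
    sp$trough_speed <- stats::runif(1, 0.7, 1.0)
    sp$if_offset <- sample(14:22, 1)
    sp$ff_offset <- sample(7:13, 1)
    sp$seed <- sample.int(.Machine$integer.max, 1)
    sp$trial_id <- sprintf("T%03d", i)
    sp$test_type <- cb$test_type
    sp$meta <- list(gender = cb$gender, category = cb$category,
                    repetition = ((i - 1L) %/% nrow(combos)) + 1L)
    st <- generate_trial(sp)
    items[[i]] <- list(trial = st$trial, labels = st$truth)
  }
  labeled_dataset(items)
}

#' Regression fixtures for the documented misdetection modes
#'
#' Deterministic noise-free trials reproducing the two known failure modes of
#' minimum-anchored detection. `"IF_OUTSIDE_REGION"` places the true heel
#' strike of one COD farther before the trough than the search region
#' reaches, so the detector misses or mislabels that IF. `"MIN_TOO_LATE"`
#' displaces one velocity trough past the true toe off, so the detector
#' latches onto the subsequent toe off and reports a late FF. Ground truth
#' still records the true edges; the other CODs are unaffected.
#'
#' @param mode `"MIN_TOO_LATE"` or `"IF_OUTSIDE_REGION"`.
#' @param spec Base [synthetic_spec()]; noise is switched off for
#'   determinism.
#' @param cod Which COD (1-based) to corrupt (default 2).
#' @return A `synthetic_trial`.
#' @export
make_failure_fixture <- function(mode = c("MIN_TOO_LATE", "IF_OUTSIDE_REGION"),
                                 spec = synthetic_spec(), cod = 2L) {
  mode <- match.arg(mode)
  spec$velocity_noise_sd <- 0
  spec$jitter_sd <- 0
  set.seed(spec$seed)
  ncod <- spec$n_cods
  stopifnot(cod >= 1L, cod <= ncod)
  if (mode == "IF_OUTSIDE_REGION") {
    offs <- rep(spec$if_offset, ncod)
    offs[cod] <- 50L                      # beyond the default -40 bound
    .build_trial(spec, if_offsets = offs)
  } else {
    shift <- integer(ncod)
    shift[cod] <- spec$ff_offset + 8L     # trough lands after the true toe off
    fs <- spec$frame_rate
    tk <- round(1.0 * fs + cod * spec$segment_duration * fs)
    L <- max(4L, as.integer(round(spec$duty_factor * 2 * fs / spec$step_rate)))
    side <- rep(c("right", "left"), length.out = ncod)[cod]
    extra <- list(list(side = side, start = tk + spec$ff_offset + 4L))
    pad <- integer(ncod)
    pad[cod] <- 36L
    .build_trial(spec, trough_shift = shift, extra_stances = extra,
                 exclusion_pad = pad)
  }
}
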