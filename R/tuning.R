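#' Labeled dataset of trials with manual gold-standard events
#'
#' Couples each trial with its manual labels and derives the stratification
#' key used by [split_dataset()]: gender x team category x test type, read
#' from the trial metadata (missing components become `"NA"` and simply form
#' their own stratum — keys are treated as opaque labels).
#'
#' @param items List of `list(trial = motion_trial, labels = manual_labels)`.
#' @return An object of class `labeled_dataset` with `items` and a `strata`
#'   character vector.
#' @export
labeled_dataset <- function(items) {
  stopifnot(is.list(items), length(items) >= 1)
  ids <- vapply(items, function(it) it$trial$trial_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate trial_ids in dataset")
  for (it in items) {
    stopifnot(inherits(it$trial, "motion_trial"),
              inherits(it$labels, "manual_labels"))
    if (it$labels$trial_id != it$trial$trial_id)
      stop("labels for '", it$labels$trial_id,
           "' do not reference trial '", it$trial$trial_id, "'")
  }
  strata <- vapply(items, function(it) {
    m <- it$trial$meta
    paste(m$gender %||% "NA", m$category %||% "NA", it$trial$test_type,
          sep = "|")
  }, character(1))
  structure(list(items = items, strata = strata), class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset> %d trials, %d CODs, %d strata\n",
              length(x$items), n_cods(x), length(unique(x$strata))))
  invisible(x)
}

#' Count gold-standard COD events in a dataset
#' @param data A [labeled_dataset()].
#' @return Integer total of labeled events.
#' @export
n_cods <- function(data) {
  sum(vapply(data$items, function(it) nrow(it$labels$events), integer(1)))
}

#' Stratified trial-level train/test split
#'
#' Splits whole trials, never events. Within each stratum the training count
#' is the smallest integer whose stratum training fraction is at least
#' `train_fraction` (a ceiling rule), so no stratum dips below the requested
#' fraction; membership is randomized by `seed`. A stratum too small to
#' contribute a test trial goes wholly to training with a warning.
#'
#' @param data A [labeled_dataset()].
#' @param train_fraction Target training fraction (default 0.8).
#' @param seed Integer seed; same seed, same split.
#' @param strata Stratum key per trial; defaults to the dataset's
#'   gender x category x test-type keys. Pass a constant vector to split the
#'   pooled dataset (e.g. when stratum composition is unknown).
#' @return List with `train` and `test`, both `labeled_dataset`s (`test` is
#'   `NULL` if empty).
#' @export
split_dataset <- function(data, train_fraction = 0.8, seed,
                          strata = data$strata) {
  stopifnot(inherits(data, "labeled_dataset"),
            train_fraction > 0, train_fraction < 1,
            length(data$items) >= 2,
            length(strata) == length(data$items))
  set.seed(seed)
  train_idx <- integer(0)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    n <- length(idx)
    n_train <- as.integer(ceiling(train_fraction * n))
    if (n_train >= n) {
      warning("stratum '", s, "' has ", n,
              " trial(s); all assigned to training")
      n_train <- n
    }
    train_idx <- c(train_idx, sort(sample(idx, n_train)))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(data$items), train_idx)
  list(train = labeled_dataset(data$items[train_idx]),
       test = if (length(test_idx)) labeled_dataset(data$items[test_idx])
              else NULL)
}

#' Grid of detection parameters to search
#'
#' @param prominences Prominence thresholds (m/s).
#' @param region_befores,region_afters Search-region bounds (frames at the
#'   reference rate).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(prominences = c(0.5, 1.0, 1.5, 2.0, 2.5),
                      region_befores = c(20, 30, 40, 50),
                      region_afters = c(15, 25, 35)) {
  if (!length(prominences) || !length(region_befores) || !length(region_afters))
    stop("grid axes must be non-empty")
  if (any(prominences <= 0) || any(region_befores <= 0) ||
      any(region_afters <= 0))
    stop("grid values must be positive")
  structure(list(prominences = prominences,
                 region_befores = as.integer(region_befores),
                 region_afters = as.integer(region_afters)),
            class = "grid_spec")
}

#' Grid-search parameter tuning by pooled RMSE
#'
#' Runs the detector on every training trial for every grid cell, pools the
#' squared IF/FF frame errors against the manual labels across the whole
#' training set (missing detections incur the squared-region-width penalty of
#' [pooled_rmse()]), and returns the cell with the lowest RMSE. Ties go to the
#' smaller prominence, then the smaller region width.
#'
#' @param train A [labeled_dataset()] (every trial labeled).
#' @param grid A [grid_spec()].
#' @param base [detection_params()] supplying the non-searched settings
#'   (cutoff, filter order, reference rate).
#' @return List with `best` ([detection_params()]) and `table` (data frame:
#'   one row per cell with `prominence`, `region_before`, `region_after`,
#'   `rmse`).
#' @export
tune_parameters <- function(train, grid = grid_spec(),
                            base = detection_params()) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(grid, "grid_spec"))
  cells <- expand.grid(prominence = grid$prominences,
                       region_before = grid$region_befores,
                       region_after = grid$region_afters)
  rmse <- numeric(nrow(cells))
  for (ci in seq_len(nrow(cells))) {
    params <- detection_params(
      prominence = cells$prominence[ci],
      region_before = cells$region_before[ci],
      region_after = cells$region_after[ci],
      cutoff = base$cutoff, filter_order = base$filter_order,
      reference_rate = base$reference_rate)
    terms <- unlist(lapply(train$items, function(it) {
      pairs <- match_events(detect_cods(it$trial, params), it$labels)
      pen <- attr(pairs, "max_sep")^2
      d <- c(pairs$diff_if, pairs$diff_ff)
      ifelse(is.na(d), pen, d^2)
    }))
    rmse[ci] <- sqrt(mean(terms))
  }
  tab <- cbind(cells, rmse = rmse)
  ord <- order(tab$rmse, tab$prominence,
               tab$region_before + tab$region_after)
  best_row <- tab[ord[1], ]
  best <- detection_params(
    prominence = best_row$prominence,
    region_before = best_row$region_before,
    region_after = best_row$region_after,
    cutoff = base$cutoff, filter_order = base$filter_order,
    reference_rate = base$reference_rate)
  list(best = best, table = tab)
}
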