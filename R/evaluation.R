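#' Pair automatic and manual COD events
#'
#' When both sequences contain the same number of events they are paired in
#' temporal order. Otherwise an order-preserving alignment is computed that
#' first maximizes the number of matches whose minimum-to-label separation is
#' within `max_sep` frames, then minimizes the total separation — the optimal
#' assignment for time-ordered events. Every manual event appears in exactly
#' one pair (with missing automatic frames when unmatched); leftover automatic
#' events are counted in the `n_extra_auto` attribute.
#'
#' @param auto A [segmentation_result()].
#' @param manual A [manual_labels()] for the same trial.
#' @param max_sep Maximum separation (frames) for a pairing; defaults to one
#'   search-region width at the trial frame rate.
#' @return Data frame of event pairs with columns `cod_index`, `auto_if`,
#'   `auto_ff`, `manual_if`, `manual_ff`, `diff_if`, `diff_ff` (automatic
#'   minus manual, `NA` when undetected/unmatched) and `matched`. Attributes:
#'   `n_extra_auto`, `max_sep`, `frame_rate`.
#' @export
match_events <- function(auto, manual, max_sep = NULL) {
  stopifnot(inherits(auto, "segmentation_result"),
            inherits(manual, "manual_labels"))
  ae <- auto$events
  me <- manual$events
  if (is.null(max_sep)) {
    p <- auto$params_used
    s <- if (is.finite(auto$frame_rate)) auto$frame_rate / p$reference_rate else 1
    max_sep <- round(p$region_before * s) + round(p$region_after * s) + 1
  }
  na <- nrow(ae); nm <- nrow(me)
  if (na == nm) {
    assign <- seq_len(nm)                       # k-th with k-th
  } else {
    apos <- ae$minimum_frame
    mpos <- (me$if_frame + me$ff_frame) / 2
    assign <- .align_events(apos, mpos, max_sep) # auto index per manual, NA
  }
  rows <- lapply(seq_len(nm), function(j) {
    i <- assign[j]
    a_if <- if (!is.na(i)) ae$if_frame[i] else NA_integer_
    a_ff <- if (!is.na(i)) ae$ff_frame[i] else NA_integer_
    data.frame(cod_index = j,
               auto_if = a_if, auto_ff = a_ff,
               manual_if = me$if_frame[j], manual_ff = me$ff_frame[j],
               diff_if = a_if - me$if_frame[j],
               diff_ff = a_ff - me$ff_frame[j],
               matched = !is.na(i))
  })
  pairs <- do.call(rbind, rows)
  attr(pairs, "n_extra_auto") <- na - sum(!is.na(assign))
  attr(pairs, "max_sep") <- max_sep
  attr(pairs, "frame_rate") <- auto$frame_rate
  pairs
}

# Order-preserving alignment of two increasing position sequences: maximize
# the number of pairs with |a - m| <= cap, break ties by minimal total
# distance. Returns, per manual event, the index of the paired auto event or
# NA. Lexicographic DP over (matches, -cost).
.align_events <- function(apos, mpos, cap) {
  na <- length(apos); nm <- length(mpos)
  M <- matrix(0L, na + 1L, nm + 1L)         # best match count
  C <- matrix(0, na + 1L, nm + 1L)          # cost at that count
  for (i in seq_len(na)) {
    for (j in seq_len(nm)) {
      # skip auto i or manual j
      best_m <- M[i, j + 1L]; best_c <- C[i, j + 1L]
      if (M[i + 1L, j] > best_m ||
          (M[i + 1L, j] == best_m && C[i + 1L, j] < best_c)) {
        best_m <- M[i + 1L, j]; best_c <- C[i + 1L, j]
      }
      d <- abs(apos[i] - mpos[j])
      if (d <= cap) {
        cand_m <- M[i, j] + 1L; cand_c <- C[i, j] + d
        if (cand_m > best_m || (cand_m == best_m && cand_c < best_c)) {
          best_m <- cand_m; best_c <- cand_c
        }
      }
      M[i + 1L, j + 1L] <- best_m; C[i + 1L, j + 1L] <- best_c
    }
  }
  assign <- rep(NA_integer_, nm)
  i <- na; j <- nm
  while (i > 0L && j > 0L) {
    d <- abs(apos[i] - mpos[j])
    if (d <= cap && M[i + 1L, j + 1L] == M[i, j] + 1L &&
        C[i + 1L, j + 1L] == C[i, j] + d) {
      assign[j] <- i; i <- i - 1L; j <- j - 1L
    } else if (M[i + 1L, j + 1L] == M[i, j + 1L] &&
               C[i + 1L, j + 1L] == C[i, j + 1L]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  assign
}

.kind_diffs <- function(pairs, kind) {
  kind <- match.arg(toupper(kind), c("IF", "FF"))
  d <- if (kind == "IF") pairs$diff_if else pairs$diff_ff
  d[!is.na(d)]
}

#' Signed-difference summaries (median, mode, IQR)
#'
#' Distribution summaries of the signed frame differences, automatic minus
#' manual, for one event kind. The IQR is Q3 - Q1 with linear interpolation
#' between order statistics; the mode is the most frequent integer
#' difference, ties broken toward the smallest absolute value.
#'
#' @param pairs Event-pair data frame from [match_events()].
#' @param kind `"IF"` or `"FF"`.
#' @return List with `median`, `mode`, `iqr`.
#' @export
difference_summaries <- function(pairs, kind) {
  d <- .kind_diffs(pairs, kind)
  if (!length(d)) stop("no matched pairs with a detected ", kind, " frame")
  tab <- table(d)
  vals <- as.numeric(names(tab))
  top <- vals[tab == max(tab)]
  mode <- top[order(abs(top), top)][1]
  list(median = stats::median(d),
       mode = mode,
       iqr = unname(stats::quantile(d, 0.75) - stats::quantile(d, 0.25)))
}

#' Absolute mean error and error standard deviation
#'
#' `|E|` is the mean absolute signed difference; `s(E)` the sample standard
#' deviation (n-1 denominator) of the signed differences.
#'
#' @inheritParams difference_summaries
#' @return List with `abs_mean_error`, `error_sd`.
#' @export
error_stats <- function(pairs, kind) {
  d <- .kind_diffs(pairs, kind)
  if (length(d) < 2) stop("need at least 2 matched pairs")
  list(abs_mean_error = mean(abs(d)), error_sd = stats::sd(d))
}

#' Average precision at a frame threshold
#'
#' Percentage of manual events whose automatic frame lies within `k` frames
#' of the manual frame. Unmatched or undetected events count in the
#' denominator only, so misdetections lower the score.
#'
#' @inheritParams difference_summaries
#' @param k Absolute frame-error threshold.
#' @return Percentage in `[0, 100]`.
#' @export
average_precision <- function(pairs, kind, k) {
  n <- nrow(pairs)
  if (!n) stop("no events to score")
  kind <- match.arg(toupper(kind), c("IF", "FF"))
  d <- if (kind == "IF") pairs$diff_if else pairs$diff_ff
  100 * sum(!is.na(d) & abs(d) <= k) / n
}

#' Bland-Altman bias and limits of agreement
#'
#' Bias is the mean signed difference; the limits of agreement are
#' `bias +/- 1.96 s(E)`, the interval expected to contain 95% of the
#' method disagreements.
#'
#' @inheritParams difference_summaries
#' @return List with `bias`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(pairs, kind) {
  d <- .kind_diffs(pairs, kind)
  if (length(d) < 2) stop("need at least 2 matched pairs")
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Total-cutting-time correlation between methods
#'
#' Total cutting time per COD is `(FF - IF) * 1000 / frame_rate`
#' milliseconds. Returns the Pearson correlation between the automatic and
#' manual times and a coefficient of determination. With
#' `method = "pearson"` (primary), `r_squared` is the square of the Pearson
#' correlation; `method = "identity_line"` instead measures the residual
#' variance around the y = x line, `1 - SS(auto - manual) / SS(manual)`.
#'
#' @inheritParams difference_summaries
#' @param frame_rate Hz; defaults to the `frame_rate` attribute of `pairs`.
#' @param method `"pearson"` or `"identity_line"`.
#' @return List with `pearson_r`, `r_squared`, `n`.
#' @export
cutting_time_correlation <- function(pairs, frame_rate = NULL,
                                     method = c("pearson", "identity_line")) {
  method <- match.arg(method)
  if (is.null(frame_rate)) frame_rate <- attr(pairs, "frame_rate")
  if (is.null(frame_rate) || !is.finite(frame_rate))
    stop("frame_rate is required to convert frames to milliseconds")
  ok <- !is.na(pairs$auto_if) & !is.na(pairs$auto_ff)
  if (sum(ok) < 3) stop("need at least 3 pairs with complete IF and FF")
  t_auto <- (pairs$auto_ff[ok] - pairs$auto_if[ok]) * 1000 / frame_rate
  t_man  <- (pairs$manual_ff[ok] - pairs$manual_if[ok]) * 1000 / frame_rate
  if (stats::sd(t_auto) == 0 || stats::sd(t_man) == 0)
    stop("degenerate: zero variance in cutting times")
  r <- stats::cor(t_auto, t_man)
  r2 <- switch(method,
    pearson = r^2,
    identity_line = 1 - sum((t_auto - t_man)^2) / sum((t_man - mean(t_man))^2))
  list(pearson_r = r, r_squared = r2, n = sum(ok))
}

#' Pooled root-mean-square frame error
#'
#' Each manual event contributes one IF term and one FF term: the squared
#' signed difference when the automatic frame exists, otherwise a penalty
#' (default the squared search-region width), so parameter sets that drop
#' events are penalized rather than rewarded. The RMSE is the square root of
#' the mean of all terms.
#'
#' @inheritParams difference_summaries
#' @param penalty Squared-frame penalty for a missing/unmatched value;
#'   defaults to the squared `max_sep` attribute of `pairs`.
#' @return RMSE in frames.
#' @export
pooled_rmse <- function(pairs, penalty = NULL) {
  if (!nrow(pairs)) stop("no events at all")
  if (is.null(penalty)) {
    ms <- attr(pairs, "max_sep")
    if (is.null(ms)) stop("penalty is required when pairs lack a max_sep attribute")
    penalty <- ms^2
  }
  term <- function(d) ifelse(is.na(d), penalty, d^2)
  sqrt(mean(c(term(pairs$diff_if), term(pairs$diff_ff))))
}

#' Full agreement report for one set of event pairs
#'
#' Bundles, per event kind (IF, FF): median/mode/IQR of signed differences,
#' `|E|` and `s(E)`, average precision at the requested thresholds, and
#' Bland-Altman bias with limits of agreement; plus the cutting-time
#' correlation, the pooled RMSE, and match counts.
#'
#' @inheritParams cutting_time_correlation
#' @param ap_thresholds Integer frame thresholds for average precision
#'   (default 2, 3, 4).
#' @param test_type Label carried into the report (e.g. `"VCUT"`).
#' @return An object of class `evaluation_report`.
#' @export
evaluate_agreement <- function(pairs, frame_rate = NULL,
                               ap_thresholds = c(2, 3, 4),
                               test_type = NA_character_) {
  kinds <- c("IF", "FF")
  per_kind <- lapply(kinds, function(kind) {
    ds <- difference_summaries(pairs, kind)
    es <- error_stats(pairs, kind)
    ba <- bland_altman(pairs, kind)
    ap <- vapply(ap_thresholds, function(k) average_precision(pairs, kind, k),
                 numeric(1))
    names(ap) <- paste0("AP_", ap_thresholds)
    c(ds, es, list(ap = as.list(ap)), list(bland_altman = ba))
  })
  names(per_kind) <- kinds
  ct <- tryCatch(cutting_time_correlation(pairs, frame_rate),
                 error = function(e) NULL)
  structure(list(
    test_type = test_type,
    kinds = per_kind,
    cutting_time = ct,
    rmse = pooled_rmse(pairs),
    n_events = nrow(pairs),
    n_matched = sum(pairs$matched),
    n_unmatched = sum(!pairs$matched),
    n_extra_auto = attr(pairs, "n_extra_auto") %||% 0L),
    class = "evaluation_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flatten evaluation reports into a summary table
#'
#' One row per test type and event kind with the columns of the standard
#' agreement table: median, mode, IQR, `|E|`, `s(E)` and the AP columns.
#'
#' @param reports A single `evaluation_report` or a list of them.
#' @return Data frame.
#' @export
report_table <- function(reports) {
  if (inherits(reports, "evaluation_report")) reports <- list(reports)
  rows <- lapply(reports, function(rep) {
    do.call(rbind, lapply(names(rep$kinds), function(kind) {
      k <- rep$kinds[[kind]]
      row <- data.frame(test = rep$test_type, frame = kind,
                        median = k$median, mode = k$mode, IQR = k$iqr,
                        abs_E = k$abs_mean_error, s_E = k$error_sd)
      for (nm in names(k$ap)) row[[nm]] <- k$ap[[nm]]
      row
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s: %d events (%d matched, %d unmatched, %d extra auto)\n",
              x$test_type, x$n_events, x$n_matched, x$n_unmatched,
              x$n_extra_auto))
  print(report_table(x))
  cat(sprintf("pooled RMSE: %.3f frames\n", x$rmse))
  if (!is.null(x$cutting_time))
    cat(sprintf("cutting time: r = %.3f, R^2 = %.3f (n = %d)\n",
                x$cutting_time$pearson_r, x$cutting_time$r_squared,
                x$cutting_time$n))
  invisible(x)
}

#' Bland-Altman plot of automatic vs manual frames
#'
#' Presentation helper (requires ggplot2): differences against means with the
#' bias and limits of agreement.
#'
#' @inheritParams difference_summaries
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(pairs, kind) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  kind <- match.arg(toupper(kind), c("IF", "FF"))
  a <- if (kind == "IF") pairs$auto_if else pairs$auto_ff
  m <- if (kind == "IF") pairs$manual_if else pairs$manual_ff
  ok <- !is.na(a)
  ba <- bland_altman(pairs, kind)
  df <- data.frame(mean = (a[ok] + m[ok]) / 2, diff = a[ok] - m[ok])
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = ba$bias) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "Mean of methods (frames)",
                  y = "Automatic - manual (frames)",
                  title = paste("Bland-Altman,", kind))
}

#' Scatter plot of total cutting times
#'
#' Presentation helper (requires ggplot2): automatic vs manual cutting times
#' with the y = x bisector.
#'
#' @inheritParams cutting_time_correlation
#' @return A ggplot object.
#' @export
plot_cutting_time <- function(pairs, frame_rate = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  if (is.null(frame_rate)) frame_rate <- attr(pairs, "frame_rate")
  ok <- stats::complete.cases(pairs[c("auto_if", "auto_ff")])
  df <- data.frame(
    manual = (pairs$manual_ff[ok] - pairs$manual_if[ok]) * 1000 / frame_rate,
    auto = (pairs$auto_ff[ok] - pairs$auto_if[ok]) * 1000 / frame_rate)
  ggplot2::ggplot(df, ggplot2::aes(x = manual, y = auto)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::labs(x = "Manual cutting time (ms)",
                  y = "Automatic cutting time (ms)")
}
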