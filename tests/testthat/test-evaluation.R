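# helpers building event pairs without running the detector
mk_result <- function(minima, if_frames, ff_frames, prom = 1.5) {
  k <- length(minima)
  ev <- data.frame(cod_index = seq_len(k), minimum_frame = as.integer(minima),
                   if_frame = as.integer(if_frames),
                   ff_frame = as.integer(ff_frames),
                   pfc_side = rep("left", k), ffc_side = rep("right", k),
                   status = ifelse(is.na(if_frames) | is.na(ff_frames),
                                   "IF_MISSING", "COMPLETE"))
  segmentation_result("t", detection_params(prominence = prom), ev,
                      frame_rate = 60, test_type = "VCUT")
}

mk_labels <- function(if_frames, ff_frames) {
  manual_labels("t", data.frame(cod_index = seq_along(if_frames),
                                if_frame = if_frames, ff_frame = ff_frames))
}

# brute force: enumerate all order-preserving matchings, maximize matches
# within cap then minimize total distance
oracle_assign <- function(apos, mpos, cap) {
  best <- list(m = -1L, c = Inf, assign = rep(NA_integer_, length(mpos)))
  rec <- function(i, j, assign, m, cost) {
    if (i > length(apos) || j > length(mpos)) {
      if (m > best$m || (m == best$m && cost < best$c))
        best <<- list(m = m, c = cost, assign = assign)
      return()
    }
    d <- abs(apos[i] - mpos[j])
    if (d <= cap) {
      a2 <- assign; a2[j] <- i
      rec(i + 1L, j + 1L, a2, m + 1L, cost + d)
    }
    rec(i + 1L, j, assign, m, cost)
    rec(i, j + 1L, assign, m, cost)
  }
  rec(1L, 1L, rep(NA_integer_, length(mpos)), 0L, 0)
  best
}

test_that("equal event counts pair in index order", {
  res <- mk_result(c(100, 200, 300, 400), c(90, 190, 290, 390),
                   c(110, 210, 310, 410))
  lab <- mk_labels(c(91, 189, 291, 390), c(111, 209, 311, 410))
  pairs <- match_events(res, lab)
  expect_equal(nrow(pairs), 4)
  expect_true(all(pairs$matched))
  expect_equal(pairs$diff_if, c(-1, 1, -1, 0))
  expect_equal(attr(pairs, "n_extra_auto"), 0)
})

test_that("unequal counts leave the distant manual event unmatched", {
  res <- mk_result(c(100, 200, 300), c(90, 190, 290), c(110, 210, 310))
  lab <- mk_labels(c(90, 190, 290, 390), c(110, 210, 310, 410))
  pairs <- match_events(res, lab)
  expect_equal(sum(pairs$matched), 3)
  expect_false(pairs$matched[4])
  expect_true(is.na(pairs$diff_if[4]))
})

test_that("alignment equals the exhaustive minimum-distance assignment", {
  set.seed(55)
  for (rep in 1:40) {
    na <- sample(1:6, 1); nm <- sample(1:6, 1)
    if (na == nm) nm <- nm + 1L          # index pairing path is separate
    apos <- sort(sample(0:500, na))
    mpos <- sort(sample(0:500, nm))
    cap <- sample(c(30, 66, 120), 1)
    got <- codseg:::.align_events(apos, mpos, cap)
    want <- oracle_assign(apos, mpos, cap)
    expect_equal(sum(!is.na(got)), want$m)
    d <- function(a) sum(abs(apos[a[!is.na(a)]] - mpos[!is.na(a)]))
    expect_equal(d(got), want$c)
  }
})

test_that("difference summaries follow the stated conventions", {
  res <- mk_result(c(100, 200, 300, 400), c(89, 189, 290, 288 + 100),
                   c(110, 210, 310, 410))
  lab <- mk_labels(c(90, 190, 290, 390), c(110, 210, 310, 410))
  pairs <- match_events(res, lab)
  # diffs (-1, -1, 0, -2): automatic minus manual
  expect_equal(pairs$diff_if, c(-1, -1, 0, -2))
  s <- difference_summaries(pairs, "IF")
  expect_equal(s$median, -1)
  expect_equal(s$mode, -1)
  # sign convention: auto 102 vs manual 103 -> -1
  p2 <- match_events(mk_result(c(100, 200), c(102, 202), c(150, 250)),
                     mk_labels(c(103, 203), c(150, 250)))
  expect_equal(p2$diff_if, c(-1, -1))
  # mode ties break toward the smallest absolute value
  p3 <- match_events(mk_result(c(100, 200, 300, 400),
                               c(88, 192, 288, 392), c(150, 250, 350, 450)),
                     mk_labels(c(90, 190, 290, 390), c(150, 250, 350, 450)))
  expect_equal(sort(unique(p3$diff_if)), c(-2, 2))
  expect_equal(difference_summaries(p3, "IF")$mode, -2)
})

test_that("summaries match an independent sort-based computation", {
  set.seed(77)
  d <- sample(-6:6, 200, replace = TRUE)
  base <- 100 * seq_along(d)
  pairs <- match_events(mk_result(base, base + d, base + 20),
                        mk_labels(base, base + 20))
  s <- difference_summaries(pairs, "IF")
  sorted <- sort(d)
  med <- if (length(d) %% 2) sorted[(length(d) + 1) / 2] else
    mean(sorted[length(d) / 2 + 0:1])
  expect_equal(s$median, med)
  expect_equal(s$iqr, unname(quantile(d, 0.75) - quantile(d, 0.25)))
  tab <- sort(table(d), decreasing = TRUE)
  expect_equal(as.integer(tab[as.character(s$mode)]), max(table(d)))
})

test_that("error stats use mean |diff| and the n-1 standard deviation", {
  pairs <- match_events(mk_result(c(100, 200), c(91, 189), c(150, 250)),
                        mk_labels(c(90, 190), c(150, 250)))
  es <- error_stats(pairs, "IF")          # diffs (1, -1)
  expect_equal(es$abs_mean_error, 1.0)
  expect_equal(es$error_sd, sqrt(2))
  # all-zero diffs
  p0 <- match_events(mk_result(c(100, 200), c(90, 190), c(150, 250)),
                     mk_labels(c(90, 190), c(150, 250)))
  expect_equal(unlist(error_stats(p0, "IF")), c(abs_mean_error = 0, error_sd = 0))
  # two-pass oracle on random diffs
  set.seed(8)
  d <- sample(-10:10, 500, replace = TRUE)
  base <- 100 * seq_along(d)
  pr <- match_events(mk_result(base, base + d, base + 20),
                     mk_labels(base, base + 20))
  es <- error_stats(pr, "IF")
  expect_equal(es$abs_mean_error, sum(abs(d)) / length(d))
  m <- sum(d) / length(d)
  expect_equal(es$error_sd, sqrt(sum((d - m)^2) / (length(d) - 1)))
  expect_error(error_stats(pairs[1, ], "IF"), "at least 2")
})

test_that("average precision counts unmatched events in the denominator only", {
  d <- c(0, 1, 2, 3, 5)
  base <- 100 * seq_along(d)
  pairs <- match_events(mk_result(base, base + d, base + 20),
                        mk_labels(base, base + 20))
  expect_equal(average_precision(pairs, "IF", 2), 60)
  # 2 hits, 2 unmatched -> 50%
  res <- mk_result(c(100, 200), c(100, 200), c(120, 220))
  lab <- mk_labels(c(100, 200, 500, 600), c(120, 220, 520, 620))
  p <- match_events(res, lab)
  expect_equal(average_precision(p, "IF", 1), 50)
  # monotone and bounded, AP_inf = matched fraction
  set.seed(5)
  for (rep in 1:20) {
    d <- sample(-8:8, 12, replace = TRUE)
    base <- 100 * seq_len(12)
    pr <- match_events(mk_result(base, base + d, base + 20),
                       mk_labels(base, base + 20))
    aps <- vapply(c(2, 3, 4), function(k) average_precision(pr, "IF", k),
                  numeric(1))
    expect_true(all(diff(aps) >= 0))
    expect_true(all(aps >= 0 & aps <= 100))
    expect_equal(average_precision(pr, "IF", Inf), 100)
  }
})

test_that("Bland-Altman bias and limits follow the 1.96 SD convention", {
  base <- c(100, 200, 300)
  p0 <- match_events(mk_result(base, base, base + 20),
                     mk_labels(base, base + 20))
  ba <- bland_altman(p0, "IF")
  expect_equal(unlist(ba), c(bias = 0, loa_low = 0, loa_high = 0))
  # constant offset +3: zero-width limits around 3
  p3 <- match_events(mk_result(base, base + 3, base + 20),
                     mk_labels(base, base + 20))
  ba3 <- bland_altman(p3, "IF")
  expect_equal(ba3$bias, 3)
  expect_equal(ba3$loa_high - ba3$loa_low, 0)
  # direct-formula oracle
  set.seed(31)
  d <- rnorm(50)
  base <- 100 * seq_along(d)
  pr <- match_events(mk_result(base, as.integer(base + round(d * 4)),
                               base + 20),
                     mk_labels(base, base + 20))
  dd <- pr$diff_if
  ba <- bland_altman(pr, "IF")
  expect_equal(ba$bias, mean(dd))
  expect_equal(ba$loa_low, mean(dd) - 1.96 * sd(dd))
  expect_equal(ba$loa_high, mean(dd) + 1.96 * sd(dd))
})

test_that("translation equivariance and invariance of the agreement statistics", {
  set.seed(17)
  d <- sample(-5:5, 30, replace = TRUE)
  d2 <- sample(-5:5, 30, replace = TRUE)
  dm <- sample(0:10, 30, replace = TRUE)   # manual durations must vary
  base <- 100 * seq_along(d)
  shift <- 7L
  p <- match_events(mk_result(base, base + d, base + 20 + dm + d2),
                    mk_labels(base, base + 20 + dm))
  ps <- match_events(mk_result(base, base + d + shift,
                               base + 20 + dm + d2 + shift),
                     mk_labels(base, base + 20 + dm))
  s <- difference_summaries(p, "IF"); ss <- difference_summaries(ps, "IF")
  expect_equal(ss$median, s$median + shift)              # equivariant
  expect_equal(ss$iqr, s$iqr)                            # invariant
  expect_equal(error_stats(ps, "IF")$error_sd,
               error_stats(p, "IF")$error_sd)
  ba <- bland_altman(p, "IF"); bas <- bland_altman(ps, "IF")
  expect_equal(bas$bias, ba$bias + shift)
  expect_equal(bas$loa_high - bas$loa_low, ba$loa_high - ba$loa_low)
  ct <- cutting_time_correlation(p); cts <- cutting_time_correlation(ps)
  expect_equal(cts$pearson_r, ct$pearson_r)
})

test_that("cutting-time correlation and its R^2 conventions", {
  base <- c(100, 200, 300, 400)
  dur <- c(20, 25, 30, 35)
  # identical times: r = 1
  p <- match_events(mk_result(base, base, base + dur),
                    mk_labels(base, base + dur))
  ct <- cutting_time_correlation(p)
  expect_equal(ct$pearson_r, 1)
  expect_equal(ct$r_squared, 1)
  # auto = manual + constant: r stays 1
  p2 <- match_events(mk_result(base, base, base + dur + 5),
                     mk_labels(base, base + dur))
  expect_equal(cutting_time_correlation(p2)$pearson_r, 1)
  # formula oracle on random paired times
  set.seed(19)
  da <- sample(10:40, 20, replace = TRUE)
  dm <- da + sample(-3:3, 20, replace = TRUE)
  base <- 200 * seq_along(da)
  pr <- match_events(mk_result(base, base, base + da),
                     mk_labels(base, base + dm))
  ta <- da * 1000 / 60; tm <- dm * 1000 / 60
  r_direct <- sum((ta - mean(ta)) * (tm - mean(tm))) /
    sqrt(sum((ta - mean(ta))^2) * sum((tm - mean(tm))^2))
  ct <- cutting_time_correlation(pr)
  expect_equal(ct$pearson_r, r_direct)
  expect_equal(ct$r_squared, ct$pearson_r^2)             # r^2 identity
  # identity-line variant is exposed but distinct
  ct2 <- cutting_time_correlation(pr, method = "identity_line")
  expect_equal(ct2$r_squared,
               1 - sum((ta - tm)^2) / sum((tm - mean(tm))^2))
  # degenerate variance fails
  pz <- match_events(mk_result(base, base, base + 20),
                     mk_labels(base, base + 20))
  expect_error(cutting_time_correlation(pz), "degenerate")
})

test_that("pooled RMSE matches its closed form and penalizes missing events", {
  p <- match_events(mk_result(100, 93, 116), mk_labels(90, 120))
  expect_equal(pooled_rmse(p), sqrt((9 + 16) / 2))   # diffs 3 and -4
  base <- c(100, 200, 300)
  p0 <- match_events(mk_result(base, base, base + 20),
                     mk_labels(base, base + 20))
  expect_equal(pooled_rmse(p0), 0)
  # direct oracle on random diffs
  set.seed(23)
  d1 <- sample(-5:5, 40, replace = TRUE); d2 <- sample(-5:5, 40, replace = TRUE)
  base <- 100 * seq_along(d1)
  pr <- match_events(mk_result(base, base + d1, base + 20 + d2),
                     mk_labels(base, base + 20))
  expect_equal(pooled_rmse(pr), sqrt(mean(c(d1^2, d2^2))))
  # an unmatched event raises the RMSE via the penalty
  res <- mk_result(c(100, 200), c(100, 200), c(120, 220))
  lab <- mk_labels(c(100, 200, 500), c(120, 220, 520))
  pu <- match_events(res, lab)
  expect_gt(pooled_rmse(pu),
            pooled_rmse(pu[pu$matched, ], penalty = attr(pu, "max_sep")^2))
})

test_that("evaluation report bundles the table columns and swaps sign", {
  st <- generate_trial(synthetic_spec(seed = 6))
  pairs <- match_events(detect_cods(st$trial), st$truth)
  rep <- evaluate_agreement(pairs, test_type = "VCUT")
  tab <- report_table(rep)
  expect_setequal(names(tab),
                  c("test", "frame", "median", "mode", "IQR",
                    "abs_E", "s_E", "AP_2", "AP_3", "AP_4"))
  expect_equal(tab$frame, c("IF", "FF"))
  # perfect detection: all AP 100, |E| 0
  expect_true(all(tab$abs_E == 0))
  expect_true(all(tab[, c("AP_2", "AP_3", "AP_4")] == 100))
  # antisymmetry: swapping the roles flips the bias sign
  d <- c(2, -1, 3, 0)
  base <- 100 * 1:4
  pf <- match_events(mk_result(base, base + d, base + 20),
                     mk_labels(base, base + 20))
  pb <- match_events(mk_result(base, base - d, base + 20),
                     mk_labels(base, base + 20))
  expect_equal(bland_altman(pf, "IF")$bias, -bland_altman(pb, "IF")$bias)
})
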