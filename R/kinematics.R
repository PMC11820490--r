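#' Trunk horizontal speed
#'
#' Euclidean norm of the trunk velocity components in the horizontal plane,
#' frame by frame. This is the braking/propulsion signal whose local minima
#' mark candidate changes of direction.
#'
#' @param trial A [motion_trial()].
#' @return Numeric vector of speeds (m/s), one per frame, nonnegative.
#' @export
compute_horizontal_velocity <- function(trial) {
  stopifnot(inherits(trial, "motion_trial"))
  sqrt(trial$trunk_vx^2 + trial$trunk_vy^2)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Applies an order-`order` Butterworth low-pass design forward and backward
#' (two-way), so the output has no phase lag: features of symmetric inputs
#' keep their position. To suppress start/end transients where a sprint
#' begins and stops abruptly, the series is extended by odd reflection
#' (point-mirrored about the end samples) before the two-way pass and trimmed
#' afterwards.
#'
#' @param x Numeric vector, the raw speed series.
#' @param frame_rate Sampling rate in Hz.
#' @param cutoff Cut-off frequency in Hz (default 1.5).
#' @param order Filter order of a single pass (default 4; the two-way
#'   magnitude response is that of an order-8 filter with no cutoff
#'   correction).
#' @param pad One of `"odd"` (default), `"even"`, `"none"`: edge padding used
#'   before the two-way pass.
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, frame_rate, cutoff = 1.5, order = 4,
                           pad = c("odd", "even", "none")) {
  pad <- match.arg(pad)
  x <- as.numeric(x)
  n <- length(x)
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= frame_rate / 2)
    stop("cutoff must lie strictly between 0 and the Nyquist frequency (",
         frame_rate / 2, " Hz)")
  # same warm-up rule as the usual forward-backward implementations
  padlen <- 3L * (order + 1L)
  min_n <- padlen + 1L
  if (n < min_n)
    stop("series too short for stable two-way filtering: need at least ",
         min_n, " samples, got ", n)
  bf <- signal::butter(order, cutoff / (frame_rate / 2), type = "low")
  xe <- switch(pad,
    odd  = c(2 * x[1] - x[(padlen + 1L):2L], x,
             2 * x[n] - x[(n - 1L):(n - padlen)]),
    even = c(x[(padlen + 1L):2L], x, x[(n - 1L):(n - padlen)]),
    none = x)
  zi <- .lfilter_zi(bf$b, bf$a)
  yf <- .lfilter(bf$b, bf$a, xe, zi * xe[1])           # forward
  yb <- .lfilter(bf$b, bf$a, rev(yf), zi * yf[length(yf)])  # backward
  ye <- rev(yb)
  if (pad == "none") ye else ye[(padlen + 1L):(padlen + n)]
}

# direct-form-II-transposed IIR filter with initial state zi; a[1] == 1
.lfilter <- function(b, a, x, zi) {
  n <- length(x)
  m <- length(a) - 1L
  z <- c(zi, 0)
  y <- numeric(n)
  for (t in seq_len(n)) {
    xt <- x[t]
    yt <- b[1] * xt + z[1]
    for (k in seq_len(m))
      z[k] <- b[k + 1] * xt + z[k + 1] - a[k + 1] * yt
    y[t] <- yt
  }
  y
}

# steady-state filter state for a unit-amplitude step input, so the
# forward-backward pass starts transient-free (constant in -> constant out)
.lfilter_zi <- function(b, a) {
  m <- length(a) - 1L
  comp <- matrix(0, m, m)
  comp[1, ] <- -a[2:(m + 1)] / a[1]
  if (m > 1) comp[cbind(2:m, 1:(m - 1))] <- 1
  B <- b[2:(m + 1)] - a[2:(m + 1)] * b[1]
  solve(diag(m) - t(comp), B)
}

#' Prominence-qualified local minima of a speed trace
#'
#' Finds every interior local minimum whose prominence — the depth of the
#' trough relative to the lower of the two enclosing higher flanks, i.e. the
#' standard peak prominence computed on the negated series — meets the
#' threshold. Endpoints are never minima; a plateau minimum is reported at
#' its first frame.
#'
#' @param filtered Numeric vector (finite), typically the filtered speed.
#' @param prominence Minimum prominence (m/s) for a trough to qualify
#'   (default 1.5).
#' @return Data frame with columns `frame` (0-based), `value`, `prominence`,
#'   ordered by frame. Zero rows when nothing qualifies.
#' @export
find_velocity_minima <- function(filtered, prominence = 1.5) {
  x <- as.numeric(filtered)
  if (anyNA(x) || any(!is.finite(x))) stop("series must be finite-valued")
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] < x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] > x[i]) cand <- c(cand, i)  # plateau start
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand))
    return(data.frame(frame = integer(0), value = numeric(0),
                      prominence = numeric(0)))
  prom <- vapply(cand, function(m) .min_prominence(x, m), numeric(1))
  keep <- prom >= prominence
  data.frame(frame = cand[keep] - 1L,  # to 0-based
             value = x[cand[keep]],
             prominence = prom[keep])
}

# prominence of the local minimum at 1-based index m: extend left and right
# until a strictly lower sample (or the series end); the flank height on each
# side is the maximum over the traversed stretch, and the prominence is the
# lower flank minus the trough value.
.min_prominence <- function(x, m) {
  v <- x[m]
  n <- length(x)
  left <- v
  k <- m - 1L
  while (k >= 1L && x[k] >= v) {
    if (x[k] > left) left <- x[k]
    k <- k - 1L
  }
  right <- v
  k <- m + 1L
  while (k <= n && x[k] >= v) {
    if (x[k] > right) right <- x[k]
    k <- k + 1L
  }
  min(left, right) - v
}
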