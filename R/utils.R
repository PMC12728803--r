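#' Symmetric Hann (Hanning) window with zero endpoints
#'
#' Raised-cosine taper of length `n` whose first and last samples are exactly
#' zero, as required for click-free template subtraction.
#'
#' @param n Window length in samples (`n >= 1`).
#' @return Numeric vector of length `n`.
#' @keywords internal
hann_window <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(0)
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
}

assert_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive finite number.", name),
          class = "lfpclean_invalid_argument")
  }
  invisible(x)
}

# local maxima by strict rise / fall (plateaus take the first sample)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(diff(sign(diff(x))) < 0) + 1L
  idx[x[idx] > x[pmax(idx - 1L, 1L)] & x[idx] >= x[pmin(idx + 1L, n)]]
}

#' Peak prominence
#'
#' Height of each peak above the higher of the two key saddle points, i.e.
#' the minimum between the peak and the nearest higher sample on each side
#' (signal edges count as boundaries), as used by MATLAB's `findpeaks`.
#'
#' @param x Numeric signal.
#' @param peaks Integer indices of local maxima of `x`.
#' @return Numeric vector of prominences, one per peak.
#' @keywords internal
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    # walk left until a strictly higher sample (or the edge)
    left <- x[seq_len(p - 1L)]
    higher <- which(left > h)
    lmin <- if (length(higher)) min(x[(max(higher) + 1L):(p - 1L)]) else
      if (p > 1L) min(left) else h
    right <- if (p < length(x)) x[(p + 1L):length(x)] else numeric(0)
    higher <- which(right > h)
    rmin <- if (length(higher)) min(right[seq_len(min(higher) - 1L)]) else
      if (length(right)) min(right) else h
    h - max(lmin, rmin)
  }, numeric(1))
}

# greedy minimum-distance enforcement, tallest peaks first (findpeaks-style)
enforce_min_distance <- function(peaks, heights, min_dist) {
  if (!length(peaks)) return(integer(0))
  ord <- order(heights, decreasing = TRUE)
  keep <- logical(length(peaks))
  for (i in ord) {
    if (!any(keep & abs(peaks - peaks[i]) < min_dist)) keep[i] <- TRUE
  }
  sort(peaks[keep])
}
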