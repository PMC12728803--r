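#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an aperiodic fit
#'
#' One row per model parameter (`k`, `x`, `b`) with its estimate.
#'
#' @param x An `aperiodic_fit`.
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `pass`.
#' @export
tidy.aperiodic_fit <- function(x, ...) {
  tibble(term = c("k", "x", "b"),
         estimate = c(x$k, x$x, x$b),
         pass = x$pass)
}

#' @rdname tidy.aperiodic_fit
#' @return For `glance`: a one-row tibble with fit-quality summaries.
#' @export
glance.aperiodic_fit <- function(x, ...) {
  r <- x$residual$residual
  tibble(pass = x$pass, n_fit_bins = length(x$fit_frequencies),
         rss = sum(r^2), sigma = sd(r),
         frac_negative = mean(r < -0.05))
}

#' Tidy a Grubbs window-rejection result
#'
#' @param x A `grubbs_result`.
#' @param ... Unused.
#' @return For `tidy`: the per-window table (already tidy). For `glance`: a
#'   one-row summary with the threshold and rejection count.
#' @export
tidy.grubbs_result <- function(x, ...) as_tibble(x)

#' @rdname tidy.grubbs_result
#' @export
glance.grubbs_result <- function(x, ...) {
  tibble(basis = attr(x, "basis"), n_windows = attr(x, "n_windows"),
         alpha = attr(x, "alpha"), z_threshold = attr(x, "z_threshold"),
         n_rejected = sum(x$rejected))
}
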