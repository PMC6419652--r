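#' Amplitude gating window
#'
#' The window [L, U] on the respiratory surrogate amplitude that retains a
#' prescribed fraction (duty cycle) of acquired data. \code{width_W_mm} is
#' U - L; \code{achieved_duty} is the fraction of trace samples actually
#' falling inside the closed interval (>= the requested duty when amplitude
#' values repeat).
#'
#' @param lower_L_mm,upper_U_mm window limits (mm).
#' @param achieved_duty fraction of samples inside [L, U].
#' @param duty_requested the requested duty cycle.
#' @param n number of trace samples.
#' @return An object of class \code{gating_window}.
#' @export
gating_window <- function(lower_L_mm, upper_U_mm, achieved_duty,
                          duty_requested, n) {
  if (upper_U_mm < lower_L_mm) stop("upper limit below lower limit")
  structure(list(lower_L_mm = lower_L_mm,
                 upper_U_mm = upper_U_mm,
                 width_W_mm = upper_U_mm - lower_L_mm,
                 achieved_duty = achieved_duty,
                 duty_requested = duty_requested,
                 n = n),
            class = "gating_window")
}

#' @export
print.gating_window <- function(x, ...) {
  cat("<gating_window> [", signif(x$lower_L_mm, 6), ", ",
      signif(x$upper_U_mm, 6), "] mm, W = ", signif(x$width_W_mm, 6),
      " mm; duty ", signif(x$achieved_duty, 4), " (requested ",
      signif(x$duty_requested, 4), ")\n", sep = "")
  invisible(x)
}

check_duty <- function(trace, duty) {
  stopifnot(inherits(trace, "respiratory_trace"))
  if (duty <= 0 || duty > 1) stop("duty must be in (0, 1]")
  n <- length(trace$amplitudes_mm)
  if (n < 2L) stop("trace must have at least 2 samples")
  n
}

#' Optimal amplitude window for a duty cycle
#'
#' Scans candidate lower limits L over the observed amplitude values; for each
#' L the upper limit U is the smallest value covering at least the requested
#' fraction of samples, and the optimum is the window minimising the width
#' W = U - L. Implemented as a sliding window of size k = ceiling(duty * n)
#' over the sorted amplitudes, which attains the exhaustive-search minimum;
#' ties in W are broken toward the smallest L (end-expiration preference).
#'
#' @param trace a \code{\link{respiratory_trace}}.
#' @param duty requested duty cycle in (0, 1]; the clinical default is 0.35.
#' @return A \code{\link{gating_window}}.
#' @export
optimal_amplitude_window <- function(trace, duty = 0.35) {
  n <- check_duty(trace, duty)
  a <- sort(trace$amplitudes_mm)
  k <- ceiling(duty * n)
  i <- seq_len(n - k + 1L)
  w <- a[i + k - 1L] - a[i]
  best <- which.min(w)  # first minimum = smallest L after sorting
  L <- a[best]
  U <- a[best + k - 1L]
  ach <- mean(trace$amplitudes_mm >= L & trace$amplitudes_mm <= U)
  gating_window(L, U, ach, duty, n)
}

#' Exhaustive-search gating window (test oracle)
#'
#' Same contract as \code{\link{optimal_amplitude_window}} but found by
#' scanning, for every candidate lower limit among the distinct amplitude
#' values, all feasible upper limits via cumulative sample counts. Quadratic;
#' intended for traces of a few thousand samples.
#'
#' @inheritParams optimal_amplitude_window
#' @return A \code{\link{gating_window}}.
#' @export
brute_force_window <- function(trace, duty = 0.35) {
  n <- check_duty(trace, duty)
  k <- ceiling(duty * n)
  a <- sort(trace$amplitudes_mm)
  u <- unique(a)
  m <- length(u)
  cum <- cumsum(tabulate(match(a, u), nbins = m))  # samples <= u[j]
  bestW <- Inf; bestL <- NA_real_; bestU <- NA_real_
  for (i in seq_len(m)) {
    below <- if (i == 1L) 0 else cum[i - 1L]
    feasible <- (cum - below) >= k
    if (!any(feasible)) next
    j <- which(feasible)[1L]
    W <- u[j] - u[i]
    if (W < bestW) {  # strict: ties keep the earlier (smaller) L
      bestW <- W; bestL <- u[i]; bestU <- u[j]
    }
  }
  ach <- mean(trace$amplitudes_mm >= bestL & trace$amplitudes_mm <= bestU)
  gating_window(bestL, bestU, ach, duty, n)
}

#' Frames falling inside a gating window
#'
#' @param trace a \code{\link{respiratory_trace}}.
#' @param window a \code{\link{gating_window}}.
#' @return Integer vector of frame indices whose amplitude lies in
#'   \code{[lower_L_mm, upper_U_mm]} (closed interval).
#' @export
select_frames <- function(trace, window) {
  stopifnot(inherits(trace, "respiratory_trace"),
            inherits(window, "gating_window"))
  which(trace$amplitudes_mm >= window$lower_L_mm &
        trace$amplitudes_mm <= window$upper_U_mm)
}

#' Gated image for a duty cycle
#'
#' Convenience composition: optimal window on the stack's trace, frame
#' selection, then frame averaging.
#'
#' @param stack a \code{\link{frame_stack}}.
#' @param duty requested duty cycle (default 0.35).
#' @return A \code{\link{phantom_image}} with the resolved
#'   \code{gating_window} attached as attribute \code{"window"}.
#' @export
gated_image <- function(stack, duty = 0.35) {
  stopifnot(inherits(stack, "frame_stack"))
  w <- optimal_amplitude_window(stack$trace, duty)
  img <- sum_frames(stack, select_frames(stack$trace, w))
  attr(img, "window") <- w
  img
}
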