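#' Construct an FMSF fluorescence trace
#'
#' A trace is a uniformly sampled time series of skin NADH fluorescence in
#' arbitrary units (a.u.). The AngioExpert-class devices sample at 25 Hz;
#' any rate fast enough to resolve the myogenic band (> 0.3 Hz) is accepted.
#'
#' @param fluorescence Numeric vector of fluorescence samples, a.u., no
#'   missing values.
#' @param sampling_rate Sampling rate in Hz. Ignored when \code{time} is
#'   supplied (the rate is then inferred from the time step).
#' @param time Optional numeric vector of sample times in seconds; must be
#'   strictly increasing with a constant step (relative tolerance
#'   \code{tol}).
#' @param tol Relative tolerance on time-step uniformity.
#' @return An object of class \code{"fmsf_trace"} with elements
#'   \code{time}, \code{fluorescence} and \code{sampling_rate}.
#' @examples
#' tr <- fmsf_trace(100 + rnorm(250), sampling_rate = 25)
#' tr
#' @export
fmsf_trace <- function(fluorescence, sampling_rate = 25, time = NULL,
                       tol = 1e-9) {
  fluorescence <- as.numeric(fluorescence)
  if (length(fluorescence) < 2L)
    stop("a trace needs at least two samples")
  if (anyNA(fluorescence) || any(!is.finite(fluorescence)))
    stop("fluorescence must be finite with no missing values")
  if (!is.null(time)) {
    time <- as.numeric(time)
    if (length(time) != length(fluorescence))
      stop("time and fluorescence lengths differ")
    steps <- diff(time)
    if (any(steps <= 0))
      stop("time must be strictly increasing")
    step <- mean(steps)
    if (max(abs(steps - step)) > tol * max(step, 1))
      stop("time is not uniformly sampled within tolerance")
    sampling_rate <- 1 / step
  } else {
    if (!is.finite(sampling_rate) || sampling_rate <= 0)
      stop("sampling_rate must be positive")
    time <- (seq_along(fluorescence) - 1) / sampling_rate
  }
  structure(list(time = time, fluorescence = fluorescence,
                 sampling_rate = sampling_rate),
            class = "fmsf_trace")
}

#' @export
print.fmsf_trace <- function(x, ...) {
  cat(sprintf("FMSF trace: %d samples at %g Hz (%.1f s)\n",
              length(x$fluorescence), x$sampling_rate,
              length(x$fluorescence) / x$sampling_rate))
  cat(sprintf("  fluorescence range %.2f - %.2f a.u.\n",
              min(x$fluorescence), max(x$fluorescence)))
  invisible(x)
}

#' @export
length.fmsf_trace <- function(x) length(x$fluorescence)

#' @export
plot.fmsf_trace <- function(x, seg = NULL, ...) {
  graphics::plot(x$time, x$fluorescence, type = "l",
                 xlab = "time [s]", ylab = "fluorescence [a.u.]", ...)
  if (!is.null(seg)) {
    bounds <- x$time[c(seg$occlusion[1], seg$hyperemic[1],
                       seg$reperfusion[1])]
    graphics::abline(v = bounds, lty = 3, col = "grey40")
  }
  invisible(x)
}
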