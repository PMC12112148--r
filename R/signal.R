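#' Segment an FMSF trace into protocol phases
#'
#' Splits the trace into the four contiguous phases of the occlusion
#' protocol: baseline, occlusion, hyperemic window and reperfusion. The
#' phases partition the protocol span exactly (no gap, no overlap); samples
#' beyond the protocol span, if any, are ignored.
#'
#' @param trace An \code{\link{fmsf_trace}}.
#' @param protocol An \code{\link{fmsf_protocol}}.
#' @return An object of class \code{"fmsf_segmentation"}: a list of four
#'   integer vectors \code{c(start, end)} of 1-based sample indices,
#'   half-open on the right (the phase covers \code{start:(end - 1)}).
#' @examples
#' tr <- simulate_trace(trace_sim_config(seed = 1))
#' segment_phases(tr, fmsf_protocol())
#' @export
segment_phases <- function(trace, protocol = fmsf_protocol()) {
  stopifnot(inherits(trace, "fmsf_trace"), inherits(protocol, "fmsf_protocol"))
  fs <- trace$sampling_rate
  n_need <- round(total_duration(protocol) * fs)
  n <- length(trace$fluorescence)
  if (n < n_need) {
    stop(sprintf("truncated trace: %.1f s missing (%d samples present, %d required)",
                 (n_need - n) / fs, n, n_need))
  }
  b_end <- round(protocol$baseline_duration * fs)
  o_end <- b_end + round(protocol$occlusion_duration * fs)
  h_end <- o_end + round(protocol$hyperemic_window * fs)
  r_end <- n_need
  structure(list(baseline    = c(1L, b_end + 1L),
                 occlusion   = c(b_end + 1L, o_end + 1L),
                 hyperemic   = c(o_end + 1L, h_end + 1L),
                 reperfusion = c(h_end + 1L, r_end + 1L)),
            class = "fmsf_segmentation")
}

#' @export
print.fmsf_segmentation <- function(x, ...) {
  cat("FMSF phase segmentation (half-open sample intervals)\n")
  for (ph in names(x))
    cat(sprintf("  %-11s [%d, %d)  (%d samples)\n", ph,
                x[[ph]][1] - 1L, x[[ph]][2] - 1L, x[[ph]][2] - x[[ph]][1]))
  invisible(x)
}

# 1-based sample indices of a named phase
phase_indices <- function(seg, phase) {
  iv <- seg[[phase]]
  if (is.null(iv)) stop("unknown phase: ", phase)
  seq.int(iv[1], iv[2] - 1L)
}

#' Estimate the resting baseline fluorescence level
#'
#' The resting level is the arithmetic mean of the fluorescence over the
#' baseline phase; excursion parameters (IRmax, HRmax) are expressed
#' relative to it.
#'
#' @param trace An \code{\link{fmsf_trace}}.
#' @param seg A segmentation from \code{\link{segment_phases}}.
#' @return Baseline level in a.u.
#' @export
estimate_baseline <- function(trace, seg) {
  idx <- phase_indices(seg, "baseline")
  if (length(idx) == 0L) stop("empty baseline interval")
  mean(trace$fluorescence[idx])
}

#' Remove the linear trend from an analysis window
#'
#' Fits a least-squares straight line to the window and returns the
#' residual, so that slow drift does not leak into the endothelial band of
#' the subsequent spectral decomposition. The residual has zero mean and
#' the operation is idempotent.
#'
#' @param segment Numeric vector of fluorescence samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param low_cut Optional lower analysis frequency in Hz. When supplied,
#'   the window must span at least two periods of \code{low_cut}, otherwise
#'   an error is raised.
#' @return Zero-mean numeric residual vector of the same length.
#' @examples
#' detrend_window(seq(90, 110, length.out = 100), 25)
#' @export
detrend_window <- function(segment, sampling_rate, low_cut = NULL) {
  segment <- as.numeric(segment)
  n <- length(segment)
  if (n < 3L) stop("window too short to detrend (need >= 3 samples)")
  if (!is.null(low_cut)) {
    need <- 2 / low_cut
    if (n / sampling_rate < need)
      stop(sprintf("window too short for low_cut: %.1f s available, %.1f s (two periods at %g Hz) required",
                   n / sampling_rate, need, low_cut))
  }
  t <- (seq_len(n) - 1) / sampling_rate
  tc <- t - mean(t)
  slope <- sum(tc * segment) / sum(tc * tc)
  segment - mean(segment) - slope * tc
}

#' Decompose an oscillatory residual into physiological frequency bands
#'
#' Computes a rectangular-window periodogram from a single FFT of the whole
#' window and sums the mean-square contribution of every frequency bin whose
#' center lies in each band. A bin at frequency f belongs to a band when
#' lower < f <= upper, making the three bands a partition of
#' (low_cut, myogenic_upper]. By Parseval's theorem the bin contributions
#' over all frequencies sum to the mean square of the residual.
#'
#' @param residual Zero-mean numeric vector, typically from
#'   \code{\link{detrend_window}}.
#' @param sampling_rate Sampling rate in Hz; must exceed twice the myogenic
#'   upper edge.
#' @param bands An \code{\link{fmsf_bands}} object.
#' @param window_label Label recorded on the result, \code{"baseline"} or
#'   \code{"reperfusion"}.
#' @return An object of class \code{"fmsf_bandpower"} with elements
#'   \code{endo}, \code{neuro}, \code{myo} (mean-square contributions,
#'   a.u.^2), \code{total_ms} (mean square of the residual),
#'   \code{below_cut}, \code{above_myo} (out-of-band power) and
#'   \code{window_label}.
#' @examples
#' fs <- 5
#' t <- (0:2999) / fs
#' r <- 2 * sin(2 * pi * 0.03 * t)
#' band_decompose(detrend_window(r, fs), fs)
#' @export
band_decompose <- function(residual, sampling_rate, bands = fmsf_bands(),
                           window_label = "baseline") {
  stopifnot(inherits(bands, "fmsf_bands"))
  if (sampling_rate <= 2 * bands$myogenic_upper)
    stop(sprintf("sampling too slow: %g Hz cannot resolve the myogenic band up to %g Hz",
                 sampling_rate, bands$myogenic_upper))
  residual <- as.numeric(residual)
  n <- length(residual)
  if (n < 4L) stop("residual too short for spectral decomposition")
  x <- stats::fft(residual)
  # one-sided mean-square contribution per bin; Nyquist bin (even n) unpaired
  kmax <- n %/% 2
  k <- seq_len(kmax)
  ms <- (Mod(x[k + 1L])^2) / n^2 * 2
  if (n %% 2 == 0) ms[kmax] <- ms[kmax] / 2
  freq <- k * sampling_rate / n
  in_band <- function(lo, hi) sum(ms[freq > lo & freq <= hi])
  endo  <- in_band(bands$low_cut, bands$endothelial_upper)
  neuro <- in_band(bands$endothelial_upper, bands$neurogenic_upper)
  myo   <- in_band(bands$neurogenic_upper, bands$myogenic_upper)
  structure(list(endo = endo, neuro = neuro, myo = myo,
                 below_cut = in_band(0, bands$low_cut),
                 above_myo = in_band(bands$myogenic_upper, Inf),
                 total_ms = mean(residual^2),
                 window_label = window_label,
                 bands = bands),
            class = "fmsf_bandpower")
}

#' @export
print.fmsf_bandpower <- function(x, ...) {
  cat(sprintf("Band power (%s window) [a.u.^2]\n", x$window_label))
  cat(sprintf("  endothelial %.4g | neurogenic %.4g | myogenic %.4g\n",
              x$endo, x$neuro, x$myo))
  cat(sprintf("  total mean square %.4g (out of band %.4g)\n", x$total_ms,
              x$below_cut + x$above_myo))
  invisible(x)
}
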