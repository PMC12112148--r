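#' Measurement protocol for a post-occlusive reactive hyperemia recording
#'
#' Describes the timing of the cuff-occlusion protocol under which an FMSF
#' trace is recorded: a resting baseline, brachial occlusion at a cuff
#' pressure above systolic, and a post-release period whose first part (the
#' hyperemic window) contains the rapid NADH-fluorescence undershoot and
#' whose remainder is the reperfusion phase.
#'
#' @param baseline_duration Baseline recording length in seconds.
#' @param occlusion_duration Occlusion length in seconds.
#' @param post_release_duration Post-release recording length in seconds.
#' @param hyperemic_window Length in seconds of the initial post-release
#'   window containing the hyperemic undershoot. Must not exceed
#'   \code{post_release_duration}.
#' @param cuff_overpressure Cuff pressure above systolic, mmHg. Recorded for
#'   provenance; it does not enter any computation.
#' @return An object of class \code{"fmsf_protocol"}.
#' @examples
#' p <- fmsf_protocol()
#' p$baseline_duration
#' @export
fmsf_protocol <- function(baseline_duration = 180,
                          occlusion_duration = 180,
                          post_release_duration = 180,
                          hyperemic_window = 30,
                          cuff_overpressure = 60) {
  durs <- c(baseline_duration, occlusion_duration, post_release_duration,
            hyperemic_window)
  if (any(!is.finite(durs)) || any(durs <= 0))
    stop("all protocol durations must be positive and finite")
  if (hyperemic_window > post_release_duration)
    stop("hyperemic_window must not exceed post_release_duration")
  structure(list(baseline_duration = baseline_duration,
                 occlusion_duration = occlusion_duration,
                 post_release_duration = post_release_duration,
                 hyperemic_window = hyperemic_window,
                 cuff_overpressure = cuff_overpressure),
            class = "fmsf_protocol")
}

#' @export
print.fmsf_protocol <- function(x, ...) {
  cat("FMSF measurement protocol\n")
  cat(sprintf("  baseline %g s | occlusion %g s | post-release %g s\n",
              x$baseline_duration, x$occlusion_duration,
              x$post_release_duration))
  cat(sprintf("  hyperemic window %g s, cuff +%g mmHg above systolic\n",
              x$hyperemic_window, x$cuff_overpressure))
  invisible(x)
}

total_duration <- function(protocol) {
  protocol$baseline_duration + protocol$occlusion_duration +
    protocol$post_release_duration
}

#' Frequency bands of low-frequency microcirculatory oscillations
#'
#' Flowmotion in the skin microcirculation is conventionally partitioned
#' into endothelial (NO-mediated), neurogenic (sympathetic) and myogenic
#' (vascular smooth muscle) bands below 0.15 Hz. \code{low_cut} excludes DC
#' and residual drift slower than the analysis window can resolve.
#'
#' @param low_cut Lower frequency bound in Hz (> 0); content below it is
#'   treated as drift, not oscillation.
#' @param endothelial_upper Upper edge of the endothelial band, Hz.
#' @param neurogenic_upper Upper edge of the neurogenic band, Hz.
#' @param myogenic_upper Upper edge of the myogenic band, Hz.
#' @return An object of class \code{"fmsf_bands"}.
#' @examples
#' fmsf_bands()
#' @export
fmsf_bands <- function(low_cut = 0.005,
                       endothelial_upper = 0.021,
                       neurogenic_upper = 0.052,
                       myogenic_upper = 0.15) {
  edges <- c(low_cut, endothelial_upper, neurogenic_upper, myogenic_upper)
  if (any(!is.finite(edges)) || low_cut <= 0 || any(diff(edges) <= 0))
    stop("band edges must satisfy 0 < low_cut < endothelial_upper ",
         "< neurogenic_upper < myogenic_upper")
  structure(list(low_cut = low_cut,
                 endothelial_upper = endothelial_upper,
                 neurogenic_upper = neurogenic_upper,
                 myogenic_upper = myogenic_upper),
            class = "fmsf_bands")
}

#' @export
print.fmsf_bands <- function(x, ...) {
  cat("Flowmotion frequency bands [Hz]\n")
  cat(sprintf("  endothelial (%.3f, %.3f]  neurogenic (%.3f, %.3f]  myogenic (%.3f, %.3f]\n",
              x$low_cut, x$endothelial_upper,
              x$endothelial_upper, x$neurogenic_upper,
              x$neurogenic_upper, x$myogenic_upper))
  invisible(x)
}
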