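#' Baseline flowmotion: mean-square oscillation of the detrended signal
#'
#' Flowmotion (FM) quantifies low-frequency microcirculatory oscillation as
#' the mean of squared deviations of the fluorescence signal from its
#' (detrended) baseline.
#'
#' @param residual Zero-mean residual from \code{\link{detrend_window}}.
#' @return FM in a.u.^2 (non-negative).
#' @export
compute_flowmotion <- function(residual) {
  residual <- as.numeric(residual)
  if (length(residual) == 0L) stop("empty residual")
  mean(residual^2)
}

#' Named baseline band parameters from a band decomposition
#'
#' @param components An \code{"fmsf_bandpower"} from
#'   \code{\link{band_decompose}} over the baseline window.
#' @return Named numeric vector \code{c(ENDO, NEURO, MYO)} in a.u.^2.
#' @export
compute_band_parameters <- function(components) {
  stopifnot(inherits(components, "fmsf_bandpower"))
  v <- c(ENDO = components$endo, NEURO = components$neuro,
         MYO = components$myo)
  if (any(v < 0)) stop("negative band component: upstream contract violated")
  v
}

#' Normoxia oscillatory index
#'
#' NOI is the percentage of baseline low-frequency oscillatory power
#' attributable to the endothelial plus neurogenic bands:
#' \code{100 * (ENDO + NEURO) / (ENDO + NEURO + MYO)}. Values below ~60%
#' are reported in states of vascular stress.
#'
#' @param endo,neuro,myo Non-negative band mean squares, a.u.^2.
#' @return NOI in percent, in [0, 100]; \code{NA} with a warning when all
#'   three components are zero.
#' @examples
#' compute_noi(2, 3, 5)
#' @export
compute_noi <- function(endo, neuro, myo) {
  if (any(c(endo, neuro, myo) < 0)) stop("band components must be >= 0")
  tot <- endo + neuro + myo
  if (tot == 0) {
    warning("all band components are zero; NOI is undefined")
    return(NA_real_)
  }
  100 * (endo + neuro) / tot
}

#' Ischemic response: peak fluorescence rise during occlusion
#'
#' IRmax is the peak increase of NADH fluorescence during the occlusion
#' phase, relative to the resting level, in percent. A negative IRmax (the
#' occlusion maximum never exceeds baseline) flags evident mitochondrial
#' dysfunction and is used as an exclusion criterion at the cohort level.
#'
#' @param trace An \code{\link{fmsf_trace}}.
#' @param seg Segmentation from \code{\link{segment_phases}}.
#' @param baseline_level Resting level from \code{\link{estimate_baseline}};
#'   must be positive.
#' @return IRmax in percent (may be negative).
#' @export
compute_ischemic_response <- function(trace, seg, baseline_level) {
  if (!is.finite(baseline_level) || baseline_level <= 0)
    stop("baseline_level must be positive")
  idx <- phase_indices(seg, "occlusion")
  if (length(idx) == 0L) stop("empty occlusion interval")
  100 * (max(trace$fluorescence[idx]) - baseline_level) / baseline_level
}

#' Hyperemic response: maximum fluorescence dip after cuff release
#'
#' HRmax is the maximum decrease of NADH fluorescence below the resting
#' level over the whole post-release span (hyperemic window plus
#' reperfusion), in percent, reported as a positive magnitude; 0 when the
#' signal never dips below baseline.
#'
#' @inheritParams compute_ischemic_response
#' @return HRmax in percent (>= 0).
#' @export
compute_hyperemic_response <- function(trace, seg, baseline_level) {
  if (!is.finite(baseline_level) || baseline_level <= 0)
    stop("baseline_level must be positive")
  idx <- c(phase_indices(seg, "hyperemic"), phase_indices(seg, "reperfusion"))
  if (length(idx) == 0L) stop("empty post-release interval")
  max(0, 100 * (baseline_level - min(trace$fluorescence[idx])) / baseline_level)
}

#' Reactive hyperemia response
#'
#' RHR summarizes the total ischemia-to-hyperemia fluorescence excursion as
#' the sum of the ischemic rise and the hyperemic dip, both in percent of
#' the resting level.
#'
#' @param ir_max Ischemic response, percent.
#' @param hr_max Hyperemic response, percent.
#' @return RHR = IRmax + HRmax, percent.
#' @export
compute_rhr <- function(ir_max, hr_max) ir_max + hr_max

#' Hypoxia sensitivity and reperfusion flowmotion
#'
#' FM(R) is the mean-square flowmotion of the detrended reperfusion window;
#' HS is its myogenic-band component (absolute magnitude, a.u.^2), indexing
#' the myogenic microvascular response to the transient hypoxia of the
#' occlusion. The myogenic share in percent of FM(R) is also returned.
#'
#' @param reperfusion_components An \code{"fmsf_bandpower"} computed on the
#'   reperfusion window.
#' @return Named vector \code{c(FM_R, HS, HS_pct)}.
#' @export
compute_hypoxia_sensitivity <- function(reperfusion_components) {
  stopifnot(inherits(reperfusion_components, "fmsf_bandpower"))
  if (!identical(reperfusion_components$window_label, "reperfusion"))
    stop("components must be computed on the reperfusion window")
  fm_r <- reperfusion_components$total_ms
  hs <- reperfusion_components$myo
  c(FM_R = fm_r, HS = hs,
    HS_pct = if (fm_r > 0) 100 * hs / fm_r else NA_real_)
}

#' Base-10 logarithm with an explicit missing-value policy
#'
#' FM-family magnitudes are right-skewed; their log10 transforms are
#' approximately normal and are the scale on which group comparisons are
#' made. Non-positive or missing input yields \code{NA} with a warning
#' rather than an error, so a subject is retained with the transformed
#' field missing.
#'
#' @param value Numeric scalar.
#' @return \code{log10(value)}, or \code{NA} when \code{value <= 0}.
#' @export
log_transform <- function(value) {
  if (is.na(value)) return(NA_real_)
  if (value <= 0) {
    warning("log transform undefined for non-positive value; returning NA")
    return(NA_real_)
  }
  log10(value)
}
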