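#' Analyze an FMSF trace: the full per-subject parameter set
#'
#' The central analysis of the package. The trace is segmented into the
#' four protocol phases; the baseline window is linearly detrended and its
#' oscillation decomposed into endothelial, neurogenic and myogenic bands;
#' excursion parameters are measured against the resting level; and the
#' reperfusion window is decomposed the same way for hypoxia sensitivity.
#'
#' The derived scalars are:
#' \describe{
#'   \item{FM}{baseline flowmotion, mean-square oscillation, a.u.^2}
#'   \item{ENDO, NEURO, MYO}{baseline band components, a.u.^2}
#'   \item{NOI}{normoxia oscillatory index, percent of baseline
#'     low-frequency power in the endothelial + neurogenic bands}
#'   \item{IRmax}{peak ischemic fluorescence rise, percent (negative values
#'     flag mitochondrial dysfunction)}
#'   \item{HRmax}{maximum post-release dip below baseline, percent}
#'   \item{RHR}{reactive hyperemia response, IRmax + HRmax, percent}
#'   \item{FM_R}{reperfusion-window flowmotion, a.u.^2}
#'   \item{HS}{hypoxia sensitivity, myogenic component of FM_R, a.u.^2}
#'   \item{HS_pct}{myogenic share of FM_R, percent}
#'   \item{logFM, logNEURO, logHS}{base-10 logs (NA when the value is
#'     non-positive)}
#' }
#'
#' @param trace An \code{\link{fmsf_trace}}.
#' @param protocol An \code{\link{fmsf_protocol}}.
#' @param bands An \code{\link{fmsf_bands}}.
#' @return An object of class \code{"fmsf"}; see
#'   \code{\link{coef.fmsf}}, \code{\link{summary.fmsf}},
#'   \code{\link{plot.fmsf}}, \code{\link{residuals.fmsf}},
#'   \code{\link{simulate.fmsf}}.
#' @examples
#' tr <- simulate_trace(trace_sim_config(seed = 7))
#' fit <- fmsf(tr)
#' coef(fit)
#' @export
fmsf <- function(trace, protocol = fmsf_protocol(), bands = fmsf_bands()) {
  stopifnot(inherits(trace, "fmsf_trace"))
  seg <- segment_phases(trace, protocol)
  fs <- trace$sampling_rate
  level <- estimate_baseline(trace, seg)

  res_base <- detrend_window(trace$fluorescence[phase_indices(seg, "baseline")], fs)
  bp_base <- band_decompose(res_base, fs, bands, window_label = "baseline")
  fm <- compute_flowmotion(res_base)
  bc <- compute_band_parameters(bp_base)
  noi <- compute_noi(bc[["ENDO"]], bc[["NEURO"]], bc[["MYO"]])

  ir <- compute_ischemic_response(trace, seg, level)
  hr <- compute_hyperemic_response(trace, seg, level)
  rhr <- compute_rhr(ir, hr)

  res_rep <- detrend_window(trace$fluorescence[phase_indices(seg, "reperfusion")], fs)
  bp_rep <- band_decompose(res_rep, fs, bands, window_label = "reperfusion")
  hs <- compute_hypoxia_sensitivity(bp_rep)

  params <- c(FM = fm, bc, NOI = noi, IRmax = ir, HRmax = hr, RHR = rhr,
              hs,
              logFM = suppressWarnings(log_transform(fm)),
              logNEURO = suppressWarnings(log_transform(bc[["NEURO"]])),
              logHS = suppressWarnings(log_transform(hs[["HS"]])))

  structure(list(parameters = params,
                 baseline_level = level,
                 segmentation = seg,
                 band_power = list(baseline = bp_base, reperfusion = bp_rep),
                 residuals = list(baseline = res_base, reperfusion = res_rep),
                 trace = trace, protocol = protocol, bands = bands),
            class = "fmsf")
}

#' Extract the derived vascular parameters
#'
#' @param object An \code{"fmsf"} fit.
#' @param ... Unused.
#' @return Named numeric vector of the derived parameters.
#' @export
coef.fmsf <- function(object, ...) object$parameters

#' @export
print.fmsf <- function(x, ...) {
  p <- x$parameters
  cat("FMSF analysis\n")
  cat(sprintf("  baseline level %.1f a.u.; %d samples at %g Hz\n",
              x$baseline_level, length(x$trace), x$trace$sampling_rate))
  cat(sprintf("  FM %.2f  NEURO %.2f  NOI %.1f%%\n",
              p[["FM"]], p[["NEURO"]], p[["NOI"]]))
  cat(sprintf("  IRmax %.1f%%  HRmax %.1f%%  RHR %.1f%%  HS %.2f\n",
              p[["IRmax"]], p[["HRmax"]], p[["RHR"]], p[["HS"]]))
  invisible(x)
}

#' Summary of an FMSF analysis
#'
#' @param object An \code{"fmsf"} fit.
#' @param ... Unused.
#' @return An object of class \code{"summary.fmsf"}.
#' @export
summary.fmsf <- function(object, ...) {
  structure(list(parameters = object$parameters,
                 baseline_level = object$baseline_level,
                 band_power = object$band_power,
                 segmentation = object$segmentation,
                 dysfunction_flag = is.finite(object$parameters[["IRmax"]]) &&
                   object$parameters[["IRmax"]] < 0),
            class = "summary.fmsf")
}

#' @export
print.summary.fmsf <- function(x, ...) {
  cat("FMSF analysis summary\n")
  cat(sprintf("  baseline level: %.2f a.u.\n", x$baseline_level))
  p <- x$parameters
  tab <- data.frame(value = round(unname(p), 3), row.names = names(p))
  print(tab)
  if (x$dysfunction_flag)
    cat("  note: IRmax < 0 (negative ischemic response -",
        "mitochondrial dysfunction flag)\n")
  invisible(x)
}

#' Oscillatory residuals of an FMSF analysis
#'
#' @param object An \code{"fmsf"} fit.
#' @param window Which analysis window, \code{"baseline"} or
#'   \code{"reperfusion"}.
#' @param ... Unused.
#' @return Zero-mean numeric residual vector.
#' @export
residuals.fmsf <- function(object, window = c("baseline", "reperfusion"), ...) {
  window <- match.arg(window)
  object$residuals[[window]]
}

#' Plot an analyzed FMSF trace
#'
#' Draws the trace with phase boundaries, the resting level, and the
#' baseline-window periodogram with band edges.
#'
#' @param x An \code{"fmsf"} fit.
#' @param which 1 = trace, 2 = baseline periodogram, or both.
#' @param ... Passed to the underlying plot calls.
#' @export
plot.fmsf <- function(x, which = 1:2, ...) {
  op <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    plot(x$trace, seg = x$segmentation,
         main = "FMSF trace with protocol phases", ...)
    graphics::abline(h = x$baseline_level, lty = 2, col = "steelblue")
  }
  if (2 %in% which) {
    r <- x$residuals$baseline
    fs <- x$trace$sampling_rate
    n <- length(r)
    k <- seq_len(n %/% 2)
    ms <- (Mod(stats::fft(r)[k + 1])^2) / n^2 * 2
    freq <- k * fs / n
    keep <- freq <= 1.5 * x$bands$myogenic_upper
    graphics::plot(freq[keep], ms[keep], type = "h",
                   xlab = "frequency [Hz]", ylab = "mean-square [a.u.^2]",
                   main = "baseline periodogram")
    graphics::abline(v = c(x$bands$endothelial_upper, x$bands$neurogenic_upper,
                           x$bands$myogenic_upper), lty = 3, col = "grey40")
  }
  invisible(x)
}

#' Simulate traces matching a fitted FMSF analysis
#'
#' Builds a synthetic-trace configuration whose ground truth matches the
#' fitted parameters (band powers placed as single mid-band tones, matching
#' excursion fractions) and simulates from it. Useful for parametric-style
#' resampling of a measured subject.
#'
#' @param object An \code{"fmsf"} fit.
#' @param nsim Number of traces.
#' @param seed Integer seed.
#' @param noise_sd Additive white-noise SD, a.u.
#' @param ... Unused.
#' @return List of \code{nsim} \code{\link{fmsf_trace}} objects.
#' @export
simulate.fmsf <- function(object, nsim = 1, seed = NULL, noise_sd = 0, ...) {
  p <- object$parameters
  tone <- function(power, freq) {
    if (power <= 0) return(NULL)
    data.frame(freq = freq, amp = sqrt(2 * power), phase = NA_real_)
  }
  base_tones <- do.call(rbind, c(list(tone(p[["ENDO"]], 0.0111),
                                      tone(p[["NEURO"]], 0.0333),
                                      tone(p[["MYO"]], 0.1))))
  rep_tones <- do.call(rbind, c(list(tone(max(0, p[["FM_R"]] - p[["HS"]]), 0.04),
                                     tone(p[["HS"]], 0.1))))
  cfg <- trace_sim_config(
    baseline_level = object$baseline_level,
    baseline_tones = base_tones,
    reperfusion_tones = rep_tones,
    ischemic_rise = p[["IRmax"]] / 100,
    hyperemic_dip = p[["HRmax"]] / 100,
    noise_sd = noise_sd,
    protocol = object$protocol,
    sampling_rate = object$trace$sampling_rate)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    cfg$seed <- if (is.null(seed)) NULL else seed + i - 1L
    simulate_trace(cfg)
  })
}
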