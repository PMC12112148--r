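#' Configuration for a synthetic FMSF trace
#'
#' Parameterizes the canonical trace morphology: a flat oscillating
#' baseline, a saturating-exponential fluorescence rise under occlusion, a
#' rapid post-release undershoot reaching its minimum inside the hyperemic
#' window, and an exponential recovery with resumed oscillations during
#' reperfusion. Ground truth is exact: with tones placed on the Fourier
#' grid of their analysis window, injected band mean-squares equal the
#' band powers the analysis recovers (up to linear-detrend absorption of
#' very slow tones).
#'
#' @param baseline_level Resting fluorescence level, a.u. (> 0).
#' @param baseline_tones Data frame with columns \code{freq} (Hz),
#'   \code{amp} (a.u.) and optionally \code{phase} (radians; \code{NA}
#'   means drawn uniformly at simulation time), describing the baseline
#'   oscillation. \code{NULL} for none.
#' @param reperfusion_tones Same format, for the reperfusion window.
#' @param ischemic_rise Target peak occlusion rise as a fraction of
#'   baseline (IRmax / 100); may be negative (dysfunctional response).
#' @param hyperemic_dip Target post-release undershoot depth as a fraction
#'   of baseline (HRmax / 100); must be >= 0.
#' @param tau_rise,tau_dip,tau_recovery Time constants in seconds of the
#'   occlusion rise, hyperemic decline and reperfusion recovery.
#' @param osc_onset_tau Time constant in seconds of the envelope with
#'   which reperfusion oscillations resume after the hyperemic minimum.
#' @param noise_sd Additive white Gaussian noise SD, a.u. (>= 0).
#' @param protocol An \code{\link{fmsf_protocol}}.
#' @param sampling_rate Sampling rate in Hz.
#' @param seed Optional integer seed; the same full configuration with the
#'   same seed reproduces the trace exactly.
#' @return An object of class \code{"trace_sim_config"}.
#' @export
trace_sim_config <- function(baseline_level = 1000,
                             baseline_tones = NULL,
                             reperfusion_tones = NULL,
                             ischemic_rise = 0.12,
                             hyperemic_dip = 0.16,
                             tau_rise = 20, tau_dip = 10, tau_recovery = 40,
                             osc_onset_tau = 15,
                             noise_sd = 0,
                             protocol = fmsf_protocol(),
                             sampling_rate = 25,
                             seed = NULL) {
  if (!is.finite(baseline_level) || baseline_level <= 0)
    stop("baseline_level must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (hyperemic_dip < 0) stop("hyperemic_dip must be >= 0")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  check_tones <- function(tones, what) {
    if (is.null(tones)) return(NULL)
    tones <- as.data.frame(tones)
    if (!all(c("freq", "amp") %in% names(tones)))
      stop(what, " must have columns freq and amp")
    if (is.null(tones$phase)) tones$phase <- NA_real_
    if (any(tones$freq <= 0) || any(tones$freq >= sampling_rate / 2))
      stop(what, ": frequencies must lie in (0, sampling_rate / 2)")
    if (any(tones$amp < 0)) stop(what, ": amplitudes must be >= 0")
    tones
  }
  structure(list(baseline_level = baseline_level,
                 baseline_tones = check_tones(baseline_tones, "baseline_tones"),
                 reperfusion_tones = check_tones(reperfusion_tones,
                                                 "reperfusion_tones"),
                 ischemic_rise = ischemic_rise,
                 hyperemic_dip = hyperemic_dip,
                 tau_rise = tau_rise, tau_dip = tau_dip,
                 tau_recovery = tau_recovery,
                 osc_onset_tau = osc_onset_tau,
                 noise_sd = noise_sd, protocol = protocol,
                 sampling_rate = sampling_rate, seed = seed),
            class = "trace_sim_config")
}

#' Tones grouped by physiological band
#'
#' Convenience constructor that validates each tone frequency against the
#' band it is declared in and returns the flat tone table
#' \code{\link{trace_sim_config}} expects.
#'
#' @param endothelial,neurogenic,myogenic Data frames with columns
#'   \code{freq}, \code{amp} and optionally \code{phase}, or \code{NULL}.
#' @param bands An \code{\link{fmsf_bands}} giving the band edges.
#' @return A tone data frame with an added \code{band} column.
#' @export
band_tones <- function(endothelial = NULL, neurogenic = NULL,
                       myogenic = NULL, bands = fmsf_bands()) {
  lims <- list(endothelial = c(bands$low_cut, bands$endothelial_upper),
               neurogenic = c(bands$endothelial_upper, bands$neurogenic_upper),
               myogenic = c(bands$neurogenic_upper, bands$myogenic_upper))
  specs <- list(endothelial = endothelial, neurogenic = neurogenic,
                myogenic = myogenic)
  out <- NULL
  for (b in names(specs)) {
    tn <- specs[[b]]
    if (is.null(tn)) next
    tn <- as.data.frame(tn)
    lo <- lims[[b]][1]; hi <- lims[[b]][2]
    if (any(tn$freq <= lo | tn$freq > hi))
      stop(sprintf("%s tone frequency outside (%g, %g] Hz", b, lo, hi))
    if (is.null(tn$phase)) tn$phase <- NA_real_
    tn$band <- b
    out <- rbind(out, tn[, c("freq", "amp", "phase", "band")])
  }
  out
}

# evaluate a tone table at times t (phases must be resolved)
eval_tones <- function(tones, t) {
  if (is.null(tones) || nrow(tones) == 0L) return(numeric(length(t)))
  out <- numeric(length(t))
  for (i in seq_len(nrow(tones)))
    out <- out + tones$amp[i] * sin(2 * pi * tones$freq[i] * t +
                                    tones$phase[i])
  out
}

#' Simulate an FMSF trace with known ground truth
#'
#' Generates one trace of exactly the protocol duration. Phase structure:
#' baseline = level + tones + noise; occlusion rises
#' saturating-exponentially toward \code{level * (1 + ischemic_rise)};
#' the hyperemic segment declines so that it attains exactly
#' \code{level * (1 - hyperemic_dip)} at the end of the hyperemic window;
#' reperfusion recovers exponentially toward the level while the
#' reperfusion tones ramp in under a \code{1 - exp(-t / osc_onset_tau)}
#' envelope (so the global minimum stays inside the hyperemic window).
#' The same configuration and seed reproduce the trace bit-identically.
#'
#' @param config A \code{\link{trace_sim_config}}.
#' @return An \code{\link{fmsf_trace}}.
#' @examples
#' tr <- simulate_trace(trace_sim_config(seed = 1))
#' coef(fmsf(tr))[c("IRmax", "HRmax")]
#' @export
simulate_trace <- function(config) {
  stopifnot(inherits(config, "trace_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  p <- config$protocol
  fs <- config$sampling_rate
  nb <- round(p$baseline_duration * fs)
  no <- round(p$occlusion_duration * fs)
  nh <- round(p$hyperemic_window * fs)
  nr <- round((p$post_release_duration - p$hyperemic_window) * fs)
  lev <- config$baseline_level

  draw_phases <- function(tones) {
    if (is.null(tones)) return(NULL)
    miss <- is.na(tones$phase)
    if (any(miss)) tones$phase[miss] <- stats::runif(sum(miss), 0, 2 * pi)
    tones
  }
  btones <- draw_phases(config$baseline_tones)
  rtones <- draw_phases(config$reperfusion_tones)

  # baseline
  tb <- (seq_len(nb) - 1) / fs
  baseline <- lev + eval_tones(btones, tb)
  # occlusion: saturating rise toward lev * (1 + rise)
  to <- seq_len(no) / fs
  occl <- lev * (1 + config$ischemic_rise * (1 - exp(-to / config$tau_rise)))
  v0 <- occl[no]
  # hyperemic: exponential decline calibrated to hit the target minimum
  # exactly at the last sample of the window
  m <- lev * (1 - config$hyperemic_dip)
  th <- seq_len(nh) / fs
  q <- exp(-th[nh] / config$tau_dip)
  target <- (m - v0 * q) / (1 - q)
  hyper <- target + (v0 - target) * exp(-th / config$tau_dip)
  # reperfusion: recovery toward the level, oscillations ramping in
  tr_ <- seq_len(nr) / fs
  env <- 1 - exp(-tr_ / config$osc_onset_tau)
  reper <- lev - (lev - m) * exp(-tr_ / config$tau_recovery) +
    env * eval_tones(rtones, tr_)

  y <- c(baseline, occl, hyper, reper)
  if (config$noise_sd > 0)
    y <- y + stats::rnorm(length(y), 0, config$noise_sd)
  fmsf_trace(y, sampling_rate = fs)
}

# moment-matched log-normal draws: mean m and SD s on the natural scale
rlnorm_moment <- function(n, m, s) {
  if (s == 0) return(rep(m, n))
  if (m <= 0) stop("log-normal target mean must be positive when SD > 0")
  sdlog <- sqrt(log(1 + (s / m)^2))
  stats::rlnorm(n, log(m) - sdlog^2 / 2, sdlog)
}

#' Group-level simulation specification
#'
#' Describes one cohort group by target distributions of the FMSF
#' parameters on the reported scale: log-normal (moment-matched mean and
#' SD) for the positive right-skewed band powers ENDO, NEURO, MYO and HS;
#' normal for the excursion percentages IRmax and HRmax (IRmax may go
#' negative, reproducing dysfunctional responses). Demographics are drawn
#' from normal distributions and comorbidity flags from Bernoulli rates.
#'
#' @param label Group label, e.g. \code{"AA"}, \code{"AU"},
#'   \code{"control"}.
#' @param n Number of subjects (>= 1).
#' @param endo,neuro,myo,hs Length-2 vectors \code{c(mean, sd)} of the
#'   band mean squares, a.u.^2 (log-normal targets).
#' @param ir_max,hr_max Length-2 vectors \code{c(mean, sd)} in percent
#'   (normal targets; simulated HRmax dips are clamped at 0).
#' @param age,bmi,sbp,dbp Length-2 vectors \code{c(mean, sd)} of the
#'   demographics.
#' @param flag_probs Named numeric vector of comorbidity-flag
#'   probabilities (names become metadata columns).
#' @param reperfusion_nonmyo_frac Non-myogenic reperfusion power as a
#'   fraction of HS (keeps FM(R) above HS).
#' @param baseline_level,noise_sd,sampling_rate,protocol Trace-level
#'   settings passed through to \code{\link{trace_sim_config}}.
#' @param seed Optional integer group seed (set by
#'   \code{\link{simulate_cohort}} from its master seed).
#' @return An object of class \code{"group_sim_spec"}.
#' @export
group_sim_spec <- function(label, n,
                           endo = c(30, 25), neuro = c(25, 22),
                           myo = c(28, 24), hs = c(75, 70),
                           ir_max = c(13, 6), hr_max = c(18, 5),
                           age = c(45, 13), bmi = c(24.5, 3.5),
                           sbp = c(120, 13), dbp = c(78, 9),
                           flag_probs = c(smoking = 0.1, depression = 0.1,
                                          hashimoto = 0.1, hypertension = 0.1,
                                          hypercholesterolemia = 0.05,
                                          diabetes = 0.05),
                           reperfusion_nonmyo_frac = 0.3,
                           baseline_level = 1000, noise_sd = 2,
                           sampling_rate = 25, protocol = fmsf_protocol(),
                           seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  for (nm in c("endo", "neuro", "myo", "hs", "ir_max", "hr_max")) {
    v <- get(nm)
    if (length(v) != 2 || v[2] < 0)
      stop(nm, " must be c(mean, sd) with sd >= 0")
  }
  for (nm in c("endo", "neuro", "myo", "hs"))
    if (get(nm)[2] > 0 && get(nm)[1] <= 0)
      stop(nm, ": log-normal target mean must be positive when SD > 0")
  structure(list(label = label, n = as.integer(n),
                 endo = endo, neuro = neuro, myo = myo, hs = hs,
                 ir_max = ir_max, hr_max = hr_max,
                 age = age, bmi = bmi, sbp = sbp, dbp = dbp,
                 flag_probs = flag_probs,
                 reperfusion_nonmyo_frac = reperfusion_nonmyo_frac,
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 sampling_rate = sampling_rate, protocol = protocol,
                 seed = seed),
            class = "group_sim_spec")
}

# bins of the analysis-window Fourier grid inside a band; tones are placed
# on this grid so that injected band power is recovered without leakage,
# and at >= 2 cycles per window so linear detrending barely touches them
band_bins <- function(window_s, lo, hi) {
  f1 <- 1 / window_s
  k <- seq.int(2, floor(hi / f1))
  k[k * f1 > lo & k * f1 <= hi]
}

# split a band mean-square across 1-3 grid tones with random weights
draw_band_tones <- function(power, window_s, lo, hi) {
  if (power <= 0) return(NULL)
  ks <- band_bins(window_s, lo, hi)
  ntone <- sample.int(min(3L, length(ks)), 1L)
  ks <- if (length(ks) == 1L) ks else sample(ks, ntone)
  w <- stats::runif(length(ks), 0.2, 1)
  w <- w / sum(w)
  data.frame(freq = ks / window_s, amp = sqrt(2 * power * w),
             phase = NA_real_)
}

#' Draw one subject from a group specification
#'
#' Samples per-subject band powers and excursion fractions from the group
#' target distributions, places the band power as tones on the Fourier
#' grid of the relevant analysis window, and returns both the trace
#' configuration and the ground truth actually used.
#'
#' @param spec A \code{\link{group_sim_spec}}.
#' @param index Subject index within the group (drives the derived seed).
#' @return List with elements \code{config} (a
#'   \code{\link{trace_sim_config}}), \code{truth} (one-row data frame of
#'   the injected parameter values) and \code{metadata} (one-row data
#'   frame of demographics).
#' @export
simulate_subject <- function(spec, index) {
  stopifnot(inherits(spec, "group_sim_spec"))
  if (!is.null(spec$seed))
    set.seed((as.integer(spec$seed) + 1009L * as.integer(index)) %%
               .Machine$integer.max)
  p <- spec$protocol
  base_win <- p$baseline_duration
  rep_win <- p$post_release_duration - p$hyperemic_window
  bands <- fmsf_bands()

  endo_p <- rlnorm_moment(1, spec$endo[1], spec$endo[2])
  neuro_p <- rlnorm_moment(1, spec$neuro[1], spec$neuro[2])
  myo_p <- rlnorm_moment(1, spec$myo[1], spec$myo[2])
  hs_p <- rlnorm_moment(1, spec$hs[1], spec$hs[2])
  ir <- stats::rnorm(1, spec$ir_max[1], spec$ir_max[2])
  hr <- max(0, stats::rnorm(1, spec$hr_max[1], spec$hr_max[2]))

  btones <- rbind(
    draw_band_tones(endo_p, base_win, bands$low_cut, bands$endothelial_upper),
    draw_band_tones(neuro_p, base_win, bands$endothelial_upper,
                    bands$neurogenic_upper),
    draw_band_tones(myo_p, base_win, bands$neurogenic_upper,
                    bands$myogenic_upper))
  rtones <- rbind(
    draw_band_tones(spec$reperfusion_nonmyo_frac * hs_p, rep_win,
                    bands$endothelial_upper, bands$neurogenic_upper),
    draw_band_tones(hs_p, rep_win, bands$neurogenic_upper,
                    bands$myogenic_upper))

  cfg <- trace_sim_config(
    baseline_level = spec$baseline_level,
    baseline_tones = btones, reperfusion_tones = rtones,
    ischemic_rise = ir / 100, hyperemic_dip = hr / 100,
    noise_sd = spec$noise_sd, protocol = p,
    sampling_rate = spec$sampling_rate,
    seed = if (is.null(spec$seed)) NULL else
      (as.integer(spec$seed) + 1009L * as.integer(index) + 1L) %%
        .Machine$integer.max)

  tot <- endo_p + neuro_p + myo_p
  truth <- data.frame(
    group = spec$label,
    ENDO = endo_p, NEURO = neuro_p, MYO = myo_p, FM = tot,
    NOI = if (tot > 0) 100 * (endo_p + neuro_p) / tot else NA_real_,
    IRmax = ir, HRmax = hr, RHR = ir + hr,
    HS = hs_p, FM_R = hs_p * (1 + spec$reperfusion_nonmyo_frac))
  metadata <- data.frame(
    group = spec$label, sex = "F",
    age = round(stats::rnorm(1, spec$age[1], spec$age[2]), 1),
    bmi = round(stats::rnorm(1, spec$bmi[1], spec$bmi[2]), 1),
    sbp = round(stats::rnorm(1, spec$sbp[1], spec$sbp[2])),
    dbp = round(stats::rnorm(1, spec$dbp[1], spec$dbp[2])))
  for (fl in names(spec$flag_probs))
    metadata[[fl]] <- as.integer(stats::runif(1) < spec$flag_probs[[fl]])
  list(config = cfg, truth = truth, metadata = metadata)
}

#' Simulate a full case-control cohort
#'
#' Generates every subject of every group with per-subject seeds derived
#' deterministically from one master seed, so the whole cohort is exactly
#' reproducible.
#'
#' @param specs List of \code{\link{group_sim_spec}} objects with distinct
#'   labels.
#' @param master_seed Integer master seed.
#' @return List with elements \code{traces} (named list of
#'   \code{\link{fmsf_trace}}), \code{metadata} (data frame, one row per
#'   subject) and \code{truth} (data frame of injected parameter values,
#'   keyed by \code{subject_id}).
#' @examples
#' specs <- default_group_specs()
#' specs <- lapply(specs, function(s) { s$n <- 2L; s })
#' coh <- simulate_cohort(specs, master_seed = 1)
#' coh$metadata$subject_id
#' @export
simulate_cohort <- function(specs, master_seed) {
  labels <- vapply(specs, function(s) s$label, character(1))
  if (anyDuplicated(labels)) stop("duplicate group labels")
  traces <- list()
  meta <- NULL; truth <- NULL
  for (g in seq_along(specs)) {
    spec <- specs[[g]]
    spec$seed <- (as.integer(master_seed) + 7919L * g) %%
      .Machine$integer.max
    for (i in seq_len(spec$n)) {
      subj <- simulate_subject(spec, i)
      id <- sprintf("%s_%02d", spec$label, i)
      traces[[id]] <- simulate_trace(subj$config)
      meta <- rbind(meta, cbind(data.frame(subject_id = id),
                                subj$metadata))
      truth <- rbind(truth, cbind(data.frame(subject_id = id),
                                  subj$truth))
    }
  }
  list(traces = traces, metadata = meta, truth = truth)
}

#' Reference group specifications for an alopecia areata case-control study
#'
#' Three \code{\link{group_sim_spec}} objects — patchy alopecia areata
#' (AA, n = 18), alopecia universalis (AU, n = 6) and healthy controls
#' (n = 17), all female — with parameter targets set to values typical of
#' such cohorts: markedly reduced flowmotion and neurogenic oscillation in
#' patients, NOI around 55% in patients versus ~74% in controls, and
#' similar ischemic responses across groups. Band powers not reported
#' separately (ENDO, MYO) are apportioned from the FM and NOI targets,
#' with coefficients of variation matched to FM's.
#'
#' @return Named list of three \code{\link{group_sim_spec}} objects.
#' @export
default_group_specs <- function() {
  list(
    AA = group_sim_spec(
      "AA", 18,
      endo = c(17.4, 14.9), neuro = c(13.2, 11.7), myo = c(24.6, 21.1),
      hs = c(62.3, 59.4), ir_max = c(11.6, 6.1), hr_max = c(16.3, 4.1),
      age = c(47.0, 16.9), bmi = c(25.6, 4.7),
      sbp = c(124.8, 16.2), dbp = c(81.5, 8.9),
      flag_probs = c(smoking = 2 / 18, depression = 3 / 18,
                     hashimoto = 5 / 18, hypertension = 3 / 18,
                     hypercholesterolemia = 0, diabetes = 0)),
    AU = group_sim_spec(
      "AU", 6,
      endo = c(8.1, 7.7), neuro = c(6.3, 6.4), myo = c(12.7, 12.1),
      hs = c(67.6, 74.8), ir_max = c(15.3, 7.8), hr_max = c(15.8, 2.8),
      age = c(50.7, 23.4), bmi = c(25.3, 3.9),
      sbp = c(129.7, 19.4), dbp = c(77.5, 11.6),
      flag_probs = c(smoking = 2 / 6, depression = 2 / 6,
                     hashimoto = 2 / 6, hypertension = 2 / 6,
                     hypercholesterolemia = 1 / 6, diabetes = 1 / 6)),
    control = group_sim_spec(
      "control", 17,
      endo = c(45.8, 37.2), neuro = c(47.3, 45.0), myo = c(32.1, 26.1),
      hs = c(84.3, 78.0), ir_max = c(13.8, 5.6), hr_max = c(20.4, 5.1),
      age = c(44.6, 12.0), bmi = c(23.9, 3.2),
      sbp = c(117.9, 11.6), dbp = c(76.5, 7.4),
      flag_probs = c(smoking = 1 / 17, depression = 0, hashimoto = 0,
                     hypertension = 0, hypercholesterolemia = 0,
                     diabetes = 0)))
}
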