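# Brute-force discrete-Fourier oracle, independent of the package's FFT
# path: computes each bin by the direct O(N^2) sum and returns one-sided
# mean-square contributions per bin, plus a band integrator.
dft_spectrum <- function(x, fs) {
  n <- length(x)
  kmax <- n %/% 2
  ms <- numeric(kmax)
  tt <- seq_len(n) - 1
  for (k in seq_len(kmax)) {
    re <- sum(x * cos(2 * pi * k * tt / n))
    im <- sum(x * sin(2 * pi * k * tt / n))
    ms[k] <- (re^2 + im^2) / n^2 * 2
    if (n %% 2 == 0 && k == kmax) ms[k] <- ms[k] / 2
  }
  list(freq = seq_len(kmax) * fs / n, ms = ms)
}

dft_band_ms <- function(x, fs, lo, hi) {
  sp <- dft_spectrum(x, fs)
  sum(sp$ms[sp$freq > lo & sp$freq <= hi])
}

# constant-level trace with prescribed occlusion/post-release excursions,
# for direct arithmetic checks of the excursion parameters
excursion_trace <- function(level = 100, occl_max = 112, post_min = 84,
                            fs = 25, protocol = fmsf_protocol()) {
  nb <- protocol$baseline_duration * fs
  no <- protocol$occlusion_duration * fs
  np <- protocol$post_release_duration * fs
  y <- c(rep(level, nb), rep(min(level, occl_max), no), rep(level, np))
  y[nb + no %/% 2] <- occl_max
  y[nb + no + np %/% 2] <- post_min
  fmsf_trace(y, sampling_rate = fs)
}
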