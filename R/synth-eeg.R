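# Synthetic multichannel EEG with class-dependent band-power signatures.
#
# Each channel is an independent realization of 1/f-shaped Gaussian
# background noise plus band-limited oscillations in the theta, alpha and
# beta bands. Class labels modulate the oscillation power per band; the
# ictal class additionally superimposes high-amplitude 3-5 Hz rhythmic
# bursts. Synthesis happens in the frequency domain (Hermitian random
# spectrum, one inverse FFT per component), which makes long records cheap
# and fully seed-deterministic.

#' Default analysis bands
#' @return data.frame with columns `name`, `lo_hz`, `hi_hz`
#' @export
band_definitions <- function() {
  data.frame(name = c("theta", "alpha", "beta"),
             lo_hz = c(4, 8, 13), hi_hz = c(7, 13, 30))
}

#' Specification for the synthetic EEG generator
#'
#' @param n_channels number of channels
#' @param fs sampling rate (Hz)
#' @param class_band_gains named list of per-class power multipliers over the
#'   (theta, alpha, beta) oscillation components
#' @param noise_exponent exponent of the 1/f background power spectrum
#' @param band_strength power of each band oscillation at gain 1, as a
#'   multiple of the background power inside that band
#' @param bg_rms background RMS amplitude in microvolts
#' @param seed base seed; per-record sub-seeds are derived from it
#' @export
synth_spec <- function(n_channels = 23L, fs = 256,
                       class_band_gains = list(
                         interictal = c(theta = 1, alpha = 1, beta = 1),
                         preictal = c(theta = 3, alpha = 2, beta = 1.5),
                         ictal = c(theta = 4, alpha = 1.5, beta = 2)),
                       noise_exponent = 1, band_strength = 1.5,
                       bg_rms = 30, seed = 1L) {
  stopifnot(n_channels >= 1L, fs > 60)
  for (g in class_band_gains) if (any(g <= 0)) stop("band gains must be positive")
  structure(list(n_channels = as.integer(n_channels), fs = fs,
                 class_band_gains = class_band_gains,
                 noise_exponent = noise_exponent,
                 band_strength = band_strength, bg_rms = bg_rms,
                 seed = as.integer(seed), bands = band_definitions()),
            class = "synth_spec")
}

# sparse one-sided power profile components on the FFT frequency grid of
# length n: each component is a list(idx, p) of positive-frequency bin
# indices (into 1..n, DC excluded) and their powers. The 1/f background is
# synthesized up to `bg_max_hz`; the pipeline low-passes at 30 Hz, so higher
# frequencies never reach the spectral images.
power_profiles <- function(spec, n, bg_max_hz = 45) {
  nh <- n %/% 2
  f <- seq_len(nh) * spec$fs / n            # positive frequencies, no DC
  f0 <- 0.5
  bg_sel <- which(f <= bg_max_hz)
  bg_p <- 1 / pmax(f[bg_sel], f0)^spec$noise_exponent
  bands <- vector("list", nrow(spec$bands))
  for (b in seq_len(nrow(spec$bands))) {
    sel <- which(f >= spec$bands$lo_hz[b] & f <= spec$bands$hi_hz[b])
    pwr <- spec$band_strength * sum(bg_p[sel]) / length(sel)
    bands[[b]] <- list(idx = sel + 1L, p = rep(pwr, length(sel)))
  }
  list(bg = list(idx = bg_sel + 1L, p = bg_p), bands = bands)
}

# synthesize one channel from a sparse one-sided power profile:
# a stationary Gaussian series whose PSD follows the profile
channel_from_profile <- function(prof, n) {
  m <- length(prof$idx)
  amp <- sqrt(prof$p / 2)
  Z <- complex(real = stats::rnorm(m) * amp, imaginary = stats::rnorm(m) * amp)
  X <- complex(length.out = n)
  X[prof$idx] <- Z
  X[n + 2L - prof$idx] <- Conj(Z)
  Re(stats::fft(X, inverse = TRUE))
}

#' Generate a synthetic EEG record for one class
#'
#' @param spec a [synth_spec()]
#' @param label one of the classes named in `spec$class_band_gains`
#' @param duration_s record length in seconds
#' @param seed RNG seed for this record (defaults to the spec seed)
#' @param ramp if `TRUE`, band-oscillation power ramps linearly from the
#'   interictal level at the start of the record to the full class level at
#'   the end (used for the preictal period, whose signature strengthens as
#'   the seizure approaches)
#' @return an [eeg_record()] with a single interval labeled `label`
#' @export
gen_eeg <- function(spec, label, duration_s, seed = NULL, ramp = FALSE) {
  stopifnot(inherits(spec, "synth_spec"), duration_s > 0)
  gains <- spec$class_band_gains[[label]]
  if (is.null(gains)) stop("unknown class label: ", label)
  if (is.null(seed)) seed <- spec$seed
  set.seed(seed)
  n <- as.integer(round(duration_s * spec$fs))
  prof <- power_profiles(spec, n)
  # scale such that the background component alone has RMS bg_rms:
  # Var(x) for this synthesis equals n/2 * sum(P) (unnormalized inverse FFT)
  scale <- spec$bg_rms / sqrt(n / 2 * sum(prof$bg$p))
  X <- matrix(0, nrow = spec$n_channels, ncol = n)
  tfrac <- if (ramp) seq(0, 1, length.out = n) else NULL
  merged <- prof$bg
  if (!ramp) {
    # band bumps add to the background power in their bins
    for (b in seq_along(prof$bands)) {
      pos <- match(prof$bands[[b]]$idx, prof$bg$idx)
      merged$p[pos] <- merged$p[pos] + gains[b] * prof$bands[[b]]$p
    }
  }
  for (ch in seq_len(spec$n_channels)) {
    if (!ramp) {
      X[ch, ] <- scale * channel_from_profile(merged, n)
    } else {
      x <- channel_from_profile(prof$bg, n)
      for (b in seq_along(prof$bands)) {
        xb <- channel_from_profile(prof$bands[[b]], n)
        env <- sqrt(1 + (gains[b] - 1) * tfrac)
        x <- x + env * xb
      }
      X[ch, ] <- scale * x
    }
  }
  if (label == "ictal") {
    # rhythmic 3-5 Hz high-amplitude bursts, 5 s on / 3 s off, as narrowband
    # noise under a smooth-ramp envelope (0.5 s cosine shoulders keep the
    # burst energy inside its band instead of splattering across the
    # spectrum at analysis time)
    tt <- seq_len(n) / spec$fs
    u <- tt %% 8
    env <- pmin(1, pmax(0, pmin(u, 5 - u) / 0.5))
    nh <- n %/% 2
    f <- seq_len(nh) * spec$fs / n
    bsel <- which(f >= 3 & f <= 5)
    bprof <- list(idx = bsel + 1L, p = rep(1, length(bsel)))
    bsd <- sqrt(n / 2 * sum(bprof$p))
    for (ch in seq_len(spec$n_channels)) {
      xb <- channel_from_profile(bprof, n) / bsd * (3 * spec$bg_rms)
      X[ch, ] <- X[ch, ] + env * xb
    }
  }
  eeg_record(X, spec$fs,
             channel_names = sprintf("ch%02d", seq_len(spec$n_channels)),
             intervals = data.frame(start_s = 0, end_s = n / spec$fs,
                                    label = label))
}

#' Generate a patient cohort for the two study datasets
#'
#' For every patient: 180 min preictal and 180 min interictal recordings
#' (binary prediction dataset) and 60 min preictal (ramped), 30 min ictal,
#' 30 min interictal recordings (four-class detection dataset). Each record
#' gets a distinct sub-seed derived from the spec seed.
#' @param spec a [synth_spec()]
#' @param n_patients cohort size
#' @param database `"I"` (prediction) or `"II"` (detection)
#' @param lazy if `TRUE`, return per-patient generator functions instead of
#'   materialized records (full-scale cohorts are large; lazy generation lets
#'   downstream code process one patient at a time)
#' @param minutes optional named override of per-class durations in minutes
#'   (for reduced-scale runs)
#' @return named list, one element per patient: either a named list of
#'   [eeg_record()]s or (if `lazy`) a function returning that list
#' @export
gen_cohort <- function(spec, n_patients = 10L, database = c("I", "II"),
                       lazy = FALSE, minutes = NULL) {
  database <- match.arg(database)
  plan <- if (database == "I") {
    # three 60-min preictal segments per patient (one per seizure event)
    list(preictal = list(min = 180, ramp = FALSE, events = 3L),
         interictal = list(min = 180, ramp = FALSE, events = 1L))
  } else {
    list(preictal = list(min = 60, ramp = TRUE, events = 1L),
         ictal = list(min = 30, ramp = FALSE, events = 1L),
         interictal = list(min = 30, ramp = FALSE, events = 1L))
  }
  if (!is.null(minutes))
    for (lb in names(minutes)) plan[[lb]]$min <- minutes[[lb]]
  make_patient <- function(pid) {
    force(pid)
    function() {
      recs <- list()
      for (lb in names(plan)) {
        sd <- sub_seed(spec$seed, pid, match(lb, c("interictal", "preictal", "ictal")))
        recs[[lb]] <- gen_eeg(spec, lb, plan[[lb]]$min * 60, seed = sd,
                              ramp = plan[[lb]]$ramp)
        ne <- plan[[lb]]$events
        if (ne > 1L) {
          dur <- plan[[lb]]$min * 60 / ne
          recs[[lb]]$intervals <- data.frame(
            start_s = (seq_len(ne) - 1) * dur, end_s = seq_len(ne) * dur,
            label = lb)
        }
      }
      recs
    }
  }
  out <- lapply(seq_len(n_patients), function(pid) {
    th <- make_patient(pid)
    if (lazy) th else th()
  })
  names(out) <- sprintf("patient%02d", seq_len(n_patients))
  out
}
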