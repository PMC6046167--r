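#' Emotiv-style 14-channel 10-20 montage
#'
#' Channel names of the consumer 14-electrode headset laid out on the
#' international 10-20 system; the four sensorimotor-adjacent channels used
#' for decoding are FC5, F3, F4 and FC6.
#'
#' @param n_channels Number of leading channels to return (max 14).
#' @return Character vector of channel names.
#' @export
emotiv_montage <- function(n_channels = 14L) {
  ch <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
          "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")
  if (n_channels > length(ch))
    stop_afcsp("montage has 14 channels; requested ", n_channels,
               class = "afcsp_bad_config")
  ch[seq_len(n_channels)]
}

#' Channels carrying motor-imagery information
#' @export
selected_channels <- function() c("FC5", "F3", "F4", "FC6")

#' Default class-by-channel ERD depth pattern
#'
#' Event-related desynchronization is simulated as a multiplicative
#' attenuation of the mu- and beta-band oscillation amplitude on a
#' class-specific subset of the four selected channels: flexion attenuates
#' FC5 and F3, extension attenuates F4 and FC6, abduction attenuates FC5 and
#' FC6. The crossed abduction pattern makes all three pairs spatially
#' discriminable.
#'
#' @param depth Attenuation fraction in `[0, 1)` applied on the active
#'   channels (0 = no class information).
#' @param channel_names Montage channel names.
#' @param class_labels Class names (rows of the returned matrix).
#' @return Numeric matrix `length(class_labels)` x `length(channel_names)`.
#' @export
default_erd_depth <- function(depth = 0.5,
                              channel_names = emotiv_montage(),
                              class_labels = c("flexion", "extension",
                                               "abduction")) {
  m <- matrix(0, nrow = length(class_labels), ncol = length(channel_names),
              dimnames = list(class_labels, channel_names))
  active <- list(flexion = c("FC5", "F3"),
                 extension = c("F4", "FC6"),
                 abduction = c("FC5", "FC6"))
  for (cl in intersect(class_labels, names(active)))
    m[cl, intersect(active[[cl]], channel_names)] <- depth
  m
}

#' Simulation configuration for synthetic motor-imagery EEG
#'
#' Defines the recording geometry (14 channels, 128 Hz, 5 s trials, 20
#' trials per class) and the signal model: per channel, 1/f background
#' noise + 50 Hz line interference + amplitude-modulated mu (8-13 Hz) and
#' beta (13-30 Hz) oscillations whose amplitude on the selected channels is
#' scaled by `1 - erd_depth[label, channel]`.
#'
#' Oscillator frequencies are drawn with +/-0.5 Hz jitter around mid-band
#' carriers (10.5 and 21 Hz) and snapped to the trial-length FFT grid, so
#' that with noise turned off the trial spectrum is exactly band-limited.
#'
#' @param n_channels Channel count (default 14).
#' @param fs Sampling rate in Hz.
#' @param trial_dur Trial duration in seconds.
#' @param n_trials_per_class Trials per class.
#' @param class_labels Class enumeration.
#' @param mu_band,beta_band Frequency intervals in Hz.
#' @param erd_depth Class x channel attenuation matrix; entries in `[0, 1)`.
#' @param mu_amp,beta_amp Baseline oscillation amplitudes in microvolts.
#' @param line_noise_amp 50 Hz interference amplitude in microvolts.
#' @param pink_noise_amp 1/f background RMS in microvolts.
#' @param am_depth Amplitude-modulation depth of the oscillations.
#' @param seed Integer seed used by [generate_trialset()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_channels = 14L,
                       fs = 128,
                       trial_dur = 5,
                       n_trials_per_class = 20L,
                       class_labels = c("flexion", "extension", "abduction"),
                       mu_band = c(8, 13),
                       beta_band = c(13, 30),
                       erd_depth = NULL,
                       mu_amp = 10,
                       beta_amp = 6,
                       line_noise_amp = 15,
                       pink_noise_amp = 8,
                       am_depth = 0.3,
                       seed = 1L) {
  channel_names <- emotiv_montage(n_channels)
  if (is.null(erd_depth))
    erd_depth <- default_erd_depth(0.5, channel_names, class_labels)
  if (any(erd_depth < 0) || any(erd_depth >= 1))
    stop_afcsp("erd_depth entries must lie in [0, 1)",
               class = "afcsp_bad_config")
  n_samples <- fs * trial_dur
  if (n_samples != round(n_samples))
    stop_afcsp("fs * trial_dur must be an integer number of samples",
               class = "afcsp_bad_config")
  cfg <- list(n_channels = as.integer(n_channels), fs = fs,
              trial_dur = trial_dur, n_samples = as.integer(n_samples),
              n_trials_per_class = as.integer(n_trials_per_class),
              class_labels = class_labels,
              channel_names = channel_names,
              mu_band = mu_band, beta_band = beta_band,
              erd_depth = erd_depth,
              mu_amp = mu_amp, beta_amp = beta_amp,
              line_noise_amp = line_noise_amp,
              pink_noise_amp = pink_noise_amp,
              am_depth = am_depth,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic motor-imagery EEG configuration\n")
  cat(sprintf("  %d channels @ %g Hz, %g s trials (%d samples)\n",
              x$n_channels, x$fs, x$trial_dur, x$n_samples))
  cat(sprintf("  %d trials/class x {%s}\n", x$n_trials_per_class,
              paste(x$class_labels, collapse = ", ")))
  cat(sprintf("  mu %g uV, beta %g uV, pink %g uV RMS, line %g uV, seed %d\n",
              x$mu_amp, x$beta_amp, x$pink_noise_amp, x$line_noise_amp,
              x$seed))
  invisible(x)
}

# 1/f-power background: white noise spectrally shaped to a 1/sqrt(f)
# amplitude profile, rescaled to the requested RMS. DC is zeroed.
pink_noise <- function(n, fs, rms) {
  if (rms <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  spec <- stats::fft(w)
  f <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  x * rms / sqrt(mean(x^2))
}

# Draw a carrier frequency near `center` with +/-0.5 Hz jitter, snapped to
# the k/dur FFT grid of the full trial (keeps the no-noise spectrum exactly
# band-limited).
draw_grid_freq <- function(center, jitter, dur) {
  f <- center + stats::runif(1, -jitter, jitter)
  round(f * dur) / dur
}

# Amplitude-modulated band oscillation; am frequency is drawn from the
# on-grid set {1,...,4}/dur so sidebands stay within a 1 Hz guard.
band_oscillation <- function(t, amp, center, dur, am_depth) {
  f0 <- draw_grid_freq(center, 0.5, dur)
  fm <- sample(seq_len(4), 1) / dur
  phi <- stats::runif(1, 0, 2 * pi)
  psi <- stats::runif(1, 0, 2 * pi)
  amp * (1 + am_depth * cos(2 * pi * fm * t + psi)) * sin(2 * pi * f0 * t + phi)
}

#' Generate one synthetic EEG trial
#'
#' Draws from the current RNG stream: repeated calls after the same
#' `set.seed()` produce identical trials.
#'
#' @param label Class label; must be one of `cfg$class_labels`.
#' @param cfg A [sim_config()].
#' @return `n_channels x n_samples` matrix in microvolts, rows named by
#'   channel.
#' @export
generate_trial <- function(label, cfg) {
  if (!label %in% cfg$class_labels)
    stop_afcsp("unknown class label: ", label, class = "afcsp_bad_label")
  n <- cfg$n_samples
  t <- (seq_len(n) - 1) / cfg$fs
  X <- matrix(0, nrow = cfg$n_channels, ncol = n,
              dimnames = list(cfg$channel_names, NULL))
  mu_center <- mean(cfg$mu_band) # 10.5 Hz
  beta_center <- 21              # mid beta, clear of both band edges
  for (ci in seq_len(cfg$n_channels)) {
    ch <- cfg$channel_names[ci]
    atten <- 1 - cfg$erd_depth[label, ch]
    x <- band_oscillation(t, cfg$mu_amp * atten, mu_center, cfg$trial_dur,
                          cfg$am_depth) +
      band_oscillation(t, cfg$beta_amp * atten, beta_center, cfg$trial_dur,
                       cfg$am_depth)
    if (cfg$line_noise_amp > 0)
      x <- x + cfg$line_noise_amp * sin(2 * pi * 50 * t +
                                          stats::runif(1, 0, 2 * pi))
    x <- x + pink_noise(n, cfg$fs, cfg$pink_noise_amp)
    X[ci, ] <- x
  }
  X
}

#' Generate a labeled synthetic trial set
#'
#' Produces exactly `n_trials_per_class` trials per class in a recorded
#' shuffled order. Fully deterministic given `cfg` (including `cfg$seed`);
#' the caller's RNG state is preserved.
#'
#' @param cfg A [sim_config()].
#' @param subject_id Identifier stored with the trials.
#' @return A `trialset`: list with `trials` (list of channel x sample
#'   matrices), `labels` (factor), `channel_names`, `fs`, `subject_id`.
#' @export
generate_trialset <- function(cfg, subject_id = "sim01") {
  if (cfg$n_trials_per_class < 1)
    stop_afcsp("n_trials_per_class must be >= 1", class = "afcsp_bad_config")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  labels <- rep(cfg$class_labels, each = cfg$n_trials_per_class)
  ord <- sample(length(labels))
  labels <- labels[ord]
  trials <- lapply(labels, generate_trial, cfg = cfg)
  trialset(trials, labels, cfg$channel_names, cfg$fs, subject_id,
           class_labels = cfg$class_labels)
}

#' Construct a trial set container
#'
#' @param trials List of channel x sample matrices (identical shapes).
#' @param labels Class label per trial.
#' @param channel_names Channel names matching the matrix rows.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param class_labels Level order for the label factor.
#' @return Object of class `trialset`.
#' @export
trialset <- function(trials, labels, channel_names, fs,
                     subject_id = "unknown",
                     class_labels = c("flexion", "extension", "abduction")) {
  stopifnot(length(trials) == length(labels))
  if (!all(labels %in% class_labels))
    stop_afcsp("labels outside the class enumeration: ",
               paste(setdiff(labels, class_labels), collapse = ", "),
               class = "afcsp_bad_label")
  shapes <- vapply(trials, function(m) paste(dim(m), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) > 1)
    stop_afcsp("all trials must share an identical channel x sample shape",
               class = "afcsp_bad_trialset")
  structure(list(trials = trials,
                 labels = factor(labels, levels = class_labels),
                 channel_names = channel_names, fs = fs,
                 subject_id = subject_id),
            class = "trialset")
}

#' @export
print.trialset <- function(x, ...) {
  d <- dim(x$trials[[1]])
  cat(sprintf("trialset '%s': %d trials (%d ch x %d samples @ %g Hz)\n",
              x$subject_id, length(x$trials), d[1], d[2], x$fs))
  print(table(x$labels))
  invisible(x)
}
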