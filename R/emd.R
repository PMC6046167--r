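#' @keywords internal
#' Indices of local maxima and minima of a series (strict left slope,
#' non-strict right slope, so flat-topped extrema register once).
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(maxima = integer(0), minima = integer(0)))
  d <- diff(x)
  # propagate the previous nonzero slope sign through flat runs
  s <- sign(d)
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  ds <- diff(s)
  list(maxima = which(ds < 0) + 1L, minima = which(ds > 0) + 1L)
}

# Cubic-spline envelope through (idx, x[idx]) with two extrema mirrored
# symmetrically past each boundary; suppresses end swings on short windows.
spline_envelope <- function(idx, vals, n) {
  k <- length(idx)
  lm <- which(idx > 1)[seq_len(min(2, sum(idx > 1)))]
  rm_ <- rev(which(idx < n))
  rm_ <- rm_[seq_len(min(2, length(rm_)))]
  xi <- c(2 - idx[lm], idx, 2 * n - idx[rm_])
  yi <- c(vals[lm], vals, vals[rm_])
  o <- order(xi)
  xi <- xi[o]; yi <- yi[o]
  keep <- !duplicated(xi)
  stats::spline(xi[keep], yi[keep], xout = seq_len(n), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Decomposes a series into intrinsic mode functions (IMFs) plus a monotone
#' (or near-extremum-free) residual by iterative sifting: the mean of the
#' upper and lower cubic-spline extrema envelopes is subtracted until the
#' Cauchy criterion `sum((h_prev - h)^2) / sum(h_prev^2) < sd_threshold`
#' fires or `max_sifts` sifts have run. Decomposition stops when the
#' residual has fewer than 3 extrema. The identity
#' `sum(imfs) + residual == x` holds exactly by construction.
#'
#' @param x Numeric series, length >= 64, non-constant.
#' @param max_sifts Per-IMF sift cap.
#' @param sd_threshold Cauchy stopping threshold.
#' @param max_imfs Upper bound on the number of IMFs extracted.
#' @param source_channel Optional channel name carried in the result.
#' @return Object of class `imf_decomposition`: `imfs` (list, fastest
#'   oscillation first), `residual`, `source_channel`.
#' @export
emd <- function(x, max_sifts = 10L, sd_threshold = 0.2, max_imfs = 12L,
                source_channel = NA_character_) {
  if (length(x) < 64)
    stop_afcsp("EMD input too short (", length(x), " < 64 samples)",
               class = "afcsp_bad_input")
  if (max(x) - min(x) < .Machine$double.eps * 64 * max(1, max(abs(x))))
    stop_afcsp("EMD input is constant", class = "afcsp_bad_input")
  n <- length(x)
  r <- x
  imfs <- list()
  while (length(imfs) < max_imfs) {
    ex <- find_extrema(r)
    if (length(ex$maxima) + length(ex$minima) < 3) break
    if (length(ex$maxima) < 2 || length(ex$minima) < 2) break
    h <- r
    for (s in seq_len(max_sifts)) {
      ex_h <- find_extrema(h)
      if (length(ex_h$maxima) < 2 || length(ex_h$minima) < 2) break
      upper <- spline_envelope(ex_h$maxima, h[ex_h$maxima], n)
      lower <- spline_envelope(ex_h$minima, h[ex_h$minima], n)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_k <- sum((h - h_new)^2) / sum(h^2)
      h <- h_new
      if (sd_k < sd_threshold) break
    }
    imfs[[length(imfs) + 1L]] <- h
    r <- r - h
  }
  structure(list(imfs = imfs, residual = r, source_channel = source_channel),
            class = "imf_decomposition")
}

#' @export
print.imf_decomposition <- function(x, ...) {
  cat(sprintf("EMD: %d IMFs + residual (n = %d)%s\n", length(x$imfs),
              length(x$residual),
              if (is.na(x$source_channel)) ""
              else paste0(" [", x$source_channel, "]")))
  invisible(x)
}

#' One-sided FFT amplitude spectrum
#'
#' Rectangular window, no zero padding; one-sided magnitudes scaled by
#' `2/N` (DC and Nyquist by `1/N`) so a unit-amplitude sinusoid on a bin
#' center reads magnitude 1.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @return List with `freq` (Hz) and `mag`.
#' @export
amplitude_spectrum <- function(x, fs) {
  n <- length(x)
  if (n < 2) stop_afcsp("need at least 2 samples", class = "afcsp_bad_input")
  raw <- Mod(stats::fft(x)) / n
  n_half <- floor(n / 2) + 1L
  mag <- raw[seq_len(n_half)] * 2
  mag[1] <- mag[1] / 2
  if (n %% 2 == 0) mag[n_half] <- mag[n_half] / 2
  list(freq = (seq_len(n_half) - 1) * fs / n, mag = mag)
}

af_row_names <- function(channels) {
  c(paste0("IMF1.", channels), paste0("IMF2.", channels))
}

#' Build the per-trial amplitude-frequency (AF) matrix
#'
#' Each of the four preprocessed channels is EMD-decomposed over the
#' analysis window (1-4 s post-cue by default, 384 samples at 128 Hz); the
#' FFT amplitude spectra of IMF1 and IMF2 are restricted to the closed
#' mu+beta interval (8-30 Hz) and stacked into an 8 x M matrix. Row order:
#' IMF1 of each channel in montage order, then IMF2 of each channel.
#'
#' @param trial 4 x sample matrix (a preprocessed trial), rows named by
#'   channel.
#' @param fs Sampling rate in Hz.
#' @param window Analysis window in seconds `(start, end)`.
#' @param band Frequency band in Hz, closed interval.
#' @param ... Passed to [emd()].
#' @return Object of class `af_matrix`: `values` (8 x M), `freq_bins`,
#'   `trial_label`.
#' @export
build_af_matrix <- function(trial, fs, window = c(1, 4), band = c(8, 30),
                            ...) {
  n <- ncol(trial)
  i0 <- round(window[1] * fs) + 1L
  i1 <- round(window[2] * fs)
  if (i0 < 1 || i1 > n)
    stop_afcsp("trial does not cover the analysis window",
               class = "afcsp_bad_input")
  channels <- rownames(trial) %||% paste0("ch", seq_len(nrow(trial)))
  seg_len <- i1 - i0 + 1L
  spec1 <- vector("list", nrow(trial))
  spec2 <- vector("list", nrow(trial))
  for (ci in seq_len(nrow(trial))) {
    dec <- emd(trial[ci, i0:i1], source_channel = channels[ci], ...)
    if (length(dec$imfs) < 2)
      stop_afcsp("EMD produced fewer than 2 IMFs on channel ", channels[ci],
                 class = "afcsp_emd_degenerate")
    spec1[[ci]] <- amplitude_spectrum(dec$imfs[[1]], fs)
    spec2[[ci]] <- amplitude_spectrum(dec$imfs[[2]], fs)
  }
  freq <- spec1[[1]]$freq
  keep <- which(freq >= band[1] - 1e-9 & freq <= band[2] + 1e-9)
  values <- rbind(
    do.call(rbind, lapply(spec1, function(s) s$mag[keep])),
    do.call(rbind, lapply(spec2, function(s) s$mag[keep])))
  dimnames(values) <- list(af_row_names(channels), NULL)
  structure(list(values = values, freq_bins = freq[keep],
                 trial_label = NA_character_),
            class = "af_matrix")
}

#' AF matrices for every trial of a preprocessed trial set
#'
#' The column count M is frozen from the first trial; any later mismatch is
#' an error, guaranteeing a rectangular feature tensor.
#'
#' @param ts A preprocessed `trialset` (4 selected channels).
#' @param window,band,... Passed to [build_af_matrix()].
#' @return List with `afmats` (list of `af_matrix`) and `labels` (factor).
#' @export
build_af_matrices <- function(ts, window = c(1, 4), band = c(8, 30), ...) {
  afmats <- vector("list", length(ts$trials))
  m_cols <- NULL
  for (i in seq_along(ts$trials)) {
    af <- build_af_matrix(ts$trials[[i]], ts$fs, window, band, ...)
    af$trial_label <- as.character(ts$labels[i])
    if (is.null(m_cols)) m_cols <- ncol(af$values)
    if (ncol(af$values) != m_cols)
      stop_afcsp("AF matrix width changed at trial ", i, " (", m_cols,
                 " -> ", ncol(af$values), ")", class = "afcsp_bad_input")
    afmats[[i]] <- af
  }
  list(afmats = afmats, labels = ts$labels)
}
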