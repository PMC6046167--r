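#' Notch filter specification
#'
#' Second-order IIR notch (constrained biquad design) applied zero-phase
#' (forward-backward), so passband tones keep their phase and the effective
#' stopband attenuation doubles. Q = 30 keeps the stopband narrow enough not
#' to erode the upper beta band.
#'
#' @param notch_freq Center frequency to suppress, Hz (power-line 50 Hz).
#' @param notch_q Quality factor `f0 / bandwidth`.
#' @param fs Sampling rate, Hz; must exceed `2 * notch_freq`.
#' @return Object of class `filter_spec` holding the biquad coefficients.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 30, fs = 128) {
  if (fs <= 2 * notch_freq)
    stop_afcsp("notch frequency ", notch_freq,
               " Hz is not below the Nyquist rate for fs = ", fs, " Hz",
               class = "afcsp_bad_config")
  # pre-warped (tangent) bandwidth: accurate even close to Nyquist, where
  # the small-angle biquad approximation widens the notch asymmetrically
  w0 <- 2 * pi * notch_freq / fs
  beta <- tan(w0 / (2 * notch_q))
  gain <- 1 / (1 + beta)
  b <- gain * c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * gain * cos(w0), 2 * gain - 1)
  structure(list(notch_freq = notch_freq, notch_q = notch_q, fs = fs,
                 b = b, a = a),
            class = "filter_spec")
}

#' Zero-phase notch filter
#'
#' @param x Numeric sample series.
#' @param spec A [filter_spec()].
#' @return Filtered series of the same length.
#' @export
notch_filter <- function(x, spec = filter_spec()) {
  n <- length(x)
  pad <- 3L * (length(spec$a) - 1L)
  if (n <= pad + 1L)
    stop_afcsp("signal shorter than the filter warm-up length",
               class = "afcsp_bad_input")
  # odd-reflection extension + steady-state initial conditions suppress the
  # forward-backward edge transients
  zi <- biquad_zi(spec$b, spec$a)
  xe <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- biquad_filter(spec$b, spec$a, xe, zi * xe[1])
  y <- rev(y)
  y <- rev(biquad_filter(spec$b, spec$a, y, zi * y[1]))
  y[(pad + 1):(pad + n)]
}

# Steady-state filter state for a unit step (transient-free startup).
biquad_zi <- function(b, a) {
  rhs <- c(b[2] - b[1] * a[2], b[3] - b[1] * a[3])
  M <- rbind(c(1 + a[2], -1), c(a[3], 1))
  solve(M, rhs)
}

# Second-order section, direct form II transposed.
biquad_filter <- function(b, a, x, zi = c(0, 0)) {
  n <- length(x)
  y <- numeric(n)
  z1 <- zi[1]; z2 <- zi[2]
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + z1
    z1 <- b[2] * x[i] - a[2] * y[i] + z2
    z2 <- b[3] * x[i] - a[3] * y[i]
  }
  y
}

#' Common average reference
#'
#' Subtracts, at every instant, the mean over channels from each channel:
#' `V_i^CAR(t) = V_i(t) - mean_j V_j(t)`. The default scope is the four
#' selected channels (FC5, F3, F4, FC6); pass `n_channels = NULL` to
#' re-reference an arbitrary montage.
#'
#' @param X Channel x sample matrix.
#' @param n_channels Expected channel count (default 4); `NULL` disables the
#'   check.
#' @return Matrix of the same shape with zero instantaneous channel mean.
#' @export
car_reference <- function(X, n_channels = 4L) {
  if (!is.matrix(X) || nrow(X) < 2)
    stop_afcsp("CAR needs a matrix with at least 2 channel rows",
               class = "afcsp_bad_input")
  if (!is.null(n_channels) && nrow(X) != n_channels)
    stop_afcsp("expected ", n_channels, " channels, got ", nrow(X),
               class = "afcsp_bad_input")
  sweep(X, 2, colMeans(X), "-")
}

#' Preprocess a trial set: notch, channel selection, CAR
#'
#' Applies the 50 Hz notch per channel, restricts to the decoding montage
#' (FC5, F3, F4, FC6 by default), then common-average references. With
#' `car_scope = "all"` the CAR average runs over the full montage before
#' channel selection.
#'
#' @param ts A `trialset`.
#' @param channels Channels kept for decoding.
#' @param spec Notch [filter_spec()]; frequency/Q taken at the trial set's
#'   sampling rate.
#' @param car_scope `"selected4"` (average over the selected channels, the
#'   printed-formula convention) or `"all"` (full-montage average).
#' @return A `trialset` containing only the selected, referenced channels.
#' @export
preprocess_trialset <- function(ts, channels = selected_channels(),
                                spec = NULL,
                                car_scope = c("selected4", "all")) {
  car_scope <- match.arg(car_scope)
  spec <- spec %||% filter_spec(fs = ts$fs)
  missing_ch <- setdiff(channels, ts$channel_names)
  if (length(missing_ch))
    stop_afcsp("channels absent from trial set: ",
               paste(missing_ch, collapse = ", "),
               class = "afcsp_bad_input")
  sel <- match(channels, ts$channel_names)
  out <- lapply(ts$trials, function(m) {
    filt <- t(apply(m, 1, notch_filter, spec = spec))
    if (car_scope == "all") {
      car_reference(filt, n_channels = NULL)[sel, , drop = FALSE]
    } else {
      car_reference(filt[sel, , drop = FALSE], n_channels = length(channels))
    }
  })
  trialset(out, as.character(ts$labels), channels, ts$fs, ts$subject_id,
           class_labels = levels(ts$labels))
}
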