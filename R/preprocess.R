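#' Construct an epoch set
#'
#' Per-subject stack of TMS-locked EEG trials. The pulse sample splits the
#' epoch into two equal halves (1 s pre, 1 s post at the default 1000 Hz).
#'
#' @param data trials x channels x samples array (microvolts).
#' @param fs_hz sampling rate.
#' @param pulse_sample index of the last pre-pulse sample.
#' @param channel_labels channel names.
#' @param subject_id,group,site optional cohort metadata.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs_hz, pulse_sample, channel_labels,
                      subject_id = NA_character_, group = NA_character_,
                      site = NA_character_) {
  stopifnot(length(dim(data)) == 3L, dim(data)[2] == length(channel_labels))
  n_samp <- dim(data)[3]
  if (2L * pulse_sample != n_samp) {
    stop("pulse_sample must split the epoch into two equal halves", call. = FALSE)
  }
  structure(list(data = data, fs_hz = fs_hz, pulse_sample = as.integer(pulse_sample),
                 channel_labels = channel_labels, subject_id = subject_id,
                 group = group, site = site),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set '%s': %d trials x %d channels x %d samples @ %g Hz (pulse at %d)\n",
              x$subject_id, d[1], d[2], d[3], x$fs_hz, x$pulse_sample))
  invisible(x)
}

erp_signal <- function(data, fs_hz, pulse_sample, channel_labels, n_trials_used) {
  structure(list(data = data, fs_hz = fs_hz, pulse_sample = as.integer(pulse_sample),
                 channel_labels = channel_labels, n_trials_used = n_trials_used),
            class = "erp_signal")
}

#' Reject trials exceeding an absolute amplitude threshold
#'
#' Drops every trial whose absolute amplitude exceeds `threshold_uv` on any
#' channel at any sample (the +/-75 microvolt artifact gate by default);
#' the order of surviving trials is preserved.
#'
#' @param epochs an `epoch_set`.
#' @param threshold_uv rejection threshold in microvolts (> 0).
#' @return the `epoch_set` with offending trials removed.
#' @export
reject_artifacts <- function(epochs, threshold_uv = 75) {
  stopifnot(threshold_uv > 0)
  # rows of the flattened array are trials (first dimension varies fastest)
  flat <- matrix(abs(epochs$data), nrow = dim(epochs$data)[1])
  keep <- rowSums(flat > threshold_uv) == 0L
  if (!any(keep)) {
    stop(sprintf("subject '%s': no trials survive the +/-%g uV gate",
                 epochs$subject_id, threshold_uv), call. = FALSE)
  }
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  epochs
}

#' Average trials to an event-related potential
#'
#' Pointwise mean over trials; trial-locked signal is preserved while
#' independent noise shrinks as 1/sqrt(N).
#'
#' @param epochs an `epoch_set` with at least one trial.
#' @return an `erp_signal` (channels x samples).
#' @export
average_erp <- function(epochs) {
  n <- dim(epochs$data)[1]
  if (n < 1L) stop("cannot average an empty epoch set", call. = FALSE)
  erp <- colMeans(epochs$data, dims = 1L)   # mean over the trial dimension
  rownames(erp) <- epochs$channel_labels
  erp_signal(erp, epochs$fs_hz, epochs$pulse_sample, epochs$channel_labels, n)
}

#' Design a zero-phase FIR bandpass
#'
#' Hamming-windowed linear-phase FIR whose order scales with the transition
#' width (about 3.3 cycles of the sampling rate per transition hertz,
#' giving at least 40 dB stopband attenuation). The taps are re-centred to
#' an exactly zero DC gain so constant offsets are fully removed even when
#' the lower edge sits close to 0 Hz.
#'
#' @param fs_hz sampling rate.
#' @param low_hz,high_hz band edges, `0 < low < high < fs/2`.
#' @param trans_hz transition width; wider transitions shorten the impulse
#'   response (less temporal smearing of band-limited envelopes) at the cost
#'   of slower roll-off.
#' @return numeric vector of (odd-length, symmetric) filter taps.
#' @keywords internal
design_fir_bandpass <- function(fs_hz, low_hz, high_hz,
                                trans_hz = max(1, 0.25 * low_hz)) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs_hz / 2)) {
    stop(sprintf("invalid band [%g, %g] Hz at fs = %g Hz", low_hz, high_hz, fs_hz),
         call. = FALSE)
  }
  trans <- trans_hz
  ntaps <- ceiling(3.3 * fs_hz / trans)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  h <- signal::fir1(ntaps - 1, c(low_hz, high_hz) / (fs_hz / 2), type = "pass")
  h - mean(h)  # exact null at DC; negligible elsewhere
}

# zero-phase application of a symmetric odd-length FIR, one signal per row;
# reflection padding then FFT convolution, output aligned and trimmed.
fir_filter_matrix <- function(X, h) {
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  pad <- (length(h) - 1L) / 2L
  n <- ncol(X)
  pl <- min(pad, n - 1L)
  idx <- c(pl + 2L - seq_len(pl), seq_len(n), n - seq_len(pl))
  Xp <- X[, idx, drop = FALSE]
  nfft <- stats::nextn(ncol(Xp) + length(h) - 1L, 2)
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  Yp <- t(apply(Xp, 1L, function(x) {
    y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - length(x)))) * H, inverse = TRUE)) / nfft
    y[(pl + pad + 1L):(pl + pad + n)]
  }))
  if (nrow(X) == 1L) Yp <- matrix(Yp, nrow = 1L)
  dimnames(Yp) <- dimnames(X)
  Yp
}

#' Zero-phase FIR bandpass filter an ERP
#'
#' @param signal_ an `erp_signal`.
#' @param low_hz,high_hz passband edges in Hz (defaults 1 and 50).
#' @return the filtered `erp_signal`.
#' @export
bandpass_fir <- function(signal_, low_hz = 1, high_hz = 50) {
  h <- design_fir_bandpass(signal_$fs_hz, low_hz, high_hz)
  signal_$data <- fir_filter_matrix(signal_$data, h)
  signal_
}

#' Decimate an ERP
#'
#' Anti-alias low-pass (FIR, cutoff at 0.8 x the new Nyquist) followed by
#' subsampling. Sample count and sampling rate are divided by `factor`; the
#' pulse index is remapped accordingly.
#'
#' @param signal_ an `erp_signal`.
#' @param factor integer decimation factor (>= 1, must divide the sample count).
#' @return the decimated `erp_signal`.
#' @export
decimate_erp <- function(signal_, factor = 2) {
  stop_if_not_count(factor, "factor")
  if (factor == 1L) return(signal_)
  n <- ncol(signal_$data)
  if (n %% factor != 0) {
    stop(sprintf("decimation factor %d does not divide the sample count %d", factor, n),
         call. = FALSE)
  }
  fs <- signal_$fs_hz
  new_nyq <- fs / (2 * factor)
  trans <- 0.2 * new_nyq
  ntaps <- ceiling(3.3 * fs / trans)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  h <- signal::fir1(ntaps - 1, 0.8 * new_nyq / (fs / 2), type = "low")
  filtered <- fir_filter_matrix(signal_$data, h)
  signal_$data <- filtered[, seq(1L, n, by = factor), drop = FALSE]
  signal_$fs_hz <- fs / factor
  signal_$pulse_sample <- signal_$pulse_sample %/% factor
  signal_
}

#' Re-reference to the common average
#'
#' Subtracts the across-channel mean at every sample, so the channel mean of
#' the output is zero everywhere (the scalp potential's arbitrary reference
#' constant is removed).
#'
#' @param signal_ an `erp_signal` with >= 2 channels.
#' @return the re-referenced `erp_signal`.
#' @export
rereference_common_average <- function(signal_) {
  if (nrow(signal_$data) < 2L) stop("common-average reference needs >= 2 channels", call. = FALSE)
  signal_$data <- sweep(signal_$data, 2L, colMeans(signal_$data))
  signal_
}

#' Full preprocessing chain: epochs to clean decimated ERP
#'
#' Fixed stage order: amplitude rejection, trial averaging, zero-phase FIR
#' bandpass, decimation, common-average re-reference.
#'
#' @param epochs an `epoch_set`.
#' @param reject_uv rejection threshold in microvolts.
#' @param band bandpass edges in Hz.
#' @param decim decimation factor.
#' @return an `erp_signal`.
#' @export
preprocess_epochs <- function(epochs, reject_uv = 75, band = c(1, 50), decim = 2) {
  erp <- average_erp(reject_artifacts(epochs, reject_uv))
  erp <- bandpass_fir(erp, band[1], band[2])
  erp <- decimate_erp(erp, decim)
  rereference_common_average(erp)
}
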