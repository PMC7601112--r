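#' Clip eye-blink artifacts at a voltage threshold
#'
#' Ocular artifacts are handled by thresholding: potentials above +threshold
#' or below -threshold microvolts are saturated at the threshold. Clipping
#' preserves epoch count and timing; see `artifact_mode = "reject_epoch"` in
#' [build_feature_table()] for the rejection alternative.
#'
#' @param rec an `eeg_recording`.
#' @param threshold positive clipping level in microvolts (default 80).
#' @return the recording with every sample limited to `[-threshold, threshold]`.
#' @export
clip_artifacts <- function(rec, threshold = 80) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("clip_artifacts: 'threshold' must be a positive scalar", call. = FALSE)
  if (!all(is.finite(rec$data)))
    stop("clip_artifacts: non-finite samples in input", call. = FALSE)
  rec$data <- pmin(pmax(rec$data, -threshold), threshold)
  rec
}

#' Zero-phase Butterworth bandpass filter
#'
#' Filters every channel with a Butterworth bandpass of the stated design
#' order, applied forward and backward (zero phase). Zero-phase application
#' is used because bispectral features depend on phase relations between
#' frequency components; a causal filter would distort quadratic phase
#' coupling. The effective magnitude response is the squared design response.
#'
#' @param rec an `eeg_recording`.
#' @param band a `band_definition`.
#' @param order Butterworth design order (default 6, as passed to the filter
#'   design routine; the bandpass transformation doubles the pole count).
#' @return the filtered recording, same dimensions.
#' @export
bandpass <- function(rec, band, order = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (inherits(band, "character")) band <- band_definition(band, fs = rec$fs)
  stopifnot(inherits(band, "band_definition"))
  nyq <- rec$fs / 2
  if (band$high >= nyq || band$low <= 0)
    stop("bandpass: band edges must lie strictly inside (0, fs/2)",
         call. = FALSE)
  bf <- signal::butter(order, c(band$low, band$high) / nyq, type = "pass")
  out <- t(apply(rec$data, 1L, function(ch) signal::filtfilt(bf, ch)))
  # apply() drops dims for single-channel recordings
  rec$data <- matrix(out, nrow = nrow(rec$data), ncol = ncol(rec$data))
  rec
}

#' Segment a recording into fixed-length single-channel epochs
#'
#' Takes the first `n_windows` consecutive non-overlapping segments of
#' `epoch_seconds` from each channel (6 s at 128 Hz gives the canonical
#' 768-sample epoch); trailing samples are discarded. Epochs are returned
#' channel-major: all windows of channel 1, then channel 2, and so on.
#'
#' @param rec an `eeg_recording`.
#' @param epoch_seconds epoch length in seconds (default 6).
#' @param n_windows number of windows per channel (default 6).
#' @return list of `epoch` objects, each with `samples`, `fs` and a `key`
#'   carrying (subject, group, emotion, trial, channel, window, band).
#' @export
segment_epochs <- function(rec, epoch_seconds = 6, n_windows = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- round(epoch_seconds * rec$fs)
  need <- n * n_windows
  if (ncol(rec$data) < need)
    stop(sprintf(
      "segment_epochs: recording has %d samples but %d are required (%g s x %d windows)",
      ncol(rec$data), need, epoch_seconds, n_windows), call. = FALSE)
  out <- vector("list", nrow(rec$data) * n_windows)
  i <- 0L
  for (ch in seq_len(nrow(rec$data))) {
    for (w in seq_len(n_windows)) {
      i <- i + 1L
      idx <- ((w - 1L) * n + 1L):(w * n)
      out[[i]] <- structure(list(
        samples = rec$data[ch, idx],
        fs = rec$fs,
        key = list(subject = rec$meta$subject, group = rec$meta$group,
                   emotion = rec$meta$emotion, trial = rec$meta$trial,
                   channel = rec$channel_labels[ch], window = w,
                   band = NA_character_)),
        class = "epoch")
    }
  }
  out
}

#' Full preprocessing chain for one recording
#'
#' clip -> broadband (0.5-49 Hz) -> band filter -> segment. Filtering is done
#' before segmentation so per-epoch edge transients are avoided.
#'
#' @param rec an `eeg_recording`.
#' @param band a `band_definition` (or band name) for the analysis band;
#'   `NULL` keeps the broadband signal.
#' @param epoch_seconds,n_windows segmentation parameters.
#' @param clip_threshold artifact threshold in microvolts.
#' @param order Butterworth design order.
#' @return list of epochs with `band` set in their keys.
#' @export
preprocess_recording <- function(rec, band = NULL, epoch_seconds = 6,
                                 n_windows = 6, clip_threshold = 80,
                                 order = 6) {
  rec <- clip_artifacts(rec, clip_threshold)
  rec <- bandpass(rec, band_definition("broadband", fs = rec$fs), order)
  band_name <- "broadband"
  if (!is.null(band)) {
    if (is.character(band)) band <- band_definition(band, fs = rec$fs)
    rec <- bandpass(rec, band, order)
    band_name <- band$name
  }
  eps <- segment_epochs(rec, epoch_seconds, n_windows)
  lapply(eps, function(e) { e$key$band <- band_name; e })
}
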