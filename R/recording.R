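#' 10-20 channel labels of the 14-electrode montage
#'
#' Electrode names of the wireless 14-channel headset montage, in the
#' conventional acquisition order. Reduced-channel configurations take the
#' first `n` labels of this vector, which keeps the frontal electrodes
#' (AF3, F7) used for blink injection.
#'
#' @export
EEG_CHANNELS_14 <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                     "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")

#' Emotion class labels
#'
#' Anger, disgust, fear, happiness, sadness, surprise.
#' @export
EMOTIONS <- c("A", "D", "F", "H", "S", "SU")

#' Construct a multi-channel EEG recording
#'
#' Container for one subject-trial: a channels x samples matrix in microvolts
#' plus sampling rate, channel labels and study metadata.
#'
#' @param data numeric matrix, channels x samples, in microvolts. All values
#'   must be finite.
#' @param fs sampling rate in Hz (default 128).
#' @param channel_labels character vector of 10-20 channel names, one per row
#'   of `data`.
#' @param meta named list with elements `subject`, `group` (one of
#'   "LBD", "RBD", "NC"), `emotion` (one of [EMOTIONS]) and `trial`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs = 128,
                          channel_labels = EEG_CHANNELS_14[seq_len(nrow(data))],
                          meta = list(subject = NA, group = "NC",
                                      emotion = NA, trial = NA)) {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop("eeg_recording: 'data' must be a finite numeric matrix", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("eeg_recording: 'fs' must be a positive scalar", call. = FALSE)
  if (length(channel_labels) != nrow(data))
    stop("eeg_recording: one channel label per data row is required",
         call. = FALSE)
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  m <- x$meta
  cat(sprintf("  subject=%s group=%s emotion=%s trial=%s\n",
              m$subject, m$group, m$emotion, m$trial))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
recording_seconds <- function(rec) ncol(rec$data) / rec$fs
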