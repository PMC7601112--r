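## Synthetic phase-coupled EEG: stands in for the (undeposited) clinical
## recordings, with the statistical structure the analysis assumes.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Default per-emotion quadratic phase coupling table
#'
#' One coupled triple per emotion per band, with both carriers inside the
#' band and the sum frequency below Nyquist. Emotions are deliberately
#' pairwise confusable within single bands (pairs share a row) while every
#' pair is separated by at least one band, so that combining bands is
#' informative; amplitudes are in the 7-13 microvolt range typical of evoked
#' band activity.
#'
#' @return data.frame with columns `emotion`, `band`, `f1`, `f2`, `amp`.
#' @export
default_coupling_table <- function() {
  rbind(
    data.frame(emotion = c("A", "D", "F", "H", "S", "SU"), band = "alpha",
               f1  = c(9, 9, 10, 10, 8, 8),
               f2  = c(11, 11, 12, 12, 13, 13),
               amp = c(12, 12, 10, 10, 8, 8)),
    data.frame(emotion = c("A", "D", "F", "H", "S", "SU"), band = "beta",
               f1  = c(14, 16, 14, 16, 18, 18),
               f2  = c(19, 22, 19, 22, 25, 25),
               amp = c(12, 10, 12, 10, 8, 8)),
    data.frame(emotion = c("A", "D", "F", "H", "S", "SU"), band = "gamma",
               f1  = c(30, 30, 30, 30, 31, 30),
               f2  = c(32, 33, 33, 32, 32, 31),
               amp = c(11, 9, 9, 11, 13, 7))
  )
}

#' Configuration of the synthetic emotion-EEG study
#'
#' Defaults reproduce the study design: 15 subjects per group, 6 emotions,
#' 6 trials per emotion (36 trials per subject), 14 channels at 128 Hz,
#' 48 s trials. Each trial superposes per-band quadratically phase-coupled
#' triples from `coupling_table` on Gaussian background noise, with sporadic
#' eye-blink deflections above the 80 microvolt artifact threshold.
#'
#' @param n_subjects subjects per group (default 15).
#' @param n_trials_per_emotion trials per emotion per subject (default 6).
#' @param emotions six distinct class labels (default [EMOTIONS]).
#' @param n_channels channels (default 14; the first `n_channels` labels of
#'   [EEG_CHANNELS_14] are used).
#' @param fs sampling rate in Hz (default 128).
#' @param trial_seconds trial duration in seconds (default 48; must be at
#'   least 36 so six non-overlapping 6 s windows fit).
#' @param coupling_table data.frame of (emotion, band, f1, f2, amp) rows; every
#'   pair must satisfy `f1 + f2 < fs/2`.
#' @param noise_sd Gaussian background noise SD in microvolts (default 15,
#'   a typical resting EEG background).
#' @param blink_rate blink events per minute (default 6; 0 disables blinks).
#' @param blink_amp blink peak amplitude in microvolts, must exceed the 80
#'   microvolt artifact threshold (default 130).
#' @param group group label attached to every recording ("LBD", "RBD", "NC").
#' @param seed integer seed governing all randomness of the dataset.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_subjects = 15, n_trials_per_emotion = 6,
                         emotions = EMOTIONS, n_channels = 14, fs = 128,
                         trial_seconds = 48,
                         coupling_table = default_coupling_table(),
                         noise_sd = 15, blink_rate = 6, blink_amp = 130,
                         group = "NC", seed = 1L) {
  if (fs <= 0) stop("synth_config: fs must be positive", call. = FALSE)
  if (length(emotions) != 6L || anyDuplicated(emotions))
    stop("synth_config: 'emotions' must be 6 distinct labels", call. = FALSE)
  if (trial_seconds < 36)
    stop("synth_config: trial_seconds must be >= 36 (six 6 s windows)",
         call. = FALSE)
  if (n_channels < 1 || n_channels > length(EEG_CHANNELS_14))
    stop("synth_config: n_channels must be in 1..14", call. = FALSE)
  need <- c("emotion", "band", "f1", "f2", "amp")
  if (!all(need %in% names(coupling_table)))
    stop("synth_config: coupling_table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(coupling_table$f1 + coupling_table$f2 >= fs / 2))
    stop("synth_config: every coupling pair must satisfy f1 + f2 < fs/2",
         call. = FALSE)
  missing_emo <- setdiff(emotions, unique(coupling_table$emotion))
  if (length(missing_emo))
    stop("synth_config: coupling_table has no rows for emotion(s): ",
         paste(missing_emo, collapse = ", "), call. = FALSE)
  if (blink_rate > 0 && blink_amp <= 80)
    stop("synth_config: blink_amp must exceed 80 microvolts", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 n_trials_per_emotion = n_trials_per_emotion,
                 emotions = emotions, n_channels = n_channels, fs = fs,
                 trial_seconds = trial_seconds,
                 coupling_table = coupling_table, noise_sd = noise_sd,
                 blink_rate = blink_rate, blink_amp = blink_amp,
                 group = group, seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate one quadratically phase-coupled test epoch
#'
#' Returns `amp * (cos(2 pi f1 t + th1) + cos(2 pi f2 t + th2) +
#' cos(2 pi (f1+f2) t + th3))` plus Gaussian noise, where `th1`, `th2` are
#' uniform random phases. When `coupled` is TRUE, `th3 = th1 + th2`
#' (quadratic phase coupling, which produces a bispectral peak at (f1, f2));
#' otherwise `th3` is an independent uniform phase and the expected
#' bispectrum at (f1, f2) vanishes.
#'
#' @param f1,f2 carrier frequencies in Hz with `f1 + f2 < fs/2`.
#' @param coupled logical; phase-couple the sum component?
#' @param amp per-component amplitude in microvolts.
#' @param n_samples epoch length in samples (>= 2).
#' @param fs sampling rate in Hz.
#' @param noise_sd Gaussian noise SD in microvolts.
#' @param seed optional integer seed; phases and noise are redrawn per call
#'   from the seeded stream.
#' @return an `epoch` object.
#' @export
generate_qpc_epoch <- function(f1, f2, coupled = TRUE, amp = 1,
                               n_samples = 768, fs = 128, noise_sd = 0,
                               seed = NULL) {
  if (f1 <= 0 || f2 <= 0 || f1 + f2 >= fs / 2)
    stop("generate_qpc_epoch: frequencies must be positive with f1 + f2 < fs/2",
         call. = FALSE)
  if (n_samples < 2)
    stop("generate_qpc_epoch: n_samples must be >= 2", call. = FALSE)
  with_seed(seed, {
    t <- (seq_len(n_samples) - 1) / fs
    th1 <- stats::runif(1, 0, 2 * pi)
    th2 <- stats::runif(1, 0, 2 * pi)
    th3 <- if (coupled) th1 + th2 else stats::runif(1, 0, 2 * pi)
    x <- amp * (cos(2 * pi * f1 * t + th1) + cos(2 * pi * f2 * t + th2) +
                  cos(2 * pi * (f1 + f2) * t + th3))
    if (noise_sd > 0) x <- x + stats::rnorm(n_samples, 0, noise_sd)
    structure(list(samples = x, fs = fs,
                   key = list(subject = NA, group = NA, emotion = NA,
                              trial = NA, channel = NA, window = NA,
                              band = NA)),
              class = "epoch")
  })
}

# One trial: per (channel, coupling row) QPC triple + channel noise.
# Assumes the RNG state is already positioned (called inside generate_dataset's
# seeded stream). gains: per-channel subject gain vector.
.generate_trial <- function(config, subject, emotion, trial, gains) {
  n <- round(config$trial_seconds * config$fs)
  t <- (seq_len(n) - 1) / config$fs
  rows <- config$coupling_table[config$coupling_table$emotion == emotion, ,
                                drop = FALSE]
  data <- matrix(0, config$n_channels, n)
  for (ch in seq_len(config$n_channels)) {
    x <- numeric(n)
    for (r in seq_len(nrow(rows))) {
      th1 <- stats::runif(1, 0, 2 * pi)
      th2 <- stats::runif(1, 0, 2 * pi)
      th3 <- th1 + th2
      x <- x + rows$amp[r] *
        (cos(2 * pi * rows$f1[r] * t + th1) +
           cos(2 * pi * rows$f2[r] * t + th2) +
           cos(2 * pi * (rows$f1[r] + rows$f2[r]) * t + th3))
    }
    if (config$noise_sd > 0) x <- x + stats::rnorm(n, 0, config$noise_sd)
    data[ch, ] <- gains[ch] * x
  }
  eeg_recording(data, fs = config$fs,
                channel_labels = EEG_CHANNELS_14[seq_len(config$n_channels)],
                meta = list(subject = subject, group = config$group,
                            emotion = emotion, trial = trial))
}

#' Generate a full synthetic emotion-EEG dataset
#'
#' Produces `n_subjects x 6 emotions x n_trials_per_emotion` recordings.
#' Each trial superposes the emotion's per-band QPC triples (independent
#' phases per channel) on Gaussian noise; subject identity contributes a
#' multiplicative lognormal(0, 0.1) gain per channel; blinks are injected on
#' frontal channels when `blink_rate > 0`. Deterministic given
#' `config$seed`.
#'
#' @param config a [synth_config()].
#' @return an `emotion_dataset`: list with `recordings` (named list keyed
#'   `S<subject>_<emotion>_T<trial>`) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    gains <- matrix(
      stats::rlnorm(config$n_subjects * config$n_channels, 0, 0.1),
      config$n_subjects, config$n_channels)
    recs <- list()
    for (s in seq_len(config$n_subjects)) {
      for (emo in config$emotions) {
        for (tr in seq_len(config$n_trials_per_emotion)) {
          rec <- .generate_trial(config, s, emo, tr, gains[s, ])
          if (config$blink_rate > 0)
            rec <- inject_blinks(rec, config$blink_rate, config$blink_amp)
          recs[[sprintf("S%02d_%s_T%d", s, emo, tr)]] <- rec
        }
      }
    }
    structure(list(recordings = recs, config = config),
              class = "emotion_dataset")
  })
}

#' @export
print.emotion_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<emotion_dataset> %d recordings (%d subjects x %d emotions x %d trials), %d ch @ %g Hz, group %s\n",
    length(x$recordings), cfg$n_subjects, length(cfg$emotions),
    cfg$n_trials_per_emotion, cfg$n_channels, cfg$fs, cfg$group))
  invisible(x)
}

#' Inject eye-blink artifacts into frontal channels
#'
#' Adds randomly placed raised-cosine deflections of 300 ms width and peak
#' amplitude `amp` to the frontal channels (AF3, AF4, F7, F8) present in the
#' recording. Event count is Poisson with the given per-minute rate. The
#' sample count is unchanged. Blinks must exceed the 80 microvolt artifact
#' threshold, otherwise they would be invisible to threshold-based artifact
#' handling.
#'
#' @param rec an `eeg_recording`.
#' @param rate blink events per minute; 0 returns the input unchanged.
#' @param amp peak deflection in microvolts, must be > 80.
#' @param seed optional integer seed.
#' @return the recording with blinks added.
#' @export
inject_blinks <- function(rec, rate, amp, seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rate == 0) return(rec)
  if (amp <= 80)
    stop("inject_blinks: amp must exceed 80 microvolts (artifact threshold)",
         call. = FALSE)
  with_seed(seed, {
    frontal <- which(rec$channel_labels %in% c("AF3", "AF4", "F7", "F8"))
    if (!length(frontal)) return(rec)
    n <- ncol(rec$data)
    dur_min <- n / rec$fs / 60
    n_events <- stats::rpois(1, rate * dur_min)
    if (n_events == 0) return(rec)
    width <- round(0.3 * rec$fs)                 # 300 ms raised cosine
    pulse <- amp * 0.5 * (1 - cos(2 * pi * seq_len(width) / (width + 1)))
    centers <- sort(sample.int(n, n_events, replace = TRUE))
    for (c0 in centers) {
      idx <- (c0 - width %/% 2) + seq_len(width) - 1L
      ok <- idx >= 1L & idx <= n
      for (ch in frontal)
        rec$data[ch, idx[ok]] <- rec$data[ch, idx[ok]] + pulse[ok]
    }
    rec
  })
}
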