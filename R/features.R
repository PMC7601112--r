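## Six bispectral features computed over the non-redundant region: the
## variance v of the (complex) bispectrum, sums of log amplitudes over the
## region (H1) and its diagonal (H2), first and second spectral moments of
## the diagonal log amplitudes (H3, H4), and a frequency-weighted amplitude
## moment (H5).

FEATURE_NAMES <- c("v", "H1", "H2", "H3", "H4", "H5")

#' Bispectral feature vector of one epoch
#'
#' Restricted to the non-redundant region Omega:
#' \itemize{
#'   \item `v  = 1/(N-1) sum |B_i - mu|^2`, with `mu` the complex mean over
#'     Omega;
#'   \item `H1 = sum over Omega of log|B(f1, f2)|`;
#'   \item `H2 = sum over the diagonal of log|B(fm, fm)|`;
#'   \item `H3 = sum m * log|B(fm, fm)|`, `m = 1..N_diag` in increasing
#'     frequency;
#'   \item `H4 = sum (m - H3)^2 * log|B(fm, fm)|` (second moment about H3,
#'     unnormalized);
#'   \item `H5 = sum over Omega of (f1^2 + f2^2) * |B(f1, f2)|` with
#'     normalized frequencies.
#' }
#' Logarithms are natural and floored via `log(|B| + eps)` so degenerate
#' (zero) bins stay finite.
#'
#' @param est a `bispectrum_estimate`.
#' @param mask a `region_mask` with matching grid size.
#' @param eps floor added to magnitudes before taking logs (default 1e-12).
#' @return named numeric vector with elements `v`, `H1`, `H2`, `H3`, `H4`,
#'   `H5`.
#' @export
compute_features <- function(est, mask, eps = 1e-12) {
  vals <- mask_values(est, mask)
  if (!length(vals))
    stop("compute_features: empty region mask", call. = FALSE)
  mu <- mean(vals)
  v <- sum(Mod(vals - mu)^2) / (length(vals) - 1)
  H1 <- sum(log(Mod(vals) + eps))
  d <- mask_diagonal(est, mask)
  ld <- log(Mod(d) + eps)
  m <- seq_along(ld)
  H2 <- sum(ld)
  H3 <- sum(m * ld)
  H4 <- sum((m - H3)^2 * ld)
  f1 <- mask$k1 / mask$nfft
  f2 <- mask$k2 / mask$nfft
  H5 <- sum((f1^2 + f2^2) * Mod(vals))
  c(v = v, H1 = H1, H2 = H2, H3 = H3, H4 = H4, H5 = H5)
}

#' Bispectrum estimation parameter set
#'
#' Bundles the indirect-method parameters used throughout the pipeline.
#' Defaults mirror common toolbox settings: 256-sample records, 50% overlap,
#' maximum lag 127, Hanning lag window, 1024-point FFT.
#'
#' @param nfft FFT length per dimension.
#' @param max_lag maximum cumulant lag.
#' @param record_len record length in samples.
#' @param overlap fractional record overlap.
#' @param lag_window lag-window name.
#' @return named list of parameters.
#' @export
bispec_params <- function(nfft = 1024, max_lag = 127, record_len = 256,
                          overlap = 0.5, lag_window = "hanning") {
  list(nfft = nfft, max_lag = max_lag, record_len = record_len,
       overlap = overlap, lag_window = lag_window)
}

#' Per-epoch bispectral feature table for a dataset
#'
#' Runs the full chain per recording and band — artifact handling,
#' zero-phase broadband then band filtering, segmentation, indirect
#' bispectrum, feature extraction — and stacks the results into a long
#' table: one row per (subject, emotion, trial, channel, window, band) with
#' the six feature columns.
#'
#' @param dataset an `emotion_dataset` (or plain list of `eeg_recording`s).
#' @param bands character vector of band names or list of
#'   `band_definition`s (default alpha, beta, gamma).
#' @param params bispectrum parameters from [bispec_params()].
#' @param epoch_seconds,n_windows segmentation settings.
#' @param artifact_mode `"clip"` (saturate at the threshold, default) or
#'   `"reject_epoch"` (drop epochs whose raw segment exceeds the threshold).
#' @param clip_threshold artifact threshold in microvolts.
#' @return data.frame with key columns `subject`, `group`, `emotion`,
#'   `trial`, `channel`, `window`, `band` and feature columns
#'   `v`, `H1`..`H5`.
#' @export
build_feature_table <- function(dataset, bands = c("alpha", "beta", "gamma"),
                                params = bispec_params(),
                                epoch_seconds = 6, n_windows = 6,
                                artifact_mode = c("clip", "reject_epoch"),
                                clip_threshold = 80) {
  artifact_mode <- match.arg(artifact_mode)
  recs <- if (inherits(dataset, "emotion_dataset")) dataset$recordings
          else dataset
  if (!length(recs))
    stop("build_feature_table: empty dataset", call. = FALSE)
  fs <- recs[[1]]$fs
  band_defs <- lapply(bands, function(b)
    if (is.character(b)) band_definition(b, fs = fs) else b)
  mask <- non_redundant_mask(params$nfft)
  rows <- vector("list", length(recs) * length(band_defs))
  i <- 0L
  for (rec in recs) {
    reject <- NULL
    if (artifact_mode == "reject_epoch") {
      raw_eps <- segment_epochs(rec, epoch_seconds, n_windows)
      reject <- vapply(raw_eps,
                       function(e) any(abs(e$samples) > clip_threshold),
                       logical(1))
    } else {
      rec <- clip_artifacts(rec, clip_threshold)
    }
    rec_bb <- bandpass(rec, band_definition("broadband", fs = rec$fs))
    for (bd in band_defs) {
      eps <- segment_epochs(bandpass(rec_bb, bd), epoch_seconds, n_windows)
      keep <- if (is.null(reject)) rep(TRUE, length(eps)) else !reject
      feats <- lapply(eps[keep], function(e) {
        est <- bispectrum_indirect(e, nfft = params$nfft,
                                   lag_window = params$lag_window,
                                   max_lag = params$max_lag,
                                   record_len = params$record_len,
                                   overlap = params$overlap)
        f <- compute_features(est, mask)
        k <- e$key
        data.frame(subject = k$subject, group = k$group, emotion = k$emotion,
                   trial = k$trial, channel = k$channel, window = k$window,
                   band = bd$name, t(f))
      })
      i <- i + 1L
      rows[[i]] <- do.call(rbind, feats)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
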