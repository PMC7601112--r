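## Dataset I/O: one delimited channel matrix per trial (rows = samples,
## columns = channels, header = 10-20 labels) plus a manifest mapping file
## to (subject, group, emotion, trial).

#' Write a dataset as delimited channel matrices with a manifest
#'
#' @param dataset an `emotion_dataset` or list of `eeg_recording`s.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest data.frame.
#' @export
write_dataset <- function(dataset, dir) {
  recs <- if (inherits(dataset, "emotion_dataset")) dataset$recordings
          else dataset
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- do.call(rbind, lapply(names(recs), function(nm) {
    rec <- recs[[nm]]
    file <- paste0(nm, ".tsv")
    mat <- t(rec$data)
    colnames(mat) <- rec$channel_labels
    utils::write.table(mat, file.path(dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    data.frame(file = file, subject = rec$meta$subject,
               group = rec$meta$group, emotion = rec$meta$emotion,
               trial = rec$meta$trial, fs = rec$fs)
  }))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the trial files and `manifest.csv`.
#' @return list of `eeg_recording`s named as in the manifest.
#' @export
read_dataset <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf))
    stop("read_dataset: no manifest.csv in ", dir, call. = FALSE)
  manifest <- utils::read.csv(mf)
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    path <- file.path(dir, m$file)
    if (!file.exists(path))
      stop("read_dataset: manifest entry missing on disk: ", m$file,
           call. = FALSE)
    mat <- utils::read.table(path, header = TRUE, sep = "\t",
                             check.names = FALSE)
    eeg_recording(t(as.matrix(mat)), fs = m$fs,
                  channel_labels = colnames(mat),
                  meta = list(subject = m$subject, group = m$group,
                              emotion = m$emotion, trial = m$trial))
  })
  names(recs) <- sub("\\.tsv$", "", manifest$file)
  recs
}
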