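#' EEG frequency band definitions
#'
#' Canonical analysis bands: alpha 8-13 Hz, beta 13-30 Hz, gamma 30-49 Hz,
#' and the broadband preprocessing range 0.5-49 Hz. Delta and theta are not
#' analyzed.
#'
#' @param name one of `"alpha"`, `"beta"`, `"gamma"`, `"broadband"`, or a
#'   custom name when `low`/`high` are supplied.
#' @param low,high optional custom band edges in Hz; both must be given to
#'   override the canonical values.
#' @param fs sampling rate in Hz used to validate the edges against Nyquist.
#' @return a `band_definition` list with `name`, `low`, `high`.
#' @export
band_definition <- function(name, low = NULL, high = NULL, fs = 128) {
  canonical <- list(alpha = c(8, 13), beta = c(13, 30),
                    gamma = c(30, 49), broadband = c(0.5, 49))
  if (is.null(low) || is.null(high)) {
    if (!name %in% names(canonical))
      stop("band_definition: unknown band '", name,
           "' and no custom edges given", call. = FALSE)
    low <- canonical[[name]][1]
    high <- canonical[[name]][2]
  }
  if (!(0 < low && low < high && high < fs / 2))
    stop("band_definition: edges must satisfy 0 < low < high < fs/2",
         call. = FALSE)
  structure(list(name = name, low = low, high = high),
            class = "band_definition")
}

#' The three analysis bands
#' @param fs sampling rate in Hz.
#' @return named list of `band_definition`s for alpha, beta, gamma.
#' @export
analysis_bands <- function(fs = 128) {
  b <- lapply(c("alpha", "beta", "gamma"), band_definition, fs = fs)
  names(b) <- c("alpha", "beta", "gamma")
  b
}
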