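## Bispectrum estimation: indirect (third-order cumulant) and direct
## (triple-product) methods, plus the non-redundant region of the
## (f1, f2) plane.

.epoch_samples <- function(epoch) {
  if (inherits(epoch, "epoch")) epoch$samples else as.numeric(epoch)
}

.record_starts <- function(n, record_len, overlap) {
  step <- max(1L, round(record_len * (1 - overlap)))
  seq.int(1L, n - record_len + 1L, by = step)
}

# fftshift in both dimensions: DC moves to index nfft/2 + 1,
# axis becomes (-nfft/2 .. nfft/2 - 1)/nfft.
.fftshift2 <- function(m) {
  n <- nrow(m)
  h <- n %/% 2
  idx <- c((h + 1L):n, 1L:h)
  m[idx, idx]
}

#' Third-order cumulant matrix of an epoch
#'
#' Splits the epoch into mean-removed records of `record_len` samples with
#' the given overlap, forms the biased (1/record_len) sample estimate of
#' `E[x(k) x(k+tau1) x(k+tau2)]` per record over lags `-max_lag..max_lag`,
#' and averages across records. For a zero-mean process the third-order
#' cumulant equals the third moment, and it vanishes for Gaussian signals.
#'
#' @param epoch an `epoch` or numeric vector.
#' @param max_lag maximum lag L; the result is (2L+1) x (2L+1).
#' @param record_len record length in samples (default: whole epoch).
#' @param overlap fractional overlap between consecutive records in `[0, 1)`.
#' @return a `cumulant_matrix`: list with `values` ((2L+1) x (2L+1), lag 0 at
#'   the centre), `max_lag`, `n_records`.
#' @export
third_order_cumulant <- function(epoch, max_lag,
                                 record_len = length(.epoch_samples(epoch)),
                                 overlap = 0) {
  x <- .epoch_samples(epoch)
  if (!all(is.finite(x)))
    stop("third_order_cumulant: non-finite samples", call. = FALSE)
  if (max_lag >= record_len)
    stop("third_order_cumulant: max_lag must be < record_len", call. = FALSE)
  if (record_len > length(x))
    stop("third_order_cumulant: record_len exceeds epoch length",
         call. = FALSE)
  if (overlap < 0 || overlap >= 1)
    stop("third_order_cumulant: overlap must be in [0, 1)", call. = FALSE)
  L <- as.integer(max_lag)
  lags <- -L:L
  starts <- .record_starts(length(x), record_len, overlap)
  C <- matrix(0, 2L * L + 1L, 2L * L + 1L)
  ks <- seq_len(record_len)
  for (s in starts) {
    r <- x[s:(s + record_len - 1L)]
    r <- r - mean(r)
    # lagged copies, zero-padded outside the record: Xl[k, j] = r[k + lag_j]
    Xl <- vapply(lags, function(tau) {
      y <- numeric(record_len)
      idx <- ks + tau
      ok <- idx >= 1L & idx <= record_len
      y[ok] <- r[idx[ok]]
      y
    }, numeric(record_len))
    # C[i, j] = sum_k r(k) r(k+tau_i) r(k+tau_j) / record_len
    C <- C + crossprod(Xl, r * Xl) / record_len
  }
  C <- C / length(starts)
  C <- (C + t(C)) / 2     # estimator is symmetric in the lags; enforce it
                          # exactly against last-bit BLAS asymmetry
  structure(list(values = C, max_lag = L, n_records = length(starts)),
            class = "cumulant_matrix")
}

.new_bispectrum <- function(values, nfft, method, params, fs = NA_real_) {
  structure(list(values = values, nfft = nfft, method = method,
                 params = params, fs = fs),
            class = "bispectrum_estimate")
}

#' @export
print.bispectrum_estimate <- function(x, ...) {
  cat(sprintf("<bispectrum_estimate> %s method, %d x %d grid, max|B| = %.4g\n",
              x$method, x$nfft, x$nfft, max(Mod(x$values))))
  invisible(x)
}

#' Normalized frequency axis of a bispectrum grid
#'
#' @param est a `bispectrum_estimate` (or an nfft integer).
#' @return frequencies in cycles/sample spanning `[-0.5, 0.5)`.
#' @export
bispectrum_freqs <- function(est) {
  nfft <- if (inherits(est, "bispectrum_estimate")) est$nfft else est
  (seq_len(nfft) - 1 - nfft %/% 2) / nfft
}

#' Bispectrum by the indirect (cumulant) method
#'
#' Estimates the third-order cumulant matrix, tapers it with a separable
#' Hanning lag window, zero-pads to `nfft x nfft` and applies the 2-D
#' discrete Fourier transform, so that `B(f1, f2) = sum C(tau1, tau2)
#' exp(-j 2 pi (f1 tau1 + f2 tau2))`. The grid is centred: the frequency
#' axis spans `[-0.5, 0.5)` cycles/sample.
#'
#' @inheritParams third_order_cumulant
#' @param nfft FFT length per dimension (default 1024); must be at least
#'   `2 * max_lag + 1`.
#' @param lag_window `"hanning"` (default) or `"rectangular"`.
#' @param record_len record length in samples (default 256).
#' @param overlap fractional record overlap (default 0.5).
#' @return a `bispectrum_estimate` with `method = "indirect"`.
#' @export
bispectrum_indirect <- function(epoch, nfft = 1024, lag_window = "hanning",
                                max_lag = 127, record_len = 256,
                                overlap = 0.5) {
  if (nfft < 2 * max_lag + 1)
    stop("bispectrum_indirect: nfft must be >= 2*max_lag + 1", call. = FALSE)
  cm <- third_order_cumulant(epoch, max_lag, record_len, overlap)
  L <- cm$max_lag
  lags <- -L:L
  w <- switch(match.arg(lag_window, c("hanning", "rectangular")),
              hanning = 0.5 * (1 + cos(pi * lags / (L + 1))),
              rectangular = rep(1, 2 * L + 1))
  Ct <- cm$values * outer(w, w)
  M <- matrix(0, nfft, nfft)
  idx <- (lags %% nfft) + 1L          # wrap negative lags for correct phase
  M[idx, idx] <- Ct
  B <- .fftshift2(stats::fft(M))
  fs <- if (inherits(epoch, "epoch")) epoch$fs else NA_real_
  .new_bispectrum(B, nfft, "indirect",
                  list(record_len = record_len, overlap = overlap,
                       lag_window = lag_window, max_lag = max_lag),
                  fs = fs)
}

#' Bispectrum by the direct (FFT) method
#'
#' Per windowed, mean-removed record the 1-D Fourier transform `X` is taken
#' and the triple product `X(f1) X(f2) conj(X(f1+f2))` accumulated on the
#' full `nfft x nfft` grid (sum frequency wrapped modulo the sampling rate),
#' then averaged over records — the sample analogue of
#' `E[X(f1) X(f2) X*(f1+f2)]`. The grid is centred as in
#' [bispectrum_indirect()].
#'
#' @inheritParams bispectrum_indirect
#' @param window per-record data window, `"hanning"` or `"rectangular"`.
#' @return a `bispectrum_estimate` with `method = "direct"`.
#' @export
bispectrum_direct <- function(epoch, nfft = 256,
                              record_len = length(.epoch_samples(epoch)),
                              overlap = 0.5, window = "hanning") {
  x <- .epoch_samples(epoch)
  if (record_len > length(x))
    stop("bispectrum_direct: record_len exceeds epoch length", call. = FALSE)
  if (nfft < record_len)
    stop("bispectrum_direct: nfft must be >= record_len", call. = FALSE)
  win <- switch(match.arg(window, c("hanning", "rectangular")),
                hanning = 0.5 * (1 - cos(2 * pi * seq_len(record_len) /
                                           (record_len + 1))),
                rectangular = rep(1, record_len))
  starts <- .record_starts(length(x), record_len, overlap)
  ks <- 0:(nfft - 1L)
  sum_idx <- (outer(ks, ks, "+") %% nfft) + 1L
  B <- matrix(0 + 0i, nfft, nfft)
  for (s in starts) {
    r <- x[s:(s + record_len - 1L)]
    r <- (r - mean(r)) * win
    X <- stats::fft(c(r, numeric(nfft - record_len)))
    B <- B + outer(X, X) * Conj(X[sum_idx])
  }
  B <- .fftshift2(B / length(starts))
  fs <- if (inherits(epoch, "epoch")) epoch$fs else NA_real_
  .new_bispectrum(B, nfft, "direct",
                  list(record_len = record_len, overlap = overlap,
                       window = window),
                  fs = fs)
}

#' Non-redundant region of the bispectrum plane
#'
#' By the symmetries of the bispectrum of a real signal, the triangular
#' region `0 <= f1 <= f2`, `f1 + f2 <= 1/2` (normalized frequency) is
#' sufficient to describe the whole bispectrum. Frequencies are grid bins
#' `k/nfft`, `k = 0..nfft/2`.
#'
#' @param nfft FFT length (>= 4).
#' @return a `region_mask`: list with integer bin vectors `k1`, `k2`
#'   (ordered k1-major), `diag_k` (the diagonal bins `(k, k)` in increasing
#'   frequency), and `nfft`.
#' @export
non_redundant_mask <- function(nfft) {
  if (nfft < 4) stop("non_redundant_mask: nfft must be >= 4", call. = FALSE)
  half <- nfft %/% 2
  k1 <- integer(0); k2 <- integer(0)
  for (a in 0:half) {
    b <- a:(half)
    b <- b[a + b <= half]
    if (length(b)) {
      k1 <- c(k1, rep.int(a, length(b)))
      k2 <- c(k2, b)
    }
  }
  structure(list(k1 = k1, k2 = k2, diag_k = unique(k1[k1 == k2]),
                 nfft = as.integer(nfft)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> nfft = %d, %d points, %d diagonal bins\n",
              x$nfft, length(x$k1), length(x$diag_k)))
  invisible(x)
}

# matrix index of frequency bin k on the centred grid
.bin_index <- function(k, nfft) ((k + nfft %/% 2) %% nfft) + 1L

#' Bispectrum values over the non-redundant region
#'
#' @param est a `bispectrum_estimate`.
#' @param mask a `region_mask` with matching `nfft`.
#' @return complex vector of `B(f1, f2)` in mask order.
#' @export
mask_values <- function(est, mask) {
  stopifnot(inherits(est, "bispectrum_estimate"),
            inherits(mask, "region_mask"))
  if (est$nfft != mask$nfft)
    stop("mask_values: mask and estimate nfft differ", call. = FALSE)
  est$values[cbind(.bin_index(mask$k1, est$nfft),
                   .bin_index(mask$k2, est$nfft))]
}

#' Diagonal bispectrum values `B(f, f)` within the non-redundant region
#'
#' @inheritParams mask_values
#' @return complex vector ordered by increasing frequency.
#' @export
mask_diagonal <- function(est, mask) {
  stopifnot(inherits(est, "bispectrum_estimate"),
            inherits(mask, "region_mask"))
  if (est$nfft != mask$nfft)
    stop("mask_diagonal: mask and estimate nfft differ", call. = FALSE)
  idx <- .bin_index(mask$diag_k, est$nfft)
  est$values[cbind(idx, idx)]
}

#' Location of the non-redundant-region magnitude maximum
#'
#' @inheritParams mask_values
#' @return list with `k1`, `k2` (bins), `f1`, `f2` (normalized) and `value`
#'   (the peak magnitude).
#' @export
mask_argmax <- function(est, mask) {
  v <- Mod(mask_values(est, mask))
  i <- which.max(v)
  list(k1 = mask$k1[i], k2 = mask$k2[i],
       f1 = mask$k1[i] / mask$nfft, f2 = mask$k2[i] / mask$nfft,
       value = v[i])
}

#' Contour plot of a bispectrum magnitude map
#'
#' Draws filled contours of `|B(f1, f2)|` on the centred normalized-frequency
#' axes with the non-redundant region outlined, optionally writing a PNG.
#'
#' @param est a `bispectrum_estimate`.
#' @param file optional PNG path; when given the plot is written there.
#' @param main plot title.
#' @param nlevels number of contour levels.
#' @return invisibly, the magnitude matrix.
#' @export
plot_bispectrum <- function(est, file = NULL, main = NULL, nlevels = 20) {
  stopifnot(inherits(est, "bispectrum_estimate"))
  f <- bispectrum_freqs(est)
  mag <- Mod(est$values)
  if (is.null(main))
    main <- sprintf("Bispectrum magnitude (%s method)", est$method)
  draw <- function() {
    graphics::filled.contour(
      f, f, t(mag), nlevels = nlevels,
      xlab = "f1 (cycles/sample)", ylab = "f2 (cycles/sample)", main = main,
      plot.axes = {
        graphics::axis(1); graphics::axis(2)
        # outline of the non-redundant triangle
        graphics::lines(c(0, 0.25, 0, 0), c(0, 0.25, 0.5, 0), lwd = 2)
      })
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 800, res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else {
    draw()
  }
  invisible(mag)
}
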