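# Independent oracles, kept deliberately literal and separate from the
# package implementations they check.

# Literal triple-product bispectrum of one rectangular record:
# B(k1, k2) = X(k1) X(k2) conj(X(k1 + k2)), indices modulo nfft,
# returned on the centred grid like the package estimates.
oracle_direct_bispectrum <- function(x, nfft = length(x)) {
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  B <- matrix(0 + 0i, nfft, nfft)
  for (k1 in 0:(nfft - 1)) {
    for (k2 in 0:(nfft - 1)) {
      B[k1 + 1, k2 + 1] <- X[k1 + 1] * X[k2 + 1] *
        Conj(X[((k1 + k2) %% nfft) + 1])
    }
  }
  h <- nfft %/% 2
  idx <- c((h + 1):nfft, 1:h)
  B[idx, idx]
}

# Average the oracle bispectrum of seeded QPC realizations (zero-mean
# cosine triples, so no mean removal is needed).
oracle_qpc_average <- function(f1, f2, coupled, n_real, n = 256, fs = 128,
                               amp = 1, seed_offset = 0) {
  acc <- matrix(0 + 0i, n, n)
  for (s in seq_len(n_real)) {
    e <- eegbispec::generate_qpc_epoch(f1, f2, coupled, amp = amp,
                                       n_samples = n, fs = fs, noise_sd = 0,
                                       seed = s + seed_offset)
    acc <- acc + oracle_direct_bispectrum(e$samples, n)
  }
  acc / n_real
}

# Construct a bispectrum_estimate from a full centred complex grid.
make_bispec <- function(values, nfft, fs = NA_real_) {
  eegbispec:::.new_bispectrum(values, nfft, "direct", list(), fs = fs)
}

# Construct an estimate that has magnitude `mag[i]` at non-negative bins
# (k1[i], k2[i]) (and the transposed bin, keeping the grid symmetric),
# `fill` elsewhere.
make_bispec_at <- function(nfft, k1, k2, mag, fill = 0) {
  m <- matrix(fill + 0i, nfft, nfft)
  idx <- function(k) ((k + nfft %/% 2) %% nfft) + 1L
  for (i in seq_along(k1)) {
    m[idx(k1[i]), idx(k2[i])] <- mag[i]
    m[idx(k2[i]), idx(k1[i])] <- mag[i]
  }
  make_bispec(m, nfft)
}

# Small deterministic epoch for structural tests.
rand_epoch <- function(n = 256, fs = 128, seed = 42) {
  set.seed(seed)
  structure(list(samples = stats::rnorm(n), fs = fs,
                 key = list(subject = 1, group = "NC", emotion = "A",
                            trial = 1, channel = "AF3", window = 1,
                            band = NA)),
            class = "epoch")
}
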