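test_that("third-order cumulant: zero input, exact lag symmetry, parameter guards", {
  z <- third_order_cumulant(numeric(512), max_lag = 16)
  expect_equal(z$values, matrix(0, 33, 33))

  cm <- third_order_cumulant(rand_epoch(512), max_lag = 12,
                             record_len = 256, overlap = 0.5)
  expect_identical(cm$values, t(cm$values))
  expect_equal(cm$n_records, 3)

  expect_error(third_order_cumulant(rnorm(64), max_lag = 64), "max_lag")
  expect_error(third_order_cumulant(rnorm(64), max_lag = 8,
                                    record_len = 128), "record_len")
})

test_that("third cumulants of Gaussian white noise vanish within Monte-Carlo error", {
  # oracle: the estimator's spread over 50 seeds; the across-seed mean at
  # every lag must sit within 5 standard errors of zero
  n_seeds <- 50
  vals <- vapply(seq_len(n_seeds), function(s) {
    set.seed(s)
    third_order_cumulant(rnorm(1e5), max_lag = 16)$values
  }, matrix(0, 33, 33))
  mu <- apply(vals, c(1, 2), mean)
  se <- apply(vals, c(1, 2), stats::sd) / sqrt(n_seeds)
  expect_lt(max(abs(mu / se)), 5)
})

test_that("direct method on one rectangular record equals the literal triple product", {
  set.seed(11)
  x <- rnorm(32)
  x <- x - mean(x)                 # oracle has no mean-removal step
  est <- bispectrum_direct(x, nfft = 32, record_len = 32,
                           window = "rectangular")
  expect_equal(est$values, oracle_direct_bispectrum(x, 32), tolerance = 1e-10)
})

test_that("real signals give conjugate-symmetric direct estimates and zeros stay zero", {
  est <- bispectrum_direct(rand_epoch(128), nfft = 128, record_len = 128)
  n <- est$nfft; h <- n %/% 2
  idx <- function(k) ((k + h) %% n) + 1L      # centred-grid index of bin k
  for (k1 in c(-30L, -5L, 0L, 7L, 20L)) {
    for (k2 in c(-20L, -3L, 4L, 25L)) {
      expect_equal(est$values[idx(-k1), idx(-k2)],
                   Conj(est$values[idx(k1), idx(k2)]),
                   tolerance = 1e-8)
    }
  }
  z <- bispectrum_direct(numeric(128), nfft = 128, record_len = 128)
  expect_equal(max(Mod(z$values)), 0)
})

test_that("indirect estimates are symmetric in (f1, f2) and zero for zero input", {
  est <- bispectrum_indirect(rand_epoch(512), nfft = 128, max_lag = 32,
                             record_len = 256, overlap = 0.5)
  expect_lt(max(Mod(est$values - t(est$values))), 1e-8 * max(Mod(est$values)))

  z <- bispectrum_indirect(numeric(512), nfft = 128, max_lag = 32,
                           record_len = 256, overlap = 0.5)
  expect_equal(max(Mod(z$values)), 0)
  expect_error(bispectrum_indirect(rand_epoch(512), nfft = 32, max_lag = 32),
               "nfft")
})

test_that("the non-redundant region mask matches exhaustive enumeration", {
  m8 <- non_redundant_mask(8)
  expect_equal(cbind(m8$k1, m8$k2),
               cbind(c(0, 0, 0, 0, 0, 1, 1, 1, 2),
                     c(0, 1, 2, 3, 4, 1, 2, 3, 2)))
  expect_equal(m8$diag_k, c(0, 1, 2))

  # enumeration oracle at a larger size
  m64 <- non_redundant_mask(64)
  pts <- expand.grid(k1 = 0:32, k2 = 0:32)
  pts <- pts[pts$k1 <= pts$k2 & pts$k1 + pts$k2 <= 32, ]
  pts <- pts[order(pts$k1, pts$k2), ]
  expect_equal(length(m64$k1), nrow(pts))
  expect_equal(m64$k1, pts$k1)
  expect_equal(m64$k2, pts$k2)
  # defining constraint in normalized frequency
  expect_true(all(m64$k1 / 64 + m64$k2 / 64 <= 0.5))
  expect_error(non_redundant_mask(2), ">= 4")
})

test_that("bispectrum magnitude scales with the cube of the signal scale", {
  e <- rand_epoch(512)
  e3 <- e; e3$samples <- 3 * e$samples
  for (f in list(
    function(x) bispectrum_direct(x, nfft = 128, record_len = 128),
    function(x) bispectrum_indirect(x, nfft = 128, max_lag = 32,
                                    record_len = 256, overlap = 0.5))) {
    b1 <- f(e); b3 <- f(e3)
    expect_equal(Mod(b3$values), 27 * Mod(b1$values), tolerance = 1e-8)
  }
})

test_that("a coupled triple peaks at the coupling bin for both methods", {
  e <- generate_qpc_epoch(10, 14, coupled = TRUE, amp = 1, n_samples = 768,
                          fs = 128, noise_sd = 0, seed = 2)
  m <- non_redundant_mask(256)
  # 10 Hz and 14 Hz at fs 128 are bins 20 and 28 on a 256-point grid
  for (est in list(
    bispectrum_direct(e, nfft = 256, record_len = 256, overlap = 0.5),
    bispectrum_indirect(e, nfft = 256, max_lag = 127, record_len = 256,
                        overlap = 0.5))) {
    am <- mask_argmax(est, m)
    expect_lte(abs(am$k1 - 20), 1)
    expect_lte(abs(am$k2 - 28), 1)
  }
})

test_that("mask accessors validate grid size and return the diagonal in order", {
  est <- bispectrum_direct(rand_epoch(64), nfft = 64, record_len = 64)
  m <- non_redundant_mask(64)
  expect_length(mask_values(est, m), length(m$k1))
  d <- mask_diagonal(est, m)
  expect_length(d, length(m$diag_k))
  i16 <- which(m$k1 == 16 & m$k2 == 16)
  expect_equal(d[m$diag_k == 16], mask_values(est, m)[i16])
  expect_error(mask_values(est, non_redundant_mask(32)), "nfft differ")
})

test_that("contour export writes an image file", {
  est <- bispectrum_direct(rand_epoch(64), nfft = 64, record_len = 64)
  f <- tempfile(fileext = ".png")
  plot_bispectrum(est, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
  unlink(f)
})
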