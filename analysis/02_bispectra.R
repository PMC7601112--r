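#!/usr/bin/env Rscript
# Stage 2: illustrate what the bispectrum sees.
#
# A coupled triple (10 + 14 -> 24 Hz with theta3 = theta1 + theta2) yields a
# sharp non-redundant-region peak at (10, 14) Hz for both estimation
# methods; breaking the phase relation removes it; Gaussian noise is
# suppressed. Writes the peak table and contour plots.

library(eegbispec)

dir.create("results", showWarnings = FALSE)
nfft <- 256
mask <- non_redundant_mask(nfft)

e <- generate_qpc_epoch(10, 14, coupled = TRUE, amp = 1, n_samples = 768,
                        fs = 128, noise_sd = 0, seed = 1)
bd <- bispectrum_direct(e, nfft = nfft, record_len = 256, overlap = 0.5)
bi <- bispectrum_indirect(e, nfft = nfft, max_lag = 127, record_len = 256,
                          overlap = 0.5)

rows <- do.call(rbind, lapply(list(direct = bd, indirect = bi), function(b) {
  am <- mask_argmax(b, mask)
  data.frame(method = b$method, f1_hz = am$f1 * 128, f2_hz = am$f2 * 128,
             peak_magnitude = am$value)
}))
rows$omega_corr <- cor(Mod(mask_values(bd, mask)), Mod(mask_values(bi, mask)))
write.csv(rows, "results/bispectrum_peaks.csv", row.names = FALSE)
print(rows, row.names = FALSE)

plot_bispectrum(bi, file = "results/bispectrum_indirect_coupled.png",
                main = "Coupled triple (10, 14) Hz - indirect method")
eu <- generate_qpc_epoch(10, 14, coupled = FALSE, amp = 1, n_samples = 768,
                         fs = 128, noise_sd = 0, seed = 1)
plot_bispectrum(bispectrum_indirect(eu, nfft = nfft, max_lag = 127,
                                    record_len = 256, overlap = 0.5),
                file = "results/bispectrum_indirect_uncoupled.png",
                main = "Uncoupled control - indirect method")
cat("contour plots written under results/\n")
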