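#!/usr/bin/env Rscript
# Stage 4: emotion classification of the retained features.
#
# Per-trial sample vectors (channels x windows per band, concatenated when
# bands are combined) are classified with cityblock KNN (k swept 1..15) and
# the Parzen PNN (spread swept 0.1..1.5) under stratified cross-validation,
# per single band and for the alpha+beta+gamma combination.

library(eegbispec)

ft <- read.csv("results/feature_table.csv")
retained <- readLines("results/retained_features.txt")
sets <- list(alpha = "alpha", beta = "beta", gamma = "gamma",
             "alpha+beta+gamma" = c("alpha", "beta", "gamma"))

sweeps <- list(); best <- list(); recalls <- list()
for (feat in retained) {
  for (nm in names(sets)) {
    sv <- trial_feature_vectors(ft, feat, bands = sets[[nm]])
    for (clf in c("knn", "pnn")) {
      sw <- sweep_classifier(sv$x, sv$y, clf, n_folds = 4, seed = 2)
      sweeps[[length(sweeps) + 1L]] <-
        data.frame(feature = feat, band_set = nm, sw$sweep)
      ib <- which.max(sw$sweep$average_accuracy)
      res <- sw$results[[ib]]
      best[[length(best) + 1L]] <-
        data.frame(feature = feat, band_set = nm, classifier = clf,
                   parameter = res$parameter,
                   average_accuracy = res$average_accuracy)
      recalls[[length(recalls) + 1L]] <-
        data.frame(feature = feat, band_set = nm,
                   summarize_classification(res))
    }
  }
}
write.csv(do.call(rbind, sweeps), "results/accuracy_sweeps.csv",
          row.names = FALSE)
write.csv(do.call(rbind, recalls), "results/per_emotion_recall.csv",
          row.names = FALSE)
best <- do.call(rbind, best)
write.csv(best, "results/best_accuracy.csv", row.names = FALSE)

cat("best cross-validated accuracy per feature and band set:\n")
print(best[order(-best$average_accuracy), ], row.names = FALSE, digits = 4)
comb <- best[best$band_set == "alpha+beta+gamma", "average_accuracy"]
single <- best[best$band_set != "alpha+beta+gamma", "average_accuracy"]
cat(sprintf("\nband combination: best %.1f%% vs best single band %.1f%%\n",
            max(comb), max(single)))
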