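## One-way ANOVA screening of bispectral features across emotion classes,
## with the p <= 0.05 retention rule.

#' One-way ANOVA across emotion classes
#'
#' Standard fixed-effects one-way decomposition: `F = MS_between /
#' MS_within` with `df_between = classes - 1` and `df_within = N - classes`,
#' p-value from the F distribution. Observations are pooled epoch values
#' (no subject-level nesting). The degenerate case of zero within-class
#' variance with unequal means is reported as `p = 0` and flagged.
#'
#' @param values_by_class named list mapping class label to a numeric vector
#'   of observations (>= 2 classes, each with >= 2 observations).
#' @return an `anova_result`: list with `F`, `p`, `df_between`, `df_within`,
#'   `significant` (p <= 0.05), `degenerate`.
#' @export
anova_oneway <- function(values_by_class) {
  if (length(values_by_class) < 2)
    stop("anova_oneway: need at least 2 classes", call. = FALSE)
  sizes <- lengths(values_by_class)
  if (any(sizes < 2))
    stop("anova_oneway: every class needs >= 2 observations", call. = FALSE)
  y <- unlist(values_by_class, use.names = FALSE)
  k <- length(values_by_class)
  N <- length(y)
  means <- vapply(values_by_class, mean, numeric(1))
  ssb <- sum(sizes * (means - mean(y))^2)
  ssw <- sum(vapply(values_by_class,
                    function(v) sum((v - mean(v))^2), numeric(1)))
  df_b <- k - 1L
  df_w <- N - k
  degenerate <- ssw <= .Machine$double.eps * sum(y^2)
  if (degenerate && ssb > 0) {
    Fstat <- Inf
    p <- 0
  } else if (degenerate) {            # all values identical everywhere
    Fstat <- 0
    p <- 1
  } else {
    Fstat <- (ssb / df_b) / (ssw / df_w)
    p <- stats::pf(Fstat, df_b, df_w, lower.tail = FALSE)
  }
  structure(list(F = Fstat, p = p, df_between = df_b, df_within = df_w,
                 significant = p <= 0.05, degenerate = degenerate),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' ANOVA table over all features and bands of a feature table
#'
#' For each (feature, band) cell, tests equality of the six emotion-class
#' means of the pooled epoch-level observations.
#'
#' @param feature_table output of [build_feature_table()].
#' @param features feature columns to test (default all six).
#' @return data.frame with columns `feature`, `band`, `F`, `p`,
#'   `df_between`, `df_within`, `significant`.
#' @export
anova_feature_table <- function(feature_table, features = FEATURE_NAMES) {
  stopifnot(all(c("emotion", "band") %in% names(feature_table)),
            all(features %in% names(feature_table)))
  out <- list()
  for (bd in unique(feature_table$band)) {
    sub <- feature_table[feature_table$band == bd, , drop = FALSE]
    for (ft in features) {
      res <- anova_oneway(split(sub[[ft]], sub$emotion))
      out[[length(out) + 1L]] <- data.frame(
        feature = ft, band = bd, F = res$F, p = res$p,
        df_between = res$df_between, df_within = res$df_within,
        significant = res$significant)
    }
  }
  do.call(rbind, out)
}

#' Select features passing the significance gate
#'
#' A feature is retained only if its ANOVA p-value is at or below `alpha`
#' in every analyzed band (the group-wide rule under which a feature that
#' fails in any band is discarded outright); `per_band = TRUE` switches to
#' per-(feature, band) retention. An optional Bonferroni correction over the
#' number of tests is available but off by default, matching the uncorrected
#' screening design.
#'
#' @param anova_table output of [anova_feature_table()] (columns `feature`,
#'   `band`, `p`).
#' @param alpha significance level (default 0.05).
#' @param per_band retain per band instead of requiring all bands?
#' @param bonferroni divide `alpha` by the number of tests first?
#' @return with `per_band = FALSE`, a character vector of retained feature
#'   names; otherwise a data.frame of retained (feature, band) pairs.
#' @export
select_significant <- function(anova_table, alpha = 0.05, per_band = FALSE,
                               bonferroni = FALSE) {
  if (is.null(anova_table) || !nrow(anova_table))
    stop("select_significant: empty results", call. = FALSE)
  if (bonferroni) alpha <- alpha / nrow(anova_table)
  if (per_band) {
    keep <- anova_table$p <= alpha
    return(anova_table[keep, c("feature", "band")])
  }
  ok <- tapply(anova_table$p <= alpha, anova_table$feature, all)
  feats <- names(ok)[ok]
  # stable feature order
  intersect(unique(anova_table$feature), feats)
}
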