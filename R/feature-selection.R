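#' Drop low-information descriptor columns
#'
#' Eliminates descriptors with more than \code{max_zero_fraction} zero values
#' and descriptors whose standard deviation is too small — interpreted as a
#' coefficient of variation below \code{min_relative_sd} (sd relative to the
#' mean absolute value); constant columns are always dropped. The returned
#' matrix carries a drop log so the rule is auditable.
#'
#' @param m Numeric descriptor matrix (compounds x descriptors).
#' @param max_zero_fraction Zero-fraction threshold (default 0.8).
#' @param min_relative_sd Relative-sd threshold (default 0.03).
#' @return The reduced matrix with a \code{"drop_log"} data frame attribute
#'   (feature, status, reason, zero_fraction, sd).
#' @export
filter_low_information <- function(m, max_zero_fraction = 0.8,
                                   min_relative_sd = 0.03) {
  m <- as.matrix(m)
  if (nrow(m) == 0L || ncol(m) == 0L) stop("empty descriptor matrix")
  zf <- colMeans(m == 0)
  sds <- apply(m, 2, stats::sd)
  mav <- apply(m, 2, function(x) mean(abs(x)))
  reason <- rep("", ncol(m))
  reason[sds == 0 | sds < min_relative_sd * mav] <- "low-sd"
  reason[zf > max_zero_fraction] <- "zero-heavy"
  keep <- reason == ""
  log <- data.frame(feature = colnames(m),
                    status = ifelse(keep, "kept", "dropped"),
                    reason = ifelse(keep, "", reason),
                    zero_fraction = zf, sd = sds, row.names = NULL)
  if (!any(keep)) stop("all descriptor columns were dropped by the filter")
  structure(m[, keep, drop = FALSE], drop_log = log)
}

#' Two-class F-score of a feature
#'
#' The feature-ranking statistic of the libsvm selection tool:
#' \deqn{F = \frac{(\bar x^{+} - \bar x)^2 + (\bar x^{-} - \bar x)^2}
#'   {\frac{1}{n^{+}-1}\sum_k (x^{+}_k - \bar x^{+})^2 +
#'    \frac{1}{n^{-}-1}\sum_k (x^{-}_k - \bar x^{-})^2}}
#' where +/- are the substrate (1) and non-substrate (0) classes. Larger F
#' means a more discriminative feature. A zero denominator with a nonzero
#' numerator returns \code{Inf}; 0/0 returns 0.
#'
#' @param x Numeric feature values.
#' @param y Labels in \{0, 1\}, both classes with at least 2 samples.
#' @return A non-negative value (possibly \code{Inf}).
#' @export
f_score <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1")
  xp <- x[y == 1]; xn <- x[y == 0]
  if (length(xp) < 2L || length(xn) < 2L) {
    stop("each class needs at least 2 samples for an F-score")
  }
  num <- (mean(xp) - mean(x))^2 + (mean(xn) - mean(x))^2
  den <- sum((xp - mean(xp))^2) / (length(xp) - 1) +
         sum((xn - mean(xn))^2) / (length(xn) - 1)
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

#' Rank features by F-score
#'
#' @param m Feature matrix.
#' @param y Labels aligned with rows of \code{m}.
#' @return A \code{feature_ranking} data frame (feature, f_score, rank)
#'   ordered by decreasing F-score; ties keep column order.
#' @export
f_score_ranking <- function(m, y) {
  m <- as.matrix(m)
  fs <- apply(m, 2, f_score, y = y)
  ord <- order(fs, decreasing = TRUE)
  structure(data.frame(feature = colnames(m)[ord], f_score = fs[ord],
                       rank = seq_along(ord), row.names = NULL),
            class = c("feature_ranking", "data.frame"))
}

#' Prune inter-correlated features
#'
#' Scans features in descending F-score order and drops any feature whose
#' absolute Pearson correlation with an already-kept feature exceeds
#' \code{max_abs_correlation} — among correlated descriptors, the one with
#' the higher F-score survives.
#'
#' @param m Feature matrix.
#' @param scores A \code{feature_ranking} from \code{\link{f_score_ranking}}
#'   covering all columns of \code{m}.
#' @param max_abs_correlation Threshold (default 0.9).
#' @return Character vector of kept feature names (in descending F order).
#' @export
prune_correlated <- function(m, scores, max_abs_correlation = 0.9) {
  m <- as.matrix(m)
  if (!all(colnames(m) %in% scores$feature)) {
    stop("ranking does not cover all features of the matrix")
  }
  ord <- scores$feature[scores$feature %in% colnames(m)]
  kept <- character(0)
  for (f in ord) {
    if (length(kept)) {
      r <- abs(stats::cor(m[, f], m[, kept, drop = FALSE]))
      if (any(r > max_abs_correlation, na.rm = TRUE)) next
    }
    kept <- c(kept, f)
  }
  kept
}

#' Incremental forward selection by F-score order
#'
#' Starting from the top-ranked feature, features are added one at a time;
#' each candidate set is scored by seeded stratified k-fold cross-validated
#' SVM accuracy, and the process stops as soon as accuracy strictly
#' decreases below the running best. The feature set with the best accuracy
#' wins; ties go to the smaller set.
#'
#' During the scan the SVM uses fixed kernel parameters
#' (\code{cfg$select_C}, \code{cfg$select_gamma}); the expensive C/gamma
#' grid search is run once afterwards on the chosen set.
#'
#' @param X Feature matrix (already restricted to candidate features).
#' @param y Labels aligned with rows.
#' @param ranking Character vector of feature names in selection order, or a
#'   \code{feature_ranking}.
#' @param cfg An \code{\link{svm_config}}.
#' @param max_features Upper bound on the scan length (defaults to all).
#' @return List with \code{features} (selected names) and \code{trace}
#'   (data frame of candidate sizes and CV accuracies).
#' @export
incremental_select <- function(X, y, ranking, cfg = svm_config(),
                               max_features = NULL) {
  if (inherits(ranking, "feature_ranking")) ranking <- ranking$feature
  ranking <- ranking[ranking %in% colnames(X)]
  if (!length(ranking)) stop("empty feature ranking")
  if (is.null(max_features)) max_features <- length(ranking)
  kmax <- min(max_features, length(ranking))
  accs <- numeric(0)
  best_acc <- -Inf; best_k <- 1L
  fold_seed <- derive_seed(cfg$seed, "select-folds")  # same folds for every k
  for (k in seq_len(kmax)) {
    feats <- ranking[seq_len(k)]
    acc <- .cv_accuracy(X[, feats, drop = FALSE], y,
                        C = cfg$select_C, gamma = cfg$select_gamma,
                        folds = cfg$folds, seed = fold_seed)
    accs[k] <- acc
    if (acc > best_acc) { best_acc <- acc; best_k <- k }
    if (acc < best_acc) break
  }
  list(features = ranking[seq_len(best_k)],
       trace = data.frame(n_features = seq_along(accs), cv_accuracy = accs))
}
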