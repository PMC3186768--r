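#' SVM run configuration
#'
#' Holds the RBF-SVM grids and cross-validation settings. The default grids
#' are the canonical exponentially growing sequences of the libsvm user
#' guide: \eqn{C \in \{2^{-5}, 2^{-3}, \ldots, 2^{15}\}},
#' \eqn{\gamma \in \{2^{-15}, 2^{-13}, \ldots, 2^{3}\}}.
#'
#' @param C_grid Positive regularization grid.
#' @param gamma_grid Positive kernel-width grid.
#' @param folds Cross-validation fold count (default 5).
#' @param seed Master seed for fold assignment and per-stage streams.
#' @param select_C,select_gamma Fixed parameters used while the incremental
#'   feature scan runs (the grid search is applied once, after selection);
#'   \code{select_gamma = NULL} means 1/(number of features).
#' @return An object of class \code{svm_config}.
#' @export
svm_config <- function(C_grid = 2^seq(-5, 15, by = 2),
                       gamma_grid = 2^seq(-15, 3, by = 2),
                       folds = 5, seed = 1,
                       select_C = 1, select_gamma = NULL) {
  stopifnot(length(C_grid) > 0, all(C_grid > 0),
            length(gamma_grid) > 0, all(gamma_grid > 0),
            folds >= 2)
  structure(list(C_grid = C_grid, gamma_grid = gamma_grid, folds = folds,
                 seed = seed, select_C = select_C, select_gamma = select_gamma),
            class = "svm_config")
}

#' Gaussian RBF kernel
#'
#' \eqn{K(u, v) = \exp(-\gamma \|u - v\|^2)}; always in (0, 1].
#'
#' @param u,v Numeric vectors of equal length.
#' @param gamma Non-negative kernel width parameter.
#' @return Kernel value.
#' @export
rbf_kernel <- function(u, v, gamma) {
  if (length(u) != length(v)) stop("u and v must have equal length")
  stopifnot(gamma >= 0)
  exp(-gamma * sum((u - v)^2))
}

# RBF kernel matrix between the rows of A and rows of B
.rbf_cross <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Z-score feature scaling
#'
#' Scales each column to mean 0, sd 1 using the training-pool statistics;
#' the returned scaler is reapplied verbatim to test, external and query
#' data (never refitted), so the RBF distance geometry is shared.
#'
#' @param m Numeric matrix with no constant column (the low-information
#'   filter guarantees this upstream).
#' @return List with \code{X} (scaled matrix) and \code{scaler}
#'   (\code{center}, \code{scale} per feature).
#' @export
scale_features <- function(m) {
  m <- as.matrix(m)
  ctr <- colMeans(m)
  scl <- apply(m, 2, stats::sd)
  zero <- scl == 0
  if (any(zero)) {
    stop("constant feature column(s) reached scaling: ",
         paste(colnames(m)[zero], collapse = ", "))
  }
  list(X = sweep(sweep(m, 2, ctr), 2, scl, "/"),
       scaler = list(center = ctr, scale = scl))
}

#' Apply (or invert) a fitted scaler
#'
#' @param scaler Scaler from \code{\link{scale_features}}.
#' @param m Matrix with the scaler's feature columns.
#' @param invert Undo the scaling instead of applying it.
#' @return Transformed matrix.
#' @export
apply_scaler <- function(scaler, m, invert = FALSE) {
  m <- as.matrix(m)[, names(scaler$center), drop = FALSE]
  if (invert) {
    sweep(sweep(m, 2, scaler$scale, "*"), 2, scaler$center, "+")
  } else {
    sweep(sweep(m, 2, scaler$center), 2, scaler$scale, "/")
  }
}

# stratified k-fold assignment; returns integer fold id per sample
.stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# mean CV accuracy of an RBF-SVM at fixed (C, gamma); per-fold z-scaling
.cv_accuracy <- function(X, y, C, gamma, folds, seed) {
  X <- as.matrix(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  fold <- .stratified_folds(y, folds, seed)
  correct <- 0L
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) next
    sc <- scale_features(X[tr, , drop = FALSE])
    fit <- e1071::svm(sc$X, factor(y[tr], levels = c(0, 1)),
                      kernel = "radial", cost = C, gamma = gamma,
                      scale = FALSE)
    pred <- predict(fit, apply_scaler(sc$scaler, X[!tr, , drop = FALSE]))
    correct <- correct + sum(as.integer(as.character(pred)) == y[!tr])
  }
  correct / length(y)
}

#' Grid search for C and gamma
#'
#' Exhaustively evaluates every (C, gamma) pair of the exponential grids by
#' seeded stratified k-fold cross-validation and returns the pair with the
#' highest mean CV accuracy; ties are broken toward smaller C, then smaller
#' gamma. The fold assignment is fixed across the grid so all pairs see the
#' same partitions.
#'
#' @param X Feature matrix.
#' @param y Labels in \{0, 1\}, both classes present.
#' @param cfg An \code{\link{svm_config}}.
#' @return List with \code{C}, \code{gamma}, \code{cv_accuracy} and the full
#'   \code{grid} (data frame of all pairs and their accuracies).
#' @export
grid_search <- function(X, y, cfg = svm_config()) {
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (cfg$folds > min(table(y))) {
    stop("fold count exceeds the minority class size")
  }
  fold_seed <- derive_seed(cfg$seed, "grid-folds")
  combos <- expand.grid(C = sort(cfg$C_grid), gamma = sort(cfg$gamma_grid),
                        KEEP.OUT.ATTRS = FALSE)
  combos <- combos[order(combos$C, combos$gamma), ]
  combos$cv_accuracy <- vapply(seq_len(nrow(combos)), function(r) {
    .cv_accuracy(X, y, combos$C[r], combos$gamma[r], cfg$folds, fold_seed)
  }, numeric(1))
  best <- which.max(combos$cv_accuracy)   # first max = smallest C, then gamma
  list(C = combos$C[best], gamma = combos$gamma[best],
       cv_accuracy = combos$cv_accuracy[best], grid = combos)
}

#' Train an RBF-SVM on the full training set
#'
#' Scales the features, fits a soft-margin RBF-kernel SVM (libsvm via
#' \pkg{e1071}) at the given (C, gamma), and packages the support-vector
#' block in a solver-independent form: predictions are computed from the
#' stored support vectors, dual coefficients and bias through
#' \code{\link{rbf_kernel}}, so a serialized model needs no fitted solver
#' object.
#'
#' @param X Feature matrix (selected features only).
#' @param y Labels in \{0, 1\}.
#' @param C,gamma Kernel parameters (e.g. from \code{\link{grid_search}}).
#' @param meta Optional list of training metadata (seed, grid, folds).
#' @return An object of class \code{pgp_model}.
#' @export
train_svm <- function(X, y, C, gamma, meta = list()) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  sc <- scale_features(X)
  fit <- e1071::svm(sc$X, factor(y, levels = c(0, 1)), kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  # decision value sign > 0 corresponds to the first label seen by libsvm
  positive_level <- fit$levels[fit$labels[1]]
  model <- structure(list(
    features = colnames(X),
    scaler = sc$scaler,
    C = C, gamma = gamma,
    SV = unname(as.matrix(fit$SV)),
    coefs = as.numeric(fit$coefs),
    rho = as.numeric(fit$rho),
    positive_level = as.character(positive_level),
    meta = meta), class = "pgp_model")
  model
}

#' @export
print.pgp_model <- function(x, ...) {
  cat(sprintf("<pgp_model> %d features (%s), C=%g, gamma=%g, %d support vectors\n",
              length(x$features), paste(x$features, collapse = ", "),
              x$C, x$gamma, nrow(x$SV)))
  invisible(x)
}

#' Predict substrate class
#'
#' Applies the model's stored scaler and evaluates the RBF decision function
#' \eqn{f(x) = \sum_k \alpha_k K(s_k, x) - \rho} over the support-vector
#' block.
#'
#' @param object A \code{pgp_model}.
#' @param newdata Matrix (or vector for one compound) over the model's
#'   features.
#' @param ... Unused.
#' @return Data frame with \code{label} (0/1) and \code{decision} value.
#' @export
predict.pgp_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list(NULL, object$features))
  }
  Z <- apply_scaler(object$scaler, newdata)
  K <- .rbf_cross(Z, object$SV, object$gamma)
  dec <- as.numeric(K %*% object$coefs) - object$rho
  lab_pos <- as.integer(object$positive_level)
  label <- ifelse(dec > 0, lab_pos, 1L - lab_pos)
  data.frame(label = label, decision = dec)
}

#' Serialize / load a trained model as plain text
#'
#' Portable JSON container holding the feature names, scaler, kernel
#' parameters and support-vector block; \code{\link{predict.pgp_model}}
#' needs nothing else.
#'
#' @param model A \code{pgp_model}.
#' @param file Output path.
#' @return \code{file} invisibly (writer); a \code{pgp_model} (reader).
#' @export
write_model <- function(model, file) {
  obj <- unclass(model)
  obj$scaler <- list(center = as.list(model$scaler$center),
                     scale = as.list(model$scaler$scale))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file)
}

#' @rdname write_model
#' @export
read_model <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  obj$scaler <- list(center = unlist(obj$scaler$center),
                     scale = unlist(obj$scaler$scale))
  obj$SV <- matrix(unlist(obj$SV), ncol = length(obj$features), byrow = FALSE)
  if (is.null(dim(obj$SV))) obj$SV <- matrix(obj$SV, ncol = length(obj$features))
  obj$features <- as.character(obj$features)
  structure(obj, class = "pgp_model")
}
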