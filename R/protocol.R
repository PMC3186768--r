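#' Repeated-split SVM evaluation protocol
#'
#' The 100-run protocol: the external validation set (from
#' \code{\link{build_external_set}}) is locked away; for each run the
#' training pool is freshly split 0.8/0.2 (stratified, seeded), descriptor
#' selection (F-score ranking, correlation pruning, incremental forward
#' selection) is performed on the 0.8 part, the (C, gamma) grid search picks
#' the kernel parameters by cross-validation, the model is refitted on the
#' whole 0.8 part, and training / test / external performance is recorded.
#' Metric means over the runs summarize the protocol.
#'
#' The low-information descriptor filter is applied once to the pool matrix
#' before the runs (the external columns follow the pool's filtering).
#'
#' @param ds A \code{labeled_dataset} with descriptor matrix.
#' @param split A \code{split_spec} partitioning the dataset into external
#'   set and training pool.
#' @param n_runs Number of repeated runs (default 100).
#' @param cfg An \code{\link{svm_config}}; \code{cfg$seed} is the master
#'   seed for every per-run stream.
#' @param features Optional fixed feature set; when given, per-run feature
#'   selection is skipped and these features are used in every run.
#' @param max_features Cap on the incremental scan length.
#' @param train_fraction Pool fraction used for training in each run.
#' @param max_zero_fraction,min_relative_sd,max_abs_correlation Filtering
#'   and pruning thresholds (see \code{\link{filter_low_information}},
#'   \code{\link{prune_correlated}}).
#' @return An object of class \code{protocol_result}: per-run records
#'   (feature set, C, gamma, train/test/external \code{eval_report}s) and
#'   mean metrics per evaluation set.
#' @export
run_protocol <- function(ds, split, n_runs = 100, cfg = svm_config(),
                         features = NULL, max_features = NULL,
                         train_fraction = 0.8,
                         max_zero_fraction = 0.8, min_relative_sd = 0.03,
                         max_abs_correlation = 0.9) {
  if (is.null(ds$X)) stop("dataset has no descriptor matrix")
  if (!setequal(c(split$external_ids, split$pool_ids), ds$ids)) {
    stop("split does not cover the dataset")
  }
  pool_X <- ds$X[split$pool_ids, , drop = FALSE]
  pool_y <- ds$labels[match(split$pool_ids, ds$ids)]
  ext_y <- ds$labels[match(split$external_ids, ds$ids)]

  pool_X <- filter_low_information(pool_X, max_zero_fraction, min_relative_sd)
  ext_X <- ds$X[split$external_ids, colnames(pool_X), drop = FALSE]

  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    sp <- split_train_test(split$pool_ids, pool_y, train_fraction,
                           seed = derive_seed(cfg$seed, "run-split", r))
    tr <- match(sp$train_ids, split$pool_ids)
    te <- match(sp$test_ids, split$pool_ids)
    Xtr <- pool_X[tr, , drop = FALSE]; ytr <- pool_y[tr]
    Xte <- pool_X[te, , drop = FALSE]; yte <- pool_y[te]

    run_cfg <- cfg
    run_cfg$seed <- derive_seed(cfg$seed, "run-cfg", r)
    feats <- if (is.null(features)) {
      ranking <- f_score_ranking(Xtr, ytr)
      kept <- prune_correlated(Xtr, ranking, max_abs_correlation)
      incremental_select(Xtr[, kept, drop = FALSE], ytr, kept,
                         cfg = run_cfg, max_features = max_features)$features
    } else {
      intersect(features, colnames(pool_X))
    }

    gs <- grid_search(Xtr[, feats, drop = FALSE], ytr, run_cfg)
    model <- train_svm(Xtr[, feats, drop = FALSE], ytr, gs$C, gs$gamma,
                       meta = list(run = r, seed = run_cfg$seed,
                                   folds = cfg$folds,
                                   cv_accuracy = gs$cv_accuracy))
    rep_tr <- evaluate_predictions(
      ytr, predict(model, Xtr[, feats, drop = FALSE])$label, "Training")
    rep_te <- evaluate_predictions(
      yte, predict(model, Xte[, feats, drop = FALSE])$label, "Test")
    rep_ex <- evaluate_predictions(
      ext_y, predict(model, ext_X[, feats, drop = FALSE])$label, "External")

    runs[[r]] <- list(run = r, features = feats, C = gs$C, gamma = gs$gamma,
                      model = model, training = rep_tr, test = rep_te,
                      external = rep_ex,
                      gap = abs(rep_tr$ACC - rep_te$ACC))
  }

  mean_metric <- function(set, metric) {
    mean(vapply(runs, function(x) x[[set]][[metric]], numeric(1)), na.rm = TRUE)
  }
  means <- do.call(rbind, lapply(c("training", "test", "external"), function(s) {
    data.frame(set = s, ACC = mean_metric(s, "ACC"), SP = mean_metric(s, "SP"),
               SE = mean_metric(s, "SE"), MCC = mean_metric(s, "MCC"))
  }))
  structure(list(runs = runs, means = means, n_runs = n_runs,
                 seed = cfg$seed,
                 mean_gap = mean(vapply(runs, `[[`, numeric(1), "gap"))),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat(sprintf("<protocol_result> %d runs (seed %s), mean train-test gap %.2f points\n",
              x$n_runs, x$seed, x$mean_gap))
  print(transform(x$means, ACC = round(ACC, 1), SP = round(SP, 1),
                  SE = round(SE, 1), MCC = round(MCC, 4)), row.names = FALSE)
  invisible(x)
}

#' Final-model selection rule
#'
#' Reproduces the best-model logic: candidates whose training-test accuracy
#' gap is not below \code{max_gap_points} percentage points are excluded
#' (strict inequality, never relaxed); among the survivors the candidate
#' with the fewest selected descriptors wins, and remaining ties are broken
#' by the highest external-set MCC.
#'
#' @param candidates Data frame (or coercible list of lists) with columns
#'   \code{train_acc}, \code{test_acc}, \code{n_features},
#'   \code{external_mcc}, and optionally \code{model}.
#' @param max_gap_points Gap threshold in accuracy percentage points
#'   (default 5).
#' @return List with \code{winner} (row index into \code{candidates}),
#'   \code{model} (if supplied), and \code{ledger} — the candidate table
#'   annotated with gap, survival status and the reason a candidate lost.
#' @export
select_final_model <- function(candidates, max_gap_points = 5) {
  if (!is.data.frame(candidates)) {
    candidates <- do.call(rbind, lapply(candidates, function(x) {
      data.frame(train_acc = x$train_acc, test_acc = x$test_acc,
                 n_features = x$n_features, external_mcc = x$external_mcc)
    }))
  }
  if (nrow(candidates) < 1L) stop("no candidate models supplied")
  ledger <- candidates
  ledger$gap <- abs(ledger$train_acc - ledger$test_acc)
  ledger$survives_gap <- ledger$gap < max_gap_points
  if (!any(ledger$survives_gap)) {
    stop("no candidate has a train-test accuracy gap below ", max_gap_points,
         " points; refusing to relax the threshold")
  }
  pool <- which(ledger$survives_gap)
  fewest <- pool[ledger$n_features[pool] == min(ledger$n_features[pool])]
  winner <- fewest[which.max(ledger$external_mcc[fewest])]
  ledger$status <- ifelse(!ledger$survives_gap, "excluded: gap",
                   ifelse(seq_len(nrow(ledger)) == winner, "selected",
                   ifelse(seq_len(nrow(ledger)) %in% fewest,
                          "lost: lower external MCC", "lost: more descriptors")))
  out <- list(winner = winner, ledger = ledger)
  if ("model" %in% names(candidates)) out$model <- candidates$model[[winner]]
  out
}
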