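#' @title Leave-one-subject-out evaluation and class-balanced metrics
#' @description One cross-validation fold per subject: all clips of the
#'   held-out subject are tested on a model trained on everyone else.
#'   Macro-domain samples only ever augment the training side. Confusion
#'   counts are pooled across folds before computing the unweighted
#'   (macro-averaged) metrics, following the grand-challenge convention.
#' @name evaluate
NULL

#' Leave-one-subject-out folds
#'
#' @param catalog An `me_catalog` (or anything with `subject_id` and
#'   `domain` columns). Only micro-domain subjects are ever held out;
#'   macro-domain rows stay in every training set.
#' @return List of folds, each with `subject`, `train_idx`, `test_idx`.
#' @export
losocv_folds <- function(catalog) {
  micro <- catalog$domain == 0
  subjects <- sort(unique(catalog$subject_id[micro]))
  if (length(subjects) < 2) {
    stop("protocol error: leave-one-subject-out needs at least 2 subjects")
  }
  lapply(subjects, function(s) {
    test <- which(micro & catalog$subject_id == s)
    list(subject = s, train_idx = setdiff(seq_len(nrow(catalog)), test),
         test_idx = test)
  })
}

#' Confusion matrix
#'
#' @param truth,pred Integer class labels in `0:(n_classes - 1)`.
#' @param n_classes Number of classes (default 3).
#' @return `n_classes x n_classes` integer matrix, rows = true class,
#'   columns = predicted class.
#' @export
confusion <- function(truth, pred, n_classes = 3) {
  stopifnot(length(truth) == length(pred))
  if (length(truth) > 0 &&
      (any(truth < 0 | truth >= n_classes) ||
       any(pred < 0 | pred >= n_classes))) {
    stop("labels must lie in 0..", n_classes - 1)
  }
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(truth)) {
    cm[truth[i] + 1L, pred[i] + 1L] <- cm[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  cm
}

.per_class_counts <- function(cm) {
  tp <- diag(cm)
  list(tp = tp, fp = colSums(cm) - tp, fn = rowSums(cm) - tp,
       n = rowSums(cm))
}

#' Unweighted F1 score
#'
#' Per class, `UF1_c = 2 TP_c / (2 TP_c + FP_c + FN_c)`; the score is the
#' unweighted mean over classes. A class with zero denominator (never
#' present and never predicted) contributes 0.
#'
#' @param cm Confusion matrix from [confusion()].
#' @return Scalar in `[0, 1]`.
#' @export
uf1 <- function(cm) {
  k <- .per_class_counts(cm)
  den <- 2 * k$tp + k$fp + k$fn
  mean(ifelse(den > 0, 2 * k$tp / pmax(den, 1), 0))
}

#' Unweighted average recall
#'
#' Per class, `Acc_c = TP_c / n_c`; the score is the unweighted mean over
#' classes, with empty classes contributing 0.
#'
#' @param cm Confusion matrix.
#' @return Scalar in `[0, 1]`.
#' @export
uar <- function(cm) {
  k <- .per_class_counts(cm)
  mean(ifelse(k$n > 0, k$tp / pmax(k$n, 1), 0))
}

#' Mean accuracy
#'
#' Ratio of true positives (the confusion-matrix trace) to all samples.
#'
#' @param cm Confusion matrix with at least one count.
#' @return Scalar in `[0, 1]`.
#' @export
mean_accuracy <- function(cm) {
  if (sum(cm) == 0) stop("mean accuracy undefined for an empty matrix")
  sum(diag(cm)) / sum(cm)
}

#' Run the full leave-one-subject-out protocol
#'
#' For every micro-domain subject: re-initialize a model (per-fold seed
#' derived from `cfg$seed`), train on all other subjects plus every
#' macro-domain sample, and predict the held-out clips. Confusion counts
#' are pooled across folds before computing UF1 / UAR / mean accuracy.
#'
#' @param tensors An `me_tensor_set` of the micro-domain catalog (from
#'   [prepare_inputs()]).
#' @param macro_tensors Optional `me_tensor_set` of macro-domain samples;
#'   when present the model is built with the domain discriminator.
#' @param cfg A [train_config()].
#' @param spec An [architecture_spec()].
#' @param verbose Print per-fold progress.
#' @return An `me_metrics` report: `uf1`, `uar`, `mean_accuracy`, the
#'   pooled confusion matrix, a per-fold tibble and all predictions.
#' @export
run_losocv <- function(tensors, macro_tensors = NULL, cfg = train_config(),
                       spec = architecture_spec(), verbose = FALSE) {
  cat_df <- tibble::tibble(subject_id = tensors$subject,
                           domain = tensors$domain)
  folds <- losocv_folds(cat_df)
  with_disc <- !is.null(macro_tensors)
  preds <- vector("list", length(folds))
  per_fold <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    train_t <- .subset_tensors(tensors, fold$train_idx)
    if (with_disc) {
      train_t <- .concat_tensors(train_t, macro_tensors)
    }
    fold_cfg <- cfg
    fold_cfg$seed <- (cfg$seed + 1000L * f) %% 2147483647L
    model <- build_model(spec, with_discriminator = with_disc,
                         seed = fold_cfg$seed)
    model <- fit(model, train_t, fold_cfg)$model
    pr <- predict_emotions(model, .subset_tensors(tensors, fold$test_idx))
    preds[[f]] <- pr
    cm_f <- confusion(pr$truth, pr$pred)
    per_fold[[f]] <- tibble::tibble(subject = fold$subject, n = nrow(pr),
                                    correct = sum(pr$truth == pr$pred),
                                    uar = uar(cm_f), uf1 = uf1(cm_f))
    if (verbose) {
      message("fold ", f, "/", length(folds), " subject ", fold$subject,
              ": ", per_fold[[f]]$correct, "/", per_fold[[f]]$n, " correct")
    }
  }
  preds <- do.call(rbind, preds)
  pooled <- confusion(preds$truth, preds$pred)
  structure(list(uf1 = uf1(pooled), uar = uar(pooled),
                 mean_accuracy = mean_accuracy(pooled), pooled = pooled,
                 per_fold = do.call(rbind, per_fold), predictions = preds),
            class = "me_metrics")
}

.concat_tensors <- function(a, b) {
  structure(list(video = c(a$video, b$video), flow = c(a$flow, b$flow),
                 y = c(a$y, b$y), domain = c(a$domain, b$domain),
                 subject = c(a$subject, b$subject),
                 clip_id = c(a$clip_id, b$clip_id)),
            class = "me_tensor_set")
}

#' @export
print.me_metrics <- function(x, ...) {
  cat("Leave-one-subject-out report (", nrow(x$per_fold), " folds, ",
      sum(x$pooled), " test clips)\n", sep = "")
  cat(sprintf("  UF1           %.4f\n", x$uf1))
  cat(sprintf("  UAR           %.4f\n", x$uar))
  cat(sprintf("  mean accuracy %.4f\n", x$mean_accuracy))
  cat("Pooled confusion (rows = truth):\n")
  print(x$pooled)
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Writes `metrics.json`, `confusion.csv` and `predictions.csv`.
#'
#' @param report An `me_metrics`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_metrics <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(uf1 = report$uf1, uar = report$uar,
                            mean_accuracy = report$mean_accuracy),
                       file.path(dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  utils::write.csv(report$pooled, file.path(dir, "confusion.csv"),
                   row.names = FALSE)
  utils::write.csv(report$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  invisible(dir)
}
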