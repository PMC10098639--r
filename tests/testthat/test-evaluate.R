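test_that("leave-one-subject-out folds partition subjects correctly", {
  cat28 <- tibble::tibble(subject_id = rep(sprintf("P%02d", 1:28), each = 3),
                          domain = 0L)
  expect_length(losocv_folds(cat28), 28)
  cat16 <- tibble::tibble(subject_id = rep(sprintf("P%02d", 1:16), each = 2),
                          domain = 0L)
  expect_length(losocv_folds(cat16), 16)
  for (fold in losocv_folds(cat16)) {
    expect_false(fold$subject %in% cat16$subject_id[fold$train_idx])
    expect_true(all(cat16$subject_id[fold$test_idx] == fold$subject))
  }
  # macro-domain rows stay in training even when the subject id matches
  mixed <- tibble::tibble(subject_id = c("A", "A", "B", "B"),
                          domain = c(0L, 1L, 0L, 1L))
  folds <- losocv_folds(mixed)
  expect_length(folds, 2)
  expect_true(all(vapply(folds, function(f) all(
    mixed$domain[f$test_idx] == 0), logical(1))))
  expect_true(all(vapply(folds, function(f) 2 %in% f$train_idx ||
                           f$subject == "A", logical(1))))
  expect_error(losocv_folds(tibble::tibble(subject_id = "A", domain = 0L)),
               "2 subjects")
})

test_that("confusion matrices tally true/predicted pairs", {
  expect_equal(confusion(c(0, 1, 2), c(0, 1, 2)), diag(c(1L, 1L, 1L)))
  expect_equal(confusion(integer(0), integer(0)), matrix(0L, 3, 3))
  truth <- c(0, 0, 1, 2, 2, 1)
  pred <- c(0, 1, 1, 2, 0, 1)
  cm <- confusion(truth, pred)
  expect_equal(cm, matrix(c(1L, 0L, 1L,  1L, 2L, 0L,  0L, 0L, 1L), 3, 3))
  expect_equal(rowSums(cm), c(2, 2, 2))  # row sums = per-class counts
  expect_error(confusion(c(0, 3), c(0, 0)), "0..2")
})

test_that("UF1, UAR and mean accuracy match hand-computed values", {
  cm <- matrix(c(8, 2, 0,  1, 6, 0,  1, 2, 10), 3, 3)  # rows = truth
  expect_equal(uf1(cm), (0.8 + 12 / 17 + 20 / 23) / 3, tolerance = 1e-6)
  expect_equal(uf1(cm), 0.79182, tolerance = 1e-4)
  expect_equal(uar(cm), 0.8, tolerance = 1e-12)
  expect_equal(mean_accuracy(cm), 24 / 30)
  perfect <- diag(c(5L, 7L, 3L))
  expect_equal(uf1(perfect), 1)
  expect_equal(uar(perfect), 1)
  expect_equal(mean_accuracy(perfect), 1)
  # a class never present and never predicted contributes 0 to the mean
  degen <- matrix(c(4L, 0L, 0L,  0L, 5L, 0L,  0L, 0L, 0L), 3, 3)
  expect_equal(uf1(degen), 2 / 3)
  expect_equal(uar(degen), 2 / 3)
  single <- matrix(0L, 3, 3); single[1, 2] <- 1L
  expect_equal(mean_accuracy(single), 0)
  expect_error(mean_accuracy(matrix(0L, 3, 3)), "empty")
})

test_that("metrics agree with an independent per-class oracle on random matrices", {
  oracle <- function(cm) {
    C <- nrow(cm)
    f1s <- recs <- numeric(C)
    for (c in seq_len(C)) {
      tp <- cm[c, c]
      fp <- sum(cm[-c, c])
      fn <- sum(cm[c, -c])
      nc <- sum(cm[c, ])
      f1s[c] <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
      recs[c] <- if (nc > 0) tp / nc else 0
    }
    c(uf1 = sum(f1s) / C, uar = sum(recs) / C)
  }
  set.seed(99)
  for (i in 1:1000) {
    cm <- matrix(rpois(9, sample(0:8, 1)), 3, 3)
    o <- oracle(cm)
    expect_equal(uf1(cm), unname(o["uf1"]), tolerance = 1e-12)
    expect_equal(uar(cm), unname(o["uar"]), tolerance = 1e-12)
  }
})

test_that("uniform random prediction on balanced classes scores near chance", {
  set.seed(7)
  n <- 10000
  truth <- rep(0:2, length.out = n)
  pred <- sample(0:2, n, replace = TRUE)
  cm <- confusion(truth, pred)
  expect_equal(uar(cm), 1 / 3, tolerance = 0.02)
  expect_equal(uf1(cm), 1 / 3, tolerance = 0.02)
})

test_that("the cross-validation harness is wired and reproducible", {
  cfg <- synth_config(n_subjects = 3, clips_per_subject = 3, seed = 14)
  tens <- prepare_inputs(synth_catalog(cfg), evm_config(fps = cfg$fps),
                         flow_config())
  tc <- train_config(lambda_da = 0, epochs = 2, batch_size = 8, seed = 5)
  rep1 <- run_losocv(tens, cfg = tc)
  expect_s3_class(rep1, "me_metrics")
  expect_equal(nrow(rep1$per_fold), 3)
  expect_equal(sum(rep1$pooled), 9)
  expect_true(all(c(rep1$uf1, rep1$uar, rep1$mean_accuracy) >= 0))
  expect_equal(nrow(rep1$predictions), 9)
  rep2 <- run_losocv(tens, cfg = tc)
  expect_identical(rep1$pooled, rep2$pooled)
  expect_identical(rep1$predictions, rep2$predictions)
  d <- file.path(tempdir(), "metrics_out")
  write_metrics(rep1, d)
  expect_true(all(file.exists(file.path(d, c("metrics.json",
                                             "confusion.csv",
                                             "predictions.csv")))))
  unlink(d, recursive = TRUE)
})
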