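test_that("emotion and domain losses match hand-computed cross-entropies", {
  expect_equal(emotion_loss(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(emotion_loss(c(0.5, 0.25, 0.25), c(1, 0, 0)), 0.69315,
               tolerance = 1e-4)
  for (k in 1:3) {
    truth <- numeric(3); truth[k] <- 1
    expect_equal(emotion_loss(rep(1 / 3, 3), truth), 1.09861,
                 tolerance = 1e-4)
  }
  expect_lt(domain_loss(1 - 1e-12, 1), 1e-10)
  expect_equal(domain_loss(0.5, 0), log(2), tolerance = 1e-10)
  expect_equal(domain_loss(0.5, 1), log(2), tolerance = 1e-10)
  expect_equal(domain_loss(0.25, 0), 0.28768, tolerance = 1e-4)
  # clamped log keeps a certain-but-wrong prediction finite
  expect_true(is.finite(emotion_loss(c(0, 1, 0), c(1, 0, 0))))
})

test_that("the batch objective is mean emotion loss minus lambda times mean domain loss", {
  batch <- list(y = rbind(c(1, 0, 0), c(0.5, 0.25, 0.25)),
                y_true = rbind(c(1, 0, 0), c(1, 0, 0)),
                d = c(0.5, 0.25), d_true = c(1, 0))
  expect_equal(total_loss(batch, 0), mean(c(0, -log(0.5))))
  val <- total_loss(batch, 15)
  expect_equal(val, mean(c(0, -log(0.5))) -
                 15 * mean(c(log(2), -log(0.75))), tolerance = 1e-12)
  # single perfect emotion prediction with an uninformative discriminator
  one <- list(y = rbind(c(1, 0, 0)), y_true = rbind(c(1, 0, 0)),
              d = 0.5, d_true = 1)
  expect_equal(total_loss(one, 15), -15 * log(2), tolerance = 1e-6)

  # decomposition holds for random batches
  set.seed(1)
  for (i in 1:20) {
    B <- sample(1:6, 1)
    p <- matrix(rgamma(3 * B, 1), B); p <- p / rowSums(p)
    yt <- t(vapply(sample(1:3, B, TRUE), function(k) {
      v <- numeric(3); v[k] <- 1; v
    }, numeric(3)))
    d <- runif(B); dt <- rbinom(B, 1, 0.5); lam <- runif(1, 0, 20)
    ly <- -log(p[cbind(1:B, max.col(yt))])
    ld <- -(dt * log(d) + (1 - dt) * log(1 - d))
    b <- list(y = p, y_true = yt, d = d, d_true = dt)
    expect_equal(total_loss(b, lam), mean(ly) - lam * mean(ld),
                 tolerance = 1e-10)
  }
})

test_that("macro-expression reduction takes the middle frame as apex", {
  mk <- function(n) structure(list(domain = 1L, n_frames = n),
                              class = "me_sample")
  expect_equal(reduce_macro_sample(mk(11))$apex_index, 6L)
  expect_equal(reduce_macro_sample(mk(10))$apex_index, 5L)   # floor convention
  red <- reduce_macro_sample(mk(30))
  expect_equal(red$apex_index, 15L)
  expect_equal(select_frame_window(30, red$apex_index), 6:23)
  expect_error(reduce_macro_sample(structure(list(domain = 0L, n_frames = 5),
                                             class = "me_sample")), "macro")
})

test_that("one optimizer step of the reversal implementation equals the explicit two-player update", {
  # dropout disabled so the fused update path is exactly reproducible from
  # per-sample evaluation-mode gradients
  spec <- toy_spec(dropout = 0)
  m <- build_model(spec, with_discriminator = TRUE, seed = 21)
  n <- 4
  set.seed(9)
  vids <- replicate(n, array(runif(6 * 6 * 16), c(6, 6, 16)), simplify = FALSE)
  flows <- replicate(n, array(rnorm(8 * 8 * 4), c(8, 8, 4)), simplify = FALSE)
  y <- c(0L, 1L, 2L, 0L); dom <- c(0, 1, 0, 1)
  tens <- structure(list(video = vids, flow = flows, y = y, domain = dom,
                         subject = rep("s", n), clip_id = as.character(1:n)),
                    class = "me_tensor_set")
  lam <- 3; lr <- 0.05
  cfg <- train_config(lambda_da = lam, lr = lr, epochs = 1, batch_size = n,
                      seed = 77, clip_features = NULL)
  trained <- fit(m, tens, cfg)$model

  # explicit saddle update from per-sample gradients:
  #   theta_y <- theta_y - lr * mean dLy ; theta_d <- theta_d - lr * mean dLd
  #   theta_f <- theta_f - lr * mean (dLy - lambda dLd)
  gs <- lapply(seq_len(n), function(i) {
    model_grads(m, vids[[i]], flows[[i]], y[i], dom[i], lambda = lam)$grads
  })
  avg <- function(extract) Reduce(`+`, lapply(gs, extract)) / n
  expect_equal(trained$params$video$W,
               m$params$video$W - lr * avg(function(g) g$video$W),
               tolerance = 1e-6)
  expect_equal(trained$params$flow$W,
               m$params$flow$W - lr * avg(function(g) g$flow$W),
               tolerance = 1e-6)
  for (k in 1:2) {
    expect_equal(trained$params$emotion[[k]]$W,
                 m$params$emotion[[k]]$W -
                   lr * avg(function(g) g$emotion[[k]]$W), tolerance = 1e-6)
    expect_equal(trained$params$discriminator[[k]]$W,
                 m$params$discriminator[[k]]$W -
                   lr * avg(function(g) g$discriminator[[k]]$W),
                 tolerance = 1e-6)
  }
  expect_equal(nrow(fit(m, tens, cfg)$history), 1)  # 1 epoch, 1 batch
})

test_that("training is seeded-deterministic and learns separable synthetic motion", {
  cfg <- synth_config(n_subjects = 2, clips_per_subject = 3, seed = 6)
  cat <- synth_catalog(cfg)
  tens <- prepare_inputs(cat, evm_config(fps = cfg$fps), flow_config())
  m <- build_model(seed = 12)
  tc <- train_config(lambda_da = 0, epochs = 30, batch_size = 8, seed = 12)
  r <- fit(m, tens, tc)
  expect_equal(nrow(r$history), 30)
  pr <- predict_emotions(r$model, tens)
  expect_gt(uar(confusion(pr$truth, pr$pred)), 0.8)
  # loss decreases overall and the rerun is bit-identical
  expect_lt(mean(tail(r$history$loss, 3)), mean(head(r$history$loss, 3)))
  r2 <- fit(m, tens, tc)
  expect_identical(r$history, r2$history)
  expect_identical(r$model$params, r2$model$params)
  expect_error(fit(m, mexr:::.subset_tensors(tens, integer(0)), tc), "empty")
})
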