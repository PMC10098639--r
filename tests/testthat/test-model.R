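test_that("layer shapes reproduce the published architecture tables", {
  sh <- stream_shapes(architecture_spec())
  expect_equal(sh$video$conv, c(62, 62, 4))
  expect_equal(sh$video$pool, c(20, 20, 1))
  expect_equal(sh$video$flatten, 12800)
  expect_equal(sh$flow$conv, c(142, 118, 6))
  expect_equal(sh$flow$pool, c(47, 39, 2))
  expect_equal(sh$flow$flatten, 117312)
  expect_equal(sh$feature_length, 130112)

  # shape oracle: out = floor((in - k) / s) + 1 per axis, for the real
  # convolution output of the compiled stream, not just the arithmetic
  m <- build_model(seed = 1)
  sf <- mexr:::.stream_fwd(array(0, c(64, 64, 18)), m$params$video,
                           c(3, 3, 15), c(1, 1, 1), 3)
  expect_equal(sf$conv_dim, (c(64, 64, 18) - c(3, 3, 15)) %/% c(1, 1, 1) + 1L)
  expect_equal(sf$pool_dim, c(20L, 20L, 1L, 32L))
  sff <- mexr:::.stream_fwd(array(0, c(144, 120, 16)), m$params$flow,
                            c(3, 3, 6), c(1, 1, 2), 3)
  expect_equal(sff$conv_dim, c(142L, 118L, 6L))
  expect_equal(sff$pool_dim, c(47L, 39L, 2L, 32L))

  expect_error(build_model(architecture_spec(video_input = c(4, 4, 4))),
               "construction error")
})

test_that("parameter counts match the published totals and a brute-force count", {
  m0 <- build_model(seed = 1)
  m1 <- build_model(with_discriminator = TRUE, seed = 1)
  expect_identical(count_parameters(m0), 16660963L)
  expect_identical(count_parameters(m1), 33325796L)
  expect_identical(count_parameters(m1, "discriminator"),
                   33325796L - 16660963L)  # 16,664,833

  # closed-form layer-by-layer enumeration for arbitrary widths
  brute <- function(spec, disc) {
    sh <- stream_shapes(spec)
    conv <- function(k) prod(k) * spec$filters + spec$filters
    chain <- function(n_in, widths) {
      tot <- 0
      for (w in widths) { tot <- tot + n_in * w + w; n_in <- w }
      tot
    }
    conv(spec$video_kernel) + conv(spec$flow_kernel) +
      chain(sh$feature_length, spec$emotion_widths) +
      if (disc) chain(sh$feature_length, spec$discriminator_widths) else 0
  }
  expect_equal(count_parameters(m1), brute(architecture_spec(), TRUE))
  odd <- architecture_spec(video_input = c(32, 32, 17),
                           flow_input = c(48, 40, 8),
                           filters = 7, flow_kernel = c(3, 3, 4),
                           emotion_widths = c(11, 3),
                           discriminator_widths = c(9, 5, 1))
  expect_equal(count_parameters(build_model(odd, TRUE, seed = 2)),
               brute(odd, TRUE))
})

test_that("initialization is deterministic given a seed", {
  a <- build_model(toy_spec(), TRUE, seed = 33)
  b <- build_model(toy_spec(), TRUE, seed = 33)
  expect_identical(a$params, b$params)
  c <- build_model(toy_spec(), TRUE, seed = 34)
  expect_false(identical(a$params, c$params))
})

test_that("the forward pass returns a softmax over 3 emotions and a domain probability", {
  m <- build_model(toy_spec(), with_discriminator = TRUE, seed = 5)
  x <- toy_inputs()
  out <- model_forward(m, x$video, x$flow)
  expect_length(out$emotion, 3)
  expect_equal(sum(out$emotion), 1, tolerance = 1e-6)
  expect_true(all(out$emotion >= 0 & out$emotion <= 1))
  expect_true(out$domain >= 0 && out$domain <= 1)

  # degenerate all-zero input stays finite
  z <- model_forward(m, array(0, c(6, 6, 16)), array(0, c(8, 8, 4)))
  expect_true(all(is.finite(z$emotion)) && is.finite(z$domain))

  # the reversal constant is forward-identity
  o1 <- model_forward(m, x$video, x$flow, grl_lambda = 0)
  o2 <- model_forward(m, x$video, x$flow, grl_lambda = 15)
  expect_identical(o1, o2)

  m0 <- build_model(toy_spec(), with_discriminator = FALSE, seed = 5)
  expect_null(model_forward(m0, x$video, x$flow)$domain)

  expect_error(model_forward(m, array(0, c(5, 6, 16)), x$flow), "video stream")
  expect_error(model_forward(m, x$video, array(0, c(8, 8, 5))), "flow stream")
})

test_that("gradient reversal multiplies the backward signal by -lambda", {
  g <- c(0.3, -1.2)
  expect_equal(grl_backward(g, 1), -g)
  expect_equal(grl_backward(g, 0), c(0, 0))
  expect_equal(grl_backward(g, 15), -15 * g)

  # finite differences on the toy network: d(total)/d(theta_f) through the
  # reversal layer equals dLy/dtheta - lambda * dLd/dtheta
  m <- build_model(toy_spec(), TRUE, seed = 11)
  x <- toy_inputs(2)
  lam <- 1
  g1 <- model_grads(m, x$video, x$flow, y_true = 2, d_true = 1, lambda = lam)
  eps <- 1e-6
  loss_at <- function(model) {
    o <- mexr:::.batch_pass(model, list(x$video), list(x$flow), y = 2,
                            dom = 1, lambda = lam, dropout = FALSE)
    o$loss_y - lam * o$loss_d
  }
  for (idx in c(1, 17)) {
    mp <- m; mp$params$flow$W[1, idx] <- mp$params$flow$W[1, idx] + eps
    mm <- m; mm$params$flow$W[1, idx] <- mm$params$flow$W[1, idx] - eps
    fd <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    expect_equal(g1$grads$flow$W[1, idx], fd, tolerance = 1e-4)
  }

  # linearity: the domain contribution to theta_f scales with lambda
  g0 <- model_grads(m, x$video, x$flow, 2, 1, lambda = 0)
  g15 <- model_grads(m, x$video, x$flow, 2, 1, lambda = 15)
  expect_equal(g15$grads$flow$W - g0$grads$flow$W,
               15 * (g1$grads$flow$W - g0$grads$flow$W), tolerance = 1e-10)
  # lambda = 0: features receive no gradient from the domain loss
  expect_equal(g0$grads$video$W,
               {
                 mnd <- build_model(toy_spec(), FALSE, seed = 11)
                 model_grads(mnd, x$video, x$flow, 2)$grads$video$W
               }, tolerance = 1e-12)
  # ...but the discriminator still trains on its own loss
  expect_gt(max(abs(g0$grads$discriminator[[1]]$W)), 0)
})

test_that("the model manifest records shapes and parameter groups", {
  m <- build_model(with_discriminator = TRUE, seed = 1)
  man <- model_manifest(m)
  expect_equal(man$layers$feature_length, 130112)
  expect_equal(man$parameters$total, 33325796L)
  d <- file.path(tempdir(), "ckpt")
  save_model(m, d)
  m2 <- load_model(d)
  expect_identical(m2$params, m$params)
  expect_true(file.exists(file.path(d, "manifest.json")))
  unlink(d, recursive = TRUE)
})
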