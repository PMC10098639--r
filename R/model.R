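#' @title Double-stream 3-D convolutional network
#' @description The recognizer has two input streams. The intensity stream
#'   convolves the magnified 64 x 64 x 18 video volume with 32 filters of
#'   3 x 3 x 15 (stride 1,1,1, no padding); the flow stream convolves the
#'   144 x 120 x 16 stacked-flow volume with 32 filters of 3 x 3 x 6 with
#'   stride (1, 1, 2) so that each two-plane flow field is consumed as one
#'   unit. Each stream is followed by ReLU, 3 x 3 x 3 max pooling (stride =
#'   pool size), dropout 0.5 and flattening; the concatenated 130,112-length
#'   feature feeds (a) an emotion head (dense 128, dropout, dense 3 +
#'   softmax) and optionally (b) a domain discriminator behind a
#'   gradient-reversal layer (dense 128, 64, 32, each with dropout, then a
#'   1-unit sigmoid output).
#' @name model
NULL

#' Architecture hyperparameters
#'
#' Defaults reproduce the reference layer tables exactly; widths of the
#' hidden dense layers (128 for the emotion head; 128, 64, 32 for the
#' discriminator) are fixed by the published parameter totals.
#'
#' @param video_input,flow_input Input volume dims, `c(H, W, D)`.
#' @param filters Convolution output channels per stream.
#' @param video_kernel,flow_kernel Kernel dims `c(kh, kw, kd)`.
#' @param video_stride,flow_stride Convolution strides `c(sh, sw, sd)`.
#' @param pool Max-pool size (cubic, stride = size, no padding).
#' @param dropout Dropout rate used after pooling and hidden dense layers.
#' @param emotion_widths Dense widths of the emotion head (last = classes).
#' @param discriminator_widths Dense widths of the discriminator
#'   (last must be 1).
#' @return An `me_arch_spec` list.
#' @export
architecture_spec <- function(video_input = c(64, 64, 18),
                              flow_input = c(144, 120, 16),
                              filters = 32,
                              video_kernel = c(3, 3, 15),
                              flow_kernel = c(3, 3, 6),
                              video_stride = c(1, 1, 1),
                              flow_stride = c(1, 1, 2),
                              pool = 3, dropout = 0.5,
                              emotion_widths = c(128, 3),
                              discriminator_widths = c(128, 64, 32, 1)) {
  stopifnot(filters >= 1, pool >= 1, dropout >= 0, dropout < 1,
            length(emotion_widths) >= 1,
            discriminator_widths[length(discriminator_widths)] == 1)
  structure(list(video_input = video_input, flow_input = flow_input,
                 filters = as.integer(filters),
                 video_kernel = video_kernel, flow_kernel = flow_kernel,
                 video_stride = video_stride, flow_stride = flow_stride,
                 pool = as.integer(pool), dropout = dropout,
                 emotion_widths = as.integer(emotion_widths),
                 discriminator_widths = as.integer(discriminator_widths)),
            class = "me_arch_spec")
}

.conv_out <- function(input, kernel, stride) {
  out <- (input - kernel) %/% stride + 1
  if (any(out < 1)) {
    stop("construction error: kernel ", paste(kernel, collapse = "x"),
         " does not fit input ", paste(input, collapse = "x"))
  }
  out
}

#' Layer output shapes of both streams
#'
#' Valid (no-padding) arithmetic: `out = floor((in - k) / s) + 1` per axis.
#'
#' @param spec An [architecture_spec()].
#' @return List with per-stream `conv`, `pool` (spatial dims), `flatten`
#'   lengths and the concatenated `feature_length`.
#' @export
stream_shapes <- function(spec = architecture_spec()) {
  sh <- function(input, kernel, stride) {
    conv <- .conv_out(input, kernel, stride)
    pool <- .conv_out(conv, rep(spec$pool, 3), rep(spec$pool, 3))
    list(conv = conv, pool = pool, flatten = prod(pool) * spec$filters)
  }
  v <- sh(spec$video_input, spec$video_kernel, spec$video_stride)
  f <- sh(spec$flow_input, spec$flow_kernel, spec$flow_stride)
  list(video = v, flow = f, feature_length = v$flatten + f$flatten)
}

.glorot <- function(n_out, n_in, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(n_out * n_in, -lim, lim), nrow = n_out)
}

#' Build a model with seeded initialization
#'
#' Weights are drawn from a fan-based uniform (Glorot-style) distribution;
#' biases start at zero. The same seed reproduces identical parameters.
#'
#' @param spec An [architecture_spec()].
#' @param with_discriminator Attach the gradient-reversal domain
#'   discriminator branch.
#' @param seed Integer seed for the initialization.
#' @return An `me_model`: list holding `spec`, `shapes`, the parameter
#'   groups (`params$video`, `params$flow` = theta_f; `params$emotion` =
#'   theta_y; `params$discriminator` = theta_d), and flags.
#' @export
build_model <- function(spec = architecture_spec(), with_discriminator = FALSE,
                        seed = 1L) {
  shapes <- stream_shapes(spec)
  set.seed(seed)
  F <- spec$filters
  conv_init <- function(kernel) {
    K <- prod(kernel)
    list(W = .glorot(F, K, fan_in = K, fan_out = K * F), b = numeric(F))
  }
  dense_chain <- function(n_in, widths) {
    layers <- list()
    for (wd in widths) {
      layers[[length(layers) + 1]] <-
        list(W = .glorot(wd, n_in, fan_in = n_in, fan_out = wd),
             b = numeric(wd))
      n_in <- wd
    }
    layers
  }
  params <- list(
    video = conv_init(spec$video_kernel),
    flow = conv_init(spec$flow_kernel),
    emotion = dense_chain(shapes$feature_length, spec$emotion_widths),
    discriminator = if (with_discriminator) {
      dense_chain(shapes$feature_length, spec$discriminator_widths)
    })
  structure(list(spec = spec, shapes = shapes, params = params,
                 with_discriminator = with_discriminator, seed = seed),
            class = "me_model")
}

#' Count trainable parameters
#'
#' @param model An `me_model`.
#' @param group `"all"` or one of the parameter groups: `"features"`
#'   (both convolution streams, theta_f), `"emotion"` (theta_y),
#'   `"discriminator"` (theta_d).
#' @return Integer count of weights plus biases.
#' @export
count_parameters <- function(model,
                             group = c("all", "features", "emotion",
                                       "discriminator")) {
  group <- match.arg(group)
  n <- function(x) if (is.null(x)) 0 else sum(vapply(
    rapply(x, length, how = "unlist"), identity, numeric(1)))
  counts <- c(features = n(model$params$video) + n(model$params$flow),
              emotion = n(model$params$emotion),
              discriminator = n(model$params$discriminator))
  if (group == "all") return(as.integer(sum(counts)))
  as.integer(counts[[group]])
}

.softmax <- function(z) {
  z <- z - matrix(apply(z, 2, max), nrow(z), ncol(z), byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(z), ncol(z), byrow = TRUE)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.check_input <- function(x, want, stream) {
  if (!identical(as.integer(dim(x)), as.integer(want))) {
    stop(stream, " stream expects input ", paste(want, collapse = "x"),
         ", got ", paste(dim(x), collapse = "x"))
  }
}

# Convolution stream forward (ReLU + pool fused in C++).
.stream_fwd <- function(x, p, kernel, stride, pool) {
  .stream_forward_cpp(x, p$W, p$b, kernel[1], kernel[2], kernel[3],
                      stride[1], stride[2], stride[3], pool)
}

#' Forward pass of the network
#'
#' Evaluation-mode pass (dropout off) for a single sample. The
#' gradient-reversal layer is the identity in forward propagation, so
#' `grl_lambda` never changes the returned values; it only scales (and
#' negates) the gradient during training.
#'
#' @param model An `me_model`.
#' @param video `64 x 64 x 18` intensity volume.
#' @param flowseq `144 x 120 x 16` stacked flow volume (or an
#'   `me_flow_sequence`).
#' @param grl_lambda Gradient-reversal constant; forward identity.
#' @return List with `emotion` (3 class probabilities summing to 1) and
#'   `domain` (probability the sample is macro-domain; `NULL` without a
#'   discriminator).
#' @export
model_forward <- function(model, video, flowseq, grl_lambda = 1) {
  if (inherits(flowseq, "me_flow_sequence")) flowseq <- flowseq$volume
  out <- .batch_pass(model, list(video), list(flowseq),
                     y = NULL, dom = NULL, lambda = grl_lambda,
                     dropout = FALSE, grads = FALSE)
  list(emotion = as.numeric(out$prob[1, ]),
       domain = if (model$with_discriminator) as.numeric(out$domain[1]))
}

#' Gradient-reversal backward rule
#'
#' Forward propagation through the reversal layer is the identity; in
#' backpropagation the upstream gradient is multiplied by `-lambda`.
#'
#' @param grad Upstream gradient (any numeric shape).
#' @param lambda Non-negative reversal constant.
#' @return `-lambda * grad`.
#' @export
grl_backward <- function(grad, lambda) -lambda * grad

# Shared batched forward/backward core. `vids` and `flows` are lists of
# arrays; `y` integer classes 0..2 (or NULL), `dom` domain labels 0/1.
# With dropout=TRUE, masks are drawn from the current R RNG stream.
# Returns probabilities, per-sample losses and (optionally) mean-over-batch
# gradients with the saddle routing: theta_y gets dLy, theta_d gets +dLd,
# theta_f gets dLy - lambda * dLd via the gradient-reversal layer.
# With sgd_lr set, the dense weight matrices are instead updated IN PLACE
# (fused gradient GEMM; the caller must own the parameter memory) and only
# the small conv/bias gradients are returned.
.batch_pass <- function(model, vids, flows, y = NULL, dom = NULL, lambda = 0,
                        dropout = FALSE, grads = FALSE, sgd_lr = NULL) {
  spec <- model$spec
  p <- model$params
  B <- length(vids)
  sh <- model$shapes
  nf <- sh$feature_length
  keep <- 1 - spec$dropout
  disc <- model$with_discriminator

  sf_v <- vector("list", B)
  sf_f <- vector("list", B)
  Fmat <- matrix(0, nf, B)
  mask_v <- if (dropout) matrix(0, sh$video$flatten, B)
  mask_f <- if (dropout) matrix(0, sh$flow$flatten, B)
  for (s in seq_len(B)) {
    .check_input(vids[[s]], spec$video_input, "video")
    .check_input(flows[[s]], spec$flow_input, "flow")
    sf_v[[s]] <- .stream_fwd(vids[[s]], p$video, spec$video_kernel,
                             spec$video_stride, spec$pool)
    sf_f[[s]] <- .stream_fwd(flows[[s]], p$flow, spec$flow_kernel,
                             spec$flow_stride, spec$pool)
    pv <- as.numeric(sf_v[[s]]$pooled)
    pf <- as.numeric(sf_f[[s]]$pooled)
    if (dropout) {
      mask_v[, s] <- stats::rbinom(length(pv), 1, keep) / keep
      mask_f[, s] <- stats::rbinom(length(pf), 1, keep) / keep
      pv <- pv * mask_v[, s]
      pf <- pf * mask_f[, s]
    }
    Fmat[, s] <- c(pv, pf)
  }

  dense_fwd <- function(layers, input, final) {
    acts <- list()
    a <- input
    nl <- length(layers)
    for (k in seq_len(nl)) {
      z <- layers[[k]]$W %*% a + layers[[k]]$b
      if (k < nl) {
        h <- pmax(z, 0)
        m <- if (dropout) matrix(stats::rbinom(length(h), 1, keep) / keep,
                                 nrow(h), ncol(h)) else NULL
        a <- if (dropout) h * m else h
        acts[[k]] <- list(z = z, a = a, mask = m)
      } else {
        acts[[k]] <- list(z = z)
        a <- final(z)
      }
    }
    list(out = a, acts = acts)
  }
  em <- dense_fwd(p$emotion, Fmat, .softmax)
  P <- em$out
  dm <- if (disc) dense_fwd(p$discriminator, Fmat, .sigmoid)
  D <- if (disc) dm$out

  loss_y <- loss_d <- NULL
  if (!is.null(y)) {
    py <- pmax(P[cbind(y + 1L, seq_len(B))], 1e-12)
    loss_y <- -log(py)
  }
  if (disc && !is.null(dom)) {
    dp <- pmin(pmax(D[1, ], 1e-12), 1 - 1e-12)
    loss_d <- -(dom * log(dp) + (1 - dom) * log(1 - dp))
  }

  g <- NULL
  if (grads || !is.null(sgd_lr)) {
    if (is.null(y)) stop("gradients require emotion labels")
    Y1 <- matrix(0, nrow(P), B)
    Y1[cbind(y + 1L, seq_len(B))] <- 1
    # Backward through a dense chain. All dz are computed against the
    # pre-update weights; with sgd_lr the weight matrices are then updated
    # in place and only bias gradients are materialized.
    dense_bwd <- function(layers, acts, dout, input) {
      nl <- length(layers)
      dzs <- vector("list", nl)
      dz <- dout
      for (k in seq(nl, 1)) {
        dzs[[k]] <- dz
        if (k > 1) {
          da <- crossprod(layers[[k]]$W, dz)
          if (!is.null(acts[[k - 1]]$mask)) da <- da * acts[[k - 1]]$mask
          dz <- da * (acts[[k - 1]]$z > 0)
        } else {
          dz <- crossprod(layers[[k]]$W, dz)
        }
      }
      gl <- vector("list", nl)
      for (k in seq_len(nl)) {
        a_prev <- if (k == 1) input else acts[[k - 1]]$a
        if (is.null(sgd_lr)) {
          gl[[k]] <- list(W = tcrossprod(dzs[[k]], a_prev),
                          b = rowSums(dzs[[k]]))
        } else {
          .sgd_gemm_update_cpp(layers[[k]]$W, dzs[[k]], a_prev, sgd_lr)
          gl[[k]] <- list(b = rowSums(dzs[[k]]))
        }
      }
      list(grads = gl, dinput = dz)
    }
    bw_y <- dense_bwd(p$emotion, em$acts, (P - Y1) / B, Fmat)
    dF <- bw_y$dinput
    g_disc <- NULL
    if (disc && !is.null(dom)) {
      dzd <- (D - matrix(dom, 1, B)) / B
      bw_d <- dense_bwd(p$discriminator, dm$acts, dzd, Fmat)
      g_disc <- bw_d$grads
      # gradient-reversal layer: features are pushed to fool the
      # discriminator while theta_d itself descends on +L_d
      dF <- dF + grl_backward(bw_d$dinput, lambda)
    }
    conv_bwd <- function(s, dpool, sf, x, kernel, stride) {
      cd <- sf$conv_dim
      .stream_backward_cpp(x, dpool, as.numeric(sf$pooled), sf$argmax,
                           spec$filters, kernel[1], kernel[2], kernel[3],
                           stride[1], stride[2], stride[3],
                           cd[1], cd[2], cd[3])
    }
    K_v <- prod(spec$video_kernel)
    K_f <- prod(spec$flow_kernel)
    g_video <- list(W = matrix(0, spec$filters, K_v), b = numeric(spec$filters))
    g_flow <- list(W = matrix(0, spec$filters, K_f), b = numeric(spec$filters))
    iv <- seq_len(sh$video$flatten)
    for (s in seq_len(B)) {
      dfeat <- dF[, s]
      dpv <- dfeat[iv]
      dpf <- dfeat[-iv]
      if (dropout) {
        dpv <- dpv * mask_v[, s]
        dpf <- dpf * mask_f[, s]
      }
      bv <- conv_bwd(s, dpv, sf_v[[s]], vids[[s]], spec$video_kernel,
                     spec$video_stride)
      bf <- conv_bwd(s, dpf, sf_f[[s]], flows[[s]], spec$flow_kernel,
                     spec$flow_stride)
      g_video$W <- g_video$W + bv$dW; g_video$b <- g_video$b + as.numeric(bv$db)
      g_flow$W <- g_flow$W + bf$dW;   g_flow$b <- g_flow$b + as.numeric(bf$db)
    }
    g <- list(video = g_video, flow = g_flow, emotion = bw_y$grads,
              discriminator = g_disc)
  }

  list(prob = t(P), domain = if (disc) as.numeric(D[1, ]),
       loss_y = loss_y, loss_d = loss_d, grads = g)
}

#' Per-sample gradients with domain-adaptation routing
#'
#' Evaluation-mode (dropout off) gradients of the adversarial objective for
#' one sample: the emotion head receives the cross-entropy gradient, the
#' discriminator descends on its own binary cross-entropy, and the shared
#' convolutional features receive
#' `d(L_y)/d(theta_f) - lambda * d(L_d)/d(theta_f)` through the
#' gradient-reversal layer. Intended for inspecting or verifying the
#' training dynamics.
#'
#' @param model An `me_model`.
#' @param video,flowseq Network inputs.
#' @param y_true Integer class in `0:2`.
#' @param d_true Domain label, 0 (micro) or 1 (macro).
#' @param lambda Domain-adaptation weight.
#' @return List with `grads` (per parameter group), `loss_y`, `loss_d`.
#' @export
model_grads <- function(model, video, flowseq, y_true, d_true = 0,
                        lambda = 0) {
  if (inherits(flowseq, "me_flow_sequence")) flowseq <- flowseq$volume
  out <- .batch_pass(model, list(video), list(flowseq), y = y_true,
                     dom = d_true, lambda = lambda, dropout = FALSE,
                     grads = TRUE)
  list(grads = out$grads, loss_y = out$loss_y,
       loss_d = out$loss_d)
}

#' Framework-neutral model manifest
#'
#' @param model An `me_model`.
#' @return List (suitable for JSON) describing layers, shapes and parameter
#'   counts.
#' @export
model_manifest <- function(model) {
  sh <- model$shapes
  list(
    layers = list(
      video = list(input = model$spec$video_input,
                   conv = c(model$spec$filters, sh$video$conv),
                   pool = c(model$spec$filters, sh$video$pool),
                   flatten = sh$video$flatten),
      flow = list(input = model$spec$flow_input,
                  conv = c(model$spec$filters, sh$flow$conv),
                  pool = c(model$spec$filters, sh$flow$pool),
                  flatten = sh$flow$flatten),
      feature_length = sh$feature_length,
      emotion_head = model$spec$emotion_widths,
      discriminator = if (model$with_discriminator)
        model$spec$discriminator_widths),
    parameters = list(
      features = count_parameters(model, "features"),
      emotion = count_parameters(model, "emotion"),
      discriminator = count_parameters(model, "discriminator"),
      total = count_parameters(model)))
}

#' Save / load a model
#'
#' Writes the native serialized parameters (`model.rds`) plus a
#' human-readable `manifest.json`.
#'
#' @param model An `me_model`.
#' @param dir Output directory (created if needed).
#' @param path For `load_model`, a directory written by `save_model`.
#' @return `save_model` returns `dir` invisibly; `load_model` an `me_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(model_manifest(model),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(file.path(path, "model.rds"))
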