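#' @title Supervised domain-adaptation training
#' @description The training objective couples a categorical cross-entropy
#'   on the emotion prediction with a binary cross-entropy on the domain
#'   prediction, `L = mean(L_y) - lambda * mean(L_d)`. The saddle structure
#'   is realized through the gradient-reversal layer: the emotion head and
#'   the discriminator each descend on their own loss, while the shared
#'   convolutional features receive
#'   `d(L_y)/d(theta_f) - lambda * d(L_d)/d(theta_f)`.
#' @name train
NULL

#' Training settings
#'
#' @param lambda_da Domain-adaptation loss weight (default 15, the ablation
#'   optimum; 0 decouples the discriminator from feature updates).
#' @param alpha_evm Magnification factor forwarded to preprocessing
#'   (default 20).
#' @param lr SGD learning rate (default 0.01).
#' @param epochs Training epochs (default 200).
#' @param batch_size Mini-batch size (default 8).
#' @param seed Seed controlling shuffling, initialization and dropout.
#' @param clip_features Maximum Euclidean norm of the shared-feature
#'   (conv-stream) gradient per step; `NULL` disables clipping. The
#'   adversarial term scales the reversed gradient by `lambda_da`, and
#'   with a constant weight as large as 15 plain SGD can enter a positive
#'   feedback loop on theta_f; clipping only this group leaves the
#'   two-player routing intact while keeping the saddle iteration stable.
#' @return A `train_config` list.
#' @export
train_config <- function(lambda_da = 15, alpha_evm = 20, lr = 0.01,
                         epochs = 200, batch_size = 8, seed = 1L,
                         clip_features = 10) {
  stopifnot(lambda_da >= 0, lr > 0, epochs >= 1, batch_size >= 1,
            alpha_evm >= 0, is.null(clip_features) || clip_features > 0)
  structure(list(lambda_da = lambda_da, alpha_evm = alpha_evm, lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), clip_features = clip_features),
            class = "train_config")
}

#' Categorical cross-entropy for the emotion prediction
#'
#' `-sum(y_true * log(y))`, with predicted probabilities floored at 1e-12
#' before the logarithm.
#'
#' @param y Predicted probability vector (sums to 1).
#' @param y_true One-hot truth vector of the same length.
#' @return Non-negative scalar; 0 iff probability 1 on the true class.
#' @export
emotion_loss <- function(y, y_true) {
  stopifnot(length(y) == length(y_true), abs(sum(y) - 1) < 1e-6)
  -sum(y_true * log(pmax(y, 1e-12)))
}

#' Binary cross-entropy for the domain prediction
#'
#' @param d Predicted probability of the macro domain.
#' @param d_true True domain label, 0 (micro) or 1 (macro).
#' @return Non-negative scalar.
#' @export
domain_loss <- function(d, d_true) {
  d <- pmin(pmax(d, 1e-12), 1 - 1e-12)
  -(d_true * log(d) + (1 - d_true) * log(1 - d))
}

#' Batch value of the adversarial objective
#'
#' `mean(L_y) - lambda * mean(L_d)` over the batch. (The per-group gradient
#' routing of the saddle objective is realized inside [fit()] /
#' [model_grads()].)
#'
#' @param batch List with `y` (B x C predicted probabilities), `y_true`
#'   (B x C one-hot), `d` (length-B domain probabilities), `d_true`
#'   (length-B 0/1 labels). `d`/`d_true` may be omitted when `lambda_da = 0`.
#' @param lambda_da Domain loss weight.
#' @return Scalar objective value.
#' @export
total_loss <- function(batch, lambda_da) {
  ly <- vapply(seq_len(nrow(batch$y)),
               function(i) emotion_loss(batch$y[i, ], batch$y_true[i, ]),
               numeric(1))
  ld <- if (!is.null(batch$d)) {
    vapply(seq_along(batch$d),
           function(i) domain_loss(batch$d[i], batch$d_true[i]), numeric(1))
  } else 0
  mean(ly) - lambda_da * mean(ld)
}

#' Macro-expression reduction
#'
#' Macro-expression clips run from a neutral onset to a full-intensity
#' apex; their intermediate expression is the closest match to a
#' micro-expression apex. The middle frame (floor convention for
#' even-length clips) is therefore declared the apex, and the standard
#' 18-frame windowing (with offset-frame duplication for short clips)
#' applies downstream.
#'
#' @param sample An `me_sample` with `domain == 1`.
#' @return The sample with `apex_index` set to the middle frame.
#' @export
reduce_macro_sample <- function(sample) {
  if (is.null(sample$domain) || sample$domain != 1) {
    stop("macro-expression reduction applies to macro-domain samples only")
  }
  n <- sample$n_frames
  if (is.null(n)) n <- dim(load_frames(sample))[3]
  if (n < 1) stop("empty clip")
  sample$apex_index <- as.integer((n - 1) %/% 2 + 1)
  sample
}

#' Preprocess a catalog into network-ready tensors
#'
#' Runs the full input pipeline for every sample: macro-expression
#' reduction (macro domain only), 18-frame window selection, resizing,
#' motion magnification of both stacks, and stacked-flow construction.
#'
#' @param catalog An `me_catalog`.
#' @param evm An [evm_config()].
#' @param flow_cfg A [flow_config()].
#' @param verbose Print progress.
#' @return An `me_tensor_set`: list of parallel vectors/lists `video`,
#'   `flow`, `y`, `domain`, `subject`, `clip_id`.
#' @export
prepare_inputs <- function(catalog, evm = evm_config(),
                           flow_cfg = flow_config(), verbose = FALSE) {
  n <- nrow(catalog)
  vids <- flows <- vector("list", n)
  for (i in seq_len(n)) {
    s <- catalog_sample(catalog, i)
    if (s$domain == 1) s <- reduce_macro_sample(s)
    win <- build_window(s, evm)
    vids[[i]] <- win$frames_small
    flows[[i]] <- build_flow_sequence(win$frames_flowres, flow_cfg)$volume
    if (verbose) message("prepared ", s$clip_id, " (", i, "/", n, ")")
  }
  structure(list(video = vids, flow = flows, y = catalog$emotion,
                 domain = catalog$domain, subject = catalog$subject_id,
                 clip_id = catalog$clip_id),
            class = "me_tensor_set")
}

.subset_tensors <- function(tensors, idx) {
  structure(list(video = tensors$video[idx], flow = tensors$flow[idx],
                 y = tensors$y[idx], domain = tensors$domain[idx],
                 subject = tensors$subject[idx],
                 clip_id = tensors$clip_id[idx]), class = "me_tensor_set")
}

# Apply the small parameter updates left over after the fused in-place
# dense-weight updates: both conv layers and every dense bias.
.apply_sgd <- function(params, grads, lr) {
  upd_conv <- function(p, g) {
    p$W <- p$W - lr * g$W
    p$b <- p$b - lr * g$b
    p
  }
  upd_bias <- function(p, g) {
    p$b <- p$b - lr * g$b
    p
  }
  params$video <- upd_conv(params$video, grads$video)
  params$flow <- upd_conv(params$flow, grads$flow)
  params$emotion <- Map(upd_bias, params$emotion, grads$emotion)
  if (!is.null(grads$discriminator)) {
    params$discriminator <- Map(upd_bias, params$discriminator,
                                grads$discriminator)
  }
  params
}

# Deep-copy the dense weight matrices so in-place SGD updates never touch
# memory the caller may still reference.
.copy_params <- function(params) {
  dup <- function(layers) lapply(layers, function(l) {
    l$W <- l$W + 0
    l
  })
  params$emotion <- dup(params$emotion)
  if (!is.null(params$discriminator)) {
    params$discriminator <- dup(params$discriminator)
  }
  params
}

#' Train a model by SGD
#'
#' Mini-batch stochastic gradient descent on the adversarial objective with
#' uniform shuffling of the combined micro + macro pool each epoch. Both
#' domains carry emotion labels and contribute to both loss terms
#' (supervised adaptation). Fully deterministic given `cfg$seed`.
#'
#' @param model An `me_model` from [build_model()].
#' @param tensors An `me_tensor_set` from [prepare_inputs()].
#' @param cfg A [train_config()].
#' @return List with the trained `model` and `history`, a tibble with one
#'   row per epoch (`loss`, `emotion_loss`, `domain_loss`).
#' @export
fit <- function(model, tensors, cfg = train_config()) {
  n <- length(tensors$video)
  if (n == 0) stop("empty training set")
  lambda <- cfg$lambda_da
  set.seed(cfg$seed)
  model$params <- .copy_params(model$params)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(n)
    sly <- sld <- 0
    nb <- 0
    for (b0 in seq(1, n, by = cfg$batch_size)) {
      idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
      out <- .batch_pass(model, tensors$video[idx], tensors$flow[idx],
                         y = tensors$y[idx], dom = tensors$domain[idx],
                         lambda = lambda, dropout = TRUE, sgd_lr = cfg$lr)
      if (any(!is.finite(out$loss_y)) ||
          (!is.null(out$loss_d) && any(!is.finite(out$loss_d)))) {
        stop("numerical failure: non-finite loss at epoch ", ep)
      }
      if (!is.null(cfg$clip_features)) {
        g <- out$grads
        nf <- sqrt(sum(g$video$W^2) + sum(g$video$b^2) +
                     sum(g$flow$W^2) + sum(g$flow$b^2))
        if (nf > cfg$clip_features) {
          sc <- cfg$clip_features / nf
          out$grads$video$W <- g$video$W * sc
          out$grads$video$b <- g$video$b * sc
          out$grads$flow$W <- g$flow$W * sc
          out$grads$flow$b <- g$flow$b * sc
        }
      }
      model$params <- .apply_sgd(model$params, out$grads, cfg$lr)
      sly <- sly + mean(out$loss_y)
      sld <- sld + if (is.null(out$loss_d)) 0 else mean(out$loss_d)
      nb <- nb + 1
    }
    hist[[ep]] <- tibble::tibble(epoch = ep, emotion_loss = sly / nb,
                                 domain_loss = sld / nb,
                                 loss = sly / nb - lambda * sld / nb)
  }
  list(model = model, history = do.call(rbind, hist))
}

#' Predict emotion classes for a tensor set
#'
#' Evaluation-mode forward passes; the predicted class is the argmax of the
#' softmax, ties broken toward the lowest class index.
#'
#' @param model A trained `me_model`.
#' @param tensors An `me_tensor_set`.
#' @return Tibble with `clip_id`, `subject`, `truth`, `pred` and the three
#'   class probabilities.
#' @export
predict_emotions <- function(model, tensors) {
  n <- length(tensors$video)
  out <- .batch_pass(model, tensors$video, tensors$flow, dropout = FALSE,
                     grads = FALSE)
  pred <- apply(out$prob, 1, which.max) - 1L
  tibble::tibble(clip_id = tensors$clip_id, subject = tensors$subject,
                 truth = tensors$y, pred = pred,
                 p0 = out$prob[, 1], p1 = out$prob[, 2], p2 = out$prob[, 3])
}
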