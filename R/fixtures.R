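#' @title Synthetic expression-clip generator
#' @description Generates labeled clips that emulate the regime the
#'   recognizer targets: a subject-specific analytic texture (the "face")
#'   locally displaced by a Gaussian-envelope warp along a class-specific
#'   direction, with displacement ramping up to a mid-clip apex and back
#'   down, plus sensor noise. Micro-domain clips move by about a pixel;
#'   macro-domain clips move several pixels. Both the texture and the warp
#'   are evaluated in closed form at fractional coordinates, so motion is
#'   genuinely sub-pixel and magnification predictions apply exactly.
#' @name fixtures
NULL

#' Generator settings
#'
#' @param n_subjects Number of synthetic subjects.
#' @param clips_per_subject Clips per subject; classes cycle 0, 1, 2 so
#'   multiples of 3 give exact class balance.
#' @param frames_per_clip Frames per clip.
#' @param fps Frame rate (frames/second).
#' @param height,width Native frame size, pixels.
#' @param amp_micro,amp_macro Peak patch displacement (pixels) for the
#'   micro and macro domains; macro must exceed micro.
#' @param noise_sd Additive Gaussian sensor noise (intensity units;
#'   the default matches a good 8-bit camera at roughly one gray level).
#' @param seed Master seed; every clip's randomness derives from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_subjects = 12, clips_per_subject = 3,
                         frames_per_clip = 24, fps = 30,
                         height = 96, width = 80,
                         amp_micro = 1.0, amp_macro = 6.0,
                         noise_sd = 0.005, seed = 1L) {
  stopifnot(amp_micro > 0, amp_macro > amp_micro, n_subjects >= 1,
            clips_per_subject >= 1, frames_per_clip >= 2)
  structure(list(n_subjects = as.integer(n_subjects),
                 clips_per_subject = as.integer(clips_per_subject),
                 frames_per_clip = as.integer(frames_per_clip), fps = fps,
                 height = as.integer(height), width = as.integer(width),
                 amp_micro = amp_micro, amp_macro = amp_macro,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

# Subject-specific analytic face texture: a sum of random Gaussian bumps.
# Because the texture is a closed-form function of continuous coordinates,
# frames can be rendered at sub-pixel warped positions exactly, with no
# resampling artifacts.
.synth_face_params <- function(subject_id, cfg, n_bumps = 80) {
  set.seed((cfg$seed + 7L * .stable_hash(subject_id)) %% 2147483647L)
  list(r = stats::runif(n_bumps, 1, cfg$height),
       c = stats::runif(n_bumps, 1, cfg$width),
       sigma = stats::runif(n_bumps, 2.5, 7),
       amp = stats::runif(n_bumps, -0.28, 0.28))
}

# Evaluate the analytic texture at (possibly fractional) coordinates.
.eval_face <- function(face, rr, cc) {
  out <- rep(0.5, length(rr))
  for (k in seq_along(face$amp)) {
    out <- out + face$amp[k] *
      exp(-((rr - face$r[k])^2 + (cc - face$c[k])^2) / (2 * face$sigma[k]^2))
  }
  out
}

#' Generate one synthetic clip
#'
#' A localized Gaussian-envelope warp displaces the face texture itself:
#' class 0 moves the patch downward, class 1 upward, class 2 moves two
#' patches horizontally outward. The displacement profile peaks at the
#' middle frame, which becomes the apex (so the net onset-to-apex
#' displacement, not the instantaneous frame-to-frame velocity, carries
#' the class direction).
#'
#' @param class_id Emotion class in `0:2`.
#' @param subject_id Subject identifier string.
#' @param domain 0 (micro amplitude) or 1 (macro amplitude).
#' @param cfg A [synth_config()].
#' @param clip_index Index distinguishing repeated clips of one
#'   (subject, class) pair.
#' @return An `me_sample` with in-memory frames.
#' @export
synth_sample <- function(class_id, subject_id, domain = 0,
                         cfg = synth_config(), clip_index = 1) {
  stopifnot(class_id %in% 0:2, domain %in% 0:1)
  h <- cfg$height; w <- cfg$width; T <- cfg$frames_per_clip
  face <- .synth_face_params(subject_id, cfg)
  amp <- if (domain == 1) cfg$amp_macro else cfg$amp_micro
  apex <- (T - 1L) %/% 2L + 1L
  profile <- exp(-((seq_len(T) - apex)^2) / (2 * (T / 6)^2))
  sig_env <- 10  # spatial extent of the moving patch, pixels
  set.seed((cfg$seed + 13L * .stable_hash(subject_id) + 101L * class_id +
              10007L * clip_index + 31L * domain) %% 2147483647L)
  jit <- stats::runif(2, -2, 2)  # clip-specific patch placement jitter
  r0 <- h / 2 + jit[1]
  c0 <- w / 2 + jit[2]
  # per-class displacement direction and envelope centres
  patches <- switch(as.character(class_id),
    "0" = list(list(r = r0, c = c0, dr = 1, dc = 0)),
    "1" = list(list(r = r0, c = c0, dr = -1, dc = 0)),
    "2" = list(list(r = r0, c = c0 - w / 5, dr = 0, dc = -1),
               list(r = r0, c = c0 + w / 5, dr = 0, dc = 1)))
  rr_g <- matrix(seq_len(h), h, w)
  cc_g <- matrix(seq_len(w), h, w, byrow = TRUE)
  base <- matrix(.eval_face(face, as.numeric(rr_g), as.numeric(cc_g)), h, w)
  envs <- lapply(patches, function(p) {
    exp(-((rr_g - p$r)^2 + (cc_g - p$c)^2) / (2 * sig_env^2))
  })
  # only pixels where some envelope is non-negligible ever move
  moving <- which(Reduce(`+`, envs) > 1e-3)
  frames <- array(0, dim = c(h, w, T))
  for (t in seq_len(T)) {
    dt <- amp * profile[t]
    img <- base
    if (length(moving) > 0 && dt != 0) {
      rr <- rr_g[moving]
      cc <- cc_g[moving]
      rw <- rr
      cw <- cc
      for (k in seq_along(patches)) {
        e <- envs[[k]][moving]
        rw <- rw - dt * patches[[k]]$dr * e
        cw <- cw - dt * patches[[k]]$dc * e
      }
      img[moving] <- .eval_face(face, rw, cw)
    }
    img <- img + matrix(stats::rnorm(h * w, sd = cfg$noise_sd), h, w)
    frames[, , t] <- .clamp01(img)
  }
  structure(list(
    clip_id = sprintf("%s_c%d_k%d_d%d", subject_id, clip_index, class_id,
                      domain),
    subject_id = subject_id, dataset = "synthetic", domain = as.integer(domain),
    emotion = as.integer(class_id), apex_index = apex, n_frames = T,
    fps = cfg$fps, path = NA_character_, frames = frames),
    class = "me_sample")
}

#' Generate a synthetic catalog
#'
#' Balanced classes per subject (classes cycle 0, 1, 2 over
#' `clips_per_subject`). Optionally writes the clips as a samm-like
#' on-disk tree (PNG frame folders plus `labels.csv`) readable by
#' [scan_dataset()].
#'
#' @param cfg A [synth_config()].
#' @param domain Domain tag for every clip: 0 micro (default) or 1 macro.
#' @param dir Optional directory to write an image-sequence tree into.
#' @return An `me_catalog` with in-memory frames.
#' @export
synth_catalog <- function(cfg = synth_config(), domain = 0, dir = NULL) {
  rows <- list()
  for (s in seq_len(cfg$n_subjects)) {
    sid <- sprintf("S%02d", s)
    for (k in seq_len(cfg$clips_per_subject)) {
      cls <- (k - 1L) %% 3L
      smp <- synth_sample(cls, sid, domain, cfg, clip_index = k)
      rows[[length(rows) + 1]] <- tibble::tibble(
        clip_id = smp$clip_id, subject_id = sid, dataset = "synthetic",
        domain = smp$domain, emotion = smp$emotion,
        apex_index = smp$apex_index, n_frames = smp$n_frames, fps = cfg$fps,
        path = NA_character_, frames = list(smp$frames))
    }
  }
  catalog <- .new_catalog(do.call(rbind, rows))
  if (!is.null(dir)) .write_synth_tree(catalog, dir)
  catalog
}

# Samm-like on-disk layout: one PNG folder per clip plus labels.csv.
.write_synth_tree <- function(catalog, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  label_names <- c("other", "happiness", "surprise")
  for (i in seq_len(nrow(catalog))) {
    clip_dir <- file.path(dir, catalog$clip_id[i])
    dir.create(clip_dir, showWarnings = FALSE)
    frames <- catalog$frames[[i]]
    for (t in seq_len(dim(frames)[3])) {
      png::writePNG(frames[, , t],
                    file.path(clip_dir, sprintf("frame_%03d.png", t)))
    }
  }
  utils::write.csv(
    data.frame(clip_id = catalog$clip_id, subject_id = catalog$subject_id,
               label = label_names[catalog$emotion + 1],
               apex_index = catalog$apex_index),
    file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}
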