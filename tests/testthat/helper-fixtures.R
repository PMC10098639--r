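# Shared helpers: small textured images, on-disk corpus trees, and an
# independent brute-force implementation of the frame-selection rules.

# Smooth random texture with enough gradient everywhere for flow to lock on.
textured_image <- function(h, w, seed = 3, passes = 2) {
  set.seed(seed)
  tex <- matrix(rnorm(h * w), h, w)
  for (i in seq_len(passes)) tex <- mexr:::.binom5_blur_cpp(tex)
  tex
}

# Write a minimal PNG corpus: `spec` is a data.frame with clip_id,
# subject_id, label (+ optional apex_index); every clip gets `n_frames`
# constant gray frames.
write_corpus <- function(root, spec, n_frames = 4, h = 16, w = 16,
                         value = 0.5) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(spec))) {
    d <- file.path(root, spec$clip_id[i])
    dir.create(d, showWarnings = FALSE)
    for (t in seq_len(n_frames)) {
      png::writePNG(matrix(value, h, w),
                    file.path(d, sprintf("f%02d.png", t)))
    }
  }
  utils::write.csv(spec, file.path(root, "labels.csv"), row.names = FALSE)
  root
}

# Independent enumeration of the five window-selection rules (oracle).
window_oracle <- function(n, apex = NULL) {
  if (n < 18) return(c(seq_len(n), rep(n, 18 - n)))         # short clip
  if (is.null(apex)) return(1:18)                           # apex unknown
  if (apex - 1 >= 9 && n - apex >= 8) return((apex - 9):(apex + 8))
  if (apex - 1 < 9) return(1:18)                            # near the start
  (n - 17):n                                                # near the end
}

# Tiny architecture with the same layer grammar as the default model, for
# fast gradient and routing checks.
toy_spec <- function(dropout = 0) {
  architecture_spec(video_input = c(6, 6, 16), flow_input = c(8, 8, 4),
                    filters = 2, video_kernel = c(3, 3, 15),
                    flow_kernel = c(3, 3, 2), video_stride = c(1, 1, 1),
                    flow_stride = c(1, 1, 2), pool = 1, dropout = dropout,
                    emotion_widths = c(5, 3),
                    discriminator_widths = c(4, 1))
}

toy_inputs <- function(seed = 1) {
  set.seed(seed)
  list(video = array(runif(6 * 6 * 16), c(6, 6, 16)),
       flow = array(rnorm(8 * 8 * 4, sd = 0.5), c(8, 8, 4)))
}
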