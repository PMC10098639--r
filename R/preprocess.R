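#' @title Apex-centered frame selection and stream input construction
#' @name preprocess
NULL

#' Select the 18-frame window around the apex
#'
#' Frame indices are 1-based. The selection rules, in order of precedence:
#' clips shorter than 18 frames take every frame and then repeat the offset
#' (last) frame up to length 18; with an unknown apex the first 18 frames
#' are taken; with a known apex and at least 9 frames before plus 8 after
#' it, the window is `(apex - 9):(apex + 8)`; with fewer than 9 frames
#' before the apex the first 18 are taken; with fewer than 8 after it, the
#' last 18.
#'
#' @param n_frames Number of frames in the clip.
#' @param apex_index Optional 1-based apex frame index.
#' @return Integer vector of exactly 18 non-decreasing frame indices.
#' @export
select_frame_window <- function(n_frames, apex_index = NULL) {
  n_frames <- as.integer(n_frames)
  if (n_frames < 1) stop("empty clip: no frames to select")
  if (!is.null(apex_index)) {
    apex_index <- as.integer(apex_index)
    stopifnot(apex_index >= 1, apex_index <= n_frames)
  }
  if (n_frames < 18) {
    return(c(seq_len(n_frames), rep(n_frames, 18 - n_frames)))
  }
  if (is.null(apex_index)) return(1:18)
  before <- apex_index - 1L
  after <- n_frames - apex_index
  if (before >= 9 && after >= 8) return((apex_index - 9L):(apex_index + 8L))
  if (before < 9) return(1:18)
  (n_frames - 17L):n_frames
}

#' Bilinear frame resizing
#'
#' Centre-aligned bilinear interpolation (a constant image stays constant;
#' 2x downsampling averages neighbouring pixels).
#'
#' @param img 2-D numeric matrix.
#' @param height,width Target size in pixels.
#' @return Matrix of dim `c(height, width)`.
#' @export
resize_frame <- function(img, height, width) {
  if (!is.matrix(img) || length(img) == 0) stop("img must be a non-empty matrix")
  if (height < 1 || width < 1) stop("target size must be positive")
  .bilinear_resize_cpp(img, as.integer(height), as.integer(width))
}

.resize_stack <- function(frames, height, width) {
  out <- array(0, dim = c(height, width, dim(frames)[3]))
  for (t in seq_len(dim(frames)[3])) {
    out[, , t] <- .bilinear_resize_cpp(frames[, , t], height, width)
  }
  out
}

#' Build the two magnified stream inputs for one sample
#'
#' Applies [select_frame_window()], resizes the selected frames to the two
#' stream resolutions (64 x 64 for the intensity stream, 144 x 120 for the
#' optical-flow stream), and motion-magnifies each full 18-frame stack with
#' [magnify_sequence()] (temporal filtering needs the whole sequence, so
#' magnification happens after windowing, not per frame).
#'
#' @param sample An `me_sample` (frames loaded on demand).
#' @param evm An [evm_config()]; its `fps` defaults to the sample's.
#' @return An `me_frame_window`: list with `indices` (length 18),
#'   `frames_small` (64 x 64 x 18) and `frames_flowres` (144 x 120 x 18).
#' @export
build_window <- function(sample, evm = evm_config()) {
  frames <- load_frames(sample)
  idx <- select_frame_window(dim(frames)[3], sample$apex_index)
  win <- frames[, , idx, drop = FALSE]
  if (is.null(evm$fps)) evm$fps <- sample$fps
  small <- magnify_sequence(.resize_stack(win, 64, 64), evm)
  flowres <- magnify_sequence(.resize_stack(win, 144, 120), evm)
  structure(list(indices = idx, frames_small = small,
                 frames_flowres = flowres),
            class = "me_frame_window")
}
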