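#' @title Dense optical-flow sequence construction
#' @name flow
NULL

#' Optical-flow engine settings
#'
#' The default engine is a Farneback polynomial-expansion implementation;
#' `engine` may be replaced by any function with the [dense_flow()] contract
#' (two equal-shape frames in, `H x W x 2` displacement out).
#'
#' @param d Frame interval between the two frames of each pair (default 2).
#' @param pyr_scale Pyramid downscale factor in `(0, 1)`.
#' @param levels Number of pyramid levels.
#' @param winsize Averaging window size, pixels.
#' @param iterations Refinement iterations per level.
#' @param poly_n Pixel neighbourhood for polynomial expansion.
#' @param poly_sigma Gaussian applicability sigma for the expansion.
#' @param standardize If `TRUE`, standardize each flow volume to zero mean
#'   and unit variance; off by default (raw pixel displacements are fed to
#'   the network).
#' @param engine Optional replacement flow function
#'   `function(a, b, cfg) -> H x W x 2`.
#' @return A `flow_config` list.
#' @export
flow_config <- function(d = 2, pyr_scale = 0.5, levels = 3, winsize = 15,
                        iterations = 3, poly_n = 5, poly_sigma = 1.1,
                        standardize = FALSE, engine = NULL) {
  stopifnot(d >= 1, d <= 17, pyr_scale > 0, pyr_scale < 1, levels >= 1,
            winsize >= 3, iterations >= 1, poly_n >= 3, poly_n %% 2 == 1,
            poly_sigma > 0)
  structure(list(d = as.integer(d), pyr_scale = pyr_scale,
                 levels = as.integer(levels), winsize = as.integer(winsize),
                 iterations = as.integer(iterations),
                 poly_n = as.integer(poly_n), poly_sigma = poly_sigma,
                 standardize = standardize, engine = engine),
            class = "flow_config")
}

#' Dense optical flow between two frames
#'
#' Per-pixel displacement (in pixels) mapping `frame_a` onto `frame_b`.
#' Plane 1 holds horizontal (column) displacement, plane 2 vertical (row)
#' displacement.
#'
#' @param frame_a,frame_b Equal-shape 2-D intensity matrices.
#' @param cfg A [flow_config()].
#' @return Array of dim `c(H, W, 2)`.
#' @export
dense_flow <- function(frame_a, frame_b, cfg = flow_config()) {
  if (!identical(dim(frame_a), dim(frame_b))) {
    stop("frames must share one shape")
  }
  if (!is.null(cfg$engine)) return(cfg$engine(frame_a, frame_b, cfg))
  f <- .farneback_cpp(frame_a, frame_b, cfg$pyr_scale, cfg$levels,
                      cfg$winsize, cfg$iterations, cfg$poly_n, cfg$poly_sigma)
  array(f, dim = dim(f))
}

#' Assemble the stacked optical-flow volume of an 18-frame window
#'
#' With interval `d = 2`, frames (1,3), (3,5), ..., (15,17) yield exactly 8
#' flow fields; each contributes its horizontal then vertical plane, giving
#' a `144 x 120 x 16` volume ordered by pair start frame. The 18th frame is
#' never touched by the flow stream (it feeds the intensity stream only).
#'
#' @param frames_flowres `144 x 120 x 18` array.
#' @param cfg A [flow_config()].
#' @return An `me_flow_sequence`: list with `volume` (`H x W x 2k`) and
#'   `pairs` (k x 2 matrix of 1-based frame indices).
#' @export
build_flow_sequence <- function(frames_flowres, cfg = flow_config()) {
  dims <- dim(frames_flowres)
  if (length(dims) != 3 || dims[3] != 18) {
    stop("expected an 18-frame stack, got ",
         paste(dims, collapse = "x"))
  }
  d <- cfg$d
  n_fields <- (18 - 1) %/% d
  starts <- (seq_len(n_fields) - 1L) * d + 1L
  volume <- array(0, dim = c(dims[1], dims[2], 2L * n_fields))
  for (k in seq_len(n_fields)) {
    fl <- dense_flow(frames_flowres[, , starts[k]],
                     frames_flowres[, , starts[k] + d], cfg)
    volume[, , 2 * k - 1] <- fl[, , 1]
    volume[, , 2 * k] <- fl[, , 2]
  }
  if (isTRUE(cfg$standardize)) {
    volume <- (volume - mean(volume)) / max(stats::sd(volume), 1e-8)
  }
  structure(list(volume = volume,
                 pairs = cbind(start = starts, end = starts + d)),
            class = "me_flow_sequence")
}
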