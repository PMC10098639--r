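#' @title Eulerian video magnification
#' @description Each frame is decomposed into a Laplacian pyramid `L`; every
#'   spatial band is temporally bandpass-filtered into `B` and the amplified
#'   band `L' = L + alpha * B` is collapsed back into the frame. The
#'   temporal filter is an ideal (discrete-Fourier) bandpass along time, so
#'   in-band gain is exactly one and the DC component is always removed.
#' @name evm
NULL

#' Magnification settings
#'
#' @param alpha Amplification factor (unitless, `>= 0`). Default 20, the
#'   value at which recognition accuracy peaks in ablation.
#' @param levels Pyramid depth (detail bands plus the lowpass residual).
#'   Frame height and width must be divisible by `2^(levels - 1)`.
#' @param f_low,f_high Passband edges in Hz; must satisfy
#'   `0 <= f_low < f_high <= fps / 2`.
#' @param fps Frames/second; may be left `NULL` and supplied at use.
#' @return An `evm_config` list.
#' @export
evm_config <- function(alpha = 20, levels = 3, f_low = 0.4, f_high = 3.0,
                       fps = NULL) {
  stopifnot(alpha >= 0, levels >= 1, f_low >= 0, f_low < f_high)
  if (!is.null(fps)) stopifnot(f_high <= fps / 2)
  structure(list(alpha = alpha, levels = as.integer(levels), f_low = f_low,
                 f_high = f_high, fps = fps), class = "evm_config")
}

#' Laplacian pyramid decomposition
#'
#' Detail bands finest first, with the lowpass residual as the last level.
#' The decomposition is exactly invertible: `collapse_pyramid(build_pyramid(x))`
#' reproduces `x` to machine precision.
#'
#' @param img 2-D numeric matrix; height and width must be divisible by
#'   `2^(levels - 1)`.
#' @param levels Number of pyramid levels (`>= 1`).
#' @return An `me_pyramid` (list of matrices).
#' @export
build_pyramid <- function(img, levels) {
  levels <- as.integer(levels)
  stopifnot(is.matrix(img), levels >= 1)
  div <- 2^(levels - 1)
  if (nrow(img) %% div != 0 || ncol(img) %% div != 0) {
    stop("image dimensions ", nrow(img), "x", ncol(img),
         " must be divisible by 2^(levels-1) = ", div)
  }
  bands <- vector("list", levels)
  g <- img
  if (levels > 1) {
    for (k in seq_len(levels - 1)) {
      gd <- .pyr_down_cpp(g)
      bands[[k]] <- g - .pyr_up_cpp(gd)
      g <- gd
    }
  }
  bands[[levels]] <- g
  structure(bands, class = "me_pyramid")
}

#' Collapse a Laplacian pyramid back into an image
#'
#' @param pyr An `me_pyramid` from [build_pyramid()].
#' @return 2-D matrix at the original resolution.
#' @export
collapse_pyramid <- function(pyr) {
  n <- length(pyr)
  g <- pyr[[n]]
  if (n > 1) {
    for (k in seq(n - 1, 1)) {
      up <- .pyr_up_cpp(g)
      if (!identical(dim(up), dim(pyr[[k]]))) {
        stop("inconsistent pyramid level shapes at level ", k)
      }
      g <- pyr[[k]] + up
    }
  }
  g
}

#' Ideal temporal bandpass filter
#'
#' Filters along the time axis with an ideal discrete-Fourier bandpass:
#' frequency bins with `f_low <= f <= f_high` pass with gain one, all
#' others (always including DC) are removed, so a constant series maps
#' to zero.
#'
#' @param x Time series: a vector of length T, a `T x N` matrix (time in
#'   rows), or an `H x W x T` array (time in the third dimension).
#' @param f_low,f_high Passband edges, Hz.
#' @param fps Sampling rate, frames/second.
#' @return Filtered series with the same shape as `x`.
#' @export
temporal_bandpass <- function(x, f_low, f_high, fps) {
  if (!(f_low >= 0 && f_low < f_high && f_high <= fps / 2)) {
    stop("passband must satisfy 0 <= f_low < f_high <= fps/2 (got ",
         f_low, "..", f_high, " at fps ", fps, ")")
  }
  dims <- dim(x)
  if (is.null(dims)) {
    m <- matrix(x, ncol = 1)
  } else if (length(dims) == 2) {
    m <- x
  } else if (length(dims) == 3) {
    m <- t(matrix(x, nrow = dims[1] * dims[2], ncol = dims[3]))
  } else {
    stop("x must be a vector, T x N matrix, or H x W x T array")
  }
  T <- nrow(m)
  if (T < 2) stop("need at least 2 time points")
  freq <- (seq_len(T) - 1) * fps / T
  folded <- pmin(freq, fps - freq)
  keep <- folded >= f_low & folded <= f_high & seq_len(T) != 1
  spec <- stats::mvfft(m)
  spec[!keep, ] <- 0
  out <- Re(stats::mvfft(spec, inverse = TRUE)) / T
  if (is.null(dims)) return(drop(out))
  if (length(dims) == 2) return(out)
  array(t(out), dim = dims)
}

#' Motion-magnify a frame sequence
#'
#' The Eulerian scheme: per frame Laplacian decomposition, per-level ideal
#' temporal bandpass `B`, amplified recombination `L' = L + alpha * B`,
#' collapse, and clipping to `[0, 1]`.
#'
#' @param frames `H x W x T` array with `T >= 2`.
#' @param config An [evm_config()] with `fps` set.
#' @return Magnified `H x W x T` array, clipped to `[0, 1]`.
#' @export
magnify_sequence <- function(frames, config) {
  stopifnot(inherits(config, "evm_config"), length(dim(frames)) == 3)
  if (is.null(config$fps)) stop("evm_config$fps must be set")
  T <- dim(frames)[3]
  if (T < 2) stop("need at least 2 frames to magnify")
  pyrs <- lapply(seq_len(T), function(t) build_pyramid(frames[, , t],
                                                       config$levels))
  out_pyrs <- pyrs
  for (k in seq_len(config$levels)) {
    d <- dim(pyrs[[1]][[k]])
    stack <- array(unlist(lapply(pyrs, `[[`, k)), dim = c(d, T))
    B <- temporal_bandpass(stack, config$f_low, config$f_high, config$fps)
    amp <- stack + config$alpha * B
    for (t in seq_len(T)) out_pyrs[[t]][[k]] <- amp[, , t]
  }
  out <- frames
  for (t in seq_len(T)) {
    out[, , t] <- .clamp01(collapse_pyramid(out_pyrs[[t]]))
  }
  out
}
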