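#' @title Array utilities for NCHW feature maps
#' @description
#' All network components in this package operate on plain R arrays with
#' dimension order (batch, channel, height, width) — the NCHW convention of
#' the major deep-learning frameworks. The helpers here implement the small
#' set of tensor primitives the detection blocks need: zero / replicate
#' padding, dense and depthwise 2-D convolution (with stride, dilation and
#' groups), stride-1 max pooling, nearest-neighbour upsampling, adaptive
#' average pooling, and numerically stable sigmoid / SiLU activations.
#' Sizes in this package are desk-scale, so convolution is implemented by
#' shift-and-add over kernel taps with a channel-mixing matrix product per
#' tap; no compiled code is required.
#' @name tensor-ops
NULL

#' Validate an NCHW array
#'
#' @param x object to check.
#' @param channels if non-NULL, required channel count.
#' @param what name used in error messages.
#' @return `x`, invisibly.
#' @keywords internal
check_nchw <- function(x, channels = NULL, what = "x") {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop(what, " must be a 4-D array (batch, channel, height, width)")
  if (!is.null(channels) && dim(x)[2L] != channels)
    stop(what, " has ", dim(x)[2L], " channels, expected ", channels)
  if (!all(is.finite(x)))
    stop(what, " contains non-finite values")
  invisible(x)
}

#' Pad an NCHW array spatially
#'
#' @param x NCHW array.
#' @param ph,pw padding rows / columns added on each side.
#' @param mode "zero" or "replicate" (edge values repeated).
#' @return padded array.
#' @keywords internal
pad_nchw <- function(x, ph, pw, mode = c("zero", "replicate")) {
  mode <- match.arg(mode)
  if (ph == 0L && pw == 0L) return(x)
  d <- dim(x)
  if (mode == "replicate") {
    ri <- pmin(pmax(seq_len(d[3L] + 2L * ph) - ph, 1L), d[3L])
    ci <- pmin(pmax(seq_len(d[4L] + 2L * pw) - pw, 1L), d[4L])
    return(x[, , ri, ci, drop = FALSE])
  }
  out <- array(0, c(d[1L], d[2L], d[3L] + 2L * ph, d[4L] + 2L * pw))
  out[, , ph + seq_len(d[3L]), pw + seq_len(d[4L])] <- x
  out
}

#' 2-D convolution on NCHW arrays
#'
#' Cross-correlation (framework convention) with optional stride, dilation
#' and channel groups. "Same" padding keeps the spatial size when
#' `stride = 1` and the kernel is odd; symmetric zero padding of
#' `dilation * (k - 1) / 2` is applied on each side.
#'
#' @param x NCHW input array.
#' @param w weight array (out_channels, in_channels / groups, kh, kw).
#' @param b bias vector of length out_channels, or NULL.
#' @param stride integer stride (same both directions).
#' @param dilation integer dilation rate.
#' @param groups channel groups; `groups = in_channels` gives a depthwise
#'   convolution.
#' @param pad "same", "valid", or an integer padding applied to both sides.
#' @return NCHW output array.
#' @export
conv2d <- function(x, w, b = NULL, stride = 1L, dilation = 1L,
                   groups = 1L, pad = "same") {
  d <- dim(x); dw <- dim(w)
  if (length(dw) != 4L) stop("w must be a 4-D array (Cout, Cin/groups, kh, kw)")
  n <- d[1L]; cin <- d[2L]; h <- d[3L]; wd <- d[4L]
  cout <- dw[1L]; kh <- dw[3L]; kw <- dw[4L]
  if (cin %% groups != 0L || cout %% groups != 0L)
    stop("channel counts must be divisible by groups")
  if (dw[2L] != cin %/% groups)
    stop("w in-channel dim ", dw[2L], " does not match input channels ",
         cin, " / groups ", groups)
  if (identical(pad, "same")) {
    if (kh %% 2L == 0L || kw %% 2L == 0L)
      stop("'same' padding requires odd kernels")
    ph <- dilation * (kh - 1L) %/% 2L
    pw <- dilation * (kw - 1L) %/% 2L
  } else if (identical(pad, "valid")) {
    ph <- 0L; pw <- 0L
  } else {
    ph <- as.integer(pad); pw <- as.integer(pad)
  }
  xp <- pad_nchw(x, ph, pw)
  hp <- h + 2L * ph; wp <- wd + 2L * pw
  span_h <- dilation * (kh - 1L) + 1L
  span_w <- dilation * (kw - 1L) + 1L
  ho <- (hp - span_h) %/% stride + 1L
  wo <- (wp - span_w) %/% stride + 1L
  if (ho < 1L || wo < 1L) stop("kernel larger than padded input")
  oi <- seq.int(1L, by = stride, length.out = ho)
  oj <- seq.int(1L, by = stride, length.out = wo)

  if (groups > 1L && !(groups == cin && cout == cin)) {
    # general grouped conv: recurse per group on channel slices
    gc_in <- cin %/% groups; gc_out <- cout %/% groups
    out <- array(0, c(n, cout, ho, wo))
    for (g in seq_len(groups)) {
      xi <- (g - 1L) * gc_in + seq_len(gc_in)
      ci <- (g - 1L) * gc_out + seq_len(gc_out)
      out[, ci, , ] <- conv2d(xp[, xi, , , drop = FALSE],
                              w[ci, , , , drop = FALSE],
                              b = NULL, stride = stride,
                              dilation = dilation, groups = 1L, pad = "valid")
    }
  } else if (groups == cin && cout == cin && cin > 1L) {
    # depthwise: per-channel scalar taps
    out <- array(0, c(n, cout, ho, wo))
    for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
      ri <- oi + (ki - 1L) * dilation
      cj <- oj + (kj - 1L) * dilation
      xs <- xp[, , ri, cj, drop = FALSE]
      wt <- w[, 1L, ki, kj]                       # length cout == cin
      out <- out + xs * rep(wt, each = n)
    }
  } else {
    out <- array(0, c(n, cout, ho, wo))
    for (ki in seq_len(kh)) for (kj in seq_len(kw)) {
      wt <- matrix(w[, , ki, kj], nrow = cout)    # (Cout, Cin)
      if (all(wt == 0)) next
      ri <- oi + (ki - 1L) * dilation
      cj <- oj + (kj - 1L) * dilation
      xs <- xp[, , ri, cj, drop = FALSE]
      m <- matrix(aperm(xs, c(2L, 1L, 3L, 4L)), nrow = cin)
      o <- wt %*% m
      out <- out + aperm(array(o, c(cout, n, ho, wo)), c(2L, 1L, 3L, 4L))
    }
  }
  if (!is.null(b)) out <- out + rep(b, each = n)
  out
}

#' Stride-1 max pooling with replicate padding
#'
#' @param x NCHW array.
#' @param k odd window size >= 3.
#' @return array of the same shape.
#' @export
maxpool2d <- function(x, k = 3L) {
  if (k %% 2L == 0L || k < 3L) stop("window size must be odd and >= 3")
  p <- (k - 1L) %/% 2L
  xp <- pad_nchw(x, p, p, mode = "replicate")
  d <- dim(x)
  out <- array(-Inf, d)
  for (ki in seq_len(k)) for (kj in seq_len(k)) {
    out <- pmax(out, xp[, , (ki - 1L) + seq_len(d[3L]),
                        (kj - 1L) + seq_len(d[4L]), drop = FALSE])
  }
  out
}

#' Nearest-neighbour 2x spatial upsampling
#' @param x NCHW array.
#' @return array with doubled height and width.
#' @export
upsample2x <- function(x) {
  d <- dim(x)
  x[, , rep(seq_len(d[3L]), each = 2L), rep(seq_len(d[4L]), each = 2L),
    drop = FALSE]
}

#' Adaptive average pooling to a target spatial size
#'
#' Each output cell averages the input window `[floor((i-1) H / oh),
#' ceil(i H / oh))`, matching the framework convention.
#'
#' @param x NCHW array.
#' @param oh,ow output height and width.
#' @return NCHW array with spatial size (oh, ow).
#' @export
adaptive_avg_pool <- function(x, oh, ow) {
  d <- dim(x)
  out <- array(0, c(d[1L], d[2L], oh, ow))
  hs <- floor((seq_len(oh) - 1L) * d[3L] / oh) + 1L
  he <- ceiling(seq_len(oh) * d[3L] / oh)
  ws <- floor((seq_len(ow) - 1L) * d[4L] / ow) + 1L
  we <- ceiling(seq_len(ow) * d[4L] / ow)
  for (i in seq_len(oh)) for (j in seq_len(ow)) {
    blk <- x[, , hs[i]:he[i], ws[j]:we[j], drop = FALSE]
    out[, , i, j] <- apply(blk, c(1L, 2L), mean)
  }
  out
}

#' Numerically stable logistic function
#' @param x numeric.
#' @return `1 / (1 + exp(-x))`, computed without overflow.
#' @export
sigmoid <- function(x) {
  out <- x
  pos <- !is.na(x) & x >= 0
  out[pos] <- 1 / (1 + exp(-x[pos]))
  ex <- exp(x[!pos])
  out[!pos] <- ex / (1 + ex)
  out
}

#' SiLU (swish) activation
#' @param x numeric.
#' @return `x * sigmoid(x)`.
#' @export
silu <- function(x) x * sigmoid(x)
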