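#' @title Multi-scale feature pyramid network (MSFPN)
#' @description
#' A detection neck that fuses a three-level feature pyramid (strides 8,
#' 16, 32) through two rounds of multi-scale focusing (MSF) and a context
#' diffusion stage.
#'
#' The MSF block aligns the three levels at the middle resolution —
#' high level upsampled then 1x1-convolved, middle level 1x1-convolved,
#' low level adaptively average-pooled then 1x1-convolved — concatenates
#' them into a fused map `F`, extracts multi-scale context with four
#' parallel depthwise convolutions of kernel sizes 5, 7, 9 and 11 summed
#' into `D`, and returns the residual `F' = F + Conv1x1(D)`.
#'
#' The full neck runs MSF once on the input pyramid, spreads its output
#' up (2x nearest upsample) and down (stride-2 3x3 convolution), fuses
#' with the low and high input levels through channel-harmonizing 1x1
#' convolutions and RepC3 blocks, runs a second MSF on the fused pyramid,
#' and finally diffuses both rounds' context into the low and high
#' detection scales. All blocks here are linear maps (convolutions,
#' pooling, upsampling) so that reparameterized inference forms are exact
#' and residual identities hold with zero weights.
#' @name msfpn
NULL

check_pyramid <- function(levels) {
  if (!all(c("low", "mid", "high") %in% names(levels)))
    stop("pyramid must have elements 'low', 'mid', 'high'")
  dl <- dim(levels$low); dm <- dim(levels$mid); dh <- dim(levels$high)
  for (nm in c("low", "mid", "high")) check_nchw(levels[[nm]], what = nm)
  if (!all(dl[3:4] == 2L * dm[3:4]) || !all(dm[3:4] == 2L * dh[3:4]))
    stop("pyramid levels misaligned: spatial sizes must halve ",
         "level-to-level (got ", paste(dl[3:4], collapse = "x"), ", ",
         paste(dm[3:4], collapse = "x"), ", ",
         paste(dh[3:4], collapse = "x"), ")")
  invisible(levels)
}

#' Construct a multi-scale focusing (MSF) block
#'
#' @param width common channel width of the three input levels.
#' @param kernel_set kernel sizes of the parallel depthwise convolutions
#'   (default `c(5, 7, 9, 11)`).
#' @param init weight initialization.
#' @return an object of class `msf_msf`. Its output has `3 * width`
#'   channels at the middle level's resolution.
#' @export
new_msf <- function(width, kernel_set = c(5L, 7L, 9L, 11L), init = "xavier") {
  cf <- 3L * width
  structure(list(
    width = as.integer(width), cf = cf,
    kernel_set = as.integer(kernel_set),
    high_conv = conv_layer(width, width, 1L, bias = FALSE, init = init),
    mid_conv = conv_layer(width, width, 1L, bias = FALSE, init = init),
    low_conv = conv_layer(width, width, 1L, bias = FALSE, init = init),
    dw_convs = lapply(kernel_set, function(k)
      conv_layer(cf, cf, k, groups = cf, bias = FALSE, init = init)),
    pw_conv = conv_layer(cf, cf, 1L, bias = FALSE, init = init)
  ), class = "msf_msf")
}

#' Concatenated multi-scale map of an MSF block
#'
#' The pre-focusing fused map `F`: channel concatenation of the aligned,
#' projected high, middle and low levels at the middle resolution.
#'
#' @param levels list with NCHW arrays `low`, `mid`, `high` (strides
#'   8 / 16 / 32; spatial sizes halving level-to-level).
#' @param msf an `msf_msf` block.
#' @return NCHW array with `3 * width` channels.
#' @export
msf_concat <- function(levels, msf) {
  check_pyramid(levels)
  dm <- dim(levels$mid)
  xh <- forward(msf$high_conv, upsample2x(levels$high))
  xm <- forward(msf$mid_conv, levels$mid)
  xl <- forward(msf$low_conv,
                adaptive_avg_pool(levels$low, dm[3L], dm[4L]))
  abind_ch(xh, xm, xl)
}

# concatenate NCHW arrays along the channel dimension
abind_ch <- function(...) {
  xs <- list(...)
  d1 <- dim(xs[[1L]])
  for (x in xs)
    if (!all(dim(x)[c(1L, 3L, 4L)] == d1[c(1L, 3L, 4L)]))
      stop("channel concatenation requires equal batch and spatial sizes ",
           "(got ", paste(vapply(xs, function(z)
             paste(dim(z), collapse = "x"), character(1)), collapse = " vs "),
           ")")
  ch <- sum(vapply(xs, function(x) dim(x)[2L], numeric(1)))
  out <- array(0, c(d1[1L], ch, d1[3L], d1[4L]))
  at <- 0L
  for (x in xs) {
    cx <- dim(x)[2L]
    out[, at + seq_len(cx), , ] <- x
    at <- at + cx
  }
  out
}

#' MSF forward pass
#'
#' `F' = F + Conv1x1( sum_k DWConv_k(F) )` with `k in kernel_set`.
#'
#' @inheritParams msf_concat
#' @return NCHW array at the middle resolution, `3 * width` channels.
#' @export
msf_forward <- function(levels, msf) {
  f <- msf_concat(levels, msf)
  d <- NULL
  for (cv in msf$dw_convs) {
    y <- forward(cv, f)
    d <- if (is.null(d)) y else d + y
  }
  f + forward(msf$pw_conv, d)
}

#' @export
forward.msf_msf <- function(object, x, ...) msf_forward(x, object)

#' Construct a RepC3 fusion block
#'
#' Channel-preserving residual block with a 3x3 and a 1x1 convolution in
#' parallel (each with its own normalization) plus the identity:
#' `y = x + norm3(conv3(x)) + norm1(conv1(x))`. Mergeable into a single
#' 3x3 convolution with [repc3_merge()].
#'
#' @param channels channel count.
#' @param init weight initialization.
#' @return an object of class `msf_repc3`.
#' @export
new_repc3 <- function(channels, init = "xavier") {
  structure(list(
    channels = as.integer(channels),
    conv3 = conv_layer(channels, channels, 3L, bias = FALSE, init = init),
    norm3 = norm_layer(channels),
    conv1 = conv_layer(channels, channels, 1L, bias = FALSE, init = init),
    norm1 = norm_layer(channels)
  ), class = "msf_repc3")
}

#' @describeIn new_repc3 forward pass (training form).
#' @param x NCHW input.
#' @export
repc3_forward <- function(x, block) {
  check_nchw(x, channels = block$channels, what = "RepC3 input")
  x + forward(block$norm3, forward(block$conv3, x)) +
    forward(block$norm1, forward(block$conv1, x))
}

#' @export
forward.msf_repc3 <- function(object, x, ...) repc3_forward(x, object)

#' Merge a RepC3 block into one 3x3 convolution
#'
#' Folds both normalizations into their convolutions, zero-pads the 1x1
#' kernel to 3x3, and adds an identity kernel, so that
#' `conv2d(x, w, b)` equals [repc3_forward()] exactly.
#'
#' @param block an `msf_repc3`.
#' @return list with `w` and `b`.
#' @export
repc3_merge <- function(block) {
  ch <- block$channels
  f3 <- fold_norm(block$conv3, block$norm3)
  f1 <- fold_norm(block$conv1, block$norm1)
  w <- f3$w
  w[, , 2L, 2L] <- w[, , 2L, 2L] + f1$w[, , 1L, 1L] + diag(ch)
  list(w = w, b = f3$b + f1$b)
}

#' Construct the MSFPN neck
#'
#' @param in_channels integer vector of the three input channel counts
#'   (strides 8, 16, 32).
#' @param width common working channel width after lateral projection
#'   (default 256).
#' @param kernel_set MSF depthwise kernel sizes (default `c(5, 7, 9, 11)`).
#' @param eq4_literal if TRUE, the first high-level fusion concatenates
#'   the (downsampled) low-level lateral instead of the high-level
#'   lateral. This reproduces a literal reading of the published wiring;
#'   the default follows the accompanying description, which fuses the
#'   strided context with the high level.
#' @param init weight initialization.
#' @return an object of class `msf_msfpn`.
#' @export
new_msfpn <- function(in_channels, width = 256L,
                      kernel_set = c(5L, 7L, 9L, 11L),
                      eq4_literal = FALSE, init = "xavier") {
  stopifnot(length(in_channels) == 3L)
  w <- as.integer(width)
  structure(list(
    width = w, eq4_literal = isTRUE(eq4_literal),
    lat_low = conv_layer(in_channels[1L], w, 1L, bias = FALSE, init = init),
    lat_mid = conv_layer(in_channels[2L], w, 1L, bias = FALSE, init = init),
    lat_high = conv_layer(in_channels[3L], w, 1L, bias = FALSE, init = init),
    msf1 = new_msf(w, kernel_set, init = init),
    msf1_red = conv_layer(3L * w, w, 1L, bias = FALSE, init = init),
    down1 = conv_layer(w, w, 3L, stride = 2L, bias = FALSE, init = init),
    low_fuse = conv_layer(2L * w, w, 1L, bias = FALSE, init = init),
    high_fuse = conv_layer(2L * w, w, 1L, bias = FALSE, init = init),
    repc3_low = new_repc3(w, init = init),
    repc3_high = new_repc3(w, init = init),
    msf2 = new_msf(w, kernel_set, init = init),
    msf2_red = conv_layer(3L * w, w, 1L, bias = FALSE, init = init),
    down2 = conv_layer(w, w, 3L, stride = 2L, bias = FALSE, init = init),
    out_low = conv_layer(2L * w, w, 1L, bias = FALSE, init = init),
    out_high = conv_layer(2L * w, w, 1L, bias = FALSE, init = init)
  ), class = "msf_msfpn")
}

#' Round-1 fusion of the MSFPN (internal ablation surface)
#'
#' Runs the lateral projections, the first MSF, and the two RepC3 fusion
#' paths, returning every intermediate used by the second round and the
#' diffusion stage. Exposed so ablation tests can compare the full neck
#' against round 1 alone.
#'
#' @param levels list with NCHW arrays `low`, `mid`, `high`.
#' @param neck an `msf_msfpn`.
#' @return list with elements `low_lat`, `mid_lat`, `high_lat`, `m1`
#'   (reduced MSF-1 output), `xup`, `xc`, `xrl` (RepC3-processed low
#'   fusion), `xrh` (RepC3-processed high fusion).
#' @export
msfpn_round1 <- function(levels, neck) {
  check_pyramid(levels)
  low <- forward(neck$lat_low, levels$low)
  mid <- forward(neck$lat_mid, levels$mid)
  high <- forward(neck$lat_high, levels$high)
  m1 <- forward(neck$msf1_red,
                msf_forward(list(low = low, mid = mid, high = high),
                            neck$msf1))
  xup <- upsample2x(m1)
  xc <- forward(neck$down1, m1)
  xrl <- repc3_forward(forward(neck$low_fuse, abind_ch(low, xup)),
                       neck$repc3_low)
  high_in <- if (neck$eq4_literal) {
    dh <- dim(high)
    adaptive_avg_pool(low, dh[3L], dh[4L])
  } else high
  xrh <- repc3_forward(forward(neck$high_fuse, abind_ch(high_in, xc)),
                       neck$repc3_high)
  list(low_lat = low, mid_lat = mid, high_lat = high,
       m1 = m1, xup = xup, xc = xc, xrl = xrl, xrh = xrh)
}

#' MSFPN forward pass
#'
#' Two focusing rounds plus context diffusion. Round 1 focuses the input
#' pyramid and fuses the result into the low and high levels (RepC3
#' blocks). Round 2 focuses the fused pyramid (`xrl`, round-1 middle,
#' `xrh`) and is spread again by upsampling (`xup2`) and strided
#' convolution (`xc2`). The final low scale fuses `xrl` with both
#' upsampled context maps, the final high scale fuses `xrh` with both
#' strided context maps (in each case the concatenated context passes a
#' 1x1 channel-harmonizing convolution and is added residually), and the
#' middle scale is the reduced round-2 focusing output. Every
#' concatenation asserts exact spatial alignment.
#'
#' @inheritParams msfpn_round1
#' @return list of three NCHW arrays `low`, `mid`, `high` at strides
#'   8 / 16 / 32, each with `width` channels.
#' @export
msfpn_forward <- function(levels, neck) {
  r1 <- msfpn_round1(levels, neck)
  m2 <- forward(neck$msf2_red,
                msf_forward(list(low = r1$xrl, mid = r1$m1, high = r1$xrh),
                            neck$msf2))
  xup2 <- upsample2x(m2)
  xc2 <- forward(neck$down2, m2)
  # residual diffusion: the harmonizing conv mixes the two context maps
  # and adds them onto the round-1 fusion, so silencing the diffusion
  # weights recovers the round-1 RepC3 outputs exactly
  out_low <- r1$xrl + forward(neck$out_low, abind_ch(xup2, r1$xup))
  out_high <- r1$xrh + forward(neck$out_high, abind_ch(xc2, r1$xc))
  list(low = out_low, mid = m2, high = out_high)
}

#' @export
forward.msf_msfpn <- function(object, x, ...) msfpn_forward(x, object)
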