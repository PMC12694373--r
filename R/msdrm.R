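#' @title Multi-scale dilation residual blocks
#' @description
#' Backbone blocks for multi-scale context extraction on leaf imagery:
#'
#' * the dilation-wise residual block (DWR) — a regional-residualization
#'   stage (3x3 conv, norm, SiLU) followed by a semantic stage of parallel
#'   depthwise dilated convolutions whose fused output is added back to
#'   the input;
#' * the dilated reparam block (DRB) — a large-kernel convolution in
#'   parallel with several dilated small-kernel convolutions, each with
#'   its own normalization, mergeable at inference into one equivalent
#'   large kernel ([drb_merge()]);
#' * the combined MSDRM — regional residualization, a plain 3x3 path plus
#'   DRB sub-modules on the regional features, a morphological
#'   (max-pool minus min-pool) pre-fusion path that preserves lesion edge
#'   continuity, a shared normalization over the fused sum, and an input
#'   residual. Output channels equal input channels so the block is a
#'   drop-in replacement for a standard residual block.
#' @name msdrm
NULL

#' Specification of a dilated reparam block
#'
#' @param large_kernel odd kernel size of the large branch (default 7).
#' @param small_branches list of `c(kernel, dilation)` pairs for the small
#'   branches (default `(3,1), (3,2), (3,3)`). Each branch's effective
#'   receptive field `(kernel - 1) * dilation + 1` must not exceed
#'   `large_kernel`, which is what makes lossless merging possible.
#' @param channels channel count.
#' @param depthwise use depthwise convolutions (default TRUE).
#' @return a `drb_spec` object.
#' @export
drb_spec <- function(large_kernel = 7L,
                     small_branches = list(c(3L, 1L), c(3L, 2L), c(3L, 3L)),
                     channels = 64L, depthwise = TRUE) {
  stopifnot(large_kernel %% 2L == 1L, large_kernel >= 3L, channels >= 1L)
  for (br in small_branches) {
    k <- br[[1L]]; d <- br[[2L]]
    if (k %% 2L != 1L) stop("small-branch kernels must be odd")
    if ((k - 1L) * d + 1L > large_kernel)
      stop("branch receptive field (", (k - 1L) * d + 1L,
           ") exceeds the large kernel (", large_kernel, ")")
  }
  structure(list(large_kernel = as.integer(large_kernel),
                 small_branches = small_branches,
                 channels = as.integer(channels),
                 depthwise = isTRUE(depthwise)),
            class = "drb_spec")
}

#' Construct a dilated reparam block
#'
#' @param spec a [drb_spec()].
#' @param init weight initialization, "he" or "zero".
#' @return an object of class `msf_drb` holding one conv + norm pair per
#'   branch.
#' @export
new_drb <- function(spec, init = "xavier") {
  g <- if (spec$depthwise) spec$channels else 1L
  mk <- function(k, d) {
    list(conv = conv_layer(spec$channels, spec$channels, k, dilation = d,
                           groups = g, bias = FALSE, init = init),
         norm = norm_layer(spec$channels))
  }
  branches <- c(list(mk(spec$large_kernel, 1L)),
                lapply(spec$small_branches, function(br) mk(br[[1L]], br[[2L]])))
  structure(list(spec = spec, branches = branches), class = "msf_drb")
}

#' @describeIn new_drb forward pass: sum of the normalized branch outputs.
#' @param x NCHW input.
#' @export
drb_forward <- function(x, drb) {
  check_nchw(x, channels = drb$spec$channels, what = "DRB input")
  out <- NULL
  for (br in drb$branches) {
    y <- forward(br$norm, forward(br$conv, x))
    out <- if (is.null(out)) y else out + y
  }
  out
}

#' @export
forward.msf_drb <- function(object, x, ...) drb_forward(x, object)

#' Expand a dilated kernel to its dense equivalent
#'
#' Inserts `dilation - 1` zeros between kernel entries, giving the dense
#' kernel with identical output: e.g. `c(1, 2, 3)` at dilation 2 expands
#' to `c(1, 0, 2, 0, 3)`.
#'
#' @param k numeric vector or matrix (a 1-D or 2-D kernel).
#' @param dilation integer dilation rate.
#' @return the expanded vector or matrix.
#' @export
dilate_kernel <- function(k, dilation) {
  if (dilation == 1L) return(k)
  if (is.matrix(k)) {
    n <- nrow(k); m <- ncol(k)
    out <- matrix(0, (n - 1L) * dilation + 1L, (m - 1L) * dilation + 1L)
    out[seq(1L, by = dilation, length.out = n),
        seq(1L, by = dilation, length.out = m)] <- k
    return(out)
  }
  n <- length(k)
  out <- numeric((n - 1L) * dilation + 1L)
  out[seq(1L, by = dilation, length.out = n)] <- k
  out
}

#' Merge a dilated reparam block into a single convolution
#'
#' Folds each branch's (frozen) normalization into its convolution
#' weights, expands every dilated small kernel to its sparse large-kernel
#' equivalent, centers it inside the large kernel, and sums all branches.
#' The returned single convolution reproduces the parallel-branch forward
#' exactly (up to floating-point error).
#'
#' @param drb an `msf_drb` block.
#' @return list with `w` (large_kernel weights), `b` (bias), `groups`,
#'   usable directly with [conv2d()].
#' @export
drb_merge <- function(drb) {
  spec <- drb$spec
  kl <- spec$large_kernel
  g <- if (spec$depthwise) spec$channels else 1L
  cin_g <- spec$channels %/% g
  wm <- array(0, c(spec$channels, cin_g, kl, kl))
  bm <- numeric(spec$channels)
  for (br in drb$branches) {
    f <- fold_norm(br$conv, br$norm)
    k <- dim(f$w)[3L]; d <- br$conv$dilation
    ke <- (k - 1L) * d + 1L
    off <- (kl - ke) %/% 2L
    for (co in seq_len(dim(f$w)[1L])) for (ci in seq_len(cin_g)) {
      wm[co, ci, , ] <- wm[co, ci, , ] +
        pad_center(dilate_kernel(matrix(f$w[co, ci, , ], k, k), d), kl, off)
    }
    bm <- bm + f$b
  }
  list(w = wm, b = bm, groups = g)
}

# place a small (ke x ke) matrix at offset `off` inside a kl x kl zero matrix
pad_center <- function(m, kl, off) {
  out <- matrix(0, kl, kl)
  out[off + seq_len(nrow(m)), off + seq_len(ncol(m))] <- m
  out
}

#' Forward pass through a merged DRB
#' @param x NCHW input.
#' @param merged result of [drb_merge()].
#' @return NCHW output identical to [drb_forward()] on the source block.
#' @export
drb_merged_forward <- function(x, merged) {
  conv2d(x, merged$w, merged$b, groups = merged$groups, pad = "same")
}

#' Construct a dilation-wise residual (DWR) block
#'
#' @param channels channel count.
#' @param dilations dilation rates of the semantic-stage paths
#'   (default `c(1, 3, 5)`).
#' @param init weight initialization.
#' @return an object of class `msf_dwr`.
#' @export
new_dwr <- function(channels, dilations = c(1L, 3L, 5L), init = "xavier") {
  structure(list(
    channels = as.integer(channels),
    dilations = as.integer(dilations),
    region_conv = conv_layer(channels, channels, 3L, init = init),
    region_norm = norm_layer(channels),
    paths = lapply(dilations, function(d)
      list(conv = conv_layer(channels, channels, 3L, dilation = d,
                             groups = channels, bias = FALSE, init = init),
           norm = norm_layer(channels))),
    fuse_conv = conv_layer(channels, channels, 1L, init = init)
  ), class = "msf_dwr")
}

#' @describeIn new_dwr forward pass: regional residualization (3x3 conv,
#'   norm, SiLU), parallel depthwise dilated convolutions, fused sum,
#'   SiLU, pointwise fusion conv, plus the input residual.
#' @param x NCHW input.
#' @export
dwr_forward <- function(x, dwr) {
  check_nchw(x, channels = dwr$channels, what = "DWR input")
  r <- silu(forward(dwr$region_norm, forward(dwr$region_conv, x)))
  s <- NULL
  for (p in dwr$paths) {
    y <- forward(p$norm, forward(p$conv, r))
    s <- if (is.null(s)) y else s + y
  }
  x + forward(dwr$fuse_conv, silu(s))
}

#' @export
forward.msf_dwr <- function(object, x, ...) dwr_forward(x, object)

#' Morphological gradient filter (max pool minus min pool)
#'
#' `MaxPool(x) - MinPool(x)` with stride 1 and replicate padding, where
#' `MinPool(x) = -MaxPool(-x)`. Zero on constant regions, non-negative
#' everywhere, and invariant to adding a constant — a local edge detector
#' used to preserve lesion boundary continuity before path fusion.
#'
#' @param x NCHW array.
#' @param k odd window size >= 3 (default 3).
#' @return NCHW array of the same shape, >= 0.
#' @export
maxmin_filter <- function(x, k = 3L) {
  if (k %% 2L == 0L) stop("window size must be odd")
  maxpool2d(x, k) + maxpool2d(-x, k)
}

#' Construct a multi-scale dilation residual module (MSDRM)
#'
#' Regional residualization (3x3 conv, norm, SiLU) followed by parallel
#' paths on the regional features: one plain 3x3 depthwise convolution
#' (dilation 1) for fine local detail, `n_drb` dilated reparam
#' sub-modules, and a morphological max-minus-min filter path. The paths
#' are summed, passed through a shared normalization and SiLU, mixed by a
#' pointwise convolution, and added to the input residual.
#'
#' @param channels channel count (output equals input).
#' @param n_drb number of DRB sub-modules (default 2).
#' @param drb_large_kernel large kernel of each DRB (default 7).
#' @param morph_k window of the morphological filter (default 3).
#' @param init weight initialization.
#' @return an object of class `msf_msdrm`.
#' @export
new_msdrm <- function(channels, n_drb = 2L, drb_large_kernel = 7L,
                      morph_k = 3L, init = "xavier") {
  structure(list(
    channels = as.integer(channels),
    morph_k = as.integer(morph_k),
    region_conv = conv_layer(channels, channels, 3L, init = init),
    region_norm = norm_layer(channels),
    path1 = conv_layer(channels, channels, 3L, groups = channels,
                       bias = FALSE, init = init),
    drbs = lapply(seq_len(n_drb), function(i)
      new_drb(drb_spec(large_kernel = drb_large_kernel, channels = channels),
              init = init)),
    shared_norm = norm_layer(channels),
    fuse_conv = conv_layer(channels, channels, 1L, init = init)
  ), class = "msf_msdrm")
}

#' @describeIn new_msdrm forward pass.
#' @param x NCHW input.
#' @export
msdrm_forward <- function(x, block) {
  check_nchw(x, channels = block$channels, what = "MSDRM input")
  r <- silu(forward(block$region_norm, forward(block$region_conv, x)))
  s <- forward(block$path1, r) + maxmin_filter(r, block$morph_k)
  for (drb in block$drbs) s <- s + drb_forward(r, drb)
  x + forward(block$fuse_conv, silu(forward(block$shared_norm, s)))
}

#' @export
forward.msf_msdrm <- function(object, x, ...) msdrm_forward(x, object)
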