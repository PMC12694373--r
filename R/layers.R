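#' @title Layer objects
#' @description
#' Lightweight S3 layer objects (weights stored as plain arrays) used to
#' assemble the detection blocks. Layers are constructed with seeded He
#' initialization using the caller's RNG state, or with all-zero weights
#' for identity / ablation tests. Normalization layers carry frozen
#' per-channel statistics plus an affine transform; with the default
#' statistics (mean 0, variance 1, gamma 1, beta 0) they are the identity,
#' which is the behaviour required for structural identity checks and for
#' kernel merging.
#' @name layers
NULL

#' Create a convolution layer
#'
#' @param in_ch,out_ch channel counts.
#' @param k odd kernel size.
#' @param stride,dilation,groups convolution geometry (see [conv2d()]).
#' @param bias include a bias vector.
#' @param init "he" (Kaiming normal, for layers followed by a
#'   rectifier-family activation), "xavier" (unit-gain normal, for linear
#'   layers), or "zero"; random inits use the current RNG.
#' @param pad padding rule passed to [conv2d()].
#' @return an object of class `msf_conv`.
#' @export
conv_layer <- function(in_ch, out_ch, k, stride = 1L, dilation = 1L,
                       groups = 1L, bias = TRUE,
                       init = c("he", "xavier", "zero"),
                       pad = "same") {
  init <- match.arg(init)
  cin_g <- in_ch %/% groups
  w <- if (init == "zero") {
    array(0, c(out_ch, cin_g, k, k))
  } else {
    gain <- if (init == "he") 2 else 1
    array(stats::rnorm(out_ch * cin_g * k * k,
                       sd = sqrt(gain / (cin_g * k * k))),
          c(out_ch, cin_g, k, k))
  }
  structure(list(w = w, b = if (bias) numeric(out_ch) else NULL,
                 stride = as.integer(stride), dilation = as.integer(dilation),
                 groups = as.integer(groups), pad = pad,
                 in_ch = as.integer(in_ch), out_ch = as.integer(out_ch)),
            class = "msf_conv")
}

#' Create a normalization layer
#'
#' Per-channel standardization with frozen statistics and an affine
#' transform, i.e. inference-mode batch normalization. Defaults make the
#' layer the identity.
#'
#' @param ch channel count.
#' @param eps variance floor.
#' @return an object of class `msf_norm`.
#' @export
norm_layer <- function(ch, eps = 1e-5) {
  structure(list(gamma = rep(1, ch), beta = numeric(ch),
                 mean = numeric(ch), var = rep(1, ch), eps = eps,
                 ch = as.integer(ch)),
            class = "msf_norm")
}

#' Set normalization statistics (for tests and merge checks)
#' @param nl an `msf_norm` layer.
#' @param mean,var,gamma,beta per-channel vectors.
#' @return the updated layer.
#' @export
set_norm_stats <- function(nl, mean = NULL, var = NULL,
                           gamma = NULL, beta = NULL) {
  if (!is.null(mean)) nl$mean <- mean
  if (!is.null(var)) nl$var <- var
  if (!is.null(gamma)) nl$gamma <- gamma
  if (!is.null(beta)) nl$beta <- beta
  nl
}

#' Forward pass through a layer or block
#' @param object a layer or block object.
#' @param x NCHW input array.
#' @param ... passed to methods.
#' @return NCHW output array.
#' @export
forward <- function(object, x, ...) UseMethod("forward")

#' @export
forward.msf_conv <- function(object, x, ...) {
  check_nchw(x, channels = object$in_ch, what = "conv input")
  conv2d(x, object$w, object$b, stride = object$stride,
         dilation = object$dilation, groups = object$groups,
         pad = object$pad)
}

#' @export
forward.msf_norm <- function(object, x, ...) {
  check_nchw(x, channels = object$ch, what = "norm input")
  n <- dim(x)[1L]
  scale <- object$gamma / sqrt(object$var + object$eps)
  shift <- object$beta - object$mean * scale
  x * rep(scale, each = n) + rep(shift, each = n)
}

#' Fold a normalization layer into convolution weights
#'
#' Returns `(w, b)` such that `conv(x, w, b)` equals
#' `norm(conv(x, w0, b0))` — the standard inference-time fusion used in
#' structural reparameterization.
#'
#' @param cl an `msf_conv` layer.
#' @param nl an `msf_norm` layer matching the conv's output channels.
#' @return list with elements `w` and `b`.
#' @keywords internal
fold_norm <- function(cl, nl) {
  scale <- nl$gamma / sqrt(nl$var + nl$eps)
  w <- cl$w * scale             # scale varies along dim 1 (out channel)
  b0 <- if (is.null(cl$b)) numeric(cl$out_ch) else cl$b
  b <- (b0 - nl$mean) * scale + nl$beta
  list(w = w, b = b)
}

#' Count learnable parameters
#'
#' Recursively sums the sizes of weight, bias and affine arrays in a layer
#' or block tree.
#'
#' @param object a layer, block, or list of them.
#' @return integer parameter count.
#' @export
count_params <- function(object) {
  if (inherits(object, "msf_conv"))
    return(length(object$w) + length(object$b))
  if (inherits(object, "msf_norm"))
    return(length(object$gamma) + length(object$beta))
  if (is.list(object)) return(sum(vapply(object, count_params, numeric(1))))
  0L
}

#' Set every learnable weight in a block tree to zero
#'
#' Used by residual-identity tests: with all weights (and normalization
#' offsets) zero, residual blocks must reduce to the identity map.
#'
#' @param object a layer, block, or list of them.
#' @return the zeroed object.
#' @export
zero_weights <- function(object) {
  if (inherits(object, "msf_conv")) {
    object$w[] <- 0
    if (!is.null(object$b)) object$b[] <- 0
    return(object)
  }
  if (inherits(object, "msf_norm")) {
    object$beta[] <- 0
    object$mean[] <- 0
    return(object)
  }
  if (is.list(object)) {
    cls <- class(object)
    object <- lapply(object, zero_weights)
    class(object) <- cls
    return(object)
  }
  object
}
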