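# dilation residual blocks: identities, oracles, reparameterization

test_that("DWR preserves shape and reduces to identity at zero weights", {
  set.seed(21)
  x <- rand_nchw(2, 8, 12, 12)
  dwr <- new_dwr(8)
  expect_equal(dim(dwr_forward(x, dwr)), dim(x))
  expect_equal(dwr_forward(x, zero_weights(dwr)), x)
  expect_error(dwr_forward(rand_nchw(1, 4, 8, 8), dwr), "channels")
})

test_that("single-path DWR equals its straight-line composition", {
  set.seed(22)
  x <- rand_nchw(1, 6, 10, 10)
  dwr <- new_dwr(6, dilations = 1L)
  # straight-line oracle recomposed from the block's own layers
  r <- silu(forward(dwr$region_norm, forward(dwr$region_conv, x)))
  p <- forward(dwr$paths[[1]]$norm, forward(dwr$paths[[1]]$conv, r))
  ref <- x + forward(dwr$fuse_conv, silu(p))
  expect_equal(dwr_forward(x, dwr), ref, tolerance = 1e-12)
})

test_that("DRB forward sums branches and respects footprints", {
  set.seed(23)
  sp <- drb_spec(channels = 5)
  drb <- new_drb(sp)
  # zero input, zero norm offsets -> zero output
  z <- array(0, c(1, 5, 9, 9))
  expect_equal(drb_forward(z, drb), z)
  # single small branch, kernel 3 dilation 1, dense: equals the direct
  # convolution computed by the sliding-window reference
  spd <- drb_spec(large_kernel = 3, small_branches = list(),
                  channels = 4, depthwise = FALSE)
  drb1 <- new_drb(spd)
  drb1$branches[[1]]$norm$eps <- 0       # exact identity normalization
  x <- rand_nchw(1, 4, 8, 8)
  expect_equal(drb_forward(x, drb1),
               conv2d_reference(x, drb1$branches[[1]]$conv$w),
               tolerance = 1e-10)
  # impulse response confined to the large-kernel footprint
  imp <- array(0, c(1, 5, 15, 15)); imp[1, 1, 8, 8] <- 1
  out <- drb_forward(imp, drb)
  nz <- which(out[1, 1, , ] != 0, arr.ind = TRUE)
  expect_true(all(abs(nz - 8) <= 3))              # 7x7 window around centre
  # invalid spec: receptive field beyond the large kernel
  expect_error(drb_spec(large_kernel = 5, small_branches = list(c(3, 3))),
               "exceeds")
})

test_that("dilated kernels expand to their sparse dense equivalents", {
  expect_equal(dilate_kernel(c(1, 2, 3), 2), c(1, 0, 2, 0, 3))
  expect_equal(dilate_kernel(matrix(1:4, 2), 3)[c(1, 4), c(1, 4)],
               matrix(1:4, 2))
  expect_equal(dilate_kernel(c(5), 4), 5)
})

test_that("merged DRB inference equals the parallel forward", {
  # fixed default spec with non-trivial frozen norm statistics,
  # 50 random inputs
  set.seed(24)
  drb <- randomize_drb_norms(new_drb(drb_spec(channels = 6)), seed = 24)
  merged <- drb_merge(drb)
  worst <- 0
  for (r in 1:50) {
    x <- rand_nchw(1, 6, 10, 10)
    y1 <- drb_forward(x, drb)
    y2 <- drb_merged_forward(x, merged)
    worst <- max(worst, max(abs(y1 - y2)) / max(abs(y1)))
  }
  expect_lt(worst, 1e-5)
  # property over sampled legal specs (depthwise and dense)
  for (case in 1:8) {
    set.seed(100 + case)
    kl <- sample(c(5L, 7L, 9L), 1)
    nb <- sample(0:3, 1)
    branches <- replicate(nb, {
      k <- 3L
      d <- sample(seq_len((kl - 1L) %/% (k - 1L)), 1)
      c(k, d)
    }, simplify = FALSE)
    spec <- drb_spec(kl, branches, channels = 4,
                     depthwise = case %% 2 == 0)
    drb <- randomize_drb_norms(new_drb(spec), seed = 200 + case)
    merged <- drb_merge(drb)
    x <- rand_nchw(2, 4, kl + 3, kl + 3)
    expect_equal(drb_merged_forward(x, merged), drb_forward(x, drb),
                 tolerance = 1e-8)
  }
  # single branch, dilation 1, identity norm: merged kernel is the
  # original zero-padded to the large size
  sp1 <- drb_spec(large_kernel = 7, small_branches = list(),
                  channels = 3)
  drb1 <- new_drb(sp1)
  drb1$branches[[1]]$norm$eps <- 0
  m1 <- drb_merge(drb1)
  expect_equal(m1$w, drb1$branches[[1]]$conv$w)
  sp2 <- drb_spec(large_kernel = 7, small_branches = list(c(3L, 1L)),
                  channels = 3)
  drb2 <- new_drb(sp2)
  drb2$branches[[1]]$conv$w[] <- 0                # silence the large branch
  drb2$branches[[2]]$norm$eps <- 0
  m2 <- drb_merge(drb2)
  expect_equal(m2$w[, , 3:5, 3:5, drop = FALSE],
               drb2$branches[[2]]$conv$w)
  expect_true(all(m2$w[, , 1, ] == 0) && all(m2$w[, , , 1] == 0))
})

test_that("max-minus-min filter detects edges and ignores levels", {
  # constant map -> zero
  expect_equal(maxmin_filter(array(5, c(1, 2, 6, 6))),
               array(0, c(1, 2, 6, 6)))
  # 1-D step response: nonzero exactly in the 2-wide band at the step
  x <- array(0, c(1, 1, 1, 6)); x[1, 1, 1, 4:6] <- 1
  expect_error(maxmin_filter(x, 4), "odd")
  out <- maxmin_filter(x, 3)
  expect_equal(as.numeric(out[1, 1, 1, ]), c(0, 0, 1, 1, 0, 0))
  # shift invariance and non-negativity
  y <- rand_nchw(1, 3, 8, 8, seed = 25)
  expect_equal(maxmin_filter(y + 17), maxmin_filter(y), tolerance = 1e-12)
  expect_true(all(maxmin_filter(y) >= 0))
  # translation equivariance in the interior
  yt <- y
  yt[1, , 2:8, ] <- y[1, , 1:7, ]                 # shift down one row
  a <- maxmin_filter(y)[1, , 3:6, 3:6]
  b <- maxmin_filter(yt)[1, , 4:7, 3:6]
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("MSDRM preserves shape, identity, and its analytic size", {
  set.seed(26)
  x <- rand_nchw(2, 8, 16, 16)
  blk <- new_msdrm(8)
  expect_equal(dim(msdrm_forward(x, blk)), dim(x))
  expect_equal(msdrm_forward(x, zero_weights(blk)), x)
  expect_error(msdrm_forward(rand_nchw(1, 4, 8, 8), blk), "channels")
  # analytic parameter count from the layer inventory, C channels:
  #   region conv 3x3 dense: 9C^2 + C; region norm: 2C
  #   path1 depthwise 3x3, no bias: 9C
  #   each DRB (large 7 + three 3x3 branches, depthwise, no bias):
  #     (49 + 27)C weights + 4 * 2C norm affine
  #   shared norm: 2C; fuse conv 1x1 dense: C^2 + C
  C <- 8
  expected <- (9 * C^2 + C) + 2 * C + 9 * C +
    2 * ((49 + 27) * C + 8 * C) + 2 * C + (C^2 + C)
  expect_equal(count_params(blk), expected)
  # swapping a plain residual block for an MSDRM changes the parameter
  # count by the analytically predicted delta
  plain <- list(conv = conv_layer(C, C, 3), norm = norm_layer(C))
  delta <- count_params(blk) - count_params(plain)
  expect_equal(delta, expected - (9 * C^2 + C + 2 * C))
})

test_that("residual gradient path is the identity at zero weights", {
  # finite-difference derivative of output w.r.t. one input entry
  blk <- zero_weights(new_msdrm(4))
  x <- rand_nchw(1, 4, 6, 6, seed = 27)
  eps <- 1e-6
  for (probe in list(c(1, 1, 3, 3), c(1, 2, 5, 2))) {
    xp <- x; xp[probe[1], probe[2], probe[3], probe[4]] <-
      xp[probe[1], probe[2], probe[3], probe[4]] + eps
    g <- (msdrm_forward(xp, blk) - msdrm_forward(x, blk)) / eps
    expect_equal(g[probe[1], probe[2], probe[3], probe[4]], 1,
                 tolerance = 1e-6)
    g[probe[1], probe[2], probe[3], probe[4]] <- 0
    expect_equal(max(abs(g)), 0)
  }
})
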