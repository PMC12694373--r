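# feature pyramid neck: focusing block, RepC3, full wiring

make_levels <- function(n = 1, ch = c(6, 6, 6), s = 16, seed = 31) {
  set.seed(seed)
  list(low = rand_nchw(n, ch[1], 2 * s, 2 * s),
       mid = rand_nchw(n, ch[2], s, s),
       high = rand_nchw(n, ch[3], s / 2, s / 2))
}

test_that("MSF output sits at the middle resolution with 3x width", {
  lev <- make_levels(n = 2, s = 16)
  msf <- new_msf(6)
  out <- msf_forward(lev, msf)
  expect_equal(dim(out), c(2, 18, 16, 16))
  expect_true(all(is.finite(out)))
  # misaligned pyramid rejected
  bad <- lev; bad$high <- rand_nchw(2, 6, 7, 7)
  expect_error(msf_forward(bad, msf), "misaligned")
})

test_that("MSF with zero focusing weights returns the concatenated map", {
  lev <- make_levels(seed = 32)
  msf <- new_msf(6)
  for (i in seq_along(msf$dw_convs)) msf$dw_convs[[i]]$w[] <- 0
  msf$pw_conv$w[] <- 0
  expect_equal(msf_forward(lev, msf), msf_concat(lev, msf))
})

test_that("the four-branch focusing sum has an 11x11 impulse footprint", {
  msf <- new_msf(2)
  lev <- list(low = array(0, c(1, 2, 32, 32)),
              mid = array(0, c(1, 2, 16, 16)),
              high = array(0, c(1, 2, 8, 8)))
  lev$mid[1, 1, 8, 8] <- 1
  # bypass the laterals: identity mid projection, zero low/high
  msf$low_conv$w[] <- 0; msf$high_conv$w[] <- 0
  msf$mid_conv$w[] <- 0
  msf$mid_conv$w[1, 1, 1, 1] <- 1; msf$mid_conv$w[2, 2, 1, 1] <- 1
  d <- NULL
  f <- msf_concat(lev, msf)
  for (cv in msf$dw_convs) {
    y <- forward(cv, f)
    d <- if (is.null(d)) y else d + y
  }
  nz <- which(apply(d[1, , , ] != 0, c(2, 3), any), arr.ind = TRUE)
  expect_true(all(abs(nz - 8) <= 5))              # 11x11 window
  expect_true(any(abs(nz - 8) == 5))              # largest kernel reaches
})

test_that("MSF is linear in its inputs and batch-equivariant", {
  lev <- make_levels(n = 2, seed = 33)
  msf <- new_msf(6)
  out <- msf_forward(lev, msf)
  # linear scaling (bias-free block)
  lev3 <- lapply(lev, function(x) 3 * x)
  expect_equal(msf_forward(lev3, msf), 3 * out, tolerance = 1e-10)
  # swapping the two batch elements permutes the output identically
  swp <- lapply(lev, function(x) x[c(2, 1), , , , drop = FALSE])
  expect_equal(msf_forward(swp, msf), out[c(2, 1), , , , drop = FALSE],
               tolerance = 1e-12)
})

test_that("RepC3 zero-weight identity and merge equivalence hold", {
  set.seed(34)
  x <- rand_nchw(2, 5, 9, 9)
  rc <- new_repc3(5)
  expect_equal(repc3_forward(x, zero_weights(rc)), x)
  expect_equal(dim(repc3_forward(x, rc)), dim(x))
  # merge with non-trivial frozen statistics
  rc$norm3 <- set_norm_stats(rc$norm3, mean = rnorm(5, 0, 0.2),
                             var = runif(5, 0.5, 2),
                             gamma = rnorm(5, 1, 0.2),
                             beta = rnorm(5, 0, 0.2))
  rc$norm1 <- set_norm_stats(rc$norm1, mean = rnorm(5, 0, 0.2),
                             var = runif(5, 0.5, 2),
                             gamma = rnorm(5, 1, 0.2),
                             beta = rnorm(5, 0, 0.2))
  m <- repc3_merge(rc)
  expect_equal(conv2d(x, m$w, m$b), repc3_forward(x, rc),
               tolerance = 1e-10)
})

test_that("the neck emits three aligned scales and stays finite", {
  set.seed(35)
  lev <- list(low = rand_nchw(1, 5, 40, 40),
              mid = rand_nchw(1, 7, 20, 20),
              high = rand_nchw(1, 9, 10, 10))
  neck <- new_msfpn(c(5, 7, 9), width = 8)
  out <- msfpn_forward(lev, neck)
  expect_equal(dim(out$low), c(1, 8, 40, 40))
  expect_equal(dim(out$mid), c(1, 8, 20, 20))
  expect_equal(dim(out$high), c(1, 8, 10, 10))
  for (seed in 36:40) {
    lev2 <- list(low = rand_nchw(1, 5, 16, 16, seed),
                 mid = rand_nchw(1, 7, 8, 8, seed + 100),
                 high = rand_nchw(1, 9, 4, 4, seed + 200))
    o <- msfpn_forward(lev2, neck)
    expect_true(all(vapply(o, function(z) all(is.finite(z)), logical(1))))
  }
  bad <- lev; bad$mid <- rand_nchw(1, 7, 21, 21)
  expect_error(msfpn_forward(bad, neck), "misaligned")
})

test_that("silencing round 2 reduces the neck to its round-1 outputs", {
  set.seed(41)
  lev <- make_levels(s = 8, seed = 41)
  neck <- new_msfpn(c(6, 6, 6), width = 6)
  # straight-line round-1 oracle recomposed from the neck's own layers
  low <- forward(neck$lat_low, lev$low)
  mid <- forward(neck$lat_mid, lev$mid)
  high <- forward(neck$lat_high, lev$high)
  m1 <- forward(neck$msf1_red,
                msf_forward(list(low = low, mid = mid, high = high),
                            neck$msf1))
  xup <- upsample2x(m1)
  xc <- forward(neck$down1, m1)
  xrl_ref <- repc3_forward(
    forward(neck$low_fuse, msfdet:::abind_ch(low, xup)), neck$repc3_low)
  xrh_ref <- repc3_forward(
    forward(neck$high_fuse, msfdet:::abind_ch(high, xc)), neck$repc3_high)
  # silence the second focusing round and the diffusion convs
  ablate <- neck
  ablate$msf2_red$w[] <- 0
  ablate$out_low$w[] <- 0
  ablate$out_high$w[] <- 0
  out <- msfpn_forward(lev, ablate)
  expect_equal(out$low, xrl_ref, tolerance = 1e-10)
  expect_equal(out$high, xrh_ref, tolerance = 1e-10)
})

test_that("gradients reach all three pyramid levels (no dead path)", {
  set.seed(42)
  lev <- make_levels(s = 8, seed = 42)
  neck <- new_msfpn(c(6, 6, 6), width = 6)
  base <- msfpn_forward(lev, neck)
  eps <- 1e-4
  for (nm in c("low", "mid", "high")) {
    pert <- lev
    pert[[nm]][1, 1, 1, 1] <- pert[[nm]][1, 1, 1, 1] + eps
    out <- msfpn_forward(pert, neck)
    delta <- sum(vapply(c("low", "mid", "high"), function(o)
      sum(abs(out[[o]] - base[[o]])), numeric(1)))
    expect_gt(delta / eps, 1e-3)
  }
})

test_that("the literal first-round high fusion variant stays shape-legal", {
  set.seed(43)
  lev <- make_levels(s = 8, seed = 43)
  neck <- new_msfpn(c(6, 6, 6), width = 6, eq4_literal = TRUE)
  out <- msfpn_forward(lev, neck)
  expect_equal(dim(out$high), c(1, 6, 4, 4))
})
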