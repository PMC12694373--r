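# shared fixtures and small oracles

rand_nchw <- function(n, c, h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(rnorm(n * c * h * w), c(n, c, h, w))
}

# give every norm layer in a DRB / RepC3 non-trivial frozen statistics
randomize_drb_norms <- function(drb, seed = 1) {
  set.seed(seed)
  for (i in seq_along(drb$branches)) {
    ch <- drb$spec$channels
    drb$branches[[i]]$norm <- set_norm_stats(
      drb$branches[[i]]$norm,
      mean = rnorm(ch, 0, 0.2), var = runif(ch, 0.5, 2),
      gamma = rnorm(ch, 1, 0.2), beta = rnorm(ch, 0, 0.2))
  }
  drb
}

# dense sliding-window reference convolution (triple-loop; the oracle
# against which the im2col implementation is checked)
conv2d_reference <- function(x, w, b = NULL, dilation = 1L) {
  d <- dim(x); dw <- dim(w)
  kh <- dw[3L]; kw <- dw[4L]
  ph <- dilation * (kh - 1L) %/% 2L
  pw <- dilation * (kw - 1L) %/% 2L
  xp <- msfdet:::pad_nchw(x, ph, pw)
  out <- array(0, c(d[1L], dw[1L], d[3L], d[4L]))
  for (n in seq_len(d[1L])) for (co in seq_len(dw[1L]))
    for (i in seq_len(d[3L])) for (j in seq_len(d[4L])) {
      s <- 0
      for (ci in seq_len(d[2L])) for (ki in seq_len(kh))
        for (kj in seq_len(kw)) {
          s <- s + w[co, ci, ki, kj] *
            xp[n, ci, i + (ki - 1L) * dilation, j + (kj - 1L) * dilation]
        }
      out[n, co, i, j] <- s + if (is.null(b)) 0 else b[co]
    }
  out
}

# brute-force AP oracle: enumerate every confidence cutoff, recompute
# TP/FP from scratch at each, and integrate the resulting PR points with
# all-point interpolation
ap_bruteforce <- function(dets, gts, iou_threshold) {
  if (nrow(dets) == 0L) return(0)
  cuts <- sort(unique(dets$score), decreasing = TRUE)
  pr <- t(vapply(cuts, function(ct) {
    d <- dets[dets$score >= ct, , drop = FALSE]
    d <- d[order(-d$score), , drop = FALSE]
    tp <- 0L
    for (img in unique(d$image_id)) {
      di <- d[d$image_id == img, , drop = FALSE]
      gi <- gts[gts$image_id == img, , drop = FALSE]
      if (nrow(gi) == 0L) next
      taken <- logical(nrow(gi))
      for (r in seq_len(nrow(di))) {
        ious <- msfdet::box_iou(
          as.matrix(di[r, c("x_min", "y_min", "x_max", "y_max")]),
          as.matrix(gi[, c("x_min", "y_min", "x_max", "y_max")]))
        ious[1L, taken] <- -1
        jj <- which.max(ious[1L, ])
        if (ious[1L, jj] >= iou_threshold) {
          tp <- tp + 1L
          taken[jj] <- TRUE
        }
      }
    }
    c(tp / nrow(gts), tp / nrow(d))
  }, numeric(2)))
  recall <- pr[, 1L]; precision <- pr[, 2L]
  env <- rev(cummax(rev(precision)))
  sum(diff(c(0, recall)) * env)
}

random_detection_problem <- function(seed, n_images = 4, max_gt = 3,
                                     max_det = 5, n_classes = 1) {
  set.seed(seed)
  gts <- NULL; dets <- NULL
  for (img in seq_len(n_images)) {
    for (g in seq_len(sample(0:max_gt, 1))) {
      x <- runif(1, 0, 60); y <- runif(1, 0, 60)
      w <- runif(1, 8, 30); h <- runif(1, 8, 30)
      gts <- rbind(gts, data.frame(
        image_id = img, category_id = sample(n_classes, 1) - 1,
        x_min = x, y_min = y, x_max = x + w, y_max = y + h))
    }
    for (d in seq_len(sample(0:max_det, 1))) {
      if (!is.null(gts) && runif(1) < 0.6) {
        base <- gts[sample(nrow(gts), 1), ]
        jit <- rnorm(4, 0, 6)
        dets <- rbind(dets, data.frame(
          image_id = img, category_id = base$category_id,
          score = runif(1),
          x_min = base$x_min + jit[1], y_min = base$y_min + jit[2],
          x_max = pmax(base$x_min + jit[1] + 5, base$x_max + jit[3]),
          y_max = pmax(base$y_min + jit[2] + 5, base$y_max + jit[4])))
      } else {
        x <- runif(1, 0, 60); y <- runif(1, 0, 60)
        dets <- rbind(dets, data.frame(
          image_id = img, category_id = sample(n_classes, 1) - 1,
          score = runif(1), x_min = x, y_min = y,
          x_max = x + runif(1, 8, 30), y_max = y + runif(1, 8, 30)))
      }
    }
  }
  list(dets = dets, gts = gts)
}
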