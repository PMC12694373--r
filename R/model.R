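#' @title Desk-scale detector harness
#' @description
#' Assembles the package's components into a small trainable detector:
#' a convolutional backbone whose two deepest stages carry multi-scale
#' dilation residual modules, the MSFPN neck, and a minimal dense
#' per-scale head (1x1 convolution) producing class-quality logits and
#' box offsets at strides 8, 16 and 32. The full transformer
#' encoder/decoder of a production real-time detector is an external
#' integration point; this harness exists so the adaptive focal loss,
#' the blocks and the evaluator can be exercised end to end on a CPU in
#' minutes.
#'
#' Training updates the head only (backbone and neck features are frozen
#' and cached), with analytic gradients of the adaptive focal / varifocal
#' classification loss and an L1 box-offset loss, under SGD with
#' momentum. Target assignment is per-location max-IoU against square
#' cell anchors with a 0.5 positive threshold (plus the best anchor per
#' ground truth), and the classification target of a positive location
#' is the IoU of its currently predicted box with the matched ground
#' truth — the IoU-aware varifocal convention.
#' @name harness
NULL

#' Default detector configuration
#'
#' @param ncls number of categories.
#' @param image_size input image side (multiple of 32).
#' @return nested configuration list (backbone widths, neck settings,
#'   head and loss hyperparameters). Serializable to YAML with
#'   [save_model_config()].
#' @export
default_model_config <- function(ncls = 9L, image_size = 96L) {
  list(
    ncls = as.integer(ncls),
    image_size = as.integer(image_size),
    backbone = list(widths = c(8L, 12L, 16L, 24L, 32L),
                    use_msdrm = TRUE, n_drb = 1L, drb_large_kernel = 7L),
    neck = list(width = 16L, kernel_set = c(5L, 7L, 9L, 11L),
                eq4_literal = FALSE),
    head = list(anchor_scale = 4, init = "he"),
    afl = list(delta = 0.999, lambda = 2000, alpha = 0.75, gamma = 2.0,
               iou_floor = 0.2),
    train = list(lr0 = 0.01, lrf = 0.1, momentum = 0.9,
                 weight_decay = 5e-4, batch_size = 4L)
  )
}

#' Read / write a detector configuration as YAML
#' @param path YAML file.
#' @return for `load_model_config`, the configuration list.
#' @export
load_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_model_config()
  utils::modifyList(base, cfg)
}

#' @rdname load_model_config
#' @param config configuration list.
#' @export
save_model_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Build the desk-scale detector
#'
#' @param config a configuration list (see [default_model_config()]).
#' @param seed integer seed for weight initialization.
#' @return object of class `msf_model`; printing it reports the
#'   parameter count.
#' @export
build_model <- function(config = default_model_config(), seed = 1L) {
  w <- config$backbone$widths
  if (length(w) != 5L) stop("backbone needs 5 stage widths")
  if (config$image_size %% 32L != 0L)
    stop("image_size must be a multiple of 32")
  nw <- config$neck$width
  nc <- config$ncls
  model <- with_seed(seed, {
    mk_msdrm <- function(ch) {
      if (config$backbone$use_msdrm)
        new_msdrm(ch, n_drb = config$backbone$n_drb,
                  drb_large_kernel = config$backbone$drb_large_kernel)
      else NULL
    }
    list(
      config = config,
      stem = conv_layer(3L, w[1L], 3L, stride = 2L),
      c2 = conv_layer(w[1L], w[2L], 3L, stride = 2L),
      c3 = conv_layer(w[2L], w[3L], 3L, stride = 2L),
      c4 = conv_layer(w[3L], w[4L], 3L, stride = 2L),
      m4 = mk_msdrm(w[4L]),
      c5 = conv_layer(w[4L], w[5L], 3L, stride = 2L),
      m5 = mk_msdrm(w[5L]),
      neck = new_msfpn(w[3:5], width = nw,
                       kernel_set = config$neck$kernel_set,
                       eq4_literal = config$neck$eq4_literal),
      head = lapply(1:3, function(i) {
        hd <- conv_layer(nw, nc + 4L, 1L, init = "zero")
        if (config$head$init != "zero") {
          # detection-head convention: near-zero weights and a class bias
          # matching a low positive prior, so the initial loss is small
          # and negatives start at low confidence
          hd$w[] <- stats::rnorm(length(hd$w), sd = 0.01)
          hd$b[seq_len(nc)] <- -log((1 - 0.01) / 0.01)
        }
        hd
      })
    )
  })
  structure(model, class = "msf_model")
}

#' @export
print.msf_model <- function(x, ...) {
  cat("<msf_model> ", x$config$ncls, " classes, strides 8/16/32, ",
      count_params(x), " parameters\n", sep = "")
  invisible(x)
}

#' Frozen feature pyramid of the detector
#'
#' Runs backbone and neck (no head). Used both by [model_forward()] and
#' by the trainer, which caches these per image.
#'
#' @param model an `msf_model`.
#' @param x NCHW image batch (3 channels, values scaled to `[0, 1]`).
#' @return list of three NCHW arrays at strides 8, 16, 32.
#' @export
model_features <- function(model, x) {
  h <- silu(forward(model$stem, x))
  h <- silu(forward(model$c2, h))
  p3 <- silu(forward(model$c3, h))
  p4 <- silu(forward(model$c4, p3))
  if (!is.null(model$m4)) p4 <- msdrm_forward(p4, model$m4)
  p5 <- silu(forward(model$c5, p4))
  if (!is.null(model$m5)) p5 <- msdrm_forward(p5, model$m5)
  msfpn_forward(list(low = p3, mid = p4, high = p5), model$neck)
}

#' Full forward pass: three per-scale prediction maps
#'
#' @inheritParams model_features
#' @return list of three NCHW arrays with `ncls + 4` channels at strides
#'   8, 16, 32 (class-quality logits then box offsets).
#' @export
model_forward <- function(model, x) {
  feats <- model_features(model, x)
  lapply(1:3, function(i) forward(model$head[[i]], feats[[i]]))
}

strides3 <- c(8L, 16L, 32L)

# cell-centre anchor grid for one scale: centres and square anchor boxes
anchor_grid <- function(h, w, stride, anchor_scale) {
  cx <- rep((seq_len(w) - 0.5) * stride, each = h)
  cy <- rep((seq_len(h) - 0.5) * stride, times = w)
  half <- anchor_scale * stride / 2
  list(cx = cx, cy = cy,
       boxes = cbind(cx - half, cy - half, cx + half, cy + half))
}

# per-location max-IoU assignment for one image and scale.
# returns gt index per cell (0 = background)
assign_cells <- function(anchors, gt_boxes, pos_iou = 0.5) {
  ncell <- nrow(anchors$boxes)
  gti <- integer(ncell)
  if (is.null(gt_boxes) || nrow(gt_boxes) == 0L) return(gti)
  iou <- box_iou(anchors$boxes, gt_boxes)
  best <- max.col(iou, ties.method = "first")
  bv <- iou[cbind(seq_len(ncell), best)]
  gti[bv >= pos_iou] <- best[bv >= pos_iou]
  gti
}

# decode box offsets (4 x ncell matrix) at anchor centres
decode_boxes <- function(off, anchors, stride, clip = NULL) {
  e <- exp(pmin(off, 8))                     # guard against blow-up
  b <- cbind(anchors$cx - e[1L, ] * stride, anchors$cy - e[2L, ] * stride,
             anchors$cx + e[3L, ] * stride, anchors$cy + e[4L, ] * stride)
  if (!is.null(clip)) {
    b[, c(1L, 3L)] <- pmin(pmax(b[, c(1L, 3L)], 0), clip[1L])
    b[, c(2L, 4L)] <- pmin(pmax(b[, c(2L, 4L)], 0), clip[2L])
  }
  b
}

# encode ground-truth ltrb offsets for positive cells
encode_boxes <- function(gt, cx, cy, stride) {
  ltrb <- cbind(cx - gt[, 1L], cy - gt[, 2L], gt[, 3L] - cx, gt[, 4L] - cy)
  t(log(pmax(ltrb, 0.25) / stride))
}

#' Run detection on images
#'
#' Decodes the head outputs into scored class boxes with per-class
#' greedy non-maximum suppression.
#'
#' @param model an `msf_model`.
#' @param samples list of [detection_sample()] objects.
#' @param score_threshold minimum class confidence (default 0.25).
#' @param nms_iou IoU above which lower-scored boxes are suppressed.
#' @param feats optional precomputed per-sample feature list (as cached
#'   by the trainer) to skip the backbone.
#' @return detection data frame (`image_id`, `category_id`, `score`,
#'   box columns).
#' @export
detect <- function(model, samples, score_threshold = 0.25, nms_iou = 0.5,
                   feats = NULL) {
  nc <- model$config$ncls
  asc <- model$config$head$anchor_scale
  rows <- list()
  for (s in samples) {
    f <- if (!is.null(feats)) feats[[s$id]]
         else model_features(model, image_to_input(s$image))
    det <- NULL
    for (k in 1:3) {
      out <- forward(model$head[[k]], f[[k]])
      d <- dim(out)
      an <- anchor_grid(d[3L], d[4L], strides3[k], asc)
      # columns enumerate cells with the row index varying fastest,
      # matching anchor_grid's ordering
      mat <- matrix(out[1L, , , ], nrow = d[2L])
      sc <- sigmoid(mat[seq_len(nc), , drop = FALSE])
      hits <- which(sc >= score_threshold, arr.ind = TRUE)
      if (nrow(hits) == 0L) next
      boxes <- decode_boxes(mat[nc + 1:4, , drop = FALSE], an, strides3[k],
                            clip = rev(dim(s$image)[1:2]))
      det <- rbind(det, data.frame(
        image_id = s$id, category_id = hits[, 1L] - 1L,
        score = sc[hits],
        x_min = boxes[hits[, 2L], 1L], y_min = boxes[hits[, 2L], 2L],
        x_max = boxes[hits[, 2L], 3L], y_max = boxes[hits[, 2L], 4L]))
    }
    if (!is.null(det)) {
      if (nrow(det) > 300L)                     # cap pre-NMS candidates
        det <- det[order(-det$score)[1:300], , drop = FALSE]
      rows[[s$id]] <- nms(det, nms_iou)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(image_id = character(0), category_id = integer(0),
                      score = numeric(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0))
  rownames(out) <- NULL
  out
}

# per-class greedy NMS within one image (matrix arithmetic throughout)
nms <- function(det, nms_iou) {
  boxes <- cbind(det$x_min, det$y_min, det$x_max, det$y_max)
  area <- pmax(boxes[, 3L] - boxes[, 1L], 0) *
    pmax(boxes[, 4L] - boxes[, 2L], 0)
  keep <- logical(nrow(det))
  for (cl in unique(det$category_id)) {
    idx <- which(det$category_id == cl)
    idx <- idx[order(-det$score[idx])]
    while (length(idx) > 0L) {
      i <- idx[1L]
      keep[i] <- TRUE
      if (length(idx) == 1L) break
      r <- idx[-1L]
      iw <- pmin(boxes[r, 3L], boxes[i, 3L]) -
        pmax(boxes[r, 1L], boxes[i, 1L])
      ih <- pmin(boxes[r, 4L], boxes[i, 4L]) -
        pmax(boxes[r, 2L], boxes[i, 2L])
      inter <- pmax(iw, 0) * pmax(ih, 0)
      un <- area[r] + area[i] - inter
      iou <- ifelse(un > 0, inter / un, 0)
      idx <- r[iou < nms_iou]
    }
  }
  det[keep, , drop = FALSE]
}

#' Convert an H x W x 3 image to a model input batch
#' @param image integer image array (0–255).
#' @return NCHW array (1, 3, H, W) scaled to `[0, 1]`.
#' @export
image_to_input <- function(image) {
  x <- aperm(image / 255, c(3L, 1L, 2L))
  dim(x) <- c(1L, dim(x))
  x
}

#' Desk-scale smoke training of the detector head
#'
#' Freezes backbone and neck, caches their features for every training
#' image, and optimizes the per-scale head with SGD + momentum for
#' `steps` steps. Classification uses the adaptive focal loss (or its
#' plain varifocal ablation); box offsets use an L1 loss on positive
#' locations. The dynamic IoU threshold is advanced once per optimizer
#' step with the batch's mean positive IoU (the previous step's value is
#' reused when a batch has no positives). Training aborts with a
#' diagnostic if the loss becomes non-finite.
#'
#' @param model an `msf_model`.
#' @param samples list of training [detection_sample()] objects.
#' @param steps optimizer steps (default 200).
#' @param seed integer seed (batch sampling).
#' @param loss "afl" (adaptive focal) or "vfl" (plain varifocal, the
#'   non-adaptive ablation).
#' @param lr0,lrf,momentum,weight_decay,batch_size optimizer settings;
#'   defaults from the model configuration (initial rate 0.01 decaying
#'   linearly to `lr0 * lrf`).
#' @param feats optional precomputed feature cache (the `feats` element
#'   of a previous [train_smoke()] run on the same model and samples);
#'   skips the backbone/neck forward passes.
#' @return list with `model` (trained head), `loss` and `auto_iou`
#'   trajectories (one entry per step), `feats` (the feature cache,
#'   reusable by [detect()]).
#' @export
train_smoke <- function(model, samples, steps = 200L, seed = 1L,
                        loss = c("afl", "vfl"),
                        lr0 = NULL, lrf = NULL, momentum = NULL,
                        weight_decay = NULL, batch_size = NULL,
                        feats = NULL) {
  loss <- match.arg(loss)
  tc <- model$config$train
  lr0 <- lr0 %||% tc$lr0; lrf <- lrf %||% tc$lrf
  momentum <- momentum %||% tc$momentum
  weight_decay <- weight_decay %||% tc$weight_decay
  batch_size <- batch_size %||% tc$batch_size
  nc <- model$config$ncls
  asc <- model$config$head$anchor_scale
  st <- afl_state(delta = model$config$afl$delta,
                  lambda = model$config$afl$lambda,
                  alpha = model$config$afl$alpha,
                  gamma = model$config$afl$gamma,
                  iou_floor = model$config$afl$iou_floor)

  # cache frozen features and per-scale assignment per image
  cache <- list()
  for (s in samples) {
    f <- if (!is.null(feats)) feats[[s$id]]
         else model_features(model, image_to_input(s$image))
    sc <- list()
    for (k in 1:3) {
      d <- dim(f[[k]])
      an <- anchor_grid(d[3L], d[4L], strides3[k], asc)
      gti <- assign_cells(an, s$boxes)
      # ensure every ground truth owns its best anchor somewhere:
      if (nrow(s$boxes) > 0L) {
        iou <- box_iou(an$boxes, s$boxes)
        for (g in seq_len(nrow(s$boxes))) {
          j <- which.max(iou[, g])
          if (max(iou[, g]) > 0 && gti[j] == 0L) gti[j] <- g
        }
      }
      fm <- matrix(f[[k]][1L, , , ], nrow = d[2L])
      sc[[k]] <- list(fm = fm, an = an, gti = gti, hw = d[3:4])
    }
    cache[[s$id]] <- list(scales = sc, boxes = s$boxes,
                          labels = s$labels, feats = f)
  }

  heads <- model$head
  vel <- lapply(heads, function(h) list(w = h$w * 0, b = h$b * 0))
  loss_tr <- numeric(steps); aiou_tr <- numeric(steps)
  ids <- names(cache)
  prev_iou_batch <- NULL
  with_seed(seed, {
    for (step in seq_len(steps)) {
      lr <- lr0 * (1 - (step - 1) / steps * (1 - lrf))
      batch <- sample(ids, min(batch_size, length(ids)))
      gw <- lapply(heads, function(h) h$w * 0)
      gb <- lapply(heads, function(h) h$b * 0)
      total <- 0; nelem <- 0
      pos_ious <- numeric(0)
      for (id in batch) {
        cc <- cache[[id]]
        # classification and box losses are normalized by the image's
        # positive-location count (detection convention), not by the
        # total location count, so positives are not drowned out
        npos_img <- sum(vapply(cc$scales, function(s)
          sum(s$gti > 0L), numeric(1)))
        fnorm <- 1 / max(1, npos_img)
        for (k in 1:3) {
          scl <- cc$scales[[k]]
          wk <- matrix(heads[[k]]$w, nrow = nc + 4L)
          logits <- wk %*% scl$fm + heads[[k]]$b
          ncell <- ncol(logits)
          q <- matrix(0, nc, ncell)
          pos <- which(scl$gti > 0L)
          tgt_off <- NULL
          if (length(pos) > 0L) {
            g <- scl$gti[pos]
            pb <- decode_boxes(logits[nc + 1:4, pos, drop = FALSE],
                               list(cx = scl$an$cx[pos],
                                    cy = scl$an$cy[pos]),
                               strides3[k])
            iou_pg <- box_iou(pb, cc$boxes[g, , drop = FALSE])
            piou <- iou_pg[cbind(seq_along(g), seq_along(g))]
            pos_ious <- c(pos_ious, piou)
            q[cbind(cc$labels[g] + 1L, pos)] <- piou
            tgt_off <- encode_boxes(cc$boxes[g, , drop = FALSE],
                                    scl$an$cx[pos], scl$an$cy[pos],
                                    strides3[k])
          }
          cls_logits <- logits[seq_len(nc), , drop = FALSE]
          mw <- if (loss == "afl")
            matrix(modulating_weight(as.numeric(q), st$auto_iou), nc)
          else 1
          lmat <- varifocal_loss(cls_logits, q, st$alpha, st$gamma) * mw
          gmat <- varifocal_grad(cls_logits, q, st$alpha, st$gamma,
                                 mod_weight = mw)
          grad <- matrix(0, nc + 4L, ncell)
          grad[seq_len(nc), ] <- gmat * fnorm
          total <- total + sum(lmat) * fnorm
          if (length(pos) > 0L) {
            doff <- logits[nc + 1:4, pos, drop = FALSE] - tgt_off
            total <- total + sum(abs(doff)) * fnorm
            grad[nc + 1:4, pos] <- sign(doff) * fnorm
          }
          gw[[k]] <- gw[[k]] + array(grad %*% t(scl$fm), dim(gw[[k]]))
          gb[[k]] <- gb[[k]] + rowSums(grad)
        }
      }
      step_loss <- total / length(batch)
      if (!is.finite(step_loss))
        stop("training diverged at step ", step, " (non-finite loss)")
      for (k in 1:3) {
        gw[[k]] <- gw[[k]] / length(batch) + weight_decay * heads[[k]]$w
        gb[[k]] <- gb[[k]] / length(batch)
        vel[[k]]$w <- momentum * vel[[k]]$w - lr * gw[[k]]
        vel[[k]]$b <- momentum * vel[[k]]$b - lr * gb[[k]]
        heads[[k]]$w <- heads[[k]]$w + vel[[k]]$w
        heads[[k]]$b <- heads[[k]]$b + vel[[k]]$b
      }
      iou_batch <- if (length(pos_ious) > 0L) mean(pos_ious)
                   else prev_iou_batch %||% st$iou_floor
      prev_iou_batch <- iou_batch
      st <- update_auto_iou(st, iou_batch)
      loss_tr[step] <- step_loss
      aiou_tr[step] <- st$auto_iou
    }
  })
  model$head <- heads
  feats <- lapply(cache, function(cc) cc$feats)
  list(model = model, loss = loss_tr, auto_iou = aiou_tr, feats = feats,
       afl_state = st)
}
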