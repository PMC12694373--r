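#' @title Synthetic leaf-lesion detection scenes
#' @description
#' A seeded generator of synthetic plant-leaf disease detection imagery,
#' used to exercise every component of the package without downloading
#' image corpora. Each scene renders one or more leaf-shaped ellipses on
#' a configurable background — "clean" emulates single-leaf laboratory
#' captures on a plain backdrop, "cluttered" emulates field captures with
#' multiple leaves and distractor blobs — and stamps category-coded
#' lesion spots onto each leaf. Every rendered leaf yields exactly one
#' axis-aligned bounding box. Boxes are half-open pixel intervals
#' `[x_min, x_max) x [y_min, y_max)` with a 0-based origin.
#'
#' The module also implements the dataset-preparation protocol used for
#' such corpora: train/test splitting on original sample ids *before*
#' augmentation (so no augmented copy of a test image can leak into
#' training), the four standard augmentations (blur, brightness
#' enhancement, rotation, horizontal flip) with exact box transforms,
#' and a salt-noise injection protocol for robustness studies.
#' @name synthetic-data
NULL

#' Scene specification for the synthetic generator
#'
#' @param n_categories number of lesion categories (default 9).
#' @param clutter "clean" (single leaf, plain background) or "cluttered"
#'   (several leaves, distractor blobs, stronger noise).
#' @param image_size image side length in pixels (square images).
#' @param leaves_per_image integer range `c(min, max)`; defaults to 1 for
#'   clean scenes and 2–4 for cluttered scenes.
#' @param seed integer seed making the whole dataset reproducible.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(n_categories = 9L,
                       clutter = c("clean", "cluttered"),
                       image_size = 128L,
                       leaves_per_image = NULL,
                       seed = 1L) {
  clutter <- match.arg(clutter)
  if (image_size < 16L) stop("image_size must be at least 16 pixels")
  if (is.null(leaves_per_image))
    leaves_per_image <- if (clutter == "clean") c(1L, 1L) else c(2L, 4L)
  structure(list(n_categories = as.integer(n_categories),
                 clutter = clutter,
                 image_size = as.integer(image_size),
                 leaves_per_image = as.integer(leaves_per_image),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' A single detection sample
#'
#' @param image H x W x 3 integer array with values 0–255.
#' @param boxes numeric matrix (n x 4): `x_min, y_min, x_max, y_max`,
#'   half-open, 0-based pixels.
#' @param labels integer category ids, one per box.
#' @param id character sample id.
#' @return object of class `detection_sample`.
#' @export
detection_sample <- function(image, boxes, labels, id) {
  boxes <- matrix(as.numeric(boxes), ncol = 4L)
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L)
    stop("image must be an H x W x 3 array")
  if (nrow(boxes) != length(labels))
    stop("one label per box required")
  if (nrow(boxes) > 0L) {
    if (any(boxes[, 1L] < 0 | boxes[, 2L] < 0 |
            boxes[, 3L] > d[2L] | boxes[, 4L] > d[1L]) ||
        any(boxes[, 1L] >= boxes[, 3L]) || any(boxes[, 2L] >= boxes[, 4L]))
      stop("boxes must satisfy 0 <= min < max <= image extent")
  }
  structure(list(image = image, boxes = boxes,
                 labels = as.integer(labels), id = as.character(id)),
            class = "detection_sample")
}

# distinct lesion colour per category (fixed palette, not seeded)
lesion_palette <- function(n) {
  t(grDevices::col2rgb(grDevices::hsv(seq(0, 0.9, length.out = n),
                                      s = 0.85, v = 0.85)))
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

# render one scene; assumes the RNG is already seeded by the caller
render_scene <- function(spec, category, id) {
  s <- spec$image_size
  gx <- matrix(rep(seq_len(s), each = s), s)        # column index (x+1)
  gy <- matrix(rep(seq_len(s), times = s), s)       # row index (y+1)
  base <- c(98, 122, 88)
  noise_sd <- if (spec$clutter == "clean") 5 else 12
  img <- array(0, c(s, s, 3L))
  for (ch in 1:3) img[, , ch] <- base[ch] + stats::rnorm(s * s, sd = noise_sd)
  if (spec$clutter == "cluttered") {
    for (b in seq_len(sample(6:12, 1L))) {
      cx <- stats::runif(1, 1, s); cy <- stats::runif(1, 1, s)
      r <- stats::runif(1, s / 20, s / 6)
      mask <- (gx - cx)^2 + (gy - cy)^2 <= r^2
      col <- stats::runif(3, 40, 200)
      for (ch in 1:3) img[, , ch][mask] <- 0.6 * img[, , ch][mask] +
          0.4 * col[ch]
    }
  }
  pal <- lesion_palette(spec$n_categories)
  n_leaves <- sample(seq(spec$leaves_per_image[1L],
                         spec$leaves_per_image[2L]), 1L)
  boxes <- NULL; labels <- integer(0)
  for (lf in seq_len(n_leaves)) {
    a <- stats::runif(1, s / 8, s / 4)              # semi-axes
    b <- a * stats::runif(1, 0.45, 0.8)
    th <- stats::runif(1, 0, pi)
    cx <- stats::runif(1, a + 2, s - a - 2)
    cy <- stats::runif(1, a + 2, s - a - 2)
    u <- (gx - cx) * cos(th) + (gy - cy) * sin(th)
    v <- -(gx - cx) * sin(th) + (gy - cy) * cos(th)
    mask <- (u / a)^2 + (v / b)^2 <= 1
    if (!any(mask)) next
    leaf_col <- c(stats::runif(1, 30, 70), stats::runif(1, 110, 160),
                  stats::runif(1, 30, 70))
    for (ch in 1:3) img[, , ch][mask] <- leaf_col[ch] +
        stats::rnorm(sum(mask), sd = 4)
    # category-coded lesion spots inside the leaf
    inside <- which(mask, arr.ind = TRUE)
    for (le in seq_len(sample(3:6, 1L))) {
      p <- inside[sample(nrow(inside), 1L), ]
      r <- stats::runif(1, 1.5, max(2.5, a / 5))
      lm <- mask & ((gx - p[2L])^2 + (gy - p[1L])^2 <= r^2)
      for (ch in 1:3) img[, , ch][lm] <- 0.2 * img[, , ch][lm] +
          0.8 * pal[category + 1L, ch]
    }
    cols <- range(which(apply(mask, 2, any)))       # x extent (1-based)
    rows <- range(which(apply(mask, 1, any)))       # y extent
    boxes <- rbind(boxes, c(cols[1L] - 1L, rows[1L] - 1L,
                            cols[2L], rows[2L]))
    labels <- c(labels, category)
  }
  detection_sample(clamp255(round(img)), boxes, labels, id)
}

#' Generate a synthetic detection dataset
#'
#' Renders `category_counts[c]` images for each category `c` (all leaves
#' in an image carry the image's category), deterministically under the
#' spec's seed. If `dir` is given, PNG images, a COCO JSON annotation
#' file and YOLO txt labels are written there.
#'
#' @param spec a [scene_spec()].
#' @param category_counts integer vector of images per category (length
#'   `n_categories`), or a single total split as evenly as possible.
#' @param dir optional output directory.
#' @return list with `samples` (list of [detection_sample()]),
#'   `index` (a [dataset_index()] of image ids per category),
#'   `categories` (integer ids), and `dir`.
#' @export
generate_dataset <- function(spec, category_counts, dir = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  k <- spec$n_categories
  if (length(category_counts) == 1L) {
    n <- category_counts
    category_counts <- rep(n %/% k, k) +
      c(rep(1L, n %% k), rep(0L, k - n %% k))
  }
  if (length(category_counts) != k) stop("need one count per category")
  if (any(category_counts < 0)) stop("counts must be non-negative")
  samples <- list(); idx <- stats::setNames(vector("list", k),
                                            as.character(0:(k - 1L)))
  with_seed(spec$seed, {
    for (cat in 0:(k - 1L)) {
      ids <- character(0)
      for (j in seq_len(category_counts[cat + 1L])) {
        id <- sprintf("img_c%d_%04d", cat, j)
        samples[[id]] <- render_scene(spec, cat, id)
        ids <- c(ids, id)
      }
      idx[[as.character(cat)]] <- ids
    }
  })
  out <- list(samples = samples,
              index = dataset_index(idx),
              categories = 0:(k - 1L), dir = dir)
  if (!is.null(dir)) write_dataset(out, dir)
  out
}

#' Apply one augmentation to a detection sample
#'
#' Box transforms are exact: horizontal flip maps `x -> W - x` (swapping
#' min and max); rotation by a multiple of 90 degrees permutes box
#' coordinates exactly; rotation by an arbitrary angle replaces each box
#' by the axis-aligned hull of its rotated corners, clipped to the frame;
#' blur and brightness leave boxes untouched.
#'
#' @param sample a [detection_sample()].
#' @param op one of "blur", "brightness", "rotate", "hflip".
#' @param params list of op parameters: `sigma` (blur, default 1.5),
#'   `factor` (brightness, default 1.3), `angle` in degrees
#'   (rotate, default 15; multiples of 90 use the exact path).
#' @param suffix appended to the sample id (default the op name).
#' @return the augmented [detection_sample()].
#' @export
augment <- function(sample, op, params = list(), suffix = op) {
  stopifnot(inherits(sample, "detection_sample"))
  id <- paste0(sample$id, "_", suffix)
  switch(op,
    blur = {
      sigma <- params$sigma %||% 1.5
      detection_sample(gauss_blur(sample$image, sigma),
                       sample$boxes, sample$labels, id)
    },
    brightness = {
      f <- params$factor %||% 1.3
      detection_sample(clamp255(round(sample$image * f)),
                       sample$boxes, sample$labels, id)
    },
    hflip = {
      w <- dim(sample$image)[2L]
      img <- sample$image[, rev(seq_len(w)), , drop = FALSE]
      b <- sample$boxes
      if (nrow(b) > 0L) b[, c(1L, 3L)] <- cbind(w - b[, 3L], w - b[, 1L])
      detection_sample(img, b, sample$labels, id)
    },
    rotate = {
      angle <- params$angle %||% 15
      rotate_sample(sample, angle, id)
    },
    stop("unknown augmentation op: ", op)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# separable gaussian blur with replicate edge handling
gauss_blur <- function(image, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2)); k <- k / sum(k)
  x <- aperm(image, c(3L, 1L, 2L))               # C,H,W
  dim(x) <- c(1L, dim(x))                        # 1,C,H,W
  kv <- array(rep(k, each = 3L), c(3L, 1L, 2L * r + 1L, 1L))
  kh <- array(rep(k, each = 3L), c(3L, 1L, 1L, 2L * r + 1L))
  x <- conv2d(pad_nchw(x, r, 0L, "replicate"), kv, groups = 3L, pad = "valid")
  x <- conv2d(pad_nchw(x, 0L, r, "replicate"), kh, groups = 3L, pad = "valid")
  clamp255(round(aperm(array(x, dim(x)[-1L]), c(2L, 3L, 1L))))
}

# rotation: exact coordinate permutation for multiples of 90 degrees,
# nearest-neighbour inverse mapping about the image centre otherwise
rotate_sample <- function(sample, angle, id) {
  h <- dim(sample$image)[1L]; w <- dim(sample$image)[2L]
  a <- angle %% 360
  if (a %% 90 == 0) {
    img <- sample$image; b <- sample$boxes
    for (q in seq_len((a %/% 90) %% 4)) {
      # quarter turn mapping (x, y) -> (y, W - x)
      wq <- dim(img)[2L]
      img <- aperm(img, c(2L, 1L, 3L))[rev(seq_len(wq)), , , drop = FALSE]
      if (nrow(b) > 0L)
        b <- cbind(b[, 2L], wq - b[, 3L], b[, 4L], wq - b[, 1L])
    }
    return(detection_sample(img, b, sample$labels, id))
  }
  th <- a * pi / 180
  cx <- w / 2; cy <- h / 2
  gx <- matrix(rep(seq_len(w) - 0.5, each = h), h)
  gy <- matrix(rep(seq_len(h) - 0.5, times = w), h)
  # inverse map: source = R(-th) (dest - centre) + centre
  sx <- cos(th) * (gx - cx) + sin(th) * (gy - cy) + cx
  sy <- -sin(th) * (gx - cx) + cos(th) * (gy - cy) + cy
  si <- pmin(pmax(ceiling(sy), 1L), h)
  sj <- pmin(pmax(ceiling(sx), 1L), w)
  ok <- sy >= 0 & sy <= h & sx >= 0 & sx <= w
  img <- array(0L, dim(sample$image))
  lin <- cbind(as.vector(si), as.vector(sj))
  for (ch in 1:3) {
    plane <- sample$image[, , ch]
    dst <- plane[lin]
    dst[!as.vector(ok)] <- 0
    img[, , ch] <- dst
  }
  b <- sample$boxes
  if (nrow(b) > 0L) {
    nb <- t(apply(b, 1L, function(bb) {
      xs <- c(bb[1L], bb[3L], bb[1L], bb[3L]) - cx
      ys <- c(bb[2L], bb[2L], bb[4L], bb[4L]) - cy
      # forward map of the corners (dest = R(th) src)
      rx <- cos(th) * xs - sin(th) * ys + cx
      ry <- sin(th) * xs + cos(th) * ys + cy
      c(max(0, min(rx)), max(0, min(ry)), min(w, max(rx)), min(h, max(ry)))
    }))
    keep <- nb[, 1L] < nb[, 3L] & nb[, 2L] < nb[, 4L]
    b <- nb[keep, , drop = FALSE]
    labels <- sample$labels[keep]
  } else labels <- sample$labels
  detection_sample(img, b, labels, id)
}

#' Inject salt noise
#'
#' Sets a seeded random fraction of pixel positions (all three channels)
#' to the maximum intensity 255; all other pixels are untouched. Each
#' pixel is salted independently with probability `p`, so the altered
#' count is Binomial(H*W, p).
#'
#' @param image H x W x 3 array, values 0–255.
#' @param p salt fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return the noised image.
#' @export
salt_noise <- function(image, p, seed = 1L) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (p == 0) return(image)
  d <- dim(image)
  mask <- with_seed(seed, stats::runif(d[1L] * d[2L]) < p)
  for (ch in 1:3) {
    plane <- image[, , ch]
    plane[mask] <- 255
    image[, , ch] <- plane
  }
  image
}

#' Split first, then augment
#'
#' Implements the leakage-safe preparation order: the train/test split is
#' drawn on the original sample ids first, augmentation is applied only
#' to the training side, and the test side is returned byte-identical to
#' the originals. The augmented training set contains each original plus
#' one variant per plan entry.
#'
#' @param dataset result of [generate_dataset()].
#' @param test_fraction fraction of each category's originals held out.
#' @param aug_plan list of augmentation steps, each a list with `op` and
#'   optional `params` (see [augment()]); default: the four standard ops.
#' @param seed integer seed for the split.
#' @return list with `train` (list of samples, originals + variants),
#'   `test` (untouched originals), `train_index`, `test_index`.
#' @export
split_then_augment <- function(dataset, test_fraction,
                               aug_plan = default_aug_plan(), seed = 1L) {
  sp <- stratified_split(dataset$index, test_fraction, seed)
  train_ids <- unlist(sp$train$samples, use.names = FALSE)
  test_ids <- unlist(sp$test$samples, use.names = FALSE)
  train <- dataset$samples[train_ids]
  for (id in train_ids) {
    for (j in seq_along(aug_plan)) {
      st <- aug_plan[[j]]
      aug <- augment(dataset$samples[[id]], st$op,
                     st$params %||% list(),
                     suffix = paste0(st$op, j))
      train[[aug$id]] <- aug
    }
  }
  list(train = train, test = dataset$samples[test_ids],
       train_index = sp$train, test_index = sp$test)
}

#' Default augmentation plan: blur, brightness, rotation, horizontal flip
#' @return list of augmentation steps for [split_then_augment()].
#' @export
default_aug_plan <- function() {
  list(list(op = "blur", params = list(sigma = 1.2)),
       list(op = "brightness", params = list(factor = 1.3)),
       list(op = "rotate", params = list(angle = 15)),
       list(op = "hflip"))
}
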