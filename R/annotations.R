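#' @title Annotation serialization (COCO JSON and YOLO txt)
#' @description
#' Readers and writers for the two common bounding-box annotation
#' dialects. COCO JSON stores boxes as `[x, y, width, height]` in
#' absolute pixels with ids for images, annotations and categories; YOLO
#' txt stores one `class cx cy w h` line per box with centre coordinates
#' and sizes normalized by the image extent. Internally boxes are
#' half-open pixel intervals `(x_min, y_min, x_max, y_max)`; conversions
#' are exact for COCO and accurate to the printed precision for YOLO.
#' @name annotations
NULL

#' Write a dataset to disk (PNG images, COCO JSON, YOLO txt)
#'
#' @param dataset result of [generate_dataset()] (or a compatible list
#'   with `samples` and `categories`).
#' @param dir output directory; `images/`, `labels/` and
#'   `annotations.json` are created inside.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "labels"), showWarnings = FALSE)
  for (s in dataset$samples) {
    png::writePNG(s$image / 255,
                  file.path(dir, "images", paste0(s$id, ".png")))
    write_yolo(s, file.path(dir, "labels", paste0(s$id, ".txt")))
  }
  write_coco(dataset$samples, dataset$categories,
             file.path(dir, "annotations.json"))
  invisible(dir)
}

#' Write samples as a COCO JSON annotation file
#'
#' @param samples list of [detection_sample()] objects.
#' @param categories integer category ids present in the dataset.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_coco <- function(samples, categories, path) {
  samples <- unname(samples)
  images <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    list(id = i, file_name = paste0(s$id, ".png"),
         height = dim(s$image)[1L], width = dim(s$image)[2L])
  })
  anns <- list(); aid <- 0L
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    for (j in seq_len(nrow(s$boxes))) {
      b <- s$boxes[j, ]
      aid <- aid + 1L
      anns[[aid]] <- list(
        id = aid, image_id = i, category_id = s$labels[j],
        bbox = c(b[1L], b[2L], b[3L] - b[1L], b[4L] - b[2L]),
        area = (b[3L] - b[1L]) * (b[4L] - b[2L]), iscrowd = 0L)
    }
  }
  cats <- lapply(categories, function(cid)
    list(id = cid, name = paste0("category_", cid)))
  jsonlite::write_json(list(images = images, annotations = anns,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO JSON annotation file
#'
#' @param path COCO JSON file.
#' @return list with `samples` — per image: `id` (file stem), `width`,
#'   `height`, `boxes` (half-open x_min/y_min/x_max/y_max matrix),
#'   `labels` — and `categories`, plus an `index` ([dataset_index()])
#'   keyed by category id (images listed under the category of each of
#'   their boxes; single-category images appear once).
#' @export
read_coco <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  imgs <- j$images
  anns <- j$annotations
  samples <- lapply(seq_len(nrow(imgs)), function(i) {
    im <- imgs[i, ]
    rows <- anns[anns$image_id == im$id, , drop = FALSE]
    bb <- if (nrow(rows) > 0L) {
      m <- do.call(rbind, rows$bbox)
      cbind(m[, 1L], m[, 2L], m[, 1L] + m[, 3L], m[, 2L] + m[, 4L])
    } else matrix(numeric(0), ncol = 4L)
    list(id = sub("\\.png$", "", im$file_name),
         width = im$width, height = im$height,
         boxes = bb, labels = as.integer(rows$category_id))
  })
  names(samples) <- vapply(samples, `[[`, character(1), "id")
  cat_ids <- sort(unique(j$categories$id))
  idx <- stats::setNames(lapply(cat_ids, function(cid) {
    unique(unlist(lapply(samples, function(s)
      if (cid %in% s$labels) s$id else NULL)))
  }), as.character(cat_ids))
  list(samples = samples, categories = cat_ids,
       index = dataset_index(idx))
}

#' Write one sample's boxes in YOLO txt format
#'
#' One line per box: `class cx cy w h`, centre and size normalized by the
#' image extent, printed with six decimals.
#'
#' @param sample a [detection_sample()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_yolo <- function(sample, path) {
  d <- dim(sample$image)
  h <- d[1L]; w <- d[2L]
  lines <- character(nrow(sample$boxes))
  for (j in seq_len(nrow(sample$boxes))) {
    b <- sample$boxes[j, ]
    lines[j] <- sprintf("%d %.6f %.6f %.6f %.6f", sample$labels[j],
                        (b[1L] + b[3L]) / 2 / w, (b[2L] + b[4L]) / 2 / h,
                        (b[3L] - b[1L]) / w, (b[4L] - b[2L]) / h)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read YOLO txt boxes back to pixel coordinates
#'
#' @param path YOLO txt file.
#' @param width,height image extent in pixels.
#' @return list with `boxes` (half-open pixel matrix) and `labels`.
#' @export
read_yolo <- function(path, width, height) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(list(boxes = matrix(numeric(0), ncol = 4L),
                labels = integer(0)))
  m <- do.call(rbind, lapply(strsplit(lines, "\\s+"), as.numeric))
  cx <- m[, 2L] * width; cy <- m[, 3L] * height
  bw <- m[, 4L] * width; bh <- m[, 5L] * height
  list(boxes = cbind(cx - bw / 2, cy - bh / 2, cx + bw / 2, cy + bh / 2),
       labels = as.integer(m[, 1L]))
}
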