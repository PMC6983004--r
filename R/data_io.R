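## Dataset IO: COCO-style JSON annotations, viewpoint-aware splits, and
## geometric preparation of images for the stride-32 network.

#' Read a COCO-style annotation file
#'
#' Parses `images`, `annotations` and `categories`; boxes are converted
#' from COCO (x, y, w, h) to corner convention (x_min, y_min, x_max,
#' y_max). Categories are indexed deterministically by sorted name, giving
#' class ids 1..K. An optional per-image `"view"` attribute (V1/V2/V3 or
#' `"synthetic"`) is preserved for the viewpoint protocol.
#'
#' COCO-style JSON is the only dialect parsed here; other annotation
#' dialects should be converted to it upstream — this reader is the single
#' ingestion point for both synthetic and real datasets.
#'
#' @param path path to the JSON file.
#' @return list of class `"FruitDataset"`: `images` (list of per-image
#'   records with an `annotations` data.frame) and `categories`
#'   (data.frame with coco_id, name, class_id).
#' @export
readCoco <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("images", "annotations", "categories"))
    if (is.null(j[[f]])) stop("COCO file missing '", f, "'")
  cat_names <- vapply(j$categories, function(c) c$name, "")
  cat_ids <- vapply(j$categories, function(c) as.numeric(c$id), 0)
  ord <- order(cat_names)
  categories <- data.frame(coco_id = cat_ids[ord], name = cat_names[ord],
                           class_id = seq_along(ord))
  id2class <- setNames(categories$class_id, as.character(categories$coco_id))
  img_ids <- vapply(j$images, function(im) as.numeric(im$id), 0)
  imgs <- lapply(j$images, function(im) {
    list(id = as.numeric(im$id),
         file_name = if (is.null(im$file_name)) NA_character_ else im$file_name,
         width = if (is.null(im$width)) NA_real_ else as.numeric(im$width),
         height = if (is.null(im$height)) NA_real_ else as.numeric(im$height),
         view = if (is.null(im$view)) NA_character_ else im$view,
         annotations = data.frame(ann_id = numeric(0), x_min = numeric(0),
                                  y_min = numeric(0), x_max = numeric(0),
                                  y_max = numeric(0), class_id = integer(0),
                                  class = character(0)))
  })
  names(imgs) <- as.character(img_ids)
  for (a in j$annotations) {
    iid <- as.character(as.numeric(a$image_id))
    if (is.null(imgs[[iid]]))
      stop("annotation ", a$id, " references unknown image id ", iid)
    cid <- as.character(as.numeric(a$category_id))
    if (is.na(id2class[cid]))
      stop("annotation ", a$id, " references unknown category id ", cid)
    bb <- as.numeric(unlist(a$bbox))
    row <- data.frame(ann_id = as.numeric(a$id), x_min = bb[1], y_min = bb[2],
                      x_max = bb[1] + bb[3], y_max = bb[2] + bb[4],
                      class_id = unname(id2class[cid]),
                      class = categories$name[id2class[cid]])
    imgs[[iid]]$annotations <- rbind(imgs[[iid]]$annotations, row)
  }
  structure(list(images = imgs, categories = categories),
            class = "FruitDataset")
}

#' @export
print.FruitDataset <- function(x, ...) {
  nb <- sum(vapply(x$images, function(im) nrow(im$annotations), 0))
  views <- table(vapply(x$images, function(im) im$view, ""))
  cat(sprintf("FruitDataset: %d images, %d boxes, classes: %s\n",
              length(x$images), nb, paste(x$categories$name, collapse = ", ")))
  if (length(views)) print(views)
  invisible(x)
}

#' Write a dataset as COCO-style JSON
#'
#' Inverse of [readCoco()]; images and annotations are written in
#' deterministic order (image id, then annotation id) and boxes converted
#' back to COCO (x, y, w, h).
#'
#' @param dataset a `"FruitDataset"`.
#' @param path output path.
#' @export
writeCoco <- function(dataset, path) {
  imgs <- dataset$images[order(vapply(dataset$images, `[[`, 0, "id"))]
  images <- lapply(imgs, function(im) {
    rec <- list(id = im$id, file_name = im$file_name,
                width = im$width, height = im$height)
    if (!is.na(im$view)) rec$view <- im$view
    rec
  })
  anns <- list()
  cls2coco <- setNames(dataset$categories$coco_id, dataset$categories$class_id)
  for (im in imgs) {
    ann <- im$annotations
    if (nrow(ann) == 0L) next
    ann <- ann[order(ann$ann_id), , drop = FALSE]
    for (r in seq_len(nrow(ann)))
      anns[[length(anns) + 1L]] <- list(
        id = ann$ann_id[r], image_id = im$id,
        category_id = unname(cls2coco[as.character(ann$class_id[r])]),
        bbox = c(ann$x_min[r], ann$y_min[r],
                 ann$x_max[r] - ann$x_min[r], ann$y_max[r] - ann$y_min[r]),
        area = (ann$x_max[r] - ann$x_min[r]) * (ann$y_max[r] - ann$y_min[r]),
        iscrowd = 0)
  }
  cats <- lapply(seq_len(nrow(dataset$categories)), function(i)
    list(id = dataset$categories$coco_id[i],
         name = dataset$categories$name[i]))
  jsonlite::write_json(list(images = unname(images), annotations = unname(anns),
                            categories = unname(cats)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Pooled ground-truth table of a dataset
#'
#' @param dataset a `"FruitDataset"`.
#' @return data.frame with image_id, view, box columns, class_id, class —
#'   the shape [evaluateRun()] expects.
#' @export
gtTable <- function(dataset) {
  rows <- lapply(dataset$images, function(im) {
    if (nrow(im$annotations) == 0L) return(NULL)
    cbind(data.frame(image_id = im$id, view = im$view), im$annotations)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(image_id = numeric(0), view = character(0),
                      ann_id = numeric(0), x_min = numeric(0),
                      y_min = numeric(0), x_max = numeric(0),
                      y_max = numeric(0), class_id = integer(0),
                      class = character(0))
  rownames(out) <- NULL
  out
}

#' Viewpoint-aware split specification
#'
#' The field protocol trains exclusively on the top view (V1) and
#' validates on all three views; [paperSplitSpec()] encodes it (train V1
#' only, 10 validation images per view).
#'
#' @param train_views views contributing training images.
#' @param val_per_view validation images sampled per view.
#' @param train_fraction fraction of the remaining training images kept
#'   (supports data-reduction sweeps at 0.75/0.5/0.25).
#' @param seed RNG seed for any sampling.
#' @return list of class `"SplitSpec"`.
#' @export
splitSpec <- function(train_views = "V1", val_per_view = 10,
                      train_fraction = 1, seed = 1L) {
  if (train_fraction <= 0 || train_fraction > 1)
    stop("train_fraction must lie in (0, 1]")
  structure(list(train_views = train_views, val_per_view = val_per_view,
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "SplitSpec")
}

#' @rdname splitSpec
#' @export
paperSplitSpec <- function(seed = 1L) splitSpec("V1", 10, 1, seed)

#' Split a dataset by viewpoint
#'
#' Deterministic given the spec's seed: per view, `val_per_view` images go
#' to validation; the remaining images of the training views (optionally
#' subsampled by `train_fraction`) form the training set. Train and
#' validation ids never overlap.
#'
#' @param dataset a `"FruitDataset"`.
#' @param spec a [splitSpec()].
#' @return list with `train` (image id vector) and `val` (named list of
#'   image id vectors keyed by view).
#' @export
makeSplit <- function(dataset, spec) {
  stopifnot(is(spec, "SplitSpec"))
  views <- vapply(dataset$images, function(im) im$view, "")
  ids <- vapply(dataset$images, function(im) im$id, 0)
  .with_seed(spec$seed, {
    val <- list()
    val_ids <- numeric(0)
    for (v in sort(unique(views))) {
      in_view <- ids[views == v]
      if (length(in_view) < spec$val_per_view)
        stop(sprintf("view %s has %d images, %d validation images requested",
                     v, length(in_view), spec$val_per_view))
      pick <- sort(sample(in_view, spec$val_per_view))
      val[[v]] <- pick
      val_ids <- c(val_ids, pick)
    }
    train_pool <- setdiff(ids[views %in% spec$train_views], val_ids)
    n_train <- floor(length(train_pool) * spec$train_fraction)
    train <- sort(sample(train_pool, n_train))
    list(train = train, val = val)
  })
}

#' Transform record produced by prepareImage
#'
#' @param scale_x,scale_y resize factors applied before padding.
#' @param orig_h,orig_w original image size.
#' @return list of class `"TransformRecord"`.
#' @export
transformRecord <- function(scale_x = 1, scale_y = 1, orig_h, orig_w) {
  structure(list(scale_x = scale_x, scale_y = scale_y,
                 orig_h = orig_h, orig_w = orig_w),
            class = "TransformRecord")
}

#' Prepare an image for the stride-32 network
#'
#' Default behaviour pads the bottom and right with zeros to the next
#' multiple of `multiple`; with an explicit `target = c(h, w)` the image is
#' bilinearly resized instead (the protocol used for 1296x964 inputs
#' sampled to 1280x736). The returned record suffices to map predicted
#' boxes back to original coordinates.
#'
#' @param img `H x W x C` array or [ChannelImage-class].
#' @param multiple stride alignment (default 32).
#' @param target optional explicit `c(height, width)`.
#' @return list with `image` (array) and `record`
#'   (a [transformRecord()]).
#' @export
prepareImage <- function(img, multiple = 32, target = NULL) {
  px <- .as_pixels(img)
  h <- dim(px)[1]; w <- dim(px)[2]; nc <- dim(px)[3]
  if (!is.null(target)) {
    out <- .bilinear_resize(px, target[1], target[2])
    rec <- transformRecord(scale_x = target[2] / w, scale_y = target[1] / h,
                           orig_h = h, orig_w = w)
    return(list(image = out, record = rec))
  }
  H <- as.integer(ceiling(h / multiple) * multiple)
  W <- as.integer(ceiling(w / multiple) * multiple)
  if (H == h && W == w)
    return(list(image = px, record = transformRecord(orig_h = h, orig_w = w)))
  out <- array(0, c(H, W, nc))
  out[seq_len(h), seq_len(w), ] <- px
  list(image = out, record = transformRecord(orig_h = h, orig_w = w))
}

.bilinear_resize <- function(px, H, W) {
  h <- dim(px)[1]; w <- dim(px)[2]; nc <- dim(px)[3]
  # sample at pixel centres in the source frame
  ys <- (seq_len(H) - 0.5) * h / H - 0.5
  xs <- (seq_len(W) - 0.5) * w / W - 0.5
  y0 <- pmin(pmax(floor(ys), 0), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(pmax(floor(xs), 0), w - 1); x1 <- pmin(x0 + 1, w - 1)
  wy <- pmin(pmax(ys - y0, 0), 1); wx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(H, W, nc))
  for (c in seq_len(nc)) {
    sl <- px[, , c]
    a <- sl[cbind(rep(y0 + 1, W), rep(x0 + 1, each = H))]
    b <- sl[cbind(rep(y0 + 1, W), rep(x1 + 1, each = H))]
    d <- sl[cbind(rep(y1 + 1, W), rep(x0 + 1, each = H))]
    e <- sl[cbind(rep(y1 + 1, W), rep(x1 + 1, each = H))]
    top <- a * (1 - rep(wx, each = H)) + b * rep(wx, each = H)
    bot <- d * (1 - rep(wx, each = H)) + e * rep(wx, each = H)
    out[, , c] <- matrix(top * (1 - rep(wy, W)) + bot * rep(wy, W), H, W)
  }
  out
}

#' Map boxes between original and prepared coordinates
#'
#' `applyTransformToBoxes` maps original-image boxes into the prepared
#' frame; `invertTransformOnBoxes` maps predictions back, clipping to the
#' original bounds.
#'
#' @param boxes data.frame with x_min, y_min, x_max, y_max (other columns
#'   pass through).
#' @param record a [transformRecord()].
#' @export
applyTransformToBoxes <- function(boxes, record) {
  boxes$x_min <- boxes$x_min * record$scale_x
  boxes$x_max <- boxes$x_max * record$scale_x
  boxes$y_min <- boxes$y_min * record$scale_y
  boxes$y_max <- boxes$y_max * record$scale_y
  boxes
}

#' @rdname applyTransformToBoxes
#' @export
invertTransformOnBoxes <- function(boxes, record) {
  boxes$x_min <- pmin(pmax(boxes$x_min / record$scale_x, 0), record$orig_w)
  boxes$x_max <- pmin(pmax(boxes$x_max / record$scale_x, 0), record$orig_w)
  boxes$y_min <- pmin(pmax(boxes$y_min / record$scale_y, 0), record$orig_h)
  boxes$y_max <- pmin(pmax(boxes$y_max / record$scale_y, 0), record$orig_h)
  boxes
}

#' Read / write an RGB image as PNG
#'
#' @param path PNG file path.
#' @return `loadImageRGB`: `H x W x 3` array in `[0,1]` (gamma-encoded
#'   sRGB as stored).
#' @export
loadImageRGB <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  px[, , 1:3, drop = FALSE]
}

#' @rdname loadImageRGB
#' @param img `H x W x 3` array in `[0,1]`.
#' @export
writeImageRGB <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}
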