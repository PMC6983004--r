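## Deterministic generator of strawberry-like annotated scenes: textured
## ellipses in two colour classes (red-dominant "ripe" vs green/white
## "unripe") over cluttered green background, with per-scene multiplicative
## illumination in linear RGB, viewpoint-like affine distortion of the berry
## geometry, partial occlusion, and exact ground-truth boxes.

#' Synthetic scene specification
#'
#' @param height,width scene size in pixels.
#' @param n_ripe,n_unripe berry counts per class.
#' @param ripe_colour,unripe_colour lists with `r`, `g`, `b` ranges (base
#'   colours are drawn uniformly per berry). Defaults: red-dominant for
#'   ripe, green/white-dominant for unripe.
#' @param berry_radius range of berry half-extents in pixels.
#' @param clutter_density background clutter blobs per 32x32 pixel tile.
#' @param illumination_gain scalar or range; per-scene multiplicative gain
#'   applied in linear RGB (must be > 0).
#' @param shear_range,scale_range affine distortion of berry geometry
#'   emulating viewpoint change.
#' @param occlusion_max maximum allowed fraction of a berry box covered by
#'   another berry or a foreground occluder.
#' @param seed default seed for [generateScene()].
#' @return list of class `"SceneSpec"`.
#' @export
sceneSpec <- function(height = 128L, width = 128L, n_ripe = 3L, n_unripe = 5L,
                      ripe_colour = list(r = c(0.62, 0.92), g = c(0.08, 0.26),
                                         b = c(0.10, 0.30)),
                      unripe_colour = list(r = c(0.45, 0.75), g = c(0.58, 0.85),
                                           b = c(0.40, 0.62)),
                      berry_radius = c(10, 20),
                      clutter_density = 0.5,
                      illumination_gain = c(0.8, 1.2),
                      shear_range = c(0, 0.15),
                      scale_range = c(0.9, 1.1),
                      occlusion_max = 0.3, seed = 1L) {
  if (n_ripe < 0 || n_unripe < 0) stop("berry counts must be >= 0")
  if (any(berry_radius <= 0)) stop("berry sizes must be positive")
  if (any(illumination_gain <= 0)) stop("illumination gain must be > 0")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_ripe = as.integer(n_ripe), n_unripe = as.integer(n_unripe),
                 ripe_colour = ripe_colour, unripe_colour = unripe_colour,
                 berry_radius = berry_radius,
                 clutter_density = clutter_density,
                 illumination_gain = illumination_gain,
                 shear_range = shear_range, scale_range = scale_range,
                 occlusion_max = occlusion_max, seed = as.integer(seed)),
            class = "SceneSpec")
}

#' @export
print.SceneSpec <- function(x, ...) {
  cat(sprintf(paste0("SceneSpec %dx%d: %d ripe + %d unripe berries, ",
                     "radius [%g, %g] px, gain [%s], occlusion <= %g\n"),
              x$height, x$width, x$n_ripe, x$n_unripe,
              x$berry_radius[1], x$berry_radius[2],
              paste(x$illumination_gain, collapse = ", "), x$occlusion_max))
  invisible(x)
}

# coarse uniform noise bilinearly upsampled to H x W (smooth variation)
.smooth_noise <- function(h, w, cell = 16) {
  gh <- max(2L, ceiling(h / cell) + 1L)
  gw <- max(2L, ceiling(w / cell) + 1L)
  g <- matrix(runif(gh * gw), gh, gw)
  ys <- seq(1, gh, length.out = h)
  xs <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(ys), gh - 1); x0 <- pmin(floor(xs), gw - 1)
  wy <- ys - y0; wx <- xs - x0
  a <- g[cbind(rep(y0, w), rep(x0, each = h))]
  b <- g[cbind(rep(y0, w), rep(x0 + 1, each = h))]
  d <- g[cbind(rep(y0 + 1, w), rep(x0, each = h))]
  e <- g[cbind(rep(y0 + 1, w), rep(x0 + 1, each = h))]
  WX <- rep(wx, each = h); WY <- rep(wy, w)
  matrix((a * (1 - WX) + b * WX) * (1 - WY) + (d * (1 - WX) + e * WX) * WY,
         h, w)
}

# paint an ellipse given centre c(cx, cy) and 2x2 shape matrix M
# (unit disc image); returns linear indices of covered pixels and their
# normalised squared radius.
.ellipse_pixels <- function(h, w, centre, M) {
  hw <- sqrt(M[1, 1]^2 + M[1, 2]^2)
  hh <- sqrt(M[2, 1]^2 + M[2, 2]^2)
  cols <- max(1L, floor(centre[1] - hw + 0.5)):min(w, ceiling(centre[1] + hw + 0.5))
  rows <- max(1L, floor(centre[2] - hh + 0.5)):min(h, ceiling(centre[2] + hh + 0.5))
  px <- expand.grid(row = rows, col = cols)
  dx <- px$col - 0.5 - centre[1]
  dy <- px$row - 0.5 - centre[2]
  Minv <- solve(M)
  u <- Minv %*% rbind(dx, dy)
  r2 <- colSums(u^2)
  inside <- r2 <= 1
  list(idx = px$row[inside] + (px$col[inside] - 1L) * h, r2 = r2[inside],
       half_w = hw, half_h = hh)
}

.box_overlap_frac <- function(a, b) {
  # intersection area over the area of box b
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  ix * iy / ((b[3] - b[1]) * (b[4] - b[2]))
}

.sample_range <- function(r) if (length(r) == 1L) r else runif(1, r[1], r[2])

#' Generate one annotated synthetic scene
#'
#' Deterministic given `(spec, seed)`. Berries are rendered as shaded,
#' speckled ellipses whose geometry carries the spec's affine (shear/scale)
#' distortion; the per-scene illumination gain is applied multiplicatively
#' in linear RGB and the result re-encoded to gamma sRGB. Ground-truth
#' boxes are the exact extents of the distorted ellipses, clipped to the
#' image.
#'
#' @param spec a [sceneSpec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return list with `pixels` (`H x W x 3` gamma sRGB array), `annotations`
#'   (data.frame: ann_id, box columns, class_id, class), `view`, `gain`.
#' @export
generateScene <- function(spec, seed = spec$seed) {
  stopifnot(is(spec, "SceneSpec"))
  .with_seed(seed, {
    h <- spec$height; w <- spec$width
    img <- array(0, c(h, w, 3L))
    img[, , 1] <- 0.08 + 0.10 * .smooth_noise(h, w)
    img[, , 2] <- 0.22 + 0.18 * .smooth_noise(h, w)
    img[, , 3] <- 0.06 + 0.08 * .smooth_noise(h, w)
    # background clutter: leaf-like green ellipses
    n_clutter <- round(spec$clutter_density * h * w / 1024)
    for (i in seq_len(n_clutter)) {
      ang <- runif(1, 0, pi)
      ax <- runif(1, 3, 12); bx <- ax * runif(1, 0.4, 0.9)
      R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
      M <- R %*% diag(c(ax, bx))
      ctr <- c(runif(1, 0, w), runif(1, 0, h))
      ep <- .ellipse_pixels(h, w, ctr, M)
      if (length(ep$idx) == 0L) next
      shade <- runif(1, 0.5, 1.4)
      col <- c(0.10, 0.30, 0.08) * shade
      for (ch in 1:3) {
        sl <- img[, , ch]
        sl[ep$idx] <- pmin(col[ch] * (1 - 0.3 * ep$r2), 1)
        img[, , ch] <- sl
      }
    }
    # berries: rejection-sampled placement bounding pairwise box occlusion
    n <- spec$n_ripe + spec$n_unripe
    classes <- c(rep(1L, spec$n_ripe), rep(2L, spec$n_unripe))
    cls_names <- c("ripe", "unripe")
    boxes <- matrix(NA_real_, n, 4)
    geoms <- vector("list", n)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (attempt in seq_len(1000L)) {
        r <- runif(1, spec$berry_radius[1], spec$berry_radius[2])
        aspect <- runif(1, 0.75, 1.3)
        ang <- runif(1, 0, pi)
        shear <- .sample_range(spec$shear_range) * sample(c(-1, 1), 1)
        sc <- c(.sample_range(spec$scale_range), .sample_range(spec$scale_range))
        R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
        V <- matrix(c(sc[1], 0, shear * sc[1], sc[2]), 2, 2)
        M <- V %*% R %*% diag(c(r, r * aspect))
        hw_e <- sqrt(M[1, 1]^2 + M[1, 2]^2)
        hh_e <- sqrt(M[2, 1]^2 + M[2, 2]^2)
        if (2 * hw_e > w - 2 || 2 * hh_e > h - 2) next
        ctr <- c(runif(1, hw_e + 1, w - hw_e - 1), runif(1, hh_e + 1, h - hh_e - 1))
        box <- c(ctr[1] - hw_e, ctr[2] - hh_e, ctr[1] + hw_e, ctr[2] + hh_e)
        ok <- TRUE
        for (j in seq_len(i - 1L)) {
          if (.box_overlap_frac(boxes[j, ], box) > spec$occlusion_max ||
              .box_overlap_frac(box, boxes[j, ]) > spec$occlusion_max) {
            ok <- FALSE; break
          }
        }
        if (!ok) next
        boxes[i, ] <- box
        geoms[[i]] <- list(centre = ctr, M = M)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("could not place berry ", i, " within the occlusion limit ",
             "after 1000 attempts")
    }
    for (i in seq_len(n)) {
      cd <- if (classes[i] == 1L) spec$ripe_colour else spec$unripe_colour
      base <- c(runif(1, cd$r[1], cd$r[2]), runif(1, cd$g[1], cd$g[2]),
                runif(1, cd$b[1], cd$b[2]))
      ep <- .ellipse_pixels(h, w, geoms[[i]]$centre, geoms[[i]]$M)
      shade <- 1 - 0.35 * ep$r2
      speck <- 1 + 0.18 * (runif(length(ep$idx)) - 0.5)
      for (ch in 1:3) {
        sl <- img[, , ch]
        sl[ep$idx] <- pmin(pmax(base[ch] * shade * speck, 0), 1)
        img[, , ch] <- sl
      }
    }
    # foreground occluders clipped to the per-berry occlusion budget
    for (i in seq_len(n)) {
      if (runif(1) > 0.5) next
      g <- geoms[[i]]
      theta <- runif(1, 0, 2 * pi)
      edge <- g$centre + as.vector(g$M %*% c(cos(theta), sin(theta)))
      lr <- runif(1, 0.25, 0.45) * spec$berry_radius[1]
      leaf_box <- c(edge[1] - lr, edge[2] - lr, edge[1] + lr, edge[2] + lr)
      frac <- vapply(seq_len(n), function(j)
        .box_overlap_frac(leaf_box, boxes[j, ]), 0)
      if (any(frac > spec$occlusion_max)) next
      M <- diag(c(lr, lr * runif(1, 0.6, 0.9)))
      ep <- .ellipse_pixels(h, w, edge, M)
      if (length(ep$idx) == 0L) next
      for (ch in 1:3) {
        sl <- img[, , ch]
        sl[ep$idx] <- c(0.12, 0.34, 0.10)[ch] * (1 - 0.3 * ep$r2)
        img[, , ch] <- sl
      }
    }
    # per-scene global illumination, multiplicative in linear RGB
    gain <- .sample_range(spec$illumination_gain)
    lin <- .srgb_linearize(img) * gain
    lin <- pmin(pmax(lin, 0), 1)
    img <- ifelse(lin <= 0.0031308, 12.92 * lin,
                  1.055 * lin^(1 / 2.4) - 0.055)
    ann <- data.frame(ann_id = seq_len(n),
                      x_min = pmax(boxes[, 1], 0), y_min = pmax(boxes[, 2], 0),
                      x_max = pmin(boxes[, 3], w), y_max = pmin(boxes[, 4], h),
                      class_id = classes, class = cls_names[classes])
    if (n == 0L)
      ann <- data.frame(ann_id = numeric(0), x_min = numeric(0),
                        y_min = numeric(0), x_max = numeric(0),
                        y_max = numeric(0), class_id = integer(0),
                        class = character(0))
    list(pixels = img, annotations = ann, view = "synthetic", gain = gain)
  })
}

# view-dependent spec adjustment: held-out views carry stronger affine
# distortion and a wider illumination range than the training view
.view_spec <- function(spec, view) {
  switch(view,
    V1 = spec,
    V2 = { spec$shear_range <- spec$shear_range + 0.12
           spec$scale_range <- spec$scale_range + c(-0.08, 0.08)
           spec$illumination_gain <- c(0.65, 1.35); spec },
    V3 = { spec$shear_range <- spec$shear_range + 0.25
           spec$scale_range <- spec$scale_range + c(-0.15, 0.15)
           spec$illumination_gain <- c(0.5, 1.5); spec },
    spec)
}

#' Generate a synthetic dataset on disk
#'
#' Writes PNG images and a COCO-style annotation file with per-image view
#' tags. Scenes tagged V2/V3 are generated with stronger affine distortion
#' and wider illumination range than V1, emulating a held-out-viewpoint
#' protocol. Per-scene seeds are derived as `seed + image index`, so the
#' output is deterministic.
#'
#' @param spec a [sceneSpec()].
#' @param n_images number of scenes.
#' @param view_labels character vector of length `n_images`, or a named
#'   count vector such as `c(V1 = 130, V2 = 10, V3 = 10)`.
#' @param seed base seed.
#' @param out_dir output directory (created if needed).
#' @return the written `"FruitDataset"` (invisibly), with `file_name`
#'   fields pointing into `out_dir/images`.
#' @export
generateDataset <- function(spec, n_images, view_labels = NULL, seed = 1L,
                            out_dir) {
  if (n_images < 1L) stop("n_images must be >= 1")
  if (is.null(view_labels)) view_labels <- rep("V1", n_images)
  if (!is.null(names(view_labels)))
    view_labels <- rep(names(view_labels), as.integer(view_labels))
  if (length(view_labels) != n_images)
    stop("view_labels must cover all images")
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  images <- list()
  ann_id0 <- 0
  for (i in seq_len(n_images)) {
    sc <- generateScene(.view_spec(spec, view_labels[i]), seed = seed + i)
    fn <- sprintf("images/scene_%04d.png", i)
    writeImageRGB(sc$pixels, file.path(out_dir, fn))
    ann <- sc$annotations
    if (nrow(ann) > 0L) ann$ann_id <- ann_id0 + seq_len(nrow(ann))
    ann_id0 <- ann_id0 + nrow(ann)
    images[[as.character(i)]] <- list(id = i, file_name = fn,
                                      width = spec$width, height = spec$height,
                                      view = view_labels[i], annotations = ann)
  }
  ds <- structure(list(images = images,
                       categories = data.frame(coco_id = c(1, 2),
                                               name = c("ripe", "unripe"),
                                               class_id = c(1L, 2L))),
                  class = "FruitDataset")
  writeCoco(ds, file.path(out_dir, "annotations.json"))
  invisible(ds)
}
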