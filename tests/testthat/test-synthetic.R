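# Synthetic scene generator: determinism, geometry, colour structure.

test_that("scene contains the requested berries with exact counts", {
  spec <- sceneSpec(n_ripe = 3, n_unripe = 5)
  sc <- generateScene(spec, seed = 7)
  expect_equal(nrow(sc$annotations), 8)
  expect_equal(sum(sc$annotations$class == "ripe"), 3)
  expect_equal(sum(sc$annotations$class == "unripe"), 5)
  expect_true(all(sc$pixels >= 0 & sc$pixels <= 1))
  expect_true(all(sc$annotations$x_max > sc$annotations$x_min))
})

test_that("generation is bitwise deterministic given (spec, seed)", {
  spec <- sceneSpec()
  expect_identical(generateScene(spec, 11), generateScene(spec, 11))
  expect_false(identical(generateScene(spec, 11)$pixels,
                         generateScene(spec, 12)$pixels))
})

test_that("ground-truth boxes tightly contain the rendered berries", {
  # render each berry onto an otherwise black scene by zeroing clutter and
  # checking that lit red pixels stay inside the ripe boxes (within 1 px)
  spec <- sceneSpec(n_ripe = 2, n_unripe = 0, clutter_density = 0,
                    illumination_gain = 1)
  sc <- generateScene(spec, seed = 3)
  ann <- sc$annotations
  red <- sc$pixels[, , 1] - sc$pixels[, , 2]
  lit <- which(red > 0.2, arr.ind = TRUE) # berry pixels (background is green)
  cx <- lit[, 2] - 0.5; cy <- lit[, 1] - 0.5
  inside <- rep(FALSE, nrow(lit))
  for (b in seq_len(nrow(ann)))
    inside <- inside | (cx >= ann$x_min[b] - 1 & cx <= ann$x_max[b] + 1 &
                          cy >= ann$y_min[b] - 1 & cy <= ann$y_max[b] + 1)
  expect_true(all(inside))
  # and each box is tight: some lit pixel within 2px of each edge
  for (b in seq_len(nrow(ann))) {
    inb <- cx >= ann$x_min[b] & cx <= ann$x_max[b] &
      cy >= ann$y_min[b] & cy <= ann$y_max[b]
    expect_lt(min(cx[inb]) - ann$x_min[b], 2)
    expect_lt(ann$x_max[b] - max(cx[inb]), 2)
    expect_lt(min(cy[inb]) - ann$y_min[b], 2)
    expect_lt(ann$y_max[b] - max(cy[inb]), 2)
  }
})

berry_pixel_mask <- function(sc, classes = c("ripe", "unripe")) {
  ann <- sc$annotations[sc$annotations$class %in% classes, ]
  h <- dim(sc$pixels)[1]
  idx <- integer(0)
  for (b in seq_len(nrow(ann))) {
    rows <- max(1, ceiling(ann$y_min[b] + 2)):floor(ann$y_max[b] - 1)
    cols <- max(1, ceiling(ann$x_min[b] + 2)):floor(ann$x_max[b] - 1)
    idx <- c(idx, as.vector(outer(rows, (cols - 1) * h, "+")))
  }
  unique(idx)
}

test_that("ripe berries sit higher on the red-green opponent axis", {
  spec <- sceneSpec(n_ripe = 3, n_unripe = 3)
  for (seed in 1:5) {
    sc <- generateScene(spec, seed = seed)
    lab <- pixels(rgbToLab(ColourImage(sc$pixels)))
    a <- lab[, , 2]
    expect_gt(mean(a[berry_pixel_mask(sc, "ripe")]),
              mean(a[berry_pixel_mask(sc, "unripe")]))
  }
})

test_that("illumination gain moves L while opponents move less (relative)", {
  base <- sceneSpec(n_ripe = 3, n_unripe = 3, illumination_gain = 1)
  dim_ <- base; dim_$illumination_gain <- 0.5
  s1 <- generateScene(base, seed = 9)
  s2 <- generateScene(dim_, seed = 9)
  # identical geometry, only the gain differs
  expect_equal(s1$annotations, s2$annotations)
  lab1 <- pixels(rgbToLab(ColourImage(s1$pixels)))
  lab2 <- pixels(rgbToLab(ColourImage(s2$pixels)))
  idx <- berry_pixel_mask(s1)
  dL <- (lab1[, , 1] - lab2[, , 1])[idx]
  da <- (lab1[, , 2] - lab2[, , 2])[idx]
  db <- (lab1[, , 3] - lab2[, , 3])[idx]
  expect_true(all(dL > 0)) # dimming lowers L at every berry pixel
  # relative change in L exceeds the relative change in a and b
  relL <- mean(abs(dL) / pmax(abs(lab1[, , 1][idx]), 1))
  rela <- mean(abs(da) / pmax(abs(lab1[, , 2][idx]), 1))
  relb <- mean(abs(db) / pmax(abs(lab1[, , 3][idx]), 1))
  expect_gt(relL, rela)
  expect_gt(relL, relb)
  # L absorbs the majority of the Lab-space shift at most berry pixels
  expect_gt(mean(abs(dL) > sqrt(da^2 + db^2)), 0.5)
})

test_that("impossible placements fail after bounded attempts", {
  spec <- sceneSpec(height = 64, width = 64, n_ripe = 12, n_unripe = 0,
                    berry_radius = c(25, 28), occlusion_max = 0.01)
  expect_error(generateScene(spec, 1), "1000 attempts")
  expect_error(sceneSpec(illumination_gain = 0), "gain")
  expect_error(sceneSpec(n_ripe = -1), "counts")
})

test_that("generated datasets round-trip exactly through COCO", {
  out <- file.path(tempdir(), "synthds")
  spec <- sceneSpec(height = 64, width = 64, n_ripe = 1, n_unripe = 2,
                    berry_radius = c(6, 10))
  ds <- generateDataset(spec, 6, view_labels = c(V1 = 4, V2 = 1, V3 = 1),
                        seed = 21, out_dir = out)
  expect_equal(length(ds$images), 6)
  views <- vapply(ds$images, function(im) im$view, "")
  expect_equal(unname(table(views)[c("V1", "V2", "V3")]),
               array(c(4L, 1L, 1L)), ignore_attr = TRUE)
  rt <- readCoco(file.path(out, "annotations.json"))
  for (i in as.character(1:6)) {
    expect_equal(rt$images[[i]]$annotations[, -1],
                 ds$images[[i]]$annotations[, -1], tolerance = 1e-12)
    expect_equal(rt$images[[i]]$view, ds$images[[i]]$view)
  }
  # per-class totals conserved across scenes
  tot <- sum(vapply(ds$images, function(im) nrow(im$annotations), 0))
  expect_equal(tot, 6 * 3)
  # images written and loadable
  px <- loadImageRGB(file.path(out, ds$images[["1"]]$file_name))
  expect_equal(dim(px), c(64L, 64L, 3L))
  # regenerating a scene with the derived seed reproduces the pixels
  sc <- generateScene(spec, seed = 21 + 1)
  expect_lt(max(abs(px - sc$pixels)), 1 / 254) # 8-bit quantisation only
})
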