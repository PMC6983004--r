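## Colour-opponent front end: sRGB -> XYZ (D65) -> CIELab, and depth-wise
## early fusion of the RGB and Lab representations into the network input.

# D65 RGB->XYZ matrix (rows X, Y, Z); applied to RGB in [0,1], result x100.
.xyz_matrix <- matrix(c(
  0.412453, 0.357580, 0.180423,
  0.212671, 0.715160, 0.072169,
  0.019334, 0.119193, 0.950227), nrow = 3, byrow = TRUE,
  dimnames = list(c("X", "Y", "Z"), c("R", "G", "B")))

# D65 reference white on the 0-100 scale.
.d65_white <- c(X = 95.047, Y = 100.000, Z = 108.883)

#' D65 conversion constants
#'
#' The 3x3 RGB-to-XYZ matrix and the reference-white tristimulus values
#' (Xn, Yn, Zn) used by the colour-opponent transform, both for the CIE D65
#' illuminant.
#'
#' @return `d65Matrix()` the 3x3 matrix; `d65White()` the named length-3
#'   vector on the 0--100 scale.
#' @export
d65Matrix <- function() .xyz_matrix

#' @rdname d65Matrix
#' @export
d65White <- function() .d65_white

.as_pixels <- function(img, class_hint = NULL) {
  if (is(img, "ChannelImage")) return(img@pixels)
  if (is.array(img) && length(dim(img)) == 3L) return(img)
  stop("expected a ChannelImage or an H x W x C array")
}

# inverse sRGB companding (IEC 61966-2-1)
.srgb_linearize <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

#' RGB to CIE XYZ conversion (D65)
#'
#' Applies the linear D65 RGB-to-XYZ matrix to an RGB image with values in
#' `[0,1]` and scales the result by 100 so that the reference white has
#' Y = 100. In `"srgb_linearized"` mode (the colourimetrically correct
#' treatment of camera PNG/JPEG data) the standard sRGB inverse gamma is
#' applied before the matrix; `"naive"` mode applies the matrix directly to
#' the stored values.
#'
#' @param img a [ColourImage-class] or `H x W x 3` array in `[0,1]`.
#' @param mode `"srgb_linearized"` (default) or `"naive"`.
#' @return An [XYZImage-class] with tristimulus values on the 0--100 scale.
#' @export
rgbToXyz <- function(img, mode = c("srgb_linearized", "naive")) {
  mode <- match.arg(mode)
  px <- .as_pixels(img)
  rng <- range(px)
  if (rng[1] < 0 || rng[2] > 1)
    stop(sprintf("RGB values must lie in [0,1]; offending extreme %g",
                 if (rng[1] < 0) rng[1] else rng[2]))
  if (mode == "srgb_linearized" &&
      !(is(img, "ColourImage") && img@space == "linear_rgb"))
    px <- .srgb_linearize(px)
  d <- dim(px)
  flat <- matrix(px, ncol = 3L)           # (H*W) x 3, columns R,G,B
  xyz <- 100 * (flat %*% t(.xyz_matrix))  # (H*W) x 3, columns X,Y,Z
  XYZImage(array(xyz, d))
}

# CIE f(): cube root above (6/29)^3, linear continuation below
.lab_f <- function(x) {
  delta <- 6 / 29
  ifelse(x > delta^3, x^(1 / 3), x / (3 * delta^2) + 4 / 29)
}

#' CIE XYZ to CIELab conversion (D65)
#'
#' L = 116 f(Y/Yn) - 16, a = 500 (f(X/Xn) - f(Y/Yn)),
#' b = 200 (f(Y/Yn) - f(Z/Zn)), with f the CIE cube-root function with
#' linear continuation below (6/29)^3 and (Xn, Yn, Zn) the D65 white.
#'
#' @param img an [XYZImage-class] or `H x W x 3` array of tristimulus values
#'   on the 0--100 scale.
#' @return A [LabImage-class]; channels ordered (L, a, b).
#' @export
xyzToLab <- function(img) {
  px <- .as_pixels(img)
  if (min(px) < -1e-9)
    stop(sprintf("negative tristimulus value %g", min(px)))
  px[px < 0] <- 0
  d <- dim(px)
  flat <- matrix(px, ncol = 3L)
  fx <- .lab_f(flat[, 1] / .d65_white["X"])
  fy <- .lab_f(flat[, 2] / .d65_white["Y"])
  fz <- .lab_f(flat[, 3] / .d65_white["Z"])
  lab <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  LabImage(array(lab, d))
}

#' RGB to CIELab conversion (D65)
#'
#' Composition of [rgbToXyz()] and [xyzToLab()].
#'
#' @inheritParams rgbToXyz
#' @return A [LabImage-class].
#' @export
rgbToLab <- function(img, mode = c("srgb_linearized", "naive")) {
  xyzToLab(rgbToXyz(img, match.arg(mode)))
}

#' Per-channel affine scaling statistics
#'
#' A (mean, sd) pair per channel; channels are transformed as
#' `(value - mean) / sd`.
#'
#' @param mean,sd numeric vectors of equal length; all `sd` strictly
#'   positive.
#' @return An object of class `"ChannelStats"`.
#' @export
channelStats <- function(mean, sd) {
  if (length(mean) != length(sd)) stop("mean and sd must have equal length")
  if (any(sd <= 0)) stop("all standard deviations must be strictly positive")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd)),
            class = "ChannelStats")
}

#' @export
print.ChannelStats <- function(x, ...) {
  cat("ChannelStats:", length(x$mean), "channel(s)\n")
  print(data.frame(mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Default rescaling of Lab channels before fusion
#'
#' Maps L from `[0,100]` to `[0,1]` and a, b from approximately
#' `[-128,127]` to `[0,1]` so the opponent channels share the RGB channels'
#' dynamic range: L/100, (a+128)/255, (b+128)/255.
#'
#' @return A [channelStats()] object for the (L, a, b) channels.
#' @export
labFusionScaling <- function() channelStats(mean = c(0, -128, -128),
                                            sd = c(100, 255, 255))

#' Depth-wise early fusion of RGB and CIELab channels
#'
#' Stacks the RGB image and its (rescaled) Lab representation into a single
#' six-channel tensor with layout (R, G, B, L, a, b) — the network input of
#' the early-fusion detector. The first three channels equal the RGB input
#' exactly; the Lab channels are rescaled per `lab_scaling`.
#'
#' @param rgb a [ColourImage-class] or array.
#' @param lab the matching [LabImage-class] or array (same H, W).
#' @param lab_scaling a [channelStats()] for the Lab channels;
#'   default [labFusionScaling()].
#' @return A [FusedTensor][ChannelImage-class] of depth 6.
#' @export
earlyFuse <- function(rgb, lab, lab_scaling = labFusionScaling()) {
  rp <- .as_pixels(rgb); lp <- .as_pixels(lab)
  if (!identical(dim(rp)[1:2], dim(lp)[1:2]))
    stop(sprintf("shape mismatch: rgb %dx%d vs lab %dx%d",
                 dim(rp)[1], dim(rp)[2], dim(lp)[1], dim(lp)[2]))
  stopifnot(is(lab_scaling, "ChannelStats"), length(lab_scaling$mean) == 3L)
  for (c in 1:3)
    lp[, , c] <- (lp[, , c] - lab_scaling$mean[c]) / lab_scaling$sd[c]
  fused <- array(c(rp, lp), c(dim(rp)[1:2], 6L))
  new("FusedTensor", pixels = fused,
      channelLayout = c("R", "G", "B", "L", "a", "b"))
}

#' Standardize / de-standardize a network input tensor
#'
#' Per-channel affine standardization `(value - mean)/sd`, invertible given
#' the same statistics.
#'
#' @param t a [FusedTensor][ChannelImage-class] or `H x W x C` array.
#' @param stats a [channelStats()] with one (mean, sd) pair per channel.
#' @return Object of the same kind as `t`.
#' @export
standardizeTensor <- function(t, stats) {
  px <- .as_pixels(t)
  if (length(stats$mean) != dim(px)[3])
    stop("stats must provide one (mean, sd) pair per channel")
  for (c in seq_len(dim(px)[3]))
    px[, , c] <- (px[, , c] - stats$mean[c]) / stats$sd[c]
  if (is(t, "FusedTensor")) { t@pixels <- px; t } else px
}

#' @rdname standardizeTensor
#' @export
unstandardizeTensor <- function(t, stats) {
  px <- .as_pixels(t)
  if (length(stats$mean) != dim(px)[3])
    stop("stats must provide one (mean, sd) pair per channel")
  for (c in seq_len(dim(px)[3]))
    px[, , c] <- px[, , c] * stats$sd[c] + stats$mean[c]
  if (is(t, "FusedTensor")) { t@pixels <- px; t } else px
}

#' Channel statistics estimated from a set of tensors
#'
#' @param tensors list of `H x W x C` arrays or [ChannelImage-class] objects
#'   with a common channel count.
#' @return A [channelStats()] with the pooled per-channel mean and sd
#'   (sd floored at 1e-6).
#' @export
estimateChannelStats <- function(tensors) {
  mats <- lapply(tensors, function(t) matrix(.as_pixels(t), ncol = dim(.as_pixels(t))[3]))
  all <- do.call(rbind, mats)
  channelStats(mean = colMeans(all), sd = pmax(apply(all, 2, stats::sd), 1e-6))
}
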