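#' Image containers
#'
#' Light S4 containers around `H x W x C` numeric arrays carrying the
#' representations the detector front end moves between: gamma-encoded or
#' linear RGB in `[0,1]` (\code{ColourImage}), CIE tristimulus values on the
#' 0--100 scale (\code{XYZImage}), CIELab opponent coordinates
#' (\code{LabImage}) and the depth-wise fused network input
#' (\code{FusedTensor}).
#'
#' @slot pixels numeric `H x W x C` array.
#' @name ChannelImage-class
#' @aliases ChannelImage
#' @exportClass ChannelImage
setClass("ChannelImage", representation("VIRTUAL", pixels = "array"))

setValidity("ChannelImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L) return("pixels must be an H x W x C array")
  if (d[1] < 1L || d[2] < 1L) return("image must have H >= 1 and W >= 1")
  if (anyNA(object@pixels)) return("pixels contain NA")
  TRUE
})

#' @rdname ChannelImage-class
#' @slot space one of `"srgb_gamma"`, `"linear_rgb"`: how the stored RGB
#'   values are encoded.
#' @exportClass ColourImage
setClass("ColourImage", contains = "ChannelImage",
         representation(space = "character"))

setValidity("ColourImage", function(object) {
  if (dim(object@pixels)[3] != 3L) return("RGB image must have 3 channels")
  if (!object@space %in% c("srgb_gamma", "linear_rgb"))
    return("space must be 'srgb_gamma' or 'linear_rgb'")
  rng <- range(object@pixels)
  if (rng[1] < 0 || rng[2] > 1)
    return(sprintf("RGB values must lie in [0,1]; found extreme %g",
                   if (rng[1] < 0) rng[1] else rng[2]))
  TRUE
})

#' @rdname ChannelImage-class
#' @exportClass XYZImage
setClass("XYZImage", contains = "ChannelImage")

setValidity("XYZImage", function(object) {
  if (dim(object@pixels)[3] != 3L) return("XYZ image must have 3 channels")
  if (min(object@pixels) < -1e-9)
    return(sprintf("negative tristimulus value %g", min(object@pixels)))
  TRUE
})

#' @rdname ChannelImage-class
#' @exportClass LabImage
setClass("LabImage", contains = "ChannelImage")

setValidity("LabImage", function(object) {
  if (dim(object@pixels)[3] != 3L) return("Lab image must have 3 channels")
  TRUE
})

#' @rdname ChannelImage-class
#' @slot channelLayout character vector naming the stacked channels in order.
#' @exportClass FusedTensor
setClass("FusedTensor", contains = "ChannelImage",
         representation(channelLayout = "character"))

setValidity("FusedTensor", function(object) {
  d <- dim(object@pixels)[3]
  if (!d %in% c(3L, 6L)) return("fused tensor depth must be 3 or 6")
  if (length(object@channelLayout) != d)
    return("channelLayout length must equal tensor depth")
  if (d == 6L && !identical(object@channelLayout, c("R", "G", "B", "L", "a", "b")))
    return("6-channel layout must be (R,G,B,L,a,b)")
  TRUE
})

#' Construct a ColourImage
#'
#' @param pixels numeric `H x W x 3` array with values in `[0,1]`
#'   (8-bit images divided by 255).
#' @param space `"srgb_gamma"` (camera PNG/JPEG, the default) or
#'   `"linear_rgb"`.
#' @return A [ColourImage-class] object.
#' @export
ColourImage <- function(pixels, space = "srgb_gamma") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  new("ColourImage", pixels = pixels, space = space)
}

#' @rdname ColourImage
#' @export
XYZImage <- function(pixels) new("XYZImage", pixels = pixels)

#' @rdname ColourImage
#' @export
LabImage <- function(pixels) new("LabImage", pixels = pixels)

#' Extract the pixel array from an image container
#'
#' @param x a [ChannelImage-class] derivative.
#' @return The underlying numeric `H x W x C` array.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setMethod("pixels", "ChannelImage", function(x) x@pixels)

#' Channel names of a fused tensor
#'
#' @param x a [FusedTensor][ChannelImage-class].
#' @return Character vector of channel names in stacking order.
#' @export
setGeneric("channelLayout", function(x) standardGeneric("channelLayout"))

#' @rdname channelLayout
#' @export
setMethod("channelLayout", "FusedTensor", function(x) x@channelLayout)

setMethod("show", "ChannelImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("%s %dx%d, %d channel(s), range [%.4g, %.4g]\n",
              class(object), d[1], d[2], d[3],
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "FusedTensor", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("FusedTensor %dx%dx%d, layout (%s)\n", d[1], d[2], d[3],
              paste(object@channelLayout, collapse = ",")))
})

#' @rdname pixels
#' @param value replacement array
setGeneric("pixels<-", function(x, value) standardGeneric("pixels<-"))

setMethod("pixels<-", "ChannelImage", function(x, value) {
  x@pixels <- value
  validObject(x)
  x
})
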