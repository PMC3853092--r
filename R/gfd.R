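# Dispatcher assembling the full generic-descriptor bank for one image.

#' Generic feature descriptor configuration
#'
#' Default settings of the descriptor bank: moment orders 2/4/8/16 for
#' the three moment families, a 5 x 12 polar Fourier grid, 8-bin GLCMs at
#' distances 1..5 and four angles, a 6-orientation x 5-scale Gabor bank,
#' and a 10-level Daubechies-4 decomposition.
#'
#' @param momentOrders orders of the Zernike/Legendre/Tchebichef moments.
#' @param gfAngles,gfFrequencies polar Fourier grid.
#' @param glcmBins,glcmDistances GLCM quantization and offsets.
#' @param gaborOrientations,gaborScales Gabor bank shape.
#' @param waveletLevels wavelet decomposition depth.
#' @param families which descriptor families to compute.
#' @return list of class `"GFDConfig"`.
#' @export
gfdConfig <- function(momentOrders = c(2, 4, 8, 16),
                      gfAngles = 5, gfFrequencies = 12,
                      glcmBins = 8, glcmDistances = 1:5,
                      gaborOrientations = 6, gaborScales = 5,
                      waveletLevels = 10,
                      families = c("zernike", "legendre", "tchebichef",
                                   "genericFourier", "haralick", "gabor",
                                   "daubechies4")) {
  stopifnot(all(momentOrders > 0), gfAngles > 0, gfFrequencies > 0)
  structure(list(momentOrders = momentOrders, gfAngles = gfAngles,
                 gfFrequencies = gfFrequencies, glcmBins = glcmBins,
                 glcmDistances = glcmDistances,
                 gaborOrientations = gaborOrientations,
                 gaborScales = gaborScales,
                 waveletLevels = waveletLevels,
                 families = families),
            class = "GFDConfig")
}

#' Extract the generic descriptor bank
#'
#' Shape families (Zernike, Legendre, Tchebichef moments at each
#' configured order; generic Fourier) are computed on the binary
#' foreground mask; texture families (Haralick, Gabor, Daubechies-4) on
#' the grayscale image. Feature counts depend only on the configuration,
#' never on image content. An empty mask is an error for the shape
#' families but leaves the texture families computable.
#'
#' @param image numeric grayscale matrix.
#' @param mask logical foreground mask of the same shape.
#' @param config a [gfdConfig()].
#' @return named list of named numeric vectors, one per family.
#' @export
extractGFD <- function(image, mask, config = gfdConfig()) {
  if (!is.null(mask) && !identical(dim(image), dim(mask)))
    stop("image and mask must have the same shape")
  fam <- config$families
  out <- list()
  concatOrders <- function(fun, prefix) {
    vs <- lapply(config$momentOrders, function(o) {
      v <- fun(mask, o)
      names(v) <- sprintf("%s_o%d_%s", prefix, o, names(v))
      v
    })
    do.call(c, vs)
  }
  if ("zernike" %in% fam)
    out$zernike <- concatOrders(zernikeFeatures, "zern")
  if ("legendre" %in% fam)
    out$legendre <- concatOrders(legendreFeatures, "leg")
  if ("tchebichef" %in% fam)
    out$tchebichef <- concatOrders(tchebichefFeatures, "tcheb")
  if ("genericFourier" %in% fam)
    out$genericFourier <- genericFourierFeatures(
      mask, config$gfAngles, config$gfFrequencies)
  if ("haralick" %in% fam)
    out$haralick <- haralickFeatures(image, config$glcmDistances,
                                     config$glcmBins)
  if ("gabor" %in% fam)
    out$gabor <- gaborFeatures(image, config$gaborOrientations,
                               config$gaborScales)
  if ("daubechies4" %in% fam)
    out$daubechies4 <- daubechies4Features(image, config$waveletLevels)
  out
}
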