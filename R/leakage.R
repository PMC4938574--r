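#' Mean fluorescence intensity under a zone mask
#'
#' Arithmetic mean of pixel intensities at mask-positive positions.
#'
#' @param img a [calibrated_image()].
#' @param mask logical matrix congruent with the image.
#' @return mean intensity (image grey-level units).
#' @export
zone_mfi <- function(img, mask) {
  stopifnot(inherits(img, "CalibratedImage"))
  if (!is.logical(mask) || !identical(dim(mask), dim(img$pixels)))
    stop_capmorph("mask must be a logical matrix congruent with the image")
  if (!any(mask)) stop_capmorph("empty zone mask")
  mean(img$pixels[mask])
}

#' Zone MFI ratios for microsphere leakage
#'
#' Computes the mean fluorescence intensity of the microsphere channel in each
#' zone and expresses leakage as the ratio between the infarct zone (core
#' union border) and the remote control zone, plus separate border/control and
#' core/control ratios. A ratio near 1 indicates no extravasation; a multiple
#' of control indicates leakage. Border >> core reproduces the no-reflow
#' pattern in which the infarct core is inaccessible to the tracer.
#'
#' @param img microsphere-channel [calibrated_image()].
#' @param zones a [zone_mask_set()].
#' @return list of class `LeakageMetrics` with per-zone MFIs and ratios.
#' @export
mfi_ratio <- function(img, zones) {
  stopifnot(inherits(zones, "ZoneMaskSet"))
  mfi_core <- zone_mfi(img, zones$infarct_core)
  mfi_border <- zone_mfi(img, zones$infarct_border)
  mfi_infarct <- zone_mfi(img, zones$infarct_core | zones$infarct_border)
  mfi_control <- zone_mfi(img, zones$control)
  if (mfi_control <= 0)
    stop_capmorph("control-zone MFI is zero; ratio undefined")
  structure(
    list(mfi_infarct = mfi_infarct, mfi_border = mfi_border,
         mfi_core = mfi_core, mfi_control = mfi_control,
         ratio_infarct_control = mfi_infarct / mfi_control,
         ratio_border_control = mfi_border / mfi_control,
         ratio_core_control = mfi_core / mfi_control),
    class = "LeakageMetrics")
}

#' @export
print.LeakageMetrics <- function(x, ...) {
  cat(sprintf(
    "LeakageMetrics: infarct/control %.3f (border %.3f, core %.3f)\n",
    x$ratio_infarct_control, x$ratio_border_control, x$ratio_core_control))
  invisible(x)
}

#' Otsu threshold of an image
#'
#' Maximises between-class variance on the intensity histogram.
#'
#' @param img a [calibrated_image()] or numeric matrix.
#' @param n_bins histogram resolution.
#' @return threshold on the image intensity scale; pixels strictly above it
#'   are "positive".
#' @export
otsu_threshold <- function(img, n_bins = 256L) {
  v <- if (inherits(img, "CalibratedImage")) as.vector(img$pixels) else as.vector(img)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Pixel-based colocalisation fraction
#'
#' Binarises the microsphere and CD31 channels and returns the fraction of
#' sphere-positive pixels that are also CD31-positive:
#' `|spheres+ AND cd31+| / |spheres+|`. By default each channel is thresholded
#' with Otsu's method; fixed cut-offs may be supplied instead (pixels strictly
#' above the cut-off are positive).
#'
#' @param spheres,cd31 congruent [calibrated_image()] objects.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param sphere_threshold,cd31_threshold fixed cut-offs (required when
#'   `threshold_method = "fixed"`).
#' @return fraction in `[0, 1]`, with the thresholds used attached as the
#'   `"thresholds"` attribute.
#' @export
colocalisation_fraction <- function(spheres, cd31,
                                    threshold_method = c("otsu", "fixed"),
                                    sphere_threshold = NULL,
                                    cd31_threshold = NULL) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(inherits(spheres, "CalibratedImage"), inherits(cd31, "CalibratedImage"))
  if (!identical(dim(spheres$pixels), dim(cd31$pixels)))
    stop_capmorph("sphere and CD31 images must be congruent")
  if (threshold_method == "otsu") {
    sphere_threshold <- otsu_threshold(spheres)
    cd31_threshold <- otsu_threshold(cd31)
  } else if (is.null(sphere_threshold) || is.null(cd31_threshold)) {
    stop_capmorph("fixed thresholding requires sphere_threshold and cd31_threshold")
  }
  sp <- spheres$pixels > sphere_threshold
  cp <- cd31$pixels > cd31_threshold
  n_sp <- sum(sp)
  if (n_sp == 0) stop_capmorph("no sphere-positive pixels: fraction undefined")
  frac <- sum(sp & cp) / n_sp
  attr(frac, "thresholds") <- c(spheres = sphere_threshold, cd31 = cd31_threshold)
  frac
}
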