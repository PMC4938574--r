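#' Capillary density from fixed counting frames
#'
#' Per-frame density is the capillary count divided by the frame area in mm^2;
#' the estimate is the mean and standard deviation of the per-frame densities.
#' This matches counting CD31-positive, SMA-negative vessels in a fixed
#' 200 x 200 um frame.
#'
#' @param frames list of [frame_count()] records sharing frame dimensions.
#' @return list of class `DensityEstimate` with `zone_label`, `n_frames`,
#'   `mean_density`, `sd_density` (capillaries/mm^2).
#' @export
density_from_frames <- function(frames) {
  if (length(frames) == 0) stop_capmorph("no counting frames supplied")
  if (inherits(frames, "FrameCount")) frames <- list(frames)
  w <- vapply(frames, `[[`, numeric(1), "frame_width_um")
  h <- vapply(frames, `[[`, numeric(1), "frame_height_um")
  if (length(unique(w)) != 1 || length(unique(h)) != 1)
    stop_capmorph("frames must share dimensions")
  area_mm2 <- w[1] * h[1] / 1e6
  if (area_mm2 <= 0) stop_capmorph("zero frame area")
  counts <- vapply(frames, `[[`, numeric(1), "count")
  dens <- counts / area_mm2
  structure(
    list(zone_label = frames[[1]]$zone_label,
         n_frames = length(frames),
         mean_density = mean(dens),
         sd_density = if (length(dens) > 1) stats::sd(dens) else NA_real_),
    class = "DensityEstimate")
}

#' @export
print.DensityEstimate <- function(x, ...) {
  cat(sprintf("DensityEstimate [%s]: %.1f +/- %.1f capillaries/mm^2 (%d frames)\n",
              x$zone_label, x$mean_density,
              if (is.na(x$sd_density)) 0 else x$sd_density, x$n_frames))
  invisible(x)
}

#' Capillary density from a TEM section
#'
#' Number of visible capillaries per square millimetre of section.
#'
#' @param capillary_count non-negative count of visible capillaries.
#' @param section_area_mm2 section area in mm^2 (> 0).
#' @return density in capillaries/mm^2.
#' @export
tem_density <- function(capillary_count, section_area_mm2) {
  if (section_area_mm2 <= 0) stop_capmorph("section area must be positive")
  if (capillary_count < 0) stop_capmorph("capillary count must be non-negative")
  capillary_count / section_area_mm2
}

#' Compare density estimates from two imaging modalities
#'
#' Paired difference between per-sample IHC and TEM density estimates for the
#' same zone: difference of means plus a paired t-test when per-sample vectors
#' are supplied.
#'
#' @param ihc,tem either `DensityEstimate` objects or numeric vectors of
#'   per-sample densities (paired, equal length).
#' @return list with `mean_difference` (tem - ihc) and, when paired vectors
#'   are given, `t_statistic`, `df`, `p_value` (two-sided).
#' @export
compare_modalities <- function(ihc, tem) {
  if (inherits(ihc, "DensityEstimate") && inherits(tem, "DensityEstimate")) {
    return(list(mean_difference = tem$mean_density - ihc$mean_density,
                t_statistic = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  ihc <- as.numeric(ihc); tem <- as.numeric(tem)
  if (length(ihc) != length(tem))
    stop_capmorph("paired comparison needs equal-length density vectors")
  d <- tem - ihc
  res <- list(mean_difference = mean(d))
  if (length(d) >= 2 && stats::sd(d) > 0) {
    t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
    df <- length(d) - 1
    res$t_statistic <- t
    res$df <- df
    res$p_value <- 2 * stats::pt(-abs(t), df)
  } else {
    res$t_statistic <- if (all(d == 0)) 0 else NA_real_
    res$df <- length(d) - 1
    res$p_value <- if (all(d == 0)) 1 else NA_real_
  }
  res
}
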