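#' Endothelial cytoplasm area
#'
#' Cytoplasm area is obtained by subtracting the lumen area and all nucleus
#' areas from the total vessel area, so the conservation identity
#' `total = lumen + nucleus + cytoplasm` holds exactly by construction.
#'
#' @param a a [capillary_annotation()].
#' @param nm_per_px calibration in nanometres per pixel.
#' @return cytoplasm area in um^2.
#' @export
cytoplasm_area <- function(a, nm_per_px) {
  total <- polygon_area(a$vessel_outer, nm_per_px)
  lum <- polygon_area(a$lumen, nm_per_px)
  nuc <- sum(vapply(a$nuclei, polygon_area, numeric(1), nm_per_px = nm_per_px))
  cyt <- total - lum - nuc
  if (cyt < -1e-9 * max(total, 1))
    stop_capmorph(
      "capillary '%s': lumen + nucleus area exceeds total vessel area",
      a$capillary_id)
  max(cyt, 0)
}

#' Mean cytoplasm (vessel wall) thickness
#'
#' The wall of a capillary cross-section is an annulus with two boundaries, so
#' "cytoplasm perimeter" is ambiguous. The default midline convention divides
#' the cytoplasm area by the mean of the outer-boundary and luminal perimeters;
#' for a circular annulus this equals the true wall width R - r exactly.
#' Nucleus boundaries never enter the perimeter term.
#'
#' @inheritParams cytoplasm_area
#' @param convention `"midline"` (default), `"outer"` (outer perimeter only) or
#'   `"summed"` (outer + luminal perimeter).
#' @return mean wall thickness in nm.
#' @export
mean_cytoplasm_thickness <- function(a, nm_per_px,
                                     convention = c("midline", "outer", "summed")) {
  convention <- match.arg(convention)
  cyt_um2 <- cytoplasm_area(a, nm_per_px)
  p_out <- polygon_perimeter(a$vessel_outer, nm_per_px)
  p_lum <- polygon_perimeter(a$lumen, nm_per_px)
  per <- switch(convention,
                midline = (p_out + p_lum) / 2,
                outer = p_out,
                summed = p_out + p_lum)
  if (per <= 0) stop_capmorph("capillary '%s': zero cytoplasm perimeter",
                              a$capillary_id)
  cyt_um2 / per * 1e3                          # um -> nm
}

#' Chromatin density variation (CDV)
#'
#' Dispersion of grey values within the nuclear area: the sample standard
#' deviation (n - 1 denominator) of the intensities of all pixels whose
#' centres fall inside the nucleus polygon. Condensed, late-apoptotic
#' chromatin appears homogeneous and gives a low CDV; healthy heterochromatin
#' speckling gives a high CDV.
#'
#' @param img a [calibrated_image()].
#' @param nucleus nucleus polygon in the image's pixel coordinates.
#' @return CDV in the image's grey-level units.
#' @export
chromatin_density_variation <- function(img, nucleus) {
  stopifnot(inherits(img, "CalibratedImage"))
  d <- dim(img$pixels)
  mask <- rasterize_polygon(nucleus, d[1], d[2])
  vals <- img$pixels[mask]
  if (length(vals) < 2L)
    stop_capmorph("nucleus region has fewer than 2 interior pixels")
  stats::sd(vals)
}

#' Count caveola or junction marks
#'
#' Caveolae are counted as total marks per capillary cross-section; for
#' caveolae the mean marked diameter is also returned (`NA` when there are no
#' marks).
#'
#' @param a a [capillary_annotation()].
#' @param kind `"caveolae"` or `"junctions"`.
#' @return list with `count` and, for caveolae, `mean_diameter_nm`.
#' @export
count_marks <- function(a, kind = c("caveolae", "junctions")) {
  kind <- match.arg(kind)
  if (kind == "junctions") return(list(count = nrow(a$junctions)))
  n <- nrow(a$caveolae)
  list(count = n,
       mean_diameter_nm = if (n > 0) mean(a$caveolae$diameter_nm) else NA_real_)
}

#' Measure one capillary
#'
#' Runs the full ultrastructural quantification on one annotated capillary:
#' areas (total vessel, lumen, nucleus, cytoplasm), mean cytoplasm thickness,
#' chromatin density variation, and caveola/junction counts. When several
#' nuclei are annotated, CDV is computed on the largest nucleus and
#' `nucleus_area_um2` sums all of them; with no nucleus, CDV is `NA`.
#'
#' @param img a [calibrated_image()] (may be `NULL`, in which case CDV is
#'   `NA`).
#' @param a a [capillary_annotation()].
#' @param nm_per_px calibration; must equal the image's calibration when an
#'   image is supplied.
#' @param convention perimeter convention for
#'   [mean_cytoplasm_thickness()].
#' @return one-row data.frame of per-capillary metrics.
#' @export
measure_capillary <- function(img, a, nm_per_px = NULL,
                              convention = "midline") {
  if (!is.null(img)) {
    stopifnot(inherits(img, "CalibratedImage"))
    if (!is.null(nm_per_px) && abs(nm_per_px - img$nm_per_px) > 1e-9)
      stop_capmorph("capillary '%s': annotation calibration (%g) conflicts with image calibration (%g)",
                    a$capillary_id, nm_per_px, img$nm_per_px)
    nm_per_px <- img$nm_per_px
  }
  if (is.null(nm_per_px))
    stop_capmorph("nm_per_px required when no image is supplied")
  total <- polygon_area(a$vessel_outer, nm_per_px)
  lum <- polygon_area(a$lumen, nm_per_px)
  nuc_areas <- vapply(a$nuclei, polygon_area, numeric(1), nm_per_px = nm_per_px)
  cyt <- cytoplasm_area(a, nm_per_px)
  thick <- mean_cytoplasm_thickness(a, nm_per_px, convention)
  p_out <- polygon_perimeter(a$vessel_outer, nm_per_px)
  p_lum <- polygon_perimeter(a$lumen, nm_per_px)
  cdv <- NA_real_
  if (length(a$nuclei) > 0 && !is.null(img)) {
    biggest <- a$nuclei[[which.max(nuc_areas)]]
    cdv <- chromatin_density_variation(img, biggest)
  }
  cav <- count_marks(a, "caveolae")
  jun <- count_marks(a, "junctions")
  data.frame(
    capillary_id = a$capillary_id,
    total_area_um2 = total,
    lumen_area_um2 = lum,
    nucleus_area_um2 = sum(nuc_areas),
    cytoplasm_area_um2 = cyt,
    cytoplasm_perimeter_um = (p_out + p_lum) / 2,
    thickness_nm = thick,
    cdv = cdv,
    n_caveolae = cav$count,
    mean_caveola_diameter_nm = cav$mean_diameter_nm,
    n_junctions = jun$count,
    stringsAsFactors = FALSE)
}

#' Measure a set of annotated capillaries
#'
#' Vectorized wrapper over [measure_capillary()]; `images` may be `NULL`
#' (no CDV), a single image, or a list parallel to `annotations`.
#'
#' @param images `NULL`, a [calibrated_image()] or list thereof.
#' @param annotations list of [capillary_annotation()].
#' @param nm_per_px calibration used when no image carries one.
#' @param convention perimeter convention.
#' @return data.frame, one row per capillary.
#' @export
measure_capillaries <- function(images, annotations, nm_per_px = NULL,
                                convention = "midline") {
  rows <- lapply(seq_along(annotations), function(i) {
    img <- if (is.null(images)) NULL
    else if (inherits(images, "CalibratedImage")) images
    else images[[i]]
    measure_capillary(img, annotations[[i]], nm_per_px, convention)
  })
  do.call(rbind, rows)
}
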