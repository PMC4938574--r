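#' Experimental group presets for the synthetic generator
#'
#' One named parameter bundle per experimental group x zone. The three groups
#' are 30 min ischemia ("I30"), 90 min ischemia ("I90") and 30 min ischemia +
#' 60 min reperfusion ("IR30-60"), each with an infarct-zone and a remote
#' control-zone preset. Printed group values (means +/- dispersions) drive the
#' generator; quantities the source study reports only qualitatively
#' (control-zone wall thickness and CDV, caveola Poisson means, control lumen
#' dispersions) are fixed once at field-plausible values reproducing the
#' reported orderings — see the methods vignette.
#'
#' Areas are in um^2, lengths in nm, densities in capillaries/mm^2. CDV is on
#' an 8-bit grey scale. `dispersion` declares how the `*_sd` entries are read:
#' `"sd"` (default) treats them as between-subject standard deviations,
#' `"sem"` rescales them by sqrt(n_animals) at draw time.
#'
#' @return named list of `GroupPreset` objects.
#' @export
group_presets <- function() {
  mk <- function(name, thick, thick_sd, total, total_sd, lumen, lumen_sd,
                 nucleus, nucleus_sd, cdv, cdv_sd, junctions, caveolae,
                 cav_diam, cav_diam_sd, ihc, ihc_sd, tem, tem_sd,
                 mfi_ratio, border_core_w, coloc) {
    structure(list(
      name = name,
      wall_thickness_nm = thick, wall_thickness_sd_nm = thick_sd,
      total_vessel_area_um2 = total, total_vessel_area_sd_um2 = total_sd,
      lumen_area_um2 = lumen, lumen_area_sd_um2 = lumen_sd,
      nucleus_area_um2 = nucleus, nucleus_area_sd_um2 = nucleus_sd,
      cdv_grey = cdv, cdv_grey_sd = cdv_sd,
      junctions_per_capillary = junctions,
      caveolae_per_capillary = caveolae,
      caveola_diameter_nm = cav_diam, caveola_diameter_sd_nm = cav_diam_sd,
      ihc_density_per_mm2 = ihc, ihc_density_sd = ihc_sd,
      tem_density_per_mm2 = tem, tem_density_sd = tem_sd,
      tem_section_area_mm2 = 0.04,
      frame_um = 200,
      mfi_ratio_infarct_control = mfi_ratio,
      border_to_core_weighting = border_core_w,
      colocalisation_target = coloc,
      n_capillaries_per_animal = 20L,
      n_animals = 10L,
      dispersion = "sd"),
      class = "GroupPreset")
  }
  list(
    "I30.infarct" = mk("I30.infarct", 407.8, 75, 36.8, 8.6, 17.9, 8.3,
                       8.4, 2.6, 50.5, 9.4, 2.5, 4, 100.2, 12.35,
                       1283, 57.9, 1586, 435, 1.2, 1, 0.25),
    "I90.infarct" = mk("I90.infarct", 407.5, 71, 30.2, 7.9, 9.75, 3.4,
                       9.9, 2.2, 35.4, 7.1, 1.8, 8, 97.14, 7.8,
                       638.1, 66.3, 1716, 283, 3, 1, 0.25),
    "IR30-60.infarct" = mk("IR30-60.infarct", 207.0, 74, 49, 20, 35.6, 15.2,
                           7.7, 2.8, 23.7, 3.8, 0.15, 2, 81.25, 26,
                           638.1, 66.3, 1185, 172.6, 3, 29, 0.25),
    "I30.control" = mk("I30.control", 400, 75, 19.56, 3.0, 2.2, 0.9,
                       8.4, 2.6, 45, 8, 2.5, 4, 100, 12,
                       1283, 57.9, 1600, 300, 1, 1, 0.25),
    "I90.control" = mk("I90.control", 400, 75, 13.7, 3.1, 0.95, 0.4,
                       5.7, 2.0, 45, 8, 2.5, 4, 100, 12,
                       1283, 57.9, 1600, 300, 1, 1, 0.25),
    "IR30-60.control" = mk("IR30-60.control", 400, 75, 19.7, 4.0, 1.8, 0.8,
                           6.5, 2.3, 45, 8, 2.5, 4, 100, 12,
                           1283, 57.9, 1600, 300, 1, 1, 0.25))
}

#' Look up a group preset by name
#'
#' @param name preset name, e.g. `"IR30-60.infarct"`. Bare group names
#'   (`"I30"`, `"I90"`, `"IR30-60"`) resolve to the infarct-zone preset.
#' @return a `GroupPreset`.
#' @export
get_preset <- function(name) {
  ps <- group_presets()
  if (name %in% c("I30", "I90", "IR30-60")) name <- paste0(name, ".infarct")
  p <- ps[[name]]
  if (is.null(p))
    stop_capmorph("unknown group preset '%s' (known: %s)", name,
                  paste(names(ps), collapse = ", "))
  validate_preset(p)
  p
}

validate_preset <- function(p) {
  if (p$lumen_area_um2 + p$nucleus_area_um2 >= p$total_vessel_area_um2)
    stop_capmorph("preset '%s': lumen + nucleus area must be below total vessel area",
                  p$name)
  pos <- c("wall_thickness_nm", "lumen_area_um2", "nucleus_area_um2",
           "cdv_grey", "caveola_diameter_nm", "ihc_density_per_mm2",
           "tem_density_per_mm2", "mfi_ratio_infarct_control")
  for (f in pos) if (p[[f]] <= 0)
    stop_capmorph("preset '%s': %s must be positive", p$name, f)
  if (p$colocalisation_target < 0 || p$colocalisation_target > 1)
    stop_capmorph("preset '%s': colocalisation target outside [0,1]", p$name)
  invisible(p)
}

# Effective capillary-level SD under the preset's dispersion reading.
preset_sd <- function(p, field_sd) {
  s <- p[[field_sd]]
  if (identical(p$dispersion, "sem")) s * sqrt(p$n_animals) else s
}

# Zone-level MFI ratios implied by the headline ratio and border:core
# weighting w (equal-area zones): border = 2rw/(1+w), core = 2r/(1+w).
preset_zone_ratios <- function(p) {
  r <- p$mfi_ratio_infarct_control
  w <- p$border_to_core_weighting
  list(core = 2 * r / (1 + w), border = 2 * r * w / (1 + w))
}
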