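## Synthetic TEM / fluorescence scene generator.
##
## Scenes are geometric phantoms with exact ground truth, not photorealistic
## micrographs: a capillary is an elliptical annulus (lumen ellipse, outer
## boundary its outward parallel curve), the endothelial nucleus a crescent
## lodged in the wall, chromatin an i.i.d. Gaussian texture. Every measurement
## operator in the package can be validated by round-trip recovery against the
## generating parameters.

# Ellipse boundary sampled at `n` parameter values, plus its outward parallel
# curve at distance `d` (px). Normals are the analytic ellipse normals, so the
# offset polygon tracks the true parallel curve to O(n^-2).
ellipse_polygon <- function(cx, cy, a, b, phi, n = 256L, offset = 0,
                            t_range = c(0, 2 * pi), closed = TRUE) {
  t <- seq(t_range[1], t_range[2], length.out = n + as.integer(closed))
  if (closed) t <- t[-length(t)]
  ct <- cos(t); st <- sin(t)
  px <- a * ct; py <- b * st
  if (offset != 0) {
    nx <- b * ct; ny <- a * st
    nn <- sqrt(nx^2 + ny^2)
    px <- px + offset * nx / nn
    py <- py + offset * ny / nn
  }
  x <- cx + px * cos(phi) - py * sin(phi)
  y <- cy + px * sin(phi) + py * cos(phi)
  cbind(x = x, y = y)
}

# Crescent between parallel curves at offsets d0 < d1, spanning parameter
# fraction `frac` starting at t0. Returned as a closed vertex loop.
crescent_polygon <- function(cx, cy, a, b, phi, d0, d1, t0, frac, n = 192L) {
  span <- 2 * pi * frac
  outer <- ellipse_polygon(cx, cy, a, b, phi, n = n, offset = d1,
                           t_range = c(t0, t0 + span), closed = FALSE)
  inner <- ellipse_polygon(cx, cy, a, b, phi, n = n, offset = d0,
                           t_range = c(t0, t0 + span), closed = FALSE)
  rbind(outer, inner[rev(seq_len(nrow(inner))), , drop = FALSE])
}

shoelace_px <- function(v) {
  x <- v[, 1]; y <- v[, 2]; n <- nrow(v); nxt <- c(2:n, 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

#' Generate one synthetic capillary TEM scene
#'
#' Draws wall thickness, lumen area, nucleus area, chromatin grey-level SD and
#' caveola/junction marks from the group preset (truncated normals / Poisson),
#' builds the exact generating contours as annotation polygons, and renders an
#' 8-bit raster: bright lumen, dark cytoplasm wall, nucleus filled with i.i.d.
#' Gaussian chromatin texture of the drawn SD (clipped to the 8-bit range).
#'
#' The outer boundary is the outward parallel curve of the lumen ellipse at a
#' distance solved so that the measured thickness (cytoplasm area over midline
#' perimeter, nucleus excluded) equals the drawn wall thickness. Draws whose
#' nucleus cannot fit in the wall annulus are redrawn (consistency
#' enforcement; this truncates only the extreme joint tail).
#'
#' @param preset a `GroupPreset` (see [group_presets()]) or preset name.
#' @param seed integer seed; the same seed reproduces the scene bit for bit.
#' @param nm_per_px calibration of the rendered scene (default 10 nm/px,
#'   matching high-magnification TEM).
#' @param capillary_id identifier for the annotation.
#' @param render if `FALSE`, skip rasterization and return `image = NULL`
#'   (annotation and ground truth are unaffected: all parameter draws happen
#'   before rendering).
#' @return list with `image` ([calibrated_image()] or `NULL`), `annotation`
#'   ([capillary_annotation()]) and `truth` (list of every drawn and realized
#'   parameter).
#' @export
generate_capillary <- function(preset, seed = NULL, nm_per_px = 10,
                               capillary_id = "cap-1", render = TRUE) {
  if (is.character(preset)) preset <- get_preset(preset)
  validate_preset(preset)
  with_seed(seed, {
    for (attempt in 1:100) {
      A_l <- rnorm_trunc(1, preset$lumen_area_um2,
                         preset_sd(preset, "lumen_area_sd_um2"),
                         lower = max(0.2, preset$lumen_area_um2 / 8))
      A_n <- rnorm_trunc(1, preset$nucleus_area_um2,
                         preset_sd(preset, "nucleus_area_sd_um2"),
                         lower = max(0.5, preset$nucleus_area_um2 / 8))
      w_nm <- rnorm_trunc(1, preset$wall_thickness_nm,
                          preset_sd(preset, "wall_thickness_sd_nm"),
                          lower = 30)
      w <- w_nm / 1e3                                   # um
      q <- stats::runif(1, 1, 1.6)                      # aspect ratio
      phi <- stats::runif(1, 0, pi)
      # smooth-ellipse geometry in um
      ae <- sqrt(A_l * q / pi); be <- sqrt(A_l / (pi * q))
      # Ramanujan perimeter of the lumen ellipse
      hh <- ((ae - be) / (ae + be))^2
      P_l <- pi * (ae + be) * (1 + 3 * hh / (10 + sqrt(4 - 3 * hh)))
      # wall offset d solving thickness identity (um)
      bq <- P_l - w * pi
      d <- (-bq + sqrt(bq^2 + 4 * pi * (A_n + w * P_l))) / (2 * pi)
      f_est <- A_n / (0.9 * d * (P_l + pi * d))
      if (f_est <= 0.92) break
    }
    if (f_est > 0.92)
      stop_capmorph("preset '%s': nucleus cannot fit in the wall annulus",
                    preset$name)
    px_per_um <- 1e3 / nm_per_px
    a_px <- ae * px_per_um; b_px <- be * px_per_um; d_px <- d * px_per_um
    margin <- 16
    half_w <- (max(a_px, b_px) + d_px) + margin
    cx <- half_w; cy <- half_w
    nc <- ceiling(2 * half_w); nr <- ceiling(2 * half_w)

    lumen_v <- ellipse_polygon(cx, cy, a_px, b_px, phi, n = 256L)
    outer_v <- ellipse_polygon(cx, cy, a_px, b_px, phi, n = 256L,
                               offset = d_px)
    t0 <- stats::runif(1, 0, 2 * pi)
    # secant-correct the crescent fraction so the realized polygon area hits A_n
    target_px2 <- A_n * px_per_um^2
    fr <- f_est
    for (it in 1:3) {
      nuc_v <- crescent_polygon(cx, cy, a_px, b_px, phi,
                                d0 = 0.05 * d_px, d1 = 0.95 * d_px,
                                t0 = t0, frac = fr)
      got <- shoelace_px(nuc_v)
      if (abs(got / target_px2 - 1) < 1e-3) break
      fr <- min(fr * target_px2 / got, 0.95)
    }
    # marks
    n_cav <- stats::rpois(1, preset$caveolae_per_capillary)
    cav <- if (n_cav > 0) {
      tc <- stats::runif(n_cav, 0, 2 * pi)
      uc <- stats::runif(n_cav, 0.25, 0.75) * d_px
      pos <- do.call(rbind, lapply(seq_len(n_cav), function(i)
        ellipse_polygon(cx, cy, a_px, b_px, phi, n = 1L, offset = uc[i],
                        t_range = c(tc[i], tc[i]), closed = FALSE)))
      data.frame(x = pos[, 1], y = pos[, 2],
                 diameter_nm = rnorm_trunc(n_cav, preset$caveola_diameter_nm,
                                           preset$caveola_diameter_sd_nm,
                                           lower = 20))
    } else empty_caveolae()
    n_jun <- stats::rpois(1, preset$junctions_per_capillary)
    jun <- if (n_jun > 0) {
      tj <- stats::runif(n_jun, 0, 2 * pi)
      pos <- do.call(rbind, lapply(seq_len(n_jun), function(i)
        ellipse_polygon(cx, cy, a_px, b_px, phi, n = 1L, offset = 0.5 * d_px,
                        t_range = c(tj[i], tj[i]), closed = FALSE)))
      data.frame(x = pos[, 1], y = pos[, 2])
    } else empty_junctions()
    sigma_cdv <- rnorm_trunc(1, preset$cdv_grey,
                             preset_sd(preset, "cdv_grey_sd"), lower = 3)

    ann <- capillary_annotation(capillary_id,
                                vessel_outer = polygon_roi(outer_v, check = FALSE),
                                lumen = polygon_roi(lumen_v, check = FALSE),
                                nuclei = list(polygon_roi(nuc_v, check = FALSE)),
                                caveolae = cav, junctions = jun,
                                validate = FALSE)

    img <- NULL
    clip_frac <- NA_real_
    realized_cdv <- NA_real_
    if (render) {
      m_out <- rasterize_polygon(ann$vessel_outer, nr, nc)
      m_lum <- rasterize_polygon(ann$lumen, nr, nc)
      m_nuc <- rasterize_polygon(ann$nuclei[[1]], nr, nc)
      px <- matrix(200, nr, nc)
      px <- px + matrix(stats::rnorm(nr * nc, 0, 8), nr, nc)
      wall <- m_out & !m_lum & !m_nuc
      px[wall] <- 90 + stats::rnorm(sum(wall), 0, 10)
      lum_only <- m_lum & !m_nuc
      px[lum_only] <- 230 + stats::rnorm(sum(lum_only), 0, 5)
      tex <- stats::rnorm(sum(m_nuc), 127.5, sigma_cdv)
      clip_frac <- mean(tex < 0 | tex > 255)
      px[m_nuc] <- tex
      px <- round(pmin(pmax(px, 0), 255))
      # ground truth of the rendered texture (clipping shaves the drawn SD)
      realized_cdv <- stats::sd(px[m_nuc])
      img <- calibrated_image(px, nm_per_px, "TEM", bits = 8L)
    }

    # realized (polygon-exact) quantities, the generator's own bookkeeping
    realized_total <- polygon_area(ann$vessel_outer, nm_per_px)
    realized_lumen <- polygon_area(ann$lumen, nm_per_px)
    realized_nucleus <- polygon_area(ann$nuclei[[1]], nm_per_px)
    realized_thickness <- mean_cytoplasm_thickness(ann, nm_per_px)
    truth <- list(
      preset = preset$name, capillary_id = capillary_id,
      nm_per_px = nm_per_px,
      drawn = list(lumen_area_um2 = A_l, nucleus_area_um2 = A_n,
                   wall_thickness_nm = w_nm, cdv_grey = sigma_cdv,
                   n_caveolae = n_cav, n_junctions = n_jun,
                   caveola_diameters_nm = cav$diameter_nm,
                   aspect = q, rotation = phi, wall_offset_um = d),
      realized = list(total_area_um2 = realized_total,
                      lumen_area_um2 = realized_lumen,
                      nucleus_area_um2 = realized_nucleus,
                      cytoplasm_area_um2 = realized_total - realized_lumen -
                        realized_nucleus,
                      thickness_nm = realized_thickness,
                      cdv_grey = realized_cdv,
                      chromatin_clip_fraction = clip_frac))
    list(image = img, annotation = ann, truth = truth)
  })
}

#' Generate a nucleus filled with the preset's chromatin texture
#'
#' Renders one capillary scene whose chromatin grey-level SD is pinned at the
#' preset's `cdv_grey` (no between-capillary draw), for validating the CDV
#' estimator against the texture parameter itself. The nucleus regions of the
#' default geometry carry well over 1e4 interior pixels.
#'
#' @inheritParams generate_capillary
#' @return list with `image`, `nucleus` (the nucleus polygon) and `sigma`
#'   (the generating grey-level SD).
#' @export
generate_nucleus_texture <- function(preset, seed = NULL, nm_per_px = 10) {
  if (is.character(preset)) preset <- get_preset(preset)
  preset$cdv_grey_sd <- 0
  g <- generate_capillary(preset, seed = seed, nm_per_px = nm_per_px,
                          capillary_id = "nucleus-texture")
  list(image = g$image, nucleus = g$annotation$nuclei[[1]],
       sigma = g$truth$drawn$cdv_grey)
}

#' Generate Poisson counting-frame counts
#'
#' Emulates counting capillaries of a homogeneous Poisson point field in fixed
#' frames: counts are independent Poisson draws with mean
#' `density x frame area`.
#'
#' @param preset `GroupPreset` or name; supplies the density and frame/section
#'   geometry.
#' @param n_frames number of frames (>= 1).
#' @param seed integer seed.
#' @param modality `"ihc"` (uses `ihc_density_per_mm2` and the 200 um counting
#'   frame) or `"tem"` (uses `tem_density_per_mm2` and the preset's TEM
#'   section area).
#' @param density_per_mm2 optional explicit intensity overriding the preset.
#' @return list of [frame_count()] records.
#' @export
generate_field <- function(preset, n_frames, seed = NULL,
                           modality = c("ihc", "tem"),
                           density_per_mm2 = NULL) {
  modality <- match.arg(modality)
  if (is.character(preset)) preset <- get_preset(preset)
  if (n_frames < 1) stop_capmorph("n_frames must be >= 1")
  dens <- density_per_mm2 %||%
    if (modality == "ihc") preset$ihc_density_per_mm2 else preset$tem_density_per_mm2
  zone <- if (grepl("control", preset$name)) "control" else "infarct"
  if (modality == "ihc") {
    w_um <- preset$frame_um; h_um <- preset$frame_um
  } else {
    w_um <- sqrt(preset$tem_section_area_mm2) * 1e3
    h_um <- w_um
  }
  area_mm2 <- w_um * h_um / 1e6
  with_seed(seed, {
    counts <- stats::rpois(n_frames, dens * area_mm2)
    lapply(counts, frame_count, frame_width_um = w_um, frame_height_um = h_um,
           zone_label = zone)
  })
}

#' Generate a two-channel fluorescence field with zone masks
#'
#' Builds a three-zone layout (infarct core, infarct border, remote control as
#' vertical bands separated by narrow gaps), a 16-bit microsphere channel
#' whose expected zone means realise the preset's infarct/control MFI ratio
#' (border-weighted with a depleted core for the reperfusion preset,
#' reproducing no-reflow heterogeneity), and a CD31 channel carrying a vessel
#' mask. Exactly the preset's colocalisation target governs, per sphere dot,
#' whether it lands on a CD31-positive pixel.
#'
#' @param preset `GroupPreset` or name.
#' @param seed integer seed.
#' @param width,height field dimensions in pixels (each zone gets about a
#'   third of the width; keep `width * height` large enough that every zone
#'   has >= 1e4 pixels).
#' @param dot_fraction expected fraction of control-zone pixels carrying a
#'   sphere dot.
#' @return list with `spheres`, `cd31` (16-bit [calibrated_image()]s),
#'   `zones` ([zone_mask_set()]) and `truth` (expected ratios, thresholds,
#'   dot bookkeeping).
#' @export
generate_fluorescence <- function(preset, seed = NULL, width = 600L,
                                  height = 400L, dot_fraction = 0.015) {
  if (is.character(preset)) preset <- get_preset(preset)
  validate_preset(preset)
  gap <- 8L
  band <- (width - 2L * gap) %/% 3L
  cols_core <- seq_len(band)
  cols_border <- seq_len(band) + band + gap
  cols_control <- seq_len(band) + 2L * (band + gap)
  zone_mask <- function(cols) {
    m <- matrix(FALSE, height, width); m[, cols] <- TRUE; m
  }
  zones <- zone_mask_set(infarct_core = zone_mask(cols_core),
                         infarct_border = zone_mask(cols_border),
                         control = zone_mask(cols_control))
  zr <- preset_zone_ratios(preset)
  ratios <- c(core = zr$core, border = zr$border, control = 1)
  mu <- 3000                               # control-zone diffuse mean
  dot_amp <- 40000
  sphere_thr <- 30000; cd31_thr <- 10000
  with_seed(seed, {
    # CD31 channel: jittered elliptical vessel profiles on a dim background
    cd31 <- matrix(1500 + stats::rnorm(height * width, 0, 200), height, width)
    vmask <- matrix(FALSE, height, width)
    step <- 24
    centers <- expand.grid(x = seq(step / 2, width - step / 2, by = step),
                           y = seq(step / 2, height - step / 2, by = step))
    centers$x <- centers$x + stats::runif(nrow(centers), -6, 6)
    centers$y <- centers$y + stats::runif(nrow(centers), -6, 6)
    rad <- stats::runif(nrow(centers), 4.5, 8)
    xs <- matrix(rep(seq_len(width) - 1, each = height), height, width)
    ys <- matrix(rep(seq_len(height) - 1, times = width), height, width)
    for (i in seq_len(nrow(centers))) {
      x0 <- centers$x[i]; y0 <- centers$y[i]; r <- rad[i]
      sel_c <- max(1, floor(x0 - r)):min(width, ceiling(x0 + r + 2))
      sel_r <- max(1, floor(y0 - r)):min(height, ceiling(y0 + r + 2))
      sub <- (xs[sel_r, sel_c] - x0)^2 + (ys[sel_r, sel_c] - y0)^2 <= r^2
      vmask[sel_r, sel_c] <- vmask[sel_r, sel_c] | sub
    }
    cd31[vmask] <- 20000 + stats::rnorm(sum(vmask), 0, 1000)
    cd31 <- round(pmin(pmax(cd31, 0), 65535))

    spheres <- matrix(0, height, width)
    n_dots_in <- 0L; n_dots <- 0L
    zone_cols <- list(core = cols_core, border = cols_border,
                      control = cols_control)
    for (zn in names(zone_cols)) {
      cols <- zone_cols[[zn]]
      zmean <- mu * ratios[[zn]]
      block <- matrix(rnorm_trunc(height * length(cols), zmean,
                                  0.05 * max(zmean, 200), lower = 0),
                      height, length(cols))
      spheres[, cols] <- block
      # sphere dots, expected count proportional to the zone ratio
      npx <- height * length(cols)
      nd <- stats::rpois(1, dot_fraction * npx * ratios[[zn]])
      if (nd > 0) {
        lin <- as.vector(matrix(seq_len(height * width), height, width)[, cols])
        on_v <- lin[vmask[lin]]
        off_v <- lin[!vmask[lin]]
        nd_in <- stats::rbinom(1, nd, preset$colocalisation_target)
        nd_in <- min(nd_in, length(on_v))
        nd_out <- min(nd - nd_in, length(off_v))
        pos <- c(sample(on_v, nd_in), sample(off_v, nd_out))
        spheres[pos] <- spheres[pos] + dot_amp
        n_dots_in <- n_dots_in + nd_in
        n_dots <- n_dots + nd_in + nd_out
      }
    }
    spheres <- round(pmin(pmax(spheres, 0), 65535))
    truth <- list(
      preset = preset$name,
      zone_ratio = as.list(ratios),
      mfi_ratio_infarct_control = preset$mfi_ratio_infarct_control,
      colocalisation_target = preset$colocalisation_target,
      realized_colocalisation = if (n_dots > 0) n_dots_in / n_dots else NA_real_,
      n_dots = n_dots,
      sphere_threshold = sphere_thr, cd31_threshold = cd31_thr)
    list(spheres = calibrated_image(spheres, 1000, "microspheres", bits = 16L),
         cd31 = calibrated_image(cd31, 1000, "CD31", bits = 16L),
         zones = zones, truth = truth)
  })
}

#' Generate a full synthetic study cohort
#'
#' Mirrors the source design: per group, `animals_per_group` animals with 20
#' annotated capillaries each (two-level draws: animal-level means around the
#' group preset, capillary draws around the animal mean, intraclass
#' correlation `icc`), counting-frame counts for density, and one fluorescence
#' field per animal. When `out_dir` is given, a directory tree consumable by
#' the CLI commands is written (TIFFs, annotation JSON per animal, counts.csv,
#' manifest.json with all ground truth).
#'
#' @param group_names character vector of group names (e.g. `"I30"` or
#'   `"I90.infarct"`).
#' @param animals_per_group animals per group.
#' @param seed master seed; fully determines every artefact.
#' @param out_dir optional output directory.
#' @param n_capillaries capillaries per animal (default the preset's 20).
#' @param icc intraclass correlation splitting between- vs within-animal
#'   variance for Gaussian parameters.
#' @param nm_per_px TEM calibration.
#' @param render render capillary rasters (needed for CDV downstream).
#' @param n_frames counting frames per animal.
#' @param fluo_size fluorescence field `c(width, height)` in px.
#' @return invisible list with per-animal scenes, counts, fluorescence and the
#'   manifest; written to `out_dir` when given.
#' @export
generate_cohort <- function(group_names, animals_per_group, seed = NULL,
                            out_dir = NULL, n_capillaries = NULL, icc = 0.3,
                            nm_per_px = 10, render = TRUE, n_frames = 12L,
                            fluo_size = c(360L, 240L)) {
  presets <- lapply(group_names, get_preset)
  base_seed <- (seed %||% 1L) %% 1000003L
  animals <- list()
  manifest <- list(seed = seed, icc = icc, nm_per_px = nm_per_px,
                   groups = group_names, animals = list())
  gauss_fields <- list(
    c("lumen_area_um2", "lumen_area_sd_um2"),
    c("nucleus_area_um2", "nucleus_area_sd_um2"),
    c("wall_thickness_nm", "wall_thickness_sd_nm"),
    c("cdv_grey", "cdv_grey_sd"),
    c("caveola_diameter_nm", "caveola_diameter_sd_nm"))
  for (gi in seq_along(presets)) {
    p <- presets[[gi]]
    for (ai in seq_len(animals_per_group)) {
      aseed <- (base_seed + gi * 7919L + ai * 104729L) %% .Machine$integer.max
      animal_id <- sprintf("%s_animal%02d", gsub("[^A-Za-z0-9.-]", "", p$name), ai)
      pa <- p
      with_seed(aseed, {
        for (f in gauss_fields) {
          s <- preset_sd(p, f[2])
          pa[[f[1]]] <- rnorm_trunc(1, p[[f[1]]], sqrt(icc) * s,
                                    lower = p[[f[1]]] / 8)
          pa[[f[2]]] <- sqrt(1 - icc) * s
        }
        # keep the preset area invariant: total tracks the shifted means with
        # the group's implied cytoplasm allowance
        pa$total_vessel_area_um2 <- pa$lumen_area_um2 + pa$nucleus_area_um2 +
          (p$total_vessel_area_um2 - p$lumen_area_um2 - p$nucleus_area_um2)
      })
      ncap <- n_capillaries %||% p$n_capillaries_per_animal
      caps <- lapply(seq_len(ncap), function(ci)
        generate_capillary(pa, seed = aseed + 13L * ci,
                           nm_per_px = nm_per_px,
                           capillary_id = sprintf("%s_cap%02d", animal_id, ci),
                           render = render))
      frames <- generate_field(p, n_frames, seed = aseed + 5003L,
                               modality = "ihc")
      tem_frames <- generate_field(p, n_frames, seed = aseed + 6007L,
                                   modality = "tem")
      fluo <- generate_fluorescence(p, seed = aseed + 9001L,
                                    width = fluo_size[1], height = fluo_size[2])
      animals[[animal_id]] <- list(group = p$name, preset = pa, caps = caps,
                                   frames = frames, tem_frames = tem_frames,
                                   fluo = fluo)
      manifest$animals[[animal_id]] <- list(
        group = p$name,
        capillaries = lapply(caps, function(cp) cp$truth),
        fluorescence = fluo$truth,
        ihc_density_per_mm2 = p$ihc_density_per_mm2,
        tem_density_per_mm2 = p$tem_density_per_mm2)
    }
  }
  result <- list(animals = animals, manifest = manifest)
  if (!is.null(out_dir)) write_cohort(result, out_dir)
  invisible(result)
}

write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts_rows <- list()
  for (animal_id in names(cohort$animals)) {
    an <- cohort$animals[[animal_id]]
    adir <- file.path(out_dir, animal_id)
    dir.create(adir, showWarnings = FALSE)
    anns <- lapply(an$caps, `[[`, "annotation")
    write_annotations(anns, an$caps[[1]]$truth$nm_per_px,
                      file.path(adir, "annotations.json"))
    for (cp in an$caps) {
      if (!is.null(cp$image))
        write_image(cp$image, file.path(adir, paste0(cp$annotation$capillary_id,
                                                     ".tif")))
    }
    write_image(an$fluo$spheres, file.path(adir, "spheres.tif"))
    write_image(an$fluo$cd31, file.path(adir, "cd31.tif"))
    for (k in seq_along(an$frames))
      counts_rows[[length(counts_rows) + 1]] <- data.frame(
        sample_id = animal_id, group = an$group, zone = an$frames[[k]]$zone_label,
        modality = "ihc", frame_index = k, count = an$frames[[k]]$count,
        frame_um = an$frames[[k]]$frame_width_um)
    for (k in seq_along(an$tem_frames))
      counts_rows[[length(counts_rows) + 1]] <- data.frame(
        sample_id = animal_id, group = an$group,
        zone = an$tem_frames[[k]]$zone_label, modality = "tem", frame_index = k,
        count = an$tem_frames[[k]]$count,
        frame_um = an$tem_frames[[k]]$frame_width_um)
  }
  utils::write.csv(do.call(rbind, counts_rows),
                   file.path(out_dir, "counts.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
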