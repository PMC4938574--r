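test_that("a seed fully determines the generated scene", {
  g1 <- generate_capillary("I30.infarct", seed = 101)
  g2 <- generate_capillary("I30.infarct", seed = 101)
  expect_identical(g1$image$pixels, g2$image$pixels)
  expect_identical(unclass(g1$annotation$vessel_outer),
                   unclass(g2$annotation$vessel_outer))
  expect_identical(g1$truth$drawn, g2$truth$drawn)
  g3 <- generate_capillary("I30.infarct", seed = 102)
  expect_false(identical(g1$truth$drawn$lumen_area_um2,
                         g3$truth$drawn$lumen_area_um2))
  # skipping rendering leaves annotation and truth draws untouched
  g4 <- generate_capillary("I30.infarct", seed = 101, render = FALSE)
  expect_null(g4$image)
  expect_identical(unclass(g4$annotation$lumen), unclass(g1$annotation$lumen))
  expect_identical(g4$truth$drawn, g1$truth$drawn)
})

test_that("generated annotations always satisfy the annotation invariants", {
  for (preset in c("IR30-60.infarct", "I90.control")) {
    for (s in 1:15) {
      g <- generate_capillary(preset, seed = 3000 + s, render = FALSE)
      expect_silent(capmorph:::validate_annotation(g$annotation))
    }
  }
})

test_that("generator draws are calibrated against the preset means", {
  n <- 400
  draws <- lapply(seq_len(n), function(i)
    generate_capillary("IR30-60.infarct", seed = 50000 + i,
                       render = FALSE)$truth$drawn)
  p <- get_preset("IR30-60.infarct")
  pull <- function(f) vapply(draws, `[[`, numeric(1), f)
  for (case in list(
    c("wall_thickness_nm", "wall_thickness_nm", "wall_thickness_sd_nm"),
    c("lumen_area_um2", "lumen_area_um2", "lumen_area_sd_um2"),
    c("nucleus_area_um2", "nucleus_area_um2", "nucleus_area_sd_um2"),
    c("cdv_grey", "cdv_grey", "cdv_grey_sd"))) {
    x <- pull(case[1])
    se <- p[[case[3]]] / sqrt(n)
    expect_lt(abs(mean(x) - p[[case[2]]]), 2.5 * se)
  }
  nj <- vapply(draws, `[[`, numeric(1), "n_junctions")
  expect_lt(abs(mean(nj) - p$junctions_per_capillary),
            2.5 * sqrt(p$junctions_per_capillary / n))
})

test_that("generate_field draws Poisson counts at the requested intensity", {
  z <- generate_field("I30.infarct", 10, seed = 4, density_per_mm2 = 0)
  expect_true(all(vapply(z, `[[`, numeric(1), "count") == 0))
  fr <- generate_field("I30.infarct", 400, seed = 4, density_per_mm2 = 1250)
  counts <- vapply(fr, `[[`, numeric(1), "count")
  expect_lt(abs(mean(counts) - 50), 2.5 * sqrt(50 / 400))
  expect_identical(counts,
                   vapply(generate_field("I30.infarct", 400, seed = 4,
                                         density_per_mm2 = 1250),
                          `[[`, numeric(1), "count"))
  expect_error(generate_field("I30.infarct", 0, seed = 1), "n_frames")
})

test_that("fluorescence fields realise the preset zone structure", {
  f1 <- generate_fluorescence("I30.control", seed = 19)
  lm1 <- mfi_ratio(f1$spheres, f1$zones)
  expect_lt(abs(lm1$ratio_infarct_control - 1), 0.02)
  # homogeneous infarct for pure-ischemia presets
  f90 <- generate_fluorescence("I90.infarct", seed = 19)
  lm90 <- mfi_ratio(f90$spheres, f90$zones)
  expect_lt(abs(lm90$ratio_border_control / lm90$ratio_core_control - 1), 0.05)
  # border-weighted, core-depleted reperfusion preset
  fir <- generate_fluorescence("IR30-60.infarct", seed = 19)
  lmir <- mfi_ratio(fir$spheres, fir$zones)
  expect_gt(lmir$ratio_border_control, lmir$ratio_core_control)
  expect_lt(lmir$ratio_core_control, 0.5)
  expect_lt(abs(lmir$ratio_infarct_control -
                get_preset("IR30-60.infarct")$mfi_ratio_infarct_control), 0.1)
  # colocalisation recovery at the generator's fixed thresholds
  frac <- colocalisation_fraction(f90$spheres, f90$cd31, "fixed",
                                  sphere_threshold = f90$truth$sphere_threshold,
                                  cd31_threshold = f90$truth$cd31_threshold)
  expect_lt(abs(as.numeric(frac) - 0.25), 0.02)
  expect_equal(as.numeric(frac), f90$truth$realized_colocalisation)
  # zones are pairwise disjoint and congruent by construction
  expect_s3_class(f90$zones, "ZoneMaskSet")
})

test_that("cohorts have the declared structure and are reproducible", {
  c1 <- generate_cohort(c("I30", "I90", "IR30-60"), 2, seed = 77,
                        n_capillaries = 3, render = FALSE, n_frames = 4)
  expect_length(c1$animals, 6L)
  expect_true(all(vapply(c1$animals, function(a) length(a$caps), integer(1)) == 3L))
  c2 <- generate_cohort(c("I30", "I90", "IR30-60"), 2, seed = 77,
                        n_capillaries = 3, render = FALSE, n_frames = 4)
  expect_identical(c1$manifest, c2$manifest)
  expect_error(generate_cohort("I45", 1, seed = 1), "unknown group")
  # written tree carries the same manifest byte for byte
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  capmorph:::write_cohort(c1, d1); capmorph:::write_cohort(c2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "manifest.json"))),
                   unname(tools::md5sum(file.path(d2, "manifest.json"))))
})

test_that("the pipeline recovers the preset ordering across groups", {
  cohort <- generate_cohort(c("I30", "I90", "IR30-60"), 3, seed = 21,
                            n_capillaries = 8, render = FALSE, n_frames = 4)
  means <- vapply(cohort$animals, function(an) {
    m <- measure_capillaries(NULL, lapply(an$caps, `[[`, "annotation"),
                             nm_per_px = 10)
    mean(m$thickness_nm)
  }, numeric(1))
  grp <- vapply(cohort$animals, `[[`, character(1), "group")
  gm <- tapply(means, grp, mean)
  expect_lt(gm[["IR30-60.infarct"]], gm[["I30.infarct"]])
  expect_lt(gm[["IR30-60.infarct"]], gm[["I90.infarct"]])
})
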