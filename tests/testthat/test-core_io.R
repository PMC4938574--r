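test_that("TIFF and PNG round-trips are bit-identical for 8- and 16-bit greyscale", {
  withr::with_seed(7, {
    m8 <- matrix(sample(0:255, 100 * 80, TRUE), 80, 100)
    m16 <- matrix(sample(0:65535, 60 * 50, TRUE), 60, 50)
  })
  for (case in list(list(px = m8, bits = 8L), list(px = m16, bits = 16L))) {
    img <- calibrated_image(case$px, 9.6, bits = case$bits)
    for (ext in c("tif", "png")) {
      path <- withr::local_tempfile(fileext = paste0(".", ext))
      write_image(img, path)
      back <- read_image(path, 9.6)
      expect_identical(back$pixels, case$px)
      expect_identical(back$bits, case$bits)
      expect_equal(back$nm_per_px, 9.6)
    }
  }
})

test_that("read_image rejects missing files, multi-channel images and odd formats", {
  expect_error(read_image("no/such/file.tif", 10), "not found")
  # minimal RGB PNG built from the codec internals
  path <- withr::local_tempfile(fileext = ".png")
  ihdr <- c(capmorph:::u32be(2), capmorph:::u32be(2), as.raw(c(8, 2, 0, 0, 0)))
  idat <- memCompress(as.raw(c(0, rep(10, 6), 0, rep(20, 6))), "gzip")
  con <- file(path, "wb")
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(capmorph:::png_chunk("IHDR", ihdr), con)
  writeBin(capmorph:::png_chunk("IDAT", idat), con)
  writeBin(capmorph:::png_chunk("IEND", raw(0)), con)
  close(con)
  expect_error(read_image(path, 10), "single-channel")
  # garbage magic bytes
  bad <- withr::local_tempfile(fileext = ".tif")
  writeBin(charToRaw("not an image"), bad)
  expect_error(read_image(bad, 10), "unsupported|valid")
  expect_error(write_image(flat_image(1), "x.bmp"), "extension")
})

test_that("image codecs agree with the Python reference readers/writers", {
  withr::with_seed(21, px <- matrix(sample(0:65535, 40 * 30, TRUE), 30, 40))
  img <- calibrated_image(px, 10, bits = 16L)
  tif <- withr::local_tempfile(fileext = ".tif")
  png <- withr::local_tempfile(fileext = ".png")
  ref <- withr::local_tempfile(fileext = ".png")
  write_image(img, tif)
  write_image(img, png)
  script <- sprintf(paste0(
    "import tifffile, numpy as np; from PIL import Image\n",
    "a = tifffile.imread('%s'); b = np.array(Image.open('%s'))\n",
    "assert a.shape == (30, 40) and b.shape == (30, 40)\n",
    "assert int(a[0,0]) == %d and int(b[5,7]) == %d\n",
    "assert (a == b).all()\n",
    "Image.fromarray(b).save('%s')\n"), tif, png, px[1, 1], px[6, 8], ref)
  status <- system2("python", c("-c", shQuote(script)))
  expect_identical(status, 0L)
  expect_identical(read_image(ref, 10)$pixels, px)
})

test_that("calibrated_image enforces its invariants", {
  expect_error(calibrated_image(matrix(1, 0, 0), 10), "non-empty")
  expect_error(calibrated_image(matrix(5, 2, 2), 0), "positive")
  expect_error(calibrated_image(matrix(5, 2, 2), NaN), "positive")
  expect_error(calibrated_image(matrix(-1, 2, 2), 10), "negative")
  expect_error(calibrated_image(matrix(300, 2, 2), 10, bits = 8L), "8-bit")
  expect_identical(dim(flat_image(3, 4, 7)), c(4L, 7L))
})

test_that("annotation JSON round-trips and validation names the offender", {
  sq <- square_poly(10, 10, 30)
  lum <- square_poly(20, 20, 8)
  nuc <- square_poly(12, 12, 5)
  a <- capillary_annotation("cap-A", sq, lum, nuclei = list(nuc),
                            caveolae = data.frame(x = 15, y = 16,
                                                  diameter_nm = 95),
                            junctions = data.frame(x = c(11, 13), y = c(11, 13)))
  path <- withr::local_tempfile(fileext = ".json")
  write_annotations(list(a), 9.6, path)
  back <- read_annotations(path)
  expect_equal(back$nm_per_px, 9.6)
  expect_length(back$annotations, 1)
  b <- back$annotations[[1]]
  expect_equal(unclass(b$lumen), unclass(lum), ignore_attr = TRUE)
  expect_equal(b$caveolae$diameter_nm, 95)
  expect_equal(nrow(b$junctions), 2)

  # empty annotation list is fine
  write_annotations(list(), 5, path)
  expect_length(read_annotations(path)$annotations, 0)

  # lumen escaping the vessel is rejected with the capillary id
  expect_error(capillary_annotation("cap-bad", square_poly(0, 0, 10),
                                    square_poly(20, 20, 5)),
               "cap-bad.*lumen")
  # nucleus overlapping the lumen interior is rejected
  expect_error(capillary_annotation("cap-ovl", square_poly(0, 0, 30),
                                    square_poly(5, 5, 10),
                                    nuclei = list(square_poly(8, 8, 10))),
               "cap-ovl.*nucleus")
  # self-intersecting polygon is rejected
  bowtie <- rbind(c(0, 0), c(10, 10), c(10, 0), c(0, 10))
  expect_error(polygon_roi(bowtie), "self-intersecting")
  expect_error(polygon_roi(rbind(c(0, 0), c(1, 1))), "degenerate")
})

test_that("metrics tables write a stable CSV and round-trip numerically", {
  recs <- data.frame(capillary_id = c("a", "b", "c"),
                     total_area_um2 = c(36.8, 30.2, 49),
                     thickness_nm = c(407.8, 407.5, 207.0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metrics_table(recs, path)
  expect_length(readLines(path), 4L)
  back <- utils::read.csv(path)
  expect_equal(back$thickness_nm, recs$thickness_nm)
  write_metrics_table(data.frame(capillary_id = character(0)), path)
  expect_length(readLines(path), 1L)
  expect_error(write_metrics_table(recs, file.path(tempdir(), "no", "dir.csv")),
               "cannot write")
})
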