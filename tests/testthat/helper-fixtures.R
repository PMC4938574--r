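# Shared fixtures built in code; no binary test data.

square_poly <- function(x0 = 0, y0 = 0, side = 10) {
  polygon_roi(rbind(c(x0, y0), c(x0 + side, y0),
                    c(x0 + side, y0 + side), c(x0, y0 + side)))
}

# Regular n-gon approximating a circle, pixel coordinates.
circle_poly <- function(cx, cy, r, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  polygon_roi(cbind(cx + r * cos(t), cy + r * sin(t)), check = FALSE)
}

# Concentric annulus annotation (outer radius R, lumen radius r, px units).
annulus_annotation <- function(R_px, r_px, cx = R_px + 5, cy = R_px + 5,
                               n = 512, id = "annulus") {
  capillary_annotation(id,
                       vessel_outer = circle_poly(cx, cy, R_px, n),
                       lumen = circle_poly(cx, cy, r_px, n),
                       validate = FALSE)
}

# Uniform test image.
flat_image <- function(value, nr = 32, nc = 32, nm_per_px = 10, bits = 8L)
  calibrated_image(matrix(value, nr, nc), nm_per_px, bits = bits)

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
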