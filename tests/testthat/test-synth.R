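# Synthetic specimen and contour generator.

test_that("specimen tables have the cell structure and obey the TL rule", {
  cfg <- synth_config(n_per_cell = 3L, seed = 11L)
  sp <- generate_specimens(cfg)
  expect_equal(nrow(sp), 18L)
  expect_equal(as.integer(table(sp$size_class)), rep(6L, 3L))
  expect_equal(as.integer(table(sp$sex)), rep(9L, 2L))
  # classes re-derived from TL match the generating cell intervals
  expect_identical(sp$size_class, classify_size_class(sp$TL_mm))
  expect_true(all(sp$TL_mm > 0 & sp$BW_g > 0))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- synth_config(n_per_cell = 2L, seed = 42L)
  s1 <- generate_specimens(cfg)
  s2 <- generate_specimens(cfg)
  expect_identical(s1, s2)
  c1 <- generate_contour(s1[1L, ], cfg)
  c2 <- generate_contour(s2[1L, ], cfg)
  expect_identical(unclass(c1), unclass(c2))
  set1 <- generate_otolith_set(cfg)
  set2 <- generate_otolith_set(cfg)
  expect_identical(set1, set2)
})

test_that("every generated TL classifies back into its generating class", {
  cfg <- synth_config(n_per_cell = 25L, seed = 3L,
                      class_TL_ranges = list(I = c(180, 240),
                                             II = c(240, 290),
                                             III = c(290, 340)))
  sp <- generate_specimens(cfg)
  gen_class <- rep(rep(c("I", "II", "III"), each = 2L * 25L))
  expect_identical(sp$size_class, gen_class)
})

test_that("invalid TL ranges are rejected", {
  expect_error(synth_config(class_TL_ranges = list(c(240, 180), c(240, 290),
                                                   c(290, 340))),
               "ordered")
  expect_error(synth_config(n_per_cell = 0L), "n_per_cell")
})

test_that("zero-effect contours are the pure scaled template", {
  cfg <- synth_config(noise_sd = 0,
                      crenation = list(amplitude = 0, frequency = 26L),
                      harmonic_effects = list(
                        size_class = list(I = numeric(), II = numeric(),
                                          III = numeric()),
                        sex = list(M = numeric(), F = numeric()),
                        side = list(L = numeric(), R = numeric())),
                      seed = 1L)
  sp1 <- list(specimen_id = "A", TL_mm = 220, sex = "F", size_class = "I")
  sp2 <- list(specimen_id = "B", TL_mm = 310, sex = "F", size_class = "III")
  c1 <- generate_contour(sp1, cfg)
  c2 <- generate_contour(sp2, cfg)
  # identical shape: contours proportional, ratio TL^c
  s <- (310 / 220)^cfg$allometric_exponent
  expect_equal(unclass(c2), unclass(c1) * s, tolerance = 1e-12)
  # areas ordered as TL^(2c)
  expect_equal(contour_area(c2) / contour_area(c1), s^2, tolerance = 1e-10)
})

test_that("crenation strictly increases the perimeter at equal size scale", {
  base <- synth_config(noise_sd = 0,
                       crenation = list(amplitude = 0, frequency = 26L))
  cren <- synth_config(noise_sd = 0,
                       crenation = list(amplitude = 0.03, frequency = 26L))
  sp <- list(specimen_id = "A", TL_mm = 250, sex = "M", size_class = "II")
  p0 <- contour_perimeter(generate_contour(sp, base))
  p1 <- contour_perimeter(generate_contour(sp, cren))
  expect_gt(p1, p0)
})

test_that("excessive amplitudes raise a generation error", {
  cfg <- synth_config(harmonic_effects = list(
    size_class = list(I = c(`2` = 2.0), II = numeric(), III = numeric()),
    sex = list(M = numeric(), F = numeric()),
    side = list(L = numeric(), R = numeric())))
  sp <- list(specimen_id = "A", TL_mm = 200, sex = "M", size_class = "I")
  expect_error(generate_contour(sp, cfg), class = "oto_generation_error")
})

test_that("rasterization matches analytic pixel counts and round-trips", {
  circ <- circle_contour(r = 1, n = 1024L)
  img <- rasterize(circ, px_per_mm = 200)
  expect_s3_class(img, "oto_image")
  expect_equal(sum(unclass(img)), pi * 200^2, tolerance = 0.01)
  # round trip: extract and compare areas
  mask <- binarize(img)
  back <- contour_px_to_mm(extract_outline(mask), 200)
  expect_equal(contour_area(back), contour_area(circ), tolerance = 0.02)
  # degenerate / under-resolved input
  expect_error(rasterize(circ, px_per_mm = 10), "resolution")
})

test_that("right-side contours are mirrored copies in distribution", {
  cfg <- synth_config(noise_sd = 0,
                      crenation = list(amplitude = 0, frequency = 26L))
  sp <- list(specimen_id = "A", TL_mm = 250, sex = "M", size_class = "II")
  cl <- generate_contour(sp, cfg, side = "L")
  cr <- generate_contour(sp, cfg, side = "R")
  # with all randomness off, R is exactly the mirror of L
  expect_equal(sort(unclass(cr)[, 1L]), sort(-unclass(cl)[, 1L]),
               tolerance = 1e-12)
  expect_equal(contour_area(cl), contour_area(cr), tolerance = 1e-12)
})
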