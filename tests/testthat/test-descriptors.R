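# Radius profiles, wavelet transform, elliptic Fourier descriptors.

test_that("polar radius profile matches analytic circles and ellipses", {
  p <- polar_radius_profile(circle_contour(r = 2.5, n = 1024L), 512L)
  expect_lt(sd(p$radii), 1e-6 * 2.5)
  a <- 2; b <- 1.2
  p2 <- polar_radius_profile(ellipse_contour(a, b, n = 2048L), 512L)
  th <- p2$theta0 + 2 * pi * (0:511) / 512
  analytic <- a * b / sqrt(b^2 * cos(th - p2$theta0)^2 +
                           a^2 * sin(th - p2$theta0)^2)
  expect_equal(p2$radii, analytic, tolerance = 1e-3)
})

test_that("re-entrant contours raise a non-star-shaped error", {
  th <- 2 * pi * (0:511) / 512
  r <- 1 + 0.8 * cos(5 * th)   # deep lobes: radius dips near zero, re-entrant
  r[r < 0.05] <- 0.05
  xy <- cbind(r * cos(th), r * sin(th))
  # push one lobe back over its neighbour to force re-entrance about centroid
  xy[100:140, ] <- xy[100:140, ] + cbind(rep(0.9, 41), rep(-0.6, 41))
  expect_error(polar_radius_profile(oto_contour(xy), 512L),
               class = "oto_non_star_shaped")
  expect_error(polar_radius_profile(circle_contour(), 100L), "power of two")
})

test_that("the wavelet transform is orthonormal and inverts exactly", {
  set.seed(21)
  for (rep in 1:5) {
    x <- rnorm(256)
    dec <- otoshape:::.dwt(x, 5L)
    coefs <- c(dec$a, unlist(dec$d))
    expect_equal(sum(coefs^2), sum(x^2), tolerance = 1e-9)      # Parseval
    expect_equal(otoshape:::.idwt(dec), x, tolerance = 1e-10)   # inversion
  }
})

test_that("wavelet descriptors of a circle have zero detail energy and
           full sets reconstruct the profile", {
  prof <- polar_radius_profile(circle_contour(r = 3), 512L)
  ds <- wavelet_descriptors(prof, keep_details = 5:1)
  expect_lt(max(abs(ds$full_coefficients)), 1e-9)
  ct <- blob_contour(3, crenation = 0.03)
  prof2 <- polar_radius_profile(ct, 512L)
  ds2 <- wavelet_descriptors(prof2, keep_details = 5:1)
  rec <- reconstruct(ds2, full = TRUE)
  expect_equal(rec$profile, prof2$radii, tolerance = 1e-9)
  # Parseval on the normalized signal
  s <- prof2$radii / mean(prof2$radii) - 1
  expect_equal(sum(ds2$full_coefficients^2), sum(s^2), tolerance = 1e-10)
})

test_that("band energy localizes by frequency", {
  n <- 512L
  t <- (0:(n - 1L))
  bands <- otoshape:::.wavelet_bands(n, 5L)
  # 2 cycles across the outline: approximation band carries the energy
  lowf <- sin(2 * pi * 2 * t / n)
  d1 <- otoshape:::.dwt(lowf, 5L)
  c1 <- c(d1$a, unlist(d1$d))
  expect_gt(sum(c1[bands == "a5"]^2) / sum(c1^2), 0.95)
  # 12 cycles: the coarsest detail band (8-16 cycles) dominates
  midf <- sin(2 * pi * 12 * t / n)
  d2 <- otoshape:::.dwt(midf, 5L)
  c2 <- c(d2$a, unlist(d2$d))
  shares <- vapply(unique(bands), function(b)
    sum(c2[bands == b]^2) / sum(c2^2), numeric(1L))
  expect_identical(names(which.max(shares)), "d5")
  expect_gt(shares[["d5"]], 0.5)
})

test_that("EFD of a mild ellipse concentrates power in harmonic 1", {
  fd <- fourier_descriptors(ellipse_contour(a = 1.2, b = 1, n = 1024L), 10L)
  v <- fd$coefficients
  p1 <- 1 + v[["d1"]]^2
  expect_gt(p1 / (p1 + sum(v[-1L]^2)), 0.999)
  # near-circular limit: higher harmonics vanish
  fd2 <- fourier_descriptors(ellipse_contour(a = 1.005, b = 1, n = 1024L), 10L)
  expect_lt(max(abs(fd2$coefficients[-1L])), 1e-3)
})

test_that("normalized EFDs are invariant to rotation, start point, scale
           and translation", {
  ct <- blob_contour(11)
  f0 <- fourier_descriptors(ct, 15L)
  xy <- unclass(ct)
  moved <- sweep(rotate_xy(xy, 63 * pi / 180)[c(301:512, 1:300), ],
                 2L, c(4.2, -1.7), "+")
  f1 <- fourier_descriptors(oto_contour(moved), 15L)
  expect_equal(f1$coefficients, f0$coefficients, tolerance = 1e-6)
  f2 <- fourier_descriptors(oto_contour(xy * 19.3), 15L)
  expect_equal(f2$coefficients, f0$coefficients, tolerance = 1e-6)
})

test_that("descriptors are deterministic", {
  ct <- blob_contour(13, crenation = 0.02)
  expect_identical(fourier_descriptors(ct, 12L)$coefficients,
                   fourier_descriptors(ct, 12L)$coefficients)
  p <- polar_radius_profile(ct, 512L)
  expect_identical(wavelet_descriptors(p)$coefficients,
                   wavelet_descriptors(p)$coefficients)
})

test_that("EFD reconstruction error is monotone non-increasing in
           harmonics and small for circles", {
  set.seed(31)
  for (i in 1:6) {
    ct <- blob_contour(100 + i, crenation = 0.04)
    fd <- fourier_descriptors(ct, 30L)
    errs <- vapply(c(1L, 2L, 5L, 10L, 20L, 30L), function(h)
      reconstruction_diagnostic(fd, ct, n_harmonics = h)$rms, numeric(1L))
    expect_true(all(diff(errs) <= 1e-12))
  }
  # crenated contour: 1 harmonic is crude, 30 harmonics is >= 10x better
  ct <- blob_contour(55, crenation = 0.05)
  fd <- fourier_descriptors(ct, 30L)
  e1 <- reconstruction_diagnostic(fd, ct, n_harmonics = 1L)$mean
  e30 <- reconstruction_diagnostic(fd, ct, n_harmonics = 30L)$mean
  expect_gt(e1, 0)
  expect_lt(e30, e1 / 10)
  # circle: any truncation is within 1e-3 of the radius
  circ <- circle_contour(r = 2)
  fdc <- fourier_descriptors(circ, 5L)
  expect_lt(reconstruction_diagnostic(fdc, circ, n_harmonics = 1L)$mean,
            1e-3 * 2)
})

test_that("truncated wavelet reconstruction error shrinks as detail bands
           are added", {
  ct <- blob_contour(77, crenation = 0.04)
  prof <- polar_radius_profile(ct, 512L)
  errs <- vapply(list(c(5L), c(5L, 4L), c(5L, 4L, 3L), 5:1), function(kd) {
    ds <- wavelet_descriptors(prof, keep_details = kd)
    reconstruction_diagnostic(ds, ct)$rms
  }, numeric(1L))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[4L], 1e-9)
})

test_that("position variation decomposes variance exactly and localizes
           constructed crenation", {
  # identical contours: zero variance everywhere
  ct <- blob_contour(8)
  sets <- replicate(10L, wavelet_descriptors(polar_radius_profile(ct, 256L),
                                             levels = 4L),
                    simplify = FALSE)
  pv <- position_variation(sets)
  expect_lt(max(pv$total_var), 1e-20)
  expect_error(position_variation(sets[1:2]), "at least 3")
  # crenation windowed onto one half of the outline
  n <- 256L
  th <- 2 * pi * (0:(n - 1L)) / n
  mk <- function(seed) {
    set.seed(seed)
    w <- ifelse(th > 0.15 * pi & th < 0.85 * pi, sin((th - 0.15 * pi) /
                 (0.7) )^2, 0)
    r <- 1 + 0.25 * cos(2 * th) + 0.06 * cos(3 * th) +
      runif(1L, 0.02, 0.06) * cos(20 * th + runif(1L, 0, 2 * pi)) * w
    oto_contour(cbind(r * cos(th), r * sin(th)))
  }
  sets2 <- lapply(1:12, function(s)
    wavelet_descriptors(polar_radius_profile(mk(s), 256L), levels = 4L))
  pv2 <- position_variation(sets2)
  # decomposition identity: band attributions sum to the total variance
  bands <- setdiff(names(pv2), c("position", "total_var"))
  expect_equal(rowSums(pv2[, bands, drop = FALSE]), pv2$total_var,
               tolerance = 1e-9)
  # variance concentrates on the crenated half
  half <- pv2$position <= n / 2
  expect_gt(sum(pv2$total_var[half]), 0.8 * sum(pv2$total_var))
})
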