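# Synthetic specimen sets and otolith contours.
#
# Contours are synthesised as positive radius functions
#   r(theta) = R0 * (1 + sum_k a_k cos(k theta + phi_k) + crenation + noise)
# about the centroid. A single-valued positive radius function is a simple
# closed star-shaped curve by construction, so validity reduces to r > 0.

# Fixed harmonic base templates, one per otolith type. Amplitudes are
# dimensionless fractions of the mean radius; phases in radians. size_ref is
# the mean radius in mm at the reference fish length TL = 240 mm.
.oto_templates <- list(
  sagitta = list(
    harmonics = c(`2` = 0.20, `3` = 0.06, `4` = 0.02),
    phases    = c(`2` = 0.00, `3` = 0.35, `4` = 0.00),
    size_ref  = 0.90),
  lapillus = list(
    harmonics = c(`2` = 0.07, `4` = 0.05),
    phases    = c(`2` = 0.00, `4` = 0.00),
    size_ref  = 0.22),
  asteriscus = list(
    harmonics = c(`2` = -0.15, `3` = -0.05),
    phases    = c(`2` = 0.00, `3` = 0.50),
    size_ref  = 0.28))

#' Configuration for the synthetic otolith generator
#'
#' Defines the study-like structure of a simulated specimen set: three
#' TL-defined size classes crossed with two sexes, paired left/right otoliths
#' of a given type, class-dependent otolith size through an allometric power
#' law, and group-dependent outline shape through additive harmonic effects.
#'
#' Defaults encode the scenario the downstream tests assume: a shape effect
#' of size class (increasing amplitude on the third radius harmonic), no sex
#' and no side effect, moderate margin crenation, and residual
#' specimen-level harmonic noise.
#'
#' @param n_per_cell specimens per (size class x sex) cell.
#' @param class_TL_ranges list of three ordered, disjoint TL intervals (mm),
#'   one per size class.
#' @param base_shape otolith type: `"sagitta"`, `"lapillus"` or
#'   `"asteriscus"`.
#' @param harmonic_effects named list with elements `size_class`, `sex`,
#'   `side`; each a named list mapping factor level to a named numeric
#'   vector of additive amplitudes on radius harmonics (names = harmonic
#'   index).
#' @param crenation list with `amplitude` (dimensionless, >= 0) and
#'   `frequency` (integer harmonic) of the high-order margin ripple.
#' @param allometric_slope named numeric vector: per-harmonic linear
#'   dependence of amplitude on centred TL (mm^-1); default none.
#' @param allometric_exponent exponent c of the otolith-size law
#'   `radius ~ TL^c`; c < 1 makes relative otolith size (OL/TL) decrease
#'   with fish length.
#' @param lw_a,lw_b,lw_cv length-weight power law `BW = a TL^b` with
#'   multiplicative lognormal noise (sdlog = `lw_cv`).
#' @param noise_sd sd of the specimen-level random amplitudes added to
#'   harmonics 2..8 (dimensionless).
#' @param n_points vertices per generated contour.
#' @param seed integer RNG seed governing the whole generated set.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_per_cell = 20L,
                         class_TL_ranges = list(I = c(180, 240),
                                                II = c(240, 290),
                                                III = c(290, 340)),
                         base_shape = "sagitta",
                         harmonic_effects = list(
                           size_class = list(I = numeric(),
                                             II = c(`3` = 0.04),
                                             III = c(`3` = 0.02, `4` = 0.05)),
                           sex  = list(M = numeric(), F = numeric()),
                           side = list(L = numeric(), R = numeric())),
                         crenation = list(amplitude = 0.012, frequency = 26L),
                         allometric_slope = numeric(),
                         allometric_exponent = 0.8,
                         lw_a = 5e-7, lw_b = 3.0, lw_cv = 0.08,
                         noise_sd = 0.008,
                         n_points = 512L,
                         seed = 1L) {
  if (n_per_cell < 1L) stop("n_per_cell must be >= 1")
  if (length(class_TL_ranges) != 3L)
    stop("class_TL_ranges must list three intervals")
  rng <- do.call(rbind, lapply(class_TL_ranges, as.numeric))
  if (any(rng[, 2L] <= rng[, 1L]) || any(diff(as.vector(t(rng))) < 0))
    stop("class_TL_ranges must be ordered, disjoint intervals")
  base_shape <- match.arg(base_shape, names(.oto_templates))
  if (crenation$amplitude < 0) stop("crenation amplitude must be >= 0")
  structure(list(
    n_per_cell = as.integer(n_per_cell),
    class_TL_ranges = class_TL_ranges,
    base_shape = base_shape,
    harmonic_effects = harmonic_effects,
    crenation = crenation,
    allometric_slope = allometric_slope,
    allometric_exponent = allometric_exponent,
    lw_a = lw_a, lw_b = lw_b, lw_cv = lw_cv,
    noise_sd = noise_sd,
    n_points = as.integer(n_points),
    seed = as.integer(seed)), class = "synth_config")
}

#' Generate a synthetic specimen table
#'
#' Draws `6 * n_per_cell` specimens (3 size classes x 2 sexes). TL is uniform
#' within each class interval; BW follows the configured length-weight power
#' law with lognormal noise; the size class is re-derived from TL by
#' [classify_size_class()], so the table always satisfies the classification
#' rule.
#'
#' @param config a [synth_config()].
#' @return data frame with columns `specimen_id`, `TL_mm`, `BW_g`, `sex`,
#'   `size_class`.
#' @export
generate_specimens <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    classes <- c("I", "II", "III")
    rows <- list()
    idx <- 0L
    for (ci in seq_along(classes)) {
      rng <- as.numeric(config$class_TL_ranges[[ci]])
      for (sex in c("M", "F")) {
        TL <- runif(config$n_per_cell, rng[1L], rng[2L])
        BW <- config$lw_a * TL^config$lw_b *
          rlnorm(config$n_per_cell, 0, config$lw_cv)
        ids <- sprintf("S%03d", idx + seq_len(config$n_per_cell))
        idx <- idx + config$n_per_cell
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = ids, TL_mm = TL, BW_g = BW, sex = sex,
          size_class = vapply(TL, classify_size_class, character(1L)),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Deterministic per-otolith sub-seed: rolling polynomial hash of the
# specimen id, side and type, mixed with the config seed (collision-free in
# practice, so no two otoliths share a noise stream).
.otolith_seed <- function(seed, specimen_id, side, type) {
  key <- paste(specimen_id, side, type, seed, sep = "|")
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483563
  as.integer(h)
}

#' Generate one synthetic otolith contour
#'
#' Builds the radius-harmonic base template for the configured otolith type,
#' scales it allometrically (`radius ~ TL^c`), adds the group harmonic
#' effects for the specimen's size class and sex and the requested side,
#' then crenation and specimen-level harmonic noise. Right-side contours are
#' mirrored. The result is a simple closed counter-clockwise contour in mm.
#'
#' @param specimen one row of a [generate_specimens()] table (or a list with
#'   `specimen_id`, `TL_mm`, `sex`, `size_class`).
#' @param config a [synth_config()].
#' @param side `"L"` or `"R"`.
#' @return an [oto_contour()] in mm.
#' @export
generate_contour <- function(specimen, config, side = "L") {
  stopifnot(inherits(config, "synth_config"))
  side <- match.arg(side, c("L", "R"))
  tmpl <- .oto_templates[[config$base_shape]]
  TL <- as.numeric(specimen$TL_mm)
  R0 <- tmpl$size_ref * (TL / 240)^config$allometric_exponent

  amp <- numeric(64L)   # amplitude per harmonic index (cos, phase below)
  phs <- numeric(64L)
  kk <- as.integer(names(tmpl$harmonics))
  amp[kk] <- tmpl$harmonics
  phs[kk] <- tmpl$phases
  add_eff <- function(eff) {
    if (length(eff)) {
      k <- as.integer(names(eff))
      amp[k] <<- amp[k] + as.numeric(eff)
    }
  }
  he <- config$harmonic_effects
  add_eff(he$size_class[[as.character(specimen$size_class)]])
  add_eff(he$sex[[as.character(specimen$sex)]])
  add_eff(he$side[[side]])
  if (length(config$allometric_slope)) {
    k <- as.integer(names(config$allometric_slope))
    amp[k] <- amp[k] + as.numeric(config$allometric_slope) * (TL - 265)
  }

  n <- config$n_points
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  r_rel <- rep(1, n)
  for (k in which(amp != 0)) r_rel <- r_rel + amp[k] * cos(k * theta + phs[k])
  with_seed(.otolith_seed(config$seed, specimen$specimen_id, side,
                          config$base_shape), {
    if (config$crenation$amplitude > 0) {
      cr_phase <- runif(1L, 0, 2 * pi)
      r_rel <- r_rel + config$crenation$amplitude *
        cos(config$crenation$frequency * theta + cr_phase)
    }
    if (config$noise_sd > 0) {
      nk <- 2:8
      na <- rnorm(length(nk), 0, config$noise_sd)
      np <- runif(length(nk), 0, 2 * pi)
      for (i in seq_along(nk))
        r_rel <- r_rel + na[i] * cos(nk[i] * theta + np[i])
    }
  })
  if (min(r_rel) <= 0.05)
    stop(errorCondition(sprintf(
      "harmonic amplitudes too large: min relative radius %.3f <= 0.05 (contour would self-intersect or pinch)",
      min(r_rel)), class = c("oto_generation_error", "error", "condition")))
  r <- R0 * r_rel
  xy <- cbind(r * cos(theta), r * sin(theta))
  ct <- oto_contour(xy, unit = "mm")
  if (side == "R") ct <- mirror_contour(ct)
  ct
}

#' Generate the full synthetic otolith set
#'
#' Convenience wrapper: specimens plus one contour per (specimen, side).
#'
#' @param config a [synth_config()].
#' @param sides character vector of sides to generate.
#' @return list with `specimens` (data frame) and `contours` (named list,
#'   keys `"<specimen_id>_<side>"`).
#' @export
generate_otolith_set <- function(config, sides = c("L", "R")) {
  specs <- generate_specimens(config)
  contours <- list()
  for (i in seq_len(nrow(specs))) {
    for (sd_ in sides) {
      contours[[paste0(specs$specimen_id[i], "_", sd_)]] <-
        generate_contour(specs[i, ], config, side = sd_)
    }
  }
  list(specimens = specs, contours = contours)
}

#' Rasterise a contour to a grayscale image
#'
#' Scanline-fills the contour polygon (bright object, value 1) on a dark
#' background (value 0) at the requested resolution, with an 8-pixel margin.
#' Pixel centres sit on the integer grid, x rightward, y upward; the image
#' matrix is stored top row first as image readers expect.
#'
#' @param contour an [oto_contour()] in mm.
#' @param px_per_mm resolution; the object must span at least 32 px.
#' @return numeric matrix in `[0,1]` of class `oto_image` with attribute
#'   `px_per_mm`.
#' @export
rasterize <- function(contour, px_per_mm = 200) {
  xy <- unclass(contour)
  span <- max(apply(xy, 2L, function(v) diff(range(v)))) * px_per_mm
  if (span < 32)
    stop("resolution too low: object spans ", round(span), " px (< 32)")
  margin <- 8
  px <- cbind((xy[, 1L] - min(xy[, 1L])) * px_per_mm + margin + 1,
              (xy[, 2L] - min(xy[, 2L])) * px_per_mm + margin + 1)
  W <- ceiling(max(px[, 1L])) + margin
  H <- ceiling(max(px[, 2L])) + margin
  img <- matrix(0, nrow = H, ncol = W)
  x1 <- px[, 1L]; y1 <- px[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  for (row in seq_len(H)) {
    yc <- H - row + 1L            # pixel-centre y for this matrix row
    crosses <- (y1 <= yc & y2 > yc) | (y2 <= yc & y1 > yc)
    if (!any(crosses)) next
    t <- (yc - y1[crosses]) / (y2[crosses] - y1[crosses])
    xc <- sort(x1[crosses] + t * (x2[crosses] - x1[crosses]))
    for (j in seq(1L, length(xc) - 1L, by = 2L)) {
      a <- ceiling(xc[j]); b <- floor(xc[j + 1L])
      if (b >= a) img[row, a:b] <- 1
    }
  }
  structure(img, class = "oto_image", px_per_mm = px_per_mm)
}

#' Write a specimen metadata table and image set
#'
#' Writes `specimens.csv` (columns `specimen_id`, `TL_mm`, `BW_g`, `sex`,
#' `size_class`, `otolith_type`, `side`, `image_path`) and one 8-bit
#' grayscale PNG per contour under `dir`.
#'
#' @param set a [generate_otolith_set()] result.
#' @param dir output directory (created if needed).
#' @param config the [synth_config()] used (for otolith type).
#' @param px_per_mm raster resolution.
#' @return path of the metadata CSV, invisibly.
#' @export
write_otolith_set <- function(set, dir, config, px_per_mm = 100) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (key in names(set$contours)) {
    parts <- strsplit(key, "_")[[1L]]
    sid <- parts[1L]; side <- parts[2L]
    img <- rasterize(set$contours[[key]], px_per_mm)
    path <- file.path(dir, paste0(key, ".png"))
    png::writePNG(unclass(img), path)
    sp <- set$specimens[set$specimens$specimen_id == sid, ]
    rows[[key]] <- data.frame(sp, otolith_type = config$base_shape,
                              side = side, image_path = path,
                              stringsAsFactors = FALSE)
  }
  meta <- do.call(rbind, rows)
  out <- file.path(dir, "specimens.csv")
  write.csv(meta, out, row.names = FALSE)
  invisible(out)
}
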