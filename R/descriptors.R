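# Contour shape descriptors: wavelet coefficients of the polar radius
# profile, and normalized elliptic Fourier descriptors (EFD) of the (x, y)
# parameterization. Both are returned as `oto_descriptors` objects carrying
# the normalization applied, so outlines can be reconstructed and compared.

#' Polar radius profile of a star-shaped contour
#'
#' Samples the distance from the area centroid to the outline at `n_points`
#' equal angular steps, counter-clockwise, starting at the principal-axis
#' direction (oriented toward the farther extreme, i.e. the anterior tip).
#' The contour must be star-shaped about its centroid — every ray from the
#' centroid crosses the outline exactly once; otherwise a `non_star_shaped`
#' error names the first offending angle.
#'
#' @param contour an [oto_contour()].
#' @param n_points number of angular samples; a power of two (>= 32) so the
#'   profile can feed the dyadic wavelet transform.
#' @param tol angular backtracking tolerance (rad): vertices that step back
#'   by at most this much (sub-pixel jitter on traced outlines) are
#'   dropped; larger backtracks mean a genuinely re-entrant outline and
#'   raise the error.
#' @return an `oto_profile`: list with `radii` (length `n_points`),
#'   `centroid`, `theta0` (start angle, rad) and `unit`.
#' @export
polar_radius_profile <- function(contour, n_points = 512L, tol = 0.02) {
  if (n_points < 32L || bitwAnd(n_points, n_points - 1L) != 0L)
    stop("n_points must be a power of two >= 32")
  cen <- contour_centroid(contour)
  xy <- sweep(unclass(contour), 2L, cen)
  th <- atan2(xy[, 2L], xy[, 1L])
  r <- sqrt(rowSums(xy^2))
  # principal-axis start angle, oriented toward the farther extreme
  u <- principal_axis(unclass(contour))$u
  p <- xy %*% u
  if (abs(min(p)) > abs(max(p))) u <- -u
  theta0 <- atan2(u[2L], u[1L])

  phi <- (th - theta0) %% (2 * pi)
  k0 <- which.min(phi)
  ord <- c(k0:length(phi), if (k0 > 1L) 1:(k0 - 1L))
  phi <- phi[ord]; rr <- r[ord]
  bt <- cummax(phi) - phi              # angular backtrack per vertex
  if (max(bt) > tol)
    stop(errorCondition(sprintf(
      "contour is not star-shaped about its centroid (re-entrant near angle %.3f rad from the principal axis)",
      phi[which.max(bt)]),
      class = c("oto_non_star_shaped", "error", "condition")))
  phi <- phi[bt <= 1e-12]; rr <- rr[bt <= 1e-12]   # now non-decreasing
  dd <- c(TRUE, diff(phi) > 1e-12)                 # drop angular ties
  phi <- phi[dd]; rr <- rr[dd]
  # periodic linear interpolation onto the angular grid
  phi_ext <- c(phi[length(phi)] - 2 * pi, phi, phi[1L] + 2 * pi)
  r_ext <- c(rr[length(rr)], rr, rr[1L])
  grid <- 2 * pi * (seq_len(n_points) - 1L) / n_points
  radii <- approx(phi_ext, r_ext, xout = grid, ties = "ordered")$y
  structure(list(radii = radii, centroid = cen, theta0 = theta0,
                 unit = attr(contour, "unit")),
            class = "oto_profile")
}

# ---- periodized orthonormal Daubechies-4 discrete wavelet transform ----

# 8-tap Daubechies filter with 4 vanishing moments (sum = sqrt(2)).
.db4 <- c(0.2303778133088552, 0.7148465705525415, 0.6308807679295904,
          -0.0279837694169839, -0.1870348117188811, 0.0308413818359870,
          0.0328830116669829, -0.0105974017849973)

# one-level analysis matrix for signal length n (orthogonal)
.dwt_step_matrix <- function(n) {
  h <- .db4
  g <- rev(h) * (-1)^(seq_along(h) - 1L)
  W <- matrix(0, n, n)
  for (i in seq_len(n / 2L)) {
    cols <- ((2L * (i - 1L) + seq_along(h) - 1L) %% n) + 1L
    for (k in seq_along(h)) {
      W[i, cols[k]] <- W[i, cols[k]] + h[k]
      W[n / 2L + i, cols[k]] <- W[n / 2L + i, cols[k]] + g[k]
    }
  }
  W
}

.dwt_cache <- new.env(parent = emptyenv())
.dwt_matrix <- function(n) {
  key <- as.character(n)
  if (is.null(.dwt_cache[[key]])) .dwt_cache[[key]] <- .dwt_step_matrix(n)
  .dwt_cache[[key]]
}

# full periodized DWT: returns list of approximation (level `levels`) and
# detail vectors d_levels..d_1
.dwt <- function(x, levels) {
  n <- length(x)
  if (bitwAnd(n, n - 1L) != 0L) stop("signal length must be a power of two")
  if (n / 2^levels < length(.db4) / 2L)
    stop("too many decomposition levels for this signal length")
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    W <- .dwt_matrix(length(a))
    y <- as.vector(W %*% a)
    a <- y[seq_len(length(a) / 2L)]
    details[[j]] <- y[-seq_len(length(a))]
  }
  list(a = a, d = rev(details))   # d[[1]] = coarsest (level `levels`)
}

.idwt <- function(dec) {
  a <- dec$a
  for (j in seq_along(dec$d)) {
    d <- dec$d[[j]]
    W <- .dwt_matrix(2L * length(a))
    a <- as.vector(crossprod(W, c(a, d)))
  }
  a
}

# band labels for a decomposition: "a<L>", "d<L>", ..., "d1"
.wavelet_bands <- function(n, levels) {
  lens <- c(n / 2^levels, n / 2^(levels:1))
  labs <- c(paste0("a", levels), paste0("d", levels:1))
  rep(labs, lens)
}

#' Wavelet descriptors of a radius profile
#'
#' Discrete wavelet transform (periodized orthonormal Daubechies-4) of the
#' mean-subtracted, scale-normalized radius profile `r / mean(r) - 1`. The
#' transform is orthonormal, so the full coefficient set preserves the
#' profile's energy (Parseval) and inverts exactly. The descriptor vector
#' retains the approximation band plus the detail bands listed in
#' `keep_details` (coarsest two by default, 64 coefficients at the default
#' 512-point / 5-level setting); the full set is kept alongside for
#' reconstruction diagnostics.
#'
#' @param profile an `oto_profile` from [polar_radius_profile()].
#' @param levels decomposition depth (default 5).
#' @param keep_details detail levels retained in the descriptor vector
#'   (default `c(5, 4)`); use `levels:1` to retain everything.
#' @return an `oto_descriptors` object (`kind = "wavelet"`).
#' @export
wavelet_descriptors <- function(profile, levels = 5L, keep_details = c(5L, 4L)) {
  r <- profile$radii
  scale <- mean(r)
  s <- r / scale - 1
  dec <- .dwt(s, levels)
  full <- c(dec$a, unlist(dec$d))
  bands <- .wavelet_bands(length(s), levels)
  keep <- bands %in% c(paste0("a", levels), paste0("d", keep_details))
  coefs <- full[keep]
  names(coefs) <- paste0("W", seq_along(coefs))
  structure(list(kind = "wavelet", coefficients = coefs,
                 full_coefficients = full, bands = bands, keep = keep,
                 levels = levels, n_points = length(s),
                 norm_info = list(centroid = profile$centroid,
                                  scale = scale, theta0 = profile$theta0)),
            class = "oto_descriptors")
}

#' @export
print.oto_descriptors <- function(x, ...) {
  cat(sprintf("<oto_descriptors> kind=%s  %d coefficients (of %d), n_points=%d\n",
              x$kind, length(x$coefficients),
              length(x$full_coefficients %||% x$coefficients), x$n_points))
  invisible(x)
}

# ---- elliptic Fourier descriptors ----

# raw Kuhl-Giardina EFD of a closed polygon: harmonic matrix [a b c d] rows
.efd_raw <- function(xy, n_harmonics) {
  closed <- rbind(xy, xy[1L, , drop = FALSE])
  dxy <- diff(closed)
  dt <- sqrt(rowSums(dxy^2))
  ok <- dt > 0
  dxy <- dxy[ok, , drop = FALSE]; dt <- dt[ok]
  t <- c(0, cumsum(dt)); T <- t[length(t)]
  t1 <- t[-length(t)]; t2 <- t[-1L]
  coefs <- matrix(0, n_harmonics, 4L,
                  dimnames = list(NULL, c("a", "b", "c", "d")))
  for (n in seq_len(n_harmonics)) {
    w <- 2 * pi * n / T
    const <- T / (2 * n^2 * pi^2)
    cosd <- cos(w * t2) - cos(w * t1)
    sind <- sin(w * t2) - sin(w * t1)
    coefs[n, "a"] <- const * sum(dxy[, 1L] / dt * cosd)
    coefs[n, "b"] <- const * sum(dxy[, 1L] / dt * sind)
    coefs[n, "c"] <- const * sum(dxy[, 2L] / dt * cosd)
    coefs[n, "d"] <- const * sum(dxy[, 2L] / dt * sind)
  }
  # DC terms (position of the outline)
  xi <- cumsum(dxy[, 1L]) - dxy[, 1L] / dt * t2
  A0 <- sum(dxy[, 1L] / (2 * dt) * (t2^2 - t1^2) + xi * dt) / T + xy[1L, 1L]
  delta <- cumsum(dxy[, 2L]) - dxy[, 2L] / dt * t2
  C0 <- sum(dxy[, 2L] / (2 * dt) * (t2^2 - t1^2) + delta * dt) / T + xy[1L, 2L]
  list(coefs = coefs, A0 = A0, C0 = C0, T = T)
}

# rotate harmonic n by start-point shift theta and spatial rotation psi
.efd_normalize <- function(coefs) {
  a1 <- coefs[1L, "a"]; b1 <- coefs[1L, "b"]
  c1 <- coefs[1L, "c"]; d1 <- coefs[1L, "d"]
  theta <- 0.5 * atan2(2 * (a1 * b1 + c1 * d1),
                       a1^2 + c1^2 - b1^2 - d1^2)
  H <- nrow(coefs)
  out <- coefs
  for (n in seq_len(H)) {
    M <- matrix(coefs[n, ], 2L, 2L, byrow = TRUE)
    R <- matrix(c(cos(n * theta), -sin(n * theta),
                  sin(n * theta),  cos(n * theta)), 2L, 2L, byrow = TRUE)
    out[n, ] <- as.vector(t(M %*% R))
  }
  psi <- atan2(out[1L, "c"], out[1L, "a"])
  Rp <- matrix(c(cos(psi), sin(psi), -sin(psi), cos(psi)), 2L, 2L, byrow = TRUE)
  for (n in seq_len(H)) {
    M <- matrix(out[n, ], 2L, 2L, byrow = TRUE)
    out[n, ] <- as.vector(t(Rp %*% M))
  }
  scale <- out[1L, "a"]
  out <- out / scale
  # resolve the residual 180-degree start/rotation ambiguity using the
  # dominant second-harmonic element (harmonic n flips by (-1)^(n+1))
  if (H >= 2L) {
    v2 <- out[2L, ]
    j <- which.max(abs(v2))
    if (abs(v2[j]) > 1e-9 && v2[j] < 0) {
      flip <- (-1)^(seq_len(H) + 1L)
      out <- out * flip
    }
  }
  list(coefs = out, theta = theta, psi = psi, scale = scale)
}

#' Elliptic Fourier descriptors of a contour
#'
#' Computes `n_harmonics` elliptic Fourier harmonics (4 coefficients each)
#' of the closed outline's arc-length parameterization, then applies the
#' standard first-harmonic normalization: translation removed (DC dropped),
#' start point rotated to the semi-major axis, spatial rotation removed,
#' scale divided by the semi-major axis length. The normalized vector keeps
#' the `4 * n_harmonics - 3` informative values (the first harmonic reduces
#' to its axis ratio `d1`).
#'
#' @param contour an [oto_contour()].
#' @param n_harmonics number of harmonics (default 20).
#' @param n_points optional: resample the contour to this many equally
#'   spaced vertices first. The default (`NULL`) uses the vertices as
#'   given, under which the normalized coefficients are exactly invariant
#'   to the starting vertex.
#' @return an `oto_descriptors` object (`kind = "fourier"`) whose
#'   `coefficients` are the normalized values (`d1`, then `a2..d2`, ...)
#'   and whose `raw` element retains the unnormalized harmonics and DC
#'   terms for reconstruction.
#' @export
fourier_descriptors <- function(contour, n_harmonics = 20L, n_points = NULL) {
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  if (!is.null(n_points)) contour <- resample_contour(contour, n_points)
  xy <- unclass(contour)
  raw <- .efd_raw(xy, n_harmonics)
  nrm <- .efd_normalize(raw$coefs)
  co <- nrm$coefs
  vec <- c(d1 = unname(co[1L, "d"]))
  if (n_harmonics >= 2L) {
    rest <- as.vector(t(co[-1L, , drop = FALSE]))
    names(rest) <- as.vector(t(outer(2:n_harmonics, c("a", "b", "c", "d"),
                                     function(n, l) paste0(l, n))))
    vec <- c(vec, rest)
  }
  structure(list(kind = "fourier", coefficients = vec,
                 raw = raw, n_harmonics = n_harmonics, n_points = nrow(xy),
                 norm_info = list(A0 = raw$A0, C0 = raw$C0,
                                  theta = nrm$theta, psi = nrm$psi,
                                  scale = nrm$scale)),
            class = "oto_descriptors")
}

#' Reconstruct an outline (or radius profile) from descriptors
#'
#' Inverse transform of a descriptor set. For wavelet descriptors the
#' retained coefficients (or the full set, if kept) are inverse-transformed
#' to a radius profile and re-wrapped around the stored centroid and start
#' angle. For elliptic Fourier descriptors the raw harmonics are summed up
#' to `n_harmonics`.
#'
#' @param descriptors an `oto_descriptors`.
#' @param n_points points of the reconstruction (EFD only; the wavelet
#'   reconstruction is at the stored dyadic resolution).
#' @param n_harmonics harmonics retained (EFD; default all stored).
#' @param full use the full wavelet coefficient set (TRUE) or only the
#'   retained descriptor bands (FALSE, default).
#' @return list with `contour` (an [oto_contour()]) and, for wavelet
#'   descriptors, `profile` (the reconstructed radius vector).
#' @export
reconstruct <- function(descriptors, n_points = NULL, n_harmonics = NULL,
                        full = FALSE) {
  ds <- descriptors
  if (ds$kind == "wavelet") {
    coefs <- if (full) ds$full_coefficients else {
      z <- numeric(length(ds$full_coefficients))
      z[ds$keep] <- ds$full_coefficients[ds$keep]
      z
    }
    n <- ds$n_points
    lens <- c(n / 2^ds$levels, n / 2^(ds$levels:1))
    parts <- split(coefs, rep(seq_along(lens), lens))
    s <- .idwt(list(a = parts[[1L]], d = parts[-1L]))
    r <- (s + 1) * ds$norm_info$scale
    th <- ds$norm_info$theta0 + 2 * pi * (seq_len(n) - 1L) / n
    xy <- cbind(ds$norm_info$centroid[1L] + r * cos(th),
                ds$norm_info$centroid[2L] + r * sin(th))
    list(contour = oto_contour(xy), profile = r)
  } else {
    H <- n_harmonics %||% ds$n_harmonics
    if (H > ds$n_harmonics) stop("more harmonics requested than stored")
    np <- n_points %||% ds$n_points
    t <- seq(0, 1, length.out = np + 1L)[-(np + 1L)]
    x <- rep(ds$raw$A0, np); y <- rep(ds$raw$C0, np)
    for (n in seq_len(H)) {
      cs <- cos(2 * pi * n * t); sn <- sin(2 * pi * n * t)
      x <- x + ds$raw$coefs[n, "a"] * cs + ds$raw$coefs[n, "b"] * sn
      y <- y + ds$raw$coefs[n, "c"] * cs + ds$raw$coefs[n, "d"] * sn
    }
    list(contour = oto_contour(cbind(x, y)))
  }
}

#' Reconstruction-quality diagnostic
#'
#' Per-point deviation between a truncated reconstruction and the source
#' outline. For wavelet descriptors the deviation is radial
#' (|reconstructed radius - original radius| at each angular position); for
#' EFD it is the Euclidean distance at matched arc-length parameter values.
#'
#' @param descriptors an `oto_descriptors` of the contour.
#' @param contour the source [oto_contour()].
#' @param n_harmonics EFD truncation (default all stored).
#' @param full wavelet: diagnose the full set instead of the retained bands.
#' @return list with `per_point` deviations, `mean`, `rms` and `max`
#'   (contour units).
#' @export
reconstruction_diagnostic <- function(descriptors, contour,
                                      n_harmonics = NULL, full = FALSE) {
  ds <- descriptors
  if (ds$kind == "wavelet") {
    prof <- polar_radius_profile(contour, ds$n_points)
    rec <- reconstruct(ds, full = full)
    dev <- abs(rec$profile - prof$radii)
  } else {
    src <- unclass(resample_contour(contour, ds$n_points))
    rec <- unclass(reconstruct(ds, n_points = ds$n_points,
                               n_harmonics = n_harmonics)$contour)
    # the EFD parameter starts at the contour start point; align lengths
    m <- min(nrow(src), nrow(rec))
    dev <- sqrt(rowSums((src[seq_len(m), ] - rec[seq_len(m), ])^2))
  }
  list(per_point = dev, mean = mean(dev),
       rms = sqrt(mean(dev^2)), max = max(dev))
}

#' Per-position variance decomposition of wavelet descriptors
#'
#' For a set of wavelet descriptor sets sharing one configuration, computes
#' the across-specimen variance of the normalized radius profile at each
#' angular position and attributes it to wavelet bands: each specimen's
#' profile is split into band components (inverse transform of one band at
#' a time) and the attribution of band b at position p is
#' `cov(component_b(p), profile(p))`, which sums exactly to the total
#' variance. Attributions can be negative where bands covary negatively.
#'
#' @param descriptor_sets list of `oto_descriptors` (`kind = "wavelet"`,
#'   same `n_points` and `levels`), at least 3.
#' @return data frame: `position` (angular index), `total_var`, one column
#'   per band (`a5`, `d5`, ..., `d1` at the default depth).
#' @export
position_variation <- function(descriptor_sets) {
  if (length(descriptor_sets) < 3L)
    stop("at least 3 specimens are required")
  k0 <- descriptor_sets[[1L]]
  if (k0$kind != "wavelet") stop("position variation is defined for wavelet descriptors")
  same <- vapply(descriptor_sets, function(d)
    d$kind == "wavelet" && d$n_points == k0$n_points && d$levels == k0$levels,
    logical(1L))
  if (!all(same)) stop("descriptor sets have mixed configurations")
  n <- k0$n_points
  band_labels <- unique(.wavelet_bands(n, k0$levels))
  lens <- c(n / 2^k0$levels, n / 2^(k0$levels:1))
  comp <- function(ds, band) {
    z <- numeric(n)
    sel <- .wavelet_bands(n, k0$levels) == band
    z[sel] <- ds$full_coefficients[sel]
    parts <- split(z, rep(seq_along(lens), lens))
    .idwt(list(a = parts[[1L]], d = parts[-1L]))
  }
  profiles <- vapply(descriptor_sets, function(ds)
    .idwt(list(a = ds$full_coefficients[seq_len(lens[1L])],
               d = split(ds$full_coefficients[-seq_len(lens[1L])],
                         rep(seq_along(lens[-1L]), lens[-1L])))),
    numeric(n))
  total <- apply(profiles, 1L, var)
  out <- data.frame(position = seq_len(n), total_var = total)
  for (b in band_labels) {
    comps <- vapply(descriptor_sets, comp, numeric(n), band = b)
    out[[b]] <- vapply(seq_len(n), function(p)
      cov(comps[p, ], profiles[p, ]), numeric(1L))
  }
  out
}

#' Descriptor matrix for a set of contours
#'
#' Applies one descriptor extraction to every contour and stacks the
#' coefficient vectors into a matrix (rows = otoliths). Right-side contours
#' are mirrored to left orientation first (configurable), so both sides
#' live in one shape space.
#'
#' @param contours named list of [oto_contour()]s (names
#'   `"<specimen_id>_<side>"`).
#' @param kind `"wavelet"` or `"fourier"`.
#' @param mirror_right mirror contours whose name ends in `"_R"`.
#' @param ... passed to [wavelet_descriptors()] (via
#'   [polar_radius_profile()]) or [fourier_descriptors()].
#' @param n_points angular / arc-length sampling resolution.
#' @return numeric matrix with rownames from `contours`; attribute
#'   `descriptor_sets` holds the per-contour `oto_descriptors`.
#' @export
descriptor_matrix <- function(contours, kind = c("wavelet", "fourier"),
                              mirror_right = TRUE, n_points = 512L, ...) {
  kind <- match.arg(kind)
  sets <- lapply(names(contours), function(key) {
    ct <- contours[[key]]
    if (mirror_right && grepl("_R$", key)) ct <- mirror_contour(ct)
    if (kind == "wavelet")
      wavelet_descriptors(polar_radius_profile(ct, n_points), ...)
    else
      fourier_descriptors(ct, ...)
  })
  names(sets) <- names(contours)
  mat <- do.call(rbind, lapply(sets, function(s) s$coefficients))
  rownames(mat) <- names(contours)
  attr(mat, "descriptor_sets") <- sets
  mat
}
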