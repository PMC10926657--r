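# Group mean shapes: average in wavelet-descriptor space, reconstruct, and
# overlay aligned contours for the classical per-class / per-sex figures.

#' Mean shape of a group of otoliths
#'
#' Averages full wavelet coefficient vectors (and normalization scales)
#' within each group and inverse-transforms the mean — because the
#' transform is linear, this equals the pointwise mean of the normalized
#' radius profiles. The per-position dispersion band is the standard
#' deviation of the radius across specimens.
#'
#' @param descriptor_sets named list of `oto_descriptors`
#'   (`kind = "wavelet"`, one shared configuration).
#' @param groups factor-like aligned with `descriptor_sets`; every group
#'   n >= 2.
#' @param scale_mm reconstruct at the group's mean radius (TRUE) or at unit
#'   mean radius (FALSE, pure shape).
#' @return an `oto_meanshape`: per group, the mean coefficient vector, the
#'   reconstructed [oto_contour()], the mean radius profile and the
#'   per-position radius sd.
#' @export
group_mean_shape <- function(descriptor_sets, groups, scale_mm = TRUE) {
  groups <- factor(groups)
  if (length(descriptor_sets) != length(groups))
    stop("descriptor_sets and groups must align")
  if (any(table(groups) < 2L)) stop("every group needs n >= 2")
  k0 <- descriptor_sets[[1L]]
  same <- vapply(descriptor_sets, function(d)
    d$kind == k0$kind && d$n_points == k0$n_points &&
      identical(d$levels, k0$levels), logical(1L))
  if (!all(same)) stop("mixed descriptor configurations")
  if (k0$kind != "wavelet")
    stop("mean shapes are computed from wavelet descriptors")
  n <- k0$n_points
  lens <- c(n / 2^k0$levels, n / 2^(k0$levels:1))
  shapes <- lapply(levels(groups), function(lev) {
    sel <- which(groups == lev)
    C <- vapply(descriptor_sets[sel], function(d) d$full_coefficients,
                numeric(n))
    scl <- vapply(descriptor_sets[sel], function(d) d$norm_info$scale,
                  numeric(1L))
    mc <- rowMeans(C)
    parts <- split(mc, rep(seq_along(lens), lens))
    s <- .idwt(list(a = parts[[1L]], d = parts[-1L]))
    R <- if (scale_mm) mean(scl) else 1
    r <- (s + 1) * R
    # dispersion of the (scaled) radius across specimens at each position
    profs <- vapply(seq_along(sel), function(i) {
      d <- descriptor_sets[[sel[i]]]
      p <- split(d$full_coefficients, rep(seq_along(lens), lens))
      ( .idwt(list(a = p[[1L]], d = p[-1L])) + 1 ) *
        (if (scale_mm) scl[i] else 1)
    }, numeric(n))
    disp <- apply(profs, 1L, sd)
    th <- 2 * pi * (seq_len(n) - 1L) / n
    list(group = lev, mean_coefficients = mc, mean_scale = R,
         radius = r, dispersion = disp,
         contour = oto_contour(cbind(r * cos(th), r * sin(th))))
  })
  names(shapes) <- levels(groups)
  structure(list(shapes = shapes, kind = k0$kind, n_points = n),
            class = "oto_meanshape")
}

#' @export
print.oto_meanshape <- function(x, ...) {
  cat(sprintf("<oto_meanshape> %d groups at %d points: %s\n",
              length(x$shapes), x$n_points,
              paste(names(x$shapes), collapse = ", ")))
  invisible(x)
}

#' @export
plot.oto_meanshape <- function(x, ..., main = "Mean shapes") {
  cols <- seq_along(x$shapes)
  xr <- range(unlist(lapply(x$shapes, function(s) unclass(s$contour)[, 1L])))
  yr <- range(unlist(lapply(x$shapes, function(s) unclass(s$contour)[, 2L])))
  plot.default(NA, xlim = xr, ylim = yr, asp = 1, xlab = "x (mm)",
               ylab = "y (mm)", main = main)
  for (i in seq_along(x$shapes)) {
    xy <- unclass(x$shapes[[i]]$contour)
    lines(rbind(xy, xy[1L, ]), col = cols[i], lwd = 2)
  }
  legend("topright", legend = names(x$shapes), col = cols, lwd = 2, bty = "n")
  invisible(x)
}

#' Export aligned mean-shape overlays
#'
#' Aligns mean shapes on a common centroid with the principal axis
#' horizontal (anterior to the left, the usual left-otolith display
#' convention), writes one coordinates CSV per group plus a combined
#' overlay plot.
#'
#' @param meanshape an [group_mean_shape()] result.
#' @param dir output directory.
#' @param format plot format, `"png"` or `"svg"`.
#' @return invisible character vector of written file paths.
#' @export
overlay_export <- function(meanshape, dir, format = c("png", "svg")) {
  format <- match.arg(format)
  if (!length(meanshape$shapes)) stop("empty mean-shape input")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  aligned <- lapply(meanshape$shapes, function(s) {
    xy <- unclass(s$contour)
    xy <- sweep(xy, 2L, contour_centroid(s$contour))
    u <- principal_axis(xy)$u
    p <- xy %*% u
    if (abs(min(p)) < abs(max(p))) u <- -u   # anterior (far tip) leftward
    v <- c(-u[2L], u[1L])
    oto_contour(cbind(xy %*% u, xy %*% v))
  })
  for (g in names(aligned)) {
    f <- file.path(dir, paste0("mean_shape_", gsub("[^A-Za-z0-9]", "_", g), ".csv"))
    write_contour_csv(aligned[[g]], f)
    paths <- c(paths, f)
  }
  pf <- file.path(dir, paste0("mean_shapes.", format))
  if (format == "png") png(pf, width = 800, height = 800) else svg(pf)
  ms <- meanshape; ms$shapes <- lapply(names(aligned), function(g) {
    s <- meanshape$shapes[[g]]; s$contour <- aligned[[g]]; s
  })
  names(ms$shapes) <- names(aligned)
  plot(ms)
  dev.off()
  invisible(c(paths, pf))
}
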