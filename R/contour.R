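#' Closed planar contour
#'
#' An `oto_contour` is an ordered set of (x, y) vertices describing a single
#' closed outline (last vertex implicitly connects to the first), stored
#' counter-clockwise so that the signed (shoelace) area is positive.
#' Coordinates are in a consistent unit, millimetres by default; pixel
#' contours carry a `px_per_mm` attribute instead.
#'
#' @param xy two-column numeric matrix (or data frame) of vertices; a
#'   duplicated closing vertex is dropped.
#' @param unit coordinate unit, `"mm"` or `"px"`.
#' @param px_per_mm pixel pitch when `unit = "px"` (NA if unknown).
#' @return an `oto_contour`: the vertex matrix with class and attributes.
#' @export
oto_contour <- function(xy, unit = "mm", px_per_mm = NA_real_) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L) stop("contour must have two columns (x, y)")
  storage.mode(xy) <- "double"
  if (anyNA(xy)) stop("contour contains NA coordinates")
  n <- nrow(xy)
  if (n > 1L && all(abs(xy[n, ] - xy[1L, ]) < 1e-12)) xy <- xy[-n, , drop = FALSE]
  if (nrow(xy) < 3L) stop("contour needs at least 3 distinct vertices")
  if (signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  if (abs(signed_area(xy)) < .Machine$double.eps * 100)
    stop("degenerate contour: zero area")
  colnames(xy) <- c("x", "y")
  structure(xy, class = "oto_contour", unit = unit, px_per_mm = px_per_mm)
}

#' @export
print.oto_contour <- function(x, ...) {
  cat(sprintf("<oto_contour> %d vertices [%s]  area %.4g  perimeter %.4g\n",
              nrow(x), attr(x, "unit"), contour_area(x), contour_perimeter(x)))
  invisible(x)
}

#' @export
plot.oto_contour <- function(x, ..., asp = 1) {
  xy <- rbind(unclass(x), unclass(x)[1L, , drop = FALSE])
  plot.default(xy, type = "l", asp = asp, xlab = "x", ylab = "y", ...)
  invisible(x)
}

# principal axis of the uniform measure on the closed curve, from exact
# line-integral (per-edge) second moments: sampling-independent and exactly
# rotation-equivariant
principal_axis <- function(xy) {
  q <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE])
  w <- sqrt(rowSums((q - xy)^2))
  keep <- w > 0
  p <- xy[keep, , drop = FALSE]; q <- q[keep, , drop = FALSE]; w <- w[keep]
  W <- sum(w)
  m <- colSums((p + q) / 2 * w) / W
  p <- sweep(p, 2L, m); q <- sweep(q, 2L, m)
  S <- (crossprod(p * w, p) + crossprod(q * w, q)) / 3 +
       (crossprod(p * w, q) + crossprod(q * w, p)) / 6
  ev <- eigen(S / W, symmetric = TRUE)
  list(center = m, u = ev$vectors[, 1L], v = ev$vectors[, 2L],
       values = ev$values)
}

signed_area <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Contour area, perimeter and centroid
#'
#' Shoelace area (absolute value), polygonal arc length of the closed
#' outline, and the area centroid of the enclosed polygon.
#'
#' @param contour an [oto_contour()].
#' @return a scalar (`contour_area`, `contour_perimeter`) or length-2 vector
#'   (`contour_centroid`).
#' @export
contour_area <- function(contour) abs(signed_area(contour))

#' @rdname contour_area
#' @export
contour_perimeter <- function(contour) {
  xy <- unclass(contour)
  d <- rbind(xy[-1L, , drop = FALSE], xy[1L, , drop = FALSE]) - xy
  sum(sqrt(rowSums(d^2)))
}

#' @rdname contour_area
#' @export
contour_centroid <- function(contour) {
  xy <- unclass(contour)
  x <- xy[, 1L]; y <- xy[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(x = sum((x + xn) * cr) / (6 * a), y = sum((y + yn) * cr) / (6 * a))
}

#' Resample a contour to equal arc-length spacing
#'
#' Re-parameterises the closed outline by arc length and places `n_points`
#' equally spaced vertices, keeping the original starting vertex. Required
#' upstream of the dyadic wavelet transform and used internally wherever a
#' uniform vertex density matters (e.g. principal-axis estimation).
#'
#' @param contour an [oto_contour()].
#' @param n_points number of vertices, at least 32; a power of two if the
#'   result feeds the wavelet descriptors.
#' @return an [oto_contour()] with `n_points` vertices.
#' @export
resample_contour <- function(contour, n_points = 512L) {
  if (n_points < 32L) stop("n_points must be >= 32")
  xy <- unclass(contour)
  closed <- rbind(xy, xy[1L, , drop = FALSE])
  seg <- sqrt(rowSums((closed[-1L, , drop = FALSE] - closed[-nrow(closed), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate contour: zero arc length")
  t_new <- seq(0, total, length.out = n_points + 1L)[-(n_points + 1L)]
  out <- cbind(approx(s, closed[, 1L], xout = t_new)$y,
               approx(s, closed[, 2L], xout = t_new)$y)
  oto_contour(out, unit = attr(contour, "unit"),
              px_per_mm = attr(contour, "px_per_mm"))
}

#' Mirror a contour about the vertical axis
#'
#' Used to bring right-side otoliths into left orientation before descriptor
#' extraction, so left and right outlines live in one shape space.
#'
#' @param contour an [oto_contour()].
#' @return the mirrored [oto_contour()] (re-oriented counter-clockwise).
#' @export
mirror_contour <- function(contour) {
  xy <- unclass(contour)
  xy[, 1L] <- -xy[, 1L]
  oto_contour(xy, unit = attr(contour, "unit"), px_per_mm = attr(contour, "px_per_mm"))
}

#' Read / write contours as two-column CSV
#'
#' Plain-text interchange used by the pipeline: columns `x_mm`, `y_mm`
#' (closure implicit).
#'
#' @param contour an [oto_contour()].
#' @param path file path.
#' @return `write_contour_csv` returns `path` invisibly; `read_contour_csv`
#'   returns an [oto_contour()].
#' @export
write_contour_csv <- function(contour, path) {
  df <- as.data.frame(unclass(contour))
  names(df) <- c("x_mm", "y_mm")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  df <- read.csv(path)
  oto_contour(as.matrix(df[, 1:2]))
}
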