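# Size measures and dimensionless shape indices.

#' Measure a contour: length, width, perimeter, area
#'
#' Aligns the outline to its principal axis (second-moment eigenvectors of
#' an equal-arc-length resampling, so the axis does not depend on vertex
#' density) and reports:
#' \describe{
#'   \item{OL}{maximum extent along the principal axis (otolith length)}
#'   \item{OW}{maximum extent perpendicular to it (otolith width)}
#'   \item{OP}{polygonal perimeter of the closed outline}
#'   \item{OS}{enclosed (shoelace) area}
#' }
#' All four are rotation- and translation-invariant. Units follow the
#' contour's unit.
#'
#' @param contour an [oto_contour()].
#' @param axis `"principal"` (default, box extents along the principal
#'   axis) or `"feret"` (OL = maximal point-pair distance, OW = maximal
#'   extent perpendicular to the Feret diameter).
#' @return named numeric vector `c(OL, OW, OP, OS)`.
#' @export
measure_contour <- function(contour, axis = c("principal", "feret")) {
  axis <- match.arg(axis)
  xy <- unclass(contour)
  OP <- contour_perimeter(contour)
  OS <- contour_area(contour)
  if (OS <= 0) stop("degenerate contour: zero area")
  if (axis == "principal") {
    u <- principal_axis(xy)$u           # principal (major) axis
  } else {
    d2 <- as.matrix(dist(xy))
    ij <- which(d2 == max(d2), arr.ind = TRUE)[1L, ]
    u <- xy[ij[2L], ] - xy[ij[1L], ]
    u <- u / sqrt(sum(u^2))
  }
  v <- c(-u[2L], u[1L])
  p1 <- xy %*% u
  p2 <- xy %*% v
  OL <- diff(range(p1))
  OW <- diff(range(p2))
  if (OW > OL && axis == "principal") { tmp <- OL; OL <- OW; OW <- tmp }
  c(OL = OL, OW = OW, OP = OP, OS = OS)
}

#' Shape indices from size measures
#'
#' The six classical dimensionless otolith shape indices:
#' circularity `C = OP^2 / OS`, rectangularity `Re = OS / (OL * OW)`,
#' ellipticity `E = (OL - OW) / (OL + OW)` (signed: negative when the
#' outline is wider than long, as in asterisci), aspect ratio
#' `AR = OW / OL`, form factor `FF = 4 * pi * OS / OP^2` and roundness
#' `Ro = 4 * OS / (pi * OL^2)`. `FF * C = 4 * pi` identically; `Ro` may
#' exceed 1 when OW > OL and is not clamped.
#'
#' @param OL,OW,OP,OS positive size measures (see [measure_contour()]).
#' @return named numeric vector `c(C, Re, E, AR, FF, Ro)`.
#' @export
shape_indices <- function(OL, OW, OP, OS) {
  if (any(c(OL, OW, OP, OS) <= 0)) stop("all size measures must be positive")
  OL <- unname(OL); OW <- unname(OW); OP <- unname(OP); OS <- unname(OS)
  c(C  = OP^2 / OS,
    Re = OS / (OL * OW),
    E  = (OL - OW) / (OL + OW),
    AR = OW / OL,
    FF = 4 * pi * OS / OP^2,
    Ro = 4 * OS / (pi * OL^2))
}

#' Relative otolith size
#'
#' Ratio of otolith length to fish total length, `OL / TL`; reported as a
#' percentage (x100) in summary tables.
#'
#' @param OL otolith length, mm (> 0).
#' @param TL fish total length, mm (> 0).
#' @return the dimensionless ratio OL/TL.
#' @export
relative_size <- function(OL, TL) {
  if (any(TL <= 0)) stop("TL must be positive")
  if (any(OL <= 0)) stop("OL must be positive")
  OL / TL
}

#' Assign the TL-defined size class
#'
#' Class I: TL <= 240 mm; Class II: 240 < TL <= 290 mm; Class III:
#' TL > 290 mm (boundaries closed above, as printed).
#'
#' @param TL fish total length in mm (> 0); vectorised.
#' @return character vector of `"I"`, `"II"`, `"III"`.
#' @export
classify_size_class <- function(TL) {
  if (any(TL <= 0)) stop("TL must be positive")
  ifelse(TL <= 240, "I", ifelse(TL <= 290, "II", "III"))
}

#' One-dimensional k-means on fish lengths
#'
#' Utility mirroring the k-means step used to motivate the fixed size-class
#' thresholds; the thresholds of [classify_size_class()] remain
#' authoritative for class assignment. Labels are renumbered by ascending
#' cluster centre and the fit is deterministic given the seed (many random
#' starts, which for 1-D data reliably reaches the global optimum).
#'
#' @param TLs numeric vector of lengths, mm.
#' @param k number of clusters.
#' @param seed RNG seed.
#' @param nstart random starts passed to [stats::kmeans()].
#' @return integer labels in `1..k`, ordered so cluster 1 has the smallest
#'   centre.
#' @export
kmeans_classes <- function(TLs, k = 3L, seed = 1L, nstart = 50L) {
  if (k > length(unique(TLs)))
    stop("k exceeds the number of distinct TL values")
  km <- with_seed(seed, kmeans(TLs, centers = k, nstart = nstart))
  ord <- order(km$centers)
  match(km$cluster, ord)
}

#' Per-otolith morphometric records
#'
#' Joins contours to specimen metadata and computes the full record for
#' each otolith: OL, OW, OP, OS, OL/TL and the six shape indices.
#'
#' @param contours named list of [oto_contour()]s, names
#'   `"<specimen_id>_<side>"`.
#' @param specimens specimen table with `specimen_id`, `TL_mm`, `BW_g`,
#'   `sex`, `size_class`.
#' @return data frame, one row per otolith, with metadata, `side`, the four
#'   size measures, `OL_TL` and the indices.
#' @export
morphometry_table <- function(contours, specimens) {
  rows <- lapply(names(contours), function(key) {
    us <- regexpr("_[^_]*$", key)
    sid <- substr(key, 1L, us - 1L)
    side <- substr(key, us + 1L, nchar(key))
    sp <- specimens[specimens$specimen_id == sid, ]
    if (nrow(sp) != 1L) stop("missing metadata for specimen ", sid)
    m <- measure_contour(contours[[key]])
    si <- shape_indices(m["OL"], m["OW"], m["OP"], m["OS"])
    data.frame(sp, side = side, t(m), t(si),
               OL_TL = relative_size(m[["OL"]], sp$TL_mm),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group summary of morphometric records
#'
#' Mean, sd, min and max of each measure and index by a grouping column,
#' shaped like the classical per-class / per-side report tables (values
#' rounded half-up to 2 decimals; OL/TL reported x100 as a percentage).
#'
#' @param records a [morphometry_table()] result.
#' @param by name of the grouping column (e.g. `"size_class"`, `"side"`,
#'   `"sex"`).
#' @param digits decimals for the rounded report (default 2).
#' @return data frame with one row per (group, variable) and columns
#'   `mean`, `sd`, `min`, `max`, `n`.
#' @export
morphometry_summary <- function(records, by = "size_class", digits = 2L) {
  vars <- c("OL", "OW", "OP", "OS", "OL_TL_pct", "C", "Re", "E", "AR", "FF", "Ro")
  records$OL_TL_pct <- records$OL_TL * 100
  half_up <- function(x) floor(x * 10^digits + 0.5) / 10^digits
  out <- list()
  for (g in unique(records[[by]])) {
    sub <- records[records[[by]] == g, ]
    for (v in vars) {
      x <- sub[[v]]
      out[[paste(g, v)]] <- data.frame(
        group = g, variable = v, n = length(x),
        mean = half_up(mean(x)), sd = half_up(sd(x)),
        min = half_up(min(x)), max = half_up(max(x)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
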