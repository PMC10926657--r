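# Image input and contour extraction: binarise a grayscale otolith
# photograph, keep the largest foreground component, and trace its outer
# boundary as a sub-pixel iso-contour at level 0.5.

#' Read a grayscale image
#'
#' Reads PNG (8/16-bit) or TIFF into a numeric matrix in `[0,1]`, top row
#' first. Multi-channel images are averaged to one channel.
#'
#' @param path image file path.
#' @return numeric matrix of class `oto_image`.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' is required to read TIFF images")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3L) img <- apply(img[, , seq_len(min(3L, dim(img)[3L])),
                                               drop = FALSE], c(1L, 2L), mean)
  structure(img, class = "oto_image", px_per_mm = NA_real_)
}

#' Binarise a grayscale image
#'
#' Thresholds at a normalised intensity and removes foreground components
#' smaller than `min_object_px`. With `polarity = "bright_object"` (the
#' default, matching a bright otolith on a dark stage) foreground pixels are
#' those above the threshold; with `"dark_object"`, those below it.
#'
#' @param image numeric matrix (intensities normalisable to `[0,1]`).
#' @param threshold normalised intensity cut in (0, 1); default 0.05.
#' @param polarity `"bright_object"` or `"dark_object"`.
#' @param min_object_px connected components smaller than this are removed.
#' @return logical matrix mask of class `oto_mask` (TRUE = object), with the
#'   input's `px_per_mm` attribute carried over.
#' @export
binarize <- function(image, threshold = 0.05, polarity = "bright_object",
                     min_object_px = 64L) {
  polarity <- match.arg(polarity, c("bright_object", "dark_object"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  img <- unclass(image)
  if (max(img) > 1) img <- img / max(img)
  mask <- if (polarity == "bright_object") img > threshold else img < threshold
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_object_px)
  mask <- matrix(lab %in% keep, nrow = nrow(img))
  if (!any(mask))
    stop(errorCondition("no foreground pixels survive binarization",
                        class = c("oto_no_foreground", "error", "condition")))
  structure(mask, class = "oto_mask", px_per_mm = attr(image, "px_per_mm"))
}

#' Extract the outer outline of the largest object
#'
#' Traces the boundary of the largest foreground component as a sub-pixel
#' iso-contour at level 0.5 (marching-squares style, via
#' [grDevices::contourLines()]), giving smoother perimeter estimates than
#' pixel-edge chain codes. Holes are ignored. Coordinates follow the
#' package convention: pixel centres at integer coordinates, x rightward,
#' y upward (row axis flipped relative to matrix storage). The contour is
#' returned counter-clockwise.
#'
#' @param mask an `oto_mask` (or logical matrix) with at least one
#'   foreground component.
#' @return an [oto_contour()] in pixel units, carrying `px_per_mm`.
#' @export
extract_outline <- function(mask) {
  m <- unclass(mask)
  storage.mode(m) <- "double"
  if (!any(m > 0)) stop("mask has no foreground component")
  lab <- EBImage::bwlabel(m > 0)
  sizes <- tabulate(lab[lab > 0L])
  big <- which.max(sizes)
  comp <- lab == big
  H <- nrow(comp); W <- ncol(comp)
  if (any(comp[1L, ]) || any(comp[H, ]) || any(comp[, 1L]) || any(comp[, W]))
    stop(errorCondition("largest component touches the image border; outline incomplete",
                        class = c("oto_border_touch", "error", "condition")))
  # contourLines wants z[i, j] at (x[i], y[j]); convert from row-major
  # top-first storage to the x-right / y-up frame.
  z <- t(comp[H:1, , drop = FALSE]) * 1
  cl <- contourLines(x = seq_len(W), y = seq_len(H), z = z, levels = 0.5)
  if (!length(cl)) stop("no iso-contour found")
  areas <- vapply(cl, function(l) abs(signed_area(cbind(l$x, l$y))), numeric(1L))
  l <- cl[[which.max(areas)]]
  oto_contour(cbind(l$x, l$y), unit = "px", px_per_mm = attr(mask, "px_per_mm"))
}

#' Convert a pixel contour to millimetres
#'
#' @param contour an [oto_contour()] in px with a known `px_per_mm`.
#' @param px_per_mm override for the stored resolution.
#' @return an [oto_contour()] in mm (centred coordinates are preserved up to
#'   the uniform scale; image-frame translation is not meaningful in mm).
#' @export
contour_px_to_mm <- function(contour, px_per_mm = attr(contour, "px_per_mm")) {
  if (is.na(px_per_mm)) stop("px_per_mm unknown; supply it explicitly")
  oto_contour(unclass(contour) / px_per_mm, unit = "mm", px_per_mm = NA_real_)
}
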