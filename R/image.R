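#' 8-bit greyscale images
#'
#' Images are stored as plain numeric matrices with \code{nrow = height} and
#' \code{ncol = width}, holding integer-valued intensities in [0, 255].
#' Pixel coordinates are 0-based with \code{x} the column index and \code{y}
#' the row index, so pixel (x, y) is matrix element \code{[y + 1, x + 1]} and
#' the pixel centre sits at the integer point (x, y).
#'
#' @param pixels numeric matrix of intensities in [0, 255].
#' @return an object of class \code{xr_image} (a matrix).
#' @export
xr_image <- function(pixels) {
  stop_if_not(is.matrix(pixels) && is.numeric(pixels), "pixels must be a numeric matrix")
  stop_if_not(all(is.finite(pixels)), "pixels must be finite")
  stop_if_not(min(pixels) >= 0 && max(pixels) <= 255,
              "intensities must lie within [0, 255]")
  structure(pixels, class = c("xr_image", "matrix", "array"))
}

#' @export
print.xr_image <- function(x, ...) {
  cat(sprintf("<xr_image %d x %d px, intensity range [%g, %g]>\n",
              ncol(x), nrow(x), min(x), max(x)))
  invisible(x)
}

img_width <- function(img) ncol(img)
img_height <- function(img) nrow(img)

#' Read / write 8-bit greyscale images
#'
#' PNG is the default interchange format; TIFF is accepted on read when the
#' \pkg{tiff} package is available. Multi-channel input is collapsed to
#' greyscale by averaging.
#'
#' @param path file path.
#' @return \code{read_image} returns an \code{xr_image}.
#' @export
read_image <- function(path) {
  stop_if_not(file.exists(path), paste0("no such image file: ", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    stop_if_not(requireNamespace("tiff", quietly = TRUE), "tiff package required for TIFF input")
    a <- tiff::readTIFF(path)
  } else {
    a <- png::readPNG(path)
  }
  if (length(dim(a)) == 3L) a <- apply(a[, , 1:min(3L, dim(a)[3]), drop = FALSE], c(1, 2), mean)
  xr_image(clip8(a * 255))
}

#' @rdname read_image
#' @param img an \code{xr_image} (or plain matrix in [0, 255]).
#' @export
write_image <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

# -- binary masks -----------------------------------------------------------

as_mask <- function(m) {
  stop_if_not(is.matrix(m), "mask must be a matrix")
  storage.mode(m) <- "integer"
  stop_if_not(all(m %in% c(0L, 1L)), "mask must be strictly binary")
  m
}

mask_area <- function(m) sum(m != 0)

# tight bounding box of a mask: list(x0, y0, x1, y1) in 0-based pixel coords,
# inclusive; NULL for an empty mask
mask_bbox <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NULL)
  list(x0 = min(idx[, 2]) - 1L, y0 = min(idx[, 1]) - 1L,
       x1 = max(idx[, 2]) - 1L, y1 = max(idx[, 1]) - 1L)
}

# -- polygon <-> mask -------------------------------------------------------

#' Rasterize a closed polygon into a binary mask
#'
#' A pixel belongs to the mask when its centre lies strictly inside the
#' polygon, or when it lies on the polygon outline (outline pixels are found
#' by walking every edge). This boundary-inclusive convention is the exact
#' inverse of [trace_mask_polygon()], which emits boundary pixel centres, so
#' the trace/rasterize round trip reproduces hole-free masks almost exactly.
#'
#' @param poly two-column matrix of (x, y) vertices in 0-based pixel
#'   coordinates; the polygon is closed implicitly.
#' @param width,height output mask dimensions in pixels.
#' @param include_boundary mark outline pixels as members (the convention
#'   for label polygons, whose vertices are boundary pixel centres). Set
#'   \code{FALSE} for continuous contours, where membership is centre-inside
#'   only.
#' @return binary integer matrix of dim \code{c(height, width)}.
#' @export
rasterize_polygon <- function(poly, width, height, include_boundary = TRUE) {
  poly <- as.matrix(poly)
  stop_if_not(ncol(poly) == 2 && nrow(poly) >= 3, "polygon needs >= 3 (x, y) vertices")
  m <- matrix(0L, height, width)

  # interior: pixel centres strictly inside (mgcv::in.out is boundary-exclusive)
  bb_x <- max(0L, floor(min(poly[, 1]))):min(width - 1L, ceiling(max(poly[, 1])))
  bb_y <- max(0L, floor(min(poly[, 2]))):min(height - 1L, ceiling(max(poly[, 2])))
  if (length(bb_x) > 0 && length(bb_y) > 0) {
    pts <- cbind(rep(bb_x, times = length(bb_y)), rep(bb_y, each = length(bb_x)))
    bnd <- rbind(poly, poly[1, ])
    inside <- mgcv::in.out(bnd, pts)
    if (any(inside)) m[cbind(pts[inside, 2] + 1L, pts[inside, 1] + 1L)] <- 1L
  }

  if (!include_boundary) return(m)

  # outline: DDA walk, one cell per major-axis step (a finer walk would mark
  # corner cells off the 8-connected path and inflate thin shapes)
  n <- nrow(poly)
  for (i in seq_len(n)) {
    p <- poly[i, ]; q <- poly[if (i == n) 1L else i + 1L, ]
    steps <- max(1L, round(max(abs(q - p))))
    t <- seq(0, 1, length.out = steps + 1L)
    xs <- round(p[1] + t * (q[1] - p[1]))
    ys <- round(p[2] + t * (q[2] - p[2]))
    keep <- xs >= 0 & xs < width & ys >= 0 & ys < height
    if (any(keep)) m[cbind(ys[keep] + 1L, xs[keep] + 1L)] <- 1L
  }
  m
}

#' Trace the outer boundary polygon of a binary mask
#'
#' Returns the ordered centres of the boundary pixels of the largest
#' connected component (8-connectivity), as a closed ring suitable for
#' polygon instance labels. Holes are not traced; callers wanting an exact
#' round trip should hole-fill first.
#'
#' @param mask binary matrix.
#' @return two-column matrix of 0-based (x, y) vertices.
#' @export
trace_mask_polygon <- function(mask) {
  mask <- as_mask(mask)
  stop_if_not(mask_area(mask) > 0, "cannot trace an empty mask")
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which.max(areas)
  oc <- EBImage::ocontour(matrix(as.integer(lab == keep), nrow(mask), ncol(mask)))[[1]]
  # ocontour reports 0-based (first-dim, second-dim) = (row, col) for our layout
  cbind(x = oc[, 2], y = oc[, 1])
}

# largest 8-connected component of a mask, as a binary matrix
largest_component <- function(mask) {
  lab <- EBImage::bwlabel(as_mask(mask))
  if (max(lab) == 0) return(as_mask(mask * 0L))
  areas <- tabulate(lab[lab > 0])
  matrix(as.integer(lab == which.max(areas)), nrow(mask), ncol(mask))
}

# hole-filled mask (EBImage::fillHull)
fill_holes <- function(mask) {
  matrix(as.integer(EBImage::fillHull(as_mask(mask)) > 0), nrow(mask), ncol(mask))
}

# -- geometric resampling ---------------------------------------------------

# Inverse-mapped affine resampling shared by sprite scaling and rotation.
# src: matrix; map: function(x, y) -> list(x, y) giving source coords (0-based)
# for each destination pixel; method "bilinear" or "nearest"; fill for
# out-of-range samples.
resample_affine <- function(src, out_w, out_h, map, method = "bilinear", fill = 0) {
  xs <- rep(0:(out_w - 1L), each = out_h)
  ys <- rep(0:(out_h - 1L), times = out_w)
  sc <- map(xs, ys)
  sx <- sc$x; sy <- sc$y
  h <- nrow(src); w <- ncol(src)
  out <- rep(fill, out_w * out_h)
  if (method == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 0 & ix < w & iy >= 0 & iy < h
    out[ok] <- src[cbind(iy[ok] + 1L, ix[ok] + 1L)]
  } else {
    # clamp-to-edge within the half-pixel border; fill beyond it
    ok <- sx > -0.5 & sx < w - 0.5 & sy > -0.5 & sy < h - 0.5
    sx <- pmin(pmax(sx, 0), w - 1); sy <- pmin(pmax(sy, 0), h - 1)
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    cx1 <- pmin(x0 + 1, w - 1); cy1 <- pmin(y0 + 1, h - 1)
    v <- rep(NA_real_, length(sx))
    o <- which(ok)
    g <- function(yy, xx) src[cbind(yy + 1L, xx + 1L)]
    v[o] <- (1 - fx[o]) * (1 - fy[o]) * g(y0[o], x0[o]) +
            fx[o] * (1 - fy[o]) * g(y0[o], cx1[o]) +
            (1 - fx[o]) * fy[o] * g(cy1[o], x0[o]) +
            fx[o] * fy[o] * g(cy1[o], cx1[o])
    out[ok] <- v[o]
  }
  matrix(out, nrow = out_h, ncol = out_w)
}

# Rotate an image (and optionally its mask) about its centre by `degrees`
# counter-clockwise; output canvas is the bounding box of the rotated frame.
rotate_image <- function(img, degrees, method = "bilinear", fill = 0) {
  th <- degrees * pi / 180
  h <- nrow(img); w <- ncol(img)
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  corners <- cbind(c(0, w - 1, 0, w - 1) - cx, c(0, 0, h - 1, h - 1) - cy)
  rx <- corners[, 1] * cos(th) - corners[, 2] * sin(th)
  ry <- corners[, 1] * sin(th) + corners[, 2] * cos(th)
  out_w <- ceiling(max(rx) - min(rx)) + 1L
  out_h <- ceiling(max(ry) - min(ry)) + 1L
  ocx <- (out_w - 1) / 2; ocy <- (out_h - 1) / 2
  map <- function(x, y) {
    dx <- x - ocx; dy <- y - ocy
    list(x = cx + dx * cos(-th) - dy * sin(-th),
         y = cy + dx * sin(-th) + dy * cos(-th))
  }
  resample_affine(img, out_w, out_h, map, method = method, fill = fill)
}

# Scale an image by independent x/y factors with the chosen interpolation.
scale_image <- function(img, sx, sy, method = "bilinear", fill = 0) {
  out_w <- max(1L, round(ncol(img) * sx))
  out_h <- max(1L, round(nrow(img) * sy))
  fx <- ncol(img) / out_w; fy <- nrow(img) / out_h
  map <- function(x, y) list(x = (x + 0.5) * fx - 0.5, y = (y + 0.5) * fy - 0.5)
  resample_affine(img, out_w, out_h, map, method = method, fill = fill)
}
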