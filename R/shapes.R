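#' Parameters for random periodic-spline contours
#'
#' Deformable liquid-device outlines (and the tissue blob of a conditioning
#' mask) are drawn as closed curves through n randomly perturbed points on a
#' circle: the i-th point's angle is sampled uniformly within its own angular
#' sector [i 2pi/n, (i+1) 2pi/n) and its radius uniformly within
#' [l_min, l_max], which keeps the points approximately evenly spread while
#' randomizing the outline.
#'
#' @param n control-point count (>= 4; periodic cubic interpolation needs at
#'   least 4 distinct points).
#' @param centre numeric (c_x, c_y) in pixels.
#' @param l_min,l_max radial sampling bounds in pixels, 0 < l_min <= l_max.
#' @param n_interp number of resampled curve points (>= n).
#' @param seed integer seed.
#' @return a \code{spline_shape_params} list.
#' @export
spline_shape_params <- function(n = 10, centre = c(0, 0), l_min = 30, l_max = 60,
                                n_interp = 200, seed = NULL) {
  stop_if_not(is_num1(n) && n >= 4, "n must be >= 4")
  stop_if_not(is.numeric(centre) && length(centre) == 2, "centre must be (c_x, c_y)")
  stop_if_not(is_num1(l_min) && is_num1(l_max) && l_min > 0 && l_min <= l_max,
              "need 0 < l_min <= l_max")
  stop_if_not(is_num1(n_interp) && n_interp >= n, "n_interp must be >= n")
  structure(list(n = as.integer(n), centre = as.numeric(centre),
                 l_min = l_min, l_max = l_max,
                 n_interp = as.integer(n_interp), seed = seed),
            class = "spline_shape_params")
}

# Interpolating periodic cubic spline through a closed point sequence.
# pts: k x 2 matrix with pts[1, ] == pts[k, ]; knots are uniform u_j = (j-1)/(k-1).
# Returns a function(u) -> matrix of (x, y) on the curve, u in [0, 1].
periodic_curve <- function(pts) {
  k <- nrow(pts)
  u <- seq(0, 1, length.out = k)
  function(uq) {
    uq <- uq %% 1
    cbind(x = stats::spline(u, pts[, 1], method = "periodic", xout = uq)$y,
          y = stats::spline(u, pts[, 2], method = "periodic", xout = uq)$y)
  }
}

# any pair of non-adjacent segments of a closed polyline intersecting?
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  p1 <- pts; p2 <- pts[c(2:n, 1), ]
  orient <- function(a, b, c) {
    (b[, 1] - a[, 1]) * (c[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (c[, 1] - a[, 1])
  }
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]  # skip the closing edge adjacent to edge 1
    if (length(js) == 0) next
    a1 <- p1[rep(i, length(js)), , drop = FALSE]; a2 <- p2[rep(i, length(js)), , drop = FALSE]
    b1 <- p1[js, , drop = FALSE]; b2 <- p2[js, , drop = FALSE]
    d1 <- orient(a1, a2, b1); d2 <- orient(a1, a2, b2)
    d3 <- orient(b1, b2, a1); d4 <- orient(b1, b2, a2)
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

#' Generate a closed random spline contour
#'
#' Samples n perturbed circle points (sector-wise uniform angles, uniform
#' radii), closes the sequence by appending the first point, fits an
#' interpolating (smoothing-free) periodic cubic spline through it, and
#' resamples \code{n_interp} points at uniform parameter values
#' u_k = k / (n_interp - 1). Self-intersecting outlines are redrawn with an
#' incremented seed (recorded in the result's provenance).
#'
#' @param params a [spline_shape_params()] object.
#' @return a \code{contour} list: \code{points} (n_interp x 2, closed:
#'   first == last), \code{closed}, \code{control_points}, \code{curve}
#'   (function of u), \code{provenance}.
#' @export
generate_spline_contour <- function(params) {
  stop_if_not(inherits(params, "spline_shape_params"), "params must be spline_shape_params")
  seed <- params$seed
  for (attempt in 1:25) {
    ct <- with_seed(seed, {
      i <- 0:(params$n - 1)
      theta <- stats::runif(params$n, i * 2 * pi / params$n, (i + 1) * 2 * pi / params$n)
      r <- stats::runif(params$n, params$l_min, params$l_max)
      cbind(x = params$centre[1] + r * cos(theta),
            y = params$centre[2] + r * sin(theta))
    })
    closed <- rbind(ct, ct[1, , drop = FALSE])
    if (anyDuplicated(signif(closed[-nrow(closed), ], 12))) {
      seed <- if (is.null(seed)) NULL else seed + 1L
      next
    }
    curve <- periodic_curve(closed)
    u <- seq(0, 1, length.out = params$n_interp)
    pts <- curve(u)
    pts[params$n_interp, ] <- pts[1, ]  # u = 1 wraps to u = 0 exactly
    if (!polygon_self_intersects(pts[-nrow(pts), , drop = FALSE])) {
      return(structure(list(points = pts, closed = TRUE, control_points = ct,
                            curve = curve,
                            provenance = list(seed = params$seed, used_seed = seed,
                                              redraws = attempt - 1L)),
                       class = "contour"))
    }
    seed <- if (is.null(seed)) NULL else seed + 1L
  }
  stop("could not draw a simple (non-self-intersecting) contour in 25 attempts",
       call. = FALSE)
}

#' Rasterize a contour into a sprite
#'
#' Fills the closed contour into a binary mask on a tight canvas plus margin
#' and paints the patch at a constant intensity inside the mask.
#'
#' @param contour a closed, simple \code{contour}.
#' @param intensity patch intensity in [0, 255].
#' @param canvas_margin margin in pixels around the tight bounding box.
#' @param class_id integer class id.
#' @return a \code{sprite} list: \code{patch} (xr_image), \code{mask}
#'   (binary matrix), \code{class_id}, \code{native_height}.
#' @export
contour_to_sprite <- function(contour, intensity = 60, canvas_margin = 2, class_id = 0L) {
  stop_if_not(inherits(contour, "contour") && isTRUE(contour$closed), "need a closed contour")
  stop_if_not(is_num1(intensity) && intensity >= 0 && intensity <= 255,
              "intensity must be in [0, 255]")
  pts <- contour$points[-nrow(contour$points), , drop = FALSE]
  if (polygon_self_intersects(pts)) {
    stop("contour is self-intersecting; fill is ambiguous", call. = FALSE)
  }
  shift <- c(min(pts[, 1]), min(pts[, 2])) - canvas_margin
  local <- sweep(pts, 2, shift)
  w <- ceiling(max(local[, 1])) + canvas_margin + 1L
  h <- ceiling(max(local[, 2])) + canvas_margin + 1L
  mask <- rasterize_polygon(local, w, h, include_boundary = FALSE)
  stop_if_not(mask_area(mask) > 0, "contour rasterized to an empty mask")
  new_sprite(patch = xr_image(mask * intensity), mask = mask, class_id = class_id)
}

new_sprite <- function(patch, mask, class_id) {
  mask <- as_mask(mask)
  stop_if_not(all(dim(patch) == dim(mask)), "patch and mask dimensions differ")
  stop_if_not(mask_area(mask) > 0, "sprite mask is empty")
  bb <- mask_bbox(mask)
  structure(list(patch = xr_image(unclass(patch)), mask = mask,
                 class_id = as.integer(class_id),
                 native_height = bb$y1 - bb$y0 + 1L),
            class = "sprite")
}

# principal-axis angle (degrees, in (-90, 90]) of a mask's pixel cloud
mask_orientation <- function(mask) {
  idx <- which(mask != 0, arr.ind = TRUE)
  xy <- cbind(idx[, 2], idx[, 1])  # (x, y)
  v <- eigen(stats::cov(xy), symmetric = TRUE)$vectors[, 1]
  ang <- atan2(v[2], v[1]) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Extract a standardized sprite from a clean-background capture
#'
#' Segments dark objects on a bright background by automatic (Otsu)
#' thresholding, keeps the largest connected component by area (ties broken
#' by first occurrence in row-major scan order), rotates the crop so the
#' component's major axis is horizontal, and trims blank borders.
#'
#' @param capture an \code{xr_image} showing dark device(s) on a near-uniform
#'   bright background.
#' @param class_id integer class id for the sprite.
#' @param min_area smallest acceptable component area in pixels.
#' @return a \code{sprite}.
#' @export
extract_sprite <- function(capture, class_id = 0L, min_area = 20L) {
  img <- unclass(capture)
  thr <- EBImage::otsu(img / 255, range = c(0, 1)) * 255
  mask <- matrix(as.integer(img < thr), nrow(img), ncol(img))
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) stop("no component found above threshold", call. = FALSE)
  areas <- tabulate(lab[lab > 0])
  best <- which(areas == max(areas))
  if (length(best) > 1L) {
    # tie-break: component whose first pixel comes first in row-major order
    first_rowmajor <- vapply(best, function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      min((idx[, 1] - 1L) * ncol(lab) + idx[, 2])
    }, numeric(1))
    best <- best[which.min(first_rowmajor)]
  }
  mask <- matrix(as.integer(lab == best), nrow(img), ncol(img))
  if (mask_area(mask) < min_area) stop("no component found above minimum area", call. = FALSE)

  ang <- mask_orientation(mask)
  patch_r <- rotate_image(img, -ang, method = "bilinear", fill = 255)
  mask_r <- rotate_image(mask, -ang, method = "nearest", fill = 0)
  bb <- mask_bbox(mask_r)
  rows <- (bb$y0 + 1L):(bb$y1 + 1L); cols <- (bb$x0 + 1L):(bb$x1 + 1L)
  new_sprite(patch = clip8(patch_r[rows, cols, drop = FALSE]),
             mask = mask_r[rows, cols, drop = FALSE],
             class_id = class_id)
}

#' Persist / load a sprite as paired PNGs plus JSON metadata
#'
#' Writes \code{<stem>_patch.png}, \code{<stem>_mask.png} and
#' \code{<stem>_meta.json} (class id, native height).
#'
#' @param sprite a \code{sprite}.
#' @param stem path stem (no extension).
#' @export
write_sprite <- function(sprite, stem) {
  write_image(sprite$patch, paste0(stem, "_patch.png"))
  write_image(sprite$mask * 255, paste0(stem, "_mask.png"))
  jsonlite::write_json(list(class_id = sprite$class_id,
                            native_height = sprite$native_height),
                       paste0(stem, "_meta.json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_sprite
#' @export
read_sprite <- function(stem) {
  patch <- read_image(paste0(stem, "_patch.png"))
  mask <- as_mask(matrix(as.integer(unclass(read_image(paste0(stem, "_mask.png"))) > 127),
                         nrow(patch), ncol(patch)))
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"))
  new_sprite(patch = patch, mask = mask, class_id = meta$class_id)
}
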