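#' Imaging-noise specification
#'
#' Describes the noise injected into rendered scenes to emulate low-dose
#' fluoroscopy: Poisson resampling (each pixel treated as a scaled photon
#' count), additive zero-mean Gaussian read noise, then pepper corruption
#' (random pixels driven to 0). Applied in that order by [inject_noise()].
#'
#' @param gaussian_sigma Gaussian noise standard deviation in intensity
#'   units, >= 0 (0 disables).
#' @param poisson_scale photons per intensity unit, > 0; larger means less
#'   relative noise. \code{NULL} disables Poisson resampling.
#' @param pepper_fraction fraction of pixels set to 0, in [0, 1].
#' @param seed integer seed.
#' @return a \code{noise_spec} list.
#' @export
noise_spec <- function(gaussian_sigma = 0, poisson_scale = NULL,
                       pepper_fraction = 0, seed = NULL) {
  stop_if_not(is_num1(gaussian_sigma) && gaussian_sigma >= 0,
              "gaussian_sigma must be >= 0")
  stop_if_not(is.null(poisson_scale) || (is_num1(poisson_scale) && poisson_scale > 0),
              "poisson_scale must be > 0 or NULL")
  stop_if_not(is_num1(pepper_fraction) && pepper_fraction >= 0 && pepper_fraction <= 1,
              "pepper_fraction must be in [0, 1]")
  structure(list(gaussian_sigma = gaussian_sigma, poisson_scale = poisson_scale,
                 pepper_fraction = pepper_fraction, seed = seed),
            class = "noise_spec")
}

#' Inject Poisson, Gaussian and pepper noise
#'
#' @param image an \code{xr_image}.
#' @param spec a [noise_spec()]. An all-disabled spec returns the input
#'   unchanged, bit-exactly.
#' @return noisy \code{xr_image}, clipped to [0, 255].
#' @export
inject_noise <- function(image, spec) {
  stop_if_not(inherits(spec, "noise_spec"), "spec must be a noise_spec")
  v <- unclass(image)
  if (is.null(spec$poisson_scale) && spec$gaussian_sigma == 0 && spec$pepper_fraction == 0) {
    return(image)
  }
  with_seed(spec$seed, {
    if (!is.null(spec$poisson_scale)) {
      v <- stats::rpois(length(v), lambda = v * spec$poisson_scale) / spec$poisson_scale
      v <- matrix(v, nrow(image), ncol(image))
    }
    if (spec$gaussian_sigma > 0) {
      v <- v + stats::rnorm(length(v), 0, spec$gaussian_sigma)
    }
    if (spec$pepper_fraction > 0) {
      n_pepper <- round(spec$pepper_fraction * length(v))
      v[sample.int(length(v), n_pepper)] <- 0
    }
    xr_image(clip8(v))
  })
}

#' Three-channel scene conditioning masks
#'
#' A scene is conditioned on three co-registered binary masks: the soft
#' tissue region \code{M_tissue}, dense metallic tooling \code{M_device} and
#' contrast-agent-filled vessel lumens \code{M_lumen}. \code{mask_triple}
#' validates and bundles existing masks; [make_mask_triple()] generates a
#' random triple.
#'
#' @param M_tissue,M_device,M_lumen binary matrices of identical dimensions.
#' @return a \code{mask_triple} list.
#' @export
mask_triple <- function(M_tissue, M_device, M_lumen) {
  M_tissue <- as_mask(M_tissue); M_device <- as_mask(M_device); M_lumen <- as_mask(M_lumen)
  stop_if_not(all(dim(M_tissue) == dim(M_device)) && all(dim(M_tissue) == dim(M_lumen)),
              "the three masks must share identical dimensions")
  structure(list(M_tissue = M_tissue, M_device = M_device, M_lumen = M_lumen),
            class = "mask_triple")
}

# stamp a disc of radius r at 0-based centre (cx, cy) into mask m
stamp_disc <- function(m, cx, cy, r) {
  xs <- max(0, floor(cx - r)):min(ncol(m) - 1, ceiling(cx + r))
  ys <- max(0, floor(cy - r)):min(nrow(m) - 1, ceiling(cy + r))
  if (length(xs) == 0 || length(ys) == 0) return(m)
  gx <- rep(xs, each = length(ys)); gy <- rep(ys, times = length(xs))
  hit <- (gx - cx)^2 + (gy - cy)^2 <= r^2
  m[cbind(gy[hit] + 1L, gx[hit] + 1L)] <- 1L
  m
}

#' Generate a random mask triple
#'
#' \code{M_tissue} is one simply connected blob bounded by a random periodic
#' spline contour; \code{M_lumen} is a union of thick spline channels fully
#' contained in the tissue; \code{M_device} is a union of simple bar/disc
#' shapes that may overlap anything. Deterministic for a fixed seed.
#'
#' @param width,height scene dimensions in pixels (>= 64).
#' @param n_lumen_branches,n_devices counts (>= 0).
#' @param seed integer seed.
#' @return a \code{mask_triple}.
#' @export
make_mask_triple <- function(width, height, n_lumen_branches = 2, n_devices = 1, seed = NULL) {
  stop_if_not(is_num1(width) && is_num1(height) && width >= 64 && height >= 64,
              "scene dimensions must be at least 64 x 64 pixels")
  stop_if_not(n_lumen_branches >= 0 && n_devices >= 0, "counts must be >= 0")
  with_seed(seed, {
    s <- min(width, height)
    ct <- generate_spline_contour(spline_shape_params(
      n = 12, centre = c((width - 1) / 2, (height - 1) / 2),
      l_min = 0.28 * s, l_max = 0.44 * s, n_interp = 240,
      seed = sample.int(2^30, 1)))
    tissue <- fill_holes(rasterize_polygon(ct$points[-nrow(ct$points), ], width, height))

    lumen <- matrix(0L, height, width)
    if (n_lumen_branches > 0) {
      inside <- which(tissue != 0, arr.ind = TRUE)
      for (b in seq_len(n_lumen_branches)) {
        # a smooth open channel: spline through a few points inside the tissue
        k <- sample(3:5, 1)
        pick <- inside[sample.int(nrow(inside), k), , drop = FALSE]
        wp <- cbind(pick[, 2] - 1, pick[, 1] - 1)  # (x, y)
        wp <- wp[order(wp[, 1]), , drop = FALSE]
        t0 <- seq(0, 1, length.out = k)
        td <- seq(0, 1, length.out = 40 * k)
        cx <- stats::spline(t0, wp[, 1], xout = td)$y
        cy <- stats::spline(t0, wp[, 2], xout = td)$y
        r <- stats::runif(1, 0.015 * s, 0.03 * s)
        for (j in seq_along(cx)) lumen <- stamp_disc(lumen, cx[j], cy[j], r)
      }
      lumen <- lumen * tissue  # lumens cannot leave the tissue
    }

    device <- matrix(0L, height, width)
    if (n_devices > 0) {
      for (d in seq_len(n_devices)) {
        cx <- stats::runif(1, 0.15, 0.85) * (width - 1)
        cy <- stats::runif(1, 0.15, 0.85) * (height - 1)
        if (stats::runif(1) < 0.5) {
          device <- stamp_disc(device, cx, cy, stats::runif(1, 0.03, 0.06) * s)
        } else {
          len <- stats::runif(1, 0.25, 0.6) * s; wdt <- stats::runif(1, 0.02, 0.05) * s
          th <- stats::runif(1, 0, pi)
          ux <- cos(th); uy <- sin(th)
          corners <- rbind(
            c(cx - len / 2 * ux - wdt / 2 * uy, cy - len / 2 * uy + wdt / 2 * ux),
            c(cx + len / 2 * ux - wdt / 2 * uy, cy + len / 2 * uy + wdt / 2 * ux),
            c(cx + len / 2 * ux + wdt / 2 * uy, cy + len / 2 * uy - wdt / 2 * ux),
            c(cx - len / 2 * ux + wdt / 2 * uy, cy - len / 2 * uy - wdt / 2 * ux))
          device <- pmax(device, rasterize_polygon(corners, width, height))
        }
      }
    }
    mask_triple(tissue, device, lumen)
  })
}

# band-limited value noise in [-1, 1]: coarse uniform grid upsampled bilinearly
value_noise <- function(width, height, scale) {
  gw <- max(2L, ceiling(width / scale)); gh <- max(2L, ceiling(height / scale))
  coarse <- matrix(stats::runif(gw * gh, -1, 1), gh, gw)
  fine <- scale_image(coarse, width / gw, height / gh, method = "bilinear")
  fine[seq_len(height), seq_len(width), drop = FALSE]
}

#' Render a procedural X-ray-like background from a mask triple
#'
#' Produces a greyscale scene whose regions are ordered by radiodensity.
#' Under the default attenuation polarity, denser material absorbs more
#' X-rays and appears darker: metallic devices darkest, contrast-filled
#' lumens darker than the surrounding tissue, air background brightest.
#' The display-inverted polarity flips the ordering. Tissue carries a
#' band-limited value-noise texture; region boundaries are softened by a
#' small Gaussian blur.
#'
#' @param mask a [mask_triple()].
#' @param polarity \code{"attenuation"} (default) or \code{"display-inverted"}.
#' @param texture_scale texture correlation length in pixels.
#' @param seed integer seed.
#' @return an \code{xr_image}.
#' @export
render_background <- function(mask, polarity = c("attenuation", "display-inverted"),
                              texture_scale = 24, seed = NULL) {
  stop_if_not(inherits(mask, "mask_triple"), "mask must be a mask_triple")
  polarity <- match.arg(polarity)
  h <- nrow(mask$M_tissue); w <- ncol(mask$M_tissue)
  with_seed(seed, {
    base <- matrix(230, h, w)                      # air: minimal attenuation
    tex <- 22 * value_noise(w, h, texture_scale)
    base[mask$M_tissue == 1] <- 165 + tex[mask$M_tissue == 1]
    base[mask$M_lumen == 1] <- 110 + 0.4 * tex[mask$M_lumen == 1]
    base[mask$M_device == 1] <- 45
    blurred <- EBImage::gblur(base, sigma = 1.2)
    # blur bleeds across region borders; re-impose the device plateau so the
    # density ordering holds even for thin bars
    blurred[mask$M_device == 1] <- 0.5 * blurred[mask$M_device == 1] + 0.5 * 45
    if (polarity == "display-inverted") blurred <- 255 - blurred
    xr_image(clip8(blurred))
  })
}

#' Persist / load a mask triple as a 3-channel PNG
#'
#' Channel order is tissue, device, lumen; membership encoded as 255.
#'
#' @param mask a \code{mask_triple}.
#' @param path PNG path.
#' @export
write_mask_triple <- function(mask, path) {
  h <- nrow(mask$M_tissue); w <- ncol(mask$M_tissue)
  arr <- array(0, dim = c(h, w, 3))
  arr[, , 1] <- mask$M_tissue; arr[, , 2] <- mask$M_device; arr[, , 3] <- mask$M_lumen
  png::writePNG(arr, path)
  invisible(path)
}

#' @rdname write_mask_triple
#' @export
read_mask_triple <- function(path) {
  arr <- png::readPNG(path)
  stop_if_not(length(dim(arr)) == 3 && dim(arr)[3] >= 3, "expected a 3-channel PNG")
  b <- function(k) matrix(as.integer(arr[, , k] > 0.5), dim(arr)[1], dim(arr)[2])
  mask_triple(b(1), b(2), b(3))
}
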