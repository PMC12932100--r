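#' Domain-randomization configuration for scene composition
#'
#' Bundles the per-instance randomization ranges used when pasting device
#' sprites into backgrounds: the contrast multiplier rho (target pixel value
#' v_t = clip(rho * v_b, v_min, v_max)), the target sprite height h with a
#' fractional jitter, the rotation range, how many instances to place, and
#' how occlusion beneath the metallic-device mask is applied and labelled.
#'
#' @param rho_low,rho_high contrast multiplier bounds (rho < 1 darkens).
#' @param v_min,v_max intensity clip bounds for the target value, in [0, 255].
#' @param target_height target sprite height h in pixels.
#' @param height_jitter fractional height perturbation range (+/-).
#' @param rotation_range rotation half-range in degrees (uniform in +/- range).
#' @param count_range integer (min, max) instances per scene.
#' @param occlusion_probability probability an instance is positioned to
#'   intersect the device mask and rendered beneath it.
#' @param min_visible_fraction instances whose visible fraction falls below
#'   this emit no label.
#' @param seed integer seed.
#' @return a \code{randomization_config} list.
#' @export
randomization_config <- function(rho_low = 0.5, rho_high = 0.9,
                                 v_min = 10, v_max = 245,
                                 target_height = 24, height_jitter = 0.2,
                                 rotation_range = 180,
                                 count_range = c(1L, 3L),
                                 occlusion_probability = 0.3,
                                 min_visible_fraction = 0.1,
                                 seed = NULL) {
  stop_if_not(is_num1(rho_low) && is_num1(rho_high) && rho_low <= rho_high,
              "need rho_low <= rho_high")
  stop_if_not(is_num1(v_min) && is_num1(v_max) && v_min >= 0 && v_min < v_max && v_max <= 255,
              "need 0 <= v_min < v_max <= 255")
  stop_if_not(is_num1(target_height) && target_height > 0, "target_height must be > 0")
  stop_if_not(is_num1(height_jitter) && height_jitter >= 0 && height_jitter < 1,
              "height_jitter must be in [0, 1)")
  stop_if_not(length(count_range) == 2 && count_range[1] >= 0 && count_range[1] <= count_range[2],
              "count_range must be (min, max) with 0 <= min <= max")
  stop_if_not(is_num1(occlusion_probability) && occlusion_probability >= 0 &&
                occlusion_probability <= 1, "occlusion_probability must be in [0, 1]")
  stop_if_not(is_num1(min_visible_fraction) && min_visible_fraction > 0 &&
                min_visible_fraction <= 1, "min_visible_fraction must be in (0, 1]")
  structure(list(rho_low = rho_low, rho_high = rho_high, v_min = v_min, v_max = v_max,
                 target_height = target_height, height_jitter = height_jitter,
                 rotation_range = rotation_range,
                 count_range = as.integer(count_range),
                 occlusion_probability = occlusion_probability,
                 min_visible_fraction = min_visible_fraction, seed = seed),
            class = "randomization_config")
}

#' Sample the per-instance target-value map
#'
#' Draws one contrast multiplier rho uniformly from [rho_low, rho_high] and
#' returns v_t(x, y) = clip(rho * v_b(x, y), v_min, v_max) over the supplied
#' background region.
#'
#' @param v_b numeric matrix (or vector) of background values over the
#'   insertion region.
#' @param cfg a [randomization_config()].
#' @param seed optional seed (defaults to the ambient stream).
#' @return list with \code{rho} and \code{v_t} (same shape as \code{v_b}).
#' @export
sample_target_values <- function(v_b, cfg, seed = NULL) {
  stop_if_not(length(v_b) > 0, "region is empty")
  rho <- with_seed(seed, stats::runif(1, cfg$rho_low, cfg$rho_high))
  list(rho = rho, v_t = pmin(pmax(rho * v_b, cfg$v_min), cfg$v_max))
}

#' Randomly rescale and rotate a sprite
#'
#' Scales the sprite so its mask height matches h * (1 + jitter) with jitter
#' uniform in +/- height_jitter, then rotates patch and mask together by a
#' uniform random angle. The patch is resampled bilinearly; the mask uses
#' nearest-neighbour so it stays strictly binary.
#'
#' @param sprite a \code{sprite}.
#' @param cfg a [randomization_config()].
#' @param seed optional seed.
#' @return a transformed \code{sprite}.
#' @export
transform_sprite <- function(sprite, cfg, seed = NULL) {
  with_seed(seed, {
    jit <- stats::runif(1, -cfg$height_jitter, cfg$height_jitter)
    ang <- stats::runif(1, -cfg$rotation_range, cfg$rotation_range)
    target_h <- cfg$target_height * (1 + jit)
    f <- target_h / sprite$native_height
    patch <- scale_image(unclass(sprite$patch), f, f, method = "bilinear")
    mask <- scale_image(sprite$mask, f, f, method = "nearest")
    if (ang != 0) {
      patch <- rotate_image(patch, ang, method = "bilinear")
      mask <- rotate_image(mask, ang, method = "nearest")
    }
    if (sum(mask != 0) < 3) {
      stop("transform collapsed the sprite mask below 3 pixels", call. = FALSE)
    }
    bb <- mask_bbox(mask)
    rows <- (bb$y0 + 1L):(bb$y1 + 1L); cols <- (bb$x0 + 1L):(bb$x1 + 1L)
    sp <- new_sprite(patch = clip8(patch[rows, cols, drop = FALSE]),
                     mask = mask[rows, cols, drop = FALSE],
                     class_id = sprite$class_id)
    attr(sp, "transform") <- list(jitter = jit, rotation = ang, scale = f)
    sp
  })
}

#' Alpha-blend a sprite into a background at a target contrast
#'
#' A single blending coefficient alpha is computed from sums over the sprite
#' mask M and the blend v_b <- alpha * v_b + (1 - alpha) * v_r is applied to
#' pixels inside M only. The default \code{corrected} mode uses
#' alpha = sum(v_t - v_r) / sum(v_b - v_r), under which the blended region's
#' mean equals the target mean (v_t = v_r gives the raw sprite, v_t = v_b an
#' invisible one). The \code{verbatim} mode evaluates
#' alpha = sum(v_t - v_b) / sum(v_b - v_r) instead, for auditability of the
#' alternative formulation. Alpha is clipped to [0, 1] in both modes.
#'
#' @param background an \code{xr_image}.
#' @param sprite a \code{sprite}.
#' @param position integer (x, y) of the sprite's top-left corner in 0-based
#'   frame coordinates; the sprite must fit inside the frame.
#' @param v_t target-value matrix over the sprite canvas (same dim as the
#'   sprite), from [sample_target_values()].
#' @param mode \code{"corrected"} (default) or \code{"verbatim"}.
#' @return list: \code{image} (blended \code{xr_image}), \code{alpha}
#'   (clipped), \code{alpha_raw}, \code{region} (frame-coordinate bbox of the
#'   sprite canvas).
#' @export
blend <- function(background, sprite, position, v_t,
                  mode = c("corrected", "verbatim")) {
  mode <- match.arg(mode)
  px <- as.integer(round(position[1])); py <- as.integer(round(position[2]))
  h <- nrow(sprite$mask); w <- ncol(sprite$mask)
  px <- min(max(px, 0L), img_width(background) - w)
  py <- min(max(py, 0L), img_height(background) - h)
  stop_if_not(px >= 0 && py >= 0, "sprite larger than the frame")
  rows <- (py + 1L):(py + h); cols <- (px + 1L):(px + w)

  bg <- unclass(background)
  v_b <- bg[rows, cols, drop = FALSE]
  v_r <- unclass(sprite$patch)
  m <- sprite$mask == 1L
  stop_if_not(all(dim(v_t) == dim(sprite$mask)), "v_t must match the sprite canvas")

  denom <- sum(v_b[m] - v_r[m])
  if (denom == 0) stop("degenerate contrast: sum(v_b - v_r) over the mask is zero",
                       call. = FALSE)
  num <- if (mode == "corrected") sum(v_t[m] - v_r[m]) else sum(v_t[m] - v_b[m])
  alpha_raw <- num / denom
  alpha <- min(max(alpha_raw, 0), 1)

  blended <- v_b
  blended[m] <- alpha * v_b[m] + (1 - alpha) * v_r[m]
  bg[rows, cols] <- blended
  list(image = xr_image(clip8(bg)), alpha = alpha, alpha_raw = alpha_raw,
       region = list(x0 = px, y0 = py, x1 = px + w - 1L, y1 = py + h - 1L))
}

#' One polygon instance label
#'
#' @param class_id integer class index.
#' @param polygon two-column matrix of (x, y) vertices normalized to [0, 1]
#'   by image width/height; at least 3 vertices.
#' @return an \code{instance_label}.
#' @export
instance_label <- function(class_id, polygon) {
  polygon <- as.matrix(polygon)
  stop_if_not(nrow(polygon) >= 3 && ncol(polygon) == 2,
              "polygon needs at least 3 (x, y) vertices")
  stop_if_not(all(polygon >= 0) && all(polygon <= 1),
              "polygon coordinates must be normalized to [0, 1]")
  structure(list(class_id = as.integer(class_id), polygon = polygon),
            class = "instance_label")
}

# visible mask -> one normalized label ring; labelling convention: the
# hole-filled largest connected component (small severed fragments and
# occlusion pinholes are not annotated separately)
label_from_mask <- function(visible, class_id, width, height) {
  vm <- fill_holes(largest_component(visible))
  poly <- trace_mask_polygon(vm)
  norm <- cbind(pmin(pmax(poly[, 1] / width, 0), 1),
                pmin(pmax(poly[, 2] / height, 0), 1))
  list(label = instance_label(class_id, norm), visible_mask = vm)
}

#' Compose a full scene: place, blend, occlude, label
#'
#' Places a random number of sprite instances into the background. Each
#' instance draws a position (biased into the lumen mask when one exists,
#' else uniform over tissue), is randomly rescaled/rotated, receives a random
#' target contrast, and is alpha-blended in. With probability
#' \code{occlusion_probability} an instance is positioned to intersect
#' \code{M_device} and the blended pixels beneath the device mask are
#' restored to the original rendering (device above, instance beneath).
#' Labels trace the visible mask; instances whose visible fraction falls
#' below \code{min_visible_fraction} emit no label. Noise, when requested,
#' is injected after all blending.
#'
#' @param background an \code{xr_image}.
#' @param mask3 the scene's [mask_triple()].
#' @param sprites non-empty list of \code{sprite} objects to draw from.
#' @param cfg a [randomization_config()]; all randomness flows from
#'   \code{cfg$seed}.
#' @param noise optional [noise_spec()] applied after blending.
#' @param max_attempts placement attempts per instance before failing.
#' @return a \code{composite_sample}: \code{image}, \code{labels} (list of
#'   [instance_label()]), \code{provenance} (seed and per-instance rho,
#'   position, rotation, occlusion flag, visible mask and fraction).
#' @export
compose_scene <- function(background, mask3, sprites, cfg, noise = NULL,
                          max_attempts = 40L) {
  stop_if_not(length(sprites) >= 1, "at least one sprite is required")
  stop_if_not(inherits(cfg, "randomization_config"), "cfg must be a randomization_config")
  W <- img_width(background); H <- img_height(background)
  with_seed(cfg$seed, {
    n <- if (cfg$count_range[1] == cfg$count_range[2]) cfg$count_range[1] else
      sample(cfg$count_range[1]:cfg$count_range[2], 1)
    img <- background
    pre_blend <- unclass(background)
    inst <- list()
    lumen_idx <- which(mask3$M_lumen != 0, arr.ind = TRUE)
    tissue_idx <- which(mask3$M_tissue != 0, arr.ind = TRUE)
    device_idx <- which(mask3$M_device != 0, arr.ind = TRUE)
    stop_if_not(nrow(tissue_idx) > 0, "tissue mask is empty; nowhere to place instances")

    for (i in seq_len(n)) {
      sp0 <- sprites[[if (length(sprites) == 1) 1 else sample.int(length(sprites), 1)]]
      sp <- transform_sprite(sp0, cfg)
      h <- nrow(sp$mask); w <- ncol(sp$mask)
      if (w > W || h > H) stop("transformed sprite larger than the frame", call. = FALSE)
      occlude <- nrow(device_idx) > 0 && stats::runif(1) < cfg$occlusion_probability

      placed <- FALSE
      for (a in seq_len(max_attempts)) {
        pool <- if (occlude) device_idx
                else if (nrow(lumen_idx) > 0 && stats::runif(1) < 0.8) lumen_idx
                else tissue_idx
        ctr <- pool[sample.int(nrow(pool), 1), ]
        px <- min(max(round(ctr[2] - 1 - w / 2), 0L), W - w)
        py <- min(max(round(ctr[1] - 1 - h / 2), 0L), H - h)
        rows <- (py + 1L):(py + h); cols <- (px + 1L):(px + w)
        sub_dev <- mask3$M_device[rows, cols, drop = FALSE]
        if (occlude && sum(sp$mask * sub_dev) == 0) next  # must intersect the device
        v_b <- unclass(img)[rows, cols, drop = FALSE]
        if (sum(v_b[sp$mask == 1] - unclass(sp$patch)[sp$mask == 1]) == 0) next
        tv <- sample_target_values(v_b, cfg)
        bl <- blend(img, sp, c(px, py), tv$v_t, mode = "corrected")
        out <- unclass(bl$image)
        # instance sits beneath the metallic device: restore device pixels
        occ_px <- sp$mask * sub_dev
        if (any(occ_px == 1)) {
          sub_pre <- pre_blend[rows, cols, drop = FALSE]
          patch_now <- out[rows, cols, drop = FALSE]
          patch_now[occ_px == 1] <- sub_pre[occ_px == 1]
          out[rows, cols] <- patch_now
        }
        img <- xr_image(out)
        frame_mask <- matrix(0L, H, W)
        frame_mask[rows, cols] <- sp$mask
        occ_frame <- matrix(0L, H, W)
        occ_frame[rows, cols] <- occ_px
        inst[[length(inst) + 1L]] <- list(
          class_id = sp$class_id, mask = frame_mask, occluded_px = occ_frame,
          rho = tv$rho, position = c(x = px, y = py),
          rotation = attr(sp, "transform")$rotation, occluded = occlude,
          alpha = bl$alpha)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf("no valid placement found for instance %d after %d attempts (occlude=%s)",
                     i, max_attempts, occlude), call. = FALSE)
      }
    }

    # visibility: later instances paint over earlier ones; device occludes all
    labels <- list()
    for (i in seq_along(inst)) {
      visible <- inst[[i]]$mask * (1L - inst[[i]]$occluded_px)
      if (i < length(inst)) {
        for (j in (i + 1L):length(inst)) visible <- visible * (1L - inst[[j]]$mask)
      }
      frac <- sum(visible) / sum(inst[[i]]$mask)
      inst[[i]]$visible_fraction <- frac
      if (frac >= cfg$min_visible_fraction && sum(visible) >= 3) {
        lb <- label_from_mask(visible, inst[[i]]$class_id, W, H)
        labels[[length(labels) + 1L]] <- lb$label
        inst[[i]]$visible_mask <- lb$visible_mask
      } else {
        inst[[i]]$visible_mask <- NULL
      }
    }
    if (!is.null(noise)) img <- inject_noise(img, noise)

    structure(list(image = img, labels = labels,
                   provenance = list(seed = cfg$seed, n_placed = length(inst),
                                     instances = inst)),
              class = "composite_sample")
  })
}
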