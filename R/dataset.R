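#' Write / read polygon instance labels
#'
#' One text file per image, one row per instance: the class index followed by
#' the polygon's 2n normalized coordinates
#' (\code{class x1 y1 x2 y2 ... xn yn}), space-separated at 6-decimal fixed
#' precision. \code{read_labels} inverts \code{write_labels} at the stored
#' precision.
#'
#' @param labels list of [instance_label()] (or a \code{composite_sample},
#'   whose labels are used).
#' @param path label file path.
#' @return \code{read_labels} returns a list of \code{instance_label}.
#' @export
write_labels <- function(labels, path) {
  if (inherits(labels, "composite_sample")) labels <- labels$labels
  rows <- vapply(labels, function(lb) {
    paste(c(lb$class_id, sprintf("%.6f", t(lb$polygon))), collapse = " ")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  stop_if_not(file.exists(path), paste0("no such label file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(f)) stop(sprintf("parse error at line %d: non-numeric field", i), call. = FALSE)
    if (length(f) < 7 || (length(f) - 1) %% 2 != 0) {
      stop(sprintf("parse error at line %d: expected class + 2n coordinates (n >= 3), got %d fields",
                   i, length(f)), call. = FALSE)
    }
    coords <- matrix(f[-1], ncol = 2, byrow = TRUE)
    if (any(coords < 0) || any(coords > 1)) {
      stop(sprintf("parse error at line %d: coordinate outside [0, 1]", i), call. = FALSE)
    }
    instance_label(f[1], coords)
  })
}

# denormalize a label polygon to 0-based pixel coordinates
label_polygon_px <- function(label, width, height) {
  cbind(label$polygon[, 1] * width, label$polygon[, 2] * height)
}

#' Tile a frame into an overlapping patch grid
#'
#' Computes patch dimensions and strides so that exactly
#' \code{n_cols x n_rows} patches cover every frame pixel with neighbouring
#' patches overlapping by at least \code{min_overlap_fraction} of a patch
#' side. The last column/row is clamped to the frame edge (overlap grows,
#' coverage is preserved). The default 5 x 5 grid is the global-search
#' tiling (25 patches per full frame).
#'
#' @param image an \code{xr_image} (or matrix).
#' @param n_cols,n_rows grid shape.
#' @param min_overlap_fraction minimum fractional overlap between adjacent
#'   patches, in [0, 1).
#' @return a \code{patch_grid}: \code{patch_width}, \code{patch_height},
#'   \code{offsets} (n x 2 matrix of 0-based top-left corners, row-major
#'   patch order), \code{patches} (list of matrices).
#' @export
tile_image <- function(image, n_cols = 5L, n_rows = 5L, min_overlap_fraction = 0.1) {
  W <- ncol(image); H <- nrow(image)
  stop_if_not(n_cols >= 1 && n_rows >= 1, "grid must be at least 1 x 1")
  stop_if_not(min_overlap_fraction >= 0 && min_overlap_fraction < 1,
              "min_overlap_fraction must be in [0, 1)")
  axis_layout <- function(total, k) {
    # patch size p with stride s = p(1 - f): coverage needs p + (k-1)s >= total
    p <- ceiling(total / (1 + (k - 1) * (1 - min_overlap_fraction)))
    p <- min(p, total)
    if (k == 1) return(list(p = total, off = 0L))
    s <- (total - p) / (k - 1)
    stop_if_not(s <= p * (1 - min_overlap_fraction) + 1e-9,
                "frame too small for the requested grid and overlap")
    off <- floor((0:(k - 1)) * s)
    off[k] <- total - p  # clamp the last patch to the frame edge
    list(p = as.integer(p), off = as.integer(off))
  }
  lx <- axis_layout(W, as.integer(n_cols))
  ly <- axis_layout(H, as.integer(n_rows))
  offsets <- cbind(x = rep(lx$off, times = n_rows), y = rep(ly$off, each = n_cols))
  patches <- lapply(seq_len(nrow(offsets)), function(i) {
    ox <- offsets[i, 1]; oy <- offsets[i, 2]
    unclass(image)[(oy + 1L):(oy + ly$p), (ox + 1L):(ox + lx$p), drop = FALSE]
  })
  structure(list(patch_width = lx$p, patch_height = ly$p,
                 offsets = offsets, n_cols = as.integer(n_cols),
                 n_rows = as.integer(n_rows), patches = patches,
                 frame_width = W, frame_height = H),
            class = "patch_grid")
}

#' Lift patch-local coordinates to frame coordinates
#'
#' @param grid a [tile_image()] result.
#' @param patch_index 1-based patch index (row-major).
#' @param xy two-column matrix of patch-local 0-based (x, y) points.
#' @return the points in frame coordinates.
#' @export
lift_to_frame <- function(grid, patch_index, xy) {
  stop_if_not(patch_index >= 1 && patch_index <= nrow(grid$offsets), "bad patch index")
  xy <- as.matrix(xy)
  sweep(xy, 2, c(grid$offsets[patch_index, 1], grid$offsets[patch_index, 2]), `+`)
}

#' Deterministic train/validation split
#'
#' Shuffles the sample indices under the given seed and splits at 20:1 for
#' synthetic data or 10:1 for real data (one validation sample per 21 / 11),
#' producing an exact partition.
#'
#' @param samples a list or vector of samples (or a sample count).
#' @param kind \code{"synthetic"} (20:1) or \code{"real"} (10:1).
#' @param seed integer seed.
#' @return list with \code{train} and \code{validation} index vectors (or
#'   sample subsets when \code{samples} is a list).
#' @export
split_dataset <- function(samples, kind = c("synthetic", "real"), seed = NULL) {
  kind <- match.arg(kind)
  ratio <- if (kind == "synthetic") 20L else 10L
  n <- if (is.numeric(samples) && length(samples) == 1) as.integer(samples) else length(samples)
  stop_if_not(n >= ratio + 1L,
              sprintf("need at least %d samples for a %d:1 split", ratio + 1L, ratio))
  n_val <- max(1L, round(n / (ratio + 1L)))
  perm <- with_seed(seed, sample.int(n))
  val <- sort(perm[seq_len(n_val)])
  train <- sort(perm[-seq_len(n_val)])
  if (is.numeric(samples) && length(samples) == 1) {
    list(train = train, validation = val)
  } else {
    list(train = samples[train], validation = samples[val],
         train_idx = train, validation_idx = val)
  }
}

#' Write a composite sample into the dataset directory layout
#'
#' Layout: \code{images/NNNN.png}, \code{labels/NNNN.txt},
#' \code{provenance/NNNN.json}.
#'
#' @param sample a \code{composite_sample}.
#' @param dir dataset root.
#' @param index sample number (zero-padded to 4 digits).
#' @return the three file paths, invisibly.
#' @export
write_sample <- function(sample, dir, index) {
  for (d in c("images", "labels", "provenance")) {
    dir.create(file.path(dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  stem <- sprintf("%04d", index)
  ip <- file.path(dir, "images", paste0(stem, ".png"))
  lp <- file.path(dir, "labels", paste0(stem, ".txt"))
  pp <- file.path(dir, "provenance", paste0(stem, ".json"))
  write_image(sample$image, ip)
  write_labels(sample, lp)
  prov <- sample$provenance
  prov$instances <- lapply(prov$instances, function(it) {
    it$mask <- NULL; it$occluded_px <- NULL; it$visible_mask <- NULL  # JSON stays light
    it
  })
  jsonlite::write_json(prov, pp, auto_unbox = TRUE, digits = NA)
  invisible(c(image = ip, labels = lp, provenance = pp))
}
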