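#' Rendering configuration for multi-view depth images
#'
#' Controls how a point cloud is turned into depth-encoded grayscale views.
#' Defaults give the standard portrait raster of 150 rows by 100 columns,
#' ten views spaced 360/10 = 36 degrees apart, round point markers of radius
#' 1 px (a 3x3 disc), and a depth-to-gray ramp from 0 (nearest point, black)
#' to 200 (farthest point) on a white (255) background, so even the farthest
#' points stay distinguishable from the background.
#'
#' @param width_px,height_px raster size in pixels (height is the vertical
#'   axis; trees are taller than wide, hence the portrait default).
#' @param n_views number of evenly spaced rotational views per tree.
#' @param marker_radius_px marker radius r: a marker covers every pixel whose
#'   centre lies within r + 0.5 px of the point's pixel (r = 1 gives a full
#'   3x3 disc).
#' @param gray_near,gray_far gray levels (0-255) assigned to the nearest and
#'   farthest point; the map in between is linear in viewing depth.
#' @param background gray level of uncovered pixels; must lie outside
#'   `[gray_near, gray_far]`.
#' @param margin_frac fraction of each image dimension kept clear as a border
#'   when fitting the tree's bounding box into the raster.
#' @return A `render_config` object (validated list).
#' @export
render_config <- function(width_px = 100L, height_px = 150L, n_views = 10L,
                          marker_radius_px = 1L, gray_near = 0L, gray_far = 200L,
                          background = 255L, margin_frac = 0.05) {
  cfg <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    n_views = as.integer(n_views), marker_radius_px = as.integer(marker_radius_px),
    gray_near = as.integer(gray_near), gray_far = as.integer(gray_far),
    background = as.integer(background), margin_frac = as.numeric(margin_frac)
  )
  if (cfg$width_px < 8L || cfg$height_px < 8L) abort("Raster must be at least 8x8 pixels.")
  if (cfg$n_views < 1L) abort("`n_views` must be >= 1.")
  if (!(cfg$gray_near >= 0L && cfg$gray_near < cfg$gray_far && cfg$gray_far <= 255L)) {
    abort("Need 0 <= gray_near < gray_far <= 255.")
  }
  if (cfg$background >= cfg$gray_near && cfg$background <= cfg$gray_far) {
    abort("`background` must lie outside [gray_near, gray_far].")
  }
  if (cfg$margin_frac < 0 || cfg$margin_frac >= 0.5) abort("`margin_frac` must be in [0, 0.5).")
  if (cfg$marker_radius_px < 0L) abort("`marker_radius_px` must be >= 0.")
  structure(cfg, class = "render_config")
}

#' Grayscale depth image of one tree view
#'
#' A `gray_image` is an integer matrix (rows = image rows, top first) with
#' values in 0..255 plus provenance attributes: the source `tree_id`, the
#' `view_index`, and whether the image was produced by augmentation.
#'
#' @param pixels integer matrix in 0..255.
#' @param tree_id source tree identifier.
#' @param view_index 0-based view index (augmented images use indices
#'   >= 1000 so their provenance is unambiguous).
#' @param augmented logical flag.
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, tree_id = "tree", view_index = 0L, augmented = FALSE) {
  stopifnot(is.matrix(pixels))
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L | pixels > 255L)) abort("Pixel values must be in 0..255.")
  structure(pixels, tree_id = as.character(tree_id), view_index = as.integer(view_index),
            augmented = isTRUE(augmented), class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %dx%d px, tree '%s', view %d%s\n",
              nrow(x), ncol(x), attr(x, "tree_id"), attr(x, "view_index"),
              if (isTRUE(attr(x, "augmented"))) " (augmented)" else ""))
  invisible(x)
}

#' @rdname gray_image
#' @param x a `gray_image`.
#' @param ... unused.
#' @export
as_tibble.gray_image <- function(x, ...) {
  tibble(
    row = rep(seq_len(nrow(x)), times = ncol(x)),
    col = rep(seq_len(ncol(x)), each = nrow(x)),
    gray = as.integer(x)
  )
}

#' @rdname gray_image
#' @param object a `gray_image`.
#' @export
autoplot.gray_image <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$gray)) +
    geom_raster() +
    scale_y_reverse() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    coord_fixed() +
    labs(x = NULL, y = NULL, fill = "gray",
         title = sprintf("tree %s, view %d", attr(object, "tree_id"), attr(object, "view_index"))) +
    theme_minimal()
}

#' Rotate a point cloud about the vertical axis
#'
#' Rigid rotation in the xy-plane about the cloud's xy-centroid; heights and
#' all pairwise distances are untouched. This is the rotation that produces
#' the different viewing angles.
#'
#' @param cloud a [point_cloud()].
#' @param angle_deg rotation angle in degrees (counter-clockwise seen from
#'   above).
#' @return The rotated [point_cloud()].
#' @export
rotate_z <- function(cloud, angle_deg) {
  stopifnot(inherits(cloud, "point_cloud"), is.finite(angle_deg))
  th <- angle_deg * pi / 180
  cx <- mean(cloud[, 1]); cy <- mean(cloud[, 2])
  x <- cloud[, 1] - cx; y <- cloud[, 2] - cy
  m <- unclass(cloud)
  m[, 1] <- cos(th) * x - sin(th) * y + cx
  m[, 2] <- sin(th) * x + cos(th) * y + cy
  restore_cloud(m, cloud)
}

# Rigid rotation about an arbitrary axis (unit vector) through the cloud's
# centroid; used for the small tilts applied during augmentation.
rotate_axis <- function(cloud, axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  ctr <- colMeans(cloud)
  m <- sweep(unclass(cloud), 2, ctr) %*% t(R)
  m <- sweep(m, 2, ctr, "+")
  restore_cloud(m, cloud)
}

# Map world coordinates to pixel centres for an orthographic view along +y.
# Returns 1-based (row, col) per point plus the scale actually used. The
# x-z bounding box is fitted inside the raster, aspect ratio preserved,
# leaving a margin_frac border; z grows upward (row 1 = top of tree).
project_pixels <- function(cloud, config) {
  x <- cloud[, 1]; z <- cloud[, 3]
  dx <- max(diff(range(x)), 1e-12)
  dz <- max(diff(range(z)), 1e-12)
  uw <- config$width_px * (1 - 2 * config$margin_frac)
  uh <- config$height_px * (1 - 2 * config$margin_frac)
  scale <- min(uw / dx, uh / dz)
  cx <- (config$width_px + 1) / 2
  cy <- (config$height_px + 1) / 2
  col <- round(cx + (x - mean(range(x))) * scale)
  row <- round(cy - (z - mean(range(z))) * scale)
  list(row = as.integer(row), col = as.integer(col), scale = scale)
}

# Depth-to-gray ramp: nearest (smallest y) -> gray_near, farthest -> gray_far,
# linear in between; a degenerate depth range maps everything to gray_near.
depth_gray <- function(y, config) {
  rng <- range(y)
  if (diff(rng) <= 0) return(rep.int(config$gray_near, length(y)))
  as.integer(round(config$gray_near +
    (y - rng[1]) / diff(rng) * (config$gray_far - config$gray_near)))
}

disc_offsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= (r + 0.5)^2, , drop = FALSE]
}

#' Render one depth-encoded grayscale view
#'
#' Orthographic projection of the cloud along the y-axis onto the x-z plane.
#' The x-z bounding box is fitted inside the raster (aspect preserved, with
#' a `margin_frac` border); every point becomes a filled disc of radius
#' `marker_radius_px`; the disc's gray level encodes viewing depth (near =
#' `gray_near`, far = `gray_far`, linear in y). Discs are painted far to
#' near, so wherever discs overlap the nearer — darker — point wins; among
#' points at identical depth the gray value is identical, so the tie is
#' invisible. Remaining pixels are `background`.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param config a [render_config()].
#' @param view_index,augmented provenance recorded on the image.
#' @return A [gray_image()] of `height_px` rows by `width_px` columns.
#' @export
render_view <- function(cloud, config = render_config(), view_index = 0L, augmented = FALSE) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(config, "render_config"))
  px <- project_pixels(cloud, config)
  gray <- depth_gray(cloud[, 2], config)
  img <- matrix(config$background, nrow = config$height_px, ncol = config$width_px)

  ord <- order(cloud[, 2], decreasing = TRUE)  # far first (painter's order)
  off <- disc_offsets(config$marker_radius_px)
  n <- length(ord); k <- nrow(off)
  rows <- rep(px$row[ord], each = k) + rep.int(off$dr, n)
  cols <- rep(px$col[ord], each = k) + rep.int(off$dc, n)
  vals <- rep(gray[ord], each = k)
  ok <- rows >= 1L & rows <= config$height_px & cols >= 1L & cols <= config$width_px
  # one subassignment: later (nearer) writes overwrite earlier (farther) ones
  img[cbind(rows[ok], cols[ok])] <- vals[ok]
  gray_image(img, tree_id(cloud), view_index, augmented)
}

#' Generate the full set of rotational views for one tree
#'
#' Subsamples the cloud once (default 6000 points — the density
#' standardisation applied before plotting) and renders `n_views` images at
#' evenly spaced rotations about the vertical axis, starting at 0 degrees.
#'
#' @param cloud a non-empty [point_cloud()].
#' @param config a [render_config()].
#' @param subsample_n points drawn (without replacement) before rendering.
#' @param seed integer seed controlling the subsample.
#' @return A list of [gray_image()]s with `view_index` 0 .. n_views - 1.
#' @export
generate_views <- function(cloud, config = render_config(), subsample_n = 6000, seed = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  sub <- subsample_cloud(cloud, subsample_n, seed)
  step <- 360 / config$n_views
  lapply(seq_len(config$n_views) - 1L, function(k) {
    render_view(rotate_z(sub, k * step), config, view_index = k)
  })
}

#' Tabulate a set of images as a tidy index
#'
#' @param images list of [gray_image()]s.
#' @param species optional species label attached to every row.
#' @return Tibble with columns `tree_id`, `species`, `view_index`,
#'   `augmented`, and `image` (list column of `gray_image`s).
#' @export
image_index <- function(images, species = NA_character_) {
  tibble(
    tree_id = vapply(images, attr, "", which = "tree_id"),
    species = species,
    view_index = vapply(images, function(i) as.integer(attr(i, "view_index")), 0L),
    augmented = vapply(images, function(i) isTRUE(attr(i, "augmented")), FALSE),
    image = images
  )
}

#' Write / read an 8-bit grayscale PNG
#'
#' Images are written single-channel; the conventional filename is
#' `<tree_id>_v<view_index>.png`.
#'
#' @param image a [gray_image()].
#' @param path PNG path.
#' @return `write_image()` returns `path` invisibly; `read_image()` a
#'   [gray_image()].
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "gray_image"))
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @param tree_id,view_index,augmented provenance for the loaded image
#'   (PNG files do not carry it); defaults parse `<tree_id>_v<k>.png` names.
#' @export
read_image <- function(path, tree_id = NULL, view_index = NULL, augmented = FALSE) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  base <- sub("\\.png$", "", basename(path))
  if (is.null(tree_id)) tree_id <- sub("_v[0-9]+$", "", base)
  if (is.null(view_index)) {
    v <- regmatches(base, regexpr("(?<=_v)[0-9]+$", base, perl = TRUE))
    view_index <- if (length(v)) as.integer(v) else 0L
  }
  gray_image(matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
             tree_id, view_index, augmented)
}

#' Render and save every view of every tree in a study
#'
#' Convenience wrapper used by the command-line pipeline: renders
#' [generate_views()] for each record and returns the combined image index.
#'
#' @param records tibble with `tree_id`, `species`, and either a `cloud`
#'   list column or a `cloud_path` column of xyz files.
#' @param config a [render_config()].
#' @param subsample_n,seed passed to [generate_views()]; each tree gets its
#'   own seed derived from `seed`.
#' @param dir if non-NULL, PNGs and an `index.csv` are written there.
#' @return Image index tibble (see [image_index()]).
#' @export
render_study <- function(records, config = render_config(), subsample_n = 6000,
                         seed = 1L, dir = NULL) {
  seeds <- derive_seeds(seed, nrow(records))
  idx <- purrr::pmap(list(seq_len(nrow(records))), function(i) {
    cl <- if ("cloud" %in% names(records) && !is.null(records$cloud[[i]])) {
      records$cloud[[i]]
    } else {
      read_xyz(records$cloud_path[i], records$tree_id[i])
    }
    image_index(generate_views(center_cloud(cl), config, subsample_n, seeds[i]),
                species = records$species[i])
  })
  idx <- dplyr::bind_rows(idx)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, sprintf("%s_v%d.png", idx$tree_id, idx$view_index))
    purrr::walk2(idx$image, paths, write_image)
    out <- dplyr::mutate(idx[c("tree_id", "species", "view_index", "augmented")],
                         path = basename(paths))
    write.csv(out, file.path(dir, "index.csv"), row.names = FALSE)
  }
  idx
}
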