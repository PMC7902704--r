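#' Single-tree point clouds
#'
#' A `point_cloud` is a numeric matrix with one row per laser return and
#' columns `x`, `y`, `z` (metres). `z` is always the vertical axis, so
#' `cloud_height()` is `max(z) - min(z)`. The tree identifier travels with
#' the object as an attribute.
#'
#' @param points numeric matrix (or data frame) with at least three columns,
#'   interpreted as x, y, z in metres. Extra columns are dropped.
#' @param tree_id single string identifying the tree.
#' @return A `point_cloud` object.
#' @examples
#' pc <- point_cloud(matrix(c(0, 0, 0, 1, 0, 0, 0, 0, 10), 3, byrow = TRUE), "t1")
#' cloud_height(pc)
#' @export
point_cloud <- function(points, tree_id = "tree") {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || !is.numeric(points)) {
    abort("`points` must be a numeric matrix with columns x, y, z.")
  }
  if (ncol(points) < 3) abort("`points` needs at least three columns (x, y, z).")
  points <- points[, 1:3, drop = FALSE]
  if (nrow(points) < 1) abort("Empty cloud: a point cloud needs at least one point.")
  if (!all(is.finite(points))) abort("All coordinates must be finite.")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  structure(points, tree_id = as.character(tree_id)[1], class = c("point_cloud", "matrix", "array"))
}

#' @export
print.point_cloud <- function(x, ...) {
  h <- diff(range(x[, "z"]))
  cat(sprintf("<point_cloud> tree '%s': %d points, height %.2f m\n",
              tree_id(x), nrow(x), h))
  invisible(x)
}

#' @rdname point_cloud
#' @param cloud a `point_cloud`.
#' @export
tree_id <- function(cloud) attr(cloud, "tree_id")

#' @rdname point_cloud
#' @export
n_points <- function(cloud) nrow(cloud)

#' @rdname point_cloud
#' @export
cloud_height <- function(cloud) diff(range(cloud[, "z"]))

#' @rdname point_cloud
#' @export
as_tibble.point_cloud <- function(x, ...) {
  tibble(x = x[, "x"], y = x[, "y"], z = x[, "z"])
}

# rebuild a point_cloud from a plain matrix, keeping provenance
restore_cloud <- function(m, template) point_cloud(m, tree_id(template))

#' Read a single-tree xyz point cloud
#'
#' Reads the plain-text `xyz` exchange format used for segmented TLS trees:
#' one point per line, the first three whitespace- or comma-separated fields
#' are x, y, z in metres, any further fields (intensity, RGB, ...) are
#' ignored. Blank lines and lines starting with `#` are skipped. Gzipped
#' files (`.xyz.gz`) are read transparently.
#'
#' @param path path to the file.
#' @param tree_id identifier for the tree; defaults to the file name without
#'   extension.
#' @return A [point_cloud()].
#' @export
read_xyz <- function(path, tree_id = NULL) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(sprintf("Cannot read point cloud: file '%s' does not exist.", as.character(path)[1]),
          class = "tlsimage_io_error")
  }
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) abort(sprintf("I/O error reading '%s': %s", path, conditionMessage(e)),
                                              class = "tlsimage_io_error"))
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, "#")
  if (!any(keep)) {
    abort(sprintf("Empty cloud: '%s' contains no data lines.", path),
          class = "tlsimage_empty_cloud")
  }
  line_no <- which(keep)
  fields <- strsplit(trimmed[keep], "[,;[:blank:]]+")
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    abort(sprintf("Parse error in '%s' at line %d: expected at least 3 numeric fields, found %d.",
                  path, line_no[bad], nf[bad]),
          class = "tlsimage_parse_error")
  }
  xyz <- vapply(fields, function(f) suppressWarnings(as.numeric(f[1:3])), numeric(3))
  not_num <- colSums(!is.finite(xyz)) > 0
  if (any(not_num)) {
    bad <- which(not_num)[1]
    abort(sprintf("Parse error in '%s' at line %d: non-numeric coordinate.", path, line_no[bad]),
          class = "tlsimage_parse_error")
  }
  id <- tree_id %||% sub("\\.(xyz|txt|csv)?(\\.gz)?$", "", basename(path))
  point_cloud(t(xyz), id)
}

#' Write a point cloud as an xyz text file
#'
#' Coordinates are written with six decimal places (micrometre precision),
#' space separated, one point per line. A `.gz` suffix triggers gzip
#' compression.
#'
#' @param cloud a [point_cloud()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%.6f %.6f %.6f", cloud[, "x"], cloud[, "y"], cloud[, "z"]), con)
  invisible(path)
}

#' Centre a point cloud on a stable rendering frame
#'
#' Translates the cloud so the centroid of (x, y) sits at the origin and the
#' lowest point is at z = 0. A pure translation: the tree's shape (all
#' pairwise distances) is unchanged.
#'
#' @param cloud a [point_cloud()].
#' @return The translated [point_cloud()].
#' @export
center_cloud <- function(cloud) {
  stopifnot(inherits(cloud, "point_cloud"))
  m <- unclass(cloud)
  m[, 1] <- m[, 1] - mean(m[, 1])
  m[, 2] <- m[, 2] - mean(m[, 2])
  m[, 3] <- m[, 3] - min(m[, 3])
  restore_cloud(m, cloud)
}

#' Randomly subsample a point cloud
#'
#' Draws `n` distinct points uniformly without replacement (the default
#' n = 6000 is the density standardisation applied before rendering views).
#' If the cloud has fewer than `n` points it is returned whole with a
#' warning; sampling with replacement would draw duplicate markers that a
#' scanner never produces.
#'
#' @param cloud a [point_cloud()].
#' @param n number of points to keep.
#' @param seed integer seed; the same seed always selects the same points.
#' @return A [point_cloud()] with `min(n, n_points(cloud))` points, in input
#'   order.
#' @export
subsample_cloud <- function(cloud, n = 6000, seed = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- as.integer(n)
  if (n < 1) abort("`n` must be a positive integer.")
  if (nrow(cloud) < n) {
    warn(sprintf("Cloud '%s' has only %d points (< %d requested); using all of them.",
                 tree_id(cloud), nrow(cloud), n))
    return(cloud)
  }
  idx <- sort(with_seed_(seed, sample.int(nrow(cloud), n)))
  restore_cloud(unclass(cloud)[idx, , drop = FALSE], cloud)
}

#' Read or write a tree manifest
#'
#' The manifest is a CSV with columns `tree_id`, `species`, `cloud_path`
#' linking every tree to its point-cloud file and species label.
#'
#' @param path CSV path.
#' @return `read_manifest()` returns a tibble with one row per tree.
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("tree_id", "species", "cloud_path")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort(sprintf("Manifest '%s' lacks column(s): %s.", path, paste(missing, collapse = ", ")))
  }
  df$tree_id <- as.character(df$tree_id)
  if (anyDuplicated(df$tree_id)) {
    abort(sprintf("Manifest '%s' has duplicated tree_id values.", path))
  }
  as_tibble(df[required])
}

#' @rdname read_manifest
#' @param records tibble with columns `tree_id`, `species`, `cloud_path`.
#' @export
write_manifest <- function(records, path) {
  stopifnot(all(c("tree_id", "species", "cloud_path") %in% names(records)))
  write.csv(records[c("tree_id", "species", "cloud_path")], path, row.names = FALSE)
  invisible(path)
}
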