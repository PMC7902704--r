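#' Trim the lowest points of a cloud
#'
#' Removes the `floor(fraction * N)` points with the smallest z (ties broken
#' by input order: among equal heights, earlier points are removed first).
#' Because TLS point density is much higher near the ground, cutting the
#' lowest 30% of *points* typically removes only around 10% of the tree's
#' *height*, while discarding the ground-heavy bulk that carries little
#' species signal.
#'
#' @param cloud a [point_cloud()].
#' @param fraction fraction of points to remove, in `[0, 1)`.
#' @return The trimmed [point_cloud()], kept points in input order.
#' @export
trim_lowest_points <- function(cloud, fraction = 0.3) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (fraction < 0 || fraction >= 1) abort("`fraction` must be in [0, 1).")
  k <- floor(fraction * nrow(cloud))
  if (k == 0) return(cloud)
  drop <- order(cloud[, "z"])[seq_len(k)]  # stable: ties by input order
  kept <- setdiff(seq_len(nrow(cloud)), drop)
  if (length(kept) == 0) abort("Trimming removed every point.")
  restore_cloud(unclass(cloud)[kept, , drop = FALSE], cloud)
}

#' Fixed-size point samples for point-set classifiers
#'
#' Input preparation for PointNet-style baselines: trim the ground-heavy
#' lowest `fraction` of points once, then draw `n_repeats` independent
#' seeded samples of exactly `n_points` points each (without replacement;
#' if the trimmed cloud is smaller than `n_points`, sampling falls back to
#' replacement with a warning).
#'
#' @param cloud a [point_cloud()].
#' @param n_points points per sample.
#' @param n_repeats number of samples per tree.
#' @param fraction passed to [trim_lowest_points()].
#' @param seed integer seed; same seed, same sample sequence.
#' @return Tibble with `tree_id`, `repeat_index` (0-based) and `points`
#'   (list column of n_points x 3 matrices).
#' @export
make_pointnet_samples <- function(cloud, n_points = 2048L, n_repeats = 10L,
                                  fraction = 0.3, seed = 1L) {
  stopifnot(inherits(cloud, "point_cloud"))
  n_points <- as.integer(n_points); n_repeats <- as.integer(n_repeats)
  if (n_points < 1L || n_repeats < 1L) abort("`n_points` and `n_repeats` must be >= 1.")
  trimmed <- trim_lowest_points(cloud, fraction)
  replace <- nrow(trimmed) < n_points
  if (replace) {
    warn(sprintf("Trimmed cloud '%s' has %d points (< %d); sampling with replacement.",
                 tree_id(cloud), nrow(trimmed), n_points))
  }
  seeds <- derive_seeds(seed, n_repeats)
  tibble(
    tree_id = tree_id(cloud),
    repeat_index = seq_len(n_repeats) - 1L,
    points = lapply(seq_len(n_repeats), function(r) {
      idx <- with_seed_(seeds[r], sample.int(nrow(trimmed), n_points, replace = replace))
      unclass(trimmed)[idx, , drop = FALSE]
    })
  )
}

#' Write point samples as one packed CSV
#'
#' One row per point with columns `tree_id`, `sample_id`, `x`, `y`, `z`;
#' `sample_id` is `<tree_id>_r<repeat_index>`.
#'
#' @param samples tibble from [make_pointnet_samples()] (rows of several
#'   trees may be bound together).
#' @param path CSV path.
#' @export
write_pointnet_samples <- function(samples, path) {
  stopifnot(all(c("tree_id", "repeat_index", "points") %in% names(samples)))
  rows <- purrr::pmap(samples[c("tree_id", "repeat_index", "points")],
    function(tree_id, repeat_index, points) {
      tibble(tree_id = tree_id,
             sample_id = sprintf("%s_r%d", tree_id, repeat_index),
             x = points[, 1], y = points[, 2], z = points[, 3])
    })
  write.csv(dplyr::bind_rows(rows), path, row.names = FALSE)
  invisible(path)
}
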