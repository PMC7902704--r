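#' Augmentation configuration
#'
#' Parameters of the transforms used to enlarge under-represented species:
#' a weak rotation of the point cloud about all three axes, a small vertical
#' and horizontal image shift, additive Gaussian pixel noise, unsharp-mask
#' sharpening and a contrast change. The balancing policy is the pair
#' (`minority_threshold_images`, `n_aug_per_minority`): any species whose
#' total base image count (all views of all its trees, before any
#' augmentation) is below the threshold receives exactly
#' `n_aug_per_minority` extra training images.
#'
#' @param max_tilt_deg largest tilt about the horizontal x and y axes
#'   (degrees); the z rotation may use any angle up to `max_z_rot_deg`.
#' @param max_z_rot_deg upper bound of the uniform rotation about the
#'   vertical axis (degrees).
#' @param max_shift_frac largest image shift, as a fraction of each image
#'   dimension; vacated pixels are filled with the background gray.
#' @param noise_sigma_gray standard deviation of the additive Gaussian pixel
#'   noise, in gray levels.
#' @param sharpen_amount unsharp-mask strength in `[0, 1]` (0 = off).
#' @param contrast_factor_range range of the multiplicative contrast factor
#'   applied about mid-gray (127.5).
#' @param n_aug_per_minority augmented images appended per under-represented
#'   species.
#' @param minority_threshold_images base-image count below which a species
#'   counts as under-represented.
#' @param seed optional default seed carried in the config.
#' @return An `augment_config` object (validated list).
#' @export
augment_config <- function(max_tilt_deg = 10, max_z_rot_deg = 360,
                           max_shift_frac = 0.05, noise_sigma_gray = 5,
                           sharpen_amount = 0.5, contrast_factor_range = c(0.8, 1.2),
                           n_aug_per_minority = 400L, minority_threshold_images = 1000L,
                           seed = NULL) {
  cfg <- list(
    max_tilt_deg = as.numeric(max_tilt_deg),
    max_z_rot_deg = as.numeric(max_z_rot_deg),
    max_shift_frac = as.numeric(max_shift_frac),
    noise_sigma_gray = as.numeric(noise_sigma_gray),
    sharpen_amount = as.numeric(sharpen_amount),
    contrast_factor_range = as.numeric(contrast_factor_range),
    n_aug_per_minority = as.integer(n_aug_per_minority),
    minority_threshold_images = as.integer(minority_threshold_images),
    seed = seed
  )
  if (any(c(cfg$max_tilt_deg, cfg$max_z_rot_deg, cfg$max_shift_frac,
            cfg$noise_sigma_gray) < 0)) {
    abort("Augmentation magnitudes must be >= 0.")
  }
  if (cfg$sharpen_amount < 0 || cfg$sharpen_amount > 1) abort("`sharpen_amount` must be in [0, 1].")
  if (length(cfg$contrast_factor_range) != 2 ||
      cfg$contrast_factor_range[1] > cfg$contrast_factor_range[2] ||
      cfg$contrast_factor_range[1] < 0) {
    abort("`contrast_factor_range` must be a valid non-negative interval.")
  }
  if (cfg$n_aug_per_minority < 0L) abort("`n_aug_per_minority` must be >= 0.")
  structure(cfg, class = "augment_config")
}

# 3x3 box blur with replicated edges; building block of the unsharp mask.
box_blur3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- m[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  acc <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + pad[dr + seq_len(h), dc + seq_len(w)]
  }
  acc / 9
}

shift_image <- function(m, dr, dc, fill) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_r <- seq_len(h) - dr; src_c <- seq_len(w) - dc
  ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
  out[which(ok_r), which(ok_c)] <- m[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Produce one augmented image from a training tree's point cloud
#'
#' Applies, in order: a random rotation of the point cloud about all three
#' axes (tilts of at most `max_tilt_deg` about x and y, any angle about z),
#' rendering of one view, then the image-space transforms — a small random
#' shift (background fill), additive Gaussian pixel noise, unsharp-mask
#' sharpening, and a multiplicative contrast change about mid-gray — with a
#' final clip to 0..255. With every magnitude set to zero (and
#' `contrast_factor_range = c(1, 1)`) the output is bit-identical to the
#' unaugmented 0-degree view rendered with the same seed.
#'
#' @param cloud a non-empty [point_cloud()] of a *training* tree.
#' @param render_cfg a [render_config()].
#' @param aug_cfg an [augment_config()].
#' @param seed integer seed; fixed seed, fixed output.
#' @param subsample_n points drawn before rendering (as for base views).
#' @param view_index index recorded on the image; augmented images use
#'   indices >= 1000.
#' @return A [gray_image()] with `augmented = TRUE`.
#' @export
augment_once <- function(cloud, render_cfg = render_config(), aug_cfg = augment_config(),
                         seed = 1L, subsample_n = 6000, view_index = 1000L) {
  stopifnot(inherits(cloud, "point_cloud"), inherits(aug_cfg, "augment_config"))
  with_seed_(seed, {
    sub <- if (nrow(cloud) >= subsample_n) {
      idx <- sort(sample.int(nrow(cloud), subsample_n))
      restore_cloud(unclass(cloud)[idx, , drop = FALSE], cloud)
    } else cloud
    tilt_x <- runif(1, -aug_cfg$max_tilt_deg, aug_cfg$max_tilt_deg)
    tilt_y <- runif(1, -aug_cfg$max_tilt_deg, aug_cfg$max_tilt_deg)
    rot_z <- runif(1, 0, aug_cfg$max_z_rot_deg)
    if (tilt_x != 0) sub <- rotate_axis(sub, c(1, 0, 0), tilt_x)
    if (tilt_y != 0) sub <- rotate_axis(sub, c(0, 1, 0), tilt_y)
    if (rot_z != 0) sub <- rotate_z(sub, rot_z)
    img <- render_view(sub, render_cfg, view_index = view_index, augmented = TRUE)
    m <- unclass(img) + 0.0

    dr <- round(runif(1, -1, 1) * aug_cfg$max_shift_frac * render_cfg$height_px)
    dc <- round(runif(1, -1, 1) * aug_cfg$max_shift_frac * render_cfg$width_px)
    if (dr != 0 || dc != 0) m <- shift_image(m, dr, dc, render_cfg$background)
    if (aug_cfg$noise_sigma_gray > 0) {
      m <- m + rnorm(length(m), 0, aug_cfg$noise_sigma_gray)
    }
    if (aug_cfg$sharpen_amount > 0) {
      m <- m + aug_cfg$sharpen_amount * (m - box_blur3(m))
    }
    fac <- runif(1, aug_cfg$contrast_factor_range[1], aug_cfg$contrast_factor_range[2])
    m <- (m - 127.5) * fac + 127.5
    m <- round(pmin(pmax(m, 0), 255))
    gray_image(matrix(as.integer(m), nrow(m), ncol(m)),
               tree_id(cloud), view_index, augmented = TRUE)
  })
}

#' Balance a training image set by augmenting under-represented species
#'
#' For every species whose *base* image count (views of all its trees,
#' train and test together, before augmentation) is below
#' `minority_threshold_images`, appends exactly `n_aug_per_minority`
#' augmented images built from randomly chosen *training* trees of that
#' species. Other species pass through unchanged. Augmentation happens after
#' the per-tree split, and only training clouds are accepted, so augmented
#' images can never leak into the test set.
#'
#' @param train_images image index tibble (see [image_index()]) for the
#'   training partition only.
#' @param train_clouds tibble with `tree_id`, `species`, `cloud` (list of
#'   [point_cloud()]s) for training trees.
#' @param base_image_counts named integer vector: species -> total base
#'   image count (typically `n_views` x total trees of that species).
#' @param render_cfg,aug_cfg configurations; the policy constants live in
#'   `aug_cfg`.
#' @param seed integer seed for tree choice and transforms.
#' @param subsample_n passed to [augment_once()].
#' @return `train_images` with augmented rows appended (fresh `view_index`
#'   values 1000, 1001, ... per species).
#' @export
balance_training_set <- function(train_images, train_clouds, base_image_counts,
                                 render_cfg = render_config(), aug_cfg = augment_config(),
                                 seed = 1L, subsample_n = 6000) {
  stopifnot(is.data.frame(train_images), is.data.frame(train_clouds))
  species <- names(base_image_counts)
  if (is.null(species)) abort("`base_image_counts` must be a named vector (names = species).")
  minority <- species[base_image_counts < aug_cfg$minority_threshold_images]
  if (length(minority) == 0 || aug_cfg$n_aug_per_minority == 0L) return(train_images)

  seeds <- derive_seeds(seed, length(minority) * (aug_cfg$n_aug_per_minority + 1L))
  out <- vector("list", length(minority))
  for (i in seq_along(minority)) {
    sp <- minority[i]
    donors <- train_clouds[train_clouds$species == sp, , drop = FALSE]
    if (nrow(donors) == 0) {
      abort(sprintf("Species '%s' needs augmentation but has no training trees.", sp))
    }
    block <- seeds[seq.int((i - 1L) * (aug_cfg$n_aug_per_minority + 1L) + 1L,
                           length.out = aug_cfg$n_aug_per_minority + 1L)]
    pick <- with_seed_(block[1], sample.int(nrow(donors), aug_cfg$n_aug_per_minority, replace = TRUE))
    imgs <- lapply(seq_len(aug_cfg$n_aug_per_minority), function(j) {
      augment_once(donors$cloud[[pick[j]]], render_cfg, aug_cfg,
                   seed = block[j + 1L], subsample_n = subsample_n,
                   view_index = 999L + j)
    })
    out[[i]] <- image_index(imgs, species = sp)
  }
  dplyr::bind_rows(train_images, dplyr::bind_rows(out))
}

#' Image bookkeeping for a study, without rendering a single pixel
#'
#' Pure arithmetic of the dataset pipeline: per-species base image counts
#' (`n_views` per tree), the balancing policy (every species below
#' `minority_threshold_images` base images gains `n_aug_per_minority`
#' augmented training images), and the train/test image tallies implied by
#' per-tree test counts. Useful to audit a design before paying for
#' rendering, and to reproduce published image tallies exactly.
#'
#' @param n_trees named integer vector: species -> number of trees.
#' @param test_trees named integer vector of per-species test-tree counts,
#'   or `NULL` to derive them from `test_fraction` (rounded half away from
#'   zero, minimum 1).
#' @param test_fraction used when `test_trees` is `NULL`.
#' @param n_views images per tree.
#' @param aug_cfg an [augment_config()] supplying the balancing policy.
#' @return Tibble with one row per species: `n_trees`, `n_images` (base),
#'   `n_images_after_aug`, `n_train`, `n_test`.
#' @examples
#' plan_image_counts(c(ash = 39, beech = 163), test_trees = c(ash = 7, beech = 35))
#' @export
plan_image_counts <- function(n_trees, test_trees = NULL, test_fraction = 0.2,
                              n_views = 10L, aug_cfg = augment_config()) {
  if (is.null(names(n_trees))) abort("`n_trees` must be named by species.")
  if (is.null(test_trees)) {
    test_trees <- pmax(1L, as.integer(floor(n_trees * test_fraction + 0.5)))
    names(test_trees) <- names(n_trees)
  }
  if (!all(names(n_trees) %in% names(test_trees))) {
    abort("`test_trees` must cover every species in `n_trees`.")
  }
  test_trees <- test_trees[names(n_trees)]
  if (any(test_trees >= n_trees)) abort("Each species needs at least one training tree.")
  base <- as.integer(n_views) * as.integer(n_trees)
  aug <- ifelse(base < aug_cfg$minority_threshold_images, aug_cfg$n_aug_per_minority, 0L)
  n_test <- as.integer(n_views) * as.integer(test_trees)
  tibble(
    species = names(n_trees),
    n_trees = as.integer(n_trees),
    n_images = base,
    n_images_after_aug = base + aug,
    n_train = base - n_test + aug,
    n_test = n_test
  )
}
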