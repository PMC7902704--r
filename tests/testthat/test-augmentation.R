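zero_aug <- function() {
  augment_config(max_tilt_deg = 0, max_z_rot_deg = 0, max_shift_frac = 0,
                 noise_sigma_gray = 0, sharpen_amount = 0,
                 contrast_factor_range = c(1, 1))
}

test_that("augment_once with zero magnitudes reproduces the 0-degree view bit-exactly", {
  pc <- random_cloud(1200, seed = 21, id = "id")
  base <- generate_views(pc, render_config(), subsample_n = 800, seed = 5)[[1]]
  aug <- augment_once(pc, render_config(), zero_aug(), seed = 5, subsample_n = 800)
  expect_identical(pixels(aug), pixels(base))
  expect_true(attr(aug, "augmented"))
  expect_gte(attr(aug, "view_index"), 1000L)
})

test_that("augment_once is seeded and keeps the configured raster", {
  pc <- random_cloud(2000, seed = 22)
  a1 <- augment_once(pc, seed = 9, subsample_n = 1500)
  a2 <- augment_once(pc, seed = 9, subsample_n = 1500)
  a3 <- augment_once(pc, seed = 10, subsample_n = 1500)
  expect_identical(unclass(a1), unclass(a2))
  expect_false(identical(unclass(a1), unclass(a3)))
  expect_equal(dim(a1), c(150, 100))
  expect_true(is.integer(unclass(a1)) && all(a1 >= 0 & a1 <= 255))
})

test_that("the balancing policy adds images exactly where base counts fall short", {
  # arbitrary species tables against independent arithmetic
  withr::with_seed(31, {
    for (rep in 1:20) {
      k <- sample(2:6, 1)
      trees <- sample(5:200, k)
      names(trees) <- paste0("sp", seq_len(k))
      test_trees <- pmax(1L, as.integer(floor(trees * 0.2 + 0.5)))
      names(test_trees) <- names(trees)
      tal <- plan_image_counts(trees, test_trees = test_trees)
      expected_aug <- ifelse(10 * trees < 1000, 400L, 0L)
      expect_equal(tal$n_images, unname(10 * trees))
      expect_equal(tal$n_images_after_aug - tal$n_images, unname(expected_aug))
      expect_equal(tal$n_train + tal$n_test, unname(10 * trees + expected_aug))
    }
  })
})

test_that("balance_training_set appends augmented images from training trees only", {
  st <- small_study(trees = 3, points = 1500)
  imgs <- render_study(st, render_config(n_views = 2), subsample_n = 1000, seed = 2)
  split <- grouped_split(st, per_species_test_counts = c(conifer = 1, broadleaf = 1), seed = 4)
  sets <- assemble_datasets(imgs, split)
  test_before <- sets$test

  # minority policy scaled to the fixture: conifer (6 base images) is below
  # a threshold of 7, broadleaf (6) is kept above by construction
  ac <- augment_config(n_aug_per_minority = 5L, minority_threshold_images = 7L)
  base_counts <- c(conifer = 6L, broadleaf = 1000L)
  train_clouds <- st[st$tree_id %in% split$train_tree_ids, c("tree_id", "species", "cloud")]
  out <- balance_training_set(sets$train, train_clouds, base_counts,
                              render_config(n_views = 2), ac, seed = 6,
                              subsample_n = 1000)
  added <- out[out$augmented, ]
  expect_equal(nrow(out), nrow(sets$train) + 5L)
  expect_equal(nrow(added), 5L)
  expect_true(all(added$species == "conifer"))
  expect_true(all(added$tree_id %in%
                    train_clouds$tree_id[train_clouds$species == "conifer"]))
  expect_true(all(added$view_index >= 1000L))
  # the test pool is untouched, bit for bit
  expect_identical(lapply(test_before$image, unclass), lapply(sets$test$image, unclass))

  # a species that needs augmentation but has no training trees is an error
  expect_error(
    balance_training_set(sets$train, train_clouds[train_clouds$species == "broadleaf", ],
                         base_counts, render_config(n_views = 2), ac, seed = 6),
    "no training trees")
})

test_that("published-style tallies come out of the policy arithmetic", {
  tal <- plan_image_counts(c(ash = 39, red_oak = 100, beech = 163),
                           test_trees = c(ash = 7, red_oak = 19, beech = 35))
  expect_equal(tal$n_images_after_aug[tal$species == "ash"], 790L)
  expect_equal(tal$n_images_after_aug[tal$species == "red_oak"], 1000L)  # unchanged
  expect_equal(tal$n_images_after_aug[tal$species == "beech"], 1630L)    # unchanged
})
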