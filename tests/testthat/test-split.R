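fake_records <- function(counts) {
  tibble::tibble(
    tree_id = unlist(lapply(names(counts), function(s) paste0(s, "_", seq_len(counts[[s]])))),
    species = rep(names(counts), unname(counts))
  )
}

test_that("grouped_split honours fractions, explicit counts, and reproducibility", {
  rec <- fake_records(c(a = 10, b = 39))
  s <- grouped_split(rec, test_fraction = 0.2, seed = 1)
  expect_equal(s$per_species$n_test_trees[s$per_species$species == "a"], 2L)
  expect_equal(s$per_species$n_test_trees[s$per_species$species == "b"], 8L)  # round(7.8)
  expect_length(intersect(s$train_tree_ids, s$test_tree_ids), 0)
  expect_setequal(c(s$train_tree_ids, s$test_tree_ids), rec$tree_id)

  s2 <- grouped_split(rec, test_fraction = 0.2, seed = 1)
  expect_identical(s$test_tree_ids, s2$test_tree_ids)

  ex <- grouped_split(rec, per_species_test_counts = c(a = 3, b = 7), seed = 2)
  expect_equal(sum(ex$test_tree_ids %in% rec$tree_id[rec$species == "b"]), 7L)

  expect_error(grouped_split(rec, per_species_test_counts = c(a = 10, b = 7), seed = 1),
               "only 10")
  expect_error(grouped_split(fake_records(c(a = 1, b = 5)), seed = 1), "at least 2")
  expect_error(grouped_split(rec, test_fraction = 0), "must be in")
})

test_that("no tree ever lands in both partitions (random designs)", {
  withr::with_seed(17, {
    for (i in 1:200) {
      counts <- sample(2:30, sample(2:5, 1))
      names(counts) <- paste0("s", seq_along(counts))
      s <- grouped_split(fake_records(counts), test_fraction = runif(1, 0.1, 0.5),
                         seed = sample.int(1e6, 1))
      expect_length(intersect(s$train_tree_ids, s$test_tree_ids), 0)
      expect_true(all(s$per_species$n_test_trees >= 1))
    }
  })
})

test_that("split manifests serialize to JSON and back", {
  s <- grouped_split(fake_records(c(a = 6, b = 8)), seed = 3)
  f <- withr::local_tempfile(fileext = ".json")
  write_split(s, f)
  back <- read_split(f)
  expect_identical(back$train_tree_ids, s$train_tree_ids)
  expect_identical(back$test_tree_ids, s$test_tree_ids)
  expect_equal(back$per_species, s$per_species)
})

test_that("assemble_datasets routes by tree, conserves images, rejects leakage", {
  st <- small_study(trees = 3, points = 1200)
  imgs <- render_study(st, render_config(n_views = 3), subsample_n = 1000, seed = 5)
  s <- grouped_split(st, seed = 7)
  sets <- assemble_datasets(imgs, s)
  expect_equal(nrow(sets$train) + nrow(sets$test), nrow(imgs))
  expect_length(intersect(unique(sets$train$tree_id), unique(sets$test$tree_id)), 0)
  expect_true(all(sets$test$tree_id %in% s$test_tree_ids))

  # unknown tree id
  rogue <- imgs[1, ]; rogue$tree_id <- "ghost"
  expect_error(assemble_datasets(rbind(imgs, rogue), s), "absent")

  # an augmented image attached to a test tree must be refused
  bad <- imgs
  i <- which(bad$tree_id %in% s$test_tree_ids)[1]
  bad$augmented[i] <- TRUE
  expect_error(assemble_datasets(bad, s), "never touch the test set")
})
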