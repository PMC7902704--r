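#' Strict per-tree train/test split
#'
#' Partitions whole trees — never individual images — into training and test
#' sets, per species, so that no tree contributes images to both sides. Per
#' species, either an explicit number of test trees is honoured exactly, or
#' `round(test_fraction * n_trees)` trees (half away from zero, floor of 1)
#' are drawn at random.
#'
#' @param records tibble with columns `tree_id` and `species` (one row per
#'   tree; `tree_id` unique).
#' @param test_fraction fraction of each species' trees held out.
#' @param per_species_test_counts optional named integer vector giving exact
#'   test-tree counts per species; species not named fall back to
#'   `test_fraction`.
#' @param seed integer seed; the same seed reproduces the same assignment.
#' @return A `split_manifest`: train/test tree-id sets plus a per-species
#'   summary tibble.
#' @export
grouped_split <- function(records, test_fraction = 0.2,
                          per_species_test_counts = NULL, seed = 1L) {
  stopifnot(all(c("tree_id", "species") %in% names(records)))
  if (anyDuplicated(records$tree_id)) abort("`tree_id` must be unique across records.")
  if (is.null(per_species_test_counts) &&
      (test_fraction <= 0 || test_fraction >= 1)) {
    abort("`test_fraction` must be in (0, 1).")
  }
  split_tbl <- split(records$tree_id, records$species)
  species <- names(split_tbl)
  seeds <- derive_seeds(seed, length(species))
  test_ids <- character(0)
  n_test <- integer(length(species))
  for (i in seq_along(species)) {
    ids <- split_tbl[[i]]
    k <- per_species_test_counts[[species[i]]]
    if (is.null(k) || is.na(k)) {
      if (length(ids) < 2) {
        abort(sprintf("Species '%s' has %d tree(s); need at least 2 to split.",
                      species[i], length(ids)))
      }
      k <- max(1L, as.integer(floor(length(ids) * test_fraction + 0.5)))
    } else {
      k <- as.integer(k)
      if (k < 1L) abort(sprintf("Species '%s': need at least 1 test tree.", species[i]))
      if (k >= length(ids)) {
        abort(sprintf("Species '%s': requested %d test trees but only %d trees exist.",
                      species[i], k, length(ids)))
      }
    }
    n_test[i] <- k
    test_ids <- c(test_ids, with_seed_(seeds[i], sample(ids, k)))
  }
  structure(list(
    train_tree_ids = sort(setdiff(records$tree_id, test_ids)),
    test_tree_ids = sort(test_ids),
    per_species = tibble(
      species = species,
      n_trees = unname(lengths(split_tbl)),
      n_test_trees = n_test
    ),
    test_fraction = test_fraction,
    seed = as.integer(seed)
  ), class = "split_manifest")
}

#' @export
print.split_manifest <- function(x, ...) {
  cat(sprintf("<split_manifest> %d train / %d test trees (seed %d)\n",
              length(x$train_tree_ids), length(x$test_tree_ids), x$seed))
  print(x$per_species)
  invisible(x)
}

#' @rdname grouped_split
#' @param manifest a `split_manifest`.
#' @param path JSON path.
#' @export
write_split <- function(manifest, path) {
  stopifnot(inherits(manifest, "split_manifest"))
  jsonlite::write_json(
    list(train_tree_ids = manifest$train_tree_ids,
         test_tree_ids = manifest$test_tree_ids,
         per_species = manifest$per_species,
         test_fraction = manifest$test_fraction,
         seed = manifest$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname grouped_split
#' @export
read_split <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    train_tree_ids = as.character(x$train_tree_ids),
    test_tree_ids = as.character(x$test_tree_ids),
    per_species = as_tibble(x$per_species),
    test_fraction = x$test_fraction,
    seed = as.integer(x$seed)
  ), class = "split_manifest")
}

#' Route images into training and test sets by tree
#'
#' Every image follows its source tree's partition; its label is the
#' species. Augmented images are asserted to land in the training set only —
#' encountering an augmented image from a test tree is an error, because it
#' would mean information leaked across the split.
#'
#' @param images image index tibble (see [image_index()]).
#' @param manifest a `split_manifest` from [grouped_split()].
#' @return List with tibbles `train` and `test`.
#' @export
assemble_datasets <- function(images, manifest) {
  stopifnot(is.data.frame(images), inherits(manifest, "split_manifest"))
  known <- c(manifest$train_tree_ids, manifest$test_tree_ids)
  unknown <- setdiff(unique(images$tree_id), known)
  if (length(unknown)) {
    abort(sprintf("Image(s) reference tree_id(s) absent from the split manifest: %s.",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  in_test <- images$tree_id %in% manifest$test_tree_ids
  if (any(images$augmented & in_test)) {
    abort("Augmented image(s) found on test trees: augmentation must never touch the test set.")
  }
  list(train = images[!in_test, , drop = FALSE],
       test = images[in_test, , drop = FALSE])
}
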