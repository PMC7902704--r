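#' Resolved run configuration
#'
#' Builds the nested configuration driving [run_pipeline()] and the
#' command-line interface: one section per stage, a global seed, and an
#' output directory. Values come from (lowest to highest precedence) the
#' package defaults, a YAML file, and the `...` overrides. Unknown keys are
#' rejected rather than silently ignored. Every pipeline run writes its
#' resolved configuration next to its artifacts so the run can be
#' regenerated.
#'
#' @param file optional YAML file with a subset of the sections.
#' @param ... named overrides, e.g. `seed = 3`,
#'   `model = list(epochs = 10)`.
#' @return A `run_config` (nested list).
#' @export
run_config <- function(file = NULL, ...) {
  defaults <- list(
    seed = 1L,
    out_dir = "tlsimage_run",
    write_images = FALSE,
    simulate = list(
      species = c(conifer = "conifer", broadleaf = "broadleaf"),
      trees_per_species = 10L,
      points_total = 8000L
    ),
    render = list(width_px = 100L, height_px = 150L, n_views = 10L,
                  marker_radius_px = 1L, gray_near = 0L, gray_far = 200L,
                  background = 255L, margin_frac = 0.05, subsample_n = 6000L),
    augment = list(enabled = TRUE, max_tilt_deg = 10, max_z_rot_deg = 360,
                   max_shift_frac = 0.05, noise_sigma_gray = 5,
                   sharpen_amount = 0.5, contrast_factor_range = c(0.8, 1.2),
                   n_aug_per_minority = 400L, minority_threshold_images = 1000L),
    split = list(test_fraction = 0.2, per_species_test_counts = NULL),
    model = list(conv_filters = c(8L, 16L, 32L, 64L), kernel_size = 3L,
                 pool_size = 2L, pool_stride = 2L, dropout_conv = 0.3,
                 dropout_dense = 0.5, dense_units = 128L,
                 learning_rate = 1e-3, batch_size = 32L, epochs = 50L),
    evaluate = list(per_tree = TRUE),
    pointnet = list(enabled = FALSE, n_points = 2048L, n_repeats = 10L,
                    fraction = 0.3)
  )
  cfg <- defaults
  if (!is.null(file)) cfg <- merge_config(cfg, yaml::read_yaml(file), "config file")
  overrides <- list(...)
  if (length(overrides)) cfg <- merge_config(cfg, overrides, "overrides")
  structure(cfg, class = "run_config")
}

merge_config <- function(base, user, where) {
  if (is.null(user)) return(base)
  unknown <- setdiff(names(user), names(base))
  if (length(unknown)) {
    abort(sprintf("Unknown configuration key(s) in %s: %s.",
                  where, paste(unknown, collapse = ", ")))
  }
  for (k in names(user)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]], sprintf("%s$%s", where, k))
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

render_cfg_from <- function(cfg) {
  r <- cfg$render
  render_config(r$width_px, r$height_px, r$n_views, r$marker_radius_px,
                r$gray_near, r$gray_far, r$background, r$margin_frac)
}

augment_cfg_from <- function(cfg) {
  a <- cfg$augment
  augment_config(a$max_tilt_deg, a$max_z_rot_deg, a$max_shift_frac,
                 a$noise_sigma_gray, a$sharpen_amount, a$contrast_factor_range,
                 a$n_aug_per_minority, a$minority_threshold_images)
}

#' Run the full pipeline end to end
#'
#' Simulate (or load) a study, render the multi-view depth images, split by
#' tree, balance the training set by augmentation, train the CNN, and
#' evaluate per-image and per-tree confusion matrices. All artifacts
#' (manifest, split, training history, confusion matrices, image tallies,
#' resolved configuration) are written under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @param records optional tibble (`tree_id`, `species`, `cloud` or
#'   `cloud_path`); when `NULL` a study is simulated per
#'   `config$simulate`.
#' @return List with `records`, `split`, `tally`, `fit`, `confusion`
#'   (per-image) and `confusion_per_tree`.
#' @export
run_pipeline <- function(config = run_config(), records = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out, "config.yaml"))
  seeds <- derive_seeds(config$seed, 5L)
  t0 <- Sys.time()

  if (is.null(records)) {
    sim <- config$simulate
    n_per <- sim$trees_per_species
    if (is.null(names(n_per))) {
      n_per <- stats::setNames(rep(as.integer(n_per), length(sim$species)), names(sim$species))
    }
    per_species <- lapply(names(sim$species), function(sp) {
      list(params = archetype_params(sim$species[[sp]], points_total = sim$points_total,
                                     label = sp),
           n_trees = n_per[[sp]])
    })
    names(per_species) <- names(sim$species)
    records <- generate_study(per_species, seed = seeds[1])
    message(sprintf("simulated %d trees (%s)", nrow(records),
                    paste(sprintf("%s: %d", names(n_per), n_per), collapse = ", ")))
  }
  write_manifest(dplyr::mutate(records, cloud_path = ifelse(is.na(.data$cloud_path),
                                                            paste0(.data$tree_id, ".xyz"),
                                                            .data$cloud_path)),
                 file.path(out, "manifest.csv"))

  rc <- render_cfg_from(config)
  images <- render_study(records, rc, config$render$subsample_n, seed = seeds[2],
                         dir = if (isTRUE(config$write_images)) file.path(out, "images") else NULL)
  message(sprintf("rendered %d images (%d views/tree)", nrow(images), rc$n_views))

  split <- grouped_split(records, config$split$test_fraction,
                         config$split$per_species_test_counts, seed = seeds[3])
  write_split(split, file.path(out, "split.json"))
  sets <- assemble_datasets(images, split)

  base_counts <- rc$n_views * table(records$species)
  ac <- augment_cfg_from(config)
  if (isTRUE(config$augment$enabled)) {
    train_clouds <- records[records$tree_id %in% split$train_tree_ids,
                            c("tree_id", "species", "cloud")]
    sets$train <- balance_training_set(sets$train, train_clouds,
                                       stats::setNames(as.integer(base_counts), names(base_counts)),
                                       rc, ac, seed = seeds[4],
                                       subsample_n = config$render$subsample_n)
    message(sprintf("training set after balancing: %d images", nrow(sets$train)))
  }

  n_trees_vec <- table(records$species)
  test_vec <- stats::setNames(split$per_species$n_test_trees, split$per_species$species)
  tally <- plan_image_counts(stats::setNames(as.integer(n_trees_vec), names(n_trees_vec)),
                             test_trees = test_vec, n_views = rc$n_views,
                             aug_cfg = if (isTRUE(config$augment$enabled)) ac else
                               augment_config(n_aug_per_minority = 0L))
  write.csv(tally, file.path(out, "image_tally.csv"), row.names = FALSE)

  labels <- sort(unique(records$species))
  mc <- config$model
  cnn_cfg <- cnn_config(input_shape = c(rc$height_px, rc$width_px, 1L),
                        conv_filters = mc$conv_filters, kernel_size = mc$kernel_size,
                        pool_size = mc$pool_size, pool_stride = mc$pool_stride,
                        dropout_conv = mc$dropout_conv, dropout_dense = mc$dropout_dense,
                        dense_units = mc$dense_units, n_classes = length(labels),
                        learning_rate = mc$learning_rate, batch_size = mc$batch_size,
                        epochs = mc$epochs, seed = seeds[5])
  fit <- cnn_train(build_model(cnn_cfg), sets$train, labels = labels)
  jsonlite::write_json(list(history = fit$history, seed = fit$seed),
                       file.path(out, "history.json"), auto_unbox = TRUE, digits = NA)

  preds <- predict(fit, sets$test)
  cm <- evaluate_predictions(preds$truth, preds$.pred, labels)
  write_confusion(cm, file.path(out, "confusion"))
  result <- list(records = records, split = split, tally = tally, fit = fit,
                 confusion = cm, confusion_per_tree = NULL)
  if (isTRUE(config$evaluate$per_tree)) {
    result$confusion_per_tree <- per_tree_evaluate(preds, labels)
    write_confusion(result$confusion_per_tree, file.path(out, "confusion_per_tree"))
  }
  message(sprintf("test accuracy (per image): %.4f  [%d test images; %.1f s elapsed]",
                  cm$overall_accuracy, cm$n_items,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  result
}

#' Load a rendered image directory
#'
#' Reads the `index.csv` + PNG layout written by [render_study()] back into
#' an image index tibble.
#'
#' @param dir directory containing `index.csv` and the PNGs.
#' @return Image index tibble (see [image_index()]).
#' @export
read_image_dir <- function(dir) {
  idx_path <- file.path(dir, "index.csv")
  if (!file.exists(idx_path)) abort(sprintf("No index.csv in '%s'.", dir))
  idx <- read.csv(idx_path, stringsAsFactors = FALSE)
  imgs <- lapply(seq_len(nrow(idx)), function(i) {
    read_image(file.path(dir, idx$path[i]), idx$tree_id[i], idx$view_index[i],
               isTRUE(idx$augmented[i]))
  })
  tibble(tree_id = as.character(idx$tree_id), species = idx$species,
         view_index = as.integer(idx$view_index), augmented = as.logical(idx$augmented),
         image = imgs)
}
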