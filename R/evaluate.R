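#' Confusion matrix and overall accuracy
#'
#' Tallies predictions against truths over a fixed label order and reports
#' the raw count matrix (rows = true class, columns = predicted class), the
#' row-normalised matrix (each row divided by its true-class support, i.e.
#' per-class recall, to be read left to right), and the overall accuracy
#' (fraction of items on the diagonal). Rows with zero support are left at
#' zero and recorded in `zero_support`.
#'
#' @param truth vector of true labels.
#' @param estimate vector of predicted labels, same length.
#' @param labels label order for rows/columns; defaults to the sorted union
#'   of the observed labels.
#' @return A `confusion_matrix` object.
#' @examples
#' cm <- evaluate_predictions(c("A", "A", "B"), c("A", "B", "B"))
#' cm$row_normalized
#' glance(cm)
#' @export
evaluate_predictions <- function(truth, estimate, labels = NULL) {
  truth <- as.character(truth); estimate <- as.character(estimate)
  if (length(truth) != length(estimate) || length(truth) < 1) {
    abort("`truth` and `estimate` must be non-empty vectors of equal length.")
  }
  labels <- labels %||% sort(unique(c(truth, estimate)))
  bad <- setdiff(unique(c(truth, estimate)), labels)
  if (length(bad)) {
    abort(sprintf("Label(s) outside the configured label set: %s.", paste(bad, collapse = ", ")))
  }
  counts <- table(factor(truth, levels = labels), factor(estimate, levels = labels))
  counts <- matrix(as.integer(counts), length(labels), length(labels),
                   dimnames = list(truth = labels, estimate = labels))
  support <- rowSums(counts)
  norm <- counts / ifelse(support == 0, 1, support)
  structure(list(
    labels = labels,
    counts = counts,
    row_normalized = norm,
    overall_accuracy = sum(diag(counts)) / length(truth),
    n_items = length(truth),
    zero_support = labels[support == 0]
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("<confusion_matrix> %d items, overall accuracy %.4f\n",
              x$n_items, x$overall_accuracy))
  cat("Row-normalised (true class in rows, read left to right):\n")
  print(round(x$row_normalized, digits))
  invisible(x)
}

#' @rdname evaluate_predictions
#' @param x a `confusion_matrix`.
#' @param ... unused.
#' @export
tidy.confusion_matrix <- function(x, ...) {
  df <- as.data.frame.table(x$counts, responseName = "n")
  norm <- as.data.frame.table(x$row_normalized, responseName = "prop")
  tibble(truth = as.character(df$truth), estimate = as.character(df$estimate),
         n = as.integer(df$n), prop = norm$prop)
}

#' @rdname evaluate_predictions
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble(accuracy = x$overall_accuracy, n = x$n_items,
         n_classes = length(x$labels))
}

#' @rdname evaluate_predictions
#' @param object a `confusion_matrix`.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = factor(.data$estimate, object$labels),
                 y = factor(.data$truth, rev(object$labels)),
                 fill = .data$prop)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$prop)), size = 3) +
    scale_fill_gradient(low = "white", high = "steelblue", limits = c(0, 1)) +
    labs(x = "predicted", y = "true", fill = "row\nprop.") +
    theme_minimal()
}

#' @rdname evaluate_predictions
#' @param path base path; `.csv` gets the counts, `.json` the full object.
#' @export
write_confusion <- function(x, path) {
  stopifnot(inherits(x, "confusion_matrix"))
  write.csv(as.data.frame(x$row_normalized), paste0(path, ".csv"))
  jsonlite::write_json(
    list(labels = x$labels, counts = x$counts, row_normalized = x$row_normalized,
         overall_accuracy = x$overall_accuracy, n_items = x$n_items),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

# argmax with ties broken by the lowest class index
argmax_label <- function(prob, labels) labels[apply(prob, 1, which.max)]

#' Per-tree evaluation by averaging view probabilities
#'
#' Aggregates per-image class-probability vectors to one prediction per
#' tree: a tree's predicted species is the argmax of the mean probability
#' vector over its views (ties broken by the lowest class index), and the
#' confusion matrix is computed over trees. This answers whether the
#' classifier identifies *trees* rather than individual views; per-image
#' scoring (the default elsewhere) matches the granularity of image tallies.
#'
#' @param probs data frame with a `tree_id` column, a `truth` column, and
#'   one numeric probability column per class named exactly as in `labels`.
#' @param labels class label order.
#' @return A `confusion_matrix` over trees.
#' @export
per_tree_evaluate <- function(probs, labels) {
  stopifnot(all(c("tree_id", "truth") %in% names(probs)),
            all(labels %in% names(probs)))
  grouped <- dplyr::summarise(
    dplyr::group_by(probs, .data$tree_id),
    truth = .data$truth[1],
    dplyr::across(dplyr::all_of(labels), mean),
    .groups = "drop"
  )
  if (nrow(grouped) < 1) abort("No trees to evaluate.")
  pred <- argmax_label(as.matrix(grouped[labels]), labels)
  evaluate_predictions(grouped$truth, pred, labels)
}
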