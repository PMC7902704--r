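test_that("confusion matrices match hand counts", {
  cm <- evaluate_predictions(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(cm$overall_accuracy, 2 / 3)
  expect_equal(unname(cm$row_normalized["A", ]), c(0.5, 0.5))
  expect_equal(unname(cm$row_normalized["B", ]), c(0, 1))

  perfect <- evaluate_predictions(c("x", "y", "z"), c("x", "y", "z"))
  expect_equal(perfect$overall_accuracy, 1)
  expect_equal(unname(diag(perfect$row_normalized)), rep(1, 3))

  one <- evaluate_predictions("A", "A", labels = c("A", "B"))
  expect_equal(sum(one$row_normalized["A", ]), 1)
  expect_equal(one$zero_support, "B")

  expect_error(evaluate_predictions("A", "Q", labels = c("A", "B")), "outside")
})

test_that("evaluate agrees with a brute-force tally and the accuracy identity holds", {
  withr::with_seed(23, {
    for (rep in 1:10) {
      labs <- paste0("s", 1:sample(2:6, 1))
      n <- sample(10:1000, 1)
      truth <- sample(labs, n, TRUE)
      est <- sample(labs, n, TRUE)
      cm <- evaluate_predictions(truth, est, labs)
      # brute-force double loop
      ref <- matrix(0L, length(labs), length(labs), dimnames = list(labs, labs))
      for (i in seq_len(n)) ref[truth[i], est[i]] <- ref[truth[i], est[i]] + 1L
      expect_equal(unname(cm$counts), unname(ref))
      # overall accuracy = support-weighted mean of row diagonals
      support <- rowSums(ref)
      diag_vals <- diag(cm$row_normalized)
      expect_equal(cm$overall_accuracy,
                   sum(diag_vals[support > 0] * support[support > 0]) / n)
      # every supported row sums to one
      expect_true(all(abs(rowSums(cm$row_normalized)[support > 0] - 1) < 1e-9))
    }
  })
})

test_that("tidy/glance expose the matrix as tibbles", {
  cm <- evaluate_predictions(c("A", "A", "B"), c("A", "B", "B"))
  td <- tidy(cm)
  expect_equal(nrow(td), 4)
  expect_equal(sum(td$n), 3)
  expect_equal(glance(cm)$accuracy, 2 / 3)
})

test_that("per-tree aggregation averages views and breaks ties by class order", {
  labs <- c("fir", "oak")
  probs <- tibble::tibble(
    tree_id = c("t1", "t1", "t2", "t2"),
    truth = c("fir", "fir", "oak", "oak"),
    fir = c(0.6, 0.4, 0.9, 0.9),
    oak = c(0.4, 0.6, 0.1, 0.1)
  )
  cm <- per_tree_evaluate(probs, labs)
  expect_equal(cm$n_items, 2)
  # t1: mean (0.5, 0.5) -> tie -> "fir" (lowest class index) -> correct
  # t2: confidently "fir" -> wrong
  expect_equal(cm$counts["fir", "fir"], 1L)
  expect_equal(cm$counts["oak", "fir"], 1L)
  expect_equal(cm$overall_accuracy, 0.5)

  # identical vectors per tree: same answer as per-image argmax
  same <- tibble::tibble(tree_id = rep("t", 10), truth = "oak",
                         fir = rep(0.3, 10), oak = rep(0.7, 10))
  expect_equal(per_tree_evaluate(same, labs)$overall_accuracy, 1)
})
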