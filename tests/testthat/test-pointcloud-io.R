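test_that("read_xyz parses clean, extra-column and comma-delimited files", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1 0 0", "0 0 10"), f)
  pc <- read_xyz(f, "a")
  expect_equal(nrow(pc), 3)
  expect_equal(cloud_height(pc), 10)
  expect_equal(tree_id(pc), "a")

  writeLines(c("0,0,0", "", "# comment", "1.5,2.5,3.5,99"), f)
  pc <- read_xyz(f)
  expect_equal(nrow(pc), 2)
  expect_equal(unname(pc[2, ]), c(1.5, 2.5, 3.5))  # 4th column dropped
})

test_that("read_xyz reports parse errors with the offending line number", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("0 0 0", "1.0 2.0", "0 0 1"), f)
  expect_error(read_xyz(f), "line 2", class = "tlsimage_parse_error")

  writeLines(c("0 0 0", "a b c"), f)
  expect_error(read_xyz(f), "line 2", class = "tlsimage_parse_error")

  writeLines(character(0), f)
  expect_error(read_xyz(f), class = "tlsimage_empty_cloud")

  expect_error(read_xyz(file.path(tempdir(), "no_such_file.xyz")),
               class = "tlsimage_io_error")
})

test_that("write_xyz/read_xyz round-trips coordinates to 1e-6 m, gz included", {
  pc <- random_cloud(200, seed = 3, id = "rt")
  for (ext in c(".xyz", ".xyz.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_xyz(pc, f)
    back <- read_xyz(f)
    expect_lt(max(abs(unclass(back) - unclass(pc))), 1e-6)
  }
})

test_that("center_cloud centres xy, floors z, and preserves shape", {
  expect_equal(unclass(center_cloud(point_cloud(matrix(c(5, 5, 5), 1)))),
               matrix(0, 1, 3), ignore_attr = TRUE)
  two <- point_cloud(matrix(c(0, 0, 0, 2, 0, 4), 2, byrow = TRUE))
  expect_equal(unclass(center_cloud(two)),
               matrix(c(-1, 0, 0, 1, 0, 4), 2, byrow = TRUE), ignore_attr = TRUE)

  pc <- random_cloud(150, seed = 9)
  cc <- center_cloud(pc)
  expect_equal(mean(cc[, 1]), 0, tolerance = 1e-12)
  expect_equal(min(cc[, 3]), 0, tolerance = 1e-12)
  expect_lt(max(abs(pairwise_dists(cc) - pairwise_dists(pc))), 1e-9)
  expect_equal(unclass(center_cloud(cc)), unclass(cc))  # idempotent
})

test_that("subsample_cloud draws exact seeded subsets and warns when short", {
  pc <- random_cloud(1000, seed = 5)
  s1 <- subsample_cloud(pc, 600, seed = 7)
  s2 <- subsample_cloud(pc, 600, seed = 7)
  expect_equal(nrow(s1), 600)
  expect_identical(unclass(s1), unclass(s2))
  # subset property: every sampled point is a point of the input
  keys <- function(m) paste(m[, 1], m[, 2], m[, 3])
  expect_true(all(keys(s1) %in% keys(pc)))
  expect_false(identical(unclass(subsample_cloud(pc, 600, seed = 8)), unclass(s1)))

  # n == cloud size: exhaustive draw returns the full point set
  s_all <- subsample_cloud(pc, 1000, seed = 1)
  expect_setequal(keys(s_all), keys(pc))

  expect_warning(small <- subsample_cloud(pc, 2000, seed = 1), "only")
  expect_equal(nrow(small), 1000)
})

test_that("manifests round-trip and reject duplicate tree ids", {
  f <- withr::local_tempfile(fileext = ".csv")
  rec <- tibble::tibble(tree_id = c("a", "b"), species = c("ash", "pine"),
                        cloud_path = c("a.xyz", "b.xyz"))
  write_manifest(rec, f)
  expect_equal(read_manifest(f), rec)

  rec$tree_id <- c("a", "a")
  write_manifest(rec, f)
  expect_error(read_manifest(f), "duplicated")
})
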