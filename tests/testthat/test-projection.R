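test_that("rotate_z is a rigid rotation: full turn, quarter turn, composition", {
  pc <- random_cloud(50, seed = 2)
  expect_lt(max(abs(unclass(rotate_z(pc, 360)) - unclass(pc))), 1e-9)
  expect_lt(max(abs(unclass(rotate_z(rotate_z(pc, 180), 180)) - unclass(pc))), 1e-9)
  expect_lt(max(abs(pairwise_dists(rotate_z(pc, 77)) - pairwise_dists(pc))), 1e-9)

  # analytic quarter turn about the origin (centroid at origin by symmetry)
  quad <- point_cloud(matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 1, 0, -1, 1), 4, byrow = TRUE))
  r <- rotate_z(quad, 90)
  expect_lt(max(abs(unclass(r)[1, ] - c(0, 1, 0))), 1e-9)
})

test_that("render_view produces the configured raster with background intact", {
  pc <- random_cloud(300, seed = 4)
  img <- render_view(pc)
  expect_s3_class(img, "gray_image")
  expect_equal(dim(img), c(150, 100))
  expect_true(all(img %in% c(255, 0:200)))
  expect_equal(img[1, 1], 255L)  # margin corner stays background
})

test_that("depth encoding: mid-depth point gets the midpoint gray, near beats far", {
  cfg <- render_config()
  # three isolated points at depths 0 / 5 / 10: gray 0 / 100 / 200
  pc <- point_cloud(matrix(c(-5, 0, 0,
                              0, 5, 5,
                              5, 10, 10), 3, byrow = TRUE))
  img <- render_view(pc, cfg)
  px <- tlsimage:::project_pixels(pc, cfg)
  expect_equal(img[px$row[1], px$col[1]], 0L)
  expect_equal(img[px$row[2], px$col[2]], 100L)
  expect_equal(img[px$row[3], px$col[3]], 200L)

  # coincident (x, z), near and far depth: the nearer (darker) point wins
  pc2 <- point_cloud(matrix(c(0, 0, 0, 0, 9, 0, 3, 4.5, 3), 3, byrow = TRUE))
  img2 <- render_view(pc2, cfg)
  px2 <- tlsimage:::project_pixels(pc2, cfg)
  expect_equal(img2[px2$row[1], px2$col[1]], cfg$gray_near)

  # degenerate depth range: everything at gray_near
  flat <- point_cloud(cbind(seq(0, 1, length.out = 20), 1, seq(0, 2, length.out = 20)))
  imgf <- render_view(flat, cfg)
  expect_setequal(unique(as.integer(imgf)), c(cfg$background, cfg$gray_near))
})

test_that("gray level increases strictly with depth for isolated points", {
  cfg <- render_config()
  ys <- c(0.3, 1.7, 2.9, 4.1, 5.6, 7.2, 8.8, 9.6)
  pc <- point_cloud(cbind(seq(-7, 7, length.out = 8), ys, seq(0, 10, length.out = 8)))
  img <- render_view(pc, cfg)
  px <- tlsimage:::project_pixels(pc, cfg)
  grays <- img[cbind(px$row, px$col)]
  expect_true(all(diff(grays) > 0))
})

test_that("fast renderer matches the brute-force minimum-depth rasterizer", {
  cfg <- render_config()
  for (s in 1:6) {
    pc <- random_cloud(sample(3:150, 1), seed = 100 + s)
    expect_identical(pixels(render_view(pc, cfg)), brute_render(pc, cfg),
                     label = sprintf("seed %d", 100 + s))
  }
  # larger marker radius exercises disc clipping at borders
  cfg3 <- render_config(marker_radius_px = 3)
  pc <- random_cloud(40, seed = 11)
  expect_identical(pixels(render_view(pc, cfg3)), brute_render(pc, cfg3))
})

test_that("generate_views is seeded, evenly spaced, and covers rotations", {
  pc <- random_cloud(4000, seed = 6)
  v1 <- generate_views(pc, subsample_n = 3000, seed = 3)
  v2 <- generate_views(pc, subsample_n = 3000, seed = 3)
  expect_length(v1, 10)
  expect_identical(lapply(v1, unclass), lapply(v2, unclass))
  expect_equal(vapply(v1, function(i) attr(i, "view_index"), 0L), 0:9)

  single <- generate_views(pc, render_config(n_views = 1), subsample_n = 3000, seed = 3)
  expect_length(single, 1)

  # a non-symmetric cloud looks different after a 36-degree offset
  tri <- point_cloud(matrix(c(0, 0, 0, 3, 0, 5, 0, 1, 9), 3, byrow = TRUE))
  expect_false(identical(unclass(render_view(tri)),
                         unclass(render_view(rotate_z(tri, 36)))))
})

test_that("PNG round-trip preserves pixels and provenance filenames", {
  img <- render_view(random_cloud(500, seed = 8, id = "oak_7"), view_index = 3L)
  f <- file.path(withr::local_tempdir(), "oak_7_v3.png")
  write_image(img, f)
  back <- read_image(f)
  expect_identical(unclass(back), unclass(img))
  expect_equal(attr(back, "tree_id"), "oak_7")
  expect_equal(attr(back, "view_index"), 3L)
})
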