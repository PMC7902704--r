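# shared fixtures and independent oracles

# small deterministic cloud: n points scattered in a box
random_cloud <- function(n, seed, id = "t", xr = c(-2, 2), yr = c(-2, 2), zr = c(0, 10)) {
  withr::with_seed(seed, {
    point_cloud(cbind(runif(n, xr[1], xr[2]),
                      runif(n, yr[1], yr[2]),
                      runif(n, zr[1], zr[2])), id)
  })
}

pairwise_dists <- function(cloud) as.vector(dist(unclass(cloud)))

# bare pixel matrix of a gray_image (provenance attributes stripped)
pixels <- function(img) {
  m <- unclass(img)
  attributes(m) <- list(dim = dim(m))
  m
}

# Brute-force reference rasterizer: for every pixel, scan all points, keep
# the minimum-depth disc cover. Written independently of render_view (per
# pixel instead of painter's order).
brute_render <- function(cloud, cfg) {
  x <- cloud[, 1]; y <- cloud[, 2]; z <- cloud[, 3]
  dx <- max(diff(range(x)), 1e-12); dz <- max(diff(range(z)), 1e-12)
  scale <- min(cfg$width_px * (1 - 2 * cfg$margin_frac) / dx,
               cfg$height_px * (1 - 2 * cfg$margin_frac) / dz)
  pc <- round((cfg$width_px + 1) / 2 + (x - mean(range(x))) * scale)
  pr <- round((cfg$height_px + 1) / 2 - (z - mean(range(z))) * scale)
  yrng <- range(y)
  gray_of <- function(yy) {
    if (diff(yrng) <= 0) return(cfg$gray_near)
    as.integer(round(cfg$gray_near + (yy - yrng[1]) / diff(yrng) *
                       (cfg$gray_far - cfg$gray_near)))
  }
  r2 <- (cfg$marker_radius_px + 0.5)^2
  img <- matrix(cfg$background, cfg$height_px, cfg$width_px)
  for (row in seq_len(cfg$height_px)) {
    for (col in seq_len(cfg$width_px)) {
      covers <- which((row - pr)^2 + (col - pc)^2 <= r2)
      if (length(covers)) img[row, col] <- gray_of(min(y[covers]))
    }
  }
  img
}

# independent layer-shape/parameter arithmetic for the CNN
oracle_param_count <- function(input, filters = c(8, 16, 32, 64), k = 3,
                               dense = 128, classes = 7, pool = 2, stride = 2) {
  h <- input[1]; w <- input[2]; cin <- input[3]
  total <- 0
  for (f in filters) {
    total <- total + (k * k * cin + 1) * f
    h <- floor((h - pool) / stride) + 1
    w <- floor((w - pool) / stride) + 1
    cin <- f
  }
  total <- total + (h * w * cin + 1) * dense
  total + (dense + 1) * classes
}

# tiny, trivially separable two-class image set for training sanity checks:
# class 0 = dark left half, class 1 = dark right half, plus pixel jitter
toy_image_set <- function(n_per_class = 10, size = 32, seed = 1) {
  withr::with_seed(seed, {
    imgs <- list(); lab <- character(0)
    for (i in seq_len(2 * n_per_class)) {
      cls <- (i - 1) %% 2
      m <- matrix(230L, size, size)
      if (cls == 0) m[, 1:(size / 2)] <- 30L else m[, (size / 2 + 1):size] <- 30L
      m <- m + matrix(sample(-10:10, size * size, TRUE), size, size)
      m <- pmin(pmax(m, 0L), 255L)
      imgs[[i]] <- gray_image(m, tree_id = paste0("toy", i))
      lab <- c(lab, paste0("c", cls))
    }
    image_index(imgs, species = lab)
  })
}

# a small rendered study reused by several tests
small_study <- function(trees = 4, points = 3000, seed = 42) {
  generate_study(list(
    conifer = list(params = archetype_params("conifer", points_total = points), n_trees = trees),
    broadleaf = list(params = archetype_params("broadleaf", points_total = points), n_trees = trees)
  ), seed = seed)
}
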