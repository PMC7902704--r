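#' Morphological archetype for the procedural tree generator
#'
#' Parameterises a procedural single-tree point-cloud model that emulates
#' what a multi-scan TLS campaign delivers for an adult forest tree: a tall
#' tapered trunk densely sampled near the ground (point density falls off
#' with height, as the scanner sees the lower trunk from every position),
#' first-order branches, and a crown envelope. Three archetypes are built
#' in: `conifer` (narrow conical crown, regular whorls of near-horizontal
#' branches), `broadleaf` (wide ellipsoidal crown, irregular upswept
#' branches) and `intermediate` (between the two, for three-class designs).
#'
#' @param archetype one of `"conifer"`, `"broadleaf"`, `"intermediate"`.
#' @param height_range tree height range (m) sampled per tree.
#' @param trunk_taper fractional radius loss from base to tip.
#' @param crown_base_frac fraction of tree height where the crown starts.
#' @param crown_width_ratio crown width divided by tree height.
#' @param branch_count_range number of first-order branches.
#' @param branch_angle_range_deg branch insertion angle from vertical
#'   (degrees; > 90 droops below horizontal).
#' @param whorled regular whorls (conifer habit) vs irregular insertion.
#' @param points_total points per cloud (>= 100).
#' @param noise_sigma_m Gaussian measurement noise (m).
#' @param vertical_density_gradient decay rate of trunk point density with
#'   relative height (0 = uniform; larger = more ground-heavy).
#' @param trunk_point_frac fraction of points on the trunk.
#' @param label species label recorded for generated trees; defaults to the
#'   archetype name.
#' @return An `archetype_params` object (validated list).
#' @export
archetype_params <- function(archetype = c("conifer", "broadleaf", "intermediate"),
                             height_range = NULL, trunk_taper = 0.7,
                             crown_base_frac = NULL, crown_width_ratio = NULL,
                             branch_count_range = NULL, branch_angle_range_deg = NULL,
                             whorled = NULL, points_total = 10000L,
                             noise_sigma_m = 0.02, vertical_density_gradient = 5,
                             trunk_point_frac = 0.5, label = NULL) {
  archetype <- match.arg(archetype)
  def <- switch(archetype,
    conifer = list(height_range = c(25, 35), crown_base_frac = 0.15,
                   crown_width_ratio = 0.25, branch_count_range = c(40L, 60L),
                   branch_angle_range_deg = c(75, 100), whorled = TRUE),
    broadleaf = list(height_range = c(22, 32), crown_base_frac = 0.35,
                     crown_width_ratio = 0.6, branch_count_range = c(15L, 30L),
                     branch_angle_range_deg = c(25, 60), whorled = FALSE),
    intermediate = list(height_range = c(23, 33), crown_base_frac = 0.25,
                        crown_width_ratio = 0.42, branch_count_range = c(25L, 45L),
                        branch_angle_range_deg = c(45, 80), whorled = FALSE)
  )
  p <- list(
    archetype = archetype,
    height_range = as.numeric(height_range %||% def$height_range),
    trunk_taper = as.numeric(trunk_taper),
    crown_base_frac = as.numeric(crown_base_frac %||% def$crown_base_frac),
    crown_width_ratio = as.numeric(crown_width_ratio %||% def$crown_width_ratio),
    branch_count_range = as.integer(branch_count_range %||% def$branch_count_range),
    branch_angle_range_deg = as.numeric(branch_angle_range_deg %||% def$branch_angle_range_deg),
    whorled = isTRUE(whorled %||% def$whorled),
    points_total = as.integer(points_total),
    noise_sigma_m = as.numeric(noise_sigma_m),
    vertical_density_gradient = as.numeric(vertical_density_gradient),
    trunk_point_frac = as.numeric(trunk_point_frac),
    label = label %||% archetype
  )
  if (length(p$height_range) != 2 || any(p$height_range <= 0) ||
      p$height_range[1] > p$height_range[2]) {
    abort("`height_range` must be a positive increasing pair.")
  }
  if (p$crown_base_frac <= 0 || p$crown_base_frac >= 1) abort("`crown_base_frac` must be in (0, 1).")
  if (p$points_total < 100L) abort("`points_total` must be >= 100.")
  if (p$vertical_density_gradient < 0) abort("`vertical_density_gradient` must be >= 0.")
  if (p$trunk_point_frac <= 0 || p$trunk_point_frac >= 1) abort("`trunk_point_frac` must be in (0, 1).")
  if (p$noise_sigma_m < 0) abort("`noise_sigma_m` must be >= 0.")
  structure(p, class = "archetype_params")
}

# heights with density ~ exp(-g * z/h): ground-heavy, like multi-scan TLS
sample_heights <- function(n, h, g) {
  u <- runif(n)
  if (g <= 0) return(u * h)
  -log(1 - u * (1 - exp(-g))) / g * h
}

# crown envelope radius at height z
envelope_radius <- function(z, h, base, radius, archetype) {
  zc <- pmax(pmin(z, h), base)
  if (archetype == "conifer") {
    radius * (h - zc) / (h - base)
  } else {
    c0 <- (base + h) / 2
    sem <- (h - base) / 2
    radius * sqrt(pmax(0, 1 - ((zc - c0) / sem)^2))
  }
}

#' Generate one synthetic tree point cloud
#'
#' Builds a cloud of exactly `points_total` points: a tapered trunk sampled
#' with the configured downward density gradient, straight noisy branch
#' segments from the trunk to the crown envelope (regular whorls for the
#' conifer habit, irregular insertions otherwise), and a surface-biased
#' crown envelope (cone for conifer, ellipsoid otherwise). Fully
#' reproducible per seed.
#'
#' @param params an [archetype_params()].
#' @param seed integer seed.
#' @param tree_id identifier for the generated tree.
#' @return A list with `cloud` (a [point_cloud()]) and `species` (the
#'   params label).
#' @export
generate_tree <- function(params, seed = 1L, tree_id = "synth") {
  stopifnot(inherits(params, "archetype_params"))
  with_seed_(seed, {
    h <- runif(1, params$height_range[1], params$height_range[2])
    crown_base <- params$crown_base_frac * h
    crown_radius <- params$crown_width_ratio * h / 2
    n <- params$points_total
    n_trunk <- round(params$trunk_point_frac * n)
    n_branch <- round(0.2 * n)
    n_crown <- n - n_trunk - n_branch

    # trunk: noisy circular cross-sections of a tapered cylinder
    zt <- sample_heights(n_trunk, h, params$vertical_density_gradient)
    r0 <- h / 100
    rt <- r0 * (1 - params$trunk_taper * zt / h)
    th <- runif(n_trunk, 0, 2 * pi)
    trunk <- cbind(rt * cos(th), rt * sin(th), zt)

    # branches: straight segments from the trunk to the crown envelope
    nb <- sample(params$branch_count_range[1]:params$branch_count_range[2], 1)
    if (params$whorled) {
      n_whorl <- as.integer(ceiling(nb / 5))
      zb_w <- seq(crown_base, 0.95 * h, length.out = n_whorl)
      zb <- rep(zb_w, each = 5L)[seq_len(nb)]
      az <- (rep(seq(0, 2 * pi, length.out = 6)[-6], length.out = nb) +
               rep(runif(ceiling(nb / 5), 0, 2 * pi), each = 5L)[seq_len(nb)])
    } else {
      zb <- runif(nb, crown_base, 0.95 * h)
      az <- runif(nb, 0, 2 * pi)
    }
    alpha <- runif(nb, params$branch_angle_range_deg[1], params$branch_angle_range_deg[2]) * pi / 180
    # branch length to the crown envelope along the branch direction, so
    # branch tips never pierce the crown surface
    if (params$archetype == "conifer") {
      slope <- crown_radius / (h - crown_base)
      reach <- envelope_radius(zb, h, crown_base, crown_radius, params$archetype)
      len <- reach / pmax(sin(alpha) + slope * cos(alpha), 0.2)
    } else {
      c0 <- (crown_base + h) / 2
      sem <- (h - crown_base) / 2
      A <- (sin(alpha) / crown_radius)^2 + (cos(alpha) / sem)^2
      B <- 2 * cos(alpha) * (zb - c0) / sem^2
      C <- ((zb - c0) / sem)^2 - 1
      len <- (-B + sqrt(pmax(B^2 - 4 * A * C, 0))) / (2 * A)
    }
    len <- pmax(len, 0.05 * crown_radius)
    bi <- sample.int(nb, n_branch, replace = TRUE, prob = len / sum(len))
    t <- runif(n_branch)
    branch <- cbind(t * len[bi] * sin(alpha[bi]) * cos(az[bi]),
                    t * len[bi] * sin(alpha[bi]) * sin(az[bi]),
                    zb[bi] + t * len[bi] * cos(alpha[bi]))

    # crown: surface-biased points within the envelope
    if (params$archetype == "conifer") {
      zc <- runif(n_crown, crown_base, h)
      rr <- envelope_radius(zc, h, crown_base, crown_radius, params$archetype) *
        runif(n_crown)^0.25
      thc <- runif(n_crown, 0, 2 * pi)
      crown <- cbind(rr * cos(thc), rr * sin(thc), zc)
    } else {
      dir <- matrix(rnorm(3 * n_crown), ncol = 3)
      dir <- dir / sqrt(rowSums(dir^2))
      sfac <- runif(n_crown)^0.25
      c0 <- (crown_base + h) / 2
      sem <- (h - crown_base) / 2
      crown <- cbind(sfac * crown_radius * dir[, 1],
                     sfac * crown_radius * dir[, 2],
                     c0 + sfac * sem * dir[, 3])
    }

    pts <- rbind(trunk, branch, crown)
    pts <- pts + matrix(rnorm(length(pts), 0, params$noise_sigma_m), ncol = 3)
    pts[, 3] <- pts[, 3] - min(pts[, 3])
    list(cloud = point_cloud(pts, tree_id), species = params$label)
  })
}

#' Generate a labelled multi-species study
#'
#' Produces `n_trees` clouds per species (parameters jittered per tree) and
#' the accompanying manifest, in exactly the formats the readers consume.
#' With `dir` set, xyz files and a `manifest.csv` are written; otherwise the
#' clouds stay in memory as a list column.
#'
#' @param per_species named list: species -> list with elements `params`
#'   (an [archetype_params()]) and `n_trees`.
#' @param seed integer master seed.
#' @param dir optional output directory for xyz files + manifest.
#' @param jitter_frac relative jitter applied per tree to crown shape
#'   parameters.
#' @return Tibble with `tree_id`, `species`, `cloud` (list column) and
#'   `cloud_path` (`NA` unless written).
#' @examples
#' st <- generate_study(list(
#'   conifer = list(params = archetype_params("conifer", points_total = 2000), n_trees = 2),
#'   broadleaf = list(params = archetype_params("broadleaf", points_total = 2000), n_trees = 2)
#' ), seed = 7)
#' st
#' @export
generate_study <- function(per_species, seed = 1L, dir = NULL, jitter_frac = 0.1) {
  if (length(per_species) < 2 || is.null(names(per_species))) {
    abort("`per_species` must be a named list covering at least two species.")
  }
  total <- sum(vapply(per_species, function(s) as.integer(s$n_trees), 0L))
  seeds <- derive_seeds(seed, 2L * total)
  rows <- vector("list", total)
  i <- 0L
  for (sp in names(per_species)) {
    spec <- per_species[[sp]]
    stopifnot(inherits(spec$params, "archetype_params"), spec$n_trees >= 1)
    for (j in seq_len(spec$n_trees)) {
      i <- i + 1L
      p <- spec$params
      p$label <- sp
      jit <- with_seed_(seeds[2L * i - 1L], runif(3, 1 - jitter_frac, 1 + jitter_frac))
      p$crown_width_ratio <- p$crown_width_ratio * jit[1]
      p$crown_base_frac <- min(0.9, p$crown_base_frac * jit[2])
      p$trunk_taper <- min(0.95, p$trunk_taper * jit[3])
      id <- sprintf("%s_%03d", sp, j)
      g <- generate_tree(p, seed = seeds[2L * i], tree_id = id)
      rows[[i]] <- tibble(tree_id = id, species = sp,
                          cloud = list(g$cloud), cloud_path = NA_character_)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$cloud_path <- file.path(dir, paste0(out$tree_id, ".xyz"))
    purrr::walk2(out$cloud, out$cloud_path, write_xyz)
    write_manifest(out, file.path(dir, "manifest.csv"))
  }
  out
}
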