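#' Generate a synthetic landscape of rasters and zones
#'
#' Builds the gridded inputs of the regional-scaling and fragmentation
#' analyses as plain matrices sharing one shape: a patchy categorical
#' land-cover grid (seeded nearest-seed patch growth), a forest-type grid
#' over the eight groups, a canopy-cover percent grid consistent with land
#' cover (forest pixels high, non-forest low), four smooth abiotic
#' covariate fields (low-frequency smoothed noise, limitation indices
#' bounded in `[0, 1]`), and a rectangular-tile zone map with biome and
#' continent labels.
#'
#' @param cfg An [edge_scenario()] (supplies the seed and covariate
#'   bounds).
#' @param nrow,ncol Grid dimensions (at least 3 x 3).
#' @param n_zones Approximate number of zones (rectangular tiles).
#' @param pixel_size_m Pixel edge length in metres (30 m default, i.e.
#'   0.09 ha pixels).
#' @param p_classes Named class probabilities for the land-cover patches.
#' @return An object of class `edge_landscape`: list of matrices
#'   `land_cover` (character), `forest_type` (character, `NA` off-forest),
#'   `canopy` (percent), `covariates` (named list of four matrices),
#'   `zones` (integer zone ids), a `zone_info` tibble (`zone`, `biome`,
#'   `continent`), and `pixel_size_m`.
#' @export
generate_landscape <- function(cfg, nrow = 60, ncol = 60, n_zones = 9,
                               pixel_size_m = 30,
                               p_classes = c(forest = 0.6, developed = 0.14,
                                             cultivated = 0.12, water = 0.06,
                                             other = 0.08)) {
  if (nrow < 3 || ncol < 3) stop_ef("landscape grid must be at least 3 x 3")
  ss <- function(stream) substream_seed(cfg$seed, stream)
  cells <- expand.grid(row = seq_len(nrow), col = seq_len(ncol))

  nearest_seed_field <- function(n_seeds, labels, probs, stream) {
    set.seed(ss(stream))
    sr <- stats::runif(n_seeds, 1, nrow)
    sc <- stats::runif(n_seeds, 1, ncol)
    lab <- sample(labels, n_seeds, replace = TRUE, prob = probs)
    d <- outer(cells$row, sr, "-")^2 + outer(cells$col, sc, "-")^2
    matrix(lab[max.col(-d, ties.method = "first")], nrow, ncol)
  }

  n_seeds <- max(8, round(nrow * ncol / 90))
  land_cover <- nearest_seed_field(n_seeds, names(p_classes), p_classes,
                                   "lc_seeds")
  forest_type <- nearest_seed_field(
    max(8, round(n_seeds / 2)), cfg$type_effects$forest_type_group,
    cfg$type_effects$weight, "ft_seeds")
  forest_type[land_cover != "forest"] <- NA_character_

  set.seed(ss("canopy"))
  canopy <- matrix(0, nrow, ncol)
  is_forest <- land_cover == "forest"
  canopy[is_forest] <- clamp(stats::rnorm(sum(is_forest), 80, 18), 11, 100)
  nonf <- land_cover %in% c("developed", "cultivated", "other")
  canopy[nonf] <- clamp(abs(stats::rnorm(sum(nonf), 2, 3)), 0, 9)

  smooth_field <- function(stream, lo, hi) {
    set.seed(ss(stream))
    f <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
    for (i in 1:6) f <- box_blur(f)
    rng <- range(f)
    lo + (f - rng[1]) / max(rng[2] - rng[1], 1e-12) * (hi - lo)
  }
  covs <- list(
    light_limit = smooth_field("cov_light", 0.05, 0.95),
    water_limit = smooth_field("cov_water", 0.05, 0.95),
    temp_limit = smooth_field("cov_temp", 0.05, 0.95),
    n_dep = smooth_field("cov_ndep", 0.5, 12)
  )

  zx <- max(1, round(sqrt(n_zones)))
  zy <- max(1, ceiling(n_zones / zx))
  zr <- pmin(ceiling(seq_len(nrow) / (nrow / zx)), zx)
  zc <- pmin(ceiling(seq_len(ncol) / (ncol / zy)), zy)
  zones <- matrix(0L, nrow, ncol)
  for (i in seq_len(nrow)) zones[i, ] <- (zr[i] - 1L) * zy + zc
  ids <- sort(unique(as.vector(zones)))
  zone_info <- tibble::tibble(
    zone = ids,
    biome = rep(c("temperate", "tropical"), length.out = length(ids)),
    continent = rep(c("North America", "Europe", "Asia", "South America",
                      "Africa"), length.out = length(ids))
  )

  structure(list(land_cover = land_cover, forest_type = forest_type,
                 canopy = canopy, covariates = covs, zones = zones,
                 zone_info = zone_info, pixel_size_m = pixel_size_m),
            class = "edge_landscape")
}

# one pass of a 3x3 box blur with edge replication
box_blur <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  acc <- matrix(0, nr, nc)
  for (dr in 0:2) for (dc in 0:2) {
    acc <- acc + pad[dr + seq_len(nr), dc + seq_len(nc)]
  }
  acc / 9
}

#' @export
print.edge_landscape <- function(x, ...) {
  cat("<edge_landscape>", nrow(x$land_cover), "x", ncol(x$land_cover),
      "pixels,", nrow(x$zone_info), "zones, pixel", x$pixel_size_m, "m\n")
  print(round(prop.table(table(x$land_cover)), 3))
  invisible(x)
}

#' Write landscape grids as CSV matrices and zones as JSON
#'
#' Plain-text serialization: each raster becomes a headerless CSV of cell
#' values; zone attributes go to a JSON file.
#'
#' @param ls An `edge_landscape`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(ls, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, name) {
    utils::write.table(m, file.path(dir, paste0(name, ".csv")), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  wm(ls$land_cover, "land_cover")
  wm(ls$forest_type, "forest_type")
  wm(ls$canopy, "canopy")
  for (v in names(ls$covariates)) wm(ls$covariates[[v]], paste0("cov_", v))
  wm(ls$zones, "zones")
  jsonlite::write_json(list(zone_info = ls$zone_info,
                            pixel_size_m = ls$pixel_size_m),
                       file.path(dir, "zone_info.json"), digits = NA)
  invisible(dir)
}
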