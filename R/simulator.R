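#' Angular sampling pattern of a simulated scan
#'
#' Pulses are emitted on a regular zenith x azimuth grid. The default grid
#' (zenith 0-90 deg in 1.5-deg rows, azimuth 0-357.5 deg in 2.5-deg columns,
#' 8784 pulses) is a desk-scale stand-in for the ~10^5-10^6 pulses of a real
#' scan; it includes a row at the optical plane (zenith 90) and fully covers
#' the 0-30 and 30-35 deg bands used by the metaproperties.
#'
#' @param zenith_start,zenith_stop,zenith_step Zenith grid in degrees.
#' @param azimuth_start,azimuth_stop,azimuth_step Azimuth grid in degrees.
#'
#' @return An object of class `scan_pattern`.
#' @export
scan_pattern <- function(zenith_start = 0, zenith_stop = 90, zenith_step = 1.5,
                         azimuth_start = 0, azimuth_stop = 357.5,
                         azimuth_step = 2.5) {
  check_number(zenith_step, "zenith_step", min = 1e-9)
  check_number(azimuth_step, "azimuth_step", min = 1e-9)
  check_number(zenith_start, "zenith_start", min = 0, max = 180)
  check_number(zenith_stop, "zenith_stop", min = 0, max = 180)
  if (zenith_stop < zenith_start) stop_validation("zenith grid is inverted")
  zen <- seq(zenith_start, zenith_stop, by = zenith_step)
  az <- seq(azimuth_start, azimuth_stop, by = azimuth_step)
  az <- az[az < 360]
  if (length(zen) * length(az) < 1) stop_validation("empty scan pattern")
  structure(list(zenith_deg = zen, azimuth_deg = az), class = "scan_pattern")
}

pattern_grid <- function(pattern) {
  g <- expand.grid(azimuth_deg = pattern$azimuth_deg,
                   zenith_deg = pattern$zenith_deg,
                   KEEP.OUT.ATTRS = FALSE)
  tibble::tibble(
    pulse_id = sprintf("p%06d", seq_len(nrow(g))),
    zenith_deg = g$zenith_deg,
    azimuth_deg = g$azimuth_deg
  )
}

#' Scene descriptions for the scan simulator
#'
#' `room_scene()` is an axis-aligned box (an enclosed room: continuous hard
#' ceiling, walls and floor) around the sensor; every pulse hits a surface,
#' second returns arise only rarely at edges, and reflectance is high.
#' `forest_scene()` is a statistical stand: skyward pulses escape through
#' canopy gaps with probability `canopy_gap_prob`; otherwise the first
#' interception is a trunk, an exponential free path through the understory
#' layer, or the canopy itself; fragmentation yields frequent second returns
#' and lower reflectance. Range noise (default sd 0.05 m, i.e. the +/-50 mm
#' class of ranging error of compact scanners) applies to every return.
#'
#' @param half_width_x,half_width_y Room half-extent in metres.
#' @param ceiling_height Ceiling height above the optical centre, metres.
#' @param floor_depth Floor depth below the optical centre, metres.
#' @param reflectance_mean,reflectance_sd Gaussian intensity model, clipped
#'   to `[0, 1]`.
#' @param range_noise_sd_m Ranging noise standard deviation, metres.
#' @param second_return_prob Probability a pulse with a first return also
#'   records a second (edge/partial interceptions).
#' @param seed Default RNG seed for generation from this scene.
#'
#' @return A `room_scene` or `forest_scene` object.
#' @export
room_scene <- function(half_width_x = 5, half_width_y = 4, ceiling_height = 3,
                       floor_depth = 1.3, reflectance_mean = 0.8,
                       reflectance_sd = 0.05, range_noise_sd_m = 0.05,
                       second_return_prob = 0.01, seed = 1L) {
  for (nm in c("half_width_x", "half_width_y", "ceiling_height", "floor_depth")) {
    check_number(get(nm), nm, min = 1e-6)
  }
  check_number(reflectance_mean, "reflectance_mean", min = 0, max = 1)
  check_number(reflectance_sd, "reflectance_sd", min = 0)
  check_number(range_noise_sd_m, "range_noise_sd_m", min = 0)
  check_number(second_return_prob, "second_return_prob", min = 0, max = 1)
  structure(list(half_width_x = half_width_x, half_width_y = half_width_y,
                 ceiling_height = ceiling_height, floor_depth = floor_depth,
                 reflectance_mean = reflectance_mean,
                 reflectance_sd = reflectance_sd,
                 range_noise_sd_m = range_noise_sd_m,
                 second_return_prob = second_return_prob,
                 seed = seed),
            class = c("room_scene", "scene_config"))
}

#' @rdname room_scene
#' @param canopy_base_height,canopy_top_height Canopy layer bounds above the
#'   sensor, metres.
#' @param canopy_gap_prob Probability a skyward pulse escapes through a gap
#'   (producing no return at all).
#' @param understory_density Mean interceptors per metre of path in the
#'   understory layer (exponential free path rate).
#' @param trunk_count,trunk_radius,stand_radius Trunk cylinders scattered in
#'   an annulus between 2 m and `stand_radius`, metres.
#' @param max_range_clip Interceptions beyond this range become no-returns.
#' @export
forest_scene <- function(canopy_base_height = 8, canopy_top_height = 20,
                         canopy_gap_prob = 0.25, understory_density = 0.05,
                         trunk_count = 15L, trunk_radius = 0.25,
                         stand_radius = 30, second_return_prob = 0.25,
                         reflectance_mean = 0.45, reflectance_sd = 0.1,
                         range_noise_sd_m = 0.05, max_range_clip = 40,
                         seed = 1L) {
  check_number(canopy_base_height, "canopy_base_height", min = 1e-6)
  check_number(canopy_top_height, "canopy_top_height", min = canopy_base_height)
  check_number(canopy_gap_prob, "canopy_gap_prob", min = 0, max = 1)
  check_number(understory_density, "understory_density", min = 0)
  check_number(second_return_prob, "second_return_prob", min = 0, max = 1)
  check_number(reflectance_mean, "reflectance_mean", min = 0, max = 1)
  check_number(max_range_clip, "max_range_clip", min = 1e-6)
  structure(list(canopy_base_height = canopy_base_height,
                 canopy_top_height = canopy_top_height,
                 canopy_gap_prob = canopy_gap_prob,
                 understory_density = understory_density,
                 trunk_count = as.integer(trunk_count),
                 trunk_radius = trunk_radius, stand_radius = stand_radius,
                 second_return_prob = second_return_prob,
                 reflectance_mean = reflectance_mean,
                 reflectance_sd = reflectance_sd,
                 range_noise_sd_m = range_noise_sd_m,
                 max_range_clip = max_range_clip, seed = seed),
            class = c("forest_scene", "scene_config"))
}

unit_directions <- function(zenith_deg, azimuth_deg) {
  zen <- zenith_deg * pi / 180
  az <- azimuth_deg * pi / 180
  list(dx = sin(zen) * cos(az), dy = sin(zen) * sin(az), dz = cos(zen))
}

clip01 <- function(x) pmin(1, pmax(0, x))

sample_intensity <- function(n, scene) {
  clip01(rnorm(n, scene$reflectance_mean, scene$reflectance_sd))
}

# Assemble a long-format scan from per-pulse first/second distances.
assemble_scan <- function(grid, d1, d2, i1, i2, scan_id, instrument, label,
                          metadata) {
  max_r <- instrument$max_range_m
  d1 <- ifelse(!is.na(d1) & d1 > max_r, NA_real_, d1)
  d2 <- ifelse(is.na(d1) | (!is.na(d2) & d2 > max_r), NA_real_, d2)
  has1 <- !is.na(d1)
  has2 <- has1 & !is.na(d2)
  rows <- dplyr::bind_rows(
    dplyr::mutate(grid[!has1, ], return_index = 0L,
                  distance_m = NA_real_, intensity = NA_real_),
    dplyr::mutate(grid[has1, ], return_index = 1L,
                  distance_m = d1[has1], intensity = i1[has1]),
    dplyr::mutate(grid[has2, ], return_index = 2L,
                  distance_m = d2[has2], intensity = i2[has2])
  )
  rows <- rows[order(rows$pulse_id, rows$return_index), ]
  tls_scan(rows, scan_id = scan_id, instrument = instrument, label = label,
           metadata = metadata, validate = FALSE)
}

#' Generate a synthetic room scan
#'
#' Casts each pulse of the pattern from the sensor (inside the box) to the
#' nearest wall/ceiling/floor plane, adds Gaussian range noise, and samples
#' intensities from the scene's reflectance model. Identical seeds give
#' identical scans.
#'
#' @param pattern A [scan_pattern()].
#' @param scene A [room_scene()] or [forest_scene()].
#' @param instrument An [instrument_spec()].
#' @param scan_id Identifier for the resulting scan.
#' @param label Optional class label.
#' @param seed RNG seed; defaults to `scene$seed`.
#'
#' @return A [tls_scan()].
#' @export
#'
#' @examples
#' scan <- generate_room_scan(scan_pattern(zenith_step = 15, azimuth_step = 45),
#'                            room_scene(seed = 42))
#' no_return_ratio(scan)  # rooms have a continuous ceiling: 0
generate_room_scan <- function(pattern, scene = room_scene(),
                               instrument = instrument_spec(),
                               scan_id = "room", label = NA,
                               seed = scene$seed) {
  if (!inherits(scene, "room_scene")) stop_validation("`scene` must be a room_scene")
  grid <- pattern_grid(pattern)
  dir <- unit_directions(grid$zenith_deg, grid$azimuth_deg)
  d_true <- ray_box_exit(dir, scene)
  set.seed(seed)
  n <- nrow(grid)
  d1 <- pmax(1e-6, d_true + rnorm(n, 0, scene$range_noise_sd_m))
  second <- runif(n) < scene$second_return_prob
  d2 <- ifelse(second, d1 + runif(n, 0.1, 0.5), NA_real_)
  i1 <- sample_intensity(n, scene)
  i2 <- ifelse(second, clip01(i1 * runif(n, 0.2, 0.6)), NA_real_)
  assemble_scan(grid, d1, d2, i1, i2, scan_id, instrument, label,
                metadata = list(scene = "room", seed = seed))
}

# Distance from the origin to the box boundary along each direction.
# The sensor sits inside the box, so the exit parameter is the smallest
# positive boundary crossing over the three axes.
ray_box_exit <- function(dir, scene) {
  cross <- function(d, lo, hi) {
    t <- rep(Inf, length(d))
    pos <- d > 1e-15
    neg <- d < -1e-15
    t[pos] <- hi / d[pos]
    t[neg] <- lo / d[neg]
    t
  }
  tx <- cross(dir$dx, -scene$half_width_x, scene$half_width_x)
  ty <- cross(dir$dy, -scene$half_width_y, scene$half_width_y)
  tz <- cross(dir$dz, -scene$floor_depth, scene$ceiling_height)
  pmin(tx, ty, tz)
}

#' Generate a synthetic forest scan
#'
#' Skyward pulses escape through canopy gaps with probability
#' `canopy_gap_prob` and record nothing. Intercepted pulses take the nearest
#' of: a trunk cylinder hit, an exponential free path through the understory
#' layer, or the canopy layer itself (a uniformly drawn surface height
#' within the canopy slab). Interceptions beyond `max_range_clip` are
#' dropped as no-returns. Fragmented vegetation yields second returns with
#' probability `second_return_prob` a short exponential distance beyond the
#' first.
#'
#' @inheritParams generate_room_scan
#' @export
#'
#' @examples
#' scan <- generate_forest_scan(scan_pattern(zenith_step = 15, azimuth_step = 45),
#'                              forest_scene(seed = 42))
generate_forest_scan <- function(pattern, scene = forest_scene(),
                                 instrument = instrument_spec(),
                                 scan_id = "forest", label = NA,
                                 seed = scene$seed) {
  if (!inherits(scene, "forest_scene")) stop_validation("`scene` must be a forest_scene")
  grid <- pattern_grid(pattern)
  dir <- unit_directions(grid$zenith_deg, grid$azimuth_deg)
  n <- nrow(grid)
  set.seed(seed)

  # trunk field: uniform in an annulus so no trunk swallows the sensor
  k <- scene$trunk_count
  trunk_r <- sqrt(runif(k, (2 / scene$stand_radius)^2, 1)) * scene$stand_radius
  trunk_a <- runif(k, 0, 2 * pi)
  cx <- trunk_r * cos(trunk_a)
  cy <- trunk_r * sin(trunk_a)

  upward <- dir$dz > 1e-12
  gap <- upward & (runif(n) < scene$canopy_gap_prob)

  t_trunk <- ray_trunk_hit(dir, cx, cy, scene)
  t_under <- understory_path(dir, scene, n)
  t_canopy <- rep(Inf, n)
  h_surface <- runif(n, scene$canopy_base_height, scene$canopy_top_height)
  t_canopy[upward] <- h_surface[upward] / dir$dz[upward]
  # non-upward rays (the optical plane row) never reach the canopy slab

  d_true <- pmin(t_trunk, t_under, t_canopy)
  d_true[gap] <- Inf
  d_true[d_true > scene$max_range_clip] <- Inf

  hit <- is.finite(d_true)
  d1 <- rep(NA_real_, n)
  d1[hit] <- pmax(1e-6, d_true[hit] + rnorm(sum(hit), 0, scene$range_noise_sd_m))
  second <- hit & (runif(n) < scene$second_return_prob)
  d2 <- rep(NA_real_, n)
  d2[second] <- d1[second] + rexp(sum(second), rate = 1) + 0.1
  d2[!is.na(d2) & d2 > scene$max_range_clip] <- NA_real_
  i1 <- ifelse(hit, sample_intensity(n, scene), NA_real_)
  i2 <- ifelse(!is.na(d2), clip01(i1 * runif(n, 0.2, 0.6)), NA_real_)
  assemble_scan(grid, d1, d2, i1, i2, scan_id, instrument, label,
                metadata = list(scene = "forest", seed = seed))
}

# Nearest trunk-cylinder intersection per ray (Inf when none).
# Trunks span ground level to the canopy base.
ray_trunk_hit <- function(dir, cx, cy, scene) {
  n <- length(dir$dx)
  t_best <- rep(Inf, n)
  a <- dir$dx^2 + dir$dy^2
  for (j in seq_along(cx)) {
    b <- -2 * (dir$dx * cx[j] + dir$dy * cy[j])
    c0 <- cx[j]^2 + cy[j]^2 - scene$trunk_radius^2
    disc <- b^2 - 4 * a * c0
    ok <- disc > 0 & a > 1e-18
    t <- rep(Inf, n)
    t[ok] <- (-b[ok] - sqrt(disc[ok])) / (2 * a[ok])
    t[t <= 0] <- Inf
    z_at <- t * dir$dz
    t[!is.finite(z_at) | z_at > scene$canopy_base_height] <- Inf
    t_best <- pmin(t_best, t)
  }
  t_best
}

# Exponential free path through the understory slab (below the canopy base,
# above the ground); rays leave the slab when they climb above the canopy
# base or drop below ground level.
understory_path <- function(dir, scene, n) {
  if (scene$understory_density <= 0) return(rep(Inf, n))
  s <- rexp(n, rate = scene$understory_density)
  t_exit <- rep(Inf, n)
  up <- dir$dz > 1e-12
  dn <- dir$dz < -1e-12
  t_exit[up] <- scene$canopy_base_height / dir$dz[up]
  t_exit[dn] <- -1.3 / dir$dz[dn]   # ground at sensor_height below the optics
  t_exit <- pmin(t_exit, scene$stand_radius / pmax(sqrt(dir$dx^2 + dir$dy^2), 1e-12))
  ifelse(s < t_exit, s, Inf)
}

#' Generate a labelled synthetic dataset of room and forest scans
#'
#' Scans of class 0 and class 1 are generated with deterministic per-scan
#' seeds derived from `base_seed`, and mild per-scan jitter (default +/-10%
#' on scene dimensions) creates within-class variance. Two calls with the
#' same arguments give identical datasets.
#'
#' @param n_class0,n_class1 Number of scans per class.
#' @param class0_config,class1_config Scene configurations; defaults are the
#'   room and forest presets.
#' @param pattern A [scan_pattern()].
#' @param instrument An [instrument_spec()].
#' @param base_seed Master seed.
#' @param jitter_frac Relative jitter applied per scan to scene dimensions.
#'
#' @return A list of labelled [tls_scan()] objects (class 0 first).
#' @export
generate_labeled_dataset <- function(n_class0, n_class1,
                                     class0_config = room_scene(),
                                     class1_config = forest_scene(),
                                     pattern = scan_pattern(),
                                     instrument = instrument_spec(),
                                     base_seed = 1L, jitter_frac = 0.1) {
  check_number(n_class0, "n_class0", min = 1)
  check_number(n_class1, "n_class1", min = 1)
  n <- n_class0 + n_class1
  seeds <- derive_seeds(base_seed, 2L * n)
  gen_seeds <- seeds[seq_len(n)]
  jit_seeds <- seeds[n + seq_len(n)]
  make <- function(i, config, label, tag) {
    cfg <- jitter_scene(config, jit_seeds[i], jitter_frac)
    gen <- if (inherits(cfg, "room_scene")) generate_room_scan else generate_forest_scan
    gen(pattern, cfg, instrument,
        scan_id = sprintf("%s_%03d", tag, i), label = label,
        seed = gen_seeds[i])
  }
  c(
    lapply(seq_len(n_class0), function(i)
      make(i, class0_config, 0, class_tag(class0_config))),
    lapply(n_class0 + seq_len(n_class1), function(i)
      make(i, class1_config, 1, class_tag(class1_config)))
  )
}

class_tag <- function(config) if (inherits(config, "room_scene")) "room" else "forest"

# Multiplicative jitter on the scene dimensions that vary between real
# locations; probabilities and noise scales are left at their set values.
jitter_scene <- function(config, seed, frac) {
  if (frac <= 0) return(config)
  set.seed(seed)
  jit <- function(v) v * runif(1, 1 - frac, 1 + frac)
  if (inherits(config, "room_scene")) {
    config$half_width_x <- jit(config$half_width_x)
    config$half_width_y <- jit(config$half_width_y)
    config$ceiling_height <- jit(config$ceiling_height)
    config$reflectance_mean <- clip01(jit(config$reflectance_mean))
  } else {
    base <- jit(config$canopy_base_height)
    config$canopy_top_height <- max(base + 1, jit(config$canopy_top_height))
    config$canopy_base_height <- base
    config$understory_density <- jit(config$understory_density)
    config$reflectance_mean <- clip01(jit(config$reflectance_mean))
  }
  config
}
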