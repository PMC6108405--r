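# Independent brute-force implementations of each metric, written against
# the raw row table only (no shared code with the package internals beyond
# the coordinate convention).
naive_metrics <- function(scan, config = metaproperty_config()) {
  rows <- tibble::as_tibble(scan)
  pb <- config$pulse_band
  first <- rows[rows$return_index == 1 & rows$zenith_deg >= pb[1] &
                  rows$zenith_deg <= pb[2], ]
  second <- rows[rows$return_index == 2 & rows$zenith_deg >= pb[1] &
                   rows$zenith_deg <= pb[2], ]
  gb <- config$gap_band
  band <- rows[rows$zenith_deg >= gb[1] & rows$zenith_deg <= gb[2], ]
  list(
    mean_distance = mean(first$distance_m),
    mean_intensity = mean(first$intensity, na.rm = TRUE),
    first_second_ratio = nrow(first) / nrow(second),
    no_return_ratio = sum(band$return_index == 0) /
      length(unique(band$pulse_id))
  )
}

test_that("pulse metaproperties match hand values and exclude no-returns", {
  scan <- make_simple_scan(d1 = c(4, 6), zenith = 45,
                           intensity = c(0.2, 0.4), n_no_return = 10)
  expect_equal(mean_distance(scan), 5.0)
  expect_equal(mean_intensity(scan), 0.3)

  one <- make_simple_scan(d1 = 3, intensity = 0.9)
  expect_equal(mean_intensity(one), 0.9)

  # pulses above 90 degrees do not contribute
  mixed <- make_simple_scan(d1 = c(4, 6, 100 - 60), zenith = c(45, 45, 120))
  expect_equal(mean_distance(mixed), 5.0)

  empty_band <- make_simple_scan(d1 = 5, zenith = 120)
  expect_error(mean_distance(empty_band), class = "metaprop_not_computable")
})

test_that("first:second ratio counts returns and flags the no-second case", {
  scan <- make_simple_scan(d1 = seq(2, 21, length.out = 100),
                           second_d = seq(3, 22, length.out = 25))
  expect_equal(first_second_ratio(scan), 4.0)

  no_second <- make_simple_scan(d1 = seq(2, 12, length.out = 50))
  expect_identical(first_second_ratio(no_second), Inf)
  tab <- extract_metaproperties(no_second)
  expect_match(tab$flags, "first_second_ratio:infinite")

  no_first <- make_simple_scan(d1 = 5, zenith = 120)
  expect_error(first_second_ratio(no_first), class = "metaprop_not_computable")
})

test_that("no-return ratio is the in-band gap fraction", {
  scan <- make_simple_scan(d1 = rep(5, 7), zenith = 32, n_no_return = 3)
  # the 3 no-return pulses were given random zenith; rebuild them in band
  rows <- tibble::as_tibble(scan)
  rows$zenith_deg <- 32
  scan <- tls_scan(rows)
  expect_equal(no_return_ratio(scan), 0.3)
  all_ret <- make_simple_scan(d1 = rep(5, 10), zenith = 33)
  expect_equal(no_return_ratio(all_ret), 0.0)
  expect_error(no_return_ratio(make_simple_scan(d1 = 5, zenith = 60)),
               class = "metaprop_not_computable")
})

test_that("no-return ratio tracks the generating gap probability", {
  dense_band <- scan_pattern(zenith_start = 30, zenith_stop = 35,
                             zenith_step = 0.25, azimuth_step = 1.5)
  scene <- forest_scene(canopy_gap_prob = 0.25, seed = 42)
  scan <- generate_forest_scan(dense_band, scene)
  n_band <- n_pulses(scan)
  expect_gte(n_band, 5000)
  se <- sqrt(0.25 * 0.75 / n_band)
  expect_lt(abs(no_return_ratio(scan) - 0.25), 3 * se)
})

test_that("optical plane area reproduces closed-form polygons", {
  diamond <- make_simple_scan(d1 = rep(1, 4), zenith = 90,
                              azimuth = c(0, 90, 180, 270))
  expect_equal(optical_plane_area(diamond), 2.0, tolerance = 1e-12)

  n <- 360
  ring <- make_simple_scan(d1 = rep(10, n), zenith = 90,
                           azimuth = seq(0, 359, length.out = n))
  expect_equal(optical_plane_area(ring), 0.5 * n * 100 * sin(2 * pi / n),
               tolerance = 1e-3)

  two <- make_simple_scan(d1 = c(1, 2), zenith = 90, azimuth = c(0, 90))
  expect_error(optical_plane_area(two), class = "metaprop_not_computable")
})

test_that("OPA is rotation invariant and scales quadratically", {
  set.seed(5)
  az <- sort(runif(40, 0, 359))
  d <- runif(40, 2, 15)
  base <- make_simple_scan(d1 = d, zenith = 90, azimuth = az)
  a0 <- optical_plane_area(base)

  rot <- make_simple_scan(d1 = d, zenith = 90, azimuth = (az + 117) %% 360)
  expect_equal(optical_plane_area(rot), a0, tolerance = 1e-9 * a0)

  scaled <- make_simple_scan(d1 = 2 * d, zenith = 90, azimuth = az)
  expect_equal(optical_plane_area(scaled), 4 * a0, tolerance = 1e-9 * a0)
})

test_that("rugosity is 1 for a flat grid and 1/cos(theta) for a tilted plane", {
  flat <- grid_scan(n_side = 5, z_fun = function(x, y) 3)
  expect_equal(rugosity(flat), 1.0, tolerance = 1e-9)

  tilted <- grid_scan(n_side = 5, z_fun = function(x, y) 10 + sqrt(3) * x)
  expect_equal(rugosity(tilted), 2.0, tolerance = 1e-6)
})

test_that("rugosity equals an independent triangle-by-triangle area sum", {
  # jittered grid avoids cocircular ties so the triangulation is unique
  set.seed(31)
  g <- expand.grid(x = seq(-1, 1, by = 0.25), y = seq(-1, 1, by = 0.25))
  g$x <- g$x + runif(nrow(g), -0.05, 0.05)
  g$y <- g$y + runif(nrow(g), -0.05, 0.05)
  z <- 8 + runif(nrow(g), 0, 0.8)
  sph <- cartesian_to_spherical(g$x, g$y, z)
  scan <- tls_scan(make_pulse_rows(sprintf("j%03d", seq_len(nrow(g))),
                                   sph$zenith_deg, sph$azimuth_deg, 1L,
                                   sph$distance_m, 0.5))
  got <- rugosity(scan)

  # oracle: deldir triangulation, explicit per-triangle Heron-style areas
  dd <- deldir::triMat(deldir::deldir(g$x, g$y))
  tri_area <- function(p1, p2, p3) {
    a <- sqrt(sum((p2 - p1)^2)); b <- sqrt(sum((p3 - p2)^2))
    cc <- sqrt(sum((p1 - p3)^2)); s <- (a + b + cc) / 2
    sqrt(max(0, s * (s - a) * (s - b) * (s - cc)))
  }
  a3 <- sum(vapply(seq_len(nrow(dd)), function(i) {
    v <- dd[i, ]
    tri_area(c(g$x[v[1]], g$y[v[1]], z[v[1]]),
             c(g$x[v[2]], g$y[v[2]], z[v[2]]),
             c(g$x[v[3]], g$y[v[3]], z[v[3]]))
  }, numeric(1)))
  hull <- grDevices::chull(g$x, g$y)
  a2 <- sum(vapply(seq_len(nrow(dd)), function(i) {
    v <- dd[i, ]
    tri_area(c(g$x[v[1]], g$y[v[1]], 0), c(g$x[v[2]], g$y[v[2]], 0),
             c(g$x[v[3]], g$y[v[3]], 0))
  }, numeric(1)))
  expect_equal(got, a3 / a2, tolerance = 1e-7)
})

test_that("rugosity is at least 1 and invariant to vertical shifts", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- expand.grid(x = seq(-1, 1, by = 0.4), y = seq(-1, 1, by = 0.4))
    g$x <- g$x + runif(nrow(g), -0.1, 0.1)
    g$y <- g$y + runif(nrow(g), -0.1, 0.1)
    z <- 8 + runif(nrow(g), 0, 1.5)
    mk <- function(zv) {
      sph <- cartesian_to_spherical(g$x, g$y, zv)
      tls_scan(make_pulse_rows(sprintf("v%03d", seq_len(nrow(g))),
                               sph$zenith_deg, sph$azimuth_deg, 1L,
                               sph$distance_m, 0.5))
    }
    r <- rugosity(mk(z))
    expect_gte(r, 1 - 1e-9)
    expect_equal(rugosity(mk(z + 3)), r, tolerance = 1e-9)
  }
})

test_that("every metric matches its brute-force twin on random scans", {
  cfg <- metaproperty_config()
  for (seed in 1:100) {
    scan <- random_scan(n_pulses = 40, seed = seed)
    ref <- naive_metrics(scan, cfg)
    got <- extract_metaproperties(scan, cfg)
    if (is.nan(ref$mean_distance)) {
      expect_true(is.na(got$mean_distance))
    } else {
      expect_equal(got$mean_distance, ref$mean_distance, tolerance = 1e-12)
      expect_equal(got$mean_intensity, ref$mean_intensity, tolerance = 1e-12)
      expect_equal(got$first_second_ratio, ref$first_second_ratio)
    }
    if (!is.nan(ref$no_return_ratio)) {
      expect_equal(got$no_return_ratio, ref$no_return_ratio, tolerance = 1e-12)
      expect_gte(got$no_return_ratio, 0)
      expect_lte(got$no_return_ratio, 1)
    }
  }
})

test_that("means are bounded by their contributing values", {
  for (seed in c(2, 12, 22)) {
    scan <- random_scan(n_pulses = 60, seed = seed)
    fr <- subset_pulses(scan, 0, 90, "first_only")
    if (nrow(fr) == 0) next
    md <- mean_distance(scan)
    expect_gte(md, min(fr$distance_m))
    expect_lte(md, max(fr$distance_m))
  }
})

test_that("extract_metaproperties flags missing metrics instead of failing", {
  # no optical-plane pulses at all: opa flagged, others present
  scan <- make_simple_scan(d1 = rep(c(3, 5), 10), zenith = rep(c(20, 33), 10),
                           n_no_return = 2)
  tab <- extract_metaproperties(scan)
  expect_true(is.na(tab$opa))
  expect_match(tab$flags, "opa:not_computable")
  expect_false(is.na(tab$mean_distance))

  # batch keeps order
  scans <- list(make_simple_scan(d1 = c(4, 6)), make_simple_scan(d1 = c(2, 8)))
  attr(scans[[1]], "scan_id") <- "one"
  attr(scans[[2]], "scan_id") <- "two"
  tab <- extract_metaproperties(scans)
  expect_equal(tab$scan_id, c("one", "two"))

  expect_error(extract_metaproperties(tls_scan(make_pulse_rows(
    character(0), numeric(0), numeric(0), integer(0)))),
    class = "metaprop_validation_error")
})
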