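`%||%` <- function(x, y) if (is.null(x)) y else x

# Fixture builders shared across test files. All scans are built in code;
# nothing is read from disk except where I/O itself is under test.

make_pulse_rows <- function(pulse_id, zenith_deg, azimuth_deg, return_index,
                            distance_m = NA_real_, intensity = NA_real_) {
  tibble::tibble(pulse_id = as.character(pulse_id), zenith_deg = zenith_deg,
                 azimuth_deg = azimuth_deg,
                 return_index = as.integer(return_index),
                 distance_m = distance_m, intensity = intensity)
}

# A small scan with known structure: n1 first-return pulses (optionally with
# seconds), n0 no-return pulses, all in a given zenith band.
make_simple_scan <- function(d1, zenith = 45, azimuth = NULL, intensity = 0.5,
                             n_no_return = 0, second_d = NULL, label = NA) {
  n <- length(d1)
  azimuth <- azimuth %||% seq(0, 359, length.out = max(n, 1)) %% 360
  zenith <- rep_len(zenith, n)
  intensity <- rep_len(intensity, n)
  rows <- make_pulse_rows(sprintf("r%03d", seq_len(n)), zenith, azimuth, 1L,
                          d1, intensity)
  if (!is.null(second_d)) {
    k <- length(second_d)
    rows <- dplyr::bind_rows(rows, make_pulse_rows(
      sprintf("r%03d", seq_len(k)), zenith[seq_len(k)], azimuth[seq_len(k)],
      2L, second_d, intensity[seq_len(k)] / 2))
  }
  if (n_no_return > 0) {
    rows <- dplyr::bind_rows(rows, make_pulse_rows(
      sprintf("n%03d", seq_len(n_no_return)),
      rep_len(zenith, n_no_return), runif(n_no_return, 0, 359), 0L))
  }
  tls_scan(rows, scan_id = "fixture", label = label)
}

# Random small scan for brute-force equivalence properties: every pulse gets
# 0, 1 or 2 returns at random angles.
random_scan <- function(n_pulses = 60, seed = 1) {
  set.seed(seed)
  zen <- runif(n_pulses, 0, 120)
  az <- runif(n_pulses, 0, 359.9)
  n_ret <- sample(0:2, n_pulses, replace = TRUE, prob = c(0.2, 0.5, 0.3))
  d1 <- runif(n_pulses, 0.5, 35)
  rows <- dplyr::bind_rows(
    make_pulse_rows(sprintf("p%03d", which(n_ret == 0)),
                    zen[n_ret == 0], az[n_ret == 0], 0L),
    make_pulse_rows(sprintf("p%03d", which(n_ret >= 1)),
                    zen[n_ret >= 1], az[n_ret >= 1], 1L,
                    d1[n_ret >= 1], runif(sum(n_ret >= 1))),
    make_pulse_rows(sprintf("p%03d", which(n_ret == 2)),
                    zen[n_ret == 2], az[n_ret == 2], 2L,
                    d1[n_ret == 2] + runif(sum(n_ret == 2), 0.1, 3),
                    runif(sum(n_ret == 2)))
  )
  tls_scan(rows, scan_id = sprintf("rand%d", seed))
}

# Grid scan in the rugosity band with prescribed heights: points on a square
# (x, y) grid at z = z_fun(x, y), expressed in spherical coordinates.
grid_scan <- function(n_side = 5, spacing = 0.5, z_fun = function(x, y) 3) {
  g <- expand.grid(x = seq_len(n_side) * spacing, y = seq_len(n_side) * spacing)
  g$x <- g$x - mean(g$x)
  g$y <- g$y - mean(g$y)
  z <- mapply(z_fun, g$x, g$y)
  stopifnot(all(z > 0))
  sph <- cartesian_to_spherical(g$x, g$y, z)
  # keep only points within the 0-30 deg rugosity cone
  stopifnot(all(sph$zenith_deg <= 30))
  rows <- make_pulse_rows(sprintf("g%03d", seq_len(nrow(g))), sph$zenith_deg,
                          sph$azimuth_deg, 1L, sph$distance_m, 0.5)
  tls_scan(rows, scan_id = "grid")
}

small_pattern <- function() scan_pattern(zenith_step = 7.5, azimuth_step = 15)
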