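#' Configuration for metaproperty extraction
#'
#' Zenith bands select the pulse subsets each metric is computed over. The
#' three pulse metrics (mean distance, mean intensity, 1st:2nd return ratio)
#' use `pulse_band`; the no-return (gap) ratio uses `gap_band`; rugosity uses
#' `rugosity_band`; the optical plane area uses the band
#' `90 +/- optical_plane_tolerance_deg`, since real scanners sample discrete
#' zenith rows and an exact 90-degree test would select nothing.
#'
#' @param pulse_band Closed zenith interval (degrees) for pulse metrics;
#'   default `c(0, 90)`, i.e. at or above the optical plane.
#' @param gap_band Zenith interval for the no-return ratio; default
#'   `c(30, 35)`, a mid-canopy view band.
#' @param rugosity_band Zenith interval for rugosity; default `c(0, 30)`,
#'   the near-vertical cone looking at ceiling or canopy.
#' @param optical_plane_tolerance_deg Half-width (degrees) of the optical
#'   plane band around 90; default 0.5, capturing the scan row nearest the
#'   horizontal.
#' @param min_polygon_vertices Minimum first returns needed to form the
#'   optical-plane polygon; default 3.
#'
#' @return An object of class `metaproperty_config`.
#' @export
metaproperty_config <- function(pulse_band = c(0, 90),
                                gap_band = c(30, 35),
                                rugosity_band = c(0, 30),
                                optical_plane_tolerance_deg = 0.5,
                                min_polygon_vertices = 3L) {
  check_band <- function(b, name) {
    if (length(b) != 2 || any(is.na(b)) || b[1] > b[2] || b[1] < 0 || b[2] > 180) {
      stop_validation("`%s` must be an ordered interval within [0, 180]", name)
    }
  }
  check_band(pulse_band, "pulse_band")
  check_band(gap_band, "gap_band")
  check_band(rugosity_band, "rugosity_band")
  check_number(optical_plane_tolerance_deg, "optical_plane_tolerance_deg", min = 1e-12)
  check_number(min_polygon_vertices, "min_polygon_vertices", min = 3)
  structure(
    list(pulse_band = as.numeric(pulse_band),
         gap_band = as.numeric(gap_band),
         rugosity_band = as.numeric(rugosity_band),
         optical_plane_tolerance_deg = optical_plane_tolerance_deg,
         min_polygon_vertices = as.integer(min_polygon_vertices)),
    class = "metaproperty_config"
  )
}

first_returns_in_band <- function(scan, band) {
  subset_pulses(scan, band[1], band[2], "first_only")
}

#' Pulse metaproperties: mean distance, mean intensity, return ratio
#'
#' All three are population statistics of the pulses at or above the optical
#' plane (zenith in `config$pulse_band`). `mean_distance()` and
#' `mean_intensity()` average over first returns only; pulses without a
#' return contribute nothing. `first_second_ratio()` is the count of first
#' returns divided by the count of second returns; with no second returns it
#' returns `Inf` (solid-surface scenes produce almost none).
#'
#' @param scan A [tls_scan()].
#' @param config A [metaproperty_config()].
#'
#' @return A single number (metres for distance, relative units in `[0, 1]`
#'   for intensity, dimensionless for the ratio). Errors with class
#'   `metaprop_not_computable` when no eligible pulses exist.
#' @export
mean_distance <- function(scan, config = metaproperty_config()) {
  fr <- first_returns_in_band(scan, config$pulse_band)
  if (nrow(fr) == 0) {
    stop_not_computable("mean_distance", "no first returns in zenith band [%g, %g]",
                        config$pulse_band[1], config$pulse_band[2])
  }
  mean(fr$distance_m)
}

#' @rdname mean_distance
#' @export
mean_intensity <- function(scan, config = metaproperty_config()) {
  fr <- first_returns_in_band(scan, config$pulse_band)
  fr <- fr[!is.na(fr$intensity), , drop = FALSE]
  if (nrow(fr) == 0) {
    stop_not_computable("mean_intensity", "no first returns with intensity in zenith band [%g, %g]",
                        config$pulse_band[1], config$pulse_band[2])
  }
  mean(fr$intensity)
}

#' @rdname mean_distance
#' @export
first_second_ratio <- function(scan, config = metaproperty_config()) {
  rows <- subset_pulses(scan, config$pulse_band[1], config$pulse_band[2], "all")
  n1 <- sum(rows$return_index == 1L)
  n2 <- sum(rows$return_index == 2L)
  if (n1 == 0) {
    stop_not_computable("first_second_ratio", "no first returns in zenith band [%g, %g]",
                        config$pulse_band[1], config$pulse_band[2])
  }
  if (n2 == 0) return(Inf)
  n1 / n2
}

#' Gap ratio: pulses with no return over total pulses
#'
#' Computed over the `config$gap_band` zenith band (default 30-35 degrees).
#' A forest canopy with gaps lets a fraction of skyward pulses escape
#' without producing a return; a ceiling intercepts every pulse. This is the
#' scan-level analogue of a lidar gap-fraction estimate.
#'
#' @inheritParams mean_distance
#' @return Proportion in `[0, 1]`.
#' @export
no_return_ratio <- function(scan, config = metaproperty_config()) {
  rows <- subset_pulses(scan, config$gap_band[1], config$gap_band[2], "all")
  n_total <- dplyr::n_distinct(rows$pulse_id)
  if (n_total == 0) {
    stop_not_computable("no_return_ratio", "no pulses in zenith band [%g, %g]",
                        config$gap_band[1], config$gap_band[2])
  }
  n_gap <- sum(rows$return_index == 0L)
  n_gap / n_total
}

#' Optical plane area (OPA)
#'
#' Area of the polygon obtained by joining the (x, y) positions of first
#' returns from pulses emitted at the optical plane (zenith within
#' `optical_plane_tolerance_deg` of 90). Vertices are ordered by azimuth
#' (ties broken by ascending distance), the polygon is closed from the last
#' vertex back to the first, and the area is the absolute shoelace sum over
#' two. Optical-plane pulses without a return contribute no vertex, so OPA
#' of open scenes underestimates the sight-line envelope.
#'
#' @inheritParams mean_distance
#' @return Area in square metres.
#' @export
optical_plane_area <- function(scan, config = metaproperty_config()) {
  tol <- config$optical_plane_tolerance_deg
  fr <- subset_pulses(scan, max(0, 90 - tol), min(180, 90 + tol), "first_only")
  if (nrow(fr) < config$min_polygon_vertices) {
    stop_not_computable("opa", "only %d optical-plane first returns (need >= %d)",
                        nrow(fr), config$min_polygon_vertices)
  }
  fr <- fr[order(fr$azimuth_deg, fr$distance_m), , drop = FALSE]
  xy <- spherical_to_cartesian(fr$distance_m, fr$zenith_deg, fr$azimuth_deg)
  polygon_area(xy$x, xy$y)
}

#' Rugosity: triangulated 3-D area over planar footprint area
#'
#' First returns in the `rugosity_band` zenith cone (default 0-30 degrees)
#' are projected to (x, y); a Delaunay triangulation of the projection is
#' lifted to the returns' z values; the metric is the ratio of the summed
#' 3-D triangle areas to the area of the triangulation footprint (the convex
#' hull of the projected points). A flat surface gives exactly 1; height
#' structure raises it.
#'
#' @inheritParams mean_distance
#' @return Dimensionless ratio, at least 1 up to numerical tolerance.
#' @export
rugosity <- function(scan, config = metaproperty_config()) {
  fr <- first_returns_in_band(scan, config$rugosity_band)
  if (nrow(fr) < 3) {
    stop_not_computable("rugosity", "only %d first returns in zenith band [%g, %g] (need >= 3)",
                        nrow(fr), config$rugosity_band[1], config$rugosity_band[2])
  }
  xyz <- spherical_to_cartesian(fr$distance_m, fr$zenith_deg, fr$azimuth_deg)
  areas <- triangulated_areas(xyz$x, xyz$y, xyz$z)
  if (areas$n_triangles == 0 || areas$area_2d <= 0) {
    stop_not_computable("rugosity", "projected points are collinear; no triangulation")
  }
  areas$area_3d / areas$area_2d
}

metaproperty_names <- c("mean_distance", "mean_intensity", "first_second_ratio",
                        "no_return_ratio", "opa", "rugosity")

#' Extract the full metaproperty vector for one scan or many
#'
#' Computes all six metaproperties. A metric that is not computable on a
#' given scan (for example OPA with fewer than three optical-plane returns)
#' becomes `NA` and is recorded in the `flags` column instead of aborting
#' the extraction; an infinite first:second ratio is likewise flagged.
#'
#' @param scans A [tls_scan()] or a list of them.
#' @param config A [metaproperty_config()].
#'
#' @return A tibble with one row per scan and columns `scan_id`, `label`,
#'   the six metrics, and `flags` (a semicolon-separated record of metrics
#'   that were not computable or infinite; empty when all are clean).
#' @export
#'
#' @examples
#' scans <- generate_labeled_dataset(2, 2, pattern = scan_pattern(
#'   zenith_step = 7.5, azimuth_step = 15), base_seed = 7)
#' extract_metaproperties(scans)
extract_metaproperties <- function(scans, config = metaproperty_config()) {
  if (inherits(scans, "tls_scan")) scans <- list(scans)
  purrr::map_dfr(scans, extract_one, config = config)
}

extract_one <- function(scan, config) {
  if (!inherits(scan, "tls_scan")) {
    stop_validation("expected a tls_scan, got %s", class(scan)[1])
  }
  if (nrow(scan) == 0) stop_validation("scan '%s' is empty", scan_id(scan))
  flags <- character(0)
  one <- function(metric, fn) {
    tryCatch(fn(scan, config),
             metaprop_not_computable = function(e) {
               flags <<- c(flags, paste0(metric, ":not_computable"))
               NA_real_
             })
  }
  vals <- c(
    mean_distance = one("mean_distance", mean_distance),
    mean_intensity = one("mean_intensity", mean_intensity),
    first_second_ratio = one("first_second_ratio", first_second_ratio),
    no_return_ratio = one("no_return_ratio", no_return_ratio),
    opa = one("opa", optical_plane_area),
    rugosity = one("rugosity", rugosity)
  )
  if (is.infinite(vals[["first_second_ratio"]])) {
    flags <- c(flags, "first_second_ratio:infinite")
  }
  tibble::tibble(
    scan_id = scan_id(scan),
    label = scan_label(scan),
    !!!as.list(vals),
    flags = paste(flags, collapse = ";")
  )
}

#' Read or write a metaproperty table CSV
#'
#' One row per scan with columns `scan_id`, `label`, the six metrics and
#' `flags`; flagged-missing metrics are empty cells.
#'
#' @param table A tibble as returned by [extract_metaproperties()].
#' @param path File path.
#' @return `write_metaproperty_csv()` returns `path` invisibly;
#'   `read_metaproperty_csv()` returns the tibble.
#' @export
write_metaproperty_csv <- function(table, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname write_metaproperty_csv
#' @export
read_metaproperty_csv <- function(path) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  tab <- readr::read_csv(path, col_types = readr::cols(
    scan_id = readr::col_character(),
    label = readr::col_double(),
    .default = readr::col_double(),
    flags = readr::col_character()
  ), progress = FALSE)
  missing_cols <- setdiff(c("scan_id", "label", metaproperty_names), names(tab))
  if (length(missing_cols) > 0) {
    stop_format("%s lacks column(s): %s", path, paste(missing_cols, collapse = ", "))
  }
  if (!"flags" %in% names(tab)) tab$flags <- ""
  tab$flags[is.na(tab$flags)] <- ""
  tab
}
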