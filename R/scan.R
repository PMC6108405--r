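#' Instrument description for a terrestrial laser scanner
#'
#' Defaults describe a compact 905 nm biomass scanner: ~40 m maximum range,
#' 15 mrad beam divergence, tripod-mounted with the optical centre at 1.3 m,
#' recording up to two returns per pulse.
#'
#' @param max_range_m Maximum usable range in metres.
#' @param beam_divergence_mrad Beam divergence in milliradians (metadata;
#'   pulses are modelled as rays).
#' @param sensor_height_m Height of the optical centre above ground, metres.
#'   Coordinates are always sensor-relative; this is carried as metadata.
#' @param max_returns Maximum number of ranged returns recorded per pulse.
#'
#' @return An object of class `instrument_spec`.
#' @export
#'
#' @examples
#' instrument_spec()
instrument_spec <- function(max_range_m = 40, beam_divergence_mrad = 15,
                            sensor_height_m = 1.3, max_returns = 2L) {
  check_number(max_range_m, "max_range_m", min = 1e-9)
  check_number(beam_divergence_mrad, "beam_divergence_mrad", min = 1e-9)
  check_number(sensor_height_m, "sensor_height_m", min = 1e-9)
  check_number(max_returns, "max_returns", min = 1)
  structure(
    list(max_range_m = max_range_m,
         beam_divergence_mrad = beam_divergence_mrad,
         sensor_height_m = sensor_height_m,
         max_returns = as.integer(max_returns)),
    class = "instrument_spec"
  )
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("<instrument_spec> max range %g m, divergence %g mrad, sensor height %g m, %d returns/pulse\n",
              x$max_range_m, x$beam_divergence_mrad, x$sensor_height_m, x$max_returns))
  invisible(x)
}

scan_columns <- c("pulse_id", "zenith_deg", "azimuth_deg",
                  "return_index", "distance_m", "intensity")

#' Construct a TLS scan from pulse-level records
#'
#' A scan is a tibble in long format: one row per ranged return, plus one row
#' with `return_index = 0` (and `NA` distance/intensity) for each pulse that
#' produced no return. The zenith convention is 0 deg = vertically up and
#' 90 deg = the horizontal optical plane; azimuth is degrees counterclockwise
#' from +x viewed from above.
#'
#' @param pulses A data frame with columns `pulse_id`, `zenith_deg`,
#'   `azimuth_deg`, `return_index`, `distance_m`, `intensity`.
#' @param scan_id Identifier for the scan.
#' @param instrument An [instrument_spec()].
#' @param label Optional binary class label (0/1) for classification.
#' @param metadata Optional named list of free-form metadata.
#' @param validate Set `FALSE` to skip invariant checks (internal use on
#'   rows already validated).
#'
#' @return A tibble of class `tls_scan` with attributes `scan_id`,
#'   `instrument`, `label` and `metadata`.
#' @export
#'
#' @examples
#' pulses <- tibble::tibble(
#'   pulse_id = c("a", "a", "b"), zenith_deg = c(45, 45, 90),
#'   azimuth_deg = c(0, 0, 10), return_index = c(1L, 2L, 0L),
#'   distance_m = c(5, 7, NA), intensity = c(0.5, 0.2, NA))
#' tls_scan(pulses, scan_id = "demo")
tls_scan <- function(pulses, scan_id = "scan", instrument = instrument_spec(),
                     label = NA, metadata = list(), validate = TRUE) {
  if (!inherits(instrument, "instrument_spec")) {
    stop_validation("`instrument` must be an instrument_spec")
  }
  missing_cols <- setdiff(scan_columns, names(pulses))
  if (length(missing_cols) > 0) {
    stop_format("pulse table lacks required column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  pulses <- tibble::as_tibble(pulses)[scan_columns]
  pulses$pulse_id <- as.character(pulses$pulse_id)
  pulses$return_index <- as.integer(pulses$return_index)
  if (!is.na(label) && !label %in% c(0, 1)) {
    stop_validation("`label` must be 0, 1 or NA")
  }
  if (validate) validate_scan_rows(pulses, instrument)
  structure(
    pulses,
    class = c("tls_scan", class(tibble::tibble())),
    scan_id = scan_id,
    instrument = instrument,
    label = if (is.na(label)) NA_real_ else as.numeric(label),
    metadata = metadata
  )
}

validate_scan_rows <- function(pulses, instrument) {
  bad <- which(pulses$zenith_deg < 0 | pulses$zenith_deg > 180 |
                 is.na(pulses$zenith_deg))
  if (length(bad) > 0) {
    stop_validation("zenith_deg outside [0, 180] at row(s) %s",
                    paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(is.na(pulses$azimuth_deg) | pulses$azimuth_deg < 0 |
                 pulses$azimuth_deg >= 360)
  if (length(bad) > 0) {
    stop_validation("azimuth_deg outside [0, 360) at row(s) %s",
                    paste(head(bad, 5), collapse = ", "))
  }
  if (any(is.na(pulses$return_index)) ||
      any(!pulses$return_index %in% 0:2)) {
    stop_validation("return_index must be 0 (no return), 1 or 2")
  }
  ranged <- pulses$return_index > 0
  bad <- which(ranged & (is.na(pulses$distance_m) | pulses$distance_m <= 0))
  if (length(bad) > 0) {
    stop_validation("non-positive or missing distance_m at row(s) %s",
                    paste(head(bad, 5), collapse = ", "))
  }
  bad <- which(ranged & pulses$distance_m > instrument$max_range_m + 1e-9)
  if (length(bad) > 0) {
    stop_validation("distance_m exceeds instrument max range (%g m) at row(s) %s",
                    instrument$max_range_m, paste(head(bad, 5), collapse = ", "))
  }
  if (any(!ranged & !is.na(pulses$distance_m))) {
    stop_validation("no-return rows (return_index 0) must have empty distance_m")
  }
  bad <- which(ranged & !is.na(pulses$intensity) &
                 (pulses$intensity < 0 | pulses$intensity > 1))
  if (length(bad) > 0) {
    stop_validation("intensity outside [0, 1] at row(s) %s",
                    paste(head(bad, 5), collapse = ", "))
  }
  # per-pulse structure: at most max_returns returns, second return beyond
  # first, no mix of return_index 0 with ranged rows, consistent angles
  grp <- dplyr::summarise(
    dplyr::group_by(pulses, .data$pulse_id),
    n = dplyr::n(),
    n0 = sum(.data$return_index == 0L),
    nr = sum(.data$return_index > 0L),
    dup = anyDuplicated(.data$return_index) > 0L,
    d1 = .data$distance_m[match(1L, .data$return_index)],
    d2 = .data$distance_m[match(2L, .data$return_index)],
    n_ang = dplyr::n_distinct(.data$zenith_deg, .data$azimuth_deg),
    .groups = "drop"
  )
  offend <- function(cond, what) {
    if (any(cond)) {
      stop_validation("pulse '%s' %s", grp$pulse_id[which(cond)[1]], what)
    }
  }
  offend(grp$n0 > 0 & grp$n > 1, "mixes a no-return row with other rows")
  offend(grp$dup, "has duplicated return_index")
  offend(grp$nr > instrument$max_returns,
         sprintf("has more than %d returns", instrument$max_returns))
  offend(!is.na(grp$d1) & !is.na(grp$d2) & grp$d2 < grp$d1,
         "has its second return nearer than its first")
  offend(is.na(grp$d1) & !is.na(grp$d2), "has a second return without a first")
  offend(grp$n_ang > 1, "has inconsistent angles across its returns")
  invisible(pulses)
}

#' @export
print.tls_scan <- function(x, ...) {
  n_pulse <- dplyr::n_distinct(x$pulse_id)
  n_ret <- sum(x$return_index > 0)
  lab <- attr(x, "label")
  cat(sprintf("<tls_scan '%s'> %d pulses, %d returns%s\n",
              scan_id(x), n_pulse, n_ret,
              if (is.na(lab)) "" else sprintf(", label = %g", lab)))
  NextMethod()
}

#' Scan accessors
#'
#' @param scan A `tls_scan`.
#' @return `scan_id()` the identifier, `scan_label()` the binary label (or
#'   `NA`), `scan_instrument()` the [instrument_spec()], `n_pulses()` the
#'   number of emitted pulses represented in the scan.
#' @export
scan_id <- function(scan) attr(scan, "scan_id")

#' @rdname scan_id
#' @export
scan_label <- function(scan) attr(scan, "label")

#' @rdname scan_id
#' @export
scan_instrument <- function(scan) attr(scan, "instrument")

#' @rdname scan_id
#' @export
n_pulses <- function(scan) dplyr::n_distinct(scan$pulse_id)

#' Subset pulses by zenith band and return status
#'
#' Selects the pulses whose zenith angle lies in the closed interval
#' `[zenith_min_deg, zenith_max_deg]` and which pass the return filter. Row
#' order is preserved. The result keeps the scan's long-format rows: for
#' `"first_only"` only the `return_index == 1` rows of qualifying pulses are
#' returned; for `"no_return"` the `return_index == 0` rows; otherwise every
#' row of qualifying pulses.
#'
#' @param scan A `tls_scan` (or any tibble with scan columns).
#' @param zenith_min_deg,zenith_max_deg Closed zenith interval in degrees.
#' @param return_filter One of `"all"`, `"first_only"`, `"with_any_return"`,
#'   `"no_return"`.
#'
#' @return A tibble of pulse rows.
#' @export
#'
#' @examples
#' scan <- generate_room_scan(scan_pattern(zenith_step = 10, azimuth_step = 45),
#'                            room_scene(seed = 1))
#' subset_pulses(scan, 0, 90, "first_only")
subset_pulses <- function(scan, zenith_min_deg, zenith_max_deg,
                          return_filter = c("all", "first_only",
                                            "with_any_return", "no_return")) {
  return_filter <- match.arg(return_filter)
  check_number(zenith_min_deg, "zenith_min_deg", min = 0, max = 180)
  check_number(zenith_max_deg, "zenith_max_deg", min = 0, max = 180)
  if (zenith_min_deg > zenith_max_deg) {
    stop_validation("zenith_min_deg (%g) exceeds zenith_max_deg (%g)",
                    zenith_min_deg, zenith_max_deg)
  }
  rows <- tibble::as_tibble(scan)
  in_band <- rows$zenith_deg >= zenith_min_deg & rows$zenith_deg <= zenith_max_deg
  rows <- rows[in_band, , drop = FALSE]
  switch(return_filter,
    all = rows,
    first_only = rows[rows$return_index == 1L, , drop = FALSE],
    with_any_return = {
      keep <- unique(rows$pulse_id[rows$return_index > 0L])
      rows[rows$pulse_id %in% keep, , drop = FALSE]
    },
    no_return = rows[rows$return_index == 0L, , drop = FALSE]
  )
}
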