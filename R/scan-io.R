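#' Read a pulse-level scan from CSV
#'
#' The long CSV dialect has header
#' `pulse_id,zenith_deg,azimuth_deg,return_index,distance_m,intensity`,
#' one row per ranged return and one row with `return_index` 0 and empty
#' `distance_m`/`intensity` for each pulse that produced no return.
#'
#' @param path Path to a CSV file.
#' @param instrument An [instrument_spec()]; pulses are validated against it.
#' @param scan_id Scan identifier; defaults to the file name sans extension.
#' @param label Optional binary class label to attach.
#'
#' @return A [tls_scan()].
#' @export
read_scan_csv <- function(path, instrument = instrument_spec(),
                          scan_id = NULL, label = NA) {
  if (!file.exists(path)) stop_validation("no such file: %s", path)
  rows <- tryCatch(
    suppressWarnings(readr::read_csv(
      path,
      col_types = readr::cols(
        pulse_id = readr::col_character(),
        zenith_deg = readr::col_double(),
        azimuth_deg = readr::col_double(),
        return_index = readr::col_integer(),
        distance_m = readr::col_double(),
        intensity = readr::col_double()
      ),
      progress = FALSE
    )),
    error = function(e) stop_format("cannot parse %s: %s", path, conditionMessage(e))
  )
  missing_cols <- setdiff(scan_columns, names(rows))
  if (length(missing_cols) > 0) {
    stop_format("%s lacks required column(s): %s", path,
                paste(missing_cols, collapse = ", "))
  }
  probs <- readr::problems(rows)
  if (nrow(probs) > 0) {
    stop_format("%s: %d malformed row(s), first at line %d (%s)", path,
                nrow(probs), probs$row[1] + 1L, probs$expected[1])
  }
  tls_scan(rows,
           scan_id = scan_id %||% sub("\\.[^.]*$", "", basename(path)),
           instrument = instrument, label = label)
}

#' Write a scan to CSV
#'
#' Inverse of [read_scan_csv()]: floats are serialized with enough digits
#' that a read-back round-trips distances and angles to well below 1e-9 m.
#'
#' @param scan A [tls_scan()].
#' @param path Output path; parent directories are created.
#'
#' @return `path`, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- tibble::as_tibble(scan)[scan_columns]
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.12g", v))
  lines <- paste(
    out$pulse_id,
    fmt(out$zenith_deg),
    fmt(out$azimuth_deg),
    out$return_index,
    fmt(out$distance_m),
    fmt(out$intensity),
    sep = ","
  )
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop_computation("cannot open %s for writing", path))
  on.exit(close(con))
  writeLines(paste(scan_columns, collapse = ","), con)
  writeLines(lines, con)
  invisible(path)
}
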