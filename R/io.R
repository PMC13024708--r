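# Readers and writers for the package's delimited-text dialects. All files
# are UTF-8, comma-separated CSV with '.' decimal separator and a mandatory
# header; numeric columns are written at full double precision so every
# writer/reader pair round-trips to 15 significant digits.

read_checked_csv <- function(path, required, comment_char = "") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        comment.char = comment_char,
                        colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(path, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df
}

parse_numeric_col <- function(df, col, path, n_comment = 0) {
  x <- suppressWarnings(as.numeric(df[[col]]))
  bad <- which(is.na(x) & !(df[[col]] %in% c("NA", "")))
  if (length(bad)) {
    # +1 for the header line, + any leading comment lines
    stop(path, ": non-numeric value `", df[[col]][bad[[1]]], "` in column `",
         col, "` at line ", bad[[1]] + 1 + n_comment, call. = FALSE)
  }
  x
}

#' Read / write impedance spectra
#'
#' The spectrum dialect is a CSV with columns `device_id, day, frequency_hz,
#' z_real_ohm, z_imag_ohm`, one row per frequency. On reading, rows are
#' grouped by `(device_id, day)`, frequencies are sorted descending within
#' each sweep, and the spectrum invariants are validated; a malformed row is
#' reported with its line number.
#'
#' @param path File path.
#' @return `read_spectra()`: a long tibble; `write_spectra()`: `path`,
#'   invisibly.
#' @export
read_spectra <- function(path) {
  req <- c("device_id", "day", "frequency_hz", "z_real_ohm", "z_imag_ohm")
  df <- read_checked_csv(path, req)
  out <- tibble::tibble(
    device_id = df$device_id,
    day = as.integer(parse_numeric_col(df, "day", path)),
    frequency_hz = parse_numeric_col(df, "frequency_hz", path),
    z_real_ohm = parse_numeric_col(df, "z_real_ohm", path),
    z_imag_ohm = parse_numeric_col(df, "z_imag_ohm", path)
  )
  validate_spectrum(out)
  out |>
    dplyr::group_by(.data$device_id, .data$day) |>
    dplyr::arrange(dplyr::desc(.data$frequency_hz), .by_group = TRUE) |>
    dplyr::ungroup()
}

write_full_precision_csv <- function(df, path, append = FALSE) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE,
                                                scientific = NA))
  utils::write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double",
                     append = append, col.names = !append,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname read_spectra
#' @param spectra Long spectrum table to write.
#' @export
write_spectra <- function(spectra, path) {
  validate_spectrum(spectra)
  cols <- c("device_id", "day", "frequency_hz", "z_real_ohm", "z_imag_ohm")
  write_full_precision_csv(spectra[cols], path)
}

#' Read / write TEER record tables
#'
#' Dialect: CSV `well_id, group, day, reading_index, raw_ohm, blank_ohm,
#' area_cm2`.
#'
#' @param path File path.
#' @return `read_teer_records()`: a tibble; `write_teer_records()`: `path`,
#'   invisibly.
#' @export
read_teer_records <- function(path) {
  req <- c("well_id", "group", "day", "reading_index", "raw_ohm",
           "blank_ohm", "area_cm2")
  df <- read_checked_csv(path, req)
  tibble::tibble(
    well_id = df$well_id,
    group = df$group,
    day = as.integer(parse_numeric_col(df, "day", path)),
    reading_index = as.integer(parse_numeric_col(df, "reading_index", path)),
    raw_ohm = parse_numeric_col(df, "raw_ohm", path),
    blank_ohm = parse_numeric_col(df, "blank_ohm", path),
    area_cm2 = parse_numeric_col(df, "area_cm2", path)
  )
}

#' @rdname read_teer_records
#' @param records TEER record table to write.
#' @export
write_teer_records <- function(records, path) {
  cols <- c("well_id", "group", "day", "reading_index", "raw_ohm",
            "blank_ohm", "area_cm2")
  write_full_precision_csv(records[cols], path)
}

#' Read / write Ussing-chamber traces
#'
#' Dialect: CSV `time_s, current_a` preceded by comment headers of the form
#' `# clamp_voltage_v=0.005` and `# area_cm2=0.33`; the reader attaches
#' these as attributes on the returned tibble.
#'
#' @param path File path.
#' @return `read_ussing_trace()`: a tibble `time_s`, `current_a` with
#'   attributes `clamp_voltage_v` and `area_cm2`;
#'   `write_ussing_trace()`: `path`, invisibly.
#' @export
read_ussing_trace <- function(path) {
  lines <- readLines(path, n = 50, encoding = "UTF-8")
  comments <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (cm in comments) {
    kv <- strsplit(sub("^#\\s*", "", cm), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[[1]])]] <- as.numeric(trimws(kv[[2]]))
  }
  df <- read_checked_csv(path, c("time_s", "current_a"), comment_char = "#")
  trace <- tibble::tibble(
    time_s = parse_numeric_col(df, "time_s", path, n_comment = length(comments)),
    current_a = parse_numeric_col(df, "current_a", path,
                                  n_comment = length(comments))
  )
  if (any(diff(trace$time_s) <= 0)) {
    stop(path, ": `time_s` must be strictly increasing", call. = FALSE)
  }
  attr(trace, "clamp_voltage_v") <- meta$clamp_voltage_v %||% 5e-3
  attr(trace, "area_cm2") <- meta$area_cm2 %||% 0.33
  trace
}

#' @rdname read_ussing_trace
#' @param trace Trace tibble to write; its `clamp_voltage_v` / `area_cm2`
#'   attributes (or the arguments below) become header comments.
#' @param clamp_voltage_v,area_cm2 Metadata written to the header when the
#'   trace carries no attributes.
#' @export
write_ussing_trace <- function(trace, path, clamp_voltage_v = NULL,
                               area_cm2 = NULL) {
  v <- clamp_voltage_v %||% attr(trace, "clamp_voltage_v") %||% 5e-3
  a <- area_cm2 %||% attr(trace, "area_cm2") %||% 0.33
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# clamp_voltage_v=%s", format(v, digits = 15)),
    sprintf("# area_cm2=%s", format(a, digits = 15))
  ), con)
  close(con)
  on.exit(NULL)
  df <- trace[c("time_s", "current_a")]
  df[] <- lapply(df, function(x) format(x, digits = 15, trim = TRUE))
  suppressWarnings(
    utils::write.table(df, path, sep = ",", row.names = FALSE, append = TRUE,
                       col.names = TRUE, qmethod = "double",
                       fileEncoding = "UTF-8")
  )
  invisible(path)
}

#' Read / write calcium-switch tables
#'
#' Dialect: long CSV `replicate_id, platform, phase, value` with `phase` in
#' `baseline`, `egta`, `washout`. The reader pivots to the wide per-replicate
#' layout used by [normalize_switch()].
#'
#' @param path File path.
#' @return `read_switch_table()`: a wide tibble `replicate_id`, `platform`,
#'   `baseline`, `egta`, `washout`; `write_switch_table()`: `path`,
#'   invisibly.
#' @export
read_switch_table <- function(path) {
  req <- c("replicate_id", "platform", "phase", "value")
  df <- read_checked_csv(path, req)
  bad <- which(!df$phase %in% switch_phases)
  if (length(bad)) {
    stop(path, ": unknown phase `", df$phase[bad[[1]]], "` at line ",
         bad[[1]] + 1, call. = FALSE)
  }
  tibble::tibble(
    replicate_id = df$replicate_id,
    platform = df$platform,
    phase = df$phase,
    value = parse_numeric_col(df, "value", path)
  ) |>
    tidyr::pivot_wider(names_from = "phase", values_from = "value") |>
    dplyr::select(dplyr::all_of(c("replicate_id", "platform", switch_phases)))
}

#' @rdname read_switch_table
#' @param series Wide switch table to write.
#' @export
write_switch_table <- function(series, path) {
  long <- series |>
    tidyr::pivot_longer(dplyr::all_of(switch_phases),
                        names_to = "phase", values_to = "value") |>
    dplyr::select(dplyr::all_of(c("replicate_id", "platform", "phase",
                                  "value")))
  write_full_precision_csv(long, path)
}

#' Write a fit or trajectory report
#'
#' Writes any result tibble as full-precision CSV; with `rounded = TRUE` a
#' companion `<stem>_rounded.csv` at 2 decimals is written alongside,
#' matching presentation tables.
#'
#' @param report A tibble.
#' @param path Output CSV path.
#' @param rounded Also write the 2-decimal companion (default FALSE).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, rounded = FALSE) {
  write_full_precision_csv(report, path)
  if (rounded) {
    rr <- report
    num <- vapply(rr, is.numeric, TRUE) & !vapply(rr, is.integer, TRUE)
    rr[num] <- lapply(rr[num], round, digits = 2)
    utils::write.table(rr, sub("\\.csv$", "_rounded.csv", path), sep = ",",
                       row.names = FALSE, qmethod = "double",
                       fileEncoding = "UTF-8", col.names = TRUE)
  }
  invisible(path)
}
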