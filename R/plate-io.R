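PLATE_COLUMNS <- c("plate_id", "well", "role", "compound", "ratio",
                   "wavelength_nm", "timepoint_min", "absorbance")
PLATE_ROLES <- c("blank", "negative_control", "positive_control", "sample")

#' Construct and validate a plate reading
#'
#' The canonical in-memory representation of one microplate experiment is a
#' long-format data.frame with one row per (well, wavelength, timepoint)
#' read and columns `plate_id`, `well`, `role`, `compound`, `ratio`,
#' `wavelength_nm`, `timepoint_min`, `absorbance`. Well coordinates follow
#' the vendor convention (letter row A-H, 1-based column 1-12). Validation
#' rejects malformed well ids, unknown roles, duplicated
#' (well, wavelength, timepoint) triples and non-finite absorbances, and —
#' when `require_controls` is set, as it is for chelation plates — plates
#' without at least one negative and one positive control.
#'
#' @param data data.frame in the long plate schema.
#' @param require_controls require >= 1 negative and >= 1 positive control.
#' @return an object of classes `plate_reading` and `data.frame`.
#' @export
plate_reading <- function(data, require_controls = TRUE) {
  data <- as.data.frame(data)
  missing_cols <- setdiff(PLATE_COLUMNS, names(data))
  if (length(missing_cols))
    stop_validation("plate data is missing columns: ",
                    paste(missing_cols, collapse = ", "))
  data <- data[PLATE_COLUMNS]
  bad_well <- !grepl("^[A-H](1[0-2]|[1-9])$", data$well)
  if (any(bad_well))
    stop_validation("malformed well id in row(s) ",
                    paste(utils::head(which(bad_well), 5), collapse = ", "),
                    ": ", paste(utils::head(unique(data$well[bad_well]), 5),
                                collapse = ", "))
  bad_role <- !data$role %in% PLATE_ROLES
  if (any(bad_role))
    stop_validation("unknown role in row(s) ",
                    paste(utils::head(which(bad_role), 5), collapse = ", "))
  data$absorbance <- suppressWarnings(as.numeric(data$absorbance))
  bad_abs <- !is.finite(data$absorbance)
  if (any(bad_abs))
    stop_validation("non-numeric or non-finite absorbance in row(s) ",
                    paste(utils::head(which(bad_abs), 5), collapse = ", "))
  key <- paste(data$well, data$wavelength_nm, data$timepoint_min)
  if (anyDuplicated(key))
    stop_validation("duplicate (well, wavelength, timepoint) in row(s) ",
                    paste(utils::head(which(duplicated(key)), 5),
                          collapse = ", "))
  if (require_controls) {
    if (!any(data$role == "negative_control"))
      stop_validation("plate has no negative control wells")
    if (!any(data$role == "positive_control"))
      stop_validation("plate has no positive control wells")
  }
  rownames(data) <- NULL
  structure(data, class = c("plate_reading", "data.frame"))
}

#' @export
print.plate_reading <- function(x, ...) {
  cat(sprintf("Plate reading '%s': %d wells, %d reads\n",
              x$plate_id[1], length(unique(x$well)), nrow(x)))
  tab <- table(x$role[!duplicated(x$well)])
  cat("  wells by role:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a plate reading as long-format CSV
#'
#' `read_plate_csv()` parses and validates; `write_plate_csv()` writes the
#' same schema so that `read_plate_csv(write_plate_csv(p, f))` returns a
#' plate equal to `p`.
#'
#' @param path CSV file path.
#' @param require_controls passed to [plate_reading()].
#' @return a [plate_reading()] (reader) or `path` invisibly (writer).
#' @export
read_plate_csv <- function(path, require_controls = TRUE) {
  if (!file.exists(path)) stop_validation("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!setequal(names(raw), PLATE_COLUMNS))
    stop_validation("unexpected CSV header; expected columns ",
                    paste(PLATE_COLUMNS, collapse = ", "))
  raw$compound[is.na(raw$compound)] <- ""
  plate_reading(raw, require_controls = require_controls)
}

#' @rdname read_plate_csv
#' @param plate a [plate_reading()].
#' @export
write_plate_csv <- function(plate, path) {
  stopifnot(inherits(plate, "plate_reading"))
  utils::write.csv(as.data.frame(plate), path, row.names = FALSE)
  invisible(path)
}

#' Read / write a spectral scan (wavelength vs absorbance) CSV
#' @param path CSV path with columns `wavelength_nm`, `absorbance`.
#' @return data.frame sorted by wavelength.
#' @export
read_scan_csv <- function(path) {
  scan <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "absorbance") %in% names(scan)))
    stop_validation("scan CSV needs columns wavelength_nm, absorbance")
  scan[order(scan$wavelength_nm), c("wavelength_nm", "absorbance")]
}

#' @rdname read_scan_csv
#' @param scan data.frame with `wavelength_nm`, `absorbance`.
#' @export
write_scan_csv <- function(scan, path) {
  utils::write.csv(scan[c("wavelength_nm", "absorbance")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read / write an aggregometry trace CSV
#' @param path CSV path with columns `time_s`, `impedance`.
#' @return an [aggregation_trace()].
#' @export
read_trace_csv <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "impedance") %in% names(tr)))
    stop_validation("trace CSV needs columns time_s, impedance")
  aggregation_trace(tr$time_s, tr$impedance)
}

#' @rdname read_trace_csv
#' @param trace an [aggregation_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "aggregation_trace"))
  utils::write.csv(data.frame(time_s = trace$time_s,
                              impedance = trace$impedance),
                   path, row.names = FALSE)
  invisible(path)
}

#' Chelator metadata record
#'
#' @param name compound name.
#' @param solvent `"water"` or `"DMSO"`.
#' @param pKa optional acid constant of the chelating hydroxyl (externally
#'   computed; an input here, never derived).
#' @param conc_range tested final concentration range (M), two values; the
#'   default bounds reflect the screen's usual 270 uM - 25 mM span.
#' @return an object of class `chelator_record`.
#' @export
chelator_record <- function(name, solvent = c("water", "DMSO"), pKa = NULL,
                            conc_range = c(2.7e-4, 2.5e-2)) {
  solvent <- match.arg(solvent)
  if (length(conc_range) != 2L || any(conc_range <= 0) ||
      conc_range[1] > conc_range[2])
    stop_validation("conc_range must be two increasing positive values")
  structure(list(name = name, solvent = solvent,
                 pKa = if (is.null(pKa)) NA_real_ else as.numeric(pKa),
                 conc_range = conc_range),
            class = "chelator_record")
}
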