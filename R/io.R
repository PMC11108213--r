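#' Read a spectrum from CSV
#'
#' Tolerant reader for two-column wavelength/intensity traces, including
#' spreadsheet exports: accepts arbitrary column names (first two numeric
#' columns are used), comma or semicolon separators, and leading junk
#' lines; rows with non-numeric entries are dropped and the trace is
#' sorted by wavelength.
#'
#' @param path CSV file path.
#' @return A `spectrum_trace`.
#' @export
read_spectrum_csv <- function(path) {
  raw <- tryCatch(
    readr::read_delim(path, delim = ",", show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) NULL)
  if (is.null(raw) || ncol(raw) < 2)
    raw <- readr::read_delim(path, delim = ";", show_col_types = FALSE,
                             progress = FALSE)
  num <- raw |> dplyr::select(dplyr::where(is.numeric))
  if (ncol(num) < 2) {
    num <- raw |>
      dplyr::mutate(dplyr::across(dplyr::everything(),
                                  ~ suppressWarnings(as.numeric(.x)))) |>
      dplyr::select(dplyr::where(~ !all(is.na(.x))))
  }
  if (ncol(num) < 2) stop("no two numeric columns found in ", path, call. = FALSE)
  df <- tibble::tibble(wavelength_nm = num[[1]], intensity = num[[2]]) |>
    dplyr::filter(is.finite(.data$wavelength_nm), is.finite(.data$intensity)) |>
    dplyr::arrange(.data$wavelength_nm) |>
    dplyr::distinct(.data$wavelength_nm, .keep_all = TRUE)
  spectrum_trace(df$wavelength_nm, df$intensity, meta = list(source = path))
}

#' Write a spectrum to CSV
#' @param trace A `spectrum_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(trace, path) {
  readr::write_csv(tibble::tibble(wavelength_nm = trace$wavelength_nm,
                                  intensity = trace$intensity), path)
  invisible(path)
}

#' Read an assay table from CSV
#'
#' Expects the tidy AssayTable layout (`arm`, `group`, `replicate`,
#' `assay`, `value`) but tolerates spreadsheet-export variants: column
#' names are matched case-insensitively with common synonyms
#' (`treatment` / `condition` for arm, `duration` / `time` for group,
#' `rep` for replicate, `measurement` / `absorbance` / `od` for value),
#' and group labels like `"240 s"` are normalized to `"240"`.
#'
#' @param path CSV file path.
#' @return An `assay_table` tibble.
#' @export
read_assay_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- tolower(names(raw))
  pick <- function(cands) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) NULL else raw[[i]]
  }
  arm <- pick(c("arm", "treatment", "condition", "supply"))
  group <- pick(c("group", "duration", "time", "exposure"))
  repl <- pick(c("replicate", "rep", "sample"))
  assay <- pick(c("assay", "measurement_type", "type"))
  value <- pick(c("value", "measurement", "absorbance", "od", "area"))
  if (is.null(group) || is.null(value))
    stop("could not identify group/value columns in ", path, call. = FALSE)
  out <- tibble::tibble(
    arm = if (is.null(arm)) "AC" else as.character(arm),
    group = sub("\\s*s(ec(onds)?)?$", "", trimws(as.character(group))),
    replicate = if (is.null(repl)) {
      stats::ave(seq_along(value), paste(arm, group), FUN = seq_along)
    } else as.integer(repl),
    assay = if (is.null(assay)) "value" else as.character(assay),
    value = as.numeric(value)
  )
  if (any(out$value < 0, na.rm = TRUE))
    stop("assay values must be nonnegative", call. = FALSE)
  class(out) <- c("assay_table", class(out))
  out
}

#' Write an assay table to CSV
#' @param table An `assay_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(table, path) {
  readr::write_csv(as.data.frame(table), path)
  invisible(path)
}

#' Export a flow field as a CSV grid
#' @param field A `flow_field`.
#' @param path Output path (columns r, z, u_r, u_z, p).
#' @return `path`, invisibly.
#' @export
write_flow_csv <- function(field, path) {
  readr::write_csv(tibble::tibble(r = field$r_m, z = field$z_m,
                                  u_r = field$u_r, u_z = field$u_z,
                                  p = field$p_Pa), path)
  invisible(path)
}
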