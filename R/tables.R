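# CSV interchange (comma separated, UTF-8, '.' decimal) and key=value config.

cilia_csv_columns <- c("id", "section_id", "region_label", "hemisphere", "zt",
                       "length_um", "width_um", "angle_deg",
                       "base_x", "base_y", "centroid_x", "centroid_y")

#' Write per-cilium records to CSV
#'
#' One row per detected cilium with the fixed column set
#' `id, section_id, region_label, hemisphere, zt, length_um, width_um,
#' angle_deg, base_x, base_y, centroid_x, centroid_y`.  An empty record set
#' yields a header-only file.
#'
#' @param records data.frame of cilium records (as from [detect_cilia()]).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cilia_csv <- function(records, path) {
  df <- as.data.frame(records)
  if (nrow(df) == 0L) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cilia_csv_columns)),
                                 cilia_csv_columns))
  }
  missing <- setdiff(cilia_csv_columns, names(df))
  for (m in missing) df[[m]] <- NA
  utils::write.csv(df[cilia_csv_columns], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read per-cilium records from CSV
#'
#' @param path file written by [write_cilia_csv()].
#' @return data.frame with the standard cilium columns.
#' @export
read_cilia_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(cilia_csv_columns, names(df))
  if (length(missing)) stop("missing columns: ", paste(missing, collapse = ", "))
  df
}

#' Write detected-cell records to CSV
#'
#' @param records data.frame of cell records (as from [detect_cells()]).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(records, path) {
  cols <- c("id", "centroid_x", "centroid_y", "area_px2", "perimeter_px",
            "circularity")
  df <- as.data.frame(records)
  if (nrow(df) == 0L) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  utils::write.csv(df[cols], path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Values that parse
#' as numbers become numeric, `true`/`false` become logical, everything else
#' stays character.  Used to carry `pixel_size_um`, detection thresholds and
#' the RNG seed across CLI invocations.
#'
#' @param path path to the configuration file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) {
      out[[key]] <- num
    } else if (tolower(val) %in% c("true", "false")) {
      out[[key]] <- tolower(val) == "true"
    } else {
      out[[key]] <- val
    }
  }
  out
}
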