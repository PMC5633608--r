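STATION_SCHEMA <- c(lat = "numeric", lon = "numeric", date = "character",
                    sst_c = "numeric", chl_mgm3 = "numeric",
                    par_mol_m2_d = "numeric", k490_m1 = "numeric",
                    zeu_m = "numeric", pro_cells_ml = "numeric",
                    syn_cells_ml = "numeric", euk_cells_ml = "numeric",
                    pp14c = "numeric")
STATION_MANDATORY <- "sst_c"

#' Read and write station tables
#'
#' The canonical station CSV schema, with units spelled out in the column
#' names: `lat`, `lon`, `date` (ISO), `sst_c` (degrees C), `chl_mgm3`
#' (mg m^-3), `par_mol_m2_d` (mol photons m^-2 d^-1), `k490_m1` (m^-1),
#' `zeu_m` (m), `pro_cells_ml` / `syn_cells_ml` / `euk_cells_ml`
#' (cells mL^-1), `pp14c` (measured production, mg C m^-3 d^-1). Empty cells
#' are missing values; there is no other missing-value sentinel. Columns may
#' appear in any order and may be omitted (they are filled with missing
#' values), but unknown columns are rejected rather than silently misread —
#' in particular an estimation *output* file is not a valid input.
#'
#' @param path Path to a CSV file.
#' @return `read_stations()`: a station data frame with all schema columns.
#' @export
read_stations <- function(path) {
  if (!file.exists(path)) stop("cannot read station file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = "", check.names = FALSE)
  unknown <- setdiff(names(df), names(STATION_SCHEMA))
  if (length(unknown))
    stop("schema mismatch in ", path, ": unknown column(s) ",
         paste(unknown, collapse = ", "),
         "; expected a subset of: ", paste(names(STATION_SCHEMA), collapse = ", "))
  absent <- setdiff(STATION_MANDATORY, names(df))
  if (length(absent))
    stop("schema error in ", path, ": missing mandatory column(s) ",
         paste(absent, collapse = ", "))
  for (col in names(STATION_SCHEMA)) {
    if (!col %in% names(df)) {
      df[[col]] <- if (STATION_SCHEMA[[col]] == "numeric") NA_real_ else NA_character_
    } else if (STATION_SCHEMA[[col]] == "numeric") {
      suppressWarnings(v <- as.numeric(df[[col]]))
      if (any(is.na(v) & !is.na(df[[col]])))
        stop("schema error in ", path, ": non-numeric values in column ", col)
      df[[col]] <- v
    } else {
      df[[col]] <- as.character(df[[col]])
    }
  }
  df[, names(STATION_SCHEMA)]
}

#' @rdname read_stations
#' @param x A station data frame.
#' @return `write_stations()`: the path, invisibly. The write/read/write
#'   round trip is byte-stable.
#' @export
write_stations <- function(x, path) {
  x <- as.data.frame(x)
  for (col in names(STATION_SCHEMA)) if (!col %in% names(x)) x[[col]] <- NA
  utils::write.csv(x[, names(STATION_SCHEMA)], path, row.names = FALSE, na = "")
  invisible(path)
}
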