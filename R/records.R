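#' Tooth record tables
#'
#' Tooth-level data are flat tables with one row per tooth:
#' `context_id` (the analysis unit, e.g. a site phase), optional `site_id`,
#' `tooth` (one of the stage map's tooth codes, e.g. dP4/M1/M2/M3/M12),
#' `wear_stage`, and optional measurements `crown_height_mm`, `dap_mm`
#' (mesio-distal crown length) and `dt_mm` (bucco-lingual breadth), blank
#' when not taken.
#'
#' @name tooth_records
NULL

REQUIRED_RECORD_COLS <- c("context_id", "tooth", "wear_stage")
MEASURE_COLS <- c("crown_height_mm", "dap_mm", "dt_mm")

#' Construct and validate a tooth-record table
#'
#' @param df data.frame with at least `context_id`, `tooth`, `wear_stage`;
#'   optional `site_id` and measurement columns (`crown_height_mm`,
#'   `dap_mm`, `dt_mm`).
#' @param scheme the [age_class_scheme()] in use.
#' @param map the [wear_stage_map()] against which tooth codes and wear
#'   stages are validated; every record must admit at least one age class.
#' @return A `tooth_records` data.frame with standardized columns.
#' @export
tooth_records <- function(df, scheme, map) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(REQUIRED_RECORD_COLS, names(df))
  if (length(miss))
    stop("tooth records missing column(s): ", paste(miss, collapse = ", "))
  if (!"site_id" %in% names(df))
    df$site_id <- rep(NA_character_, nrow(df))
  for (m in MEASURE_COLS) {
    if (!m %in% names(df)) df[[m]] <- rep(NA_real_, nrow(df))
    df[[m]] <- suppressWarnings(as.numeric(df[[m]]))
  }
  df$context_id <- as.character(df$context_id)
  df$site_id <- as.character(df$site_id)
  df$tooth <- as.character(df$tooth)
  df$wear_stage <- as.character(df$wear_stage)

  bad_ctx <- which(is.na(df$context_id) | df$context_id == "")
  if (length(bad_ctx))
    stop(sprintf("row %d: missing context_id", bad_ctx[1L]))
  bad_tooth <- which(!df$tooth %in% map_teeth(map))
  if (length(bad_tooth))
    stop(sprintf("row %d: unknown tooth code '%s'",
                 bad_tooth[1L], df$tooth[bad_tooth[1L]]))
  key <- paste(df$tooth, df$wear_stage, sep = "\r")
  map_key <- paste(map$tooth, map$wear_stage, sep = "\r")
  bad_stage <- which(!key %in% map_key)
  if (length(bad_stage))
    stop(sprintf(
      "row %d: wear stage '%s' has no stage-map entry for tooth '%s'",
      bad_stage[1L], df$wear_stage[bad_stage[1L]], df$tooth[bad_stage[1L]]))
  for (m in MEASURE_COLS) {
    bad <- which(!is.na(df[[m]]) & df[[m]] <= 0)
    if (length(bad))
      stop(sprintf("row %d: non-positive %s", bad[1L], m))
  }
  df <- df[c("context_id", "site_id", "tooth", "wear_stage", MEASURE_COLS)]
  class(df) <- c("tooth_records", "data.frame")
  df
}

#' Read tooth records from CSV
#'
#' Reads a one-row-per-tooth CSV (columns `context_id`, `site_id`, `tooth`,
#' `wear_stage`, `crown_height_mm`, `dap_mm`, `dt_mm`; blank = missing) and
#' validates every row against the scheme and stage map. Errors name the
#' offending data row.
#'
#' @param path path to the CSV file.
#' @inheritParams tooth_records
#' @param quiet suppress the row-count message.
#' @return A `tooth_records` data.frame.
#' @export
read_tooth_records <- function(path, scheme, map, quiet = FALSE) {
  if (!file.exists(path)) stop("tooth record file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  rec <- tooth_records(df, scheme, map)
  if (!quiet)
    message(sprintf("read %d tooth records over %d context(s) from %s",
                    nrow(rec), length(unique(rec$context_id)), path))
  rec
}

#' Write tooth records to CSV
#' @param records a `tooth_records` data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tooth_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Discriminate first from second molars on crown dimensions
#'
#' Isolated lower M1 and M2 are morphologically similar; they are told apart
#' on crown size, M1 being the smaller tooth. A tooth is called M1 when both
#' the mesio-distal length (DAP) and the bucco-lingual breadth (DT) fall
#' below their cutoffs, M2 when both lie above, and `M12` (undiscriminated)
#' when the two measurements disagree or either is missing. No default
#' cutoffs are applied: thresholds are assemblage-specific and must be
#' supplied by the analyst.
#'
#' @param dap mesio-distal crown length, mm.
#' @param dt bucco-lingual crown breadth, mm.
#' @param thresholds list or named numeric with elements `dap` and `dt`:
#'   the cutoffs (mm) separating M1 (below) from M2 (above).
#' @return `"M1"`, `"M2"` or `"M12"` (vectorized over `dap`/`dt`).
#' @export
classify_molar <- function(dap, dt, thresholds) {
  if (is.null(thresholds$dap) || is.null(thresholds$dt))
    stop("thresholds must supply both 'dap' and 'dt' cutoffs")
  n <- max(length(dap), length(dt))
  dap <- rep_len(as.numeric(dap), n)
  dt <- rep_len(as.numeric(dt), n)
  bad <- which(!is.na(dap) & dap <= 0 | !is.na(dt) & dt <= 0)
  if (length(bad))
    stop("non-positive measurement at position ", bad[1L])
  out <- rep("M12", n)
  missing <- is.na(dap) | is.na(dt)
  if (any(missing))
    warning(sum(missing), " tooth/teeth with missing DAP or DT left as M12")
  below <- !missing & dap < thresholds$dap & dt < thresholds$dt
  above <- !missing & dap > thresholds$dap & dt > thresholds$dt
  out[below] <- "M1"
  out[above] <- "M2"
  out
}
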