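# File-format dialects: the canonical call-table CSV (with DeepSqueak
# export headers accepted as aliases on import), cohort CSVs, and JSON
# reports. Units are fixed throughout: seconds, kHz, ms, dB; intervals are
# half-open [t_start, t_end).

CALL_TABLE_COLUMNS <- c(
  "call_id", "mouse_id", "test_type", "channel", "begin_s", "end_s",
  "low_khz", "high_khz", "mean_khz", "range_khz", "duration_ms", "power_db",
  "slope_khz_per_s", "n_inflections", "category", "complexity"
)

# DeepSqueak export header -> canonical column
DEEPSQUEAK_ALIASES <- c(
  "Begin Time (s)" = "begin_s",
  "End Time (s)" = "end_s",
  "Low Freq (kHz)" = "low_khz",
  "High Freq (kHz)" = "high_khz",
  "Call Length (s)" = "call_length_s",
  "Slope (kHz/s)" = "slope_khz_per_s",
  "Mean Power (dB/Hz)" = "power_db"
)

#' Write a call table CSV
#'
#' Writes the canonical call-table dialect (columns `call_id, mouse_id,
#' test_type, channel, begin_s, end_s, low_khz, high_khz, mean_khz,
#' range_khz, duration_ms, power_db, slope_khz_per_s, n_inflections,
#' category, complexity`). Internal call data.frames (with `t_start`,
#' `f_min`, ... names) are mapped automatically; missing fields are written
#' empty. Contour list-columns are not serialized. Extra columns (e.g.
#' ground-truth `true_category`) are appended after the canonical set.
#'
#' @param calls Call data.frame.
#' @param path Output CSV path.
#' @param extra_columns Additional columns of `calls` to append.
#' @return `path`, invisibly.
#' @export
write_call_table <- function(calls, path, extra_columns = character()) {
  internal_map <- c(t_start = "begin_s", t_end = "end_s", f_min = "low_khz",
                    f_max = "high_khz", f_mean = "mean_khz",
                    f_range = "range_khz", slope = "slope_khz_per_s")
  for (from in names(internal_map)) {
    to <- internal_map[[from]]
    if (is.null(calls[[to]]) && !is.null(calls[[from]])) {
      calls[[to]] <- calls[[from]]
    }
  }
  out <- data.frame(row.names = seq_len(nrow(calls)))
  for (col in c(CALL_TABLE_COLUMNS, extra_columns)) {
    out[[col]] <- calls[[col]] %||% rep(NA, nrow(calls))
  }
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a call table CSV
#'
#' Accepts the canonical dialect written by [write_call_table()] as well as
#' DeepSqueak export headers (`Begin Time (s)`, `End Time (s)`,
#' `Low Freq (kHz)`, `High Freq (kHz)`, `Call Length (s)`, `Slope (kHz/s)`,
#' `Mean Power (dB/Hz)`), which are mapped onto the canonical columns;
#' `Call Length (s)` is converted to `duration_ms`. Derived columns that
#' are absent or empty are recomputed where possible (`mean_khz`,
#' `range_khz`, `duration_ms`).
#'
#' @param path CSV path.
#' @return Call data.frame in canonical columns (plus any extra columns).
#' @export
read_call_table <- function(path) {
  raw <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
  nm <- names(raw)
  hit <- nm %in% names(DEEPSQUEAK_ALIASES)
  nm[hit] <- DEEPSQUEAK_ALIASES[nm[hit]]
  names(raw) <- nm
  if (!is.null(raw$call_length_s)) {
    if (is.null(raw$duration_ms)) raw$duration_ms <- raw$call_length_s * 1000
    raw$call_length_s <- NULL
  }
  if (is.null(raw$begin_s) || is.null(raw$end_s)) {
    stop("call table lacks begin/end time columns: ", path, call. = FALSE)
  }
  fill <- function(col, value) {
    if (is.null(raw[[col]]) || all(is.na(raw[[col]]))) raw[[col]] <<- value
  }
  if (!is.null(raw$low_khz) && !is.null(raw$high_khz)) {
    fill("mean_khz", (raw$low_khz + raw$high_khz) / 2)
    fill("range_khz", raw$high_khz - raw$low_khz)
  }
  fill("duration_ms", (raw$end_s - raw$begin_s) * 1000)
  raw
}

#' Write / read a cohort table CSV
#'
#' One row per mouse: `mouse_id`, `genotype`, then numeric measure columns.
#'
#' @param table Cohort data.frame.
#' @param path CSV path.
#' @return `path` (write) or the cohort data.frame (read).
#' @export
write_cohort_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(out$mouse_id) || is.null(out$genotype)) {
    stop("cohort table needs mouse_id and genotype columns: ", path,
         call. = FALSE)
  }
  out
}

#' Write a JSON report
#'
#' Serializes a statistics or severity result to JSON with scalars
#' unboxed and full numeric precision.
#'
#' @param x A list (e.g. of test results) or `usv_severity` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json_report <- function(x, path) {
  if (inherits(x, "usv_severity")) {
    x <- list(
      measures = x$measures,
      explained_variance = x$explained_variance,
      loadings = apply(x$loadings, 2L, identity, simplify = FALSE),
      scores = cbind(data.frame(mouse_id = x$mouse_id %||% NA,
                                genotype = x$genotypes,
                                cluster = x$clusters),
                     as.data.frame(x$scores)),
      accuracy = x$accuracy,
      centroid_WT = x$centroid_WT,
      centroid_AS = x$centroid_AS,
      centroid_distance = x$centroid_distance
    )
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
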