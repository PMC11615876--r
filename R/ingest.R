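# Ingestion and repair of the standard study tables.

default_schema <- function() {
  list(
    cgm = c("patient_id", "timestamp", "glucose_mgdl"),
    meals = c("patient_id", "meal_id", "timestamp", "meal_type", "calories",
              "carbs_g", "protein_g", "fat_g", "fiber_g", "glycemic_index",
              "glycemic_load"),
    activity = c("patient_id", "timestamp", "steps", "active_minutes",
                 "sedentary_minutes"),
    sleep = c("patient_id", "date", "sleep_minutes", "efficiency")
  )
}

parse_iso <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC",
                    origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(strptime(x[todo], fmt, tz = "UTC"))
  }
  out
}

#' Load a study dataset from disk
#'
#' Reads the CSV/JSON tables written by [write_dataset()] (or any files in
#' the same dialect), validates each table against the expected schema, and
#' parses timestamps. Rows whose timestamp cannot be parsed are dropped and
#' reported; a missing required column is a hard schema error naming the
#' column.
#'
#' @param dir Directory holding cgm.csv, meals.csv, activity.csv, sleep.csv,
#'   profiles.json (and optionally truth_ppgr.csv).
#' @param schema Named list of required columns per table; see
#'   `default_schema()` internals for the default.
#' @return A list of typed data.tables (class `glyco_rawdata`) with a
#'   `row_errors` attribute listing dropped rows.
#' @export
load_dataset <- function(dir, schema = default_schema()) {
  read_one <- function(name) {
    path <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(path)) stop_schema(sprintf("missing file: %s", path))
    dt <- data.table::fread(path)
    missing_cols <- setdiff(schema[[name]], names(dt))
    if (length(missing_cols)) {
      stop_schema(sprintf("table '%s' lacks required column(s): %s",
                          name, paste(missing_cols, collapse = ", ")))
    }
    dt
  }
  row_errors <- list()
  out <- list()
  for (name in c("cgm", "meals", "activity")) {
    dt <- read_one(name)
    ts <- suppressWarnings(parse_iso(dt$timestamp))
    bad <- which(is.na(ts))
    if (length(bad)) {
      row_errors[[name]] <- data.table(table = name, row = bad,
                                       value = as.character(dt$timestamp[bad]),
                                       reason = "unparseable timestamp")
      dt <- dt[-bad]
      ts <- ts[-bad]
    }
    dt[, timestamp := ts]
    out[[name]] <- dt
  }
  out$sleep <- read_one("sleep")
  out$sleep[, date := as.Date(date)]
  prof_path <- file.path(dir, "profiles.json")
  if (!file.exists(prof_path)) stop_schema("missing file: profiles.json")
  out$profiles <- data.table::as.data.table(jsonlite::read_json(
    prof_path, simplifyVector = TRUE))
  truth_path <- file.path(dir, "truth_ppgr.csv")
  if (file.exists(truth_path)) {
    out$truth <- data.table::fread(truth_path)
    out$truth[, timestamp := parse_iso(timestamp)]
  }
  data.table::setorder(out$cgm, patient_id, timestamp)
  out$cgm[, quality_flag := if ("quality_flag" %in% names(out$cgm))
    quality_flag else "ok"]
  attr(out, "row_errors") <- data.table::rbindlist(row_errors)
  class(out) <- c("glyco_rawdata", "list")
  out
}

#' Flag CGM outliers by robust rolling z-score
#'
#' A Hampel-style impulse detector. Each sample is scored by its deviation
#' from a short rolling median (over `window` samples), in units of the
#' trace's sensor-noise scale estimated robustly from first differences
#' (MAD(diff)/sqrt(2), which smooth physiological trends barely perturb);
#' samples with robust z above `z_threshold` are flagged. Values are never
#' altered or deleted, only flagged, so the operation is idempotent, and a
#' lower threshold always flags a superset. The window is deliberately short
#' (default 3: the sample and its two neighbours): a sensor impulse deviates
#' from both neighbours by its full magnitude, while a sampled smooth
#' postprandial peak sits within one inter-sample step of its nearest
#' neighbour — a long window would lag genuine meal rises and flag real
#' peaks.
#'
#' @param trace data.table with timestamp, glucose_mgdl and (optionally)
#'   quality_flag, one patient, time-ordered.
#' @param window Rolling window length in samples (odd; >= 3).
#' @param z_threshold Robust z-score cutoff.
#' @return The trace with quality_flag set to "outlier" where flagged.
#' @export
flag_outliers <- function(trace, window = 3, z_threshold = 5) {
  if (window < 3) stop_invalid_config("window must be >= 3 samples")
  trace <- data.table::copy(trace)
  if (!"quality_flag" %in% names(trace)) trace[, quality_flag := "ok"]
  k <- if (window %% 2 == 0) window + 1 else window
  x <- trace$glucose_mgdl
  if (length(x) < k) k <- max(3, length(x) - (1 - length(x) %% 2))
  med <- stats::runmed(x, k, endrule = "median")
  dev <- abs(x - med)
  scale <- 1.4826 * median(abs(diff(x))) / sqrt(2)  # sensor-noise estimate
  z <- dev / pmax(scale, 1)  # 1 mg/dL floor guards constant traces
  trace[z > z_threshold & quality_flag != "imputed", quality_flag := "outlier"]
  trace[]
}

#' Fill short CGM gaps by linear interpolation
#'
#' Interior gaps no longer than `max_gap` minutes are filled on the sensor
#' grid and flagged "imputed"; longer gaps are left missing and endpoints are
#' never extrapolated.
#'
#' @param trace One patient's time-ordered CGM data.table.
#' @param max_gap Longest gap to fill, minutes.
#' @param interval Sensor interval, minutes; inferred from the modal timestamp
#'   spacing when NULL.
#' @return The trace with imputed rows inserted.
#' @export
interpolate_gaps <- function(trace, max_gap = 30, interval = NULL) {
  if (!nrow(trace)) stop_insufficient_data("empty trace")
  trace <- data.table::copy(trace)
  if (!"quality_flag" %in% names(trace)) trace[, quality_flag := "ok"]
  data.table::setorder(trace, timestamp)
  if (nrow(trace) < 2) return(trace[])
  d <- as.numeric(diff(trace$timestamp), units = "mins")
  if (is.null(interval)) {
    interval <- as.numeric(names(sort(table(d), decreasing = TRUE))[1])
  }
  gaps <- which(d > interval + 1e-9 & d <= max_gap)
  if (!length(gaps)) return(trace[])
  fills <- lapply(gaps, function(i) {
    t1 <- trace$timestamp[i]; t2 <- trace$timestamp[i + 1]
    tt <- seq(t1 + interval * 60, t2 - interval * 60, by = interval * 60)
    if (!length(tt)) return(NULL)
    g <- stats::approx(as.numeric(c(t1, t2)),
                       c(trace$glucose_mgdl[i], trace$glucose_mgdl[i + 1]),
                       xout = as.numeric(tt))$y
    data.table(patient_id = trace$patient_id[i], timestamp = tt,
               glucose_mgdl = g, quality_flag = "imputed")
  })
  out <- rbindlist(c(list(trace), fills), use.names = TRUE, fill = TRUE)
  data.table::setorder(out, timestamp)
  out[]
}

#' Clean every CGM trace in a dataset
#'
#' Applies [flag_outliers()] and [interpolate_gaps()] per patient and
#' assembles a cleaning report (counts of flagged and imputed samples).
#' Flagged outliers are retained but carry quality_flag "outlier" so that
#' downstream feature extraction can exclude them.
#'
#' @param dataset A `glyco_dataset` or `glyco_rawdata` list with a cgm table.
#' @param window,z_threshold Passed to [flag_outliers()].
#' @param max_gap Passed to [interpolate_gaps()].
#' @param report_path Optional path for cleaning_report.json.
#' @return The dataset with a cleaned cgm table and a `cleaning_report`
#'   attribute.
#' @export
clean_cgm <- function(dataset, window = 3, z_threshold = 5, max_gap = 30,
                      report_path = NULL) {
  cgm <- dataset$cgm
  cleaned <- rbindlist(lapply(split(cgm, by = "patient_id"), function(tr) {
    tr <- flag_outliers(tr, window = window, z_threshold = z_threshold)
    interpolate_gaps(tr, max_gap = max_gap,
                     interval = dataset$config$cgm_interval)
  }), use.names = TRUE, fill = TRUE)
  report <- list(
    n_samples = nrow(cleaned),
    n_flagged_outlier = cleaned[quality_flag == "outlier", .N],
    n_imputed = cleaned[quality_flag == "imputed", .N],
    window = window, z_threshold = z_threshold, max_gap = max_gap
  )
  if (!is.null(report_path)) {
    jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  }
  dataset$cgm <- cleaned
  attr(dataset, "cleaning_report") <- report
  dataset
}
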