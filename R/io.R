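#' Read a long-format timecourse CSV
#'
#' Expected columns: `solvent_code`, `replicate`, a time column (`time_h`
#' in hours or `time_min` in minutes, converted on read), and either
#' `concentration_mg_ml` or `absorbance` (+ optional `dilution`, default
#' 1, in which case a calibration curve is required to convert). Extra
#' columns (e.g. `sample_id`) are ignored. Validation is strict: a
#' missing required column, a non-numeric cell or a duplicated
#' (solvent, replicate, time) triple is a hard error naming the offending
#' row.
#'
#' @param path CSV path.
#' @param calib A [calibration_curve()], required when the file carries
#'   absorbances instead of concentrations.
#' @return A [concentration_records()] frame.
#' @export
read_timecourse <- function(path, calib = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need_num <- function(col) {
    x <- df[[col]]
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !(is.na(x) | x == ""))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at data row %d ('%s')",
                   col, bad[1], x[bad[1]]), call. = FALSE)
    }
    if (anyNA(v)) {
      stop(sprintf("missing value in column '%s' at data row %d",
                   col, which(is.na(v))[1]), call. = FALSE)
    }
    v
  }
  for (col in c("solvent_code", "replicate")) {
    if (!col %in% names(df)) stop("missing column: ", col, call. = FALSE)
  }
  time_h <- if ("time_h" %in% names(df)) need_num("time_h")
            else if ("time_min" %in% names(df)) need_num("time_min") / 60
            else stop("missing column: time_h (or time_min)", call. = FALSE)

  dup <- duplicated(data.frame(df$solvent_code, df$replicate, time_h))
  if (any(dup)) {
    stop(sprintf("duplicate (solvent, replicate, time) at data row %d (%s, rep %s, t = %g h)",
                 which(dup)[1], df$solvent_code[which(dup)[1]],
                 df$replicate[which(dup)[1]], time_h[which(dup)[1]]),
         call. = FALSE)
  }

  if ("concentration_mg_ml" %in% names(df)) {
    conc <- need_num("concentration_mg_ml")
  } else if ("absorbance" %in% names(df)) {
    if (is.null(calib)) {
      stop("file carries absorbances: a calibration curve is required",
           call. = FALSE)
    }
    dil <- if ("dilution" %in% names(df)) need_num("dilution") else 1
    conc <- as.numeric(absorbance_to_concentration(need_num("absorbance"),
                                                   calib, dil))
  } else {
    stop("missing column: concentration_mg_ml (or absorbance)", call. = FALSE)
  }
  concentration_records(df$solvent_code, need_num("replicate"), time_h, conc)
}

#' Read a flat key/value configuration file
#'
#' Minimal `key: value` text format (a strict subset of YAML): one entry
#' per line, `#` comments, comma-separated values become vectors, numeric
#' strings become numbers. Nested structures are deliberately unsupported.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln, call. = FALSE)
    vals <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(vals))
    out[[m[2]]] <- if (!anyNA(num)) num else vals
  }
  out
}

#' Build plan and calibration from a configuration list
#'
#' Recognised keys: `sampling_times_h` or `sampling_times_min`,
#' `acceptor_volume_ml`, `sampled_volume_ml`, `replacement_mode`,
#' `exposure_area_cm2`, `donor_volume_ml`, `donor_concentration_mg_ml`,
#' `dilution_factors`, and calibration `calibration_slope`,
#' `calibration_intercept`, `calibration_range_ug_ml`.
#'
#' @param cfg A list from [read_config()].
#' @return List with `plan` ([sampling_plan()]) and `calib`
#'   ([calibration_curve()] or NULL when no calibration keys are present).
#' @export
config_to_plan <- function(cfg) {
  get1 <- function(key, default = NULL) {
    if (!is.null(cfg[[key]])) cfg[[key]] else default
  }
  times <- if (!is.null(cfg$sampling_times_h)) cfg$sampling_times_h
           else if (!is.null(cfg$sampling_times_min)) cfg$sampling_times_min / 60
           else stop("config must set sampling_times_h or sampling_times_min",
                     call. = FALSE)
  plan <- sampling_plan(
    sampling_times = times,
    acceptor_volume = get1("acceptor_volume_ml") %||%
      stop("config must set acceptor_volume_ml (no default: receptor volumes are cell-specific)",
           call. = FALSE),
    sampled_volume = get1("sampled_volume_ml", get1("acceptor_volume_ml")),
    replacement_mode = get1("replacement_mode", "full_replacement"),
    exposure_area = get1("exposure_area_cm2") %||%
      stop("config must set exposure_area_cm2", call. = FALSE),
    donor_volume = get1("donor_volume_ml") %||%
      stop("config must set donor_volume_ml", call. = FALSE),
    donor_concentration = get1("donor_concentration_mg_ml") %||%
      stop("config must set donor_concentration_mg_ml", call. = FALSE),
    dilution_factors = get1("dilution_factors", 1))
  calib <- NULL
  if (!is.null(cfg$calibration_slope)) {
    calib <- calibration_curve(
      slope = cfg$calibration_slope,
      intercept = get1("calibration_intercept", 0),
      valid_range = get1("calibration_range_ug_ml", c(0, Inf)))
  }
  list(plan = plan, calib = calib)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial rolling hash (mod 2^31 - 1) over the deparsed object: a cheap,
# dependency-free content fingerprint for run-log provenance (not crypto).
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write an analysis report
#'
#' CSV output uses a fixed column order mirroring the standard per-solvent
#' summary layout; JSON output wraps the same content in a versioned
#' schema with run provenance (config hash and seed).
#'
#' @param metrics Per-solvent summary frame (see [summarize_replicates()]);
#'   may have zero rows (a valid header-only report is written).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param comparisons Optional list of comparison results (regression
#'   summaries, concordance frames) for the JSON report.
#' @param config,seed Optional provenance recorded in the JSON report.
#' @return `path`, invisibly.
#' @export
write_report <- function(metrics, path, format = c("csv", "json"),
                         comparisons = NULL, config = NULL, seed = NULL) {
  format <- match.arg(format)
  cols <- c("code", "C_D_mg_ml", "J_mean", "J_sd", "lag_min_mean",
            "lag_min_sd", "Q_mean", "Q_sd", "auc_norm_mean", "logPm_mean",
            "logPm_sd", "n", "perm_class", "flags")
  if (nrow(metrics) == 0L) {
    metrics <- as.data.frame(stats::setNames(
      lapply(cols, function(x) vector(mode = "character", length = 0L)), cols))
  } else {
    missing_cols <- setdiff(cols, names(metrics))
    for (mc in missing_cols) metrics[[mc]] <- NA
    metrics <- metrics[, cols]
  }
  if (format == "csv") {
    utils::write.csv(metrics, path, row.names = FALSE)
  } else {
    payload <- list(schema_version = "1.0",
                    config_hash = config_hash(config),
                    seed = seed, metrics = metrics)
    if (!is.null(comparisons)) {
      payload$comparisons <- lapply(comparisons, function(x) {
        if (inherits(x, "regression_summary")) x[c("slope", "intercept", "r_squared", "n", "excluded")]
        else x
      })
    }
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
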