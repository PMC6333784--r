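#' Long-format trace table
#'
#' The canonical on-disk representation of a set of kinetic traces: one row
#' per (condition, replicate, time point) with the per-condition metadata
#' repeated on every row.  Construct from [kinetic_trace] objects with
#' [as_trace_table()] and convert back with [as_kinetic_traces()].
#'
#' @param data data frame with columns `condition`, `replicate`, `time_h`,
#'   `signal`, `m_total_uM`, `seed_fraction`, `modulator_ratio` and
#'   optionally `seed_length`.
#' @return An object of class `trace_table`.
#' @export
trace_table <- function(data) {
  need <- c("condition", "replicate", "time_h", "signal", "m_total_uM",
            "seed_fraction", "modulator_ratio")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    ak_validation_error(paste("trace table lacks columns:",
                              paste(missing_cols, collapse = ", ")))
  if (is.null(data$seed_length)) data$seed_length <- 500
  # canonical column types regardless of source (CSV readers return integers)
  data$condition <- as.character(data$condition)
  data$replicate <- as.character(data$replicate)
  for (cn in c("time_h", "signal", "m_total_uM", "seed_fraction",
               "modulator_ratio", "seed_length"))
    data[[cn]] <- as.numeric(data[[cn]])
  key <- paste(data$condition, data$replicate, data$time_h)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key))
    ak_validation_error(sprintf(
      "duplicate (condition, replicate, time_h) keys at rows %s",
      paste(utils::head(rows, 5L), collapse = ", ")))
  }
  for (id in unique(paste(data$condition, data$replicate, sep = "\r"))) {
    ix <- which(paste(data$condition, data$replicate, sep = "\r") == id)
    tt <- data$time_h[ix]
    if (is.unsorted(tt, strictly = TRUE)) {
      bad <- ix[which(diff(tt) <= 0)[1L] + 1L]
      ak_validation_error(sprintf(
        "times not strictly increasing for condition '%s' replicate %s (row %d)",
        data$condition[ix[1L]], data$replicate[ix[1L]], bad))
    }
  }
  for (cn in c("m_total_uM", "seed_fraction", "modulator_ratio")) {
    if (anyNA(data[[cn]]))
      ak_validation_error(sprintf(
        "metadata column '%s' missing at rows %s", cn,
        paste(utils::head(which(is.na(data[[cn]])), 5L), collapse = ", ")))
    per <- tapply(data[[cn]], data$condition, function(v) length(unique(v)))
    if (any(per > 1L))
      ak_validation_error(sprintf(
        "metadata column '%s' is inconsistent within condition '%s'",
        cn, names(per)[which(per > 1L)[1L]]))
  }
  structure(list(data = data[, c(need, "seed_length")]),
            class = "trace_table")
}

#' @export
print.trace_table <- function(x, ...) {
  cat(sprintf("Trace table: %d conditions, %d rows\n",
              length(unique(x$data$condition)), nrow(x$data)))
  invisible(x)
}

#' Convert kinetic traces to a long trace table
#' @param traces list of [kinetic_trace] objects with condition metadata.
#' @return A [trace_table].
#' @export
as_trace_table <- function(traces) {
  rows <- lapply(traces, function(tr) {
    data.frame(condition = tr$label, replicate = tr$replicate,
               time_h = tr$times, signal = tr$values,
               m_total_uM = tr$m_total, seed_fraction = tr$seed_fraction,
               modulator_ratio = tr$modulator_ratio,
               seed_length = tr$seed_length, stringsAsFactors = FALSE)
  })
  trace_table(do.call(rbind, rows))
}

#' Convert a trace table to a list of kinetic traces
#' @param table a [trace_table].
#' @param normalized are the stored signals on the normalized 0--1 scale?
#' @return A list of [kinetic_trace] objects.
#' @export
as_kinetic_traces <- function(table, normalized = TRUE) {
  stopifnot(inherits(table, "trace_table"))
  d <- table$data
  ids <- unique(paste(d$condition, d$replicate, sep = "\r"))
  lapply(ids, function(id) {
    ix <- which(paste(d$condition, d$replicate, sep = "\r") == id)
    kinetic_trace(d$time_h[ix], d$signal[ix], label = d$condition[ix[1L]],
                  normalized = normalized, replicate = d$replicate[ix[1L]],
                  m_total = d$m_total_uM[ix[1L]],
                  seed_fraction = d$seed_fraction[ix[1L]],
                  modulator_ratio = d$modulator_ratio[ix[1L]],
                  seed_length = d$seed_length[ix[1L]])
  })
}

#' Read kinetic traces from CSV
#'
#' Two dialects are auto-detected:
#' * long (canonical): header `condition, replicate, time_h, signal,
#'   m_total_uM, seed_fraction, modulator_ratio[, seed_length]`.
#' * wide (plate-reader export): a `time_h` column plus one column per well
#'   named `<condition>.<replicate>`, with per-condition metadata in leading
#'   comment lines of the form
#'   `#meta,<condition>,m_total_uM=2,seed_fraction=0,modulator_ratio=0`.
#'
#' @param path CSV file path (UTF-8, header required).
#' @return A [trace_table].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path))
    ak_validation_error(paste("file not found:", path))
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  if (!length(body)) ak_validation_error(paste("no data in", path))
  d <- utils::read.csv(text = paste(body, collapse = "\n"),
                       stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("condition", "replicate", "time_h", "signal") %in% names(d)))
    return(trace_table(d))
  if (!"time_h" %in% names(d))
    ak_validation_error(
      "unrecognized trace CSV: need long-format columns or a 'time_h' column")
  # wide dialect
  meta <- list()
  for (ml in grep("^#meta,", meta_lines, value = TRUE)) {
    parts <- strsplit(sub("^#meta,", "", ml), ",")[[1L]]
    lab <- parts[1L]
    kv <- strsplit(parts[-1L], "=")
    vals <- stats::setNames(vapply(kv, function(x) as.numeric(x[2L]), 0),
                            vapply(kv, `[[`, "", 1L))
    meta[[lab]] <- vals
  }
  wells <- setdiff(names(d), "time_h")
  rows <- lapply(wells, function(w) {
    dot <- regexpr("\\.[^.]*$", w)
    if (dot < 0)
      ak_validation_error(sprintf(
        "well column '%s' is not of the form <condition>.<replicate>", w))
    lab <- substr(w, 1L, dot - 1L)
    rep_id <- substr(w, dot + 1L, nchar(w))
    mv <- meta[[lab]]
    if (is.null(mv))
      ak_validation_error(sprintf(
        "missing #meta line for condition '%s' in %s", lab, path))
    data.frame(condition = lab, replicate = rep_id, time_h = d$time_h,
               signal = d[[w]],
               m_total_uM = unname(mv[["m_total_uM"]]),
               seed_fraction = unname(mv[["seed_fraction"]]),
               modulator_ratio = unname(mv[["modulator_ratio"]]),
               seed_length = if ("seed_length" %in% names(mv))
                 unname(mv[["seed_length"]]) else 500,
               stringsAsFactors = FALSE)
  })
  trace_table(do.call(rbind, rows))
}

#' Write kinetic traces to CSV
#'
#' @param table a [trace_table].
#' @param path output path.
#' @param format `"long"` (canonical) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(table, path, format = c("long", "wide")) {
  stopifnot(inherits(table, "trace_table"))
  format <- match.arg(format)
  d <- table$data
  if (format == "long") {
    out <- d
    for (cn in c("time_h", "signal", "m_total_uM", "seed_fraction",
                 "modulator_ratio", "seed_length"))
      out[[cn]] <- formatC(out[[cn]], digits = 17, format = "g")
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    conds <- unique(d$condition)
    hdr <- vapply(conds, function(lab) {
      r <- d[d$condition == lab, ][1L, ]
      sprintf("#meta,%s,m_total_uM=%.17g,seed_fraction=%.17g,modulator_ratio=%.17g,seed_length=%.17g",
              lab, r$m_total_uM, r$seed_fraction, r$modulator_ratio,
              r$seed_length)
    }, "")
    ids <- unique(paste(d$condition, d$replicate, sep = "."))
    tg <- sort(unique(d$time_h))
    wide <- data.frame(time_h = formatC(tg, digits = 17, format = "g"),
                       check.names = FALSE)
    for (id in ids) {
      sel <- paste(d$condition, d$replicate, sep = ".") == id
      v <- rep(NA_real_, length(tg))
      v[match(d$time_h[sel], tg)] <- d$signal[sel]
      wide[[id]] <- formatC(v, digits = 17, format = "g")
    }
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.csv(wide, con, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a fibril morphometry table from CSV
#'
#' Expected columns: `condition`, `modality` (AFM/TEM), `dimension`
#' (length/height/width), `value`, `unit` (`nm` or `um` only), and an
#' optional `fibril_id` (periodic TEM widths contribute two rows per
#' fibril).  Rows are grouped into one [fibril_measurements] per
#' (condition, modality, dimension).
#'
#' @param path CSV file path.
#' @param sensitivity_error optional named overrides
#'   (`"<modality>_<dimension>"` -> floor); defaults per
#'   [default_sensitivity()].
#' @return A named list of [fibril_measurements].
#' @export
read_morphometry_csv <- function(path, sensitivity_error = NULL) {
  if (!file.exists(path))
    ak_validation_error(paste("file not found:", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("condition", "modality", "dimension", "value", "unit")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols))
    ak_validation_error(paste("morphometry CSV lacks columns:",
                              paste(missing_cols, collapse = ", ")))
  bad_unit <- which(!d$unit %in% c("nm", "um"))
  if (length(bad_unit))
    ak_validation_error(sprintf(
      "unit must be 'nm' or 'um'; offending rows %s",
      paste(utils::head(bad_unit, 5L), collapse = ", ")))
  bad_val <- which(!is.finite(d$value) | d$value <= 0)
  if (length(bad_val))
    ak_validation_error(sprintf(
      "values must be positive; offending rows %s",
      paste(utils::head(bad_val, 5L), collapse = ", ")))
  # native units: lengths in um, cross-sections in nm
  to_native <- function(value, unit, dimension) {
    native <- ifelse(dimension == "length", "um", "nm")
    scale <- ifelse(unit == native, 1,
                    ifelse(native == "um", 1e-3, 1e3))
    value * scale
  }
  d$native <- to_native(d$value, d$unit, d$dimension)
  keys <- unique(d[, c("condition", "modality", "dimension")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    sel <- d$condition == k$condition & d$modality == k$modality &
      d$dimension == k$dimension
    key_name <- paste(k$condition, k$modality, k$dimension, sep = "_")
    se <- if (!is.null(sensitivity_error) &&
              paste(k$modality, k$dimension, sep = "_") %in%
                names(sensitivity_error))
      sensitivity_error[[paste(k$modality, k$dimension, sep = "_")]]
    else NULL
    out[[key_name]] <- fibril_measurements(
      d$native[sel], dimension = k$dimension, modality = k$modality,
      sensitivity_error = se, condition = k$condition,
      fibril_id = if ("fibril_id" %in% names(d)) d$fibril_id[sel] else NULL)
  }
  out
}

#' Write a fibril morphometry table to CSV
#' @param msets a named list of [fibril_measurements].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_morphometry_csv <- function(msets, path) {
  rows <- lapply(msets, function(m) {
    data.frame(condition = m$condition, modality = m$modality,
               dimension = m$dimension,
               value = formatC(m$values, digits = 17, format = "g"),
               unit = m$unit,
               fibril_id = if (is.null(m$fibril_id)) NA else m$fibril_id,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

.config_schema <- list(
  model = c("n_c", "n_2"),
  normalization = c("baseline_window", "plateau_window"),
  fit = c("hypothesis", "n_hops", "stall_hops", "hop_sd", "seed",
          "bounds_decades", "factor_min", "factor_max"),
  generator = c("noise_sd", "replicates", "t_max", "n_points", "seed",
                "drift_slope"),
  output = c("dir", "report"),
  log_level = NULL)

#' Read and validate a run configuration file
#'
#' YAML configuration with sections `model`, `normalization`, `fit`,
#' `generator`, `output` and scalar `log_level`.  Unknown keys anywhere are
#' rejected, so typos fail loudly instead of being ignored.
#'
#' @param path YAML file path.
#' @return The validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    ak_validation_error(paste("file not found:", path))
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    ak_validation_error(paste("unknown config keys:",
                              paste(unknown, collapse = ", ")))
  for (sec in names(cfg)) {
    allowed <- .config_schema[[sec]]
    if (is.null(allowed)) next
    bad <- setdiff(names(cfg[[sec]]), allowed)
    if (length(bad))
      ak_validation_error(sprintf("unknown config keys in '%s': %s",
                                  sec, paste(bad, collapse = ", ")))
  }
  cfg
}
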