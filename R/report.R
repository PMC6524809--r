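# Ensemble statistics: the per-(aneurysm, group) parameter table, its
# median / standard-deviation / relative-standard-deviation summary, and
# box-plot statistics — the tabular deliverables of a segmentation
# variability study.
#
# The relative standard deviation is reported as sample std / mean * 100%
# (primary) and std / median * 100% (secondary); both are emitted because
# published tables rarely state the denominator.

.param_columns <- c("ostium_area", "parent_area", "volume", "nsi",
                    "neck_inflow", "parent_flow", "mean_velocity",
                    "mean_wss")
.param_units <- c(ostium_area = "mm^2", parent_area = "mm^2",
                  volume = "mm^3", nsi = "-", neck_inflow = "ml/s",
                  parent_flow = "ml/s", mean_velocity = "m/s",
                  mean_wss = "Pa")

#' Assemble a per-(aneurysm, group) parameter table
#'
#' @param records list of lists, each with `aneurysm`, `group`, the
#'   parameter values (any of `ostium_area`, `parent_area`, `volume`,
#'   `nsi`, `neck_inflow`, `parent_flow`, `mean_velocity`, `mean_wss`) and
#'   optionally `failure` (a reason string; its parameters stay `NA`).
#' @return data.frame of class `parameter_table`, one row per
#'   (aneurysm, group).
#' @export
parameter_table <- function(records) {
  .assert(length(records) > 0, "aneumorph_domain_error", "no records")
  rows <- lapply(records, function(r) {
    out <- data.frame(aneurysm = as.character(r$aneurysm),
                      group = as.character(r$group),
                      stringsAsFactors = FALSE)
    for (p in .param_columns)
      out[[p]] <- if (!is.null(r[[p]])) as.numeric(r[[p]]) else NA_real_
    out$failure <- if (!is.null(r$failure)) as.character(r$failure)
                   else NA_character_
    out
  })
  df <- do.call(rbind, rows)
  key <- paste(df$aneurysm, df$group)
  .assert(!anyDuplicated(key), "aneumorph_domain_error",
          "duplicate (aneurysm, group) rows")
  class(df) <- c("parameter_table", "data.frame")
  df
}

#' Summarise a parameter table into ensemble statistics
#'
#' Per (aneurysm, parameter): number of contributing groups, median,
#' sample (n-1) standard deviation, and relative standard deviations
#' (std/mean and std/median, in percent).  A `mean` row per parameter
#' holds the unweighted mean over aneurysms with at least two groups.
#' Cells with all values missing stay absent, never zero.
#' @param table a [parameter_table].
#' @return data.frame of class `summary_stats` with columns `parameter`,
#'   `aneurysm`, `n`, `median`, `std`, `rel_std` (%), `rel_std_median`
#'   (%), `unit`.
#' @export
summarize_parameters <- function(table) {
  .assert(inherits(table, "parameter_table"), "aneumorph_domain_error",
          "need a parameter_table")
  aneus <- unique(table$aneurysm)
  out <- list()
  for (p in .param_columns) {
    rows <- list()
    for (a in aneus) {
      v <- table[[p]][table$aneurysm == a]
      v <- v[!is.na(v)]
      if (length(v) == 0) next
      mu <- mean(v)
      sdv <- if (length(v) >= 2) stats::sd(v) else NA_real_
      med <- stats::median(v)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = p, aneurysm = a, n = length(v), median = med,
        std = sdv,
        rel_std = if (!is.na(sdv) && mu != 0) 100 * sdv / mu else NA_real_,
        rel_std_median = if (!is.na(sdv) && med != 0) 100 * sdv / med
                         else NA_real_,
        unit = unname(.param_units[p]), stringsAsFactors = FALSE)
    }
    if (!length(rows)) next
    block <- do.call(rbind, rows)
    ok <- block$n >= 2
    if (any(ok)) {
      block <- rbind(block, data.frame(
        parameter = p, aneurysm = "mean", n = sum(block$n[ok]),
        median = mean(block$median[ok]),
        std = mean(block$std[ok]),
        rel_std = mean(block$rel_std[ok]),
        rel_std_median = mean(block$rel_std_median[ok]),
        unit = unname(.param_units[p]), stringsAsFactors = FALSE))
    }
    out[[p]] <- block
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("summary_stats", "data.frame")
  df
}

#' Five-number box-plot statistics with 1.5 IQR outlier fences
#'
#' Quartiles by linear interpolation (type 7); whiskers reach the most
#' extreme values inside the Tukey fences `Q1 - 1.5 IQR` and
#' `Q3 + 1.5 IQR`; values beyond are listed as outliers (reported, never
#' excluded from other statistics).
#' @param values numeric vector, at least two values.
#' @return list with `lower_whisker`, `q1`, `median`, `q3`,
#'   `upper_whisker`, `outliers`.
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  .assert(length(values) >= 2, "aneumorph_domain_error",
          "boxplot statistics need at least 2 values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo_f <- q[1] - 1.5 * iqr
  hi_f <- q[3] + 1.5 * iqr
  inside <- values >= lo_f & values <= hi_f
  list(lower_whisker = min(values[inside]), q1 = q[1], median = q[2],
       q3 = q[3], upper_whisker = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Write the summary report to CSV and JSON
#'
#' The CSV mirrors the block structure of a published variability table —
#' one block per parameter, rows for each aneurysm plus the `mean` row,
#' with medians to two decimals and percents to one decimal.  The JSON
#' carries full-precision values and metadata (units, the relative-std
#' denominator convention) and round-trips through [read_report_json()].
#' @param stats a [summarize_parameters()] result.
#' @param dir output directory (created if needed).
#' @param name base file name.
#' @return invisibly, the paths written.
#' @export
emit_report <- function(stats, dir, name = "variability_report") {
  .assert(inherits(stats, "summary_stats") && nrow(stats) > 0,
          "aneumorph_domain_error", "empty summary")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, paste0(name, ".csv"))
  json_path <- file.path(dir, paste0(name, ".json"))
  lines <- character(0)
  for (p in unique(stats$parameter)) {
    block <- stats[stats$parameter == p, ]
    lines <- c(lines,
               sprintf("# %s [%s]", p, block$unit[1]),
               "aneurysm,n,median,rel_std_pct")
    for (i in seq_len(nrow(block)))
      lines <- c(lines, sprintf("%s,%d,%.2f,%.1f", block$aneurysm[i],
                                block$n[i], block$median[i],
                                block$rel_std[i]))
    lines <- c(lines, "")
  }
  writeLines(lines, csv_path)
  payload <- list(
    metadata = list(
      rel_std_denominator = "mean",
      rel_std_median_also_reported = TRUE,
      units = as.list(.param_units)),
    stats = stats)
  jsonlite::write_json(payload, json_path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv = csv_path, json = json_path))
}

#' @rdname emit_report
#' @param path a JSON report path.
#' @export
read_report_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  df <- as.data.frame(payload$stats, stringsAsFactors = FALSE)
  class(df) <- c("summary_stats", "data.frame")
  df
}
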