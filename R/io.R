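MEASUREMENT_COLUMNS <- c("subject_id", "sample_id", "sample_type", "stage",
                         "load_percent")

SAMPLE_TYPES <- c("embryo", "blastomere", "trophectoderm", "amniocyte",
                  "trophoblast_cell", "lymphocyte", "tissue", "oocyte")

#' Read a table of heteroplasmy measurements
#'
#' Reads a UTF-8, headered TSV (or CSV) of mutant-load measurements with
#' required columns `subject_id`, `sample_id`, `sample_type`, `stage`,
#' `load_percent` (0-100) and optional `replicate_index` and `pool_id`.
#' Loads travel as percentages in files - the unit clinical reports use -
#' and are converted to fractions on ingest (column `load`); all internal
#' computation is on the fraction scale. Validation failures report the
#' offending file line numbers.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return A tibble with the file's columns plus `load` (fraction).
#' @examples
#' demo <- system.file("extdata", "synthetic_embryo_cohort.tsv",
#'                     package = "mtdrift")
#' head(read_measurements(demo))
#' @export
read_measurements <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, check.names = TRUE,
                          fileEncoding = "UTF-8")
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  lines <- seq_len(nrow(df)) + 1L  # header is line 1
  lp <- suppressWarnings(as.numeric(df$load_percent))
  bad <- !is.finite(lp) | lp < 0 | lp > 100
  if (any(bad))
    stop("load_percent outside [0, 100] (or non-numeric) on line(s): ",
         paste(lines[bad], collapse = ", "), call. = FALSE)
  bad_type <- !df$sample_type %in% SAMPLE_TYPES
  if (any(bad_type))
    stop("unknown sample_type on line(s): ",
         paste(lines[bad_type], collapse = ", "),
         " (expected one of: ", paste(SAMPLE_TYPES, collapse = ", "), ")",
         call. = FALSE)
  key <- paste(df$subject_id, df$sample_id,
               if ("replicate_index" %in% names(df)) df$replicate_index
               else "", sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (subject_id, sample_id, replicate_index) key on ",
         "line(s): ", paste(lines[dup], collapse = ", "), call. = FALSE)
  df$load_percent <- lp
  df$load <- lp / 100
  tibble::as_tibble(df)
}

#' Write a measurement table
#'
#' Writes the TSV (or CSV) dialect read by [read_measurements()]. The
#' internal fraction column `load` is dropped; `load_percent` is written
#' as plain decimal text so a write/read cycle reproduces the numbers
#' bit-identically.
#'
#' @param table A data frame with the measurement columns.
#' @param path Output path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  table <- as.data.frame(table)
  table$load <- NULL
  missing_cols <- setdiff(MEASUREMENT_COLUMNS, names(table))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.table(table, path, sep = if (dialect == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Convert a simulated cohort to a measurement table
#'
#' Bridges the simulator to the file dialect: one `embryo` row per
#' offspring carrying the measured (noisy, censored) load, plus - when
#' replicates were simulated - one `blastomere` row per replicate.
#'
#' @param cohort A `synthetic_cohort`.
#' @param subject_id Subject label for all rows.
#' @param stage Free-text stage label (default `"day3"`).
#' @return A tibble in the [read_measurements()] dialect.
#' @export
cohort_to_table <- function(cohort, subject_id = "S1", stage = "day3") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  n <- length(cohort$measured_loads)
  rows <- tibble::tibble(
    subject_id = subject_id,
    sample_id = sprintf("embryo%02d", seq_len(n)),
    sample_type = "embryo",
    stage = stage,
    load_percent = 100 * cohort$measured_loads,
    replicate_index = NA_integer_,
    pool_id = NA_character_)
  if (!is.null(cohort$replicates)) {
    k <- ncol(cohort$replicates)
    rep_rows <- tibble::tibble(
      subject_id = subject_id,
      sample_id = rep(sprintf("embryo%02d", seq_len(n)), k),
      sample_type = "blastomere",
      stage = stage,
      load_percent = 100 * as.vector(cohort$replicates),
      replicate_index = rep(seq_len(k), each = n),
      pool_id = NA_character_)
    rows <- rbind(rows, rep_rows)
  }
  rows$load <- rows$load_percent / 100
  rows
}

#' JSON report of a Kimura fit
#'
#' Serialises a fit (and its Monte-Carlo intervals, when present) to a
#' versioned JSON report mirroring the usual table layout: one entry per
#' statistic with point estimate and interval, fractions and percentages
#' both given, plus sample size, replicate count and seed for
#' reproducibility.
#'
#' @param fit A `kimura_fit`.
#' @param path Optional path; when supplied the JSON is written there.
#' @return The JSON string, invisibly when `path` is given.
#' @export
fit_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "kimura_fit"))
  pct <- c(p0 = TRUE, V = FALSE, normalized_variance = FALSE, b = FALSE,
           f0 = TRUE, f1 = TRUE, tail_prob = TRUE)
  stat_entry <- function(nm) {
    entry <- list(value = fit[[nm]])
    if (pct[[nm]]) entry$value_percent <- 100 * fit[[nm]]
    if (!is.null(fit$ci)) {
      row <- fit$ci[fit$ci$statistic == nm, ]
      if (nrow(row) == 1L) {
        entry$ci95 <- c(row$lower, row$upper)
        if (pct[[nm]]) entry$ci95_percent <- 100 * c(row$lower, row$upper)
      }
    }
    entry
  }
  report <- list(
    schema_version = "1.0",
    generator = paste0("mtdrift ",
                       as.character(utils::packageVersion("mtdrift"))),
    n = fit$n,
    exceedance_threshold = fit$exceedance_threshold,
    ci_reps = fit$ci_reps,
    ci_failed = fit$ci_failed,
    seed = fit$seed,
    statistics = stats::setNames(lapply(names(pct), stat_entry), names(pct)))
  json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
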