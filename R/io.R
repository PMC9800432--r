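FID_CONTAINER_VERSION <- 1L

#' Write / read an FID grid container
#'
#' Single-file JSON container holding the complex FID array (real and
#' imaginary parts, column-major over the documented axis order
#' row / col / time) and a header with the acquisition configuration,
#' spatial domain and a format version.
#'
#' @param grid an [fid_grid()].
#' @param path file path to write to / read from.
#' @return `write_fid_container` returns `path` invisibly;
#'   `read_fid_container` returns the `mrs_fid_grid`, bit-identical to what
#'   was written.
#' @export
write_fid_container <- function(grid, path) {
  stopifnot(inherits(grid, "mrs_fid_grid"))
  obj <- list(
    container = "mrsioi-fid",
    version = FID_CONTAINER_VERSION,
    domain = grid$domain,
    shape = dim(grid$data),
    acq = unclass(grid$acq),
    data = list(
      real = as.vector(Re(grid$data)),
      imag = as.vector(Im(grid$data))
    )
  )
  # 17 significant digits: lossless for IEEE doubles
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_fid_container
#' @export
read_fid_container <- function(path) {
  if (!file.exists(path)) stop("FID container not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$container, "mrsioi-fid") || is.null(obj$acq) ||
    is.null(obj$shape) || is.null(obj$data)) {
    stop("corrupt FID container header: ", path, call. = FALSE)
  }
  if (!identical(as.integer(obj$version), FID_CONTAINER_VERSION)) {
    stop(
      sprintf(
        "unsupported FID container version %s (supported: %d)",
        obj$version, FID_CONTAINER_VERSION
      ),
      call. = FALSE
    )
  }
  acq <- acq_config(
    acq_matrix = obj$acq$acq_matrix, recon_matrix = obj$acq$recon_matrix,
    n_time_points = obj$acq$n_time_points, dwell_time = obj$acq$dwell_time,
    carrier_ppm = obj$acq$carrier_ppm, transmitter_mhz = obj$acq$transmitter_mhz
  )
  shape <- as.integer(obj$shape)
  if (length(obj$data$real) != prod(shape) ||
    length(obj$data$imag) != prod(shape) ||
    shape[3] != acq$n_time_points) {
    stop("FID container shape mismatch between header and data", call. = FALSE)
  }
  arr <- array(complex(real = obj$data$real, imaginary = obj$data$imag), shape)
  fid_grid(arr, acq, domain = obj$domain)
}

# Shared CSV writer stamping an optional config hash as a comment line.
write_csv_hashed <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash)) writeLines(paste0("# config_hash=", config_hash), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

COHORT_COLUMNS <- c(
  "scan_id", "subject_id", "group", "age_years", "gmfc", "iq", "iq_ge_85",
  "urine_naa_over_creatinine"
)
GROUP_LEVELS <- c("control", "juvenile", "late_infantile")

#' Write / read a cohort table
#'
#' CSV with columns `scan_id`, `subject_id`, `group`, `age_years`, `gmfc`,
#' `iq`, `iq_ge_85`, `urine_naa_over_creatinine`; missing values are empty
#' fields. On reading, `group` must be one of `control`, `juvenile`,
#' `late_infantile` and `gmfc` (when present) an integer in 0..6; rows
#' violating this are reported with their line numbers.
#'
#' @param subjects data frame of subject records.
#' @param path CSV file path.
#' @param config_hash optional hash stamped as a leading comment line.
#' @return `read_cohort_csv` returns the validated data frame.
#' @export
write_cohort_csv <- function(subjects, path, config_hash = NULL) {
  missing <- setdiff(COHORT_COLUMNS, names(subjects))
  if (length(missing)) {
    stop("cohort table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  write_csv_hashed(subjects[, COHORT_COLUMNS], path, config_hash)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("cohort table not found: ", path, call. = FALSE)
  raw <- readLines(path)
  n_comment <- sum(startsWith(raw, "#"))
  df <- utils::read.csv(path,
    stringsAsFactors = FALSE, comment.char = "#",
    colClasses = c(
      scan_id = "character", subject_id = "character", group = "character"
    )
  )
  missing <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing)) {
    stop("cohort table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  # line number of each data row in the file (header + comments skipped)
  lines <- seq_len(nrow(df)) + 1L + n_comment
  problems <- character()
  bad_group <- !df$group %in% GROUP_LEVELS
  if (any(bad_group)) {
    problems <- c(problems, sprintf(
      "line %d: unknown group '%s'", lines[bad_group], df$group[bad_group]
    ))
  }
  bad_gmfc <- !is.na(df$gmfc) & (df$gmfc < 0 | df$gmfc > 6 | df$gmfc != round(df$gmfc))
  if (any(bad_gmfc)) {
    problems <- c(problems, sprintf(
      "line %d: gmfc %s outside the 0..6 motor-score range",
      lines[bad_gmfc], df$gmfc[bad_gmfc]
    ))
  }
  if (length(problems)) {
    stop("invalid cohort table:\n", paste(problems, collapse = "\n"), call. = FALSE)
  }
  df$gmfc <- as.integer(df$gmfc)
  df$iq_ge_85 <- as.logical(df$iq_ge_85)
  df
}

#' Write / read a tidy ratio table
#'
#' @param ratio_table data frame with columns `scan_id`, `region`, `ioi`,
#'   `ratio`.
#' @param path CSV file path.
#' @param config_hash optional hash stamped as a leading comment line.
#' @export
write_ratio_csv <- function(ratio_table, path, config_hash = NULL) {
  write_csv_hashed(
    ratio_table[, c("scan_id", "region", "ioi", "ratio")], path, config_hash
  )
}

#' @rdname write_ratio_csv
#' @export
read_ratio_csv <- function(path) {
  if (!file.exists(path)) stop("ratio table not found: ", path, call. = FALSE)
  utils::read.csv(path,
    stringsAsFactors = FALSE, comment.char = "#",
    colClasses = c(scan_id = "character", region = "character", ioi = "character")
  )
}

#' Serialize a clinical results bundle
#'
#' Writes `group_comparisons.csv`, `correlations.csv`, `odds_ratio.csv`
#' and `age_check.csv` plus a `results.json` mirror of the whole bundle
#' into `dir`.
#'
#' @param results an `mrs_clinical_results` object.
#' @param dir output directory (created if needed).
#' @param config_hash optional hash stamped on every table.
#' @return `dir`, invisibly.
#' @export
write_results_bundle <- function(results, dir, config_hash = NULL) {
  stopifnot(inherits(results, "mrs_clinical_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tables <- list(
    group_comparisons = results$group_comparisons,
    correlations = results$correlations,
    odds_ratio = results$odds_ratio,
    age_check = results$age_check
  )
  for (nm in names(tables)) {
    if (!is.null(tables[[nm]])) {
      write_csv_hashed(tables[[nm]], file.path(dir, paste0(nm, ".csv")), config_hash)
    }
  }
  jsonlite::write_json(
    list(
      config_hash = config_hash, n_scans = results$n_scans,
      options = unclass(results$options),
      group_comparisons = results$group_comparisons,
      correlations = results$correlations,
      odds_ratio = results$odds_ratio,
      age_check = results$age_check
    ),
    file.path(dir, "results.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(dir)
}
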