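#' Default run configuration
#'
#' Single structured object collecting every constant of a pipeline run:
#' acquisition settings, processing flags (apodization half-decay, NAA
#' search window, baseline window), interval and ROI definitions, the
#' synthetic-cohort parameters, statistics options and the seed. Serialized
#' as JSON; [read_run_config()] validates user files against this template
#' and rejects unknown keys.
#'
#' @return Nested named list of class `mrs_run_config`.
#' @export
default_run_config <- function() {
  structure(
    list(
      seed = 1L,
      output_dir = "mrsioi-output",
      acquisition = list(
        acq_matrix = c(12L, 12L), recon_matrix = c(32L, 32L),
        n_time_points = 1024L, dwell_time = 1 / 1200,
        carrier_ppm = 4.7, transmitter_mhz = 123.25
      ),
      processing = list(
        apodize = TRUE, fwhm = 0.355,
        frequency_correct = TRUE, naa_window = c(1.75, 2.25),
        shift_method = "bin",
        baseline = TRUE, baseline_window = c(0.9, 1.6)
      ),
      iois = "default",
      roi = "default",
      cohort = list(
        n_control = 12L, n_juvenile = 19L, n_late_infantile = 10L,
        target_gmfc_spearman = -0.75, target_iq_pearson = 0.84,
        target_urine_spearman = -0.55,
        severity_sd = 0.35, subject_sd = 0.08, noise_sd = 0.3,
        shift_range = 0.1, baseline_range = 2,
        iq_absolute_fraction = 0.5, n_followup = 0L
      ),
      stats = list(
        threshold = 1.5, threshold_ioi = "NAA2", threshold_region = "FWM",
        independent_only = FALSE, fdr = FALSE, alpha = 0.05
      )
    ),
    class = "mrs_run_config"
  )
}

# Recursively collect keys present in `x` but absent from template `ref`.
unknown_keys <- function(x, ref, prefix = "") {
  bad <- character()
  for (nm in names(x)) {
    path <- paste0(prefix, nm)
    if (!nm %in% names(ref)) {
      bad <- c(bad, path)
    } else if (is.list(x[[nm]]) && is.list(ref[[nm]])) {
      bad <- c(bad, unknown_keys(x[[nm]], ref[[nm]], paste0(path, ".")))
    }
  }
  bad
}

#' Read and validate a run configuration
#'
#' Reads a JSON configuration file, rejects any key not present in
#' [default_run_config()] (naming the offending keys), and fills every
#' omitted key with its default.
#'
#' @param path JSON file path.
#' @return A complete `mrs_run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- default_run_config()
  bad <- unknown_keys(user, defaults)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  merged <- utils::modifyList(unclass(defaults), user)
  structure(merged, class = "mrs_run_config")
}

#' Stable hash of a run configuration
#'
#' 32-bit FNV-1a hash of the canonical JSON serialization, stamped on every
#' output table so results are traceable to the exact configuration that
#' produced them.
#'
#' @param config an `mrs_run_config`.
#' @return 8-character lowercase hex string.
#' @export
config_hash <- function(config) {
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(js))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor32(h, b)
    h <- mulmod32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# 32-bit helpers on doubles (R integers overflow at 2^31).
bitwXor32 <- function(a, b) {
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  hi * 65536 + lo
}

mulmod32 <- function(a, b) {
  lo <- a %% 65536
  hi <- a %/% 65536
  (lo * b + ((hi * b) %% 65536) * 65536) %% 4294967296
}
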