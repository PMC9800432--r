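# Build the processing objects a config describes.
config_objects <- function(config) {
  acq <- do.call(acq_config, config$acquisition)
  iois <- if (identical(config$iois, "default")) {
    default_iois()
  } else {
    read_ioi_config(config$iois)
  }
  map <- if (identical(config$roi, "default")) {
    default_roi_map(acq$recon_matrix)
  } else {
    stop("custom ROI maps must be passed programmatically via `roi_map()`",
      call. = FALSE
    )
  }
  proc <- process_options(
    apodize = config$processing$apodize, fwhm = config$processing$fwhm,
    frequency_correct = config$processing$frequency_correct,
    naa_window = config$processing$naa_window,
    shift_method = config$processing$shift_method,
    baseline = config$processing$baseline,
    baseline_window = config$processing$baseline_window
  )
  stats_opts <- do.call(analysis_options, config$stats)
  list(acq = acq, iois = iois, roi_map = map, proc = proc, stats = stats_opts)
}

cohort_params_from_config <- function(config) {
  cohort_params(
    n_control = config$cohort$n_control,
    n_juvenile = config$cohort$n_juvenile,
    n_late_infantile = config$cohort$n_late_infantile,
    target_gmfc_spearman = config$cohort$target_gmfc_spearman,
    target_iq_pearson = config$cohort$target_iq_pearson,
    target_urine_spearman = config$cohort$target_urine_spearman,
    severity_sd = config$cohort$severity_sd,
    subject_sd = config$cohort$subject_sd,
    noise_sd = config$cohort$noise_sd,
    shift_range = config$cohort$shift_range,
    baseline_range = config$cohort$baseline_range,
    iq_absolute_fraction = config$cohort$iq_absolute_fraction,
    n_followup = config$cohort$n_followup,
    seed = config$seed
  )
}

#' Region ratio table for one scan
#'
#' Convenience wrapper chaining the per-scan steps: reconstruct the ROI
#' voxels from a k-space grid, post-process each voxel's spectrum,
#' integrate the intervals of interest, normalize to Cr2, and aggregate to
#' the region scheme.
#'
#' @param grid a k-space [fid_grid()].
#' @param roi_map an [roi_map()].
#' @param iois an `mrs_ioi_set`.
#' @param proc_options a [process_options()] list.
#' @param scan_id identifier stamped on the output.
#' @param verbose print the shift and baseline offset applied per voxel.
#' @return Tidy ratio table (see [aggregate_regions()]).
#' @export
scan_ratio_table <- function(grid, roi_map, iois = default_iois(),
                             proc_options = process_options(),
                             scan_id = "scan", verbose = FALSE) {
  vox <- roi_voxels(roi_map)
  fids <- reconstruct_voxels(grid, vox)
  rows <- vector("list", nrow(vox))
  for (j in seq_len(nrow(vox))) {
    spec <- process_voxel(fids[j, ], grid$acq, proc_options,
      meta = list(voxel = vox[j, ])
    )
    if (verbose) {
      message(sprintf(
        "%s voxel (%d,%d): shift %+.4f ppm, baseline %+.4g",
        scan_id, vox[j, 1], vox[j, 2],
        if (is.null(spec$meta$shift_applied)) NA else spec$meta$shift_applied,
        if (is.null(spec$meta$baseline_offset)) NA else spec$meta$baseline_offset
      ))
    }
    ratios <- compute_ratios(spec, iois)
    rows[[j]] <- data.frame(
      row = vox[j, 1], col = vox[j, 2],
      ioi = names(ratios), ratio = as.numeric(ratios),
      stringsAsFactors = FALSE
    )
  }
  aggregate_regions(do.call(rbind, rows), roi_map, scan_id = scan_id)
}

#' Run the full synthetic-cohort pipeline
#'
#' Chains simulate, process, integrate and analyze: generates the cohort
#' and per-scan FID grids, post-processes the ROI voxels of every scan,
#' builds the Cr2-normalized region ratio table, and runs the clinical
#' statistics. With an output directory, writes `cohort.csv`,
#' `ratios.csv` and the results bundle, each stamped with the
#' configuration hash.
#'
#' @param config an `mrs_run_config` (see [default_run_config()]).
#' @param output_dir directory for result files; `NULL` writes nothing.
#' @param verbose log the per-voxel processing decisions.
#' @return List of class `mrs_pipeline_result`: the config and its hash,
#'   the subject table, truths, ratio table and clinical results.
#' @export
run_pipeline <- function(config = default_run_config(), output_dir = NULL,
                         verbose = FALSE) {
  obj <- config_objects(config)
  hash <- config_hash(config)
  cohort <- simulate_cohort(cohort_params_from_config(config))
  lines <- metabolite_basis(obj$iois)
  tables <- vector("list", nrow(cohort$subjects))
  for (i in seq_len(nrow(cohort$subjects))) {
    sid <- cohort$subjects$scan_id[i]
    grid <- simulate_fid(cohort$truths[[sid]], lines, obj$acq)
    tables[[i]] <- scan_ratio_table(grid, obj$roi_map, obj$iois, obj$proc,
      scan_id = sid, verbose = verbose
    )
  }
  ratio_table <- do.call(rbind, lapply(tables, function(t) {
    attr(t, "roi_values") <- NULL
    t
  }))
  results <- run_clinical_analysis(ratio_table, cohort$subjects, obj$stats)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_csv(cohort$subjects, file.path(output_dir, "cohort.csv"), hash)
    write_ratio_csv(ratio_table, file.path(output_dir, "ratios.csv"), hash)
    write_results_bundle(results, output_dir, hash)
  }
  structure(
    list(
      config = config, config_hash = hash,
      subjects = cohort$subjects, truths = cohort$truths,
      ratio_table = ratio_table, results = results, roi_map = obj$roi_map
    ),
    class = "mrs_pipeline_result"
  )
}

#' Command-line entry point
#'
#' Thin shell interface over the package functions, installed as
#' `inst/cli/mrsioi`. Subcommands: `simulate` (cohort table and FID
#' containers), `process` (one container to per-voxel spectrum CSVs),
#' `integrate` (one container to a region ratio table), `analyze` (ratio
#' table + cohort table to the results bundle) and `all` (full pipeline).
#'
#' @param args character vector of command-line arguments.
#' @return Integer exit code (0 on success), invisibly.
#' @export
mrs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch(
    {
      mrs_cli_run(args)
      0L
    },
    error = function(e) {
      message("mrsioi error: ", conditionMessage(e))
      1L
    }
  )
  invisible(code)
}

parse_cli_flags <- function(args) {
  flags <- list(verbose = FALSE)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--verbose") {
      flags$verbose <- TRUE
      i <- i + 1L
    } else if (startsWith(a, "--")) {
      if (i == length(args)) stop("flag ", a, " needs a value")
      flags[[substring(a, 3)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      stop("unexpected argument: ", a)
    }
  }
  flags
}

cli_config <- function(flags) {
  cfg <- if (!is.null(flags$config)) read_run_config(flags$config) else default_run_config()
  if (!is.null(flags$seed)) cfg$seed <- as.integer(flags$seed)
  cfg
}

mrs_cli_run <- function(args) {
  if (!length(args)) {
    stop("usage: mrsioi <simulate|process|integrate|analyze|all> [--config F] [--seed N] [--out D] [--fid F] [--ratios F] [--cohort F] [--verbose]")
  }
  cmd <- args[1]
  flags <- parse_cli_flags(args[-1])
  out <- flags$out
  switch(cmd,
    simulate = {
      if (is.null(out)) stop("simulate needs --out")
      cfg <- cli_config(flags)
      obj <- config_objects(cfg)
      cohort <- simulate_cohort(cohort_params_from_config(cfg))
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      hash <- config_hash(cfg)
      write_cohort_csv(cohort$subjects, file.path(out, "cohort.csv"), hash)
      lines <- metabolite_basis(obj$iois)
      for (sid in cohort$subjects$scan_id) {
        grid <- simulate_fid(cohort$truths[[sid]], lines, obj$acq)
        write_fid_container(grid, file.path(out, paste0("fid_", sid, ".json")))
      }
      message("wrote cohort and ", nrow(cohort$subjects), " FID containers to ", out)
    },
    process = {
      if (is.null(flags$fid) || is.null(out)) stop("process needs --fid and --out")
      cfg <- cli_config(flags)
      obj <- config_objects(cfg)
      grid <- read_fid_container(flags$fid)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      vox <- roi_voxels(obj$roi_map)
      fids <- reconstruct_voxels(grid, vox)
      for (j in seq_len(nrow(vox))) {
        spec <- process_voxel(fids[j, ], grid$acq, obj$proc)
        write_csv_hashed(
          data.frame(
            ppm = spec$ppm, real = Re(spec$intensity), imag = Im(spec$intensity)
          ),
          file.path(out, sprintf("spectrum_r%02d_c%02d.csv", vox[j, 1], vox[j, 2])),
          config_hash(cfg)
        )
      }
      message("wrote ", nrow(vox), " voxel spectra to ", out)
    },
    integrate = {
      if (is.null(flags$fid) || is.null(out)) stop("integrate needs --fid and --out")
      cfg <- cli_config(flags)
      obj <- config_objects(cfg)
      grid <- read_fid_container(flags$fid)
      sid <- sub("\\.json$", "", sub("^fid_", "", basename(flags$fid)))
      tab <- scan_ratio_table(grid, obj$roi_map, obj$iois, obj$proc,
        scan_id = sid, verbose = flags$verbose
      )
      attr(tab, "roi_values") <- NULL
      write_ratio_csv(tab, out, config_hash(cfg))
      message("wrote ratio table to ", out)
    },
    analyze = {
      if (is.null(flags$ratios) || is.null(flags$cohort) || is.null(out)) {
        stop("analyze needs --ratios, --cohort and --out")
      }
      cfg <- cli_config(flags)
      obj <- config_objects(cfg)
      results <- run_clinical_analysis(
        read_ratio_csv(flags$ratios), read_cohort_csv(flags$cohort), obj$stats
      )
      write_results_bundle(results, out, config_hash(cfg))
      message("wrote results bundle to ", out)
    },
    all = {
      if (is.null(out)) stop("all needs --out")
      cfg <- cli_config(flags)
      run_pipeline(cfg, output_dir = out, verbose = flags$verbose)
      message("wrote full results to ", out)
    },
    stop("unknown subcommand: ", cmd)
  )
  invisible(NULL)
}
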