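#' Options for the clinical analysis
#'
#' @param threshold marker threshold for the odds-ratio analysis.
#' @param threshold_ioi,threshold_region interval and region whose ratio is
#'   dichotomized (NAA2 in frontal white matter by default).
#' @param independent_only keep only each subject's most recent scan
#'   (sensitivity analysis); by default repeated scans enter as
#'   independent observations.
#' @param fdr apply Benjamini-Hochberg adjustment within each analysis
#'   family (off by default: the primary analysis uses unadjusted p < 0.05).
#' @param alpha significance level.
#' @return List of class `mrs_analysis_options`.
#' @export
analysis_options <- function(threshold = 1.5, threshold_ioi = "NAA2",
                             threshold_region = "FWM",
                             independent_only = FALSE, fdr = FALSE,
                             alpha = 0.05) {
  structure(
    list(
      threshold = threshold, threshold_ioi = threshold_ioi,
      threshold_region = threshold_region,
      independent_only = isTRUE(independent_only), fdr = isTRUE(fdr),
      alpha = alpha
    ),
    class = "mrs_analysis_options"
  )
}

#' Clinical correlation and group-comparison analysis
#'
#' Joins the region-level ratio table with the subject records and
#' reproduces the statistical layer of the interval-integration approach:
#' per interval and region, a one-way ANOVA across the three cohorts with
#' Tukey post-hoc pairs; per interval, Spearman correlation of the
#' corticospinal-tract ratio with the GMFC-MLD motor score, Pearson
#' correlation of the frontal-white-matter ratio with absolute IQ, Spearman
#' correlation of the FWM ratio with the IQ >= 85 indicator (coded 1/0),
#' and Spearman correlation of the mean-white-matter ratio with the
#' urinary NAA/creatinine ratio; plus the urine-vs-GMFC correlation, the
#' threshold odds ratio for the configured marker, and a control-cohort age
#' check (Spearman of age against each interval's WM ratio).
#'
#' @param ratio_table tidy data frame (`scan_id`, `region`, `ioi`, `ratio`)
#'   as produced by [aggregate_regions()] / [run_pipeline()].
#' @param subjects data frame of subject records (one row per scan).
#' @param options an [analysis_options()] list.
#' @return List of class `mrs_clinical_results` with data-frame elements
#'   `group_comparisons`, `correlations`, `odds_ratio`, `age_check`, and
#'   the options used.
#' @export
run_clinical_analysis <- function(ratio_table, subjects,
                                  options = analysis_options()) {
  stopifnot(inherits(options, "mrs_analysis_options"))
  only_ratios <- setdiff(unique(ratio_table$scan_id), subjects$scan_id)
  only_subjects <- setdiff(subjects$scan_id, unique(ratio_table$scan_id))
  if (length(only_ratios) || length(only_subjects)) {
    stop(
      "ratio table and subject records do not join:",
      if (length(only_ratios)) {
        paste0(" no subject record for ", paste(only_ratios, collapse = ", "), ".")
      } else "",
      if (length(only_subjects)) {
        paste0(" no ratios for ", paste(only_subjects, collapse = ", "), ".")
      } else "",
      call. = FALSE
    )
  }
  if (options$independent_only) {
    keep <- unlist(lapply(split(subjects, subjects$subject_id), function(d) {
      d$scan_id[order(d$age_years, d$scan_id, decreasing = TRUE)][1]
    }), use.names = FALSE)
    subjects <- subjects[subjects$scan_id %in% keep, ]
    ratio_table <- ratio_table[ratio_table$scan_id %in% keep, ]
  }

  iois <- unique(ratio_table$ioi)
  regions <- unique(ratio_table$region)
  # wide lookup: one row per scan, one column per region x ioi
  wide <- function(region, ioi) {
    sub <- ratio_table[ratio_table$region == region & ratio_table$ioi == ioi, ]
    sub$ratio[match(subjects$scan_id, sub$scan_id)]
  }

  gc_rows <- list()
  for (reg in regions) {
    for (io in iois) {
      vals <- wide(reg, io)
      res <- tryCatch(anova_tukey(vals, subjects$group, alpha = options$alpha),
        error = function(e) NULL
      )
      if (is.null(res)) next
      pair <- function(a, b) {
        hit <- res$tukey[names(res$tukey) %in% c(paste(a, b, sep = "-"), paste(b, a, sep = "-"))]
        if (length(hit)) unname(hit[1]) else NA_real_
      }
      nmap <- stats::setNames(res$n, res$group_labels)
      gc_rows[[length(gc_rows) + 1L]] <- data.frame(
        ioi = io, region = reg, f = res$f, anova_p = res$anova_p,
        p_control_juvenile = pair("control", "juvenile"),
        p_control_late_infantile = pair("control", "late_infantile"),
        p_juvenile_late_infantile = pair("juvenile", "late_infantile"),
        n_control = unname(nmap["control"]),
        n_juvenile = unname(nmap["juvenile"]),
        n_late_infantile = unname(nmap["late_infantile"]),
        stringsAsFactors = FALSE
      )
    }
  }
  group_comparisons <- do.call(rbind, gc_rows)

  cor_row <- function(analysis, ioi, region, res) {
    data.frame(
      analysis = analysis, ioi = ioi, region = region,
      method = res$method, estimate = res$estimate, p = res$p, n = res$n,
      stringsAsFactors = FALSE
    )
  }
  cr <- list()
  for (io in iois) {
    cst <- wide("CST", io)
    fwm <- wide("FWM", io)
    wm <- wide("WM", io)
    add <- function(analysis, region, res) {
      if (!is.null(res)) cr[[length(cr) + 1L]] <<- cor_row(analysis, io, region, res)
    }
    try_cor <- function(f, x, y) tryCatch(f(x, y), error = function(e) NULL)
    add("gmfc", "CST", try_cor(spearman, cst, subjects$gmfc))
    add("iq", "FWM", try_cor(pearson, fwm, subjects$iq))
    add("iq_ge_85", "FWM", try_cor(spearman, fwm, as.numeric(subjects$iq_ge_85)))
    add("urine", "WM", try_cor(spearman, wm, subjects$urine_naa_over_creatinine))
  }
  ur_gmfc <- tryCatch(
    spearman(subjects$urine_naa_over_creatinine, subjects$gmfc),
    error = function(e) NULL
  )
  if (!is.null(ur_gmfc)) {
    cr[[length(cr) + 1L]] <- cor_row("urine_gmfc", NA_character_, NA_character_, ur_gmfc)
  }
  correlations <- do.call(rbind, cr)
  correlations$significant <- correlations$p < options$alpha
  if (options$fdr) {
    correlations$p_adj <- stats::ave(correlations$p, correlations$analysis,
      FUN = function(p) stats::p.adjust(p, "BH")
    )
  }

  or_vals <- wide(options$threshold_region, options$threshold_ioi)
  or_res <- tryCatch(
    threshold_odds_ratio(or_vals, subjects$iq_ge_85, options$threshold),
    error = function(e) NULL
  )
  odds_ratio <- if (is.null(or_res)) {
    NULL
  } else {
    data.frame(
      ioi = options$threshold_ioi, region = options$threshold_region,
      threshold = or_res$threshold, odds_ratio = or_res$odds_ratio,
      a = or_res$table[1, 1], b = or_res$table[1, 2],
      c = or_res$table[2, 1], d = or_res$table[2, 2],
      corrected = or_res$corrected, n = or_res$n,
      stringsAsFactors = FALSE
    )
  }

  ctrl <- subjects$group == "control"
  age_check <- do.call(rbind, lapply(iois, function(io) {
    res <- tryCatch(spearman(subjects$age_years[ctrl], wide("WM", io)[ctrl]),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    cor_row("age_control", io, "WM", res)
  }))

  structure(
    list(
      group_comparisons = group_comparisons, correlations = correlations,
      odds_ratio = odds_ratio, age_check = age_check,
      options = options, n_scans = nrow(subjects)
    ),
    class = "mrs_clinical_results"
  )
}

#' @export
print.mrs_clinical_results <- function(x, ...) {
  cat(sprintf(
    "<mrs_clinical_results> %d scans; %d group comparisons, %d correlations\n",
    x$n_scans,
    if (is.null(x$group_comparisons)) 0L else nrow(x$group_comparisons),
    if (is.null(x$correlations)) 0L else nrow(x$correlations)
  ))
  invisible(x)
}
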