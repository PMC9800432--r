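#' Default metabolite line basis
#'
#' One Lorentzian line per interval of interest, centred at the interval
#' midpoint and named after the metabolite that interval represents. The
#' relative amplitudes are chosen so a healthy (all multipliers = 1)
#' spectrum shows the familiar proton brain pattern: a dominant NAA peak
#' near 2 ppm about twice the main creatine peak, prominent choline, and
#' smaller myo-inositol, glutamine/glutamate and aspartate signals.
#'
#' @param iois an `mrs_ioi_set`; one line is placed in each interval.
#' @param linewidth_hz Lorentzian full width at half maximum per line, Hz.
#' @param relative_amplitudes named vector (by interval abbreviation) of
#'   dimensionless relative line amplitudes; must be >= 0.
#' @return Data frame with columns `metabolite`, `chemical_shift`,
#'   `relative_amplitude`, `linewidth_hz`.
#' @examples
#' metabolite_basis()
#' @export
metabolite_basis <- function(iois = default_iois(), linewidth_hz = 4,
                             relative_amplitudes = c(
                               Myo1 = 0.6, Cr1 = 0.9, Glx = 0.5, Myo2 = 0.7,
                               Cho = 0.9, Cr2 = 1.0, Asp = 0.4, NAA1 = 0.5,
                               Gln = 0.45, NAA2 = 2.0
                             )) {
  missing <- setdiff(iois$abbreviation, names(relative_amplitudes))
  if (length(missing)) {
    stop("no relative amplitude for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  amp <- relative_amplitudes[iois$abbreviation]
  if (any(amp < 0)) stop("relative amplitudes must be >= 0", call. = FALSE)
  if (any(linewidth_hz <= 0)) stop("linewidth must be > 0", call. = FALSE)
  data.frame(
    metabolite = iois$abbreviation,
    chemical_shift = (iois$ppm_high + iois$ppm_low) / 2,
    relative_amplitude = as.numeric(amp),
    linewidth_hz = rep_len(linewidth_hz, nrow(iois)),
    stringsAsFactors = FALSE
  )
}

#' Ground truth for one simulated scan
#'
#' @param amplitudes named non-negative vector: per-metabolite amplitude
#'   multipliers applied to the basis line amplitudes.
#' @param frequency_shift global chemical-shift offset injected into every
#'   line (ppm); what frequency correction must recover.
#' @param baseline_offset additive constant realized in the frequency
#'   domain (equivalently, added to the first time-domain sample, its DFT
#'   pair); what baseline subtraction must remove.
#' @param noise_sd standard deviation of the complex Gaussian noise added
#'   independently to each spatial voxel and time point, >= 0.
#' @param seed integer seed making the scan reproducible.
#' @return An object of class `mrs_sim_truth`.
#' @export
simulation_truth <- function(amplitudes, frequency_shift = 0,
                             baseline_offset = 0, noise_sd = 0, seed = 1L) {
  if (is.null(names(amplitudes)) || any(!nzchar(names(amplitudes)))) {
    stop("`amplitudes` must be a named vector", call. = FALSE)
  }
  if (any(amplitudes < 0)) stop("amplitudes must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(
      amplitudes = amplitudes, frequency_shift = frequency_shift,
      baseline_offset = baseline_offset, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "mrs_sim_truth"
  )
}

#' Simulate a CSI k-space FID grid from ground truth
#'
#' Forward model: each voxel's FID is a sum of exponentially damped complex
#' sinusoids, one per basis line, with frequency set by the line's chemical
#' shift plus the injected global shift, Lorentzian damping set by its
#' linewidth, and amplitude `truth$amplitudes[metabolite] *
#' relative_amplitude`. The baseline offset is added as the DFT pair of a
#' frequency-domain constant, complex Gaussian noise is added per voxel,
#' and the spatial grid (uniform across voxels) is encoded to k-space at
#' the acquisition matrix size.
#'
#' @param truth an [simulation_truth()].
#' @param lines a line basis from [metabolite_basis()].
#' @param acq an [acq_config()].
#' @return A k-space [fid_grid()]; deterministic given `truth$seed`.
#' @export
simulate_fid <- function(truth, lines = metabolite_basis(), acq = acq_config()) {
  stopifnot(inherits(truth, "mrs_sim_truth"))
  unknown <- setdiff(names(truth$amplitudes), lines$metabolite)
  if (length(unknown)) {
    stop("unknown metabolite(s) in truth: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  uncovered <- setdiff(lines$metabolite, names(truth$amplitudes))
  if (length(uncovered)) {
    stop("truth lacks amplitudes for: ", paste(uncovered, collapse = ", "),
      call. = FALSE
    )
  }
  tt <- time_axis(acq)
  base <- complex(real = numeric(acq$n_time_points))
  for (i in seq_len(nrow(lines))) {
    a <- truth$amplitudes[[lines$metabolite[i]]] * lines$relative_amplitude[i]
    if (a == 0) next
    f_hz <- (lines$chemical_shift[i] + truth$frequency_shift - acq$carrier_ppm) *
      acq$transmitter_mhz
    base <- base + a * exp((2i * pi * f_hz - pi * lines$linewidth_hz[i]) * tt)
  }
  base[1] <- base[1] + truth$baseline_offset
  n <- acq$acq_matrix
  arr <- array(rep(base, each = prod(n)), c(n[1], n[2], acq$n_time_points))
  if (truth$noise_sd > 0) {
    arr <- arr + with_seed(truth$seed, {
      complex(
        real = rnorm(length(arr), sd = truth$noise_sd),
        imaginary = rnorm(length(arr), sd = truth$noise_sd)
      )
    })
  }
  spatial_encode(new_fid_grid(arr, acq, domain = "image"))
}

#' Cohort-generator parameters
#'
#' Defines the three study cohorts (healthy controls and patients with
#' juvenile or late-infantile disease onset), the per-metabolite group
#' effects (myo-inositol and choline intervals elevated in patients, the
#' remaining metabolites depressed, most strongly N-acetylaspartate, with
#' larger effects in the late-infantile group and a stable Cr2), and the
#' generative association targets linking the NAA amplitude to the clinical
#' covariates: a monotone negative link to the 0-6 gross motor score
#' (GMFC-MLD), a positive linear link to IQ, and a negative link to the
#' urinary NAA/creatinine ratio.
#'
#' @param n_control,n_juvenile,n_late_infantile subjects per cohort
#'   (defaults mirror a 12/19/10 clinical cohort).
#' @param effect_juvenile,effect_late_infantile named multipliers (> 0) per
#'   metabolite applied at a subject severity of 1.
#' @param target_gmfc_spearman,target_urine_spearman,target_iq_pearson
#'   generative association strengths.
#' @param severity_sd between-subject spread of the disease-severity scale.
#' @param subject_sd log-normal per-metabolite biological variability.
#' @param noise_sd time-domain noise level passed into each scan's truth.
#' @param shift_range scans receive a frequency shift uniform in
#'   `[-shift_range, shift_range]` ppm.
#' @param baseline_range scans receive a baseline offset uniform in
#'   `[-baseline_range, baseline_range]` intensity units.
#' @param iq_absolute_fraction fraction of juvenile scans with an absolute
#'   IQ value (the rest keep only the IQ >= 85 indicator).
#' @param n_followup number of juvenile subjects receiving a second,
#'   later scan with progressed severity.
#' @param seed integer seed; all randomness derives from it.
#' @return A list of class `mrs_cohort_params`.
#' @export
cohort_params <- function(n_control = 12L, n_juvenile = 19L, n_late_infantile = 10L,
                          effect_juvenile = c(
                            Myo1 = 1.30, Cr1 = 0.90, Glx = 0.95, Myo2 = 1.30,
                            Cho = 1.25, Cr2 = 1.00, Asp = 0.80, NAA1 = 0.95,
                            Gln = 0.85, NAA2 = 0.75
                          ),
                          effect_late_infantile = c(
                            Myo1 = 1.60, Cr1 = 0.80, Glx = 0.90, Myo2 = 1.60,
                            Cho = 1.50, Cr2 = 1.00, Asp = 0.65, NAA1 = 0.90,
                            Gln = 0.70, NAA2 = 0.50
                          ),
                          target_gmfc_spearman = -0.75,
                          target_iq_pearson = 0.84,
                          target_urine_spearman = -0.55,
                          severity_sd = 0.35, subject_sd = 0.08,
                          noise_sd = 0.3, shift_range = 0.1,
                          baseline_range = 2,
                          iq_absolute_fraction = 0.5,
                          n_followup = 0L, seed = 1L) {
  ns <- c(n_control, n_juvenile, n_late_infantile)
  if (any(ns < 0)) stop("cohort sizes must be >= 0", call. = FALSE)
  if (any(effect_juvenile <= 0) || any(effect_late_infantile <= 0)) {
    stop("effect multipliers must be > 0", call. = FALSE)
  }
  structure(
    list(
      n_control = as.integer(n_control), n_juvenile = as.integer(n_juvenile),
      n_late_infantile = as.integer(n_late_infantile),
      effect_juvenile = effect_juvenile,
      effect_late_infantile = effect_late_infantile,
      target_gmfc_spearman = target_gmfc_spearman,
      target_iq_pearson = target_iq_pearson,
      target_urine_spearman = target_urine_spearman,
      severity_sd = severity_sd, subject_sd = subject_sd,
      noise_sd = noise_sd, shift_range = shift_range,
      baseline_range = baseline_range,
      iq_absolute_fraction = iq_absolute_fraction,
      n_followup = as.integer(n_followup), seed = as.integer(seed)
    ),
    class = "mrs_cohort_params"
  )
}

# Bivariate-normal (Pearson) correlation that yields a given Spearman
# correlation after rank transformation: rho = 2 sin(pi * rho_s / 6).
greiner_rho <- function(rho_s) 2 * sin(pi * min(abs(rho_s), 0.999) / 6)

# Latent variable with target correlation `rho` (signed) to standardized x.
latent_with_cor <- function(z, rho) {
  sign(rho) * abs(rho) * z + sqrt(max(0, 1 - rho^2)) * rnorm(length(z))
}

#' Simulate a study cohort with known ground truth
#'
#' Generates one subject record per scan (group, age, GMFC-MLD, IQ, IQ >=
#' 85 indicator, urinary NAA/creatinine) together with the simulation truth
#' (per-metabolite amplitude multipliers, injected frequency shift,
#' baseline offset, noise level, child seed) for each scan. Controls carry
#' no disease effect and a GMFC-MLD of 0; patient metabolite amplitudes
#' follow the group effect multipliers scaled by a subject-level severity.
#' GMFC-MLD is a noisy monotone-decreasing integer function of the
#' subject's NAA amplitude clipped to 0..6, IQ a noisy increasing linear
#' function of it, and the urine ratio a noisy decreasing function, each
#' calibrated to the requested association target.
#'
#' @param params a [cohort_params()] object.
#' @return List with elements `subjects` (data frame, one row per scan)
#'   and `truths` (named list of [simulation_truth()] per `scan_id`).
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "mrs_cohort_params"))
  with_seed(params$seed, {
    groups <- rep(
      c("control", "juvenile", "late_infantile"),
      c(params$n_control, params$n_juvenile, params$n_late_infantile)
    )
    n_sub <- length(groups)
    subject_id <- sprintf("S%03d", seq_len(n_sub))
    age <- numeric(n_sub)
    age[groups == "control"] <- runif(sum(groups == "control"), 10, 59)
    age[groups == "juvenile"] <- runif(sum(groups == "juvenile"), 7.3, 37.1)
    age[groups == "late_infantile"] <- runif(sum(groups == "late_infantile"), 2.1, 5.9)
    severity <- ifelse(groups == "control", 0, pmax(0, rnorm(n_sub, 1, params$severity_sd)))

    # scan-level frame (follow-up scans re-enter with progressed severity)
    scans <- data.frame(
      subject_id = subject_id, group = groups, age_years = age,
      severity = severity, stringsAsFactors = FALSE
    )
    if (params$n_followup > 0) {
      juv <- which(groups == "juvenile")
      take <- head(juv, params$n_followup)
      fup <- scans[take, ]
      fup$age_years <- fup$age_years + 1.2
      fup$severity <- fup$severity + 0.3
      scans <- rbind(scans, fup)
    }
    n_scan <- nrow(scans)
    scans$scan_id <- sprintf("%s_T%d", scans$subject_id, stats::ave(
      rep(1, n_scan),
      scans$subject_id,
      FUN = seq_along
    ))

    mets <- names(params$effect_juvenile)
    log_eff <- rbind(
      control = rep(0, length(mets)),
      juvenile = log(params$effect_juvenile),
      late_infantile = log(params$effect_late_infantile)
    )
    colnames(log_eff) <- mets
    amp <- matrix(NA_real_, n_scan, length(mets), dimnames = list(NULL, mets))
    for (i in seq_len(n_scan)) {
      amp[i, ] <- exp(
        log_eff[scans$group[i], ] * scans$severity[i] +
          rnorm(length(mets), sd = params$subject_sd)
      )
    }

    naa <- amp[, "NAA2"]
    z <- as.numeric(scale(naa))

    # GMFC-MLD: latent Gaussian coupled to -NAA at the Greiner-transformed
    # level, mapped to integers 0..6; controls are developmentally normal.
    rho_g <- greiner_rho(params$target_gmfc_spearman)
    lat_g <- latent_with_cor(z, sign(params$target_gmfc_spearman) * rho_g)
    gmfc <- pmin(6, pmax(0, round(3 + 1.9 * lat_g)))
    gmfc[scans$group == "control"] <- 0L

    # IQ: linear-in-NAA with noise calibrated to the Pearson target,
    # observed for controls and juvenile patients (late-infantile patients
    # are below testable age). The latent is standardized within the
    # observed subset so the target holds where IQ is actually measured.
    # A fraction of juvenile scans keeps only the IQ >= 85 indicator.
    iq <- rep(NA_real_, n_scan)
    iq_obs <- scans$group %in% c("control", "juvenile")
    iq_full <- rep(NA_real_, n_scan)
    if (sum(iq_obs) >= 2) {
      z_iq <- as.numeric(scale(naa[iq_obs]))
      iq_full[iq_obs] <- round(
        92 + 12 * latent_with_cor(z_iq, abs(params$target_iq_pearson))
      )
    }
    iq[iq_obs] <- iq_full[iq_obs]
    iq_ge_85 <- ifelse(iq_obs, iq_full >= 85, NA)
    iq_ge_85[scans$group == "late_infantile"] <- FALSE
    juv_idx <- which(scans$group == "juvenile")
    hide <- juv_idx[runif(length(juv_idx)) > params$iq_absolute_fraction]
    iq[hide] <- NA_real_

    # urine NAA/creatinine: positive, monotone-decreasing in brain NAA
    # (Spearman is invariant under the exp transform), patients only.
    pat <- scans$group != "control"
    urine <- rep(NA_real_, n_scan)
    if (sum(pat) >= 2) {
      zp <- as.numeric(scale(naa[pat]))
      rho_u <- greiner_rho(params$target_urine_spearman)
      urine[pat] <- round(
        exp(1.1 + 0.6 * latent_with_cor(zp, sign(params$target_urine_spearman) * rho_u)),
        3
      )
    }

    subjects <- data.frame(
      scan_id = scans$scan_id, subject_id = scans$subject_id,
      group = scans$group, age_years = round(scans$age_years, 1),
      gmfc = as.integer(gmfc), iq = iq, iq_ge_85 = iq_ge_85,
      urine_naa_over_creatinine = urine, stringsAsFactors = FALSE
    )

    truths <- lapply(seq_len(n_scan), function(i) {
      simulation_truth(
        amplitudes = amp[i, ],
        frequency_shift = runif(1, -params$shift_range, params$shift_range),
        baseline_offset = runif(1, -params$baseline_range, params$baseline_range),
        noise_sd = params$noise_sd,
        seed = child_seed(params$seed, i)
      )
    })
    names(truths) <- scans$scan_id
    list(subjects = subjects, truths = truths)
  })
}
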