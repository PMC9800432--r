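#' The ten default intervals of interest
#'
#' Fixed 0.08-ppm-wide chemical-shift intervals, each oriented towards one
#' main peak of the in-vivo proton brain spectrum and named after the
#' metabolite primarily contributing to it. The absolute integral over each
#' interval serves as a model-free proxy for that metabolite's signal;
#' interval 6 (Cr2, the main creatine peak) is the normalization denominator
#' for all ratios.
#'
#' @return A data frame of class `mrs_ioi_set` with columns `index`, `name`,
#'   `abbreviation`, `ppm_high`, `ppm_low`.
#' @examples
#' default_iois()
#' @export
default_iois <- function() {
  ioi_set(data.frame(
    index = 1:10,
    name = c(
      "Myo-Inositol 1", "Creatine 1", "Glutamate/Glutamine", "Myo-Inositol 2",
      "Choline", "Creatine 2", "Aspartate", "N-Acetylaspartate 1",
      "Glutamine", "N-Acetylaspartate 2"
    ),
    abbreviation = c(
      "Myo1", "Cr1", "Glx", "Myo2", "Cho", "Cr2", "Asp", "NAA1", "Gln", "NAA2"
    ),
    ppm_high = c(4.087, 3.944, 3.786, 3.595, 3.238, 3.048, 2.627, 2.540, 2.341, 2.040),
    ppm_low  = c(4.008, 3.865, 3.706, 3.516, 3.159, 2.968, 2.548, 2.460, 2.262, 1.960),
    stringsAsFactors = FALSE
  ))
}

#' Validate a set of interval-of-interest definitions
#'
#' @param df data frame with columns `index`, `name`, `abbreviation`,
#'   `ppm_high`, `ppm_low`. Every interval must have `ppm_high > ppm_low`,
#'   a width that rounds to 0.08 ppm at two decimals, and a unique
#'   abbreviation.
#' @return `df` with class `mrs_ioi_set` prepended.
#' @export
ioi_set <- function(df) {
  required <- c("index", "name", "abbreviation", "ppm_high", "ppm_low")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("IOI definitions lack columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(df$ppm_high <= df$ppm_low)) {
    stop("every IOI must have ppm_high > ppm_low", call. = FALSE)
  }
  widths <- round(df$ppm_high - df$ppm_low, 2)
  if (any(widths != 0.08)) {
    bad <- df$abbreviation[widths != 0.08]
    stop("IOI width must round to 0.08 ppm; violated by: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(df$abbreviation)) {
    stop("IOI abbreviations must be unique", call. = FALSE)
  }
  class(df) <- c("mrs_ioi_set", "data.frame")
  df
}

#' Read interval definitions from a CSV configuration file
#'
#' The file must have columns `name`, `abbreviation`, `ppm_high`, `ppm_low`
#' (an `index` column is optional and regenerated from row order if absent).
#'
#' @param path path to a CSV file.
#' @return An `mrs_ioi_set`.
#' @export
read_ioi_config <- function(path) {
  if (!file.exists(path)) stop("IOI config not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (is.null(df$index)) df$index <- seq_len(nrow(df))
  ioi_set(df[, c("index", "name", "abbreviation", "ppm_high", "ppm_low")])
}

#' Absolute integral of a spectrum over one interval of interest
#'
#' Integrates the real part of the spectrum over all axis points with
#' `ppm_low <= ppm <= ppm_high` (closed on both ends, no partial-bin
#' weighting) by the trapezoidal rule on the native axis, and returns the
#' absolute value. Intended for baseline-subtracted spectra.
#'
#' @param spec an [mrs_spectrum()].
#' @param ioi one row of an `mrs_ioi_set` (or any list with `ppm_high`,
#'   `ppm_low`).
#' @param mode `"real"` (default) integrates the real part;
#'   `"magnitude"` integrates `Mod(intensity)`.
#' @return Non-negative scalar, units intensity x ppm.
#' @export
integrate_interval <- function(spec, ioi, mode = c("real", "magnitude")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "mrs_spectrum"))
  sel <- spec$ppm >= ioi$ppm_low & spec$ppm <= ioi$ppm_high
  if (!any(sel)) {
    stop(
      sprintf("no axis points inside interval [%g, %g] ppm", ioi$ppm_low, ioi$ppm_high),
      call. = FALSE
    )
  }
  x <- rev(spec$ppm[sel]) # ascending ppm
  y <- if (mode == "real") rev(Re(spec$intensity[sel])) else rev(Mod(spec$intensity[sel]))
  abs(trapezoid(x, y))
}

# Trapezoidal rule on an ascending grid.
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

#' Creatine-normalized interval ratios for one spectrum
#'
#' Integrates every interval of interest and divides by the Cr2 integral
#' (the main creatine peak). The Cr2 ratio is exactly 1 by construction;
#' all ratios are invariant to global intensity scaling.
#'
#' @param spec an [mrs_spectrum()], baseline-subtracted.
#' @param iois an `mrs_ioi_set`; must contain an interval abbreviated
#'   `reference`.
#' @param reference abbreviation of the normalization interval (`"Cr2"`).
#' @param tol spectra whose reference integral is `<= tol` are rejected as
#'   unusable (no creatine signal to normalize by).
#' @param mode passed to [integrate_interval()].
#' @return Named numeric vector of ratios, one per interval.
#' @export
compute_ratios <- function(spec, iois = default_iois(), reference = "Cr2",
                           tol = 1e-10, mode = c("real", "magnitude")) {
  mode <- match.arg(mode)
  if (!reference %in% iois$abbreviation) {
    stop("reference interval '", reference, "' is not among the IOIs", call. = FALSE)
  }
  integrals <- vapply(
    seq_len(nrow(iois)),
    function(i) integrate_interval(spec, iois[i, ], mode = mode),
    numeric(1)
  )
  names(integrals) <- iois$abbreviation
  ref <- integrals[[reference]]
  if (!is.finite(ref) || ref <= tol) {
    stop(
      sprintf(
        "unusable spectrum: %s integral (%.3g) is not above tolerance %.3g",
        reference, ref, tol
      ),
      call. = FALSE
    )
  }
  ratios <- integrals / ref
  ratios[[reference]] <- 1
  ratios
}
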