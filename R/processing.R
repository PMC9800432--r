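#' Spectrum container
#'
#' Intensities on a strictly decreasing chemical-shift (ppm) axis, plus a
#' metadata list recording the voxel of origin and which processing steps
#' have been applied.
#'
#' @param ppm numeric, strictly decreasing chemical-shift axis.
#' @param intensity complex (or numeric) vector, same length as `ppm`.
#' @param meta list of metadata (voxel index, processing flags, ...).
#' @return An object of class `mrs_spectrum`.
#' @export
mrs_spectrum <- function(ppm, intensity, meta = list()) {
  if (length(ppm) != length(intensity)) {
    stop("`ppm` and `intensity` must have the same length", call. = FALSE)
  }
  if (any(diff(ppm) >= 0)) {
    stop("`ppm` axis must be strictly decreasing", call. = FALSE)
  }
  if (!is.complex(intensity)) intensity <- as.complex(intensity)
  structure(list(ppm = ppm, intensity = intensity, meta = meta),
    class = "mrs_spectrum"
  )
}

#' @export
print.mrs_spectrum <- function(x, ...) {
  cat(sprintf(
    "<mrs_spectrum> %d pts, %.2f..%.2f ppm, steps: %s\n",
    length(x$ppm), max(x$ppm), min(x$ppm),
    if (length(x$meta$steps)) paste(x$meta$steps, collapse = " > ") else "none"
  ))
  invisible(x)
}

#' Exponential apodization of FID data
#'
#' Multiplies each FID time point by the one-sided exponential window
#' `w(t) = 2^(-t / fwhm)`, so `w(0) = 1` and the filter has decayed to one
#' half at `t = fwhm`. Smooths the spectrum at the cost of Lorentzian line
#' broadening of `log(2) / (pi * fwhm)` Hz (about 0.62 Hz at the default).
#'
#' @param x an [fid_grid()] (either domain) or a complex FID vector.
#' @param fwhm half-decay time of the filter in seconds; must be > 0.
#' @param acq required when `x` is a bare vector, ignored for grids.
#' @return Object of the same shape as `x`.
#' @export
apodize <- function(x, fwhm = 0.355, acq = NULL) {
  if (!is.numeric(fwhm) || length(fwhm) != 1L || fwhm <= 0) {
    stop("`fwhm` must be a single value > 0", call. = FALSE)
  }
  if (inherits(x, "mrs_fid_grid")) {
    w <- 2^(-time_axis(x$acq) / fwhm)
    d <- dim(x$data)
    x$data <- x$data * rep(w, each = d[1] * d[2])
    return(x)
  }
  if (is.null(acq)) stop("`acq` is required to apodize a bare FID vector", call. = FALSE)
  x * 2^(-time_axis(acq) / fwhm)
}

# Centered k-space index offsets for a grid of length n (DC at floor(n/2)+1).
k_offsets <- function(n) seq_len(n) - (floor(n / 2) + 1L)

# Forward spatial encoding: image-domain grid -> centered k-space, same size.
# K[u,v,t] = sum_{x,y} S[x,y,t] exp(-2i pi (k_u x / N_r + k_v y / N_c))
spatial_encode <- function(grid) {
  stopifnot(inherits(grid, "mrs_fid_grid"))
  d <- dim(grid$data)
  er <- exp(-2i * pi * outer(k_offsets(d[1]), 0:(d[1] - 1)) / d[1])
  ec <- exp(-2i * pi * outer(k_offsets(d[2]), 0:(d[2] - 1)) / d[2])
  out <- apply_spatial(grid$data, er, ec)
  acq <- grid$acq
  acq$acq_matrix <- d[1:2]
  new_fid_grid(out, acq, domain = "kspace")
}

# Apply row matrix `mr` (R' x R) and column matrix `mc` (C' x C) to every
# time slice of a 3-d array: out[i,j,t] = sum_{x,y} mr[i,x] a[x,y,t] mc[j,y].
apply_spatial <- function(a, mr, mc) {
  d <- dim(a)
  tmp <- mr %*% matrix(a, d[1], d[2] * d[3]) # R' x (C*T)
  tmp <- aperm(array(tmp, c(nrow(mr), d[2], d[3])), c(2, 1, 3)) # C x R' x T
  out <- mc %*% matrix(tmp, d[2], nrow(mr) * d[3]) # C' x (R'*T)
  aperm(array(out, c(nrow(mc), nrow(mr), d[3])), c(2, 1, 3))
}

#' Zero-filled spatial reconstruction of a CSI k-space grid
#'
#' Pads the centered k-space matrix symmetrically with zeros up to the
#' reconstruction matrix (keeping the DC sample centered) and applies an
#' inverse two-dimensional discrete Fourier transform per time point,
#' normalized by the number of acquired k-space samples. A k-space grid
#' with only the DC sample non-zero therefore reconstructs to spatially
#' constant voxel FIDs.
#'
#' @param grid a k-space [fid_grid()].
#' @return An image-domain `mrs_fid_grid` of size `recon_matrix`.
#' @export
spatial_reconstruct <- function(grid) {
  stopifnot(inherits(grid, "mrs_fid_grid"))
  if (grid$domain != "kspace") stop("`grid` must be in k-space", call. = FALSE)
  acq <- grid$acq
  n <- acq$acq_matrix
  m <- acq$recon_matrix
  if (any(m < n)) stop("recon matrix must be >= acquisition matrix", call. = FALSE)
  d <- dim(grid$data)
  # decode matrix evaluating the zero-padded inverse DFT on the recon grid:
  # S[x] = (1/(n_r n_c)) sum_u K[u] exp(+2i pi k_u x / m)
  dr <- exp(2i * pi * outer(0:(m[1] - 1), k_offsets(n[1])) / m[1])
  dc <- exp(2i * pi * outer(0:(m[2] - 1), k_offsets(n[2])) / m[2])
  out <- apply_spatial(grid$data, dr, dc) / prod(n)
  new_fid_grid(out, acq, domain = "image")
}

#' Reconstruct selected voxels directly from k-space
#'
#' Evaluates the zero-filled inverse DFT of [spatial_reconstruct()] at the
#' requested reconstruction-grid positions only (the padded k-space entries
#' are zero, so the truncated sum is exact). Orders of magnitude faster
#' when only a handful of region-of-interest voxels are needed.
#'
#' @param grid a k-space [fid_grid()].
#' @param voxels integer matrix with columns (row, col), 1-based positions
#'   on the reconstruction grid.
#' @return Complex matrix, one row per voxel, `n_time_points` columns.
#' @export
reconstruct_voxels <- function(grid, voxels) {
  stopifnot(inherits(grid, "mrs_fid_grid"))
  if (grid$domain != "kspace") stop("`grid` must be in k-space", call. = FALSE)
  voxels <- matrix(as.integer(voxels), ncol = 2)
  acq <- grid$acq
  n <- acq$acq_matrix
  m <- acq$recon_matrix
  if (any(voxels < 1L) || any(voxels[, 1] > m[1]) || any(voxels[, 2] > m[2])) {
    stop("voxel positions fall outside the reconstruction grid", call. = FALSE)
  }
  kr <- k_offsets(n[1])
  kc <- k_offsets(n[2])
  # phase[j, (u,v)] over k-space cells in column-major order
  ph_r <- exp(2i * pi * outer(voxels[, 1] - 1, kr) / m[1]) # nv x n_r
  ph_c <- exp(2i * pi * outer(voxels[, 2] - 1, kc) / m[2]) # nv x n_c
  nv <- nrow(voxels)
  phase <- matrix(0i, nv, prod(n))
  for (j in seq_len(nv)) {
    phase[j, ] <- as.vector(outer(ph_r[j, ], ph_c[j, ]))
  }
  (phase %*% matrix(grid$data, prod(n), acq$n_time_points)) / prod(n)
}

#' Fourier transform a voxel FID into a spectrum
#'
#' Applies the (unnormalized) discrete Fourier transform and maps the
#' frequency axis to chemical shift via
#' `ppm = carrier_ppm + f / transmitter_mhz`, returning the spectrum on a
#' strictly decreasing ppm axis. Time-domain and spectral energy obey
#' Parseval's identity (`sum |fid|^2 = sum |spectrum|^2 / N`).
#'
#' @param voxel_fid complex FID vector.
#' @param acq an [acq_config()].
#' @param meta metadata list carried into the spectrum.
#' @return An [mrs_spectrum()].
#' @export
fourier_transform <- function(voxel_fid, acq, meta = list()) {
  if (length(voxel_fid) != acq$n_time_points) {
    stop("FID length does not match `n_time_points`", call. = FALSE)
  }
  ax <- axis_info(acq)
  spec <- stats::fft(as.complex(voxel_fid))[ax$order]
  meta$steps <- c(meta$steps, "fourier_transform")
  mrs_spectrum(ax$ppm, spec, meta)
}

#' Locate the NAA peak and measure its offset from 2 ppm
#'
#' Searches the real part of the spectrum inside `window` for its maximum
#' and returns the signed chemical-shift distance of that maximum from the
#' expected N-acetylaspartate position of 2 ppm. If the window is flat
#' (e.g. all-zero), 0 is returned with a `"flat_window"` flag attribute and
#' a warning.
#'
#' @param spec an [mrs_spectrum()].
#' @param window ppm pair delimiting the search range.
#' @param reference_ppm expected peak position (2 ppm for NAA).
#' @return Scalar shift in ppm (peak position minus `reference_ppm`).
#' @export
find_naa_shift <- function(spec, window = c(1.75, 2.25), reference_ppm = 2.0) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  lo <- min(window)
  hi <- max(window)
  sel <- which(spec$ppm >= lo & spec$ppm <= hi)
  if (!length(sel)) {
    stop(sprintf("search window [%g, %g] ppm is outside the axis", lo, hi), call. = FALSE)
  }
  y <- Re(spec$intensity[sel])
  if (diff(range(y)) == 0) {
    warning("flat spectrum in NAA search window; assuming zero shift")
    return(structure(0, flag = "flat_window"))
  }
  spec$ppm[sel[which.max(y)]] - reference_ppm
}

#' Frequency-correct a spectrum by a measured shift
#'
#' Moves the spectral content by `-shift` ppm so a peak found at
#' `2 + shift` ppm lands back on 2 ppm. The default rotates the intensity
#' vector by the nearest integer number of spectral bins (the axis is
#' unchanged); `method = "interp"` instead linearly interpolates the real
#' and imaginary parts onto the shifted axis for sub-bin correction.
#'
#' @param spec an [mrs_spectrum()].
#' @param shift measured offset in ppm (as returned by [find_naa_shift()]).
#' @param method `"bin"` (default, circular integer-bin shift) or
#'   `"interp"`.
#' @return The corrected `mrs_spectrum`.
#' @export
frequency_correct <- function(spec, shift, method = c("bin", "interp")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "mrs_spectrum"))
  span <- max(spec$ppm) - min(spec$ppm)
  if (abs(shift) >= span) stop("|shift| must be smaller than the axis span", call. = FALSE)
  n <- length(spec$ppm)
  if (method == "bin") {
    step <- -mean(diff(spec$ppm)) # ppm per index (axis decreasing)
    k <- as.integer(round(shift / step))
    idx <- ((seq_len(n) - 1 - k) %% n) + 1
    spec$intensity <- spec$intensity[idx]
  } else {
    xout <- spec$ppm + shift
    re <- stats::approx(spec$ppm, Re(spec$intensity), xout = xout, rule = 2)$y
    im <- stats::approx(spec$ppm, Im(spec$intensity), xout = xout, rule = 2)$y
    spec$intensity <- complex(real = re, imaginary = im)
  }
  spec$meta$steps <- c(spec$meta$steps, "frequency_correct")
  spec$meta$shift_applied <- shift
  spec
}

#' Subtract the baseline offset estimated from a signal-free window
#'
#' Estimates the spectrum's baseline as the mean real intensity over the
#' spectral range between 0.9 and 1.6 ppm (a region without major
#' metabolite peaks) and subtracts it from every point, so the window mean
#' of the result is zero.
#'
#' @param spec an [mrs_spectrum()].
#' @param window ppm pair of the baseline estimation range.
#' @return The baseline-subtracted `mrs_spectrum`; the removed offset is
#'   recorded in `meta$baseline_offset`.
#' @export
subtract_baseline <- function(spec, window = c(0.9, 1.6)) {
  stopifnot(inherits(spec, "mrs_spectrum"))
  sel <- spec$ppm >= min(window) & spec$ppm <= max(window)
  if (!any(sel)) {
    stop(
      sprintf("no axis points in baseline window [%g, %g] ppm", min(window), max(window)),
      call. = FALSE
    )
  }
  offset <- mean(Re(spec$intensity[sel]))
  spec$intensity <- spec$intensity - offset
  spec$meta$steps <- c(spec$meta$steps, "subtract_baseline")
  spec$meta$baseline_offset <- offset
  spec
}

#' Processing options for [process_voxel()]
#'
#' @param apodize apply exponential apodization before the transform.
#' @param fwhm apodization half-decay time, seconds.
#' @param frequency_correct align the NAA peak to 2 ppm.
#' @param naa_window ppm search window for the NAA peak.
#' @param shift_method `"bin"` or `"interp"`, see [frequency_correct()].
#' @param baseline subtract the baseline offset.
#' @param baseline_window ppm window for the baseline estimate.
#' @param phase0 optional zero-order phase (radians) applied after the
#'   transform; `NULL` (default) applies none, matching acquisitions where
#'   no phase correction is necessary.
#' @return A list of class `mrs_proc_options`.
#' @export
process_options <- function(apodize = TRUE, fwhm = 0.355,
                            frequency_correct = TRUE,
                            naa_window = c(1.75, 2.25),
                            shift_method = c("bin", "interp"),
                            baseline = TRUE, baseline_window = c(0.9, 1.6),
                            phase0 = NULL) {
  structure(
    list(
      apodize = isTRUE(apodize), fwhm = fwhm,
      frequency_correct = isTRUE(frequency_correct),
      naa_window = naa_window, shift_method = match.arg(shift_method),
      baseline = isTRUE(baseline), baseline_window = baseline_window,
      phase0 = phase0
    ),
    class = "mrs_proc_options"
  )
}

#' Full post-processing chain for one voxel FID
#'
#' Composes, in order: exponential apodization, Fourier transform,
#' (optional zero-order phase), frequency correction to the NAA peak, and
#' baseline-offset subtraction. Each enabled step is recorded in the
#' spectrum metadata together with the shift and offset that were applied.
#'
#' @param voxel_fid complex FID vector.
#' @param acq an [acq_config()].
#' @param options an [process_options()] list.
#' @param meta initial metadata (e.g. voxel index).
#' @return A processed [mrs_spectrum()].
#' @export
process_voxel <- function(voxel_fid, acq, options = process_options(),
                          meta = list()) {
  if (options$apodize) {
    voxel_fid <- apodize(voxel_fid, fwhm = options$fwhm, acq = acq)
    meta$steps <- c(meta$steps, "apodize")
  }
  spec <- fourier_transform(voxel_fid, acq, meta = meta)
  if (!is.null(options$phase0)) {
    spec$intensity <- spec$intensity * exp(-1i * options$phase0)
    spec$meta$steps <- c(spec$meta$steps, "phase0")
  }
  if (options$frequency_correct) {
    shift <- find_naa_shift(spec, window = options$naa_window)
    spec <- frequency_correct(spec, shift, method = options$shift_method)
    if (!is.null(attr(shift, "flag"))) spec$meta$flags <- attr(shift, "flag")
  }
  if (options$baseline) {
    spec <- subtract_baseline(spec, window = options$baseline_window)
  }
  spec
}

#' Pointwise average of spectra on a common axis
#'
#' @param specs list of [mrs_spectrum()] objects with identical ppm axes.
#' @return An `mrs_spectrum` holding the arithmetic mean intensity.
#' @export
average_spectra <- function(specs) {
  if (!length(specs)) stop("no spectra to average", call. = FALSE)
  ref <- specs[[1]]
  for (s in specs[-1]) {
    if (!isTRUE(all.equal(ref$ppm, s$ppm))) {
      stop("spectra have mismatched ppm axes", call. = FALSE)
    }
  }
  total <- Reduce(`+`, lapply(specs, function(s) s$intensity))
  mrs_spectrum(ref$ppm, total / length(specs),
    meta = list(steps = "average_spectra", n = length(specs))
  )
}
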