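#' Acquisition configuration for a CSI measurement
#'
#' Bundles the geometric and spectral constants of a chemical shift imaging
#' acquisition: the k-space acquisition matrix, the reconstruction matrix the
#' raw data are zero-filled to, the number of time-domain samples per FID,
#' the dwell time (reciprocal of the spectral width), and the two constants
#' that map frequency to chemical shift -- the carrier position in ppm and
#' the transmitter frequency in MHz.
#'
#' The defaults describe a 12 x 12 acquisition reconstructed to a 32 x 32
#' grid of 1024-point spectra. The spectral-axis constants (spectral width
#' 1200 Hz, transmitter 123.25 MHz, carrier 4.7 ppm) are typical 3 T proton
#' values; all downstream results are creatine-normalized ratios and are
#' insensitive to them, but they remain user configuration.
#'
#' @param acq_matrix integer pair, k-space acquisition matrix (rows, cols).
#' @param recon_matrix integer pair, reconstruction matrix; must be
#'   elementwise >= `acq_matrix`.
#' @param n_time_points number of complex FID samples per voxel.
#' @param dwell_time sampling interval in seconds (1 / spectral width in Hz).
#' @param carrier_ppm chemical shift of the carrier (axis centre), ppm.
#' @param transmitter_mhz transmitter frequency in MHz (Hz per ppm).
#' @return An object of class `mrs_acq`.
#' @examples
#' acq <- acq_config()
#' acq$recon_matrix
#' @export
acq_config <- function(acq_matrix = c(12L, 12L),
                       recon_matrix = c(32L, 32L),
                       n_time_points = 1024L,
                       dwell_time = 1 / 1200,
                       carrier_ppm = 4.7,
                       transmitter_mhz = 123.25) {
  acq_matrix <- as.integer(acq_matrix)
  recon_matrix <- as.integer(recon_matrix)
  if (length(acq_matrix) != 2L || any(acq_matrix < 1L)) {
    stop("`acq_matrix` must be two positive integers", call. = FALSE)
  }
  if (length(recon_matrix) != 2L || any(recon_matrix < acq_matrix)) {
    stop("`recon_matrix` must be elementwise >= `acq_matrix`", call. = FALSE)
  }
  n_time_points <- as.integer(n_time_points)
  if (n_time_points < 1L) stop("`n_time_points` must be positive", call. = FALSE)
  if (!is.numeric(dwell_time) || dwell_time <= 0) {
    stop("`dwell_time` must be > 0", call. = FALSE)
  }
  if (!is.numeric(transmitter_mhz) || transmitter_mhz <= 0) {
    stop("`transmitter_mhz` must be > 0", call. = FALSE)
  }
  structure(
    list(
      acq_matrix = acq_matrix,
      recon_matrix = recon_matrix,
      n_time_points = n_time_points,
      dwell_time = dwell_time,
      carrier_ppm = carrier_ppm,
      transmitter_mhz = transmitter_mhz
    ),
    class = "mrs_acq"
  )
}

#' @export
print.mrs_acq <- function(x, ...) {
  cat(
    sprintf(
      "<mrs_acq> %dx%d k-space -> %dx%d recon, %d pts, SW %.0f Hz, %s MHz, carrier %.2f ppm\n",
      x$acq_matrix[1], x$acq_matrix[2], x$recon_matrix[1], x$recon_matrix[2],
      x$n_time_points, 1 / x$dwell_time, format(x$transmitter_mhz), x$carrier_ppm
    )
  )
  invisible(x)
}

# Time vector of the FID samples (seconds).
time_axis <- function(acq) {
  (seq_len(acq$n_time_points) - 1) * acq$dwell_time
}

#' Chemical-shift axis of the processed spectrum
#'
#' Frequencies of the discrete Fourier transform of an FID sampled at the
#' configured dwell time, mapped to chemical shift by
#' `ppm = carrier_ppm + f / transmitter_mhz` (f in Hz) and returned in the
#' conventional strictly decreasing ppm order.
#'
#' @param acq an [acq_config()] object.
#' @return Numeric vector of length `n_time_points`, strictly decreasing.
#' @export
ppm_axis <- function(acq) {
  axis_info(acq)$ppm
}

# ppm axis plus the permutation that reorders raw FFT output (DC first,
# negative frequencies in the upper half) into descending-ppm order.
axis_info <- function(acq) {
  n <- acq$n_time_points
  k <- seq_len(n) - 1
  f <- k / (n * acq$dwell_time)
  f[k >= ceiling(n / 2)] <- f[k >= ceiling(n / 2)] - 1 / acq$dwell_time
  ppm_fft <- acq$carrier_ppm + f / acq$transmitter_mhz
  ord <- order(ppm_fft, decreasing = TRUE)
  list(ppm = ppm_fft[ord], order = ord, step = 1 / (n * acq$dwell_time * acq$transmitter_mhz))
}

#' FID grid container
#'
#' A three-dimensional complex array of free induction decays indexed
#' (row, column, time) together with its acquisition configuration. The
#' `domain` field records whether the spatial dimensions are k-space (as
#' extracted from a CSI data set) or image space (after reconstruction).
#'
#' @param data complex array, `dim = c(rows, cols, n_time_points)`.
#' @param acq an [acq_config()] object.
#' @param domain `"kspace"` or `"image"`.
#' @return An object of class `mrs_fid_grid`.
#' @export
fid_grid <- function(data, acq, domain = c("kspace", "image")) {
  domain <- match.arg(domain)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (row, col, time)", call. = FALSE)
  }
  if (domain == "kspace" && !identical(dim(data)[1:2], acq$acq_matrix)) {
    stop(
      sprintf(
        "spatial dimensions %dx%d do not match the acquisition matrix %dx%d",
        dim(data)[1], dim(data)[2], acq$acq_matrix[1], acq$acq_matrix[2]
      ),
      call. = FALSE
    )
  }
  if (dim(data)[3] != acq$n_time_points) {
    stop(
      sprintf(
        "time dimension %d does not match n_time_points = %d",
        dim(data)[3], acq$n_time_points
      ),
      call. = FALSE
    )
  }
  if (!is.complex(data)) storage.mode(data) <- "complex"
  if (anyNA(data) || any(is.infinite(data))) {
    stop("FID data must be finite", call. = FALSE)
  }
  new_fid_grid(data, acq, domain)
}

# trusted-path constructor: no validation
new_fid_grid <- function(data, acq, domain) {
  structure(list(data = data, acq = acq, domain = domain), class = "mrs_fid_grid")
}

#' @export
print.mrs_fid_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mrs_fid_grid> %s %dx%dx%d\n", x$domain, d[1], d[2], d[3]))
  invisible(x)
}
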