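test_that("apodization implements the half-decay exponential window", {
  acq <- voxel_acq(256L)
  # choose fwhm = 32 dwell times so t = fwhm falls exactly on a sample
  fwhm <- 32 * acq$dwell_time
  ones <- rep(1 + 0i, acq$n_time_points)
  out <- apodize(ones, fwhm = fwhm, acq = acq)
  expect_identical(out[1], 1 + 0i) # w(0) = 1
  expect_equal(Re(out[33]), 0.5) # w(fwhm) = 1/2
  tt <- (0:255) * acq$dwell_time
  expect_equal(Re(out), 2^(-tt / fwhm))
  expect_error(apodize(ones, fwhm = 0, acq = acq), "> 0")
  expect_error(apodize(ones, fwhm = -1, acq = acq), "> 0")
  # infinitely slow filter is the identity
  out2 <- apodize(ones, fwhm = 1e12, acq = acq)
  expect_lt(max(Mod(out2 - ones)), 1e-12)
})

test_that("apodizing a grid equals apodizing each voxel FID", {
  acq <- tiny_acq()
  grid <- random_grid(acq, seed = 7)
  ga <- apodize(grid, fwhm = 0.1)
  expect_equal(
    ga$data[2, 3, ],
    apodize(grid$data[2, 3, ], fwhm = 0.1, acq = acq)
  )
})

test_that("fourier transform matches a brute-force DFT and conserves energy", {
  acq <- tiny_acq(64L)
  set.seed(3)
  fid <- complex(real = rnorm(64), imaginary = rnorm(64))
  spec <- fourier_transform(fid, acq)
  expect_true(all(diff(spec$ppm) < 0))
  oracle <- dft_oracle(fid)
  expect_equal(sort(Mod(spec$intensity)), sort(Mod(oracle)), tolerance = 1e-10)
  # Parseval
  expect_equal(sum(Mod(fid)^2), sum(Mod(spec$intensity)^2) / 64, tolerance = 1e-8)
  # a pure complex exponential lands on the predicted ppm
  f_hz <- 100
  fid2 <- exp(2i * pi * f_hz * (0:63) * acq$dwell_time)
  spec2 <- fourier_transform(fid2, acq)
  peak_ppm <- spec2$ppm[which.max(Mod(spec2$intensity))]
  expect_equal(peak_ppm, 4.7 + 100 / 123.25, tolerance = 1200 / 64 / 123.25)
  o2 <- dft_oracle(fid2)
  expect_equal(Mod(spec2$intensity[which.max(Mod(spec2$intensity))]),
    max(Mod(o2)),
    tolerance = 1e-8
  )
  # impulse at t = 0 gives a flat magnitude spectrum
  imp <- c(1 + 0i, rep(0i, 63))
  spec3 <- fourier_transform(imp, acq)
  expect_equal(Mod(spec3$intensity), rep(1, 64), tolerance = 1e-12)
})

test_that("zero-filled reconstruction has the documented Fourier properties", {
  acq <- acq_config(
    acq_matrix = c(12L, 12L), recon_matrix = c(32L, 32L), n_time_points = 4L
  )
  # DC-only k-space reconstructs to spatially constant FIDs
  arr <- array(0i, c(12, 12, 4))
  arr[7, 7, ] <- c(1 + 0i, 2 + 0i, 3 + 0i, 4 + 0i) # DC at floor(n/2)+1
  rec <- spatial_reconstruct(fid_grid(arr, acq, domain = "kspace"))
  expect_equal(dim(rec$data), c(32L, 32L, 4L))
  for (t in 1:4) {
    expect_equal(max(Mod(rec$data[, , t] - rec$data[1, 1, t])), 0, tolerance = 1e-12)
  }
  # linearity
  g1 <- random_grid(acq, seed = 1)
  g2 <- random_grid(acq, seed = 2)
  comb <- g1
  comb$data <- 2 * g1$data - 3i * g2$data
  lhs <- spatial_reconstruct(comb)$data
  rhs <- 2 * spatial_reconstruct(g1)$data - 3i * spatial_reconstruct(g2)$data
  expect_lt(max(Mod(lhs - rhs)), 1e-10)
  # recon smaller than acquisition is rejected
  bad <- acq
  expect_error(
    acq_config(acq_matrix = c(12, 12), recon_matrix = c(8, 8)),
    ">="
  )
})

test_that("per-voxel DFT reconstruction equals the full zero-filled transform", {
  acq <- acq_config(
    acq_matrix = c(6L, 5L), recon_matrix = c(16L, 17L), n_time_points = 8L
  )
  grid <- random_grid(acq, seed = 11)
  full <- spatial_reconstruct(grid)
  vox <- rbind(c(1, 1), c(5, 9), c(16, 17), c(8, 3))
  fast <- reconstruct_voxels(grid, vox)
  for (j in seq_len(nrow(vox))) {
    expect_lt(max(Mod(fast[j, ] - full$data[vox[j, 1], vox[j, 2], ])), 1e-12)
  }
  expect_error(reconstruct_voxels(grid, rbind(c(0, 1))), "outside")
})

test_that("round-trip: encoding a uniform image and reconstructing recovers it", {
  acq <- acq_config(
    acq_matrix = c(4L, 4L), recon_matrix = c(4L, 4L), n_time_points = 16L
  )
  set.seed(5)
  base <- complex(real = rnorm(16), imaginary = rnorm(16))
  img <- array(rep(base, each = 16), c(4, 4, 16))
  k <- mrsioi:::spatial_encode(fid_grid(img, acq, domain = "image"))
  back <- spatial_reconstruct(k)
  expect_lt(max(Mod(back$data - img)), 1e-10)
})

test_that("the NAA shift estimator finds displaced peaks", {
  acq <- voxel_acq()
  step <- 1 / (1024 * acq$dwell_time * acq$transmitter_mhz)
  on_target <- fourier_transform(single_line_fid(2.0, acq), acq)
  expect_lt(abs(find_naa_shift(on_target)), step / 2 + 1e-12)
  displaced <- fourier_transform(single_line_fid(2.08, acq), acq)
  expect_lt(abs(find_naa_shift(displaced) - 0.08), step)
  zero <- mrs_spectrum(ppm_axis(acq), rep(0i, 1024))
  expect_warning(s <- find_naa_shift(zero), "flat")
  expect_identical(as.numeric(s), 0)
  expect_identical(attr(s, "flag"), "flat_window")
  expect_error(find_naa_shift(on_target, window = c(30, 31)), "outside the axis")
})

test_that("negative shifts are recovered under noise", {
  acq <- voxel_acq()
  step <- 1 / (1024 * acq$dwell_time * acq$transmitter_mhz)
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    fid <- single_line_fid(1.95, acq, amplitude = 1) +
      complex(real = rnorm(1024, sd = 0.2), imaginary = rnorm(1024, sd = 0.2))
    spec <- fourier_transform(apodize(fid, acq = acq), acq)
    if (abs(find_naa_shift(spec) - (-0.05)) <= step) hits <- hits + 1L
  }
  expect_gte(hits, 99L)
})

test_that("frequency correction moves content by whole bins", {
  acq <- voxel_acq()
  spec <- fourier_transform(single_line_fid(2.1, acq), acq)
  same <- frequency_correct(spec, 0)
  expect_equal(same$intensity, spec$intensity)
  step <- -mean(diff(spec$ppm))
  one <- frequency_correct(spec, step)
  n <- length(spec$ppm)
  expect_equal(one$intensity, spec$intensity[c(n, 1:(n - 1))])
  expect_error(frequency_correct(spec, 100), "span")
})

test_that("shift-correct round trip leaves at most half a bin of residual", {
  acq <- voxel_acq()
  step <- 1 / (1024 * acq$dwell_time * acq$transmitter_mhz)
  win <- c(1.65, 2.35)
  for (delta in seq(-0.3, 0.3, by = 0.06)) {
    fid <- single_line_fid(2.0 + delta, acq)
    spec <- fourier_transform(fid, acq)
    est <- find_naa_shift(spec, window = win)
    corrected <- frequency_correct(spec, est)
    resid <- find_naa_shift(corrected, window = win)
    expect_lte(abs(resid), step / 2 + 1e-9)
  }
})

test_that("sub-bin interpolated correction also recenters the peak", {
  acq <- voxel_acq()
  step <- 1 / (1024 * acq$dwell_time * acq$transmitter_mhz)
  spec <- fourier_transform(single_line_fid(2.123, acq), acq)
  est <- find_naa_shift(spec, window = c(1.65, 2.35))
  corrected <- frequency_correct(spec, est, method = "interp")
  expect_lte(abs(find_naa_shift(corrected, window = c(1.65, 2.35))), step + 1e-9)
})

test_that("baseline subtraction zeroes the reference window", {
  acq <- acq_config()
  const <- analytic_spectrum(function(p) rep(3, length(p)), acq)
  out <- subtract_baseline(const)
  expect_equal(max(Mod(out$intensity)), 0, tolerance = 1e-12)
  expect_equal(out$meta$baseline_offset, 3)

  spec <- analytic_spectrum(function(p) exp(-(p - 3)^2 / 0.1), acq)
  win <- spec$ppm >= 0.9 & spec$ppm <= 1.6
  base <- subtract_baseline(spec)
  expect_lt(abs(mean(Re(base$intensity[win]))), 1e-12)
  # adding a constant then subtracting equals subtracting alone
  shifted <- spec
  shifted$intensity <- shifted$intensity + 7.5
  expect_equal(subtract_baseline(shifted)$intensity, base$intensity,
    tolerance = 1e-12
  )
  expect_error(subtract_baseline(spec, window = c(40, 41)), "no axis points")
})

test_that("the full voxel chain composes the steps in order", {
  acq <- voxel_acq()
  step <- 1 / (1024 * acq$dwell_time * acq$transmitter_mhz)
  lines <- metabolite_basis(
    relative_amplitudes = c(
      Myo1 = 0, Cr1 = 0, Glx = 0, Myo2 = 0, Cho = 0, Cr2 = 1, Asp = 0,
      NAA1 = 0, Gln = 0, NAA2 = 2
    )
  )
  truth <- unit_truth(frequency_shift = 0.1, baseline_offset = 2)
  grid <- simulate_fid(truth, lines, acq)
  spec <- process_voxel(grid$data[1, 1, ], acq, process_options())
  expect_equal(
    spec$meta$steps,
    c("apodize", "fourier_transform", "frequency_correct", "subtract_baseline")
  )
  expect_lte(abs(find_naa_shift(spec)), step / 2 + 1e-9)
  win <- spec$ppm >= 0.9 & spec$ppm <= 1.6
  expect_lt(abs(mean(Re(spec$intensity[win]))), 1e-9)

  # disabling every step yields the raw transform
  raw <- process_voxel(
    grid$data[1, 1, ], acq,
    process_options(apodize = FALSE, frequency_correct = FALSE, baseline = FALSE)
  )
  expect_equal(raw$intensity, fourier_transform(grid$data[1, 1, ], acq)$intensity)

  # an all-zero FID passes through as an all-zero spectrum (flat-window warning)
  expect_warning(
    z <- process_voxel(rep(0i, 1024), acq, process_options()),
    "flat"
  )
  expect_equal(max(Mod(z$intensity)), 0)
})

test_that("fully processed spectra are invariant to injected constant offsets", {
  acq <- voxel_acq()
  lines <- metabolite_basis()
  g0 <- simulate_fid(unit_truth(baseline_offset = 0), lines, acq)
  g5 <- simulate_fid(unit_truth(baseline_offset = 5), lines, acq)
  s0 <- process_voxel(g0$data[1, 1, ], acq)
  s5 <- process_voxel(g5$data[1, 1, ], acq)
  expect_lt(max(abs(Re(s5$intensity) - Re(s0$intensity))), 1e-10)
})

test_that("spectrum averaging is the pointwise mean", {
  acq <- tiny_acq()
  s1 <- analytic_spectrum(function(p) sin(p), acq)
  expect_equal(average_spectra(list(s1))$intensity, s1$intensity)
  neg <- s1
  neg$intensity <- -neg$intensity
  expect_equal(max(Mod(average_spectra(list(s1, neg))$intensity)), 0)
  other <- mrs_spectrum(s1$ppm - 1, s1$intensity)
  expect_error(average_spectra(list(s1, other)), "mismatched")
})

test_that("averaging replicates shrinks noise about sqrt(n)-fold", {
  acq <- voxel_acq(256L)
  specs <- lapply(1:100, function(s) {
    set.seed(s)
    fourier_transform(
      complex(real = rnorm(256, sd = 1), imaginary = rnorm(256, sd = 1)), acq
    )
  })
  avg <- average_spectra(specs)
  sd_single <- mean(vapply(specs, function(s) sd(Re(s$intensity)), numeric(1)))
  sd_avg <- sd(Re(avg$intensity))
  expect_gt(sd_single / sd_avg, 8)
  expect_lt(sd_single / sd_avg, 12.5)
})
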