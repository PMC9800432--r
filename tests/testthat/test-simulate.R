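test_that("the default line basis sits at the interval midpoints", {
  lines <- metabolite_basis()
  iois <- default_iois()
  expect_equal(lines$chemical_shift[lines$metabolite == "NAA2"], 2.000)
  expect_equal(lines$chemical_shift[lines$metabolite == "Cr2"], 3.008)
  # every line lies inside exactly one interval
  for (i in seq_len(nrow(lines))) {
    inside <- sum(
      lines$chemical_shift[i] >= iois$ppm_low & lines$chemical_shift[i] <= iois$ppm_high
    )
    expect_equal(inside, 1L)
  }
  expect_error(metabolite_basis(relative_amplitudes = c(NAA2 = 1)), "no relative amplitude")
  expect_error(metabolite_basis(linewidth_hz = 0), "> 0")
})

test_that("the forward model is linear and anchored at t = 0", {
  acq <- tiny_acq(32L)
  lines <- metabolite_basis()
  tr <- unit_truth()
  grid <- simulate_fid(tr, lines, acq)
  vox <- reconstruct_voxels(grid, rbind(c(1, 1)))
  expect_equal(Re(vox[1, 1]), sum(lines$relative_amplitude), tolerance = 1e-9)

  # all-zero amplitudes, no noise: all-zero grid
  zero_tr <- simulation_truth(
    stats::setNames(rep(0, nrow(lines)), lines$metabolite),
    seed = 1
  )
  zero <- simulate_fid(zero_tr, lines, acq)
  expect_equal(max(Mod(zero$data)), 0)

  # doubling every amplitude doubles every spectrum intensity
  dbl_tr <- simulation_truth(tr$amplitudes * 2, seed = 1)
  dbl <- simulate_fid(dbl_tr, lines, acq)
  expect_lt(max(Mod(dbl$data - 2 * grid$data)), 1e-9)
})

test_that("a single line appears at its shifted position (DFT oracle)", {
  acq <- tiny_acq(64L)
  lines <- metabolite_basis(
    relative_amplitudes = c(
      Myo1 = 0, Cr1 = 0, Glx = 0, Myo2 = 0, Cho = 0, Cr2 = 0, Asp = 0,
      NAA1 = 0, Gln = 0, NAA2 = 1
    )
  )
  shift <- 0.4
  grid <- simulate_fid(unit_truth(frequency_shift = shift), lines, acq)
  fid <- reconstruct_voxels(grid, rbind(c(1, 1)))[1, ]
  spec <- fourier_transform(fid, acq)
  peak <- spec$ppm[which.max(Re(spec$intensity))]
  bin <- 1 / (64 * acq$dwell_time * acq$transmitter_mhz)
  expect_equal(peak, 2.0 + shift, tolerance = bin)
  # the spectrum is the DFT of the voxel FID (oracle check)
  oracle <- dft_oracle(fid)
  expect_equal(sort(Mod(spec$intensity)), sort(Mod(oracle)), tolerance = 1e-8)
})

test_that("unknown or missing metabolites are reported by name", {
  acq <- tiny_acq(16L)
  lines <- metabolite_basis()
  tr <- simulation_truth(c(unit_truth()$amplitudes, Lactate = 1), seed = 1)
  expect_error(simulate_fid(tr, lines, acq), "Lactate")
  tr2 <- simulation_truth(unit_truth()$amplitudes[-10], seed = 1)
  expect_error(simulate_fid(tr2, lines, acq), "NAA2")
})

test_that("simulation is deterministic given the seed", {
  acq <- tiny_acq(16L)
  tr <- unit_truth(noise_sd = 0.5, seed = 123)
  g1 <- simulate_fid(tr, acq = acq)
  g2 <- simulate_fid(tr, acq = acq)
  expect_identical(g1$data, g2$data)
  tr2 <- unit_truth(noise_sd = 0.5, seed = 124)
  expect_false(identical(simulate_fid(tr2, acq = acq)$data, g1$data))

  c1 <- simulate_cohort(cohort_params(seed = 77))
  c2 <- simulate_cohort(cohort_params(seed = 77))
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$truths, c2$truths)
})

test_that("generated cohorts respect the declared clinical ranges", {
  cohort <- simulate_cohort(cohort_params(seed = 5))
  s <- cohort$subjects
  expect_true(all(s$gmfc %in% 0:6))
  expect_true(all(s$gmfc[s$group == "control"] == 0L))
  expect_true(all(is.finite(s$iq[!is.na(s$iq)])))
  expect_true(all(s$urine_naa_over_creatinine[!is.na(s$urine_naa_over_creatinine)] > 0))
  expect_true(all(is.na(s$urine_naa_over_creatinine[s$group == "control"])))
  expect_equal(nrow(s), 12 + 19 + 10)
  expect_false(anyDuplicated(s$scan_id) > 0)
  # truths cover every scan with non-negative amplitudes
  expect_setequal(names(cohort$truths), s$scan_id)
  expect_true(all(vapply(cohort$truths, function(t) all(t$amplitudes >= 0), logical(1))))
})

test_that("maximal association produces a monotone NAA-GMFC relationship", {
  params <- cohort_params(
    n_control = 5, n_juvenile = 20, n_late_infantile = 15,
    target_gmfc_spearman = -0.999, subject_sd = 0.02, seed = 3
  )
  cohort <- simulate_cohort(params)
  naa <- vapply(cohort$truths, function(t) t$amplitudes[["NAA2"]], numeric(1))
  rs <- spearman_oracle(naa, cohort$subjects$gmfc)
  expect_lt(rs, -0.9)
})

test_that("the default generator yields a negative NAA-GMFC link across seeds", {
  signs <- vapply(1:20, function(s) {
    cohort <- simulate_cohort(cohort_params(seed = s))
    naa <- vapply(cohort$truths, function(t) t$amplitudes[["NAA2"]], numeric(1))
    spearman_oracle(naa, cohort$subjects$gmfc)
  }, numeric(1))
  expect_true(all(signs < 0))
})

test_that("patient metabolite effects follow the disease pattern", {
  cohort <- simulate_cohort(cohort_params(seed = 9, subject_sd = 0.02))
  s <- cohort$subjects
  amp <- t(vapply(cohort$truths, function(t) t$amplitudes, numeric(10)))
  by_group <- function(m) tapply(amp[, m], s$group, mean)
  for (m in c("Myo1", "Myo2", "Cho")) {
    g <- by_group(m)
    expect_gt(g["late_infantile"], g["juvenile"])
    expect_gt(g["juvenile"], g["control"])
  }
  for (m in c("NAA2", "Asp", "Gln")) {
    g <- by_group(m)
    expect_lt(g["late_infantile"], g["juvenile"])
    expect_lt(g["juvenile"], g["control"])
  }
})

test_that("follow-up scans extend juvenile subjects with unique scan ids", {
  cohort <- simulate_cohort(cohort_params(n_followup = 3, seed = 4))
  s <- cohort$subjects
  expect_equal(nrow(s), 41 + 3)
  expect_false(anyDuplicated(s$scan_id) > 0)
  dup <- names(which(table(s$subject_id) == 2))
  expect_length(dup, 3)
  expect_true(all(s$group[s$subject_id %in% dup] == "juvenile"))
})
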