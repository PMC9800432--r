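# Independent oracles and fixture builders shared across the test files.
# Each oracle is a direct, definitional computation kept deliberately naive
# so it cannot share a code path with the implementation it checks.

# Brute-force discrete Fourier transform (O(N^2)); for signals <= 64 points.
dft_oracle <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    sum(x * exp(-2i * pi * k * (0:(n - 1)) / n))
  }, complex(1))
}

# Midpoint Riemann sum of a function over [lo, hi] at resolution `n`.
riemann_oracle <- function(f, lo, hi, n) {
  h <- (hi - lo) / n
  mid <- lo + (seq_len(n) - 0.5) * h
  sum(f(mid)) * h
}

# Definitional Pearson correlation.
pearson_oracle <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Definitional Spearman: Pearson on average ranks.
spearman_oracle <- function(x, y) {
  pearson_oracle(rank(x), rank(y))
}

# One-way ANOVA F statistic from sums of squares.
fstat_oracle <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Permutation p value for the ANOVA F statistic.
perm_anova_oracle <- function(values, groups, n_perm = 1e4, seed = 99) {
  f_obs <- fstat_oracle(values, groups)
  set.seed(seed)
  f_perm <- replicate(n_perm, fstat_oracle(sample(values), groups))
  mean(f_perm >= f_obs - 1e-12)
}

# Acquisition small enough for the O(N^2) DFT oracle.
tiny_acq <- function(n_time = 64L) {
  acq_config(
    acq_matrix = c(4L, 4L), recon_matrix = c(8L, 8L),
    n_time_points = n_time, dwell_time = 1 / 1200
  )
}

# Single-voxel acquisition: the k-space "grid" equals the voxel FID, so
# spectral behaviour can be studied without spatial reconstruction.
voxel_acq <- function(n_time = 1024L) {
  acq_config(
    acq_matrix = c(1L, 1L), recon_matrix = c(1L, 1L),
    n_time_points = n_time
  )
}

# FID of a single damped complex sinusoid at `ppm` under `acq`.
single_line_fid <- function(ppm, acq, amplitude = 1, linewidth_hz = 4) {
  tt <- (seq_len(acq$n_time_points) - 1) * acq$dwell_time
  f_hz <- (ppm - acq$carrier_ppm) * acq$transmitter_mhz
  amplitude * exp((2i * pi * f_hz - pi * linewidth_hz) * tt)
}

# Spectrum evaluated from an analytic intensity function on the acq axis.
analytic_spectrum <- function(f, acq) {
  ppm <- ppm_axis(acq)
  mrs_spectrum(ppm, f(ppm))
}

# Random k-space grid for linear-algebra properties.
random_grid <- function(acq, seed = 1) {
  set.seed(seed)
  d <- c(acq$acq_matrix, acq$n_time_points)
  arr <- array(complex(real = rnorm(prod(d)), imaginary = rnorm(prod(d))), d)
  fid_grid(arr, acq, domain = "kspace")
}

# Truth with all ten metabolites at multiplier 1 unless overridden.
unit_truth <- function(..., lines = metabolite_basis()) {
  amps <- stats::setNames(rep(1, nrow(lines)), lines$metabolite)
  simulation_truth(amplitudes = amps, ...)
}
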