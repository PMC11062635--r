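test_that("FPKM conversion and global normalization behave as defined", {
  # plug-in value: count 100, length 1000 bp, 1e6 total reads -> FPKM 100
  counts <- matrix(c(100, 900), ncol = 1,
                   dimnames = list(NULL, "S1"))
  prof <- normalize_expression(counts, c("a", "b"), c(1, 2001), c(1000, 6000),
                               genome_length = 10000,
                               total_reads = 1e6, target = 0)
  fpkm_a <- 100 * 1e9 / (1000 * 1e6)
  fpkm_b <- 900 * 1e9 / (4000 * 1e6)
  shift <- mean(log10(c(fpkm_a, fpkm_b)))
  expect_equal(prof[[1]]$expr, log10(c(fpkm_a, fpkm_b)) - shift,
               tolerance = 1e-12)
  expect_equal(fpkm_a, 100)

  # depth invariance: a global scale factor normalizes away
  withr::with_seed(9, base <- rpois(50, 200))
  cm <- cbind(S1 = base, S2 = base * 5L)
  profs <- normalize_expression(cm, sprintf("g%02d", 1:50),
                                (0:49) * 1000 + 1, (0:49) * 1000 + 900,
                                genome_length = 50000)
  expect_equal(profs[[1]]$expr, profs[[2]]$expr, tolerance = 1e-9)
  # defining property: every sample's mean log expression hits the target
  expect_equal(mean(profs[[1]]$expr), mean(profs[[2]]$expr), tolerance = 1e-9)
  expect_error(normalize_expression(cbind(c(0, 0)), c("a", "b"), c(1, 10),
                                    c(5, 15), 100, total_reads = 0),
               "zero total")
})

test_that("binning assigns genes by midpoint and interpolates empty bins", {
  # single gene with midpoint in bin 5
  prof <- expression_profile(c("a", "b"), c(4100, 9100), c(4900, 9900),
                             c(2, 4), genome_length = 10000)
  bp <- bin_profile(prof, bin_bp = 1000, smooth_bp = 1000)
  expect_equal(bp$binned[5], 2)
  expect_equal(bp$binned[10], 4)
  expect_equal(bp$n_empty, 8)
  expect_length(bp$binned, 10)
  # interpolation is linear on the circle between the two known bins
  expect_equal(bp$binned[6], 2 + (4 - 2) / 5)
  # constant profile -> constant binned and smoothed series
  flat <- expression_profile(sprintf("g%d", 1:20), (0:19) * 500 + 1,
                             (0:19) * 500 + 400, rep(1.5, 20),
                             genome_length = 10000)
  bf <- bin_profile(flat, 1000, 3000)
  expect_true(all(abs(bf$binned - 1.5) < 1e-12))
  expect_true(all(abs(bf$smoothed - 1.5) < 1e-12))
  expect_error(bin_profile(flat, bin_bp = 20000), "exceeds")
})

test_that("moving average attenuates a pure tone by the Dirichlet factor", {
  L <- 100000
  n_genes <- 400
  starts <- (seq_len(n_genes) - 1) * 250 + 1
  k <- 4
  mids <- starts + 49
  prof <- expression_profile(sprintf("g%d", seq_len(n_genes)), starts,
                             starts + 99,
                             1 + 0.5 * sin(2 * pi * mids * k / L),
                             genome_length = L)
  bp <- bin_profile(prof, bin_bp = 1000, smooth_bp = 10000)
  n <- length(bp$binned); w <- 10
  atten <- abs(sin(pi * k * w / n) / (w * sin(pi * k / n)))
  amp_smoothed <- (max(bp$smoothed) - min(bp$smoothed)) / 2
  expect_equal(amp_smoothed, 0.5 * atten, tolerance = 0.02)
})

test_that("periodogram peak finds the dominant tone and matches brute DFT", {
  n <- 128; L <- 128000
  x6 <- sin(2 * pi * 6 * (0:(n - 1)) / n)
  pk <- periodogram_peak(x6, L)
  expect_equal(pk$k, 6)
  expect_equal(pk$T, L / 6)
  # dominant tone wins over a weak low-frequency component
  x <- x6 + 0.1 * sin(2 * pi * 2 * (0:(n - 1)) / n)
  expect_equal(periodogram_peak(x, L)$k, 6)
  # white noise: peak equals brute-force DFT argmax, spectrum matches
  withr::with_seed(31, z <- rnorm(100))
  pk2 <- periodogram_peak(z, 1e5)
  brute <- brute_periodogram(z)
  expect_equal(pk2$spectrum, brute, tolerance = 1e-8)
  expect_equal(pk2$k, which.max(brute))
  expect_error(periodogram_peak(rep(1, 50), 1e5), "constant")
  expect_error(periodogram_peak(rnorm(4), 1e3), ">= 8")
})

test_that("Parseval: spectrum total accounts for the series variance", {
  withr::with_seed(8, x <- rnorm(101))  # odd n: no Nyquist ordinate
  pk <- periodogram_peak(x, 1e5)
  expect_equal(2 * sum(pk$spectrum), sum((x - mean(x))^2), tolerance = 1e-10)
})

test_that("Fisher's g: exact edge cases and null calibration", {
  # all ordinates equal -> g = 1/m, p = 1 exactly
  out <- fisher_g_test(rep(2, 25))
  expect_equal(out$g, 1 / 25)
  expect_equal(out$p, 1)
  # single dominant ordinate -> p ~ m * (1 - g)^(m - 1), near 0
  spike <- c(rep(1e-9, 19), 1)
  out2 <- fisher_g_test(spike)
  expect_lt(out2$p, 1e-6)
  expect_equal(out2$p, 20 * (1 - out2$g)^19, tolerance = 1e-3)
  expect_error(fisher_g_test(c(1, 2)), ">= 3")
  # agreement with the closed form on a hand-sized spectrum: m = 4,
  # g = 0.5 -> p = C(4,1)(1-g)^3 - C(4,2)(1-2g)^3 = 4 * 0.125 = 0.5
  expect_equal(fisher_g_test(c(2, 1, 0.5, 0.5))$p, 0.5, tolerance = 1e-12)
  # (the 2000-run KS uniformity check lives in the acceptance suite)
})

test_that("fit_sinusoid recovers noiseless parameters to 1e-6", {
  T <- 2500; x <- seq(1, 10000, by = 25)
  y <- 2 * sin(2 * pi * (x + 0.3 * T) / T) + 5
  fit <- fit_sinusoid(x, y, T)
  expect_equal(fit$a, 2, tolerance = 1e-6)
  expect_equal(fit$b, 0.3 * T, tolerance = 1e-6)
  expect_equal(fit$c, 5, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-12)
  # near-flat input: a ~ 0, c ~ mean
  withr::with_seed(2, yn <- 3 + rnorm(length(x), 0, 1e-3))
  fit2 <- fit_sinusoid(x, yn, T)
  expect_lt(fit2$a, 1e-3)
  expect_equal(fit2$c, mean(yn), tolerance = 1e-3)
  expect_error(fit_sinusoid(x, rep(1, length(x)), T), "constant")
})

test_that("periodicity pipeline recovers the planted six-period signal", {
  layout <- gen_genome_layout(sim_config(seed = 1))
  prof <- gen_expression_profile(layout, period_count = 6, amplitude = 0.2,
                                 noise_sd = 0.2, seed = 3)
  fit <- periodicity_pipeline(prof)
  expect_equal(fit$period_count, 6)
  expect_lt(fit$p_g, 0.05)
  # amplitude within 15% of the moving-average-attenuated planted amplitude
  n <- length(fit$binned$smoothed); w <- 100
  atten <- abs(sin(pi * 6 * w / n) / (w * sin(pi * 6 / n)))
  expect_equal(fit$a, 0.2 * atten, tolerance = 0.15)
  # determinism
  expect_identical(unclass(fit)[c("T", "a", "b", "c", "g", "p_g")],
                   unclass(periodicity_pipeline(prof))[c("T", "a", "b", "c",
                                                         "g", "p_g")])
})

test_that("peak wavelength is insensitive to the smoothing window", {
  layout <- gen_genome_layout(sim_config(seed = 6))
  prof <- gen_expression_profile(layout, period_count = 6, amplitude = 0.2,
                                 noise_sd = 0.2, seed = 12)
  Ts <- vapply(c(50000, 100000, 200000), function(sm) {
    periodicity_pipeline(prof, smooth_bp = sm)$T
  }, numeric(1))
  expect_equal(Ts[1], Ts[2])
  expect_equal(Ts[2], Ts[3])
})

test_that("pipeline is equivariant under genome rotation", {
  cfg <- sim_config(seed = 3, n_genes = 500, genome_length = 1e6, n_scars = 0)
  layout <- gen_genome_layout(cfg)
  prof <- gen_expression_profile(layout, period_count = 4, amplitude = 0.3,
                                 noise_sd = 0.1, seed = 5)
  delta <- 333000
  rot_start <- ((prof$start - 1 + delta) %% 1e6) + 1
  rot_end <- rot_start + (prof$end - prof$start)
  keep <- rot_end <= 1e6  # drop genes broken by the rotation cut
  prof_rot <- expression_profile(prof$gene_id[keep], rot_start[keep],
                                 rot_end[keep], prof$expr[keep], 1e6)
  f0 <- periodicity_pipeline(prof, smooth_bp = 50000)
  f1 <- periodicity_pipeline(prof_rot, smooth_bp = 50000)
  expect_equal(f1$T, f0$T)
  expect_equal(f1$a, f0$a, tolerance = 0.05)
  # phase shifts by -delta modulo the wavelength
  shift <- (f0$b - delta) %% f0$T
  diff_b <- min(abs(f1$b - shift), f0$T - abs(f1$b - shift))
  expect_lt(diff_b, 0.02 * f0$T)
})

test_that("expression TSV round-trips with genome length header", {
  dir <- withr::local_tempdir()
  layout <- gen_genome_layout(sim_config(seed = 8, n_genes = 40,
                                         genome_length = 80000, n_scars = 2))
  prof <- gen_expression_profile(layout, seed = 2, sample_id = "evo1")
  path <- file.path(dir, "expr.tsv")
  write_expression_profile(prof, path)
  back <- read_expression_profiles(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$expr, prof$expr, tolerance = 1e-12)
  expect_equal(back[[1]]$sample_id, "evo1")
  expect_equal(back[[1]]$genome_length, 80000)
})
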