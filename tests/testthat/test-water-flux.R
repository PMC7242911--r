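test_that("double-exponential fit round-trips noiseless traces and selects the fast rate", {
  d <- stopflow_design(k_fast = 63.7, k_slow = 5, a_fast = 0.8,
                       a_slow = 0.2, noise_sd = 0, seed = 1)
  fit <- fit_double_exponential(gen_stopflow_trace(d))
  expect_true(fit$converged)
  expect_false(fit$single_exponential)
  expect_equal(fit$k_fast, 63.7, tolerance = 1e-3)
  expect_equal(fit$k_slow, 5, tolerance = 1e-3)
  expect_equal(fit$k_selected, fit$k_fast)
})

test_that("single-exponential traces trigger the degenerate-component fallback", {
  d <- stopflow_design(k_fast = 20, k_slow = 0, a_fast = 1, a_slow = 0,
                       noise_sd = 0.002, seed = 2)
  fit <- fit_double_exponential(gen_stopflow_trace(d))
  expect_true(fit$single_exponential)
  expect_equal(fit$k_selected, 20, tolerance = 0.02)
})

test_that("non-plateauing traces are flagged non-converged", {
  tr <- tibble::tibble(time_s = seq(0, 2, by = 0.01),
                       fluorescence = 0.01 * seq(0, 2, by = 0.01))
  fit <- fit_double_exponential(tr)
  expect_false(fit$converged)
})

test_that("k_fast recovery is nearly unbiased at 1% noise", {
  kds <- sapply(1:40, function(s) {
    d <- stopflow_design(k_fast = 63.7, k_slow = 5, a_fast = 0.8,
                         a_slow = 0.2, noise_sd = 0.01, seed = s)
    fit_double_exponential(gen_stopflow_trace(d))$k_fast
  })
  expect_lt(abs(median(kds) / 63.7 - 1), 0.02)
})

test_that("osmotic permeability is linear in k and inverse-linear in geometry", {
  geom <- liposome_geometry()
  expect_equal(geom$s_over_v0, 6e5)
  expect_equal(osmotic_permeability(0, geom), 0)
  expect_equal(osmotic_permeability(1.08, geom), 1.0e-3)
  expect_equal(osmotic_permeability(63.7, geom), 63.7 / 1080)
  # linearity in k
  k <- c(0.5, 1, 2, 8)
  expect_equal(osmotic_permeability(2 * k, geom),
               2 * osmotic_permeability(k, geom))
  # inverse-linearity in each geometry factor
  g2 <- liposome_geometry(radius_cm = 100e-7)
  expect_equal(osmotic_permeability(1, g2), 2 * osmotic_permeability(1, geom))
  g3 <- liposome_geometry(c_out = 2e-4)
  expect_equal(osmotic_permeability(1, g3), osmotic_permeability(1, geom) / 2)
})

test_that("channel density follows the reconstitution conventions", {
  g_molar <- liposome_geometry(lpr_basis = "molar")
  sud <- channel_density(g_molar)
  expect_equal(sud, 1e14 / 47) # 200 lipids * 0.47 nm^2 / 2 leaflets
  expect_equal(sud, 2.13e12, tolerance = 0.002)
  # doubling LPR halves the density
  g2 <- liposome_geometry(lpr = 400, lpr_basis = "molar")
  expect_equal(channel_density(g2), sud / 2)
  # one leaflet doubles area per channel
  g1 <- liposome_geometry(lpr_basis = "molar", leaflets = 1)
  expect_equal(channel_density(g1), sud / 2)
  # mass basis needs molecular weights
  expect_error(channel_density(liposome_geometry()), "protein_mw")
  sud_mass <- channel_density(liposome_geometry(),
                              protein_mw = 34800, lipid_mw = 610)
  expect_equal(sud_mass, 1 / (200 * 34800 / 610 * 0.47 / 2 * 1e-14))
})

test_that("single-channel permeability divides and subtracts as configured", {
  expect_equal(single_channel_permeability(2.13e12 * 1e-13, 2.13e12,
                                           subtract_background = FALSE),
               1e-13)
  expect_equal(single_channel_permeability(0.05, 1e12, pf_control = 0.05),
               0)
  expect_warning(
    pu <- single_channel_permeability(0.01, 1e12, pf_control = 0.02),
    "clamped"
  )
  expect_equal(pu, 0)
  # arithmetic under the molar monomer convention
  pu2 <- single_channel_permeability(5.9e-2, 1e14 / 47, pf_control = 1.2e-2)
  expect_equal(pu2, (5.9e-2 - 1.2e-2) * 47e-14)
})

test_that("quench fit recovers rates, preserves ratios, and flags flat traces", {
  tr <- gen_quench_trace(k = 0.5, noise_sd = 0, seed = 1)
  fit <- fit_quench(tr, injection_time = 5)
  expect_true(fit$decay_detected)
  expect_equal(fit$k, 0.5, tolerance = 1e-5)

  flat <- tibble::tibble(time_s = seq(0, 55, by = 0.05), fluorescence = 1)
  ffit <- fit_quench(flat)
  expect_false(ffit$decay_detected)
  expect_equal(ffit$k, 0)

  # 2:1 permeability ratio preserved within 2% at 1% noise
  amp <- 0.3
  k1 <- fit_quench(gen_quench_trace(0.6, f0 = 1, f_inf = 1 - amp,
                                    noise_sd = 0.01 * amp, seed = 2))$k
  k2 <- fit_quench(gen_quench_trace(0.3, f0 = 1, f_inf = 1 - amp,
                                    noise_sd = 0.01 * amp, seed = 3))$k
  expect_equal(k1 / k2, 2, tolerance = 0.02)
})

test_that("quench rate ordering survives noise (rank correlation 1 over 50 seeds)", {
  k_true <- c(0.1, 0.25, 0.5, 1)
  ok <- sapply(1:50, function(s) {
    k_hat <- sapply(seq_along(k_true), function(i) {
      tr <- gen_quench_trace(k_true[i], f0 = 1, f_inf = 0.7,
                             noise_sd = 0.05 * 0.3, seed = s * 10 + i)
      fit_quench(tr)$k
    })
    cor(k_hat, k_true, method = "spearman") == 1
  })
  expect_true(all(ok))
})

test_that("volume calibration maps monotonically and round-trips", {
  cal <- volume_calibration(c(0.5, 0.75, 1), c(0.4, 0.72, 1))
  expect_equal(to_volume(1, cal), 1)
  f <- c(0.55, 0.8, 0.95)
  v <- to_volume(f, cal)
  expect_true(all(diff(v) > 0))
  # inverse mapping reproduces the input
  inv <- volume_calibration(c(0.4, 0.72, 1), c(0.5, 0.75, 1))
  expect_equal(to_volume(v, inv), f, tolerance = 1e-12)

  lin <- volume_calibration(c(0, 1), c(0.5, 1), method = "linear")
  expect_equal(to_volume(0.6, lin), 0.8)
  expect_error(volume_calibration(c(0, 0.5, 1), c(1, 0.2, 1)), "monotone")
  expect_error(volume_calibration(c(0, 1), c(0.2, 0.9)), "1 -> 1")
  expect_warning(to_volume(0.2, cal), "outside")

  df <- tibble::tibble(time_s = 1:3, fluorescence = f)
  out <- to_volume(df, cal)
  expect_equal(out$volume, v)
})

test_that("accumulation half-time identities hold", {
  tt <- tibble::tibble(time = seq(0, 10, by = 0.25))
  for (k in c(0.7702, 0.1238, 2)) {
    tt$signal <- 1 - exp(-k * tt$time)
    fit <- accumulation_halftime(tt)
    expect_equal(fit$k, k, tolerance = 1e-6)
    expect_equal(fit$t_half * fit$k, log(2))
  }
  # non-saturating data flagged
  slow <- tibble::tibble(time = 0:10, signal = 0.005 * (0:10))
  expect_false(accumulation_halftime(slow)$converged)
})

test_that("equal-volume mannitol injection halves the stock concentration", {
  expect_equal(injection_dilution(400, 75, 75), 200)
  expect_equal(injection_dilution(100, 50, 150), 25)
})
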