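test_that("free_ligand matches its analytic limits and the mass-balance oracle", {
  # no receptor: no depletion
  expect_equal(free_ligand(10, 0, 29), 10)
  expect_equal(free_ligand(c(1, 50, 160), 0, 7), c(1, 50, 160))
  # stoichiometric limit: kd -> 0 consumes min(l, p)
  expect_equal(free_ligand(17, 17, 0), 0)
  expect_equal(free_ligand(40, 17, 0), 23)
  expect_equal(free_ligand(5, 17, 0), 0)
  # printed-formula value cross-checked by solving the quadratic numerically
  lf <- free_ligand(160, 17, 29)
  expect_equal(lf, oracle_free_ligand(160, 17, 29), tolerance = 1e-9)
  expect_equal(round(lf, 2), 145.82)
  for (l in c(0.4, 3, 45, 160)) {
    expect_equal(free_ligand(l, 17, 29), oracle_free_ligand(l, 17, 29),
                 tolerance = 1e-9)
    expect_lte(free_ligand(l, 17, 29), l)
  }
  expect_error(free_ligand(-1, 17, 29), "non-negative")
})

test_that("binding_signal hits its anchor points", {
  expect_equal(binding_signal(0, 1, 0.9, 29), 1)
  expect_equal(binding_signal(29, 1, 0.9, 29), 0.95)
  expect_lt(abs(binding_signal(100 * 29, 1, 0.9, 29) - 0.9), 0.01 * 0.1)
})

test_that("isotherm signal is monotone in total ligand when s2 > s1", {
  set.seed(42)
  for (i in 1:20) {
    kd <- runif(1, 0.5, 200)
    p_tot <- runif(1, 0, 50)
    s1 <- runif(1, -1, 1)
    s2 <- s1 + runif(1, 0.01, 2)
    l <- sort(runif(50, 0.01, 500))
    y <- binding_signal(free_ligand(l, p_tot, kd), s1, s2, kd)
    expect_true(all(diff(y) >= -1e-12))
  }
})

test_that("fit_binding round-trips noiseless data and absorbs affine signal rescaling", {
  des <- mst_design(n_points = 14, noise_sd = 0, seed = 1)
  tt <- gen_mst_titration(1, 0.92, 29, design = des)
  fit <- fit_binding(tt, p_tot = 17)
  expect_true(fit$converged)
  expect_true(fit$binding_detected)
  expect_equal(fit$kd, 29, tolerance = 1e-4)
  expect_equal(fit$s1, 1, tolerance = 1e-5)
  expect_equal(fit$s2, 0.92, tolerance = 1e-5)

  # affine rescaling of the signal axis leaves Kd invariant
  tt2 <- dplyr::mutate(tt, signal = 1000 * signal - 500)
  fit2 <- fit_binding(tt2, p_tot = 17)
  expect_equal(fit2$kd, fit$kd, tolerance = 1e-4)
})

test_that("flat control series raise the no-binding flag", {
  des <- mst_design(n_points = 14, noise_sd = 0.001, seed = 9)
  flat <- gen_mst_titration(s1 = 1, design = des, no_binding = TRUE)
  fit <- fit_binding(flat, p_tot = 17)
  expect_false(fit$binding_detected)
})

test_that("fit_binding rejects underdetermined input", {
  d <- tibble::tibble(conc_um = c(1, 2, 4, 8), signal = 1:4)
  expect_error(fit_binding(d, p_tot = 17), "5 distinct")
})

test_that("median Kd error shrinks as noise falls", {
  errs <- sapply(c(0.02, 0.005, 0.001), function(ns) {
    kds <- sapply(1:25, function(s) {
      tt <- gen_mst_titration(1, 0.9, 29, design = mst_design(
        n_points = 14, noise_sd = ns, seed = s))
      fit_binding(tt, p_tot = 17)$kd
    })
    median(abs(kds - 29))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("dose_response_signal midpoint, asymptote and slope-doubling identities", {
  expect_equal(dose_response_signal(2.5, 1, 0.8, 2.5, 1.3), 0.9)
  expect_equal(dose_response_signal(-8, 1, 0.8, 2.5, 1.3), 1,
               tolerance = 1e-6)
  # analytic slope at the midpoint: (a2 - a1) p ln(10) / 4
  num_slope <- function(p) {
    h <- 1e-6
    (dose_response_signal(2.5 + h, 1, 0.8, 2.5, p) -
        dose_response_signal(2.5 - h, 1, 0.8, 2.5, p)) / (2 * h)
  }
  expect_equal(num_slope(1), (0.8 - 1) * 1 * log(10) / 4, tolerance = 1e-5)
  expect_equal(num_slope(2) / num_slope(1), 2, tolerance = 1e-5)
})

test_that("fit_dose_response round-trips and flags degenerate data", {
  conc <- 10^seq(log10(50), log10(5000), length.out = 12)
  dd <- gen_dose_response(1, 0.75, log10(790), 1, conc, noise_sd = 0,
                          seed = 3)
  fit <- fit_dose_response(dd)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 790, tolerance = 1e-4)

  flat <- gen_dose_response(1, 1, log10(790), 1, conc, noise_sd = 0.002,
                            seed = 5)
  ffit <- fit_dose_response(flat)
  expect_false(ffit$converged)
})

test_that("extract_fnorm computes window-mean ratios and validates windows", {
  tr <- tibble::tibble(time = seq(0, 10, by = 0.1),
                       rel_fluorescence = 1)
  expect_equal(extract_fnorm(tr, c(0, 1), c(5, 6))$fnorm, 1.0)

  tr2 <- tibble::tibble(
    time = seq(0, 10, by = 0.1),
    rel_fluorescence = ifelse(seq(0, 10, by = 0.1) < 3, 1.0, 0.8)
  )
  expect_equal(extract_fnorm(tr2, c(0, 2), c(4, 6))$fnorm, 1.25)

  expect_error(extract_fnorm(tr2, c(4, 6), c(0, 2)), "f1_window")
  expect_error(extract_fnorm(tr2, c(0, 20), c(4, 6)), "f0_window")
})

test_that("auto F1 window maximises signal-to-noise over an exhaustive scan", {
  set.seed(8)
  time <- seq(0, 12, by = 0.05)
  f <- ifelse(time < 4, 1, 0.85) + rnorm(length(time), 0, 0.01)
  tr <- tibble::tibble(time = time, rel_fluorescence = f)
  res <- extract_fnorm(tr, c(0, 2), "auto", auto_width = 1)

  # brute force: score every candidate start in the post-F0 region
  in0 <- time >= 0 & time <= 2
  m0 <- mean(f[in0]); v0 <- var(f[in0]); n0 <- sum(in0)
  starts <- time[time >= 2 & time + 1 <= max(time)]
  snr <- sapply(starts, function(t0) {
    in1 <- time >= t0 & time <= t0 + 1
    if (sum(in1) < 3) return(-Inf)
    pooled <- sqrt(((n0 - 1) * v0 + (sum(in1) - 1) * var(f[in1])) /
                     (n0 + sum(in1) - 2))
    abs(mean(f[in1]) - m0) / pooled
  })
  expect_equal(res$f1_window[1], starts[which.max(snr)])
})
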