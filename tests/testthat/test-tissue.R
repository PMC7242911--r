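test_that("water content computes the gravimetric formula and is scale invariant", {
  expect_equal(water_content(tibble::tibble(wet_g = 1, dry_g = 0.3))$water_pct,
               70)
  expect_equal(
    water_content(tibble::tibble(wet_g = 0.5, dry_g = 0.147))$water_pct,
    70.6
  )
  expect_equal(water_content(tibble::tibble(wet_g = 2, dry_g = 1))$water_pct,
               50)
  w <- tibble::tibble(wet_g = c(0.1, 0.2), dry_g = c(0.03, 0.05))
  scaled <- dplyr::mutate(w, wet_g = wet_g * 7.3, dry_g = dry_g * 7.3)
  expect_equal(water_content(scaled)$water_pct, water_content(w)$water_pct)
  expect_error(water_content(tibble::tibble(wet_g = 1, dry_g = 1)),
               "dry_g < wet_g")
})

test_that("water content group summary aggregates by group", {
  g <- tibble::tibble(group = c("sham", "injured"),
                      water_pct = c(70.6, 75.6), sd_pct = c(0.5, 0.5),
                      n = c(8, 8))
  s <- water_content_summary(gen_tissue_weights(g, seed = 3))
  expect_equal(nrow(s), 2)
  expect_lt(abs(s$mean_pct[s$group == "injured"] - 75.6), 0.6)
})

test_that("perivascular ratio aggregates hierarchically without image-count bias", {
  set <- gen_roi_intensities(2.5, n_animals = 4, noise_cv = 0.1, seed = 6)
  per_animal <- perivascular_ratio(set)
  per_image <- perivascular_ratio(set, level = "image")
  manual <- tapply(per_image$ratio, per_image$animal, mean)
  expect_equal(per_animal$ratio, as.numeric(manual[per_animal$animal]))

  # permuting images within an animal leaves the animal mean unchanged
  shuffled <- dplyr::arrange(set, dplyr::desc(image))
  expect_equal(dplyr::arrange(perivascular_ratio(shuffled), animal),
               dplyr::arrange(per_animal, animal))

  # an image-rich animal does not pull the mean of animal-level ratios
  a1 <- tibble::tibble(animal = "a1", image = paste0("a1_", 1:9),
                       roi_class = "peri", mean_intensity = 30) |>
    dplyr::bind_rows(tibble::tibble(animal = "a1",
                                    image = paste0("a1_", 1:9),
                                    roi_class = "nonperi",
                                    mean_intensity = 10))
  a2 <- tibble::tibble(animal = "a2", image = "a2_1",
                       roi_class = c("peri", "nonperi"),
                       mean_intensity = c(10, 10))
  both <- dplyr::bind_rows(a1, a2)
  expect_equal(mean(perivascular_ratio(both)$ratio), 2) # (3 + 1) / 2
})

test_that("all-equal ROI means give unit ratios and 2x enrichment gives 2", {
  eq <- tibble::tibble(animal = "a", image = rep(c("i1", "i2"), each = 4),
                       roi_class = rep(c("peri", "peri", "nonperi",
                                         "nonperi"), 2),
                       mean_intensity = 50)
  expect_equal(perivascular_ratio(eq)$ratio, 1)
  dbl <- dplyr::mutate(eq, mean_intensity = ifelse(roi_class == "peri",
                                                   100, 50))
  expect_equal(perivascular_ratio(dbl)$ratio, 2)
})

test_that("positive pixel counting matches brute force and auto-thresholds on controls", {
  set.seed(13)
  control1 <- matrix(sample(0:40, 100, replace = TRUE), 10)
  control2 <- matrix(sample(0:38, 100, replace = TRUE), 10)
  img <- matrix(sample(0:255, 400, replace = TRUE), 20)
  res <- positive_pixel_count(img, "auto", list(control1, control2))
  expect_equal(res$threshold, max(control1, control2))
  expect_equal(res$count, oracle_pixel_count(img, res$threshold))
  # a control image scores zero against the auto threshold
  expect_equal(positive_pixel_count(control1, "auto",
                                    list(control1, control2))$count, 0)
  # monotone non-increasing in the threshold
  counts <- sapply(c(10, 40, 100, 200), function(th)
    positive_pixel_count(img, th)$count)
  expect_true(all(diff(counts) <= 0))
  expect_error(positive_pixel_count(img, "auto"), "control")
})

test_that("CAP metrics: zero trace, trough-to-peak amplitude, half-sine area", {
  zero <- tibble::tibble(time_ms = seq(0, 2, by = 0.01), voltage = 0)
  z <- cap_metrics(zero)
  expect_equal(z$amplitude, 0)
  expect_equal(z$area, 0)
  expect_false(z$deflection_found)

  hs <- half_sine_cap(a = 1, t_ms = 1, dt = 1e-4)
  m <- cap_metrics(hs)
  expect_equal(m$area, 2 * 1 * 1 / pi, tolerance = 1e-6)
  expect_equal(m$amplitude, 1, tolerance = 1e-6)

  # trough -1 followed by peak +0.4
  tr <- tibble::tibble(
    time_ms = seq(0, 3, by = 0.01),
    voltage = -sin(pi * pmin(seq(0, 3, by = 0.01), 1)) +
      0.4 * sin(pi * pmax(pmin(seq(0, 3, by = 0.01) - 1, 1), 0))
  )
  m2 <- cap_metrics(tr)
  expect_equal(m2$amplitude, 1.4, tolerance = 1e-3)

  # area converges to the analytic value as dt shrinks
  errs <- sapply(c(1e-2, 1e-3, 1e-4), function(dt) {
    abs(cap_metrics(half_sine_cap(dt = dt))$area - 2 / pi)
  })
  expect_true(all(diff(errs) < 0))
})
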