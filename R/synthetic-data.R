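#' MST titration design
#'
#' Experimental design of a thermophoresis titration: a descending
#' geometric dilution series of the titrated ligand at fixed receptor
#' (fluorescently labelled binding partner) concentration. Defaults follow
#' a typical design: 12-16 points spanning 0.4-160 uM at 17 uM total
#' receptor with a 2:1 dilution.
#'
#' @param n_points Number of titration points (>= 3).
#' @param l_min,l_max Ligand concentration bounds (uM).
#' @param dilution_factor Ratio between consecutive concentrations; used
#'   only for documentation of the design (the series is laid out
#'   geometrically between the bounds).
#' @param p_tot Total receptor concentration (uM).
#' @param noise_sd Gaussian signal noise SD (normalized-signal units).
#' @param conc_um Optional explicit concentration vector overriding the
#'   geometric series.
#' @param seed Integer seed (required).
#' @return A list of class `mst_design`.
#' @export
mst_design <- function(n_points = 16, l_min = 0.4, l_max = 160,
                       dilution_factor = 2, p_tot = 17,
                       noise_sd = 0.005, conc_um = NULL, seed) {
  seed <- check_seed(seed)
  if (n_points < 3L) abort("`n_points` must be at least 3.")
  check_positive(l_min, "l_min")
  if (l_max <= l_min) abort("`l_max` must exceed `l_min`.")
  check_number(p_tot, "p_tot", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (!is.null(conc_um) && any(conc_um <= 0)) {
    abort("`conc_um` must be positive.")
  }
  structure(list(n_points = as.integer(n_points), l_min = l_min,
                 l_max = l_max, dilution_factor = dilution_factor,
                 p_tot = p_tot, noise_sd = noise_sd, conc_um = conc_um,
                 seed = seed),
            class = "mst_design")
}

#' Simulate an MST binding titration
#'
#' Generates (concentration, signal) pairs from the depletion-corrected
#' one-to-one isotherm plus additive Gaussian noise. Intended as the exact
#' inverse of [fit_binding()]: at zero noise the points lie on the model
#' curve. In `no_binding` mode (an EDTA- or inhibitor-abolished control)
#' the underlying curve is flat at `s1`.
#'
#' @param s1,s2 Signals of the unbound and bound forms.
#' @param kd Dissociation constant (uM); ignored in `no_binding` mode.
#' @param design An [mst_design()].
#' @param n_replicates Number of independent replicate series.
#' @param no_binding If `TRUE`, generate a flat control series.
#' @return Tibble with columns `conc_um`, `signal`, `replicate`.
#' @export
gen_mst_titration <- function(s1, s2, kd = NULL, design, n_replicates = 1,
                              no_binding = FALSE) {
  stopifnot(inherits(design, "mst_design"))
  if (!no_binding) check_positive(kd, "kd")
  conc <- design$conc_um %||%
    10^seq(log10(design$l_max), log10(design$l_min),
           length.out = design$n_points)
  mu <- if (no_binding) rep(s1, length(conc)) else
    binding_signal(free_ligand(conc, design$p_tot, kd), s1, s2, kd)
  withr::with_seed(design$seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      tibble::tibble(
        conc_um = conc,
        signal = mu + rnorm(length(conc), 0, design$noise_sd),
        replicate = r
      )
    })
  })
}

#' Simulate an inhibitor dose-response titration
#'
#' Generates signals from the four-parameter logistic
#' [dose_response_signal()] over an explicit inhibitor concentration
#' vector, plus Gaussian noise. The concentration list is explicit because
#' published dilution-series descriptions are often internally
#' inconsistent; the caller states exactly what was pipetted.
#'
#' @param a1,a2 Signals of the unbound and bound forms.
#' @param x0 Midpoint on the log10-concentration axis (log10 uM).
#' @param p Hill coefficient.
#' @param conc_um Inhibitor concentrations (uM), all positive.
#' @param noise_sd Gaussian noise SD (signal units).
#' @param n_replicates Number of replicate series.
#' @param seed Integer seed (required).
#' @return Tibble with columns `conc_um`, `signal`, `replicate`.
#' @export
gen_dose_response <- function(a1, a2, x0, p, conc_um, noise_sd = 0,
                              n_replicates = 1, seed) {
  seed <- check_seed(seed)
  if (any(conc_um <= 0)) abort("`conc_um` must be positive.")
  check_number(noise_sd, "noise_sd", lower = 0)
  mu <- dose_response_signal(log10(conc_um), a1, a2, x0, p)
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      tibble::tibble(
        conc_um = conc_um,
        signal = mu + rnorm(length(conc_um), 0, noise_sd),
        replicate = r
      )
    })
  })
}

#' Stopped-flow shrinkage trace design
#'
#' Parameters of a biexponential liposome-shrinkage fluorescence rise: the
#' fast component reports protein-containing liposomes, the slow component
#' protein-free background. Defaults emulate a 2 s acquisition averaged
#' over 10 instrument readings.
#'
#' @param k_fast,k_slow Rate constants (1/s), `k_fast > k_slow >= 0`.
#' @param a_fast,a_slow Component amplitudes (a.u.).
#' @param baseline Fluorescence offset (a.u.).
#' @param duration Acquisition length (s).
#' @param dt Sampling interval (s).
#' @param noise_sd Per-reading Gaussian noise SD (a.u.).
#' @param n_reads Number of readings averaged per trace.
#' @param seed Integer seed (required).
#' @return A list of class `stopflow_design`.
#' @export
stopflow_design <- function(k_fast, k_slow = 5, a_fast = 0.8, a_slow = 0.2,
                            baseline = 0, duration = 2, dt = 0.002,
                            noise_sd = 0, n_reads = 10, seed) {
  seed <- check_seed(seed)
  if (!(k_fast > k_slow) || k_slow < 0) {
    abort("Require `k_fast` > `k_slow` >= 0.")
  }
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  check_number(noise_sd, "noise_sd", lower = 0)
  if (n_reads < 1L) abort("`n_reads` must be at least 1.")
  structure(list(k_fast = k_fast, k_slow = k_slow, a_fast = a_fast,
                 a_slow = a_slow, baseline = baseline, duration = duration,
                 dt = dt, noise_sd = noise_sd, n_reads = as.integer(n_reads),
                 seed = seed),
            class = "stopflow_design")
}

#' Simulate a stopped-flow shrinkage trace
#'
#' Rising double-exponential fluorescence
#' `F(t) = baseline + a_fast (1 - e^{-k_fast t}) + a_slow (1 - e^{-k_slow t})`
#' plus Gaussian noise, averaged over `n_reads` independent noisy readings
#' (so the residual SD scales as `noise_sd / sqrt(n_reads)`).
#'
#' @param design A [stopflow_design()].
#' @return Tibble with columns `time_s`, `fluorescence`.
#' @export
gen_stopflow_trace <- function(design) {
  stopifnot(inherits(design, "stopflow_design"))
  t <- seq(0, design$duration, by = design$dt)
  mu <- design$baseline +
    design$a_fast * (1 - exp(-design$k_fast * t)) +
    design$a_slow * (1 - exp(-design$k_slow * t))
  withr::with_seed(design$seed, {
    reads <- replicate(design$n_reads,
                       mu + rnorm(length(t), 0, design$noise_sd))
    tibble::tibble(time_s = t, fluorescence = rowMeans(reads))
  })
}

#' Simulate a calcein-quench trace
#'
#' Flat baseline fluorescence until the hyperosmotic injection, then
#' single-exponential decay `f_inf + (f0 - f_inf) e^{-k (t - t_inj)}` as the
#' cell shrinks and intracellular calcein self-quenches. Defaults follow a
#' plate-reader protocol: 5 s baseline at 50 ms sampling, 50 s post
#' injection.
#'
#' @param k Decay rate constant (1/s), >= 0.
#' @param f0 Pre-injection fluorescence (a.u.).
#' @param f_inf Plateau fluorescence (a.u.).
#' @param injection_time Injection time (s).
#' @param duration Total trace length (s).
#' @param dt Sampling interval (s).
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param seed Integer seed (required).
#' @return Tibble with columns `time_s`, `fluorescence`.
#' @export
gen_quench_trace <- function(k, f0 = 1, f_inf = 0.7, injection_time = 5,
                             duration = 55, dt = 0.05, noise_sd = 0, seed) {
  seed <- check_seed(seed)
  check_number(k, "k", lower = 0)
  check_positive(dt, "dt")
  if (duration <= injection_time) {
    abort("`duration` must exceed `injection_time`.")
  }
  t <- seq(0, duration, by = dt)
  mu <- ifelse(t < injection_time, f0,
               f_inf + (f0 - f_inf) * exp(-k * (t - injection_time)))
  withr::with_seed(seed, {
    tibble::tibble(time_s = t,
                   fluorescence = mu + rnorm(length(t), 0, noise_sd))
  })
}

#' Simulate wet/dry tissue weights with a target water content
#'
#' Inverts the gravimetric water-content formula: per-animal wet weights
#' are lognormal around a 0.1 g tissue-piece scale and dry weights are
#' `wet * (1 - w/100)` with per-animal water percentage
#' `w ~ Normal(water_pct, sd_pct)`. Dry < wet is guaranteed by
#' construction for water percentages inside (0, 100).
#'
#' @param groups Data frame with columns `group`, `water_pct` (target mean
#'   water content, percent, in (0, 100)), `sd_pct` (between-animal SD of
#'   the water percentage), and `n` (animals per group).
#' @param wet_meanlog,wet_sdlog Lognormal parameters of the wet weight (g).
#' @param seed Integer seed (required).
#' @return Tibble with columns `group`, `animal`, `wet_g`, `dry_g`.
#' @export
gen_tissue_weights <- function(groups, wet_meanlog = log(0.1),
                               wet_sdlog = 0.15, seed) {
  seed <- check_seed(seed)
  stopifnot(is.data.frame(groups))
  if (!all(c("group", "water_pct", "sd_pct", "n") %in% names(groups))) {
    abort("`groups` needs columns `group`, `water_pct`, `sd_pct`, `n`.")
  }
  if (any(groups$water_pct <= 0 | groups$water_pct >= 100)) {
    abort("`water_pct` targets must lie strictly inside (0, 100).")
  }
  if (any(groups$n < 1)) abort("`n` must be at least 1 per group.")
  withr::with_seed(seed, {
    purrr::pmap_dfr(groups, function(group, water_pct, sd_pct, n, ...) {
      wet <- rlnorm(n, wet_meanlog, wet_sdlog)
      w <- rnorm(n, water_pct, sd_pct)
      w <- pmin(pmax(w, 0.1), 99.9) # physical domain guard
      tibble::tibble(group = group,
                     animal = paste0(group, "_", seq_len(n)),
                     wet_g = wet,
                     dry_g = wet * (1 - w / 100))
    })
  })
}

#' Simulate peri- and non-peri-endothelial ROI intensities
#'
#' Per image, a non-peri-endothelial baseline intensity is drawn and each
#' ROI mean is that baseline times multiplicative lognormal noise;
#' peri-endothelial ROI means are additionally scaled by the true
#' `enrichment` ratio. ROI counts per image and class are drawn uniformly
#' from the stated range (3-10 by default).
#'
#' @param enrichment True peri/non-peri intensity ratio (> 0).
#' @param n_animals Number of animals.
#' @param images_per_animal Range (length-2) of images per animal;
#'   a count is drawn uniformly per animal (default 4-9).
#' @param rois_per_image Range (length-2) of ROIs per image and class
#'   (default 3-10).
#' @param base_intensity Mean non-peri intensity (a.u., 0-255 scale).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal noise.
#' @param seed Integer seed (required).
#' @return Tibble with columns `animal`, `image`, `roi_class`
#'   (`"peri"`/`"nonperi"`), `mean_intensity`.
#' @export
gen_roi_intensities <- function(enrichment, n_animals = 6,
                                images_per_animal = c(4, 9),
                                rois_per_image = c(3, 10),
                                base_intensity = 100, noise_cv = 0.2,
                                seed) {
  seed <- check_seed(seed)
  check_positive(enrichment, "enrichment")
  check_number(noise_cv, "noise_cv", lower = 0)
  sdlog <- sqrt(log(1 + noise_cv^2))
  mlog <- -sdlog^2 / 2 # unit-mean lognormal
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_animals), function(a) {
      n_img <- sample(seq(images_per_animal[1], images_per_animal[2]), 1)
      purrr::map_dfr(seq_len(n_img), function(i) {
        base <- base_intensity * rlnorm(1, mlog, sdlog)
        n_roi <- sample(seq(rois_per_image[1], rois_per_image[2]), 2,
                        replace = TRUE)
        tibble::tibble(
          animal = paste0("animal_", a),
          image = paste0("animal_", a, "_img_", i),
          roi_class = c(rep("peri", n_roi[1]), rep("nonperi", n_roi[2])),
          mean_intensity = c(
            enrichment * base * rlnorm(n_roi[1], mlog, sdlog),
            base * rlnorm(n_roi[2], mlog, sdlog)
          )
        )
      })
    })
  })
}
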