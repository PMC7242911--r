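#' Liposome geometry and reconstitution conventions
#'
#' Geometric and compositional constants needed to convert a shrinkage
#' rate constant into an osmotic water permeability (Pf) and a
#' single-channel permeability (Pu). Defaults describe 100 nm
#' extruded unilamellar liposomes (radius 50 nm, spherical
#' surface-to-volume ratio 3/r), the partial molar volume of water
#' (18 cm^3/mol), a 0.1 Osm external osmotic step, a theoretical area per
#' lipid of 0.47 nm^2 and a lipid-to-protein ratio (LPR) of 200.
#'
#' @param radius_cm Liposome radius (cm). Default `50e-7` (50 nm).
#' @param v_w Partial molar volume of water (cm^3/mol).
#' @param c_out External osmolality (mol/cm^3). Default `1e-4`
#'   (0.1 Osm).
#' @param area_per_lipid_nm2 Theoretical membrane area per lipid (nm^2).
#' @param lpr Lipid-to-protein ratio.
#' @param lpr_basis `"mass"` (lipid mass / protein mass, the usual
#'   reconstitution convention) or `"molar"` (lipids per protein monomer).
#' @param leaflets Number of bilayer leaflets sharing the lipid budget.
#' @param oligomer Protein subunits per channel particle (1 treats each
#'   monomer as a channel; 4 for a tetramer counted as one particle).
#' @return A list of class `liposome_geometry` with the above fields plus
#'   `s_over_v0` (cm^-1).
#' @export
liposome_geometry <- function(radius_cm = 50e-7, v_w = 18, c_out = 1e-4,
                              area_per_lipid_nm2 = 0.47, lpr = 200,
                              lpr_basis = c("mass", "molar"), leaflets = 2,
                              oligomer = 1) {
  lpr_basis <- match.arg(lpr_basis)
  check_positive(radius_cm, "radius_cm")
  check_positive(v_w, "v_w")
  check_positive(c_out, "c_out")
  check_positive(area_per_lipid_nm2, "area_per_lipid_nm2")
  check_positive(lpr, "lpr")
  if (!leaflets %in% c(1, 2)) abort("`leaflets` must be 1 or 2.")
  check_positive(oligomer, "oligomer")
  structure(list(radius_cm = radius_cm, s_over_v0 = 3 / radius_cm,
                 v_w = v_w, c_out = c_out,
                 area_per_lipid_nm2 = area_per_lipid_nm2, lpr = lpr,
                 lpr_basis = lpr_basis, leaflets = leaflets,
                 oligomer = oligomer),
            class = "liposome_geometry")
}

#' Fit a double-exponential shrinkage trace
#'
#' Least-squares fit of
#' `F(t) = baseline + a_fast (1 - e^{-k_fast t}) + a_slow (1 - e^{-k_slow t})`
#' to a stopped-flow fluorescence trace. The larger rate constant is
#' selected (`k_selected`) as the component reporting channel-mediated
#' water efflux; the smaller one absorbs the protein-free background. If
#' the two components are degenerate (rates within 20% of each other or a
#' component carrying under 2% of the total amplitude) the fit falls back
#' to a single exponential and is flagged. A trace that has not approached
#' a plateau within the acquisition (under one selected time constant) is
#' flagged non-converged.
#'
#' @param trace Data frame with columns `time_s` (strictly increasing) and
#'   `fluorescence`; at least 20 samples.
#' @return An object of class `double_exp_fit` with elements `k_fast`,
#'   `k_slow`, `a_fast`, `a_slow`, `baseline`, `k_selected`,
#'   `residual_norm`, `single_exponential`, `converged`, `data`.
#' @export
fit_double_exponential <- function(trace) {
  stopifnot(is.data.frame(trace))
  if (!all(c("time_s", "fluorescence") %in% names(trace))) {
    abort("`trace` must have columns `time_s` and `fluorescence`.")
  }
  t <- trace$time_s
  y <- trace$fluorescence
  check_time_increasing(t, "time_s")
  if (length(t) < 20L) abort("At least 20 samples are required.")

  b0 <- y[1]
  amp0 <- mean(tail(y, max(3, length(y) %/% 20))) - b0
  if (amp0 == 0) amp0 <- diff(range(y))
  # crude rate from time to half amplitude
  half_idx <- which(abs(y - b0) >= abs(amp0) / 2)[1]
  k0 <- if (!is.na(half_idx) && t[half_idx] > 0) log(2) / t[half_idx] else
    1 / diff(range(t))

  fit2 <- NULL
  for (ratio in c(10, 30, 100)) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        y ~ b + af * (1 - exp(-kf * t)) + as * (1 - exp(-ks * t)),
        start = list(b = b0, af = 0.8 * amp0, as = 0.2 * amp0,
                     kf = k0 * sqrt(ratio), ks = k0 / sqrt(ratio)),
        lower = c(-Inf, -Inf, -Inf, 1e-6, 0),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (!is.null(f) && (is.null(fit2) || deviance(f) < deviance(fit2))) {
      fit2 <- f
    }
  }

  fit1 <- tryCatch(
    minpack.lm::nlsLM(
      y ~ b + a * (1 - exp(-k * t)),
      start = list(b = b0, a = amp0, k = k0),
      lower = c(-Inf, -Inf, 1e-6),
      control = minpack.lm::nls.lm.control(maxiter = 300)
    ),
    error = function(e) NULL
  )
  if (is.null(fit2) && is.null(fit1)) {
    abort("Exponential fit failed to converge from any start.")
  }

  single <- FALSE
  if (!is.null(fit2)) {
    cf <- coef(fit2)
    kf <- max(cf[["kf"]], cf[["ks"]])
    ks <- min(cf[["kf"]], cf[["ks"]])
    af <- if (cf[["kf"]] >= cf[["ks"]]) cf[["af"]] else cf[["as"]]
    as_ <- if (cf[["kf"]] >= cf[["ks"]]) cf[["as"]] else cf[["af"]]
    amp_frac <- abs(c(af, as_)) / (abs(af) + abs(as_))
    degenerate <- (ks > 0 && kf / ks < 1.2) || any(amp_frac < 0.02)
  } else {
    degenerate <- TRUE
  }

  if (degenerate && !is.null(fit1)) {
    single <- TRUE
    cf1 <- coef(fit1)
    kf <- cf1[["k"]]
    ks <- 0
    af <- cf1[["a"]]
    as_ <- 0
    b <- cf1[["b"]]
    rss <- deviance(fit1)
  } else {
    b <- cf[["b"]]
    rss <- deviance(fit2)
  }

  converged <- kf * (max(t) - min(t)) >= 1
  out <- list(k_fast = unname(kf), k_slow = unname(ks),
              a_fast = unname(af), a_slow = unname(as_),
              baseline = unname(b), k_selected = unname(kf),
              residual_norm = sqrt(rss), single_exponential = single,
              converged = converged, data = tibble::as_tibble(trace))
  class(out) <- "double_exp_fit"
  out
}

#' @export
print.double_exp_fit <- function(x, ...) {
  cat("Double-exponential shrinkage fit\n")
  cat(sprintf("  k_fast = %.4g /s, k_slow = %.4g /s (selected k = %.4g /s)\n",
              x$k_fast, x$k_slow, x$k_selected))
  if (x$single_exponential) cat("  [single-exponential fallback]\n")
  if (!x$converged) cat("  [trace did not plateau: non-converged]\n")
  invisible(x)
}

#' Osmotic water permeability from a shrinkage rate constant
#'
#' \deqn{P_f = k / ((S/V_0)\, V_w\, C_{out})}
#' with `S/V0` the initial surface-to-volume ratio (cm^-1), `V_w` the
#' partial molar volume of water (cm^3/mol) and `C_out` the external
#' osmolality (mol/cm^3). For the default 100 nm liposome geometry the
#' denominator is 6e5 * 18 * 1e-4 = 1080, so Pf = k / 1080 cm/s.
#'
#' @param k Shrinkage rate constant (1/s), >= 0. Vectorised.
#' @param geom A [liposome_geometry()].
#' @return Pf in cm/s.
#' @export
osmotic_permeability <- function(k, geom = liposome_geometry()) {
  stopifnot(inherits(geom, "liposome_geometry"))
  if (any(k < 0)) abort("`k` must be non-negative.")
  k / (geom$s_over_v0 * geom$v_w * geom$c_out)
}

#' Channel density per unit membrane area
#'
#' Converts the reconstitution lipid-to-protein ratio (LPR) and the
#' theoretical area per lipid (Am) into channels per cm^2 of liposome
#' surface. Under a molar LPR, `lipids_per_channel = lpr * oligomer`;
#' under a mass LPR, `lipids_per_channel = lpr * protein_mw * oligomer /
#' lipid_mw`. The membrane area per channel is
#' `lipids_per_channel * Am / leaflets` and the density its reciprocal.
#'
#' @param geom A [liposome_geometry()]; `lpr_basis`, `lpr`, `leaflets`,
#'   `oligomer` and `area_per_lipid_nm2` are taken from it.
#' @param protein_mw Protein monomer molecular weight (g/mol); required
#'   under the mass basis. AQP4 M1 isoform is about 34.8 kDa.
#' @param lipid_mw Mean lipid molecular weight (g/mol); required under the
#'   mass basis. A POPC/POPG/cholesterol 2:1:2 mix averages about 610.
#' @return Channel density SuD in channels/cm^2.
#' @export
channel_density <- function(geom = liposome_geometry(), protein_mw = NULL,
                            lipid_mw = NULL) {
  stopifnot(inherits(geom, "liposome_geometry"))
  lipids_per_channel <- switch(
    geom$lpr_basis,
    molar = geom$lpr * geom$oligomer,
    mass = {
      if (is.null(protein_mw) || is.null(lipid_mw)) {
        abort("Mass-basis LPR requires `protein_mw` and `lipid_mw`.")
      }
      geom$lpr * protein_mw * geom$oligomer / lipid_mw
    }
  )
  area_nm2 <- lipids_per_channel * geom$area_per_lipid_nm2 / geom$leaflets
  1 / (area_nm2 * 1e-14) # nm^2 -> cm^2
}

#' Single-channel water permeability
#'
#' `Pu = Pf / SuD`, optionally after subtracting the protein-free control
#' permeability so that Pu reflects channel-mediated flux only (the
#' default). If the control exceeds the sample Pf under subtraction the
#' result is clamped at zero with a warning.
#'
#' @param pf Osmotic permeability of the proteoliposome (cm/s).
#' @param su_d Channel density (channels/cm^2), > 0.
#' @param pf_control Osmotic permeability of protein-free liposomes (cm/s).
#' @param subtract_background Subtract `pf_control` before dividing?
#' @return Pu in cm^3/s.
#' @export
single_channel_permeability <- function(pf, su_d, pf_control = 0,
                                        subtract_background = TRUE) {
  check_positive(su_d, "su_d")
  check_number(pf, "pf", lower = 0)
  check_number(pf_control, "pf_control", lower = 0)
  eff <- if (subtract_background) pf - pf_control else pf
  if (eff < 0) {
    warn("Control Pf exceeds sample Pf; Pu clamped at 0.")
    eff <- 0
  }
  eff / su_d
}

#' Fit a single-exponential calcein-quench decay
#'
#' Fits `F(t) = F_inf + (F0 - F_inf) e^{-k (t - t_inj)}` to the
#' post-injection segment of a calcein fluorescence trace; the rate
#' constant is proportional to membrane water permeability. The injection
#' time is either supplied (the plate-reader protocol injects at a known
#' time) or detected as the point of maximum absolute derivative. If no
#' decay is distinguishable from a constant (F-test at `alpha`), `k = 0`
#' is returned with `decay_detected = FALSE`.
#'
#' @param trace Data frame with columns `time_s` and `fluorescence`.
#' @param injection_time Injection time (s), or `NULL` to detect it.
#' @param alpha Significance level of the decay-vs-constant F-test.
#' @return An object of class `quench_fit` with elements `k`, `f0`,
#'   `f_inf`, `injection_time`, `decay_detected`, `residual_norm`, `data`.
#' @export
fit_quench <- function(trace, injection_time = 5, alpha = 0.05) {
  stopifnot(is.data.frame(trace))
  if (!all(c("time_s", "fluorescence") %in% names(trace))) {
    abort("`trace` must have columns `time_s` and `fluorescence`.")
  }
  t <- trace$time_s
  y <- trace$fluorescence
  check_time_increasing(t, "time_s")
  if (is.null(injection_time)) {
    dydt <- abs(diff(y) / diff(t))
    injection_time <- t[which.max(dydt)]
  }
  keep <- t >= injection_time
  if (sum(keep) < 5L) abort("Too few samples after the injection time.")
  ts <- t[keep] - injection_time
  ys <- y[keep]

  no_decay <- function() {
    out <- list(k = 0, f0 = mean(ys), f_inf = mean(ys),
                injection_time = injection_time, decay_detected = FALSE,
                residual_norm = sqrt(sum((ys - mean(ys))^2)),
                data = tibble::as_tibble(trace))
    class(out) <- "quench_fit"
    out
  }

  k0 <- 2 / max(ts)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ys ~ finf + (f0 - finf) * exp(-k * ts),
      start = list(finf = tail(ys, 1), f0 = ys[1], k = k0),
      lower = c(-Inf, -Inf, 0),
      control = minpack.lm::nls.lm.control(maxiter = 300)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) return(no_decay())
  rss1 <- deviance(fit)
  rss0 <- sum((ys - mean(ys))^2)
  n <- length(ys)
  fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
  p_f <- stats::pf(fstat, 2, n - 3, lower.tail = FALSE)
  if (!is.finite(p_f) || p_f > alpha || coef(fit)[["k"]] <= 0) {
    return(no_decay())
  }
  cf <- coef(fit)
  out <- list(k = unname(cf[["k"]]), f0 = unname(cf[["f0"]]),
              f_inf = unname(cf[["finf"]]),
              injection_time = injection_time, decay_detected = TRUE,
              residual_norm = sqrt(rss1), data = tibble::as_tibble(trace))
  class(out) <- "quench_fit"
  out
}

#' @export
print.quench_fit <- function(x, ...) {
  cat(sprintf("Calcein-quench fit: k = %.4g /s (decay detected: %s)\n",
              x$k, x$decay_detected))
  invisible(x)
}

#' Fluorescence-to-volume calibration
#'
#' A monotone standard curve mapping normalized fluorescence to normalized
#' cell volume (as generated from an independent cell-sizing measurement).
#' `"interpolate"` uses piecewise-linear interpolation through the pairs;
#' `"linear"` fits a straight line. The mapping must be strictly monotone
#' and map 1 to 1 (both signals normalized to the resting state).
#'
#' @param fluorescence,volume Paired normalized values (same length,
#'   >= 2 points).
#' @param method `"interpolate"` (piecewise linear) or `"linear"`.
#' @return An object of class `volume_calibration`.
#' @export
volume_calibration <- function(fluorescence, volume,
                               method = c("interpolate", "linear")) {
  method <- match.arg(method)
  if (length(fluorescence) != length(volume) || length(volume) < 2L) {
    abort("Calibration needs >= 2 paired points.")
  }
  ord <- order(fluorescence)
  f <- fluorescence[ord]
  v <- volume[ord]
  if (any(diff(f) <= 0) || any(diff(v) <= 0)) {
    abort("Calibration mapping must be strictly monotone.")
  }
  map <- if (method == "interpolate") {
    approxfun(f, v, rule = 2)
  } else {
    cf <- coef(stats::lm(v ~ f))
    function(x) cf[[1]] + cf[[2]] * x
  }
  one <- map(1)
  if (abs(one - 1) > 1e-6) {
    abort(sprintf("Calibration must map 1 -> 1; it maps 1 -> %.4g.", one))
  }
  structure(list(fluorescence = f, volume = v, method = method, map = map),
            class = "volume_calibration")
}

#' Convert normalized fluorescence to normalized volume
#'
#' Applies a monotone [volume_calibration()] elementwise. Values outside
#' the calibrated fluorescence range are converted by boundary
#' extrapolation and reported with a warning.
#'
#' @param data Data frame with a `fluorescence` column (plus any others,
#'   retained), or a numeric vector.
#' @param cal A [volume_calibration()].
#' @return The input with a `volume` column appended (or a numeric vector
#'   if `data` was a vector).
#' @export
to_volume <- function(data, cal) {
  stopifnot(inherits(cal, "volume_calibration"))
  f <- if (is.data.frame(data)) data$fluorescence else data
  if (is.null(f)) abort("`data` must contain a `fluorescence` column.")
  outside <- f < min(cal$fluorescence) | f > max(cal$fluorescence)
  if (any(outside)) {
    warn(sprintf("%d value(s) outside the calibrated range; extrapolated.",
                 sum(outside)))
  }
  v <- cal$map(f)
  if (is.data.frame(data)) {
    data$volume <- v
    tibble::as_tibble(data)
  } else {
    v
  }
}

#' Membrane accumulation kinetics and half-time
#'
#' Fits surface-accumulation time courses of the saturating form
#' `y(t) = 1 - e^{-kt}` (signal normalized to its plateau) and reports the
#' half-time `t_half = ln(2) / k`. Data that do not approach saturation
#' within the observed window are flagged non-converged.
#'
#' @param data Data frame with columns `time` and `signal` (normalized to
#'   a plateau of 1); at least 4 time points.
#' @return An object of class `accumulation_fit` with elements `k`,
#'   `t_half`, `residual_norm`, `converged`, `data`. Units of `t_half`
#'   follow the units of `time`.
#' @examples
#' tt <- tibble::tibble(time = 0:10, signal = 1 - exp(-0.7702 * time))
#' accumulation_halftime(tt)$t_half # ~0.9
#' @export
accumulation_halftime <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("time", "signal") %in% names(data))) {
    abort("`data` must have columns `time` and `signal`.")
  }
  if (nrow(data) < 4L) abort("At least 4 time points are required.")
  t <- data$time
  y <- data$signal
  k0 <- {
    half_idx <- which(y >= 0.5)[1]
    if (!is.na(half_idx) && t[half_idx] > 0) log(2) / t[half_idx] else
      1 / max(t)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 - exp(-k * t), start = list(k = k0),
                      lower = 0,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out <- list(k = NA_real_, t_half = NA_real_, residual_norm = NA_real_,
                converged = FALSE, data = tibble::as_tibble(data))
    class(out) <- "accumulation_fit"
    return(out)
  }
  k <- coef(fit)[["k"]]
  converged <- is.finite(k) && k > 0 && k * max(t) >= 1
  out <- list(k = unname(k), t_half = log(2) / k,
              residual_norm = sqrt(deviance(fit)), converged = converged,
              data = tibble::as_tibble(data))
  class(out) <- "accumulation_fit"
  out
}

#' Final concentration after an equal-volume style injection
#'
#' Concentration of an osmolyte after injecting `v_inject_ul` of stock at
#' `stock_mm` into a well already holding `v_well_ul` of osmolyte-free
#' medium: `stock * v_inject / (v_inject + v_well)`. For a non-penetrating
#' nonionic osmolyte such as mannitol the imposed osmotic gradient in mOsm
#' equals the final concentration in mM.
#'
#' @param stock_mm Stock concentration (mM).
#' @param v_inject_ul Injected volume (uL).
#' @param v_well_ul Volume already in the well (uL).
#' @return Final concentration (mM).
#' @examples
#' injection_dilution(400, 75, 75) # 200 mM, i.e. a 200 mOsm gradient
#' @export
injection_dilution <- function(stock_mm, v_inject_ul, v_well_ul) {
  check_positive(stock_mm, "stock_mm")
  check_positive(v_inject_ul, "v_inject_ul")
  check_number(v_well_ul, "v_well_ul", lower = 0)
  stock_mm * v_inject_ul / (v_inject_ul + v_well_ul)
}
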