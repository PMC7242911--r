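#' Free ligand concentration under depletion
#'
#' Solves the 1:1 mass balance for the free concentration of a titrated
#' ligand when binding to a fixed concentration of receptor appreciably
#' depletes it (the regime of an MST titration where total receptor is
#' comparable to the dissociation constant):
#' \deqn{L_{free} = 0.5\,(L_{tot} - P_{tot} - K_d) +
#'   \sqrt{0.25\,(K_d + P_{tot} - L_{tot})^2 + L_{tot} K_d}}
#' This is the positive root of the mass-balance quadratic; it reduces to
#' \eqn{L_{tot}} when \eqn{P_{tot} = 0} and to
#' \eqn{\max(0, L_{tot} - P_{tot})} as \eqn{K_d \to 0}.
#'
#' @param l_tot Total ligand concentration (uM). Vectorised.
#' @param p_tot Total receptor concentration (uM).
#' @param kd Dissociation constant (uM).
#' @return Free ligand concentration (uM), clamped to `[0, l_tot]` against
#'   floating-point round-off.
#' @examples
#' free_ligand(160, 17, 29)
#' free_ligand(10, 0, 29) # no receptor, no depletion
#' @export
free_ligand <- function(l_tot, p_tot, kd) {
  if (any(l_tot < 0) || p_tot < 0 || kd < 0) {
    abort("`l_tot`, `p_tot` and `kd` must all be non-negative.")
  }
  lf <- 0.5 * (l_tot - p_tot - kd) +
    sqrt(0.25 * (kd + p_tot - l_tot)^2 + l_tot * kd)
  pmin(pmax(lf, 0), l_tot)
}

#' One-to-one binding isotherm signal
#'
#' Signal of a titration at a given free ligand concentration under a
#' one-site model: `s1` is the signal of the unbound receptor, `s2` of the
#' saturated complex, and the occupancy is `l_free / (l_free + kd)`.
#'
#' @param l_free Free ligand concentration (uM). Vectorised.
#' @param s1,s2 Signals of the unbound and bound forms.
#' @param kd Dissociation constant (uM), must be positive.
#' @return Signal values between `s1` (at zero ligand) and `s2` (asymptote).
#' @export
binding_signal <- function(l_free, s1, s2, kd) {
  if (any(l_free < 0)) abort("`l_free` must be non-negative.")
  check_positive(kd, "kd")
  s1 + (s2 - s1) * l_free / (l_free + kd)
}

#' Sigmoidal dose-response signal
#'
#' Four-parameter logistic on the log10 concentration axis:
#' \deqn{y = A_1 + (A_2 - A_1) / (1 + 10^{(x_0 - x)\,p})}
#' where `x0` is the midpoint and `p` the Hill coefficient. At `x = x0` the
#' signal equals `(a1 + a2) / 2`.
#'
#' @param x log10 concentration. Vectorised.
#' @param a1,a2 Signals of the unbound and bound forms.
#' @param x0 Midpoint on the log10-concentration axis.
#' @param p Hill coefficient (nonzero).
#' @return Signal values bounded by `a1` and `a2`.
#' @export
dose_response_signal <- function(x, a1, a2, x0, p) {
  if (!is.finite(p) || p == 0) abort("`p` must be finite and nonzero.")
  a1 + (a2 - a1) / (1 + 10^((x0 - x) * p))
}

#' Extract Fnorm from an MST trace
#'
#' Computes the thermophoresis readout Fnorm = F0 / F1 where F0 and F1 are
#' mean relative fluorescences in windows before and after infrared heating.
#' With `f1_window = "auto"` a fixed-width window is slid over the region
#' after the F0 window and the window maximising the signal-to-noise ratio
#' `|mean(F1) - mean(F0)| / pooled SD` is selected (earliest window on ties),
#' mimicking instrument-software window selection.
#'
#' @param trace Data frame with columns `time` (s, strictly increasing) and
#'   `rel_fluorescence`.
#' @param f0_window Length-2 numeric, `(t_start, t_end)` of the pre-heating
#'   window (s).
#' @param f1_window Length-2 numeric window, or `"auto"`.
#' @param auto_width Width (s) of the candidate F1 windows under `"auto"`.
#' @return A list with `fnorm`, the selected `f1_window`, and the window
#'   means `f0`, `f1`.
#' @export
extract_fnorm <- function(trace, f0_window, f1_window = "auto",
                          auto_width = 1) {
  time <- trace$time
  f <- trace$rel_fluorescence
  check_time_increasing(time)
  if (length(f0_window) != 2L || diff(f0_window) <= 0) {
    abort("`f0_window` must be (t_start, t_end) with t_end > t_start.")
  }
  if (f0_window[1] < min(time) || f0_window[2] > max(time)) {
    abort("`f0_window` lies outside the trace extent.")
  }
  in0 <- time >= f0_window[1] & time <= f0_window[2]
  if (sum(in0) < 3L) abort("`f0_window` must contain at least 3 samples.")
  f0_mean <- mean(f[in0])
  v0 <- stats::var(f[in0])
  n0 <- sum(in0)

  if (identical(f1_window, "auto")) {
    check_positive(auto_width, "auto_width")
    starts <- time[time >= f0_window[2] & time + auto_width <= max(time)]
    if (length(starts) == 0L) {
      abort("`f1_window` auto search: no room for a window after `f0_window`.")
    }
    score <- function(t0) {
      in1 <- time >= t0 & time <= t0 + auto_width
      if (sum(in1) < 3L) return(c(-Inf, NA, NA))
      m1 <- mean(f[in1]); n1 <- sum(in1); v1 <- stats::var(f[in1])
      pooled <- sqrt(((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2))
      snr <- if (pooled > 0) abs(m1 - f0_mean) / pooled else
        if (m1 != f0_mean) Inf else 0
      c(snr, m1, t0)
    }
    sc <- vapply(starts, score, numeric(3))
    best <- which.max(sc[1, ]) # which.max returns the first (earliest) max
    f1_window <- c(sc[3, best], sc[3, best] + auto_width)
    f1_mean <- sc[2, best]
  } else {
    if (length(f1_window) != 2L || diff(f1_window) <= 0) {
      abort("`f1_window` must be (t_start, t_end) with t_end > t_start.")
    }
    if (f1_window[1] < f0_window[2]) {
      abort("`f1_window` must start after `f0_window` ends.")
    }
    if (f1_window[2] > max(time)) {
      abort("`f1_window` lies outside the trace extent.")
    }
    in1 <- time >= f1_window[1] & time <= f1_window[2]
    if (sum(in1) < 3L) abort("`f1_window` must contain at least 3 samples.")
    f1_mean <- mean(f[in1])
  }
  list(fnorm = f0_mean / f1_mean, f1_window = f1_window,
       f0 = f0_mean, f1 = f1_mean)
}

# kd search bounds shared by the binding fit and its no-binding criterion
.kd_bounds <- c(1e-3, 1e5)

#' Fit a depletion-corrected one-to-one binding isotherm
#'
#' Nonlinear least squares of `binding_signal(free_ligand(l_tot, p_tot, kd))`
#' over (S1, S2, Kd) on an MST titration. The free-ligand quadratic corrects
#' for ligand depletion by the fixed receptor concentration `p_tot`.
#' Replicate series (a `replicate` column) are pooled into a single global
#' fit by default. Kd is fitted on a bounded scale with a multi-start over
#' log-spaced initial values, because the isotherm's likelihood is flat when
#' Kd far exceeds the largest titrated concentration.
#'
#' A no-binding decision (`binding_detected`) uses an extra-sum-of-squares
#' F-test of the 3-parameter model against a constant model at `alpha`; a fit
#' that runs into the upper Kd bound is also declared no-binding.
#'
#' @param data Data frame with columns `conc_um` (total titrated ligand, uM)
#'   and `signal`; an optional `replicate` column is retained but pooled.
#' @param p_tot Fixed total receptor concentration (uM).
#' @param alpha Significance level of the no-binding F-test.
#' @return An object of class `binding_fit` with elements `s1`, `s2`, `kd`,
#'   `se_kd`, `se_s1`, `se_s2`, `residual_norm`, `converged`,
#'   `binding_detected`, `n`, `p_tot`, `data`.
#' @examples
#' tt <- gen_mst_titration(s1 = 1, s2 = 0.9, kd = 29,
#'                         design = mst_design(noise_sd = 0, seed = 1))
#' fit_binding(tt, p_tot = 17)$kd
#' @export
fit_binding <- function(data, p_tot, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  if (!all(c("conc_um", "signal") %in% names(data))) {
    abort("`data` must have columns `conc_um` and `signal`.")
  }
  check_number(p_tot, "p_tot", lower = 0)
  l <- data$conc_um
  y <- data$signal
  if (any(l <= 0)) abort("`conc_um` must be positive.")
  if (length(unique(l)) < 5L) {
    abort("At least 5 distinct concentrations are required.")
  }
  if (max(l) / min(l) < 10) {
    warn("Titration spans less than one decade; Kd may be poorly determined.")
  }

  model <- function(l, s1, s2, kd) {
    binding_signal(free_ligand(l, p_tot, kd), s1, s2, kd)
  }
  s1_0 <- y[which.min(l)]
  s2_0 <- y[which.max(l)]
  kd_starts <- 10^seq(log10(max(min(l), 0.01)), log10(max(l) * 10),
                      length.out = 5)
  fits <- purrr::map(kd_starts, function(k0) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ model(l, s1, s2, kd),
        start = list(s1 = s1_0, s2 = s2_0, kd = k0),
        lower = c(-Inf, -Inf, .kd_bounds[1]),
        upper = c(Inf, Inf, .kd_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  converged <- length(fits) > 0L
  if (!converged) {
    warn("Binding fit did not converge from any start; returning NA estimates.")
    out <- list(s1 = NA_real_, s2 = NA_real_, kd = NA_real_,
                se_s1 = NA_real_, se_s2 = NA_real_, se_kd = NA_real_,
                residual_norm = NA_real_, converged = FALSE,
                binding_detected = FALSE, n = length(y), p_tot = p_tot,
                data = tibble::as_tibble(data))
    class(out) <- "binding_fit"
    return(out)
  }
  best <- fits[[which.min(purrr::map_dbl(fits, deviance))]]
  cf <- coef(best)
  se <- fit_se(best)
  rss1 <- deviance(best)
  rss0 <- sum((y - mean(y))^2)
  n <- length(y)
  # extra-sum-of-squares F-test: 3-parameter isotherm vs constant model
  fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 3))
  p_f <- stats::pf(fstat, 2, n - 3, lower.tail = FALSE)
  hit_bound <- cf[["kd"]] >= 0.99 * .kd_bounds[2]
  binding_detected <- is.finite(p_f) && p_f <= alpha && !hit_bound

  out <- list(
    s1 = unname(cf[["s1"]]), s2 = unname(cf[["s2"]]), kd = unname(cf[["kd"]]),
    se_s1 = unname(se[["s1"]]), se_s2 = unname(se[["s2"]]),
    se_kd = unname(se[["kd"]]),
    residual_norm = sqrt(rss1), converged = TRUE,
    binding_detected = binding_detected,
    f_vs_constant = unname(fstat), p_vs_constant = unname(p_f),
    n = n, p_tot = p_tot, data = tibble::as_tibble(data)
  )
  class(out) <- "binding_fit"
  out
}

#' Fit a sigmoidal dose-response curve and report IC50
#'
#' Least-squares fit of [dose_response_signal()] over (A1, A2, x0, p) to an
#' inhibitor titration, on the log10 concentration axis. The midpoint is
#' reported as `ic50 = 10^x0` in concentration units; its standard error is
#' propagated from `se(x0)` by the delta method. Data indistinguishable from
#' a constant (flat or A1 = A2) are flagged `converged = FALSE`.
#'
#' @param data Data frame with columns `conc_um` (inhibitor concentration,
#'   uM) and `signal`; optional `replicate` pooled into one global fit.
#' @param alpha Significance level of the flatness F-test.
#' @return An object of class `dose_response_fit` with elements `a1`, `a2`,
#'   `x0`, `p`, `ic50`, `se_ic50`, `se_x0`, `residual_norm`, `converged`,
#'   `n`, `data`.
#' @examples
#' dd <- gen_dose_response(a1 = 1, a2 = 0.8, x0 = log10(790), p = 1,
#'                         conc_um = 10^seq(1.7, 3.7, length.out = 12),
#'                         noise_sd = 0, seed = 1)
#' fit_dose_response(dd)$ic50
#' @export
fit_dose_response <- function(data, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  if (!all(c("conc_um", "signal") %in% names(data))) {
    abort("`data` must have columns `conc_um` and `signal`.")
  }
  if (any(data$conc_um <= 0)) abort("`conc_um` must be positive.")
  if (length(unique(data$conc_um)) < 6L) {
    abort("At least 6 distinct concentrations are required.")
  }
  x <- log10(data$conc_um)
  y <- data$signal

  a1_0 <- mean(y[x <= stats::quantile(x, 0.25)])
  a2_0 <- mean(y[x >= stats::quantile(x, 0.75)])
  x0_0 <- mean(range(x))
  fits <- purrr::map(c(0.5, 1, 2), function(p0) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ dose_response_signal(x, a1, a2, x0, p),
        start = list(a1 = a1_0, a2 = a2_0, x0 = x0_0, p = p0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  n <- length(y)
  if (length(fits) == 0L) {
    out <- list(a1 = NA_real_, a2 = NA_real_, x0 = NA_real_, p = NA_real_,
                ic50 = NA_real_, se_ic50 = NA_real_, se_x0 = NA_real_,
                residual_norm = NA_real_, converged = FALSE, n = n,
                data = tibble::as_tibble(data))
    class(out) <- "dose_response_fit"
    return(out)
  }
  best <- fits[[which.min(purrr::map_dbl(fits, deviance))]]
  cf <- coef(best)
  se <- fit_se(best)
  rss1 <- deviance(best)
  rss0 <- sum((y - mean(y))^2)
  fstat <- ((rss0 - rss1) / 3) / (rss1 / (n - 4))
  p_f <- stats::pf(fstat, 3, n - 4, lower.tail = FALSE)
  flat <- !is.finite(p_f) || p_f > alpha
  ic50 <- 10^cf[["x0"]]
  se_ic50 <- log(10) * ic50 * se[["x0"]]

  out <- list(
    a1 = unname(cf[["a1"]]), a2 = unname(cf[["a2"]]),
    x0 = unname(cf[["x0"]]), p = unname(cf[["p"]]),
    ic50 = unname(ic50), se_ic50 = unname(se_ic50),
    se_x0 = unname(se[["x0"]]),
    residual_norm = sqrt(rss1), converged = !flat, n = n,
    data = tibble::as_tibble(data)
  )
  class(out) <- "dose_response_fit"
  out
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("One-to-one binding fit (ligand depletion corrected)\n")
  cat(sprintf("  Kd = %.3g +/- %.2g uM  (P_tot = %g uM, n = %d)\n",
              x$kd, x$se_kd, x$p_tot, x$n))
  cat(sprintf("  S1 = %.4g, S2 = %.4g\n", x$s1, x$s2))
  cat(sprintf("  binding detected: %s\n", x$binding_detected))
  invisible(x)
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Sigmoidal dose-response fit\n")
  cat(sprintf("  IC50 = %.4g +/- %.2g uM (x0 = %.4g, Hill p = %.3g)\n",
              x$ic50, x$se_ic50, x$x0, x$p))
  cat(sprintf("  converged: %s\n", x$converged))
  invisible(x)
}
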