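# broom-style tidiers for the fitted-object classes

#' @rdname binding_fit_tidiers
#' @title Tidiers for binding and dose-response fits
#' @description `tidy()` returns one row per model parameter with its
#'   standard error; `glance()` returns a one-row model summary.
#' @param x A `binding_fit` or `dose_response_fit`.
#' @param ... Unused.
#' @method tidy binding_fit
#' @export
tidy.binding_fit <- function(x, ...) {
  tibble::tibble(
    term = c("s1", "s2", "kd"),
    estimate = c(x$s1, x$s2, x$kd),
    std.error = c(x$se_s1, x$se_s2, x$se_kd)
  )
}

#' @rdname binding_fit_tidiers
#' @method glance binding_fit
#' @export
glance.binding_fit <- function(x, ...) {
  tibble::tibble(kd = x$kd, se_kd = x$se_kd,
                 residual_norm = x$residual_norm,
                 converged = x$converged,
                 binding_detected = x$binding_detected,
                 p_tot = x$p_tot, nobs = x$n)
}

#' @rdname binding_fit_tidiers
#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a1", "a2", "x0", "p"),
    estimate = c(x$a1, x$a2, x$x0, x$p),
    std.error = c(NA_real_, NA_real_, x$se_x0, NA_real_)
  )
}

#' @rdname binding_fit_tidiers
#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(ic50 = x$ic50, se_ic50 = x$se_ic50,
                 hill = x$p, residual_norm = x$residual_norm,
                 converged = x$converged, nobs = x$n)
}

#' @rdname kinetics_tidiers
#' @title Tidiers for kinetic fits
#' @description Parameter tables and one-row summaries for
#'   double-exponential shrinkage, calcein-quench and membrane
#'   accumulation fits.
#' @param x A `double_exp_fit`, `quench_fit` or `accumulation_fit`.
#' @param ... Unused.
#' @method tidy double_exp_fit
#' @export
tidy.double_exp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k_fast", "k_slow", "a_fast", "a_slow", "baseline"),
    estimate = c(x$k_fast, x$k_slow, x$a_fast, x$a_slow, x$baseline)
  )
}

#' @rdname kinetics_tidiers
#' @method glance double_exp_fit
#' @export
glance.double_exp_fit <- function(x, ...) {
  tibble::tibble(k_selected = x$k_selected,
                 residual_norm = x$residual_norm,
                 single_exponential = x$single_exponential,
                 converged = x$converged)
}

#' @rdname kinetics_tidiers
#' @method tidy quench_fit
#' @export
tidy.quench_fit <- function(x, ...) {
  tibble::tibble(term = c("k", "f0", "f_inf"),
                 estimate = c(x$k, x$f0, x$f_inf))
}

#' @rdname kinetics_tidiers
#' @method glance quench_fit
#' @export
glance.quench_fit <- function(x, ...) {
  tibble::tibble(k = x$k, decay_detected = x$decay_detected,
                 injection_time = x$injection_time,
                 residual_norm = x$residual_norm)
}

#' @rdname kinetics_tidiers
#' @method tidy accumulation_fit
#' @export
tidy.accumulation_fit <- function(x, ...) {
  tibble::tibble(term = c("k", "t_half"), estimate = c(x$k, x$t_half))
}

#' @rdname kinetics_tidiers
#' @method glance accumulation_fit
#' @export
glance.accumulation_fit <- function(x, ...) {
  tibble::tibble(k = x$k, t_half = x$t_half,
                 residual_norm = x$residual_norm, converged = x$converged)
}

#' @rdname kw_tidiers
#' @title Tidiers for the Kruskal-Wallis test
#' @param x A `kw_test`.
#' @param ... Unused.
#' @method tidy kw_test
#' @export
tidy.kw_test <- function(x, ...) {
  tibble::tibble(statistic = x$h, df = x$df, p.value = x$p,
                 method = if (!is.na(x$p_exact)) "exact permutation" else
                   "chi-square approximation")
}

#' @rdname kw_tidiers
#' @method glance kw_test
#' @export
glance.kw_test <- function(x, ...) {
  tibble::tibble(statistic = x$h, df = x$df, p_chisq = x$p_chisq,
                 p_exact = x$p_exact, nobs = x$n, k = x$k)
}
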