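# internal validation helpers

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_zero_lower = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (allow_zero_lower) x >= lower else x > lower
  if (!lo_ok || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s]; got %g.", name,
                  format(lower), format(upper), x))
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number.", name))
  }
  invisible(x)
}

check_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.numeric(seed) ||
      length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` is required and must be a single integer.")
  }
  as.integer(seed)
}

check_time_increasing <- function(time, name = "time") {
  if (!is.numeric(time) || anyNA(time) || any(diff(time) <= 0)) {
    abort(sprintf("`%s` must be numeric and strictly increasing.", name))
  }
  invisible(time)
}

# safe covariance-based standard errors from an nls/nlsLM fit
fit_se <- function(fit) {
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) NULL)
  if (is.null(se)) {
    se <- rep(NA_real_, length(coef(fit)))
    names(se) <- names(coef(fit))
  }
  se
}
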