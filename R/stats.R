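#' Z-test for two independent estimates
#'
#' Compares two fitted constants (e.g. dissociation constants from two
#' titrations) given their standard deviations:
#' \deqn{Z = (\bar X_1 - \bar X_2) / \sqrt{\sigma_1^2 + \sigma_2^2}}
#' with the p-value from the standard normal tail(s). The one-sided test
#' uses the tail in the direction of the observed difference.
#'
#' @param x1,sd1 First estimate and its standard deviation.
#' @param x2,sd2 Second estimate and its standard deviation.
#' @param tail `"one"` or `"two"` sided.
#' @return Tibble with columns `z`, `p`, `tail`, `infinite_z`.
#' @examples
#' z_test_estimates(29, 5.6, 17, 3.1, tail = "one") # p ~ 0.030
#' @export
z_test_estimates <- function(x1, sd1, x2, sd2, tail = c("one", "two")) {
  tail <- match.arg(tail)
  check_number(sd1, "sd1", lower = 0)
  check_number(sd2, "sd2", lower = 0)
  denom <- sqrt(sd1^2 + sd2^2)
  infinite_z <- FALSE
  if (denom == 0) {
    if (x1 == x2) {
      z <- 0
    } else {
      warn("Both standard deviations are zero with unequal estimates; Z is infinite.")
      z <- sign(x1 - x2) * Inf
      infinite_z <- TRUE
    }
  } else {
    z <- (x1 - x2) / denom
  }
  p_one <- pnorm(abs(z), lower.tail = FALSE)
  p <- if (tail == "one") p_one else 2 * p_one
  tibble::tibble(z = z, p = p, tail = tail, infinite_z = infinite_z)
}

# rank-sum machinery shared by the omnibus and post hoc tests
.kw_h <- function(value, group) {
  r <- rank(value) # mid-ranks for ties
  n <- length(value)
  ni <- tapply(r, group, length)
  rbar <- tapply(r, group, mean)
  h <- 12 / (n * (n + 1)) * sum(ni * rbar^2) - 3 * (n + 1)
  ties <- table(value)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (correction > 0) h <- h / correction
  h
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square approximation
#' (df = groups - 1). For small samples (total n <= `exact_n`) an exact
#' p-value is also computed by enumerating every assignment of the pooled
#' observations to the observed group sizes.
#'
#' @param data Data frame with columns `group` and `value`.
#' @param exact_n Largest total n for which the exact permutation p-value
#'   is computed.
#' @return An object of class `kw_test` with elements `h`, `df`,
#'   `p_chisq`, `p_exact` (`NA` above `exact_n`), `p` (exact when
#'   available, else chi-square), `n`, `k`, `data`.
#' @export
kruskal_wallis <- function(data, exact_n = 8) {
  stopifnot(is.data.frame(data))
  if (!all(c("group", "value") %in% names(data))) {
    abort("`data` must have columns `group` and `value`.")
  }
  g <- as.factor(data$group)
  v <- data$value
  if (nlevels(g) < 2L) abort("At least 2 groups are required.")
  if (any(tapply(v, g, length) == 0)) abort("Every group must be non-empty.")
  n <- length(v)
  k <- nlevels(g)
  h <- .kw_h(v, g)
  p_chisq <- pchisq(h, df = k - 1, lower.tail = FALSE)

  p_exact <- NA_real_
  if (n <= exact_n) {
    perms <- .permutations(n)
    hs <- apply(perms, 1, function(idx) .kw_h(v[idx], g))
    p_exact <- mean(hs >= h - 1e-12)
  }
  out <- list(h = h, df = k - 1, p_chisq = p_chisq, p_exact = p_exact,
              p = if (is.na(p_exact)) p_chisq else p_exact,
              n = n, k = k, data = tibble::as_tibble(data))
  class(out) <- "kw_test"
  out
}

# all permutations of 1:n as a matrix (n! rows); n <= 8 keeps this small
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g%s\n",
              x$h, x$df, x$p,
              if (!is.na(x$p_exact)) " (exact permutation)" else
                " (chi-square)"))
  invisible(x)
}

#' Conover-Iman post hoc comparisons
#'
#' Rank-based pairwise comparisons following a Kruskal-Wallis test, using
#' the pooled rank variance: for groups i, j,
#' \deqn{t = (\bar R_i - \bar R_j) / \sqrt{S^2 \frac{N-1-H}{N-k}
#'   \left(\frac{1}{n_i} + \frac{1}{n_j}\right)}}
#' with \eqn{S^2 = \frac{1}{N-1}\left(\sum R^2 - N (N+1)^2/4\right)} and
#' `N - k` degrees of freedom; two-sided p per pair. Pairs involving a
#' singleton group are flagged untestable (p = NA).
#'
#' @param data Data frame with columns `group` and `value`.
#' @param kw Optional [kruskal_wallis()] result computed on the same data
#'   (recomputed if omitted).
#' @return Tibble with columns `group1`, `group2`, `mean_rank_diff`,
#'   `statistic`, `df`, `p`, `testable`.
#' @export
conover_inman <- function(data, kw = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("group", "value") %in% names(data))) {
    abort("`data` must have columns `group` and `value`.")
  }
  if (is.null(kw)) kw <- kruskal_wallis(data)
  stopifnot(inherits(kw, "kw_test"))
  g <- as.factor(data$group)
  v <- data$value
  r <- rank(v)
  n <- length(v)
  k <- nlevels(g)
  ni <- tapply(r, g, length)
  rbar <- tapply(r, g, mean)
  s2 <- (sum(r^2) - n * (n + 1)^2 / 4) / (n - 1)
  scale2 <- s2 * (n - 1 - kw$h) / (n - k)
  df <- n - k

  pairs <- utils::combn(levels(g), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    testable <- ni[[g1]] >= 2 && ni[[g2]] >= 2
    d <- rbar[[g1]] - rbar[[g2]]
    se <- sqrt(scale2 * (1 / ni[[g1]] + 1 / ni[[g2]]))
    tt <- if (se > 0) d / se else if (d == 0) 0 else sign(d) * Inf
    p <- 2 * pt(abs(tt), df, lower.tail = FALSE)
    tibble::tibble(group1 = g1, group2 = g2, mean_rank_diff = d,
                   statistic = tt, df = df,
                   p = if (testable) p else NA_real_,
                   testable = testable)
  })
}

#' Bonferroni-corrected pairwise t tests
#'
#' Two-sample t tests for every group pair (or each group against a
#' reference), with Bonferroni adjustment `p_adj = min(1, m p)` where `m`
#' is the number of comparisons performed. The one-way ANOVA p-value over
#' all groups is reported alongside but does not gate the pairwise tests
#' by default.
#'
#' @param data Data frame with columns `group` and `value`.
#' @param reference Optional group label; if given, only
#'   reference-vs-other comparisons are made.
#' @param var_equal Assume equal variances (classic t test) or not
#'   (Welch, the default).
#' @param gatekeep If `TRUE`, pairwise p-values are only reported when
#'   the ANOVA is significant at 0.05.
#' @return Tibble with columns `group1`, `group2`, `statistic`, `df`,
#'   `p`, `p_adj`, `m`, `testable`, with the ANOVA p in attribute
#'   `anova_p`.
#' @export
bonferroni_ttests <- function(data, reference = NULL, var_equal = FALSE,
                              gatekeep = FALSE) {
  stopifnot(is.data.frame(data))
  if (!all(c("group", "value") %in% names(data))) {
    abort("`data` must have columns `group` and `value`.")
  }
  g <- as.factor(data$group)
  v <- data$value
  if (nlevels(g) < 2L) abort("At least 2 groups are required.")
  anova_p <- tryCatch(
    summary(aov(v ~ g))[[1]][["Pr(>F)"]][1],
    error = function(e) NA_real_
  )
  pairs <- if (is.null(reference)) {
    utils::combn(levels(g), 2)
  } else {
    if (!reference %in% levels(g)) abort("`reference` is not a group label.")
    rbind(reference, setdiff(levels(g), reference))
  }
  m <- ncol(pairs)
  res <- purrr::map_dfr(seq_len(m), function(j) {
    v1 <- v[g == pairs[1, j]]
    v2 <- v[g == pairs[2, j]]
    testable <- !(sd(v1) == 0 && sd(v2) == 0) &&
      length(v1) >= 2 && length(v2) >= 2
    if (testable) {
      tt <- t.test(v1, v2, var.equal = var_equal)
      tibble::tibble(group1 = pairs[1, j], group2 = pairs[2, j],
                     statistic = unname(tt$statistic),
                     df = unname(tt$parameter), p = tt$p.value,
                     testable = TRUE)
    } else {
      tibble::tibble(group1 = pairs[1, j], group2 = pairs[2, j],
                     statistic = NA_real_, df = NA_real_, p = NA_real_,
                     testable = FALSE)
    }
  })
  res$p_adj <- pmin(1, m * res$p)
  res$m <- m
  if (gatekeep && (is.na(anova_p) || anova_p > 0.05)) {
    res$p_adj <- NA_real_
  }
  attr(res, "anova_p") <- anova_p
  res
}
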