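# independent oracles coded from first principles, used to cross-check the
# package implementations

# free-ligand by numerically solving the 1:1 mass balance
# Kd = L_free * P_free / C with C = L_tot - L_free, P_free = P_tot - C
oracle_free_ligand <- function(l_tot, p_tot, kd) {
  f <- function(lf) kd * (l_tot - lf) - lf * (p_tot - l_tot + lf)
  stats::uniroot(f, c(0, l_tot), tol = 1e-12)$root
}

# Conover-Iman pairwise p-values via explicit loops over the textbook
# formula (pooled rank variance, N - k degrees of freedom)
oracle_conover <- function(value, group) {
  group <- as.factor(group)
  r <- rank(value)
  n <- length(value)
  k <- nlevels(group)
  # tie-corrected Kruskal-Wallis H, recomputed here from scratch
  ssum <- 0
  for (g in levels(group)) {
    rg <- r[group == g]
    ssum <- ssum + length(rg) * mean(rg)^2
  }
  h <- 12 / (n * (n + 1)) * ssum - 3 * (n + 1)
  tie_tab <- table(value)
  corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
  if (corr > 0) h <- h / corr
  s2 <- (sum(r^2) - n * (n + 1)^2 / 4) / (n - 1)
  out <- NULL
  levs <- levels(group)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ri <- r[group == levs[i]]
      rj <- r[group == levs[j]]
      se <- sqrt(s2 * ((n - 1 - h) / (n - k)) *
                   (1 / length(ri) + 1 / length(rj)))
      tt <- (mean(ri) - mean(rj)) / se
      p <- 2 * stats::pt(abs(tt), n - k, lower.tail = FALSE)
      out <- rbind(out, data.frame(group1 = levs[i], group2 = levs[j],
                                   p = p))
    }
  }
  out
}

# exact Kruskal-Wallis p for two groups by enumerating which observations
# fall in group 1 (combn-based, independent of the package's permutation
# recursion)
oracle_kw_exact_2group <- function(value, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L)
  h_of <- function(g) {
    r <- rank(value)
    n <- length(value)
    ssum <- sum(tapply(r, g, function(x) length(x) * mean(x)^2))
    h <- 12 / (n * (n + 1)) * ssum - 3 * (n + 1)
    tie_tab <- table(value)
    corr <- 1 - sum(tie_tab^3 - tie_tab) / (n^3 - n)
    if (corr > 0) h / corr else h
  }
  h_obs <- h_of(group)
  n1 <- sum(group == levels(group)[1])
  idx <- utils::combn(length(value), n1)
  hs <- apply(idx, 2, function(ii) {
    g <- factor(ifelse(seq_along(value) %in% ii, "a", "b"))
    h_of(g)
  })
  mean(hs >= h_obs - 1e-12)
}

# brute-force positive-pixel count by an explicit per-pixel loop
oracle_pixel_count <- function(image, threshold) {
  cnt <- 0L
  for (px in as.vector(image)) if (px > threshold) cnt <- cnt + 1L
  cnt
}

# a compound-action-potential-like trace: negative half-sine of amplitude
# `a` and duration `t_ms`, followed by a flat return to baseline
half_sine_cap <- function(a = 1, t_ms = 1, dt = 1e-3, tail_ms = 0.5) {
  tt <- seq(0, t_ms + tail_ms, by = dt)
  v <- ifelse(tt <= t_ms, -a * sin(pi * tt / t_ms), 0)
  tibble::tibble(time_ms = tt, voltage = v)
}
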