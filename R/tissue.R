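#' Gravimetric tissue water content
#'
#' Percent water content from wet and dry tissue weights:
#' `100 * (wet - dry) / wet`. The measure is scale invariant, so the
#' weighing units cancel.
#'
#' @param data Data frame with columns `wet_g` and `dry_g` (any other
#'   columns, e.g. `group` or `animal`, are retained).
#' @return The input as a tibble with a `water_pct` column appended.
#' @examples
#' water_content(tibble::tibble(wet_g = 1, dry_g = 0.3))
#' @export
water_content <- function(data) {
  stopifnot(is.data.frame(data))
  if (!all(c("wet_g", "dry_g") %in% names(data))) {
    abort("`data` must have columns `wet_g` and `dry_g`.")
  }
  bad <- which(!(data$dry_g > 0 & data$dry_g < data$wet_g))
  if (length(bad) > 0L) {
    abort(sprintf("Rows %s violate 0 < dry_g < wet_g.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  dplyr::mutate(tibble::as_tibble(data),
                water_pct = 100 * (.data$wet_g - .data$dry_g) / .data$wet_g)
}

#' Group summaries of water content
#'
#' Mean, SD and n of per-sample water content by group. Whether samples
#' are individual animals or pooled repeats is the caller's choice of
#' rows; both groupings are supported by passing the appropriate table.
#'
#' @param data Data frame with columns `group`, `wet_g`, `dry_g`.
#' @return Tibble with one row per group: `group`, `mean_pct`, `sd_pct`,
#'   `n`.
#' @export
water_content_summary <- function(data) {
  water_content(data) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_pct = mean(.data$water_pct),
                     sd_pct = sd(.data$water_pct),
                     n = dplyr::n(), .groups = "drop")
}

#' Perivascular enrichment ratio from ROI intensities
#'
#' Per image, the ratio of the mean of peri-endothelial ROI means to the
#' mean of non-peri-endothelial ROI means (mean of ROI means, weighting
#' ROIs equally); per animal, the mean of its image ratios. Group-level
#' statistics should always be computed over animal values, never over
#' images, so that image-rich animals do not dominate.
#'
#' @param data Data frame with columns `animal`, `image`, `roi_class`
#'   (values `"peri"` and `"nonperi"`) and `mean_intensity`.
#' @param level `"animal"` (default) for per-animal means or `"image"`
#'   for per-image ratios.
#' @return Tibble with `animal` and `ratio` (level `"animal"`), or
#'   `animal`, `image`, `ratio` (level `"image"`).
#' @export
perivascular_ratio <- function(data, level = c("animal", "image")) {
  level <- match.arg(level)
  stopifnot(is.data.frame(data))
  need <- c("animal", "image", "roi_class", "mean_intensity")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (!all(data$roi_class %in% c("peri", "nonperi"))) {
    abort("`roi_class` must be 'peri' or 'nonperi'.")
  }
  per_image <- data |>
    dplyr::group_by(.data$animal, .data$image, .data$roi_class) |>
    dplyr::summarise(m = mean(.data$mean_intensity), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "roi_class", values_from = "m")
  if (!all(c("peri", "nonperi") %in% names(per_image)) ||
      anyNA(per_image$peri) || anyNA(per_image$nonperi)) {
    abort("Every image needs ROIs of both classes.")
  }
  zero <- per_image$nonperi == 0
  if (any(zero)) {
    warn(sprintf("%d image(s) with zero non-peri mean excluded.", sum(zero)))
    per_image <- per_image[!zero, ]
  }
  per_image <- dplyr::mutate(per_image,
                             ratio = .data$peri / .data$nonperi)
  if (level == "image") {
    return(dplyr::select(per_image, "animal", "image", "ratio"))
  }
  per_image |>
    dplyr::group_by(.data$animal) |>
    dplyr::summarise(ratio = mean(.data$ratio), n_images = dplyr::n(),
                     .groups = "drop")
}

#' Count pixels above a background threshold
#'
#' Immunostaining quantification by thresholded pixel counting. Under
#' `threshold = "auto"` the background threshold is set to the maximum
#' pixel value observed across antibody-control images - the smallest
#' threshold at which every control pixel counts as negative - and pixels
#' strictly above the threshold are counted.
#'
#' @param image Numeric matrix (or vector) of pixel intensities.
#' @param threshold Numeric threshold, or `"auto"`.
#' @param control_images List of control image matrices; required under
#'   `"auto"`.
#' @return A list with `count` (pixels strictly above threshold) and
#'   `threshold` (the value used).
#' @export
positive_pixel_count <- function(image, threshold = "auto",
                                 control_images = NULL) {
  if (!is.numeric(image)) abort("`image` must be numeric.")
  if (identical(threshold, "auto")) {
    if (is.null(control_images) || length(control_images) == 0L) {
      abort("`threshold = \"auto\"` requires `control_images`.")
    }
    threshold <- max(vapply(control_images, max, numeric(1)))
  }
  check_number(threshold, "threshold")
  list(count = sum(image > threshold), threshold = threshold)
}

#' Compound action potential amplitude and rectified area
#'
#' From a voltage trace after the stimulus artifact: the amplitude is the
#' vertical distance from the first qualifying local minimum (the negative
#' deflection) to the next local maximum; the area is the trapezoidal
#' integral of the full-wave-rectified negative component,
#' `integral |min(v, 0)| dt`, over the post-artifact window. A trough/peak
#' pair qualifies when its vertical extent is at least `prominence` times
#' the post-artifact voltage range, which ignores noise wiggles without
#' smoothing.
#'
#' @param trace Data frame with columns `time_ms` and `voltage`.
#' @param artifact_end_ms End of the stimulus artifact (ms); the search
#'   and integration start here.
#' @param prominence Minimum trough-to-peak extent as a fraction of the
#'   post-artifact voltage range.
#' @return A list with `amplitude`, `area`, `trough_time_ms`,
#'   `peak_time_ms`, and `deflection_found`.
#' @export
cap_metrics <- function(trace, artifact_end_ms = 0, prominence = 0.05) {
  stopifnot(is.data.frame(trace))
  if (!all(c("time_ms", "voltage") %in% names(trace))) {
    abort("`trace` must have columns `time_ms` and `voltage`.")
  }
  check_time_increasing(trace$time_ms, "time_ms")
  keep <- trace$time_ms >= artifact_end_ms
  t <- trace$time_ms[keep]
  v <- trace$voltage[keep]
  if (length(v) < 3L) abort("Too few samples after the artifact.")

  area <- pracma::trapz(t, abs(pmin(v, 0)))
  rng <- diff(range(v))

  amplitude <- 0
  trough_time <- NA_real_
  peak_time <- NA_real_
  found <- FALSE
  if (rng > 0) {
    n <- length(v)
    is_min <- c(FALSE, v[2:(n - 1)] <= v[1:(n - 2)] &
                  v[2:(n - 1)] <= v[3:n], FALSE)
    is_max <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] &
                  v[2:(n - 1)] >= v[3:n], FALSE)
    for (i in which(is_min & v < 0)) {
      j <- which(is_max & seq_len(n) > i)
      j <- j[1]
      if (is.na(j)) next
      ext <- v[j] - v[i]
      if (ext >= prominence * rng) {
        amplitude <- ext
        trough_time <- t[i]
        peak_time <- t[j]
        found <- TRUE
        break
      }
    }
  }
  list(amplitude = amplitude, area = area, trough_time_ms = trough_time,
       peak_time_ms = peak_time, deflection_found = found)
}
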