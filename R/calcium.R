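#' Normalize a raw kymograph to dF/F0
#'
#' Background-subtracted fluorescence divided by per-pixel baseline
#' fluorescence: `dF/F0 = (F - bg) / F0 - 1`, where `F0` for each spatial
#' pixel is a low quantile of its own time series (default the 20th
#' percentile), so sparse events do not bias the baseline.
#'
#' @param kymo a raw [san_kymo()].
#' @param background constant background fluorescence to subtract.
#' @param f0_quantile quantile of each pixel's time series used as `F0`.
#' @return A normalized [san_kymo()] (values in dF/F0, `normalized = TRUE`).
#' @export
normalize_kymograph <- function(kymo, background = 0, f0_quantile = 0.2) {
  stopifnot(inherits(kymo, "san_kymo"))
  if (kymo$normalized) return(kymo)
  f <- kymo$fluor - background
  f0 <- apply(f, 1, quantile, probs = f0_quantile, names = FALSE)
  if (any(f0 <= 0)) {
    stop("baseline fluorescence F0 must be positive everywhere; check the background estimate")
  }
  san_kymo(sweep(f, 1, f0, "/") - 1, kymo$pixel_um, kymo$line_interval_ms,
           normalized = TRUE)
}

# half-maximum width of a profile through its peak, linearly interpolating
# the crossing positions; x in physical units, baseline-relative
half_max_width <- function(x, y, baseline = 0) {
  ipk <- which.max(y)
  half <- baseline + (y[ipk] - baseline) / 2
  left <- NA_real_
  for (i in rev(seq_len(ipk - 1))) {
    if (y[i] <= half) {
      left <- approx(y[i:(i + 1)], x[i:(i + 1)], xout = half, ties = "ordered")$y
      break
    }
  }
  right <- NA_real_
  if (ipk < length(y)) {
    for (i in ipk:(length(y) - 1)) {
      if (y[i + 1] <= half) {
        right <- approx(y[c(i + 1, i)], x[c(i + 1, i)], xout = half, ties = "ordered")$y
        break
      }
    }
  }
  if (is.na(left)) left <- x[1]
  if (is.na(right)) right <- x[length(y)]
  right - left
}

box_smooth_mat <- function(m, ks, kt) {
  # separable box smoothing of a space x time matrix
  if (ks > 1) m <- apply(m, 2, ma_smooth, k = ks)
  if (kt > 1) m <- t(apply(m, 1, ma_smooth, k = kt))
  m
}

#' Detect Ca2+ sparks in a normalized kymograph
#'
#' Criteria-based line-scan spark detector: the dF/F0 image is lightly
#' smoothed, thresholded at the robust baseline mean plus `criterion` baseline
#' SDs (default 3.8), and connected space-time components above the minimum
#' area become candidate sparks. Per spark: peak position/time, amplitude
#' (peak of the spatially 3-pixel-averaged raw dF/F0 profile), spatial FWHM
#' and temporal FDHM through the peak, both interpolated at half maximum
#' relative to the local baseline. Components whose spatial extent exceeds
#' `transient_fraction` of the scan line are treated as whole-cell transients
#' and excluded here.
#'
#' @param kymo a normalized [san_kymo()] (see [normalize_kymograph()]).
#' @param criterion detection threshold in baseline SDs.
#' @param min_area_px minimum component area (pixels).
#' @param transient_fraction spatial-extent fraction above which a component
#'   counts as a whole-cell transient rather than a spark.
#' @return A tibble (class `san_spark_table`): `spark_id`, `position_um`,
#'   `time_s`, `amplitude_dff`, `fwhm_um`, `fdhm_ms`, `area_px`.
#' @export
detect_sparks <- function(kymo, criterion = 3.8, min_area_px = 4,
                          transient_fraction = 0.6) {
  stopifnot(inherits(kymo, "san_kymo"))
  if (!kymo$normalized) stop("normalize the kymograph first (dF/F0 expected)")
  img <- kymo$fluor
  ns <- nrow(img); nt <- ncol(img)
  # remove the whole-cell component (Ca2+ transients span the full line,
  # sparks only a small part of it): subtract each line's spatial median so
  # sparks are measured against their local diastolic baseline
  img <- sweep(img, 2, apply(img, 2, median), "-")
  base_mean <- median(img)
  base_sd <- stats::mad(img)
  if (base_sd == 0) base_sd <- max(sd(img), 1e-12)
  thr <- base_mean + criterion * base_sd

  sm <- box_smooth_mat(img, 3L, 3L)
  # watershed on the above-threshold relief: connected regions are split at
  # intensity saddles deeper than one baseline SD, so sparks that collide in
  # space-time are still counted separately
  relief <- pmax(sm - thr, 0)
  lab <- EBImage::watershed(EBImage::Image(relief), tolerance = base_sd, ext = 1)
  lab <- as.matrix(EBImage::imageData(lab))
  nlab <- max(lab)
  empty <- tibble::tibble(
    spark_id = integer(0), position_um = numeric(0), time_s = numeric(0),
    amplitude_dff = numeric(0), fwhm_um = numeric(0), fdhm_ms = numeric(0),
    area_px = integer(0)
  )
  if (nlab == 0) return(structure(empty, class = c("san_spark_table", class(empty))))

  x_um <- (seq_len(ns) - 0.5) * kymo$pixel_um
  t_s <- (seq_len(nt) - 0.5) * kymo$line_interval_ms / 1000
  rows <- lapply(seq_len(nlab), function(l) {
    px <- which(lab == l, arr.ind = TRUE)
    if (nrow(px) < min_area_px) return(NULL)
    extent_px <- diff(range(px[, 1])) + 1
    if (extent_px > transient_fraction * ns) return(NULL)
    # peak from the smoothed image, measurements from the raw image
    vals <- sm[px]
    ipk <- which.max(vals)
    i0 <- px[ipk, 1]; j0 <- px[ipk, 2]
    si <- max(1, i0 - 1):min(ns, i0 + 1)
    t_lo <- max(1, min(px[, 2]) - 2)
    t_hi <- min(nt, max(px[, 2]) + 5)
    prof_t <- colMeans(img[si, t_lo:t_hi, drop = FALSE])
    jpk_rel <- which.max(prof_t)
    amp <- prof_t[jpk_rel]
    jpk <- t_lo + jpk_rel - 1
    s_lo <- max(1, i0 - round(4 / kymo$pixel_um))
    s_hi <- min(ns, i0 + round(4 / kymo$pixel_um))
    prof_x <- rowMeans(img[s_lo:s_hi, max(1, jpk - 1):min(nt, jpk + 1), drop = FALSE])
    fwhm <- half_max_width(x_um[s_lo:s_hi], ma_smooth(prof_x, 3), baseline = base_mean)
    fdhm <- half_max_width(t_s[t_lo:t_hi] * 1000, prof_t, baseline = base_mean)
    tibble::tibble(
      position_um = x_um[i0], time_s = t_s[jpk],
      amplitude_dff = amp - base_mean,
      fwhm_um = fwhm, fdhm_ms = fdhm, area_px = nrow(px)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(structure(empty, class = c("san_spark_table", class(empty))))
  out <- dplyr::arrange(out, .data$time_s)
  out$spark_id <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "spark_id")
  structure(out, class = unique(c("san_spark_table", class(out))))
}

#' Ca2+ spark rate in events per 100 um * s
#'
#' @param sparks a spark table (or its row count).
#' @param scan_length_um scan line length (um).
#' @param duration_s recording duration (s).
#' @return Spark rate, events / (100 um * s).
#' @export
spark_rate <- function(sparks, scan_length_um, duration_s) {
  if (scan_length_um <= 0 || duration_s <= 0) {
    stop("scan length and duration must be positive")
  }
  n <- if (is.data.frame(sparks)) nrow(sparks) else as.numeric(sparks)
  n / (scan_length_um / 100 * duration_s)
}

#' Detect whole-cell Ca2+ transients in a normalized kymograph
#'
#' The kymograph is spatially averaged into a whole-cell dF/F0 trace; peaks
#' above `amp_floor` separated by at least `min_sep_ms` are transients.
#' Per-transient amplitude and FDHM come from the averaged trace
#' (half-maximum crossings linearly interpolated); frequency is events per
#' trace duration.
#'
#' @param kymo a normalized [san_kymo()].
#' @param amp_floor minimum transient amplitude (dF/F0).
#' @param min_sep_ms minimum separation between transient peaks (ms).
#' @return A list of class `san_transient_table`: `events` tibble
#'   (`transient_id`, `time_s`, `amplitude_dff`, `fdhm_ms`), `frequency_hz`,
#'   and the averaged `trace` tibble.
#' @export
detect_transients <- function(kymo, amp_floor = 0.5, min_sep_ms = 100) {
  stopifnot(inherits(kymo, "san_kymo"))
  if (!kymo$normalized) stop("normalize the kymograph first (dF/F0 expected)")
  tl <- kymo$line_interval_ms
  y <- colMeans(kymo$fluor)
  ys <- ma_smooth(y, max(3L, round(8 / tl)))
  base <- median(ys)
  nt <- length(y)
  t_s <- (seq_len(nt) - 0.5) * tl / 1000
  sep <- max(1L, round(min_sep_ms / tl))
  # local maxima above the floor with minimum separation
  cand <- which(ys > base + amp_floor)
  cand <- cand[cand > 1 & cand < nt]
  cand <- cand[ys[cand] >= ys[cand - 1] & ys[cand] >= ys[cand + 1]]
  peaks <- integer(0)
  for (i in cand[order(-ys[cand])]) {
    if (all(abs(peaks - i) >= sep)) peaks <- c(peaks, i)
  }
  peaks <- sort(peaks)
  events <- dplyr::bind_rows(lapply(peaks, function(i) {
    lo <- max(1, i - round(1500 / tl))
    hi <- min(nt, i + round(3000 / tl))
    tibble::tibble(
      time_s = t_s[i],
      amplitude_dff = max(y[max(1, i - 1):min(nt, i + 1)]) - base,
      fdhm_ms = half_max_width(seq(lo, hi) * tl, ys[lo:hi], baseline = base)
    )
  }))
  if (nrow(events) == 0) {
    events <- tibble::tibble(time_s = numeric(0), amplitude_dff = numeric(0),
                             fdhm_ms = numeric(0))
  }
  events$transient_id <- seq_len(nrow(events))
  events <- dplyr::relocate(events, "transient_id")
  structure(
    list(
      events = events,
      frequency_hz = nrow(events) / (nt * tl / 1000),
      trace = tibble::tibble(time_s = t_s, dff = y)
    ),
    class = "san_transient_table"
  )
}

#' @export
print.san_transient_table <- function(x, ...) {
  cat(sprintf("<san_transient_table> %d transients, %.2f Hz\n",
              nrow(x$events), x$frequency_hz))
  invisible(x)
}

#' Gaussian-mixture decomposition of spark amplitudes
#'
#' Convenience wrapper around [fit_amplitude_mixture()] for a spark table:
#' decomposes the amplitude histogram into 1 or 2 Gaussian populations (two
#' spark populations are expected in both superior and inferior SAN
#' myocytes).
#'
#' @param sparks a `san_spark_table` from [detect_sparks()].
#' @inheritParams fit_amplitude_mixture
#' @return A `san_mixture`.
#' @export
spark_amplitude_mixture <- function(sparks, k_candidates = c(1, 2), seed = 1L) {
  fit_amplitude_mixture(sparks$amplitude_dff, k_candidates = k_candidates,
                        seed = seed)
}
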