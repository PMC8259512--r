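#' Align Ca2+ spark times to AP take-offs
#'
#' For each AP, collects the sparks falling in the pre-AP window
#' `(takeoff - window_ms, takeoff]`, truncated at the preceding AP's
#' take-off, and expresses their times relative to the AP (<= 0).
#'
#' @param ap_times_s AP take-off times (s), e.g. `takeoff_time_s` from
#'   [detect_aps()].
#' @param spark_times_s spark times (s), e.g. `time_s` from [detect_sparks()].
#' @param window_ms maximum pre-AP window (default 300 ms, spanning typical
#'   SAN diastolic durations).
#' @return A tibble (class `san_aligned_sparks`): `ap_id`, `ap_time_s`,
#'   `spark_time_s`, `rel_ms` (<= 0); zero rows when there are no APs or no
#'   sparks in any window. The AP count is kept as attribute `n_aps`.
#' @export
align_sparks_to_aps <- function(ap_times_s, spark_times_s, window_ms = 300) {
  ap_times_s <- sort(as.numeric(ap_times_s))
  spark_times_s <- as.numeric(spark_times_s)
  rows <- lapply(seq_along(ap_times_s), function(k) {
    tk <- ap_times_s[k]
    w0 <- tk - window_ms / 1000
    if (k > 1) w0 <- max(w0, ap_times_s[k - 1])
    hit <- spark_times_s[spark_times_s > w0 & spark_times_s <= tk]
    if (length(hit) == 0) return(NULL)
    tibble::tibble(
      ap_id = k, ap_time_s = tk, spark_time_s = hit,
      rel_ms = (hit - tk) * 1000
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(ap_id = integer(0), ap_time_s = numeric(0),
                          spark_time_s = numeric(0), rel_ms = numeric(0))
  }
  attr(out, "n_aps") <- length(ap_times_s)
  attr(out, "window_ms") <- window_ms
  structure(out, class = unique(c("san_aligned_sparks", class(out))))
}

#' Ca2+ sparks per AP
#'
#' @param aligned output of [align_sparks_to_aps()].
#' @param n_aps number of APs; defaults to the attribute carried by
#'   `aligned` (APs without sparks count as zero).
#' @return A list: `counts` tibble (`ap_id`, `n_sparks`), `mean`, `sd`, `n_aps`.
#' @export
sparks_per_ap <- function(aligned, n_aps = NULL) {
  n_aps <- n_aps %||% attr(aligned, "n_aps")
  if (is.null(n_aps) || n_aps < 1) stop("need at least one AP")
  counts <- tibble::tibble(ap_id = seq_len(n_aps), n_sparks = 0L)
  if (nrow(aligned) > 0) {
    tab <- dplyr::count(aligned, .data$ap_id, name = "n")
    counts$n_sparks[tab$ap_id] <- tab$n
  }
  list(
    counts = counts,
    mean = mean(counts$n_sparks),
    sd = sd(counts$n_sparks),
    n_aps = n_aps
  )
}

#' Slope of the pre-AP spark-probability histogram
#'
#' Bins the aligned pre-AP spark times into `n_bins` equal bins across the
#' window, normalizes to probability per bin, and fits a least-squares line
#' against bin index running toward the AP. A positive slope (probability per
#' bin per bin) means sparks accumulate as the AP approaches.
#'
#' @param aligned output of [align_sparks_to_aps()].
#' @param n_bins number of histogram bins.
#' @param min_sparks fewer aligned sparks than this flags the estimate.
#' @return A list of class `san_preap_slope`: `histogram` tibble (`bin`,
#'   `rel_ms_center`, `probability`), `slope`, `std_error`, `p_value`,
#'   `n_sparks`, `flagged`.
#' @export
pre_ap_slope <- function(aligned, n_bins = 10, min_sparks = 20) {
  window_ms <- attr(aligned, "window_ms") %||% max(-aligned$rel_ms, 300)
  n <- nrow(aligned)
  edges <- seq(-window_ms, 0, length.out = n_bins + 1)
  bin <- cut(aligned$rel_ms, breaks = edges, include.lowest = TRUE,
             labels = FALSE)
  counts <- tabulate(bin, nbins = n_bins)
  prob <- if (n > 0) counts / n else rep(NA_real_, n_bins)
  hist <- tibble::tibble(
    bin = seq_len(n_bins),
    rel_ms_center = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    probability = prob
  )
  flagged <- n < min_sparks
  slope <- se <- p <- NA_real_
  if (!flagged) {
    fit <- lm(probability ~ bin, data = hist)
    cf <- summary(fit)$coefficients
    slope <- cf["bin", "Estimate"]
    se <- cf["bin", "Std. Error"]
    p <- cf["bin", "Pr(>|t|)"]
  }
  structure(
    list(histogram = hist, slope = slope, std_error = se, p_value = p,
         n_sparks = n, flagged = flagged),
    class = "san_preap_slope"
  )
}

#' @export
print.san_preap_slope <- function(x, ...) {
  cat(sprintf(
    "<san_preap_slope> slope %.4g prob/bin/bin (SE %.3g, p %.3g, %d sparks%s)\n",
    x$slope, x$std_error, x$p_value, x$n_sparks,
    if (x$flagged) ", flagged: too few sparks" else ""
  ))
  invisible(x)
}

#' Per-spark membrane-potential deflection and amplitude correlation
#'
#' For each diastolic spark, the voltage deflection is the mean membrane
#' potential in the `window_ms` after the spark peak minus the mean in the
#' `window_ms` before its onset; sparks whose windows run off the trace or
#' overlap an AP upstroke are excluded. The association between spark
#' amplitude and deflection is summarized by Pearson r, r^2, adjusted r^2
#' and the correlation-test p-value.
#'
#' @param trace a [san_trace()].
#' @param sparks a spark table with `time_s` and `amplitude_dff`.
#' @param ap_times_s optional AP take-off times; sparks within
#'   `(takeoff - 20 ms, takeoff + 150 ms)` are excluded as AP-contaminated.
#' @param window_ms averaging window on each side of the spark (default 20).
#' @return A list of class `san_spark_coupling`: `per_spark` tibble
#'   (`spark_id`, `time_s`, `amplitude_dff`, `delta_v_mv`), `r`, `r_squared`,
#'   `adj_r_squared`, `p_value`, `n`, `n_excluded`, `flagged` (TRUE when the
#'   correlation is undefined, e.g. flat voltage).
#' @export
spark_voltage_coupling <- function(trace, sparks, ap_times_s = NULL,
                                   window_ms = 20) {
  fs <- trace_rate(trace)
  v <- trace$mv
  n <- length(v)
  w <- round(window_ms / 1000 * fs)
  rows <- lapply(seq_len(nrow(sparks)), function(i) {
    t0 <- sparks$time_s[i]
    c0 <- round(t0 * fs) + 1
    if (c0 - w < 1 || c0 + w > n) return(NULL)           # trace edge
    if (!is.null(ap_times_s) &&
        any(t0 > ap_times_s - 0.02 & t0 < ap_times_s + 0.15)) {
      return(NULL)                                        # AP overlap
    }
    tibble::tibble(
      spark_id = sparks$spark_id[i] %||% i,
      time_s = t0,
      amplitude_dff = sparks$amplitude_dff[i],
      delta_v_mv = mean(v[(c0 + 1):(c0 + w)]) - mean(v[(c0 - w):(c0 - 1)])
    )
  })
  per_spark <- dplyr::bind_rows(rows)
  n_used <- nrow(per_spark)
  flagged <- n_used < 3 || sd(per_spark$delta_v_mv) == 0 ||
    sd(per_spark$amplitude_dff) == 0
  r <- r2 <- adj <- p <- NA_real_
  if (!flagged) {
    ct <- cor.test(per_spark$amplitude_dff, per_spark$delta_v_mv)
    r <- unname(ct$estimate)
    r2 <- r^2
    adj <- 1 - (1 - r2) * (n_used - 1) / (n_used - 2)
    p <- ct$p.value
  }
  structure(
    list(per_spark = per_spark, r = r, r_squared = r2, adj_r_squared = adj,
         p_value = p, n = n_used,
         n_excluded = nrow(sparks) - n_used, flagged = flagged),
    class = "san_spark_coupling"
  )
}

#' @export
print.san_spark_coupling <- function(x, ...) {
  cat(sprintf(
    "<san_spark_coupling> n = %d sparks, r = %.3f, r^2 = %.3f, p = %.3g%s\n",
    x$n, x$r, x$r_squared, x$p_value,
    if (x$flagged) " (flagged: correlation undefined)" else ""
  ))
  invisible(x)
}
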