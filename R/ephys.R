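ma_smooth <- function(x, k) {
  if (k <= 1) return(x)
  kern <- rep(1 / k, k)
  y <- stats::filter(x, kern, sides = 2)
  y <- as.numeric(y)
  # fill the ends with the nearest defined value
  nas <- which(is.na(y))
  if (length(nas)) {
    first_ok <- which(!is.na(y))[1]
    last_ok <- max(which(!is.na(y)))
    y[nas[nas < first_ok]] <- y[first_ok]
    y[nas[nas > last_ok]] <- y[last_ok]
  }
  y
}

# smoothed first derivative in mV/ms (central difference after a 0.5 ms
# moving-average smooth)
trace_dvdt <- function(v, fs, smooth_ms = 0.5) {
  k <- max(1L, round(smooth_ms / 1000 * fs))
  vs <- ma_smooth(v, k)
  dv <- c(NA, (vs[-(1:2)] - vs[1:(length(vs) - 2)]) / 2, NA)
  dv <- dv * fs / 1000  # mV per ms
  dv[1] <- dv[2]
  dv[length(dv)] <- dv[length(dv) - 1]
  dv
}

#' Detect action potentials in a membrane-potential trace
#'
#' Candidate upstrokes are upward crossings of the AP threshold (default
#' -29 mV) separated by a refractory gap; each candidate must reach a maximum
#' upstroke velocity of at least `min_dvdt` (mV/ms) and a peak above
#' `min_peak_mv`, which excludes large subthreshold fluctuations. The AP time
#' is the take-off: the last sample before the upstroke at which the smoothed
#' dV/dt first reaches 10% of that AP's maximum dV/dt.
#'
#' @param trace a [san_trace()].
#' @param ap_threshold_mv membrane potential that APs must cross (mV).
#' @param min_dvdt minimum phase-0 dV/dt (mV/ms) for an AP candidate.
#' @param min_peak_mv minimum AP peak (mV).
#' @param refractory_ms minimum separation between threshold crossings (ms).
#' @return A tibble (class `san_ap_table`) with one row per AP: `ap_id`,
#'   `takeoff_time_s`, `takeoff_mv`, `peak_time_s`, `peak_mv`,
#'   `max_dvdt_mv_ms`. Empty when no APs are found.
#' @export
detect_aps <- function(trace, ap_threshold_mv = -29, min_dvdt = 1,
                       min_peak_mv = -20, refractory_ms = 50) {
  fs <- trace_rate(trace)
  v <- trace$mv
  n <- length(v)
  if (n < 0.5 * fs) stop("need at least 0.5 s of data")
  dv <- trace_dvdt(v, fs)
  empty <- tibble::tibble(
    ap_id = integer(0), takeoff_time_s = numeric(0), takeoff_mv = numeric(0),
    peak_time_s = numeric(0), peak_mv = numeric(0), max_dvdt_mv_ms = numeric(0)
  )
  up <- which(v[-1] >= ap_threshold_mv & v[-n] < ap_threshold_mv)
  if (length(up) == 0) return(structure(empty, class = c("san_ap_table", class(empty))))
  # hysteresis: a crossing only counts once the trace has been at least
  # 2 mV below threshold since the last accepted crossing, so noise jitter
  # around a slow repolarization cannot spawn spurious candidates
  gap <- round(refractory_ms / 1000 * fs)
  kept <- integer(0)
  last <- 1L
  for (i in up) {
    if (length(kept) > 0 && (i - kept[length(kept)]) <= gap) next
    if (min(v[last:i]) > ap_threshold_mv - 2) next
    kept <- c(kept, i)
    last <- i
  }
  up <- kept
  if (length(up) == 0) return(structure(empty, class = c("san_ap_table", class(empty))))

  rows <- lapply(up, function(i) {
    w0 <- max(1, i - round(0.01 * fs))
    w1 <- min(n, i + round(0.01 * fs))
    imax <- w0 - 1 + which.max(dv[w0:w1])
    max_dvdt <- dv[imax]
    if (is.na(max_dvdt) || max_dvdt < min_dvdt) return(NULL)
    p1 <- min(n, i + round(0.03 * fs))
    ipk <- i - 1 + which.max(v[i:p1])
    if (v[ipk] < min_peak_mv) return(NULL)
    # take-off: walk back from the dV/dt maximum to the last sample below
    # 10% of this AP's maximum dV/dt
    thr <- 0.1 * max_dvdt
    j <- imax
    lim <- max(1, imax - round(0.02 * fs))
    while (j > lim && !is.na(dv[j - 1]) && dv[j - 1] >= thr) j <- j - 1
    tibble::tibble(
      takeoff_time_s = (j - 1) / fs, takeoff_mv = v[j],
      peak_time_s = (ipk - 1) / fs, peak_mv = v[ipk],
      max_dvdt_mv_ms = max_dvdt
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(structure(empty, class = c("san_ap_table", class(empty))))
  out <- dplyr::arrange(out, .data$takeoff_time_s)
  out$ap_id <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "ap_id")
  structure(out, class = c("san_ap_table", class(out)))
}

#' Full per-AP waveform features
#'
#' For each detected AP: the maximum diastolic potential (MDP, most negative
#' potential since the previous AP), diastolic duration (MDP to take-off),
#' early diastolic duration (10% to 50% of the diastolic interval), EDD rate
#' (least-squares slope over that window, mV/s), APD90 (take-off until
#' repolarization to 90% of the take-off-to-peak amplitude below the peak)
#' and maximum dV/dt. Features that would require data beyond the trace edge
#' are `NA` rather than extrapolated.
#'
#' @param trace a [san_trace()].
#' @param aps output of [detect_aps()] (recomputed when omitted).
#' @inheritParams detect_aps
#' @return The AP tibble with added columns `mdp_mv`, `mdp_time_s`,
#'   `diastolic_ms`, `edd_ms`, `edd_rate_mv_s`, `apd90_ms`.
#' @export
ap_features <- function(trace, aps = NULL, ap_threshold_mv = -29) {
  if (is.null(aps)) aps <- detect_aps(trace, ap_threshold_mv = ap_threshold_mv)
  fs <- trace_rate(trace)
  v <- trace$mv
  n <- length(v)
  k <- nrow(aps)
  mdp_mv <- mdp_time <- dia <- edd <- edd_rate <- apd90 <- rep(NA_real_, k)
  if (k == 0) {
    out <- dplyr::mutate(aps, mdp_mv = numeric(0), mdp_time_s = numeric(0),
                         diastolic_ms = numeric(0), edd_ms = numeric(0),
                         edd_rate_mv_s = numeric(0), apd90_ms = numeric(0))
    return(structure(out, class = unique(c("san_ap_table", class(out)))))
  }
  tko_i <- round(aps$takeoff_time_s * fs) + 1
  pk_i <- round(aps$peak_time_s * fs) + 1
  # locate the MDP on a lightly smoothed trace: the raw minimum jitters by
  # noise/|slope| around the repolarization-diastole junction, which would
  # leak repolarization samples into the early-diastolic window
  v_sm <- ma_smooth(v, max(1L, round(0.002 * fs)))
  for (j in seq_len(k)) {
    # MDP and diastolic features need the preceding AP's repolarization
    if (j > 1) {
      a <- pk_i[j - 1] + round(0.005 * fs)
      b <- tko_i[j]
      if (b - a > 4) {
        imin <- a - 1 + which.min(v_sm[a:b])
        mdp_mv[j] <- v[imin]
        mdp_time[j] <- (imin - 1) / fs
        dd_s <- aps$takeoff_time_s[j] - mdp_time[j]
        dia[j] <- dd_s * 1000
        e0 <- imin + round(0.1 * dd_s * fs)
        e1 <- imin + round(0.5 * dd_s * fs)
        if (e1 - e0 >= 4) {
          tt <- (seq(e0, e1) - 1) / fs
          fit <- lm(v[e0:e1] ~ tt)
          edd_rate[j] <- unname(coef(fit)[2])
          edd[j] <- (0.5 - 0.1) * dd_s * 1000
        }
      }
    }
    # APD90 needs the repolarization to stay within the trace
    v90 <- aps$peak_mv[j] - 0.9 * (aps$peak_mv[j] - aps$takeoff_mv[j])
    lim <- min(n, pk_i[j] + round(0.5 * fs))
    if (j < k) lim <- min(lim, tko_i[j + 1])
    seg <- v[pk_i[j]:lim]
    hit <- which(seg <= v90)[1]
    if (!is.na(hit)) {
      apd90[j] <- ((pk_i[j] + hit - 1 - tko_i[j]) / fs) * 1000
    }
  }
  out <- dplyr::mutate(aps, mdp_mv = mdp_mv, mdp_time_s = mdp_time,
                       diastolic_ms = dia, edd_ms = edd,
                       edd_rate_mv_s = edd_rate, apd90_ms = apd90)
  structure(out, class = unique(c("san_ap_table", class(out))))
}

#' Inter-event interval statistics
#'
#' @param event_times event times in seconds (APs or subthreshold events).
#' @param frequency_mode `"span"` (default): frequency = (n-1)/(last-first);
#'   `"duration"`: n/`duration_s`.
#' @param duration_s trace duration, only used for `frequency_mode =
#'   "duration"`.
#' @return A `san_interval_stats` object: inter-event intervals (ms), sample
#'   mean/SD, CV = SD/mean, event frequency (Hz) and the joint-interval pairs
#'   (each interval against the next). Use [tidy()] for the intervals and
#'   [glance()] for the summary. With fewer than 2 events the frequency is
#'   `NA` and flagged; CV needs at least 3 events.
#' @export
interval_stats <- function(event_times, frequency_mode = c("span", "duration"),
                           duration_s = NULL) {
  frequency_mode <- match.arg(frequency_mode)
  t <- sort(as.numeric(event_times))
  n <- length(t)
  isi <- diff(t) * 1000
  freq <- if (frequency_mode == "duration") {
    if (is.null(duration_s)) stop("duration_s required for frequency_mode = 'duration'")
    n / duration_s
  } else if (n >= 2) {
    (n - 1) / (t[n] - t[1])
  } else {
    NA_real_
  }
  joint <- if (length(isi) >= 2) {
    tibble::tibble(isi_ms = isi[-length(isi)], next_isi_ms = isi[-1])
  } else {
    tibble::tibble(isi_ms = numeric(0), next_isi_ms = numeric(0))
  }
  structure(
    list(
      n_events = n,
      intervals_ms = isi,
      mean_ms = if (length(isi)) mean(isi) else NA_real_,
      sd_ms = if (length(isi) >= 2) sd(isi) else NA_real_,
      cv = if (n >= 3) sd(isi) / mean(isi) else NA_real_,
      frequency_hz = freq,
      frequency_flagged = n < 2,
      joint = joint
    ),
    class = "san_interval_stats"
  )
}

#' @export
print.san_interval_stats <- function(x, ...) {
  cat(sprintf(
    "<san_interval_stats> %d events, mean ISI %.1f ms, CV %.3f, %.2f Hz\n",
    x$n_events, x$mean_ms, x$cv, x$frequency_hz
  ))
  invisible(x)
}

#' @export
tidy.san_interval_stats <- function(x, ...) {
  tibble::tibble(interval = seq_along(x$intervals_ms), isi_ms = x$intervals_ms)
}

#' @export
glance.san_interval_stats <- function(x, ...) {
  tibble::tibble(
    n_events = x$n_events, mean_ms = x$mean_ms, sd_ms = x$sd_ms,
    cv = x$cv, frequency_hz = x$frequency_hz
  )
}

#' Classify the firing modality of a recording
#'
#' `"silent"` when there are neither APs nor subthreshold events,
#' `"subthreshold_only"` when only subthreshold events occur, then for firing
#' cells: `"tonic"` when the ISI coefficient of variation is below `cv_tonic`;
#' otherwise `"burst"` when the ISI distribution is strongly bimodal — the
#' ratio of the upper ISI mode (95th percentile) to the median exceeds
#' `burst_mode_ratio`, the signature of silences alternating with
#' high-frequency clusters — and `"irregular"` otherwise.
#'
#' @param aps AP table from [detect_aps()].
#' @param subthreshold events from [detect_subthreshold()] (may be empty).
#' @param stats optional precomputed [interval_stats()] of the AP times.
#' @param cv_tonic CV below which firing counts as tonic.
#' @param burst_mode_ratio upper-mode/median ISI ratio above which firing
#'   counts as bursting.
#' @return One of `"silent"`, `"subthreshold_only"`, `"tonic"`,
#'   `"irregular"`, `"burst"`.
#' @export
classify_modality <- function(aps, subthreshold = NULL, stats = NULL,
                              cv_tonic = 0.7, burst_mode_ratio = 6) {
  n_aps <- if (is.null(aps)) 0L else nrow(aps)
  n_sub <- if (is.null(subthreshold)) 0L else nrow(subthreshold)
  if (n_aps == 0 && n_sub == 0) return("silent")
  if (n_aps == 0) return("subthreshold_only")
  if (n_aps < 4) return("irregular")  # too few APs to assess periodicity
  if (is.null(stats)) stats <- interval_stats(aps$takeoff_time_s)
  if (!is.na(stats$cv) && stats$cv < cv_tonic) return("tonic")
  isi <- stats$intervals_ms
  ratio <- quantile(isi, 0.95, names = FALSE) / median(isi)
  if (is.finite(ratio) && ratio > burst_mode_ratio) "burst" else "irregular"
}

#' Detect subthreshold voltage fluctuations
#'
#' A subthreshold event is a depolarization whose amplitude exceeds the
#' baseline mean by more than 3 baseline standard deviations, lasts at least
#' 1 ms (measured at the 3-SD crossing level), and whose absolute peak stays
#' below the AP threshold (default -29 mV). The baseline is estimated from
#' the longest AP-free stretch (robustly, via median and MAD, so sparse
#' events do not inflate the baseline SD); AP windows are excluded from the
#' search.
#'
#' @param trace a [san_trace()].
#' @param aps AP table from [detect_aps()]; detected internally when `NULL`.
#' @param ap_threshold_mv AP take-off threshold (mV).
#' @param n_sd amplitude criterion in baseline SDs.
#' @param min_duration_ms minimum event duration (ms).
#' @param min_baseline_ms minimum usable baseline window (ms).
#' @return A tibble (class `san_subthreshold`) with `event_id`,
#'   `onset_time_s`, `peak_time_s`, `amplitude_mv` (above baseline mean),
#'   `duration_ms`, `peak_abs_mv`.
#' @export
detect_subthreshold <- function(trace, aps = NULL, ap_threshold_mv = -29,
                                n_sd = 3, min_duration_ms = 1,
                                min_baseline_ms = 200) {
  fs <- trace_rate(trace)
  v <- trace$mv
  n <- length(v)
  if (n < min_baseline_ms / 1000 * fs) {
    stop("trace shorter than the minimum baseline window")
  }
  if (is.null(aps)) aps <- detect_aps(trace, ap_threshold_mv = ap_threshold_mv)

  # mask out AP cycles (take-off - 10 ms to take-off + 150 ms)
  usable <- rep(TRUE, n)
  if (nrow(aps) > 0) {
    for (tk in aps$takeoff_time_s) {
      a <- max(1, round((tk - 0.01) * fs))
      b <- min(n, round((tk + 0.15) * fs))
      usable[a:b] <- FALSE
    }
  }
  # longest AP-free run defines the baseline
  r <- rle(usable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  free <- which(r$values)
  if (length(free) == 0) stop("no AP-free segment to estimate the baseline")
  best <- free[which.max(r$lengths[free])]
  if (r$lengths[best] < min_baseline_ms / 1000 * fs) {
    stop("longest AP-free segment is shorter than the baseline window")
  }
  base_seg <- v[starts[best]:ends[best]]
  base_mean <- median(base_seg)
  base_sd <- stats::mad(base_seg)
  thr <- base_mean + n_sd * base_sd

  # find above-threshold runs on a lightly smoothed copy (noise on a slow
  # event would otherwise split one fluctuation into several), then merge
  # runs separated by sub-threshold gaps shorter than 3 ms
  v_det <- ma_smooth(v, max(1L, round(0.001 * fs)))
  above <- v_det > thr & usable
  gap_max <- round(0.003 * fs)
  r_gap <- rle(above)
  if (length(r_gap$lengths) > 2) {
    short_gap <- !r_gap$values & r_gap$lengths <= gap_max
    short_gap[1] <- FALSE
    short_gap[length(short_gap)] <- FALSE
    r_gap$values[short_gap] <- TRUE
    above <- inverse.rle(r_gap)
  }
  r2 <- rle(above)
  e2 <- cumsum(r2$lengths)
  s2 <- e2 - r2$lengths + 1
  runs <- which(r2$values)
  rows <- lapply(runs, function(i) {
    a <- s2[i]; b <- e2[i]
    if ((b - a + 1) < min_duration_ms / 1000 * fs) return(NULL)
    ipk <- a - 1 + which.max(v[a:b])
    if (v[ipk] >= ap_threshold_mv) return(NULL)  # too depolarized: not subthreshold
    tibble::tibble(
      onset_time_s = (a - 1) / fs,
      peak_time_s = (ipk - 1) / fs,
      amplitude_mv = v[ipk] - base_mean,
      duration_ms = (b - a + 1) / fs * 1000,
      peak_abs_mv = v[ipk]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      onset_time_s = numeric(0), peak_time_s = numeric(0),
      amplitude_mv = numeric(0), duration_ms = numeric(0),
      peak_abs_mv = numeric(0)
    )
  }
  out$event_id <- seq_len(nrow(out))
  out <- dplyr::relocate(out, "event_id")
  attr(out, "baseline_mean_mv") <- base_mean
  attr(out, "baseline_sd_mv") <- base_sd
  structure(out, class = unique(c("san_subthreshold", class(out))))
}

#' Fit a 1- or 2-component Gaussian mixture to event amplitudes
#'
#' Maximum-likelihood decomposition of an amplitude histogram into Gaussian
#' components (EM with seeded restarts); the number of components is chosen
#' by BIC over `k_candidates`. Superior-cell subthreshold amplitudes are
#' expected to need two components, inferior-cell amplitudes one.
#'
#' @param amplitudes numeric event amplitudes (mV or dF/F0).
#' @param k_candidates component counts to compare.
#' @param seed seed for the EM restarts.
#' @return A `san_mixture` (see [fit_gaussian_mixture()]) with the selected
#'   `k`, components sorted by center, and BIC per candidate.
#' @export
fit_amplitude_mixture <- function(amplitudes, k_candidates = c(1, 2),
                                  seed = 1L) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (length(amplitudes) < 30) stop("need at least 30 amplitudes")
  fits <- lapply(k_candidates, function(k) {
    fit_gaussian_mixture(amplitudes, k = k, seed = seed)
  })
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  best <- if (all(is.na(bics))) fits[[1]] else fits[[which.min(bics)]]
  best$bic_by_k <- setNames(bics, paste0("k", k_candidates))
  best$k_candidates <- k_candidates
  best
}

#' Compare event statistics between two recording conditions
#'
#' Pairs per-cell summaries from two conditions (e.g. control vs
#' SR Ca2+-pump inhibition), computes per-cell deltas of every shared numeric
#' metric and a paired group test per metric (Student's t when the deltas
#' pass Shapiro-Wilk normality, Wilcoxon otherwise).
#'
#' @param before,after tibbles with a `cell` column and numeric metric
#'   columns (e.g. `ap_frequency_hz`, `event_frequency_hz`,
#'   `resting_potential_mv`).
#' @return A list: `deltas` (per-cell after - before) and `tests` (one row
#'   per metric: mean delta, test used, statistic, p-value, significance).
#' @export
compare_conditions <- function(before, after) {
  if (!"cell" %in% names(before) || !"cell" %in% names(after)) {
    stop("both tables need a 'cell' column")
  }
  if (!setequal(before$cell, after$cell)) {
    stop("conditions cover different cells; they must be paired")
  }
  metrics <- intersect(
    names(before)[vapply(before, is.numeric, logical(1))],
    names(after)[vapply(after, is.numeric, logical(1))]
  )
  b <- dplyr::arrange(before, .data$cell)
  a <- dplyr::arrange(after, .data$cell)
  deltas <- tibble::tibble(cell = b$cell)
  for (m in metrics) deltas[[m]] <- a[[m]] - b[[m]]
  tests <- dplyr::bind_rows(lapply(metrics, function(m) {
    res <- group_compare(a[[m]], b[[m]], paired = TRUE)
    dplyr::mutate(res, metric = m, mean_delta = mean(deltas[[m]], na.rm = TRUE),
                  .before = 1)
  }))
  list(deltas = deltas, tests = tests)
}
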