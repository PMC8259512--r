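#' Two-channel labelled SAN volume
#'
#' Container for a dual-channel 3D image volume: a myocyte (HCN4+) channel and
#' an endothelial/vessel (CD31+) channel on the same voxel grid. Axis order is
#' `(z, row, col)` with the node axis along `row`; the superior end of the node
#' is at row 1. Voxel spacing is given per axis in micrometres.
#'
#' @param myocyte,vessel numeric or logical 3D arrays of identical dimension.
#' @param voxel_size_um length-3 numeric, micrometres per voxel along
#'   `(z, row, col)`.
#' @return An object of class `san_volume`: a list with elements `myocyte`,
#'   `vessel` and `voxel_size_um`.
#' @export
san_volume <- function(myocyte, vessel, voxel_size_um = c(1, 1, 1)) {
  myocyte <- as.array(myocyte)
  vessel <- as.array(vessel)
  if (!identical(dim(myocyte), dim(vessel))) {
    stop("myocyte and vessel channels must have identical dimensions")
  }
  if (length(dim(myocyte)) != 3L) stop("channels must be 3D arrays")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(voxel_size_um <= 0)) {
    stop("voxel_size_um must be 3 positive values (z, row, col)")
  }
  structure(
    list(myocyte = myocyte, vessel = vessel, voxel_size_um = voxel_size_um),
    class = "san_volume"
  )
}

#' @export
print.san_volume <- function(x, ...) {
  d <- dim(x$myocyte)
  cat(sprintf(
    "<san_volume> %d x %d x %d voxels (z, row, col), voxel %s um\n",
    d[1], d[2], d[3], paste(signif(x$voxel_size_um, 3), collapse = " x ")
  ))
  invisible(x)
}

#' Binary mask with voxel metadata
#'
#' @param data logical 3D array.
#' @param voxel_size_um micrometres per voxel along `(z, row, col)`.
#' @param channel,method,value provenance: source channel name, thresholding
#'   method and the threshold that was applied.
#' @return Object of class `san_mask`: the logical array with attributes
#'   `voxel_size_um` and `provenance`.
#' @export
san_mask <- function(data, voxel_size_um, channel = NA_character_,
                     method = NA_character_, value = NA_real_) {
  data <- as.array(data)
  storage.mode(data) <- "logical"
  structure(
    data,
    voxel_size_um = as.numeric(voxel_size_um),
    provenance = list(channel = channel, method = method, value = value),
    class = c("san_mask", "array")
  )
}

#' @export
print.san_mask <- function(x, ...) {
  d <- dim(x)
  p <- attr(x, "provenance")
  cat(sprintf(
    "<san_mask> %d x %d x %d, %d foreground voxels (%s threshold on %s)\n",
    d[1], d[2], d[3], sum(x), p$method, p$channel
  ))
  invisible(x)
}

#' Membrane-potential trace
#'
#' A uniformly sampled current-clamp recording held as a tibble with columns
#' `time_s` and `mv`, carrying the sampling rate as an attribute.
#'
#' @param mv numeric vector of membrane potential samples (mV).
#' @param sample_rate_hz sampling rate (default 10 kHz).
#' @param condition optional condition label (e.g. "control").
#' @return A tibble of class `san_trace` with columns `time_s`, `mv`.
#' @export
san_trace <- function(mv, sample_rate_hz = 10000, condition = NA_character_) {
  if (sample_rate_hz <= 0) stop("sample_rate_hz must be positive")
  out <- tibble::tibble(
    time_s = (seq_along(mv) - 1) / sample_rate_hz,
    mv = as.numeric(mv)
  )
  attr(out, "sample_rate_hz") <- sample_rate_hz
  attr(out, "condition") <- condition
  class(out) <- c("san_trace", class(out))
  out
}

#' Sampling rate of a trace
#' @param trace a [san_trace()] (or tibble with a `time_s` column).
#' @return Sampling rate in Hz.
#' @export
trace_rate <- function(trace) {
  r <- attr(trace, "sample_rate_hz")
  if (!is.null(r)) return(r)
  dt <- median(diff(trace$time_s))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from time_s")
  1 / dt
}

#' Line-scan kymograph
#'
#' Space-by-time fluorescence image from repeated confocal line scanning of a
#' single cell. Rows index position along the scan line, columns index time.
#'
#' @param fluor numeric matrix, space pixels x time lines.
#' @param pixel_um spatial pixel size (um).
#' @param line_interval_ms time between successive lines (ms).
#' @param normalized logical; `TRUE` once values are dF/F0 rather than raw
#'   fluorescence.
#' @return Object of class `san_kymo`.
#' @export
san_kymo <- function(fluor, pixel_um, line_interval_ms, normalized = FALSE) {
  fluor <- as.matrix(fluor)
  if (pixel_um <= 0 || line_interval_ms <= 0) {
    stop("pixel_um and line_interval_ms must be positive")
  }
  structure(
    list(
      fluor = fluor, pixel_um = pixel_um,
      line_interval_ms = line_interval_ms, normalized = normalized
    ),
    class = "san_kymo"
  )
}

#' @export
print.san_kymo <- function(x, ...) {
  cat(sprintf(
    "<san_kymo> %d px x %d lines (%.1f um x %.2f s), %s\n",
    nrow(x$fluor), ncol(x$fluor),
    nrow(x$fluor) * x$pixel_um,
    ncol(x$fluor) * x$line_interval_ms / 1000,
    if (x$normalized) "dF/F0" else "raw fluorescence"
  ))
  invisible(x)
}

#' Scan length and duration of a kymograph
#' @param kymo a [san_kymo()].
#' @return Named numeric: `scan_length_um`, `duration_s`.
#' @export
kymo_extent <- function(kymo) {
  c(
    scan_length_um = nrow(kymo$fluor) * kymo$pixel_um,
    duration_s = ncol(kymo$fluor) * kymo$line_interval_ms / 1000
  )
}

#' Paired voltage + Ca2+ recording
#'
#' @param trace a [san_trace()].
#' @param kymo a [san_kymo()] on the same time base.
#' @param offset_s time of the first scan line on the trace clock.
#' @return Object of class `san_paired`.
#' @export
san_paired <- function(trace, kymo, offset_s = 0) {
  dur_t <- nrow(trace) / trace_rate(trace)
  dur_k <- unname(kymo_extent(kymo)["duration_s"])
  overlap <- min(dur_t, offset_s + dur_k) - max(0, offset_s)
  if (overlap <= 1) stop("overlapping time span of trace and kymograph must exceed 1 s")
  structure(
    list(trace = trace, kymo = kymo, offset_s = offset_s),
    class = "san_paired"
  )
}

# internal: deterministic child seed derived from a parent seed
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 69069 + as.numeric(stream) * 1013) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
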