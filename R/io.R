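#' Write / read a two-channel volume as multi-page TIFF + JSON sidecar
#'
#' Pages hold all z-planes of the myocyte channel followed by all z-planes of
#' the vessel channel; the sidecar records shape, channel order, voxel size
#' and the intensity scale used to fit the data into the TIFF range.
#'
#' @param volume a [san_volume()].
#' @param tif_path,json_path output paths (the JSON defaults to the TIFF path
#'   with extension `.json`).
#' @return `io_write_volume()` returns the paths invisibly; `io_read_volume()`
#'   returns a [san_volume()].
#' @export
io_write_volume <- function(volume, tif_path,
                            json_path = sub("\\.tiff?$", ".json", tif_path)) {
  stopifnot(inherits(volume, "san_volume"))
  d <- dim(volume$myocyte)
  scale <- max(volume$myocyte, volume$vessel, 1)
  pages <- c(
    lapply(seq_len(d[1]), function(z) volume$myocyte[z, , ] / scale),
    lapply(seq_len(d[1]), function(z) volume$vessel[z, , ] / scale)
  )
  tiff::writeTIFF(pages, tif_path, bits.per.sample = 32L)
  meta <- list(
    shape = d, channels = c("myocyte", "vessel"),
    voxel_size_um = volume$voxel_size_um, intensity_scale = scale
  )
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tif = tif_path, json = json_path))
}

#' @rdname io_write_volume
#' @export
io_read_volume <- function(tif_path,
                           json_path = sub("\\.tiff?$", ".json", tif_path)) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  for (field in c("shape", "voxel_size_um", "channels")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("volume metadata is missing the '%s' field", field))
    }
  }
  pages <- tiff::readTIFF(tif_path, all = TRUE)
  d <- as.integer(meta$shape)
  scale <- meta$intensity_scale %||% 1
  to_array <- function(pp) {
    a <- array(0, d)
    for (z in seq_len(d[1])) a[z, , ] <- pp[[z]] * scale
    a
  }
  san_volume(to_array(pages[seq_len(d[1])]),
             to_array(pages[d[1] + seq_len(d[1])]),
             as.numeric(meta$voxel_size_um))
}

#' Write / read a membrane-potential trace as CSV
#'
#' Two columns, `time_s` and `mv`; the sampling rate is recovered from the
#' time column on read.
#'
#' @param trace a [san_trace()].
#' @param path CSV path.
#' @return `io_read_trace()` returns a [san_trace()].
#' @export
io_write_trace <- function(trace, path) {
  write.csv(as.data.frame(trace[c("time_s", "mv")]), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_write_trace
#' @export
io_read_trace <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_s", "mv") %in% names(df))) {
    stop("trace CSV must have columns 'time_s' and 'mv'")
  }
  dt <- median(diff(df$time_s))
  san_trace(df$mv, sample_rate_hz = 1 / dt)
}

#' Write / read a kymograph as TIFF + JSON sidecar
#'
#' @param kymo a [san_kymo()].
#' @param tif_path,json_path output paths.
#' @return `io_read_kymo()` returns a [san_kymo()].
#' @export
io_write_kymo <- function(kymo, tif_path,
                          json_path = sub("\\.tiff?$", ".json", tif_path)) {
  stopifnot(inherits(kymo, "san_kymo"))
  lo <- min(kymo$fluor)
  hi <- max(kymo$fluor)
  span <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((kymo$fluor - lo) / span, tif_path, bits.per.sample = 32L)
  meta <- list(
    pixel_um = kymo$pixel_um, line_interval_ms = kymo$line_interval_ms,
    normalized = kymo$normalized, intensity_offset = lo, intensity_span = span
  )
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tif = tif_path, json = json_path))
}

#' @rdname io_write_kymo
#' @export
io_read_kymo <- function(tif_path,
                         json_path = sub("\\.tiff?$", ".json", tif_path)) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  for (field in c("pixel_um", "line_interval_ms")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("kymograph metadata is missing the '%s' field", field))
    }
  }
  img <- tiff::readTIFF(tif_path)
  img <- img * (meta$intensity_span %||% 1) + (meta$intensity_offset %||% 0)
  san_kymo(img, meta$pixel_um, meta$line_interval_ms,
           normalized = isTRUE(meta$normalized))
}

#' Write a named list of tables as CSV files
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if needed).
#' @return Paths written, invisibly.
#' @export
io_write_tables <- function(tables, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
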