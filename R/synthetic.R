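#' Reference AP waveform parameters for superior and inferior SAN myocytes
#'
#' Mean action-potential parameters of isolated superior and inferior SAN
#' myocytes used as generator defaults: spontaneous AP frequency, coefficient
#' of variation of the inter-AP interval, maximum diastolic potential (MDP),
#' take-off potential, early diastolic duration, early diastolic
#' depolarization (EDD) rate, phase-0 maximum upstroke velocity and AP
#' duration at 90% repolarization (APD90).
#'
#' @return A tibble with one row per node region.
#' @export
san_ap_parameters <- function() {
  tibble::tibble(
    region = c("superior", "inferior"),
    ap_frequency_hz = c(4.04, 1.44),
    isi_cv = c(0.46, 0.96),
    mdp_mv = c(-56.88, -54.63),
    takeoff_mv = c(-36.051, -30.99),
    edd_ms = c(51.36, 325.09),
    edd_rate_mv_s = c(83.80, 36.73),
    dvdt_max_mv_ms = c(40.08, 29.67),
    apd90_ms = c(51.56, 75.38)
  )
}

#' Reference subthreshold-fluctuation amplitude mixtures
#'
#' Gaussian amplitude components of stochastic subthreshold voltage
#' fluctuations: superior cells show two populations (low ~2 mV, high ~11 mV),
#' inferior cells a single ~6 mV population.
#'
#' @param region `"superior"` or `"inferior"`.
#' @return A list of `c(weight, center_mv, width_mv)` components.
#' @export
san_subthreshold_mixture <- function(region = c("superior", "inferior")) {
  region <- match.arg(region)
  if (region == "superior") {
    list(c(0.5, 2.0, 1.3), c(0.5, 11.0, 1.1))
  } else {
    list(c(1.0, 6.0, 2.3))
  }
}

#' Reference Ca2+ spark amplitude mixtures
#'
#' Two spark populations per region: a shared low-amplitude population at
#' dF/F0 = 0.30 and a high-amplitude population at 0.9 (superior) or 1.2
#' (inferior).
#'
#' @param region `"superior"` or `"inferior"`.
#' @return A list of `c(weight, center_dff, width_dff)` components.
#' @export
san_spark_mixture <- function(region = c("superior", "inferior")) {
  region <- match.arg(region)
  if (region == "superior") {
    list(c(0.6, 0.30, 0.05), c(0.4, 0.90, 0.10))
  } else {
    list(c(0.6, 0.30, 0.05), c(0.4, 1.20, 0.10))
  }
}

check_mixture <- function(mixture) {
  m <- do.call(rbind, lapply(mixture, as.numeric))
  if (ncol(m) != 3) stop("mixture components must be c(weight, center, width)")
  if (abs(sum(m[, 1]) - 1) > 1e-6) stop("mixture weights must sum to 1")
  if (any(m[, 3] <= 0)) stop("mixture widths must be positive")
  m
}

sample_mixture <- function(n, mixture) {
  m <- check_mixture(mixture)
  comp <- sample.int(nrow(m), n, replace = TRUE, prob = m[, 1])
  rnorm(n, mean = m[comp, 2], sd = m[comp, 3])
}

# ---------------------------------------------------------------------------
# Node volume generator
# ---------------------------------------------------------------------------

#' Configuration for the synthetic SAN node volume
#'
#' Describes a scaled-down two-channel SAN volume: a primary artery descending
#' the node (row) axis whose diameter tapers from the superior to the inferior
#' value, orders 2-4 branch segments, random capillary segments added per
#' region until the target vessel fractional volume is met, and a myocyte
#' channel realising per-region density targets with a transition at
#' `boundary_fraction` of the node length.
#'
#' @param shape voxels per axis `(z, row, col)`; the node axis is `row`,
#'   superior at row 1.
#' @param voxel_size_um micrometres per voxel per axis.
#' @param boundary_fraction fraction of node-axis length occupied by the
#'   superior region, in (0, 1). Default 0.6 (superior ~60% of the node).
#' @param vessel_density_superior,vessel_density_inferior target vessel
#'   fractional volumes per region; `NULL` disables capillary in-fill (only
#'   the artery and configured branches are drawn).
#' @param myocyte_density_superior,myocyte_density_inferior target myocyte
#'   fractional volumes per region.
#' @param artery_diameter_superior_um,artery_diameter_inferior_um primary
#'   artery diameter at the superior and inferior ends (um).
#' @param branch_counts integer vector: number of order 2, 3 and 4 branch
#'   segments.
#' @param branch_diameters_um,branch_lengths_um mean diameter and length per
#'   branch order (orders 2-4).
#' @param capillary_diameter_um,capillary_length_um range (min, max) of
#'   capillary in-fill segment diameters and lengths.
#' @param seed RNG seed.
#' @return A `node_volume_config` list.
#' @export
node_volume_config <- function(shape = c(32, 240, 240),
                               voxel_size_um = c(1, 1, 1),
                               boundary_fraction = 0.6,
                               vessel_density_superior = 0.10,
                               vessel_density_inferior = 0.04,
                               myocyte_density_superior = 0.30,
                               myocyte_density_inferior = 0.18,
                               artery_diameter_superior_um = 14,
                               artery_diameter_inferior_um = 10.7,
                               branch_counts = c(4, 8, 12),
                               branch_diameters_um = c(8, 5.5, 4),
                               branch_lengths_um = c(40, 30, 22),
                               capillary_diameter_um = c(2.5, 3.5),
                               capillary_length_um = c(15, 30),
                               seed = NULL) {
  cfg <- list(
    shape = as.integer(shape), voxel_size_um = as.numeric(voxel_size_um),
    boundary_fraction = boundary_fraction,
    vessel_density_superior = vessel_density_superior,
    vessel_density_inferior = vessel_density_inferior,
    myocyte_density_superior = myocyte_density_superior,
    myocyte_density_inferior = myocyte_density_inferior,
    artery_diameter_superior_um = artery_diameter_superior_um,
    artery_diameter_inferior_um = artery_diameter_inferior_um,
    branch_counts = as.integer(branch_counts),
    branch_diameters_um = branch_diameters_um,
    branch_lengths_um = branch_lengths_um,
    capillary_diameter_um = capillary_diameter_um,
    capillary_length_um = capillary_length_um,
    seed = seed
  )
  stopifnot(
    length(cfg$shape) == 3, all(cfg$shape > 0),
    all(cfg$voxel_size_um > 0),
    cfg$boundary_fraction > 0, cfg$boundary_fraction < 1
  )
  dens <- c(
    cfg$vessel_density_superior, cfg$vessel_density_inferior,
    cfg$myocyte_density_superior, cfg$myocyte_density_inferior
  )
  if (any(dens <= 0 | dens >= 1)) stop("densities must lie in (0, 1)")
  structure(cfg, class = "node_volume_config")
}

# rasterize a cylinder segment into a logical array; coordinates in um,
# axis order (z, row, col); returns linear voxel indices covered
cylinder_voxels <- function(dims, vs, p0, p1, radius) {
  lo <- pmax(1, floor((pmin(p0, p1) - radius) / vs) + 1)
  hi <- pmin(dims, ceiling((pmax(p0, p1) + radius) / vs) + 1)
  if (any(lo > hi)) return(integer(0))
  iz <- lo[1]:hi[1]
  ir <- lo[2]:hi[2]
  ic <- lo[3]:hi[3]
  # voxel centres in um
  g <- expand.grid(z = (iz - 0.5) * vs[1], r = (ir - 0.5) * vs[2],
                   c = (ic - 0.5) * vs[3])
  ab <- p1 - p0
  len2 <- sum(ab^2)
  if (len2 == 0) return(integer(0))
  t <- ((g$z - p0[1]) * ab[1] + (g$r - p0[2]) * ab[2] + (g$c - p0[3]) * ab[3]) / len2
  t <- pmin(1, pmax(0, t))
  d2 <- (g$z - p0[1] - t * ab[1])^2 + (g$r - p0[2] - t * ab[2])^2 +
    (g$c - p0[3] - t * ab[3])^2
  keep <- d2 <= radius^2
  if (!any(keep)) return(integer(0))
  gi <- expand.grid(z = iz, r = ir, c = ic)[keep, , drop = FALSE]
  gi$z + dims[1] * (gi$r - 1) + dims[1] * dims[2] * (gi$c - 1)
}

# clip a segment to the volume box with an additional row-axis interval
clip_segment_rows <- function(p0, p1, box_um, row_range_um) {
  seg <- clip_segment(p0, p1, box_um)
  if (is.null(seg)) return(NULL)
  p0 <- seg$p0; p1 <- seg$p1
  d <- p1 - p0
  t0 <- 0; t1 <- 1
  if (d[2] == 0) {
    if (p0[2] < row_range_um[1] || p0[2] > row_range_um[2]) return(NULL)
  } else {
    ta <- (row_range_um[1] - p0[2]) / d[2]
    tb <- (row_range_um[2] - p0[2]) / d[2]
    t0 <- max(t0, min(ta, tb))
    t1 <- min(t1, max(ta, tb))
  }
  if (t0 >= t1) return(NULL)
  list(p0 = p0 + t0 * d, p1 = p0 + t1 * d)
}

# clip segment p0 -> p1 (um) to the volume box; returns NULL if empty
clip_segment <- function(p0, p1, box_um) {
  d <- p1 - p0
  t0 <- 0
  t1 <- 1
  for (a in 1:3) {
    if (d[a] == 0) {
      if (p0[a] < 0 || p0[a] > box_um[a]) return(NULL)
    } else {
      ta <- (0 - p0[a]) / d[a]
      tb <- (box_um[a] - p0[a]) / d[a]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 >= t1) return(NULL)
  list(p0 = p0 + t0 * d, p1 = p0 + t1 * d)
}

#' Generate a two-channel synthetic SAN node volume with ground truth
#'
#' Builds the vessel channel from explicit tube segments (tapering primary
#' artery, orders 2-4 branches, optional capillary in-fill realising the
#' per-region density targets) and the myocyte channel as a random density
#' field with a step at the configured boundary. Every planted segment and the
#' boundary row are recorded in the ground truth.
#'
#' @param cfg a [node_volume_config()].
#' @return A list with elements `volume` ([san_volume()]) and `truth` (list
#'   with `boundary_row`, `boundary_fraction`, `segments` tibble and realized
#'   per-region densities).
#' @export
gen_node_volume <- function(cfg) {
  stopifnot(inherits(cfg, "node_volume_config"))
  with_seed(cfg$seed, {
    dims <- cfg$shape
    vs <- cfg$voxel_size_um
    nz <- dims[1]; nr <- dims[2]; nc <- dims[3]
    box_um <- dims * vs
    boundary_row <- floor(cfg$boundary_fraction * nr) + 1L  # first inferior row
    sup_rows <- seq_len(boundary_row - 1L)
    inf_rows <- boundary_row:nr

    vessel <- array(FALSE, dims)
    segments <- list()

    # primary artery: straight tube along the row axis, tapering diameter
    cz <- box_um[1] / 2
    cc <- box_um[3] / 2
    r_sup <- cfg$artery_diameter_superior_um / 2
    r_inf <- cfg$artery_diameter_inferior_um / 2
    zg <- ((seq_len(nz) - 0.5) * vs[1] - cz)^2
    cg <- ((seq_len(nc) - 0.5) * vs[3] - cc)^2
    plane_d2 <- outer(zg, cg, "+")
    for (j in seq_len(nr)) {
      rj <- r_sup + (j - 0.5) / nr * (r_inf - r_sup)
      vessel[, j, ][plane_d2 <= rj^2] <- TRUE
    }
    segments[[1]] <- tibble::tibble(
      segment_id = 1L, order = 1L, type = "artery",
      z0 = cz, row0 = 0, col0 = cc, z1 = cz, row1 = box_um[2], col1 = cc,
      length_um = box_um[2],
      diameter_um = (cfg$artery_diameter_superior_um +
                       cfg$artery_diameter_inferior_um) / 2,
      attach_overlap_um = 0
    )

    # branch segments: each order attaches to a random point on a parent of
    # the previous order and leaves at a random, mostly in-plane direction
    rand_dir <- function() {
      v <- c(rnorm(1, sd = 0.4), rnorm(1, sd = 0.6), rnorm(1))
      v / sqrt(sum(v^2))
    }
    parents <- list(list(p0 = c(cz, 0, cc), p1 = c(cz, box_um[2], cc),
                         dia = function(u) 2 * (r_sup + u * (r_inf - r_sup))))
    seg_id <- 1L
    for (ord in 2:4) {
      k <- cfg$branch_counts[ord - 1]
      if (is.na(k) || k <= 0) {
        parents <- list()
        next
      }
      if (length(parents) == 0) break
      new_parents <- list()
      for (i in seq_len(k)) {
        if (ord == 2) {
          # the artery arborizes along its whole descent: stratified
          # attachment points keep the branch tree balanced along the axis
          par <- parents[[1]]
          u <- (i - 0.5) / k + runif(1, -0.3, 0.3) / k
        } else {
          par <- parents[[1 + (i - 1) %% length(parents)]]
          u <- runif(1, 0.1, 0.9)
        }
        start <- par$p0 + u * (par$p1 - par$p0)
        par_dia <- if (is.function(par$dia)) par$dia(u) else par$dia
        len <- cfg$branch_lengths_um[ord - 1] * runif(1, 0.8, 1.2)
        dia <- cfg$branch_diameters_um[ord - 1] * runif(1, 0.85, 1.15)
        seg <- clip_segment(start, start + len * rand_dir(), box_um)
        if (is.null(seg)) next
        act_len <- sqrt(sum((seg$p1 - seg$p0)^2))
        if (act_len < 5) next
        vox <- cylinder_voxels(dims, vs, seg$p0, seg$p1, dia / 2)
        vessel[vox] <- TRUE
        seg_id <- seg_id + 1L
        segments[[seg_id]] <- tibble::tibble(
          segment_id = seg_id, order = ord, type = "branch",
          z0 = seg$p0[1], row0 = seg$p0[2], col0 = seg$p0[3],
          z1 = seg$p1[1], row1 = seg$p1[2], col1 = seg$p1[3],
          length_um = act_len, diameter_um = dia,
          # the part of the tube buried inside its parent is not distinct
          # centerline; skeleton-based lengths exclude it
          attach_overlap_um = par_dia / 2
        )
        new_parents[[length(new_parents) + 1]] <- c(seg, list(dia = dia))
      }
      parents <- new_parents
    }

    # capillary in-fill per region up to the target fractional volume
    region_rows <- list(superior = sup_rows, inferior = inf_rows)
    targets <- c(cfg$vessel_density_superior, cfg$vessel_density_inferior)
    for (rg in 1:2) {
      tgt <- targets[rg]
      if (is.null(tgt)) next
      rows <- region_rows[[rg]]
      nvox_region <- nz * length(rows) * nc
      want <- tgt * nvox_region
      have <- sum(vessel[, rows, ])
      if (have > 1.10 * want) {
        stop(sprintf(
          "vessel density target %.3f infeasible in %s region: artery/branches alone occupy %.3f",
          tgt, names(region_rows)[rg], have / nvox_region
        ))
      }
      row_range_um <- c(min(rows) - 1, max(rows)) * vs[2]
      # per-row deficit-targeted fill: branches and the tapering artery are
      # spatially clustered, so capillaries are steered toward rows still
      # below the per-row target, keeping density stationary along the axis
      row_counts <- apply(vessel[, rows, , drop = FALSE], 2, sum)
      # water-filling: rows already above the uniform level (artery, branch
      # clusters) keep their count; the rest fill up to a common level L so
      # the regional total meets the target and density stays stationary
      # along the axis. L is re-solved as counts grow, so placement
      # quantization cannot push the total past the target.
      water_level <- function(counts) {
        lo <- 0; hi <- want
        for (it in 1:60) {
          L <- (lo + hi) / 2
          if (sum(pmax(counts, L)) > want) hi <- L else lo <- L
        }
        L
      }
      guard <- 0L
      repeat {
        guard <- guard + 1L
        if (guard > 8000L) break
        if (sum(row_counts) >= 0.985 * want) break
        len <- runif(1, cfg$capillary_length_um[1], cfg$capillary_length_um[2])
        dia <- runif(1, cfg$capillary_diameter_um[1], cfg$capillary_diameter_um[2])
        deficit <- pmax(water_level(row_counts) - row_counts, 0)
        if (sum(deficit) < 0.01 * want) break
        r_pick <- rows[sample.int(length(rows), 1, prob = deficit + 1e-9)]
        mar <- len / 2
        centre <- c(runif(1, -mar, box_um[1] + mar),
                    (r_pick - 0.5) * vs[2] + runif(1, -2, 2),
                    runif(1, -mar, box_um[3] + mar))
        dirv <- rand_dir()
        # the region boundary acts as a clipping face, keeping the step crisp
        seg <- clip_segment_rows(centre - len / 2 * dirv,
                                 centre + len / 2 * dirv, box_um, row_range_um)
        if (is.null(seg)) next
        act_len <- sqrt(sum((seg$p1 - seg$p0)^2))
        if (act_len < 5) next
        vox <- cylinder_voxels(dims, vs, seg$p0, seg$p1, dia / 2)
        if (length(vox) == 0) next
        new_vox <- vox[!vessel[vox]]
        vessel[new_vox] <- TRUE
        seg_id <- seg_id + 1L
        segments[[seg_id]] <- tibble::tibble(
          segment_id = seg_id, order = 4L, type = "capillary",
          z0 = seg$p0[1], row0 = seg$p0[2], col0 = seg$p0[3],
          z1 = seg$p1[1], row1 = seg$p1[2], col1 = seg$p1[3],
          length_um = act_len, diameter_um = dia, attach_overlap_um = 0
        )
        vox_rows <- ((new_vox - 1) %/% dims[1]) %% dims[2] + 1L
        vr <- vox_rows[vox_rows %in% rows]
        tab <- table(vr)
        row_counts[match(as.integer(names(tab)), rows)] <-
          row_counts[match(as.integer(names(tab)), rows)] + as.integer(tab)
        have <- have + length(new_vox)
      }
      realized <- have / nvox_region
      if (abs(realized - tgt) > 0.10 * tgt) {
        stop(sprintf(
          "could not realize vessel density %.3f in %s region (got %.3f)",
          tgt, names(region_rows)[rg], realized
        ))
      }
    }

    # myocyte channel: Bernoulli density field with a step at the boundary
    p_row <- c(
      rep(cfg$myocyte_density_superior, length(sup_rows)),
      rep(cfg$myocyte_density_inferior, length(inf_rows))
    )
    u <- array(runif(prod(dims)), dims)
    myo <- sweep(u, 2, p_row, "<")

    vol <- san_volume(myo * 1, vessel * 1, vs)
    seg_tbl <- dplyr::bind_rows(segments)
    truth <- list(
      boundary_row = boundary_row,
      boundary_fraction = cfg$boundary_fraction,
      segments = seg_tbl,
      # each branch attachment splits its parent, so the skeleton-graph
      # segment count exceeds the planted-tube count by one per attachment
      n_segments_topological = nrow(seg_tbl) + sum(seg_tbl$type == "branch"),
      centerline_length_um = sum(seg_tbl$length_um - seg_tbl$attach_overlap_um),
      vessel_density = c(
        superior = sum(vessel[, sup_rows, ]) / (nz * length(sup_rows) * nc),
        inferior = sum(vessel[, inf_rows, ]) / (nz * length(inf_rows) * nc)
      ),
      myocyte_density = c(
        superior = sum(myo[, sup_rows, ]) / (nz * length(sup_rows) * nc),
        inferior = sum(myo[, inf_rows, ]) / (nz * length(inf_rows) * nc)
      )
    )
    list(volume = vol, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Voltage trace generator
# ---------------------------------------------------------------------------

#' Configuration for a synthetic membrane-potential trace
#'
#' Waveform defaults are the superior-cell reference parameters from
#' [san_ap_parameters()]; pass `region = "inferior"` for the inferior set.
#'
#' @param duration_s trace length (s).
#' @param sample_rate_hz sampling rate (default 10 kHz).
#' @param modality firing modality: `"tonic"` (near-periodic), `"irregular"`
#'   (exponential-like intervals, CV near 1), `"burst"` (silences alternating
#'   with high-frequency clusters), `"subthreshold_only"` or `"silent"`.
#' @param region which reference parameter set seeds the waveform defaults.
#' @param ap_frequency_hz mean AP rate; tonic/irregular use it directly.
#' @param isi_cv_target ISI coefficient of variation for tonic firing.
#' @param mdp_mv,takeoff_mv,peak_mv,apd90_ms,edd_rate_mv_s,dvdt_max_mv_ms
#'   waveform parameters: maximum diastolic potential, take-off potential, AP
#'   peak, APD90, early diastolic depolarization rate and maximum phase-0
#'   upstroke velocity.
#' @param refractory_s minimum inter-AP interval for stochastic modalities;
#'   irregular ISIs are `refractory_s` plus an exponential tail, so the ISI
#'   CV approaches 1 when the mean interval is long relative to the
#'   refractory period.
#' @param burst_intra_hz,burst_size_mean,burst_silence_s intra-burst AP rate,
#'   mean APs per burst and mean inter-burst silence for `modality = "burst"`.
#' @param subthreshold_rate_hz mean rate of stochastic subthreshold bumps.
#' @param subthreshold_amp_mixture list of `c(weight, center_mv, width_mv)`
#'   Gaussian components for bump amplitudes.
#' @param noise_sd_mv additive Gaussian instrument noise (mV).
#' @param seed RNG seed.
#' @return A `trace_config` list.
#' @export
trace_config <- function(duration_s = 30,
                         sample_rate_hz = 10000,
                         modality = c("tonic", "irregular", "burst",
                                      "subthreshold_only", "silent"),
                         region = c("superior", "inferior"),
                         ap_frequency_hz = NULL,
                         isi_cv_target = 0.05,
                         mdp_mv = NULL, takeoff_mv = NULL, peak_mv = 15,
                         apd90_ms = NULL, edd_rate_mv_s = NULL,
                         dvdt_max_mv_ms = NULL,
                         refractory_s = 0.12,
                         burst_intra_hz = 5, burst_size_mean = 6,
                         burst_silence_s = 2.5,
                         subthreshold_rate_hz = 2.10,
                         subthreshold_amp_mixture = NULL,
                         noise_sd_mv = 0.3,
                         seed = NULL) {
  modality <- match.arg(modality)
  region <- match.arg(region)
  ref <- san_ap_parameters()
  ref <- ref[ref$region == region, ]
  cfg <- list(
    duration_s = duration_s, sample_rate_hz = sample_rate_hz,
    modality = modality, region = region,
    ap_frequency_hz = ap_frequency_hz %||% ref$ap_frequency_hz,
    isi_cv_target = isi_cv_target,
    mdp_mv = mdp_mv %||% ref$mdp_mv,
    takeoff_mv = takeoff_mv %||% ref$takeoff_mv,
    peak_mv = peak_mv,
    apd90_ms = apd90_ms %||% ref$apd90_ms,
    edd_rate_mv_s = edd_rate_mv_s %||% ref$edd_rate_mv_s,
    dvdt_max_mv_ms = dvdt_max_mv_ms %||% ref$dvdt_max_mv_ms,
    refractory_s = refractory_s,
    burst_intra_hz = burst_intra_hz, burst_size_mean = burst_size_mean,
    burst_silence_s = burst_silence_s,
    subthreshold_rate_hz = subthreshold_rate_hz,
    subthreshold_amp_mixture = subthreshold_amp_mixture %||%
      san_subthreshold_mixture(region),
    noise_sd_mv = noise_sd_mv,
    seed = seed
  )
  stopifnot(
    cfg$duration_s > 0, cfg$sample_rate_hz > 0,
    cfg$mdp_mv < cfg$takeoff_mv, cfg$takeoff_mv < cfg$peak_mv
  )
  check_mixture(cfg$subthreshold_amp_mixture)
  structure(cfg, class = "trace_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw AP take-off times for a modality; returns sorted times within margins
draw_ap_times <- function(cfg) {
  dur <- cfg$duration_s
  f <- cfg$ap_frequency_hz
  t0 <- 0.3  # settle-in margin before the first AP
  if (cfg$modality %in% c("silent", "subthreshold_only") || f <= 0) {
    return(numeric(0))
  }
  isis <- switch(cfg$modality,
    tonic = {
      n <- ceiling((dur - t0) * f * 1.3) + 10
      cv <- max(cfg$isi_cv_target, 1e-4)
      rgamma_isi(n, mean = 1 / f, cv = cv)
    },
    irregular = {
      n <- ceiling((dur - t0) * f * 2) + 20
      r <- cfg$refractory_s
      if (1 / f <= r) stop("ap_frequency too high for the refractory period")
      r + rexp(n, rate = 1 / (1 / f - r))
    },
    burst = {
      isis <- numeric(0)
      while (sum(isis) < dur) {
        nb <- max(2, rpois(1, cfg$burst_size_mean))
        intra <- rgamma_isi(nb - 1, mean = 1 / cfg$burst_intra_hz, cv = 0.1)
        silence <- 1 + rexp(1, 1 / max(cfg$burst_silence_s - 1, 0.5))
        isis <- c(isis, intra, silence)
      }
      isis
    }
  )
  times <- t0 + cumsum(c(0, isis))
  times[times < dur - 0.15]
}

rgamma_isi <- function(n, mean, cv) {
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, scale = mean / shape)
}

# render the deterministic AP waveform onto a sample grid given take-off
# times; returns list(v, mdp_times)
render_waveform <- function(ap_times, cfg) {
  fs <- cfg$sample_rate_hz
  n <- round(cfg$duration_s * fs)
  v <- rep(cfg$mdp_mv, n)
  if (length(ap_times) == 0) {
    return(list(v = v, mdp_times = numeric(0)))
  }
  mdp <- cfg$mdp_mv
  tko <- cfg$takeoff_mv
  peak <- cfg$peak_mv
  A <- peak - tko
  s_ms <- A / (4 * cfg$dvdt_max_mv_ms)      # logistic time constant, ms
  t_up <- max(8 * s_ms, 1) / 1000           # upstroke duration, s
  undershoot <- 3
  v_inf <- mdp - undershoot
  v90 <- peak - 0.9 * A
  tau_r <- (cfg$apd90_ms / 1000 - t_up) /
    log((peak - v_inf) / (v90 - v_inf))
  t_rep <- tau_r * log((peak - v_inf) / undershoot)  # time peak -> MDP
  s_e <- cfg$edd_rate_mv_s                   # early diastolic slope, mV/s
  dv_dia <- tko - mdp
  dd_max <- dv_dia / (0.7 * s_e)             # longest diastole rendered at s_e

  idx <- function(t) pmin(n, pmax(1, floor(t * fs) + 1))
  fill <- function(ta, tb, fun) {
    ia <- idx(ta); ib <- idx(tb)
    if (ib < ia) return(invisible())
    tt <- (seq(ia, ib) - 1) / fs
    v[seq(ia, ib)] <<- fun(tt)
    invisible()
  }
  sigm <- function(x) 1 / (1 + exp(-x))

  diastole_fun <- function(t_start, t_end) {
    # from MDP at t_start to take-off at t_end; near-MDP plateau when the
    # interval exceeds what the configured EDD rate can span
    dd <- t_end - t_start
    function(tt) {
      tt <- pmax(tt - t_start, 0)
      dd_nom <- min(dd, dd_max)
      t_plateau <- dd - dd_nom
      out <- numeric(length(tt))
      pre <- tt < t_plateau
      out[pre] <- mdp + 0.05 * dv_dia * (tt[pre] / max(t_plateau, 1e-9))
      u <- tt[!pre] - t_plateau
      base <- if (t_plateau > 0) mdp + 0.05 * dv_dia else mdp
      dv_rem <- tko - base
      f_e <- 0.6
      if (s_e * f_e * dd_nom > dv_rem) f_e <- max(0.2, 0.8 * dv_rem / (s_e * dd_nom))
      early <- u <= f_e * dd_nom
      val <- numeric(length(u))
      val[early] <- base + s_e * u[early]
      late_len <- (1 - f_e) * dd_nom
      a_q <- (dv_rem - s_e * dd_nom) / max(late_len^2, 1e-12)
      ul <- u[!early] - f_e * dd_nom
      val[!early] <- base + s_e * (f_e * dd_nom + ul) + a_q * ul^2
      out[!pre] <- pmin(val, tko)
      out
    }
  }

  mdp_times <- numeric(length(ap_times))
  # lead-in diastole before the first AP
  lead <- min(ap_times[1], dd_max)
  if (lead > 0) fill(ap_times[1] - lead, ap_times[1],
                     diastole_fun(ap_times[1] - lead, ap_times[1]))
  for (k in seq_along(ap_times)) {
    tk <- ap_times[k]
    t_peak <- tk + t_up
    # upstroke: logistic anchored exactly at take-off and peak
    mid <- tk + t_up / 2
    lo <- sigm(-t_up / 2 / (s_ms / 1000))
    hi <- sigm(t_up / 2 / (s_ms / 1000))
    fill(tk, t_peak, function(tt) {
      tko + A * (sigm((tt - mid) / (s_ms / 1000)) - lo) / (hi - lo)
    })
    t_next <- if (k < length(ap_times)) ap_times[k + 1] else cfg$duration_s
    t_mdp <- t_peak + t_rep
    if (t_mdp >= t_next) {
      # compressed cycle: truncated repolarization, no rendered diastole
      fill(t_peak, t_next, function(tt) {
        v_inf + (peak - v_inf) * exp(-(tt - t_peak) / tau_r)
      })
      mdp_times[k] <- NA_real_
    } else {
      fill(t_peak, t_mdp, function(tt) {
        v_inf + (peak - v_inf) * exp(-(tt - t_peak) / tau_r)
      })
      fill(t_mdp, t_next, diastole_fun(t_mdp, t_next))
      mdp_times[k] <- t_mdp
    }
  }
  list(v = v, mdp_times = mdp_times)
}

#' Generate a synthetic membrane-potential trace with ground truth
#'
#' Renders a parametric SAN action-potential waveform (logistic upstroke with
#' the configured maximum dV/dt, exponential repolarization tuned to APD90,
#' linear early-diastolic ramp at the configured EDD rate) at take-off times
#' drawn for the requested firing modality, adds alpha-function subthreshold
#' bumps with amplitudes from the configured Gaussian mixture (always kept
#' below the -29 mV AP threshold), and additive Gaussian noise.
#'
#' @param cfg a [trace_config()].
#' @return List with `trace` ([san_trace()]) and `truth` (list with
#'   `ap_times_s`, `mdp_times_s`, `subthreshold` tibble and the config).
#' @export
gen_voltage_trace <- function(cfg) {
  stopifnot(inherits(cfg, "trace_config"))
  with_seed(cfg$seed, {
    fs <- cfg$sample_rate_hz
    ap_times <- draw_ap_times(cfg)
    wf <- render_waveform(ap_times, cfg)
    v <- wf$v
    n <- length(v)

    # subthreshold bumps: Poisson candidates, placed only where the membrane
    # sits near MDP so the bump peak stays below the -29 mV AP threshold
    bumps <- tibble::tibble(
      time_s = numeric(0), peak_time_s = numeric(0),
      amplitude_mv = numeric(0), duration_ms = numeric(0)
    )
    if (cfg$modality != "silent" && cfg$subthreshold_rate_hz > 0) {
      n_cand <- rpois(1, cfg$subthreshold_rate_hz * cfg$duration_s * 1.5)
      cand <- sort(runif(n_cand, 0.05, cfg$duration_s - 0.1))
      amps <- abs(sample_mixture(length(cand), cfg$subthreshold_amp_mixture))
      durs <- runif(length(cand), 5, 50)
      keep <- logical(length(cand))
      target_n <- rpois(1, cfg$subthreshold_rate_hz * cfg$duration_s)
      placed <- 0L
      for (i in seq_along(cand)) {
        if (placed >= target_n) break
        i0 <- floor(cand[i] * fs) + 1
        base <- v[i0]
        if (base > cfg$mdp_mv + 6) next           # too depolarized
        if (base + amps[i] > -29.5) next          # would cross AP threshold
        tau <- durs[i] / 5 / 1000
        span <- min(n, i0 + round(durs[i] / 1000 * 2 * fs))
        tt <- (seq(i0, span) - i0) / fs
        v[seq(i0, span)] <- v[seq(i0, span)] + amps[i] * (tt / tau) * exp(1 - tt / tau)
        keep[i] <- TRUE
        placed <- placed + 1L
      }
      bumps <- tibble::tibble(
        time_s = cand[keep],
        peak_time_s = cand[keep] + durs[keep] / 5 / 1000,
        amplitude_mv = amps[keep],
        duration_ms = durs[keep]
      )
    }

    if (cfg$noise_sd_mv > 0) v <- v + rnorm(n, sd = cfg$noise_sd_mv)
    trace <- san_trace(v, fs)
    truth <- list(
      ap_times_s = ap_times,
      mdp_times_s = wf$mdp_times,
      subthreshold = bumps,
      config = cfg
    )
    list(trace = trace, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Kymograph generator
# ---------------------------------------------------------------------------

#' Configuration for a synthetic line-scan kymograph
#'
#' Sparks are localized events, Gaussian in space with the configured FWHM and
#' instantaneous-rise/exponential-decay in time with the configured FDHM;
#' whole-cell transients span the full scan line. Fluorescence is emitted in
#' raw units around `f0_baseline` with multiplicative event amplitudes in
#' dF/F0 and additive Gaussian noise.
#'
#' @param scan_length_um scan line length (um).
#' @param pixel_um spatial pixel size (um).
#' @param duration_s recording duration (s).
#' @param line_interval_ms time between line scans (default ~4 ms).
#' @param spark_rate_per_100um_s mean spark rate in events / (100 um * s).
#' @param spark_amp_mixture list of `c(weight, center_dff, width_dff)`
#'   components for spark amplitudes.
#' @param spark_fwhm_um,spark_fdhm_ms spark spatial full width and temporal
#'   full duration at half maximum.
#' @param transient_frequency_hz whole-cell transient rate (0 disables).
#' @param transient_amp_dff,transient_fdhm_ms transient amplitude and FDHM.
#' @param noise_sd_dff additive noise SD in dF/F0 units.
#' @param f0_baseline baseline fluorescence (arbitrary units).
#' @param seed RNG seed.
#' @return A `kymo_config` list.
#' @export
kymo_config <- function(scan_length_um = 50, pixel_um = 0.25,
                        duration_s = 10, line_interval_ms = 4,
                        spark_rate_per_100um_s = 4.7,
                        spark_amp_mixture = san_spark_mixture("superior"),
                        spark_fwhm_um = 2, spark_fdhm_ms = 30,
                        transient_frequency_hz = 0,
                        transient_amp_dff = 1.37, transient_fdhm_ms = 300,
                        noise_sd_dff = 0.03, f0_baseline = 100,
                        seed = NULL) {
  cfg <- list(
    scan_length_um = scan_length_um, pixel_um = pixel_um,
    duration_s = duration_s, line_interval_ms = line_interval_ms,
    spark_rate_per_100um_s = spark_rate_per_100um_s,
    spark_amp_mixture = spark_amp_mixture,
    spark_fwhm_um = spark_fwhm_um, spark_fdhm_ms = spark_fdhm_ms,
    transient_frequency_hz = transient_frequency_hz,
    transient_amp_dff = transient_amp_dff,
    transient_fdhm_ms = transient_fdhm_ms,
    noise_sd_dff = noise_sd_dff, f0_baseline = f0_baseline,
    seed = seed
  )
  pos <- c(
    cfg$scan_length_um, cfg$pixel_um, cfg$duration_s, cfg$line_interval_ms,
    cfg$spark_fwhm_um, cfg$spark_fdhm_ms, cfg$f0_baseline
  )
  if (any(pos <= 0)) stop("all physical kymograph quantities must be positive")
  if (cfg$spark_fwhm_um >= cfg$scan_length_um) {
    stop("spark FWHM must be smaller than the scan length")
  }
  check_mixture(cfg$spark_amp_mixture)
  structure(cfg, class = "kymo_config")
}

# add one spark (instant rise, exponential decay x spatial Gaussian) to a
# dF/F0 accumulator; x0 in um, t0 in s
add_spark <- function(dff, cfg, x0, t0, amp, fwhm_um = cfg$spark_fwhm_um,
                      fdhm_ms = cfg$spark_fdhm_ms) {
  ns <- nrow(dff); nt <- ncol(dff)
  sigma <- fwhm_um / 2.3548
  tau_lines <- (fdhm_ms / log(2)) / cfg$line_interval_ms
  x <- (seq_len(ns) - 0.5) * cfg$pixel_um
  i0 <- floor(t0 * 1000 / cfg$line_interval_ms) + 1
  if (i0 > nt) return(dff)
  span <- min(nt, i0 + ceiling(tau_lines * 6))
  prof_x <- exp(-(x - x0)^2 / (2 * sigma^2))
  prof_t <- exp(-(seq(i0, span) - i0) / tau_lines)
  dff[, i0:span] <- dff[, i0:span] + amp * outer(prof_x, prof_t)
  dff
}

#' Generate a synthetic line-scan kymograph with ground truth
#'
#' @param cfg a [kymo_config()].
#' @return List with `kymo` (raw-fluorescence [san_kymo()]) and `truth`
#'   (tibbles `sparks` and `transients`).
#' @export
gen_kymograph <- function(cfg) {
  stopifnot(inherits(cfg, "kymo_config"))
  with_seed(cfg$seed, {
    ns <- round(cfg$scan_length_um / cfg$pixel_um)
    nt <- round(cfg$duration_s * 1000 / cfg$line_interval_ms)
    dff <- matrix(0, ns, nt)

    n_sparks <- rpois(1, cfg$spark_rate_per_100um_s *
                        cfg$scan_length_um / 100 * cfg$duration_s)
    sparks <- tibble::tibble(
      position_um = runif(n_sparks, 1, cfg$scan_length_um - 1),
      time_s = runif(n_sparks, 0.02, cfg$duration_s - 0.1),
      amplitude_dff = abs(sample_mixture(n_sparks, cfg$spark_amp_mixture)),
      fwhm_um = cfg$spark_fwhm_um,
      fdhm_ms = cfg$spark_fdhm_ms
    )
    for (i in seq_len(n_sparks)) {
      dff <- add_spark(dff, cfg, sparks$position_um[i], sparks$time_s[i],
                       sparks$amplitude_dff[i])
    }

    transients <- tibble::tibble(
      time_s = numeric(0), amplitude_dff = numeric(0), fdhm_ms = numeric(0)
    )
    if (cfg$transient_frequency_hz > 0) {
      period <- 1 / cfg$transient_frequency_hz
      times <- seq(period / 2, cfg$duration_s - period / 4, by = period)
      times <- times + rnorm(length(times), sd = 0.02 * period)
      rise_ms <- 25
      tau_ms <- (cfg$transient_fdhm_ms - rise_ms / 2) / log(2)
      tl <- cfg$line_interval_ms
      for (t0 in times) {
        i0 <- floor(t0 * 1000 / tl) + 1
        span <- min(nt, i0 + ceiling((rise_ms + 6 * tau_ms) / tl))
        if (i0 > nt) next
        tt <- (seq(i0, span) - i0) * tl
        prof <- ifelse(tt < rise_ms, tt / rise_ms, exp(-(tt - rise_ms) / tau_ms))
        dff[, i0:span] <- dff[, i0:span] +
          cfg$transient_amp_dff * matrix(prof, ns, length(prof), byrow = TRUE)
      }
      transients <- tibble::tibble(
        time_s = times + rise_ms / 1000,
        amplitude_dff = cfg$transient_amp_dff,
        fdhm_ms = cfg$transient_fdhm_ms
      )
    }

    f <- cfg$f0_baseline * (1 + dff)
    if (cfg$noise_sd_dff > 0) {
      f <- f + rnorm(length(f), sd = cfg$noise_sd_dff * cfg$f0_baseline)
    }
    kymo <- san_kymo(matrix(f, ns, nt), cfg$pixel_um, cfg$line_interval_ms,
                     normalized = FALSE)
    list(kymo = kymo, truth = list(sparks = sparks, transients = transients,
                                   config = cfg))
  })
}

# ---------------------------------------------------------------------------
# Paired recording generator
# ---------------------------------------------------------------------------

#' Generate a paired voltage + Ca2+ recording with spark-to-AP coupling
#'
#' Produces a membrane-potential trace and a simultaneous kymograph on a
#' shared time base. Diastolic Ca2+ sparks are planted before each AP with a
#' configurable mean count per AP and a linearly ramping rate toward the AP
#' take-off; background sparks follow the kymograph config rate.
#'
#' @param cfg_trace a [trace_config()].
#' @param cfg_kymo a [kymo_config()] with the same duration.
#' @param sparks_per_ap mean number of diastolic sparks planted before each AP.
#' @param pre_ap_ramp slope of the spark-time density across the pre-AP
#'   window: 0 gives uniform times, larger values concentrate sparks toward
#'   the AP (density proportional to `1 + pre_ap_ramp * u` with `u = 1` at the
#'   AP).
#' @param window_ms maximum pre-AP window used for planted sparks (ms).
#' @param seed RNG seed.
#' @return List with `paired` ([san_paired()]) and `truth` (trace truth,
#'   spark tibble with `ap_id`, coupling settings).
#' @export
gen_paired_recording <- function(cfg_trace, cfg_kymo, sparks_per_ap = 4.5,
                                 pre_ap_ramp = 1, window_ms = 300,
                                 seed = NULL) {
  stopifnot(inherits(cfg_trace, "trace_config"), inherits(cfg_kymo, "kymo_config"))
  if (abs(cfg_trace$duration_s - cfg_kymo$duration_s) > 1e-9) {
    stop("trace and kymograph durations must match")
  }
  if (sparks_per_ap < 0 || pre_ap_ramp < 0) {
    stop("coupling parameters must be non-negative")
  }
  with_seed(seed, {
    cfg_trace$seed <- child_seed(seed, 1L)
    vt <- gen_voltage_trace(cfg_trace)
    ap_times <- vt$truth$ap_times_s

    # coupled diastolic sparks
    rows <- list()
    for (k in seq_along(ap_times)) {
      tk <- ap_times[k]
      w_start <- max(0, tk - window_ms / 1000)
      if (k > 1) w_start <- max(w_start, ap_times[k - 1] + cfg_trace$apd90_ms / 1000 + 0.02)
      w <- tk - w_start
      if (w <= 0.01) next
      nk <- rpois(1, sparks_per_ap)
      if (nk == 0) next
      # inverse-CDF sample of density proportional to 1 + ramp * u on [0, 1]
      p <- runif(nk)
      u <- if (pre_ap_ramp == 0) p else
        (sqrt(1 + pre_ap_ramp * (2 + pre_ap_ramp) * p) - 1) / pre_ap_ramp
      rows[[length(rows) + 1]] <- tibble::tibble(
        ap_id = k, time_s = w_start + u * w,
        position_um = runif(nk, 1, cfg_kymo$scan_length_um - 1),
        amplitude_dff = abs(sample_mixture(nk, cfg_kymo$spark_amp_mixture))
      )
    }
    coupled <- dplyr::bind_rows(rows)

    # background sparks at the kymograph config rate
    n_bg <- rpois(1, cfg_kymo$spark_rate_per_100um_s *
                    cfg_kymo$scan_length_um / 100 * cfg_kymo$duration_s)
    background <- tibble::tibble(
      ap_id = NA_integer_,
      time_s = runif(n_bg, 0.02, cfg_kymo$duration_s - 0.1),
      position_um = runif(n_bg, 1, cfg_kymo$scan_length_um - 1),
      amplitude_dff = abs(sample_mixture(n_bg, cfg_kymo$spark_amp_mixture))
    )
    sparks <- dplyr::bind_rows(coupled, background)

    ns <- round(cfg_kymo$scan_length_um / cfg_kymo$pixel_um)
    nt <- round(cfg_kymo$duration_s * 1000 / cfg_kymo$line_interval_ms)
    dff <- matrix(0, ns, nt)
    for (i in seq_len(nrow(sparks))) {
      dff <- add_spark(dff, cfg_kymo, sparks$position_um[i], sparks$time_s[i],
                       sparks$amplitude_dff[i])
    }
    # AP-triggered whole-cell transients
    rise_ms <- 25
    tau_ms <- (cfg_kymo$transient_fdhm_ms - rise_ms / 2) / log(2)
    tl <- cfg_kymo$line_interval_ms
    for (t0 in ap_times) {
      i0 <- floor(t0 * 1000 / tl) + 1
      span <- min(nt, i0 + ceiling((rise_ms + 5 * tau_ms) / tl))
      if (i0 > nt) next
      tt <- (seq(i0, span) - i0) * tl
      prof <- ifelse(tt < rise_ms, tt / rise_ms, exp(-(tt - rise_ms) / tau_ms))
      dff[, i0:span] <- dff[, i0:span] +
        cfg_kymo$transient_amp_dff * matrix(prof, ns, length(prof), byrow = TRUE)
    }
    f <- cfg_kymo$f0_baseline * (1 + dff)
    if (cfg_kymo$noise_sd_dff > 0) {
      f <- f + rnorm(length(f), sd = cfg_kymo$noise_sd_dff * cfg_kymo$f0_baseline)
    }
    kymo <- san_kymo(matrix(f, ns, nt), cfg_kymo$pixel_um, tl, normalized = FALSE)
    paired <- san_paired(vt$trace, kymo, offset_s = 0)
    truth <- list(
      ap_times_s = ap_times,
      sparks = sparks,
      trace_truth = vt$truth,
      sparks_per_ap = sparks_per_ap,
      pre_ap_ramp = pre_ap_ramp,
      window_ms = window_ms
    )
    list(paired = paired, truth = truth)
  })
}
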