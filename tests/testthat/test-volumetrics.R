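test_that("fixed thresholding reproduces a binary channel exactly", {
  fx <- node_analysis()
  expect_identical(unclass(fx$myo) == TRUE, fx$nv$volume$myocyte == 1)
  zero <- san_volume(array(0, c(4, 4, 4)), array(0, c(4, 4, 4)))
  expect_identical(sum(threshold_mask(zero, "myocyte", "fixed", 0.5)), 0L)
})

test_that("otsu thresholding recovers a known foreground fraction", {
  set.seed(11)
  d <- c(20, 40, 40)
  fg <- array(runif(prod(d)) < 0.10, d)
  intens <- ifelse(fg, rnorm(prod(d), 0.8, 0.1), rnorm(prod(d), 0.15, 0.08))
  vol <- san_volume(array(intens, d), array(intens, d))
  m <- threshold_mask(vol, "myocyte", "otsu")
  frac <- sum(m) / length(m)
  expect_lt(abs(frac - 0.10), 0.02)  # within 20% of the planted fraction
  flat <- san_volume(array(1, c(4, 4, 4)), array(1, c(4, 4, 4)))
  expect_error(threshold_mask(flat, "myocyte", "otsu"), "flat")
})

test_that("fractional volume map counts voxels exactly and conserves totals", {
  full <- san_mask(array(TRUE, c(5, 64, 64)), c(1, 1, 1))
  dm <- fractional_volume_map(full, c(32, 32))
  expect_true(all(dm$fraction == 1))
  # forced arithmetic: 125 of 1000 voxels set in a single tile
  m <- array(FALSE, c(10, 10, 10))
  m[seq_len(125)] <- TRUE
  dm2 <- fractional_volume_map(san_mask(m, c(1, 1, 1)), c(10, 10))
  expect_identical(dm2$fraction, 0.125)
  # conservation: tile counts sum to the global foreground count
  fx <- node_analysis()
  dmv <- fractional_volume_map(fx$ves, c(32, 32))
  expect_identical(sum(dmv$n_set), sum(unclass(fx$ves)))
  expect_equal(attr(dmv, "global_fraction"), sum(fx$ves) / length(fx$ves))
})

test_that("superior tiles are denser than inferior tiles on the synthetic node", {
  fx <- node_analysis()
  dmv <- fractional_volume_map(fx$ves, c(32, 32))
  b_tile <- fx$nv$truth$boundary_row / 32
  sup <- dmv$fraction[dmv$tile_row <= floor(b_tile)]
  inf <- dmv$fraction[dmv$tile_row > ceiling(b_tile)]
  expect_gt(mean(sup), mean(inf))
})

test_that("distance transform matches hand values and errors on empty vessels", {
  v <- array(FALSE, c(3, 3, 3)); v[2, 2, 2] <- TRUE
  m <- array(TRUE, c(3, 3, 3))
  dm <- distance_transform(m, v, c(0.5, 0.5, 0.5))
  expect_identical(dm[2, 2, 2], 0)            # overlap voxel
  expect_identical(dm[1, 2, 2], 0.5)          # face-adjacent at 0.5 um
  expect_equal(dm[1, 1, 1], sqrt(3) * 0.5)
  expect_error(distance_transform(m, array(FALSE, c(3, 3, 3)), c(1, 1, 1)),
               "empty")
})

test_that("distance transform equals the brute-force oracle on random volumes", {
  set.seed(42)
  for (rep in 1:12) {
    d <- sample(4:15, 3, replace = TRUE)
    v <- array(runif(prod(d)) < 0.08, d)
    if (!any(v)) v[1, 1, 1] <- TRUE
    m <- array(runif(prod(d)) < 0.5, d)
    if (!any(m)) m[d[1], d[2], d[3]] <- TRUE
    vs <- runif(3, 0.3, 2)
    got <- distance_transform(m, v, vs)
    want <- brute_force_edt(m, v, vs)
    expect_equal(got[!is.na(got)], want[!is.na(want)], tolerance = 1e-12)
    expect_true(all(is.na(got[!m])))
  }
})

test_that("distance profile reports per-row mean, SEM and missing rows", {
  d <- array(NA_real_, c(2, 6, 4))
  d[, 1:3, ] <- 3
  d[, 5:6, ] <- 7       # row 4 has no myocyte voxels
  dm <- structure(d, voxel_size_um = c(1, 1, 1),
                  class = c("san_distance_map", "array"))
  prof <- distance_profile(dm)
  expect_identical(prof$mean_um[1:3], rep(3, 3))
  expect_identical(prof$sem_um[1], 0)
  expect_identical(prof$n[4], 0L)
  expect_true(is.na(prof$mean_um[4]))
  expect_identical(prof$mean_um[5:6], rep(7, 2))
  expect_error(distance_profile(structure(array(NA_real_, c(2, 2, 2)),
                                          voxel_size_um = c(1, 1, 1),
                                          class = c("san_distance_map", "array"))),
               "no myocyte")
})

test_that("boundary fit recovers a noiseless logistic and flags flat profiles", {
  x <- 1:100
  y <- 2 + (8 - 2) / (1 + exp(-0.5 * (x - 40)))
  prof <- tibble::tibble(row = x, mean_um = y, sem_um = 0, n = 100L)
  attr(prof, "axis_length_rows") <- 100
  fit <- fit_region_boundary(prof)
  expect_false(fit$degenerate)
  expect_lt(abs(fit$boundary_row - 40), 0.5)
  flat <- tibble::tibble(row = x, mean_um = rep(5, 100), sem_um = 0, n = 100L)
  ffit <- fit_region_boundary(flat)
  expect_true(ffit$degenerate)
  expect_true(is.na(ffit$boundary_row))
})

test_that("boundary recovery holds across boundary fractions and seeds", {
  # default generator conditions across the plausible boundary placements
  cases <- expand.grid(bf = c(0.4, 0.5, 0.6, 0.7), seed = 1:5)
  for (i in seq_len(nrow(cases))) {
    cfg <- node_volume_config(boundary_fraction = cases$bf[i],
                              seed = 2000 + cases$seed[i])
    nv <- gen_node_volume(cfg)
    dmap <- distance_transform(
      threshold_mask(nv$volume, "myocyte", "fixed", 0.5),
      threshold_mask(nv$volume, "vessel", "fixed", 0.5)
    )
    fit <- fit_region_boundary(distance_profile(dmap))
    expect_lt(abs(fit$superior_fraction - cases$bf[i]), 0.05,
              label = sprintf("bf=%.1f seed=%d: |%.3f - %.1f|", cases$bf[i],
                              cases$seed[i], fit$superior_fraction, cases$bf[i]))
  }
})

test_that("region split is exhaustive, disjoint and follows the boundary rule", {
  m <- array(TRUE, c(3, 10, 4))
  sp <- region_split(m, 1)
  expect_identical(dim(sp$superior)[2], 0L)    # boundary at row 1: all inferior
  expect_identical(dim(sp$inferior)[2], 10L)
  sp2 <- region_split(m, 11)
  expect_identical(dim(sp2$superior)[2], 10L)  # boundary past the end: all superior
  sp3 <- region_split(m, 4)
  expect_identical(dim(sp3$superior)[2] + dim(sp3$inferior)[2], 10L)
  tb <- tibble::tibble(row = 1:10, x = 1:10)
  sp4 <- region_split(tb, 4)
  expect_identical(nrow(sp4$superior), 3L)     # rows 1-3; row 4 is inferior
  expect_identical(sp4$inferior$row[1], 4L)
})

test_that("distance ECDF is a proper CDF and separates the regions", {
  fx <- node_analysis()
  ec <- distance_ecdf(fx$dmap, fx$nv$truth$boundary_row)
  for (rg in c("superior", "inferior")) {
    cf <- ec$ecdf$cum_fraction[ec$ecdf$region == rg]
    expect_true(all(diff(cf) >= 0))
    expect_equal(cf[length(cf)], 1)
  }
  expect_lt(ec$summary$mean_um[ec$summary$region == "superior"],
            ec$summary$mean_um[ec$summary$region == "inferior"])
  # single value => step ECDF
  one <- structure(array(c(2.5, rep(NA, 7)), c(2, 2, 2)),
                   voxel_size_um = c(1, 1, 1),
                   class = c("san_distance_map", "array"))
  ec1 <- distance_ecdf(one, 3)
  expect_identical(ec1$ecdf$cum_fraction, 1)
  expect_identical(ec1$ecdf$distance_um, 2.5)
  expect_true(ec1$summary$empty[ec1$summary$region == "inferior"])
})

test_that("regional distance means match a brute-force oracle on a small node", {
  cfg <- node_volume_config(shape = c(16, 60, 60),
                            artery_diameter_superior_um = 7,
                            artery_diameter_inferior_um = 5.5,
                            branch_counts = c(1, 2, 2), seed = 77)
  nv <- gen_node_volume(cfg)
  myo <- threshold_mask(nv$volume, "myocyte", "fixed", 0.5)
  ves <- threshold_mask(nv$volume, "vessel", "fixed", 0.5)
  dmap <- distance_transform(myo, ves)
  ec <- distance_ecdf(dmap, nv$truth$boundary_row)
  # oracle on a voxel subsample
  set.seed(1)
  idx <- sample(which(unclass(myo)), 300)
  co_v <- which(unclass(ves), arr.ind = TRUE)
  d <- dim(myo)
  bf <- vapply(idx, function(i) {
    p <- arrayInd(i, d)
    sqrt(min((co_v[, 1] - p[1])^2 + (co_v[, 2] - p[2])^2 + (co_v[, 3] - p[3])^2))
  }, numeric(1))
  rows <- arrayInd(idx, d)[, 2]
  b <- nv$truth$boundary_row
  expect_equal(ec$summary$mean_um[1], mean(bf[rows < b]), tolerance = 0.1)
  expect_equal(ec$summary$mean_um[2], mean(bf[rows >= b]), tolerance = 0.1)
  expect_lt(ec$summary$mean_um[1], ec$summary$mean_um[2])
})

test_that("a straight tube skeletonizes to one segment of the right length", {
  m <- make_tube(c(11, 50, 11), radius = 1.4)
  g <- skeletonize_vessels(san_mask(m, c(1, 1, 1)))
  expect_identical(nrow(g$segments), 1L)
  # thin tube: end erosion is at most ~radius per end
  expect_lt(abs(g$segments$length_um - 49), 4)
})

test_that("a Y-shaped vessel gives three segments around one junction", {
  dims <- c(17, 70, 40)
  m <- make_tube(dims, radius = 3, c0 = 12)
  # thinner side branch leaving the main tube at row 35
  for (s in 0:24) {
    r <- 35 + s; c0 <- 12 + s
    if (r <= dims[2] && c0 <= dims[3]) {
      m[, r, ][outer((seq_len(dims[1]) - 9)^2, (seq_len(dims[3]) - c0)^2, "+") <= 4] <- TRUE
    }
  }
  g <- skeletonize_vessels(san_mask(m, c(1, 1, 1)))
  expect_identical(nrow(g$segments), 3L)
  expect_identical(sum(g$nodes$kind == "junction"), 1L)
  g <- vessel_diameters(g, m)
  g <- branch_orders(g)
  # the two collinear main pieces continue as order 1, the side branch is 2
  expect_identical(sort(g$segments$order), c(1L, 1L, 2L))
})

test_that("skeleton totals match generator ground truth within 15%", {
  for (s in c(2, 5)) {
    cfg <- node_volume_config(shape = c(48, 160, 160),
                              vessel_density_superior = NULL,
                              vessel_density_inferior = NULL,
                              branch_counts = c(3, 5, 0), seed = s)
    nv <- gen_node_volume(cfg)
    g <- skeletonize_vessels(threshold_mask(nv$volume, "vessel", "fixed", 0.5))
    expect_lt(abs(nrow(g$segments) / nv$truth$n_segments_topological - 1), 0.15)
    expect_lt(abs(sum(g$segments$length_um) /
                    nv$truth$centerline_length_um - 1), 0.15)
  }
})

test_that("skeleton length is invariant under translation and axis flips", {
  m <- make_tube(c(13, 40, 13), radius = 1.4)
  base <- sum(skeletonize_vessels(san_mask(m, c(1, 1, 1)))$segments$length_um)
  shifted <- array(FALSE, c(13, 46, 13))
  shifted[, 4 + seq_len(40), ] <- m
  flipped <- m[rev(seq_len(13)), rev(seq_len(40)), , drop = FALSE]
  diag_tol <- sqrt(3)
  expect_lt(abs(sum(skeletonize_vessels(san_mask(shifted, c(1, 1, 1)))$segments$length_um) - base), diag_tol)
  expect_lt(abs(sum(skeletonize_vessels(san_mask(flipped, c(1, 1, 1)))$segments$length_um) - base), diag_tol)
})

test_that("branch orders recover a planted three-level tree exactly", {
  # explicit tree with mid-segment attachments and ordered calibres:
  # artery (radius 5) along rows, 2-degree branch (radius 3) along cols from
  # its middle, 3-degree branch (radius 2) along z from the branch's middle
  dims <- c(31, 120, 70)
  m <- make_tube(dims, radius = 5, z0 = 16, c0 = 14)          # along rows
  zz <- slice.index(array(0, dims), 1)
  rr <- slice.index(array(0, dims), 2)
  cc <- slice.index(array(0, dims), 3)
  m[(zz - 16)^2 + (rr - 60)^2 <= 9 & cc >= 14 & cc <= 58] <- TRUE  # along cols
  m[(rr - 60)^2 + (cc - 36)^2 <= 4 & zz >= 16 & zz <= 29] <- TRUE  # along z
  g <- skeletonize_vessels(san_mask(m, c(1, 1, 1)))
  g <- vessel_diameters(g, m)
  g <- branch_orders(g, root_voxel = c(16, 1, 14))
  ord <- sort(stats::na.omit(g$segments$order))
  # artery split in two by the junction, branch split in two, one sub-branch
  expect_identical(ord, c(1L, 1L, 2L, 2L, 3L))
  expect_error(branch_orders(g, root_voxel = c(500, 500, 500)), "root")
})

test_that("branch orders on a generated vessel tree stay within the planted range", {
  cfg <- node_volume_config(shape = c(48, 160, 160),
                            vessel_density_superior = NULL,
                            vessel_density_inferior = NULL,
                            branch_counts = c(2, 3, 0), seed = 12)
  nv <- gen_node_volume(cfg)
  ves <- threshold_mask(nv$volume, "vessel", "fixed", 0.5)
  g <- branch_orders(vessel_diameters(skeletonize_vessels(ves), ves))
  ords <- stats::na.omit(g$segments$order)
  expect_true(all(ords >= 1 & ords <= max(nv$truth$segments$order)))
  expect_true(any(ords == 2))
  # the order-1 chain follows the artery for most of its length
  o1 <- sum(g$segments$length_um[g$segments$order == 1], na.rm = TRUE)
  expect_gt(o1, 0.8 * 160)
})

test_that("vessel diameters recover planted calibres and the artery taper", {
  tube <- make_tube(c(21, 40, 21), radius = 5)
  g <- vessel_diameters(skeletonize_vessels(san_mask(tube, c(1, 1, 1))), tube)
  expect_lt(abs(g$segments$mean_diameter_um[1] - 10), 1)
  # one-voxel-wide line at 0.5 um voxels ~ 1 um calibre
  line <- array(FALSE, c(9, 30, 9)); line[5, , 5] <- TRUE
  gl <- vessel_diameters(skeletonize_vessels(san_mask(line, c(0.5, 0.5, 0.5))),
                         line)
  expect_lt(abs(gl$segments$mean_diameter_um[1] - 1), 0.5)
  # tapering artery: superior half thicker than inferior half
  cfgd <- node_volume_config(
    shape = c(48, 120, 64), vessel_density_superior = NULL,
    vessel_density_inferior = NULL, branch_counts = c(0, 0, 0),
    artery_diameter_superior_um = 30.62, artery_diameter_inferior_um = 23.37,
    seed = 1
  )
  nvd <- gen_node_volume(cfgd)
  vesd <- threshold_mask(nvd$volume, "vessel", "fixed", 0.5)
  gd <- vessel_diameters(skeletonize_vessels(vesd), vesd)
  path <- gd$paths[[which.max(gd$segments$n_voxels)]]
  dvals <- 2 * gd$dist_bg[path[, 1] + 48 * (path[, 2] - 1) + 48 * 120 * (path[, 3] - 1)]
  sup_mean <- mean(dvals[path[, 2] < 60])
  inf_mean <- mean(dvals[path[, 2] >= 60])
  expect_gt(sup_mean, inf_mean)
})
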