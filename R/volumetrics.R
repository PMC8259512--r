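#' Threshold an image channel into a binary mask
#'
#' @param volume a [san_volume()].
#' @param channel `"myocyte"` or `"vessel"`.
#' @param method `"fixed"` (absolute intensity), `"otsu"` (between-class
#'   variance maximisation on a 256-bin histogram) or `"percentile"`.
#' @param value threshold for `"fixed"`, or the percentile in (0, 1) for
#'   `"percentile"`.
#' @return A [san_mask()] carrying provenance (channel, method, threshold).
#' @export
threshold_mask <- function(volume, channel = c("myocyte", "vessel"),
                           method = c("fixed", "otsu", "percentile"),
                           value = 0.5) {
  stopifnot(inherits(volume, "san_volume"))
  channel <- match.arg(channel)
  method <- match.arg(method)
  x <- volume[[channel]]
  if (length(x) == 0) stop("empty channel")
  thr <- switch(method,
    fixed = value,
    percentile = quantile(x, probs = value, names = FALSE),
    otsu = {
      rng <- range(x)
      if (diff(rng) == 0) stop("otsu thresholding needs a non-flat channel")
      otsu_threshold(x)
    }
  )
  san_mask(x >= thr, volume$voxel_size_um, channel = channel,
           method = method, value = thr)
}

# Otsu's method on a 256-bin histogram
otsu_threshold <- function(x) {
  rng <- range(x)
  h <- tabulate(pmin(256L, floor((x - rng[1]) / diff(rng) * 256) + 1L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- seq(0.5, 255.5) / 256
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  rng[1] + k / 256 * diff(rng)
}

#' Fractional-volume density map
#'
#' Tiles the volume in-plane (full z per tile) and reports the fractional
#' volume of the mask in each tile: set voxels / total voxels, counted exactly
#' (edge tiles are truncated, not padded).
#'
#' @param mask a [san_mask()] or logical 3D array.
#' @param tile_shape in-plane tile size in voxels `(row, col)`.
#' @return A tibble of class `san_density_map` with columns `tile_row`,
#'   `tile_col`, `row_start`, `col_start`, `n_voxels`, `n_set`, `fraction`;
#'   the global fraction is available as attribute `global_fraction`.
#' @export
fractional_volume_map <- function(mask, tile_shape = c(32, 32)) {
  m <- unclass(mask)
  stopifnot(length(dim(m)) == 3)
  d <- dim(m)
  tr <- tile_shape[1]
  tc <- tile_shape[2]
  row_bins <- ceiling(d[2] / tr)
  col_bins <- ceiling(d[3] / tc)
  # collapse z, then aggregate in-plane counts per tile
  plane <- apply(m, c(2, 3), sum)
  out <- expand.grid(tile_row = seq_len(row_bins), tile_col = seq_len(col_bins))
  out$row_start <- (out$tile_row - 1L) * tr + 1L
  out$col_start <- (out$tile_col - 1L) * tc + 1L
  out$n_set <- mapply(function(r0, c0) {
    sum(plane[r0:min(r0 + tr - 1L, d[2]), c0:min(c0 + tc - 1L, d[3])])
  }, out$row_start, out$col_start)
  out$n_voxels <- mapply(function(r0, c0) {
    d[1] * length(r0:min(r0 + tr - 1L, d[2])) * length(c0:min(c0 + tc - 1L, d[3]))
  }, out$row_start, out$col_start)
  out$fraction <- out$n_set / out$n_voxels
  out <- tibble::as_tibble(out[c("tile_row", "tile_col", "row_start",
                                 "col_start", "n_voxels", "n_set", "fraction")])
  attr(out, "global_fraction") <- sum(m) / length(m)
  attr(out, "tile_shape") <- c(tr, tc)
  class(out) <- c("san_density_map", class(out))
  out
}

#' Anisotropic 3D Euclidean distance transform (myocyte to nearest vessel)
#'
#' Exact Euclidean distance, in micrometres, from each myocyte voxel to the
#' nearest vessel voxel, honouring per-axis voxel spacing. Non-myocyte voxels
#' are `NA`.
#'
#' @param myocyte_mask,vessel_mask logical 3D arrays of identical shape
#'   ([san_mask()] or plain arrays).
#' @param voxel_size_um micrometres per voxel `(z, row, col)`; taken from the
#'   mask attribute when omitted.
#' @return A `san_distance_map`: numeric 3D array (um; `NA` outside the
#'   myocyte mask) with attribute `voxel_size_um`.
#' @export
distance_transform <- function(myocyte_mask, vessel_mask, voxel_size_um = NULL) {
  voxel_size_um <- voxel_size_um %||% attr(myocyte_mask, "voxel_size_um")
  if (is.null(voxel_size_um)) stop("voxel_size_um required")
  m <- unclass(myocyte_mask)
  v <- unclass(vessel_mask)
  if (!identical(dim(m), dim(v))) stop("masks must have identical shape")
  if (!any(v)) stop("vessel mask is empty: distances are undefined")
  d <- .edt3d_cpp(as.logical(v), dim(v), as.numeric(voxel_size_um))
  d[!m] <- NA_real_
  structure(d, voxel_size_um = as.numeric(voxel_size_um),
            class = c("san_distance_map", "array"))
}

#' Per-row myocyte-to-vessel distance profile along the node axis
#'
#' @param dmap a `san_distance_map` from [distance_transform()].
#' @param row_bin number of voxel rows aggregated per profile row.
#' @return A tibble of class `san_distance_profile`: `row` (bin index),
#'   `row_center_voxel`, `position_um` (bin centre along the node axis),
#'   `mean_um`, `sem_um`, `n`. Rows without myocyte voxels have `NA` mean and
#'   are flagged by `n = 0`.
#' @export
distance_profile <- function(dmap, row_bin = 1L) {
  stopifnot(inherits(dmap, "san_distance_map"))
  if (all(is.na(dmap))) stop("distance map holds no myocyte voxels")
  vs <- attr(dmap, "voxel_size_um")
  d <- dim(dmap)
  bins <- ceiling(d[2] / row_bin)
  bin_of <- rep(seq_len(bins), each = row_bin, length.out = d[2])
  res <- lapply(seq_len(bins), function(b) {
    vals <- dmap[, bin_of == b, ]
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    tibble::tibble(
      row = b,
      row_center_voxel = mean(which(bin_of == b)),
      position_um = (mean(which(bin_of == b)) - 0.5) * vs[2],
      mean_um = if (n > 0) mean(vals) else NA_real_,
      sem_um = if (n > 1) sd(vals) / sqrt(n) else NA_real_,
      n = n
    )
  })
  out <- dplyr::bind_rows(res)
  attr(out, "axis_length_rows") <- bins
  attr(out, "voxel_size_um") <- vs
  class(out) <- c("san_distance_profile", class(out))
  out
}

#' Fit the sigmoidal superior/inferior boundary to a distance profile
#'
#' Fits a 4-parameter logistic
#' \deqn{d(x) = d_{sup} + (d_{inf} - d_{sup}) / (1 + e^{-k (x - x_0)})}
#' to the per-row mean myocyte-to-vessel distance by least squares. The
#' boundary row is the inflection \eqn{x_0}: rows before it belong to the
#' superior region (shorter distances), rows after to the inferior region.
#'
#' @param profile a [distance_profile()] tibble (or any tibble with `row` and
#'   `mean_um`).
#' @return A `san_boundary_fit` (wraps the underlying [fit_logistic4()]):
#'   access the boundary with `$boundary_row`, the superior fraction with
#'   `$superior_fraction`, diagnostics via [glance()].
#' @export
fit_region_boundary <- function(profile) {
  ok <- !is.na(profile$mean_um) & profile$n > 0
  if (sum(ok) < 8) stop("need at least 8 non-missing profile rows")
  fit <- fit_logistic4(profile$row[ok], profile$mean_um[ok])
  n_rows <- attr(profile, "axis_length_rows") %||% max(profile$row)
  boundary <- unname(fit$parameters["x0"])
  if (fit$degenerate || is.na(boundary) ||
      boundary < min(profile$row) || boundary > max(profile$row)) {
    boundary <- NA_real_
  }
  structure(
    list(
      fit = fit,
      boundary_row = boundary,
      superior_fraction = boundary / n_rows,
      d_sup = unname(fit$parameters["lower"]),
      d_inf = unname(fit$parameters["upper"]),
      steepness = unname(fit$parameters["k"]),
      degenerate = fit$degenerate,
      converged = fit$converged,
      profile = profile
    ),
    class = "san_boundary_fit"
  )
}

#' @export
print.san_boundary_fit <- function(x, ...) {
  if (is.na(x$boundary_row)) {
    cat("<san_boundary_fit> degenerate (no boundary)\n")
  } else {
    cat(sprintf(
      "<san_boundary_fit> boundary at row %.1f (superior fraction %.1f%%), d_sup %.2f um, d_inf %.2f um\n",
      x$boundary_row, 100 * x$superior_fraction, x$d_sup, x$d_inf
    ))
  }
  invisible(x)
}

#' @export
tidy.san_boundary_fit <- function(x, ...) tidy(x$fit, ...)

#' @export
glance.san_boundary_fit <- function(x, ...) {
  tibble::tibble(
    boundary_row = x$boundary_row,
    superior_fraction = x$superior_fraction,
    d_sup_um = x$d_sup, d_inf_um = x$d_inf, steepness = x$steepness,
    rss = x$fit$rss, converged = x$converged, degenerate = x$degenerate,
    n = x$fit$n
  )
}

#' Split a volume, mask, distance map or per-row table at a boundary row
#'
#' Rows strictly before the boundary are superior; the boundary row itself and
#' everything after it are inferior. The split is exhaustive and disjoint.
#'
#' @param x a 3D array ([san_mask()], `san_distance_map`, channel array) or a
#'   data frame with a `row` column.
#' @param boundary_row the boundary (rows `>= boundary_row` are inferior).
#' @return A list with elements `superior` and `inferior`.
#' @export
region_split <- function(x, boundary_row) {
  if (is.data.frame(x)) {
    sup <- x[x$row < boundary_row, , drop = FALSE]
    inf <- x[x$row >= boundary_row, , drop = FALSE]
    return(list(superior = sup, inferior = inf))
  }
  d <- dim(x)
  stopifnot(length(d) == 3)
  rows <- seq_len(d[2])
  keep_attrs <- function(sub) {
    attr(sub, "voxel_size_um") <- attr(x, "voxel_size_um")
    class(sub) <- class(x)
    sub
  }
  list(
    superior = keep_attrs(x[, rows[rows < boundary_row], , drop = FALSE]),
    inferior = keep_attrs(x[, rows[rows >= boundary_row], , drop = FALSE])
  )
}

#' Per-region cumulative distribution of myocyte-to-vessel distances
#'
#' @param dmap a `san_distance_map`.
#' @param boundary_row boundary row (voxel units) separating superior from
#'   inferior; e.g. from [fit_region_boundary()] (converted to voxel rows if
#'   the profile was binned).
#' @return A list of class `san_distance_ecdf`: `ecdf` tibble (`region`,
#'   `distance_um`, `cum_fraction`) and `summary` tibble (`region`, `mean_um`,
#'   `median_um`, `n`, `empty` flag).
#' @export
distance_ecdf <- function(dmap, boundary_row) {
  stopifnot(inherits(dmap, "san_distance_map"))
  parts <- region_split(dmap, boundary_row)
  mk <- function(region, vals) {
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) {
      return(list(
        ecdf = tibble::tibble(region = character(0), distance_um = numeric(0),
                              cum_fraction = numeric(0)),
        summary = tibble::tibble(region = region, mean_um = NA_real_,
                                 median_um = NA_real_, n = 0L, empty = TRUE)
      ))
    }
    s <- sort(vals)
    list(
      ecdf = tibble::tibble(
        region = region, distance_um = s,
        cum_fraction = seq_along(s) / length(s)
      ),
      summary = tibble::tibble(
        region = region, mean_um = mean(s), median_um = median(s),
        n = length(s), empty = FALSE
      )
    )
  }
  sup <- mk("superior", parts$superior)
  inf <- mk("inferior", parts$inferior)
  structure(
    list(
      ecdf = dplyr::bind_rows(sup$ecdf, inf$ecdf),
      summary = dplyr::bind_rows(sup$summary, inf$summary)
    ),
    class = "san_distance_ecdf"
  )
}

# ---------------------------------------------------------------------------
# Vessel skeleton and graph
# ---------------------------------------------------------------------------

#' Skeletonize a vessel mask into a segment graph
#'
#' Thins the vessel mask to a one-voxel curve skeleton (sequential
#' simple-point thinning with 26-connectivity for the object and
#' 6-connectivity for the background, eroding from the outside in by distance
#' to background), then traces the skeleton into segments between junction
#' and endpoint nodes. Segment lengths are polyline lengths in micrometres
#' using anisotropic step lengths. Segments shorter than `prune_voxels`
#' skeleton voxels that dead-end at an endpoint are pruned as thinning spurs.
#'
#' @param vessel_mask a [san_mask()] (or logical 3D array plus
#'   `voxel_size_um`).
#' @param voxel_size_um micrometres per voxel; defaults to the mask attribute.
#' @param prune_voxels spur-pruning threshold (skeleton voxels).
#' @return A `san_vessel_graph`: list with `nodes` tibble (`node_id`, `kind`,
#'   `z`, `row`, `col` in voxels), `segments` tibble (`segment_id`,
#'   `from_node`, `to_node`, `n_voxels`, `length_um`, `order`,
#'   `mean_diameter_um`), `paths` (list of voxel-coordinate matrices) and the
#'   skeleton mask.
#' @export
skeletonize_vessels <- function(vessel_mask, voxel_size_um = NULL,
                                prune_voxels = 3L) {
  voxel_size_um <- voxel_size_um %||% attr(vessel_mask, "voxel_size_um")
  if (is.null(voxel_size_um)) stop("voxel_size_um required")
  m <- unclass(vessel_mask)
  storage.mode(m) <- "logical"
  if (!any(m)) stop("vessel mask is empty")
  # erode outside-in: priority = distance to background
  dist_bg <- .edt3d_cpp(!m, dim(m), as.numeric(voxel_size_um))
  skel <- .skeletonize3d_cpp(m, dim(m), as.numeric(dist_bg))
  g <- trace_skeleton(skel, voxel_size_um, prune_voxels)
  g$skeleton <- skel
  g$voxel_size_um <- as.numeric(voxel_size_um)
  g$dist_bg <- dist_bg
  class(g) <- "san_vessel_graph"
  g
}

#' @export
print.san_vessel_graph <- function(x, ...) {
  cat(sprintf(
    "<san_vessel_graph> %d segments, %d nodes, total length %.1f um\n",
    nrow(x$segments), nrow(x$nodes), sum(x$segments$length_um)
  ))
  invisible(x)
}

# trace a 1-voxel skeleton into nodes + segments (26-connectivity)
trace_skeleton <- function(skel, vs, prune_voxels) {
  idx <- which(skel)
  d <- dim(skel)
  if (length(idx) == 0) stop("skeleton is empty")
  co <- arrayInd(idx, d)          # z, row, col
  offs <- as.matrix(expand.grid(dz = -1:1, dr = -1:1, dc = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nbr_mat <- matrix(NA_integer_, length(idx), nrow(offs))
  for (o in seq_len(nrow(offs))) {
    zz <- co[, 1] + offs[o, 1]
    rr <- co[, 2] + offs[o, 2]
    cc <- co[, 3] + offs[o, 3]
    ok <- zz >= 1 & zz <= d[1] & rr >= 1 & rr <= d[2] & cc >= 1 & cc <= d[3]
    nl <- ifelse(ok, zz + d[1] * (rr - 1) + d[1] * d[2] * (cc - 1), NA_real_)
    nbr_mat[, o] <- match(nl, idx)
  }
  nbrs <- apply(nbr_mat, 1, function(r) r[!is.na(r)], simplify = FALSE)
  deg <- lengths(nbrs)
  is_node <- deg != 2L
  step_len <- function(a, b) {
    sqrt(sum(((co[a, ] - co[b, ]) * vs)^2))
  }

  seg_list <- list()
  path_list <- list()
  visited_edge <- new.env(hash = TRUE)
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  trace_from <- function(start, nxt) {
    path <- c(start, nxt)
    while (!is_node[path[length(path)]]) {
      cur <- path[length(path)]
      if (cur == start) break  # closed loop with no junctions
      prev <- path[length(path) - 1]
      following <- setdiff(nbrs[[cur]], prev)
      if (length(following) == 0) break
      path <- c(path, following[1])
    }
    path
  }
  node_ids <- which(is_node)
  for (a in node_ids) {
    for (b in nbrs[[a]]) {
      ek <- edge_key(a, b)
      if (!is.null(visited_edge[[ek]])) next
      path <- trace_from(a, b)
      # mark traversed elementary edges
      for (j in seq_len(length(path) - 1)) {
        visited_edge[[edge_key(path[j], path[j + 1])]] <- TRUE
      }
      seg_list[[length(seg_list) + 1]] <- path
    }
  }
  # isolated cycles (all degree-2): pick any unvisited voxel and walk
  unseen <- setdiff(which(deg == 2L), unique(unlist(seg_list)))
  while (length(unseen) > 0) {
    a <- unseen[1]
    b <- nbrs[[a]][1]
    path <- trace_from(a, b)
    seg_list[[length(seg_list) + 1]] <- path
    unseen <- setdiff(unseen, path)
  }

  # prune short spurs: few voxels and at least one free end (degree-1 tip)
  keep <- vapply(seg_list, function(p) {
    tip <- deg[p[1]] == 1L || deg[p[length(p)]] == 1L
    !(tip && length(p) < prune_voxels + 1L)
  }, logical(1))
  if (!any(keep)) keep[which.max(lengths(seg_list))] <- TRUE
  seg_list <- seg_list[keep]

  # node table: group junction voxels that are 26-adjacent into single nodes
  ends <- unique(unlist(lapply(seg_list, function(p) c(p[1], p[length(p)]))))
  node_group <- setNames(seq_along(ends), ends)
  for (a in ends) {
    for (b in intersect(nbrs[[a]], ends)) {
      ga <- node_group[[as.character(a)]]
      gb <- node_group[[as.character(b)]]
      if (ga != gb) node_group[node_group == gb] <- ga
    }
  }
  group_ids <- unique(node_group)
  remap <- setNames(seq_along(group_ids), group_ids)
  node_of_voxel <- setNames(remap[as.character(node_group)], names(node_group))

  nodes <- dplyr::bind_rows(lapply(seq_along(group_ids), function(g) {
    vox <- as.integer(names(node_group)[node_group == group_ids[g]])
    kind <- if (any(deg[vox] >= 3L)) "junction" else "endpoint"
    tibble::tibble(
      node_id = g, kind = kind,
      z = mean(co[vox, 1]), row = mean(co[vox, 2]), col = mean(co[vox, 3])
    )
  }))

  segments <- dplyr::bind_rows(lapply(seq_along(seg_list), function(s) {
    p <- seg_list[[s]]
    len <- sum(vapply(seq_len(length(p) - 1),
                      function(j) step_len(p[j], p[j + 1]), numeric(1)))
    tibble::tibble(
      segment_id = s,
      from_node = unname(node_of_voxel[as.character(p[1])]),
      to_node = unname(node_of_voxel[as.character(p[length(p)])]),
      n_voxels = length(p),
      length_um = len,
      order = NA_integer_,
      mean_diameter_um = NA_real_
    )
  }))
  # drop micro-segments internal to a fused junction cluster
  micro <- segments$from_node == segments$to_node & segments$n_voxels <= 3L
  segments <- segments[!micro, , drop = FALSE]
  seg_list <- seg_list[!micro]
  segments$segment_id <- seq_len(nrow(segments))
  list(
    nodes = nodes, segments = segments,
    paths = lapply(seg_list, function(p) co[p, , drop = FALSE])
  )
}

#' Assign branch orders to vessel segments
#'
#' The primary artery path through the skeleton is order 1; at each junction,
#' the continuation that best preserves the parent's calibre keeps the
#' parent's order and the remaining children are one order higher. Segments
#' not reachable from the root keep `NA` (flagged unreachable).
#'
#' @param graph a `san_vessel_graph` (diameters are computed first if absent,
#'   via [vessel_diameters()] when `vessel_mask` is supplied).
#' @param root_voxel `(z, row, col)` voxel coordinate of the artery root; by
#'   default the skeleton node closest to the superior (row 1) face.
#' @param vessel_mask optional mask used to fill diameters when missing.
#' @return The graph with `segments$order` populated.
#' @export
branch_orders <- function(graph, root_voxel = NULL, vessel_mask = NULL) {
  stopifnot(inherits(graph, "san_vessel_graph"))
  if (all(is.na(graph$segments$mean_diameter_um)) && !is.null(vessel_mask)) {
    graph <- vessel_diameters(graph, vessel_mask)
  }
  nodes <- graph$nodes
  if (is.null(root_voxel)) {
    root <- nodes$node_id[which.min(nodes$row)]
  } else {
    dd <- (nodes$z - root_voxel[1])^2 + (nodes$row - root_voxel[2])^2 +
      (nodes$col - root_voxel[3])^2
    root <- nodes$node_id[which.min(dd)]
    if (min(dd) > 20^2) stop("root voxel is not near any skeleton node")
  }
  segs <- graph$segments
  segs$order <- NA_integer_
  # breadth-first over segments; the largest-diameter child continues the
  # parent's order, others increment
  frontier <- list()
  inc <- which(segs$from_node == root | segs$to_node == root)
  for (i in inc) frontier[[length(frontier) + 1]] <-
    list(seg = i, ord = 1L, from = root)
  while (length(frontier) > 0) {
    item <- frontier[[1]]
    frontier <- frontier[-1]
    i <- item$seg
    if (!is.na(segs$order[i])) next
    segs$order[i] <- item$ord
    far <- if (segs$from_node[i] == item$from) segs$to_node[i] else segs$from_node[i]
    children <- which((segs$from_node == far | segs$to_node == far) &
                        is.na(segs$order))
    children <- setdiff(children, i)
    if (length(children) == 0) next
    dia <- segs$mean_diameter_um[children]
    cont <- if (all(is.na(dia))) children[1] else children[which.max(dia)]
    for (ch in children) {
      ord <- if (ch == cont) item$ord else item$ord + 1L
      frontier[[length(frontier) + 1]] <- list(seg = ch, ord = ord, from = far)
    }
  }
  graph$segments <- segs
  graph$root_node <- root
  graph
}

#' Per-segment mean vessel diameter
#'
#' Diameter at a skeleton voxel is twice its Euclidean distance to the nearest
#' background voxel; segment diameter is the mean along the segment path.
#'
#' @param graph a `san_vessel_graph`.
#' @param vessel_mask the mask the skeleton came from.
#' @return The graph with `segments$mean_diameter_um` populated.
#' @export
vessel_diameters <- function(graph, vessel_mask) {
  stopifnot(inherits(graph, "san_vessel_graph"))
  m <- unclass(vessel_mask)
  storage.mode(m) <- "logical"
  dist_bg <- graph$dist_bg
  if (is.null(dist_bg) || !identical(dim(dist_bg), dim(m))) {
    dist_bg <- .edt3d_cpp(!m, dim(m), graph$voxel_size_um)
  }
  d <- dim(m)
  graph$segments$mean_diameter_um <- vapply(graph$paths, function(p) {
    lin <- p[, 1] + d[1] * (p[, 2] - 1) + d[1] * d[2] * (p[, 3] - 1)
    mean(2 * dist_bg[lin])
  }, numeric(1))
  graph
}
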