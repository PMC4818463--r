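#' Kernel utilisation-distribution surface for one movement segment
#'
#' Bivariate Gaussian kernel density of the segment's fixes on a regular
#' grid, padded at least three bandwidths beyond the fixes' bounding box and
#' normalised to integrate to one.  The default per-axis bandwidth is the
#' bivariate normal reference (Silverman) rule `sd * n^(-1/6)`.
#'
#' @param x,y planar fix coordinates (m).
#' @param bandwidth length-2 bandwidth (m) or `NULL` for the reference rule.
#' @param cell grid cell size in metres (default 100, below the smallest FPT
#'   radius).
#' @return a `density_grid`: list with cell-centre coordinate vectors `xg`,
#'   `yg`, `cell`, bandwidth `h`, and density matrix `z` (rows follow `xg`).
#' @export
estimate_density <- function(x, y, bandwidth = NULL, cell = 100) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  n <- length(x)
  if (is.null(bandwidth)) {
    bandwidth <- c(sd(x), sd(y)) * n^(-1 / 6)
    if (any(!is.finite(bandwidth) | bandwidth <= 0)) bandwidth <- c(0, 0)
  }
  if (all(bandwidth <= 0) || (diff(range(x)) == 0 && diff(range(y)) == 0 &&
                              all(bandwidth == 0))) {
    # degenerate cloud: all mass in the single cell containing the fixes
    warning("degenerate fixes (zero spread); returning single-cell mass")
    xg <- mean(x) + cell * (-2:2)
    yg <- mean(y) + cell * (-2:2)
    z <- matrix(0, 5, 5)
    z[3, 3] <- 1 / cell^2
    return(structure(list(xg = xg, yg = yg, cell = cell, h = bandwidth, z = z),
                     class = "density_grid"))
  }
  bandwidth <- pmax(bandwidth, cell / 2)  # resolvable on the grid
  pad <- 3.5 * bandwidth
  xg <- .grid_axis(range(x) + c(-1, 1) * pad[1], cell)
  yg <- .grid_axis(range(y) + c(-1, 1) * pad[2], cell)
  # MASS::kde2d uses normal kernels with sd = h/4
  kd <- MASS::kde2d(x, y, h = 4 * bandwidth, n = c(length(xg), length(yg)),
                    lims = c(range(xg), range(yg)))
  z <- kd$z / (sum(kd$z) * cell^2)
  structure(list(xg = kd$x, yg = kd$y, cell = cell, h = bandwidth, z = z),
            class = "density_grid")
}

.grid_axis <- function(rng, cell) {
  lo <- floor(rng[1] / cell) * cell
  hi <- ceiling(rng[2] / cell) * cell
  seq(lo, hi, by = cell)
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("<density_grid: %d x %d cells of %g m, h = (%.0f, %.0f) m>\n",
              length(x$xg), length(x$yg), x$cell, x$h[1], x$h[2]))
  invisible(x)
}

#' Isopleth polygons of a utilisation distribution
#'
#' Finds the smallest density superlevel set holding at least `level` of the
#' total mass (the conventional home-range isopleth) and vectorises its
#' boundary with contour tracing.  Each connected component becomes one
#' polygon; rings nested inside another ring an odd number of times are holes
#' of their enclosing ring.
#'
#' @param grid a `density_grid`.
#' @param level isopleth mass fraction in (0, 1); default 0.95.
#' @return list of polygons; each polygon is a list with `rings` (list of
#'   two-column coordinate matrices, outer ring first) and `area_m2`.
#' @export
isopleth_polygons <- function(grid, level = 0.95) {
  if (!(level > 0 && level < 1)) stop("isopleth level must be in (0, 1)")
  dens <- sort(as.vector(grid$z), decreasing = TRUE)
  mass <- cumsum(dens) * grid$cell^2
  thr <- dens[which(mass >= level)[1]]
  if (is.na(thr)) thr <- dens[length(dens)]
  cl <- grDevices::contourLines(grid$xg, grid$yg, grid$z,
                                levels = thr * (1 - 1e-9))
  rings <- lapply(cl, function(r) cbind(r$x, r$y))
  rings <- lapply(rings, .close_ring)
  if (!length(rings)) {  # threshold below every cell: whole padded support
    xr <- range(grid$xg) + c(-0.5, 0.5) * grid$cell
    yr <- range(grid$yg) + c(-0.5, 0.5) * grid$cell
    ring <- cbind(c(xr[1], xr[2], xr[2], xr[1], xr[1]),
                  c(yr[1], yr[1], yr[2], yr[2], yr[1]))
    return(list(list(rings = list(ring), area_m2 = diff(xr) * diff(yr))))
  }
  .assemble_polygons(rings)
}

.close_ring <- function(m) {
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

.ring_area <- function(m) {
  # shoelace, absolute value
  x <- m[, 1]; y <- m[, 2]
  n <- nrow(m)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

.point_in_ring <- function(px, py, ring) {
  # even-odd ray casting; points on the boundary count as inside
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring) - 1
  inside <- rep(FALSE, length(px))
  for (i in seq_len(n)) {
    x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1]; y2 <- y[i + 1]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xint <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- crosses
      hit[crosses] <- px[crosses] < xint
      inside <- xor(inside, hit)
    }
  }
  inside
}

.assemble_polygons <- function(rings) {
  k <- length(rings)
  depth <- integer(k)
  parent <- rep(NA_integer_, k)
  areas <- vapply(rings, .ring_area, numeric(1))
  for (i in seq_len(k)) {
    p <- rings[[i]][1, ]
    for (j in seq_len(k)) {
      if (i != j && areas[j] > areas[i] &&
          .point_in_ring(p[1], p[2], rings[[j]])) {
        depth[i] <- depth[i] + 1L
        if (is.na(parent[i]) || areas[j] < areas[parent[i]]) parent[i] <- j
      }
    }
  }
  outers <- which(depth %% 2L == 0L)
  polys <- lapply(outers, function(o) {
    holes <- which(depth %% 2L == 1L & parent == o)
    list(rings = c(rings[o], rings[holes]),
         area_m2 = areas[o] - sum(areas[holes]))
  })
  polys[order(vapply(polys, `[[`, numeric(1), "area_m2"), decreasing = TRUE)]
}

#' Point-in-polygon membership
#'
#' Even-odd rule over all rings of the polygon (so holes exclude); boundary
#' points count as inside.
#'
#' @param px,py point coordinates.
#' @param polygon a polygon as returned by [isopleth_polygons()].
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, polygon) {
  inside <- rep(FALSE, length(px))
  for (ring in polygon$rings)
    inside <- xor(inside, .point_in_ring(px, py, ring))
  inside | .on_boundary(px, py, polygon)
}

.on_boundary <- function(px, py, polygon, tol = 1e-9) {
  on <- rep(FALSE, length(px))
  for (ring in polygon$rings) {
    n <- nrow(ring) - 1
    for (i in seq_len(n)) {
      ax <- ring[i, 1]; ay <- ring[i, 2]
      bx <- ring[i + 1, 1]; by <- ring[i + 1, 2]
      vx <- bx - ax; vy <- by - ay
      L2 <- vx^2 + vy^2
      t <- if (L2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / L2))
      d2 <- (ax + t * vx - px)^2 + (ay + t * vy - py)^2
      on <- on | d2 <= tol^2 * max(L2, 1)
    }
  }
  on
}

#' Per-polygon sampling-unit metrics
#'
#' Membership is point-in-polygon over the segment's fixes; `mFPT_Rmax` is
#' the mean of the defined FPT values at `r_max` over member fixes; area from
#' planar geometry; occupancy is the member fixes' time span in days.
#' Polygons with no member fixes or no defined FPT are dropped (message).
#'
#' @param polygon one polygon from [isopleth_polygons()].
#' @param fixes data frame of the segment's fixes (`x`, `y`, `timestamp`).
#' @param fpt_at_rmax the fixes' FPT values (h) at the analysis radius.
#' @return one-row data frame with `area_km2`, `t_start`, `t_end`,
#'   `occupancy_days`, `n_fixes`, `mfpt_rmax_h`, or `NULL` when dropped.
#' @export
polygon_metrics <- function(polygon, fixes, fpt_at_rmax) {
  member <- point_in_polygon(fixes$x, fixes$y, polygon)
  if (!any(member)) {
    message("polygon dropped: no member fixes")
    return(NULL)
  }
  v <- fpt_at_rmax[member]
  v <- v[!is.na(v)]
  if (!length(v)) {
    message("polygon dropped: no defined FPT among member fixes")
    return(NULL)
  }
  ts <- fixes$timestamp[member]
  data.frame(area_km2 = polygon$area_m2 / 1e6,
             t_start = min(ts), t_end = max(ts),
             occupancy_days = as.numeric(difftime(max(ts), min(ts),
                                                  units = "days")),
             n_fixes = sum(member),
             mfpt_rmax_h = mean(v))
}

#' Utilisation-distribution sampling units for a segmented track
#'
#' For each movement segment with at least five fixes: estimate the kernel
#' UD, extract the isopleth polygons, and compute per-polygon metrics.  The
#' polygons are the analysis sampling units of the downstream regression.
#'
#' @param track planar `track`.
#' @param segmentation a `track_segmentation` for that track.
#' @param profile the track's `fpt_profile`.
#' @param r_max analysis radius (m), member of `profile$radii`.
#' @param level isopleth level (default 0.95).
#' @param bandwidth,cell see [estimate_density()].
#' @param min_fixes smallest number of member fixes for a polygon to count
#'   as a sampling unit (default 1; higher values discard slivers crossed by
#'   a handful of transit fixes).
#' @return list with `table` (one row per retained polygon: `track_label`,
#'   `bird_id`, `segment_id`, `polygon_id`, metrics) and `polygons` (their
#'   geometries).
#' @export
build_ud_polygons <- function(track, segmentation, profile, r_max,
                              level = 0.95, bandwidth = NULL, cell = 100,
                              min_fixes = 1) {
  ir <- match(r_max, profile$radii)
  if (is.na(ir)) stop("r_max is not on the profile's radius grid")
  fptv <- profile$fpt[, ir]
  rows <- list()
  geoms <- list()
  pid <- 0L
  for (seg in sort(unique(segmentation$segment_id))) {
    in_seg <- segmentation$segment_id == seg
    if (sum(in_seg) < 5) next
    fx <- as.data.frame(track)[in_seg, , drop = FALSE]
    grid <- estimate_density(fx$x, fx$y, bandwidth = bandwidth, cell = cell)
    polys <- isopleth_polygons(grid, level = level)
    for (p in polys) {
      met <- polygon_metrics(p, fx, fptv[in_seg])
      if (is.null(met)) next
      if (met$n_fixes < min_fixes) {
        message(sprintf("polygon dropped: %d member fixes < min_fixes = %d",
                        met$n_fixes, min_fixes))
        next
      }
      pid <- pid + 1L
      met <- cbind(data.frame(track_label = track$track_label[1],
                              bird_id = track$bird_id[1],
                              segment_id = seg, polygon_id = pid,
                              stringsAsFactors = FALSE),
                   met)
      rows[[length(rows) + 1L]] <- met
      geoms[[pid]] <- p
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(track_label = character(), bird_id = character(),
               segment_id = integer(), polygon_id = integer(),
               area_km2 = numeric(), t_start = as.POSIXct(character()),
               t_end = as.POSIXct(character()), occupancy_days = numeric(),
               n_fixes = integer(), mfpt_rmax_h = numeric())
  rownames(table) <- NULL
  list(table = table, polygons = geoms)
}

#' Write utilisation-distribution polygons as GeoJSON
#'
#' Planar coordinates are written as-is; the projection centre (if any) is
#' recorded in the feature properties.
#'
#' @param ud result of [build_ud_polygons()].
#' @param path output file.
#' @param proj optional projection descriptor recorded in properties.
#' @export
write_ud_geojson <- function(ud, path, proj = NULL) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required to write GeoJSON")
  feats <- lapply(seq_len(nrow(ud$table)), function(i) {
    p <- ud$polygons[[ud$table$polygon_id[i]]]
    coords <- lapply(p$rings, function(r) lapply(seq_len(nrow(r)),
                                                 function(k) r[k, ]))
    list(type = "Feature",
         properties = c(as.list(ud$table[i, setdiff(names(ud$table),
                                                    c("t_start", "t_end"))]),
                        list(t_start = format(ud$table$t_start[i]),
                             t_end = format(ud$table$t_end[i]),
                             projection = proj)),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
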