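#' Dynamic raster time series container
#'
#' A stack of regular rasters on a shared planar grid, one slice per time
#' step.  Composite variables (NDVI, mNDWI) use a 16-day step; precipitation
#' and temperature are daily.  Slice k covers the interval
#' `[times[k], times[k] + step_days)`.
#'
#' @param variable one of "NDVI", "mNDWI", "precip", "temp".
#' @param times Date vector of slice start dates, strictly increasing and
#'   evenly spaced.
#' @param step_days slice length in days.
#' @param xg,yg cell-centre coordinate vectors (m), evenly spaced.
#' @param values numeric array `[length(xg), length(yg), length(times)]`.
#' @return a `raster_series`.
#' @export
raster_series <- function(variable, times, step_days, xg, yg, values) {
  variable <- match.arg(variable, c("NDVI", "mNDWI", "precip", "temp"))
  times <- as.Date(times)
  stopifnot(length(times) >= 1,
            all(dim(values) == c(length(xg), length(yg), length(times))))
  if (length(times) > 1) {
    dt <- diff(as.numeric(times))
    if (any(dt <= 0) || any(dt != step_days))
      stop("times must be strictly increasing and evenly spaced at step_days")
  }
  if (variable %in% c("NDVI", "mNDWI") &&
      any(values < -1 - 1e-9 | values > 1 + 1e-9, na.rm = TRUE))
    stop(variable, " values must lie in [-1, 1]")
  if (variable == "precip" && any(values < 0, na.rm = TRUE))
    stop("precipitation must be non-negative")
  structure(list(variable = variable, times = times, step_days = step_days,
                 xg = xg, yg = yg, values = values),
            class = "raster_series")
}

#' @export
print.raster_series <- function(x, ...) {
  cat(sprintf("<raster_series %s: %d x %d cells, %d slices of %g d from %s>\n",
              x$variable, length(x$xg), length(x$yg), length(x$times),
              x$step_days, format(x$times[1])))
  invisible(x)
}

#' Static raster container
#'
#' @param variable e.g. "elev".
#' @param xg,yg cell-centre coordinates (m).
#' @param values matrix `[length(xg), length(yg)]`.
#' @return a `static_raster`.
#' @export
static_raster <- function(variable, xg, yg, values) {
  stopifnot(all(dim(values) == c(length(xg), length(yg))),
            all(is.finite(values)))
  structure(list(variable = variable, xg = xg, yg = yg, values = values),
            class = "static_raster")
}

#' Normalised-difference spectral index
#'
#' `(a - b) / (a + b)`: with `a` = NIR and `b` = red this is NDVI; with
#' `a` = green and `b` = MIR it is mNDWI.  Zero-sum pixels give `NA` rather
#' than a division error.
#'
#' @param band_a,band_b non-negative band reflectances (vectorised).
#' @param kind "ndvi" or "mndwi" (informational).
#' @return values in `[-1, 1]`, `NA` where both bands are zero.
#' @export
spectral_index <- function(band_a, band_b, kind = c("ndvi", "mndwi")) {
  kind <- match.arg(kind)
  stopifnot(all(band_a >= 0, na.rm = TRUE), all(band_b >= 0, na.rm = TRUE))
  s <- band_a + band_b
  out <- ifelse(s == 0, NA_real_, (band_a - band_b) / s)
  out
}

#' Temporal mean of a raster series over an occupancy window
#'
#' Unweighted mean over all slices whose coverage interval
#' `[time, time + step)` overlaps the window `[t0, t1]`.  Optionally each
#' slice can be weighted by its overlap in days.
#'
#' @param series a `raster_series`.
#' @param window length-2 Date (or coercible) vector `c(t0, t1)`, `t0 <= t1`.
#' @param weighted logical; weight slices by overlap days (default FALSE).
#' @return matrix `[length(xg), length(yg)]`.
#' @export
temporal_mean <- function(series, window, weighted = FALSE) {
  window <- as.Date(window)
  stopifnot(length(window) == 2, window[1] <= window[2])
  t0 <- as.numeric(window[1])
  t1 <- as.numeric(window[2])
  st <- as.numeric(series$times)
  en <- st + series$step_days
  ov <- pmin(en, t1) - pmax(st, t0)
  # a window inside one slice has ov possibly 0 (t0 == t1); use half-open
  # interval overlap: slice covers [st, en)
  sel <- which(st <= t1 & en > t0)
  # full coverage required: slices span days [st[1], en[last] - 1]
  if (!length(sel) || t0 < st[1] || t1 > en[length(en)] - 1)
    stop(sprintf("window %s..%s not covered by %s series (%s..%s)",
                 window[1], window[2], series$variable,
                 series$times[1], series$times[length(series$times)]))
  if (weighted) {
    w <- pmax(ov[sel], .Machine$double.eps)
    sl <- series$values[, , sel, drop = FALSE]
    out <- 0
    for (k in seq_along(sel)) out <- out + sl[, , k] * w[k]
    out / sum(w)
  } else {
    rowMeans(series$values[, , sel, drop = FALSE], dims = 2)
  }
}

#' Spatial (zonal) mean of a raster over a polygon
#'
#' Mean over cells whose centre lies inside the polygon; `NA` cells are
#' excluded.  If no cell centre falls inside (small polygons), the value of
#' the cell nearest to the polygon's first vertex centroid is used.
#'
#' @param values raster matrix `[length(xg), length(yg)]`.
#' @param xg,yg cell-centre coordinates.
#' @param polygon polygon as returned by [isopleth_polygons()].
#' @return scalar mean.
#' @export
zonal_mean <- function(values, xg, yg, polygon) {
  ring <- polygon$rings[[1]]
  bx <- range(ring[, 1]); by <- range(ring[, 2])
  if (bx[2] < min(xg) - diff(range(xg)) || bx[1] > max(xg) + diff(range(xg)) ||
      by[2] < min(yg) - diff(range(yg)) || by[1] > max(yg) + diff(range(yg)))
    stop("polygon does not overlap the raster extent")
  ix <- which(xg >= bx[1] - 1e-9 & xg <= bx[2] + 1e-9)
  iy <- which(yg >= by[1] - 1e-9 & yg <= by[2] + 1e-9)
  if (length(ix) && length(iy)) {
    cc <- expand.grid(i = ix, j = iy)
    inside <- point_in_polygon(xg[cc$i], yg[cc$j], polygon)
    if (any(inside)) {
      v <- values[cbind(cc$i[inside], cc$j[inside])]
      v <- v[!is.na(v)]
      if (length(v)) return(mean(v))
    }
  }
  # small-polygon guard: nearest cell to the polygon centroid
  cx <- mean(ring[-nrow(ring), 1]); cy <- mean(ring[-nrow(ring), 2])
  values[which.min(abs(xg - cx)), which.min(abs(yg - cy))]
}

#' Lagged difference of temporally and spatially averaged rasters
#'
#' The covariate `Delta_lag` for a sampling unit: zonal mean of the temporal
#' mean over the occupancy window, minus the same quantity with the whole
#' window shifted back by `lag_days`.
#'
#' @param series a `raster_series`.
#' @param window occupancy window `c(t0, t1)` (Dates).
#' @param lag_days lag in days (16 or 32 in the standard analysis).
#' @param polygon sampling-unit polygon.
#' @param weighted see [temporal_mean()].
#' @return scalar difference.
#' @export
lagged_difference <- function(series, window, lag_days, polygon,
                              weighted = FALSE) {
  window <- as.Date(window)
  cur <- temporal_mean(series, window, weighted = weighted)
  lag <- temporal_mean(series, window - lag_days, weighted = weighted)
  zonal_mean(cur, series$xg, series$yg, polygon) -
    zonal_mean(lag, series$xg, series$yg, polygon)
}

#' Build the per-polygon covariate table
#'
#' One record per utilisation-distribution polygon carrying the response
#' `log(mFPT_Rmax)` and the twelve predictors: current-window means of NDVI,
#' mNDWI and precipitation, their 16- and 32-day lagged differences,
#' temperature, elevation, and site.  Records whose current or lagged window
#' is not covered by a series are dropped with a message.
#'
#' @param ud result of [build_ud_polygons()] (or a combined table/polygon
#'   pair across tracks).
#' @param env named list with elements `ndvi`, `mndwi`, `precip`, `temp`
#'   (`raster_series`) and `elev` (`static_raster`).
#' @param sites named character vector mapping `bird_id` to site code.
#' @param lags integer lags in days (default `c(16, 32)`).
#' @param weighted see [temporal_mean()].
#' @return data frame of `covariate_record`s.
#' @export
build_covariate_table <- function(ud, env, sites, lags = c(16, 32),
                                  weighted = FALSE) {
  tab <- ud$table
  stopifnot(nrow(tab) >= 1)
  miss <- setdiff(unique(tab$bird_id), names(sites))
  if (length(miss))
    stop("site mapping missing bird(s): ", paste(miss, collapse = ", "))
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    poly <- ud$polygons[[tab$polygon_id[i]]]
    bbox <- .poly_bbox(poly)
    # crop rasters to the polygon's neighbourhood before averaging
    dyn <- lapply(list(ndvi = env$ndvi, mndwi = env$mndwi,
                       precip = env$precip), .crop_series, bbox = bbox)
    temp_cr <- .crop_series(env$temp, bbox)
    win <- as.Date(c(tab$t_start[i], tab$t_end[i]))
    rec <- list(polygon_id = tab$polygon_id[i],
                track_label = tab$track_label[i],
                bird_id = tab$bird_id[i],
                site = unname(sites[tab$bird_id[i]]),
                mfpt_rmax_h = tab$mfpt_rmax_h[i],
                log_mfpt = log(tab$mfpt_rmax_h[i]))
    ok <- TRUE
    for (v in names(dyn)) {
      res <- tryCatch({
        cur <- temporal_mean(dyn[[v]], win, weighted = weighted)
        val <- zonal_mean(cur, dyn[[v]]$xg, dyn[[v]]$yg, poly)
        deltas <- vapply(lags, function(L)
          lagged_difference(dyn[[v]], win, L, poly, weighted = weighted),
          numeric(1))
        c(val, deltas)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        message(sprintf("polygon %d dropped: %s", tab$polygon_id[i],
                        conditionMessage(res)))
        ok <- FALSE
        break
      }
      rec[[paste0(v, "_t")]] <- res[1]
      for (k in seq_along(lags))
        rec[[paste0("d_", v, "_", lags[k])]] <- res[1 + k]
    }
    if (!ok) next
    res <- tryCatch({
      tm <- temporal_mean(temp_cr, win, weighted = weighted)
      zonal_mean(tm, temp_cr$xg, temp_cr$yg, poly)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("polygon %d dropped: %s", tab$polygon_id[i],
                      conditionMessage(res)))
      next
    }
    rec$temp <- res
    rec$elev <- zonal_mean(env$elev$values, env$elev$xg, env$elev$yg, poly)
    out[[i]] <- as.data.frame(rec, stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) stop("no covariate records could be built")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.poly_bbox <- function(polygon) {
  xs <- unlist(lapply(polygon$rings, function(r) range(r[, 1])))
  ys <- unlist(lapply(polygon$rings, function(r) range(r[, 2])))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

# spatial crop (cells within the bbox plus one-cell margin); time untouched
.crop_series <- function(series, bbox) {
  cw <- diff(series$xg[1:2])
  ix <- which(series$xg >= bbox["xmin"] - cw & series$xg <= bbox["xmax"] + cw)
  iy <- which(series$yg >= bbox["ymin"] - cw & series$yg <= bbox["ymax"] + cw)
  if (!length(ix) || !length(iy)) return(series)  # let zonal_mean handle it
  series$xg <- series$xg[ix]
  series$yg <- series$yg[iy]
  series$values <- series$values[ix, iy, , drop = FALSE]
  series
}

#' The twelve standard predictor names
#'
#' Nine dynamic terms (current means and two lagged differences of NDVI,
#' mNDWI and precipitation), temperature, elevation, and site.
#'
#' @return character vector of length 12.
#' @export
predictor_names <- function() {
  c("ndvi_t", "d_ndvi_16", "d_ndvi_32",
    "mndwi_t", "d_mndwi_16", "d_mndwi_32",
    "precip_t", "d_precip_16", "d_precip_32",
    "temp", "elev", "site")
}

#' Serialise a raster series to long-format CSV
#'
#' Plain-text interchange (`time,x,y,value` rows plus a header comment with
#' the variable and step); [read_raster_csv()] restores the object.
#'
#' @param series a `raster_series`.
#' @param path output path.
#' @export
write_raster_csv <- function(series, path) {
  grid <- expand.grid(x = series$xg, y = series$yg,
                      time = format(series$times))
  grid$value <- as.vector(series$values)
  con <- file(path, "w")
  writeLines(sprintf("# variable=%s step_days=%g", series$variable,
                     series$step_days), con)
  write.csv(grid, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_raster_csv
#' @param path CSV produced by [write_raster_csv()].
#' @return a `raster_series`.
#' @export
read_raster_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("variable=(\\S+) step_days=(\\S+)", hdr))[[1]]
  df <- read.csv(path, comment.char = "#")
  xg <- sort(unique(df$x))
  yg <- sort(unique(df$y))
  times <- sort(unique(as.Date(df$time)))
  arr <- array(NA_real_, c(length(xg), length(yg), length(times)))
  arr[cbind(match(df$x, xg), match(df$y, yg), match(as.Date(df$time), times))] <-
    df$value
  raster_series(m[2], times, as.numeric(m[3]), xg, yg, arr)
}
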