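#' @useDynLib fptars, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats var sd complete.cases dnorm qnorm quantile setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# mean Earth radius (m), used by the per-track azimuthal equidistant frame
.R_EARTH <- 6371008.8

#' Construct a track object
#'
#' A track is an ordered set of GPS fixes for one tracking bout of one bird,
#' stored as a data frame with columns `bird_id`, `track_label`, `timestamp`
#' (POSIXct, UTC), `x`, `y` (planar metres once projected) and optionally
#' `lon`, `lat` (degrees).  Attributes carry `species`, `site` and whether the
#' coordinates are planar.
#'
#' @param fixes data frame with at least `bird_id`, `timestamp` and
#'   coordinate columns (`x`/`y` planar metres or `lon`/`lat` degrees).
#' @param species optional species tag (e.g. "goose", "teal").
#' @param site optional site code.
#' @param planar logical; `TRUE` if `x`/`y` are already metric.
#' @return an object of class `track`.
#' @export
track <- function(fixes, species = NA_character_, site = NA_character_,
                  planar = FALSE) {
  stopifnot(is.data.frame(fixes), nrow(fixes) >= 1)
  if (is.null(fixes$track_label)) fixes$track_label <- fixes$bird_id
  if (!inherits(fixes$timestamp, "POSIXct"))
    stop("timestamp must be POSIXct")
  if (is.unsorted(fixes$timestamp, strictly = TRUE))
    stop("track timestamps must be strictly increasing")
  if (length(unique(fixes$bird_id)) != 1L ||
      length(unique(fixes$track_label)) != 1L)
    stop("all fixes of a track must share bird_id and track_label")
  structure(fixes, class = c("track", "data.frame"),
            species = species, site = site, planar = planar)
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track %s: %d fixes, %.1f days, %s>\n",
              x$track_label[1], nrow(x), track_duration(x),
              if (isTRUE(attr(x, "planar"))) "planar" else "geographic"))
  invisible(x)
}

#' Track duration in days
#' @param track a `track` object.
#' @return numeric, (last - first timestamp) in days.
#' @export
track_duration <- function(track) {
  as.numeric(difftime(track$timestamp[nrow(track)], track$timestamp[1],
                      units = "days"))
}

#' Parse GPS telemetry from CSV into tracks
#'
#' Reads a fix table (one row per GPS relocation), groups rows by bird and
#' track label, sorts by time, and drops duplicated timestamps within a track
#' (first occurrence kept, drops reported via message).  Naive timestamps are
#' interpreted as UTC.
#'
#' @param path CSV file path.
#' @param col_map named list mapping the canonical column names (`bird_id`,
#'   `timestamp`, `x`, `y`, `lon`, `lat`, `track_label`, `species`, `site`) to
#'   the file's column names; Movebank-style files can be mapped with e.g.
#'   `list(bird_id = "individual-local-identifier", timestamp = "timestamp",
#'   lon = "location-long", lat = "location-lat")`.
#' @param planar logical; `TRUE` when `x`/`y` are already planar metres.
#' @param tz timezone applied to naive timestamps (default UTC).
#' @return a list of `track` objects.
#' @export
parse_tracks <- function(path, col_map = NULL, planar = FALSE, tz = "UTC") {
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty input: ", path, " contains no fixes")
  if (!is.null(col_map))
    for (canon in names(col_map))
      if (col_map[[canon]] %in% names(raw))
        names(raw)[names(raw) == col_map[[canon]]] <- canon
  need <- c("bird_id", "timestamp")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("missing required columns: ",
                         paste(miss, collapse = ", "))
  if (!all(c("x", "y") %in% names(raw)) &&
      !all(c("lon", "lat") %in% names(raw)))
    stop("need either x/y or lon/lat coordinate columns")
  fmts <- c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
            "%Y-%m-%d %H:%M", "%Y-%m-%d")
  parse_ts <- function(x) as.POSIXct(x, tz = tz, tryFormats = fmts)
  ts <- tryCatch(parse_ts(raw$timestamp), error = function(e) NULL)
  if (is.null(ts) || anyNA(ts)) {
    ok <- vapply(raw$timestamp, function(x)
      !inherits(tryCatch(parse_ts(x), error = function(e) e), "error"),
      logical(1))
    bad <- which(!ok | (if (is.null(ts)) FALSE else is.na(ts)))
    stop("unparseable timestamp at row(s): ",
         paste(head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (+%d more)", length(bad) - 5) else "")
  }
  raw$timestamp <- ts
  if (is.null(raw$track_label)) raw$track_label <- raw$bird_id
  out <- list()
  for (lab in unique(raw$track_label)) {
    g <- raw[raw$track_label == lab, , drop = FALSE]
    g <- g[order(g$timestamp), , drop = FALSE]
    dup <- duplicated(g$timestamp)
    if (any(dup)) {
      message(sprintf("track %s: dropped %d duplicate timestamp(s), kept first",
                      lab, sum(dup)))
      g <- g[!dup, , drop = FALSE]
    }
    rownames(g) <- NULL
    out[[lab]] <- track(g,
                        species = if (!is.null(g$species)) g$species[1] else NA_character_,
                        site = if (!is.null(g$site)) g$site[1] else NA_character_,
                        planar = planar || all(c("x", "y") %in% names(g)) &&
                          !all(c("lon", "lat") %in% names(g)))
  }
  out
}

#' Write tracks back to CSV
#'
#' Inverse of [parse_tracks()]: one row per fix with a `track_label` column;
#' timestamps serialised to the second in UTC.
#'
#' @param tracks list of `track` objects.
#' @param path output CSV path.
#' @export
write_tracks <- function(tracks, path) {
  rows <- lapply(tracks, function(tr) {
    df <- as.data.frame(tr)
    df$species <- attr(tr, "species")
    df$site <- attr(tr, "site")
    df$timestamp <- format(df$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
    df
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Split a track at large time gaps
#'
#' Tracks are split wherever the interval between successive fixes is strictly
#' greater than `max_gap_hours` (default one week).  Following the published
#' labelling convention, the first product keeps the original label and later
#' products are suffixed `a`, `b`, `c`, ... in temporal order.
#'
#' @param track a `track`.
#' @param max_gap_hours gap threshold in hours (default `7 * 24`).
#' @return list of `track` objects (length 1 when no gap exceeds the
#'   threshold).
#' @export
split_on_gaps <- function(track, max_gap_hours = 7 * 24) {
  stopifnot(nrow(track) >= 2)
  dt <- diff(as.numeric(track$timestamp)) / 3600
  cut_after <- which(dt > max_gap_hours)
  if (!length(cut_after)) return(list(track))
  bounds <- c(0, cut_after, nrow(track))
  base <- track$track_label[1]
  out <- vector("list", length(bounds) - 1)
  for (i in seq_along(out)) {
    seg <- as.data.frame(track)[(bounds[i] + 1):bounds[i + 1], , drop = FALSE]
    lab <- if (i == 1) base else paste0(base, letters[i - 1])
    seg$track_label <- lab
    rownames(seg) <- NULL
    out[[i]] <- track(seg, species = attr(track, "species"),
                      site = attr(track, "site"),
                      planar = attr(track, "planar"))
  }
  out
}

#' Drop tracks shorter than a minimum duration
#'
#' Tracks tracked for strictly less than `min_days` are removed; each removal
#' is reported via `message()`.
#'
#' @param tracks list of `track` objects.
#' @param min_days minimum duration in days (default 90).
#' @return filtered list.
#' @export
filter_min_duration <- function(tracks, min_days = 90) {
  keep <- vapply(tracks, function(tr) track_duration(tr) >= min_days,
                 logical(1))
  for (tr in tracks[!keep])
    message(sprintf("dropped track %s: duration %.1f d < %g d",
                    tr$track_label[1], track_duration(tr), min_days))
  tracks[keep]
}

#' Project a track to planar coordinates
#'
#' Uses a spherical azimuthal equidistant frame centred (by default) on the
#' track's mean coordinate, so distances from the centre are true; adequate
#' for FPT radii well below continental scale.  Tracks already flagged planar
#' are returned unchanged.
#'
#' @param track a `track` with `lon`/`lat` in degrees.
#' @param lon0,lat0 optional projection centre (degrees); defaults to the
#'   track's mean coordinate.
#' @return the track with planar `x`, `y` in metres and attribute
#'   `proj = c(lon0, lat0)`.
#' @export
to_planar <- function(track, lon0 = NULL, lat0 = NULL) {
  if (isTRUE(attr(track, "planar"))) return(track)
  if (is.null(track$lon) || is.null(track$lat))
    stop("track has no lon/lat columns to project")
  if (any(abs(track$lon) > 180) || any(abs(track$lat) > 90))
    stop("coordinates outside [-180,180] x [-90,90]")
  if (is.null(lon0)) lon0 <- mean(track$lon)
  if (is.null(lat0)) lat0 <- mean(track$lat)
  xy <- .aeqd_forward(track$lon, track$lat, lon0, lat0)
  df <- as.data.frame(track)
  df$x <- xy$x
  df$y <- xy$y
  out <- track(df, species = attr(track, "species"), site = attr(track, "site"),
               planar = TRUE)
  attr(out, "proj") <- c(lon0 = lon0, lat0 = lat0)
  out
}

#' Inverse of the planar projection
#'
#' @param x,y planar coordinates in metres.
#' @param lon0,lat0 projection centre in degrees.
#' @return data frame with `lon`, `lat` in degrees.
#' @export
from_planar <- function(x, y, lon0, lat0) {
  rad <- pi / 180
  c_ang <- sqrt(x^2 + y^2) / .R_EARTH
  lat0r <- lat0 * rad
  lat <- ifelse(c_ang == 0, lat0r,
                asin(cos(c_ang) * sin(lat0r) +
                       (y * sin(c_ang) * cos(lat0r)) / (c_ang * .R_EARTH)))
  lon <- lon0 * rad +
    ifelse(c_ang == 0, 0,
           atan2(x * sin(c_ang),
                 c_ang * .R_EARTH * cos(lat0r) * cos(c_ang) -
                   y * sin(lat0r) * sin(c_ang)))
  data.frame(lon = lon / rad, lat = lat / rad)
}

.aeqd_forward <- function(lon, lat, lon0, lat0) {
  rad <- pi / 180
  lam <- (lon - lon0) * rad
  phi <- lat * rad
  phi0 <- lat0 * rad
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang == 0, 1, c_ang / sin(c_ang))
  list(x = .R_EARTH * k * cos(phi) * sin(lam),
       y = .R_EARTH * k * (cos(phi0) * sin(phi) -
                             sin(phi0) * cos(phi) * cos(lam)))
}
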