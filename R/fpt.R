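#' Default first-passage-time radius grid
#'
#' Arithmetic grid of circle radii, by default from 100 m upward in 80 m
#' steps, keeping every grid point at or below `r_max` (the default sweep thus
#' ends at 9,940 m).
#'
#' @param r_min smallest radius (m).
#' @param r_step grid step (m).
#' @param r_max upper bound (m); the last grid point is the largest
#'   `r_min + k * r_step` not exceeding it.
#' @return numeric vector of radii in metres.
#' @export
fpt_radii <- function(r_min = 100, r_step = 80, r_max = 10000) {
  stopifnot(r_min > 0, r_step > 0, r_max >= r_min)
  seq(r_min, r_max, by = r_step)
}

#' First-passage time at every fix over a radius sweep
#'
#' The first-passage time of fix i at radius r is the residence time of the
#' path in the circle of radius r centred on the fix: time to the first
#' forward exit plus time since the last backward exit.  Exit instants are
#' found by exact segment-circle intersection with linear time interpolation
#' along the crossing segment, which removes the bias a nearest-fix rule would
#' introduce at coarse fix rates.  Fixes for which the path never leaves the
#' circle before the track end (or start) get `NA` at that radius; in
#' particular the first and last fix are always `NA`.
#'
#' @param track a planar `track` (see [to_planar()]).
#' @param radii ascending radius grid in metres (default [fpt_radii()]).
#' @return an `fpt_profile`: list with `track_label`, `radii`, and `fpt`, an
#'   `n_fixes x n_radii` matrix of durations in hours.
#' @export
compute_fpt <- function(track, radii = fpt_radii()) {
  if (!isTRUE(attr(track, "planar")))
    stop("track must be planar; call to_planar() first")
  if (nrow(track) < 2) stop("track too short for FPT")
  stopifnot(!is.unsorted(radii, strictly = TRUE))
  t_h <- as.numeric(track$timestamp) / 3600
  fpt <- cpp_fpt(track$x, track$y, t_h, radii)
  structure(list(track_label = track$track_label[1],
                 species = attr(track, "species"),
                 radii = radii, fpt = fpt),
            class = "fpt_profile")
}

#' @export
print.fpt_profile <- function(x, ...) {
  cat(sprintf("<fpt_profile %s: %d fixes x %d radii (%g-%g m), %.0f%% defined>\n",
              x$track_label, nrow(x$fpt), length(x$radii), min(x$radii),
              max(x$radii), 100 * mean(!is.na(x$fpt))))
  invisible(x)
}

#' Per-radius variance of log first-passage time
#'
#' Sample variance of the natural log of FPT across fixes, per radius.  Radii
#' with fewer than two defined values give `NA`.  The log base only rescales
#' the whole curve and cannot move its peak, so natural log is used
#' throughout.
#'
#' @param profile an `fpt_profile`.
#' @return numeric vector of variances, one per radius.
#' @export
variance_log_fpt <- function(profile) {
  apply(profile$fpt, 2, function(col) {
    v <- col[!is.na(col) & col > 0]
    if (length(v) < 2) NA_real_ else var(log(v))
  })
}

#' Population-level ARS scale from per-track variance curves
#'
#' Averages each track's variance-of-log-FPT curve across tracks (unweighted;
#' tracks with an undefined variance at a radius are excluded at that radius
#' only) and locates the radius of the global maximum of the mean curve.
#' This peak radius, `r_max`, is the common spatial scale of area-restricted
#' search for the population; ties go to the smaller radius.
#'
#' @param profiles list of `fpt_profile` objects on a common radius grid.
#' @return a `scale_curve`: list with `radii`, `var_fpt` (track x radius
#'   matrix), `var_fpt_mean`, and `r_max` (m).
#' @export
population_scale <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  radii <- profiles[[1]]$radii
  for (p in profiles)
    if (!identical(p$radii, radii))
      stop("profiles are not on a common radius grid")
  vf <- t(vapply(profiles, variance_log_fpt, numeric(length(radii))))
  rownames(vf) <- vapply(profiles, `[[`, character(1), "track_label")
  all_na <- rowSums(!is.na(vf)) == 0
  if (any(all_na))
    stop("variance curve undefined at every radius for track(s): ",
         paste(rownames(vf)[all_na], collapse = ", "))
  vmean <- colMeans(vf, na.rm = TRUE)
  vmean[!is.finite(vmean)] <- NA_real_
  r_max <- radii[which.max(vmean)]  # which.max: first max, i.e. smaller radius
  structure(list(radii = radii, var_fpt = vf, var_fpt_mean = vmean,
                 r_max = r_max),
            class = "scale_curve")
}

#' @export
print.scale_curve <- function(x, ...) {
  cat(sprintf("<scale_curve: %d tracks, radii %g-%g m, r_max = %g m>\n",
              nrow(x$var_fpt), min(x$radii), max(x$radii), x$r_max))
  invisible(x)
}

#' @param x a `scale_curve`.
#' @param ... passed to [graphics::matplot()].
#' @rdname population_scale
#' @export
plot.scale_curve <- function(x, ...) {
  graphics::matplot(x$radii, t(x$var_fpt), type = "l", lty = 1,
                    col = grDevices::grey(0.7),
                    xlab = "radius (m)", ylab = "var(log FPT)", ...)
  graphics::lines(x$radii, x$var_fpt_mean, lwd = 2)
  graphics::abline(v = x$r_max, lty = 2)
  invisible(x)
}
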