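#' Gaussian segment cost for penalized-contrast segmentation
#'
#' Cost of treating `series[i..j]` as one homogeneous segment:
#' `n * log(max(sigma2, eps))` where `sigma2` is the within-segment
#' (population) variance about the segment mean and `eps` a small variance
#' floor guarding constant segments.  This is the Gaussian
#' change-in-mean-and-variance contrast of the Lavielle family.
#'
#' @param series numeric vector.
#' @param i,j segment bounds (1-based, inclusive).
#' @param l_min minimum admissible segment length (contract check).
#' @param eps variance floor; default `1e-9 * var(series)` (an absolute tiny
#'   floor is used when the whole series is constant).
#' @return scalar cost.
#' @export
segment_cost <- function(series, i, j, l_min = 1, eps = NULL) {
  n <- j - i + 1
  if (n < l_min) stop("segment shorter than l_min")
  if (is.null(eps)) eps <- .contrast_eps(series)
  seg <- series[i:j]
  v <- mean(seg^2) - mean(seg)^2
  n * log(max(v, eps))
}

.contrast_eps <- function(series) {
  v <- var(series)
  if (!is.finite(v) || v <= 0) 1e-12 else 1e-9 * v
}

#' Optimal segmentations for each candidate number of segments
#'
#' For every K in 1..K_max, finds the partition of the series into K
#' contiguous segments (each at least `l_min` long) minimising the summed
#' Gaussian contrast, by dynamic programming over prefix-sum segment costs.
#' `J(K)` is the minimised contrast; it is non-increasing in K.
#'
#' @param series numeric vector (e.g. a track's FPT series at `r_max`).
#' @param k_max largest number of segments considered; default
#'   `min(20, floor(n / l_min))`.
#' @param l_min minimum segment length in fixes (default 10).
#' @return a `lavielle_contrast`: list with `K_values`, `J`, `breaks`
#'   (per-K list of 1-based inclusive segment end indices), `l_min`, `k_max`.
#' @export
optimal_segmentation <- function(series, k_max = NULL, l_min = 10) {
  n <- length(series)
  feas <- floor(n / l_min)
  if (is.null(k_max)) k_max <- min(20L, feas)
  if (k_max < 1 || feas < 1)
    stop("series too short for any segmentation with l_min = ", l_min)
  if (n < k_max * l_min)
    stop(sprintf("infeasible k_max = %d with l_min = %d for n = %d (max feasible K = %d)",
                 k_max, l_min, n, feas))
  res <- cpp_lavielle(series, as.integer(k_max), as.integer(l_min),
                      .contrast_eps(series))
  structure(list(K_values = seq_len(k_max), J = res$J, breaks = res$breaks,
                 l_min = l_min, k_max = k_max, n = n),
            class = "lavielle_contrast")
}

#' @export
print.lavielle_contrast <- function(x, ...) {
  cat(sprintf("<lavielle_contrast: n = %d, K = 1..%d, l_min = %d>\n",
              x$n, x$k_max, x$l_min))
  invisible(x)
}

#' @param x a `lavielle_contrast`.
#' @param ... passed to [graphics::plot()].
#' @rdname optimal_segmentation
#' @export
plot.lavielle_contrast <- function(x, ...) {
  graphics::plot(x$K_values, x$J, type = "b", xlab = "K",
                 ylab = "contrast J(K)", ...)
  invisible(x)
}

#' Choose the number of segments from the contrast decay
#'
#' The contrast is standardised affinely to span `[1, K_max]`
#' (`J_std(1) = K_max`, `J_std(K_max) = 1`), its discrete second derivative
#' `D(K) = J_std(K-1) - 2 J_std(K) + J_std(K+1)` is computed at interior K,
#' and `K_opt` is the last K at which `D(K)` exceeds the threshold `S`
#' (default 0.75, the recommended value).  A flat contrast, or no qualifying
#' K, yields `K_opt = 1`.
#'
#' @param contrast a `lavielle_contrast`.
#' @param S curvature threshold (default 0.75).
#' @return list with `K_opt`, `J_std` and `D`.
#' @export
choose_kopt <- function(contrast, S = 0.75) {
  J <- contrast$J
  K <- contrast$k_max
  flat <- K >= 2 && (!is.finite(J[1]) || !is.finite(J[K]) ||
                       abs(J[1] - J[K]) <= 1e-10 * max(abs(J[1]), abs(J[K]), 1))
  if (K < 3 || flat) {
    if (flat) warning("flat contrast function; K_opt = 1")
    return(list(K_opt = 1L, J_std = rep(NA_real_, K), D = rep(NA_real_, K)))
  }
  J_std <- (J[K] - J) / (J[K] - J[1]) * (K - 1) + 1
  D <- rep(NA_real_, K)
  for (k in 2:(K - 1)) D[k] <- J_std[k - 1] - 2 * J_std[k] + J_std[k + 1]
  qual <- which(D > S)
  list(K_opt = if (length(qual)) max(qual) else 1L, J_std = J_std, D = D)
}

#' Segment a track's FPT series into homogeneous movement bouts
#'
#' Runs the penalized-contrast segmentation on the FPT series at the ARS
#' scale `r_max`.  Fixes with undefined FPT at `r_max` (track endpoints and
#' circles never exited) are dropped before segmentation and afterwards
#' inherit the segment label of the nearest analysed fix, so labels cover
#' every fix.
#'
#' @param profile an `fpt_profile`.
#' @param r_max analysis radius; must be a member of `profile$radii`.
#' @param k_max,l_min see [optimal_segmentation()].
#' @param S see [choose_kopt()].
#' @return a `track_segmentation`: list with `track_label`, `segment_id`
#'   (integer per fix), `breakpoints` (end fix index of each segment, on the
#'   original fix indexing), `K_opt` and the `contrast` table; or `NULL`
#'   (with a message) when too few fixes have defined FPT.
#' @export
segment_track <- function(profile, r_max, k_max = NULL, l_min = 10,
                          S = 0.75) {
  ir <- match(r_max, profile$radii)
  if (is.na(ir)) stop("r_max is not on the profile's radius grid")
  series <- profile$fpt[, ir]
  ok <- which(!is.na(series))
  if (length(ok) < 2 * l_min) {
    message(sprintf("track %s skipped: only %d fixes with defined FPT at r_max (< 2*l_min)",
                    profile$track_label, length(ok)))
    return(NULL)
  }
  contrast <- optimal_segmentation(series[ok], k_max = k_max, l_min = l_min)
  sel <- choose_kopt(contrast, S = S)
  K <- sel$K_opt
  ends_ok <- contrast$breaks[[K]]            # ends on the reduced series
  seg_ok <- rep(seq_len(K), times = diff(c(0, ends_ok)))
  n <- length(series)
  segment_id <- rep(NA_integer_, n)
  segment_id[ok] <- seg_ok
  # dropped fixes inherit the nearest analysed fix's label
  if (anyNA(segment_id)) {
    na_idx <- which(is.na(segment_id))
    nearest <- vapply(na_idx, function(i) ok[which.min(abs(ok - i))],
                      integer(1))
    segment_id[na_idx] <- segment_id[nearest]
  }
  breakpoints <- c(which(diff(segment_id) != 0), n)
  structure(list(track_label = profile$track_label, segment_id = segment_id,
                 breakpoints = breakpoints, K_opt = K, contrast = contrast,
                 D = sel$D, analysed = ok, r_max = r_max),
            class = "track_segmentation")
}

#' @export
print.track_segmentation <- function(x, ...) {
  cat(sprintf("<track_segmentation %s: %d fixes -> %d segment(s) at r_max = %g m>\n",
              x$track_label, length(x$segment_id), x$K_opt, x$r_max))
  invisible(x)
}
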