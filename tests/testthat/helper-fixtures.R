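# shared fixture builders

# a planar track from coordinate vectors at a fixed time step
make_track <- function(x, y, dt_s = 7200, bird = "b1",
                       t0 = as.POSIXct("2008-07-01", tz = "UTC"),
                       species = "goose", site = "BAR") {
  df <- data.frame(bird_id = bird, track_label = bird,
                   timestamp = t0 + (seq_along(x) - 1) * dt_s, x = x, y = y)
  track(df, species = species, site = site, planar = TRUE)
}

# correlated random walk coordinates
crw_xy <- function(n, step = 100, rho = 0.5, seed = 1) {
  set.seed(seed)
  turn <- 2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (runif(n - 1) - 0.5)))
  heading <- cumsum(c(runif(1, -pi, pi), turn))
  len <- rgamma(n - 1, shape = 3, scale = step / 3)
  list(x = cumsum(c(0, len * cos(heading[-n]))),
       y = cumsum(c(0, len * sin(heading[-n]))))
}

# brute-force FPT oracle: resample the polyline densely and count the
# contiguous run of samples inside the circle around each fix
fpt_oracle <- function(x, y, t_s, radii, res_s = 1) {
  n <- length(x)
  tt <- seq(t_s[1], t_s[n], by = res_s)
  xx <- approx(t_s, x, xout = tt)$y
  yy <- approx(t_s, y, xout = tt)$y
  out <- matrix(NA_real_, n, length(radii))
  for (i in seq_len(n)) {
    d <- sqrt((xx - x[i])^2 + (yy - y[i])^2)
    ti <- which.min(abs(tt - t_s[i]))
    for (k in seq_along(radii)) {
      inside <- d <= radii[k]
      fwd <- which(!inside & seq_along(tt) > ti)
      bwd <- which(!inside & seq_along(tt) < ti)
      if (length(fwd) && length(bwd))
        out[i, k] <- tt[min(fwd)] - tt[max(bwd)]
    }
  }
  out
}

# exhaustive-enumeration segmentation oracle (small n)
enum_segmentation <- function(series, K, lmin) {
  n <- length(series)
  eps <- fptars:::.contrast_eps(series)
  cost <- function(i, j) segment_cost(series, i, j, eps = eps)
  best <- Inf
  best_ends <- NULL
  rec <- function(start, k, ends, acc) {
    if (k == 1) {
      if (n - start + 1 < lmin) return()
      v <- acc + cost(start, n)
      if (v < best) { best <<- v; best_ends <<- c(ends, n) }
      return()
    }
    for (e in (start + lmin - 1):(n - (k - 1) * lmin)) {
      rec(e + 1, k - 1, c(ends, e), acc + cost(start, e))
    }
  }
  rec(1, K, integer(), 0)
  list(J = best, ends = best_ends)
}
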