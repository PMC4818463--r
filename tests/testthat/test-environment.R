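# a small raster series fixture: constant-in-space values per slice
make_series <- function(values_by_slice, variable = "NDVI", step = 16,
                        t0 = as.Date("2008-07-01"),
                        xg = seq(0, 2000, by = 250),
                        yg = seq(0, 2000, by = 250)) {
  arr <- array(rep(values_by_slice, each = length(xg) * length(yg)),
               c(length(xg), length(yg), length(values_by_slice)))
  raster_series(variable, t0 + step * (seq_along(values_by_slice) - 1),
                step, xg, yg, arr)
}

square_poly <- function(x0, x1, y0, y1) {
  list(rings = list(cbind(c(x0, x1, x1, x0, x0), c(y0, y0, y1, y1, y0))),
       area_m2 = (x1 - x0) * (y1 - y0))
}

test_that("spectral indices follow the normalized-difference form", {
  expect_equal(spectral_index(0.5, 0.3, "ndvi"), 0.25)
  expect_equal(spectral_index(0.4, 0.4, "mndwi"), 0)
  expect_equal(spectral_index(0.7, 0, "ndvi"), 1)
  expect_true(is.na(spectral_index(0, 0, "ndvi")))
  x <- runif(50); y <- runif(50)
  expect_true(all(abs(spectral_index(x, y)) <= 1))
})

test_that("raster series container validates its invariants", {
  expect_error(make_series(c(0.2, 1.5)), "\\[-1, 1\\]")
  expect_error(make_series(c(1, -2), variable = "precip"), "non-negative")
  arr <- array(0, c(2, 2, 2))
  expect_error(raster_series("NDVI", as.Date("2008-07-01") + c(0, 20), 16,
                             1:2, 1:2, arr), "evenly spaced")
})

test_that("temporal mean follows the interval-overlap rule", {
  s <- make_series(c(0.2, 0.4, 0.8))
  # window inside one composite: that slice unchanged
  m1 <- temporal_mean(s, as.Date(c("2008-07-02", "2008-07-10")))
  expect_true(all(m1 == 0.2))
  # window exactly covering two slices
  m2 <- temporal_mean(s, as.Date(c("2008-07-01", "2008-08-01")))
  expect_true(all(abs(m2 - 0.3) < 1e-12))
  # coverage errors name the variable
  expect_error(temporal_mean(s, as.Date(c("2008-06-01", "2008-06-10"))),
               "NDVI")
  expect_error(temporal_mean(s, as.Date(c("2008-09-01", "2008-09-30"))),
               "not covered")
})

test_that("temporal mean equals a daily-expansion oracle on random windows", {
  set.seed(10)
  vals <- runif(8, -0.2, 0.8)
  s <- make_series(vals)
  t0 <- as.Date("2008-07-01")
  for (rep in 1:20) {
    w0 <- t0 + sample(0:100, 1)
    w1 <- w0 + sample(0:25, 1)
    got <- temporal_mean(s, c(w0, w1))[1, 1]
    # oracle: which slices own each day of the window, unweighted by slice
    slice_of <- function(d) findInterval(as.numeric(d - t0), 16 * 0:8)
    touched <- unique(vapply(seq(w0, w1, by = 1), slice_of, numeric(1)))
    expect_equal(got, mean(vals[touched]))
  }
})

test_that("weighted temporal mean weights slices by overlap days", {
  s <- make_series(c(0, 1))
  # interval overlap: 16 days of slice 1 and 3 of slice 2
  w <- as.Date(c("2008-07-01", "2008-07-20"))
  expect_equal(temporal_mean(s, w, weighted = TRUE)[1, 1], 3 / 19,
               tolerance = 1e-9)
  expect_equal(temporal_mean(s, w)[1, 1], 0.5)
})

test_that("zonal mean averages cell centres inside the polygon", {
  xg <- seq(0, 900, by = 100)
  yg <- seq(0, 900, by = 100)
  vals <- matrix(7, length(xg), length(yg))
  p <- square_poly(0, 900, 0, 900)
  expect_equal(zonal_mean(vals, xg, yg, p), 7)
  # polygon covering exactly two cells valued 1 and 3
  vals2 <- vals
  vals2[1, 1] <- 1; vals2[2, 1] <- 3
  p2 <- square_poly(-50, 150, -50, 50)
  expect_equal(zonal_mean(vals2, xg, yg, p2), 2)
  # small-polygon fallback: nearest cell
  p3 <- square_poly(410, 440, 410, 440)
  vals3 <- vals
  vals3[5, 5] <- 99  # cell centred at (400, 400)
  expect_equal(zonal_mean(vals3, xg, yg, p3), 99)
  # disjoint extent errors
  p4 <- square_poly(1e6, 2e6, 1e6, 2e6)
  expect_error(zonal_mean(vals, xg, yg, p4), "overlap")
})

test_that("zonal mean approaches a supersampled oracle on random fields", {
  set.seed(4)
  xg <- seq(50, 950, by = 100)
  vals <- matrix(runif(100), 10, 10)
  p <- square_poly(130, 680, 230, 840)
  got <- zonal_mean(vals, xg, xg, p)
  # supersample at 10 m and average true cell values inside the polygon
  fx <- seq(5, 995, by = 10)
  cc <- expand.grid(x = fx, y = fx)
  inside <- cc$x >= 130 & cc$x <= 680 & cc$y >= 230 & cc$y <= 840
  ref <- mean(vals[cbind(findInterval(cc$x[inside], seq(0, 1000, 100)),
                         findInterval(cc$y[inside], seq(0, 1000, 100)))])
  expect_lt(abs(got - ref), 0.1)
})

test_that("lagged differences subtract the back-shifted window", {
  # constant field: zero difference at any lag
  s <- make_series(rep(0.5, 10))
  p <- square_poly(200, 800, 200, 800)
  expect_equal(lagged_difference(s, as.Date(c("2008-11-20", "2008-11-28")),
                                 32, p), 0)
  # step of +0.2 between lagged and current windows
  s2 <- make_series(c(0.1, 0.1, 0.3, 0.3))
  w <- as.Date(c("2008-08-02", "2008-08-15"))  # inside slice 3
  expect_equal(lagged_difference(s2, w, 32, p), 0.2)
  # linear ramp at m per day: difference approximately m * lag
  m <- 0.01
  daily <- raster_series("precip", as.Date("2008-07-01") + 0:99, 1,
                         s$xg, s$yg,
                         array(rep(m * (0:99), each = length(s$xg)^2),
                               c(length(s$xg), length(s$yg), 100)))
  w2 <- as.Date(c("2008-08-20", "2008-08-28"))
  expect_equal(lagged_difference(daily, w2, 16, p), m * 16, tolerance = 1e-9)
  # uncovered lagged window raises a coverage error
  expect_error(lagged_difference(s2, as.Date(c("2008-07-05", "2008-07-10")),
                                 32, p), "not covered")
})

test_that("temporal-then-spatial equals spatial-then-temporal averaging", {
  set.seed(6)
  xg <- seq(0, 1000, by = 125)
  nt <- 5
  arr <- array(runif(length(xg)^2 * nt), c(length(xg), length(xg), nt))
  s <- raster_series("temp", as.Date("2008-07-01") + 0:(nt - 1), 1, xg, xg, arr)
  p <- square_poly(100, 700, 250, 900)
  w <- as.Date(c("2008-07-01", "2008-07-05"))
  a <- zonal_mean(temporal_mean(s, w), xg, xg, p)
  per_slice <- vapply(1:nt, function(k) zonal_mean(arr[, , k], xg, xg, p),
                      numeric(1))
  expect_equal(a, mean(per_slice), tolerance = 1e-12)
})

test_that("covariate table has twelve predictors and drops uncovered records", {
  cfg <- sim_config(seed = 5, n_birds_per_site = 1, track_days = 100)
  st <- simulate_study(cfg)
  tr <- st$tracks[[1]]
  pr <- compute_fpt(tr, fpt_radii(100, 80, 1500))
  seg <- structure(list(track_label = tr$track_label[1],
                        segment_id = rep(1L, nrow(tr)),
                        breakpoints = nrow(tr), K_opt = 1L),
                   class = "track_segmentation")
  ud <- build_ud_polygons(tr, seg, pr, 500, bandwidth = c(300, 300),
                          cell = 250, min_fixes = 5)
  cov <- build_covariate_table(ud, st$env, st$sites)
  expect_true(all(predictor_names() %in% names(cov)))
  expect_length(predictor_names(), 12)
  expect_equal(cov$log_mfpt, log(cov$mfpt_rmax_h))
  # lagged window pushed before series start -> record dropped, logged
  ud_bad <- ud
  ud_bad$table <- ud$table[1, , drop = FALSE]
  ud_bad$table$t_start <- ud$table$t_start[1] - 50 * 86400
  expect_message(
    expect_error(build_covariate_table(ud_bad, st$env, st$sites),
                 "no covariate records"),
    "dropped")
  # missing site mapping is an error
  expect_error(build_covariate_table(ud, st$env, c(nobody = "BAR")),
               "missing bird")
})

test_that("raster CSV round trip preserves the series", {
  s <- make_series(c(0.1, 0.6, -0.2), xg = seq(0, 500, 250),
                   yg = seq(0, 500, 250))
  f <- withr::local_tempfile(fileext = ".csv")
  write_raster_csv(s, f)
  back <- read_raster_csv(f)
  expect_equal(back$values, s$values)
  expect_equal(back$times, s$times)
  expect_equal(back$variable, s$variable)
  expect_equal(back$step_days, s$step_days)
})
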