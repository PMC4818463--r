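#' Configuration for the synthetic telemetry study
#'
#' Defines a desk-scale study with known ground truth: multiple wetland
#' sites, several birds per site, two-phase movement (fast directed transit
#' between resource patches, slow tortuous area-restricted search inside
#' them), and dynamic resource rasters whose per-patch step changes precede
#' occupation.  Intensive-bout durations are drawn from the log-linear model
#' `log T = log T0 + beta_ndvi * z(dNDVI_32) + beta_precip * z(dPrecip_32) +
#' site_offset + b_bird + e`, with `z` standardised by the design moments of
#' the patch magnitude distributions, `b_bird ~ N(0, sigma_id^2)` and
#' `e ~ N(0, sigma_e^2)`; those durations are what the downstream FPT
#' pipeline recovers as `mFPT_Rmax`.
#'
#' @param seed integer master seed; all child streams derive from it.
#' @param sites data frame with `site`, `cx`, `cy` (planar site centres, m).
#' @param n_birds_per_site birds tagged per site.
#' @param species species tag ("goose" = 2 h fixes, "teal" = 4 h).
#' @param fix_interval_h hours between fixes.
#' @param track_days tracking duration per bird.
#' @param step_mean_ext,step_mean_int mean step length (m per fix interval)
#'   in the extensive and intensive state.
#' @param step_shape gamma shape of step lengths.
#' @param rho_ext,rho_int wrapped-Cauchy concentration of turning angles.
#' @param core_frac fraction of the patch radius forming the attraction core
#'   of intensive search (steps beyond it are redirected to the centre).
#' @param patch_radius radius (m) of the area-restricted search patches.
#' @param patch_spacing centre spacing (m) of the candidate patch lattice.
#' @param plateau_radius radius (m) of the constant resource plateau laid
#'   around each patch (covers the patch's utilisation polygon).
#' @param bout_t0_h baseline intensive-bout duration (h).
#' @param beta_ndvi,beta_precip true effects (per design SD of the patch
#'   magnitudes) on log bout duration.
#' @param sigma_id,sigma_e random-intercept and residual SD on the log scale.
#' @param site_offsets named numeric site effects on the log scale.
#' @param ndvi_step_range,precip_step_range,mndwi_step_range uniform ranges
#'   of the per-patch step magnitudes (the resource "pulses").
#' @param rain_lead_days days by which the rain step precedes green-up.
#' @param composite_days composite length for NDVI/mNDWI (16).
#' @param cell_ndvi,cell_precip,cell_temp raster cell sizes (m).
#' @param origin_date calendar date of tracking day 0.
#' @param gap_days if positive, one bird per study gets a data gap of this
#'   many days inserted mid-track (default 0: no gaps).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       sites = data.frame(site = c("BAR", "STR", "MAN"),
                                          cx = c(25e3, 80e3, 135e3),
                                          cy = c(25e3, 25e3, 25e3)),
                       n_birds_per_site = 4,
                       species = "goose",
                       fix_interval_h = if (species == "teal") 4 else 2,
                       track_days = 120,
                       step_mean_ext = 900, step_mean_int = 40,
                       step_shape = 3,
                       rho_ext = 0.8, rho_int = 0.2,
                       core_frac = 0.15,
                       patch_radius = 600,
                       patch_spacing = 4000,
                       plateau_radius = 1400,
                       bout_t0_h = 144,
                       beta_ndvi = 0.3, beta_precip = 0.35,
                       sigma_id = 0.12, sigma_e = 0.08,
                       site_offsets = c(BAR = 0, STR = 0.25, MAN = -0.25),
                       ndvi_step_range = c(0.10, 0.45),
                       precip_step_range = c(1, 4),
                       mndwi_step_range = c(0.05, 0.30),
                       rain_lead_days = 0,
                       composite_days = 16,
                       cell_ndvi = 250, cell_precip = 500, cell_temp = 1000,
                       origin_date = as.Date("2008-07-01"),
                       gap_days = 0) {
  stopifnot(step_mean_int < step_mean_ext, seed == as.integer(seed))
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Deterministic seed splitting: child k of master seed s.
.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 7919 * k) %% 2147483647)
}

.rwrappedcauchy <- function(n, rho) {
  # wrapped Cauchy turning angles centred on zero
  if (rho <= 0) return(stats::runif(n, -pi, pi))
  u <- stats::runif(n)
  2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5)))
}

# Candidate patch lattice for one bird: a 5x5 serpentine-ordered grid of
# patch centres around the bird's own sub-area of the site, so consecutive
# bouts are short transits apart and no two birds share a patch (each patch
# then has a single well-defined green-up time).
.bird_patches <- function(cfg, site_row, bird_index, n_birds) {
  off_r <- if (n_birds > 1) 14e3 else 0
  ang <- 2 * pi * (bird_index - 1) / max(n_birds, 1) + pi / 4
  cx <- site_row$cx + off_r * cos(ang)
  cy <- site_row$cy + off_r * sin(ang)
  sp <- cfg$patch_spacing
  ii <- -2:2
  ord <- do.call(rbind, lapply(seq_along(ii), function(r) {
    cols <- if (r %% 2 == 1) ii else rev(ii)
    cbind(i = cols, j = ii[r])
  }))
  data.frame(x = cx + ord[, "i"] * sp, y = cy + ord[, "j"] * sp)
}

#' Simulate one bird's two-state movement track
#'
#' Alternates directed extensive transit towards the next patch (gamma step
#' lengths, wrapped-Cauchy headings biased to the target) with intensive
#' area-restricted search confined to the patch (short tortuous steps,
#' redirected towards the patch centre at the boundary).  The fix interval is
#' honoured exactly.  Bout durations come from the configured log-linear
#' model, so the patch-resource effects are encoded in the emitted movement.
#'
#' @param cfg a `sim_config`.
#' @param bird_id bird identifier.
#' @param site site code for the bird.
#' @param patches data frame of this bird's patch centres (`x`, `y`) with
#'   magnitudes (`s_ndvi`, `q_precip`, `w_mndwi`).
#' @param b_bird the bird's random intercept on the log scale.
#' @param seed RNG seed for this bird's stream.
#' @return list with `track` (planar `track`), `states` (per-fix
#'   "extensive"/"intensive"), and `bouts` (one row per intensive bout:
#'   patch, arrival/end times, target duration, linear predictor).
#' @export
simulate_track <- function(cfg, bird_id, site, patches, b_bird = 0,
                           seed = cfg$seed) {
  set.seed(seed)
  dt_h <- cfg$fix_interval_h
  n_fix <- as.integer(cfg$track_days * 24 / dt_h) + 1L
  xs <- ys <- numeric(n_fix)
  state <- character(n_fix)
  sds <- .design_sds(cfg)
  # start at the first patch edge
  xs[1] <- patches$x[1] + cfg$patch_radius
  ys[1] <- patches$y[1]
  state[1] <- "extensive"
  heading <- stats::runif(1, -pi, pi)
  bouts <- list()
  i <- 1L
  p_idx <- 1L
  mode <- "transit"
  int_left <- 0L
  cur_eta <- NA_real_
  arrive_i <- NA_integer_
  while (i < n_fix) {
    if (mode == "transit") {
      tgt <- c(patches$x[p_idx], patches$y[p_idx])
      bearing <- atan2(tgt[2] - ys[i], tgt[1] - xs[i])
      heading <- bearing + .rwrappedcauchy(1, cfg$rho_ext)
      len <- stats::rgamma(1, shape = cfg$step_shape,
                           scale = cfg$step_mean_ext / cfg$step_shape)
      dist_tgt <- sqrt(sum((tgt - c(xs[i], ys[i]))^2))
      if (len >= dist_tgt - cfg$patch_radius / 2) {
        # step lands in the patch: place near the centre line
        len <- max(dist_tgt - cfg$patch_radius / 2, cfg$step_mean_int)
        heading <- bearing
      }
      xs[i + 1] <- xs[i] + len * cos(heading)
      ys[i + 1] <- ys[i] + len * sin(heading)
      i <- i + 1L
      state[i] <- "extensive"
      if (sqrt(sum((c(xs[i], ys[i]) - tgt)^2)) <= cfg$patch_radius) {
        # patch entry: draw this bout's duration from the log-linear model
        eta <- cfg$beta_ndvi * (patches$s_ndvi[p_idx] - sds$mu_s) / sds$sd_s +
          cfg$beta_precip * (patches$q_precip[p_idx] - sds$mu_q) / sds$sd_q +
          cfg$site_offsets[[site]] + b_bird
        T_h <- cfg$bout_t0_h * exp(eta + stats::rnorm(1, 0, cfg$sigma_e))
        int_left <- max(3L, as.integer(round(T_h / dt_h)))
        if (i + int_left >= n_fix) break
        # the track ends mid-transit when the next bout cannot complete, so
        # every recorded bout has its full drawn duration
        cur_eta <- eta
        arrive_i <- i
        state[i] <- "intensive"
        mode <- "ars"
      }
    } else if (mode == "ars") {
      ctr <- c(patches$x[p_idx], patches$y[p_idx])
      heading <- heading + .rwrappedcauchy(1, cfg$rho_int)
      len <- stats::rgamma(1, shape = cfg$step_shape,
                           scale = cfg$step_mean_int / cfg$step_shape)
      nx <- xs[i] + len * cos(heading)
      ny <- ys[i] + len * sin(heading)
      if (sqrt(sum((c(nx, ny) - ctr)^2)) > cfg$core_frac * cfg$patch_radius) {
        # redirect towards the patch centre: keeps the search cloud
        # concentrated in the core of the patch
        heading <- atan2(ctr[2] - ys[i], ctr[1] - xs[i]) +
          .rwrappedcauchy(1, 0.7)
        nx <- xs[i] + len * cos(heading)
        ny <- ys[i] + len * sin(heading)
      }
      xs[i + 1] <- nx
      ys[i + 1] <- ny
      i <- i + 1L
      state[i] <- "intensive"
      int_left <- int_left - 1L
      if (int_left <= 0L) {
        bouts[[length(bouts) + 1L]] <-
          data.frame(patch = p_idx, i_start = arrive_i, i_end = i,
                     t_start_h = (arrive_i - 1) * dt_h,
                     t_end_h = (i - 1) * dt_h,
                     eta = cur_eta,
                     s_ndvi = patches$s_ndvi[p_idx],
                     q_precip = patches$q_precip[p_idx],
                     w_mndwi = patches$w_mndwi[p_idx])
        p_idx <- p_idx + 1L
        if (p_idx > nrow(patches)) break
        mode <- "transit"
      }
    }
  }
  n_used <- i
  ts <- as.POSIXct(cfg$origin_date, tz = "UTC") +
    (seq_len(n_used) - 1) * dt_h * 3600
  df <- data.frame(bird_id = bird_id, track_label = bird_id,
                   timestamp = ts, x = xs[seq_len(n_used)],
                   y = ys[seq_len(n_used)])
  tr <- track(df, species = cfg$species, site = site, planar = TRUE)
  list(track = tr, states = state[seq_len(n_used)],
       bouts = if (length(bouts)) do.call(rbind, bouts) else NULL)
}

.design_sds <- function(cfg) {
  list(mu_s = mean(cfg$ndvi_step_range),
       sd_s = diff(cfg$ndvi_step_range) / sqrt(12),
       mu_q = mean(cfg$precip_step_range),
       sd_q = diff(cfg$precip_step_range) / sqrt(12))
}

# smooth static background noise: coarse white noise, bilinearly interpolated
.smooth_noise <- function(xg, yg, coarse = 4000, sd = 1, seed = 1) {
  set.seed(seed)
  cx <- seq(min(xg) - coarse, max(xg) + coarse, by = coarse)
  cy <- seq(min(yg) - coarse, max(yg) + coarse, by = coarse)
  zc <- matrix(stats::rnorm(length(cx) * length(cy), 0, sd),
               length(cx), length(cy))
  ix <- findInterval(xg, cx)
  iy <- findInterval(yg, cy)
  fx <- (xg - cx[ix]) / coarse
  fy <- (yg - cy[iy]) / coarse
  z <- matrix(0, length(xg), length(yg))
  for (j in seq_along(yg)) {
    z[, j] <- zc[cbind(ix, iy[j])] * (1 - fx) * (1 - fy[j]) +
      zc[cbind(ix + 1L, iy[j])] * fx * (1 - fy[j]) +
      zc[cbind(ix, iy[j] + 1L)] * (1 - fx) * fy[j] +
      zc[cbind(ix + 1L, iy[j] + 1L)] * fx * fy[j]
  }
  z
}

#' Simulate the environmental raster bundle
#'
#' Builds NDVI and mNDWI 16-day composites, daily precipitation and
#' temperature, and a static elevation surface on planar grids covering all
#' sites.  Each patch carries a constant resource plateau that steps from its
#' pre- to post-event value at the patch's event date (rain optionally
#' leading green-up by `rain_lead_days`); the background is smooth static
#' noise, so lagged differences are zero away from patches.
#'
#' @param cfg a `sim_config`.
#' @param schedule data frame with one row per patch: `x`, `y`, `event_day`
#'   (tracking day of the composite-aligned green-up), `s_ndvi`, `q_precip`,
#'   `w_mndwi`.
#' @param seed RNG seed for the background noise stream.
#' @return named list of `raster_series` (`ndvi`, `mndwi`, `precip`, `temp`)
#'   and `static_raster` `elev`.
#' @export
simulate_env <- function(cfg, schedule, seed = cfg$seed) {
  pad <- cfg$plateau_radius + 4 * cfg$cell_ndvi + 1.2e4
  xr <- range(schedule$x) + c(-pad, pad)
  yr <- range(schedule$y) + c(-pad, pad)
  lead <- 48  # days of pre-track coverage for the 32-day lag windows
  comp_start <- seq(-lead, cfg$track_days + cfg$composite_days,
                    by = cfg$composite_days)
  days <- seq(-lead, cfg$track_days + 16)
  if (cfg$track_days > max(days))
    stop("raster dates too short for the configured track length and lags")
  grids <- list(
    ndvi = list(xg = .grid_axis(xr, cfg$cell_ndvi),
                yg = .grid_axis(yr, cfg$cell_ndvi)),
    precip = list(xg = .grid_axis(xr, cfg$cell_precip),
                  yg = .grid_axis(yr, cfg$cell_precip)),
    temp = list(xg = .grid_axis(xr, cfg$cell_temp),
                yg = .grid_axis(yr, cfg$cell_temp)))

  plateau_cells <- function(g, px, py) {
    ix <- which(abs(g$xg - px) <= cfg$plateau_radius)
    iy <- which(abs(g$yg - py) <= cfg$plateau_radius)
    cc <- expand.grid(i = ix, j = iy)
    keep <- (g$xg[cc$i] - px)^2 + (g$yg[cc$j] - py)^2 <= cfg$plateau_radius^2
    cc[keep, , drop = FALSE]
  }

  # per-patch pre/post plateau levels; post level independent of step size
  np <- nrow(schedule)
  set.seed(.child_seed(seed, 101))
  ndvi_post <- stats::runif(np, 0.45, 0.75)
  mndwi_post <- stats::runif(np, 0.0, 0.4)
  precip_wet <- stats::runif(np, 4.5, 12)

  g <- grids$ndvi
  base_ndvi <- 0.2 + 0.02 * .smooth_noise(g$xg, g$yg, seed = .child_seed(seed, 1))
  base_mndwi <- -0.15 + 0.02 * .smooth_noise(g$xg, g$yg, seed = .child_seed(seed, 2))
  nslice <- length(comp_start)
  ndvi <- array(rep(pmin(pmax(base_ndvi, -1), 1), nslice),
                c(length(g$xg), length(g$yg), nslice))
  mndwi <- array(rep(pmin(pmax(base_mndwi, -1), 1), nslice),
                 c(length(g$xg), length(g$yg), nslice))
  for (p in seq_len(np)) {
    cc <- plateau_cells(g, schedule$x[p], schedule$y[p])
    post <- comp_start >= schedule$event_day[p]
    idx <- cbind(rep(cc$i, nslice), rep(cc$j, nslice),
                 rep(seq_len(nslice), each = nrow(cc)))
    ndvi[idx] <- ifelse(rep(post, each = nrow(cc)), ndvi_post[p],
                        ndvi_post[p] - schedule$s_ndvi[p])
    mndwi[idx] <- ifelse(rep(post, each = nrow(cc)), mndwi_post[p],
                         mndwi_post[p] - schedule$w_mndwi[p])
  }
  ndvi <- pmin(pmax(ndvi, -1), 1)
  mndwi <- pmin(pmax(mndwi, -1), 1)

  gp <- grids$precip
  base_p <- pmax(0.4 + 0.05 * .smooth_noise(gp$xg, gp$yg,
                                            seed = .child_seed(seed, 3)), 0.05)
  nd <- length(days)
  precip <- array(rep(base_p, nd), c(length(gp$xg), length(gp$yg), nd))
  for (p in seq_len(np)) {
    cc <- plateau_cells(gp, schedule$x[p], schedule$y[p])
    wet <- days >= schedule$event_day[p] - cfg$rain_lead_days
    dry <- max(precip_wet[p] - schedule$q_precip[p], 0)
    idx <- cbind(rep(cc$i, nd), rep(cc$j, nd), rep(seq_len(nd), each = nrow(cc)))
    precip[idx] <- ifelse(rep(wet, each = nrow(cc)), precip_wet[p], dry)
  }

  gt <- grids$temp
  base_t <- 18 + 0.5 * .smooth_noise(gt$xg, gt$yg, seed = .child_seed(seed, 4))
  temp <- array(0, c(length(gt$xg), length(gt$yg), nd))
  seas <- 6 * sin(2 * pi * (days + 30) / 365)
  for (k in seq_len(nd)) temp[, , k] <- base_t + seas[k]

  elevv <- 1200 + 0.002 * outer(gt$xg - mean(gt$xg), rep(1, length(gt$yg))) +
    15 * .smooth_noise(gt$xg, gt$yg, seed = .child_seed(seed, 5))

  d0 <- cfg$origin_date
  list(ndvi = raster_series("NDVI", d0 + comp_start, cfg$composite_days,
                            g$xg, g$yg, ndvi),
       mndwi = raster_series("mNDWI", d0 + comp_start, cfg$composite_days,
                             g$xg, g$yg, mndwi),
       precip = raster_series("precip", d0 + days, 1, gp$xg, gp$yg, precip),
       temp = raster_series("temp", d0 + days, 1, gt$xg, gt$yg, temp),
       elev = static_raster("elev", gt$xg, gt$yg, elevv))
}

#' Simulate a complete synthetic study
#'
#' Draws per-patch resource magnitudes and per-bird random intercepts,
#' simulates every bird's two-state track, aligns each visited patch's
#' resource step to the 16-day composite boundary preceding the bird's
#' arrival (so occupation follows a positive lagged resource change), and
#' renders the raster bundle.  Everything is reproducible from the master
#' seed via fixed child streams.
#'
#' @param cfg a `sim_config`.
#' @return a `sim_study`: list with `tracks` (list of planar `track`s),
#'   `env` (see [simulate_env()]), `sites` (named bird -> site vector), and
#'   `truth` (per-bout design table, per-bird intercepts, the true betas and
#'   design SDs, per-fix state labels).
#' @export
simulate_study <- function(cfg = sim_config()) {
  comp <- cfg$composite_days
  tracks <- list()
  states <- list()
  bouts_all <- list()
  sched_all <- list()
  sites_map <- character()
  b_birds <- numeric()
  bird_no <- 0L
  for (srow in seq_len(nrow(cfg$sites))) {
    site <- cfg$sites$site[srow]
    for (b in seq_len(cfg$n_birds_per_site)) {
      bird_no <- bird_no + 1L
      bird_id <- sprintf("%s%02d", site, b)
      set.seed(.child_seed(cfg$seed, 1000 + bird_no))
      pb <- .bird_patches(cfg, cfg$sites[srow, ], b, cfg$n_birds_per_site)
      np <- nrow(pb)
      pb$s_ndvi <- stats::runif(np, cfg$ndvi_step_range[1],
                                cfg$ndvi_step_range[2])
      pb$q_precip <- stats::runif(np, cfg$precip_step_range[1],
                                  cfg$precip_step_range[2])
      pb$w_mndwi <- stats::runif(np, cfg$mndwi_step_range[1],
                                 cfg$mndwi_step_range[2])
      b_bird <- stats::rnorm(1, 0, cfg$sigma_id)
      sim <- simulate_track(cfg, bird_id, site, pb, b_bird,
                            seed = .child_seed(cfg$seed, 2000 + bird_no))
      if (cfg$gap_days > 0 && bird_no == 1L) {
        # carve a data gap mid-track (exercises gap splitting downstream)
        tr <- as.data.frame(sim$track)
        day <- as.numeric(difftime(tr$timestamp, tr$timestamp[1],
                                   units = "days"))
        keep <- day < 40 | day >= 40 + cfg$gap_days
        sim$track <- track(tr[keep, , drop = FALSE], species = cfg$species,
                           site = site, planar = TRUE)
        sim$states <- sim$states[keep]
      }
      tracks[[bird_id]] <- sim$track
      states[[bird_id]] <- sim$states
      sites_map[bird_id] <- site
      b_birds[bird_id] <- b_bird
      if (!is.null(sim$bouts)) {
        bt <- sim$bouts
        bt$bird_id <- bird_id
        bt$site <- site
        # resource step at the composite boundary preceding arrival
        bt$event_day <- comp * floor(bt$t_start_h / 24 / comp)
        bouts_all[[bird_id]] <- bt
        sched_all[[bird_id]] <-
          data.frame(x = pb$x[bt$patch], y = pb$y[bt$patch],
                     event_day = bt$event_day, s_ndvi = bt$s_ndvi,
                     q_precip = bt$q_precip, w_mndwi = bt$w_mndwi)
      }
    }
  }
  schedule <- do.call(rbind, sched_all)
  env <- simulate_env(cfg, schedule, seed = .child_seed(cfg$seed, 3))
  structure(list(tracks = tracks, env = env, sites = sites_map,
                 truth = list(bouts = do.call(rbind, bouts_all),
                              schedule = schedule, b_birds = b_birds,
                              beta = c(ndvi = cfg$beta_ndvi,
                                       precip = cfg$beta_precip),
                              design = .design_sds(cfg),
                              site_offsets = cfg$site_offsets,
                              states = states),
                 config = cfg),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study: %d tracks at %d sites, %d true bouts, seed %d>\n",
              length(x$tracks), nrow(x$config$sites),
              nrow(x$truth$bouts), x$config$seed))
  invisible(x)
}

#' Simulate a covariate table directly from the regression model
#'
#' Bypasses the movement and raster stages: draws the twelve predictors and
#' generates `log_mfpt` from the random-intercept linear model
#' `log T0 + beta' x + site offset + b_bird + e`.  Used to check coefficient
#' and interval recovery of the model-fitting stage against exact truth.
#'
#' @param n_polygons records to draw.
#' @param n_birds birds (random-effect groups), split evenly over 3 sites.
#' @param beta named effects on the z-scale of the drawn predictors; any of
#'   the numeric predictor names (default: effects on `d_ndvi_32` and
#'   `d_precip_32`).
#' @param site_offsets named site effects.
#' @param sigma_id,sigma_e random-intercept and residual SD.
#' @param seed RNG seed.
#' @return list with `table` (a covariate table accepted by
#'   [prepare_inputs()]) and `truth` (betas, intercepts).
#' @export
simulate_covariate_data <- function(n_polygons = 150, n_birds = 12,
                                    beta = c(d_ndvi_32 = 0.3,
                                             d_precip_32 = 0.35),
                                    site_offsets = c(BAR = 0, STR = 0.25,
                                                     MAN = -0.25),
                                    sigma_id = 0.12, sigma_e = 0.3,
                                    seed = 1) {
  set.seed(seed)
  sites <- names(site_offsets)
  birds <- sprintf("%s%02d", rep(sites, length.out = n_birds),
                   seq_len(n_birds))
  bird_site <- setNames(rep(sites, length.out = n_birds), birds)
  b <- setNames(stats::rnorm(n_birds, 0, sigma_id), birds)
  tab <- data.frame(polygon_id = seq_len(n_polygons),
                    track_label = sample(birds, n_polygons, replace = TRUE))
  tab$bird_id <- tab$track_label
  tab$site <- unname(bird_site[tab$bird_id])
  for (v in setdiff(predictor_names(), "site"))
    tab[[v]] <- stats::rnorm(n_polygons)
  eta <- log(144) + unname(site_offsets[tab$site]) + unname(b[tab$bird_id])
  for (v in names(beta)) eta <- eta + beta[[v]] * tab[[v]]
  tab$log_mfpt <- eta + stats::rnorm(n_polygons, 0, sigma_e)
  tab$mfpt_rmax_h <- exp(tab$log_mfpt)
  list(table = tab, truth = list(beta = beta, site_offsets = site_offsets,
                                 b_birds = b, sigma_id = sigma_id,
                                 sigma_e = sigma_e))
}

#' Write a simulated study to disk as plain-text files
#'
#' Emits the formats the pipeline consumes: a tracks CSV, per-variable raster
#' CSVs, and a bird-to-site mapping CSV.
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if needed).
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tracks(study$tracks, file.path(dir, "tracks.csv"))
  for (v in c("ndvi", "mndwi", "precip", "temp"))
    write_raster_csv(study$env[[v]], file.path(dir, paste0(v, ".csv")))
  el <- study$env$elev
  grid <- expand.grid(x = el$xg, y = el$yg)
  grid$value <- as.vector(el$values)
  write.csv(grid, file.path(dir, "elev.csv"), row.names = FALSE)
  write.csv(data.frame(bird_id = names(study$sites),
                       site = unname(study$sites)),
            file.path(dir, "sites.csv"), row.names = FALSE)
  invisible(dir)
}
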