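const_track <- function(v_um_s, n = 20, dt = 0.12, start = 0,
                        direction = "anterograde", id = 1) {
  train_track(id, direction,
              data.frame(frame = seq_len(n),
                         arc_um = start + v_um_s * seq_len(n) * dt),
              frame_interval_s = dt, pixel_size_um = 0.13)
}

test_that("blank directional kymographs yield no tracks", {
  km <- structure(list(matrix = matrix(0, 30, 30), pixel_size_um = 0.13,
                       frame_interval_s = 0.12), class = "kymograph")
  dk <- structure(list(anterograde = km, retrograde = km, static = km),
                  class = "directional_kymographs")
  expect_length(extract_tracks(dk), 0)
})

test_that("two well-separated trains are recovered with correct directions", {
  cfg <- ift_sim_config(seed = 45, antero_injection_rate_hz = 0.012,
                        retro_injection_rate_hz = 0.03, n_frames = 300,
                        pause_prob = 0, photons_per_train = 3000)
  sim <- simulate_ift_movie(cfg)
  truth_dirs <- table(sim$truth$tracks$direction)
  expect_equal(unname(truth_dirs["anterograde"]), 1)
  expect_equal(unname(truth_dirs["retrograde"]), 1)
  res <- analyze_movie(sim)
  got <- table(vapply(res$tracks, function(t) t$direction, ""))
  expect_equal(unname(got["anterograde"]), 1)
  expect_equal(unname(got["retrograde"]), 1)
})

test_that("track recovery on a multi-train movie matches ground truth", {
  # accumulate a 20+-train ensemble over fixed seeds; pauses off so every
  # truth train is a single unbroken streak
  n_truth <- 0
  n_matched <- 0
  n_false_dir <- 0
  for (seed in c(31, 32, 33)) {
    cfg <- ift_sim_config(seed = seed, pause_prob = 0)
    sim <- simulate_ift_movie(cfg)
    res <- analyze_movie(sim)
    tt <- sim$truth
    vis <- which(tt$tracks$visible &
                   vapply(tt$trajectories, nrow, 1L) >= 5)
    n_truth <- n_truth + length(vis)
    for (i in vis) {
      traj <- tt$trajectories[[i]]
      cand_dirs <- character(0)
      for (t in res$tracks) {
        common <- intersect(t$samples$frame, traj$frame)
        if (length(common) < 3) next
        d <- abs(t$samples$arc_um[match(common, t$samples$frame)] -
                   traj$arc_um[match(common, traj$frame)])
        if (median(d) <= 2 * 0.13) cand_dirs <- c(cand_dirs, t$direction)
      }
      if (length(cand_dirs)) {
        n_matched <- n_matched + 1
        # a truth train matched only by wrong-direction tracks is a
        # direction error; spatial co-location with an opposite train
        # passing through is not
        if (!tt$tracks$direction[i] %in% cand_dirs) {
          n_false_dir <- n_false_dir + 1
        }
      }
    }
  }
  expect_gte(n_truth, 20)
  expect_gte(n_matched / n_truth, 0.9)
  expect_equal(n_false_dir, 0)
})

test_that("track velocity arithmetic is exact on constructed tracks", {
  # 0.0264 um per 0.12 s frame
  tr <- const_track(0.0264 / 0.12)
  expect_equal(as.numeric(track_velocity(tr)), 0.22, tolerance = 1e-10)
  tr0 <- const_track(0)
  expect_equal(as.numeric(track_velocity(tr0)), 0)
  degen <- train_track(1, "anterograde",
                       data.frame(frame = 1:4, arc_um = 1:4 * 0.1),
                       0.12, 0.13)
  expect_error(track_velocity(degen), "at least 5")
})

test_that("stall detection finds an injected zero-motion plateau", {
  arc <- c(seq(0, 0.9, by = 0.1), rep(0.9, 5), seq(1.0, 1.5, by = 0.1))
  tr <- train_track(1, "anterograde",
                    data.frame(frame = seq_along(arc), arc_um = arc),
                    0.12, 0.13)
  st <- detect_stalls(tr)
  expect_equal(nrow(st), 1)
  expect_equal(st$start_frame, 10)
  expect_equal(st$end_frame, 15)
  # constant-velocity track above threshold: no stalls
  expect_equal(nrow(detect_stalls(const_track(0.22))), 0)
})

test_that("velocity is recovered within 10% across truth speeds", {
  for (speeds in list(c(0.22, 1.2), c(0.1, 0.5), c(0.4, 2.0))) {
    cfg <- ift_sim_config(seed = 101 + round(10 * speeds[1]),
                          antero_speed_um_s = speeds[1],
                          retro_speed_um_s = speeds[2], pause_prob = 0)
    sim <- simulate_ift_movie(cfg)
    res <- analyze_movie(sim)
    pd <- summarize_trains(res$tracks)$per_direction
    expect_equal(pd$velocity_median_um_s[pd$direction == "anterograde"],
                 speeds[1], tolerance = 0.1)
    expect_equal(pd$velocity_median_um_s[pd$direction == "retrograde"],
                 speeds[2], tolerance = 0.1)
  }
})

test_that("measured streak FWHM matches the boxcar-PSF convolution oracle", {
  widths <- numeric(0)
  for (l_nm in c(200, 358, 500)) {
    cfg <- ift_sim_config(seed = 10, antero_injection_rate_hz = 0.02,
                          retro_injection_rate_hz = 0, n_frames = 300,
                          antero_length_nm = l_nm, antero_length_sd_nm = 0,
                          photons_per_train = 5000)
    sim <- simulate_ift_movie(cfg, noise = FALSE)
    res <- analyze_movie(sim)
    ant <- Filter(function(t) t$direction == "anterograde", res$tracks)
    expect_length(ant, 1)
    got <- train_length(ant[[1]], res$kymo)
    oracle <- boxcar_psf_fwhm(l_nm, 110)
    expect_equal(got, oracle, tolerance = 0.1)
    widths <- c(widths, got)
  }
  # monotonic in true length at fixed PSF
  expect_true(all(diff(widths) > 0))
})

test_that("a delta-like train measures the PSF width itself", {
  cfg <- ift_sim_config(seed = 10, antero_injection_rate_hz = 0.02,
                        retro_injection_rate_hz = 0, n_frames = 300,
                        antero_length_nm = 50, antero_length_sd_nm = 0,
                        photons_per_train = 5000)
  sim <- simulate_ift_movie(cfg, noise = FALSE)
  res <- analyze_movie(sim)
  ant <- Filter(function(t) t$direction == "anterograde", res$tracks)
  got <- train_length(ant[[1]], res$kymo)
  psf_fwhm <- 2 * sqrt(2 * log(2)) * 110
  # at ~2 px per PSF FWHM the sampled profile reads up to ~8% wide
  # depending on sub-pixel phase; that pixelation bias is part of the
  # measurement, as it is for a manual line measurement on real images
  expect_equal(got, psf_fwhm, tolerance = 0.1)
})

test_that("particle counts follow the repeat-spacing arithmetic", {
  expect_identical(particles_per_train(358), 58L)
  expect_identical(particles_per_train(237), 38L)
  expect_identical(particles_per_train(0), 0L)
  expect_error(particles_per_train(-5), "negative")
})

test_that("crossing tracks yield one encounter at the analytic intersection", {
  # retro: s = 5 - 1.2 t ; antero: s = 0.22 t -> t* = 5/1.42, s* = 0.22 t*
  dt <- 0.12
  n <- 40
  retro <- train_track(1, "retrograde",
                       data.frame(frame = 1:n, arc_um = 5 - 1.2 * (1:n) * dt),
                       dt, 0.13)
  antero <- train_track(2, "anterograde",
                        data.frame(frame = 1:n, arc_um = 0.22 * (1:n) * dt),
                        dt, 0.13)
  ev <- find_encounters(list(retro, antero))
  expect_equal(nrow(ev), 1)
  t_star <- 5 / 1.42 / dt
  expect_equal(ev$frame, t_star, tolerance = 1e-6)
  expect_equal(ev$arc_um, 0.22 * t_star * dt, tolerance = 1e-6)
  expect_equal(ev$outcome, "pass")
  # parallel same-direction tracks: no events
  a2 <- train_track(3, "anterograde",
                    data.frame(frame = 1:n, arc_um = 1 + 0.22 * (1:n) * dt),
                    dt, 0.13)
  expect_equal(nrow(find_encounters(list(antero, a2))), 0)
})

test_that("pause classification is unbiased over seeds", {
  fr <- numeric(0)
  for (seed in 1:10) {
    cfg <- ift_sim_config(seed = 700 + seed, pause_prob = 0.5)
    sim <- simulate_ift_movie(cfg, noise = FALSE)
    tracks <- truth_to_tracks(sim$truth)
    tracks <- lapply(tracks, function(t) {
      if (t$direction == "retrograde") t$stalls <- detect_stalls(t)
      t
    })
    enc <- find_encounters(tracks)
    if (nrow(enc)) fr <- c(fr, mean(enc$outcome == "pause"))
  }
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 2 * se + 1e-9)
})

test_that("summary statistics handle empty and single-track inputs", {
  st <- summarize_trains(list())
  expect_equal(st$per_direction$n_tracks, c(0L, 0L))
  expect_true(is.na(st$fraction_retro_with_stall))
  expect_true(is.na(st$fraction_pause_on_encounter))

  tr <- const_track(0.22)
  st1 <- summarize_trains(list(tr))
  pd <- st1$per_direction
  expect_equal(pd$velocity_median_um_s[pd$direction == "anterograde"], 0.22,
               tolerance = 1e-10)
  expect_equal(pd$velocity_mean_um_s[pd$direction == "anterograde"], 0.22,
               tolerance = 1e-10)
})
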