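#' Configuration for the synthetic IFT time-lapse generator
#'
#' Describes bidirectional sub-resolution IFT trains moving along a straight
#' 1D ciliary track, rendered with a Gaussian point-spread function and
#' photon noise, at the acquisition settings of spinning-disc live imaging
#' of chordotonal cilia (120 ms frame interval by default).
#'
#' Train lengths are drawn per train from normal distributions
#' (`*_length_nm` mean, `*_length_sd_nm` spread, truncated at 50 nm).
#' Retrograde trains pause with probability `pause_prob` for
#' `pause_duration_s` when they meet an anterograde train; anterograde
#' trains never pause.
#'
#' @param n_frames Number of frames (>= 2).
#' @param frame_interval_s Frame interval in seconds (default 0.12).
#' @param pixel_size_um Pixel size in micrometres (default 0.13).
#' @param cilium_length_um Length of the imaged proximal ciliary segment.
#' @param antero_speed_um_s,retro_speed_um_s Train speeds in um/s.
#' @param antero_injection_rate_hz,retro_injection_rate_hz Train injection
#'   rates in trains/s (0 allowed: blank movie).
#' @param antero_length_nm,retro_length_nm Mean train lengths in nm.
#' @param antero_length_sd_nm,retro_length_sd_nm Train-length spreads in nm.
#' @param pause_prob Probability that a retrograde train pauses at an
#'   encounter with an anterograde train.
#' @param pause_duration_s Pause duration in seconds.
#' @param psf_sigma_um Gaussian PSF sigma in micrometres.
#' @param background Mean background level in photon counts per pixel.
#' @param photons_per_train Integrated photons per train per frame.
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param seed RNG seed (mandatory).
#' @return An `ift_sim_config` list.
#' @export
ift_sim_config <- function(n_frames = 500, frame_interval_s = 0.12,
                           pixel_size_um = 0.13, cilium_length_um = 5,
                           antero_speed_um_s = 0.22, retro_speed_um_s = 1.2,
                           antero_injection_rate_hz = 0.15,
                           retro_injection_rate_hz = 0.15,
                           antero_length_nm = 358, retro_length_nm = 237,
                           antero_length_sd_nm = 80, retro_length_sd_nm = 50,
                           pause_prob = 0.76, pause_duration_s = 1.0,
                           psf_sigma_um = 0.11, background = 20,
                           photons_per_train = 1000, read_noise_sd = 2,
                           seed = 1) {
  stopifnot(
    n_frames >= 2, frame_interval_s > 0, pixel_size_um > 0,
    cilium_length_um > 0, antero_speed_um_s >= 0, retro_speed_um_s >= 0,
    antero_injection_rate_hz >= 0, retro_injection_rate_hz >= 0,
    antero_length_nm > 0, retro_length_nm > 0,
    antero_length_sd_nm >= 0, retro_length_sd_nm >= 0,
    pause_prob >= 0, pause_prob <= 1, pause_duration_s >= 0,
    psf_sigma_um > 0, background >= 0, photons_per_train >= 0,
    read_noise_sd >= 0
  )
  if (cilium_length_um < 2 * psf_sigma_um * 2.3548) {
    stop("cilium shorter than two PSF widths (FWHM); nothing resolvable to render")
  }
  structure(as.list(environment()), class = "ift_sim_config")
}

#' Simulate an IFT time-lapse movie with known ground truth
#'
#' Renders bidirectional IFT trains on a straight ciliary path (left = base,
#' arc coordinate 0; right = tip). Each train is a boxcar of its length
#' convolved with the Gaussian PSF, carrying `photons_per_train` integrated
#' counts, spread transversely with the same Gaussian. Retrograde trains
#' pause at encounters with anterograde trains with probability
#' `pause_prob`; each (retrograde, anterograde) pair triggers at most one
#' encounter event. Photon (Poisson) noise and Gaussian read noise are
#' applied when `noise = TRUE`.
#'
#' @param config An [ift_sim_config()].
#' @param noise Apply Poisson + read noise (default `TRUE`). `FALSE` yields
#'   the noiseless expectation image, useful for calibration tests.
#' @return A list with `movie` (a [movie_stack()]) and `truth`, a ground
#'   truth list holding `tracks` (per-train id, direction, entry frame,
#'   speed, length), `trajectories` (per-train data frame of `frame`,
#'   `arc_um` while inside the cilium), `encounters` (retro/antero pair,
#'   frame, arc, outcome, pause duration), `pauses`, and `path` (the (y, x)
#'   base and tip vertices of the rendered track, in pixels).
#' @export
simulate_ift_movie <- function(config, noise = TRUE) {
  stopifnot(inherits(config, "ift_sim_config"))
  set.seed(config$seed)
  px <- config$pixel_size_um
  dt <- config$frame_interval_s
  L <- config$cilium_length_um
  nf <- config$n_frames
  T_total <- nf * dt

  pad <- 6L
  nx <- as.integer(ceiling(L / px)) + 2L * pad
  ny <- 9L
  y0 <- 5L
  arc_of_col <- (seq_len(nx) - 1L - pad) * px  # arc (um) at each column

  draw_trains <- function(direction) {
    rate <- if (direction == "anterograde") {
      config$antero_injection_rate_hz
    } else {
      config$retro_injection_rate_hz
    }
    speed <- if (direction == "anterograde") {
      config$antero_speed_um_s
    } else {
      config$retro_speed_um_s
    }
    len_mean <- if (direction == "anterograde") {
      config$antero_length_nm
    } else {
      config$retro_length_nm
    }
    len_sd <- if (direction == "anterograde") {
      config$antero_length_sd_nm
    } else {
      config$retro_length_sd_nm
    }
    if (rate == 0 || speed == 0) {
      return(data.frame(direction = character(), t0 = numeric(),
                        speed = numeric(), length_nm = numeric()))
    }
    transit <- L / speed
    n <- stats::rpois(1, rate * (T_total + transit))
    if (n == 0) {
      return(data.frame(direction = character(), t0 = numeric(),
                        speed = numeric(), length_nm = numeric()))
    }
    t0 <- sort(stats::runif(n, -transit, T_total))
    lens <- pmax(stats::rnorm(n, len_mean, len_sd), 50)
    data.frame(direction = direction, t0 = t0, speed = speed,
               length_nm = lens)
  }

  trains <- rbind(draw_trains("anterograde"), draw_trains("retrograde"))
  n_trains <- nrow(trains)
  if (n_trains > 0) trains$id <- seq_len(n_trains)

  t_frames <- (seq_len(nf) - 1) * dt
  # position matrix: rows frames, cols trains; NA when outside the cilium
  pos <- matrix(NA_real_, nf, max(n_trains, 1))
  encounters <- list()
  pauses <- list()

  if (n_trains > 0) {
    is_retro <- trains$direction == "retrograde"
    antero_idx <- which(!is_retro)
    # anterograde trains: deterministic straight trajectories
    for (j in antero_idx) {
      s <- trains$speed[j] * (t_frames - trains$t0[j])
      s[s < 0 | s > L] <- NA
      pos[, j] <- s
    }
    # retrograde trains: stepwise, with stochastic pausing at encounters
    for (j in which(is_retro)) {
      v <- trains$speed[j]
      entered <- FALSE
      s <- NA_real_
      pause_until <- -Inf
      seen <- logical(n_trains)
      for (f in seq_len(nf)) {
        t_now <- t_frames[f]
        if (t_now < trains$t0[j]) next  # not yet injected at the tip
        if (!entered) {
          s <- L - v * (t_now - trains$t0[j])
          entered <- TRUE
        }
        if (s < 0) break  # reached the base and left the cilium
        pos[f, j] <- s
        # encounter check against anterograde trains active this frame; a
        # decision point requires the retrograde train to have moved into
        # the crossing - crossings while it sits paused are not decisions
        # and are neither drawn nor recorded
        moved <- f > 1 && !is.na(pos[f - 1, j]) && pos[f, j] != pos[f - 1, j]
        if (moved) {
          for (a in antero_idx) {
            if (seen[a]) next
            sa_prev <- pos[f - 1, a]
            sa_now <- pos[f, a]
            sr_prev <- pos[f - 1, j]
            sr_now <- pos[f, j]
            if (anyNA(c(sa_prev, sa_now, sr_prev, sr_now))) next
            if ((sr_prev - sa_prev) * (sr_now - sa_now) <= 0) {
              seen[a] <- TRUE
              outcome <- if (stats::runif(1) < config$pause_prob) "pause" else "pass"
              dur <- if (outcome == "pause") config$pause_duration_s else 0
              encounters[[length(encounters) + 1]] <- data.frame(
                retro_id = trains$id[j], antero_id = trains$id[a],
                frame = f, arc_um = (sr_now + sa_now) / 2,
                outcome = outcome, pause_duration_s = dur
              )
              if (outcome == "pause") {
                pause_until <- t_now + config$pause_duration_s
                pauses[[length(pauses) + 1]] <- data.frame(
                  track_id = trains$id[j], start_frame = f,
                  end_frame = min(nf, f + round(config$pause_duration_s / dt)),
                  duration_s = config$pause_duration_s
                )
              }
            }
          }
        }
        # advance to next frame unless paused
        if (t_now >= pause_until) s <- s - v * dt
      }
    }
  }

  # render expectation images
  sigma_um <- config$psf_sigma_um
  sigma_px <- sigma_um / px
  wy <- stats::dnorm(seq_len(ny), y0, sigma_px)
  wy <- wy / sum(wy)
  stack <- array(config$background, dim = c(nf, ny, nx))
  if (n_trains > 0 && config$photons_per_train > 0) {
    for (f in seq_len(nf)) {
      active <- which(!is.na(pos[f, seq_len(n_trains)]))
      if (!length(active)) next
      profile <- numeric(nx)
      for (j in active) {
        cen <- pos[f, j]
        l_um <- trains$length_nm[j] / 1000
        amp <- config$photons_per_train / l_um *
          (stats::pnorm((arc_of_col - cen + l_um / 2) / sigma_um) -
             stats::pnorm((arc_of_col - cen - l_um / 2) / sigma_um))
        profile <- profile + amp * px
      }
      stack[f, , ] <- stack[f, , ] + outer(wy, profile)
    }
  }

  if (noise) {
    n_el <- length(stack)
    noisy <- stats::rpois(n_el, lambda = as.vector(stack)) +
      stats::rnorm(n_el, sd = config$read_noise_sd)
    stack <- array(pmax(noisy, 0), dim = dim(stack))
  }

  trajectories <- list()
  truth_tracks <- NULL
  if (n_trains > 0) {
    for (j in seq_len(n_trains)) {
      ok <- which(!is.na(pos[, j]))
      trajectories[[j]] <- data.frame(frame = ok, arc_um = pos[ok, j])
    }
    visible <- vapply(trajectories, nrow, 1L) > 0
    truth_tracks <- data.frame(
      id = trains$id, direction = trains$direction,
      entry_frame = vapply(trajectories, function(d) {
        if (nrow(d)) d$frame[1] else NA_integer_
      }, 1L),
      speed_um_s = trains$speed, length_nm = trains$length_nm,
      visible = visible
    )
  } else {
    truth_tracks <- data.frame(id = integer(), direction = character(),
                               entry_frame = integer(), speed_um_s = numeric(),
                               length_nm = numeric(), visible = logical())
  }

  movie <- movie_stack(stack, frame_interval_s = dt, pixel_size_um = px)
  truth <- list(
    tracks = truth_tracks,
    trajectories = trajectories,
    encounters = if (length(encounters)) do.call(rbind, encounters) else
      data.frame(retro_id = integer(), antero_id = integer(),
                 frame = integer(), arc_um = numeric(),
                 outcome = character(), pause_duration_s = numeric()),
    pauses = if (length(pauses)) do.call(rbind, pauses) else
      data.frame(track_id = integer(), start_frame = integer(),
                 end_frame = integer(), duration_s = numeric()),
    path = cbind(y = c(y0, y0), x = c(pad + 1, pad + ceiling(L / px))),
    config = unclass(config)
  )
  list(movie = movie, truth = truth)
}

#' Rebuild analysable train tracks from generator ground truth
#'
#' Converts the ground-truth trajectories written by [simulate_ift_movie()]
#' into `train_track` objects (the same structure produced by
#' [extract_tracks()]), so downstream operations - velocity, stall and
#' encounter analysis - can be exercised on noise-free tracks without
#' re-simulation.
#'
#' @param truth Ground truth list from [simulate_ift_movie()].
#' @param min_frames Drop trains visible in fewer frames (default 5).
#' @return List of `train_track` objects.
#' @export
truth_to_tracks <- function(truth, min_frames = 5) {
  dtf <- truth$config$frame_interval_s
  out <- list()
  for (i in seq_along(truth$trajectories)) {
    traj <- truth$trajectories[[i]]
    if (nrow(traj) < min_frames) next
    tr <- train_track(
      id = truth$tracks$id[i],
      direction = truth$tracks$direction[i],
      samples = traj,
      frame_interval_s = dtf,
      pixel_size_um = truth$config$pixel_size_um
    )
    out[[length(out) + 1]] <- tr
  }
  out
}
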