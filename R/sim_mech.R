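#' Configuration for the harmonic-oscillator (antennal mechanics) simulator
#'
#' Describes the fly antennal sound receiver as a damped harmonic oscillator
#' of mass `mass_kg`, natural frequency `f0_hz` and quality factor `Q`,
#' driven by thermal force noise at `temperature_K`. `active_force_factor`
#' scales the force-noise amplitude: 1 corresponds to passive thermal
#' equilibrium, values above 1 emulate active amplification by the
#' mechanosensory neurons (which multiplies the fluctuation power by the
#' factor squared).
#'
#' @param mass_kg Oscillator mass in kg (default 5e-11, i.e. 50 ng, the
#'   standard effective mass of the antennal receiver).
#' @param f0_hz Natural frequency in Hz.
#' @param Q Quality factor (dimensionless).
#' @param temperature_K Bath temperature in kelvin.
#' @param active_force_factor Multiplier (>= 0) on the thermal force-noise
#'   amplitude; the stationary displacement variance scales with its square.
#' @param duration_s Simulated duration in seconds.
#' @param sample_rate_hz Output sampling rate; must be at least `20 * f0_hz`.
#' @param seed RNG seed (mandatory).
#' @return A `mech_sim_config` list.
#' @export
mech_sim_config <- function(mass_kg = 5.0e-11, f0_hz = 300, Q = 2,
                            temperature_K = 298, active_force_factor = 1,
                            duration_s = 60, sample_rate_hz = 6000,
                            seed = 1) {
  stopifnot(
    mass_kg > 0, f0_hz > 0, Q > 0, temperature_K >= 0,
    active_force_factor >= 0, duration_s > 0, sample_rate_hz > 0
  )
  if (sample_rate_hz < 20 * f0_hz) {
    stop("sample_rate_hz must be at least 20 * f0_hz (integration step too coarse)")
  }
  structure(
    list(
      mass_kg = mass_kg, f0_hz = f0_hz, Q = Q,
      temperature_K = temperature_K,
      active_force_factor = active_force_factor,
      duration_s = duration_s, sample_rate_hz = sample_rate_hz,
      seed = seed
    ),
    class = "mech_sim_config"
  )
}

#' Simulate free mechanical fluctuations of the antennal receiver
#'
#' Underdamped Langevin dynamics `m x'' = -Ks x - gamma x' + a F_th(t)` with
#' `Ks = m (2 pi f0)^2`, `gamma = m 2 pi f0 / Q`, and white thermal force
#' noise of one-sided PSD `4 gamma kB T` scaled by `a = active_force_factor`.
#' Integration uses a semi-implicit (symplectic) Euler scheme at an internal
#' step of at most `1 / (50 f0)`, then keeps every k-th sample to deliver
#' the requested `sample_rate_hz`. An initial transient of ten relaxation
#' times is discarded, so the returned trace is stationary.
#'
#' At `a = 1` the stationary variance obeys equipartition,
#' `<x^2> = kB T / Ks`; the ground truth records the expected fluctuation
#' energy `a^2` in kB*T units.
#'
#' @param config A [mech_sim_config()].
#' @return A list with `trace` (a `mech_trace`: `values` in metres,
#'   `sample_rate_hz`, `kind = "displacement_m"`, `temperature_K`) and
#'   `truth` (f0_hz, Q, Ks_N_per_m, expected_energy_kBT).
#' @export
simulate_thermal_trace <- function(config) {
  stopifnot(inherits(config, "mech_sim_config"))
  m <- config$mass_kg
  w0 <- 2 * pi * config$f0_hz
  Ks <- m * w0^2
  gamma <- m * w0 / config$Q
  fs <- config$sample_rate_hz

  # oversample so the internal step satisfies dt <= 1/(50 f0)
  os <- max(1L, as.integer(ceiling(50 * config$f0_hz / fs)))
  dt <- 1 / (fs * os)
  if (dt > 1 / (20 * config$f0_hz)) {
    stop("unstable integration step: dt exceeds 1/(20*f0)")
  }

  n_out <- ceiling(config$duration_s * fs)
  burn_s <- 10 * 2 * m / gamma  # ten velocity-relaxation times
  n_burn <- ceiling(burn_s / dt)
  n_tot <- n_out * os + n_burn

  sd_F <- config$active_force_factor *
    sqrt(2 * gamma * kB * config$temperature_K / dt)

  set.seed(config$seed)
  if (sd_F == 0) {
    x <- numeric(n_out)
  } else {
    # Semi-implicit Euler written as its equivalent driven AR(2) recursion:
    #   x[n+1] = (2 - c - (dt*w0)^2) x[n] - (1 - c) x[n-1] + (dt^2/m) F[n]
    # with c = dt*gamma/m; identical, step for step, to the (x, v) update.
    c1 <- dt * gamma / m
    a1 <- 2 - c1 - (dt * w0)^2
    a2 <- -(1 - c1)
    drive <- (dt^2 / m) * stats::rnorm(n_tot, sd = sd_F)
    x_full <- as.numeric(stats::filter(drive, c(a1, a2), method = "recursive"))
    x <- x_full[n_burn + seq(os, n_out * os, by = os)]
  }

  trace <- structure(
    list(values = x, sample_rate_hz = fs, kind = "displacement_m",
         temperature_K = config$temperature_K),
    class = "mech_trace"
  )
  truth <- list(
    f0_hz = config$f0_hz, Q = config$Q, Ks_N_per_m = Ks,
    expected_energy_kBT = config$active_force_factor^2
  )
  list(trace = trace, truth = truth)
}

#' Simulate a stimulus-response sweep at the antennal eigenfrequency
#'
#' Emulates pure-tone stimulation over a wide intensity range: by default 17
#' sound-particle-velocity (SPV) levels spanning 96 dB in 6 dB steps. The
#' antennal displacement amplitude at the stimulus frequency follows
#' `X = SPV * g(SPV) / (2 pi f0)`, where the gain `g` interpolates along a
#' normalised sigmoid in log-SPV from `gain_max` at the lowest level (active
#' amplification of faint stimuli) down to `gain_min` at the highest level
#' (compressive saturation). The sigmoid is rescaled so the endpoints are
#' met exactly.
#'
#' @param config A [mech_sim_config()]; only `f0_hz` is used.
#' @param spv_levels Ascending positive SPVs in m/s, or `NULL` for the
#'   default 17-level, 96 dB sweep starting at 1e-7 m/s.
#' @param gain_max,gain_min Gains at the lowest/highest level;
#'   `gain_max >= gain_min > 0`.
#' @return A `stimulus_response` object: data frame with columns `spv_m_s`,
#'   `displacement_m`, plus attribute `f_eigen_hz`.
#' @export
simulate_forced_responses <- function(config, spv_levels = NULL,
                                      gain_max = 1, gain_min = 1) {
  stopifnot(inherits(config, "mech_sim_config"),
            gain_min > 0, gain_max >= gain_min)
  if (is.null(spv_levels)) {
    spv_levels <- 1e-7 * 10^(seq(0, 96, by = 6) / 20)
  }
  if (length(spv_levels) == 0) stop("empty SPV level list")
  stopifnot(all(spv_levels > 0), !is.unsorted(spv_levels, strictly = TRUE))

  f0 <- config$f0_hz
  ls <- log10(spv_levels)
  if (length(spv_levels) == 1 || gain_max == gain_min) {
    g <- rep(gain_max, length(spv_levels))
  } else {
    mid <- (min(ls) + max(ls)) / 2
    width <- (max(ls) - min(ls)) / 8
    s <- stats::plogis(-(ls - mid) / width)
    s <- (s - min(s)) / (max(s) - min(s))  # endpoints hit exactly
    g <- gain_min + (gain_max - gain_min) * s
  }
  x <- spv_levels * g / (2 * pi * f0)
  out <- data.frame(spv_m_s = spv_levels, displacement_m = x)
  attr(out, "f_eigen_hz") <- f0
  class(out) <- c("stimulus_response", "data.frame")
  out
}
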