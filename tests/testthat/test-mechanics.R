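test_that("zero temperature gives an all-zero trace", {
  cfg <- mech_sim_config(temperature_K = 0, duration_s = 2, seed = 1)
  r <- simulate_thermal_trace(cfg)
  expect_true(all(r$trace$values == 0))
})

test_that("simulated traces are deterministic in the seed", {
  cfg <- mech_sim_config(duration_s = 3, seed = 11)
  expect_identical(simulate_thermal_trace(cfg)$trace$values,
                   simulate_thermal_trace(cfg)$trace$values)
})

test_that("equipartition: passive trace variance approaches kBT/Ks", {
  cfg <- mech_sim_config(f0_hz = 300, Q = 2, duration_s = 60, seed = 42)
  r <- simulate_thermal_trace(cfg)
  expect_equal(var(r$trace$values), kB * 298 / r$truth$Ks_N_per_m,
               tolerance = 0.05)
})

test_that("force-noise scaling: variance grows with the square of the factor", {
  v <- vapply(c(1, 2), function(a) {
    cfg <- mech_sim_config(active_force_factor = a, duration_s = 30,
                           seed = 7)
    var(simulate_thermal_trace(cfg)$trace$values)
  }, numeric(1))
  expect_equal(v[2] / v[1], 4, tolerance = 0.05)
})

test_that("an integration step coarser than 1/(20 f0) is rejected", {
  expect_error(mech_sim_config(f0_hz = 300, sample_rate_hz = 1000),
               "sample_rate")
})

test_that("a pure sine velocity trace integrates to the sine displacement power", {
  fs <- 6000
  f <- 300
  V <- 1e-6
  t <- seq(0, 20, by = 1 / fs)
  tr <- mech_trace(V * sin(2 * pi * f * t), fs, kind = "velocity_m_s")
  psd <- displacement_psd(tr, band_hz = c(100, 1500))
  power <- trapz_test(psd$frequencies_hz, psd$psd_m2_per_hz)
  expect_equal(power, (V / (2 * pi * f))^2 / 2, tolerance = 0.02)
})

test_that("white displacement noise satisfies Parseval over the band", {
  set.seed(3)
  fs <- 4000
  x <- rnorm(fs * 30, sd = 1e-9)
  tr <- mech_trace(x, fs, kind = "displacement_m")
  psd <- displacement_psd(tr, band_hz = c(100, 1500))
  band_power <- trapz_test(psd$frequencies_hz, psd$psd_m2_per_hz)
  band_share <- (1500 - 100) / (fs / 2)
  expect_equal(band_power, var(x) * band_share, tolerance = 0.05)
})

test_that("the PSD grid excludes zero frequency and respects Nyquist", {
  set.seed(4)
  tr <- mech_trace(rnorm(2^16), 4000, kind = "velocity_m_s")
  psd <- displacement_psd(tr, band_hz = c(0, 1500))
  expect_true(all(psd$frequencies_hz > 0))
  expect_error(displacement_psd(tr, band_hz = c(100, 3000)), "Nyquist")
})

test_that("SHO fit recovers exact model parameters to < 0.1%", {
  f <- seq(100, 1500, by = 2)
  F0 <- 3e-11
  psd <- structure(list(frequencies_hz = f,
                        psd_m2_per_hz = ciliamech:::sho_model_psd(
                          f, F0, 300, 2, 5e-11)),
                   class = "psd_spectrum")
  fit <- fit_sho(psd)
  expect_equal(fit$f0_hz, 300, tolerance = 1e-3)
  expect_equal(fit$Q, 2, tolerance = 1e-3)
  expect_equal(fit$F0, F0, tolerance = 1e-3)
  # model value at resonance equals F0^2 Q^2 / (m^2 w0^4)
  w0 <- 2 * pi * 300
  expect_equal(ciliamech:::sho_model_psd(300, F0, 300, 2, 5e-11),
               F0^2 * 2^2 / ((5e-11)^2 * w0^4), tolerance = 1e-12)
})

test_that("refitting the fitted model returns the same parameters", {
  cfg <- mech_sim_config(duration_s = 30, seed = 5)
  r <- simulate_thermal_trace(cfg)
  psd <- displacement_psd(r$trace)
  fit1 <- fit_sho(psd)
  psd_model <- structure(
    list(frequencies_hz = psd$frequencies_hz,
         psd_m2_per_hz = ciliamech:::sho_model_psd(
           psd$frequencies_hz, fit1$F0, fit1$f0_hz, fit1$Q, fit1$m_kg)),
    class = "psd_spectrum")
  fit2 <- fit_sho(psd_model)
  expect_equal(fit2$f0_hz, fit1$f0_hz, tolerance = 1e-4)
  expect_equal(fit2$Q, fit1$Q, tolerance = 1e-4)
})

test_that("a spectrum without an interior peak is rejected", {
  f <- seq(500, 1500, by = 2)
  psd <- structure(list(frequencies_hz = f, psd_m2_per_hz = 1e-20 / f),
                   class = "psd_spectrum")
  expect_error(fit_sho(psd), "no resonance")
})

test_that("fluctuation energy scales with trace amplitude squared", {
  cfg <- mech_sim_config(duration_s = 30, seed = 8)
  r <- simulate_thermal_trace(cfg)
  en_of <- function(scale) {
    tr <- r$trace
    tr$values <- tr$values * scale
    psd <- displacement_psd(tr)
    fit <- fit_sho(psd)
    list(fit = fit, en = fluctuation_energy(fit, psd, 298))
  }
  a <- en_of(1)
  b <- en_of(3)
  expect_equal(b$en$energy_kBT / a$en$energy_kBT, 9, tolerance = 1e-6)
  expect_equal(b$en$msd_band_m2 / a$en$msd_band_m2, 9, tolerance = 1e-10)
  expect_equal(b$fit$f0_hz, a$fit$f0_hz, tolerance = 1e-6)
  expect_equal(b$fit$Q, a$fit$Q, tolerance = 1e-6)
})

test_that("energy errors on a degenerate spectrum", {
  psd <- structure(list(frequencies_hz = c(100, 200),
                        psd_m2_per_hz = c(0, 0)), class = "psd_spectrum")
  fit <- structure(list(F0 = 1e-12, m_kg = 5e-11, f0_hz = 300, Q = 2,
                        Ks = 1e-4), class = "sho_fit")
  expect_error(fluctuation_energy(fit, psd), "zero")
})

test_that("gain arithmetic and dimensionlessness", {
  resp <- data.frame(spv_m_s = c(1.2566e-6, 2e-6),
                     displacement_m = c(1e-9, 1e-9))
  gc <- gain_curve(resp, f_eigen_hz = 200)
  expect_equal(gc$levels$gain[1], 2 * pi * 200 * 1e-9 / 1.2566e-6,
               tolerance = 1e-4)
  expect_equal(gc$levels$gain[1], 1.0, tolerance = 1e-4)
  # joint unit rescaling consistent with omega leaves gain unchanged
  gc2 <- gain_curve(data.frame(spv_m_s = resp$spv_m_s * 10,
                               displacement_m = resp$displacement_m * 10),
                    f_eigen_hz = 200)
  expect_equal(gc2$levels$gain, gc$levels$gain)
})

test_that("simulated stimulus sweeps recover configured sensitivities", {
  cfg <- mech_sim_config(seed = 1)
  lin <- simulate_forced_responses(cfg, gain_max = 1, gain_min = 1)
  expect_equal(nrow(lin), 17)
  expect_equal(max(lin$spv_m_s) / min(lin$spv_m_s), 10^(96 / 20),
               tolerance = 1e-9)
  expect_equal(gain_curve(lin)$sensitivity, 1, tolerance = 1e-9)
  gc <- gain_curve(simulate_forced_responses(cfg, gain_max = 10,
                                             gain_min = 1))
  expect_equal(gc$sensitivity, 10, tolerance = 0.01)
  expect_error(simulate_forced_responses(cfg, spv_levels = numeric(0)),
               "empty")
})
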