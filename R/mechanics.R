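#' Construct a mechanical trace object
#'
#' @param values Numeric time series (displacement in metres or velocity in
#'   m/s, per `kind`).
#' @param sample_rate_hz Sampling rate in Hz.
#' @param kind Either `"displacement_m"` or `"velocity_m_s"`.
#' @param temperature_K Bath temperature used downstream for energy in
#'   kB*T units.
#' @return A `mech_trace` object.
#' @export
mech_trace <- function(values, sample_rate_hz,
                       kind = c("displacement_m", "velocity_m_s"),
                       temperature_K = 298) {
  kind <- match.arg(kind)
  stopifnot(sample_rate_hz > 0, all(is.finite(values)))
  structure(
    list(values = as.numeric(values), sample_rate_hz = sample_rate_hz,
         kind = kind, temperature_K = temperature_K),
    class = "mech_trace"
  )
}

#' One-sided displacement power spectral density (Welch estimate)
#'
#' Welch-averaged periodogram: Hann window, 50% overlap, segment length the
#' largest power of two giving at most `df_hz` frequency resolution. If the
#' trace holds velocities, the velocity PSD is converted to a displacement
#' PSD by dividing by `(2 pi f)^2`; the zero-frequency bin is always
#' excluded. The result is restricted to `band_hz`.
#'
#' @param trace A [mech_trace()].
#' @param band_hz Analysis band `c(low, high)` in Hz (default 100-1500).
#' @param df_hz Target frequency resolution in Hz (default 2).
#' @return A `psd_spectrum` object: list with `frequencies_hz` and
#'   `psd_m2_per_hz`.
#' @export
displacement_psd <- function(trace, band_hz = c(100, 1500), df_hz = 2) {
  stopifnot(inherits(trace, "mech_trace"), length(band_hz) == 2,
            band_hz[1] >= 0, band_hz[2] > band_hz[1])
  fs <- trace$sample_rate_hz
  if (band_hz[2] > fs / 2) stop("band exceeds Nyquist frequency")
  x <- trace$values
  nseg <- 2^ceiling(log2(fs / df_hz))
  n <- length(x)
  step <- nseg %/% 2
  n_segments <- if (n >= nseg) (n - nseg) %/% step + 1 else 0
  if (n_segments < 8) {
    stop("trace too short: need at least 8 Welch segments at the requested resolution")
  }
  w <- hann_window(nseg)
  scale <- fs * sum(w^2)
  acc <- numeric(nseg %/% 2 + 1)
  for (k in seq_len(n_segments)) {
    seg <- x[(k - 1) * step + seq_len(nseg)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / scale
    half <- p[seq_len(nseg %/% 2 + 1)]
    half[2:(nseg %/% 2)] <- 2 * half[2:(nseg %/% 2)]  # one-sided, DC/Nyquist once
    acc <- acc + half
  }
  psd <- acc / n_segments
  freq <- seq(0, nseg %/% 2) * fs / nseg

  keep <- freq > 0  # guard: f = 0 excluded before any 1/f^2 conversion
  freq <- freq[keep]
  psd <- psd[keep]
  if (trace$kind == "velocity_m_s") {
    psd <- psd / (2 * pi * freq)^2
  }
  inband <- freq >= band_hz[1] & freq <= band_hz[2]
  structure(
    list(frequencies_hz = freq[inband], psd_m2_per_hz = psd[inband]),
    class = "psd_spectrum"
  )
}

# Model PSD of a simple harmonic oscillator, one-sided, in m^2/Hz:
#   S(f) = F0^2 / (m^2 [(w0^2 - w^2)^2 + (w w0 / Q)^2]),  w = 2 pi f.
sho_model_psd <- function(f, F0, f0, Q, m) {
  w <- 2 * pi * f
  w0 <- 2 * pi * f0
  F0^2 / (m^2 * ((w0^2 - w^2)^2 + (w * w0 / Q)^2))
}

#' Fit a simple-harmonic-oscillator model to a displacement PSD
#'
#' Least-squares fit of the log-PSD over the band to
#' `S(f) = F0^2 / (m^2 [(w0^2 - w^2)^2 + (w w0/Q)^2])` with `w = 2 pi f`,
#' for the force amplitude `F0`, natural frequency `f0` and quality factor
#' `Q` (mass is fixed). Initial values: `f0` at the spectral maximum, `Q`
#' from the half-power width, `F0` from the peak height. Derived outputs:
#' damping `gamma = m w0 / Q` and spring constant `Ks = m w0^2`.
#'
#' @param psd A `psd_spectrum` from [displacement_psd()].
#' @param m_kg Oscillator mass in kg (default 50 ng).
#' @param band_hz Optional sub-band `c(low, high)` for the fit; default is
#'   the full spectrum band.
#' @return An `sho_fit` object with elements `F0`, `m_kg`, `f0_hz`, `Q`,
#'   `gamma`, `Ks`, `fit_band_hz`, `residual` (mean squared log residual).
#' @export
fit_sho <- function(psd, m_kg = 5.0e-11, band_hz = NULL) {
  stopifnot(inherits(psd, "psd_spectrum"))
  f <- psd$frequencies_hz
  S <- psd$psd_m2_per_hz
  if (!is.null(band_hz)) {
    keep <- f >= band_hz[1] & f <= band_hz[2]
    f <- f[keep]
    S <- S[keep]
  }
  if (length(f) < 8) stop("too few PSD points in band")
  i_max <- which.max(S)
  if (i_max <= 1 || i_max >= length(f)) stop("no resonance in band")

  f0_init <- f[i_max]
  half <- S[i_max] / 2
  i_lo <- which(f < f0_init & S < half)
  i_hi <- which(f > f0_init & S < half)
  width <- if (length(i_lo) && length(i_hi)) {
    f[min(i_hi)] - f[max(i_lo)]
  } else {
    f0_init / 2
  }
  Q_init <- max(f0_init / max(width, diff(range(f)) / length(f)), 0.5)
  F0_init <- sqrt(S[i_max]) * m_kg * (2 * pi * f0_init)^2 / Q_init

  obj <- function(par) {
    log(sho_model_psd(f, exp(par[1]), exp(par[2]), exp(par[3]), m_kg)) - log(S)
  }
  fit <- minpack.lm::nls.lm(
    par = log(c(F0_init, f0_init, Q_init)), fn = obj,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- exp(fit$par)
  F0 <- p[1]; f0 <- p[2]; Q <- p[3]
  w0 <- 2 * pi * f0
  structure(
    list(F0 = F0, m_kg = m_kg, f0_hz = f0, Q = Q,
         gamma = m_kg * w0 / Q, Ks = m_kg * w0^2,
         fit_band_hz = range(f),
         residual = mean(fit$fvec^2)),
    class = "sho_fit"
  )
}

#' Fluctuation energy of the antennal receiver in kB*T units
#'
#' Computes the mean-squared displacement two ways and the corresponding
#' fluctuation energy `E = Ks * <X^2>` relative to `kB T`:
#' * `msd_model_m2`: full-band integral of the fitted oscillator model,
#'   `F0^2 Q / (4 m^2 w0^3)` (closed form) - this feeds the primary
#'   `energy_kBT`, matching an effective stiffness `K = kB T / <X^2>`
#'   derived from the fit;
#' * `msd_band_m2`: trapezoid integral of the measured PSD over its band -
#'   reported as `energy_kBT_band` for comparison (it omits the variance
#'   outside the analysis band).
#'
#' At passive thermal equilibrium `E/kBT = 1` (equipartition,
#' `K <X^2> = kB T`); active amplification with force factor `a` gives
#' `E/kBT = a^2`.
#'
#' @param fit An `sho_fit` from [fit_sho()].
#' @param psd The `psd_spectrum` the fit was computed on.
#' @param temperature_K Bath temperature in kelvin.
#' @return A `fluctuation_energy` list: `msd_model_m2`, `msd_band_m2`,
#'   `K_eff_N_per_m`, `energy_kBT`, `energy_kBT_band`.
#' @export
fluctuation_energy <- function(fit, psd, temperature_K = 298) {
  stopifnot(inherits(fit, "sho_fit"), inherits(psd, "psd_spectrum"),
            temperature_K > 0)
  msd_band <- trapz(psd$frequencies_hz, psd$psd_m2_per_hz)
  if (msd_band <= 0) stop("zero mean-squared displacement in band")
  w0 <- 2 * pi * fit$f0_hz
  msd_model <- fit$F0^2 * fit$Q / (4 * fit$m_kg^2 * w0^3)
  kT <- kB * temperature_K
  structure(
    list(
      msd_model_m2 = msd_model,
      msd_band_m2 = msd_band,
      K_eff_N_per_m = kT / msd_model,
      energy_kBT = fit$Ks * msd_model / kT,
      energy_kBT_band = fit$Ks * msd_band / kT
    ),
    class = "fluctuation_energy"
  )
}

#' Mechanical sensitivity gain curve from a stimulus-response sweep
#'
#' Per stimulus level, `gain = displacement * 2 pi f_eigen / SPV`
#' (dimensionless); the mechanical sensitivity of the receiver is
#' `gain_max / gain_min` across levels.
#'
#' @param responses A `stimulus_response` data frame (columns `spv_m_s`,
#'   `displacement_m`) with attribute `f_eigen_hz`, or any data frame with
#'   those columns plus `f_eigen_hz` supplied explicitly.
#' @param f_eigen_hz Stimulus frequency in Hz; defaults to the attribute.
#' @return A `gain_curve` list: `levels` (data frame with per-level `gain`),
#'   `gain_max`, `gain_min`, `sensitivity`.
#' @export
gain_curve <- function(responses, f_eigen_hz = attr(responses, "f_eigen_hz")) {
  stopifnot(is.data.frame(responses), nrow(responses) >= 2,
            all(c("spv_m_s", "displacement_m") %in% names(responses)))
  if (is.null(f_eigen_hz)) stop("f_eigen_hz must be given")
  if (any(responses$spv_m_s <= 0)) stop("all SPVs must be positive")
  g <- responses$displacement_m * 2 * pi * f_eigen_hz / responses$spv_m_s
  levels <- data.frame(spv_m_s = responses$spv_m_s,
                       displacement_m = responses$displacement_m,
                       gain = g)
  structure(
    list(levels = levels, gain_max = max(g), gain_min = min(g),
         sensitivity = max(g) / min(g), f_eigen_hz = f_eigen_hz),
    class = "gain_curve"
  )
}
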