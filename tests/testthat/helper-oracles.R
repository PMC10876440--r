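# Independent oracles used across the suite.

# Plain trapezoid rule, independent of package internals.
trapz_test <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Brute-force Mann-Whitney U enumeration: exact two-sided p over all
# C(n1+n2, n1) group assignments (no ties assumed).
mw_enumeration_p <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Numerical convolution of a boxcar (length l_nm) with a Gaussian PSF
# (sigma_nm); returns the FWHM of the blurred profile in nm.
boxcar_psf_fwhm <- function(l_nm, sigma_nm, dx = 0.1) {
  x <- seq(-4 * sigma_nm - l_nm, 4 * sigma_nm + l_nm, by = dx)
  box <- as.numeric(abs(x) <= l_nm / 2)
  ker <- dnorm(x, 0, sigma_nm)
  prof <- convolve(box, rev(ker), type = "open")
  xx <- seq_along(prof)
  half <- max(prof) / 2
  above <- which(prof >= half)
  lo <- min(above)
  hi <- max(above)
  interp <- function(i, j) {
    i + (half - prof[i]) / (prof[j] - prof[i]) * (j - i)
  }
  (interp(hi, hi + 1) - interp(lo, lo - 1)) * dx
}

# Convenience: full image-level kymograph analysis of a simulated movie.
analyze_movie <- function(sim, intensity_k = 1.5, v_stall = 0.5,
                          smooth = 5) {
  kymo <- build_kymograph(sim$movie, cilium_path(sim$truth$path))
  dk <- separate_directions(kymo)
  tracks <- extract_tracks(dk, intensity_k = intensity_k)
  tracks <- lapply(tracks, function(t) {
    if (t$direction == "retrograde") {
      t$stalls <- detect_stalls(t, v_stall_um_s = v_stall,
                                smooth_frames = smooth)
    }
    t
  })
  list(kymo = kymo, dk = dk, tracks = tracks)
}
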