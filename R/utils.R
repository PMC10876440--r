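#' @keywords internal
"_PACKAGE"

# Symmetric Hann window (endpoints at zero), n >= 2.
hann_window <- function(n) {
  if (n < 2) stop("Hann window needs n >= 2")
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

# Trapezoid integral of y over grid x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Least-absolute-deviations straight-line slope via iteratively reweighted
# least squares. Returns c(intercept, slope).
lad_fit <- function(x, y, max_iter = 50, tol = 1e-10) {
  if (length(unique(x)) < 2) stop("degenerate abscissa: all x identical")
  X <- cbind(1, x)
  beta <- stats::lm.fit(X, y)$coefficients
  for (i in seq_len(max_iter)) {
    r <- abs(y - as.vector(X %*% beta))
    w <- 1 / pmax(r, 1e-8 * max(r, 1e-300))
    beta_new <- stats::lm.wfit(X, y, w)$coefficients
    if (max(abs(beta_new - beta)) < tol * max(1, max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  unname(beta)
}

# Expand one user seed into named per-stage seeds (stable, < 2^31).
derive_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- seq_along(stages) * 10007L
  out <- (as.integer(seed) %% 1000003L) + offsets
  names(out) <- stages
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Boltzmann constant
#'
#' In joules per kelvin, as used throughout the fluctuation-energy analysis.
#' @export
kB <- 1.380649e-23
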