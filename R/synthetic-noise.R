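#' Coloured 1/f noise
#'
#' Generates Gaussian noise with a power spectrum proportional to
#' \eqn{1/f^\alpha}, by spectral shaping of white Gaussian noise
#' (the DC component is zeroed). The output is rescaled to unit standard
#' deviation before applying \code{sigma}, so \code{sigma} is the
#' time-domain SD whatever the exponent.
#'
#' @param n number of samples.
#' @param alpha spectral exponent (1 gives pink noise); 0 gives white.
#' @param sigma time-domain standard deviation.
#' @return numeric vector of length \code{n}.
#' @export
oneOverFNoise <- function(n, alpha = 1, sigma = 1) {
  if (sigma < 0) stop("noise sigma must be non-negative")
  if (sigma == 0 || n < 2) return(numeric(n))
  w <- rnorm(n)
  W <- fft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)             # two-sided frequency index
  scale <- ifelse(f == 0, 0, f^(-alpha / 2))
  x <- Re(fft(W * scale, inverse = TRUE)) / n
  s <- sd(x)
  if (s == 0) return(numeric(n))
  sigma * x / s
}

#' First-order autoregressive noise
#'
#' AR(1) Gaussian noise with lag-one correlation \code{rho} and marginal
#' standard deviation \code{sigma}, initialised from the stationary
#' distribution.
#'
#' @param n number of samples.
#' @param rho AR(1) coefficient, |rho| < 1.
#' @param sigma marginal standard deviation.
#' @return numeric vector of length \code{n}.
#' @export
ar1Noise <- function(n, rho = 0.3, sigma = 1) {
  if (abs(rho) >= 1) stop("AR(1) coefficient must satisfy |rho| < 1")
  if (sigma < 0) stop("noise sigma must be non-negative")
  if (sigma == 0) return(numeric(n))
  innov <- rnorm(n, sd = sigma * sqrt(1 - rho^2))
  x <- numeric(n)
  x[1] <- rnorm(1, sd = sigma)
  for (i in seq_len(n)[-1]) x[i] <- rho * x[i - 1] + innov[i]
  x
}
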