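## Generalized gamma distribution in the location-scale-shape (GAMLSS)
## parameterization: location mu > 0 (same units as y), relative dispersion
## sigma > 0, power shape nu. With theta = 1 / (sigma^2 nu^2) and
## z = (y / mu)^nu, theta * z is Gamma(theta) distributed (upper tail for
## nu < 0). Special cases: sigma = 1, nu = 1 is the exponential with mean mu;
## nu -> 0 is the lognormal with median mu (used when |nu| < .ggNuEps).

.ggNuEps <- 1e-4

.ggCheck <- function(mu, sigma) {
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be finite and > 0")
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("sigma must be finite and > 0")
}

#' Generalized gamma density, distribution, quantile and random generation
#'
#' Location-scale-shape parameterization used throughout the normative models:
#' `mu` is the location (mm^3 for ROI volumes), `sigma` the relative
#' dispersion on the log scale, and `nu` the power shape. `nu = 1, sigma = 1`
#' reduces to the exponential with mean `mu`; as `nu -> 0` the distribution
#' tends to the lognormal with median `mu` (the lognormal form is used when
#' `|nu| < 1e-4`). `ggQuantile` is the exact inverse of `ggCdf`.
#'
#' @param y,q strictly positive observation / quantile (vectorized).
#' @param p probability in (0, 1).
#' @param n number of random draws.
#' @param mu,sigma,nu distribution parameters (recycled).
#' @param log return the log density.
#' @return numeric vector.
#' @examples
#' ggCdf(2, mu = 2, sigma = 1, nu = 1)   # 1 - exp(-1)
#' ggQuantile(ggCdf(1.7, 2, 0.3, 0.5), 2, 0.3, 0.5)
#' @export
ggCdf <- function(q, mu, sigma, nu) {
  .ggCheck(mu, sigma)
  if (any(!is.finite(q))) stop("q must be finite")
  n <- max(length(q), length(mu), length(sigma), length(nu))
  q <- rep_len(q, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  out <- numeric(n)
  pos <- q > 0
  ln <- pos & abs(nu) < .ggNuEps
  if (any(ln))
    out[ln] <- plnorm(q[ln], meanlog = log(mu[ln]), sdlog = sigma[ln])
  i <- pos & !ln
  if (any(i)) {
    theta <- 1 / (sigma[i]^2 * nu[i]^2)
    logz <- nu[i] * (log(q[i]) - log(mu[i]))
    pg <- pgamma(exp(pmin(log(theta) + logz, 700)), shape = theta)
    out[i] <- ifelse(nu[i] > 0, pg, 1 - pg)
  }
  out
}

#' @rdname ggCdf
#' @export
ggPdf <- function(y, mu, sigma, nu, log = FALSE) {
  .ggCheck(mu, sigma)
  if (any(y <= 0)) stop("y must be > 0")
  ll <- ggLogLik(y, mu, sigma, nu)
  if (log) ll else exp(ll)
}

#' @rdname ggCdf
#' @export
ggQuantile <- function(p, mu, sigma, nu) {
  .ggCheck(mu, sigma)
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  n <- max(length(p), length(mu), length(sigma), length(nu))
  p <- rep_len(p, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  out <- numeric(n)
  ln <- abs(nu) < .ggNuEps
  if (any(ln))
    out[ln] <- qlnorm(p[ln], meanlog = log(mu[ln]), sdlog = sigma[ln])
  i <- !ln
  if (any(i)) {
    theta <- 1 / (sigma[i]^2 * nu[i]^2)
    pp <- ifelse(nu[i] > 0, p[i], 1 - p[i])
    out[i] <- mu[i] * (qgamma(pp, shape = theta) / theta)^(1 / nu[i])
  }
  out
}

#' @rdname ggCdf
#' @export
ggRandom <- function(n, mu, sigma, nu) {
  .ggCheck(mu, sigma)
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  out <- numeric(n)
  ln <- abs(nu) < .ggNuEps
  if (any(ln)) out[ln] <- rlnorm(sum(ln), log(mu[ln]), sigma[ln])
  i <- !ln
  if (any(i)) {
    theta <- 1 / (sigma[i]^2 * nu[i]^2)
    out[i] <- mu[i] * (rgamma(sum(i), shape = theta) / theta)^(1 / nu[i])
  }
  out
}

## vectorized log-likelihood contribution per observation (internal; also the
## building block of the normative fit)
ggLogLik <- function(y, mu, sigma, nu) {
  n <- max(length(y), length(mu), length(sigma), length(nu))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  out <- numeric(n)
  ln <- abs(nu) < .ggNuEps
  if (any(ln))
    out[ln] <- dlnorm(y[ln], log(mu[ln]), sigma[ln], log = TRUE)
  i <- !ln
  if (any(i)) {
    theta <- 1 / (sigma[i]^2 * nu[i]^2)
    w <- nu[i] * (log(y[i]) - log(mu[i]))
    out[i] <- log(abs(nu[i])) + theta * (log(theta) + w - exp(pmin(w, 700))) -
      lgamma(theta) - log(y[i])
  }
  out
}
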