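#' @importFrom stats dnorm dgamma dexp dnbinom rnorm rgamma rexp rnbinom
#'   runif quantile sd uniroot integrate
NULL

COND_FAMILIES <- c("gamma_reflected", "gamma", "negative_binomial",
                   "gaussian", "gaussian_mixture", "exponential_shifted")

new_cond_density <- function(family, params, transform = list(),
                             n_fit = NA_integer_, floor = 1e-12) {
  stopifnot(family %in% COND_FAMILIES)
  structure(list(family = family, params = params, transform = transform,
                 n_fit = as.integer(n_fit), floor = floor),
            class = "cond_density")
}

#' @export
print.cond_density <- function(x, ...) {
  cat("Conditional score density:", x$family, "\n")
  cat("  params:", paste(sprintf("%s=%.6g", names(x$params),
                                 unlist(x$params)), collapse = ", "), "\n")
  if (length(x$transform)) {
    cat("  transform:", paste(sprintf("%s=%.6g", names(x$transform),
                                      unlist(x$transform)), collapse = ", "),
        "\n")
  }
  cat("  fitted on", x$n_fit, "scores; density floor", x$floor, "\n")
  invisible(x)
}

check_fit_input <- function(x, min_n) {
  x <- x[!is.na(x)]
  if (any(!is.finite(x))) stop("scores must be finite")
  if (length(x) < min_n) {
    stop("insufficient data: need at least ", min_n, " scores, got ",
         length(x))
  }
  if (length(unique(x)) == 1L) stop("degenerate sample: all scores equal")
  x
}

# Exact Gamma MLE: shape solves log(a) - digamma(a) = log(mean) - mean(log),
# a strictly decreasing left-hand side, so the root is unique.
gamma_mle <- function(z) {
  if (any(z <= 0)) stop("gamma fit requires strictly positive values")
  rhs <- log(mean(z)) - mean(log(z))
  if (rhs <= 0) stop("degenerate sample for gamma fit")
  f <- function(a) log(a) - digamma(a) - rhs
  shape <- uniroot(f, interval = c(1e-3, 1e3), extendInt = "downX",
                   tol = 1e-12)$root
  list(shape = shape, scale = mean(z) / shape)
}

#' Fit a reflected Gamma density
#'
#' For score distributions skewed toward a finite maximum (TargetScan total
#' context scores, where more negative means a stronger predicted target),
#' the score axis is flipped at a reflection point just above the sample
#' maximum and a Gamma distribution is fitted by maximum likelihood to the
#' reflected values. The reflection point is stored and reused when the
#' density is evaluated on new scores.
#'
#' @param x numeric vector of at least 10 finite scores, not all equal.
#' @param floor minimum density returned by [dcond()]; guards against zero
#'   likelihoods for scores outside the fitted support.
#' @return A `cond_density` object.
#' @export
fit_gamma_reflected <- function(x, floor = 1e-12) {
  x <- check_fit_input(x, 10L)
  eps <- 1e-9 * diff(range(x))
  r <- max(x) + eps
  p <- gamma_mle(r - x)
  new_cond_density("gamma_reflected", p, transform = list(reflect = r),
                   n_fit = length(x), floor = floor)
}

#' Fit a Gamma density (no reflection)
#'
#' For right-skewed positive scores (PicTar). Maximum likelihood.
#'
#' @inheritParams fit_gamma_reflected
#' @return A `cond_density` object.
#' @export
fit_gamma <- function(x, floor = 1e-12) {
  x <- check_fit_input(x, 10L)
  p <- gamma_mle(x)
  new_cond_density("gamma", p, n_fit = length(x), floor = floor)
}

#' Fit a Negative Binomial mass function to real-valued scores
#'
#' Scores are shifted so the sample minimum maps to zero, multiplied by
#' `scale`, and rounded to the nearest integer; Negative Binomial parameters
#' are then estimated by maximum likelihood ([MASS::fitdistr]). The shift,
#' scale and rounding are recorded so that new scores are discretized the
#' same way at evaluation time, and the reported density is the probability
#' mass times `scale` (the mass per unit of the original score axis).
#'
#' @inheritParams fit_gamma_reflected
#' @param scale positive multiplier applied before rounding (default 1).
#' @return A `cond_density` object with parameters `size` and `mu`
#'   (equivalently `prob = size / (size + mu)`).
#' @export
fit_negative_binomial <- function(x, scale = 1, floor = 1e-12) {
  stopifnot(scale > 0)
  x <- check_fit_input(x, 10L)
  shift <- min(x)
  counts <- round(scale * (x - shift))
  if (any(counts < 0)) stop("negative count after discretization")
  if (length(unique(counts)) == 1L) {
    stop("degenerate sample: all scores discretize to one count")
  }
  fit <- tryCatch(
    suppressWarnings(MASS::fitdistr(counts, "negative binomial")),
    error = function(e) stop("negative binomial fit failed: ",
                             conditionMessage(e)))
  size <- unname(fit$estimate["size"])
  mu <- unname(fit$estimate["mu"])
  new_cond_density("negative_binomial",
                   list(size = size, mu = mu, prob = size / (size + mu)),
                   transform = list(shift = shift, scale = scale),
                   n_fit = length(x), floor = floor)
}

#' Fit a Gaussian density
#'
#' Maximum likelihood: sample mean and the 1/n standard deviation.
#'
#' @inheritParams fit_gamma_reflected
#' @return A `cond_density` object.
#' @export
fit_gaussian <- function(x, floor = 1e-12) {
  x <- check_fit_input(x, 10L)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) stop("degenerate sample: zero variance")
  new_cond_density("gaussian", list(mean = m, sd = s),
                   n_fit = length(x), floor = floor)
}

mixture_loglik <- function(x, w, mu, sd) {
  d <- w[1] * dnorm(x, mu[1], sd[1]) + w[2] * dnorm(x, mu[2], sd[2])
  d[d <= 0] <- .Machine$double.xmin
  sum(log(d))
}

em_2gauss <- function(x, mu, sd, w, tol = 1e-8, maxit = 500L, min_sd) {
  ll_old <- -Inf
  for (it in seq_len(maxit)) {
    d1 <- w[1] * dnorm(x, mu[1], sd[1])
    d2 <- w[2] * dnorm(x, mu[2], sd[2])
    tot <- d1 + d2
    tot[tot <= 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    g <- d1 / tot
    n1 <- sum(g); n2 <- length(x) - n1
    if (n1 <= 0 || n2 <= 0) return(NULL)
    w <- c(n1, n2) / length(x)
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sd <- sqrt(c(sum(g * (x - mu[1])^2) / n1,
                 sum((1 - g) * (x - mu[2])^2) / n2))
    if (any(!is.finite(sd)) || any(sd < min_sd)) return(NULL)
    if (is.finite(ll_old) && ll - ll_old < tol) break
    ll_old <- ll
  }
  list(w = w, mu = mu, sd = sd, loglik = ll)
}

#' Fit a two-component Gaussian mixture by EM
#'
#' Deterministic initialization: component means at the 25th and 75th sample
#' percentiles, both standard deviations at half the sample standard
#' deviation, equal weights. EM stops when the log-likelihood improves by
#' less than 1e-8 or after 500 iterations. If a component collapses (sd
#' below 1e-6 of the sample range) the fit restarts from seeded random pairs
#' of data points, up to 5 times, then errors. Components are ordered by
#' ascending mean.
#'
#' @inheritParams fit_gamma_reflected
#' @param x numeric vector of at least 20 finite scores.
#' @param seed integer controlling restart initializations only; the default
#'   first fit is fully deterministic.
#' @return A `cond_density` object with parameters `w1, w2, mean1, mean2,
#'   sd1, sd2`.
#' @export
fit_gaussian_mixture <- function(x, seed = 1L, floor = 1e-12) {
  x <- check_fit_input(x, 20L)
  min_sd <- 1e-6 * diff(range(x))
  s0 <- stats::sd(x) / 2
  fit <- em_2gauss(x, mu = unname(quantile(x, c(0.25, 0.75))),
                   sd = c(s0, s0), w = c(0.5, 0.5), min_sd = min_sd)
  attempt <- 0L
  while (is.null(fit) && attempt < 5L) {
    attempt <- attempt + 1L
    init <- with_seed(seed + attempt, sort(sample(x, 2L)))
    if (init[1] == init[2]) init <- range(x)
    fit <- em_2gauss(x, mu = init, sd = c(s0, s0), w = c(0.5, 0.5),
                     min_sd = min_sd)
  }
  if (is.null(fit)) stop("EM collapse: mixture fit failed after 5 restarts")
  o <- order(fit$mu)
  new_cond_density("gaussian_mixture",
                   list(w1 = fit$w[o][1], w2 = fit$w[o][2],
                        mean1 = fit$mu[o][1], mean2 = fit$mu[o][2],
                        sd1 = fit$sd[o][1], sd2 = fit$sd[o][2]),
                   n_fit = length(x), floor = floor)
}

#' Fit a shifted Exponential density
#'
#' The shift is the sample minimum; the rate is the maximum-likelihood
#' estimate 1 / mean(x - shift).
#'
#' @inheritParams fit_gamma_reflected
#' @return A `cond_density` object.
#' @export
fit_exponential_shifted <- function(x, floor = 1e-12) {
  x <- check_fit_input(x, 10L)
  shift <- min(x)
  m <- mean(x - shift)
  if (m == 0) stop("degenerate sample: zero mean after shift")
  new_cond_density("exponential_shifted", list(rate = 1 / m),
                   transform = list(shift = shift),
                   n_fit = length(x), floor = floor)
}

#' Fit a conditional score density by family name
#'
#' Dispatcher over the five supported families.
#'
#' @param x numeric score vector.
#' @param family one of `"gamma_reflected"`, `"gamma"`,
#'   `"negative_binomial"`, `"gaussian"`, `"gaussian_mixture"`,
#'   `"exponential_shifted"`.
#' @param ... passed to the family fitter (e.g. `scale`, `seed`, `floor`).
#' @return A `cond_density` object.
#' @export
fit_conditional <- function(x, family, ...) {
  switch(match.arg(family, COND_FAMILIES),
         gamma_reflected = fit_gamma_reflected(x, ...),
         gamma = fit_gamma(x, ...),
         negative_binomial = fit_negative_binomial(x, ...),
         gaussian = fit_gaussian(x, ...),
         gaussian_mixture = fit_gaussian_mixture(x, ...),
         exponential_shifted = fit_exponential_shifted(x, ...))
}

dcond_raw <- function(fc, x) {
  p <- fc$params
  tr <- fc$transform
  switch(fc$family,
    gamma_reflected = {
      z <- tr$reflect - x
      out <- numeric(length(x))
      ok <- z > 0
      out[ok] <- dgamma(z[ok], shape = p$shape, scale = p$scale)
      out
    },
    gamma = {
      out <- numeric(length(x))
      ok <- x > 0
      out[ok] <- dgamma(x[ok], shape = p$shape, scale = p$scale)
      out
    },
    negative_binomial = {
      cnt <- round(tr$scale * (x - tr$shift))
      out <- numeric(length(x))
      ok <- cnt >= 0
      out[ok] <- dnbinom(cnt[ok], size = p$size, mu = p$mu) * tr$scale
      out
    },
    gaussian = dnorm(x, p$mean, p$sd),
    gaussian_mixture =
      p$w1 * dnorm(x, p$mean1, p$sd1) + p$w2 * dnorm(x, p$mean2, p$sd2),
    exponential_shifted = {
      z <- x - tr$shift
      out <- numeric(length(x))
      ok <- z >= 0
      out[ok] <- dexp(z[ok], rate = p$rate)
      out
    })
}

#' Evaluate a fitted conditional density
#'
#' Returns the fitted density (or, for the Negative Binomial, the
#' probability mass per unit score) at `x`, floored at the density floor so
#' that a score outside the fitted support never produces a zero likelihood.
#'
#' @param fc a `cond_density` object.
#' @param x numeric vector of finite scores.
#' @param floored if FALSE, return the raw family density without flooring
#'   (used e.g. to verify normalization).
#' @return Numeric vector of densities.
#' @export
dcond <- function(fc, x, floored = TRUE) {
  stopifnot(inherits(fc, "cond_density"), all(is.finite(x)))
  d <- dcond_raw(fc, x)
  if (floored) pmax(d, fc$floor) else d
}

#' Sample from a fitted conditional density
#'
#' Inverse of the support transform applied to a draw from the underlying
#' family; used by the synthetic score generator.
#'
#' @param fc a `cond_density` object.
#' @param n number of draws.
#' @return Numeric vector of length `n`.
#' @export
rcond_density <- function(fc, n) {
  stopifnot(inherits(fc, "cond_density"))
  p <- fc$params
  tr <- fc$transform
  switch(fc$family,
    gamma_reflected = tr$reflect - rgamma(n, shape = p$shape,
                                          scale = p$scale),
    gamma = rgamma(n, shape = p$shape, scale = p$scale),
    negative_binomial = tr$shift + rnbinom(n, size = p$size, mu = p$mu) /
      tr$scale,
    gaussian = rnorm(n, p$mean, p$sd),
    gaussian_mixture = {
      z <- runif(n) < p$w1
      ifelse(z, rnorm(n, p$mean1, p$sd1), rnorm(n, p$mean2, p$sd2))
    },
    exponential_shifted = tr$shift + rexp(n, rate = p$rate))
}

#' Log-likelihood of scores under a fitted conditional
#'
#' @param object a `cond_density`.
#' @param x numeric score vector.
#' @param ... unused.
#' @return Scalar log-likelihood (unfloored density).
#' @export
logLik.cond_density <- function(object, x, ...) {
  d <- dcond_raw(object, x)
  d[d <= 0] <- .Machine$double.xmin
  sum(log(d))
}

# Numerical check that the unfloored density integrates (or, for the
# discrete family, sums) to 1 over its support.
cond_total_mass <- function(fc) {
  p <- fc$params
  tr <- fc$transform
  if (fc$family == "negative_binomial") {
    upper <- stats::qnbinom(1 - 1e-12, size = p$size, mu = p$mu)
    return(sum(dnbinom(0:upper, size = p$size, mu = p$mu)))
  }
  bounds <- switch(fc$family,
    gamma_reflected = c(tr$reflect - stats::qgamma(1 - 1e-12, p$shape,
                                                   scale = p$scale),
                        tr$reflect),
    gamma = c(0, stats::qgamma(1 - 1e-12, p$shape, scale = p$scale)),
    gaussian = p$mean + c(-1, 1) * 10 * p$sd,
    gaussian_mixture = c(min(p$mean1, p$mean2) - 10 * max(p$sd1, p$sd2),
                         max(p$mean1, p$mean2) + 10 * max(p$sd1, p$sd2)),
    exponential_shifted = c(tr$shift,
                            tr$shift + stats::qexp(1 - 1e-12, p$rate)))
  integrate(function(v) dcond_raw(fc, v), bounds[1], bounds[2],
            rel.tol = 1e-9, subdivisions = 500L)$value
}

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
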