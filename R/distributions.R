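#' Fit a samplable distribution to a (base, range) specification
#'
#' Turns one PSA specification — family, base-case value and low/high range —
#' into a distribution object that can be sampled. All families are
#' parameterised so that the distribution mean equals the base-case value;
#' when no standard deviation is stated the range is read as an approximate
#' central 95% interval and the dispersion solved from it.
#'
#' * `beta`: method of moments with mean `base` and SD `(high - low)/3.92`,
#'   capped just below the largest SD a beta with that mean admits.
#' * `normal`: mean `base`; SD as given (`sd` field) or derived from the
#'   range. Draws are truncated to the support given in `truncate`.
#' * `lognormal`: log-scale SD from the range (`(log high - log low)/3.92`,
#'   falling back to the upper half-interval when `low <= 0`), with the
#'   log-mean shifted by `-sigma^2/2` so the arithmetic mean is `base`.
#' * `dirichlet`: concentration `alpha0 * base` (default `alpha0 = 100`);
#'   draws are probability vectors summing to one exactly.
#'
#' A zero-width range (`low == base == high`) yields a point mass.
#'
#' @param spec a list with `family`, `base`, `low`, `high` and optionally
#'   `sd` or `alpha0`, as in [default_psa_specs()].
#' @param truncate optional length-2 support for normal draws; out-of-range
#'   draws are resampled.
#' @return an object of class `ich_dist` with fields `family`, `mean` and a
#'   sampling function `sample(n)`.
#' @examples
#' d <- fit_distribution(list(family = "beta", base = 0.96, low = 0.8, high = 1))
#' mean(d$sample(5000))
#' @export
fit_distribution <- function(spec, truncate = NULL) {
  if (any(spec$base < spec$low - 1e-12) || any(spec$base > spec$high + 1e-12))
    stop("distribution base must lie within [low, high]", call. = FALSE)

  point_mass <- all(abs(spec$high - spec$low) < 1e-15)
  if (point_mass) {
    base <- spec$base
    out <- list(family = "point", mean = base,
                sample = function(n) {
                  if (length(base) > 1)
                    matrix(base, n, length(base), byrow = TRUE,
                           dimnames = list(NULL, names(base)))
                  else rep(base, n)
                })
    class(out) <- "ich_dist"
    return(out)
  }

  out <- switch(spec$family,
    beta = fit_beta(spec),
    normal = fit_normal(spec, truncate),
    lognormal = fit_lognormal(spec),
    dirichlet = fit_dirichlet(spec),
    stop("unknown distribution family '", spec$family, "'", call. = FALSE)
  )
  class(out) <- "ich_dist"
  out
}

fit_beta <- function(spec) {
  m <- spec$base
  if (m <= 0 || m >= 1)
    stop("beta base must lie strictly inside (0, 1)", call. = FALSE)
  sd <- (spec$high - spec$low) / 3.92
  # a beta with mean m cannot have sd >= sqrt(m(1-m)); cap keeps a0 > 0
  sd <- min(sd, 0.95 * sqrt(m * (1 - m)))
  a0 <- m * (1 - m) / sd^2 - 1
  shape1 <- m * a0
  shape2 <- (1 - m) * a0
  list(family = "beta", mean = m, shape1 = shape1, shape2 = shape2,
       sample = function(n) stats::rbeta(n, shape1, shape2))
}

fit_normal <- function(spec, truncate = NULL) {
  m <- spec$base
  sd <- if (!is.null(spec$sd)) spec$sd else (spec$high - spec$low) / 3.92
  lo <- if (is.null(truncate)) -Inf else truncate[1]
  hi <- if (is.null(truncate)) Inf else truncate[2]
  list(family = "normal", mean = m, sd = sd,
       sample = function(n) {
         x <- stats::rnorm(n, m, sd)
         bad <- which(x < lo | x > hi)
         while (length(bad)) {
           x[bad] <- stats::rnorm(length(bad), m, sd)
           bad <- bad[x[bad] < lo | x[bad] > hi]
         }
         x
       })
}

fit_lognormal <- function(spec) {
  m <- spec$base
  if (m <= 0)
    stop("lognormal base must be positive", call. = FALSE)
  sigma <- if (spec$low > 0)
    (log(spec$high) - log(spec$low)) / 3.92
  else
    (log(spec$high) - log(m)) / 1.96
  mu <- log(m) - sigma^2 / 2  # arithmetic mean = base
  list(family = "lognormal", mean = m, meanlog = mu, sdlog = sigma,
       sample = function(n) stats::rlnorm(n, mu, sigma))
}

fit_dirichlet <- function(spec) {
  p <- spec$base
  alpha0 <- if (!is.null(spec$alpha0)) spec$alpha0 else 100
  alpha <- alpha0 * p
  list(family = "dirichlet", mean = p, alpha = alpha,
       sample = function(n) {
         g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
                     nrow = n, byrow = TRUE)
         out <- g / rowSums(g)
         colnames(out) <- names(p)
         out
       })
}

#' @export
print.ich_dist <- function(x, ...) {
  cat(sprintf("<ich_dist %s, mean %s>\n", x$family,
              paste(signif(x$mean, 4), collapse = "/")))
  invisible(x)
}
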