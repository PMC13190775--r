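#' Uncertainty-distribution specification
#'
#' A small tagged container describing how a model input is distributed in the
#' probabilistic sensitivity analysis. Four kinds are supported, matching the
#' way the inputs are reported: `fixed` (a point value), `beta_mean_se` (a
#' proportion or utility reported as mean and standard error, converted to a
#' Beta by the method of moments), `beta_shape` (an explicit Beta shape pair)
#' and `binomial` (a count reported as a mean, resampled as
#' Binomial(n, mean/n)).
#'
#' @param kind One of `"fixed"`, `"beta_mean_se"`, `"beta_shape"`, `"binomial"`.
#' @param ... Kind-dependent parameters: `mean` (fixed); `mean`, `se`
#'   (beta_mean_se); `alpha`, `beta` (beta_shape); `n`, `mean` (binomial).
#' @return An object of class `distribution_spec`.
#' @examples
#' distribution_spec("beta_mean_se", mean = 0.12, se = 0.022)
#' distribution_spec("beta_shape", alpha = 81.27, beta = 8.08)
#' @export
distribution_spec <- function(kind = c("fixed", "beta_mean_se", "beta_shape", "binomial"),
                              ...) {
  kind <- match.arg(kind)
  pars <- list(...)
  switch(kind,
    fixed = {
      stopifnot("fixed spec needs a mean" = !is.null(pars$mean))
    },
    beta_mean_se = {
      m <- pars$mean; se <- pars$se
      if (is.null(m) || is.null(se)) stop("beta_mean_se spec needs mean and se")
      if (m <= 0 || m >= 1) stop("beta mean must lie in (0, 1), got ", m)
      if (se <= 0) stop("standard error must be > 0, got ", se)
      if (se^2 >= m * (1 - m)) {
        stop("se^2 >= mean*(1-mean): Beta distribution undefined for mean ",
             m, ", se ", se)
      }
    },
    beta_shape = {
      a <- pars$alpha; b <- pars$beta
      if (is.null(a) || is.null(b)) stop("beta_shape spec needs alpha and beta")
      if (a <= 0 || b <= 0) stop("Beta shape parameters must be > 0")
    },
    binomial = {
      n <- pars$n; m <- pars$mean
      if (is.null(n) || is.null(m)) stop("binomial spec needs n and mean")
      if (n != round(n) || n < 1) stop("binomial n must be a positive integer")
      if (m < 0 || m / n > 1) stop("binomial mean/n must lie in [0, 1]")
    }
  )
  structure(c(list(kind = kind), pars), class = "distribution_spec")
}

#' Beta shape parameters from a mean and standard error
#'
#' Method-of-moments conversion: solves
#' \eqn{\alpha/(\alpha+\beta) = m} and
#' \eqn{\alpha\beta/((\alpha+\beta)^2(\alpha+\beta+1)) = se^2}
#' for the shape pair, so that the returned Beta reproduces the requested
#' mean and variance exactly. This is the conventional way proportions and
#' utilities reported as "mean (SE)" enter a probabilistic sensitivity
#' analysis.
#'
#' @param mean Mean, strictly inside (0, 1).
#' @param se Standard error, > 0 and with `se^2 < mean * (1 - mean)`.
#' @return Named numeric vector `c(alpha = , beta = )`.
#' @examples
#' beta_from_mean_se(0.5, 0.1)  # alpha = beta = 12
#' @export
beta_from_mean_se <- function(mean, se) {
  if (mean <= 0 || mean >= 1) stop("mean must lie strictly in (0, 1), got ", mean)
  if (se <= 0) stop("se must be > 0, got ", se)
  v <- se^2
  if (v >= mean * (1 - mean)) {
    stop("se^2 >= mean*(1-mean); no Beta distribution has this mean and variance")
  }
  nu <- mean * (1 - mean) / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Draw one value from a distribution specification
#'
#' Fixed specs return their mean unchanged; `beta_mean_se` converts to shapes
#' with [beta_from_mean_se()] and samples; `beta_shape` samples directly;
#' `binomial` returns an integer count drawn as Binomial(n, mean/n), whose
#' expectation is the reported mean.
#'
#' @param spec A [distribution_spec()].
#' @return A single numeric draw.
#' @keywords internal
draw_from_spec <- function(spec) {
  switch(spec$kind,
    fixed = spec$mean,
    beta_mean_se = {
      sh <- beta_from_mean_se(spec$mean, spec$se)
      stats::rbeta(1L, sh[["alpha"]], sh[["beta"]])
    },
    beta_shape = stats::rbeta(1L, spec$alpha, spec$beta),
    binomial = stats::rbinom(1L, spec$n, spec$mean / spec$n),
    stop("unknown distribution kind: ", spec$kind)
  )
}
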