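#' Cumulative link functions
#'
#' A link function maps the latent scale onto cumulative response
#' probabilities. The probit link implies a normally distributed latent
#' variable; the logit link implies a logistic latent variable.
#'
#' @param name Either \code{"probit"} (default) or \code{"logit"}.
#'
#' @return An object of class \code{"link_function"}: a list with elements
#'   \code{name}, \code{cdf}, \code{density}, \code{ddensity} (derivative of
#'   the density, used for Hessians) and \code{quantile}.
#'
#' @examples
#' lk <- link_function("probit")
#' lk$cdf(0)     # 0.5
#' lk$density(0) # dnorm(0)
#' @export
link_function <- function(name = c("probit", "logit")) {
  name <- match.arg(name)
  if (name == "probit") {
    out <- list(
      name     = "probit",
      cdf      = stats::pnorm,
      density  = stats::dnorm,
      ddensity = function(x) -x * stats::dnorm(x),
      quantile = stats::qnorm
    )
  } else {
    out <- list(
      name     = "logit",
      cdf      = stats::plogis,
      density  = stats::dlogis,
      ddensity = function(x) {
        f <- stats::dlogis(x)
        f * (1 - 2 * stats::plogis(x))
      },
      quantile = stats::qlogis
    )
  }
  class(out) <- "link_function"
  out
}

as_link <- function(link) {
  if (inherits(link, "link_function")) return(link)
  link_function(link)
}

# cdf clipped away from exact 0/1 so log-likelihood cells never vanish
clip_cdf <- function(p) pmin(pmax(p, 1e-300), 1 - 1e-16)
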