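#' Threshold sets and response patterns
#'
#' A threshold set partitions the latent scale into K ordered regions, one
#' per Likert response. K responses require K - 1 strictly increasing
#' cut-points tau_1 < ... < tau_{K-1}; the outer bounds are -Inf and +Inf.
#' The configuration of the cut-points is the *response pattern*: it
#' determines which categories are over- or under-used for a given latent
#' distribution, independent of any real difference between items.
#'
#' @param tau Numeric vector of strictly increasing cut-points (latent units).
#' @param pattern_name Optional label carried along for bookkeeping.
#'
#' @return An object of class \code{"threshold_set"} with elements
#'   \code{tau}, \code{n_levels} (\code{length(tau) + 1}) and
#'   \code{pattern_name}.
#' @export
threshold_set <- function(tau, pattern_name = NULL) {
  tau <- as.numeric(tau)
  if (length(tau) < 1L || anyNA(tau) || any(!is.finite(tau)))
    stop("'tau' must be a finite numeric vector of length >= 1")
  if (any(diff(tau) <= 0))
    stop("'tau' must be strictly increasing")
  structure(
    list(tau = tau, n_levels = length(tau) + 1L,
         pattern_name = pattern_name),
    class = "threshold_set"
  )
}

#' @export
print.threshold_set <- function(x, ...) {
  nm <- if (is.null(x$pattern_name)) "custom" else x$pattern_name
  cat(sprintf("<threshold_set> %s, K = %d\n  tau: %s\n",
              nm, x$n_levels, paste(signif(x$tau, 4), collapse = ", ")))
  invisible(x)
}

# Registry of the five stylised response patterns (K = 5). The constants are
# fixed so that a latent value of 2.5 recodes to 4, 3, 5, 5 and 4 under
# equidistant, left-, right-, edge- and centre-biased patterns respectively.
.pattern_registry <- list(
  "equidistant"   = c(-3, -1, 1, 3),
  "left-biased"   = c(-1, 1, 3, 5),
  "right-biased"  = c(-5, -3, -1, 1),
  "edge-biased"   = c(-1, -0.35, 0.35, 1),
  "centre-biased" = c(-4, -1.5, 1.5, 4)
)

#' Construct one of the five stock response patterns
#'
#' The five named patterns mirror the qualitative response styles described
#' in the item-response literature: \code{equidistant} (evenly spaced
#' thresholds symmetric about 0), \code{left-biased} and \code{right-biased}
#' (thresholds shifted so low or high categories dominate),
#' \code{edge-biased} (narrow central regions, so extreme responses are
#' over-used) and \code{centre-biased} (wide central region).
#'
#' @param name Pattern name; one of \code{"equidistant"}, \code{"left-biased"},
#'   \code{"right-biased"}, \code{"edge-biased"}, \code{"centre-biased"}.
#' @param n_levels Number of response categories; only \code{5} is registered.
#' @return A \code{\link{threshold_set}}.
#' @examples
#' make_pattern("edge-biased")
#' recode_latent(2.5, make_pattern("left-biased")) # 3
#' @export
make_pattern <- function(name, n_levels = 5L) {
  if (length(name) != 1L || !name %in% names(.pattern_registry))
    stop("unknown pattern name: ", paste(name, collapse = ", "),
         " (known: ", paste(names(.pattern_registry), collapse = ", "), ")")
  if (n_levels != 5L)
    stop("only n_levels = 5 patterns are registered (got ", n_levels, ")")
  threshold_set(.pattern_registry[[name]], pattern_name = name)
}

#' Table of all registered response patterns
#'
#' @return A data.frame with one row per (pattern, threshold index):
#'   columns \code{pattern}, \code{n_levels}, \code{index}, \code{tau}.
#'   Suitable for writing out as delimited text.
#' @export
pattern_registry <- function() {
  do.call(rbind, lapply(names(.pattern_registry), function(nm) {
    tau <- .pattern_registry[[nm]]
    data.frame(pattern = nm, n_levels = length(tau) + 1L,
               index = seq_along(tau), tau = tau,
               stringsAsFactors = FALSE)
  }))
}

resolve_pattern <- function(pattern) {
  if (inherits(pattern, "threshold_set")) return(pattern)
  if (is.character(pattern) && length(pattern) == 1L) return(make_pattern(pattern))
  stop("'pattern' must be a threshold_set or a registered pattern name")
}

#' Recode latent values to ordinal responses
#'
#' A latent value falling in region k, i.e. in the half-open interval
#' (tau_{k-1}, tau_k], is recoded to response k. The boundary itself belongs
#' to the lower region, so \code{recode_latent(tau[k])} is exactly \code{k}.
#'
#' @param value Numeric vector of latent values (must be finite).
#' @param thresholds A \code{\link{threshold_set}} or pattern name.
#' @return Integer vector of responses in \code{1..K}.
#' @examples
#' recode_latent(2.5, make_pattern("equidistant")) # 4
#' @export
recode_latent <- function(value, thresholds) {
  thresholds <- resolve_pattern(thresholds)
  if (anyNA(value) || any(!is.finite(value)))
    stop("latent values must be finite")
  # response = 1 + #{k : value > tau_k}
  idx <- findInterval(value, thresholds$tau, left.open = TRUE)
  as.integer(idx + 1L)
}

#' Ordinal response probabilities for a latent normal/logistic variable
#'
#' Computes \code{p_k = F((tau_k - mu)/sd) - F((tau_{k-1} - mu)/sd)} for
#' each response k, where F is the link cdf: the probability mass of the
#' latent distribution falling into each threshold region.
#'
#' @param mu Latent mean.
#' @param sd Latent standard deviation (> 0).
#' @param thresholds A \code{\link{threshold_set}} or pattern name.
#' @param link A \code{\link{link_function}} or its name; default probit.
#' @return Numeric probability vector of length K summing to 1.
#' @export
response_probs <- function(mu, sd, thresholds, link = "probit") {
  thresholds <- resolve_pattern(thresholds)
  link <- as_link(link)
  if (length(mu) != 1L || length(sd) != 1L) stop("'mu' and 'sd' must be scalars")
  if (!is.finite(sd) || sd <= 0) stop("'sd' must be > 0")
  cum <- clip_cdf(link$cdf((thresholds$tau - mu) / sd))
  p <- diff(c(0, cum, 1))
  pmax(p, 0)
}

#' Sample ordinal responses from a latent distribution
#'
#' Draws latent values from Normal(mu, sd) (probit link) or a scaled
#' logistic (logit link) and recodes them with \code{\link{recode_latent}}.
#' Uses the current R random number stream; seed with \code{set.seed()}.
#'
#' @inheritParams response_probs
#' @param n Number of draws.
#' @return Integer response vector of length n.
#' @export
sample_responses <- function(mu, sd, n, thresholds, link = "probit") {
  thresholds <- resolve_pattern(thresholds)
  link <- as_link(link)
  if (n < 1) stop("'n' must be >= 1")
  if (sd < 0) stop("'sd' must be >= 0")
  latent <- if (link$name == "probit") {
    stats::rnorm(n, mu, sd)
  } else {
    mu + sd * stats::rlogis(n)
  }
  recode_latent(latent, thresholds)
}
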