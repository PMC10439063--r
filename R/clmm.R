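#' Intercept-only cumulative link model thresholds
#'
#' Maximum-likelihood thresholds for an ordered regression with no
#' predictors and no random effects: the k-th threshold is the link-inverse
#' of the empirical cumulative proportion P(response <= k). Used for
#' starting values and as a closed-form oracle for the mixed model in the
#' zero-variance limit.
#'
#' @param responses Integer responses in \code{1..n_levels}.
#' @param n_levels Number of response categories K.
#' @param link Link function or name.
#' @return Numeric vector of K - 1 thresholds. Thresholds bounding
#'   unobserved extreme categories are \code{-Inf}/\code{Inf}.
#' @examples
#' fit_thresholds_only(rep(1:5, c(10, 20, 40, 20, 10)), 5)
#' @export
fit_thresholds_only <- function(responses, n_levels, link = "probit") {
  link <- as_link(link)
  responses <- as.integer(responses)
  if (any(responses < 1L | responses > n_levels))
    stop("responses must lie in 1..", n_levels)
  counts <- tabulate(responses, nbins = n_levels)
  if (sum(counts > 0) < 2L)
    stop("degenerate data: all responses are in category ",
         which(counts > 0))
  cum <- cumsum(counts[-n_levels]) / sum(counts)
  link$quantile(cum)
}

# ---- internal machinery for the Laplace-approximated marginal likelihood ----

# per-observation log-likelihood, d/deta and -d2/deta2 given thresholds tau,
# linear predictor eta, responses y (1..K). Returns list(ll, g, w).
clmm_obs_terms <- function(y, eta, tau, link, K) {
  lo <- c(-Inf, tau)[y]       # tau_{y-1}
  hi <- c(tau, Inf)[y]        # tau_y
  a <- lo - eta
  b <- hi - eta
  Fa <- ifelse(is.finite(a), link$cdf(a), 0)
  Fb <- ifelse(is.finite(b), link$cdf(b), 1)
  p <- pmax(Fb - Fa, 1e-300)
  fa <- ifelse(is.finite(a), link$density(a), 0)
  fb <- ifelse(is.finite(b), link$density(b), 0)
  da <- ifelse(is.finite(a), link$ddensity(a), 0)
  db <- ifelse(is.finite(b), link$ddensity(b), 0)
  # cap score/curvature so near-impossible observations (underflowing p in
  # the far probit tails) cannot inject Inf into the Newton system
  g <- pmin(pmax((fa - fb) / p, -1e6), 1e6)
  w <- g^2 - (db - da) / p
  w[!is.finite(w)] <- 1e12
  list(ll = log(p), g = g, w = pmin(pmax(w, 1e-10), 1e12))
}

# joint penalised objective, gradient and sparse Hessian over stacked modes u
# idx: list of integer index vectors (one per factor), nlev: levels per factor
clmm_inner <- function(y, tau, link, K, idx, nlev, sigmas, u,
                       tol = 1e-6, max_iter = 50L) {
  nf <- length(idx)
  offs <- c(0L, cumsum(nlev))[seq_len(nf)]
  q <- sum(nlev)
  eta_of <- function(u) {
    eta <- 0
    for (f in seq_len(nf)) eta <- eta + u[offs[f] + idx[[f]]]
    eta
  }
  pen_of <- function(u, ll) sum(ll) - sum(u^2 / (2 * rep(sigmas^2, nlev)))
  terms <- clmm_obs_terms(y, eta_of(u), tau, link, K)
  obj <- pen_of(u, terms$ll)
  iters <- 0L
  H <- NULL
  gnorm <- Inf
  repeat {
    grad <- numeric(q)
    for (f in seq_len(nf))
      grad[offs[f] + seq_len(nlev[f])] <-
        rowsum_vec(terms$g, idx[[f]], nlev[f])
    grad <- grad - u / rep(sigmas^2, nlev)
    H <- clmm_hessian(terms$w, idx, nlev, sigmas, offs)
    gnorm <- max(abs(grad))
    if (gnorm < tol || iters >= max_iter) break
    step <- tryCatch(as.numeric(Matrix::solve(H, grad)),
                     error = function(e) as.numeric(Matrix::solve(
                       H + Matrix::Diagonal(q, 1e-6), grad)))
    alpha <- 1
    repeat {
      u_new <- u + alpha * step
      t_new <- clmm_obs_terms(y, eta_of(u_new), tau, link, K)
      o_new <- pen_of(u_new, t_new$ll)
      if (o_new >= obj - 1e-12 || alpha < 1e-4) break
      alpha <- alpha / 2
    }
    if (o_new < obj + 1e-12 && alpha < 1e-4) { iters <- iters + 1L; break }
    u <- u_new; terms <- t_new; obj <- o_new
    iters <- iters + 1L
  }
  list(u = u, obj = obj, H = H, iters = iters, grad_norm = gnorm,
       converged = gnorm < tol)
}

rowsum_vec <- function(x, idx, n) {
  out <- numeric(n)
  if (length(x) == 0L) return(out)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s
  out
}

# penalised Hessian -d2/du2 as a sparse symmetric matrix
clmm_hessian <- function(w, idx, nlev, sigmas, offs) {
  q <- sum(nlev)
  diags <- unlist(lapply(seq_along(idx), function(f)
    rowsum_vec(w, idx[[f]], nlev[f])))
  diags <- diags + 1 / rep(sigmas^2, nlev)
  if (length(idx) == 1L) return(Matrix::Diagonal(x = diags))
  B <- Matrix::sparseMatrix(i = idx[[1L]], j = idx[[2L]], x = w,
                            dims = c(nlev[1L], nlev[2L]))
  H <- rbind(cbind(Matrix::Diagonal(x = diags[seq_len(nlev[1L])]), B),
             cbind(Matrix::t(B),
                   Matrix::Diagonal(x = diags[nlev[1L] + seq_len(nlev[2L])])))
  methods::as(H, "CsparseMatrix")
}

# Laplace log marginal likelihood at (tau, sigmas); returns value and mode
clmm_laplace <- function(y, tau, link, K, idx, nlev, sigmas, u) {
  inner <- clmm_inner(y, tau, link, K, idx, nlev, sigmas, u)
  ld <- Matrix::determinant(inner$H, logarithm = TRUE)$modulus
  ll <- inner$obj - sum(nlev * log(sigmas)) - 0.5 * as.numeric(ld)
  list(loglik = ll, inner = inner)
}

#' Fit a cumulative link mixed model by maximum likelihood
#'
#' Fits an ordinal regression with flexible thresholds and random intercepts
#' on the latent mean for one or two crossed grouping factors (items,
#' participants). The latent grand mean is fixed at 0 for identifiability,
#' so the conditional modes of the item effects are direct estimates of each
#' item's latent mean -- the norms. The marginal likelihood is approximated
#' by a Laplace approximation over the stacked random-effects vector, with
#' inner Newton iterations exploiting the sparse block structure of the
#' penalised Hessian; the outer optimisation runs over the first threshold,
#' log threshold increments and log random-effect SDs.
#'
#' @param trials Trial table with columns \code{item_id}, \code{response}
#'   and (if participants are modelled) \code{participant_id}.
#' @param n_levels Number of response categories K (declared, not inferred).
#' @param factors Character subset of \code{c("item", "participant")}
#'   receiving random intercepts.
#' @param link Link function or name; default probit.
#' @param control List; supported entries \code{outer_tol} (relative
#'   objective change, default 1e-8), \code{max_outer} (default 200),
#'   \code{sd_start} (default 0.5).
#' @return An object of class \code{"clmm_fit"}: thresholds \code{tau},
#'   random-effect SDs \code{re_sd}, per-factor conditional modes and SDs,
#'   \code{loglik}, convergence information.
#' @seealso \code{\link{ranef.clmm_fit}} to extract the norms.
#' @export
fit_clmm <- function(trials, n_levels, factors = c("item", "participant"),
                     link = "probit", control = list()) {
  link <- as_link(link)
  K <- as.integer(n_levels)
  factors <- intersect(c("item", "participant"), factors)
  if (length(factors) == 0L) stop("at least one grouping factor is required")
  cols <- paste0(ifelse(factors == "item", "item", "participant"), "_id")
  missing_cols <- setdiff(c(cols, "response"), names(trials))
  if (length(missing_cols))
    stop("trials lack column(s): ", paste(missing_cols, collapse = ", "))
  y <- as.integer(trials$response)
  if (any(y < 1L | y > K)) stop("responses outside 1..K")
  counts <- tabulate(y, nbins = K)
  if (sum(counts > 0) < 2L) stop("all responses identical; cannot fit")

  # unobserved categories allowed only at the extremes: clamp their
  # thresholds to +/-10 and fit the observed sub-range
  kmin <- min(y); kmax <- max(y)
  if (any(counts[kmin:kmax] == 0L))
    stop("unobserved interior response categories: ",
         paste(which(counts == 0L), collapse = ", "))
  if (kmin > 1L || kmax < K)
    warning("unobserved extreme categories; adjacent thresholds clamped to +/-10")
  y_int <- y - kmin + 1L
  K_int <- kmax - kmin + 1L

  levels_by_factor <- lapply(cols, function(cl) sort(unique(as.character(trials[[cl]]))))
  idx <- lapply(seq_along(cols), function(f)
    match(as.character(trials[[cols[f]]]), levels_by_factor[[f]]))
  nlev <- vapply(levels_by_factor, length, integer(1))
  nf <- length(idx)

  # parameter vector: tau_1, log-increments (K_int - 2), log sigma per factor
  tau0 <- fit_thresholds_only(y_int, K_int, link)
  tau0 <- pmin(pmax(tau0, -4), 4)
  tau0 <- tau0 + cumsum(c(0, pmax(1e-3 - diff(tau0), 0)))
  sd_start <- if (is.null(control$sd_start)) 0.5 else control$sd_start
  theta0 <- c(tau0[1L],
              if (K_int > 2L) log(diff(tau0)),
              rep(log(sd_start), nf))
  unpack <- function(theta) {
    tau <- theta[1L]
    if (K_int > 2L) tau <- cumsum(c(tau, exp(theta[2:(K_int - 1L)])))
    sigmas <- pmax(exp(theta[(K_int - 1L) + seq_len(nf)]), 1e-6)
    list(tau = tau, sigmas = sigmas)
  }

  env <- new.env()
  env$u <- numeric(sum(nlev))
  env$evals <- 0L
  env$trace <- numeric(0)
  negloglik <- function(theta) {
    pr <- unpack(theta)
    lap <- clmm_laplace(y_int, pr$tau, link, K_int, idx, nlev, pr$sigmas, env$u)
    env$u <- lap$inner$u
    env$evals <- env$evals + 1L
    if (!is.finite(lap$loglik)) return(1e10)
    env$trace <- c(env$trace, lap$loglik)
    -lap$loglik
  }
  outer_tol <- if (is.null(control$outer_tol)) 1e-8 else control$outer_tol
  max_outer <- if (is.null(control$max_outer)) 200L else control$max_outer
  # box constraints keep the optimiser away from degenerate regions:
  # thresholds within +/-30, increments and RE SDs within sane log ranges
  lower <- c(-30, rep(-8, K_int - 2L), rep(log(1e-6), nf))
  upper <- c(30, rep(log(60), K_int - 2L), rep(log(30), nf))
  opt <- stats::nlminb(theta0, negloglik, lower = lower, upper = upper,
                       control = list(rel.tol = outer_tol,
                                      iter.max = max_outer,
                                      eval.max = 10L * max_outer))
  pr <- unpack(opt$par)
  lap <- clmm_laplace(y_int, pr$tau, link, K_int, idx, nlev, pr$sigmas, env$u)

  # conditional SDs from the inverse penalised Hessian
  Hinv_diag <- Matrix::diag(Matrix::solve(lap$inner$H))
  offs <- c(0L, cumsum(nlev))[seq_len(nf)]
  modes <- lapply(seq_len(nf), function(f) {
    data.frame(level_id = levels_by_factor[[f]],
               mode = lap$inner$u[offs[f] + seq_len(nlev[f])],
               cond_sd = sqrt(Hinv_diag[offs[f] + seq_len(nlev[f])]),
               stringsAsFactors = FALSE)
  })
  names(modes) <- factors

  tau_full <- c(rep(-10, kmin - 1L), pr$tau, rep(10, K - kmax))
  re_sd <- pr$sigmas
  names(re_sd) <- factors
  structure(
    list(tau = tau_full, re_sd = re_sd, modes = modes,
         loglik = lap$loglik, link = link$name, n_levels = K,
         factors = factors,
         converged = opt$convergence == 0 &&
           all(pr$sigmas > 1.5e-6),
         boundary = any(pr$sigmas <= 1.5e-6),
         outer_iterations = opt$iterations, outer_evals = env$evals,
         objective_trace = env$trace,
         inner_iterations = lap$inner$iters,
         n_obs = length(y), message = opt$message),
    class = "clmm_fit")
}

#' @export
print.clmm_fit <- function(x, ...) {
  cat(sprintf("<clmm_fit> %s link, K = %d, n = %d, logLik = %.3f\n",
              x$link, x$n_levels, x$n_obs, x$loglik))
  cat("  thresholds:", paste(signif(x$tau, 4), collapse = ", "), "\n")
  for (f in x$factors)
    cat(sprintf("  RE SD (%s): %.4f  [%d levels]\n", f, x$re_sd[[f]],
                nrow(x$modes[[f]])))
  if (!x$converged) cat("  WARNING: fit did not converge cleanly\n")
  invisible(x)
}

#' @export
logLik.clmm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$tau) + length(object$re_sd),
            class = "logLik")
}

#' Extract conditional modes (the norms) from a CLMM fit
#'
#' Conditional modes of the random effects are each level's most likely
#' latent-mean deviation from the (zero) grand mean -- for the item factor
#' these are the latent item norms. Estimates are shrunken: an item rated at
#' one scale extreme still receives a finite mode, pulled toward more likely
#' values in proportion to how little its data constrain it.
#'
#' @param object A \code{\link{fit_clmm}} result.
#' @param factor \code{"item"} or \code{"participant"}.
#' @param ... Unused.
#' @return A data.frame with columns \code{level_id}, \code{mode},
#'   \code{cond_sd}.
#' @importFrom lme4 ranef
#' @export
#' @method ranef clmm_fit
ranef.clmm_fit <- function(object, factor = "item", ...) {
  if (!factor %in% object$factors)
    stop("factor '", factor, "' not in fit (has: ",
         paste(object$factors, collapse = ", "), ")")
  object$modes[[factor]]
}

#' Marginal log-likelihood by adaptive Gauss-Hermite quadrature
#'
#' Independent brute-force evaluation of the marginal likelihood for a
#' single-grouping-factor CLMM: the likelihood factorises by group, and each
#' group's one-dimensional integral over its random effect is computed with
#' adaptive Gauss-Hermite quadrature (nodes centred at the group's
#' conditional mode and scaled by its conditional curvature). Serves as an
#' oracle for the Laplace approximation used by \code{\link{fit_clmm}}.
#'
#' @param trials Trial table with \code{item_id} (or \code{participant_id})
#'   and \code{response}.
#' @param tau Threshold vector (length K - 1, increasing).
#' @param re_sd Random-effect SD (>= 0).
#' @param n_levels K.
#' @param factor Grouping factor name; default \code{"item"}.
#' @param n_nodes Number of quadrature nodes (>= 5).
#' @param link Link function or name.
#' @return Scalar log-likelihood.
#' @export
marginal_loglik_quadrature <- function(trials, tau, re_sd, n_levels,
                                       factor = "item", n_nodes = 50L,
                                       link = "probit") {
  link <- as_link(link)
  if (n_nodes < 5L) stop("n_nodes must be >= 5")
  K <- as.integer(n_levels)
  col <- paste0(factor, "_id")
  if (!col %in% names(trials)) stop("missing column ", col)
  y <- as.integer(trials$response)
  grp <- as.character(trials[[col]])
  gh <- statmod::gauss.quad(n_nodes, kind = "hermite")
  total <- 0
  for (g in unique(grp)) {
    yg <- y[grp == g]
    if (re_sd < 1e-12) {
      total <- total + sum(clmm_obs_terms(yg, 0, tau, link, K)$ll)
      next
    }
    # 1-D Newton for the group's conditional mode
    u <- 0
    for (it in 1:50) {
      t1 <- clmm_obs_terms(yg, rep(u, length(yg)), tau, link, K)
      gr <- sum(t1$g) - u / re_sd^2
      h <- sum(t1$w) + 1 / re_sd^2
      step <- gr / h
      u <- u + step
      if (abs(step) < 1e-10) break
    }
    h <- sum(clmm_obs_terms(yg, rep(u, length(yg)), tau, link, K)$w) +
      1 / re_sd^2
    scale <- sqrt(2 / h)
    nodes <- u + scale * gh$nodes
    logint <- vapply(seq_along(nodes), function(m) {
      ll <- sum(clmm_obs_terms(yg, rep(nodes[m], length(yg)), tau, link, K)$ll)
      ll + stats::dnorm(nodes[m], 0, re_sd, log = TRUE) + gh$nodes[m]^2
    }, numeric(1))
    lw <- log(gh$weights) + logint + log(scale)
    mx <- max(lw)
    total <- total + mx + log(sum(exp(lw - mx)))
  }
  total
}
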