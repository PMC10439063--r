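#' Specification for the Bayesian distributional CLMM
#'
#' The distributional model estimates, per trial, a latent mean
#' \code{eta_mu = mu_i + mu_j} and a log-discrimination
#' \code{eta_disc = disc_i + disc_j}; the response probability is
#' \code{F(exp(eta_disc) * (tau_k - eta_mu)) -
#'       F(exp(eta_disc) * (tau_{k-1} - eta_mu))}.
#' Discrimination is the inverse of the latent SD on the log scale, so
#' \code{latent SD = 1 / exp(eta_disc)}. Neither linear predictor has a free
#' intercept: the latent grand mean is 0 and the baseline latent SD is 1,
#' for identifiability.
#'
#' Priors: thresholds Normal(0, 5) (with an ordering transform), all
#' random-effect SDs half-Normal(0, 1), level effects Normal(0, SD)
#' (sampled non-centred).
#'
#' @param n_levels Number of response categories K.
#' @param mu_factors Factors receiving latent-mean random intercepts.
#' @param disc_factors Factors receiving discrimination random intercepts;
#'   empty for an equal-variance model.
#' @param link Link function or name.
#' @param chains Number of MCMC chains (>= 2).
#' @param iter Total iterations per chain (warmup + sampling).
#' @param warmup Warmup iterations (adaptation; discarded).
#' @param adapt_target Target acceptance rate for step-size adaptation
#'   (the backend's \code{adapt_delta} analogue).
#' @param max_leapfrog Maximum leapfrog steps per iteration.
#' @param seed Integer seed.
#' @return An object of class \code{"distributional_spec"}.
#' @export
distributional_spec <- function(n_levels = 5L,
                                mu_factors = c("item", "participant"),
                                disc_factors = c("item", "participant"),
                                link = "probit",
                                chains = 4L, iter = 1000L, warmup = 500L,
                                adapt_target = 0.8, max_leapfrog = 16L,
                                seed = 1L) {
  if (chains < 2L) stop("chains must be >= 2")
  if (iter <= warmup) stop("iter must exceed warmup")
  if (length(mu_factors) == 0L) stop("at least one mu factor required")
  structure(list(n_levels = as.integer(n_levels),
                 mu_factors = mu_factors, disc_factors = disc_factors,
                 link = link, chains = as.integer(chains),
                 iter = as.integer(iter), warmup = as.integer(warmup),
                 adapt_target = adapt_target,
                 max_leapfrog = as.integer(max_leapfrog),
                 seed = as.integer(seed)),
            class = "distributional_spec")
}

# log posterior and gradient for the packed parameter vector
# layout: [t (K-1): tau1, log-diffs][log sd per group][z per group ...]
make_logpost <- function(y, K, link, groups) {
  ng <- length(groups)
  nlev <- vapply(groups, function(g) g$nlev, integer(1))
  n_t <- K - 1L
  off_s <- n_t
  off_z <- n_t + ng + c(0L, cumsum(nlev))[seq_len(ng)]
  npar <- n_t + ng + sum(nlev)

  function(q) {
    t_raw <- q[seq_len(n_t)]
    tau <- if (n_t > 1L) cumsum(c(t_raw[1L], exp(t_raw[-1L]))) else t_raw[1L]
    log_sd <- q[off_s + seq_len(ng)]
    sds <- exp(log_sd)
    z <- lapply(seq_len(ng), function(g) q[off_z[g] + seq_len(nlev[g])])

    eta_mu <- 0; eta_disc <- 0
    for (g in seq_len(ng)) {
      eff <- sds[g] * z[[g]]
      if (groups[[g]]$role == "mu") {
        eta_mu <- eta_mu + eff[groups[[g]]$idx]
      } else {
        eta_disc <- eta_disc + eff[groups[[g]]$idx]
      }
    }
    s <- exp(eta_disc)
    lo <- c(-Inf, tau)[y]
    hi <- c(tau, Inf)[y]
    a <- s * (lo - eta_mu)
    b <- s * (hi - eta_mu)
    fin_a <- is.finite(a); fin_b <- is.finite(b)
    Fa <- ifelse(fin_a, link$cdf(a), 0)
    Fb <- ifelse(fin_b, link$cdf(b), 1)
    p <- pmax(Fb - Fa, 1e-300)
    fa <- ifelse(fin_a, link$density(a), 0)
    fb <- ifelse(fin_b, link$density(b), 0)

    ll <- sum(log(p))
    d_mu <- s * (fa - fb) / p
    d_disc <- (fb * ifelse(fin_b, b, 0) - fa * ifelse(fin_a, a, 0)) / p

    # d loglik / d tau_m, accumulated over observations
    g_tau <- numeric(n_t)
    up <- y; lw <- y - 1L
    add_b <- rowsum_vec((s * fb / p)[up <= n_t], up[up <= n_t], n_t)
    add_a <- rowsum_vec((s * fa / p)[lw >= 1L], lw[lw >= 1L], n_t)
    g_tau <- add_b - add_a

    # priors
    lp <- ll - sum(tau^2) / 50 +                      # thresholds N(0,5)
      sum(-sds^2 / 2 + log_sd) +                      # half-N(0,1) + Jacobian
      sum(vapply(z, function(v) -sum(v^2) / 2, numeric(1)))
    if (n_t > 1L) lp <- lp + sum(t_raw[-1L])          # ordering Jacobian
    g_tau <- g_tau - tau / 25

    grad <- numeric(npar)
    # chain rule through the ordering transform
    rev_cum <- rev(cumsum(rev(g_tau)))
    grad[1L] <- rev_cum[1L]
    if (n_t > 1L)
      grad[2:n_t] <- exp(t_raw[-1L]) * rev_cum[-1L] + 1
    for (g in seq_len(ng)) {
      d_eta <- if (groups[[g]]$role == "mu") d_mu else d_disc
      agg <- rowsum_vec(d_eta, groups[[g]]$idx, nlev[g])
      grad[off_z[g] + seq_len(nlev[g])] <- sds[g] * agg - z[[g]]
      grad[off_s + g] <- sds[g] * sum(agg * z[[g]]) - sds[g]^2 + 1
    }
    list(lp = lp, grad = grad)
  }
}

# Exact Gibbs update along the threshold/mean-effect translation direction.
# Adding delta to every threshold and to every effect of one mu factor
# (z -> z + delta/sd) leaves the likelihood invariant; the conditional
# posterior of delta given everything else is Gaussian under the
# Normal(0, 5) threshold prior and standard-normal z prior. Sampling it
# directly removes the slowest-mixing posterior direction.
translation_gibbs <- function(q, shift_info) {
  n_t <- length(shift_info$tau_idx)
  t_raw <- q[shift_info$tau_idx]
  tau <- if (n_t > 1L) cumsum(c(t_raw[1L], exp(t_raw[-1L]))) else t_raw[1L]
  for (g in shift_info$mu_groups) {
    sdg <- exp(q[g$sd_idx])
    z <- q[g$z_idx]
    prec <- n_t / 25 + length(z) / sdg^2
    mean_d <- -(sum(tau) / 25 + sum(z) / sdg) / prec
    delta <- stats::rnorm(1, mean_d, 1 / sqrt(prec))
    tau <- tau + delta
    q[g$z_idx] <- z + delta / sdg
  }
  q[shift_info$tau_idx[1L]] <- tau[1L]  # log-increments are unchanged
  q
}

# Interweaving move for each random-effect scale: log sd -> log sd + delta,
# z -> z * exp(-delta) keeps the effects (sd * z) and hence the likelihood
# fixed. The 1-D conditional log-density of delta,
#   g(delta) = -sd^2 e^{2 delta} / 2 + delta - e^{-2 delta} sum(z^2) / 2
#              - nlev * delta,
# (half-normal sd prior + z prior + transform Jacobian) is log-concave;
# sampled by a stepping-out slice sampler.
scale_gibbs <- function(q, groups_idx) {
  for (g in groups_idx) {
    ls <- q[g$sd_idx]
    z <- q[g$z_idx]
    S <- sum(z^2)
    nl <- length(z)
    gfun <- function(d) {
      s2 <- exp(2 * (ls + d))
      -s2 / 2 + d - exp(-2 * d) * S / 2 - nl * d
    }
    # slice sample delta around 0
    y0 <- gfun(0) + log(stats::runif(1))
    w <- 0.3
    lo <- -w * stats::runif(1); hi <- lo + w
    for (i in 1:20) { if (gfun(lo) <= y0) break; lo <- lo - w }
    for (i in 1:20) { if (gfun(hi) <= y0) break; hi <- hi + w }
    repeat {
      d <- stats::runif(1, lo, hi)
      if (gfun(d) >= y0) break
      if (d < 0) lo <- d else hi <- d
      if (hi - lo < 1e-8) { d <- 0; break }
    }
    q[g$sd_idx] <- ls + d
    q[g$z_idx] <- z * exp(-d)
  }
  q
}

hmc_chain <- function(lpg, q0, n_iter, warmup, target, max_leapfrog,
                      shift_info = NULL) {
  npar <- length(q0)
  q <- q0
  cur <- lpg(q)
  eps <- 0.1
  # dual averaging state
  mu_da <- log(10 * eps); log_eps_bar <- 0; Hbar <- 0; m0 <- 0L
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  inv_mass <- rep(1, npar)
  mass_window <- NULL
  # two mass-matrix updates during warmup, each followed by step-size re-adaptation
  w_marks <- floor(warmup * c(0.5, 0.85))
  w_starts <- floor(warmup * c(0.25, 0.5))
  draws <- matrix(NA_real_, n_iter - warmup, npar)
  accepts <- 0
  for (it in seq_len(n_iter)) {
    L <- sample(seq.int(max(2L, max_leapfrog %/% 2L), max_leapfrog), 1L)
    p <- stats::rnorm(npar) / sqrt(inv_mass)
    q_new <- q; g_new <- cur$grad
    p_new <- p + 0.5 * eps * g_new
    bad <- FALSE
    for (l in seq_len(L)) {
      q_new <- q_new + eps * inv_mass * p_new
      prop <- lpg(q_new)
      if (!all(is.finite(prop$grad)) || !is.finite(prop$lp)) { bad <- TRUE; break }
      p_new <- p_new + (if (l < L) eps else 0.5 * eps) * prop$grad
    }
    if (!bad) {
      h_cur <- -cur$lp + 0.5 * sum(inv_mass * p^2)
      h_prop <- -prop$lp + 0.5 * sum(inv_mass * p_new^2)
      log_acc <- min(0, h_cur - h_prop)
      alpha <- exp(log_acc)
      if (log(stats::runif(1)) < log_acc) {
        q <- q_new; cur <- prop
        if (it > warmup) accepts <- accepts + 1
      }
    } else alpha <- 0
    if (!is.null(shift_info)) {
      q <- translation_gibbs(q, shift_info)
      q <- scale_gibbs(q, shift_info$all_groups)
      cur <- lpg(q)
    }
    if (it <= warmup) {
      m <- it - m0
      Hbar <- (1 - 1 / (m + t0)) * Hbar + (target - alpha) / (m + t0)
      log_eps <- mu_da - sqrt(m) / gamma * Hbar
      eta <- m^(-kappa)
      log_eps_bar <- eta * log_eps + (1 - eta) * log_eps_bar
      eps <- exp(log_eps)
      phase <- findInterval(it, w_marks) + 1L
      if (phase <= 2L && it > w_starts[phase])
        mass_window <- rbind(mass_window, q)
      if (it %in% w_marks && !is.null(mass_window) &&
          nrow(mass_window) > 10) {
        v <- apply(mass_window, 2, stats::var)
        inv_mass <- pmax(v, 1e-3)
        mass_window <- NULL
        # restart step-size adaptation under the new metric
        eps <- exp(log_eps_bar); mu_da <- log(10 * eps)
        Hbar <- 0; log_eps_bar <- log(eps)
        m0 <- it
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      draws[it - warmup, ] <- q
    }
  }
  list(draws = draws, accept_rate = accepts / (n_iter - warmup), eps = eps)
}

split_rhat <- function(mat_list) {
  # mat_list: one matrix per chain (draws x params); split each chain in half
  halves <- list()
  for (m in mat_list) {
    n <- nrow(m); h <- n %/% 2
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[(h + 1):(2 * h), , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1]])))
  vars <- vapply(halves, function(m) apply(m, 2, stats::var),
                 numeric(ncol(halves[[1]])))
  if (is.null(dim(means))) { means <- matrix(means, nrow = 1); vars <- matrix(vars, nrow = 1) }
  B <- n * apply(means, 1, stats::var)
  W <- rowMeans(vars)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit a Bayesian distributional CLMM by Hamiltonian Monte Carlo
#'
#' Samples the joint posterior of thresholds, random-effect SDs and
#' per-level latent-mean (\code{mu}) and log-discrimination (\code{disc})
#' effects under the model described in
#' \code{\link{distributional_spec}}. Sampling uses Hamiltonian Monte Carlo
#' with analytic gradients, non-centred random effects, dual-averaging
#' step-size adaptation and a diagonal mass matrix estimated during warmup.
#' With \code{disc_factors = character(0)} this is an equal-variance
#' Bayesian CLMM.
#'
#' The fit fails loudly (error by default) if the split-chain convergence
#' diagnostic exceeds 1.05 for any threshold or random-effect SD.
#'
#' @param trials Trial table with \code{item_id}, \code{participant_id}
#'   (if modelled) and \code{response}.
#' @param spec A \code{\link{distributional_spec}}.
#' @param on_nonconvergence \code{"error"} (default) or \code{"warn"}.
#' @param prior_only If \code{TRUE}, sample the prior: the trials are used
#'   only to define the factor levels and the likelihood is dropped.
#' @return An object of class \code{"posterior_fit"}: \code{draws} (matrix,
#'   pooled post-warmup draws x parameters, named columns), \code{chain}
#'   (chain index per draw), \code{rhat}, \code{ess} and bookkeeping.
#' @export
fit_distributional <- function(trials, spec = distributional_spec(),
                               on_nonconvergence = c("error", "warn"),
                               prior_only = FALSE) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  link <- as_link(spec$link)
  K <- spec$n_levels
  y <- as.integer(trials$response)
  if (any(y < 1L | y > K)) stop("responses outside 1..K")
  if (length(unique(y)) < 2L) stop("all responses identical; cannot fit")

  groups <- list()
  lvl <- list()
  for (role in c("mu", "disc")) {
    facs <- if (role == "mu") spec$mu_factors else spec$disc_factors
    for (fc in facs) {
      col <- paste0(fc, "_id")
      if (!col %in% names(trials)) stop("missing column ", col)
      levels_f <- sort(unique(as.character(trials[[col]])))
      groups[[paste(role, fc, sep = "_")]] <-
        list(role = role, factor = fc, nlev = length(levels_f),
             idx = match(as.character(trials[[col]]), levels_f))
      lvl[[paste(role, fc, sep = "_")]] <- levels_f
    }
  }
  if (prior_only) {
    groups <- lapply(groups, function(g) { g$idx <- integer(0); g })
    lpg <- make_logpost(integer(0), K, link, groups)
  } else {
    lpg <- make_logpost(y, K, link, groups)
  }
  n_t <- K - 1L; ng <- length(groups)
  nlev <- vapply(groups, function(g) g$nlev, integer(1))
  npar <- n_t + ng + sum(nlev)

  # parameter names on the natural scale
  par_names <- c(paste0("tau[", seq_len(n_t), "]"),
                 paste0("sd_", names(groups)),
                 unlist(lapply(seq_len(ng), function(g)
                   paste0(names(groups)[g], "[", lvl[[g]], "]"))))

  off_z <- n_t + ng + c(0L, cumsum(nlev))[seq_len(ng)]
  shift_info <- list(
    tau_idx = seq_len(n_t),
    mu_groups = lapply(which(vapply(groups, function(g) g$role == "mu",
                                    logical(1))), function(g)
      list(sd_idx = n_t + g, z_idx = off_z[g] + seq_len(nlev[g]))),
    all_groups = lapply(seq_len(ng), function(g)
      list(sd_idx = n_t + g, z_idx = off_z[g] + seq_len(nlev[g]))))

  tau_start <- fit_thresholds_only(y, K, link)
  tau_start <- pmin(pmax(tau_start, -3), 3)
  tau_start <- tau_start + cumsum(c(0, pmax(0.05 - diff(tau_start), 0)))
  chains <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + 104729L * ch)
    q0 <- c(tau_start[1L] + stats::rnorm(1, 0, 0.1),
            if (n_t > 1L) log(diff(tau_start)) + stats::rnorm(n_t - 1L, 0, 0.1),
            stats::rnorm(ng, log(0.5), 0.1),
            stats::rnorm(sum(nlev), 0, 0.1))
    chains[[ch]] <- hmc_chain(lpg, q0, spec$iter, spec$warmup,
                              spec$adapt_target, spec$max_leapfrog,
                              shift_info = shift_info)
  }

  # transform raw draws to natural-scale draws
  to_natural <- function(m) {
    out <- m
    if (n_t > 1L)
      out[, 1:n_t] <- t(apply(m[, 1:n_t, drop = FALSE], 1, function(r)
        cumsum(c(r[1L], exp(r[-1L])))))
    out[, n_t + seq_len(ng)] <- exp(m[, n_t + seq_len(ng), drop = FALSE])
    off <- n_t + ng
    for (g in seq_len(ng)) {
      cols <- off + seq_len(nlev[g])
      out[, cols] <- m[, cols, drop = FALSE] * out[, n_t + g]
      off <- off + nlev[g]
    }
    colnames(out) <- par_names
    out
  }
  nat <- lapply(chains, function(ch) to_natural(ch$draws))
  rhat <- split_rhat(nat)
  names(rhat) <- par_names
  core <- seq_len(n_t + ng)  # thresholds + RE SDs: the reported parameters
  ess <- apply(do.call(rbind, nat)[, core, drop = FALSE], 2, ess_basic)

  if (any(rhat[core] > 1.05)) {
    msg <- paste0("convergence diagnostic exceeds 1.05 for: ",
                  paste(par_names[core][rhat[core] > 1.05], collapse = ", "))
    if (on_nonconvergence == "error") stop(msg) else warning(msg)
  }

  draws <- do.call(rbind, nat)
  # per-item observed summaries for norm tables
  obs <- NULL
  if ("item_id" %in% names(trials)) {
    sp <- split(as.numeric(trials$response), as.character(trials$item_id))
    obs <- data.frame(item_id = names(sp),
                      n = vapply(sp, length, integer(1)),
                      raw_mean = vapply(sp, mean, numeric(1)),
                      raw_sd = vapply(sp, function(v)
                        if (length(v) > 1) stats::sd(v) else NA_real_,
                        numeric(1)),
                      stringsAsFactors = FALSE)
    obs <- obs[order(obs$item_id), ]
  }
  structure(
    list(draws = draws,
         chain = rep(seq_len(spec$chains), each = spec$iter - spec$warmup),
         par_names = par_names, n_levels = K, link = link$name,
         groups = lapply(groups, function(g) g[c("role", "factor", "nlev")]),
         levels = lvl, rhat = rhat, ess = ess,
         accept_rates = vapply(chains, function(c) c$accept_rate, numeric(1)),
         item_obs = obs, spec = spec),
    class = "posterior_fit")
}

# initial-positive-sequence effective sample size (Geyer)
ess_basic <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[, 1, 1]
  s <- 0; k <- 2
  while (k + 1 <= length(ac)) {
    pair <- ac[k] + ac[k + 1]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}

#' @export
print.posterior_fit <- function(x, ...) {
  nc <- length(unique(x$chain))
  cat(sprintf("<posterior_fit> %s link, K = %d, %d chains x %d draws\n",
              x$link, x$n_levels, nc, sum(x$chain == 1L)))
  core <- seq_len((x$n_levels - 1L) + length(x$groups))
  med <- apply(x$draws[, core, drop = FALSE], 2, stats::median)
  for (i in core)
    cat(sprintf("  %-22s %8.3f  (rhat %.3f)\n", x$par_names[i], med[i],
                x$rhat[i]))
  invisible(x)
}

#' Per-draw latent SDs for one level of a factor
#'
#' Discrimination is the inverse latent SD on the log scale; each posterior
#' draw's latent SD is \code{1 / exp(disc draw)}. Summary statistics of
#' latent SDs must be computed on this scale, not the disc scale.
#'
#' @param posterior A \code{\link{fit_distributional}} result.
#' @param factor Factor name with disc effects (e.g. \code{"item"}).
#' @param level Level id (e.g. \code{"item_001"}).
#' @return Numeric vector of latent SD draws.
#' @export
latent_sd_draws <- function(posterior, factor, level) {
  gname <- paste0("disc_", factor)
  if (!gname %in% names(posterior$groups))
    stop("factor '", factor, "' has no disc effects in this fit")
  col <- paste0(gname, "[", level, "]")
  if (!col %in% posterior$par_names) stop("unknown level: ", level)
  1 / exp(posterior$draws[, col])
}

#' Highest density interval of a draw vector
#'
#' Shortest contiguous interval containing \code{ceiling(prob * n)} of the
#' sorted draws.
#'
#' @param draws Numeric vector (>= 100 draws unless \code{prob = 1}).
#' @param prob Probability mass; default 0.89.
#' @return Named numeric vector \code{c(lower, upper)}.
#' @export
hdi <- function(draws, prob = 0.89) {
  if (prob <= 0 || prob > 1) stop("prob must be in (0, 1]")
  n <- length(draws)
  if (n < 100 && prob < 1) stop("need at least 100 draws")
  x <- sort(draws)
  if (prob == 1) return(c(lower = x[1L], upper = x[n]))
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = x[1L], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Summarise a distributional posterior into a norm table
#'
#' Per item: posterior median latent mean with its 89% HDI, and (when item
#' disc effects were modelled) posterior median latent SD with its 89% HDI,
#' computed on the SD scale via \code{\link{latent_sd_draws}}. Raw per-item
#' mean, SD and rating count are carried over from the fitted data.
#'
#' @param posterior A \code{\link{fit_distributional}} result.
#' @param prob HDI mass; default 0.89.
#' @return A norm table (see \code{\link{raw_norms}} for the column layout)
#'   with \code{method = "clmm_bayes"}.
#' @export
summarize_posterior_norms <- function(posterior, prob = 0.89) {
  items <- posterior$levels[["mu_item"]]
  if (is.null(items)) stop("posterior has no item mu effects")
  mu_cols <- paste0("mu_item[", items, "]")
  med <- apply(posterior$draws[, mu_cols, drop = FALSE], 2, stats::median)
  his <- apply(posterior$draws[, mu_cols, drop = FALSE], 2, hdi, prob = prob)
  has_disc <- "disc_item" %in% names(posterior$groups)
  if (has_disc) {
    sd_draws <- vapply(items, function(it)
      latent_sd_draws(posterior, "item", it),
      numeric(nrow(posterior$draws)))
    sd_med <- apply(sd_draws, 2, stats::median)
    sd_hdi <- apply(sd_draws, 2, hdi, prob = prob)
  }
  obs <- posterior$item_obs
  out <- data.frame(
    item_id = items,
    n = obs$n[match(items, obs$item_id)],
    raw_mean = obs$raw_mean[match(items, obs$item_id)],
    raw_sd = obs$raw_sd[match(items, obs$item_id)],
    latent_mean = med,
    latent_mean_lo = his[1L, ], latent_mean_hi = his[2L, ],
    latent_sd = if (has_disc) sd_med else NA_real_,
    latent_sd_lo = if (has_disc) sd_hdi[1L, ] else NA_real_,
    latent_sd_hi = if (has_disc) sd_hdi[2L, ] else NA_real_,
    method = "clmm_bayes",
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$item_id), ]
}
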