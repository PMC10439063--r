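test_that("intercept-only thresholds equal link-inverted cumulative proportions", {
  y <- rep(1:5, c(10, 20, 40, 20, 10))
  expect_equal(fit_thresholds_only(y, 5),
               qnorm(c(0.1, 0.3, 0.7, 0.9)), tolerance = 1e-12)
  # uniform counts: symmetric about 0
  tu <- fit_thresholds_only(rep(1:5, each = 7), 5)
  expect_equal(tu, -rev(tu))
  # K = 2 reduces to the probit of a proportion
  yb <- rep(1:2, c(3, 7))
  expect_equal(fit_thresholds_only(yb, 2), qnorm(0.3))
  # logit link
  expect_equal(fit_thresholds_only(y, 5, link = "logit"),
               qlogis(c(0.1, 0.3, 0.7, 0.9)))
  expect_error(fit_thresholds_only(rep(3L, 10), 5), "degenerate")
})

test_that("quadrature oracle: convergence, RE-SD-zero collapse, Monte Carlo", {
  set.seed(71)
  des <- simulation_design(n_items = 10, n_participants = NULL,
                           ratings_per_item = 10, seed = 71)
  tt <- simulate_items_only(des, "edge-biased")
  tau <- c(-1, -0.3, 0.4, 1.1)
  # node-count convergence
  q20 <- marginal_loglik_quadrature(tt, tau, 0.8, 5, n_nodes = 20)
  q50 <- marginal_loglik_quadrature(tt, tau, 0.8, 5, n_nodes = 50)
  expect_lt(abs(q20 - q50), 1e-6)
  # RE SD = 0: integral collapses to the fixed-effects log-likelihood
  q0 <- marginal_loglik_quadrature(tt, tau, 0, 5)
  probs <- diff(c(0, pnorm(tau), 1))
  expect_equal(q0, sum(log(probs[tt$response])), tolerance = 1e-10)
  # second independent oracle: naive Monte-Carlo integration per item
  set.seed(72)
  ll_mc <- 0
  mc_vars <- 0
  n_mc <- 1e5
  for (g in unique(tt$item_id)) {
    yg <- tt$response[tt$item_id == g]
    u <- rnorm(n_mc, 0, 0.8)
    li <- vapply(u, function(ui)
      prod(diff(c(0, pnorm(tau - ui), 1))[yg]), numeric(1))
    ll_mc <- ll_mc + log(mean(li))
    mc_vars <- mc_vars + var(li) / (n_mc * mean(li)^2)
  }
  expect_lt(abs(q50 - ll_mc), 3 * sqrt(mc_vars))
})

test_that("Laplace agrees with quadrature and the zero-variance limit", {
  set.seed(73)
  des <- simulation_design(n_items = 10, n_participants = NULL,
                           ratings_per_item = 10, seed = 73)
  tt <- simulate_items_only(des, "left-biased")
  fit <- quiet_fit(tt, 5, factors = "item")
  gh <- marginal_loglik_quadrature(tt, fit$tau, fit$re_sd[["item"]], 5,
                                   n_nodes = 50)
  expect_lt(abs(fit$loglik - gh), 0.5)
  # likelihood ascent: final objective at least as good as the first
  expect_gte(fit$loglik, fit$objective_trace[1] - 1e-9)
  expect_equal(max(fit$objective_trace), fit$loglik, tolerance = 1e-6)
  # closed-form limit: data with no item signal
  des0 <- simulation_design(n_items = 50, n_participants = NULL,
                            ratings_per_item = 25, sd_mu_item = 0, seed = 74)
  tt0 <- simulate_items_only(des0, "edge-biased")
  fit0 <- quiet_fit(tt0, 5, factors = "item")
  expect_lte(fit0$re_sd[["item"]], 0.15)
  expect_lte(max(abs(ranef(fit0, "item")$mode)), 0.2)
  # with RE SD forced near zero the profiled thresholds match the
  # intercept-only closed form
  expect_equal(fit0$tau, fit_thresholds_only(tt0$response, 5),
               tolerance = 0.05)
})

test_that("Laplace is within 0.5 of 50-node quadrature at matched optima", {
  # smaller sweep here; the full 20-dataset sweep runs in the acceptance suite
  for (s in 1:5) {
    des <- simulation_design(n_items = 10, n_participants = NULL,
                             ratings_per_item = 10,
                             sd_mu_item = runif(1, 0.4, 1.5), seed = 80 + s)
    tt <- simulate_items_only(des, sample(all_patterns, 1))
    fit <- quiet_fit(tt, 5, factors = "item")
    gh <- marginal_loglik_quadrature(tt, fit$tau, fit$re_sd[["item"]], 5,
                                     n_nodes = 50)
    expect_lt(abs(fit$loglik - gh), 0.5)
  }
})

test_that("Laplace and quadrature surfaces share their optimum", {
  # maximise the 50-node GH surface directly and compare the argmax with the
  # Laplace fit, parameter by parameter
  for (s in 1:3) {
    des <- simulation_design(n_items = 10, n_participants = NULL,
                             ratings_per_item = 10, seed = 85 + s)
    tt <- simulate_items_only(des, "centre-biased")
    fit <- quiet_fit(tt, 5, factors = "item")
    gh_obj <- function(theta) {
      tau <- cumsum(c(theta[1], exp(theta[2:4])))
      -marginal_loglik_quadrature(tt, tau, exp(theta[5]), 5, n_nodes = 50)
    }
    start <- c(fit$tau[1], log(diff(fit$tau)), log(fit$re_sd[["item"]]))
    opt <- optim(start, gh_obj, method = "BFGS",
                 control = list(reltol = 1e-10))
    tau_gh <- cumsum(c(opt$par[1], exp(opt$par[2:4])))
    expect_true(all(abs(tau_gh - fit$tau) < 0.05))
    expect_lt(abs(exp(opt$par[5]) - fit$re_sd[["item"]]), 0.05)
  }
})

test_that("fit is invariant to row order and recovers Sim-1 structure", {
  tt <- sim1_small(101)
  fit <- quiet_fit(tt, 5, factors = "item")
  set.seed(91)
  perm <- sample(nrow(tt))
  fit_p <- quiet_fit(tt[perm, ], 5, factors = "item")
  expect_equal(fit$tau, fit_p$tau, tolerance = 1e-6)
  expect_equal(ranef(fit, "item")$mode, ranef(fit_p, "item")$mode,
               tolerance = 1e-6)
  # recovery of the simulated item effects (reduced Sim-1 scale)
  truth <- item_truth_vec(tt)
  re <- ranef(fit, "item")
  expect_gte(cor(truth, re$mode[match(names(truth), re$level_id)]), 0.85)
  # modes rank-agree with per-item raw means within one pattern
  raw <- raw_norms(tt)
  expect_gte(cor(re$mode[match(raw$item_id, re$level_id)], raw$raw_mean,
                 method = "spearman"), 0.95)
})

test_that("ranef: extreme items stay finite, shrinkage weakens with data", {
  set.seed(95)
  des <- simulation_design(n_items = 20, n_participants = NULL,
                           ratings_per_item = 25, seed = 95)
  tt <- simulate_items_only(des, "equidistant")
  # force one item to the top of the scale
  ceil_item <- "item_07"
  tt$response[tt$item_id == ceil_item] <- 5L
  fit <- quiet_fit(tt, 5, factors = "item")
  re <- ranef(fit, "item")
  expect_true(all(is.finite(re$mode)))
  expect_equal(re$level_id[which.max(re$mode)], ceil_item)
  expect_error(ranef(fit, "participant"), "not in fit")
  # duplicating every row doubles the information; magnitudes grow
  tt2 <- rbind(tt, tt)
  fit2 <- quiet_fit(tt2, 5, factors = "item")
  re2 <- ranef(fit2, "item")
  m <- match(re$level_id, re2$level_id)
  expect_gte(mean(abs(re2$mode[m]) >= abs(re$mode) - 1e-6), 0.9)
  expect_gt(mean(abs(re2$mode[m])), mean(abs(re$mode)))
})

test_that("unobserved extreme categories clamp thresholds with a warning", {
  set.seed(97)
  des <- simulation_design(n_items = 20, n_participants = NULL,
                           ratings_per_item = 20, seed = 97)
  tt <- simulate_items_only(des, "equidistant")
  tt$response[tt$response == 5L] <- 4L   # empty top category
  expect_warning(fit <- fit_clmm(tt, 5, factors = "item"), "clamped")
  expect_equal(fit$tau[4], 10)
  expect_length(fit$tau, 4L)
  # interior gap is an error
  tt$response[tt$response == 3L] <- 2L
  expect_error(suppressWarnings(fit_clmm(tt, 5, factors = "item")),
               "interior")
})
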