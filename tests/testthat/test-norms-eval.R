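test_that("raw norms: polarised item, sample SD convention, singletons", {
  trials <- data.frame(item_id = c(rep("a", 4), "b"),
                       response = c(1L, 1L, 5L, 5L, 3L))
  nt <- raw_norms(trials)
  expect_equal(nt$raw_mean[nt$item_id == "a"], 3)
  # half 1s, half 5s: SD = sqrt(16/3) ~ 2.309, beyond the >= 2 flag
  expect_equal(nt$raw_sd[nt$item_id == "a"], sqrt(16 / 3))
  expect_gte(nt$raw_sd[nt$item_id == "a"], 2)
  expect_true(is.na(nt$raw_sd[nt$item_id == "b"]))
  expect_equal(nt$n[nt$item_id == "b"], 1L)
  expect_error(raw_norms(trials[0, ]), "empty")
})

test_that("z-score norms: location invariance and exclusions", {
  trials <- data.frame(
    participant_id = rep(c("p1", "p2"), each = 4),
    item_id = rep(c("i1", "i2", "i3", "i4"), 2),
    response = c(1L, 2L, 3L, 4L,   2L, 3L, 4L, 5L))  # p2 = p1 + 1
  nt <- zscore_norms(trials)
  # a constant per-participant shift leaves z-scores identical, so both
  # participants contribute the same values and item z-means are exact
  expect_equal(nt$latent_mean, scale(1:4)[, 1], tolerance = 1e-12)
  # grand mean of item z-means is 0 for complete designs
  expect_equal(mean(nt$latent_mean), 0, tolerance = 1e-12)
  # zero-variance participant is excluded with a warning
  trials2 <- rbind(trials,
                   data.frame(participant_id = "p3",
                              item_id = c("i1", "i2", "i3", "i4"),
                              response = rep(3L, 4)))
  expect_warning(nt2 <- zscore_norms(trials2), "zero-variance")
  expect_equal(nt2$latent_mean, nt$latent_mean)
  expect_error(zscore_norms(trials[, c("item_id", "response")]),
               "participant")
})

test_that("z-score norms stay distorted on biased patterns where CLMM is not", {
  des <- simulation_design(n_items = 40, n_participants = 40,
                           ratings_per_item = 20, items_per_participant = 20,
                           seed = 301)
  tt <- simulate_crossed(des, "edge-biased")
  truth <- item_truth_vec(tt)
  z <- zscore_norms(tt)
  cl <- clmm_norms(tt, 5)
  m_z <- match(names(truth), z$item_id)
  m_c <- match(names(truth), cl$item_id)
  expect_lt(cor(truth, z$latent_mean[m_z]), cor(truth, cl$latent_mean[m_c]))
})

test_that("LMM norms match the classical one-way BLUP closed form", {
  # single participant, balanced items: mode = lambda * (item mean - grand
  # mean) with lambda = n sb^2 / (n sb^2 + s^2), using the ANOVA (= REML,
  # balanced case) variance estimates as an independent oracle
  set.seed(310)
  n_items <- 12; n_per <- 20
  mu_i <- rnorm(n_items, 0, 1.2)
  trials <- data.frame(
    participant_id = "p1",
    item_id = rep(sprintf("i%02d", 1:n_items), each = n_per),
    response = round(pmin(pmax(rep(3 + mu_i, each = n_per) +
                                 rnorm(n_items * n_per, 0, 1), 1), 5)))
  nt <- lmm_norms(trials)
  ybar_i <- tapply(trials$response, trials$item_id, mean)
  ybar <- mean(trials$response)
  msb <- n_per * var(ybar_i)
  msw <- mean(tapply(trials$response, trials$item_id, var))
  sb2 <- max((msb - msw) / n_per, 0)
  lambda <- n_per * sb2 / (n_per * sb2 + msw)
  oracle <- lambda * (ybar_i - ybar)
  expect_equal(nt$latent_mean, as.numeric(oracle[nt$item_id]),
               tolerance = 1e-3)
  # shrinkage: modes never exceed the centred item means in magnitude
  expect_true(all(abs(nt$latent_mean) <=
                    abs(ybar_i[nt$item_id] - ybar) + 1e-9))
  expect_equal(attr(nt, "grand_mean"), ybar, tolerance = 1e-6)
})

test_that("LMM norms collapse to zero without item variance", {
  set.seed(311)
  trials <- data.frame(
    participant_id = rep(sprintf("p%02d", 1:10), each = 8),
    item_id = rep(sprintf("i%02d", 1:8), times = 10),
    response = sample(1:5, 80, replace = TRUE))
  trials$response <- rep(sample(1:5, 10, TRUE), each = 8)  # participant-only
  nt <- lmm_norms(trials)
  expect_true(all(abs(nt$latent_mean) < 0.05))
})

test_that("predict_item_probs delegates to the latent response model", {
  nt <- data.frame(item_id = c("a", "b"), latent_mean = c(0.4, -8),
                   latent_sd = c(1.5, NA))
  ts <- make_pattern("centre-biased")
  expect_equal(predict_item_probs(nt, "a", ts),
               response_probs(0.4, 1.5, ts))
  expect_equal(sum(predict_item_probs(nt, "a", ts)), 1, tolerance = 1e-12)
  # far below the lowest threshold: floor response almost surely
  expect_gte(predict_item_probs(nt, "b", ts)[1], 0.99)
  expect_error(predict_item_probs(nt, "c", ts), "not found")
})

test_that("recovery_error: identity, scaling invariance, hand-computed case", {
  tr <- c(a = 0, b = 1, c = 2)
  expect_equal(recovery_error(tr, tr)$errors, tr - tr)
  est <- c(a = 0, b = 2, c = 4)
  un <- recovery_error(tr, est)
  expect_equal(unname(un$errors), c(0, -1, -2))
  sc <- recovery_error(tr, est, scaled = TRUE)
  expect_equal(unname(sc$errors), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(recovery_error(tr, est * 7.3, scaled = TRUE)$error_sd,
               sc$error_sd)
  expect_error(recovery_error(tr, est[1:2]), "differ")
})

test_that("split-half: degenerate splits, granularity, exclusions", {
  # every row within an item identical: any split gives equal halves
  trials <- data.frame(item_id = rep(sprintf("i%d", 1:6), each = 4),
                       response = rep(c(1L, 2L, 3L, 4L, 5L, 3L), each = 4))
  rep1 <- split_half_consistency(trials, 5, n_iterations = 3,
                                 methods = "raw", seed = 320)
  expect_true(all(rep1$differences$diff == 0))
  # raw-mean differences live on a finite lattice
  set.seed(321)
  trials2 <- data.frame(item_id = rep(sprintf("i%d", 1:10), each = 6),
                        response = sample(1:5, 60, replace = TRUE))
  rep2 <- split_half_consistency(trials2, 5, n_iterations = 10,
                                 methods = "raw", seed = 322)
  raw_d <- rep2$differences$est_a - rep2$differences$est_b
  # means of 3 integers differ by multiples of 1/3
  expect_true(all(abs(raw_d * 3 - round(raw_d * 3)) < 1e-9))
  # under-sampled items are dropped with a warning
  trials3 <- rbind(trials2, data.frame(item_id = "lonely", response = 3L))
  expect_warning(split_half_consistency(trials3, 5, n_iterations = 2,
                                        methods = "raw", seed = 323),
                 "excluded")
  expect_error(split_half_consistency(trials2, 5, methods = "bogus"),
               "unknown method")
})

test_that("experiment runner produces structured reports at small scale", {
  # tiny designs legitimately warn about unobserved extreme categories
  rep1 <- suppressWarnings(run_experiment("1", scale = 0.03, seed = 330))
  expect_s3_class(rep1, "evaluation_report")
  expect_setequal(unique(rep1$results$pattern), all_patterns)
  expect_true(all(rep1$results$r_clmm > 0.5))
  expect_equal(rep1$seed, 330)
  # extreme grid cells legitimately warn about unobserved categories
  rep2b <- suppressWarnings(run_experiment("2b", scale = 0.03, seed = 331))
  expect_true(all(c("sd_item", "sd_participant", "accuracy_gain") %in%
                    names(rep2b$grid_summary)))
  expect_error(run_experiment("1", scale = 0), "scale")
  expect_error(run_experiment("9"), "arg")
})
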