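test_that("allocation is balanced and duplicate-free across designs", {
  set.seed(5)
  designs <- list(c(100, 100, 25), c(20, 20, 5), c(12, 36, 4), c(30, 15, 8))
  for (d in designs) {
    a <- allocate_raters(d[1], d[2], d[3])
    expect_equal(nrow(a), d[2] * d[3])
    expect_true(all(table(a$participant) == d[3]))
    expect_true(all(table(a$item) == d[2] * d[3] / d[1]))
    expect_equal(anyDuplicated(a[, c("participant", "item")]), 0L)
    # no participant rates an item twice
    expect_true(all(tapply(a$item, a$participant,
                           function(x) !anyDuplicated(x))))
  }
  expect_error(allocate_raters(7, 5, 3), "divisible|infeasible")
  # complete design: one participant rating everything once
  a1 <- allocate_raters(10, 1, 10)
  expect_setequal(a1$item, 1:10)
})

test_that("items-only generator has the stated structure and moments", {
  des <- simulation_design(n_items = 100, n_participants = NULL,
                           ratings_per_item = 25, seed = 31)
  tt <- simulate_items_only(des, "equidistant")
  expect_equal(nrow(tt), 2500L)
  expect_equal(length(unique(tt$item_id)), 100L)
  expect_true(all(table(tt$item_id) == 25L))
  # unit item variance + unit residual variance => pooled latent SD ~ sqrt(2)
  expect_equal(sd(tt$latent), sqrt(2), tolerance = 0.05 * sqrt(2))
  # responses are exact recodings of the stored latent truth
  expect_identical(tt$response, recode_latent(tt$latent, "equidistant"))
  # zero residual SD: all of an item's responses identical
  des0 <- simulation_design(n_items = 10, n_participants = NULL,
                            ratings_per_item = 25,
                            residual_dist = dist_spec("normal", sd = 0),
                            seed = 32)
  tt0 <- simulate_items_only(des0, "edge-biased")
  expect_true(all(tapply(tt0$response, tt0$item_id,
                         function(x) length(unique(x)) == 1L)))
})

test_that("generation is byte-identical under a repeated seed", {
  des <- simulation_design(n_items = 20, n_participants = 20,
                           ratings_per_item = 5, items_per_participant = 5,
                           seed = 77)
  expect_identical(simulate_crossed(des, "centre-biased"),
                   simulate_crossed(des, "centre-biased"))
})

test_that("crossed generator: latent SD algebra and reduction to equal variance", {
  # sigma_ij = 1/exp(disc_i + disc_j); zero disc SDs give sigma = 1 exactly
  des <- simulation_design(n_items = 20, n_participants = 20,
                           ratings_per_item = 10, items_per_participant = 10,
                           seed = 41)
  tt <- simulate_crossed(des, "equidistant")
  expect_true(all(tt$sigma == 1))
  expect_identical(tt$response, recode_latent(tt$latent, "equidistant"))
  des3 <- simulation_design(n_items = 20, n_participants = 20,
                            ratings_per_item = 10, items_per_participant = 10,
                            sd_disc_item = 0.5, sd_disc_participant = 0.5,
                            seed = 42)
  tt3 <- simulate_crossed(des3, "equidistant")
  expect_equal(tt3$sigma, 1 / exp(tt3$disc_item + tt3$disc_participant))
  # disc_i = -ln 8 makes that item's latent SD exactly 8
  expect_equal(1 / exp(-log(8) + 0), 8)
  # distributional reduction: zero-disc Sim-3 generator matches the
  # equal-variance generator in distribution (KS on latents)
  # near-independent trials (each random effect shared by only 4 rows) so
  # the two-sample KS test is approximately valid despite the clustering
  big <- simulation_design(n_items = 2500, n_participants = 2500,
                           ratings_per_item = 4, items_per_participant = 4,
                           seed = 43)
  l_equal <- simulate_crossed(big, "equidistant")$latent
  big$seed <- 44
  big$sd_disc_item <- 0; big$sd_disc_participant <- 0
  l_disc0 <- simulate_crossed(big, "equidistant")$latent
  expect_gt(suppressWarnings(stats::ks.test(l_equal, l_disc0)$p.value), 0.01)
})

test_that("non-normal variants use the fixed parameterisations", {
  des <- function(s) simulation_design(n_items = 100, n_participants = 100,
                                       ratings_per_item = 25,
                                       items_per_participant = 25, seed = s)
  # normal variant reproduces the crossed generator exactly
  expect_identical(simulate_nonnormal(des(51), "latent_residual", "normal"),
                   simulate_crossed(des(51), "edge-biased"))
  expect_identical(simulate_nonnormal(des(52), "item_re", "normal",
                                      pattern = "edge-biased"),
                   simulate_crossed(des(52), "edge-biased"))
  # mixture moments: mean 0, SD sqrt(1.5^2 + 0.75^2)
  set.seed(53)
  bim <- dist_spec("bimodal")$sample(1e5)
  expect_lt(abs(mean(bim)), 0.02)
  expect_equal(sd(bim), sqrt(1.5^2 + 0.75^2),
               tolerance = 0.02)
  set.seed(54)
  unif <- dist_spec("uniform")$sample(1e5)
  expect_true(all(unif >= -2 & unif <= 2))
  set.seed(55)
  hn <- dist_spec("halfnormal")$sample(1e5)
  expect_true(all(hn >= 0))
  expect_equal(mean(hn), sqrt(2 / pi), tolerance = 0.01)
  expect_error(simulate_nonnormal(des(56), "item_re", "poisson"), "arg")
})

test_that("trial tables always recode their stored latent truth", {
  set.seed(61)
  for (i in 1:5) {
    p <- sample(all_patterns, 1)
    des <- simulation_design(n_items = 12, n_participants = 12,
                             ratings_per_item = 6, items_per_participant = 6,
                             sd_disc_item = runif(1, 0, .5),
                             sd_disc_participant = runif(1, 0, .5),
                             seed = 500 + i)
    tt <- simulate_crossed(des, p)
    expect_identical(tt$response, recode_latent(tt$latent, p))
    expect_true(all(tt$response %in% 1:5))
  }
})
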