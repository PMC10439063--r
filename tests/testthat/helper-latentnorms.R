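# shared fixtures, built in code and cached for the session
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

all_patterns <- c("equidistant", "left-biased", "right-biased",
                  "edge-biased", "centre-biased")

# small items-only dataset used by several clmm tests
sim1_small <- function(seed = 101, pattern = "edge-biased") {
  cached(paste0("sim1_", seed, "_", pattern), {
    simulate_items_only(
      simulation_design(n_items = 50, n_participants = NULL,
                        ratings_per_item = 25, seed = seed),
      pattern)
  })
}

item_truth_vec <- function(tt, col = "mu_item") {
  u <- unique(tt[, c("item_id", col)])
  stats::setNames(u[[col]], u$item_id)
}

quiet_fit <- function(...) suppressWarnings(fit_clmm(...))
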