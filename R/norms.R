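norm_table_columns <- c("item_id", "n", "raw_mean", "raw_sd",
                        "latent_mean", "latent_mean_lo", "latent_mean_hi",
                        "latent_sd", "latent_sd_lo", "latent_sd_hi", "method")

new_norm_table <- function(item_id, n, raw_mean, raw_sd,
                           latent_mean = NA_real_,
                           latent_mean_lo = NA_real_,
                           latent_mean_hi = NA_real_,
                           latent_sd = NA_real_, latent_sd_lo = NA_real_,
                           latent_sd_hi = NA_real_, method) {
  out <- data.frame(item_id = item_id, n = n, raw_mean = raw_mean,
                    raw_sd = raw_sd, latent_mean = latent_mean,
                    latent_mean_lo = latent_mean_lo,
                    latent_mean_hi = latent_mean_hi,
                    latent_sd = latent_sd, latent_sd_lo = latent_sd_lo,
                    latent_sd_hi = latent_sd_hi, method = method,
                    stringsAsFactors = FALSE)
  out <- out[order(out$item_id), ]
  rownames(out) <- NULL
  out
}

#' Traditional per-item norms: raw means and SDs
#'
#' The conventional summary of a norming study: each item's arithmetic mean
#' rating, sample SD (n - 1 denominator) and rating count. These are the
#' quantities that nonlinear response patterns distort; they are computed
#' here both as a baseline method and for reporting alongside latent norms.
#'
#' @param trials Trial table with \code{item_id} and \code{response}.
#' @return A norm table with \code{method = "raw"}; items with a single
#'   rating get \code{NA} SD.
#' @export
raw_norms <- function(trials) {
  if (nrow(trials) == 0L) stop("empty trial table")
  sp <- split(as.numeric(trials$response), as.character(trials$item_id))
  new_norm_table(
    item_id = names(sp),
    n = vapply(sp, length, integer(1)),
    raw_mean = vapply(sp, mean, numeric(1)),
    raw_sd = vapply(sp, function(v)
      if (length(v) > 1L) stats::sd(v) else NA_real_, numeric(1)),
    method = "raw")
}

#' Per-item norms from within-participant z-scores
#'
#' Standardises each participant's responses (mean 0, sample SD 1) before
#' averaging by item. This removes per-participant location and scale
#' differences, but still treats the ordinal scale as interval, so
#' nonlinear response patterns distort it in the same way as raw means.
#' Participants with zero response variance carry no ranking information
#' and are excluded with a warning.
#'
#' @param trials Trial table with \code{participant_id}, \code{item_id},
#'   \code{response}.
#' @return A norm table with the z-based mean in \code{latent_mean} (it is
#'   not a latent-scale quantity, but fills the estimate slot for
#'   comparability) and \code{method = "zscore"}.
#' @export
zscore_norms <- function(trials) {
  if (!"participant_id" %in% names(trials))
    stop("z-scoring requires participant ids")
  resp <- as.numeric(trials$response)
  pid <- as.character(trials$participant_id)
  p_mean <- tapply(resp, pid, mean)
  p_sd <- tapply(resp, pid, stats::sd)
  zero <- names(p_sd)[is.na(p_sd) | p_sd == 0]
  if (length(zero)) {
    warning(length(zero), " zero-variance participant(s) excluded from ",
            "z-score norms")
    keep <- !pid %in% zero
    trials <- trials[keep, , drop = FALSE]
    resp <- resp[keep]; pid <- pid[keep]
  }
  z <- (resp - p_mean[pid]) / p_sd[pid]
  raw <- raw_norms(trials)
  zmean <- tapply(z, as.character(trials$item_id), mean)
  raw$latent_mean <- as.numeric(zmean[raw$item_id])
  raw$method <- "zscore"
  raw
}

#' Per-item norms from a Gaussian linear mixed model
#'
#' Fits \code{response ~ 1 + (1 | item) [+ (1 | participant)]} with a
#' Gaussian identity link on the raw 1..K responses and reports the
#' conditional modes (BLUPs) of the item intercepts. This shares the random
#' effect structure and shrinkage of the CLMM but still treats the scale as
#' interval; it isolates the contribution of ordinality when compared
#' against CLMM norms. The participant intercept is included whenever more
#' than one participant is present.
#'
#' @param trials Trial table.
#' @return A norm table with \code{method = "lmm"}; the fitted grand mean is
#'   attached as attribute \code{"grand_mean"}.
#' @export
lmm_norms <- function(trials) {
  df <- data.frame(response = as.numeric(trials$response),
                   item_id = factor(trials$item_id))
  has_part <- "participant_id" %in% names(trials) &&
    length(unique(trials$participant_id)) > 1L
  if (has_part) {
    df$participant_id <- factor(trials$participant_id)
    form <- response ~ 1 + (1 | item_id) + (1 | participant_id)
  } else {
    form <- response ~ 1 + (1 | item_id)
  }
  fit <- lme4::lmer(form, data = df, REML = TRUE,
                    control = lme4::lmerControl(calc.derivs = FALSE,
                                                check.conv.singular =
                                                  lme4::.makeCC("ignore", 1e-4)))
  re <- lme4::ranef(fit, condVar = TRUE)$item_id
  cv <- sqrt(as.numeric(attr(re, "postVar")))
  raw <- raw_norms(trials)
  m <- match(raw$item_id, rownames(re))
  raw$latent_mean <- re[m, 1L]
  raw$latent_mean_lo <- re[m, 1L] - cv[m]
  raw$latent_mean_hi <- re[m, 1L] + cv[m]
  raw$method <- "lmm"
  attr(raw, "grand_mean") <- unname(lme4::fixef(fit)[1L])
  raw
}

#' CLMM maximum-likelihood norms as a norm table
#'
#' Convenience wrapper: fits \code{\link{fit_clmm}} and formats the item
#' conditional modes (with +/- one conditional SD as the uncertainty band)
#' as a norm table with \code{method = "clmm_ml"}.
#'
#' @param trials Trial table.
#' @param n_levels Declared number of response categories.
#' @param factors Random-intercept factors (see \code{\link{fit_clmm}}).
#' @param ... Passed to \code{\link{fit_clmm}}.
#' @export
clmm_norms <- function(trials, n_levels,
                       factors = c("item", "participant"), ...) {
  factors <- intersect(factors,
    c("item", if ("participant_id" %in% names(trials)) "participant"))
  fit <- fit_clmm(trials, n_levels, factors = factors, ...)
  re <- ranef(fit, "item")
  raw <- raw_norms(trials)
  m <- match(raw$item_id, re$level_id)
  raw$latent_mean <- re$mode[m]
  raw$latent_mean_lo <- re$mode[m] - re$cond_sd[m]
  raw$latent_mean_hi <- re$mode[m] + re$cond_sd[m]
  raw$method <- "clmm_ml"
  attr(raw, "fit") <- fit
  raw
}

#' Predict response probabilities for a normed item
#'
#' With latent mean, latent SD and threshold estimates in hand, the full
#' probability distribution over Likert responses for an item follows from
#' the latent model: the chance of each response is the latent mass falling
#' in its threshold region.
#'
#' @param norms A norm table containing \code{latent_mean} (and optionally
#'   \code{latent_sd}; 1 assumed where missing).
#' @param item_id Item to predict.
#' @param thresholds A \code{\link{threshold_set}} (e.g. fitted \code{tau}
#'   wrapped with \code{threshold_set()}).
#' @param link Link function or name.
#' @return Probability vector of length K.
#' @export
predict_item_probs <- function(norms, item_id, thresholds, link = "probit") {
  row <- norms[norms$item_id == item_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("item not found (or duplicated): ", item_id)
  if (is.na(row$latent_mean)) stop("no latent mean estimate for ", item_id)
  sd <- if (!is.null(row$latent_sd) && !is.na(row$latent_sd))
    row$latent_sd else 1
  response_probs(row$latent_mean, sd, thresholds, link)
}

#' Recovery error between true and estimated per-item values
#'
#' \code{error_i = truth_i - estimate_i}. With \code{scaled = TRUE}, both
#' vectors are first divided by their own SDs across items, so the
#' comparison is invariant to the overall magnitude of the estimates
#' (shrinkage compresses conditional modes relative to the truth).
#'
#' @param truth Named numeric vector (names = item ids) of true values.
#' @param estimates Named numeric vector of estimates for the same items.
#' @param scaled Standardise both vectors first?
#' @return List with \code{errors} (named vector, truth order) and
#'   \code{error_sd}.
#' @export
recovery_error <- function(truth, estimates, scaled = FALSE) {
  if (is.null(names(truth)) || is.null(names(estimates)))
    stop("truth and estimates must be named by item id")
  if (!setequal(names(truth), names(estimates)))
    stop("item sets of truth and estimates differ")
  est <- estimates[names(truth)]
  if (scaled) {
    truth <- truth / stats::sd(truth)
    est <- est / stats::sd(est)
  }
  err <- truth - est
  list(errors = err, error_sd = stats::sd(err))
}

#' Split-half consistency of norming methods
#'
#' Repeatedly splits each item's trials at random into two halves, norms
#' both halves independently with each method, and pools the between-half
#' differences of per-item estimates over iterations. For comparability
#' across methods with different scales, each method's estimates are
#' standardised by the SD of its estimates pooled over both halves before
#' differencing. Methods whose norms are more stable across samples produce
#' narrower difference distributions.
#'
#' When an item has an odd number of trials the extra trial goes to half A
#' for odd item indices and half B for even ones.
#'
#' @param trials Trial table.
#' @param n_levels Declared K (needed for CLMM methods).
#' @param n_iterations Number of random splits.
#' @param methods Character subset of \code{c("raw", "zscore", "lmm",
#'   "clmm_ml")}.
#' @param seed Integer seed.
#' @return Object of class \code{"split_half_report"}: \code{differences}
#'   (long data.frame: iteration, method, item_id, diff (standardised
#'   A - B), est_a, est_b), \code{sd_by_method}, and the call's seeds.
#' @export
split_half_consistency <- function(trials, n_levels, n_iterations = 20L,
                                   methods = c("raw", "clmm_ml"),
                                   seed = 1L) {
  known <- c("raw", "zscore", "lmm", "clmm_ml")
  if (!all(methods %in% known))
    stop("unknown method(s): ", paste(setdiff(methods, known), collapse = ", "))
  counts <- table(trials$item_id)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning(length(small), " item(s) with < 2 ratings excluded from ",
            "split-half analysis")
    trials <- trials[!trials$item_id %in% small, , drop = FALSE]
  }
  norm_one <- function(half) {
    lapply(stats::setNames(methods, methods), function(m) {
      nt <- switch(m,
                   raw = raw_norms(half),
                   zscore = zscore_norms(half),
                   lmm = lmm_norms(half),
                   clmm_ml = clmm_norms(half, n_levels))
      est <- if (m == "raw") nt$raw_mean else nt$latent_mean
      stats::setNames(est, nt$item_id)
    })
  }
  items <- sort(unique(as.character(trials$item_id)))
  rows <- list()
  for (it in seq_len(n_iterations)) {
    set.seed(seed + 7919L * it)
    in_a <- logical(nrow(trials))
    for (ii in seq_along(items)) {
      rows_i <- which(trials$item_id == items[ii])
      n_i <- length(rows_i)
      n_a <- n_i %/% 2L + (n_i %% 2L) * (ii %% 2L)
      in_a[sample(rows_i, n_a)] <- TRUE
    }
    est_a <- norm_one(trials[in_a, , drop = FALSE])
    est_b <- norm_one(trials[!in_a, , drop = FALSE])
    for (m in methods) {
      common <- intersect(names(est_a[[m]]), names(est_b[[m]]))
      pooled_sd <- stats::sd(c(est_a[[m]][common], est_b[[m]][common]))
      rows[[length(rows) + 1L]] <- data.frame(
        iteration = it, method = m, item_id = common,
        est_a = unname(est_a[[m]][common]),
        est_b = unname(est_b[[m]][common]),
        diff = unname(est_a[[m]][common] - est_b[[m]][common]) / pooled_sd,
        stringsAsFactors = FALSE)
    }
  }
  differences <- do.call(rbind, rows)
  sd_by_method <- tapply(differences$diff, differences$method, stats::sd)
  structure(list(differences = differences,
                 sd_by_method = sd_by_method,
                 methods = methods, n_iterations = n_iterations,
                 seed = seed),
            class = "split_half_report")
}

#' @export
print.split_half_report <- function(x, ...) {
  cat(sprintf("<split_half_report> %d iterations, methods: %s\n",
              x$n_iterations, paste(x$methods, collapse = ", ")))
  cat("SD of standardised between-half differences:\n")
  print(round(x$sd_by_method, 4))
  invisible(x)
}

#' Run a complete simulation experiment
#'
#' Orchestrates the simulation studies at a configurable scale. At
#' \code{scale = 1} the designs match the reference settings (100 items x
#' 100 participants x 25 ratings; 100 iterations for the main studies, 250
#' for the robustness studies, a .25-to-5-in-.25-steps SD grid with 50
#' iterations per cell for the allocation study). Iteration counts, item
#' and participant numbers and the grid resolution shrink proportionally at
#' smaller scales (with sensible floors), which is how the full designs fit
#' in test budgets.
#'
#' @param sim_id One of \code{"1"}, \code{"2"}, \code{"2b"}, \code{"3"},
#'   \code{"4a"}, \code{"4b"}.
#' @param scale Fraction of the full design in (0, 1].
#' @param seed Integer seed.
#' @param patterns Patterns to run where the study sweeps patterns.
#' @return A list of class \code{"evaluation_report"} whose shape depends
#'   on the study; all entries carry the seeds used.
#' @export
run_experiment <- function(sim_id = c("1", "2", "2b", "3", "4a", "4b"),
                           scale = 0.1, seed = 1L,
                           patterns = names_of_patterns()) {
  sim_id <- match.arg(as.character(sim_id), c("1", "2", "2b", "3", "4a", "4b"))
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  sc <- function(full, floor_at) max(floor_at, round(full * scale))
  out <- switch(
    sim_id,
    "1" = run_sim1(sc(100, 3), patterns, seed, n_items = sc(100, 20)),
    "2" = run_sim2(sc(100, 3), patterns, seed,
                   n_items = sc(100, 20), n_participants = sc(100, 20)),
    "2b" = run_sim2b(iterations = sc(50, 2), seed = seed,
                     grid = if (scale >= 1) seq(0.25, 5, by = 0.25)
                            else c(0.25, 1, 2, 5),
                     n_items = sc(100, 20), n_participants = sc(100, 20)),
    "3" = run_sim3(sc(100, 1), patterns, seed,
                   n_items = sc(100, 20), n_participants = sc(100, 20)),
    "4a" = run_sim4(sc(250, 2), seed, target = "latent_residual",
                    n_items = sc(100, 20), n_participants = sc(100, 20)),
    "4b" = run_sim4(sc(250, 2), seed, target = "item_re",
                    n_items = sc(100, 20), n_participants = sc(100, 20)))
  out$sim_id <- sim_id
  out$scale <- scale
  out$seed <- seed
  class(out) <- "evaluation_report"
  out
}

names_of_patterns <- function() names(.pattern_registry)

item_truth <- function(tt, col = "mu_item") {
  u <- unique(tt[, c("item_id", col)])
  stats::setNames(u[[col]], u$item_id)
}

sub_seed <- function(seed, a, b = 0L) {
  (as.integer(seed) * 7L + a * 1009L + b * 613L) %% 2000000011L
}

run_sim1 <- function(iterations, patterns, seed, n_items) {
  res <- list()
  for (it in seq_len(iterations)) {
    des <- simulation_design(n_items = n_items, n_participants = NULL,
                             ratings_per_item = 25,
                             seed = sub_seed(seed, it))
    base <- simulate_items_only(des, "equidistant")
    for (p in patterns) {
      tt <- base
      tt$response <- recode_latent(tt$latent, make_pattern(p))
      nt <- clmm_norms(tt, 5, factors = "item")
      truth <- item_truth(tt)
      res[[length(res) + 1L]] <- data.frame(
        iteration = it, pattern = p,
        r_clmm = stats::cor(truth, nt$latent_mean[match(names(truth), nt$item_id)]),
        r_raw = stats::cor(truth, nt$raw_mean[match(names(truth), nt$item_id)]),
        stringsAsFactors = FALSE)
    }
  }
  list(results = do.call(rbind, res))
}

run_sim2 <- function(iterations, patterns, seed, n_items, n_participants) {
  res <- list()
  for (it in seq_len(iterations)) {
    des <- simulation_design(n_items = n_items,
                             n_participants = n_participants,
                             ratings_per_item = n_participants %/% 4,
                             items_per_participant = n_items %/% 4,
                             seed = sub_seed(seed, it))
    base <- simulate_crossed(des, "equidistant")
    for (p in patterns) {
      tt <- base
      tt$response <- recode_latent(tt$latent, make_pattern(p))
      truth <- item_truth(tt)
      nt_i <- clmm_norms(tt, 5, factors = "item")
      nt_ip <- clmm_norms(tt, 5, factors = c("item", "participant"))
      e_i <- recovery_error(truth, stats::setNames(nt_i$latent_mean,
                                                   nt_i$item_id), scaled = TRUE)
      e_ip <- recovery_error(truth, stats::setNames(nt_ip$latent_mean,
                                                    nt_ip$item_id), scaled = TRUE)
      res[[length(res) + 1L]] <- data.frame(
        iteration = it, pattern = p,
        error_sd_item_only = e_i$error_sd,
        error_sd_item_participant = e_ip$error_sd,
        stringsAsFactors = FALSE)
    }
  }
  list(results = do.call(rbind, res))
}

run_sim2b <- function(iterations, seed, grid, n_items, n_participants) {
  res <- list()
  for (sd_i in grid) for (sd_j in grid) {
    for (it in seq_len(iterations)) {
      des <- simulation_design(n_items = n_items,
                               n_participants = n_participants,
                               ratings_per_item = n_participants %/% 4,
                               items_per_participant = n_items %/% 4,
                               sd_mu_item = sd_i, sd_mu_participant = sd_j,
                               seed = sub_seed(seed, it,
                                               round(100 * (sd_i + 31 * sd_j))))
      tt <- simulate_crossed(des, "edge-biased")
      truth <- item_truth(tt)
      nt_i <- clmm_norms(tt, 5, factors = "item")
      nt_ip <- clmm_norms(tt, 5, factors = c("item", "participant"))
      e_i <- recovery_error(truth, stats::setNames(nt_i$latent_mean,
                                                   nt_i$item_id), scaled = TRUE)
      e_ip <- recovery_error(truth, stats::setNames(nt_ip$latent_mean,
                                                    nt_ip$item_id), scaled = TRUE)
      res[[length(res) + 1L]] <- data.frame(
        sd_item = sd_i, sd_participant = sd_j, iteration = it,
        error_sd_item_only = e_i$error_sd,
        error_sd_item_participant = e_ip$error_sd,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, res)
  agg <- stats::aggregate(
    cbind(error_sd_item_only, error_sd_item_participant) ~
      sd_item + sd_participant, data = tab, FUN = mean)
  agg$accuracy_gain <- agg$error_sd_item_only - agg$error_sd_item_participant
  list(results = tab, grid_summary = agg)
}

run_sim3 <- function(iterations, patterns, seed, n_items, n_participants) {
  res <- list()
  for (it in seq_len(iterations)) {
    des <- simulation_design(n_items = n_items,
                             n_participants = n_participants,
                             ratings_per_item = n_participants %/% 4,
                             items_per_participant = n_items %/% 4,
                             sd_disc_item = 0.5, sd_disc_participant = 0.5,
                             seed = sub_seed(seed, it))
    base <- simulate_crossed(des, "equidistant")
    for (p in patterns) {
      tt <- base
      tt$response <- recode_latent(tt$latent, make_pattern(p))
      fit <- fit_distributional(
        tt, distributional_spec(seed = sub_seed(seed, it, match(p, patterns))),
        on_nonconvergence = "warn")
      nt <- summarize_posterior_norms(fit)
      truth_mu <- item_truth(tt)
      truth_sd <- 1 / exp(item_truth(tt, "disc_item"))
      m <- match(names(truth_mu), nt$item_id)
      res[[length(res) + 1L]] <- data.frame(
        iteration = it, pattern = p,
        r_mu = stats::cor(truth_mu, nt$latent_mean[m]),
        r_sd_rank = stats::cor(truth_sd, nt$latent_sd[m], method = "spearman"),
        stringsAsFactors = FALSE)
    }
  }
  list(results = do.call(rbind, res))
}

run_sim4 <- function(iterations, seed, target, n_items, n_participants) {
  dists <- c("normal", "logistic", "uniform", "bimodal", "halfnormal")
  res <- list()
  for (dist in dists) for (it in seq_len(iterations)) {
    des <- simulation_design(n_items = n_items,
                             n_participants = n_participants,
                             ratings_per_item = n_participants %/% 4,
                             items_per_participant = n_items %/% 4,
                             seed = sub_seed(seed, it, match(dist, dists)))
    tt <- simulate_nonnormal(des, target = target, dist = dist,
                             pattern = "edge-biased")
    truth <- item_truth(tt)
    nt <- clmm_norms(tt, 5)
    m <- match(names(truth), nt$item_id)
    res[[length(res) + 1L]] <- data.frame(
      dist = dist, iteration = it,
      r_clmm = stats::cor(truth, nt$latent_mean[m]),
      r_raw = stats::cor(truth, nt$raw_mean[m]),
      stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, res))
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> simulation %s at scale %.2f (seed %d)\n",
              x$sim_id, x$scale, x$seed))
  utils::str(x$results, max.level = 1)
  invisible(x)
}
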