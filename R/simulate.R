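#' Distribution specifications for simulation components
#'
#' The generators draw random-effect and residual components from a small
#' fixed menu of distributions. Parameters are fixed to the values used in
#' the robustness simulations: \code{logistic} has location 0 and scale 1;
#' \code{uniform} ranges over [-2, 2]; \code{bimodal} is an equal mixture of
#' Normal(-1.5, 0.75) and Normal(1.5, 0.75); \code{halfnormal} is |Z| for
#' Z ~ Normal(0, 1) (not recentred). \code{normal} takes a free \code{sd}.
#'
#' @param name Distribution name.
#' @param sd Standard deviation, used by \code{name = "normal"} only.
#' @return An object of class \code{"dist_spec"} with a \code{sample(n)}
#'   function.
#' @export
dist_spec <- function(name = c("normal", "logistic", "uniform", "bimodal",
                               "halfnormal"), sd = 1) {
  name <- match.arg(name)
  sampler <- switch(name,
    normal     = function(n) stats::rnorm(n, 0, sd),
    logistic   = function(n) stats::rlogis(n, 0, 1),
    uniform    = function(n) stats::runif(n, -2, 2),
    bimodal    = function(n) {
      side <- stats::runif(n) < 0.5
      stats::rnorm(n, ifelse(side, -1.5, 1.5), 0.75)
    },
    halfnormal = function(n) abs(stats::rnorm(n, 0, 1))
  )
  structure(list(name = name, sd = if (name == "normal") sd else NA_real_,
                 sample = sampler),
            class = "dist_spec")
}

as_dist <- function(x, sd = 1) {
  if (inherits(x, "dist_spec")) return(x)
  dist_spec(x, sd = sd)
}

#' Simulation design for trial-level rating data
#'
#' Describes a norming-study-like design: \code{n_items} items each receiving
#' \code{ratings_per_item} ratings; optionally \code{n_participants} raters
#' who each rate \code{items_per_participant} items (each item at most once
#' per participant). Latent values are built from item effects mu_i
#' (SD \code{sd_mu_item}), participant effects mu_j (SD
#' \code{sd_mu_participant}), and a residual. Discrimination effects disc_i,
#' disc_j (SDs \code{sd_disc_item}, \code{sd_disc_participant}) act on the
#' latent SD as \code{sigma_ij = 1 / exp(disc_i + disc_j)}.
#'
#' Defaults mirror the reference crossed design: 100 items x 100
#' participants, 25 ratings per item, 25 items per participant, all mean
#' SDs 1, no discrimination variance.
#'
#' @param n_items Number of items.
#' @param n_participants Number of participants, or \code{NULL} for an
#'   items-only design.
#' @param ratings_per_item Ratings per item.
#' @param items_per_participant Items rated by each participant (crossed
#'   designs only). Must satisfy
#'   \code{n_participants * items_per_participant ==
#'   n_items * ratings_per_item}.
#' @param sd_mu_item,sd_mu_participant SDs of the latent-mean random effects.
#' @param sd_disc_item,sd_disc_participant SDs of the log-discrimination
#'   random effects.
#' @param residual_dist Residual distribution (\code{\link{dist_spec}} or
#'   name); default standard normal.
#' @param item_re_dist Distribution of mu_i; default Normal(0, sd_mu_item).
#' @param seed Integer seed; required for reproducible generation.
#' @return An object of class \code{"simulation_design"}.
#' @export
simulation_design <- function(n_items = 100L, n_participants = 100L,
                              ratings_per_item = 25L,
                              items_per_participant = 25L,
                              sd_mu_item = 1, sd_mu_participant = 1,
                              sd_disc_item = 0, sd_disc_participant = 0,
                              residual_dist = dist_spec("normal"),
                              item_re_dist = NULL,
                              seed = NULL) {
  if (n_items < 1 || ratings_per_item < 1) stop("invalid design size")
  sds <- c(sd_mu_item, sd_mu_participant, sd_disc_item, sd_disc_participant)
  if (any(sds < 0)) stop("random-effect SDs must be >= 0")
  if (!is.null(n_participants)) {
    if (n_participants * items_per_participant !=
        n_items * ratings_per_item)
      stop("infeasible design: n_participants * items_per_participant must ",
           "equal n_items * ratings_per_item")
  }
  structure(
    list(n_items = as.integer(n_items),
         n_participants = if (is.null(n_participants)) NULL else
           as.integer(n_participants),
         ratings_per_item = as.integer(ratings_per_item),
         items_per_participant = if (is.null(n_participants)) NULL else
           as.integer(items_per_participant),
         sd_mu_item = sd_mu_item, sd_mu_participant = sd_mu_participant,
         sd_disc_item = sd_disc_item,
         sd_disc_participant = sd_disc_participant,
         residual_dist = as_dist(residual_dist),
         item_re_dist = if (is.null(item_re_dist)) NULL else
           as_dist(item_re_dist, sd = sd_mu_item),
         seed = seed),
    class = "simulation_design"
  )
}

pad_ids <- function(prefix, n) sprintf("%s_%0*d", prefix, nchar(n), seq_len(n))

#' Allocate participants to items pseudo-randomly
#'
#' Builds a balanced incomplete assignment in which every participant rates
#' \code{items_per_participant} distinct items and every item is rated
#' exactly \code{n_participants * items_per_participant / n_items} times.
#' Random permutations of the item list are concatenated and chunked into
#' participant blocks; blocks containing a duplicate item are repaired by
#' swapping with other blocks (deterministic given the RNG state).
#'
#' @param n_items,n_participants,items_per_participant Design dimensions;
#'   \code{n_participants * items_per_participant} must be divisible by
#'   \code{n_items}.
#' @return A data.frame with columns \code{participant} (integer index),
#'   \code{item} (integer index), one row per rating.
#' @export
allocate_raters <- function(n_items, n_participants, items_per_participant) {
  total <- n_participants * items_per_participant
  if (total %% n_items != 0)
    stop("infeasible allocation: total ratings not divisible by n_items")
  if (items_per_participant > n_items)
    stop("items_per_participant cannot exceed n_items")
  reps <- total %/% n_items
  # concatenated random permutations guarantee per-item balance
  pool <- as.vector(vapply(seq_len(reps), function(i) sample.int(n_items),
                           integer(n_items)))
  blocks <- matrix(pool, nrow = items_per_participant)
  # repair within-participant duplicates by swapping entries across blocks
  for (j in seq_len(ncol(blocks))) {
    tries <- 0L
    while (anyDuplicated(blocks[, j]) && tries < 1000L) {
      d <- which(duplicated(blocks[, j]))[1L]
      val <- blocks[d, j]
      done <- FALSE
      for (j2 in seq_len(ncol(blocks))) {
        if (j2 == j) next
        for (d2 in seq_len(nrow(blocks))) {
          cand <- blocks[d2, j2]
          if (cand != val && !(cand %in% blocks[, j]) &&
              !(val %in% blocks[, j2])) {
            blocks[d, j] <- cand
            blocks[d2, j2] <- val
            done <- TRUE
            break
          }
        }
        if (done) break
      }
      if (!done) break
      tries <- tries + 1L
    }
    if (anyDuplicated(blocks[, j]))
      stop("allocation repair failed; design may be infeasible")
  }
  data.frame(participant = rep(seq_len(n_participants),
                               each = items_per_participant),
             item = as.vector(blocks))
}

finish_table <- function(tab, pattern) {
  tab$response <- recode_latent(tab$latent, pattern)
  attr(tab, "pattern") <- pattern
  attr(tab, "n_levels") <- pattern$n_levels
  tab
}

#' Simulate an items-only rating study
#'
#' Latent value for each trial of item i is \code{L_i = mu_i + e_i} with
#' \code{mu_i} drawn from the item random-effect distribution and \code{e_i}
#' from the residual distribution; responses arise by threshold recoding.
#'
#' @param design A \code{\link{simulation_design}} with
#'   \code{n_participants = NULL} (participants, if present, are ignored)
#'   and zero discrimination SDs.
#' @param pattern A \code{\link{threshold_set}} or pattern name.
#' @return A trial table (data.frame) with columns \code{item_id},
#'   \code{response} plus ground truth \code{latent}, \code{mu_item}.
#' @export
simulate_items_only <- function(design, pattern = "equidistant") {
  pattern <- resolve_pattern(pattern)
  if (design$sd_disc_item != 0 || design$sd_disc_participant != 0)
    stop("items-only generator does not support discrimination effects")
  if (!is.null(design$seed)) set.seed(design$seed)
  ni <- design$n_items
  ri <- design$ratings_per_item
  mu_i <- if (!is.null(design$item_re_dist)) {
    design$item_re_dist$sample(ni)
  } else stats::rnorm(ni, 0, design$sd_mu_item)
  e <- design$residual_dist$sample(ni * ri)
  item <- rep(seq_len(ni), each = ri)
  tab <- data.frame(item_id = pad_ids("item", ni)[item],
                    latent = mu_i[item] + e,
                    mu_item = mu_i[item],
                    stringsAsFactors = FALSE)
  finish_table(tab, pattern)
}

#' Simulate a crossed item-by-participant rating study
#'
#' Latent values follow \code{L_ij ~ Normal(mu_i + mu_j, sigma_ij)} with
#' \code{sigma_ij = 1 / exp(disc_i + disc_j)}. With zero discrimination SDs
#' this reduces to \code{L_ij = mu_i + mu_j + e_ij}, \code{e_ij ~ N(0, 1)}.
#' Participants are allocated to items with \code{\link{allocate_raters}} so
#' no participant rates an item twice.
#'
#' @inheritParams simulate_items_only
#' @param latent_residual_dist Residual distribution on the latent scale
#'   (used when both disc SDs are 0; non-normal variants for robustness
#'   checks). Defaults to the design's \code{residual_dist}.
#' @return Trial table with columns \code{participant_id}, \code{item_id},
#'   \code{response} and ground truth \code{latent}, \code{mu_item},
#'   \code{mu_participant}, \code{disc_item}, \code{disc_participant},
#'   \code{sigma}.
#' @export
simulate_crossed <- function(design, pattern = "equidistant",
                             latent_residual_dist = NULL) {
  pattern <- resolve_pattern(pattern)
  if (is.null(design$n_participants))
    stop("crossed generator needs n_participants in the design")
  if (!is.null(design$seed)) set.seed(design$seed)
  ni <- design$n_items; np <- design$n_participants
  alloc <- allocate_raters(ni, np, design$items_per_participant)
  mu_i <- if (!is.null(design$item_re_dist)) {
    design$item_re_dist$sample(ni)
  } else stats::rnorm(ni, 0, design$sd_mu_item)
  mu_j <- stats::rnorm(np, 0, design$sd_mu_participant)
  disc_i <- stats::rnorm(ni, 0, design$sd_disc_item)
  disc_j <- stats::rnorm(np, 0, design$sd_disc_participant)
  n <- nrow(alloc)
  sigma <- 1 / exp(disc_i[alloc$item] + disc_j[alloc$participant])
  rdist <- if (is.null(latent_residual_dist)) design$residual_dist else
    as_dist(latent_residual_dist)
  has_disc <- design$sd_disc_item != 0 || design$sd_disc_participant != 0
  e <- if (has_disc) {
    if (rdist$name != "normal")
      stop("discrimination effects require a normal residual")
    stats::rnorm(n, 0, 1) * sigma
  } else {
    rdist$sample(n) # sigma is identically 1 here
  }
  tab <- data.frame(
    participant_id = pad_ids("participant", np)[alloc$participant],
    item_id = pad_ids("item", ni)[alloc$item],
    latent = mu_i[alloc$item] + mu_j[alloc$participant] + e,
    mu_item = mu_i[alloc$item],
    mu_participant = mu_j[alloc$participant],
    disc_item = disc_i[alloc$item],
    disc_participant = disc_j[alloc$participant],
    sigma = sigma,
    stringsAsFactors = FALSE)
  finish_table(tab, pattern)
}

#' Simulate crossed data with a non-normal component
#'
#' Robustness variant of \code{\link{simulate_crossed}}: either the
#' per-trial latent residual (\code{target = "latent_residual"}) or the item
#' random effects (\code{target = "item_re"}) are drawn from one of the
#' fixed non-normal distributions of \code{\link{dist_spec}}; all other
#' components stay standard normal. With \code{dist = "normal"} the output
#' is identical to \code{simulate_crossed} under the same seed.
#'
#' @inheritParams simulate_crossed
#' @param target Which component to replace.
#' @param dist Distribution name (see \code{\link{dist_spec}}).
#' @export
simulate_nonnormal <- function(design, target = c("latent_residual", "item_re"),
                               dist = "normal", pattern = "edge-biased") {
  target <- match.arg(target)
  d <- as_dist(dist)
  if (target == "latent_residual") {
    simulate_crossed(design, pattern, latent_residual_dist = d)
  } else {
    design$item_re_dist <- d
    simulate_crossed(design, pattern)
  }
}
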