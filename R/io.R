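#' Read a trial-level rating table
#'
#' Reads delimited text (comma by default, header required) with columns
#' \code{participant_id} (optional), \code{item_id}, \code{response}, plus
#' any ground-truth columns written by the simulators. Rows with blank or
#' out-of-range responses (below 1 or above the declared K) are dropped and
#' counted -- no outlier trimming of any kind is applied. The number of
#' scale levels must be declared by the caller: it cannot be inferred from
#' the data because extreme categories may legitimately be unobserved
#' (floor/ceiling effects), and K changes the model.
#'
#' @param path File path.
#' @param n_levels Declared number of response categories K.
#' @param sep Field separator.
#' @param max_bad_fraction Error if more than this fraction of rows is
#'   dropped (default 0.5).
#' @return Trial table (data.frame) with attributes \code{n_levels} and
#'   \code{dropped} (named counts of dropped rows).
#' @export
read_trials <- function(path, n_levels, sep = ",", max_bad_fraction = 0.5) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (missing(n_levels)) stop("n_levels must be declared, not inferred")
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = NA, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"))
  if (!all(c("item_id", "response") %in% names(tab)))
    stop("file must have 'item_id' and 'response' columns")
  n0 <- nrow(tab)
  resp <- suppressWarnings(as.numeric(tab$response))
  blank <- is.na(resp)
  nonint <- !blank & resp != floor(resp)
  out_of_range <- !blank & !nonint & (resp < 1 | resp > n_levels)
  bad <- blank | nonint | out_of_range
  dropped <- c(blank = sum(blank), non_integer = sum(nonint),
               out_of_range = sum(out_of_range))
  if (all(bad)) stop("no valid rows in ", path)
  if (sum(bad) / n0 > max_bad_fraction)
    stop(sum(bad), "/", n0, " rows invalid in ", path)
  if (any(bad))
    message("read_trials: dropped ", sum(bad), " row(s) [blank: ",
            dropped["blank"], ", non-integer: ", dropped["non_integer"],
            ", out-of-range: ", dropped["out_of_range"], "]")
  tab <- tab[!bad, , drop = FALSE]
  tab$response <- as.integer(resp[!bad])
  if (any(tab$item_id == "" | is.na(tab$item_id))) stop("empty item ids")
  rownames(tab) <- NULL
  attr(tab, "n_levels") <- as.integer(n_levels)
  attr(tab, "dropped") <- dropped
  tab
}

#' Write a trial table as delimited text
#'
#' @param trials Trial table.
#' @param path Output path.
#' @param sep Field separator.
#' @export
write_trials <- function(trials, path, sep = ",") {
  utils::write.table(trials, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a norm table as delimited text
#'
#' Fixed column order (\code{item_id, n, raw_mean, raw_sd, latent_mean,
#' latent_mean_lo, latent_mean_hi, latent_sd, latent_sd_lo, latent_sd_hi,
#' method}), rows ordered by item id, missing values as empty fields,
#' numbers at 12 significant digits. Two writes of the same table are
#' byte-identical.
#'
#' @param norms A norm table.
#' @param path Output path.
#' @export
write_norms <- function(norms, path) {
  for (cl in setdiff(norm_table_columns, names(norms))) norms[[cl]] <- NA
  norms <- norms[order(norms$item_id), norm_table_columns]
  num <- vapply(norms, is.numeric, logical(1))
  norms[num] <- lapply(norms[num], function(v)
    ifelse(is.na(v), "", formatC(signif(v, 12), format = "g", digits = 12)))
  utils::write.table(norms, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read a norm table written by \code{\link{write_norms}}
#'
#' @param path File path.
#' @export
read_norms <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE, na.strings = "")
}

#' Generate a seed-pinned miniature dataset
#'
#' Packaged miniatures of the simulation designs for tests and docs:
#' \code{tiny} (5 items x 4 participants), \code{sim1} (items-only),
#' \code{sim2} (crossed), \code{sim3} (crossed with discrimination
#' effects), and \code{floors}, which contains one item rated 1 on every
#' trial (a floor-effect analogue) and one item with around half of its
#' responses at the scale ceiling.
#'
#' @param name Fixture name.
#' @param seed Integer seed.
#' @param path Optional path; if given the table is also written there.
#' @return The trial table (invisibly if \code{path} is given).
#' @export
generate_fixture <- function(name = c("tiny", "sim1", "sim2", "sim3",
                                      "floors"),
                             seed = 1L, path = NULL) {
  name <- match.arg(name)
  tt <- switch(name,
    tiny = simulate_crossed(
      simulation_design(n_items = 5, n_participants = 4,
                        ratings_per_item = 4, items_per_participant = 5,
                        seed = seed), "edge-biased"),
    sim1 = simulate_items_only(
      simulation_design(n_items = 30, n_participants = NULL,
                        ratings_per_item = 25, seed = seed), "edge-biased"),
    sim2 = simulate_crossed(
      simulation_design(n_items = 40, n_participants = 40,
                        ratings_per_item = 10, items_per_participant = 10,
                        seed = seed), "edge-biased"),
    sim3 = simulate_crossed(
      simulation_design(n_items = 30, n_participants = 30,
                        ratings_per_item = 15, items_per_participant = 15,
                        sd_disc_item = 0.5, sd_disc_participant = 0.5,
                        seed = seed), "edge-biased"),
    floors = {
      base <- simulate_crossed(
        simulation_design(n_items = 20, n_participants = 20,
                          ratings_per_item = 10, items_per_participant = 10,
                          seed = seed), "edge-biased")
      # floored item: far below the lowest threshold
      floored <- base$item_id == "item_01"
      base$latent[floored] <- base$latent[floored] - 8
      # ceiling-ish item: ~50% top responses
      topish <- base$item_id == "item_02"
      base$latent[topish] <- base$latent[topish] -
        stats::median(base$latent[topish]) + 1
      base$mu_item[floored] <- base$mu_item[floored] - 8
      base$response <- recode_latent(base$latent, attr(base, "pattern"))
      base
    })
  if (!is.null(path)) {
    write_trials(tt, path)
    return(invisible(tt))
  }
  tt
}

#' Read a minimal TOML configuration file
#'
#' Supports the subset of TOML needed for run configurations: [section]
#' headers, \code{key = value} pairs with string, number, boolean and flat
#' array values, and comments. Nested tables beyond one level are not
#' supported.
#'
#' @param path File path.
#' @return Nested named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  parse_val <- function(v) {
    v <- trimws(v)
    if (grepl("^\\[", v)) {
      inner <- sub("^\\[", "", sub("\\]$", "", v))
      if (trimws(inner) == "") return(list())
      return(lapply(strsplit(inner, ",")[[1]], parse_val))
    }
    if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
    if (grepl("^'.*'$", v)) return(gsub("^'|'$", "", v))
    if (v %in% c("true", "false")) return(v == "true")
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3L) stop("cannot parse config line: ", ln)
    val <- parse_val(kv[3L])
    if (is.list(val)) val <- unlist(val)
    if (is.null(section)) out[[kv[2L]]] <- val else
      out[[section]][[kv[2L]]] <- val
  }
  out
}

#' Write a JSON run manifest next to an output artifact
#'
#' Records inputs, seeds and the package version so any output can be
#' regenerated exactly.
#'
#' @param path Output path of the artifact the manifest describes
#'   (manifest goes to \code{<path>.manifest.json}).
#' @param inputs Named list of input descriptions.
#' @param seed Integer seed used.
#' @export
write_manifest <- function(path, inputs, seed) {
  manifest <- list(
    artifact = basename(path),
    inputs = inputs,
    seed = seed,
    package = "latentnorms",
    version = as.character(utils::packageVersion("latentnorms")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Serialise a CLMM fit to JSON
#'
#' Self-describing text artifact with parameters, conditional modes,
#' diagnostics and package version.
#'
#' @param fit A \code{\link{fit_clmm}} result.
#' @param path Output path.
#' @export
write_clmm_fit <- function(fit, path) {
  obj <- list(
    type = "clmm_ml", link = fit$link, n_levels = fit$n_levels,
    tau = fit$tau, re_sd = as.list(fit$re_sd),
    modes = fit$modes, loglik = fit$loglik,
    converged = fit$converged, boundary = fit$boundary,
    outer_iterations = fit$outer_iterations,
    package_version = as.character(utils::packageVersion("latentnorms")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Write posterior draws as a columnar delimited table
#'
#' Long format: \code{chain, draw, parameter, value}. Only the requested
#' parameters are written (all by default).
#'
#' @param posterior A \code{\link{fit_distributional}} result.
#' @param path Output path.
#' @param parameters Optional subset of parameter names.
#' @export
write_draws <- function(posterior, path, parameters = NULL) {
  pars <- if (is.null(parameters)) posterior$par_names else parameters
  miss <- setdiff(pars, posterior$par_names)
  if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
  n_per <- sum(posterior$chain == 1L)
  long <- data.frame(
    chain = rep(posterior$chain, times = length(pars)),
    draw = rep(rep(seq_len(n_per), length(unique(posterior$chain))),
               times = length(pars)),
    parameter = rep(pars, each = length(posterior$chain)),
    value = as.vector(posterior$draws[, pars]),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
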