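#' Configure a synthetic mid-water trawl survey
#'
#' Builds the configuration object consumed by [simulate_trawl_survey()].
#' Counts follow a zero-inflated negative binomial: each species is present
#' in a haul with probability `presence_prob`, and when present its count is
#' negative binomial with mean `mean_count` and dispersion `dispersion`
#' (variance \eqn{\mu + \mu^2/k}). `dispersion = Inf` gives Poisson counts;
#' `dispersion = 0` is the degenerate point mass at `round(mean_count)`.
#' Individual body masses are lognormal with arithmetic mean `mass_mean_g`
#' grams and log-scale SD `mass_sigma`; haul biomass is the sum of the
#' individual masses, so biomass is zero exactly when the count is zero.
#'
#' @param n_hauls Positive integer, number of hauls.
#' @param species Data frame with columns `name`, `presence_prob` (in
#'   \[0, 1\]), `mean_count` (> 0), `dispersion` (>= 0, may be `Inf`),
#'   `mass_mean_g` (> 0) and `mass_sigma` (>= 0). Species names must be
#'   unique.
#' @param seed Integer seed; all survey randomness derives from it.
#' @return A list of class `survey_sim_config`.
#' @seealso [default_survey_config()] for a ready-made patchy 26-species
#'   community.
#' @export
survey_sim_config <- function(n_hauls, species, seed = 1L) {
  if (!is.numeric(n_hauls) || length(n_hauls) != 1L || n_hauls < 1 ||
      n_hauls != round(n_hauls)) {
    stop("`n_hauls` must be a positive integer", call. = FALSE)
  }
  if (!is.data.frame(species) || nrow(species) == 0L) {
    stop("`species` must be a non-empty data frame", call. = FALSE)
  }
  needed <- c("name", "presence_prob", "mean_count", "dispersion",
              "mass_mean_g", "mass_sigma")
  missing <- setdiff(needed, names(species))
  if (length(missing)) {
    stop("`species` lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(species$name)) {
    stop("species names must be unique", call. = FALSE)
  }
  if (any(species$presence_prob < 0 | species$presence_prob > 1)) {
    stop("presence probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(species$mean_count <= 0) || any(species$mass_mean_g <= 0)) {
    stop("`mean_count` and `mass_mean_g` must be strictly positive",
         call. = FALSE)
  }
  if (any(species$dispersion < 0) || any(species$mass_sigma < 0)) {
    stop("`dispersion` and `mass_sigma` must be non-negative", call. = FALSE)
  }
  structure(list(n_hauls = as.integer(n_hauls), species = species,
                 seed = as.integer(seed)),
            class = "survey_sim_config")
}

#' Default patchy forage community configuration
#'
#' A 26-species configuration emulating a demersal forage community in which
#' one small schooling species contributes roughly 88% of expected
#' individuals and 16 species occur in fewer than 10% of hauls. Intended
#' for parameter-recovery tests of the availability indices and as a
#' worked-example input.
#'
#' @param n_hauls Number of hauls (default 21).
#' @param seed Integer seed.
#' @return A `survey_sim_config`.
#' @export
default_survey_config <- function(n_hauls = 21L, seed = 1L) {
  sp <- data.frame(
    name = sprintf("sp%02d", 1:26),
    presence_prob = c(0.48, 1.00, 0.43, 0.62, 0.29, 0.19, 0.19, 0.62, 0.33,
                      0.29, 0.14, 0.14, 0.10, 0.10, 0.10, 0.10,
                      rep(0.05, 10)),
    mean_count = c(3100, 82, 90, 35, 20, 107, 113, 4, 2, 10, 12, 12,
                   8, 8, 8, 8, rep(8, 10)),
    dispersion = c(1, 0.7, 0.7, 0.7, 0.7, 0.5, 0.5, 0.7, 0.7, 0.7,
                   rep(0.7, 16)),
    mass_mean_g = c(4, 10, 40, 25, 120, 200, 2, 60, 1500, 300,
                    rep(50, 16)),
    mass_sigma = rep(0.35, 26)
  )
  survey_sim_config(n_hauls, sp, seed = seed)
}

#' Expected catch composition of a survey configuration
#'
#' Analytic expectation of the count model: the expected per-haul count of
#' species i is `presence_prob * mean_count`, so its expected share of
#' individuals (the large-sample percent-by-number) is that product
#' normalized over species. Used as the oracle in law-of-large-numbers
#' checks of the generator.
#'
#' @param config A `survey_sim_config`.
#' @return Data frame with `species` and `expected_pct_n`.
#' @export
expected_composition <- function(config) {
  stopifnot(inherits(config, "survey_sim_config"))
  e <- config$species$presence_prob * config$species$mean_count
  data.frame(species = config$species$name,
             expected_pct_n = 100 * e / sum(e))
}

#' Simulate a trawl survey catch table
#'
#' Draws one zero-inflated negative-binomial count and a lognormal-mass
#' biomass for every haul-by-species cell of `config`. The output is a
#' long-format catch table (zero cells included) suitable for
#' [availability()].
#'
#' @param config A [survey_sim_config()].
#' @return Data frame with columns `haul_id`, `species`, `count`,
#'   `biomass_kg`; `biomass_kg` is 0 exactly when `count` is 0. Identical
#'   `config` (including its seed) always yields an identical table.
#' @export
simulate_trawl_survey <- function(config) {
  stopifnot(inherits(config, "survey_sim_config"))
  sp <- config$species
  n_h <- config$n_hauls
  set.seed(child_seed(config$seed, "trawl-survey"))
  out <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    present <- rbinom(n_h, 1L, sp$presence_prob[i])
    k <- sp$dispersion[i]
    mu <- sp$mean_count[i]
    counts <- if (k == 0) {
      rep(as.integer(round(mu)), n_h)
    } else if (is.infinite(k)) {
      rpois(n_h, mu)
    } else {
      rnbinom(n_h, size = k, mu = mu)
    }
    counts <- counts * present
    sigma <- sp$mass_sigma[i]
    meanlog <- log(sp$mass_mean_g[i]) - sigma^2 / 2
    biomass_g <- vapply(counts, function(ct) {
      if (ct == 0L) return(0)
      if (sigma == 0) return(ct * sp$mass_mean_g[i])
      sum(rlnorm(ct, meanlog, sigma))
    }, numeric(1))
    out[[i]] <- data.frame(
      haul_id = sprintf("haul%03d", seq_len(n_h)),
      species = sp$name[i],
      count = as.integer(counts),
      biomass_kg = biomass_g / 1000
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(res$haul_id, res$species), , drop = FALSE]
  rownames(res) <- NULL
  res
}
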