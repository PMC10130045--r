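#' Prey availability indices from a trawl catch table
#'
#' Computes, per species, the percent occurrence
#' \eqn{\%O_i = n_i/N \times 100} (fraction of hauls in which the species
#' was caught), percent by number \eqn{\%N_i = x_i/X \times 100} and percent
#' by biomass \eqn{\%B_i = b_i/B \times 100}, together with percentile
#' bootstrap confidence intervals for %N and %B obtained by resampling
#' hauls with replacement.
#'
#' @param table Catch table: data frame with columns `haul_id`, `species`,
#'   `count` (integer >= 0) and `biomass_kg` (>= 0). Zero-count rows are
#'   allowed and contribute to the haul list only.
#' @param boot_reps Bootstrap replicates (default 1000); set to 0 to skip
#'   the intervals.
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return Data frame of class `availability_summary`, one row per species:
#'   `n_hauls_present`, `pct_occurrence`, `total_count`, `pct_number`,
#'   `total_biomass_kg`, `pct_biomass`, and when bootstrapped
#'   `pct_number_lo/hi`, `pct_biomass_lo/hi`. Attributes `n_hauls`,
#'   `total_count`, `total_biomass_kg` hold the survey totals.
#' @export
availability <- function(table, boot_reps = 1000L, level = 0.95, seed = 1L) {
  check_catch_table(table)
  species <- sort(unique(table$species))
  hauls <- unique(table$haul_id)
  n_hauls <- length(hauls)
  agg <- function(v) {
    s <- tapply(v, table$species, sum)
    as.numeric(s[species])
  }
  n_present <- as.numeric(
    tapply(table$count > 0, table$species, sum)[species])
  x <- agg(table$count)
  b <- agg(table$biomass_kg)
  res <- data.frame(
    species = species,
    n_hauls_present = n_present,
    pct_occurrence = 100 * n_present / n_hauls,
    total_count = x,
    pct_number = 100 * x / sum(x),
    total_biomass_kg = b,
    pct_biomass = 100 * b / sum(b)
  )
  if (boot_reps > 0 && n_hauls >= 2) {
    ci_n <- bootstrap_ci(table, metric = "pct_number", reps = boot_reps,
                         level = level, seed = seed)
    ci_b <- bootstrap_ci(table, metric = "pct_biomass", reps = boot_reps,
                         level = level, seed = seed)
    res$pct_number_lo <- ci_n$lower[match(species, ci_n$species)]
    res$pct_number_hi <- ci_n$upper[match(species, ci_n$species)]
    res$pct_biomass_lo <- ci_b$lower[match(species, ci_b$species)]
    res$pct_biomass_hi <- ci_b$upper[match(species, ci_b$species)]
  }
  attr(res, "n_hauls") <- n_hauls
  attr(res, "total_count") <- sum(x)
  attr(res, "total_biomass_kg") <- sum(b)
  class(res) <- c("availability_summary", "data.frame")
  res
}

#' @export
print.availability_summary <- function(x, digits = 2, ...) {
  cat("Prey availability over", attr(x, "n_hauls"), "hauls:",
      format(attr(x, "total_count"), big.mark = ","), "individuals,",
      round(attr(x, "total_biomass_kg"), 2), "kg\n\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], round, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Percent occurrence per species
#'
#' `occurrence()` is \eqn{\%O_i = n_i/N \times 100}: the share of hauls in
#' which species i appeared with a positive count.
#'
#' @param table Catch table (see [availability()]).
#' @return Named numeric vector of percentages.
#' @export
occurrence <- function(table) {
  check_catch_table(table)
  n_hauls <- length(unique(table$haul_id))
  s <- tapply(table$count > 0, table$species, sum)
  100 * as.numeric(s) / n_hauls -> p
  setNames(p, names(s))
}

#' Percent by number per species
#'
#' \eqn{\%N_i = x_i/X \times 100}, where `x_i` is the species' total count
#' and `X` the survey total. Sums to 100 over species.
#'
#' @inheritParams occurrence
#' @return Named numeric vector of percentages.
#' @export
relative_abundance <- function(table) {
  check_catch_table(table)
  s <- tapply(table$count, table$species, sum)
  X <- sum(s)
  if (X <= 0) stop("total count is zero", call. = FALSE)
  setNames(100 * as.numeric(s) / X, names(s))
}

#' Percent by biomass per species
#'
#' \eqn{\%B_i = b_i/B \times 100}, where `b_i` is the species' total
#' biomass (kg). Sums to 100 over species.
#'
#' @inheritParams occurrence
#' @return Named numeric vector of percentages.
#' @export
relative_biomass <- function(table) {
  check_catch_table(table)
  s <- tapply(table$biomass_kg, table$species, sum)
  B <- sum(s)
  if (B <= 0) stop("total biomass is zero", call. = FALSE)
  setNames(100 * as.numeric(s) / B, names(s))
}

#' Bootstrap percentile confidence intervals for %N or %B
#'
#' Resamples hauls (the independent sampling units of the survey design)
#' with replacement, recomputes the requested index per replicate, and
#' returns per-species percentile intervals. Quantiles use the inverse
#' empirical CDF (`type = 1`) so that small-sample intervals are attained
#' resample values and agree with exhaustive enumeration of resamples.
#'
#' @param table Catch table (see [availability()]); needs >= 2 hauls.
#' @param metric `"pct_number"` or `"pct_biomass"`.
#' @param reps Number of bootstrap replicates (>= 1).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return Data frame with `species`, `point`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(table, metric = c("pct_number", "pct_biomass"),
                         reps = 1000L, level = 0.95, seed = 1L) {
  check_catch_table(table)
  metric <- match.arg(metric)
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  hauls <- unique(table$haul_id)
  if (length(hauls) < 2L) stop("need >= 2 hauls to bootstrap", call. = FALSE)
  species <- sort(unique(table$species))
  col <- if (metric == "pct_number") "count" else "biomass_kg"
  # haul x species totals matrix, so a resample is a row re-weighting
  m <- matrix(0, length(hauls), length(species),
              dimnames = list(hauls, species))
  idx <- cbind(match(table$haul_id, hauls), match(table$species, species))
  m[idx] <- m[idx] + table[[col]]
  pct <- function(w) {
    tot <- drop(w %*% m)
    100 * tot / sum(tot)
  }
  point <- pct(rep(1, length(hauls)))
  set.seed(child_seed(seed, paste0("bootstrap-", metric)))
  draws <- matrix(NA_real_, reps, length(species))
  for (r in seq_len(reps)) {
    pick <- sample.int(length(hauls), replace = TRUE)
    draws[r, ] <- pct(tabulate(pick, nbins = length(hauls)))
  }
  alpha <- (1 - level) / 2
  data.frame(
    species = species,
    point = point,
    lower = apply(draws, 2, quantile, probs = alpha, type = 1),
    upper = apply(draws, 2, quantile, probs = 1 - alpha, type = 1),
    row.names = NULL
  )
}

check_catch_table <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0L) {
    stop("catch table must be a non-empty data frame", call. = FALSE)
  }
  needed <- c("haul_id", "species", "count", "biomass_kg")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop("catch table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(table[c("haul_id", "species")])) {
    stop("(haul_id, species) pairs must be unique", call. = FALSE)
  }
  if (any(table$count < 0) || any(table$biomass_kg < 0)) {
    stop("counts and biomasses must be non-negative", call. = FALSE)
  }
  if (any(table$count == 0 & table$biomass_kg > 0)) {
    stop("biomass must be 0 where count is 0", call. = FALSE)
  }
  invisible(table)
}
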