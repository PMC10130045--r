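#' Chesson's selectivity index
#'
#' Compares the diet proportions `r` of a predator (here, posterior means
#' from the isotope mixing model) against the availability proportions `p`
#' of the same prey in the environment. The default is the standard ratio
#' form
#' \deqn{\alpha_i = \frac{r_i/p_i}{\sum_j r_j/p_j},}
#' which is invariant to rescaling of `p` (so renormalizing availability
#' over the modeled prey is immaterial) and sums to 1. \eqn{\alpha_i =
#' 1/m} for all i indicates random feeding. A product form
#' \eqn{\alpha_i \propto r_i p_i} is available behind
#' `formula = "product"` for compatibility with reports that print the
#' index in that nonstandard way; it is not the default because it does
#' not measure selectivity.
#'
#' @param r Diet proportions (non-negative; renormalized internally).
#' @param p Availability proportions (renormalized internally); under the
#'   ratio form every `p_i` must be > 0 where `r_i > 0`.
#' @param species Optional species names (defaults to `names(r)`).
#' @param formula `"ratio"` (default) or `"product"`.
#' @return List of class `selectivity_result`: `alpha` (named, sums to 1),
#'   `r`, `p` (renormalized), `m`, `threshold` (= 1/m), `formula`.
#' @seealso [classify_selection()], [pianka()]
#' @export
chesson <- function(r, p, species = NULL, formula = c("ratio", "product")) {
  formula <- match.arg(formula)
  if (length(r) != length(p)) stop("`r` and `p` differ in length",
                                   call. = FALSE)
  if (any(r < 0) || any(p < 0)) {
    stop("proportions must be non-negative", call. = FALSE)
  }
  if (sum(r) <= 0 || sum(p) <= 0) stop("zero vector", call. = FALSE)
  species <- species %||% names(r) %||% paste0("prey", seq_along(r))
  r <- r / sum(r)
  p <- p / sum(p)
  if (formula == "ratio") {
    if (any(p == 0 & r > 0)) {
      stop("selectivity undefined: prey with r > 0 but availability 0",
           call. = FALSE)
    }
    w <- ifelse(r == 0 & p == 0, 0, r / p)
  } else {
    w <- r * p
  }
  alpha <- setNames(w / sum(w), species)
  structure(list(alpha = alpha, r = setNames(r, species),
                 p = setNames(p, species), m = length(r),
                 threshold = 1 / length(r), formula = formula),
            class = "selectivity_result")
}

#' Label prey as positively or negatively selected
#'
#' Two classification rules are provided. `"threshold_1_over_m"` (the
#' conventional reading of Chesson's index) labels prey i Positive iff
#' \eqn{\alpha_i > 1/m}, strictly. `"exceeds_availability"` labels prey i
#' Positive iff \eqn{\alpha_i > p_i}, i.e. its selectivity exceeds its
#' availability share; this rule reproduces published selection labels
#' that flag prey with \eqn{\alpha_i < 1/m} as Positive when they are
#' still taken far in excess of their availability.
#'
#' @param result A [chesson()] result.
#' @param rule `"threshold_1_over_m"` (default) or
#'   `"exceeds_availability"`.
#' @return The result with added `labels` (named character,
#'   "Positive"/"Negative") and `rule`.
#' @export
classify_selection <- function(result,
                               rule = c("threshold_1_over_m",
                                        "exceeds_availability")) {
  stopifnot(inherits(result, "selectivity_result"))
  rule <- match.arg(rule)
  pos <- if (rule == "threshold_1_over_m") {
    result$alpha > result$threshold
  } else {
    result$alpha > result$p
  }
  result$labels <- setNames(ifelse(pos, "Positive", "Negative"),
                            names(result$alpha))
  result$rule <- rule
  result
}

#' @export
print.selectivity_result <- function(x, digits = 3, ...) {
  cat("Chesson's selectivity (", x$formula, " form, m = ", x$m,
      ", random-feeding threshold 1/m = ", round(x$threshold, digits),
      ")\n\n", sep = "")
  df <- data.frame(species = names(x$alpha),
                   diet_r = round(x$r, digits),
                   avail_p = round(x$p, digits),
                   alpha = round(x$alpha, digits))
  if (!is.null(x$labels)) {
    df$selection <- x$labels
    cat("Rule:", x$rule, "\n")
  }
  print(df, row.names = FALSE)
  invisible(x)
}

#' Pianka's niche overlap index
#'
#' \deqn{O = \frac{\sum_i p_{iA} p_{iB}}
#'   {\sqrt{\sum_i p_{iA}^2 \sum_i p_{iB}^2}}}
#' between two non-negative proportion vectors over the same prey set
#' (here: availability vs diet). O lies in \[0, 1\]: 0 for disjoint
#' support, 1 iff the vectors are proportional. Scale-invariant in each
#' argument.
#'
#' @param p_a,p_b Non-negative vectors of equal length, neither all zero.
#' @return List of class `overlap_result` with `overlap`, `p_a`, `p_b`.
#' @export
pianka <- function(p_a, p_b) {
  if (length(p_a) != length(p_b)) stop("vectors differ in length",
                                       call. = FALSE)
  if (any(p_a < 0) || any(p_b < 0)) {
    stop("proportions must be non-negative", call. = FALSE)
  }
  if (sum(p_a) == 0 || sum(p_b) == 0) stop("zero vector", call. = FALSE)
  o <- sum(p_a * p_b) / sqrt(sum(p_a^2) * sum(p_b^2))
  structure(list(overlap = min(max(o, 0), 1), p_a = p_a, p_b = p_b),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, digits = 3, ...) {
  cat("Pianka niche overlap O =", round(x$overlap, digits),
      "(0 = no overlap, 1 = complete overlap)\n")
  invisible(x)
}

#' Map trawl catch categories to mixing-model sources
#'
#' Trawl catch tables enumerate more taxa (including pooled groups) than
#' the isotope mixing model can resolve. This maps trawl categories onto
#' the modeled sources, sums the chosen availability metric over each
#' source's categories, and renormalizes over the modeled sources to give
#' the availability simplex used by [chesson()] and [pianka()].
#'
#' @param avail An [availability()] summary (or any data frame with
#'   `species` plus the metric column).
#' @param mapping Data frame with columns `trawl_category`, `source`; every
#'   modeled source must receive >= 1 category and no category may map to
#'   two sources.
#' @param basis `"pct_number"` (%N, default) or `"pct_biomass"` (%B).
#' @return Named numeric availability simplex over the modeled sources,
#'   with attribute `basis`.
#' @export
map_trawl_to_sources <- function(avail, mapping,
                                 basis = c("pct_number", "pct_biomass")) {
  basis <- match.arg(basis)
  stopifnot(is.data.frame(mapping),
            all(c("trawl_category", "source") %in% names(mapping)))
  if (anyDuplicated(mapping$trawl_category)) {
    stop("a trawl category maps to more than one source", call. = FALSE)
  }
  miss <- setdiff(mapping$trawl_category, avail$species)
  if (length(miss)) {
    stop("trawl categories not in availability table: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  metric <- avail[[basis]][match(mapping$trawl_category, avail$species)]
  tot <- tapply(metric, mapping$source, sum)
  if (any(is.na(tot)) || any(tot < 0)) stop("bad mapping", call. = FALSE)
  srcs <- unique(mapping$source)
  p <- as.numeric(tot[srcs])
  if (sum(p) <= 0) stop("mapped availability is all zero", call. = FALSE)
  structure(setNames(p / sum(p), srcs), basis = basis)
}
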