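#' Delta notation from isotope ratios
#'
#' \eqn{\delta X = (R_{sample}/R_{standard} - 1)\times 10^3} per mil, the
#' standard expression of heavy-to-light isotope ratios relative to an
#' international standard (VPDB for carbon, atmospheric N2 for nitrogen).
#'
#' @param r_sample,r_standard Positive isotope ratios.
#' @return Delta value(s) in per mil.
#' @export
delta_from_ratios <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0)) {
    stop("isotope ratios must be strictly positive", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1e3
}

#' Lipid-extraction quality control via C:N ratios
#'
#' Lipids are depleted in 13C, so isotope samples are lipid extracted
#' before analysis; a group mean C:N ratio strictly below 3 indicates the
#' extraction was adequate.
#'
#' @param samples Data frame with columns `group` and `CN_ratio`.
#' @return Data frame with `group`, `mean_CN`, `pass` (TRUE iff
#'   `mean_CN < 3`).
#' @export
qc_lipid_extraction <- function(samples) {
  if (!"CN_ratio" %in% names(samples)) {
    stop("`samples` lacks a CN_ratio column", call. = FALSE)
  }
  if (anyNA(samples$CN_ratio)) {
    stop("CN_ratio must be present for every sample", call. = FALSE)
  }
  m <- tapply(samples$CN_ratio, samples$group, mean)
  data.frame(group = names(m), mean_CN = as.numeric(m),
             pass = as.numeric(m) < 3, row.names = NULL)
}

#' Summarize per-source isotope distributions
#'
#' Collapses per-specimen prey isotope samples into the per-source mean and
#' sample SD (n - 1 denominator) table consumed by [fit_mixing_model()],
#' [simulate_consumers()] and [simulate_mixing_region()].
#'
#' @param samples Data frame with columns `group`, `d13C`, `d15N`; every
#'   group needs >= 2 samples.
#' @return Data frame with `source`, `mean_d13C`, `sd_d13C`, `mean_d15N`,
#'   `sd_d15N`, `n`.
#' @export
summarize_sources <- function(samples) {
  stopifnot(is.data.frame(samples))
  counts <- table(samples$group)
  if (any(counts < 2)) {
    stop("every source needs >= 2 samples", call. = FALSE)
  }
  groups <- names(counts)
  stat <- function(col, f) {
    as.numeric(tapply(samples[[col]], samples$group, f)[groups])
  }
  data.frame(
    source = groups,
    mean_d13C = stat("d13C", mean),
    sd_d13C = stat("d13C", sd),
    mean_d15N = stat("d15N", mean),
    sd_d15N = stat("d15N", sd),
    n = as.integer(counts),
    row.names = NULL
  )
}

#' Trophic enrichment factor specification
#'
#' The mean and SD per-tracer isotopic shift between prey tissue and
#' consumer tissue, added to source distributions in the mixing model.
#'
#' @param mean_d13C,sd_d13C,mean_d15N,sd_d15N TEF mean and SD per tracer,
#'   per mil; SDs must be >= 0.
#' @return A list of class `tef_spec`.
#' @export
tef_spec <- function(mean_d13C, sd_d13C, mean_d15N, sd_d15N) {
  if (sd_d13C < 0 || sd_d15N < 0) stop("TEF SDs must be >= 0", call. = FALSE)
  structure(list(mean_d13C = mean_d13C, sd_d13C = sd_d13C,
                 mean_d15N = mean_d15N, sd_d15N = sd_d15N),
            class = "tef_spec")
}

check_tef <- function(tef) {
  if (!inherits(tef, "tef_spec")) {
    if (is.list(tef) &&
        all(c("mean_d13C", "sd_d13C", "mean_d15N", "sd_d15N") %in%
            names(tef))) {
      return(invisible(tef))
    }
    stop("`tef` must be a tef_spec()", call. = FALSE)
  }
  invisible(tef)
}

check_source_table <- function(sources) {
  needed <- c("source", "mean_d13C", "sd_d13C", "mean_d15N", "sd_d15N")
  if (!is.data.frame(sources) || !all(needed %in% names(sources))) {
    stop("source table needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(sources$sd_d13C < 0) || any(sources$sd_d15N < 0)) {
    stop("source SDs must be >= 0", call. = FALSE)
  }
  invisible(sources)
}
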