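#' Dry/wet-basis conversion via moisture content
#'
#' `wet_from_dry()` converts a per-gram dry-mass quantity (energy density,
#' %lipid, %protein) to a wet-mass basis:
#' `value_wet = value_dry * (1 - moisture_pct/100)`. `dry_from_wet()` is
#' the inverse (moisture strictly below 100).
#'
#' @param value_dry,value_wet Numeric quantity per gram dry or wet mass.
#' @param moisture_pct Moisture content, percent of wet mass, in \[0, 100\].
#' @return Converted numeric vector.
#' @export
wet_from_dry <- function(value_dry, moisture_pct) {
  if (any(moisture_pct < 0 | moisture_pct > 100)) {
    stop("moisture must lie in [0, 100]", call. = FALSE)
  }
  value_dry * (1 - moisture_pct / 100)
}

#' @rdname wet_from_dry
#' @export
dry_from_wet <- function(value_wet, moisture_pct) {
  if (any(moisture_pct < 0 | moisture_pct >= 100)) {
    stop("moisture must lie in [0, 100)", call. = FALSE)
  }
  value_wet / (1 - moisture_pct / 100)
}

#' Protein content from total nitrogen
#'
#' Standard nitrogen-to-protein conversion for animal tissue:
#' `protein = 6.25 * nitrogen`.
#'
#' @param nitrogen_pct Total nitrogen, percent (>= 0).
#' @return Protein percent.
#' @export
protein_from_nitrogen <- function(nitrogen_pct) {
  if (any(nitrogen_pct < 0)) stop("nitrogen must be >= 0", call. = FALSE)
  6.25 * nitrogen_pct
}

#' Between-species comparison of a proximate-composition variable
#'
#' One-way ANOVA with Tukey HSD pairwise contrasts, or a Kruskal-Wallis
#' test with pairwise Wilcoxon contrasts (Holm-adjusted) for variables
#' that cannot be normalized. The pairwise "difference" reported is the
#' difference of species means (row species minus column species),
#' whatever the test, so the table reads as a mean-contrast matrix;
#' significance flags are set only where the adjusted pairwise p-value is
#' below `alpha`.
#'
#' @param records Per-individual data frame with a `species` column and
#'   the target variable; >= 2 species with >= 2 records each.
#' @param variable Column name to compare (e.g. `"ed_dry"`).
#' @param method `"anova_tukey"` or `"kruskal"`.
#' @param alpha Family-wise significance level for flags (default 0.05).
#' @return List of class `group_comparison`: `test`, `statistic`,
#'   `p_value`, `pairwise` (data frame `species_a`, `species_b`,
#'   `mean_diff`, `p_adj`, `significant`), `means`.
#' @export
group_compare <- function(records, variable,
                          method = c("anova_tukey", "kruskal"),
                          alpha = 0.05) {
  method <- match.arg(method)
  if (!variable %in% names(records)) {
    stop("no column `", variable, "` in records", call. = FALSE)
  }
  sp <- factor(records$species)
  y <- records[[variable]]
  counts <- table(sp)
  if (length(counts) < 2L || any(counts < 2L)) {
    stop("need >= 2 species with >= 2 records each", call. = FALSE)
  }
  if (var(y) == 0) stop("zero variance in `", variable, "`", call. = FALSE)
  means <- tapply(y, sp, mean)
  lev <- levels(sp)
  pairs <- t(combn(length(lev), 2))
  pw <- data.frame(
    species_a = lev[pairs[, 2]],
    species_b = lev[pairs[, 1]],
    mean_diff = as.numeric(means[pairs[, 2]] - means[pairs[, 1]])
  )
  if (method == "anova_tukey") {
    fit <- aov(y ~ sp)
    tab <- summary(fit)[[1]]
    tk <- TukeyHSD(fit, conf.level = 1 - alpha)$sp
    key <- paste(lev[pairs[, 2]], lev[pairs[, 1]], sep = "-")
    pw$p_adj <- tk[match(key, rownames(tk)), "p adj"]
    out <- list(test = "one-way ANOVA / Tukey HSD",
                statistic = c(F = tab[1, "F value"]),
                p_value = tab[1, "Pr(>F)"])
  } else {
    kw <- kruskal.test(y ~ sp)
    wt <- pairwise.wilcox.test(y, sp, p.adjust.method = "holm",
                               exact = FALSE)$p.value
    pw$p_adj <- mapply(function(a, b) {
      if (a %in% rownames(wt) && b %in% colnames(wt) &&
          !is.na(wt[a, b])) wt[a, b] else wt[b, a]
    }, pw$species_a, pw$species_b)
    out <- list(test = "Kruskal-Wallis / pairwise Wilcoxon (Holm)",
                statistic = c(H = unname(kw$statistic)),
                p_value = kw$p.value)
  }
  pw$significant <- !is.na(pw$p_adj) & pw$p_adj < alpha
  out$pairwise <- pw
  out$means <- setNames(as.numeric(means), lev)
  out$variable <- variable
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$test, "on", x$variable, "\n")
  cat(names(x$statistic), "=", round(x$statistic, 3),
      ", p =", format.pval(x$p_value, digits = 3), "\n\n")
  pw <- x$pairwise
  pw$mean_diff <- round(pw$mean_diff, 3)
  pw$p_adj <- signif(pw$p_adj, 3)
  print(pw, row.names = FALSE)
  invisible(x)
}

#' Normality gate: choose raw ANOVA, log ANOVA, or a non-parametric test
#'
#' Applies a Shapiro-Wilk test to the pooled within-species-centered
#' residuals of the variable (the quantity one-way ANOVA assumes normal);
#' if it fails at `alpha`, retries after a log transform (requires
#' strictly positive data); if normality still fails, recommends a
#' Kruskal-Wallis test. This mirrors the usual analysis chain for
#' proximate-composition variables, where %lipid typically needs a log
#' transform and %protein resists transformation altogether.
#'
#' @param records Per-individual data frame with `species` and the
#'   variable; >= 3 records per species.
#' @param variable Column name.
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return List with `recommendation` (one of `"raw_anova"`,
#'   `"log_anova"`, `"kruskal"`), `transform`, `method` (for
#'   [group_compare()]), and `shapiro_p` per branch tried.
#' @export
normality_gate <- function(records, variable, alpha = 0.05) {
  if (!variable %in% names(records)) {
    stop("no column `", variable, "` in records", call. = FALSE)
  }
  sp <- factor(records$species)
  y <- records[[variable]]
  if (any(table(sp) < 3L)) {
    stop("need >= 3 records per species for Shapiro-Wilk", call. = FALSE)
  }
  sw <- function(v) {
    r <- v - ave(v, sp)
    if (length(unique(r)) < 3L) return(0)  # degenerate: fails normality
    shapiro.test(r)$p.value
  }
  p_raw <- sw(y)
  if (p_raw >= alpha) {
    return(list(recommendation = "raw_anova", transform = "identity",
                method = "anova_tukey", shapiro_p = list(raw = p_raw)))
  }
  p_log <- NULL
  if (all(y > 0)) {
    p_log <- sw(log(y))
    if (p_log >= alpha) {
      return(list(recommendation = "log_anova", transform = "log",
                  method = "anova_tukey",
                  shapiro_p = list(raw = p_raw, log = p_log)))
    }
  }
  list(recommendation = "kruskal", transform = "none",
       method = "kruskal", shapiro_p = list(raw = p_raw, log = p_log))
}
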