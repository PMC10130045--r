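#' MCMC configuration for the mixing model
#'
#' @param chains Number of MCMC chains (>= 1; >= 2 needed for Gelman-Rubin
#'   diagnostics). Default 3.
#' @param draws Draws per chain including burn-in. Default 300000.
#' @param burnin Burn-in draws discarded per chain (< `draws`). Step-size
#'   adaptation happens only during burn-in. Default 200000.
#' @param thin Keep every `thin`-th post-burn-in draw. Default 1.
#' @param prior_alpha Dirichlet prior concentration for the diet simplex;
#'   a scalar (recycled) or one value per source. Default 1 (uniform over
#'   the simplex).
#' @param error_structure `"residual_process"` (default): multiplicative
#'   residual, per-tracer variance \eqn{v_t = \xi_t \sum_i
#'   p_i^2(\sigma_{it}^2+\tau_t^2)} with \eqn{\xi_t \sim U(0,
#'   \xi_{max})}. `"additive"`: \eqn{v_t = \sum_i
#'   p_i^2(\sigma_{it}^2+\tau_t^2) + \epsilon_t^2} with a half-normal
#'   prior on \eqn{\epsilon_t}.
#' @param hierarchical_sources `NULL` (default: hierarchical whenever the
#'   source table carries sample sizes `n`), or logical. Hierarchical
#'   treatment samples each source mean as \eqn{N(m_{it},
#'   s_{it}/\sqrt{n_i})} and each source variance from its scaled
#'   inverse-chi-squared sampling distribution, propagating the finite
#'   sample size of the prey isotope data.
#' @param resid_prior_sd Scale (per mil) of the half-normal prior on each
#'   \eqn{\epsilon_t} (additive structure only). Default 5.
#' @param resid_sd_fixed Optional length-2 numeric: fix the additive
#'   residual SDs at these values (d13C, d15N) instead of sampling them.
#'   Used for oracle comparisons where the posterior must be
#'   one-dimensional; forces `error_structure = "additive"`.
#' @param xi_prior_max Upper bound of the uniform prior on the
#'   multiplicative residual factors. Default 20.
#' @param seed Integer seed; chain seeds are derived from it.
#' @return A list of class `mixing_config`.
#' @export
mixing_config <- function(chains = 3L, draws = 300000L, burnin = 200000L,
                          thin = 1L, prior_alpha = 1,
                          error_structure = c("residual_process",
                                              "additive"),
                          hierarchical_sources = NULL,
                          resid_prior_sd = 5, resid_sd_fixed = NULL,
                          xi_prior_max = 20, seed = 1L) {
  error_structure <- match.arg(error_structure)
  if (chains < 1L) stop("`chains` must be >= 1", call. = FALSE)
  if (burnin >= draws) stop("`burnin` must be < `draws`", call. = FALSE)
  if (thin < 1L) stop("`thin` must be >= 1", call. = FALSE)
  if (any(prior_alpha <= 0)) stop("`prior_alpha` must be > 0", call. = FALSE)
  if (resid_prior_sd <= 0) stop("`resid_prior_sd` must be > 0", call. = FALSE)
  if (xi_prior_max <= 0) stop("`xi_prior_max` must be > 0", call. = FALSE)
  if (!is.null(resid_sd_fixed)) {
    resid_sd_fixed <- rep_len(as.numeric(resid_sd_fixed), 2L)
    if (any(resid_sd_fixed <= 0)) {
      stop("fixed residual SDs must be > 0", call. = FALSE)
    }
    error_structure <- "additive"
  }
  structure(list(chains = as.integer(chains), draws = as.integer(draws),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 prior_alpha = prior_alpha,
                 error_structure = error_structure,
                 hierarchical_sources = hierarchical_sources,
                 resid_prior_sd = resid_prior_sd,
                 resid_sd_fixed = resid_sd_fixed,
                 xi_prior_max = xi_prior_max,
                 seed = as.integer(seed)),
            class = "mixing_config")
}

#' Fit the Bayesian mass-balance stable-isotope mixing model
#'
#' Estimates the diet simplex `p` of a consumer population over `m` prey
#' sources from two tracers (d13C, d15N). The likelihood for consumer `j`
#' and tracer `t` is
#' \deqn{X_{jt} \sim N\Big(\sum_i p_i(\mu_{it} + \lambda_t),
#'   \sqrt{v_t}\Big)}
#' where \eqn{(\mu_{it}, \sigma_{it})} are the source moments,
#' \eqn{(\lambda_t, \tau_t)} the trophic enrichment factor, and the
#' per-tracer variance `v_t` follows the configured error structure:
#' multiplicative residual
#' \eqn{v_t = \xi_t \sum_i p_i^2(\sigma_{it}^2 + \tau_t^2)} (default) or
#' additive residual
#' \eqn{v_t = \sum_i p_i^2(\sigma_{it}^2 + \tau_t^2) + \epsilon_t^2}.
#' With hierarchical sources (the default whenever the source table has
#' sample sizes) the source moments are themselves sampled from their
#' summary-statistic sampling distributions, so the finite prey sample
#' sizes propagate into the diet posterior. The prior on `p` is
#' Dirichlet(`prior_alpha`).
#'
#' Sampling is blocked Metropolis-within-Gibbs: a random-walk Metropolis
#' block on the unconstrained diet/error parameters (additive log-ratio
#' for `p`, log for the error factors), a second random-walk block on the
#' log source variances, and exact conjugate Gibbs draws of the source
#' means; proposal scales adapt during burn-in only. Convergence is
#' assessed per parameter with [gelman_rubin()] and [geweke()]; any
#' \eqn{\hat R > 1.05} is flagged in the result and raised as a warning
#' (never silently dropped).
#'
#' @param consumers Data frame with columns `d13C`, `d15N`, one row per
#'   consumer.
#' @param sources Source summary table (see [summarize_sources()]): columns
#'   `source`, `mean_d13C`, `sd_d13C`, `mean_d15N`, `sd_d15N`, optionally
#'   `n`; >= 1 row (a single source gives the degenerate simplex p = 1).
#' @param tef A [tef_spec()].
#' @param config A [mixing_config()].
#' @return An object of class `mixing_fit`: a list with `draws` (matrix of
#'   retained draws across chains, columns = source proportions then the
#'   two per-tracer error parameters), `chain_draws` (per-chain list),
#'   `rhat`, `geweke`, `convergence_ok`, `singular_sources`,
#'   `accept_rate`, `sources`, `tef`, `consumers`, `config`. Methods:
#'   `print`, `summary`, `coef`, `plot`, `simulate`, `fitted`,
#'   `residuals`.
#' @seealso [posterior_summary()], [simulate_consumers()] for the forward
#'   model, [simulate_mixing_region()] for geometric validation.
#' @export
fit_mixing_model <- function(consumers, sources, tef,
                             config = mixing_config()) {
  check_source_table(sources)
  check_tef(tef)
  stopifnot(inherits(config, "mixing_config"))
  if (!all(c("d13C", "d15N") %in% names(consumers)) ||
      nrow(consumers) < 1L) {
    stop("`consumers` needs >= 1 row with d13C and d15N columns",
         call. = FALSE)
  }
  m <- nrow(sources)
  n <- nrow(consumers)
  x <- cbind(consumers$d13C, consumers$d15N)
  xbar <- colMeans(x)
  ss0 <- colSums(sweep(x, 2, xbar)^2)
  hier <- config$hierarchical_sources %||% !is.null(sources$n)
  if (hier && is.null(sources$n)) {
    stop("hierarchical sources need an `n` column in `sources`",
         call. = FALSE)
  }
  mult <- config$error_structure == "residual_process"
  MU <- cbind(sources$mean_d13C, sources$mean_d15N)      # m x 2
  S2 <- cbind(sources$sd_d13C^2, sources$sd_d15N^2)
  lam <- c(tef$mean_d13C, tef$mean_d15N)
  tau2 <- c(tef$sd_d13C^2, tef$sd_d15N^2)
  ns <- if (hier) sources$n else NULL
  singular <- m > 1 && all(apply(sweep(MU, 2, lam, `+`), 2,
                                 function(col) diff(range(col)) < 1e-12))
  alpha <- rep_len(config$prior_alpha, m)
  fixed <- !is.null(config$resid_sd_fixed)
  d_z <- max(m - 1L, 0L)
  d_e <- if (fixed) 0L else 2L
  dA <- d_z + d_e
  lximax <- log(config$xi_prior_max)
  prior_s2 <- config$resid_prior_sd^2

  p_from_z <- function(z) {
    if (m == 1L) return(1)
    e <- exp(c(z, 0))
    e / sum(e)
  }

  # log posterior of the Metropolis block (z, log error params), given the
  # current source moments; also returns pieces reused by the other blocks
  make_logpost <- function() {
    function(thA, mu_s, s2_s) {
      p <- p_from_z(thA[seq_len(d_z)])
      pv <- colSums(p^2 * sweep(s2_s, 2, tau2, `+`))
      if (mult) {
        lxi <- thA[d_z + 1:2]
        if (any(lxi > lximax)) return(-Inf)
        v <- exp(lxi) * pv
        lp_err <- sum(lxi)                       # U(0, max) + log Jacobian
      } else if (fixed) {
        v <- pv + config$resid_sd_fixed^2
        lp_err <- 0
      } else {
        leps <- thA[d_z + 1:2]
        eps2 <- exp(2 * leps)
        v <- pv + eps2
        lp_err <- sum(-eps2 / (2 * prior_s2) + leps)
      }
      mu <- colSums(p * mu_s) + lam
      ll <- sum(-n / 2 * log(v) - (ss0 + n * (xbar - mu)^2) / (2 * v))
      # Dirichlet(alpha) + ALR Jacobian collapse to sum(alpha * log p)
      ll + sum(alpha * log(p)) + lp_err
    }
  }
  logpost <- make_logpost()

  # log prior of log source variances u = log s2 (scaled inv-chi-squared
  # sampling distribution of a sample variance, nu = n - 1), incl. Jacobian
  ls2_logprior <- function(u) {
    nu <- rep(ns - 1, 2)
    sum(-nu / 2 * u - nu * as.vector(S2) * exp(-u) / 2)
  }

  keep_idx <- seq.int(config$burnin + 1L, config$draws, by = config$thin)
  n_keep <- length(keep_idx)
  err_names <- if (mult) c("xi_d13C", "xi_d15N") else
    c("eps_d13C", "eps_d15N")
  par_names <- c(sources$source, err_names)

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    init_err <- function() {
      if (mult) runif(2, log(0.2), min(log(3), lximax)) else
        if (fixed) NULL else runif(2, log(0.1), log(2))
    }
    thA <- c(rnorm(d_z, 0, 1), init_err())
    mu_s <- MU
    s2_s <- S2
    u <- log(as.vector(S2))
    lpA <- logpost(thA, mu_s, s2_s)
    tries <- 0L
    while (!is.finite(lpA) && tries < 50L) {
      thA <- c(rnorm(d_z, 0, 1), init_err())
      lpA <- logpost(thA, mu_s, s2_s)
      tries <- tries + 1L
    }
    scaleA <- 0.5 / sqrt(max(dA, 1L))
    scaleB <- 0.3
    out <- matrix(NA_real_, n_keep, m + 2L)
    accA <- 0L; winA <- 0L; winB <- 0L
    ki <- 1L
    for (it in seq_len(config$draws)) {
      if (dA > 0L) {
        prop <- thA + rnorm(dA, 0, scaleA)
        lp_prop <- logpost(prop, mu_s, s2_s)
        if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lpA) {
          thA <- prop; lpA <- lp_prop
          accA <- accA + 1L; winA <- winA + 1L
        }
      }
      if (hier) {
        # block B: log source variances
        u_prop <- u + rnorm(2L * m, 0, scaleB)
        s2_prop <- matrix(exp(u_prop), m, 2)
        num <- logpost(thA, mu_s, s2_prop) + ls2_logprior(u_prop)
        den <- logpost(thA, mu_s, s2_s) + ls2_logprior(u)
        if (is.finite(num) && log(runif(1)) < num - den) {
          u <- u_prop; s2_s <- s2_prop
          winB <- winB + 1L
        }
        # Gibbs: source means (conjugate normal given everything else)
        p <- p_from_z(thA[seq_len(d_z)])
        pv <- colSums(p^2 * sweep(s2_s, 2, tau2, `+`))
        v <- if (mult) exp(thA[d_z + 1:2]) * pv else
          pv + (if (fixed) config$resid_sd_fixed^2 else
            exp(2 * thA[d_z + 1:2]))
        for (t in 1:2) {
          for (i in seq_len(m)) {
            prec0 <- ns[i] / S2[i, t]
            r <- xbar[t] - lam[t] - sum(p[-i] * mu_s[-i, t])
            prec1 <- n * p[i]^2 / v[t]
            prec <- prec0 + prec1
            mean_post <- (prec0 * MU[i, t] + n * p[i] * r / v[t]) / prec
            mu_s[i, t] <- rnorm(1, mean_post, sqrt(1 / prec))
          }
        }
        lpA <- logpost(thA, mu_s, s2_s)
      }
      if (it <= config$burnin && it %% 50L == 0L) {
        if (dA > 0L) {
          scaleA <- min(max(scaleA * exp(winA / 50 - 0.25), 1e-4), 10)
          winA <- 0L
        }
        if (hier) {
          scaleB <- min(max(scaleB * exp(winB / 50 - 0.25), 1e-4), 10)
          winB <- 0L
        }
      }
      if (ki <= n_keep && it == keep_idx[ki]) {
        p <- p_from_z(thA[seq_len(d_z)])
        err <- if (mult) exp(thA[d_z + 1:2]) else
          if (fixed) config$resid_sd_fixed else exp(thA[d_z + 1:2])
        out[ki, ] <- c(p, err)
        ki <- ki + 1L
      }
    }
    colnames(out) <- par_names
    list(draws = out, accept = accA / max(config$draws, 1L))
  }

  chains <- lapply(seq_len(config$chains), function(k) {
    run_chain(child_seed(config$seed, paste0("mixing-chain-", k)))
  })
  chain_draws <- lapply(chains, `[[`, "draws")
  draws <- do.call(rbind, chain_draws)

  rhat <- rep(NA_real_, m + 2L)
  names(rhat) <- par_names
  if (config$chains >= 2L) {
    for (j in seq_len(m + 2L)) {
      cols <- lapply(chain_draws, function(cd) cd[, j])
      W <- mean(vapply(cols, var, numeric(1)))
      rhat[j] <- if (W > 0) gelman_rubin(cols) else NA_real_
    }
  }
  gw <- lapply(seq_len(m + 2L), function(j) {
    vapply(chain_draws, function(cd) {
      tryCatch(geweke(cd[, j])$z, error = function(e) NA_real_)
    }, numeric(1))
  })
  names(gw) <- par_names
  conv_ok <- all(is.na(rhat) | rhat <= 1.05)

  fit <- structure(list(
    draws = draws, chain_draws = chain_draws,
    rhat = rhat, geweke = gw, convergence_ok = conv_ok,
    singular_sources = singular,
    accept_rate = vapply(chains, `[[`, numeric(1), "accept"),
    hierarchical = hier,
    sources = sources, tef = tef, consumers = consumers, config = config
  ), class = "mixing_fit")
  if (!conv_ok) {
    warning("mixing model did not converge: max R-hat = ",
            round(max(rhat, na.rm = TRUE), 3), call. = FALSE)
  }
  if (singular) {
    warning("all TEF-corrected source means are identical; ",
            "diet proportions are unidentifiable", call. = FALSE)
  }
  fit
}

#' Posterior summary of diet proportions
#'
#' Per-source posterior mean, SD and central credible interval of the diet
#' proportions, on the percent scale.
#'
#' @param fit A `mixing_fit`.
#' @param level Credible level for the interval (default 0.95).
#' @return Data frame with `source`, `mean_pct`, `sd_pct`, `lo_pct`,
#'   `median_pct`, `hi_pct`.
#' @export
posterior_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "mixing_fit"))
  m <- nrow(fit$sources)
  pd <- fit$draws[, seq_len(m), drop = FALSE] * 100
  a <- (1 - level) / 2
  data.frame(
    source = fit$sources$source,
    mean_pct = colMeans(pd),
    sd_pct = apply(pd, 2, sd),
    lo_pct = apply(pd, 2, quantile, probs = a),
    median_pct = apply(pd, 2, quantile, probs = 0.5),
    hi_pct = apply(pd, 2, quantile, probs = 1 - a),
    row.names = NULL
  )
}

#' @export
print.mixing_fit <- function(x, ...) {
  m <- nrow(x$sources)
  cat("Bayesian stable-isotope mixing model (", m, " sources, ",
      nrow(x$consumers), " consumers)\n", sep = "")
  cat("error structure:", x$config$error_structure,
      if (x$hierarchical) "| hierarchical sources" else
        "| fixed source moments", "\n")
  cat(length(x$chain_draws), "chains,", nrow(x$draws), "retained draws;",
      "mean acceptance", round(mean(x$accept_rate), 3), "\n")
  if (!all(is.na(x$rhat))) {
    cat("max R-hat:", round(max(x$rhat, na.rm = TRUE), 4),
        if (x$convergence_ok) "(converged)" else "(NOT converged)", "\n")
  }
  cat("\nPosterior mean diet proportions (%):\n")
  s <- posterior_summary(x)
  print(data.frame(source = s$source,
                   mean = round(s$mean_pct, 1),
                   sd = round(s$sd_pct, 1)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mixing_fit <- function(object, level = 0.95, ...) {
  m <- nrow(object$sources)
  err <- object$draws[, m + 1:2, drop = FALSE]
  structure(list(
    proportions = posterior_summary(object, level = level),
    error_params = data.frame(parameter = colnames(err),
                              mean = colMeans(err),
                              sd = apply(err, 2, sd)),
    rhat = object$rhat,
    geweke = object$geweke,
    convergence_ok = object$convergence_ok,
    n_consumers = nrow(object$consumers),
    accept_rate = object$accept_rate
  ), class = "summary.mixing_fit")
}

#' @export
print.summary.mixing_fit <- function(x, ...) {
  cat("Diet proportions (posterior, % scale):\n")
  print(cbind(x$proportions[1], round(x$proportions[-1], 2)),
        row.names = FALSE)
  cat("\nError parameters:\n")
  print(cbind(x$error_params[1], round(x$error_params[-1], 3)),
        row.names = FALSE)
  cat("\nGelman-Rubin R-hat:\n")
  print(round(x$rhat, 4))
  cat(if (x$convergence_ok) "All R-hat <= 1.05\n" else
    "WARNING: R-hat > 1.05 for at least one parameter\n")
  invisible(x)
}

#' @export
coef.mixing_fit <- function(object, ...) {
  m <- nrow(object$sources)
  setNames(colMeans(object$draws[, seq_len(m), drop = FALSE]),
           object$sources$source)
}

#' @export
fitted.mixing_fit <- function(object, ...) {
  p <- coef(object)
  mom <- mixture_moments(p / sum(p), object$sources, object$tef)
  setNames(mom$mean, c("d13C", "d15N"))
}

#' @export
residuals.mixing_fit <- function(object, ...) {
  f <- fitted(object)
  cbind(d13C = object$consumers$d13C - f["d13C"],
        d15N = object$consumers$d15N - f["d15N"])
}

#' Posterior-predictive consumer draws
#'
#' For each of `nsim` retained posterior draws (sampled uniformly), one
#' consumer tracer pair is generated from the fitted likelihood (source
#' moments fixed at their summaries).
#'
#' @param object A `mixing_fit`.
#' @param nsim Number of simulated consumers.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `d13C`, `d15N`.
#' @export
simulate.mixing_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(object$sources)
  mult <- object$config$error_structure == "residual_process"
  pick <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  out <- matrix(NA_real_, nsim, 2)
  for (i in seq_len(nsim)) {
    dr <- object$draws[pick[i], ]
    p <- dr[seq_len(m)]
    mom <- mixture_moments(p, object$sources, object$tef)
    v <- if (mult) mom$sd^2 * dr[m + 1:2] else mom$sd^2 + dr[m + 1:2]^2
    out[i, ] <- rnorm(2, mom$mean, sqrt(v))
  }
  data.frame(d13C = out[, 1], d15N = out[, 2])
}

#' @export
plot.mixing_fit <- function(x, ...) {
  m <- nrow(x$sources)
  pd <- x$draws[, seq_len(m), drop = FALSE] * 100
  boxplot(as.data.frame(pd), ylab = "Dietary contribution (%)",
          las = 2, outline = FALSE, ...)
  invisible(x)
}
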