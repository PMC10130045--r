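test_that("delta notation arithmetic is exact", {
  expect_equal(delta_from_ratios(0.0112372, 0.0112372), 0)
  expect_equal(delta_from_ratios(1.001 * 0.5, 0.5), 1, tolerance = 1e-9)
  # independent hand calculation against the VPDB standard ratio
  expect_equal(delta_from_ratios(0.0110, 0.0112372),
               (0.0110 / 0.0112372 - 1) * 1e3)
  expect_error(delta_from_ratios(-1, 0.5), "positive")
})

test_that("lipid-extraction QC applies the strict C:N < 3 rule", {
  s <- data.frame(group = c("a", "a", "b", "b", "c", "c"),
                  CN_ratio = c(2.8, 2.9, 3.5, 3.5, 2.9, 3.1))
  qc <- qc_lipid_extraction(s)
  expect_equal(qc$mean_CN[qc$group == "a"], 2.85)
  expect_true(qc$pass[qc$group == "a"])
  expect_false(qc$pass[qc$group == "b"])
  expect_false(qc$pass[qc$group == "c"])  # mean exactly 3.0 fails
  expect_error(qc_lipid_extraction(data.frame(group = "a", d13C = 1)),
               "CN_ratio")
})

test_that("source summaries use sample SD and round-trip the generator", {
  s <- data.frame(group = "x", d13C = c(-18.0, -18.68), d15N = c(10, 11))
  out <- summarize_sources(s)
  expect_equal(out$mean_d13C, -18.34)
  expect_equal(out$sd_d13C, sd(c(-18.0, -18.68)))
  same <- data.frame(group = "y", d13C = c(-17, -17, -17), d15N = rep(9, 3))
  expect_equal(summarize_sources(same)$sd_d13C, 0)
  expect_error(summarize_sources(data.frame(group = "z", d13C = 1, d15N = 2)),
               ">= 2 samples")
})

test_that("single-source fit is the degenerate simplex", {
  src <- two_sources()[1, ]
  cons <- data.frame(d13C = c(-19.9, -20.1), d15N = c(10.1, 9.9))
  cfg <- mixing_config(chains = 2, draws = 2000, burnin = 500,
                       error_structure = "additive",
                       hierarchical_sources = FALSE, seed = 1)
  fit <- fit_mixing_model(cons, src, tef_zero(), cfg)
  expect_true(all(fit$draws[, 1] == 1))
})

test_that("two-source posterior mean matches 1-D grid integration", {
  src <- two_sources()
  cons <- data.frame(d13C = -18, d15N = 12)
  cfg <- mixing_config(draws = 15000, burnin = 5000,
                       resid_sd_fixed = c(0.1, 0.1),
                       hierarchical_sources = FALSE, seed = 3)
  fit <- fit_mixing_model(cons, src, tef_zero(), cfg)
  p1 <- unname(coef(fit)[1])
  expect_gt(p1, 0.45)
  expect_lt(p1, 0.55)
  # oracle: grid evaluation of the same unnormalized posterior
  grid <- seq(0, 1, by = 0.001)
  lp <- vapply(grid, function(g) {
    p <- c(g, 1 - g)
    mu <- c(sum(p * src$mean_d13C), sum(p * src$mean_d15N))
    v <- c(sum(p^2 * src$sd_d13C^2), sum(p^2 * src$sd_d15N^2)) + 0.01
    sum(-0.5 * log(v) - (c(-18, 12) - mu)^2 / (2 * v))
  }, numeric(1))
  w <- exp(lp - max(lp))
  expect_lt(abs(p1 - sum(grid * w) / sum(w)), 0.02)
})

test_that("every retained draw lies on the simplex with positive error", {
  cfg <- quick_cfg(seed = 5)
  fit <- suppressWarnings(
    fit_mixing_model(gom_consumers(seed = 5), gom_prey_sources(),
                     gom_tef(), cfg))
  m <- nrow(fit$sources)
  sums <- rowSums(fit$draws[, seq_len(m)])
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(fit$draws[, seq_len(m)] >= 0))
  expect_true(all(fit$draws[, m + 1:2] > 0))
  ps <- posterior_summary(fit)
  expect_equal(sum(ps$mean_pct), 100, tolerance = 0.01)
})

test_that("permuting source order permutes posterior summaries", {
  cfg <- mixing_config(draws = 12000, burnin = 6000, seed = 9)
  src <- gom_prey_sources()
  cons <- gom_consumers(seed = 9)
  perm <- c(3, 1, 4, 2)
  f1 <- fit_mixing_model(cons, src, gom_tef(), cfg)
  f2 <- fit_mixing_model(cons, src[perm, ], gom_tef(), cfg)
  m1 <- posterior_summary(f1)
  m2 <- posterior_summary(f2)
  m2 <- m2[match(m1$source, m2$source), ]
  expect_true(all(abs(m1$mean_pct - m2$mean_pct) < 3))
})

test_that("deliberately under-mixed runs are flagged by R-hat", {
  cfg <- mixing_config(chains = 3, draws = 6, burnin = 1, seed = 2)
  expect_warning(
    fit <- fit_mixing_model(gom_consumers(seed = 2), gom_prey_sources(),
                            gom_tef(), cfg),
    "did not converge")
  expect_false(fit$convergence_ok)
  expect_gt(max(fit$rhat, na.rm = TRUE), 1.05)
})

test_that("identical sources are flagged as unidentifiable", {
  src <- data.frame(source = c("a", "b", "c"),
                    mean_d13C = -18, sd_d13C = 0.2,
                    mean_d15N = 11, sd_d15N = 0.2)
  cons <- data.frame(d13C = c(-18.1, -17.9), d15N = c(11.2, 10.8))
  cfg <- mixing_config(chains = 2, draws = 1200, burnin = 400,
                       error_structure = "additive",
                       hierarchical_sources = FALSE, seed = 1)
  fit <- suppressWarnings(fit_mixing_model(cons, src, tef_zero(), cfg))
  expect_true(fit$singular_sources)
})

test_that("fit methods expose coefficients, residuals and simulations", {
  cfg <- quick_cfg(seed = 6)
  cons <- gom_consumers(seed = 6)
  fit <- suppressWarnings(
    fit_mixing_model(cons, gom_prey_sources(), gom_tef(), cfg))
  cf <- coef(fit)
  expect_length(cf, 4)
  expect_equal(sum(cf), 1, tolerance = 1e-9)
  f <- fitted(fit)
  r <- residuals(fit)
  expect_equal(unname(r[, "d13C"]), cons$d13C - unname(f["d13C"]))
  sim <- simulate(fit, nsim = 50, seed = 1)
  expect_equal(nrow(sim), 50)
  expect_true(all(is.finite(sim$d13C)))
  s <- summary(fit)
  expect_s3_class(s, "summary.mixing_fit")
  expect_output(print(fit), "mixing model")
})

test_that("hierarchical multiplicative fit agrees with an independent JAGS run", {
  library(rjags)
  src <- gom_prey_sources()
  cons <- gom_consumers(seed = 21)
  cfg <- mixing_config(draws = 30000, burnin = 20000, seed = 21)
  fit <- fit_mixing_model(cons, src, gom_tef(), cfg)
  model <- "
  model {
    p ~ ddirch(alpha)
    for (i in 1:m) { for (t in 1:2) {
      mu_s[i,t] ~ dnorm(MU[i,t], ns[i]/S2[i,t])
      chi[i,t] ~ dchisqr(ns[i]-1)
      s2_s[i,t] <- S2[i,t]*(ns[i]-1)/chi[i,t]
    }}
    for (t in 1:2) {
      mixmu[t] <- inprod(p, mu_s[,t]) + lam[t]
      v[t] <- xi[t] * inprod(p*p, s2_s[,t] + tau2[t])
      xi[t] ~ dunif(0, 20)
    }
    for (j in 1:N) { for (t in 1:2) { X[j,t] ~ dnorm(mixmu[t], 1/v[t]) } }
  }"
  dat <- list(X = cbind(cons$d13C, cons$d15N), N = nrow(cons), m = 4,
              MU = cbind(src$mean_d13C, src$mean_d15N),
              S2 = cbind(src$sd_d13C^2, src$sd_d15N^2),
              ns = src$n, lam = c(1.29, 2.73),
              tau2 = c(0.56, 0.58)^2, alpha = rep(1, 4))
  con <- textConnection(model)
  jm <- jags.model(con, data = dat, n.chains = 2, n.adapt = 2000,
                   quiet = TRUE)
  close(con)
  update(jm, 8000, progress.bar = "none")
  sm <- coda.samples(jm, "p", 20000, thin = 5, progress.bar = "none")
  jags_mean <- summary(sm)$statistics[, "Mean"]
  expect_true(all(abs(coef(fit) - jags_mean) < 0.05))
})
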