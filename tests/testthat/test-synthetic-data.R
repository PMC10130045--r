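test_that("degenerate survey config yields deterministic counts and biomass", {
  sp <- data.frame(name = "only", presence_prob = 1, mean_count = 5,
                   dispersion = 0, mass_mean_g = 10, mass_sigma = 0)
  cfg <- survey_sim_config(3, sp, seed = 1)
  tab <- simulate_trawl_survey(cfg)
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(tab$count), 15L)
  expect_equal(sum(tab$biomass_kg), 0.150)  # 150 g
})

test_that("survey generation is a pure function of config and seed", {
  cfg <- default_survey_config(n_hauls = 15, seed = 42)
  expect_identical(simulate_trawl_survey(cfg), simulate_trawl_survey(cfg))
  cfg2 <- default_survey_config(n_hauls = 15, seed = 43)
  expect_false(identical(simulate_trawl_survey(cfg),
                         simulate_trawl_survey(cfg2)))
})

test_that("survey config validation rejects bad inputs", {
  sp <- data.frame(name = "a", presence_prob = 1, mean_count = 5,
                   dispersion = 1, mass_mean_g = 10, mass_sigma = 0.3)
  expect_error(survey_sim_config(0, sp), "positive integer")
  expect_error(survey_sim_config(3, sp[0, ]), "non-empty")
  sp2 <- rbind(sp, sp)
  expect_error(survey_sim_config(3, sp2), "unique")
  sp$presence_prob <- 1.2
  expect_error(survey_sim_config(3, sp), "\\[0, 1\\]")
})

test_that("realized catch composition converges to the configured mixture", {
  # oracle: analytic expectation of the zero-inflated NB count model
  cfg <- default_survey_config(n_hauls = 2000, seed = 7)
  expected <- expected_composition(cfg)
  dominant <- expected$species[which.max(expected$expected_pct_n)]
  expect_gt(max(expected$expected_pct_n), 85)  # patchy community shape
  tab <- simulate_trawl_survey(cfg)
  pn <- relative_abundance(tab)
  expect_lt(abs(pn[dominant] -
                  expected$expected_pct_n[expected$species == dominant]), 2)
})

test_that("prey isotope simulation honours truth, zero-SD and seeding", {
  truth <- gom_prey_sources()
  truth0 <- truth
  truth0$sd_d13C <- 0
  truth0$sd_d15N <- 0
  s0 <- simulate_prey_isotopes(truth0, seed = 5)
  expect_equal(s0$d13C, rep(truth0$mean_d13C, truth0$n))
  expect_equal(s0$d15N, rep(truth0$mean_d15N, truth0$n))

  big <- truth
  big$n <- 10000L
  sb <- simulate_prey_isotopes(big, seed = 5)
  est <- summarize_sources(sb)
  est <- est[match(truth$source, est$source), ]
  expect_true(all(abs(est$mean_d13C - truth$mean_d13C) < 0.05))
  expect_true(all(abs(est$mean_d15N - truth$mean_d15N) < 0.05))

  expect_identical(simulate_prey_isotopes(truth, seed = 9),
                   simulate_prey_isotopes(truth, seed = 9))
  bad <- truth
  bad$sd_d13C[1] <- -1
  expect_error(simulate_prey_isotopes(bad), ">= 0")
  small <- truth
  small$n[1] <- 1L
  expect_error(simulate_prey_isotopes(small), "n >= 2")
})

test_that("consumer forward model matches the mass-balance mean exactly", {
  src <- two_sources()
  # pure diet, no variance: consumer = source mean + TEF mean
  src0 <- src
  src0$sd_d13C <- 0
  src0$sd_d15N <- 0
  tef <- tef_spec(1.29, 0, 2.73, 0)
  cons <- simulate_consumers(c(1, 0), src0, tef, n = 5, seed = 2)
  expect_equal(cons$d13C, rep(-20 + 1.29, 5))
  expect_equal(cons$d15N, rep(10 + 2.73, 5))
  # midpoint mixture
  cons2 <- simulate_consumers(c(0.5, 0.5), src0, tef_zero(), n = 3, seed = 2)
  expect_equal(cons2$d13C, rep(-18, 3))
  expect_equal(cons2$d15N, rep(12, 3))
})

test_that("large-n consumer mean matches the hand-computed mixture mean", {
  src <- gom_prey_sources()
  tef <- gom_tef()
  p <- c(0.668, 0.178, 0.064, 0.091)
  p <- p / sum(p)  # published rounded proportions sum to 1.001
  # oracle: direct mixture-mean formula
  mu13 <- sum(p * (src$mean_d13C + 1.29))
  cons <- simulate_consumers(p, src, tef, n = 10000, resid_sd = c(0.3, 0.3),
                             seed = 4)
  expect_lt(abs(mean(cons$d13C) - mu13), 0.05)
  expect_error(simulate_consumers(c(0.5, 0.6, 0, 0), src, tef, n = 2),
               "simplex")
})

test_that("rescaling consumers hits target summaries exactly", {
  set.seed(1)
  raw <- data.frame(d13C = rnorm(10), d15N = rnorm(10))
  sc <- rescale_consumers_to_summary(raw, c(-17.09, 12.38), c(0.20, 0.28))
  expect_equal(mean(sc$d13C), -17.09, tolerance = 1e-10)
  expect_equal(sd(sc$d13C), 0.20, tolerance = 1e-10)
  expect_equal(mean(sc$d15N), 12.38, tolerance = 1e-10)
  expect_equal(sd(sc$d15N), 0.28, tolerance = 1e-10)
  # affine invariance: z-scores unchanged
  expect_equal(scale(sc$d13C)[, 1], scale(raw$d13C)[, 1])
  # identity when rescaling to own summaries
  id <- rescale_consumers_to_summary(raw, c(mean(raw$d13C), mean(raw$d15N)),
                                     c(sd(raw$d13C), sd(raw$d15N)))
  expect_equal(id$d13C, raw$d13C)
  const <- data.frame(d13C = rep(1, 5), d15N = rnorm(5))
  expect_error(rescale_consumers_to_summary(const, c(0, 0), c(1, 1)),
               "zero input variance")
})

test_that("proximate simulation is internally consistent and recovers truth", {
  truth <- gom_proximate_summary()
  rec <- simulate_proximate(truth, n = 200, seed = 3)
  expect_true(all(abs(rec$ed_wet -
                        rec$ed_dry * (1 - rec$moisture_pct / 100)) < 1e-9))
  expect_true(all(rec$moisture_pct >= 0 & rec$moisture_pct <= 100))
  # zero-SD degenerate case
  t0 <- truth
  for (col in grep("_sd$", names(t0), value = TRUE)) t0[[col]] <- 0
  t0$ed_dry_mean <- 20
  t0$moisture_mean <- 75
  r0 <- simulate_proximate(t0[1, ], n = 4, seed = 1)
  expect_equal(r0$ed_wet, rep(5, 4))
  # Monte-Carlo convergence to truth within 2%
  big <- simulate_proximate(truth, n = 1000, seed = 8)
  for (i in seq_len(nrow(truth))) {
    mfit <- mean(big$ed_dry[big$species == truth$species[i]])
    expect_lt(abs(mfit - truth$ed_dry_mean[i]) / truth$ed_dry_mean[i], 0.02)
  }
  expect_identical(simulate_proximate(truth, 50, seed = 2),
                   simulate_proximate(truth, 50, seed = 2))
  bad <- truth
  bad$moisture_mean[1] <- 105
  expect_error(simulate_proximate(bad, 10), "\\[0, 100\\]")
})
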