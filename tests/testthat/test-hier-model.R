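fast_mcmc <- function(...) mcmc_config(chains = 2, iter = 1500, seed = 42, ...)

test_that("fixed-sd marginals match the closed-form multilevel posterior", {
  set.seed(1)
  tax <- hand_taxonomy(c("s1", "s2", "s3", "s4"),
                       c("g1", "g1", "g2", "g2"),
                       c("f1", "f1", "f1", "f1"))
  rec <- data.frame(
    species_id = rep(c("s1", "s2", "s3", "s4"), times = c(8, 3, 5, 2)),
    value = c(rnorm(8, 1.2, 0.5), rnorm(3, 0.4, 0.5),
              rnorm(5, -0.8, 0.5), rnorm(2, -0.2, 0.5)))
  mc <- mcmc_config(chains = 3, iter = 4000, seed = 5, sd_obs = 0.5,
                    sd_sp_fixed = 0.7, sd_g = 0.6, sd_f = 0.8)
  fit <- fit_hierarchy(rec, tax, mc)
  oracle <- conjugate_hierarchy_posterior(rec, tax, sd_obs = 0.5,
                                          sd_sp = 0.7, sd_g = 0.6,
                                          sd_f = 0.8)
  sp_draws <- traitsets:::flat_draws(fit, "mu_sp")
  for (k in seq_along(oracle$species)) {
    d <- sp_draws[, match(oracle$species[k], fit$species)]
    mcse <- sd(d) / sqrt(100)  # conservative ESS floor
    expect_lt(abs(mean(d) - oracle$mean[oracle$idx$s[k]]), 3 * mcse)
    expect_lt(abs(sd(d) / oracle$sd[oracle$idx$s[k]] - 1), 0.15)
  }
  g_draws <- traitsets:::flat_draws(fit, "mu_g")
  for (k in seq_along(oracle$genera)) {
    d <- g_draws[, match(oracle$genera[k], fit$genera)]
    expect_lt(abs(mean(d) - oracle$mean[oracle$idx$g[k]]),
              3 * sd(d) / sqrt(100))
  }
  glob <- traitsets:::flat_draws(fit, "mu_global")[, 1]
  expect_lt(abs(mean(glob) - oracle$mean[1]), 3 * sd(glob) / sqrt(100))
})

test_that("single data-rich species: posterior mean tracks the sample mean", {
  set.seed(2)
  tax <- hand_taxonomy("s1", "g1", "f1")
  y <- rnorm(60, 0.9, 1)
  fit <- fit_hierarchy(data.frame(species_id = "s1", value = y), tax,
                       fast_mcmc())
  d <- traitsets:::flat_draws(fit, "mu_sp")[, 1]
  # with n = 60 and sd_obs = 1 the data dominate the unit-scale hierarchy
  expect_lt(abs(mean(d) - mean(y)), 0.08)

  # degenerate limit: identical records, tiny sd_obs -> concentration
  fit0 <- fit_hierarchy(data.frame(species_id = "s1",
                                   value = rep(0.5, 20)), tax,
                        mcmc_config(chains = 2, iter = 1500, seed = 3,
                                    sd_obs = 1e-3))
  d0 <- traitsets:::flat_draws(fit0, "mu_sp")[, 1]
  expect_lt(abs(mean(d0) - 0.5), 1e-3)
  expect_lt(sd(d0), 1e-2)
})

test_that("congeners shrink toward the genus mean", {
  set.seed(3)
  tax <- hand_taxonomy(c("s1", "s2"), c("g1", "g1"), c("f1", "f1"))
  y1 <- rnorm(6, 1, 0.3); y2 <- rnorm(6, -1, 0.3)
  rec <- data.frame(species_id = rep(c("s1", "s2"), each = 6),
                    value = c(y1, y2))
  mc <- mcmc_config(chains = 2, iter = 3000, seed = 7, sd_obs = 0.3,
                    sd_sp_fixed = 0.5)
  fit <- fit_hierarchy(rec, tax, mc)
  sp <- traitsets:::flat_draws(fit, "mu_sp")
  gmean <- mean(traitsets:::flat_draws(fit, "mu_g")[, 1])
  m1 <- mean(sp[, match("s1", fit$species)])
  m2 <- mean(sp[, match("s2", fit$species)])
  # each posterior mean lies strictly between its sample mean and the
  # genus mean estimate (conjugate shrinkage property)
  expect_true(m1 < mean(y1) && m1 > gmean)
  expect_true(m2 > mean(y2) && m2 < gmean)
  # closed-form check of the same property
  oracle <- conjugate_hierarchy_posterior(rec, tax, 0.3, 0.5, 0.5, 0.5)
  expect_true(oracle$mean[oracle$idx$s[1]] < mean(y1))
  expect_true(oracle$mean[oracle$idx$s[1]] > oracle$mean[oracle$idx$g[1]])
})

test_that("imputation falls back through the hierarchy with growing sd", {
  set.seed(4)
  tax <- hand_taxonomy(sprintf("s%02d", 1:9),
                       rep(c("g1", "g2", "g3"), each = 3),
                       rep(c("f1", "f1", "f2"), each = 3))
  # data for 2 of 3 species in g1, all of g2; none for g3 (family f2)
  with_data <- c("s01", "s02", "s04", "s05", "s06")
  rec <- data.frame(species_id = rep(with_data, each = 6),
                    value = rnorm(30, rep(c(1, 1.3, -0.5, 0, 0.4), each = 6),
                                  0.4))
  fit <- fit_hierarchy(rec, tax, fast_mcmc(sd_obs = 0.4))

  imp <- impute_species_mean(fit, c("s03", "s07"), tax, seed = 1)
  expect_identical(imp$provenance, rep("imputed_taxonomic", 2))
  expect_identical(imp$n_records, c(0L, 0L))
  # genus-level imputation tracks the genus posterior mean
  g1 <- mean(traitsets:::flat_draws(fit, "mu_g")[, match("g1", fit$genera)])
  expect_lt(abs(imp$mean[1] - g1), 0.15)
  # family-with-no-data fallback is more uncertain than the genus case
  expect_gt(imp$sd[2], imp$sd[1])
  # global fallback tracks the global mean, roughly
  glob <- mean(traitsets:::flat_draws(fit, "mu_global")[, 1])
  expect_lt(abs(imp$mean[2] - glob), 0.8)

  # observed species are returned unchanged (posterior summary, measured)
  obs <- impute_species_mean(fit, "s01", tax)
  expect_identical(obs$provenance, "measured")
  expect_gte(obs$n_records, 1L)
  expect_error(impute_species_mean(fit, "zz", tax), "not in taxonomy")
})

test_that("leave-out R2 reflects the taxonomic signal in the world", {
  # strong genus signal: species within genus nearly identical
  cfg_sig <- world_config(n_families = 8, genera_per_family = 3,
                          species_per_genus = 4, sd_f = 0.6, sd_g = 0.8,
                          sd_sp_scale = 0.1, trait_names = "sla",
                          p_onsite_found = 0, p_offsite_covered = 1,
                          offsite_n_mean = 6, sd_obs_offsite = 0.3,
                          seed = 31)
  w <- generate_world(cfg_sig)
  p <- log_standardize(w$records$value)$params
  std <- data.frame(species_id = w$records$species_id,
                    value = log_standardize(w$records$value, p)$values)
  subset <- sample(unique(std$species_id), 30)
  ev <- evaluate_by_leave_out(std, w$taxonomy, subset, fast_mcmc())
  expect_gt(ev$r2, 0.5)

  # no taxonomic signal: iid species means, no predictive skill
  cfg_null <- world_config(n_families = 50, genera_per_family = 2,
                           species_per_genus = 2, sd_f = 0, sd_g = 0,
                           sd_sp_scale = 1, trait_names = "sla",
                           p_onsite_found = 0, p_offsite_covered = 1,
                           offsite_n_mean = 6, sd_obs_offsite = 0.3,
                           seed = 32)
  w0 <- generate_world(cfg_null)
  p0 <- log_standardize(w0$records$value)$params
  std0 <- data.frame(species_id = w0$records$species_id,
                     value = log_standardize(w0$records$value, p0)$values)
  sub0 <- sample(unique(std0$species_id), 40)
  ev0 <- evaluate_by_leave_out(std0, w0$taxonomy, sub0, fast_mcmc())
  expect_lt(ev0$r2, 0.1)

  expect_error(evaluate_by_leave_out(std, w$taxonomy, character(0)),
               "empty")
  # R2 wiring: identical observed/imputed pairs give exactly 1
  pairs <- data.frame(observed = c(1, 2, 3), imputed = c(1, 2, 3))
  expect_equal(traitsets:::leave_out_r2(pairs), 1)
})

test_that("posterior summaries are invariant to record order", {
  set.seed(6)
  tax <- hand_taxonomy(c("s1", "s2"), c("g1", "g1"), c("f1", "f1"))
  rec <- data.frame(species_id = rep(c("s1", "s2"), each = 5),
                    value = rnorm(10))
  f1 <- fit_hierarchy(rec, tax, fast_mcmc())
  f2 <- fit_hierarchy(rec[sample(nrow(rec)), ], tax, fast_mcmc())
  expect_equal(traitsets:::flat_draws(f1, "mu_sp"),
               traitsets:::flat_draws(f2, "mu_sp"), tolerance = 1e-8)
})
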