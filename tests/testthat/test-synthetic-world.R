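test_that("taxonomy generation respects counts, nesting and determinism", {
  cfg <- world_config(n_families = 3, genera_per_family = 2,
                      species_per_genus = 4, seed = 1)
  tax <- generate_taxonomy(cfg)
  expect_equal(nrow(tax), 24L)
  expect_equal(length(unique(tax$genus)), 6L)
  expect_equal(length(unique(tax$family)), 3L)
  expect_false(anyDuplicated(tax$species_id) > 0)
  # each genus maps to exactly one family
  expect_true(all(tapply(tax$family, tax$genus,
                         function(f) length(unique(f))) == 1L))
  expect_identical(tax, generate_taxonomy(cfg))

  one <- generate_taxonomy(world_config(n_families = 1,
                                        genera_per_family = 1,
                                        species_per_genus = 1))
  expect_equal(nrow(one), 1L)
  expect_error(world_config(n_families = 0), "counts")
})

test_that("true means follow the nested hierarchy and injected correlation", {
  # degenerate variances: every species mean equals the global mean
  cfg0 <- world_config(n_families = 3, genera_per_family = 2,
                       species_per_genus = 2, sd_f = 0, sd_g = 0,
                       sd_sp_scale = 0, mu_global = c(1.5, -2, 0), seed = 2)
  tm0 <- generate_true_means(generate_taxonomy(cfg0), cfg0)
  expect_true(all(abs(tm0[, "sla"] - 1.5) < 1e-12))
  expect_true(all(abs(tm0[, "height"] + 2) < 1e-12))

  # correlation oracle over a large world: sample correlation of species
  # deviations matches the configured value within MC error
  cc <- diag(3); cc[1, 2] <- cc[2, 1] <- 0.8
  cfg <- world_config(n_families = 250, genera_per_family = 2,
                      species_per_genus = 4, sd_f = 0, sd_g = 0,
                      sd_sp_scale = 1, cross_trait_corr = cc, seed = 3)
  tm <- generate_true_means(generate_taxonomy(cfg), cfg)
  expect_gt(nrow(tm), 1999)
  expect_lt(abs(cor(tm[, "sla"], tm[, "height"]) - 0.8), 0.05)
  expect_lt(abs(cor(tm[, "sla"], tm[, "seed_mass"])), 0.05)

  expect_error(world_config(cross_trait_corr = matrix(c(1, 2, 2, 1), 2),
                            trait_names = c("a", "b")),
               "positive-definite")
})

test_that("variance of species means decomposes into the level variances", {
  cfg <- world_config(n_families = 200, genera_per_family = 3,
                      species_per_genus = 4, sd_f = 0.5, sd_g = 0.4,
                      sd_sp_scale = 0.8, seed = 4)
  tm <- generate_true_means(generate_taxonomy(cfg), cfg)
  expected <- 0.5^2 + 0.4^2 + 0.8^2
  expect_lt(abs(var(tm[, "sla"]) / expected - 1), 0.10)
})

test_that("phylogeny construction orders patristic distances by taxonomy", {
  w <- small_world()
  tree <- w$phylogeny
  expect_setequal(tree$tip.label, w$taxonomy$species_id)

  d <- ape::cophenetic.phylo(tree)
  tax <- w$taxonomy
  same_genus <- outer(tax$genus, tax$genus, "==")
  same_family <- outer(tax$family, tax$family, "==")
  off <- upper.tri(d)
  dg <- d[match(tax$species_id, rownames(d)),
          match(tax$species_id, colnames(d))]
  expect_lt(max(dg[same_genus & off]),
            min(dg[same_family & !same_genus & off]))
  expect_lt(max(dg[same_family & !same_genus & off]),
            min(dg[!same_family & off]))

  # round-trips through newick unchanged (patristic distances preserved)
  path <- tempfile(fileext = ".nwk")
  write_newick(tree, path)
  tree2 <- read_newick(path)
  d2 <- ape::cophenetic.phylo(tree2)
  expect_equal(d2[rownames(d), colnames(d)], d, tolerance = 1e-12)

  # two congeners + outgroup: the congeners are mutual nearest tips
  tax3 <- hand_taxonomy(c("a", "b", "c"), c("g1", "g1", "g2"),
                        c("f1", "f1", "f2"))
  t3 <- generate_phylogeny(tax3)
  d3 <- ape::cophenetic.phylo(t3)
  expect_equal(names(which.min(d3["a", c("b", "c")])), "b")
  expect_error(generate_phylogeny(tax3[1, ]), "at least 2")
})

test_that("record sampling honours coverage, noise and count settings", {
  cfg <- world_config(n_families = 3, genera_per_family = 2,
                      species_per_genus = 2, p_offsite_covered = 0,
                      p_onsite_found = 1, sd_obs_onsite = 0, seed = 5)
  tm <- generate_true_means(generate_taxonomy(cfg), cfg)
  rec <- sample_records(tm, cfg)
  expect_false(any(rec$source == "off_site"))
  # noiseless on-site records equal exp(true log mean)
  for (i in seq_len(nrow(rec))) {
    expect_equal(rec$value[i],
                 exp(tm[rec$species_id[i], rec$trait[i]]), tolerance = 1e-12)
  }
  expect_true(all(rec$value > 0))

  # law of large numbers for the off-site count model
  cfg2 <- world_config(n_families = 250, genera_per_family = 1,
                       species_per_genus = 2, trait_names = "sla",
                       p_onsite_found = 0, p_offsite_covered = 1,
                       offsite_n_mean = 12, seed = 6)
  tm2 <- generate_true_means(generate_taxonomy(cfg2), cfg2)
  rec2 <- sample_records(tm2, cfg2)
  per_sp <- table(rec2$species_id)
  expect_equal(length(per_sp), 500L)
  expect_lt(abs(mean(per_sp) - 12), 0.5)
})

test_that("off-site dispersion exceeds on-site when configured that way", {
  w <- small_world(seed = 11, p_onsite_found = 1, p_offsite_covered = 1,
                   sd_obs_onsite = 0.2, sd_obs_offsite = 0.6,
                   offsite_n_mean = 8)
  r <- w$records[w$records$trait == "sla", ]
  disp <- function(src) {
    sub <- r[r$source == src, ]
    mean(tapply(log(sub$value), sub$species_id, sd), na.rm = TRUE)
  }
  expect_gt(disp("off_site"), disp("on_site"))
})

test_that("invasiveness generation follows the latent linear model", {
  # zero effects, zero noise: constant latent response
  cfg <- world_config(n_families = 3, genera_per_family = 2,
                      species_per_genus = 2,
                      beta_true = list(local_abundance = c(sla = 0),
                                       spread_rate = c(height = 0)),
                      response_noise_sd = 0, seed = 8)
  tm <- generate_true_means(generate_taxonomy(cfg), cfg)
  inv <- generate_invasiveness(tm, cfg)
  expect_lt(diff(range(qlogis(inv$local_abundance))), 1e-12)
  expect_lt(diff(range(log(inv$spread_rate))), 1e-12)

  # zero noise: least squares on the latent scale recovers beta exactly
  beta <- c(sla = -0.4, seed_mass = 0.25, min_residence_time = 0.15)
  cfg2 <- world_config(n_families = 25, genera_per_family = 2,
                       species_per_genus = 3,
                       beta_true = list(local_abundance = beta,
                                        spread_rate = c(height = 0.3)),
                       response_noise_sd = 0, seed = 9)
  tm2 <- generate_true_means(generate_taxonomy(cfg2), cfg2)
  inv2 <- generate_invasiveness(tm2, cfg2)
  std <- function(x) (x - mean(x)) / sd(x)
  fit <- lm(qlogis(inv2$local_abundance) ~ std(tm2[, "sla"]) +
              std(tm2[, "seed_mass"]) + std(inv2$min_residence_time))
  expect_equal(unname(coef(fit)[-1]), unname(beta), tolerance = 1e-9)

  # noisy case: OLS estimate within sampling error of truth
  cfg3 <- world_config(n_families = 25, genera_per_family = 3,
                       species_per_genus = 4,
                       beta_true = list(local_abundance = c(sla = -0.3),
                                        spread_rate = c(height = 0.3)),
                       response_noise_sd = 0.5, seed = 10)
  tm3 <- generate_true_means(generate_taxonomy(cfg3), cfg3)
  inv3 <- generate_invasiveness(tm3, cfg3)
  fit3 <- lm(qlogis(inv3$local_abundance) ~ std(tm3[, "sla"]))
  expect_lt(abs(coef(fit3)[2] - (-0.3)), 0.1)
})

test_that("worlds are fully deterministic given their configuration", {
  w1 <- small_world(seed = 21)
  w2 <- small_world(seed = 21)
  expect_identical(w1$taxonomy, w2$taxonomy)
  expect_identical(w1$true_means, w2$true_means)
  expect_identical(w1$records, w2$records)
  expect_identical(w1$invasiveness, w2$invasiveness)
  expect_identical(ape::write.tree(w1$phylogeny),
                   ape::write.tree(w2$phylogeny))
  w3 <- small_world(seed = 22)
  expect_false(identical(w1$records, w3$records))
})
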