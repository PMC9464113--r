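light_engines <- function() {
  engines_config(mcmc = mcmc_config(chains = 2, iter = 1200, seed = 1),
                 pmf = pmf_config(iter = 400))
}

assembly_world <- function(seed = 51) {
  generate_world(world_config(n_families = 6, genera_per_family = 3,
                              species_per_genus = 3, p_onsite_found = 0.5,
                              p_offsite_covered = 0.65, seed = seed))
}

test_that("strategy I averages log on-site records (geometric mean)", {
  rec <- rbind(hand_records(values = c(exp(0), exp(2)), species = c("s1", "s1")),
               hand_records(values = c(exp(1), exp(3)), species = c("s2", "s2")),
               hand_records(values = exp(c(0.5, 1.5, 2.5)),
                            species = rep("s3", 3), source = "off_site"))
  tax <- hand_taxonomy(c("s1", "s2", "s3"), rep("g1", 3), rep("f1", 3))
  ds <- build_dataset("I", rec, tax, target_species = c("s1", "s2"),
                      trait = "sla")
  # back-transformed means are the geometric means of the raw records
  raw <- inverse_log_standardize(ds$summaries$mean, ds$transform)
  expect_equal(raw[ds$summaries$species_id == "s1"], exp(1),
               tolerance = 1e-10)
  expect_equal(raw[ds$summaries$species_id == "s2"], exp(2),
               tolerance = 1e-10)
  expect_identical(unique(ds$summaries$provenance), "measured")
  expect_equal(ds$summaries$n_records, c(2L, 2L))
})

test_that("strategies fill gaps with the right provenance and rosters", {
  w <- assembly_world()
  rec <- filter_records(w$records)$records
  tgt <- sort(unique(rec$species_id[rec$source == "on_site"]))
  eng <- light_engines()
  ds <- lapply(c(I = "I", II = "II", III = "III", IV = "IV", V = "V",
                 VI = "VI"), function(s)
    build_dataset(s, rec, w$taxonomy, w$phylogeny, target_species = tgt,
                  trait = "sla", engines = eng, seed = 3))

  # roster invariants
  expect_setequal(ds$I$roster, tgt)
  expect_setequal(ds$II$roster, tgt)
  expect_setequal(ds$V$roster, tgt)
  expect_lte(length(ds$III$roster), length(ds$II$roster))
  expect_lte(length(ds$IV$roster), length(ds$II$roster))
  # VI takes every species with off-site records, ignoring the target set
  off_sp <- unique(rec$species_id[rec$trait == "sla" &
                                    rec$source == "off_site"])
  expect_setequal(ds$VI$roster, off_sp)

  # provenance rules: off-site species stay measured, gaps get imputed
  off_in_tgt <- intersect(tgt, off_sp)
  gaps <- setdiff(tgt, off_sp)
  s2 <- ds$II$summaries
  expect_identical(unique(s2$provenance[s2$species_id %in% off_in_tgt]),
                   "measured")
  expect_identical(unique(s2$provenance[s2$species_id %in% gaps]),
                   "imputed_taxonomic")
  expect_identical(unique(ds$V$summaries$provenance), "fused")

  # II, III, IV agree exactly on measured species
  for (other in list(ds$III, ds$IV)) {
    so <- other$summaries
    common <- intersect(off_in_tgt, so$species_id)
    expect_equal(so$mean[match(common, so$species_id)],
                 s2$mean[match(common, s2$species_id)], tolerance = 1e-12)
  }
  expect_error(build_dataset("VII", rec, w$taxonomy), "unknown strategy")
  expect_error(build_dataset("II", rec, w$taxonomy, trait = "sla"),
               "target_species")
})

test_that("dataset correlations match brute-force formulas on hand pairs", {
  mk <- function(means, ids = paste0("s", seq_along(means))) {
    structure(list(strategy = "I_onsite", trait = "sla",
                   summaries = data.frame(species_id = ids, mean = means,
                                          sd = 0, n_records = 1,
                                          provenance = "measured"),
                   roster = ids, transform = list(mean = 0, sd = 1),
                   report = list()),
              class = "trait_dataset")
  }
  d1 <- mk(c(1, 2, 3)); d2 <- mk(c(2, 1, 3))
  cmp <- compare_datasets(d1, d2)
  # brute force: r = cov/(sd sd) = 0.5; rho over ranks = 1 - 6*2/24 = 0.5
  expect_equal(cmp$pearson_r, 0.5, tolerance = 1e-12)
  expect_equal(cmp$spearman_rho, 0.5, tolerance = 1e-12)
  expect_equal(cmp$n_common, 3L)

  ident <- compare_datasets(d1, d1)
  expect_equal(ident$pearson_r, 1)
  expect_equal(ident$spearman_rho, 1)

  # monotone nonlinear transform: rho stays 1, r drops below 1
  d3 <- mk(c(1, 2, 3)^3)
  cmp3 <- compare_datasets(d1, d3)
  expect_equal(cmp3$spearman_rho, 1)
  expect_lt(cmp3$pearson_r, 1)

  expect_error(compare_datasets(mk(c(1, 2)), mk(c(2, 1))), "at least 3")
})

test_that("on/off-site correlation is exact on noiseless worlds and hand data", {
  w0 <- generate_world(world_config(n_families = 4, genera_per_family = 2,
                                    species_per_genus = 2,
                                    p_onsite_found = 1,
                                    p_offsite_covered = 1,
                                    sd_obs_onsite = 0, sd_obs_offsite = 0,
                                    seed = 52))
  res <- onsite_offsite_correlation(w0$records)
  expect_true(all(abs(res$pearson_r - 1) < 1e-12))

  # textbook Pearson on constructed pairs
  rec <- rbind(
    hand_records(values = exp(c(1, 1)), species = c("a", "a")),
    hand_records(values = exp(c(2, 2)), species = c("b", "b")),
    hand_records(values = exp(c(4, 4)), species = c("c", "c")),
    hand_records(values = exp(c(2, 2)), species = c("a", "a"),
                 source = "off_site"),
    hand_records(values = exp(c(1, 1)), species = c("b", "b"),
                 source = "off_site"),
    hand_records(values = exp(c(3, 3)), species = c("c", "c"),
                 source = "off_site"))
  res2 <- onsite_offsite_correlation(rec)
  x <- c(1, 2, 4); y <- c(2, 1, 3)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res2$pearson_r, r_hand, tolerance = 1e-12)
  pairs <- attr(res2, "pairs")
  expect_equal(nrow(pairs), 3L)
})

test_that("measurement noise attenuates the on/off-site correlation as predicted", {
  # single trait, iid species means (var 1), equal noise both sources
  cfg <- world_config(n_families = 300, genera_per_family = 1,
                      species_per_genus = 2, trait_names = "sla",
                      sd_f = 0, sd_g = 0, sd_sp_scale = 1,
                      sd_obs_onsite = 0.5, sd_obs_offsite = 0.5,
                      onsite_n = 5, offsite_n_mean = 5,
                      p_onsite_found = 1, p_offsite_covered = 1, seed = 53)
  w <- generate_world(cfg)
  res <- onsite_offsite_correlation(w$records)
  # attenuation: r = 1/sqrt((1 + v_on)(1 + v_off)) with v = sd^2 * E[1/n]
  v_on <- 0.25 / 5
  n_off <- table(w$records$species_id[w$records$source == "off_site"])
  v_off <- 0.25 * mean(1 / n_off)
  expected <- 1 / sqrt((1 + v_on) * (1 + v_off))
  expect_lt(abs(res$pearson_r - expected), 0.05)
})
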