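# Shared fixtures built in code.

small_world <- function(seed = 7L, ...) {
  generate_world(world_config(n_families = 4, genera_per_family = 2,
                              species_per_genus = 3, seed = seed, ...))
}

# a record table built by hand (valid under the reader contract)
hand_records <- function(values = c(1, 2, 3),
                         species = c("s1", "s1", "s2"),
                         trait = "sla", source = "on_site") {
  data.frame(species_id = species, trait = trait, value = values,
             source = source, woody_flag = FALSE,
             shade_or_experimental_flag = FALSE, immature_flag = FALSE,
             out_of_env_flag = FALSE, stringsAsFactors = FALSE)
}

hand_taxonomy <- function(species, genus, family) {
  data.frame(species_id = species, genus = genus, family = family,
             stringsAsFactors = FALSE)
}

# Exact posterior of the jointly Gaussian hierarchy (all sds fixed):
# brute-force precision-matrix assembly over theta =
# (mu_global, mu_f..., mu_g..., mu_sp...), conditioned on per-species
# sufficient statistics. Independent of the Gibbs implementation.
conjugate_hierarchy_posterior <- function(records, taxonomy, sd_obs, sd_sp,
                                          sd_g, sd_f, global_prior_sd = 10) {
  sp <- sort(unique(records$species_id))
  tax <- taxonomy[match(sp, taxonomy$species_id), ]
  gen <- sort(unique(tax$genus)); fam <- sort(unique(tax$family))
  p <- 1L + length(fam) + length(gen) + length(sp)
  i_glob <- 1L
  i_f <- 1L + seq_along(fam)
  i_g <- 1L + length(fam) + seq_along(gen)
  i_s <- 1L + length(fam) + length(gen) + seq_along(sp)
  Q <- matrix(0, p, p); b <- numeric(p)
  add_pair <- function(i, j, v) {
    Q[i, i] <<- Q[i, i] + v; Q[j, j] <<- Q[j, j] + v
    Q[i, j] <<- Q[i, j] - v; Q[j, i] <<- Q[j, i] - v
  }
  Q[i_glob, i_glob] <- 1 / global_prior_sd^2
  for (k in seq_along(fam)) add_pair(i_f[k], i_glob, 1 / sd_f^2)
  for (k in seq_along(gen)) {
    fk <- match(taxonomy$family[match(gen[k], taxonomy$genus)], fam)
    add_pair(i_g[k], i_f[fk], 1 / sd_g^2)
  }
  for (k in seq_along(sp)) {
    gk <- match(tax$genus[k], gen)
    add_pair(i_s[k], i_g[gk], 1 / sd_sp^2)
    ys <- records$value[records$species_id == sp[k]]
    Q[i_s[k], i_s[k]] <- Q[i_s[k], i_s[k]] + length(ys) / sd_obs^2
    b[i_s[k]] <- sum(ys) / sd_obs^2
  }
  Sigma <- solve(Q)
  list(mean = as.numeric(Sigma %*% b), sd = sqrt(diag(Sigma)),
       species = sp, genera = gen, families = fam,
       idx = list(global = i_glob, f = i_f, g = i_g, s = i_s))
}
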