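#' Configuration of a synthetic trait world
#'
#' Bundles every parameter of the ground-truth generative model used by
#' [generate_world()]: the taxonomic design (families, genera per family,
#' species per genus), the variance components of the nested normal hierarchy
#' on the natural-log trait scale, the cross-trait correlation injected at the
#' species level, the on-site/off-site sampling design, and the linear
#' trait-invasiveness model used to emit response variables.
#'
#' Traits live on the natural-log scale throughout: species true means are
#' sums of independent family, genus and species-level normal deviates, and
#' raw records are exponentials of noisy log values, so every record is
#' strictly positive.
#'
#' @param n_families Number of families.
#' @param genera_per_family Genera per family; a single count or a length-2
#'   inclusive range sampled uniformly per family.
#' @param species_per_genus Species per genus; count or length-2 range.
#' @param trait_names Character vector of trait names. The defaults mirror a
#'   typical invasion-ecology panel: specific leaf area, vegetative height and
#'   seed mass.
#' @param mu_global Global log-scale mean per trait (recycled to
#'   `length(trait_names)`).
#' @param sd_f,sd_g,sd_sp_scale Standard deviations of family, genus and
#'   species deviations on the log scale. `sd_sp_scale` may be a scalar or one
#'   value per trait. Zero is allowed (degenerate, useful for testing).
#' @param sd_obs_onsite,sd_obs_offsite Log-scale observation noise of on-site
#'   and off-site records. Off-site records are typically noisier because they
#'   pool measurements from the species' whole range.
#' @param cross_trait_corr Correlation matrix over traits applied to the
#'   species-level deviations (family/genus deviations are trait-independent).
#'   Must be symmetric positive-definite.
#' @param onsite_n Records per species found on-site.
#' @param offsite_n_mean Mean off-site records per covered species-trait; the
#'   count is drawn as `1 + Poisson(offsite_n_mean - 1)` so covered species
#'   always have at least one record.
#' @param p_onsite_found Probability that a species is found on-site (one
#'   draw per species; found species are measured for all traits).
#' @param p_offsite_covered Probability that a (species, trait) cell has any
#'   off-site coverage; drawn independently per cell so that species can be
#'   covered for some traits and not others.
#' @param offsite_bias_sd Standard deviation of an optional per-species latent
#'   shifting off-site coverage odds (database bias toward widespread species);
#'   0 disables it.
#' @param flag_probs Named probabilities for the four record exclusion flags
#'   (`woody`, `shade_or_experimental`, `immature`, `out_of_env`); all 0 by
#'   default.
#' @param alpha_true,beta_true Intercepts and effect sizes of the latent
#'   linear invasiveness model; `beta_true` is a list with named vectors for
#'   `local_abundance` (over sla, seed_mass, min_residence_time) and
#'   `spread_rate` (over height, seed_mass, longevity), on standardized
#'   predictor scales.
#' @param response_noise_sd Residual sd of the latent invasiveness responses.
#' @param seed Integer seed; every stage of world generation derives its own
#'   sub-stream deterministically from it.
#'
#' @return An object of class `world_config` (a validated list).
#' @seealso [generate_world()]
#' @export
world_config <- function(n_families = 10L,
                         genera_per_family = 3L,
                         species_per_genus = 4L,
                         trait_names = c("sla", "height", "seed_mass"),
                         mu_global = 0,
                         sd_f = 0.5,
                         sd_g = 0.5,
                         sd_sp_scale = 1,
                         sd_obs_onsite = 0.3,
                         sd_obs_offsite = 0.5,
                         cross_trait_corr = diag(length(trait_names)),
                         onsite_n = 5L,
                         offsite_n_mean = 10,
                         p_onsite_found = 0.5,
                         p_offsite_covered = 0.6,
                         offsite_bias_sd = 0,
                         flag_probs = c(woody = 0, shade_or_experimental = 0,
                                        immature = 0, out_of_env = 0),
                         alpha_true = c(local_abundance = 0, spread_rate = 0),
                         beta_true = list(
                           local_abundance = c(sla = -0.3, seed_mass = 0.2,
                                               min_residence_time = 0.2),
                           spread_rate = c(height = 0.3, seed_mass = -0.2,
                                           longevity = -0.2)),
                         response_noise_sd = 1,
                         seed = 1L) {
  cfg <- list(
    n_families = as.integer(n_families),
    genera_per_family = as.integer(genera_per_family),
    species_per_genus = as.integer(species_per_genus),
    trait_names = as.character(trait_names),
    mu_global = rep_len(as.numeric(mu_global), length(trait_names)),
    sd_f = as.numeric(sd_f),
    sd_g = as.numeric(sd_g),
    sd_sp_scale = rep_len(as.numeric(sd_sp_scale), length(trait_names)),
    sd_obs_onsite = as.numeric(sd_obs_onsite),
    sd_obs_offsite = as.numeric(sd_obs_offsite),
    cross_trait_corr = as.matrix(cross_trait_corr),
    onsite_n = as.integer(onsite_n),
    offsite_n_mean = as.numeric(offsite_n_mean),
    p_onsite_found = as.numeric(p_onsite_found),
    p_offsite_covered = as.numeric(p_offsite_covered),
    offsite_bias_sd = as.numeric(offsite_bias_sd),
    flag_probs = flag_probs,
    alpha_true = alpha_true,
    beta_true = beta_true,
    response_noise_sd = as.numeric(response_noise_sd),
    seed = as.integer(seed)
  )
  names(cfg$mu_global) <- cfg$trait_names
  names(cfg$sd_sp_scale) <- cfg$trait_names
  # effects on predictors this world does not generate are dropped, so the
  # default effect sizes remain usable under reduced trait panels
  allowed <- c(cfg$trait_names, "min_residence_time", "longevity")
  cfg$beta_true <- lapply(cfg$beta_true,
                          function(b) b[names(b) %in% allowed])
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  nt <- length(cfg$trait_names)
  if (nt < 1L) stop("at least one trait is required", call. = FALSE)
  if (cfg$n_families < 1L ||
      any(cfg$genera_per_family < 1L) || any(cfg$species_per_genus < 1L))
    stop("taxonomy counts must all be >= 1", call. = FALSE)
  if (length(cfg$genera_per_family) > 2L || length(cfg$species_per_genus) > 2L)
    stop("genera_per_family and species_per_genus must be a count or a length-2 range",
         call. = FALSE)
  sds <- c(cfg$sd_f, cfg$sd_g, cfg$sd_sp_scale,
           cfg$sd_obs_onsite, cfg$sd_obs_offsite, cfg$response_noise_sd)
  if (any(!is.finite(sds)) || any(sds < 0))
    stop("all standard deviations must be finite and >= 0", call. = FALSE)
  pr <- c(cfg$p_onsite_found, cfg$p_offsite_covered, cfg$flag_probs)
  if (any(pr < 0 | pr > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  cc <- cfg$cross_trait_corr
  if (!is.matrix(cc) || nrow(cc) != nt || ncol(cc) != nt)
    stop("cross_trait_corr must be a ", nt, "x", nt, " matrix", call. = FALSE)
  if (max(abs(cc - t(cc))) > 1e-8 || any(abs(diag(cc) - 1) > 1e-8))
    stop("cross_trait_corr must be symmetric with unit diagonal", call. = FALSE)
  ch <- try(chol(cc), silent = TRUE)
  if (inherits(ch, "try-error"))
    stop("cross_trait_corr is not positive-definite", call. = FALSE)
  if (cfg$onsite_n < 1L || cfg$offsite_n_mean < 1)
    stop("onsite_n and offsite_n_mean must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.world_config <- function(x, ...) {
  n_g <- mean(x$genera_per_family)
  n_s <- mean(x$species_per_genus)
  cat("Synthetic trait world configuration\n")
  cat(sprintf("  taxonomy: %d families x ~%.1f genera x ~%.1f species (~%d species)\n",
              x$n_families, n_g, n_s, round(x$n_families * n_g * n_s)))
  cat(sprintf("  traits: %s\n", paste(x$trait_names, collapse = ", ")))
  cat(sprintf("  log-scale sds: family %.2f, genus %.2f, species %s\n",
              x$sd_f, x$sd_g, paste(format(x$sd_sp_scale), collapse = "/")))
  cat(sprintf("  sampling: on-site n=%d (p=%.2f, sd=%.2f); off-site mean n=%.1f (p=%.2f, sd=%.2f)\n",
              x$onsite_n, x$p_onsite_found, x$sd_obs_onsite,
              x$offsite_n_mean, x$p_offsite_covered, x$sd_obs_offsite))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Deterministic per-stage sub-seed so partial reruns of a stage reproduce the
# full-world draw for that stage.
stage_seed <- function(seed, stage) {
  stages <- c(taxonomy = 1L, true_means = 2L, phylogeny = 3L,
              records = 4L, invasiveness = 5L)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage, call. = FALSE)
  (abs(as.integer(seed)) + 104729L * stages[[stage]]) %% 2147483629L
}
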