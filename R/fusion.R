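#' Cap off-site records per species
#'
#' Limits the off-site pool to at most `max_per_species` records per
#' (species, trait), sampled uniformly without replacement, so that priors
#' estimated from the pool and a comparably-sized on-site sample contribute
#' on equal footing when fused.
#'
#' @param records Off-site record data.frame (long format).
#' @param max_per_species Cap per (species, trait).
#' @param seed Integer seed; the subsample is deterministic given it.
#' @return The subsampled records (original row order preserved).
#' @export
subsample_offsite <- function(records, max_per_species = 5L, seed = 1L) {
  if (nrow(records) == 0L) return(records)
  if (any(records$source != "off_site"))
    stop("subsample_offsite expects off-site records only", call. = FALSE)
  set.seed(as.integer(seed))
  key <- paste(records$species_id, records$trait)
  keep <- unlist(lapply(split(seq_len(nrow(records)), key), function(idx) {
    if (length(idx) <= max_per_species) idx
    else sort(sample(idx, max_per_species))
  }), use.names = FALSE)
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate per-species priors from the off-site pool
#'
#' Fits the taxonomy-nested hierarchy to the (typically capped) off-site
#' pool and returns, for each target species, the posterior mean and sd of
#' its species-level mean — the prior used by [fuse()]. Species without
#' off-site data receive level-fallback priors (genus, then family, then
#' global), whose sd grows with every fallback level.
#'
#' @param records Standardized off-site records (`species_id`, `value`),
#'   usually after [subsample_offsite()].
#' @param taxonomy Taxonomy table.
#' @param target_species Species requiring priors.
#' @param mcmc An [mcmc_config()].
#' @return A data.frame (`species_id`, `prior_mean`, `prior_sd`,
#'   `prior_source` = measured/imputed_taxonomic).
#' @export
estimate_priors <- function(records, taxonomy, target_species,
                            mcmc = mcmc_config()) {
  fit <- fit_hierarchy(records, taxonomy, mcmc)
  imp <- impute_species_mean(fit, target_species, taxonomy, seed = mcmc$seed)
  data.frame(species_id = imp$species_id,
             prior_mean = imp$mean, prior_sd = imp$sd,
             prior_source = imp$provenance, stringsAsFactors = FALSE)
}

#' Fuse on-site records with off-site priors
#'
#' Per species, updates the prior `N(prior_mean, prior_sd)` on the species
#' mean with the on-site observations under a normal likelihood
#' `N(mu_s, sd_t)`. With `sd_t` fixed the posterior is the exact conjugate
#' normal-normal solution
#' \deqn{1/\sigma_n^2 = 1/\sigma_0^2 + n/sd_t^2, \qquad
#'       \mu_n = \sigma_n^2 (\mu_0/\sigma_0^2 + n\bar y/sd_t^2);}
#' with `sd_t = NULL` a shared-per-trait residual sd is estimated by Gibbs
#' under a weakly-informative inverse-gamma prior on its square, and the
#' posterior summaries are across-draw means/sds. The `prior_weight` w
#' rescales every prior sd by `1/sqrt(w)`: w = 1 keeps the sources on equal
#' footing, w < 1 downweights the off-site prior toward the on-site data.
#'
#' @param onsite_records Standardized on-site records (`species_id`,
#'   `value`).
#' @param priors Data.frame from [estimate_priors()] (columns `species_id`,
#'   `prior_mean`, `prior_sd`) covering every on-site species.
#' @param sd_t Fixed observation sd, or NULL to estimate it.
#' @param prior_weight Prior weight w (> 0), default 1.
#' @param gibbs_iter,gibbs_burnin,ig_shape,ig_scale,seed Settings for the
#'   estimated-sd path.
#' @return A data.frame (`species_id`, `mean`, `sd`, `n_records`,
#'   `provenance = "fused"`, `prior_only`); species in `priors` with no
#'   on-site records keep their prior and are flagged `prior_only`.
#' @export
fuse <- function(onsite_records, priors, sd_t = NULL, prior_weight = 1,
                 gibbs_iter = 2000L, gibbs_burnin = 1000L,
                 ig_shape = 2, ig_scale = 0.5, seed = 1L) {
  stopifnot(prior_weight > 0, all(c("species_id", "prior_mean", "prior_sd")
                                  %in% names(priors)))
  sp_on <- unique(onsite_records$species_id)
  no_prior <- setdiff(sp_on, priors$species_id)
  if (length(no_prior) > 0L)
    stop("on-site species without a prior: ",
         paste(no_prior, collapse = ", "), call. = FALSE)
  species <- priors$species_id
  mu0 <- priors$prior_mean
  sd0 <- priors$prior_sd / sqrt(prior_weight)
  if (any(!is.finite(sd0) | sd0 <= 0))
    stop("prior sds must be positive and finite", call. = FALSE)
  n_i <- vapply(species, function(s)
    sum(onsite_records$species_id == s), 0L)
  ybar <- vapply(species, function(s) {
    v <- onsite_records$value[onsite_records$species_id == s]
    if (length(v) == 0L) NA_real_ else mean(v)
  }, 0)

  if (!is.null(sd_t)) {
    stopifnot(sd_t > 0)
    prec <- 1 / sd0^2 + n_i / sd_t^2
    post_mean <- ifelse(n_i > 0L,
                        (mu0 / sd0^2 + n_i * ybar / sd_t^2) / prec, mu0)
    post_sd <- ifelse(n_i > 0L, sqrt(1 / prec), sd0)
  } else {
    # shared residual sd per trait, estimated by Gibbs
    set.seed(as.integer(seed))
    y <- onsite_records$value
    s_of_y <- match(onsite_records$species_id, species)
    mu <- ifelse(n_i > 0L, ybar, mu0)
    sig2 <- stats::var(y)
    if (!is.finite(sig2) || sig2 == 0) sig2 <- 1
    kept <- gibbs_iter - gibbs_burnin
    acc_m <- acc_s <- numeric(length(species))
    sum_y <- vapply(seq_along(species), function(i)
      sum(y[s_of_y == i]), 0)
    for (it in seq_len(gibbs_iter)) {
      prec <- 1 / sd0^2 + n_i / sig2
      m <- (mu0 / sd0^2 + sum_y / sig2) / prec
      mu <- stats::rnorm(length(species), m, sqrt(1 / prec))
      ss <- sum((y - mu[s_of_y])^2)
      sig2 <- 1 / stats::rgamma(1L, shape = ig_shape + length(y) / 2,
                                rate = ig_scale + ss / 2)
      if (it > gibbs_burnin) {
        acc_m <- acc_m + mu
        acc_s <- acc_s + mu^2
      }
    }
    post_mean <- acc_m / kept
    post_var <- pmax(acc_s / kept - post_mean^2, 0) * kept / (kept - 1L)
    post_sd <- sqrt(post_var)
    post_mean[n_i == 0L] <- mu0[n_i == 0L]
    post_sd[n_i == 0L] <- sd0[n_i == 0L]
  }
  data.frame(species_id = species, mean = post_mean, sd = post_sd,
             n_records = as.integer(n_i), provenance = "fused",
             prior_only = n_i == 0L, stringsAsFactors = FALSE)
}
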