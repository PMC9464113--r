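#' MCMC settings for the taxonomy-nested hierarchy
#'
#' The four-level model fixes the observation, genus and family standard
#' deviations (they are weakly identified from typical trait-record pools
#' and fixing them stabilises convergence) and lets the species-level sd vary
#' among genera with an inverse-gamma prior on its square.
#'
#' @param chains Number of independent chains.
#' @param iter Iterations per chain (including burn-in).
#' @param burnin Burn-in iterations discarded per chain; default half.
#' @param seed Integer seed for the sampler.
#' @param sd_obs,sd_g,sd_f Fixed standard deviations on the standardized log
#'   scale: across observations within a species, across genera within a
#'   family, and across families.
#' @param ig_shape,ig_scale Inverse-gamma hyperparameters of the
#'   genus-specific species-level variance `sd_sp^2`.
#' @param sd_sp_fixed Optional fixed species-level sd shared by all genera;
#'   when set the inverse-gamma update is skipped and the whole model is
#'   jointly Gaussian, so every marginal posterior has a closed form.
#' @param global_prior_sd Sd of the normal prior on the global mean.
#' @param rhat_threshold Split-R-hat above which a convergence warning is
#'   emitted.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3L, iter = 4000L, burnin = iter %/% 2L,
                        seed = 1L, sd_obs = 1, sd_g = 0.5, sd_f = 0.5,
                        ig_shape = 2, ig_scale = 1, sd_sp_fixed = NULL,
                        global_prior_sd = 10, rhat_threshold = 1.05) {
  stopifnot(chains >= 1L, iter > burnin, burnin >= 0L,
            sd_obs > 0, sd_g > 0, sd_f > 0, ig_shape > 0, ig_scale > 0,
            is.null(sd_sp_fixed) || sd_sp_fixed > 0)
  structure(list(chains = as.integer(chains), iter = as.integer(iter),
                 burnin = as.integer(burnin), seed = as.integer(seed),
                 sd_obs = sd_obs, sd_g = sd_g, sd_f = sd_f,
                 ig_shape = ig_shape, ig_scale = ig_scale,
                 sd_sp_fixed = sd_sp_fixed,
                 global_prior_sd = global_prior_sd,
                 rhat_threshold = rhat_threshold),
            class = "mcmc_config")
}

#' Fit the taxonomy-nested normal hierarchy by Gibbs sampling
#'
#' Model, on the standardized log-trait scale:
#' \deqn{y_r  \sim N(\mu_{sp(s_r)}, sd_{obs})}
#' \deqn{\mu_{sp,s} \sim N(\mu_{g(s)}, sd_{sp,g}),\quad
#'       sd_{sp,g}^2 \sim \mathrm{InvGamma}(a_0, b_0)}
#' \deqn{\mu_{g} \sim N(\mu_{f(g)}, sd_g),\quad
#'       \mu_{f} \sim N(\mu_{global}, sd_f)}
#' All full conditionals are conjugate (normal or inverse-gamma), so the
#' sampler is an exact blocked Gibbs scheme with vectorized level updates; no
#' external MCMC engine is involved, and with all sds fixed every marginal
#' can be checked against the closed-form multilevel normal posterior.
#'
#' @param records Data.frame with columns `species_id` and `value`, the
#'   values already filtered, log-transformed and standardized (see
#'   [filter_records()], [log_standardize()]).
#' @param taxonomy Taxonomy table covering every species in `records`.
#' @param mcmc An [mcmc_config()].
#' @return A `hierarchical_fit`: posterior draw arrays (`kept x chains x n`)
#'   for the global mean, family, genus and species means and the
#'   genus-specific species sd, the index vectors linking levels, and
#'   convergence diagnostics (max split-R-hat, min effective sample size).
#' @export
fit_hierarchy <- function(records, taxonomy, mcmc = mcmc_config()) {
  if (nrow(records) == 0L) stop("no records to fit", call. = FALSE)
  if (!all(records$species_id %in% taxonomy$species_id))
    stop("records contain species absent from the taxonomy", call. = FALSE)
  y <- as.numeric(records$value)

  sp <- sort(unique(records$species_id))
  tax_sp <- taxonomy[match(sp, taxonomy$species_id), ]
  gen <- sort(unique(tax_sp$genus))
  fam <- sort(unique(tax_sp$family))
  s_of_y <- match(records$species_id, sp)
  g_of_s <- match(tax_sp$genus, gen)
  f_of_g <- match(taxonomy$family[match(gen, taxonomy$genus)], fam)

  n_sp <- length(sp); n_g <- length(gen); n_f <- length(fam)
  n_s <- tabulate(s_of_y, n_sp)
  sum_s <- as.numeric(rowsum(y, s_of_y, reorder = TRUE))
  m_g <- tabulate(g_of_s, n_g)           # species with data per genus
  k_f <- tabulate(f_of_g, n_f)           # genera with data per family

  kept <- mcmc$iter - mcmc$burnin
  arr <- function(n) array(NA_real_, c(kept, mcmc$chains, n))
  dr_sp <- arr(n_sp); dr_g <- arr(n_g); dr_f <- arr(n_f)
  dr_sd <- arr(n_g); dr_glob <- arr(1L)

  v_obs <- mcmc$sd_obs^2; v_g <- mcmc$sd_g^2; v_f <- mcmc$sd_f^2
  v_glob <- mcmc$global_prior_sd^2
  a0 <- mcmc$ig_shape; b0 <- mcmc$ig_scale

  set.seed(mcmc$seed)
  for (ch in seq_len(mcmc$chains)) {
    mu_sp <- sum_s / pmax(n_s, 1L)
    mu_g <- as.numeric(rowsum(mu_sp, g_of_s) / m_g)
    mu_f <- as.numeric(rowsum(mu_g, f_of_g) / k_f)
    mu_glob <- mean(mu_f)
    sd_sp2 <- rep(if (is.null(mcmc$sd_sp_fixed)) 1 else
      mcmc$sd_sp_fixed^2, n_g)
    if (ch > 1L) {  # overdisperse chain starts
      mu_sp <- mu_sp + stats::rnorm(n_sp, 0, 0.5)
      mu_g <- mu_g + stats::rnorm(n_g, 0, 0.5)
      mu_f <- mu_f + stats::rnorm(n_f, 0, 0.5)
    }
    for (it in seq_len(mcmc$iter)) {
      prec <- n_s / v_obs + 1 / sd_sp2[g_of_s]
      mu <- (sum_s / v_obs + mu_g[g_of_s] / sd_sp2[g_of_s]) / prec
      mu_sp <- stats::rnorm(n_sp, mu, sqrt(1 / prec))

      if (is.null(mcmc$sd_sp_fixed)) {
        ss <- as.numeric(rowsum((mu_sp - mu_g[g_of_s])^2, g_of_s))
        sd_sp2 <- 1 / stats::rgamma(n_g, shape = a0 + m_g / 2,
                                    rate = b0 + ss / 2)
      }

      prec <- m_g / sd_sp2 + 1 / v_g
      mu <- (as.numeric(rowsum(mu_sp / sd_sp2[g_of_s], g_of_s)) +
               mu_f[f_of_g] / v_g) / prec
      mu_g <- stats::rnorm(n_g, mu, sqrt(1 / prec))

      prec <- k_f / v_g + 1 / v_f
      mu <- (as.numeric(rowsum(mu_g, f_of_g)) / v_g + mu_glob / v_f) / prec
      mu_f <- stats::rnorm(n_f, mu, sqrt(1 / prec))

      prec <- n_f / v_f + 1 / v_glob
      mu_glob <- stats::rnorm(1L, sum(mu_f) / v_f / prec, sqrt(1 / prec))

      if (it > mcmc$burnin) {
        j <- it - mcmc$burnin
        dr_sp[j, ch, ] <- mu_sp
        dr_g[j, ch, ] <- mu_g
        dr_f[j, ch, ] <- mu_f
        dr_sd[j, ch, ] <- sqrt(sd_sp2)
        dr_glob[j, ch, 1L] <- mu_glob
      }
    }
  }
  diag <- diagnose_draws(list(mu_sp = dr_sp, mu_g = dr_g, mu_f = dr_f,
                              mu_global = dr_glob))
  if (is.finite(diag$max_rhat) && diag$max_rhat > mcmc$rhat_threshold)
    warning(sprintf("convergence: max split-R-hat %.3f exceeds %.2f",
                    diag$max_rhat, mcmc$rhat_threshold), call. = FALSE)
  structure(list(species = sp, genera = gen, families = fam,
                 g_of_s = g_of_s, f_of_g = f_of_g, n_records = n_s,
                 draws = list(mu_sp = dr_sp, mu_g = dr_g, mu_f = dr_f,
                              sd_sp = dr_sd, mu_global = dr_glob),
                 diagnostics = diag, mcmc = mcmc),
            class = "hierarchical_fit")
}

#' @export
print.hierarchical_fit <- function(x, ...) {
  cat(sprintf("Taxonomy-nested hierarchical fit: %d species, %d genera, %d families\n",
              length(x$species), length(x$genera), length(x$families)))
  cat(sprintf("  %d chains x %d kept draws; max split-R-hat %.3f, min ESS %.0f\n",
              x$mcmc$chains, dim(x$draws$mu_sp)[1L],
              x$diagnostics$max_rhat, x$diagnostics$min_ess))
  invisible(x)
}

# Split-R-hat and a truncated-autocorrelation effective sample size over a
# list of kept x chains x n draw arrays.
diagnose_draws <- function(draw_list) {
  rhat_one <- function(m) {  # m: iterations x chains
    half <- nrow(m) %/% 2L
    if (half < 2L) return(NA_real_)
    sm <- cbind(m[seq_len(half), , drop = FALSE],
                m[(nrow(m) - half + 1L):nrow(m), , drop = FALSE])
    w <- mean(apply(sm, 2L, stats::var))
    b <- half * stats::var(colMeans(sm))
    if (!is.finite(w) || w == 0) return(1)
    sqrt(((half - 1) / half * w + b / half) / w)
  }
  ess_one <- function(m) {
    v <- as.vector(m)
    n <- length(v)
    if (stats::var(v) == 0) return(n)
    ac <- stats::acf(v, lag.max = min(100L, n - 1L), plot = FALSE)$acf[-1L]
    pos <- which(ac < 0.05)
    cut <- if (length(pos) > 0L) pos[1L] - 1L else length(ac)
    n / (1 + 2 * sum(ac[seq_len(cut)]))
  }
  rhats <- ess <- numeric(0)
  for (a in draw_list) {
    for (j in seq_len(dim(a)[3L])) {
      rhats <- c(rhats, rhat_one(a[, , j, drop = TRUE]))
      ess <- c(ess, ess_one(a[, , j, drop = TRUE]))
    }
  }
  list(max_rhat = suppressWarnings(max(rhats, na.rm = TRUE)),
       min_ess = suppressWarnings(min(ess, na.rm = TRUE)))
}

flat_draws <- function(fit, what) {
  a <- fit$draws[[what]]
  matrix(a, nrow = dim(a)[1L] * dim(a)[2L], ncol = dim(a)[3L])
}

#' Species-level summaries and taxonomic imputation from a hierarchical fit
#'
#' For species with fitted data, returns the posterior mean and sd of their
#' species-level mean (provenance `measured` in the model's sense).
#' For species absent from the fitted data the species mean is simulated per
#' posterior draw by descending the hierarchy from the deepest level that has
#' data: genus level `N(mu_g, sd_sp_g)`; genus unseen but family seen,
#' `mu_g* ~ N(mu_f, sd_g)` then `N(mu_g*, sd_sp*)` with `sd_sp*^2` drawn from
#' its prior; neither seen, start from the global mean. Uncertainty therefore
#' grows with every level of fallback. Provenance is `imputed_taxonomic` and
#' `n_records` 0.
#'
#' @param fit A `hierarchical_fit`.
#' @param species_id Character vector of species to summarise/impute; all
#'   must be in `taxonomy`.
#' @param taxonomy The taxonomy table.
#' @param seed Seed for the fallback simulation draws.
#' @return A data.frame with columns `species_id`, `mean`, `sd`,
#'   `n_records`, `provenance` (standardized log scale).
#' @export
impute_species_mean <- function(fit, species_id, taxonomy, seed = 1L) {
  miss <- setdiff(species_id, taxonomy$species_id)
  if (length(miss) > 0L)
    stop("species not in taxonomy: ", paste(miss, collapse = ", "),
         call. = FALSE)
  set.seed(stage_seed(seed, "true_means") + 17L)
  sp_d <- flat_draws(fit, "mu_sp"); g_d <- flat_draws(fit, "mu_g")
  f_d <- flat_draws(fit, "mu_f"); sd_d <- flat_draws(fit, "sd_sp")
  glob_d <- flat_draws(fit, "mu_global")[, 1L]
  ndr <- length(glob_d)
  a0 <- fit$mcmc$ig_shape; b0 <- fit$mcmc$ig_scale

  out <- lapply(species_id, function(s) {
    i <- match(s, fit$species)
    if (!is.na(i)) {
      d <- sp_d[, i]
      return(data.frame(species_id = s, mean = mean(d), sd = stats::sd(d),
                        n_records = fit$n_records[i],
                        provenance = "measured", stringsAsFactors = FALSE))
    }
    gen <- taxonomy$genus[match(s, taxonomy$species_id)]
    fam <- taxonomy$family[match(s, taxonomy$species_id)]
    gi <- match(gen, fit$genera)
    if (!is.na(gi)) {
      mu <- g_d[, gi]; sd_sp <- sd_d[, gi]
    } else {
      fi <- match(fam, fit$families)
      base <- if (!is.na(fi)) f_d[, fi] else
        stats::rnorm(ndr, glob_d, fit$mcmc$sd_f)
      mu <- stats::rnorm(ndr, base, fit$mcmc$sd_g)
      sd_sp <- if (is.null(fit$mcmc$sd_sp_fixed))
        sqrt(1 / stats::rgamma(ndr, shape = a0, rate = b0))
      else rep(fit$mcmc$sd_sp_fixed, ndr)
    }
    d <- stats::rnorm(ndr, mu, sd_sp)
    data.frame(species_id = s, mean = mean(d), sd = stats::sd(d),
               n_records = 0L, provenance = "imputed_taxonomic",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Leave-out evaluation of taxonomic imputation
#'
#' Excludes the records of a set of data-bearing species, refits the
#' hierarchy once on the remainder (jointly, the default, or one species at
#' a time with `jackknife = TRUE`), imputes each excluded species, and
#' scores imputed against observed species means.
#'
#' @param records Standardized records (`species_id`, `value`).
#' @param taxonomy Taxonomy table.
#' @param species_subset Species to hold out; each must have records.
#' @param mcmc An [mcmc_config()].
#' @param jackknife Refit once per held-out species instead of once overall.
#' @return A list of class `imputation_evaluation` with `pairs` (species,
#'   observed mean, imputed mean, imputed sd) and `r2`, the squared Pearson
#'   correlation of observed on imputed means.
#' @export
evaluate_by_leave_out <- function(records, taxonomy, species_subset,
                                  mcmc = mcmc_config(), jackknife = FALSE) {
  if (length(species_subset) == 0L)
    stop("species_subset is empty", call. = FALSE)
  has <- species_subset %in% records$species_id
  if (!all(has))
    stop("held-out species without records: ",
         paste(species_subset[!has], collapse = ", "), call. = FALSE)
  obs <- vapply(species_subset, function(s)
    mean(records$value[records$species_id == s]), 0)
  if (jackknife) {
    imp <- do.call(rbind, lapply(species_subset, function(s) {
      fit <- fit_hierarchy(records[records$species_id != s, , drop = FALSE],
                           taxonomy, mcmc)
      impute_species_mean(fit, s, taxonomy, seed = mcmc$seed)
    }))
  } else {
    fit <- fit_hierarchy(
      records[!records$species_id %in% species_subset, , drop = FALSE],
      taxonomy, mcmc)
    imp <- impute_species_mean(fit, species_subset, taxonomy,
                               seed = mcmc$seed)
  }
  pairs <- data.frame(species_id = species_subset, observed = as.numeric(obs),
                      imputed = imp$mean, imputed_sd = imp$sd,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, r2 = leave_out_r2(pairs)),
            class = "imputation_evaluation")
}

# Squared Pearson correlation of observed on imputed; 0 when degenerate.
leave_out_r2 <- function(pairs) {
  if (nrow(pairs) < 3L) return(NA_real_)
  if (stats::sd(pairs$imputed) == 0 || stats::sd(pairs$observed) == 0)
    return(0)
  stats::cor(pairs$observed, pairs$imputed)^2
}

#' @export
print.imputation_evaluation <- function(x, ...) {
  cat(sprintf("Leave-out imputation evaluation: %d species, R^2 = %.3f\n",
              nrow(x$pairs), x$r2))
  invisible(x)
}
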