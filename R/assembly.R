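#' Engine settings for dataset construction
#'
#' @param mcmc [mcmc_config()] for the taxonomy-nested hierarchy (strategies
#'   II and V).
#' @param pmf [pmf_config()] for matrix-factorization gap-filling (IV).
#' @param phylo_n_iter Resampling iterations for phylogenetic stand-ins (III).
#' @param fusion_sd_t Fixed on-site observation sd for fusion (V), or NULL
#'   to estimate it.
#' @param fusion_prior_weight Prior weight w for fusion.
#' @param max_offsite_per_species Cap on off-site records per species when
#'   estimating fusion priors.
#' @return A list of class `engines_config`.
#' @export
engines_config <- function(mcmc = mcmc_config(), pmf = pmf_config(),
                           phylo_n_iter = 1000L, fusion_sd_t = NULL,
                           fusion_prior_weight = 1,
                           max_offsite_per_species = 5L) {
  structure(list(mcmc = mcmc, pmf = pmf,
                 phylo_n_iter = as.integer(phylo_n_iter),
                 fusion_sd_t = fusion_sd_t,
                 fusion_prior_weight = fusion_prior_weight,
                 max_offsite_per_species = as.integer(max_offsite_per_species)),
            class = "engines_config")
}

strategy_labels <- c(I = "I_onsite", II = "II_taxonomic", III = "III_phylo",
                     IV = "IV_pmf", V = "V_fusion", VI = "VI_all_offsite")

normalize_strategy <- function(strategy) {
  if (strategy %in% names(strategy_labels)) return(strategy)
  hit <- names(strategy_labels)[strategy_labels == strategy]
  if (length(hit) == 1L) return(hit)
  stop("unknown strategy: ", strategy, " (use I..VI)", call. = FALSE)
}

# pooled log-scale standardization parameters for one trait
pooled_params <- function(records, trait) {
  v <- records$value[records$trait == trait]
  if (length(v) < 2L)
    stop("need at least 2 records of trait ", trait, call. = FALSE)
  log_standardize(v)$params
}

# standardized per-species summaries of one source for one trait
source_species_means <- function(records, trait, params,
                                 source = "off_site") {
  r <- records[records$trait == trait & records$source == source, ,
               drop = FALSE]
  if (nrow(r) == 0L)
    return(data.frame(species_id = character(), mean = numeric(),
                      sd = numeric(), n_records = integer(),
                      stringsAsFactors = FALSE))
  z <- log_standardize(r$value, params)$values
  sp <- sort(unique(r$species_id))
  idx <- match(r$species_id, sp)
  n <- tabulate(idx, length(sp))
  m <- as.numeric(rowsum(z, idx) / n)
  s <- vapply(seq_along(sp), function(i) {
    v <- z[idx == i]
    if (length(v) < 2L) NA_real_ else stats::sd(v)
  }, 0)
  data.frame(species_id = sp, mean = m, sd = s, n_records = n,
             stringsAsFactors = FALSE)
}

# standardized long records of one trait/source as (species_id, value)
std_records <- function(records, trait, params, source = NULL) {
  r <- records[records$trait == trait, , drop = FALSE]
  if (!is.null(source)) r <- r[r$source == source, , drop = FALSE]
  data.frame(species_id = r$species_id,
             value = if (nrow(r) > 0L)
               log_standardize(r$value, params)$values else numeric(),
             stringsAsFactors = FALSE)
}

# species x trait matrix of standardized off-site species means
offsite_trait_matrix <- function(records, params_by_trait) {
  traits <- names(params_by_trait)
  per_trait <- lapply(traits, function(t)
    source_species_means(records, t, params_by_trait[[t]]))
  species <- sort(unique(unlist(lapply(per_trait, `[[`, "species_id"))))
  mat <- matrix(NA_real_, length(species), length(traits),
                dimnames = list(species, traits))
  for (j in seq_along(traits)) {
    sm <- per_trait[[j]]
    mat[match(sm$species_id, species), j] <- sm$mean
  }
  mat
}

#' Build one of the six trait datasets
#'
#' Constructs a species-level trait dataset for one trait under one of the
#' six strategies:
#' \describe{
#'   \item{I (on-site)}{mean/sd of log on-site records per target species.}
#'   \item{II (off-site + taxonomic imputation)}{off-site species means where
#'     available; gaps filled by the taxonomy-nested hierarchy fitted to the
#'     whole off-site pool.}
#'   \item{III (off-site + phylogenetic stand-ins)}{gaps replaced by
#'     resampling among the nearest data-bearing relatives; species with no
#'     relative in the tree are dropped and reported.}
#'   \item{IV (off-site + matrix factorization)}{gaps filled by hierarchical
#'     PMF over all traits; species with no trait data at all are dropped.}
#'   \item{V (fusion)}{per-species off-site priors (capped pool) updated
#'     with on-site records.}
#'   \item{VI (all off-site)}{every species with off-site records, ignoring
#'     the target roster.}
#' }
#' All values are on a standardized natural-log scale whose parameters are
#' estimated once from the pooled record set of the trait, so means are
#' directly comparable across strategies.
#'
#' @param strategy `"I"` .. `"VI"` (or the long labels `I_onsite` ..
#'   `VI_all_offsite`).
#' @param records Filtered trait records (long format, raw values).
#' @param taxonomy Taxonomy table.
#' @param phylogeny `phylo` tree (required for III).
#' @param target_species The on-site-found roster (required for I-V).
#' @param trait Trait to build.
#' @param engines An [engines_config()].
#' @param seed Integer seed for the stochastic engines.
#' @return A `trait_dataset`: `strategy`, `trait`, `summaries` (species_id,
#'   mean, sd, n_records, provenance), `roster`, `transform` (the pooled
#'   log-scale parameters) and `report` (dropped species etc.).
#' @export
build_dataset <- function(strategy, records, taxonomy, phylogeny = NULL,
                          target_species = NULL, trait,
                          engines = engines_config(), seed = 1L) {
  strategy <- normalize_strategy(strategy)
  if (strategy != "VI" && is.null(target_species))
    stop("strategies I-V need target_species", call. = FALSE)
  params <- pooled_params(records, trait)
  off <- source_species_means(records, trait, params)
  report <- list()

  if (strategy == "I") {
    on <- source_species_means(records, trait, params, source = "on_site")
    sm <- on[on$species_id %in% target_species, , drop = FALSE]
    missing_on <- setdiff(target_species, sm$species_id)
    if (length(missing_on) > 0L)
      report$no_onsite_records <- missing_on
    sm$provenance <- "measured"
  } else if (strategy == "VI") {
    sm <- off
    sm$provenance <- "measured"
  } else {
    measured <- off[off$species_id %in% target_species, , drop = FALSE]
    measured$provenance <- "measured"
    gaps <- setdiff(target_species, measured$species_id)
    if (strategy == "II") {
      if (length(gaps) > 0L) {
        fit <- fit_hierarchy(std_records(records, trait, params,
                                         source = "off_site"),
                             taxonomy, engines$mcmc)
        imp <- impute_species_mean(fit, gaps, taxonomy, seed = seed)
        sm <- rbind(measured, imp[, names(measured)])
      } else sm <- measured
    } else if (strategy == "III") {
      if (is.null(phylogeny))
        stop("strategy III needs a phylogeny", call. = FALSE)
      if (length(gaps) > 0L) {
        donors <- setdiff(off$species_id, gaps)
        map <- find_phylo_equivalents(phylogeny,
                                      intersect(donors,
                                                phylogeny$tip.label),
                                      gaps)
        imp <- impute_phylogenetic(map, off,
                                   n_iter = engines$phylo_n_iter,
                                   seed = seed)
        imp$n_records <- 0L
        report$unmatched <- attr(imp, "excluded")
        sm <- rbind(measured, imp[, names(measured)])
      } else sm <- measured
    } else if (strategy == "IV") {
      params_all <- lapply(sort(unique(records$trait)),
                           function(t) pooled_params(records, t))
      names(params_all) <- sort(unique(records$trait))
      mat <- offsite_trait_matrix(records, params_all)
      fit <- fit_pmf(mat, taxonomy, config = engines$pmf, seed = seed)
      report$dropped_no_data <- union(fit$dropped,
                                      setdiff(gaps, rownames(mat)))
      fillable <- intersect(gaps, fit$species)
      if (length(fillable) > 0L) {
        imp <- impute_pmf(fit, fillable, trait)
        imp$n_records <- 0L
        sm <- rbind(measured, imp[, names(measured)])
      } else sm <- measured
    } else { # V
      capped <- subsample_offsite(
        records[records$trait == trait & records$source == "off_site", ,
                drop = FALSE],
        max_per_species = engines$max_offsite_per_species, seed = seed)
      pri <- estimate_priors(
        data.frame(species_id = capped$species_id,
                   value = log_standardize(capped$value, params)$values,
                   stringsAsFactors = FALSE),
        taxonomy, target_species, engines$mcmc)
      fused <- fuse(std_records(records, trait, params,
                                source = "on_site"),
                    pri, sd_t = engines$fusion_sd_t,
                    prior_weight = engines$fusion_prior_weight,
                    seed = seed)
      fused <- fused[fused$species_id %in% target_species, , drop = FALSE]
      sm <- fused[, c("species_id", "mean", "sd", "n_records", "provenance")]
    }
  }
  rownames(sm) <- NULL
  structure(list(strategy = strategy_labels[[strategy]], trait = trait,
                 summaries = sm, roster = sm$species_id,
                 transform = params, report = report),
            class = "trait_dataset")
}

#' @export
print.trait_dataset <- function(x, ...) {
  prov <- table(x$summaries$provenance)
  cat(sprintf("Trait dataset %s / %s: %d species (%s)\n",
              x$strategy, x$trait, length(x$roster),
              paste(sprintf("%s %d", names(prov), prov), collapse = ", ")))
  invisible(x)
}

#' @describeIn build_dataset Export the dataset as a plain data.frame with
#'   `trait` and `strategy` columns appended.
#' @param dataset A `trait_dataset`.
#' @export
dataset_table <- function(dataset) {
  cbind(dataset$summaries,
        trait = dataset$trait, strategy = dataset$strategy,
        stringsAsFactors = FALSE)
}

#' Correlate two trait datasets over their common species
#'
#' Pearson's r measures linear agreement of the mean values; Spearman's rho
#' (average-rank ties) measures whether the species rank order holds across
#' the two construction strategies even where the values differ.
#'
#' @param d1,d2 `trait_dataset` objects for the same trait.
#' @return A list with `pearson_r`, `spearman_rho`, `n_common`.
#' @export
compare_datasets <- function(d1, d2) {
  common <- intersect(d1$summaries$species_id, d2$summaries$species_id)
  if (length(common) < 3L)
    stop("need at least 3 common species to correlate", call. = FALSE)
  x <- d1$summaries$mean[match(common, d1$summaries$species_id)]
  y <- d2$summaries$mean[match(common, d2$summaries$species_id)]
  list(pearson_r = stats::cor(x, y),
       spearman_rho = stats::cor(x, y, method = "spearman"),
       n_common = length(common))
}

#' On-site vs off-site correlation of species means
#'
#' For each trait, correlates per-species mean log values computed from
#' on-site records against those from off-site records, over species with
#' both sources, and returns the per-species means/sds for plotting.
#'
#' @param records Trait records (long format, raw values).
#' @param species Optional roster restriction.
#' @return A data.frame (`trait`, `pearson_r`, `n`), with the per-species
#'   pair table in `attr(, "pairs")`.
#' @export
onsite_offsite_correlation <- function(records, species = NULL) {
  if (!is.null(species))
    records <- records[records$species_id %in% species, , drop = FALSE]
  traits <- sort(unique(records$trait))
  pair_rows <- list()
  out <- lapply(traits, function(t) {
    r <- records[records$trait == t, , drop = FALSE]
    agg <- function(src) {
      rr <- r[r$source == src, , drop = FALSE]
      sp <- unique(rr$species_id)
      data.frame(species_id = sp,
                 mean = vapply(sp, function(s)
                   mean(log(rr$value[rr$species_id == s])), 0),
                 sd = vapply(sp, function(s) {
                   v <- log(rr$value[rr$species_id == s])
                   if (length(v) < 2L) NA_real_ else stats::sd(v)
                 }, 0), stringsAsFactors = FALSE)
    }
    on <- agg("on_site"); offs <- agg("off_site")
    common <- intersect(on$species_id, offs$species_id)
    if (length(common) < 3L)
      stop("fewer than 3 species with both sources for trait ", t,
           call. = FALSE)
    p <- data.frame(trait = t, species_id = common,
                    onsite_mean = on$mean[match(common, on$species_id)],
                    onsite_sd = on$sd[match(common, on$species_id)],
                    offsite_mean = offs$mean[match(common, offs$species_id)],
                    offsite_sd = offs$sd[match(common, offs$species_id)],
                    stringsAsFactors = FALSE)
    pair_rows[[t]] <<- p
    data.frame(trait = t,
               pearson_r = stats::cor(p$onsite_mean, p$offsite_mean),
               n = length(common), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  attr(res, "pairs") <- do.call(rbind, pair_rows)
  rownames(res) <- NULL
  res
}
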