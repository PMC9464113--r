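#' Leave-out evaluation of an imputation method
#'
#' Implements the accuracy check used for the off-site gap-filling methods:
#' take species that do have off-site records, hide those records (for the
#' focal trait), impute the species with the chosen method, and score the
#' imputed means against the observed off-site means by squared Pearson
#' correlation. For the matrix-factorization method only the focal-trait
#' cells are masked, so the method can still exploit the species' other
#' traits — exactly the advantage it is supposed to have.
#'
#' @param records Filtered trait records (long format, raw values).
#' @param taxonomy Taxonomy table.
#' @param phylogeny `phylo` tree (needed for `method = "phylo"`).
#' @param trait Focal trait.
#' @param method `"taxonomic"`, `"phylo"` or `"pmf"`.
#' @param species_subset Species to hold out; defaults to every species with
#'   off-site records of the focal trait.
#' @param engines An [engines_config()].
#' @param seed Integer seed.
#' @return An `imputation_evaluation` (`pairs`, `r2`, `method`); for
#'   `"phylo"` unmatched species are absent from `pairs` and listed in
#'   `attr(pairs, "excluded")`.
#' @export
evaluate_imputation <- function(records, taxonomy, phylogeny = NULL,
                                trait, method = c("taxonomic", "phylo",
                                                  "pmf"),
                                species_subset = NULL,
                                engines = engines_config(), seed = 1L) {
  method <- match.arg(method)
  params <- pooled_params(records, trait)
  off_means <- source_species_means(records, trait, params)
  if (is.null(species_subset)) species_subset <- off_means$species_id
  if (length(species_subset) == 0L)
    stop("species_subset is empty", call. = FALSE)
  if (!all(species_subset %in% off_means$species_id))
    stop("held-out species must have off-site records of the focal trait",
         call. = FALSE)
  obs <- off_means$mean[match(species_subset, off_means$species_id)]

  if (method == "taxonomic") {
    std <- std_records(records, trait, params, source = "off_site")
    ev <- evaluate_by_leave_out(std, taxonomy, species_subset,
                                mcmc = engines$mcmc)
    ev$method <- method
    return(ev)
  }

  if (method == "phylo") {
    donors <- setdiff(off_means$species_id, species_subset)
    donors <- intersect(donors, phylogeny$tip.label)
    map <- find_phylo_equivalents(phylogeny, donors, species_subset)
    imp <- impute_phylogenetic(map, off_means,
                               n_iter = engines$phylo_n_iter, seed = seed)
    keep <- match(imp$species_id, species_subset)
    pairs <- data.frame(species_id = imp$species_id,
                        observed = obs[keep], imputed = imp$mean,
                        imputed_sd = imp$sd, stringsAsFactors = FALSE)
    attr(pairs, "excluded") <- attr(imp, "excluded")
  } else { # pmf
    traits_all <- sort(unique(records$trait))
    params_all <- lapply(traits_all, function(t) pooled_params(records, t))
    names(params_all) <- traits_all
    mat <- offsite_trait_matrix(records, params_all)
    mat[match(species_subset, rownames(mat)), trait] <- NA
    mat <- mat[rowSums(!is.na(mat)) > 0L, , drop = FALSE]
    fit <- fit_pmf(mat, taxonomy, config = engines$pmf, seed = seed)
    fillable <- intersect(species_subset, fit$species)
    imp <- impute_pmf(fit, fillable, trait)
    pairs <- data.frame(species_id = fillable,
                        observed = obs[match(fillable, species_subset)],
                        imputed = imp$mean, imputed_sd = imp$sd,
                        stringsAsFactors = FALSE)
    attr(pairs, "excluded") <- setdiff(species_subset, fillable)
  }
  structure(list(pairs = pairs, r2 = leave_out_r2(pairs), method = method),
            class = "imputation_evaluation")
}
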