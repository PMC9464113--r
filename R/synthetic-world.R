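#' Generate a nested taxonomy
#'
#' Draws a species -> genus -> family table according to the counts (or count
#' ranges) in the configuration. Identifiers are zero-padded (`f01`, `g0001`,
#' `s00001`) so tables sort naturally.
#'
#' @param config A [world_config()].
#' @return A data.frame with columns `species_id`, `genus`, `family`; one row
#'   per species, each species in exactly one genus, each genus in exactly one
#'   family.
#' @export
generate_taxonomy <- function(config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(stage_seed(config$seed, "taxonomy"))
  draw_count <- function(spec) {
    if (length(spec) == 1L) spec else sample(seq(spec[1L], spec[2L]), 1L)
  }
  fams <- sprintf("f%02d", seq_len(config$n_families))
  rows <- vector("list", config$n_families)
  g_idx <- 0L
  s_idx <- 0L
  for (i in seq_along(fams)) {
    n_gen <- draw_count(config$genera_per_family)
    fam_rows <- vector("list", n_gen)
    for (j in seq_len(n_gen)) {
      g_idx <- g_idx + 1L
      n_sp <- draw_count(config$species_per_genus)
      sp <- sprintf("s%05d", s_idx + seq_len(n_sp))
      s_idx <- s_idx + n_sp
      fam_rows[[j]] <- data.frame(species_id = sp,
                                  genus = sprintf("g%04d", g_idx),
                                  family = fams[i],
                                  stringsAsFactors = FALSE)
    }
    rows[[i]] <- do.call(rbind, fam_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate true species-level trait means
#'
#' Runs the taxonomy-nested normal hierarchy forward on the natural-log
#' scale: family means are drawn around the global mean, genus means around
#' their family mean, and species deviations around their genus mean.
#' Cross-trait correlation is injected at the species level only (family and
#' genus deviations are independent across traits), which is the structure a
#' matrix-factorization gap-filler can exploit.
#'
#' @param taxonomy A taxonomy table from [generate_taxonomy()].
#' @param config A [world_config()].
#' @return A species x trait numeric matrix of log-scale means, rownames =
#'   species ids; no missing cells.
#' @export
generate_true_means <- function(taxonomy, config) {
  stopifnot(inherits(config, "world_config"), nrow(taxonomy) >= 1L)
  set.seed(stage_seed(config$seed, "true_means"))
  traits <- config$trait_names
  fams <- unique(taxonomy$family)
  gens <- unique(taxonomy$genus)
  gen_fam <- taxonomy$family[match(gens, taxonomy$genus)]
  n_sp <- nrow(taxonomy)
  nt <- length(traits)

  mu_f <- matrix(rnorm(length(fams) * nt, 0, config$sd_f),
                 length(fams), nt, dimnames = list(fams, traits))
  mu_f <- sweep(mu_f, 2L, config$mu_global, "+")
  mu_g <- mu_f[match(gen_fam, fams), , drop = FALSE] +
    matrix(rnorm(length(gens) * nt, 0, config$sd_g), length(gens), nt)
  rownames(mu_g) <- gens

  L <- chol(config$cross_trait_corr)
  z <- matrix(rnorm(n_sp * nt), n_sp, nt)
  dev <- z %*% L
  dev <- sweep(dev, 2L, config$sd_sp_scale, "*")
  means <- mu_g[match(taxonomy$genus, gens), , drop = FALSE] + dev
  dimnames(means) <- list(taxonomy$species_id, traits)
  means
}

#' Generate a phylogeny consistent with the taxonomy
#'
#' Builds an ultrametric tree in which species coalesce within their genus,
#' genera within their family, and families at the root, with unit branch
#' lengths per level (tip depth 3). By construction every pair of congeners
#' is closer (patristic distance 2) than any confamilial cross-genus pair
#' (distance 4), which in turn is closer than any cross-family pair
#' (distance 6) -- the ordering nearest-relative matching relies on.
#'
#' @param taxonomy A taxonomy table.
#' @param seed Unused (the construction is deterministic); kept so all
#'   generator stages share one signature.
#' @return An [ape] `phylo` object whose tip labels are the species ids.
#' @export
generate_phylogeny <- function(taxonomy, seed = NULL) {
  if (nrow(taxonomy) < 2L)
    stop("a phylogeny needs at least 2 species", call. = FALSE)
  # nodes are (subtree string without root edge, pending edge length); a
  # single-child node collapses by accumulating its edge onto the child
  mk_node <- function(children, edge) {
    if (length(children) == 1L) {
      children[[1L]]$edge <- children[[1L]]$edge + edge
      return(children[[1L]])
    }
    inner <- vapply(children, function(k) paste0(k$str, ":", k$edge), "")
    list(str = paste0("(", paste(inner, collapse = ","), ")"), edge = edge)
  }
  fams <- unique(taxonomy$family)
  fam_nodes <- lapply(fams, function(f) {
    gens <- unique(taxonomy$genus[taxonomy$family == f])
    gen_nodes <- lapply(gens, function(g) {
      sp <- taxonomy$species_id[taxonomy$genus == g]
      mk_node(lapply(sp, function(s) list(str = s, edge = 1)), 1)
    })
    mk_node(gen_nodes, 1)
  })
  root <- mk_node(fam_nodes, 0)
  txt <- if (length(fam_nodes) == 1L) paste0(root$str, ";") else
    paste0(root$str, ";")
  tree <- ape::read.tree(text = txt)
  tree
}

#' Sample on-site and off-site trait records
#'
#' Emulates the two record sources: a field campaign that finds a
#' Bernoulli(`p_onsite_found`) subset of species and measures `onsite_n`
#' individuals per found species for every trait, and a global database with
#' independent Bernoulli(`p_offsite_covered`) coverage per (species, trait)
#' cell and `1 + Poisson(offsite_n_mean - 1)` records per covered cell.
#' Records are exponentials of the true log mean plus normal noise
#' (`sd_obs_onsite` / `sd_obs_offsite`), hence strictly positive. Exclusion
#' flags are drawn independently with `config$flag_probs`.
#'
#' @param true_means Species x trait log-mean matrix.
#' @param config A [world_config()].
#' @return A long-format data.frame of trait records (see [read_records()]
#'   for the column contract).
#' @export
sample_records <- function(true_means, config) {
  stopifnot(inherits(config, "world_config"), !anyNA(true_means))
  set.seed(stage_seed(config$seed, "records"))
  species <- rownames(true_means)
  traits <- colnames(true_means)
  n_sp <- length(species)

  found <- stats::runif(n_sp) < config$p_onsite_found
  bias <- if (config$offsite_bias_sd > 0)
    stats::rnorm(n_sp, 0, config$offsite_bias_sd) else numeric(n_sp)
  p_cov <- stats::plogis(stats::qlogis(min(max(config$p_offsite_covered, 1e-12),
                                           1 - 1e-12)) + bias)
  if (config$p_offsite_covered == 0) p_cov <- rep(0, n_sp)
  if (config$p_offsite_covered == 1) p_cov <- rep(1, n_sp)

  out <- vector("list", 2L * n_sp * length(traits))
  k <- 0L
  for (t in traits) {
    for (i in seq_len(n_sp)) {
      lm_i <- true_means[i, t]
      if (found[i]) {
        n <- config$onsite_n
        vals <- exp(lm_i + stats::rnorm(n, 0, config$sd_obs_onsite))
        k <- k + 1L
        out[[k]] <- data.frame(species_id = species[i], trait = t,
                               value = vals, source = "on_site",
                               stringsAsFactors = FALSE)
      }
      if (stats::runif(1) < p_cov[i]) {
        n <- 1L + stats::rpois(1L, max(config$offsite_n_mean - 1, 0))
        vals <- exp(lm_i + stats::rnorm(n, 0, config$sd_obs_offsite))
        k <- k + 1L
        out[[k]] <- data.frame(species_id = species[i], trait = t,
                               value = vals, source = "off_site",
                               stringsAsFactors = FALSE)
      }
    }
  }
  rec <- if (k > 0L) do.call(rbind, out[seq_len(k)]) else
    data.frame(species_id = character(), trait = character(),
               value = numeric(), source = character(),
               stringsAsFactors = FALSE)
  n_rec <- nrow(rec)
  fp <- config$flag_probs
  flag <- function(p) if (n_rec == 0L) logical() else stats::runif(n_rec) < p
  rec$woody_flag <- flag(fp[["woody"]])
  rec$shade_or_experimental_flag <- flag(fp[["shade_or_experimental"]])
  rec$immature_flag <- flag(fp[["immature"]])
  rec$out_of_env_flag <- flag(fp[["out_of_env"]])
  rownames(rec) <- NULL
  rec
}

#' Generate invasiveness responses from true trait means
#'
#' Emits the per-species covariate/response table of the case study. Latent
#' responses follow the linear model
#' `latent = alpha + sum_t beta_t * x_t + Normal(0, response_noise_sd)` over
#' standardized log-scale predictors; local abundance is the inverse-logit of
#' its latent (so it lies in (0,1)), spread rate the exponential of its
#' latent (positive). Longevity is Bernoulli(0.5) with reference class
#' annual/biennial; minimum residence time is a uniform integer between 5 and
#' 120 years.
#'
#' @param true_means Species x trait log-mean matrix (must contain the traits
#'   named in `config$beta_true`).
#' @param config A [world_config()].
#' @return A data.frame with columns `species_id`, `local_abundance`,
#'   `spread_rate`, `seed_mass`, `longevity`, `min_residence_time`.
#' @export
generate_invasiveness <- function(true_means, config) {
  stopifnot(inherits(config, "world_config"))
  set.seed(stage_seed(config$seed, "invasiveness"))
  species <- rownames(true_means)
  n <- length(species)
  std <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, n))
    (x - mean(x)) / s
  }
  mrt <- sample(5:120, n, replace = TRUE)
  longevity <- stats::rbinom(n, 1L, 0.5)

  predictors <- list(min_residence_time = std(mrt), longevity = longevity)
  for (t in colnames(true_means)) predictors[[t]] <- std(true_means[, t])

  latent <- function(resp) {
    beta <- config$beta_true[[resp]]
    if (is.null(beta)) beta <- numeric()
    if (!all(names(beta) %in% names(predictors)))
      stop("beta_true for ", resp, " names unknown predictors", call. = FALSE)
    mu <- rep(config$alpha_true[[resp]], n)
    for (p in names(beta)) mu <- mu + beta[[p]] * predictors[[p]]
    mu + stats::rnorm(n, 0, config$response_noise_sd)
  }
  ab <- stats::plogis(latent("local_abundance"))
  sp <- exp(latent("spread_rate"))

  seed_mass <- if ("seed_mass" %in% colnames(true_means))
    exp(true_means[, "seed_mass"]) else exp(stats::rnorm(n, 0, 1))

  data.frame(species_id = species,
             local_abundance = as.numeric(ab),
             spread_rate = as.numeric(sp),
             seed_mass = as.numeric(seed_mass),
             longevity = ifelse(longevity == 1L, "perennial", "annual_biennial"),
             min_residence_time = as.integer(mrt),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic trait world
#'
#' Runs every generator stage in order under deterministic per-stage seeds
#' derived from `config$seed`, and returns the bundle every downstream module
#' consumes: taxonomy, phylogeny, true log-scale species means, trait
#' records, invasiveness table and the configuration echo.
#'
#' @param config A [world_config()].
#' @return An object of class `synthetic_world`.
#' @examples
#' w <- generate_world(world_config(n_families = 3, genera_per_family = 2,
#'                                  species_per_genus = 2, seed = 42))
#' w
#' @export
generate_world <- function(config = world_config()) {
  taxonomy <- generate_taxonomy(config)
  true_means <- generate_true_means(taxonomy, config)
  phylogeny <- generate_phylogeny(taxonomy)
  records <- sample_records(true_means, config)
  invasiveness <- generate_invasiveness(true_means, config)
  stopifnot(all(records$species_id %in% taxonomy$species_id),
            setequal(phylogeny$tip.label, taxonomy$species_id))
  structure(list(taxonomy = taxonomy,
                 phylogeny = phylogeny,
                 true_means = true_means,
                 records = records,
                 invasiveness = invasiveness,
                 beta_true = config$beta_true,
                 config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic trait world\n")
  cat(sprintf("  %d species, %d genera, %d families; traits: %s\n",
              nrow(x$taxonomy), length(unique(x$taxonomy$genus)),
              length(unique(x$taxonomy$family)),
              paste(colnames(x$true_means), collapse = ", ")))
  tab <- table(x$records$source)
  cat(sprintf("  records: %d on-site, %d off-site\n",
              if ("on_site" %in% names(tab)) tab[["on_site"]] else 0L,
              if ("off_site" %in% names(tab)) tab[["off_site"]] else 0L))
  invisible(x)
}

#' Write all world artifacts to a directory
#'
#' Emits the standard CSV/newick/JSON artifacts: records, taxonomy, tree,
#' invasiveness table, ground-truth means and a JSON echo of the
#' configuration.
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(records = file.path(dir, "records.csv"),
             taxonomy = file.path(dir, "taxonomy.csv"),
             tree = file.path(dir, "phylogeny.nwk"),
             invasiveness = file.path(dir, "invasiveness.csv"),
             truth = file.path(dir, "true_means.csv"),
             config = file.path(dir, "world_config.json"))
  write_records(world$records, paths[["records"]])
  write_taxonomy(world$taxonomy, paths[["taxonomy"]])
  write_newick(world$phylogeny, paths[["tree"]])
  write_invasiveness(world$invasiveness, paths[["invasiveness"]])
  truth <- data.frame(species_id = rownames(world$true_means),
                      world$true_means, check.names = FALSE)
  utils::write.csv(truth, paths[["truth"]], row.names = FALSE)
  cfg <- world$config
  cfg$cross_trait_corr <- as.vector(cfg$cross_trait_corr)
  jsonlite::write_json(unclass(cfg), paths[["config"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
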