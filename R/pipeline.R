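#' Configuration of an end-to-end run
#'
#' Exactly one of `world` (generate a synthetic world) or `paths` (load
#' records/taxonomy/tree/invasiveness CSVs + newick) may be active.
#'
#' @param world A [world_config()], or NULL when loading from files.
#' @param paths Named list with `records`, `taxonomy`, `phylogeny`,
#'   `invasiveness`, or NULL.
#' @param engines An [engines_config()].
#' @param strategies Strategies to build (subset of I..VI).
#' @param traits Focal traits; default the first trait for abundance models
#'   and the second for spread models when present (`sla`, `height` under
#'   the default world).
#' @param filter_rules Record-exclusion rules, see [filter_records()].
#' @param evaluate Run the leave-out evaluations for the three imputation
#'   methods.
#' @param uniform_roster Intersect all built rosters before fitting the
#'   regressions (uniform-sample-size sensitivity mode).
#' @param out_dir Output directory, or NULL for no file output.
#' @param seed Global seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(world = world_config(), paths = NULL,
                       engines = engines_config(),
                       strategies = c("I", "II", "III", "IV", "V", "VI"),
                       traits = NULL,
                       filter_rules = c("woody", "shade_or_experimental",
                                        "immature", "out_of_env",
                                        "single_record"),
                       evaluate = TRUE, uniform_roster = FALSE,
                       out_dir = NULL, seed = 1L) {
  if (is.null(world) == is.null(paths))
    stop("exactly one of world or paths must be given", call. = FALSE)
  strategies <- vapply(strategies, normalize_strategy, "")
  structure(list(world = world, paths = paths, engines = engines,
                 strategies = unname(strategies), traits = traits,
                 filter_rules = filter_rules, evaluate = evaluate,
                 uniform_roster = uniform_roster, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

load_inputs <- function(config) {
  if (!is.null(config$world)) {
    w <- config$world
    w$seed <- config$seed
    world <- generate_world(do.call(world_config, unclass(w)))
    list(records = world$records, taxonomy = world$taxonomy,
         phylogeny = world$phylogeny, invasiveness = world$invasiveness,
         world = world)
  } else {
    p <- config$paths
    list(records = read_records(p$records),
         taxonomy = read_taxonomy(p$taxonomy),
         phylogeny = read_newick(p$phylogeny),
         invasiveness = read_invasiveness(p$invasiveness),
         world = NULL)
  }
}

#' Run the full dataset-construction and inference pipeline
#'
#' Generates (or loads) the inputs, filters records, builds the requested
#' trait datasets under every strategy, runs the leave-out evaluations for
#' the taxonomic/phylogenetic/matrix-factorization methods, computes the
#' pairwise dataset correlation matrix (strategies I-V; VI is kept out of
#' pairwise comparisons because its roster differs), the on-site/off-site
#' correlation, and the per-strategy invasiveness regressions with their
#' effect-consistency comparison. When `out_dir` is set, every table is
#' written as CSV plus a JSON run manifest.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result` list: `datasets` (per trait, per strategy),
#'   `evaluations`, `comparisons`, `onsite_offsite`, `regressions`,
#'   `consistency`, `filter_report`, `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  inputs <- load_inputs(config)
  flt <- filter_records(inputs$records, config$filter_rules)
  records <- flt$records
  target_species <- sort(unique(
    records$species_id[records$source == "on_site"]))

  traits <- config$traits
  if (is.null(traits)) {
    avail <- sort(unique(records$trait))
    traits <- intersect(c("sla", "height"), avail)
    if (length(traits) == 0L) traits <- avail[1L]
  }

  datasets <- list()
  for (tr in traits) {
    datasets[[tr]] <- list()
    for (s in config$strategies) {
      datasets[[tr]][[s]] <- build_dataset(
        s, records, inputs$taxonomy, inputs$phylogeny,
        target_species = target_species, trait = tr,
        engines = config$engines, seed = config$seed)
    }
  }

  evaluations <- NULL
  if (config$evaluate) {
    evaluations <- list()
    for (tr in traits) {
      subset <- intersect(target_species,
                          unique(records$species_id[
                            records$trait == tr &
                              records$source == "off_site"]))
      if (length(subset) < 3L) next
      evaluations[[tr]] <- lapply(
        c(taxonomic = "taxonomic", phylo = "phylo", pmf = "pmf"),
        function(m) tryCatch(
          evaluate_imputation(records, inputs$taxonomy, inputs$phylogeny,
                              trait = tr, method = m,
                              species_subset = subset,
                              engines = config$engines,
                              seed = config$seed),
          error = function(e) NULL))
    }
  }

  comparisons <- list()
  for (tr in traits) {
    built <- intersect(config$strategies, c("I", "II", "III", "IV", "V"))
    if (length(built) >= 2L) {
      rows <- list()
      for (i in seq_len(length(built) - 1L)) {
        for (j in (i + 1L):length(built)) {
          cmp <- tryCatch(compare_datasets(datasets[[tr]][[built[i]]],
                                           datasets[[tr]][[built[j]]]),
                          error = function(e) NULL)
          if (!is.null(cmp))
            rows[[length(rows) + 1L]] <-
              data.frame(trait = tr, d1 = built[i], d2 = built[j],
                         pearson_r = cmp$pearson_r,
                         spearman_rho = cmp$spearman_rho,
                         n_common = cmp$n_common, stringsAsFactors = FALSE)
        }
      }
      comparisons[[tr]] <- do.call(rbind, rows)
    }
  }

  onsite_offsite <- tryCatch(
    onsite_offsite_correlation(records, species = target_species),
    error = function(e) NULL)

  response_of_trait <- c(sla = "local_abundance", height = "spread_rate")
  regressions <- list(); consistency <- list()
  for (tr in traits) {
    resp <- response_of_trait[[tr]] %||% "local_abundance"
    roster_cut <- NULL
    if (config$uniform_roster)
      roster_cut <- Reduce(intersect, lapply(datasets[[tr]], `[[`, "roster"))
    fits <- list()
    for (s in config$strategies) {
      ds <- datasets[[tr]][[s]]
      if (!is.null(roster_cut)) {
        ds$summaries <- ds$summaries[ds$summaries$species_id %in%
                                       roster_cut, , drop = FALSE]
        ds$roster <- ds$summaries$species_id
      }
      fit <- tryCatch({
        d <- prepare_design(ds, inputs$invasiveness, response = resp)
        fit_invasiveness_model(d, regression_config(seed = config$seed))
      }, error = function(e) NULL)
      if (!is.null(fit)) fits[[s]] <- fit
    }
    regressions[[resp]] <- fits
    if (length(fits) >= 2L) {
      inc <- setdiff(names(fits), "VI")
      if (length(inc) >= 2L)
        consistency[[resp]] <- compare_effects(fits[inc])
    }
  }

  manifest <- list(
    seed = config$seed,
    strategies = config$strategies,
    traits = traits,
    n_target_species = length(target_species),
    n_records = nrow(records),
    filter = flt$report[c("n_input", "n_output")],
    datasets = lapply(traits, function(tr)
      lapply(datasets[[tr]], function(d)
        list(strategy = d$strategy, n = length(d$roster)))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  result <- structure(list(datasets = datasets, evaluations = evaluations,
                           comparisons = comparisons,
                           onsite_offsite = onsite_offsite,
                           regressions = regressions,
                           consistency = consistency,
                           filter_report = flt$report,
                           target_species = target_species,
                           manifest = manifest, config = config,
                           world = inputs$world),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result,
                                                      config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run\n")
  cat(sprintf("  traits: %s; strategies: %s\n",
              paste(names(x$datasets), collapse = ", "),
              paste(x$config$strategies, collapse = ", ")))
  cat(sprintf("  %d target species; %d records after filtering\n",
              length(x$target_species), x$manifest$n_records))
  for (resp in names(x$regressions))
    cat(sprintf("  %s models: %d fitted\n", resp,
                length(x$regressions[[resp]])))
  invisible(x)
}

write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in names(result$datasets)) {
    tabs <- lapply(result$datasets[[tr]], dataset_table)
    utils::write.csv(do.call(rbind, tabs),
                     file.path(dir, paste0("datasets_", tr, ".csv")),
                     row.names = FALSE)
    if (!is.null(result$comparisons[[tr]]))
      utils::write.csv(result$comparisons[[tr]],
                       file.path(dir, paste0("comparisons_", tr, ".csv")),
                       row.names = FALSE)
    if (!is.null(result$evaluations[[tr]])) {
      ev <- result$evaluations[[tr]]
      rows <- do.call(rbind, lapply(names(ev), function(m)
        if (!is.null(ev[[m]]))
          data.frame(trait = tr, method = m, r2 = ev[[m]]$r2,
                     n = nrow(ev[[m]]$pairs), stringsAsFactors = FALSE)))
      utils::write.csv(rows,
                       file.path(dir, paste0("evaluation_", tr, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(result$onsite_offsite))
    utils::write.csv(result$onsite_offsite,
                     file.path(dir, "onsite_offsite_correlation.csv"),
                     row.names = FALSE)
  for (resp in names(result$regressions)) {
    rows <- do.call(rbind, lapply(names(result$regressions[[resp]]),
                                  function(s) {
      f <- result$regressions[[resp]][[s]]
      cbind(data.frame(response = resp, strategy = s, n = f$n, r2 = f$r2,
                       stringsAsFactors = FALSE), f$terms)
    }))
    utils::write.csv(rows,
                     file.path(dir, paste0("regressions_", resp, ".csv")),
                     row.names = FALSE)
    if (!is.null(result$consistency[[resp]]))
      utils::write.csv(result$consistency[[resp]]$differences,
                       file.path(dir, paste0("consistency_", resp, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Replicated recovery experiment
#'
#' Re-runs the core recovery checks over independent synthetic worlds: the
#' leave-out R-squared of the taxonomic and matrix-factorization imputers,
#' the error of the regression coefficient estimates against the generating
#' effects, and whether each 95% credible interval covers its true effect.
#' Regressions are fit on the ground-truth trait means so that coefficient
#' recovery isolates the inference machinery.
#'
#' @param config A [run_config()] with a `world` (worlds are re-generated
#'   per replicate with derived seeds).
#' @param n_replicates Number of replicate worlds.
#' @return A list of class `recovery_experiment` with `replicates` (long
#'   table: replicate, metric, label, value) and `summary` (mean and Monte
#'   Carlo standard error per metric/label).
#' @export
run_recovery_experiment <- function(config = run_config(),
                                    n_replicates = 5L) {
  stopifnot(n_replicates >= 1L)
  if (is.null(config$world))
    stop("recovery experiments need a generated world", call. = FALSE)
  rows <- list()
  add <- function(rep, metric, label, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      replicate = rep, metric = metric, label = label, value = value,
      stringsAsFactors = FALSE)

  for (r in seq_len(n_replicates)) {
    wcfg <- config$world
    wcfg$seed <- (config$seed + 1009L * r) %% 2147483629L
    world <- generate_world(do.call(world_config, unclass(wcfg)))
    records <- filter_records(world$records, config$filter_rules)$records
    tr <- world$config$trait_names[1L]
    off_sp <- sort(unique(records$species_id[
      records$trait == tr & records$source == "off_site"]))
    target <- sort(unique(records$species_id[records$source == "on_site"]))
    # hold out the target species with off-site records, keeping the rest
    # of the off-site pool as the imputation reference
    subset <- intersect(target, off_sp)
    if (length(setdiff(off_sp, subset)) == 0L)
      subset <- subset[seq_len(length(subset) %/% 2L)]
    if (length(subset) >= 5L) {
      for (m in c("taxonomic", "pmf")) {
        ev <- evaluate_imputation(records, world$taxonomy,
                                  world$phylogeny, trait = tr, method = m,
                                  species_subset = subset,
                                  engines = config$engines,
                                  seed = wcfg$seed)
        add(r, "leave_out_r2", m, ev$r2)
      }
    }
    # coefficient recovery on ground-truth predictors
    inv <- world$invasiveness
    tm <- world$true_means
    std <- function(x) (x - mean(x)) / stats::sd(x)
    beta <- world$beta_true$local_abundance
    X <- cbind(sla = std(tm[, "sla"]),
               seed_mass = std(tm[, "seed_mass"]),
               min_residence_time = std(inv$min_residence_time))
    y <- std(stats::qlogis(inv$local_abundance))
    fit <- fit_invasiveness_model(
      list(X = X, y = y, response = "local_abundance",
           strategy = "truth", trait = "sla"),
      regression_config(seed = wcfg$seed))
    # truth on the standardized response scale
    scale_y <- stats::sd(stats::qlogis(inv$local_abundance))
    for (term in names(beta)) {
      est <- fit$terms$estimate[fit$terms$term == term]
      lo <- fit$terms$lower95[fit$terms$term == term]
      hi <- fit$terms$upper95[fit$terms$term == term]
      truth <- beta[[term]] / scale_y
      add(r, "beta_error", term, est - truth)
      add(r, "beta_covered", term, as.numeric(lo <= truth & truth <= hi))
    }
  }
  long <- do.call(rbind, rows)
  agg <- stats::aggregate(value ~ metric + label, long, function(v)
    c(mean = mean(v), mc_se = stats::sd(v) / sqrt(length(v))))
  summary <- data.frame(metric = agg$metric, label = agg$label,
                        mean = agg$value[, "mean"],
                        mc_se = agg$value[, "mc_se"],
                        stringsAsFactors = FALSE)
  structure(list(replicates = long, summary = summary),
            class = "recovery_experiment")
}

#' @export
print.recovery_experiment <- function(x, ...) {
  cat(sprintf("Recovery experiment: %d replicates\n",
              max(x$replicates$replicate)))
  s <- x$summary
  s$mean <- round(s$mean, 3); s$mc_se <- round(s$mc_se, 4)
  print(s, row.names = FALSE)
  invisible(x)
}
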