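#' Read and validate a long-format trait record table
#'
#' One row per measurement: `species_id`, `trait`, `value` (raw units,
#' strictly positive), `source` (`on_site`/`off_site`) and the four boolean
#' exclusion flags (`woody_flag`, `shade_or_experimental_flag`,
#' `immature_flag`, `out_of_env_flag`). Files are UTF-8, comma-separated,
#' "." decimal, header mandatory. Readers reject invalid rows rather than
#' coercing them, naming the offending row.
#'
#' @param path Path to a records CSV.
#' @param traits Optional character vector of allowed trait names; records of
#'   other traits are an error.
#' @return A validated data.frame of trait records, row order preserved.
#' @export
read_records <- function(path, traits = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species_id", "trait", "value", "source", "woody_flag",
                "shade_or_experimental_flag", "immature_flag", "out_of_env_flag")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("records file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  validate_records(df, traits = traits)
  df
}

validate_records <- function(df, traits = NULL) {
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0L)
      stop(what, " in record row ", i[1L], call. = FALSE)
  }
  val <- suppressWarnings(as.numeric(df$value))
  bad_row(is.na(val), "non-numeric trait value")
  bad_row(val <= 0, "non-positive trait value")
  bad_row(!df$source %in% c("on_site", "off_site"), "unknown source")
  if (!is.null(traits))
    bad_row(!df$trait %in% traits, "trait outside the declared trait set")
  for (fl in c("woody_flag", "shade_or_experimental_flag",
               "immature_flag", "out_of_env_flag")) {
    v <- df[[fl]]
    if (!is.logical(v)) {
      v2 <- as.logical(v)
      bad_row(is.na(v2), paste0("non-boolean ", fl))
    }
  }
  invisible(df)
}

#' @rdname read_records
#' @param records A validated record data.frame.
#' @export
write_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a taxonomy table
#'
#' Expects columns `species_id`, `genus`, `family`; species ids must be
#' unique and no field may be empty.
#'
#' @param path Path to a taxonomy CSV.
#' @return A validated data.frame.
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species_id", "genus", "family")
  if (!all(required %in% names(df)))
    stop("taxonomy file must have columns species_id, genus, family",
         call. = FALSE)
  if (anyDuplicated(df$species_id))
    stop("duplicated species_id in taxonomy: ",
         df$species_id[anyDuplicated(df$species_id)], call. = FALSE)
  empty <- !nzchar(df$species_id) | !nzchar(df$genus) | !nzchar(df$family) |
    is.na(df$species_id) | is.na(df$genus) | is.na(df$family)
  if (any(empty))
    stop("empty taxonomy field in row ", which(empty)[1L], call. = FALSE)
  df
}

#' @rdname read_taxonomy
#' @param taxonomy A taxonomy data.frame.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.csv(taxonomy[, c("species_id", "genus", "family")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a per-species invasiveness table
#'
#' Columns: `species_id` (unique), `local_abundance` in the open interval
#' (0,1) (maximum relative cover; the boundary values are rejected because
#' the regression stage logit-transforms this column), `spread_rate` > 0,
#' `seed_mass` > 0, `longevity` in \{annual_biennial, perennial\},
#' `min_residence_time` a non-negative integer number of years.
#'
#' @param path Path to an invasiveness CSV.
#' @return A validated data.frame.
#' @export
read_invasiveness <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("species_id", "local_abundance", "spread_rate", "seed_mass",
                "longevity", "min_residence_time")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L)
    stop("invasiveness file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$species_id))
    stop("duplicated species_id in invasiveness table", call. = FALSE)
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0L) stop(what, " in row ", i[1L], call. = FALSE)
  }
  bad_row(!is.finite(df$local_abundance) | df$local_abundance <= 0 |
            df$local_abundance >= 1,
          "local_abundance outside the open interval (0,1)")
  bad_row(!is.finite(df$spread_rate) | df$spread_rate <= 0,
          "non-positive spread_rate")
  bad_row(!is.finite(df$seed_mass) | df$seed_mass <= 0,
          "non-positive seed_mass")
  bad_row(!df$longevity %in% c("annual_biennial", "perennial"),
          "unknown longevity class")
  bad_row(is.na(df$min_residence_time) | df$min_residence_time < 0 |
            df$min_residence_time != round(df$min_residence_time),
          "min_residence_time is not a non-negative integer")
  df
}

#' @rdname read_invasiveness
#' @param invasiveness An invasiveness data.frame.
#' @export
write_invasiveness <- function(invasiveness, path) {
  utils::write.csv(invasiveness, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a phylogeny in newick format
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that enforce
#' the invariants downstream matching relies on: tip labels must be unique
#' and branch lengths present.
#'
#' @param path Path to a newick file.
#' @return For `read_newick`, an `ape` `phylo` object.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("newick parse error: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree)) stop("newick parse error: no tree in file", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels in tree", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  tree
}

#' @rdname read_newick
#' @param tree An `ape` `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
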