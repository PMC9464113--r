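#' Find phylogenetic equivalents for species without data
#'
#' For each species lacking trait records, identifies the data-bearing tips
#' at minimal patristic distance (sum of branch lengths along the connecting
#' path). All tips tied at the minimum (within a small numerical tolerance)
#' are retained as candidates rather than broken arbitrarily; species with no
#' data-bearing tip in the tree are reported as unmatched.
#'
#' @param phylogeny An `ape` `phylo` with branch lengths.
#' @param species_with_data Tips that carry trait records.
#' @param species_missing Tips needing a stand-in; disjoint from
#'   `species_with_data`.
#' @param tol Tie tolerance on patristic distance.
#' @return An `equivalent_map`: per missing species a data.frame of
#'   `candidate` and `distance` rows (empty if unmatched), plus the unmatched
#'   species vector.
#' @export
find_phylo_equivalents <- function(phylogeny, species_with_data,
                                   species_missing, tol = 1e-8) {
  tips <- phylogeny$tip.label
  not_tip <- setdiff(c(species_with_data, species_missing), tips)
  if (length(not_tip) > 0L)
    stop("species not in the tree: ", paste(not_tip, collapse = ", "),
         call. = FALSE)
  if (length(intersect(species_with_data, species_missing)) > 0L)
    stop("species_with_data and species_missing must be disjoint",
         call. = FALSE)
  dmat <- ape::cophenetic.phylo(phylogeny)
  donors <- intersect(tips, species_with_data)
  cand <- lapply(species_missing, function(s) {
    if (length(donors) == 0L)
      return(data.frame(candidate = character(), distance = numeric(),
                        stringsAsFactors = FALSE))
    d <- dmat[s, donors]
    keep <- which(d <= min(d) + tol)
    data.frame(candidate = donors[keep], distance = as.numeric(d[keep]),
               stringsAsFactors = FALSE)
  })
  names(cand) <- species_missing
  unmatched <- species_missing[vapply(cand, nrow, 0L) == 0L]
  structure(list(candidates = cand, unmatched = unmatched,
                 policy = "nearest-patristic-tip, all ties retained"),
            class = "equivalent_map")
}

#' @export
print.equivalent_map <- function(x, ...) {
  n <- length(x$candidates)
  cat(sprintf("Phylogenetic equivalent map: %d species, %d unmatched\n",
              n, length(x$unmatched)))
  invisible(x)
}

#' @describeIn find_phylo_equivalents Export the map as a long data.frame
#'   (`missing_species`, `candidate`, `distance`).
#' @param map An `equivalent_map`.
#' @export
equivalent_map_table <- function(map) {
  rows <- lapply(names(map$candidates), function(s) {
    df <- map$candidates[[s]]
    if (nrow(df) == 0L) return(NULL)
    cbind(data.frame(missing_species = s, stringsAsFactors = FALSE), df)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(missing_species = character(), candidate = character(),
                      distance = numeric(), stringsAsFactors = FALSE)
  out
}

#' Impute species means by resampling phylogenetic equivalents
#'
#' Per missing species, draws one candidate uniformly at random per
#' iteration and records that candidate's mean; the imputed value is the
#' across-iteration mean and its uncertainty the across-iteration sd
#' (0 when a single candidate exists). Species with an empty candidate set
#' are excluded and reported.
#'
#' @param map An `equivalent_map` from [find_phylo_equivalents()].
#' @param summaries Data.frame of measured species summaries with columns
#'   `species_id` and `mean` covering every candidate.
#' @param n_iter Number of resampling iterations.
#' @param seed Integer seed; output is deterministic given it.
#' @return A data.frame (`species_id`, `mean`, `sd`, `n_records`,
#'   `provenance = "imputed_phylo"`), one row per matched species; excluded
#'   species in `attr(, "excluded")`.
#' @export
impute_phylogenetic <- function(map, summaries, n_iter = 1000L, seed = 1L) {
  stopifnot(inherits(map, "equivalent_map"), n_iter >= 1L)
  set.seed(as.integer(seed))
  matched <- setdiff(names(map$candidates), map$unmatched)
  out <- lapply(matched, function(s) {
    cands <- map$candidates[[s]]$candidate
    idx <- match(cands, summaries$species_id)
    if (anyNA(idx))
      stop("candidate without a measured summary: ",
           paste(cands[is.na(idx)], collapse = ", "), call. = FALSE)
    mu <- summaries$mean[idx]
    draws <- mu[sample.int(length(mu), n_iter, replace = TRUE)]
    data.frame(species_id = s, mean = mean(draws),
               sd = if (length(mu) == 1L) 0 else stats::sd(draws),
               n_records = 0L, provenance = "imputed_phylo",
               stringsAsFactors = FALSE)
  })
  res <- if (length(out) > 0L) do.call(rbind, out) else
    data.frame(species_id = character(), mean = numeric(), sd = numeric(),
               n_records = integer(), provenance = character(),
               stringsAsFactors = FALSE)
  attr(res, "excluded") <- map$unmatched
  res
}
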