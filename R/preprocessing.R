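#' Apply record-exclusion rules before modeling
#'
#' Drops records carrying any active exclusion flag (woody species, shaded or
#' experimental growing conditions, immature individuals, environmental
#' conditions outside the study region), then applies the single-record rule:
#' within each (species, trait), if exactly one off-site record remains, that
#' record is dropped too, because a single measurement cannot anchor the
#' imputation reference pool. On-site records are never touched by the
#' single-record rule. A record excluded by several flags is counted once,
#' under the first active rule in `rules` order, so the report balances
#' exactly.
#'
#' @param records A validated record data.frame (see [read_records()]).
#' @param rules Character vector of active rules, a subset of
#'   `c("woody", "shade_or_experimental", "immature", "out_of_env",
#'   "single_record")`. Defaults to all.
#' @return A list with `records` (the retained rows, original order) and
#'   `report`, a `filter_report` with `n_input`, `n_excluded_by_rule` and
#'   `n_output` satisfying `n_input == n_output + sum(n_excluded_by_rule)`.
#' @export
filter_records <- function(records,
                           rules = c("woody", "shade_or_experimental",
                                     "immature", "out_of_env",
                                     "single_record")) {
  known <- c("woody", "shade_or_experimental", "immature", "out_of_env",
             "single_record")
  bad <- setdiff(rules, known)
  if (length(bad) > 0L)
    stop("unknown filter rule(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n_input <- nrow(records)
  excluded_by <- rep(NA_character_, n_input)
  flag_col <- c(woody = "woody_flag",
                shade_or_experimental = "shade_or_experimental_flag",
                immature = "immature_flag",
                out_of_env = "out_of_env_flag")
  for (rule in intersect(rules, names(flag_col))) {
    hit <- is.na(excluded_by) & as.logical(records[[flag_col[[rule]]]])
    excluded_by[hit] <- rule
  }
  if ("single_record" %in% rules && n_input > 0L) {
    keep <- is.na(excluded_by)
    off <- keep & records$source == "off_site"
    key <- paste(records$species_id, records$trait)
    cnt <- table(key[off])
    single <- off & cnt[key] == 1L
    excluded_by[which(single)] <- "single_record"
  }
  counts <- vapply(rules, function(r) sum(excluded_by == r, na.rm = TRUE), 0L)
  out <- records[is.na(excluded_by), , drop = FALSE]
  rownames(out) <- NULL
  report <- structure(list(n_input = n_input,
                           n_excluded_by_rule = as.list(counts),
                           n_output = nrow(out)),
                      class = "filter_report")
  stopifnot(report$n_input == report$n_output + sum(counts))
  list(records = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Record filter: %d in, %d out\n", x$n_input, x$n_output))
  for (r in names(x$n_excluded_by_rule))
    cat(sprintf("  %-22s %d\n", r, x$n_excluded_by_rule[[r]]))
  invisible(x)
}

#' Log-transform and standardize trait values
#'
#' `log_standardize` maps strictly positive raw values to
#' `(log(x) - m) / s` where `m` and `s` are the mean and sample (n-1) sd of
#' the log values; the parameters are returned so the transform can be
#' inverted and so one pooled scale can be shared across datasets (effects
#' estimated on different datasets are then directly comparable).
#' `inverse_log_standardize` is its exact inverse.
#'
#' @param values Strictly positive numeric vector (length >= 2, not all
#'   equal) when `params` is NULL.
#' @param params Optional precomputed `list(mean=, sd=)` of log-scale
#'   parameters; supply these to place new values on an existing scale.
#' @return For `log_standardize`, a list with `values` (standardized) and
#'   `params`; for `inverse_log_standardize`, the raw-scale values.
#' @examples
#' z <- log_standardize(c(1, exp(2)))
#' z$values                                  # +/- 1/sqrt(2)
#' inverse_log_standardize(z$values, z$params)
#' @export
log_standardize <- function(values, params = NULL) {
  if (any(!is.finite(values) | values <= 0))
    stop("log_standardize requires strictly positive finite values",
         call. = FALSE)
  lv <- log(values)
  if (is.null(params)) {
    if (length(lv) < 2L)
      stop("need at least 2 values to estimate a scale", call. = FALSE)
    s <- stats::sd(lv)
    if (!is.finite(s) || s == 0)
      stop("zero variance: cannot standardize identical values",
           call. = FALSE)
    params <- list(mean = mean(lv), sd = s)
  }
  list(values = (lv - params$mean) / params$sd, params = params)
}

#' @rdname log_standardize
#' @param standardized Numeric vector on the standardized log scale.
#' @export
inverse_log_standardize <- function(standardized, params) {
  exp(standardized * params$sd + params$mean)
}
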