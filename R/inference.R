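#' Prepare a design matrix for an invasiveness model
#'
#' Applies the case-study transforms: local abundance is logit-transformed,
#' spread rate log-transformed, both then standardized; the focal trait
#' (the dataset's trait), seed mass (log) and minimum residence time are
#' standardized; longevity enters as a 0/1 dummy (annual/biennial = 0,
#' perennial = 1) and is not standardized. Abundance models use
#' \{focal trait, seed mass, residence time\}; spread models use
#' \{focal trait, seed mass, longevity\}.
#'
#' @param dataset A `trait_dataset` supplying the focal trait means.
#' @param invasiveness Validated invasiveness table.
#' @param response `"local_abundance"` or `"spread_rate"`.
#' @param boundary How to treat abundance values at 0 or 1: `"error"`
#'   (default) or `"squeeze"`, the (y(n-1)+0.5)/n compression.
#' @return A list of class `invasiveness_design`: `X` (predictor matrix,
#'   no intercept), `y` (standardized transformed response), `species`,
#'   `response`, `strategy`, `trait`.
#' @export
prepare_design <- function(dataset, invasiveness,
                           response = c("local_abundance", "spread_rate"),
                           boundary = c("error", "squeeze")) {
  response <- match.arg(response)
  boundary <- match.arg(boundary)
  roster <- intersect(dataset$summaries$species_id,
                      invasiveness$species_id)
  if (length(roster) == 0L)
    stop("no species shared between dataset and invasiveness table",
         call. = FALSE)
  inv <- invasiveness[match(roster, invasiveness$species_id), ]
  std <- function(x) (x - mean(x)) / stats::sd(x)

  trait_vals <- dataset$summaries$mean[match(roster,
                                             dataset$summaries$species_id)]
  if (response == "local_abundance") {
    y_raw <- inv$local_abundance
    if (any(y_raw <= 0 | y_raw >= 1)) {
      if (boundary == "error")
        stop("local_abundance values at or beyond the (0,1) boundary; ",
             "use boundary = \"squeeze\" to compress them", call. = FALSE)
      n <- length(y_raw)
      y_raw <- (y_raw * (n - 1) + 0.5) / n
    }
    y <- std(stats::qlogis(y_raw))
    X <- cbind(std(trait_vals),
               std(log(inv$seed_mass)),
               std(inv$min_residence_time))
    colnames(X) <- c(dataset$trait, "seed_mass", "min_residence_time")
  } else {
    if (any(inv$spread_rate <= 0))
      stop("spread_rate must be strictly positive", call. = FALSE)
    y <- std(log(inv$spread_rate))
    X <- cbind(std(trait_vals),
               std(log(inv$seed_mass)),
               as.numeric(inv$longevity == "perennial"))
    colnames(X) <- c(dataset$trait, "seed_mass", "longevity")
  }
  rownames(X) <- roster
  structure(list(X = X, y = as.numeric(y), species = roster,
                 response = response, strategy = dataset$strategy,
                 trait = dataset$trait),
            class = "invasiveness_design")
}

#' Settings for the Bayesian linear invasiveness model
#'
#' @param n_draws Posterior draws used for interval summaries.
#' @param seed Integer seed for the posterior sampling.
#' @param r2_method Deviance-explained convention: `"cor"` (squared Pearson
#'   correlation of fitted vs observed, the default) or `"rss"`
#'   (1 - RSS/TSS).
#' @param prior `"flat"` (improper uniform on coefficients, Jeffreys on the
#'   variance; posterior means equal least squares exactly) or `"gprior"`
#'   (Zellner g-prior shrinking toward zero).
#' @param g g-prior scale (default n is used when NULL).
#' @return A list of class `regression_config`.
#' @export
regression_config <- function(n_draws = 4000L, seed = 1L,
                              r2_method = c("cor", "rss"),
                              prior = c("flat", "gprior"), g = NULL) {
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 r2_method = match.arg(r2_method),
                 prior = match.arg(prior), g = g),
            class = "regression_config")
}

#' Fit a Bayesian normal linear model of invasiveness on traits
#'
#' Conjugate normal linear model `y ~ N(alpha + X beta, sd^2)`. Under the
#' default flat prior the posterior is the exact normal-inverse-chi-square
#' form around the least-squares solution, from which `n_draws` joint draws
#' are taken for the 95% central credible intervals. Reports deviance
#' explained (R^2), variance inflation factors computed from the design
#' matrix, and residuals for diagnostics.
#'
#' @param design An `invasiveness_design` (or a list with `X` and `y`).
#' @param config A [regression_config()].
#' @return A `regression_result`: `terms` (term, estimate, lower95, upper95,
#'   significant), `draws`, `r2`, `vif`, `n`, `residuals`, `fitted`,
#'   `sigma`, plus the design metadata.
#' @export
fit_invasiveness_model <- function(design, config = regression_config()) {
  X <- design$X; y <- design$y
  n <- length(y); p <- ncol(X) + 1L
  if (n <= p + 2L)
    stop("need n > p + 2 observations", call. = FALSE)
  Xd <- cbind(`(Intercept)` = 1, X)
  qrX <- qr(Xd)
  if (qrX$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1L):ncol(Xd)]]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  XtX_inv <- chol2inv(qr.R(qrX))
  beta_hat <- qr.coef(qrX, y)
  fitted <- as.numeric(Xd %*% beta_hat)
  resid <- y - fitted
  rss <- sum(resid^2)
  nu <- n - ncol(Xd)
  s2 <- rss / nu

  shrink <- 1
  if (config$prior == "gprior") {
    g <- if (is.null(config$g)) n else config$g
    shrink <- g / (1 + g)
  }
  set.seed(config$seed)
  sig2_draws <- rss * shrink / stats::rchisq(config$n_draws, df = nu)
  L <- chol(XtX_inv)
  Z <- matrix(stats::rnorm(config$n_draws * ncol(Xd)), config$n_draws)
  beta_draws <- matrix(rep(shrink * beta_hat, each = config$n_draws),
                       config$n_draws) +
    (Z %*% L) * sqrt(sig2_draws)
  colnames(beta_draws) <- colnames(Xd)

  qs <- apply(beta_draws, 2L, stats::quantile, probs = c(0.025, 0.975))
  terms <- data.frame(term = colnames(Xd),
                      estimate = colMeans(beta_draws),
                      lower95 = qs[1L, ], upper95 = qs[2L, ],
                      stringsAsFactors = FALSE, row.names = NULL)
  terms$significant <- terms$lower95 > 0 | terms$upper95 < 0

  r2 <- if (config$r2_method == "cor")
    stats::cor(fitted, y)^2 else 1 - rss / sum((y - mean(y))^2)
  vif <- vapply(seq_len(ncol(X)), function(j) {
    if (ncol(X) == 1L) return(1)
    r2j <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    1 / (1 - r2j)
  }, 0)
  names(vif) <- colnames(X)

  structure(list(terms = terms, draws = beta_draws, r2 = r2, vif = vif,
                 n = n, residuals = resid, fitted = fitted,
                 sigma = sqrt(mean(sig2_draws)),
                 response = design$response, strategy = design$strategy,
                 trait = design$trait),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("Invasiveness model: %s ~ traits [%s], n = %d, R^2 = %.3f\n",
              x$response, x$strategy %||% "", x$n, x$r2))
  df <- x$terms
  df$estimate <- round(df$estimate, 3)
  df$lower95 <- round(df$lower95, 3)
  df$upper95 <- round(df$upper95, 3)
  print(df, row.names = FALSE)
  cat(sprintf("  max VIF %.2f\n", max(x$vif)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare trait effects across datasets
#'
#' For every pair of fitted models on the same response and every shared
#' predictor, summarises the posterior of the effect difference
#' `beta_d1 - beta_d2` (independent posteriors) with its 95% credible
#' interval and a flag for intervals excluding zero, plus a per-model
#' sign/significance table — the effect-consistency view of the sensitivity
#' analysis.
#'
#' The two posteriors are independent, so the draw vectors are independently
#' permuted before differencing (fits produced with a shared seed would
#' otherwise have artificially coupled Monte Carlo noise).
#'
#' @param results A list of `regression_result` objects sharing a response.
#' @param seed Seed for the permutation of draws.
#' @return A list of class `effect_comparison` with `differences` and
#'   `effects` data.frames.
#' @export
compare_effects <- function(results, seed = 1L) {
  if (length(results) < 2L)
    stop("need at least 2 results to compare", call. = FALSE)
  responses <- unique(vapply(results, `[[`, "", "response"))
  if (length(responses) != 1L)
    stop("all results must model the same response; got: ",
         paste(responses, collapse = ", "), call. = FALSE)
  labels <- vapply(seq_along(results), function(i)
    results[[i]]$strategy %||% paste0("model", i), "")

  effects <- do.call(rbind, lapply(seq_along(results), function(i) {
    t <- results[[i]]$terms
    t <- t[t$term != "(Intercept)", , drop = FALSE]
    cbind(data.frame(model = labels[i], stringsAsFactors = FALSE), t)
  }))

  set.seed(as.integer(seed))
  diffs <- list()
  for (i in seq_len(length(results) - 1L)) {
    for (j in (i + 1L):length(results)) {
      shared <- setdiff(intersect(colnames(results[[i]]$draws),
                                  colnames(results[[j]]$draws)),
                        "(Intercept)")
      for (term in shared) {
        di <- results[[i]]$draws[, term]
        dj <- results[[j]]$draws[, term]
        m <- min(length(di), length(dj))
        d <- sample(di, m) - sample(dj, m)
        q <- stats::quantile(d, c(0.025, 0.975))
        diffs[[length(diffs) + 1L]] <-
          data.frame(term = term, model_1 = labels[i], model_2 = labels[j],
                     difference = mean(d), lower95 = q[[1L]],
                     upper95 = q[[2L]],
                     significant = q[[1L]] > 0 | q[[2L]] < 0,
                     stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(differences = do.call(rbind, diffs), effects = effects,
                 response = responses),
            class = "effect_comparison")
}

#' @export
print.effect_comparison <- function(x, ...) {
  n <- nrow(x$differences)
  cat(sprintf("Effect consistency (%s): %d pairwise differences, %d significant\n",
              x$response, n, sum(x$differences$significant)))
  invisible(x)
}
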