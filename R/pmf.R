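#' Settings for the hierarchical probabilistic matrix factorization
#'
#' @param k Latent dimension (2 is a sensible default for a 3-trait panel).
#' @param iter,burnin Gibbs iterations and burn-in.
#' @param sigma_sp,sigma_g,sigma_f Sds of the latent-factor hierarchy:
#'   species factors around their genus factor, genus around family, family
#'   around zero.
#' @param sigma_v Sd of the trait-factor prior.
#' @param sigma_obs_shape,sigma_obs_scale Inverse-gamma hyperparameters of
#'   the residual variance.
#' @param method `"gibbs"` (default; draws give predictive sds) or `"als"`
#'   (alternating ridge least squares with a bootstrap ensemble for spread).
#' @param n_ensemble Ensemble size for the ALS method.
#' @param ridge Ridge penalty for the ALS method.
#' @return A list of class `pmf_config`.
#' @export
pmf_config <- function(k = 2L, iter = 600L, burnin = iter %/% 2L,
                       sigma_sp = 1, sigma_g = 0.5, sigma_f = 0.5,
                       sigma_v = 1, sigma_obs_shape = 2,
                       sigma_obs_scale = 0.5,
                       method = c("gibbs", "als"),
                       n_ensemble = 30L, ridge = 1e-3) {
  method <- match.arg(method)
  stopifnot(k >= 1L, iter > burnin, sigma_sp > 0, sigma_g > 0, sigma_f > 0,
            sigma_v > 0)
  structure(list(k = as.integer(k), iter = as.integer(iter),
                 burnin = as.integer(burnin), sigma_sp = sigma_sp,
                 sigma_g = sigma_g, sigma_f = sigma_f, sigma_v = sigma_v,
                 sigma_obs_shape = sigma_obs_shape,
                 sigma_obs_scale = sigma_obs_scale, method = method,
                 n_ensemble = as.integer(n_ensemble), ridge = ridge),
            class = "pmf_config")
}

#' Fit a hierarchical probabilistic matrix factorization
#'
#' Gap-filling model for a species x trait matrix of standardized log means
#' with missing cells: observed cells are `N(U_s . V_t, sigma^2)` with
#' latent species factors `U_s` shrunk toward genus-level factors, genus
#' toward family, family toward zero, and trait factors `V_t` with a
#' zero-mean prior. Because every full conditional is normal (and the
#' residual variance inverse-gamma) the model is fit by blocked Gibbs;
#' species-row updates are batched by missingness pattern. The taxonomy
#' shrinkage lets sparse species borrow strength from relatives while the
#' low-rank structure borrows across correlated traits — so a species
#' observed for seed mass only can still receive an informed leaf-trait
#' estimate.
#'
#' Species rows are processed in canonical (sorted id) order internally, so
#' permuting input rows (with the taxonomy relabeled consistently) leaves
#' every imputation identical.
#'
#' @param mat Species x trait numeric matrix (rownames = species ids), NA
#'   for missing cells; at least 2 traits. Species missing every trait are
#'   dropped and reported.
#' @param taxonomy Taxonomy table covering the species.
#' @param k Latent dimension; overrides `config$k` when given.
#' @param config A [pmf_config()].
#' @param seed Integer seed.
#' @return A `pmf_fit` with per-cell predictive means and sds, the observed
#'   matrix and mask, the observed-cell RMSE trace, and the dropped species.
#' @export
fit_pmf <- function(mat, taxonomy, k = NULL, config = pmf_config(),
                    seed = 1L) {
  if (is.null(k)) k <- config$k
  k <- as.integer(k)
  if (ncol(mat) < 2L)
    stop("matrix factorization needs at least 2 traits", call. = FALSE)
  if (is.null(rownames(mat)))
    stop("matrix must have species ids as rownames", call. = FALSE)
  dropped <- rownames(mat)[rowSums(!is.na(mat)) == 0L]
  mat <- mat[!rownames(mat) %in% dropped, , drop = FALSE]
  if (nrow(mat) < 2L)
    stop("need at least 2 species with data", call. = FALSE)
  ord <- order(rownames(mat))
  X <- mat[ord, , drop = FALSE]
  mask <- !is.na(X)
  species <- rownames(X); traits <- colnames(X)

  tax <- taxonomy[match(species, taxonomy$species_id), ]
  if (anyNA(tax$species_id))
    stop("species missing from taxonomy", call. = FALSE)
  gen <- sort(unique(tax$genus)); fam <- sort(unique(tax$family))
  g_of_s <- match(tax$genus, gen)
  f_of_g <- match(taxonomy$family[match(gen, taxonomy$genus)], fam)
  n <- nrow(X); nt <- ncol(X)

  fit <- if (config$method == "gibbs")
    pmf_gibbs(X, mask, g_of_s, f_of_g, k, config, seed)
  else
    pmf_als_ensemble(X, mask, k, config, seed)

  structure(c(fit,
              list(species = species, traits = traits, X = X, mask = mask,
                   dropped = dropped, k = k, config = config, seed = seed)),
            class = "pmf_fit")
}

pmf_gibbs <- function(X, mask, g_of_s, f_of_g, k, config, seed) {
  n <- nrow(X); nt <- ncol(X)
  n_g <- max(g_of_s); n_f <- max(f_of_g)
  Xz <- X; Xz[!mask] <- 0
  # deterministic spectral init, then seeded chain
  sv <- svd(Xz, nu = min(k, n), nv = min(k, nt))
  kk <- min(k, length(sv$d))
  U <- matrix(0, n, k); V <- matrix(0, nt, k)
  U[, seq_len(kk)] <- sv$u[, seq_len(kk), drop = FALSE] %*%
    diag(sqrt(sv$d[seq_len(kk)]), kk)
  V[, seq_len(kk)] <- sv$v[, seq_len(kk), drop = FALSE] %*%
    diag(sqrt(sv$d[seq_len(kk)]), kk)
  Ug <- matrix(0, n_g, k); Uf <- matrix(0, n_f, k)
  sig2 <- 1

  v_sp <- config$sigma_sp^2; v_g <- config$sigma_g^2
  v_f <- config$sigma_f^2; v_v <- config$sigma_v^2
  a0 <- config$sigma_obs_shape; b0 <- config$sigma_obs_scale
  m_g <- tabulate(g_of_s, n_g); k_f <- tabulate(f_of_g, n_f)
  n_obs <- sum(mask)
  patt <- apply(mask, 1L, function(r) paste(as.integer(r), collapse = ""))
  patt_groups <- split(seq_len(n), patt)

  kept <- config$iter - config$burnin
  pred_sum <- matrix(0, n, nt); pred_sq <- matrix(0, n, nt)
  rmse_trace <- numeric(config$iter)

  set.seed(as.integer(seed))
  for (it in seq_len(config$iter)) {
    # species factors, batched by missingness pattern
    Z <- matrix(stats::rnorm(n * k), n, k)
    for (rows in patt_groups) {
      obs_t <- which(mask[rows[1L], ])
      Vo <- V[obs_t, , drop = FALSE]
      Lam <- crossprod(Vo) / sig2 + diag(1 / v_sp, k)
      C <- chol(Lam)
      Eta <- Xz[rows, obs_t, drop = FALSE] %*% Vo / sig2 +
        Ug[g_of_s[rows], , drop = FALSE] / v_sp
      Mean <- t(backsolve(C, backsolve(C, t(Eta), transpose = TRUE)))
      U[rows, ] <- Mean + t(backsolve(C, t(Z[rows, , drop = FALSE])))
    }
    # trait factors
    for (t in seq_len(nt)) {
      obs_s <- which(mask[, t])
      Uo <- U[obs_s, , drop = FALSE]
      Lam <- crossprod(Uo) / sig2 + diag(1 / v_v, k)
      C <- chol(Lam)
      eta <- crossprod(Uo, Xz[obs_s, t]) / sig2
      mu <- backsolve(C, backsolve(C, eta, transpose = TRUE))
      V[t, ] <- mu + backsolve(C, stats::rnorm(k))
    }
    # genus and family latent means (componentwise conjugate normals)
    prec_g <- m_g / v_sp + 1 / v_g
    Ug <- (rowsum(U, g_of_s) / v_sp + Uf[f_of_g, , drop = FALSE] / v_g) /
      prec_g + matrix(stats::rnorm(n_g * k), n_g, k) / sqrt(prec_g)
    prec_f <- k_f / v_g + 1 / v_f
    Uf <- (rowsum(Ug, f_of_g) / v_g) / prec_f +
      matrix(stats::rnorm(n_f * k), n_f, k) / sqrt(prec_f)
    # residual variance
    P <- U %*% t(V)
    ss <- sum((X[mask] - P[mask])^2)
    sig2 <- 1 / stats::rgamma(1L, shape = a0 + n_obs / 2,
                              rate = b0 + ss / 2)
    rmse_trace[it] <- sqrt(ss / n_obs)
    if (it > config$burnin) {
      pred_sum <- pred_sum + P
      pred_sq <- pred_sq + P^2
    }
  }
  pred_mean <- pred_sum / kept
  pred_var <- pmax(pred_sq / kept - pred_mean^2, 0)
  # unbiased across-draw sd
  pred_sd <- sqrt(pred_var * kept / max(kept - 1L, 1L))
  dimnames(pred_mean) <- dimnames(pred_sd) <- dimnames(X)
  list(pred_mean = pred_mean, pred_sd = pred_sd, rmse_trace = rmse_trace,
       sigma = sqrt(sig2))
}

pmf_als_ensemble <- function(X, mask, k, config, seed) {
  n <- nrow(X); nt <- ncol(X)
  als_once <- function(Xb, maskb) {
    V <- matrix(stats::rnorm(nt * k, 0, 0.1), nt, k)
    U <- matrix(0, n, k)
    for (sweep in seq_len(50L)) {
      for (s in seq_len(n)) {
        o <- which(maskb[s, ])
        if (length(o) == 0L) { U[s, ] <- 0; next }
        Vo <- V[o, , drop = FALSE]
        U[s, ] <- solve(crossprod(Vo) + diag(config$ridge, k),
                        crossprod(Vo, Xb[s, o]))
      }
      for (t in seq_len(nt)) {
        o <- which(maskb[, t])
        Uo <- U[o, , drop = FALSE]
        V[t, ] <- solve(crossprod(Uo) + diag(config$ridge, k),
                        crossprod(Uo, Xb[o, t]))
      }
    }
    U %*% t(V)
  }
  set.seed(as.integer(seed))
  preds <- array(0, c(n, nt, config$n_ensemble))
  for (b in seq_len(config$n_ensemble)) {
    maskb <- mask
    # bootstrap the observed cells (keep >= 1 per species)
    obs <- which(mask)
    drop <- obs[stats::runif(length(obs)) < 0.2]
    maskb[drop] <- FALSE
    bad <- rowSums(maskb) == 0L
    maskb[bad, ] <- mask[bad, ]
    preds[, , b] <- als_once(X, maskb)
  }
  pred_mean <- apply(preds, c(1L, 2L), mean)
  pred_sd <- apply(preds, c(1L, 2L), stats::sd)
  dimnames(pred_mean) <- dimnames(pred_sd) <- dimnames(X)
  P <- pred_mean
  rmse <- sqrt(mean((X[mask] - P[mask])^2))
  list(pred_mean = pred_mean, pred_sd = pred_sd, rmse_trace = rmse,
       sigma = rmse)
}

#' @export
print.pmf_fit <- function(x, ...) {
  cat(sprintf("Hierarchical PMF fit: %d species x %d traits, k = %d (%s)\n",
              length(x$species), length(x$traits), x$k, x$config$method))
  cat(sprintf("  observed cells: %d (%.0f%%); final observed RMSE %.4f\n",
              sum(x$mask), 100 * mean(x$mask),
              utils::tail(x$rmse_trace, 1L)))
  if (length(x$dropped) > 0L)
    cat(sprintf("  dropped (no data in any trait): %s\n",
                paste(x$dropped, collapse = ", ")))
  invisible(x)
}

#' Extract an imputed (or observed) cell from a PMF fit
#'
#' Observed cells are returned unchanged with provenance `measured`; missing
#' cells get the model's predictive mean and across-draw sd with provenance
#' `imputed_pmf`.
#'
#' @param fit A `pmf_fit`.
#' @param species_id Species (vectorised).
#' @param trait Single trait name.
#' @return A data.frame (`species_id`, `mean`, `sd`, `n_records`,
#'   `provenance`).
#' @export
impute_pmf <- function(fit, species_id, trait) {
  stopifnot(inherits(fit, "pmf_fit"), trait %in% fit$traits)
  i <- match(species_id, fit$species)
  if (anyNA(i))
    stop("species not retained in the PMF fit: ",
         paste(species_id[is.na(i)], collapse = ", "), call. = FALSE)
  obs <- fit$mask[cbind(i, match(trait, fit$traits))]
  j <- match(trait, fit$traits)
  data.frame(species_id = species_id,
             mean = ifelse(obs, fit$X[cbind(i, j)],
                           fit$pred_mean[cbind(i, j)]),
             sd = ifelse(obs, 0, fit$pred_sd[cbind(i, j)]),
             n_records = NA_integer_,
             provenance = ifelse(obs, "measured", "imputed_pmf"),
             stringsAsFactors = FALSE)
}
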