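# Parametric bootstrap: multivariate-normal resampling of vital-rate
# coefficients, propagation to growth rates and coexistence quantities.

#' Draw one coefficient vector from a fitted model's sampling distribution
#'
#' One multivariate-normal draw centred at the fitted coefficients with the
#' fitted covariance matrix. A covariance matrix that is not positive
#' semi-definite (within tolerance) is repaired by clipping negative
#' eigenvalues at zero, with a warning. Aliased (NA) coefficients are left NA.
#'
#' @param fit A `vital_rate_fit`.
#' @return Named coefficient vector of the same length as `fit$coef`.
#' @export
draw_parameters <- function(fit) {
  co <- fit$coef
  vc <- fit$vcov
  est <- names(co)[!is.na(co)]
  est <- intersect(est, rownames(vc))
  if (length(est) == 0 || all(vc[est, est] == 0)) return(co)
  V <- vc[est, est, drop = FALSE]
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE)
  tol <- 1e-8 * max(abs(ev$values), 1)
  if (min(ev$values) < -tol) {
    warning("covariance matrix not PSD; clipping negative eigenvalues")
    V <- ev$vectors %*% diag(pmax(ev$values, 0), nrow = length(ev$values)) %*%
      t(ev$vectors)
    dimnames(V) <- dimnames(vc[est, est, drop = FALSE])
  }
  co[est] <- MASS::mvrnorm(1, mu = co[est], Sigma = V)
  co
}

# per-context design matrices on each species' mesh, computed once per run
.context_designs <- function(fits_list, contexts, meshes) {
  lapply(seq_len(nrow(contexts)), function(r) {
    sp <- contexts$species[r]
    .context_design(fits_list[[sp]], contexts$site_elevation_m[r],
                    contexts$background[r], meshes[[sp]]$mids)
  })
}

# lambda for every context from one set of per-species coefficient draws
.lambda_for_contexts <- function(fits_list, contexts, betas = NULL,
                                 n_bins = 100L, mesh_extension = 0.3,
                                 meshes = NULL, designs = NULL) {
  if (is.null(meshes))
    meshes <- lapply(fits_list, function(sf)
      make_mesh(sf$size_range, n_bins = n_bins, extension = mesh_extension))
  if (is.null(designs)) designs <- .context_designs(fits_list, contexts, meshes)
  lam <- numeric(nrow(contexts))
  for (r in seq_len(nrow(contexts))) {
    sp <- contexts$species[r]
    d <- designs[[r]]
    rates <- .context_rates(d, fits_list[[sp]]$fits, betas[[sp]])
    K <- .kernel_matrices(rates$s, rates$mu, d$grow_sd, rates$pfl, rates$fec,
                          d$germ, d$estab, d$rec_mean, d$rec_sd,
                          meshes[[sp]])$K
    lam[r] <- .lambda_fast(K)
  }
  data.frame(species = contexts$species, background = contexts$background,
             site_elevation_m = contexts$site_elevation_m,
             lambda = lam, ln_lambda = log(lam), stringsAsFactors = FALSE)
}

#' Point-estimate growth rates for a set of contexts
#'
#' Builds a kernel from the selected vital-rate fits for every row of
#' `contexts` and returns lambda and ln(lambda).
#'
#' @param fits_list Named list of `species_fits`, one per species.
#' @param contexts Data frame with columns `species`, `background` (`"none"`
#'   for intrinsic contexts) and `site_elevation_m`.
#' @param n_bins Mesh resolution (default 100).
#' @param mesh_extension Fractional extension of each species' observed size
#'   range used for its integration mesh (default 0.3, wide enough that
#'   lambda is insensitive to further widening; see the methods vignette).
#' @return Data frame: contexts with `lambda` and `ln_lambda`.
#' @export
estimate_lambda_table <- function(fits_list, contexts, n_bins = 100L,
                                  mesh_extension = 0.3) {
  .lambda_for_contexts(fits_list, contexts, betas = NULL, n_bins = n_bins,
                       mesh_extension = mesh_extension)
}

#' Parametric bootstrap of growth rates and coexistence quantities
#'
#' For each of `B` replicates, draws one coefficient vector per species and
#' size-dependent vital rate (survival, growth, flowering, fecundity) from
#' its multivariate-normal sampling distribution - size-independent rates
#' (germination, establishment, residual and offspring-size SDs) are held at
#' their point estimates - rebuilds every kernel, and recomputes every growth
#' rate and (when `origins` is supplied) every pairwise coexistence quantity.
#' Each species' draw is shared coherently across all kernels that use its
#' fits within a replicate. Replicates are seeded from a single master seed,
#' so runs are reproducible; replicates that fail numerically are dropped and
#' counted.
#'
#' @inheritParams estimate_lambda_table
#' @param B Number of bootstrap replicates (default 500).
#' @param seed Master seed.
#' @param origins Optional named vector (species -> origin) enabling the
#'   per-replicate pair table.
#' @inheritParams estimate_lambda_table
#' @return Object of class `bootstrap_ensemble`: `lambda` (long data frame
#'   with a `replicate` column), `pairs` (long pair table or NULL), `B`,
#'   `seed`, `replicate_seeds`, `n_failed`.
#' @export
run_bootstrap <- function(fits_list, contexts, B = 500L, seed = 1L,
                          origins = NULL, n_bins = 100L,
                          mesh_extension = 0.3) {
  stopifnot(B >= 1)
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, B)
  meshes <- lapply(fits_list, function(sf)
    make_mesh(sf$size_range, n_bins = n_bins, extension = mesh_extension))
  designs <- .context_designs(fits_list, contexts, meshes)
  lam_list <- vector("list", B)
  failed <- integer(0)
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    res <- tryCatch({
      betas <- lapply(fits_list, function(sf)
        lapply(sf$fits, draw_parameters))
      lt <- .lambda_for_contexts(fits_list, contexts, betas, meshes = meshes,
                                 designs = designs)
      lt$replicate <- b
      lt
    }, error = function(e) NULL)
    if (is.null(res)) failed <- c(failed, b) else lam_list[[b]] <- res
  }
  lam <- do.call(rbind, lam_list)
  pairs <- if (!is.null(origins) && !is.null(lam) &&
               any(lam$background != "none"))
    pair_table(lam, origins) else NULL
  structure(list(lambda = lam, pairs = pairs, B = as.integer(B),
                 seed = as.integer(seed), replicate_seeds = rep_seeds,
                 n_failed = length(failed), failed_replicates = failed),
            class = "bootstrap_ensemble")
}

#' Median and percentile 95% confidence interval across replicates
#'
#' @param x Numeric vector of per-replicate values (NAs dropped); at least
#'   two values required.
#' @return Named numeric: `median`, `lo95`, `hi95` (2.5 and 97.5 percentiles,
#'   linear interpolation).
#' @export
summarize_ensemble <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least two valid replicates")
  q <- stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  c(median = q[1], lo95 = q[2], hi95 = q[3])
}
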