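# Size-structured vital-rate regressions: model specification, AICc-based
# nested-model selection, recruitment estimation, and construction of
# per-context predictor sets for kernel assembly.

.TERM_UNIVERSE <- c("z", "site", "background",
                    "z:site", "z:background", "site:background")
.TERM_DEPS <- list("z:site" = c("z", "site"),
                   "z:background" = c("z", "background"),
                   "site:background" = c("site", "background"))
.DEFAULT_FULL_TERMS <- c("z", "site", "background", "z:site", "z:background")

#' Akaike information criterion corrected for small samples
#'
#' AICc = -2 loglik + 2k + 2k(k+1)/(n-k-1).
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of estimated parameters (including the residual variance
#'   for Gaussian models).
#' @param n Number of observations; must exceed k + 1.
#' @return AICc value.
#' @examples
#' aicc(-10, 2, 10)  # 24 + 12/7
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Specify a vital-rate regression model
#'
#' @param response One of `"survival"`, `"growth"`, `"flowering"`,
#'   `"fecundity"`, `"offspring_size"`. Survival and flowering are fitted as
#'   binomial GLMs with a logit link; growth, fecundity (on log(seeds + 1))
#'   and offspring size as Gaussian linear models.
#' @param terms Character vector of predictor terms, a subset of
#'   `z`, `site`, `background`, `z:site`, `z:background`, `site:background`
#'   (the intercept is always included). Interactions require their main
#'   effects.
#' @return List of class `model_spec`.
#' @export
model_spec <- function(response = c("survival", "growth", "flowering",
                                    "fecundity", "offspring_size"),
                       terms = character(0)) {
  response <- match.arg(response)
  terms <- unique(terms)
  bad <- setdiff(terms, .TERM_UNIVERSE)
  if (length(bad) > 0) stop("unknown terms: ", paste(bad, collapse = ", "))
  for (tm in intersect(terms, names(.TERM_DEPS)))
    if (!all(.TERM_DEPS[[tm]] %in% terms))
      stop("interaction ", tm, " requires its main effects")
  family <- if (response %in% c("survival", "flowering")) "binomial" else "gaussian"
  structure(list(response = response, terms = .canonical_terms(terms),
                 family = family),
            class = "model_spec")
}

.canonical_terms <- function(terms) .TERM_UNIVERSE[.TERM_UNIVERSE %in% terms]

#' Enumerate all hierarchy-valid nested models of a full model
#'
#' Returns every subset of the full model's terms in which each interaction
#' is accompanied by its main effects, from the intercept-only model up to
#' the full model.
#'
#' @param full A `model_spec`, or a character vector of terms.
#' @param response Response used for the returned specs when `full` is a
#'   character vector.
#' @return List of `model_spec` objects (no duplicates).
#' @examples
#' length(enumerate_nested_models(c("z", "site", "z:site"), "growth"))  # 5
#' @export
enumerate_nested_models <- function(full, response = NULL) {
  if (inherits(full, "model_spec")) {
    terms <- full$terms
    response <- full$response
  } else {
    terms <- .canonical_terms(full)
    if (is.null(response)) stop("supply a response for character terms")
  }
  k <- length(terms)
  specs <- list()
  for (mask in 0:(2^k - 1)) {
    sub <- terms[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    ok <- all(vapply(intersect(sub, names(.TERM_DEPS)),
                     function(tm) all(.TERM_DEPS[[tm]] %in% sub), logical(1)))
    if (ok) specs[[length(specs) + 1L]] <- model_spec(response, sub)
  }
  specs
}

# response-specific model frame: columns y, z, site, background
.vital_rate_frame <- function(records, response, seedling_sizes = NULL) {
  if (response == "offspring_size") {
    stopifnot(!is.null(seedling_sizes))
    return(data.frame(y = seedling_sizes$size,
                      z = 0,
                      site = factor(seedling_sizes$site_elevation_m),
                      background = factor("none")))
  }
  d <- records[is.finite(records$size_t), , drop = FALSE]
  if (response == "growth")
    d <- d[d$survived == 1L & is.finite(d$size_t1), , drop = FALSE]
  if (response == "fecundity")
    d <- d[d$flowered == 1L, , drop = FALSE]
  y <- switch(response,
              survival = d$survived,
              growth = d$size_t1,
              flowering = d$flowered,
              fecundity = log(d$seeds + 1))
  bg <- factor(d$background)
  if ("none" %in% levels(bg)) bg <- stats::relevel(bg, ref = "none")
  data.frame(y = y, z = d$size_t, site = factor(d$site_elevation_m),
             background = bg)
}

#' Fit one vital-rate regression
#'
#' Maximum-likelihood fit of a `model_spec` to demographic records. Binomial
#' responses with no variation (all zero or all one) yield an intercept-only
#' fit at a clipped probability with a zero covariance matrix, flagged
#' `degenerate`. Non-converged or separated fits are flagged `unreliable` and
#' are excluded by [select_by_aicc()].
#'
#' @param records Data frame of demographic records (see
#'   [simulate_individuals()] for the column contract), or a prepared model
#'   frame with columns `y`, `z`, `site`, `background`.
#' @param spec A `model_spec`.
#' @param seedling_sizes Seedling-size table, required for
#'   `response = "offspring_size"`.
#' @return Object of class `vital_rate_fit`: coefficients, covariance matrix,
#'   log-likelihood, `n_obs`, `k_params`, `aicc`, residual `sigma` (Gaussian),
#'   factor levels, and flags.
#' @export
fit_vital_rate <- function(records, spec, seedling_sizes = NULL) {
  stopifnot(inherits(spec, "model_spec"))
  d <- if (all(c("y", "z", "site", "background") %in% names(records)))
    records
  else .vital_rate_frame(records, spec$response, seedling_sizes)
  d <- d[is.finite(d$y), , drop = FALSE]
  rhs <- if (length(spec$terms) == 0) "1" else paste(spec$terms, collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))

  flags <- character(0)
  if (spec$family == "binomial" && length(unique(d$y)) < 2L) {
    # all-zero or all-one response: clipped intercept-only fit
    p <- pmin(pmax(mean(d$y), 1e-12), 1 - 1e-12)
    co <- c(`(Intercept)` = stats::qlogis(p))
    ll <- sum(stats::dbinom(d$y, 1, p, log = TRUE))
    return(structure(list(spec = model_spec(spec$response, character(0)),
                          coef = co,
                          vcov = matrix(0, 1, 1,
                                        dimnames = list(names(co), names(co))),
                          loglik = ll, n_obs = nrow(d), k_params = 1L,
                          aicc = aicc(ll, 1L, nrow(d)), sigma = NA_real_,
                          xlevels = list(site = levels(d$site),
                                         background = levels(d$background)),
                          terms_obj = stats::delete.response(stats::terms(form)),
                          flags = "degenerate"),
                     class = "vital_rate_fit"))
  }

  fit <- if (spec$family == "binomial") {
    suppressWarnings(stats::glm(form, data = d, family = stats::binomial()))
  } else {
    stats::lm(form, data = d)
  }
  if (spec$family == "binomial" && !fit$converged) flags <- c(flags, "unreliable")
  co <- stats::coef(fit)
  if (anyNA(co)) flags <- c(flags, "unreliable")
  # separation heuristic: absurd coefficient magnitudes or exploded SEs
  vc <- suppressWarnings(stats::vcov(fit))
  if (spec$family == "binomial" &&
      (any(abs(co[!is.na(co)]) > 15) ||
       any(!is.finite(vc)) || any(diag(vc) > 1e4)))
    flags <- c(flags, "unreliable")
  ll_obj <- stats::logLik(fit)
  k <- as.integer(attr(ll_obj, "df"))
  n <- stats::nobs(fit)
  a <- if (n > k + 1) aicc(as.numeric(ll_obj), k, n) else NA_real_
  if (!is.finite(a)) flags <- c(flags, "ineligible")
  structure(list(spec = spec, coef = co, vcov = vc,
                 loglik = as.numeric(ll_obj), n_obs = n, k_params = k,
                 aicc = a,
                 sigma = if (spec$family == "gaussian")
                   stats::sigma(fit) else NA_real_,
                 xlevels = list(site = levels(d$site),
                                background = levels(d$background)),
                 terms_obj = stats::delete.response(stats::terms(fit)),
                 flags = flags),
            class = "vital_rate_fit")
}

#' Select the minimum-AICc fit
#'
#' Ties are broken in favour of fewer parameters, then by the lexicographic
#' order of the term list. Flagged (`unreliable`, `ineligible`) fits are
#' excluded.
#'
#' @param fits List of `vital_rate_fit` objects.
#' @return The selected `vital_rate_fit`.
#' @export
select_by_aicc <- function(fits) {
  if (length(fits) == 0) stop("no fits supplied")
  ok <- vapply(fits, function(f)
    !any(c("unreliable", "ineligible") %in% f$flags) && is.finite(f$aicc),
    logical(1))
  # degenerate intercept-only fallbacks are only used if nothing else is valid
  if (!any(ok)) {
    deg <- vapply(fits, function(f) "degenerate" %in% f$flags, logical(1))
    if (any(deg)) return(fits[[which(deg)[1]]])
    stop("no valid fits to select from")
  }
  fits <- fits[ok]
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  k <- vapply(fits, `[[`, numeric(1), "k_params")
  tl <- vapply(fits, function(f) paste(f$spec$terms, collapse = "+"),
               character(1))
  fits[[order(a, k, tl)[1]]]
}

#' Estimate germination and establishment probabilities from trial counts
#'
#' Raw proportions: g = germinated/sown, e = established/germinated. A zero
#' denominator yields a zero estimate flagged `undefined`.
#'
#' @param trials Data frame with columns `species`, `site_elevation_m`,
#'   `n_sown`, `n_germinated`, `n_established`.
#' @return The input with added columns `g`, `e`, `flag_e_undefined`.
#' @export
fit_recruitment <- function(trials) {
  stopifnot(all(c("n_sown", "n_germinated", "n_established") %in% names(trials)))
  if (any(trials$n_sown < 1)) stop("n_sown must be >= 1")
  if (any(trials$n_germinated > trials$n_sown |
          trials$n_established > trials$n_germinated |
          trials$n_germinated < 0 | trials$n_established < 0))
    stop("recruitment counts must satisfy established <= germinated <= sown")
  trials$g <- trials$n_germinated / trials$n_sown
  trials$flag_e_undefined <- trials$n_germinated == 0
  trials$e <- ifelse(trials$flag_e_undefined, 0,
                     trials$n_established / pmax(trials$n_germinated, 1))
  trials
}

#' Fit and select all vital-rate models for one species
#'
#' Fits every hierarchy-valid nested model of the full model for each of the
#' four size-dependent vital rates (survival, growth, flowering, fecundity),
#' selects by AICc, and estimates the size-independent rates: germination and
#' establishment per site (raw proportions) and the offspring size
#' distribution (intercept-only Gaussian on observed seedling sizes).
#' Terms involving factors with fewer than two levels in the data are dropped
#' from the full model automatically.
#'
#' @param records Demographic records (all species or one; filtered to
#'   `species`).
#' @param recruitment Recruitment-trial table.
#' @param seedling_sizes Seedling-size table.
#' @param species Species id.
#' @param full_terms Terms of the full model (default
#'   `z + site + background + z:site + z:background`).
#' @param include_replacements Include records of replacement transplants
#'   (default TRUE).
#' @return Object of class `species_fits`: selected `fits` per response,
#'   `selection` table (one row per candidate model), recruitment estimates,
#'   offspring and growth SDs, and the observed size range.
#' @export
fit_species_vital_rates <- function(records, recruitment, seedling_sizes,
                                    species,
                                    full_terms = .DEFAULT_FULL_TERMS,
                                    include_replacements = TRUE) {
  d <- records[records$species == species, , drop = FALSE]
  if (nrow(d) == 0) stop("no records for species ", species)
  if (!include_replacements) d <- d[d$is_replacement == 0L, , drop = FALSE]
  sdl <- seedling_sizes[seedling_sizes$species == species, , drop = FALSE]

  # prune terms whose factor has < 2 levels in this species' data
  terms <- .canonical_terms(full_terms)
  if (length(unique(d$site_elevation_m)) < 2L)
    terms <- terms[!grepl("site", terms)]
  if (length(unique(d$background)) < 2L)
    terms <- terms[!grepl("background", terms)]

  fits <- list()
  sel_rows <- list()
  for (resp in c("survival", "growth", "flowering", "fecundity")) {
    frame <- .vital_rate_frame(d, resp)
    cand <- enumerate_nested_models(terms, resp)
    cfits <- lapply(cand, function(sp) fit_vital_rate(frame, sp))
    fits[[resp]] <- select_by_aicc(cfits)
    sel_rows[[resp]] <- data.frame(
      species = species, response = resp,
      terms = vapply(cfits, function(f)
        paste(f$spec$terms, collapse = "+"), character(1)),
      k = vapply(cfits, `[[`, numeric(1), "k_params"),
      n = vapply(cfits, `[[`, numeric(1), "n_obs"),
      loglik = vapply(cfits, `[[`, numeric(1), "loglik"),
      aicc = vapply(cfits, `[[`, numeric(1), "aicc"),
      flags = vapply(cfits, function(f)
        paste(f$flags, collapse = ";"), character(1)),
      stringsAsFactors = FALSE)
    sel_rows[[resp]]$selected <- sel_rows[[resp]]$terms ==
      paste(fits[[resp]]$spec$terms, collapse = "+")
  }

  os <- fit_vital_rate(d, model_spec("offspring_size"), seedling_sizes = sdl)
  rec <- fit_recruitment(
    recruitment[recruitment$species == species, , drop = FALSE])

  sizes <- c(d$size_t, d$size_t1, sdl$size)
  structure(list(species = species,
                 fits = fits,
                 selection = do.call(rbind, sel_rows),
                 grow_sd = fits$growth$sigma,
                 rec_mean = unname(os$coef[1]),
                 rec_sd = os$sigma,
                 recruitment = rec,
                 size_range = range(sizes[is.finite(sizes)])),
            class = "species_fits")
}

# design row for a context, honouring the factor levels seen at fit time
.context_frame <- function(fit, z, site, background) {
  data.frame(z = z,
             site = factor(as.character(site), levels = fit$xlevels$site),
             background = factor(as.character(background),
                                 levels = fit$xlevels$background))
}

# linear predictor of a fit at sizes z for a fixed site/background context;
# beta overrides the fitted coefficients (parametric bootstrap)
.predict_lp <- function(fit, z, site, background, beta = NULL) {
  if (is.null(beta)) beta <- fit$coef
  nd <- .context_frame(fit, z, site, background)
  X <- stats::model.matrix(fit$terms_obj, nd,
                           xlev = fit$xlevels[names(fit$xlevels) %in%
                                                all.vars(fit$terms_obj)])
  b <- beta
  b[is.na(b)] <- 0
  drop(X %*% b[colnames(X)])
}

# Precomputed design for one species x site x background context: the mesh-
# midpoint model matrices of the four size-dependent fits plus the fixed
# size-independent rates. Evaluating a coefficient draw then reduces to four
# matrix-vector products (see .context_rates), which is what the bootstrap
# loop uses.
.context_design <- function(sf, site, background, z) {
  X <- lapply(sf$fits, function(fit) {
    nd <- .context_frame(fit, z, site, background)
    M <- stats::model.matrix(fit$terms_obj, nd,
                             xlev = fit$xlevels[names(fit$xlevels) %in%
                                                  all.vars(fit$terms_obj)])
    idx <- match(colnames(M), names(fit$coef))
    list(M = M, idx = idx)
  })
  rr <- sf$recruitment
  i <- which(rr$site_elevation_m == site)
  if (length(i) == 0) stop("no recruitment estimate for site ", site)
  list(X = X, grow_sd = sf$grow_sd, germ = rr$g[i[1]], estab = rr$e[i[1]],
       rec_mean = sf$rec_mean, rec_sd = sf$rec_sd)
}

# vital rates on the mesh for one coefficient set (NULL beta = point estimate)
.context_rates <- function(design, fits, betas = NULL) {
  eta <- function(resp) {
    b <- if (!is.null(betas) && !is.null(betas[[resp]])) betas[[resp]]
    else fits[[resp]]$coef
    b <- b[design$X[[resp]]$idx]
    b[is.na(b)] <- 0
    drop(design$X[[resp]]$M %*% b)
  }
  clip <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  list(s = clip(stats::plogis(eta("survival"))),
       mu = eta("growth"),
       pfl = clip(stats::plogis(eta("flowering"))),
       fec = pmax(exp(eta("fecundity")) - 1, 0))
}

#' Estimated vital-rate set for one species in one context
#'
#' Assembles the [vital_rate_set()] predictor container for a species at a
#' given site and background, from selected fits. Probability predictions are
#' clipped to (1e-12, 1 - 1e-12); fecundity is back-transformed from the
#' log(seeds + 1) scale as exp(mu) - 1, clipped at zero.
#'
#' @param sf A `species_fits` object.
#' @param site Site elevation (must be a level seen at fit time).
#' @param background Background species id or `"none"`.
#' @param beta Optional named list of coefficient vectors
#'   (`survival`, `growth`, `flowering`, `fecundity`) overriding the fitted
#'   means (used by the parametric bootstrap).
#' @param fec_bias_correction Add sigma^2/2 to the fecundity linear predictor
#'   before back-transforming (default FALSE).
#' @return A `vital_rate_set`.
#' @export
estimated_vital_rates <- function(sf, site, background = "none", beta = NULL,
                                  fec_bias_correction = FALSE) {
  stopifnot(inherits(sf, "species_fits"))
  b <- function(r) if (!is.null(beta)) beta[[r]] else NULL
  clip <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  fcorr <- if (fec_bias_correction) sf$fits$fecundity$sigma^2 / 2 else 0
  rr <- sf$recruitment
  i <- which(rr$site_elevation_m == site)
  if (length(i) == 0) stop("no recruitment estimate for site ", site)
  vital_rate_set(
    surv = function(z) clip(stats::plogis(
      .predict_lp(sf$fits$survival, z, site, background, b("survival")))),
    grow_mean = function(z)
      .predict_lp(sf$fits$growth, z, site, background, b("growth")),
    grow_sd = sf$grow_sd,
    flower = function(z) clip(stats::plogis(
      .predict_lp(sf$fits$flowering, z, site, background, b("flowering")))),
    fec = function(z) pmax(exp(
      .predict_lp(sf$fits$fecundity, z, site, background, b("fecundity")) +
        fcorr) - 1, 0),
    germ = rr$g[i[1]], estab = rr$e[i[1]],
    rec_mean = sf$rec_mean, rec_sd = sf$rec_sd
  )
}
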