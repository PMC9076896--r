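# Elevation-trend inference: mixed-effects models with likelihood-ratio
# tests, per-replicate coefficient intervals, and outcome tallies.

# fit y ~ elevation (* group) with a random intercept; falls back to a
# fixed-effects-only model when the random effect is singular or inestimable.
# Elevation is rescaled to km internally for numerical stability; reported
# slopes are per metre.
.fit_trend_model <- function(d, response, group, random, reduced = FALSE) {
  d$.y <- d[[response]]
  d$.ekm <- d$site_elevation_m / 1000
  d <- d[is.finite(d$.y), , drop = FALSE]
  has_group <- !is.null(group)
  if (has_group) d$.g <- factor(d[[group]])
  fixed <- if (!has_group) ".y ~ .ekm"
  else if (reduced) ".y ~ .ekm + .g"
  else ".y ~ .ekm * .g"
  if (reduced && !has_group) fixed <- ".y ~ 1"
  use_lmer <- !is.null(random) && length(unique(d[[random]])) >= 2
  if (use_lmer) {
    d$.r <- factor(d[[random]])
    m <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(stats::as.formula(paste(fixed, "+ (1 | .r)")),
                   data = d, REML = FALSE))),
      error = function(e) NULL)
    if (!is.null(m) && !lme4::isSingular(m, tol = 1e-5))
      return(list(model = m, type = "lmer", data = d))
  }
  list(model = stats::lm(stats::as.formula(fixed), data = d), type = "lm",
       data = d)
}

.fixef_of <- function(fm) {
  if (fm$type == "lmer") lme4::fixef(fm$model) else stats::coef(fm$model)
}

# slopes reported per metre: divide coefficients on .ekm terms by 1000
.per_metre <- function(co) {
  i <- grepl("\\.ekm", names(co))
  co[i] <- co[i] / 1000
  names(co) <- gsub("\\.ekm", "elevation", names(co))
  names(co) <- gsub("\\.g", "group", names(co))
  co
}

#' Test an elevation trend with a mixed-effects model
#'
#' Fits `response ~ elevation * group` (or `response ~ elevation` when
#' `group` is NULL) with a random intercept for `random`, by maximum
#' likelihood, and performs a likelihood-ratio test of the focal term: the
#' elevation x group interaction (tested against the both-main-effects
#' model), or the elevation effect when there is no group. Singular
#' random-effect fits fall back to a fixed-effects-only model, flagged in the
#' result.
#'
#' @param data Data frame with columns `site_elevation_m`, the response, the
#'   grouping variable and the random-effect variable.
#' @param response Name of the response column.
#' @param group Name of the grouping factor (e.g. species origin or pair
#'   type), or NULL.
#' @param random Name of the random-intercept variable (e.g. species or pair
#'   id), or NULL.
#' @return Object of class `trend_result`: `term`, `chisq`, `df`, `p`,
#'   `coefficients` (elevation slopes per metre), `model_type`,
#'   `singular_fallback`.
#' @export
fit_trend <- function(data, response, group = NULL, random = NULL) {
  full <- .fit_trend_model(data, response, group, random)
  red <- .fit_trend_model(full$data, response, group, random, reduced = TRUE)
  # compare on a common model class
  if (full$type != red$type) {
    full <- list(model = stats::lm(stats::formula(full$model,
                                                  fixed.only = TRUE),
                                   data = full$data),
                 type = "lm", data = full$data)
  }
  ll_full <- as.numeric(stats::logLik(full$model))
  ll_red <- as.numeric(stats::logLik(red$model))
  df <- attr(stats::logLik(full$model), "df") -
    attr(stats::logLik(red$model), "df")
  chisq <- max(0, 2 * (ll_full - ll_red))
  p <- stats::pchisq(chisq, df = max(df, 1), lower.tail = FALSE)
  structure(list(term = if (is.null(group)) "elevation"
                 else "elevation:group",
                 chisq = chisq, df = df, p = p,
                 coefficients = .per_metre(.fixef_of(full)),
                 model_type = full$type,
                 singular_fallback = full$type == "lm" && !is.null(random) &&
                   length(unique(full$data[[random]])) >= 2),
            class = "trend_result")
}

#' Per-replicate trend test with percentile confidence interval
#'
#' Fits the trend model separately to each bootstrap replicate and summarizes
#' a focal coefficient (or a linear contrast of the fixed effects) across
#' replicates by its median and 2.5/97.5 percentiles. The term is judged
#' significant after uncertainty propagation when the interval excludes zero.
#'
#' @inheritParams fit_trend
#' @param data Long data frame with a `replicate` column.
#' @param coef_name Name of the fixed-effect coefficient to track (after
#'   per-metre rescaling; e.g. `"elevation"` or an `elevation:group...`
#'   interaction name). Defaults to the last elevation term of the model.
#' @param contrast Optional named numeric vector of weights applied to the
#'   per-metre fixed effects instead of a single coefficient.
#' @return List of class `trend_replicate_result`: `median`, `lo95`, `hi95`,
#'   `significant`, `n_fitted`, `n_failed`, `values`.
#' @export
per_replicate_test <- function(data, response, group = NULL, random = NULL,
                               coef_name = NULL, contrast = NULL) {
  reps <- unique(data$replicate)
  vals <- rep(NA_real_, length(reps))
  for (k in seq_along(reps)) {
    d <- data[data$replicate == reps[k], , drop = FALSE]
    fm <- tryCatch(.fit_trend_model(d, response, group, random),
                   error = function(e) NULL)
    if (is.null(fm)) next
    co <- .per_metre(.fixef_of(fm))
    vals[k] <- if (!is.null(contrast)) {
      if (!all(names(contrast) %in% names(co))) NA_real_
      else sum(contrast * co[names(contrast)])
    } else {
      cn <- coef_name
      if (is.null(cn)) {
        en <- grep("elevation", names(co), value = TRUE)
        cn <- en[length(en)]
      }
      if (cn %in% names(co)) co[[cn]] else NA_real_
    }
  }
  ok <- is.finite(vals)
  if (sum(ok) < 2) stop("fewer than two replicates could be fitted")
  s <- summarize_ensemble(vals[ok])
  structure(list(median = s[["median"]], lo95 = s[["lo95"]],
                 hi95 = s[["hi95"]],
                 significant = s[["lo95"]] > 0 || s[["hi95"]] < 0,
                 n_fitted = sum(ok), n_failed = sum(!ok), values = vals),
            class = "trend_replicate_result")
}

#' Tally competitive outcomes across bootstrap replicates
#'
#' Counts, per replicate and stratum (site x pair type by default), the pairs
#' predicted to coexist stably versus not (competitive exclusion or priority
#' effect), and reports the mean count and percentile 95% CI across
#' replicates, plus the mean proportion coexisting among classified pairs.
#'
#' @param pairs A pair table (see [pair_table()]) with a `replicate` column
#'   (a single replicate is treated as a deterministic ensemble).
#' @param by Character vector of stratifying columns (default
#'   `c("site_elevation_m", "pair_type")`).
#' @return Data frame: one row per stratum with `n_pairs`, `mean_coexist`,
#'   `lo95_coexist`, `hi95_coexist`, `mean_not_coexist`, `lo95_not`,
#'   `hi95_not`, `prop_coexist`.
#' @export
tally_outcomes <- function(pairs, by = c("site_elevation_m", "pair_type")) {
  if (!"replicate" %in% names(pairs)) pairs$replicate <- 0L
  p <- pairs[!is.na(pairs$outcome), , drop = FALSE]
  if (nrow(p) == 0)
    return(data.frame())
  strata <- unique(p[, by, drop = FALSE])
  rows <- lapply(seq_len(nrow(strata)), function(s) {
    sel <- rep(TRUE, nrow(p))
    for (cn in by) sel <- sel & p[[cn]] == strata[[cn]][s]
    d <- p[sel, , drop = FALSE]
    cx <- tapply(d$outcome == "stable_coexistence", d$replicate, sum)
    nn <- tapply(d$outcome != "stable_coexistence", d$replicate, sum)
    tot <- tapply(rep(1L, nrow(d)), d$replicate, sum)
    ci <- function(x) if (length(x) >= 2) summarize_ensemble(x)[2:3]
    else c(lo95 = unname(x[1]), hi95 = unname(x[1]))
    cbind(strata[s, , drop = FALSE],
          data.frame(n_pairs = max(tot), mean_coexist = mean(cx),
                     lo95_coexist = ci(cx)[[1]], hi95_coexist = ci(cx)[[2]],
                     mean_not_coexist = mean(nn),
                     lo95_not = ci(nn)[[1]], hi95_not = ci(nn)[[2]],
                     prop_coexist = mean(cx / tot)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
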