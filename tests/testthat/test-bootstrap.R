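make_fake_fit <- function(coef, vcov) {
  structure(list(spec = model_spec("growth", "z"), coef = coef, vcov = vcov,
                 flags = character(0)),
            class = "vital_rate_fit")
}

test_that("a zero covariance matrix returns the coefficients exactly", {
  f <- make_fake_fit(c(`(Intercept)` = 1.5, z = -0.3),
                     matrix(0, 2, 2, dimnames = list(c("(Intercept)", "z"),
                                                     c("(Intercept)", "z"))))
  expect_identical(draw_parameters(f), f$coef)
})

test_that("parameter draws reproduce the multivariate-normal moments", {
  V <- matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  f <- make_fake_fit(c(a = 1, b = 2), V)
  set.seed(123)
  draws <- t(replicate(10000, draw_parameters(f)))
  se_mean <- sqrt(diag(V) / 10000)
  expect_lt(abs(mean(draws[, 1]) - 1), 4 * se_mean[1])
  expect_lt(abs(mean(draws[, 2]) - 2), 4 * se_mean[2])
  expect_lt(norm(stats::cov(draws) - V, "F") / norm(V, "F"), 0.1)
  # seeded reproducibility
  set.seed(5); d1 <- draw_parameters(f)
  set.seed(5); d2 <- draw_parameters(f)
  expect_identical(d1, d2)
})

test_that("non-PSD covariance matrices are repaired by eigenvalue clipping", {
  V <- matrix(c(1, 2, 2, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  f <- make_fake_fit(c(a = 0, b = 0), V)
  set.seed(1)
  expect_warning(draw_parameters(f), "not PSD")
})

test_that("pipeline growth rates equal the reference kernel-and-eigen route", {
  fx <- shared_pipeline()
  ctx <- fx$contexts[sample.int(nrow(fx$contexts), 12), ]
  lt <- estimate_lambda_table(fx$fits, ctx)
  for (r in seq_len(nrow(ctx))) {
    sf <- fx$fits[[ctx$species[r]]]
    mesh <- make_mesh(sf$size_range, n_bins = 100, extension = 0.3)
    vr <- estimated_vital_rates(sf, ctx$site_elevation_m[r],
                                ctx$background[r])
    ref <- lambda_of(build_kernel(vr, mesh))$lambda
    expect_equal(lt$lambda[r], ref, tolerance = 1e-8)
  }
})

test_that("a deterministic ensemble equals the point estimates", {
  fx <- shared_pipeline()
  fits0 <- lapply(fx$fits, function(sf) {
    sf$fits <- lapply(sf$fits, function(f) { f$vcov[] <- 0; f })
    sf
  })
  ctx <- fx$contexts[fx$contexts$species == names(fits0)[1] &
                       fx$contexts$background == "none", ]
  ens <- run_bootstrap(fits0, ctx, B = 1, seed = 4)
  pt <- estimate_lambda_table(fits0, ctx)
  expect_equal(ens$lambda$lambda, pt$lambda, tolerance = 1e-12)
})

test_that("bootstrap runs are reproducible and summaries match a brute-force oracle", {
  fx <- shared_pipeline()
  sp <- names(fx$fits)[1]
  ctx <- fx$contexts[fx$contexts$species == sp &
                       fx$contexts$background %in% c("none", sp), ]
  e1 <- run_bootstrap(fx$fits[sp], ctx, B = 30, seed = 77)
  e2 <- run_bootstrap(fx$fits[sp], ctx, B = 30, seed = 77)
  expect_identical(e1$lambda, e2$lambda)
  expect_equal(e1$n_failed, 0)
  x <- e1$lambda$ln_lambda[e1$lambda$background == "none" &
                             e1$lambda$site_elevation_m == 890]
  s <- summarize_ensemble(x)
  # brute-force percentile with linear interpolation on the sorted array
  brute <- function(x, p) {
    xs <- sort(x); h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(unname(s["median"]), brute(x, 0.5), tolerance = 1e-12)
  expect_equal(unname(s["lo95"]), brute(x, 0.025), tolerance = 1e-12)
  expect_equal(unname(s["hi95"]), brute(x, 0.975), tolerance = 1e-12)
})

test_that("summaries of trivial replicate sets are exact", {
  expect_equal(unname(summarize_ensemble(c(1, 2, 3))["median"]), 2)
  s <- summarize_ensemble(rep(1.7, 10))
  expect_equal(unname(s["hi95"] - s["lo95"]), 0)
  expect_error(summarize_ensemble(2), "at least two")
})

test_that("inflating coefficient covariances never narrows lambda intervals", {
  fx <- shared_pipeline()
  sp <- names(fx$fits)[1]
  ctx <- fx$contexts[fx$contexts$species == sp &
                       fx$contexts$background == "none", ]
  fits4 <- fx$fits[sp]
  fits4[[sp]]$fits <- lapply(fits4[[sp]]$fits, function(f) {
    f$vcov <- f$vcov * 4; f
  })
  e1 <- run_bootstrap(fx$fits[sp], ctx, B = 60, seed = 12)
  e4 <- run_bootstrap(fits4, ctx, B = 60, seed = 12)
  w <- function(e, s) {
    x <- e$lambda$ln_lambda[e$lambda$site_elevation_m == s]
    unname(diff(summarize_ensemble(x)[c("lo95", "hi95")]))
  }
  for (s in unique(ctx$site_elevation_m)) expect_gte(w(e4, s), w(e1, s))
})

test_that("seeded half-ensembles agree with the full run within Monte-Carlo error", {
  fx <- shared_pipeline()
  sp <- names(fx$fits)[1]
  ctx <- fx$contexts[fx$contexts$species == sp &
                       fx$contexts$background == "none" &
                       fx$contexts$site_elevation_m == 1400, ]
  e <- run_bootstrap(fx$fits[sp], ctx, B = 100, seed = 31)
  x <- e$lambda$ln_lambda[order(e$lambda$replicate)]
  m1 <- stats::median(x[1:50]); m2 <- stats::median(x[51:100])
  mc_err <- 4 * stats::sd(x) / sqrt(50)
  expect_lt(abs(m1 - m2), mc_err)
})
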