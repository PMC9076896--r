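test_that("AICc follows its definition and collapses to AIC at large n", {
  expect_equal(aicc(-10, 2, 10), 24 + 12 / 7, tolerance = 1e-12)
  expect_error(aicc(-10, 9, 10), "n must exceed")
  expect_equal(aicc(-50, 3, 1e9), -2 * (-50) + 2 * 3, tolerance = 1e-6)
  set.seed(1)
  for (i in 1:20) {
    ll <- stats::rnorm(1, -100, 30)
    k <- sample(1:8, 1)
    n <- k + 1 + sample(1:200, 1)
    expect_equal(aicc(ll, k, n), -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1))
  }
})

test_that("nested-model enumeration respects the term hierarchy", {
  expect_length(enumerate_nested_models("z", "growth"), 2)
  m <- enumerate_nested_models(c("z", "site", "z:site"), "growth")
  expect_length(m, 5)
  term_sets <- lapply(m, function(s) s$terms)
  expect_true(any(vapply(term_sets, function(x) length(x) == 0, TRUE)))
  expect_true(any(vapply(term_sets, identical, TRUE,
                         c("z", "site", "z:site"))))
  # the package default full model: 13 hierarchy-valid submodels
  full <- enumerate_nested_models(c("z", "site", "background",
                                    "z:site", "z:background"), "survival")
  expect_length(full, 13)
  for (s in full) {
    if ("z:site" %in% s$terms) expect_true(all(c("z", "site") %in% s$terms))
    if ("z:background" %in% s$terms)
      expect_true(all(c("z", "background") %in% s$terms))
  }
  expect_error(model_spec("survival", c("z:site")), "requires its main")
})

test_that("logistic survival coefficients are recovered within sampling error", {
  set.seed(42)
  n <- 2000
  z <- stats::rnorm(n)
  p <- stats::plogis(0.5 + 1.0 * z)
  d <- data.frame(y = stats::rbinom(n, 1, p), z = z,
                  site = factor(1400), background = factor("none"))
  fit <- fit_vital_rate(d, model_spec("survival", "z"))
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$coef[1] - 0.5), 3 * se[1])
  expect_lt(abs(fit$coef[2] - 1.0), 3 * se[2])
  # deterministic refit
  fit2 <- fit_vital_rate(d, model_spec("survival", "z"))
  expect_identical(fit$coef, fit2$coef)
})

test_that("noiseless Gaussian growth gives an exact fit with vanishing vcov", {
  z <- seq(-1, 1, length.out = 50)
  d <- data.frame(y = 1 + 2 * z, z = z, site = factor(890),
                  background = factor("none"))
  fit <- fit_vital_rate(d, model_spec("growth", "z"))
  expect_equal(unname(fit$coef), c(1, 2), tolerance = 1e-10)
  expect_lt(max(abs(fit$vcov)), 1e-15)
  expect_lt(fit$sigma, 1e-10)
})

test_that("degenerate binomial responses fall back to a clipped intercept fit", {
  d <- data.frame(y = rep(1L, 30), z = stats::rnorm(30),
                  site = factor(890), background = factor("none"))
  fit <- fit_vital_rate(d, model_spec("survival", "z"))
  expect_true("degenerate" %in% fit$flags)
  expect_length(fit$coef, 1)
  expect_true(all(fit$vcov == 0))
  expect_lt(stats::plogis(fit$coef[1]), 1)
})

test_that("AICc selection prefers fewer parameters on ties and skips flagged fits", {
  mk <- function(a, k, terms, flags = character(0)) {
    structure(list(spec = model_spec("growth", terms), aicc = a,
                   k_params = k, flags = flags),
              class = "vital_rate_fit")
  }
  single <- mk(10, 2, "z")
  expect_identical(select_by_aicc(list(single)), single)
  tie <- list(mk(10, 3, c("z", "site")), mk(10, 2, "z"))
  expect_equal(select_by_aicc(tie)$k_params, 2)
  flagged <- list(mk(5, 2, "z", "unreliable"), mk(10, 2, "site"))
  expect_equal(unname(select_by_aicc(flagged)$aicc), 10)
  expect_error(select_by_aicc(list()), "no fits")
})

test_that("recruitment proportions and degenerate trials are handled", {
  t1 <- data.frame(species = "a", site_elevation_m = 890,
                   n_sown = 100, n_germinated = 50, n_established = 25)
  r1 <- fit_recruitment(t1)
  expect_equal(r1$g, 0.5)
  expect_equal(r1$e, 0.5)
  t2 <- data.frame(species = "a", site_elevation_m = 890,
                   n_sown = 100, n_germinated = 0, n_established = 0)
  r2 <- fit_recruitment(t2)
  expect_equal(r2$g, 0)
  expect_equal(r2$e, 0)
  expect_true(r2$flag_e_undefined)
  t3 <- t1; t3$n_established <- 80
  expect_error(fit_recruitment(t3), "must satisfy")
  # large trials recover the truth within binomial error
  set.seed(11)
  g_true <- 0.2; e_true <- 0.4; n <- 1000
  germ <- stats::rbinom(1, n, g_true)
  est <- stats::rbinom(1, germ, e_true)
  r4 <- fit_recruitment(data.frame(species = "a", site_elevation_m = 890,
                                   n_sown = n, n_germinated = germ,
                                   n_established = est))
  expect_lt(abs(r4$g - g_true), 3 * sqrt(g_true * (1 - g_true) / n))
  expect_lt(abs(r4$e - e_true), 3 * sqrt(e_true * (1 - e_true) / germ))
})

test_that("coefficient variances shrink roughly as 1/n", {
  set.seed(33)
  sim <- function(n) {
    z <- stats::rnorm(n)
    data.frame(y = stats::rbinom(n, 1, stats::plogis(0.3 + 0.8 * z)), z = z,
               site = factor(890), background = factor("none"))
  }
  v1 <- mean(diag(fit_vital_rate(sim(1500), model_spec("survival", "z"))$vcov))
  v2 <- mean(diag(fit_vital_rate(sim(3000), model_spec("survival", "z"))$vcov))
  expect_gt(v2 / v1, 0.3)
  expect_lt(v2 / v1, 0.8)
})

test_that("fitted probability predictions are strictly inside (0, 1)", {
  fx <- shared_pipeline()
  vr <- estimated_vital_rates(fx$fits[[1]], 890, "none")
  z <- seq(-50, 50, length.out = 101)
  expect_true(all(vr$surv(z) > 0 & vr$surv(z) < 1))
  expect_true(all(vr$flower(z) > 0 & vr$flower(z) < 1))
  expect_true(all(vr$fec(z) >= 0))
})

test_that("selected models track the generating structure on pipeline data", {
  fx <- shared_pipeline()
  # the generator has real size effects on survival/growth/fecundity,
  # and real background effects; with n=40 the selected models must at
  # least include the size term for growth
  expect_true("z" %in% fx$fits[[1]]$fits$growth$spec$terms)
  expect_true(is.finite(fx$fits[[1]]$grow_sd) && fx$fits[[1]]$grow_sd > 0)
  expect_true(all(c("survival", "growth", "flowering", "fecundity") %in%
                    names(fx$fits[[1]]$fits)))
  # selection table bookkeeping: exactly one selected model per response
  sel <- fx$fits[[1]]$selection
  expect_equal(unname(tapply(sel$selected, sel$response, sum)),
               rep(1L, 4), ignore_attr = TRUE)
})
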