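test_that("the Poisson log-likelihood matches hand computations", {
  one <- site_spectrum(1, 2)
  expect_equal(as.numeric(poisson_ll(one, one)), -1)

  # empty data: LL is minus the total expectation
  zeros <- site_spectrum(c(0, 0, 0), 4)
  e <- site_spectrum(c(2, 1, 0.5), 4)
  expect_equal(as.numeric(poisson_ll(zeros, e)), -3.5)

  # scanning scaled expectations: the maximum sits at the observation
  obs <- site_spectrum(c(12, 5, 2), 4)
  lls <- vapply(seq(0.2, 3, by = 0.05), function(cc) {
    as.numeric(poisson_ll(obs, site_spectrum(cc * obs$counts, 4)))
  }, numeric(1))
  expect_equal(seq(0.2, 3, by = 0.05)[which.max(lls)], 1)

  # impossible expectation flags the degenerate sentinel
  deg <- poisson_ll(obs, site_spectrum(c(0, 5, 2), 4))
  expect_equal(as.numeric(deg), -1e18)
  expect_true(attr(deg, "degenerate"))

  expect_error(poisson_ll(obs, site_spectrum(c(1, 2), 5, folded = TRUE)),
               "same length and folding")
})

test_that("free-parameter counting follows the model menu", {
  ds <- small_datasets(seed = 2)[[1]]
  n_free <- function(...) length(model_spec(ds, ...)$free_params)
  expect_equal(n_free(dominance_form = "additive"), 2)
  expect_equal(n_free(dominance_form = "constant"), 3)
  expect_equal(n_free(dominance_form = "inverse"), 4)
  expect_equal(n_free(dominance_form = "logistic"), 5)
  expect_equal(n_free(dominance_form = "inverse",
                      constrain_intercept = 0.5), 3)
  expect_equal(n_free(dominance_form = "inverse", shared_dfe = FALSE), 6)
  expect_equal(n_free(dominance_form = "additive", p_neutral_free = TRUE),
               3)
})

test_that("the composite likelihood is the sum over datasets and order-invariant", {
  ds <- small_datasets(seed = 3)[[1]]
  params <- c(shape = 0.3, mean_s = 0.01, theta_intercept = 0.6,
              theta_rate = 100)
  both <- model_spec(ds, dominance_form = "inverse")
  out_only <- model_spec(ds["outcrossing"], dominance_form = "inverse")
  self_only <- model_spec(ds["selfing"], dominance_form = "inverse")
  ll_both <- composite_ll(both, params)
  ll_o <- composite_ll(out_only, params)
  ll_s <- composite_ll(self_only, params)
  expect_equal(as.numeric(ll_both), as.numeric(ll_o) + as.numeric(ll_s),
               tolerance = 1e-12)
  rev_spec <- model_spec(rev(ds), dominance_form = "inverse")
  expect_equal(as.numeric(composite_ll(rev_spec, params)),
               as.numeric(ll_both), tolerance = 1e-12)
  # the selfing term ignores the dominance parameters entirely
  p2 <- params; p2["theta_intercept"] <- 0.1; p2["theta_rate"] <- 1e6
  expect_identical(as.numeric(composite_ll(self_only, p2)),
                   as.numeric(ll_s))
  expect_error(composite_ll(both, c(shape = 0.3)), "missing parameter")
})

test_that("model fitting is reproducible and recovers simulated DFE parameters", {
  ds <- small_datasets(seed = 4)[[1]]
  spec <- model_spec(ds, dominance_form = "additive")
  f1 <- fit_dominance_model(spec, n_starts = 3, seed = 11)
  f2 <- fit_dominance_model(spec, n_starts = 3, seed = 11)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loglik, f2$loglik)

  # truth: shape 0.3, mean |s| 0.01 (additive simulations)
  expect_equal(unname(f1$params["shape"]), 0.3, tolerance = 0.5)
  expect_equal(unname(f1$params["mean_s"]), 0.01, tolerance = 0.5)

  gl <- glance(f1)
  expect_identical(gl$n_params, 2L)
  td <- tidy(f1)
  expect_setequal(td$term, c("shape", "mean_s"))
})

test_that("the model menu orders log-likelihoods by nesting", {
  ds <- small_datasets(seed = 5)[[1]]
  menu <- fit_dominance_models(ds, n_starts = 3, seed = 6)
  expect_gte(menu$fits$constant$loglik, menu$fits$additive$loglik - 1e-3)
  expect_gte(menu$fits$hs$loglik, menu$fits$constant$loglik - 1e-3)
  expect_true(all(menu$tests$lambda >= 0))

  # outcrossing-only inference runs end-to-end with the same ordering
  menu1 <- fit_dominance_models(ds["outcrossing"], n_starts = 3, seed = 6)
  expect_gte(menu1$fits$constant$loglik, menu1$fits$additive$loglik - 1e-3)
  expect_gte(menu1$fits$hs$loglik, menu1$fits$constant$loglik - 1e-3)
})

test_that("likelihood-ratio tests use the chi-square tail and demand nesting", {
  ds <- small_datasets(seed = 7)[[1]]
  spec_a <- model_spec(ds, dominance_form = "additive")
  spec_h <- model_spec(ds, dominance_form = "inverse")
  fa <- fit_dominance_model(spec_a, n_starts = 2, seed = 1)
  fh <- fit_dominance_model(spec_h, n_starts = 2, seed = 1,
                            warm_starts = list(
                              c(fa$params, theta_intercept = 0.5,
                                theta_rate = 0)))
  t2 <- lrt(fa, fh)
  expect_identical(t2$df, 2L)
  expect_equal(t2$p_value, pchisq(t2$lambda, 2, lower.tail = FALSE))

  # hand-checked tail: Lambda = 4 at df = 1
  fake_null <- fa; fake_null$loglik <- -12
  fake_alt <- fa; fake_alt$loglik <- -10
  fake_alt$dominance_form <- "constant"; fake_alt$n_free <- 3L
  t1 <- lrt(fake_null, fake_alt)
  expect_equal(t1$lambda, 4)
  expect_equal(t1$p_value, 0.04550026, tolerance = 1e-6)

  same <- lrt(fake_null, { x <- fake_alt; x$loglik <- -12; x })
  expect_equal(same$lambda, 0)
  expect_equal(same$p_value, 1)

  expect_error(lrt(fh, fa), "not nested")
})

test_that("bootstrap resampling yields positive, reproducible uncertainty", {
  ds <- small_datasets(seed = 8)[[1]]
  spec <- model_spec(ds, dominance_form = "additive")
  fit <- fit_dominance_model(spec, n_starts = 3, seed = 2)
  b1 <- bootstrap_fit(fit, B = 4, seed = 13, n_starts = 2)
  b2 <- bootstrap_fit(fit, B = 4, seed = 13, n_starts = 2)
  expect_identical(b1$se, b2$se)
  expect_true(all(b1$se > 0))
  expect_true(all(b1$ci_lo < b1$ci_hi))
  expect_setequal(b1$term, c("shape", "mean_s"))
  expect_identical(attr(b1, "failures"), 0L)
  # the point estimate sits inside its own 95% interval
  expect_true(all(b1$estimate > b1$ci_lo - 2 * b1$se &
                    b1$estimate < b1$ci_hi + 2 * b1$se))
})

test_that("category Z-tests follow the normal reference with Bonferroni capping", {
  expect_equal(z_compare(1, 1, 1, 1)$z, 0)
  expect_equal(z_compare(1, 1, 1, 1)$p_raw, 1)
  z <- z_compare(3, 1, 1, 1)
  expect_equal(z$z, sqrt(2), tolerance = 1e-12)
  expect_equal(z$p_raw, 0.1572992, tolerance = 1e-6)
  expect_equal(z_compare(3, 1, 1, 1, n_tests = 10)$p_bonferroni,
               min(1, z$p_raw * 10))
  expect_equal(z_compare(0.1, 0.01, 0.1001, 0.01, n_tests = 10)$p_bonferroni,
               1)
  expect_error(z_compare(1, 0, 1, 1), "positive")
})
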