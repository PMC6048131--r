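test_that("drift and selection terms reproduce the inbreeding diffusion coefficients", {
  p <- c(0.1, 0.37, 0.9)
  # outcrossing additive case
  t0 <- drift_selection_terms(p, s = -0.01, h = 0.5, F = 0, N = 500)
  expect_equal(t0$M, -0.01 * p * (1 - p) / 2)
  expect_equal(t0$V, p * (1 - p) / 1000)
  # full selfing: independent of h, twice the additive mean change
  for (h in c(0, 0.3, 1)) {
    t1 <- drift_selection_terms(p, s = -0.01, h = h, F = 1, N = 500)
    expect_equal(t1$M, -0.01 * p * (1 - p))
    expect_equal(t1$M / t0$M, rep(2, length(p)))
    expect_equal(t1$V, p * (1 - p) / 500)
  }
  # no selection, no directional change
  expect_equal(drift_selection_terms(p, s = 0, h = 0.2, F = 0.5)$M,
               rep(0, 3))
  expect_error(drift_selection_terms(c(0, 0.5), s = 0), "inside \\(0, 1\\)")
})

test_that("selfing effective parameters double s and fix h at one half", {
  expect_equal(selfing_effective_params(-0.001)$s_e, -0.002)
  expect_equal(selfing_effective_params(0)$s_e, 0)
  expect_equal(selfing_effective_params(-0.1, h = 0.9)$h_e, 0.5)
})

test_that("expected SFS is neutral-exact, theta-linear and oracle-consistent", {
  sp <- expected_sfs(demographic_model(), gamma = 0, n = 11, theta = 1)
  expect_equal(sp$counts, 1 / (1:10), tolerance = 0.01)

  sp2 <- expected_sfs(demographic_model(), gamma = 0, n = 11, theta = 2)
  expect_equal(sp2$counts, 2 * sp$counts)

  # Wright-Fisher transition-matrix oracle at N = 200
  wf <- wf_exact_expected_sfs(N = 200, s = -0.01, h = 0.5, F = 0, n = 20)
  di <- expected_sfs(demographic_model(), gamma = -2, h = 0.5, F = 0,
                     n = 20, N_anc = 200)
  expect_equal(di$counts, wf$counts, tolerance = 0.02)

  expect_error(expected_sfs(demographic_model(), gamma = 1, n = 10),
               "<= 0")
})

test_that("stronger purifying selection suppresses variation", {
  # Entrywise monotonicity holds for h >= 0.5.  For strongly recessive
  # mutations the singleton class can slightly exceed its neutral value
  # at weak selection (alleles hide from selection at low frequency; the
  # exact WF chain shows the same excess), so for low h only the total
  # segregating count is required to be monotone.
  gammas <- c(-0.01, -1, -10, -100, -1000)
  for (h in c(0.05, 0.5, 0.95)) {
    prev <- NULL
    for (g in gammas) {
      cur <- expected_sfs(demographic_model(), gamma = g, h = h, n = 12)$counts
      if (!is.null(prev)) {
        if (h >= 0.5) {
          expect_true(all(cur <= prev * (1 + 1e-8) + 1e-9 * max(prev)))
        }
        expect_lte(sum(cur), sum(prev) * (1 + 1e-8))
      }
      prev <- cur
    }
  }
})

test_that("expected SFS is continuous in h and h-invariant at F = 1", {
  for (g in c(-0.5, -5, -50)) {
    base <- expected_sfs(demographic_model(), gamma = g, h = 0.3, n = 12)
    near <- expected_sfs(demographic_model(), gamma = g, h = 0.3 + 1e-4,
                         n = 12)
    far <- expected_sfs(demographic_model(), gamma = g, h = 0.5, n = 12)
    d_near <- max(abs(near$counts - base$counts) / base$counts)
    d_far <- max(abs(far$counts - base$counts) / base$counts)
    expect_lt(d_near, 0.01 * max(d_far, 1e-6) + 1e-5)
  }
  f1_a <- expected_sfs(demographic_model(), gamma = -5, h = 0, F = 1,
                       n = 12)
  f1_b <- expected_sfs(demographic_model(), gamma = -5, h = 1, F = 1,
                       n = 12)
  expect_equal(f1_a$counts, f1_b$counts, tolerance = 1e-10)
})

test_that("multi-epoch demography shifts the spectrum the expected way", {
  # recent growth inflates rare variants relative to common ones
  growth <- demographic_model(c(1, 5), c(Inf, 0.1))
  g <- expected_sfs(growth, gamma = 0, n = 12)$counts
  c0 <- expected_sfs(demographic_model(), gamma = 0, n = 12)$counts
  expect_gt((g[1] / g[8]) / (c0[1] / c0[8]), 1.2)
  # a long epoch at the ancestral size returns to equilibrium
  same <- expected_sfs(demographic_model(c(1, 1), c(Inf, 3)), gamma = 0,
                       n = 12)$counts
  expect_equal(same, c0, tolerance = 1e-6)
})

test_that("ancestral Ne follows from theta, mu and L", {
  expect_equal(ancestral_ne(4, 1, 1), 1)
  expect_equal(ancestral_ne(41800, 7e-9, 1e7), 41800 / (4 * 7e-9 * 1e7))
  expect_equal(ancestral_ne(41800, 7e-9, 1e7), 149285.714, tolerance = 1e-6)
  expect_equal(ancestral_ne(100, 1e-8, 2e6),
               ancestral_ne(100, 1e-8, 1e6) / 2)
  expect_error(ancestral_ne(1, 0, 1), "positive")
})

test_that("demographic fitting profiles theta analytically and prefers the truth", {
  # exact 5x scaling of theta on a noiseless neutral spectrum
  e <- fold_spectrum(expected_sfs(demographic_model(), gamma = 0, n = 12))
  obs5 <- site_spectrum(5 * e$counts, 12, folded = TRUE)
  f_const <- fit_demography(obs5, family = "constant", n_grid = 800,
                            dt = 1e-3)
  expect_equal(f_const$theta_syn, 5, tolerance = 1e-12)

  # neutral constant-size data: no spurious size changes beyond noise
  obs <- poisson_resample(site_spectrum(4000 * e$counts, 12, folded = TRUE),
                          seed = 2)
  fc <- fit_demography(obs, family = "constant")
  f3 <- fit_demography(obs, family = "three_epoch", n_starts = 4, seed = 1)
  expect_gte(f3$loglik + 1e-6, fc$loglik)
  expect_lt(f3$loglik - fc$loglik, 2)
})

test_that("a simulated bottleneck is recovered from the synonymous SFS", {
  truth <- demographic_model(c(1, 0.25), c(Inf, 0.15))
  e <- fold_spectrum(wf_exact_expected_sfs(N = 300, s = 0, n = 14,
                                           theta = 4000,
                                           demography = truth))
  obs <- poisson_resample(e, seed = 4)
  fit <- fit_demography(obs, family = "two_epoch", n_starts = 6, seed = 1)
  expect_equal(fit$model$nu[2], 0.25, tolerance = 0.3)
  expect_equal(fit$theta_syn, 4000, tolerance = 0.15)
})
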