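test_that("h-s relationship forms evaluate their closed forms", {
  inv <- hs_relationship("inverse", theta_intercept = 0.5,
                         theta_rate = 1e4)
  expect_equal(h_of_s(inv, 0), 0.5)                 # h at s = 0
  expect_equal(h_of_s(inv, -0.001), 1 / 12)         # 1/(2 + 10)

  # zero rate collapses to the constant-h model
  flat <- hs_relationship("inverse", theta_intercept = 0.37,
                          theta_rate = 0)
  s <- -c(0, 1e-4, 1e-2, 0.5)
  expect_equal(h_of_s(flat, s), rep(0.37, 4))
  expect_equal(h_of_s(hs_relationship("constant", h_const = 0.37), s),
               rep(0.37, 4))
  expect_equal(h_of_s(hs_relationship("additive"), s), rep(0.5, 4))

  lg <- hs_relationship("logistic", theta_intercept = 0.8,
                        theta_rate = 100, theta_offset = 2)
  expect_equal(h_of_s(lg, 0), 0.8)
  expect_equal(h_of_s(lg, -0.05),
               0.8 * (1 + exp(-2)) / (1 + exp(100 * 0.05 - 2)))

  expect_error(hs_relationship("inverse", theta_rate = -1), ">= 0")
  expect_error(h_of_s(inv, 0.01), "<= 0")
})

test_that("inverse and logistic forms are monotone non-increasing in |s|", {
  s <- -exp(seq(log(1e-6), log(1), length.out = 60))
  for (ti in c(0.1, 0.5, 1)) {
    for (tr in c(0, 10, 1e4, 1e6)) {
      h_inv <- h_of_s(hs_relationship("inverse", theta_intercept = ti,
                                      theta_rate = tr), s)
      expect_true(all(diff(h_inv) <= 1e-12))   # |s| ascending => h falling
      expect_true(all(h_inv >= 0 & h_inv <= 1))
      for (to in c(-2, 0, 3)) {
        h_lg <- h_of_s(hs_relationship("logistic", theta_intercept = ti,
                                       theta_rate = tr,
                                       theta_offset = to), s)
        expect_true(all(diff(h_lg) <= 1e-12))
        expect_true(all(h_lg >= 0 & h_lg <= 1))
      }
    }
  }
})

test_that("theta_nonsyn scaling multiplies by the length ratio", {
  expect_identical(theta_nonsyn_from_syn(131600), 131600 * 2.31)
  expect_equal(theta_nonsyn_from_syn(131600), 303996)
  expect_equal(theta_nonsyn_from_syn(41800), 96558)
  expect_identical(theta_nonsyn_from_syn(7, multiplier = 1), 7)
  expect_error(theta_nonsyn_from_syn(-1), "> 0")
})

test_that("a fully neutral DFE returns theta times the neutral spectrum", {
  grid <- build_coarse_grid(demographic_model(), n = 10, N_e = 500,
                            gamma_points = 12, h_points = 4)
  dfe <- gamma_dfe(0.3, 0.01, p_neutral = 1)
  sp <- expected_nonsyn_sfs(grid, dfe, hs_relationship("additive"),
                            N_e = 500, theta_nonsyn = 7)
  expect_equal(sp$counts, 7 * grid$neutral)
})

test_that("grid quadrature matches a dense direct-solver Riemann sum", {
  N_e <- 500
  coarse <- build_coarse_grid(demographic_model(), n = 10, N_e = N_e,
                              gamma_points = 40, h_points = 1,
                              h_range = c(0.5, 0.5))
  fine <- refine_grid(coarse, gamma_points = 300, h_points = 1)
  dfe <- gamma_dfe(0.4, 0.02 / 0.4)
  rel <- hs_relationship("additive")
  got <- expected_nonsyn_sfs(fine, dfe, rel, N_e = N_e, theta_nonsyn = 1)

  # oracle: brute-force quadrature at 10x the fine node density, each
  # node solved directly by the diffusion engine
  g <- exp(seq(log(1e-4), log(N_e), length.out = 3000))
  dens <- dgamma(g, 0.4, scale = N_e * 0.02 / 0.4)
  dg <- diff(g)
  w <- c(dg[1] / 2, (dg[-1] + dg[-length(dg)]) / 2, dg[length(dg)] / 2)
  acc <- numeric(9)
  for (i in seq_along(g)) {
    if (dens[i] * w[i] < 1e-10) next
    acc <- acc + dens[i] * w[i] *
      expected_sfs(demographic_model(), gamma = -g[i], h = 0.5, n = 10,
                   N_anc = N_e)$counts
  }
  acc <- acc + pgamma(1e-4, 0.4, scale = N_e * 0.02 / 0.4) * (1 / (1:9))
  expect_equal(got$counts, acc, tolerance = 0.01)
})

test_that("DFE integration is theta-linear, h-invariant for F = 1 grids, and nests", {
  grid <- build_coarse_grid(demographic_model(), n = 10, N_e = 300, F = 1,
                            gamma_points = 16, h_points = 5)
  dfe <- gamma_dfe(0.3, 0.005)
  rels <- list(hs_relationship("additive"),
               hs_relationship("constant", h_const = 0.1),
               hs_relationship("inverse", theta_intercept = 0.9,
                               theta_rate = 1e5),
               hs_relationship("logistic", theta_intercept = 0.7,
                               theta_rate = 1e3, theta_offset = 1))
  base <- expected_nonsyn_sfs(grid, dfe, rels[[1]], 300, 1)$counts
  for (r in rels[-1]) {
    expect_equal(expected_nonsyn_sfs(grid, dfe, r, 300, 1)$counts, base,
                 tolerance = 1e-10)
  }
  # linearity in theta
  expect_equal(expected_nonsyn_sfs(grid, dfe, rels[[1]], 300, 3.5)$counts,
               3.5 * base)

  # constant h = 0.5 reproduces the additive integration exactly
  g0 <- build_coarse_grid(demographic_model(), n = 10, N_e = 300,
                          gamma_points = 16, h_points = 5)
  a <- expected_nonsyn_sfs(g0, dfe, hs_relationship("additive"), 300, 1)
  c5 <- expected_nonsyn_sfs(g0, dfe,
                            hs_relationship("constant", h_const = 0.5),
                            300, 1)
  expect_identical(a$counts, c5$counts)
})

test_that("DFE integration is continuous in its parameters", {
  grid <- refine_grid(
    build_coarse_grid(demographic_model(), n = 10, N_e = 500,
                      gamma_points = 30, h_points = 8),
    gamma_points = 200, h_points = 60)
  rel <- hs_relationship("inverse", theta_intercept = 0.6,
                         theta_rate = 300)
  base <- expected_nonsyn_sfs(grid, gamma_dfe(0.4, 0.01), rel, 500, 1)$counts
  for (eps in c(1e-3, 1e-4)) {
    near <- expected_nonsyn_sfs(grid, gamma_dfe(0.4 * (1 + eps), 0.01),
                                rel, 500, 1)$counts
    expect_lt(max(abs(near - base) / base), 50 * eps)
  }
})
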