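# Small single-species configuration used by the simulator tests.
tiny_conditions <- function(theta_syn = 40, theta_nonsyn = 92.4,
                            N_anc = 1500, downscale = 50, n = 10,
                            dfe = gamma_dfe(0.3, 0.001 / 0.3),
                            hs = hs_relationship("additive"),
                            F = 0, h_noise_sd = NULL) {
  cond <- study_conditions(dfe = dfe, hs = hs, downscale = downscale,
                           h_noise_sd = h_noise_sd)
  sp <- cond$species$outcrossing
  sp$F <- F
  sp$n_sample <- as.integer(n)
  sp$N_anc <- N_anc
  sp$theta_syn <- theta_syn
  sp$theta_nonsyn <- theta_nonsyn
  sp$L_syn <- theta_syn / (4 * N_anc * sp$mu)
  cond$species <- list(outcrossing = sp)
  cond
}

test_that("the exact WF chain reproduces the neutral spectrum and orders selection", {
  neut <- wf_exact_expected_sfs(N = 100, s = 0, h = 0.5, F = 0, n = 10,
                                theta = 2)
  expect_equal(neut$counts, 2 / (1:9), tolerance = 0.02)

  sel <- wf_exact_expected_sfs(N = 100, s = -0.05, h = 0.5, F = 0, n = 10,
                               theta = 2)
  expect_true(all(sel$counts < neut$counts))

  expect_error(wf_exact_expected_sfs(N = 600, s = 0, n = 10),
               "max 500")
})

test_that("full selfing reduces to the scaled additive chain as s tends to zero", {
  # The s_e = 2 s reduction is a first-order (diffusion-limit) identity;
  # in the exact chain the residual shrinks quadratically in s.
  dev <- vapply(c(-0.001, -0.01), function(s) {
    a <- wf_exact_expected_sfs(N = 100, s = s, h = 0.1, F = 1, n = 12)
    b <- wf_exact_expected_sfs(N = 50, s = 2 * s, h = 0.5, F = 0, n = 12)
    max(abs(a$counts - b$counts) / b$counts)
  }, numeric(1))
  expect_lt(dev[1], 1e-3)
  expect_gt(dev[2] / dev[1], 50)   # ~ s^2 scaling
  # and the chain is h-invariant at F = 1
  c1 <- wf_exact_expected_sfs(N = 100, s = -0.01, h = 0, F = 1, n = 12)
  c2 <- wf_exact_expected_sfs(N = 100, s = -0.01, h = 1, F = 1, n = 12)
  expect_identical(c1$counts, c2$counts)
})

test_that("both simulation engines are seed-reproducible", {
  cond <- tiny_conditions()
  m1 <- forward_simulate(cond, replicates = 2, seed = 9, engine = "matrix")
  m2 <- forward_simulate(cond, replicates = 2, seed = 9, engine = "matrix")
  expect_identical(lapply(m1$spectrum, `[[`, "counts"),
                   lapply(m2$spectrum, `[[`, "counts"))

  small <- tiny_conditions(theta_syn = 10, theta_nonsyn = 23.1,
                           N_anc = 1000)
  t1 <- forward_simulate(small, replicates = 1, seed = 4,
                         engine = "tracked")
  t2 <- forward_simulate(small, replicates = 1, seed = 4,
                         engine = "tracked")
  expect_identical(lapply(t1$spectrum, `[[`, "counts"),
                   lapply(t2$spectrum, `[[`, "counts"))
})

test_that("tracked forward simulation matches the neutral expectation", {
  cond <- tiny_conditions(theta_syn = 30, theta_nonsyn = 30,
                          N_anc = 1000, n = 8,
                          dfe = gamma_dfe(1, 1e-12))  # point mass at ~0
  R <- 60
  sims <- forward_simulate(cond, replicates = R, seed = 21,
                           engine = "tracked")
  syn <- sims[sims$class == "synonymous", ]
  mat <- do.call(rbind, lapply(syn$spectrum, `[[`, "counts"))
  exp_counts <- fold_spectrum(neutral_spectrum(8, theta = 30))$counts
  se <- sqrt(exp_counts / R)
  expect_true(all(abs(colMeans(mat) - exp_counts) < 4 * se))
})

test_that("matrix and tracked engines agree in distribution", {
  cond <- tiny_conditions(theta_syn = 25, theta_nonsyn = 57.75,
                          N_anc = 1000, n = 8,
                          dfe = gamma_dfe(0.3, 0.05 / 0.3))
  R <- 60
  tr <- forward_simulate(cond, replicates = R, seed = 31,
                         engine = "tracked")
  ns <- tr[tr$class == "nonsynonymous", ]
  mat <- do.call(rbind, lapply(ns$spectrum, `[[`, "counts"))
  ex <- domdfe:::matrix_engine_expectations(
    cond$species$outcrossing, cond,
    N_sc = round(1000 / 50))$nonsynonymous
  se <- sqrt(ex$counts / R)
  expect_true(all(abs(colMeans(mat) - ex$counts) < 4 * se))
})

test_that("downscaling is compensated by selection rescaling", {
  # expectation engines at downscale 50 vs 25 (gamma held fixed) agree
  # up to O(1/N) chain discretization
  c50 <- tiny_conditions(N_anc = 5000, downscale = 50,
                         dfe = gamma_dfe(0.3, 0.001 / 0.3))
  c25 <- tiny_conditions(N_anc = 5000, downscale = 25,
                         dfe = gamma_dfe(0.3, 0.001 / 0.3))
  e50 <- domdfe:::matrix_engine_expectations(c50$species$outcrossing, c50,
                                             N_sc = 100)$nonsynonymous
  e25 <- domdfe:::matrix_engine_expectations(c25$species$outcrossing, c25,
                                             N_sc = 200)$nonsynonymous
  expect_equal(e50$counts, e25$counts, tolerance = 0.03)
})

test_that("beta-distributed dominance noise has the requested moments", {
  rel <- hs_relationship("inverse", theta_intercept = 0.5,
                         theta_rate = 1000)
  s <- rep(-0.001, 20000)
  set.seed(5)
  h <- domdfe:::hs_draw(rel, s, h_noise_sd = 0.1)
  m <- h_of_s(rel, -0.001)
  expect_equal(mean(h), m, tolerance = 0.01)
  expect_equal(sd(h), 0.1, tolerance = 0.02)
  expect_true(all(h >= 0 & h <= 1))
  # infeasible moments fall back to the clipped mean
  h2 <- domdfe:::hs_draw(rel, rep(-0.5, 10), h_noise_sd = 0.1)
  expect_true(all(h2 >= 0.001))
})

test_that("fixture bundles round trip with a faithful manifest", {
  dir <- tempfile("fixtures")
  paths <- generate_fixtures(dir, profile = "genome_wide", seed = 3,
                             theta_divisor = 100)
  man <- yaml::read_yaml(paths[["manifest.yaml"]])
  for (sp in man$species) {
    expect_equal(sp$theta_nonsyn / sp$theta_syn, 2.31, tolerance = 1e-3)
  }
  expect_equal(man$species$outcrossing$theta_syn, 1316)

  sp <- read_spectrum(paths[["outcrossing_syn.fs"]])
  expect_true(sp$folded)
  expect_equal(sp$sample_size, 22)

  # small_category profile is one tenth of genome-wide
  man_small <- yaml::read_yaml(generate_fixtures(
    tempfile("fx2"), profile = "small_category", seed = 3,
    theta_divisor = 100)[["manifest.yaml"]])
  expect_equal(man_small$species$outcrossing$theta_syn, 131.6)

  # byte-identical reruns under the same seed
  d1 <- tempfile("fxa"); d2 <- tempfile("fxb")
  p1 <- generate_fixtures(d1, "small_category", seed = 11,
                          theta_divisor = 100)
  p2 <- generate_fixtures(d2, "small_category", seed = 11,
                          theta_divisor = 100)
  for (nm in setdiff(names(p1), "manifest.yaml")) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]))
  }
})
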