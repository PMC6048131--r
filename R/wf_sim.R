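#' Post-selection allele frequency under inbreeding
#'
#' Deterministic change of the derived-allele frequency in one generation
#' of selection, with genotype fitnesses 1 (wild type), `1 + h s`
#' (heterozygote), `1 + s` (mutant homozygote) and genotype frequencies
#' at inbreeding coefficient `F`.
#'
#' @keywords internal
selection_response <- function(q, s, h, F) {
  hom <- q^2 + F * q * (1 - q)
  het <- 2 * q * (1 - q) * (1 - F)
  wbar <- 1 + s * hom + h * s * het
  (hom * (1 + s) + 0.5 * het * (1 + h * s)) / wbar
}

#' Exact Wright-Fisher expected SFS (small-N oracle)
#'
#' Brute-force stationary expectation of the sample SFS from the full
#' Wright-Fisher Markov chain with selection, dominance and inbreeding,
#' used as an independent oracle for the diffusion solver.  The chain
#' acts on `M = round(2N / (1 + F))` sampling units (allele copies for
#' `F = 0`, individuals for `F = 1`, matching the drift variance
#' `p(1-p)(1+F)/(2N)`), with mutational influx `theta / 2` per
#' generation at the lowest segregating frequency `1 / M`.  The
#' stationary mean occupancy of segregating states solves a dense linear
#' system, so `N` must be modest.
#'
#' @param N Population size (diploid individuals), `<= 500`.
#' @param s,h,F Selection, dominance and inbreeding coefficients.
#' @param n Sample size (allele copies).
#' @param theta Population mutation rate of the site class.
#' @param demography Optional [demographic_model()]; non-ancestral epochs
#'   are iterated generation by generation from the ancestral stationary
#'   state (durations in units of `2 N` generations).
#' @return An unfolded `site_spectrum` of expected counts.
#' @export
wf_exact_expected_sfs <- function(N, s = 0, h = 0.5, F = 0, n, theta = 1,
                                  demography = demographic_model()) {
  N <- as.integer(N)
  if (N > 500L) {
    stop("N too large for the exact transition-matrix oracle (max 500)",
         call. = FALSE)
  }
  mu_vec <- wf_stationary_occupancy(N, s, h, F, theta, demography)
  M <- attr(mu_vec, "M")
  q <- seq_len(M - 1L) / M
  counts <- vapply(seq_len(n - 1L),
                   function(i) sum(mu_vec * stats::dbinom(i, n, q)),
                   numeric(1))
  site_spectrum(counts, n, folded = FALSE,
                label = sprintf("wf N=%d s=%.4g h=%.3g F=%.2g", N, s, h, F))
}

# Mean number of segregating mutations per population-frequency state.
wf_stationary_occupancy <- function(N, s, h, F, theta, demography) {
  M <- as.integer(round(2 * N / (1 + F)))
  qs <- selection_response(seq_len(M - 1L) / M, s, h, F)
  # P[j, k]: probability a mutation at count j has count k next generation
  P <- outer(qs, seq_len(M - 1L),
             function(q, k) stats::dbinom(k, M, q))
  b <- numeric(M - 1L)
  b[1] <- theta / 2
  A <- diag(M - 1L) - t(P)
  mu <- solve(A, b)
  if (demography$n_epochs > 1L) {
    for (k in 2:demography$n_epochs) {
      Nk <- max(2L, as.integer(round(demography$nu[k] * N)))
      Mk <- as.integer(round(2 * Nk / (1 + F)))
      gens <- max(1L, as.integer(round(demography$duration[k] * 2 * N)))
      # re-map occupancy onto the new state space once, then iterate
      if (Mk != M) {
        qs_map <- seq_along(mu) / (length(mu) + 1L)
        Pmap <- outer(selection_response(qs_map, s, h, F),
                      seq_len(Mk - 1L),
                      function(q, k2) stats::dbinom(k2, Mk, q))
        mu <- as.numeric(t(Pmap) %*% mu)
        M <- Mk
      }
      qk <- selection_response(seq_len(M - 1L) / M, s, h, F)
      Pk <- outer(qk, seq_len(M - 1L),
                  function(q, k2) stats::dbinom(k2, M, q))
      tPk <- t(Pk)
      bk <- numeric(M - 1L)
      bk[1] <- demography$nu[k] * theta / 2   # influx scales with 2 N_k mu L
      for (g in seq_len(gens)) mu <- as.numeric(tPk %*% mu) + bk
    }
  }
  attr(mu, "M") <- M
  mu
}

#' Study conditions for the two-species simulation experiments
#'
#' The default synthetic study pairs an outcrossing population
#' (`F = 0`, 22 sampled allele copies) with a fully selfing one
#' (`F = 1`, 12 sampled copies, one copy per effectively homozygous
#' accession), at the genome-wide-over-ten mutation-rate profile
#' (`theta_syn` 13,160 / 4,180 and `theta_nonsyn` 30,400 / 9,660;
#' nonsynonymous/synonymous length multiplier 2.31), constant
#' demography, a gamma DFE with shape 0.3 and mean `|s|` 0.001, neutral
#' mutation rate `7e-9`, and forward simulations run at a 50-fold
#' downscaled population size.
#'
#' @param theta_profile `"small_category"` (the default, one tenth of
#'   genome-wide) or `"genome_wide"`.
#' @param dfe True DFE of the simulations.
#' @param hs True h-s relationship of the simulations.
#' @param downscale Population-size reduction factor of the forward
#'   simulations (selection rescaled to keep `gamma` invariant).
#' @param h_noise_sd Optional SD of beta-distributed per-mutation
#'   dominance noise around `f(s)` (tracked engine only).
#' @return A `simulation_config` list.
#' @export
study_conditions <- function(theta_profile = c("small_category",
                                               "genome_wide"),
                             dfe = gamma_dfe(shape = 0.3,
                                             scale = 0.001 / 0.3),
                             hs = hs_relationship("additive"),
                             downscale = 50,
                             h_noise_sd = NULL) {
  theta_profile <- match.arg(theta_profile)
  div <- if (theta_profile == "small_category") 10 else 1
  mu <- 7e-9
  species <- list(
    outcrossing = list(
      label = "outcrossing", F = 0, n_sample = 22L,
      N_anc = 25000, demography = demographic_model(),
      theta_syn = 131600 / div, theta_nonsyn = 304000 / div,
      mu = mu, L_syn = 131600 / div / (4 * 25000 * mu)
    ),
    selfing = list(
      label = "selfing", F = 1, n_sample = 12L,
      N_anc = 10000, demography = demographic_model(),
      theta_syn = 41800 / div, theta_nonsyn = 96600 / div,
      mu = mu, L_syn = 41800 / div / (4 * (10000 / 2) * mu)
    )
  )
  structure(list(species = species, dfe = dfe, hs = hs,
                 downscale = downscale, h_noise_sd = h_noise_sd,
                 theta_profile = theta_profile),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("<simulation_config> %s profile, downscale %g\n",
              x$theta_profile, x$downscale))
  for (sp in x$species) {
    cat(sprintf("  %s: F = %g, n = %d, N_anc = %g, theta_syn = %g, theta_nonsyn = %g\n",
                sp$label, sp$F, sp$n_sample, sp$N_anc, sp$theta_syn,
                sp$theta_nonsyn))
  }
  print(x$dfe)
  print(x$hs)
  invisible(x)
}

# ---------------------------------------------------------------------------
# DFE discretization shared by the matrix engine
# ---------------------------------------------------------------------------

# Discretize the gamma DFE into K bins of |s| (true units) with exact bin
# masses and mass-weighted conditional means; mass below s_lo is treated
# as neutral and mass beyond |s| = 1 as lethal (s = -1).
discretize_dfe <- function(dfe, K = 64, s_lo = 1e-7, s_hi = 1) {
  edges <- exp(seq(log(s_lo), log(s_hi), length.out = K + 1L))
  p_edges <- stats::pgamma(edges, dfe$shape, scale = dfe$scale)
  mass <- diff(p_edges)
  # conditional mean within each bin via the shape+1 identity
  p1_edges <- stats::pgamma(edges, dfe$shape + 1, scale = dfe$scale)
  mean_num <- dfe$shape * dfe$scale * diff(p1_edges)
  s_rep <- ifelse(mass > 0, mean_num / mass, sqrt(edges[-1] * edges[-(K + 1)]))
  keep <- mass > 1e-12
  gamma_part <- 1 - dfe$p_neutral
  list(
    s = -s_rep[keep],
    mass = gamma_part * mass[keep],
    mass_neutral = dfe$p_neutral + gamma_part * p_edges[1],
    mass_lethal = gamma_part * (1 - p_edges[K + 1L])
  )
}

# ---------------------------------------------------------------------------
# Forward simulation
# ---------------------------------------------------------------------------

#' Forward-simulate site frequency spectra
#'
#' Simulates per-replicate synonymous and nonsynonymous folded spectra
#' for each species of a [study_conditions()] configuration, at the
#' downscaled population size (`N / downscale`, `s * downscale`, `theta`
#' invariant).
#'
#' Two engines are provided.  `"matrix"` (default) exploits the Poisson
#' random-field structure exactly: because mutations arise as a Poisson
#' stream and evolve independently, the sampled SFS entries are
#' independent Poisson variables whose means are the expected spectra of
#' the Wright-Fisher chain; the engine computes those means from the
#' exact chain (integrating the DFE over a fine discretization) and
#' draws Poisson replicates.  `"tracked"` is a literal per-mutation
#' forward simulation (every segregating mutation's allele count updated
#' by Wright-Fisher binomial sampling each generation, with per-mutation
#' `s` drawn from the DFE and `h = f(s)`, optionally with beta noise),
#' identical in distribution but far slower; use it at small `theta`
#' and population size.  Results are reproducible given `seed`.
#'
#' @param config A `simulation_config` from [study_conditions()].
#' @param replicates Number of replicates.
#' @param seed Integer seed.
#' @param engine `"matrix"` or `"tracked"`.
#' @param burnin_factor Tracked engine: burn-in of
#'   `burnin_factor * 2 * N_scaled` generations (default 10).
#' @return A tibble with columns `replicate`, `species`, `class`
#'   (`"synonymous"`/`"nonsynonymous"`) and `spectrum` (list column of
#'   folded `site_spectrum` objects).
#' @export
forward_simulate <- function(config, replicates = 1, seed = 1,
                             engine = c("matrix", "tracked"),
                             burnin_factor = 10) {
  stopifnot(inherits(config, "simulation_config"))
  engine <- match.arg(engine)
  with_preserved_seed(seed, {
    rows <- list()
    for (sp in config$species) {
      N_sc <- max(2L, as.integer(round(sp$N_anc / config$downscale)))
      if (engine == "matrix") {
        ex <- matrix_engine_expectations(sp, config, N_sc)
        for (r in seq_len(replicates)) {
          for (cl in c("synonymous", "nonsynonymous")) {
            mean_sp <- ex[[cl]]
            draw <- stats::rpois(length(mean_sp$counts), mean_sp$counts)
            rows[[length(rows) + 1L]] <- tibble::tibble(
              replicate = r, species = sp$label, class = cl,
              spectrum = list(site_spectrum(
                as.numeric(draw), mean_sp$sample_size, folded = TRUE,
                label = paste(sp$label, cl)))
            )
          }
        }
      } else {
        for (r in seq_len(replicates)) {
          sim <- tracked_engine_once(sp, config, N_sc, burnin_factor)
          for (cl in c("synonymous", "nonsynonymous")) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              replicate = r, species = sp$label, class = cl,
              spectrum = list(sim[[cl]])
            )
          }
        }
      }
    }
    do.call(rbind, rows)
  })
}

# Expected folded spectra of one species under the downscaled WF chain.
# Cached per (species, DFE, hs, downscale) in the package cache
# environment, since the dense chain solves dominate the cost.
matrix_engine_expectations <- function(sp, config, N_sc) {
  key <- rlang::hash(list(sp$label, sp$F, sp$n_sample, sp$N_anc,
                          sp$theta_syn, sp$theta_nonsyn,
                          sp$demography$nu, sp$demography$duration,
                          config$dfe[c("shape", "scale", "p_neutral")],
                          unclass(config$hs), config$downscale))
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  ds <- config$downscale
  neutral_unit <- wf_exact_expected_sfs(N_sc, s = 0, h = 0.5, F = sp$F,
                                        n = sp$n_sample, theta = 1,
                                        demography = sp$demography)
  syn <- fold_spectrum(site_spectrum(
    sp$theta_syn * neutral_unit$counts, sp$n_sample, folded = FALSE,
    label = paste(sp$label, "synonymous")))
  bins <- discretize_dfe(config$dfe)
  acc <- (bins$mass_neutral) * neutral_unit$counts
  for (k in seq_along(bins$s)) {
    s_true <- bins$s[k]
    h_k <- h_of_s(config$hs, s_true)
    s_sim <- max(-1, s_true * ds)
    sp_k <- wf_exact_expected_sfs(N_sc, s = s_sim, h = h_k, F = sp$F,
                                  n = sp$n_sample, theta = 1,
                                  demography = sp$demography)
    acc <- acc + bins$mass[k] * sp_k$counts
  }
  if (bins$mass_lethal > 0) {
    h_l <- h_of_s(config$hs, -1)
    sp_l <- wf_exact_expected_sfs(N_sc, s = -1, h = h_l, F = sp$F,
                                  n = sp$n_sample, theta = 1,
                                  demography = sp$demography)
    acc <- acc + bins$mass_lethal * sp_l$counts
  }
  nonsyn <- fold_spectrum(site_spectrum(
    sp$theta_nonsyn * acc, sp$n_sample, folded = FALSE,
    label = paste(sp$label, "nonsynonymous")))
  out <- list(synonymous = syn, nonsynonymous = nonsyn)
  cache_set(key, out)
  out
}

# Literal per-mutation forward simulation of one replicate of one
# species (downscaled).  Selfing (F = 1) tracks mutant homozygous
# individuals (M = N states); outcrossing tracks allele copies (M = 2N).
tracked_engine_once <- function(sp, config, N_sc, burnin_factor) {
  ds <- config$downscale
  M <- as.integer(round(2 * N_sc / (1 + sp$F)))
  influx_syn <- sp$theta_syn / 2
  influx_ns <- sp$theta_nonsyn / 2
  if (influx_syn + influx_ns < 1) {
    warning("theta and downscale imply < 1 expected mutation per ",
            "generation; spectra will be sparse")
  }
  gens <- as.integer(ceiling(burnin_factor * 2 * N_sc))
  counts <- integer(0)
  s_sim <- numeric(0)
  h_mut <- numeric(0)
  is_syn <- logical(0)
  for (g in seq_len(gens)) {
    # Wright-Fisher update of the standing mutations, then this
    # generation's new mutations enter at one copy (so the final tally
    # includes freshly arisen mutations, matching the stationary chain).
    if (length(counts) > 0L) {
      q <- counts / M
      qs <- selection_response(q, s_sim, h_mut, sp$F)
      counts <- stats::rbinom(length(counts), M, qs)
      keep <- counts > 0L & counts < M    # fixed and lost alleles leave
      counts <- counts[keep]
      s_sim <- s_sim[keep]
      h_mut <- h_mut[keep]
      is_syn <- is_syn[keep]
    }
    n_new_syn <- stats::rpois(1, influx_syn)
    n_new_ns <- stats::rpois(1, influx_ns)
    if (n_new_ns > 0) {
      s_true <- dfe_draw(config$dfe, n_new_ns)
      h_new <- hs_draw(config$hs, s_true, config$h_noise_sd)
      s_new <- pmax(-1, s_true * ds)
      counts <- c(counts, rep(1L, n_new_ns))
      s_sim <- c(s_sim, s_new)
      h_mut <- c(h_mut, h_new)
      is_syn <- c(is_syn, rep(FALSE, n_new_ns))
    }
    if (n_new_syn > 0) {
      counts <- c(counts, rep(1L, n_new_syn))
      s_sim <- c(s_sim, rep(0, n_new_syn))
      h_mut <- c(h_mut, rep(0.5, n_new_syn))
      is_syn <- c(is_syn, rep(TRUE, n_new_syn))
    }
  }
  tally <- function(sel) {
    if (!any(sel)) {
      return(site_spectrum(numeric(sp$n_sample %/% 2L), sp$n_sample,
                           folded = TRUE))
    }
    samp <- stats::rbinom(sum(sel), sp$n_sample, counts[sel] / M)
    samp <- samp[samp > 0L & samp < sp$n_sample]
    minor <- pmin(samp, sp$n_sample - samp)
    spectrum_from_counts(minor, sp$n_sample)
  }
  list(synonymous = tally(is_syn), nonsynonymous = tally(!is_syn))
}

# Draw |s| from the gamma DFE (true, un-downscaled units), with the
# neutral point mass.
dfe_draw <- function(dfe, n) {
  s <- -stats::rgamma(n, dfe$shape, scale = dfe$scale)
  if (dfe$p_neutral > 0) {
    s[stats::runif(n) < dfe$p_neutral] <- 0
  }
  s
}

# Draw per-mutation dominance: deterministic h = f(s), or beta noise
# with mean f(s) and the configured SD when feasible.
hs_draw <- function(rel, s, h_noise_sd = NULL) {
  m <- h_of_s(rel, s)
  if (is.null(h_noise_sd) || h_noise_sd <= 0) return(m)
  v <- h_noise_sd^2
  feasible <- m > 0 & m < 1 & v < m * (1 - m)
  out <- pmin(pmax(m, 0.001), 0.999)
  if (any(feasible)) {
    k <- m[feasible] * (1 - m[feasible]) / v - 1
    a <- m[feasible] * k
    b <- (1 - m[feasible]) * k
    out[feasible] <- stats::rbeta(sum(feasible), a, b)
  }
  out
}

#' Write a bundle of simulated .fs fixtures
#'
#' Simulates one species-pair replicate under the given profile and
#' writes the four spectra (synonymous/nonsynonymous for the outcrossing
#' and selfing species) as dadi-style `.fs` files plus a YAML manifest
#' recording the seed, mutation rates, DFE and h-s parameters and the
#' downscale factor.
#'
#' @param dir Output directory (created if needed).
#' @param profile `"genome_wide"` or `"small_category"`.
#' @param seed Integer seed.
#' @param theta_divisor Additional desk-scale divisor applied to every
#'   `theta` (default 1: the profile's stated magnitudes).
#' @param config Optional pre-built `simulation_config`; defaults to
#'   [study_conditions()] at the requested profile.
#' @return Invisibly, a named character vector of file paths.
#' @export
generate_fixtures <- function(dir, profile = c("genome_wide",
                                               "small_category"),
                              seed = 1, theta_divisor = 1,
                              config = NULL) {
  profile <- match.arg(profile)
  if (is.null(config)) config <- study_conditions(theta_profile = profile)
  if (theta_divisor != 1) {
    for (i in seq_along(config$species)) {
      config$species[[i]]$theta_syn <-
        config$species[[i]]$theta_syn / theta_divisor
      config$species[[i]]$theta_nonsyn <-
        config$species[[i]]$theta_nonsyn / theta_divisor
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sims <- forward_simulate(config, replicates = 1, seed = seed,
                           engine = "matrix")
  paths <- character(0)
  for (i in seq_len(nrow(sims))) {
    nm <- sprintf("%s_%s.fs", sims$species[i],
                  sub("onymous", "", sims$class[i]))
    p <- file.path(dir, nm)
    write_spectrum(sims$spectrum[[i]], p)
    paths[nm] <- p
  }
  manifest <- list(
    seed = seed, profile = profile, theta_divisor = theta_divisor,
    downscale = config$downscale,
    dfe = config$dfe[c("shape", "scale", "p_neutral")],
    hs = unclass(config$hs),
    species = lapply(config$species, function(sp) {
      sp[c("label", "F", "n_sample", "N_anc", "theta_syn",
           "theta_nonsyn", "mu", "L_syn")]
    })
  )
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  paths["manifest.yaml"] <- mp
  invisible(paths)
}

# Package-level memo cache for expensive deterministic computations.
the_cache <- new.env(parent = emptyenv())
cache_get <- function(key) {
  if (exists(key, envir = the_cache, inherits = FALSE)) {
    get(key, envir = the_cache)
  } else NULL
}
cache_set <- function(key, value) assign(key, value, envir = the_cache)
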