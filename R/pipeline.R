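#' Run configuration for the full inference pipeline
#'
#' @param spectra Named list of four file paths (or `site_spectrum`
#'   objects): `out_syn`, `out_nonsyn`, `self_syn`, `self_nonsyn`.
#'   The selfing pair may be omitted for outcrossing-only inference.
#' @param mu Neutral mutation rate (shared).
#' @param L_syn Named numeric: synonymous sequence length per dataset
#'   (`out`, and `self` if present).
#' @param F Named numeric inbreeding coefficients (defaults 0 / 1).
#' @param demography_family Family per dataset (recycled).
#' @param hs_form Richest dominance model to fit.
#' @param shared_dfe,constrain_intercept,p_neutral_free Model structure.
#' @param n_starts Optimizer starts for the selection fits.
#' @param demog_n_starts Starts for the demographic fits.
#' @param coarse_gamma,coarse_h,fine_gamma,fine_h Grid resolutions.
#' @param bootstrap_B Bootstrap replicates for the richest model
#'   (0 = skip).
#' @param seed Integer seed for every stochastic stage.
#' @param theta_multiplier `L_NS / L_S` ratio.
#' @param paper_scale If `TRUE`, restore 1000 optimizer starts and
#'   1000 x 1000 fine grids (full-scale analysis settings).
#' @return A `run_config` list.
#' @export
run_config <- function(spectra, mu = 7e-9, L_syn,
                       F = c(out = 0, self = 1),
                       demography_family = "three_epoch",
                       hs_form = "inverse", shared_dfe = TRUE,
                       constrain_intercept = NULL,
                       p_neutral_free = FALSE,
                       n_starts = 50, demog_n_starts = 10,
                       coarse_gamma = 50, coarse_h = 20,
                       fine_gamma = 400, fine_h = 500,
                       bootstrap_B = 0, seed = 1,
                       theta_multiplier = 2.31, paper_scale = FALSE) {
  if (paper_scale) {
    n_starts <- 1000
    fine_gamma <- 1000
    fine_h <- 1000
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full co-estimation workflow
#'
#' Executes the complete inference: demographic fits on the synonymous
#' spectra, `(gamma, h)` grid builds, maximum-likelihood fits of the
#' additive, constant-`h` and h-s relationship models, the three nested
#' likelihood-ratio tests, and (optionally) a bootstrap of the richest
#' model.  Every stage is seeded from the config.
#'
#' @param config A [run_config()].
#' @param grids Optional named list of pre-built grids (`out`, `self`).
#' @return An `inference_report`: list with `datasets` (prepared),
#'   `menu` (fits + LRT table), `bootstrap` (tibble or `NULL`),
#'   `config`, and a `log` of per-stage timings.
#' @export
run_full_inference <- function(config, grids = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  log <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf("[%8.2fs] %s", proc.time()[["elapsed"]] - t0,
                   sprintf(fmt, ...))
    log <<- c(log, msg)
    message(msg)
  }
  get_spec <- function(x) {
    if (is_site_spectrum(x)) x else read_spectrum(x)
  }
  labels <- if (!is.null(config$spectra$self_syn)) c("out", "self") else "out"
  fam <- rep(config$demography_family, length.out = length(labels))
  datasets <- list()
  for (i in seq_along(labels)) {
    lab <- labels[i]
    note("preparing dataset '%s' (demography: %s)", lab, fam[i])
    ds <- inference_dataset(
      label = lab,
      syn = get_spec(config$spectra[[paste0(lab, "_syn")]]),
      nonsyn = get_spec(config$spectra[[paste0(lab, "_nonsyn")]]),
      F = unname(config$F[[lab]]), mu = config$mu,
      L_syn = unname(config$L_syn[[lab]]),
      demography_family = fam[i],
      theta_multiplier = config$theta_multiplier)
    datasets[[lab]] <- prepare_dataset(
      ds, grid = grids[[lab]],
      demog_n_starts = config$demog_n_starts, seed = config$seed,
      coarse_gamma = config$coarse_gamma, coarse_h = config$coarse_h,
      fine_gamma = config$fine_gamma, fine_h = config$fine_h)
    note("  theta_syn = %.6g, N_e = %.6g", datasets[[lab]]$theta_syn,
         datasets[[lab]]$N_e)
  }
  note("fitting dominance models (%s as richest form)", config$hs_form)
  menu <- fit_dominance_models(
    datasets, hs_form = config$hs_form, n_starts = config$n_starts,
    seed = config$seed, shared_dfe = config$shared_dfe,
    constrain_intercept = config$constrain_intercept,
    p_neutral_free = config$p_neutral_free)
  boot <- NULL
  if (config$bootstrap_B > 0) {
    note("bootstrapping richest model (B = %d)", config$bootstrap_B)
    boot <- bootstrap_fit(menu$fits$hs, B = config$bootstrap_B,
                          seed = config$seed)
  }
  note("done")
  structure(list(datasets = datasets, menu = menu, bootstrap = boot,
                 config = config, log = log),
            class = "inference_report")
}

#' @export
print.inference_report <- function(x, ...) {
  cat("<inference_report>\n")
  for (lab in names(x$datasets)) {
    d <- x$datasets[[lab]]
    cat(sprintf("  %s: theta_syn = %.6g, N_e = %.6g, F = %g\n",
                lab, d$theta_syn, d$N_e, d$F))
  }
  print(x$menu)
  invisible(x)
}

#' Serialize an inference report to JSON
#'
#' @param report An `inference_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "inference_report"))
  out <- list(
    datasets = lapply(report$datasets, function(d) {
      list(label = d$label, theta_syn = d$theta_syn,
           theta_nonsyn = d$theta_nonsyn, N_e = d$N_e, F = d$F,
           demography = list(family = d$demography$family,
                             nu = d$demography$model$nu,
                             duration = d$demography$model$duration,
                             loglik = d$demography$loglik))
    }),
    fits = lapply(report$menu$fits, function(f) {
      list(form = f$dominance_form, loglik = f$loglik,
           params = as.list(f$params))
    }),
    tests = report$menu$tests,
    bootstrap = report$bootstrap,
    seed = report$config$seed,
    log = report$log
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

# Prepared datasets for one simulated replicate, reusing shared grids.
prepare_replicate_datasets <- function(sims, rep_id, conditions, grids,
                                       seed) {
  out <- list()
  for (i in seq_along(conditions$species)) {
    sp <- conditions$species[[i]]
    lab <- sp$label
    syn <- sims$spectrum[[which(sims$replicate == rep_id &
                                  sims$species == lab &
                                  sims$class == "synonymous")]]
    nonsyn <- sims$spectrum[[which(sims$replicate == rep_id &
                                     sims$species == lab &
                                     sims$class == "nonsynonymous")]]
    ds <- inference_dataset(lab, syn, nonsyn, F = sp$F, mu = sp$mu,
                            L_syn = sp$L_syn,
                            demography_family = "constant")
    out[[lab]] <- prepare_dataset(ds, grid = grids[[lab]], seed = seed)
  }
  out
}

#' Build the shared inference grids for a simulation-study configuration
#'
#' @param conditions A [study_conditions()] configuration.
#' @param coarse_gamma,coarse_h,fine_gamma,fine_h Grid resolutions.
#' @return Named list of refined, folded grids keyed by species label.
#' @export
condition_grids <- function(conditions, coarse_gamma = 50, coarse_h = 20,
                            fine_gamma = 400, fine_h = 500) {
  grids <- list()
  for (sp in conditions$species) {
    selfing <- sp$F >= 1
    N_e <- if (selfing) sp$N_anc / 2 else sp$N_anc
    g <- build_inference_grid(sp$demography, n = sp$n_sample, N_e = N_e,
                              selfing = selfing,
                              coarse_gamma = coarse_gamma,
                              coarse_h = coarse_h,
                              fine_gamma = fine_gamma, fine_h = fine_h)
    grids[[sp$label]] <- fold_grid(g)
  }
  grids
}

#' Null calibration of the likelihood-ratio tests
#'
#' Simulates `replicates` additive datasets under the study conditions
#' (both species, downscaled forward simulation), runs the full
#' inference on each (demographic re-fit, then additive, constant-`h`
#' and h-s model fits with warm-started nesting) and returns the
#' likelihood-ratio statistics, whose null distributions should track
#' chi-square with 1 df (additive vs constant) and 2 df (additive vs
#' h-s).
#'
#' @param replicates Number of simulated replicates.
#' @param conditions A [study_conditions()]; the DFE/h-s in it define
#'   the simulation truth (additive by default).
#' @param seed Integer seed.
#' @param n_starts Optimizer starts per model fit.
#' @param grids Optional pre-built [condition_grids()].
#' @param engine Simulation engine (see [forward_simulate()]).
#' @return A tibble with one row per replicate: log-likelihoods of the
#'   three models and `lambda_const_add`, `lambda_hs_add`,
#'   `lambda_hs_const`.
#' @export
lrt_calibration <- function(replicates = 100,
                            conditions = study_conditions(),
                            seed = 1, n_starts = 4, grids = NULL,
                            engine = "matrix") {
  if (is.null(grids)) grids <- condition_grids(conditions)
  sims <- forward_simulate(conditions, replicates = replicates,
                           seed = seed, engine = engine)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    datasets <- prepare_replicate_datasets(sims, r, conditions, grids,
                                           seed = seed + r)
    menu <- fit_dominance_models(datasets, n_starts = n_starts,
                                 seed = seed * 100 + r)
    tt <- menu$tests
    rows[[r]] <- tibble::tibble(
      replicate = r,
      ll_additive = menu$fits$additive$loglik,
      ll_constant = menu$fits$constant$loglik,
      ll_hs = menu$fits$hs$loglik,
      lambda_const_add = tt$lambda[tt$null == "additive" &
                                     tt$alternative == "constant"],
      lambda_hs_add = tt$lambda[tt$null == "additive" &
                                  tt$alternative == "inverse"],
      lambda_hs_const = tt$lambda[tt$null == "constant" &
                                    tt$alternative == "inverse"]
    )
  }
  do.call(rbind, rows)
}

#' Power and parameter recovery under an h-s relationship truth
#'
#' Simulates datasets under a (non-additive) h-s relationship, fits the
#' constant-`h` and h-s models, and reports the constant-vs-h-s LRT and
#' the fitted dominance at a reference selection coefficient.
#'
#' @param replicates Number of simulated replicates.
#' @param conditions A [study_conditions()] whose `hs` is the simulation
#'   truth.
#' @param s_ref Reference selection coefficient at which the fitted
#'   `h(s)` is evaluated (default -0.001).
#' @param seed,n_starts,grids,engine As in [lrt_calibration()].
#' @return A tibble with per-replicate `lambda_hs_const`, `p_value`,
#'   `h_at_ref` and the fitted h-s parameters.
#' @export
power_recovery <- function(replicates = 20,
                           conditions = study_conditions(
                             hs = hs_relationship(
                               "inverse", theta_intercept = 0.5,
                               theta_rate = 48000)),
                           s_ref = -0.001, seed = 1, n_starts = 4,
                           grids = NULL, engine = "matrix") {
  if (is.null(grids)) grids <- condition_grids(conditions)
  sims <- forward_simulate(conditions, replicates = replicates,
                           seed = seed, engine = engine)
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    datasets <- prepare_replicate_datasets(sims, r, conditions, grids,
                                           seed = seed + r)
    menu <- fit_dominance_models(datasets, n_starts = n_starts,
                                 seed = seed * 100 + r)
    test <- menu$tests[menu$tests$null == "constant", ]
    rel_hat <- fitted_relationship(menu$fits$hs)
    rows[[r]] <- tibble::tibble(
      replicate = r,
      lambda_hs_const = test$lambda,
      p_value = test$p_value,
      h_at_ref = h_of_s(rel_hat, s_ref),
      theta_intercept = rel_hat$theta_intercept,
      theta_rate = rel_hat$theta_rate,
      shape = unname(menu$fits$hs$params["shape"]),
      mean_s = unname(menu$fits$hs$params["mean_s"])
    )
  }
  do.call(rbind, rows)
}
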