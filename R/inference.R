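#' Poisson log-likelihood of an observed spectrum
#'
#' `sum_i [X_i log E_i - E_i - log X_i!]` over unmasked entries (the
#' union of both spectra's masks).  A zero expectation with a positive
#' observation makes the model impossible; a large negative sentinel
#' (`-1e18`) is returned with attribute `degenerate = TRUE` so
#' optimizers can recover.
#'
#' @param observed,expected `site_spectrum` objects with identical
#'   length and folding.
#' @return The log-likelihood (numeric scalar).
#' @export
poisson_ll <- function(observed, expected) {
  assert_spectrum(observed, "observed")
  assert_spectrum(expected, "expected")
  if (length(observed$counts) != length(expected$counts) ||
      observed$folded != expected$folded) {
    stop("observed and expected spectra must have the same length and folding",
         call. = FALSE)
  }
  keep <- !(observed$mask | expected$mask)
  x <- observed$counts[keep]
  e <- expected$counts[keep]
  poisson_ll_terms(x, e)
}

poisson_ll_terms <- function(x, e) {
  bad <- e <= 0 & x > 0
  if (any(bad)) {
    out <- -1e18
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  pos <- e > 0
  sum(x[pos] * log(e[pos]) - e[pos] - lgamma(x[pos] + 1))
}

#' Assemble an inference dataset
#'
#' Bundles one population's folded synonymous and nonsynonymous spectra
#' with its mating system and mutation-rate context.  [prepare_dataset()]
#' then fits the demography and attaches the `(gamma, h)` grid.
#'
#' @param label Dataset label.
#' @param syn,nonsyn Folded `site_spectrum` objects.
#' @param F Inbreeding coefficient (0 = outcrossing; 1 = full selfing,
#'   which switches the dataset to the scaled-additive `s_e = 2 s`
#'   engine with `h` fixed at 0.5).
#' @param mu Neutral per-base mutation rate.
#' @param L_syn Synonymous sequence length (bp).
#' @param demography_family Family fitted to the synonymous SFS.
#' @param theta_multiplier `L_NS / L_S` ratio fixing
#'   `theta_nonsyn = multiplier * theta_syn` (default 2.31).
#' @return An `inference_dataset`.
#' @export
inference_dataset <- function(label, syn, nonsyn, F = 0, mu = 7e-9,
                              L_syn, demography_family = "three_epoch",
                              theta_multiplier = 2.31) {
  assert_spectrum(syn, "syn"); assert_spectrum(nonsyn, "nonsyn")
  if (!syn$folded || !nonsyn$folded) {
    stop("inference operates on folded spectra", call. = FALSE)
  }
  if (syn$sample_size != nonsyn$sample_size) {
    stop("synonymous and nonsynonymous spectra must share a sample size",
         call. = FALSE)
  }
  structure(list(label = label, syn = syn, nonsyn = nonsyn, F = F,
                 mu = mu, L_syn = L_syn,
                 demography_family = demography_family,
                 theta_multiplier = theta_multiplier),
            class = "inference_dataset")
}

#' Prepare a dataset for likelihood evaluation
#'
#' Fits the demographic model to the synonymous SFS, derives
#' `theta_syn`, the ancestral `N_e` and `theta_nonsyn`, and builds (or
#' accepts) the expected-SFS lookup grid.  For a fully selfing dataset
#' (`F = 1`) the grid is one-dimensional and additive, spanning
#' `gamma_e = 2 N_e s` down to `-2 N_e` (the `s_e = 2 s` reduction at
#' the drift-matched effective size); otherwise it is the full 2D
#' `(gamma, h)` grid.
#'
#' @param dataset An [inference_dataset()].
#' @param grid Optional pre-built `sfs_grid` (reused, e.g., across
#'   bootstrap replicates under a constant demography).
#' @param demog_n_starts,seed Options for [fit_demography()].
#' @param coarse_gamma,coarse_h,fine_gamma,fine_h Grid resolutions.
#' @param n_grid,dt Diffusion solver resolution.
#' @return A `prepared_dataset`.
#' @export
prepare_dataset <- function(dataset, grid = NULL, demog_n_starts = 10,
                            seed = 1, coarse_gamma = 50, coarse_h = 20,
                            fine_gamma = 400, fine_h = 500,
                            n_grid = 600, dt = 2e-3) {
  stopifnot(inherits(dataset, "inference_dataset"))
  demog <- fit_demography(dataset$syn, family = dataset$demography_family,
                          n_starts = demog_n_starts, seed = seed,
                          n_grid = n_grid, dt = dt)
  N_e <- ancestral_ne(demog$theta_syn, dataset$mu, dataset$L_syn)
  selfing <- dataset$F >= 1
  if (is.null(grid)) {
    grid <- build_inference_grid(
      demog$model, n = dataset$syn$sample_size, N_e = N_e,
      selfing = selfing, coarse_gamma = coarse_gamma,
      coarse_h = coarse_h, fine_gamma = fine_gamma, fine_h = fine_h,
      n_grid = n_grid, dt = dt)
  }
  if (!grid$folded) grid <- fold_grid(grid)
  if (dim(grid$spectra)[3] != length(dataset$nonsyn$counts)) {
    stop("grid sample size does not match the nonsynonymous spectrum",
         call. = FALSE)
  }
  structure(
    list(label = dataset$label, dataset = dataset, demography = demog,
         theta_syn = demog$theta_syn,
         theta_nonsyn = theta_nonsyn_from_syn(demog$theta_syn,
                                              dataset$theta_multiplier),
         N_e = N_e, F = dataset$F, selfing = selfing, grid = grid,
         prep_opts = list(demog_n_starts = demog_n_starts, seed = seed,
                          coarse_gamma = coarse_gamma,
                          coarse_h = coarse_h, fine_gamma = fine_gamma,
                          fine_h = fine_h, n_grid = n_grid, dt = dt)),
    class = "prepared_dataset")
}

#' Build the lookup grid appropriate for a dataset
#'
#' @inheritParams prepare_dataset
#' @param demography Fitted [demographic_model()].
#' @param n Sample size.
#' @param N_e Ancestral effective size.
#' @param selfing Build the 1D additive (selfing) grid?
#' @return A refined, unfolded `sfs_grid`.
#' @export
build_inference_grid <- function(demography, n, N_e, selfing = FALSE,
                                 coarse_gamma = 50, coarse_h = 20,
                                 fine_gamma = 400, fine_h = 500,
                                 n_grid = 600, dt = 2e-3) {
  if (selfing) {
    coarse <- build_coarse_grid(demography, n = n, N_e = N_e, F = 0,
                                gamma_points = coarse_gamma, h_points = 1,
                                gamma_range = c(-2 * N_e, -1e-4),
                                h_range = c(0.5, 0.5),
                                n_grid = n_grid, dt = dt)
    refine_grid(coarse, gamma_points = fine_gamma, h_points = 1)
  } else {
    coarse <- build_coarse_grid(demography, n = n, N_e = N_e, F = 0,
                                gamma_points = coarse_gamma,
                                h_points = coarse_h,
                                n_grid = n_grid, dt = dt)
    refine_grid(coarse, gamma_points = fine_gamma, h_points = fine_h)
  }
}

#' Specify a dominance/DFE model over one or two datasets
#'
#' @param datasets List of one (outcrossing only) or two (outcrossing +
#'   selfing) `prepared_dataset` objects.
#' @param dominance_form `"additive"`, `"constant"`, `"inverse"` or
#'   `"logistic"`.
#' @param shared_dfe One DFE for all datasets (`TRUE`, default) or one
#'   per dataset.
#' @param constrain_intercept Optional fixed `theta_intercept` (e.g.
#'   0.5, forcing almost-neutral mutations to additivity).
#' @param p_neutral_free Add a free neutral point mass to the DFE?
#' @return A `model_spec`.
#' @export
model_spec <- function(datasets, dominance_form = "inverse",
                       shared_dfe = TRUE, constrain_intercept = NULL,
                       p_neutral_free = FALSE) {
  if (inherits(datasets, "prepared_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, TRUE, "prepared_dataset")))
  dominance_form <- match.arg(dominance_form,
                              c("additive", "constant", "inverse",
                                "logistic"))
  dfe_blocks <- if (shared_dfe) "shared" else {
    vapply(datasets, `[[`, "", "label")
  }
  free <- character(0)
  for (b in dfe_blocks) {
    suff <- if (identical(b, "shared")) "" else paste0("_", b)
    free <- c(free, paste0("shape", suff), paste0("mean_s", suff))
  }
  if (p_neutral_free) free <- c(free, "p_neutral")
  dom_free <- switch(dominance_form,
    additive = character(0),
    constant = "h_const",
    inverse = c("theta_intercept", "theta_rate"),
    logistic = c("theta_intercept", "theta_rate", "theta_offset"))
  if (!is.null(constrain_intercept)) {
    dom_free <- setdiff(dom_free, "theta_intercept")
  }
  free <- c(free, dom_free)
  compiled <- lapply(datasets, function(d) {
    list(ctx = dfe_integration_context(d$grid),
         x = d$dataset$nonsyn$counts,
         mask = d$dataset$nonsyn$mask,
         theta_nonsyn = d$theta_nonsyn,
         N_e = d$N_e, selfing = d$selfing, label = d$label)
  })
  structure(list(datasets = datasets, dominance_form = dominance_form,
                 shared_dfe = shared_dfe,
                 constrain_intercept = constrain_intercept,
                 p_neutral_free = p_neutral_free, free_params = free,
                 compiled = compiled),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> %s dominance, %d dataset(s), %s DFE%s, %d free parameter(s)\n",
    x$dominance_form, length(x$datasets),
    if (x$shared_dfe) "shared" else "per-dataset",
    if (!is.null(x$constrain_intercept)) {
      sprintf(", theta_intercept fixed at %g", x$constrain_intercept)
    } else "",
    length(x$free_params)))
  invisible(x)
}

# Relationship implied by a parameter vector under a spec.
spec_relationship <- function(spec, params) {
  ti <- if (!is.null(spec$constrain_intercept)) {
    spec$constrain_intercept
  } else params[["theta_intercept"]]
  switch(spec$dominance_form,
    additive = hs_relationship("additive"),
    constant = hs_relationship("constant", h_const = params[["h_const"]]),
    inverse = hs_relationship("inverse", theta_intercept = ti,
                              theta_rate = params[["theta_rate"]]),
    logistic = hs_relationship("logistic", theta_intercept = ti,
                               theta_rate = params[["theta_rate"]],
                               theta_offset = params[["theta_offset"]]))
}

spec_dfe <- function(spec, params, label) {
  suff <- if (spec$shared_dfe) "" else paste0("_", label)
  shape <- params[[paste0("shape", suff)]]
  m <- params[[paste0("mean_s", suff)]]
  pn <- if (spec$p_neutral_free) params[["p_neutral"]] else 0
  gamma_dfe(shape = shape, scale = m / shape, p_neutral = pn)
}

#' Composite log-likelihood of a parameter vector
#'
#' Sums the per-dataset Poisson log-likelihoods of the nonsynonymous
#' spectra.  Outcrossing datasets integrate the 2D `(gamma, h)` grid
#' with `h = f(s)`; fully selfing datasets integrate the 1D additive
#' grid with the DFE scale pre-multiplied by 2 (`s_e = 2 s`) and `h`
#' fixed at 0.5.
#'
#' @param spec A [model_spec()].
#' @param params Named numeric vector (or list) of the spec's free
#'   parameters.
#' @return The composite log-likelihood.
#' @export
composite_ll <- function(spec, params) {
  stopifnot(inherits(spec, "model_spec"))
  params <- as.list(params)
  missing <- setdiff(spec$free_params, names(params))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rel <- spec_relationship(spec, params)
  ll <- 0
  for (cd in spec$compiled) {
    dfe <- spec_dfe(spec, params, cd$label)
    if (cd$selfing) {
      dfe_eff <- gamma_dfe(dfe$shape, dfe$scale * 2, dfe$p_neutral)
      e <- integrate_dfe(cd$ctx, dfe_eff, hs_relationship("additive"),
                         cd$N_e, cd$theta_nonsyn)
    } else {
      e <- integrate_dfe(cd$ctx, dfe, rel, cd$N_e, cd$theta_nonsyn)
    }
    keep <- !cd$mask
    term <- poisson_ll_terms(cd$x[keep], e[keep])
    ll <- ll + term
    if (isTRUE(attr(term, "degenerate"))) {
      attr(ll, "degenerate") <- TRUE
      return(ll)
    }
  }
  ll
}

# Parameter transforms: optimization runs on an unconstrained-ish scale
# with box clamping + quadratic penalty.
param_transform_table <- function(free) {
  tab <- list(
    shape = list(lo = log(0.01), hi = log(5), to = log, from = exp),
    mean_s = list(lo = log(1e-6), hi = log(0.2), to = log, from = exp),
    h_const = list(lo = 0, hi = 1, to = identity, from = identity),
    theta_intercept = list(lo = 1e-4, hi = 1, to = identity,
                           from = identity),
    theta_rate = list(lo = 0, hi = log1p(1e7), to = log1p, from = expm1),
    theta_offset = list(lo = -50, hi = 50, to = identity,
                        from = identity),
    p_neutral = list(lo = 0, hi = 0.999, to = identity, from = identity)
  )
  base <- ifelse(startsWith(free, "shape"), "shape",
                 ifelse(startsWith(free, "mean_s"), "mean_s", free))
  lapply(seq_along(free), function(i) c(tab[[base[i]]], name = free[i]))
}

#' Fit a dominance/DFE model by multi-start maximum likelihood
#'
#' Maximizes [composite_ll()] by Nelder-Mead from `n_starts` random
#' starting points (uniform on the transformed parameter box), plus any
#' warm starts supplied.  Bounds: shape in `[0.01, 5]`, mean `|s|` in
#' `[1e-6, 0.2]`, `theta_intercept` in `(0, 1]`, `theta_rate` in
#' `[0, 1e7]`, `h_const` in `[0, 1]`.  Reproducible given `seed`.
#'
#' @param spec A [model_spec()].
#' @param n_starts Number of random starts.
#' @param seed Integer seed.
#' @param warm_starts List of named parameter vectors used as additional
#'   deterministic starts (e.g. the optimum of a nested null model).
#' @param maxit Nelder-Mead iteration cap per start.
#' @return A `dominance_fit` with parameter estimates, the maximized
#'   log-likelihood and a per-start trace.
#' @export
fit_dominance_model <- function(spec, n_starts = 50, seed = 1,
                                warm_starts = list(), maxit = 600) {
  stopifnot(inherits(spec, "model_spec"))
  free <- spec$free_params
  tt <- param_transform_table(free)
  lo <- vapply(tt, `[[`, 0, "lo")
  hi <- vapply(tt, `[[`, 0, "hi")
  untransform <- function(t) {
    p <- numeric(length(t))
    for (i in seq_along(t)) p[i] <- tt[[i]]$from(t[i])
    stats::setNames(p, free)
  }
  transform <- function(p) {
    vapply(seq_along(free),
           function(i) tt[[i]]$to(as.numeric(p[[free[i]]])), numeric(1))
  }
  objective <- function(t) {
    tc <- pmin(pmax(t, lo), hi)
    pen <- 1e4 * sum((t - tc)^2)
    ll <- composite_ll(spec, untransform(tc))
    -as.numeric(ll) + pen
  }
  starts <- with_preserved_seed(seed, {
    lapply(seq_len(n_starts), function(i) stats::runif(length(free), lo, hi))
  })
  for (ws in warm_starts) {
    if (all(free %in% names(ws))) {
      starts <- c(starts, list(pmin(pmax(transform(ws), lo), hi)))
    }
  }
  if (length(free) == 0L) {
    stop("model has no free parameters", call. = FALSE)
  }
  best <- NULL
  trace <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    opt <- tryCatch(
      stats::optim(starts[[i]], objective, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) {
      trace[[i]] <- tibble::tibble(start = i, loglik = NA_real_,
                                   converged = FALSE)
      next
    }
    trace[[i]] <- tibble::tibble(start = i, loglik = -opt$value,
                                 converged = opt$convergence == 0)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    stop("no optimization start converged; incumbents: ",
         paste(vapply(trace, function(t) format(t$loglik), ""),
               collapse = ", "), call. = FALSE)
  }
  params <- untransform(pmin(pmax(best$par, lo), hi))
  structure(
    list(params = params, loglik = -best$value,
         dominance_form = spec$dominance_form, spec = spec,
         n_free = length(free), trace = do.call(rbind, trace),
         n_starts = length(starts), seed = seed,
         converged = best$convergence == 0),
    class = "dominance_fit")
}

#' @export
print.dominance_fit <- function(x, ...) {
  cat(sprintf("<dominance_fit> %s model, logLik = %.3f, %d free parameter(s)\n",
              x$dominance_form, x$loglik, x$n_free))
  print(signif(x$params, 5))
  invisible(x)
}

#' @export
tidy.dominance_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unname(x$params))
}

#' @export
glance.dominance_fit <- function(x, ...) {
  tibble::tibble(form = x$dominance_form, logLik = x$loglik,
                 n_params = x$n_free, n_starts = x$n_starts,
                 converged = x$converged)
}

#' Fitted h-s relationship of a dominance fit
#'
#' @param fit A `dominance_fit`.
#' @return An [hs_relationship()] at the fitted parameters.
#' @export
fitted_relationship <- function(fit) {
  stopifnot(inherits(fit, "dominance_fit"))
  spec_relationship(fit$spec, as.list(fit$params))
}

#' @export
autoplot.dominance_fit <- function(object, s_range = c(1e-5, 0.1), ...) {
  plot_hs_relationship(fitted_relationship(object), s_range = s_range)
}

# Is `null_form` nested in `alt_form`?
forms_nested <- function(null_form, alt_form) {
  nests <- list(additive = c("constant", "inverse", "logistic"),
                constant = c("inverse", "logistic"),
                inverse = character(0), logistic = character(0))
  alt_form %in% nests[[null_form]]
}

#' Likelihood-ratio test between nested dominance models
#'
#' `Lambda = 2 (LL_alt - LL_null)`, compared to a chi-square
#' distribution with degrees of freedom equal to the difference in free
#' parameter counts (additive vs constant: 1; additive vs h-s: 2;
#' constant vs h-s: 1).
#'
#' @param null,alt `dominance_fit` objects for the nested pair.
#' @return An `lrt_result` with `lambda`, `df` and `p_value`.
#' @export
lrt <- function(null, alt) {
  stopifnot(inherits(null, "dominance_fit"), inherits(alt, "dominance_fit"))
  if (!forms_nested(null$dominance_form, alt$dominance_form)) {
    stop(sprintf("'%s' is not nested in '%s'", null$dominance_form,
                 alt$dominance_form), call. = FALSE)
  }
  df <- alt$n_free - null$n_free
  if (df < 1L) stop("alternative model has no extra parameters",
                    call. = FALSE)
  lambda <- 2 * (alt$loglik - null$loglik)
  if (lambda < -1e-6) {
    warning(sprintf(
      "alternative fit is worse than the null (Lambda = %.3g); flooring at 0 -- increase n_starts",
      lambda))
  }
  lambda <- max(lambda, 0)
  structure(list(lambda = lambda, df = df,
                 p_value = stats::pchisq(lambda, df, lower.tail = FALSE),
                 null_form = null$dominance_form,
                 alt_form = alt$dominance_form),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt> %s vs %s: Lambda = %.4g, df = %d, p = %.4g\n",
              x$alt_form, x$null_form, x$lambda, x$df, x$p_value))
  invisible(x)
}

#' @export
tidy.lrt_result <- function(x, ...) {
  tibble::tibble(null = x$null_form, alternative = x$alt_form,
                 lambda = x$lambda, df = x$df, p_value = x$p_value)
}

#' Fit the full menu of dominance models with warm-started nesting
#'
#' Fits the additive, constant-`h` and h-s relationship models (sharing
#' the spec's datasets and DFE structure), warm-starting each richer
#' model from the optimum of the models it nests so the log-likelihood
#' ordering `LL(h-s) >= LL(constant) >= LL(additive)` holds up to
#' optimizer tolerance, and computes the three likelihood-ratio tests.
#'
#' @param datasets List of `prepared_dataset` objects.
#' @param hs_form `"inverse"` (default) or `"logistic"` for the richest
#'   model.
#' @param n_starts,seed,maxit Passed to [fit_dominance_model()].
#' @param shared_dfe,constrain_intercept,p_neutral_free Passed to
#'   [model_spec()].
#' @return A `dominance_model_menu`: list with `fits` (named list of
#'   `dominance_fit`), `tests` (tibble of the three LRTs).
#' @export
fit_dominance_models <- function(datasets, hs_form = "inverse",
                                 n_starts = 50, seed = 1, maxit = 600,
                                 shared_dfe = TRUE,
                                 constrain_intercept = NULL,
                                 p_neutral_free = FALSE) {
  mk <- function(form) {
    model_spec(datasets, dominance_form = form, shared_dfe = shared_dfe,
               constrain_intercept = constrain_intercept,
               p_neutral_free = p_neutral_free)
  }
  fit_add <- fit_dominance_model(mk("additive"), n_starts = n_starts,
                                 seed = seed, maxit = maxit)
  ws_const <- list(c(fit_add$params, h_const = 0.5))
  fit_const <- fit_dominance_model(mk("constant"), n_starts = n_starts,
                                   seed = seed + 1, maxit = maxit,
                                   warm_starts = ws_const)
  ws_hs <- list(
    c(fit_add$params, theta_intercept = 0.5, theta_rate = 0,
      theta_offset = 0),
    c(fit_const$params[setdiff(names(fit_const$params), "h_const")],
      theta_intercept = max(min(unname(fit_const$params["h_const"]), 1),
                            1e-3),
      theta_rate = 0, theta_offset = 0)
  )
  fit_hs <- fit_dominance_model(mk(hs_form), n_starts = n_starts,
                                seed = seed + 2, maxit = maxit,
                                warm_starts = ws_hs)
  tests <- rbind(
    tidy.lrt_result(lrt(fit_add, fit_const)),
    tidy.lrt_result(lrt(fit_add, fit_hs)),
    tidy.lrt_result(lrt(fit_const, fit_hs))
  )
  structure(list(fits = list(additive = fit_add, constant = fit_const,
                             hs = fit_hs),
                 tests = tests),
            class = "dominance_model_menu")
}

#' @export
print.dominance_model_menu <- function(x, ...) {
  cat("<dominance_model_menu>\n")
  for (nm in names(x$fits)) {
    cat(sprintf("  %-9s logLik = %.3f\n", nm, x$fits[[nm]]$loglik))
  }
  print(x$tests)
  invisible(x)
}

#' Bootstrap uncertainty of a fitted model
#'
#' Poisson-resamples every dataset's synonymous and nonsynonymous SFS,
#' re-estimates the demographic and selection parameters for each
#' resampling, and summarizes the `B` bootstrap estimates as standard
#' errors and normal-approximation 95% confidence intervals
#' (`mean +- 1.96 SE`; with `B = 20` percentile intervals would be
#' unstable).  Grids are rebuilt per replicate when the demography
#' family is non-constant (a constant demography leaves the unit-`theta`
#' grid unchanged).
#'
#' @param fit A `dominance_fit` (defines the model and the original
#'   datasets).
#' @param B Number of bootstrap replicates (default 20).
#' @param seed Integer seed.
#' @param n_starts Optimizer starts per replicate (each replicate is
#'   also warm-started at the original estimates).
#' @return A tibble with `term`, `estimate`, `se`, `ci_lo`, `ci_hi`;
#'   the per-replicate estimates are attached as attribute
#'   `"replicates"` and the number of failed replicates as
#'   `"failures"` (flagged with a warning if more than 20% fail).
#' @export
bootstrap_fit <- function(fit, B = 20, seed = 1, n_starts = 5) {
  stopifnot(inherits(fit, "dominance_fit"))
  spec <- fit$spec
  reps <- vector("list", B)
  failures <- 0L
  for (b in seq_len(B)) {
    res <- tryCatch({
      new_ds <- lapply(spec$datasets, function(pd) {
        d <- pd$dataset
        d$syn <- poisson_resample(d$syn, seed = seed * 1000L + b)
        d$nonsyn <- poisson_resample(d$nonsyn, seed = seed * 1000L + b + 500L)
        reuse <- if (d$demography_family == "constant") pd$grid else NULL
        po <- pd$prep_opts
        prepare_dataset(d, grid = reuse,
                        demog_n_starts = po$demog_n_starts,
                        seed = seed + b, coarse_gamma = po$coarse_gamma,
                        coarse_h = po$coarse_h,
                        fine_gamma = po$fine_gamma, fine_h = po$fine_h,
                        n_grid = po$n_grid, dt = po$dt)
      })
      bspec <- model_spec(new_ds, dominance_form = spec$dominance_form,
                          shared_dfe = spec$shared_dfe,
                          constrain_intercept = spec$constrain_intercept,
                          p_neutral_free = spec$p_neutral_free)
      bfit <- fit_dominance_model(bspec, n_starts = n_starts,
                                  seed = seed + b,
                                  warm_starts = list(fit$params))
      bfit$params
    }, error = function(e) NULL)
    if (is.null(res)) failures <- failures + 1L else reps[[b]] <- res
  }
  reps <- reps[!vapply(reps, is.null, TRUE)]
  if (length(reps) < 2L) {
    stop("bootstrap failed: fewer than two successful replicates",
         call. = FALSE)
  }
  if (failures > 0.2 * B) {
    warning(sprintf("%d of %d bootstrap replicates failed", failures, B))
  }
  mat <- do.call(rbind, reps)
  se <- apply(mat, 2, stats::sd)
  out <- tibble::tibble(
    term = names(fit$params),
    estimate = unname(fit$params),
    se = unname(se),
    ci_lo = unname(colMeans(mat) - 1.96 * se),
    ci_hi = unname(colMeans(mat) + 1.96 * se)
  )
  attr(out, "replicates") <- tibble::as_tibble(as.data.frame(mat))
  attr(out, "failures") <- failures
  out
}

#' Z-test for a parameter difference between two gene categories
#'
#' `Z = (a - b) / sqrt(se_a^2 + se_b^2)` (the category estimates are
#' treated as independent, appropriate for disjoint gene sets), with a
#' two-sided normal p-value and a Bonferroni-corrected p-value for
#' `n_tests` comparisons.
#'
#' @param est_a,se_a,est_b,se_b Estimates and standard errors.
#' @param n_tests Number of tests in the family (Bonferroni factor).
#' @return A list with `z`, `p_raw`, `p_bonferroni`.
#' @export
z_compare <- function(est_a, se_a, est_b, se_b, n_tests = 1) {
  if (se_a <= 0 || se_b <= 0) {
    stop("standard errors must be positive", call. = FALSE)
  }
  z <- (est_a - est_b) / sqrt(se_a^2 + se_b^2)
  p <- 2 * stats::pnorm(-abs(z))
  list(z = z, p_raw = p, p_bonferroni = min(1, p * n_tests))
}
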