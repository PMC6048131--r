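#' Fit a demographic model to a synonymous spectrum
#'
#' Maximum-Poisson-likelihood fit of a piecewise-constant size history
#' (constant, two-epoch or three-epoch) to a neutral (synonymous) SFS.
#' The mutation-rate scale is profiled out analytically: for any shape
#' parameters the optimal `theta_syn` is the ratio of observed to
#' unit-`theta` expected totals over unmasked entries.  Shape parameters
#' are optimized by multi-start Nelder-Mead on log scale within
#' `nu` in `[1e-3, 1e3]` and epoch durations in `[1e-4, 5]` (units of
#' `2 N_anc` generations).
#'
#' @param syn_spectrum Observed synonymous `site_spectrum` (folded or
#'   unfolded).
#' @param family `"constant"`, `"two_epoch"` or `"three_epoch"`.
#' @param n_starts Number of random starts (non-constant families).
#' @param seed Integer seed for the random starts.
#' @param n_grid,dt Solver resolution (see [expected_sfs()]).
#' @return An object of class `demography_fit`: the fitted
#'   [demographic_model()], `theta_syn`, the maximized log-likelihood,
#'   a per-start trace and a convergence flag.
#' @export
fit_demography <- function(syn_spectrum,
                           family = c("constant", "two_epoch",
                                      "three_epoch"),
                           n_starts = 50, seed = 1,
                           n_grid = 600, dt = 2e-3) {
  assert_spectrum(syn_spectrum, "syn_spectrum")
  family <- match.arg(family)
  if (sum(syn_spectrum$counts[!syn_spectrum$mask]) <= 0) {
    stop("synonymous spectrum is empty", call. = FALSE)
  }
  n <- syn_spectrum$sample_size

  eval_model <- function(model) {
    e_unit <- expected_sfs(model, gamma = 0, h = 0.5, F = 0, n = n,
                           theta = 1, N_anc = 1e5, n_grid = n_grid,
                           dt = dt)
    if (syn_spectrum$folded) e_unit <- fold_spectrum(e_unit)
    keep <- !syn_spectrum$mask
    theta_hat <- sum(syn_spectrum$counts[keep]) / sum(e_unit$counts[keep])
    scaled <- site_spectrum(theta_hat * e_unit$counts, n,
                            folded = syn_spectrum$folded,
                            mask = syn_spectrum$mask)
    list(theta = theta_hat,
         ll = as.numeric(poisson_ll(syn_spectrum, scaled)))
  }

  lb <- c(nu = log(1e-3), T = log(1e-4))
  ub <- c(nu = log(1e3), T = log(5))
  n_par <- switch(family, constant = 0L, two_epoch = 2L, three_epoch = 4L)
  par_is_nu <- rep(c(TRUE, FALSE), length.out = n_par)

  make_model <- function(p) {
    p <- exp(p)
    switch(family,
      constant = demographic_model(),
      two_epoch = demographic_model(c(1, p[1]), c(Inf, p[2])),
      three_epoch = demographic_model(c(1, p[1], p[3]),
                                      c(Inf, p[2], p[4]))
    )
  }

  if (family == "constant") {
    res <- eval_model(demographic_model())
    return(structure(
      list(model = demographic_model(), theta_syn = res$theta,
           loglik = res$ll, family = family, converged = TRUE,
           trace = tibble::tibble(start = 1L, loglik = res$ll),
           seed = seed),
      class = "demography_fit"))
  }

  lo <- ifelse(par_is_nu, lb["nu"], lb["T"])
  hi <- ifelse(par_is_nu, ub["nu"], ub["T"])
  objective <- function(p) {
    pc <- pmin(pmax(p, lo), hi)
    pen <- 1e4 * sum((p - pc)^2)
    r <- tryCatch(eval_model(make_model(pc)), error = function(e) NULL)
    if (is.null(r) || !is.finite(r$ll)) return(1e18)
    -r$ll + pen
  }

  starts <- with_preserved_seed(seed, {
    lapply(seq_len(n_starts), function(i) stats::runif(n_par, lo, hi))
  })
  starts <- c(list(rep(0, n_par)), starts)   # the constant-size point
  trace <- vector("list", length(starts))
  best <- NULL
  for (i in seq_along(starts)) {
    opt <- tryCatch(
      stats::optim(starts[[i]], objective, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL
    )
    if (is.null(opt)) {
      trace[[i]] <- tibble::tibble(start = i, loglik = NA_real_)
      next
    }
    trace[[i]] <- tibble::tibble(start = i, loglik = -opt$value)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e17) {
    stop("demographic optimization failed to converge from any start; ",
         "best incumbent objective: ",
         if (is.null(best)) "none" else -best$value, call. = FALSE)
  }
  p_hat <- pmin(pmax(best$par, lo), hi)
  model <- make_model(p_hat)
  res <- eval_model(model)
  structure(
    list(model = model, theta_syn = res$theta, loglik = res$ll,
         family = family, converged = best$convergence == 0,
         trace = do.call(rbind, trace), seed = seed),
    class = "demography_fit")
}

#' @export
print.demography_fit <- function(x, ...) {
  cat(sprintf("<demography_fit> family = %s, logLik = %.3f, theta_syn = %.6g\n",
              x$family, x$loglik, x$theta_syn))
  print(x$model)
  invisible(x)
}

#' @export
glance.demography_fit <- function(x, ...) {
  tibble::tibble(family = x$family, logLik = x$loglik,
                 theta_syn = x$theta_syn, converged = x$converged)
}

#' Serialize a demographic fit to a YAML-compatible list / file
#'
#' @param fit A `demography_fit`.
#' @param path Optional path; if given, written as YAML.
#' @return The list representation, invisibly if written to file.
#' @export
demography_fit_config <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "demography_fit"))
  out <- list(family = fit$family, nu = fit$model$nu,
              duration = fit$model$duration, theta_syn = fit$theta_syn,
              loglik = fit$loglik, converged = fit$converged,
              seed = fit$seed)
  if (!is.null(path)) {
    yaml::write_yaml(out, path)
    return(invisible(out))
  }
  out
}
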