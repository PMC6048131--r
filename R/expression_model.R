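#' Expression-cost model of dominance
#'
#' A mechanistic model in which fitness is a diminishing-returns function
#' of gene expression level minus a linear expression cost:
#' `f(x) = (x + intercept * scale) * (1 - c * x) / (x + scale)`.
#' The `intercept` is the fitness of a gene expressed at zero level (a
#' value near 1 marks a non-essential gene), `scale` is the expression
#' level at which the costless fitness gain is half-maximal (the amount
#' of protein the organism needs), and `c` is the fitness cost per unit
#' of expression.  Loss-of-function selection and dominance coefficients
#' follow from evaluating fitness at optimal, half, and zero expression.
#'
#' @param c_cost Cost of expression per unit level, `>= 0`.
#' @param intercept Fitness at zero expression, in `[0, 1]`.
#' @param scale Expression level of half-maximal fitness gain, `> 0`.
#' @return An object of class `gene_expression_model`.
#' @export
#' @examples
#' m <- gene_expression_model(c_cost = 0.001, intercept = 0.95, scale = 0.1)
#' optimal_expression(m)
#' loss_of_function_sh(m)
gene_expression_model <- function(c_cost = 0.001, intercept = 0.95,
                                  scale = 0.1) {
  if (!is.numeric(c_cost) || c_cost < 0) {
    stop("`c_cost` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(intercept) || intercept < 0 || intercept > 1) {
    stop("`intercept` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(scale) || scale <= 0) {
    stop("`scale` must be > 0", call. = FALSE)
  }
  # Fitness must stay positive over the expression range the model probes
  # (up to the optimum); c * x >= 1 puts the gene outside the model domain.
  m <- structure(list(c_cost = c_cost, intercept = intercept, scale = scale),
                 class = "gene_expression_model")
  if (intercept < 1 && c_cost > 0) {
    xo <- optimal_expression_raw(m)
    if (is.finite(xo) && xo > 0 && c_cost * xo >= 1) {
      stop("expression cost drives fitness below zero before the optimum; ",
           "model parameters are outside the admissible domain",
           call. = FALSE)
    }
  }
  m
}

#' @export
print.gene_expression_model <- function(x, ...) {
  cat(sprintf("<gene_expression_model> c = %g, intercept = %g, scale = %g\n",
              x$c_cost, x$intercept, x$scale))
  invisible(x)
}

#' Fitness at a given expression level
#'
#' @param model A `gene_expression_model`.
#' @param x Expression level(s), `>= 0` (arbitrary units).
#' @return Fitness value(s).
#' @export
expression_fitness <- function(model, x) {
  stopifnot(inherits(model, "gene_expression_model"))
  if (any(x < 0)) stop("expression level `x` must be >= 0", call. = FALSE)
  (x + model$intercept * model$scale) * (1 - model$c_cost * x) /
    (x + model$scale)
}

# Closed-form optimum; may be non-positive when no interior optimum exists.
optimal_expression_raw <- function(model) {
  cc <- model$c_cost
  sc <- model$scale
  it <- model$intercept
  if (cc == 0) return(Inf)  # without cost, fitness increases monotonically
  sqrt(sc * cc * (1 - it) * (1 + sc * cc)) / cc - sc
}

#' Optimal expression level
#'
#' The positive root of `df/dx = 0`:
#' `x_opt = sqrt(scale * c * (1 - intercept) * (1 + scale * c)) / c - scale`.
#' A positive optimum requires `intercept < 1` (an essential enough gene)
#' and a non-degenerate cost.
#'
#' @param model A `gene_expression_model`.
#' @return The optimal expression level `x_opt`.
#' @export
optimal_expression <- function(model) {
  stopifnot(inherits(model, "gene_expression_model"))
  if (model$intercept >= 1) {
    stop("no positive optimum: with intercept >= 1 fitness is maximal at ",
         "zero expression", call. = FALSE)
  }
  if (model$c_cost == 0) {
    stop("no finite optimum: with zero expression cost fitness increases ",
         "monotonically", call. = FALSE)
  }
  xo <- optimal_expression_raw(model)
  if (!is.finite(xo) || xo <= 0) {
    stop("no positive optimum for these parameters", call. = FALSE)
  }
  xo
}

#' Selection and dominance coefficient of a loss-of-function mutation
#'
#' Assuming the gene is expressed at `expression_fraction * x_opt`, a
#' heterozygous loss-of-function mutation halves expression and a
#' homozygous one abolishes it.  With `x* = expression_fraction * x_opt`:
#' `|s| = (f(x*) - f(0)) / f(x*)` and
#' `h = (f(x*) - f(x*/2)) / (f(x*) - f(0))`.
#' The returned `s` is reported as non-positive (deleterious), matching
#' the sign convention of the SFS inference machinery.
#'
#' @param model A `gene_expression_model`.
#' @param expression_fraction Fraction of the optimal expression level at
#'   which the wild type is expressed, in `(0, 1]`.
#' @return A named list with elements `s` (<= 0) and `h`.
#' @export
loss_of_function_sh <- function(model, expression_fraction = 1.0) {
  stopifnot(inherits(model, "gene_expression_model"))
  if (length(expression_fraction) != 1 || !is.finite(expression_fraction) ||
      expression_fraction <= 0 || expression_fraction > 1) {
    stop("`expression_fraction` must lie in (0, 1]", call. = FALSE)
  }
  xs <- expression_fraction * optimal_expression(model)
  f_wt <- expression_fitness(model, xs)
  f_het <- expression_fitness(model, xs / 2)
  f_mut <- expression_fitness(model, 0)
  s_mag <- (f_wt - f_mut) / f_wt
  h <- if (f_wt > f_mut) (f_wt - f_het) / (f_wt - f_mut) else NA_real_
  list(s = -s_mag, h = h)
}

#' Simulate an ensemble of genes under the expression-cost model
#'
#' Draws `n_genes` genes with random `intercept` and `scale` parameters,
#' computes each gene's optimal expression and the implied `(s, h)` of a
#' loss-of-function mutation.  Genes with no positive expression optimum
#' (effectively neutral knockouts) are recorded with `s = 0` and `h = NA`
#' and should be excluded from dominance summaries.
#'
#' @param n_genes Number of genes (default 5000).
#' @param c_cost Shared expression cost (default 0.001).
#' @param intercept_range Range of the uniform intercept distribution
#'   (default `c(0.9, 1)`, i.e. mostly nearly neutral knockouts).
#' @param scale_mean,scale_sd Mean and SD of the normal distribution whose
#'   absolute value is the scale parameter (default both 0.1).
#' @param expression_fraction Wild-type expression as a fraction of the
#'   optimum (1 = optimal expression, 0.8 = chronically suboptimal).
#' @param seed Integer seed for reproducibility (optional).
#' @return A tibble with one row per gene: `gene`, `c_cost`, `intercept`,
#'   `scale`, `x_opt`, `s`, `h`.
#' @export
simulate_gene_ensemble <- function(n_genes = 5000, c_cost = 0.001,
                                   intercept_range = c(0.9, 1),
                                   scale_mean = 0.1, scale_sd = 0.1,
                                   expression_fraction = 1.0,
                                   seed = NULL) {
  run <- function() {
    intercept <- stats::runif(n_genes, intercept_range[1], intercept_range[2])
    scale <- abs(stats::rnorm(n_genes, scale_mean, scale_sd))
    scale[scale == 0] <- .Machine$double.eps
    list(intercept = intercept, scale = scale)
  }
  draws <- if (is.null(seed)) run() else with_preserved_seed(seed, run())
  x_opt <- s <- h <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    m <- gene_expression_model(c_cost, draws$intercept[g], draws$scale[g])
    xo <- optimal_expression_raw(m)
    if (!is.finite(xo) || xo <= 0) {
      x_opt[g] <- 0; s[g] <- 0; h[g] <- NA_real_
    } else {
      x_opt[g] <- xo
      sh <- loss_of_function_sh(m, expression_fraction)
      s[g] <- sh$s
      h[g] <- sh$h
    }
  }
  tibble::tibble(
    gene = seq_len(n_genes),
    c_cost = c_cost,
    intercept = draws$intercept,
    scale = draws$scale,
    x_opt = x_opt,
    s = s,
    h = h
  )
}

#' Plot an (s, h) gene ensemble
#'
#' @param ensemble A tibble from [simulate_gene_ensemble()].
#' @return A ggplot of `h` against `|s|` (log x axis).
#' @export
plot_sh_ensemble <- function(ensemble) {
  df <- ensemble[ensemble$s < 0 & is.finite(ensemble$h), ]
  ggplot2::ggplot(df, ggplot2::aes(x = abs(.data$s), y = .data$h)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "darkorange3") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "|s| (loss of function)", y = "dominance h") +
    ggplot2::theme_minimal()
}
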