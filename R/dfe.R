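#' Gamma distribution of fitness effects
#'
#' The DFE of new nonsynonymous mutations: `s = -g` with
#' `g ~ Gamma(shape, scale)` (scale in units of the per-generation
#' selection coefficient), plus an optional point mass of strictly
#' neutral mutations.
#'
#' @param shape Gamma shape parameter, `> 0`.
#' @param scale Gamma scale parameter (units of `|s|`), `> 0`.
#' @param p_neutral Proportion of neutral mutations, in `[0, 1]`.
#' @return An object of class `gamma_dfe`.
#' @export
#' @examples
#' gamma_dfe(shape = 0.3, scale = 0.001 / 0.3)  # mean |s| = 0.001
gamma_dfe <- function(shape, scale, p_neutral = 0) {
  if (!is.numeric(shape) || shape <= 0 || !is.numeric(scale) || scale <= 0) {
    stop("`shape` and `scale` must be positive", call. = FALSE)
  }
  if (p_neutral < 0 || p_neutral > 1) {
    stop("`p_neutral` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(shape = shape, scale = scale, p_neutral = p_neutral),
            class = "gamma_dfe")
}

#' @export
print.gamma_dfe <- function(x, ...) {
  cat(sprintf(
    "<gamma_dfe> shape = %g, scale = %g (mean |s| = %g)%s\n",
    x$shape, x$scale, x$shape * x$scale,
    if (x$p_neutral > 0) sprintf(", p_neutral = %g", x$p_neutral) else ""
  ))
  invisible(x)
}

#' Mean selection coefficient of a DFE
#'
#' @param dfe A `gamma_dfe`.
#' @return `E[|s|]` of the deleterious component.
#' @export
mean_s <- function(dfe) {
  stopifnot(inherits(dfe, "gamma_dfe"))
  dfe$shape * dfe$scale
}

#' Dominance-selection relationship models
#'
#' Parametric functions `h = f(s)` linking the dominance coefficient of a
#' mutation to its selection coefficient:
#' * `additive`: `h = 0.5`, no free parameters;
#' * `constant`: `h = h_const`, one parameter;
#' * `inverse`: `h = 1 / (1 / theta_intercept - theta_rate * s)`, two
#'   parameters -- `theta_intercept` is `h` at `s = 0` and `theta_rate`
#'   controls how fast `h` decays to zero as mutations become more
#'   deleterious;
#' * `logistic`: `h = theta_intercept * (1 + exp(-theta_offset)) /
#'   (1 + exp(theta_rate * |s| - theta_offset))`, three parameters.
#'
#' All forms are monotone non-increasing in `|s|`.
#'
#' @param form One of `"additive"`, `"constant"`, `"inverse"`,
#'   `"logistic"`.
#' @param theta_intercept Value of `h` at `s = 0`, in `(0, 1]`.
#' @param theta_rate Decay rate, `>= 0` (inverse and logistic forms).
#' @param theta_offset Offset of the logistic form.
#' @param h_const Constant dominance (constant form), in `[0, 1]`.
#' @return An object of class `hs_relationship`.
#' @export
#' @examples
#' rel <- hs_relationship("inverse", theta_intercept = 0.5,
#'                        theta_rate = 1e4)
#' h_of_s(rel, -0.001)  # 1 / (2 + 10) = 0.0833...
hs_relationship <- function(form = c("additive", "constant", "inverse",
                                     "logistic"),
                            theta_intercept = 0.5, theta_rate = 0,
                            theta_offset = 0, h_const = 0.5) {
  form <- match.arg(form)
  if (theta_rate < 0) stop("`theta_rate` must be >= 0", call. = FALSE)
  if (form %in% c("inverse", "logistic") &&
      (theta_intercept <= 0 || theta_intercept > 1)) {
    stop("`theta_intercept` must lie in (0, 1]", call. = FALSE)
  }
  if (form == "constant" && (h_const < 0 || h_const > 1)) {
    stop("`h_const` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(form = form, theta_intercept = theta_intercept,
                 theta_rate = theta_rate, theta_offset = theta_offset,
                 h_const = h_const),
            class = "hs_relationship")
}

#' @export
print.hs_relationship <- function(x, ...) {
  desc <- switch(x$form,
    additive = "h = 0.5",
    constant = sprintf("h = %g", x$h_const),
    inverse = sprintf("h = 1/(1/%g - %g s)", x$theta_intercept,
                      x$theta_rate),
    logistic = sprintf("h = %g (1+e^-%g)/(1+e^(%g|s| - %g))",
                       x$theta_intercept, x$theta_offset, x$theta_rate,
                       x$theta_offset))
  cat(sprintf("<hs_relationship> %s: %s\n", x$form, desc))
  invisible(x)
}

# Number of free dominance parameters per functional form.
hs_n_params <- function(form) {
  switch(form, additive = 0L, constant = 1L, inverse = 2L, logistic = 3L)
}

#' Evaluate the dominance coefficient at given selection coefficients
#'
#' @param rel An [hs_relationship()].
#' @param s Selection coefficient(s), `<= 0`.
#' @return Dominance coefficient(s) in `[0, 1]`.
#' @export
h_of_s <- function(rel, s) {
  stopifnot(inherits(rel, "hs_relationship"))
  if (any(s > 0)) stop("`s` must be <= 0 (deleterious or neutral)",
                       call. = FALSE)
  switch(rel$form,
    additive = rep(0.5, length(s)),
    constant = rep(rel$h_const, length(s)),
    inverse = 1 / (1 / rel$theta_intercept - rel$theta_rate * s),
    logistic = rel$theta_intercept * (1 + exp(-rel$theta_offset)) /
      (1 + exp(rel$theta_rate * abs(s) - rel$theta_offset))
  )
}

#' Nonsynonymous mutation rate from the synonymous one
#'
#' Scales `theta_syn` by the ratio of nonsynonymous to synonymous
#' sequence length (default multiplier 2.31).
#'
#' @param theta_syn Synonymous population mutation rate, `> 0`.
#' @param multiplier Length ratio `L_NS / L_S`.
#' @return `theta_nonsyn = multiplier * theta_syn`.
#' @export
theta_nonsyn_from_syn <- function(theta_syn, multiplier = 2.31) {
  if (any(theta_syn <= 0)) stop("`theta_syn` must be > 0", call. = FALSE)
  multiplier * theta_syn
}

#' Expected nonsynonymous SFS under a DFE and h-s relationship
#'
#' Integrates the grid of per-`(gamma, h)` expected spectra against the
#' gamma DFE along the scaled-selection axis (trapezoid rule on the
#' grid's exponential nodes), evaluating `h = f(s)` at each node and
#' taking the nearest grid `h`.  DFE mass more negative than the grid's
#' lethal boundary is assigned to the boundary cell; mass in the
#' effectively-neutral window `|gamma| < 1e-4`, plus any neutral point
#' mass, is assigned to the analytic neutral spectrum.  The result is
#' linear in `theta_nonsyn`.
#'
#' @param grid An `sfs_grid` (see [build_coarse_grid()]).
#' @param dfe A [gamma_dfe()] in units of `s`.
#' @param rel An [hs_relationship()].
#' @param N_e Ancestral effective size used to scale `s` to
#'   `gamma = N_e * s`.  For a fully selfing dataset pass the
#'   drift-matched `N_e` and a DFE whose scale has been pre-multiplied
#'   by 2 (the `s_e = 2 s` reduction), with `rel = additive`.
#' @param theta_nonsyn Nonsynonymous population mutation rate.
#' @return A `site_spectrum` of expected counts (same folding as the
#'   grid's spectra).
#' @export
expected_nonsyn_sfs <- function(grid, dfe, rel, N_e, theta_nonsyn) {
  stopifnot(inherits(grid, "sfs_grid"), inherits(dfe, "gamma_dfe"),
            inherits(rel, "hs_relationship"))
  ctx <- dfe_integration_context(grid)
  counts <- integrate_dfe(ctx, dfe, rel, N_e, theta_nonsyn)
  site_spectrum(counts, grid$provenance$n, folded = grid$folded,
                label = "expected nonsynonymous")
}

# Precomputed pieces reused across many likelihood evaluations on the
# same grid: |gamma| nodes, trapezoid weights, gathered spectra matrix.
dfe_integration_context <- function(grid) {
  g <- abs(grid$gamma_axis)               # decreasing with index? ensure
  ord <- order(g)                         # ascending |gamma|
  Gg <- length(g)
  Gh <- length(grid$h_axis)
  nent <- dim(grid$spectra)[3]
  smat <- matrix(grid$spectra, nrow = Gg * Gh, ncol = nent)
  g_sorted <- g[ord]
  tw <- numeric(Gg)
  dg <- diff(g_sorted)
  tw[1] <- dg[1] / 2
  tw[Gg] <- dg[Gg - 1] / 2
  if (Gg > 2) tw[2:(Gg - 1)] <- (dg[-1] + dg[-(Gg - 1)]) / 2
  list(
    g = g_sorted, ord = ord, tw = tw, Gg = Gg, Gh = Gh,
    h_axis = grid$h_axis, smat = smat, neutral = grid$neutral,
    g_max = max(g_sorted), g_min = min(g_sorted), n_entries = nent
  )
}

# Trapezoid integration of the grid spectra against the DFE.
integrate_dfe <- function(ctx, dfe, rel, N_e, theta_nonsyn) {
  scale_g <- dfe$scale * N_e              # DFE in units of gamma
  dens <- stats::dgamma(ctx$g, shape = dfe$shape, scale = scale_g)
  w <- dens * ctx$tw
  s_nodes <- -ctx$g / N_e
  h_nodes <- h_of_s(rel, s_nodes)
  hidx <- nearest_h_index(ctx$h_axis, h_nodes)
  rows <- ctx$ord + (hidx - 1L) * ctx$Gg
  body <- as.numeric(w %*% ctx$smat[rows, , drop = FALSE])
  mass_lethal <- stats::pgamma(ctx$g_max, dfe$shape, scale = scale_g,
                               lower.tail = FALSE)
  mass_neutral <- stats::pgamma(ctx$g_min, dfe$shape, scale = scale_g)
  h_lethal <- h_of_s(rel, -ctx$g_max / N_e)
  lethal_row <- ctx$ord[ctx$Gg] + (nearest_h_index(ctx$h_axis, h_lethal) - 1L) * ctx$Gg
  lethal <- ctx$smat[lethal_row, ]
  pn <- dfe$p_neutral
  counts <- (1 - pn) * (body + mass_lethal * lethal +
                          mass_neutral * ctx$neutral) +
    pn * ctx$neutral
  theta_nonsyn * counts
}

# Nearest node on a sorted (possibly non-uniform) axis.
nearest_axis_index <- function(axis, x) {
  if (length(axis) == 1L) return(rep(1L, length(x)))
  lo <- findInterval(x, axis, all.inside = TRUE)
  hi <- lo + 1L
  ifelse(x - axis[lo] <= axis[hi] - x, lo, hi)
}

nearest_h_index <- function(h_axis, h) nearest_axis_index(h_axis, h)

#' Plot an h-s relationship
#'
#' @param rel An [hs_relationship()].
#' @param s_range Range of `|s|` to draw (log axis), default
#'   `c(1e-5, 0.1)`.
#' @return A ggplot object.
#' @export
plot_hs_relationship <- function(rel, s_range = c(1e-5, 0.1)) {
  s <- -exp(seq(log(s_range[1]), log(s_range[2]), length.out = 200))
  df <- tibble::tibble(abs_s = abs(s), h = h_of_s(rel, s))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_s, y = .data$h)) +
    ggplot2::geom_line(colour = "steelblue4", linewidth = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "|s|", y = "dominance h") +
    ggplot2::theme_minimal()
}
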