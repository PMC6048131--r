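#' Piecewise-constant demographic models
#'
#' A demographic history of one to three epochs.  The first epoch is the
#' ancestral population (relative size `nu[1]`, unbounded duration); later
#' epochs have relative size `nu[k]` (a multiple of the ancestral
#' effective size) and duration `duration[k]` in units of `2 * N_anc`
#' generations, ordered from past to present.
#'
#' @param nu Positive numeric vector of relative sizes (length 1 to 3).
#' @param duration Durations; the ancestral entry must be `Inf`.
#' @return An object of class `demographic_model`.
#' @export
#' @examples
#' demographic_model()                                  # constant size
#' demographic_model(c(1, 0.1, 2), c(Inf, 0.05, 0.2))   # bottleneck-growth
demographic_model <- function(nu = 1, duration = Inf) {
  nu <- as.numeric(nu)
  duration <- as.numeric(duration)
  if (length(nu) < 1L || length(nu) > 3L || length(duration) != length(nu)) {
    stop("need 1 to 3 epochs with matching `nu` and `duration`",
         call. = FALSE)
  }
  if (any(!is.finite(nu)) || any(nu <= 0)) {
    stop("all relative sizes `nu` must be positive and finite",
         call. = FALSE)
  }
  if (!is.infinite(duration[1])) {
    stop("the ancestral epoch must have unbounded duration (Inf)",
         call. = FALSE)
  }
  if (length(nu) > 1L &&
      (any(!is.finite(duration[-1])) || any(duration[-1] <= 0))) {
    stop("non-ancestral epoch durations must be positive and finite",
         call. = FALSE)
  }
  structure(list(nu = nu, duration = duration, n_epochs = length(nu)),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat(sprintf("<demographic_model> %d epoch(s)\n", x$n_epochs))
  for (k in seq_len(x$n_epochs)) {
    cat(sprintf("  epoch %d: nu = %g, duration = %g\n",
                k, x$nu[k], x$duration[k]))
  }
  invisible(x)
}

#' Mean and variance of the per-generation allele-frequency change
#'
#' Under selection `s` with dominance `h` and inbreeding coefficient `F`,
#' the diffusion drift and variance terms at frequency `p` are
#' `M(p) = s p (1-p) {(1-F)[h + (1-2h) p] + F}` and
#' `V(p) = p (1-p) (1+F) / (2N)`.
#' For `F = 1` both become independent of `h`: `M = s p (1-p)` (twice the
#' additive outcrossing term) and `V = p (1-p) / N` (twice the drift).
#'
#' @param p Allele frequency (vectorized), strictly inside `(0, 1)`.
#' @param s Selection coefficient (homozygote fitness `1 + s`).
#' @param h Dominance coefficient (heterozygote fitness `1 + h s`).
#' @param F Inbreeding coefficient in `[0, 1]`.
#' @param N Population size (diploid individuals).
#' @return A list with numeric vectors `M` and `V`.
#' @export
drift_selection_terms <- function(p, s, h = 0.5, F = 0, N = 1000) {
  if (any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (F < 0 || F > 1) stop("`F` must lie in [0, 1]", call. = FALSE)
  pq <- p * (1 - p)
  list(
    M = s * pq * ((1 - F) * (h + (1 - 2 * h) * p) + F),
    V = pq * (1 + F) / (2 * N)
  )
}

#' Effective parameters of a fully selfing population
#'
#' With inbreeding coefficient `F = 1` the diffusion becomes independent
#' of `h` and reduces to a scaled additive model: the effective selection
#' coefficient is `s_e = 2 s` (twice the mean frequency change) with
#' `h_e = 0.5`, evaluated at the drift-matched effective population size.
#'
#' @param s Selection coefficient(s).
#' @param h Dominance coefficient (ignored; the reduction removes it).
#' @return A list with `s_e = 2 * s` and `h_e = 0.5`.
#' @export
selfing_effective_params <- function(s, h = 0.5) {
  list(s_e = 2 * s, h_e = 0.5)
}

# ---------------------------------------------------------------------------
# Finite-volume PRF solver internals
# ---------------------------------------------------------------------------

# Frequency grid: logarithmic below `split` (resolving rare deleterious
# alleles), uniform above.  Cell centers strictly inside (0, 1).
make_q_grid <- function(q_min, n_points = 800, split = 0.08) {
  n_log <- ceiling(0.55 * n_points)
  n_lin <- n_points - n_log
  q_log <- exp(seq(log(q_min), log(split), length.out = n_log + 1L))[-(n_log + 1L)]
  q_lin <- seq(split, 1 - q_min, length.out = n_lin)
  unique(c(q_log, q_lin))
}

# Bernoulli function B(x) = x / (e^x - 1) of the Scharfetter-Gummel flux,
# evaluated stably for small and large |x|.
bernoulli_fn <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-8
  out[small] <- 1 - x[small] / 2
  out[!small] <- x[!small] / expm1(x[!small])   # x / Inf -> 0 for large x
  out
}

# Tridiagonal generator of the forward diffusion on the grid for one epoch.
# gamma = N_anc * s; time in units of 2 * N_anc generations.
fv_operator <- function(q, gamma, h, F, nu) {
  G <- length(q)
  faces <- c(q[1] / 2, (q[-G] + q[-1]) / 2, (q[G] + 1) / 2)
  dist <- c(q[1], diff(q), 1 - q[G])          # f = 0 beyond both boundaries
  w <- diff(c(q[1] / 2, (q[-G] + q[-1]) / 2, (q[G] + 1) / 2))
  # w has length G: cell widths between consecutive face positions, with
  # half-cells at the ends.
  dom <- (1 - F) * (h + (1 - 2 * h) * faces) + F
  a <- 2 * gamma * faces * (1 - faces) * dom
  b <- faces * (1 - faces) * (1 + F) / nu
  bp <- (1 - 2 * faces) * (1 + F) / nu
  atil <- a - bp / 2
  Dd <- pmax(b / 2, 1e-300)
  P <- atil * dist / Dd
  c1 <- (Dd / dist) * bernoulli_fn(-P)        # weight of the left cell
  c2 <- (Dd / dist) * bernoulli_fn(P)         # weight of the right cell
  # Row j of L: (c1[j] f_{j-1} - (c2[j] + c1[j+1]) f_j + c2[j+1] f_{j+1})/w_j
  sub <- c(0, c1[2:G]) / w
  diagv <- -(c2[1:G] + c1[2:(G + 1)]) / w
  super <- c(c2[2:G], 0) / w
  list(sub = sub, diag = diagv, super = super, w = w)
}

# Tridiagonal matrix-vector product L f.
tridiag_mv <- function(op, f) {
  G <- length(f)
  op$diag * f + op$sub * c(0, f[-G]) + op$super * c(f[-1], 0)
}

# Distributed source equivalent to the mutational influx: chosen so that
# the epoch's analytic stationary density is exactly stationary under
# the discrete operator (src = -L f_eq), eliminating first-order
# injection-cell error.  In the continuum this equals a point influx of
# nu * theta * N_anc mutations per unit time at frequency
# 1 / (2 nu N_anc).
fv_source <- function(q, op, gamma, h, F, nu, theta) {
  f_eq <- prf_equilibrium_density(q, gamma, h = h, F = F, nu = nu,
                                  theta = theta)
  list(src = -tridiag_mv(op, f_eq), f_eq = f_eq)
}

#' Expected SFS under the Poisson random field diffusion
#'
#' Solves the 1D forward diffusion of allele frequencies with steady
#' mutational influx under arbitrary (non-positive) scaled selection
#' `gamma = N_anc * s`, dominance `h`, inbreeding `F` and a
#' piecewise-constant demography, by a Scharfetter-Gummel finite-volume
#' discretization.  The ancestral epoch is solved as the stationary state
#' of the discrete operator; later epochs are integrated with backward
#' Euler.  Sampling `n` allele copies binomially yields the expected
#' unfolded spectrum, which is linear in `theta`.
#'
#' @param demography A [demographic_model()].
#' @param gamma Scaled selection coefficient `N_anc * s`, `<= 0`.
#' @param h Dominance coefficient in `[0, 1]`.
#' @param F Inbreeding coefficient in `[0, 1]`.
#' @param n Sample size (allele copies), `>= 2`.
#' @param theta Population mutation rate `4 N_anc mu L` of the site class.
#' @param N_anc Ancestral population size; sets the injection frequency
#'   `1 / (2 nu N_anc)`.  The dynamics depend on selection only through
#'   `gamma`.
#' @param n_grid Number of frequency grid points.
#' @param dt Time step (units of `2 N_anc` generations) for non-ancestral
#'   epochs.
#' @return An unfolded `site_spectrum` of expected counts.
#' @export
expected_sfs <- function(demography = demographic_model(), gamma = 0,
                         h = 0.5, F = 0, n, theta = 1, N_anc = 1e5,
                         n_grid = 800, dt = 1e-3) {
  stopifnot(inherits(demography, "demographic_model"))
  if (gamma > 0) stop("`gamma` must be <= 0 (deleterious or neutral)",
                      call. = FALSE)
  if (h < 0 || h > 1) stop("`h` must lie in [0, 1]", call. = FALSE)
  if (F < 0 || F > 1) stop("`F` must lie in [0, 1]", call. = FALSE)
  n <- as.integer(n)
  if (n < 2L) stop("`n` must be >= 2", call. = FALSE)

  q_min <- min(1e-6, 1 / (2 * N_anc * min(demography$nu)))
  q <- make_q_grid(q_min, n_grid)
  f <- fv_density(demography, gamma, h, F, theta, N_anc, q, dt)
  if (any(!is.finite(f))) {
    stop("diffusion solve failed: non-finite density (gamma = ", gamma,
         ", h = ", h, ", F = ", F, ")", call. = FALSE)
  }
  f[f < 0] <- 0
  op <- fv_operator(q, gamma, h, F, demography$nu[demography$n_epochs])
  counts <- sample_expected_sfs(f, q, op$w, n)
  site_spectrum(counts, n, folded = FALSE,
                label = sprintf("prf gamma=%.4g h=%.3g F=%.2g", gamma, h, F))
}

# Density of segregating mutations per unit frequency at the end of the
# final epoch.
fv_density <- function(demography, gamma, h, F, theta, N_anc, q, dt) {
  f <- prf_equilibrium_density(q, gamma, h = h, F = F,
                               nu = demography$nu[1], theta = theta)
  if (demography$n_epochs > 1L) {
    for (k in 2:demography$n_epochs) {
      op <- fv_operator(q, gamma, h, F, demography$nu[k])
      src <- fv_source(q, op, gamma, h, F, demography$nu[k], theta)$src
      T_k <- demography$duration[k]
      nsteps <- max(10L, ceiling(T_k / dt))
      f <- .tridiag_be_steps(f, op$sub, op$diag, op$super, src,
                             T_k / nsteps, nsteps)
    }
  }
  f
}

# Binomial sampling of the population density into sample classes 1..n-1.
sample_expected_sfs <- function(f, q, w, n) {
  mass <- f * w
  i <- seq_len(n - 1L)
  vapply(i, function(ii) sum(mass * stats::dbinom(ii, n, q)), numeric(1))
}

# Analytic stationary density of the PRF diffusion at constant size
# (internal cross-check of the discrete solver).
prf_equilibrium_density <- function(q, gamma, h = 0.5, F = 0, nu = 1,
                                    theta = 1) {
  Gfun <- function(y) (1 - F) * (h * y + (1 - 2 * h) * y^2 / 2) + F * y
  lpsi <- -(4 * gamma * nu / (1 + F)) * Gfun(q)
  A <- max(lpsi, 0)
  u <- exp(lpsi - A)
  # right-to-left cumulative trapezoid of psi / e^A
  du <- diff(q) * (u[-1] + u[-length(u)]) / 2
  Iq <- rev(c(0, cumsum(rev(du))))
  I0 <- Iq[1] + q[1] * (exp(-A) + u[1]) / 2    # extend down to 0, psi(0) = 1
  theta * nu / (1 + F) / (q * (1 - q)) * (Iq / I0) * exp(-lpsi)
}

#' Ancestral effective population size from the synonymous mutation rate
#'
#' `N_e = theta_syn / (4 mu L_syn)`.
#'
#' @param theta_syn Fitted synonymous population mutation rate.
#' @param mu Per-base per-generation neutral mutation rate.
#' @param L_syn Synonymous sequence length (bp).
#' @return The ancestral effective population size.
#' @export
ancestral_ne <- function(theta_syn, mu, L_syn) {
  if (any(c(theta_syn, mu, L_syn) <= 0)) {
    stop("`theta_syn`, `mu` and `L_syn` must all be positive",
         call. = FALSE)
  }
  theta_syn / (4 * mu * L_syn)
}
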