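#' Build a coarse (gamma, h) lookup grid of expected spectra
#'
#' Computes the expected unfolded SFS at unit `theta` for every node of a
#' 2D lattice of scaled selection coefficients `gamma = N_e * s`
#' (exponentially spaced from `-N_e`, lethal, to `-1e-4`, effectively
#' neutral) and dominance coefficients `h` (linearly spaced on `[0, 1]`),
#' under a fixed demography, inbreeding level and sample size.  Cells
#' where the solver fails are marked invalid and counted; the build
#' continues.
#'
#' @param demography A [demographic_model()].
#' @param n Sample size (allele copies).
#' @param N_e Ancestral effective population size (sets the lethal
#'   boundary `gamma = -N_e` and the injection frequency).
#' @param F Inbreeding coefficient.
#' @param gamma_points,h_points Lattice resolution (default 50 x 20).
#' @param gamma_range Axis bounds as negative values, default
#'   `c(-N_e, -1e-4)`.
#' @param h_range Dominance bounds, default `c(0, 1)`.  With
#'   `h_points = 1` a single-`h` (1D) grid is built, as used for the
#'   additive engine of a fully selfing population.
#' @param n_grid,dt Solver resolution passed to [expected_sfs()].
#' @return An object of class `sfs_grid` holding the axes, a 3D spectra
#'   array `(gamma, h, frequency)`, the analytic neutral spectrum and
#'   provenance.
#' @export
build_coarse_grid <- function(demography, n, N_e, F = 0,
                              gamma_points = 50, h_points = 20,
                              gamma_range = c(-N_e, -1e-4),
                              h_range = c(0, 1),
                              n_grid = 800, dt = 1e-3) {
  stopifnot(inherits(demography, "demographic_model"))
  if (any(gamma_range >= 0) || gamma_range[1] >= gamma_range[2]) {
    stop("`gamma_range` must be negative and increasing", call. = FALSE)
  }
  gamma_axis <- -exp(seq(log(abs(gamma_range[1])), log(abs(gamma_range[2])),
                         length.out = gamma_points))
  gamma_axis <- sort(gamma_axis)          # from most negative to near 0
  h_axis <- if (h_points == 1L) mean(h_range) else {
    seq(h_range[1], h_range[2], length.out = h_points)
  }
  n <- as.integer(n)
  spectra <- array(NA_real_, dim = c(gamma_points, h_points, n - 1L))
  failures <- 0L
  for (jh in seq_along(h_axis)) {
    for (ig in seq_along(gamma_axis)) {
      sp <- tryCatch(
        expected_sfs(demography, gamma = gamma_axis[ig], h = h_axis[jh],
                     F = F, n = n, theta = 1, N_anc = N_e,
                     n_grid = n_grid, dt = dt),
        error = function(e) NULL
      )
      if (is.null(sp)) failures <- failures + 1L else {
        spectra[ig, jh, ] <- sp$counts
      }
    }
  }
  if (failures > 0L) {
    warning(sprintf("%d of %d grid cells failed to solve and are invalid",
                    failures, gamma_points * h_points))
  }
  neutral <- expected_sfs(demography, gamma = 0, h = 0.5, F = F, n = n,
                          theta = 1, N_anc = N_e, n_grid = n_grid,
                          dt = dt)$counts
  structure(
    list(gamma_axis = gamma_axis, h_axis = h_axis, spectra = spectra,
         neutral = neutral, folded = FALSE, resolution = "coarse",
         clamped = 0L, failures = failures,
         provenance = list(demography = demography, n = n, N_e = N_e,
                           F = F, n_grid = n_grid, dt = dt)),
    class = "sfs_grid"
  )
}

#' @export
print.sfs_grid <- function(x, ...) {
  cat(sprintf(
    "<sfs_grid> %s, %d x %d (gamma x h), n = %d (%s), gamma in [%.4g, %.4g], F = %g\n",
    x$resolution, length(x$gamma_axis), length(x$h_axis),
    x$provenance$n, if (x$folded) "folded" else "unfolded",
    min(x$gamma_axis), max(x$gamma_axis), x$provenance$F
  ))
  if (x$failures > 0L) cat(sprintf("  %d invalid cells\n", x$failures))
  if (x$clamped > 0L) {
    cat(sprintf("  %d interpolated values clamped to 0\n", x$clamped))
  }
  invisible(x)
}

#' Refine a coarse grid by two-pass cubic-spline interpolation
#'
#' Each frequency entry is interpolated separately: first along the
#' `gamma` axis (on a log-|gamma| coordinate, matching the axis's
#' exponential spacing) at every coarse `h`, then along the `h` axis at
#' every fine `gamma`.  The fine axes contain the coarse nodes, so
#' coarse-node values are preserved exactly.  Spline undershoot below
#' zero (possible for steep near-lethal cells) is clamped to 0 and
#' counted.
#'
#' @param grid A coarse `sfs_grid` with no invalid cells.
#' @param gamma_points,h_points Target resolution (default 1000 x 1000).
#' @return A refined `sfs_grid` with `resolution = "fine"`.
#' @export
refine_grid <- function(grid, gamma_points = 1000, h_points = 1000) {
  stopifnot(inherits(grid, "sfs_grid"))
  if (anyNA(grid$spectra)) {
    stop("coarse grid contains invalid cells; rebuild before refining",
         call. = FALSE)
  }
  ga <- grid$gamma_axis                     # ascending: -N_e ... -1e-4
  x_coarse <- rev(log(abs(ga)))             # ascending log|gamma|
  lg_fine <- sort(unique(c(
    x_coarse, seq(min(x_coarse), max(x_coarse), length.out = gamma_points)
  )))
  gamma_fine <- sort(-exp(lg_fine))         # ascending gamma again
  h_coarse <- grid$h_axis
  one_h <- length(h_coarse) == 1L
  h_fine <- if (one_h) h_coarse else {
    sort(unique(c(h_coarse, seq(min(h_coarse), max(h_coarse),
                                length.out = h_points))))
  }
  Ggf <- length(lg_fine)
  Ghf <- length(h_fine)
  nent <- dim(grid$spectra)[3]
  fine <- array(NA_real_, dim = c(Ggf, Ghf, nent))
  for (e in seq_len(nent)) {
    # pass 1: along gamma (log-|gamma| coordinate) at each coarse h
    mid <- matrix(NA_real_, Ggf, length(h_coarse))
    for (jh in seq_along(h_coarse)) {
      y <- rev(grid$spectra[, jh, e])       # matched to x_coarse
      mid[, jh] <- rev(stats::spline(x_coarse, y, xout = lg_fine,
                                     method = "fmm")$y)
    }
    if (one_h) {
      fine[, 1, e] <- mid[, 1]
    } else {
      # pass 2: along h at each fine gamma
      for (ig in seq_len(Ggf)) {
        fine[ig, , e] <- stats::spline(h_coarse, mid[ig, ],
                                       xout = h_fine, method = "fmm")$y
      }
    }
  }
  clamped <- sum(fine < 0)
  fine[fine < 0] <- 0
  out <- grid
  out$gamma_axis <- gamma_fine
  out$h_axis <- h_fine
  out$spectra <- fine
  out$resolution <- "fine"
  out$clamped <- as.integer(clamped)
  out
}

#' Look up the expected spectrum nearest to a (gamma, h) pair
#'
#' `gamma` values below the lethal boundary clamp to the boundary;
#' values in `(-1e-4, 0]` (effectively neutral) return the analytic
#' neutral spectrum.  Otherwise the nearest node is selected by index
#' distance on each axis's native spacing (logarithmic in `gamma`,
#' linear in `h`).
#'
#' @param grid An `sfs_grid`.
#' @param gamma Scaled selection coefficient, `<= 0`.
#' @param h Dominance coefficient.
#' @return A `site_spectrum` at unit `theta`.
#' @export
grid_lookup <- function(grid, gamma, h) {
  stopifnot(inherits(grid, "sfs_grid"))
  if (length(grid$gamma_axis) == 0L) {
    stop("empty grid", call. = FALSE)
  }
  n <- grid$provenance$n
  if (gamma > -1e-4) {
    return(site_spectrum(grid$neutral, n, folded = grid$folded,
                         label = "neutral (below cutoff)"))
  }
  g_lo <- min(grid$gamma_axis)
  gamma <- max(gamma, g_lo)
  ig <- nearest_axis_index(log(abs(rev(grid$gamma_axis))),
                           log(abs(gamma)))
  ig <- length(grid$gamma_axis) + 1L - ig   # axis ascending (toward 0)
  jh <- nearest_axis_index(grid$h_axis, h)
  site_spectrum(grid$spectra[ig, jh, ], n, folded = grid$folded,
                label = sprintf("grid node gamma=%.4g h=%.4g",
                                grid$gamma_axis[ig], grid$h_axis[jh]))
}

# Fold the spectra stored in a grid (linear operation on entries).
fold_grid <- function(grid) {
  if (grid$folded) return(grid)
  n <- grid$provenance$n
  k <- n %/% 2L
  fold_one <- function(v) {
    out <- numeric(k)
    for (j in seq_len(k)) {
      out[j] <- if (j < n - j) v[j] + v[n - j] else v[j]
    }
    out
  }
  dims <- dim(grid$spectra)
  folded <- array(NA_real_, dim = c(dims[1], dims[2], k))
  for (jh in seq_len(dims[2])) {
    folded[, jh, ] <- t(apply(grid$spectra[, jh, , drop = FALSE], 1,
                              function(v) fold_one(as.numeric(v))))
  }
  grid$spectra <- folded
  grid$neutral <- fold_one(grid$neutral)
  grid$folded <- TRUE
  grid
}

#' Cache key of a grid's provenance
#'
#' Grids are only valid for the exact demography, sample size,
#' inbreeding level and axes they were built for; the key identifies
#' that context so stale caches are detected.
#'
#' @param grid An `sfs_grid`.
#' @return A short hash string.
#' @export
grid_cache_key <- function(grid) {
  p <- grid$provenance
  rlang::hash(list(p$demography$nu, p$demography$duration, p$n, p$N_e,
                   p$F, range(grid$gamma_axis), length(grid$gamma_axis),
                   range(grid$h_axis), length(grid$h_axis)))
}

#' Persist / restore a grid
#'
#' Round trips are bit-identical.  On load the stored provenance key is
#' recomputed and compared; a mismatch raises an error so silently stale
#' caches cannot be used.
#'
#' @param grid An `sfs_grid`.
#' @param path File path.
#' @return `save_sfs_grid` returns `path` invisibly; `load_sfs_grid`
#'   returns the grid.
#' @export
save_sfs_grid <- function(grid, path) {
  stopifnot(inherits(grid, "sfs_grid"))
  obj <- list(grid = grid, key = grid_cache_key(grid))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_sfs_grid
#' @export
load_sfs_grid <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$key, grid_cache_key(obj$grid))) {
    stop("grid cache is stale: stored key does not match provenance",
         call. = FALSE)
  }
  obj$grid
}
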