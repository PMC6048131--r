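#' Site frequency spectrum objects
#'
#' A `site_spectrum` holds the number of segregating sites (observed counts
#' or model expectations) at each sample allele-frequency class.  Unfolded
#' spectra index derived-allele copies `1..n-1`; folded spectra index
#' minor-allele copies `1..floor(n/2)`.  Entries can be masked, in which
#' case they are excluded from every likelihood computation.
#'
#' @param counts Non-negative numeric vector of per-frequency-class counts.
#' @param sample_size Integer number of sampled allele copies (`n >= 2`).
#' @param folded Logical; is `counts` indexed by minor-allele frequency?
#' @param label Free-text label (species, mutation class).
#' @param mask Logical vector, same length as `counts`; `TRUE` entries are
#'   excluded from likelihoods.  Defaults to all `FALSE`.
#' @return An object of class `site_spectrum`.
#' @export
#' @examples
#' site_spectrum(c(10, 5, 3), sample_size = 4, folded = FALSE)
site_spectrum <- function(counts, sample_size, folded = FALSE, label = "",
                          mask = NULL) {
  n <- as.integer(sample_size)
  if (is.na(n) || n < 2L) {
    stop("`sample_size` must be an integer >= 2", call. = FALSE)
  }
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("spectrum counts must be finite and non-negative", call. = FALSE)
  }
  expected_len <- if (folded) n %/% 2L else n - 1L
  if (length(counts) != expected_len) {
    stop(sprintf(
      "a %s spectrum with n = %d must have %d entries, got %d",
      if (folded) "folded" else "unfolded", n, expected_len, length(counts)
    ), call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(FALSE, expected_len)
  mask <- as.logical(mask)
  if (length(mask) != expected_len || anyNA(mask)) {
    stop("`mask` must be a logical vector matching `counts`", call. = FALSE)
  }
  structure(
    list(counts = counts, sample_size = n, folded = isTRUE(folded),
         label = as.character(label), mask = mask),
    class = "site_spectrum"
  )
}

#' @export
print.site_spectrum <- function(x, ...) {
  cat(sprintf(
    "<site_spectrum> n = %d, %s%s, %d entries (%d masked), total = %.6g\n",
    x$sample_size, if (x$folded) "folded" else "unfolded",
    if (nzchar(x$label)) paste0(", '", x$label, "'") else "",
    length(x$counts), sum(x$mask), sum(x$counts[!x$mask])
  ))
  print(signif(x$counts, 6))
  invisible(x)
}

is_site_spectrum <- function(x) inherits(x, "site_spectrum")

assert_spectrum <- function(x, arg = "spectrum") {
  if (!is_site_spectrum(x)) {
    stop(sprintf("`%s` must be a site_spectrum object", arg), call. = FALSE)
  }
  invisible(x)
}

#' Neutral equilibrium spectrum
#'
#' Expected SFS at mutation-drift equilibrium without selection:
#' `theta / i` per derived-allele class `i`.
#'
#' @param n Sample size (allele copies).
#' @param theta Population mutation rate `4 Ne mu L`.
#' @param folded Fold the spectrum before returning?
#' @return A `site_spectrum` of expected counts.
#' @export
neutral_spectrum <- function(n, theta = 1, folded = FALSE) {
  out <- site_spectrum(theta / seq_len(n - 1L), n, folded = FALSE,
                       label = "neutral")
  if (folded) fold_spectrum(out) else out
}

#' Fold an unfolded spectrum
#'
#' Collapses derived-allele classes `i` and `n - i` into minor-allele
#' classes, as used when the ancestral allele cannot be assigned.  The
#' central class (`n` even) is counted once.  Total count is conserved.
#'
#' @param spectrum An unfolded `site_spectrum`.
#' @return A folded `site_spectrum`.
#' @export
#' @examples
#' fold_spectrum(site_spectrum(c(3, 2, 1), 4))  # -> c(4, 2)
fold_spectrum <- function(spectrum) {
  assert_spectrum(spectrum)
  if (spectrum$folded) {
    stop("spectrum is already folded", call. = FALSE)
  }
  n <- spectrum$sample_size
  k <- n %/% 2L
  counts <- numeric(k)
  mask <- logical(k)
  for (j in seq_len(k)) {
    if (j < n - j) {
      counts[j] <- spectrum$counts[j] + spectrum$counts[n - j]
      mask[j] <- spectrum$mask[j] || spectrum$mask[n - j]
    } else {            # central class when n is even
      counts[j] <- spectrum$counts[j]
      mask[j] <- spectrum$mask[j]
    }
  }
  site_spectrum(counts, n, folded = TRUE, label = spectrum$label, mask = mask)
}

#' Project a spectrum to a smaller sample size
#'
#' Hypergeometric downsampling of the SFS from `n` to `m` allele copies.
#' The projected count in class `j` is
#' `sum_i counts[i] * C(i, j) C(n - i, m - j) / C(n, m)`; the monomorphic
#' classes `j = 0` and `j = m` are dropped, so the expected total never
#' increases.  Folded spectra are projected by splitting each minor-allele
#' class evenly over its two unfolded pre-images, projecting, and
#' re-folding; by the symmetry of the hypergeometric weights this equals
#' projecting the (unknown) unfolded spectrum and folding afterwards.
#'
#' @param spectrum A `site_spectrum`.
#' @param m Target sample size, `2 <= m <= n`.
#' @return A `site_spectrum` with sample size `m`, same folding as input.
#' @export
project_spectrum <- function(spectrum, m) {
  assert_spectrum(spectrum)
  m <- as.integer(m)
  n <- spectrum$sample_size
  if (is.na(m) || m < 2L || m > n) {
    stop(sprintf("`m` must be an integer in [2, %d]", n), call. = FALSE)
  }
  if (any(spectrum$mask)) {
    stop("cannot project a spectrum with masked interior entries",
         call. = FALSE)
  }
  if (m == n) return(spectrum)
  if (spectrum$folded) {
    unf <- unfold_symmetric(spectrum)
    return(fold_spectrum(project_spectrum(unf, m)))
  }
  counts <- vapply(seq_len(m - 1L), function(j) {
    i <- seq_len(n - 1L)
    sum(spectrum$counts * stats::dhyper(j, i, n - i, m))
  }, numeric(1))
  site_spectrum(counts, m, folded = FALSE, label = spectrum$label)
}

# Symmetric unfolded pre-image of a folded spectrum: each minor-allele class
# is split evenly between derived classes j and n - j.
unfold_symmetric <- function(spectrum) {
  n <- spectrum$sample_size
  counts <- numeric(n - 1L)
  for (j in seq_len(n %/% 2L)) {
    if (j < n - j) {
      counts[j] <- counts[j] + spectrum$counts[j] / 2
      counts[n - j] <- counts[n - j] + spectrum$counts[j] / 2
    } else {
      counts[j] <- spectrum$counts[j]
    }
  }
  site_spectrum(counts, n, folded = FALSE, label = spectrum$label)
}

#' Poisson-resample a spectrum
#'
#' Draws each entry independently from a Poisson distribution with mean
#' equal to the input entry, as used for non-parametric bootstrapping of
#' SNP count spectra.  Masked entries are resampled like any other (they
#' stay masked).
#'
#' @param spectrum A `site_spectrum` (counts are the Poisson means).
#' @param seed Integer seed; the draw is reproducible given `seed` and the
#'   caller's RNG state is left untouched.  `NULL` uses (and advances) the
#'   current RNG state.
#' @return A `site_spectrum` of resampled counts.
#' @export
poisson_resample <- function(spectrum, seed = NULL) {
  assert_spectrum(spectrum)
  draw <- function() stats::rpois(length(spectrum$counts), spectrum$counts)
  counts <- if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
  site_spectrum(as.numeric(counts), spectrum$sample_size,
                folded = spectrum$folded, label = spectrum$label,
                mask = spectrum$mask)
}

# Evaluate `expr` under set.seed(seed), restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Build a folded spectrum from per-site minor-allele counts
#'
#' @param minor_allele_counts Integer vector; each element is the
#'   minor-allele count of one segregating site, in `1..floor(n/2)`.
#' @param n Sample size (allele copies).
#' @param label Optional label.
#' @return A folded `site_spectrum` (the histogram of the counts).
#' @export
spectrum_from_counts <- function(minor_allele_counts, n, label = "") {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  k <- n %/% 2L
  mac <- as.integer(minor_allele_counts)
  if (length(mac) > 0 && (anyNA(mac) || any(mac < 1L) || any(mac > k))) {
    stop(sprintf("minor-allele counts must lie in 1..%d for n = %d", k, n),
         call. = FALSE)
  }
  counts <- tabulate(mac, nbins = k)
  site_spectrum(as.numeric(counts), n, folded = TRUE, label = label)
}

#' Read a spectrum from a dadi-style .fs text file
#'
#' The dialect is: a header line `"<n+1> {folded|unfolded} [label]"`, one
#' line of `n+1` whitespace-separated counts (frequency classes `0..n`),
#' and one line of `n+1` mask flags (`1` = masked).  The monomorphic
#' corners, and for folded spectra the upper half, are always masked.
#'
#' @param path Path to the file.
#' @return A `site_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) < 3L) {
    stop(sprintf("'%s': expected header, counts and mask lines", path),
         call. = FALSE)
  }
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  if (length(header) < 2L) {
    stop(sprintf("'%s' line 1: malformed header '%s'", path, lines[1L]),
         call. = FALSE)
  }
  len <- suppressWarnings(as.integer(header[1L]))
  fold_word <- header[2L]
  if (is.na(len) || len < 3L || !fold_word %in% c("folded", "unfolded")) {
    stop(sprintf("'%s' line 1: header must be '<n+1> {folded|unfolded}'",
                 path), call. = FALSE)
  }
  label <- if (length(header) > 2L) {
    gsub('^"|"$', "", paste(header[-(1:2)], collapse = " "))
  } else ""
  n <- len - 1L
  folded <- fold_word == "folded"
  full <- suppressWarnings(as.numeric(strsplit(trimws(lines[2L]), "\\s+")[[1]]))
  if (length(full) != len || anyNA(full)) {
    stop(sprintf("'%s' line 2: expected %d numeric counts, got %d",
                 path, len, length(full)), call. = FALSE)
  }
  mask_full <- suppressWarnings(as.integer(strsplit(trimws(lines[3L]),
                                                   "\\s+")[[1]]))
  if (length(mask_full) != len || anyNA(mask_full)) {
    stop(sprintf("'%s' line 3: expected %d mask flags, got %d",
                 path, len, length(mask_full)), call. = FALSE)
  }
  interior <- if (folded) 1L + seq_len(n %/% 2L) else 1L + seq_len(n - 1L)
  if (folded) {
    upper <- setdiff(seq_len(len), c(1L, interior))
    if (any(full[upper] != 0)) {
      stop(sprintf(
        "'%s' line 2: header says folded but entries above floor(n/2) are non-zero",
        path), call. = FALSE)
    }
  }
  site_spectrum(full[interior], n, folded = folded, label = label,
                mask = mask_full[interior] != 0L)
}

#' Write a spectrum as a dadi-style .fs text file
#'
#' Numerals are written with 12 significant digits so a write/read
#' round trip reproduces the counts to printed precision.
#'
#' @param spectrum A `site_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  assert_spectrum(spectrum)
  n <- spectrum$sample_size
  len <- n + 1L
  full <- numeric(len)
  mask_full <- rep(1L, len)
  interior <- if (spectrum$folded) 1L + seq_len(n %/% 2L) else 1L + seq_len(n - 1L)
  full[interior] <- spectrum$counts
  mask_full[interior] <- as.integer(spectrum$mask)
  header <- sprintf("%d %s%s", len,
                    if (spectrum$folded) "folded" else "unfolded",
                    if (nzchar(spectrum$label)) {
                      paste0(' "', spectrum$label, '"')
                    } else "")
  writeLines(c(header,
               paste(sprintf("%.12g", full), collapse = " "),
               paste(mask_full, collapse = " ")),
             con = path)
  invisible(path)
}

#' Tidy a spectrum into a tibble
#'
#' @param x A `site_spectrum`.
#' @param ... Unused.
#' @return A tibble with columns `frequency`, `count`, `masked`.
#' @export
tidy.site_spectrum <- function(x, ...) {
  tibble::tibble(
    frequency = seq_along(x$counts),
    count = x$counts,
    masked = x$mask
  )
}

#' @export
autoplot.site_spectrum <- function(object, ...) {
  df <- tidy.site_spectrum(object)
  ggplot2::ggplot(df[!df$masked, ],
                  ggplot2::aes(x = .data$frequency, y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = if (object$folded) "minor-allele count" else "derived-allele count",
      y = "segregating sites",
      title = object$label
    ) +
    ggplot2::theme_minimal()
}
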