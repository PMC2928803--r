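#' Adaptive histogram binning with a minimum bin occupancy
#'
#' Histogram-based density estimates trade resolution against sampling noise:
#' bins that are too wide hide features such as bimodality, bins that are too
#' narrow fluctuate wildly. The rule used throughout this package starts from
#' unit-width integer bins spanning the observed range and greedily merges
#' undersized bins until every bin of the reference sample holds at least
#' `min_count` observations (default 10). The sweep is leftmost-first and an
#' undersized bin merges with whichever neighbour currently holds fewer
#' counts (ties merge rightward), which makes the result deterministic and
#' invariant to the input ordering. If the whole sample is smaller than
#' `min_count` a single bin results.
#'
#' Bins are half-open `[e_l, e_{l+1})` with the last bin closed, so integer
#' observations on a shared edge belong to the right bin. Negative counts
#' (possible after measurement noise) are handled like any other integer.
#'
#' @param samples Non-empty integer vector (one timepoint's observations).
#' @param min_count Minimum occupancy per bin (positive integer).
#' @param reference Tag recording which side of the comparison defined the
#'   edges: `"experimental"` or `"simulation"`.
#' @return A `binning_scheme`: edges, bin centers and the occupancy rule.
#' @export
build_bins <- function(samples, min_count = 10L,
                       reference = c("experimental", "simulation")) {
  reference <- match.arg(reference)
  if (length(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  stopifnot(min_count >= 1L)
  samples <- as.integer(samples)

  lo <- min(samples)
  hi <- max(samples)
  counts <- tabulate(samples - lo + 1L, nbins = hi - lo + 1L)
  edges <- as.numeric(lo:(hi + 1L))  # unit bins [v, v+1)

  repeat {
    if (length(counts) == 1L || all(counts >= min_count)) break
    i <- which(counts < min_count)[1L]  # leftmost-first sweep
    merge_right <-
      if (i == 1L) TRUE
      else if (i == length(counts)) FALSE
      else counts[i + 1L] <= counts[i - 1L]  # smaller neighbour; tie -> right
    if (merge_right) {
      counts[i] <- counts[i] + counts[i + 1L]
      counts <- counts[-(i + 1L)]
      edges <- edges[-(i + 1L)]
    } else {
      counts[i - 1L] <- counts[i - 1L] + counts[i]
      counts <- counts[-i]
      edges <- edges[-i]
    }
  }

  structure(
    list(edges = edges, centers = (edges[-length(edges)] + edges[-1L]) / 2,
         min_count = as.integer(min_count), reference = reference),
    class = "binning_scheme"
  )
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat("<binning_scheme> ", length(x$centers), " bins on [",
      x$edges[1L], ", ", x$edges[length(x$edges)], "), min_count ",
      x$min_count, ", reference ", x$reference, "\n", sep = "")
  invisible(x)
}

# Bin index for each observation under the half-open convention; values
# outside the covered range are clamped into the nearest edge bin when
# clamp = TRUE, otherwise marked NA (out of support).
bin_index <- function(scheme, x, clamp = TRUE) {
  L <- length(scheme$centers)
  idx <- findInterval(x, scheme$edges, rightmost.closed = TRUE)
  if (clamp) {
    idx[idx < 1L] <- 1L
    idx[idx > L] <- L
  } else {
    idx[idx < 1L | idx > L] <- NA_integer_
  }
  idx
}

#' Binned probability and cumulative density functions
#'
#' `pdf_from_samples()` classifies a sample into the bins of a
#' [build_bins()] scheme and returns relative frequencies with the binomial
#' finite-sampling variance of each bin frequency,
#' \eqn{s^2_l = P_l (1 - P_l) / N}. Samples outside the covered range are
#' counted into the nearest edge bin (this matters when the scheme comes from
#' the experimental data and the model strays outside it).
#' `cdf_from_pdf()` forms the cumulative sums and attaches the analogous
#' variance \eqn{S^2_l = F_l (1 - F_l) / N}.
#'
#' @param samples Integer vector of observations at one timepoint.
#' @param scheme A `binning_scheme`.
#' @param pdf A `binned_density` of kind `"pdf"`.
#' @return A `binned_density` with fields `kind` (`"pdf"` or `"cdf"`),
#'   `prob`, `var`, `n` (sample size) and `scheme`.
#' @export
pdf_from_samples <- function(samples, scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  if (length(samples) == 0L) stop("samples must be non-empty", call. = FALSE)
  L <- length(scheme$centers)
  idx <- bin_index(scheme, samples, clamp = TRUE)
  n <- length(samples)
  p <- tabulate(idx, nbins = L) / n
  structure(
    list(kind = "pdf", prob = p, var = p * (1 - p) / n, n = n,
         scheme = scheme),
    class = "binned_density"
  )
}

#' @rdname pdf_from_samples
#' @export
cdf_from_pdf <- function(pdf) {
  stopifnot(inherits(pdf, "binned_density"), pdf$kind == "pdf")
  f <- cumsum(pdf$prob)
  f[length(f)] <- 1  # guard against accumulated rounding
  structure(
    list(kind = "cdf", prob = f, var = f * (1 - f) / pdf$n, n = pdf$n,
         scheme = pdf$scheme),
    class = "binned_density"
  )
}

#' @export
print.binned_density <- function(x, ...) {
  cat("<binned_density> ", x$kind, ", ", length(x$prob), " bins, n = ",
      x$n, "\n", sep = "")
  invisible(x)
}

#' Binomial variance of a bin frequency
#'
#' The spread of a histogram bin frequency estimated from `N` independent
#' samples, under the binomial model of bin classification:
#' \eqn{p (1 - p) / N}. The same formula applies to cumulative frequencies.
#'
#' @param p Bin probability (or cumulative probability) in `[0, 1]`.
#' @param n Sample size, `>= 1`.
#' @return The variance, zero exactly when `p` is 0 or 1.
#' @export
binomial_variance <- function(p, n) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  stopifnot(all(n >= 1))
  p * (1 - p) / n
}

#' Order-statistic empirical CDF for sparse data
#'
#' With few replicates a histogram is unreliable; instead each sorted
#' observation \eqn{o_{(l)}} is assigned the plotting position
#' \eqn{F_e = (l - 0.5) / m}. Tied values keep consecutive positions
#' (zero-width steps), so positions are always strictly increasing in
#' (0, 1).
#'
#' @param replicates Integer vector of `m >= 1` observations.
#' @return A `sparse_ecdf` with sorted `values`, `positions` and `m`.
#' @export
sparse_ecdf <- function(replicates) {
  m <- length(replicates)
  stopifnot(m >= 1L)
  structure(
    list(values = sort(as.numeric(replicates)),
         positions = (seq_len(m) - 0.5) / m, m = m),
    class = "sparse_ecdf"
  )
}

#' Likelihood of an observation under a binned model PDF
#'
#' Returns the probability of the bin containing each observation. An
#' observation falling outside the simulated support, or into a bin with zero
#' probability, returns the floor value \eqn{1 / (10 N)} (with `N` the number
#' of simulated realizations behind the PDF) rather than zero, so a
#' log-likelihood stays finite while unexplained observations are still
#' heavily penalised.
#'
#' @param pdf A `binned_density` of kind `"pdf"` built from simulations.
#' @param observation Integer observation(s).
#' @return Probability vector, elementwise `>= 1/(10 N)`.
#' @export
likelihood_lookup <- function(pdf, observation) {
  stopifnot(inherits(pdf, "binned_density"), pdf$kind == "pdf")
  floor_p <- 1 / (10 * pdf$n)
  idx <- bin_index(pdf$scheme, observation, clamp = FALSE)
  p <- rep(floor_p, length(observation))
  inside <- !is.na(idx)
  p[inside] <- pdf$prob[idx[inside]]
  p[p <= 0] <- floor_p
  p
}

#' Tabular view and TSV export of binned densities
#'
#' @param density A `binned_density`, or a list of them (one per timepoint).
#' @param times Optional numeric timepoints matching the list.
#' @param path Output TSV path.
#' @return A tibble with columns `time`, `bin_low`, `bin_high`,
#'   `probability`, `variance`.
#' @export
density_to_tibble <- function(density, times = NULL) {
  if (inherits(density, "binned_density")) density <- list(density)
  if (is.null(times)) times <- seq_along(density)
  purrr::map2_dfr(density, times, function(d, t) {
    e <- d$scheme$edges
    tibble::tibble(time = t, bin_low = e[-length(e)], bin_high = e[-1L],
                   probability = d$prob, variance = d$var)
  })
}

#' @rdname density_to_tibble
#' @export
write_density_tsv <- function(density, path, times = NULL) {
  readr::write_tsv(density_to_tibble(density, times), path)
  invisible(path)
}
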