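#' Estimation criteria: likelihood and density-function distances
#'
#' Four criteria compare measured replicate counts with the model-side state
#' distribution reconstructed from SSA realizations (with the dataset's
#' measurement noise added to the simulations before binning, so both sides
#' see the same observation process):
#'
#' * `neg_log_likelihood()` — \eqn{\sum_{j} \sum_{i} -\log P(o_{ij}, t_i)},
#'   with [likelihood_lookup()] semantics so the sum is always finite. The
#'   model histogram is binned on the simulation side. Works at any replicate
#'   number, including single cells.
#' * `dfd_pdf()` — weighted quadratic distance between the data and model
#'   PDFs, \eqn{\sum_i \sum_{l=1}^{L-1} (P_e - P)^2 / s^2_{l,i}}, where the
#'   bins come from the experimental data and the weights are the binomial
#'   finite-sampling variances of the data-side frequencies. The last bin is
#'   excluded: normalisation makes it linearly dependent on the others.
#' * `dfd_cdf()` — the same construction on cumulative frequencies, weights
#'   \eqn{S^2_{l,i} = F_e(1-F_e)/N}. For sparse data (`data` a
#'   [sparse_ecdf]) the data side uses the order-statistic positions
#'   \eqn{(l - 0.5)/m}, the model CDF is binned on the SSA realizations and
#'   interpolated at the sorted data values, and `N = m` in the weights.
#' * `dfd_max()` — the maximum-discrepancy variants: per timepoint the
#'   largest \eqn{|\Delta| / s_{l,i}} over the first `L - 1` bins (standard
#'   deviation, not variance, in the denominator), summed over timepoints.
#'
#' All criteria are non-negative and exactly zero when the two sides
#' coincide. Degenerate bins with zero variance contribute nothing when the
#' probabilities agree and fall back to the floor variance \eqn{1/(4N^2)}
#' when they disagree, keeping every ratio finite.
#'
#' Each function accepts a single `binned_density` (one timepoint) or a list
#' of them (one per timepoint); data and model lists must pair up, and paired
#' densities must share the same binning scheme.
#'
#' @param dataset A [cme_dataset] (or a plain integer matrix of `m`
#'   replicates by `n` timepoints).
#' @param model_pdf,model_cdf Model-side `binned_density` or list thereof.
#' @param data_pdf,data_cdf Data-side `binned_density` or list thereof; for
#'   sparse mode `data_cdf` is a [sparse_ecdf] or list thereof.
#' @param kind `"pdf"` or `"cdf"` for the maximum-distance variant.
#' @return A single non-negative number.
#' @name objectives
NULL

as_density_list <- function(x, class = "binned_density") {
  if (inherits(x, class)) return(list(x))
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), class)))
  x
}

check_shared_scheme <- function(a, b) {
  ea <- a$scheme$edges
  eb <- b$scheme$edges
  if (length(ea) != length(eb) || any(ea != eb)) {
    stop("data and model densities must share the same binning scheme",
         call. = FALSE)
  }
}

# Weighted squared discrepancy over the first L-1 bins of one timepoint.
# (identical() short-circuits the edge comparison when both densities carry
# the same scheme object, the common case on the estimation hot path)
weighted_sq_distance <- function(data_d, model_d) {
  if (!identical(data_d$scheme, model_d$scheme)) {
    check_shared_scheme(data_d, model_d)
  }
  L <- length(data_d$prob)
  if (L < 2L) return(0)
  keep <- seq_len(L - 1L)
  d2 <- (data_d$prob[keep] - model_d$prob[keep])^2
  v <- data_d$var[keep]
  zero_v <- v <= 0
  if (any(zero_v)) {
    v[zero_v] <- 1 / (4 * data_d$n^2)
    d2[zero_v & d2 == 0] <- 0  # agreeing degenerate bins contribute nothing
  }
  sum(d2 / v)
}

max_sd_distance <- function(data_d, model_d) {
  if (!identical(data_d$scheme, model_d$scheme)) {
    check_shared_scheme(data_d, model_d)
  }
  L <- length(data_d$prob)
  if (L < 2L) return(0)
  keep <- seq_len(L - 1L)
  dd <- abs(data_d$prob[keep] - model_d$prob[keep])
  v <- data_d$var[keep]
  zero_v <- v <= 0
  if (any(zero_v)) {
    v[zero_v] <- 1 / (4 * data_d$n^2)
    dd[zero_v & dd == 0] <- 0
  }
  max(dd / sqrt(v))
}

#' @rdname objectives
#' @export
neg_log_likelihood <- function(dataset, model_pdf) {
  obs <- dataset_observations(dataset)  # list over (time, species)
  model_pdf <- as_density_grid(model_pdf, obs)
  total <- 0
  for (i in seq_along(obs)) {
    p <- likelihood_lookup(model_pdf[[i]], obs[[i]])
    total <- total - sum(log(p))
  }
  total
}

#' @rdname objectives
#' @export
dfd_pdf <- function(data_pdf, model_pdf) {
  data_pdf <- as_density_list(data_pdf)
  model_pdf <- as_density_list(model_pdf)
  stopifnot(length(data_pdf) == length(model_pdf))
  sum(purrr::map2_dbl(data_pdf, model_pdf, weighted_sq_distance))
}

#' @rdname objectives
#' @export
dfd_cdf <- function(data_cdf, model_cdf) {
  if (inherits(data_cdf, "sparse_ecdf") ||
      (is.list(data_cdf) && length(data_cdf) &&
       inherits(data_cdf[[1L]], "sparse_ecdf"))) {
    data_cdf <- as_density_list(data_cdf, "sparse_ecdf")
    model_cdf <- as_density_list(model_cdf)
    stopifnot(length(data_cdf) == length(model_cdf))
    return(sum(purrr::map2_dbl(data_cdf, model_cdf, sparse_cdf_distance)))
  }
  data_cdf <- as_density_list(data_cdf)
  model_cdf <- as_density_list(model_cdf)
  stopifnot(length(data_cdf) == length(model_cdf))
  sum(purrr::map2_dbl(data_cdf, model_cdf, weighted_sq_distance))
}

#' @rdname objectives
#' @export
dfd_max <- function(data_density, model_density, kind = c("pdf", "cdf")) {
  kind <- match.arg(kind)
  data_density <- as_density_list(data_density)
  model_density <- as_density_list(model_density)
  stopifnot(length(data_density) == length(model_density))
  bad <- vapply(data_density, function(d) d$kind != kind, logical(1))
  if (any(bad)) stop("data density kind does not match 'kind'", call. = FALSE)
  sum(purrr::map2_dbl(data_density, model_density, max_sd_distance))
}

# Sparse mode: model CDF (binned on the SSA side) linearly interpolated at
# the sorted data values; weights (l - 0.5)/m (1 - (l - 0.5)/m) / m; the
# last order statistic is excluded, mirroring the L - 1 sum of the dense
# criterion.
sparse_cdf_distance <- function(se, model_cdf) {
  stopifnot(inherits(se, "sparse_ecdf"),
            inherits(model_cdf, "binned_density"), model_cdf$kind == "cdf")
  m <- se$m
  if (m < 2L) return(0)
  keep <- seq_len(m - 1L)
  fe <- se$positions[keep]
  f_model <- interpolate_cdf(model_cdf, se$values[keep])
  s2 <- fe * (1 - fe) / m
  sum((fe - f_model)^2 / s2)
}

# Piecewise-linear model CDF through (bin centre, cumulative probability),
# clamped to 0 below the support and 1 above it.
interpolate_cdf <- function(model_cdf, at) {
  x <- model_cdf$scheme$centers
  y <- model_cdf$prob
  if (length(x) == 1L) {
    out <- numeric(length(at))
    out[at >= x] <- 1
    return(out)
  }
  stats::approx(x, y, xout = at, yleft = 0, yright = 1, ties = "ordered")$y
}

#' Objective specification
#'
#' Bundles the choices that define one estimation criterion: the method, the
#' number of SSA realizations behind each model-side density, the binning
#' occupancy rule, the measurement-noise variance applied to simulations, and
#' the replicate threshold below which histogram-based criteria refuse to
#' run (PDF histograms from few replicates are wildly unreliable; the sparse
#' CDF mode or the likelihood should be used instead).
#'
#' @param method One of `"ml"`, `"dfd_pdf"`, `"dfd_cdf"`, `"dfd_pdf_max"`,
#'   `"dfd_cdf_max"`.
#' @param n_ssa SSA realizations per objective evaluation.
#' @param min_count Minimum histogram bin occupancy.
#' @param sigma2 Measurement-noise variance added to simulated counts
#'   (`NULL`: inherit from the dataset's provenance).
#' @param population_threshold Minimum replicates for dense histogram
#'   criteria (default 1000).
#' @param allow_sparse_pdf Set `TRUE` to override the threshold.
#' @return An `objective_spec`.
#' @export
objective_spec <- function(method = c("dfd_cdf", "dfd_pdf", "ml",
                                      "dfd_pdf_max", "dfd_cdf_max"),
                           n_ssa = 1000L, min_count = 10L, sigma2 = NULL,
                           population_threshold = 1000L,
                           allow_sparse_pdf = FALSE) {
  method <- match.arg(method)
  stopifnot(n_ssa >= 1L, min_count >= 1L)
  structure(
    list(method = method, n_ssa = as.integer(n_ssa),
         min_count = as.integer(min_count), sigma2 = sigma2,
         population_threshold = as.integer(population_threshold),
         allow_sparse_pdf = isTRUE(allow_sparse_pdf)),
    class = "objective_spec"
  )
}

#' Append objective evaluations to a JSON-lines log
#'
#' @param path Log file path.
#' @param method,params,value,seed,n_ssa Fields of one evaluation record.
#' @return `path`, invisibly.
#' @export
log_objective_eval <- function(path, method, params, value, seed, n_ssa) {
  line <- jsonlite::toJSON(
    list(method = method, params = as.list(params), value = value,
         seed = seed, n_ssa = n_ssa),
    auto_unbox = TRUE, digits = NA
  )
  cat(line, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}
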