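#' Build the data-side summaries an estimation method needs
#'
#' Internal-but-exported helper: computes, once per dataset, whatever the
#' chosen criterion compares against — experimental-referenced histograms
#' (dense density distances), order-statistic ECDFs (sparse CDF mode), or
#' nothing (likelihood).
#'
#' @param dataset A [cme_dataset].
#' @param spec An [objective_spec].
#' @return A list with elements `mode` and per-(time, species) data
#'   summaries.
#' @keywords internal
#' @export
prepare_data_side <- function(dataset, spec) {
  obs <- dataset_observations(dataset)
  m <- dim(dataset$observations)[1L]
  dense_methods <- c("dfd_pdf", "dfd_pdf_max", "dfd_cdf_max")
  if (spec$method %in% dense_methods && m < spec$population_threshold &&
      !spec$allow_sparse_pdf) {
    stop("method '", spec$method, "' needs at least ",
         spec$population_threshold, " replicates (got ", m, "); ",
         "histogram estimates from sparse data are unreliable - use ",
         "'dfd_cdf' (sparse mode) or 'ml', or set allow_sparse_pdf = TRUE",
         call. = FALSE)
  }

  if (spec$method == "ml") {
    # observations are fixed integers: tabulate once and weight the
    # log-likelihood by counts instead of looking up every replicate
    tabs <- lapply(obs, function(o) {
      tt <- table(o)
      list(values = as.integer(names(tt)), counts = as.integer(tt))
    })
    return(list(mode = "ml", obs = obs, tabs = tabs))
  }
  if (spec$method == "dfd_cdf" && m < spec$population_threshold) {
    return(list(mode = "sparse_cdf", obs = obs,
                ecdf = lapply(obs, sparse_ecdf)))
  }
  schemes <- lapply(obs, build_bins, min_count = spec$min_count,
                    reference = "experimental")
  pdfs <- purrr::map2(obs, schemes, pdf_from_samples)
  out <- list(mode = "dense", obs = obs, schemes = schemes, pdfs = pdfs)
  if (spec$method %in% c("dfd_cdf", "dfd_cdf_max")) {
    out$cdfs <- lapply(pdfs, cdf_from_pdf)
  }
  out
}

#' Objective function over parameters for a dataset and network
#'
#' Returns a closure `f(params) -> value` implementing the criterion in
#' `spec`: each call simulates `n_ssa` SSA realizations at the candidate
#' parameters, applies the dataset's measurement-noise model to the
#' simulated observables, builds the model-side densities under the method's
#' binning-reference rule, and evaluates the distance to the (precomputed)
#' data side.
#'
#' By default the SSA and noise seeds are held fixed across calls (common
#' random numbers), so differences between candidates reflect the
#' parameters, not fresh Monte-Carlo noise, and the optimizer's greedy
#' selection compares like with like. Set `crn = FALSE` for an independent
#' simulation seed per evaluation.
#'
#' @param dataset A [cme_dataset].
#' @param network The [reaction_network] being fitted (its observables must
#'   cover the dataset's species).
#' @param spec An [objective_spec].
#' @param seed Base seed for the model-side simulations.
#' @param crn Use common random numbers across evaluations (default TRUE).
#' @param x0,t0 Initial condition; default from the dataset's provenance.
#' @return A function of a (named) parameter vector.
#' @export
objective_function <- function(dataset, network, spec, seed, crn = TRUE,
                               x0 = NULL, t0 = NULL) {
  stopifnot(inherits(dataset, "cme_dataset"),
            inherits(network, "reaction_network"),
            inherits(spec, "objective_spec"))
  data_side <- prepare_data_side(dataset, spec)
  seed <- check_seed(seed)

  if (is.null(x0)) {
    x0 <- unlist(dataset$provenance$x0)
    if (is.null(x0)) stop("x0 not supplied and absent from provenance",
                          call. = FALSE)
  }
  if (is.null(t0)) t0 <- dataset$provenance$t0 %||% 0
  sigma2 <- spec$sigma2 %||% dataset$provenance$sigma2 %||% 0
  obs_idx <- match(dataset$species, network$species)
  if (anyNA(obs_idx)) {
    stop("dataset species not present in the network", call. = FALSE)
  }

  times <- dataset$sample_times
  n_times <- length(times)
  n_sp <- length(dataset$species)
  counter <- 0L

  function(params) {
    counter <<- counter + 1L
    ssa_seed <- if (crn) seed else derive_seed(seed, counter)
    ens <- simulate_ensemble(network, params, x0, times,
                             n_realizations = spec$n_ssa, seed = ssa_seed,
                             t0 = t0)
    if (sigma2 > 0) {
      ens <- add_measurement_noise(ens, sigma2,
                                   seed = derive_seed(ssa_seed, 2L),
                                   species = dataset$species)
    }
    total <- 0
    k <- 1L
    for (s in seq_len(n_sp)) {
      sim_all <- ens$states[, , obs_idx[s], drop = FALSE]
      for (ti in seq_len(n_times)) {
        sim <- as.integer(sim_all[, ti, 1L])
        total <- total + objective_term(data_side, spec, k, sim)
        k <- k + 1L
      }
    }
    total
  }
}

# One (timepoint, species) contribution for the prepared data side.
objective_term <- function(data_side, spec, k, sim) {
  switch(data_side$mode,
    ml = {
      scheme <- build_bins(sim, min_count = spec$min_count,
                           reference = "simulation")
      mp <- pdf_from_samples(sim, scheme)
      tab <- data_side$tabs[[k]]
      -sum(tab$counts * log(likelihood_lookup(mp, tab$values)))
    },
    sparse_cdf = {
      scheme <- build_bins(sim, min_count = spec$min_count,
                           reference = "simulation")
      mc <- cdf_from_pdf(pdf_from_samples(sim, scheme))
      sparse_cdf_distance(data_side$ecdf[[k]], mc)
    },
    dense = {
      mp <- pdf_from_samples(sim, data_side$schemes[[k]])
      switch(spec$method,
        dfd_pdf = weighted_sq_distance(data_side$pdfs[[k]], mp),
        dfd_pdf_max = max_sd_distance(data_side$pdfs[[k]], mp),
        dfd_cdf = weighted_sq_distance(data_side$cdfs[[k]],
                                       cdf_from_pdf(mp)),
        dfd_cdf_max = max_sd_distance(data_side$cdfs[[k]],
                                      cdf_from_pdf(mp))
      )
    }
  )
}

#' End-to-end parameter estimation
#'
#' Runs the full pipeline: prepare the data-side densities once, wrap the
#' criterion in [objective_function()], minimise it with [de_minimize()],
#' and score the estimates against the true parameters when the dataset's
#' provenance carries them.
#'
#' @param dataset A [cme_dataset].
#' @param network The [reaction_network] to fit.
#' @param spec An [objective_spec].
#' @param de A [de_config]; its bounds default to the network's if omitted
#'   via [de_config()].
#' @param crn Common random numbers across objective evaluations.
#' @return An `estimation_run` with the `de_result`, a `recovery` tibble
#'   (when the truth is known) and every seed needed to replay the run.
#' @export
estimate <- function(dataset, network, spec, de, crn = TRUE) {
  stopifnot(inherits(de, "de_config"))
  if (!identical(de$bounds$parameter, network$parameter_names)) {
    stop("DE bounds must cover the network parameters in order",
         call. = FALSE)
  }
  obj <- objective_function(dataset, network, spec,
                            seed = derive_seed(de$seed, 11L), crn = crn)
  result <- de_minimize(obj, de)

  truth <- dataset$provenance$true_params
  recovery <- if (!is.null(truth)) {
    recovery_score(result$best_params, unlist(truth))
  }
  structure(
    list(result = result, recovery = recovery, spec = spec, de = de,
         crn = crn, dataset_provenance = dataset$provenance,
         network_species = network$species),
    class = "estimation_run"
  )
}

#' @export
print.estimation_run <- function(x, ...) {
  cat("<estimation_run> method ", x$spec$method, ", best value ",
      format(x$result$best_value), "\n", sep = "")
  print(round(x$result$best_params, 6))
  if (!is.null(x$recovery)) {
    s <- attr(x$recovery, "summary")
    cat(sprintf("recovery: max error %.3g, median %.3g\n",
                s[["max"]], s[["median"]]))
  }
  invisible(x)
}

#' @export
tidy.estimation_run <- function(x, ...) {
  if (!is.null(x$recovery)) return(x$recovery)
  tibble::tibble(parameter = names(x$result$best_params),
                 estimate = as.numeric(x$result$best_params))
}

#' @export
glance.estimation_run <- function(x, ...) {
  out <- tibble::tibble(
    method = x$spec$method, best_value = x$result$best_value,
    n_evaluations = x$result$n_evaluations,
    generations = nrow(x$result$history), np = x$de$np,
    n_ssa = x$spec$n_ssa, seed = x$de$seed
  )
  if (!is.null(x$recovery)) {
    s <- attr(x$recovery, "summary")
    out$max_error <- s[["max"]]
    out$median_error <- s[["median"]]
  }
  out
}

#' Scan an objective over a 1- or 2-parameter grid
#'
#' Evaluates the criterion on every node of a parameter grid (all other
#' parameters held fixed) and normalises by the grid minimum, so the best
#' node maps to 1. Used to visualise the shape — curvature, roughness — of
#' the different criteria's landscapes.
#'
#' @param network The [reaction_network].
#' @param dataset A [cme_dataset].
#' @param spec An [objective_spec].
#' @param grid Named list of one or two numeric vectors (grid axes).
#' @param fixed Named numeric vector covering the remaining parameters.
#' @param seed Simulation seed.
#' @param crn Reuse one SSA seed across all nodes (common random numbers,
#'   the default): the frozen sampling noise varies smoothly with the
#'   parameters and the scan shows the surface DE actually sees. With
#'   `crn = FALSE` every node gets an independent seed, exposing the raw
#'   finite-sampling roughness of the criterion.
#' @return An `objective_scan` tibble: one row per node with the varied
#'   parameters, `value` and `normalized`.
#' @export
scan_objective <- function(network, dataset, spec, grid, fixed = NULL,
                           seed = 1L, crn = TRUE) {
  stopifnot(is.list(grid), length(grid) >= 1L, length(grid) <= 2L,
            !is.null(names(grid)))
  if (any(lengths(grid) == 0L)) stop("empty grid", call. = FALSE)
  p <- network$parameter_names
  free <- names(grid)
  stopifnot(all(free %in% p))
  fixed_names <- setdiff(p, free)
  if (length(fixed_names)) {
    stopifnot(!is.null(names(fixed)), all(fixed_names %in% names(fixed)))
  }

  obj <- objective_function(dataset, network, spec, seed = seed, crn = crn)
  nodes <- do.call(tidyr::expand_grid, grid)
  values <- purrr::pmap_dbl(nodes, function(...) {
    node <- c(...)
    params <- numeric(length(p))
    names(params) <- p
    params[free] <- node
    if (length(fixed_names)) params[fixed_names] <- fixed[fixed_names]
    obj(params)
  })
  out <- nodes
  out$value <- values
  mn <- min(values)
  # ratio normalisation (minimum maps to 1); shift instead when the
  # minimum is exactly zero, which only happens for degenerate scans
  out$normalized <- if (mn > 0) values / mn else 1 + (values - mn)
  class(out) <- c("objective_scan", class(out))
  attr(out, "method") <- spec$method
  attr(out, "free_params") <- free
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
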