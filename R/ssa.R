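#' Exact stochastic simulation (Gillespie direct method)
#'
#' `ssa_simulate()` draws one trajectory of a [reaction_network] and records
#' the state at each requested sample time; `simulate_ensemble()` draws many
#' statistically independent realizations. The direct method is used: the
#' waiting time to the next reaction is exponential with rate
#' \eqn{a_0 = \sum_j a_j}, the firing reaction is chosen with probability
#' \eqn{a_j / a_0}, and the recorded state at a sample time is the state
#' holding over the interval containing it (right-continuous convention).
#' When all propensities vanish the state is frozen thereafter.
#'
#' Reproducibility: `seed` is an explicit argument, never global state. Each
#' realization runs on its own counter-partitioned RNG sub-stream, so the
#' same `(seed, n_realizations)` always yields a bit-identical ensemble and
#' realization `r` of an ensemble equals a single run on sub-stream `r`.
#'
#' Networks whose propensities are all mass-action or Hill run in compiled
#' code; networks containing `prop_expression()` terms fall back to a pure-R
#' engine (also selectable with `engine = "r"`, useful as an independent
#' cross-check).
#'
#' @param network A [reaction_network].
#' @param params Parameter values (named or in declaration order).
#' @param x0 Initial integer state at time `t0`.
#' @param t0 Initial time (default 0).
#' @param sample_times Non-decreasing observation times, all `>= t0`.
#' @param seed Integer seed.
#' @param n_realizations Number of independent trajectories.
#' @param engine `"auto"` (compiled when possible), `"cpp"` or `"r"`.
#' @return `ssa_simulate()`: an integer matrix `length(sample_times) x N`
#'   with species columns. `simulate_ensemble()`: an `ensemble` object
#'   holding an `n_realizations x n_times x N` integer array.
#' @examples
#' net <- builtin_model("birth_death_test")
#' ens <- simulate_ensemble(net, c(k = 5, gamma = 1), x0 = 0,
#'                          sample_times = c(5, 20), n_realizations = 200,
#'                          seed = 1)
#' colMeans(ens$states[, 2, , drop = FALSE])  # near stationary mean 5
#' @export
simulate_ensemble <- function(network, params, x0, sample_times,
                              n_realizations, seed, t0 = 0,
                              engine = c("auto", "cpp", "r")) {
  engine <- match.arg(engine)
  params <- align_params(network, params)
  x0 <- align_state(network, x0)
  if (any(x0 < 0)) stop("initial state must be non-negative", call. = FALSE)
  sample_times <- as.numeric(sample_times)
  if (length(sample_times) < 1L || is.unsorted(sample_times) ||
      any(sample_times < t0)) {
    stop("sample_times must be non-decreasing and >= t0", call. = FALSE)
  }
  stopifnot(n_realizations >= 1L)
  seed <- check_seed(seed)

  tab <- compile_propensity_table(network, params)
  use_cpp <- switch(engine,
    auto = !is.null(tab),
    cpp = { if (is.null(tab)) stop("network has expression propensities; ",
                                   "use engine = 'r'", call. = FALSE); TRUE },
    r = FALSE
  )

  n_times <- length(sample_times)
  N <- length(network$species)
  if (use_cpp) {
    res <- ssa_ensemble_cpp(network$stoichiometry, tab, as.integer(x0),
                            t0, sample_times, as.integer(n_realizations),
                            as.double(seed))
    if (res$n_clamped > 0) {
      warning(res$n_clamped,
              " negative propensity evaluations clamped to zero",
              call. = FALSE)
    }
    states <- array(res$states, dim = c(n_realizations, n_times, N))
  } else {
    states <- ssa_ensemble_r(network, params, x0, t0, sample_times,
                             n_realizations, seed)
  }
  dimnames(states) <- list(NULL, NULL, network$species)

  structure(
    list(states = states, sample_times = sample_times,
         species = network$species, x0 = as.integer(x0), t0 = t0,
         noisy = FALSE,
         seed_info = list(seed = seed, engine = if (use_cpp) "cpp" else "r",
                          n_realizations = n_realizations)),
    class = "ensemble"
  )
}

#' @rdname simulate_ensemble
#' @export
ssa_simulate <- function(network, params, x0, sample_times, seed, t0 = 0,
                         engine = c("auto", "cpp", "r")) {
  ens <- simulate_ensemble(network, params, x0, sample_times,
                           n_realizations = 1L, seed = seed, t0 = t0,
                           engine = engine)
  out <- ens$states[1L, , , drop = FALSE]
  dim(out) <- dim(ens$states)[2:3]
  colnames(out) <- ens$species
  out
}

# Pure-R direct-method engine; handles any propensity kind (including parsed
# expressions) and optionally records per-reaction firing counts. Slower than
# the compiled path by orders of magnitude; used for expression models and as
# an independent implementation in tests.
ssa_ensemble_r <- function(network, params, x0, t0, sample_times,
                           n_realizations, seed, record_firings = FALSE) {
  n_times <- length(sample_times)
  N <- length(network$species)
  M <- nrow(network$stoichiometry)
  states <- array(0L, dim = c(n_realizations, n_times, N))
  firings <- if (record_firings) matrix(0L, n_realizations, M) else NULL

  with_preserved_seed(seed, {
    for (r in seq_len(n_realizations)) {
      x <- x0
      t <- t0
      ti <- 1L
      repeat {
        a <- numeric(M)
        for (j in seq_len(M)) {
          a[j] <- eval_propensity(network$propensities[[j]], x, params)
        }
        if (anyNA(a) || any(!is.finite(a))) {
          bad <- which(!is.finite(a))[1L]
          stop("propensity of reaction '", network$reaction_names[bad],
               "' is not finite at state (", paste(x, collapse = ", "), ")",
               call. = FALSE)
        }
        a[a < 0] <- 0
        a0 <- sum(a)
        tnext <- if (a0 <= 0) Inf else t + stats::rexp(1L, a0)
        while (ti <= n_times && sample_times[ti] < tnext) {
          states[r, ti, ] <- as.integer(x)
          ti <- ti + 1L
        }
        if (ti > n_times || !is.finite(tnext)) break
        t <- tnext
        j <- sample.int(M, 1L, prob = a)
        x <- x + network$stoichiometry[j, ]
        if (record_firings) firings[r, j] <- firings[r, j] + 1L
      }
    }
  })
  if (record_firings) attr(states, "firings") <- firings
  states
}

#' Add measurement noise to an ensemble
#'
#' Emulates the error of converting a fluorescence signal into a molecular
#' count: each observed value is \eqn{o = \mathrm{round}(x + \epsilon)} with
#' \eqn{\epsilon \sim N(0, \sigma^2)} i.i.d. Values are deliberately not
#' clipped at zero — small negative observed counts can and do occur, and the
#' binning machinery accepts them. Noise is applied only to the designated
#' observable species; hidden states (promoter configurations and the like)
#' are not measured, so they carry no measurement error.
#'
#' @param ensemble An un-noised `ensemble`.
#' @param sigma2 Noise variance \eqn{\sigma^2 \ge 0} (counts squared).
#' @param seed Integer seed (independent of the simulation seed).
#' @param species Species to perturb; defaults to all species in the
#'   ensemble (callers working from a network usually pass its
#'   `observables`).
#' @return A new `ensemble` with `noisy = TRUE`.
#' @export
add_measurement_noise <- function(ensemble, sigma2, seed = NULL,
                                  species = ensemble$species) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (ensemble$noisy) stop("ensemble already carries noise", call. = FALSE)
  if (!is.numeric(sigma2) || length(sigma2) != 1L || sigma2 < 0) {
    stop("sigma2 must be a single value >= 0", call. = FALSE)
  }
  out <- ensemble
  if (sigma2 > 0) {
    if (is.null(seed)) stop("seed is required when sigma2 > 0", call. = FALSE)
    seed <- check_seed(seed)
    idx <- match(species, ensemble$species)
    if (anyNA(idx)) stop("unknown species in noise target", call. = FALSE)
    sd_eps <- sqrt(sigma2)
    n_block <- prod(dim(out$states)[1:2])
    with_preserved_seed(seed, {
      for (s in idx) {
        out$states[, , s] <- as.integer(
          round(out$states[, , s] + stats::rnorm(n_block, sd = sd_eps))
        )
      }
    })
    out$seed_info$noise_seed <- seed
  }
  out$noisy <- TRUE
  out$seed_info$sigma2 <- sigma2
  out
}

#' @export
print.ensemble <- function(x, ...) {
  d <- dim(x$states)
  cat("<ensemble> ", d[1L], " realizations x ", d[2L], " times x ", d[3L],
      " species (", if (x$noisy) "noisy" else "noise-free", ")\n", sep = "")
  invisible(x)
}

#' Long-format view and CSV round-trip of an ensemble
#'
#' @param ensemble An `ensemble`.
#' @param path File path for CSV export/import.
#' @return `ensemble_to_tibble()`: a tibble with columns `realization`,
#'   `time`, `species`, `count`.
#' @export
ensemble_to_tibble <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble"))
  d <- dim(ensemble$states)
  tibble::tibble(
    realization = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    time = rep(rep(ensemble$sample_times, each = d[1L]), times = d[3L]),
    species = rep(ensemble$species, each = d[1L] * d[2L]),
    count = as.integer(ensemble$states)
  )
}

#' @rdname ensemble_to_tibble
#' @export
write_ensemble_csv <- function(ensemble, path) {
  readr::write_csv(ensemble_to_tibble(ensemble), path)
  invisible(path)
}

#' @rdname ensemble_to_tibble
#' @export
read_ensemble_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("realization", "time", "species", "count") %in% names(df)))
  species <- unique(df$species)
  times <- sort(unique(df$time))
  n_real <- max(df$realization)
  states <- array(NA_integer_,
                  dim = c(n_real, length(times), length(species)))
  states[cbind(df$realization, match(df$time, times),
               match(df$species, species))] <- as.integer(df$count)
  structure(
    list(states = states, sample_times = times, species = species,
         x0 = NULL, t0 = NA_real_, noisy = any(states < 0, na.rm = TRUE),
         seed_info = list()),
    class = "ensemble"
  )
}

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  as.integer(seed)
}

# Run code under a fixed RNG seed, restoring the caller's RNG state on exit.
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(check_seed(seed))
  force(code)
}
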