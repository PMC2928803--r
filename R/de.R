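#' Differential Evolution configuration
#'
#' Settings for the DE/rand/1/bin global minimizer. The stochastic,
#' non-smooth objective landscapes produced by finite-sample density
#' comparisons rule out gradient methods; DE's difference-vector mutation
#' and greedy selection need only objective values and cope well with such
#' surfaces.
#'
#' Defaults follow the canonical recommendations: differential weight
#' `f = 0.5`, crossover rate `cr = 0.9`, and population size `10 x` the
#' number of parameters. Termination is after a fixed number of generations;
#' an optional population-spread threshold (`tol_spread`) can stop earlier
#' but is off by default.
#'
#' @param bounds Named list of `c(lower, upper)` per parameter, or the
#'   `bounds` tibble of a [reaction_network].
#' @param generations Number of generations `G >= 1`.
#' @param np Population size (`NP >= 4`); default `10 * n_parameters`.
#' @param f Differential weight in `(0, 2]`.
#' @param cr Crossover rate in `[0, 1]`.
#' @param seed Integer seed; the run is deterministic given it.
#' @param tol_spread Optional early-stop threshold on the standard deviation
#'   of population objective values.
#' @return A `de_config`.
#' @export
de_config <- function(bounds, generations, np = NULL, f = 0.5, cr = 0.9,
                      seed = 1L, tol_spread = NULL) {
  if (tibble::is_tibble(bounds) || is.data.frame(bounds)) {
    b <- bounds
    stopifnot(all(c("parameter", "lower", "upper") %in% names(b)))
  } else {
    stopifnot(is.list(bounds), !is.null(names(bounds)))
    b <- tibble::tibble(
      parameter = names(bounds),
      lower = vapply(bounds, function(x) as.numeric(x[[1L]]), numeric(1)),
      upper = vapply(bounds, function(x) as.numeric(x[[2L]]), numeric(1))
    )
  }
  stopifnot(all(is.finite(b$lower)), all(is.finite(b$upper)),
            all(b$lower <= b$upper))
  if (is.null(np)) np <- 10L * nrow(b)
  stopifnot(np >= 4L, generations >= 1L, f > 0, f <= 2, cr >= 0, cr <= 1)
  structure(
    list(bounds = b, np = as.integer(np),
         generations = as.integer(generations), f = f, cr = cr,
         seed = check_seed(seed), tol_spread = tol_spread,
         strategy = "rand/1/bin"),
    class = "de_config"
  )
}

#' Minimise a box-constrained objective with Differential Evolution
#'
#' Classic DE/rand/1/bin: for each target vector a mutant
#' \eqn{v = x_{r1} + F (x_{r2} - x_{r3})} is built from three distinct
#' random population members, binomial crossover with rate `CR` (one
#' coordinate always crosses) forms the trial vector, out-of-bounds
#' coordinates are reflected back into the box, and greedy selection keeps
#' the better of trial and target. The best objective value is therefore
#' non-increasing across generations.
#'
#' @param objective Function mapping a named parameter vector to a single
#'   finite number. Errors raised inside it abort the run with the offending
#'   parameter vector reported.
#' @param config A [de_config].
#' @return A `de_result`: `best_params`, `best_value`, per-generation
#'   `history` (best, median, spread), `n_evaluations` and the config.
#' @examples
#' sphere <- function(x) sum(x^2)
#' cfg <- de_config(list(a = c(-5, 5), b = c(-5, 5)), generations = 50,
#'                  seed = 1)
#' de_minimize(sphere, cfg)$best_value
#' @export
de_minimize <- function(objective, config) {
  stopifnot(inherits(config, "de_config"))
  lower <- config$bounds$lower
  upper <- config$bounds$upper
  pnames <- config$bounds$parameter
  p <- length(lower)
  np <- config$np
  G <- config$generations

  eval_count <- 0L
  safe_eval <- function(x) {
    eval_count <<- eval_count + 1L
    val <- tryCatch(objective(stats::setNames(x, pnames)),
                    error = function(e) {
      stop("objective failed at parameters (",
           paste(signif(x, 6), collapse = ", "), "): ",
           conditionMessage(e), call. = FALSE)
    })
    if (!is.finite(val)) {
      stop("objective returned a non-finite value at parameters (",
           paste(signif(x, 6), collapse = ", "), ")", call. = FALSE)
    }
    val
  }

  history <- matrix(NA_real_, nrow = G, ncol = 3,
                    dimnames = list(NULL, c("best", "median", "spread")))

  with_preserved_seed(config$seed, {
    X <- matrix(stats::runif(np * p), nrow = np, ncol = p)
    X <- sweep(sweep(X, 2, upper - lower, `*`), 2, lower, `+`)
    fx <- apply(X, 1L, safe_eval)

    for (g in seq_len(G)) {
      for (i in seq_len(np)) {
        r <- sample.int(np - 1L, 3L)
        r <- ifelse(r >= i, r + 1L, r)  # three distinct indices != i
        while (anyDuplicated(r)) {
          r <- sample.int(np - 1L, 3L)
          r <- ifelse(r >= i, r + 1L, r)
        }
        v <- X[r[1L], ] + config$f * (X[r[2L], ] - X[r[3L], ])
        # reflect into the box, then clamp any residual overshoot
        below <- v < lower
        v[below] <- 2 * lower[below] - v[below]
        above <- v > upper
        v[above] <- 2 * upper[above] - v[above]
        v <- pmin(pmax(v, lower), upper)

        cross <- stats::runif(p) < config$cr
        cross[sample.int(p, 1L)] <- TRUE
        u <- ifelse(cross, v, X[i, ])
        fu <- safe_eval(u)
        if (fu <= fx[i]) {
          X[i, ] <- u
          fx[i] <- fu
        }
      }
      history[g, ] <- c(min(fx), stats::median(fx), stats::sd(fx))
      if (!is.null(config$tol_spread) &&
          history[g, "spread"] < config$tol_spread) {
        history <- history[seq_len(g), , drop = FALSE]
        break
      }
    }

    best <- which.min(fx)
    structure(
      list(best_params = stats::setNames(X[best, ], pnames),
           best_value = fx[best],
           history = tibble::tibble(
             generation = seq_len(nrow(history)),
             best = history[, "best"], median = history[, "median"],
             spread = history[, "spread"]
           ),
           n_evaluations = eval_count, config = config),
      class = "de_result"
    )
  })
}

#' @export
print.de_result <- function(x, ...) {
  cat("<de_result> best value ", format(x$best_value), " after ",
      nrow(x$history), " generations (", x$n_evaluations,
      " evaluations)\n", sep = "")
  print(round(x$best_params, 6))
  invisible(x)
}

#' @export
tidy.de_result <- function(x, ...) x$history

#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    best_value = x$best_value, generations = nrow(x$history),
    n_evaluations = x$n_evaluations, np = x$config$np,
    f = x$config$f, cr = x$config$cr, seed = x$config$seed
  )
}

#' Export a DE convergence history to CSV
#'
#' @param result A `de_result`.
#' @param path Output file.
#' @export
write_de_history_csv <- function(result, path) {
  readr::write_csv(result$history, path)
  invisible(path)
}
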