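#' Define a stochastic reaction network
#'
#' A `reaction_network` is the chemical-master-equation view of a biochemical
#' system: `N` species with integer molecular counts, `M` reactions, each
#' with a stoichiometric change vector \eqn{\nu_j} and a propensity function
#' \eqn{a_j(x, k)}, and `p` kinetic parameters with box bounds used by the
#' optimizer.
#'
#' @param species Character vector of species names (length `N >= 1`).
#' @param reactions List of reactions, each created by [reaction()].
#' @param parameters Named list of length-2 numeric bounds `c(lower, upper)`,
#'   one per parameter, in the model's rate units.
#' @param true_params Optional named numeric vector of reference ("true")
#'   parameter values, kept as metadata for synthetic-data generation and
#'   recovery scoring.
#' @param observables Character vector of species reported by measurements
#'   (e.g. a fluorescent reporter); defaults to all species. Measurement
#'   noise, when requested, is applied to these only.
#' @param volume_label Optional free-text note on the system volume
#'   (informational only; propensities are already in molecule units).
#' @return An object of class `reaction_network`.
#' @examples
#' net <- reaction_network(
#'   species = "X",
#'   reactions = list(
#'     reaction("birth", c(X = 1), prop_mass_action("k")),
#'     reaction("death", c(X = -1), prop_mass_action("gamma", "X"))
#'   ),
#'   parameters = list(k = c(0, 10), gamma = c(0, 5)),
#'   true_params = c(k = 5, gamma = 1)
#' )
#' evaluate_propensities(net, state = 10, params = c(k = 5, gamma = 1))
#' @export
reaction_network <- function(species, reactions, parameters,
                             true_params = NULL, observables = species,
                             volume_label = NULL) {
  stopifnot(is.character(species), length(species) >= 1L,
            !anyDuplicated(species))
  stopifnot(is.list(reactions), length(reactions) >= 1L)
  stopifnot(is.list(parameters), length(parameters) >= 1L,
            !is.null(names(parameters)))

  bounds <- tibble::tibble(
    parameter = names(parameters),
    lower = vapply(parameters, function(b) as.numeric(b[[1L]]), numeric(1)),
    upper = vapply(parameters, function(b) as.numeric(b[[2L]]), numeric(1))
  )
  if (any(bounds$lower > bounds$upper)) {
    stop("parameter bounds must satisfy lower <= upper", call. = FALSE)
  }

  M <- length(reactions)
  N <- length(species)
  stoich <- matrix(0L, nrow = M, ncol = N,
                   dimnames = list(NULL, species))
  rnames <- character(M)
  props <- vector("list", M)
  for (j in seq_len(M)) {
    r <- reactions[[j]]
    stopifnot(inherits(r, "cme_reaction"))
    unknown <- setdiff(names(r$changes), species)
    if (length(unknown)) {
      stop("reaction '", r$name, "' changes undeclared species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    stoich[j, names(r$changes)] <- as.integer(r$changes)
    rnames[j] <- r$name
    props[[j]] <- r$propensity
  }

  net <- structure(
    list(species = species, reaction_names = rnames, stoichiometry = stoich,
         propensities = props, parameter_names = bounds$parameter,
         bounds = bounds, true_params = true_params,
         observables = observables, volume_label = volume_label),
    class = "reaction_network"
  )
  validate_network(net)
  net
}

#' @rdname reaction_network
#' @param name Reaction label.
#' @param changes Named integer vector of stoichiometric changes (species
#'   absent from the name list are unchanged).
#' @param propensity A [propensity_spec] object.
#' @export
reaction <- function(name, changes, propensity) {
  stopifnot(is.character(name), length(changes) >= 1L,
            !is.null(names(changes)), inherits(propensity, "propensity_spec"))
  structure(list(name = name, changes = changes, propensity = propensity),
            class = "cme_reaction")
}

validate_network <- function(net) {
  for (j in seq_along(net$propensities)) {
    syms <- propensity_symbols(net$propensities[[j]])
    if (net$propensities[[j]]$kind == "expression") {
      known <- c(net$species, net$parameter_names)
      bad <- setdiff(syms$params, known)
      if (length(bad)) {
        stop("reaction '", net$reaction_names[j],
             "' references unknown names: ", paste(bad, collapse = ", "),
             call. = FALSE)
      }
    } else {
      bad_p <- setdiff(syms$params, net$parameter_names)
      bad_s <- setdiff(syms$species, net$species)
      if (length(bad_p) || length(bad_s)) {
        stop("reaction '", net$reaction_names[j], "' references undeclared ",
             "species/parameters: ", paste(c(bad_p, bad_s), collapse = ", "),
             call. = FALSE)
      }
    }
  }
  bad_obs <- setdiff(net$observables, net$species)
  if (length(bad_obs)) {
    stop("observables not among species: ", paste(bad_obs, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(net$true_params)) {
    if (!setequal(names(net$true_params), net$parameter_names)) {
      stop("true_params names must match the declared parameters",
           call. = FALSE)
    }
  }
  invisible(net)
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", nrow(x$stoichiometry), " reactions, ",
      length(x$species), " species, ", length(x$parameter_names),
      " parameters\n", sep = "")
  cat("species:    ", paste(x$species, collapse = ", "), "\n", sep = "")
  for (j in seq_along(x$propensities)) {
    cat(sprintf("  %-12s a = %s\n", x$reaction_names[j],
                format(x$propensities[[j]])))
  }
  cat("observables:", paste(x$observables, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate all propensities at a state
#'
#' Returns the vector \eqn{(a_1, \ldots, a_M)} at the given integer state and
#' parameter values. Small negative values (possible for user-supplied
#' expression propensities) are clamped to zero with a warning; non-finite
#' values are an error naming the reaction.
#'
#' @param network A [reaction_network].
#' @param state Integer vector of molecular counts, length `N` (named or in
#'   species order).
#' @param params Numeric vector of parameter values, length `p` (named or in
#'   declaration order).
#' @return Numeric vector of length `M`, finite and `>= 0`.
#' @export
evaluate_propensities <- function(network, state, params) {
  state <- align_state(network, state)
  params <- align_params(network, params)
  a <- numeric(length(network$propensities))
  for (j in seq_along(a)) {
    aj <- eval_propensity(network$propensities[[j]], state, params)
    if (!is.finite(aj)) {
      stop("propensity of reaction '", network$reaction_names[j],
           "' is not finite at state (", paste(state, collapse = ", "), ")",
           call. = FALSE)
    }
    a[j] <- aj
  }
  if (any(a < 0)) {
    warning("negative propensities clamped to zero (reactions: ",
            paste(network$reaction_names[a < 0], collapse = ", "), ")",
            call. = FALSE)
    a[a < 0] <- 0
  }
  a
}

align_state <- function(network, state) {
  if (length(state) != length(network$species)) {
    stop("state must have length ", length(network$species),
         " (one count per species)", call. = FALSE)
  }
  if (!is.null(names(state))) state <- state[network$species]
  stats::setNames(as.numeric(state), network$species)
}

align_params <- function(network, params) {
  p <- network$parameter_names
  if (length(params) != length(p)) {
    stop("params must have length ", length(p), call. = FALSE)
  }
  if (!is.null(names(params))) params <- params[p]
  stats::setNames(as.numeric(params), p)
}

# Compile propensities into the numeric table consumed by the C++ SSA core.
# Returns NULL when any propensity is an expression (the pure-R engine is
# used instead).  Parameter-dependent constants (e.g. the inducer scale of a
# Hill term) are folded in here, once per candidate parameter vector.
compile_propensity_table <- function(network, params) {
  params <- align_params(network, params)
  M <- length(network$propensities)
  type <- integer(M); cst <- numeric(M)
  ridx <- matrix(-1L, M, 2); rmult <- matrix(0L, M, 2)
  hreg <- rep(-1L, M); hmult <- numeric(M); hexp <- numeric(M)
  for (j in seq_len(M)) {
    p <- network$propensities[[j]]
    if (p$kind == "mass_action") {
      type[j] <- 1L
      cst[j] <- if (is.character(p$rate)) params[[p$rate]] else p$rate
      if (length(p$reactants) > 2L) return(NULL)
      for (slot in seq_along(p$reactants)) {
        ridx[j, slot] <- match(names(p$reactants)[slot], network$species) - 1L
        rmult[j, slot] <- p$reactants[[slot]]
      }
    } else if (p$kind == "hill") {
      type[j] <- 2L
      cst[j] <- params[[p$numerator]]
      hreg[j] <- match(p$regulator, network$species) - 1L
      hexp[j] <- params[[p$exponent]]
      hmult[j] <- if (is.null(p$half_sat)) 1 else {
        (1 + p$conc / params[[p$half_sat]])^(-params[[p$sat_exponent]])
      }
    } else {
      return(NULL)
    }
  }
  list(type = type, cst = cst, ridx = ridx, rmult = rmult,
       hreg = hreg, hmult = hmult, hexp = hexp)
}
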