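#' Propensity specifications
#'
#' A reaction's propensity \eqn{a_j(x, k)} gives the probability per unit time
#' that reaction \eqn{j} fires when the system is in state \eqn{x} with rate
#' parameters \eqn{k}. Three kinds are supported:
#'
#' * `prop_mass_action()` — stochastic mass action: the rate constant times
#'   the number of distinct reactant combinations, e.g. `k * x` for a
#'   unimolecular reaction and `k * x * (x - 1) / 2` for a dimerisation.
#' * `prop_hill()` — repressive Hill kinetics
#'   \eqn{a = \alpha / (1 + (x_r \cdot s)^e)} for a regulator species
#'   \eqn{x_r}; the optional inner scale \eqn{s = (1 + c/K)^{-\eta}} models an
#'   inducer at concentration \eqn{c} that sequesters the regulator (the form
#'   used by genetic toggle-switch models, where an inducer such as IPTG
#'   weakens repression through its binding constant \eqn{K} and
#'   cooperativity \eqn{\eta}).
#' * `prop_expression()` — an arbitrary arithmetic formula over species and
#'   parameter names, parsed through a whitelist (no function calls beyond
#'   elementary math), so model files remain data, not code.
#'
#' @param rate Name of the rate-constant parameter, or a fixed numeric value
#'   for a rate that is not estimated (e.g. a unit degradation rate in a
#'   non-dimensionalised model).
#' @param reactants Character vector of reactant species (repeat a name for a
#'   second-order self-reaction), or a named integer vector of multiplicities.
#'   The propensity order is independent of the stoichiometric change, so
#'   catalytic reactions (e.g. transcription from an active promoter) name the
#'   catalyst here while leaving it unchanged in the stoichiometry.
#' @param numerator Name of the maximal-rate parameter \eqn{\alpha}.
#' @param regulator Species whose count enters the Hill denominator.
#' @param exponent Name of the Hill-exponent parameter.
#' @param half_sat,sat_exponent,conc Optional inducer triplet: binding-constant
#'   parameter name, cooperativity parameter name and inducer concentration
#'   (same units as the binding constant).
#' @param text A formula as a string, e.g. `"k1 * A * B / (1 + B)"`.
#' @return An object of class `propensity_spec`.
#' @name propensity_spec
NULL

#' @rdname propensity_spec
#' @export
prop_mass_action <- function(rate, reactants = character()) {
  if (is.character(reactants)) {
    reactants <- table(reactants)
    reactants <- stats::setNames(as.integer(reactants), names(reactants))
  }
  stopifnot(is.character(rate) || is.numeric(rate), length(rate) == 1L)
  if (length(reactants) > 0L) {
    stopifnot(!is.null(names(reactants)), all(reactants >= 1L))
  }
  structure(
    list(kind = "mass_action", rate = rate,
         reactants = stats::setNames(as.integer(reactants), names(reactants))),
    class = "propensity_spec"
  )
}

#' @rdname propensity_spec
#' @export
prop_hill <- function(numerator, regulator, exponent,
                      half_sat = NULL, sat_exponent = NULL, conc = 0) {
  stopifnot(is.character(numerator), is.character(regulator),
            is.character(exponent))
  if (!is.null(half_sat)) stopifnot(is.character(half_sat),
                                    is.character(sat_exponent), conc >= 0)
  structure(
    list(kind = "hill", numerator = numerator, regulator = regulator,
         exponent = exponent, half_sat = half_sat,
         sat_exponent = sat_exponent, conc = conc),
    class = "propensity_spec"
  )
}

#' @rdname propensity_spec
#' @export
prop_expression <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  expr <- tryCatch(str2lang(text), error = function(e) {
    stop("cannot parse propensity expression: ", conditionMessage(e),
         call. = FALSE)
  })
  check_safe_expression(expr)
  structure(list(kind = "expression", text = text, expr = expr),
            class = "propensity_spec")
}

# Whitelisted AST walk: only arithmetic, parentheses and elementary math
# functions are allowed, so model files cannot execute arbitrary code.
check_safe_expression <- function(expr) {
  allowed_fns <- c("+", "-", "*", "/", "^", "(", "exp", "log", "sqrt", "abs",
                   "min", "max")
  walk <- function(e) {
    if (is.call(e)) {
      fn <- as.character(e[[1L]])
      if (!fn %in% allowed_fns) {
        stop("function '", fn, "' not allowed in propensity expressions",
             call. = FALSE)
      }
      for (i in seq_along(e)[-1L]) walk(e[[i]])
    } else if (!(is.name(e) || is.numeric(e))) {
      stop("propensity expressions may contain only names and numbers",
           call. = FALSE)
    }
    invisible(NULL)
  }
  walk(expr)
}

#' @export
print.propensity_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
format.propensity_spec <- function(x, ...) {
  switch(x$kind,
    mass_action = {
      terms <- mapply(function(sp, m) {
        if (m == 1L) sp else paste0("C(", sp, ",", m, ")")
      }, names(x$reactants), x$reactants)
      paste(c(x$rate, terms), collapse = " * ")
    },
    hill = {
      inner <- if (is.null(x$half_sat)) x$regulator else {
        sprintf("%s/(1 + %g/%s)^%s", x$regulator, x$conc, x$half_sat,
                x$sat_exponent)
      }
      sprintf("%s / (1 + (%s)^%s)", x$numerator, inner, x$exponent)
    },
    expression = x$text
  )
}

# All parameter / species names a propensity refers to.
propensity_symbols <- function(p) {
  switch(p$kind,
    mass_action = list(
      params = if (is.character(p$rate)) p$rate else character(),
      species = names(p$reactants)
    ),
    hill = list(
      params = c(p$numerator, p$exponent, p$half_sat, p$sat_exponent),
      species = p$regulator
    ),
    expression = {
      syms <- all.vars(p$expr)
      list(params = syms, species = syms)  # split against network later
    }
  )
}

# Evaluate one propensity at an integer state with named parameter values.
eval_propensity <- function(p, state, params) {
  switch(p$kind,
    mass_action = {
      a <- if (is.character(p$rate)) params[[p$rate]] else p$rate
      if (length(p$reactants)) {
        for (i in seq_along(p$reactants)) {
          x <- state[[names(p$reactants)[i]]]
          m <- p$reactants[[i]]
          a <- a * prod((x - seq_len(m) + 1) / seq_len(m))
        }
      }
      a
    },
    hill = {
      s <- 1
      if (!is.null(p$half_sat)) {
        s <- (1 + p$conc / params[[p$half_sat]])^(-params[[p$sat_exponent]])
      }
      params[[p$numerator]] /
        (1 + (state[[p$regulator]] * s)^params[[p$exponent]])
    },
    expression = {
      env <- list2env(c(as.list(state), as.list(params)), parent = baseenv())
      eval(p$expr, env)
    }
  )
}

# Serialise a propensity to plain lists for YAML round-tripping.
propensity_to_list <- function(p) {
  switch(p$kind,
    mass_action = list(kind = "mass_action", rate = p$rate,
                       reactants = as.list(p$reactants)),
    hill = {
      out <- list(kind = "hill", numerator = p$numerator,
                  regulator = p$regulator, exponent = p$exponent)
      if (!is.null(p$half_sat)) {
        out$half_sat <- p$half_sat
        out$sat_exponent <- p$sat_exponent
        out$conc <- p$conc
      }
      out
    },
    expression = list(kind = "expression", text = p$text)
  )
}

propensity_from_list <- function(x) {
  switch(x$kind,
    mass_action = prop_mass_action(
      x$rate,
      stats::setNames(as.integer(unlist(x$reactants)), names(x$reactants))
    ),
    hill = prop_hill(x$numerator, x$regulator, x$exponent,
                     half_sat = x$half_sat, sat_exponent = x$sat_exponent,
                     conc = if (is.null(x$conc)) 0 else x$conc),
    expression = prop_expression(x$text),
    stop("unknown propensity kind: ", x$kind, call. = FALSE)
  )
}
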