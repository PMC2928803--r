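#' Read and write model definition files
#'
#' Networks round-trip losslessly through a structured YAML file with keys
#' `species`, `reactions` (each with `name`, a `stoichiometry` map and a
#' `propensity` spec), `parameters` (name, bounds, optional true value) and
#' optional `observables` / `volume_label`. Propensity expressions are
#' stored as strings and re-parsed through the arithmetic whitelist on
#' reading, so model files remain data.
#'
#' @param network A [reaction_network].
#' @param path YAML file path.
#' @return `read_network_yaml()` returns the [reaction_network];
#'   `write_network_yaml()` returns `path` invisibly.
#' @export
write_network_yaml <- function(network, path) {
  stopifnot(inherits(network, "reaction_network"))
  reactions <- lapply(seq_along(network$reaction_names), function(j) {
    ch <- network$stoichiometry[j, ]
    ch <- ch[ch != 0]
    list(name = network$reaction_names[j],
         stoichiometry = as.list(ch),
         propensity = propensity_to_list(network$propensities[[j]]))
  })
  parameters <- lapply(seq_along(network$parameter_names), function(i) {
    out <- list(name = network$parameter_names[i],
                bounds = c(network$bounds$lower[i], network$bounds$upper[i]))
    if (!is.null(network$true_params)) {
      out$true_value <- unname(
        network$true_params[[network$parameter_names[i]]])
    }
    out
  })
  doc <- list(species = as.list(network$species), reactions = reactions,
              parameters = parameters,
              observables = as.list(network$observables))
  if (!is.null(network$volume_label)) doc$volume_label <- network$volume_label
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname write_network_yaml
#' @export
read_network_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  species <- unlist(doc$species)
  reactions <- lapply(doc$reactions, function(r) {
    changes <- stats::setNames(as.integer(unlist(r$stoichiometry)),
                               names(r$stoichiometry))
    reaction(r$name, changes, propensity_from_list(r$propensity))
  })
  parameters <- stats::setNames(
    lapply(doc$parameters, function(p) as.numeric(unlist(p$bounds))),
    vapply(doc$parameters, function(p) p$name, character(1))
  )
  truths <- vapply(doc$parameters, function(p) {
    if (is.null(p$true_value)) NA_real_ else as.numeric(p$true_value)
  }, numeric(1))
  true_params <- if (!anyNA(truths)) {
    stats::setNames(truths, names(parameters))
  }
  reaction_network(
    species = species, reactions = reactions, parameters = parameters,
    true_params = true_params,
    observables = if (is.null(doc$observables)) species
                  else unlist(doc$observables),
    volume_label = doc$volume_label
  )
}
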