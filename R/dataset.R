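#' Replicate-by-timepoint measurement datasets
#'
#' A `cme_dataset` holds the "experimental" side of every estimation
#' criterion: integer observations for `m` replicates (cells) at `n`
#' timepoints, for one or more observed species, plus provenance metadata
#' (generating model, true parameters when synthetic, measurement-noise
#' variance, seeds) that makes synthetic datasets fully reproducible and
#' scorable.
#'
#' @param observations An `m x n` integer matrix (single species) or an
#'   `m x n x s` array.
#' @param sample_times Strictly increasing numeric timepoints, length `n`.
#' @param species Character vector of observed species names, length `s`.
#' @param provenance Named list of metadata (free-form; generated datasets
#'   record `model`, `true_params`, `sigma2`, `x0`, `t0`, `seed`).
#' @return A `cme_dataset`.
#' @export
cme_dataset <- function(observations, sample_times, species = "X",
                        provenance = list()) {
  if (is.matrix(observations)) {
    observations <- array(observations,
                          dim = c(dim(observations), 1L))
  }
  stopifnot(is.array(observations), length(dim(observations)) == 3L)
  d <- dim(observations)
  stopifnot(d[1L] >= 1L, d[2L] == length(sample_times),
            d[3L] == length(species))
  if (length(sample_times) > 1L && any(diff(sample_times) <= 0)) {
    stop("sample_times must be strictly increasing", call. = FALSE)
  }
  dimnames(observations) <- list(NULL, NULL, species)
  structure(
    list(observations = observations, sample_times = sample_times,
         species = species, provenance = provenance),
    class = "cme_dataset"
  )
}

#' @export
print.cme_dataset <- function(x, ...) {
  d <- dim(x$observations)
  cat("<cme_dataset> ", d[1L], " replicates x ", d[2L], " timepoints x ",
      d[3L], " species (", paste(x$species, collapse = ", "), ")\n", sep = "")
  if (!is.null(x$provenance$model)) {
    cat("generated from:", x$provenance$model, "\n")
  }
  invisible(x)
}

#' @export
dim.cme_dataset <- function(x) dim(x$observations)

# Coerce the dataset (or a plain matrix) to the flat list of observation
# vectors used by the objectives: one element per (timepoint, species) pair,
# timepoints varying fastest.
dataset_observations <- function(dataset) {
  if (is.matrix(dataset)) {
    dataset <- cme_dataset(dataset, seq_len(ncol(dataset)))
  }
  stopifnot(inherits(dataset, "cme_dataset"))
  d <- dim(dataset$observations)
  out <- vector("list", d[2L] * d[3L])
  k <- 1L
  for (s in seq_len(d[3L])) {
    for (ti in seq_len(d[2L])) {
      out[[k]] <- as.integer(dataset$observations[, ti, s])
      k <- k + 1L
    }
  }
  out
}

# Accept a single density, a flat list, or a nested [[species]][[time]]
# list, and return the flat list aligned with dataset_observations().
as_density_grid <- function(model_density, obs) {
  if (inherits(model_density, "binned_density")) {
    model_density <- list(model_density)
  }
  if (length(model_density) && is.list(model_density[[1L]]) &&
      !inherits(model_density[[1L]], "binned_density")) {
    model_density <- unlist(model_density, recursive = FALSE)
  }
  if (length(model_density) != length(obs)) {
    stop("model densities do not match the dataset layout (need one per ",
         "timepoint and species)", call. = FALSE)
  }
  model_density
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.cme_dataset <- function(x, ...) {
  d <- dim(x$observations)
  tibble::tibble(
    replicate = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
    time = rep(rep(x$sample_times, each = d[1L]), times = d[3L]),
    species = rep(x$species, each = d[1L] * d[2L]),
    count = as.integer(x$observations)
  )
}

#' Write/read a dataset as TSV with a JSON provenance sidecar
#'
#' The TSV is wide — one row per (replicate, species), one column per
#' timepoint — and the sidecar (`<path>.json`) records sample times, species
#' and provenance so the dataset round-trips losslessly.
#'
#' @param dataset A [cme_dataset].
#' @param path TSV file path.
#' @return `write_dataset_tsv()`: `path`, invisibly; `read_dataset_tsv()`:
#'   the reconstructed [cme_dataset].
#' @export
write_dataset_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "cme_dataset"))
  d <- dim(dataset$observations)
  wide <- do.call(rbind, lapply(seq_len(d[3L]), function(s) {
    m <- dataset$observations[, , s, drop = FALSE]
    dim(m) <- d[1:2]
    df <- as.data.frame(m)
    names(df) <- paste0("t_", dataset$sample_times)
    cbind(data.frame(replicate = seq_len(d[1L]),
                     species = dataset$species[s]), df)
  }))
  readr::write_tsv(tibble::as_tibble(wide), path)
  prov <- dataset$provenance
  if (!is.null(prov$true_params)) {
    prov$true_params <- as.list(unlist(prov$true_params))  # keep names in JSON
  }
  sidecar <- list(format_version = 1L, sample_times = dataset$sample_times,
                  species = dataset$species, provenance = prov)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_dataset_tsv
#' @export
read_dataset_tsv <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  species <- sidecar$species
  times <- as.numeric(sidecar$sample_times)
  m <- max(wide$replicate)
  obs <- array(NA_integer_, dim = c(m, length(times), length(species)))
  for (s in seq_along(species)) {
    block <- wide[wide$species == species[s], paste0("t_", times)]
    obs[, , s] <- as.matrix(block)
  }
  prov <- sidecar$provenance
  if (!is.null(prov$true_params)) prov$true_params <- unlist(prov$true_params)
  cme_dataset(obs, times, species, provenance = as.list(prov))
}
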