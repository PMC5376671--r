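#' Construct a gene-network specification
#'
#' A `network_spec` defines a sigmoidal-relaxation ODE system for a set of
#' molecular species (mRNAs, proteins, microRNAs). Each species \eqn{X_i}
#' relaxes toward a logistic function of its summed regulatory input,
#' \deqn{dX_i/dt = \gamma_i (F(u_i) - X_i), \quad
#'       u_i = b_i + \sum_j \omega_{j \to i} X_j +
#'       \omega_{RA \to i}\,RA + \omega_{FGF \to i}\,FGF,}
#' with \eqn{F(u) = 1/(1 + e^{-\sigma u})}. All quantities are dimensionless;
#' one time unit corresponds to roughly one day of development.
#'
#' @param species Character vector of unique species identifiers.
#' @param gamma Named numeric vector of per-species relaxation rates
#'   (1/day), strictly positive.
#' @param sigma Sigmoid steepness shared across species, strictly positive.
#' @param basal Named numeric vector of basal offsets entering the sigmoid
#'   argument (the value of \eqn{u_i} in the absence of any regulator).
#' @param omega Numeric matrix of signed influence coefficients
#'   \eqn{\omega_{j\to i}}: rows are targets (species), columns are
#'   regulators (species plus the morphogens `"RA"` and `"FGF"`).
#' @param clamp_zero Character vector of species clamped at zero
#'   (used by the mir-x-null transformation); normally empty.
#'
#' @return An object of class `network_spec`.
#' @seealso [hox_basal_network()], [apply_mutant()], [derivatives()]
#' @export
#' @examples
#' spec <- network_spec(
#'   species = c("m", "p"),
#'   gamma = c(m = 5, p = 2), sigma = 10,
#'   basal = c(m = -0.3, p = -0.5),
#'   omega = matrix(c(0, 0, 1, 0, 1, 0, 0, 0),
#'     nrow = 2, byrow = TRUE,
#'     dimnames = list(c("m", "p"), c("m", "p", "RA", "FGF"))
#'   )
#' )
#' spec
network_spec <- function(species, gamma, sigma, basal, omega,
                         clamp_zero = character()) {
  species <- as.character(species)
  if (anyDuplicated(species)) {
    stop("species identifiers must be unique", call. = FALSE)
  }
  n <- length(species)
  regulators <- c(species, "RA", "FGF")

  gamma <- align_to_species(unlist(gamma), species, "gamma")
  basal <- align_to_species(unlist(basal), species, "basal")
  if (any(is.na(gamma)) || any(!is.finite(gamma)) || any(gamma < 0)) {
    stop("`gamma` must give a finite non-negative rate for every species",
      call. = FALSE
    )
  }
  assert_scalar_number(sigma, "sigma", positive = TRUE)
  if (any(is.na(basal)) || any(!is.finite(basal))) {
    stop("`basal` must give a finite offset for every species", call. = FALSE)
  }

  omega <- as.matrix(omega)
  if (is.null(rownames(omega)) || is.null(colnames(omega))) {
    stop("`omega` must have species row names and regulator column names",
      call. = FALSE
    )
  }
  if (!setequal(rownames(omega), species) ||
    !all(colnames(omega) %in% regulators)) {
    stop("`omega` rows must be the species; columns must be species, RA or FGF",
      call. = FALSE
    )
  }
  full <- matrix(0, n, n + 2L, dimnames = list(species, regulators))
  full[rownames(omega), colnames(omega)] <- omega
  if (any(!is.finite(full))) {
    stop("`omega` entries must be finite", call. = FALSE)
  }
  if (!all(clamp_zero %in% species)) {
    stop("`clamp_zero` must name known species", call. = FALSE)
  }

  structure(
    list(
      species = species, gamma = gamma, sigma = sigma,
      basal = basal, omega = full, clamp_zero = clamp_zero
    ),
    class = "network_spec"
  )
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> ", length(x$species), " species, sigma = ", x$sigma,
    "\n",
    sep = ""
  )
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  el <- edge_list(x)
  if (nrow(el) == 0L) {
    cat("  no interactions\n")
  } else {
    cat("  interactions:\n")
    for (i in seq_len(nrow(el))) {
      cat(sprintf(
        "    %s %s %s (%+.3g)\n", el$source[i],
        if (el$weight[i] >= 0) "->" else "-|", el$target[i], el$weight[i]
      ))
    }
  }
  if (length(x$clamp_zero)) {
    cat("  clamped at zero:", paste(x$clamp_zero, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Nonzero interactions of a network as a tibble
#'
#' @param spec A [network_spec()].
#' @return A tibble with columns `source`, `target`, `weight`.
#' @export
edge_list <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  idx <- which(spec$omega != 0, arr.ind = TRUE)
  tibble::tibble(
    source = colnames(spec$omega)[idx[, "col"]],
    target = rownames(spec$omega)[idx[, "row"]],
    weight = spec$omega[idx]
  ) |> dplyr::arrange(.data$target, .data$source)
}

#' Read / write a network specification as YAML
#'
#' The on-disk format stores species, per-species `gamma` and `basal`,
#' the shared `sigma`, and the nonzero interactions as a labelled edge list
#' (`source`, `target`, `weight`), with `RA` and `FGF` as morphogen sources.
#'
#' @param path File path.
#' @return `read_network_spec()` returns a [network_spec()];
#'   `write_network_spec()` returns `path` invisibly.
#' @export
read_network_spec <- function(path) {
  y <- yaml::read_yaml(path)
  omega <- matrix(0, length(y$species), length(y$species) + 2L,
    dimnames = list(y$species, c(y$species, "RA", "FGF"))
  )
  for (e in y$edges) {
    omega[e$target, e$source] <- e$weight
  }
  network_spec(
    species = y$species,
    gamma = unlist(y$gamma), sigma = y$sigma, basal = unlist(y$basal),
    omega = omega,
    clamp_zero = as.character(y$clamp_zero %||% character())
  )
}

#' @rdname read_network_spec
#' @param spec A [network_spec()].
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  el <- edge_list(spec)
  yaml::write_yaml(
    list(
      species = spec$species,
      sigma = spec$sigma,
      gamma = as.list(spec$gamma),
      basal = as.list(spec$basal),
      edges = purrr::pmap(el, \(source, target, weight) {
        list(source = source, target = target, weight = weight)
      }),
      clamp_zero = spec$clamp_zero
    ),
    path
  )
  invisible(path)
}

#' The calibrated basal Hoxa5/Hoxc8 network
#'
#' Returns the five-species network (Hoxa5 and Hoxc8 mRNA and protein plus
#' the hypothetical microRNA `mir_x`) used throughout the package. In the
#' basal network mir-x is present but unconnected: its candidate regulatory
#' edges are added by [instantiate_topology()]. The basal interactions are
#' RA activation of *Hoxa5* transcription, FGF activation of *Hoxc8*
#' transcription, asymmetric repression of *Hoxa5* transcription by Hoxc8
#' protein, and translation of each mRNA into its protein. Parameter values
#' are a documented calibration (shipped as
#' `extdata/basal_network.yaml`) chosen so that, without mir-x, noisy
#' morphogens produce overlapping, ragged Hoxa5/Hoxc8 expression, while the
#' consensus mir-x circuit sharpens the boundary.
#'
#' @return A [network_spec()].
#' @seealso [hox_consensus_network()], [consensus_topology()]
#' @export
hox_basal_network <- function() {
  read_network_spec(
    system.file("extdata", "basal_network.yaml",
      package = "hoxmir", mustWork = TRUE
    )
  )
}

#' The wild-type Hox-miRNA network with the consensus mir-x interactions
#'
#' The basal network plus the three consensus mir-x interactions recovered
#' by the topology screen: repression of mir-x by RA, repression of Hoxa5
#' translation by mir-x, and activation of mir-x by Hoxc8 protein.
#'
#' @param strength Magnitude applied to each consensus interaction.
#' @return A [network_spec()].
#' @export
hox_consensus_network <- function(strength = 1) {
  instantiate_topology(hox_basal_network(), consensus_topology(), strength)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Accept either a named vector (reordered by species) or an unnamed vector
# in species order.
align_to_species <- function(x, species, what) {
  if (is.null(names(x))) {
    if (length(x) != length(species)) {
      stop(sprintf("`%s` must have one value per species", what),
        call. = FALSE
      )
    }
    return(setNames(as.numeric(x), species))
  }
  x[species]
}
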