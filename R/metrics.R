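#' Binary expression calls for a species
#'
#' A cell is called "expressing" when its value strictly exceeds
#' `threshold` (default 0.5 units).
#'
#' @param result A `tissue_result`, or a `[replicate, cell, species]`
#'   snapshot array from [snapshot()].
#' @param species Species identifier.
#' @param t Time of the snapshot (default: final stored time); ignored if
#'   a snapshot array is supplied.
#' @param threshold Expression call threshold (strict inequality).
#' @return Logical matrix `replicate` x `cell`.
#' @export
expression_calls <- function(result, species, t = NULL, threshold = 0.5) {
  snap <- as_snapshot(result, t)
  if (!species %in% dimnames(snap)[[3L]]) {
    stop("species `", species, "` not present in snapshot", call. = FALSE)
  }
  vals <- snap[, , species, drop = FALSE]
  dim(vals) <- dim(snap)[1:2]
  vals > threshold
}

as_snapshot <- function(result, t = NULL) {
  if (inherits(result, "tissue_result")) {
    snapshot(result, t %||% max(result$times))
  } else {
    stopifnot(is.array(result), length(dim(result)) == 3L)
    result
  }
}

#' Occupancy profile: per-position fraction of expressing replicates
#'
#' @param calls Logical `replicate` x `cell` matrix from
#'   [expression_calls()].
#' @param positions Optional numeric vector of cell positions (defaults to
#'   cell index).
#' @return A tibble with columns `cell`, `position`, `occupancy`
#'   (fractions in `[0, 1]`).
#' @export
occupancy_profile <- function(calls, positions = NULL) {
  stopifnot(is.matrix(calls), nrow(calls) >= 1L)
  occ <- colMeans(calls)
  tibble::tibble(
    cell = seq_along(occ),
    position = positions %||% seq_along(occ),
    occupancy = unname(occ)
  )
}

profile_parts <- function(profile) {
  if (is.data.frame(profile)) {
    list(occ = profile$occupancy, pos = profile$position)
  } else {
    list(occ = as.numeric(profile), pos = seq_along(profile))
  }
}

#' Transition zone and transition width of an occupancy profile
#'
#' The transition zone is the positional envelope of cells whose occupancy
#' lies strictly between `lo` and `hi` (defaults 15% and 85%). The
#' transition width Omega is the zone extent counted in cells,
#' `(max - min + 1)` cell spacings; an empty zone (perfectly sharp
#' boundary) has width 0.
#'
#' @param profile Tibble from [occupancy_profile()] (or a bare numeric
#'   occupancy vector, positions taken as cell indices).
#' @param lo,hi Open-interval occupancy bounds.
#' @return A list with elements `start`, `end` (positions, `NA` if empty),
#'   `width`, and `empty`.
#' @export
transition_zone <- function(profile, lo = 0.15, hi = 0.85) {
  p <- profile_parts(profile)
  spacing <- spacing_of(p$pos)
  idx <- which(p$occ > lo & p$occ < hi)
  if (!length(idx)) {
    return(list(start = NA_real_, end = NA_real_, width = 0, empty = TRUE))
  }
  list(
    start = p$pos[min(idx)], end = p$pos[max(idx)],
    width = p$pos[max(idx)] - p$pos[min(idx)] + spacing, empty = FALSE
  )
}

spacing_of <- function(pos) {
  if (length(pos) > 1L) pos[2L] - pos[1L] else 1
}

#' Expression boundary position of an occupancy profile
#'
#' The boundary is the midpoint of the transition zone. For an empty zone
#' (perfectly sharp profile) it falls back to the midpoint between the
#' last position on the high side (occupancy >= `hi`) and the adjacent
#' first position on the low side (occupancy <= `lo`). A species expressed
#' everywhere or nowhere has no boundary (`NA`).
#'
#' @inheritParams transition_zone
#' @param zone Optional precomputed [transition_zone()].
#' @return Boundary position (same units as `position`), or `NA_real_`
#'   when undefined.
#' @export
boundary_position <- function(profile, zone = NULL, lo = 0.15, hi = 0.85) {
  p <- profile_parts(profile)
  zone <- zone %||% transition_zone(profile, lo, hi)
  high <- p$occ >= hi
  low <- p$occ <= lo
  # a boundary requires an expressing side and a silent side somewhere in
  # the domain; a species that never (or everywhere) reaches the high
  # occupancy bound has no defined expression boundary
  if (!any(high) || !any(low)) {
    return(NA_real_)
  }
  if (!zone$empty) {
    return((zone$start + zone$end) / 2)
  }
  # sharp step: midpoint between adjacent high/low cells
  flips <- which(high[-length(high)] != high[-1L])
  if (!length(flips)) {
    return(NA_real_)
  }
  mean(c(p$pos[flips[1L]], p$pos[flips[1L] + 1L]))
}

#' Boundary robustness score
#'
#' Sum of the two transition widths and the absolute distance between the
#' Hoxa5 and Hoxc8 expression boundaries,
#' \eqn{\Omega_{a5} + \Omega_{c8} + |\Delta_{a5-c8}|}; a low score means a
#' sharp, accurately positioned boundary. Any undefined component yields
#' `Inf`, ranking the topology last.
#'
#' @param omega_a5,omega_c8 Transition widths (length units).
#' @param delta Distance between the two expression boundaries.
#' @param weights Length-3 positive weights on the three components
#'   (default unweighted).
#' @return Scalar score (length units), `Inf` if any component is `NA`.
#' @export
robustness_score <- function(omega_a5, omega_c8, delta,
                             weights = c(1, 1, 1)) {
  stopifnot(length(weights) == 3L, all(weights >= 0))
  if (anyNA(c(omega_a5, omega_c8, delta))) {
    return(Inf)
  }
  weights[1L] * omega_a5 + weights[2L] * omega_c8 + weights[3L] * abs(delta)
}

#' Boundary report for a simulated tissue
#'
#' Computes, at time `t`, the expression calls and occupancy profiles of
#' the two proteins, their transition zones and widths, boundary midpoints,
#' the boundary distance Delta, and the robustness score.
#'
#' @param result A `tissue_result` from [run_development()].
#' @param t Snapshot time (default: final time).
#' @param threshold Expression call threshold.
#' @param lo,hi Transition-zone occupancy bounds.
#' @param species_a5,species_c8 Names of the two protein species.
#' @param weights Score weights, see [robustness_score()].
#' @return A one-row tibble of class `boundary_report` with columns
#'   `omega_a5`, `omega_c8`, `boundary_a5`, `boundary_c8`, `delta`,
#'   `score`, `time`. The occupancy profiles are attached as attribute
#'   `"profiles"` (a tibble with `species`, `cell`, `position`,
#'   `occupancy`).
#' @export
boundary_report <- function(result, t = NULL, threshold = 0.5,
                            lo = 0.15, hi = 0.85,
                            species_a5 = "hoxa5_protein",
                            species_c8 = "hoxc8_protein",
                            weights = c(1, 1, 1)) {
  stopifnot(inherits(result, "tissue_result"))
  snap <- as_snapshot(result, t)
  one <- function(sp) {
    calls <- expression_calls(snap, sp, threshold = threshold)
    prof <- occupancy_profile(calls, positions = result$positions)
    zone <- transition_zone(prof, lo, hi)
    list(
      prof = prof, zone = zone,
      boundary = boundary_position(prof, zone, lo, hi)
    )
  }
  a5 <- one(species_a5)
  c8 <- one(species_c8)
  delta <- a5$boundary - c8$boundary
  out <- tibble::tibble(
    omega_a5 = a5$zone$width, omega_c8 = c8$zone$width,
    boundary_a5 = a5$boundary, boundary_c8 = c8$boundary,
    delta = delta,
    score = robustness_score(
      a5$zone$width, c8$zone$width, delta,
      weights
    ),
    time = attr(snap, "time") %||% NA_real_
  )
  attr(out, "profiles") <- dplyr::bind_rows(
    dplyr::mutate(a5$prof, species = species_a5, .before = 1L),
    dplyr::mutate(c8$prof, species = species_c8, .before = 1L)
  )
  class(out) <- c("boundary_report", class(out))
  out
}

#' Coefficient of variation
#'
#' Sample standard deviation (denominator `n - 1`) divided by the mean;
#' the scale-free cell-to-cell variability statistic. Undefined (returns
#' `NA`) for a zero mean.
#'
#' @param values Numeric vector, length at least 2.
#' @return Scalar CV, or `NA_real_` when the mean is zero.
#' @export
coefficient_of_variation <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m == 0) {
    return(NA_real_)
  }
  stats::sd(values) / m
}

#' Histogram of expression values across cells and replicates
#'
#' Bins the values of one species at a snapshot into equal-width bins over
#' `[0, 1]`; counts sum to `cells x replicates`.
#'
#' @inheritParams expression_calls
#' @param bins Number of bins (>= 2).
#' @return A tibble with columns `bin_lo`, `bin_hi`, `mid`, `count`.
#' @export
expression_histogram <- function(result, species, t = NULL, bins = 20) {
  bins <- as.integer(bins)
  if (bins < 2L) stop("`bins` must be at least 2", call. = FALSE)
  snap <- as_snapshot(result, t)
  vals <- as.vector(snap[, , species])
  breaks <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(vals, breaks, rightmost.closed = TRUE), 1L),
    bins
  )
  counts <- tabulate(idx, nbins = bins)
  tibble::tibble(
    bin_lo = breaks[-(bins + 1L)], bin_hi = breaks[-1L],
    mid = (breaks[-(bins + 1L)] + breaks[-1L]) / 2,
    count = counts
  )
}
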