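#' Morphogen gradient parameters for the one-dimensional tissue
#'
#' Describes the deterministic, steady-state exponential gradients of RA
#' (sourced at the rostral end, position 0) and FGF (sourced at the caudal
#' end, position `domain_length`). Each gradient is
#' \eqn{M(x) = M^0 \exp(-x\sqrt{k/D})} with `x` the distance from that
#' morphogen's source boundary -- the steady state of a linear
#' reaction-diffusion system with degradation rate `k` (1/day) and
#' diffusion rate `D` (length^2/day). Cells sit at `n_cells` evenly spaced
#' centres spanning `[0, domain_length]`.
#'
#' @param M0_RA,M0_FGF Source strengths (dimensionless), non-negative. The
#'   calibrated default field pairs a shallow RA gradient (decay length
#'   0.5) with a steeper FGF gradient (decay length 0.3), matching the
#'   calibrated Hoxc8 induction threshold at the boundary position.
#' @param k_RA,k_FGF Degradation rates (1/day), strictly positive.
#' @param D_RA,D_FGF Diffusion rates (length^2/day), strictly positive.
#' @param domain_length Length of the rostrocaudal domain.
#' @param n_cells Number of cells (at least 2).
#' @return An object of class `gradient_params`.
#' @export
gradient_params <- function(M0_RA = 1, M0_FGF = 0.75,
                            k_RA = 1, k_FGF = 1,
                            D_RA = 0.25, D_FGF = 0.09,
                            domain_length = 1, n_cells = 100) {
  for (nm in c("k_RA", "k_FGF", "D_RA", "D_FGF", "domain_length")) {
    assert_scalar_number(get(nm), nm, positive = TRUE)
  }
  if (M0_RA < 0 || M0_FGF < 0) {
    stop("source strengths must be non-negative", call. = FALSE)
  }
  n_cells <- as.integer(n_cells)
  if (n_cells < 2L) stop("`n_cells` must be at least 2", call. = FALSE)
  structure(
    list(
      M0 = c(RA = M0_RA, FGF = M0_FGF),
      k = c(RA = k_RA, FGF = k_FGF),
      D = c(RA = D_RA, FGF = D_FGF),
      domain_length = domain_length, n_cells = n_cells
    ),
    class = "gradient_params"
  )
}

#' Cell-centre positions of a gradient configuration
#' @param params A [gradient_params()].
#' @return Numeric vector of length `n_cells` spanning `[0, domain_length]`.
#' @export
cell_positions <- function(params) {
  seq(0, params$domain_length, length.out = params$n_cells)
}

#' Deterministic steady-state gradient of one morphogen
#'
#' @param params A [gradient_params()].
#' @param morphogen `"RA"` or `"FGF"`.
#' @return A tibble with columns `cell`, `position`, `level`. RA decreases
#'   rostral to caudal; FGF decreases caudal to rostral.
#' @export
#' @examples
#' steady_gradient(gradient_params(n_cells = 5), "RA")
steady_gradient <- function(params, morphogen = c("RA", "FGF")) {
  stopifnot(inherits(params, "gradient_params"))
  morphogen <- match.arg(morphogen)
  pos <- cell_positions(params)
  x <- if (morphogen == "RA") pos else params$domain_length - pos
  lam <- sqrt(params$k[[morphogen]] / params$D[[morphogen]])
  tibble::tibble(
    cell = seq_along(pos), position = pos,
    level = params$M0[[morphogen]] * exp(-x * lam)
  )
}

# Base gradient as an (n_cells x 2) matrix, the engine's input format.
gradient_matrix <- function(params) {
  cbind(
    RA = steady_gradient(params, "RA")$level,
    FGF = steady_gradient(params, "FGF")$level
  )
}

#' Noise parameters for the morphogen field
#'
#' The RA and FGF levels experienced by each cell are perturbed by
#' multiplicative factors drawn once per `1/frequency` time interval
#' (piecewise-constant extrinsic noise), each factor uniform on
#' `(1 - amplitude, 1 + amplitude)` so the perturbation range is
#' proportional to the local mean concentration. Factors are independent
#' per morphogen and per interval, and (by default) per cell.
#'
#' @param frequency Noise frequency \eqn{\omega} in 1/day (default 10).
#' @param amplitude Fractional amplitude \eqn{\eta} in `[0, 1)`
#'   (default 0.3).
#' @param per_cell If `TRUE` (default) each cell receives an independent
#'   factor, modelling local morphogen fluctuations; if `FALSE` one factor
#'   per morphogen is shared across the domain.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(frequency = 10, amplitude = 0.3, per_cell = TRUE) {
  assert_scalar_number(frequency, "frequency", positive = TRUE)
  assert_scalar_number(amplitude, "amplitude")
  if (amplitude < 0 || amplitude >= 1) {
    stop("`amplitude` must be in [0, 1)", call. = FALSE)
  }
  structure(
    list(
      frequency = frequency, amplitude = amplitude,
      per_cell = isTRUE(per_cell)
    ),
    class = "noise_params"
  )
}

#' Sample a piecewise-constant noisy morphogen trace
#'
#' Draws multiplicative perturbation factors for every noise interval over
#' `duration` days and combines them with the deterministic base gradient.
#' The trace is evaluable at any `(t, cell)` via [evaluate_trace()] and is
#' bit-reproducible from `seed`.
#'
#' @param gradient A [gradient_params()], or an `n_cells` x 2 matrix of
#'   base `RA`/`FGF` levels (used for homogeneous stimulation protocols).
#' @param noise A [noise_params()].
#' @param duration Days covered by the trace (> 0).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return An object of class `morphogen_trace`.
#' @export
sample_noise_trace <- function(gradient, noise = noise_params(), duration,
                               seed = NULL) {
  stopifnot(inherits(noise, "noise_params"))
  assert_scalar_number(duration, "duration", positive = TRUE)
  base <- if (inherits(gradient, "gradient_params")) {
    gradient_matrix(gradient)
  } else {
    stopifnot(is.matrix(gradient), ncol(gradient) == 2L)
    colnames(gradient) <- c("RA", "FGF")
    gradient
  }
  n_cells <- nrow(base)
  n_int <- ceiling(duration * noise$frequency - 1e-9)
  n_draw <- if (noise$per_cell) n_cells else 1L
  eta <- noise$amplitude
  factors <- with_seed(seed, {
    array(
      runif(n_int * n_draw * 2L, min = 1 - eta, max = 1 + eta),
      dim = c(n_int, n_draw, 2L),
      dimnames = list(NULL, NULL, c("RA", "FGF"))
    )
  })
  structure(
    list(
      base = base, factors = factors, n_cells = n_cells,
      interval = 1 / noise$frequency, duration = duration,
      n_intervals = n_int, noise = noise, seed = seed
    ),
    class = "morphogen_trace"
  )
}

# Per-interval morphogen matrices (list of n_cells x 2), the engine input.
trace_matrices <- function(trace) {
  lapply(seq_len(trace$n_intervals), function(i) {
    f <- trace$factors[i, , , drop = TRUE]
    if (is.null(dim(f))) { # shared factor across cells
      sweep(trace$base, 2L, f, `*`)
    } else {
      trace$base * f
    }
  })
}

#' Evaluate a morphogen trace at a time and cell
#'
#' Returns the base gradient at the cell multiplied by the perturbation
#' factor of the interval containing `t`. Right-continuous at interval
#' boundaries; `t = duration` falls in the final interval.
#'
#' @param trace A [sample_noise_trace()] result.
#' @param t Time in days, within `[0, duration]`.
#' @param cell Cell index.
#' @return Named numeric vector with elements `RA` and `FGF`.
#' @export
evaluate_trace <- function(trace, t, cell) {
  stopifnot(inherits(trace, "morphogen_trace"))
  if (t < 0 || t > trace$duration + 1e-9) {
    stop("`t` outside trace duration", call. = FALSE)
  }
  if (cell < 1L || cell > trace$n_cells) {
    stop("`cell` out of range", call. = FALSE)
  }
  iv <- min(floor(t / trace$interval) + 1L, trace$n_intervals)
  d <- if (trace$noise$per_cell) cell else 1L
  setNames(
    trace$base[cell, ] * trace$factors[iv, d, ],
    c("RA", "FGF")
  )
}

#' @export
print.morphogen_trace <- function(x, ...) {
  cat(sprintf(
    "<morphogen_trace> %d cells, %d intervals of %.3g day (%.3g days), eta = %.3g%s\n",
    x$n_cells, x$n_intervals, x$interval, x$duration, x$noise$amplitude,
    if (x$noise$per_cell) ", per-cell" else ", shared"
  ))
  invisible(x)
}

#' @describeIn sample_noise_trace Long-format view of the sampled factors
#'   (columns `interval`, `morphogen`, `cell`, `factor`), suitable for CSV
#'   provenance export.
#' @param x A `morphogen_trace`.
#' @param ... Unused.
#' @export
tidy.morphogen_trace <- function(x, ...) {
  n_draw <- dim(x$factors)[2L]
  tibble::tibble(
    interval = rep(seq_len(x$n_intervals), times = 2L * n_draw),
    morphogen = rep(c("RA", "FGF"), each = x$n_intervals * n_draw),
    cell = rep(rep(seq_len(n_draw), each = x$n_intervals), times = 2L),
    factor = as.vector(x$factors)
  )
}
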