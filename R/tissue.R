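#' Tissue simulation configuration
#'
#' @param n_cells Cells along the rostrocaudal axis (default 100).
#' @param n_replicates Independent noisy replicates of the tissue
#'   (default 50).
#' @param t_dev Days of morphogen exposure after the pre-morphogen
#'   equilibration (default 5).
#' @param dt Integration step in days (default 0.01).
#' @param store_every Days between stored snapshots (default 0.1, one noise
#'   interval at the default noise frequency).
#' @param relax_tol,relax_t_max Tolerance and time cap for the
#'   pre-morphogen relaxation (see [relax_to_steady_state()]).
#' @return An object of class `tissue_config`.
#' @export
tissue_config <- function(n_cells = 100, n_replicates = 50, t_dev = 5,
                          dt = 0.01, store_every = 0.1,
                          relax_tol = 1e-6, relax_t_max = 100) {
  n_cells <- as.integer(n_cells)
  n_replicates <- as.integer(n_replicates)
  if (n_cells < 2L) stop("`n_cells` must be at least 2", call. = FALSE)
  if (n_replicates < 1L) stop("`n_replicates` must be >= 1", call. = FALSE)
  assert_scalar_number(t_dev, "t_dev", positive = TRUE)
  assert_scalar_number(dt, "dt", positive = TRUE)
  structure(
    list(
      n_cells = n_cells, n_replicates = n_replicates, t_dev = t_dev,
      dt = dt, store_every = store_every,
      relax_tol = relax_tol, relax_t_max = relax_t_max
    ),
    class = "tissue_config"
  )
}

new_tissue_result <- function(states, times, species, positions, protocol,
                              spec, config, seed, replicate_seeds) {
  structure(
    list(
      states = states, # [replicate, cell, species, time]
      times = times, species = species, positions = positions,
      protocol = protocol, spec = spec, config = config,
      seed = seed, replicate_seeds = replicate_seeds
    ),
    class = "tissue_result"
  )
}

#' @export
print.tissue_result <- function(x, ...) {
  d <- dim(x$states)
  cat(sprintf(
    "<tissue_result> protocol = %s: %d replicate(s) x %d cells x %d species x %d times (0..%g days)\n",
    x$protocol, d[1L], d[2L], d[3L], d[4L], max(x$times)
  ))
  invisible(x)
}

#' Simulate boundary development in the one-dimensional tissue
#'
#' Runs the developmental protocol: every cell is first relaxed to the
#' morphogen-free steady state, then the noisy RA/FGF gradients are
#' switched on and the tissue is integrated for `t_dev` days. Each
#' replicate receives an independently sampled noise trace; all randomness
#' derives from `seed`, and replicate `k` is reproducible in isolation from
#' its recorded per-replicate seed.
#'
#' @param spec A [network_spec()].
#' @param tissue A [tissue_config()].
#' @param gradient A [gradient_params()]; its `n_cells` must match
#'   `tissue$n_cells`.
#' @param noise A [noise_params()].
#' @param seed Master integer seed.
#' @return A `tissue_result` whose `states` array is indexed
#'   `[replicate, cell, species, time]`; see [snapshot()] and
#'   [tidy.tissue_result()].
#' @export
#' @examples
#' res <- run_development(hox_consensus_network(),
#'   tissue = tissue_config(n_cells = 30, n_replicates = 2, t_dev = 1),
#'   gradient = gradient_params(n_cells = 30), seed = 1
#' )
#' res
run_development <- function(spec, tissue = tissue_config(),
                            gradient = gradient_params(n_cells = tissue$n_cells),
                            noise = noise_params(), seed = 1L) {
  stopifnot(
    inherits(spec, "network_spec"), inherits(tissue, "tissue_config"),
    inherits(gradient, "gradient_params"), inherits(noise, "noise_params")
  )
  if (gradient$n_cells != tissue$n_cells) {
    stop("`gradient$n_cells` must match `tissue$n_cells`", call. = FALSE)
  }
  base <- gradient_matrix(gradient)
  run_protocol(spec, tissue, base, noise, seed,
    protocol = "development",
    positions = cell_positions(gradient)
  )
}

#' Simulate homogeneous RA-only differentiation
#'
#' Models a group of identical cells exposed to a uniform RA step with no
#' FGF, mimicking RA-driven motor-neuron differentiation of an ES-cell
#' culture. Each cell experiences an independent noisy RA input; the full
#' time course is returned for histogram and response-delay analyses.
#'
#' @param spec A [network_spec()].
#' @param n_cells_group Number of cells in the group (default 200).
#' @param ra_level RA step amplitude applied at `t = 0` (dimensionless,
#'   non-negative). The default (0.1) is a sub-saturating dose just above
#'   the calibrated Hoxa5 transcription threshold, so that multiplicative
#'   input noise spans the activation threshold as it does at the
#'   prospective boundary; use 1 for a saturating step.
#' @param noise A [noise_params()].
#' @param duration Days of stimulation to simulate (default 5).
#' @param dt,store_every Integration step and storage cadence, days.
#' @param relax_tol,relax_t_max Pre-stimulation relaxation settings.
#' @param seed Master integer seed.
#' @return A `tissue_result` (single replicate; cells are the population).
#' @export
run_differentiation <- function(spec, n_cells_group = 200, ra_level = 0.1,
                                noise = noise_params(), duration = 5,
                                dt = 0.01, store_every = 0.1,
                                relax_tol = 1e-6, relax_t_max = 100,
                                seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  if (ra_level < 0) stop("`ra_level` must be non-negative", call. = FALSE)
  tissue <- tissue_config(
    n_cells = n_cells_group, n_replicates = 1L, t_dev = duration,
    dt = dt, store_every = store_every,
    relax_tol = relax_tol, relax_t_max = relax_t_max
  )
  base <- matrix(c(ra_level, 0), tissue$n_cells, 2L,
    byrow = TRUE, dimnames = list(NULL, c("RA", "FGF"))
  )
  run_protocol(spec, tissue, base, noise, seed,
    protocol = "differentiation",
    positions = seq_len(tissue$n_cells)
  )
}

# Shared driver: pre-relax (once; cells are identical before morphogens),
# then integrate each replicate under its own noise trace.
run_protocol <- function(spec, tissue, base, noise, seed, protocol,
                         positions) {
  ss <- relax_to_steady_state(spec,
    tol = tissue$relax_tol, t_max = tissue$relax_t_max
  )
  eng <- build_engine(spec, tissue$n_cells)
  S0 <- init_state_matrix(spec, ss, tissue$n_cells)

  rep_seeds <- derive_seeds(seed, tissue$n_replicates)
  n_times <- round(tissue$t_dev / tissue$store_every) + 1L
  states <- array(NA_real_,
    dim = c(
      tissue$n_replicates, tissue$n_cells, length(spec$species), n_times
    ),
    dimnames = list(NULL, NULL, spec$species, NULL)
  )
  times <- NULL
  for (r in seq_len(tissue$n_replicates)) {
    trace <- sample_noise_trace(base, noise, tissue$t_dev,
      seed = rep_seeds[r]
    )
    res <- tryCatch(
      engine_integrate(
        eng, S0, trace_matrices(trace), trace$interval,
        tissue$t_dev, tissue$dt, tissue$store_every
      ),
      error = function(e) {
        stop(sprintf("replicate %d: %s", r, conditionMessage(e)),
          call. = FALSE
        )
      }
    )
    states[r, , , ] <- res$states
    times <- res$times
  }
  new_tissue_result(
    states, times, spec$species, positions, protocol,
    spec, tissue, seed, rep_seeds
  )
}

#' Extract the tissue state at a given time
#'
#' Returns the stored slice nearest to `t` (storage cadence
#' `config$store_every` days).
#'
#' @param result A `tissue_result`.
#' @param t Time in days within the simulated span.
#' @return A 3-d array `[replicate, cell, species]`, with attribute
#'   `"time"` giving the stored time actually used.
#' @export
snapshot <- function(result, t) {
  stopifnot(inherits(result, "tissue_result"))
  if (t < min(result$times) - 1e-9 || t > max(result$times) + 1e-9) {
    stop("`t` outside the simulated time span", call. = FALSE)
  }
  i <- which.min(abs(result$times - t))
  out <- result$states[, , , i, drop = FALSE]
  dim(out) <- dim(result$states)[1:3]
  dimnames(out) <- list(NULL, NULL, result$species)
  attr(out, "time") <- result$times[i]
  out
}

#' @describeIn run_development Long-format view of a simulation
#'   (`replicate`, `cell`, `position`, `species`, `time`, `value`).
#' @param x A `tissue_result`.
#' @param ... Unused.
#' @export
tidy.tissue_result <- function(x, ...) {
  d <- dim(x$states)
  tibble::tibble(
    replicate = rep(seq_len(d[1L]), times = prod(d[2:4])),
    cell = rep(rep(seq_len(d[2L]), each = d[1L]), times = prod(d[3:4])),
    species = rep(rep(x$species, each = prod(d[1:2])), times = d[4L]),
    time = rep(x$times, each = prod(d[1:3])),
    value = as.vector(x$states)
  ) |>
    dplyr::mutate(position = x$positions[.data$cell], .after = "cell")
}

#' @describeIn run_development One-row summary of a simulation.
#' @export
glance.tissue_result <- function(x, ...) {
  d <- dim(x$states)
  tibble::tibble(
    protocol = x$protocol, n_replicates = d[1L], n_cells = d[2L],
    n_species = d[3L], n_times = d[4L], t_end = max(x$times),
    seed = x$seed
  )
}

#' Time for the population-mean signal to reach half its final value
#'
#' Computes the mean of `species` over replicates and cells at every stored
#' time, takes the value at the final time as the plateau, and returns the
#' first time the mean crosses half of it (linear interpolation between
#' stored points). Used to quantify the feed-forward-loop delay of Hoxa5
#' protein activation.
#'
#' @param result A `tissue_result`.
#' @param species Species identifier (default `"hoxa5_protein"`).
#' @return Half-maximum time in days (`NA` if the mean never crosses).
#' @export
half_max_time <- function(result, species = "hoxa5_protein") {
  stopifnot(inherits(result, "tissue_result"))
  if (!species %in% result$species) {
    stop("unknown species `", species, "`", call. = FALSE)
  }
  k <- match(species, result$species)
  traj <- apply(result$states[, , k, , drop = FALSE], 4L, mean)
  target <- traj[length(traj)] / 2
  above <- which(traj >= target)
  if (!length(above)) {
    return(NA_real_)
  }
  i <- above[1L]
  if (i == 1L) {
    return(result$times[1L])
  }
  t0 <- result$times[i - 1L]
  t1 <- result$times[i]
  y0 <- traj[i - 1L]
  y1 <- traj[i]
  t0 + (target - y0) / (y1 - y0) * (t1 - t0)
}
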