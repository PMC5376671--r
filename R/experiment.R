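#' Run a packaged experiment from a configuration
#'
#' Drives one of the canned experiment protocols from a configuration list
#' or YAML/JSON file and writes its artifacts (long-format CSV results,
#' JSON summaries, a JSON log with seeds and runtimes, and a copy of the
#' resolved configuration) to `out_dir`. Re-running with the same
#' configuration and seed reproduces the outputs.
#'
#' Protocols:
#' * `"develop"`: noisy 1-d development ([run_development()]) plus a
#'   [boundary_report()].
#' * `"differentiate"`: homogeneous RA stimulation
#'   ([run_differentiation()]).
#' * `"screen"`: the 324-topology screen ([run_screen()]) with the
#'   consensus summary.
#' * `"sweep"`: the interaction-strength sweep ([strength_sweep()]).
#' * `"mutants"`: paired wild-type / Dicer-null / fast-mir-x development
#'   runs under identical noise seeds, with their boundary reports.
#'
#' Configuration fields: `protocol` (required), `seed` (required), and
#' optional `network` (path to a YAML network; default the calibrated
#' consensus network, or the basal network for `screen`/`sweep`),
#' `mutant`, `n_cells`, `n_replicates`, `t_dev`, `dt`, `noise_amplitude`,
#' `noise_frequency`, `strength`, `strengths`, `ra_level`, `duration`.
#'
#' @param config Path to a YAML/JSON configuration file, or an equivalent
#'   named list.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results and the paths of
#'   all files written.
#' @export
run_experiment <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop("`config` must be a list or a path to a YAML/JSON file",
      call. = FALSE
    )
  }
  protocols <- c("develop", "differentiate", "screen", "sweep", "mutants")
  missing <- setdiff("protocol", names(config))
  if (is.null(config$seed)) missing <- c(missing, "seed")
  if (length(missing)) {
    stop("configuration is missing required field(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!config$protocol %in% protocols) {
    stop("`protocol` must be one of: ", paste(protocols, collapse = ", "),
      call. = FALSE
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t_start <- Sys.time()

  spec <- if (!is.null(config$network)) {
    read_network_spec(config$network)
  } else if (config$protocol %in% c("screen", "sweep")) {
    hox_basal_network()
  } else {
    hox_consensus_network()
  }
  if (!is.null(config$mutant)) spec <- apply_mutant(spec, config$mutant)

  noise <- noise_params(
    frequency = config$noise_frequency %||% 10,
    amplitude = config$noise_amplitude %||% 0.3
  )
  tissue <- tissue_config(
    n_cells = config$n_cells %||% 100,
    n_replicates = config$n_replicates %||%
      if (config$protocol %in% c("screen", "sweep")) 10 else 50,
    t_dev = config$t_dev %||% 5,
    dt = config$dt %||% 0.01
  )
  gradient <- gradient_params(n_cells = tissue$n_cells)
  seed <- config$seed

  paths <- character()
  save_csv <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  save_json <- function(x, name) {
    p <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths[[name]] <<- p
  }

  results <- switch(config$protocol,
    develop = {
      res <- run_development(spec, tissue, gradient, noise, seed = seed)
      rep <- boundary_report(res)
      save_csv(tidy(res), "tissue")
      save_csv(attr(rep, "profiles"), "occupancy")
      save_json(as.list(tibble::as_tibble(rep)), "boundary_report")
      list(result = res, report = rep)
    },
    differentiate = {
      res <- run_differentiation(spec,
        n_cells_group = config$n_cells %||% 200,
        ra_level = config$ra_level %||% 0.35,
        noise = noise, duration = config$duration %||% 5,
        seed = seed
      )
      save_csv(tidy(res), "differentiation")
      list(result = res)
    },
    screen = {
      sc <- run_screen(spec,
        strength = config$strength %||% 1,
        tissue = tissue, gradient = gradient, noise = noise, seed = seed
      )
      save_csv(tidy(sc), "screen")
      save_json(list(
        consensus = consensus_interactions(sc),
        glance = as.list(glance(sc))
      ), "consensus")
      list(screen = sc)
    },
    sweep = {
      sw <- strength_sweep(
        strengths = unlist(config$strengths) %||% seq(0.2, 1.2, by = 0.2),
        base = spec, tissue = tissue, gradient = gradient, noise = noise,
        seed = seed
      )
      save_csv(sw, "sweep")
      save_json(list(
        stable_range = attr(sw, "stable_range"),
        modal_winner = attr(sw, "modal_winner")
      ), "sweep_summary")
      list(sweep = sw)
    },
    mutants = {
      kinds <- c("wild_type", "dicer_null", "mirx_fast")
      runs <- purrr::map(kinds, function(k) {
        run_development(apply_mutant(spec, k), tissue, gradient, noise,
          seed = seed # identical noise seeds across conditions
        )
      })
      reps <- purrr::map2_dfr(runs, kinds, function(r, k) {
        dplyr::mutate(tibble::as_tibble(boundary_report(r)),
          condition = k, .before = 1L
        )
      })
      save_csv(reps, "mutant_boundary_reports")
      list(results = setNames(runs, kinds), reports = reps)
    }
  )

  log <- list(
    package_version = as.character(utils::packageVersion("hoxmir")),
    r_version = R.version.string,
    protocol = config$protocol, seed = seed,
    runtime_seconds = as.numeric(difftime(Sys.time(), t_start,
      units = "secs"
    )),
    config = config
  )
  save_json(log, "log")
  save_json(config, "config")
  invisible(c(results, list(paths = paths)))
}

#' Compare two simulated conditions
#'
#' Computes the differences in boundary metrics and temporal response
#' between two tissue simulations sharing the same geometry: difference in
#' Hoxa5/Hoxc8 transition widths and score, difference in Hoxa5
#' half-maximum response time, and the ratio of across-cell Hoxa5-protein
#' variances at an early time point.
#'
#' @param result_a,result_b `tissue_result` objects with identical cell
#'   counts and time grids (condition A minus / over condition B).
#' @param early_t Early time point (days) for the variance ratio
#'   (default 1).
#' @param species Species compared temporally (default Hoxa5 protein).
#' @return A one-row tibble: `d_omega_a5`, `d_omega_c8`, `d_score`,
#'   `d_half_max_time`, `early_var_ratio`.
#' @export
compare_conditions <- function(result_a, result_b, early_t = 1,
                               species = "hoxa5_protein") {
  stopifnot(
    inherits(result_a, "tissue_result"),
    inherits(result_b, "tissue_result")
  )
  if (dim(result_a$states)[2L] != dim(result_b$states)[2L] ||
    !isTRUE(all.equal(result_a$times, result_b$times))) {
    stop("conditions have incompatible geometry or time grids",
      call. = FALSE
    )
  }
  ra <- boundary_report(result_a)
  rb <- boundary_report(result_b)
  early_var <- function(res) {
    snap <- snapshot(res, early_t)
    stats::var(as.vector(snap[, , species]))
  }
  tibble::tibble(
    d_omega_a5 = ra$omega_a5 - rb$omega_a5,
    d_omega_c8 = ra$omega_c8 - rb$omega_c8,
    d_score = ra$score - rb$score,
    d_half_max_time = half_max_time(result_a, species) -
      half_max_time(result_b, species),
    early_var_ratio = early_var(result_a) / early_var(result_b)
  )
}
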