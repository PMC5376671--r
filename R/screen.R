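#' Enumerate all candidate mir-x network topologies
#'
#' The hypothetical microRNA mir-x has six candidate interactions: four
#' incoming edges (from RA, FGF, Hoxa5 protein and Hoxc8 protein), each
#' absent, inhibitory or activating (`0`, `-1`, `+1`), and two outgoing
#' translational-repression edges (onto Hoxa5 protein and Hoxc8 protein),
#' each absent or inhibitory (`0`, `-1`) since a miRNA silences, but does
#' not activate, translation of its targets. The full factorial set is
#' \eqn{3^4 \times 2^2 = 324} topologies, returned in a fixed mixed-radix
#' order with a canonical `topology_id` from 1 to 324 (id 1 is the basal
#' network with no mir-x edges).
#'
#' @return A tibble with columns `topology_id`, `ra_to_mirx`,
#'   `fgf_to_mirx`, `a5p_to_mirx`, `c8p_to_mirx`, `mirx_to_a5p`,
#'   `mirx_to_c8p`.
#' @export
enumerate_topologies <- function() {
  grid <- expand.grid(
    mirx_to_c8p = c(0, -1),
    mirx_to_a5p = c(0, -1),
    c8p_to_mirx = c(0, -1, 1),
    a5p_to_mirx = c(0, -1, 1),
    fgf_to_mirx = c(0, -1, 1),
    ra_to_mirx = c(0, -1, 1),
    KEEP.OUT.ATTRS = FALSE
  )
  tibble::as_tibble(grid) |>
    dplyr::select(
      "ra_to_mirx", "fgf_to_mirx", "a5p_to_mirx", "c8p_to_mirx",
      "mirx_to_a5p", "mirx_to_c8p"
    ) |>
    dplyr::mutate(topology_id = dplyr::row_number(), .before = 1L)
}

topology_edge_cols <- c(
  "ra_to_mirx", "fgf_to_mirx", "a5p_to_mirx", "c8p_to_mirx",
  "mirx_to_a5p", "mirx_to_c8p"
)

# source/target species of each candidate edge
topology_edge_map <- list(
  ra_to_mirx = c("RA", "mir_x"),
  fgf_to_mirx = c("FGF", "mir_x"),
  a5p_to_mirx = c("hoxa5_protein", "mir_x"),
  c8p_to_mirx = c("hoxc8_protein", "mir_x"),
  mirx_to_a5p = c("mir_x", "hoxa5_protein"),
  mirx_to_c8p = c("mir_x", "hoxc8_protein")
)

#' The consensus mir-x topology
#'
#' The three-interaction assignment recovered as the screen consensus:
#' RA represses mir-x, mir-x represses Hoxa5 translation, and Hoxc8
#' protein activates mir-x (all other candidate edges absent). Together
#' with the basal RA activation of *Hoxa5* these form two coherent
#' feed-forward loops through mir-x.
#'
#' @return A one-row tibble in the format of [enumerate_topologies()]
#'   (including its canonical `topology_id`).
#' @export
consensus_topology <- function() {
  enumerate_topologies() |>
    dplyr::filter(
      .data$ra_to_mirx == -1, .data$fgf_to_mirx == 0,
      .data$a5p_to_mirx == 0, .data$c8p_to_mirx == 1,
      .data$mirx_to_a5p == -1, .data$mirx_to_c8p == 0
    )
}

#' Add the mir-x edges of a topology to a base network
#'
#' Each nonzero edge value `v` of the assignment becomes an influence
#' coefficient `v * strength` in the returned network; the base network is
#' not modified.
#'
#' @param base A [network_spec()] containing `mir_x`.
#' @param topology A one-row tibble (or named vector/list) with the six
#'   edge columns of [enumerate_topologies()].
#' @param strength Positive magnitude applied to every nonzero edge.
#' @return A new [network_spec()].
#' @export
instantiate_topology <- function(base, topology, strength = 1) {
  stopifnot(inherits(base, "network_spec"))
  assert_scalar_number(strength, "strength", positive = TRUE)
  if (is.data.frame(topology)) {
    stopifnot(nrow(topology) == 1L)
    topology <- as.list(topology)
  }
  out <- base
  for (edge in topology_edge_cols) {
    v <- topology[[edge]]
    if (is.null(v)) stop("topology is missing edge `", edge, "`",
        call. = FALSE
      )
    if (v == 0) next
    st <- topology_edge_map[[edge]]
    if (!all(setdiff(st, c("RA", "FGF")) %in% base$species)) {
      stop("edge `", edge, "` references species absent from the network",
        call. = FALSE
      )
    }
    out$omega[st[2L], st[1L]] <- v * strength
  }
  out
}

#' Score one network topology by boundary robustness
#'
#' Runs the developmental tissue simulation in one or more independent
#' replicate batches and evaluates the [boundary_report()] score on the
#' final snapshot of each batch (the occupancy profile of a batch pools
#' its replicates).
#'
#' @param spec A [network_spec()] (typically from
#'   [instantiate_topology()]).
#' @param tissue A [tissue_config()]; `n_replicates` is the replicate
#'   budget per batch.
#' @param gradient A [gradient_params()].
#' @param noise A [noise_params()].
#' @param n_batches Number of independent batches (default 1).
#' @param seed Integer seed.
#' @return A tibble with one row per batch: `batch`, `score`, `omega_a5`,
#'   `omega_c8`, `delta`.
#' @export
score_topology <- function(spec, tissue = tissue_config(n_replicates = 10),
                           gradient = gradient_params(n_cells = tissue$n_cells),
                           noise = noise_params(), n_batches = 1L,
                           seed = 1L) {
  batch_seeds <- derive_seeds(seed, n_batches)
  purrr::map_dfr(seq_len(n_batches), function(b) {
    res <- run_development(spec, tissue, gradient, noise,
      seed = batch_seeds[b]
    )
    rep <- boundary_report(res)
    tibble::tibble(
      batch = b, score = rep$score, omega_a5 = rep$omega_a5,
      omega_c8 = rep$omega_c8, delta = rep$delta
    )
  })
}

#' Screen mir-x topologies by boundary robustness
#'
#' Instantiates each topology on the base network at the given interaction
#' strength, simulates the noisy developmental protocol, scores the
#' resulting Hoxa5/Hoxc8 boundary, and ranks all topologies by mean score
#' (ascending; ties broken by canonical id). Per-topology seeds are
#' derived from the master seed and the canonical topology id, so results
#' are independent of execution order and a partial screen of a topology
#' subset reproduces the full screen's rows.
#'
#' @param base Base [network_spec()] (default [hox_basal_network()]).
#' @param strength Interaction strength applied to candidate edges.
#' @param topologies Tibble of topologies to score (default: all 324).
#' @param tissue A [tissue_config()]; its `n_replicates` is the
#'   per-topology replicate budget per batch (default 10).
#' @param gradient,noise Field configuration, see [gradient_params()] and
#'   [noise_params()].
#' @param n_batches Independent score batches per topology; with more than
#'   one, `score_sd` reports the Monte-Carlo spread.
#' @param seed Master integer seed.
#' @param progress Print a progress line every 50 topologies.
#' @return A `screen_result` tibble: the topology columns plus
#'   `mean_score`, `score_sd`, `omega_a5`, `omega_c8`, `delta` (batch
#'   means) and `rank`.
#' @export
run_screen <- function(base = hox_basal_network(), strength = 1,
                       topologies = enumerate_topologies(),
                       tissue = tissue_config(n_replicates = 10),
                       gradient = gradient_params(n_cells = tissue$n_cells),
                       noise = noise_params(), n_batches = 1L, seed = 1L,
                       progress = FALSE) {
  all_seeds <- derive_seeds(seed, 324L) # indexed by canonical topology id
  rows <- purrr::map_dfr(seq_len(nrow(topologies)), function(i) {
    topo <- topologies[i, ]
    spec <- instantiate_topology(base, topo, strength)
    sc <- score_topology(spec, tissue, gradient, noise,
      n_batches = n_batches, seed = all_seeds[topo$topology_id]
    )
    if (progress && i %% 50L == 0L) {
      message(sprintf("screened %d / %d topologies", i, nrow(topologies)))
    }
    dplyr::bind_cols(
      topo,
      tibble::tibble(
        mean_score = mean(sc$score),
        score_sd = if (nrow(sc) > 1L) stats::sd(sc$score) else NA_real_,
        omega_a5 = mean(sc$omega_a5), omega_c8 = mean(sc$omega_c8),
        delta = mean(sc$delta)
      )
    )
  })
  out <- rank_topologies(rows)
  attr(out, "settings") <- list(
    strength = strength, seed = seed, n_batches = n_batches,
    n_replicates = tissue$n_replicates, n_cells = tissue$n_cells,
    t_dev = tissue$t_dev, noise = noise
  )
  class(out) <- c("screen_result", class(out))
  out
}

#' Rank screened topologies
#'
#' Orders topologies by ascending mean score, breaking ties by canonical
#' topology id, and adds a `rank` column. Infinite scores (undefined
#' boundaries) rank last.
#'
#' @param screen A [run_screen()] result (or any tibble with
#'   `mean_score` and `topology_id`).
#' @return The tibble ordered by rank.
#' @export
rank_topologies <- function(screen) {
  screen |>
    dplyr::arrange(.data$mean_score, .data$topology_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' Consensus interactions of the top-ranked topologies
#'
#' Takes the top `fraction` of the ranking (by default the top 2%:
#' `ceiling(0.02 * N)`, i.e. 7 of 324) and returns the candidate edges
#' that carry the identical nonzero value in every one of them.
#'
#' @param screen A ranked [run_screen()] result.
#' @param fraction Fraction of topologies forming the top set.
#' @param cut `"ceiling"` (default) or `"floor"` for the top-set size.
#' @return A tibble with columns `edge`, `value` (one row per consensus
#'   interaction).
#' @export
consensus_interactions <- function(screen, fraction = 0.02,
                                   cut = c("ceiling", "floor")) {
  cut <- match.arg(cut)
  stopifnot(nrow(screen) >= 1L, fraction > 0, fraction <= 1)
  n_top <- if (cut == "ceiling") {
    ceiling(fraction * nrow(screen))
  } else {
    max(1L, floor(fraction * nrow(screen)))
  }
  top <- rank_topologies(screen) |> dplyr::slice_head(n = n_top)
  vals <- purrr::map_dbl(topology_edge_cols, function(e) {
    v <- unique(top[[e]])
    if (length(v) == 1L && v != 0) v else NA_real_
  })
  tibble::tibble(edge = topology_edge_cols, value = vals) |>
    dplyr::filter(!is.na(.data$value))
}

#' Repeat the screen over a range of interaction strengths
#'
#' Runs a full topology screen at each strength and reports the winning
#' topology per strength, plus whether a single topology wins across a
#' contiguous sub-range.
#'
#' @inheritParams run_screen
#' @param strengths Positive interaction strengths (default the six values
#'   0.2 to 1.2).
#' @return A tibble with one row per strength: `strength`,
#'   `best_topology_id`, `best_score`, and the six edge values of the
#'   winner. Attribute `"screens"` holds the per-strength screen results;
#'   attribute `"stable_range"` the range of strengths sharing the modal
#'   winner.
#' @export
strength_sweep <- function(strengths = seq(0.2, 1.2, by = 0.2),
                           base = hox_basal_network(),
                           topologies = enumerate_topologies(),
                           tissue = tissue_config(n_replicates = 10),
                           gradient = gradient_params(n_cells = tissue$n_cells),
                           noise = noise_params(), seed = 1L,
                           progress = FALSE) {
  stopifnot(all(strengths > 0))
  screens <- purrr::map(strengths, function(s) {
    run_screen(base, s, topologies, tissue, gradient, noise,
      seed = seed, progress = progress
    )
  })
  out <- purrr::map2_dfr(strengths, screens, function(s, sc) {
    best <- sc[1L, ]
    dplyr::bind_cols(
      tibble::tibble(
        strength = s, best_topology_id = best$topology_id,
        best_score = best$mean_score
      ),
      best[topology_edge_cols]
    )
  })
  winners <- out$best_topology_id
  modal <- as.integer(names(sort(table(winners), decreasing = TRUE))[1L])
  stable <- strengths[winners == modal]
  attr(out, "screens") <- screens
  attr(out, "stable_range") <- range(stable)
  attr(out, "modal_winner") <- modal
  out
}

#' @export
print.screen_result <- function(x, ...) {
  s <- attr(x, "settings")
  cat(sprintf(
    "<screen_result> %d topologies, strength %.2g, %d replicates/batch, seed %s\n",
    nrow(x), s$strength, s$n_replicates, format(s$seed)
  ))
  NextMethod()
}

#' @describeIn run_screen Ranked tibble of per-topology scores (already
#'   the screen's columns, stripped of the result class).
#' @param x A `screen_result`.
#' @param ... Unused.
#' @export
tidy.screen_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' @describeIn run_screen One-row screen summary: topology count, best
#'   topology and score, number of consensus edges.
#' @export
glance.screen_result <- function(x, ...) {
  cons <- consensus_interactions(x)
  s <- attr(x, "settings")
  tibble::tibble(
    n_topologies = nrow(x),
    best_topology_id = x$topology_id[x$rank == 1L],
    best_score = min(x$mean_score),
    n_consensus = nrow(cons),
    strength = s$strength,
    seed = s$seed
  )
}
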