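test_that("the candidate topology space is complete and canonical", {
  topos <- enumerate_topologies()
  expect_equal(nrow(topos), 324L)
  # distinctness via set-of-tuples cardinality
  keys <- do.call(paste, topos[, -1])
  expect_equal(length(unique(keys)), 324L)
  expect_equal(topos$topology_id, 1:324)
  # value sets: incoming edges ternary, outgoing miRNA edges binary
  for (e in c("ra_to_mirx", "fgf_to_mirx", "a5p_to_mirx", "c8p_to_mirx")) {
    expect_setequal(unique(topos[[e]]), c(0, -1, 1))
  }
  for (e in c("mirx_to_a5p", "mirx_to_c8p")) {
    expect_setequal(unique(topos[[e]]), c(0, -1))
  }
  # restricting all edges to 0 leaves exactly the basal topology
  basal <- dplyr::filter(topos, dplyr::if_all(-1, ~ .x == 0))
  expect_equal(nrow(basal), 1L)
  expect_equal(basal$topology_id, 1L)
  # one ternary x one binary edge -> 6 assignments (brute-force product)
  sub <- dplyr::distinct(topos[, c("ra_to_mirx", "mirx_to_a5p")])
  expect_equal(nrow(sub), 6L)
})

test_that("instantiation scales edges without touching the base network", {
  base <- hox_basal_network()
  topos <- enumerate_topologies()
  same <- instantiate_topology(base, topos[1, ], 0.7)
  expect_equal(same$omega, base$omega)
  one <- instantiate_topology(
    base, list(
      ra_to_mirx = -1, fgf_to_mirx = 0, a5p_to_mirx = 0,
      c8p_to_mirx = 0, mirx_to_a5p = 0, mirx_to_c8p = 0
    ),
    strength = 0.6
  )
  expect_equal(one$omega["mir_x", "RA"], -0.6)
  expect_equal(base$omega["mir_x", "RA"], 0) # base unmodified
  # consensus assignment at strength 1, edge list checked by hand
  wt <- instantiate_topology(base, consensus_topology(), 1)
  expect_equal(wt$omega["mir_x", "RA"], -1)
  expect_equal(wt$omega["mir_x", "hoxc8_protein"], 1)
  expect_equal(wt$omega["hoxa5_protein", "mir_x"], -1)
  expect_equal(wt$omega["hoxc8_protein", "mir_x"], 0)
  expect_error(instantiate_topology(base, topos[1, -2]), "missing edge")
  no_mirx <- chain_spec()
  expect_error(
    instantiate_topology(no_mirx, consensus_topology(), 1),
    "absent"
  )
})

test_that("ranking sorts ascending with canonical-id tie breaks", {
  sc <- tibble::tibble(topology_id = c(5L, 2L, 9L), mean_score = c(3, 1, 2))
  r <- rank_topologies(sc)
  expect_equal(r$topology_id, c(2L, 9L, 5L))
  tied <- tibble::tibble(topology_id = c(7L, 3L), mean_score = c(1, 1))
  expect_equal(rank_topologies(tied)$topology_id, c(3L, 7L))
  set.seed(2)
  rnd <- tibble::tibble(topology_id = 1:50, mean_score = runif(50))
  expect_equal(
    rank_topologies(rnd)$mean_score,
    sort(rnd$mean_score)
  )
})

test_that("consensus extraction intersects signed edges over the top set", {
  topos <- enumerate_topologies()
  # single topology in the top set: consensus = its nonzero edges
  one <- dplyr::mutate(consensus_topology(), mean_score = 0)
  cons <- consensus_interactions(one, fraction = 1)
  expect_setequal(cons$edge, c("ra_to_mirx", "c8p_to_mirx", "mirx_to_a5p"))
  # three hand-built assignments sharing only RA -| mir-x
  three <- topos[topos$ra_to_mirx == -1 &
    topos$mirx_to_a5p %in% c(0, -1), ][c(1, 20, 50), ]
  three$mean_score <- c(1, 2, 3)
  shared <- consensus_interactions(three, fraction = 1)
  manual <- purrr::map_lgl(names(topos)[-1], function(e) {
    v <- unique(three[[e]])
    length(v) == 1 && v != 0
  })
  expect_setequal(shared$edge, names(topos)[-1][manual])
  expect_true("ra_to_mirx" %in% shared$edge)
  # ceiling vs floor top-set sizes at 2% of 324
  full <- dplyr::mutate(topos, mean_score = topology_id)
  expect_equal(ceiling(0.02 * 324), 7)
  cons7 <- consensus_interactions(full, 0.02, cut = "ceiling")
  cons6 <- consensus_interactions(full, 0.02, cut = "floor")
  expect_s3_class(cons7, "tbl_df")
  expect_s3_class(cons6, "tbl_df")
})

test_that("screens are deterministic and independent of execution order", {
  topos <- enumerate_topologies()
  pickset <- topos[c(1, 119, 131, 120), ]
  ts <- tissue_config(n_cells = 30, n_replicates = 3, t_dev = 2)
  gr <- gradient_params(n_cells = 30)
  a <- run_screen(topologies = pickset, tissue = ts, gradient = gr, seed = 77)
  b <- run_screen(topologies = pickset[c(3, 1, 4, 2), ], tissue = ts,
    gradient = gr, seed = 77)
  am <- dplyr::arrange(tidy(a), topology_id)
  bm <- dplyr::arrange(tidy(b), topology_id)
  expect_equal(am$mean_score, bm$mean_score)
  # eta = 0 scores are deterministic across reruns
  c1 <- run_screen(topologies = pickset[2, ], tissue = ts, gradient = gr,
    noise = noise_params(amplitude = 0), seed = 1)
  c2 <- run_screen(topologies = pickset[2, ], tissue = ts, gradient = gr,
    noise = noise_params(amplitude = 0), seed = 2)
  expect_equal(c1$mean_score, c2$mean_score)
})

test_that("the basal topology scores worse than the consensus circuit", {
  ts <- tissue_config(n_replicates = 8)
  topos <- enumerate_topologies()
  basal_row <- topos[1, ]
  sc <- run_screen(
    topologies = dplyr::bind_rows(basal_row, consensus_topology()),
    tissue = ts, seed = 21
  )
  ranked <- tidy(sc)
  expect_equal(
    ranked$topology_id[1],
    consensus_topology()$topology_id
  )
  expect_gt(max(ranked$mean_score), 2 * min(ranked$mean_score))
})

test_that("doubling the replicate budget moves scores within Monte-Carlo error", {
  spec <- hox_consensus_network()
  s10 <- score_topology(spec, tissue_config(n_replicates = 10),
    n_batches = 2, seed = 5
  )
  s20 <- score_topology(spec, tissue_config(n_replicates = 20),
    n_batches = 2, seed = 6
  )
  expect_lt(abs(mean(s20$score) - mean(s10$score)), 0.05)
})

test_that("a reduced strength sweep keeps a core-circuit winner", {
  topos <- enumerate_topologies()
  # subset containing the consensus family and representative competitors
  sub <- topos[topos$topology_id %in% c(1, 119, 120, 131, 155, 183, 203), ]
  sw <- strength_sweep(
    strengths = c(0.6, 1.2), topologies = sub,
    tissue = tissue_config(n_cells = 50, n_replicates = 4, t_dev = 3),
    gradient = gradient_params(n_cells = 50), seed = 13
  )
  expect_equal(nrow(sw), 2L)
  for (i in 1:2) {
    expect_equal(sw$ra_to_mirx[i], -1)
    expect_equal(sw$c8p_to_mirx[i], 1)
    expect_equal(sw$mirx_to_a5p[i], -1)
  }
  expect_length(attr(sw, "screens"), 2L)
  expect_true(all(attr(sw, "stable_range") %in% c(0.6, 1.2)))
})
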