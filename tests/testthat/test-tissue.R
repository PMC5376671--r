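small_tissue <- function(reps = 2, cells = 20, t_dev = 1) {
  tissue_config(n_cells = cells, n_replicates = reps, t_dev = t_dev)
}

test_that("noise-free development makes replicates identical", {
  res <- run_development(hox_consensus_network(),
    small_tissue(reps = 3),
    gradient = gradient_params(n_cells = 20),
    noise = noise_params(amplitude = 0), seed = 1
  )
  expect_equal(res$states[1, , , ], res$states[2, , , ])
  expect_equal(res$states[1, , , ], res$states[3, , , ])
})

test_that("development is bit-reproducible from the master seed", {
  a <- run_development(hox_consensus_network(), small_tissue(),
    gradient = gradient_params(n_cells = 20), seed = 33
  )
  b <- run_development(hox_consensus_network(), small_tissue(),
    gradient = gradient_params(n_cells = 20), seed = 33
  )
  expect_identical(a$states, b$states)
})

test_that("a single-replicate tissue equals a direct network integration", {
  spec <- hox_consensus_network()
  tis <- tissue_config(n_cells = 5, n_replicates = 1, t_dev = 1)
  grad <- gradient_params(n_cells = 5)
  res <- run_development(spec, tis, grad, noise_params(), seed = 9)
  # rebuild the replicate's trace from its recorded seed and integrate
  trace <- sample_noise_trace(grad, noise_params(), 1,
    seed = res$replicate_seeds[1]
  )
  ss <- relax_to_steady_state(spec)
  init <- matrix(ss, 5, 5, byrow = TRUE, dimnames = list(NULL, spec$species))
  traj <- integrate_network(spec, init, trace,
    t_span = 1, dt = 0.01, store_every = 0.1
  )
  direct <- attr(traj, "states")
  expect_equal(res$states[1, , , ], direct, tolerance = 1e-12)
})

test_that("the wild-type tissue forms a mutually exclusive boundary", {
  res <- run_development(hox_consensus_network(),
    tissue_config(n_replicates = 5),
    seed = 4
  )
  snap <- snapshot(res, 5)
  a5 <- colMeans(snap[, , "hoxa5_protein"] > 0.5)
  c8 <- colMeans(snap[, , "hoxc8_protein"] > 0.5)
  expect_gt(mean(a5[1:30]), 0.95) # rostral Hoxa5
  expect_lt(mean(c8[1:30]), 0.05)
  expect_gt(mean(c8[70:100]), 0.95) # caudal Hoxc8
  expect_lt(mean(a5[70:100]), 0.05)
  # co-expression limited to the boundary region
  co <- colMeans(snap[, , "hoxa5_protein"] > 0.5 &
    snap[, , "hoxc8_protein"] > 0.5)
  expect_lt(max(co[c(1:35, 55:100)]), 0.2)
})

test_that("mir-x is expressed everywhere early and caudally late", {
  res <- run_development(hox_consensus_network(),
    tissue_config(n_replicates = 3),
    seed = 5
  )
  early <- snapshot(res, 0.2)
  expect_gt(min(apply(early[, , "mir_x"], 2, mean)), 0.5)
  late <- snapshot(res, 5)
  mirx <- apply(late[, , "mir_x"], 2, mean)
  c8 <- apply(late[, , "hoxc8_protein"], 2, mean)
  expect_gt(mean(mirx[c8 > 0.5]), 0.9) # high across the Hoxc8 domain
  expect_lt(mean(mirx[1:30]), 0.1) # cleared rostrally
})

test_that("differentiation without RA leaves Hoxa5 at its resting state", {
  spec <- hox_consensus_network()
  res <- run_differentiation(spec, n_cells_group = 3, ra_level = 0,
    noise = noise_params(amplitude = 0), duration = 1, seed = 1
  )
  ss <- relax_to_steady_state(spec)
  expect_equal(
    unname(res$states[1, 1, "hoxa5_protein", dim(res$states)[4]]),
    ss[["hoxa5_protein"]],
    tolerance = 1e-4
  )
})

test_that("differentiation reruns are bit-identical under a fixed seed", {
  a <- run_differentiation(hox_consensus_network(), 20, duration = 0.5, seed = 8)
  b <- run_differentiation(hox_consensus_network(), 20, duration = 0.5, seed = 8)
  expect_identical(a$states, b$states)
})

test_that("mir-x removal abolishes the Hoxa5 activation delay", {
  wt <- hox_consensus_network()
  nul <- apply_mutant(wt, "mirx_null")
  q <- noise_params(amplitude = 0)
  r_wt <- run_differentiation(wt, 2, ra_level = 1, noise = q,
    duration = 4, seed = 1)
  r_nul <- run_differentiation(nul, 2, ra_level = 1, noise = q,
    duration = 4, seed = 1)
  expect_gt(half_max_time(r_wt), half_max_time(r_nul))
})

test_that("snapshot selects the nearest stored slice", {
  res <- run_development(hox_consensus_network(), small_tissue(),
    gradient = gradient_params(n_cells = 20), seed = 2
  )
  s0 <- snapshot(res, 0)
  expect_equal(s0[1, 1, ], res$states[1, 1, , 1])
  send <- snapshot(res, 1)
  expect_equal(send[2, 3, ], res$states[2, 3, , dim(res$states)[4]])
  mid <- snapshot(res, 0.52)
  expect_equal(attr(mid, "time"), 0.5)
  expect_equal(mid[1, 1, ], res$states[1, 1, , 6])
  expect_error(snapshot(res, 7), "span")
})

test_that("tidy and glance views are consistent with the stored array", {
  res <- run_development(hox_consensus_network(),
    small_tissue(reps = 2, cells = 5),
    gradient = gradient_params(n_cells = 5), seed = 3
  )
  td <- tidy(res)
  expect_equal(nrow(td), prod(dim(res$states)))
  row <- td[td$replicate == 2 & td$cell == 4 &
    td$species == "mir_x" & td$time == 0.5, ]
  expect_equal(row$value, unname(res$states[2, 4, "mir_x", 6]))
  g <- glance(res)
  expect_equal(g$n_replicates, 2L)
  expect_equal(g$n_cells, 5L)
  expect_equal(g$protocol, "development")
})
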