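test_that("sigmoid has logistic form, symmetry and saturation", {
  expect_equal(sigmoid(0, 5), 0.5)
  expect_equal(sigmoid(1e6, 3), 1)
  expect_equal(sigmoid(-1e6, 3), 0)
  # closed-form oracle 1/(1+exp(-sigma*u))
  expect_equal(sigmoid(1, 5), 1 / (1 + exp(-5)))
  expect_equal(sigmoid(-0.3, 12), 1 / (1 + exp(12 * 0.3)))
  u <- seq(-2, 2, by = 0.1)
  expect_true(all(diff(sigmoid(u, 4)) > 0))
  expect_error(sigmoid(0, -1), "positive")
})

test_that("regulatory_input sums basal, species and morphogen terms", {
  spec <- chain_spec(w_in = 1, w_tr = -1)
  # all regulators zero -> basal only
  expect_equal(
    regulatory_input(spec, c(m = 0, p = 0), c(RA = 0, FGF = 0), "m"), -0.3
  )
  # single regulator with omega = -1 at X = 0.5
  expect_equal(
    regulatory_input(
      chain_spec(w_tr = -1, basal = c(m = 0, p = 0)),
      c(m = 0.5, p = 0), c(RA = 0, FGF = 0), "p"
    ),
    -0.5
  )
  # hand-summed dot product on the full 5-species network
  wt <- hox_consensus_network()
  state <- setNames(c(0.2, 0.4, 0.6, 0.8, 0.5), wt$species)
  m <- c(RA = 0.7, FGF = 0.1)
  for (target in wt$species) {
    manual <- wt$basal[[target]] +
      sum(wt$omega[target, wt$species] * state) +
      wt$omega[target, "RA"] * m[["RA"]] + wt$omega[target, "FGF"] * m[["FGF"]]
    expect_equal(
      regulatory_input(wt, state, m, target), manual,
      tolerance = 1e-12
    )
  }
  expect_error(regulatory_input(wt, state, m, "nope"), "unknown species")
  expect_error(regulatory_input(wt, state, c(RA = -1, FGF = 0), "mir_x"),
    "non-negative"
  )
})

test_that("derivatives vanish exactly at the sigmoidal fixed point", {
  spec <- chain_spec()
  m <- c(RA = 0.5, FGF = 0)
  u_m <- regulatory_input(spec, c(m = 0, p = 0), m, "m")
  x_m <- sigmoid(u_m, spec$sigma)
  u_p <- regulatory_input(spec, c(m = x_m, p = 0), m, "p")
  x_p <- sigmoid(u_p, spec$sigma)
  d <- derivatives(spec, c(m = x_m, p = x_p), m)
  expect_equal(unname(d), c(0, 0), tolerance = 1e-12)
})

test_that("a zero relaxation rate freezes a species", {
  spec <- chain_spec(gamma = c(m = 0, p = 2))
  d <- derivatives(spec, c(m = 0.42, p = 0.1), c(RA = 1, FGF = 0))
  expect_equal(d[["m"]], 0)
  expect_false(d[["p"]] == 0)
})

test_that("derivatives match hand-computed gamma * (F - X)", {
  spec <- chain_spec(gamma = c(m = 3, p = 0.5), sigma = 8,
    basal = c(m = 0.2, p = -0.1))
  st <- c(m = 0.6, p = 0.3)
  m <- c(RA = 0.25, FGF = 0)
  d <- derivatives(spec, st, m)
  f_m <- 1 / (1 + exp(-8 * (0.2 + 0.25)))
  f_p <- 1 / (1 + exp(-8 * (-0.1 + 0.6)))
  expect_equal(d[["m"]], 3 * (f_m - 0.6), tolerance = 1e-12)
  expect_equal(d[["p"]], 0.5 * (f_p - 0.3), tolerance = 1e-12)
})

test_that("integration reproduces the exponential closed form", {
  # basal offset saturates F at 1, so X relaxes exponentially toward 1
  spec <- single_species_spec(gamma = 2, sigma = 10, basal = 5)
  traj <- integrate_network(spec, c(x = 0.2), c(RA = 0, FGF = 0),
    t_span = 2, dt = 0.01, store_every = 0.01
  )
  st <- attr(traj, "states")
  tt <- attr(traj, "times")
  analytic <- 1 + (0.2 - 1) * exp(-2 * tt)
  expect_lt(max(abs(st[1, 1, ] - analytic) / analytic), 1e-4)
})

test_that("halving the step leaves trajectories essentially unchanged", {
  wt <- hox_consensus_network()
  args <- list(
    spec = wt, initial = rep(0.3, 5), morphogens = c(RA = 0.5, FGF = 0.2),
    t_span = 2, store_every = 0.1
  )
  t1 <- do.call(integrate_network, c(args, dt = 0.01))
  t2 <- do.call(integrate_network, c(args, dt = 0.005))
  expect_lt(max(abs(attr(t1, "states") - attr(t2, "states"))), 1e-4)
})

test_that("the unit box is forward-invariant", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(2:4, 1)
    ids <- paste0("s", seq_len(n))
    omega <- matrix(rnorm(n * (n + 2), sd = 1.5), n, n + 2,
      dimnames = list(ids, c(ids, "RA", "FGF"))
    )
    spec <- network_spec(ids,
      gamma = runif(n, 0.5, 5), sigma = runif(1, 1, 20),
      basal = rnorm(n), omega = omega
    )
    traj <- integrate_network(spec, runif(n), c(RA = runif(1), FGF = runif(1)),
      t_span = 3, dt = 0.01, store_every = 0.1
    )
    st <- attr(traj, "states")
    expect_true(all(st >= 0 & st <= 1))
  }
})

test_that("integration validates steps and trace coverage", {
  spec <- single_species_spec()
  expect_error(
    integrate_network(spec, c(x = 0), c(RA = 0, FGF = 0),
      t_span = 1, dt = 0.01, store_every = 0.003
    ),
    "multiple"
  )
  trace <- sample_noise_trace(matrix(c(1, 0), 1, 2), noise_params(),
    duration = 0.5, seed = 1
  )
  expect_error(
    integrate_network(spec, c(x = 0), trace, t_span = 1),
    "cover"
  )
})

test_that("relaxation finds the scalar fixed point and honours tol", {
  spec <- single_species_spec(gamma = 1, sigma = 6, basal = 0.4)
  ss <- relax_to_steady_state(spec, tol = 1e-8)
  expect_equal(ss[["x"]], sigmoid(0.4, 6), tolerance = 1e-6)
  d <- derivatives(spec, ss, c(RA = 0, FGF = 0))
  expect_lt(max(abs(d)), 1e-8)
})

test_that("relaxation agrees with a long fine-step integration", {
  spec <- hox_basal_network()
  ss <- relax_to_steady_state(spec)
  traj <- integrate_network(spec, rep(0, 5), c(RA = 0, FGF = 0),
    t_span = 40, dt = 0.005, store_every = 40
  )
  long <- attr(traj, "states")[1, , dim(attr(traj, "states"))[3]]
  expect_equal(unname(ss), unname(long), tolerance = 1e-4)
})

test_that("non-convergent relaxation reports the residual", {
  spec <- single_species_spec(gamma = 0.001)
  expect_error(
    relax_to_steady_state(spec, initial = c(x = 1), tol = 1e-10, t_max = 2),
    "not reached"
  )
})
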