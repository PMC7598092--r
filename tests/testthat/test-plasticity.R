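# Hebbian updates, normalization, and equivalence with scalar references

test_that("normalize_weights matches hand values and is idempotent", {
  v <- c(0.2, 0.6, 0, 1.2)
  expect_equal(normalize_weights(v), c(0.1, 0.3, 0, 0.6))
  expect_identical(normalize_weights(normalize_weights(v)),
                   normalize_weights(v))
  expect_identical(normalize_weights(c(0, 0, 0)), c(0, 0, 0))
  W <- rbind(c(0, 0.2, 0.6), c(0, 0, 0), c(1, 0, 1))
  Wn <- normalize_weights(W)
  expect_equal(rowSums(Wn), c(1, 0, 1))
  expect_identical(Wn[2, ], c(0, 0, 0))
  expect_error(normalize_weights(c(-0.1, 1)), "non-negative")
})

test_that("external Hebbian increments match direct arithmetic", {
  # c = 0.01, delayed source 0.5, target 0.3 -> 0.4: dW = 5e-4
  W <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE)
  dE <- matrix(c(0, 0.5, 0, 0), 2, 2, byrow = TRUE)
  W2 <- hebbian_update_external(W, dE, E_now = c(0.4, 0), E_prev = c(0.3, 0),
                                c = 0.01, normalize = FALSE)
  expect_equal(W2[1, 2], 1 + 5e-4, tolerance = 1e-15)
  # zero delayed source or unchanged target -> no change
  W3 <- hebbian_update_external(W, dE * 0, c(0.4, 0), c(0.3, 0), 0.01,
                                normalize = FALSE)
  expect_identical(W3, W)
  W4 <- hebbian_update_external(W, dE, c(0.4, 0), c(0.4, 0), 0.01,
                                normalize = FALSE)
  expect_identical(W4, W)
})

test_that("internal Hebbian increments match direct arithmetic", {
  expect_equal(hebbian_update_internal(0.5, 1, 0.5, 0.6, 0.01),
               0.5 - 1e-3, tolerance = 1e-15)
  expect_identical(hebbian_update_internal(0.5, 0, 0.9, 0.1, 0.01), 0.5)
  expect_identical(hebbian_update_internal(0.5, 1, 0.7, 0.7, 0.01), 0.5)
  # clipping at zero
  expect_identical(hebbian_update_internal(0.001, 1, 0, 1, 1), 0)
})

test_that("zero-structure is preserved and incoming sums stay at one", {
  withr::with_seed(77, {
    n <- 6
    W <- matrix(runif(n * n, 0.1, 0.6), n, n) *
      (matrix(runif(n * n), n, n) < 0.5)
    diag(W) <- 0
    pattern <- W == 0
    for (cycle in 1:25) {
      dE <- matrix(runif(n * n, 0, 0.5), n, n)
      E_now <- runif(n, 0, 0.5); E_prev <- runif(n, 0, 0.5)
      W <- hebbian_update_external(W, dE, E_now, E_prev, c = 0.05)
      expect_true(all(W[pattern] == 0))
      expect_true(all(W >= 0))
      s <- rowSums(W)
      expect_true(all(abs(s[s > 0] - 1) < 1e-12))
    }
  })
})

test_that("a c = 0 cycle is a strict no-op", {
  con <- tiny_connectome(n = 3, seed = 2)
  iw <- matrix(rep(population_params()$w, each = 3), 3, 7)
  st <- network_state(c(0.1, 0.2, 0.3), c(0.1, 0.1, 0.1), c(0.2, 0.2, 0.2))
  stp <- network_state(c(0.2, 0.1, 0.3), c(0.1, 0.2, 0.1), c(0.2, 0.1, 0.2))
  upd <- apply_plasticity_cycle(con$W, iw, st, stp,
                                delayed_E = matrix(0.3, 3, 3),
                                config = plasticity_config(c = 0))
  expect_identical(upd$W, con$W)
  expect_identical(upd$internal_w, iw)
})

test_that("equilibrium activity leaves weights fixed after one normalization", {
  con <- tiny_connectome(n = 3, seed = 2)
  iw <- matrix(rep(population_params()$w, each = 3), 3, 7)
  st <- network_state(rep(0.2, 3), rep(0.1, 3), rep(0.1, 3))
  cfg <- plasticity_config(c = 0.05)
  one <- apply_plasticity_cycle(con$W, iw, st, st, matrix(0.2, 3, 3), cfg)
  expect_identical(one$W, normalize_weights(con$W))
  expect_identical(one$internal_w, iw)  # conservation restores the sums
  two <- apply_plasticity_cycle(one$W, one$internal_w, st, st,
                                matrix(0.2, 3, 3), cfg)
  expect_identical(two$W, one$W)
})

test_that("internal renormalization conserves each node's plastic total", {
  withr::with_seed(5, {
    n <- 4
    iw <- matrix(runif(n * 7, 0.2, 2), n, 7)
    now <- list(E = runif(n), Is = runif(n), Id = runif(n))
    prev <- list(E = runif(n), Is = runif(n), Id = runif(n))
    cfg <- plasticity_config(c = 0.1, external_on = FALSE)
    upd <- apply_plasticity_cycle(matrix(0, n, n), iw,
                                  network_state(now$E, now$Is, now$Id),
                                  network_state(prev$E, prev$Is, prev$Id),
                                  matrix(0, n, n), cfg)
    expect_equal(rowSums(upd$internal_w), rowSums(iw), tolerance = 1e-12)
    expect_false(identical(upd$internal_w, iw))
    # reference scalar implementation agrees
    ref <- ref_internal_update(iw, now, prev, 0.1)
    expect_equal(upd$internal_w, ref, tolerance = 1e-14)
  })
})

test_that("matrix update rule equals the scalar double-loop reference", {
  withr::with_seed(31, {
    n <- 5
    W <- matrix(runif(n * n, 0.05, 0.5), n, n) *
      (matrix(runif(n * n), n, n) < 0.6)
    diag(W) <- 0
    dE <- matrix(runif(n * n, 0, 0.6), n, n)
    E_now <- runif(n); E_prev <- runif(n)
    expect_equal(hebbian_update_external(W, dE, E_now, E_prev, 0.02),
                 ref_external_update(W, dE, E_now, E_prev, 0.02),
                 tolerance = 1e-14)
  })
})

test_that("c = 0 engine run is bitwise identical to plasticity off", {
  con <- tiny_connectome(n = 3, seed = 13)
  eng <- engine_config(t_end = 200)
  off <- run_chunked(con, test_params(), eng,
                     recorder = recorder_config(interval = 100))
  zero <- run_chunked(con, test_params(), eng,
                      plasticity = plasticity_config(c = 0),
                      recorder = recorder_config(interval = 100))
  expect_identical(off$final_state$E, zero$final_state$E)
  expect_identical(off$final_state$Is, zero$final_state$Is)
  expect_identical(off$final_state$Id, zero$final_state$Id)
  expect_identical(off$W, zero$W)
  expect_identical(off$series$E, zero$series$E)
})

test_that("engine plasticity equals an independent scalar reference run", {
  con <- tiny_connectome(n = 3, seed = 19, p = 0.9)
  params <- test_params()
  cfg <- plasticity_config(c = 0.01, update_every = 10)
  sim <- run_chunked(con, params, engine_config(t_end = 100),
                     plasticity = cfg,
                     recorder = recorder_config(interval = 100))
  ref <- ref_plastic_run(con, params, nsteps = 100, h = 1, plast = cfg)
  final <- c(sim$final_state$E, sim$final_state$Is, sim$final_state$Id)
  expect_lt(max(abs(final - ref$final)), 1e-9)
  expect_lt(max(abs(sim$W - ref$W)), 1e-9)
  expect_lt(max(abs(sim$internal_w - ref$internal_w)), 1e-9)
})

test_that("weight sparsity pattern survives a full plastic engine run", {
  con <- tiny_connectome(n = 4, seed = 23, p = 0.5)
  sim <- run_chunked(con, test_params(), engine_config(t_end = 300),
                     plasticity = plasticity_config(c = 0.02),
                     recorder = recorder_config(interval = 300))
  expect_true(all(sim$W[con$W == 0] == 0))
  expect_true(all(sim$W >= 0))
  s <- rowSums(sim$W)
  expect_true(all(abs(s[s > 0] - 1) < 1e-12))
})

test_that("the Oja plug-in rule runs and keeps the contract invariants", {
  con <- tiny_connectome(n = 3, seed = 29, p = 0.9)
  sim <- run_chunked(con, test_params(), engine_config(t_end = 100),
                     plasticity = plasticity_config(c = 0.01, rule = "oja",
                                                    internal_on = FALSE),
                     recorder = recorder_config(interval = 100))
  expect_true(all(sim$W[con$W == 0] == 0))
  expect_true(all(sim$W >= 0))
})
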