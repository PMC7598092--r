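# RK(2,3) stepping, the monolithic reference, and the chunked engine

test_that("a zero rhs leaves the state and error estimate at zero", {
  s <- step_rk23(function(t, y) rep(0, 3), 0, c(1, 2, 3), 0.5)
  expect_identical(s$y, c(1, 2, 3))
  expect_identical(s$err_norm, 0)
})

test_that("one-step error on y' = -y is fourth order in h", {
  f <- function(t, y) -y
  h <- 0.1
  e1 <- abs(step_rk23(f, 0, 1, h)$y - exp(-h))
  e2 <- abs(step_rk23(f, 0, 1, h / 2)$y - exp(-h / 2))
  expect_lt(e1, 1e-5)                  # C * h^4 with modest C
  ratio <- e1 / e2
  expect_gt(ratio, 10)                 # halving h cuts the defect ~16x
  expect_lt(ratio, 24)
})

test_that("global convergence order on a smooth problem is 3 +/- 0.3", {
  f <- function(t, y, ylag) -y
  hs <- c(0.4, 0.2, 0.1, 0.05)
  errs <- vapply(hs, function(h) {
    sol <- dde_integrate(f, 1, 0, 2, h)
    abs(sol$final - exp(-2))
  }, numeric(1))
  slope <- coef(lm(log(errs) ~ log(hs)))[[2]]
  expect_gt(slope, 2.7)
  expect_lt(slope, 3.3)
})

test_that("delayed test equation matches the method-of-steps solution", {
  # y'(t) = -y(t - 1), history 1 on [-1, 0] -> y(t) = 1 - t on [0, 1]
  sol <- dde_integrate(function(t, y, ylag) -ylag(t - 1), 1, 0, 1, 0.01)
  expect_lt(max(abs(sol$y[, 1] - (1 - sol$times))), 5e-7)
})

test_that("non-finite stages abort with a timestamp", {
  f <- function(t, y) if (t > 0.4) NaN else -y
  expect_error(dde_integrate(function(t, y, ylag) f(t, y), 1, 0, 1, 0.1),
               "non-finite stage value at t")
})

test_that("chunked engine agrees with the monolithic reference to 1e-9", {
  con <- tiny_connectome(n = 3, seed = 5, p = 0.8)
  params <- test_params()
  eng <- engine_config(t_end = 1000, step = 1)
  sim <- run_chunked(con, params, eng,
                     recorder = recorder_config(interval = 1000))
  mono <- run_monolithic(con, params, eng)
  chunk_final <- c(sim$final_state$E, sim$final_state$Is, sim$final_state$Id)
  expect_lt(max(abs(chunk_final - mono$final)), 1e-9)
})

test_that("chunked-vs-monolithic agreement holds across random small nets", {
  for (seed in c(21, 22, 23)) {
    con <- tiny_connectome(n = 4, seed = seed, p = 0.5)
    eng <- engine_config(t_end = 300, step = 1)
    sim <- run_chunked(con, test_params(), eng,
                       recorder = recorder_config(interval = 300))
    mono <- run_monolithic(con, test_params(), eng)
    final <- c(sim$final_state$E, sim$final_state$Is, sim$final_state$Id)
    expect_lt(max(abs(final - mono$final)), 1e-9)
  }
})

test_that("buffer capacity is auto-raised to cover the longest delay", {
  # max delay 21.4 ms at 1 ms step -> capacity >= ceil(21.4) + 4 = 26
  L <- matrix(0, 2, 2); L[1, 2] <- 149.8; L[2, 1] <- 70
  S <- matrix(0, 2, 2); S[1, 2] <- 10; S[2, 1] <- 10
  con <- connectome(S, L)
  expect_equal(max(con$D), 21.4)
  sim <- run_chunked(con, test_params(), engine_config(t_end = 50),
                     recorder = recorder_config(interval = 50))
  expect_gte(sim$capacity, 26)
  # and never grows with t_end (memory contract)
  sim2 <- run_chunked(con, test_params(), engine_config(t_end = 500),
                      recorder = recorder_config(interval = 500))
  expect_identical(sim2$capacity, sim$capacity)
})

test_that("t_end = 0 returns the initial state with one snapshot", {
  con <- tiny_connectome(n = 3)
  sim <- run_chunked(con, test_params(), engine_config(t_end = 0))
  expect_identical(sim$counters$snapshots, 1L)
  expect_identical(sim$series$times, 0)
  expect_identical(sim$final_state$E, rep(0.1, 3))
})

test_that("snapshots fall on every multiple of the interval", {
  con <- tiny_connectome(n = 2, seed = 8, p = 1)
  # scaled-down analogue of 50 s interval / 200 s horizon: 50 ms / 200 ms
  sim <- run_chunked(con, test_params(), engine_config(t_end = 200),
                     recorder = recorder_config(interval = 50))
  expect_identical(sim$series$times, c(0, 50, 100, 150, 200))
})

test_that("sub-step delays are clamped up with a warning", {
  S <- matrix(c(0, 5, 5, 0), 2, 2)
  L <- matrix(c(0, 3, 3, 0), 2, 2)   # 3 mm / 7 m/s = 0.43 ms < 1 ms step
  con <- connectome(S, L)
  expect_warning(
    sim <- run_chunked(con, test_params(), engine_config(t_end = 10),
                       recorder = recorder_config(interval = 10)),
    "clamped")
  expect_identical(sim$steps, 10L)
})

test_that("divergent runs abort with a flushed last snapshot", {
  con <- tiny_connectome(n = 2, seed = 3, p = 1)
  dir <- withr::local_tempdir()
  # tau_e far below the step makes the explicit pair numerically unstable,
  # so the iterates blow past the divergence limit
  params <- population_params(tau_e = 0.001)
  expect_error(
    suppressWarnings(run_chunked(con, params,
                engine_config(t_end = 100, divergence_limit = 10),
                recorder = recorder_config(interval = 10, out_dir = dir))),
    class = "brainmass_divergence")
  # the t = 0 snapshot survived on disk
  series <- read_series(dir)
  expect_gte(length(series$times), 1)
  expect_identical(series$times[1], 0)
})
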