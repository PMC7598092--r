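# weights, delays, synthetic generation, edge counts, file round trips

test_that("init_weights follows 0.1*log(S) with a zero branch", {
  S <- matrix(c(0, 1, 100, 0), 2, 2, byrow = TRUE)
  W <- init_weights(S)
  expect_identical(W[1, 1], 0)   # S = 0
  expect_identical(W[1, 2], 0)   # ln(1) = 0
  expect_equal(W[2, 1], 0.1 * log(100), tolerance = 1e-12)
  expect_equal(W[2, 1], 0.4605170, tolerance = 1e-7)
  expect_error(init_weights(matrix(c(0, 0.5, 0, 0), 2, 2)), "negative weight")
  expect_error(init_weights(matrix(c(0, -1, 0, 0), 2, 2)), "negative")
  # log10 option
  expect_equal(init_weights(S, base = "log10")[2, 1], 0.2, tolerance = 1e-12)
})

test_that("init_weights is monotone in the count", {
  S_vals <- c(2, 5, 17, 120, 4000)
  W_vals <- vapply(S_vals, function(s) init_weights(matrix(c(0, s, 0, 0), 2, 2))[2, 1],
                   numeric(1))
  expect_true(all(diff(W_vals) > 0))
})

test_that("delays are lengths over speed with forced unit conversion", {
  L <- matrix(c(0, 70, 7, 0), 2, 2, byrow = TRUE)
  D <- compute_delays(L, v = 7)   # 7 m/s == 7 mm/ms
  expect_identical(D[1, 1], 0)
  expect_equal(D[1, 2], 10)
  expect_equal(D[2, 1], 1)
  expect_error(compute_delays(L, v = 0), "> 0")
  expect_error(compute_delays(L, v = -2), "> 0")
})

test_that("synthetic connectome is seed-deterministic with exact boundary p", {
  c1 <- synthetic_connectome(10, 0.3, seed = 42)
  c2 <- synthetic_connectome(10, 0.3, seed = 42)
  expect_identical(c1$S, c2$S)
  expect_identical(c1$L, c2$L)
  expect_identical(c1$W, c2$W)
  expect_identical(c1$D, c2$D)
  expect_identical(sum(synthetic_connectome(8, 0, seed = 1)$S != 0), 0L)
  full <- synthetic_connectome(8, 1, seed = 1)
  expect_identical(sum(full$S != 0), 8L * 7L)
  expect_error(synthetic_connectome(5, 1.2), "\\[0, 1\\]")
})

test_that("generated connectomes have valid structure", {
  con <- synthetic_connectome(30, 0.2, seed = 9)
  expect_true(all(diag(con$S) == 0))
  expect_true(all(diag(con$W) == 0))
  expect_true(all(con$W[con$S == 0] == 0))
  expect_true(all(con$D[con$W != 0] > 0))
  expect_true(all(con$S[con$S != 0] >= 2))
  # weight scale comparable to 0.1*log of counts with mean ~ 50
  ws <- con$W[con$W != 0]
  expect_gt(min(ws), 0.05)
  expect_lt(max(ws), 0.8)
})

test_that("external edge count is unbiased at the reference size", {
  n <- 82; p <- 0.2
  m <- 1000
  counts <- vapply(seq_len(m), function(s) {
    sum(synthetic_connectome(n, p, seed = 1000 + s)$S != 0)
  }, numeric(1))
  mu <- p * n * (n - 1)
  se <- sqrt(n * (n - 1) * p * (1 - p) / m)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("count_edges reproduces the published p = 0.2 family", {
  expect_identical(count_edges(1, 0.7), 7)
  expect_identical(count_edges(c(100, 150, 250, 350), 0.2),
                   c(2680, 5520, 14200, 26880))
  # full-connectivity closed form (not a published value)
  expect_identical(count_edges(350, 1), 350 * 349 + 7 * 350)
})

test_that("connectome files round-trip exactly and reject bad input", {
  dir <- withr::local_tempdir()
  con <- synthetic_connectome(10, 0.4, seed = 3)
  write_connectome(con, dir)
  back <- read_connectome(file.path(dir, "S.csv"), file.path(dir, "L.csv"))
  expect_identical(back$S, con$S)
  expect_identical(back$L, con$L)
  expect_identical(back$W, con$W)
  expect_identical(back$D, con$D)

  bad <- file.path(dir, "bad.csv")
  writeLines(c("1,2,3,4", "5,6,7,8", "9,10,11,12"), bad)
  expect_error(read_connectome(bad, file.path(dir, "L.csv")), "square")

  neg <- file.path(dir, "neg.csv")
  writeLines(c("0,-3", "1,0"), neg)
  expect_error(read_connectome(neg, neg), "negative value at \\[1, 2\\]")

  txt <- file.path(dir, "alpha.csv")
  writeLines(c("0,a", "1,0"), txt)
  expect_error(read_connectome(txt, txt), "non-numeric")

  # nonzero diagonal is zeroed with a warning
  dg <- file.path(dir, "diag.csv")
  writeLines(c("5,3", "1,2"), dg)
  ln <- file.path(dir, "dlen.csv")
  writeLines(c("0,30", "40,0"), ln)
  expect_warning(cc <- read_connectome(dg, ln), "diagonal")
  expect_identical(diag(cc$S), c(0, 0))
})

test_that("tab-separated matrices are sniffed", {
  dir <- withr::local_tempdir()
  s <- file.path(dir, "S.tsv"); l <- file.path(dir, "L.tsv")
  writeLines(c("0\t20", "10\t0"), s)
  writeLines(c("0\t70", "35\t0"), l)
  con <- read_connectome(s, l)
  expect_equal(con$W[1, 2], 0.1 * log(20))
  expect_equal(con$D[2, 1], 5)
})
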