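test_that("a single cascade step implements the normalized recursive filter", {
  l <- scale_layout(2, c = 2, K = 1)  # mu_disc = 1
  expect_equal(l$mu_disc, 1)
  st <- cascade_step(cascade_state(l), 1, l)
  expect_equal(st$y, 0.5)
  # DC fixed point
  st2 <- cascade_state(l, init = 3.3)
  expect_equal(cascade_step(st2, 3.3, l)$y, 3.3)
  # impulse response through mu = 1 is geometric with ratio 1/2
  st3 <- cascade_state(l)
  out <- numeric(30)
  for (t in 1:30) {
    st3 <- cascade_step(st3, if (t == 1) 1 else 0, l)
    out[t] <- st3$y
  }
  expect_equal(out, 0.5^(1:30))
  expect_lt(abs(sum(out) - 1), 1e-9)
})

test_that("constants are fixed points of the filtered representation", {
  ss <- scale_space(rep(2.5, 64), scale_layout(16, c = 2, K = 3))
  expect_true(all(ss$L == 2.5))
  ssp <- scale_space(rep(-1, 64), scale_layout(16, c = 2, K = 3),
                     mode = "parallel")
  expect_true(all(ssp$L == -1))
})

test_that("impulse responses have unit mass and cascade composition holds", {
  l <- scale_layout(16, c = 2, K = 3)
  imp <- scale_space(c(1, numeric(699)), l, init = "zero")
  expect_lt(max(abs(colSums(imp$L) - 1)), 1e-12)
  # column K equals sequential application of the three single-stage filters
  x <- random_signal("white", 256, seed = 2)
  ss <- scale_space(x, l, init = "zero")
  cur <- x
  for (k in 1:3) {
    a <- 1 / (1 + l$mu_disc[k])
    cur <- as.numeric(stats::filter(a * cur, 1 - a, method = "recursive",
                                    init = 0))
  }
  expect_equal(cur, unname(ss$L[, 3]))
})

test_that("streaming and batch filtering agree bit-identically", {
  l <- scale_layout(64, c = sqrt(2), K = 6)
  x <- random_signal("wiener", 300, seed = 9)
  ss <- scale_space(x, l)
  st <- cascade_state(l, init = x[1])
  for (s in x) st <- cascade_step(st, s, l)
  expect_identical(st$y, unname(ss$L[300, ]))
})

test_that("filtering a level with the next stage reproduces the next level", {
  l <- scale_layout(16, c = 2, K = 3)
  x <- random_signal("wiener", 400, seed = 4)
  ss <- scale_space(x, l)
  for (k in 1:2) {
    a <- 1 / (1 + l$mu_disc[k + 1])
    single <- stats::filter(a * ss$L[, k], 1 - a, method = "recursive",
                            init = x[1])
    expect_equal(as.numeric(single), unname(ss$L[, k + 1]), tolerance = 1e-14)
  }
})

test_that("materialized discrete kernels are non-negative with variance tau_k", {
  l1 <- scale_layout(2, c = 2, K = 1)
  h <- impulse_responses(l1, 1e-10)[, 1]
  expect_equal(h[1:5], 0.5^(1:5))
  l <- scale_layout(16, c = 2, K = 3)
  imp <- impulse_responses(l, 1e-12)
  expect_true(all(imp >= 0))
  expect_lt(abs(kernel_variance(imp[, 3]) - 16), 1e-6)
  expect_error(impulse_responses(l, 2), class = "tcss_invalid_parameter")
})

test_that("temporal differences are exact on polynomial sequences", {
  n <- 64
  l <- scale_layout(1e-9, c = 2, K = 2)  # nearly-identity smoothing
  ramp <- scale_space(seq_len(n), l)
  d1 <- temporal_derivative(ramp, 1)
  expect_equal(unname(d1$L[5:n, 1]), rep(1, n - 4), tolerance = 1e-6)
  expect_true(all(is.na(d1$L[1, ])))
  d0 <- temporal_derivative(scale_space(rep(4, n), l), 2)
  expect_equal(unname(d0$L[3:n, 1]), rep(0, n - 2))
  quad <- scale_space((seq_len(n))^2, l)
  d2 <- temporal_derivative(quad, 2)
  expect_equal(unname(d2$L[8:n, 1]), rep(2, n - 7), tolerance = 1e-5)
  expect_error(temporal_derivative(ramp, -1), class = "tcss_invalid_parameter")
})

test_that("the temporal jet supports a local Taylor reconstruction", {
  x <- sin(2 * pi * (0:2047) / 512)
  ss <- scale_space(x, scale_layout(64, c = 2, K = 6))
  jet <- temporal_jet(ss, 2, scheme = "none")
  expect_length(jet, 3)
  expect_equal(dim(jet[[3]]$L), dim(jet[[1]]$L))
  expect_equal(jet[[1]]$L, ss$L)  # order zero is the smoothed signal
  t0 <- 1000
  err <- vapply(c(2, 4, 8), function(Dt) {
    pred <- jet[[1]]$L[t0, 6] + Dt * jet[[2]]$L[t0, 6] +
      Dt^2 / 2 * jet[[3]]$L[t0, 6]
    abs(pred - jet[[1]]$L[t0 + Dt, 6])
  }, numeric(1))
  expect_lt(max(err), 1e-3 * max(abs(jet[[1]]$L[, 6])))
})

test_that("extrema counting collapses plateaus", {
  expect_equal(count_extrema(c(1, 2, 1)), 1)
  expect_equal(count_extrema(c(1, 2, 3, 4)), 0)
  expect_equal(count_extrema(c(1, 2, 2, 1)), 1)
  expect_equal(count_extrema(c(2, 2)), 0)
  expect_equal(count_extrema(c(1, 2, 1, 2, 1)), 3)
})

test_that("smoothing never creates local extrema across cascade levels", {
  for (seed in 1:20) {
    kind <- c("wiener", "white", "varying_sine")[seed %% 3 + 1]
    n <- c(64, 200, 1024)[seed %% 3 + 1]
    x <- random_signal(kind, n, seed)
    ss <- scale_space(x, scale_layout(min(256, n / 4), c = sqrt(2), K = 8))
    counts <- c(count_extrema(x),
                vapply(seq_len(8), function(k) count_extrema(ss$L[, k]),
                       numeric(1)))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("parallel memory channels are simplifications of the input only", {
  x <- random_signal("wiener", 1024, seed = 13)
  l <- scale_layout(256, c = 2, K = 5)
  ssp <- scale_space(x, l, mode = "parallel")
  n0 <- count_extrema(x)
  for (k in 1:5) expect_lte(count_extrema(ssp$L[, k]), n0)
  # and each channel has the discrete variance of its own tau level
  impp <- scale_space(c(1, numeric(4095)), l, mode = "parallel", init = "zero")
  expect_lt(abs(kernel_variance(impp$L[, 5]) - l$tau[5]) / l$tau[5], 1e-6)
})

test_that("state/layout mismatches and empty inputs are rejected", {
  l3 <- scale_layout(16, c = 2, K = 3)
  l2 <- scale_layout(16, c = 2, K = 2)
  expect_error(cascade_step(cascade_state(l2), 1, l3),
               class = "tcss_contract_violation")
  expect_error(scale_space(numeric(0), l3), class = "tcss_invalid_input")
})
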