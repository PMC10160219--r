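test_that("closed-form ex-Gaussian moments match adaptive quadrature", {
  for (mu in c(0.8, 2, 4)) for (s in c(0.3, 1, 2)) for (m in c(0.5, 2, 5)) {
    mom <- exgauss_moments(mu, s, m)
    up <- m + 80 * mu + 20 * s
    quad <- vapply(0:3, function(k)
      integrate(function(t) t^k * ex_gaussian(t, mu, s, m), 0, up,
                rel.tol = 1e-12, subdivisions = 4000L)$value, numeric(1))
    expect_equal(mom$M, quad, tolerance = 1e-8)
  }
})

test_that("ex-Gaussian moments behave as half-line moments should", {
  mom <- exgauss_moments(4, 0.5, 2)
  expect_equal(mom$M[1], 5.01, tolerance = 0.001)
  # negligible mass below zero: mean ~ m + mu, variance ~ sigma^2 + mu^2
  expect_equal(mom$delta, 6, tolerance = 1e-4)
  expect_equal(mom$V, 16.25, tolerance = 1e-3)
  expect_equal(exgauss_moments(4, 0.5, 2, a1 = 2)$M, 2 * mom$M)
})

test_that("second-order moment matching reproduces the reference fits", {
  cases <- list(
    list(par = c(4, 0.5, 2), exp = c(tau = 16.25, c = 2.65, b1 = 5.01)),
    list(par = c(4, 2, 2),   exp = c(tau = 18.94, c = 2.89, b1 = 19.37)),
    list(par = c(1, 0.5, 1), exp = c(tau = 1.24, c = 1.89, b1 = 1.25)))
  for (cs in cases) {
    fit <- fit_limit_kernel(exgauss_moments(cs$par[1], cs$par[2], cs$par[3]))
    expect_equal(fit$tau, unname(cs$exp["tau"]), tolerance = 0.01 / cs$exp["tau"])
    expect_equal(fit$c, unname(cs$exp["c"]), tolerance = 0.01 / cs$exp["c"])
    expect_equal(fit$b1, unname(cs$exp["b1"]), tolerance = 0.01 / cs$exp["b1"])
    expect_equal(fit$t0, 0)
  }
})

test_that("moment maps are self-consistent and fail exactly when infeasible", {
  # limit-kernel moments in closed form: mean sqrt((c+1)/(c-1)) sqrt(tau), var tau
  for (tau in c(1, 9, 100)) for (cc in c(1.3, 2, 5)) {
    mean_t <- sqrt((cc + 1) / (cc - 1)) * sqrt(tau)
    mom <- structure(list(M = c(1, mean_t, tau + mean_t^2),
                          delta = mean_t, V = tau), class = "moment_set")
    fit <- fit_limit_kernel(mom)
    expect_equal(fit$tau, tau, tolerance = 1e-12)
    expect_equal(fit$c, cc, tolerance = 1e-12)
  }
  # Gamma-shaped input: delta = 4, V = 4 -> c = 5/3, tau = 4
  momg <- structure(list(M = c(1, 4, 20), delta = 4, V = 4),
                    class = "moment_set")
  fitg <- fit_limit_kernel(momg)
  expect_equal(fitg$c, 5 / 3)
  expect_equal(fitg$tau, 4)
  # infeasible: delta^2 <= V
  bad <- structure(list(M = c(1, 2, 4 + 5), delta = 2, V = 5),
                   class = "moment_set")
  expect_error(fit_limit_kernel(bad), class = "tcss_infeasible_fit")
  edge <- structure(list(M = c(1, 2, 8), delta = 2, V = 4),
                    class = "moment_set")
  expect_error(fit_limit_kernel(edge), class = "tcss_infeasible_fit")
})

test_that("the offset fit recovers shifted limit-kernel parameters", {
  tg <- seq(0, 120, by = 0.01)
  x <- 2.5 * limit_kernel(tg - 5, 16, 2, K_trunc = 12)
  fit <- fit_limit_kernel_offset(signal_moments(tibble::tibble(time = tg, value = x)))
  expect_equal(fit$b1, 2.5, tolerance = 0.01)
  expect_equal(fit$t0, 5, tolerance = 0.01)
  expect_equal(fit$tau, 16, tolerance = 0.01)
  expect_equal(fit$c, 2, tolerance = 0.01)
})

test_that("the offset fit reduces to the second-order fit at t0 = 0", {
  mean_t <- sqrt(3) * 4  # tau = 16, c = 2
  g1 <- limit_kernel_shape(2)$gamma1
  mu3 <- g1 * 16^1.5
  M3 <- mu3 + 3 * mean_t * 16 + mean_t^3
  mom <- structure(list(M = c(1, mean_t, 16 + mean_t^2, M3),
                        delta = mean_t, V = 16), class = "moment_set")
  f0 <- fit_limit_kernel(mom)
  f3 <- fit_limit_kernel_offset(mom)
  expect_equal(f3$t0, 0, tolerance = 1e-6)
  expect_equal(f3$c, f0$c, tolerance = 1e-6)
  expect_equal(f3$tau, f0$tau, tolerance = 1e-6)
})

test_that("recovered c increases with the skewness of the input", {
  cs <- c(1.3, 1.8, 2.5, 4)
  rec <- vapply(cs, function(cc) {
    tg <- seq(0, 80, by = 0.02)
    x <- limit_kernel(tg, 4, cc, K_trunc = 16)
    fit_limit_kernel_offset(signal_moments(tibble::tibble(time = tg, value = x)))$c
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
  expect_equal(rec, cs, tolerance = 0.02)
})

test_that("fitting a sampled kernel recovers its parameters", {
  tg <- seq(0, 120, by = 0.01)
  fit <- fit_signal(tibble::tibble(time = tg, value = limit_kernel(tg, 9, 2, 24)))
  expect_equal(fit$tau, 9, tolerance = 0.02)
  expect_equal(fit$c, 2, tolerance = 0.02)
  expect_lt(fit$diagnostics$rel_residual, 0.01)
  fitg <- fit_signal(tibble::tibble(time = tg,
                                    value = compose_uniform_kernel(tg, 1, 4)))
  expect_equal(fitg$c, 5 / 3, tolerance = 0.02)
  expect_equal(fitg$tau, 4, tolerance = 0.02)
  expect_error(fit_signal(numeric(32)), class = "tcss_infeasible_fit")
})

test_that("tidy and glance expose the fitted parameters", {
  fit <- fit_limit_kernel(exgauss_moments(4, 0.5, 2))
  td <- tidy(fit)
  expect_equal(td$term, c("b0", "b1", "t0", "tau", "c"))
  expect_equal(td$estimate[4], fit$tau)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$c, fit$c)
})

test_that("the Koenderink map round-trips and degenerates as documented", {
  km <- koenderink_map(1, 2)
  expect_equal(km$sigma, sqrt(log(4 / 3)))
  expect_equal(km$delta, 9 / 8)
  inv <- koenderink_inverse(km$sigma, km$delta)
  expect_equal(inv$tau, 1)
  expect_equal(inv$c, 2)
  expect_lt(koenderink_map(1, 1 + 1e-9)$sigma, 1e-4)
  # sup over c > 1 of sigma is sqrt(log 2)
  expect_lt(koenderink_map(1, 1e9)$sigma, sqrt(log(2)))
  expect_equal(koenderink_map(1, 1e9)$sigma, sqrt(log(2)), tolerance = 1e-8)
  expect_error(koenderink_inverse(0.9, 1), class = "tcss_out_of_domain")
})

test_that("the peak-location estimate overestimates and scales as sqrt(tau)", {
  expect_equal(tmax_estimate(1, 2), 1.125)
  # a delay estimate, close to (and typically past) the true peak; much
  # better than the temporal mean, which badly overshoots
  for (cc in c(sqrt(2), 2)) for (tau in c(1, 16)) {
    tg <- seq(0, 20 * sqrt(tau), by = sqrt(tau) / 500)
    t_peak <- tg[which.max(limit_kernel(tg, tau, cc, K_trunc = 16))]
    est <- tmax_estimate(tau, cc)
    expect_gte(est, 0.95 * t_peak)
    mean_t <- sqrt((cc + 1) / (cc - 1)) * sqrt(tau)
    expect_lt(abs(est - t_peak), abs(mean_t - t_peak))
  }
  expect_equal(tmax_estimate(16, 2) / tmax_estimate(1, 2), 4)
})
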