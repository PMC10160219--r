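# independent numerical oracles used across the suite

# rectangle-rule causal convolution of two sampled kernels on a shared grid
grid_convolve <- function(a, b, dt) {
  stats::convolve(a, rev(b), type = "open")[seq_along(a)] * dt
}

# raw moments of a sampled non-negative function by quadrature on [0, upper]
quad_moment <- function(fun, k, upper, ...) {
  stats::integrate(function(t) t^k * fun(t, ...), 0, upper,
                   rel.tol = 1e-10, subdivisions = 2000L)$value
}

# discrete kernel moments (index-weighted, mass-renormalized)
kernel_variance <- function(h) {
  u <- seq_along(h) - 1
  m <- sum(h)
  sum(u^2 * h) / m - (sum(u * h) / m)^2
}

# random test signal of a given kind, deterministic in seed
random_signal <- function(kind, n, seed) {
  withr::with_seed(seed, switch(kind,
    wiener = cumsum(c(0, rnorm(n - 1))),
    white  = rnorm(n),
    varying_sine = sin(exp(pmin((n / 2 - seq_len(n)) / (n / 8), 700)))))
}
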