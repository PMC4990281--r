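# shared fixtures for the test suite

# the noise-versus-mean scan's reference parameter set: geometric bursts
# with <B> = 1.5, Erlang-20 clock (CV_T^2 = 0.05), binomial partitioning
fig_params <- function(kx = 10) {
  list(b = burst_model(kx, 1.5, burst_family = "geometric0"),
       p = partition_model(1),
       clock = erlang_mixture_from_target(1, 0.05))
}

# random valid Erlang mixture with up to `max_comp` adjacent-ish orders
random_mixture <- function(max_order = 20, max_comp = 3) {
  k <- stats::runif(1, 0.2, 5)
  nc <- sample.int(max_comp, 1)
  orders <- sort(sample.int(max_order, nc))
  pr <- stats::runif(nc)
  erlang_mixture(orders, pr / sum(pr), rate_scale = k)
}

# random model parameters for property sweeps
random_params <- function() {
  fam <- sample(c("geometric0", "geometric1", "point_mass"), 1)
  bm <- stats::runif(1, 1, 8)
  list(b = burst_model(stats::runif(1, 1, 30), bm, burst_family = fam),
       p = partition_model(stats::runif(1, 0, 4)))
}

expect_rel_equal <- function(actual, expected, rel_tol = 1e-8) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), rel_tol)
}
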