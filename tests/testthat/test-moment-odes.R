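test_that("occupancy block conserves probability and gives p_i/i per stage", {
  b <- burst_model(5, 2)
  p <- partition_model(1)
  clk <- erlang_mixture(c(2L, 5L), c(0.3, 0.7), 1.3)
  sys <- build_moment_system(clk, b, p)
  S <- sys$n_stages
  # columns of the occupancy block sum to zero (exact conservation)
  expect_lt(max(abs(colSums(sys$A[1:S, 1:S]))), 1e-12)
  ss <- steady_state_moments(sys)
  expect_equal(sum(ss$occupancy), 1)
  # stationary occupancy of stage (i, j) is p_i / i
  pr <- ifelse(ss$stages$branch == 2L, 0.3, 0.7)
  expect_equal(ss$occupancy, pr / ss$stages$branch, tolerance = 1e-12)
})

test_that("first-moment steady state obeys the division balance and Eq-16 form", {
  b <- burst_model(7, 1.5)
  p <- partition_model(2)
  clk <- erlang_mixture(c(3L, 4L), c(0.6, 0.4), 2)
  ss <- steady_state_moments(build_moment_system(clk, b, p))
  st <- ss$stages
  # sum over terminal stages of (branch order) * <x g_jj> = 2 kx <B> / k
  term <- st$step == st$branch
  expect_rel_equal(sum(st$branch[term] * ss$first[term]),
                   2 * b$kx * b$burst_mean / clk$rate_scale)
  # per-stage closed form <x g_ij> = kx <B> p_i (1 + j/i) / (i k)
  pr <- ifelse(st$branch == 3, 0.6, 0.4)
  ref <- b$kx * b$burst_mean * pr * (1 + st$step / st$branch) /
    (st$branch * clk$rate_scale)
  expect_equal(ss$first, ref, tolerance = 1e-10)
})

test_that("steady states reproduce every closed form over random draws", {
  set.seed(101)
  for (i in 1:60) {
    pars <- random_params()
    clk <- random_mixture()
    tm <- timing_moments(clk)
    mx <- mean_protein(pars$b, tm)
    # hybrid B: timing-only second moment and extrinsic CV^2
    hb <- steady_state_moments(build_moment_system(
      clk, pars$b, pars$p, model_flags(FALSE, FALSE)))
    kb <- pars$b$kx * pars$b$burst_mean
    second_ref <- kb^2 * tm$mean^2 *
      (tm$third_moment_ratio + 4 * tm$cv2 + 6) / 3
    expect_rel_equal(hb$second_x, second_ref)
    expect_rel_equal(hb$cv2, extrinsic_noise(tm$cv2, tm$third_moment_ratio))
    # hybrid C adds the partitioning term 2 alpha kx <B> <T> / 3
    hc <- steady_state_moments(build_moment_system(
      clk, pars$b, pars$p, model_flags(FALSE, TRUE)))
    expect_rel_equal(hc$second_x,
                     second_ref + 2 * pars$p$alpha * kb * tm$mean / 3)
    expect_rel_equal(hc$cv2 - hb$cv2,
                     partitioning_noise(pars$p, tm$cv2, mx))
    # full model adds kx <B^2> <T> (3 CV_T^2 + 5) / 6
    fm <- steady_state_moments(build_moment_system(
      clk, pars$b, pars$p, model_flags(TRUE, TRUE)))
    expect_rel_equal(fm$second_x,
                     second_ref + 2 * pars$p$alpha * kb * tm$mean / 3 +
                       pars$b$kx * pars$b$burst_second_moment * tm$mean *
                       (3 * tm$cv2 + 5) / 6)
    expect_rel_equal(fm$mean_x, mx)
    expect_rel_equal(fm$cv2 - hc$cv2,
                     production_noise(pars$b, tm$cv2, mx))
  }
})

test_that("constant-variance partitioning matches its closed form", {
  b <- burst_model(4, 2)
  p <- partition_model(3, variance_law = "constant")
  clk <- erlang_mixture(c(4L, 5L), c(0.5, 0.5), 1)
  tm <- timing_moments(clk)
  mx <- mean_protein(b, tm)
  hb <- steady_state_moments(build_moment_system(
    clk, b, p, model_flags(FALSE, FALSE)))
  hc <- steady_state_moments(build_moment_system(
    clk, b, p, model_flags(FALSE, TRUE)))
  expect_rel_equal(hc$cv2 - hb$cv2, 4 * p$alpha / 3 / mx^2, 1e-8)
})

test_that("duplication steady states match the mean and f = 2 closed forms", {
  set.seed(33)
  for (i in 1:25) {
    pars <- random_params()
    d <- duplication_schedule(
      2,
      erlang_mixture_from_target(stats::runif(1, 0.2, 0.8),
                                 stats::runif(1, 0.05, 1)),
      erlang_mixture_from_target(stats::runif(1, 0.2, 0.8),
                                 stats::runif(1, 0.05, 1)))
    mx <- duplication_mean(pars$b, d)
    dn <- decompose_numeric(NULL, pars$b, pars$p, duplication = d)
    expect_rel_equal(dn$mean_x, mx)
    intr <- duplication_intrinsic_f2(pars$b, pars$p, d$beta,
                                     d$cv2_T1, d$cv2_T2, mx)
    expect_rel_equal(dn$cv2_part, intr[["cv2_part"]])
    expect_rel_equal(dn$cv2_prod, intr[["cv2_prod"]])
  }
  # general dosage factor: additivity holds by construction and the mean
  # follows the general-f formula
  b <- burst_model(6, 2); p <- partition_model(1.2)
  d3 <- duplication_schedule(3, erlang_mixture_from_target(0.5, 0.2),
                             erlang_mixture_from_target(0.5, 0.2))
  dn3 <- decompose_numeric(NULL, b, p, duplication = d3)
  expect_identical(dn3$cv2_total, dn3$cv2_ext + dn3$cv2_part + dn3$cv2_prod)
  expect_rel_equal(dn3$mean_x, duplication_mean(b, d3))
})

test_that("deterministic-timing duplication extrinsic matches the ODE limit", {
  # Richardson extrapolation in the phase CV^2 (error is linear in cv2)
  for (beta in c(0.3, 0.5)) {
    e1 <- cycnoise:::dup_extrinsic_numeric(beta, 1 / 100, 1 / 100, 2)
    e2 <- cycnoise:::dup_extrinsic_numeric(beta, 1 / 200, 1 / 200, 2)
    extrap <- 2 * e2 - e1
    expect_rel_equal(extrap, duplication_extrinsic_limit(beta), 1e-4)
  }
})

test_that("fast-turnover degradation recovers the unstable-protein forms", {
  b <- burst_model(10, 1.5)
  p <- partition_model(1)
  beta <- 0.5
  d <- duplication_schedule(2, erlang_mixture_from_target(beta, 0.01),
                            erlang_mixture_from_target(1 - beta, 0.01))
  # gamma_x <T> = 50: extrinsic within 2% of the two-level dosage formula
  hb <- steady_state_moments(build_moment_system(
    NULL, b, p, model_flags(FALSE, FALSE, duplication = d,
                            degradation = 50)))
  ref <- (1 - beta) * beta / (2 - beta)^2
  expect_lt(abs(hb$cv2 - ref) / ref, 0.02)
  # full model: mean and production Fano near the fast-decay closed form
  dn <- decompose_numeric(NULL, b, p, duplication = d, degradation = 50)
  un <- unstable_noise(b, beta, 50)
  expect_lt(abs(dn$mean_x - un$mean_x) / un$mean_x, 0.02)
  expect_lt(abs(dn$cv2_prod - un$cv2_prod) / un$cv2_prod, 0.05)
  # partitioning contribution is wiped out by fast turnover
  expect_lt(dn$cv2_part / dn$cv2_total, 0.01)
})

test_that("transients conserve occupancy and converge to the steady state", {
  b <- burst_model(5, 1.5)
  p <- partition_model(1)
  clk <- erlang_mixture(c(2L, 3L), c(0.4, 0.6), 1)
  sys <- build_moment_system(clk, b, p)
  ss <- steady_state_moments(sys)
  # starting at the fixed point stays there
  tr <- transient_moments(sys, ss, horizon = 5, n_points = 30)
  expect_lt(max(abs(tr$mean_x - ss$mean_x)) / ss$mean_x, 1e-7)
  expect_lt(max(abs(tr$occ_total - 1)), 1e-9)
  # a newborn zero-protein lineage rises monotonically to the Eq-17 mean
  tr0 <- transient_moments(sys, NULL, horizon = 30, n_points = 120)
  expect_lt(max(abs(tr0$occ_total - 1)), 1e-9)
  expect_true(all(diff(tr0$mean_x) > -1e-8))
  expect_rel_equal(tr0$mean_x[nrow(tr0)], mean_protein(b, clk), 1e-5)
})

test_that("system dump writes inspectable triplets", {
  sys <- build_moment_system(erlang_mixture(2L, 1, 1), burst_model(1, 1),
                             partition_model(1))
  tf <- tempfile(fileext = ".tsv")
  trip <- write_system_triplets(sys, tf)
  expect_true(file.exists(tf))
  got <- utils::read.delim(tf)
  expect_equal(nrow(got), nrow(trip))
  A2 <- matrix(0, nrow(sys$A), ncol(sys$A))
  A2[cbind(got$row, got$col)] <- got$value
  expect_equal(A2, sys$A)
})
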