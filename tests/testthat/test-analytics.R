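test_that("mean protein level depends on timing noise as (3 + CV_T^2)/2", {
  b <- burst_model(1, 1, burst_family = "point_mass")
  expect_equal(mean_protein(b, timing_moments_manual(1, 0)), 1.5)
  expect_equal(mean_protein(b, timing_moments_manual(1, 1)), 2.0)
  # 25% reduction moving from exponential to periodic cycles at fixed <T>
  m1 <- mean_protein(b, timing_moments_manual(1, 1))
  m0 <- mean_protein(b, timing_moments_manual(1, 0))
  expect_equal(100 * (m1 - m0) / m1, 25)
})

test_that("extrinsic noise hits the 1/27 delta-timing floor and known forms", {
  expect_identical(extrinsic_noise(0, 1), 1 / 27)
  # lognormal closed form, independently evaluated as the printed polynomial
  c2 <- 0.05
  poly <- 1 / 27 + 4 * (21 * c2 + 20 * c2^2 + 9 * c2^3) / (27 * (3 + c2)^2)
  expect_equal(extrinsic_noise_lognormal(c2), poly, tolerance = 1e-14)
  # Taylor form agrees with the full formula at small CV
  c2 <- 0.01
  full <- extrinsic_noise_clock(erlang_mixture(100L, 1, 1))
  tay <- extrinsic_noise(c2, NA, taylor = TRUE)
  expect_lt(abs(full - tay) / full, 1e-3)
  expect_error(extrinsic_noise(0.1, 0.5), "Jensen")
})

test_that("partitioning noise follows the proportional and constant laws", {
  m <- 40
  expect_equal(partitioning_noise(partition_model(0), 0.3, m), 0)
  expect_equal(partitioning_noise(partition_model(1), 0, m), 4 / (9 * m))
  # value at cv2_T = 1 is 3/4 of the value at cv2_T = 0 (fixed mean)
  p1 <- partition_model(1)
  expect_equal(partitioning_noise(p1, 1, m) / partitioning_noise(p1, 0, m),
               3 / 4)
  # constant law: no timing dependence, 1/mean^2 scaling
  pc <- partition_model(2, variance_law = "constant")
  expect_equal(partitioning_noise(pc, 0, m), partitioning_noise(pc, 1, m))
  expect_equal(partitioning_noise(pc, 0.5, m), 8 / (3 * m^2))
})

test_that("production noise carries the burst moment ratio", {
  m <- 40
  b <- burst_model(1, 2, burst_family = "point_mass")
  expect_equal(production_noise(b, 0, m), (5 / 9) * 2 / m)
  # geometric bursts on {0,1,...}: <B^2>/<B> = 1 + 2<B>
  bg <- burst_model(1, 1.5)
  expect_equal(bg$burst_second_moment / bg$burst_mean, 4)
  expect_equal(production_noise(bg, 0, m), (5 / 9) * 4 / m)
  # shifted geometric: 2<B> - 1
  bs <- burst_model(1, 1.5, burst_family = "geometric1")
  expect_equal(bs$burst_second_moment / bs$burst_mean, 2)
})

test_that("B = 1, alpha = 1 gives intrinsic noise exactly 1/mean", {
  b <- burst_model(1, 1, burst_family = "point_mass")
  p <- partition_model(1)
  for (c2 in c(0, 0.05, 0.3, 1)) {
    m <- 25
    expect_equal(partitioning_noise(p, c2, m) + production_noise(b, c2, m),
                 1 / m, tolerance = 1e-14)
  }
})

test_that("decomposition is additive and approaches the extrinsic baseline", {
  set.seed(7)
  for (i in 1:50) {
    pars <- random_params()
    clk <- random_mixture()
    d <- decompose_noise(pars$b, clk, pars$p)
    expect_identical(d$cv2_total, d$cv2_ext + d$cv2_part + d$cv2_prod)
  }
  # k_x -> infinity: total -> extrinsic
  clk <- erlang_mixture_from_target(1, 0.05)
  p <- partition_model(1)
  d <- decompose_noise(burst_model(1e8, 1.5), clk, p)
  expect_lt((d$cv2_total - d$cv2_ext) / d$cv2_ext, 1e-6)
  # intrinsic terms scale as 1/mean with the stated prefactors
  tm <- timing_moments(clk)
  for (kx in c(2, 20, 200)) {
    d <- decompose_noise(burst_model(kx, 1.5), clk, p)
    expect_equal(d$cv2_part * d$mean_x, 4 / (3 * (3 + tm$cv2)))
    expect_equal(d$cv2_prod * d$mean_x, 4 * (3 * tm$cv2 + 5) / (3 * (3 + tm$cv2)))
  }
})

test_that("closed forms are monotone in timing noise as predicted", {
  c2 <- seq(0, 1, by = 0.05)
  m <- 30
  p <- partition_model(1)
  b <- burst_model(1, 2)
  part <- vapply(c2, function(c) partitioning_noise(p, c, m), 1)
  prod <- vapply(c2, function(c) production_noise(b, c, m), 1)
  means <- vapply(c2, function(c) {
    mean_protein(b, timing_moments_manual(1, c))
  }, 1)
  expect_true(all(diff(part) < 0))
  expect_true(all(diff(prod) > 0))
  expect_true(all(diff(means) > 0))
})

test_that("duplication mean reduces correctly at the endpoints", {
  b <- burst_model(3, 2)
  tiny <- 1e-9
  # beta = 1: pre-duplication phase spans the cycle -> no-duplication mean
  d1 <- duplication_schedule(2, erlang_mixture_from_target(1, 0.2),
                             erlang_mixture_from_target(tiny, 0.5))
  expect_equal(duplication_mean(b, d1),
               mean_protein(b, timing_moments_manual(1, 0.2)),
               tolerance = 1e-6)
  # beta = 0 with f = 2: twice the no-duplication mean
  d0 <- duplication_schedule(2, erlang_mixture_from_target(tiny, 0.5),
                             erlang_mixture_from_target(1, 0.2))
  expect_equal(duplication_mean(b, d0),
               2 * mean_protein(b, timing_moments_manual(1, 0.2)),
               tolerance = 1e-6)
})

test_that("duplication mean matches the hand-evaluated midpoint case", {
  # f = 2, beta = 0.5, deterministic phases, kx<B><T> = 1:
  # beta*T*(4 - beta)/2 + (1 - beta)*T*(3 - beta) = 0.875 + 1.25 = 2.125
  b <- burst_model(1, 1, burst_family = "point_mass")
  expect_equal(duplication_mean_params(b, f = 2, beta = 0.5), 2.125,
               tolerance = 1e-12)
  # schedule-based path agrees with the parameter-level form
  d <- duplication_schedule(2, erlang_mixture_from_target(0.4, 0.3),
                            erlang_mixture_from_target(0.6, 0.2))
  expect_equal(duplication_mean(b, d),
               duplication_mean_params(b, 2, d$beta, d$mean_T,
                                       d$cv2_T1, d$cv2_T2))
})

test_that("f = 2 intrinsic closed form recovers the no-duplication limits", {
  set.seed(11)
  for (i in 1:200) {
    pars <- random_params()
    c1 <- stats::runif(1, 0, 1); c2 <- stats::runif(1, 0, 1)
    m <- stats::runif(1, 10, 200)
    for (beta in c(0, 1)) {
      cv_here <- if (beta == 0) c2 else c1
      intr <- duplication_intrinsic_f2(pars$b, pars$p, beta, c1, c2, m)
      expect_lt(abs(intr[["cv2_part"]] -
                      partitioning_noise(pars$p, cv_here, m)), 1e-12)
      expect_lt(abs(intr[["cv2_prod"]] -
                      production_noise(pars$b, cv_here, m)), 1e-12)
    }
    # B = 1, alpha = 1: intrinsic sum is 1/mean for any beta and phase CVs
    beta <- stats::runif(1)
    b1 <- burst_model(1, 1, burst_family = "point_mass")
    intr <- duplication_intrinsic_f2(b1, partition_model(1), beta, c1, c2, m)
    expect_lt(abs(sum(intr) - 1 / m), 1e-14)
  }
  expect_error(
    duplication_intrinsic_f2(burst_model(1, 1), partition_model(1),
                             0.5, 0, 0, 10, f = 3),
    "decompose_numeric")
})

test_that("deterministic-timing duplication extrema sit at beta = 2 - sqrt(2)", {
  expect_equal(duplication_extrinsic_limit(0), 1 / 27)
  expect_equal(duplication_extrinsic_limit(1), 1 / 27)
  opt_p <- beta_optimum("production")
  expect_equal(opt_p$beta_opt, 2 - sqrt(2), tolerance = 1e-6)
  expect_equal(opt_p$rel_change, duplication_prod_factor(2 - sqrt(2)) /
                 duplication_prod_factor(0) - 1, tolerance = 1e-10)
  opt_r <- beta_optimum("partitioning")
  expect_equal(opt_r$beta_opt, 2 - sqrt(2), tolerance = 1e-6)
  # exponential phases: same optimum location when the phase CVs are equal
  opt_e <- beta_optimum("production", cv2_T1 = 1, cv2_T2 = 1)
  expect_equal(opt_e$beta_opt, 2 - sqrt(2), tolerance = 1e-6)
})

test_that("unstable-protein limit has the stated extrinsic maximum", {
  b <- burst_model(2, 1.5)
  expect_equal(unstable_noise(b, 0, 10)$cv2_ext, 0)
  expect_equal(unstable_noise(b, 2 / 3, 10)$cv2_ext, 1 / 8)
  # beta = 2/3 is the maximizer
  ext <- vapply(seq(0, 1, 1e-3),
                function(beta) unstable_noise(b, beta, 10)$cv2_ext, 1)
  expect_equal(seq(0, 1, 1e-3)[which.max(ext)], 2 / 3, tolerance = 1e-3)
  # B = 1: production Fano factor is 1 for every beta
  b1 <- burst_model(2, 1, burst_family = "point_mass")
  for (beta in c(0, 0.3, 0.9)) {
    u <- unstable_noise(b1, beta, 10)
    expect_equal(u$cv2_prod * u$mean_x, 1)
    expect_equal(u$cv2_part, 0)
    expect_equal(u$mean_x, 2 * 1 * (2 - beta) / 10)
  }
})

test_that("stage-conditioned moments have the birth/division prefactors", {
  b <- burst_model(5, 2)
  p <- partition_model(1.5)
  n <- 4000
  ratio <- b$burst_second_moment / b$burst_mean
  birth <- synchronized_moments(n, 1, b, p)
  expect_equal(birth$cv2_part * birth$cond_mean, 2 * p$alpha / 3,
               tolerance = 1e-3)
  expect_equal(birth$cv2_prod * birth$cond_mean, ratio / 3, tolerance = 1e-3)
  division <- synchronized_moments(n, n, b, p)
  expect_equal(division$cv2_part * division$cond_mean, p$alpha / 3,
               tolerance = 1e-3)
  expect_equal(division$cv2_prod * division$cond_mean, 2 * ratio / 3,
               tolerance = 1e-3)
  # B = 1, alpha = 1: conditional intrinsic Fano is 1 at every stage
  b1 <- burst_model(5, 1, burst_family = "point_mass")
  for (j in c(1, 7, 20)) {
    sm <- synchronized_moments(20, j, b1, partition_model(1))
    expect_equal((sm$cv2_part + sm$cv2_prod) * sm$cond_mean, 1,
                 tolerance = 1e-14)
  }
  expect_error(synchronized_moments(10, 11, b, p), "1..n")
})
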