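test_that("bias factor and epsilon follow the barrier relations", {
  st <- init_explore("x", barrier = 50, pace = 5000, sigma0 = 0.2, T = 300)
  expect_equal(st$gamma, 50 / (kB * 300))
  expect_equal(st$gamma, 20.045, tolerance = 1e-4)
  # printed standard-OPES relation and the Explore-consistent pairing
  expect_equal(epsilon_from_barrier(50, 300, variant = "paper"),
               exp(-21.098), tolerance = 1e-4)
  expect_equal(epsilon_from_barrier(50, 300, variant = "explore"),
               0.34906, tolerance = 1e-4)
  # large-barrier limits: the `paper` variant vanishes; the `explore`
  # variant at the default gamma = dE/kBT rises monotonically towards exp(-1)
  expect_lt(epsilon_from_barrier(500, 300, variant = "paper"), 1e-80)
  eps_seq <- vapply(c(10, 30, 100, 1000),
                    function(dE) epsilon_from_barrier(dE, 300,
                                                      variant = "explore"), 0)
  expect_true(all(diff(eps_seq) > 0))           # rises towards the limit
  expect_true(all(eps_seq < exp(-1)))           # exp(-gamma/(gamma-1)) < 1/e
  expect_equal(eps_seq[4], exp(-1), tolerance = 1e-2)
  # at fixed gamma, epsilon does vanish with the barrier in both pairings
  expect_lt(epsilon_from_barrier(500, 300, gamma = 20, variant = "explore"),
            1e-4)
  # degenerate gamma = 1 is a guarded error
  expect_error(init_explore("x", barrier = kB * 300, pace = 100, sigma0 = 0.1),
               "degenerate")
  expect_error(epsilon_from_barrier(50, 300, gamma = 0.9), "gamma")
  expect_error(init_explore("x", barrier = -1, pace = 100, sigma0 = 0.1))
  expect_error(init_explore("x", barrier = 50, pace = 100, sigma0 = 0))
})

test_that("deposits merge by the weighted-moment rule and conserve weight", {
  st <- init_explore("x", barrier = 50, pace = 100, sigma0 = 0.2)
  st <- deposit(st, 0)
  st <- deposit(st, 0)
  expect_equal(nrow(st$centers), 1)
  expect_equal(st$heights, 2)
  expect_equal(st$centers[1, 1], 0)
  expect_equal(st$sigmas[1, 1], 0.2)
  # beyond one sigma: two kernels
  st2 <- deposit(deposit(init_explore("x", 50, 100, 0.2), 0), 3 * 0.2)
  expect_equal(nrow(st2$centers), 2)
  # within half a sigma: weighted mean center
  st3 <- deposit(deposit(init_explore("x", 50, 100, 0.2), 0), 0.5 * 0.2)
  expect_equal(nrow(st3$centers), 1)
  expect_equal(st3$centers[1, 1], 0.25 * 0.2)
  # brute-force second-moment check for the merged sigma
  h1 <- 1; c1 <- 0; c2 <- 0.1; s0 <- 0.2
  vexp <- (h1 * (s0^2 + c1^2) + (s0^2 + c2^2)) / 2 - ((c1 + c2) / 2)^2
  expect_equal(st3$sigmas[1, 1], sqrt(vexp))
  # weight conservation under long random deposition streams
  set.seed(3)
  st4 <- init_explore("x", 50, 100, 0.15)
  svals <- rnorm(300, sd = 0.6)
  for (s in svals) st4 <- deposit(st4, s)
  expect_equal(sum(st4$heights), 300)
  expect_equal(st4$n_deposited, 300L)
  expect_lt(nrow(st4$centers), 60)  # compression keeps K << n
  expect_error(deposit(st4, NaN), "non-finite")
})

test_that("kernel density is normalized, symmetric and correct at a peak", {
  st <- deposit(init_explore("x", 50, 100, 1), 0)
  expect_equal(as.numeric(opes_density(st, 0)), 1 / sqrt(2 * pi))
  expect_lt(as.numeric(opes_density(st, 40)), 1e-300)
  st2 <- deposit(deposit(init_explore("x", 50, 100, 0.3), -1), 1)
  for (x in c(0.2, 0.7, 1.3))
    expect_equal(as.numeric(opes_density(st2, x)),
                 as.numeric(opes_density(st2, -x)))
  expect_error(opes_density(init_explore("x", 50, 100, 1), 0), "empty")
})

test_that("Z is the mean kernel-center density", {
  st <- deposit(init_explore("x", 50, 100, 1), 0)
  expect_equal(st$Z, as.numeric(opes_density(st, 0)))
  # coincident kernels merge, leaving Z unchanged
  st2 <- deposit(st, 0)
  expect_equal(st2$Z, st$Z)
  # well-separated pair: Z ~ half the single-kernel peak
  st3 <- deposit(deposit(init_explore("x", 50, 100, 0.1), -5), 5)
  expect_equal(st3$Z, 0.5 / (0.1 * sqrt(2 * pi)), tolerance = 1e-10)
  expect_error(update_normalization(init_explore("x", 50, 100, 1)), "empty")
})

test_that("the Explore bias has the exact -barrier floor and known values", {
  st <- deposit(init_explore("x", barrier = 50, pace = 100, sigma0 = 0.2), 0)
  kbt <- kB * 300
  # far away (phat = 0): V = kBT (gamma-1) log eps = -barrier exactly
  expect_equal(as.numeric(explore_bias(st, 100)), -50)
  # at the kernel center: direct substitution of the bias formula
  vc <- as.numeric(explore_bias(st, 0))
  expect_equal(vc, kbt * (st$gamma - 1) * log(1 + st$epsilon))
  expect_equal(vc, 14.224, tolerance = 1e-3)
  expect_gt(vc, 0)
  # monotone nondecreasing in phat at fixed Z, eps
  sq <- seq(0, 3, by = 0.1)
  v <- as.numeric(explore_bias(st, matrix(sq, ncol = 1)))
  p <- as.numeric(opes_density(st, matrix(sq, ncol = 1)))
  expect_true(all(diff(v[order(p)]) >= -1e-12))
  # before any deposition the bias and gradient are identically zero
  st0 <- init_explore("x", 50, 100, 0.2)
  v0 <- explore_bias(st0, matrix(c(-1, 0, 1), ncol = 1), gradient = TRUE)
  expect_equal(as.numeric(v0), c(0, 0, 0))
  expect_equal(attr(v0, "deriv"), matrix(0, 3, 1))
})

test_that("bias gradient matches finite differences", {
  set.seed(8)
  st <- init_explore("x", 30, 100, 0.25)
  for (s in rnorm(40, sd = 0.7)) st <- deposit(st, s)
  for (x in c(-1.2, -0.3, 0.4, 1.5)) {
    v <- explore_bias(st, x, gradient = TRUE)
    fd <- fd_gradient(function(p) as.numeric(explore_bias(st, p)), x)
    expect_equal(as.numeric(attr(v, "deriv")), fd, tolerance = 1e-6)
  }
})

test_that("R and compiled kernel machinery agree exactly", {
  set.seed(21)
  svals <- rnorm(250, sd = 0.5)
  st <- init_explore("x", 40, 100, 0.2)
  for (s in svals) st <- deposit(st, s)
  cpp <- oneopes:::.explore_deposit_seq_cpp(svals, 0.2)
  expect_equal(unname(cbind(st$centers, st$sigmas, st$heights)),
               unname(cpp$kernels))
  expect_equal(st$Z, cpp$Z)
  sq <- seq(-2, 2, by = 0.05)
  vr <- explore_bias(st, matrix(sq, ncol = 1), gradient = TRUE)
  vc <- oneopes:::.explore_eval_cpp(st$centers[, 1], st$sigmas[, 1],
                                    st$heights, st$Z, st$epsilon, st$gamma,
                                    st$kbt, sq)
  expect_equal(as.numeric(vr), vc$value)
  expect_equal(as.numeric(attr(vr, "deriv")), vc$deriv)
})

test_that("multidimensional kernels work with diagonal covariance", {
  st <- init_explore(list(make_cv("x"), make_cv("y")), barrier = 30,
                     pace = 100, sigma0 = c(0.2, 0.1))
  st <- deposit(st, c(0, 0))
  st <- deposit(st, c(1, 1))
  expect_equal(nrow(st$centers), 2)
  expect_equal(as.numeric(opes_density(st, c(0, 0))),
               0.5 * (1 / (2 * pi * 0.2 * 0.1) +
                        exp(-0.5 * (1 / 0.2^2 + 1 / 0.1^2)) / (2 * pi * 0.2 * 0.1)))
  v <- explore_bias(st, c(0.1, 0.05), gradient = TRUE)
  fd <- fd_gradient(function(p) as.numeric(explore_bias(st, p)), c(0.1, 0.05))
  expect_equal(as.numeric(attr(v, "deriv")), fd, tolerance = 1e-6)
})

test_that("kernel checkpoints round-trip through the KERNELS dialect", {
  set.seed(4)
  st <- init_explore("x", 30, 200, 0.2)
  for (s in rnorm(50)) st <- deposit(st, s)
  path <- tempfile()
  write_kernels(st, path)
  st2 <- read_kernels(path, init_explore("x", 30, 200, 0.2))
  expect_equal(unname(st2$centers), unname(st$centers))
  expect_equal(unname(st2$sigmas), unname(st$sigmas))
  expect_equal(st2$heights, st$heights)
  expect_equal(st2$Z, st$Z)
  expect_equal(st2$n_deposited, st$n_deposited)
  sq <- seq(-2, 2, 0.25)
  expect_equal(as.numeric(explore_bias(st2, matrix(sq, ncol = 1))),
               as.numeric(explore_bias(st, matrix(sq, ncol = 1))))
})

test_that("a single-replica Explore run on an ideal CV recovers the oracle", {
  dw <- make_system("double_well_1d")
  run <- run_explore(dw, "x", barrier = 30, pace = 1000, n_steps = 1e6,
                     seed = 1)
  tb <- run$tables[[1]]
  w <- frame_weights(tb, mode = "main", discard_fraction = 0.1)
  est <- delta_f(tb, w, c(-2.5, 0), c(0, 2.5))$value
  oracle <- quadrature_delta_f(dw, "x", c(-2.5, 0), c(0, 2.5))
  expect_lt(abs(est - oracle), 0.5 * kB * 300)
})
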