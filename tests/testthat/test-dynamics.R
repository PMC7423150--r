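test_that("the transfer function is continuous through its singularity", {
  p <- sim_params()
  # exact limit x / (1 - exp(-d x)) -> 1/d at a*chi = b (chi = 0.4)
  expect_equal(firing_rate(0.4, p), 1 / p$d)
  # direct high-precision evaluation at chi = 0:
  # R = -108 / (1 - exp(0.154 * 108))
  expect_equal(firing_rate(0, p), -108 / (1 - exp(0.154 * 108)),
               tolerance = 1e-12)
  expect_lt(firing_rate(0, p), 1e-5)   # effectively silent
  # linear asymptote for large input
  chi <- 2
  expect_lt(abs(firing_rate(chi, p) - (p$a * chi - p$b)), 1e-10)
  # continuity and monotonicity across the singular point
  chi <- seq(0.39, 0.41, length.out = 4001)
  r <- firing_rate(chi, p)
  expect_true(all(diff(r) > 0))
  expect_lt(max(abs(diff(r))), 1e-2)
})

test_that("synaptic input composes local, network and basal terms", {
  conn <- random_connectome(5, seed = 1)
  p <- sim_params(G = 1.3)
  expect_equal(synaptic_input(rep(0, 5), conn, p), rep(p$I_0, 5))

  p0 <- sim_params(G = 0)
  S <- runif(5)
  expect_equal(synaptic_input(S, conn, p0), p0$w * p0$J_N * S + p0$I_0)

  for (seed in 1:5) {
    set.seed(seed)
    S <- runif(5)
    chi <- synaptic_input(S, conn, p)
    brute <- sapply(1:5, function(i) {
      p$w * p$J_N * S[i] + p$J_N * p$G * sum(conn$weights[i, ] * S) + p$I_0
    })
    expect_equal(chi, brute)
  }
  expect_error(synaptic_input(rep(0, 4), conn, p), "length")
})

test_that("a fixed point is invariant under integration", {
  p <- sim_params(T = 2)
  fp <- isolated_fixed_points(p)
  S_star <- fp$S[fp$stability == "stable"][1]
  one <- connectome(matrix(0, 1, 1))
  out <- simulate_network(one, p, S_star)
  expect_equal(out$S, S_star, tolerance = 1e-9)
})

test_that("the isolated node is bistable at I0 = 0.322, w = 1 and monostable at defaults", {
  one <- connectome(matrix(0, 1, 1))
  p_bi <- sim_params(I_0 = 0.322, w = 1, T = 30)
  lo <- steady_state(one, p_bi, 0.05)
  hi <- steady_state(one, p_bi, 0.9)
  expect_true(lo$converged && hi$converged)
  expect_gt(hi$R - lo$R, 5)   # baseline vs ignited branch

  p_mono <- sim_params(T = 30)   # I_0 = 0.3, w = 0.9
  lo <- steady_state(one, p_mono, 0.02)
  hi <- steady_state(one, p_mono, 0.95)
  expect_equal(lo$R, hi$R, tolerance = 1e-6)
})

test_that("fixed-point counts and the nullcline identity hold", {
  fp_bi <- isolated_fixed_points(sim_params(I_0 = 0.322, w = 1))
  expect_equal(nrow(fp_bi), 3)
  expect_equal(fp_bi$stability, c("stable", "unstable", "stable"))

  fp_mono <- isolated_fixed_points(sim_params())
  expect_equal(nrow(fp_mono), 1)
  expect_equal(fp_mono$stability, "stable")

  # dS/dt = 0 rearranges to S* = gamma R tau / (1 + gamma R tau)
  for (fp in list(fp_bi, fp_mono)) {
    p <- sim_params()
    grt <- 0.641 * fp$R * 0.1
    expect_equal(fp$S, grt / (1 + grt), tolerance = 1e-7)
  }
})

test_that("Euler endpoint agrees with the bistable root-finding oracle", {
  one <- connectome(matrix(0, 1, 1))
  p <- sim_params(I_0 = 0.322, w = 1, T = 60)
  fp <- isolated_fixed_points(p)
  stable <- fp[fp$stability == "stable", ]
  hi <- steady_state(one, p, 0.9)
  expect_true(hi$converged)
  expect_equal(hi$R, max(stable$R), tolerance = 1e-6)
  lo <- steady_state(one, p, 0.01)
  expect_equal(lo$R, min(stable$R), tolerance = 1e-6)
})

test_that("trajectories stay inside [0, 1] and are bit-reproducible", {
  conn <- random_connectome(6, seed = 8)
  p <- sim_params(G = 2, T = 5)
  set.seed(1); S0 <- runif(6)
  out1 <- simulate_network(conn, p, S0, keep_trajectory = TRUE, thin = 5)
  expect_true(all(out1$trajectory >= 0 & out1$trajectory <= 1))
  out2 <- simulate_network(conn, p, S0, keep_trajectory = TRUE, thin = 5)
  expect_identical(out1$trajectory, out2$trajectory)
  expect_identical(out1$S, out2$S)
})

test_that("halving dt moves the converged rate by less than 1e-4 Hz", {
  conn <- random_connectome(5, seed = 3)
  set.seed(2); S0 <- runif(5, 0.3, 1)
  p1 <- sim_params(G = 1.5, dt = 0.001, T = 60)
  p2 <- sim_params(G = 1.5, dt = 0.0005, T = 60)
  r1 <- steady_state(conn, p1, S0)
  r2 <- steady_state(conn, p2, S0)
  expect_true(r1$converged && r2$converged)
  expect_lt(max(abs(r1$R - r2$R)), 1e-4)
})

test_that("degenerate tolerance contracts hold", {
  conn <- random_connectome(4, seed = 5)
  S0 <- rep(0.5, 4)
  out <- steady_state(conn, sim_params(), S0, tol = Inf)
  expect_true(out$converged)
  expect_equal(out$S, S0)
  expect_equal(out$t, 0)
  # an unreachable tolerance reports non-convergence via the flag
  out <- steady_state(conn, sim_params(G = 1, T = 0.05), S0, tol = 1e-16,
                      max_T = 0.05)
  expect_false(out$converged)
})

test_that("parameter validation and config files work", {
  expect_error(sim_params(tau_S = -1), "positive")
  expect_error(sim_params(dt = 0.02), "dt")
  f <- withr::local_tempfile()
  writeLines(c("# desk configuration", "G = 1.25", "I_0 = 0.322", "w = 1"), f)
  p <- read_sim_params(f)
  expect_equal(p$G, 1.25)
  expect_equal(p$I_0, 0.322)
  expect_equal(p$w, 1)
  expect_equal(p$tau_S, 0.1)   # untouched default
  writeLines("bogus = 3", f)
  expect_error(read_sim_params(f), "unknown parameter")
})
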