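test_that("the generator implements the mass-conserving flux scheme", {
  sys <- transport_system(build_cable(2, 2), a = 0.5, b = 0.5)
  A <- as.matrix(transport_generator(sys))
  expect_equal(A, matrix(c(-0.5, 0.5, 0.5, -0.5), 2, 2))

  # unbranched cable, bound block is tridiagonal
  sys5 <- transport_system(build_cable(5, 5), a = c(1, 2, 3, 4),
                           b = c(4, 3, 2, 1))
  A5 <- as.matrix(transport_generator(sys5))
  off <- abs(row(A5) - col(A5)) > 1
  expect_true(all(A5[off] == 0))

  # column sums vanish for random trees with both pools
  for (seed in 1:6) {
    sys <- random_system(sample(3:40, 1), seed, c_max = 0.5, d_max = 0.2)
    A <- transport_generator(sys)
    expect_lt(max(abs(Matrix::colSums(A))), 1e-12)
  }
})

test_that("exact evolution matches limits and conserves mass", {
  sys <- random_system(12, 3)
  traj0 <- evolve_transport(sys, c(1e-12))
  expect_equal(traj0$bound, sys$u0, tolerance = 1e-9)

  # uniform irreversible detachment: total bound mass decays exponentially
  tr <- build_cable(20, 20)
  sysc <- transport_system(tr, a = 1, b = 1, c = 0.05)
  times <- c(5, 20, 60)
  traj <- evolve_transport(sysc, times)
  bound_tot <- as.numeric(tapply(traj$bound, traj$time_s, sum))
  expect_equal(bound_tot, exp(-0.05 * times), tolerance = 1e-8)

  # two-compartment ratio relaxes to b/a
  sys2 <- transport_system(build_cable(2, 2), a = 1, b = 2)
  tt <- evolve_transport(sys2, c(50))
  expect_equal(tt$bound[1] / tt$bound[2], 2, tolerance = 1e-6)

  # mass conserved along trajectories of reversible systems
  for (seed in 1:4) {
    sys <- random_system(15, seed, c_max = 0.4, d_max = 0.3)
    traj <- evolve_transport(sys, log_times(0.1, 1e4, 20))
    tot <- tapply(traj$bound + traj$detached, traj$time_s, sum)
    expect_lt(max(abs(tot - sum(sys$u0))) / sum(sys$u0), 1e-8)
  }
})

test_that("matrix-exponential evolution agrees with explicit integration", {
  for (seed in 1:4) {
    n <- sample(5:50, 1)
    sys <- random_system(n, seed, c_max = 0.3,
                         d_max = if (seed %% 2) 0.2 else 0)
    times <- c(0.5, 2, 8)
    traj <- evolve_transport(sys, times)
    A <- transport_generator(sys)
    state0 <- if (nrow(A) == n) sys$u0 else c(sys$u0, sys$ustar0)
    oracle <- rk4_evolve(A, state0, times)
    # traj is sorted by time then id, so columns are times
    ub <- matrix(traj$bound, nrow = n)
    ud <- matrix(traj$detached, nrow = n)
    for (i in seq_along(times)) {
      ref_b <- oracle[i, 1:n]
      expect_equal(ub[, i], ref_b, tolerance = 1e-6)
      if (nrow(A) == 2 * n) {
        expect_equal(ud[, i], oracle[i, n + 1:n], tolerance = 1e-6)
      }
    }
  }
})

test_that("ode fallback matches the matrix-exponential path", {
  sys <- random_system(20, 9, c_max = 0.2, d_max = 0.1)
  times <- log_times(1, 1e3, 10)
  t1 <- evolve_transport(sys, times)
  t2 <- evolve_transport(sys, times, method = "ode")
  expect_equal(t1$bound, t2$bound, tolerance = 1e-6)
  expect_equal(t1$detached, t2$detached, tolerance = 1e-6)
})

test_that("steady states satisfy the parent/child ratio law on random trees", {
  for (seed in 1:6) {
    sys <- random_system(sample(3:50, 1), seed)
    ss <- steady_state(sys)
    e <- sys$edges
    ratio <- ss$bound[e$parent] / ss$bound[e$child]
    expect_equal(ratio, e$b / e$a, tolerance = 1e-8)
    expect_equal(sum(ss$bound), sum(sys$u0), tolerance = 1e-8)
  }

  # uniform rates give a uniform profile
  tr <- random_tree(25, 42)
  ssu <- steady_state(transport_system(tr, a = 0.7, b = 0.7))
  expect_equal(ssu$bound, rep(sum(ssu$bound) / 25, 25), tolerance = 1e-10)

  # doubling total cargo doubles every steady-state entry
  sys1 <- transport_system(tr, a = 0.3, b = 0.9)
  sys2 <- transport_system(tr, a = 0.3, b = 0.9, u0 = 2 * sys1$u0)
  expect_equal(steady_state(sys2)$bound, 2 * steady_state(sys1)$bound)

  expect_error(
    steady_state(transport_system(build_cable(3, 3), a = c(1, 0), b = 1)),
    "disconnected"
  )
})

test_that("a linear cargo gradient arises from b/a = i/(i+1)", {
  n <- 30
  i <- seq_len(n - 1)
  sys <- transport_system(build_cable(n, n), a = (i + 1) / (2 * i + 1),
                          b = i / (2 * i + 1))
  ss <- steady_state(sys)
  expect_equal(ss$bound / sum(ss$bound), seq_len(n) / sum(seq_len(n)),
               tolerance = 1e-8)
})

test_that("reversible steady states split pools by c/d per compartment", {
  tr <- random_tree(12, 8)
  sys <- transport_system(tr, a = 0.5, b = 0.5, c = 2, d = 1)
  ss <- steady_state(sys)
  expect_equal(ss$detached / ss$bound, rep(2, 12), tolerance = 1e-10)
  expect_equal(sum(ss$bound) / (sum(ss$bound) + sum(ss$detached)), 1 / 3,
               tolerance = 1e-10)

  # heterogeneous rates
  sysh <- random_system(10, 4, c_max = 1, d_max = 1)
  ssh <- steady_state(sysh)
  expect_equal(ssh$detached / ssh$bound, sysh$c / sysh$d, tolerance = 1e-8)
})

test_that("delivered distributions absorb all mass and match long evolution", {
  one <- transport_system(build_cable(2, 2), a = 1, b = 1, c = c(0.5, 0))
  deliv1 <- delivered_distribution(one)
  expect_equal(sum(deliv1$delivered), 1, tolerance = 1e-8)

  for (seed in 1:3) {
    sys <- random_system(20, seed, c_max = 0.3)
    deliv <- delivered_distribution(sys)
    expect_true(all(deliv$delivered >= 0))
    expect_equal(sum(deliv$delivered), sum(sys$u0), tolerance = 1e-8)
    t_long <- 20 / min(sys$c[sys$c > 0])
    traj <- evolve_transport(sys, c(t_long))
    expect_equal(traj$detached, deliv$delivered, tolerance = 1e-4)
  }

  expect_error(delivered_distribution(random_system(5, 1)), "absorbing")
})

test_that("relaxation timescale equals the subdominant eigenvalue and tracks simulation", {
  sys2 <- transport_system(build_cable(2, 2), a = 0.5, b = 0.5)
  expect_equal(convergence_timescale(sys2), 1, tolerance = 1e-10)

  # bottleneck: halving epsilon doubles the timescale, diverging as eps -> 0
  taus <- vapply(c(0.02, 0.01, 0.005), function(e) {
    convergence_timescale(bottleneck_system(e))
  }, numeric(1))
  expect_equal(taus[2] / taus[1], 2, tolerance = 0.05)
  expect_equal(taus[3] / taus[2], 2, tolerance = 0.05)

  # timescale vs direct relaxation of the slowest deviation on random cables
  for (seed in 1:3) {
    n <- 12
    sys <- withr::with_seed(seed, transport_system(
      build_cable(n, n), a = stats::runif(n - 1, 0.5, 1.5),
      b = stats::runif(n - 1, 0.5, 1.5)
    ))
    tau <- convergence_timescale(sys)
    ss <- steady_state(sys)$bound
    times <- tau * seq(2, 6, by = 0.25)
    traj <- evolve_transport(sys, times)
    dev <- vapply(split(abs(traj$bound - ss[traj$id]), traj$time_s), max,
                  numeric(1))
    # asymptotic decay rate of the dominant deviation
    fitted_tau <- -mean(diff(times)) / mean(diff(log(dev)))
    expect_equal(fitted_tau, tau, tolerance = 0.2)
  }
})

test_that("per-compartment delays are monotone and respect initial content", {
  sys <- transport_system(build_cable(10, 10), a = 0.5, b = 0.5)
  traj <- evolve_transport(sys, c(1e-9, log_times(0.01, 2e3, 40)))
  d1 <- compartment_delays(traj, 1e-3)
  expect_equal(d1$delay_s[1], 1e-9)  # soma starts above threshold
  d2 <- compartment_delays(traj, 1e-2)
  expect_true(all(d2$delay_s >= d1$delay_s))
  # delays grow with distance from the soma on a uniform cable (ties only
  # where adjacent compartments cross between stored grid times)
  expect_true(all(diff(d1$delay_s) >= 0))
  expect_gt(d1$delay_s[10], d1$delay_s[2])
})

test_that("a demand bottleneck shortens proximal delays and lengthens distal ones", {
  n <- 60
  tr <- build_cable(n, n)
  uniform <- ddt_system(tr, demand_profile(rep(1, n)), normalization = "unit")
  bneck <- ddt_system(tr, demand_bottleneck(n, ratio = 10),
                      normalization = "unit")
  times <- c(1e-9, log_times(0.1, 1e6, 150))
  # threshold comparable to the steady-state level (1/60 for uniform demand):
  # the bottleneck dams cargo proximally, so proximal compartments fill to
  # that level sooner while distal ones fill later
  du <- compartment_delays(evolve_transport(uniform, times), 0.012)
  db <- compartment_delays(evolve_transport(bneck, times), 0.012)
  low <- middle_third(n)
  proximal <- 2:(min(low) - 1)
  distal <- (max(low) + 1):n
  expect_true(all(db$delay_s[proximal] <= du$delay_s[proximal]))
  expect_lt(mean(db$delay_s[proximal]), mean(du$delay_s[proximal]))
  expect_true(all(db$delay_s[distal] >= du$delay_s[distal]))
  expect_gt(mean(db$delay_s[distal]), mean(du$delay_s[distal]))
})

test_that("all generator eigenvalues have nonpositive real part", {
  for (seed in 1:5) {
    sys <- random_system(sample(4:30, 1), seed, c_max = 0.5, d_max = 0.5)
    ev <- eigen(as.matrix(transport_generator(sys)), only.values = TRUE)$values
    expect_lt(max(Re(ev)), 1e-10)
  }
})
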