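test_that("partition_rbc follows the flux power law", {
  expect_equal(partition_rbc(c(1, 1), bias_exponent = 3), c(0.5, 0.5))
  expect_equal(partition_rbc(c(3, 1), bias_exponent = 1), c(0.75, 0.25))
  # hand arithmetic: 9 / (9 + 1)
  expect_equal(partition_rbc(c(3, 1), bias_exponent = 2), c(0.9, 0.1))
  expect_error(partition_rbc(c(0, 0)), "zero")
  expect_error(partition_rbc(c(1, 2), bias_exponent = 0.5), "bias_exponent")

  # skimming property: larger-flux branch exceeds its flux fraction
  set.seed(11)
  for (i in 1:20) {
    q <- sort(stats::runif(2, 0.1, 5), decreasing = TRUE)
    p <- partition_rbc(q, bias_exponent = 1 + stats::runif(1, 0.5, 3))
    expect_gt(p[1], q[1] / sum(q))
    expect_equal(sum(p), 1)
  }
})

test_that("cells traverse a single-path network deterministically", {
  net <- make_series_net(p_in = 2000)
  sim <- simulate_rbc_transport(net, inflow_rate = 20, duration = 2,
                                dt = 0.005, seed = 3)
  # every injected cell entered e1; no alternative branch exists
  expect_equal(unname(sim$entered[["e1"]]), sim$n_cells_injected)
  expect_equal(sim$n_stranded, 0)
  # all trajectory rows stay on the two edges
  expect_true(all(sim$trajectories$edge_id %in% c("e1", "e2")))
})

test_that("identical seeds give identical trajectories", {
  net <- make_y_net(p_in = 50)   # slow flow: cells persist across steps
  a <- simulate_rbc_transport(net, inflow_rate = 50, duration = 2,
                              dt = 0.005, seed = 42)
  b <- simulate_rbc_transport(net, inflow_rate = 50, duration = 2,
                              dt = 0.005, seed = 42)
  expect_gt(nrow(a$trajectories), 0)
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$counts, b$counts)
  c <- simulate_rbc_transport(net, inflow_rate = 50, duration = 2,
                              dt = 0.005, seed = 43)
  expect_false(identical(a$trajectories, c$trajectories))
})

test_that("unbiased routing matches the binomial law on a symmetric fork", {
  net <- make_y_net()          # identical branches
  sim <- simulate_rbc_transport(net, inflow_rate = 2000, duration = 5,
                                dt = 0.01, bias_exponent = 1, seed = 9,
                                record_trajectories = FALSE)
  n <- sim$entered[["b1"]] + sim$entered[["b2"]]
  expect_gt(n, 5000)
  # binomial(n, 1/2) oracle: 3 sigma band
  expect_lt(abs(sim$entered[["b1"]] - n / 2), 3 * sqrt(n * 0.25))
})

test_that("long-run branch fractions track flux fractions (exponent 1)", {
  net <- make_y_net(r_b1 = 6, r_b2 = 4)   # asymmetric branches
  st <- solve_flow(net)
  frac <- abs(st$edge_fluxes[["b1"]]) /
    (abs(st$edge_fluxes[["b1"]]) + abs(st$edge_fluxes[["b2"]]))
  sim <- simulate_rbc_transport(net, inflow_rate = 2000, duration = 5,
                                dt = 0.01, bias_exponent = 1, seed = 5,
                                record_trajectories = FALSE)
  n <- sim$entered[["b1"]] + sim$entered[["b2"]]
  expect_lt(abs(sim$entered[["b1"]] - n * frac),
            3 * sqrt(n * frac * (1 - frac)))
})

test_that("occlusion feedback slows the flow it loads", {
  net <- make_y_net(p_in = 50)   # slow enough that cells occupy the steps
  net$edges$alpha_c <- 5e15
  base <- simulate_rbc_transport(net, inflow_rate = 500, duration = 1,
                                 dt = 0.01, seed = 2,
                                 record_trajectories = FALSE)
  fed <- simulate_rbc_transport(net, inflow_rate = 500, duration = 1,
                                dt = 0.01, seed = 2,
                                occlusion_feedback = TRUE,
                                record_trajectories = FALSE)
  expect_lt(fed$state$inlet_flux, base$state$inlet_flux)
})

test_that("set-point adaptation converges to the closed-form radius", {
  fl <- fluid_params()
  net <- make_single_edge_net(radius_um = 3, p_in = 100)
  st <- solve_flow(net, fl)
  Q <- abs(st$edge_fluxes[["only"]])
  set_point <- 30   # dyne/cm^2
  res <- adapt_radii(net, fl, set_point = set_point, gain = 0.2,
                     max_iter = 500, tol = 1e-6, edges = "only",
                     fixed_flux = TRUE)
  r_closed_m <- (4 * fl$mu * Q / (pi * set_point / 10))^(1 / 3)
  expect_true(res$converged)
  expect_equal(res$network$edges$radius_um[1] * 1e-6, r_closed_m,
               tolerance = 1e-3)

  # monotone approach: radius moves toward the fixed point without
  # overshoot at gain <= 1/3 (grows iff the stress starts above set point)
  traj <- res$radius_trajectory[, 1]
  sigma0 <- plasma_wss(wss_params(radius = 3),
                       abs(st$edge_mean_velocities[["only"]]) * 100)
  expect_true(all(sign(diff(traj)) == sign(sigma0 - set_point)))

  # gain 0.5 still converges (contraction), gain > 1 rejected
  res2 <- adapt_radii(net, fl, set_point = set_point, gain = 0.5,
                      max_iter = 500, tol = 1e-6, edges = "only",
                      fixed_flux = TRUE)
  expect_true(res2$converged)
  expect_error(adapt_radii(net, fl, set_point = 30, gain = 1.5), "gain")
  expect_error(adapt_radii(net, fl, set_point = -1), "set_point")
})

test_that("non-convergence is flagged, not thrown", {
  net <- make_single_edge_net()
  res <- adapt_radii(net, set_point = 30, gain = 0.2, max_iter = 2,
                     tol = 1e-12, edges = "only", fixed_flux = TRUE)
  expect_false(res$converged)
})
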