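test_that("trunk builder yields the stated topology and alpha_c profile", {
  net <- build_trunk_network(3)
  kinds <- table(net$edges$kind)
  expect_equal(unname(kinds[["SeA"]]), 3)
  expect_equal(unname(kinds[["SeV"]]), 3)
  expect_equal(unname(kinds[["ECL"]]), 1)

  # constant profile: every edge gets the same alpha_c
  flat <- build_trunk_network(3, alpha_c_profile = c(7e14, 7e14))
  expect_true(all(flat$edges$alpha_c == 7e14))

  # gradient decreases head to tail for the SeA sequence
  grad <- build_trunk_network(4, alpha_c_profile = c(2e15, 5e14))
  sea <- grad$edges[grad$edges$kind == "SeA", ]
  expect_true(all(diff(sea$alpha_c) < 0))

  expect_error(build_trunk_network(1), "n_se_pairs")
  expect_error(build_trunk_network(3, se_radius = -1), "positive")
})

test_that("16-rung default network is connected inlet to outlet", {
  net <- build_trunk_network(16)
  # independent graph-search oracle over the edge list
  ids <- net$nodes$id
  reach <- local({
    adj <- list()
    for (i in seq_len(nrow(net$edges))) {
      h <- net$edges$head[i]; t <- net$edges$tail[i]
      adj[[h]] <- c(adj[[h]], t)
      adj[[t]] <- c(adj[[t]], h)
    }
    seen <- "da_0"
    frontier <- "da_0"
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  })
  expect_true("pcv_0" %in% reach)
  expect_true(all(c(net$edges$head, net$edges$tail) %in% ids))
})

test_that("edge_resistance matches hand arithmetic and is linear in cells", {
  fl <- fluid_params(1e-3)
  e <- edge_row("e", "a", "b", length_um = 100, radius_um = 3,
                alpha_c = 1e15)
  # 8 * 1e-3 * 1e-4 / (pi * (3e-6)^4), worked by hand
  r0_hand <- 8e-7 / (pi * 8.1e-23)
  expect_equal(edge_resistance(e, fl, 0), r0_hand, tolerance = 1e-12)
  expect_equal(edge_resistance(e, fl, 2), r0_hand + 2e15, tolerance = 1e-12)
  expect_error(edge_resistance(e, fl, -1), ">= 0")
})

test_that("solver reproduces series and parallel closed forms", {
  fl <- fluid_params()
  ser <- make_series_net(l1 = 120, l2 = 260, r1 = 3, r2 = 4, p_in = 80)
  st <- solve_flow(ser, fl)
  R1 <- edge_resistance(ser$edges[1, ], fl, 0)
  R2 <- edge_resistance(ser$edges[2, ], fl, 0)
  expect_equal(unname(st$edge_fluxes[["e1"]]), 80 / (R1 + R2),
               tolerance = 1e-12)
  expect_equal(unname(st$edge_fluxes[["e2"]]), 80 / (R1 + R2),
               tolerance = 1e-12)

  par <- make_parallel_net(l1 = 150, l2 = 150, p_in = 60)
  stp <- solve_flow(par, fl)
  expect_equal(unname(stp$edge_fluxes[["b1"]]),
               unname(stp$edge_fluxes[["b2"]]), tolerance = 1e-12)
  Rb <- edge_resistance(par$edges[1, ], fl, 0)
  expect_equal(unname(stp$edge_fluxes[["b1"]]), 60 / Rb, tolerance = 1e-12)

  # velocity definition: flux over cross-section
  r_m <- 3e-6
  expect_equal(unname(st$edge_mean_velocities[["e1"]]),
               unname(st$edge_fluxes[["e1"]]) / (pi * r_m^2),
               tolerance = 1e-12)
})

test_that("flow conservation holds on trunk networks of several sizes", {
  fl <- fluid_params()
  for (n in c(2, 3, 8, 16)) {
    st <- solve_flow(build_trunk_network(n), fl)
    expect_lt(st$residual_rel, 1e-10)
  }
  # with per-edge cell loads too
  net <- build_trunk_network(5)
  counts <- stats::setNames(rep(2L, nrow(net$edges)), net$edges$id)
  expect_lt(solve_flow(net, fl, counts)$residual_rel, 1e-10)
})

test_that("occlusion raises resistance and lowers flux", {
  net <- build_trunk_network(4)
  st0 <- solve_flow(net)
  loaded <- stats::setNames(rep(5L, nrow(net$edges)), net$edges$id)
  st1 <- solve_flow(net, n_cells = loaded)
  expect_lt(st1$inlet_flux, st0$inlet_flux)
})

test_that("amputation removes the ECL and the distal rungs, reroutes flow", {
  net <- build_trunk_network(16)
  amp0 <- amputate(net, 0)
  expect_false(any(amp0$edges$kind == "ECL"))
  expect_equal(sum(amp0$edges$kind == "SeA"), 16)
  expect_false(any(grepl("tip", c(amp0$edges$head, amp0$edges$tail))))

  amp2 <- amputate(net, 2)
  expect_equal(sum(amp2$edges$kind == "SeA"), 14)
  expect_equal(sum(amp2$edges$kind == "SeV"), 14)

  # the SeA nearest the cut carries strictly more flow afterwards
  pre <- solve_flow(net)
  post <- solve_flow(amp0)
  expect_gt(abs(post$edge_fluxes[["SeA_16"]]),
            abs(pre$edge_fluxes[["SeA_16"]]))

  # monotone repartitioning: totals through surviving SeAs equal inlet flux
  sea_ids <- net$edges$id[net$edges$kind == "SeA"]
  pre_sea <- sum(abs(pre$edge_fluxes[sea_ids]))
  post_sea <- sum(abs(post$edge_fluxes[sea_ids]))
  expect_gte(post_sea, pre_sea)
  expect_equal(post_sea, post$inlet_flux, tolerance = 1e-9)

  expect_error(amputate(net, 16), "n_distal_rungs")
  expect_error(amputate(amputate(net, 0), 0), "ECL")
})

test_that("network JSON round-trips losslessly", {
  net <- build_trunk_network(3)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  back <- read_network_json(path)
  expect_equal(back$edges$id, net$edges$id)
  expect_equal(back$edges$alpha_c, net$edges$alpha_c)
  expect_equal(back$boundary$inlet_pressure, net$boundary$inlet_pressure)
  st1 <- solve_flow(net)
  st2 <- solve_flow(back)
  expect_equal(st1$edge_fluxes, st2$edge_fluxes, tolerance = 1e-12)
})
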