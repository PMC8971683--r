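# Discrete red-cell transport on a solved hydraulic network.
#
# Cells are advected as points at the local edge mean velocity. At a node
# they pick a downstream branch at random with plasma-skimming bias: the
# probability of a branch scales as its volumetric flux raised to a
# configurable exponent (Zweifach-Fung effect; exponent 1 recovers unbiased
# flux-proportional routing).

#' Branch selection probabilities at a bifurcation
#'
#' Probability of branch i is `flux_i^bias_exponent / sum_j flux_j^bias_exponent`.
#' For `bias_exponent > 1` the larger-flux branch receives a larger share of
#' cells than its share of flow (plasma skimming).
#'
#' @param branch_fluxes non-negative volumetric fluxes (m^3/s), not all zero.
#' @param branch_radii branch radii in micrometres; accepted for interface
#'   completeness but unused (the bias law operates on fluxes).
#' @param bias_exponent dimensionless exponent >= 1. Default 2.
#' @return probability vector summing to 1.
#' @export
partition_rbc <- function(branch_fluxes, branch_radii = NULL,
                          bias_exponent = 2) {
  if (any(branch_fluxes < 0)) stop("fluxes must be >= 0", call. = FALSE)
  if (bias_exponent < 1) stop("`bias_exponent` must be >= 1", call. = FALSE)
  s <- sum(branch_fluxes^bias_exponent)
  if (s == 0) stop("all branch fluxes are zero: partition undefined",
                   call. = FALSE)
  branch_fluxes^bias_exponent / s
}

#' Simulate red-cell transport through the network
#'
#' Cells enter at the inlet as a Poisson process of rate `inflow_rate` and
#' advect at the local edge mean velocity. Sub-stepping is adaptive: within
#' one recording step `dt` a cell may cross several nodes, each crossing
#' handled exactly at its arrival time, so `dt` only sets the recording and
#' (optional) flow-update cadence. At each node the downstream branch is
#' drawn via [partition_rbc()] over the edges carrying flow away from the
#' node. Cells reaching the outlet leave the system; a cell arriving at a
#' node with no positive-flux outlet is removed with a warning.
#'
#' @param net a `trunk_network`.
#' @param fluid a [fluid_params()] object.
#' @param inflow_rate mean cell arrival rate at the inlet, cells/s.
#' @param duration simulated time, s.
#' @param dt recording step, s.
#' @param bias_exponent plasma-skimming exponent passed to [partition_rbc()].
#' @param seed integer seed; all stochastic draws derive from it.
#' @param occlusion_feedback if `TRUE`, the flow field is re-solved every
#'   recording step with the current per-edge cell counts (cells then slow
#'   the vessels they occupy). Default `FALSE`.
#' @param record_trajectories if `FALSE`, skip per-cell trajectory rows
#'   (cheaper for long runs).
#' @return object of class `rbc_transport`: `trajectories` (data frame
#'   time_s, cell_id, edge_id, arclength_um), `times`, `counts` (steps x
#'   edges matrix of instantaneous cell counts), `entered` (total cells that
#'   entered each edge), `state` (the `network_state` used for the final
#'   step), `n_cells_injected`, `n_stranded`.
#' @export
simulate_rbc_transport <- function(net, fluid = fluid_params(),
                                   inflow_rate = 100, duration = 30,
                                   dt = 0.01, bias_exponent = 2, seed = 1L,
                                   occlusion_feedback = FALSE,
                                   record_trajectories = TRUE) {
  validate_network(net)
  set.seed(seed)
  e <- net$edges
  ne <- nrow(e)
  ids <- net$nodes$id
  eid <- e$id
  hi <- match(e$head, ids)
  ti <- match(e$tail, ids)
  len <- e$length_um
  outlet <- match(net$boundary$outlet_node, ids)
  inlet <- match(net$boundary$inlet_node, ids)

  counts <- stats::setNames(integer(ne), eid)
  state <- solve_flow(net, fluid, counts)

  # routing tables for the current flow field
  routing <- NULL
  build_routing <- function(st) {
    q <- unname(st$edge_fluxes)
    out_edges <- vector("list", length(ids))
    out_probs <- vector("list", length(ids))
    for (n in seq_along(ids)) {
      away <- which((hi == n & q > 0) | (ti == n & q < 0))
      out_edges[[n]] <- away
      if (length(away)) {
        out_probs[[n]] <- partition_rbc(abs(q[away]),
                                        bias_exponent = bias_exponent)
      }
    }
    list(out_edges = out_edges, out_probs = out_probs,
         v_umps = unname(st$edge_mean_velocities) * 1e6,
         q = q)
  }
  routing <- build_routing(state)

  # Poisson arrivals
  gaps <- stats::rexp(ceiling(inflow_rate * duration * 2) + 20,
                      rate = inflow_rate)
  arrivals <- cumsum(gaps)
  arrivals <- arrivals[arrivals <= duration]
  n_inject <- length(arrivals)

  # cell state (parallel vectors over active cells)
  c_id <- integer(0)      # cell id
  c_edge <- integer(0)    # edge index
  c_pos <- numeric(0)     # um travelled from the upstream end
  next_arrival <- 1L
  n_stranded <- 0L
  entered <- stats::setNames(numeric(ne), eid)

  # route a single cell standing at node `n`; returns c(edge, dir) or NULL
  pick_branch <- function(n) {
    away <- routing$out_edges[[n]]
    if (!length(away)) return(NULL)
    if (length(away) == 1L) k <- away else {
      k <- sample(away, 1L, prob = routing$out_probs[[n]])
    }
    k
  }

  times <- seq(dt, duration, by = dt)
  n_steps <- length(times)
  counts_mat <- matrix(0L, n_steps, ne, dimnames = list(NULL, eid))

  traj_cap <- if (record_trajectories) 4096L else 0L
  traj_t <- numeric(traj_cap); traj_c <- integer(traj_cap)
  traj_e <- integer(traj_cap); traj_s <- numeric(traj_cap)
  traj_n <- 0L
  push_traj <- function(tt, cc, ee, ss) {
    k <- length(cc)
    if (k == 0L) return(invisible())
    while (traj_n + k > length(traj_t)) {
      traj_t <<- c(traj_t, numeric(length(traj_t)))
      traj_c <<- c(traj_c, integer(length(traj_c)))
      traj_e <<- c(traj_e, integer(length(traj_e)))
      traj_s <<- c(traj_s, numeric(length(traj_s)))
    }
    idx <- traj_n + seq_len(k)
    traj_t[idx] <<- tt; traj_c[idx] <<- cc
    traj_e[idx] <<- ee; traj_s[idx] <<- ss
    traj_n <<- traj_n + k
  }

  # advance one cell (index j in the state vectors) by `h` seconds,
  # crossing nodes as needed; returns FALSE if the cell left the system
  advance_cell <- function(j, h) {
    guard <- 0L
    while (h > 0) {
      guard <- guard + 1L
      if (guard > 10000L) break  # safety against zero-length loops
      k <- c_edge[j]
      v <- abs(routing$v_umps[k])
      if (v <= 0) return(TRUE)   # stagnant edge: cell waits
      remain_um <- len[k] - c_pos[j]
      t_cross <- remain_um / v
      if (t_cross > h) {
        c_pos[j] <<- c_pos[j] + v * h
        return(TRUE)
      }
      h <- h - t_cross
      # arrive at downstream node
      node <- if (routing$q[k] >= 0) ti[k] else hi[k]
      if (node == outlet) return(FALSE)
      nk <- pick_branch(node)
      if (is.null(nk)) {
        n_stranded <<- n_stranded + 1L
        return(FALSE)
      }
      c_edge[j] <<- nk
      c_pos[j] <<- 0
      entered[eid[nk]] <<- entered[eid[nk]] + 1
    }
    TRUE
  }

  warn_stranded <- FALSE
  t_prev <- 0
  for (s in seq_len(n_steps)) {
    t_now <- times[s]
    if (occlusion_feedback) {
      cnt <- tabulate(c_edge, nbins = ne)
      state <- solve_flow(net, fluid, stats::setNames(cnt, eid))
      routing <- build_routing(state)
    }
    # inject cells arriving within (t_prev, t_now]
    while (next_arrival <= n_inject && arrivals[next_arrival] <= t_now) {
      t_in <- arrivals[next_arrival]
      k <- pick_branch(inlet)
      if (is.null(k)) {
        n_stranded <- n_stranded + 1L
        warn_stranded <- TRUE
      } else {
        c_id <- c(c_id, next_arrival)
        c_edge <- c(c_edge, k)
        c_pos <- c(c_pos, 0)
        entered[eid[k]] <- entered[eid[k]] + 1
        j <- length(c_id)
        stranded_before <- n_stranded
        if (!advance_cell(j, t_now - t_in)) {
          if (n_stranded > stranded_before) warn_stranded <- TRUE
          c_id <- c_id[-j]; c_edge <- c_edge[-j]; c_pos <- c_pos[-j]
        }
      }
      next_arrival <- next_arrival + 1L
    }
    # advance cells already in flight over the full step
    if (length(c_id)) {
      v <- abs(routing$v_umps[c_edge])
      new_pos <- c_pos + v * dt
      simple <- new_pos <= len[c_edge]
      c_pos[simple] <- new_pos[simple]
      gone <- logical(length(c_id))
      for (j in which(!simple)) {
        stranded_before <- n_stranded
        if (!advance_cell(j, dt)) {
          if (n_stranded > stranded_before) warn_stranded <- TRUE
          gone[j] <- TRUE
        }
      }
      if (any(gone)) {
        c_id <- c_id[!gone]; c_edge <- c_edge[!gone]; c_pos <- c_pos[!gone]
      }
    }
    if (length(c_id)) {
      counts_mat[s, ] <- tabulate(c_edge, nbins = ne)
      if (record_trajectories) push_traj(t_now, c_id, c_edge, c_pos)
    }
    t_prev <- t_now
  }
  if (warn_stranded) {
    warning(sprintf("%d cell(s) reached a node with no downstream flux and were removed",
                    n_stranded), call. = FALSE)
  }

  traj <- if (record_trajectories && traj_n > 0L) {
    idx <- seq_len(traj_n)
    data.frame(time_s = traj_t[idx], cell_id = traj_c[idx],
               edge_id = eid[traj_e[idx]], arclength_um = traj_s[idx])
  } else {
    data.frame(time_s = numeric(0), cell_id = integer(0),
               edge_id = character(0), arclength_um = numeric(0))
  }

  structure(list(
    trajectories = traj,
    times = times,
    counts = counts_mat,
    entered = entered,
    state = state,
    n_cells_injected = n_inject,
    n_stranded = n_stranded,
    dt = dt,
    duration = duration,
    seed = seed
  ), class = "rbc_transport")
}

#' Wall-shear-stress set-point radius adaptation
#'
#' Iteratively remodels vessel radii toward a target (set-point) wall shear
#' stress: `r <- r * (1 + gain * (sigma/sigma_set - 1))`, where `sigma` is
#' the plasma wall shear stress `4 mu |v| / r` of the current flow solution.
#' For a vessel carrying fixed flux Q the fixed point is the closed-form
#' radius `(4 mu Q / (pi sigma_set))^(1/3)`.
#'
#' @param net a `trunk_network`.
#' @param fluid a [fluid_params()] object.
#' @param set_point target wall shear stress in dyne/cm^2.
#' @param gain relaxation gain in (0, 1]; values <= 1/3 give a monotone
#'   approach, values <= 2/3 a contraction. Default 0.2.
#' @param max_iter iteration cap.
#' @param tol relative stress tolerance for convergence.
#' @param edges character vector of edge ids to adapt; default all SeA edges.
#' @param n_cells per-edge cell counts entering the resistances (see
#'   [solve_flow()]).
#' @param fixed_flux if `TRUE`, edge fluxes are frozen at the initial
#'   solution instead of re-solved each iteration (single-vessel closed-form
#'   regime).
#' @return list: `radius_trajectory` (iterations x adapted-edges matrix, um),
#'   `wss` (final plasma WSS per adapted edge, dyne/cm^2), `converged`,
#'   `iterations`, `network` (with final radii).
#' @export
adapt_radii <- function(net, fluid = fluid_params(), set_point, gain = 0.2,
                        max_iter = 200, tol = 1e-4, edges = NULL,
                        n_cells = NULL, fixed_flux = FALSE) {
  if (set_point <= 0) stop("`set_point` must be > 0", call. = FALSE)
  if (gain <= 0 || gain > 1) stop("`gain` must be in (0, 1]", call. = FALSE)
  if (is.null(edges)) edges <- net$edges$id[net$edges$kind == "SeA"]
  sel <- match(edges, net$edges$id)
  if (anyNA(sel)) stop("unknown edge id in `edges`", call. = FALSE)
  sigma_set_pa <- set_point / 10  # dyne/cm^2 -> Pa

  st <- solve_flow(net, fluid, n_cells)
  q_fixed <- st$edge_fluxes
  traj <- matrix(NA_real_, max_iter + 1L, length(sel),
                 dimnames = list(NULL, edges))
  traj[1L, ] <- net$edges$radius_um[sel]
  converged <- FALSE
  it <- 0L
  sigma_pa <- NULL
  for (it in seq_len(max_iter)) {
    if (fixed_flux) {
      q <- q_fixed[sel]
    } else {
      st <- solve_flow(net, fluid, n_cells)
      q <- st$edge_fluxes[sel]
    }
    r_m <- net$edges$radius_um[sel] * 1e-6
    v <- abs(q) / (pi * r_m^2)
    sigma_pa <- 4 * fluid$mu * v / r_m
    if (all(abs(sigma_pa - sigma_set_pa) / sigma_set_pa < tol)) {
      converged <- TRUE
      break
    }
    net$edges$radius_um[sel] <- net$edges$radius_um[sel] *
      (1 + gain * (sigma_pa / sigma_set_pa - 1))
    traj[it + 1L, ] <- net$edges$radius_um[sel]
  }
  used <- !apply(traj, 1L, function(r) all(is.na(r)))
  list(
    radius_trajectory = traj[used, , drop = FALSE],
    wss = stats::setNames(sigma_pa * 10, edges),
    converged = converged,
    iterations = it,
    network = net
  )
}

#' Expected per-edge cell traversal under the routing model
#'
#' Propagates the plasma-skimming branch probabilities deterministically
#' through the solved flow field: since pressure strictly decreases along
#' every flow direction the flow graph is acyclic, and the expected number of
#' cells entering each edge per injected cell follows from one pass over the
#' nodes in order of decreasing pressure. This is the exact expectation of
#' the Monte Carlo transport in [simulate_rbc_transport()] (occlusion
#' feedback off).
#'
#' @param net a `trunk_network`.
#' @param fluid a [fluid_params()] object.
#' @param bias_exponent plasma-skimming exponent (see [partition_rbc()]).
#' @param n_cells per-edge cell counts entering the resistances.
#' @return named numeric vector: expected entries per edge per injected cell.
#' @export
expected_cell_entries <- function(net, fluid = fluid_params(),
                                  bias_exponent = 2, n_cells = NULL) {
  st <- solve_flow(net, fluid, n_cells)
  e <- net$edges
  ids <- net$nodes$id
  hi <- match(e$head, ids)
  ti <- match(e$tail, ids)
  q <- unname(st$edge_fluxes)
  ord <- order(st$node_pressures[ids], decreasing = TRUE)
  f <- stats::setNames(numeric(length(ids)), ids)
  f[net$boundary$inlet_node] <- 1
  out <- stats::setNames(numeric(nrow(e)), e$id)
  for (n in ord) {
    if (f[n] == 0) next
    away <- which((hi == n & q > 0) | (ti == n & q < 0))
    if (!length(away)) next
    pr <- partition_rbc(abs(q[away]), bias_exponent = bias_exponent)
    share <- f[n] * pr
    out[away] <- out[away] + share
    downstream <- ifelse(q[away] > 0, ti[away], hi[away])
    for (k in seq_along(away)) {
      f[downstream[k]] <- f[downstream[k]] + share[k]
    }
  }
  out
}
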