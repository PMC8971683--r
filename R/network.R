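# Hydraulic model of the embryonic zebrafish trunk vasculature.
#
# The trunk is modelled as a ladder network: the dorsal aorta (DA, ventral
# arterial rail) feeds parallel segmental arteries (SeA) that drain into the
# dorsal longitudinal anastomotic vessel (DLAV, dorsal rail); segmental veins
# (SeV) return blood from the DLAV to the posterior cardinal vein (PCV,
# venous rail), and a distal DA-PCV anastomosis (the embryonic circulatory
# loop, ECL) closes the circuit at the tail. All vessels are treated as
# Poiseuille resistors; each red cell inside a vessel adds a constant
# occlusive resistance increment alpha_c.

VESSEL_KINDS <- c("DA", "SeA", "SeV", "DLAV", "PCV", "ECL")

#' Fluid parameters
#'
#' @param mu dynamic viscosity of plasma in Pa·s. Default `1e-3` (water-like
#'   plasma at 28.5 °C).
#' @return object of class `fluid_params`.
#' @export
fluid_params <- function(mu = 1e-3) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0) {
    stop("`mu` must be a single positive number (Pa·s)", call. = FALSE)
  }
  structure(list(mu = mu), class = "fluid_params")
}

#' Build the default trunk ladder network
#'
#' Constructs the zebrafish trunk topology: a DA rail carrying blood tailward,
#' `n_se_pairs` SeA rungs (DA to DLAV) alternating with `n_se_pairs` SeV rungs
#' (DLAV to PCV) along the trunk axis, a DLAV rail connecting the rung tops, a
#' PCV rail returning blood headward, and a single terminal ECL edge joining
#' the distal DA and PCV stubs. Flow is driven by fixed inlet/outlet pressures
#' at the head ends of DA and PCV (the heart is modelled as a pressure
#' source).
#'
#' Per-edge occlusive strength `alpha_c` is linearly interpolated along the
#' trunk axis from `alpha_c_profile[1]` at the head to `alpha_c_profile[2]` at
#' the tail, mirroring the head-to-tail decrease of measured occlusive
#' strengths. The default magnitudes (~1e15 Pa·s·m^-3 per cell) make one red
#' cell roughly double the Poiseuille resistance of a segmental vessel, as
#' expected when cell and vessel radii nearly coincide.
#'
#' @param n_se_pairs number of SeA/SeV rung pairs (>= 2). Default 16.
#' @param da_length total DA length head-to-tail-tip in micrometres; default
#'   places rungs every 75 um (one somite width).
#' @param se_length SeA length (DA to DLAV) in micrometres. Default 75.
#' @param se_radius radius of all Se vessels and the DLAV in micrometres.
#'   Default 3 (uniform radius across Se vessels).
#' @param trunk_radius radius of DA and PCV in micrometres. Default 10.
#' @param ecl_radius radius of the terminal DA-PCV anastomosis in
#'   micrometres. Default 4: the distal connection runs through the fine
#'   caudal plexus, and a plexus-like bore keeps a finite share of red cells
#'   routed through the distal segmental arteries before amputation, as
#'   observed in intact embryos.
#' @param alpha_c_profile length-2 numeric: occlusive strength at the head
#'   and tail ends of the trunk, Pa·s·m^-3 per cell.
#' @param inlet_pressure,outlet_pressure boundary pressures in Pa. The default
#'   drop of 250 Pa yields DA velocities of ~0.3 cm/s and Se velocities of
#'   ~0.1-0.2 cm/s, within the physiological range for 3 dpf embryos.
#' @return object of class `trunk_network`: list with `nodes` (data frame:
#'   id, x, y in um), `edges` (data frame: id, head, tail, length_um,
#'   radius_um, alpha_c, kind) and `boundary`.
#' @export
build_trunk_network <- function(n_se_pairs = 16,
                                da_length = NULL,
                                se_length = 75,
                                se_radius = 3,
                                trunk_radius = 10,
                                ecl_radius = 4,
                                alpha_c_profile = c(2e15, 5e14),
                                inlet_pressure = 250,
                                outlet_pressure = 0) {
  if (n_se_pairs < 2) stop("`n_se_pairs` must be >= 2", call. = FALSE)
  n_rungs <- 2L * as.integer(n_se_pairs)        # alternating SeA / SeV
  if (is.null(da_length)) da_length <- 75 * (n_rungs + 1L)
  if (any(c(da_length, se_length, se_radius, trunk_radius,
            ecl_radius) <= 0)) {
    stop("network geometry must be positive", call. = FALSE)
  }
  if (length(alpha_c_profile) != 2L || any(alpha_c_profile < 0)) {
    stop("`alpha_c_profile` must be two non-negative values", call. = FALSE)
  }
  if (inlet_pressure <= outlet_pressure) {
    stop("inlet pressure must exceed outlet pressure", call. = FALSE)
  }

  spacing <- da_length / (n_rungs + 1L)
  xs <- spacing * seq_len(n_rungs)              # rung positions
  pcv_dy <- 25                                  # DA-PCV dorsoventral offset, um

  nodes <- rbind(
    data.frame(id = "da_0", x = 0, y = 0),
    data.frame(id = paste0("da_", seq_len(n_rungs)), x = xs, y = 0),
    data.frame(id = "da_tip", x = da_length, y = 0),
    data.frame(id = paste0("dlav_", seq_len(n_rungs)), x = xs, y = se_length),
    data.frame(id = "pcv_0", x = 0, y = -pcv_dy),
    data.frame(id = paste0("pcv_", seq_len(n_rungs)), x = xs, y = -pcv_dy),
    data.frame(id = "pcv_tip", x = da_length, y = -pcv_dy)
  )

  edges <- list()
  add_edge <- function(id, head, tail, length_um, radius_um, kind) {
    edges[[length(edges) + 1L]] <<- data.frame(
      id = id, head = head, tail = tail, length_um = length_um,
      radius_um = radius_um, alpha_c = NA_real_, kind = kind
    )
  }

  # DA rail: head -> tail tip (flow direction head -> tail is positive)
  da_ids <- c("da_0", paste0("da_", seq_len(n_rungs)), "da_tip")
  for (i in seq_len(n_rungs + 1L)) {
    add_edge(paste0("DA_", i), da_ids[i], da_ids[i + 1L], spacing,
             trunk_radius, "DA")
  }
  # PCV rail: tail tip -> head (positive flow tailward-to-headward)
  pcv_ids <- c(paste0("pcv_", seq_len(n_rungs)), "pcv_tip")
  add_edge("PCV_tipseg", "pcv_tip", pcv_ids[n_rungs], spacing,
           trunk_radius, "PCV")
  for (i in rev(seq_len(n_rungs - 1L))) {
    add_edge(paste0("PCV_", i + 1L), paste0("pcv_", i + 1L),
             paste0("pcv_", i), spacing, trunk_radius, "PCV")
  }
  add_edge("PCV_1", "pcv_1", "pcv_0", spacing, trunk_radius, "PCV")
  # rungs: odd positions SeA (DA -> DLAV), even positions SeV (DLAV -> PCV)
  se_idx <- 0L
  sv_idx <- 0L
  for (j in seq_len(n_rungs)) {
    if (j %% 2L == 1L) {
      se_idx <- se_idx + 1L
      add_edge(paste0("SeA_", se_idx), paste0("da_", j), paste0("dlav_", j),
               se_length, se_radius, "SeA")
    } else {
      sv_idx <- sv_idx + 1L
      add_edge(paste0("SeV_", sv_idx), paste0("dlav_", j), paste0("pcv_", j),
               se_length + pcv_dy, se_radius, "SeV")
    }
  }
  # DLAV rail between consecutive rung tops
  for (j in seq_len(n_rungs - 1L)) {
    add_edge(paste0("DLAV_", j), paste0("dlav_", j), paste0("dlav_", j + 1L),
             spacing, se_radius, "DLAV")
  }
  # terminal anastomosis closing the loop at the tail
  add_edge("ECL", "da_tip", "pcv_tip", 2 * pcv_dy, ecl_radius, "ECL")

  edges <- do.call(rbind, edges)
  rownames(edges) <- NULL

  # head-to-tail linear alpha_c gradient evaluated at edge midpoints
  node_x <- stats::setNames(nodes$x, nodes$id)
  mid_x <- (node_x[edges$head] + node_x[edges$tail]) / 2
  frac <- pmin(pmax(mid_x / da_length, 0), 1)
  edges$alpha_c <- alpha_c_profile[1] + frac *
    (alpha_c_profile[2] - alpha_c_profile[1])

  net <- structure(list(
    nodes = nodes,
    edges = edges,
    boundary = list(inlet_node = "da_0", outlet_node = "pcv_0",
                    inlet_pressure = inlet_pressure,
                    outlet_pressure = outlet_pressure)
  ), class = "trunk_network")
  validate_network(net)
  net
}

#' Validate a trunk network
#'
#' Checks structural invariants: positive geometry, endpoints present,
#' inlet/outlet connectivity.
#' @param net a `trunk_network`.
#' @return the network, invisibly. Errors on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "trunk_network"))
  e <- net$edges
  if (any(e$length_um <= 0) || any(e$radius_um <= 0)) {
    stop("edge geometry must be positive", call. = FALSE)
  }
  if (any(e$alpha_c < 0)) stop("alpha_c must be >= 0", call. = FALSE)
  if (any(e$head == e$tail)) stop("self-loop edge", call. = FALSE)
  ids <- net$nodes$id
  if (!all(c(e$head, e$tail) %in% ids)) {
    stop("edge endpoint missing from node table", call. = FALSE)
  }
  bi <- match(net$boundary$inlet_node, ids)
  bo <- match(net$boundary$outlet_node, ids)
  if (is.na(bi) || is.na(bo)) stop("boundary node missing", call. = FALSE)
  reach <- bfs_reachable(match(e$head, ids), match(e$tail, ids),
                         length(ids), bi)
  if (!reach[bo]) {
    stop("inlet and outlet are not connected", call. = FALSE)
  }
  invisible(net)
}

#' Hydraulic resistance of one vessel
#'
#' Poiseuille resistance plus a constant occlusive increment per red cell:
#' `R = 8 mu L / (pi r^4) + n_cells * alpha_c`, with the vessel length and
#' radius converted from micrometres to metres.
#'
#' @param edge one row of a network `edges` data frame (or any list with
#'   `length_um`, `radius_um`, `alpha_c`).
#' @param fluid a [fluid_params()] object.
#' @param n_cells number of red cells currently inside the vessel (>= 0).
#' @return resistance in Pa·s·m^-3.
#' @export
edge_resistance <- function(edge, fluid = fluid_params(), n_cells = 0) {
  if (any(n_cells < 0)) stop("`n_cells` must be >= 0", call. = FALSE)
  L <- edge$length_um * 1e-6
  r <- edge$radius_um * 1e-6
  8 * fluid$mu * L / (pi * r^4) + n_cells * edge$alpha_c
}

#' Solve the hydraulic network
#'
#' Solves the linear conductance balance (Kirchhoff current law with the
#' pressure/flux Ohm analogue) for node pressures, with Dirichlet pressures at
#' the inlet and outlet. Edge resistances include the occlusive increment for
#' the supplied per-edge red-cell counts.
#'
#' @param net a `trunk_network`.
#' @param fluid a [fluid_params()] object.
#' @param n_cells named integer vector of per-edge cell counts (names = edge
#'   ids); missing edges count as 0. `NULL` means no cells anywhere.
#' @return object of class `network_state`: `node_pressures` (Pa, named),
#'   `edge_fluxes` (m^3/s, signed positive head -> tail, named),
#'   `edge_mean_velocities` (m/s, flux / (pi r^2)), and `residual_rel`, the
#'   largest interior-node net flux relative to the inlet flux.
#' @export
solve_flow <- function(net, fluid = fluid_params(), n_cells = NULL) {
  validate_network(net)
  e <- net$edges
  ids <- net$nodes$id
  nn <- length(ids)
  counts <- stats::setNames(numeric(nrow(e)), e$id)
  if (!is.null(n_cells)) {
    counts[names(n_cells)] <- as.numeric(n_cells)
  }
  R <- edge_resistance(e, fluid, counts)
  g <- 1 / R
  hi <- match(e$head, ids)
  ti <- match(e$tail, ids)

  # weighted graph Laplacian
  L <- matrix(0, nn, nn)
  for (k in seq_along(g)) {
    L[hi[k], hi[k]] <- L[hi[k], hi[k]] + g[k]
    L[ti[k], ti[k]] <- L[ti[k], ti[k]] + g[k]
    L[hi[k], ti[k]] <- L[hi[k], ti[k]] - g[k]
    L[ti[k], hi[k]] <- L[ti[k], hi[k]] - g[k]
  }
  b <- net$boundary
  fixed <- c(match(b$inlet_node, ids), match(b$outlet_node, ids))
  p_fixed <- c(b$inlet_pressure, b$outlet_pressure)
  free <- setdiff(seq_len(nn), fixed)
  p <- numeric(nn)
  p[fixed] <- p_fixed
  if (length(free)) {
    rhs <- -L[free, fixed, drop = FALSE] %*% p_fixed
    sol <- tryCatch(solve(L[free, free, drop = FALSE], rhs),
                    error = function(err) {
                      stop("singular hydraulic system (disconnected network?)",
                           call. = FALSE)
                    })
    p[free] <- sol
  }
  q <- (p[hi] - p[ti]) * g
  v <- q / (pi * (e$radius_um * 1e-6)^2)

  # conservation residual at interior nodes
  net_flux <- numeric(nn)
  for (k in seq_along(q)) {
    net_flux[hi[k]] <- net_flux[hi[k]] - q[k]
    net_flux[ti[k]] <- net_flux[ti[k]] + q[k]
  }
  inlet_flux <- abs(net_flux[fixed[1]])
  resid <- if (length(free)) max(abs(net_flux[free])) / inlet_flux else 0

  structure(list(
    node_pressures = stats::setNames(p, ids),
    edge_fluxes = stats::setNames(q, e$id),
    edge_mean_velocities = stats::setNames(v, e$id),
    inlet_flux = inlet_flux,
    residual_rel = resid
  ), class = "network_state")
}

#' Amputate the tail of a trunk network
#'
#' Emulates tail amputation: removes the ECL edge, the distal DA/PCV/DLAV
#' stubs, and the `n_distal_rungs` most distal SeA/SeV rung pairs. Dangling
#' rail fragments left by the cut are pruned.
#'
#' @param net a `trunk_network` built by [build_trunk_network()].
#' @param n_distal_rungs number of distal SeA/SeV pairs removed together with
#'   the tail (0 keeps every rung).
#' @return the amputated `trunk_network`.
#' @export
amputate <- function(net, n_distal_rungs = 0) {
  validate_network(net)
  e <- net$edges
  if (!any(e$kind == "ECL")) stop("network has no ECL edge", call. = FALSE)
  n_se <- sum(e$kind == "SeA")
  if (n_distal_rungs >= n_se) {
    stop("`n_distal_rungs` must be < number of SeA rungs", call. = FALSE)
  }
  drop <- e$kind == "ECL"
  if (n_distal_rungs > 0) {
    for (k in c("SeA", "SeV")) {
      idx <- which(e$kind == k)
      # rung ids are numbered head-to-tail; distal = highest numbers
      num <- as.integer(sub(".*_", "", e$id[idx]))
      drop[idx[order(num, decreasing = TRUE)[seq_len(n_distal_rungs)]]] <- TRUE
    }
  }
  e <- e[!drop, , drop = FALSE]

  # prune dangling chains (degree-1 nodes other than inlet/outlet)
  keep_nodes <- c(net$boundary$inlet_node, net$boundary$outlet_node)
  repeat {
    deg <- table(c(e$head, e$tail))
    dangling <- names(deg)[deg == 1L]
    dangling <- setdiff(dangling, keep_nodes)
    if (!length(dangling)) break
    e <- e[!(e$head %in% dangling | e$tail %in% dangling), , drop = FALSE]
  }
  used <- unique(c(e$head, e$tail))
  out <- structure(list(
    nodes = net$nodes[net$nodes$id %in% used, , drop = FALSE],
    edges = e,
    boundary = net$boundary
  ), class = "trunk_network")
  validate_network(out)  # errors if the cut disconnected inlet from outlet
  out
}

#' @export
print.trunk_network <- function(x, ...) {
  cat("trunk_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  print(table(x$edges$kind))
  cat("boundary:", x$boundary$inlet_node, "->", x$boundary$outlet_node,
      sprintf("(%.4g -> %.4g Pa)\n", x$boundary$inlet_pressure,
              x$boundary$outlet_pressure))
  invisible(x)
}
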