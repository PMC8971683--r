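# Programmatic fixtures: small hand-built networks and ground-truthed
# synthetic movies. Everything is generated at test time from explicit seeds.

make_net <- function(nodes, edges, inlet, outlet, p_in = 100, p_out = 0) {
  structure(list(
    nodes = nodes,
    edges = edges,
    boundary = list(inlet_node = inlet, outlet_node = outlet,
                    inlet_pressure = p_in, outlet_pressure = p_out)
  ), class = "trunk_network")
}

edge_row <- function(id, head, tail, length_um = 100, radius_um = 3,
                     alpha_c = 0, kind = "SeA") {
  data.frame(id = id, head = head, tail = tail, length_um = length_um,
             radius_um = radius_um, alpha_c = alpha_c, kind = kind)
}

# two edges in series: in -> m -> out
make_series_net <- function(l1 = 100, l2 = 200, r1 = 3, r2 = 3,
                            p_in = 100) {
  nodes <- data.frame(id = c("in", "m", "out"), x = c(0, 100, 300), y = 0)
  edges <- rbind(edge_row("e1", "in", "m", l1, r1),
                 edge_row("e2", "m", "out", l2, r2))
  make_net(nodes, edges, "in", "out", p_in)
}

# two parallel edges between inlet and outlet
make_parallel_net <- function(l1 = 100, l2 = 100, r1 = 3, r2 = 3,
                              p_in = 100) {
  nodes <- data.frame(id = c("in", "out"), x = c(0, 100), y = c(0, 0))
  edges <- rbind(edge_row("b1", "in", "out", l1, r1),
                 edge_row("b2", "in", "out", l2, r2))
  make_net(nodes, edges, "in", "out", p_in)
}

# Y network: stem, two branches, re-merge, tail (for routing statistics).
# Short fast vessels so transported cells clear the system quickly.
make_y_net <- function(r_b1 = 5, r_b2 = 5, p_in = 2000) {
  nodes <- data.frame(id = c("in", "s", "m", "out"),
                      x = c(0, 50, 150, 200),
                      y = 0)
  edges <- rbind(
    edge_row("stem", "in", "s", 50, 8),
    edge_row("b1", "s", "m", 100, r_b1),
    edge_row("b2", "s", "m", 100, r_b2),
    edge_row("tail", "m", "out", 50, 8)
  )
  make_net(nodes, edges, "in", "out", p_in)
}

# single-edge network (for the fixed-flux adaptation closed form)
make_single_edge_net <- function(radius_um = 3, length_um = 100,
                                 p_in = 100) {
  nodes <- data.frame(id = c("in", "out"), x = c(0, length_um), y = 0)
  make_net(nodes, edge_row("only", "in", "out", length_um, radius_um),
           "in", "out", p_in)
}

# Ground-truthed straight-vessel movie: n_cells advect at a constant speed
# along a horizontal vessel, wrapping inside [margin, margin + span] so the
# per-frame census stays constant and no cell sits on a profile boundary.
make_tracking_movie <- function(n_cells = 50, speed_cms = 0.012, fps = 20,
                                n_frames = 40, span_um = 1000,
                                margin_um = 10, noise = noise_model("none"),
                                seed = 1L, jitter_um = 2) {
  set.seed(seed)
  v_umps <- speed_cms * 1e4
  s0 <- (seq_len(n_cells) - 1) * span_um / n_cells +
    stats::runif(n_cells, -jitter_um, jitter_um)
  t_frames <- (seq_len(n_frames) - 1) / fps
  traj <- do.call(rbind, lapply(seq_len(n_frames), function(f) {
    data.frame(time_s = t_frames[f], cell_id = seq_len(n_cells),
               edge_id = "v1",
               arclength_um = margin_um + (s0 + v_umps * t_frames[f]) %%
                 span_um)
  }))
  trace_len <- span_um + 2 * margin_um
  height_um <- 30
  trace <- vessel_trace("v1", c(0, trace_len), c(height_um / 2,
                                                 height_um / 2))
  px <- 1.136
  cfg <- imaging_config(pixel_size = px, frame_rate = fps,
                        noise = noise,
                        field_size = c(ceiling(height_um / px),
                                       ceiling(trace_len / px)))
  movie <- render_movie(traj, list(v1 = trace), cfg, seed = seed)
  list(movie = movie, trace = trace, config = cfg, speed_cms = speed_cms,
       n_cells = n_cells, trajectories = traj)
}

# detection recall/precision against truth for one frame's detections
match_truth <- function(detected, truth, tol_um) {
  if (!length(truth)) {
    return(list(tp = 0L, fp = length(detected), fn = 0L))
  }
  used <- logical(length(truth))
  tp <- 0L
  for (d in detected) {
    j <- which.min(abs(truth - d))
    if (!used[j] && abs(truth[j] - d) <= tol_um) {
      used[j] <- TRUE
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = length(detected) - tp, fn = length(truth) - tp)
}

movie_recall <- function(fix, params = tracking_params(), tol_um = 3) {
  stack <- fix$movie$stack
  n_frames <- dim(stack)[3]
  tp <- 0L
  fn <- 0L
  fp <- 0L
  for (f in seq_len(n_frames)) {
    prof <- sample_centerline_profile(stack[, , f], fix$trace, params,
                                      fix$config$pixel_size)
    det <- coalesce_peaks(detect_cells(prof, params),
                          params$coalesce_radius)
    truth <- fix$movie$truth$arclength_um[fix$movie$truth$frame == f]
    m <- match_truth(det, truth, tol_um)
    tp <- tp + m$tp
    fp <- fp + m$fp
    fn <- fn + m$fn
  }
  list(recall = tp / (tp + fn), precision = tp / (tp + fp))
}
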