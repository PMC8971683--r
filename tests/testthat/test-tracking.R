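test_that("centerline profile is flat on uniform frames, peaked on blobs", {
  trace <- vessel_trace("v", c(0, 100), c(15, 15))
  frame <- matrix(40, 30, 100)
  prof <- sample_centerline_profile(frame, trace, pixel_size = 1.136)
  expect_true(all(abs(prof$intensity - 40) < 1e-9))

  # a Gaussian blob on the centerline surfaces at its arclength
  cfg <- imaging_config(field_size = c(30, 100), noise = noise_model("none"))
  traj <- data.frame(time_s = 0, cell_id = 1L, edge_id = "v",
                     arclength_um = 43.7)
  mv <- render_movie(traj, list(v = trace), cfg, seed = 1)
  prof2 <- sample_centerline_profile(mv$stack[, , 1], trace,
                                     pixel_size = cfg$pixel_size)
  s_hat <- prof2$arclength[which.max(prof2$intensity)]
  expect_lt(abs(s_hat - 43.7), prof2$step + 1e-9)

  expect_error(vessel_trace("v", c(0, 0), c(1, 1)), "degenerate")
})

test_that("peak detection finds blobs and ignores flats and ramps", {
  params <- tracking_params()
  flat <- list(arclength = seq(0, 50, 0.25), step = 0.25)
  flat$intensity <- rep(5, length(flat$arclength))
  expect_length(detect_cells(flat, params), 0)

  ramp <- flat
  ramp$intensity <- seq_along(ramp$arclength)
  expect_length(detect_cells(ramp, params), 0)

  # two Gaussians 10 um apart recovered at truth
  s <- seq(0, 60, 0.25)
  y <- exp(-(s - 20)^2 / 2) + exp(-(s - 30)^2 / 2)
  two <- list(arclength = s, intensity = y, step = 0.25)
  pk <- detect_cells(two, params)
  expect_length(pk, 2)
  expect_equal(pk, c(20, 30), tolerance = 0.3)

  expect_error(detect_cells(list(arclength = numeric(0),
                                 intensity = numeric(0)), params), "empty")
})

test_that("coalescence follows the single-linkage centroid rule", {
  expect_equal(coalesce_peaks(c(10, 12), 3), 11)
  expect_equal(coalesce_peaks(c(10, 14), 3), c(10, 14))
  # chained gaps of 2.5 merge into one cluster at the mean
  expect_equal(coalesce_peaks(c(10, 12.5, 15), 3), 12.5)

  # idempotence and oracle equivalence on random instances
  set.seed(13)
  for (i in 1:40) {
    peaks <- sort(stats::runif(sample(1:15, 1), 0, 60))
    got <- coalesce_peaks(peaks, 3)
    expect_equal(got, oracle_single_linkage(peaks, 3), tolerance = 1e-12)
    expect_equal(coalesce_peaks(got, 3), got, tolerance = 1e-12)
  }
})

test_that("number density divides count by length in cm", {
  expect_equal(number_density(5, 100), 500)
  expect_equal(number_density(0, 100), 0)
  expect_equal(number_density(3, 250), 120)
  expect_error(number_density(1, 0), "vessel_length")
})

test_that("frame linking applies the nearest-within-30um rule", {
  params <- tracking_params()
  lk <- link_frames(10, 12, params, frame_rate = 20)
  expect_equal(lk$speed_cms, 4e-3)
  expect_equal(nrow(link_frames(10, 45, params, 20)), 0)

  # brute-force enumeration oracle, instances up to 20 detections
  set.seed(17)
  for (i in 1:40) {
    a <- sort(stats::runif(sample(1:20, 1), 0, 300))
    b <- sort(stats::runif(sample(1:20, 1), 0, 300))
    got <- link_frames(a, b, params, 25)
    want <- oracle_link(a, b, params$max_link_distance, 25)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("majority rule fixes direction and removes counter-flow samples", {
  r <- infer_direction_and_filter(c(1, 2, -0.5))
  expect_equal(r$direction, 1L)
  expect_length(r$speeds, 2)
  expect_equal(r$n_removed, 1L)

  tie <- infer_direction_and_filter(c(1, -1))
  expect_equal(tie$direction, 0L)
  expect_true(tie$tie)
  expect_length(tie$speeds, 2)

  # 5% artifactual reversals on a 1000-sample synthetic vessel
  set.seed(6)
  sp <- abs(stats::rnorm(1000, 0.05, 0.005))
  flip <- sample(1000, 50)
  sp[flip] <- -sp[flip]
  r2 <- infer_direction_and_filter(sp)
  expect_equal(r2$direction, 1L)
  expect_equal(r2$n_removed, 50L)
  expect_error(infer_direction_and_filter(numeric(0)), "samples")
})

test_that("summarize_vessel reports density, direction and median speed", {
  trace <- vessel_trace("v", c(0, 100), c(0, 0))
  det <- list(c(10, 30, 50, 70, 90), c(11, 31, 51, 71, 91))
  st <- summarize_vessel(det, c(1, 2, 9), trace)
  expect_equal(st$number_density_cm, 500)
  expect_equal(st$median_speed_cms, 2)
  expect_equal(st$direction, 1L)
})

test_that("noiseless movies round-trip: perfect detection, exact speed", {
  fix <- make_tracking_movie(n_cells = 50, speed_cms = 0.012, fps = 20,
                             n_frames = 30, seed = 2)
  params <- tracking_params()
  pr <- movie_recall(fix, params, tol_um = 0.5 * fix$config$pixel_size)
  expect_equal(pr$recall, 1)
  expect_equal(pr$precision, 1)

  res <- track_vessel(fix$movie$stack, fix$trace, params,
                      fix$config$pixel_size, fix$config$frame_rate)
  # median speed within the arclength discretization bound
  bound <- 0.25 * fix$config$pixel_size * fix$config$frame_rate * 1e-4
  expect_lt(abs(res$stats$median_speed_cms - fix$speed_cms), bound)
  expect_equal(res$stats$direction, 1L)
  # density exact: constant census of 50 cells on the trace
  expect_equal(res$stats$number_density_cm,
               50 / (fix$trace$length * 1e-4))
})

test_that("detection recall does not improve with heavier noise", {
  recalls <- vapply(c(0, 60, 200), function(sd) {
    nm <- if (sd == 0) noise_model("none") else noise_model("gaussian",
                                                            sd = sd)
    r <- vapply(1:3, function(seed) {
      fix <- make_tracking_movie(n_cells = 20, n_frames = 4,
                                 span_um = 400, noise = nm, seed = seed)
      movie_recall(fix, tol_um = 3)$recall
    }, numeric(1))
    mean(r)
  }, numeric(1))
  expect_true(all(diff(recalls) <= 0))
  expect_equal(recalls[1], 1)
})
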