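test_that("clustering separates pores and ignores strays and background", {
  truth <- make_scaffold_truth(2, spacing_nm = 300, seed = 1)
  st <- simulate_scaffold_stream(truth, mean_bursts_per_corner = 3,
                                 mean_locs_per_burst = 4, seed = 2)
  cl <- cluster_localizations(st$records)
  expect_length(cl, 2)
  # membership: every cluster point lies near one pore centre
  for (k in 1:2) {
    d <- sapply(seq_len(nrow(truth)), function(p)
      min(sqrt((cl[[k]]$x - truth$x0[p])^2 + (cl[[k]]$y - truth$y0[p])^2)))
    expect_lt(sort(sapply(1:2, function(p)
      mean(sqrt((cl[[k]]$x - truth$x0[p])^2 +
                  (cl[[k]]$y - truth$y0[p])^2))))[1], 80)
  }
  memb <- lapply(cl, function(x) attr(x, "member_rows"))
  expect_length(intersect(memb[[1]], memb[[2]]), 0)

  # uniform sparse background only -> no clusters
  set.seed(3)
  bg <- localizations(1:60, sort(runif(60, 0, 10)) + seq_len(60) * 1e-6,
                      runif(60, 0, 5000), runif(60, 0, 5000),
                      runif(60, -100, 100))
  expect_length(cluster_localizations(bg), 0)

  # one pore plus 5 strays 500 nm away -> one cluster, strays unassigned
  one <- simulate_scaffold_stream(truth[1, ], mean_bursts_per_corner = 3,
                                  mean_locs_per_burst = 4, seed = 4)
  strays <- localizations(1000 + 1:5, 100 + 1:5,
                          truth$x0[1] + 500 + runif(5, 0, 30),
                          truth$y0[1] + 500, rep(0, 5))
  rec <- rbind(one$records, strays)
  cl <- cluster_localizations(rec)
  expect_length(cl, 1)
  expect_true(all(sqrt((cl[[1]]$x - truth$x0[1])^2 +
                         (cl[[1]]$y - truth$y0[1])^2) < 200))
})

test_that("double-circle fit is exact on noiseless corners", {
  truth <- make_scaffold_truth(1, ring_radius = 53.5, ring_spacing = 51.5,
                               seed = 5)
  st <- simulate_scaffold_stream(truth, sigma_spec = species_spec(sigma_x = 0),
                                 mean_bursts_per_corner = 1,
                                 mean_locs_per_burst = 2,
                                 deterministic = TRUE, seed = 6)
  f <- fit_double_circle(st$records, min_points = 16)
  expect_equal(f$ring_radius, 53.5, tolerance = 1e-6)
  expect_equal(f$ring_spacing, 51.5, tolerance = 1e-6)
  expect_equal(unname(f$centre), c(truth$x0, truth$y0, truth$z0),
               tolerance = 1e-6)
  expect_lt(f$rms_residual, 1e-6)
})

test_that("double-circle fit recovers spacing within 2 nm at realistic noise", {
  truth <- make_scaffold_truth(12, seed = 7)
  st <- simulate_scaffold_stream(truth,
                                 sigma_spec = species_spec(sigma_x = 6.5,
                                                           sigma_y = 7.0,
                                                           sigma_z = 4.2),
                                 mean_bursts_per_corner = 3,
                                 mean_locs_per_burst = 5, seed = 8)
  cl <- cluster_localizations(st$records)
  expect_length(cl, 12)
  sp <- vapply(cl, function(x) fit_double_circle(x)$ring_spacing, numeric(1))
  expect_lt(abs(mean(sp) - 51.5), 2)
  expect_lt(median(abs(sp - 51.5)), 2)
})

test_that("single-plane clusters are flagged degenerate", {
  set.seed(9)
  th <- runif(40, 0, 2 * pi)
  ring <- localizations(1:40, 1:40, 53.5 * cos(th), 53.5 * sin(th),
                        rep(0, 40))
  f <- fit_double_circle(ring)
  expect_true(f$degenerate)
  expect_true(is.na(f$ring_spacing))
  expect_error(fit_double_circle(ring[1:10, ]), "min_points")
})

test_that("symmetry phase is recovered and respects mod-45 invariance", {
  mk <- function(phase, seed = 10, sigma = 0) {
    truth <- make_scaffold_truth(1, seed = seed)
    truth$phase_deg <- phase
    simulate_scaffold_stream(truth, sigma_spec = species_spec(sigma_x = sigma),
                             mean_bursts_per_corner = 1,
                             mean_locs_per_burst = 4,
                             deterministic = TRUE, seed = seed + 1)$records
  }
  rec <- mk(12)
  f <- fit_double_circle(rec, min_points = 16)
  expect_equal(fit_symmetry_phase(rec, f)$phase_deg, 12, tolerance = 0.1)

  rec0 <- mk(0)
  f0 <- fit_double_circle(rec0, min_points = 16)
  expect_lt(min(fit_symmetry_phase(rec0, f0)$phase_deg %% 45,
                45 - fit_symmetry_phase(rec0, f0)$phase_deg %% 45), 0.1)

  # rotating the input by 45 degrees leaves the phase unchanged
  rot <- rec
  a <- 45 * pi / 180
  cx <- f$centre["x0"]; cy <- f$centre["y0"]
  rot$x <- cx + (rec$x - cx) * cos(a) - (rec$y - cy) * sin(a)
  rot$y <- cy + (rec$x - cx) * sin(a) + (rec$y - cy) * cos(a)
  fr <- fit_double_circle(rot, min_points = 16)
  expect_equal(fit_symmetry_phase(rot, fr)$phase_deg, 12, tolerance = 0.1)
})

test_that("rotating inputs by beta rotates the phase by beta mod 45", {
  truth <- make_scaffold_truth(1, seed = 12)
  truth$phase_deg <- 5
  rec <- simulate_scaffold_stream(truth,
                                  sigma_spec = species_spec(sigma_x = 3),
                                  mean_bursts_per_corner = 2,
                                  mean_locs_per_burst = 6,
                                  deterministic = TRUE, seed = 13)$records
  f <- fit_double_circle(rec)
  base_phase <- fit_symmetry_phase(rec, f)$phase_deg
  for (beta in c(10, 30)) {
    a <- beta * pi / 180
    rot <- rec
    cx <- truth$x0; cy <- truth$y0
    rot$x <- cx + (rec$x - cx) * cos(a) - (rec$y - cy) * sin(a)
    rot$y <- cy + (rec$x - cx) * sin(a) + (rec$y - cy) * cos(a)
    fr <- fit_double_circle(rot)
    expect_equal(fit_symmetry_phase(rot, fr)$phase_deg %% 45,
                 (base_phase + beta) %% 45, tolerance = 0.5)
    expect_equal(fr$ring_radius, f$ring_radius, tolerance = 0.2)
    expect_equal(fr$ring_spacing, f$ring_spacing, tolerance = 0.2)
  }
})

test_that("flat azimuthal distributions get a low-confidence phase", {
  set.seed(14)
  th <- runif(300, 0, 2 * pi)
  r <- 53.5 + rnorm(300, 0, 4)
  z <- sample(c(-25.75, 25.75), 300, TRUE) + rnorm(300, 0, 4)
  rec <- localizations(1:300, 1:300, r * cos(th), r * sin(th), z)
  f <- fit_double_circle(rec)
  expect_true(fit_symmetry_phase(rec, f)$low_confidence)
})

test_that("alignment and averaging build a faithful composite", {
  truth <- make_scaffold_truth(1, seed = 15)
  rec <- simulate_scaffold_stream(truth, sigma_spec = species_spec(sigma_x = 0),
                                  mean_bursts_per_corner = 1,
                                  mean_locs_per_burst = 3,
                                  deterministic = TRUE, seed = 16)$records
  f <- fit_double_circle(rec, min_points = 16)
  f$phase_deg <- fit_symmetry_phase(rec, f)$phase_deg
  comp <- align_and_average(list(f), list(rec))
  # 8 azimuthal maxima at k * 45 degrees (pore frame: corners at 0 mod 45)
  az <- sort(unique(round(atan2(comp$points$y, comp$points$x) * 180 / pi,
                          3))) %% 45
  expect_true(all(pmin(az, 45 - az) < 0.1))
  expect_equal(max(comp$xy$percent), 100)

  # composite of N copies equals the single image with counts scaled by N
  compN <- align_and_average(rep(list(f), 3), rep(list(rec), 3))
  expect_equal(compN$z_profile$count, 3 * comp$z_profile$count)

  # 50-pore composite recovers the ring spacing
  truth50 <- make_scaffold_truth(20, seed = 17)
  st <- simulate_scaffold_stream(truth50,
                                 sigma_spec = species_spec(sigma_x = 4.1),
                                 mean_bursts_per_corner = 3,
                                 mean_locs_per_burst = 5, seed = 18)
  cl <- cluster_localizations(st$records)
  fits <- lapply(cl, fit_double_circle)
  for (i in seq_along(fits))
    fits[[i]]$phase_deg <- fit_symmetry_phase(cl[[i]], fits[[i]])$phase_deg
  comp50 <- align_and_average(fits, cl)
  expect_equal(composite_ring_spacing(comp50), 51.5, tolerance = 1.5)
})

test_that("centroid-deviation precision is unbiased without drift and inflated with it", {
  cfg <- simulation_config(seed = 19, n_traj = 800, traj_len = 25,
                           species = species_spec(D = 0, sigma_x = 4.1),
                           timesteps = timestep_model("fixed", 3.3))
  pe <- estimate_precision_centroid(simulate_jump_trajectories(cfg)$points)
  expect_equal(unname(pe$sigma["x"]), 4.1, tolerance = 0.02)
  expect_equal(unname(pe$sigma["z"]), 4.1 / 1.55, tolerance = 0.03)

  drift <- simulation_config(seed = 19, n_traj = 800, traj_len = 25,
                             species = species_spec(
                               D = c(0.00072, 0.00083, 0.0003),
                               sigma_x = 4.1),
                             timesteps = timestep_model("fixed", 3.3))
  pd <- estimate_precision_centroid(simulate_jump_trajectories(drift)$points)
  expect_gt(pd$sigma["x"], pe$sigma["x"] + 1)  # clearly inflated

  # degenerate: identical points give sigma = 0
  still <- data.frame(traj_id = 1, t = 1:25, x = 5, y = 5, z = 5)
  expect_equal(unname(estimate_precision_centroid(still)$sigma), c(0, 0, 0))
  expect_error(estimate_precision_centroid(still, min_points = 30),
               "no burst")
})

test_that("early/late splits detect pore displacement and drift", {
  set.seed(20)
  n <- 60
  stationary <- data.frame(t = seq_len(n),
                           x = rnorm(n, 0, 4), y = rnorm(n, 0, 4),
                           z = rnorm(n, 0, 3))
  s <- stability_split(list(stationary))
  expect_lt(s$displacement, 3 * 4 / sqrt(n / 4))

  moved <- stationary
  moved$x[31:60] <- moved$x[31:60] + 20
  s <- stability_split(list(moved))
  expect_equal(s$displacement, 20, tolerance = 3)
  expect_equal(s$dx, 20, tolerance = 3)

  # displacement grows with the drift coefficient
  disp_at <- function(Dd, seed) {
    cfg <- simulation_config(seed = seed, n_traj = 1, traj_len = 200,
                             species = species_spec(D = Dd, sigma_x = 3),
                             timesteps = timestep_model("fixed", 3.3))
    pts <- simulate_jump_trajectories(cfg)$points
    median(sapply(1:12, function(s2) {
      cfg$seed <- seed + s2
      p <- simulate_jump_trajectories(cfg)$points
      stability_split(list(p))$displacement
    }))
  }
  expect_gt(disp_at(0.002, 21), disp_at(0.00005, 21))

  # too few points in a half -> excluded with NA
  tiny <- stationary[1:12, ]
  expect_true(is.na(stability_split(list(tiny), min_half = 10)$displacement))
})
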