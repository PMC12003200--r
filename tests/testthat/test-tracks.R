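test_that("a hand-built toy table is filtered with an exact rejection log", {
  # 6 tracks: 2 clean, 1 short, 1 bad CFR point mid-track (splits short),
  # 1 out-of-window DCR, 1 high EFO
  mk <- function(id, n, cfr = 0.5, dcr = 0.5, efo = 30) {
    localizations(rep(id, n), seq_len(n) * 0.001, seq_len(n), 0, 0,
                  efo = rep(efo, n), efc = cfr * efo, cfr = rep(cfr, n),
                  dcr = rep(dcr, n), channel = "cargo")
  }
  t1 <- mk(1, 6)                      # clean
  t2 <- mk(2, 8)                      # clean
  t3 <- mk(3, 4)                      # too short
  t4 <- mk(4, 7); t4$cfr[4] <- 0.95   # split into 3 + 3 -> both too short
  t5 <- mk(5, 6, dcr = 0.1)           # all points fail DCR
  t6 <- mk(6, 6, efo = 150)           # all points fail EFO high
  tab <- rbind(t1, t2, t3, t4, t5, t6)
  ts <- filter_tracks(tab, filter_params(min_len = 5, efo_max_kHz = 100))
  expect_length(ts$segments, 2)
  expect_setequal(sapply(ts$segments, function(s) s$trace_id[1]), c(1, 2))
  expect_identical(unname(ts$rejection_log["cfr"]), 1L)
  expect_identical(unname(ts$rejection_log["dcr"]), 6L)
  expect_identical(unname(ts$rejection_log["efo_high"]), 6L)
  # dropped fragments: t3 (1) + two fragments of t4 (2)
  expect_identical(unname(ts$rejection_log["too_short"]), 3L)
})

test_that("tracks shorter than five consecutive localizations are rejected", {
  t4 <- localizations(rep(1, 4), 1:4 * 0.001, 1:4, 0, 0, efo = 30,
                      cfr = 0.4, dcr = 0.5, channel = "cargo")
  expect_length(filter_tracks(t4, filter_params())$segments, 0)
  t5 <- localizations(rep(1, 5), 1:5 * 0.001, 1:5, 0, 0, efo = 30,
                      cfr = 0.4, dcr = 0.5, channel = "cargo")
  expect_length(filter_tracks(t5, filter_params())$segments, 1)
})

test_that("double-dye tracks are kept but flagged", {
  set.seed(1)
  lowA <- localizations(rep(1, 10), 1:10 * 0.001, 1:10, 0, 0,
                        efo = rnorm(10, 30, 1), cfr = 0.4, dcr = 0.5,
                        channel = "cargo")
  lowB <- localizations(rep(2, 10), 1:10 * 0.001, 1:10, 0, 0,
                        efo = rnorm(10, 30, 1), cfr = 0.4, dcr = 0.5,
                        channel = "cargo")
  high <- localizations(rep(3, 10), 1:10 * 0.001, 1:10, 0, 0,
                        efo = rnorm(10, 63, 1), cfr = 0.4, dcr = 0.5,
                        channel = "cargo")
  ts <- filter_tracks(rbind(lowA, lowB, high), filter_params())
  expect_length(ts$segments, 3)
  flags <- sapply(ts$segments, attr, "double_dye_flag")
  ids <- sapply(ts$segments, function(s) s$trace_id[1])
  expect_identical(unname(flags[ids == 3]), TRUE)
  expect_false(any(flags[ids != 3]))
})

test_that("filtering is idempotent", {
  truth <- make_scaffold_truth(3, seed = 2)
  cohort <- make_track_cohort(truth, seed = 3)
  sim <- simulate_cargo_dataset(cohort, truth, seed = 4)
  p <- filter_params()
  once <- filter_tracks(sim$records, p)
  again <- filter_tracks(do.call(rbind, once$segments), p)
  expect_identical(length(again$segments), length(once$segments))
  expect_true(all(again$rejection_log[c("cfr", "efo_low", "efo_high",
                                        "dcr", "too_short")] == 0))
  expect_identical(do.call(rbind, again$segments)$x,
                   do.call(rbind, once$segments)$x)
})

test_that("tracks are assigned by the 400-nm cube rule with nearest-centre ties", {
  one_pore <- data.frame(pore_id = 1L, x0 = 0, y0 = 0, z0 = 0,
                         ring_radius = 53.5, ring_spacing = 51.5,
                         phase_deg = 0, n = 100, rms = 5)
  strip <- function(s) { s$xp <- NULL; s$yp <- NULL; s$zp <- NULL; s }
  graze <- make_pore_track(z = c(50, 40, 30, 20, 10))
  graze$x <- 190; graze$y <- 0     # grazing inside the 200-nm half width
  far <- make_pore_track(z = c(50, 40, 30, 20, 10), track_id = 2L)
  far$x <- 300; far$y <- 0         # 300 nm lateral offset: outside
  out <- assign_tracks_to_npcs(lapply(list(graze, far), strip), one_pore)
  expect_identical(attr(out[[1]], "pore_id"), 1L)
  expect_true(is.na(attr(out[[2]], "pore_id")))

  # overlapping cubes: deterministic nearest-centre rule
  two_pores <- rbind(one_pore, within(one_pore, { pore_id <- 2L; x0 <- 350 }))
  tie <- make_pore_track(z = c(50, 40, 30, 20, 10), track_id = 3L)
  tie$x <- 160; tie$y <- 0         # inside both cubes, nearer pore 1
  out <- assign_tracks_to_npcs(list(strip(tie)), two_pores)
  expect_identical(attr(out[[1]], "pore_id"), 1L)
  # pore-frame coordinates: translation to centre, cytoplasm at +z
  expect_equal(out[[1]]$xp, rep(160, 5))
  expect_equal(out[[1]]$zp, c(50, 40, 30, 20, 10))
  # pore-frame rotation by -phase
  pores2 <- one_pore; pores2$phase_deg <- 90
  out2 <- assign_tracks_to_npcs(list(strip(tie)), pores2)
  expect_equal(out2[[1]]$yp, rep(-160, 5), tolerance = 1e-9)
})

test_that("transit detection is inclusive at the 25-nm boundary", {
  tr <- make_pore_track(z = c(60, 40, 25, 40, 60))
  d <- detect_transit(tr)
  expect_true(d$transit)
  expect_identical(d$in_pore, 3L)
  tr26 <- make_pore_track(z = c(60, 40, 26, 40, 60))
  expect_false(detect_transit(tr26)$transit)
  all_in <- make_pore_track(z = c(20, 10, 0, -10, -20))
  expect_identical(detect_transit(all_in)$in_pore, 1:5)
})

test_that("track classes follow the compartment geometry", {
  expect_identical(classify_track(make_pore_track(seq(60, -60, length.out = 9))),
                   "import")
  expect_identical(classify_track(make_pore_track(seq(-60, 60, length.out = 9))),
                   "export")
  expect_identical(classify_track(make_pore_track(c(60, 30, 5, 30, 70))),
                   "abortive_import")
  expect_identical(classify_track(make_pore_track(c(-60, -30, -5, -30, -70))),
                   "abortive_export")
  expect_identical(classify_track(make_pore_track(c(60, 20, 10, 20, 15))),
                   "unclassified")
})

test_that("negating z mirrors the classification exactly", {
  mirror_of <- c(import = "export", export = "import",
                 abortive_import = "abortive_export",
                 abortive_export = "abortive_import",
                 unclassified = "unclassified")
  set.seed(5)
  for (i in 1:30) {
    n <- sample(6:15, 1)
    z <- cumsum(rnorm(n, 0, 40)) + runif(1, -80, 80)
    tr <- make_pore_track(z)
    cls <- classify_track(tr)
    trm <- tr; trm$zp <- -trm$zp
    expect_identical(classify_track(trm), unname(mirror_of[cls]))
  }
})

test_that("noiseless synthetic cohorts classify with an identity confusion matrix", {
  truth <- make_scaffold_truth(5, seed = 6)
  cohort <- make_track_cohort(truth, n_import = 8, n_export = 8,
                              n_abortive_import = 6, n_abortive_export = 6,
                              n_background = 6, seed = 7)
  sim <- simulate_cargo_dataset(cohort, truth,
                                sigma_spec = species_spec(sigma_x = 0),
                                decoy_frac = 0, double_dye_frac = 0, seed = 8)
  tset <- filter_tracks(sim$records, filter_params())
  tset <- assign_tracks_to_npcs(tset, truth)
  cls <- classify_tracks(tset)
  # original trace id is embedded in the track_id
  trace_of <- cls$track_id %/% 1000
  for (i in seq_len(nrow(cohort))) {
    expect_identical(cls$class[trace_of == cohort$track_id[i]],
                     cohort$class[i])
  }
})

test_that("angular statistics recover a known confinement width", {
  # all in-pore points at one azimuth -> width collapses to the lower bound
  tr <- make_pore_track(z = seq(25, -25, length.out = 8))
  expect_equal(angular_analysis(list(tr))$gaussian_width_deg, 0.5)

  # differences drawn from N(0, 19 deg) are recovered
  set.seed(9)
  tracks <- lapply(1:20, function(i) {
    n <- 12
    z <- seq(24, -24, length.out = n)
    ref <- runif(1, 0, 360)
    th <- (ref + c(rnorm(n - 1, 0, 19), 0)) * pi / 180
    # put the reference angle (exact) at the point nearest z = 0
    ord <- order(abs(z))
    th[ord[1]] <- ref * pi / 180
    tr <- make_pore_track(z)
    tr$xp <- 23 * cos(th); tr$yp <- 23 * sin(th)
    tr
  })
  st <- angular_analysis(tracks)
  expect_equal(st$gaussian_width_deg, 19, tolerance = 0.15)
  expect_gt(st$goodness_p, 0.01)

  # uniform azimuths: Gaussian model flagged as fitting poorly
  set.seed(10)
  utracks <- lapply(1:20, function(i) {
    n <- 14
    tr <- make_pore_track(seq(24, -24, length.out = n))
    th <- runif(n, 0, 2 * pi)
    tr$xp <- 23 * cos(th); tr$yp <- 23 * sin(th)
    tr
  })
  expect_lt(angular_analysis(utracks)$goodness_p, 0.01)
})

test_that("residence time sums consecutive in-pore intervals", {
  tr <- make_pore_track(z = c(60, 40, rep(c(20, 10, 0, -5, -10, -15, -20), 1),
                              -40, -60), dt = 0.002)
  res <- residence_time(tr)
  expect_identical(res$n_in_pore, 7L)
  expect_equal(res$seconds, 0.012)  # 6 intervals at 2 ms

  single <- make_pore_track(z = c(60, 40, 20, 40, 60))
  res1 <- residence_time(single)
  expect_identical(res1$n_in_pore, 1L)
  expect_equal(res1$seconds, 0)
})

test_that("an import cohort's residence matches its in-pore dwell arithmetic", {
  truth <- make_scaffold_truth(4, seed = 11)
  cohort <- make_track_cohort(truth, n_import = 30, n_export = 0,
                              n_abortive_import = 0, n_abortive_export = 0,
                              n_background = 0, seed = 12)
  sim <- simulate_cargo_dataset(cohort, truth,
                                sigma_spec = species_spec(sigma_x = 0),
                                n_in_pore = 7,
                                timesteps = timestep_model("fixed", 2),
                                decoy_frac = 0, double_dye_frac = 0,
                                seed = 13)
  tset <- assign_tracks_to_npcs(filter_tracks(sim$records, filter_params()),
                                truth)
  cls <- classify_tracks(tset)
  med_pts <- median(cls$n_in_pore[cls$transit])
  med_res <- median(cls$residence_s[cls$transit]) * 1000
  expect_equal(med_res, (med_pts - 1) * 2, tolerance = 0.1)
  expect_gte(med_pts, 5)
})
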