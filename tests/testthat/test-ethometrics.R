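# Fixture helpers -----------------------------------------------------------

# Stationary trajectory at a point, optional per-frame nose/tail offsets.
point_traj <- function(x, y, n = 50, fr = 10, nose = NULL, tail = NULL) {
  df <- data.frame(t = (seq_len(n) - 1) / fr, x = rep(x, n), y = rep(y, n))
  if (!is.null(nose)) {
    df$nose_x <- nose[, 1]; df$nose_y <- nose[, 2]
    df$tail_x <- tail[, 1]; df$tail_y <- tail[, 2]
  }
  as_trajectory(df, frame_rate = fr)
}

test_that("zone labeling agrees with direct point-in-polygon lookup", {
  zm <- build_zonemap("epm")
  set.seed(1)
  n <- 1000
  df <- data.frame(t = (seq_len(n) - 1) / 25,
                   x = runif(n, -35, 35), y = runif(n, -35, 35))
  tr <- as_trajectory(df)
  lab <- zone_timeseries(tr, zm)
  expect_equal(lab, locate_points(df$x, df$y, zm))

  stationary <- point_traj(0, 0)
  expect_true(all(zone_timeseries(stationary, zm) == "center"))
})

test_that("dwell times conserve trial duration and match a frame tally", {
  zm <- build_zonemap("epm")
  # 300 s stationary in center at 25 Hz
  still <- point_traj(0, 0, n = 300 * 25, fr = 25)
  d <- dwell_times(zone_timeseries(still, zm), 25, zm)
  expect_equal(unname(d["center"]), 300)
  expect_equal(sum(unclass(d)[names(d) != "center"]), 0)

  # alternating frames center/entry for 10 s
  lab <- rep(c("center", "open_entry_east"), 125)
  d2 <- dwell_times(lab, 25)
  expect_equal(unname(unclass(d2)[c("center", "open_entry_east")]), c(5, 5))

  # random labels: conservation + brute-force tally
  set.seed(2)
  for (i in 1:20) {
    lab <- sample(c(names(zm$zones), "off_arena"), 200, replace = TRUE)
    d3 <- dwell_times(lab, 25, zm)
    expect_equal(sum(d3), length(lab) / 25)
    for (z in unique(lab)) {
      expect_equal(unname(unclass(d3)[z]), sum(lab == z) / 25)
    }
  }
})

test_that("risk indices follow their definitions, including degenerate cases", {
  d <- c(center = 60, open_entry_east = 30, open_entry_west = 30,
         open_distal_east = 90, open_distal_west = 90)
  expect_equal(epm_risk_index(d), 0.4)
  expect_equal(epm_risk_index(c(center = 10, open_entry_east = 0,
                                open_distal_east = 0)), 1)
  expect_true(is.na(epm_risk_index(c(center = 0, open_entry_east = 0,
                                     open_distal_east = 0, closed_north = 300))))

  expect_equal(dl_risk_index(c(entry = 30, light_core = 70)), 0.3)
  expect_equal(dl_risk_index(c(entry = 25, light_core = 0)), 1)
  expect_true(is.na(dl_risk_index(c(entry = 0, light_core = 0, hidden = 300))))
})

test_that("transition runs and entries match a brute-force scan", {
  r <- transition_runs(c("H", "H", "E", "E", "H"))
  expect_equal(r$runs$zone, c("H", "E", "H"))
  expect_equal(unname(r$entries[c("E", "H")]), c(1L, 1L))

  const <- transition_runs(rep("center", 40))
  expect_equal(nrow(const$runs), 1)
  expect_equal(unname(const$entries["center"]), 0L)

  set.seed(3)
  for (i in 1:100) {
    lab <- sample(c("hidden", "entry", "light_core"), 50, replace = TRUE)
    r <- transition_runs(lab)
    expect_equal(r$runs$zone, runs_oracle(lab))
    oe <- entries_oracle(lab)
    expect_equal(unname(r$entries[names(oe)]), unname(oe))
  }
})

test_that("HEH frequency counts triples over hidden-to-entry pairs", {
  expect_equal(heh_frequency(c("H", "E", "H", "E", "L", "E", "H"),
                             hidden = "H", entry = "E"), 0.5)
  expect_equal(heh_frequency(c("hidden", "entry", "hidden")), 1)
  expect_true(is.na(heh_frequency(c("hidden"))))
  expect_true(is.na(heh_frequency(c("entry", "light_core", "entry"))))

  set.seed(4)
  for (i in 1:100) {
    z <- runs_oracle(sample(c("hidden", "entry", "light_core"), 60, replace = TRUE))
    expect_equal(heh_frequency(z), heh_oracle(z))
  }
})

test_that("stretch-attend detection finds constructed bouts and honors thresholds", {
  zm <- build_zonemap("epm")
  n <- 100; fr <- 10
  # baseline body: nose (x+4, 0), tail (x-4, 0), length 8; bout frames have
  # nose at x+8 -> length 12 = 1.5x baseline
  nose <- cbind(rep(4, n), rep(0, n))
  tail <- cbind(rep(-4, n), rep(0, n))
  nose[41:50, 1] <- 8  # one 1-second bout
  tr <- point_traj(0, 0, n = n, fr = fr, nose = nose, tail = tail)
  ev <- detect_stretch_attend(tr, zm, elong_factor = 1.2, speed_max = 2,
                              min_dur = 0.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$zone, "center")
  expect_equal(ev$duration, 1)

  # constant elongation at baseline: no events
  tr0 <- point_traj(0, 0, n = n, fr = fr,
                    nose = cbind(rep(4, n), 0), tail = cbind(rep(-4, n), 0))
  expect_equal(nrow(detect_stretch_attend(tr0, zm)), 0)

  # sub-threshold duration is filtered
  nose2 <- cbind(rep(4, n), rep(0, n)); nose2[41:42, 1] <- 8
  tr2 <- point_traj(0, 0, n = n, fr = fr, nose = nose2, tail = tail)
  expect_equal(nrow(detect_stretch_attend(tr2, zm, min_dur = 0.5)), 0)

  expect_error(detect_stretch_attend(point_traj(0, 0), zm), "body points")
})

test_that("relative stretch-attend frequency uses risk-zone events", {
  ev <- data.frame(role = c("entry", "entry", "entry", "open_distal"))
  expect_equal(sap_relative_frequency(ev), 0.75)
  expect_equal(sap_relative_frequency(data.frame(role = rep("center", 4))), 1)
  expect_true(is.na(sap_relative_frequency(data.frame(role = character(0)))))
})

test_that("protected head dips require nose out and centroid protected", {
  zm <- build_zonemap("epm")
  n <- 60; fr <- 10
  base_nose <- cbind(rep(1, n), rep(0, n))
  base_tail <- cbind(rep(-1, n), rep(0, n))

  # centroid in entry zone, nose 1 cm past the arm's side edge for 0.5 s
  nose <- base_nose; nose[21:25, ] <- matrix(rep(c(5, 3.5), 5), ncol = 2, byrow = TRUE)
  tr <- point_traj(5, 0, n = n, fr = fr, nose = nose, tail = base_tail)
  expect_equal(detect_protected_head_dips(tr, zm), 1)

  # nose always inside: zero
  tr0 <- point_traj(5, 0, n = n, fr = fr, nose = base_nose, tail = base_tail)
  expect_equal(detect_protected_head_dips(tr0, zm), 0)

  # unprotected dip (centroid in the distal open arm) is excluded
  nose2 <- base_nose; nose2[21:25, ] <- matrix(rep(c(20, 3.5), 5), ncol = 2, byrow = TRUE)
  tr2 <- point_traj(20, 0, n = n, fr = fr, nose = nose2, tail = base_tail)
  expect_equal(detect_protected_head_dips(tr2, zm), 0)

  # pre-annotated events pass through
  expect_equal(detect_protected_head_dips(tr0, zm,
               events = data.frame(start_t = c(1, 2), end_t = c(1.5, 2.5))), 2)
})

test_that("locomotion summary matches analytic path lengths", {
  tr <- as_trajectory(data.frame(t = c(0, 1), x = c(0, 3), y = c(0, 4)))
  expect_equal(locomotion_summary(tr)$total_distance, 5)
  expect_equal(locomotion_summary(tr)$mean_velocity, 5)

  still <- point_traj(2, 2)
  expect_equal(locomotion_summary(still)$total_distance, 0)

  # discretized circle of radius 10
  th <- seq(0, 2 * pi, length.out = 1001)
  circ <- as_trajectory(data.frame(t = seq_along(th) - 1,
                                   x = 10 * cos(th), y = 10 * sin(th)))
  expect_equal(locomotion_summary(circ)$total_distance, 2 * pi * 10,
               tolerance = 0.005)
})

test_that("profiles assemble the metric set and flag undefined values", {
  zm <- build_zonemap("epm")
  p <- behavior_sim_params("epm", duration = 60, open_preference = 0, seed = 2)
  prof <- behavioral_profile(simulate_trajectory(p, zm), zm)
  expect_equal(prof$open_arm_time, 0)
  expect_true(is.na(prof$epm_risk_index))

  p2 <- behavior_sim_params("epm", duration = 60, seed = 3)
  tr <- simulate_trajectory(p2, zm)
  prof1 <- behavioral_profile(tr, zm)
  prof2 <- behavioral_profile(tr, zm)
  expect_identical(prof1, prof2)

  # hand-assembled record for a fixed fixture
  lab <- zone_timeseries(tr, zm)
  d <- dwell_times(lab, attr(tr, "frame_rate"), zm)
  expect_equal(prof1$epm_risk_index, epm_risk_index(d))
  expect_equal(prof1$total_distance, locomotion_summary(tr)$total_distance)
  ev <- detect_stretch_attend(tr, zm)
  expect_equal(prof1$sap_count, nrow(ev))
})

test_that("risk indices are insensitive to frame-rate upsampling", {
  zm <- build_zonemap("epm")
  p <- behavior_sim_params("epm", duration = 120, risk_propensity = 0.6,
                           body_points = FALSE, seed = 9)
  tr <- simulate_trajectory(p, zm)
  idx1 <- epm_risk_index(dwell_times(zone_timeseries(tr, zm), 25, zm))

  # 2x linear interpolation
  n <- nrow(tr)
  t2 <- seq(tr$t[1], tr$t[n], by = 1 / 50)
  up <- as_trajectory(data.frame(t = t2,
                                 x = approx(tr$t, tr$x, t2)$y,
                                 y = approx(tr$t, tr$y, t2)$y))
  idx2 <- epm_risk_index(dwell_times(zone_timeseries(up, zm), 50, zm))
  expect_lt(abs(idx1 - idx2) / idx1, 0.01)
})

test_that("trajectory CSV and profile TSV round-trip", {
  p <- behavior_sim_params("dl", duration = 30, seed = 6)
  tr <- simulate_trajectory(p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path, arena_kind = "dl")
  expect_equal(back$x, tr$x, tolerance = 1e-12)
  expect_true(has_body_points <- all(c("nose_x", "tail_y") %in% names(back)))

  zm <- build_zonemap("dl")
  prof <- profile_trajectories(list(tr, tr), zm, group = "wt")
  expect_equal(nrow(prof), 2)
  ppath <- withr::local_tempfile(fileext = ".tsv")
  write_profiles(prof, ppath)
  expect_equal(nrow(utils::read.delim(ppath)), 2)
})
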