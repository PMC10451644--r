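# Synthetic deployment generator: determinism, schedule arithmetic, noise
# calibration, movement-model limiting cases, ground-truth recovery.

test_that("fixed seed gives identical output; different seeds differ", {
  a <- simulate_study(tiny_scenario(rng_seed = 601))
  b <- simulate_study(tiny_scenario(rng_seed = 601))
  expect_identical(a, b)
  c <- simulate_study(tiny_scenario(rng_seed = 602))
  expect_identical(names(c), names(a))
  expect_identical(names(c$fixes), names(a$fixes))
  expect_false(identical(a$fixes$lat, c$fixes$lat))
})

test_that("schedule arithmetic: tracker counts, days, fixes per day", {
  sc <- sim_scenario(days = 2, rng_seed = 603, fix_dropout_prob = 0)
  sim <- simulate_study(sc)
  expect_equal(nrow(sim$manifest), 17)
  expect_equal(sort(as.integer(table(sim$manifest$placement))), c(5L, 6L, 6L))
  per_day <- table(sim$fixes$tracker_id,
                   format(sim$fixes$timestamp, "%Y-%m-%d", tz = "UTC"))
  expect_true(all(per_day[per_day > 0] == 96))
  expect_equal(nrow(sim$truth), 17 * 2)
  # static truth is zero path; animal phase is a different calendar window
  expect_true(all(sim$truth$true_path_m[grepl("^[IO]", sim$truth$tracker_id)]
                  == 0))
  expect_true(min(sim$truth$date[grepl("^A", sim$truth$tracker_id)]) >
                max(sim$truth$date[grepl("^[IO]", sim$truth$tracker_id)]))
})

test_that("dropout thins fixes binomially", {
  sc <- sim_scenario(days = 2, n_animal = 0, n_indoor = 0, n_outdoor = 6,
                     fix_dropout_prob = 0.5, rng_seed = 604)
  sim <- simulate_study(sc)
  n <- nrow(sim$fixes)
  expected <- 6 * 2 * 96 * 0.5
  expect_lt(abs(n - expected), 4 * sqrt(expected * 0.5))
})

test_that("static noise calibration: ~95% of fixes inside the R95 radius", {
  sc <- sim_scenario(days = 11, outlier_prob = 0, fix_dropout_prob = 0,
                     rng_seed = 605)
  set.seed(sc$rng_seed)
  st <- simulate_static(sc, "Outdoor", offset_m = c(0, 0))
  p <- project_to_utm(st$fixes, "13N")
  org <- latlon_to_utm(sc$site_lat, sc$site_lon, "13N")
  r <- sqrt((p$easting - org$easting)^2 + (p$northing - org$northing)^2)
  expect_gt(length(r), 1000)
  expect_lt(abs(mean(r <= 15) - 0.95), 0.02)
})

test_that("sigma -> 0 limit: RawDist is 0 on every static day", {
  sc <- sim_scenario(days = 2, n_animal = 0, n_indoor = 0, n_outdoor = 1,
                     r95_outdoor_m = 0, outlier_prob = 0, rng_seed = 606)
  sim <- simulate_study(sc)
  daily <- compute_all(sim$fixes, sim$motion, sim$manifest, pipeline_config())
  expect_true(all(daily$distance_m == 0))
})

test_that("always-rest animal degenerates to a static tracker with MI = 0", {
  sc <- sim_scenario(days = 2, p_rest_to_active = 0, outlier_prob = 0,
                     rng_seed = 607)
  set.seed(sc$rng_seed)
  an <- simulate_animal(sc)
  expect_true(all(an$motion$motion_index == 0))
  expect_true(all(an$truth$true_path_m == 0))
  p <- project_to_utm(an$fixes, "13N")
  expect_lt(diff(range(p$easting)), 100)  # position noise only
})

test_that("noiseless straight-line walker: exact path and chord recovery", {
  # always active, constant 2 m/min step, fixed heading, no noise:
  # true path = 1440 * 2 = 2880 m/day; the within-day chord sum spans
  # fix minutes 0..1425, i.e. 2850 m — the 30 m gap is the cross-midnight
  # step, which the within-day summation deliberately discards
  sc <- sim_scenario(days = 3, n_indoor = 0, n_outdoor = 0, n_animal = 1,
                     p_rest_to_active = 1, p_active_to_rest = 0,
                     step_mean_m_per_min = 2, step_shape = Inf,
                     turn_sd_rad = 0, r95_outdoor_m = 0, outlier_prob = 0,
                     fix_dropout_prob = 0, rng_seed = 608)
  sim <- simulate_study(sc)
  expect_equal(sim$truth$true_path_m, rep(2880, 3), tolerance = 1e-12)
  daily <- compute_all(sim$fixes, sim$motion, sim$manifest, pipeline_config())
  d <- daily$distance_m[daily$algorithm == "CorrectedDist_Act"]
  expect_equal(d, rep(2850, 3), tolerance = 1e-9)
  # no removals when always in motion and noiseless: all algorithms equal
  expect_equal(daily$distance_m[daily$algorithm == "RawDist"], d,
               tolerance = 1e-9)
})

test_that("default calibration walks a plausible daily path", {
  sc <- sim_scenario(days = 5, n_indoor = 0, n_outdoor = 0, n_animal = 3,
                     rng_seed = 609)
  sim <- simulate_study(sc)
  m <- mean(sim$truth$true_path_m)
  expect_gt(m, 2000); expect_lt(m, 3500)
})

test_that("heavy-tailed noise option produces wilder static days", {
  base <- sim_scenario(days = 2, n_animal = 0, n_indoor = 0, n_outdoor = 3,
                       outlier_prob = 0, rng_seed = 610)
  heavy <- sim_scenario(days = 2, n_animal = 0, n_indoor = 0, n_outdoor = 3,
                        outlier_prob = 0, noise_df = 3, rng_seed = 610)
  g <- simulate_study(base); t3 <- simulate_study(heavy)
  pg <- project_to_utm(g$fixes, "13N"); pt3 <- project_to_utm(t3$fixes, "13N")
  expect_gt(max(abs(pt3$easting - mean(pt3$easting))),
            max(abs(pg$easting - mean(pg$easting))))
})

test_that("simulate_study writes the file set the readers consume", {
  dir <- withr::local_tempdir()
  sim <- simulate_study(tiny_scenario(rng_seed = 611), out_dir = dir)
  expect_true(all(file.exists(sim$files)))
  fx <- read_fixes(sim$files[["fixes"]])
  expect_equal(nrow(fx), nrow(sim$fixes))
  expect_equal(fx$lat, sim$fixes$lat, tolerance = 1e-12)
  mf <- read_manifest(sim$files[["manifest"]])
  expect_identical(mf, sim$manifest)
  mo <- read_motion(sim$files[["motion"]])
  expect_identical(sum(mo$motion_index), sum(sim$motion$motion_index))
})
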