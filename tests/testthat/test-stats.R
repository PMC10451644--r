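# Placement comparison: LS means, pairwise tests, letters, contrasts.

make_daily <- function(placements, trackers_per, dates, mean_by_placement,
                       sd_tracker = 0, sd_noise = 1, algorithm = "CorrectedDist_Act",
                       seed = 1) {
  set.seed(seed)
  rows <- list()
  t_idx <- 0
  for (p in placements) {
    for (tr in seq_len(trackers_per)) {
      t_idx <- t_idx + 1
      eff <- rnorm(1, 0, sd_tracker)
      rows[[length(rows) + 1]] <- data.frame(
        tracker_id = sprintf("T%02d", t_idx), date = dates, placement = p,
        algorithm = algorithm,
        distance_m = mean_by_placement[[p]] + eff + rnorm(length(dates), 0,
                                                          sd_noise),
        n_fixes_total = 96L, n_fixes_used = 90L, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

dates7 <- as.Date("2020-12-25") + 0:6

test_that("LS means equal arithmetic group means on a balanced design", {
  d <- make_daily(c("Animal", "Indoor", "Outdoor"), 4, dates7,
                  c(Animal = 2500, Indoor = 100, Outdoor = 60),
                  sd_tracker = 50, sd_noise = 120, seed = 11)
  s <- suppressWarnings(fit_placement_model(d))  # tolerance-level conv msg
  gm <- c(tapply(d$distance_m, d$placement, mean))
  expect_equal(unname(s$table$ls_mean), unname(gm[s$table$placement]),
               tolerance = 1e-6)
  expect_true(all(s$table$se > 0))
  # contrast consistency: non-static minus mean of the static LS means
  ls <- setNames(s$table$ls_mean, s$table$placement)
  expect_equal(s$static_contrast$estimate,
               ls[["Animal"]] - mean(ls[c("Indoor", "Outdoor")]),
               tolerance = 1e-8)
})

test_that("ground-truth recovery: study-sized design separates placements", {
  # 6 animal trackers walking ~2500 m/day, 5 + 6 static trackers at 0 m
  d <- rbind(
    make_daily("Animal", 6, dates7, c(Animal = 2500), sd_tracker = 200,
               sd_noise = 300, seed = 21),
    make_daily("Indoor", 5, dates7 - 40, c(Indoor = 0), seed = 22,
               sd_noise = 0),
    make_daily("Outdoor", 6, dates7 - 40, c(Outdoor = 0), seed = 23,
               sd_noise = 0))
  s <- suppressWarnings(fit_placement_model(d))
  expect_lte(s$p_placement, 0.05)
  expect_lte(s$pairwise["Animal", "Indoor"], 0.05)
  expect_lte(s$pairwise["Animal", "Outdoor"], 0.05)
  expect_gt(s$pairwise["Indoor", "Outdoor"], 0.05)
  tab <- s$table
  expect_lte(tab$p_vs_zero[tab$placement == "Animal"], 0.05)
  expect_true(all(tab$p_vs_zero[tab$placement != "Animal"] > 0.05 |
                    is.na(tab$p_vs_zero[tab$placement != "Animal"])))
  expect_lte(s$static_contrast$p, 0.05)
  expect_equal(unname(tab$letter[tab$placement == "Animal"]), "a")
  expect_identical(unique(tab$letter[tab$placement != "Animal"]), "b")
})

test_that("all-zero distances: zero LS means, undefined-or-1 p-values", {
  d <- make_daily(c("Animal", "Indoor"), 3, dates7,
                  c(Animal = 0, Indoor = 0), sd_noise = 0, seed = 31)
  s <- suppressWarnings(fit_placement_model(d))
  expect_true(all(s$table$ls_mean == 0))
  expect_true(all(is.na(s$table$p_vs_zero) | s$table$p_vs_zero > 0.99))
  expect_true(is.na(s$p_placement) || s$p_placement > 0.99)
  expect_true(length(s$notes) > 0)
})

test_that("a placement duplicated from identical data shows p ~ 1", {
  ind <- make_daily("Indoor", 4, dates7, c(Indoor = 800), sd_tracker = 100,
                    sd_noise = 150, seed = 41)
  out <- ind
  out$placement <- "Outdoor"
  out$tracker_id <- sub("T0", "T9", out$tracker_id)
  s <- suppressWarnings(fit_placement_model(rbind(ind, out)))
  expect_gt(s$pairwise["Indoor", "Outdoor"], 0.9)
  expect_identical(unname(s$table$letter[1]), unname(s$table$letter[2]))
})

test_that("trackers reused across placements get two random terms", {
  # animal collars reuse static-phase trackers: tracker (11) != unit (17)
  d <- rbind(
    make_daily("Animal", 6, dates7, c(Animal = 2500), sd_tracker = 200,
               sd_noise = 300, seed = 51),
    make_daily("Indoor", 5, dates7 - 40, c(Indoor = 50), sd_noise = 30,
               seed = 52),
    make_daily("Outdoor", 6, dates7 - 40, c(Outdoor = 50), sd_noise = 30,
               seed = 53))
  # 11 physical trackers: O1..O6 (outdoor phase, reused on the animals),
  # I1..I5 (indoor); 17 tracker-placement units
  d$tracker_id[d$placement == "Animal"] <- rep(sprintf("O%d", 1:6), each = 7)
  d$tracker_id[d$placement == "Outdoor"] <- rep(sprintf("O%d", 1:6), each = 7)
  d$tracker_id[d$placement == "Indoor"] <- rep(sprintf("I%d", 1:5), each = 7)
  s <- suppressWarnings(fit_placement_model(d))
  expect_false(any(grepl("aliased", s$notes)))
  expect_true(is.finite(s$ddf) && s$ddf > 0)
})

test_that("fit errors fall back to fixed-effects ANOVA with a warning", {
  # two placements, one tracker-day each is unfittable as a mixed model
  d <- make_daily(c("Animal", "Indoor"), 2, dates7[1:2],
                  c(Animal = 100, Indoor = 2), sd_noise = 1, seed = 61)
  d2 <- d[c(1, 3, 5, 7), ]  # one day per tracker: units == observations
  expect_warning(s <- fit_placement_model(d2), "falling back")
  expect_identical(s$method, "lm_fallback")
})

test_that("letter display matches the classical patterns", {
  pm <- function(v) {
    m <- matrix(1, 3, 3, dimnames = list(c("Animal", "Indoor", "Outdoor"),
                                         c("Animal", "Indoor", "Outdoor")))
    m["Animal", "Indoor"] <- m["Indoor", "Animal"] <- v[1]
    m["Animal", "Outdoor"] <- m["Outdoor", "Animal"] <- v[2]
    m["Indoor", "Outdoor"] <- m["Outdoor", "Indoor"] <- v[3]
    m
  }
  means <- c(Animal = 2500, Indoor = 100, Outdoor = 150)
  # all different
  expect_identical(unname(letter_grouping(pm(c(0.01, 0.01, 0.01)), 0.05,
                                          means)),
                   c("a", "c", "b"))
  # none different
  expect_identical(unname(letter_grouping(pm(c(0.5, 0.5, 0.5)), 0.05, means)),
                   c("a", "a", "a"))
  # animal apart, statics together: the a / b / b pattern
  expect_identical(letter_grouping(pm(c(0.001, 0.001, 0.62)), 0.05, means),
                   c(Animal = "a", Indoor = "b", Outdoor = "b"))
  # overlap chain needs a shared letter
  m <- pm(c(0.01, 0.2, 0.3))
  lg <- letter_grouping(m, 0.05, means)
  expect_true(lg[["Animal"]] != lg[["Indoor"]])
  expect_true(grepl(substr(lg[["Outdoor"]], 1, 1), paste0(lg, collapse = "")))
})

test_that("single-algorithm contract is enforced", {
  d <- make_daily("Animal", 2, dates7, c(Animal = 10), seed = 71)
  d2 <- d; d2$algorithm <- "RawDist"
  expect_error(fit_placement_model(rbind(d, d2)), "single algorithm")
})
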