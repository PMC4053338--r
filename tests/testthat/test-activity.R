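test_that("carcass use summary counts visited and fed correctly", {
  fx <- packaged_fixture()
  use <- carcass_use_summary(fx$events, fx$sites)
  dog <- use[use$species == "wild_dog", ]
  fox <- use[use$species == "fox", ]
  cat_ <- use[use$species == "feral_cat", ]
  expect_equal(dog$n_visited, 26)
  expect_equal(dog$n_fed, 21)
  expect_equal(fox$n_visited, 29)
  expect_equal(fox$n_fed, 18)
  expect_equal(cat_$n_visited, 13)
  expect_equal(cat_$n_fed, 3)
  ## fed is a subset of visited for every species
  expect_true(all(use$n_fed <= use$n_visited))

  empty <- fx$events[0, ]
  use0 <- carcass_use_summary(empty, fx$sites)
  expect_true(all(use0$n_visited == 0) && all(use0$pct_fed == 0))
})

test_that("activity clock apportions minutes pro-rata and conserves totals", {
  ## single 30-min event inside one bin
  ev <- make_event(start = "2012-09-03 18:10:00", duration = 1800)
  ck <- activity_clock(ev, "wild_dog", bin_minutes = 60, monitored_days = 1)
  expect_equal(sum(ck$minutes_per_day), 30)
  ## bin starting at 18:00 = 6 h after the midday anchor
  expect_equal(ck$minutes_per_day[ck$bin_start_min == 360], 30)

  ## event straddling a boundary: 10 min before, 20 after
  ev2 <- make_event(start = "2012-09-03 18:50:00", duration = 1800)
  ck2 <- activity_clock(ev2, "wild_dog", bin_minutes = 60,
                        monitored_days = 1)
  expect_equal(ck2$minutes_per_day[ck2$bin_start_min == 360], 10)
  expect_equal(ck2$minutes_per_day[ck2$bin_start_min == 420], 20)

  ## conservation across many random events (1e-9 min tolerance),
  ## including events wrapping past midnight
  set.seed(12)
  evs <- do.call(rbind, lapply(1:50, function(i)
    make_event(start = sprintf("2012-09-%02d %02d:%02d:00",
                               3 + i %% 5, sample(0:23, 1), sample(0:59, 1)),
               duration = runif(1, 60, 3 * 3600))))
  ck3 <- activity_clock(evs, "wild_dog", bin_minutes = 30,
                        monitored_days = 7)
  expect_equal(sum(ck3$minutes_per_day) * 7, sum(evs$duration) / 60,
               tolerance = 1e-9)
  expect_true(all(ck3$minutes_per_day >= 0))
  expect_equal(nrow(ck3), 48)
})

test_that("bout statistics summarise durations and visit shares", {
  evs <- rbind(
    make_event(start = "2012-09-03 18:00:00", duration = 600),
    make_event(start = "2012-09-04 18:00:00", duration = 600),
    make_event(start = "2012-09-05 18:00:00", duration = 600))
  bs <- bout_stats(evs, "wild_dog")
  expect_equal(bs$mean_min, 10)
  expect_equal(bs$sd_min, 0)
  expect_equal(bs$share_of_visits, 1)

  ## empty selection: explicit empty result, not an error
  bs0 <- bout_stats(evs, "fox")
  expect_equal(bs0$n_bouts, 0L)
  expect_true(is.na(bs0$mean_min))

  ## mixed behaviours: share counts visits containing feeding
  evs2 <- rbind(evs,
                make_event(start = "2012-09-06 18:00:00", duration = 300,
                           behaviour = "investigating"))
  bs2 <- bout_stats(evs2, "wild_dog")
  expect_equal(bs2$share_of_visits, 0.75)

  ## log-normal simulator truth recovered within Monte-Carlo error
  truth <- default_sim_truth()
  sites <- generate_design(30, seed = 31)
  ser <- simulate_daily_presence(truth, sites, flat_biomass(sites, 60),
                                 seed = 32)
  ev <- simulate_events(ser, truth, seed = 33)
  bs3 <- bout_stats(ev, "wild_dog", merge_gap = 0)
  ## durations truncated at midnight, so compare against the same-seed
  ## lognormal moments loosely
  expect_lt(abs(bs3$mean_min - 26.1) / 26.1, 0.25)
  expect_lt(abs(bs3$share_of_visits - 0.576), 0.08)
})

test_that("BCa bootstrap interval behaves like its percentile oracle", {
  ## degenerate sample: zero-width interval
  d <- bca_bootstrap_ci(rep(5, 10))
  expect_equal(c(d$estimate, d$lo, d$hi), c(5, 5, 5))

  ## large symmetric sample: BCa ~ percentile within 2% of interval width
  set.seed(51)
  x <- rnorm(600)
  b <- bca_bootstrap_ci(x, n_boot = 4000, seed = 52)
  set.seed(52)
  perc <- quantile(replicate(4000, mean(sample(x, replace = TRUE))),
                   c(0.025, 0.975))
  width <- perc[[2]] - perc[[1]]
  expect_lt(abs(b$lo - perc[[1]]), 0.04 * width)
  expect_lt(abs(b$hi - perc[[2]]), 0.04 * width)

  ## skewed sample: BCa shifts toward the long (right) tail
  set.seed(53)
  sk <- rexp(40)^2
  bca <- bca_bootstrap_ci(sk, n_boot = 4000, seed = 54)
  set.seed(54)
  perc2 <- quantile(replicate(4000, mean(sample(sk, replace = TRUE))),
                    c(0.025, 0.975))
  expect_gt(bca$hi, perc2[[2]])

  ## contains the point estimate; reproducible under the seed
  y <- rnorm(30)
  b1 <- bca_bootstrap_ci(y, seed = 9)
  b2 <- bca_bootstrap_ci(y, seed = 9)
  expect_identical(b1, b2)
  expect_true(b1$lo <= b1$estimate && b1$estimate <= b1$hi)
})

test_that("interspecific intervals report departure-to-arrival gaps", {
  fx <- packaged_fixture()
  ii <- interspecies_intervals(fx$events)
  ## the fixture's closest interaction: fox out 02:02, dogs in 02:12
  top <- ii[1, ]
  expect_equal(top$from_species, "fox")
  expect_equal(top$to_species, "wild_dog")
  expect_equal(top$gap_min, 10)
  expect_false(top$co_presence)

  ## overlapping events flag co-presence
  ov <- rbind(
    make_event(start = "2012-09-03 18:00:00", duration = 3600),
    make_event(species = "fox", start = "2012-09-03 18:30:00",
               duration = 600))
  io <- interspecies_intervals(ov)
  expect_true(any(io$co_presence))
  expect_lte(min(io$gap_min), 0)

  ## single-species table: empty result
  expect_equal(nrow(interspecies_intervals(make_event())), 0)
})
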