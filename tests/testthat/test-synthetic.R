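test_that("design generator reproduces the study layout deterministically", {
  sites <- generate_design()
  expect_equal(nrow(sites), 30)
  expect_equal(length(unique(sites$transect_id)), 6)
  expect_equal(unname(table(sites$transect_id)), rep(5L, 6),
               ignore_attr = TRUE)
  expect_true(all(sort(unique(sites$distance_to_farm)) ==
                    c(0.05, 1, 2, 3, 4)))
  expect_setequal(unique(sites$season), c("winter", "spring"))
  expect_equal(nrow(generate_design(1)), 5)
  expect_identical(generate_design(seed = 7), generate_design(seed = 7))
  expect_no_error(validate_sites(sites))
})

test_that("first-visit simulation follows its closed forms", {
  truth <- default_sim_truth()
  sites <- generate_design(2, seed = 1)

  ## vanishing hazard: everything censored
  t0 <- truth
  t0$weibull$wild_dog[c("alpha_spring", "alpha_winter")] <- list(-30, -30)
  t0$weibull$wild_dog$beta <- 0
  t0$weibull$wild_dog$sigma2_transect <- 0
  fv <- simulate_first_visits(t0, sites, horizon_days = 50, seed = 2)
  expect_true(all(fv$censored))

  ## k = 1, constant rate lambda: mean day ~ 1/lambda + 1/2 (discretised)
  lam <- 0.2
  t1 <- t0
  t1$weibull$wild_dog$k <- 1
  t1$weibull$wild_dog[c("alpha_spring", "alpha_winter")] <-
    list(log(lam), log(lam))
  big <- do.call(rbind, replicate(400, sites, simplify = FALSE))
  big$transect_id <- rep(seq_len(400 * 2), each = 5)
  fv <- simulate_first_visits(t1, big, horizon_days = 500, seed = 3)
  expect_lt(abs(mean(fv$day[!fv$censored]) - (1 / lam + 0.5)), 0.35)

  ## beta > 0: visits earlier far from the farm (sign check by simulation)
  t2 <- truth
  t2$weibull$wild_dog$sigma2_transect <- 0
  near <- far <- generate_design(300, seasons = rep("spring", 300), seed = 4)
  near <- near[near$distance_to_farm == 0.05, ]
  far <- far[far$distance_to_farm == 4, ]
  fn <- simulate_first_visits(t2, near, horizon_days = 400, seed = 5)
  ff <- simulate_first_visits(t2, far, horizon_days = 400, seed = 5)
  expect_gt(mean(fn$day), mean(ff$day))
})

test_that("coupled presence chains honour their generating probabilities", {
  truth <- default_sim_truth()
  for (sp in c("wild_dog", "fox")) {
    truth$markov[[sp]]$sigma2_transect <- 0
    truth$markov[[sp]]$sigma2_carcass <- 0
  }

  ## intercept -20 proxy for -Inf: all-absent chains
  t0 <- truth
  for (sp in c("wild_dog", "fox"))
    for (pv in c("absent", "present"))
      for (se in c("spring", "winter"))
        t0$markov[[sp]]$coef[[pv]][[se]][1] <- -20
  sites <- generate_design(2, seed = 1)
  ser <- simulate_daily_presence(t0, sites, flat_biomass(sites, 30), seed = 2)
  expect_true(all(vapply(ser, function(s)
    all(s$dog_present == 0) && all(s$fox_present == 0), TRUE)))

  ## zero coefficients: long-run occupancy ~ 0.5
  t1 <- truth
  for (sp in c("wild_dog", "fox")) {
    for (pv in c("absent", "present"))
      for (se in c("spring", "winter"))
        t1$markov[[sp]]$coef[[pv]][[se]] <- rep(0, 5)
    t1$markov[[sp]]$cross <- list(absent = 0, present = 0)
  }
  ser <- simulate_daily_presence(t1, sites, flat_biomass(sites, 400),
                                 seed = 3)
  occ <- mean(vapply(ser, function(s) mean(s$dog_present), 0))
  expect_lt(abs(occ - 0.5), 0.05)

  ## empirical transition frequencies match generating probabilities
  ## within 3 Monte-Carlo standard errors (direct-counting oracle), and a
  ## positive dog->fox cross coefficient raises fox presence after dog days
  sites2 <- generate_design(30, seasons = rep("spring", 30), seed = 4)
  sites2 <- sites2[sites2$distance_to_farm == 2, ]
  ser <- simulate_daily_presence(truth, sites2, flat_biomass(sites2, 400),
                                 seed = 5)
  fr <- do.call(rbind, lapply(ser, function(s) {
    n <- nrow(s)
    data.frame(y = s$fox_present[-1], fp = s$fox_present[-n],
               dp = s$dog_present[-n])
  }))
  p <- truth$markov$fox
  for (fp in 0:1) for (dp in 0:1) {
    sub <- fr[fr$fp == fp & fr$dp == dp, ]
    if (nrow(sub) < 30) next
    prev_lab <- c("absent", "present")[fp + 1]
    cf <- p$coef[[prev_lab]]$spring
    expect_p <- plogis(cf[1] + p$cross[[prev_lab]] * dp)
    se <- sqrt(expect_p * (1 - expect_p) / nrow(sub))
    expect_lt(abs(mean(sub$y) - expect_p), 3 * se + 1e-6)
  }
  emp0 <- with(fr[fr$fp == 0, ], tapply(y, dp, mean))
  expect_gt(emp0[["1"]], emp0[["0"]])   # cross_absent = 0.869 > 0
})

test_that("biomass simulation decays by season with AR(1) noise", {
  truth <- default_sim_truth()
  site_w <- make_site("W1", 1L, 2, "winter", as.Date("2012-05-15"))
  site_s <- make_site("S1", 2L, 2, "spring", as.Date("2012-09-01"))

  ## zero noise, zero feeding: deterministic season curve
  t0 <- truth
  t0$biomass$sigma <- 0
  iw <- simulate_biomass(t0, site_w, seed = 1)
  is <- simulate_biomass(t0, site_s, seed = 1)
  iw2 <- simulate_biomass(t0, site_w, seed = 99)
  expect_equal(iw$front_half, iw2$front_half)  # no noise => seed-invariant
  ## winter stays above spring at matched days
  shared <- intersect(as.numeric(iw$date - site_w$deploy_date),
                      as.numeric(is$date - site_s$deploy_date))
  shared <- setdiff(shared, 0)
  bw <- iw$front_half[match(shared, as.numeric(iw$date - site_w$deploy_date))]
  bs <- is$front_half[match(shared, as.numeric(is$date - site_s$deploy_date))]
  expect_true(all(bw >= bs))
  ## spring exhausted (<= 10%) by ~11 weeks, winter later (> 14 weeks)
  expect_lte(max(as.numeric(is$date - site_s$deploy_date)), 84)
  expect_gte(max(as.numeric(iw$date - site_w$deploy_date)), 98)

  ## values on the 5% grid
  expect_true(all(abs(iw$front_half * 20 - round(iw$front_half * 20)) < 1e-9))

  ## AR(1): lag-1 autocorrelation of logit-scale values ~ rho (flat mean,
  ## noise sd large enough that the 5% recording grid is negligible)
  t1 <- truth
  t1$biomass$rho <- 0.5
  t1$biomass$slope_spring <- 0
  t1$biomass$logit_full <- 0
  t1$biomass$sigma <- 1.2
  set.seed(6)
  acs <- vapply(1:300, function(r) {
    ins <- simulate_biomass(t1, site_s, seed = 5000 + r, max_days = 364)
    v <- logit_clamped(ins$front_half[-1])   # drop the forced intact row
    if (length(v) < 8) return(NA_real_)
    suppressWarnings(cor(v[-1], v[-length(v)]))
  }, 0)
  expect_lt(abs(mean(acs, na.rm = TRUE) - 0.5), 0.12)
})

test_that("event simulation is consistent with presence and diel truth", {
  truth <- default_sim_truth()
  sites <- generate_design(4, seed = 1)
  ser <- simulate_daily_presence(truth, sites, flat_biomass(sites, 60),
                                 seed = 2)
  ev <- simulate_events(ser, truth, seed = 3)
  expect_no_error(validate_events(ev))

  ## event days equal presence days exactly
  for (s in ser) {
    mine <- ev[ev$carcass_id == s$carcass_id[1] & ev$species == "wild_dog", ]
    ev_days <- sort(unique(as.Date(mine$start_time, tz = "UTC")))
    pres_days <- s$date[s$dog_present == 1]
    expect_equal(ev_days, sort(pres_days))
  }

  ## empty presence: no events
  empty <- lapply(ser, function(s) {
    s$dog_present <- 0L; s$fox_present <- 0L; s
  })
  expect_equal(nrow(simulate_events(empty, truth, seed = 4)), 0)

  ## >= 50% of dog activity minutes during 1600-2200
  sites2 <- generate_design(40, seed = 5)
  ser2 <- simulate_daily_presence(truth, sites2, flat_biomass(sites2, 60),
                                  seed = 6)
  ev2 <- simulate_events(ser2, truth, seed = 7)
  dog <- ev2[ev2$species == "wild_dog", ]
  hrs <- as.POSIXlt(dog$start_time, tz = "UTC")$hour
  frac <- sum(dog$duration[hrs >= 16 & hrs < 22]) / sum(dog$duration)
  expect_gte(frac, 0.5)

  ## determinism / seed sensitivity
  expect_identical(simulate_events(ser, truth, seed = 3), ev)
  expect_false(identical(simulate_events(ser, truth, seed = 4), ev))
})

test_that("whole-study simulation is deterministic and validator-clean", {
  st1 <- simulate_study(n_transects = 2, horizon_days = 40, seed = 11)
  st2 <- simulate_study(n_transects = 2, horizon_days = 40, seed = 11)
  expect_identical(st1$events, st2$events)
  expect_no_error(validate_sites(st1$sites))
  expect_no_error(validate_events(st1$events))
  expect_no_error(validate_inspections(st1$inspections))
  st3 <- simulate_study(n_transects = 2, horizon_days = 40, seed = 12)
  expect_false(identical(st1$events, st3$events))
})
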