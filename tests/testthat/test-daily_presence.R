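mk_params <- function(int = 0, dist = 0, dist2 = 0, bio = 0, bio2 = 0,
                      cross_a = 0, cross_p = 0) {
  cf <- c(int, dist, dist2, bio, bio2)
  list(coef = list(absent = list(spring = cf, winter = cf),
                   present = list(spring = cf, winter = cf)),
       cross = list(absent = cross_a, present = cross_p))
}

test_that("transition probabilities follow the logit model", {
  ## all parameters zero: probability one half
  expect_equal(transition_prob(0, "spring", 2, 0.5, 0, mk_params()), 0.5)

  ## an intercept of -2.231 at the covariate centres
  p <- mk_params(int = -2.231)
  expect_equal(transition_prob(0, "spring", 2, 0.5, 0, p),
               plogis(-2.231), tolerance = 1e-12)
  expect_equal(plogis(-2.231), 0.097, tolerance = 0.005)

  ## increasing the cross coefficient strictly raises the probability when
  ## the other species was present
  ps <- lapply(c(0, 0.5, 1.4), function(cc) mk_params(cross_a = cc))
  pr <- vapply(ps, function(p)
    transition_prob(0, "spring", 2, 0.5, 1, p), 0)
  expect_true(all(diff(pr) > 0))
  ## ...but not when it was absent
  pr0 <- vapply(ps, function(p)
    transition_prob(0, "spring", 2, 0.5, 0, p), 0)
  expect_equal(diff(pr0), c(0, 0))

  ## rows are proper distributions by construction
  p2 <- mk_params(int = -1, dist = 0.3, bio = -0.5)
  pres <- transition_prob(1, "winter", 3, 0.8, 1, p2)
  expect_true(pres >= 0 && pres <= 1)
  expect_error(transition_prob(0, "spring", 2, 1.3, 0, p2), "biomass")
})

test_that("odds multipliers exponentiate the lag coefficients", {
  p <- mk_params(cross_a = 0.869, cross_p = 1.361)
  expect_equal(odds_multiplier(p, "absent"), exp(0.869))
  expect_equal(round(odds_multiplier(p, "absent"), 1), 2.4)
  expect_equal(odds_multiplier(p, "present"), exp(1.361))
  expect_equal(round(odds_multiplier(p, "present")), 4)
  expect_equal(odds_multiplier(mk_params(), "absent"), 1)
})

test_that("chain log-likelihood equals the product-of-transitions oracle", {
  site <- make_site(days = 6)
  truth <- default_sim_truth()
  p <- truth$markov$wild_dog
  p$transect_effects <- 0.2
  p$carcass_effects <- -0.1
  series <- data.frame(carcass_id = "C01", day_index = 1:6,
                       date = site$deploy_date + 0:5,
                       dog_present = c(0L, 1L, 1L, 0L, 0L, 1L),
                       fox_present = c(0L, 0L, 1L, 0L, 1L, 0L),
                       biomass = c(1, 0.9, 0.8, 0.7, 0.6, 0.5))
  ll <- chain_log_likelihood(list(series), p, site, "wild_dog")

  ## direct product of daily transition probabilities
  oracle <- 0
  prev_dog <- 0L; prev_fox <- 0L
  for (t in 1:6) {
    pp <- transition_prob(prev_dog, site$season, site$distance_to_farm,
                          series$biomass[t], prev_fox,
                          c(p, list(transect_effect = 0.2,
                                    carcass_effect = -0.1)))
    y <- series$dog_present[t]
    oracle <- oracle + log(ifelse(y == 1, pp, 1 - pp))
    prev_dog <- y; prev_fox <- series$fox_present[t]
  }
  expect_equal(ll, oracle, tolerance = 1e-12)

  ## total probability over all 2^6 dog state sequences is 1
  total <- 0
  for (code in 0:63) {
    states <- as.integer(intToBits(code)[1:6])
    s2 <- series
    s2$dog_present <- states
    total <- total + exp(chain_log_likelihood(list(s2), p, site, "wild_dog"))
  }
  expect_equal(total, 1, tolerance = 1e-10)

  ## permutation invariance over carcasses
  site2 <- make_site("C02", 2L, 3, "winter", site$deploy_date, days = 6)
  s3 <- series
  s3$carcass_id <- "C02"
  sites <- rbind(site, site2)
  p$transect_effects <- c(0.2, -0.2)
  p$carcass_effects <- c(-0.1, 0.1)
  ll_ab <- chain_log_likelihood(list(series, s3), p, sites, "wild_dog")
  p_rev <- p
  p_rev$carcass_effects <- c(0.1, -0.1)
  ll_ba <- chain_log_likelihood(list(s3, series), p_rev, sites, "wild_dog")
  expect_equal(ll_ab, ll_ba, tolerance = 1e-12)

  ## gaps in the series are rejected
  s4 <- series[-3, ]
  expect_error(chain_log_likelihood(list(s4), p, site, "wild_dog"), "gap")
})

test_that("daily-presence fit is seed-reproducible and covers a null", {
  truth <- default_sim_truth()
  sites <- generate_design(6, seed = 71)
  ser <- simulate_daily_presence(truth, sites, flat_biomass(sites, 40),
                                 seed = 72)
  cfg <- small_mcmc(seed = 73, n_burnin = 300, n_keep = 300)
  f1 <- suppressWarnings(fit_daily_presence(ser, sites, "fox", config = cfg))
  f2 <- suppressWarnings(fit_daily_presence(ser, sites, "fox", config = cfg))
  expect_identical(f1$draws, f2$draws)

  ## zero-covariate truth: distance and biomass intervals contain 0
  t0 <- truth
  for (sp in c("wild_dog", "fox")) {
    for (pv in c("absent", "present"))
      for (se in c("spring", "winter"))
        t0$markov[[sp]]$coef[[pv]][[se]] <- c(-1.5, 0, 0, 0, 0)
    t0$markov[[sp]]$cross <- list(absent = 0, present = 0)
    t0$markov[[sp]]$sigma2_transect <- 0.1
    t0$markov[[sp]]$sigma2_carcass <- 0.1
  }
  sites2 <- generate_design(10, seed = 74)
  ser0 <- simulate_daily_presence(t0, sites2, flat_biomass(sites2, 60),
                                  seed = 75)
  f0 <- suppressWarnings(fit_daily_presence(
    ser0, sites2, "wild_dog",
    config = small_mcmc(seed = 76, n_burnin = 500, n_keep = 500)))
  m <- as.matrix(f0)
  for (nm in c("absent_spring_dist", "absent_winter_bio", "cross_absent")) {
    h <- hpd_interval(m[, nm])
    expect_true(h[1] <= 0 && 0 <= h[2])
  }
})

test_that("visit-probability curves reflect the quadratic distance shape", {
  ## synthetic point-mass posterior centred on a concave-down quadratic
  ## with vertex at 2 km
  par_names <- carrion:::markov_par_names(2, 2)
  draws <- array(0, c(40, 2, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  draws[, , "absent_spring_int"] <- -1
  draws[, , "absent_spring_dist"] <- 0      # centred => vertex at 2 km
  draws[, , "absent_spring_dist2"] <- -0.5
  fit <- structure(list(draws = draws, parameters = par_names,
                        scaling = covariate_scaling()),
                   class = c("daily_presence_fit", "posterior_fit"))
  cur <- visit_probability_curve(fit, "spring", prev_state = 0,
                                 grid = seq(0, 4, 0.5))
  expect_equal(cur$grid[which.max(cur$median)], 2)
  ## concave-down: interior maximum, symmetric about the vertex
  expect_equal(cur$median[cur$grid == 1], cur$median[cur$grid == 3],
               tolerance = 1e-12)
  ## point-mass posterior: curve equals transition_prob exactly
  p <- mk_params(int = -1, dist2 = -0.5)
  expect_equal(cur$median[cur$grid == 0.5],
               transition_prob(0, "spring", 0.5, 0.5, 0, p),
               tolerance = 1e-12)
})
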