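# Small in-code fixtures shared across test files.

make_site <- function(carcass_id = "C01", transect_id = 1L, distance = 2,
                      season = "spring", deploy = as.Date("2012-09-01"),
                      days = 28) {
  data.frame(carcass_id = carcass_id, transect_id = transect_id,
             distance_to_farm = distance, season = season,
             deploy_date = deploy, removal_date = deploy + days,
             censored = FALSE, stringsAsFactors = FALSE)
}

make_event <- function(carcass_id = "C01", species = "wild_dog",
                       start = "2012-09-03 18:00:00", duration = 600,
                       behaviour = "feeding", n_individuals = 1L) {
  data.frame(carcass_id = carcass_id, species = species,
             start_time = as.POSIXct(start, tz = "UTC"),
             duration = duration, behaviour = behaviour,
             n_individuals = n_individuals, stringsAsFactors = FALSE)
}

make_inspections <- function(carcass_id = "C01",
                             deploy = as.Date("2012-09-01"),
                             days = c(0, 14, 28),
                             biomass = c(1, 0.65, 0.2)) {
  data.frame(carcass_id = carcass_id, date = deploy + days,
             front_half = biomass, rear_half = biomass,
             stringsAsFactors = FALSE)
}

## flat-biomass trajectory list for presence simulations
flat_biomass <- function(sites, n_days, value = 0.5) {
  out <- lapply(seq_len(nrow(sites)), function(i) rep(value, n_days))
  names(out) <- sites$carcass_id
  out
}

small_mcmc <- function(seed = 1, n_burnin = 400, n_keep = 400)
  mcmc_config(n_chains = 3, n_burnin = n_burnin, n_keep = n_keep,
              thin = 1, seed = seed)

## Inspection tables simulated directly from the biomass model's own
## assumptions (logit-linear season trend, feeding effects, AR(1) errors,
## no 5% recording grid) so estimator recovery is judged against the model
## it fits.
gen_biomass_data <- function(sites, rho = 0.4, sigma = 0.9,
                             theta_dog = -0.5, theta_fox = -0.3,
                             seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    d <- seq(0, 98, by = 14)
    ## feeding arrives in bursts: per-interval minutes are zero-inflated
    ## and exponentially sized, so cumulative feeding is a lumpy step
    ## path, not a straight line in days (carcasses differ in both level
    ## and shape, which is what identifies the feeding coefficients
    ## alongside the day smooth)
    lump <- function() {
      feeds <- stats::runif(length(d) - 1) < 0.55
      c(0, cumsum(feeds * stats::rexp(length(d) - 1, 1 / 35)))
    }
    cum_d <- lump() * (stats::runif(1) < 0.75)
    cum_f <- lump() * (stats::runif(1) < 0.75)
    slope <- if (sites$season[i] == "winter") -9.097 / 105 else -9.097 / 77
    mu <- 6.9 + slope * d + theta_dog * cum_d / 100 +
      theta_fox * cum_f / 100
    e <- numeric(length(d))
    e[1] <- stats::rnorm(1, 0, sigma)
    for (j in 2:length(d))
      e[j] <- rho * e[j - 1] + stats::rnorm(1, 0, sigma * sqrt(1 - rho^2))
    data.frame(carcass_id = sites$carcass_id[i],
               transect_id = sites$transect_id[i],
               season = sites$season[i], day = d,
               biomass = stats::plogis(mu + e),
               cum_dog_min = cum_d, cum_fox_min = cum_f,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
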