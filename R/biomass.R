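## Biomass-decay model.  Logit edible biomass over days available, with a
## baseline thin-plate smooth of days plus a winter deviation smooth,
## z-scored cumulative dog and fox feeding-time covariates, a transect
## random intercept, and AR(1) errors within carcass across successive
## inspections.  Fitted by penalised likelihood via mgcv::gamm (nlme
## machinery underneath).

#' Clamped logit transform for proportions
#'
#' Proportions of exactly 0 or 1 are moved to 0.001 and 0.999 before the
#' logit so the transform stays finite; strictly increasing on the clamped
#' range and antisymmetric about 0.5.
#'
#' @param p proportion(s) in \[0,1\].
#' @return log(p'/(1-p')) with p' = clamp(p, 0.001, 0.999).
#' @export
logit_clamped <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p must lie in [0,1]", call. = FALSE)
  pc <- pmin(0.999, pmax(0.001, p))
  log(pc / (1 - pc))
}

#' Low-rank thin-plate smooth basis with penalty
#'
#' Exposes the smooth construction the biomass model uses: a thin-plate
#' regression spline basis over days with its quadratic roughness penalty,
#' reproducible for a given set of evaluation points.
#'
#' @param days numeric vector of evaluation points (>= 0).
#' @param knots basis dimension (>= 4).
#' @param penalty_order order of the roughness penalty (default 2).
#' @return list with `X` (basis matrix) and `S` (penalty matrix).
#' @export
spline_basis <- function(days, knots = 8, penalty_order = 2) {
  stopifnot(knots >= 4, all(days >= 0))
  sm <- mgcv::smoothCon(mgcv::s(day, bs = "tp", k = knots,
                                m = penalty_order),
                        data = data.frame(day = days))[[1]]
  list(X = sm$X, S = sm$S[[1]])
}

#' Model frame for the biomass model
#'
#' One row per inspection: days available since deployment, mean-of-halves
#' biomass, season, and cumulative feeding minutes by dogs and foxes up to
#' the inspection date.
#'
#' @param inspections validated inspections table.
#' @param events validated events table.
#' @param sites validated sites table.
#' @return data frame with `carcass_id`, `transect_id`, `season`, `day`,
#'   `biomass`, `cum_dog_min`, `cum_fox_min`, `inspection_index`.
#' @export
biomass_model_frame <- function(inspections, events, sites) {
  validate_inspections(inspections)
  validate_events(events)
  validate_sites(sites)
  rows <- lapply(seq_len(nrow(inspections)), function(i) {
    ins <- inspections[i, ]
    site <- sites[sites$carcass_id == ins$carcass_id, ]
    cut <- as.POSIXct(paste(ins$date, "00:00:00"), tz = "UTC")
    feed <- function(sp) {
      ev <- events[events$carcass_id == ins$carcass_id &
                     events$species == sp &
                     events$behaviour == "feeding" &
                     events$start_time < cut, , drop = FALSE]
      sum(ev$duration) / 60
    }
    data.frame(carcass_id = ins$carcass_id,
               transect_id = site$transect_id,
               season = site$season,
               day = as.numeric(ins$date - site$deploy_date),
               biomass = mean_halves(ins$front_half, ins$rear_half),
               cum_dog_min = feed("wild_dog"),
               cum_fox_min = feed("fox"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$carcass_id, out$day), ]
  out$inspection_index <- stats::ave(out$day, out$carcass_id,
                                     FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Fit the biomass-decay mixed model
#'
#' logit(biomass) ~ s(day) + s(day, by = winter) + z(dog feeding minutes)
#' + z(fox feeding minutes), with a transect random intercept and AR(1)
#' correlation across successive inspections within carcass.  Feeding
#' covariates are z-scored internally; returned coefficients are per SD of
#' cumulative feeding minutes.
#'
#' @param data model frame from [biomass_model_frame()] (or equivalent
#'   columns).
#' @param knots basis dimension per smooth (default 8, suited to ~6
#'   inspections per carcass).
#' @param use_ar1 include the AR(1) within-carcass correlation.
#' @return object of class `biomass_fit`: the mgcv/nlme fit plus extracted
#'   `theta_dog`, `theta_fox` (with standard errors), `rho`,
#'   `sigma2_transect`, `sigma2_residual`, `fitted`, `observed_logit`,
#'   `r_squared`, and the feeding-covariate scaling.
#' @export
fit_biomass <- function(data, knots = 8, use_ar1 = TRUE) {
  stopifnot(all(c("carcass_id", "transect_id", "season", "day", "biomass",
                  "cum_dog_min", "cum_fox_min") %in% names(data)))
  if (any(table(data$carcass_id) < 2))
    stop("need >= 2 inspections per carcass", call. = FALSE)
  df <- data
  df$y <- logit_clamped(df$biomass)
  df$winter01 <- as.numeric(df$season == "winter")
  dog_mu <- mean(df$cum_dog_min); dog_sd <- stats::sd(df$cum_dog_min)
  fox_mu <- mean(df$cum_fox_min); fox_sd <- stats::sd(df$cum_fox_min)
  has_dog <- is.finite(dog_sd) && dog_sd > 0
  has_fox <- is.finite(fox_sd) && fox_sd > 0
  if (!has_dog) dog_sd <- 1
  if (!has_fox) fox_sd <- 1
  df$dog_z <- (df$cum_dog_min - dog_mu) / dog_sd
  df$fox_z <- (df$cum_fox_min - fox_mu) / fox_sd
  df$transect <- factor(df$transect_id)
  df$carcass <- factor(df$carcass_id)
  if (is.null(df$inspection_index))
    df$inspection_index <- stats::ave(df$day, df$carcass_id, FUN = seq_along)

  knots <- min(knots, length(unique(df$day)))
  if (knots < 4) stop("need >= 4 distinct inspection days", call. = FALSE)
  rhs <- c(sprintf("s(day, k = %d)", knots),
           if (length(unique(df$winter01)) > 1)
             sprintf("s(day, by = winter01, k = %d)", knots),
           if (has_dog) "dog_z", if (has_fox) "fox_z")
  form <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
  ## the AR(1) profile surface is occasionally singular from a cold start;
  ## retry from a short ladder of starting correlations
  starts <- if (use_ar1) c(0.3, 0.1, 0.5) else NA
  fit <- NULL
  last_err <- "unknown"
  for (st in starts) {
    corr <- if (use_ar1)
      nlme::corAR1(st, form = ~ inspection_index | carcass) else NULL
    fit <- tryCatch(
      mgcv::gamm(form, random = list(transect = ~1), correlation = corr,
                 data = df, method = "REML"),
      error = function(e) { last_err <<- conditionMessage(e); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("biomass model failed to converge: ", last_err, call. = FALSE)

  co <- summary(fit$gam)$p.table
  pick <- function(nm, col) if (nm %in% rownames(co)) co[nm, col] else NA_real_
  vc <- nlme::VarCorr(fit$lme)
  ## transect variance: the "(Intercept)" row of the transect stratum
  vc_num <- suppressWarnings(as.numeric(vc[, "Variance"]))
  names(vc_num) <- rownames(vc)
  ix <- which(rownames(vc) == "(Intercept)")
  sigma2_transect <- if (length(ix)) vc_num[ix[length(ix)]] else NA_real_
  rho <- if (use_ar1)
    unname(stats::coef(fit$lme$modelStruct$corStruct,
                       unconstrained = FALSE)) else 0
  fitted_logit <- as.numeric(stats::predict(fit$gam))
  structure(list(
    gamm = fit,
    theta_dog = pick("dog_z", "Estimate"),
    theta_dog_se = pick("dog_z", "Std. Error"),
    theta_fox = pick("fox_z", "Estimate"),
    theta_fox_se = pick("fox_z", "Std. Error"),
    intercept = pick("(Intercept)", "Estimate"),
    rho = rho,
    sigma2_transect = sigma2_transect,
    sigma2_residual = fit$lme$sigma^2,
    fitted = fitted_logit,
    observed_logit = df$y,
    r_squared = stats::cor(df$y, fitted_logit)^2,
    scaling = list(dog_mu = dog_mu, dog_sd = dog_sd,
                   fox_mu = fox_mu, fox_sd = fox_sd),
    knots = knots, data = df), class = "biomass_fit")
}

#' @export
print.biomass_fit <- function(x, ...) {
  cat("biomass_fit: theta_dog =", format(x$theta_dog, digits = 3),
      "theta_fox =", format(x$theta_fox, digits = 3),
      "rho =", format(x$rho, digits = 3),
      "R^2 =", format(x$r_squared, digits = 3), "\n")
  invisible(x)
}

#' Variance explained on the logit scale
#'
#' Squared correlation between observed and fitted logit biomass; invariant
#' to affine rescaling of the fitted values.
#'
#' @param fit a `biomass_fit`.
#' @param observed,fitted optional replacement vectors (e.g. new data).
#' @return R^2 in \[0,1\].
#' @export
r_squared <- function(fit, observed = NULL, fitted = NULL) {
  obs <- observed %||% fit$observed_logit
  ftd <- fitted %||% fit$fitted
  stats::cor(obs, ftd)^2
}

#' Predicted biomass trajectory
#'
#' Inverse-logit of the fitted mean over a day grid for a given cumulative
#' feeding scenario.
#'
#' @param fit a `biomass_fit`.
#' @param season "spring" or "winter".
#' @param days day grid (default 0..max observed).
#' @param dog_minutes,fox_minutes cumulative feeding minutes at each grid
#'   day (scalars are recycled; default 0 = no feeding).
#' @return data frame `day`, `biomass` (proportions).
#' @export
predict_trajectory <- function(fit, season, days = NULL, dog_minutes = 0,
                               fox_minutes = 0) {
  if (is.null(days)) days <- seq(0, max(fit$data$day), by = 1)
  nd <- data.frame(
    day = days,
    winter01 = as.numeric(season == "winter"),
    dog_z = (rep_len(dog_minutes, length(days)) - fit$scaling$dog_mu) /
      fit$scaling$dog_sd,
    fox_z = (rep_len(fox_minutes, length(days)) - fit$scaling$fox_mu) /
      fit$scaling$fox_sd)
  eta <- as.numeric(stats::predict(fit$gamm$gam, newdata = nd))
  data.frame(day = days, biomass = stats::plogis(eta))
}
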