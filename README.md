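# carrion

Bayesian and mixed-model analyses of carnivore scavenging at camera-trapped
ungulate carcasses.

Hunter-shot deer carcasses are a large, unpredictable food subsidy for
carnivore guilds. Given a landscape design of carcasses along transects at
fixed distances from the farm–forest boundary, monitored continuously by
cameras and inspected fortnightly for remaining edible biomass, `carrion`
answers the three questions such a study poses, for ecologists working on
scavenging, interference competition and mesopredator dynamics:

1. **How long until a carcass is found?**  A discrete-time Weibull
   survival model with right-censoring:
   `S(t) = exp(−λ tᵏ)`, `log λ = α_season + β·Dtf + u_transect`,
   fitted by MCMC (`fit_first_visit()`).  β > 0 means carcasses further
   from farms are found sooner.
2. **What drives daily presence?**  A hierarchical two-state Markov model:
   `logit P(present today) = γ_{state,season} + b₁d + b₂d² + b₃x + b₄x² +
   c_state·(other species present yesterday) + u_transect + v_carcass`
   (`fit_daily_presence()`).  `exp(c)` is the odds multiplier that one
   species' visit yesterday applies to the other species' odds today —
   the statistic of interest for avoidance/attraction between a dominant
   predator and a mesopredator.
3. **How fast does edible biomass disappear?**  A penalised-spline mixed
   model of logit biomass over days available — baseline smooth plus a
   winter deviation smooth, cumulative dog/fox feeding minutes, transect
   random effect, AR(1) within carcass (`fit_biomass()`, via `mgcv`).

Around these sit a generic adaptive Metropolis-within-Gibbs engine with
Gelman–Rubin, DIC, HPD and posterior-predictive machinery (`mcmc_sample()`
and friends), descriptive summaries (carcass use, midday-anchored diel
activity clocks, feeding-bout statistics, BCa bootstrap intervals,
interspecific departure–arrival gaps), and a fully seeded synthetic-study
generator (`simulate_study()`) whose known ground truth makes every model
verifiable by parameter recovery.

## Worked example

The package ships a deterministic 30-carcass fixture whose per-carcass
outcomes are exact, plus numbered analysis drivers under `analysis/`
(`01_simulate.R` … `05_activity.R`) that run the full pipeline on a
simulated study and write tidy tables under `results/`. The descriptive
stage prints:

```
$ Rscript analysis/05_activity.R
Feeding percentages over 30 carcasses: wild_dog 70%, fox 60%, feral_cat 10%
Closest interspecific interval: fox to wild_dog - 10 minutes
```

Dogs fed at 70% of carcasses, foxes at 60%, cats at only 10% — cats are
effectively obligate predators here — and the nearest the two canids came
to meeting was a fox leaving ten minutes before wild dogs arrived. The
same tables give bout statistics and BCa intervals for per-carcass total
feeding time (`results/total_feeding_bca.csv`).

The model stages report the quantities an ecologist would quote, e.g.:

```r
library(carrion)
study <- simulate_study(seed = 1)                       # known truth
fvd   <- first_visit_data(study$events, study$sites, "wild_dog")
fit   <- fit_first_visit(fvd, config = mcmc_config(seed = 1))
first_visit_summary(fit, distance = 2, season = "spring")  # median days + HPD
odds_multiplier(default_sim_truth()$markov$fox, "absent")  # 2.38: dog-yesterday
                                                           # boosts fox odds
```

Under the default generating truth the cross-species odds multipliers are
2.38 (dog visit yesterday → fox odds, absent state) and 3.90 (fox visit
yesterday → dog odds, present state); spring carcasses are found sooner
than winter ones and lose edible biomass by week ~11 against ~15 in
winter. The methods vignette (`vignettes/scavenging-models.Rmd`) documents
every model, prior, tuning constant and design decision.

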