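#' Ground-truth parameter set for the synthetic study
#'
#' Bundles every parameter of the synthetic data generator. Three named
#' profiles are provided. `"paper-like"` emulates the magnitudes of the
#' field study: 9 breeding seasons, a few hundred adults, adult apparent
#' survival 0.58 (males) / 0.51 (females), juvenile survival 0.21 / 0.20,
#' fecundity 2.4 juveniles per female, Poisson immigration averaging 79
#' males and 40 females per year, nest searches finding 1/k of juveniles
#' (k = 2), and weak weather effects on the vital rates. `"null-weather"`
#' is identical but with every weather effect set to zero.
#' `"decline"` has depressed survival and immigration, a strong negative
#' effect of the lagged precipitation index on adult survival, and rising
#' projected precipitation, so the simulated population declines.
#'
#' Weather effects act on the logit scale for survival probabilities and
#' the log scale for fecundity and immigration, per standard deviation of
#' the (z-scored) annual weather metric, so rates always stay in range.
#'
#' @param profile one of `"paper-like"`, `"null-weather"`, `"decline"`.
#' @param ... named overrides of any truth field.
#' @return list of class `simulation_truth`.
#' @export
simulation_truth <- function(profile = c("paper-like", "null-weather",
                                         "decline"), ...) {
  profile <- match.arg(profile)
  truth <- list(
    profile = profile,
    years = 2013:2021,
    phi_a = c(male = 0.58, female = 0.51),
    phi_j = c(male = 0.21, female = 0.20),
    p_a = c(male = 0.60, female = 0.20),
    p_j = c(male = 0.25, female = 0.15),
    fecundity = 2.4,
    k_true = 2,
    immigration_mean = c(male = 79, female = 40),
    # near the demographic equilibrium of the rates above, so the
    # simulated population is roughly stationary like the study population
    initial_N = c(male = 280, female = 160),
    prob_juv_sexed = 0.06,       # fraction of juveniles molecularly sexed
    # weather -> rate coefficients per SD of each metric
    # (order: wetbulb_mean, n_storms, espi_lag2)
    effects = list(
      phi_a = c(wetbulb_mean = 0, n_storms = -0.05, espi_lag2 = -0.15),
      phi_j = c(wetbulb_mean = 0, n_storms = 0, espi_lag2 = 0),
      fecundity = c(wetbulb_mean = -0.10, n_storms = 0, espi_lag2 = 0),
      immigration = c(wetbulb_mean = 0, n_storms = 0, espi_lag2 = -0.20)
    ),
    weather = list(
      tmax_mean = 32, tmax_sd = 3.5,
      rh_mean = 75, rh_sd = 12,
      rain_prob = 0.33,
      rain_shape = 0.5, rain_scale = 30,
      sigma_year = 0.4,            # between-year log-scale precip SD
      espi_mean = 0.4, espi_sd = 1.1,
      espi_precip_cor = 0.5,       # target ESPI-precipitation correlation
      gcm_n = 18,
      gcm_precip_mean = 600, gcm_offset_sd = 50,
      gcm_sigma = 0.35, gcm_trend = 0
    ),
    max_expected_N = 20000
  )
  if (profile == "null-weather") {
    truth$effects <- lapply(truth$effects, function(e) e * 0)
  }
  if (profile == "decline") {
    truth$phi_a <- c(male = 0.45, female = 0.40)
    truth$immigration_mean <- c(male = 30, female = 15)
    truth$effects$phi_a <- c(wetbulb_mean = 0, n_storms = 0,
                             espi_lag2 = -0.35)
    truth$weather$gcm_trend = 3    # mm extra per projection year
  }
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(truth)) stop("unknown truth field: ", nm)
    truth[[nm]] <- over[[nm]]
  }
  structure(truth, class = "simulation_truth")
}

#' Simulate daily weather, monthly ESPI, and projected GCM precipitation
#'
#' Generates breeding-season daily weather for each requested year (daily
#' maxima of temperature and relative humidity around seasonal means;
#' zero-inflated gamma rainfall), monthly ESPI values whose May-August sum
#' is correlated with the year's total breeding-season precipitation at the
#' configured target (both are driven by a shared yearly wetness factor),
#' and per-GCM annual May-August precipitation totals for the projection
#' span.
#'
#' @param years integer vector of weather years (include two leading years
#'   if lag-2 covariates are needed for the first study year).
#' @param settings the `weather` element of a [simulation_truth()].
#' @param seed integer seed.
#' @param gcm_years years to cover with GCM precipitation (default
#'   2019-2098, feeding lag-2 projections for 2021-2100).
#' @return list with `daily`, `espi_monthly`, `gcm` data.frames and the
#'   latent `yearly` table (year, wetness z, precip total, seasonal ESPI).
#' @export
simulate_weather <- function(years, settings = simulation_truth()$weather,
                             seed = 1, gcm_years = 2019:2098) {
  if (length(years) < 4) stop("need at least 4 years for lag-2 structure")
  rho <- settings$espi_precip_cor
  if (abs(rho) >= 1) stop("espi_precip_cor must lie in (-1, 1)")
  with_seed(seed, {
    ny <- length(years)
    z_wet <- stats::rnorm(ny)                       # shared wetness factor
    espi_z <- rho * z_wet + sqrt(1 - rho^2) * stats::rnorm(ny)
    espi_season <- settings$espi_mean + settings$espi_sd * espi_z

    daily_list <- vector("list", ny)
    for (i in seq_len(ny)) {
      days <- breeding_season_days(years[i])
      nd <- length(days)
      tmax <- stats::rnorm(nd, settings$tmax_mean, settings$tmax_sd)
      rh <- pmin(100, pmax(20, stats::rnorm(nd, settings$rh_mean,
                                            settings$rh_sd)))
      wet <- stats::runif(nd) < settings$rain_prob
      amt <- numeric(nd)
      amt[wet] <- stats::rgamma(sum(wet), shape = settings$rain_shape,
                                scale = settings$rain_scale *
                                  exp(settings$sigma_year * z_wet[i]))
      daily_list[[i]] <- data.frame(
        date = days, tmax_c = round(tmax, 2), rhmax_pct = round(rh, 2),
        precip_mm = round(amt, 2))
    }
    daily <- do.call(rbind, daily_list)

    espi_monthly <- do.call(rbind, lapply(seq_len(ny), function(i) {
      eps <- stats::rnorm(4, 0, 0.1)
      eps <- eps - mean(eps)                  # months sum to the seasonal value
      data.frame(year = years[i], month = 5:8,
                 espi = espi_season[i] / 4 + eps)
    }))

    gcm_names <- sprintf("GCM%02d", seq_len(settings$gcm_n))
    offs <- stats::rnorm(settings$gcm_n, 0, settings$gcm_offset_sd)
    gcm <- do.call(rbind, lapply(seq_along(gcm_names), function(g) {
      trend <- settings$gcm_trend * (gcm_years - gcm_years[1])
      tot <- (settings$gcm_precip_mean + offs[g] + trend) *
        exp(stats::rnorm(length(gcm_years), 0, settings$gcm_sigma) -
              settings$gcm_sigma^2 / 2)
      data.frame(gcm = gcm_names[g], year = gcm_years,
                 precip_mm = round(pmax(tot, 0), 1))
    }))

    precip_total <- vapply(seq_len(ny), function(i)
      sum(daily_list[[i]]$precip_mm), numeric(1))
    list(daily = daily, espi_monthly = espi_monthly, gcm = gcm,
         yearly = data.frame(year = years, z_wet = z_wet,
                             precip_total = precip_total,
                             espi_season = espi_season))
  })
}

# Annual vital rates implied by the truth and the generated weather.
# Rates are labelled by their end year, as in the stage recurrence: the
# weather metrics of year t (including the 2-year-lagged ESPI) drive the
# apparent survival over t-1 -> t (the return-rate mechanism: conditions at
# t decide whether surviving birds come back), the immigrant arrivals at t,
# and the fecundity of season t. Columns are years 1..T; survival and
# immigration are undefined (NA) in column 1.
truth_annual_rates <- function(truth, wseries) {
  years <- truth$years
  T <- length(years)
  wy <- wseries[match(years, wseries$year), ]
  # a metric with no between-year variation carries no effect
  zsafe <- function(x) if (stats::sd(x) == 0) x * 0 else zscale(x)
  Z <- cbind(wetbulb_mean = zsafe(wy$wetbulb_mean),
             n_storms = zsafe(wy$n_storms),
             espi_lag2 = zsafe(wy$espi_lag2))
  lin <- function(base_link, eff) base_link + as.vector(Z %*% eff)
  inv_logit <- function(x) 1 / (1 + exp(-x))
  logit <- function(p) log(p / (1 - p))
  mask1 <- c(NA_real_, rep(1, T - 1))   # no transition ends in year 1
  phi_a <- rbind(
    male = inv_logit(lin(logit(truth$phi_a["male"]), truth$effects$phi_a)),
    female = inv_logit(lin(logit(truth$phi_a["female"]),
                           truth$effects$phi_a)))
  phi_j <- rbind(
    male = inv_logit(lin(logit(truth$phi_j["male"]), truth$effects$phi_j)),
    female = inv_logit(lin(logit(truth$phi_j["female"]),
                           truth$effects$phi_j)))
  phi_a <- sweep(phi_a, 2, mask1, `*`)
  phi_j <- sweep(phi_j, 2, mask1, `*`)
  fec <- exp(lin(log(truth$fecundity), truth$effects$fecundity))
  imm <- rbind(
    male = exp(lin(log(truth$immigration_mean["male"]),
                   truth$effects$immigration)),
    female = exp(lin(log(truth$immigration_mean["female"]),
                     truth$effects$immigration)))
  imm <- sweep(imm, 2, mask1, `*`)
  list(phi_a = phi_a, phi_j = phi_j, fecundity = fec, immigration = imm,
       years = years)
}

#' Simulate an individual-based study population
#'
#' Forward-simulates the two-sex demographic process that the IPM assumes:
#' adults survive each interval as Bernoulli trials with the year's
#' sex-specific adult rate, each female produces a Poisson number of
#' juveniles, juveniles survive their first year with the juvenile rate and
#' recruit as adults, and a Poisson number of immigrant adults arrives per
#' sex per year. Observation mirrors the field protocol: adults are
#' detected with sex- and age-specific probabilities; juveniles are found
#' (and banded) in their hatch year with probability `1/k_true`; juveniles
#' never found are still alive and can later enter the data as unbanded
#' "immigrant-like" adults. A juvenile's sex is recorded as unknown unless
#' molecularly sexed or recaptured in a later year.
#'
#' @param truth a [simulation_truth()].
#' @param weather output of [simulate_weather()] covering
#'   `min(truth$years) - 2` onwards (needed for lag-2 covariates).
#' @param seed integer seed.
#' @return list with `encounters` (CSV-shaped data.frame: `individual_id`,
#'   `year`, `sex` M/F/U, `age` J/A, `detections`), `productivity`
#'   (`year`, `females`, `juveniles`), and `ledger` (true abundances,
#'   annual rates, and `lambda` per transition).
#' @export
simulate_population <- function(truth, weather, seed = 1) {
  years <- truth$years
  T <- length(years)
  wser <- weather_series(weather$daily, weather$espi_monthly,
                         years = sort(unique(weather$espi_monthly$year)))
  rates <- truth_annual_rates(truth, wser)

  growth <- max(rates$phi_a, na.rm = TRUE) +
    max(rates$fecundity) / 2 * max(rates$phi_j, na.rm = TRUE)
  exp_N <- (sum(truth$initial_N) + T * sum(truth$immigration_mean)) *
    max(1, growth)^T
  if (exp_N > truth$max_expected_N) {
    stop("explosive settings: expected population exceeds ",
         truth$max_expected_N, "; reduce survival or fecundity")
  }

  with_seed(seed, {
    next_id <- 1L
    new_ids <- function(n) {
      ids <- sprintf("ind%06d", seq.int(next_id, length.out = n))
      next_id <<- next_id + n
      ids
    }
    sexes <- c("male", "female")
    # adult pool: id, sex, banded year (NA if unbanded), sexed flag
    adults <- data.frame(
      id = new_ids(sum(truth$initial_N)),
      sex = rep(sexes, truth$initial_N),
      stringsAsFactors = FALSE)

    enc <- list(); prod_rows <- list()
    true_N <- matrix(NA_real_, 2, T, dimnames = list(sexes, years))
    surv_trials <- c(male = 0, female = 0)
    surv_success <- c(male = 0, female = 0)

    for (t in seq_len(T)) {
      y <- years[t]
      true_N[, t] <- c(sum(adults$sex == "male"),
                       sum(adults$sex == "female"))
      # adult detection
      p_det <- truth$p_a[adults$sex]
      det <- stats::runif(nrow(adults)) < p_det
      if (any(det)) {
        enc[[length(enc) + 1]] <- data.frame(
          individual_id = adults$id[det], year = y,
          sex = ifelse(adults$sex[det] == "male", "M", "F"),
          age = "A",
          detections = 1L + stats::rpois(sum(det), 0.5),
          stringsAsFactors = FALSE)
      }
      # births: per-sex Poisson around half the per-female total
      n_f <- sum(adults$sex == "female")
      born <- stats::rpois(2, n_f * rates$fecundity[t] / 2)
      juv <- data.frame(id = new_ids(sum(born)),
                        sex = rep(sexes, born),
                        stringsAsFactors = FALSE)
      # juveniles found by nest searches (banded in hatch year)
      jdet <- stats::runif(nrow(juv)) < 1 / truth$k_true
      juv$banded <- jdet
      if (any(jdet)) {
        sexed <- stats::runif(sum(jdet)) < truth$prob_juv_sexed
        enc[[length(enc) + 1]] <- data.frame(
          individual_id = juv$id[jdet], year = y,
          sex = ifelse(sexed, ifelse(juv$sex[jdet] == "male", "M", "F"),
                       "U"),
          age = "J", detections = 1L,
          stringsAsFactors = FALSE)
      }
      # the productivity female count is the nesting-female census (the
      # field protocol tallies nesting females whether or not identified),
      # so it tracks the female population, not female resight probability
      prod_rows[[length(prod_rows) + 1]] <-
        data.frame(year = y, females = n_f, juveniles = sum(jdet))

      if (t == T) break
      # survival over t -> t+1 and arrivals at t+1 use the rates labelled
      # by their end year t+1
      a_surv <- stats::runif(nrow(adults)) <
        rates$phi_a[cbind(match(adults$sex, sexes),
                          rep(t + 1L, nrow(adults)))]
      j_surv <- stats::runif(nrow(juv)) < rates$phi_j[
        cbind(match(juv$sex, sexes), rep(t + 1L, nrow(juv)))]
      imm_n <- stats::rpois(2, rates$immigration[, t + 1L])
      imm <- data.frame(id = new_ids(sum(imm_n)),
                        sex = rep(sexes, imm_n),
                        stringsAsFactors = FALSE)
      for (s in sexes) {
        surv_trials[s] <- surv_trials[s] + sum(adults$sex == s)
        surv_success[s] <- surv_success[s] + sum(a_surv & adults$sex == s)
      }
      adults <- rbind(adults[a_surv, c("id", "sex")],
                      juv[j_surv, c("id", "sex")],
                      imm)
    }

    encounters <- do.call(rbind, enc)
    # sex of juvenile-marked birds becomes known on any later (adult)
    # capture; earlier U records are then resolved by the ingest step
    productivity <- do.call(rbind, prod_rows)
    Ntot <- colSums(true_N)
    ledger <- list(
      true_N = true_N, true_N_total = Ntot,
      lambda = Ntot[-1] / Ntot[-T],
      rates = rates, truth = truth,
      realized_adult_survival = surv_success / pmax(surv_trials, 1),
      adult_survival_trials = surv_trials,
      years = years)
    list(encounters = encounters, productivity = productivity,
         ledger = ledger)
  })
}

#' Write a complete synthetic study fixture to disk
#'
#' Generates weather and population data for the requested profile and
#' writes every input file the pipeline reads — `encounters.csv`,
#' `productivity.csv`, `daily_weather.csv`, `espi_monthly.csv`,
#' `gcm_precip.csv` — plus `truth.json` (the generating parameters and the
#' true abundance/growth ledger) for recovery tests.
#'
#' @param profile profile name passed to [simulation_truth()].
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @param truth optionally a ready-made [simulation_truth()] (overrides
#'   `profile`).
#' @return invisibly, a list with the file paths and the in-memory objects.
#' @export
make_study_fixture <- function(profile = "paper-like", seed = 1,
                               out_dir = tempfile("fixture"),
                               truth = NULL) {
  if (is.null(truth)) truth <- simulation_truth(profile)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wyears <- (min(truth$years) - 2):max(truth$years)
  weather <- simulate_weather(wyears, truth$weather, seed = seed)
  pop <- simulate_population(truth, weather, seed = seed + 1L)

  paths <- list(
    encounters = file.path(out_dir, "encounters.csv"),
    productivity = file.path(out_dir, "productivity.csv"),
    daily_weather = file.path(out_dir, "daily_weather.csv"),
    espi_monthly = file.path(out_dir, "espi_monthly.csv"),
    gcm_precip = file.path(out_dir, "gcm_precip.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  utils::write.csv(pop$encounters, paths$encounters, row.names = FALSE)
  utils::write.csv(pop$productivity, paths$productivity, row.names = FALSE)
  utils::write.csv(weather$daily, paths$daily_weather, row.names = FALSE)
  utils::write.csv(weather$espi_monthly, paths$espi_monthly,
                   row.names = FALSE)
  utils::write.csv(weather$gcm, paths$gcm_precip, row.names = FALSE)
  led <- pop$ledger
  jsonlite::write_json(
    list(profile = truth$profile, seed = seed, years = led$years,
         phi_a_annual_mean = as.list(rowMeans(led$rates$phi_a[, -1])),
         phi_j_annual_mean = as.list(rowMeans(led$rates$phi_j[, -1])),
         phi_a = as.list(truth$phi_a), phi_j = as.list(truth$phi_j),
         p_a = as.list(truth$p_a), p_j = as.list(truth$p_j),
         fecundity = truth$fecundity, k_true = truth$k_true,
         immigration_mean = as.list(truth$immigration_mean),
         true_N_total = unname(led$true_N_total),
         true_lambda = unname(led$lambda)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth, weather = weather,
                 population = pop))
}
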