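#' Construct an annual vital-rate series
#'
#' Bundles the annual vital rates driving the deterministic stage model:
#' sex-specific adult and juvenile apparent survival per transition,
#' fecundity of the season preceding each transition, immigrant counts per
#' arrival year, and the initial abundance per sex.
#'
#' @param phi_a,phi_j 2 x (T-1) matrices (rows male, female) of apparent
#'   survival per transition, or length-2 vectors for constant rates (then
#'   `n_years` must be given).
#' @param F_prev length T-1 fecundity applying to each transition (offspring
#'   per female in the season before the transition), or a scalar.
#' @param I_m,I_f length T-1 immigrant counts per transition, or scalars.
#' @param N0 named `c(male =, female =)` initial abundances.
#' @param n_years total number of years T (needed when rates are scalar).
#' @param years optional calendar years (length T).
#' @return list of class `vital_rate_series`.
#' @export
vital_rate_series <- function(phi_a, phi_j, F_prev, I_m = 0, I_f = 0, N0,
                              n_years = NULL, years = NULL) {
  to_mat <- function(x, Tm1) {
    if (is.matrix(x)) x else matrix(rep(as_sex_vec(x), Tm1), nrow = 2)
  }
  if (is.matrix(phi_a)) {
    Tm1 <- ncol(phi_a)
  } else {
    if (is.null(n_years)) stop("give n_years when rates are scalar")
    Tm1 <- n_years - 1
  }
  phi_a <- to_mat(phi_a, Tm1); phi_j <- to_mat(phi_j, Tm1)
  F_prev <- rep_len(F_prev, Tm1)
  I_m <- rep_len(I_m, Tm1); I_f <- rep_len(I_f, Tm1)
  if (any(phi_a < 0 | phi_a > 1) || any(phi_j < 0 | phi_j > 1)) {
    stop("survival probabilities must lie in [0, 1]")
  }
  if (any(F_prev < 0) || any(I_m < 0) || any(I_f < 0)) {
    stop("fecundity and immigration must be nonnegative")
  }
  N0 <- as_sex_vec(N0)
  if (any(N0 < 0)) stop("initial abundances must be nonnegative")
  structure(list(phi_a = phi_a, phi_j = phi_j, F_prev = F_prev,
                 I = rbind(male = I_m, female = I_f), N0 = N0,
                 n_years = Tm1 + 1L,
                 years = if (is.null(years)) seq_len(Tm1 + 1L) else years),
            class = "vital_rate_series")
}

#' Deterministic two-sex stage-model projection
#'
#' Expectation dynamics of the three-stage bookkeeping model: for each sex
#' `s` and transition into year `t`,
#' `N_{s,t} = I_{s,t} + N_{s,t-1} * phi_a_{s,t} + N_{f,t-1} * F_{t-1} * 1/2 * phi_j_{s,t}`.
#' Immigrants, surviving adults, and locally produced recruits (per-female
#' fecundity split 1:1 between offspring sexes) are summed per sex and
#' across sexes.
#'
#' @param series a [vital_rate_series()].
#' @return data.frame with `year`, `N_male`, `N_female`, `N_total`.
#' @export
project_stage_model <- function(series) {
  Tn <- series$n_years
  N <- matrix(NA_real_, 2, Tn, dimnames = list(c("male", "female"), NULL))
  N[, 1] <- series$N0
  for (t in 2:Tn) {
    rec_base <- N["female", t - 1] * series$F_prev[t - 1] * 0.5
    for (s in 1:2) {
      N[s, t] <- series$I[s, t - 1] +
        N[s, t - 1] * series$phi_a[s, t - 1] +
        rec_base * series$phi_j[s, t - 1]
    }
  }
  data.frame(year = series$years, N_male = N[1, ], N_female = N[2, ],
             N_total = colSums(N))
}

#' Annual population growth rates
#'
#' `lambda_t = N_t / N_{t-1}` for a series of (total) abundances.
#'
#' @param N numeric abundance series, all positive.
#' @return numeric vector of length `length(N) - 1`.
#' @export
annual_lambda <- function(N) {
  if (any(N[-length(N)] <= 0)) stop("abundances must be positive")
  N[-1] / N[-length(N)]
}

#' Stochastic (geometric-mean) growth rate
#'
#' `lambda_s = (prod lambda_t)^(1/T)`, computed on the log scale for
#' numerical stability.
#'
#' @param lambda vector of annual growth rates, all positive.
#' @return scalar geometric mean.
#' @export
geometric_mean_lambda <- function(lambda) {
  if (any(lambda <= 0)) stop("annual growth rates must be positive")
  exp(mean(log(lambda)))
}

#' Names of the perturbable vital rates
#' @return character vector accepted by [perturbation_sensitivity()].
#' @export
vital_rate_names <- function() {
  c("phi_a_male", "phi_a_female", "phi_j_male", "phi_j_female",
    "fecundity", "immigration_male", "immigration_female")
}

# apply a proportional perturbation to one named rate of a series;
# probabilities are clipped to [0, 1] with a warning
perturb_series <- function(series, rate_name, delta) {
  s2 <- series
  bump <- function(x) x * (1 + delta)
  clip <- function(x) {
    if (any(x > 1)) {
      warning("perturbed survival clipped to 1 for rate ", rate_name)
      x[x > 1] <- 1
    }
    x
  }
  switch(rate_name,
    phi_a = { s2$phi_a <- clip(bump(s2$phi_a)) },
    phi_a_male = { s2$phi_a[1, ] <- clip(bump(s2$phi_a[1, ])) },
    phi_a_female = { s2$phi_a[2, ] <- clip(bump(s2$phi_a[2, ])) },
    phi_j = { s2$phi_j <- clip(bump(s2$phi_j)) },
    phi_j_male = { s2$phi_j[1, ] <- clip(bump(s2$phi_j[1, ])) },
    phi_j_female = { s2$phi_j[2, ] <- clip(bump(s2$phi_j[2, ])) },
    fecundity = { s2$F_prev <- bump(s2$F_prev) },
    immigration = { s2$I <- bump(s2$I) },
    immigration_male = { s2$I[1, ] <- bump(s2$I[1, ]) },
    immigration_female = { s2$I[2, ] <- bump(s2$I[2, ]) },
    stop("unknown vital rate: ", rate_name)
  )
  s2
}

# values of the named rate as a plain vector (for the delta-v denominator)
rate_values <- function(series, rate_name) {
  switch(rate_name,
    phi_a = as.vector(series$phi_a),
    phi_a_male = series$phi_a[1, ],
    phi_a_female = series$phi_a[2, ],
    phi_j = as.vector(series$phi_j),
    phi_j_male = series$phi_j[1, ],
    phi_j_female = series$phi_j[2, ],
    fecundity = series$F_prev,
    immigration = as.vector(series$I),
    immigration_male = series$I[1, ],
    immigration_female = series$I[2, ],
    stop("unknown vital rate: ", rate_name)
  )
}

#' Perturbation sensitivity and elasticity of the stochastic growth rate
#'
#' Perturbs every annual estimate of one vital rate by a fixed proportion
#' (default 5%), reprojects the stage model, and recomputes the
#' geometric-mean growth rate. Sensitivity is the absolute response per unit
#' of (mean absolute) change in the rate,
#' `(lambda_s' - lambda_s) / mean(|v' - v|)`; elasticity is the proportional
#' response per proportional change, `((lambda_s' - lambda_s)/lambda_s) / delta`.
#'
#' A rate that is identically zero cannot be perturbed proportionally; its
#' sensitivity and elasticity are reported as 0 with a warning (for
#' immigration, use `additive_fallback = TRUE` to perturb by one individual
#' instead).
#'
#' @param series a [vital_rate_series()].
#' @param rate_name one of [vital_rate_names()], or the pooled names
#'   `"phi_a"`, `"phi_j"`, `"immigration"` (both sexes at once).
#' @param delta proportional perturbation (default 0.05).
#' @param drop_first_transition drop the first annual transition from
#'   `lambda_s` (the study's first transition is atypically high and can be
#'   treated separately).
#' @param additive_fallback for an identically-zero immigration series,
#'   perturb by +1 individual per year instead of proportionally.
#' @return list with `sensitivity`, `elasticity`, `lambda_s`,
#'   `lambda_s_perturbed`, and `delta_v_mean`.
#' @export
perturbation_sensitivity <- function(series, rate_name, delta = 0.05,
                                     drop_first_transition = FALSE,
                                     additive_fallback = FALSE) {
  lam_s_of <- function(ser) {
    N <- project_stage_model(ser)$N_total
    lam <- annual_lambda(N)
    if (drop_first_transition) lam <- lam[-1]
    geometric_mean_lambda(lam)
  }
  v0 <- rate_values(series, rate_name)
  lam0 <- lam_s_of(series)

  if (all(v0 == 0)) {
    if (additive_fallback && grepl("immigration", rate_name)) {
      s2 <- series
      if (rate_name == "immigration") s2$I <- s2$I + 1
      if (rate_name == "immigration_male") s2$I[1, ] <- s2$I[1, ] + 1
      if (rate_name == "immigration_female") s2$I[2, ] <- s2$I[2, ] + 1
      lam1 <- lam_s_of(s2)
      warning("zero immigration: additive +1 perturbation used; ",
              "elasticity not defined, reported as NA")
      return(list(sensitivity = (lam1 - lam0) / 1,
                  elasticity = NA_real_, lambda_s = lam0,
                  lambda_s_perturbed = lam1, delta_v_mean = 1))
    }
    warning("rate ", rate_name, " is identically 0; proportional ",
            "perturbation is degenerate, sensitivity reported as 0")
    return(list(sensitivity = 0, elasticity = 0, lambda_s = lam0,
                lambda_s_perturbed = lam0, delta_v_mean = 0))
  }

  s2 <- perturb_series(series, rate_name, delta)
  v1 <- rate_values(s2, rate_name)
  lam1 <- lam_s_of(s2)
  dv <- mean(abs(v1 - v0))
  list(sensitivity = (lam1 - lam0) / dv,
       elasticity = ((lam1 - lam0) / lam0) / delta,
       lambda_s = lam0, lambda_s_perturbed = lam1, delta_v_mean = dv)
}

#' Sensitivity/elasticity table for all vital rates
#'
#' Runs [perturbation_sensitivity()] for every rate in
#' [vital_rate_names()].
#'
#' @inheritParams perturbation_sensitivity
#' @return data.frame `rate`, `sensitivity`, `elasticity`, `lambda_s`.
#' @export
sensitivity_table <- function(series, delta = 0.05,
                              drop_first_transition = FALSE) {
  rows <- lapply(vital_rate_names(), function(rn) {
    res <- perturbation_sensitivity(series, rn, delta = delta,
                                    drop_first_transition =
                                      drop_first_transition)
    data.frame(rate = rn, sensitivity = res$sensitivity,
               elasticity = res$elasticity, lambda_s = res$lambda_s)
  })
  do.call(rbind, rows)
}

#' Vital-rate series from the posterior means of a fitted IPM
#'
#' @param post an `ipm_posterior`.
#' @return a [vital_rate_series()] built from posterior-mean annual rates,
#'   immigrant counts, and initial abundances.
#' @export
vital_series_from_posterior <- function(post) {
  dr <- extract_vital_draws(post)
  vital_rate_series(
    phi_a = apply(dr$phi_a, c(2, 3), mean),
    phi_j = apply(dr$phi_j, c(2, 3), mean),
    F_prev = colMeans(dr$F)[-ncol(dr$F)],
    I_m = apply(dr$I, c(2, 3), mean)[1, ],
    I_f = apply(dr$I, c(2, 3), mean)[2, ],
    N0 = c(male = mean(dr$N[, 1, 1]), female = mean(dr$N[, 2, 1])),
    years = post$years
  )
}
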