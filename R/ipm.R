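#' Prior specification for the integrated population model
#'
#' All vital-rate priors are uniform on the scales the field literature
#' supports: adult apparent survival 0.3-0.9, juvenile apparent survival
#' 0.1-0.5 (roughly half the adult rate), recapture probability 0-1 for
#' adult males, 0-0.5 for juvenile males, 0-0.3 for females of both ages,
#' 0-175 immigrants per sex per year, 0-14 offspring per female, a
#' juvenile-detection denominator k between 1 and 3 (nest searches find
#' between a third and all juveniles), and an initial population size of
#' 80-350 individuals (split evenly across the two sexes as 40-175 each).
#'
#' @param adult_survival,juvenile_survival length-2 (lower, upper) bounds on
#'   apparent survival probabilities.
#' @param p_adult_male,p_juvenile_male,p_female bounds on recapture
#'   probabilities (`p_female` applies to both female age classes).
#' @param immigration bounds on the integer number of immigrants per sex per
#'   year.
#' @param fecundity bounds on offspring per female per year.
#' @param k bounds on the fecundity denominator.
#' @param initial_N bounds on total initial population size (individuals).
#' @return list of class `ipm_priors`.
#' @export
ipm_priors <- function(adult_survival = c(0.3, 0.9),
                       juvenile_survival = c(0.1, 0.5),
                       p_adult_male = c(0, 1),
                       p_juvenile_male = c(0, 0.5),
                       p_female = c(0, 0.3),
                       immigration = c(0, 175),
                       fecundity = c(0, 14),
                       k = c(1, 3),
                       initial_N = c(80, 350)) {
  pr <- list(adult_survival = adult_survival,
             juvenile_survival = juvenile_survival,
             p_adult_male = p_adult_male,
             p_juvenile_male = p_juvenile_male,
             p_female = p_female,
             immigration = immigration,
             fecundity = fecundity,
             k = k,
             initial_N = initial_N)
  for (nm in names(pr)) {
    b <- pr[[nm]]
    if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2]) {
      stop("prior '", nm, "' must be numeric (lower, upper) with lower < upper")
    }
  }
  prob <- c("adult_survival", "juvenile_survival", "p_adult_male",
            "p_juvenile_male", "p_female")
  for (nm in prob) {
    if (pr[[nm]][1] < 0 || pr[[nm]][2] > 1) {
      stop("probability prior '", nm, "' must lie within [0, 1]")
    }
  }
  structure(pr, class = "ipm_priors")
}

#' MCMC settings
#'
#' Defaults mirror the full analysis (three chains of 1,500,000 iterations,
#' burn-in 750,000, thinning 100). `mcmc_config(fast = TRUE)` gives the
#' desk-scale profile (3 x 20,000, burn-in 10,000, thin 10) used by the test
#' suite and simulation studies.
#'
#' @param n_chains,n_iterations,burn_in,thin MCMC dimensions.
#' @param seed integer seed driving all chains.
#' @param fast use the reduced desk-scale profile.
#' @return list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iterations = 1500000,
                        burn_in = 750000, thin = 100, seed = 1,
                        fast = FALSE) {
  if (fast) {
    n_iterations <- 20000; burn_in <- 10000; thin <- 10
  }
  if (burn_in >= n_iterations) stop("burn_in must be < n_iterations")
  if (thin < 1) stop("thin must be >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Poisson productivity log-likelihood
#'
#' Log-probability of the annual juvenile counts `J_t` given female counts
#' `B_t`, fecundity `F_t`, and the shared detection denominator `k`:
#' `J_t ~ Poisson(B_t * F_t / k)`. `k > 1` models juveniles being missed by
#' nest searches (only a fraction 1/k of juveniles is recorded).
#'
#' @param J,B integer vectors per year.
#' @param F_t fecundity per year (scalar recycled).
#' @param k detection denominator in `[1, 3]`.
#' @return scalar log-likelihood (can be `-Inf` when a zero mean meets a
#'   positive count).
#' @export
productivity_log_likelihood <- function(J, B, F_t, k) {
  if (k < 1 || k > 3) stop("k must lie in [1, 3]")
  if (any(F_t < 0)) stop("fecundity must be nonnegative")
  if (any(J < 0) || any(B < 0)) stop("counts must be nonnegative")
  mu <- B * F_t / k
  ll <- stats::dpois(J, mu, log = TRUE)
  # dpois(0, 0) = 1; dpois(j>0, 0) = 0 -> -Inf, which is the honest value
  sum(ll)
}

#' Sample one year of the two-sex, three-stage state process
#'
#' Demographically stochastic transition: per sex, survivors
#' `S ~ Binomial(N_prev, phi_a)`, locally produced recruits
#' `R ~ Poisson(N_female_prev * F_prev * 1/2 * phi_j)` (the 1/2 is the
#' offspring sex ratio), plus immigrants `I`. Returns component and total
#' abundances.
#'
#' @param N_prev named numeric `c(male =, female =)` previous abundances.
#' @param phi_a,phi_j named length-2 survival probabilities per sex.
#' @param F_prev fecundity of the previous breeding season.
#' @param I named length-2 immigrant counts for the focal year.
#' @param n number of independent samples.
#' @return list with `S`, `R`, `I`, `N` (each n x 2 matrices, columns male /
#'   female) and `N_total` (length n).
#' @export
state_transition_sample <- function(N_prev, phi_a, phi_j, F_prev, I, n = 1) {
  N_prev <- as_sex_vec(N_prev); phi_a <- as_sex_vec(phi_a)
  phi_j <- as_sex_vec(phi_j); I <- as_sex_vec(I)
  if (any(N_prev < 0)) stop("N_prev must be nonnegative")
  if (F_prev < 0) stop("F_prev must be nonnegative")
  S <- cbind(male = stats::rbinom(n, N_prev["male"], phi_a["male"]),
             female = stats::rbinom(n, N_prev["female"], phi_a["female"]))
  mu <- N_prev["female"] * F_prev * 0.5
  R <- cbind(male = stats::rpois(n, mu * phi_j["male"]),
             female = stats::rpois(n, mu * phi_j["female"]))
  Im <- matrix(rep(I, each = n), ncol = 2,
               dimnames = list(NULL, c("male", "female")))
  N <- S + R + Im
  list(S = S, R = R, I = Im, N = N, N_total = rowSums(N))
}

as_sex_vec <- function(x) {
  if (is.null(names(x))) names(x) <- c("male", "female")
  x[c("male", "female")]
}

# JAGS model for the integrated population model. The CJS component uses
# four m-arrays (sex x age-at-release); birds released as juveniles survive
# their first interval at the juvenile rate and are detected at the first
# occasion after marking with the juvenile recapture probability, adult
# rates thereafter. include_likelihood = FALSE strips every observation
# node, leaving the priors (used to validate prior sampling).
jags_ipm_string <- function(include_likelihood = TRUE) {
  lik_counts <- "
  for (t in 1:T) {
    y[t] ~ dpois(Ntot[t])
  }"
  lik_prod <- "
  for (t in 1:T) {
    J[t] ~ dpois(B[t] * F[t] / k + 1.0E-10)
  }"
  lik_cjs <- "
  for (g in 1:4) {
    for (r in 1:(T-1)) {
      marr[g, r, 1:T] ~ dmulti(pr[g, r, 1:T], rel[g, r])
    }
  }"
  paste0("
model {
  # ---- priors: vital rates ----
  for (s in 1:2) {
    for (t in 1:(T-1)) {
      phi_a[s, t] ~ dunif(phi_a_lo, phi_a_hi)
      phi_j[s, t] ~ dunif(phi_j_lo, phi_j_hi)
    }
  }
  p_a[1] ~ dunif(p_am_lo, p_am_hi)
  p_a[2] ~ dunif(p_f_lo, p_f_hi)
  p_j[1] ~ dunif(p_jm_lo, p_jm_hi)
  p_j[2] ~ dunif(p_f_lo, p_f_hi)
  for (t in 1:T) {
    F[t] ~ dunif(F_lo, F_hi)
  }
  k ~ dunif(k_lo, k_hi)

  # ---- priors: immigrants and initial abundance (discrete uniform) ----
  for (s in 1:2) {
    for (t in 2:T) {
      Icat[s, t] ~ dcat(pI[1:nI])
      I[s, t] <- Icat[s, t] - 1 + I_lo
    }
    N1cat[s] ~ dcat(pN[1:nN])
    N[s, 1] <- N1cat[s] - 1 + N1_lo
  }

  # ---- state process: two sexes, three stages ----
  for (t in 2:T) {
    for (s in 1:2) {
      S[s, t] ~ dbin(phi_a[s, t-1], N[s, t-1])
      R[s, t] ~ dpois(0.5 * N[2, t-1] * F[t-1] * phi_j[s, t-1] + 1.0E-10)
      N[s, t] <- S[s, t] + R[s, t] + I[s, t]
    }
  }
  for (t in 1:T) {
    Ntot[t] <- N[1, t] + N[2, t]
  }
  for (t in 2:T) {
    lambda[t-1] <- Ntot[t] / Ntot[t-1]
  }

  # ---- CJS m-array cell probabilities ----
  for (g in 1:4) {
    for (r in 1:(T-1)) {
      fs[g, r] <- isjuv[g] * phi_j[sx[g], r] + (1 - isjuv[g]) * phi_a[sx[g], r]
    }
    pf[g] <- isjuv[g] * p_j[sx[g]] + (1 - isjuv[g]) * p_a[sx[g]]
    for (r in 1:(T-1)) {
      pr[g, r, r] <- fs[g, r] * pf[g]
      U[g, r, r] <- fs[g, r] * (1 - pf[g])
    }
    for (j in 2:(T-1)) {
      for (r in 1:(j-1)) {
        pr[g, r, j] <- U[g, r, j-1] * phi_a[sx[g], j] * p_a[sx[g]]
        U[g, r, j] <- U[g, r, j-1] * phi_a[sx[g], j] * (1 - p_a[sx[g]])
      }
    }
    for (r in 2:(T-1)) {
      for (j in 1:(r-1)) {
        pr[g, r, j] <- 0
      }
    }
    for (r in 1:(T-1)) {
      pr[g, r, T] <- 1 - sum(pr[g, r, 1:(T-1)])
    }
  }
", if (include_likelihood) paste0("
  # ---- observation models ----", lik_counts, lik_prod, lik_cjs), "
}
")
}

#' Fit the integrated population model
#'
#' Joins the three datasets — annual counts (Poisson observation around the
#' latent total), capture histories (CJS, via sex x age m-arrays), and
#' productivity (Poisson regression with the detection denominator k) —
#' under the shared two-sex, three-stage (recruits, surviving adults,
#' immigrants) state process, and samples the joint posterior with JAGS.
#'
#' @param counts data.frame `year`, `count` from [build_counts()].
#' @param histories `capture_histories` object covering the same years.
#' @param productivity data.frame `year`, `B`, `J`.
#' @param priors an [ipm_priors()] object.
#' @param config an [mcmc_config()] object.
#' @param include_likelihood set `FALSE` to sample the priors only (no
#'   observation nodes); used for validation.
#' @param quiet suppress JAGS progress output.
#' @return object of class `ipm_posterior`: a list with `draws` (the
#'   combined draws matrix, one row per retained sample), `mcmc` (the coda
#'   `mcmc.list`), `years`, `n_draws`, `rhat` (potential scale reduction per
#'   scalar parameter), `priors`, `config`.
#' @export
fit_ipm <- function(counts, histories, productivity, priors = ipm_priors(),
                    config = mcmc_config(fast = TRUE),
                    include_likelihood = TRUE, quiet = TRUE) {
  years <- histories$years
  T <- length(years)
  if (T < 3) stop("need at least 3 annual occasions")
  if (!identical(as.integer(counts$year), as.integer(years)) ||
      !identical(as.integer(productivity$year), as.integer(years))) {
    stop("counts, histories, and productivity must cover the same years, ",
         "in order")
  }

  marr_list <- build_marray(histories)
  marr <- array(0, dim = c(4, T - 1, T))
  for (g in 1:4) marr[g, , ] <- marr_list[[g]]
  rel <- apply(marr, c(1, 2), sum)

  pr <- priors
  nI <- as.integer(pr$immigration[2] - pr$immigration[1] + 1)
  # per-sex initial abundance: half the stated total bounds
  N1_lo <- as.integer(ceiling(pr$initial_N[1] / 2))
  N1_hi <- as.integer(floor(pr$initial_N[2] / 2))
  nN <- N1_hi - N1_lo + 1L

  dat <- list(
    T = T,
    sx = c(1L, 2L, 1L, 2L),       # group order: juv_m, juv_f, ad_m, ad_f
    isjuv = c(1L, 1L, 0L, 0L),
    phi_a_lo = pr$adult_survival[1], phi_a_hi = pr$adult_survival[2],
    phi_j_lo = pr$juvenile_survival[1], phi_j_hi = pr$juvenile_survival[2],
    p_am_lo = pr$p_adult_male[1], p_am_hi = pr$p_adult_male[2],
    p_jm_lo = pr$p_juvenile_male[1], p_jm_hi = pr$p_juvenile_male[2],
    p_f_lo = pr$p_female[1], p_f_hi = pr$p_female[2],
    F_lo = pr$fecundity[1], F_hi = pr$fecundity[2],
    k_lo = pr$k[1], k_hi = pr$k[2],
    I_lo = as.integer(pr$immigration[1]),
    pI = rep(1 / nI, nI), nI = nI,
    pN = rep(1 / nN, nN), nN = nN, N1_lo = N1_lo
  )
  if (include_likelihood) {
    dat$y <- as.integer(counts$count)
    dat$J <- as.integer(productivity$J)
    dat$B <- as.integer(productivity$B)
    dat$marr <- marr
    dat$rel <- rel
  }

  inits <- lapply(seq_len(config$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = config$seed * 1000L + ch)
  })

  model <- rjags::jags.model(
    textConnection(jags_ipm_string(include_likelihood)),
    data = dat, inits = inits, n.chains = config$n_chains,
    n.adapt = min(1000L, config$burn_in), quiet = quiet)
  post_adapt_burn <- config$burn_in - min(1000L, config$burn_in)
  if (post_adapt_burn > 0) {
    stats::update(model, post_adapt_burn,
                  progress.bar = if (quiet) "none" else "text")
  }
  monitors <- c("phi_a", "phi_j", "p_a", "p_j", "F", "k", "I", "N", "Ntot",
                "lambda")
  mcmc <- rjags::coda.samples(
    model, monitors, n.iter = config$n_iterations - config$burn_in,
    thin = config$thin, progress.bar = if (quiet) "none" else "text")

  draws <- as.matrix(mcmc)
  rhat <- tryCatch({
    gd <- coda::gelman.diag(mcmc, autoburnin = FALSE, multivariate = FALSE)
    stats::setNames(gd$psrf[, 1], rownames(gd$psrf))
  }, error = function(e) NULL)
  if (!is.null(rhat)) {
    bad <- rhat[is.finite(rhat) & rhat > 1.1]
    if (include_likelihood && length(bad) > 0) {
      warning("potential scale reduction > 1.1 for ", length(bad),
              " parameter(s); consider a longer run. Worst: ",
              paste(utils::head(names(sort(bad, decreasing = TRUE)), 3),
                    collapse = ", "))
    }
  }

  structure(list(draws = draws, mcmc = mcmc, years = as.integer(years),
                 n_draws = nrow(draws), rhat = rhat, priors = priors,
                 config = config),
            class = "ipm_posterior")
}

#' Extract posterior draws as named arrays
#'
#' Reshapes the flat draws matrix of an `ipm_posterior` into arrays indexed
#' by draw, sex, and year: `phi_a`, `phi_j` (draw x sex x interval), `p_a`,
#' `p_j` (draw x sex), `F` (draw x year), `k` (draw), `I` (draw x sex x
#' year, first year `NA`), `N` (draw x sex x year), `Ntot` (draw x year),
#' `lambda` (draw x transition).
#'
#' @param post an `ipm_posterior`.
#' @return list of arrays; year dimnames use calendar years.
#' @export
extract_vital_draws <- function(post) {
  dr <- post$draws
  years <- post$years
  T <- length(years)
  nd <- nrow(dr)
  sexes <- c("male", "female")
  grab2 <- function(name, cols, colnames2) {
    a <- array(NA_real_, dim = c(nd, 2, length(cols)),
               dimnames = list(NULL, sexes, colnames2))
    for (s in 1:2) for (ci in seq_along(cols)) {
      a[, s, ci] <- dr[, sprintf("%s[%d,%d]", name, s, cols[ci])]
    }
    a
  }
  out <- list(
    phi_a = grab2("phi_a", 1:(T - 1), years[-1]),
    phi_j = grab2("phi_j", 1:(T - 1), years[-1]),
    N = grab2("N", 1:T, years),
    I = grab2("I", 2:T, years[-1]),
    p_a = cbind(male = dr[, "p_a[1]"], female = dr[, "p_a[2]"]),
    p_j = cbind(male = dr[, "p_j[1]"], female = dr[, "p_j[2]"]),
    F = dr[, sprintf("F[%d]", 1:T), drop = FALSE],
    k = dr[, "k"],
    Ntot = dr[, sprintf("Ntot[%d]", 1:T), drop = FALSE],
    lambda = dr[, sprintf("lambda[%d]", 1:(T - 1)), drop = FALSE]
  )
  colnames(out$F) <- years
  colnames(out$Ntot) <- years
  colnames(out$lambda) <- years[-1]
  out
}

#' Summarise an IPM posterior
#'
#' Posterior mean, median, and central credible interval for every monitored
#' parameter, keyed by parameter name, sex, and calendar year where
#' applicable.
#'
#' @param post an `ipm_posterior`.
#' @param level credible-interval probability (default 0.95).
#' @return data.frame with columns `parameter`, `sex`, `year`, `mean`,
#'   `median`, `lower`, `upper`, `rhat`.
#' @export
summarize_posterior <- function(post, level = 0.95) {
  if (post$n_draws < 2) stop("need at least 2 retained draws")
  dr <- post$draws
  alpha <- (1 - level) / 2
  qs <- apply(dr, 2, stats::quantile, probs = c(alpha, 0.5, 1 - alpha),
              names = FALSE)
  years <- post$years
  T <- length(years)
  nm <- colnames(dr)
  base <- sub("\\[.*", "", nm)
  sexes <- c("male", "female")
  sex <- rep(NA_character_, length(nm))
  year <- rep(NA_integer_, length(nm))
  for (ci in seq_along(nm)) {
    idx <- sub("\\]$", "", sub("^[^\\[]*\\[?", "", nm[ci]))
    if (idx == "") next
    ii <- as.integer(strsplit(idx, ",")[[1]])
    b <- base[ci]
    if (length(ii) == 2) {
      sex[ci] <- sexes[ii[1]]
      # survival indices label the interval by its end year
      year[ci] <- if (b %in% c("phi_a", "phi_j")) years[ii[2] + 1L]
                  else years[ii[2]]
    } else if (b %in% c("p_a", "p_j")) {
      sex[ci] <- sexes[ii[1]]
    } else if (b == "lambda") {
      year[ci] <- years[ii[1] + 1L]
    } else {
      year[ci] <- years[ii[1]]
    }
  }
  data.frame(parameter = base, sex = sex, year = year,
             mean = colMeans(dr), median = qs[2, ],
             lower = qs[1, ], upper = qs[3, ],
             rhat = if (is.null(post$rhat)) NA_real_ else
               unname(post$rhat[nm]),
             row.names = NULL)
}
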