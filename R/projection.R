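#' Fit the growth-rate vs lagged-precipitation regression
#'
#' Ordinary least squares of annual growth rate `lambda_t` on the 2-year
#' lagged May-August precipitation total (the projectable proxy for the
#' lagged ESPI covariate). The residual standard deviation feeds the
#' stochastic projection mode.
#'
#' @param lambda annual growth rates (one per transition).
#' @param precip_lag2 lagged precipitation (mm) aligned with `lambda`;
#'   pairs with an `NA` on either side are dropped.
#' @return list of class `lambda_climate_model`: `intercept`, `slope` (per
#'   mm), `residual_sd`, `n`, `data` (the fitted pairs).
#' @export
fit_lambda_regression <- function(lambda, precip_lag2) {
  keep <- is.finite(lambda) & is.finite(precip_lag2)
  if (sum(keep) < 3) stop("need at least 3 aligned (lambda, precip) pairs")
  fit <- stats::lm(lambda[keep] ~ precip_lag2[keep])
  co <- unname(stats::coef(fit))
  rsd <- sqrt(sum(stats::resid(fit)^2) / stats::df.residual(fit))
  structure(list(intercept = co[1], slope = co[2],
                 residual_sd = if (is.finite(rsd)) rsd else 0,
                 n = sum(keep),
                 data = data.frame(lambda = lambda[keep],
                                   precip_lag2 = precip_lag2[keep])),
            class = "lambda_climate_model")
}

#' Project population size under per-GCM precipitation
#'
#' For each GCM, predicts `lambda_t = intercept + slope * precip_{t-2}` for
#' every projection year (`precip` is the GCM's May-August total two years
#' earlier), optionally adds a regression residual draw
#' (`mode = "stochastic"`), truncates `lambda` below at 0, and accumulates
#' `N_t = lambda_t * N_{t-1}` from `N_start`.
#'
#' @param model a `lambda_climate_model`.
#' @param gcm_precip data.frame with columns `gcm`, `year`, `precip_mm`;
#'   must cover `(start_year - lag) .. (end_year - lag)` for every GCM.
#' @param N_start starting population size (individuals), anchored at
#'   `start_year - 1`.
#' @param start_year,end_year projection span (defaults 2021-2100).
#' @param mode `"deterministic"` (no residual noise) or `"stochastic"`.
#' @param n_replicates stochastic replicates per GCM.
#' @param seed integer seed (stochastic mode).
#' @param lag precipitation lag in years (default 2).
#' @return object of class `projection_ensemble`: list with `lambda` and
#'   `N` (year x trajectory matrices; one column per GCM, or per GCM x
#'   replicate in stochastic mode), `years`, `gcms`, `mode`, `N_start`.
#' @export
project_population <- function(model, gcm_precip, N_start,
                               start_year = 2021, end_year = 2100,
                               mode = c("deterministic", "stochastic"),
                               n_replicates = 1, seed = 1, lag = 2) {
  mode <- match.arg(mode)
  if (N_start < 0) stop("N_start must be nonnegative")
  years <- start_year:end_year
  need <- (start_year - lag):(end_year - lag)
  gcms <- sort(unique(gcm_precip$gcm))
  P <- matrix(NA_real_, nrow = length(need), ncol = length(gcms),
              dimnames = list(need, gcms))
  for (g in gcms) {
    sub <- gcm_precip[gcm_precip$gcm == g, , drop = FALSE]
    P[, g] <- sub$precip_mm[match(need, sub$year)]
  }
  if (anyNA(P)) {
    bad <- which(is.na(P), arr.ind = TRUE)
    stop("missing lag-source precipitation, e.g. GCM ",
         gcms[bad[1, 2]], " year ", need[bad[1, 1]])
  }
  nrep <- if (mode == "stochastic") n_replicates else 1L
  ntraj <- length(gcms) * nrep
  lam <- matrix(NA_real_, length(years), ntraj)
  traj_names <- character(ntraj)
  if (mode == "stochastic") set.seed(seed)
  col <- 0L
  for (g in gcms) {
    mu <- model$intercept + model$slope * P[, g]
    for (r in seq_len(nrep)) {
      col <- col + 1L
      lam_col <- mu
      if (mode == "stochastic" && model$residual_sd > 0) {
        lam_col <- mu + stats::rnorm(length(mu), 0, model$residual_sd)
      }
      lam[, col] <- pmax(lam_col, 0)
      traj_names[col] <- if (nrep > 1) paste0(g, "_rep", r) else g
    }
  }
  dimnames(lam) <- list(years, traj_names)
  N <- apply(lam, 2, function(l) N_start * cumprod(l))
  dimnames(N) <- dimnames(lam)
  structure(list(lambda = lam, N = N, years = years, gcms = gcms,
                 mode = mode, N_start = N_start),
            class = "projection_ensemble")
}

#' Summarise a projection ensemble
#'
#' Per-year median, mean, and central 95% prediction interval of population
#' size across trajectories (GCMs, and replicates in stochastic mode), plus
#' the overall arithmetic mean annual growth rate with its 95% interval
#' across all projected year x trajectory values.
#'
#' @param ensemble a `projection_ensemble`.
#' @param level interval probability (default 0.95).
#' @return list with `by_year` (data.frame `year`, `median_N`, `mean_N`,
#'   `lower_N`, `upper_N`) and `lambda_overall` (named vector `mean`,
#'   `lower`, `upper`).
#' @export
summarize_ensemble <- function(ensemble, level = 0.95) {
  alpha <- (1 - level) / 2
  N <- ensemble$N
  by_year <- data.frame(
    year = ensemble$years,
    median_N = apply(N, 1, stats::median),
    mean_N = rowMeans(N),
    lower_N = apply(N, 1, stats::quantile, probs = alpha),
    upper_N = apply(N, 1, stats::quantile, probs = 1 - alpha)
  )
  lam <- as.vector(ensemble$lambda)
  lambda_overall <- c(mean = mean(lam),
                      lower = unname(stats::quantile(lam, alpha)),
                      upper = unname(stats::quantile(lam, 1 - alpha)))
  list(by_year = by_year, lambda_overall = lambda_overall)
}
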